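#' Build a circuit reaction network
#'
#' Assembles the reaction set for one circuit topology: species list,
#' stoichiometry matrix, propensity definitions (used both for the
#' deterministic ODE right-hand side and for exact stochastic simulation),
#' and the parameter set. Transcription of NF-containing topologies is
#' repressed by active TetR through a Hill law with leakage; doxycycline
#' inactivates TetR (`TetR_active = TetR / (1 + (dox/K_dox)^h_dox)`).
#' miRNA-containing topologies co-produce one miRNA per transcript, load it
#' onto free RISC, and silence target-bearing transcripts at a rate
#' proportional to the loaded-RISC pool (quasi-steady-state treatment of the
#' RISC-target complex).
#'
#' @param topology One of [TOPOLOGIES].
#' @param params An `eq_params` object, see [rate_params()].
#' @return An object of class `eq_network` with elements `topology`,
#'   `params`, `species`, `reactions` (a data frame of propensity
#'   definitions) and `stoich` (species x reactions matrix).
#' @examples
#' net <- build_network("UNREGULATED", rate_params())
#' nrow(net$reactions)  # 4: transcription, translation, two decays
#' @export
build_network <- function(topology, params) {
  topology <- match_topology(topology)
  if (!inherits(params, "eq_params")) {
    stop("`params` must be an `eq_params` object (see rate_params())",
         call. = FALSE)
  }
  validate_params(params)
  if (topology == "NF_IDEAL") params$leak <- 0

  has_tetr  <- topology %in% c("NF_IDEAL", "NF_LEAKY", "EQUALIZER",
                               "EQUALIZER_SPLIT")
  has_mirna <- topology %in% c("IFF", "EQUALIZER", "EQUALIZER_SPLIT")

  species <- switch(topology,
    UNREGULATED      = c("mRNA", "POI"),
    IFF              = c("mRNA", "miRNA_free", "RISC_loaded", "POI"),
    NF_IDEAL         = ,
    NF_LEAKY         = c("mRNA", "TetR", "POI"),
    EQUALIZER        = c("mRNA", "miRNA_free", "RISC_loaded", "TetR", "POI"),
    EQUALIZER_SPLIT  = c("mRNA", "mRNA_tetr", "miRNA_free", "RISC_loaded",
                         "TetR", "POI"))

  idx <- function(nm) match(nm, species)
  ccl <- cleavage_const(params)

  # Reaction table columns:
  #   type: "tx" (per-plasmid transcription, TetR-repressible),
  #         "lin" (k * x[i]), "bilin" (k * x[i] * x[j]),
  #         "load" (k_load * x[i] * (R_tot - x[j]) / R_tot)
  rxn <- list()
  st  <- list()
  add <- function(name, type, k, i = NA_integer_, j = NA_integer_, delta) {
    rxn[[length(rxn) + 1L]] <<- data.frame(
      name = name, type = type, k = k, i = i, j = j,
      stringsAsFactors = FALSE)
    v <- integer(length(species))
    v[match(names(delta), species)] <- unname(delta)
    st[[length(st) + 1L]] <<- v
  }

  if (topology == "UNREGULATED") {
    add("tx", "tx", params$k_tx, delta = c(mRNA = 1L))
    add("tl", "lin", params$k_tl, i = idx("mRNA"), delta = c(POI = 1L))
    add("deg_m", "lin", params$d_m, i = idx("mRNA"), delta = c(mRNA = -1L))
    add("deg_p", "lin", params$d_p, i = idx("POI"), delta = c(POI = -1L))
  } else if (topology == "IFF") {
    add("tx", "tx", params$k_tx, delta = c(mRNA = 1L, miRNA_free = 1L))
    add("tl", "lin", params$k_tl, i = idx("mRNA"), delta = c(POI = 1L))
    add("deg_m", "lin", params$d_m, i = idx("mRNA"), delta = c(mRNA = -1L))
    add("cleave", "bilin", ccl, i = idx("mRNA"), j = idx("RISC_loaded"),
        delta = c(mRNA = -1L))
    add("load", "load", params$k_load, i = idx("miRNA_free"),
        j = idx("RISC_loaded"), delta = c(miRNA_free = -1L, RISC_loaded = 1L))
    add("deg_mi_free", "lin", params$d_mi, i = idx("miRNA_free"),
        delta = c(miRNA_free = -1L))
    add("deg_mi", "lin", params$d_mi, i = idx("RISC_loaded"),
        delta = c(RISC_loaded = -1L))
    add("deg_p", "lin", params$d_p, i = idx("POI"), delta = c(POI = -1L))
  } else if (topology %in% c("NF_IDEAL", "NF_LEAKY")) {
    add("tx", "tx", params$k_tx, delta = c(mRNA = 1L))
    add("tl", "lin", params$k_tl, i = idx("mRNA"),
        delta = c(POI = 1L, TetR = as.integer(params$stoich_tetr)))
    add("deg_m", "lin", params$d_m, i = idx("mRNA"), delta = c(mRNA = -1L))
    add("deg_p", "lin", params$d_p, i = idx("POI"), delta = c(POI = -1L))
    add("deg_t", "lin", params$d_p, i = idx("TetR"), delta = c(TetR = -1L))
  } else if (topology == "EQUALIZER") {
    add("tx", "tx", params$k_tx, delta = c(mRNA = 1L, miRNA_free = 1L))
    add("tl", "lin", params$k_tl, i = idx("mRNA"),
        delta = c(POI = 1L, TetR = as.integer(params$stoich_tetr)))
    add("deg_m", "lin", params$d_m, i = idx("mRNA"), delta = c(mRNA = -1L))
    add("cleave", "bilin", ccl, i = idx("mRNA"), j = idx("RISC_loaded"),
        delta = c(mRNA = -1L))
    add("load", "load", params$k_load, i = idx("miRNA_free"),
        j = idx("RISC_loaded"), delta = c(miRNA_free = -1L, RISC_loaded = 1L))
    add("deg_mi_free", "lin", params$d_mi, i = idx("miRNA_free"),
        delta = c(miRNA_free = -1L))
    add("deg_mi", "lin", params$d_mi, i = idx("RISC_loaded"),
        delta = c(RISC_loaded = -1L))
    add("deg_p", "lin", params$d_p, i = idx("POI"), delta = c(POI = -1L))
    add("deg_t", "lin", params$d_p, i = idx("TetR"), delta = c(TetR = -1L))
  } else { # EQUALIZER_SPLIT
    add("tx_poi", "tx", params$k_tx, delta = c(mRNA = 1L))
    add("tx_tetr", "tx", params$k_tx, delta = c(mRNA_tetr = 1L))
    add("tx_mi", "tx", params$k_tx, delta = c(miRNA_free = 1L))
    add("tl_poi", "lin", params$k_tl, i = idx("mRNA"), delta = c(POI = 1L))
    add("tl_tetr", "lin", params$stoich_tetr * params$k_tl,
        i = idx("mRNA_tetr"), delta = c(TetR = 1L))
    add("deg_m", "lin", params$d_m, i = idx("mRNA"), delta = c(mRNA = -1L))
    add("deg_mt", "lin", params$d_m, i = idx("mRNA_tetr"),
        delta = c(mRNA_tetr = -1L))
    add("cleave", "bilin", ccl, i = idx("mRNA"), j = idx("RISC_loaded"),
        delta = c(mRNA = -1L))
    add("cleave_t", "bilin", ccl, i = idx("mRNA_tetr"),
        j = idx("RISC_loaded"), delta = c(mRNA_tetr = -1L))
    add("load", "load", params$k_load, i = idx("miRNA_free"),
        j = idx("RISC_loaded"), delta = c(miRNA_free = -1L, RISC_loaded = 1L))
    add("deg_mi_free", "lin", params$d_mi, i = idx("miRNA_free"),
        delta = c(miRNA_free = -1L))
    add("deg_mi", "lin", params$d_mi, i = idx("RISC_loaded"),
        delta = c(RISC_loaded = -1L))
    add("deg_p", "lin", params$d_p, i = idx("POI"), delta = c(POI = -1L))
    add("deg_t", "lin", params$d_p, i = idx("TetR"), delta = c(TetR = -1L))
  }

  reactions <- do.call(rbind, rxn)
  stoich <- matrix(unlist(st), nrow = length(species),
                   dimnames = list(species, reactions$name))

  structure(list(topology = topology, params = params, species = species,
                 reactions = reactions, stoich = stoich,
                 has_tetr = has_tetr, has_mirna = has_mirna,
                 tetr_index = if (has_tetr) idx("TetR") else 0L),
            class = "eq_network")
}

#' @export
print.eq_network <- function(x, ...) {
  cat(sprintf("<eq_network> topology %s: %d species, %d reactions\n",
              x$topology, length(x$species), nrow(x$reactions)))
  cat("species:", paste(x$species, collapse = ", "), "\n")
  invisible(x)
}

#' Per-plasmid transcription rate under TetR repression
#'
#' `k_tx * (leak + (1 - leak) / (1 + (TetR_active / K_op)^n_op))` with
#' `TetR_active = tetR / (1 + (dox / K_dox)^h_dox)`. Bounded in
#' `[leak * k_tx, k_tx]`, non-increasing in `tetR` and non-decreasing in
#' doxycycline.
#'
#' @param tetR Total TetR amount (molecules), vectorised.
#' @param dox Doxycycline concentration (ng/mL).
#' @param params An `eq_params` object.
#' @return Transcription rate (mRNA h^-1 plasmid^-1).
#' @export
transcription_rate_per_plasmid <- function(tetR, dox, params) {
  check_numeric_nonneg(tetR, "tetR")
  check_numeric_nonneg(dox, "dox")
  tetr_active <- tetR / (1 + (dox / params$K_dox)^params$h_dox)
  params$k_tx * (params$leak +
    (1 - params$leak) / (1 + (tetr_active / params$K_op)^params$n_op))
}

#' Proteins translated per mRNA
#'
#' The expected number of output proteins produced over an mRNA's lifetime:
#' `k_tl / (d_m + cleavage)`, where the per-mRNA cleavage rate is
#' `n_ts * k_on * RISC_loaded * k_cat / (k_off + k_cat)`. Equals `k_tl / d_m`
#' when no loaded RISC is present.
#'
#' @param state A steady state as returned by [steady_state()], or any list
#'   with a `RISC_loaded` entry.
#' @param params An `eq_params` object.
#' @return Proteins per mRNA (dimensionless count).
#' @export
proteins_per_mrna <- function(state, params) {
  rl <- state$RISC_loaded
  if (is.null(rl)) rl <- 0
  params$k_tl / (params$d_m + cleavage_const(params) * rl)
}

# Propensity vector at a given state (deterministic rates).
propensities <- function(network, state, copy_number, dox) {
  p <- network$params
  r <- network$reactions
  a <- numeric(nrow(r))
  tx_rate <- if (network$has_tetr) {
    transcription_rate_per_plasmid(state[network$tetr_index], dox, p)
  } else {
    p$k_tx
  }
  for (k in seq_len(nrow(r))) {
    a[k] <- switch(r$type[k],
      tx    = copy_number * tx_rate * (r$k[k] / p$k_tx),
      lin   = r$k[k] * state[r$i[k]],
      bilin = r$k[k] * state[r$i[k]] * state[r$j[k]],
      load  = if (p$R_tot > 0) {
        r$k[k] * state[r$i[k]] * (p$R_tot - state[r$j[k]]) / p$R_tot
      } else 0)
  }
  a
}

# ODE right-hand side: dy/dt = S %*% a(y).
network_rhs <- function(network, copy_number, dox) {
  force(network); force(copy_number); force(dox)
  function(t, y, parms = NULL) {
    a <- propensities(network, y, copy_number, dox)
    list(as.numeric(network$stoich %*% a))
  }
}
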