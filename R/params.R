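#' Circuit topologies
#'
#' The six circuit architectures the package models. `NF_IDEAL` is the
#' TetR negative-feedback loop with leakage fixed at zero; `NF_LEAKY` allows
#' residual transcription at saturating repressor. `EQUALIZER` combines the
#' transcriptional NF loop with the post-transcriptional miRNA IFF loop on a
#' single promoter; `EQUALIZER_SPLIT` expresses TetR, the miRNA, and the
#' output protein from three separate (identically regulated) promoters.
#'
#' @format Character vector of valid topology names.
#' @export
TOPOLOGIES <- c("UNREGULATED", "IFF", "NF_IDEAL", "NF_LEAKY",
                "EQUALIZER", "EQUALIZER_SPLIT")

match_topology <- function(topology) {
  if (!is.character(topology) || length(topology) != 1L ||
      !(toupper(topology) %in% TOPOLOGIES)) {
    stop("unknown topology; valid values are: ",
         paste(TOPOLOGIES, collapse = ", "), call. = FALSE)
  }
  toupper(topology)
}

#' Kinetic parameters of the circuit reaction network
#'
#' One container for every rate constant of the reaction networks. Rates are
#' per hour and amounts are molecules per cell, except `k_off` which follows
#' the RNA-interference literature convention of s^-1 (it is converted
#' internally). The defaults are the package's calibrated parameter set: with
#' them the Equalizer's induction spans roughly four- to eight-fold over
#' 0-30 ng/mL doxycycline, and the population-CV-optimal inducer
#' concentration is ~1 ng/mL for the Equalizer and ~10 ng/mL for the NF
#' circuit.
#'
#' @param k_tx Maximal transcription rate per plasmid (mRNA h^-1 plasmid^-1).
#' @param k_tl Translation rate (protein mRNA^-1 h^-1).
#' @param d_m mRNA decay rate (h^-1). Must be > 0.
#' @param d_p Protein decay/dilution rate (h^-1); dominated by cell-cycle
#'   dilution in non-dividing-reporter systems.
#' @param K_op TetR-operator repression constant (molecules of active TetR at
#'   half-maximal repression).
#' @param n_op Repression Hill coefficient (>= 1; 2 for the TetR dimer
#'   acting on tandem tetO2 sites).
#' @param leak Leakage fraction in `[0, 1]`: residual per-plasmid
#'   transcription at saturating repressor.
#' @param K_dox Doxycycline half-inactivation constant (ng/mL).
#' @param h_dox Doxycycline Hill coefficient (>= 1).
#' @param R_tot Total RISC pool (molecules).
#' @param k_load miRNA processing + RISC-loading rate (h^-1).
#' @param d_mi Decay rate of the loaded RISC-miRNA complex (h^-1); also used
#'   for the free miRNA pool so that the free pool has a steady state past
#'   RISC saturation.
#' @param k_on RISC-miRNA/target association rate (molecule^-1 h^-1).
#' @param k_off miRNA-target dissociation rate constant (s^-1, default 0.3).
#' @param k_cat Target-cleavage rate (h^-1).
#' @param n_ts Number of miRNA target sites on the transcript (1 or 2; 2 for
#'   the strongest, Equalizer-L-like configuration).
#' @param stoich_tetr TetR molecules produced per output protein (1 under the
#'   2A co-translation assumption).
#'
#' @return An object of class `eq_params` (a validated named list).
#' @examples
#' p <- rate_params()
#' p$k_tx
#' @export
rate_params <- function(k_tx = 3, k_tl = 4, d_m = 0.5, d_p = 0.03,
                        K_op = 150, n_op = 4, leak = 0.03,
                        K_dox = 1.5, h_dox = 2,
                        R_tot = 350, k_load = 1, d_mi = 0.1,
                        k_on = 0.55, k_off = 0.3, k_cat = 30,
                        n_ts = 2, stoich_tetr = 1) {
  p <- list(k_tx = k_tx, k_tl = k_tl, d_m = d_m, d_p = d_p,
            K_op = K_op, n_op = n_op, leak = leak,
            K_dox = K_dox, h_dox = h_dox,
            R_tot = R_tot, k_load = k_load, d_mi = d_mi,
            k_on = k_on, k_off = k_off, k_cat = k_cat,
            n_ts = n_ts, stoich_tetr = stoich_tetr)
  validate_params(p)
  class(p) <- "eq_params"
  p
}

validate_params <- function(p) {
  for (nm in names(p)) check_scalar_nonneg(p[[nm]], nm)
  if (p$leak < 0 || p$leak > 1) stop("`leak` must lie in [0, 1]", call. = FALSE)
  if (p$n_op < 1) stop("`n_op` must be >= 1", call. = FALSE)
  if (p$h_dox < 1) stop("`h_dox` must be >= 1", call. = FALSE)
  if (!(p$n_ts %in% c(1, 2))) stop("`n_ts` must be 1 or 2", call. = FALSE)
  if (p$d_m <= 0) stop("`d_m` must be > 0", call. = FALSE)
  if (p$d_p <= 0) stop("`d_p` must be > 0", call. = FALSE)
  invisible(p)
}

#' @export
print.eq_params <- function(x, ...) {
  cat("Circuit rate parameters (per hour; amounts in molecules):\n")
  print(unlist(x))
  invisible(x)
}

# Effective per-mRNA cleavage constant per loaded RISC, from the
# quasi-steady-state treatment of the RISC-target complex:
# n_ts * k_on * k_cat / (k_off + k_cat), with k_off converted s^-1 -> h^-1.
cleavage_const <- function(params) {
  k_off_h <- params$k_off * 3600
  params$n_ts * params$k_on * params$k_cat / (k_off_h + params$k_cat)
}

# Lumped Michaelis-type miRNA-target affinity constant (molecules):
# K_mi = (k_off + k_cat) / k_on. Smaller K_mi = stronger silencing.
#' Lumped miRNA-target affinity
#'
#' The single scalar affinity knob used in model fitting:
#' `K_mi = (k_off + k_cat) / k_on` (with `k_off` converted to h^-1).
#' `set_affinity()` returns a parameter set whose `k_on` is adjusted so the
#' lumped constant equals `K_mi`, leaving `k_off` and `k_cat` untouched.
#'
#' @param params An `eq_params` object.
#' @param K_mi Target affinity constant (molecules); must be > 0.
#' @return `affinity()` returns the lumped constant; `set_affinity()` a new
#'   `eq_params`.
#' @export
affinity <- function(params) {
  (params$k_off * 3600 + params$k_cat) / params$k_on
}

#' @rdname affinity
#' @export
set_affinity <- function(params, K_mi) {
  if (!is.numeric(K_mi) || length(K_mi) != 1L || !is.finite(K_mi) || K_mi <= 0) {
    stop("`K_mi` must be a single positive number", call. = FALSE)
  }
  params$k_on <- (params$k_off * 3600 + params$k_cat) / K_mi
  validate_params(params)
  params
}

#' Read and write topology parameter files
#'
#' Parameter files are YAML with one block per topology; keys inside each
#' block must be valid [rate_params()] arguments (unknown keys are rejected).
#' The package ships its calibrated default preset at
#' `system.file("params", "default.yaml", package = "eqsim")`.
#'
#' @param path Path to a YAML file.
#' @param topology Which block to read.
#' @return An `eq_params` object.
#' @export
read_params_yaml <- function(path, topology) {
  topology <- match_topology(topology)
  if (!file.exists(path)) stop("parameter file not found: ", path, call. = FALSE)
  blocks <- yaml::read_yaml(path)
  if (is.null(blocks[[topology]])) {
    stop("no parameter block for topology ", topology, " in ", path,
         call. = FALSE)
  }
  block <- blocks[[topology]]
  valid <- names(formals(rate_params))
  unknown <- setdiff(names(block), valid)
  if (length(unknown) > 0) {
    stop("unknown parameter key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(rate_params, block)
}

#' @rdname read_params_yaml
#' @param params_list Named list of `eq_params`, one per topology.
#' @export
write_params_yaml <- function(params_list, path) {
  for (nm in names(params_list)) match_topology(nm)
  blocks <- lapply(params_list, function(p) lapply(unclass(p), identity))
  yaml::write_yaml(blocks, path)
  invisible(path)
}

#' Default parameter preset
#'
#' Returns the calibrated defaults for a topology. `NF_IDEAL` fixes
#' `leak = 0`; all other topologies share the common default set.
#'
#' @param topology Topology name (see [TOPOLOGIES]).
#' @param ... Overrides forwarded to [rate_params()].
#' @return An `eq_params` object.
#' @export
default_params <- function(topology = "EQUALIZER", ...) {
  topology <- match_topology(topology)
  p <- rate_params(...)
  if (topology == "NF_IDEAL") p$leak <- 0
  p
}
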