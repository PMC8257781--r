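#' Deterministic steady state of a circuit at fixed copy number
#'
#' Computes the state where all time derivatives vanish. Two routes are
#' provided. The default, `method = "algebraic"`, reduces the steady-state
#' conditions exactly to one scalar equation in total TetR (with a
#' closed-form quadratic for the loaded-RISC pool) and solves it by bracketed
#' root finding; it is exact to root-finder tolerance and fast enough for
#' population-scale sweeps. `method = "ode"` integrates the stiff ODE system
#' from the empty state until `max |dy/dt| / (|y| + 1)` falls below `tol`,
#' then polishes the root by damped Newton iteration; it is retained as an
#' independent route and the two are cross-checked in the test suite.
#'
#' @param network An `eq_network` from [build_network()].
#' @param copy_number Integer plasmid copy number, >= 1.
#' @param dox Doxycycline concentration (ng/mL).
#' @param method `"algebraic"` (default) or `"ode"`.
#' @param tol Convergence tolerance on the scaled derivative norm.
#' @return An object of class `eq_state`: a list with all canonical species
#'   (`mRNA`, `miRNA_free`, `RISC_free`, `RISC_loaded`, `TetR`, `POI`; absent
#'   species are 0) plus `copy_number` and `dox`.
#' @examples
#' net <- build_network("UNREGULATED", rate_params())
#' st <- steady_state(net, 10, 0)
#' st$POI  # = 10 * k_tx * k_tl / (d_m * d_p)
#' @export
steady_state <- function(network, copy_number, dox,
                         method = c("algebraic", "ode"), tol = 1e-9) {
  method <- match.arg(method)
  if (!is.numeric(copy_number) || length(copy_number) != 1L ||
      is.na(copy_number) || copy_number < 1 ||
      copy_number != round(copy_number)) {
    stop("`copy_number` must be a single integer >= 1", call. = FALSE)
  }
  check_scalar_nonneg(dox, "dox")
  y <- if (method == "algebraic") {
    steady_state_algebraic(network, copy_number, dox)
  } else {
    steady_state_ode(network, copy_number, dox, tol = tol)
  }
  as_state(network, y, copy_number, dox)
}

as_state <- function(network, y, copy_number, dox) {
  p <- network$params
  get0 <- function(nm) if (nm %in% network$species) unname(y[nm]) else 0
  rl <- get0("RISC_loaded")
  structure(list(
    mRNA = get0("mRNA"),
    mRNA_tetr = get0("mRNA_tetr"),
    miRNA_free = get0("miRNA_free"),
    RISC_free = if (network$has_mirna) max(p$R_tot - rl, 0) else p$R_tot,
    RISC_loaded = rl,
    TetR = get0("TetR"),
    POI = get0("POI"),
    copy_number = copy_number,
    dox = dox), class = "eq_state")
}

#' @export
print.eq_state <- function(x, ...) {
  cat(sprintf("<eq_state> CN = %d, dox = %g ng/mL\n", x$copy_number, x$dox))
  v <- unlist(x[c("mRNA", "miRNA_free", "RISC_free", "RISC_loaded",
                  "TetR", "POI")])
  print(signif(v, 6))
  invisible(x)
}

# Loaded-RISC steady state given a total transcription flux A (molecules/h):
# the balance  k_load * mi * f = d_mi * RL  with
# mi = A / (k_load * f + d_mi), f = (R_tot - RL) / R_tot
# reduces to a quadratic in RL with a unique root in [0, R_tot).
risc_loaded_at_flux <- function(A, p) {
  if (p$R_tot <= 0 || p$k_load <= 0 || A <= 0) return(0)
  if (p$d_mi <= 0) {
    stop("`d_mi` must be > 0 for miRNA-containing topologies", call. = FALSE)
  }
  alpha <- p$k_load / p$R_tot
  a2 <- p$d_mi * alpha
  b  <- -(p$d_mi * alpha * p$R_tot + p$d_mi^2 + alpha * A)
  c0 <- alpha * A * p$R_tot
  disc <- b^2 - 4 * a2 * c0
  rl <- (-b - sqrt(max(disc, 0))) / (2 * a2)
  min(max(rl, 0), p$R_tot)
}

steady_state_algebraic <- function(network, cn, dox) {
  p <- network$params
  ccl <- cleavage_const(network$params)

  # Species levels implied by a given total TetR (0 if topology lacks TetR).
  levels_at_tetr <- function(tetr) {
    tx <- if (network$has_tetr) {
      transcription_rate_per_plasmid(tetr, dox, p)
    } else p$k_tx
    A <- cn * tx                      # transcript (and miRNA) flux per hour
    rl <- if (network$has_mirna) risc_loaded_at_flux(A, p) else 0
    mi <- if (network$has_mirna) {
      f <- (p$R_tot - rl) / max(p$R_tot, .Machine$double.xmin)
      A / (p$k_load * f + p$d_mi)
    } else 0
    m <- A / (p$d_m + ccl * rl)
    list(tx = tx, A = A, rl = rl, mi = mi, m = m)
  }

  tetr <- 0
  if (network$has_tetr) {
    tmax <- p$stoich_tetr * p$k_tl * cn * p$k_tx / (p$d_m * p$d_p) + 1
    g <- function(tetr) {
      tetr - p$stoich_tetr * p$k_tl * levels_at_tetr(tetr)$m / p$d_p
    }
    if (g(tmax) < 0) tmax <- tmax * 2  # defensive; g(tmax) >= 0 analytically
    tetr <- stats::uniroot(g, c(0, tmax), tol = 1e-12 * tmax)$root
  }
  lv <- levels_at_tetr(tetr)
  poi <- p$k_tl * lv$m / p$d_p

  y <- numeric(length(network$species))
  names(y) <- network$species
  y["mRNA"] <- lv$m
  if ("mRNA_tetr" %in% network$species) y["mRNA_tetr"] <- lv$m
  if (network$has_mirna) {
    y["miRNA_free"] <- lv$mi
    y["RISC_loaded"] <- lv$rl
  }
  if (network$has_tetr) y["TetR"] <- tetr
  y["POI"] <- poi
  y
}

steady_state_ode <- function(network, cn, dox, tol = 1e-9,
                             t_max = 1e6) {
  rhs <- network_rhs(network, cn, dox)
  scaled_resid <- function(y) max(abs(rhs(0, y)[[1]]) / (abs(y) + 1))
  y <- stats::setNames(numeric(length(network$species)), network$species)
  t_chunk <- 200
  t_acc <- 0
  while (t_acc < t_max) {
    sol <- deSolve::ode(y = y, times = c(0, t_chunk), func = rhs,
                        parms = NULL, method = "lsoda",
                        rtol = 1e-10, atol = 1e-8)
    y <- sol[nrow(sol), -1]
    t_acc <- t_acc + t_chunk
    t_chunk <- min(t_chunk * 2, t_max - t_acc + 1)
    # the integrator relaxes the trajectory; Newton finishes the root
    if (scaled_resid(y) < 1e-5) break
  }
  y <- newton_polish(rhs, y)
  if (scaled_resid(y) > tol) {
    stop(sprintf(paste0("steady state not reached within t = %g h; ",
                        "scaled residual norm %.3e"), t_max,
                 scaled_resid(y)), call. = FALSE)
  }
  y
}

# Damped Newton refinement of F(y) = 0 with a central-difference Jacobian.
# Falls back to the unpolished state if the step fails to reduce the
# residual or leaves the non-negative orthant.
newton_polish <- function(rhs, y, max_iter = 20, tol = 1e-13) {
  f <- function(z) rhs(0, z)[[1]]
  n <- length(y)
  for (iter in seq_len(max_iter)) {
    fy <- f(y)
    if (max(abs(fy) / (abs(y) + 1)) < tol) break
    J <- matrix(0, n, n)
    h <- pmax(abs(y), 1) * 1e-7
    for (j in seq_len(n)) {
      yp <- y; ym <- y
      yp[j] <- yp[j] + h[j]
      ym[j] <- max(ym[j] - h[j], 0)
      J[, j] <- (f(yp) - f(ym)) / (yp[j] - ym[j])
    }
    step <- tryCatch(solve(J, -fy), error = function(e) NULL)
    if (is.null(step)) break
    cand <- y + step
    if (any(!is.finite(cand)) || any(cand < -1e-8)) break
    cand <- pmax(cand, 0)
    if (max(abs(f(cand))) <= max(abs(fy))) y <- cand else break
  }
  y
}

#' Steady-state dose response over a copy-number grid
#'
#' Evaluates the steady state at each copy number and collects the circuit
#' output together with the mechanistic sub-rates used in the compensation
#' analysis.
#'
#' @inheritParams steady_state
#' @param cn_grid Strictly increasing integer copy numbers, >= 1.
#' @return A data frame of class `eq_transfer_curve` with columns `cn`,
#'   `poi`, `risc_free`, `tx_rate_per_plasmid`, `proteins_per_mrna`.
#' @examples
#' net <- build_network("UNREGULATED", rate_params())
#' dr <- dose_response(net, 1:10, 0)
#' all.equal(dr$poi / dr$poi[1], as.numeric(1:10))  # exactly linear
#' @export
dose_response <- function(network, cn_grid, dox = 0,
                          method = c("algebraic", "ode")) {
  method <- match.arg(method)
  if (length(cn_grid) == 0 || !is_count_vector(cn_grid) ||
      any(diff(cn_grid) <= 0)) {
    stop("`cn_grid` must be non-empty, strictly increasing integers >= 1",
         call. = FALSE)
  }
  rows <- lapply(cn_grid, function(cn) {
    st <- tryCatch(steady_state(network, cn, dox, method = method),
                   error = function(e) {
                     stop(sprintf("steady state failed at CN = %d: %s",
                                  cn, conditionMessage(e)), call. = FALSE)
                   })
    data.frame(cn = cn, poi = st$POI, risc_free = st$RISC_free,
               tx_rate_per_plasmid = transcription_rate_per_plasmid(
                 st$TetR, dox, network$params),
               proteins_per_mrna = proteins_per_mrna(st, network$params))
  })
  out <- do.call(rbind, rows)
  attr(out, "topology") <- network$topology
  attr(out, "dox") <- dox
  class(out) <- c("eq_transfer_curve", "data.frame")
  out
}

# Memoised POI steady states over a set of copy numbers (not necessarily
# sorted or unique). Returns a numeric vector aligned with `cn`.
poi_at_cn <- function(network, cn, dox, method = "algebraic") {
  u <- sort(unique(cn))
  poi_u <- vapply(u, function(k) {
    steady_state(network, k, dox, method = method)$POI
  }, numeric(1))
  poi_u[match(cn, u)]
}
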