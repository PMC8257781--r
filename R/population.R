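#' Log-normal plasmid copy-number distribution
#'
#' Model of plasmid copies per transfected cell: `log(CN)` is normal with
#' mean `mu_log` and SD `sigma_log`; samples are rounded to the nearest
#' integer and floored at 1. The package default
#' ([default_cn_distribution()]) is calibrated so that ~99 % of transfected
#' cells harbour between 1 and 432 plasmids, interpreting that as the
#' central interval: median `sqrt(1 * 432) ~ 20.8`, so
#' `mu_log = log(20.78)` and `sigma_log = log(432 / 20.78) / qnorm(0.995)
#' ~ 1.178`.
#'
#' @param mu_log Mean of log copy number.
#' @param sigma_log SD of log copy number, > 0.
#' @return An object of class `eq_cn_dist`.
#' @export
cn_distribution <- function(mu_log, sigma_log) {
  if (!is.numeric(mu_log) || length(mu_log) != 1L || !is.finite(mu_log)) {
    stop("`mu_log` must be a single finite number", call. = FALSE)
  }
  if (!is.numeric(sigma_log) || length(sigma_log) != 1L || sigma_log <= 0) {
    stop("`sigma_log` must be > 0", call. = FALSE)
  }
  structure(list(mu_log = mu_log, sigma_log = sigma_log),
            class = "eq_cn_dist")
}

#' @rdname cn_distribution
#' @export
default_cn_distribution <- function() {
  med <- sqrt(432)
  cn_distribution(mu_log = log(med),
                  sigma_log = log(432 / med) / stats::qnorm(0.995))
}

#' @export
print.eq_cn_dist <- function(x, ...) {
  cat(sprintf(paste0("<eq_cn_dist> log-normal copy numbers: mu_log = %.4g,",
                     " sigma_log = %.4g (median ~ %.1f)\n"),
              x$mu_log, x$sigma_log, exp(x$mu_log)))
  invisible(x)
}

# Probability mass of the rounded-and-floored distribution at integer cn.
cn_pmf <- function(dist, cn) {
  stopifnot(inherits(dist, "eq_cn_dist"))
  hi <- stats::plnorm(cn + 0.5, dist$mu_log, dist$sigma_log)
  lo <- stats::plnorm(pmax(cn - 0.5, 0), dist$mu_log, dist$sigma_log)
  lo[cn <= 1] <- 0  # everything below 1.5 folds into CN = 1
  hi - lo
}

#' Sample integer plasmid copy numbers
#'
#' @param dist An `eq_cn_dist` from [cn_distribution()].
#' @param n Number of cells, >= 1.
#' @param seed Optional seed; the caller's RNG state is restored afterwards.
#' @return Integer vector of length `n`, all values >= 1.
#' @examples
#' cn <- sample_copy_numbers(default_cn_distribution(), 1000, seed = 1)
#' mean(cn >= 1 & cn <= 432)  # ~0.99
#' @export
sample_copy_numbers <- function(dist, n, seed = NULL) {
  stopifnot(inherits(dist, "eq_cn_dist"))
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1) {
    stop("`n` must be >= 1", call. = FALSE)
  }
  with_seed(seed, {
    raw <- stats::rlnorm(n, dist$mu_log, dist$sigma_log)
    pmax(1L, as.integer(round(raw)))
  })
}

#' Intrinsic-noise model
#'
#' Multiplicative intrinsic expression noise: each cell's output is scaled
#' by an i.i.d. unit-mean log-normal factor with coefficient of variation
#' `cv_int`. The default 0.71 is the cell-to-cell CV measured for a
#' chromosomally integrated CMV cassette, attributed entirely to intrinsic
#' noise.
#'
#' @param cv_int Intrinsic CV, >= 0 (dimensionless).
#' @return An object of class `eq_noise`.
#' @export
noise_model <- function(cv_int = 0.71) {
  if (!is.numeric(cv_int) || length(cv_int) != 1L || is.na(cv_int) ||
      cv_int < 0) {
    stop("`cv_int` must be a single number >= 0", call. = FALSE)
  }
  structure(list(cv_int = cv_int,
                 sigma = sqrt(log(1 + cv_int^2))), class = "eq_noise")
}

noise_factors <- function(noise, n) {
  if (noise$cv_int == 0) return(rep(1, n))
  stats::rlnorm(n, meanlog = -noise$sigma^2 / 2, sdlog = noise$sigma)
}

#' Apply multiplicative intrinsic noise
#'
#' Multiplies each value by an independent unit-mean log-normal factor with
#' CV `cv_int`; expectations are preserved.
#'
#' @param values Non-negative numeric vector.
#' @param noise An `eq_noise` from [noise_model()].
#' @param seed Optional seed.
#' @return Noisy values, same length as the input.
#' @export
apply_intrinsic_noise <- function(values, noise = noise_model(),
                                  seed = NULL) {
  check_numeric_nonneg(values, "values")
  stopifnot(inherits(noise, "eq_noise"))
  with_seed(seed, values * noise_factors(noise, length(values)))
}

#' Predict the population expression distribution
#'
#' Samples plasmid copy numbers for `n` cells, evaluates the deterministic
#' steady-state output at each unique copy number (memoised), and injects
#' multiplicative intrinsic noise. A gene-dosage reporter channel
#' proportional to copy number (with its own independent noise) is returned
#' alongside.
#'
#' @param network An `eq_network`.
#' @param dist An `eq_cn_dist`.
#' @param dox Doxycycline concentration (ng/mL).
#' @param n Number of cells.
#' @param noise An `eq_noise`.
#' @param seed Optional seed (covers copy-number sampling and both noise
#'   channels).
#' @return An object of class `eq_population`: list with `cells` (data frame
#'   `cell`, `copy_number`, `output`, `reporter`), `cv`, `mean`, and the
#'   simulation metadata.
#' @export
predict_population <- function(network, dist, dox, n = 10000,
                               noise = noise_model(), seed = NULL) {
  stopifnot(inherits(network, "eq_network"), inherits(dist, "eq_cn_dist"))
  with_seed(seed, {
    cn <- sample_copy_numbers(dist, n)
    poi <- poi_at_cn(network, cn, dox)
    output <- poi * noise_factors(noise, n)
    reporter <- cn * noise_factors(noise, n)
    cells <- data.frame(cell = seq_len(n), copy_number = cn,
                        output = output, reporter = reporter)
    structure(list(cells = cells,
                   cv = stats::sd(output) / mean(output),
                   mean = mean(output),
                   topology = network$topology, dox = dox, n = n,
                   cv_int = noise$cv_int, seed = seed),
              class = "eq_population")
  })
}

#' @export
print.eq_population <- function(x, ...) {
  cat(sprintf(paste0("<eq_population> %s at dox = %g ng/mL, n = %d cells:",
                     " mean output %.4g, CV = %.1f %%\n"),
              x$topology, x$dox, x$n, x$mean, 100 * x$cv))
  invisible(x)
}

#' Population CV as a function of inducer concentration
#'
#' Evaluates [predict_population()] over a doxycycline grid using common
#' random numbers (the same seed for every concentration), so the shape of
#' the curve reflects the circuit, not sampling noise.
#'
#' @inheritParams predict_population
#' @param dox_grid Non-empty numeric vector of concentrations.
#' @param seed Seed reused across grid points.
#' @return Data frame with columns `dox`, `cv`, `mean`.
#' @export
dox_cv_curve <- function(network, dist, dox_grid, n = 10000,
                         noise = noise_model(), seed = 1) {
  if (length(dox_grid) == 0) stop("`dox_grid` is empty", call. = FALSE)
  rows <- lapply(dox_grid, function(dox) {
    pop <- predict_population(network, dist, dox, n = n, noise = noise,
                              seed = seed)
    data.frame(dox = dox, cv = pop$cv, mean = pop$mean)
  })
  do.call(rbind, rows)
}

#' Exact stochastic simulation of a circuit
#'
#' Gillespie's direct method over the network's propensities, implemented in
#' compiled code. Reports the time-averaged stationary mean, variance, CV
#' and Fano factor of the output protein (and of every species) after a
#' burn-in period, plus an optionally thinned output trajectory.
#'
#' @param network An `eq_network` (requires integer `stoich_tetr`).
#' @param copy_number Integer plasmid copy number >= 1.
#' @param dox Doxycycline concentration (ng/mL).
#' @param t_end Simulation horizon (h); must exceed the relaxation time
#'   (~`1/d_p`).
#' @param seed Optional seed (R's RNG; runs are bit-reproducible).
#' @param burnin Time discarded before accumulating moments (default
#'   `t_end / 5`).
#' @param record_dt Sampling interval for the returned POI trajectory;
#'   `NULL` records ~500 points.
#' @param max_steps Safety cap on reaction events.
#' @return An object of class `eq_ssa`: list with `mean`, `var` (named per
#'   species), `poi_mean`, `poi_var`, `poi_cv`, `poi_fano`, `trajectory`
#'   (data frame `time`, `poi`), `n_steps`, and `completed`.
#' @export
ssa_simulate <- function(network, copy_number, dox, t_end, seed = NULL,
                         burnin = t_end / 5, record_dt = NULL,
                         max_steps = 5e8) {
  stopifnot(inherits(network, "eq_network"))
  if (!is.numeric(copy_number) || copy_number < 1 ||
      copy_number != round(copy_number)) {
    stop("`copy_number` must be an integer >= 1", call. = FALSE)
  }
  p <- network$params
  if (p$stoich_tetr != round(p$stoich_tetr)) {
    stop("stochastic simulation requires integer `stoich_tetr`",
         call. = FALSE)
  }
  if (burnin >= t_end) stop("`burnin` must be < `t_end`", call. = FALSE)
  if (is.null(record_dt)) record_dt <- t_end / 500
  r <- network$reactions
  type_code <- match(r$type, c("tx", "lin", "bilin", "load"))
  pars <- c(cn = copy_number, dox = dox, k_tx = p$k_tx, leak = p$leak,
            K_op = p$K_op, n_op = p$n_op, K_dox = p$K_dox, h_dox = p$h_dox,
            R_tot = p$R_tot, tetr_idx = network$tetr_index)
  y0 <- numeric(length(network$species))
  res <- with_seed(seed, {
    ssa_run_cpp(network$stoich, type_code, r$k,
                ifelse(is.na(r$i), 0L, r$i), ifelse(is.na(r$j), 0L, r$j),
                pars, y0, t_end, burnin, record_dt,
                match("POI", network$species), max_steps)
  })
  mean_v <- stats::setNames(res$mean, network$species)
  var_v <- stats::setNames(pmax(res$var, 0), network$species)
  pm <- mean_v[["POI"]]
  pv <- var_v[["POI"]]
  structure(list(mean = mean_v, var = var_v,
                 poi_mean = pm, poi_var = pv,
                 poi_cv = if (pm > 0) sqrt(pv) / pm else NA_real_,
                 poi_fano = if (pm > 0) pv / pm else NA_real_,
                 trajectory = data.frame(time = res$t_rec, poi = res$poi_rec),
                 n_steps = res$n_steps, completed = res$completed,
                 topology = network$topology, copy_number = copy_number,
                 dox = dox, t_end = t_end, burnin = burnin, seed = seed),
            class = "eq_ssa")
}

#' @export
print.eq_ssa <- function(x, ...) {
  cat(sprintf(paste0("<eq_ssa> %s at CN = %d, dox = %g: POI mean %.4g,",
                     " CV %.3f, Fano %.3f (%d events)\n"),
              x$topology, x$copy_number, x$dox, x$poi_mean, x$poi_cv,
              x$poi_fano, x$n_steps))
  invisible(x)
}
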