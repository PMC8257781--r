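#' Fit result container
#'
#' Returned by the model-calibration routines. `trace` holds the running
#' best objective value per evaluation (non-increasing by construction).
#'
#' @param estimate Parameter estimate(s).
#' @param objective Final objective value (>= 0).
#' @param n_eval Number of objective evaluations.
#' @param converged Logical convergence flag.
#' @param trace Numeric vector of best-so-far objective values.
#' @return An object of class `eq_fit`.
#' @keywords internal
fit_result <- function(estimate, objective, n_eval, converged, trace) {
  structure(list(estimate = estimate, objective = objective,
                 n_eval = n_eval, converged = converged, trace = trace),
            class = "eq_fit")
}

#' @export
print.eq_fit <- function(x, ...) {
  cat(sprintf(paste0("<eq_fit> estimate = %s, objective = %.4g",
                     " (%d evaluations, converged: %s)\n"),
              paste(signif(unlist(x$estimate), 5), collapse = ", "),
              x$objective, x$n_eval, x$converged))
  invisible(x)
}

#' Estimate the plasmid copy-number distribution
#'
#' Under the multiplicative model `expr = scale * CN * noise` with unit-mean
#' log-normal intrinsic noise, the log-expression variance decomposes as
#' `Var(log expr) = sigma_log^2 + sigma_int^2` with
#' `sigma_int^2 = log(1 + cv_int^2)`. The copy-number log-SD is therefore
#' recovered by variance subtraction, and `mu_log` from the mean
#' log-expression once an expression scale is fixed.
#'
#' @param expression Per-cell expression values of an unregulated (linear)
#'   circuit; at least 100 positive values.
#' @param noise An `eq_noise` giving the assumed intrinsic CV.
#' @param scale Expression units per plasmid copy (default 1); reported
#'   alongside the fit since `mu_log` and the scale are only jointly
#'   identified.
#' @return An `eq_cn_dist` with attributes `scale` and `sigma_int`.
#' @export
fit_copy_number_distribution <- function(expression, noise = noise_model(),
                                         scale = 1) {
  if (length(expression) < 100 || any(expression <= 0)) {
    stop("need >= 100 strictly positive expression values", call. = FALSE)
  }
  stopifnot(inherits(noise, "eq_noise"))
  lx <- log(expression)
  v <- stats::var(lx)
  s2_int <- log(1 + noise$cv_int^2)
  if (v <= s2_int) {
    stop(paste("log-expression variance does not exceed the intrinsic-noise",
               "variance; `cv_int` is likely overstated for these data"),
         call. = FALSE)
  }
  sigma_log <- sqrt(v - s2_int)
  # E[log noise] = -sigma_int^2 / 2 for the unit-mean log-normal factor
  mu_log <- mean(lx) - log(scale) + s2_int / 2
  out <- cn_distribution(mu_log, sigma_log)
  attr(out, "scale") <- scale
  attr(out, "sigma_int") <- sqrt(s2_int)
  out
}

# Distribution-weighted population mean of the steady-state output,
# computed by quadrature over equal-probability copy-number nodes.
population_mean_quadrature <- function(network, dist, dox, n_nodes = 256) {
  p_mid <- (seq_len(n_nodes) - 0.5) / n_nodes
  cn <- pmax(1L, as.integer(round(stats::qlnorm(p_mid, dist$mu_log,
                                                dist$sigma_log))))
  mean(poi_at_cn(network, cn, dox))
}

#' Estimate the TetR leakage fraction
#'
#' Fits the leakage parameter of the NF circuit by matching simulated to
#' observed mean expression across doxycycline concentrations (which must
#' include 0 and a saturating level >= 100 * K_dox). The arbitrary
#' expression scale is profiled out by least squares, and the remaining 1-D
#' problem is solved by bounded golden-section/parabolic search on
#' `[0, 1]`.
#'
#' @param dox Doxycycline concentrations of the observations (ng/mL).
#' @param mean_expression Observed mean NF expression per concentration.
#' @param network An NF `eq_network` supplying all other parameters.
#' @param dist Copy-number distribution over which means are computed.
#' @param n_nodes Quadrature nodes for the population mean.
#' @return An `eq_fit` whose `estimate` is the leakage fraction.
#' @export
estimate_leakage <- function(dox, mean_expression, network,
                             dist = default_cn_distribution(),
                             n_nodes = 256) {
  if (length(dox) != length(mean_expression) || length(dox) < 2) {
    stop("need >= 2 matched (dox, mean) observations", call. = FALSE)
  }
  if (!any(dox == 0)) stop("observations must include dox = 0", call. = FALSE)
  if (max(dox) < 100 * network$params$K_dox) {
    stop(sprintf("a saturating dox level >= %g ng/mL (100 * K_dox) is required",
                 100 * network$params$K_dox), call. = FALSE)
  }
  evals <- numeric(0)
  sim_means <- function(leak) {
    p <- network$params
    p$leak <- leak
    net <- build_network(network$topology, p)
    vapply(dox, function(d) {
      population_mean_quadrature(net, dist, d, n_nodes)
    }, numeric(1))
  }
  objective <- function(leak) {
    sim <- sim_means(leak)
    s_hat <- sum(mean_expression * sim) / sum(sim^2)  # profiled scale
    obj <- sum((mean_expression - s_hat * sim)^2)
    evals <<- c(evals, obj)
    obj
  }
  # identifiability: the simulated response must actually depend on dox
  probe <- sim_means(0.5)
  if (diff(range(probe)) < 1e-9 * max(probe)) {
    stop("simulated NF response is flat across dox; leakage not identifiable",
         call. = FALSE)
  }
  opt <- stats::optimize(objective, interval = c(0, 1), tol = 1e-5)
  fit_result(estimate = opt$minimum, objective = opt$objective,
             n_eval = length(evals), converged = TRUE,
             trace = cummin(evals))
}

#' Estimate the miRNA-target affinity
#'
#' Fits the lumped Michaelis-type affinity constant
#' `K_mi = (k_off + k_cat) / k_on` by derivative-free simplex (Nelder-Mead)
#' search on `log(K_mi)`, minimising the mean squared error between observed
#' and simulated Equalizer/NF mean-expression ratios across doxycycline
#' concentrations. Each simulated ratio is computed from `n`-cell population
#' means with common random numbers (the same sampled copy numbers and noise
#' factors at every objective evaluation), which makes the stochastic
#' objective smooth and the fit deterministic for a fixed seed. Ratios are
#' scale-free, so no expression scale enters.
#'
#' @param ratio_obs Observed Equalizer/NF mean-expression ratios, one per
#'   entry of `dox`, all > 0.
#' @param dox Doxycycline concentrations (default the panel
#'   0, 1, 5, 10, 50, 100 ng/mL).
#' @param params Shared `eq_params` for both circuits (the NF circuit does
#'   not use the miRNA constants).
#' @param dist Copy-number distribution.
#' @param n Cells per simulated population mean.
#' @param seed Seed for the common random numbers.
#' @param start Starting affinity (molecules); default the value implied by
#'   `params`.
#' @param max_eval Evaluation budget for the simplex search.
#' @return An `eq_fit` whose `estimate` is `K_mi` (molecules).
#' @export
estimate_mirna_affinity <- function(ratio_obs,
                                    dox = c(0, 1, 5, 10, 50, 100),
                                    params = default_params("EQUALIZER"),
                                    dist = default_cn_distribution(),
                                    n = 10000, seed = 1,
                                    start = NULL, max_eval = 200) {
  if (length(ratio_obs) != length(dox) || any(ratio_obs <= 0)) {
    stop("`ratio_obs` must be positive with one value per dox level",
         call. = FALSE)
  }
  if (is.null(start)) start <- affinity(params)

  # common random numbers: fixed copy numbers and noise factors
  crn <- with_seed(seed, {
    cn <- sample_copy_numbers(dist, n)
    nf <- noise_factors(noise_model(), n)
    list(cn = cn, nf = nf)
  })
  nf_net <- build_network("NF_LEAKY", params)
  nf_means <- vapply(dox, function(d) {
    mean(poi_at_cn(nf_net, crn$cn, d) * crn$nf)
  }, numeric(1))

  evals <- numeric(0)
  sim_ratio <- function(K_mi) {
    eq_net <- build_network("EQUALIZER", set_affinity(params, K_mi))
    eq_means <- vapply(dox, function(d) {
      mean(poi_at_cn(eq_net, crn$cn, d) * crn$nf)
    }, numeric(1))
    eq_means / nf_means
  }
  objective <- function(log_kmi) {
    obj <- mean((sim_ratio(exp(log_kmi)) - ratio_obs)^2)
    evals <<- c(evals, obj)
    obj
  }
  opt <- suppressWarnings(stats::optim(
    par = log(start), fn = objective, method = "Nelder-Mead",
    control = list(maxit = max_eval, reltol = 1e-8)))
  fit_result(estimate = exp(opt$par), objective = opt$value,
             n_eval = length(evals),
             converged = opt$convergence == 0,
             trace = cummin(evals))
}
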