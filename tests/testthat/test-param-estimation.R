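test_that("copy-number distribution is recovered by variance subtraction", {
  set.seed(21)
  n <- 1e4
  cn <- pmax(1, round(stats::rlnorm(n, 3.0, 1.2)))

  # noiseless linear expression: recover sigma_log within 5 %
  fit0 <- fit_copy_number_distribution(7 * cn, noise_model(0), scale = 7)
  expect_equal(fit0$sigma_log, 1.2, tolerance = 0.05)
  expect_equal(fit0$mu_log, 3.0, tolerance = 0.05)

  # with unit-mean intrinsic noise of known CV: same recovery
  expr <- 7 * cn * noise_draw(n, 0.71)
  fit1 <- fit_copy_number_distribution(expr, noise_model(0.71), scale = 7)
  expect_equal(fit1$sigma_log, 1.2, tolerance = 0.05)
  expect_equal(fit1$mu_log, 3.0, tolerance = 0.05)

  # degenerate input: no variance left after subtraction
  expect_error(fit_copy_number_distribution(rep(4, 200), noise_model(0)),
               "variance")
  expect_error(fit_copy_number_distribution(7 * cn, noise_model(3)),
               "overstated")
  expect_error(fit_copy_number_distribution(c(-1, 1:200)), "positive")
})

test_that("TetR leakage is identified from NF dose-response means", {
  d <- default_cn_distribution()
  dox <- c(0, 1, 5, 10, 50, 1000)
  p_true <- rate_params(leak = 0.05)
  net_true <- build_network("NF_LEAKY", p_true)
  obs <- vapply(dox, function(dd) {
    predict_population(net_true, d, dd, n = 10000, seed = 22)$mean
  }, numeric(1))

  fit <- estimate_leakage(dox, obs, net_of("NF_LEAKY"), dist = d)
  expect_equal(fit$estimate, 0.05, tolerance = 0.2)
  expect_lt(abs(fit$estimate - 0.05), 0.01)
  # best-vertex trace never increases
  expect_true(all(diff(fit$trace) <= 0))

  # local-minimum check: the profiled objective at the generating value
  # is below its value at leak +- 0.1
  obj_at <- function(leak) {
    net <- build_network("NF_LEAKY", rate_params(leak = leak))
    sim <- vapply(dox, function(dd) {
      eqsim:::population_mean_quadrature(net, d, dd, 256)
    }, numeric(1))
    s <- sum(obs * sim) / sum(sim^2)
    sum((obs - s * sim)^2)
  }
  expect_lt(obj_at(0.05), obj_at(0.15))
  expect_lt(obj_at(0.05), obj_at(0.001))

  # no repression signature: uninduced mean equals saturated mean -> leak ~ 1
  flat_obs <- rep(obs[length(obs)], length(dox))
  fit_flat <- estimate_leakage(dox, flat_obs, net_of("NF_LEAKY"), dist = d)
  expect_gt(fit_flat$estimate, 0.9)

  expect_error(estimate_leakage(c(1, 5), obs[1:2], net_of("NF_LEAKY")),
               "dox = 0")
  expect_error(estimate_leakage(c(0, 5), obs[1:2], net_of("NF_LEAKY")),
               "saturating")
})

test_that("miRNA affinity fit recovers truth and brackets the optimum", {
  d <- default_cn_distribution()
  dox <- c(0, 1, 5, 10, 50, 100)
  p <- default_p
  K_true <- affinity(p)
  n <- 10000
  seed <- 23

  # observed ratios generated with the estimator's own common random
  # numbers: the self-fit objective vanishes at the generating affinity
  set.seed(seed)
  cn <- sample_copy_numbers(d, n)
  fac <- noise_draw(n)
  eq_net <- net_of("EQUALIZER")
  nf_net <- net_of("NF_LEAKY")
  ratio <- vapply(dox, function(dd) {
    mean(eqsim:::poi_at_cn(eq_net, cn, dd) * fac) /
      mean(eqsim:::poi_at_cn(nf_net, cn, dd) * fac)
  }, numeric(1))

  fit <- estimate_mirna_affinity(ratio, dox, p, d, n = n, seed = seed,
                                 start = K_true * 5)
  expect_true(fit$converged)
  expect_equal(fit$estimate, K_true, tolerance = 0.02)
  expect_lt(fit$objective, 1e-8)
  expect_true(all(diff(fit$trace) <= 0))

  # recovery from dispersed starting points stays within 20 %
  for (start in c(K_true / 4, K_true * 4)) {
    f <- estimate_mirna_affinity(ratio, dox, p, d, n = n, seed = seed,
                                 start = start)
    expect_equal(f$estimate, K_true, tolerance = 0.2)
  }

  # a 20-point log-grid of the objective brackets the simplex optimum
  with_crn <- function(K_mi) {
    eqn <- build_network("EQUALIZER", set_affinity(p, K_mi))
    sim <- vapply(dox, function(dd) {
      mean(eqsim:::poi_at_cn(eqn, cn, dd) * fac) /
        mean(eqsim:::poi_at_cn(nf_net, cn, dd) * fac)
    }, numeric(1))
    mean((sim - ratio)^2)
  }
  kgrid <- exp(seq(log(K_true / 10), log(K_true * 10), length.out = 20))
  obj_grid <- vapply(kgrid, with_crn, numeric(1))
  k_best <- which.min(obj_grid)
  expect_gt(k_best, 1)
  expect_lt(k_best, 20)
  expect_true(kgrid[k_best - 1] <= fit$estimate &&
                fit$estimate <= kgrid[k_best + 1])

  expect_error(estimate_mirna_affinity(ratio[1:3], dox, p, d), "per dox")
})

test_that("raising the uninduced ratio shifts the fit to weaker silencing", {
  d <- default_cn_distribution()
  dox <- c(0, 1, 5, 10, 50, 100)
  p <- default_p
  K_true <- affinity(p)
  seed <- 24
  n <- 4000
  set.seed(seed)
  cn <- sample_copy_numbers(d, n)
  fac <- noise_draw(n)
  nf_net <- net_of("NF_LEAKY")
  ratio <- vapply(dox, function(dd) {
    mean(eqsim:::poi_at_cn(net_of("EQUALIZER"), cn, dd) * fac) /
      mean(eqsim:::poi_at_cn(nf_net, cn, dd) * fac)
  }, numeric(1))
  base <- estimate_mirna_affinity(ratio, dox, p, d, n = n, seed = seed)
  bumped <- ratio
  bumped[1] <- bumped[1] * 1.5  # less silencing apparent at dox = 0
  shifted <- estimate_mirna_affinity(bumped, dox, p, d, n = n, seed = seed)
  # weaker silencing = larger lumped affinity constant K_mi
  expect_gt(shifted$estimate, base$estimate)
})
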