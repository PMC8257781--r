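test_that("network construction matches each topology's mechanism", {
  net <- net_of("UNREGULATED")
  expect_equal(nrow(net$reactions), 4L)
  expect_setequal(net$reactions$name, c("tx", "tl", "deg_m", "deg_p"))

  expect_error(build_network("RING_OSC", default_p), "valid values")
  expect_error(build_network("IFF", list(k_tx = 1)), "eq_params")

  # full leakage removes TetR dependence of the transcription propensity
  p_leaky <- rate_params(leak = 1)
  nf <- build_network("NF_LEAKY", p_leaky)
  tx_row <- which(nf$reactions$type == "tx")
  states <- list(c(0, 0, 0), c(5, 1e5, 50), c(1, 10, 1))
  a <- vapply(states, function(s) {
    st <- stats::setNames(s, nf$species)
    eqsim:::propensities(nf, st, 7, 0)[tx_row]
  }, numeric(1))
  expect_equal(a, rep(a[1], 3))
})

test_that("transcription rate law obeys its bounds and limits", {
  p <- default_p
  expect_equal(transcription_rate_per_plasmid(0, 0, p), p$k_tx)
  p1 <- rate_params(leak = 1)
  expect_equal(transcription_rate_per_plasmid(c(0, 10, 1e6), 3, p1),
               rep(p1$k_tx, 3))
  # half-maximal repression when active TetR equals K_op (n_op = 1, leak 0)
  ph <- rate_params(n_op = 1, leak = 0)
  expect_equal(transcription_rate_per_plasmid(ph$K_op, 0, ph), ph$k_tx / 2)

  tet <- seq(0, 5000, by = 50)
  r <- transcription_rate_per_plasmid(tet, 0, p)
  expect_true(all(diff(r) <= 0))
  expect_true(all(r >= p$leak * p$k_tx - 1e-12 & r <= p$k_tx + 1e-12))
  rd <- transcription_rate_per_plasmid(1000, c(0, 1, 10, 100), p)
  expect_true(all(diff(rd) >= 0))
  expect_error(transcription_rate_per_plasmid(-1, 0, p), "non-negative")
})

test_that("proteins per mRNA follows the quasi-steady-state silencing law", {
  p <- default_p
  expect_equal(proteins_per_mrna(list(RISC_loaded = 0), p), p$k_tl / p$d_m)
  x1 <- proteins_per_mrna(list(RISC_loaded = 40), p)
  x2 <- proteins_per_mrna(list(RISC_loaded = 80), p)
  expect_lt(x2, x1)
  # arithmetic on the stated formula: k_tl/(d_m + cleavage) = 10/(0.5+0.5)
  pa <- rate_params(k_tl = 10, d_m = 0.5)
  rl <- 0.5 / eqsim:::cleavage_const(pa)
  expect_equal(proteins_per_mrna(list(RISC_loaded = rl), pa), 10)
})

test_that("steady states match closed forms and reduce across limits", {
  p <- default_p
  # linear cascade closed form
  st <- steady_state(net_of("UNREGULATED"), 10, 0)
  expect_equal(st$POI, 10 * p$k_tx * p$k_tl / (p$d_m * p$d_p))

  cns <- c(1L, 7L, 60L, 400L)
  poi_of <- function(topology, params, dox = 0) {
    vapply(cns, function(k) {
      steady_state(build_network(topology, params), k, dox)$POI
    }, numeric(1))
  }
  # leak = 1: NF -> unregulated, EQUALIZER -> IFF
  p1 <- rate_params(leak = 1)
  expect_rel_equal(poi_of("NF_LEAKY", p1), poi_of("UNREGULATED", p1), 1e-6)
  expect_rel_equal(poi_of("EQUALIZER", p1), poi_of("IFF", p1), 1e-6)
  # R_tot = 0: IFF -> unregulated, EQUALIZER -> NF
  p0 <- rate_params(R_tot = 0)
  expect_rel_equal(poi_of("IFF", p0), poi_of("UNREGULATED", p0), 1e-6)
  expect_rel_equal(poi_of("EQUALIZER", p0, 1), poi_of("NF_LEAKY", p0, 1),
                   1e-6)
  # dox -> infinity: NF -> unregulated
  expect_rel_equal(poi_of("NF_LEAKY", default_p, 1e9),
                   poi_of("UNREGULATED", default_p), 1e-6)

  expect_error(steady_state(net_of("UNREGULATED"), 0, 0), "integer")
  expect_error(steady_state(net_of("UNREGULATED"), 2.5, 0), "integer")
})

test_that("ODE integration agrees with the algebraic root to 1e-8", {
  for (topology in c("UNREGULATED", "NF_IDEAL", "NF_LEAKY")) {
    for (cn in c(1L, 30L, 250L)) {
      a <- steady_state(net_of(topology), cn, 2, method = "algebraic")
      o <- steady_state(net_of(topology), cn, 2, method = "ode")
      expect_rel_equal(o$POI, a$POI, 1e-8)
      expect_rel_equal(o$mRNA, a$mRNA, 1e-8)
    }
  }
  # spot-check the miRNA-containing topologies as well
  a <- steady_state(net_of("EQUALIZER"), 80, 1, method = "algebraic")
  o <- steady_state(net_of("EQUALIZER"), 80, 1, method = "ode")
  expect_rel_equal(o$POI, a$POI, 1e-8)
  expect_rel_equal(o$RISC_loaded, a$RISC_loaded, 1e-8)
})

test_that("dose response is linear for unregulated and monotone elsewhere", {
  dr <- dose_response(net_of("UNREGULATED"), 1:10, 0)
  expect_equal(dr$poi / dr$poi[1], as.numeric(1:10))
  s <- log_sensitivity(dr)$log_sensitivity
  expect_equal(s[2:9], rep(1, 8))

  # free RISC non-increasing, POI non-decreasing over CN for random draws
  set.seed(401)
  for (rep in 1:3) {
    p <- rate_params(k_tx = runif(1, 1, 5), k_tl = runif(1, 2, 6),
                     K_op = runif(1, 50, 500), R_tot = runif(1, 100, 2000),
                     k_on = runif(1, 0.1, 1), leak = runif(1, 0.01, 0.2))
    cn_grid <- unique(round(10^seq(0, 3, length.out = 25)))
    for (topology in c("IFF", "EQUALIZER")) {
      dr <- dose_response(build_network(topology, p), cn_grid, 1)
      expect_true(all(diff(dr$risc_free) <= 1e-9))
      expect_true(all(diff(dr$poi) >= -1e-9 * dr$poi[-1]))
    }
  }

  # IFF at depleted free RISC: local slope returns to 1 (compensation lost)
  dr <- dose_response(net_of("IFF"), 2000:2002, 0)
  expect_lt(dr$risc_free[2] / default_p$R_tot, 0.05)
  s_mid <- 2001 * (dr$poi[3] - dr$poi[1]) / (2 * dr$poi[2])
  expect_equal(s_mid, 1, tolerance = 0.05)

  expect_error(dose_response(net_of("IFF"), c(5, 3, 1), 0), "increasing")
})

test_that("NF_IDEAL output rises with inducer at fixed copy number", {
  poi <- vapply(c(0, 0.5, 1, 5, 20), function(dox) {
    steady_state(net_of("NF_IDEAL"), 50, dox)$POI
  }, numeric(1))
  expect_true(all(diff(poi) > 0))
})

test_that("split-promoter circuit matches the single-promoter dose response", {
  cn_grid <- c(1L, 3L, 10L, 50L, 200L, 700L)
  for (dox in c(0, 1, 10)) {
    single <- dose_response(net_of("EQUALIZER"), cn_grid, dox)
    split <- dose_response(net_of("EQUALIZER_SPLIT"), cn_grid, dox)
    expect_rel_equal(split$poi, single$poi, 1e-6)
  }
})

test_that("parameter YAML round-trips and rejects unknown keys", {
  path <- tempfile(fileext = ".yaml")
  on.exit(unlink(path), add = TRUE)
  write_params_yaml(list(EQUALIZER = rate_params(k_tx = 7)), path)
  p <- read_params_yaml(path, "EQUALIZER")
  expect_equal(p$k_tx, 7)
  writeLines("EQUALIZER:\n  k_tx: 2\n  warp_speed: 9", path)
  expect_error(read_params_yaml(path, "EQUALIZER"), "warp_speed")
  preset <- system.file("params", "default.yaml", package = "eqsim")
  expect_equal(read_params_yaml(preset, "NF_IDEAL")$leak, 0)
  expect_equal(unclass(read_params_yaml(preset, "EQUALIZER")),
               unclass(rate_params()))
})
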