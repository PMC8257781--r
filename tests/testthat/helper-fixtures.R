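# Shared fixtures: all built in code, no stored data.

default_p <- rate_params()

# Network cache so repeated test blocks do not rebuild identical objects.
net_of <- local({
  cache <- new.env(parent = emptyenv())
  function(topology, params = default_p) {
    key <- paste0(topology, "#", paste(unlist(params), collapse = ","))
    if (is.null(cache[[key]])) cache[[key]] <- build_network(topology, params)
    cache[[key]]
  }
})

# Unit-mean log-normal noise factors drawn through the public surface,
# continuing the current RNG stream (mirrors the generator's internals).
noise_draw <- function(n, cv = 0.71) {
  apply_intrinsic_noise(rep(1, n), noise_model(cv))
}

expect_rel_equal <- function(x, y, tol) {
  expect_true(all(abs(x - y) <= tol * pmax(abs(y), .Machine$double.eps)),
              label = sprintf("max rel err %.3e <= %g",
                              max(abs(x - y) / pmax(abs(y), 1e-300)), tol))
}
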