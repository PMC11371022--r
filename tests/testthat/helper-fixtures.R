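# Shared fixtures. The canonical-network exposure surface is expensive
# (dozens of stiff ODE solves), so it is computed once per test run and
# memoized here.
.fixture_env <- new.env(parent = emptyenv())

canonical_surface_fixture <- function() {
  if (is.null(.fixture_env$surface)) {
    net <- canonical_network()
    .fixture_env$surface <- exposure_surface(
      net,
      dose_grid = c(5, 10, 20, 30),
      dose_rate_grid = 10^seq(-2, 7, by = 0.75))
  }
  .fixture_env$surface
}

canonical_surrogate_fixture <- function() {
  if (is.null(.fixture_env$surrogate))
    .fixture_env$surrogate <- fit_surrogate(canonical_surface_fixture(),
                                            poly_degree = 3L)
  .fixture_env$surrogate
}

cepc_fixture <- function() cepc_source()

# independent trapezoid quadrature for spectrum oracles
trapz_local <- function(x, y) {
  n <- length(x)
  sum(diff(x) * (y[-1L] + y[-n]) / 2)
}

# moderate-steepness truth for recovery tests: data actually informative
# about both parameters (the packaged steepness saturates all groups)
moderate_truth <- function() ntcp_params(gamma = 15, m = 0.5)
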