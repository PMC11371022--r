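test_that("the sigmoid response has its documented anchors", {
  p <- ntcp_params()
  # midpoint is exactly one half
  expect_equal(ntcp_from_exposure(p, p$m), 0.5)
  # zero exposure under the packaged steepness underflows gracefully
  v0 <- ntcp_from_exposure(p, 0)
  expect_gt(v0, 0)
  expect_lt(v0, 1e-100)
  # near-step behaviour at extreme steepness
  step <- ntcp_params(gamma = 1e8, m = 0.3)
  expect_equal(ntcp_from_exposure(step, 0.2999), 0, tolerance = 1e-12)
  expect_equal(ntcp_from_exposure(step, 0.3001), 1, tolerance = 1e-12)
  # monotone non-decreasing in exposure
  n <- seq(0, 1, by = 0.01)
  expect_true(all(diff(ntcp_from_exposure(ntcp_params(30, 0.4), n)) > 0))
  expect_error(ntcp_from_exposure(p, -0.1), "0, 1")
  expect_error(ntcp_from_exposure(p, 1.2), "0, 1")
  expect_error(ntcp_params(gamma = -1), "positive")
  expect_error(ntcp_params(m = 1.5), "between 0 and 1")
})

test_that("predicted NTCP is non-increasing in dose rate", {
  sur <- canonical_surrogate_fixture()
  p <- ntcp_params()
  dr <- 10^seq(-2, 7, by = 0.25)
  pred <- predict_ntcp(p, sur, 10, dr)
  expect_true(all(pred >= 0 & pred <= 1))
  expect_true(all(diff(pred) <= 1e-9))
  # the conventional plateau is flat
  plat <- predict_ntcp(p, sur, 10, c(0.01, 0.02, 0.03))
  expect_lt(max(plat) - min(plat), 1e-6)
  # FLASH-rate prediction at 10 Gy drops below the conventional one
  expect_lt(predict_ntcp(p, sur, 10, 6.13e6),
            predict_ntcp(p, sur, 10, 0.1))
})

test_that("tolerated-dose roots honour the solver contract", {
  sur <- canonical_surrogate_fixture()
  p <- ntcp_params()
  dr <- 10^seq(0.5, 6, length.out = 10)
  td <- tolerated_dose_surface(p, sur, ntcp_level = 0.5,
                               dose_rate_grid = dr,
                               dose_range = c(1, 45))
  expect_gt(sum(td$reachable), 5)
  # at the 0.5 level the root satisfies N(D, Dr) = m
  i <- which(td$reachable)[1L]
  expect_equal(normalized_exposure(sur, td$dose[i], td$dose_rate[i]),
               p$m, tolerance = 1e-6)
  # NTCP residual at the root is below the solver contract
  expect_lt(abs(predict_ntcp(p, sur, td$dose[i], td$dose_rate[i]) - 0.5),
            1e-6)
  # at conventional dose rates the anchored exposure is 1 for every
  # dose, NTCP saturates at 1, and the 0.5 level is flagged unreachable
  td_conv <- tolerated_dose_surface(p, sur, 0.5, c(1e-2), c(1, 45))
  expect_false(td_conv$reachable)
  expect_true(is.na(td_conv$dose))
})

test_that("tolerated dose rises with dose rate when sparing wanes with dose", {
  # with a sparing amplitude a(D) decreasing in dose, exposure grows
  # with dose and the iso-NTCP dose climbs across the FLASH transition
  sur <- surrogate_coefficients(c(0.95, -0.02), c(2, 0), 0.5)
  p <- ntcp_params()
  dr <- 10^seq(3, 6.5, length.out = 9)
  td <- tolerated_dose_surface(p, sur, 0.5, dr, dose_range = c(0.5, 45))
  reach <- td$dose[td$reachable]
  expect_gt(length(reach), 5)
  expect_true(all(diff(reach) > 0))
})

test_that("the fitter recovers moderate-steepness parameters", {
  truth <- moderate_truth()
  sur <- default_synthetic_surrogate()
  ests <- t(vapply(1:5, function(s) {
    obs <- generate_toxicity_dataset(
      synthetic_design(seed = s, true_params = truth,
                       subjects_per_group = 80))
    coef(ntcp_fit(cbind(responders, total - responders) ~
                    dose_Gy + dose_rate_Gy_s,
                  data = obs, surrogate = sur,
                  start = ntcp_params(10, 0.4), n_boot = 0))
  }, numeric(2)))
  expect_equal(mean(ests[, "m"]), truth$m, tolerance = 0.05)
  expect_equal(mean(ests[, "gamma"]), truth$gamma, tolerance = 0.25)
})

test_that("separated data bracket the midpoint and flag separation", {
  sur <- default_synthetic_surrogate()
  obs <- generate_toxicity_dataset(synthetic_design(seed = 1))
  fit <- ntcp_fit(cbind(responders, total - responders) ~
                    dose_Gy + dose_rate_Gy_s,
                  data = obs, surrogate = sur, n_boot = 0)
  expo <- fit$data$exposure
  frac <- fit$data$responders / fit$data$total
  hi <- min(expo[frac == 1])  # smallest all-responder exposure
  lo <- max(expo[frac == 0])  # largest no-responder exposure
  expect_gt(fit$params$m, lo)
  expect_lt(fit$params$m, hi)
  expect_true(summary(fit)$separated)
})

test_that("refits on self-simulated data fall inside the bootstrap CI", {
  truth <- moderate_truth()
  sur <- default_synthetic_surrogate()
  obs <- generate_toxicity_dataset(
    synthetic_design(seed = 3, true_params = truth,
                     subjects_per_group = 80))
  fml <- cbind(responders, total - responders) ~ dose_Gy + dose_rate_Gy_s
  fit <- ntcp_fit(fml, data = obs, surrogate = sur,
                  start = ntcp_params(10, 0.4), n_boot = 300,
                  boot_seed = 11)
  ci <- confint(fit, level = 0.95)
  hits <- vapply(1:10, function(s) {
    obs2 <- obs
    obs2$responders <- simulate(fit, seed = 100 + s)$sim_1
    f2 <- ntcp_fit(fml, data = obs2, surrogate = sur,
                   start = fit$params, n_boot = 0)
    co <- coef(f2)
    co["m"] >= ci["m", 1] && co["m"] <= ci["m", 2]
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("degenerate designs and malformed responses are rejected", {
  sur <- default_synthetic_surrogate()
  obs <- data.frame(dose_Gy = c(10, 10), dose_rate_Gy_s = c(1, 1),
                    responders = c(1, 2), total = c(10, 10))
  expect_error(
    ntcp_fit(cbind(responders, total - responders) ~
               dose_Gy + dose_rate_Gy_s,
             data = obs, surrogate = sur, n_boot = 0),
    "degenerate")
  obs2 <- generate_toxicity_dataset(synthetic_design(seed = 1))
  expect_error(
    ntcp_fit(responders ~ dose_Gy + dose_rate_Gy_s, data = obs2,
             surrogate = sur, n_boot = 0),
    "two-column")
})

test_that("least-squares mode fits digitized NTCP fractions", {
  truth <- moderate_truth()
  sur <- default_synthetic_surrogate()
  des <- synthetic_design(seed = 5, true_params = truth,
                          outcome = "gaussian", gaussian_sd = 0.03)
  obs <- generate_toxicity_dataset(des)
  obs$fraction <- obs$responders / obs$total
  fit <- ntcp_fit(fraction ~ dose_Gy + dose_rate_Gy_s, data = obs,
                  surrogate = sur, method = "least-squares",
                  start = ntcp_params(10, 0.4), n_boot = 0)
  expect_equal(coef(fit)[["m"]], truth$m, tolerance = 0.1)
  expect_equal(coef(fit)[["gamma"]], truth$gamma, tolerance = 0.5)
})

test_that("ntcp_fit methods behave like a classed model fit", {
  truth <- moderate_truth()
  sur <- default_synthetic_surrogate()
  obs <- generate_toxicity_dataset(
    synthetic_design(seed = 2, true_params = truth,
                     subjects_per_group = 60))
  fit <- ntcp_fit(cbind(responders, total - responders) ~
                    dose_Gy + dose_rate_Gy_s,
                  data = obs, surrogate = sur,
                  start = ntcp_params(10, 0.4), n_boot = 50,
                  boot_seed = 7)
  expect_named(coef(fit), c("gamma", "m"))
  expect_equal(dim(vcov(fit)), c(2L, 2L))
  expect_s3_class(logLik(fit), "logLik")
  expect_equal(attr(logLik(fit), "df"), 2L)
  pr <- predict(fit)
  expect_true(all(pr >= 0 & pr <= 1))
  nd <- data.frame(dose_Gy = 10, dose_rate_Gy_s = c(0.1, 6.13e6))
  expect_length(predict(fit, nd), 2L)
  expect_equal(predict(fit, nd, type = "exposure"),
               normalized_exposure(sur, 10, c(0.1, 6.13e6)))
  rs <- residuals(fit)
  expect_true(all(is.finite(rs)))
  expect_equal(residuals(fit, "response"),
               with(fit$data, responders / total - fitted))
  sim1 <- simulate(fit, nsim = 2, seed = 9)
  sim2 <- simulate(fit, nsim = 2, seed = 9)
  expect_identical(sim1, sim2)
  expect_true(all(sim1$sim_1 <= fit$data$total))
  expect_output(print(summary(fit)), "gamma")
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  expect_invisible(plot(fit))
})

test_that("toxicity observations round-trip through CSV", {
  obs <- generate_toxicity_dataset(synthetic_design(seed = 4))
  path <- tempfile(fileext = ".csv")
  write_toxicity_csv(obs, path)
  back <- read_toxicity_csv(path)
  expect_equal(back$responders, obs$responders)
  expect_equal(back$dose_rate_Gy_s, obs$dose_rate_Gy_s, tolerance = 1e-10)
  bad <- obs; bad$responders[1] <- bad$total[1] + 5
  path2 <- tempfile(fileext = ".csv")
  utils::write.csv(bad, path2, row.names = FALSE)
  expect_error(read_toxicity_csv(path2), "responders")
})
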