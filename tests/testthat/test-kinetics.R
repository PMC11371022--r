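test_that("first-order decay matches its closed form tightly", {
  net <- reaction_network(list(species("A", initial = 1e-3)),
                          list(reaction("A ->", 2)))
  res <- integrate_kinetics(net, irradiation_protocol(0, 1, followup = 5),
                            roo_species = NULL)
  exact <- 1e-3 * exp(-2 * res$time)
  expect_equal(res$concentrations[, "A"], exact, tolerance = 1e-6)
})

test_that("production-decay exposure matches the g D / k closed form", {
  # S produced at g Dr for T = D/Dr, decaying at k: AUC over [0, inf)
  # is p T / k = g D / k independent of the dose rate split
  net <- generate_toy_network("production-decay", g_value = 0.28, k = 0.5)
  for (dr in c(2, 50)) {
    prot <- irradiation_protocol(10, dr, followup = 40)
    res <- integrate_kinetics(net, prot, roo_species = "S",
                              n_irradiation = 400L, n_followup = 2000L)
    expect_equal(res$roo_auc, 0.28e-6 * 10 / 0.5, tolerance = 1e-4)
    # trajectory against the attached analytic solution
    exact <- attr(net, "analytic")(res$time, prot)
    expect_equal(res$concentrations[, "S"], unname(exact[, "S"]),
                 tolerance = 1e-5)
  }
})

test_that("a linear chain conserves mass and matches its closed form", {
  net <- generate_toy_network("linear-chain", k = 1.2, r0 = 2e-6)
  prot <- irradiation_protocol(0, 1, followup = 10)
  res <- integrate_kinetics(net, prot, roo_species = NULL,
                            n_followup = 1200L)
  exact <- attr(net, "analytic")(res$time, prot)
  expect_equal(res$concentrations[, "A"], unname(exact[, "A"]),
               tolerance = 1e-5)
  expect_equal(res$concentrations[, "B"], unname(exact[, "B"]),
               tolerance = 1e-4)
  total <- rowSums(res$concentrations)
  expect_equal(total, rep(2e-6, length(total)), tolerance = 1e-8)
})

test_that("oxygen capture conserves R + ROO and O2 + ROO", {
  net <- generate_toy_network("oxygen-capture", r0 = 1e-6, o2 = 1e-3)
  res <- integrate_kinetics(net, irradiation_protocol(0, 1, followup = 1e-5),
                            roo_species = "ROO", n_followup = 800L)
  conc <- res$concentrations
  expect_equal(conc[, "R"] + conc[, "ROO"],
               rep(1e-6, nrow(conc)), tolerance = 1e-8)
  expect_equal(conc[, "O2"] + conc[, "ROO"],
               rep(1e-3, nrow(conc)), tolerance = 1e-8)
  # pseudo-first-order closed form in the excess-oxygen limit
  exact <- attr(net, "analytic")(res$time, NULL)
  expect_equal(conc[, "R"], unname(exact[, "R"]), tolerance = 2e-3)
})

test_that("zero dose leaves initial concentrations untouched", {
  net <- canonical_network()
  res <- integrate_kinetics(net, irradiation_protocol(0, 1, followup = 1))
  expect_equal(res$roo_auc, 0)
  o2 <- res$concentrations[, "O2"]
  expect_equal(o2, rep(o2[1L], length(o2)), tolerance = 1e-8)
  expect_true(all(res$concentrations[, "e_aq"] == 0))
})

test_that("linear kinetics rescale when dose rate and rates are halved", {
  # dS/dt = g Dr - k S: halving Dr and k and doubling the horizon maps
  # trajectories onto each other and doubles the exposure integral
  auc <- function(dr, k, fu) {
    net <- generate_toy_network("production-decay", g_value = 0.3, k = k)
    integrate_kinetics(net, irradiation_protocol(8, dr, followup = fu),
                       roo_species = "S", n_irradiation = 300L,
                       n_followup = 1200L)$roo_auc
  }
  expect_equal(auc(4, 0.25, 80), 2 * auc(8, 0.5, 40), tolerance = 1e-4)
})

test_that("canonical-network concentrations stay nonnegative", {
  net <- canonical_network()
  for (dr in c(0.1, 1e3, 1e7)) {
    res <- integrate_kinetics(net, irradiation_protocol(10, dr))
    expect_true(all(res$concentrations >= 0))
    expect_gt(res$roo_auc, 0)
  }
})

test_that("the irradiation-only AUC window is a lower bound", {
  net <- canonical_network()
  prot <- irradiation_protocol(10, 100)
  full <- integrate_kinetics(net, prot, auc_window = "total")
  irr <- integrate_kinetics(net, prot, auc_window = "irradiation")
  expect_lt(irr$roo_auc, full$roo_auc)
})

test_that("kinetics results export as long CSV", {
  net <- generate_toy_network("production-decay")
  res <- integrate_kinetics(net, irradiation_protocol(5, 10, followup = 1),
                            roo_species = "S")
  path <- tempfile(fileext = ".csv")
  write_kinetics_csv(res, path)
  back <- utils::read.csv(path)
  expect_named(back, c("time_s", "species", "concentration_M"))
  expect_equal(nrow(back), length(res$time) * ncol(res$concentrations))
})

test_that("raw peroxyl exposure shows the FLASH sparing signature", {
  surf <- canonical_surface_fixture()
  raw10 <- surf$raw[match(10, surf$dose_grid), ]
  r <- surf$dose_rate_grid
  expect_lt(raw10[which.min(abs(r - 1e6))],
            raw10[which.min(abs(r - 0.1))])
})

test_that("normalized exposure surfaces anchor at the lowest dose rate", {
  surf <- canonical_surface_fixture()
  expect_equal(unname(surf$normalized[, 1L]),
               rep(1, length(surf$dose_grid)))
  expect_true(all(surf$normalized > 0 & surf$normalized <= 1))
  # non-increasing along dose rate for every dose row; the far plateau
  # beyond the transition carries a real sub-percent wiggle, so allow it
  for (i in seq_along(surf$dose_grid)) {
    row <- surf$normalized[i, ]
    expect_true(all(diff(row) <= 5e-3))
    # strictly decreasing across the transition itself
    trans <- surf$dose_rate_grid <= 1e4
    expect_true(all(diff(row[trans]) < 0))
  }
  # deeper sparing at higher dose (stronger oxygen depletion)
  plateau <- surf$normalized[, ncol(surf$normalized)]
  expect_true(all(diff(plateau) < 0))
})

test_that("doubling the dose doubles the linear-regime exposure", {
  net <- generate_toy_network("production-decay", g_value = 0.28, k = 0.5)
  a1 <- integrate_kinetics(net, irradiation_protocol(5, 0.5, followup = 40),
                           roo_species = "S", n_followup = 1000L)$roo_auc
  a2 <- integrate_kinetics(net, irradiation_protocol(10, 0.5, followup = 40),
                           roo_species = "S", n_followup = 1000L)$roo_auc
  expect_equal(a2 / a1, 2, tolerance = 1e-3)
})
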