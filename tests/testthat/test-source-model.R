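test_that("closed-form source quantities match hand-evaluated values", {
  s <- cepc_fixture()
  # 88.5 * 120^4 / 10700
  expect_equal(energy_loss_per_turn(s), 1.71508e6, tolerance = 1e-5)
  # keV * mA = W, at the CDR beam current
  expect_equal(total_power(s), 1.71508e6 * 17.4, tolerance = 1e-5)
  expect_equal(power_per_unit_length(s),
               total_power(s) / (2 * pi * 10700))
  expect_equal(power_per_unit_length(s), 443.9, tolerance = 1e-3)
  # 2.218 * 120^3 / 10700
  expect_equal(critical_energy(s), 358.197, tolerance = 1e-5)
  # arc length of the magnet
  expect_equal(10700 * 2.844e-3, 30.43, tolerance = 1e-3)
})

test_that("photon rates agree with the published chain", {
  s <- cepc_fixture()
  # closed form with the CDR current lands within ~7% of the published
  # per-metre rate (the current behind that figure is not stated)
  expect_equal(photon_rate_per_unit_length(s), 2.363e16, tolerance = 0.07)
  # arc multiplication with the published per-metre rate reproduces the
  # published magnet rate
  expect_equal(magnet_photon_rate(s, rate_per_metre = 2.363e16),
               7.19e17, tolerance = 2e-3)
  # exact factorization through the arc length
  expect_equal(magnet_photon_rate(s) / photon_rate_per_unit_length(s),
               s$bend_radius * s$bend_angle, tolerance = 1e-12)
})

test_that("source outputs scale as E^4/rho, E^3/rho and linearly in current", {
  base <- bending_magnet_source(60, 8000, beam_current = 10)
  e2 <- bending_magnet_source(120, 8000, beam_current = 10)
  r2 <- bending_magnet_source(60, 16000, beam_current = 10)
  i2 <- bending_magnet_source(60, 8000, beam_current = 20)
  expect_equal(energy_loss_per_turn(e2) / energy_loss_per_turn(base), 16)
  expect_equal(energy_loss_per_turn(r2) / energy_loss_per_turn(base), 0.5)
  expect_equal(critical_energy(e2) / critical_energy(base), 8)
  expect_equal(total_power(i2) / total_power(base), 2)
  expect_equal(photon_rate_per_unit_length(i2) /
                 photon_rate_per_unit_length(base), 2)
  # current-independent quantities
  expect_equal(energy_loss_per_turn(i2), energy_loss_per_turn(base))
  expect_equal(critical_energy(i2), critical_energy(base))
  # per-unit-length power ignores the bend angle
  a2 <- bending_magnet_source(60, 8000, beam_current = 10,
                              bend_angle = 5.688e-3)
  expect_equal(power_per_unit_length(a2), power_per_unit_length(base))
  # zero current, zero power
  i0 <- bending_magnet_source(60, 8000, beam_current = 0)
  expect_equal(total_power(i0), 0)
})

test_that("the K_5/3 spectrum integrates to the closed-form totals", {
  s <- cepc_fixture()
  ec <- critical_energy(s)
  energy <- 10^seq(-9, log10(40), length.out = 700) * ec
  spec <- photon_spectrum(s, energy)
  expect_true(all(spec >= 0))
  # vanishes in the hard tail
  expect_lt(spec[length(spec)] * energy[length(energy)],
            1e-12 * max(spec * energy))
  p_e <- energy_loss_per_turn(s) * s$revolution_frequency
  # energy-weighted integral = single-electron radiated power
  expect_equal(trapz_local(energy, energy * spec), p_e, tolerance = 5e-3)
  # number-weighted integral = (15 sqrt(3) / 8) P_e / E_c
  expect_equal(trapz_local(energy, spec), 15 * sqrt(3) / 8 * p_e / ec,
               tolerance = 5e-3)
  # per-unit-length closed form equals quadrature x electrons per metre
  n_e_per_m <- s$beam_current * 1e-3 /
    (1.602176634e-19 * s$revolution_frequency) / (2 * pi * s$bend_radius)
  expect_equal(photon_rate_per_unit_length(s),
               trapz_local(energy, spec) * n_e_per_m, tolerance = 5e-3)
})

test_that("equal radiated energy lies on both sides of the critical energy", {
  s <- cepc_fixture()
  ec <- critical_energy(s)
  energy <- 10^seq(-6, log10(45), length.out = 2000) * ec
  spec <- photon_spectrum(s, energy)
  power <- energy * spec
  below <- energy <= ec
  ratio <- trapz_local(energy[below], power[below]) /
    trapz_local(energy, power)
  expect_equal(ratio, 0.5, tolerance = 5e-3)
})

test_that("spectrum rejects non-positive or unsorted grids", {
  s <- cepc_fixture()
  expect_error(photon_spectrum(s, c(0, 1, 2)), "positive")
  expect_error(photon_spectrum(s, c(-1, 1)), "positive")
  expect_error(photon_spectrum(s, c(2, 1)), "ascending")
})

test_that("pulse structure follows the bunch pattern", {
  s <- cepc_fixture()
  ps <- pulse_structure(s, mean_dose_rate = 6.13e6)
  expect_equal(ps$pulses_per_second, 242 * 3003)
  expect_equal(ps$pulses_per_second, 726726)
  expect_equal(ps$pulse_period * ps$pulses_per_second, 1)
  expect_equal(ps$dose_per_pulse * ps$pulses_per_second, 6.13e6,
               tolerance = 1e-12)
  expect_equal(ps$instantaneous_dose_rate,
               ps$dose_per_pulse / 14.7e-12)
  ps0 <- pulse_structure(s, 0)
  expect_equal(ps0$dose_per_pulse, 0)
  expect_equal(ps0$instantaneous_dose_rate, 0)
})

test_that("source constructor enforces its invariants", {
  expect_error(bending_magnet_source(-1, 10700), "positive")
  expect_error(bending_magnet_source(120, 0), "positive")
  expect_error(bending_magnet_source(120, 10700, beam_current = -2),
               "nonnegative")
  # duty factor at or above unity is unphysical
  expect_error(bending_magnet_source(120, 10700, n_bunches = 1000,
                                     revolution_frequency = 3003,
                                     bunch_duration = 1e-3),
               "duty factor")
})

test_that("the packaged machine file carries the published parameters", {
  s <- cepc_source()
  expect_equal(s$electron_energy, 120)
  expect_equal(s$bend_radius, 10700)
  expect_equal(s$bend_angle, 2.844e-3)
  expect_equal(s$n_bunches, 242L)
  expect_equal(s$revolution_frequency, 3003)
  expect_equal(s$bunch_duration, 14.7e-12)
  expect_equal(s$sigma_x, 2.09e-2)
  expect_equal(s$emittance_x, 1.21)
})
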