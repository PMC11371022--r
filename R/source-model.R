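#' Bending-magnet synchrotron source description
#'
#' Collects the machine and optics parameters of a storage-ring bending
#' magnet that drive all closed-form source quantities: the energy loss per
#' turn, radiated power, critical energy, photon spectrum and photon rates,
#' and the bunch-by-bunch pulse structure of the emitted beam.
#'
#' @param electron_energy Electron energy E in GeV.
#' @param bend_radius Radius of curvature rho of the bending magnet in m.
#' @param beam_current Stored beam current I in mA. May be zero (no beam).
#' @param bend_angle Bending angle of the magnet in rad.
#' @param n_bunches Number of circulating bunches.
#' @param revolution_frequency Revolution frequency in Hz.
#' @param bunch_duration Duration of a single bunch in s.
#' @param sigma_x,sigma_y Horizontal/vertical RMS beam size in mm (optional,
#'   carried for reference; they do not enter the closed-form quantities).
#' @param emittance_x,emittance_y Horizontal/vertical emittance in nm rad
#'   (optional, carried for reference).
#'
#' @return An object of class \code{"bending_magnet_source"}.
#' @seealso \code{\link{source_summary}}, \code{\link{pulse_structure}},
#'   \code{\link{cepc_source}}
#' @export
bending_magnet_source <- function(electron_energy,
                                  bend_radius,
                                  beam_current = 17.4,
                                  bend_angle = 2.844e-3,
                                  n_bunches = 242L,
                                  revolution_frequency = 3003,
                                  bunch_duration = 14.7e-12,
                                  sigma_x = NA_real_, sigma_y = NA_real_,
                                  emittance_x = NA_real_,
                                  emittance_y = NA_real_) {
  check_scalar(electron_energy, "electron_energy", positive = TRUE)
  check_scalar(bend_radius, "bend_radius", positive = TRUE)
  check_scalar(beam_current, "beam_current", nonneg = TRUE)
  check_scalar(bend_angle, "bend_angle", positive = TRUE)
  check_scalar(n_bunches, "n_bunches", positive = TRUE)
  check_scalar(revolution_frequency, "revolution_frequency", positive = TRUE)
  check_scalar(bunch_duration, "bunch_duration", positive = TRUE)
  if (n_bunches < 1) stop_domain("'n_bunches' must be at least 1")
  duty <- bunch_duration * n_bunches * revolution_frequency
  if (duty >= 1)
    stop_domain("duty factor (bunch_duration * n_bunches * ",
                "revolution_frequency) must be below unity, got ", duty)
  structure(
    list(electron_energy = electron_energy,
         bend_radius = bend_radius,
         beam_current = beam_current,
         bend_angle = bend_angle,
         n_bunches = as.integer(n_bunches),
         revolution_frequency = revolution_frequency,
         bunch_duration = bunch_duration,
         sigma_x = sigma_x, sigma_y = sigma_y,
         emittance_x = emittance_x, emittance_y = emittance_y),
    class = "bending_magnet_source")
}

#' @export
print.bending_magnet_source <- function(x, ...) {
  cat("Bending-magnet synchrotron source\n")
  cat(sprintf("  electron energy      : %g GeV\n", x$electron_energy))
  cat(sprintf("  bend radius          : %g m\n", x$bend_radius))
  cat(sprintf("  beam current         : %g mA\n", x$beam_current))
  cat(sprintf("  bend angle           : %g mrad\n", 1e3 * x$bend_angle))
  cat(sprintf("  bunches x f_rev      : %d x %g Hz\n",
              x$n_bunches, x$revolution_frequency))
  cat(sprintf("  bunch duration       : %g ps\n", 1e12 * x$bunch_duration))
  invisible(x)
}

#' Machine parameters of the CEPC bending magnet
#'
#' Convenience constructor reading the packaged CEPC machine description
#' (120 GeV electrons, 10700 m bend radius, 2.844 mrad bend angle, 242
#' bunches at 3003 Hz revolution frequency, 14.7 ps bunches) from the
#' shipped YAML file.
#'
#' @param path Optional path to an alternative machine YAML file with the
#'   same keys.
#' @return A \code{\link{bending_magnet_source}}.
#' @export
cepc_source <- function(path = system.file("extdata", "cepc.yaml",
                                           package = "synflash")) {
  cfg <- yaml::read_yaml(path)
  bending_magnet_source(
    electron_energy = cfg$electron_energy_GeV,
    bend_radius = cfg$bend_radius_m,
    beam_current = cfg$beam_current_mA,
    bend_angle = cfg$bend_angle_rad,
    n_bunches = cfg$n_bunches,
    revolution_frequency = cfg$revolution_frequency_Hz,
    bunch_duration = cfg$bunch_duration_s,
    sigma_x = cfg$sigma_x_mm %||% NA_real_,
    sigma_y = cfg$sigma_y_mm %||% NA_real_,
    emittance_x = cfg$emittance_x_nmrad %||% NA_real_,
    emittance_y = cfg$emittance_y_nmrad %||% NA_real_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Energy radiated by one electron per turn
#'
#' Isomagnetic-ring practical formula U[keV] = 88.5 E^4[GeV] / rho[m].
#'
#' @param source A \code{\link{bending_magnet_source}}.
#' @return Energy loss per turn in keV.
#' @export
energy_loss_per_turn <- function(source) {
  stopifnot(inherits(source, "bending_magnet_source"))
  .U_COEF * source$electron_energy^4 / source$bend_radius
}

#' Total synchrotron-radiation power of the stored beam
#'
#' P[W] = U[keV] x I[mA]; the keV.mA product is numerically a watt.
#'
#' @inheritParams energy_loss_per_turn
#' @return Radiated power in W.
#' @export
total_power <- function(source) {
  energy_loss_per_turn(source) * source$beam_current
}

#' Radiated power per unit length of bending path
#'
#' Total power divided by the full bending circumference 2 pi rho.
#'
#' @inheritParams energy_loss_per_turn
#' @return Power per unit length in W/m.
#' @export
power_per_unit_length <- function(source) {
  total_power(source) / (2 * pi * source$bend_radius)
}

#' Critical energy of the synchrotron spectrum
#'
#' E_c[keV] = 2.218 E^3[GeV] / rho[m]. The critical energy splits the
#' spectrum into two halves of equal radiated energy and characterizes the
#' spectral hardness of the source.
#'
#' @inheritParams energy_loss_per_turn
#' @return Critical energy in keV.
#' @export
critical_energy <- function(source) {
  stopifnot(inherits(source, "bending_magnet_source"))
  .EC_COEF * source$electron_energy^3 / source$bend_radius
}

# Universal synchrotron spectral shape F(xi) = (9 sqrt(3) / 8 pi) *
# xi * int_xi^inf K_{5/3}(x) dx, normalized so int_0^inf F = 1.
# The Bessel-tail integral is evaluated by adaptive quadrature: on a log
# abscissa below t = 1 (K_{5/3} ~ t^(-5/3) there, so the linear-scale
# integrand spans many decades) and on the linear scale above, truncated
# where the exponentially decaying integrand falls below 1e-30
# (K_{5/3}(80) ~ 1e-36).
synchrotron_shape <- function(xi) {
  k53_tail <- function(x) {
    lo <- min(x, 1)
    val <- stats::integrate(function(t) besselK(t, 5 / 3),
                            lower = max(x, 1), upper = 81,
                            rel.tol = 1e-10, abs.tol = 0,
                            subdivisions = 500L)$value
    if (x < 1)
      val <- val + stats::integrate(function(s) exp(s) * besselK(exp(s), 5 / 3),
                                    lower = log(x), upper = 0,
                                    rel.tol = 1e-10, abs.tol = 0,
                                    subdivisions = 500L)$value
    val
  }
  vapply(xi, function(x) {
    if (x <= 0) stop_domain("spectral variable must be positive")
    9 * sqrt(3) / (8 * pi) * x * k53_tail(x)
  }, numeric(1))
}

#' Single-electron synchrotron photon spectrum
#'
#' Photon number spectrum emitted by one circulating electron,
#' dN/dE = (P_e / (E_c E)) F(E / E_c), where F is the universal
#' K_{5/3} shape and P_e = U f_rev is the power radiated by a single
#' electron. The energy-weighted integral of the returned spectrum equals
#' P_e; the number-weighted integral equals (15 sqrt(3) / 8) P_e / E_c.
#'
#' @inheritParams energy_loss_per_turn
#' @param photon_energy Strictly positive, ascending photon energies in keV.
#' @return Photons s^-1 keV^-1 per electron, same length as
#'   \code{photon_energy}.
#' @export
photon_spectrum <- function(source, photon_energy) {
  stopifnot(inherits(source, "bending_magnet_source"))
  if (any(!is.finite(photon_energy)) || any(photon_energy <= 0))
    stop_domain("'photon_energy' grid must be strictly positive")
  if (is.unsorted(photon_energy, strictly = TRUE))
    stop_domain("'photon_energy' grid must be strictly ascending")
  ec <- critical_energy(source)
  # single-electron radiated power in keV/s
  p_e <- energy_loss_per_turn(source) * source$revolution_frequency
  p_e / (ec * photon_energy) * synchrotron_shape(photon_energy / ec)
}

#' Photon rate emitted per unit length of bending path
#'
#' Closed form (15 sqrt(3) / 8) x power-per-unit-length / critical energy,
#' i.e. the exact integral of the K_{5/3} number spectrum.
#'
#' @inheritParams energy_loss_per_turn
#' @return Photons m^-1 s^-1.
#' @export
photon_rate_per_unit_length <- function(source) {
  ec_joule <- critical_energy(source) * 1e3 * .QE
  .PHOTON_RATE_FACTOR * power_per_unit_length(source) / ec_joule
}

#' Photon rate of one bending magnet
#'
#' Multiplies a per-metre photon rate by the arc length (bend radius x bend
#' angle) of the magnet. The per-metre rate defaults to the closed-form
#' value for the source but can be supplied explicitly (e.g. a published
#' figure).
#'
#' @inheritParams energy_loss_per_turn
#' @param rate_per_metre Photon rate per unit length in photons m^-1 s^-1.
#' @return Photons s^-1 emitted over the magnet arc.
#' @export
magnet_photon_rate <- function(source,
                               rate_per_metre = photon_rate_per_unit_length(source)) {
  stopifnot(inherits(source, "bending_magnet_source"))
  check_scalar(rate_per_metre, "rate_per_metre", nonneg = TRUE)
  rate_per_metre * source$bend_radius * source$bend_angle
}

#' Closed-form source summary
#'
#' @inheritParams energy_loss_per_turn
#' @return An object of class \code{"source_summary"}: energy loss per turn
#'   (keV), total power (W), power per unit length (W/m), critical energy
#'   (keV), photon rate per unit length (m^-1 s^-1) and the photon rate of
#'   the magnet (s^-1).
#' @export
source_summary <- function(source) {
  structure(
    list(energy_loss_per_turn_keV = energy_loss_per_turn(source),
         total_power_W = total_power(source),
         power_per_unit_length_W_m = power_per_unit_length(source),
         critical_energy_keV = critical_energy(source),
         photon_rate_per_unit_length = photon_rate_per_unit_length(source),
         magnet_photon_rate = magnet_photon_rate(source)),
    class = "source_summary")
}

#' @export
print.source_summary <- function(x, ...) {
  cat("Synchrotron source summary\n")
  cat(sprintf("  energy loss per turn     : %.4g keV\n",
              x$energy_loss_per_turn_keV))
  cat(sprintf("  total radiated power     : %.4g W\n", x$total_power_W))
  cat(sprintf("  power per unit length    : %.4g W/m\n",
              x$power_per_unit_length_W_m))
  cat(sprintf("  critical energy          : %.4g keV\n",
              x$critical_energy_keV))
  cat(sprintf("  photon rate per metre    : %.4g m^-1 s^-1\n",
              x$photon_rate_per_unit_length))
  cat(sprintf("  magnet photon rate       : %.4g s^-1\n",
              x$magnet_photon_rate))
  invisible(x)
}

#' Pulse structure of the emitted beam
#'
#' Converts the bunch filling pattern into a pulse description: the pulse
#' rate (bunches x revolution frequency), the pulse period, and - given a
#' mean dose rate at the target - the dose delivered per pulse and the
#' instantaneous dose rate within one bunch.
#'
#' @inheritParams energy_loss_per_turn
#' @param mean_dose_rate Time-averaged dose rate at the target in Gy/s.
#' @return An object of class \code{"pulse_structure"} with fields
#'   \code{pulses_per_second}, \code{pulse_period} (s),
#'   \code{dose_per_pulse} (Gy) and \code{instantaneous_dose_rate} (Gy/s).
#' @export
pulse_structure <- function(source, mean_dose_rate = 0) {
  stopifnot(inherits(source, "bending_magnet_source"))
  check_scalar(mean_dose_rate, "mean_dose_rate", nonneg = TRUE)
  pps <- source$n_bunches * source$revolution_frequency
  if (pps <= 0) stop_domain("pulse rate must be positive")
  dpp <- mean_dose_rate / pps
  structure(
    list(pulses_per_second = pps,
         pulse_period = 1 / pps,
         dose_per_pulse = dpp,
         instantaneous_dose_rate = dpp / source$bunch_duration),
    class = "pulse_structure")
}

#' @export
print.pulse_structure <- function(x, ...) {
  cat("Beam pulse structure\n")
  cat(sprintf("  pulses per second        : %.6g\n", x$pulses_per_second))
  cat(sprintf("  pulse period             : %.4g s\n", x$pulse_period))
  cat(sprintf("  dose per pulse           : %.4g Gy\n", x$dose_per_pulse))
  cat(sprintf("  instantaneous dose rate  : %.4g Gy/s\n",
              x$instantaneous_dose_rate))
  invisible(x)
}
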