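#' Dose curve (depth dose or lateral profile)
#'
#' A sampled one-dimensional dose distribution: depth along the beam axis
#' for a percentage-depth-dose (PDD) curve, or lateral position for a
#' profile. Coordinates are physical millimetres, zero at the phantom
#' entrance (or field centre for profiles).
#'
#' @param coordinate Strictly ascending positions in mm, length >= 3.
#' @param dose Nonnegative doses (arbitrary units), same length.
#' @return An object of class \code{"dose_curve"}.
#' @export
dose_curve <- function(coordinate, dose) {
  if (length(coordinate) != length(dose))
    stop_domain("'coordinate' and 'dose' must have the same length")
  if (length(coordinate) < 3L)
    stop_domain("a dose curve needs at least 3 points")
  if (any(!is.finite(coordinate)) || any(!is.finite(dose)))
    stop_domain("dose curve values must be finite")
  if (is.unsorted(coordinate, strictly = TRUE))
    stop_domain("'coordinate' must be strictly ascending")
  if (any(dose < 0)) stop_domain("doses must be nonnegative")
  structure(list(coordinate = as.numeric(coordinate),
                 dose = as.numeric(dose)),
            class = "dose_curve")
}

#' @export
print.dose_curve <- function(x, ...) {
  cat(sprintf("Dose curve: %d points, %g..%g mm, max dose %g at %g mm\n",
              length(x$coordinate), min(x$coordinate), max(x$coordinate),
              max(x$dose), x$coordinate[which.max(x$dose)]))
  invisible(x)
}

#' Read / write a dose curve as two-column CSV
#'
#' The file format is a one-line header \code{coordinate_mm,dose} followed
#' by comma-separated numeric rows.
#'
#' @param path File path.
#' @return \code{read_dose_curve} returns a \code{\link{dose_curve}};
#'   \code{write_dose_curve} returns \code{path} invisibly.
#' @export
read_dose_curve <- function(path) {
  d <- utils::read.csv(path)
  dose_curve(d[[1L]], d[[2L]])
}

#' @rdname read_dose_curve
#' @param curve A \code{\link{dose_curve}}.
#' @export
write_dose_curve <- function(curve, path) {
  stopifnot(inherits(curve, "dose_curve"))
  utils::write.csv(data.frame(coordinate_mm = curve$coordinate,
                              dose = curve$dose),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Energy-deposition geometry of a scoring voxel
#'
#' Holds the per-photon energy deposit e (eV), the scoring volume V (m^3)
#' and the medium density rho (kg/m^3) entering the mean dose-rate
#' relation Dr = e q_e N / (V rho).
#'
#' @param per_photon_energy_deposit Mean deposited energy per incident
#'   photon in eV.
#' @param scoring_volume Scoring volume in m^3.
#' @param medium_density Medium density in kg/m^3 (water: 1000).
#' @return An object of class \code{"deposition_geometry"}.
#' @export
deposition_geometry <- function(per_photon_energy_deposit,
                                scoring_volume,
                                medium_density = 1000) {
  check_scalar(per_photon_energy_deposit, "per_photon_energy_deposit",
               nonneg = TRUE)
  check_scalar(scoring_volume, "scoring_volume", positive = TRUE)
  check_scalar(medium_density, "medium_density", positive = TRUE)
  structure(list(per_photon_energy_deposit = per_photon_energy_deposit,
                 scoring_volume = scoring_volume,
                 medium_density = medium_density),
            class = "deposition_geometry")
}

#' Mean dose rate from a photon rate
#'
#' Dr[Gy/s] = e[eV] q_e N[s^-1] / (V rho), i.e. deposited power divided by
#' the scoring mass; a gray is one joule per kilogram.
#'
#' @param geometry A \code{\link{deposition_geometry}}.
#' @param photon_rate Photons per second reaching the scoring volume.
#' @return Dose rate in Gy/s.
#' @export
dose_rate <- function(geometry, photon_rate) {
  stopifnot(inherits(geometry, "deposition_geometry"))
  check_scalar(photon_rate, "photon_rate", nonneg = TRUE)
  mass <- geometry$scoring_volume * geometry$medium_density
  if (mass <= 0) stop_domain("scoring mass must be positive")
  geometry$per_photon_energy_deposit * .QE * photon_rate / mass
}

#' Normalize a depth-dose curve to its maximum
#'
#' Divides all doses by d_max so that the returned curve has maximum
#' exactly 1 (the conventional PDD normalization).
#'
#' @param curve A \code{\link{dose_curve}} with positive maximum.
#' @return A normalized \code{\link{dose_curve}}.
#' @export
normalize_pdd <- function(curve) {
  stopifnot(inherits(curve, "dose_curve"))
  dmax <- max(curve$dose)
  if (dmax <= 0) stop_domain("cannot normalize an all-zero dose curve")
  dose_curve(curve$coordinate, curve$dose / dmax)
}

# linearly interpolated coordinate where dose crosses 'level' between
# samples i and i+1
.cross_at <- function(x, y, i, level) {
  x[i] + (level - y[i]) * (x[i + 1L] - x[i]) / (y[i + 1L] - y[i])
}

#' Effective treatment range of a depth-dose curve
#'
#' Returns the contiguous depth interval around the dose maximum where the
#' dose stays at or above \code{threshold_fraction} of d_max (the 85
#' percent cut-off convention by default). Interval boundaries are located
#' by linear interpolation between adjacent samples. If the curve never
#' drops below the threshold on a side, the boundary is clamped to the
#' curve end and flagged. Additional super-threshold lobes of multi-modal
#' curves are reported separately.
#'
#' @param curve A \code{\link{dose_curve}} (raw or normalized).
#' @param threshold_fraction Fraction of the maximum dose defining the
#'   cut-off, in (0, 1).
#' @return An object of class \code{"treatment_range"}: \code{start},
#'   \code{end} (mm), logical \code{clamped_start}/\code{clamped_end},
#'   \code{width}, and \code{other_lobes} (two-column matrix of any other
#'   super-threshold intervals).
#' @export
effective_treatment_range <- function(curve, threshold_fraction = 0.85) {
  stopifnot(inherits(curve, "dose_curve"))
  check_scalar(threshold_fraction, "threshold_fraction")
  if (threshold_fraction <= 0 || threshold_fraction >= 1)
    stop_domain("'threshold_fraction' must lie strictly between 0 and 1")
  x <- curve$coordinate
  y <- curve$dose
  dmax <- max(y)
  if (dmax <= 0) stop_domain("curve has no positive dose")
  level <- threshold_fraction * dmax
  imax <- which.max(y)
  n <- length(x)

  # walk left from the peak
  i <- imax
  while (i > 1L && y[i - 1L] >= level) i <- i - 1L
  if (i == 1L) {
    start <- x[1L]; clamped_start <- TRUE
  } else {
    start <- .cross_at(x, y, i - 1L, level); clamped_start <- FALSE
  }
  # walk right
  j <- imax
  while (j < n && y[j + 1L] >= level) j <- j + 1L
  if (j == n) {
    end <- x[n]; clamped_end <- TRUE
  } else {
    end <- .cross_at(x, y, j, level); clamped_end <- FALSE
  }

  # other contiguous super-threshold lobes (multi-modal curves)
  above <- y >= level
  runs <- rle(above)
  stops <- cumsum(runs$lengths)
  starts <- c(1L, head(stops, -1L) + 1L)
  lobes <- NULL
  for (r in seq_along(runs$values)) {
    if (!runs$values[r]) next
    a <- starts[r]; b <- stops[r]
    if (a <= imax && imax <= b) next  # main interval
    lo <- if (a == 1L) x[1L] else .cross_at(x, y, a - 1L, level)
    hi <- if (b == n) x[n] else .cross_at(x, y, b, level)
    lobes <- rbind(lobes, c(start = lo, end = hi))
  }

  structure(list(start = start, end = end, width = end - start,
                 clamped_start = clamped_start, clamped_end = clamped_end,
                 threshold_fraction = threshold_fraction,
                 other_lobes = lobes),
            class = "treatment_range")
}

#' @export
print.treatment_range <- function(x, ...) {
  cat(sprintf("Effective treatment range (>= %g%% of d_max): %.3g .. %.3g mm (width %.3g mm)\n",
              100 * x$threshold_fraction, x$start, x$end, x$width))
  if (x$clamped_start || x$clamped_end)
    cat("  note: boundary clamped to curve end on",
        paste(c("left", "right")[c(x$clamped_start, x$clamped_end)],
              collapse = " and "), "\n")
  if (!is.null(x$other_lobes))
    cat(sprintf("  %d additional super-threshold lobe(s)\n",
                nrow(x$other_lobes)))
  invisible(x)
}

#' Fraction of effective positions across a profile window
#'
#' Counts the sampled positions inside \code{window} whose dose lies
#' between \code{threshold_fraction} x d_max and d_max (the "effective"
#' band of a lateral dose profile) and returns their fraction.
#'
#' @param curve A \code{\link{dose_curve}} lateral profile.
#' @param window Length-2 numeric, the (min, max) position window in mm;
#'   must intersect the curve support and contain at least one sample.
#' @param threshold_fraction Lower edge of the effective band as a
#'   fraction of the maximum dose.
#' @return Fraction in [0, 1] of window samples within the effective band.
#' @export
profile_effective_fraction <- function(curve, window,
                                       threshold_fraction = 0.85) {
  stopifnot(inherits(curve, "dose_curve"))
  if (length(window) != 2L || !all(is.finite(window)) ||
      window[1L] >= window[2L])
    stop_domain("'window' must be an ascending (min, max) pair")
  x <- curve$coordinate
  if (window[2L] < x[1L] || window[1L] > x[length(x)])
    stop_domain("'window' lies outside the curve support")
  inside <- x >= window[1L] & x <= window[2L]
  if (!any(inside)) stop_domain("'window' contains no curve samples")
  dmax <- max(curve$dose)
  eff <- curve$dose[inside] >= threshold_fraction * dmax
  mean(eff)
}
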