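#' Irradiation protocol
#'
#' A continuous irradiation block delivering dose D at dose rate Dr over
#' duration D/Dr, followed by a chemistry-only follow-up window during
#' which radical populations decay.
#'
#' @param dose Total absorbed dose D in Gy (>= 0).
#' @param dose_rate Mean dose rate Dr in Gy/s (> 0).
#' @param followup Post-irradiation follow-up in s.
#' @return An object of class \code{"irradiation_protocol"} with the
#'   derived \code{duration = dose / dose_rate}.
#' @export
irradiation_protocol <- function(dose, dose_rate, followup = 100) {
  check_scalar(dose, "dose", nonneg = TRUE)
  check_scalar(dose_rate, "dose_rate", positive = TRUE)
  check_scalar(followup, "followup", nonneg = TRUE)
  structure(list(dose = dose, dose_rate = dose_rate,
                 duration = dose / dose_rate, followup = followup),
            class = "irradiation_protocol")
}

#' @export
print.irradiation_protocol <- function(x, ...) {
  cat(sprintf("Irradiation: %g Gy at %g Gy/s (%.3g s on-beam, %g s follow-up)\n",
              x$dose, x$dose_rate, x$duration, x$followup))
  invisible(x)
}

#' Integrate a reaction network over an irradiation protocol
#'
#' Solves the mass-action ODE system with the stiff-capable \code{lsoda}
#' integrator from \pkg{deSolve}, in two legs (beam on, beam off) so the
#' production-term discontinuity at t = D/Dr falls on a mesh point.
#' Output is dense: linear in time during irradiation and logarithmic in
#' time since beam-off during follow-up. The peroxyl-radical exposure
#' \code{roo_auc} is the trapezoidal time-integral of the ROO
#' concentration over the requested window.
#'
#' @param network A \code{\link{reaction_network}}.
#' @param protocol An \code{\link{irradiation_protocol}}.
#' @param roo_species Name of the peroxyl-radical species whose
#'   time-integral is reported (default \code{"ROO"}); set NULL to skip.
#' @param auc_window \code{"total"} integrates ROO over irradiation plus
#'   follow-up; \code{"irradiation"} restricts to the beam-on window.
#' @param rtol,atol Relative / absolute solver tolerances (mol/L).
#' @param n_irradiation,n_followup Number of dense output points per leg.
#' @return An object of class \code{"kinetics_result"}: \code{time} (s),
#'   \code{concentrations} (time x species matrix, mol/L),
#'   \code{roo_auc} (mol s / L) and the protocol.
#' @export
integrate_kinetics <- function(network, protocol,
                               roo_species = "ROO",
                               auc_window = c("total", "irradiation"),
                               rtol = 1e-8, atol = 1e-15,
                               n_irradiation = 200L, n_followup = 500L) {
  stopifnot(inherits(network, "reaction_network"),
            inherits(protocol, "irradiation_protocol"))
  auc_window <- match.arg(auc_window)
  nm <- network$species_names
  y0 <- vapply(network$species, `[[`, numeric(1), "initial")
  names(y0) <- nm
  rhs <- assemble_rhs(network, protocol)
  desolve_fun <- function(t, y, parms) list(rhs(t, y))

  t_irr <- protocol$duration
  solve_leg <- function(y_start, times) {
    out <- deSolve::lsoda(y = y_start, times = times, func = desolve_fun,
                          parms = NULL, rtol = rtol, atol = atol,
                          maxsteps = 50000L)
    if (attr(out, "istate")[1L] < 0)
      stop_domain(sprintf(
        "kinetics integration failed (dose %g Gy, dose rate %g Gy/s)",
        protocol$dose, protocol$dose_rate))
    out
  }

  times <- NULL
  conc <- NULL
  if (t_irr > 0) {
    t1 <- seq(0, t_irr, length.out = n_irradiation + 1L)
    out1 <- solve_leg(y0, t1)
    times <- out1[, 1L]
    conc <- out1[, -1L, drop = FALSE]
    y_mid <- conc[nrow(conc), ]
  } else {
    times <- 0
    conc <- matrix(y0, nrow = 1L, dimnames = list(NULL, nm))
    y_mid <- y0
  }
  if (protocol$followup > 0) {
    # log-spaced offsets after beam-off, resolving fast radical decay
    dt0 <- max(protocol$followup * 1e-9, 1e-12)
    offs <- 10^seq(log10(dt0), log10(protocol$followup),
                   length.out = n_followup)
    t2 <- t_irr + c(0, offs)
    out2 <- solve_leg(y_mid, t2)
    times <- c(times, out2[-1L, 1L])
    conc <- rbind(conc, out2[-1L, -1L, drop = FALSE])
  }
  colnames(conc) <- nm

  neg_floor <- -max(1e6 * atol, 1e-9)  # gross integrator failure only
  if (min(conc) < neg_floor)
    stop_domain(sprintf(
      "negative concentration %.3g beyond tolerance for species '%s'",
      min(conc), nm[which(conc == min(conc), arr.ind = TRUE)[1L, 2L]]))
  conc[conc < 0] <- 0

  roo_auc <- NA_real_
  if (!is.null(roo_species)) {
    if (!roo_species %in% nm)
      stop_domain("species '", roo_species, "' not in the network")
    keep <- if (auc_window == "irradiation") times <= t_irr else
      rep(TRUE, length(times))
    roo_auc <- trapz(times[keep], conc[keep, roo_species])
  }

  structure(list(time = times, concentrations = conc,
                 roo_auc = roo_auc, roo_species = roo_species,
                 auc_window = auc_window, protocol = protocol),
            class = "kinetics_result")
}

#' @export
print.kinetics_result <- function(x, ...) {
  cat(sprintf("Kinetics result: %d time points over %.3g s\n",
              length(x$time), max(x$time)))
  print(x$protocol)
  if (!is.na(x$roo_auc))
    cat(sprintf("  %s exposure (AUC, %s window): %.4g mol s/L\n",
                x$roo_species, x$auc_window, x$roo_auc))
  invisible(x)
}

#' Export a kinetics result as long-format CSV
#'
#' Columns: \code{time_s}, \code{species}, \code{concentration_M}.
#'
#' @param result A \code{\link{integrate_kinetics}} result.
#' @param path Output file path.
#' @export
write_kinetics_csv <- function(result, path) {
  stopifnot(inherits(result, "kinetics_result"))
  long <- data.frame(
    time_s = rep(result$time, times = ncol(result$concentrations)),
    species = rep(colnames(result$concentrations),
                  each = length(result$time)),
    concentration_M = as.vector(result$concentrations))
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Peroxyl-radical exposure surface N(D, Dr)
#'
#' Integrates the network over every (dose, dose rate) grid point,
#' collects the raw peroxyl-radical exposure (time-integral of [ROO]) and
#' normalizes each dose row by its value at the lowest dose rate of the
#' grid - the conventional-dose-rate anchor - so that N(D, Dr) lies in
#' (0, 1] and equals 1 at the first column by construction.
#'
#' @param network A \code{\link{reaction_network}}.
#' @param dose_grid Positive doses in Gy.
#' @param dose_rate_grid Positive dose rates in Gy/s, spanning the
#'   conventional-to-FLASH transition; sorted ascending internally.
#' @param followup Follow-up window per run (s).
#' @param ... Further arguments passed to \code{\link{integrate_kinetics}}.
#' @return An object of class \code{"exposure_surface"}: \code{dose_grid},
#'   \code{dose_rate_grid}, \code{normalized} (doses x rates matrix N) and
#'   \code{raw} (mol s / L).
#' @export
exposure_surface <- function(network, dose_grid, dose_rate_grid,
                             followup = 100, ...) {
  if (any(dose_grid <= 0) || any(dose_rate_grid <= 0))
    stop_domain("dose and dose-rate grids must be strictly positive")
  dose_rate_grid <- sort(dose_rate_grid)
  dose_grid <- sort(dose_grid)
  raw <- matrix(NA_real_, length(dose_grid), length(dose_rate_grid),
                dimnames = list(signif(dose_grid, 6),
                                signif(dose_rate_grid, 6)))
  for (i in seq_along(dose_grid)) {
    for (j in seq_along(dose_rate_grid)) {
      res <- tryCatch(
        integrate_kinetics(network,
                           irradiation_protocol(dose_grid[i],
                                                dose_rate_grid[j],
                                                followup = followup),
                           ...),
        error = function(e) stop_domain(sprintf(
          "exposure surface failed at D = %g Gy, Dr = %g Gy/s: %s",
          dose_grid[i], dose_rate_grid[j], conditionMessage(e))))
      raw[i, j] <- res$roo_auc
    }
  }
  anchor <- raw[, 1L]
  if (any(anchor <= 0))
    stop_domain("zero exposure at the normalization anchor; ",
                "does the network produce the peroxyl radical?")
  structure(list(dose_grid = dose_grid, dose_rate_grid = dose_rate_grid,
                 normalized = raw / anchor, raw = raw),
            class = "exposure_surface")
}

#' @export
print.exposure_surface <- function(x, ...) {
  cat(sprintf(
    "Exposure surface: %d doses (%g..%g Gy) x %d dose rates (%g..%g Gy/s)\n",
    length(x$dose_grid), min(x$dose_grid), max(x$dose_grid),
    length(x$dose_rate_grid), min(x$dose_rate_grid), max(x$dose_rate_grid)))
  cat(sprintf("  N range: %.4g .. %.4g\n", min(x$normalized),
              max(x$normalized)))
  invisible(x)
}

#' Export an exposure surface as a CSV matrix
#'
#' Rows are doses (first column \code{dose_Gy}); the header row carries
#' the dose rates in Gy/s.
#'
#' @param surface An \code{\link{exposure_surface}}.
#' @param path Output file path.
#' @param what Write the normalized (default) or raw exposure matrix.
#' @export
write_surface_csv <- function(surface, path,
                              what = c("normalized", "raw")) {
  stopifnot(inherits(surface, "exposure_surface"))
  what <- match.arg(what)
  m <- surface[[what]]
  df <- data.frame(dose_Gy = surface$dose_grid, m, check.names = FALSE)
  colnames(df) <- c("dose_Gy", format(surface$dose_rate_grid,
                                      scientific = TRUE, trim = TRUE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
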