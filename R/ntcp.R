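#' Sigmoid NTCP parameters
#'
#' Parameters of the logistic link between normalized peroxyl-radical
#' exposure N and the normal-tissue complication probability,
#' NTCP(N) = 1 / (1 + exp(-gamma (N - m))). The packaged defaults
#' gamma = 1320 and m = 0.2002 are literature estimates obtained from 13
#' published dose/dose-rate toxicity groups; with an exposure normalized
#' to (0, 1] they make the response nearly a step at N = m.
#'
#' @param gamma Sigmoid steepness (> 0), unitless.
#' @param m Sigmoid midpoint exposure, in (0, 1).
#' @return An object of class \code{"ntcp_params"}.
#' @export
ntcp_params <- function(gamma = 1320, m = 0.2002) {
  check_scalar(gamma, "gamma", positive = TRUE)
  check_scalar(m, "m")
  if (m <= 0 || m >= 1)
    stop_domain("'m' must lie strictly between 0 and 1")
  structure(list(gamma = gamma, m = m), class = "ntcp_params")
}

#' @export
print.ntcp_params <- function(x, ...) {
  cat(sprintf("NTCP sigmoid: gamma = %g, midpoint m = %g\n", x$gamma, x$m))
  invisible(x)
}

#' Complication probability from normalized exposure
#'
#' Evaluates the logistic NTCP(N) = plogis(gamma (N - m)); the
#' \code{plogis} form is underflow-safe for the very steep packaged
#' steepness.
#'
#' @param params An \code{\link{ntcp_params}}.
#' @param exposure Normalized exposure value(s) N in [0, 1].
#' @return Probabilities in [0, 1], non-decreasing in N.
#' @export
ntcp_from_exposure <- function(params, exposure) {
  stopifnot(inherits(params, "ntcp_params"))
  if (any(!is.finite(exposure)) || any(exposure < 0) || any(exposure > 1))
    stop_domain("'exposure' must lie in [0, 1]")
  stats::plogis(params$gamma * (exposure - params$m))
}

#' Predict NTCP at a dose and dose rate
#'
#' Composes the exposure surrogate with the sigmoid response:
#' NTCP(D, Dr) = ntcp_from_exposure(params, N(D, Dr)). Because N is
#' non-increasing in dose rate across the FLASH transition and the
#' sigmoid is increasing in N, the prediction is non-increasing in dose
#' rate at fixed dose.
#'
#' @param params An \code{\link{ntcp_params}}.
#' @param surrogate An \code{"exposure_surrogate"}.
#' @param dose Dose(s) in Gy.
#' @param dose_rate Dose rate(s) in Gy/s.
#' @return Probabilities in [0, 1].
#' @export
predict_ntcp <- function(params, surrogate, dose, dose_rate) {
  ntcp_from_exposure(params,
                     normalized_exposure(surrogate, dose, dose_rate))
}

#' Tolerated dose as a function of dose rate
#'
#' For each dose rate, solves NTCP(D, Dr) = \code{ntcp_level} for the
#' dose D by bisection within \code{dose_range}. Across the FLASH
#' transition of the canonical model the tolerated dose is non-decreasing
#' in dose rate: faster delivery spares normal tissue, so a higher dose
#' reaches the same complication probability. Dose rates at which the
#' level is not bracketed within \code{dose_range} yield \code{NA} and
#' are flagged.
#'
#' @param params An \code{\link{ntcp_params}}.
#' @param surrogate An \code{"exposure_surrogate"}.
#' @param ntcp_level Target complication probability in (0, 1).
#' @param dose_rate_grid Dose rates in Gy/s.
#' @param dose_range Length-2 search interval for the dose in Gy.
#' @param tol Absolute NTCP residual tolerance of the root.
#' @return A data frame with columns \code{dose_rate}, \code{dose} (Gy,
#'   NA where unreachable) and logical \code{reachable}.
#' @export
tolerated_dose_surface <- function(params, surrogate, ntcp_level = 0.5,
                                   dose_rate_grid,
                                   dose_range = c(0.5, 50),
                                   tol = 1e-6) {
  stopifnot(inherits(params, "ntcp_params"),
            inherits(surrogate, "exposure_surrogate"))
  check_scalar(ntcp_level, "ntcp_level")
  if (ntcp_level <= 0 || ntcp_level >= 1)
    stop_domain("'ntcp_level' must lie strictly between 0 and 1")
  if (any(dose_rate_grid <= 0))
    stop_domain("'dose_rate_grid' must be strictly positive")
  # solve on the link scale: gamma (N - m) is finite where NTCP saturates
  target_link <- stats::qlogis(ntcp_level)
  doses <- vapply(dose_rate_grid, function(dr) {
    f <- function(d)
      params$gamma * (normalized_exposure(surrogate, d, dr) - params$m) -
        target_link
    lo <- f(dose_range[1L]); hi <- f(dose_range[2L])
    if (!is.finite(lo) || !is.finite(hi) || lo * hi > 0) return(NA_real_)
    stats::uniroot(f, interval = dose_range, tol = 1e-10)$root
  }, numeric(1))
  data.frame(dose_rate = dose_rate_grid, dose = doses,
             reachable = !is.na(doses))
}
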