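#' Synthetic toxicity study design
#'
#' Describes a seeded synthetic dose/dose-rate toxicity study standing in
#' for the grouped literature observations the NTCP model is fitted to:
#' 13 groups at the 10 Gy dose scale with dose rates log-spaced from
#' conventional (0.01 Gy/s) to ultra-high (1e7 Gy/s), 50 subjects per
#' group, outcomes drawn from the model itself at the packaged parameter
#' defaults through a known exposure surrogate.
#'
#' @param seed Integer seed; a fixed seed makes all generated outputs
#'   byte-identical.
#' @param n_groups Number of observation groups.
#' @param dose Dose(s) in Gy; a single value is recycled, a length-2
#'   vector is treated as a range spanned geometrically.
#' @param dose_rate_range Length-2 range in Gy/s, spanned by a log-spaced
#'   grid.
#' @param subjects_per_group Subjects per group (recycled).
#' @param true_params The generating \code{\link{ntcp_params}}.
#' @param surrogate The generating \code{"exposure_surrogate"}; the
#'   default spans the sigmoid midpoint at the 10 Gy scale.
#' @param outcome \code{"binomial"} draws grouped counts;
#'   \code{"gaussian"} emulates NTCP values digitized from figures by
#'   adding truncated Gaussian noise to the model probability.
#' @param gaussian_sd Noise standard deviation for the Gaussian mode.
#' @return An object of class \code{"synthetic_design"}.
#' @export
synthetic_design <- function(seed = 1L, n_groups = 13L, dose = 10,
                             dose_rate_range = c(1e-2, 1e7),
                             subjects_per_group = 50L,
                             true_params = ntcp_params(),
                             surrogate = default_synthetic_surrogate(),
                             outcome = c("binomial", "gaussian"),
                             gaussian_sd = 0.05) {
  outcome <- match.arg(outcome)
  stopifnot(inherits(true_params, "ntcp_params"),
            inherits(surrogate, "exposure_surrogate"))
  check_scalar(seed, "seed")
  if (n_groups < 2L) stop_domain("'n_groups' must be at least 2")
  if (any(dose <= 0) || any(dose_rate_range <= 0))
    stop_domain("doses and dose rates must be positive")
  structure(list(seed = as.integer(seed), n_groups = as.integer(n_groups),
                 dose = dose, dose_rate_range = dose_rate_range,
                 subjects_per_group = subjects_per_group,
                 true_params = true_params, surrogate = surrogate,
                 outcome = outcome, gaussian_sd = gaussian_sd),
            class = "synthetic_design")
}

#' Default generating surrogate of the synthetic design
#'
#' A fixed exposure surrogate whose 10 Gy high-dose-rate plateau
#' (1 - a(10) = 0.15) lies below the packaged sigmoid midpoint
#' m = 0.2002, so synthetic studies at the 10 Gy scale cross the NTCP
#' transition as the dose rate sweeps the FLASH window.
#'
#' @return An \code{"exposure_surrogate"}.
#' @export
default_synthetic_surrogate <- function() {
  surrogate_coefficients(a_coefficients = c(0.70, 0.017, -2e-4),
                         b_coefficients = c(2.2, -0.03),
                         w = 0.45)
}

#' Generate a synthetic toxicity dataset
#'
#' Computes each group's exposure through the design's surrogate and its
#' complication probability through the true sigmoid parameters, then
#' draws outcomes (binomial counts, or truncated-Gaussian fractions in
#' the digitized-NTCP mode). Deterministic given the design seed.
#'
#' @param design A \code{\link{synthetic_design}}.
#' @return A data frame with columns \code{dose_Gy},
#'   \code{dose_rate_Gy_s}, \code{responders}, \code{total},
#'   \code{true_ntcp}, \code{source_label}.
#' @export
generate_toxicity_dataset <- function(design) {
  stopifnot(inherits(design, "synthetic_design"))
  k <- design$n_groups
  dose <- if (length(design$dose) == 2L)
    exp(seq(log(design$dose[1L]), log(design$dose[2L]), length.out = k))
  else rep_len(design$dose, k)
  dr <- log_spaced(design$dose_rate_range[1L], design$dose_rate_range[2L],
                   k)
  n <- rep_len(design$subjects_per_group, k)
  expo <- normalized_exposure(design$surrogate, dose, dr)
  p <- ntcp_from_exposure(design$true_params, expo)
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(design$seed)
  if (design$outcome == "binomial") {
    responders <- stats::rbinom(k, n, p)
  } else {
    frac <- pmin(pmax(stats::rnorm(k, p, design$gaussian_sd), 0), 1)
    responders <- frac * n
  }
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)
  data.frame(dose_Gy = dose, dose_rate_Gy_s = dr,
             responders = responders, total = n, true_ntcp = p,
             source_label = sprintf("synthetic-%d", seq_len(k)))
}

#' Toy reaction networks with closed-form solutions
#'
#' Small networks used as independent oracles for the kinetics
#' integrator. Each returned network carries its analytic solution as
#' the \code{"analytic"} attribute (a function of time and the
#' irradiation protocol).
#'
#' \describe{
#'   \item{production-decay}{One species produced radiolytically at rate
#'     g Dr during irradiation and decaying first order:
#'     [S](t) = (p/k)(1 - exp(-k t)) while the beam is on.}
#'   \item{linear-chain}{A -> B -> C with no production; total mass
#'     conserved, A decays exponentially.}
#'   \item{oxygen-capture}{R + O2 -> ROO with O2 in large excess:
#'     pseudo-first-order capture of an initial R population.}
#' }
#'
#' @param kind One of \code{"production-decay"}, \code{"linear-chain"},
#'   \code{"oxygen-capture"}.
#' @param g_value Radiolytic yield of the produced species (umol/J), for
#'   \code{"production-decay"}.
#' @param k Decay / chain rate constant (1/s).
#' @param r0 Initial radical concentration (mol/L), for kinds with an
#'   initial population.
#' @param o2 Initial oxygen concentration (mol/L), for
#'   \code{"oxygen-capture"}; chosen large relative to \code{r0}.
#' @return A \code{\link{reaction_network}} with attribute
#'   \code{"analytic"}.
#' @export
generate_toy_network <- function(kind = c("production-decay",
                                          "linear-chain",
                                          "oxygen-capture"),
                                 g_value = 0.28, k = 0.5,
                                 r0 = 1e-6, o2 = 1e-3) {
  kind <- match.arg(kind)
  if (kind == "production-decay") {
    net <- reaction_network(list(species("S", g_value = g_value)),
                            list(reaction("S ->", k)))
    analytic <- function(t, protocol) {
      p <- g_value * 1e-6 * protocol$dose_rate
      t_irr <- protocol$duration
      on <- pmin(t, t_irr)
      s_on <- p / k * (1 - exp(-k * on))
      s <- s_on * exp(-k * pmax(t - t_irr, 0))
      cbind(S = s)
    }
  } else if (kind == "linear-chain") {
    k2 <- k / 3  # distinct rates keep the chain non-degenerate
    net <- reaction_network(
      list(species("A", initial = r0), species("B"), species("C")),
      list(reaction("A -> B", k), reaction("B -> C", k2)))
    analytic <- function(t, protocol) {
      a <- r0 * exp(-k * t)
      b <- r0 * k / (k2 - k) * (exp(-k * t) - exp(-k2 * t))
      cbind(A = a, B = b, C = r0 - a - b)
    }
  } else {
    net <- reaction_network(
      list(species("R", initial = r0), species("O2", initial = o2),
           species("ROO")),
      list(reaction("R + O2 -> ROO", k2 <- 4.9e9)))
    analytic <- function(t, protocol) {
      # pseudo-first-order limit o2 >> r0
      keff <- 4.9e9 * o2
      r <- r0 * exp(-keff * t)
      cbind(R = r, O2 = o2 - (r0 - r), ROO = r0 - r)
    }
  }
  attr(net, "analytic") <- analytic
  net
}

#' Generate a synthetic depth-dose or profile curve
#'
#' Deterministic analytic curves emulating the qualitative shapes of
#' measured percentage-depth-dose curves and lateral profiles, for use
#' as dosimetry fixtures.
#'
#' \describe{
#'   \item{triangle}{Linear rise to a peak and fall back to zero.}
#'   \item{flat}{Constant dose across the support.}
#'   \item{buildup-exponential}{(1 - exp(-z / buildup)) exp(-mu z): a
#'     short build-up followed by exponential attenuation, the canonical
#'     kilovoltage-photon depth-dose shape.}
#' }
#'
#' @param kind Curve shape, see above.
#' @param span Length-2 coordinate support in mm.
#' @param n_points Number of samples (>= 3).
#' @param peak Peak position in mm (triangle).
#' @param buildup Build-up depth constant in mm.
#' @param mu Attenuation coefficient in 1/mm.
#' @param noise_sd Optional relative Gaussian noise level.
#' @param seed Seed used when \code{noise_sd > 0}.
#' @return A \code{\link{dose_curve}}.
#' @export
generate_depth_dose <- function(kind = c("buildup-exponential",
                                         "flat", "triangle"),
                                span = c(0, 50), n_points = 201L,
                                peak = 10, buildup = 2, mu = 0.05,
                                noise_sd = 0, seed = 1L) {
  kind <- match.arg(kind)
  if (n_points < 3L) stop_domain("'n_points' must be at least 3")
  z <- seq(span[1L], span[2L], length.out = n_points)
  d <- switch(kind,
              "triangle" = pmax(pmin((z - span[1L]) / (peak - span[1L]),
                                     (span[2L] - z) / (span[2L] - peak)),
                                0),
              "flat" = rep(1, n_points),
              "buildup-exponential" =
                (1 - exp(-pmax(z - span[1L], 0) / buildup)) *
                exp(-mu * pmax(z - span[1L], 0)))
  if (noise_sd > 0) {
    old_seed <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    set.seed(seed)
    d <- pmax(d * (1 + stats::rnorm(n_points, 0, noise_sd)), 0)
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)
  }
  dose_curve(z, d)
}
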