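#' Evaluate the exposure surrogate N(D, Dr)
#'
#' The smooth surrogate compressing the ODE exposure surface:
#' \deqn{N(D, Dr) = 1 - a(D) / (1 + exp(-(log10(Dr) - b(D)) / w))}
#' a logistic step in log10 dose rate whose amplitude a(D) and midpoint
#' b(D) are polynomials in dose and whose width w is shared. N tends to 1
#' in the conventional-dose-rate limit and to 1 - a(D) in the
#' ultra-high-dose-rate limit. Values are clamped to (0, 1].
#'
#' @param surrogate An \code{"exposure_surrogate"} (from
#'   \code{\link{fit_surrogate}} or \code{\link{surrogate_coefficients}}).
#' @param dose Dose(s) in Gy.
#' @param dose_rate Dose rate(s) in Gy/s; strictly positive.
#' @return Normalized exposure values in (0, 1], recycled over the longer
#'   of \code{dose} / \code{dose_rate}.
#' @export
normalized_exposure <- function(surrogate, dose, dose_rate) {
  stopifnot(inherits(surrogate, "exposure_surrogate"))
  if (any(!is.finite(dose_rate)) || any(dose_rate <= 0))
    stop_domain("'dose_rate' must be strictly positive")
  if (any(!is.finite(dose)) || any(dose < 0))
    stop_domain("'dose' must be nonnegative")
  a <- .polyval(surrogate$a_coefficients, dose)
  b <- .polyval(surrogate$b_coefficients, dose)
  n <- 1 - a * stats::plogis((log10(dose_rate) - b) / surrogate$w)
  pmin(pmax(n, 1e-12), 1)
}

# evaluate sum coef[k] * x^(k-1) (ascending powers)
.polyval <- function(coef, x) {
  out <- numeric(length(x)) + 0 * x
  for (k in seq_along(coef)) out <- out + coef[k] * x^(k - 1)
  out
}

#' Bundle known surrogate coefficients
#'
#' @param a_coefficients Ascending-power polynomial coefficients of the
#'   amplitude a(D).
#' @param b_coefficients Ascending-power polynomial coefficients of the
#'   log10 dose-rate midpoint b(D).
#' @param w Shared logistic width in decades of dose rate (> 0).
#' @return An object of class \code{"exposure_surrogate"}.
#' @export
surrogate_coefficients <- function(a_coefficients, b_coefficients, w) {
  check_scalar(w, "w", positive = TRUE)
  stopifnot(is.numeric(a_coefficients), length(a_coefficients) >= 1,
            is.numeric(b_coefficients), length(b_coefficients) >= 1)
  structure(list(a_coefficients = as.numeric(a_coefficients),
                 b_coefficients = as.numeric(b_coefficients),
                 w = w, fit = NULL),
            class = "exposure_surrogate")
}

#' @export
print.exposure_surrogate <- function(x, ...) {
  cat("Exposure surrogate N(D, Dr) = 1 - a(D) * logistic((log10 Dr - b(D)) / w)\n")
  cat("  a(D) coefficients:", signif(x$a_coefficients, 6), "\n")
  cat("  b(D) coefficients:", signif(x$b_coefficients, 6), "\n")
  cat("  width w           :", signif(x$w, 6), "decades\n")
  if (!is.null(x$fit))
    cat(sprintf("  fitted to a %d x %d surface, max |residual| = %.3g\n",
                length(x$fit$dose_grid), length(x$fit$dose_rate_grid),
                x$fit$max_residual))
  invisible(x)
}

#' Fit the surrogate to an exposure surface
#'
#' Least-squares fit of the logistic-in-log10(Dr) surrogate with
#' polynomial amplitude a(D) and midpoint b(D) to a tabulated normalized
#' exposure surface, by Levenberg-Marquardt. Starting values come from
#' row-wise amplitude/midpoint heuristics.
#'
#' @param surface An \code{\link{exposure_surface}}.
#' @param poly_degree Degree of the a(D) and b(D) polynomials (>= 1).
#' @param w_init Starting value for the shared width (decades).
#' @return An \code{"exposure_surrogate"} whose \code{fit} element carries
#'   the residual matrix, the maximum absolute residual and the grids.
#' @export
fit_surrogate <- function(surface, poly_degree = 3L, w_init = 0.5) {
  stopifnot(inherits(surface, "exposure_surface"))
  if (poly_degree < 1) stop_domain("'poly_degree' must be at least 1")
  D <- surface$dose_grid
  L <- log10(surface$dose_rate_grid)
  N <- surface$normalized
  nd <- length(D)

  # row-wise heuristics: amplitude = 1 - plateau, midpoint = half-drop L
  a_row <- pmax(1 - apply(N, 1L, min), 0)
  b_row <- vapply(seq_len(nd), function(i) {
    target <- 1 - a_row[i] / 2
    if (a_row[i] < 1e-8) return(stats::median(L))
    idx <- which(N[i, ] <= target)
    if (!length(idx)) return(max(L))
    j <- idx[1L]
    if (j == 1L) return(L[1L])
    stats::approx(N[i, c(j - 1L, j)], L[c(j - 1L, j)], xout = target)$y
  }, numeric(1))
  fit_poly <- function(y) {
    deg <- min(poly_degree, nd - 1L)
    co <- stats::coef(stats::lm(y ~ stats::poly(D, deg, raw = TRUE)))
    co[is.na(co)] <- 0
    c(co, rep(0, poly_degree - deg))
  }
  p0 <- c(fit_poly(a_row), fit_poly(b_row), log(w_init))
  np <- poly_degree + 1L

  resid_fun <- function(p) {
    a <- .polyval(p[seq_len(np)], D)
    b <- .polyval(p[np + seq_len(np)], D)
    w <- exp(p[2L * np + 1L])
    z <- outer(-b, L, `+`) / w      # (L_j - b(D_i)) / w
    pred <- 1 - a * stats::plogis(z)  # a recycles down columns (rows = doses)
    as.vector(pred - N)
  }

  fit <- minpack.lm::nls.lm(
    par = p0, fn = resid_fun,
    control = minpack.lm::nls.lm.control(maxiter = 400L,
                                         ftol = 1e-15, ptol = 1e-15))
  if (fit$info %in% c(0L, 5L))
    stop_domain("surrogate fit did not converge: ", fit$message,
                " (deviance ", signif(fit$deviance, 6), ")")
  p <- unname(fit$par)
  sur <- surrogate_coefficients(p[seq_len(np)], p[np + seq_len(np)],
                                exp(p[2L * np + 1L]))
  resid <- matrix(resid_fun(p), nrow = nd)
  sur$fit <- list(dose_grid = D, dose_rate_grid = surface$dose_rate_grid,
                  residuals = resid,
                  max_residual = max(abs(resid)),
                  deviance = fit$deviance, info = fit$info)
  sur
}
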