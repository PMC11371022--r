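# Physical constants and small numeric helpers shared across modules.

# elementary charge [C]; numerically equal to joules per electronvolt
.QE <- 1.602176634e-19

# practical-unit coefficients for an isomagnetic ring:
#   U [keV]  = 88.5  * E^4 [GeV] / rho [m]   (energy radiated per turn)
#   E_c [keV] = 2.218 * E^3 [GeV] / rho [m]  (critical energy)
.U_COEF <- 88.5
.EC_COEF <- 2.218

# closed-form total-photon-rate factor: N_dot = (15 sqrt(3) / 8) * P / E_c
.PHOTON_RATE_FACTOR <- 15 * sqrt(3) / 8

#' @keywords internal
stop_domain <- function(...) stop(..., call. = FALSE)

check_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_domain(sprintf("'%s' must be a single finite number", name))
  if (positive && x <= 0)
    stop_domain(sprintf("'%s' must be strictly positive", name))
  if (nonneg && x < 0)
    stop_domain(sprintf("'%s' must be nonnegative", name))
  invisible(x)
}

# trapezoidal rule on an irregular grid
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum(diff(x) * (y[-1L] + y[-n]) / 2)
}

# log10-spaced grid helper
log_spaced <- function(from, to, length.out) {
  10^seq(log10(from), log10(to), length.out = length.out)
}
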