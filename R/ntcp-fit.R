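#' Fit the sigmoid NTCP model to grouped toxicity observations
#'
#' Maximum-likelihood estimation of the sigmoid steepness gamma and
#' midpoint exposure m from grouped (dose, dose rate, toxicity)
#' observations, through the composed model
#' NTCP = plogis(gamma (N(D, Dr) - m)) with N evaluated by the exposure
#' surrogate. Two observation modes are supported:
#' \itemize{
#'   \item \code{method = "likelihood"}: the response is a two-column
#'     matrix \code{cbind(responders, total - responders)} and the fit
#'     maximizes the binomial log-likelihood (grouped outcome counts);
#'   \item \code{method = "least-squares"}: the response is a numeric
#'     complication fraction in [0, 1] (e.g. NTCP values digitized from a
#'     published figure) and the fit minimizes squared residuals.
#' }
#' Optimization runs on the unconstrained scale (log gamma, logit m) by
#' Nelder-Mead with a BFGS polish. Uncertainty is quantified by a seeded
#' parametric bootstrap: datasets are re-simulated from the fitted model
#' and refitted.
#'
#' Observations whose exposures are nearly perfectly separated (every
#' group fraction 0 or 1 on either side of a threshold) identify m as the
#' bracketing interval but only bound gamma from below; the bootstrap
#' spread makes this visible and \code{summary} warns about it.
#'
#' @param formula Model formula \code{response ~ dose + dose_rate}. The
#'   right-hand side must name, in order, the dose (Gy) and dose-rate
#'   (Gy/s) columns of \code{data}; the response is a count matrix or a
#'   fraction depending on \code{method}.
#' @param data Data frame of observations.
#' @param surrogate An \code{"exposure_surrogate"} mapping (dose, dose
#'   rate) to normalized exposure.
#' @param method Fitting objective, see above.
#' @param start Starting \code{\link{ntcp_params}}.
#' @param n_boot Number of parametric-bootstrap replicates (0 disables).
#' @param boot_seed Integer seed of the bootstrap generator.
#' @return An object of class \code{"ntcp_fit"}.
#' @examples
#' sur <- surrogate_coefficients(c(0.6, 0.02), c(2, -0.02), 0.5)
#' obs <- generate_toxicity_dataset(synthetic_design(seed = 1))
#' fit <- ntcp_fit(cbind(responders, total - responders) ~
#'                   dose_Gy + dose_rate_Gy_s,
#'                 data = obs, surrogate = sur, n_boot = 50)
#' coef(fit)
#' @export
ntcp_fit <- function(formula, data, surrogate,
                     method = c("likelihood", "least-squares"),
                     start = ntcp_params(), n_boot = 1000L,
                     boot_seed = 1L) {
  method <- match.arg(method)
  stopifnot(inherits(surrogate, "exposure_surrogate"),
            inherits(start, "ntcp_params"))
  cl <- match.call()
  mf <- stats::model.frame(formula, data)
  rhs_terms <- attr(stats::terms(formula), "term.labels")
  if (length(rhs_terms) != 2L)
    stop_domain("the formula right-hand side must name the dose and ",
                "dose-rate columns: response ~ dose + dose_rate")
  dose <- data[[rhs_terms[1L]]]
  dose_rate <- data[[rhs_terms[2L]]]
  if (any(dose <= 0) || any(dose_rate <= 0))
    stop_domain("doses and dose rates must be strictly positive")
  y <- stats::model.response(mf)

  if (method == "likelihood") {
    if (is.null(dim(y)) || ncol(y) != 2L)
      stop_domain("likelihood fitting needs a two-column response: ",
                  "cbind(responders, total - responders)")
    responders <- y[, 1L]
    total <- y[, 1L] + y[, 2L]
    if (any(responders < 0) || any(y[, 2L] < 0))
      stop_domain("negative counts in the response")
    if (length(total) < 2L)
      stop_domain("at least 2 observation groups are required")
  } else {
    if (!is.null(dim(y)))
      stop_domain("least-squares fitting needs a numeric fraction response")
    if (any(y < 0) || any(y > 1))
      stop_domain("fractions must lie in [0, 1]")
    responders <- y
    total <- rep(1, length(y))
  }

  exposure <- normalized_exposure(surrogate, dose, dose_rate)
  if (diff(range(exposure)) < 1e-9)
    stop_domain("degenerate design: all observations map to the same ",
                "exposure; gamma and m are not identifiable")

  # theta = (log gamma, logit m)
  objective <- function(theta) {
    g <- exp(theta[1L]); mm <- stats::plogis(theta[2L])
    eta <- g * (exposure - mm)
    if (method == "likelihood") {
      # -log L, numerically stable via plogis on the log scale
      -sum(responders * stats::plogis(eta, log.p = TRUE) +
             (total - responders) * stats::plogis(-eta, log.p = TRUE))
    } else {
      sum((responders - stats::plogis(eta))^2)
    }
  }
  theta0 <- c(log(start$gamma), stats::qlogis(start$m))
  opt <- stats::optim(theta0, objective, method = "Nelder-Mead",
                      control = list(maxit = 2000L, reltol = 1e-12))
  opt <- stats::optim(opt$par, objective, method = "BFGS",
                      control = list(maxit = 500L, reltol = 1e-12))
  if (!is.finite(opt$value))
    stop_domain("NTCP fit did not converge: non-finite objective")
  est <- ntcp_params(exp(opt$par[1L]), stats::plogis(opt$par[2L]))

  fitted_p <- stats::plogis(est$gamma * (exposure - est$m))

  boot <- NULL
  if (n_boot > 0L) {
    boot <- matrix(NA_real_, n_boot, 2L,
                   dimnames = list(NULL, c("gamma", "m")))
    refit <- function(resp) {
      obj <- function(theta) {
        g <- exp(theta[1L]); mm <- stats::plogis(theta[2L])
        eta <- g * (exposure - mm)
        if (method == "likelihood")
          -sum(resp * stats::plogis(eta, log.p = TRUE) +
                 (total - resp) * stats::plogis(-eta, log.p = TRUE))
        else sum((resp - stats::plogis(eta))^2)
      }
      o <- stats::optim(opt$par, obj, method = "Nelder-Mead",
                        control = list(maxit = 1000L, reltol = 1e-10))
      c(exp(o$par[1L]), stats::plogis(o$par[2L]))
    }
    old_seed <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    set.seed(boot_seed)
    for (b in seq_len(n_boot)) {
      resp <- if (method == "likelihood")
        stats::rbinom(length(total), total, fitted_p)
      else pmin(pmax(stats::rnorm(length(total), fitted_p,
                                  stats::sd(responders - fitted_p)), 0), 1)
      boot[b, ] <- refit(resp)
    }
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)
  }

  structure(
    list(params = est, surrogate = surrogate, method = method,
         formula = formula, call = cl,
         data = data.frame(dose = dose, dose_rate = dose_rate,
                           exposure = exposure,
                           responders = responders, total = total,
                           fitted = fitted_p),
         objective_value = opt$value,
         logLik = if (method == "likelihood") -opt$value else NA_real_,
         convergence = opt$convergence,
         boot = boot, boot_seed = boot_seed, n_boot = n_boot),
    class = "ntcp_fit")
}

#' @export
print.ntcp_fit <- function(x, ...) {
  cat("Sigmoid NTCP model fit (", x$method, ")\n", sep = "")
  cat(sprintf("  groups: %d, exposure range: %.4g .. %.4g\n",
              nrow(x$data), min(x$data$exposure), max(x$data$exposure)))
  cat(sprintf("  gamma = %.6g, m = %.6g\n", x$params$gamma, x$params$m))
  if (x$method == "likelihood")
    cat(sprintf("  log-likelihood: %.4g\n", x$logLik))
  invisible(x)
}

#' @export
coef.ntcp_fit <- function(object, ...) {
  c(gamma = object$params$gamma, m = object$params$m)
}

#' @export
logLik.ntcp_fit <- function(object, ...) {
  val <- object$logLik
  attr(val, "df") <- 2L
  attr(val, "nobs") <- nrow(object$data)
  class(val) <- "logLik"
  val
}

#' @export
vcov.ntcp_fit <- function(object, ...) {
  if (is.null(object$boot))
    stop_domain("no bootstrap replicates stored; refit with n_boot > 0")
  stats::cov(object$boot)
}

#' @export
confint.ntcp_fit <- function(object, parm = c("gamma", "m"),
                             level = 0.95, ...) {
  if (is.null(object$boot))
    stop_domain("no bootstrap replicates stored; refit with n_boot > 0")
  parm <- match.arg(parm, several.ok = TRUE)
  a <- (1 - level) / 2
  t(vapply(parm, function(p)
    stats::quantile(object$boot[, p], c(a, 1 - a), names = FALSE),
    numeric(2L)))
}

#' @export
summary.ntcp_fit <- function(object, level = 0.95, ...) {
  ci <- if (!is.null(object$boot)) confint(object, level = level) else NULL
  separated <- all(object$data$responders %in%
                     c(0, object$data$total)) &&
    object$method == "likelihood"
  out <- list(fit = object, ci = ci, level = level,
              separated = separated)
  class(out) <- "summary.ntcp_fit"
  out
}

#' @export
print.summary.ntcp_fit <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$ci)) {
    cat(sprintf("  bootstrap %g%% CI (%d replicates, seed %d):\n",
                100 * x$level, x$fit$n_boot, x$fit$boot_seed))
    cat(sprintf("    gamma: %.6g .. %.6g\n", x$ci["gamma", 1L],
                x$ci["gamma", 2L]))
    cat(sprintf("    m    : %.6g .. %.6g\n", x$ci["m", 1L], x$ci["m", 2L]))
  }
  if (x$separated)
    cat("  note: all group outcomes are 0/n or n/n (separation);\n",
        "  m is bracketed by the data but gamma is only bounded below\n")
  invisible(x)
}

#' @export
predict.ntcp_fit <- function(object, newdata = NULL,
                             type = c("response", "exposure", "link"),
                             ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    exposure <- object$data$exposure
  } else if (!is.null(newdata$exposure)) {
    exposure <- newdata$exposure
  } else {
    rhs_terms <- attr(stats::terms(object$formula), "term.labels")
    exposure <- normalized_exposure(object$surrogate,
                                    newdata[[rhs_terms[1L]]],
                                    newdata[[rhs_terms[2L]]])
  }
  eta <- object$params$gamma * (exposure - object$params$m)
  switch(type,
         response = stats::plogis(eta),
         exposure = exposure,
         link = eta)
}

#' @export
simulate.ntcp_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  p <- object$data$fitted
  n <- object$data$total
  out <- as.data.frame(replicate(nsim, stats::rbinom(length(n), n, p)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
residuals.ntcp_fit <- function(object,
                               type = c("deviance", "pearson",
                                        "response"), ...) {
  type <- match.arg(type)
  obs <- object$data$responders / object$data$total
  p <- object$data$fitted
  n <- object$data$total
  switch(type,
         response = obs - p,
         pearson = (obs - p) * sqrt(n) / sqrt(pmax(p * (1 - p), 1e-12)),
         deviance = {
           r <- object$data$responders
           d <- 2 * (ifelse(r == 0, 0, r * log(r / (n * p))) +
                       ifelse(r == n, 0,
                              (n - r) * log((n - r) / (n * (1 - p)))))
           sign(obs - p) * sqrt(pmax(d, 0))
         })
}

#' @export
plot.ntcp_fit <- function(x, dose = NULL, n_grid = 200L, ...) {
  d <- x$data
  if (is.null(dose)) dose <- stats::median(d$dose)
  dr_grid <- log_spaced(min(d$dose_rate) / 2, max(d$dose_rate) * 2, n_grid)
  pred <- predict_ntcp(x$params, x$surrogate, dose, dr_grid)
  graphics::plot(dr_grid, pred, type = "l", log = "x", ylim = c(0, 1),
                 xlab = "dose rate [Gy/s]", ylab = "NTCP",
                 main = sprintf("Fitted NTCP vs dose rate at %g Gy", dose),
                 ...)
  graphics::points(d$dose_rate, d$responders / d$total, pch = 19)
  invisible(x)
}

#' Read / write toxicity observations as CSV
#'
#' Columns: \code{dose_Gy}, \code{dose_rate_Gy_s}, \code{responders},
#' \code{total}, \code{source_label}.
#'
#' @param path File path.
#' @return \code{read_toxicity_csv} returns a validated data frame.
#' @export
read_toxicity_csv <- function(path) {
  d <- utils::read.csv(path)
  need <- c("dose_Gy", "dose_rate_Gy_s", "responders", "total")
  missing <- setdiff(need, names(d))
  if (length(missing))
    stop_domain("observations file lacks columns: ",
                paste(missing, collapse = ", "))
  if (any(d$responders < 0) || any(d$responders > d$total))
    stop_domain("responders must lie in [0, total]")
  if (any(d$dose_Gy <= 0) || any(d$dose_rate_Gy_s <= 0))
    stop_domain("doses and dose rates must be positive")
  d
}

#' @rdname read_toxicity_csv
#' @param observations Data frame with the columns above.
#' @export
write_toxicity_csv <- function(observations, path) {
  utils::write.csv(observations, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
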