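#' Gompertz growth-curve value
#'
#' The modified (Zwietering) Gompertz model on the log scale:
#' `y(t) = A exp(-exp(mu e / A (lam - t) + 1))`, where `y` is
#' `ln(RFU_t / RFU_min)`, `A = ln(RFU_max / RFU_min)` is the asymptotic log
#' fold-increase, `mu` (d\eqn{^{-1}}) is the maximum specific growth rate —
#' the slope of `y` at the inflection — `lam` (days) is the lag phase, and
#' `e` is Euler's number.
#'
#' @param t_days Time in days (vectorized).
#' @param A Asymptote, `ln(RFU_max / RFU_min)` (> 0).
#' @param mu Maximum specific growth rate, d\eqn{^{-1}} (> 0).
#' @param lam Lag phase, days (>= 0).
#' @return `y(t)`, the log-scale growth value.
#' @examples
#' gompertz_value(0:10, A = 3, mu = 1.2, lam = 1.5)
#' @export
gompertz_value <- function(t_days, A, mu, lam) {
  A * exp(-exp(mu * exp(1) / A * (lam - t_days) + 1))
}

#' Fit the Gompertz growth model to a daily RFU series
#'
#' Nonlinear least squares of [gompertz_value()] against
#' `ln(rfu / min(rfu))`, so the asymptote `A` is estimated on the scale it
#' is defined on. Initialization is multi-start: `A` from the observed log
#' range (and a 20% inflation), `mu` from the steepest day-to-day log
#' difference, `lam` from the last day the signal was still below 10% of its
#' log range (and 0); the converged start with the smallest deviance wins.
#' The back-calculated culture maximum is `rfu_max_est = exp(A) * rfu_min`.
#'
#' @param days Time in days (at least 5 points spanning lag and growth).
#' @param rfu Daily RFU values, strictly positive.
#' @param rfu_min Baseline (pre-growth) RFU. Defaults to the observed
#'   minimum of `rfu`; supply the known inoculation fluorescence when
#'   available — the observed minimum slightly overestimates the baseline
#'   because even the first read sits a little way up the growth curve.
#' @return An object of class `gompertz_fit`: list with `A`, `mu`, `lam`,
#'   their standard errors, `rfu_min`, `rfu_max_est`, `rss`, `n`,
#'   `convergence` and the underlying `nls` object.
#' @examples
#' d <- 0:14
#' r <- 50 * exp(gompertz_value(d, A = 3, mu = 1.2, lam = 1.5))
#' fit_gompertz(d, r)
#' @export
fit_gompertz <- function(days, rfu, rfu_min = NULL) {
  stopifnot(length(days) == length(rfu))
  keep <- is.finite(days) & is.finite(rfu)
  days <- days[keep]; rfu <- rfu[keep]
  if (length(days) < 5L) abort("Need at least 5 points to fit a growth curve.")
  if (any(rfu <= 0)) abort("RFU values must be strictly positive.")
  if (is.null(rfu_min)) rfu_min <- min(rfu)
  if (rfu_min <= 0) abort("`rfu_min` must be strictly positive.")
  y <- log(rfu / rfu_min)
  if (max(y) < 0.05) {
    abort("No growth detected: RFU series is flat (log range < 0.05).")
  }
  A0 <- max(y)
  dy <- diff(y) / diff(days)
  mu0 <- max(dy)
  if (mu0 <= 0) mu0 <- A0 / diff(range(days))
  below <- days[y < 0.1 * A0]
  lam0 <- if (length(below) > 0L) max(below) else 0
  starts <- list(
    c(A = A0, mu = mu0, lam = lam0),
    c(A = 1.2 * A0, mu = mu0, lam = 0),
    c(A = A0, mu = mu0 / 2, lam = max(lam0, min(days)))
  )
  dat <- data.frame(t = days, y = y)
  fits <- list(); errs <- character(0)
  for (st in starts) {
    f <- tryCatch(
      minpack.lm::nlsLM(
        y ~ A * exp(-exp(mu * exp(1) / A * (lam - t) + 1)),
        data = dat, start = as.list(st),
        lower = c(A = 1e-8, mu = 1e-8, lam = 0),
        control = minpack.lm::nls.lm.control(
          maxiter = 500, ftol = 1e-15, ptol = 1e-15
        )
      ),
      error = function(e) e
    )
    if (inherits(f, "nls")) fits[[length(fits) + 1L]] <- f
    else errs <- c(errs, conditionMessage(f))
  }
  if (length(fits) == 0L) {
    abort(paste0("Gompertz fit failed to converge from all starts: ",
                 paste(unique(errs), collapse = "; ")))
  }
  dev <- vapply(fits, stats::deviance, numeric(1))
  best <- fits[[which.min(dev)]]
  cf <- summary(best)$coefficients
  A <- cf["A", 1]; mu <- cf["mu", 1]; lam <- cf["lam", 1]
  structure(
    list(
      A = A, mu = mu, lam = lam,
      A_se = cf["A", 2], mu_se = cf["mu", 2], lam_se = cf["lam", 2],
      rfu_min = rfu_min, rfu_max_est = exp(A) * rfu_min,
      rss = stats::deviance(best), n = length(days),
      convergence = best$convInfo$isConv, fit = best
    ),
    class = "gompertz_fit"
  )
}

#' Flag the onset of stationary phase
#'
#' A culture is considered stationary after a run of days with stable RFU:
#' the first day `d` such that the coefficient of variation of RFU over the
#' trailing `window` days (inclusive) is at or below `tol`.
#'
#' @param days Day numbers.
#' @param rfu Daily RFU values.
#' @param window Number of consecutive days that must be stable (default 3).
#' @param tol Maximum coefficient of variation counted as "stable"
#'   (default 0.05).
#' @return The first stationary day, or `NA` if the series never stabilizes
#'   (with a warning when the series is shorter than `window`).
#' @examples
#' detect_stationary(1:8, c(1, 2, 4, 8, 10, 10.1, 9.9, 10))
#' @export
detect_stationary <- function(days, rfu, window = 3, tol = 0.05) {
  stopifnot(length(days) == length(rfu))
  ord <- order(days)
  days <- days[ord]; rfu <- rfu[ord]
  n <- length(days)
  if (n < window) {
    warn("Series shorter than the stability window; cannot assess stationarity.")
    return(NA_real_)
  }
  for (d in seq.int(window, n)) {
    win <- rfu[(d - window + 1L):d]
    cv <- sd(win) / mean(win)
    if (is.finite(cv) && cv <= tol) return(days[d])
  }
  NA_real_
}
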