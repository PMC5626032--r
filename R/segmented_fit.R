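#' Ordinary least-squares line fit, optionally with a fixed intercept
#'
#' Fits `y = a + b t` by OLS. With `fixed_intercept = c` only the slope is
#' free and the closed form `b = sum(t (y - c)) / sum(t^2)` applies; this is
#' the variant where the depth signal is pinned to the culture depth at
#' t = 0, as an evenly resuspended well demands.
#'
#' @param times Elapsed minutes (at least 3 points, not all equal).
#' @param y Response (depth signal, mm).
#' @param fixed_intercept If non-`NULL`, the intercept is fixed at this
#'   value and only the slope is estimated.
#' @return An object of class `sink_line_fit` with elements `slope1`,
#'   `slope1_se`, `intercept`, `rss`, `n`, `df_residual`, `fixed_intercept`.
#' @examples
#' t <- 0:10
#' fit_line(t, 3.8 - 0.02 * t)
#' @export
fit_line <- function(times, y, fixed_intercept = NULL) {
  stopifnot(length(times) == length(y))
  if (length(times) < 3L) abort("Need at least 3 points to fit a line.")
  if (max(times) == min(times)) abort("Zero time variance; cannot fit a slope.")
  n <- length(y)
  if (is.null(fixed_intercept)) {
    mx <- mean(times)
    sxx <- sum((times - mx)^2)
    slope <- sum((times - mx) * (y - mean(y))) / sxx
    intercept <- mean(y) - slope * mx
    rss <- sum((y - intercept - slope * times)^2)
    df <- n - 2L
    sigma2 <- if (df > 0L) rss / df else 0
    out <- list(
      model = "single", intercept = intercept,
      intercept_se = sqrt(sigma2 * (1 / n + mx^2 / sxx)),
      slope1 = slope, slope1_se = sqrt(sigma2 / sxx),
      rss = rss, n = n, df_residual = df, fixed_intercept = FALSE
    )
  } else {
    z <- y - fixed_intercept
    stt <- sum(times^2)
    slope <- sum(times * z) / stt
    rss <- sum((z - slope * times)^2)
    df <- n - 1L
    sigma2 <- if (df > 0L) rss / df else 0
    out <- list(
      model = "single", intercept = fixed_intercept, intercept_se = NA_real_,
      slope1 = slope, slope1_se = sqrt(sigma2 / stt),
      rss = rss, n = n, df_residual = df, fixed_intercept = TRUE
    )
  }
  structure(out, class = c("sink_line_fit", "sink_fit"))
}

# Conditional least squares at a fixed breakpoint psi.
# Continuous parameterization: y = a + b1*t + d*(t - psi)_+ , slope2 = b1 + d.
seg_ls <- function(times, y, psi, fixed_intercept = NULL) {
  tp <- pmax(times - psi, 0)
  if (is.null(fixed_intercept)) {
    X <- cbind(1, times, tp)
  } else {
    X <- cbind(times, tp)
    y <- y - fixed_intercept
  }
  fit <- stats::lm.fit(X, y)
  list(coef = fit$coefficients, rss = sum(fit$residuals^2))
}

# Fast RSS(psi) evaluator via 3x3 (or 2x2) normal equations; the sums not
# involving the hinge term are precomputed once per trace.
make_rss_fun <- function(times, y, fixed_intercept = NULL) {
  if (!is.null(fixed_intercept)) y <- y - fixed_intercept
  n <- length(times)
  s_t <- sum(times); s_tt <- sum(times^2)
  s_y <- sum(y); s_ty <- sum(times * y); s_yy <- sum(y^2)
  free <- is.null(fixed_intercept)
  function(psi) {
    tp <- pmax(times - psi, 0)
    s_p <- sum(tp); s_tp <- sum(times * tp); s_pp <- sum(tp^2)
    s_py <- sum(tp * y)
    if (free) {
      A <- matrix(c(n, s_t, s_p,
                    s_t, s_tt, s_tp,
                    s_p, s_tp, s_pp), 3, 3)
      b <- c(s_y, s_ty, s_py)
    } else {
      A <- matrix(c(s_tt, s_tp,
                    s_tp, s_pp), 2, 2)
      b <- c(s_ty, s_py)
    }
    cf <- tryCatch(solve(A, b), error = function(e) NULL)
    if (is.null(cf)) return(Inf)
    max(s_yy - sum(cf * b), 0)
  }
}

golden_section <- function(f, lower, upper, tol = 1e-10, max_iter = 200L) {
  gr <- (sqrt(5) - 1) / 2
  a <- lower; b <- upper
  x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
  f1 <- f(x1); f2 <- f(x2)
  for (i in seq_len(max_iter)) {
    if (b - a < tol) break
    if (f1 <= f2) {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - gr * (b - a); f1 <- f(x1)
    } else {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + gr * (b - a); f2 <- f(x2)
    }
  }
  if (f1 <= f2) list(minimum = x1, objective = f1)
  else list(minimum = x2, objective = f2)
}

#' Continuous one-breakpoint segmented regression
#'
#' Fits the continuous piecewise-linear model
#' `y = a + b1 t` for `t <= psi`, `y = a + b1 psi + b2 (t - psi)` for
#' `t > psi`, by profiling the breakpoint: every midpoint between
#' consecutive observed times that leaves at least `min_seg` points per
#' segment is a candidate; the conditionally linear least-squares problem is
#' solved at each, the candidate with minimal RSS wins (earliest breakpoint
#' among ties), and the breakpoint is then refined by golden-section search
#' within the winning inter-observation interval. The procedure is
#' deterministic and matches an exhaustive dense-grid scan.
#'
#' @inheritParams fit_line
#' @param min_seg Minimum points per segment (default 3, the smallest size
#'   leaving a residual degree of freedom per segment).
#' @param psi Optional manual breakpoint (minutes): skips the search and
#'   fits at this value (it must leave `min_seg` points per side).
#' @param refine Refine the winning candidate by golden-section search
#'   (default `TRUE`).
#' @return An object of class `sink_seg_fit` with elements `slope1`,
#'   `slope2` (and their standard errors), `intercept`, `breakpoint`, `rss`,
#'   `n`, `df_residual`, `fixed_intercept`, `psi_manual`.
#' @examples
#' t <- seq(0, 60, by = 2)
#' y <- ifelse(t <= 20, 3.8 - 0.1 * t, 3.8 - 0.1 * 20 - 0.01 * (t - 20))
#' fit_segmented(t, y)
#' @export
fit_segmented <- function(times, y, min_seg = 3, fixed_intercept = NULL,
                          psi = NULL, refine = TRUE) {
  stopifnot(length(times) == length(y))
  ord <- order(times)
  times <- times[ord]; y <- y[ord]
  n <- length(times)
  if (n < 2L * min_seg) {
    abort(paste0("Need at least ", 2L * min_seg,
                 " points for a segmented fit (min_seg = ", min_seg, ")."))
  }
  obj <- make_rss_fun(times, y, fixed_intercept)

  if (is.null(psi)) {
    idx <- seq.int(min_seg, n - min_seg)
    cand <- (times[idx] + times[idx + 1L]) / 2
    ok <- vapply(cand, function(p) {
      sum(times <= p) >= min_seg && sum(times > p) >= min_seg
    }, logical(1))
    idx <- idx[ok]; cand <- cand[ok]
    if (length(cand) == 0L) abort("No feasible breakpoint candidates.")
    rss <- vapply(cand, obj, numeric(1))
    best <- which(rss <= min(rss) + 1e-12)[1]  # earliest psi among ties
    psi_hat <- cand[best]
    rss_hat <- rss[best]
    if (refine) {
      # RSS(psi) can dip anywhere between observations, not only in the
      # interval whose midpoint scored best, so refine every feasible
      # interval and keep the global minimum.
      for (k in seq_along(idx)) {
        i <- idx[k]
        width <- times[i + 1L] - times[i]
        eps <- width * 1e-6
        gs <- golden_section(obj, times[i] + eps, times[i + 1L] - eps,
                             tol = width * 1e-8)
        better <- gs$objective < rss_hat - 1e-12
        tied_earlier <- abs(gs$objective - rss_hat) <= 1e-12 &&
          gs$minimum < psi_hat
        if (better || tied_earlier) {
          psi_hat <- gs$minimum
          rss_hat <- gs$objective
        }
      }
    }
    psi_manual <- FALSE
  } else {
    if (sum(times <= psi) < min_seg || sum(times > psi) < min_seg) {
      abort("Manual breakpoint leaves fewer than `min_seg` points per side.")
    }
    psi_hat <- psi
    psi_manual <- TRUE
  }

  # Final conditional LS at the chosen breakpoint; covariance from the
  # normal equations (avoids summary.lm's perfect-fit warnings on
  # noiseless traces).
  tp <- pmax(times - psi_hat, 0)
  if (is.null(fixed_intercept)) {
    X <- cbind(1, times, tp)
    z <- y
    p <- 4L  # a, b1, b2, psi
    i1 <- 2L; i2 <- 3L
  } else {
    X <- cbind(times, tp)
    z <- y - fixed_intercept
    p <- 3L  # b1, b2, psi
    i1 <- 1L; i2 <- 2L
  }
  fit <- stats::lm.fit(X, z)
  cf <- fit$coefficients
  rss <- sum(fit$residuals^2)
  df <- n - (p - 1L)
  sigma2 <- if (df > 0L) rss / df else 0
  XtXinv <- tryCatch(solve(crossprod(X)), error = function(e) NULL)
  if (is.null(XtXinv)) {
    se1 <- NA_real_; se2 <- NA_real_
  } else {
    se1 <- sqrt(sigma2 * XtXinv[i1, i1])
    se2 <- sqrt(sigma2 * (XtXinv[i1, i1] + XtXinv[i2, i2] +
                            2 * XtXinv[i1, i2]))
  }
  a <- if (is.null(fixed_intercept)) unname(cf[1]) else fixed_intercept
  b1 <- unname(cf[i1]); d <- unname(cf[i2])
  structure(
    list(
      model = "segmented", intercept = a, slope1 = b1, slope2 = b1 + d,
      slope1_se = se1, slope2_se = se2, breakpoint = psi_hat,
      rss = rss, n = n, df_residual = df,
      n_params = p, fixed_intercept = !is.null(fixed_intercept),
      psi_manual = psi_manual
    ),
    class = c("sink_seg_fit", "sink_fit")
  )
}

#' @export
predict.sink_line_fit <- function(object, times, ...) {
  object$intercept + object$slope1 * times
}

#' @export
predict.sink_seg_fit <- function(object, times, ...) {
  psi <- object$breakpoint
  object$intercept + object$slope1 * pmin(times, psi) +
    object$slope2 * pmax(times - psi, 0)
}

#' Choose between the single-line and segmented fits
#'
#' The segmented model is accepted only when (a) the extra-parameters F-test
#' — 2 extra degrees of freedom, for the second slope and the breakpoint —
#' rejects the single line at level `alpha`, and (b) both fitted slopes are
#' negative, i.e. both phases describe sinking. Otherwise the single line is
#' kept. A BIC variant is available.
#'
#' @param single_fit A [fit_line()] result.
#' @param segmented_fit A [fit_segmented()] result on the same points.
#' @param alpha Significance level for the F-test (default 0.05).
#' @param method `"ftest"` (default) or `"bic"`.
#' @return An object of class `sink_model_choice`: a list with `model`
#'   (`"single"` or `"segmented"`), `statistic`, `p_value`, `df`.
#' @export
select_model <- function(single_fit, segmented_fit, alpha = 0.05,
                         method = c("ftest", "bic")) {
  method <- match.arg(method)
  if (single_fit$n != segmented_fit$n) {
    abort("Both fits must be computed on the same points.")
  }
  n <- single_fit$n
  slopes_neg <- segmented_fit$slope1 < 0 && segmented_fit$slope2 < 0
  df2 <- n - segmented_fit$n_params
  stat <- NA_real_; pval <- NA_real_
  if (method == "ftest") {
    if (df2 <= 0L) {
      choice <- "single"
    } else if (segmented_fit$rss <= .Machine$double.eps * single_fit$rss) {
      # perfect segmented fit: significant iff it actually improves
      pval <- if (single_fit$rss > segmented_fit$rss + 1e-12) 0 else 1
      stat <- Inf
      choice <- if (pval < alpha && slopes_neg) "segmented" else "single"
    } else {
      stat <- ((single_fit$rss - segmented_fit$rss) / 2) /
        (segmented_fit$rss / df2)
      pval <- pf(stat, 2, df2, lower.tail = FALSE)
      choice <- if (pval < alpha && slopes_neg) "segmented" else "single"
    }
  } else {
    k_single <- if (single_fit$fixed_intercept) 1L else 2L
    k_seg <- segmented_fit$n_params
    bic1 <- n * log(max(single_fit$rss, 1e-300) / n) + k_single * log(n)
    bic2 <- n * log(max(segmented_fit$rss, 1e-300) / n) + k_seg * log(n)
    stat <- bic1 - bic2
    choice <- if (bic2 < bic1 && slopes_neg) "segmented" else "single"
  }
  structure(
    list(model = choice, statistic = stat, p_value = pval,
         df = c(2L, df2), alpha = alpha, method = method,
         slopes_negative = slopes_neg),
    class = "sink_model_choice"
  )
}

#' Detect and excise the initial NPQ-relaxation fluorescence rise
#'
#' Some cultures brighten during the first ~30 min of the assay as
#' non-photochemical quenching relaxes after the drop from growth light,
#' masking early sinking. A segmented fit separates the rise from the
#' sinking phase: when the first segment rises (slope > 0, one-sided
#' p < `alpha`) and the second declines, the rise segment is discarded, the
#' sinking segment's line is extrapolated back to t = 0, and the retained
#' signal is rescaled multiplicatively so that extrapolated intercept equals
#' the culture depth (scaled value 1). Traces without a detectable rise pass
#' through unchanged.
#'
#' @param times Elapsed minutes.
#' @param depth_signal Depth signal in mm (from [depth_transform()]).
#' @param depth_mm Culture depth in mm.
#' @param min_seg Minimum points per segment for the detection fit.
#' @param alpha One-sided significance level for declaring a rise; `alpha =
#'   1` forces correction whenever the first slope is positive.
#' @return A list with `times`, `depth_signal` (corrected), `npq_corrected`
#'   (logical) and `rise_end_min` (the fitted end of the rise, `NA` when no
#'   rise was found).
#' @export
correct_npq_rise <- function(times, depth_signal, depth_mm = 3.8,
                             min_seg = 3, alpha = 0.05) {
  unchanged <- list(times = times, depth_signal = depth_signal,
                    npq_corrected = FALSE, rise_end_min = NA_real_)
  if (length(times) < 2L * min_seg) return(unchanged)
  seg <- fit_segmented(times, depth_signal, min_seg = min_seg)
  if (!(seg$slope1 > 0)) return(unchanged)
  tstat <- seg$slope1 / seg$slope1_se
  p_rise <- if (is.finite(tstat)) pt(tstat, seg$df_residual,
                                     lower.tail = FALSE) else 0
  if (!(p_rise < alpha || alpha >= 1)) return(unchanged)
  if (seg$slope2 >= 0) {
    abort("no sinking phase detected (trace rises but never declines)")
  }
  psi <- seg$breakpoint
  keep <- times > psi
  y0 <- seg$intercept + (seg$slope1 - seg$slope2) * psi
  if (y0 <= 0) abort("NPQ correction failed: extrapolated intercept <= 0.")
  list(
    times = times[keep],
    depth_signal = depth_signal[keep] * depth_mm / y0,
    npq_corrected = TRUE,
    rise_end_min = psi
  )
}

#' Phase amplitudes of a fitted sinking model
#'
#' The amplitude of the first sinking phase is the fraction of the fitted
#' depth signal at t = 0 lost before the breakpoint,
#' `(y(0) - y(psi)) / y(0)`, with `y` the fitted piecewise line; the second
#' phase takes the remainder, so the two always sum to 1. A single-line fit
#' has a single phase of amplitude 1. Amplitudes estimate the relative
#' abundances of sinking subpopulations.
#'
#' @param fit A [fit_line()] or [fit_segmented()] result.
#' @param depth_mm Culture depth in mm (used only for validation messages).
#' @return Named numeric vector `c(amplitude1, amplitude2)`; `amplitude2` is
#'   `NA` for a single-line fit.
#' @export
amplitudes <- function(fit, depth_mm = 3.8) {
  if (inherits(fit, "sink_line_fit")) {
    return(c(amplitude1 = 1, amplitude2 = NA_real_))
  }
  y0 <- fit$intercept
  if (y0 <= 0) abort("Fitted signal at t = 0 is not positive.")
  ypsi <- fit$intercept + fit$slope1 * fit$breakpoint
  a1 <- (y0 - ypsi) / y0
  c(amplitude1 = a1, amplitude2 = 1 - a1)
}

#' Extract sinking rates from a fitted model
#'
#' Converts the fitted decline slopes (mm min\eqn{^{-1}}, the fit being on
#' the depth signal) to rates in m d\eqn{^{-1}} via [slope_to_rate()], and
#' carries the breakpoint, amplitudes and regression standard errors.
#'
#' @param fit A [fit_line()] or [fit_segmented()] result whose slopes are
#'   non-positive (apply [correct_npq_rise()] first if the trace rises).
#' @param depth_mm Culture depth in mm.
#' @return A one-row tibble of class `sinking_rates` with columns
#'   `model`, `rate1_m_per_day`, `rate1_se`, `rate2_m_per_day`, `rate2_se`,
#'   `breakpoint_min`, `amplitude1`, `amplitude2`.
#' @export
extract_rates <- function(fit, depth_mm = 3.8) {
  slopes <- c(fit$slope1, if (inherits(fit, "sink_seg_fit")) fit$slope2)
  if (any(slopes > 0)) {
    abort("Positive (rising) slope: correct the NPQ rise before extracting rates.")
  }
  amp <- amplitudes(fit, depth_mm)
  if (inherits(fit, "sink_seg_fit")) {
    out <- tibble::tibble(
      model = "segmented",
      rate1_m_per_day = slope_to_rate(abs(fit$slope1)),
      rate1_se = fit$slope1_se * MIN_PER_DAY_OVER_MM_PER_M,
      rate2_m_per_day = slope_to_rate(abs(fit$slope2)),
      rate2_se = fit$slope2_se * MIN_PER_DAY_OVER_MM_PER_M,
      breakpoint_min = fit$breakpoint,
      amplitude1 = amp[["amplitude1"]],
      amplitude2 = amp[["amplitude2"]]
    )
  } else {
    out <- tibble::tibble(
      model = "single",
      rate1_m_per_day = slope_to_rate(abs(fit$slope1)),
      rate1_se = fit$slope1_se * MIN_PER_DAY_OVER_MM_PER_M,
      rate2_m_per_day = NA_real_, rate2_se = NA_real_,
      breakpoint_min = NA_real_,
      amplitude1 = 1, amplitude2 = NA_real_
    )
  }
  class(out) <- c("sinking_rates", class(out))
  out
}
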