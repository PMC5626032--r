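#' Tidy a line or segmented fit
#'
#' @param x A `sink_line_fit` or `sink_seg_fit` object.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`.
#' @export
tidy.sink_line_fit <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "slope1"),
    estimate = c(x$intercept, x$slope1),
    std.error = c(x$intercept_se, x$slope1_se)
  )
}

#' @rdname tidy.sink_line_fit
#' @export
tidy.sink_seg_fit <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "slope1", "slope2", "breakpoint"),
    estimate = c(x$intercept, x$slope1, x$slope2, x$breakpoint),
    std.error = c(if (x$fixed_intercept) NA_real_ else NA_real_,
                  x$slope1_se, x$slope2_se, NA_real_)
  )
}

#' One-row fit summary
#'
#' @param x A `sink_line_fit` or `sink_seg_fit` object.
#' @param ... Unused.
#' @return A one-row tibble with `model`, `rss`, `n`, `df.residual`,
#'   `fixed.intercept`.
#' @export
glance.sink_line_fit <- function(x, ...) {
  tibble::tibble(model = x$model, rss = x$rss, n = x$n,
                 df.residual = x$df_residual,
                 fixed.intercept = x$fixed_intercept)
}

#' @rdname glance.sink_line_fit
#' @export
glance.sink_seg_fit <- glance.sink_line_fit

#' Tidy a Gompertz growth fit
#'
#' @param x A `gompertz_fit` object.
#' @param ... Unused.
#' @return A tibble with one row per parameter (`A`, `mu`, `lam`).
#' @export
tidy.gompertz_fit <- function(x, ...) {
  tibble::tibble(
    term = c("A", "mu", "lam"),
    estimate = c(x$A, x$mu, x$lam),
    std.error = c(x$A_se, x$mu_se, x$lam_se)
  )
}

#' @rdname tidy.gompertz_fit
#' @export
glance.gompertz_fit <- function(x, ...) {
  tibble::tibble(rss = x$rss, n = x$n, converged = isTRUE(x$convergence),
                 rfu_min = x$rfu_min, rfu_max_est = x$rfu_max_est)
}

#' Tidy assay results
#'
#' @param x A `sink_assay_results` object.
#' @param ... Unused.
#' @return The per-well results tibble (`tidy`) or a one-row run summary
#'   (`glance`).
#' @export
tidy.sink_assay_results <- function(x, ...) x$wells

#' @rdname tidy.sink_assay_results
#' @export
glance.sink_assay_results <- function(x, ...) {
  tibble::tibble(
    n_wells = nrow(x$wells),
    n_failed = x$n_failed,
    n_segmented = sum(x$wells$model == "segmented", na.rm = TRUE),
    n_single = sum(x$wells$model == "single", na.rm = TRUE),
    n_npq_corrected = sum(x$wells$npq_corrected, na.rm = TRUE)
  )
}
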