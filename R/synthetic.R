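#' Specification for a synthetic sinking trace
#'
#' Collects the generative parameters for a simulated well. The defaults are
#' the conditions used throughout the package's validation: 40 reads over
#' 200 minutes (5-min cadence), two sinking subpopulations at scaled rates
#' 0.05 and 0.005 min\eqn{^{-1}} with weights 0.3/0.7, detector noise of 1%
#' of the initial amplitude, a settled-cell baseline of 5% of the initial
#' amplitude, and no NPQ rise. The trace model is
#' `rfu(t) = [baseline + f0 * sum_i w_i / (1 + s_i t)^2] *
#' [1 - npq_amp * exp(-t / npq_tau)] + N(0, noise_sd)`.
#'
#' @param times Read times, minutes.
#' @param f0 Initial RFU amplitude of the suspended population.
#' @param weights Subpopulation fractions (1 or 2 entries, summing to 1).
#' @param s_values Per-subpopulation scaled sinking rates, min\eqn{^{-1}}.
#' @param npq_amp Amplitude of the initial NPQ-relaxation rise, as the
#'   fraction of signal initially quenched, in `[0, 1)`.
#' @param npq_tau Time constant of NPQ relaxation, minutes.
#' @param baseline Additive floor RFU from settled cells that still
#'   fluoresce at the well bottom.
#' @param noise_sd Gaussian detector noise SD, RFU.
#' @param seed RNG seed (`NULL` for the session RNG).
#' @param depth_mm Culture depth, mm.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(times = seq(0, 195, by = 5),
                           f0 = 1000,
                           weights = c(0.3, 0.7),
                           s_values = c(0.05, 0.005),
                           npq_amp = 0,
                           npq_tau = 10,
                           baseline = 0.05 * f0,
                           noise_sd = 0.01 * f0,
                           seed = NULL,
                           depth_mm = 3.8) {
  if (length(weights) != length(s_values)) {
    abort("`weights` and `s_values` must have the same length.")
  }
  if (!length(weights) %in% 1:2) {
    abort("One or two subpopulations are supported.")
  }
  if (abs(sum(weights) - 1) > 1e-9) abort("`weights` must sum to 1.")
  if (any(s_values < 0)) abort("`s_values` must be nonnegative.")
  if (noise_sd < 0) abort("`noise_sd` must be nonnegative.")
  if (npq_amp < 0 || npq_amp >= 1) abort("`npq_amp` must be in [0, 1).")
  if (npq_tau <= 0) abort("`npq_tau` must be positive.")
  structure(
    list(times = times, f0 = f0, weights = weights, s_values = s_values,
         npq_amp = npq_amp, npq_tau = npq_tau, baseline = baseline,
         noise_sd = noise_sd, seed = seed, depth_mm = depth_mm),
    class = "synthetic_spec"
  )
}

#' Simulate one sinking trace
#'
#' Evaluates the mixture of inverse-square decay kernels, applies the
#' single-exponential NPQ-relaxation factor multiplicatively, and adds
#' seeded Gaussian detector noise. Deterministic for a fixed seed; the
#' session RNG state is restored afterwards.
#'
#' @param spec A [synthetic_spec()].
#' @return A tibble with columns `time_min` and `rfu`.
#' @examples
#' simulate_trace(synthetic_spec(seed = 1))
#' @export
simulate_trace <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  t <- spec$times
  decay <- rowSums(vapply(
    seq_along(spec$weights),
    function(i) spec$weights[i] * forward_scaled(t, spec$s_values[i]),
    numeric(length(t))
  ))
  clean <- (spec$baseline + spec$f0 * decay) *
    (1 - spec$npq_amp * exp(-t / spec$npq_tau))
  noise <- with_seed(spec$seed, rnorm(length(t), 0, spec$noise_sd))
  tibble::tibble(time_min = t, rfu = clean + noise)
}

# Noise-free expectation of a trace, used in tests and plots.
trace_expectation <- function(spec) {
  s0 <- spec; s0$noise_sd <- 0
  simulate_trace(s0)$rfu
}

#' Simulate a whole plate with a matching catalog
#'
#' Generates one trace per well from per-group generative parameters, with
#' optional multiplicative lognormal jitter on each well's `f0` and
#' `s_values` to emulate replicate-to-replicate variation, and emits the
#' matching well catalog.
#'
#' @param layout A data frame with columns `well`, `species`,
#'   `growth_phase`, `replicate_group` assigning wells to groups (groups are
#'   the distinct `replicate_group` values). Wells must be unique.
#' @param specs A named list of [synthetic_spec()] objects, one per
#'   `replicate_group`.
#' @param jitter Multiplicative jitter SD (lognormal, on `f0` and
#'   `s_values`); 0 for identical traces within a group up to noise.
#' @param seed Base RNG seed; each well w gets `seed + w`'s own stream.
#' @param plate_format 96 or 24.
#' @param depth_mm Culture depth, mm.
#' @return A list with `kinetics` (a [plate_kinetics]) and `catalog` (a
#'   `well_catalog` tibble).
#' @examples
#' layout <- data.frame(
#'   well = c("A1", "A2", "B1", "B2"),
#'   species = rep(c("sp1", "sp2"), each = 2),
#'   growth_phase = "exponential",
#'   replicate_group = rep(c("g1", "g2"), each = 2)
#' )
#' specs <- list(g1 = synthetic_spec(), g2 = synthetic_spec(s_values = c(0.02), weights = 1))
#' sim <- simulate_plate(layout, specs, seed = 1)
#' @export
simulate_plate <- function(layout, specs, jitter = 0, seed = NULL,
                           plate_format = 96, depth_mm = 3.8) {
  layout <- tibble::as_tibble(layout)
  req <- c("well", "species", "growth_phase", "replicate_group")
  missing <- setdiff(req, names(layout))
  if (length(missing) > 0L) {
    abort(paste0("Layout is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  dup <- layout$well[duplicated(layout$well)]
  if (length(dup) > 0L) {
    abort(paste0("Overlapping well assignment(s): ",
                 paste(unique(dup), collapse = ", ")))
  }
  groups <- unique(layout$replicate_group)
  missing_spec <- setdiff(groups, names(specs))
  if (length(missing_spec) > 0L) {
    abort(paste0("No synthetic_spec for group(s): ",
                 paste(missing_spec, collapse = ", ")))
  }
  traces <- purrr::imap(seq_len(nrow(layout)), function(i, ...) {
    row <- layout[i, ]
    sp <- specs[[row$replicate_group]]
    well_seed <- if (is.null(seed)) NULL else seed + i
    if (jitter > 0) {
      jit <- with_seed(
        if (is.null(well_seed)) NULL else well_seed + 10000L,
        exp(rnorm(1 + length(sp$s_values), 0, jitter))
      )
      sp$f0 <- sp$f0 * jit[1]
      sp$s_values <- sp$s_values * jit[-1]
    }
    sp$seed <- well_seed
    tr <- simulate_trace(sp)
    tr$well <- row$well
    tr
  })
  long <- dplyr::bind_rows(traces)[, c("well", "time_min", "rfu")]
  long$rfu <- pmax(long$rfu, 0)  # a fluorometer never reports negative RFU
  kinetics <- new_plate_kinetics(long, plate_format = plate_format,
                                 depth_mm = depth_mm)
  catalog <- layout
  catalog$strain <- if ("strain" %in% names(layout)) layout$strain else NA_character_
  catalog$plate_format <- as.integer(plate_format)
  catalog$depth_mm <- NA_real_
  catalog <- catalog[, c("well", "species", "strain", "growth_phase",
                         "replicate_group", "plate_format", "depth_mm")]
  class(catalog) <- c("well_catalog", class(tibble::tibble()))
  list(kinetics = kinetics, catalog = catalog)
}
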