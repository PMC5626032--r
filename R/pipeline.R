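#' Assay analysis configuration
#'
#' @param depth_mm Culture depth in mm (default 3.8); overridden per well by
#'   the catalog's `depth_mm` column when present.
#' @param alpha Significance level for segmented-vs-single model selection.
#' @param min_seg Minimum points per fitted segment.
#' @param intercept_mode `"free"` (default) or `"fixed"`: which intercept
#'   variant supplies the primary reported rates. Both variants are always
#'   computed and reported side by side.
#' @param npq_correction `"auto"` (correct when a significant rise is
#'   detected), `"off"`, or `"force"` (correct whenever the first fitted
#'   slope rises at all).
#' @param breakpoints Named list/vector mapping well IDs to manual
#'   breakpoints (minutes); those wells are fit as segmented at the given
#'   breakpoint, skipping the search and the model selection.
#' @param selection `"ftest"` or `"bic"`.
#' @return A list of class `assay_config`.
#' @export
assay_config <- function(depth_mm = 3.8, alpha = 0.05, min_seg = 3,
                         intercept_mode = c("free", "fixed"),
                         npq_correction = c("auto", "off", "force"),
                         breakpoints = NULL,
                         selection = c("ftest", "bic")) {
  if (depth_mm <= 0) abort("`depth_mm` must be positive.")
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must be in (0, 1).")
  structure(
    list(depth_mm = depth_mm, alpha = alpha, min_seg = min_seg,
         intercept_mode = match.arg(intercept_mode),
         npq_correction = match.arg(npq_correction),
         breakpoints = breakpoints, selection = match.arg(selection)),
    class = "assay_config"
  )
}

# Analyse a single well's trace; returns list(row = tibble row, fits = list).
analyze_well <- function(times, rfu, depth_mm, config, manual_psi = NULL) {
  st <- scale_rfu(times, rfu)
  min_early <- !attr(st, "min_in_tail")
  ds <- depth_transform(st, depth_mm)
  t_fit <- st$time_min
  y_fit <- ds
  npq <- list(npq_corrected = FALSE, rise_end_min = NA_real_)
  if (config$npq_correction != "off") {
    npq_alpha <- if (config$npq_correction == "force") 1 else 0.05
    npq <- correct_npq_rise(t_fit, y_fit, depth_mm,
                            min_seg = config$min_seg, alpha = npq_alpha)
    t_fit <- npq$times
    y_fit <- npq$depth_signal
  }

  fit_variant <- function(fixed) {
    fi <- if (fixed) depth_mm else NULL
    single <- fit_line(t_fit, y_fit, fixed_intercept = fi)
    seg <- tryCatch(
      fit_segmented(t_fit, y_fit, min_seg = config$min_seg,
                    fixed_intercept = fi, psi = manual_psi),
      error = function(e) NULL
    )
    if (!is.null(manual_psi) && !is.null(seg)) {
      choice <- list(model = "segmented", p_value = NA_real_,
                     statistic = NA_real_)
    } else if (is.null(seg)) {
      choice <- list(model = "single", p_value = NA_real_,
                     statistic = NA_real_)
    } else {
      choice <- select_model(single, seg, alpha = config$alpha,
                             method = config$selection)
    }
    chosen <- if (choice$model == "segmented") seg else single
    rates <- extract_rates(chosen, depth_mm)
    list(single = single, segmented = seg, choice = choice,
         chosen = chosen, rates = rates)
  }

  primary <- fit_variant(config$intercept_mode == "fixed")
  alt <- fit_variant(config$intercept_mode != "fixed")

  row <- primary$rates
  row$intercept_mm <- primary$chosen$intercept
  row$rss <- primary$chosen$rss
  row$n_points <- primary$chosen$n
  row$p_value <- primary$choice$p_value
  row$npq_corrected <- npq$npq_corrected
  row$rise_end_min <- npq$rise_end_min
  row$min_early <- min_early
  row$rate1_alt_m_per_day <- alt$rates$rate1_m_per_day
  row$rate2_alt_m_per_day <- alt$rates$rate2_m_per_day
  row$model_alt <- alt$rates$model
  list(row = row, fits = list(
    primary = primary, alt = alt, npq = npq,
    trace = tibble::tibble(time_min = t_fit, depth_signal = y_fit),
    full_trace = tibble::tibble(time_min = st$time_min, depth_signal = ds)
  ))
}

#' Run the end-to-end sinking assay analysis
#'
#' For every cataloged well: min-max scale the RFU trace, transform to the
#' depth signal, excise an NPQ rise if configured and detected, fit the
#' single-line and segmented models (both free- and fixed-intercept
#' variants), select the model, and extract phase rates and amplitudes.
#' Per-well failures are quarantined — the well's row carries the error
#' message and the run continues — so one bad well cannot kill a 96-well
#' screen. Replicate groups are summarized as mean and standard error across
#' wells.
#'
#' @param kinetics A [plate_kinetics] object.
#' @param catalog A `well_catalog` tibble ([read_catalog()]); every
#'   cataloged well must be present in `kinetics`.
#' @param config An [assay_config()].
#' @return An object of class `sink_assay_results`: list with `wells` (one
#'   tibble row per well), `groups` (replicate-group summaries), `fits`
#'   (per-well fit objects, for plotting and inspection), `config`,
#'   `n_failed`.
#' @examples
#' layout <- data.frame(well = c("A1", "A2", "A3"), species = "synthetic",
#'                      growth_phase = "exponential", replicate_group = "g1")
#' sim <- simulate_plate(layout, list(g1 = synthetic_spec()), seed = 42)
#' res <- run_assay(sim$kinetics, sim$catalog)
#' res$wells
#' @export
run_assay <- function(kinetics, catalog, config = assay_config()) {
  stopifnot(inherits(kinetics, "plate_kinetics"))
  missing_wells <- setdiff(catalog$well, wells(kinetics))
  if (length(missing_wells) > 0L) {
    abort(paste0("Cataloged well(s) absent from the kinetics: ",
                 paste(missing_wells, collapse = ", ")))
  }
  na_row <- tibble::tibble(
    model = NA_character_, rate1_m_per_day = NA_real_, rate1_se = NA_real_,
    rate2_m_per_day = NA_real_, rate2_se = NA_real_,
    breakpoint_min = NA_real_, amplitude1 = NA_real_, amplitude2 = NA_real_,
    intercept_mm = NA_real_, rss = NA_real_, n_points = NA_integer_,
    p_value = NA_real_, npq_corrected = NA, rise_end_min = NA_real_,
    min_early = NA, rate1_alt_m_per_day = NA_real_,
    rate2_alt_m_per_day = NA_real_, model_alt = NA_character_
  )
  fits <- list()
  rows <- purrr::map(seq_len(nrow(catalog)), function(i) {
    meta <- catalog[i, ]
    dwell <- if (!is.na(meta$depth_mm)) meta$depth_mm else config$depth_mm
    tr <- well_trace(kinetics, meta$well)
    manual_psi <- if (!is.null(config$breakpoints) &&
                      meta$well %in% names(config$breakpoints)) {
      as.numeric(config$breakpoints[[meta$well]])
    } else NULL
    res <- tryCatch(
      analyze_well(tr$times, tr$rfu, dwell, config, manual_psi),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      row <- na_row
      row$error <- conditionMessage(res)
    } else {
      fits[[meta$well]] <<- res$fits
      row <- res$row
      row$error <- NA_character_
    }
    dplyr::bind_cols(
      tibble::tibble(well = meta$well, species = meta$species,
                     strain = meta$strain, growth_phase = meta$growth_phase,
                     replicate_group = meta$replicate_group,
                     depth_mm = dwell),
      row
    )
  })
  wells_df <- dplyr::bind_rows(rows)
  n_failed <- sum(!is.na(wells_df$error))
  if (n_failed > 0L) {
    warn(paste0(n_failed, " well(s) failed and were quarantined; see the ",
                "`error` column."))
  }
  structure(
    list(wells = wells_df, groups = summarize_groups(wells_df),
         fits = fits, config = config, n_failed = n_failed),
    class = "sink_assay_results"
  )
}

#' Summarize per-well rates by replicate group
#'
#' Mean and standard error (sd / sqrt(n)) across the wells of each
#' replicate group, for both phase rates and the first-phase amplitude.
#'
#' @param wells_df The `wells` tibble of a `sink_assay_results` object.
#' @return A tibble with one row per replicate group.
#' @export
summarize_groups <- function(wells_df) {
  se <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2L) return(NA_real_)
    sd(x) / sqrt(length(x))
  }
  grp_cols <- intersect(c("replicate_group", "species", "growth_phase"),
                        names(wells_df))
  if ("error" %in% names(wells_df)) {
    wells_df <- dplyr::filter(wells_df, is.na(.data$error))
  }
  wells_df |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp_cols))) |>
    dplyr::summarise(
      n_wells = dplyr::n(),
      rate1_mean = mean(.data$rate1_m_per_day, na.rm = TRUE),
      rate1_se = se(.data$rate1_m_per_day),
      rate2_mean = mean(.data$rate2_m_per_day, na.rm = TRUE),
      rate2_se = se(.data$rate2_m_per_day),
      amplitude1_mean = mean(.data$amplitude1, na.rm = TRUE),
      amplitude1_se = se(.data$amplitude1),
      breakpoint_mean = mean(.data$breakpoint_min, na.rm = TRUE),
      .groups = "drop"
    )
}

#' @export
print.sink_assay_results <- function(x, ...) {
  cat("<sink_assay_results>\n")
  cat("  wells analysed: ", nrow(x$wells), " (", x$n_failed, " failed)\n",
      sep = "")
  cat("  segmented: ", sum(x$wells$model == "segmented", na.rm = TRUE),
      ", single: ", sum(x$wells$model == "single", na.rm = TRUE), "\n",
      sep = "")
  cat("  NPQ-corrected: ", sum(x$wells$npq_corrected, na.rm = TRUE), "\n",
      sep = "")
  print(x$groups)
  invisible(x)
}
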