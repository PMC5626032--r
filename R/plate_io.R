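#' Read a plate-fluorometer kinetic export
#'
#' Parses a kinetic export into a [plate_kinetics] object. Two dialects are
#' supported. The `canonical` dialect is the package's contract: a delimited
#' table (TSV or CSV, sniffed from the header line) whose first column is
#' elapsed time and whose remaining columns are wells, e.g. header
#' `time_min,A1,A2,...`. The `softmax_block` dialect is a best-effort reader
#' for SoftMax-style block `.txt` exports: banner lines are skipped, the
#' kinetic block is located by its `Time` column, and a `Temperature` column,
#' if present, is dropped.
#'
#' Times are normalized to elapsed minutes whatever the source unit:
#' `time_unit = "auto"` treats a first column named with a `sec`/`_s` suffix
#' as seconds and `h:mm:ss` strings as clock durations, otherwise minutes.
#' The origin is shifted so the first read is 0. Empty RFU cells are dropped
#' pairwise (that time point is removed for that well only) with a message;
#' non-numeric non-empty cells are an error.
#'
#' @param path Path to the export file.
#' @param dialect `"canonical"` or `"softmax_block"`.
#' @param time_unit `"auto"`, `"min"`, `"sec"` or `"hms"`.
#' @param plate_format 96 or 24; if `NULL`, inferred from the well IDs
#'   present (24 only when all wells fit A1..D6).
#' @param depth_mm Culture depth in mm (default 3.8).
#' @return A [plate_kinetics] tibble.
#' @export
read_plate_export <- function(path,
                              dialect = c("canonical", "softmax_block"),
                              time_unit = c("auto", "min", "sec", "hms"),
                              plate_format = NULL,
                              depth_mm = 3.8) {
  dialect <- match.arg(dialect)
  time_unit <- match.arg(time_unit)
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  lines <- readr::read_lines(path)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) == 0L) abort(paste0("Empty export file: ", path))

  if (dialect == "softmax_block") {
    hit <- grep("(^|\\t|,)\\s*Time", lines)[1]
    if (is.na(hit)) abort("No kinetic block found (no 'Time' column header).")
    lines <- lines[hit:length(lines)]
    # block ends at the first row whose first field is not time-like
    body <- lines[-1]
    first_field <- sub("[\t,].*$", "", body)
    timey <- grepl("^\\s*[0-9.:]+\\s*$", first_field)
    if (any(!timey)) body <- body[seq_len(which(!timey)[1] - 1L)]
    lines <- c(lines[1], body)
    if (length(lines) < 2L) abort("Kinetic block contains no data rows.")
  }

  sep <- if (grepl("\t", lines[1])) "\t" else ","
  fields <- strsplit(lines, sep, fixed = TRUE)
  header <- trimws(fields[[1]])
  body <- fields[-1]
  ncol_expect <- length(header)
  body <- lapply(body, function(f) {
    length(f) <- ncol_expect
    trimws(f)
  })
  drop_cols <- grepl("^temperature", header, ignore.case = TRUE)
  time_col <- header[1]
  well_cols <- header[-1][!drop_cols[-1]]

  raw_time <- vapply(body, `[[`, character(1), 1L)
  times <- parse_time_minutes(raw_time, time_col, time_unit)
  dt <- diff(times)
  if (any(dt <= 0)) {
    row <- which(dt <= 0)[1] + 1L
    abort(paste0(
      "Time column is not strictly increasing at data row ", row,
      " (", raw_time[row], " follows ", raw_time[row - 1L], ")."
    ))
  }
  times <- times - times[1]

  keep_idx <- which(!drop_cols)[-1]
  mat <- matrix(NA_real_, nrow = length(body), ncol = length(keep_idx),
                dimnames = list(NULL, well_cols))
  n_missing <- 0L
  for (j in seq_along(keep_idx)) {
    cells <- vapply(body, function(f) {
      v <- f[[keep_idx[j]]]
      if (is.na(v)) "" else v
    }, character(1))
    empty <- cells == "" | toupper(cells) == "NA"
    n_missing <- n_missing + sum(empty)
    vals <- suppressWarnings(as.numeric(cells))
    bad <- !empty & is.na(vals)
    if (any(bad)) {
      abort(paste0(
        "Non-numeric RFU value '", cells[which(bad)[1]], "' in well ",
        well_cols[j], ", data row ", which(bad)[1], "."
      ))
    }
    mat[, j] <- vals
  }
  if (n_missing > 0L) {
    inform(paste0("Dropped ", n_missing, " missing RFU cell(s) pairwise."))
  }

  if (is.null(plate_format)) {
    plate_format <- if (all(is_valid_well(well_cols, 24))) 24L else 96L
  }
  bad_wells <- well_cols[!is_valid_well(well_cols, plate_format)]
  if (length(bad_wells) > 0L) {
    abort(paste0(
      "Well ID(s) invalid for a ", plate_format, "-well plate: ",
      paste(bad_wells, collapse = ", ")
    ))
  }
  plate_kinetics(times, t(mat), plate_format = plate_format,
                 depth_mm = depth_mm)
}

parse_time_minutes <- function(raw, colname, time_unit) {
  if (time_unit == "auto") {
    time_unit <- if (grepl("(_s$|_sec|\\bsec)", colname, ignore.case = TRUE)) {
      "sec"
    } else if (any(grepl(":", raw, fixed = TRUE))) {
      "hms"
    } else "min"
  }
  if (time_unit == "hms") {
    parts <- strsplit(raw, ":", fixed = TRUE)
    mins <- vapply(parts, function(p) {
      p <- suppressWarnings(as.numeric(p))
      if (any(is.na(p))) return(NA_real_)
      # h:mm:ss or mm:ss
      if (length(p) == 3L) p[1] * 60 + p[2] + p[3] / 60
      else if (length(p) == 2L) p[1] + p[2] / 60
      else NA_real_
    }, numeric(1))
  } else {
    mins <- suppressWarnings(as.numeric(raw))
    if (time_unit == "sec") mins <- mins / 60
  }
  if (any(is.na(mins))) {
    abort(paste0(
      "Non-numeric time value '", raw[which(is.na(mins))[1]],
      "' at data row ", which(is.na(mins))[1], "."
    ))
  }
  mins
}

#' Write a plate-kinetics object as a canonical kinetic TSV
#'
#' The canonical layout (`time_min` column followed by one column per well)
#' round-trips through [read_plate_export()] exactly.
#'
#' @param kinetics A [plate_kinetics] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_plate_export <- function(kinetics, path) {
  wide <- kinetics |>
    tibble::as_tibble() |>
    tidyr::pivot_wider(names_from = "well", values_from = "rfu") |>
    dplyr::arrange(.data$time_min)
  readr::write_tsv(wide, path)
  invisible(path)
}

#' Read a well catalog
#'
#' The catalog CSV maps wells to their contents. Required columns: `well`,
#' `species`, `growth_phase` (`exponential` or `stationary`),
#' `replicate_group`, `plate_format`. Optional: `strain`, `depth_mm` (per-well
#' depth override). Rows with a blank well ID are dropped with a warning.
#'
#' @param path Path to the catalog CSV.
#' @return A tibble of class `well_catalog`.
#' @export
read_catalog <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  cat_df <- readr::read_csv(path, show_col_types = FALSE,
                            col_types = readr::cols(.default = "c"))
  required <- c("well", "species", "growth_phase", "replicate_group",
                "plate_format")
  missing <- setdiff(required, names(cat_df))
  if (length(missing) > 0L) {
    abort(paste0("Catalog is missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  blank <- is.na(cat_df$well) | trimws(cat_df$well) == ""
  if (any(blank)) {
    warn(paste0("Dropped ", sum(blank), " catalog row(s) with blank well ID."))
    cat_df <- cat_df[!blank, , drop = FALSE]
  }
  cat_df$well <- trimws(cat_df$well)
  dup <- cat_df$well[duplicated(cat_df$well)]
  if (length(dup) > 0L) {
    abort(paste0("Duplicate well ID(s) in catalog: ",
                 paste(unique(dup), collapse = ", ")))
  }
  allowed_phase <- c("exponential", "stationary")
  bad_phase <- setdiff(unique(cat_df$growth_phase), allowed_phase)
  if (length(bad_phase) > 0L) {
    abort(paste0(
      "Unknown growth_phase value(s): ", paste(bad_phase, collapse = ", "),
      ". Allowed: ", paste(allowed_phase, collapse = ", "), "."
    ))
  }
  cat_df$plate_format <- as.integer(cat_df$plate_format)
  if (any(!cat_df$plate_format %in% c(96L, 24L))) {
    abort("`plate_format` must be 96 or 24 for every catalog row.")
  }
  bad_well <- !mapply(is_valid_well, cat_df$well, cat_df$plate_format)
  if (any(bad_well)) {
    abort(paste0(
      "Well ID(s) invalid for their plate format (96-well: A1..H12, ",
      "24-well: A1..D6): ", paste(cat_df$well[bad_well], collapse = ", ")
    ))
  }
  if (!"strain" %in% names(cat_df)) cat_df$strain <- NA_character_
  if ("depth_mm" %in% names(cat_df)) {
    cat_df$depth_mm <- as.numeric(cat_df$depth_mm)
  } else {
    cat_df$depth_mm <- NA_real_
  }
  out <- cat_df[, c("well", "species", "strain", "growth_phase",
                    "replicate_group", "plate_format", "depth_mm")]
  class(out) <- c("well_catalog", class(tibble::tibble()))
  out
}

#' Write per-well sinking results and a replicate-group summary
#'
#' Writes one CSV row per well with columns `well`, `species`,
#' `growth_phase`, `model`, `npq_corrected`, `breakpoint_min`,
#' `rate1_m_per_day`, `rate2_m_per_day`, `amplitude1`, `amplitude2`, `rss`,
#' `n_points` (rates rounded to 3 decimals, matching the precision sinking
#' rates are conventionally reported at), and a JSON summary per replicate
#' group (mean and standard error across wells, full precision).
#'
#' @param results A `sink_assay_results` object from [run_assay()], or a
#'   tibble shaped like its `$wells` component.
#' @param path Output CSV path. The JSON summary goes to `json_path`.
#' @param json_path Output JSON path; default is `path` with a `.json`
#'   extension.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, json_path = NULL) {
  if (is.null(json_path)) json_path <- sub("\\.[Cc][Ss][Vv]$", ".json", path)
  if (identical(json_path, path)) json_path <- paste0(path, ".json")
  wells_df <- if (inherits(results, "sink_assay_results")) results$wells
              else tibble::as_tibble(results)
  cols <- c("well", "species", "growth_phase", "model", "npq_corrected",
            "breakpoint_min", "rate1_m_per_day", "rate2_m_per_day",
            "amplitude1", "amplitude2", "rss", "n_points")
  for (cl in setdiff(cols, names(wells_df))) wells_df[[cl]] <- NA
  out <- wells_df[, cols]
  out <- dplyr::mutate(out, dplyr::across(
    dplyr::all_of(c("rate1_m_per_day", "rate2_m_per_day")),
    ~ round(.x, 3)
  ))
  readr::write_csv(out, path, na = "")

  groups <- if (inherits(results, "sink_assay_results")) results$groups
            else summarize_groups(wells_df)
  jsonlite::write_json(groups, json_path, auto_unbox = TRUE, digits = NA,
                       na = "null", dataframe = "rows")
  invisible(path)
}

#' Convert supplementary .RData trace files to plate kinetics
#'
#' Reproduction helper: loads an `.RData` file, finds every data frame whose
#' first column is a time axis and whose remaining numeric columns look like
#' per-well traces, and converts each to a [plate_kinetics] object. Column
#' names that are not well IDs are mapped onto plate positions in row-major
#' order, preserving the original name in the returned `well_map` attribute.
#'
#' @param path Path to an `.RData` file.
#' @param depth_mm Culture depth in mm (default 3.8).
#' @param plate_format 96 or 24.
#' @return A named list of [plate_kinetics] objects, one per usable data
#'   frame in the file.
#' @export
read_supplementary_rdata <- function(path, depth_mm = 3.8, plate_format = 96) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  env <- new.env(parent = emptyenv())
  load(path, envir = env)
  objs <- mget(ls(env), envir = env)
  dfs <- Filter(is.data.frame, objs)
  out <- list()
  for (nm in names(dfs)) {
    df <- dfs[[nm]]
    if (ncol(df) < 2L) next
    tname <- names(df)[1]
    if (!grepl("time|min|elapsed", tname, ignore.case = TRUE)) next
    times <- suppressWarnings(as.numeric(df[[1]]))
    if (any(is.na(times))) next
    traces <- df[-1]
    num <- vapply(traces, is.numeric, logical(1))
    traces <- traces[num]
    if (ncol(traces) == 0L) next
    cn <- names(traces)
    if (!all(is_valid_well(cn, plate_format))) {
      mapped <- valid_wells(plate_format)[seq_along(cn)]
      well_map <- setNames(cn, mapped)
      names(traces) <- mapped
    } else {
      well_map <- setNames(cn, cn)
    }
    pk <- plate_kinetics(times - times[1], t(as.matrix(traces)),
                         plate_format = plate_format, depth_mm = depth_mm)
    attr(pk, "well_map") <- well_map
    out[[nm]] <- pk
  }
  if (length(out) == 0L) {
    abort("No time-by-well data frames found in the .RData file.")
  }
  out
}
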