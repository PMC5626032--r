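#' Plate kinetics container
#'
#' A `plate_kinetics` object is a long tibble with one row per (well, read):
#' columns `well` (character, e.g. `"A1"`), `time_min` (elapsed minutes,
#' strictly increasing within each well, starting at 0) and `rfu`
#' (nonnegative relative fluorescence units). Plate geometry travels as
#' attributes: `plate_format` (96 or 24), `depth_mm` (culture depth, default
#' 3.8 mm — the depth used in both 96- and 24-well plates when filled to
#' 300 uL and 2.8 mL respectively) and `read_interval_min` (nominal cadence,
#' taken from the data).
#'
#' @param times Numeric vector of elapsed minutes, strictly increasing,
#'   first element 0.
#' @param rfu A numeric matrix (wells x times, rownames are well IDs) or a
#'   long data frame with columns `well`, `time_min`, `rfu`.
#' @param plate_format 96 or 24.
#' @param depth_mm Culture depth in mm (> 0).
#' @return A tibble of class `plate_kinetics`.
#' @examples
#' m <- rbind(A1 = c(100, 50, 25), A2 = c(80, 40, 20))
#' pk <- plate_kinetics(c(0, 10, 20), m)
#' wells(pk)
#' @export
plate_kinetics <- function(times, rfu, plate_format = 96, depth_mm = 3.8) {
  if (is.matrix(rfu)) {
    if (is.null(rownames(rfu))) {
      abort("`rfu` matrix must have well IDs as rownames.")
    }
    if (ncol(rfu) != length(times)) {
      abort("`rfu` must have one column per time point.")
    }
    long <- tibble::tibble(
      well = rep(rownames(rfu), each = length(times)),
      time_min = rep(as.numeric(times), times = nrow(rfu)),
      rfu = as.numeric(t(rfu))
    )
  } else {
    long <- tibble::as_tibble(rfu)[, c("well", "time_min", "rfu")]
  }
  new_plate_kinetics(long, plate_format = plate_format, depth_mm = depth_mm)
}

new_plate_kinetics <- function(long, plate_format, depth_mm) {
  plate_format <- as.integer(plate_format)
  if (!plate_format %in% c(96L, 24L)) {
    abort("`plate_format` must be 96 or 24.")
  }
  if (!is.numeric(depth_mm) || length(depth_mm) != 1L || depth_mm <= 0) {
    abort("`depth_mm` must be a single positive number.")
  }
  long <- dplyr::filter(long, !is.na(.data$rfu))
  if (nrow(long) == 0L) abort("No finite RFU values.")
  if (any(!is.finite(long$rfu))) abort("RFU values must be finite.")
  if (any(long$rfu < 0)) abort("RFU values must be nonnegative.")
  bad_t <- long |>
    dplyr::group_by(.data$well) |>
    dplyr::summarise(ok = all(diff(.data$time_min) > 0), .groups = "drop")
  if (any(!bad_t$ok)) {
    abort(paste0(
      "Times must be strictly increasing; offending well(s): ",
      paste(bad_t$well[!bad_t$ok], collapse = ", ")
    ))
  }
  all_t <- sort(unique(long$time_min))
  structure(
    long,
    class = c("plate_kinetics", class(tibble::tibble()))
    ,
    plate_format = plate_format,
    depth_mm = depth_mm,
    read_interval_min = if (length(all_t) > 1L) stats::median(diff(all_t)) else NA_real_
  )
}

#' @rdname plate_kinetics
#' @param x A `plate_kinetics` object.
#' @export
wells <- function(x) unique(x$well)

#' @rdname plate_kinetics
#' @export
depth_mm <- function(x) attr(x, "depth_mm")

#' @rdname plate_kinetics
#' @export
plate_format <- function(x) attr(x, "plate_format")

# Valid well IDs for a plate format: 96-well = A1..H12, 24-well = A1..D6.
valid_wells <- function(plate_format) {
  dims <- if (as.integer(plate_format) == 96L) c(8L, 12L) else c(4L, 6L)
  as.vector(outer(LETTERS[seq_len(dims[1])], seq_len(dims[2]), paste0))
}

is_valid_well <- function(well, plate_format) {
  well %in% valid_wells(plate_format)
}

# Extract one well's trace as (times, rfu) vectors.
well_trace <- function(kinetics, well) {
  tr <- kinetics[kinetics$well == well, , drop = FALSE]
  list(times = tr$time_min, rfu = tr$rfu)
}
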