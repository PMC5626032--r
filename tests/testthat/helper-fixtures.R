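# Fixtures built in code: canonical exports, catalogs, reference fits.

# Write a canonical kinetic TSV with the given wells and return its path.
write_canonical_fixture <- function(times, traces, path = tempfile(fileext = ".tsv"),
                                    time_col = "time_min") {
  df <- data.frame(times, traces, check.names = FALSE)
  names(df)[1] <- time_col
  readr::write_tsv(df, path)
  path
}

write_catalog_fixture <- function(wells, species = "S. marinoi",
                                  growth_phase = "exponential",
                                  replicate_group = "rep1",
                                  plate_format = 96,
                                  path = tempfile(fileext = ".csv"), ...) {
  df <- data.frame(well = wells, species = species,
                   growth_phase = growth_phase,
                   replicate_group = replicate_group,
                   plate_format = plate_format, ...)
  readr::write_csv(df, path)
  path
}

# Exact continuous piecewise-linear response.
piecewise_y <- function(t, a, b1, b2, psi) {
  a + b1 * pmin(t, psi) + b2 * pmax(t - psi, 0)
}

# Independent brute-force breakpoint oracle: exhaustive scan of a dense psi
# grid, solving the conditionally linear LS problem at each grid point with
# stats::lm.fit (a different code path from the package's profiled search).
brute_force_segmented <- function(t, y, min_seg = 3, ngrid = 1000,
                                  fixed_intercept = NULL) {
  lo <- sort(t)[min_seg]
  hi <- sort(t)[length(t) - min_seg + 1]
  grid <- seq(lo + 1e-9, hi - 1e-9, length.out = ngrid)
  ok <- vapply(grid, function(p) {
    sum(t <= p) >= min_seg && sum(t > p) >= min_seg
  }, logical(1))
  grid <- grid[ok]
  rss <- vapply(grid, function(p) {
    if (is.null(fixed_intercept)) {
      X <- cbind(1, t, pmax(t - p, 0))
      z <- y
    } else {
      X <- cbind(t, pmax(t - p, 0))
      z <- y - fixed_intercept
    }
    sum(stats::lm.fit(X, z)$residuals^2)
  }, numeric(1))
  list(psi = grid[which.min(rss)], rss = min(rss),
       step = grid[2] - grid[1])
}
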