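test_that("canonical export parses into a plate_kinetics with minute times", {
  p <- write_canonical_fixture(c(0, 10, 20),
                               data.frame(A1 = c(100, 50, 25),
                                          A2 = c(80, 60, 40)))
  pk <- read_plate_export(p)
  expect_s3_class(pk, "plate_kinetics")
  expect_equal(sort(wells(pk)), c("A1", "A2"))
  tr <- pk[pk$well == "A1", ]
  expect_equal(tr$time_min, c(0, 10, 20))
  expect_equal(tr$rfu, c(100, 50, 25))
  expect_equal(depth_mm(pk), 3.8)
})

test_that("second-based and h:mm:ss time columns normalize to minutes", {
  p_sec <- write_canonical_fixture(c(0, 600, 1200),
                                   data.frame(A1 = c(100, 50, 25)),
                                   time_col = "time_s")
  pk <- read_plate_export(p_sec)
  expect_equal(unique(pk$time_min), c(0, 10, 20))

  p_hms <- write_canonical_fixture(c("0:00:00", "0:10:00", "0:20:30"),
                                   data.frame(A1 = c(100, 50, 25)),
                                   time_col = "time")
  pk2 <- read_plate_export(p_hms)
  expect_equal(unique(pk2$time_min), c(0, 10, 20.5))
})

test_that("non-monotonic times are rejected naming the offending row", {
  p <- write_canonical_fixture(c(0, 10, 5), data.frame(A1 = c(3, 2, 1)))
  expect_error(read_plate_export(p), "row 3")
})

test_that("non-numeric RFU cells are rejected; empty cells drop pairwise", {
  p <- write_canonical_fixture(c(0, 10, 20),
                               data.frame(A1 = c("100", "oops", "25")))
  expect_error(read_plate_export(p), "Non-numeric RFU")

  p2 <- write_canonical_fixture(c(0, 10, 20, 30),
                                data.frame(A1 = c("100", "", "25", "10"),
                                           A2 = c("90", "60", "40", "20")))
  expect_message(pk <- read_plate_export(p2), "1 missing RFU")
  expect_equal(pk[pk$well == "A1", ]$time_min, c(0, 20, 30))
  expect_equal(pk[pk$well == "A2", ]$time_min, c(0, 10, 20, 30))
})

test_that("empty files and missing files are rejected", {
  empty <- tempfile(fileext = ".tsv")
  writeLines(character(0), empty)
  expect_error(read_plate_export(empty), "Empty")
  expect_error(read_plate_export(tempfile()), "not found")
})

test_that("softmax block exports are located by their Time header", {
  p <- tempfile(fileext = ".txt")
  writeLines(c(
    "##BLOCKS= 1",
    "Plate: Kinetic read 2 reads",
    "",
    "Time\tTemperature\tA1\tA2",
    "0:00:00\t21.5\t100\t80",
    "0:05:00\t21.6\t70\t60",
    "0:10:00\t21.4\t50\t40",
    "",
    "~End"
  ), p)
  pk <- read_plate_export(p, dialect = "softmax_block")
  expect_equal(sort(wells(pk)), c("A1", "A2"))
  expect_equal(unique(pk$time_min), c(0, 5, 10))
  expect_equal(pk[pk$well == "A1", ]$rfu, c(100, 70, 50))
})

test_that("canonical write/read round trip preserves times and RFU", {
  set.seed(11)
  times <- seq(0, 100, by = 2.5)
  m <- rbind(A1 = 1000 * forward_scaled(times, 0.02) + rnorm(41),
             B7 = 800 * forward_scaled(times, 0.01) + rnorm(41))
  m <- pmax(m, 0)
  pk <- plate_kinetics(times, m)
  p <- tempfile(fileext = ".tsv")
  write_plate_export(pk, p)
  pk2 <- read_plate_export(p)
  expect_equal(pk2$time_min, pk$time_min, tolerance = 1e-12)
  expect_equal(pk2$rfu, pk$rfu, tolerance = 1e-12)
})

test_that("scientific notation is accepted by the reader", {
  p <- write_canonical_fixture(c(0, 10, 20),
                               data.frame(A1 = c("1e2", "5.0e1", "2.5e1")))
  pk <- read_plate_export(p)
  expect_equal(pk$rfu, c(100, 50, 25))
})

test_that("catalogs validate wells, phases and duplicates", {
  p <- write_catalog_fixture(c("A1", "A2", "A3"))
  ctl <- read_catalog(p)
  expect_s3_class(ctl, "well_catalog")
  expect_equal(nrow(ctl), 3)
  expect_equal(ctl$growth_phase, rep("exponential", 3))

  expect_error(read_catalog(write_catalog_fixture(c("A1", "A1"))),
               "Duplicate")
  expect_error(read_catalog(write_catalog_fixture("Z9")), "invalid")
  expect_error(read_catalog(write_catalog_fixture("E2", plate_format = 24)),
               "invalid")
  expect_error(
    read_catalog(write_catalog_fixture("A1", growth_phase = "lagging")),
    "exponential"
  )
})

test_that("blank well rows are dropped with a warning", {
  p <- tempfile(fileext = ".csv")
  readr::write_csv(data.frame(
    well = c("A1", ""), species = "sp", growth_phase = "stationary",
    replicate_group = "r1", plate_format = 96
  ), p)
  expect_warning(ctl <- read_catalog(p), "blank")
  expect_equal(ctl$well, "A1")
})

test_that("results writer emits per-well CSV and per-group JSON summary", {
  layout <- data.frame(well = c("A1", "A2", "A3"), species = "synthetic",
                       growth_phase = "exponential", replicate_group = "g1")
  sim <- simulate_plate(layout, list(g1 = synthetic_spec()), seed = 3)
  res <- run_assay(sim$kinetics, sim$catalog)
  csv <- tempfile(fileext = ".csv")
  write_results(res, csv)
  out <- readr::read_csv(csv, show_col_types = FALSE)
  expect_equal(nrow(out), 3)
  expect_named(out, c("well", "species", "growth_phase", "model",
                      "npq_corrected", "breakpoint_min", "rate1_m_per_day",
                      "rate2_m_per_day", "amplitude1", "amplitude2", "rss",
                      "n_points"))
  js <- jsonlite::read_json(sub("\\.csv$", ".json", csv),
                            simplifyVector = TRUE)
  expect_equal(js$n_wells, 3)
  expect_equal(js$rate1_se,
               sd(res$wells$rate1_m_per_day) / sqrt(3), tolerance = 1e-12)
})

test_that("single-phase wells leave rate2/amplitude2 empty, amplitude1 = 1", {
  wells_df <- tibble::tibble(
    well = "A1", species = "sp", growth_phase = "exponential",
    replicate_group = "g", model = "single", npq_corrected = FALSE,
    breakpoint_min = NA_real_, rate1_m_per_day = 0.027,
    rate2_m_per_day = NA_real_, amplitude1 = 1, amplitude2 = NA_real_,
    rss = 0.1, n_points = 40L
  )
  csv <- tempfile(fileext = ".csv")
  write_results(wells_df, csv)
  out <- readr::read_csv(csv, show_col_types = FALSE)
  expect_equal(nrow(out), 1)
  expect_true(is.na(out$rate2_m_per_day))
  expect_true(is.na(out$amplitude2))
  expect_equal(out$amplitude1, 1)
  # empty CSV still writes a header
  csv0 <- tempfile(fileext = ".csv")
  write_results(wells_df[0, ], csv0)
  expect_length(readLines(csv0), 1)
})

test_that("replicate wells with identical rates summarize to SE 0", {
  wells_df <- tibble::tibble(
    well = c("A1", "A2", "A3"), species = "sp",
    growth_phase = "exponential", replicate_group = "g",
    model = "single", npq_corrected = FALSE, breakpoint_min = NA_real_,
    rate1_m_per_day = 0.06, rate2_m_per_day = NA_real_,
    amplitude1 = 1, amplitude2 = NA_real_, rss = 0.1, n_points = 40L
  )
  g <- summarize_groups(wells_df)
  expect_equal(g$rate1_mean, 0.06)
  expect_equal(g$rate1_se, 0)
})

test_that(".RData supplementary files convert to plate kinetics", {
  rd <- tempfile(fileext = ".RData")
  trace_df <- data.frame(Time = seq(0, 60, by = 5),
                         A1 = 100 * forward_scaled(seq(0, 60, by = 5), 0.02),
                         A2 = 90 * forward_scaled(seq(0, 60, by = 5), 0.03))
  save(trace_df, file = rd)
  pks <- read_supplementary_rdata(rd)
  expect_named(pks, "trace_df")
  expect_equal(sort(wells(pks$trace_df)), c("A1", "A2"))
  expect_equal(unique(pks$trace_df$time_min), seq(0, 60, by = 5))
})
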