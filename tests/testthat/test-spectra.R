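# Spectrum I/O, windowing and baseline handling.

test_that("spectrum files round-trip and parse all dialects", {
  sp <- two_band_spectrum()
  path <- withr::local_tempfile(fileext = ".txt")
  write_raman(sp, path)
  back <- read_raman(path, sample_id = sp$sample_id[1])
  expect_equal(back$wavenumber, sp$wavenumber, tolerance = 1e-6)
  expect_equal(back$intensity, sp$intensity, tolerance = 1e-6)

  # csv dialect with a text header line and a comment
  csv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# acquired 2016-06-01", "wavenumber,intensity",
               paste(sp$wavenumber, sp$intensity, sep = ",")), csv)
  back2 <- read_raman(csv)
  expect_equal(nrow(back2), nrow(sp))
  expect_equal(back2$intensity, sp$intensity, tolerance = 1e-6)
})

test_that("reading sorts descending data and averages duplicate wavenumbers", {
  path <- withr::local_tempfile(fileext = ".txt")
  x <- seq(1800, 1000, by = -1)
  writeLines(paste(x, seq_along(x)), path)
  sp <- read_raman(path)
  expect_false(is.unsorted(sp$wavenumber, strictly = TRUE))
  expect_equal(sp$intensity[sp$wavenumber == 1800], 1)

  dup <- tibble::tibble(wavenumber = c(seq(1000, 1100), 1000),
                        intensity = c(rep(2, 101), 4))
  sp2 <- as_raman(dup)
  expect_equal(nrow(sp2), 101)
  expect_equal(sp2$intensity[sp2$wavenumber == 1000], 3)
})

test_that("degenerate spectrum files are rejected", {
  short <- withr::local_tempfile(fileext = ".txt")
  writeLines(paste(1:10, 1:10), short)
  expect_error(read_raman(short), "fewer than 50")
  empty <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# only", "# comments"), empty)
  expect_error(read_raman(empty), "No data")
  expect_error(read_raman(file.path(tempdir(), "nope.txt")), "not found")
  bad <- tibble::tibble(wavenumber = seq(1000, 1100), intensity = NA_real_)
  expect_error(as_raman(bad), "finite")
})

test_that("crop_window retains exactly the requested points", {
  grid <- seq(800, 2000, by = 1)
  sp <- as_raman(tibble::tibble(wavenumber = grid, intensity = 1 + grid / 1e4))
  expect_equal(nrow(crop_window(sp, 1000, 1800)), 801)
  expect_equal(crop_window(sp, 800, 2000), sp)
  expect_error(crop_window(sp, 3000, 3500), "no data")
  expect_error(crop_window(sp, 1800, 1000))
})

test_that("linear baselines cancel exactly and subtraction is idempotent", {
  grid <- seq(1000, 1800, by = 1)
  line <- as_raman(tibble::tibble(wavenumber = grid,
                                  intensity = 3 + 0.002 * grid))
  out <- subtract_baseline(line)
  expect_lt(max(abs(out$intensity)), 1e-9)

  flat <- as_raman(tibble::tibble(wavenumber = grid, intensity = 0))
  expect_lt(max(abs(subtract_baseline(flat)$intensity)), 1e-12)

  # Lorentzian on a line: peak height recovered with <= 1% distortion
  b <- band("D1", "lorentzian", 1350, 2, 60)
  sp <- sim_spectrum(b, baseline = c(5, 0.003))
  rec <- subtract_baseline(sp)
  expect_lt(abs(max(rec$intensity) / 2 - 1), 0.01)

  # idempotence on its own output
  again <- subtract_baseline(rec)
  expect_lt(max(abs(again$intensity - rec$intensity)),
            1e-9 * max(abs(rec$intensity)))

  expect_error(subtract_baseline(sp, anchors = list(c(100, 200), c(1700, 1800))),
               "anchor")
})

test_that("results tables have a fixed layout and round-trip", {
  recs <- chert_reference() |> classify_maturity()
  path <- withr::local_tempfile(fileext = ".csv")
  write_table(recs, path)
  lines <- readLines(path)
  expect_length(lines, 18)  # header + 17 samples
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(names(back)[1:4], c("sample_id", "age_ga", "facies", "is_archean"))
  expect_equal(back$r1, recs$r1)
  expect_equal(back$stage, as.character(recs$stage))

  one <- write_table(recs[1, ], withr::local_tempfile(fileext = ".csv"))
  back1 <- readr::read_csv(one, show_col_types = FALSE)
  expect_equal(nrow(back1), 1)
  expect_equal(back1$sample_id, recs$sample_id[1])

  expect_error(write_table(recs[0, ], path), "empty")
})

test_that("screening operations refuse uncharacterized lasers", {
  sp <- two_band_spectrum()
  sp$laser_nm <- 785
  expect_error(fit_bands(sp), "514.5")
  expect_error(graphical_params(sp), "514.5")
  expect_s3_class(graphical_params(sp, allow_any_laser = TRUE), "tbl_df")
})
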