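# Carbonization-continuum classification and the diagram.

test_that("classification reproduces the reference reading of the plane", {
  t <- screen_thresholds()
  cases <- tibble::tibble(
    r1 = c(0.60, 1.58, 2.6, 0.85, 0.5),
    fwhm_d1 = c(249, 61, 55, 180, 45),
    is_archean = c(FALSE, TRUE, TRUE, TRUE, TRUE))
  out <- classify_maturity(cases, t)
  expect_equal(as.character(out$stage),
               c("stage1", "stage2", "altered", "stage1", "stage1"))
  expect_equal(out$on_continuum, c(TRUE, TRUE, FALSE, TRUE, FALSE))
  expect_equal(out$graphitization_suspect, c(FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_equal(out$best_preserved_candidate, c(FALSE, FALSE, FALSE, TRUE, FALSE))
  # altered samples are never candidates; suspects are never on-continuum
  expect_false(any(out$stage == "altered" & out$best_preserved_candidate))
  expect_false(any(out$graphitization_suspect & out$on_continuum))
  # temperature annotation appears once R1 crosses 1
  expect_true(all(is.na(out$temperature_note[out$r1 < 1])))
  expect_true(all(!is.na(out$temperature_note[out$r1 >= 1])))
})

test_that("classification is total, exhaustive and monotone in R1", {
  grid <- tidyr::expand_grid(r1 = seq(0.05, 3.5, by = 0.07),
                             fwhm_d1 = seq(20, 350, by = 15))
  out <- classify_maturity(grid)
  expect_false(any(is.na(out$stage)))
  expect_setequal(levels(out$stage), c("stage1", "stage2", "altered"))
  # raising r1 at fixed fwhm never moves a sample to an earlier stage
  mono <- out |>
    dplyr::arrange(fwhm_d1, r1) |>
    dplyr::group_by(fwhm_d1) |>
    dplyr::summarise(ok = all(diff(as.integer(stage)) >= 0))
  expect_true(all(mono$ok))
  expect_error(classify_maturity(tibble::tibble(r1 = NA_real_, fwhm_d1 = 100)),
               "finite")
})

test_that("threshold objects are validated", {
  expect_s3_class(screen_thresholds(), "screen_thresholds")
  expect_error(screen_thresholds(candidate_r1_lo = 1.2, candidate_r1_hi = 1),
               "candidate")
  expect_error(screen_thresholds(carbonization_r1 = c(2, 1)), "non-empty")
})

test_that("the reference cohort separates as published", {
  ref <- chert_reference() |> classify_maturity()
  expect_equal(sum(ref$is_archean), 9)
  expect_true(all(ref$stage[ref$is_archean] == "stage2"))
  expect_equal(sum(ref$stage == "altered"), 0)
  expect_equal(sum(ref$graphitization_suspect), 0)

  rng <- cohort_ranges(ref)
  get <- function(arch, par, what) {
    rng[[what]][rng$group == arch & rng$parameter == par]
  }
  expect_equal(get(FALSE, "r1", "min"), 0.47)
  expect_equal(get(FALSE, "r1", "max"), 0.97)
  expect_equal(get(TRUE, "r1", "min"), 1.20)
  expect_equal(get(TRUE, "r1", "max"), 2.17)
  expect_equal(get(TRUE, "fwhm_d1", "min"), 59)
  expect_equal(get(TRUE, "fwhm_d1", "max"), 87)
  expect_equal(get(FALSE, "fwhm_d1", "min"), 162)
  expect_equal(get(FALSE, "fwhm_d1", "max"), 249)
})

test_that("cohort_ranges handles single-member groups and empty input", {
  one <- tibble::tibble(r1 = 1.2, fwhm_d1 = 80, fwhm_g = 60,
                        is_archean = TRUE)
  rng <- cohort_ranges(one)
  expect_true(all(rng$min == rng$max))
  expect_error(cohort_ranges(one[0, ]), "Empty")
})

test_that("the continuum diagram draws all groups and writes a file", {
  ref <- chert_reference() |> classify_maturity()
  p <- plot_continuum(ref)
  expect_s3_class(p, "ggplot")
  built <- ggplot2::ggplot_build(p)
  expect_equal(nrow(built$data[[1]]), 17)

  # a graphitization suspect introduces a third marker class
  extra <- classify_maturity(tibble::tibble(
    r1 = c(0.6, 1.5, 0.5), fwhm_d1 = c(240, 70, 45),
    is_archean = c(FALSE, TRUE, TRUE)))
  p2 <- plot_continuum(extra)
  grp <- ggplot2::ggplot_build(p2)$data[[1]]$shape
  expect_equal(length(unique(grp)), 3)
  expect_s3_class(autoplot(extra), "ggplot")

  path <- withr::local_tempfile(fileext = ".png")
  continuum_diagram(ref, path)
  expect_true(file.exists(path))
  expect_gt(file.size(path), 0)

  expect_error(plot_continuum(tibble::tibble(r1 = NA_real_, fwhm_d1 = NA_real_)),
               "finite")
})
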