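# Spectrum container, readers, windowing and baseline handling.
#
# A Raman spectrum is a long tibble with columns
#   sample_id, replicate_id, laser_nm, wavenumber (cm^-1), intensity (a.u.)
# sorted by ascending wavenumber within each (sample_id, replicate_id) group.
# Several spectra may be stacked in one tibble; all verbs operate group-wise.

SPECTRUM_COLS <- c("sample_id", "replicate_id", "laser_nm", "wavenumber", "intensity")

# minimum number of points a usable first-order spectrum must retain
MIN_SPECTRUM_POINTS <- 50

#' Coerce a two-column table to a Raman spectrum tibble
#'
#' Sorts by ascending wavenumber, averages duplicate wavenumbers and attaches
#' acquisition metadata columns. Input may already carry `sample_id`,
#' `replicate_id` and `laser_nm` columns, in which case they are kept.
#'
#' @param data Data frame with numeric columns `wavenumber` and `intensity`
#'   (additional metadata columns are preserved if present).
#' @param sample_id,replicate_id,laser_nm Metadata applied when the
#'   corresponding column is absent. `laser_nm` defaults to 514.5 (green Ar+
#'   excitation, the usual choice for CM maturity work).
#' @param min_points Minimum number of points required (default 50).
#' @return A tibble with columns `sample_id`, `replicate_id`, `laser_nm`,
#'   `wavenumber`, `intensity`.
#' @export
as_raman <- function(data, sample_id = "spectrum", replicate_id = 1L,
                     laser_nm = 514.5, min_points = MIN_SPECTRUM_POINTS) {
  stopifnot(is.data.frame(data))
  if (!all(c("wavenumber", "intensity") %in% names(data))) {
    abort("`data` must have `wavenumber` and `intensity` columns.")
  }
  out <- tibble::as_tibble(data)
  if (!"sample_id" %in% names(out)) out$sample_id <- sample_id
  if (!"replicate_id" %in% names(out)) out$replicate_id <- as.integer(replicate_id)
  if (!"laser_nm" %in% names(out)) out$laser_nm <- laser_nm
  if (!all(is.finite(out$wavenumber)) || !all(is.finite(out$intensity))) {
    abort("Non-finite wavenumber or intensity values.")
  }
  out <- out |>
    dplyr::group_by(.data$sample_id, .data$replicate_id, .data$laser_nm,
                    .data$wavenumber) |>
    dplyr::summarise(intensity = mean(.data$intensity), .groups = "drop") |>
    dplyr::arrange(.data$sample_id, .data$replicate_id, .data$wavenumber) |>
    dplyr::select(dplyr::all_of(SPECTRUM_COLS))
  n_pts <- dplyr::count(out, .data$sample_id, .data$replicate_id)$n
  if (any(n_pts < min_points)) {
    abort(sprintf("Spectrum has fewer than %d points.", min_points))
  }
  out
}

#' Read a two-column spectrum file
#'
#' Parses ASCII spectrum files: two numeric columns (wavenumber in cm^-1,
#' intensity in arbitrary units), comma-, tab- or whitespace-delimited.
#' Lines starting with `#` and non-numeric header lines are skipped.
#' Duplicate wavenumbers are averaged and rows are sorted ascending.
#'
#' @param path File path.
#' @param dialect Delimiter: `"auto"` (default, sniffed from the first data
#'   line), `"csv"`, `"tsv"` or `"whitespace"`.
#' @inheritParams as_raman
#' @return A Raman spectrum tibble (see [as_raman()]).
#' @export
read_raman <- function(path, dialect = c("auto", "csv", "tsv", "whitespace"),
                       sample_id = NULL, replicate_id = 1L, laser_nm = 514.5) {
  xy <- read_xy(path, dialect)
  as_raman(tibble::tibble(wavenumber = xy$x, intensity = xy$y),
           sample_id = sample_id %||% sub("\\.[^.]*$", "", basename(path)),
           replicate_id = replicate_id, laser_nm = laser_nm)
}

# shared two-column ASCII parser (also used for NMR spectra)
read_xy <- function(path, dialect = c("auto", "csv", "tsv", "whitespace")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) abort(sprintf("No data lines in %s", path))
  sep <- switch(dialect,
    csv = ",", tsv = "\t", whitespace = "[[:space:]]+",
    auto = {
      probe <- lines[[1]]
      if (grepl(",", probe, fixed = TRUE)) "," else
        if (grepl("\t", probe, fixed = TRUE)) "\t" else "[[:space:]]+"
    })
  fields <- strsplit(lines, sep)
  parse2 <- function(f) {
    f <- f[nzchar(f)]
    if (length(f) < 2) return(c(NA_real_, NA_real_))
    suppressWarnings(as.numeric(f[1:2]))
  }
  mat <- do.call(rbind, lapply(fields, parse2))
  keep <- stats::complete.cases(mat)
  if (!any(keep)) abort(sprintf("No numeric two-column rows in %s", path))
  list(x = mat[keep, 1], y = mat[keep, 2])
}

#' Restrict a spectrum to a wavenumber window
#'
#' The default window, 1000-1800 cm^-1, brackets the first-order CM region
#' from the D4 band (~1200 cm^-1) through D2 (~1620 cm^-1) with margin.
#'
#' @param spectra Spectrum tibble (possibly several stacked spectra).
#' @param lo,hi Window bounds in cm^-1 (`lo < hi`).
#' @return The rows with `lo <= wavenumber <= hi`.
#' @export
crop_window <- function(spectra, lo = 1000, hi = 1800) {
  stopifnot(is.data.frame(spectra), lo < hi)
  out <- dplyr::filter(spectra, .data$wavenumber >= lo, .data$wavenumber <= hi)
  if (nrow(out) == 0) {
    abort(sprintf("Window [%g, %g] cm^-1 contains no data points.", lo, hi))
  }
  out
}

#' Subtract a linear baseline anchored in two flat windows
#'
#' Fits a straight line through the median (wavenumber, intensity) point of
#' each anchor window and subtracts it, per spectrum. The defaults
#' ([1000, 1100] and [1700, 1800] cm^-1) flank the first-order band system
#' where kerogen spectra are close to featureless. Output intensities may be
#' slightly negative where noise dips below the line.
#'
#' @param spectra Spectrum tibble.
#' @param anchors List of two length-2 numeric vectors, the anchor windows.
#' @return The spectra with the per-spectrum baseline removed.
#' @export
subtract_baseline <- function(spectra,
                              anchors = list(c(1000, 1100), c(1700, 1800))) {
  stopifnot(is.data.frame(spectra), length(anchors) == 2)
  one <- function(df) {
    pts <- lapply(anchors, function(a) {
      in_a <- df$wavenumber >= a[1] & df$wavenumber <= a[2]
      if (!any(in_a)) {
        abort(sprintf("Baseline anchor window [%g, %g] is empty.", a[1], a[2]))
      }
      c(x = stats::median(df$wavenumber[in_a]),
        y = stats::median(df$intensity[in_a]))
    })
    slope <- (pts[[2]]["y"] - pts[[1]]["y"]) / (pts[[2]]["x"] - pts[[1]]["x"])
    df$intensity <- df$intensity -
      (pts[[1]]["y"] + slope * (df$wavenumber - pts[[1]]["x"]))
    df
  }
  spectra |>
    dplyr::group_by(.data$sample_id, .data$replicate_id) |>
    dplyr::group_modify(~ one(.x)) |>
    dplyr::ungroup() |>
    dplyr::select(dplyr::all_of(intersect(SPECTRUM_COLS, names(spectra))),
                  dplyr::everything())
}

#' Write a spectrum to a two-column ASCII file
#'
#' @param spectra A single spectrum tibble.
#' @param path Output path.
#' @param sep Field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_raman <- function(spectra, path, sep = "\t") {
  stopifnot(is.data.frame(spectra), nrow(spectra) > 0)
  header <- sprintf("# sample_id=%s laser_nm=%g replicate_id=%d",
                    spectra$sample_id[1], spectra$laser_nm[1],
                    spectra$replicate_id[1])
  body <- paste(format(spectra$wavenumber, digits = 10, trim = TRUE),
                format(spectra$intensity, digits = 10, trim = TRUE), sep = sep)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write a joined results table to CSV
#'
#' One row per sample, with a fixed, documented column order mirroring the
#' layout of published chert compilations: identification and metadata first,
#' then elemental / NMR / HRTEM indices, then Raman parameters, then
#' screening results. Missing columns are filled with `NA`; extra columns are
#' appended after the canonical ones so nothing is dropped.
#'
#' @param records Non-empty data frame of per-sample results (e.g. the output
#'   of [classify_maturity()] joined to sample metadata).
#' @param path Output CSV path.
#' @return `path`, invisibly. The file round-trips through
#'   [readr::read_csv()].
#' @export
write_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0) abort("`records` is empty; nothing to write.")
  canonical <- c(
    "sample_id", "age_ga", "facies", "is_archean",
    "h_wt", "c_wt", "hc_atomic", "ash_pct", "aromaticity", "la_angstrom",
    "fwhm_g", "fwhm_g_sd", "fwhm_d1", "fwhm_d1_sd", "r1", "r1_sd", "method",
    "stage", "on_continuum", "graphitization_suspect",
    "best_preserved_candidate", "temperature_note")
  out <- tibble::as_tibble(records)
  missing <- setdiff(canonical, names(out))
  for (m in missing) out[[m]] <- NA
  out <- dplyr::select(out, dplyr::all_of(canonical), dplyr::everything())
  readr::write_csv(out, path, na = "")
  invisible(path)
}

# Screening comparability is established only for green excitation; refuse
# other lasers unless the caller overrides.
check_laser <- function(laser_nm, allow_any_laser = FALSE,
                        allowed = c(514.5, 532)) {
  if (allow_any_laser) return(invisible(TRUE))
  bad <- setdiff(unique(laser_nm), allowed)
  if (length(bad) > 0) {
    abort(sprintf(paste(
      "Spectra acquired at %s nm: R1/FWHM-D1 comparability is established",
      "only for 514.5 and 532 nm excitation. Set `allow_any_laser = TRUE`",
      "to override."), paste(bad, collapse = ", ")))
  }
  invisible(TRUE)
}

# split a stacked spectra tibble into a list of single spectra
split_spectra <- function(spectra) {
  key <- paste(spectra$sample_id, spectra$replicate_id, sep = "\r")
  split(spectra, factor(key, levels = unique(key)))
}
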