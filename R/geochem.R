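# Companion maturity indices: atomic H/C from elemental wt%, and 13C NMR
# aromaticity by split integration at 90 ppm.

#' Atomic H/C ratio from elemental weight percentages
#'
#' `(h_wt / mass_H) / (c_wt / mass_C)`. H/C decreases with thermal
#' maturation of kerogen; values near 0.3 indicate advanced carbonization.
#' Vectorised over samples.
#'
#' @param h_wt Hydrogen content, % mass (0-100).
#' @param c_wt Carbon content, % mass (0 < c_wt <= 100).
#' @param masses Named numeric vector of atomic masses; the default is the
#'   IUPAC pair `c(H = 1.008, C = 12.011)`. `atomic_masses("integer")` gives
#'   the rounded 1/12 convention some compilations use.
#' @return Dimensionless atomic H/C, same length as the inputs.
#' @export
hc_atomic <- function(h_wt, c_wt, masses = atomic_masses("iupac")) {
  stopifnot(is.numeric(h_wt), is.numeric(c_wt),
            all(c("H", "C") %in% names(masses)))
  if (any(!is.finite(c_wt)) || any(c_wt <= 0)) {
    abort("Carbon content must be positive.")
  }
  if (any(h_wt < 0 | h_wt > 100) || any(c_wt > 100)) {
    abort("Weight percentages must lie in [0, 100].")
  }
  (h_wt / masses[["H"]]) / (c_wt / masses[["C"]])
}

#' @rdname hc_atomic
#' @param convention `"iupac"` (1.008/12.011) or `"integer"` (1/12).
#' @export
atomic_masses <- function(convention = c("iupac", "integer")) {
  convention <- match.arg(convention)
  switch(convention,
         iupac = c(H = 1.008, C = 12.011),
         integer = c(H = 1, C = 12))
}

#' Read a two-column NMR spectrum file
#'
#' Same ASCII dialects as [read_raman()]; columns are chemical shift (ppm)
#' and intensity.
#'
#' @inheritParams read_raman
#' @return Tibble with columns `sample_id`, `shift`, `intensity`, sorted by
#'   ascending shift (duplicate shifts averaged).
#' @export
read_nmr <- function(path, dialect = c("auto", "csv", "tsv", "whitespace"),
                     sample_id = NULL) {
  xy <- read_xy(path, dialect)
  tibble::tibble(sample_id = sample_id %||% sub("\\.[^.]*$", "", basename(path)),
                 shift = xy$x, intensity = xy$y) |>
    dplyr::group_by(.data$sample_id, .data$shift) |>
    dplyr::summarise(intensity = mean(.data$intensity), .groups = "drop") |>
    dplyr::arrange(.data$shift)
}

#' NMR aromaticity by 90 ppm split integration
#'
#' Percentage of carbon in aromatic environments:
#' `100 * A_aromatic / (A_aromatic + A_aliphatic)` with trapezoidal areas
#' over the aromatic (default 90-240 ppm) and aliphatic (default -10-90 ppm)
#' windows of a baseline-corrected 13C CP/MAS spectrum. Window edges are
#' interpolated onto the shift grid so the split is exact at 90 ppm.
#'
#' Spinning side bands are not excluded automatically; pass their ppm
#' windows via `exclude` to bridge them by linear interpolation.
#'
#' @param nmr Tibble with `shift` (ppm, strictly increasing) and `intensity`
#'   columns.
#' @param split Split point in ppm (the aromatic/aliphatic limit).
#' @param aromatic,aliphatic Integration windows in ppm.
#' @param exclude Optional list of length-2 ppm windows to bridge (e.g.
#'   spinning side bands).
#' @return Aromaticity in percent, clipped to [0, 100].
#' @export
nmr_aromaticity <- function(nmr, split = 90,
                            aromatic = c(split, 240),
                            aliphatic = c(-10, split),
                            exclude = NULL) {
  stopifnot(is.data.frame(nmr),
            all(c("shift", "intensity") %in% names(nmr)))
  x <- nmr$shift
  y <- nmr$intensity
  if (is.unsorted(x, strictly = TRUE)) {
    o <- order(x)
    x <- x[o]
    y <- y[o]
  }
  for (ex in exclude) {
    inside <- x > ex[1] & x < ex[2]
    if (any(inside)) {
      y[inside] <- stats::approx(x[!inside], y[!inside], xout = x[inside],
                                 rule = 2)$y
    }
  }
  a_arom <- window_area(x, y, aromatic)
  a_alip <- window_area(x, y, aliphatic)
  if (a_arom + a_alip == 0) abort("Both integration windows have zero area.")
  min(100, max(0, 100 * a_arom / (a_arom + a_alip)))
}

# trapezoid area over a ppm window, with interpolated edge points
window_area <- function(x, y, win) {
  lo <- max(win[1], min(x))
  hi <- min(win[2], max(x))
  if (lo >= hi) abort(sprintf("Window [%g, %g] does not overlap the data.",
                              win[1], win[2]))
  inside <- x > lo & x < hi
  xs <- c(lo, x[inside], hi)
  ys <- c(stats::approx(x, y, xout = lo)$y, y[inside],
          stats::approx(x, y, xout = hi)$y)
  pracma::trapz(xs, ys)
}
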