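# Band shapes and the five-band model of the first-order CM spectrum.
#
# The decomposition follows the usual G + D1-D4 scheme for disordered
# carbonaceous matter: G (graphitic E2g) near 1580 cm^-1, D1 (defect) near
# 1350, D2 shoulder near 1620, D3 (amorphous) near 1500, D4 near 1200.
# G, D1, D2 and D4 are Lorentzian, D3 Gaussian; shapes are configurable.

BAND_NAMES <- c("G", "D1", "D2", "D3", "D4")

DEFAULT_CENTERS <- c(G = 1580, D1 = 1350, D2 = 1620, D3 = 1500, D4 = 1200)
DEFAULT_SHAPES  <- c(G = "lorentzian", D1 = "lorentzian", D2 = "lorentzian",
                     D3 = "gaussian",  D4 = "lorentzian")
SEED_FWHM       <- c(G = 70, D1 = 150, D2 = 50, D3 = 150, D4 = 100)
FWHM_BOUNDS     <- c(5, 400)

# physically sensible per-band width windows for disordered CM (cm^-1);
# the default fit bounds, all inside the (5, 400) envelope
FWHM_LOWER <- c(G = 40, D1 = 40, D2 = 20, D3 = 60, D4 = 40)
FWHM_UPPER <- c(G = 120, D1 = 380, D2 = 90, D3 = 250, D4 = 200)

# alternative width-seed sets spanning the maturity series, used as extra
# deterministic optimizer starts
START_FWHM <- list(
  canonical = SEED_FWHM,
  immature = c(G = 100, D1 = 280, D2 = 60, D3 = 160, D4 = 120),
  mature = c(G = 55, D1 = 60, D2 = 45, D3 = 90, D4 = 70))

#' Construct a band table
#'
#' @param band Character vector of band names among `"G"`, `"D1"`..`"D4"`.
#' @param shape `"lorentzian"` or `"gaussian"`, recycled.
#' @param center Band centre, cm^-1.
#' @param height Peak height, arbitrary units, `>= 0`.
#' @param fwhm Full width at half maximum, cm^-1, in (5, 400).
#' @return A tibble with one row per band.
#' @export
band <- function(band, shape, center, height, fwhm) {
  out <- tibble::tibble(band = band, shape = shape, center = center,
                        height = height, fwhm = fwhm)
  validate_bands(out)
  out
}

validate_bands <- function(bands, require_all = FALSE) {
  stopifnot(is.data.frame(bands))
  need <- c("band", "shape", "center", "height", "fwhm")
  if (!all(need %in% names(bands))) {
    abort("Band table needs columns band, shape, center, height, fwhm.")
  }
  if (!all(bands$band %in% BAND_NAMES)) {
    abort(sprintf("Unknown band name(s): %s",
                  paste(setdiff(bands$band, BAND_NAMES), collapse = ", ")))
  }
  if (!all(bands$shape %in% c("lorentzian", "gaussian"))) {
    abort("Band shape must be 'lorentzian' or 'gaussian'.")
  }
  if (anyDuplicated(bands$band)) abort("Duplicate band names.")
  if (require_all && !setequal(bands$band, BAND_NAMES)) {
    abort("Expected exactly one row per band G, D1, D2, D3, D4.")
  }
  if (any(bands$height < 0)) abort("Band heights must be >= 0.")
  if (any(bands$fwhm <= 0)) abort("Band FWHM must be > 0.")
  invisible(bands)
}

#' Evaluate a single band profile
#'
#' Lorentzian: `h / (1 + ((x - c) / (w/2))^2)`; Gaussian:
#' `h * exp(-4 log(2) (x - c)^2 / w^2)`. Both equal `h` at the centre and
#' `h/2` at `c +/- w/2`.
#'
#' @param b One-row band table (or list with `shape`, `center`, `height`,
#'   `fwhm`).
#' @param x Wavenumbers, cm^-1.
#' @return Intensity at `x`.
#' @export
evaluate_band <- function(b, x) {
  band_profile(b$shape[[1]], b$center[[1]], b$height[[1]], b$fwhm[[1]], x)
}

band_profile <- function(shape, center, height, fwhm, x) {
  switch(shape,
    lorentzian = height / (1 + ((x - center) / (fwhm / 2))^2),
    gaussian = height * exp(-4 * log(2) * (x - center)^2 / fwhm^2),
    abort(sprintf("Unknown band shape '%s'.", shape)))
}

#' Evaluate the summed multi-band model
#'
#' @param bands Band table.
#' @param x Wavenumbers, cm^-1.
#' @return Summed intensity of all bands at `x`.
#' @export
evaluate_bands <- function(bands, x) {
  y <- numeric(length(x))
  for (i in seq_len(nrow(bands))) {
    y <- y + band_profile(bands$shape[i], bands$center[i], bands$height[i],
                          bands$fwhm[i], x)
  }
  y
}

#' Seed a five-band initial guess from a spectrum
#'
#' Centres start at the canonical positions (G 1580, D1 1350, D2 1620,
#' D3 1500, D4 1200 cm^-1). G and D1 heights are read from the spectrum
#' maxima in the G (1560-1640) and D (1300-1400) windows; D3 and D4 start at
#' 10% of the D1 seed and D2 at 10% of the G seed. Seed widths are
#' (G 70, D1 150, D2 50, D3 150, D4 100) cm^-1.
#'
#' Ties in the window maxima break deterministically: the lowest wavenumber
#' wins in the D window, the highest in the G window.
#'
#' @param spectrum A single baseline-corrected, cropped spectrum tibble.
#' @param shapes Named character vector assigning `"lorentzian"`/`"gaussian"`
#'   per band.
#' @return A five-row band table.
#' @export
initial_guess <- function(spectrum, shapes = DEFAULT_SHAPES) {
  w <- spectrum$wavenumber
  y <- spectrum$intensity
  rng <- range(y)
  if (!all(is.finite(rng)) || diff(rng) <= 1e-12 * max(abs(rng), 1)) {
    abort("Flat spectrum: no discernible D or G band structure.")
  }
  hD <- window_peak(w, y, 1300, 1400, prefer = "low")
  hG <- window_peak(w, y, 1560, 1640, prefer = "high")
  if (!is.finite(hD$height) || !is.finite(hG$height) ||
      (hD$height <= 0 && hG$height <= 0)) {
    abort("No discernible D or G maximum in the fit window.")
  }
  band(
    band = BAND_NAMES,
    shape = unname(shapes[BAND_NAMES]),
    center = unname(DEFAULT_CENTERS[BAND_NAMES]),
    height = pmax(c(G = hG$height, D1 = hD$height, D2 = 0.1 * hG$height,
                    D3 = 0.1 * hD$height, D4 = 0.1 * hD$height), 0),
    fwhm = unname(SEED_FWHM[BAND_NAMES]))
}

# D-band peak on a (smoothed) curve: interior local maximum in
# [1300, 1400] nearest 1350; when the D band is only a shoulder (no interior
# maximum) the reading falls back to 1350 itself
find_d_peak <- function(w, y, lo = 1300, hi = 1400, target = 1350) {
  didx <- which(w >= lo & w <= hi)
  if (length(didx) < 3) {
    abort(sprintf("Spectrum has no points in the D window [%g, %g].", lo, hi))
  }
  interior <- didx[didx > 1 & didx < length(w)]
  is_max <- y[interior] > y[interior - 1] & y[interior] >= y[interior + 1]
  fallback <- !any(is_max)
  idx <- if (fallback) {
    didx[which.min(abs(w[didx] - target))]
  } else {
    cand <- interior[is_max]
    cand[which.min(abs(w[cand] - target))]
  }
  list(index = idx, height = y[idx], wavenumber = w[idx],
       fallback = fallback)
}

# Savitzky-Golay smoothing guard: window must be odd and fit the data
smooth_curve <- function(y, window = 11, order = 3) {
  if (window <= 1) return(y)
  if (window %% 2 == 0) abort("Smoothing window must be odd.")
  if (window > length(y)) abort("Smoothing window longer than the spectrum.")
  signal::sgolayfilt(y, p = order, n = window)
}

# highest point inside [lo, hi]; deterministic tie-break by `prefer` side
window_peak <- function(w, y, lo, hi, prefer = c("low", "high")) {
  prefer <- match.arg(prefer)
  in_w <- which(w >= lo & w <= hi)
  if (length(in_w) == 0) {
    abort(sprintf("Spectrum has no points in [%g, %g] cm^-1.", lo, hi))
  }
  yy <- y[in_w]
  hits <- in_w[yy == max(yy)]
  idx <- if (prefer == "low") hits[1] else hits[length(hits)]
  list(height = y[idx], wavenumber = w[idx], index = idx)
}
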