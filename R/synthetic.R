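# Seeded synthetic-data generators: first-order CM Raman spectra along the
# carbonization trend, 13C NMR spectra with a prescribed aromatic fraction,
# and HRTEM-like fringe images with known layouts. All generators are pure
# functions of (parameters, seed).

with_seed_opt <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

#' Synthesize a spectrum from known bands
#'
#' Sum of the evaluated bands plus an optional linear baseline and seeded
#' additive Gaussian noise with standard deviation `noise_sd` times the D1
#' height. The generating truth is attached as the `"truth"` attribute.
#'
#' @param bands Five-row band table (see [band()]).
#' @param grid Wavenumber grid, cm^-1. Default `seq(1000, 1800, by = 1)`.
#' @param noise_sd Noise standard deviation as a fraction of the D1 height.
#' @param baseline Length-2 numeric `c(intercept, slope)` of a linear
#'   baseline added to the spectrum.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param sample_id,replicate_id Metadata for the generated spectrum.
#' @return A spectrum tibble with attribute `truth` (list with `bands` and
#'   `params`).
#' @export
sim_spectrum <- function(bands, grid = seq(1000, 1800, by = 1),
                         noise_sd = 0, baseline = c(0, 0), seed = NULL,
                         sample_id = "synthetic", replicate_id = 1L) {
  validate_bands(bands)
  stopifnot(noise_sd >= 0, length(baseline) == 2)
  clean <- evaluate_bands(bands, grid) + baseline[1] + baseline[2] * grid
  hD1 <- if ("D1" %in% bands$band) bands$height[bands$band == "D1"] else
    max(bands$height)
  noise <- if (noise_sd > 0) {
    with_seed_opt(seed, stats::rnorm(length(grid), sd = noise_sd * hD1))
  } else {
    numeric(length(grid))
  }
  out <- tibble::tibble(
    sample_id = sample_id, replicate_id = as.integer(replicate_id),
    laser_nm = 514.5, wavenumber = grid, intensity = clean + noise)
  attr(out, "truth") <- list(bands = bands, params = true_params(bands))
  out
}

# screening parameters implied by a band table
true_params <- function(bands) {
  tibble::tibble(
    r1 = bands$height[bands$band == "D1"] / bands$height[bands$band == "G"],
    fwhm_d1 = bands$fwhm[bands$band == "D1"],
    fwhm_g = bands$fwhm[bands$band == "G"])
}

# linear interpolation between trend endpoints
lerp <- function(a, b, m) a + (b - a) * m

#' Band parameters at a maturity index
#'
#' Linear interpolation along the carbonization trend: as `m` runs 0 to 1,
#' R1 rises 0.4 to 2.2 while FWHM-D1 falls 280 to 55 cm^-1 and FWHM-G
#' 100 to 55 cm^-1 (spanning the ranges observed across Phanerozoic to
#' Archean kerogens); D2/D3/D4 heights fall from 25% to 5% of the G height
#' (fixed at 1) and their widths narrow with maturity.
#'
#' @param m Maturity index in [0, 1].
#' @return Five-row band table.
#' @export
maturity_bands <- function(m) {
  stopifnot(is.numeric(m), length(m) == 1, m >= 0, m <= 1)
  band(
    band = BAND_NAMES,
    shape = unname(DEFAULT_SHAPES[BAND_NAMES]),
    center = unname(DEFAULT_CENTERS[BAND_NAMES]),
    height = c(G = 1, D1 = lerp(0.4, 2.2, m), D2 = lerp(0.25, 0.05, m),
               D3 = lerp(0.25, 0.05, m), D4 = lerp(0.25, 0.05, m)),
    fwhm = c(G = lerp(100, 55, m), D1 = lerp(280, 55, m),
             D2 = lerp(60, 40, m), D3 = lerp(160, 90, m),
             D4 = lerp(120, 70, m)))
}

#' Generate a synthetic maturity series
#'
#' Draws `n` maturity indices uniformly on [0, 1] (sorted ascending) and
#' synthesizes one spectrum per index from [maturity_bands()] with seeded
#' noise. The generated trend occupies the carbonization box of
#' [screen_thresholds()] for every `m`.
#'
#' @param n Number of spectra (`>= 2`).
#' @param seed Integer seed.
#' @param noise_sd Noise sd as a fraction of D1 height (default 0.02).
#' @param grid Wavenumber grid.
#' @return Nested tibble, one row per spectrum: `sample_id`, `m`, `true_r1`,
#'   `true_fwhm_d1`, `true_fwhm_g`, list-columns `true_bands` and
#'   `spectrum`. `tidyr::unnest(x, spectrum)` gives the long spectra table.
#' @export
sim_maturity_series <- function(n, seed = NULL, noise_sd = 0.02,
                                grid = seq(1000, 1800, by = 1)) {
  if (!is.numeric(n) || n < 2) abort("Need n >= 2 spectra.")
  with_seed_opt(seed, {
    m <- sort(stats::runif(n))
    purrr::map_dfr(seq_len(n), function(i) {
      bands <- maturity_bands(m[i])
      sp <- sim_spectrum(bands, grid = grid, noise_sd = noise_sd,
                         sample_id = sprintf("sim%03d", i))
      tp <- true_params(bands)
      tibble::tibble(
        sample_id = sprintf("sim%03d", i), m = m[i],
        true_r1 = tp$r1, true_fwhm_d1 = tp$fwhm_d1, true_fwhm_g = tp$fwhm_g,
        true_bands = list(bands), spectrum = list(sp))
    })
  })
}

#' Synthesize a 13C NMR spectrum with a known aromatic fraction
#'
#' Two Gaussian envelopes — aliphatic centred at 30 ppm, aromatic at
#' 130 ppm, both 30 ppm FWHM — with areas in the requested ratio, plus
#' seeded Gaussian noise.
#'
#' @param aromatic_fraction Fraction of total area in the aromatic envelope,
#'   in [0, 1].
#' @param seed Integer seed.
#' @param noise_sd Noise sd as a fraction of the taller envelope height.
#' @param grid Chemical-shift grid, ppm.
#' @param sample_id Identifier.
#' @return Tibble with columns `sample_id`, `shift`, `intensity`.
#' @export
sim_nmr <- function(aromatic_fraction, seed = NULL, noise_sd = 0.005,
                    grid = seq(-20, 240, by = 0.5), sample_id = "synthetic") {
  if (!is.numeric(aromatic_fraction) || aromatic_fraction < 0 ||
      aromatic_fraction > 1) {
    abort("`aromatic_fraction` must lie in [0, 1].")
  }
  fwhm <- 30
  # Gaussian area = h * fwhm * sqrt(pi / (4 log 2))
  area_to_h <- function(area) area / (fwhm * sqrt(pi / (4 * log(2))))
  h_arom <- area_to_h(aromatic_fraction)
  h_alip <- area_to_h(1 - aromatic_fraction)
  clean <- band_profile("gaussian", 130, h_arom, fwhm, grid) +
    band_profile("gaussian", 30, h_alip, fwhm, grid)
  noise <- if (noise_sd > 0) {
    with_seed_opt(seed, stats::rnorm(length(grid),
                                     sd = noise_sd * max(h_arom, h_alip)))
  } else {
    numeric(length(grid))
  }
  tibble::tibble(sample_id = sample_id, shift = grid,
                 intensity = clean + noise)
}

#' Synthesize an HRTEM-like fringe image
#'
#' Dark, slightly curved strokes on a bright noisy background, emulating
#' lattice fringes of polyaromatic layers. Fringes are drawn locally
#' sub-parallel (orientations scatter around a random preferred direction),
#' as in real HRTEM images of carbonized CM. The generating layout is
#' attached as the `"truth"` attribute: a tibble of per-fringe lengths (Å,
#' after clipping at the canvas edge) and polylines.
#'
#' @param n_fringes Number of strokes.
#' @param mean_len Mean fringe length in Angstrom.
#' @param length_dist `"exponential"` (default) or `"fixed"`.
#' @param orientation_sd Orientation scatter around the preferred direction,
#'   radians.
#' @param curvature Maximum absolute curvature, radians per pixel of arc.
#' @param scale Angstrom per pixel.
#' @param noise_sd Background noise sd (grayscale units).
#' @param dim Canvas size in pixels, `c(rows, cols)`.
#' @param seed Integer seed.
#' @param sample_id Identifier.
#' @return A [fringe_image()] with attribute `truth`.
#' @export
sim_fringe_image <- function(n_fringes, mean_len = 7,
                             length_dist = c("exponential", "fixed"),
                             orientation_sd = 0.2, curvature = 0.02,
                             scale = 0.2, noise_sd = 0.05,
                             dim = c(256, 256), seed = NULL,
                             sample_id = "synthetic") {
  length_dist <- match.arg(length_dist)
  stopifnot(n_fringes >= 1, mean_len > 0, scale > 0)
  if (mean_len / scale > sqrt(sum(dim^2))) {
    abort("Fringes cannot fit the canvas: mean length exceeds the diagonal.")
  }
  with_seed_opt(seed, {
    px <- matrix(0.9, dim[1], dim[2]) +
      matrix(stats::rnorm(prod(dim), sd = noise_sd), dim[1], dim[2])
    theta0 <- stats::runif(1, 0, pi)
    lens_px <- switch(length_dist,
      exponential = stats::rexp(n_fringes, rate = scale / mean_len),
      fixed = rep(mean_len / scale, n_fringes))
    lens_px <- pmax(lens_px, 1)
    truth <- vector("list", n_fringes)
    for (i in seq_len(n_fringes)) {
      r0 <- stats::runif(1, 2, dim[1] - 1)
      c0 <- stats::runif(1, 2, dim[2] - 1)
      th <- theta0 + stats::rnorm(1, sd = orientation_sd)
      kap <- stats::runif(1, -curvature, curvature)
      step <- 0.5
      n_step <- max(2, ceiling(lens_px[i] / step))
      pts <- matrix(NA_real_, n_step + 1, 2)
      pts[1, ] <- c(r0, c0)
      ang <- th
      for (s in seq_len(n_step)) {
        ang <- ang + kap * step
        cand <- pts[s, ] + step * c(sin(ang), cos(ang))
        if (cand[1] < 2 || cand[1] > dim[1] - 1 ||
            cand[2] < 2 || cand[2] > dim[2] - 1) break
        pts[s + 1, ] <- cand
      }
      pts <- pts[stats::complete.cases(pts), , drop = FALSE]
      if (nrow(pts) < 2) {
        truth[[i]] <- NULL
        next
      }
      # arc length of the drawn (possibly clipped) polyline
      seg <- sqrt(rowSums((pts[-1, , drop = FALSE] -
                             pts[-nrow(pts), , drop = FALSE])^2))
      truth[[i]] <- tibble::tibble(fringe = i,
                                   length_px = sum(seg),
                                   length_A = sum(seg) * scale,
                                   polyline = list(pts))
      # splat dark strokes onto the 4 nearest pixels of each sample point
      for (s in seq_len(nrow(pts))) {
        rr <- pts[s, 1]
        cc <- pts[s, 2]
        for (dr in 0:1) for (dc in 0:1) {
          ri <- floor(rr) + dr
          ci <- floor(cc) + dc
          wgt <- (1 - abs(rr - ri)) * (1 - abs(cc - ci))
          px[ri, ci] <- px[ri, ci] - 0.8 * wgt
        }
      }
    }
    px <- pmin(pmax(px, 0), 1)
    img <- fringe_image(px, scale = scale, sample_id = sample_id)
    attr(img, "truth") <- dplyr::bind_rows(truth)
    img
  })
}
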