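# Constrained five-band decomposition via bounded nonlinear least squares.

#' Fit the five-band model to spectra
#'
#' Decomposes each baseline-corrected spectrum into G + D1 + D2 + D3 + D4 by
#' bounded Levenberg-Marquardt least squares ([minpack.lm::nls.lm()]).
#' Centres are confined to +/- `center_slack` of their canonical positions
#' and widths to per-band windows (`fwhm_lower`/`fwhm_upper`); heights are
#' `>= 0`. Tight centre bounds and per-band width windows keep the heavily
#' overlapped G/D2/D3 subsystem identifiable under noise; widening them
#' towards the full (5, 400) cm^-1 envelope is possible but degrades
#' parameter recovery. The optimizer is started from the canonical seed of
#' [initial_guess()] and from immature-type and mature-type width seeds; the
#' lowest-residual solution is kept, so the result does not depend on where
#' along the carbonization trend a spectrum lies.
#'
#' With `pin_d1 = TRUE` (the default, mirroring the usual protocol of fixing
#' the D1 height to that of the observed defect band) the D1 height is held
#' equal to the smoothed-curve height at the detected D peak and only the
#' remaining parameters vary; `pin_d1 = FALSE` frees all fifteen
#' parameters. The pin equates the observed D maximum with D1 alone, which
#' is accurate when the D3/D4 contribution under the D peak is small; the
#' free fit is the better reference when it is not (very immature CM).
#'
#' @param spectra Spectrum tibble (one or many stacked spectra); should be
#'   baseline-corrected. Cropped internally to `window`.
#' @param window Fit window in cm^-1 (default `c(1000, 1800)`).
#' @param pin_d1 Pin the D1 height to the observed D-peak height?
#' @param shapes Named per-band shape assignment (see [initial_guess()]).
#' @param center_slack Allowed centre excursion from defaults, cm^-1
#'   (default 10).
#' @param fwhm_lower,fwhm_upper Named per-band FWHM bounds, cm^-1.
#' @param max_eval Maximum residual evaluations per start before the fit is
#'   returned with `converged = FALSE`.
#' @param ftol Relative cost-reduction tolerance declaring convergence.
#' @param multistart Use the additional maturity-spanning width seeds
#'   (default `TRUE`).
#' @param allow_any_laser Permit excitation wavelengths other than
#'   514.5/532 nm.
#' @return A tibble with one row per spectrum: `sample_id`, `replicate_id`,
#'   `r1`, `fwhm_d1`, `fwhm_g`, `residual_rms`, `converged`, `n_eval`,
#'   `d1_pinned`, `method`, and a `fit` list-column of `"five_band_fit"`
#'   objects (see [tidy.five_band_fit()], [glance.five_band_fit()]).
#' @export
fit_bands <- function(spectra, window = c(1000, 1800), pin_d1 = TRUE,
                      shapes = DEFAULT_SHAPES, center_slack = 10,
                      fwhm_lower = FWHM_LOWER, fwhm_upper = FWHM_UPPER,
                      max_eval = 5000, ftol = 1e-10, multistart = TRUE,
                      allow_any_laser = FALSE) {
  stopifnot(is.data.frame(spectra))
  check_laser(spectra$laser_nm, allow_any_laser)
  fits <- lapply(split_spectra(spectra), fit_five_bands_one,
                 window = window, pin_d1 = pin_d1, shapes = shapes,
                 center_slack = center_slack, fwhm_lower = fwhm_lower,
                 fwhm_upper = fwhm_upper, max_eval = max_eval,
                 ftol = ftol, multistart = multistart)
  out <- purrr::map_dfr(fits, glance)
  out$fit <- unname(fits)
  out
}

fit_five_bands_one <- function(spectrum, window = c(1000, 1800),
                               pin_d1 = TRUE, shapes = DEFAULT_SHAPES,
                               center_slack = 10,
                               fwhm_lower = FWHM_LOWER,
                               fwhm_upper = FWHM_UPPER,
                               max_eval = 5000, ftol = 1e-10,
                               multistart = TRUE) {
  spectrum <- crop_window(spectrum, window[1], window[2])
  if (nrow(spectrum) < MIN_SPECTRUM_POINTS) {
    abort(sprintf("Fewer than %d points in the fit window.",
                  MIN_SPECTRUM_POINTS))
  }
  stopifnot(all(BAND_NAMES %in% names(fwhm_lower)),
            all(BAND_NAMES %in% names(fwhm_upper)))
  w <- spectrum$wavenumber
  y <- spectrum$intensity
  guess <- initial_guess(spectrum, shapes = shapes)
  guess <- guess[match(BAND_NAMES, guess$band), ]

  d1_height <- if (pin_d1) {
    ys <- smooth_curve(y, window = min(11, 2 * (length(y) %/% 2) - 1))
    max(0, find_d_peak(w, ys)$height)
  } else {
    NA_real_
  }

  # parameter order: centers (G, D1..D4), heights, fwhms; D1 height dropped
  # from the free vector when pinned
  centers0 <- unname(DEFAULT_CENTERS[BAND_NAMES])
  h_upper <- max(3 * max(y), 1e-6)
  lower <- c(centers0 - center_slack, rep(0, 5),
             unname(fwhm_lower[BAND_NAMES]))
  upper <- c(centers0 + center_slack, rep(h_upper, 5),
             unname(fwhm_upper[BAND_NAMES]))
  free <- rep(TRUE, 15)
  if (pin_d1) free[5 + 2] <- FALSE  # D1 height slot

  shape_vec <- unname(shapes[BAND_NAMES])
  is_gauss <- shape_vec == "gaussian"
  model_from_full <- function(full) {
    if (pin_d1) full[7] <- d1_height
    out <- numeric(length(w))
    for (i in 1:5) {
      out <- out + if (is_gauss[i]) {
        full[5 + i] * exp(-4 * log(2) * (w - full[i])^2 / full[10 + i]^2)
      } else {
        full[5 + i] / (1 + ((w - full[i]) / (full[10 + i] / 2))^2)
      }
    }
    out
  }
  bands_from_full <- function(full) {
    if (pin_d1) full[7] <- d1_height
    tibble::tibble(
      band = BAND_NAMES,
      shape = shape_vec,
      center = full[1:5], height = full[6:10], fwhm = full[11:15])
  }
  make_full <- function(p, template) {
    full <- template
    full[free] <- p
    full
  }

  ctl <- minpack.lm::nls.lm.control(ftol = ftol, ptol = 1e-10,
                                    maxfev = max_eval,
                                    maxiter = min(1024, max_eval))
  starts <- list(unname(SEED_FWHM[BAND_NAMES]))
  if (multistart) {
    starts <- c(starts, lapply(START_FWHM[-1],
                               function(s) unname(s[BAND_NAMES])))
  }
  init_rms <- NA_real_
  best <- NULL
  for (si in seq_along(starts)) {
    full0 <- c(guess$center, guess$height, starts[[si]])
    full0 <- pmin(pmax(full0, lower), upper)
    resid_fn <- function(p) model_from_full(make_full(p, full0)) - y
    if (si == 1) init_rms <- sqrt(mean(resid_fn(full0[free])^2))
    sol <- minpack.lm::nls.lm(par = full0[free], fn = resid_fn,
                              lower = lower[free], upper = upper[free],
                              control = ctl)
    rms <- sqrt(mean(sol$fvec^2))
    if (is.null(best) || rms < best$rms) {
      best <- list(rms = rms, par = sol$par, info = sol$info,
                   niter = sol$niter, template = full0)
    }
  }
  bands <- bands_from_full(make_full(best$par, best$template))
  fitted <- evaluate_bands(bands, w)
  structure(list(
    bands = bands,
    residual_rms = best$rms,
    init_rms = init_rms,
    converged = best$info %in% 1:4,
    n_eval = best$niter,
    d1_pinned = pin_d1,
    window = window,
    sample_id = spectrum$sample_id[1],
    replicate_id = spectrum$replicate_id[1],
    data = tibble::tibble(wavenumber = w, intensity = y, fitted = fitted),
    control = list(center_slack = center_slack, fwhm_lower = fwhm_lower,
                   fwhm_upper = fwhm_upper, max_eval = max_eval,
                   ftol = ftol, shapes = shapes, multistart = multistart)
  ), class = "five_band_fit")
}

#' @export
print.five_band_fit <- function(x, ...) {
  cat(sprintf("Five-band decomposition of %s (replicate %d)\n",
              x$sample_id, x$replicate_id))
  cat(sprintf("  converged: %s after %d iterations; residual RMS %.4g\n",
              x$converged, x$n_eval, x$residual_rms))
  cat(sprintf("  D1 height %s\n",
              if (x$d1_pinned) "pinned to the observed D peak" else "free"))
  print(x$bands)
  invisible(x)
}

#' Tidy a five-band fit: one row per band
#'
#' @param x A `"five_band_fit"` object.
#' @param ... Unused.
#' @return Tibble with columns `band`, `shape`, `center`, `height`, `fwhm`.
#' @method tidy five_band_fit
#' @export
tidy.five_band_fit <- function(x, ...) x$bands

#' One-row summary of a five-band fit
#'
#' @param x A `"five_band_fit"` object.
#' @param ... Unused.
#' @return One-row tibble with the screening parameters and fit diagnostics.
#' @method glance five_band_fit
#' @export
glance.five_band_fit <- function(x, ...) {
  p <- band_params(x)
  tibble::tibble(
    sample_id = x$sample_id, replicate_id = x$replicate_id,
    r1 = p$r1, fwhm_d1 = p$fwhm_d1, fwhm_g = p$fwhm_g,
    residual_rms = x$residual_rms, converged = x$converged,
    n_eval = x$n_eval, d1_pinned = x$d1_pinned, method = "decomposition")
}

#' Screening parameters from a converged decomposition
#'
#' R1 = height(D1)/height(G); FWHM-D1 and FWHM-G are the fitted band widths.
#'
#' @param fit A `"five_band_fit"` object.
#' @return One-row tibble: `sample_id`, `replicate_id`, `r1`, `fwhm_d1`,
#'   `fwhm_g`, `method = "decomposition"`.
#' @export
band_params <- function(fit) {
  stopifnot(inherits(fit, "five_band_fit"))
  b <- fit$bands
  hG <- b$height[b$band == "G"]
  if (hG <= 0) abort("G band height is zero; R1 is undefined.")
  tibble::tibble(
    sample_id = fit$sample_id, replicate_id = fit$replicate_id,
    r1 = b$height[b$band == "D1"] / hG,
    fwhm_d1 = b$fwhm[b$band == "D1"],
    fwhm_g = b$fwhm[b$band == "G"],
    method = "decomposition")
}

#' Per-sample parameters from replicate spectra
#'
#' Fits (or graphically reads) each replicate spectrum of every sample and
#' reports the mean and sample standard deviation of R1, FWHM-D1 and FWHM-G
#' over replicates, the way multi-spot Raman measurements are usually
#' summarised.
#'
#' @param spectra Spectrum tibble containing `>= 2` replicates per sample.
#' @param method `"decomposition"` (default) or `"graphical"`.
#' @param ... Passed on to [fit_bands()] or [graphical_params()].
#' @return One row per `sample_id`: `n_replicates`, `r1`, `r1_sd`,
#'   `fwhm_d1`, `fwhm_d1_sd`, `fwhm_g`, `fwhm_g_sd`, `method`.
#' @export
replicate_params <- function(spectra, method = c("decomposition", "graphical"),
                             ...) {
  method <- match.arg(method)
  stopifnot(is.data.frame(spectra))
  n_rep <- spectra |>
    dplyr::distinct(.data$sample_id, .data$replicate_id) |>
    dplyr::count(.data$sample_id)
  if (any(n_rep$n < 2)) {
    abort(sprintf("Need >= 2 replicates per sample; got %d for '%s'.",
                  min(n_rep$n), n_rep$sample_id[which.min(n_rep$n)]))
  }
  per_rep <- if (method == "decomposition") {
    res <- fit_bands(spectra, ...)
    bad <- res[!res$converged, ]
    if (nrow(bad) > 0) {
      abort(sprintf("Replicate fit(s) failed to converge: %s",
                    paste(sprintf("%s/rep%d", bad$sample_id,
                                  bad$replicate_id), collapse = ", ")))
    }
    res
  } else {
    graphical_params(spectra, ...)
  }
  per_rep |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      n_replicates = dplyr::n(),
      r1_sd = stats::sd(.data$r1), r1 = mean(.data$r1),
      fwhm_d1_sd = stats::sd(.data$fwhm_d1), fwhm_d1 = mean(.data$fwhm_d1),
      fwhm_g_sd = stats::sd(.data$fwhm_g), fwhm_g = mean(.data$fwhm_g),
      .groups = "drop") |>
    dplyr::mutate(method = method) |>
    dplyr::select("sample_id", "n_replicates", "r1", "r1_sd", "fwhm_d1",
                  "fwhm_d1_sd", "fwhm_g", "fwhm_g_sd", "method")
}
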