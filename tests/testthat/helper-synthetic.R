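# Shared helpers: independent brute-force oracles (own closed forms, not the
# package's evaluators) and small constructors used across test files.

# independent band evaluators for oracle computations
oracle_lorentzian <- function(h, c, w, x) h / (1 + ((x - c) / (w / 2))^2)
oracle_gaussian <- function(h, c, w, x) h * exp(-4 * log(2) * (x - c)^2 / w^2)

oracle_curve <- function(bands, x) {
  y <- numeric(length(x))
  for (i in seq_len(nrow(bands))) {
    f <- if (bands$shape[i] == "gaussian") oracle_gaussian else
      oracle_lorentzian
    y <- y + f(bands$height[i], bands$center[i], bands$fwhm[i], x)
  }
  y
}

# graphical reading of a noiseless curve on a fine grid: peak heights in the
# D and G windows of the summed curve
oracle_graphical_r1 <- function(bands, step = 0.01) {
  x <- seq(1000, 1800, by = step)
  y <- oracle_curve(bands, x)
  hD <- max(y[x >= 1300 & x <= 1400])
  hG <- max(y[x >= 1560 & x <= 1640])
  hD / hG
}

# a simple two-band (D1 + G) spectrum tibble
two_band_spectrum <- function(hD = 1.4, cD = 1350, wD = 80,
                              hG = 1, cG = 1580, wG = 60,
                              noise_sd = 0, seed = NULL) {
  b <- band(c("G", "D1"), "lorentzian", c(cG, cD), c(hG, hD), c(wG, wD))
  sim_spectrum(b, noise_sd = noise_sd, seed = seed)
}

# rasterize straight strokes (px step counts `lengths_px`, horizontal or
# diagonal) into a 1-px skeleton matrix, stacked in disjoint bands so
# strokes never touch; a horizontal stroke of k steps spans k+1 pixels and
# has path length k, a diagonal one k * sqrt(2)
rasterize_strokes <- function(lengths_px, diagonal) {
  stopifnot(length(lengths_px) == length(diagonal))
  heights <- ifelse(diagonal, lengths_px + 3, 3)
  m <- matrix(FALSE, sum(heights) + 4, max(lengths_px) + 5)
  row <- 2
  for (i in seq_along(lengths_px)) {
    k <- lengths_px[i]
    if (diagonal[i]) {
      m[cbind(row + 0:k, 2 + 0:k)] <- TRUE
    } else {
      m[row, 2 + 0:k] <- TRUE
    }
    row <- row + heights[i]
  }
  m
}
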