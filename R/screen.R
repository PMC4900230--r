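# Carbonization-continuum screening: stage assignment, alteration and
# graphitization flags, best-preserved-candidate selection, and the
# R1 vs FWHM-D1 diagram.

#' Screening thresholds
#'
#' Defaults encode the carbonization-continuum reading of the R1/FWHM-D1
#' plane: the second carbonization stage begins at R1 ~ 0.8-1 (default
#' boundary 0.9, the midpoint); R1 >= 2.5 marks unusually altered CM off the
#' continuum; Archean samples with R1 in 0.72-1 are best-preserved
#' candidates; the carbonization box spans R1 0.4-2.5 and FWHM-D1
#' 50-300 cm^-1; the narrow-D1 / low-R1 corner (FWHM-D1 <= 60 cm^-1 and
#' R1 <= 0.7) is flagged as graphitization-suspect, the operational reading
#' of where partially graphitized samples leave the continuum.
#'
#' @param stage2_r1 R1 at which the second carbonization stage begins.
#' @param altered_r1 R1 at and above which CM is classed altered.
#' @param candidate_r1_lo,candidate_r1_hi R1 window for best-preserved
#'   Archean candidates.
#' @param carbonization_fwhm_d1,carbonization_r1 The carbonization box.
#' @param graphitization_fwhm_d1_max,graphitization_r1_max The
#'   graphitization-suspect corner.
#' @return A `"screen_thresholds"` list.
#' @export
screen_thresholds <- function(stage2_r1 = 0.9,
                              altered_r1 = 2.5,
                              candidate_r1_lo = 0.72,
                              candidate_r1_hi = 1.0,
                              carbonization_fwhm_d1 = c(50, 300),
                              carbonization_r1 = c(0.4, 2.5),
                              graphitization_fwhm_d1_max = 60,
                              graphitization_r1_max = 0.7) {
  t <- list(stage2_r1 = stage2_r1, altered_r1 = altered_r1,
            candidate_r1_lo = candidate_r1_lo,
            candidate_r1_hi = candidate_r1_hi,
            carbonization_fwhm_d1 = carbonization_fwhm_d1,
            carbonization_r1 = carbonization_r1,
            graphitization_fwhm_d1_max = graphitization_fwhm_d1_max,
            graphitization_r1_max = graphitization_r1_max)
  if (!(candidate_r1_lo < candidate_r1_hi && candidate_r1_hi <= altered_r1)) {
    abort("Need candidate_r1_lo < candidate_r1_hi <= altered_r1.")
  }
  if (diff(carbonization_fwhm_d1) <= 0 || diff(carbonization_r1) <= 0) {
    abort("Carbonization box intervals must be non-empty.")
  }
  structure(t, class = "screen_thresholds")
}

STAGE_LEVELS <- c("stage1", "stage2", "altered")

#' Classify samples on the carbonization continuum
#'
#' Assigns a carbonization stage from R1 (stage 1 below `stage2_r1`, stage 2
#' up to `altered_r1`, altered at and above), flags the
#' graphitization-suspect corner (narrow D1 and low R1), tests membership of
#' the carbonization box, and marks best-preserved Archean candidates
#' (Archean samples with R1 in the candidate window that are not
#' graphitization suspects). Samples with R1 >= 1 receive a temperature note
#' recalling that published Raman-maturity calibrations place R1 = 1 near
#' 300 degrees C (an annotation, never a computed temperature).
#'
#' @param data Data frame with finite `r1` and `fwhm_d1` columns and either
#'   an `is_archean` logical column or an `age_ga` column from which it is
#'   derived (`age_ga >= archean_min_ga`). Without either, samples are
#'   treated as non-Archean.
#' @param thresholds A [screen_thresholds()] object.
#' @param archean_min_ga Age cutoff (Ga) for auto-deriving `is_archean`.
#' @return The input with added columns `stage` (factor), `on_continuum`,
#'   `graphitization_suspect`, `best_preserved_candidate`,
#'   `temperature_note`, and a `thr_*` snapshot of every threshold used.
#' @export
classify_maturity <- function(data, thresholds = screen_thresholds(),
                              archean_min_ga = 2.5) {
  stopifnot(is.data.frame(data), inherits(thresholds, "screen_thresholds"))
  if (!all(c("r1", "fwhm_d1") %in% names(data))) {
    abort("`data` must have `r1` and `fwhm_d1` columns.")
  }
  if (!all(is.finite(data$r1)) || !all(is.finite(data$fwhm_d1))) {
    abort("Non-finite r1 or fwhm_d1; classification requires finite inputs.")
  }
  t <- thresholds
  out <- tibble::as_tibble(data)
  if (!"is_archean" %in% names(out)) {
    out$is_archean <- if ("age_ga" %in% names(out)) {
      out$age_ga >= archean_min_ga
    } else {
      FALSE
    }
  }
  out <- out |> dplyr::mutate(
    stage = factor(dplyr::case_when(
      .data$r1 < t$stage2_r1 ~ "stage1",
      .data$r1 < t$altered_r1 ~ "stage2",
      TRUE ~ "altered"), levels = STAGE_LEVELS),
    graphitization_suspect =
      .data$fwhm_d1 <= t$graphitization_fwhm_d1_max &
      .data$r1 <= t$graphitization_r1_max,
    on_continuum =
      .data$r1 >= t$carbonization_r1[1] & .data$r1 <= t$carbonization_r1[2] &
      .data$fwhm_d1 >= t$carbonization_fwhm_d1[1] &
      .data$fwhm_d1 <= t$carbonization_fwhm_d1[2] &
      !.data$graphitization_suspect,
    best_preserved_candidate =
      .data$is_archean &
      .data$r1 >= t$candidate_r1_lo & .data$r1 <= t$candidate_r1_hi &
      !.data$graphitization_suspect,
    temperature_note = ifelse(
      .data$r1 >= 1,
      "R1 >= 1: published Raman maturity calibrations place R1 = 1 near 300 C",
      NA_character_))
  # auditable snapshot of the thresholds in every row
  out$thr_stage2_r1 <- t$stage2_r1
  out$thr_altered_r1 <- t$altered_r1
  out$thr_candidate_r1_lo <- t$candidate_r1_lo
  out$thr_candidate_r1_hi <- t$candidate_r1_hi
  out$thr_box_r1_lo <- t$carbonization_r1[1]
  out$thr_box_r1_hi <- t$carbonization_r1[2]
  out$thr_box_fwhm_d1_lo <- t$carbonization_fwhm_d1[1]
  out$thr_box_fwhm_d1_hi <- t$carbonization_fwhm_d1[2]
  out$thr_graph_fwhm_d1_max <- t$graphitization_fwhm_d1_max
  out$thr_graph_r1_max <- t$graphitization_r1_max
  class(out) <- c("maturity_screen", class(out))
  out
}

#' Per-cohort parameter ranges
#'
#' Exact min/max of R1, FWHM-D1 and FWHM-G per group (typically Archean vs
#' non-Archean), the summary used to compare cohorts of screened samples.
#'
#' @param data Data frame with `r1`, `fwhm_d1` and (optionally) `fwhm_g`.
#' @param group_by Column (unquoted) defining the cohorts; default
#'   `is_archean`.
#' @return Long tibble with columns `group`, `parameter`, `min`, `max`.
#' @export
cohort_ranges <- function(data, group_by = is_archean) {
  stopifnot(is.data.frame(data))
  if (nrow(data) == 0) abort("Empty sample set.")
  pars <- intersect(c("r1", "fwhm_d1", "fwhm_g"), names(data))
  data |>
    dplyr::group_by(group = {{ group_by }}) |>
    dplyr::summarise(dplyr::across(
      dplyr::all_of(pars),
      list(min = ~ min(.x, na.rm = TRUE), max = ~ max(.x, na.rm = TRUE)),
      .names = "{.col}.{.fn}"), .groups = "drop") |>
    tidyr::pivot_longer(-"group", names_to = c("parameter", ".value"),
                        names_sep = "\\.")
}

#' Carbonization-continuum diagram
#'
#' Scatter of R1 (y) against FWHM-D1 (x, descending by default so maturity
#' increases to the right), with era and flag groups distinguished
#' (non-Archean open, Archean filled, graphitization suspects as crossed
#' squares) and the stage-2 and altered R1 guides drawn.
#'
#' @param data A classified sample table ([classify_maturity()] output).
#' @param descending_x Reverse the FWHM-D1 axis (default `TRUE`).
#' @param label Optional unquoted column used to label points.
#' @return A ggplot object.
#' @export
plot_continuum <- function(data, descending_x = TRUE, label = NULL) {
  stopifnot(is.data.frame(data))
  keep <- is.finite(data$r1) & is.finite(data$fwhm_d1)
  if (!any(keep)) abort("No records with finite r1 and fwhm_d1 to plot.")
  df <- tibble::as_tibble(data)[keep, ]
  gs <- if ("graphitization_suspect" %in% names(df)) {
    df$graphitization_suspect
  } else {
    rep(FALSE, nrow(df))
  }
  era <- if ("is_archean" %in% names(df)) df$is_archean else rep(FALSE, nrow(df))
  df$group <- dplyr::case_when(
    gs ~ "graphitization suspect",
    era ~ "Archean",
    TRUE ~ "non-Archean")
  df$group <- factor(df$group,
                     levels = c("non-Archean", "Archean",
                                "graphitization suspect"))
  df$group <- droplevels(df$group)
  shapes <- c("non-Archean" = 21, "Archean" = 19,
              "graphitization suspect" = 7)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$fwhm_d1, y = .data$r1,
                                        shape = .data$group)) +
    ggplot2::geom_point(size = 2.6, stroke = 0.7) +
    ggplot2::scale_shape_manual(values = shapes[levels(df$group)],
                                name = NULL) +
    ggplot2::labs(x = expression(paste("FWHM-D1 (", cm^-1, ")")),
                  y = "R1 = I(D1)/I(G)") +
    ggplot2::theme_minimal()
  if ("thr_stage2_r1" %in% names(df)) {
    p <- p +
      ggplot2::geom_hline(yintercept = df$thr_stage2_r1[1],
                          linetype = "dashed", colour = "grey40") +
      ggplot2::geom_hline(yintercept = df$thr_altered_r1[1],
                          linetype = "dotted", colour = "grey40")
  }
  if (descending_x) p <- p + ggplot2::scale_x_reverse()
  lab <- rlang::enquo(label)
  if (!rlang::quo_is_null(lab)) {
    p <- p + ggplot2::geom_text(ggplot2::aes(label = !!lab),
                                nudge_y = 0.06, size = 2.7,
                                show.legend = FALSE)
  }
  p
}

#' @rdname plot_continuum
#' @param object A classified sample table.
#' @param ... Passed to [plot_continuum()].
#' @method autoplot maturity_screen
#' @export
autoplot.maturity_screen <- function(object, ...) plot_continuum(object, ...)

#' Write the continuum diagram to a file
#'
#' @inheritParams plot_continuum
#' @param path Output figure path (extension selects the device, e.g. `.png`
#'   or `.svg`).
#' @param width,height,dpi Device settings passed to [ggplot2::ggsave()].
#' @return `path`, invisibly.
#' @export
continuum_diagram <- function(data, path, descending_x = TRUE,
                              width = 6, height = 4.5, dpi = 150) {
  p <- plot_continuum(data, descending_x = descending_x)
  ggplot2::ggsave(path, p, width = width, height = height, dpi = dpi)
  invisible(path)
}
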