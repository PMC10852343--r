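#' Morphometry parameters
#'
#' @param pixel_area_um2 Pixel footprint for the area-to-diameter
#'   conversion; the published conversion constant 6.718 um^2/px is the
#'   default.
#' @param small_max_um Somata with equivalent diameter at or below this are
#'   "small" (default 25 um, the nociceptor-scale class).
#' @param large_min_um Somata strictly above this are "large" (default
#'   30 um). The 25-30 um band belongs to neither class and is tracked as
#'   "intermediate" rather than forced into one.
#' @return A list of class `drgq_morph_params`.
#' @export
morphometry_params <- function(pixel_area_um2 = 6.718, small_max_um = 25,
                               large_min_um = 30) {
  if (small_max_um >= large_min_um) {
    abort("`small_max_um` must be < `large_min_um`")
  }
  structure(list(pixel_area_um2 = pixel_area_um2,
                 small_max_um = small_max_um, large_min_um = large_min_um),
            class = "drgq_morph_params")
}

#' Convert a pixel area to an equivalent diameter in micrometres
#'
#' The soma is treated as a disc of equal area: the pixel count is scaled
#' to um^2 and inverted through A = pi r^2, giving
#' `d = 2 * sqrt(area_px * pixel_area_um2 / pi)`.
#'
#' @param area_px Object area in pixels (vectorized).
#' @param pixel_area_um2 um^2 per pixel; default 6.718.
#' @return Equivalent diameter(s) in um.
#' @examples
#' area_to_diameter(400)  # 58.49 um at the default conversion
#' @export
area_to_diameter <- function(area_px, pixel_area_um2 = 6.718) {
  if (any(area_px < 0)) abort("`area_px` must be >= 0")
  2 * sqrt(area_px * pixel_area_um2 / pi)
}

#' Convert an equivalent diameter back to a pixel area
#'
#' Inverse of [area_to_diameter()]; round-trips to machine precision.
#'
#' @param diameter_um Diameter(s) in um.
#' @inheritParams area_to_diameter
#' @return Area(s) in pixels (not rounded).
#' @export
diameter_to_area <- function(diameter_um, pixel_area_um2 = 6.718) {
  pi * (diameter_um / 2)^2 / pixel_area_um2
}

#' Classify somata into small / intermediate / large diameter classes
#'
#' Small means diameter <= `small_max_um` (boundary included: a 25.0 um
#' soma is small); large means strictly > `large_min_um`; everything
#' between is "intermediate" and reported separately. Every record falls in
#' exactly one class.
#'
#' @param records A record table. If it has no `diameter_um` column, one is
#'   computed from `area_px`.
#' @param params [morphometry_params()].
#' @return `records` with `diameter_um` and a `size_class` factor
#'   (`small`, `intermediate`, `large`).
#' @export
classify_size <- function(records, params = morphometry_params()) {
  if (!"diameter_um" %in% names(records)) {
    if (!"area_px" %in% names(records)) {
      abort("`records` needs a `diameter_um` or `area_px` column")
    }
    records$diameter_um <- area_to_diameter(records$area_px,
                                            params$pixel_area_um2)
  }
  d <- records$diameter_um
  cls <- ifelse(d <= params$small_max_um, "small",
                ifelse(d > params$large_min_um, "large", "intermediate"))
  records$size_class <- factor(cls, levels = c("small", "intermediate", "large"))
  records
}

#' Fit a Gaussian to a pooled diameter distribution
#'
#' Maximum-likelihood single-Gaussian fit (sample mean and SD); for a
#' single Gaussian the mode equals the mean. Bimodal small/large structure
#' is handled by the size classes, not by this fit, which mirrors how
#' pooled-neuron diameter histograms are summarized. Degenerate inputs
#' (fewer than 10 diameters, or zero spread) are rejected.
#'
#' @param diameters_um Numeric vector of soma diameters (um).
#' @param group Free-text group label carried into the fit.
#' @return A `drgq_diameter_fit` with fields `mean_um`, `sd_um`, `mode_um`,
#'   `n`, `group`, `diameters_um`.
#' @export
fit_diameter_distribution <- function(diameters_um, group = "") {
  diameters_um <- diameters_um[!is.na(diameters_um)]
  n <- length(diameters_um)
  if (n < 10) abort(sprintf("need at least 10 diameters, got %d", n))
  s <- sd(diameters_um)
  if (!is.finite(s) || s <= 0) {
    abort("degenerate diameter distribution (zero spread)")
  }
  structure(list(mean_um = mean(diameters_um), sd_um = s,
                 mode_um = mean(diameters_um), n = n,
                 group = as.character(group), diameters_um = diameters_um),
            class = "drgq_diameter_fit")
}

#' @export
print.drgq_diameter_fit <- function(x, ...) {
  cat(sprintf("<drgq_diameter_fit>%s n = %d: mean %.2f um, sd %.2f um (mode = mean)\n",
              if (nzchar(x$group)) paste0(" [", x$group, "]") else "",
              x$n, x$mean_um, x$sd_um))
  invisible(x)
}

#' @method tidy drgq_diameter_fit
#' @export
tidy.drgq_diameter_fit <- function(x, ...) {
  tibble(term = c("mean_um", "sd_um", "mode_um"),
         estimate = c(x$mean_um, x$sd_um, x$mode_um))
}

#' @method glance drgq_diameter_fit
#' @export
glance.drgq_diameter_fit <- function(x, ...) {
  tibble(mean_um = x$mean_um, sd_um = x$sd_um, mode_um = x$mode_um,
         n = x$n, group = x$group)
}

#' Histogram export of a diameter fit
#'
#' @param x A `drgq_diameter_fit`.
#' @param binwidth_um Histogram bin width in um.
#' @return Tibble with `bin_mid_um`, `count`, `density`.
#' @export
diameter_histogram <- function(x, binwidth_um = 2) {
  stopifnot(inherits(x, "drgq_diameter_fit"))
  brk <- seq(floor(min(x$diameters_um)),
             ceiling(max(x$diameters_um)) + binwidth_um, by = binwidth_um)
  h <- hist(x$diameters_um, breaks = brk, plot = FALSE)
  tibble(bin_mid_um = h$mids, count = h$counts, density = h$density)
}

#' Per-mouse summary of all pipeline metrics
#'
#' Pools neurons (and sections) within each mouse and emits one row per
#' mouse: percent MHCII+ neurons overall and within the small/large size
#' classes, mean puncta per neuron and mean percent puncta area (over
#' MHCII-scored neurons), pooled CD4+ T-cell density, and percent RFX1+
#' neurons among neurons with a visible nucleus. Fractions are pooled
#' counts over pooled denominators (10/100 + 3/10 gives 13/110, not the
#' mean of the two section percentages); density is the pooled ratio of
#' [tcell_density()]. Neurons flagged unmeasurable contribute to neither
#' numerator nor denominator.
#'
#' @param records Neuron-level table with columns `mouse_id`, `measurable`,
#'   `mhcii_positive`, `size_class`, and optionally `rfx1_positive`,
#'   `has_nucleus`.
#' @param puncta Optional neuron-level puncta table (`mouse_id`,
#'   `n_puncta`, `percent_area`).
#' @param tcells Optional per-section table (`mouse_id`, `n_tcells`,
#'   `tissue_area_px`).
#' @param pixel_area_um2 Pixel footprint for the density denominator.
#' @return One-row-per-mouse tibble.
#' @export
summarize_mouse <- function(records, puncta = NULL, tcells = NULL,
                            pixel_area_um2 = 6.718) {
  if (!"mouse_id" %in% names(records)) abort("`records` needs `mouse_id`")
  if (!nrow(records)) abort("zero neurons to summarize")
  pct <- function(flag) 100 * mean(flag, na.rm = TRUE)
  meas <- if ("measurable" %in% names(records)) {
    records[records$measurable, ]
  } else records
  out <- meas |>
    group_by(.data$mouse_id) |>
    summarise(
      n_neurons = dplyr::n(),
      pct_mhcii_pos = pct(.data$mhcii_positive),
      pct_mhcii_pos_small = pct(.data$mhcii_positive[.data$size_class == "small"]),
      pct_mhcii_pos_large = pct(.data$mhcii_positive[.data$size_class == "large"]),
      pct_rfx1_pos = if ("rfx1_positive" %in% names(meas)) {
        pct(.data$rfx1_positive)
      } else NA_real_,
      .groups = "drop")
  if (!is.null(puncta)) {
    ps <- puncta |>
      group_by(.data$mouse_id) |>
      summarise(mean_puncta_per_neuron = mean(.data$n_puncta, na.rm = TRUE),
                mean_pct_puncta_area = mean(.data$percent_area, na.rm = TRUE),
                .groups = "drop")
    out <- left_join(out, ps, by = "mouse_id")
  }
  if (!is.null(tcells)) {
    ts <- tcells |>
      group_by(.data$mouse_id) |>
      summarise(tcells_per_mm2 = tcell_density(.data$n_tcells,
                                               .data$tissue_area_px,
                                               pixel_area_um2),
                .groups = "drop")
    out <- left_join(out, ts, by = "mouse_id")
  }
  out
}

#' Group summary across mice (mean and SEM)
#'
#' The mouse is the analysis unit: metrics pooled within mouse by
#' [summarize_mouse()] are averaged across the mice of each group and
#' reported as mean and standard error of the mean. SEM is blank (NA) for
#' groups of one.
#'
#' @param mouse_tbl Output of [summarize_mouse()], plus a grouping column.
#' @param group Name of the grouping column.
#' @return Long tibble: `group`, `metric`, `mean`, `sem`, `n_mice`.
#' @export
group_summary <- function(mouse_tbl, group = "group") {
  if (!group %in% names(mouse_tbl)) {
    abort(sprintf("no grouping column '%s'", group))
  }
  metrics <- setdiff(names(mouse_tbl),
                     c("mouse_id", group, "n_neurons"))
  mouse_tbl |>
    tidyr::pivot_longer(all_of(metrics), names_to = "metric",
                        values_to = "value") |>
    group_by(.data[[group]], .data$metric) |>
    summarise(mean = mean(.data$value, na.rm = TRUE),
              sem = if (sum(!is.na(.data$value)) > 1) {
                sd(.data$value, na.rm = TRUE) / sqrt(sum(!is.na(.data$value)))
              } else NA_real_,
              n_mice = sum(!is.na(.data$value)),
              .groups = "drop") |>
    rename(group = 1)
}

#' Score thermal place preference (TPP) trials
#'
#' Each trial reports the percent of trial time spent on the test plate:
#' `100 * seconds_on_test_plate / trial_length_s` (3-minute trials by
#' default). Trial 1 is the habituation/baseline trial; any mouse that
#' spent strictly less than `habituation_min_s` seconds (30 s) on the test
#' plate during habituation is flagged excluded and its test trials
#' (indices 2-4) are dropped from the output. A mouse at exactly 30 s is
#' retained.
#'
#' @param trials Tibble with columns `mouse_id`, `trial_index` (1 =
#'   habituation), `seconds_on_test_plate`, and optionally `trial_length_s`
#'   (default 180).
#' @param habituation_min_s Exclusion cutoff, default 30.
#' @return Tibble `mouse_id`, `trial_index`, `percent_time`, `excluded`;
#'   habituation rows of excluded mice are retained (flagged), their test
#'   trials are dropped.
#' @export
score_tpp <- function(trials, habituation_min_s = 30) {
  need <- c("mouse_id", "trial_index", "seconds_on_test_plate")
  if (!all(need %in% names(trials))) {
    abort(paste("`trials` needs columns:", paste(need, collapse = ", ")))
  }
  if (!"trial_length_s" %in% names(trials)) trials$trial_length_s <- 180
  bad <- trials$seconds_on_test_plate < 0 |
    trials$seconds_on_test_plate > trials$trial_length_s
  if (any(bad)) {
    abort("seconds_on_test_plate must lie in [0, trial_length_s]")
  }
  hab <- trials[trials$trial_index == 1, ]
  missing_hab <- setdiff(trials$mouse_id, hab$mouse_id)
  if (length(missing_hab)) {
    abort(paste("no habituation trial for mouse:",
                paste(missing_hab, collapse = ", ")))
  }
  excluded_mice <- hab$mouse_id[hab$seconds_on_test_plate < habituation_min_s]
  out <- trials
  out$percent_time <- 100 * out$seconds_on_test_plate / out$trial_length_s
  out$excluded <- out$mouse_id %in% excluded_mice
  out <- out[!(out$excluded & out$trial_index > 1), ]
  as_tibble(out[c("mouse_id", "trial_index", "percent_time", "excluded")])
}
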