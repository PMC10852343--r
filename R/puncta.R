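#' Puncta and polarization parameters
#'
#' Parameters of sub-cellular spot detection and surface-polarization
#' scoring. The published puncta rule is "regions of >= 1.5 pixels" of
#' signal ">= 800 MPI above local background": component areas are integer
#' pixel counts, so the effective minimum area is `ceiling(min_area_px)`
#' (2 px for the 1.5 default), and the 800 AFU offset is applied per pixel
#' (a punctum pixel must reach background + `delta_afu`, comparator `>=`).
#' Polarization uses a contiguous area of at least `polar_min_area_px`
#' (2 px) at `polar_fold` (1.7) times local background.
#'
#' @param min_area_px Minimum punctum area; fractional values are rounded up
#'   since areas are integers. Default 1.5 (effective 2).
#' @param delta_afu Per-pixel AFU offset above local background; default 800.
#' @param background_estimator `"median_in_neuron"` (default; robust to the
#'   puncta themselves) or `"annulus_median"` (median over a 5-px ring just
#'   outside the instance).
#' @param polar_min_area_px Minimum polarized-component area; default 2.
#' @param polar_fold Fold-over-background for polarization; default 1.7.
#' @param min_neuron_px Instances smaller than this are not scored (their
#'   background estimate is meaningless); default 25.
#' @return A list of class `drgq_puncta_params`.
#' @export
puncta_params <- function(min_area_px = 1.5, delta_afu = 800,
                          background_estimator = c("median_in_neuron",
                                                   "annulus_median"),
                          polar_min_area_px = 2, polar_fold = 1.7,
                          min_neuron_px = 25) {
  background_estimator <- match.arg(background_estimator)
  if (delta_afu <= 0) abort("`delta_afu` must be > 0")
  if (polar_fold <= 1) abort("`polar_fold` must be > 1")
  if (min_area_px < 1 || polar_min_area_px < 1) {
    abort("minimum areas must be >= 1 pixel")
  }
  structure(list(min_area_px = min_area_px,
                 effective_min_area_px = as.integer(ceiling(min_area_px)),
                 delta_afu = delta_afu,
                 background_estimator = background_estimator,
                 polar_min_area_px = as.integer(ceiling(polar_min_area_px)),
                 polar_fold = polar_fold,
                 min_neuron_px = min_neuron_px),
            class = "drgq_puncta_params")
}

# background AFU for one instance (index vector idx into channel ch)
.local_bg <- function(ch, labels_mat, idx, id, estimator) {
  if (estimator == "median_in_neuron") {
    median(ch[idx])
  } else {
    nr <- nrow(labels_mat)
    inst <- matrix(FALSE, nr, ncol(labels_mat))
    inst[idx] <- TRUE
    ring <- .dilate_disc(inst, 5L) & !inst & labels_mat == 0L
    if (!any(ring)) return(NA_real_)
    median(ch[ring])
  }
}

#' Local-background estimate per instance
#'
#' The default estimator is the median channel intensity over the
#' instance's own measurable pixels: puncta occupy a small fraction of the
#' soma, so the median sits on the diffuse background level and is not
#' dragged up by the puncta the way a mean would be. The `annulus_median`
#' variant uses a 5-px ring outside the instance (excluding other
#' instances) for sensitivity analysis. Instances with fewer than
#' `min_neuron_px` measurable pixels are flagged unscored.
#'
#' @param stack An [image_stack()].
#' @param neurons Instance [label_map()].
#' @param params [puncta_params()].
#' @param channel Channel to estimate on (default `"MHCII"`).
#' @return A tibble: `neuron_id`, `n_px`, `background_afu`, `scored`.
#' @export
local_background <- function(stack, neurons, params = puncta_params(),
                             channel = "MHCII") {
  stopifnot(inherits(neurons, "drgq_labels"))
  ch <- get_channel(stack, channel)
  lab <- neurons$labels
  ids <- label_ids(neurons)
  out <- tibble(neuron_id = ids, n_px = NA_integer_,
                background_afu = NA_real_, scored = FALSE)
  for (i in seq_along(ids)) {
    idx <- which(lab == ids[i])
    out$n_px[i] <- length(idx)
    if (length(idx) < params$min_neuron_px) next
    out$background_afu[i] <- .local_bg(ch, lab, idx, ids[i],
                                       params$background_estimator)
    out$scored[i] <- !is.na(out$background_afu[i])
  }
  out
}

#' Detect sub-cellular puncta within each instance
#'
#' Per instance: the detection threshold is local background plus
#' `delta_afu`; supra-threshold pixels inside the instance's measurable
#' mask are labeled into 8-connected components; components of at least
#' `ceiling(min_area_px)` pixels are puncta. The percent area is
#' `100 * (sum of puncta areas) / (instance measurable area)`. Puncta
#' touching the mask border are kept if their in-mask area passes the gate
#' (pixels in exclusion zones are untrusted and never counted).
#'
#' @inheritParams local_background
#' @return A tibble with one row per instance: `neuron_id`, `neuron_area_px`,
#'   `background_afu`, `n_puncta`, `puncta_area_px`, `percent_area`,
#'   `scored`, and a `components` list column (per-punctum `area_px`,
#'   `centroid_row`, `centroid_col`, `peak_afu`).
#' @export
detect_puncta <- function(stack, neurons, params = puncta_params(),
                          channel = "MHCII") {
  stopifnot(inherits(neurons, "drgq_labels"))
  ch <- get_channel(stack, channel)
  lab <- neurons$labels
  nr <- nrow(lab)
  ids <- label_ids(neurons)
  empty_comp <- tibble(area_px = integer(), centroid_row = numeric(),
                       centroid_col = numeric(), peak_afu = numeric(),
                       pixels = list())
  out <- tibble(neuron_id = ids, neuron_area_px = NA_integer_,
                background_afu = NA_real_, n_puncta = NA_integer_,
                puncta_area_px = NA_integer_, percent_area = NA_real_,
                scored = FALSE, components = rep(list(empty_comp), length(ids)))
  for (i in seq_along(ids)) {
    idx <- which(lab == ids[i])
    out$neuron_area_px[i] <- length(idx)
    if (length(idx) < params$min_neuron_px) next
    bg <- .local_bg(ch, lab, idx, ids[i], params$background_estimator)
    if (is.na(bg)) next
    out$background_afu[i] <- bg
    r <- (idx - 1L) %% nr + 1L; cc <- (idx - 1L) %/% nr + 1L
    rs <- min(r):max(r); cs <- min(cc):max(cc)
    sub_inst <- matrix(FALSE, length(rs), length(cs))
    sub_inst[cbind(r - rs[1] + 1L, cc - cs[1] + 1L)] <- TRUE
    sub_ch <- ch[rs, cs, drop = FALSE]
    supra <- sub_inst & sub_ch >= bg + params$delta_afu
    plab <- label_components(supra, 8)
    st <- .component_stats(plab, intensity = sub_ch)
    st <- st[st$area_px >= params$effective_min_area_px, , drop = FALSE]
    peak <- vapply(st$label, function(id) max(sub_ch[plab == id]), numeric(1))
    # full-image linear pixel indices of each punctum, for exact auditing
    pix <- lapply(st$label, function(id) {
      sidx <- which(plab == id)
      sr <- (sidx - 1L) %% length(rs) + 1L
      sc <- (sidx - 1L) %/% length(rs) + 1L
      sort((cs[sc] - 1L) * nr + rs[sr])
    })
    out$components[[i]] <- tibble(area_px = st$area_px,
                                  centroid_row = st$centroid_row + rs[1] - 1,
                                  centroid_col = st$centroid_col + cs[1] - 1,
                                  peak_afu = peak,
                                  pixels = pix)
    out$n_puncta[i] <- nrow(st)
    out$puncta_area_px[i] <- sum(st$area_px)
    out$percent_area[i] <- 100 * sum(st$area_px) / length(idx)
    out$scored[i] <- TRUE
  }
  out
}

#' Surface-signal polarization score per instance
#'
#' Polarization is the accumulation of surface signal (MHCII or bound OVA
#' peptide) into a contiguous region: pixels at or above `polar_fold`
#' (1.7) times local background, in components of at least
#' `polar_min_area_px` (2) pixels, expressed as percent of the instance
#' area. A zero background with non-zero signal makes the fold undefined;
#' such instances are scored against a background floor of 1 AFU and
#' flagged with a warning.
#'
#' @inheritParams local_background
#' @param channel Channel to score (`"MHCII"` or `"OVA"`).
#' @return A tibble: `neuron_id`, `neuron_area_px`, `background_afu`,
#'   `polarized_area_px`, `percent_polarized`, `scored`, `bg_floored`.
#' @export
polarization_score <- function(stack, neurons, params = puncta_params(),
                               channel = "MHCII") {
  stopifnot(inherits(neurons, "drgq_labels"))
  ch <- get_channel(stack, channel)
  lab <- neurons$labels
  nr <- nrow(lab)
  ids <- label_ids(neurons)
  out <- tibble(neuron_id = ids, neuron_area_px = NA_integer_,
                background_afu = NA_real_, polarized_area_px = NA_integer_,
                percent_polarized = NA_real_, scored = FALSE,
                bg_floored = FALSE)
  for (i in seq_along(ids)) {
    idx <- which(lab == ids[i])
    out$neuron_area_px[i] <- length(idx)
    if (length(idx) < params$min_neuron_px) next
    bg <- .local_bg(ch, lab, idx, ids[i], params$background_estimator)
    if (is.na(bg)) next
    if (bg == 0) {
      if (!any(ch[idx] > 0)) {
        # identically dark instance: nothing can be polarized
        out$background_afu[i] <- 0
        out$polarized_area_px[i] <- 0L
        out$percent_polarized[i] <- 0
        out$scored[i] <- TRUE
        next
      }
      warn(sprintf("instance %d: zero background with non-zero signal; using background floor of 1 AFU",
                   ids[i]))
      bg <- 1
      out$bg_floored[i] <- TRUE
    }
    out$background_afu[i] <- bg
    r <- (idx - 1L) %% nr + 1L; cc <- (idx - 1L) %/% nr + 1L
    rs <- min(r):max(r); cs <- min(cc):max(cc)
    sub_inst <- matrix(FALSE, length(rs), length(cs))
    sub_inst[cbind(r - rs[1] + 1L, cc - cs[1] + 1L)] <- TRUE
    sub_ch <- ch[rs, cs, drop = FALSE]
    polar <- sub_inst & sub_ch >= params$polar_fold * bg
    plab <- label_components(polar, 8)
    st <- .component_stats(plab)
    st <- st[st$area_px >= params$polar_min_area_px, , drop = FALSE]
    out$polarized_area_px[i] <- sum(st$area_px)
    out$percent_polarized[i] <- 100 * sum(st$area_px) / length(idx)
    out$scored[i] <- TRUE
  }
  out
}
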