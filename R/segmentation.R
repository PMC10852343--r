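#' Segmentation parameters
#'
#' All tunable knobs of the mask-building stage. Size gates are given in
#' pixels; the defaults are derived from equivalent-diameter gates in
#' micrometres (neurons 8-60 um, nuclei 4-15 um, immune cells 5-15 um)
#' converted through `pixel_area_um2`. Thresholds the underlying method
#' leaves symbolic (tissue, neuron marker, CD3, CD4, DAPI) default to
#' `"otsu"`, i.e. an Otsu threshold computed on the relevant channel, and can
#' be overridden with absolute AFU values. The `nonneuronal_mhcii_min`
#' default of 25,000 AFU is the published cutoff for bright non-neuronal
#' (immune-cell) MHCII, which runs at more than 5x the neuronal level.
#'
#' @param pixel_area_um2 Pixel footprint used to convert the um size gates
#'   to pixel gates.
#' @param tissue_smooth_sigma Gaussian sigma (px) applied before the tissue
#'   threshold.
#' @param tissue_threshold `"otsu"` (applied on log-intensity) or AFU.
#' @param neuron_marker_threshold `"otsu"` or AFU; pixel-level gate for the
#'   neuron marker.
#' @param neuron_min_area_px,neuron_max_area_px Neuron instance area gate.
#' @param neuron_marker_min_mpi Minimum neuron-marker MPI per instance.
#' @param shrink_px Erosion radius applied to neuron masks to exclude
#'   perisomatic (satellite glia) signal; default 4.
#' @param grow_px Dilation radius applied to the non-neuronal MHCII mask to
#'   capture its low-intensity fringe; default 7.
#' @param nonneuronal_mhcii_min AFU cutoff for non-neuronal MHCII; default
#'   25000.
#' @param immune_cell_min_area_px,immune_cell_max_area_px Area gate for
#'   immune-scale objects (non-neuronal MHCII cells, CD3/CD4 cells).
#' @param cd3_threshold,cd4_threshold,dapi_threshold `"otsu"` or AFU
#'   pixel-level gates.
#' @param cd3_min_mpi,cd4_min_mpi Minimum per-component MPI for T-cell
#'   candidates.
#' @param cd4_overlap_frac Fraction of a CD3 component's pixels that must
#'   fall in CD4+ components for the cell to count as double positive;
#'   default 0.5.
#' @param nucleus_min_area_px,nucleus_max_area_px Nucleus area gate.
#' @param dapi_min_mpi Minimum DAPI MPI per nucleus.
#' @param fiber_eccentricity,fiber_elongation Components with moment
#'   eccentricity above the former or major/minor axis ratio above the
#'   latter are treated as nerve fibers and excluded.
#' @param connectivity Pixel connectivity for component labeling (8 or 4).
#' @return A list of class `drgq_seg_params`.
#' @export
seg_params <- function(pixel_area_um2 = 6.718,
                       tissue_smooth_sigma = 2,
                       tissue_threshold = "otsu",
                       neuron_marker_threshold = "otsu",
                       neuron_min_area_px = NULL,
                       neuron_max_area_px = NULL,
                       neuron_marker_min_mpi = 0,
                       shrink_px = 4L,
                       grow_px = 7L,
                       nonneuronal_mhcii_min = 25000,
                       immune_cell_min_area_px = NULL,
                       immune_cell_max_area_px = NULL,
                       cd3_threshold = "otsu",
                       cd4_threshold = "otsu",
                       cd3_min_mpi = 0,
                       cd4_min_mpi = 0,
                       cd4_overlap_frac = 0.5,
                       nucleus_min_area_px = NULL,
                       nucleus_max_area_px = NULL,
                       dapi_threshold = "otsu",
                       dapi_min_mpi = 0,
                       fiber_eccentricity = 0.97,
                       fiber_elongation = 5,
                       connectivity = 8L) {
  diam_area_px <- function(d_um) pi * (d_um / 2)^2 / pixel_area_um2
  neuron_min_area_px <- neuron_min_area_px %||% round(diam_area_px(8))
  neuron_max_area_px <- neuron_max_area_px %||% round(diam_area_px(60))
  immune_cell_min_area_px <- immune_cell_min_area_px %||% round(diam_area_px(5))
  immune_cell_max_area_px <- immune_cell_max_area_px %||% round(diam_area_px(15))
  nucleus_min_area_px <- nucleus_min_area_px %||% round(diam_area_px(4))
  nucleus_max_area_px <- nucleus_max_area_px %||% round(diam_area_px(15))
  p <- list(pixel_area_um2 = pixel_area_um2,
            tissue_smooth_sigma = tissue_smooth_sigma,
            tissue_threshold = tissue_threshold,
            neuron_marker_threshold = neuron_marker_threshold,
            neuron_min_area_px = neuron_min_area_px,
            neuron_max_area_px = neuron_max_area_px,
            neuron_marker_min_mpi = neuron_marker_min_mpi,
            shrink_px = as.integer(shrink_px),
            grow_px = as.integer(grow_px),
            nonneuronal_mhcii_min = nonneuronal_mhcii_min,
            immune_cell_min_area_px = immune_cell_min_area_px,
            immune_cell_max_area_px = immune_cell_max_area_px,
            cd3_threshold = cd3_threshold, cd4_threshold = cd4_threshold,
            cd3_min_mpi = cd3_min_mpi, cd4_min_mpi = cd4_min_mpi,
            cd4_overlap_frac = cd4_overlap_frac,
            nucleus_min_area_px = nucleus_min_area_px,
            nucleus_max_area_px = nucleus_max_area_px,
            dapi_threshold = dapi_threshold, dapi_min_mpi = dapi_min_mpi,
            fiber_eccentricity = fiber_eccentricity,
            fiber_elongation = fiber_elongation,
            connectivity = as.integer(connectivity))
  for (pair in list(c("neuron_min_area_px", "neuron_max_area_px"),
                    c("immune_cell_min_area_px", "immune_cell_max_area_px"),
                    c("nucleus_min_area_px", "nucleus_max_area_px"))) {
    if (p[[pair[1]]] >= p[[pair[2]]]) {
      abort(sprintf("%s must be < %s", pair[1], pair[2]))
    }
  }
  if (p$shrink_px < 0 || p$grow_px < 0) abort("shrink_px/grow_px must be >= 0")
  if (!p$connectivity %in% c(4L, 8L)) abort("connectivity must be 4 or 8")
  structure(p, class = "drgq_seg_params")
}

#' Mask of neuron-containing tissue
#'
#' Smooths the neuron-marker channel, thresholds it, and fills holes, giving
#' a binary mask of the tissue regions that contain neurons. With the
#' default `"otsu"` setting, the threshold is computed on the log-scaled
#' smoothed channel: the tissue/background split must be found in the
#' presence of the far brighter somata, and log scaling stops the
#' soma mode from dominating the between-class variance.
#'
#' @param stack An [image_stack()].
#' @param params [seg_params()].
#' @param channels [channel_map()].
#' @return Binary [label_map()] (`"tissue"`; labels 0/1).
#' @export
tissue_mask <- function(stack, params = seg_params(), channels = channel_map()) {
  ch <- .role_channel(stack, channels, "neuron_marker")
  sm <- if (params$tissue_smooth_sigma > 0) {
    as.matrix(EBImage::gblur(EBImage::Image(ch), sigma = params$tissue_smooth_sigma))
  } else ch
  if (identical(params$tissue_threshold, "otsu")) {
    # split on log intensity (so the bright somata cannot dominate the
    # between-class variance), then refine to the midpoint of the two class
    # medians in linear space: that places the mask edge at the 50% point of
    # the smoothing ramp, i.e. at the true tissue boundary
    t_log <- .otsu(log1p(sm))
    lo <- sm[log1p(sm) <= t_log]
    hi <- sm[log1p(sm) > t_log]
    thr <- if (length(lo) && length(hi)) {
      (median(lo) + median(hi)) / 2
    } else expm1(t_log)
    mask <- sm > thr
  } else {
    mask <- sm >= as.numeric(params$tissue_threshold)
  }
  filled <- as.matrix(EBImage::fillHull(EBImage::Image(mask * 1)))
  label_map(matrix(as.integer(filled > 0), nrow(ch), ncol(ch)), "tissue")
}

#' Single-neuron instance segmentation
#'
#' Thresholds the neuron-marker channel, labels connected components,
#' and keeps components that look like somata: area within the neuron size
#' gate, marker MPI at or above `neuron_marker_min_mpi`, and not fiber-like.
#' Elongated components (moment eccentricity > `fiber_eccentricity` or
#' major/minor axis ratio > `fiber_elongation`) are treated as nerve fibers
#' and removed. Survivors are relabeled 1..K in raster order.
#'
#' @inheritParams tissue_mask
#' @return A [label_map()] (`"neuron"`) with a `"dropped"` attribute: a
#'   tibble of removed components and the reason (`area`, `mpi`, `fiber`).
#' @export
neuron_instances <- function(stack, params = seg_params(),
                             channels = channel_map()) {
  ch <- .role_channel(stack, channels, "neuron_marker")
  thr <- .resolve_threshold(params$neuron_marker_threshold, ch)
  mask <- if (identical(params$neuron_marker_threshold, "otsu")) ch > thr else ch >= thr
  lab <- label_components(mask, params$connectivity)
  st <- .component_stats(lab, intensity = ch, moments = TRUE)
  reason <- rep(NA_character_, nrow(st))
  reason[st$area_px < params$neuron_min_area_px |
           st$area_px > params$neuron_max_area_px] <- "area"
  reason[is.na(reason) & st$mpi < params$neuron_marker_min_mpi] <- "mpi"
  reason[is.na(reason) &
           (st$eccentricity > params$fiber_eccentricity |
              st$axis_ratio > params$fiber_elongation)] <- "fiber"
  keep <- st$label[is.na(reason)]
  lab[!(lab %in% keep)] <- 0L
  out <- label_map(.relabel(lab), "neuron")
  attr(out, "dropped") <- tibble(label = st$label[!is.na(reason)],
                                 area_px = st$area_px[!is.na(reason)],
                                 reason = reason[!is.na(reason)])
  out
}

#' Shrink (erode) every instance of a label map
#'
#' Erodes each instance independently by a Euclidean disc of radius `k`
#' (pixels outside the image count as background). This is the "Shrink"
#' step that pulls the neuron border inwards -- 4 px by default in the
#' pipeline -- so that perisomatic satellite-glia signal cannot leak into
#' the soma measurement. Instance ids are preserved; instances eroded to
#' extinction are dropped and listed in the `"dropped"` attribute with a
#' message.
#'
#' @param labels A [label_map()].
#' @param k Erosion radius in pixels (`k = 0` is the identity).
#' @return A [label_map()] with the same class name and ids.
#' @export
shrink_mask <- function(labels, k) {
  stopifnot(inherits(labels, "drgq_labels"), k >= 0)
  k <- as.integer(k)
  lab <- labels$labels
  if (k == 0L) {
    out <- label_map(lab, labels$class_name)
    attr(out, "ids") <- label_ids(labels)
    attr(out, "dropped") <- integer(0)
    return(out)
  }
  nr <- nrow(lab); nc <- ncol(lab)
  out_lab <- matrix(0L, nr, nc)
  ids <- label_ids(labels)
  dropped <- integer(0)
  for (id in ids) {
    idx <- which(lab == id)
    r <- (idx - 1L) %% nr + 1L; cc <- (idx - 1L) %/% nr + 1L
    rs <- max(1L, min(r) - k):min(nr, max(r) + k)
    cs <- max(1L, min(cc) - k):min(nc, max(cc) + k)
    sub <- lab[rs, cs, drop = FALSE] == id
    er <- .erode_disc(sub, k)
    if (!any(er)) {
      dropped <- c(dropped, id)
    } else {
      block <- out_lab[rs, cs, drop = FALSE]
      block[er] <- id
      out_lab[rs, cs] <- block
    }
  }
  if (length(dropped)) {
    message(sprintf("shrink_mask: %d instance(s) eroded to extinction (ids %s)",
                    length(dropped), paste(dropped, collapse = ", ")))
  }
  out <- label_map(out_lab, labels$class_name)
  attr(out, "ids") <- ids
  attr(out, "dropped") <- dropped
  out
}

#' Grow (dilate) every instance of a label map
#'
#' Dilates each instance by a Euclidean disc of radius `k`. This is the
#' "Grow" step -- 7 px by default -- that expands the bright non-neuronal
#' MHCII mask to swallow its dim fringe before it is subtracted from the
#' neuron masks. Where two grown instances claim the same pixel, the pixel
#' goes to the instance whose original pixels are nearest (ties to the lower
#' id).
#'
#' @inheritParams shrink_mask
#' @return A [label_map()] with the same class name and ids.
#' @export
grow_mask <- function(labels, k) {
  stopifnot(inherits(labels, "drgq_labels"), k >= 0)
  k <- as.integer(k)
  lab <- labels$labels
  if (k == 0L) {
    out <- label_map(lab, labels$class_name)
    attr(out, "ids") <- label_ids(labels)
    return(out)
  }
  nr <- nrow(lab); nc <- ncol(lab)
  out_lab <- lab
  claim_n <- matrix(0L, nr, nc)
  ids <- label_ids(labels)
  grown_idx <- vector("list", length(ids))
  names(grown_idx) <- as.character(ids)
  for (id in ids) {
    idx <- which(lab == id)
    r <- (idx - 1L) %% nr + 1L; cc <- (idx - 1L) %/% nr + 1L
    rs <- max(1L, min(r) - k):min(nr, max(r) + k)
    cs <- max(1L, min(cc) - k):min(nc, max(cc) + k)
    sub <- lab[rs, cs, drop = FALSE] == id
    di <- .dilate_disc(sub, k)
    # linear indices of the dilated instance in the full image
    sub_idx <- which(di)
    srow <- (sub_idx - 1L) %% length(rs) + 1L
    scol <- (sub_idx - 1L) %/% length(rs) + 1L
    full_idx <- (cs[scol] - 1L) * nr + rs[srow]
    grown_idx[[as.character(id)]] <- full_idx
    new_idx <- full_idx[lab[full_idx] == 0L]
    claim_n[new_idx] <- claim_n[new_idx] + 1L
    out_lab[new_idx] <- id
  }
  conflicts <- which(claim_n > 1L)
  if (length(conflicts)) {
    pix_by_id <- lapply(ids, function(id) which(lab == id))
    names(pix_by_id) <- as.character(ids)
    for (p in conflicts) {
      pr <- (p - 1L) %% nr + 1L; pc <- (p - 1L) %/% nr + 1L
      claimants <- ids[vapply(as.character(ids),
                              function(nm) p %in% grown_idx[[nm]], TRUE)]
      d2 <- vapply(as.character(claimants), function(nm) {
        q <- pix_by_id[[nm]]
        qr <- (q - 1L) %% nr + 1L; qc <- (q - 1L) %/% nr + 1L
        min((qr - pr)^2 + (qc - pc)^2)
      }, numeric(1))
      out_lab[p] <- claimants[which.min(d2)]
    }
  }
  out <- label_map(out_lab, labels$class_name)
  attr(out, "ids") <- ids
  out
}

#' Mask of bright non-neuronal MHCII cells
#'
#' Connected components of MHCII signal at or above
#' `nonneuronal_mhcii_min` (default 25,000 AFU, the published cutoff; immune
#' cell MHCII runs >5x brighter than neuronal MHCII) with area inside the
#' immune-cell size gate.
#'
#' @inheritParams tissue_mask
#' @return A [label_map()] (`"immune"`).
#' @export
nonneuronal_mhcii_mask <- function(stack, params = seg_params(),
                                   channels = channel_map()) {
  ch <- .role_channel(stack, channels, "mhcii")
  mask <- ch >= params$nonneuronal_mhcii_min
  lab <- label_components(mask, params$connectivity)
  st <- .component_stats(lab)
  keep <- st$label[st$area_px >= params$immune_cell_min_area_px &
                     st$area_px <= params$immune_cell_max_area_px]
  lab[!(lab %in% keep)] <- 0L
  label_map(.relabel(lab), "immune")
}

#' Remove exclusion-zone pixels from instances
#'
#' Per-pixel set difference: pixels of `labels` that fall inside the
#' (typically grown) `exclusion` mask are removed before any intensity
#' measurement. Instance ids are preserved; instances losing every pixel
#' are flagged in the `"dropped"` attribute so they can be excluded from
#' MPI statistics rather than measured as empty.
#'
#' @param labels Instance [label_map()] (e.g. shrunken neurons).
#' @param exclusion [label_map()] of pixels to exclude (non-zero = exclude).
#' @return A [label_map()] with attributes `"ids"` (incoming ids) and
#'   `"dropped"` (ids with zero measurable pixels).
#' @export
exclude_overlap <- function(labels, exclusion) {
  stopifnot(inherits(labels, "drgq_labels"), inherits(exclusion, "drgq_labels"))
  if (!identical(dim(labels), dim(exclusion))) abort("shape mismatch")
  ids <- attr(labels, "ids") %||% label_ids(labels)
  lab <- labels$labels
  lab[exclusion$labels > 0L] <- 0L
  remaining <- unique(lab[lab > 0L])
  out <- label_map(lab, labels$class_name)
  attr(out, "ids") <- ids
  attr(out, "dropped") <- sort(setdiff(ids, remaining))
  out
}

#' Neuronal and non-neuronal nuclei
#'
#' DAPI components are size- and intensity-filtered, then split by
#' location: a nucleus is neuronal iff its centroid pixel lies inside a
#' neuron instance, in which case it takes that neuron's id (so nuclear
#' measurements join directly onto neuron records); all other nuclei are
#' non-neuronal (satellite glia, immune cells) and are relabeled 1..K.
#' Subtracting the non-neuronal map from neuron masks is done downstream
#' with [exclude_overlap()].
#'
#' @param stack An [image_stack()].
#' @param neurons Neuron instances from [neuron_instances()].
#' @param params,channels See [seg_params()], [channel_map()].
#' @return List with elements `neuronal` and `nonneuronal`, both
#'   [label_map()]s.
#' @export
nuclei_instances <- function(stack, neurons, params = seg_params(),
                             channels = channel_map()) {
  ch <- .role_channel(stack, channels, "dapi")
  thr <- .resolve_threshold(params$dapi_threshold, ch)
  mask <- if (identical(params$dapi_threshold, "otsu")) ch > thr else ch >= thr
  lab <- label_components(mask, params$connectivity)
  st <- .component_stats(lab, intensity = ch)
  keep <- st[st$area_px >= params$nucleus_min_area_px &
               st$area_px <= params$nucleus_max_area_px &
               st$mpi >= params$dapi_min_mpi, ]
  nlab <- neurons$labels
  nr <- nrow(nlab)
  host <- integer(nrow(keep))
  if (nrow(keep)) {
    cr <- pmin(pmax(round(keep$centroid_row), 1L), nr)
    ccol <- pmin(pmax(round(keep$centroid_col), 1L), ncol(nlab))
    host <- nlab[cbind(cr, ccol)]
  }
  neu <- matrix(0L, nr, ncol(lab))
  non <- matrix(0L, nr, ncol(lab))
  for (i in seq_len(nrow(keep))) {
    idx <- which(lab == keep$label[i])
    if (host[i] > 0L) neu[idx] <- host[i] else non[idx] <- keep$label[i]
  }
  list(neuronal = label_map(neu, "neuronal nuclei"),
       nonneuronal = label_map(.relabel(non), "non-neuronal nuclei"))
}
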