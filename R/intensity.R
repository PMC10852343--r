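#' Per-instance mean pixel intensity (MPI)
#'
#' For every instance of `labels`, computes the arithmetic mean of the
#' channel's intensities over the instance's measurable pixels (i.e. after
#' any shrink/exclusion already applied to `labels`). Instance ids that the
#' label map carries in its `"ids"` attribute but that have no remaining
#' pixels are returned with `measurable = FALSE` and `NA` MPI so they can be
#' excluded from downstream statistics rather than silently lost.
#'
#' @param stack An [image_stack()].
#' @param labels A [label_map()].
#' @param channel Channel name to measure.
#' @return A tibble with columns `object_id`, `class_name`, `channel`,
#'   `area_px`, `area_um2`, `centroid_row`, `centroid_col`, `mpi`,
#'   `measurable`.
#' @export
measure_mpi <- function(stack, labels, channel) {
  stopifnot(inherits(stack, "drgq_stack"), inherits(labels, "drgq_labels"))
  ch <- get_channel(stack, channel)
  if (!identical(dim(ch), dim(labels))) abort("labels do not match stack shape")
  st <- .component_stats(labels$labels, intensity = ch)
  all_ids <- sort(union(attr(labels, "ids") %||% integer(0), st$label))
  if (!length(all_ids)) {
    abort("label map has no instances to measure")
  }
  out <- tibble(object_id = all_ids,
                class_name = labels$class_name,
                channel = channel)
  m <- match(all_ids, st$label)
  out$area_px <- ifelse(is.na(m), 0L, st$area_px[m])
  out$area_um2 <- out$area_px * stack$pixel_area_um2
  out$centroid_row <- st$centroid_row[m]
  out$centroid_col <- st$centroid_col[m]
  out$mpi <- st$mpi[m]
  out$measurable <- !is.na(m)
  out
}

#' Positivity threshold from isotype-control sections
#'
#' The per-object MPI distribution measured on sections stained with an
#' isotype-control antibody (no specific signal) defines the positivity
#' threshold as its 99th percentile. The percentile uses linear
#' interpolation between order statistics (the "type 7" convention,
#' position `1 + 0.99 * (n - 1)`), fixed for reproducibility; the statistic
#' is order-free in the reference records.
#'
#' @param isotype_records MPI records from [measure_mpi()] run on
#'   isotype-stained sections (only `measurable` rows are used).
#' @param rule_name Name of the classification rule this threshold feeds
#'   (becomes the flag column name downstream).
#' @param probs Percentile to use, default 0.99.
#' @return A `drgq_threshold` model with fields `rule_name`,
#'   `threshold_afu`, `provenance = "isotype_p99"`, `n_reference`.
#' @export
isotype_threshold <- function(isotype_records, rule_name = "mhcii_positive",
                              probs = 0.99) {
  if (!is.data.frame(isotype_records) || !"mpi" %in% names(isotype_records)) {
    abort("`isotype_records` must be a measurement table with an `mpi` column")
  }
  mpis <- isotype_records$mpi
  if ("measurable" %in% names(isotype_records)) {
    mpis <- mpis[isotype_records$measurable]
  }
  mpis <- mpis[!is.na(mpis)]
  if (!length(mpis)) abort("empty isotype reference set")
  if (length(mpis) < 20) {
    warn(sprintf("only %d isotype reference objects; percentile threshold is unstable below 20",
                 length(mpis)))
  }
  structure(list(rule_name = rule_name,
                 threshold_afu = unname(quantile(mpis, probs, type = 7)),
                 provenance = "isotype_p99",
                 n_reference = length(mpis)),
            class = "drgq_threshold")
}

#' Fixed AFU threshold
#'
#' A classification threshold fixed by configuration rather than derived
#' from an isotype reference, e.g. the nuclear RFX1 cutoff of 37.19 AFU.
#'
#' @param threshold_afu Threshold value (AFU), must be >= 0.
#' @param rule_name Rule name, see [isotype_threshold()].
#' @return A `drgq_threshold` model with `provenance = "fixed"`.
#' @export
fixed_threshold <- function(threshold_afu, rule_name) {
  if (!is.numeric(threshold_afu) || threshold_afu < 0) {
    abort("`threshold_afu` must be a non-negative number")
  }
  structure(list(rule_name = rule_name, threshold_afu = threshold_afu,
                 provenance = "fixed", n_reference = 0L),
            class = "drgq_threshold")
}

#' @export
print.drgq_threshold <- function(x, ...) {
  cat(sprintf("<drgq_threshold> %s: MPI > %.4g AFU (%s%s)\n", x$rule_name,
              x$threshold_afu, x$provenance,
              if (x$n_reference > 0) sprintf(", n = %d", x$n_reference) else ""))
  invisible(x)
}

#' @method tidy drgq_threshold
#' @export
tidy.drgq_threshold <- function(x, ...) {
  tibble(term = x$rule_name, estimate = x$threshold_afu,
         provenance = x$provenance, n_reference = x$n_reference)
}

#' @method glance drgq_threshold
#' @export
glance.drgq_threshold <- function(x, ...) {
  tibble(rule_name = x$rule_name, threshold_afu = x$threshold_afu,
         provenance = x$provenance, n_reference = x$n_reference)
}

#' Classify objects against an intensity threshold
#'
#' Flags each measurable record positive iff its MPI strictly exceeds the
#' model threshold (strict ">", matching the published comparator
#' "MPI > 37.19"; an object whose MPI equals the threshold is negative).
#' Unmeasurable records get `NA` and are excluded from the positive
#' fraction.
#'
#' @param records A measurement table from [measure_mpi()].
#' @param model A `drgq_threshold` from [isotype_threshold()] or
#'   [fixed_threshold()].
#' @param flag Name of the logical flag column to add; defaults to the
#'   model's `rule_name`.
#' @return `records` with the flag column added; the attribute
#'   `"positive_fraction"` carries the fraction of measurable objects
#'   flagged positive (see [positive_fraction()]).
#' @export
classify_positive <- function(records, model, flag = model$rule_name) {
  stopifnot(inherits(model, "drgq_threshold"))
  if (!"mpi" %in% names(records)) abort("`records` must carry an `mpi` column")
  measurable <- if ("measurable" %in% names(records)) records$measurable else !is.na(records$mpi)
  pos <- ifelse(measurable, records$mpi > model$threshold_afu, NA)
  records[[flag]] <- pos
  attr(records, "positive_fraction") <- mean(pos[measurable])
  records
}

#' Fraction of measurable objects flagged positive
#'
#' @param records Output of [classify_positive()].
#' @param flag Flag column name.
#' @return Proportion in `[0, 1]` (NaN if nothing is measurable).
#' @export
positive_fraction <- function(records, flag = "mhcii_positive") {
  f <- records[[flag]]
  if (is.null(f)) abort(sprintf("no flag column '%s'", flag))
  mean(f, na.rm = TRUE)
}

#' Identify CD3+CD4+ T cells inside neuron-containing tissue
#'
#' CD3 and CD4 components are detected independently (pixel threshold,
#' connected components, immune-cell size gate, minimum MPI). A CD3
#' component counts as a CD4+ T cell iff at least `cd4_overlap_frac`
#' (default 50%) of its pixels fall inside CD4+ components -- a tolerant
#' double-positivity rule that survives small channel registration error --
#' and its centroid lies inside the tissue mask.
#'
#' @param stack An [image_stack()].
#' @param tissue Tissue mask from [tissue_mask()].
#' @param params,channels See [seg_params()], [channel_map()].
#' @return A tibble of T-cell records (`object_id`, `area_px`, `area_um2`,
#'   `centroid_row`, `centroid_col`, `mpi_cd3`, `mpi_cd4`,
#'   `cd4_overlap`). The attribute `"n_cd3_candidates"` counts all CD3
#'   components that passed the size/intensity gates.
#' @export
find_cd4_tcells <- function(stack, tissue, params = seg_params(),
                            channels = channel_map()) {
  cd3 <- .role_channel(stack, channels, "cd3")
  cd4 <- .role_channel(stack, channels, "cd4")
  stopifnot(inherits(tissue, "drgq_labels"))
  gate <- function(ch, thr_param, min_mpi) {
    thr <- .resolve_threshold(thr_param, ch)
    mask <- if (identical(thr_param, "otsu")) ch > thr else ch >= thr
    lab <- label_components(mask, params$connectivity)
    st <- .component_stats(lab, intensity = ch)
    keep <- st$label[st$area_px >= params$immune_cell_min_area_px &
                       st$area_px <= params$immune_cell_max_area_px &
                       st$mpi >= min_mpi]
    lab[!(lab %in% keep)] <- 0L
    lab
  }
  cd3_lab <- gate(cd3, params$cd3_threshold, params$cd3_min_mpi)
  cd4_lab <- gate(cd4, params$cd4_threshold, params$cd4_min_mpi)
  st <- .component_stats(cd3_lab, intensity = cd3)
  n_candidates <- nrow(st)
  if (!nrow(st)) {
    out <- tibble(object_id = integer(), area_px = integer(),
                  area_um2 = numeric(), centroid_row = numeric(),
                  centroid_col = numeric(), mpi_cd3 = numeric(),
                  mpi_cd4 = numeric(), cd4_overlap = numeric())
    attr(out, "n_cd3_candidates") <- 0L
    return(out)
  }
  nr <- nrow(cd3_lab)
  cd4_bin <- cd4_lab > 0L
  overlap <- vapply(st$label, function(id) {
    idx <- which(cd3_lab == id)
    mean(cd4_bin[idx])
  }, numeric(1))
  mpi_cd4 <- vapply(st$label, function(id) mean(cd4[cd3_lab == id]), numeric(1))
  cr <- pmin(pmax(round(st$centroid_row), 1L), nr)
  ccol <- pmin(pmax(round(st$centroid_col), 1L), ncol(cd3_lab))
  in_tissue <- tissue$labels[cbind(cr, ccol)] > 0L
  keep <- overlap >= params$cd4_overlap_frac & in_tissue
  out <- tibble(object_id = seq_len(sum(keep)),
                area_px = st$area_px[keep],
                area_um2 = st$area_px[keep] * stack$pixel_area_um2,
                centroid_row = st$centroid_row[keep],
                centroid_col = st$centroid_col[keep],
                mpi_cd3 = st$mpi[keep],
                mpi_cd4 = mpi_cd4[keep],
                cd4_overlap = overlap[keep])
  attr(out, "n_cd3_candidates") <- n_candidates
  out
}

#' CD4+ T-cell density per mm^2 of neuron-containing tissue
#'
#' Density is the pooled ratio: total cells divided by total tissue area.
#' With multi-section input (vectors of per-section counts and areas),
#' counts and areas are summed before dividing -- the unbiased choice for
#' unequal section areas -- rather than averaging per-section densities.
#'
#' @param tcells Either a T-cell record table ([find_cd4_tcells()] output)
#'   or a numeric vector of per-section cell counts.
#' @param tissue Either a tissue [label_map()] or a numeric vector of
#'   per-section tissue areas in pixels.
#' @param pixel_area_um2 Pixel footprint, um^2/px.
#' @return Density in cells per mm^2.
#' @export
tcell_density <- function(tcells, tissue, pixel_area_um2 = 6.718) {
  n <- if (is.data.frame(tcells)) nrow(tcells) else sum(tcells)
  area_px <- if (inherits(tissue, "drgq_labels")) label_area_px(tissue) else sum(tissue)
  if (length(area_px) == 0 || area_px <= 0) abort("zero tissue area")
  area_mm2 <- area_px * pixel_area_um2 * 1e-6
  n / area_mm2
}
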