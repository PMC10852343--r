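#' Bundle of all pipeline parameters
#'
#' @param pixel_area_um2 Pixel footprint used to derive size gates and the
#'   area-to-diameter conversion.
#' @param seg,puncta,morph Module parameter sets; defaults are built from
#'   `pixel_area_um2`.
#' @param rfx1_threshold Fixed nuclear RFX1 positivity cutoff (AFU,
#'   strict ">"); default 37.19.
#' @param channels [channel_map()].
#' @return A list of class `drgq_params`.
#' @export
drgq_params <- function(pixel_area_um2 = 6.718,
                        seg = seg_params(pixel_area_um2 = pixel_area_um2),
                        puncta = puncta_params(),
                        morph = morphometry_params(pixel_area_um2 = pixel_area_um2),
                        rfx1_threshold = 37.19,
                        channels = channel_map()) {
  structure(list(pixel_area_um2 = pixel_area_um2, seg = seg, puncta = puncta,
                 morph = morph, rfx1_threshold = rfx1_threshold,
                 channels = channels),
            class = "drgq_params")
}

#' Quantify one DRG section end to end
#'
#' Runs the full section pipeline: tissue mask; neuron instances (fiber
#' exclusion); 4-px shrink of each soma; bright non-neuronal MHCII mask
#' grown by 7 px and subtracted from the shrunken somata; per-neuron MHCII
#' MPI on the surviving pixels; puncta detection inside the measurable
#' masks; nuclei split into neuronal/non-neuronal with nuclear RFX1
#' classification (strict MPI > 37.19); CD3+CD4+ T cells gated to tissue
#' and their pooled density per mm^2. Soma diameters are computed from the
#' full (pre-shrink) instance areas and classified small/intermediate/
#' large.
#'
#' @param stack An [image_stack()].
#' @param params A [drgq_params()]; defaults are derived from the stack's
#'   pixel area.
#' @param mhcii_model Optional `drgq_threshold` from [isotype_threshold()];
#'   when supplied, neurons are flagged `mhcii_positive`.
#' @param mouse_id,section_id Identifiers copied onto every record.
#' @return A `drgq_section` list: `neurons` (per-neuron tibble), `puncta`
#'   (per-neuron puncta tibble), `tcells`, `tissue_area_px`,
#'   `tcell_density_mm2`, `masks` (tissue, neurons, measurable,
#'   nonneuronal_grown, nuclei), `params`.
#' @export
quantify_section <- function(stack, params = NULL, mhcii_model = NULL,
                             mouse_id = stack$source_id, section_id = 1L) {
  stopifnot(inherits(stack, "drgq_stack"))
  params <- params %||% drgq_params(pixel_area_um2 = stack$pixel_area_um2)
  ch <- params$channels
  tissue <- tissue_mask(stack, params$seg, ch)
  neurons <- neuron_instances(stack, params$seg, ch)

  shrunk <- shrink_mask(neurons, params$seg$shrink_px)
  nonneur <- nonneuronal_mhcii_mask(stack, params$seg, ch)
  grown <- grow_mask(nonneur, params$seg$grow_px)
  measurable <- exclude_overlap(shrunk, grown)

  rec <- measure_mpi(stack, neurons, ch$mhcii)["object_id"]
  full_stats <- .component_stats(neurons$labels)
  rec$area_px <- full_stats$area_px[match(rec$object_id, full_stats$label)]
  rec$area_um2 <- rec$area_px * stack$pixel_area_um2
  rec$centroid_row <- full_stats$centroid_row[match(rec$object_id, full_stats$label)]
  rec$centroid_col <- full_stats$centroid_col[match(rec$object_id, full_stats$label)]
  rec <- classify_size(rec, params$morph)

  mh <- measure_mpi(stack, measurable, ch$mhcii)
  rec$mhcii_mpi <- mh$mpi[match(rec$object_id, mh$object_id)]
  rec$measurable_area_px <- mh$area_px[match(rec$object_id, mh$object_id)]
  rec$measurable <- mh$measurable[match(rec$object_id, mh$object_id)]
  if (!is.null(mhcii_model)) {
    mh <- classify_positive(mh, mhcii_model, flag = "mhcii_positive")
    rec$mhcii_positive <- mh$mhcii_positive[match(rec$object_id, mh$object_id)]
  }

  pun <- detect_puncta(stack, measurable, params$puncta, channel = ch$mhcii)

  has_dapi <- !is.na(ch$dapi) && ch$dapi %in% names(stack$channels)
  has_rfx1 <- !is.na(ch$rfx1) && ch$rfx1 %in% names(stack$channels)
  nuclei <- NULL
  if (has_dapi) {
    nuclei <- nuclei_instances(stack, neurons, params$seg, ch)
    rec$has_nucleus <- rec$object_id %in% label_ids(nuclei$neuronal)
    if (has_rfx1 && any(rec$has_nucleus)) {
      rf <- measure_mpi(stack, nuclei$neuronal, ch$rfx1)
      rf <- classify_positive(rf, fixed_threshold(params$rfx1_threshold,
                                                  "rfx1_positive"))
      rec$rfx1_mpi <- rf$mpi[match(rec$object_id, rf$object_id)]
      rec$rfx1_positive <- rf$rfx1_positive[match(rec$object_id, rf$object_id)]
    } else {
      rec$rfx1_mpi <- NA_real_
      rec$rfx1_positive <- NA
    }
  }

  has_cd3 <- !is.na(ch$cd3) && ch$cd3 %in% names(stack$channels) &&
    !is.na(ch$cd4) && ch$cd4 %in% names(stack$channels)
  tcells <- NULL
  dens <- NA_real_
  if (has_cd3) {
    tcells <- find_cd4_tcells(stack, tissue, params$seg, ch)
    if (label_area_px(tissue) > 0) {
      dens <- tcell_density(tcells, tissue, stack$pixel_area_um2)
    }
    tcells$mouse_id <- mouse_id
    tcells$section_id <- section_id
  }

  rec$mouse_id <- mouse_id
  rec$section_id <- section_id
  pun$mouse_id <- mouse_id
  pun$section_id <- section_id

  structure(list(neurons = rec, puncta = pun, tcells = tcells,
                 tissue_area_px = label_area_px(tissue),
                 tcell_density_mm2 = dens,
                 masks = list(tissue = tissue, neurons = neurons,
                              measurable = measurable,
                              nonneuronal_grown = grown, nuclei = nuclei),
                 params = params, source_id = stack$source_id),
            class = "drgq_section")
}

#' @export
print.drgq_section <- function(x, ...) {
  cat(sprintf("<drgq_section> '%s': %d neuron(s), %d measurable, %s T cell(s), tissue %.3g mm^2\n",
              x$source_id, nrow(x$neurons), sum(x$neurons$measurable),
              if (is.null(x$tcells)) "no" else nrow(x$tcells),
              x$tissue_area_px * x$params$pixel_area_um2 * 1e-6))
  invisible(x)
}

#' @method glance drgq_section
#' @export
glance.drgq_section <- function(x, ...) {
  tibble(
    n_neurons = nrow(x$neurons),
    n_measurable = sum(x$neurons$measurable),
    pct_mhcii_pos = if ("mhcii_positive" %in% names(x$neurons)) {
      100 * mean(x$neurons$mhcii_positive, na.rm = TRUE)
    } else NA_real_,
    mean_puncta = mean(x$puncta$n_puncta, na.rm = TRUE),
    n_tcells = if (is.null(x$tcells)) NA_integer_ else nrow(x$tcells),
    tissue_area_mm2 = x$tissue_area_px * x$params$pixel_area_um2 * 1e-6,
    tcell_density_mm2 = x$tcell_density_mm2)
}

#' Isotype reference model from isotype-stained sections
#'
#' Runs segmentation and per-neuron MHCII MPI measurement on each
#' isotype-control stack (the same shrink/grow/exclusion logic as real
#' sections), pools the per-neuron MPIs across sections, and returns the
#' 99th-percentile threshold model.
#'
#' @param stacks A list of [image_stack()]s from isotype-stained sections.
#' @param params A [drgq_params()]; defaults derive from the first stack.
#' @return A `drgq_threshold` (see [isotype_threshold()]).
#' @export
isotype_reference <- function(stacks, params = NULL) {
  if (inherits(stacks, "drgq_stack")) stacks <- list(stacks)
  if (!length(stacks)) abort("need at least one isotype stack")
  params <- params %||% drgq_params(pixel_area_um2 = stacks[[1]]$pixel_area_um2)
  recs <- lapply(stacks, function(st) {
    sec <- quantify_section(st, params)
    tibble(mpi = sec$neurons$mhcii_mpi, measurable = sec$neurons$measurable)
  })
  isotype_threshold(bind_rows(recs))
}

#' Quantify a study: many sections against one isotype reference
#'
#' @param stacks Named list of section [image_stack()]s.
#' @param isotype_stacks List of isotype-control stacks used to derive the
#'   MHCII threshold.
#' @param params A [drgq_params()].
#' @param mouse_ids Optional vector assigning each stack to a mouse
#'   (defaults to each stack's `source_id`).
#' @return A list with `neurons`, `puncta`, `tcell_sections` (per-section
#'   counts and tissue areas), `mhcii_model`, `sections` (the individual
#'   `drgq_section` objects).
#' @export
quantify_study <- function(stacks, isotype_stacks, params = NULL,
                           mouse_ids = NULL) {
  if (inherits(stacks, "drgq_stack")) stacks <- list(stacks)
  params <- params %||% drgq_params(pixel_area_um2 = stacks[[1]]$pixel_area_um2)
  model <- isotype_reference(isotype_stacks, params)
  mouse_ids <- mouse_ids %||% vapply(stacks, function(s) s$source_id, "")
  sections <- vector("list", length(stacks))
  for (i in seq_along(stacks)) {
    sections[[i]] <- quantify_section(stacks[[i]], params, mhcii_model = model,
                                      mouse_id = mouse_ids[i], section_id = i)
  }
  tc <- bind_rows(lapply(sections, function(s) {
    tibble(mouse_id = s$neurons$mouse_id[1], section_id = s$neurons$section_id[1],
           n_tcells = if (is.null(s$tcells)) NA_integer_ else nrow(s$tcells),
           tissue_area_px = s$tissue_area_px)
  }))
  list(neurons = bind_rows(lapply(sections, function(s) s$neurons)),
       puncta = bind_rows(lapply(sections, function(s) s$puncta)),
       tcell_sections = tc,
       mhcii_model = model,
       sections = sections)
}
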