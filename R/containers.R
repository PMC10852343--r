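#' Multi-channel image stack
#'
#' The basic image container of the pipeline: a set of named 2D intensity
#' channels (arbitrary fluorescent units, AFU) that share a common height and
#' width, together with the pixel footprint in square micrometres, the
#' acquisition bit depth, and a free-text source identifier
#' (mouse/section/slide).
#'
#' All channels are stored as plain numeric matrices indexed `[row, col]`,
#' 1-based, origin at the top-left pixel. Intensities are raw stored AFU: no
#' normalization is applied anywhere in the pipeline, so AFU-denominated
#' thresholds (for example the 25,000 AFU non-neuronal cutoff) compare
#' directly against stored values.
#'
#' @param channels Named list of numeric matrices, all the same dimension.
#' @param pixel_area_um2 Area of one pixel in um^2; must be > 0.
#' @param bit_depth Integer bit depth (12, 14 or 16), or `"unbounded"` for
#'   synthetic floating-point data with no container ceiling.
#' @param source_id Free-text identifier carried through to measurement
#'   tables.
#'
#' @return An object of class `drgq_stack`.
#' @examples
#' st <- image_stack(list(PGP9.5 = matrix(0, 8, 8)), pixel_area_um2 = 1)
#' dim(st)
#' @export
image_stack <- function(channels, pixel_area_um2 = 6.718, bit_depth = 16,
                        source_id = "") {
  if (!is.list(channels) || length(channels) == 0 ||
      is.null(names(channels)) || any(!nzchar(names(channels)))) {
    abort("`channels` must be a non-empty named list of matrices.")
  }
  dims <- lapply(channels, dim)
  if (any(vapply(channels, function(m) !is.matrix(m) || !is.numeric(m), TRUE))) {
    abort("every channel must be a numeric matrix")
  }
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1) {
    abort("all channels must share identical height x width")
  }
  if (nrow(channels[[1]]) == 0 || ncol(channels[[1]]) == 0) {
    abort("degenerate 0-extent image rejected")
  }
  if (!identical(bit_depth, "unbounded")) {
    bit_depth <- as.integer(bit_depth)
    if (!bit_depth %in% c(8L, 12L, 14L, 16L)) {
      abort("`bit_depth` must be one of 8, 12, 14, 16 or \"unbounded\"")
    }
    ceiling_afu <- 2^bit_depth - 1
    rng <- range(vapply(channels, function(m) range(m), numeric(2)))
    if (rng[1] < 0 || rng[2] > ceiling_afu) {
      abort(sprintf("intensities must lie in [0, %d] for bit depth %d",
                    ceiling_afu, bit_depth))
    }
  } else if (min(vapply(channels, min, 0)) < 0) {
    abort("intensities must be non-negative")
  }
  if (!is.numeric(pixel_area_um2) || length(pixel_area_um2) != 1 ||
      !is.finite(pixel_area_um2) || pixel_area_um2 <= 0) {
    abort("`pixel_area_um2` must be a single positive number")
  }
  structure(
    list(channels = channels, pixel_area_um2 = pixel_area_um2,
         bit_depth = bit_depth, source_id = as.character(source_id)),
    class = "drgq_stack")
}

#' @export
dim.drgq_stack <- function(x) dim(x$channels[[1]])

#' @export
print.drgq_stack <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<drgq_stack> %d x %d px, %s channel(s): %s\n", d[1], d[2],
              length(x$channels), paste(names(x$channels), collapse = ", ")))
  cat(sprintf("  pixel area %.4g um^2/px, bit depth %s, source '%s'\n",
              x$pixel_area_um2, as.character(x$bit_depth), x$source_id))
  invisible(x)
}

#' Extract one channel from a stack
#'
#' @param stack A [image_stack()].
#' @param channel Channel name.
#' @return The channel's numeric matrix.
#' @export
get_channel <- function(stack, channel) {
  stopifnot(inherits(stack, "drgq_stack"))
  if (!channel %in% names(stack$channels)) {
    abort(sprintf("channel '%s' not present (have: %s)", channel,
                  paste(names(stack$channels), collapse = ", ")))
  }
  stack$channels[[channel]]
}

#' Integer-labeled instance mask
#'
#' A `drgq_labels` object is an integer matrix aligned to an [image_stack()]
#' in which 0 is background and positive integers identify object instances.
#' Freshly produced label maps carry contiguous labels `1..K`; operations
#' that remove pixels from existing instances ([exclude_overlap()],
#' [shrink_mask()]) preserve the incoming instance ids so measurements can be
#' joined back, and record fully-removed ids in the `"dropped"` attribute.
#'
#' @param labels Integer matrix, non-negative; 0 is background.
#' @param class_name What the instances are (e.g. "neuron", "tissue",
#'   "nucleus", "immune").
#' @return An object of class `drgq_labels`.
#' @export
label_map <- function(labels, class_name = "object") {
  if (!is.matrix(labels) || !is.numeric(labels)) {
    abort("`labels` must be a numeric matrix")
  }
  if (any(labels < 0) || any(labels != floor(labels))) {
    abort("labels must be non-negative integers (0 = background)")
  }
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, class_name = as.character(class_name)),
            class = "drgq_labels")
}

#' @export
dim.drgq_labels <- function(x) dim(x$labels)

#' @export
print.drgq_labels <- function(x, ...) {
  ids <- label_ids(x)
  cat(sprintf("<drgq_labels> '%s': %d x %d px, %d instance(s)\n",
              x$class_name, nrow(x$labels), ncol(x$labels), length(ids)))
  invisible(x)
}

#' Instance ids present in a label map
#'
#' @param labels A [label_map()].
#' @return Sorted integer vector of instance ids with at least one pixel.
#' @export
label_ids <- function(labels) {
  stopifnot(inherits(labels, "drgq_labels"))
  v <- labels$labels
  sort(unique(v[v > 0L]))
}

#' Total foreground area of a label map, in pixels
#'
#' @param labels A [label_map()].
#' @return Number of pixels with a non-zero label.
#' @export
label_area_px <- function(labels) {
  stopifnot(inherits(labels, "drgq_labels"))
  sum(labels$labels > 0L)
}

# relabel foreground to contiguous 1..K, keeping raster (column-major) order
# of first occurrence so the result is deterministic
.relabel <- function(lab) {
  v <- lab[lab > 0L]
  if (!length(v)) return(lab)
  ids <- unique(v)            # order of first occurrence in column-major scan
  lab[lab > 0L] <- match(v, ids)
  storage.mode(lab) <- "integer"
  lab
}

#' Stain-role to channel-name bindings
#'
#' Maps the pipeline's stain roles to the channel names used in a given
#' acquisition. Every role referenced by a requested stage must be bound;
#' unused roles may be `NA`.
#'
#' @param neuron_marker,mhcii,cd3,cd4,dapi,rfx1,ova Channel names.
#' @return Named list of class `drgq_channels`.
#' @export
channel_map <- function(neuron_marker = "PGP9.5", mhcii = "MHCII",
                        cd3 = "CD3", cd4 = "CD4", dapi = "DAPI",
                        rfx1 = "RFX1", ova = "OVA") {
  structure(list(neuron_marker = neuron_marker, mhcii = mhcii, cd3 = cd3,
                 cd4 = cd4, dapi = dapi, rfx1 = rfx1, ova = ova),
            class = "drgq_channels")
}

.role_channel <- function(stack, channels, role) {
  nm <- channels[[role]]
  if (is.null(nm) || is.na(nm)) {
    abort(sprintf("stain role '%s' is not bound to a channel", role))
  }
  get_channel(stack, nm)
}
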