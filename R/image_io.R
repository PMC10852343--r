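#' Read a multi-page TIFF into an image stack
#'
#' Reads a multi-page (or single-page multi-sample) grayscale TIFF and names
#' the pages according to `channels`. Integer data are read as stored
#' (`as.is`), so a 14-bit-valued image in a 16-bit container keeps its raw
#' AFU values. If a metadata sidecar written by [write_image()] sits next to
#' the file (`<path>.yml`), channel names, pixel area, bit depth and source
#' id are taken from it; arguments act as fallbacks.
#'
#' @param path TIFF file path.
#' @param channels Character vector naming the pages, in page order. Ignored
#'   when a sidecar is present.
#' @param pixel_area_um2,bit_depth,source_id Metadata fallbacks when no
#'   sidecar is present; see [image_stack()].
#' @return An [image_stack()].
#' @export
read_image <- function(path, channels = NULL, pixel_area_um2 = 6.718,
                       bit_depth = 16, source_id = basename(path)) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  sidecar <- paste0(path, ".yml")
  meta <- if (file.exists(sidecar)) yaml::read_yaml(sidecar) else NULL
  if (!is.null(meta)) {
    channels <- unlist(meta$channels) %||% channels
    pixel_area_um2 <- meta$pixel_area_um2 %||% pixel_area_um2
    bit_depth <- meta$bit_depth %||% bit_depth
    source_id <- meta$source_id %||% source_id
  }
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  # single-page multi-sample TIFF: split samples into channels
  if (length(pages) == 1 && length(dim(pages[[1]])) == 3) {
    arr <- pages[[1]]
    pages <- lapply(seq_len(dim(arr)[3]), function(i) arr[, , i])
  }
  bad <- which(vapply(pages, function(p) length(dim(p)) != 2, TRUE))
  if (length(bad)) {
    abort(sprintf("page %d is not a grayscale 2D image", bad[1]))
  }
  if (is.null(channels)) {
    channels <- paste0("ch", seq_along(pages))
  }
  if (length(pages) != length(channels)) {
    abort(sprintf("channel-count mismatch: TIFF has %d page(s), %d name(s) given",
                  length(pages), length(channels)))
  }
  names(pages) <- channels
  image_stack(pages, pixel_area_um2 = pixel_area_um2, bit_depth = bit_depth,
              source_id = source_id)
}

#' Write an image stack as a multi-page TIFF
#'
#' Channels are written as 16-bit grayscale pages (or 32-bit float for
#' `bit_depth = "unbounded"`), one page per channel in stack order, and the
#' stack metadata (channel names, pixel area, bit depth, source id) goes to a
#' YAML sidecar `<path>.yml` so that `read_image(write_image(x))` is the
#' identity on both pixel data and metadata.
#'
#' @param stack An [image_stack()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_image <- function(stack, path) {
  stopifnot(inherits(stack, "drgq_stack"))
  unbounded <- identical(stack$bit_depth, "unbounded")
  pages <- lapply(stack$channels, function(m) {
    if (unbounded) m else m / 65535
  })
  bits <- if (unbounded) 32L else 16L
  ok <- try(tiff::writeTIFF(unname(pages), path, bits.per.sample = bits),
            silent = TRUE)
  if (inherits(ok, "try-error")) {
    abort(sprintf("could not write TIFF at '%s'", path))
  }
  yaml::write_yaml(
    list(channels = as.list(names(stack$channels)),
         pixel_area_um2 = stack$pixel_area_um2,
         bit_depth = stack$bit_depth,
         source_id = stack$source_id),
    paste0(path, ".yml"))
  invisible(path)
}

#' Write a label map as a 16-bit TIFF label image
#'
#' @param labels A [label_map()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_label_map <- function(labels, path) {
  stopifnot(inherits(labels, "drgq_labels"))
  if (max(labels$labels) > 65535) abort("more than 65535 labels")
  tiff::writeTIFF(labels$labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a label image written by [write_label_map()]
#'
#' @param path TIFF path.
#' @param class_name Instance class of the map.
#' @return A [label_map()].
#' @export
read_label_map <- function(path, class_name = "object") {
  m <- tiff::readTIFF(path, as.is = TRUE)
  label_map(m, class_name)
}

#' Write a measurement table to CSV
#'
#' One row per object, header included, stable column order. Doubles are
#' written with shortest round-trip precision, so a written-then-parsed
#' table equals the source values exactly. List columns (e.g. nested puncta
#' component tables) are dropped with a message, since they have no flat CSV
#' representation.
#'
#' @param records A data frame of per-object records sharing one schema.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  if (!is.data.frame(records)) abort("`records` must be a data frame")
  is_list <- vapply(records, is.list, TRUE)
  if (any(is_list)) {
    message("dropping list column(s): ",
            paste(names(records)[is_list], collapse = ", "))
    records <- records[!is_list]
  }
  readr::write_csv(records, path, progress = FALSE)
  invisible(path)
}

#' Read a measurement table written by [write_records()]
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_records <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Read a pipeline configuration file
#'
#' A YAML file with optional blocks `channels` (stain-role to channel-name
#' bindings, see [channel_map()]), `segmentation`, `puncta`, `morphometry`
#' (parameter overrides for [seg_params()], [puncta_params()],
#' [morphometry_params()]) and top-level scalars `pixel_area_um2`,
#' `rfx1_threshold` and `isotype` (logical flag marking isotype-control
#' images).
#'
#' @param path YAML file path.
#' @return A list with elements `channels`, `seg`, `puncta`, `morph`,
#'   `pixel_area_um2`, `rfx1_threshold`, `isotype`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  y <- yaml::read_yaml(path)
  pa <- y$pixel_area_um2 %||% 6.718
  list(
    channels = do.call(channel_map, y$channels %||% list()),
    seg = do.call(seg_params, c(list(pixel_area_um2 = pa),
                                y$segmentation %||% list())),
    puncta = do.call(puncta_params, y$puncta %||% list()),
    morph = do.call(morphometry_params, c(list(pixel_area_um2 = pa),
                                          y$morphometry %||% list())),
    pixel_area_um2 = pa,
    rfx1_threshold = y$rfx1_threshold %||% 37.19,
    isotype = isTRUE(y$isotype))
}
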