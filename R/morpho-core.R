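# Low-level raster primitives: exact Euclidean-disc morphology and
# 8/4-connected component labeling. Written in-package because the
# shrink/grow contract is defined against a Euclidean-distance oracle
# (a pixel survives erosion by radius k iff every pixel within Euclidean
# distance <= k of it is foreground; pixels outside the image count as
# background) and because component connectivity must be selectable.

# integer offsets (dr, dc) with dr^2 + dc^2 <= k^2
.disc_offsets <- function(k) {
  k <- as.integer(k)
  g <- expand.grid(dr = -k:k, dc = -k:k)
  as.matrix(g[g$dr^2 + g$dc^2 <= k^2, , drop = FALSE])
}

# s[r, c] <- m[r + dr, c + dc], out-of-bounds filled with `fill`
.shift_mat <- function(m, dr, dc, fill = FALSE) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  r1 <- max(1L, 1L - dr); r2 <- min(nr, nr - dr)
  c1 <- max(1L, 1L - dc); c2 <- min(nc, nc - dc)
  if (r1 <= r2 && c1 <= c2) {
    rs <- r1:r2; cs <- c1:c2
    out[rs, cs] <- m[rs + dr, cs + dc]
  }
  out
}

# binary erosion by a Euclidean disc of radius k (outside image = background)
.erode_disc <- function(mask, k) {
  if (k == 0) return(mask)
  offs <- .disc_offsets(k)
  out <- mask
  for (i in seq_len(nrow(offs))) {
    if (offs[i, 1] == 0 && offs[i, 2] == 0) next
    out <- out & .shift_mat(mask, offs[i, 1], offs[i, 2], fill = FALSE)
    if (!any(out)) break
  }
  out
}

# binary dilation by a Euclidean disc of radius k
.dilate_disc <- function(mask, k) {
  if (k == 0) return(mask)
  offs <- .disc_offsets(k)
  out <- mask
  for (i in seq_len(nrow(offs))) {
    if (offs[i, 1] == 0 && offs[i, 2] == 0) next
    out <- out | .shift_mat(mask, offs[i, 1], offs[i, 2], fill = FALSE)
  }
  out
}

.neighbor_offsets <- function(connectivity) {
  if (connectivity == 8) {
    cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
          dc = c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else if (connectivity == 4) {
    cbind(dr = c(-1, 1, 0, 0), dc = c(0, 0, -1, 1))
  } else {
    abort("connectivity must be 4 or 8")
  }
}

#' Label connected components of a binary mask
#'
#' Breadth-first flood fill over the foreground pixels. Components are
#' numbered 1..K in raster (column-major) order of their first pixel, so the
#' labeling is deterministic.
#'
#' @param mask Logical or 0/1 numeric matrix.
#' @param connectivity 8 (default) or 4.
#' @return Integer matrix of component labels, 0 = background.
#' @export
label_components <- function(mask, connectivity = 8) {
  if (!is.matrix(mask)) abort("`mask` must be a matrix")
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  fg <- which(mask != 0)
  if (!length(fg)) return(lab)
  offs <- .neighbor_offsets(connectivity)
  inmask <- matrix(FALSE, nr, nc)
  inmask[fg] <- TRUE
  k <- 0L
  for (s in fg) {
    if (lab[s] != 0L) next
    k <- k + 1L
    lab[s] <- k
    frontier <- s
    while (length(frontier)) {
      r <- (frontier - 1L) %% nr + 1L
      cc <- (frontier - 1L) %/% nr + 1L
      nxt <- integer(0)
      for (i in seq_len(nrow(offs))) {
        rr <- r + offs[i, 1]; c2 <- cc + offs[i, 2]
        ok <- rr >= 1L & rr <= nr & c2 >= 1L & c2 <= nc
        if (any(ok)) nxt <- c(nxt, (c2[ok] - 1L) * nr + rr[ok])
      }
      nxt <- unique(nxt)
      nxt <- nxt[inmask[nxt] & lab[nxt] == 0L]
      lab[nxt] <- k
      frontier <- nxt
    }
  }
  lab
}

# per-component area, centroid, optional intensity statistics and second
# moments; rows ordered by ascending label id
.component_stats <- function(lab, intensity = NULL, moments = FALSE) {
  idx <- which(lab > 0L)
  empty <- tibble(label = integer(), area_px = integer(),
                  centroid_row = numeric(), centroid_col = numeric())
  if (!length(idx)) {
    if (!is.null(intensity)) empty$mpi <- numeric(0)
    if (moments) {
      empty$eccentricity <- numeric(0); empty$axis_ratio <- numeric(0)
    }
    return(empty)
  }
  l <- lab[idx]
  nr <- nrow(lab)
  r <- (idx - 1L) %% nr + 1L
  cc <- (idx - 1L) %/% nr + 1L
  ids <- sort(unique(l))
  m <- match(l, ids)
  area <- tabulate(m, length(ids))
  sum_r <- unname(rowsum(r, m)[, 1])
  sum_c <- unname(rowsum(cc, m)[, 1])
  out <- tibble(label = as.integer(ids), area_px = as.integer(area),
                centroid_row = sum_r / area, centroid_col = sum_c / area)
  if (!is.null(intensity)) {
    out$mpi <- unname(rowsum(intensity[idx], m)[, 1]) / area
  }
  if (moments) {
    mu_r <- out$centroid_row[m]; mu_c <- out$centroid_col[m]
    m20 <- unname(rowsum((r - mu_r)^2, m)[, 1]) / area
    m02 <- unname(rowsum((cc - mu_c)^2, m)[, 1]) / area
    m11 <- unname(rowsum((r - mu_r) * (cc - mu_c), m)[, 1]) / area
    tr2 <- (m20 + m02) / 2
    det <- sqrt(((m20 - m02) / 2)^2 + m11^2)
    l1 <- tr2 + det
    l2 <- pmax(tr2 - det, 0)
    out$eccentricity <- ifelse(l1 > 0, sqrt(pmax(1 - l2 / l1, 0)), 0)
    out$axis_ratio <- ifelse(l2 > 0, sqrt(l1 / l2), Inf)
  }
  out
}

# Otsu threshold wrapper; returns a value t such that `v > t` separates the
# foreground. Degenerate (constant) inputs yield an empty foreground.
.otsu <- function(v, levels = 1024) {
  mx <- max(v); mn <- min(v)
  if (mx <= mn) return(mx)
  t01 <- EBImage::otsu(EBImage::Image(v / mx), range = c(0, 1),
                       levels = levels)
  t01 * mx
}

# resolve a threshold parameter: numeric AFU pass through, "otsu" computes
.resolve_threshold <- function(param, v) {
  if (identical(param, "otsu")) .otsu(v) else as.numeric(param)
}
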