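# Independent brute-force oracles, deliberately written without the
# package's raster primitives.

# Erosion oracle straight from the definition: a pixel survives iff every
# pixel within Euclidean distance <= k is foreground (outside the image is
# background). Computed as min squared distance to any background pixel,
# with a one-pixel background border representing the outside.
oracle_erode <- function(mask, k) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- mask
  fg <- which(pad)
  bg <- which(!pad)
  if (!length(fg)) return(mask & FALSE)
  fr <- (fg - 1) %% (nr + 2) + 1; fc <- (fg - 1) %/% (nr + 2) + 1
  br <- (bg - 1) %% (nr + 2) + 1; bc <- (bg - 1) %/% (nr + 2) + 1
  d2 <- outer(fr, br, `-`)^2 + outer(fc, bc, `-`)^2
  keep <- apply(d2, 1, min) > k^2
  out <- matrix(FALSE, nr + 2, nc + 2)
  out[fg[keep]] <- TRUE
  out[2:(nr + 1), 2:(nc + 1)]
}

# Dilation oracle: a pixel is set iff some foreground pixel lies within
# Euclidean distance <= k.
oracle_dilate <- function(mask, k) {
  nr <- nrow(mask); nc <- ncol(mask)
  fg <- which(mask)
  if (!length(fg)) return(mask)
  all_idx <- seq_len(nr * nc)
  ar <- (all_idx - 1) %% nr + 1; ac <- (all_idx - 1) %/% nr + 1
  fr <- (fg - 1) %% nr + 1; fc <- (fg - 1) %/% nr + 1
  d2 <- outer(ar, fr, `-`)^2 + outer(ac, fc, `-`)^2
  matrix(apply(d2, 1, min) <= k^2, nr, nc)
}

# Component labeling oracle: iterative minimum-neighbor propagation until a
# fixed point (no flood fill, no package code).
oracle_label <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  lab[mask] <- seq_len(sum(mask))
  offs <- if (connectivity == 8) {
    list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1), c(0, 1), c(1, -1),
         c(1, 0), c(1, 1))
  } else list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  shift0 <- function(m, dr, dc) {
    out <- matrix(0L, nr, nc)
    rs <- max(1, 1 - dr):min(nr, nr - dr)
    cs <- max(1, 1 - dc):min(nc, nc - dc)
    if (rs[1] <= rs[length(rs)]) out[rs, cs] <- m[rs + dr, cs + dc]
    out
  }
  repeat {
    nxt <- lab
    for (o in offs) {
      s <- shift0(lab, o[1], o[2])
      upd <- mask & s > 0L & (nxt == 0L | s < nxt)
      nxt[upd] <- s[upd]
    }
    if (identical(nxt, lab)) break
    lab <- nxt
  }
  # normalize to contiguous ids by first occurrence
  v <- lab[lab > 0L]
  lab[lab > 0L] <- match(v, unique(v))
  lab
}

# Puncta detection oracle: median background, per-pixel >= bg + delta gate,
# labeling by oracle_label, integer area gate. Returns the sorted pixel sets.
oracle_puncta_pixels <- function(ch, inst_mask, delta, min_area) {
  bg <- median(ch[inst_mask])
  supra <- inst_mask & ch >= bg + delta
  lab <- oracle_label(supra, 8)
  ids <- setdiff(unique(as.vector(lab)), 0L)
  sets <- lapply(ids, function(id) sort(which(lab == id)))
  sets <- sets[vapply(sets, length, 1L) >= ceiling(min_area)]
  # canonical order by first pixel
  sets[order(vapply(sets, function(s) s[1], 1L))]
}

# random blob mask: union of a few random discs on an h x w frame
random_blob_mask <- function(h, w, n_discs = 3, r_max = 8) {
  m <- matrix(FALSE, h, w)
  for (i in seq_len(n_discs)) {
    cy <- runif(1, 1, h); cx <- runif(1, 1, w); r <- runif(1, 1, r_max)
    rows <- matrix(seq_len(h), h, w)
    cols <- matrix(seq_len(w), h, w, byrow = TRUE)
    m <- m | ((rows - cy)^2 + (cols - cx)^2 <= r^2)
  }
  m
}
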