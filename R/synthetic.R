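#' Scene specification for synthetic ground-truth images
#'
#' Defines the study conditions a synthetic DRG scene emulates: a band of
#' neuron-containing tissue holding a bimodal population of near-circular
#' somata (small, mean 18 um, truncated to (8, 25]; large, mean 38 um,
#' truncated to (30, 60]), a fraction of which express diffuse somatic
#' MHCII plus discrete interior puncta; bright compact non-neuronal immune
#' cells whose MHCII runs far above the neuronal level; CD3+CD4+ T cells
#' (plus CD3-only distractors); DAPI nuclei -- one per cell plus satellite
#' nuclei pressed against neuron borders; and an RFX1 nuclear signal.
#' Rendering is binary (filled rotated ellipses for somata, discs for the
#' rest) with additive Gaussian read noise clipped to the container range,
#' so every planted object's rendered pixel area is exact in the noiseless
#' limit.
#'
#' The default pixel footprint is 1 um^2/px (about a 40x widefield
#' acquisition after binning). At this scale the pixel-denominated pipeline
#' parameters (4-px shrink, 7-px grow, 2-px puncta) span roughly 1-7 um,
#' matching the satellite-glia rim and sub-cellular spots they are meant to
#' capture.
#'
#' @param image_size Frame height = width, px.
#' @param pixel_area_um2 um^2 per pixel.
#' @param bit_depth Container bit depth (intensities are clipped to it).
#' @param n_neurons_small,n_neurons_large Somata counts.
#' @param small_diam_mean_um,small_diam_sd_um Small-diameter normal, um,
#'   truncated to (8, 25].
#' @param large_diam_mean_um,large_diam_sd_um Large-diameter normal, um,
#'   truncated to (30, 60].
#' @param neuron_marker_intensity PGP9.5 AFU over somata.
#' @param tissue_intensity PGP9.5 AFU of the diffuse tissue (neuropil)
#'   band.
#' @param neuron_mhcii_base Diffuse somatic MHCII AFU on positive neurons.
#' @param frac_mhcii_pos Fraction of neurons planted MHCII-positive.
#' @param puncta_per_pos_neuron Integer range `c(min, max)` of puncta
#'   planted per positive neuron (capacity permitting).
#' @param puncta_area_px Integer range of per-punctum pixel areas (>= 2).
#' @param puncta_delta AFU added above the somatic base inside puncta.
#' @param n_immune Bright non-neuronal MHCII cells.
#' @param immune_mhcii_intensity Their MHCII AFU (>= 5x the neuronal base).
#' @param immune_diam_um Their diameter.
#' @param n_tcells CD3+CD4+ cells; `n_cd3_only` CD3-only distractors.
#' @param tcell_intensity CD3/CD4 AFU on T cells.
#' @param tcell_diam_um T-cell diameter.
#' @param nucleus_diam_um Neuronal/satellite nucleus diameter.
#' @param dapi_intensity DAPI AFU inside nuclei.
#' @param n_satellite Satellite (perisomatic, non-neuronal) nuclei.
#' @param frac_rfx1_pos Fraction of neurons whose nucleus is RFX1+.
#' @param rfx1_pos_intensity,rfx1_neg_intensity Nuclear RFX1 AFU for
#'   positive / negative nuclei (the RFX1 channel is a low-AFU confocal
#'   scale; its cutoff is 37.19).
#' @param rfx1_noise_sd Read-noise SD of the RFX1 channel (its own scale).
#' @param n_culture_neurons Somata per cultured-neuron (ICC) scene.
#' @param culture_diam_mean_um,culture_diam_sd_um Cultured soma diameters.
#' @param frac_polarized Fraction of cultured neurons with a polarized cap.
#' @param polar_cap_fraction Target fraction of soma area in the cap.
#' @param polar_fold_planted Cap intensity as a fold over the soma surface
#'   base (must exceed the 1.7 detection fold to be recoverable).
#' @param ova_intensity Surface OVA-peptide AFU base.
#' @param tissue_fraction Fraction of the frame covered by the tissue band.
#' @param noise_sd Read-noise SD (AFU) for all 14-bit-scale channels.
#' @param seed Integer seed; one seed drives the entire scene.
#' @return A list of class `drgq_scene_spec`.
#' @export
scene_spec <- function(image_size = 512, pixel_area_um2 = 1.0, bit_depth = 16,
                       n_neurons_small = 35, n_neurons_large = 15,
                       small_diam_mean_um = 18, small_diam_sd_um = 3,
                       large_diam_mean_um = 38, large_diam_sd_um = 4,
                       neuron_marker_intensity = 12000, tissue_intensity = 500,
                       neuron_mhcii_base = 4000, frac_mhcii_pos = 0.30,
                       puncta_per_pos_neuron = c(2L, 4L),
                       puncta_area_px = c(3L, 6L), puncta_delta = 1200,
                       n_immune = 6, immune_mhcii_intensity = 30000,
                       immune_diam_um = 10,
                       n_tcells = 12, n_cd3_only = 5, tcell_intensity = 8000,
                       tcell_diam_um = 8,
                       nucleus_diam_um = 8, dapi_intensity = 6000,
                       n_satellite = 10,
                       frac_rfx1_pos = 0.5, rfx1_pos_intensity = 300,
                       rfx1_neg_intensity = 10, rfx1_noise_sd = 8,
                       n_culture_neurons = 8, culture_diam_mean_um = 25,
                       culture_diam_sd_um = 4,
                       frac_polarized = 0.5, polar_cap_fraction = 0.10,
                       polar_fold_planted = 2.0, ova_intensity = 3000,
                       tissue_fraction = 0.5, noise_sd = 100, seed = 1L) {
  spec <- as.list(environment())
  counts <- c("n_neurons_small", "n_neurons_large", "n_immune", "n_tcells",
              "n_cd3_only", "n_satellite", "n_culture_neurons")
  if (any(unlist(spec[counts]) < 0)) abort("counts must be >= 0")
  fr <- c("frac_mhcii_pos", "frac_rfx1_pos", "frac_polarized",
          "tissue_fraction", "polar_cap_fraction")
  if (any(unlist(spec[fr]) < 0 | unlist(spec[fr]) > 1)) {
    abort("fractions must lie in [0, 1]")
  }
  if (spec$polar_cap_fraction >= 0.5) {
    abort("`polar_cap_fraction` must be < 0.5 (the cap must not dominate the median background)")
  }
  if (min(puncta_area_px) < 2) abort("`puncta_area_px` must be >= 2")
  if (noise_sd < 0 || rfx1_noise_sd < 0) abort("noise SDs must be >= 0")
  if (immune_mhcii_intensity < 5 * neuron_mhcii_base) {
    warn("immune MHCII below 5x the neuronal base; scenes will not separate immune and neuronal MHCII the way real tissue does")
  }
  spec$seed <- as.integer(seed)
  structure(spec, class = "drgq_scene_spec")
}

# --- geometry helpers -------------------------------------------------------

.rtrunc_norm <- function(n, mean, sd, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(max(n, 10), mean, sd)
    out <- c(out, x[x > lo & x <= hi])
  }
  out[seq_len(n)]
}

# pixel index set of a filled rotated ellipse; pixel centers at integer
# (row, col) coordinates
.ellipse_idx <- function(nr, nc, cy, cx, a, b, theta) {
  rr <- max(1L, floor(cy - a)):min(nr, ceiling(cy + a))
  cc <- max(1L, floor(cx - a)):min(nc, ceiling(cx + a))
  dy <- rr - cy
  dx <- cc - cx
  DX <- matrix(dx, length(rr), length(cc), byrow = TRUE)
  DY <- matrix(dy, length(rr), length(cc))
  xr <- DX * cos(theta) + DY * sin(theta)
  yr <- -DX * sin(theta) + DY * cos(theta)
  ins <- (xr / a)^2 + (yr / b)^2 <= 1
  idx_mat <- outer(rr, (cc - 1L) * nr, `+`)
  idx_mat[ins]
}

# n pixel offsets forming a compact connected blob (sorted by radius)
.compact_offsets <- function(n) {
  k <- ceiling(sqrt(n)) + 2L
  g <- expand.grid(dr = -k:k, dc = -k:k)
  g <- g[order(g$dr^2 + g$dc^2, atan2(g$dr, g$dc)), ]
  as.matrix(g[seq_len(n), , drop = FALSE])
}

# sample all object geometry for a section scene; returns a list with the
# object table and per-object pixel-level placements (puncta, nuclei)
.sample_section_geometry <- function(spec) {
  nr <- nc <- spec$image_size
  pitch <- sqrt(spec$pixel_area_um2)
  band_h <- round(spec$tissue_fraction * nr)
  r0 <- floor((nr - band_h) / 2) + 1L
  r1 <- r0 + band_h - 1L
  n_objects <- spec$n_neurons_small + spec$n_neurons_large + spec$n_immune +
    spec$n_tcells + spec$n_cd3_only + spec$n_satellite
  if (band_h <= 0 && n_objects > 0) {
    abort("tissue_fraction is too small to hold any objects")
  }

  placed_r <- numeric(0); placed_c <- numeric(0); placed_rad <- numeric(0)
  place <- function(radius, near = NULL) {
    if (is.null(near) &&
        (r0 + radius + 3 >= r1 - radius - 3 || 1 + radius + 3 >= nc - radius - 3)) {
      abort("infeasible packing: object larger than the tissue band")
    }
    for (i in seq_len(4000)) {
      if (is.null(near)) {
        rr <- runif(1, r0 + radius + 3, r1 - radius - 3)
        cc <- runif(1, 1 + radius + 3, nc - radius - 3)
      } else {
        phi <- runif(1, 0, 2 * pi)
        rr <- near$row + near$dist * sin(phi)
        cc <- near$col + near$dist * cos(phi)
        if (rr < radius + 2 || rr > nr - radius - 1 ||
            cc < radius + 2 || cc > nc - radius - 1) next
      }
      ok <- if (length(placed_r)) {
        d2 <- (rr - placed_r)^2 + (cc - placed_c)^2
        gap2 <- (radius + placed_rad + 3)^2
        if (!is.null(near) && !is.null(near$ignore)) {
          all(d2 >= gap2 | seq_along(d2) == near$ignore)
        } else all(d2 >= gap2)
      } else TRUE
      if (ok) {
        placed_r <<- c(placed_r, rr); placed_c <<- c(placed_c, cc)
        placed_rad <<- c(placed_rad, radius)
        return(c(rr, cc))
      }
    }
    abort("infeasible packing: could not place an object after 4000 attempts")
  }

  n_s <- spec$n_neurons_small; n_l <- spec$n_neurons_large
  diam <- c(if (n_l) .rtrunc_norm(n_l, spec$large_diam_mean_um,
                                  spec$large_diam_sd_um, 30, 60),
            if (n_s) .rtrunc_norm(n_s, spec$small_diam_mean_um,
                                  spec$small_diam_sd_um, 8, 25))
  cls <- c(rep("neuron_large", n_l), rep("neuron_small", n_s))
  n_neu <- n_s + n_l
  neurons <- tibble(class = cls, diam_um = diam)
  if (n_neu) {
    neurons$r_eq_px <- (neurons$diam_um / 2) / pitch
    neurons$axis_ratio <- runif(n_neu, 0.8, 1.0)
    # equal-area semi-axes so the equivalent diameter is exactly diam_um
    neurons$a <- neurons$r_eq_px / sqrt(neurons$axis_ratio)
    neurons$b <- neurons$r_eq_px * sqrt(neurons$axis_ratio)
    neurons$theta <- runif(n_neu, 0, pi)
    pos <- t(vapply(neurons$a, place, numeric(2)))
    neurons$row <- pos[, 1]; neurons$col <- pos[, 2]
    neurons$mhcii_positive <- runif(n_neu) < spec$frac_mhcii_pos
    neurons$rfx1_positive <- runif(n_neu) < spec$frac_rfx1_pos
  }

  disc_tbl <- function(n, class, diam_um) {
    if (!n) return(tibble())
    rad <- (diam_um / 2) / pitch
    pos <- t(vapply(rep(rad, n), place, numeric(2)))
    tibble(class = class, diam_um = diam_um, r_eq_px = rad,
           axis_ratio = 1, a = rad, b = rad, theta = 0,
           row = pos[, 1], col = pos[, 2],
           mhcii_positive = NA, rfx1_positive = NA)
  }
  immune <- disc_tbl(spec$n_immune, "immune", spec$immune_diam_um)
  tcells <- disc_tbl(spec$n_tcells, "tcell", spec$tcell_diam_um)
  cd3only <- disc_tbl(spec$n_cd3_only, "cd3_only", spec$tcell_diam_um)

  # nuclei: one centered (with a small jitter) in every cell; satellites
  # pressed against neuron borders, centroid outside the soma
  r_nuc <- (spec$nucleus_diam_um / 2) / pitch
  nuc <- list()
  if (n_neu) {
    jit_max <- pmax(0, neurons$b - r_nuc - 5)
    phi <- runif(n_neu, 0, 2 * pi)
    jr <- runif(n_neu, 0, jit_max)
    nuc$neuron <- tibble(host = seq_len(n_neu),
                         class = "nucleus_neuronal",
                         row = neurons$row + jr * sin(phi),
                         col = neurons$col + jr * cos(phi),
                         radius = pmin(r_nuc, pmax(2, neurons$b * 0.45)))
  }
  cell_nuc <- function(tbl, class) {
    if (!nrow(tbl)) return(NULL)
    tibble(host = NA_integer_, class = class, row = tbl$row, col = tbl$col,
           radius = pmin(r_nuc, pmax(2, tbl$r_eq_px * 0.6)))
  }
  nuc$immune <- cell_nuc(immune, "nucleus_immune")
  nuc$tcell <- cell_nuc(bind_rows(tcells, cd3only), "nucleus_tcell")
  if (spec$n_satellite > 0 && n_neu > 0) {
    sat <- vector("list", spec$n_satellite)
    for (i in seq_len(spec$n_satellite)) {
      h <- sample.int(n_neu, 1)
      pos <- place(r_nuc, near = list(row = neurons$row[h],
                                      col = neurons$col[h],
                                      dist = neurons$a[h] + r_nuc + 3,
                                      ignore = h))
      sat[[i]] <- tibble(host = NA_integer_, class = "nucleus_satellite",
                         row = pos[1], col = pos[2], radius = r_nuc)
    }
    nuc$satellite <- bind_rows(sat)
  }
  nuclei <- bind_rows(nuc)

  # puncta inside MHCII+ somata. Each punctum's pixel set is placed so that
  # every pixel survives a 5-px erosion of the rasterized soma: the 4-px
  # analysis shrink can then never clip a planted punctum, and a grown
  # (7-px) immune mask seeded >= 3 px outside the soma can reach at most
  # 4 px deep. Puncta keep >= 2 px clearance from each other so they
  # cannot merge into one component. Capacity-limited: the smallest somata
  # may hold fewer puncta than drawn (truth reflects what was rendered).
  puncta <- vector("list", n_neu)
  for (i in seq_len(n_neu)) {
    puncta[[i]] <- list()
    if (!isTRUE(neurons$mhcii_positive[i])) next
    idx <- .ellipse_idx(nr, nc, neurons$row[i], neurons$col[i],
                        neurons$a[i], neurons$b[i], neurons$theta[i])
    r <- (idx - 1L) %% nr + 1L; cc <- (idx - 1L) %/% nr + 1L
    rs0 <- min(r); cs0 <- min(cc)
    sub <- matrix(FALSE, max(r) - rs0 + 1L, max(cc) - cs0 + 1L)
    sub[cbind(r - rs0 + 1L, cc - cs0 + 1L)] <- TRUE
    core <- .erode_disc(sub, 5L)
    cand <- which(core)
    if (!length(cand)) next
    snr <- nrow(sub)
    want <- sample(spec$puncta_per_pos_neuron[1]:spec$puncta_per_pos_neuron[2], 1)
    got <- list()
    got_pix_r <- numeric(0); got_pix_c <- numeric(0)
    for (p in seq_len(want)) {
      ar <- sample(spec$puncta_area_px[1]:spec$puncta_area_px[2], 1)
      offs <- .compact_offsets(ar)
      ok <- FALSE
      for (try in seq_len(60)) {
        ctr <- cand[sample.int(length(cand), 1)]
        pr <- (ctr - 1L) %% snr + 1L + offs[, 1]
        pc <- (ctr - 1L) %/% snr + 1L + offs[, 2]
        if (any(pr < 1L | pr > snr | pc < 1L | pc > ncol(sub))) next
        if (!all(core[cbind(pr, pc)])) next
        if (length(got_pix_r)) {
          d2 <- outer(pr, got_pix_r, `-`)^2 + outer(pc, got_pix_c, `-`)^2
          if (min(d2) < 4) next
        }
        got[[length(got) + 1L]] <- (cs0 + pc - 2L) * nr + (rs0 + pr - 1L)
        got_pix_r <- c(got_pix_r, pr); got_pix_c <- c(got_pix_c, pc)
        ok <- TRUE
        break
      }
      if (!ok) break
    }
    puncta[[i]] <- got
  }

  list(nr = nr, nc = nc, band = c(r0, r1), neurons = neurons,
       immune = immune, tcells = tcells, cd3only = cd3only,
       nuclei = nuclei, puncta = puncta)
}

# render a sampled section geometry into channels + truth table
.render_section <- function(spec, geom, isotype = FALSE) {
  nr <- geom$nr; nc <- geom$nc
  zero <- matrix(0, nr, nc)
  chans <- list(PGP9.5 = zero, MHCII = zero, CD3 = zero, CD4 = zero,
                DAPI = zero, RFX1 = zero)
  tissue_area_px <- 0L
  if (geom$band[2] >= geom$band[1]) {
    band_rows <- geom$band[1]:geom$band[2]
    chans$PGP9.5[band_rows, ] <- spec$tissue_intensity
    tissue_area_px <- length(band_rows) * nc
  }

  truth <- list()
  oid <- 0L
  add_truth <- function(class, idx, diam = NA_real_, mhcii = FALSE,
                        rfx1 = NA, n_puncta = 0L, puncta_area = 0L,
                        puncta_detail = NULL) {
    oid <<- oid + 1L
    r <- (idx - 1L) %% nr + 1L; cc <- (idx - 1L) %/% nr + 1L
    truth[[oid]] <<- tibble(
      object_id = oid, class = class, centroid_row = mean(r),
      centroid_col = mean(cc), area_px = length(idx),
      true_diameter_um = diam, mhcii_positive = mhcii, rfx1_positive = rfx1,
      n_puncta = n_puncta, puncta_area_px = puncta_area,
      planted_puncta = list(puncta_detail %||%
                              tibble(centroid_row = numeric(0),
                                     centroid_col = numeric(0),
                                     area_px = integer(0))),
      planted_polarized_fraction = NA_real_)
    oid
  }

  neu <- geom$neurons
  neuron_truth_id <- integer(nrow(neu))
  for (i in seq_len(nrow(neu))) {
    idx <- .ellipse_idx(nr, nc, neu$row[i], neu$col[i], neu$a[i], neu$b[i],
                        neu$theta[i])
    chans$PGP9.5[idx] <- spec$neuron_marker_intensity
    pd <- NULL
    p_total <- 0L
    pl <- geom$puncta[[i]]
    if (neu$mhcii_positive[i] && !isotype) {
      chans$MHCII[idx] <- spec$neuron_mhcii_base
    }
    if (length(pl) > 0) {
      det <- vector("list", length(pl))
      for (p in seq_along(pl)) {
        pidx <- pl[[p]]
        if (!isotype) {
          chans$MHCII[pidx] <- spec$neuron_mhcii_base + spec$puncta_delta
        }
        det[[p]] <- tibble(centroid_row = mean((pidx - 1L) %% nr + 1L),
                           centroid_col = mean((pidx - 1L) %/% nr + 1L),
                           area_px = length(pidx))
        p_total <- p_total + length(pidx)
      }
      pd <- bind_rows(det)
    }
    planted_pos <- neu$mhcii_positive[i] && !isotype
    neuron_truth_id[i] <- add_truth(neu$class[i], idx, diam = neu$diam_um[i],
                                    mhcii = planted_pos,
                                    rfx1 = neu$rfx1_positive[i],
                                    n_puncta = if (planted_pos) length(pl) else 0L,
                                    puncta_area = if (planted_pos) p_total else 0L,
                                    puncta_detail = if (planted_pos) pd else NULL)
  }
  for (i in seq_len(nrow(geom$immune))) {
    im <- geom$immune[i, ]
    idx <- .ellipse_idx(nr, nc, im$row, im$col, im$a, im$b, 0)
    if (!isotype) chans$MHCII[idx] <- spec$immune_mhcii_intensity
    add_truth("immune", idx, diam = im$diam_um)
  }
  for (i in seq_len(nrow(geom$tcells))) {
    tc <- geom$tcells[i, ]
    idx <- .ellipse_idx(nr, nc, tc$row, tc$col, tc$a, tc$b, 0)
    chans$CD3[idx] <- spec$tcell_intensity
    chans$CD4[idx] <- spec$tcell_intensity
    add_truth("tcell", idx, diam = tc$diam_um)
  }
  for (i in seq_len(nrow(geom$cd3only))) {
    tc <- geom$cd3only[i, ]
    idx <- .ellipse_idx(nr, nc, tc$row, tc$col, tc$a, tc$b, 0)
    chans$CD3[idx] <- spec$tcell_intensity
    add_truth("cd3_only", idx, diam = tc$diam_um)
  }
  for (i in seq_len(nrow(geom$nuclei))) {
    nu <- geom$nuclei[i, ]
    idx <- .ellipse_idx(nr, nc, nu$row, nu$col, nu$radius, nu$radius, 0)
    chans$DAPI[idx] <- spec$dapi_intensity
    if (identical(nu$class, "nucleus_neuronal")) {
      pos <- geom$neurons$rfx1_positive[nu$host]
      chans$RFX1[idx] <- if (isTRUE(pos)) spec$rfx1_pos_intensity else spec$rfx1_neg_intensity
    } else {
      chans$RFX1[idx] <- spec$rfx1_neg_intensity
    }
    add_truth(nu$class, idx)
  }

  ceiling_afu <- 2^spec$bit_depth - 1
  for (nm in names(chans)) {
    s <- if (nm == "RFX1") spec$rfx1_noise_sd else spec$noise_sd
    if (s > 0) {
      chans[[nm]] <- chans[[nm]] + round(rnorm(nr * nc, 0, s))
    }
    chans[[nm]] <- matrix(pmin(pmax(chans[[nm]], 0), ceiling_afu), nr, nc)
  }

  truth_tbl <- if (length(truth)) bind_rows(truth) else
    tibble(object_id = integer(), class = character(),
           centroid_row = numeric(), centroid_col = numeric(),
           area_px = integer(), true_diameter_um = numeric(),
           mhcii_positive = logical(), rfx1_positive = logical(),
           n_puncta = integer(), puncta_area_px = integer(),
           planted_puncta = list(),
           planted_polarized_fraction = numeric())
  attr(truth_tbl, "tissue_area_px") <- tissue_area_px
  attr(truth_tbl, "isotype") <- isotype

  stack <- image_stack(chans, pixel_area_um2 = spec$pixel_area_um2,
                       bit_depth = spec$bit_depth,
                       source_id = sprintf("synthetic-section-seed%d%s",
                                           spec$seed,
                                           if (isotype) "-isotype" else ""))
  list(stack = stack, truth = truth_tbl)
}

#' Generate a synthetic DRG section with ground truth
#'
#' Renders the scene described by a [scene_spec()] and returns both the
#' image stack (channels PGP9.5, MHCII, CD3, CD4, DAPI, RFX1) and a truth
#' table with one row per planted object (class, centroid, exact rendered
#' pixel area, true diameter, MHCII/RFX1 flags, planted puncta). The whole
#' scene is driven by `spec$seed`: identical seeds give bitwise-identical
#' stacks and truth tables. The tissue-band pixel area is carried in the
#' truth table's `"tissue_area_px"` attribute.
#'
#' @param spec A [scene_spec()].
#' @return List with elements `stack` ([image_stack()]) and `truth`
#'   (tibble).
#' @export
generate_section <- function(spec) {
  stopifnot(inherits(spec, "drgq_scene_spec"))
  withr::with_seed(spec$seed, {
    geom <- .sample_section_geometry(spec)
    .render_section(spec, geom, isotype = FALSE)
  })
}

#' Generate an isotype-control section
#'
#' Identical geometry generation to [generate_section()] under the same
#' seed (same somata, immune cells, T cells, nuclei), but the MHCII channel
#' carries only background noise: isotype-control staining has no true
#' signal on any object, which is what makes its per-neuron MPI
#' distribution a null reference for [isotype_threshold()].
#'
#' @inheritParams generate_section
#' @return As [generate_section()]; all `mhcii_positive` truth flags are
#'   `FALSE`.
#' @export
generate_isotype_section <- function(spec) {
  stopifnot(inherits(spec, "drgq_scene_spec"))
  withr::with_seed(spec$seed, {
    geom <- .sample_section_geometry(spec)
    .render_section(spec, geom, isotype = TRUE)
  })
}

#' Generate a cultured-neuron (ICC) scene with ground truth
#'
#' Sparse isolated somata on a clean background (no tissue band), each with
#' a DAPI nucleus and a surface MHCII/OVA signal that is either uniform or
#' concentrated into a planted polar cap: the `polar_cap_fraction` of the
#' soma's pixels furthest along a random direction, at
#' `polar_fold_planted` times the surface base. The truth table records the
#' exact planted polarized fraction (cap pixels / soma pixels).
#'
#' @inheritParams generate_section
#' @return List with `stack` (channels PGP9.5, MHCII, OVA, DAPI) and
#'   `truth`.
#' @export
generate_culture <- function(spec) {
  stopifnot(inherits(spec, "drgq_scene_spec"))
  withr::with_seed(spec$seed, {
    nr <- nc <- spec$image_size
    pitch <- sqrt(spec$pixel_area_um2)
    n <- spec$n_culture_neurons
    zero <- matrix(0, nr, nc)
    chans <- list(PGP9.5 = zero, MHCII = zero, OVA = zero, DAPI = zero)
    placed <- matrix(numeric(0), 0, 3)
    truth <- vector("list", n)
    r_nuc <- (spec$nucleus_diam_um / 2) / pitch
    for (i in seq_len(n)) {
      d <- .rtrunc_norm(1, spec$culture_diam_mean_um, spec$culture_diam_sd_um,
                        10, 45)
      r_eq <- (d / 2) / pitch
      q <- runif(1, 0.8, 1.0)
      a <- r_eq / sqrt(q); b <- r_eq * sqrt(q); th <- runif(1, 0, pi)
      ok <- FALSE
      for (try in seq_len(4000)) {
        rr <- runif(1, a + 3, nr - a - 2)
        cc <- runif(1, a + 3, nc - a - 2)
        if (!nrow(placed) ||
            all((rr - placed[, 1])^2 + (cc - placed[, 2])^2 >=
                  (a + placed[, 3] + 3)^2)) { ok <- TRUE; break }
      }
      if (!ok) abort("infeasible packing in culture scene")
      placed <- rbind(placed, c(rr, cc, a))
      idx <- .ellipse_idx(nr, nc, rr, cc, a, b, th)
      chans$PGP9.5[idx] <- spec$neuron_marker_intensity
      chans$MHCII[idx] <- spec$neuron_mhcii_base
      chans$OVA[idx] <- spec$ova_intensity
      polarized <- runif(1) < spec$frac_polarized
      cap_frac <- 0
      if (polarized && spec$polar_cap_fraction > 0) {
        pr <- (idx - 1L) %% nr + 1L; pc <- (idx - 1L) %/% nr + 1L
        phi <- runif(1, 0, 2 * pi)
        proj <- (pr - rr) * sin(phi) + (pc - cc) * cos(phi)
        n_cap <- round(spec$polar_cap_fraction * length(idx))
        cap <- idx[order(proj, decreasing = TRUE)[seq_len(n_cap)]]
        chans$MHCII[cap] <- spec$neuron_mhcii_base * spec$polar_fold_planted
        chans$OVA[cap] <- spec$ova_intensity * spec$polar_fold_planted
        cap_frac <- n_cap / length(idx)
      }
      nidx <- .ellipse_idx(nr, nc, rr, cc, min(r_nuc, b * 0.45),
                           min(r_nuc, b * 0.45), 0)
      chans$DAPI[nidx] <- spec$dapi_intensity
      truth[[i]] <- tibble(object_id = i, class = "neuron_culture",
                           centroid_row = mean((idx - 1L) %% nr + 1L),
                           centroid_col = mean((idx - 1L) %/% nr + 1L),
                           area_px = length(idx), true_diameter_um = d,
                           mhcii_positive = TRUE, rfx1_positive = NA,
                           n_puncta = 0L, puncta_area_px = 0L,
                           planted_puncta = list(tibble()),
                           planted_polarized_fraction = cap_frac)
    }
    ceiling_afu <- 2^spec$bit_depth - 1
    for (nm in names(chans)) {
      if (spec$noise_sd > 0) {
        chans[[nm]] <- chans[[nm]] + round(rnorm(nr * nc, 0, spec$noise_sd))
      }
      chans[[nm]] <- matrix(pmin(pmax(chans[[nm]], 0), ceiling_afu), nr, nc)
    }
    truth_tbl <- if (n) bind_rows(truth) else tibble()
    stack <- image_stack(chans, pixel_area_um2 = spec$pixel_area_um2,
                         bit_depth = spec$bit_depth,
                         source_id = sprintf("synthetic-culture-seed%d", spec$seed))
    list(stack = stack, truth = truth_tbl)
  })
}
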