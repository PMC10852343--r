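test_that("shrink and grow agree with the Euclidean-distance oracle", {
  withr::with_seed(101, {
    for (i in 1:30) {
      h <- sample(10:40, 1); w <- sample(10:40, 1)
      mask <- random_blob_mask(h, w)
      k <- sample(0:7, 1)
      lm <- label_map(matrix(as.integer(mask), h, w), "test")
      expect_identical(shrink_mask(lm, k)$labels > 0L, oracle_erode(mask, k))
      expect_identical(grow_mask(lm, k)$labels > 0L, oracle_dilate(mask, k))
    }
  })
})

test_that("shrink at k = 0 is the identity and extinction is logged", {
  lab <- matrix(0L, 12, 12)
  lab[5:7, 5:7] <- 1L  # 3x3 block dies under k = 4
  lm <- label_map(lab, "neuron")
  expect_identical(shrink_mask(lm, 0)$labels, lab)
  expect_message(out <- shrink_mask(lm, 4), "extinction")
  expect_identical(attr(out, "dropped"), 1L)
  expect_identical(sum(out$labels), 0L)
})

test_that("grow then shrink by the same radius contains a convex instance", {
  m <- matrix(FALSE, 40, 40)
  rows <- matrix(seq_len(40), 40, 40)
  cols <- t(rows)
  m <- (rows - 20)^2 + (cols - 20)^2 <= 10^2
  lm <- label_map(matrix(as.integer(m), 40, 40), "x")
  closed <- shrink_mask(grow_mask(lm, 5), 5)
  expect_true(all(closed$labels[m] == 1L))
})

test_that("grown instances resolve overlaps by nearest seed", {
  lab <- matrix(0L, 30, 40)
  lab[14:16, 8:10] <- 1L   # seed centered at col 9
  lab[14:16, 22:24] <- 2L  # seed centered at col 23
  g <- grow_mask(label_map(lab, "immune"), 7)
  # contested mid-zone pixels (claimed by both grown discs) go to the
  # closer seed
  expect_identical(g$labels[15, 15], 1L)
  expect_identical(g$labels[15, 17], 2L)
  # single-claim fringe pixels keep their only claimant
  expect_identical(g$labels[15, 14], 1L)
  expect_identical(g$labels[15, 18], 2L)
  # original pixels keep their ids
  expect_identical(g$labels[15, 9], 1L)
  expect_identical(g$labels[15, 23], 2L)
})

test_that("tissue mask recovers the planted tissue area and ignores other channels", {
  g <- generate_section(scene_spec(seed = 5, noise_sd = 0, rfx1_noise_sd = 0))
  p <- drgq_params(pixel_area_um2 = 1)
  tm <- tissue_mask(g$stack, p$seg)
  planted <- attr(g$truth, "tissue_area_px")
  expect_lt(abs(label_area_px(tm) - planted) / planted, 0.02)
  # depends only on the neuron marker: zeroing every other channel changes nothing
  st2 <- g$stack
  for (nm in setdiff(names(st2$channels), "PGP9.5")) {
    st2$channels[[nm]][] <- 0
  }
  expect_identical(tissue_mask(st2, p$seg)$labels, tm$labels)
  # an all-zero image has no tissue
  blank <- image_stack(list(PGP9.5 = matrix(0, 64, 64)), pixel_area_um2 = 1)
  expect_identical(label_area_px(tissue_mask(blank, p$seg)), 0L)
})

test_that("neuron segmentation recovers planted instances exactly on noiseless scenes", {
  g <- generate_section(noiseless_spec(seed = 17))
  p <- drgq_params(pixel_area_um2 = 1)
  inst <- neuron_instances(g$stack, p$seg)
  truth_neu <- g$truth[grepl("^neuron", g$truth$class), ]
  st <- drgquant:::.component_stats(inst$labels)
  expect_identical(nrow(st), nrow(truth_neu))
  m <- vapply(seq_len(nrow(truth_neu)), function(i) {
    which.min((st$centroid_row - truth_neu$centroid_row[i])^2 +
                (st$centroid_col - truth_neu$centroid_col[i])^2)
  }, integer(1))
  expect_identical(st$area_px[m], truth_neu$area_px)
  expect_lt(max(abs(st$centroid_row[m] - truth_neu$centroid_row)), 1e-9)
  # blank image segments nothing
  blank <- image_stack(list(PGP9.5 = matrix(0, 64, 64)), pixel_area_um2 = 1)
  expect_length(label_ids(neuron_instances(blank, p$seg)), 0)
})

test_that("a bright thin ribbon is excluded as a nerve fiber", {
  ch <- matrix(0, 120, 260)
  ch[60:62, 30:229] <- 12000          # 3 x 200 px fiber
  rows <- matrix(seq_len(120), 120, 260)
  cols <- matrix(seq_len(260), 120, 260, byrow = TRUE)
  soma <- (rows - 30)^2 + (cols - 60)^2 <= 9^2
  ch[soma] <- 12000
  st <- image_stack(list(PGP9.5 = ch), pixel_area_um2 = 1)
  p <- seg_params(pixel_area_um2 = 1, neuron_marker_threshold = 6000,
                  neuron_max_area_px = 5000)
  inst <- neuron_instances(st, p)
  expect_length(label_ids(inst), 1)
  expect_true("fiber" %in% attr(inst, "dropped")$reason)
})

test_that("exclusion removes exactly the overlapping pixels and flags empties", {
  lab <- matrix(0L, 20, 20)
  lab[5:14, 5:14] <- 1L  # 100 px
  neurons <- label_map(lab, "neuron")
  excl <- matrix(0L, 20, 20)
  excl[5:14, 5:9] <- 1L  # covers exactly half
  half <- exclude_overlap(neurons, label_map(excl, "immune"))
  expect_identical(sum(half$labels == 1L), 50L)
  # empty exclusion is the identity
  none <- exclude_overlap(neurons, label_map(matrix(0L, 20, 20), "x"))
  expect_identical(none$labels, lab)
  # full coverage drops the instance but remembers its id
  full <- exclude_overlap(neurons, label_map(lab, "x"))
  expect_identical(attr(full, "dropped"), 1L)
  expect_identical(attr(full, "ids"), 1L)
  expect_error(exclude_overlap(neurons, label_map(matrix(0L, 5, 5), "x")),
               "shape")
})

test_that("exclusion never increases pixel counts and is monotone in grow radius", {
  g <- generate_section(noiseless_spec(seed = 23))
  p <- drgq_params(pixel_area_um2 = 1)
  neurons <- neuron_instances(g$stack, p$seg)
  shrunk <- shrink_mask(neurons, p$seg$shrink_px)
  nn <- nonneuronal_mhcii_mask(g$stack, p$seg)
  areas <- vapply(c(0, 3, 7, 11), function(k) {
    sum(exclude_overlap(shrunk, grow_mask(nn, k))$labels > 0L)
  }, numeric(1))
  expect_true(all(diff(areas) <= 0))
  expect_lte(areas[1], sum(shrunk$labels > 0L))
})

test_that("the 25,000 AFU gate separates immune cells from neuronal MHCII", {
  g <- generate_section(noiseless_spec(seed = 31))
  p <- drgq_params(pixel_area_um2 = 1)
  nn <- nonneuronal_mhcii_mask(g$stack, p$seg)
  expect_length(label_ids(nn), sum(g$truth$class == "immune"))
  # lowering the cutoff below the neuronal base sweeps in neurons too
  p_low <- seg_params(pixel_area_um2 = 1, nonneuronal_mhcii_min = 3000,
                      immune_cell_max_area_px = 5000)
  nn_low <- nonneuronal_mhcii_mask(g$stack, p_low)
  expect_gt(length(label_ids(nn_low)), length(label_ids(nn)))
})

test_that("nuclei split into neuronal and satellite by centroid location", {
  g <- generate_section(noiseless_spec(seed = 37))
  p <- drgq_params(pixel_area_um2 = 1)
  neurons <- neuron_instances(g$stack, p$seg)
  nuc <- nuclei_instances(g$stack, neurons, p$seg)
  n_neu <- sum(grepl("^neuron", g$truth$class))
  expect_identical(length(label_ids(nuc$neuronal)), n_neu)
  # neuronal nuclei take their host neuron's id
  expect_true(all(label_ids(nuc$neuronal) %in% label_ids(neurons)))
  # satellites plus immune/T-cell nuclei are non-neuronal
  n_non <- sum(g$truth$class %in%
                 c("nucleus_satellite", "nucleus_immune", "nucleus_tcell"))
  expect_identical(length(label_ids(nuc$nonneuronal)), n_non)
})

test_that("label maps are reproducible bitwise and inputs are never mutated", {
  g <- generate_section(noiseless_spec(seed = 41))
  p <- drgq_params(pixel_area_um2 = 1)
  before <- g$stack$channels
  a <- neuron_instances(g$stack, p$seg)
  b <- neuron_instances(g$stack, p$seg)
  expect_identical(a$labels, b$labels)
  shrink_mask(a, 4); grow_mask(a, 7)
  expect_identical(g$stack$channels, before)
})
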