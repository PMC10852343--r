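test_that("MPI is the arithmetic mean over measurable pixels", {
  ch <- matrix(0, 10, 10)
  lab <- matrix(0L, 10, 10)
  lab[2:5, 2:5] <- 1L
  ch[2:5, 2:5] <- 250
  lab[7:8, 7:8] <- 2L
  ch[7:8, 7] <- 100; ch[7:8, 8] <- 300  # half 100, half 300
  st <- image_stack(list(MHCII = ch), pixel_area_um2 = 2)
  rec <- measure_mpi(st, label_map(lab, "neuron"), "MHCII")
  expect_equal(rec$mpi, c(250, 200))
  expect_equal(rec$area_um2, rec$area_px * 2)
  # ids carried by the map but absent from the raster come back unmeasurable
  lm <- label_map(lab, "neuron")
  attr(lm, "ids") <- 1:3
  rec3 <- measure_mpi(st, lm, "MHCII")
  expect_identical(rec3$measurable, c(TRUE, TRUE, FALSE))
  expect_true(is.na(rec3$mpi[3]))
})

test_that("the isotype 99th percentile follows the type-7 interpolation rule", {
  rec <- tibble::tibble(mpi = as.numeric(1:100))
  m <- isotype_threshold(rec)
  expect_equal(m$threshold_afu, 99.01)
  expect_identical(m$provenance, "isotype_p99")
  expect_identical(m$n_reference, 100L)
  # constant reference: the threshold is that constant
  m2 <- tibble::tibble(mpi = rep(7, 100)) |> isotype_threshold()
  expect_equal(m2$threshold_afu, 7)
  # permutation invariance
  m3 <- isotype_threshold(tibble::tibble(mpi = as.numeric(sample(1:100))))
  expect_equal(m3$threshold_afu, m$threshold_afu)
  expect_error(isotype_threshold(tibble::tibble(mpi = numeric(0))), "empty")
  expect_warning(isotype_threshold(tibble::tibble(mpi = 1:5)), "unstable")
})

test_that("positivity is strictly greater-than the threshold", {
  rec <- tibble::tibble(mpi = c(37.19, 37.20, 10, 50), measurable = TRUE)
  out <- classify_positive(rec, fixed_threshold(37.19, "rfx1_positive"))
  expect_identical(out$rfx1_positive, c(FALSE, TRUE, FALSE, TRUE))
  # all below: zero positive fraction
  low <- classify_positive(tibble::tibble(mpi = c(1, 2), measurable = TRUE),
                           fixed_threshold(10, "f"))
  expect_identical(positive_fraction(low, "f"), 0)
  # monotone: raising the threshold never increases the positive count
  mpis <- tibble::tibble(mpi = runif(200, 0, 100), measurable = TRUE)
  counts <- vapply(c(10, 30, 50, 70), function(t) {
    sum(classify_positive(mpis, fixed_threshold(t, "f"))$f)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("tidy and glance expose threshold models as tibbles", {
  m <- fixed_threshold(37.19, "rfx1_positive")
  td <- tidy(m)
  expect_identical(td$term, "rfx1_positive")
  expect_identical(td$estimate, 37.19)
  expect_identical(glance(m)$provenance, "fixed")
})

test_that("CD3/CD4 double positives are found inside tissue only", {
  g <- generate_section(noiseless_spec(seed = 19))
  p <- drgq_params(pixel_area_um2 = 1)
  tm <- tissue_mask(g$stack, p$seg)
  tc <- find_cd4_tcells(g$stack, tm, p$seg)
  expect_identical(nrow(tc), sum(g$truth$class == "tcell"))
  # CD3-only distractors appear as candidates but are not double positive
  expect_identical(attr(tc, "n_cd3_candidates"),
                   sum(g$truth$class %in% c("tcell", "cd3_only")))
  # no CD3 signal means no T cells regardless of CD4
  st0 <- g$stack
  st0$channels$CD3[] <- 0
  expect_identical(nrow(find_cd4_tcells(st0, tm, p$seg)), 0L)
  # count is invariant to the MHCII and DAPI channel contents
  st1 <- g$stack
  st1$channels$MHCII[] <- 0
  st1$channels$DAPI[] <- 0
  expect_identical(nrow(find_cd4_tcells(st1, tm, p$seg)), nrow(tc))
})

test_that("a double-positive cell outside the tissue mask is not counted", {
  n <- 80
  cd3 <- matrix(0, n, n); cd4 <- matrix(0, n, n)
  rows <- matrix(seq_len(n), n, n); cols <- t(rows)
  inside <- (rows - 30)^2 + (cols - 40)^2 <= 4^2   # centroid row 30: in tissue
  outside <- (rows - 70)^2 + (cols - 40)^2 <= 4^2  # centroid row 70: outside
  cd3[inside | outside] <- 8000
  cd4[inside | outside] <- 8000
  st <- image_stack(list(CD3 = cd3, CD4 = cd4), pixel_area_um2 = 1)
  tis <- matrix(0L, n, n); tis[1:50, ] <- 1L
  tc <- find_cd4_tcells(st, label_map(tis, "tissue"), seg_params(pixel_area_um2 = 1))
  expect_identical(nrow(tc), 1L)
  expect_lt(tc$centroid_row, 50)
})

test_that("T-cell density is a pooled ratio across sections", {
  # 12 cells on exactly 0.5 mm^2
  expect_equal(tcell_density(12, 0.5e6, 1), 24)
  # pooling: (8 + 4) cells over (0.4 + 0.1) mm^2 = 24, not mean(20, 40) = 30
  expect_equal(tcell_density(c(8, 4), c(0.4e6, 0.1e6), 1), 24)
  # zero cells is zero density; zero area is an error
  expect_equal(tcell_density(0, 1e6, 1), 0)
  expect_error(tcell_density(3, 0, 1), "zero tissue")
})
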