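# build a single rectangular "neuron" stack for constructed-input cases
rect_neuron <- function(h = 30, w = 30, rows = 6:25, cols = 6:25, value = 1000) {
  ch <- matrix(0, h, w)
  lab <- matrix(0L, h, w)
  ch[rows, cols] <- value
  lab[rows, cols] <- 1L
  list(stack = image_stack(list(MHCII = ch), pixel_area_um2 = 1,
                           bit_depth = "unbounded"),
       labels = label_map(lab, "neuron"))
}

test_that("the median background is robust to the puncta themselves", {
  x <- rect_neuron(value = 1000)           # 400 px at 1000
  ch <- x$stack$channels$MHCII
  ch[6:9, 6:15] <- 2500                    # 40 px (10%) puncta-bright
  st <- image_stack(list(MHCII = ch), pixel_area_um2 = 1, bit_depth = "unbounded")
  bg <- local_background(st, x$labels)
  expect_equal(bg$background_afu, 1000)
  # the mean estimator would have been dragged to 1150 -- why median is default
  expect_equal(mean(ch[x$labels$labels == 1L]), 1150)
  # annulus variant measures outside the instance
  ch2 <- matrix(700, 30, 30); ch2[6:25, 6:25] <- 1000
  st2 <- image_stack(list(MHCII = ch2), pixel_area_um2 = 1, bit_depth = "unbounded")
  bg2 <- local_background(st2, x$labels,
                          puncta_params(background_estimator = "annulus_median"))
  expect_equal(bg2$background_afu, 700)
  # instances below the pixel floor are not scored
  tiny <- rect_neuron(rows = 6:8, cols = 6:8)
  expect_false(local_background(tiny$stack, tiny$labels)$scored)
})

test_that("puncta detection applies the area and offset gates exactly", {
  x <- rect_neuron()  # 400 px neuron at 1000
  ch <- x$stack$channels$MHCII
  # five 4-px puncta at background + 1200 (>= the 800 offset)
  for (ctr in list(c(8, 8), c(8, 16), c(16, 8), c(16, 16), c(22, 22))) {
    ch[ctr[1] + 0:1, ctr[2] + 0:1] <- 2200
  }
  st <- image_stack(list(MHCII = ch), pixel_area_um2 = 1, bit_depth = "unbounded")
  res <- detect_puncta(st, x$labels)
  expect_identical(res$n_puncta, 5L)
  expect_identical(res$puncta_area_px, 20L)
  expect_equal(res$percent_area, 100 * 20 / 400)
  expect_equal(res$components[[1]]$peak_afu, rep(2200, 5))
  # a lone 1-px punctum fails the >= 1.5 px (effective 2 px) gate
  ch2 <- x$stack$channels$MHCII
  ch2[10, 10] <- 2200
  st2 <- image_stack(list(MHCII = ch2), pixel_area_um2 = 1, bit_depth = "unbounded")
  expect_identical(detect_puncta(st2, x$labels)$n_puncta, 0L)
  # uniform signal: no puncta, 0% area
  res0 <- detect_puncta(x$stack, x$labels)
  expect_identical(res0$n_puncta, 0L)
  expect_equal(res0$percent_area, 0)
})

test_that("puncta detection matches the pixel-by-pixel oracle on random neurons", {
  withr::with_seed(202, {
    for (i in 1:15) {
      h <- sample(20:50, 1); w <- sample(20:50, 1)
      inst <- random_blob_mask(h, w, n_discs = 2, r_max = 12)
      if (sum(inst) < 25) next
      ch <- matrix(1000, h, w) + matrix(round(rnorm(h * w, 0, 150)), h, w)
      hot <- inst & matrix(runif(h * w) < 0.06, h, w)
      ch[hot] <- ch[hot] + sample(600:1600, sum(hot), TRUE)
      ch <- pmax(ch, 0)
      st <- image_stack(list(MHCII = ch), pixel_area_um2 = 1,
                        bit_depth = "unbounded")
      lm <- label_map(matrix(as.integer(inst), h, w), "neuron")
      got <- detect_puncta(st, lm)
      want <- oracle_puncta_pixels(ch, inst, 800, 1.5)
      got_sets <- got$components[[1]]$pixels
      got_sets <- got_sets[order(vapply(got_sets, function(s) s[1], 1L))]
      expect_identical(length(got_sets), length(want))
      expect_identical(got_sets, want)
    }
  })
})

test_that("puncta counts are monotone in the offset and area gates", {
  g <- generate_section(small_spec(seed = 55, frac_mhcii_pos = 1))
  p <- drgq_params(pixel_area_um2 = 1)
  neurons <- shrink_mask(neuron_instances(g$stack, p$seg), 4)
  count_at <- function(delta, amin) {
    sum(detect_puncta(g$stack, neurons,
                      puncta_params(delta_afu = delta, min_area_px = amin)
                      )$n_puncta, na.rm = TRUE)
  }
  by_delta <- vapply(c(400, 800, 1100, 1300), count_at, numeric(1), amin = 1.5)
  expect_true(all(diff(by_delta) <= 0))
  by_area <- vapply(c(1, 2, 4, 8), function(a) count_at(800, a), numeric(1))
  expect_true(all(diff(by_area) <= 0))
  expect_gt(by_delta[2], 0)
})

test_that("polarization scores a planted cap and respects the 1.7-fold gate", {
  # 500-px neuron with a 50-px cap at exactly 2x background
  ch <- matrix(0, 40, 40)
  lab <- matrix(0L, 40, 40)
  lab[11:30, 11:35] <- 1L  # 20 x 25 = 500 px
  ch[11:30, 11:35] <- 1000
  ch[11:30, 11:12] <- 2000 # 40 px cap... extend to 50
  ch[11:20, 13] <- 2000    # + 10 px = 50 px contiguous cap
  st <- image_stack(list(MHCII = ch), pixel_area_um2 = 1, bit_depth = "unbounded")
  res <- polarization_score(st, label_map(lab, "neuron"))
  expect_equal(res$percent_polarized, 10)
  expect_equal(res$background_afu, 1000)
  # a cap at 1.6-fold stays below the gate
  ch2 <- ch; ch2[ch2 == 2000] <- 1600
  st2 <- image_stack(list(MHCII = ch2), pixel_area_um2 = 1, bit_depth = "unbounded")
  expect_equal(polarization_score(st2, label_map(lab, "neuron"))$percent_polarized, 0)
  # uniform surface scores 0
  ch3 <- ch; ch3[lab == 1L] <- 1000
  st3 <- image_stack(list(MHCII = ch3), pixel_area_um2 = 1, bit_depth = "unbounded")
  expect_equal(polarization_score(st3, label_map(lab, "neuron"))$percent_polarized, 0)
})

test_that("zero background with signal is floored and flagged", {
  ch <- matrix(0, 30, 30)
  lab <- matrix(0L, 30, 30)
  lab[6:25, 6:25] <- 1L
  ch[6:9, 6:9] <- 50  # a minority of bright pixels; median is 0
  st <- image_stack(list(MHCII = ch), pixel_area_um2 = 1, bit_depth = "unbounded")
  expect_warning(res <- polarization_score(st, label_map(lab, "neuron")),
                 "floor")
  expect_true(res$bg_floored)
  expect_gt(res$percent_polarized, 0)
  # identically dark instance scores 0 without flooring
  dark <- rect_neuron(value = 0)
  res0 <- polarization_score(dark$stack, dark$labels)
  expect_false(res0$bg_floored)
  expect_equal(res0$percent_polarized, 0)
})

test_that("percent areas stay within [0, 100] on random inputs", {
  withr::with_seed(303, {
    for (i in 1:10) {
      h <- 40
      inst <- random_blob_mask(h, h, n_discs = 2, r_max = 12)
      if (sum(inst) < 25) next
      ch <- matrix(abs(rnorm(h * h, 500, 400)), h, h)
      st <- image_stack(list(MHCII = ch), pixel_area_um2 = 1,
                        bit_depth = "unbounded")
      lm <- label_map(matrix(as.integer(inst), h, h), "neuron")
      pa <- detect_puncta(st, lm)$percent_area
      pp <- suppressWarnings(polarization_score(st, lm)$percent_polarized)
      expect_true(all(pa >= 0 & pa <= 100, na.rm = TRUE))
      expect_true(all(pp >= 0 & pp <= 100, na.rm = TRUE))
    }
  })
})

test_that("culture scenes recover the planted polarized fraction", {
  sp <- scene_spec(image_size = 256, n_culture_neurons = 5, frac_polarized = 1,
                   polar_cap_fraction = 0.10, noise_sd = 0, seed = 77)
  g <- generate_culture(sp)
  p <- drgq_params(pixel_area_um2 = 1)
  neurons <- neuron_instances(g$stack, p$seg)
  res <- polarization_score(g$stack, neurons)
  m <- match_truth(g$truth, drgquant:::.component_stats(neurons$labels) |>
                     dplyr::rename(centroid_row = centroid_row,
                                   centroid_col = centroid_col))
  expect_equal(res$percent_polarized[m] / 100,
               g$truth$planted_polarized_fraction, tolerance = 1e-8)
  # OVA channel scores the same cap
  res_ova <- polarization_score(g$stack, neurons, channel = "OVA")
  expect_equal(res_ova$percent_polarized, res$percent_polarized)
})
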