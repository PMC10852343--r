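test_that("the area-to-diameter conversion matches the closed form", {
  expect_equal(area_to_diameter(400), 2 * sqrt(400 * 6.718 / pi))
  expect_equal(round(area_to_diameter(400), 2), 58.49)
  expect_equal(area_to_diameter(0), 0)
  # round trip to machine precision
  d <- c(12.3, 25, 30, 58.49)
  expect_equal(area_to_diameter(diameter_to_area(d)), d, tolerance = 1e-12)
  # strictly increasing in area
  a <- sort(runif(50, 1, 3000))
  expect_true(all(diff(area_to_diameter(a)) > 0))
  expect_error(area_to_diameter(-1), ">= 0")
})

test_that("size classes partition at the published boundaries", {
  rec <- tibble::tibble(diameter_um = c(25.0, 27, 30.1, 10, 30.0, 25.0001))
  out <- classify_size(rec)
  expect_identical(as.character(out$size_class),
                   c("small", "intermediate", "large", "small",
                     "intermediate", "intermediate"))
  # every neuron lands in exactly one class
  rnd <- classify_size(tibble::tibble(diameter_um = runif(500, 5, 60)))
  expect_identical(sum(table(rnd$size_class)), 500L)
  # diameters computed from areas when absent
  out2 <- classify_size(tibble::tibble(area_px = 400), morphometry_params())
  expect_equal(out2$diameter_um, area_to_diameter(400))
  expect_error(morphometry_params(small_max_um = 30, large_min_um = 25), "<")
})

test_that("the Gaussian diameter fit recovers simulated parameters", {
  withr::with_seed(404, d <- rnorm(1000, 20, 3))
  fit <- fit_diameter_distribution(d, group = "sim")
  expect_lt(abs(fit$mean_um - 20), 0.3)
  expect_lt(abs(fit$sd_um - 3), 0.25)
  expect_identical(fit$mode_um, fit$mean_um)
  expect_identical(fit$n, 1000L)
  # order invariance
  fit2 <- fit_diameter_distribution(rev(d))
  expect_equal(fit2$mean_um, fit$mean_um)
  # degenerate inputs are rejected
  expect_error(fit_diameter_distribution(rep(20, 50)), "degenerate")
  expect_error(fit_diameter_distribution(rnorm(5, 20)), "at least 10")
  # tidy/glance/histogram accessors
  expect_identical(tidy(fit)$term, c("mean_um", "sd_um", "mode_um"))
  expect_identical(glance(fit)$group, "sim")
  h <- diameter_histogram(fit)
  expect_identical(sum(h$count), 1000L)
})

test_that("mouse summaries pool counts before dividing", {
  rec <- tibble::tibble(
    mouse_id = "m1",
    measurable = TRUE,
    mhcii_positive = c(rep(c(TRUE, FALSE), c(10, 90)), rep(c(TRUE, FALSE), c(3, 7))),
    size_class = factor("small", levels = c("small", "intermediate", "large")),
    diameter_um = 15)
  out <- summarize_mouse(rec)
  # 10/100 and 3/10 pool to 13/110, not the mean of the section percentages
  expect_equal(out$pct_mhcii_pos, 100 * 13 / 110)
  expect_identical(out$n_neurons, 110L)
  # small-only scene: the large-class percentage is empty, not zero
  expect_true(is.nan(out$pct_mhcii_pos_large))
})

test_that("group summaries report mean and SEM across mice", {
  mice <- tibble::tibble(mouse_id = c("a", "b"), n_neurons = c(100L, 100L),
                         pct_mhcii_pos = c(20, 40), group = "naive")
  gs <- group_summary(mice)
  row <- gs[gs$metric == "pct_mhcii_pos", ]
  expect_equal(row$mean, 30)
  expect_equal(row$sem, 10)
  expect_identical(row$n_mice, 2L)
  # a group of one has no SEM
  gs1 <- group_summary(mice[1, ])
  expect_true(is.na(gs1$sem[gs1$metric == "pct_mhcii_pos"]))
})

test_that("TPP scoring applies the habituation exclusion rule strictly", {
  trials <- tibble::tibble(
    mouse_id = rep(c("m1", "m2", "m3"), each = 4),
    trial_index = rep(1:4, 3),
    seconds_on_test_plate = c(180, 90, 45, 30,   # m1: full habituation
                              29, 90, 90, 90,    # m2: 29 s -> excluded
                              30, 60, 60, 60))   # m3: exactly 30 s -> kept
  out <- score_tpp(trials)
  expect_equal(out$percent_time[out$mouse_id == "m1" & out$trial_index == 1], 100)
  # m2 keeps only its flagged habituation row
  m2 <- out[out$mouse_id == "m2", ]
  expect_identical(nrow(m2), 1L)
  expect_true(all(m2$excluded))
  # m3 is retained in full (strict <30)
  expect_identical(nrow(out[out$mouse_id == "m3", ]), 4L)
  expect_false(any(out$excluded[out$mouse_id == "m3"]))
  # scale invariance: doubling both trial length and seconds changes nothing
  t2 <- trials
  t2$trial_length_s <- 360
  t2$seconds_on_test_plate <- trials$seconds_on_test_plate * 2
  out2 <- score_tpp(t2, habituation_min_s = 60)
  expect_equal(out2$percent_time, out$percent_time)
  # validation
  bad <- trials; bad$seconds_on_test_plate[2] <- 200
  expect_error(score_tpp(bad), "trial_length")
  expect_error(score_tpp(trials[trials$trial_index > 1, ]), "habituation")
})
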