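test_that("the 2.5 km rule removes distant artefacts only", {
  withr::with_seed(1, {
    near <- toy_track("t1", 1:10, rnorm(10, 0, 50), rnorm(10, 0, 50))
  })
  far <- toy_track("t1", 11:12, c(3000, -3000), c(0, 0))
  track <- rbind(near, far)
  filtered <- filter_outliers(track)
  expect_equal(nrow(filtered), 10L)
  expect_equal(filtered$interval_index, 1:10)

  # idempotence and identity on clean tracks
  expect_identical(filter_outliers(filtered), filtered)
  expect_identical(filter_outliers(near), near)
  single <- toy_track("t1", 1, 5000, 5000)
  expect_equal(nrow(filter_outliers(single)), 1L)
  expect_error(filter_outliers(near[0, ]), "no fixes")
})

test_that("each individual is filtered against its own median", {
  a <- toy_track("a", 1:10, rnorm(10, 0, 10), rnorm(10, 0, 10))
  b <- toy_track("b", 1:10, rnorm(10, 10000, 10), rnorm(10, 0, 10))
  both <- rbind(a, b, toy_track("a", 11, 9000, 0))
  filtered <- filter_outliers(both)
  expect_equal(sum(filtered$tag_id == "a"), 10L)
  expect_equal(sum(filtered$tag_id == "b"), 10L)
})

test_that("paired fixes share intervals and measure separation", {
  a <- toy_track("a", 1:5, 0, 0)
  b <- toy_track("b", 1:5, 30, 40)
  pf <- pair_fixes(a, b)
  expect_equal(nrow(pf), 5L)
  expect_equal(pf$separation, rep(50, 5))
  expect_equal(pair_fixes(a, a)$separation, rep(0, 5))
  expect_equal(nrow(pair_fixes(a, toy_track("b", 6:9, 0, 0))), 0L)
})

test_that("dyad summaries follow their definitions on toy tracks", {
  a <- toy_track("a", 1:4, 0, 0)
  s_sync <- summarize_dyad(a, toy_track("b", 1:4, 3, 4))
  expect_equal(s_sync$frac_simultaneous, 1)
  expect_equal(s_sync$median_gap, 0)
  expect_equal(s_sync$median_separation, 5)
  expect_equal(s_sync$n_paired, 4L)

  # interleaved tracks: even vs odd intervals share nothing, every fix is
  # one interval (15 s) from the partner's nearest fix
  a <- toy_track("a", c(2, 4, 6, 8), 0, 0)
  s_shift <- summarize_dyad(a, toy_track("b", c(3, 5, 7, 9), 0, 0))
  expect_equal(s_shift$frac_simultaneous, 0)
  expect_equal(s_shift$median_gap, 15)
  expect_true(is.na(s_shift$median_separation))
  expect_error(summarize_dyad(a, a[0, ]), "one fix")
})

test_that("dyad summaries are symmetric in the two tracks", {
  withr::with_seed(2, {
    a <- toy_track("a", sort(sample(1:40, 20)), rnorm(20), rnorm(20))
    b <- toy_track("b", sort(sample(1:40, 25)), rnorm(25), rnorm(25))
  })
  ab <- summarize_dyad(a, b)
  ba <- summarize_dyad(b, a)
  expect_equal(ab$median_separation, ba$median_separation)
  expect_equal(ab$frac_simultaneous, ba$frac_simultaneous)
  expect_equal(ab$median_gap, ba$median_gap)
  expect_equal(ab$n_paired, ba$n_paired)
})

test_that("observed separation grows with coupling and confounds noise", {
  cfg <- localization_config()
  med_sep <- vapply(c(0, 50, 200, 600), function(ss) {
    pr <- simulate_pair(movement_params(sigma_pos = 150, sigma_sep = ss),
                        15000, 15, seed = 11)
    summarize_dyad(track_from_positions(pr[[1]], cfg),
                   track_from_positions(pr[[2]], cfg))$median_separation
  }, numeric(1))
  expect_true(all(diff(med_sep) >= 0))

  # a perfectly glued pair still shows positive separation once RSS noise
  # enters through localization
  obs <- observation_model(rss_noise_sd = 5)
  recv <- make_grid(600, 600, 150, "triangular")
  pr <- simulate_pair(movement_params(300, 300, 60, 600, sigma_sep = 0),
                      duration = 900, dt = 5, seed = 12,
                      tag_ids = c("a", "b"))
  det <- simulate_detections(pr, recv, obs, seed = 13)
  model <- calibration_model(obs$intercept_b0, obs$slope_b1,
                             resid_sd = 0.1, d_max = 150)
  locs <- suppressMessages(
    localize_all(det, recv, model, cfg, seed = 14))
  tracks <- split(locs, locs$tag_id)
  s <- summarize_dyad(tracks[["a"]], tracks[["b"]])
  expect_gt(s$median_separation, 5)
  expect_true(is.finite(s$median_separation))
})
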