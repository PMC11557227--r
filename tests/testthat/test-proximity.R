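test_that("movement fit recovers known OU parameters", {
  tr <- simulate_independent(list(movement_params(500, 700, 150, 600)),
                             duration = 75000, dt = 15, seed = 1)[[1]]
  fit <- fit_movement(track_from_positions(tr))
  expect_equal(fit$sigma_pos, 150, tolerance = 0.10)
  expect_equal(fit$tau, 600, tolerance = 0.25)
  expect_equal(fit$center_x, 500, tolerance = 0.2)
  expect_equal(fit$center_y, 700, tolerance = 0.2)
})

test_that("white-noise and constant tracks are handled explicitly", {
  withr::with_seed(2, {
    wn <- toy_track("t1", 1:300, rnorm(300, 0, 50), rnorm(300, 0, 50))
  })
  expect_warning(fit <- fit_movement(wn), "autocorrelation")
  expect_equal(fit$tau, 15)  # floored at the sampling interval

  expect_error(fit_movement(toy_track("t1", 1:60, 5, 5)), "constant")
  expect_error(fit_movement(wn[1:49, ]), "50 fixes")
})

test_that("identical tracks give a proximity ratio of zero", {
  withr::with_seed(3, {
    a <- toy_track("a", 1:100, rnorm(100, 0, 100), rnorm(100, 0, 100))
  })
  res <- proximity_ratio(a, a, make_fit(), make_fit(), n_sims = 50,
                         seed = 4)
  expect_equal(res$ratio, 0)
  expect_equal(res$observed_mean, 0)
})

test_that("proximity preconditions are enforced", {
  withr::with_seed(5, {
    a <- toy_track("a", 1:30, rnorm(30), rnorm(30))
    b <- toy_track("b", 1:30, rnorm(30), rnorm(30))
  })
  expect_error(proximity_ratio(a, b, make_fit(), make_fit(), n_sims = 10,
                               seed = 1), "n_sims")
  short <- a[1:5, ]
  expect_error(proximity_ratio(short, b, make_fit(), make_fit(),
                               n_sims = 50, seed = 1), "paired")
})

test_that("the simulated null matches the analytic mean-separation oracle", {
  # two independent circular normals (same centre, per-axis SD sigma):
  # E||X - Y|| = sigma * sqrt(pi); MC oracle cross-checks the closed form
  sigma <- 150
  oracle <- mc_mean_separation(sigma, n = 1e6)
  expect_equal(oracle, sigma * sqrt(pi), tolerance = 0.005)

  # null simulated at widely spaced times (~independent draws) must agree
  times <- seq(0, by = 7200, length.out = 40)
  a <- data.frame(tag_id = "a", interval_index = seq_along(times),
                  t_mid = times, x = 0, y = 0)
  b <- a
  b$tag_id <- "b"
  fit <- make_fit(sigma_pos = sigma, tau = 600)
  res <- proximity_ratio(a, b, fit, fit, n_sims = 400, seed = 6)
  expect_equal(res$null_mean, oracle, tolerance = 0.02)
})

test_that("CI orientation flags attraction only when observed is low", {
  trs <- simulate_independent(
    list(movement_params(0, 0, 150, 600), movement_params(0, 0, 150, 600)),
    duration = 7500, dt = 15, seed = 7)
  a <- track_from_positions(trs[[1]])
  b <- track_from_positions(trs[[2]])
  res <- proximity_ratio(a, b, fit_movement(a), fit_movement(b),
                         n_sims = 200, seed = 8)
  expect_lte(res$ci_low, res$ratio)
  expect_gte(res$ci_high, res$ratio)
  expect_true(res$ci_low < 1 && res$ci_high > 1)  # independent pair

  glued <- simulate_pair(movement_params(0, 0, 150, 600, sigma_sep = 25),
                         duration = 7500, dt = 15, seed = 9)
  ga <- track_from_positions(glued[[1]])
  gb <- track_from_positions(glued[[2]])
  gres <- proximity_ratio(ga, gb, fit_movement(ga), fit_movement(gb),
                          n_sims = 200, seed = 10)
  expect_lt(gres$ratio, 1)
  expect_lt(gres$ci_high, 1)
})
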