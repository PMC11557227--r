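make_detections <- function(tag, receiver, t, rss) {
  data.frame(tag_id = tag, receiver_id = receiver, t = t, rss = rss,
             stringsAsFactors = FALSE)
}

test_that("RSS windows average detections in lag-shifted tumbling bins", {
  cfg <- localization_config()
  det <- make_detections("t1", "R1", c(0, 2, 4), c(-60, -70, -80))
  win <- window_rss(det, cfg)
  expect_equal(nrow(win), 1L)
  expect_equal(win$mean_rss, -70)
  expect_equal(win$n_detections, 3L)

  # boundary between intervals 0 and 1 sits at t = 10 with the -5 s lag
  det2 <- make_detections("t1", "R1", c(4, 12), c(-60, -60))
  win2 <- window_rss(det2, cfg)
  expect_equal(win2$interval_index, c(0L, 1L))

  one <- window_rss(make_detections("t1", "R1", 3, -55), cfg)
  expect_equal(one$n_detections, 1L)
  expect_equal(nrow(window_rss(det[0, ], cfg)), 0L)
})

test_that("receiver retention keeps only nodes near the strongest signal", {
  cfg <- localization_config(retain_radius = 200)
  recv <- data.frame(receiver_id = c("A", "B", "C"),
                     x = c(0, 150, 250), y = 0)
  rows <- data.frame(tag_id = "t1", interval_index = 0L,
                     receiver_id = c("A", "B", "C"),
                     mean_rss = c(-50, -70, -60), n_detections = 1L,
                     stringsAsFactors = FALSE)
  kept <- select_receivers(rows, recv, cfg)
  expect_setequal(kept$receiver_id, c("A", "B"))

  # all within the radius: identity
  recv2 <- data.frame(receiver_id = c("A", "B", "C"),
                      x = c(0, 100, 180), y = 0)
  expect_equal(nrow(select_receivers(rows, recv2, cfg)), 3L)

  # RSS tie broken by lexicographic receiver id (anchor = A, not C)
  rows_tie <- transform(rows, mean_rss = c(-50, -70, -50))
  expect_setequal(select_receivers(rows_tie, recv, cfg)$receiver_id,
                  c("A", "B"))
  expect_error(select_receivers(transform(rows, receiver_id = c("A", "B", "Z")),
                                recv, cfg), "Z")
})

test_that("noiseless multilateration matches a dense grid-search oracle", {
  rx <- c(0, 100, 0)
  ry <- c(0, 0, 100)
  target <- c(30, 40)
  d <- sqrt((target[1] - rx)^2 + (target[2] - ry)^2)
  est <- data.frame(receiver_id = c("A", "B", "C"), x = rx, y = ry,
                    d_hat = d, d_se = 0)
  fix <- multilaterate(est, localization_config(), seed = 1)
  oracle <- grid_search_position(rx, ry, d, lo = -20, hi = 120)
  expect_lt(sqrt((fix$x - oracle[1])^2 + (fix$y - oracle[2])^2), 0.1)
  expect_lt(sqrt((fix$x - 30)^2 + (fix$y - 40)^2), 0.1)
  expect_equal(fix$ell_a, 0, tolerance = 1e-6)
  expect_equal(fix$ell_b, 0, tolerance = 1e-6)
})

test_that("fewer than three receivers yields no localization", {
  est <- data.frame(receiver_id = c("A", "B"), x = c(0, 100), y = 0,
                    d_hat = c(50, 50), d_se = 0)
  expect_null(multilaterate(est, localization_config(), seed = 1))
})

test_that("error ellipse matches the replicate covariance eigenstructure", {
  withr::with_seed(42, {
    S <- matrix(c(400, 120, 120, 100), 2)
    L <- chol(S)
    pts <- matrix(rnorm(2e4), ncol = 2) %*% L
  })
  ell <- error_ellipse(pts)
  ev <- eigen(cov(pts), symmetric = TRUE)$values   # oracle decomposition
  expect_equal(ell$ell_a, 2 * sqrt(ev[1]), tolerance = 1e-9)
  expect_equal(ell$ell_b, 2 * sqrt(ev[2]), tolerance = 1e-9)
  expect_true(ell$ell_theta >= 0 && ell$ell_theta < pi)
  # orientation near the true leading eigenvector of S
  true_theta <- atan2(eigen(S)$vectors[2, 1], eigen(S)$vectors[1, 1]) %% pi
  expect_equal(ell$ell_theta, true_theta, tolerance = 0.05)
})

test_that("more retained receivers do not worsen accuracy", {
  target <- c(40, 35)
  rx <- c(0, 100, 0, 100, 50, -50)
  ry <- c(0, 0, 100, 100, -50, 50)
  d <- sqrt((target[1] - rx)^2 + (target[2] - ry)^2)
  cfg <- localization_config(n_reps = 50)
  err <- function(n_recv, seed) {
    est <- data.frame(receiver_id = LETTERS[1:n_recv], x = rx[1:n_recv],
                      y = ry[1:n_recv], d_hat = d[1:n_recv], d_se = 15)
    fix <- multilaterate(est, cfg, seed = seed)
    sqrt((fix$x - target[1])^2 + (fix$y - target[2])^2)
  }
  errs3 <- vapply(1:30, function(s) err(3, s), numeric(1))
  errs6 <- vapply(1:30, function(s) err(6, s), numeric(1))
  expect_lte(median(errs6), median(errs3))
})

test_that("the full localizer recovers a noiseless synthetic scene", {
  obs <- observation_model(rss_noise_sd = 0, detection_radius = 400)
  recv <- make_grid(600, 600, 150, "triangular")
  # slow movement (tau >> window) so within-window displacement does not
  # confound solver exactness
  tr <- simulate_independent(list(movement_params(300, 300, 60, 36000)),
                             duration = 450, dt = 5, seed = 3)[[1]]
  det <- simulate_detections(tr, recv, obs, seed = 4)
  # ceiling set to the detection radius so no exact distance is truncated:
  # this isolates solver exactness (truncation bias is tested separately)
  model <- calibration_model(obs$intercept_b0, obs$slope_b1, resid_sd = 0,
                             d_max = 400)
  locs <- localize_all(det, recv, model, localization_config(), seed = 5)
  expect_gt(nrow(locs), 10)
  expect_true(all(locs$n_receivers >= 3))
  expect_true(!is.unsorted(locs$t_mid))
  acc <- assess_accuracy(locs, tr)
  expect_lt(acc$median_error, 1)
})

test_that("tags heard by fewer than three receivers are never localized", {
  cfg <- localization_config()
  model <- calibration_model(-1.27009, -0.03302)
  recv <- data.frame(receiver_id = c("A", "B", "C"),
                     x = c(0, 100, 200), y = 0)
  det2 <- make_detections("t1", rep(c("A", "B"), 4),
                          rep(c(0, 5, 10, 12), each = 2), -60)
  expect_equal(nrow(localize_all(det2, recv, model, cfg, seed = 1)), 0L)
  det3 <- make_detections("t1", rep(c("A", "B", "C"), 2),
                          rep(c(0, 5), each = 3), -60)
  expect_equal(nrow(localize_all(det3, recv, model, cfg, seed = 1)), 1L)
  expect_equal(nrow(localize_all(det2[0, ], recv, model, cfg, seed = 1)),
               0L)
})

test_that("accuracy assessment handles exact and unmatched inputs", {
  tr <- data.frame(tag_id = "t1", t = seq(0, 100, 10),
                   x = seq(0, 100, 10), y = 0)
  locs <- data.frame(tag_id = "t1", t_mid = c(25, 55), x = c(25, 55),
                     y = 0)
  acc <- assess_accuracy(locs, tr)
  expect_equal(acc$median_error, 0)
  expect_equal(acc$n, 2L)
  locs_out <- transform(locs, t_mid = c(500, 600))
  expect_error(assess_accuracy(locs_out, tr), "matched")
})
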