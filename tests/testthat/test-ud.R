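test_that("utilization distributions are normalized probability grids", {
  withr::with_seed(1, {
    tr <- toy_track("t1", 1:200, rnorm(200, 0, 100), rnorm(200, 0, 100))
  })
  u <- estimate_ud(tr, cell = 20)
  expect_s3_class(u, "ud")
  expect_equal(sum(u$mass), 1, tolerance = 1e-9)
  expect_true(all(u$mass >= 0))
  expect_error(estimate_ud(tr[1:9, ], cell = 20), "10 fixes")
})

test_that("degenerate tracks fall back to a cell-size bandwidth", {
  tr <- toy_track("t1", 1:12, 100, 200)
  expect_warning(u <- estimate_ud(tr, cell = 10), "degenerate")
  expect_equal(sum(u$mass), 1, tolerance = 1e-9)
})

test_that("localization uncertainty widens the estimated UD", {
  withr::with_seed(2, {
    tr <- toy_track("t1", 1:500, rnorm(500, 0, 100), rnorm(500, 0, 100))
  })
  noisy <- transform(tr, ell_a = 120, ell_b = 120)
  a_tight <- home_range_area(estimate_ud(tr, cell = 10))
  a_wide <- home_range_area(estimate_ud(noisy, cell = 10))
  expect_gt(a_wide, a_tight)
})

test_that("95% home-range area matches the circular-normal closed form", {
  sigma <- 150
  withr::with_seed(3, {
    tr <- toy_track("t1", 1:10000, rnorm(1e4, 0, sigma),
                    rnorm(1e4, 0, sigma))
  })
  u <- estimate_ud(tr, cell = 10)
  # area of the 95% probability disk: pi * chi2_{0.95,2} * sigma^2
  truth_km2 <- pi * qchisq(0.95, 2) * sigma^2 / 1e6
  expect_equal(home_range_area(u, 0.95), truth_km2, tolerance = 0.1)
})

test_that("home-range area ranks mass and respects the level", {
  m <- matrix(1, 10, 10)
  u <- ud(m, 0, 0, cell = 100)
  expect_equal(home_range_area(u, 0.95), 0.95)  # 95 cells of 0.01 km^2
  expect_gte(home_range_area(u, 1), home_range_area(u, 0.95))
  expect_error(home_range_area(u, 0), "level")
  expect_error(home_range_area(u, 1.2), "level")
})

test_that("Bhattacharyya coefficient hits its bounds and symmetry", {
  u1 <- gaussian_ud(0, 0, 1, cell = 0.1, half_width = 5)
  expect_equal(bhattacharyya(u1, u1), 1, tolerance = 1e-9)

  a <- ud(matrix(c(1, 0, 0, 0), 2), 0, 0, 10)
  b <- ud(matrix(c(0, 0, 0, 1), 2), 0, 0, 10)
  expect_equal(bhattacharyya(a, b), 0)

  withr::with_seed(4, {
    p <- ud(matrix(runif(100), 10), 0, 0, 10)
    q <- ud(matrix(runif(100), 10), 0, 0, 10)
  })
  expect_equal(bhattacharyya(p, q), bhattacharyya(q, p))
  expect_gte(bhattacharyya(p, q), 0)
  expect_lte(bhattacharyya(p, q), 1)
})

test_that("resampling aggregates mass exactly onto a coarser grid", {
  u <- gaussian_ud(0, 0, 2, cell = 0.5, half_width = 8)
  r <- resample_ud(u, origin_x = -9, origin_y = -9, cell = 1, nx = 19,
                   ny = 19)
  expect_equal(sum(r$mass), 1, tolerance = 1e-12)
  # overlap of mismatched grids goes through the common-grid path
  shifted <- gaussian_ud(0.25, 0.25, 2, cell = 0.4, half_width = 8)
  bc <- bhattacharyya(u, shifted)
  expect_gt(bc, 0.9)
  expect_lte(bc, 1)
})

test_that("UD exports are readable plain-text artifacts", {
  u <- gaussian_ud(100, 200, 30, cell = 10, half_width = 90)
  asc <- tempfile(fileext = ".asc")
  write_ud_asc(u, asc)
  header <- readLines(asc, n = 6)
  expect_match(header[1], "^ncols 19$")
  expect_match(header[5], "^cellsize 10")
  body <- scan(asc, skip = 6, quiet = TRUE)
  expect_equal(sum(body), 1, tolerance = 1e-6)

  gj <- jsonlite::fromJSON(ud_contour_geojson(u, 0.95),
                           simplifyVector = FALSE)
  expect_equal(gj$geometry$type, "MultiLineString")
  expect_gt(length(gj$geometry$coordinates), 0)
})
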