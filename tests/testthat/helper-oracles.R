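# Independent oracles and small fixture builders used across the suite.

# Dense grid search for the multilateration objective, refined in two
# stages (1 m then 0.01 m). Independent of the package's solver.
grid_search_position <- function(rx, ry, d, lo, hi) {
  objective <- function(px, py) {
    total <- 0
    for (j in seq_along(rx)) {
      total <- total + (sqrt((px - rx[j])^2 + (py - ry[j])^2) - d[j])^2
    }
    total
  }
  search <- function(x0, x1, y0, y1, step) {
    gx <- seq(x0, x1, by = step)
    gy <- seq(y0, y1, by = step)
    gg <- expand.grid(px = gx, py = gy)
    vals <- objective(gg$px, gg$py)
    as.numeric(gg[which.min(vals), ])
  }
  best <- search(lo, hi, lo, hi, 1)
  best <- search(best[1] - 2, best[1] + 2, best[2] - 2, best[2] + 2, 0.1)
  search(best[1] - 0.2, best[1] + 0.2, best[2] - 0.2, best[2] + 0.2, 0.01)
}

# Euler-Maruyama integration of the OU SDE dx = -(x/tau) dt + sigma
# sqrt(2/tau) dW; empirical long-run SD should approach sigma.
em_ou_sd <- function(sigma, tau, n_steps, dt, seed) {
  withr::with_seed(seed, {
    x <- 0
    out <- numeric(n_steps)
    noise <- rnorm(n_steps, 0, sigma * sqrt(2 * dt / tau))
    for (k in seq_len(n_steps)) {
      x <- x - x * dt / tau + noise[k]
      out[k] <- x
    }
    sd(out[-(1:1000)])  # discard burn-in from the x = 0 start
  })
}

# Brute-force Monte-Carlo mean distance between two independent circular
# bivariate normal points with per-axis SD sigma and a common centre.
mc_mean_separation <- function(sigma, n = 1e6, seed = 424242) {
  withr::with_seed(seed, {
    dx <- rnorm(n, 0, sigma) - rnorm(n, 0, sigma)
    dy <- rnorm(n, 0, sigma) - rnorm(n, 0, sigma)
    mean(sqrt(dx^2 + dy^2))
  })
}

# Movement fit with known parameters (bypasses estimation).
make_fit <- function(center_x = 0, center_y = 0, sigma_pos = 150,
                     tau = 600, dt = 15) {
  structure(list(center_x = center_x, center_y = center_y,
                 sigma_pos = sigma_pos, tau = tau, dt = dt),
            class = "movement_fit")
}

# Circular-Gaussian utilization distribution evaluated analytically.
gaussian_ud <- function(cx, cy, sigma, cell, half_width) {
  gx <- seq(cx - half_width, cx + half_width, by = cell)
  gy <- seq(cy - half_width, cy + half_width, by = cell)
  mass <- outer(dnorm(gx, cx, sigma), dnorm(gy, cy, sigma))
  ud(mass, origin_x = gx[1], origin_y = gy[1], cell = cell)
}

# Minimal localization-shaped track.
toy_track <- function(tag, intervals, x, y, window = 15) {
  data.frame(tag_id = tag, interval_index = as.integer(intervals),
             t_mid = intervals * window + 2.5, x = x, y = y,
             ell_a = 0, ell_b = 0, ell_theta = 0,
             n_receivers = 3L, n_reps = 100L, stringsAsFactors = FALSE)
}
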