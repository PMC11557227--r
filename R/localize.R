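#' Localization configuration
#'
#' Settings of the windowed multilateration pipeline. RSS is averaged in
#' tumbling windows of `window` seconds whose boundaries are shifted `lag`
#' seconds relative to clock-aligned bins: interval `k` covers
#' `[k*window + lag, (k+1)*window + lag)`, so the defaults (15 s window,
#' -5 s lag) give interval 0 = `[-5, 10)` seconds. Only receivers within
#' `retain_radius` of the strongest-signal receiver contribute; at least
#' `min_receivers` are needed for a fix. Each fix is re-solved `n_reps`
#' times with distances perturbed within their standard errors
#' (`perturbation` = `"normal"` for N(0, se), `"uniform"` for U(-se, se)),
#' and the replicate scatter is summarised as a 2-sigma error ellipse.
#'
#' @param window Averaging window, seconds (default 15).
#' @param lag Window boundary shift, seconds (default -5).
#' @param retain_radius Receiver retention radius, metres (default 200).
#' @param min_receivers Minimum receivers per fix (>= 3).
#' @param n_reps Number of resampled replicate solutions (default 100).
#' @param perturbation Replicate perturbation distribution.
#' @return An object of class `localization_config`.
#' @export
localization_config <- function(window = 15, lag = -5, retain_radius = 200,
                                min_receivers = 3, n_reps = 100,
                                perturbation = c("normal", "uniform")) {
  check_number(window, "window", positive = TRUE)
  check_number(lag, "lag")
  check_number(retain_radius, "retain_radius", positive = TRUE)
  check_number(min_receivers, "min_receivers")
  if (min_receivers < 3)
    stop("`min_receivers` must be >= 3 for planar multilateration",
         call. = FALSE)
  check_number(n_reps, "n_reps", positive = TRUE)
  perturbation <- match.arg(perturbation)
  structure(list(window = window, lag = lag, retain_radius = retain_radius,
                 min_receivers = as.integer(min_receivers),
                 n_reps = as.integer(n_reps), perturbation = perturbation),
            class = "localization_config")
}

#' Average detections into RSS windows
#'
#' Assigns each detection to a tumbling interval,
#' `interval_index = floor((t - lag) / window)`, and averages RSS within
#' each (tag, interval, receiver) cell. With the default -5 s lag a
#' detection at time t falls in interval `floor((t + 5) / 15)`.
#'
#' @param detections Data frame `tag_id`, `receiver_id`, `t`, `rss`.
#' @param config A [localization_config()].
#' @return Data frame `tag_id`, `interval_index`, `receiver_id`,
#'   `mean_rss`, `n_detections`. Empty input gives an empty frame.
#' @export
window_rss <- function(detections, config = localization_config()) {
  check_columns(detections, c("tag_id", "receiver_id", "t", "rss"),
                "detections")
  stopifnot(inherits(config, "localization_config"))
  if (!nrow(detections)) {
    return(data.frame(tag_id = character(), interval_index = integer(),
                      receiver_id = character(), mean_rss = numeric(),
                      n_detections = integer()))
  }
  idx <- floor((detections$t - config$lag) / config$window)
  o <- order(detections$tag_id, idx, detections$receiver_id)
  d <- detections[o, , drop = FALSE]
  idx <- idx[o]
  n <- nrow(d)
  new_grp <- c(TRUE, d$tag_id[-1L] != d$tag_id[-n] |
                 idx[-1L] != idx[-n] |
                 d$receiver_id[-1L] != d$receiver_id[-n])
  gid <- cumsum(new_grp)
  sums <- rowsum(d$rss, gid, reorder = TRUE)
  cnt <- tabulate(gid)
  first <- which(new_grp)
  out <- data.frame(
    tag_id = d$tag_id[first],
    interval_index = as.integer(idx[first]),
    receiver_id = d$receiver_id[first],
    mean_rss = as.numeric(sums) / cnt,
    n_detections = cnt,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Retain receivers near the strongest signal
#'
#' Within one (tag, interval), finds the receiver with the highest averaged
#' RSS (ties broken by lexicographically smallest `receiver_id`) and keeps
#' only receivers within `retain_radius` of it. Distant receivers carry
#' little distance information and mostly inject multipath noise.
#'
#' @param interval_rows Windowed rows for a single tag-interval
#'   (from [window_rss()]).
#' @param receivers Receiver coordinate table.
#' @param config A [localization_config()].
#' @return The retained subset of `interval_rows` (anchor always kept).
#' @export
select_receivers <- function(interval_rows, receivers,
                             config = localization_config()) {
  check_columns(interval_rows, c("receiver_id", "mean_rss"), "interval_rows")
  check_receivers(receivers)
  stopifnot(inherits(config, "localization_config"))
  if (!nrow(interval_rows)) return(interval_rows)

  miss <- setdiff(interval_rows$receiver_id, receivers$receiver_id)
  if (length(miss))
    stop("receiver_id not in receiver table: ",
         paste(miss, collapse = ", "), call. = FALSE)
  pos <- receivers[match(interval_rows$receiver_id, receivers$receiver_id), ]
  best <- which(interval_rows$mean_rss == max(interval_rows$mean_rss))
  anchor <- best[order(interval_rows$receiver_id[best])][1L]
  d <- sqrt((pos$x - pos$x[anchor])^2 + (pos$y - pos$y[anchor])^2)
  interval_rows[d <= config$retain_radius, , drop = FALSE]
}

# Mean and 2-sigma ellipse of a cloud of replicate positions. Axes are
# 2*sqrt(eigenvalues) of the sample covariance; theta is the orientation of
# the major axis in [0, pi). Such an ellipse holds 1 - exp(-2) ~ 0.8647 of
# a bivariate normal's mass.
#' Summarise replicate positions as a 2-sigma error ellipse
#'
#' @param points Two-column matrix (x, y) of replicate position solutions.
#' @return List with `x`, `y` (mean position), `ell_a`, `ell_b` (semi-major
#'   and semi-minor axes, metres) and `ell_theta` (radians in `[0, pi)`).
#' @export
error_ellipse <- function(points) {
  points <- as.matrix(points)
  if (ncol(points) != 2L || !nrow(points))
    stop("`points` must be an n x 2 matrix", call. = FALSE)
  mu <- colMeans(points)
  if (nrow(points) < 2L)
    return(list(x = mu[1L], y = mu[2L], ell_a = 0, ell_b = 0, ell_theta = 0))
  S <- cov(points)
  e <- eigen(S, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  theta <- atan2(e$vectors[2L, 1L], e$vectors[1L, 1L]) %% pi
  list(x = mu[1L], y = mu[2L],
       ell_a = 2 * sqrt(ev[1L]), ell_b = 2 * sqrt(ev[2L]),
       ell_theta = theta)
}

# Damped Gauss-Newton for sum_i (||p - r_i|| - d_i)^2, vectorised across
# replicate distance sets. D is n_rep x k; returns n_rep x 2 positions.
solve_multilateration <- function(rx, ry, D, start, max_iter = 80L,
                                  tol = 1e-9, max_step = 250) {
  n <- nrow(D)
  k <- length(rx)
  px <- rep(start[1L], n)
  py <- rep(start[2L], n)
  lambda <- 1e-8
  for (it in seq_len(max_iter)) {
    A11 <- A12 <- A22 <- b1 <- b2 <- numeric(n)
    for (j in seq_len(k)) {
      dx <- px - rx[j]
      dy <- py - ry[j]
      dd <- sqrt(dx^2 + dy^2)
      dd[dd < 1e-9] <- 1e-9
      ux <- dx / dd
      uy <- dy / dd
      r <- dd - D[, j]
      A11 <- A11 + ux * ux
      A12 <- A12 + ux * uy
      A22 <- A22 + uy * uy
      b1 <- b1 + ux * r
      b2 <- b2 + uy * r
    }
    det <- (A11 + lambda) * (A22 + lambda) - A12^2
    det[abs(det) < 1e-12] <- 1e-12
    sx <- ((A22 + lambda) * b1 - A12 * b2) / det
    sy <- ((A11 + lambda) * b2 - A12 * b1) / det
    sn <- sqrt(sx^2 + sy^2)
    shrink <- pmin(1, max_step / pmax(sn, 1e-12))
    px <- px - sx * shrink
    py <- py - sy * shrink
    if (max(sn) < tol) break
  }
  cbind(px, py)
}

#' Multilaterate one tag-interval from distance estimates
#'
#' Solves for the tag position minimising the sum of squared differences
#' between receiver-to-position distances and the RSS-derived distance
#' estimates, starting from a signal-weighted centroid of the retained
#' receivers. The solution is replicated `n_reps` times with each distance
#' perturbed within its standard error (draws truncated below at 0.1 m);
#' the replicate cloud yields the mean position and a 2-sigma error
#' ellipse. Replicates landing more than two grid diagonals outside the
#' retained receivers' bounding box are treated as non-converged and
#' dropped; if more than half fail, no localization is returned.
#'
#' @param estimates Data frame with one row per retained receiver:
#'   `receiver_id`, `x`, `y`, `d_hat`, `d_se`.
#' @param config A [localization_config()].
#' @param seed Integer seed for the replicate perturbations (required).
#' @return One-row data frame (`x`, `y`, `ell_a`, `ell_b`, `ell_theta`,
#'   `n_receivers`, `n_reps`), or `NULL` if fewer than `min_receivers`
#'   receivers are available or too many replicates fail.
#' @export
multilaterate <- function(estimates, config = localization_config(), seed) {
  check_columns(estimates, c("receiver_id", "x", "y", "d_hat", "d_se"),
                "estimates")
  stopifnot(inherits(config, "localization_config"))
  seed <- check_seed(seed)
  if (nrow(estimates) < config$min_receivers) return(NULL)

  withr::with_seed(seed, multilaterate_impl(estimates, config))
}

# Core solver; consumes RNG, assumes the receiver count precondition holds.
multilaterate_impl <- function(estimates, config) {
  k <- nrow(estimates)
  n <- config$n_reps
  noise <- if (config$perturbation == "normal") {
    matrix(rnorm(n * k, 0, rep(estimates$d_se, each = n)), n, k)
  } else {
    matrix(runif(n * k, -rep(estimates$d_se, each = n),
                 rep(estimates$d_se, each = n)), n, k)
  }
  D <- pmax(matrix(estimates$d_hat, n, k, byrow = TRUE) + noise, 0.1)

  w <- 1 / pmax(estimates$d_hat, 1)          # strongest signal pulls hardest
  start <- c(weighted.mean(estimates$x, w), weighted.mean(estimates$y, w))
  sols <- solve_multilateration(estimates$x, estimates$y, D, start)

  bb <- c(range(estimates$x), range(estimates$y))
  diag_len <- sqrt((bb[2L] - bb[1L])^2 + (bb[4L] - bb[3L])^2)
  slack <- 2 * max(diag_len, 1)
  ok <- sols[, 1L] >= bb[1L] - slack & sols[, 1L] <= bb[2L] + slack &
        sols[, 2L] >= bb[3L] - slack & sols[, 2L] <= bb[4L] + slack &
        is.finite(sols[, 1L]) & is.finite(sols[, 2L])
  if (mean(ok) <= 0.5) {
    message(sprintf("multilaterate: %d/%d replicates non-convergent; no fix",
                    sum(!ok), n))
    return(NULL)
  }
  ell <- error_ellipse(sols[ok, , drop = FALSE])
  out <- data.frame(x = ell$x, y = ell$y, ell_a = ell$ell_a,
                    ell_b = ell$ell_b, ell_theta = ell$ell_theta,
                    n_receivers = k, n_reps = sum(ok))
  rownames(out) <- NULL
  out
}

#' Localize all tag-intervals in a detection table
#'
#' Full localization pipeline: window-average RSS, retain receivers near the
#' strongest signal, convert averaged RSS to distances via the calibration,
#' and multilaterate every (tag, interval) heard by at least
#' `min_receivers` receivers. `t_mid` is the interval midpoint,
#' `k * window + window/2 + lag`.
#'
#' @param detections Data frame `tag_id`, `receiver_id`, `t`, `rss`.
#' @param receivers Receiver coordinate table.
#' @param model A [calibration_model()].
#' @param config A [localization_config()].
#' @param seed Integer seed driving all replicate perturbations (required).
#' @return Data frame of localizations, time-sorted within tag: `tag_id`,
#'   `interval_index`, `t_mid`, `x`, `y`, `ell_a`, `ell_b`, `ell_theta`,
#'   `n_receivers`, `n_reps`.
#' @export
localize_all <- function(detections, receivers, model,
                         config = localization_config(), seed) {
  check_receivers(receivers)
  stopifnot(inherits(model, "calibration_model"),
            inherits(config, "localization_config"))
  seed <- check_seed(seed)

  win <- window_rss(detections, config)
  empty <- data.frame(tag_id = character(), interval_index = integer(),
                      t_mid = numeric(), x = numeric(), y = numeric(),
                      ell_a = numeric(), ell_b = numeric(),
                      ell_theta = numeric(), n_receivers = integer(),
                      n_reps = integer())
  if (!nrow(win)) return(empty)

  groups <- split(win, list(win$tag_id, win$interval_index), drop = TRUE)
  withr::with_seed(seed, {
    fixes <- lapply(groups, function(g) {
      kept <- select_receivers(g, receivers, config)
      if (nrow(kept) < config$min_receivers) return(NULL)
      est <- rss_to_distance(kept$mean_rss, model)
      pos <- receivers[match(kept$receiver_id, receivers$receiver_id), ]
      est <- data.frame(receiver_id = kept$receiver_id,
                        x = pos$x, y = pos$y,
                        d_hat = est$d_hat, d_se = est$d_se)
      fix <- multilaterate_impl(est, config)
      if (is.null(fix)) return(NULL)
      cbind(data.frame(tag_id = g$tag_id[1L],
                       interval_index = g$interval_index[1L],
                       t_mid = g$interval_index[1L] * config$window +
                         config$window / 2 + config$lag,
                       stringsAsFactors = FALSE),
            fix)
    })
  })
  out <- do.call(rbind, fixes)
  if (is.null(out)) return(empty)
  out <- out[order(out$tag_id, out$t_mid), ]
  rownames(out) <- NULL
  out
}

#' Assess localization accuracy against ground truth
#'
#' Matches each localization to the true position of its tag at the
#' interval midpoint (linear interpolation of the truth track) and
#' summarises the per-fix Euclidean errors.
#'
#' @param localizations Output of [localize_all()].
#' @param truth Truth track data frame (`tag_id`, `t`, `x`, `y`).
#' @return List with `n`, `median_error`, and `quantiles` (50/90/95%), all
#'   in metres, plus the per-fix `errors`.
#' @export
assess_accuracy <- function(localizations, truth) {
  check_columns(localizations, c("tag_id", "t_mid", "x", "y"),
                "localizations")
  check_columns(truth, c("tag_id", "t", "x", "y"), "truth")

  errs <- unlist(lapply(split(localizations, localizations$tag_id),
                        function(L) {
    tr <- truth[truth$tag_id == L$tag_id[1L], ]
    if (nrow(tr) < 2L) return(numeric())
    inside <- L$t_mid >= min(tr$t) & L$t_mid <= max(tr$t)
    L <- L[inside, , drop = FALSE]
    if (!nrow(L)) return(numeric())
    tx <- approx(tr$t, tr$x, xout = L$t_mid)$y
    ty <- approx(tr$t, tr$y, xout = L$t_mid)$y
    sqrt((L$x - tx)^2 + (L$y - ty)^2)
  }), use.names = FALSE)
  if (!length(errs))
    stop("no localizations could be matched to truth", call. = FALSE)
  list(n = length(errs),
       median_error = median(errs),
       quantiles = quantile(errs, c(0.5, 0.9, 0.95)),
       errors = errs)
}
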