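#' Radio-observation model
#'
#' Generative model linking true tag-receiver distance to received signal
#' strength (RSS, dB). The default coefficients are the inverse of the field
#' calibration `distance = 10^(b0 + b1 * RSS)` with `b0 = -1.27009` and
#' `b1 = -0.03302` (log10-metres per dB), so the expected RSS at distance d
#' is `(log10(d) - b0) / b1`. Gaussian noise of SD `rss_noise_sd` is added
#' to each detection; the field noise magnitude is not pinned down by the
#' deployment, so the default (5 dB) is an explicit, tunable choice.
#' Receivers beyond `detection_radius` never detect the tag (hard dropout).
#'
#' @param intercept_b0 Calibration intercept, log10-metres.
#' @param slope_b1 Calibration slope, log10-metres per dB; must be negative
#'   (signal weakens with distance).
#' @param rss_noise_sd Detection-level RSS noise SD, dB (>= 0).
#' @param detection_radius Hard detection cutoff, metres.
#' @param beacon_interval Tag beacon period, seconds (default 5).
#' @return An object of class `observation_model`.
#' @export
observation_model <- function(intercept_b0 = -1.27009, slope_b1 = -0.03302,
                              rss_noise_sd = 5, detection_radius = 400,
                              beacon_interval = 5) {
  check_number(intercept_b0, "intercept_b0")
  check_number(slope_b1, "slope_b1")
  if (slope_b1 >= 0)
    stop("`slope_b1` must be negative: RSS weakens with distance",
         call. = FALSE)
  check_number(rss_noise_sd, "rss_noise_sd", nonneg = TRUE)
  check_number(detection_radius, "detection_radius", positive = TRUE)
  check_number(beacon_interval, "beacon_interval", positive = TRUE)
  structure(list(intercept_b0 = intercept_b0, slope_b1 = slope_b1,
                 rss_noise_sd = rss_noise_sd,
                 detection_radius = detection_radius,
                 beacon_interval = beacon_interval),
            class = "observation_model")
}

#' @export
print.observation_model <- function(x, ...) {
  cat(sprintf(
    "Observation model: E[RSS] = (log10(d) - %.5f)/%.5f, noise %.1f dB,\n  detection radius %.0f m, beacon every %.0f s\n",
    x$intercept_b0, x$slope_b1, x$rss_noise_sd, x$detection_radius,
    x$beacon_interval))
  invisible(x)
}

# Expected RSS at distance d (metres); d floored at 0.1 m before the log.
expected_rss <- function(d, obs) {
  (log10(pmax(d, 0.1)) - obs$intercept_b0) / obs$slope_b1
}

#' Simulate beacon detections on a receiver grid
#'
#' At each beacon time (every `beacon_interval` seconds along each track),
#' every receiver within `detection_radius` of the tag's true position
#' records a detection with RSS equal to the expected RSS at the true
#' distance plus Gaussian noise. True positions are linearly interpolated
#' to beacon times when the track is sampled on a different step.
#'
#' @param tracks A track data frame (`tag_id`, `t`, `x`, `y`) or a list of
#'   them; times must be sorted within each tag.
#' @param receivers Receiver table from [make_grid()] or [read_receivers()].
#' @param obs An [observation_model()].
#' @param seed Integer seed (required).
#' @return Data frame of detections: `tag_id`, `receiver_id`, `t`, `rss`.
#' @export
simulate_detections <- function(tracks, receivers, obs, seed) {
  if (is.data.frame(tracks)) tracks <- split(tracks, tracks$tag_id)
  if (!length(tracks)) stop("no tracks supplied", call. = FALSE)
  check_receivers(receivers)
  stopifnot(inherits(obs, "observation_model"))
  seed <- check_seed(seed)

  withr::with_seed(seed, {
    per_tag <- lapply(tracks, function(tr) {
      check_columns(tr, c("tag_id", "t", "x", "y"), "track")
      if (is.unsorted(tr$t, strictly = TRUE))
        stop("track times must be strictly increasing per tag", call. = FALSE)
      if (nrow(tr) == 1L) {
        beacons <- tr$t
        bx <- tr$x
        by <- tr$y
      } else {
        beacons <- seq(min(tr$t), max(tr$t), by = obs$beacon_interval)
        bx <- approx(tr$t, tr$x, xout = beacons)$y
        by <- approx(tr$t, tr$y, xout = beacons)$y
      }
      dx <- outer(bx, receivers$x, "-")
      dy <- outer(by, receivers$y, "-")
      dmat <- sqrt(dx^2 + dy^2)             # beacons x receivers
      hit <- which(dmat <= obs$detection_radius, arr.ind = TRUE)
      if (!nrow(hit)) return(NULL)
      hit <- hit[order(hit[, 1L], hit[, 2L]), , drop = FALSE]
      d <- dmat[hit]
      data.frame(
        tag_id = tr$tag_id[1L],
        receiver_id = receivers$receiver_id[hit[, 2L]],
        t = beacons[hit[, 1L]],
        rss = expected_rss(d, obs) + rnorm(length(d), 0, obs$rss_noise_sd),
        stringsAsFactors = FALSE
      )
    })
  })
  out <- do.call(rbind, per_tag)
  if (is.null(out))
    out <- data.frame(tag_id = character(), receiver_id = character(),
                      t = numeric(), rss = numeric())
  rownames(out) <- NULL
  out
}

#' Simulate a calibration exercise
#'
#' Emulates holding reference tags at a fixed set of distances from
#' receivers and recording RSS: `reps_per_distance` noisy RSS draws at each
#' distance. The default distances are the standard ten-step ladder
#' (1--150 m) and the default replication (24 = 6 tags x 4 receivers)
#' mirrors a typical field calibration.
#'
#' @param distances Positive distances in metres.
#' @param obs An [observation_model()].
#' @param reps_per_distance Number of RSS draws per distance.
#' @param seed Integer seed (required).
#' @return Data frame with columns `distance_m`, `rss`.
#' @export
simulate_calibration <- function(distances = c(1, 2, 5, 10, 15, 25, 50, 75,
                                               100, 150),
                                 obs = observation_model(),
                                 reps_per_distance = 24, seed) {
  if (!length(distances)) stop("`distances` must be non-empty", call. = FALSE)
  if (!all(is.finite(distances)) || any(distances <= 0))
    stop("`distances` must all be positive", call. = FALSE)
  stopifnot(inherits(obs, "observation_model"))
  check_number(reps_per_distance, "reps_per_distance", positive = TRUE)
  seed <- check_seed(seed)

  d <- rep(distances, each = reps_per_distance)
  withr::with_seed(seed, {
    rss <- expected_rss(d, obs) + rnorm(length(d), 0, obs$rss_noise_sd)
  })
  data.frame(distance_m = d, rss = rss)
}
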