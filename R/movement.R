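#' Movement-process parameters
#'
#' Parameters of the Ornstein-Uhlenbeck (OU) movement model used by the
#' simulators: a mean-reverting Gaussian process, the standard stationary
#' home-range model. `sigma_pos` is the stationary per-axis SD of position
#' around the home-range centre; `tau` is the autocorrelation timescale.
#' For coupled pairs, `sigma_sep` is the stationary per-axis SD of the
#' pair-separation vector: 0 means a perfectly glued pair.
#'
#' @param center_x,center_y Home-range centre, metres.
#' @param sigma_pos Stationary positional SD per axis, metres (> 0).
#' @param tau Autocorrelation timescale, seconds (> 0).
#' @param sigma_sep Stationary SD of the separation process, metres (>= 0).
#' @return An object of class `movement_params`.
#' @export
movement_params <- function(center_x = 0, center_y = 0, sigma_pos = 150,
                            tau = 600, sigma_sep = 0) {
  check_number(center_x, "center_x")
  check_number(center_y, "center_y")
  check_number(sigma_pos, "sigma_pos", positive = TRUE)
  check_number(tau, "tau", positive = TRUE)
  check_number(sigma_sep, "sigma_sep", nonneg = TRUE)
  structure(list(center_x = center_x, center_y = center_y,
                 sigma_pos = sigma_pos, tau = tau, sigma_sep = sigma_sep),
            class = "movement_params")
}

#' @export
print.movement_params <- function(x, ...) {
  cat(sprintf(
    "OU movement: centre (%.1f, %.1f) m, sigma_pos %.1f m, tau %.0f s, sigma_sep %.1f m\n",
    x$center_x, x$center_y, x$sigma_pos, x$tau, x$sigma_sep))
  invisible(x)
}

# Stationary OU sample paths at arbitrary (sorted) times, via the exact
# discrete transition x_{k+1} = mu + phi (x_k - mu) + sigma sqrt(1-phi^2) z,
# phi = exp(-dt/tau). Stationary at every step, for any dt. For regular
# steps the recursion is delegated to stats::filter (column-wise AR(1)).
# Returns list(x, y): n_times x n_sim matrices. Consumes RNG; callers seed.
ou_paths <- function(times, center_x, center_y, sigma, tau, n_sim = 1L) {
  n <- length(times)
  if (n < 1L) stop("`times` must be non-empty", call. = FALSE)
  if (is.unsorted(times, strictly = TRUE))
    stop("`times` must be strictly increasing", call. = FALSE)
  if (sigma <= 0) {
    return(list(x = matrix(center_x, n, n_sim),
                y = matrix(center_y, n, n_sim)))
  }
  dts <- diff(times)
  one_axis <- function(mu) {
    z <- matrix(rnorm(n * n_sim), n, n_sim)
    if (n == 1L) return(mu + sigma * z)
    if (diff(range(dts)) < 1e-9) {
      phi <- exp(-dts[1] / tau)
      innov <- z * (sigma * sqrt(1 - phi^2))
      innov[1L, ] <- z[1L, ] * sigma           # stationary start
      dev <- stats::filter(innov, phi, method = "recursive")
      mu + matrix(as.numeric(dev), n, n_sim)
    } else {
      phi <- exp(-dts / tau)
      isd <- sigma * sqrt(1 - phi^2)
      dev <- matrix(0, n, n_sim)
      dev[1L, ] <- sigma * z[1L, ]
      for (k in 2:n)
        dev[k, ] <- phi[k - 1L] * dev[k - 1L, ] + isd[k - 1L] * z[k, ]
      mu + dev
    }
  }
  list(x = one_axis(center_x), y = one_axis(center_y))
}

new_track_df <- function(tag_id, t, x, y) {
  data.frame(tag_id = tag_id, t = t, x = x, y = y, stringsAsFactors = FALSE)
}

#' Simulate a spatially coupled pair of movement tracks
#'
#' Generates ground-truth tracks for two individuals that share a home range
#' and move together. The pair's shared path `S(t)` is a stationary OU
#' process per axis (SD `sigma_pos`, timescale `tau`) around the home-range
#' centre; an independent OU separation vector `D(t)` (SD `sigma_sep`, same
#' `tau`) splits the two individuals as `S + D/2` and `S - D/2`. With
#' `sigma_sep = 0` the two tracks coincide exactly.
#'
#' @param params A [movement_params()] object.
#' @param duration Track duration in seconds (>= `dt`).
#' @param dt Sampling step in seconds; must satisfy `dt <= tau / 5` so the
#'   discretisation resolves the autocorrelation.
#' @param seed Integer seed (required; all randomness is explicit).
#' @param tag_ids Character vector of length 2 naming the two individuals.
#' @return A list of two data frames (`tag_id`, `t`, `x`, `y`).
#' @export
simulate_pair <- function(params, duration, dt, seed,
                          tag_ids = c("bird1", "bird2")) {
  stopifnot(inherits(params, "movement_params"))
  check_number(duration, "duration", positive = TRUE)
  check_number(dt, "dt", positive = TRUE)
  if (duration < dt) stop("`duration` must be >= `dt`", call. = FALSE)
  if (dt > params$tau / 5)
    stop("`dt` must be <= tau/5 to resolve the movement autocorrelation",
         call. = FALSE)
  seed <- check_seed(seed)
  stopifnot(length(tag_ids) == 2L)

  times <- seq(0, duration, by = dt)
  withr::with_seed(seed, {
    S <- ou_paths(times, params$center_x, params$center_y,
                  params$sigma_pos, params$tau)
    D <- ou_paths(times, 0, 0, params$sigma_sep, params$tau)
  })
  list(
    new_track_df(tag_ids[1], times, S$x[, 1] + D$x[, 1] / 2,
                 S$y[, 1] + D$y[, 1] / 2),
    new_track_df(tag_ids[2], times, S$x[, 1] - D$x[, 1] / 2,
                 S$y[, 1] - D$y[, 1] / 2)
  )
}

#' Simulate independent movement tracks
#'
#' One stationary OU track per entry of `params_list`, each driven by an
#' independent noise stream (any `sigma_sep` values are ignored).
#'
#' @param params_list List of [movement_params()] objects (may be empty).
#' @param duration,dt,seed As in [simulate_pair()].
#' @param tag_ids Optional character vector naming the tracks.
#' @return A list of track data frames (`tag_id`, `t`, `x`, `y`).
#' @export
simulate_independent <- function(params_list, duration, dt, seed,
                                 tag_ids = NULL) {
  if (!is.list(params_list))
    stop("`params_list` must be a list of movement_params", call. = FALSE)
  if (!length(params_list)) return(list())
  check_number(duration, "duration", positive = TRUE)
  check_number(dt, "dt", positive = TRUE)
  if (duration < dt) stop("`duration` must be >= `dt`", call. = FALSE)
  seed <- check_seed(seed)
  if (is.null(tag_ids)) tag_ids <- sprintf("tag%02d", seq_along(params_list))
  stopifnot(length(tag_ids) == length(params_list))

  times <- seq(0, duration, by = dt)
  withr::with_seed(seed, {
    lapply(seq_along(params_list), function(i) {
      p <- params_list[[i]]
      stopifnot(inherits(p, "movement_params"))
      if (dt > p$tau / 5)
        stop("`dt` must be <= tau/5 to resolve the movement autocorrelation",
             call. = FALSE)
      path <- ou_paths(times, p$center_x, p$center_y, p$sigma_pos, p$tau)
      new_track_df(tag_ids[i], times, path$x[, 1], path$y[, 1])
    })
  })
}
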