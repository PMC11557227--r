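#' Remove outlying fixes from a localization stream
#'
#' Drops fixes lying further than `threshold` metres (default 2.5 km) from
#' the component-wise median coordinates of each individual's fixes. Such
#' points are almost always multipath artefacts rather than movement.
#' Order is preserved and the filter is idempotent.
#'
#' @param localizations Localization data frame (`tag_id`, `x`, `y`, ...);
#'   may contain several tags, each filtered against its own median.
#' @param threshold Removal distance in metres (default 2500).
#' @return The filtered data frame.
#' @export
filter_outliers <- function(localizations, threshold = 2500) {
  check_columns(localizations, c("tag_id", "x", "y"), "localizations")
  check_number(threshold, "threshold", positive = TRUE)
  if (!nrow(localizations))
    stop("no fixes to filter", call. = FALSE)
  keep <- unsplit(lapply(split(localizations, localizations$tag_id),
                         function(L) {
    mx <- median(L$x)
    my <- median(L$y)
    sqrt((L$x - mx)^2 + (L$y - my)^2) <= threshold
  }), localizations$tag_id)
  out <- localizations[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Turn true positions into a track of fixes
#'
#' Convenience for analyses that operate directly on simulated ground-truth
#' positions: assigns each position an `interval_index` on the same tumbling
#' grid the localizer uses and zero-size error ellipses.
#'
#' @param positions Data frame `tag_id`, `t`, `x`, `y`.
#' @param config A [localization_config()] fixing the interval grid.
#' @return A localization-shaped data frame.
#' @export
track_from_positions <- function(positions, config = localization_config()) {
  check_columns(positions, c("tag_id", "t", "x", "y"), "positions")
  stopifnot(inherits(config, "localization_config"))
  data.frame(
    tag_id = positions$tag_id,
    interval_index = as.integer(floor((positions$t - config$lag) /
                                        config$window)),
    t_mid = positions$t,
    x = positions$x, y = positions$y,
    ell_a = 0, ell_b = 0, ell_theta = 0,
    n_receivers = NA_integer_, n_reps = NA_integer_,
    stringsAsFactors = FALSE
  )
}

#' Pair simultaneous fixes of two tracks
#'
#' Two fixes are simultaneous when they share a localization interval.
#' Returns one row per shared interval with the Euclidean separation.
#'
#' @param track_a,track_b Localization data frames with `interval_index`.
#' @return Data frame `interval_index`, `t_mid`, `separation` (metres).
#' @export
pair_fixes <- function(track_a, track_b) {
  check_columns(track_a, c("interval_index", "t_mid", "x", "y"), "track_a")
  check_columns(track_b, c("interval_index", "t_mid", "x", "y"), "track_b")
  shared <- intersect(track_a$interval_index, track_b$interval_index)
  if (!length(shared)) {
    return(data.frame(interval_index = integer(), t_mid = numeric(),
                      separation = numeric()))
  }
  ia <- match(shared, track_a$interval_index)
  ib <- match(shared, track_b$interval_index)
  out <- data.frame(
    interval_index = as.integer(shared),
    t_mid = track_a$t_mid[ia],
    separation = sqrt((track_a$x[ia] - track_b$x[ib])^2 +
                        (track_a$y[ia] - track_b$y[ib])^2)
  )
  out <- out[order(out$interval_index), ]
  rownames(out) <- NULL
  out
}

#' Summarise spatial cohesion of a dyad
#'
#' Computes the separation summaries for a pair of tracked individuals:
#' the median separation over simultaneous (shared-interval) fixes, the
#' fraction of fixes that were simultaneous (paired count divided by the
#' mean of the two individuals' fix counts), and the median time from each
#' fix to the partner's nearest fix.
#'
#' @param track_a,track_b Localization data frames (at least one fix each).
#' @return One-row data frame `tag_a`, `tag_b`, `median_separation`,
#'   `frac_simultaneous`, `median_gap`, `n_paired`. `median_separation` is
#'   `NA` when no fixes pair up; gaps are computed regardless.
#' @export
summarize_dyad <- function(track_a, track_b) {
  check_columns(track_a, c("tag_id", "interval_index", "t_mid", "x", "y"),
                "track_a")
  check_columns(track_b, c("tag_id", "interval_index", "t_mid", "x", "y"),
                "track_b")
  if (!nrow(track_a) || !nrow(track_b))
    stop("both tracks need at least one fix", call. = FALSE)

  paired <- pair_fixes(track_a, track_b)
  nearest_gap <- function(from, to)
    vapply(from, function(t) min(abs(to - t)), numeric(1))
  gaps <- c(nearest_gap(track_a$t_mid, track_b$t_mid),
            nearest_gap(track_b$t_mid, track_a$t_mid))
  data.frame(
    tag_a = track_a$tag_id[1L],
    tag_b = track_b$tag_id[1L],
    median_separation = if (nrow(paired)) median(paired$separation)
                        else NA_real_,
    frac_simultaneous = nrow(paired) /
      mean(c(nrow(track_a), nrow(track_b))),
    median_gap = median(gaps),
    n_paired = nrow(paired),
    stringsAsFactors = FALSE
  )
}
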