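#' Configuration for an end-to-end synthetic scene
#'
#' Bundles every tunable of the simulate-localize-analyse pipeline. The
#' defaults describe the reference scene: a triangular receiver grid at
#' 150 m spacing over ~1.5 km^2; two sub-colony sites, each with three
#' tagged pairs; stationary OU movement with a 600 s timescale composed of
#' a site-shared component (`sigma_site`), a pair-shared component
#' (`sigma_pair`) and a per-pair separation process (`sigma_sep`); tags
#' beaconing every 5 s with 5 dB RSS noise and a 400 m hard detection
#' radius; and the standard localization settings (15 s window, -5 s lag,
#' 200 m retention, >= 3 receivers, 100 replicates, 150 m truncation via
#' the fitted calibration).
#'
#' @param n_sites Number of sub-colony sites.
#' @param pairs_per_site Tagged pairs per site.
#' @param extent Square study-area side, metres.
#' @param spacing Receiver spacing, metres.
#' @param layout Receiver grid layout, `"triangular"` or `"square"`.
#' @param sigma_site SD of the site-shared movement component, metres.
#'   Neighbours at one site are correlated only through this component
#'   (they jointly track shared resources); set 0 for fully independent
#'   neighbours.
#' @param sigma_pair SD of the pair-shared movement component, metres.
#' @param sigma_sep SD of the within-pair separation process, metres.
#' @param tau Movement autocorrelation timescale, seconds.
#' @param center_jitter_sd SD of pair-centre scatter around the site
#'   centre, metres.
#' @param duration Simulated tracking duration, seconds.
#' @param dt Movement simulation step, seconds.
#' @param rss_noise_sd,detection_radius,beacon_interval Observation model;
#'   see [observation_model()].
#' @param calib_reps RSS draws per calibration distance (default 24).
#' @param window,lag,retain_radius,min_receivers,n_reps Localization
#'   settings; see [localization_config()].
#' @param outlier_threshold Trajectory outlier cutoff, metres.
#' @param ud_cell UD grid cell, metres.
#' @param n_sims Null simulations per proximity ratio.
#' @param n_perm Permutations per comparison test.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(n_sites = 2, pairs_per_site = 3, extent = 1224,
                            spacing = 150, layout = "triangular",
                            sigma_site = 75, sigma_pair = 125,
                            sigma_sep = 25, tau = 600,
                            center_jitter_sd = 100,
                            duration = 3600, dt = 5,
                            rss_noise_sd = 5, detection_radius = 400,
                            beacon_interval = 5, calib_reps = 24,
                            window = 15, lag = -5, retain_radius = 200,
                            min_receivers = 3, n_reps = 100,
                            outlier_threshold = 2500, ud_cell = 25,
                            n_sims = 100, n_perm = 999) {
  structure(as.list(environment()), class = "pipeline_config")
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage `%s` failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full synthetic-scene pipeline
#'
#' Simulates a multi-site scene with known ground truth, then runs the
#' complete analysis: calibration fit, windowed multilateration, outlier
#' filtering, dyad separation summaries, utilization distributions with
#' home-range areas and Bhattacharyya overlap, proximity ratios against the
#' independent-movement null, and within-site permutation tests contrasting
#' partner and neighbour dyads. Every stage is seeded from `seed`; a fixed
#' (config, seed) gives byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param seed Integer master seed (required).
#' @param out_dir Optional directory; when given, `localizations.csv`,
#'   `dyads.csv`, `proximity.csv`, `bc_matrix.csv`,
#'   `hourly_separation.csv` and `report.json` are written there.
#' @param quiet Suppress per-stage log messages.
#' @return A list of class `pairtrack_report`: inputs (`receivers`,
#'   `truth`, `detections`, fitted `model`), intermediates
#'   (`localizations`, `tracks`, `uds`, `fits`), dyad-level results
#'   (`dyads`, `bc_matrix`), `tests` (one [permutation_test()] per metric)
#'   and `report` (group medians, home-range summary, localization
#'   accuracy).
#' @export
run_pipeline <- function(config = pipeline_config(), seed, out_dir = NULL,
                         quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- check_seed(seed)
  say <- function(...) if (!quiet) message(sprintf(...))

  n_dyads <- config$n_sites * choose(2L * config$pairs_per_site, 2L)
  n_seeds <- 8L + config$n_sites * (2L + config$pairs_per_site) + n_dyads
  seeds <- withr::with_seed(seed, sample.int(2^31 - 2L, n_seeds))
  next_seed <- local({
    i <- 0L
    function() {
      i <<- i + 1L
      seeds[i]
    }
  })

  # --- simulate ---------------------------------------------------------
  sim <- run_stage("simulate", {
    if (config$duration < config$dt)
      stop("duration must cover at least one movement step")
    receivers <- make_grid(config$extent, config$extent, config$spacing,
                           config$layout)
    obs <- observation_model(rss_noise_sd = config$rss_noise_sd,
                             detection_radius = config$detection_radius,
                             beacon_interval = config$beacon_interval)
    calib <- simulate_calibration(obs = obs,
                                  reps_per_distance = config$calib_reps,
                                  seed = next_seed())
    times <- seq(0, config$duration, by = config$dt)
    frac <- seq_len(config$n_sites) / (config$n_sites + 1)
    site_centers <- cbind(config$extent * frac, config$extent * frac)

    tracks <- list()
    dyads <- NULL
    for (s in seq_len(config$n_sites)) {
      site_dev <- withr::with_seed(next_seed(),
        ou_paths(times, 0, 0, config$sigma_site, config$tau))
      centers <- withr::with_seed(next_seed(), cbind(
        rnorm(config$pairs_per_site, site_centers[s, 1L],
              config$center_jitter_sd),
        rnorm(config$pairs_per_site, site_centers[s, 2L],
              config$center_jitter_sd)))
      site_tags <- character()
      pair_of <- character()
      for (p in seq_len(config$pairs_per_site)) {
        ids <- sprintf("S%dP%d%s", s, p, c("a", "b"))
        pr <- simulate_pair(
          movement_params(centers[p, 1L], centers[p, 2L],
                          sigma_pos = config$sigma_pair, tau = config$tau,
                          sigma_sep = config$sigma_sep),
          duration = config$duration, dt = config$dt,
          seed = next_seed(), tag_ids = ids)
        for (b in 1:2) {
          pr[[b]]$x <- pr[[b]]$x + site_dev$x[, 1L]
          pr[[b]]$y <- pr[[b]]$y + site_dev$y[, 1L]
          tracks[[ids[b]]] <- pr[[b]]
        }
        site_tags <- c(site_tags, ids)
        pair_of <- c(pair_of, rep(sprintf("S%dP%d", s, p), 2L))
        dyads <- rbind(dyads, data.frame(
          tag_a = ids[1L], tag_b = ids[2L], relationship = "partner",
          site = sprintf("S%d", s), stringsAsFactors = FALSE))
      }
      combos <- utils::combn(seq_along(site_tags), 2L)
      for (k in seq_len(ncol(combos))) {
        i <- combos[1L, k]
        j <- combos[2L, k]
        if (pair_of[i] == pair_of[j]) next
        dyads <- rbind(dyads, data.frame(
          tag_a = site_tags[i], tag_b = site_tags[j],
          relationship = "neighbour", site = sprintf("S%d", s),
          stringsAsFactors = FALSE))
      }
    }
    truth <- do.call(rbind, tracks)
    rownames(truth) <- NULL
    detections <- simulate_detections(tracks, receivers, obs,
                                      seed = next_seed())
    list(receivers = receivers, obs = obs, calib = calib, truth = truth,
         dyads = dyads, detections = detections)
  })
  say("stage=simulate tags=%d detections=%d dyads=%d",
      length(unique(sim$truth$tag_id)), nrow(sim$detections),
      nrow(sim$dyads))

  # --- calibrate --------------------------------------------------------
  model <- run_stage("calibrate", fit_calibration(sim$calib))
  say("stage=calibrate b0=%.5f b1=%.5f resid_sd=%.4f", model$b0, model$b1,
      model$resid_sd)

  # --- localize ---------------------------------------------------------
  loc_config <- localization_config(window = config$window,
                                    lag = config$lag,
                                    retain_radius = config$retain_radius,
                                    min_receivers = config$min_receivers,
                                    n_reps = config$n_reps)
  locs <- run_stage("localize",
    suppressMessages(localize_all(sim$detections, sim$receivers, model,
                                  loc_config, seed = next_seed())))
  if (!nrow(locs))
    run_stage("localize", stop("no localizations produced"))
  say("stage=localize intervals_in=%d fixes_out=%d",
      nrow(window_rss(sim$detections, loc_config)), nrow(locs))

  # --- clean ------------------------------------------------------------
  clean <- run_stage("clean",
                     filter_outliers(locs, config$outlier_threshold))
  say("stage=clean fixes_in=%d fixes_out=%d", nrow(locs), nrow(clean))
  tracks <- split(clean, clean$tag_id)

  # --- summarize --------------------------------------------------------
  dyads <- run_stage("summarize", {
    cbind(sim$dyads, do.call(rbind, lapply(seq_len(nrow(sim$dyads)),
                                           function(i) {
      s <- summarize_dyad(tracks[[sim$dyads$tag_a[i]]],
                          tracks[[sim$dyads$tag_b[i]]])
      s[, c("median_separation", "frac_simultaneous", "median_gap",
            "n_paired")]
    })))
  })
  dyads$weight <- dyads$n_paired * config$window
  say("stage=summarize dyads=%d median_paired=%d", nrow(dyads),
      as.integer(median(dyads$n_paired)))

  # --- space_use --------------------------------------------------------
  space <- run_stage("space_use", {
    uds <- lapply(tracks, estimate_ud, cell = config$ud_cell)
    areas <- vapply(uds, home_range_area, numeric(1))
    fits <- lapply(tracks, fit_movement)
    tags <- names(tracks)
    bc <- matrix(1, length(tags), length(tags),
                 dimnames = list(tags, tags))
    for (i in seq_along(tags)) {
      for (j in seq_len(i - 1L)) {
        bc[i, j] <- bc[j, i] <- bhattacharyya(uds[[i]], uds[[j]])
      }
    }
    prox <- do.call(rbind, lapply(seq_len(nrow(dyads)), function(k) {
      tryCatch(
        proximity_ratio(tracks[[dyads$tag_a[k]]], tracks[[dyads$tag_b[k]]],
                        fits[[dyads$tag_a[k]]], fits[[dyads$tag_b[k]]],
                        n_sims = config$n_sims, seed = next_seed()),
        error = function(e) data.frame(
          ratio = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
          n_sims = NA_integer_, observed_mean = NA_real_,
          null_mean = NA_real_, n_paired = NA_integer_))
    }))
    list(uds = uds, areas = areas, fits = fits, bc_matrix = bc,
         prox = prox)
  })
  dyads$bc <- space$bc_matrix[cbind(dyads$tag_a, dyads$tag_b)]
  dyads <- cbind(dyads, space$prox[, c("ratio", "ci_low", "ci_high",
                                       "n_sims")])
  say("stage=space_use mean_area_km2=%.3f prox_ok=%d",
      mean(space$areas), sum(is.finite(dyads$ratio)))

  # --- comparison -------------------------------------------------------
  tests <- run_stage("comparison", {
    lapply(setNames(nm = c("bc", "ratio", "median_separation")),
           function(m) permutation_test(dyads, m, n_perm = config$n_perm,
                                        seed = next_seed()))
  })

  # descriptive separation-by-hour table (time-of-day smooths are out of
  # scope; this is the raw analogue)
  hourly <- run_stage("comparison", {
    rows <- do.call(rbind, lapply(seq_len(nrow(dyads)), function(k) {
      pf <- pair_fixes(tracks[[dyads$tag_a[k]]], tracks[[dyads$tag_b[k]]])
      if (!nrow(pf)) return(NULL)
      data.frame(relationship = dyads$relationship[k],
                 hour = floor((pf$t_mid %% 86400) / 3600),
                 separation = pf$separation)
    }))
    agg <- aggregate(separation ~ relationship + hour, rows, median)
    names(agg)[3L] <- "median_separation"
    agg[order(agg$relationship, agg$hour), ]
  })

  accuracy <- assess_accuracy(clean, sim$truth)
  group_median <- function(col) {
    vapply(split(dyads[[col]], dyads$relationship),
           median, numeric(1), na.rm = TRUE)
  }
  report <- list(
    n_tags = length(tracks),
    n_fixes = nrow(clean),
    median_localization_error_m = accuracy$median_error,
    mean_home_range_km2 = mean(space$areas),
    median_bc = group_median("bc"),
    median_ratio = group_median("ratio"),
    median_separation = group_median("median_separation"),
    frac_ratio_below_1 = mean(dyads$ratio < 1, na.rm = TRUE),
    p_values = vapply(tests, function(t) t$p_value, numeric(1))
  )
  say("stage=comparison partner_bc=%.3f neighbour_bc=%.3f partner_ratio=%.3f neighbour_ratio=%.3f",
      report$median_bc[["partner"]], report$median_bc[["neighbour"]],
      report$median_ratio[["partner"]], report$median_ratio[["neighbour"]])

  out <- structure(list(
    config = config, seed = seed, receivers = sim$receivers,
    truth = sim$truth, detections = sim$detections, calib = sim$calib,
    model = model, localizations = locs, tracks = tracks,
    uds = space$uds, areas = space$areas, fits = space$fits,
    bc_matrix = space$bc_matrix, dyads = dyads, tests = tests,
    hourly = hourly, accuracy = accuracy, report = report
  ), class = "pairtrack_report")

  if (!is.null(out_dir)) write_report(out, out_dir)
  out
}

#' @export
print.pairtrack_report <- function(x, ...) {
  r <- x$report
  cat(sprintf("Synthetic-scene tracking report (seed %d)\n", x$seed))
  cat(sprintf("  %d tags, %d fixes; median localization error %.1f m\n",
              r$n_tags, r$n_fixes, r$median_localization_error_m))
  cat(sprintf("  mean 95%% home range %.3f km^2\n", r$mean_home_range_km2))
  cat(sprintf("  median BC: partner %.3f vs neighbour %.3f (p = %.3g)\n",
              r$median_bc[["partner"]], r$median_bc[["neighbour"]],
              r$p_values[["bc"]]))
  cat(sprintf("  median proximity ratio: partner %.3f vs neighbour %.3f (p = %.3g)\n",
              r$median_ratio[["partner"]], r$median_ratio[["neighbour"]],
              r$p_values[["ratio"]]))
  cat(sprintf("  median separation: partner %.1f m vs neighbour %.1f m\n",
              r$median_separation[["partner"]],
              r$median_separation[["neighbour"]]))
  cat(sprintf("  dyads with ratio < 1: %.0f%%\n",
              100 * r$frac_ratio_below_1))
  invisible(x)
}

write_report <- function(x, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(x$localizations, file.path(out_dir, "localizations.csv"),
            row.names = FALSE)
  write.csv(x$dyads, file.path(out_dir, "dyads.csv"), row.names = FALSE)
  prox_cols <- c("tag_a", "tag_b", "relationship", "ratio", "ci_low",
                 "ci_high", "n_sims")
  write.csv(x$dyads[, prox_cols], file.path(out_dir, "proximity.csv"),
            row.names = FALSE)
  write.csv(as.data.frame(x$bc_matrix),
            file.path(out_dir, "bc_matrix.csv"))
  write.csv(x$hourly, file.path(out_dir, "hourly_separation.csv"),
            row.names = FALSE)
  jsonlite::write_json(x$report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = 10)
  invisible(out_dir)
}
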