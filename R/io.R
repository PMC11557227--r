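#' Read and write the pipeline's tabular interchange formats
#'
#' Thin, header-validated CSV readers/writers for the standard files:
#' `receivers.csv` (`receiver_id,x,y`; metres), `detections.csv`
#' (`tag_id,receiver_id,t,rss`; seconds, dB), `calibration.csv`
#' (`distance_m,rss`), truth tracks (`tag_id,t,x,y`) and localizations
#' (`tag_id,t_mid,x,y,ell_a,ell_b,ell_theta,n_receivers,n_reps`, plus
#' `interval_index`).
#'
#' @param path File path.
#' @name pairtrack-io
NULL

read_checked <- function(path, cols, what) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, cols, what)
  df
}

#' @rdname pairtrack-io
#' @export
read_receivers <- function(path) {
  out <- read_checked(path, c("receiver_id", "x", "y"), "receivers.csv")
  out$receiver_id <- as.character(out$receiver_id)
  check_receivers(out)
  out
}

#' @rdname pairtrack-io
#' @export
read_detections <- function(path) {
  out <- read_checked(path, c("tag_id", "receiver_id", "t", "rss"),
                      "detections.csv")
  out$tag_id <- as.character(out$tag_id)
  out$receiver_id <- as.character(out$receiver_id)
  if (any(!is.finite(out$rss)) || any(out$t < 0))
    stop("detections must have finite rss and t >= 0", call. = FALSE)
  out
}

#' @rdname pairtrack-io
#' @export
read_calibration <- function(path) {
  read_checked(path, c("distance_m", "rss"), "calibration.csv")
}

#' @rdname pairtrack-io
#' @export
read_truth <- function(path) {
  out <- read_checked(path, c("tag_id", "t", "x", "y"), "truth.csv")
  out$tag_id <- as.character(out$tag_id)
  out
}

#' @rdname pairtrack-io
#' @export
read_localizations <- function(path) {
  out <- read_checked(path, c("tag_id", "interval_index", "t_mid", "x", "y",
                              "ell_a", "ell_b", "ell_theta", "n_receivers",
                              "n_reps"), "localizations.csv")
  out$tag_id <- as.character(out$tag_id)
  out
}

#' @rdname pairtrack-io
#' @param x Data frame to write.
#' @export
write_localizations <- function(x, path) {
  check_columns(x, c("tag_id", "interval_index", "t_mid", "x", "y", "ell_a",
                     "ell_b", "ell_theta", "n_receivers", "n_reps"),
                "localizations")
  write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' Write a fitted calibration model as JSON
#'
#' @param model A [calibration_model()].
#' @param path Output path.
#' @export
write_calibration_json <- function(model, path) {
  stopifnot(inherits(model, "calibration_model"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE,
                       digits = 10)
  invisible(path)
}

#' Read a calibration model from JSON
#'
#' @param path JSON file written by [write_calibration_json()].
#' @return A [calibration_model()].
#' @export
read_calibration_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  calibration_model(x$b0, x$b1, x$resid_sd, x$d_max)
}
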