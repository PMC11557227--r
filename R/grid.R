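#' Build a regular receiver grid
#'
#' Lays out radio receivers over a rectangular study area, either on a square
#' lattice or on a triangular (hexagonal-packing) lattice in which alternate
#' rows are offset by half the spacing and the row pitch is
#' `spacing * sqrt(3) / 2`. The triangular layout matches typical automated
#' telemetry deployments (receivers every 150 m covering ~1.5 km^2).
#'
#' @param extent_x,extent_y Extent of the study area in metres.
#' @param spacing Distance between neighbouring receivers in a row, metres.
#' @param layout `"triangular"` (default) or `"square"`.
#' @return A data frame with columns `receiver_id`, `x`, `y` (metres, local
#'   planar coordinates).
#' @examples
#' grid <- make_grid(300, 300, 150, layout = "square")
#' nrow(grid)  # 9
#' @export
make_grid <- function(extent_x, extent_y, spacing,
                      layout = c("triangular", "square")) {
  check_number(extent_x, "extent_x", positive = TRUE)
  check_number(extent_y, "extent_y", positive = TRUE)
  check_number(spacing, "spacing", positive = TRUE)
  layout <- match.arg(layout)

  if (layout == "square") {
    xs <- seq(0, extent_x, by = spacing)
    ys <- seq(0, extent_y, by = spacing)
    pts <- expand.grid(x = xs, y = ys)
  } else {
    pitch <- spacing * sqrt(3) / 2
    ys <- seq(0, extent_y, by = pitch)
    rows <- lapply(seq_along(ys), function(i) {
      offset <- if (i %% 2 == 0) spacing / 2 else 0
      xs <- seq(offset, extent_x, by = spacing)
      if (!length(xs)) return(NULL)
      data.frame(x = xs, y = ys[i])
    })
    pts <- do.call(rbind, rows)
  }
  data.frame(
    receiver_id = sprintf("R%03d", seq_len(nrow(pts))),
    x = pts$x, y = pts$y,
    stringsAsFactors = FALSE
  )
}

check_receivers <- function(receivers) {
  check_columns(receivers, c("receiver_id", "x", "y"), "receivers")
  if (!nrow(receivers)) stop("receiver table is empty", call. = FALSE)
  if (anyDuplicated(receivers$receiver_id))
    stop("receiver_id values must be unique", call. = FALSE)
  if (!all(is.finite(receivers$x)) || !all(is.finite(receivers$y)))
    stop("receiver coordinates must be finite", call. = FALSE)
  invisible(receivers)
}
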