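#' Construct a utilization distribution
#'
#' A utilization distribution (UD) is a probability mass function on a
#' regular spatial grid: `mass[i, j]` is the probability in the cell whose
#' centre is `(origin_x + (i-1)*cell, origin_y + (j-1)*cell)`. Mass is
#' normalised to sum to one.
#'
#' @param mass Non-negative numeric matrix (x index in rows).
#' @param origin_x,origin_y Centre of the `[1, 1]` cell, metres.
#' @param cell Cell side length, metres (> 0).
#' @return An object of class `ud`.
#' @export
ud <- function(mass, origin_x, origin_y, cell) {
  mass <- as.matrix(mass)
  if (!is.numeric(mass) || any(!is.finite(mass)) || any(mass < 0))
    stop("`mass` must be a finite non-negative matrix", call. = FALSE)
  check_number(origin_x, "origin_x")
  check_number(origin_y, "origin_y")
  check_number(cell, "cell", positive = TRUE)
  total <- sum(mass)
  if (total <= 0) stop("`mass` must have positive total", call. = FALSE)
  structure(list(mass = mass / total, origin_x = origin_x,
                 origin_y = origin_y, cell = cell),
            class = "ud")
}

#' @export
print.ud <- function(x, ...) {
  cat(sprintf(
    "Utilization distribution: %d x %d cells of %.1f m, origin (%.1f, %.1f)\n",
    nrow(x$mass), ncol(x$mass), x$cell, x$origin_x, x$origin_y))
  invisible(x)
}

#' Estimate a utilization distribution from a track
#'
#' Gaussian kernel density of the fix positions on a regular grid padded
#' three bandwidths beyond the fix bounding box. The automatic bandwidth is
#' Silverman's rule per axis, inflated in quadrature by the mean 1-sigma
#' scale of the fixes' error ellipses (`(ell_a + ell_b) / 4`), so that
#' localization uncertainty widens the UD rather than being ignored.
#'
#' @param track Localization data frame with at least 10 fixes; `ell_a`,
#'   `ell_b` are used for the uncertainty inflation when present.
#' @param cell Grid cell size in metres.
#' @param bandwidth Kernel SD in metres, or `"auto"` (default).
#' @return A [ud()] object.
#' @export
estimate_ud <- function(track, cell = 25, bandwidth = "auto") {
  check_columns(track, c("x", "y"), "track")
  check_number(cell, "cell", positive = TRUE)
  if (nrow(track) < 10L)
    stop("need at least 10 fixes to estimate a utilization distribution",
         call. = FALSE)

  if (identical(bandwidth, "auto")) {
    if (sd(track$x) < 1e-9 && sd(track$y) < 1e-9) {
      warning("degenerate fix spread; falling back to cell-size bandwidth")
      hx <- hy <- cell
    } else {
      hx <- bw.nrd0(track$x)
      hy <- bw.nrd0(track$y)
      if (!is.finite(hx) || hx <= 0) hx <- cell
      if (!is.finite(hy) || hy <= 0) hy <- cell
    }
    ell_scale <- if (all(c("ell_a", "ell_b") %in% names(track)))
      mean((track$ell_a + track$ell_b) / 4, na.rm = TRUE) else 0
    if (!is.finite(ell_scale)) ell_scale <- 0
    hx <- sqrt(hx^2 + ell_scale^2)
    hy <- sqrt(hy^2 + ell_scale^2)
  } else {
    check_number(bandwidth, "bandwidth", positive = TRUE)
    hx <- hy <- bandwidth
  }

  gx <- seq(min(track$x) - 3 * hx, max(track$x) + 3 * hx, by = cell)
  gy <- seq(min(track$y) - 3 * hy, max(track$y) + 3 * hy, by = cell)
  # separable kernel: mass = Kx %*% t(Ky), Kx[i, f] = phi((gx_i - x_f)/hx)
  Kx <- outer(gx, track$x, function(g, x) stats::dnorm(g - x, sd = hx))
  Ky <- outer(gy, track$y, function(g, y) stats::dnorm(g - y, sd = hy))
  ud(Kx %*% t(Ky), origin_x = gx[1L], origin_y = gy[1L], cell = cell)
}

#' Home-range area from a utilization distribution
#'
#' Area of the smallest set of grid cells whose cumulative mass reaches
#' `level` (cells ranked by mass): the `level`-contour home range.
#'
#' @param x A [ud()] object.
#' @param level Mass level in (0, 1]; default 0.95.
#' @return Area in km^2.
#' @export
home_range_area <- function(x, level = 0.95) {
  stopifnot(inherits(x, "ud"))
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level > 1)
    stop("`level` must be in (0, 1]", call. = FALSE)
  m <- sort(as.numeric(x$mass), decreasing = TRUE)
  n_cells <- which(cumsum(m) >= level - 1e-12)[1L]
  n_cells * x$cell^2 / 1e6
}

#' Resample a utilization distribution onto another grid
#'
#' Mass-preserving aggregation: each source cell's mass is assigned to the
#' target cell containing its centre. The target grid must cover the
#' source support; total mass is preserved exactly.
#'
#' @param x A [ud()] object.
#' @param origin_x,origin_y,cell Target grid geometry (cell centres as in
#'   [ud()]).
#' @param nx,ny Target grid dimensions.
#' @return A [ud()] on the target grid.
#' @export
resample_ud <- function(x, origin_x, origin_y, cell, nx, ny) {
  stopifnot(inherits(x, "ud"))
  check_number(cell, "cell", positive = TRUE)
  src_x <- x$origin_x + (seq_len(nrow(x$mass)) - 1L) * x$cell
  src_y <- x$origin_y + (seq_len(ncol(x$mass)) - 1L) * x$cell
  # half-cell ties broken upward so commensurate grids map without aliasing
  ix <- as.integer(floor((src_x - origin_x) / cell + 0.5 + 1e-9)) + 1L
  iy <- as.integer(floor((src_y - origin_y) / cell + 0.5 + 1e-9)) + 1L
  if (any(ix < 1L) || any(ix > nx) || any(iy < 1L) || any(iy > ny))
    stop("target grid does not cover the source support", call. = FALSE)
  mass <- matrix(0, nx, ny)
  for (j in seq_along(src_y)) {
    sums <- rowsum(x$mass[, j], ix, reorder = TRUE)
    mass[as.integer(rownames(sums)), iy[j]] <-
      mass[as.integer(rownames(sums)), iy[j]] + as.numeric(sums)
  }
  ud(mass, origin_x, origin_y, cell)
}

# Smallest grid (coarser of the two cells) covering both UDs.
common_grid <- function(a, b) {
  cell <- max(a$cell, b$cell)
  lo_x <- min(a$origin_x, b$origin_x)
  lo_y <- min(a$origin_y, b$origin_y)
  hi_x <- max(a$origin_x + (nrow(a$mass) - 1L) * a$cell,
              b$origin_x + (nrow(b$mass) - 1L) * b$cell)
  hi_y <- max(a$origin_y + (ncol(a$mass) - 1L) * a$cell,
              b$origin_y + (ncol(b$mass) - 1L) * b$cell)
  # origin aligned with the lower-left UD's cell centres, so commensurate
  # grids aggregate exactly rather than through rounding ties
  list(origin_x = lo_x, origin_y = lo_y, cell = cell,
       nx = as.integer(ceiling((hi_x - lo_x) / cell)) + 2L,
       ny = as.integer(ceiling((hi_y - lo_y) / cell)) + 2L)
}

#' Bhattacharyya coefficient between two utilization distributions
#'
#' `BC = sum(sqrt(p * q))` over grid cells: 1 for identical distributions,
#' 0 for disjoint supports. UDs on different grids are first aggregated
#' (mass-preserving) onto a common grid at the coarser cell size.
#'
#' @param a,b [ud()] objects.
#' @return The coefficient, in `[0, 1]`.
#' @export
bhattacharyya <- function(a, b) {
  stopifnot(inherits(a, "ud"), inherits(b, "ud"))
  same_grid <- isTRUE(all.equal(a$cell, b$cell)) &&
    isTRUE(all.equal(a$origin_x, b$origin_x)) &&
    isTRUE(all.equal(a$origin_y, b$origin_y)) &&
    all(dim(a$mass) == dim(b$mass))
  if (!same_grid) {
    g <- common_grid(a, b)
    a <- resample_ud(a, g$origin_x, g$origin_y, g$cell, g$nx, g$ny)
    b <- resample_ud(b, g$origin_x, g$origin_y, g$cell, g$nx, g$ny)
  }
  min(1, sum(sqrt(a$mass * b$mass)))
}

#' Write a utilization distribution as an ASCII raster
#'
#' Plain-text ESRI ASCII grid (`ncols`/`nrows`/`xllcorner`/`yllcorner`/
#' `cellsize`/`NODATA_value` header followed by rows north to south).
#'
#' @param x A [ud()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ud_asc <- function(x, path) {
  stopifnot(inherits(x, "ud"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", nrow(x$mass)),
    sprintf("nrows %d", ncol(x$mass)),
    sprintf("xllcorner %.6f", x$origin_x - x$cell / 2),
    sprintf("yllcorner %.6f", x$origin_y - x$cell / 2),
    sprintf("cellsize %.6f", x$cell),
    "NODATA_value -9999"
  ), con)
  for (j in rev(seq_len(ncol(x$mass))))
    writeLines(paste(format(x$mass[, j], scientific = TRUE, digits = 8),
                     collapse = " "), con)
  invisible(path)
}

#' Home-range contour as GeoJSON
#'
#' Extracts the contour of the `level` home range (the mass-ranked density
#' threshold) and writes it as a GeoJSON MultiLineString in the local
#' planar coordinate system.
#'
#' @param x A [ud()] object.
#' @param level Home-range mass level (default 0.95).
#' @param path Optional output file; when `NULL` the GeoJSON string is
#'   returned.
#' @return `path` invisibly, or the GeoJSON string.
#' @export
ud_contour_geojson <- function(x, level = 0.95, path = NULL) {
  stopifnot(inherits(x, "ud"))
  m <- sort(as.numeric(x$mass), decreasing = TRUE)
  cutoff <- m[which(cumsum(m) >= level - 1e-12)[1L]]
  gx <- x$origin_x + (seq_len(nrow(x$mass)) - 1L) * x$cell
  gy <- x$origin_y + (seq_len(ncol(x$mass)) - 1L) * x$cell
  lines <- grDevices::contourLines(gx, gy, x$mass, levels = cutoff)
  coords <- lapply(lines, function(l) Map(c, l$x, l$y))
  gj <- list(
    type = "Feature",
    properties = list(level = level),
    geometry = list(type = "MultiLineString", coordinates = coords)
  )
  txt <- jsonlite::toJSON(gj, auto_unbox = TRUE, digits = 8)
  if (is.null(path)) return(as.character(txt))
  writeLines(as.character(txt), path)
  invisible(path)
}
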