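# Pooled cell-coordinate density maps in the standardised larva frame.

#' Pool larva-frame cell coordinates for one group and day
#'
#' Concatenates the larva-frame (x, y) centroids of gated objects over all
#' records matching the group and day.  Pooling is meaningful because every
#' record's coordinates were mapped into the common standardised larva
#' frame during measurement.
#'
#' @param records list of [larvaRecord()]s.
#' @param group group label to match.
#' @param dpi day post-injection to match.
#' @param gate a [volumeGate()].
#' @return n x 2 matrix of (x, y) um; zero rows when nothing matches.
#' @export
poolCoordinates <- function(records, group, dpi, gate = volumeGate()) {
  pts <- lapply(records, function(r) {
    if (r$group != group || r$dpi != dpi) return(NULL)
    g <- gateObjects(r$objects, gate)
    if (!nrow(g)) return(NULL)
    cbind(g$larva_x_um, g$larva_y_um)
  })
  pts <- do.call(rbind, pts)
  if (is.null(pts)) pts <- matrix(numeric(0), 0L, 2L)
  colnames(pts) <- c("x", "y")
  pts
}

#' Render a min-max normalised Gaussian density map
#'
#' Evaluates an isotropic Gaussian kernel density (kernel standard
#' deviation = `bandwidth`) on a regular grid over `extent`, then
#' normalises the map to `[0, 1]` by its own minimum and maximum — so every
#' map with at least one point has maximum exactly 1 and the map visualises
#' distribution only, not total burden.  With no points the map is all
#' zero.
#'
#' @param points n x 2 matrix of (x, y) um.
#' @param extent list with `x = c(lo, hi)`, `y = c(lo, hi)` um (non-zero
#'   spans).
#' @param gridShape `(ny, nx)` grid nodes, each `>= 2`.
#' @param bandwidth Gaussian kernel sd in um, `> 0` (default 25).
#' @return list with class `"DensityMap"`: `grid` (`[y, x]` matrix in
#'   `[0, 1]`), `xCoords`, `yCoords` (node positions, um), `extent`,
#'   `bandwidth`, `nPoints`.
#' @export
renderDensity <- function(points, extent, gridShape = c(128L, 512L),
                          bandwidth = 25) {
  stopifnot(bandwidth > 0, length(gridShape) == 2L, all(gridShape >= 2L))
  if (diff(extent$x) == 0 || diff(extent$y) == 0)
    stop("extent has zero area")
  ny <- gridShape[1L]; nx <- gridShape[2L]
  gx <- seq(extent$x[1L], extent$x[2L], length.out = nx)
  gy <- seq(extent$y[1L], extent$y[2L], length.out = ny)
  pts <- matrix(as.numeric(points), ncol = 2L)
  if (nrow(pts) == 0L) {
    grid <- matrix(0, ny, nx)
  } else {
    # separable kernel: density = Wy %*% t(Wx)
    wy <- exp(-outer(gy, pts[, 2L], "-")^2 / (2 * bandwidth^2))
    wx <- exp(-outer(gx, pts[, 1L], "-")^2 / (2 * bandwidth^2))
    grid <- wy %*% t(wx)
    rng <- range(grid)
    grid <- if (rng[2] > rng[1]) (grid - rng[1]) / (rng[2] - rng[1])
            else matrix(1, ny, nx)  # flat but non-empty: saturate
  }
  structure(list(grid = grid, xCoords = gx, yCoords = gy, extent = extent,
                 bandwidth = bandwidth, nPoints = nrow(pts)),
            class = "DensityMap")
}

# blue -> cyan -> green -> yellow -> red ramp on [0, 1]
.jetRgb <- function(v) {
  r <- pmin(pmax(1.5 - abs(4 * v - 3), 0), 1)
  g <- pmin(pmax(1.5 - abs(4 * v - 2), 0), 1)
  b <- pmin(pmax(1.5 - abs(4 * v - 1), 0), 1)
  array(c(r, g, b), c(dim(v), 3L))
}

#' Write a density map as a coloured PNG
#'
#' Blue marks the lowest and red the highest cell density.
#'
#' @param map a `"DensityMap"` from [renderDensity()].
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
writeDensityPng <- function(map, path) {
  stopifnot(inherits(map, "DensityMap"))
  png::writePNG(.jetRgb(map$grid), path)
  invisible(path)
}

#' Write the raw density grid as CSV
#'
#' Long format with columns `x_um`, `y_um`, `density`.
#'
#' @inheritParams writeDensityPng
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeDensityCsv <- function(map, path) {
  stopifnot(inherits(map, "DensityMap"))
  df <- data.frame(x_um = rep(map$xCoords, each = length(map$yCoords)),
                   y_um = rep(map$yCoords, times = length(map$xCoords)),
                   density = as.numeric(map$grid))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
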