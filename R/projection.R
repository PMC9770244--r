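# Flattening of 3D stacks to 2D: max projection (fluorescence) and
# sharpness-selecting focus stacking (brightfield).

# symmetric (half-sample) reflection of 1-based indices onto 1..n
.reflectIdx <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  p <- 2L * n
  j <- ((i - 1L) %% p + p) %% p  # 0-based, period 2n
  ifelse(j < n, j + 1L, p - j)
}

# sum over (2r+1)^2 windows with reflected borders, via padded cumsum
.boxSum2d <- function(m, r) {
  ny <- nrow(m); nx <- ncol(m)
  pad <- m[.reflectIdx(seq(1L - r, ny + r), ny),
           .reflectIdx(seq(1L - r, nx + r), nx), drop = FALSE]
  cs <- apply(apply(pad, 2L, cumsum), 1L, cumsum)  # transposed cumsum2d
  cs <- t(cs)
  cs <- rbind(0, cbind(0, cs))  # prepend zero row/col for window sums
  w <- 2L * r + 1L
  iy <- seq_len(ny); ix <- seq_len(nx)
  cs[iy + w, ix + w, drop = FALSE] - cs[iy, ix + w, drop = FALSE] -
    cs[iy + w, ix, drop = FALSE] + cs[iy, ix, drop = FALSE]
}

#' Maximum-intensity projection
#'
#' Flattens a fluorescence grid to 2D: each output pixel is the maximum over
#' z of the voxel column at that (y, x).  Pixel size is inherited from the
#' grid's (dx, dy).
#'
#' @param grid a [VoxelGrid-class].
#' @return A [FlatImage-class].
#' @examples
#' g <- VoxelGrid(array(seq_len(8), c(2, 2, 2)))
#' pixelData(maxProject(g))
#' @export
maxProject <- function(grid) {
  stopifnot(is(grid, "VoxelGrid"))
  d <- voxelData(grid)
  FlatImage(apply(d, c(1L, 2L), max), calibration(grid)[c("dx", "dy")])
}

#' Sharpness-based focus stacking
#'
#' Composes an all-in-focus 2D image from a brightfield stack: for every
#' (y, x) the z-slice maximising a local sharpness score is selected, and the
#' output takes that slice's value (selection, never interpolation).  The
#' sharpness score is the local intensity variance in a
#' `(2 * radius + 1)^2` window with reflected borders; ties are broken by
#' the lowest z.
#'
#' @param grid a [VoxelGrid-class] (typically the brightfield channel).
#' @param sharpnessRadius window half-width in pixels (default 5).
#' @return list with `image` (a [FlatImage-class]) and `heightMap`
#'   (integer matrix of selected 1-based z-slice indices).
#' @export
focusStack <- function(grid, sharpnessRadius = 5L) {
  stopifnot(is(grid, "VoxelGrid"), sharpnessRadius >= 1L)
  d <- voxelData(grid)
  nz <- dim(d)[3]
  r <- as.integer(sharpnessRadius)
  n <- (2 * r + 1)^2
  best <- matrix(-Inf, nrow(d), ncol(d))
  height <- matrix(1L, nrow(d), ncol(d))
  for (z in seq_len(nz)) {
    s <- .boxSum2d(d[, , z], r)
    s2 <- .boxSum2d(d[, , z]^2, r)
    v <- s2 / n - (s / n)^2
    upd <- v > best  # strict: ties keep the lowest z
    best[upd] <- v[upd]
    height[upd] <- z
  }
  img <- matrix(0, nrow(d), ncol(d))
  for (z in seq_len(nz)) {
    sel <- height == z
    img[sel] <- d[, , z][sel]
  }
  list(image = FlatImage(img, calibration(grid)[c("dx", "dy")]),
       heightMap = height)
}
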