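# Larva pose standardisation from a user-supplied 2D outline polygon:
# Feret-angle orientation, distance-map interior anchor (yolk-sac proxy),
# rigid realignment transform, and montages.

#' @importFrom mgcv in.out
NULL

# ---- polygon helpers --------------------------------------------------------

.asPolygon <- function(p) {
  p <- as.matrix(p)
  storage.mode(p) <- "double"
  if (ncol(p) != 2L) stop("polygon must be an n x 2 matrix of (x, y)")
  # drop an explicitly repeated closing vertex; closure is implicit
  if (nrow(p) > 1L && all(p[1L, ] == p[nrow(p), ])) p <- p[-nrow(p), , drop = FALSE]
  p
}

.polygonArea <- function(p) {  # signed shoelace area
  x <- p[, 1L]; y <- p[, 2L]
  j <- c(seq_len(nrow(p))[-1L], 1L)
  sum(x * y[j] - x[j] * y) / 2
}

.polygonCentroid <- function(p) {  # area centroid
  x <- p[, 1L]; y <- p[, 2L]
  j <- c(seq_len(nrow(p))[-1L], 1L)
  cr <- x * y[j] - x[j] * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(colMeans(p))
  c(sum((x + x[j]) * cr), sum((y + y[j]) * cr)) / (6 * a)
}

.segmentsIntersect <- function(p1, p2, q1, q2) {
  # proper intersection test via orientation signs
  o <- function(a, b, c)
    sign((b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1]))
  o1 <- o(p1, p2, q1); o2 <- o(p1, p2, q2)
  o3 <- o(q1, q2, p1); o4 <- o(q1, q2, p2)
  o1 != o2 && o3 != o4 && o1 != 0 && o2 != 0 && o3 != 0 && o4 != 0
}

#' Validate an outline polygon
#'
#' Checks the requirements on outlines and exclusion masks: at least three
#' vertices, simple (no two non-adjacent edges intersect), positive area.
#'
#' @param polygon n x 2 matrix of (x, y) vertices, first vertex not
#'   repeated (closure implicit).
#' @return the polygon (invisibly) if valid; otherwise an error.
#' @export
validateOutline <- function(polygon) {
  p <- .asPolygon(polygon)
  n <- nrow(p)
  if (n < 3L) stop("outline needs >= 3 vertices")
  if (abs(.polygonArea(p)) < 1e-12) stop("outline is degenerate (zero area)")
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i + 1L || (i == 1L && j == n)) next
      if (.segmentsIntersect(p[i, ], p[.wrap(i + 1L, n), ],
                             p[j, ], p[.wrap(j + 1L, n), ]))
        stop("outline is self-intersecting")
    }
  }
  invisible(p)
}

.wrap <- function(i, n) ((i - 1L) %% n) + 1L

# TRUE for points strictly inside the (closed) polygon
.pointsInPolygon <- function(points, polygon) {
  p <- .asPolygon(polygon)
  mgcv::in.out(rbind(p, p[1L, ]), matrix(as.numeric(points), ncol = 2L))
}

#' Read an outline/exclusion-mask JSON file
#'
#' Schema: `{"larva_id": str, "outline": [[x, y], ...],
#' "exclusion_masks": [[[x, y], ...], ...]}` with coordinates in
#' flattened-image pixel units.  Replaces the interactive boundary-drawing
#' step with a file for headless operation.
#'
#' @param path JSON file.
#' @return list with `larvaId`, `outline` (n x 2 matrix), `exclusions`
#'   (list of matrices, possibly empty).
#' @export
readOutlineJson <- function(path) {
  if (!file.exists(path)) stop("cannot read outline file: ", path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(j$outline)) stop("outline file has no 'outline' field")
  outline <- validateOutline(as.matrix(j$outline))
  excl <- list()
  if (!is.null(j$exclusion_masks)) {
    raw <- j$exclusion_masks
    if (is.array(raw) && length(dim(raw)) == 3L)
      raw <- lapply(seq_len(dim(raw)[1]), function(i) raw[i, , ])
    excl <- lapply(raw, function(m) validateOutline(as.matrix(m)))
  }
  list(larvaId = if (is.null(j$larva_id)) "larva" else j$larva_id,
       outline = outline, exclusions = excl)
}

#' Write an outline/exclusion-mask JSON file
#' @param larvaId larva identifier.
#' @param outline n x 2 matrix in pixel coordinates.
#' @param exclusions list of polygons (possibly empty).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeOutlineJson <- function(larvaId, outline, exclusions, path) {
  jsonlite::write_json(
    list(larva_id = larvaId,
         outline = apply(unname(as.matrix(outline)), 1L, identity,
                         simplify = FALSE),
         exclusion_masks = lapply(exclusions, function(m)
           apply(unname(as.matrix(m)), 1L, identity, simplify = FALSE))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# ---- orientation and anchor -------------------------------------------------

#' Feret angle of an outline polygon
#'
#' Orientation of the longest caliper diameter: the vertex pair at maximum
#' Euclidean distance, measured from the +x axis, in degrees in `[0, 180)`.
#' Computed exactly on the polygon vertices.  When several pairs tie for the
#' maximum distance, the smallest angle is returned.
#'
#' @param outline n x 2 matrix of (x, y) vertices.
#' @return angle in degrees in `[0, 180)`.
#' @export
feretAngle <- function(outline) {
  p <- validateOutline(outline)
  n <- nrow(p)
  best <- -1
  ang <- numeric(0)
  for (i in seq_len(n - 1L)) {
    dx <- p[(i + 1L):n, 1L] - p[i, 1L]
    dy <- p[(i + 1L):n, 2L] - p[i, 2L]
    d2 <- dx^2 + dy^2
    m <- max(d2)
    a <- (atan2(dy, dx) * 180 / pi) %% 180
    if (m > best * (1 + 1e-9)) {
      best <- m
      ang <- a[d2 >= m * (1 - 1e-9)]
    } else if (m >= best * (1 - 1e-9)) {
      ang <- c(ang, a[d2 >= best * (1 - 1e-9)])
    }
  }
  if (best <= 0) stop("degenerate polygon: all vertices coincide")
  min(ang %% 180)
}

# rasterize polygon(s) to a logical mask [y, x] over pixel centres
# (ix - 0.5, iy - 0.5); `origin` in the same pixel units.
.rasterMask <- function(polygon, ny, nx, origin = c(0, 0)) {
  cx <- origin[1] + (seq_len(nx) - 0.5)
  cy <- origin[2] + (seq_len(ny) - 0.5)
  pts <- cbind(rep(cx, each = ny), rep(cy, times = nx))
  matrix(.pointsInPolygon(pts, polygon), ny, nx)
}

#' Interior anchor of an outline (yolk-sac proxy)
#'
#' The interior point furthest from the outline boundary: the polygon is
#' rasterized (at `min(pixelSize)` resolution in micrometre space when
#' pixels are anisotropic), the Euclidean distance transform of the mask is
#' taken, and the pixel with maximal distance is returned; ties are broken
#' by the lowest (y, then x).
#'
#' @param outline n x 2 matrix of (x, y) vertices in pixel coordinates.
#' @param pixelSize `(dx, dy)` um of the flattened image.
#' @return `(x, y)` anchor in the outline's pixel coordinates, plus an
#'   attribute `distance_um` with the boundary clearance.
#' @export
interiorAnchor <- function(outline, pixelSize = c(1, 1)) {
  p <- validateOutline(outline)
  pum <- cbind(p[, 1L] * pixelSize[1], p[, 2L] * pixelSize[2])
  s <- min(pixelSize)
  lo <- floor(apply(pum, 2L, min) / s) - 2
  hi <- ceiling(apply(pum, 2L, max) / s) + 2
  nx <- as.integer(hi[1] - lo[1]); ny <- as.integer(hi[2] - lo[2])
  mask <- .rasterMask(pum / s, ny, nx, origin = lo)
  if (!any(mask)) stop("outline rasterizes to an empty mask")
  dm <- EBImage::distmap(mask * 1)
  mx <- max(dm)
  hits <- which(dm == mx, arr.ind = TRUE)   # (row = y, col = x)
  hits <- hits[order(hits[, 1L], hits[, 2L]), , drop = FALSE]
  iy <- hits[1L, 1L]; ix <- hits[1L, 2L]
  aum <- c((lo[1] + ix - 0.5) * s, (lo[2] + iy - 0.5) * s)
  out <- c(x = aum[1] / pixelSize[1], y = aum[2] / pixelSize[2])
  attr(out, "distance_um") <- mx * s
  out
}

# ---- the rigid realignment frame -------------------------------------------

.rotmat <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L, 2L)
}

#' Build the standardised larva frame from an outline
#'
#' Computes the rigid (plus optional reflection) transform taking
#' flattened-image micrometre coordinates to the standardised larva frame:
#' rotation by minus the Feret angle puts the long axis horizontal and the
#' outline area centroid at the origin; the residual 180-degree / mirror
#' ambiguity is resolved by placing the interior anchor (the yolk sac,
#' which is anterior) in the left half-plane (`x < 0`, anterior-left) and
#' orienting the outline's larger vertical lobe downwards (sign of the
#' vertical third moment of the vertices — a pose-stable criterion; the
#' anchor's half-plane is used as tie-break only for vertically symmetric
#' outlines).
#'
#' @param outline n x 2 matrix of (x, y) vertices in pixel coordinates.
#' @param pixelSize `(dx, dy)` um.
#' @return A [LarvaFrame-class].
#' @export
buildFrame <- function(outline, pixelSize = c(1, 1)) {
  p <- validateOutline(outline)
  pum <- cbind(p[, 1L] * pixelSize[1], p[, 2L] * pixelSize[2])
  theta <- feretAngle(pum)
  ctr <- .polygonCentroid(pum)
  anch <- interiorAnchor(p, pixelSize)
  aum <- c(anch[1] * pixelSize[1], anch[2] * pixelSize[2])
  a1 <- .rotmat(-theta) %*% (aum - ctr)
  # two of the four horizontal-axis-preserving variants put the anchor left;
  # they differ by a vertical mirror
  if (a1[1] > 0) { cand <- list(c(-theta + 180, FALSE), c(-theta, TRUE)) }
  else           { cand <- list(c(-theta, FALSE), c(-theta + 180, TRUE)) }
  # resolve the vertical mirror by the outline's exact vertical asymmetry
  # (third moment of vertex y in the candidate frame; larger lobe down);
  # anchor half-plane decides only when the outline is vertically symmetric
  applyCand <- function(cd, pts) {
    q <- t(.rotmat(cd[1]) %*% (t(pts) - ctr))
    if (cd[2]) q[, 1L] <- -q[, 1L]
    q
  }
  q1 <- applyCand(cand[[1L]], pum)
  skew <- sum((q1[, 2L] - mean(q1[, 2L]))^3)
  pick <- if (abs(skew) > 1e-9) skew >= 0
          else applyCand(cand[[1L]], rbind(aum))[2L] >= 0
  chosen <- if (pick) cand[[1L]] else cand[[2L]]
  rot <- chosen[1L]; flip <- as.logical(chosen[2L])
  rot <- ((rot + 180) %% 360) - 180
  new("LarvaFrame", rotation = rot, centroid = as.numeric(ctr), flip = flip,
      anchor = as.numeric(aum), outline = p,
      pixelSize = as.numeric(pixelSize))
}

#' Map image coordinates to the standardised larva frame
#'
#' @param frame a [LarvaFrame-class].
#' @param points `(x, y)` in um (length-2 vector or n x 2 matrix) in the
#'   flattened-image frame.
#' @return points in larva-frame um, same shape as the input.
#' @export
toLarvaCoords <- function(frame, points) {
  stopifnot(is(frame, "LarvaFrame"))
  vec <- is.null(dim(points))
  pts <- matrix(as.numeric(points), ncol = 2L)
  q <- t(.rotmat(frame@rotation) %*%
           (t(pts) - frame@centroid))
  if (frame@flip) q[, 1L] <- -q[, 1L]
  if (vec) as.numeric(q) else q
}

#' Inverse of [toLarvaCoords()]
#' @inheritParams toLarvaCoords
#' @param points `(x, y)` in larva-frame um.
#' @return points in flattened-image um.
#' @export
fromLarvaCoords <- function(frame, points) {
  stopifnot(is(frame, "LarvaFrame"))
  vec <- is.null(dim(points))
  q <- matrix(as.numeric(points), ncol = 2L)
  if (frame@flip) q[, 1L] <- -q[, 1L]
  p <- t(.rotmat(-frame@rotation) %*% t(q) + frame@centroid)
  if (vec) as.numeric(p) else p
}

#' Realigned montage of daily images of one larva
#'
#' Resamples each flattened image into its larva frame (nearest-neighbour,
#' montages being visual QC rather than quantitative output) and stacks the
#' realigned images as rows, in input order, on a common canvas sized to the
#' largest realigned outline extent.
#'
#' @param images list of [FlatImage-class], length >= 1.
#' @param frames matching list of [LarvaFrame-class].
#' @param padding extra margin around the pooled outline extent, um.
#' @return A [FlatImage-class] with `length(images)` rows.
#' @export
makeMontage <- function(images, frames, padding = 10) {
  if (length(images) < 1L) stop("montage needs at least one image")
  if (length(images) != length(frames))
    stop("images and frames must have the same length")
  boxes <- lapply(frames, function(fr) {
    o <- fr@outline
    oum <- cbind(o[, 1L] * fr@pixelSize[1], o[, 2L] * fr@pixelSize[2])
    q <- toLarvaCoords(fr, oum)
    c(min(q[, 1L]), max(q[, 1L]), min(q[, 2L]), max(q[, 2L]))
  })
  bb <- do.call(rbind, boxes)
  xlo <- min(bb[, 1L]) - padding; xhi <- max(bb[, 2L]) + padding
  ylo <- min(bb[, 3L]) - padding; yhi <- max(bb[, 4L]) + padding
  ps <- pixelSize(images[[1L]])
  nx <- max(2L, ceiling((xhi - xlo) / ps[1]))
  nyRow <- max(2L, ceiling((yhi - ylo) / ps[2]))
  rows <- vector("list", length(images))
  gx <- xlo + (seq_len(nx) - 0.5) * ps[1]
  gy <- ylo + (seq_len(nyRow) - 0.5) * ps[2]
  grid <- cbind(rep(gx, each = nyRow), rep(gy, times = nx))
  for (i in seq_along(images)) {
    img <- pixelData(images[[i]])
    fr <- frames[[i]]
    src <- fromLarvaCoords(fr, grid)
    ix <- as.integer(round(src[, 1L] / fr@pixelSize[1] + 0.5))
    iy <- as.integer(round(src[, 2L] / fr@pixelSize[2] + 0.5))
    ok <- ix >= 1L & ix <= ncol(img) & iy >= 1L & iy <= nrow(img)
    vals <- numeric(nrow(grid))
    vals[ok] <- img[cbind(iy[ok], ix[ok])]
    rows[[i]] <- matrix(vals, nyRow, nx)
  }
  FlatImage(do.call(rbind, rows), ps)
}
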