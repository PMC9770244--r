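#' @import methods
#' @importFrom Rcpp evalCpp
#' @useDynLib larvaSeg, .registration = TRUE
NULL

#' Calibrated 3D voxel grid
#'
#' The elementary container for one channel of a confocal acquisition: a 3D
#' scalar intensity array with isotropic-or-not voxel calibration in
#' micrometres.  Data are stored as an R array with `dim = c(ny, nx, nz)` so
#' that `voxelData(g)[, , k]` is the k-th z-slice as an ordinary `[y, x]`
#' matrix; indices are 1-based as usual in R.  Voxel centres sit at
#' `(i - 0.5) * d` micrometres along each axis.
#'
#' @slot data 3D numeric array, `dim = c(ny, nx, nz)`; finite, non-negative.
#' @slot calibration named numeric of voxel edge lengths, `c(dx, dy, dz)`,
#'   in micrometres; all strictly positive.
#' @export
setClass("VoxelGrid",
  representation(data = "array", calibration = "numeric"))

setValidity("VoxelGrid", function(object) {
  d <- object@data
  if (length(dim(d)) != 3L) return("data must be a 3D array (y, x, z)")
  if (any(dim(d) < 1L)) return("all dimensions must be >= 1")
  if (!is.numeric(d)) return("data must be numeric")
  if (any(!is.finite(d))) return("intensities must be finite")
  if (any(d < 0)) return("intensities must be >= 0")
  cal <- object@calibration
  if (length(cal) != 3L || any(!is.finite(cal)) || any(cal <= 0))
    return("calibration must be three positive values (dx, dy, dz) in um")
  TRUE
})

#' Construct a VoxelGrid
#'
#' @param data 3D numeric array with `dim = c(ny, nx, nz)`.
#' @param calibration numeric length-3 `(dx, dy, dz)` voxel size in um.
#' @return A [VoxelGrid-class] object.
#' @examples
#' g <- VoxelGrid(array(0, c(4, 4, 2)), calibration = c(0.6, 0.6, 2))
#' calibration(g)
#' @export
VoxelGrid <- function(data, calibration = c(1, 1, 1)) {
  calibration <- as.numeric(calibration)
  names(calibration) <- c("dx", "dy", "dz")
  new("VoxelGrid", data = data, calibration = calibration)
}

#' Multi-channel confocal stack
#'
#' A named set of [VoxelGrid-class] channels sharing dimensions and
#' calibration, with role tags (exactly one `"brightfield"` channel, at
#' least one `"fluorescence"`) and acquisition metadata identifying the
#' larva, the treatment group and the imaging day (days post-injection).
#'
#' @slot channels named list of [VoxelGrid-class] objects.
#' @slot roles named character; for every channel one of `"brightfield"`,
#'   `"fluorescence"`.
#' @slot larvaId character scalar.
#' @slot group character scalar.
#' @slot dpi integer scalar, days post-injection, `>= 0`.
#' @export
setClass("ConfocalStack",
  representation(channels = "list", roles = "character",
                 larvaId = "character", group = "character",
                 dpi = "integer"))

setValidity("ConfocalStack", function(object) {
  ch <- object@channels
  if (length(ch) < 1L) return("at least one channel required")
  if (is.null(names(ch)) || any(!nzchar(names(ch))) || anyDuplicated(names(ch)))
    return("channels must be uniquely named")
  if (!all(vapply(ch, is, logical(1), "VoxelGrid")))
    return("all channels must be VoxelGrid objects")
  dims <- vapply(ch, function(g) dim(g@data), integer(3))
  if (length(ch) > 1L && any(dims[, -1, drop = FALSE] != dims[, 1]))
    return("all channels must share dimensions")
  cals <- vapply(ch, function(g) g@calibration, numeric(3))
  if (length(ch) > 1L && any(cals[, -1, drop = FALSE] != cals[, 1]))
    return("all channels must share calibration")
  rl <- object@roles
  if (!setequal(names(rl), names(ch)) || length(rl) != length(ch))
    return("roles must name every channel exactly once")
  if (!all(rl %in% c("brightfield", "fluorescence")))
    return("roles must be 'brightfield' or 'fluorescence'")
  if (sum(rl == "brightfield") != 1L)
    return("exactly one brightfield channel required")
  if (sum(rl == "fluorescence") < 1L)
    return("at least one fluorescence channel required")
  if (length(object@dpi) != 1L || is.na(object@dpi) || object@dpi < 0L)
    return("dpi must be a single integer >= 0")
  TRUE
})

#' Construct a ConfocalStack
#'
#' @param channels named list of [VoxelGrid-class] objects (identical
#'   dimensions and calibration).
#' @param roles named character vector mapping each channel name to
#'   `"brightfield"` or `"fluorescence"`.
#' @param larvaId,group identifiers carried into all downstream tables.
#' @param dpi days post-injection (integer `>= 0`).
#' @return A [ConfocalStack-class] object.
#' @export
ConfocalStack <- function(channels, roles, larvaId = "larva", group = "none",
                          dpi = 0L) {
  new("ConfocalStack", channels = channels, roles = roles[names(channels)],
      larvaId = as.character(larvaId), group = as.character(group),
      dpi = as.integer(dpi))
}

#' Flattened 2D image
#'
#' The 2D representation of a stack (max projection or focus stack), stored
#' as a `[y, x]` matrix with pixel size in micrometres.
#'
#' @slot data numeric matrix `[y, x]`.
#' @slot pixelSize numeric `(dx, dy)` in um, both positive.
#' @export
setClass("FlatImage",
  representation(data = "matrix", pixelSize = "numeric"))

setValidity("FlatImage", function(object) {
  if (!is.numeric(object@data)) return("data must be numeric")
  ps <- object@pixelSize
  if (length(ps) != 2L || any(!is.finite(ps)) || any(ps <= 0))
    return("pixelSize must be two positive values (dx, dy) in um")
  TRUE
})

#' Construct a FlatImage
#' @param data numeric `[y, x]` matrix.
#' @param pixelSize numeric `(dx, dy)` in um.
#' @return A [FlatImage-class] object.
#' @export
FlatImage <- function(data, pixelSize = c(1, 1)) {
  pixelSize <- as.numeric(pixelSize)
  names(pixelSize) <- c("dx", "dy")
  new("FlatImage", data = data, pixelSize = pixelSize)
}

#' Watershed label map
#'
#' Output of the seeded watershed: an integer array of the same shape as the
#' segmented grid, 0 = background, labels contiguous `1..N`.
#'
#' @slot labels 3D integer array `[y, x, z]`.
#' @slot calibration inherited voxel calibration `(dx, dy, dz)` um.
#' @export
setClass("LabelMap",
  representation(labels = "array", calibration = "numeric"))

setValidity("LabelMap", function(object) {
  l <- object@labels
  if (length(dim(l)) != 3L) return("labels must be a 3D array")
  if (any(l < 0)) return("labels must be non-negative")
  u <- sort(unique(as.integer(l[l > 0])))
  if (length(u) && !identical(u, seq_len(max(u))))
    return("labels must be contiguous 1..N")
  cal <- object@calibration
  if (length(cal) != 3L || any(cal <= 0))
    return("calibration must be three positive values")
  TRUE
})

LabelMap <- function(labels, calibration) {
  calibration <- as.numeric(calibration)
  names(calibration) <- c("dx", "dy", "dz")
  new("LabelMap", labels = labels, calibration = calibration)
}

#' Standardised larva coordinate frame
#'
#' A rigid (plus optional reflection) transform from flattened-image
#' micrometre coordinates to a standardised larva frame: the long axis
#' (Feret orientation) horizontal, the outline centroid at the origin, the
#' interior anchor (yolk-sac proxy) in the left half-plane (anterior-left),
#' and the outline's larger vertical lobe downwards.  Mapping:
#' `q = F %*% R(rotation) %*% (p - centroid)` with `F = diag(-1, 1)` when
#' `flip` is set.
#'
#' @slot rotation rotation in degrees.
#' @slot centroid outline area centroid `(x, y)` in um (image frame).
#' @slot flip logical; `TRUE` when a reflection is part of the transform.
#' @slot anchor interior anchor `(x, y)` in um (image frame).
#' @slot outline source outline polygon, n x 2 matrix in pixel coordinates.
#' @slot pixelSize `(dx, dy)` um of the flattened image.
#' @export
setClass("LarvaFrame",
  representation(rotation = "numeric", centroid = "numeric",
                 flip = "logical", anchor = "numeric",
                 outline = "matrix", pixelSize = "numeric"))

setValidity("LarvaFrame", function(object) {
  if (length(object@rotation) != 1L || !is.finite(object@rotation))
    return("rotation must be a single finite angle (degrees)")
  if (length(object@centroid) != 2L) return("centroid must be (x, y)")
  if (length(object@flip) != 1L) return("flip must be a single logical")
  TRUE
})

#' Per-frame heart video intensity trace
#'
#' @slot values numeric vector of per-frame mean ROI intensities (>= 2).
#' @slot frameRate frames per second, positive.
#' @slot roi integer `(x, y, w, h)` rectangle in pixels (1-based origin).
#' @export
setClass("HeartRateTrace",
  representation(values = "numeric", frameRate = "numeric", roi = "numeric"))

setValidity("HeartRateTrace", function(object) {
  if (length(object@values) < 2L) return("trace needs >= 2 frames")
  if (any(!is.finite(object@values))) return("trace values must be finite")
  if (length(object@frameRate) != 1L || object@frameRate <= 0)
    return("frameRate must be a single positive value")
  TRUE
})

HeartRateTrace <- function(values, frameRate, roi = c(NA, NA, NA, NA)) {
  new("HeartRateTrace", values = as.numeric(values),
      frameRate = as.numeric(frameRate), roi = as.numeric(roi))
}

#' Heart-rate estimate
#'
#' @slot bpm beats per minute, `60 * peakHz`.
#' @slot peakHz fundamental frequency (spectral argmax within the band), Hz.
#' @slot resolutionHz spectral bin width `frameRate / paddedLength`, Hz.
#' @slot spectrum data.frame with columns `freq_hz`, `power` up to Nyquist.
#' @slot band the `(lo, hi)` Hz search band used.
#' @export
setClass("HeartRateResult",
  representation(bpm = "numeric", peakHz = "numeric",
                 resolutionHz = "numeric", spectrum = "data.frame",
                 band = "numeric"))

#' @describeIn VoxelGrid-class the raw 3D array `[y, x, z]`.
#' @param x object.
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))
setMethod("voxelData", "VoxelGrid", function(x) x@data)

#' @describeIn VoxelGrid-class voxel (or pixel) sizes in um.
#' @export
setGeneric("calibration", function(x) standardGeneric("calibration"))
setMethod("calibration", "VoxelGrid", function(x) x@calibration)
setMethod("calibration", "LabelMap", function(x) x@calibration)
setMethod("calibration", "ConfocalStack",
          function(x) x@channels[[1]]@calibration)

#' @describeIn ConfocalStack-class named list of channel VoxelGrids.
#' @export
setGeneric("channels", function(x) standardGeneric("channels"))
setMethod("channels", "ConfocalStack", function(x) x@channels)

#' @describeIn ConfocalStack-class named character vector of channel roles.
#' @export
setGeneric("channelRoles", function(x) standardGeneric("channelRoles"))
setMethod("channelRoles", "ConfocalStack", function(x) x@roles)

#' @describeIn ConfocalStack-class the single brightfield channel.
#' @export
setGeneric("brightfield", function(x) standardGeneric("brightfield"))
setMethod("brightfield", "ConfocalStack",
          function(x) x@channels[[names(x@roles)[x@roles == "brightfield"][1]]])

#' @describeIn ConfocalStack-class fluorescence channels (named list).
#' @export
setGeneric("fluorescence", function(x) standardGeneric("fluorescence"))
setMethod("fluorescence", "ConfocalStack",
          function(x) x@channels[names(x@roles)[x@roles == "fluorescence"]])

#' @describeIn FlatImage-class the `[y, x]` pixel matrix.
#' @export
setGeneric("pixelData", function(x) standardGeneric("pixelData"))
setMethod("pixelData", "FlatImage", function(x) x@data)

#' @describeIn FlatImage-class pixel size `(dx, dy)` um.
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))
setMethod("pixelSize", "FlatImage", function(x) x@pixelSize)
setMethod("pixelSize", "LarvaFrame", function(x) x@pixelSize)

#' @describeIn LabelMap-class the integer label array `[y, x, z]`.
#' @export
setGeneric("labelData", function(x) standardGeneric("labelData"))
setMethod("labelData", "LabelMap", function(x) x@labels)

#' @describeIn LabelMap-class number of labelled objects.
#' @export
setGeneric("nObjects", function(x) standardGeneric("nObjects"))
setMethod("nObjects", "LabelMap", function(x) max(0L, as.integer(x@labels)))

#' @describeIn HeartRateResult-class estimated beats per minute.
#' @export
setGeneric("bpm", function(x) standardGeneric("bpm"))
setMethod("bpm", "HeartRateResult", function(x) x@bpm)

setMethod("show", "VoxelGrid", function(object) {
  d <- dim(object@data)
  cal <- object@calibration
  cat(sprintf("VoxelGrid: %d x %d x %d (y, x, z), voxel %.3g x %.3g x %.3g um\n",
              d[1], d[2], d[3], cal[1], cal[2], cal[3]))
})

setMethod("show", "ConfocalStack", function(object) {
  d <- dim(object@channels[[1]]@data)
  cat(sprintf("ConfocalStack '%s' (group %s, %d dpi): %d channel(s), %d x %d x %d\n",
              object@larvaId, object@group, object@dpi,
              length(object@channels), d[1], d[2], d[3]))
  for (nm in names(object@channels))
    cat(sprintf("  %s [%s]\n", nm, object@roles[[nm]]))
})

setMethod("show", "FlatImage", function(object) {
  d <- dim(object@data)
  cat(sprintf("FlatImage: %d x %d (y, x), pixel %.3g x %.3g um\n",
              d[1], d[2], object@pixelSize[1], object@pixelSize[2]))
})

setMethod("show", "LabelMap", function(object) {
  d <- dim(object@labels)
  cat(sprintf("LabelMap: %d x %d x %d, %d object(s)\n",
              d[1], d[2], d[3], nObjects(object)))
})

setMethod("show", "LarvaFrame", function(object) {
  cat(sprintf(
    "LarvaFrame: rotation %.2f deg, flip %s, centroid (%.1f, %.1f) um\n",
    object@rotation, object@flip, object@centroid[1], object@centroid[2]))
})

setMethod("show", "HeartRateResult", function(object) {
  cat(sprintf("HeartRateResult: %.1f BPM (peak %.3f Hz, resolution %.4f Hz)\n",
              object@bpm, object@peakHz, object@resolutionHz))
})
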