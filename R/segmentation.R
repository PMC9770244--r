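# 3D seeded-watershed segmentation: masking, median pre-filter,
# local-maximum seeding above the background cutoff, descending-intensity
# priority flood, and per-object measurement.

#' Segmentation configuration
#'
#' Bundles the tunables of the 3D pipeline.  The background level plays the
#' role of the user-determined background fluorescence: strictly greater
#' intensities are foreground, ties are background.  Median radii are in
#' voxels, defaults `(3, 3, 2)` for (x, y, z).
#'
#' @param backgroundLevel background fluorescence cutoff B, intensity
#'   units, `>= 0`.
#' @param medianRadii `(rx, ry, rz)` voxel radii of the 3D median
#'   pre-filter (also the local-maximum search box), `>= 0`.
#' @param connectivity 6 or 26, used for flooding and plateau linking.
#' @param minSeedSeparation minimum Euclidean seed distance in voxels;
#'   0 disables the filter.
#' @return list with class `"SegmentationConfig"`.
#' @export
segmentationConfig <- function(backgroundLevel, medianRadii = c(3L, 3L, 2L),
                               connectivity = 26L, minSeedSeparation = 0) {
  stopifnot(length(backgroundLevel) == 1L, backgroundLevel >= 0,
            length(medianRadii) == 3L, all(medianRadii >= 0),
            connectivity %in% c(6L, 26L), minSeedSeparation >= 0)
  structure(list(backgroundLevel = as.numeric(backgroundLevel),
                 medianRadii = as.integer(medianRadii),
                 connectivity = as.integer(connectivity),
                 minSeedSeparation = as.numeric(minSeedSeparation)),
            class = "SegmentationConfig")
}

#' Zero voxels outside the larva or inside exclusion masks
#'
#' Polygons live in the flattened (x, y) frame and are extruded through z:
#' a voxel is kept only when its (x, y) pixel centre falls inside the larva
#' outline and outside every exclusion polygon (high-autofluorescence areas
#' such as iridophores, gut and yolk sac).
#'
#' @param grid a [VoxelGrid-class].
#' @param larvaOutline n x 2 polygon in pixel coordinates, or `NULL` to
#'   keep the whole field.
#' @param exclusions list of polygons (possibly empty).
#' @return A masked [VoxelGrid-class].
#' @export
applyMasks <- function(grid, larvaOutline = NULL, exclusions = list()) {
  stopifnot(is(grid, "VoxelGrid"))
  d <- voxelData(grid)
  ny <- dim(d)[1]; nx <- dim(d)[2]
  keep <- matrix(TRUE, ny, nx)
  if (!is.null(larvaOutline))
    keep <- .rasterMask(validateOutline(larvaOutline), ny, nx)
  for (ex in exclusions)
    keep <- keep & !.rasterMask(validateOutline(ex), ny, nx)
  out <- d * as.numeric(keep)  # recycles over z
  dim(out) <- dim(d)
  VoxelGrid(out, calibration(grid))
}

#' 3D median filter
#'
#' Replaces each voxel by the median of its
#' `(2rx+1) x (2ry+1) x (2rz+1)` box neighbourhood, with reflected
#' (half-sample symmetric) padding at the borders.
#'
#' @param grid a [VoxelGrid-class].
#' @param radii `(rx, ry, rz)` in voxels, default `(3, 3, 2)`.
#' @return A filtered [VoxelGrid-class].
#' @export
median3d <- function(grid, radii = c(3L, 3L, 2L)) {
  stopifnot(is(grid, "VoxelGrid"), length(radii) == 3L, all(radii >= 0))
  d <- voxelData(grid)
  out <- .median3d_cpp(as.numeric(d), dim(d), as.integer(radii))
  dim(out) <- dim(d)
  VoxelGrid(out, calibration(grid))
}

#' Detect watershed seeds as supra-background local maxima
#'
#' A voxel is a seed iff its (filtered) intensity is strictly above the
#' background cutoff and not exceeded anywhere in its
#' `(2rx+1) x (2ry+1) x (2rz+1)` box; a connected plateau of equal maxima
#' yields exactly one seed, at the plateau voxel with the lowest (z, y, x).
#'
#' @param filtered a [VoxelGrid-class], normally the median-filtered grid.
#' @param B background cutoff, `>= 0`.
#' @param radii `(rx, ry, rz)` search-box radii in voxels.
#' @param connectivity plateau-linking connectivity, 6 or 26.
#' @return integer matrix with columns `y`, `x`, `z` (1-based voxel
#'   indices), ordered by (z, y, x); zero rows when nothing exceeds B.
#' @export
detectSeeds <- function(filtered, B, radii = c(3L, 3L, 2L),
                        connectivity = 26L) {
  stopifnot(is(filtered, "VoxelGrid"), B >= 0,
            connectivity %in% c(6L, 26L))
  d <- voxelData(filtered)
  s <- .detect_seeds_cpp(as.numeric(d), dim(d), as.numeric(B),
                         as.integer(radii), as.integer(connectivity))
  colnames(s) <- c("y", "x", "z")
  s
}

# Greedy minimum-separation filter: seeds accepted in order of descending
# intensity (ties by (z, y, x)); a seed closer than `sep` voxels to an
# accepted one is dropped.
.filterSeedSeparation <- function(seeds, grid, sep) {
  if (sep <= 0 || nrow(seeds) < 2L) return(seeds)
  d <- voxelData(grid)
  v <- d[seeds]
  ord <- order(-v, seeds[, "z"], seeds[, "y"], seeds[, "x"])
  acc <- integer(0)
  for (i in ord) {
    if (!length(acc) ||
        min(sqrt(colSums((t(seeds[acc, , drop = FALSE]) - seeds[i, ])^2))) >= sep)
      acc <- c(acc, i)
  }
  seeds[sort(acc), , drop = FALSE]
}

#' Seeded 3D watershed by descending-intensity flooding
#'
#' Floods the grid from the seed voxels with a global priority queue ordered
#' by descending intensity (FIFO among equal intensities; neighbours are
#' examined in ascending (z, y, x) offset order), assigning each reached
#' supra-background voxel to the basin that reaches it first.  Voxels with
#' intensity `<= B` stay background; every flooded voxel receives a label
#' (no watershed-line voxels), so touching objects are split along their
#' intensity saddle whenever a border between them is detectable.
#'
#' @param filtered a [VoxelGrid-class] — the grid to flood (in the full
#'   pipeline, the masked original fluorescence stack).
#' @param seeds integer matrix with columns `y`, `x`, `z` as from
#'   [detectSeeds()]; labels 1..N follow the row order.  All seeds must
#'   have intensity above B.
#' @param B background cutoff.
#' @param connectivity 6 or 26 (default 26).
#' @return A [LabelMap-class].
#' @export
watershed3d <- function(filtered, seeds, B, connectivity = 26L) {
  stopifnot(is(filtered, "VoxelGrid"), connectivity %in% c(6L, 26L))
  d <- voxelData(filtered)
  seeds <- matrix(as.integer(as.matrix(seeds)[, c("y", "x", "z"), drop = FALSE]),
                  ncol = 3L, dimnames = list(NULL, c("y", "x", "z")))
  lab <- .watershed_cpp(as.numeric(d), dim(d), seeds, as.numeric(B),
                        as.integer(connectivity))
  dim(lab) <- dim(d)
  LabelMap(lab, calibration(filtered))
}

#' Equivalent spherical diameter
#'
#' Diameter of the sphere with the same volume as the object,
#' `d = (6 V / pi)^(1/3)`.  At the default viable-cell volume gate of
#' 1000 um^3 this evaluates to about 12.4 um.
#'
#' @param volume volume(s) in um^3, `>= 0`.
#' @return diameter(s) in um.
#' @examples
#' esd(1000)   # ~12.407
#' esd(pi / 6) # exactly 1
#' @export
esd <- function(volume) {
  if (any(volume < 0)) stop("volume must be >= 0")
  (6 * volume / pi)^(1 / 3)
}

#' Measure per-object features from a label map
#'
#' One row per label: voxel count, volume (`count * dx * dy * dz`),
#' equivalent spherical diameter, intensity-unweighted centroid of voxel
#' centres in micrometres (image frame), the same (x, y) mapped to the
#' larva frame when one is given, a 0-based half-open voxel bounding box,
#' and per-channel mean / integrated / max intensity.
#'
#' @param labelmap a [LabelMap-class].
#' @param stack the source [ConfocalStack-class] (same dims/calibration).
#' @param frame optional [LarvaFrame-class] for larva-frame centroids
#'   (`NA` columns when absent).
#' @return data.frame, one row per object, with the schema documented in
#'   [writeObjectsCsv()].
#' @export
measureObjects <- function(labelmap, stack, frame = NULL) {
  stopifnot(is(labelmap, "LabelMap"), is(stack, "ConfocalStack"))
  lab <- labelData(labelmap)
  dims <- dim(lab)
  if (!identical(dims, dim(voxelData(channels(stack)[[1]]))))
    stop("label map and stack dimensions differ")
  cal <- calibration(labelmap)
  if (any(abs(cal - calibration(stack)) > 1e-12))
    stop("label map and stack calibration differ")
  n <- nObjects(labelmap)
  empty <- data.frame(larva_id = character(0), group = character(0),
                      dpi = integer(0), label = integer(0),
                      voxel_count = integer(0), volume_um3 = numeric(0),
                      esd_um = numeric(0), centroid_x_um = numeric(0),
                      centroid_y_um = numeric(0), centroid_z_um = numeric(0),
                      larva_x_um = numeric(0), larva_y_um = numeric(0),
                      bbox_x0 = integer(0), bbox_x1 = integer(0),
                      bbox_y0 = integer(0), bbox_y1 = integer(0),
                      bbox_z0 = integer(0), bbox_z1 = integer(0))
  if (n == 0L) return(empty)
  idx <- which(lab > 0)
  l <- as.integer(lab[idx])
  iy <- ((idx - 1L) %% dims[1]) + 1L
  ix <- (((idx - 1L) %/% dims[1]) %% dims[2]) + 1L
  iz <- ((idx - 1L) %/% (dims[1] * dims[2])) + 1L
  cnt <- tabulate(l, n)
  sx <- rowsum(ix - 0.5, l)[, 1L] / cnt * cal["dx"]
  sy <- rowsum(iy - 0.5, l)[, 1L] / cnt * cal["dy"]
  sz <- rowsum(iz - 0.5, l)[, 1L] / cnt * cal["dz"]
  agg <- function(v, f) as.numeric(tapply(v, factor(l, levels = seq_len(n)), f))
  vol <- cnt * prod(cal)
  df <- data.frame(
    larva_id = stack@larvaId, group = stack@group, dpi = stack@dpi,
    label = seq_len(n), voxel_count = cnt, volume_um3 = vol,
    esd_um = esd(vol),
    centroid_x_um = as.numeric(sx), centroid_y_um = as.numeric(sy),
    centroid_z_um = as.numeric(sz),
    larva_x_um = NA_real_, larva_y_um = NA_real_,
    bbox_x0 = agg(ix, min) - 1L, bbox_x1 = agg(ix, max),
    bbox_y0 = agg(iy, min) - 1L, bbox_y1 = agg(iy, max),
    bbox_z0 = agg(iz, min) - 1L, bbox_z1 = agg(iz, max))
  if (!is.null(frame)) {
    q <- toLarvaCoords(frame, cbind(df$centroid_x_um, df$centroid_y_um))
    df$larva_x_um <- q[, 1L]
    df$larva_y_um <- q[, 2L]
  }
  for (nm in names(channels(stack))) {
    v <- voxelData(channels(stack)[[nm]])[idx]
    df[[paste0("sum_", nm)]] <- as.numeric(rowsum(v, l)[, 1L])
    df[[paste0("mean_", nm)]] <- df[[paste0("sum_", nm)]] / cnt
    df[[paste0("max_", nm)]] <- agg(v, max)
  }
  df
}

#' Extract a single-object cut-out from a stack
#'
#' Sub-stack of all channels over the object's bounding box dilated by
#' `margin` voxels and clipped to the stack bounds, for downstream
#' single-cell analysis in the style of imaging flow cytometry.
#'
#' @param stack a [ConfocalStack-class].
#' @param object one row of the [measureObjects()] table.
#' @param margin dilation in voxels, `>= 0`.
#' @return A [ConfocalStack-class]; the source label is recorded in the
#'   larva id as `"<larva>#<label>"`.
#' @export
extractCutout <- function(stack, object, margin = 0L) {
  stopifnot(is(stack, "ConfocalStack"), nrow(object) == 1L, margin >= 0L)
  d <- dim(voxelData(channels(stack)[[1]]))
  x0 <- max(1L, object$bbox_x0 + 1L - margin); x1 <- min(d[2], object$bbox_x1 + margin)
  y0 <- max(1L, object$bbox_y0 + 1L - margin); y1 <- min(d[1], object$bbox_y1 + margin)
  z0 <- max(1L, object$bbox_z0 + 1L - margin); z1 <- min(d[3], object$bbox_z1 + margin)
  grids <- lapply(channels(stack), function(g)
    VoxelGrid(voxelData(g)[y0:y1, x0:x1, z0:z1, drop = FALSE],
              calibration(g)))
  ConfocalStack(grids, channelRoles(stack),
                larvaId = paste0(stack@larvaId, "#", object$label),
                group = stack@group, dpi = stack@dpi)
}

#' Run the full per-larva segmentation
#'
#' Composition of the pipeline on one fluorescence channel: mask the grid
#' with the larva outline and exclusion polygons, median-filter the masked
#' grid to find starting points (seeds = supra-background local maxima of
#' the filtered grid), then flood the *masked original* fluorescence grid
#' from those seeds, and measure the resulting objects.  Seeds whose raw
#' masked intensity does not exceed the cutoff are dropped before flooding.
#'
#' @param stack a [ConfocalStack-class].
#' @param outline larva outline polygon (pixel coordinates) or `NULL`.
#' @param exclusions list of exclusion polygons.
#' @param config a [segmentationConfig()].
#' @param channel fluorescence channel name; default = first fluorescence
#'   channel.
#' @param frame optional [LarvaFrame-class]; computed from `outline` when
#'   omitted and an outline is given.
#' @return list with `labels` (a [LabelMap-class]), `objects`
#'   (data.frame), `seeds` and `frame`.
#' @export
segmentLarva <- function(stack, outline = NULL, exclusions = list(),
                         config, channel = NULL, frame = NULL) {
  stopifnot(is(stack, "ConfocalStack"),
            inherits(config, "SegmentationConfig"))
  if (is.null(channel))
    channel <- names(channelRoles(stack))[channelRoles(stack) == "fluorescence"][1]
  grid <- channels(stack)[[channel]]
  if (is.null(grid)) stop("no such channel: ", channel)
  if (is.null(frame) && !is.null(outline))
    frame <- buildFrame(outline, calibration(stack)[c("dx", "dy")])
  masked <- applyMasks(grid, outline, exclusions)
  filtered <- median3d(masked, config$medianRadii)
  seeds <- detectSeeds(filtered, config$backgroundLevel, config$medianRadii,
                       config$connectivity)
  seeds <- .filterSeedSeparation(seeds, filtered, config$minSeedSeparation)
  # flood the masked raw grid: keep only seeds supra-B there as well
  if (nrow(seeds))
    seeds <- seeds[voxelData(masked)[seeds] > config$backgroundLevel, ,
                   drop = FALSE]
  labels <- watershed3d(masked, seeds, config$backgroundLevel,
                        config$connectivity)
  objects <- measureObjects(labels, stack, frame)
  list(labels = labels, objects = objects, seeds = seeds, frame = frame)
}

#' Write a label map as 16-bit multi-page TIFF
#' @param labelmap a [LabelMap-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeLabelTiff <- function(labelmap, path) {
  lab <- labelData(labelmap)
  if (max(lab) > 65535L) stop("more than 65535 labels")
  pages <- lapply(seq_len(dim(lab)[3]), function(z) lab[, , z] / 65535)
  writeTIFF(pages, path, bits.per.sample = 16L, compression = "none",
            reduce = FALSE)
  invisible(path)
}
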