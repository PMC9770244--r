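#' @importFrom tiff readTIFF writeTIFF
#' @importFrom jsonlite fromJSON toJSON write_json read_json
#' @importFrom xml2 read_xml xml_ns_strip xml_find_first xml_find_all xml_attr
NULL

# Core column schema of the per-object table (intensity columns are appended
# per channel as mean_<ch>, sum_<ch>, max_<ch>).
.objectsCoreCols <- c("larva_id", "group", "dpi", "label", "voxel_count",
                      "volume_um3", "esd_um",
                      "centroid_x_um", "centroid_y_um", "centroid_z_um",
                      "larva_x_um", "larva_y_um",
                      "bbox_x0", "bbox_x1", "bbox_y0", "bbox_y1",
                      "bbox_z0", "bbox_z1")

#' Write a multi-channel stack as multi-page TIFF plus metadata sidecar
#'
#' Pages are written z-major with channels interleaved fastest (page
#' `k = (z - 1) * nC + c`).  Voxel values are stored as 16-bit samples
#' scaled by `scale` (recorded in the sidecar); integer data with values in
#' `[0, 65535]` round-trip losslessly.  A JSON sidecar `<path>.meta.json`
#' records calibration, channel names and roles, page order and metadata,
#' because the TIFF writer in use cannot embed an ImageDescription tag.
#'
#' @param stack a [ConfocalStack-class].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @seealso [readStack()]
#' @export
writeStack <- function(stack, path) {
  ch <- channels(stack)
  d <- dim(voxelData(ch[[1]]))
  mx <- max(vapply(ch, function(g) max(g@data), numeric(1)), 0)
  isInt <- all(vapply(ch, function(g) all(g@data == round(g@data)), logical(1)))
  scale <- if (isInt && mx <= 65535) 65535 else max(mx, 1e-12)
  pages <- vector("list", d[3] * length(ch))
  k <- 1L
  for (z in seq_len(d[3])) {
    for (ci in seq_along(ch)) {
      pages[[k]] <- pmin(voxelData(ch[[ci]])[, , z] / scale, 1)
      k <- k + 1L
    }
  }
  writeTIFF(pages, path, bits.per.sample = 16L, compression = "none",
            reduce = FALSE)
  meta <- list(
    format = "larvaSeg-stack-v1",
    larva_id = stack@larvaId, group = stack@group, dpi = stack@dpi,
    channels = names(ch), roles = as.list(channelRoles(stack)),
    size = list(ny = d[1], nx = d[2], nz = d[3]),
    calibration = as.list(calibration(stack)),
    page_order = "channel_fastest", scale = scale, integer_data = isInt)
  write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Parse calibration and channel layout from an OME-XML description
#'
#' Extracts `PhysicalSizeX/Y/Z`, `SizeC`, `SizeZ`, `DimensionOrder` and
#' channel names from the OME-XML string some microscope exports embed in
#' the TIFF ImageDescription tag.  Physical sizes are assumed to be in
#' micrometres (the OME default).
#'
#' @param xmlString the ImageDescription contents.
#' @return list with elements `calibration` (`c(dx, dy, dz)`, `NA` when
#'   absent), `sizeC`, `sizeZ`, `channelNames`, `dimensionOrder`.
#' @export
parseOmeDescription <- function(xmlString) {
  doc <- xml2::read_xml(xmlString)
  xml2::xml_ns_strip(doc)
  px <- xml2::xml_find_first(doc, ".//Pixels")
  if (inherits(px, "xml_missing")) stop("no <Pixels> element in OME-XML")
  num <- function(a) {
    v <- xml2::xml_attr(px, a)
    if (is.na(v)) NA_real_ else as.numeric(v)
  }
  int <- function(a) {
    v <- xml2::xml_attr(px, a)
    if (is.na(v)) NA_integer_ else as.integer(v)
  }
  chn <- xml2::xml_attr(xml2::xml_find_all(px, ".//Channel"), "Name")
  list(calibration = c(dx = num("PhysicalSizeX"), dy = num("PhysicalSizeY"),
                       dz = num("PhysicalSizeZ")),
       sizeC = int("SizeC"), sizeZ = int("SizeZ"),
       channelNames = if (length(chn)) chn else NULL,
       dimensionOrder = xml2::xml_attr(px, "DimensionOrder"))
}

#' Read a calibrated multi-channel stack
#'
#' Reads a multi-page TIFF written by [writeStack()] (JSON sidecar) or a
#' third-party TIFF/OME-TIFF.  Calibration precedence is explicit
#' `calibration` argument, then sidecar / OME-XML metadata; a stack without
#' any calibration source is an error, never a silent default, because all
#' downstream volumes are in cubic micrometres.
#'
#' @param path TIFF file.
#' @param channelRoles named character mapping channel names to
#'   `"brightfield"` / `"fluorescence"`.  The channel count implied must
#'   match the file.
#' @param calibration optional `(dx, dy, dz)` um override.
#' @param channelNames channel names, for plain TIFFs without metadata
#'   (order = page interleaving order).
#' @param pageOrder `"channel_fastest"` (default; page `(z-1)*nC + c`) or
#'   `"z_fastest"` for plain TIFFs.
#' @param larvaId,group,dpi metadata overrides.
#' @return A [ConfocalStack-class].
#' @export
readStack <- function(path, channelRoles, calibration = NULL,
                      channelNames = NULL,
                      pageOrder = c("channel_fastest", "z_fastest"),
                      larvaId = NULL, group = NULL, dpi = NULL) {
  if (!file.exists(path)) stop("cannot read stack: no such file: ", path)
  pageOrder <- match.arg(pageOrder)
  pages <- readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  nPages <- length(pages)
  scale <- 1
  isInt <- FALSE
  metaPath <- paste0(path, ".meta.json")
  if (file.exists(metaPath)) {
    meta <- read_json(metaPath, simplifyVector = TRUE)
    if (is.null(channelNames)) channelNames <- meta$channels
    if (is.null(calibration))
      calibration <- unlist(meta$calibration)[c("dx", "dy", "dz")]
    if (!is.null(meta$page_order)) pageOrder <- meta$page_order
    if (!is.null(meta$scale)) scale <- meta$scale
    isInt <- isTRUE(meta$integer_data)
    if (is.null(larvaId)) larvaId <- meta$larva_id
    if (is.null(group)) group <- meta$group
    if (is.null(dpi)) dpi <- meta$dpi
  } else {
    desc <- attr(pages[[1]], "description")
    if (!is.null(desc) && grepl("<", desc, fixed = TRUE)) {
      ome <- tryCatch(parseOmeDescription(desc), error = function(e) NULL)
      if (!is.null(ome)) {
        if (is.null(calibration) && all(is.finite(ome$calibration)))
          calibration <- ome$calibration
        if (is.null(channelNames)) channelNames <- ome$channelNames
      }
    }
    scale <- 65535  # 16-bit samples read back as value / 65535
    isInt <- TRUE
  }
  if (is.null(channelNames)) channelNames <- names(channelRoles)
  nC <- length(channelNames)
  if (is.null(nC) || nC < 1L) stop("channel names could not be determined")
  if (length(channelRoles) != nC ||
      !setequal(names(channelRoles), channelNames))
    stop("channel roles do not match the file's channels (",
         nC, " channel(s): ", paste(channelNames, collapse = ", "), ")")
  if (nPages %% nC != 0L)
    stop("page count ", nPages, " is not a multiple of channel count ", nC)
  nz <- nPages %/% nC
  if (is.null(calibration))
    stop("no calibration: none in metadata and no override supplied")
  calibration <- as.numeric(calibration)
  if (length(calibration) != 3L || any(!is.finite(calibration)))
    stop("calibration must be three finite values (dx, dy, dz) in um")
  d1 <- dim(pages[[1]])
  grids <- vector("list", nC)
  for (ci in seq_len(nC)) {
    a <- array(0, c(d1[1], d1[2], nz))
    for (z in seq_len(nz)) {
      k <- if (pageOrder == "channel_fastest") (z - 1L) * nC + ci
           else (ci - 1L) * nz + z
      a[, , z] <- pages[[k]] * scale
    }
    if (isInt) a <- round(a)
    grids[[ci]] <- VoxelGrid(a, calibration)
  }
  names(grids) <- channelNames
  ConfocalStack(grids, channelRoles,
                larvaId = if (is.null(larvaId)) "larva" else larvaId,
                group = if (is.null(group)) "none" else group,
                dpi = if (is.null(dpi)) 0L else dpi)
}

#' Export segmented objects as CSV
#'
#' One row per object with the fixed column schema documented in
#' [measureObjects()]: identifiers (`larva_id`, `group`, `dpi`, `label`),
#' size (`voxel_count`, `volume_um3`, `esd_um`), centroids in micrometres in
#' the image frame (`centroid_x/y/z_um`) and the larva frame
#' (`larva_x/y_um`), 0-based half-open voxel bounding boxes, and per-channel
#' `mean_`/`sum_`/`max_` intensities.  UTF-8, comma-delimited, `.` decimal.
#' An empty object table yields a header-only CSV.
#'
#' @param objects data.frame as returned by [measureObjects()] (possibly
#'   with rows from several larvae).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeObjectsCsv <- function(objects, path) {
  if (is.null(objects) || nrow(objects) == 0L) {
    objects <- as.data.frame(
      setNames(rep(list(numeric(0)), length(.objectsCoreCols)),
               .objectsCoreCols))
  }
  missing <- setdiff(.objectsCoreCols, names(objects))
  if (length(missing))
    stop("objects table lacks required columns: ",
         paste(missing, collapse = ", "))
  utils::write.csv(objects, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read an objects CSV written by [writeObjectsCsv()]
#' @param path CSV file.
#' @return data.frame with the documented schema.
#' @export
readObjectsCsv <- function(path) {
  if (!file.exists(path)) stop("cannot read objects CSV: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  missing <- setdiff(.objectsCoreCols, names(df))
  if (length(missing))
    stop("not an objects CSV (missing: ", paste(missing, collapse = ", "), ")")
  df
}
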