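# Deterministic, seeded generator of test fixtures: larva-shaped stacks
# with planted cells / debris / autofluorescent patches and ground truth,
# plus periodic-intensity heartbeat videos.

# evaluate expr under a fixed seed without disturbing the session RNG
.withSeed <- function(seed, expr) {
  hadSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (hadSeed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (hadSeed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Specification of a synthetic larva stack
#'
#' Defaults define the reference simulation conditions used throughout the
#' test-suite: a 160 x 80 x 32 um field at 1 um isotropic calibration
#' holding 5 well-separated cells (ESD 13-16 um, comfortably above the
#' 1000 um^3 viable-cell gate, whose own ESD is 12.4 um), 3 debris
#' fragments (ESD 7-8 um — below the gate yet large enough to survive the
#' (3, 3, 2) median pre-filter, which erases supra-background blobs
#' narrower than about 6.3 um), no touching pairs and no autofluorescent
#' patches, with cell peak intensity 200, background cutoff 50 and additive
#' Gaussian noise of sd 10 (5% of peak).
#'
#' Objects are isotropic Gaussian blobs; a planted object's ESD is defined
#' through its expected supra-background voxel set (the blob sd is chosen
#' as `(ESD/2) / sqrt(2 log(peak / B))`), so ground truth matches what the
#' segmentation can see.  Touching pairs are placed with centres
#' `1.2 * ESD` apart, which leaves a detectable intensity saddle (about
#' `0.27 * peak`, just above B) between two distinct local maxima.
#'
#' @param dims `(ny, nx, nz)` voxels.
#' @param calibration `(dx, dy, dz)` um.
#' @param nCells,cellEsd number and ESD range (um) of viable-cell blobs.
#' @param nDebris,debrisEsd number and ESD range (um) of debris blobs.
#' @param touchingPairs number of additional touching cell pairs.
#' @param nPatches number of broad autofluorescent patches (each paired
#'   with an exclusion polygon in the ground truth).
#' @param peak cell peak intensity.
#' @param backgroundLevel the background cutoff B the truth is defined
#'   against (and the recommended segmentation setting).
#' @param noiseSd additive Gaussian noise sd, intensity units.
#' @param seed RNG seed; every random draw in the generator derives from
#'   it (the session RNG is left untouched).
#' @return list with class `"SyntheticLarvaSpec"`.
#' @export
syntheticLarvaSpec <- function(dims = c(80L, 160L, 32L),
                               calibration = c(1, 1, 1),
                               nCells = 5L, cellEsd = c(13, 16),
                               nDebris = 3L, debrisEsd = c(7, 8),
                               touchingPairs = 0L, nPatches = 0L,
                               peak = 200, backgroundLevel = 50,
                               noiseSd = 10, seed = 1L) {
  stopifnot(length(dims) == 3L, all(dims >= 8L),
            peak > backgroundLevel, backgroundLevel > 0, noiseSd >= 0,
            cellEsd[1L] > esd(1000),
            debrisEsd[2L] < esd(1000))
  structure(list(dims = as.integer(dims), calibration = as.numeric(calibration),
                 nCells = as.integer(nCells), cellEsd = as.numeric(cellEsd),
                 nDebris = as.integer(nDebris), debrisEsd = as.numeric(debrisEsd),
                 touchingPairs = as.integer(touchingPairs),
                 nPatches = as.integer(nPatches),
                 peak = as.numeric(peak),
                 backgroundLevel = as.numeric(backgroundLevel),
                 noiseSd = as.numeric(noiseSd), seed = as.integer(seed)),
            class = "SyntheticLarvaSpec")
}

# larva-like silhouette in um: a pronounced anterior (yolk) bulge so the
# deepest interior point is unique and pose-stable, a thin tail, and a
# ventral bias so the up/down realignment convention is well defined
.larvaOutlineUm <- function(W, H, nPts = 72L) {
  u <- seq(-1, 1, length.out = nPts %/% 2L)
  a <- 0.46 * W; b <- 0.42 * H
  half <- b * sqrt(pmax(1 - u^2, 0)) *
    (0.4 + 0.6 * exp(-((u + 0.5) / 0.4)^2))
  x <- W / 2 + a * u
  top <- cbind(x, H / 2 - 0.75 * half)
  bot <- cbind(rev(x), H / 2 + rev(1.25 * half))
  poly <- rbind(top, bot)
  poly <- poly[c(TRUE, diff(poly[, 1L]) != 0 | diff(poly[, 2L]) != 0), ,
               drop = FALSE]
  if (all(poly[1L, ] == poly[nrow(poly), ])) poly <- poly[-nrow(poly), , drop = FALSE]
  poly
}

.addBlob <- function(vol, centerUm, sigma, amp, cal) {
  d <- dim(vol)
  rx <- ceiling(3.5 * sigma / cal[1L]); ry <- ceiling(3.5 * sigma / cal[2L])
  rz <- ceiling(3.5 * sigma / cal[3L])
  ix <- max(1L, floor(centerUm[1L] / cal[1L]) - rx):min(d[2L], ceiling(centerUm[1L] / cal[1L]) + rx)
  iy <- max(1L, floor(centerUm[2L] / cal[2L]) - ry):min(d[1L], ceiling(centerUm[2L] / cal[2L]) + ry)
  iz <- max(1L, floor(centerUm[3L] / cal[3L]) - rz):min(d[3L], ceiling(centerUm[3L] / cal[3L]) + rz)
  dx2 <- ((ix - 0.5) * cal[1L] - centerUm[1L])^2
  dy2 <- ((iy - 0.5) * cal[2L] - centerUm[2L])^2
  dz2 <- ((iz - 0.5) * cal[3L] - centerUm[3L])^2
  g <- amp * exp(-(outer(outer(dy2, dx2, "+"), dz2, "+")) / (2 * sigma^2))
  vol[iy, ix, iz] <- vol[iy, ix, iz] + g
  vol
}

#' Generate a synthetic larva stack with ground truth
#'
#' Fluorescence channel = sum of spherical Gaussian blobs (cells and
#' debris) plus broad dim autofluorescent patches plus Gaussian noise,
#' clipped at zero and rounded to integers; brightfield = textured larva
#' silhouette sharpest at the middle slice.  Identical seeds give
#' bit-identical output.
#'
#' @param spec a [syntheticLarvaSpec()].
#' @return list with `stack` (a [ConfocalStack-class]) and `truth`: a
#'   data.frame `objects` (type, centre um, ESD, expected volume), the
#'   larva `outline` and patch `exclusions` (pixel-coordinate polygons),
#'   and the `backgroundLevel` the truth is defined against.
#' @export
genLarvaStack <- function(spec) {
  stopifnot(inherits(spec, "SyntheticLarvaSpec"))
  .withSeed(spec$seed, {
    d <- spec$dims; cal <- spec$calibration
    W <- d[2L] * cal[1L]; H <- d[1L] * cal[2L]; D <- d[3L] * cal[3L]
    outlineUm <- .larvaOutlineUm(W, H)
    A <- spec$peak; B <- spec$backgroundLevel
    sigFor <- function(esdUm) (esdUm / 2) / sqrt(2 * log(A / B))

    placed <- list()  # rows: cx, cy, cz (um), R (supra-B radius um)
    tryPlace <- function(R, sep, zR) {
      for (attempt in seq_len(4000L)) {
        cx <- runif(1, R + 4, W - R - 4)
        cy <- runif(1, R + 4, H - R - 4)
        cz <- runif(1, zR + 2, D - zR - 2)
        ring <- cbind(cx + (R + 3) * cos(seq(0, 2 * pi, length.out = 9L)[-9L]),
                      cy + (R + 3) * sin(seq(0, 2 * pi, length.out = 9L)[-9L]))
        if (!all(.pointsInPolygon(ring, outlineUm))) next
        ok <- TRUE
        for (p in placed)
          if (sqrt(sum((c(cx, cy, cz) - p$c)^2)) < R + p$R + sep) { ok <- FALSE; break }
        if (ok) return(c(cx, cy, cz))
      }
      stop("could not place object within retry budget")
    }

    objects <- list()
    addObject <- function(type, esdUm, center) {
      R <- esdUm / 2
      objects[[length(objects) + 1L]] <<- data.frame(
        type = type, cx_um = center[1L], cy_um = center[2L],
        cz_um = center[3L], esd_um = esdUm,
        volume_um3 = 4 / 3 * pi * R^3)
      placed[[length(placed) + 1L]] <<- list(c = center, R = R)
    }
    for (i in seq_len(spec$nCells)) {
      e <- runif(1, spec$cellEsd[1L], spec$cellEsd[2L])
      addObject("cell", e, tryPlace(e / 2, sep = 8, zR = e / 2))
    }
    for (i in seq_len(spec$touchingPairs)) {
      e <- runif(1, spec$cellEsd[1L], spec$cellEsd[2L])
      c1 <- tryPlace(1.2 * e, sep = 8, zR = e / 2)  # room for the partner
      ang <- runif(1, 0, 2 * pi)
      c2 <- c1 + 1.2 * e * c(cos(ang), sin(ang), 0)
      addObject("cell", e, c1)
      addObject("cell", e, c2)
    }
    for (i in seq_len(spec$nDebris)) {
      e <- runif(1, spec$debrisEsd[1L], spec$debrisEsd[2L])
      addObject("debris", e, tryPlace(e / 2, sep = 8, zR = e / 2))
    }
    exclusions <- list()
    patchAmp <- 1.6 * B
    patchSigma <- 10
    for (i in seq_len(spec$nPatches)) {
      pr <- patchSigma * sqrt(2 * log(patchAmp / B))  # supra-B radius
      ctr <- tryPlace(pr, sep = 12, zR = 2)
      objects[[length(objects) + 1L]] <- data.frame(
        type = "patch", cx_um = ctr[1L], cy_um = ctr[2L], cz_um = ctr[3L],
        esd_um = NA_real_, volume_um3 = NA_real_)
      placed[[length(placed) + 1L]] <- list(c = ctr, R = pr)
      hw <- pr + 4
      exclusions[[length(exclusions) + 1L]] <- cbind(
        c(ctr[1L] - hw, ctr[1L] + hw, ctr[1L] + hw, ctr[1L] - hw) / cal[1L],
        c(ctr[2L] - hw, ctr[2L] - hw, ctr[2L] + hw, ctr[2L] + hw) / cal[2L])
    }
    objects <- do.call(rbind, c(objects, list(make.row.names = FALSE)))

    fluo <- array(0, d)
    for (i in seq_len(nrow(objects))) {
      o <- objects[i, ]
      if (o$type == "patch") {
        fluo <- .addBlob(fluo, c(o$cx_um, o$cy_um, o$cz_um), patchSigma,
                         patchAmp, cal)
      } else {
        fluo <- .addBlob(fluo, c(o$cx_um, o$cy_um, o$cz_um),
                         sigFor(o$esd_um), A, cal)
      }
    }
    if (spec$noiseSd > 0)
      fluo <- fluo + stats::rnorm(length(fluo), 0, spec$noiseSd)
    fluo <- round(pmin(pmax(fluo, 0), 65535))

    inside <- .rasterMask(cbind(outlineUm[, 1L] / cal[1L],
                                outlineUm[, 2L] / cal[2L]), d[1L], d[2L])
    texture <- matrix(stats::rnorm(d[1L] * d[2L], 0, 15), d[1L], d[2L])
    bf <- array(0, d)
    zc <- (d[3L] + 1) / 2
    for (z in seq_len(d[3L])) {
      sharp <- exp(-((z - zc) / (d[3L] / 6))^2)
      bf[, , z] <- 20 + inside * (120 + sharp * texture)
    }
    bf <- round(pmin(pmax(bf, 0), 65535))

    stack <- ConfocalStack(
      list(bf = VoxelGrid(bf, cal), fluor = VoxelGrid(fluo, cal)),
      c(bf = "brightfield", fluor = "fluorescence"),
      larvaId = paste0("synth", spec$seed), group = "synthetic", dpi = 0L)
    truth <- list(objects = objects,
                  outline = cbind(outlineUm[, 1L] / cal[1L],
                                  outlineUm[, 2L] / cal[2L]),
                  exclusions = exclusions,
                  backgroundLevel = B, spec = spec)
    list(stack = stack, truth = truth)
  })
}

#' Generate a synthetic heartbeat video
#'
#' A bright disk whose radius pulsates at `bpm / 60` Hz on a dim
#' background, plus optional per-pixel Gaussian noise.  Deterministic for a
#' given seed.
#'
#' @param bpm true heart rate, beats per minute, in `[30, 300]`.
#' @param fps frame rate, Hz; must exceed `2 * bpm / 60` (Nyquist).
#' @param seconds duration; `round(fps * seconds)` frames are produced.
#' @param noiseSd per-pixel Gaussian noise sd as a fraction of the disk
#'   intensity (0.1 = 10% noise).
#' @param seed RNG seed.
#' @param dims `(ny, nx)` frame size in pixels.
#' @return list of `[y, x]` frame matrices.
#' @export
genHeartVideo <- function(bpm, fps, seconds = 12, noiseSd = 0, seed = 1L,
                          dims = c(64L, 64L)) {
  stopifnot(bpm >= 30, bpm <= 300)
  if (fps <= 2 * bpm / 60) stop("frame rate violates the Nyquist criterion")
  .withSeed(seed, {
    nF <- round(fps * seconds)
    ny <- dims[1L]; nx <- dims[2L]
    cx <- nx / 2 + 0.5; cy <- ny / 2 + 0.5
    r0 <- min(ny, nx) / 5
    d2 <- outer((seq_len(ny) - cy)^2, (seq_len(nx) - cx)^2, "+")
    peak <- 200
    lapply(seq_len(nF) - 1L, function(k) {
      r <- r0 * (1 + 0.25 * sin(2 * pi * (bpm / 60) * k / fps))
      f <- 20 + (peak - 20) * (d2 <= r^2)
      if (noiseSd > 0)
        f <- pmax(f + matrix(stats::rnorm(ny * nx, 0, noiseSd * peak), ny, nx), 0)
      f
    })
  })
}

#' Write a frame list as a 16-bit multi-page TIFF video
#' @param frames list of `[y, x]` matrices.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeVideoTiff <- function(frames, path) {
  pages <- lapply(frames, function(f) pmin(pmax(f, 0), 65535) / 65535)
  writeTIFF(pages, path, bits.per.sample = 16L, compression = "none",
            reduce = FALSE)
  invisible(path)
}
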