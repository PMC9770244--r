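# Independent brute-force oracles and small fixture builders.  These stay
# deliberately naive (exhaustive scans, O(n^2) loops) so they cannot share
# a defect with the implementation they check.

# -- 3D median with half-sample symmetric reflection --------------------------
oracleMedian3d <- function(a, radii) {
  d <- dim(a)
  refl <- function(i, n) {
    while (i < 1 || i > n) {
      if (i < 1) i <- 1 - i
      if (i > n) i <- 2 * n + 1 - i
    }
    i
  }
  out <- array(0, d)
  for (z in 1:d[3]) for (x in 1:d[2]) for (y in 1:d[1]) {
    vals <- numeric(0)
    for (dz in -radii[3]:radii[3])
      for (dx in -radii[1]:radii[1])
        for (dy in -radii[2]:radii[2])
          vals <- c(vals, a[refl(y + dy, d[1]), refl(x + dx, d[2]),
                            refl(z + dz, d[3])])
    out[y, x, z] <- sort(vals)[(length(vals) + 1) / 2]
  }
  out
}

# -- seeded priority-flood watershed ------------------------------------------
# Descending intensity, FIFO among equal intensities, neighbours examined in
# ascending (dz, dy, dx) order, labels assigned at first reach.
oracleWatershed <- function(a, seeds, B, conn = 26) {
  d <- dim(a)
  lab <- array(0L, d)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[order(offs[, "dz"], offs[, "dy"], offs[, "dx"]), , drop = FALSE]
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (conn == 6) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  qv <- numeric(0); qc <- integer(0); act <- logical(0)
  qy <- integer(0); qx <- integer(0); qz <- integer(0)
  n <- 0L
  for (s in seq_len(nrow(seeds))) {
    y <- seeds[s, 1]; x <- seeds[s, 2]; z <- seeds[s, 3]
    stopifnot(a[y, x, z] > B, lab[y, x, z] == 0L)
    lab[y, x, z] <- s
    qv <- c(qv, a[y, x, z]); qc <- c(qc, n); n <- n + 1L
    qy <- c(qy, y); qx <- c(qx, x); qz <- c(qz, z); act <- c(act, TRUE)
  }
  while (any(act)) {
    cand <- which(act)
    i <- cand[order(-qv[cand], qc[cand])][1L]
    act[i] <- FALSE
    l <- lab[qy[i], qx[i], qz[i]]
    for (k in seq_len(nrow(offs))) {
      yy <- qy[i] + offs[k, "dy"]; xx <- qx[i] + offs[k, "dx"]
      zz <- qz[i] + offs[k, "dz"]
      if (yy < 1 || yy > d[1] || xx < 1 || xx > d[2] || zz < 1 || zz > d[3])
        next
      if (lab[yy, xx, zz] == 0L && a[yy, xx, zz] > B) {
        lab[yy, xx, zz] <- l
        qv <- c(qv, a[yy, xx, zz]); qc <- c(qc, n); n <- n + 1L
        qy <- c(qy, yy); qx <- c(qx, xx); qz <- c(qz, zz)
        act <- c(act, TRUE)
      }
    }
  }
  lab
}

# -- exhaustive Euclidean distance transform ----------------------------------
oracleEdt <- function(mask) {
  out <- matrix(0, nrow(mask), ncol(mask))
  bg <- which(!mask, arr.ind = TRUE)
  fg <- which(mask, arr.ind = TRUE)
  for (i in seq_len(nrow(fg)))
    out[fg[i, 1], fg[i, 2]] <-
      sqrt(min((bg[, 1] - fg[i, 1])^2 + (bg[, 2] - fg[i, 2])^2))
  out
}

# -- max vertex-pair caliper angle (degrees in [0, 180)) ----------------------
oracleFeret <- function(p) {
  best <- -1; angs <- numeric(0)
  n <- nrow(p)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    d2 <- sum((p[i, ] - p[j, ])^2)
    a <- (atan2(p[j, 2] - p[i, 2], p[j, 1] - p[i, 1]) * 180 / pi) %% 180
    if (d2 > best * (1 + 1e-9)) { best <- d2; angs <- a }
    else if (d2 >= best * (1 - 1e-9)) angs <- c(angs, a)
  }
  min(angs)
}

# -- direct (non-separable) Gaussian KDE on a grid ----------------------------
oracleKde <- function(points, gx, gy, h) {
  out <- matrix(0, length(gy), length(gx))
  for (iy in seq_along(gy)) for (ix in seq_along(gx)) {
    s <- 0
    for (k in seq_len(nrow(points)))
      s <- s + exp(-((gx[ix] - points[k, 1])^2 + (gy[iy] - points[k, 2])^2) /
                     (2 * h^2))
    out[iy, ix] <- s
  }
  out
}

# -- per-pixel sharpest-slice selection with reflected borders ----------------
oracleFocus <- function(a, r) {
  d <- dim(a)
  refl <- function(i, n) {
    while (i < 1 || i > n) {
      if (i < 1) i <- 1 - i
      if (i > n) i <- 2 * n + 1 - i
    }
    i
  }
  height <- matrix(1L, d[1], d[2])
  for (y in 1:d[1]) for (x in 1:d[2]) {
    best <- -Inf
    for (z in 1:d[3]) {
      vals <- numeric(0)
      for (dy in -r:r) for (dx in -r:r)
        vals <- c(vals, a[refl(y + dy, d[1]), refl(x + dx, d[2]), z])
      v <- mean((vals - mean(vals))^2)
      if (v > best) { best <- v; height[y, x] <- z }
    }
  }
  height
}

# -- fixtures -----------------------------------------------------------------
mkGrid <- function(a, cal = c(1, 1, 1)) VoxelGrid(a, cal)

# isotropic Gaussian blob added into an array (voxel units, 1 um voxels)
blobArray <- function(d, center, sigma, amp) {
  a <- array(0, d)
  for (z in 1:d[3]) {
    dz2 <- (z - 0.5 - center[3])^2
    dy2 <- (seq_len(d[1]) - 0.5 - center[2])^2
    dx2 <- (seq_len(d[2]) - 0.5 - center[1])^2
    a[, , z] <- amp * exp(-(outer(dy2, dx2, "+") + dz2) / (2 * sigma^2))
  }
  a
}

rotatePoly <- function(p, deg, center = c(0, 0)) {
  th <- deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  t(R %*% (t(p) - center) + center)
}

# asymmetric test outline (bulged-head larva shape), in pixel coordinates
eggOutline <- function(W = 120, H = 60, n = 48) {
  u <- seq(-1, 1, length.out = n %/% 2)
  a <- 0.45 * W; b <- 0.4 * H
  half <- b * sqrt(pmax(1 - u^2, 0)) * (0.4 + 0.6 * exp(-((u + 0.5) / 0.4)^2))
  x <- W / 2 + a * u
  poly <- rbind(cbind(x, H / 2 - 0.7 * half),
                cbind(rev(x), H / 2 + rev(1.3 * half)))
  poly <- poly[c(TRUE, diff(poly[, 1]) != 0 | diff(poly[, 2]) != 0), ,
               drop = FALSE]
  if (all(poly[1, ] == poly[nrow(poly), ])) poly <- poly[-nrow(poly), , drop = FALSE]
  unname(poly)
}
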