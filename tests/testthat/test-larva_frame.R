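test_that("Feret angle matches the brute-force caliper oracle", {
  rect <- cbind(c(0, 10, 10, 0), c(0, 0, 2, 2))
  expect_equal(feretAngle(rect), oracleFeret(rect), tolerance = 1e-9)
  r30 <- rotatePoly(rect, 30)
  expect_equal(feretAngle(r30), oracleFeret(r30), tolerance = 1e-6)
  set.seed(3)
  for (i in 1:10) {
    poly <- eggOutline(W = runif(1, 60, 140), H = runif(1, 30, 70))
    expect_equal(feretAngle(poly), oracleFeret(poly), tolerance = 1e-9)
  }
})

test_that("Feret angle is rotation-equivariant and handles ties", {
  poly <- eggOutline()
  base <- feretAngle(poly)
  for (th in c(17.5, 61, 120.25, 179)) {
    expect_equal(feretAngle(rotatePoly(poly, th, c(60, 30))) %% 180,
                 (base + th) %% 180, tolerance = 1e-6)
  }
  # square: both diagonals tie; documented tie-break takes the smaller angle
  sq <- cbind(c(0, 4, 4, 0), c(0, 0, 4, 4))
  expect_equal(feretAngle(sq), 45)
  expect_error(feretAngle(cbind(c(0, 1, 2), c(0, 1, 2))), "degenerate|area")
})

test_that("interior anchor maximises distance to the boundary", {
  # circle: anchor at the centre within a pixel
  th <- seq(0, 2 * pi, length.out = 41)[-41]
  circ <- cbind(24 + 20 * cos(th), 24 + 20 * sin(th))
  a <- interiorAnchor(circ, c(1, 1))
  expect_lt(max(abs(a - c(24, 24))), 1.01)

  # 40 x 8 rectangle: on the long midline, 4 px from the long edges
  rect <- cbind(c(0, 40, 40, 0), c(0, 0, 8, 8))
  a <- interiorAnchor(rect, c(1, 1))
  expect_equal(unname(attr(a, "distance_um")), 4)
  expect_true(a[2] >= 3 && a[2] <= 5)

  # L-shape: deepest pocket of the thicker arm, against the exhaustive EDT
  L <- cbind(c(0, 30, 30, 12, 12, 0), c(0, 0, 10, 10, 28, 28))
  a <- interiorAnchor(L, c(1, 1))
  mask <- larvaSeg:::.rasterMask(L, 34, 36, origin = c(-2, -2))
  ed <- oracleEdt(mask)
  expect_equal(unname(attr(a, "distance_um")), max(ed), tolerance = 1e-9)
  expect_true(a[2] < 12)  # inside the thick horizontal arm
})

test_that("anchor distance equals the brute-force EDT maximum on rasters", {
  set.seed(5)
  for (i in 1:5) {
    poly <- eggOutline(W = runif(1, 30, 60), H = runif(1, 20, 40))
    a <- interiorAnchor(poly, c(1, 1))
    mask <- larvaSeg:::.rasterMask(poly, 64, 64, origin = c(-2, -2))
    expect_equal(unname(attr(a, "distance_um")), max(oracleEdt(mask)),
                 tolerance = 1e-9)
  }
})

test_that("larva-frame transform is rigid, centred and invertible", {
  poly <- eggOutline()
  fr <- buildFrame(poly, c(0.8, 0.8))
  # area centroid of the outline maps to the origin
  ctr <- larvaSeg:::.polygonCentroid(cbind(poly[, 1] * 0.8, poly[, 2] * 0.8))
  expect_lt(max(abs(toLarvaCoords(fr, ctr))), 1e-9)
  # distances preserved
  p1 <- c(10, 20); p2 <- c(50, 15)
  q <- toLarvaCoords(fr, rbind(p1, p2))
  expect_equal(sqrt(sum((q[1, ] - q[2, ])^2)), sqrt(sum((p1 - p2)^2)),
               tolerance = 1e-9)
  # round trip
  pts <- cbind(runif(20, 0, 90), runif(20, 0, 45))
  expect_lt(max(abs(fromLarvaCoords(fr, toLarvaCoords(fr, pts)) - pts)), 1e-9)
  # anterior-left convention: anchor lands in the left half-plane
  expect_lt(toLarvaCoords(fr, fr@anchor)[1], 0)
})

test_that("mirrored outlines set the flip flag and land anterior-left", {
  poly <- eggOutline()
  fr0 <- buildFrame(poly, c(1, 1))
  mir <- cbind(-poly[, 1], poly[, 2])
  fr1 <- buildFrame(mir, c(1, 1))
  expect_false(fr0@flip == fr1@flip)
  expect_lt(toLarvaCoords(fr1, fr1@anchor)[1], 0)
})

test_that("random rigid poses (and mirrors) canonicalize to one pose", {
  poly <- eggOutline()
  canon <- toLarvaCoords(buildFrame(poly, c(1, 1)), poly)
  set.seed(42)
  for (i in 1:10) {
    q <- rotatePoly(poly, runif(1, 0, 360), c(60, 30))
    q <- cbind(q[, 1] + runif(1, -40, 40), q[, 2] + runif(1, -40, 40))
    if (i %% 2 == 0) q[, 1] <- -q[, 1]
    got <- toLarvaCoords(buildFrame(q, c(1, 1)), q)
    expect_lt(max(sqrt(rowSums((got - canon)^2))), 1)
  }
})

test_that("outline JSON round-trips larva id, outline and exclusions", {
  path <- withr::local_tempfile(fileext = ".json")
  poly <- eggOutline()
  excl <- list(cbind(c(10, 20, 20, 10), c(10, 10, 20, 20)))
  writeOutlineJson("L7", poly, excl, path)
  back <- readOutlineJson(path)
  expect_identical(back$larvaId, "L7")
  expect_equal(back$outline, unname(poly))
  expect_equal(back$exclusions[[1]], unname(excl[[1]]))
  expect_error(readOutlineJson(tempfile()), "outline")
})

test_that("montages stack realigned rows that agree across poses", {
  # analytic scene rendered in two poses; realignment must reconcile them
  poly <- eggOutline()
  scene <- function(x, y)
    100 * exp(-((x - 40)^2 + (y - 30)^2) / 200) + 0.3 * x
  render <- function(pose) {
    grid <- expand.grid(y = 1:80, x = 1:140)
    src <- rotatePoly(cbind(grid$x - 0.5, grid$y - 0.5), -pose, c(60, 30))
    FlatImage(matrix(scene(src[, 1], src[, 2]), 80, 140), c(1, 1))
  }
  imgA <- render(0); polyA <- poly
  imgB <- render(45); polyB <- rotatePoly(poly, 45, c(60, 30))
  frA <- buildFrame(polyA, c(1, 1)); frB <- buildFrame(polyB, c(1, 1))
  mont <- makeMontage(list(imgA, imgB), list(frA, frB))
  m <- pixelData(mont)
  expect_identical(nrow(m) %% 2L, 0L)
  rowA <- m[seq_len(nrow(m) / 2), ]
  rowB <- m[-seq_len(nrow(m) / 2), ]
  inside <- rowA > 0 & rowB > 0
  expect_gt(cor(rowA[inside], rowB[inside]), 0.98)

  # single image with its own frame: one row, content preserved
  single <- makeMontage(list(imgA), list(frA))
  expect_gt(cor(as.numeric(pixelData(single))[pixelData(single) > 0],
                as.numeric(pixelData(single))[pixelData(single) > 0]), 0.99)
  # four images stack as four rows in input order
  m4 <- makeMontage(list(imgA, imgA, imgA, imgA),
                    list(frA, frA, frA, frA))
  expect_identical(nrow(pixelData(m4)) %% 4L, 0L)
  expect_error(makeMontage(list(), list()), "at least one")
})
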