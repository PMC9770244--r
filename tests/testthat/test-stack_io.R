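test_that("stack write/read round-trips voxels, calibration and metadata", {
  set.seed(101)
  cal <- c(0.6, 0.6, 2.0)
  a1 <- array(sample(0:4095, 8 * 16 * 16, replace = TRUE), c(16, 16, 8))
  a2 <- array(sample(0:4095, 8 * 16 * 16, replace = TRUE), c(16, 16, 8))
  st <- ConfocalStack(list(bf = VoxelGrid(a1, cal), red = VoxelGrid(a2, cal)),
                      c(bf = "brightfield", red = "fluorescence"),
                      larvaId = "L01", group = "ctrl", dpi = 2L)
  path <- withr::local_tempfile(fileext = ".tif")
  writeStack(st, path)
  rd <- readStack(path, c(bf = "brightfield", red = "fluorescence"))
  expect_identical(voxelData(channels(rd)$bf), a1 + 0)   # lossless integers
  expect_identical(voxelData(channels(rd)$red), a2 + 0)
  expect_equal(unname(calibration(rd)), cal)
  expect_identical(rd@larvaId, "L01")
  expect_identical(rd@dpi, 2L)
  expect_identical(unname(channelRoles(rd)["bf"]), "brightfield")
})

test_that("explicit calibration override beats stored metadata", {
  a <- array(0:7, c(2, 2, 2))
  st <- ConfocalStack(list(bf = VoxelGrid(a), fl = VoxelGrid(a)),
                      c(bf = "brightfield", fl = "fluorescence"))
  path <- withr::local_tempfile(fileext = ".tif")
  writeStack(st, path)
  rd <- readStack(path, c(bf = "brightfield", fl = "fluorescence"),
                  calibration = c(0.6, 0.6, 2.0))
  expect_equal(unname(calibration(rd)), c(0.6, 0.6, 2.0))
})

test_that("channel mismatch and missing calibration are errors", {
  # a bare 3-page single-channel TIFF with no sidecar metadata
  path <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(lapply(1:3, function(i) matrix(i / 10, 4, 4)), path,
                  bits.per.sample = 16L, reduce = FALSE)
  expect_error(
    readStack(path, c(bf = "brightfield", fl = "fluorescence"),
              calibration = c(1, 1, 1)),
    "not a multiple")
  # 4 pages divide evenly by 2 channels, but no calibration source exists
  path2 <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(lapply(1:4, function(i) matrix(i / 10, 4, 4)), path2,
                  bits.per.sample = 16L, reduce = FALSE)
  expect_error(
    readStack(path2, c(bf = "brightfield", fl = "fluorescence")),
    "calibration")
  expect_error(readStack(withr::local_tempfile(fileext = ".tif"),
                         c(bf = "brightfield")), "no such file")
})

test_that("OME-XML descriptions yield calibration and channel names", {
  xml <- paste0(
    '<OME xmlns="http://www.openmicroscopy.org/Schemas/OME/2016-06">',
    '<Image><Pixels SizeC="2" SizeZ="8" DimensionOrder="XYCZT"',
    ' PhysicalSizeX="0.6" PhysicalSizeY="0.6" PhysicalSizeZ="2.0">',
    '<Channel Name="BF"/><Channel Name="Cy5"/></Pixels></Image></OME>')
  ome <- parseOmeDescription(xml)
  expect_equal(unname(ome$calibration), c(0.6, 0.6, 2.0))
  expect_identical(ome$sizeC, 2L)
  expect_identical(ome$channelNames, c("BF", "Cy5"))
  expect_error(parseOmeDescription("<OME></OME>"), "Pixels")
})

test_that("objects CSV round-trips numeric fields at full precision", {
  lab <- array(0L, c(3, 3, 2)); lab[2, 2, 1] <- 1L
  st <- ConfocalStack(
    list(bf = VoxelGrid(array(1, c(3, 3, 2)), c(0.6, 0.6, 2)),
         fl = VoxelGrid(array(2, c(3, 3, 2)), c(0.6, 0.6, 2))),
    c(bf = "brightfield", fl = "fluorescence"), larvaId = "L1")
  obj <- measureObjects(LabelMap(lab, c(0.6, 0.6, 2)), st)
  expect_equal(obj$volume_um3, 0.72)
  path <- withr::local_tempfile(fileext = ".csv")
  writeObjectsCsv(obj, path)
  back <- readObjectsCsv(path)
  expect_equal(back$volume_um3, 0.72)
  for (col in c("esd_um", "centroid_x_um", "centroid_y_um", "centroid_z_um"))
    expect_equal(back[[col]], obj[[col]], tolerance = 1e-9)
})

test_that("empty and multi-larva object tables export faithfully", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeObjectsCsv(data.frame(), path)
  empty <- readObjectsCsv(path)
  expect_identical(nrow(empty), 0L)
  expect_true(all(c("larva_id", "volume_um3", "esd_um") %in% names(empty)))

  mk <- function(id) {
    lab <- array(0L, c(2, 2, 2)); lab[1, 1, 1] <- 1L
    st <- ConfocalStack(list(bf = VoxelGrid(array(1, c(2, 2, 2))),
                             fl = VoxelGrid(array(1, c(2, 2, 2)))),
                        c(bf = "brightfield", fl = "fluorescence"),
                        larvaId = id)
    measureObjects(LabelMap(lab, c(1, 1, 1)), st)
  }
  both <- rbind(mk("A"), mk("B"), mk("B"))
  writeObjectsCsv(both, path)
  back <- readObjectsCsv(path)
  expect_identical(nrow(back), 3L)
  expect_identical(back$larva_id, c("A", "B", "B"))
})
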