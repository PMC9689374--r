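random_volume <- function(size = c(16, 12, 3), spacing = c(0.7, 0.7, 5),
                          origin = c(-20, -15, 4), seed = 42) {
  set.seed(seed)
  hu <- array(sample(-1024:1500, prod(size), replace = TRUE), size)
  ct_volume(hu, volume_geometry(origin, spacing, diag(3), size),
            tags = list(SliceThickness = spacing[3]))
}

test_that("DICOM series round-trips intensities exactly and geometry to 1e-6 mm", {
  vol <- random_volume()
  dir <- withr::local_tempdir()
  paths <- write_dicom_series(vol, dir)
  expect_length(paths, 3L)
  back <- read_dicom_series(dir)
  expect_identical(back$data, vol$data + 0)     # bit-exact in stored integers
  expect_equal(back$geometry$origin, vol$geometry$origin, tolerance = 1e-9)
  expect_lt(max(abs(back$geometry$spacing - vol$geometry$spacing)), 1e-6)
  expect_lt(max(abs(back$geometry$direction - vol$geometry$direction)), 1e-6)
  expect_identical(back$geometry$size, vol$geometry$size)
  # constant -1000 HU volume round-trips unchanged
  cvol <- ct_volume(array(-1000, c(8, 8, 2)),
                    volume_geometry(c(0, 0, 0), c(1, 1, 5), diag(3), c(8, 8, 2)))
  d2 <- withr::local_tempdir()
  expect_length(write_dicom_series(cvol, d2), 2L)
  expect_true(all(read_dicom_series(d2)$data == -1000))
})

test_that("slice order is recovered from positions, not file names", {
  vol <- random_volume(size = c(10, 10, 5))
  dir <- withr::local_tempdir()
  paths <- write_dicom_series(vol, dir)
  shuffled <- withr::local_tempdir()
  perm <- c(3, 5, 1, 4, 2)
  for (i in seq_along(paths)) {
    file.copy(paths[perm[i]], file.path(shuffled, sprintf("slice_%04d.dcm", i)))
  }
  expect_identical(read_dicom_series(shuffled)$data, read_dicom_series(dir)$data)
})

test_that("rescale transform maps stored values to HU", {
  # stored 0 with intercept -1024 -> -1024 HU on read
  vol <- ct_volume(array(-1024, c(6, 6, 1)),
                   volume_geometry(c(0, 0, 0), c(1, 1, 1), diag(3), c(6, 6, 1)))
  dir <- withr::local_tempdir()
  write_dicom_series(vol, dir, slope = 1, intercept = -1024)
  back <- read_dicom_series(dir)
  expect_true(all(back$data == -1024))
  expect_equal(back$tags$RescaleIntercept, -1024)
})

test_that("out-of-range intensities are refused with the offending extreme", {
  vol <- ct_volume(array(c(rep(0, 35), 40000), c(6, 6, 1)),
                   volume_geometry(c(0, 0, 0), c(1, 1, 1), diag(3), c(6, 6, 1)))
  expect_error(write_dicom_series(vol, withr::local_tempdir()), "40000")
})

test_that("derived-series provenance survives a round trip", {
  vol <- random_volume(size = c(8, 8, 2))
  dir <- withr::local_tempdir()
  write_dicom_series(vol, dir,
                     tags = list(SeriesDescription = "SR output",
                                 DerivationDescription = "super-resolved from fused LR"))
  back <- read_dicom_series(dir)
  expect_identical(back$tags$SeriesDescription, "SR output")
  expect_match(back$tags$DerivationDescription, "super-resolved")
})

test_that("inconsistent series are rejected", {
  a <- random_volume(size = c(8, 8, 2), seed = 1)
  dir <- withr::local_tempdir()
  write_dicom_series(a, dir, tags = list(SeriesInstanceUID = "2.25.111"))
  # mixed series UIDs: drop in a slice from a second series
  p2 <- write_dicom_series(a, withr::local_tempdir(),
                           tags = list(SeriesInstanceUID = "2.25.222"))
  file.copy(p2[1], file.path(dir, "slice_8888.dcm"))
  expect_error(read_dicom_series(dir), "mixed SeriesInstanceUID")

  # non-uniform inter-slice spacing: third slice at 11 mm after gaps of 5 mm
  d2 <- withr::local_tempdir()
  write_dicom_series(a, d2, tags = list(SeriesInstanceUID = "2.25.333"))
  b <- random_volume(size = c(8, 8, 1), origin = c(-20, -15, 4 + 11), seed = 2)
  p <- write_dicom_series(b, withr::local_tempdir(),
                          tags = list(SeriesInstanceUID = "2.25.333"))
  file.copy(p, file.path(d2, "slice_9999.dcm"))
  expect_error(read_dicom_series(d2), "non-uniform inter-slice spacing")

  # inconsistent orientation across slices
  d3 <- withr::local_tempdir()
  write_dicom_series(a, d3, tags = list(SeriesInstanceUID = "2.25.444"))
  rot <- ct_volume(b$data,
                   volume_geometry(b$geometry$origin, b$geometry$spacing,
                                   cbind(c(0, 1, 0), c(1, 0, 0), c(0, 0, 1)),
                                   b$geometry$size))
  p3 <- write_dicom_series(rot, withr::local_tempdir(),
                           tags = list(SeriesInstanceUID = "2.25.444"))
  file.copy(p3, file.path(d3, "slice_9999.dcm"))
  expect_error(read_dicom_series(d3), "orientation")
})

test_that("deidentification empties identifiers, resets dates, renews UIDs", {
  tags <- list(PatientName = "DOE^JOHN", PatientID = "A123",
               StudyDate = "20190715", SeriesDate = "20191224",
               StudyInstanceUID = "2.25.1", SeriesInstanceUID = "2.25.2",
               Modality = "CT")
  out <- deidentify(tags)
  expect_identical(out$PatientName, "")
  expect_identical(out$PatientID, "")
  expect_identical(out$StudyDate, "20190101")
  expect_identical(out$SeriesDate, "20190101")
  expect_false(out$SeriesInstanceUID == tags$SeriesInstanceUID)
  expect_identical(out$Modality, "CT")
  # two calls on the same input yield distinct fresh UIDs
  out2 <- deidentify(tags)
  expect_false(out$SeriesInstanceUID == out2$SeriesInstanceUID)
  # missing date tags are skipped silently
  expect_silent(deidentify(list(PatientName = "X")))
})

test_that("written files are readable by an independent DICOM implementation", {
  vol <- random_volume(size = c(9, 7, 2))
  dir <- withr::local_tempdir()
  write_dicom_series(vol, dir, tags = list(SeriesDescription = "xcheck"))
  script <- "
import json, sys, glob
import pydicom
files = sorted(glob.glob(sys.argv[1] + '/*.dcm'))
out = []
for f in files:
    ds = pydicom.dcmread(f)
    arr = ds.pixel_array * float(ds.RescaleSlope) + float(ds.RescaleIntercept)
    out.append({'ipp': [float(v) for v in ds.ImagePositionPatient],
                'rows': int(ds.Rows), 'cols': int(ds.Columns),
                'desc': str(ds.SeriesDescription),
                'corner': float(arr[0, 0]),
                'sum': float(arr.sum())})
print(json.dumps(out))
"
  sf <- withr::local_tempfile(fileext = ".py")
  writeLines(script, sf)
  res <- system2("python", c(sf, dir), stdout = TRUE)
  parsed <- jsonlite::fromJSON(paste(res, collapse = ""), simplifyVector = FALSE)
  expect_length(parsed, 2L)
  s1 <- parsed[[1]]
  expect_identical(s1$rows, 7L)  # pydicom rows = our second axis
  expect_identical(s1$cols, 9L)
  expect_equal(unlist(s1$ipp), vol$geometry$origin, tolerance = 1e-9)
  # pixel_array[0,0] is row 0 / col 0 = our [1,1]; totals match per slice
  expect_equal(s1$corner, vol$data[1, 1, 1])
  expect_equal(s1$sum, sum(vol$data[, , 1]))
  expect_identical(s1$desc, "xcheck")
})
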