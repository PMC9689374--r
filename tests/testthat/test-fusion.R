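test_that("resampling onto the source grid is the identity", {
  vol <- make_phantom_hr(micro_spec(seed = 2L))
  r <- resample_to_grid(vol, vol$geometry)
  expect_true(all(r$covered))
  expect_equal(r$values, vol$data, tolerance = 1e-12)
})

test_that("trilinear resampling is exact on an affine field", {
  # source f(x, y, z) = x (mm); target shifted by half a voxel in every axis
  g <- volume_geometry(c(0, 0, 0), c(1, 1, 1), diag(3), c(10, 10, 10))
  xs <- array(rep(0:9, times = 100), c(10, 10, 10))
  src <- ct_volume(xs, g)
  tg <- volume_geometry(c(0.5, 0.5, 0.5), c(1, 1, 1), diag(3), c(9, 9, 9))
  r <- resample_to_grid(src, tg)
  expected <- array(rep(0:8 + 0.5, times = 81), c(9, 9, 9))
  expect_true(all(r$covered))
  expect_equal(r$values, expected, tolerance = 1e-12)
})

test_that("voxels outside the source extent are flagged uncovered", {
  g <- volume_geometry(c(0, 0, 0), c(1, 1, 1), diag(3), c(5, 5, 5))
  src <- ct_volume(array(1, c(5, 5, 5)), g)
  # target extends 1 mm beyond the source voxel-centre hull in +z
  tg <- volume_geometry(c(0, 0, 1), c(1, 1, 1), diag(3), c(5, 5, 5))
  r <- resample_to_grid(src, tg)
  expect_true(all(r$covered[, , 1:4]))
  expect_false(any(r$covered[, , 5]))
  expect_true(all(is.na(r$values[, , 5])))
})

test_that("degenerate direction matrices are refused", {
  g <- volume_geometry(c(0, 0, 0), c(1, 1, 1), diag(3), c(4, 4, 4))
  src <- ct_volume(array(0, c(4, 4, 4)), g)
  bad <- g; bad$direction <- matrix(0, 3, 3)
  expect_error(resample_to_grid(src, bad), "degenerate")
})

test_that("fusing two constant sources yields the constant where covered", {
  trip <- make_triplet(micro_spec(seed = 4L))
  ca <- ct_volume(array(12, dim(trip$thick_axial$data)),
                  trip$thick_axial$geometry)
  cc <- ct_volume(array(12, dim(trip$thick_coronal$data)),
                  trip$thick_coronal$geometry)
  fr <- fuse_series(ca, cc, trip$thin_axial$geometry)
  ra <- resample_to_grid(ca, trip$thin_axial$geometry)
  rc <- resample_to_grid(cc, trip$thin_axial$geometry)
  covered_any <- ra$covered | rc$covered
  expect_lt(max(abs(fr$lr$data[covered_any] - 12)), 1e-9)
  expect_true(all(fr$lr$data[!covered_any] == -1000))
  expect_identical(fr$coverage_mask, ra$covered & rc$covered)
})

test_that("fusion equals the brute-force per-voxel oracle to 1e-6 HU", {
  trip <- make_triplet(micro_spec(seed = 7L))
  fr <- fuse_series(trip$thick_axial, trip$thick_coronal,
                    trip$thin_axial$geometry)
  oracle <- fuse_oracle(trip$thick_axial, trip$thick_coronal,
                        trip$thin_axial$geometry)
  expect_lt(max(abs(fr$lr$data - oracle)), 1e-6)
})

test_that("fusion is symmetric and bounded by the source intensity range", {
  trip <- make_triplet(micro_spec(seed = 9L))
  f1 <- fuse_series(trip$thick_axial, trip$thick_coronal,
                    trip$thin_axial$geometry)
  f2 <- fuse_series(trip$thick_coronal, trip$thick_axial,
                    trip$thin_axial$geometry)
  expect_equal(f1$lr$data, f2$lr$data, tolerance = 1e-12)
  lo <- min(trip$thick_axial$data, trip$thick_coronal$data)
  hi <- max(trip$thick_axial$data, trip$thick_coronal$data)
  covered_any <- f1$lr$data != -1000
  expect_gte(min(f1$lr$data[covered_any]), lo - 1e-9)
  expect_lte(max(f1$lr$data[covered_any]), hi + 1e-9)
})

test_that("non-orthogonal pairs are discarded", {
  trip <- make_triplet(micro_spec(seed = 5L))
  theta <- 5 * pi / 180
  R <- rbind(c(1, 0, 0), c(0, cos(theta), -sin(theta)),
             c(0, sin(theta), cos(theta)))
  tilted <- trip$thick_coronal
  tilted$geometry <- volume_geometry(tilted$geometry$origin,
                                     tilted$geometry$spacing,
                                     R %*% tilted$geometry$direction,
                                     tilted$geometry$size)
  expect_error(fuse_series(trip$thick_axial, tilted, trip$thin_axial$geometry),
               "orthogonal")
})

test_that("fused LR beats the resampled thick-axial series alone (body ROI PSNR)", {
  case <- make_case(seed = 13L)
  rois <- segment_rois(case$hr)
  crop <- function(a) a[rois$body$min[1]:rois$body$max[1],
                        rois$body$min[2]:rois$body$max[2],
                        rois$body$min[3]:rois$body$max[3]]
  ra <- resample_to_grid(case$triplet$thick_axial, case$hr$geometry)
  axial_only <- ifelse(is.na(ra$values), -1000, ra$values)
  expect_gt(psnr(crop(case$hr$data), crop(case$lr$data)),
            psnr(crop(case$hr$data), crop(axial_only)))
})
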