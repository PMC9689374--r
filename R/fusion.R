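# Building the low-resolution volume on the thin-axial grid: each thick
# series is resampled onto the target grid through patient-space coordinates
# (trilinear interpolation), then the two resampled volumes are averaged
# voxelwise where both cover.

#' Resample a volume onto a target grid through world coordinates
#'
#' Maps every target voxel centre to patient space, converts it to continuous
#' source indices, and interpolates trilinearly. A voxel is covered when its
#' continuous index lies inside the source voxel-centre hull on every axis
#' (no extrapolation); uncovered voxels get `NA`.
#'
#' @param src A [ct_volume()].
#' @param target A [volume_geometry()] defining the output grid.
#' @return A list with `values` (3D array, `NA` outside coverage) and
#'   `covered` (logical 3D array).
#' @export
resample_to_grid <- function(src, target) {
  if (abs(det(src$geometry$direction)) < 1e-8 ||
      abs(det(target$direction)) < 1e-8)
    stop("degenerate direction matrix")
  n <- target$size
  idx <- as.matrix(expand.grid(i = seq_len(n[1]) - 1,
                               j = seq_len(n[2]) - 1,
                               k = seq_len(n[3]) - 1))
  world <- voxel_to_world(target, t(idx))
  cont <- world_to_voxel(src$geometry, world)     # 3 x N, 0-based
  ns <- src$geometry$size
  eps <- 1e-9
  covered <- cont[1, ] >= -eps & cont[1, ] <= ns[1] - 1 + eps &
             cont[2, ] >= -eps & cont[2, ] <= ns[2] - 1 + eps &
             cont[3, ] >= -eps & cont[3, ] <= ns[3] - 1 + eps
  vals <- rep(NA_real_, ncol(cont))
  if (any(covered)) {
    p <- cont[, covered, drop = FALSE]
    p <- pmin(pmax(p, 0), ns - 1)   # recycled by row: clamp each axis
    i0 <- floor(p)
    i0 <- pmin(i0, pmax(ns - 2, 0)) # keep the upper corner in range; n==1 axes stay 0
    f <- p - i0
    nx <- ns[1]; nxy <- ns[1] * ns[2]
    acc <- 0
    dat <- src$data
    for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
      w <- (if (di) f[1, ] else 1 - f[1, ]) *
           (if (dj) f[2, ] else 1 - f[2, ]) *
           (if (dk) f[3, ] else 1 - f[3, ])
      ii <- pmin(i0[1, ] + di, ns[1] - 1)
      jj <- pmin(i0[2, ] + dj, ns[2] - 1)
      kk <- pmin(i0[3, ] + dk, ns[3] - 1)
      acc <- acc + w * dat[1 + ii + nx * jj + nxy * kk]
    }
    vals[covered] <- acc
  }
  list(values = array(vals, n), covered = array(covered, n))
}

#' Fuse thick axial and coronal series into a low-resolution volume
#'
#' Resamples both thick series onto the target (thin-axial) grid in world
#' coordinates and averages them voxelwise. Where only one series covers a
#' voxel its value is used alone; where neither covers, the fill value
#' (-1000 HU, ambient air) is used. Pairs that fail the right-orthogonality
#' admission rule are rejected.
#'
#' @param thick_axial,thick_coronal [ct_volume()] objects.
#' @param target A [volume_geometry()], normally the thin-axial grid.
#' @param fill Fill value for voxels outside both sources (HU).
#' @param orthogonality_tol Tolerance for [check_orthogonality()].
#' @return An object of class `fusion_result`: list with `lr` ([ct_volume()]
#'   on the target grid), `coverage_mask` (logical array, TRUE where both
#'   sources covered the voxel) and `provenance`.
#' @export
fuse_series <- function(thick_axial, thick_coronal, target,
                        fill = -1000, orthogonality_tol = 1e-3) {
  if (!check_orthogonality(thick_axial$geometry, thick_coronal$geometry,
                           orthogonality_tol))
    stop("series pair is not right-orthogonal; set discarded")
  ra <- resample_to_grid(thick_axial, target)
  rc <- resample_to_grid(thick_coronal, target)
  both <- ra$covered & rc$covered
  vals <- array(fill, target$size)
  vals[both] <- (ra$values[both] + rc$values[both]) / 2
  only_a <- ra$covered & !rc$covered
  only_c <- rc$covered & !ra$covered
  vals[only_a] <- ra$values[only_a]
  vals[only_c] <- rc$values[only_c]
  lr <- ct_volume(vals, target,
                  tags = list(SliceThickness = target$spacing[3],
                              SeriesDescription = "fused LR volume",
                              DerivationDescription =
                                "mean of world-registered thick axial and coronal series"))
  structure(list(lr = lr, coverage_mask = both,
                 provenance = c(axial = thick_axial$tags$SeriesInstanceUID %||% "thick_axial",
                                coronal = thick_coronal$tags$SeriesInstanceUID %||% "thick_coronal")),
            class = "fusion_result")
}

#' @export
print.fusion_result <- function(x, ...) {
  cat("<fusion_result> LR grid", paste(dim(x$lr$data), collapse = "x"),
      sprintf("; both-source coverage %.1f%%\n", 100 * mean(x$coverage_mask)))
  invisible(x)
}
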