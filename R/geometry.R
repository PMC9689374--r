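#' Volume geometry in patient (LPS) coordinates
#'
#' Describes how 0-based voxel indices `(i, j, k)` of a 3D grid map to
#' patient-space millimetres: `world = origin + direction %*% (spacing * c(i, j, k))`.
#' `origin` is the centre of the first voxel, `direction` holds unit column
#' vectors for the in-plane row axis, in-plane column axis and the slice
#' normal, and `spacing[3]` is the inter-slice spacing.
#'
#' @param origin Numeric length-3, position of the first voxel centre (mm, LPS).
#' @param spacing Numeric length-3, strictly positive voxel sizes (mm); the
#'   third component is the spacing between consecutive slices.
#' @param direction 3x3 matrix with (approximately) orthonormal columns.
#' @param size Integer length-3, voxel counts per axis (all >= 1).
#' @return An object of class `volume_geometry`.
#' @export
volume_geometry <- function(origin, spacing, direction = diag(3), size) {
  origin <- as.numeric(origin)
  spacing <- as.numeric(spacing)
  direction <- as.matrix(direction)
  size <- as.integer(round(size))
  stopifnot(length(origin) == 3, length(spacing) == 3, length(size) == 3,
            all(dim(direction) == c(3, 3)))
  if (any(!is.finite(origin)) || any(!is.finite(spacing)) || any(!is.finite(direction)))
    stop("geometry fields must be finite")
  if (any(spacing <= 0)) stop("spacing must be strictly positive")
  if (any(size < 1L)) stop("size must be >= 1 on every axis")
  gram <- crossprod(direction)
  if (max(abs(gram - diag(3))) > 1e-5)
    stop("direction columns must be unit length and mutually orthogonal")
  structure(list(origin = origin, spacing = spacing,
                 direction = direction, size = size),
            class = "volume_geometry")
}

#' @export
print.volume_geometry <- function(x, ...) {
  cat("<volume_geometry> size", paste(x$size, collapse = "x"),
      " spacing", paste(signif(x$spacing, 6), collapse = "x"), "mm\n")
  cat("  origin:", paste(signif(x$origin, 6), collapse = ", "), "\n")
  invisible(x)
}

#' Map voxel indices to patient-space coordinates
#'
#' @param geom A [volume_geometry()].
#' @param ijk Numeric matrix with 3 rows (or a length-3 vector) of 0-based,
#'   possibly fractional voxel indices.
#' @return 3 x n matrix of world coordinates (mm, LPS).
#' @export
voxel_to_world <- function(geom, ijk) {
  ijk <- if (is.matrix(ijk)) ijk else matrix(as.numeric(ijk), nrow = 3)
  geom$origin + geom$direction %*% (geom$spacing * ijk)
}

#' Map patient-space coordinates to continuous voxel indices
#'
#' Inverse of [voxel_to_world()]; returns fractional 0-based indices.
#'
#' @inheritParams voxel_to_world
#' @param xyz Numeric matrix with 3 rows (or a length-3 vector), mm LPS.
#' @return 3 x n matrix of continuous voxel indices.
#' @export
world_to_voxel <- function(geom, xyz) {
  xyz <- if (is.matrix(xyz)) xyz else matrix(as.numeric(xyz), nrow = 3)
  if (abs(det(geom$direction)) < 1e-8) stop("degenerate direction matrix")
  solve(geom$direction, xyz - geom$origin) / geom$spacing
}

#' CT volume: Hounsfield intensities plus geometry
#'
#' The intensity array is indexed `[i, j, k]` with `i` along the image row
#' direction (direction column 1), `j` along the image column direction and
#' `k` along the slice normal; `dim(data)` must equal `geometry$size`.
#'
#' @param data 3D numeric array of Hounsfield units.
#' @param geometry A [volume_geometry()] whose `size` matches `dim(data)`.
#' @param tags Named list of DICOM-style metadata carried with the volume
#'   (e.g. `SliceThickness`, `SeriesInstanceUID`).
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(data, geometry, tags = list()) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  if (!identical(as.integer(dim(data)), geometry$size))
    stop("array shape does not match geometry size")
  if (any(!is.finite(data))) stop("intensities must be finite")
  structure(list(data = data, geometry = geometry, tags = tags),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  cat("<ct_volume>", paste(dim(x$data), collapse = "x"), "voxels, HU range [",
      signif(min(x$data), 5), ",", signif(max(x$data), 5), "]\n")
  print(x$geometry)
  invisible(x)
}

#' @export
dim.ct_volume <- function(x) dim(x$data)

#' Slice-normal orthogonality of an axial/coronal series pair
#'
#' Two series are treated as right-orthogonal when the coronal slice normal is
#' perpendicular to the axial slice normal and the in-plane axes of both
#' geometries are aligned with the patient axes, all within `tol` on absolute
#' cosine residuals. Pairs failing this are discarded upstream.
#'
#' @param axial,coronal [volume_geometry()] objects.
#' @param tol Tolerance on absolute cosine residuals (default 1e-3).
#' @return `TRUE` or `FALSE` (pure predicate; symmetric in its arguments).
#' @export
check_orthogonality <- function(axial, coronal, tol = 1e-3) {
  n_ax <- axial$direction[, 3]
  n_co <- coronal$direction[, 3]
  if (abs(sum(n_ax * n_co)) > tol) return(FALSE)
  axis_aligned <- function(geom) {
    # every direction column within tol of +/- a patient axis
    all(apply(abs(geom$direction), 2, function(v) sum(v) - max(v)) <= tol)
  }
  axis_aligned(axial) && axis_aligned(coronal)
}
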