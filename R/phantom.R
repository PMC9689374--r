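# Seeded synthetic chest phantoms: a high-resolution volume with a soft-tissue
# trunk (elliptical cylinder), two lung ellipsoids carrying vessel-like tubes,
# ground-glass-like nodules and fine parenchymal texture, plus body-confined
# Gaussian noise. Thick series are derived from the same volume by boxcar
# block averaging, so every downstream stage is testable without clinical data.

.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specification of a synthetic chest phantom
#'
#' Defaults emulate a small chest field of view at 1 mm isotropic thin-slice
#' resolution: ambient air at -1000 HU, a soft-tissue trunk (an elliptical
#' cylinder crossing the whole scanned z-range, as a torso does) at 40 HU,
#' lung parenchyma at -800 HU containing tubular vessels (0 HU) and
#' ground-glass-like nodules (-400 HU), with additive Gaussian noise
#' (sd 15 HU, a realistic reconstruction-noise level) confined to the body.
#'
#' @param size Voxel counts per axis.
#' @param spacing Thin-slice voxel size (mm); 1 mm isotropic by default.
#' @param body_axes Length-2 semi-axes (mm) of the trunk cross-section
#'   (left-right, anterior-posterior); the trunk spans the full z extent.
#' @param lung_axes Semi-axes of each lung ellipsoid (mm).
#' @param lung_offsets 2x3 matrix of lung centre offsets from the volume
#'   centre (mm); one row per lung.
#' @param n_vessels,n_nodules Structure counts inside the lungs.
#' @param lung_texture_sd Amplitude (HU) of the fine parenchymal texture
#'   inside the lungs, emulating the interstitial/vascular markings that make
#'   lung fields the most detail-dense region of a chest CT; thin-slice
#'   volumes keep this texture while thick-slice averaging removes it.
#' @param noise_sd Additive Gaussian noise inside the body (HU).
#' @param seed RNG seed; the phantom is deterministic given the seed.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(size = c(96, 96, 60),
                         spacing = c(1, 1, 1),
                         body_axes = c(40, 34),
                         lung_axes = c(14, 16, 16),
                         lung_offsets = rbind(c(-19, -3, 0), c(19, -3, 0)),
                         n_vessels = 6L,
                         n_nodules = 4L,
                         lung_texture_sd = 200,
                         noise_sd = 15,
                         seed = 1L) {
  stopifnot(length(size) == 3, all(size >= 8), all(spacing > 0),
            length(body_axes) == 2, noise_sd >= 0, lung_texture_sd >= 0,
            nrow(lung_offsets) == 2)
  structure(list(size = as.integer(size), spacing = as.numeric(spacing),
                 body_axes = body_axes, lung_axes = lung_axes,
                 lung_offsets = lung_offsets, n_vessels = as.integer(n_vessels),
                 n_nodules = as.integer(n_nodules),
                 lung_texture_sd = lung_texture_sd, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

.ellipsoid_mask <- function(cx, cy, cz, axes, centre) {
  ((cx - centre[1]) / axes[1])^2 + ((cy - centre[2]) / axes[2])^2 +
    ((cz - centre[3]) / axes[3])^2 <= 1
}

#' Generate the high-resolution phantom volume
#'
#' @param spec A [phantom_spec()].
#' @return A [ct_volume()] on an axis-aligned thin-slice grid with the volume
#'   centre at the patient origin.
#' @export
make_phantom_hr <- function(spec = phantom_spec()) {
  n <- spec$size; sp <- spec$spacing
  extent <- (n - 1) * sp / 2
  x <- seq(-extent[1], extent[1], length.out = n[1])
  y <- seq(-extent[2], extent[2], length.out = n[2])
  z <- seq(-extent[3], extent[3], length.out = n[3])
  cx <- array(rep(x, times = n[2] * n[3]), n)
  cy <- array(rep(rep(y, each = n[1]), times = n[3]), n)
  cz <- array(rep(z, each = n[1] * n[2]), n)

  # trunk: elliptical cylinder crossing the full scanned z-range
  body <- (cx / spec$body_axes[1])^2 + (cy / spec$body_axes[2])^2 <= 1
  lung <- array(FALSE, n)
  centres <- list()
  for (l in 1:2) {
    m <- .ellipsoid_mask(cx, cy, cz, spec$lung_axes, spec$lung_offsets[l, ])
    if (any(m & !body)) stop("lung ellipsoid exceeds the body ellipsoid")
    lung <- lung | m
    centres[[l]] <- spec$lung_offsets[l, ]
  }

  hu <- array(-1000, n)
  hu[body] <- 40
  hu[lung] <- -800

  .with_seed(spec$seed, {
    pts <- cbind(as.vector(cx[lung]), as.vector(cy[lung]), as.vector(cz[lung]))
    for (v in seq_len(spec$n_vessels)) {
      l <- sample(1:2, 1)
      c0 <- centres[[l]] + stats::runif(3, -0.3, 0.3) * spec$lung_axes
      d <- stats::rnorm(3); d <- d / sqrt(sum(d^2))
      half_len <- stats::runif(1, 0.4, 0.9) * min(spec$lung_axes)
      radius <- stats::runif(1, 1.0, 2.0)
      rel <- sweep(pts, 2, c0)
      t <- pmin(pmax(rel %*% d, -half_len), half_len)
      d2 <- rowSums((rel - t %*% t(d))^2)
      sel <- d2 <= radius^2
      idx <- which(lung)[sel]
      hu[idx] <- 0
    }
    for (nd in seq_len(spec$n_nodules)) {
      l <- sample(1:2, 1)
      c0 <- centres[[l]] + stats::runif(3, -0.4, 0.4) * spec$lung_axes
      radius <- stats::runif(1, 2, 4)
      rel <- sweep(pts, 2, c0)
      sel <- rowSums(rel^2) <= radius^2
      idx <- which(lung)[sel]
      hu[idx] <- -400
    }
    if (spec$lung_texture_sd > 0) {
      # fine parenchymal markings: resolved on the thin grid, lost to
      # thick-slice averaging
      hu[lung] <- hu[lung] + stats::rnorm(sum(lung), 0, spec$lung_texture_sd)
    }
    if (spec$noise_sd > 0) {
      nb <- sum(body)
      hu[body] <- hu[body] + stats::rnorm(nb, 0, spec$noise_sd)
    }
  })

  geom <- volume_geometry(origin = -extent, spacing = sp,
                          direction = diag(3), size = n)
  ct_volume(hu, geom, tags = list(SliceThickness = sp[3],
                                  SeriesDescription = "synthetic chest phantom HR"))
}

#' Derive a thick series from a thin-slice volume by block averaging
#'
#' Each thick slice is the arithmetic mean of `factor` consecutive thin
#' slices along the chosen patient axis (a pure boxcar slice profile); any
#' trailing remainder is dropped. The geometry is updated so the third axis
#' of a coronal output is the anterior-posterior patient axis, and the
#' origin moves to the first block centre.
#'
#' @param hr An axis-aligned [ct_volume()] (direction = identity).
#' @param axis `"axial"` (average along the patient z axis) or `"coronal"`
#'   (average along the patient y axis and re-grid).
#' @param factor Integer >= 1, number of thin slices per thick slice.
#' @return A [ct_volume()] with `SliceThickness = factor * thin spacing`.
#' @export
degrade_to_thick <- function(hr, axis = c("axial", "coronal"), factor = 5L) {
  axis <- match.arg(axis)
  factor <- as.integer(factor)
  if (factor < 1L) stop("factor must be >= 1")
  g <- hr$geometry
  if (max(abs(g$direction - diag(3))) > 1e-9)
    stop("degrade_to_thick expects an axis-aligned thin axial volume")
  ax <- if (axis == "axial") 3L else 2L
  n_in <- g$size[ax]
  n_out <- n_in %/% factor
  if (n_out < 1L) stop("volume too small along the chosen axis")
  arr <- hr$data
  # block mean along `ax` for the leading n_out * factor slices
  keep <- seq_len(n_out * factor)
  if (ax == 3L) {
    a <- arr[, , keep, drop = FALSE]
    dim(a) <- c(g$size[1] * g$size[2], factor, n_out)
    m <- colMeans(aperm(a, c(2, 1, 3)))
    out <- array(m, c(g$size[1], g$size[2], n_out))
  } else {
    a <- arr[, keep, , drop = FALSE]
    a <- aperm(a, c(2, 1, 3))                    # (y, x, z)
    dim(a) <- c(factor, n_out, g$size[1], g$size[3])
    m <- colMeans(a)                             # (n_out, x, z)
    out <- aperm(array(m, c(n_out, g$size[1], g$size[3])), c(2, 3, 1))  # (x, z, y)
  }
  thick <- factor * g$spacing[ax]
  shift <- (factor - 1) / 2 * g$spacing[ax]
  if (axis == "axial") {
    geom <- volume_geometry(origin = g$origin + c(0, 0, shift),
                            spacing = c(g$spacing[1], g$spacing[2], thick),
                            direction = diag(3),
                            size = c(g$size[1], g$size[2], n_out))
  } else {
    # re-grid: axes become (left-right, inferior-superior, anterior-posterior)
    dir <- cbind(c(1, 0, 0), c(0, 0, 1), c(0, 1, 0))
    geom <- volume_geometry(origin = g$origin + c(0, shift, 0),
                            spacing = c(g$spacing[1], g$spacing[3], thick),
                            direction = dir,
                            size = c(g$size[1], g$size[3], n_out))
  }
  ct_volume(out, geom,
            tags = utils::modifyList(hr$tags %||% list(),
                                     list(SliceThickness = thick)))
}

#' Generate a thin-axial / thick-axial / thick-coronal phantom triplet
#'
#' Both thick series (5 mm by default, from `thick_mm`) are derived from the
#' same high-resolution phantom, so the triplet passes [validate_triplet()]
#' by construction.
#'
#' @param spec A [phantom_spec()] with (near-)1 mm thin spacing.
#' @param thick_mm Thick-series thickness/interval (mm); must be an integer
#'   multiple of the thin spacing.
#' @return A list with elements `thin_axial`, `thick_axial`, `thick_coronal`.
#' @export
make_triplet <- function(spec = phantom_spec(), thick_mm = 5) {
  hr <- make_phantom_hr(spec)
  fz <- thick_mm / spec$spacing[3]
  fy <- thick_mm / spec$spacing[2]
  if (abs(fz - round(fz)) > 1e-9 || abs(fy - round(fy)) > 1e-9)
    stop("thick_mm must be an integer multiple of the thin spacing")
  list(thin_axial = hr,
       thick_axial = degrade_to_thick(hr, "axial", round(fz)),
       thick_coronal = degrade_to_thick(hr, "coronal", round(fy)))
}
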