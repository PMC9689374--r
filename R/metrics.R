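# ROI-aware image quality: PSNR and SSIM between a reconstructed volume and
# the thin-slice ground truth, over the whole image, the body-area bounding
# box and the lung-fields bounding box.

#' Peak signal-to-noise ratio
#'
#' `10 * log10(data_range^2 / MSE)`. Identical inputs (zero MSE) report the
#' sentinel cap of 100 dB; values above the cap are clipped to it.
#'
#' @param ref,test Numeric arrays of identical shape.
#' @param data_range Dynamic range of the data (default: the 4095 HU
#'   normalization-window width, for comparability across cases).
#' @return PSNR in dB.
#' @export
psnr <- function(ref, test, data_range = 4095) {
  if (!identical(dim(ref) %||% length(ref), dim(test) %||% length(test)))
    stop("shape mismatch between ref and test")
  stopifnot(data_range > 0)
  mse <- mean((as.numeric(ref) - as.numeric(test))^2)
  if (mse == 0) return(100)
  min(10 * log10(data_range^2 / mse), 100)
}

.gauss_kernel_1d <- function(size = 11L, sigma = 1.5) {
  r <- (size - 1) / 2
  g <- exp(-((-r):r)^2 / (2 * sigma^2))
  g / sum(g)
}

.valid_filter_2d <- function(x, g) {
  # separable Gaussian filtering, valid mode: G_r %*% x %*% t(G_c)
  k <- length(g)
  band <- function(n) {
    m <- matrix(0, n - k + 1L, n)
    for (i in seq_len(n - k + 1L)) m[i, i:(i + k - 1L)] <- g
    m
  }
  band(nrow(x)) %*% x %*% t(band(ncol(x)))
}

.ssim_2d <- function(ref, test, data_range, size = 11L, sigma = 1.5,
                     K1 = 0.01, K2 = 0.03) {
  if (nrow(ref) < size || ncol(ref) < size)
    stop("SSIM window larger than image")
  g <- .gauss_kernel_1d(size, sigma)
  C1 <- (K1 * data_range)^2
  C2 <- (K2 * data_range)^2
  mu1 <- .valid_filter_2d(ref, g)
  mu2 <- .valid_filter_2d(test, g)
  s11 <- .valid_filter_2d(ref * ref, g) - mu1^2
  s22 <- .valid_filter_2d(test * test, g) - mu2^2
  s12 <- .valid_filter_2d(ref * test, g) - mu1 * mu2
  num <- (2 * mu1 * mu2 + C1) * (2 * s12 + C2)
  den <- (mu1^2 + mu2^2 + C1) * (s11 + s22 + C2)
  mean(num / den)
}

#' Structural similarity index
#'
#' Mean local SSIM with an 11 x 11 Gaussian window (sigma 1.5) and stability
#' constants `K1 = 0.01`, `K2 = 0.03` on the data range; windows are taken in
#' valid mode (fully inside the image). 3D inputs are scored per slice along
#' the third axis and averaged.
#'
#' @inheritParams psnr
#' @return SSIM in \[-1, 1\] (1 iff the images are identical).
#' @export
ssim <- function(ref, test, data_range = 4095) {
  if (!identical(dim(ref), dim(test))) stop("shape mismatch between ref and test")
  if (is.matrix(ref)) return(.ssim_2d(ref, test, data_range))
  stopifnot(length(dim(ref)) == 3)
  mean(vapply(seq_len(dim(ref)[3]),
              function(k) .ssim_2d(ref[, , k], test[, , k], data_range), 0))
}

# --- 3D connected components by iterative label propagation ---------------

.label_components <- function(mask) {
  d <- dim(mask)
  lab <- array(Inf, d)
  lab[mask] <- which(mask)
  shift_min <- function(l) {
    n1 <- d[1]; n2 <- d[2]; n3 <- d[3]
    l[1:(n1 - 1), , ] <- pmin(l[1:(n1 - 1), , ], l[2:n1, , ])
    l[2:n1, , ] <- pmin(l[2:n1, , ], l[1:(n1 - 1), , ])
    l[, 1:(n2 - 1), ] <- pmin(l[, 1:(n2 - 1), ], l[, 2:n2, ])
    l[, 2:n2, ] <- pmin(l[, 2:n2, ], l[, 1:(n2 - 1), ])
    l[, , 1:(n3 - 1)] <- pmin(l[, , 1:(n3 - 1)], l[, , 2:n3])
    l[, , 2:n3] <- pmin(l[, , 2:n3], l[, , 1:(n3 - 1)])
    l[!mask] <- Inf
    l
  }
  repeat {
    nl <- shift_min(lab)
    if (identical(nl, lab)) break
    lab <- nl
  }
  lab[!mask] <- 0
  lab
}

.fill_holes <- function(mask) {
  bg <- !mask
  lab <- .label_components(bg)
  d <- dim(mask)
  border <- unique(c(lab[c(1, d[1]), , ], lab[, c(1, d[2]), ], lab[, , c(1, d[3])]))
  border <- border[border > 0]
  mask | (bg & !(lab %in% border))
}

.bbox <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  list(min = apply(idx, 2, min), max = apply(idx, 2, max))
}

#' ROI bounding box
#'
#' @param label One of `"whole-DICOM"`, `"body-area"`, `"lung-fields"`.
#' @param bounds List with `min` and `max` inclusive 1-based voxel indices.
#' @return Object of class `roi_box`.
#' @export
roi_box <- function(label, bounds) {
  structure(list(label = label, min = as.integer(bounds$min),
                 max = as.integer(bounds$max)), class = "roi_box")
}

.crop_box <- function(arr, box) {
  arr[box$min[1]:box$max[1], box$min[2]:box$max[2], box$min[3]:box$max[3],
      drop = FALSE]
}

#' Segment body-area and lung-fields bounding boxes
#'
#' Body: largest connected component of HU > -500, holes filled, tight 3D
#' bounding box. Lung: connected components of HU < -320 inside the body
#' mask, excluding components touching the volume border, keeping the two
#' largest; bounding box of their union. Thresholds follow common chest-CT
#' practice.
#'
#' @param hr A [ct_volume()] in Hounsfield units (ROIs are always derived
#'   from the ground-truth volume).
#' @return List with `body` and `lung` [roi_box()] objects.
#' @export
segment_rois <- function(hr) {
  a <- if (inherits(hr, "ct_volume")) hr$data else hr
  body_raw <- a > -500
  if (!any(body_raw)) stop("empty scan: no body component found")
  lab <- .label_components(body_raw)
  tab <- table(lab[lab > 0])
  keep <- as.numeric(names(tab)[which.max(tab)])
  body <- .fill_holes(lab == keep)
  lung_raw <- (a < -320) & body
  lung_box <- NULL
  if (any(lung_raw)) {
    lab_l <- .label_components(lung_raw)
    d <- dim(a)
    border <- unique(c(lab_l[c(1, d[1]), , ], lab_l[, c(1, d[2]), ],
                       lab_l[, , c(1, d[3])]))
    sizes <- table(lab_l[lab_l > 0])
    sizes <- sizes[!(as.numeric(names(sizes)) %in% border)]
    if (length(sizes) > 0) {
      keep_l <- as.numeric(names(sort(sizes, decreasing = TRUE)))[
        seq_len(min(2, length(sizes)))]
      lung_box <- roi_box("lung-fields", .bbox(array(lab_l %in% keep_l, dim(a))))
    }
  }
  body_box <- roi_box("body-area", .bbox(body))
  if (is.null(lung_box)) stop("no lung component found inside the body")
  list(body = body_box, lung = lung_box)
}

#' Per-case ROI-aware quality record
#'
#' Computes PSNR and SSIM per axial slice and averages over slices, for the
#' whole volume and for the body-area and lung-fields bounding boxes derived
#' from the ground truth.
#'
#' @param hr Ground-truth [ct_volume()].
#' @param test Reconstructed [ct_volume()] on the same geometry.
#' @param case_id Case identifier recorded in the output.
#' @param condition Condition label (e.g. `"LR"` or `"EDSR-sagittal"`).
#' @param data_range Dynamic range for both metrics.
#' @param rois Optionally precomputed output of [segment_rois()].
#' @return A tibble with one row per ROI: `case_id`, `condition`, `roi`,
#'   `psnr`, `ssim`.
#' @export
evaluate_case <- function(hr, test, case_id = "case", condition = "test",
                          data_range = 4095, rois = NULL) {
  if (!identical(hr$geometry$size, test$geometry$size))
    stop("hr and test volumes differ in size")
  rois <- rois %||% segment_rois(hr)
  d <- dim(hr$data)
  boxes <- list(
    `whole-DICOM` = roi_box("whole-DICOM", list(min = c(1, 1, 1), max = d)),
    `body-area` = rois$body,
    `lung-fields` = rois$lung)
  rows <- lapply(names(boxes), function(lbl) {
    b <- boxes[[lbl]]
    r <- .crop_box(hr$data, b); t <- .crop_box(test$data, b)
    ks <- seq_len(dim(r)[3])
    ps <- vapply(ks, function(k) psnr(r[, , k], t[, , k], data_range), 0)
    ss <- vapply(ks, function(k) .ssim_2d(r[, , k], t[, , k], data_range), 0)
    tibble::tibble(case_id = case_id, condition = condition, roi = lbl,
                   psnr = mean(ps), ssim = mean(ss))
  })
  dplyr::bind_rows(rows)
}

#' Boxplot of per-case quality records
#'
#' @param object A tibble of quality records ([evaluate_case()] rows).
#' @param metric `"psnr"` or `"ssim"`.
#' @param ... Unused.
#' @return A ggplot object: one box per condition, faceted by ROI.
#' @method autoplot quality_records
#' @export
autoplot.quality_records <- function(object, metric = c("psnr", "ssim"), ...) {
  metric <- match.arg(metric)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$condition, y = .data[[metric]])) +
    ggplot2::geom_boxplot(outlier.size = 0.7) +
    ggplot2::facet_wrap(~roi, scales = "free_y") +
    ggplot2::labs(x = NULL, y = toupper(metric)) +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @rdname autoplot.quality_records
#' @param records Quality-record tibble to plot.
#' @export
plot_quality <- function(records, metric = c("psnr", "ssim")) {
  class(records) <- c("quality_records", class(records))
  autoplot.quality_records(records, metric)
}
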