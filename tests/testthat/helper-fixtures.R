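# Shared fixtures and independent brute-force oracles.

# small phantom (1 mm grid) sized so lung/body boxes stay >= the SSIM window
tiny_spec <- function(seed = 1L) {
  phantom_spec(size = c(48, 48, 30), body_axes = c(20, 17),
               lung_axes = c(7, 8, 8),
               lung_offsets = rbind(c(-9.5, -1.5, 0), c(9.5, -1.5, 0)),
               n_vessels = 4L, n_nodules = 2L, seed = seed)
}

# even smaller phantom for voxel-loop oracles
micro_spec <- function(seed = 1L) {
  phantom_spec(size = c(24, 24, 15), body_axes = c(10, 8.5),
               lung_axes = c(3.5, 4, 4),
               lung_offsets = rbind(c(-4.75, -0.75, 0), c(4.75, -0.75, 0)),
               n_vessels = 2L, n_nodules = 1L, seed = seed)
}

make_case <- function(seed = 1L, spec_fn = tiny_spec) {
  trip <- make_triplet(spec_fn(seed))
  fr <- fuse_series(trip$thick_axial, trip$thick_coronal,
                    trip$thin_axial$geometry)
  list(hr = trip$thin_axial, lr = fr$lr, triplet = trip, fusion = fr)
}

# scalar trilinear interpolation of one world point, NA outside the
# voxel-centre hull (independent of the vectorised implementation)
trilinear_at <- function(vol, xyz) {
  g <- vol$geometry
  p <- as.vector(solve(g$direction, xyz - g$origin) / g$spacing)
  n <- g$size
  if (any(p < -1e-9) || any(p > n - 1 + 1e-9)) return(NA_real_)
  p <- pmin(pmax(p, 0), n - 1)
  i0 <- pmin(floor(p), pmax(n - 2, 0)); f <- p - i0
  acc <- 0
  for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
    w <- (if (di) f[1] else 1 - f[1]) * (if (dj) f[2] else 1 - f[2]) *
         (if (dk) f[3] else 1 - f[3])
    acc <- acc + w * vol$data[min(i0[1] + di, n[1] - 1) + 1,
                              min(i0[2] + dj, n[2] - 1) + 1,
                              min(i0[3] + dk, n[3] - 1) + 1]
  }
  acc
}

# brute-force per-voxel fusion oracle: loop every target voxel
fuse_oracle <- function(thick_axial, thick_coronal, target, fill = -1000) {
  n <- target$size
  out <- array(fill, n)
  for (k in seq_len(n[3])) for (j in seq_len(n[2])) for (i in seq_len(n[1])) {
    w <- voxel_to_world(target, c(i - 1, j - 1, k - 1))
    va <- trilinear_at(thick_axial, w)
    vc <- trilinear_at(thick_coronal, w)
    out[i, j, k] <-
      if (!is.na(va) && !is.na(vc)) (va + vc) / 2
      else if (!is.na(va)) va
      else if (!is.na(vc)) vc
      else fill
  }
  out
}

psnr_oracle <- function(ref, test, data_range) {
  mse <- sum((ref - test)^2) / length(ref)
  10 * log10(data_range^2 / mse)
}

# direct per-window SSIM: explicit loops over window positions
ssim_oracle <- function(ref, test, data_range, size = 11L, sigma = 1.5,
                        K1 = 0.01, K2 = 0.03) {
  r <- (size - 1) / 2
  g1 <- exp(-((-r):r)^2 / (2 * sigma^2)); g1 <- g1 / sum(g1)
  w <- outer(g1, g1)
  C1 <- (K1 * data_range)^2; C2 <- (K2 * data_range)^2
  vals <- c()
  for (i in seq_len(nrow(ref) - size + 1)) {
    for (j in seq_len(ncol(ref) - size + 1)) {
      a <- ref[i:(i + size - 1), j:(j + size - 1)]
      b <- test[i:(i + size - 1), j:(j + size - 1)]
      mu1 <- sum(w * a); mu2 <- sum(w * b)
      s1 <- sum(w * a^2) - mu1^2
      s2 <- sum(w * b^2) - mu2^2
      s12 <- sum(w * a * b) - mu1 * mu2
      vals <- c(vals, ((2 * mu1 * mu2 + C1) * (2 * s12 + C2)) /
                        ((mu1^2 + mu2^2 + C1) * (s1 + s2 + C2)))
    }
  }
  mean(vals)
}

# exhaustive one-sided signed-rank p-value over all 2^n sign assignments
wilcoxon_enum <- function(x, y) {
  d <- (x - y); d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  count <- 0L
  for (mask in 0:(2^n - 1)) {
    signs <- as.logical(bitwAnd(mask, bitwShiftL(1L, 0:(n - 1))))
    if (sum(r[signs]) >= W - 1e-9) count <- count + 1L
  }
  count / 2^n
}

# short desk-scale training profile used in network/learning tests
short_config <- function(arch, epochs = 3L, seed = 5L) {
  train_config(arch, patch_size = 24L, batch_size = 4L,
               batches_per_epoch = 8L, total_epochs = epochs,
               learning_rate = 1e-3, plane = "sagittal", seed = seed)
}
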