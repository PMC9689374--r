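test_that("exact signed-rank p-values match exhaustive sign enumeration", {
  set.seed(101)
  for (rep in 1:8) {
    n <- sample(5:12, 1)
    x <- rnorm(n)
    y <- rnorm(n)
    expect_equal(wilcoxon_one_sided(x, y), wilcoxon_enum(x, y),
                 tolerance = 1e-12)
  }
  # tied absolute differences (midranks) and zero differences
  for (rep in 1:8) {
    n <- sample(6:11, 1)
    x <- sample(-3:3, n, replace = TRUE) / 2
    y <- numeric(n)
    expect_equal(wilcoxon_one_sided(x, y), wilcoxon_enum(x, y),
                 tolerance = 1e-12)
  }
})

test_that("untied exact p-values agree with the base-R reference", {
  set.seed(55)
  for (rep in 1:6) {
    n <- sample(6:20, 1)
    x <- rnorm(n); y <- rnorm(n)
    ref <- stats::wilcox.test(x, y, paired = TRUE, alternative = "greater",
                              exact = TRUE)$p.value
    expect_equal(wilcoxon_one_sided(x, y), ref, tolerance = 1e-12)
  }
})

test_that("degenerate and directional properties hold", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(wilcoxon_one_sided(x, x), 1)            # all-zero differences
  set.seed(77)
  a <- rnorm(10); b <- rnorm(10)
  # midrank convention: one-sided p of each direction sums to >= 1
  expect_gte(wilcoxon_one_sided(a, b) + wilcoxon_one_sided(b, a), 1)
  # monotonicity: appending a positive difference never increases the p
  # favouring x
  for (rep in 1:10) {
    x1 <- rnorm(8); y1 <- rnorm(8)
    p0 <- wilcoxon_one_sided(x1, y1)
    p1 <- wilcoxon_one_sided(c(x1, 10 + rep), c(y1, 1))
    expect_lte(p1, p0 + 1e-12)
  }
})

test_that("Bonferroni thresholds reproduce the published family corrections", {
  expect_equal(signif(bonferroni_threshold(78, 0.05), 3), 6.41e-4)
  expect_equal(signif(bonferroni_threshold(45, 0.05), 3), 1.11e-3)
  expect_equal(bonferroni_threshold(1, 0.05), 0.05)
  expect_error(bonferroni_threshold(0))
})

fake_records <- function(conditions, n_cases = 22, seed = 1) {
  set.seed(seed)
  rois <- c("whole-DICOM", "body-area", "lung-fields")
  grid <- expand.grid(case_id = sprintf("c%02d", seq_len(n_cases)),
                      condition = conditions, roi = rois,
                      stringsAsFactors = FALSE)
  grid$psnr <- 30 + as.integer(factor(grid$condition)) + rnorm(nrow(grid))
  grid$ssim <- 0.8 + 0.01 * as.integer(factor(grid$condition)) +
    rnorm(nrow(grid), 0, 0.01)
  tibble::as_tibble(grid)
}

test_that("plane-mode matrices evaluate all 78 pairs of 13 conditions", {
  conds <- c("LR", paste(rep(c("SRCNN", "VDSR", "SRResNet", "EDSR"), each = 3),
                         c("axial", "coronal", "sagittal"), sep = "-"))
  rec <- fake_records(conds)
  cm <- comparison_matrix(rec, metric = "psnr", mode = "plane")
  expect_equal(cm$n_comparisons, choose(13, 2))
  expect_equal(cm$n_comparisons, 78L)
  expect_equal(cm$threshold, 0.05 / 78)
  expect_true(all(cm$pairs$p > 0 & cm$pairs$p <= 1))
  # one-sided convention: cell (i, j) only for i before j; (j, i) absent
  idx <- function(v) match(v, cm$conditions)
  expect_true(all(idx(cm$pairs$row) < idx(cm$pairs$col)))
  expect_equal(nrow(dplyr::distinct(cm$pairs[, c("row", "col")])), 78L)
  expect_equal(sum(tidy(cm)$significant), sum(cm$pairs$p < cm$threshold))
})

test_that("roi-mode matrices evaluate only the 45 shared-method/ROI pairs", {
  conds <- c("LR", "SRCNN", "VDSR", "SRResNet", "EDSR")
  rec <- fake_records(conds)
  cm <- comparison_matrix(rec, metric = "ssim", mode = "roi")
  # 5 methods x C(3,2) ROI pairs + 3 ROIs x C(5,2) method pairs
  expect_equal(cm$n_comparisons, 5 * choose(3, 2) + 3 * choose(5, 2))
  expect_equal(cm$n_comparisons, 45L)
  expect_equal(cm$threshold, 0.05 / 45)
  split_lab <- function(v) do.call(rbind, strsplit(v, " | ", fixed = TRUE))
  a <- split_lab(cm$pairs$row); b <- split_lab(cm$pairs$col)
  expect_true(all(a[, 1] == b[, 1] | a[, 2] == b[, 2]))
})

test_that("missing case values are reported by case and condition", {
  rec <- fake_records(c("LR", "EDSR-sagittal"), n_cases = 6)
  rec <- rec[!(rec$case_id == "c03" & rec$condition == "EDSR-sagittal"), ]
  expect_error(comparison_matrix(rec, "psnr", "plane"), "c03.*EDSR-sagittal")
})
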