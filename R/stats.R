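# One-sided Wilcoxon signed-rank comparisons with Bonferroni correction.
# The exact null distribution is computed by a generating-function dynamic
# program over doubled midranks, so ties are handled exactly (base R's
# wilcox.test falls back to a normal approximation under ties).

#' One-sided Wilcoxon signed-rank test
#'
#' Tests the alternative that `x` exceeds `y` in paired samples. Zero
#' differences are dropped before ranking and tied absolute differences get
#' midranks. For `n <= exact_max` remaining pairs, the p-value is exact: the
#' signed-rank statistic `W` (sum of ranks of positive differences) is
#' compared against its full conditional null distribution over all `2^n`
#' sign assignments, computed by convolution over doubled midranks. Larger
#' samples use the normal approximation with continuity and tie correction.
#' All-zero differences yield `p = 1`.
#'
#' @param x,y Paired numeric vectors of equal length.
#' @param exact_max Largest `n` for which the exact distribution is used.
#' @return One-sided p-value in (0, 1].
#' @export
wilcoxon_one_sided <- function(x, y, exact_max = 25L) {
  stopifnot(length(x) == length(y))
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= exact_max) {
    r2 <- as.integer(round(2 * r))        # doubled midranks are integers
    total <- sum(r2)
    counts <- numeric(total + 1L)         # counts[s + 1] = #assignments with sum s
    counts[1L] <- 1
    for (rv in r2) {
      shifted <- c(numeric(rv), counts[seq_len(total + 1L - rv)])
      counts <- counts + shifted
    }
    w2 <- round(2 * W)
    p <- sum(counts[(w2 + 1L):(total + 1L)]) / 2^n
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (W - mu - 0.5) / sqrt(sigma2)
    p <- stats::pnorm(z, lower.tail = FALSE)
  }
  min(max(p, .Machine$double.xmin), 1)
}

#' Bonferroni-corrected significance threshold
#'
#' @param n_comparisons Number of evaluated pairwise comparisons.
#' @param alpha Family-wise significance level.
#' @return `alpha / n_comparisons`.
#' @export
bonferroni_threshold <- function(n_comparisons, alpha = 0.05) {
  stopifnot(n_comparisons >= 1, alpha > 0, alpha < 1)
  alpha / n_comparisons
}

#' Pairwise one-sided comparison matrix across conditions
#'
#' Builds the upper-triangular matrix of one-sided signed-rank p-values, each
#' cell testing "the row condition exceeds the column condition" on paired
#' per-case metric values, with the Bonferroni threshold for the evaluated
#' family.
#'
#' Two families are supported. `mode = "plane"` compares all unordered pairs
#' among the condition labels (e.g. LR plus 4 models x 3 planes = 13
#' conditions, 78 pairs), using the whole-image ROI. `mode = "roi"` crosses
#' each condition label with the three ROIs (e.g. LR plus 4 models = 15
#' method-ROI conditions) and evaluates only pairs sharing the method or
#' sharing the ROI (45 pairs); cross-method-cross-ROI cells are absent, not
#' zero.
#'
#' @param records Quality-record tibble ([evaluate_case()] rows) with columns
#'   `case_id`, `condition`, `roi`, and the metric columns.
#' @param metric `"psnr"` or `"ssim"`.
#' @param mode `"plane"` or `"roi"`.
#' @param alpha Family-wise level for the Bonferroni threshold.
#' @param roi ROI used in plane mode (default whole image).
#' @return An object of class `comparison_matrix`: list with `pairs` (tibble:
#'   row, col, p), `conditions`, `threshold`, `n_comparisons`, `alpha`,
#'   `metric`, `mode`.
#' @export
comparison_matrix <- function(records, metric = c("psnr", "ssim"),
                              mode = c("plane", "roi"), alpha = 0.05,
                              roi = "whole-DICOM") {
  metric <- match.arg(metric)
  mode <- match.arg(mode)
  if (mode == "plane") {
    df <- dplyr::filter(records, .data$roi == !!roi)
    df$label <- df$condition
  } else {
    df <- records
    df$label <- paste(df$condition, df$roi, sep = " | ")
  }
  conditions <- unique(df$label)
  cases <- unique(df$case_id)
  # every condition must have a value for every case
  vals <- lapply(conditions, function(cond) {
    sub <- df[df$label == cond, ]
    v <- sub[[metric]][match(cases, sub$case_id)]
    if (anyNA(v))
      stop(sprintf("missing value for case '%s' under condition '%s'",
                   cases[which(is.na(v))[1]], cond))
    v
  })
  names(vals) <- conditions
  share_family <- function(a, b) {
    if (mode == "plane") return(TRUE)
    pa <- strsplit(a, " | ", fixed = TRUE)[[1]]
    pb <- strsplit(b, " | ", fixed = TRUE)[[1]]
    pa[1] == pb[1] || pa[2] == pb[2]
  }
  rows <- list()
  for (i in seq_along(conditions)) {
    for (j in seq_along(conditions)) {
      if (j <= i) next
      if (!share_family(conditions[i], conditions[j])) next
      rows[[length(rows) + 1L]] <- tibble::tibble(
        row = conditions[i], col = conditions[j],
        p = wilcoxon_one_sided(vals[[i]], vals[[j]]))
    }
  }
  pairs <- dplyr::bind_rows(rows)
  structure(list(pairs = pairs, conditions = conditions,
                 n_comparisons = nrow(pairs),
                 threshold = bonferroni_threshold(nrow(pairs), alpha),
                 alpha = alpha, metric = metric, mode = mode),
            class = "comparison_matrix")
}

#' @export
print.comparison_matrix <- function(x, ...) {
  cat(sprintf("<comparison_matrix> %s, %s mode: %d conditions, %d comparisons\n",
              toupper(x$metric), x$mode, length(x$conditions), x$n_comparisons))
  cat(sprintf("  Bonferroni threshold (alpha %.3g): %.3g\n", x$alpha, x$threshold))
  cat(sprintf("  significant (row better than column): %d\n",
              sum(x$pairs$p < x$threshold)))
  invisible(x)
}

#' @rdname comparison_matrix_tidiers
#' @method tidy comparison_matrix
#' @export
tidy.comparison_matrix <- function(x, ...) {
  dplyr::mutate(x$pairs, significant = .data$p < x$threshold)
}

#' Tidiers for comparison matrices
#'
#' `tidy()` returns one row per evaluated pair with the one-sided p-value and
#' significance under the Bonferroni threshold; `glance()` a one-row summary.
#'
#' @param x A `comparison_matrix`.
#' @param ... Unused.
#' @name comparison_matrix_tidiers
#' @method glance comparison_matrix
#' @export
glance.comparison_matrix <- function(x, ...) {
  tibble::tibble(metric = x$metric, mode = x$mode,
                 n_conditions = length(x$conditions),
                 n_comparisons = x$n_comparisons,
                 threshold = x$threshold,
                 n_significant = sum(x$pairs$p < x$threshold))
}

#' Tile plot of a comparison matrix
#'
#' @param object A `comparison_matrix`.
#' @param ... Unused.
#' @return A ggplot object; tiles show -log10 p with significant cells marked.
#' @method autoplot comparison_matrix
#' @export
autoplot.comparison_matrix <- function(object, ...) {
  df <- tidy(object)
  df$row <- factor(df$row, levels = object$conditions)
  df$col <- factor(df$col, levels = object$conditions)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = -log10(.data$p))) +
    ggplot2::geom_tile() +
    ggplot2::geom_point(data = df[df$significant, ], size = 1) +
    ggplot2::scale_fill_viridis_c(name = "-log10 p") +
    ggplot2::labs(x = "worse condition", y = "better condition",
                  subtitle = sprintf("one-sided signed-rank, threshold %.3g",
                                     object$threshold)) +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
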