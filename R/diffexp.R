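# Pooled-variance two-sample Student t-test on two numeric vectors.
# Conventions: zero pooled variance with equal means -> t = 0, p = 1;
# zero pooled variance with unequal means -> t = +/-Inf, p = 0.
pooled_ttest2 <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  if (n1 < 2 || n2 < 2) stop("t-test needs at least 2 values per class")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) / df
  d <- mean(a) - mean(b)
  if (sp2 == 0) {
    if (d == 0) return(list(t = 0, p = 1, df = df))
    return(list(t = sign(d) * Inf, p = 0, df = df))
  }
  t <- d / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, p = 2 * stats::pt(-abs(t), df), df = df)
}

# tumor-vs-benign wrapper used throughout the pipeline
pooled_ttest <- function(x, labels) {
  labels <- check_class_labels(labels)
  pooled_ttest2(x[labels == "tumor"], x[labels == "benign"])
}

#' Two-sided Student t-test for one spot
#'
#' Pooled-variance (classical Student) two-sample t-test of tumor vs benign
#' log2 expression, with `df = n1 + n2 - 2`.
#'
#' @param x numeric vector of log2 expression for one feature.
#' @param labels "tumor"/"benign" per value.
#' @return A list `t`, `p`, `df`.
#' @export
spot_ttest <- function(x, labels) pooled_ttest(x, labels)

#' Fold change of one spot
#'
#' On the default `scale = "log"`, the fold change is
#' `2^(mean_tumor - mean_benign)` of the log2 values, i.e. the ratio of
#' geometric means of the normalized volumes. `scale = "raw"` instead takes
#' the ratio of arithmetic means of the back-transformed ratios.
#'
#' @param x numeric vector of log2 expression for one feature.
#' @param labels "tumor"/"benign" per value.
#' @param scale "log" (geometric means, default) or "raw".
#' @return Positive fold change (tumor over benign).
#' @export
fold_change <- function(x, labels, scale = c("log", "raw")) {
  scale <- match.arg(scale)
  labels <- check_class_labels(labels)
  a <- x[labels == "tumor"]; b <- x[labels == "benign"]
  if (scale == "log") 2^(mean(a) - mean(b)) else mean(2^a) / mean(2^b)
}

#' Spot-wise differential expression table
#'
#' Per-feature class means, fold change, pooled t statistic, raw two-sided
#' p, and the significance flag `(fold >= min_fold or fold <= 1/min_fold)
#' and p < alpha`. No multiple-testing correction is applied: the filter is
#' deliberately on raw p-values.
#'
#' @param em an [expression_matrix()].
#' @param alpha significance level on the raw p-value (default 0.05).
#' @param min_fold fold-change filter (default 1.5, either direction;
#'   boundary included).
#' @param fold_scale passed to [fold_change()].
#' @return A data.frame `feature`, `mean_tumor`, `mean_benign`, `fold`,
#'   `t`, `p`, `significant`, in input feature order.
#' @export
diffexp <- function(em, alpha = 0.05, min_fold = 1.5,
                    fold_scale = c("log", "raw")) {
  fold_scale <- match.arg(fold_scale)
  labels <- em$class
  res <- lapply(seq_len(nrow(em$values)), function(i) {
    x <- em$values[i, ]
    tt <- pooled_ttest(x, labels)
    data.frame(feature = rownames(em$values)[i],
               mean_tumor = mean(x[labels == "tumor"]),
               mean_benign = mean(x[labels == "benign"]),
               fold = fold_change(x, labels, fold_scale),
               t = tt$t, p = tt$p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$significant <- (res$fold >= min_fold | res$fold <= 1 / min_fold) &
    res$p < alpha
  res
}

#' Filter and sort significant spots
#'
#' @param results data.frame from [diffexp()].
#' @param alpha,min_fold filter thresholds (re-applied here so the function
#'   is usable on raw result tables).
#' @return The significant rows sorted by p ascending.
#' @export
significant_spots <- function(results, alpha = 0.05, min_fold = 1.5) {
  sig <- (results$fold >= min_fold | results$fold <= 1 / min_fold) &
    results$p < alpha
  out <- results[sig, , drop = FALSE]
  out[order(out$p), , drop = FALSE]
}
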