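#' Average-linkage clustering of samples
#'
#' UPGMA (agglomeration method "average") on Euclidean distances between
#' sample profiles, the unsupervised clustering used to look for sample
#' structure in the log-expression data. Typically run on the significant
#' features only.
#'
#' @param em an [expression_matrix()].
#' @param features optional character vector of feature ids to cluster on
#'   (e.g. the significant spots); default all.
#' @return A list of class `dige_dendrogram`: `hclust` (a [stats::hclust]
#'   object), `newick` (Newick serialization with sample ids as leaf
#'   names).
#' @export
hclust_average <- function(em, features = NULL) {
  m <- em$values
  if (!is.null(features)) {
    missing <- setdiff(features, rownames(m))
    if (length(missing)) stop("unknown features: ",
                              paste(missing, collapse = ", "))
    m <- m[features, , drop = FALSE]
  }
  if (ncol(m) < 2) stop("clustering needs at least 2 samples")
  hc <- stats::hclust(stats::dist(t(m), method = "euclidean"),
                      method = "average")
  structure(list(hclust = hc,
                 newick = ape::write.tree(ape::as.phylo(hc))),
            class = "dige_dendrogram")
}

#' Single-feature partition classifier (decision stump)
#'
#' Finds the threshold on one feature that best separates tumor from benign
#' samples: candidate cuts are midpoints between consecutive distinct
#' sorted values, both orientations ("high predicts tumor" and "low
#' predicts tumor") are considered, ties are broken toward the lower
#' threshold (and toward the high-predicts-tumor orientation). The best
#' rule's 2x2 confusion table is tested with Fisher's exact test.
#'
#' @param x numeric vector, one feature's expression.
#' @param labels "tumor"/"benign" per value.
#' @return A list: `threshold`, `orientation` ("high" or "low" side
#'   predicting tumor), `confusion` (2x2, actual x predicted), `accuracy`,
#'   `fisher_p`, `degenerate`.
#' @export
single_feature_partition <- function(x, labels) {
  labels <- check_class_labels(labels)
  if (!any(labels == "tumor") || !any(labels == "benign"))
    stop("both classes must be present")
  n <- length(x)
  v <- sort(unique(x))
  confusion_of <- function(pred) {
    table(factor(labels, levels = c("tumor", "benign")),
          factor(ifelse(pred, "tumor", "benign"),
                 levels = c("tumor", "benign")))
  }
  if (length(v) < 2) {
    # constant feature: majority-class rule, flagged degenerate
    maj <- names(which.max(table(labels)))
    conf <- confusion_of(rep(maj == "tumor", n))
    return(list(threshold = NA_real_, orientation = NA_character_,
                confusion = conf, accuracy = max(table(labels)) / n,
                fisher_p = fisher_exact_2x2(conf), degenerate = TRUE))
  }
  cuts <- (v[-1] + v[-length(v)]) / 2
  best <- NULL
  for (orient in c("high", "low")) {
    for (thr in cuts) {
      pred <- if (orient == "high") x > thr else x < thr
      acc <- mean((labels == "tumor") == pred)
      better <- is.null(best) || acc > best$accuracy + 1e-12 ||
        (abs(acc - best$accuracy) <= 1e-12 && thr < best$threshold - 1e-12)
      if (better) best <- list(threshold = thr, orientation = orient,
                               accuracy = acc)
    }
  }
  pred <- if (best$orientation == "high") x > best$threshold else x < best$threshold
  conf <- confusion_of(pred)
  list(threshold = best$threshold, orientation = best$orientation,
       confusion = conf, accuracy = best$accuracy,
       fisher_p = fisher_exact_2x2(conf), degenerate = FALSE)
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided exact test by the probability-mass rule: with margins fixed,
#' the p-value sums the hypergeometric probabilities of all tables whose
#' probability does not exceed that of the observed table (within a 1e-7
#' relative slack for floating-point ties). Any zero margin gives p = 1 by
#' convention.
#'
#' @param tab 2x2 matrix (or table) of non-negative integer counts.
#' @return Two-sided p-value in (0, 1\].
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  storage.mode(tab) <- "double"
  if (!identical(dim(tab), c(2L, 2L)) || any(tab < 0) ||
      any(tab != round(tab)))
    stop("need a 2x2 table of non-negative integers")
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1]); c2 <- sum(tab[, 2])
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) return(1)
  n <- r1 + r2
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(support, r1, r2, c1)
  p_obs <- stats::dhyper(tab[1, 1], r1, r2, c1)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}
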