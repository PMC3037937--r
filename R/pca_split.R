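#' Principal component analysis of an expression matrix
#'
#' Samples are observations and features (spots) are variables. Each
#' feature is centered across samples; no unit-variance scaling is applied
#' (values are already on a comparable log2 scale). Components come from
#' the singular value decomposition of the centered matrix. The sign of
#' each component is fixed so that the largest-magnitude entry of its score
#' vector is positive, which makes results reproducible across linear
#' algebra backends.
#'
#' @param em an [expression_matrix()] (or plain features x samples matrix
#'   with dimnames, plus `labels`).
#' @param K number of leading components retained for the S3 subspace
#'   (default 3).
#' @param labels optional class labels when `em` is a plain matrix.
#' @return An object of class `dige_pca`: `center` (per-feature means),
#'   `basis` (features x K left singular vectors), `scores` (samples x K
#'   orthonormal score vectors t_1..t_K spanning S3), `sample_scores`
#'   (samples x K, scaled by the singular values), `evar`
#'   (explained-variance fractions, all components), `K`, `retained`
#'   (sample ids), `outliers`, `class`.
#' @export
fit_pca <- function(em, K = 3, labels = NULL) {
  if (inherits(em, "ExpressionMatrix")) {
    m <- em$values; labels <- em$class
  } else m <- as.matrix(em)
  n <- ncol(m); p <- nrow(m)
  if (!all(is.finite(m))) stop("expression values must be finite")
  if (K >= min(n, p)) stop("K must be smaller than min(n_samples, n_features)")
  if (n < K + 1) stop("need at least K+1 samples")
  center <- rowMeans(m)
  xc <- m - center
  sv <- svd(xc)
  d2 <- sv$d^2
  evar <- if (sum(d2) > 0) d2 / sum(d2) else d2
  u <- sv$u[, seq_len(K), drop = FALSE]
  v <- sv$v[, seq_len(K), drop = FALSE]
  for (k in seq_len(K)) {           # sign convention on the score vectors
    j <- which.max(abs(v[, k]))
    if (v[j, k] < 0) { v[, k] <- -v[, k]; u[, k] <- -u[, k] }
  }
  rownames(u) <- rownames(m)
  rownames(v) <- colnames(m)
  ss <- v %*% diag(sv$d[seq_len(K)], K, K)
  dimnames(ss) <- list(colnames(m), paste0("PC", seq_len(K)))
  colnames(v) <- colnames(u) <- paste0("PC", seq_len(K))
  if (!is.null(labels)) labels <- check_class_labels(labels)
  structure(list(center = center, basis = u, scores = v, sample_scores = ss,
                 evar = evar, K = K, retained = colnames(m),
                 outliers = character(0), class = labels),
            class = "dige_pca")
}

#' Outlier detection on principal-component scores
#'
#' A sample is an outlier iff its robust z-score,
#' `|score - median| / (1.4826 * MAD)`, exceeds 3.5 on any of the first K
#' components. Components with zero MAD are skipped.
#'
#' @param model a fitted [fit_pca()] model.
#' @param cutoff robust z cutoff (default 3.5).
#' @return Character vector of outlier sample ids (possibly empty).
#' @export
detect_outliers <- function(model, cutoff = 3.5) {
  stopifnot(inherits(model, "dige_pca"))
  out <- logical(nrow(model$scores))
  for (k in seq_len(model$K)) {
    # components with (numerically) zero singular value carry arbitrary
    # basis-completion vectors, not data structure: never flag on them
    if (model$evar[k] <= 1e-10) next
    s <- model$scores[, k]
    med <- stats::median(s)
    mad0 <- stats::median(abs(s - med))
    if (mad0 == 0) next
    out <- out | (abs(s - med) / (1.4826 * mad0) > cutoff)
  }
  rownames(model$scores)[out]
}

#' Two-step outlier-robust PCA
#'
#' Fits a PCA on the original data, detects outliers on the component
#' scores, and refits exactly once on the retained samples. The outlier ids
#' are recorded on the returned model.
#'
#' @inheritParams fit_pca
#' @param cutoff robust z cutoff passed to [detect_outliers()].
#' @return A `dige_pca` model fitted on the retained samples.
#' @export
robust_pca <- function(em, K = 3, labels = NULL, cutoff = 3.5) {
  m1 <- fit_pca(em, K = K, labels = labels)
  out <- detect_outliers(m1, cutoff = cutoff)
  if (!length(out)) return(m1)
  if (inherits(em, "ExpressionMatrix")) {
    vals <- em$values; labels <- em$class
  } else vals <- as.matrix(em)
  keep <- setdiff(colnames(vals), out)
  if (length(keep) < K + 1)
    stop("outlier removal leaves fewer than K+1 samples")
  m2 <- fit_pca(vals[, keep, drop = FALSE], K = K,
                labels = if (!is.null(labels)) labels[keep] else NULL)
  m2$outliers <- out
  m2
}

#' Split feature profiles into S3 projection and residual
#'
#' For each feature i, the centered profile is projected onto the span of
#' the first K score vectors (the S3 subspace): `x_p,i` is the feature mean
#' plus that rank-K reconstruction and `x_r,i = x_i - x_p,i` is the part of
#' the profile living in the orthogonal complement CS3. By construction
#' `x_p,i + x_r,i = x_i` exactly and the centered residual is orthogonal to
#' every retained score vector.
#'
#' @param em an [expression_matrix()] (or matrix); only the model's
#'   retained samples are used.
#' @param model a `dige_pca` model fitted on those samples.
#' @return A list of class `dige_decomposition`: `projection` and
#'   `residual` (features x retained-samples matrices), `model`.
#' @export
decompose_profiles <- function(em, model) {
  stopifnot(inherits(model, "dige_pca"))
  m <- if (inherits(em, "ExpressionMatrix")) em$values else as.matrix(em)
  if (!all(model$retained %in% colnames(m)))
    stop("matrix lacks samples the model was fitted on")
  m <- m[, model$retained, drop = FALSE]
  xc <- m - model$center
  tmat <- model$scores                       # n x K, orthonormal columns
  proj <- model$center + (xc %*% tmat) %*% t(tmat)
  structure(list(projection = proj, residual = m - proj, model = model),
            class = "dige_decomposition")
}

#' Component-wise differential-expression t-tests
#'
#' Runs the two-sided pooled-variance t-test per feature on the original
#' profiles, on their S3 projections, and on their CS3 residuals, all over
#' the model's retained samples. Comparing `p_orig` with `p_proj` and
#' `p_resid` shows how much of the differential expression is carried by
#' the first K components.
#'
#' @param dec a [decompose_profiles()] result.
#' @param em the expression matrix the decomposition came from.
#' @param labels optional labels (default: the matrix's class labels).
#' @return A data.frame `feature`, `p_orig`, `p_proj`, `p_resid`.
#' @export
component_ttests <- function(dec, em, labels = NULL) {
  stopifnot(inherits(dec, "dige_decomposition"))
  m <- if (inherits(em, "ExpressionMatrix")) em$values else as.matrix(em)
  if (is.null(labels))
    labels <- if (inherits(em, "ExpressionMatrix")) em$class else dec$model$class
  keep <- dec$model$retained
  if (is.null(names(labels))) {
    if (length(labels) != ncol(m))
      stop("unnamed labels must match the matrix columns")
    names(labels) <- colnames(m)
  }
  labels <- check_class_labels(labels[keep])
  m <- m[, keep, drop = FALSE]
  pval <- function(mat) vapply(seq_len(nrow(mat)), function(i)
    pooled_ttest(mat[i, ], labels)$p, numeric(1))
  data.frame(feature = rownames(m),
             p_orig = pval(m),
             p_proj = pval(dec$projection),
             p_resid = pval(dec$residual),
             stringsAsFactors = FALSE)
}
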