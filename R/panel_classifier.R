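# Core IRLS fit for logistic regression with optional ridge penalty on the
# slopes (never the intercept). X: n x p matrix WITHOUT intercept column.
logit_irls <- function(X, y, lambda = 0, maxit = 100, tol = 1e-10) {
  X <- as.matrix(X)
  Xd <- cbind(1, X)
  p <- ncol(Xd)
  pen <- diag(c(0, rep(lambda, p - 1)), p, p)
  beta <- numeric(p)
  dev_old <- Inf
  converged <- FALSE
  for (it in seq_len(maxit)) {
    eta <- drop(Xd %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    A <- crossprod(Xd, Xd * w) + pen
    bn <- tryCatch(solve(A, crossprod(Xd, w * z)), error = function(e) NULL)
    if (is.null(bn)) break
    beta <- drop(bn)
    eta <- drop(Xd %*% beta)
    mu <- stats::plogis(eta)
    dev <- -2 * sum(y * log(pmax(mu, 1e-300)) +
                      (1 - y) * log(pmax(1 - mu, 1e-300))) +
      lambda * sum(beta[-1]^2)
    if (is.finite(dev) && abs(dev - dev_old) < tol * (abs(dev) + 0.1)) {
      converged <- TRUE
      break
    }
    dev_old <- dev
  }
  names(beta) <- c("(Intercept)",
                   if (!is.null(colnames(X))) colnames(X) else
                     paste0("x", seq_len(ncol(X))))
  eta <- drop(Xd %*% beta)
  mu <- stats::plogis(eta)
  list(coef = beta, converged = converged,
       deviance = -2 * sum(y * log(pmax(mu, 1e-300)) +
                             (1 - y) * log(pmax(1 - mu, 1e-300))),
       linear_predictor = eta, fitted = mu)
}

# unpenalized fit with separation fallback: complete/quasi-separation shows
# up as non-convergence, runaway coefficients, or a vanishing deviance
fit_logit_core <- function(X, y) {
  fit <- logit_irls(X, y, lambda = 0)
  separated <- !fit$converged || max(abs(fit$coef)) > 1e3 ||
    fit$deviance < 1e-4
  if (separated) fit <- logit_irls(X, y, lambda = 1e-3)
  fit$penalized <- separated
  fit
}

#' Logistic classifier on principal-component scores
#'
#' Maximum-likelihood logistic regression of tumor status on the (usually
#' three) PC scores. If complete or quasi-separation is detected (any
#' coefficient beyond 1e3 in magnitude, or non-convergence), the model is
#' refit with a small L2 penalty (1e-3) on the slopes and flagged.
#'
#' @param scores samples x K numeric matrix of PC scores (rownames =
#'   sample ids).
#' @param labels "tumor"/"benign" per sample.
#' @return A list of class `dige_logit`: `coef`, `linear_predictor` (named
#'   per sample), `fitted` probabilities, `penalized` flag, `labels`.
#' @export
fit_logit_on_pcs <- function(scores, labels) {
  scores <- as.matrix(scores)
  labels <- check_class_labels(labels)
  if (length(unique(labels)) < 2) stop("both classes must be present")
  y <- as.numeric(labels == "tumor")
  fit <- fit_logit_core(scores, y)
  penalized <- fit$penalized
  lp <- fit$linear_predictor
  names(lp) <- rownames(scores)
  structure(list(coef = fit$coef, linear_predictor = lp,
                 fitted = stats::setNames(fit$fitted, rownames(scores)),
                 penalized = penalized, labels = labels),
            class = "dige_logit")
}

# Leave-one-out CV of a logistic model on a fixed score matrix (no PCA
# refit; used by the panel experiment where proxies replace the PCs).
loocv_scores <- function(scores, labels) {
  labels <- check_class_labels(labels)
  y <- as.numeric(labels == "tumor")
  n <- nrow(scores)
  pred <- numeric(n)
  for (i in seq_len(n)) {
    fit <- fit_logit_core(scores[-i, , drop = FALSE], y[-i])
    pred[i] <- stats::plogis(sum(c(1, scores[i, ]) * fit$coef))
  }
  cls_pred <- ifelse(pred > 0.5, "tumor", "benign")
  conf <- table(factor(as.character(labels), levels = c("tumor", "benign")),
                factor(cls_pred, levels = c("tumor", "benign")))
  list(accuracy = mean(cls_pred == as.character(labels)), confusion = conf,
       prob = stats::setNames(pred, rownames(scores)))
}

#' Leave-one-out cross-validation of the 3-PC logit classifier
#'
#' For each held-out sample the whole pipeline is refit on the remaining
#' samples: feature centering, two-step robust PCA with `K` components, and
#' the logistic model on the training scores. The held-out profile is then
#' centered with the training means, projected onto the training basis, and
#' classified as tumor iff its predicted probability exceeds 0.5. No
#' information from the held-out sample leaks into the fold's model.
#'
#' @param em an [expression_matrix()].
#' @param K number of principal components (default 3).
#' @return A list: `accuracy`, `confusion` (actual x predicted), `prob`
#'   (per-sample held-out probability), `predicted`.
#' @export
loocv <- function(em, K = 3) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  vals <- em$values
  labels <- em$class
  n <- ncol(vals)
  prob <- stats::setNames(numeric(n), colnames(vals))
  for (i in seq_len(n)) {
    train <- vals[, -i, drop = FALSE]
    model <- robust_pca(train, K = K, labels = labels[-i])
    fit <- fit_logit_on_pcs(model$sample_scores,
                            labels[model$retained])
    s_hold <- drop(crossprod(model$basis, vals[, i] - model$center))
    prob[i] <- stats::plogis(sum(c(1, s_hold) * fit$coef))
  }
  cls_pred <- ifelse(prob > 0.5, "tumor", "benign")
  conf <- table(factor(as.character(labels), levels = c("tumor", "benign")),
                factor(cls_pred, levels = c("tumor", "benign")))
  list(accuracy = mean(cls_pred == as.character(labels)),
       confusion = conf, prob = prob,
       predicted = stats::setNames(cls_pred, colnames(vals)))
}

# Exact 1-D 2-means: scan all splits of the sorted values; deterministic
# and globally optimal, so no random restarts are needed.
two_means_1d <- function(x) {
  ord <- order(x)
  xs <- x[ord]
  n <- length(xs)
  best <- NULL
  css <- function(v) if (length(v) < 2) 0 else sum((v - mean(v))^2)
  for (j in seq_len(n - 1)) {
    ss <- css(xs[1:j]) + css(xs[(j + 1):n])
    if (is.null(best) || ss < best$ss - 1e-12) best <- list(ss = ss, j = j)
  }
  cl <- integer(n)
  cl[ord] <- rep(1:2, c(best$j, n - best$j))
  tot <- css(xs)
  list(cluster = cl, within_ss = best$ss, total_ss = tot,
       separation = if (tot > 0) 1 - best$ss / tot else 0)
}

#' Split tumors into two groups on the logit output
#'
#' Among tumor samples only, clusters the model's linear predictor into two
#' groups with exact 1-D 2-means. Group 1 is the cluster whose mean linear
#' predictor is nearer the benign samples' mean, i.e. the tumors that are
#' less separable from normal tissue. The between/total sum-of-squares
#' fraction of the split is reported and flagged as weak below 0.75 (a
#' unimodal sample typically splits near 0.64).
#'
#' @param fit a [fit_logit_on_pcs()] model (or a named numeric linear
#'   predictor).
#' @param labels "tumor"/"benign" per sample in the linear predictor.
#' @return A list of class `TumorGroups`: `group` (named 1/2 per tumor
#'   sample), `separation` (BSS/TSS in \[0,1\]), `weak`, `threshold_stat`.
#' @export
split_tumor_groups <- function(fit, labels) {
  lp <- if (inherits(fit, "dige_logit")) fit$linear_predictor else fit
  labels <- check_class_labels(labels)
  if (is.null(names(lp)) || length(lp) != length(labels))
    stop("linear predictor must be named and match the labels")
  tum <- lp[labels == "tumor"]
  if (length(tum) < 2) stop("need at least 2 tumor samples")
  ben_mean <- mean(lp[labels == "benign"])
  km <- two_means_1d(tum)
  m1 <- mean(tum[km$cluster == 1]); m2 <- mean(tum[km$cluster == 2])
  grp <- km$cluster
  if (abs(m2 - ben_mean) < abs(m1 - ben_mean)) grp <- 3L - grp
  structure(list(group = stats::setNames(grp, names(tum)),
                 separation = km$separation,
                 weak = km$separation < 0.75),
            class = "TumorGroups")
}

#' Differential expression between the two tumor groups
#'
#' Two-sided pooled-variance t-test per feature between tumor group 1 and
#' tumor group 2, reported as log10 p and sorted most-significant first.
#'
#' @param em an [expression_matrix()].
#' @param groups a [split_tumor_groups()] result.
#' @return A data.frame `feature`, `protein` (if annotated), `log10_p`,
#'   sorted ascending by `log10_p`.
#' @export
tumor_group_diffexp <- function(em, groups) {
  stopifnot(inherits(groups, "TumorGroups"))
  g <- groups$group
  if (length(unique(g)) < 2) stop("need two non-empty tumor groups")
  ids <- names(g)
  m <- em$values[, ids, drop = FALSE]
  lp <- vapply(seq_len(nrow(m)), function(i) {
    tt <- pooled_ttest2(m[i, g == 1], m[i, g == 2])
    log10(max(tt$p, .Machine$double.xmin))
  }, numeric(1))
  out <- data.frame(feature = rownames(m),
                    protein = if (!is.null(em$protein))
                      unname(em$protein[rownames(m)]) else NA_character_,
                    log10_p = lp, stringsAsFactors = FALSE)
  out[order(out$log10_p), , drop = FALSE]
}

#' Features most correlated with each principal component
#'
#' Per component k, features are ranked by the absolute Pearson correlation
#' between their profile (over the model's retained samples) and the score
#' vector t_k; the top `n` are kept. Ties break by feature id.
#'
#' @param em an [expression_matrix()].
#' @param model a fitted `dige_pca` model.
#' @param n list size per component (default 38).
#' @return A list of length K; each element a data.frame `feature`,
#'   `correlation` sorted by |correlation| descending.
#' @export
top_correlated <- function(em, model, n = 38) {
  stopifnot(inherits(model, "dige_pca"))
  m <- em$values[, model$retained, drop = FALSE]
  if (n > nrow(m)) stop("n exceeds the number of features")
  lapply(seq_len(model$K), function(k) {
    r <- drop(stats::cor(t(m), model$scores[, k]))
    ord <- order(-abs(r), rownames(m))
    data.frame(feature = rownames(m)[ord][seq_len(n)],
               correlation = r[ord][seq_len(n)], stringsAsFactors = FALSE)
  })
}

#' Random protein-panel averaging experiment
#'
#' Tests how well small averaged protein panels can stand in for the
#' principal components. For each panel size s, in each replicate, s
#' features are drawn (without replacement, independently per component)
#' from that component's top-`n_top` correlation list; each component is
#' replaced by the mean centered profile of its drawn features; and the
#' three proxy scores are evaluated with a leave-one-out cross-validated
#' logistic model (the PCA itself is not refit -- the proxies replace the
#' components by design). Per size, the median accuracy and median
#' continuity-corrected odds ratio over replicates are reported.
#'
#' @param em an [expression_matrix()].
#' @param model a fitted `dige_pca` model.
#' @param sizes panel sizes (default 1:25).
#' @param reps replicates per size (default 200).
#' @param seed RNG seed for the panel draws.
#' @param n_top size of the per-component candidate lists (default 38).
#' @return A data.frame of class `PanelCurve`: `size`, `median_accuracy`,
#'   `median_odds_ratio`, `reps`, `seed`.
#' @export
panel_experiment <- function(em, model, sizes = 1:25, reps = 200, seed = 1,
                             n_top = 38) {
  if (reps < 1) stop("reps must be at least 1")
  if (any(sizes < 1 | sizes > n_top)) stop("sizes must lie in 1..n_top")
  lists <- top_correlated(em, model, n = n_top)
  keep <- model$retained
  labels <- em$class[keep]
  xc <- em$values[, keep, drop = FALSE] - model$center
  res <- with_seed(stage_seed(seed, "panel"), {
    lapply(sizes, function(s) {
      acc <- or <- numeric(reps)
      for (r in seq_len(reps)) {
        proxy <- vapply(lists, function(l) {
          idx <- sample(nrow(l), s)
          # orient each feature by the sign of its correlation with the
          # component, so that averaging suppresses noise instead of
          # cancelling the shared signal
          colMeans(xc[l$feature[idx], , drop = FALSE] *
                     sign(l$correlation[idx]))
        }, numeric(length(keep)))
        rownames(proxy) <- keep
        cv <- loocv_scores(proxy, labels)
        acc[r] <- cv$accuracy
        or[r] <- odds_ratio(cv$confusion)
      }
      data.frame(size = s, median_accuracy = stats::median(acc),
                 median_odds_ratio = stats::median(or),
                 reps = reps, seed = seed)
    })
  })
  out <- do.call(rbind, res)
  class(out) <- c("PanelCurve", class(out))
  out
}
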