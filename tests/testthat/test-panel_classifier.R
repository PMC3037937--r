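test_that("logit fit agrees with the glm (IRLS) oracle on random instances", {
  set.seed(41)
  for (rep in 1:8) {
    n <- 60
    X <- matrix(rnorm(n * 3), n, 3,
                dimnames = list(sprintf("s%d", 1:n), paste0("PC", 1:3)))
    beta <- c(0.3, -0.8, 0.5, 0.2)
    y <- rbinom(n, 1, plogis(cbind(1, X) %*% beta))
    if (length(unique(y)) < 2) next
    lab <- ifelse(y == 1, "tumor", "benign")
    fit <- fit_logit_on_pcs(X, lab)
    gfit <- stats::glm(y ~ X, family = stats::binomial())
    expect_false(fit$penalized)
    expect_equal(unname(fit$coef), unname(coef(gfit)), tolerance = 1e-6)
  }
})

test_that("class-symmetric scores give intercept ~ log(n1/n0), zero slopes", {
  set.seed(2)
  n <- 6000
  X <- matrix(rnorm(n * 3), n, 3,
              dimnames = list(sprintf("s%d", 1:n), paste0("PC", 1:3)))
  lab <- rep(c("tumor", "benign"), c(4000, 2000))
  fit <- fit_logit_on_pcs(X, lab)
  expect_equal(unname(fit$coef[1]), log(4000 / 2000), tolerance = 0.1)
  expect_lt(max(abs(fit$coef[-1])), 0.1)
})

test_that("perfect separation triggers the penalized fallback, predictions stay perfect", {
  X <- matrix(c(-3, -2, -1, 1, 2, 3), 6, 1,
              dimnames = list(sprintf("s%d", 1:6), "PC1"))
  lab <- rep(c("benign", "tumor"), each = 3)
  fit <- fit_logit_on_pcs(X, lab)
  expect_true(fit$penalized)
  expect_true(all(is.finite(fit$coef)))
  expect_equal(unname(fit$fitted > 0.5), lab == "tumor")
  expect_error(fit_logit_on_pcs(X, rep("tumor", 6)), "both classes")
})

test_that("logit predictions are invariant to affine transforms of the scores", {
  set.seed(7)
  X <- matrix(rnorm(40 * 3), 40, 3,
              dimnames = list(sprintf("s%d", 1:40), paste0("PC", 1:3)))
  lab <- ifelse(X[, 1] + rnorm(40, sd = 2) > 0, "tumor", "benign")
  A <- matrix(c(2, 0.3, 0, -0.5, 1.5, 0.2, 0.1, 0, -3), 3, 3)
  b <- c(1, -2, 0.5)
  X2 <- sweep(X %*% A, 2, -b)
  dimnames(X2) <- dimnames(X)
  f1 <- fit_logit_on_pcs(X, lab)
  f2 <- fit_logit_on_pcs(X2, lab)
  expect_equal(f1$fitted, f2$fitted, tolerance = 1e-5)
})

test_that("LOOCV: no leakage -- fold models never see the held-out sample", {
  em <- default_study(seed = 1)$em
  idx <- c(which(em$class == "tumor")[1:9], which(em$class == "benign")[1:9])
  sub <- expression_matrix(em$values[1:40, idx], em$class[idx])
  cv <- loocv(sub, K = 3)
  for (j in c(1, 9)) {
    train <- sub$values[, -j, drop = FALSE]
    model <- robust_pca(train, K = 3, labels = sub$class[-j])
    fit <- fit_logit_on_pcs(model$sample_scores, sub$class[model$retained])
    s_hold <- drop(crossprod(model$basis, sub$values[, j] - model$center))
    expect_equal(unname(cv$prob[j]),
                 unname(plogis(sum(c(1, s_hold) * fit$coef))),
                 tolerance = 1e-12)
  }
})

test_that("LOOCV is ~chance under permuted labels and perfect on separable data", {
  d <- default_study(seed = 2)
  em <- d$em
  # single permutations scatter widely around chance (LOOCV has a known
  # pessimistic bias at the null), so assert the mean over permutations
  accs <- vapply(1:4, function(s) {
    set.seed(s)
    perm_class <- setNames(sample(as.character(em$class)), names(em$class))
    loocv(expression_matrix(em$values, perm_class), K = 3)$accuracy
  }, numeric(1))
  expect_gt(mean(accs), 0.25)
  expect_lt(mean(accs), 0.70)
  # zero-noise rank-1 class-separated data
  cls <- rep(c("tumor", "benign"), each = 6)
  m <- outer(seq(0.5, 2, length.out = 10), ifelse(cls == "tumor", 1, -1))
  dimnames(m) <- list(sprintf("f%d", 1:10), sprintf("s%d", 1:12))
  expect_equal(loocv(expression_matrix(m, cls), K = 2)$accuracy, 1.0)
})

test_that("tumor-group split: contract, orientation and determinism", {
  lp <- c(a = -4, b = -3.5, c = -4.2,          # benign
          d = 1, e = 1.2, f = 0.8, g = 6, h = 6.5, i = 7)  # tumors
  lab <- c(rep("benign", 3), rep("tumor", 6))
  gr <- split_tumor_groups(lp, lab)
  expect_equal(sort(unique(gr$group)), c(1, 2))
  expect_equal(unname(gr$group[c("d", "e", "f")]), rep(1L, 3)) # near benign
  expect_equal(unname(gr$group[c("g", "h", "i")]), rep(2L, 3))
  expect_false(gr$weak)
  expect_identical(gr, split_tumor_groups(lp, lab))
  # unimodal tumors: still returns a split, flagged weak
  set.seed(11)
  lp2 <- c(setNames(rnorm(10, -4), paste0("b", 1:10)),
           setNames(rnorm(20, 2), paste0("t", 1:20)))
  lab2 <- rep(c("benign", "tumor"), c(10, 20))
  gr2 <- split_tumor_groups(lp2, lab2)
  expect_equal(length(gr2$group), 20)
  expect_true(gr2$weak)
  expect_error(split_tumor_groups(lp[1:4], lab[1:4]), "2 tumor samples")
})

test_that("tumor-group differential expression behaves at the extremes", {
  em <- default_study(seed = 1)$em
  tum <- names(em$class)[em$class == "tumor"]
  gr <- structure(list(group = setNames(rep(c(1L, 2L), each = 12), tum),
                       separation = 1, weak = FALSE), class = "TumorGroups")
  # identical groups: duplicate group 1's columns into group 2
  vals <- em$values
  vals[, tum[13:24]] <- vals[, tum[1:12]]
  em_id <- expression_matrix(vals, em$class, em$protein)
  de_id <- tumor_group_diffexp(em_id, gr)
  expect_true(all(de_id$log10_p == 0))
  # permuted-group null: no extreme p-values expected at ~100+ features
  hits <- vapply(1:10, function(s) {
    set.seed(s)
    g2 <- gr; g2$group <- setNames(sample(gr$group), tum)
    min(tumor_group_diffexp(em, g2)$log10_p)
  }, numeric(1))
  expect_gte(mean(hits > -4), 0.9)
  expect_true(all(diff(tumor_group_diffexp(em, gr)$log10_p) >= 0))
})

test_that("planted subgroup effects dominate the tumor-group ranking", {
  # implant a strong two-group difference on 26 features and check they
  # rank in the top 40
  em <- default_study(seed = 5)$em
  tum <- names(em$class)[em$class == "tumor"]
  g1 <- tum[1:12]; g2 <- tum[13:24]
  vals <- em$values
  planted <- rownames(vals)[10 + seq_len(26)]
  vals[planted, g2] <- vals[planted, g2] + 2
  em2 <- expression_matrix(vals, em$class, em$protein)
  gr <- structure(list(group = setNames(rep(c(1L, 2L), each = 12), tum),
                       separation = 1, weak = FALSE), class = "TumorGroups")
  de <- tumor_group_diffexp(em2, gr)
  expect_gte(mean(planted %in% de$feature[1:40]), 0.8)
})

test_that("top_correlated: dominant feature ranks first; rank-3 identity", {
  set.seed(15)
  n <- 12
  pattern <- rnorm(n)
  m <- rbind(strong = 10 * pattern,
             matrix(rnorm(8 * n, sd = 0.05), 8, n))
  rownames(m) <- c("strong", sprintf("f%d", 1:8))
  colnames(m) <- sprintf("s%d", 1:n)
  em <- expression_matrix(m, rep(c("tumor", "benign"), 6))
  model <- fit_pca(em, K = 3)
  tc <- top_correlated(em, model, n = 5)
  expect_equal(tc[[1]]$feature[1], "strong")
  expect_gt(abs(tc[[1]]$correlation[1]), 0.999)
  expect_error(top_correlated(em, model, n = 100), "exceeds")
  # rank-3 data: per-feature squared correlations over the 3 PCs sum to 1
  p <- synthetic_params(noise_sd = 0, frac_direct_de = 0, seed = 3)
  ex <- generate_expression(generate_design(p), p)
  cls <- ifelse(grepl("^T", colnames(ex$x)), "tumor", "benign")
  model3 <- fit_pca(ex$x, K = 3, labels = cls)
  r2 <- sapply(1:3, function(k) drop(cor(t(ex$x), model3$scores[, k]))^2)
  expect_equal(unname(rowSums(r2)), rep(1, nrow(ex$x)), tolerance = 1e-8)
})

test_that("odds ratio arithmetic and the continuity correction", {
  conf <- matrix(c(23, 3, 1, 18), 2, 2)
  expect_equal(odds_ratio(conf, correct = FALSE), 138.0)
  # +0.5 on every cell: (23.5*18.5)/(1.5*3.5)
  expect_equal(odds_ratio(conf, correct = TRUE), 82.8095, tolerance = 1e-4)
  withzero <- matrix(c(10, 0, 2, 8), 2, 2)
  expect_equal(odds_ratio(withzero), (10.5 * 8.5) / (2.5 * 0.5))
})

test_that("panel experiment: degenerate full panel, reproducibility, errors", {
  d <- default_study(seed = 1)
  em <- d$em
  model <- robust_pca(em, K = 3)
  # s = n_top: every replicate draws the whole list -> zero sampling
  # variance, so different draw seeds give identical medians
  p1 <- panel_experiment(em, model, sizes = 38, reps = 2, seed = 1)
  p2 <- panel_experiment(em, model, sizes = 38, reps = 2, seed = 99)
  expect_equal(p1$median_accuracy, p2$median_accuracy)
  expect_equal(p1$median_odds_ratio, p2$median_odds_ratio)
  # bit-for-bit reproducibility for fixed (seed, reps)
  q1 <- panel_experiment(em, model, sizes = c(2, 4), reps = 5, seed = 7)
  q2 <- panel_experiment(em, model, sizes = c(2, 4), reps = 5, seed = 7)
  expect_identical(q1, q2)
  expect_error(panel_experiment(em, model, sizes = 2, reps = 0), "reps")
  expect_error(panel_experiment(em, model, sizes = 50), "1..n_top")
})
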