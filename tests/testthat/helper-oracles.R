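# Independent oracles used by the test suite. These deliberately avoid the
# package's own code paths.

# O(n^3) UPGMA: returns the full cophenetic distance matrix, built by
# merging the closest pair of clusters and recording the average linkage
# distance for every cross pair at merge time.
upgma_cophenetic_oracle <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  coph <- matrix(0, n, n, dimnames = dimnames(d))
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  avg_dist <- function(a, b) mean(d[a, b])
  while (length(clusters) > 1) {
    best <- NULL
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (j <= i) next
      h <- avg_dist(clusters[[i]], clusters[[j]])
      if (is.null(best) || h < best$h) best <- list(i = i, j = j, h = h)
    }
    for (a in clusters[[best$i]]) for (b in clusters[[best$j]]) {
      coph[a, b] <- coph[b, a] <- best$h
    }
    heights <- c(heights, best$h)
    clusters[[best$i]] <- c(clusters[[best$i]], clusters[[best$j]])
    clusters[[best$j]] <- NULL
  }
  list(cophenetic = coph, heights = heights)
}

# Full-enumeration Fisher oracle: hypergeometric probabilities computed
# from log-factorials directly, probability-mass two-sided rule.
fisher_oracle <- function(tab) {
  tab <- as.matrix(tab)
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1]); c2 <- sum(tab[, 2])
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) return(1)
  n <- r1 + r2
  lprob <- function(a) {
    b <- r1 - a; c <- c1 - a; dd <- r2 - c1 + a
    lgamma(r1 + 1) + lgamma(r2 + 1) + lgamma(c1 + 1) + lgamma(c2 + 1) -
      lgamma(n + 1) - lgamma(a + 1) - lgamma(b + 1) - lgamma(c + 1) -
      lgamma(dd + 1)
  }
  support <- max(0, c1 - r2):min(r1, c1)
  lp <- vapply(support, lprob, numeric(1))
  lp_obs <- lprob(tab[1, 1])
  min(1, sum(exp(lp[lp <= lp_obs + 1e-7])))
}

# Two-sided t p-value by numerical integration of the t density.
t_pvalue_integrate <- function(tstat, df) {
  dens <- function(x) {
    exp(lgamma((df + 1) / 2) - lgamma(df / 2)) / sqrt(df * pi) *
      (1 + x^2 / df)^(-(df + 1) / 2)
  }
  2 * stats::integrate(dens, abs(tstat), Inf, rel.tol = 1e-12)$value
}

# Brute-force projection of each centered feature onto span{t_1..t_K}.
projection_oracle <- function(m, center, tmat) {
  xc <- m - center
  proj <- matrix(0, nrow(m), ncol(m), dimnames = dimnames(m))
  for (i in seq_len(nrow(m))) {
    v <- xc[i, ]
    for (k in seq_len(ncol(tmat))) {
      proj[i, ] <- proj[i, ] + sum(v * tmat[, k]) * tmat[, k]
    }
  }
  proj + center
}

# principal angles (degrees) between the column spaces of two orthonormal
# bases
principal_angles_deg <- function(A, B) {
  s <- svd(crossprod(A, B))$d
  s <- pmin(pmax(s, -1), 1)
  acos(s) * 180 / pi
}
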