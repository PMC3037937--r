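#' @keywords internal
"_PACKAGE"

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state. All stochastic operations in the package go through this so
# that identical (params, seed) give bit-identical output.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Per-stage RNG streams: each generator stage draws from its own stream,
# seeded as params$seed + a fixed stage offset (kept far below 2^31).
stage_seed <- function(seed, stage) {
  offsets <- c(design = 101L, expression = 211L, spots = 307L,
               split = 401L, panel = 503L)
  if (!stage %in% names(offsets)) stop("unknown RNG stage: ", stage)
  as.integer(seed) + offsets[[stage]]
}

#' Rand index between two partitions
#'
#' Plain (unadjusted) Rand index: the fraction of sample pairs on which two
#' partitions agree (both together or both apart).
#'
#' @param a,b partition labels of the same length (any atomic type).
#' @return A number in \[0, 1\].
#' @export
rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  n <- length(a)
  same_a <- outer(a, a, "==")
  same_b <- outer(b, b, "==")
  idx <- upper.tri(same_a)
  mean(same_a[idx] == same_b[idx])
}

#' Odds ratio of a 2x2 confusion table
#'
#' Computes (a*d)/(b*c). When any cell is zero the Haldane--Anscombe
#' correction (+0.5 to every cell) is applied so the ratio stays finite and
#' positive; `correct` can force either behaviour.
#'
#' @param tab 2x2 numeric matrix of non-negative counts.
#' @param correct logical; default applies +0.5 only if some cell is zero.
#' @return Positive number.
#' @export
odds_ratio <- function(tab, correct = any(tab == 0)) {
  tab <- as.matrix(tab)
  stopifnot(identical(dim(tab), c(2L, 2L)), all(tab >= 0))
  if (correct) tab <- tab + 0.5
  (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
}

# shared input check used across modules
check_class_labels <- function(labels) {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), c("tumor", "benign"))
  if (length(bad)) stop("class labels must be 'tumor' or 'benign', got: ",
                        paste(bad, collapse = ", "))
  factor(labels, levels = c("benign", "tumor"))
}
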