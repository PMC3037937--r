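# Shared fixtures built in code. Default studies are cached per seed so
# several test files can reuse them without re-simulating.
.study_cache <- new.env(parent = emptyenv())

default_study <- function(seed = 1, ...) {
  extra <- list(...)
  key <- paste(seed, paste(names(extra), unlist(extra), sep = "=",
                           collapse = ","), sep = "|")
  if (is.null(.study_cache[[key]])) {
    params <- do.call(synthetic_params, c(list(seed = seed), extra))
    st <- simulate_study(params)
    em <- suppressMessages(assemble_matrix(
      normalize_internal_standard(st$tables), st$design,
      spot_map = st$spot_map))
    .study_cache[[key]] <- list(study = st, em = em)
  }
  .study_cache[[key]]
}

# small labeled matrix with a tunable class shift on the first `k_sig`
# features; iid Gaussian otherwise
make_em <- function(p = 30, n = 16, shift = 0, k_sig = 5, seed = 1,
                    sd = 1) {
  set.seed(seed)
  m <- matrix(rnorm(p * n, sd = sd), p, n,
              dimnames = list(sprintf("f%02d", seq_len(p)),
                              sprintf("s%02d", seq_len(n))))
  cls <- rep(c("tumor", "benign"), length.out = n)
  m[seq_len(k_sig), cls == "tumor"] <-
    m[seq_len(k_sig), cls == "tumor"] + shift
  expression_matrix(m, cls)
}
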