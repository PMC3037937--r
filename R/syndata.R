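#' Parameters of a synthetic 2D-DIGE study
#'
#' Bundles and validates the knobs of the synthetic-study generator. The
#' defaults emulate the design of a paired tumor/benign prostate DIGE study:
#' 24 tumor and 24 benign samples run pairwise on 24 gels against a pooled
#' Cy2 internal standard, 3 benign samples lost to failed labeling (leaving
#' 21 in the analysis set), about 79 proteins spread over roughly 118 gel
#' spots, class signal carried by three co-regulated latent factors plus a
#' sparse set of directly shifted proteins, and a 10-sample tumor subgroup.
#'
#' All abundances live on the log2 scale; spot volumes are `2^x`, so the
#' internal-standard normalization downstream reconstructs `x` exactly (up
#' to a per-spot constant) when nuisance effects are switched off.
#'
#' @param n_tumor,n_benign numbers of tumor and benign samples.
#' @param n_failed_benign benign samples whose labeling failed; they are
#'   generated but flagged and excluded from analysis.
#' @param subgroup_size size of the planted tumor subgroup (shifted on
#'   latent factor 2).
#' @param n_proteins number of proteins.
#' @param spots_per_protein probabilities of a protein mapping to 1, 2 or 3
#'   gel spots (must sum to 1).
#' @param factor_effect_a standardized shift of latent factor 1 for tumors.
#' @param factor_effect_b standardized shift of latent factor 2 for the
#'   tumor subgroup.
#' @param loading_scale standard deviation of the factor loadings.
#' @param noise_sd residual standard deviation on the log2 scale.
#' @param frac_direct_de fraction of proteins with a direct class shift.
#' @param direct_log_fc magnitude of the direct shift (log2 scale; the
#'   default log2(1.5) sits exactly on the 1.5-fold filter boundary).
#' @param gel_effect_sd,dye_effect_sd standard deviations of multiplicative
#'   gel and dye nuisance effects (log2 scale).
#' @param missing_rate probability that a spot is not detected on a gel.
#' @param seed integer seed; every generator stage derives its own stream
#'   from it.
#' @return An object of class `synthetic_params` (a validated list).
#' @export
synthetic_params <- function(n_tumor = 24, n_benign = 24, n_failed_benign = 3,
                             subgroup_size = 10, n_proteins = 79,
                             spots_per_protein = c(0.7, 0.2, 0.1),
                             factor_effect_a = 2.0, factor_effect_b = 2.0,
                             loading_scale = 0.5, noise_sd = 0.3,
                             frac_direct_de = 0.15,
                             direct_log_fc = log2(1.5),
                             gel_effect_sd = 0.2, dye_effect_sd = 0.1,
                             missing_rate = 0.02, seed = 1L) {
  p <- list(n_tumor = as.integer(n_tumor), n_benign = as.integer(n_benign),
            n_failed_benign = as.integer(n_failed_benign),
            subgroup_size = as.integer(subgroup_size),
            n_proteins = as.integer(n_proteins),
            spots_per_protein = as.numeric(spots_per_protein),
            factor_effect_a = factor_effect_a,
            factor_effect_b = factor_effect_b,
            loading_scale = loading_scale, noise_sd = noise_sd,
            frac_direct_de = frac_direct_de, direct_log_fc = direct_log_fc,
            gel_effect_sd = gel_effect_sd, dye_effect_sd = dye_effect_sd,
            missing_rate = missing_rate, seed = as.integer(seed))
  for (f in c("n_tumor", "n_benign", "n_proteins"))
    if (p[[f]] < 1) stop("parameter '", f, "' must be positive")
  for (f in c("n_failed_benign", "subgroup_size"))
    if (p[[f]] < 0) stop("parameter '", f, "' must be non-negative")
  if (p$subgroup_size > p$n_tumor)
    stop("parameter 'subgroup_size' cannot exceed 'n_tumor'")
  if (length(p$spots_per_protein) != 3 || any(p$spots_per_protein < 0) ||
      abs(sum(p$spots_per_protein) - 1) > 1e-8)
    stop("parameter 'spots_per_protein' must be 3 probabilities summing to 1")
  if (p$n_benign - p$n_failed_benign < 2)
    stop("parameter 'n_failed_benign' leaves fewer than 2 benign samples")
  for (f in c("loading_scale", "noise_sd", "gel_effect_sd", "dye_effect_sd"))
    if (p[[f]] < 0) stop("parameter '", f, "' must be non-negative")
  if (p$missing_rate < 0 || p$missing_rate > 1)
    stop("parameter 'missing_rate' must be in [0, 1]")
  if (p$frac_direct_de < 0 || p$frac_direct_de > 1)
    stop("parameter 'frac_direct_de' must be in [0, 1]")
  structure(p, class = "synthetic_params")
}

#' Generate the sample/gel design of a synthetic study
#'
#' Pairs one tumor and one benign sample per gel where possible (leftover
#' samples get their own gels), alternates the Cy3/Cy5 assignment across
#' gels (dye swap), flags exactly `n_failed_benign` benign samples as failed
#' labelings, and marks the planted tumor subgroup.
#'
#' @param params a [synthetic_params()] object.
#' @return A data.frame with one row per sample: `sample_id`, `class`,
#'   `subgroup`, `failed`, `gel_id`, `dye`.
#' @export
generate_design <- function(params) {
  if (!inherits(params, "synthetic_params")) params <- do.call(synthetic_params, params)
  tum <- sprintf("T%02d", seq_len(params$n_tumor))
  ben <- sprintf("B%02d", seq_len(params$n_benign))
  n_gel <- max(params$n_tumor, params$n_benign)
  gel_of <- function(i) sprintf("G%02d", i)
  des <- rbind(
    data.frame(sample_id = tum, class = "tumor",
               gel_id = gel_of(seq_len(params$n_tumor)),
               stringsAsFactors = FALSE),
    data.frame(sample_id = ben, class = "benign",
               gel_id = gel_of(seq_len(params$n_benign)),
               stringsAsFactors = FALSE))
  # dye swap: odd gels run tumor on Cy3, even gels on Cy5
  gel_idx <- as.integer(sub("^G", "", des$gel_id))
  des$dye <- ifelse((gel_idx %% 2 == 1) == (des$class == "tumor"), "Cy3", "Cy5")
  with_seed(stage_seed(params$seed, "design"), {
    failed <- sample(ben, params$n_failed_benign)
    sub <- sample(tum, params$subgroup_size)
  })
  des$failed <- des$sample_id %in% failed
  des$subgroup <- des$sample_id %in% sub
  des <- des[, c("sample_id", "class", "subgroup", "failed", "gel_id", "dye")]
  rownames(des) <- des$sample_id
  des
}

#' Generate true log2 abundances and ground truth
#'
#' The model is `x_js = mu_j + sum_k l_jk f_ks + delta_j 1[tumor] + eps_js`
#' with three latent factors: factor 1 shifted by `factor_effect_a` for
#' tumors, factor 2 shifted by `factor_effect_b` for the tumor subgroup,
#' factor 3 pure structured noise. Exactly
#' `round(frac_direct_de * n_proteins)` proteins carry a direct class shift
#' `delta_j` of magnitude `direct_log_fc` with random sign.
#'
#' @param design output of [generate_design()].
#' @param params a [synthetic_params()] object.
#' @param seed seed for this stage (defaults to `params$seed`).
#' @return A list with `x` (noisy proteins x samples log2 matrix), and
#'   `truth`: `clean` (pre-noise matrix), `mu`, `loadings`, `factors`,
#'   `delta`, plus the design columns.
#' @export
generate_expression <- function(design, params, seed = params$seed) {
  if (!inherits(params, "synthetic_params")) params <- do.call(synthetic_params, params)
  if (nrow(design) != params$n_tumor + params$n_benign)
    stop("design is inconsistent with params: wrong number of samples")
  P <- params$n_proteins
  S <- nrow(design)
  prot <- sprintf("P%03d", seq_len(P))
  is_tum <- design$class == "tumor"
  with_seed(stage_seed(seed, "expression"), {
    mu <- stats::rnorm(P, mean = 8, sd = 1)
    L <- matrix(stats::rnorm(P * 3, sd = params$loading_scale), P, 3)
    f <- matrix(stats::rnorm(3 * S), 3, S)
    f[1, ] <- f[1, ] + params$factor_effect_a * is_tum
    f[2, ] <- f[2, ] + params$factor_effect_b * design$subgroup
    n_de <- round(params$frac_direct_de * P)
    de_idx <- if (n_de > 0) sample.int(P, n_de) else integer(0)
    delta <- numeric(P)
    if (n_de > 0)
      delta[de_idx] <- params$direct_log_fc * sample(c(-1, 1), n_de, replace = TRUE)
    eps <- matrix(stats::rnorm(P * S, sd = params$noise_sd), P, S)
  })
  clean <- mu + L %*% f + outer(delta, as.numeric(is_tum))
  x <- clean + eps
  dimnames(x) <- dimnames(clean) <- list(prot, design$sample_id)
  rownames(L) <- prot
  names(mu) <- names(delta) <- prot
  colnames(f) <- design$sample_id
  list(x = x,
       truth = list(clean = clean, mu = mu, loadings = L, factors = f,
                    delta = delta, class = stats::setNames(design$class, design$sample_id),
                    subgroup = stats::setNames(design$subgroup, design$sample_id)))
}

#' Expand protein abundances to per-gel spot-volume tables
#'
#' Each protein maps to 1--3 spots with fixed per-spot log2 offsets (a crude
#' stand-in for charge/mass variants of one protein). A sample's volume on
#' its gel is `2^(x_js + offset + gel effect + dye effect)`; the Cy2
#' internal-standard volume is built from the pooled mean of `x_js` over all
#' non-failed samples. Whole spots go missing per gel at `missing_rate`.
#'
#' @param x proteins x samples log2 abundance matrix.
#' @param design output of [generate_design()].
#' @param params a [synthetic_params()] object.
#' @param seed seed for this stage (defaults to `params$seed`).
#' @return A list: `tables` (named list of per-gel data.frames with columns
#'   `gel_id`, `spot_id`, `channel`, `sample_id`, `volume`), `spot_map`
#'   (data.frame `spot_id`, `protein`, `offset`).
#' @export
expand_to_spots <- function(x, design, params, seed = params$seed) {
  if (!inherits(params, "synthetic_params")) params <- do.call(synthetic_params, params)
  if (!all(is.finite(x))) stop("abundance matrix must be finite")
  prot <- rownames(x)
  gels <- unique(design$gel_id)
  with_seed(stage_seed(seed, "spots"), {
    n_spots <- sample(1:3, length(prot), replace = TRUE,
                      prob = params$spots_per_protein)
    spot_prot <- rep(prot, n_spots)
    offset <- stats::rnorm(length(spot_prot), sd = 0.5)
    gel_eff <- stats::setNames(stats::rnorm(length(gels), sd = params$gel_effect_sd), gels)
    dye_eff <- stats::setNames(stats::rnorm(3, sd = params$dye_effect_sd),
                               c("Cy2", "Cy3", "Cy5"))
    miss <- matrix(stats::runif(length(spot_prot) * length(gels)) < params$missing_rate,
                   length(spot_prot), length(gels), dimnames = list(NULL, gels))
  })
  spot_id <- sprintf("S%03d", seq_along(spot_prot))
  spot_map <- data.frame(spot_id = spot_id, protein = spot_prot,
                         offset = offset, stringsAsFactors = FALSE)
  # pooled internal standard: mean over non-failed samples only
  keep <- design$sample_id[!design$failed]
  pool <- rowMeans(x[, keep, drop = FALSE])
  tables <- lapply(gels, function(g) {
    on_gel <- design[design$gel_id == g, , drop = FALSE]
    present <- which(!miss[, g])
    if (!length(present))
      return(data.frame(gel_id = character(0), spot_id = character(0),
                        channel = character(0), sample_id = character(0),
                        volume = numeric(0), stringsAsFactors = FALSE))
    base <- offset[present] + gel_eff[[g]]
    prot_p <- spot_prot[present]
    ns <- nrow(on_gel)
    out <- data.frame(
      gel_id = g,
      spot_id = c(spot_id[present], rep(spot_id[present], each = ns)),
      channel = c(rep("Cy2", length(present)), rep(on_gel$dye, length(present))),
      sample_id = c(rep("POOL", length(present)),
                    rep(on_gel$sample_id, length(present))),
      volume = c(2^(pool[prot_p] + base + dye_eff[["Cy2"]]),
                 2^(as.vector(t(x[prot_p, on_gel$sample_id, drop = FALSE])) +
                      rep(base, each = ns) + dye_eff[on_gel$dye])),
      stringsAsFactors = FALSE)
    # interleave so each spot's Cy2 row precedes its sample rows
    out <- out[order(out$spot_id, out$channel != "Cy2"), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
  names(tables) <- gels
  list(tables = tables, spot_map = spot_map)
}

#' Simulate a complete synthetic DIGE study
#'
#' Convenience wrapper: design, expression, spot expansion.
#'
#' @param params a [synthetic_params()] object (or argument list).
#' @return A list with `params`, `design`, `x`, `truth`, `tables`,
#'   `spot_map`.
#' @export
simulate_study <- function(params = synthetic_params()) {
  if (!inherits(params, "synthetic_params")) params <- do.call(synthetic_params, params)
  design <- generate_design(params)
  expr <- generate_expression(design, params)
  spots <- expand_to_spots(expr$x, design, params)
  list(params = params, design = design, x = expr$x, truth = expr$truth,
       tables = spots$tables, spot_map = spots$spot_map)
}

#' Write the packaged clinical-metadata fixture
#'
#' Copies the packaged 24-patient clinical table (tumor stage, Gleason
#' score, preoperative hormone therapy, preoperative PSA in ng/ml, with NA
#' for missing entries) to `path`.
#'
#' @param path destination file path.
#' @return `path`, invisibly.
#' @export
write_clinical_fixture <- function(path) {
  src <- system.file("extdata", "clinical_metadata.tsv", package = "digeclass",
                     mustWork = TRUE)
  if (!file.copy(src, path, overwrite = TRUE))
    stop("could not write clinical fixture to ", path)
  invisible(path)
}
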