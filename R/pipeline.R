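#' Run the full analysis pipeline on a synthetic study
#'
#' Simulates a study (unless spot tables are supplied), normalizes against
#' the Cy2 internal standard, assembles the log2 expression matrix, and
#' runs differential expression, clustering + single-feature partition,
#' robust PCA with the projection/residual split, the 3-PC logit with
#' LOOCV, the tumor-group split, and (optionally) the panel experiment.
#'
#' @param params a [synthetic_params()] object or argument list.
#' @param outdir optional output directory; when given, every stage writes
#'   TSV/JSON artifacts and diagnostic plots there.
#' @param run_panel run the (slower) panel-averaging experiment.
#' @param panel_sizes,panel_reps panel experiment settings.
#' @return A list with all stage results.
#' @export
run_pipeline <- function(params = synthetic_params(), outdir = NULL,
                         run_panel = FALSE, panel_sizes = 1:25,
                         panel_reps = 200) {
  if (!inherits(params, "synthetic_params")) params <- do.call(synthetic_params, params)
  study <- simulate_study(params)
  ratios <- normalize_internal_standard(study$tables)
  em <- assemble_matrix(ratios, study$design, spot_map = study$spot_map)
  de <- diffexp(em)
  sig <- significant_spots(de)
  dendro <- hclust_average(em, features = if (nrow(sig)) sig$feature else NULL)
  best_feat <- if (nrow(sig)) sig$feature[1] else rownames(em$values)[1]
  part <- single_feature_partition(em$values[best_feat, ], em$class)
  model <- robust_pca(em, K = 3)
  if (length(model$outliers))
    message("robust PCA removed outliers: ",
            paste(model$outliers, collapse = ", "))
  dec <- decompose_profiles(em, model)
  ttests <- component_ttests(dec, em)
  fit <- fit_logit_on_pcs(model$sample_scores, em$class[model$retained])
  if (fit$penalized) message("logit: separation fallback (ridge) triggered")
  cv <- loocv(em, K = 3)
  groups <- split_tumor_groups(fit, em$class[model$retained])
  group_de <- tumor_group_diffexp(em, groups)
  panel <- NULL
  if (run_panel)
    panel <- panel_experiment(em, model, sizes = panel_sizes,
                              reps = panel_reps, seed = params$seed)
  res <- list(params = params, study = study, em = em, diffexp = de,
              significant = sig, dendrogram = dendro, partition = part,
              pca = model, decomposition = dec, component_ttests = ttests,
              logit = fit, loocv = cv, tumor_groups = groups,
              tumor_group_diffexp = group_de, panel = panel)
  if (!is.null(outdir)) write_pipeline_outputs(res, outdir)
  res
}

write_pipeline_outputs <- function(res, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(x, f) utils::write.table(x, file.path(outdir, f),
                                           sep = "\t", quote = FALSE,
                                           row.names = FALSE)
  write_spot_tables(res$study$tables, file.path(outdir, "spots"))
  tsv(res$study$design, "design.tsv")
  write_expression_matrix(res$em, file.path(outdir, "expression"))
  tsv(res$diffexp, "diffexp.tsv")
  tsv(res$significant, "significant.tsv")
  writeLines(res$dendrogram$newick, file.path(outdir, "dendrogram.nwk"))
  tsv(res$component_ttests, "component_ttests.tsv")
  tsv(res$tumor_group_diffexp, "tumor_group_diffexp.tsv")
  jsonlite::write_json(list(
    partition = list(threshold = res$partition$threshold,
                     orientation = res$partition$orientation,
                     accuracy = res$partition$accuracy,
                     fisher_p = res$partition$fisher_p),
    pca = list(explained_variance = res$pca$evar[seq_len(res$pca$K)],
               outliers = res$pca$outliers),
    logit = list(coef = as.list(res$logit$coef),
                 penalized = res$logit$penalized),
    loocv = list(accuracy = res$loocv$accuracy,
                 confusion = as.vector(res$loocv$confusion)),
    tumor_groups = list(group = as.list(res$tumor_groups$group),
                        separation = res$tumor_groups$separation,
                        weak = res$tumor_groups$weak)),
    file.path(outdir, "summary.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA)
  if (!is.null(res$panel)) tsv(res$panel, "panel_curve.tsv")
  plot_outputs(res, outdir)
  invisible(outdir)
}

plot_outputs <- function(res, outdir) {
  sc <- res$pca$sample_scores
  cls <- res$em$class[res$pca$retained]
  grDevices::pdf(file.path(outdir, "figures.pdf"), width = 7, height = 6)
  on.exit(grDevices::dev.off(), add = TRUE)
  # PC scatter (first two components)
  graphics::plot(sc[, 1], sc[, 2], col = ifelse(cls == "tumor", 2, 4),
                 pch = 19, xlab = "PC1 score", ylab = "PC2 score",
                 main = "Sample scores (red = tumor, blue = benign)")
  # original vs projection/residual p-values
  tt <- res$component_ttests
  graphics::plot(log10(tt$p_orig), log10(tt$p_proj), col = 2, pch = 3,
                 xlab = "log10 p (original)", ylab = "log10 p (component)",
                 main = "Differential expression split across S3 / CS3")
  graphics::points(log10(tt$p_orig), log10(tt$p_resid), col = 4, pch = 3)
  graphics::abline(0, 1, lty = 2)
  # logit output by group
  lp <- res$logit$linear_predictor
  grp <- rep("benign", length(lp))
  names(grp) <- names(lp)
  grp[names(res$tumor_groups$group)] <-
    paste0("tumor_g", res$tumor_groups$group)
  graphics::boxplot(split(lp, grp), ylab = "logit linear predictor",
                    main = "Regression output by sample group")
  if (!is.null(res$panel)) {
    graphics::plot(res$panel$size, res$panel$median_accuracy, type = "b",
                   xlab = "panel size", ylab = "median LOOCV accuracy",
                   main = "Panel averaging experiment")
    graphics::plot(res$panel$size, res$panel$median_odds_ratio, type = "b",
                   log = "y", xlab = "panel size",
                   ylab = "median odds ratio")
  }
  invisible(NULL)
}

#' Command-line interface
#'
#' Entry point behind the `dige-biomarker` script:
#' `dige-biomarker <simulate|normalize|diffexp|cluster|pca|classify|panel|all>
#' [--config cfg.json] [--seed N] [--outdir DIR]`. The JSON config may
#' override any [synthetic_params()] field plus `alpha`, `min_fold`,
#' `panel_sizes`, `panel_reps`. Every stage up to the requested one is run
#' (stages are cheap and self-contained); artifacts land in `--outdir`.
#'
#' @param args character vector of command-line arguments.
#' @return The pipeline result, invisibly.
#' @export
dige_biomarker_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  stages <- c("simulate", "normalize", "diffexp", "cluster", "pca",
              "classify", "panel", "all")
  if (!length(args) || !args[1] %in% stages)
    stop("usage: dige-biomarker <", paste(stages, collapse = "|"),
         "> [--config cfg.json] [--seed N] [--outdir DIR]")
  stage <- args[1]
  parser <- optparse::OptionParser(option_list = list(
    optparse::make_option("--config", type = "character", default = NULL),
    optparse::make_option("--seed", type = "integer", default = 1L),
    optparse::make_option("--outdir", type = "character", default = "dige_out")))
  opt <- optparse::parse_args(parser, args = args[-1])
  cfg <- if (!is.null(opt$config)) jsonlite::read_json(opt$config,
                                                       simplifyVector = TRUE)
         else list()
  par_names <- names(formals(synthetic_params))
  params <- do.call(synthetic_params,
                    c(cfg[intersect(names(cfg), par_names)],
                      list(seed = opt$seed)))
  run_panel <- stage %in% c("panel", "all")
  res <- run_pipeline(params, outdir = opt$outdir, run_panel = run_panel,
                      panel_sizes = if (!is.null(cfg$panel_sizes))
                        cfg$panel_sizes else 1:25,
                      panel_reps = if (!is.null(cfg$panel_reps))
                        cfg$panel_reps else 200)
  message("pipeline artifacts written to ", opt$outdir)
  invisible(res)
}
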