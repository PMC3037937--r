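#' Expression matrix container
#'
#' Light S3 container for log2-normalized spot abundances: a features x
#' samples matrix with a tumor/benign label per sample and an optional
#' spot-to-protein annotation.
#'
#' @param values numeric matrix, rownames = feature (spot) ids, colnames =
#'   sample ids.
#' @param class character/factor of "tumor"/"benign", one per sample (named
#'   or in column order).
#' @param protein optional character vector mapping features to protein
#'   labels.
#' @return An `ExpressionMatrix` object.
#' @export
expression_matrix <- function(values, class, protein = NULL) {
  values <- as.matrix(values)
  if (is.null(colnames(values)) || is.null(rownames(values)))
    stop("values must have feature rownames and sample colnames")
  if (anyDuplicated(colnames(values))) stop("sample ids must be unique")
  if (!all(is.finite(values))) stop("values must be finite after imputation")
  if (!is.null(names(class))) class <- class[colnames(values)]
  if (length(class) != ncol(values))
    stop("every sample needs a class label")
  cls <- check_class_labels(class)
  names(cls) <- colnames(values)
  if (!is.null(protein)) {
    if (length(protein) != nrow(values))
      stop("protein annotation must match feature count")
    names(protein) <- rownames(values)
  }
  structure(list(values = values, class = cls, protein = protein),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat("ExpressionMatrix:", nrow(x$values), "features x", ncol(x$values),
      "samples (", sum(x$class == "tumor"), "tumor /",
      sum(x$class == "benign"), "benign )\n")
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Read per-gel spot-volume tables
#'
#' Reads one or more TSV files with columns `gel_id`, `spot_id`, `channel`,
#' `sample_id`, `volume` and concatenates them after validation. Malformed
#' rows are reported with their file and line numbers.
#'
#' @param paths character vector of file paths.
#' @return A validated data.frame of all rows.
#' @export
read_spot_tables <- function(paths) {
  tabs <- lapply(paths, function(p) {
    tab <- utils::read.delim(p, stringsAsFactors = FALSE, colClasses = list(
      gel_id = "character", spot_id = "character", channel = "character",
      sample_id = "character", volume = "numeric"))
    need <- c("gel_id", "spot_id", "channel", "sample_id", "volume")
    if (!all(need %in% names(tab)))
      stop("spot table ", p, " lacks columns: ",
           paste(setdiff(need, names(tab)), collapse = ", "))
    tab$.src <- p
    tab$.line <- seq_len(nrow(tab)) + 1L  # +1 for the header
    tab
  })
  tab <- do.call(rbind, tabs)
  validate_spot_table(tab)
  tab$.src <- NULL; tab$.line <- NULL
  tab
}

validate_spot_table <- function(tab) {
  where <- function(i) {
    if (!is.null(tab$.src))
      paste0(" (", tab$.src[i], " line ", tab$.line[i], ")")
    else paste0(" (row ", i, ")")
  }
  bad <- which(!tab$channel %in% c("Cy2", "Cy3", "Cy5"))
  if (length(bad))
    stop("unknown channel '", tab$channel[bad[1]], "'", where(bad[1]))
  bad <- which(!is.finite(tab$volume) | tab$volume <= 0)
  if (length(bad))
    stop("non-positive or missing volume", where(bad[1]))
  key <- paste(tab$gel_id, tab$spot_id, tab$channel, tab$sample_id)
  bad <- which(duplicated(key))
  if (length(bad))
    stop("duplicate (gel, spot, channel, sample) record", where(bad[1]))
  invisible(tab)
}

#' Write spot-volume tables
#'
#' Writes one TSV per gel into `dir` (named `spots_<gel>.tsv`), in the same
#' schema [read_spot_tables()] consumes.
#'
#' @param tables named list of per-gel data.frames (as produced by
#'   [expand_to_spots()]) or a single combined data.frame.
#' @param dir output directory (created if needed).
#' @return The written paths, invisibly.
#' @export
write_spot_tables <- function(tables, dir) {
  if (is.data.frame(tables)) tables <- split(tables, tables$gel_id)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(tables), function(g) {
    p <- file.path(dir, paste0("spots_", g, ".tsv"))
    utils::write.table(tables[[g]], p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    p
  }, character(1))
  invisible(paths)
}

#' Internal-standard normalization
#'
#' Divides every sample-channel (Cy3/Cy5) volume by the Cy2 volume of the
#' same spot on the same gel. This is the DIGE internal-standard step: the
#' pooled Cy2 sample runs on every gel, so the ratio cancels gel-to-gel
#' scaling exactly. Spots lacking a Cy2 record on a gel are marked missing
#' for that gel only.
#'
#' @param tables combined spot-volume data.frame or named list of per-gel
#'   tables.
#' @return A data.frame `gel_id`, `spot_id`, `sample_id`, `ratio`; spots
#'   without Cy2 on a gel are absent (missing).
#' @export
normalize_internal_standard <- function(tables) {
  if (is.list(tables) && !is.data.frame(tables))
    tables <- do.call(rbind, tables)
  if (!nrow(tables)) stop("no spot-volume records to normalize")
  validate_spot_table(tables)
  out <- lapply(split(tables, tables$gel_id), function(g) {
    cy2 <- g[g$channel == "Cy2", ]
    if (!nrow(cy2))
      stop("gel ", g$gel_id[1], " has no Cy2 internal-standard channel")
    smp <- g[g$channel != "Cy2", ]
    std <- stats::setNames(cy2$volume, cy2$spot_id)
    keep <- smp$spot_id %in% names(std)
    smp <- smp[keep, , drop = FALSE]
    data.frame(gel_id = smp$gel_id, spot_id = smp$spot_id,
               sample_id = smp$sample_id,
               ratio = smp$volume / std[smp$spot_id],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Assemble the analysis expression matrix
#'
#' Drops samples flagged as failed labelings, pivots the normalized ratios
#' to a spots x samples matrix, drops features detected in fewer than
#' `min_presence` of the retained samples, log2-transforms, and imputes the
#' remaining missing cells with the feature median (observed cells are
#' never changed).
#'
#' @param ratios output of [normalize_internal_standard()].
#' @param design design data.frame with `sample_id`, `class`, `failed`.
#' @param min_presence minimum fraction of retained samples in which a
#'   feature must be observed.
#' @param spot_map optional data.frame `spot_id`, `protein` used to
#'   annotate features.
#' @return An [expression_matrix()].
#' @export
assemble_matrix <- function(ratios, design, min_presence = 0.8,
                            spot_map = NULL) {
  if (!nrow(ratios)) stop("empty ratio table: nothing to assemble")
  keep <- design[!design$failed, , drop = FALSE]
  ratios <- ratios[ratios$sample_id %in% keep$sample_id, , drop = FALSE]
  if (!nrow(ratios)) stop("no records left after excluding failed samples")
  spots <- sort(unique(ratios$spot_id))
  m <- matrix(NA_real_, length(spots), nrow(keep),
              dimnames = list(spots, keep$sample_id))
  m[cbind(ratios$spot_id, ratios$sample_id)] <- ratios$ratio
  pres <- rowMeans(!is.na(m))
  m <- m[pres >= min_presence, , drop = FALSE]
  if (!nrow(m)) stop("no features pass the presence filter")
  m <- log2(m)
  for (i in seq_len(nrow(m))) {
    na <- is.na(m[i, ])
    if (any(na)) m[i, na] <- stats::median(m[i, !na])
  }
  cls <- stats::setNames(keep$class, keep$sample_id)
  n_t <- sum(cls == "tumor"); n_b <- sum(cls == "benign")
  if (n_t < 2 || n_b < 2)
    stop("fewer than 2 samples in a class after exclusion (",
         n_t, " tumor, ", n_b, " benign)")
  message("assembled ", nrow(m), " features x ", ncol(m), " samples (",
          n_t, " tumor, ", n_b, " benign; ", sum(design$failed),
          " failed samples excluded)")
  protein <- NULL
  if (!is.null(spot_map))
    protein <- stats::setNames(spot_map$protein, spot_map$spot_id)[rownames(m)]
  expression_matrix(m, cls, protein)
}

#' Read a clinical-metadata table
#'
#' @param path TSV with columns `patient_id`, `tumor_stage`, `gleason`,
#'   `hormone_therapy`, `psa` ("NA" for missing).
#' @return A data.frame; `psa` numeric with NA for missing.
#' @export
read_clinical <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = "NA",
                           colClasses = list(patient_id = "character"))
  need <- c("patient_id", "tumor_stage", "gleason", "hormone_therapy", "psa")
  if (!all(need %in% names(tab)))
    stop("clinical table lacks columns: ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  tab$psa <- as.numeric(tab$psa)
  if (any(!is.na(tab$psa) & tab$psa <= 0))
    stop("PSA values must be positive when present")
  tab
}

#' Summarize a clinical table
#'
#' @param clinical data.frame from [read_clinical()].
#' @return A list: `n_patients`, `n_psa` (non-missing), `psa_mean` (2
#'   decimals), `psa_min`, `psa_max`, `stage_counts`.
#' @export
summarize_clinical <- function(clinical) {
  if (!nrow(clinical)) stop("clinical table is empty")
  psa <- clinical$psa[!is.na(clinical$psa)]
  if (!length(psa)) stop("no non-missing PSA values")
  list(n_patients = nrow(clinical),
       n_psa = length(psa),
       psa_mean = round(mean(psa), 2),
       psa_min = min(psa),
       psa_max = max(psa),
       stage_counts = table(clinical$tumor_stage, useNA = "ifany"))
}

#' Read the packaged tumor-group protein table
#'
#' A 26-row table of proteins differentially expressed between the two
#' tumor groups (gene symbol, protein name, log10 p of a two-sided t-test),
#' shipped with the package as a reference fixture.
#'
#' @param path path to the TSV; defaults to the packaged copy.
#' @return A data.frame `gene`, `protein`, `log10_p`.
#' @export
read_tumor_group_table <- function(path = system.file("extdata",
                                                      "tumor_group_proteins.tsv",
                                                      package = "digeclass",
                                                      mustWork = TRUE)) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write an ExpressionMatrix to disk
#'
#' TSV matrix (features x samples) plus a JSON sidecar with the class
#' labels and protein annotation.
#'
#' @param em an [expression_matrix()].
#' @param path base path; writes `<path>.tsv` and `<path>.json`.
#' @return Paths, invisibly.
#' @export
write_expression_matrix <- function(em, path) {
  tsv <- paste0(path, ".tsv"); js <- paste0(path, ".json")
  utils::write.table(data.frame(feature = rownames(em$values), em$values,
                                check.names = FALSE),
                     tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(class = as.list(stats::setNames(as.character(em$class),
                                                            names(em$class))),
                            protein = as.list(em$protein)),
                       js, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(tsv, js))
}
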