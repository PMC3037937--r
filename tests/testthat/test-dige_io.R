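spot_row <- function(gel = "G01", spot = "S001", channel = "Cy3",
                     sample = "T01", volume = 100) {
  data.frame(gel_id = gel, spot_id = spot, channel = channel,
             sample_id = sample, volume = volume, stringsAsFactors = FALSE)
}

test_that("spot tables round-trip losslessly through write/read", {
  st <- simulate_study(synthetic_params(seed = 4))
  dir <- withr::local_tempdir()
  paths <- write_spot_tables(st$tables, dir)
  tab <- read_spot_tables(paths)
  orig <- do.call(rbind, st$tables)
  rownames(orig) <- rownames(tab) <- NULL
  ord <- function(d) d[order(d$gel_id, d$spot_id, d$channel, d$sample_id), ]
  expect_equal(ord(tab), ord(orig), tolerance = 1e-12)
})

test_that("malformed spot tables are rejected with located errors", {
  dir <- withr::local_tempdir()
  bad1 <- rbind(spot_row(), spot_row(channel = "Cy2", sample = "POOL",
                                     volume = 0))
  f1 <- file.path(dir, "bad1.tsv")
  utils::write.table(bad1, f1, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_spot_tables(f1), "line 3")
  bad2 <- spot_row(channel = "Cy7")
  f2 <- file.path(dir, "bad2.tsv")
  utils::write.table(bad2, f2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_spot_tables(f2), "Cy7")
  bad3 <- rbind(spot_row(), spot_row())
  f3 <- file.path(dir, "bad3.tsv")
  utils::write.table(bad3, f3, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_spot_tables(f3), "duplicate")
})

test_that("normalization divides by the same-gel Cy2 volume", {
  tab <- rbind(spot_row(channel = "Cy2", sample = "POOL", volume = 100),
               spot_row(channel = "Cy3", sample = "T01", volume = 200),
               spot_row(channel = "Cy5", sample = "B01", volume = 50))
  r <- normalize_internal_standard(tab)
  expect_equal(r$ratio[r$sample_id == "T01"], 2.0)
  expect_equal(r$ratio[r$sample_id == "B01"], 0.5)
})

test_that("normalization is invariant to per-gel multiplicative scaling", {
  st <- simulate_study(synthetic_params(seed = 6))
  tab <- do.call(rbind, st$tables)
  base <- normalize_internal_standard(tab)
  set.seed(42)
  for (rep in 1:3) {
    scale_of <- setNames(2^runif(length(unique(tab$gel_id)), -3, 3),
                         unique(tab$gel_id))
    tab2 <- tab
    tab2$volume <- tab$volume * scale_of[tab$gel_id]
    r2 <- normalize_internal_standard(tab2)
    expect_equal(log2(r2$ratio), log2(base$ratio), tolerance = 1e-10)
  }
})

test_that("missing Cy2 marks only that (spot, gel) missing; no Cy2 at all errors", {
  tab <- rbind(spot_row(channel = "Cy2", sample = "POOL"),
               spot_row(channel = "Cy3", sample = "T01"),
               spot_row(spot = "S002", channel = "Cy3", sample = "T01"))
  r <- normalize_internal_standard(tab)
  expect_equal(r$spot_id, "S001")
  expect_error(
    normalize_internal_standard(spot_row(channel = "Cy3", sample = "T01")),
    "no Cy2")
})

test_that("default synthetic assembly keeps 45 samples (24 tumor, 21 benign)", {
  em <- default_study(seed = 1)$em
  expect_equal(ncol(em$values), 45)
  expect_equal(sum(em$class == "tumor"), 24)
  expect_equal(sum(em$class == "benign"), 21)
})

test_that("assembly equals log2 ratios when nothing is missing or failed", {
  tab <- rbind(spot_row(channel = "Cy2", sample = "POOL", volume = 100),
               spot_row(channel = "Cy3", sample = "T01", volume = 400),
               spot_row(channel = "Cy5", sample = "B01", volume = 25),
               spot_row(gel = "G02", channel = "Cy2", sample = "POOL",
                        volume = 10),
               spot_row(gel = "G02", channel = "Cy3", sample = "T02",
                        volume = 80),
               spot_row(gel = "G02", channel = "Cy5", sample = "B02",
                        volume = 5))
  design <- data.frame(sample_id = c("T01", "T02", "B01", "B02"),
                       class = c("tumor", "tumor", "benign", "benign"),
                       failed = FALSE, stringsAsFactors = FALSE)
  em <- suppressMessages(
    assemble_matrix(normalize_internal_standard(tab), design))
  expect_equal(unname(em$values["S001", c("T01", "T02", "B01", "B02")]),
               c(2, 3, -2, -1))
})

test_that("presence filter drops sparse features; imputation keeps observed cells", {
  st <- simulate_study(synthetic_params(seed = 8, missing_rate = 0))
  ratios <- normalize_internal_standard(st$tables)
  spot <- ratios$spot_id[1]
  keep_samples <- st$design$sample_id[!st$design$failed]
  # knock the first spot out of half the retained samples
  drop <- ratios$spot_id == spot &
    ratios$sample_id %in% keep_samples[1:23]
  em <- suppressMessages(assemble_matrix(ratios[!drop, ], st$design))
  expect_false(spot %in% rownames(em$values))
  # mild missingness: imputation must not change observed cells
  drop2 <- ratios$spot_id == spot & ratios$sample_id %in% keep_samples[1:3]
  em2 <- suppressMessages(assemble_matrix(ratios[!drop2, ], st$design))
  obs <- ratios[ratios$spot_id == spot &
                  ratios$sample_id %in% keep_samples[-(1:3)], ]
  expect_equal(em2$values[spot, obs$sample_id],
               setNames(log2(obs$ratio), obs$sample_id), tolerance = 1e-12)
  # imputed cells equal the feature median of observed log2 ratios
  expect_equal(unname(em2$values[spot, keep_samples[1:3]]),
               rep(stats::median(log2(obs$ratio)), 3), tolerance = 1e-12)
})

test_that("assembly errors when a class has fewer than 2 samples", {
  tab <- rbind(spot_row(channel = "Cy2", sample = "POOL"),
               spot_row(channel = "Cy3", sample = "T01"),
               spot_row(channel = "Cy5", sample = "B01"))
  design <- data.frame(sample_id = c("T01", "B01"),
                       class = c("tumor", "benign"), failed = FALSE,
                       stringsAsFactors = FALSE)
  expect_error(suppressMessages(
    assemble_matrix(normalize_internal_standard(tab), design)),
    "fewer than 2")
})

test_that("clinical summary matches the packaged metadata", {
  clin <- read_clinical(system.file("extdata", "clinical_metadata.tsv",
                                    package = "digeclass"))
  s <- summarize_clinical(clin)
  expect_equal(s$n_patients, 24)
  expect_equal(s$n_psa, 19)
  expect_equal(s$psa_mean, 10.93)
  expect_equal(s$psa_min, 3.9)
  expect_equal(s$psa_max, 30.4)
  one <- data.frame(patient_id = "X", tumor_stage = "pT2c", gleason = "3+4",
                    hormone_therapy = "No", psa = 5.0)
  s1 <- summarize_clinical(one)
  expect_equal(c(s1$psa_mean, s1$psa_min, s1$psa_max), c(5, 5, 5))
  expect_error(summarize_clinical(clin[0, ]), "empty")
})
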