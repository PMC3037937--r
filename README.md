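# digeclass

Statistical pipeline for 2D-DIGE tissue proteomics with a pooled Cy2
internal standard, built around a prostate tumor vs. benign study design:
internal-standard normalization, spot-wise differential expression,
clustering and partition analysis, outlier-robust PCA with a
projection/residual split of every protein profile, a 3-PC logistic
biomarker classifier with leave-one-out cross-validation, tumor-subgroup
identification, and random protein-panel averaging.

## Who this is for

Proteomics analysts who have per-gel spot-volume tables (gel, spot,
channel, sample, volume) from a DIGE experiment — or who want to study the
behaviour of this class of pipeline on simulated data. Raw gels from the
motivating study are not public, so the package includes a first-class
synthetic-study generator (`simulate_study()`) that emulates the design:
24 tumor + 24 benign samples on 24 gels with dye swap, 3 failed benign
labelings (45 analysis samples), ~79 proteins over ~111 spots, class signal
carried by three latent factors plus sparse direct 1.5-fold shifts.

## The model in brief

Log2 abundances are modelled as
`x_js = mu_j + sum_k l_jk f_ks + delta_j 1[tumor] + eps_js` (three latent
factors; factor 1 shifted 2 sd in tumors, factor 2 shifted 2 sd in a
10-sample tumor subgroup). The analysis splits each feature profile into
`x_i = x_p,i + x_r,i`, its projection onto the space S3 spanned by the
first three principal-component score vectors and the residual in the
complement CS3, and compares two-sided pooled t-tests on all three. A
logistic model on the three PC scores is evaluated by leave-one-out
cross-validation with the PCA refit inside every fold.

## Worked example

```r
library(digeclass)
study  <- simulate_study(synthetic_params(seed = 1))
ratios <- normalize_internal_standard(study$tables)
em     <- assemble_matrix(ratios, study$design, spot_map = study$spot_map)
#> assembled 109 features x 45 samples (24 tumor, 21 benign; 3 failed samples excluded)

de <- diffexp(em)                 # pooled t + 1.5-fold filter, raw p < 0.05
sum(de$significant)
#> [1] 54

model <- robust_pca(em, K = 3)    # two-step PCA: fit, drop outliers, refit
round(model$evar[1:3], 3)
#> [1] 0.429 0.328 0.147

loocv(em, K = 3)$accuracy         # 3-PC logit, PCA refit per fold
#> [1] 0.8888889
```

The 54 significant spots are those changing at least 1.5-fold with raw
p < 0.05; the three retained components explain ~90% of the variance (the
two class-linked factors plus one noise factor); 88.9% of held-out samples
are classified correctly — the median over ten simulation seeds is 86.7%,
matching the 86% real-data benchmark used as a floor.

A one-shot driver and CLI exist as well:

```r
res <- run_pipeline(synthetic_params(seed = 1), outdir = "dige_out")
```

```sh
inst/exec/dige-biomarker all --seed 1 --outdir dige_out   # after install
```

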