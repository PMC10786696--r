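# cfgvhd

Tissue-of-origin cell-free DNA (cfDNA) methylation analysis for chronic
graft-versus-host disease (cGVHD) after hematopoietic stem cell
transplantation (HCT).

## What it does, and for whom

Dying cells shed DNA into plasma, and every cell type carries a
characteristic DNA methylation signature. A genomic locus whose CpGs are
unmethylated *only* in one cell type is a marker for that tissue: after
bisulfite conversion, a sequenced molecule that reads unmethylated at all of
the locus's CpGs almost certainly derives from it. `cfgvhd` is for
computational biologists and transplant researchers who want to

1. **quantify** tissue-specific cfDNA from targeted bisulfite amplicon
   reads: per-molecule methylation-pattern calls with conversion QC,
   per-marker unmethylated fractions, per-tissue averages, and absolute
   loads in genome equivalents per mL plasma,

   `GE/mL = fraction × total cfDNA (ng/mL) × 1000 / 3.3 pg`,

2. **characterize assay sensitivity** by spike-in simulation — the smallest
   target-tissue fraction robustly detected above a leukocyte background,

3. **compare cohorts** of healthy controls and transplanted patients with
   and without cGVHD (Mann-Whitney comparisons, Spearman correlation
   matrices with significance stars), and

4. **model cGVHD** from 17 features (GGTp, ALP, ALT, AST, TBil, total
   cfDNA, and 11 tissue/immune cfDNA loads) with a
   **nonnegativity-constrained logistic regression** (slopes `β ≥ 0`,
   encoding that disease only elevates cell-death markers), **Shapley-value
   feature ranking** (closed form `φ_ij = β_j (x_ij − x̄_j)`, with an
   exhaustive-coalition oracle), and **repeated stratified 5-fold
   cross-validation** over nested feature sets.

A seeded synthetic-data module generates bisulfite amplicon reads for known
tissue mixtures (with a molecule-level truth table) and transplant cohort
tables with planted group effects, latent-factor correlation, NIH-style
organ scores and missing data — so the full pipeline is testable without
patient data. See the methods vignette
(`vignettes/cfdna-methylation-gvhd.Rmd`) for the model and every tunable
default.

## Worked example

Quantify a 2% liver spike-in from synthetic reads:

```r
library(cfgvhd)
panel <- example_panel()                      # 56 loci, 11 cell types
liver <- panel[panel$target_celltype == "liver", ]
spec  <- mixture_spec(c(liver = 0.02, leukocyte_other = 0.98),
                      reads_per_marker = 10000, seed = 1)
reads <- generate_reads(liver, spec)
quantify_sample(reads$reads, liver, total_cfdna_ng_per_ml = 10,
                references = reads$references)
#> tissue_profile (rule: all ; GE mass: 3.3 pg)
#>   celltype n_markers_used fraction ge_per_ml
#> 1    liver              5  0.01901      57.6
```

The 2% spike is recovered at 1.9% (the small deficit is the 0.5%/CpG
bisulfite-failure default) and converted to 57.6 genome equivalents per mL
at 10 ng/mL total cfDNA. The spike-in detection limit for the same panel:

```r
detection_limit(panel, "liver", grid = c(0.001, 0.0025, 0.005, 0.01, 0.02),
                seed = 1)
#> detection_limit: liver ( 5 markers, 10000 reads/marker )
#>   LOD (rate >= 0.95): 0.1%
#>   null false-detection rate: 0.030 (alpha 0.05)
#>   linearity slope: 0.978
```

Every grid fraction down to 0.1% is detected in 100% of replicates — the
multi-CpG rule leaves essentially no background — while 0% controls
false-alarm at about the test level (0.03 ≈ α = 0.05).

Model a synthetic cohort (25 healthy / 36 HCT without cGVHD / 65 with):

```r
cohort <- generate_cohort(cohort_spec(seed = 8))
pipe <- cgvhd_pipeline(cohort, seed = 8)       # rank, sweep, cross-validate
head(pipe$shapley$ranking, 4)
#>             feature mean_abs_shap rank  tied
#> 1       cf_monocyte     0.9224065    1 FALSE
#> 2               alt     0.7259657    2 FALSE
#> 3 cfdna_total_ng_ml     0.4916800    3 FALSE
#> 4           cf_treg     0.1644759    4 FALSE
pipe$sweep
#> feature_sweep: best set size 3 -> cf_monocyte, alt, cfdna_total_ng_ml
pipe$best
#> cv_report: 5-fold x 20 repeats, features: cf_monocyte, alt, cfdna_total_ng_ml
#>        metric  mean     sd
#> 1    accuracy 0.759 0.0787
#> 3 specificity 0.666 0.1498
#> 4         ppv 0.814 0.0744
#> 8         auc 0.823 0.0914
```

The three planted signal features (monocyte cfDNA, ALT, total cfDNA) rank
on top, the nested sweep selects exactly those three, and the chosen model
cross-validates at AUC 0.82 with specificity 0.67 and positive predictive
value 0.81. Selected sets fluctuate between sizes 2 and 4 across cohort
realizations at this sample size — see the vignette's limitations section.

Command-line wrappers for the three stages live in `inst/cli/`
(`quantify.R`, `cohort_stats.R`, `model.R`), e.g.

```sh
Rscript $(Rscript -e 'cat(system.file("cli", package="cfgvhd"))')/model.R \
  --table cohort.csv --repeats 20 --seed 1 --out model_out
```

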