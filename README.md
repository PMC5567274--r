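# lohscar

Locus-specific loss of heterozygosity (LOH) and genomic scar scores in
BRCA1/BRCA2 germline carrier tumors.

Tumors in carriers of heterozygous germline *BRCA1*/*BRCA2* mutations
usually lose the remaining wild-type allele — the second hit that
abolishes homologous-recombination repair and confers sensitivity to
platinum chemotherapy and PARP inhibitors. A meaningful minority retain
the wild-type allele; these tumors lack the genomic footprint of
homologous-recombination deficiency (HRD) and do worse on DNA-damaging
therapy. `lohscar` is for analysts working with tumor/normal whole-exome
data who need to (a) call locus-specific LOH and its mechanism per
sample, (b) quantify HRD "scars", and (c) relate the two to mutational
and clinical endpoints.

## What it computes

**The LOH call** combines three evidence sources at the carrier
mutation locus:

1. a two-sided Fisher exact test on the tumor-vs-normal ref/alt count
   table, plus an exact binomial test of tumor heterozygosity;
2. the allele-specific copy number (ASCN) state of the covering
   segment, with the mutant copy count `m` estimated by inverting the
   purity model
   `f = (p·m + (1−p)) / (p·CN + 2(1−p))`
   (the contaminating normal carries the variant heterozygously);
3. the purity-corrected allele-fraction difference from blood,
   ΔAF = m/CN − AF_blood, which breaks ties between the first two at
   the threshold ΔAF > 0.20.

Mechanisms follow the copy-state taxonomy: `(1,1)` LOH with deletion,
`(2,2)` copy-neutral LOH, `(CN≥3, m=CN)` LOH in gain, any retained
wild-type copy = absent LOH; an LOH-negative tumor with a pathogenic
somatic mutation in the same gene is reclassified as
absent-plus-somatic and grouped as biallelic.

**The scar scores**, from Sequenza-dialect segment tables:

- NtAI — allelic-imbalance segments > 11 Mb reaching a telomere
  without spanning the centromere;
- LST — transitions between ≥ 10 Mb segments after 3 Mb smoothing,
  ploidy-corrected as LSTm = LST − 15.5·ψ;
- HRD-LOH — LOH segments > 15 Mb excluding chromosome 17;
- HRD-Mean — the mean of the three.

**Cohort machinery**: carrier eligibility and somatic-variant filters
with per-rule rejection accounting, mutational burden per Mb,
artifact-signature exclusion, PTEN extrapolation, Grubbs-screened
pooled t-tests, Fisher exact, ANOVA/Tukey, Kaplan–Meier/log-rank and
Cox adjustment, and a synthetic 160-tumor cohort generator with known
ground truth that exercises every stage.

## Worked example

```r
library(lohscar)

# simulate a small carrier cohort on the built-in 3-chromosome genome
params <- sim_params(group_sizes = tibble::tibble(
  gene = c("BRCA1", "BRCA2"), site = c("ovary", "breast"), n = c(20, 20)))
sim <- simulate_cohort(params, seed = 7)

# HRD scar scores per sample
scores <- score_hrd(sim$cohort)
head(scores, 3)
#> # A tibble: 3 × 7
#>   sample  ntai   lst  lstm hrd_loh hrd_mean ploidy
#>   <chr>  <int> <int> <dbl>   <int>    <dbl>  <dbl>
#> 1 S001       1     2 -30.7       1    -9.58   2.11
#> 2 S002       6     5 -26.7       4    -5.56   2.04
#> 3 S003       6     5 -30.4       2    -7.46   2.28

# call locus-specific LOH and assign biallelic groups
kept <- filter_somatic_variants(sim$somatic_variants)$kept
calls <- call_locus_loh(sim$locus_observations, sim$cohort) |>
  assign_biallelic_group(kept[kept$gene %in% c("BRCA1", "BRCA2"), ])
table(calls$mechanism, calls$group_for_genomics)
#>                      BIALLELIC NON_BIALLELIC
#>   ABSENT                      0            11
#>   ABSENT_PLUS_SOMATIC         2             0
#>   CN_LOH                     17             0
#>   LOH_DELETION                5             0
#>   LOH_GAIN                    5             0

# do biallelic tumors carry more scar?
hi <- scores$hrd_mean[calls$group_for_genomics == "BIALLELIC"]
lo <- scores$hrd_mean[calls$group_for_genomics == "NON_BIALLELIC"]
compare_means_ttest(hi, lo, grubbs = TRUE)
#> # A tibble: 1 × 7
#>       t    df         p mean_a mean_b   n_a   n_b
#>   <dbl> <dbl>     <dbl>  <dbl>  <dbl> <int> <int>
#> 1  4.63    38 0.0000416  -7.93  -10.2     29    11
```

The mechanism table shows the familiar picture: copy-neutral LOH is
the most common route to biallelic loss, a minority of tumors retain
the wild-type allele (BRCA2-breast-enriched under the default mix),
and two tumors reach biallelic status through a somatic second hit
rather than LOH. The t-test shows the non-biallelic group carrying
significantly less genomic scar (HRD-Mean −10.2 vs −7.9, p ≈ 4e-5;
negative values are normal for near-diploid genomes because the
ploidy-corrected LSTm is LST − 31 at ploidy 2).

`run_pipeline(pipeline_config(...))` wires all stages together
(simulate/ingest → score → call → filter → statistics) and returns the
per-sample tables, the test results, truth-recovery rates, and a
reproducibility manifest.

## Documentation

The methods vignette (`vignettes/lohscar-methods.Rmd`) describes the
models, every threshold and its default, the generator's assumptions,
and known limitations. All user-facing functions carry roxygen
documentation.
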