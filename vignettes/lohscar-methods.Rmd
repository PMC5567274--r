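---
title: "Locus-specific LOH and genomic scar scores: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locus-specific LOH and genomic scar scores: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lohscar)
```

## The problem

Tumors arising in carriers of heterozygous germline BRCA1 or BRCA2
mutations are classically assumed to lose the remaining wild-type allele
("locus-specific loss of heterozygosity", LOH) — the second hit that
abolishes homologous-recombination repair and, with it, confers
sensitivity to platinum agents and PARP inhibitors. A substantial
minority of carrier tumors, however, retain the wild-type allele. Such
tumors lack the genomic footprint of homologous-recombination deficiency
(HRD) and respond poorly to DNA-damaging therapy, which makes
locus-specific LOH a candidate predictive biomarker.

`lohscar` implements the computational core of this analysis for
whole-exome data summarized as allele-specific copy number (ASCN)
segments and tumor/normal read counts:

1. calling locus-specific LOH and its mechanism from three evidence
   sources;
2. computing the three exome-based HRD scar scores and their mean;
3. the cohort and somatic-variant eligibility rules;
4. the group and survival statistics;
5. a synthetic cohort generator with known truth, so each stage has a
   measurable recovery target without controlled-access patient data.

## The LOH caller

### Evidence 1: tumor/normal allele counts

At the germline mutation locus we observe ref/alt read counts in blood
and tumor. `fisher_allele_test()` runs a two-sided Fisher exact test of
independence on the 2×2 table (is the tumor allele fraction different
from blood?) and a two-sided exact binomial test of the tumor alt count
against 0.5 (is the tumor still heterozygous?). The verdict is POSITIVE
when the shift is significant toward the mutant allele,
WILDTYPE_RETAINED when it is significant toward the wild-type allele
(the *mutant* copy was lost — still LOH as a genomic event, but negative
for the biomarker, since functional protein remains), NEGATIVE when not
significant, and INDETERMINATE when the tumor has no coverage. α = 0.05
for both tests (configurable via `loh_config()`).

### Evidence 2: the ASCN state

The segment covering the locus supplies the total copy number CN. With
tumor purity *p*, the contaminating normal cells carry the germline
variant heterozygously (1 mutant of 2 copies), so the expected tumor alt
fraction with *m* mutant copies is

$$f = \frac{p\,m + (1-p)}{p\,\mathrm{CN} + 2(1-p)}.$$

`purity_corrected_af()` inverts this for *m* given the observed
fraction, clamps to [0, CN], and reports the corrected fraction
$f_\mathrm{corr} = m/\mathrm{CN}$ and its difference from the blood
allele fraction, ΔAF. Rounding the continuous *m* gives the state
classified by `classify_ascn_state()`:

| CN | m | call |
|----|---|------|
| 1 | 1 | LOH with deletion |
| 2 | 2 | copy-neutral LOH |
| ≥3 | = CN | LOH in gain |
| ≥2 | 1 ≤ m < CN | absent LOH (wild-type allele retained) |
| any | 0 | wild-type-retained LOH |

Any retained wild-type copy means absent locus-specific LOH, including
gains with one mutant and several wild-type copies. Rounding ties at
exactly .5 go away from heterozygosity (toward the nearer of 0 or CN);
an unbiased tie rule matters because the heterozygous state sits exactly
between the two LOH states at low purity.

### The decision ladder

`call_locus_loh()` combines the routes: when both agree, the shared
status is final; when they disagree, ΔAF > 0.20 (strict) decides in
favor of LOH; when the count route is indeterminate (mutation seen only
in the normal), the call is positive only if the ASCN route is positive
*and* ΔAF clears the threshold. The mechanism label always comes from
the ASCN route, and `rule_path` records the branch, so every call is
auditable.

`assign_biallelic_group()` then forms the groups used for genomic
comparisons: a LOH-negative tumor with a pathogenic somatic mutation in
the same gene has its second hit by mutation and joins the biallelic
group (mechanism ABSENT_PLUS_SOMATIC). Promoter methylation does *not*
move a tumor into the biallelic group: bulk methylation assays cannot
phase the methylated allele and methylated tumors frequently retain
protein.

## The scar scores

All three scores are computed from ASCN segments (1-based closed
intervals, Sequenza dialect) against a genome build with centromere
intervals:

* **NtAI** (`score_ntai()`): allelic-imbalance segments (major ≠ minor
  count) longer than 11 Mb that reach a chromosome terminus without
  spanning the centromere. "Reaching the terminus" is operationalized
  as: the first/last segment of its chromosome, within 1 Mb of the
  chromosome end (both configurable). This reading — one arm, anchored
  at the telomere — is the established telomeric-AI construct.
* **LST** (`score_lst()`): per chromosome arm (segments split at the
  centromere midpoint), segments shorter than 3 Mb are smoothed out —
  iteratively, shortest first, merging equal-state neighbours, until
  stable — and a transition is counted at each junction between two
  smoothed segments of at least 10 Mb differing in (a, b) state. The
  ploidy-corrected score is LSTm = LST − 15.5 × ψ, applied literally:
  LSTm is negative for quiet diploid genomes (−31 at ψ = 2) and no
  floor is imposed.
* **HRD-LOH** (`score_hrd_loh()`): LOH segments (minor allele 0, total
  copies ≥ 1) longer than 15 Mb, excluding chromosome 17. The
  exclusion reflects near-universal chromosome 17 LOH in these tumors;
  whole-chromosome LOH elsewhere counts by default, with an
  `exclude_whole_chromosome_loh` switch because the score's original
  SNP-array formulation excluded it.
* **HRD-Mean** (`score_hrd()`): the mean of NtAI, LSTm and HRD-LOH.
  Whether the published mean used raw LST or LSTm is not stated in the
  source; LSTm is the default here and `hrd_config(hrd_mean_use_lstm =
  FALSE)` substitutes raw LST.

Chromosome X is excluded from all three scores by default (allele
states on X are ill-defined in males; the setting is exposed).
Homozygous deletions (CN = 0) are not LOH for the score. Gaps between
segments are tolerated; adjacency for smoothing is positional.

## Filters and burden

The somatic-variant filter chain evaluates, in a fixed order so
rejection tallies are deterministic: germline alt depth < 5; population
frequency < 1%; segmental-duplication fraction ≤ 0.89; not synonymous;
tumor alt depth > 10; then pathogenicity (D/LD kept, VUS only when
population frequency < 0.1%, benign dropped). Every threshold honors
the strict/non-strict form of its definition; the boundary unit tests
pin each one. Mutational burden is kept nonsynonymous mutations per
megabase; the callable footprint is not derivable from a variant table
and defaults to 30 Mb (the scale of a standard whole-exome capture),
shared with the generator so simulated burdens are recovered on the
same scale. Carrier eligibility (pathogenic, germline AF > 0.30, depth
> 30 in both samples), the non-carrier comparator exclusions, the
artifact-signature exclusion (R1–R3/U1–U2 sum > 30%, strict), and the
PTEN extrapolation rules (loss below two copies or truncating mutation
with copy-neutral LOH; retention for wild type at ≥ 2 copies with the
minor allele present; copy-neutral LOH without a mutation
indeterminate) are direct tabular implementations.

Floating-point note: "strict" thresholds on computed sums (the
artifact fraction, ΔAF) are evaluated with a 1e-9 guard so that a value
mathematically equal to the threshold is never pushed over it by
round-off.

## Statistics

Group means are compared with a pooled-variance two-tailed Student's t
(not Welch), Grubbs-screened per group first — the screen iterates the
extreme studentized deviate test at α = 0.05 until no point exceeds the
two-sided critical value. Rates use the two-tailed Fisher exact test;
three-group comparisons use ordinary one-way ANOVA with Tukey HSD on
the single pooled variance; survival uses Kaplan–Meier curves with the
log-rank (Mantel–Cox) test and a Cox proportional-hazards adjustment
(site, stage) via the `survival` package. Fitted survival objects carry
`tidy()`/`glance()`/`autoplot()` methods.

One calibration caveat is worth stating explicitly: the Fisher exact
test is conservative by construction — with discrete 2×2 support its
achieved size is strictly below the nominal α for any finite sample —
so its null rejection rate cannot be expected to match 0.05 the way the
t-test's and log-rank's do. The calibration tests assert the two-sided
Monte-Carlo band for t and log-rank, and for Fisher assert only that it
is not anti-conservative (plus a floor that rules out degenerate
implementations).

## The synthetic cohort

`sim_params()`/`simulate_cohort()` generate a 160-tumor carrier cohort
(93 BRCA1 / 67 BRCA2; 41/52/35/32 by gene × site) with known truth.
The generative choices and their sources:

* **Mechanism mix** — absent-LOH probability 10/7/46/16% for
  BRCA1-breast/BRCA1-ovary/BRCA2-breast/BRCA2-ovary, a 2%
  absent-plus-somatic rate in breast, and the remaining probability
  split over deletion : copy-neutral : gain as 17:36:31 (BRCA1) and
  14:20:11 (BRCA2) — the observed carrier-cohort proportions.
* **Locus counts** — purity ~ Beta(6, 3) clamped to [0.05, 0.99]
  (most mass between 0.35 and 0.9, as in purity-filtered FFPE/frozen
  cohorts); depths Poisson with means 141 (tumor) and 155 (normal);
  alt counts Binomial at the model fraction *f* above. The generator
  and the caller share the same *f* formula by construction, which is
  exactly what makes the recovery targets meaningful.
* **Segment profiles** — scar events placed on a diploid balanced
  backbone: telomeric AI segments (12–35 Mb), interstitial LOH
  (16–30 Mb) and interstitial state-change blocks (10–18 Mb), with
  Poisson counts per class. The default intensities (biallelic 6/6/6
  vs absent 0.5/0.5/1 events genome-wide) were set so the HRD-Mean
  separation between groups is about two pooled standard deviations on
  the 3-chromosome test genome — the magnitude of the published
  biallelic vs non-biallelic separation — and are deliberately not
  scaled by genome size. Placement retries a bounded number of times
  and silently drops events once the genome is geometrically saturated
  (the truth table records what was placed); erroring instead would
  abort whole-cohort simulations at a few-percent rate on the small
  test genome. Ploidy is the length-weighted mean copy number of the
  finished profile. Ploidy variation (whole-genome duplication) is
  *not* simulated: the event model does not couple LST rate to ploidy,
  so simulating WGD would let the 15.5 × ψ correction inject variance
  with no compensating signal — a known realism gap, listed under
  limitations.
* **Burden and TP53** — per gene × LOH group, nonsynonymous rates
  0.78/1.00 (BRCA1 biallelic/non) and 1.41/0.37 (BRCA2), TP53
  probabilities 0.84/0.44 and 0.68/0.24; the variant table also
  contains decoy rows that each violate exactly one filter rule, so
  the filter tallies are exercised.
* **Survival** — exponential with baseline median 45 months and hazard
  ratio 2.5 for non-biallelic ovarian tumors (breast hazards are
  group-independent), censoring Uniform(24, 120) months.
* **Signatures** — a three-signature proportion profile plus artifact
  signatures; 3% of samples draw an artifact fraction above the 30%
  exclusion threshold.

What passing tests on this cohort do **not** show: recovery on real
data with subclonal heterogeneity (the caller assumes one dominant
clone), FFPE artifacts, segmentation errors from Sequenza itself, or
mis-estimated purity — the generator feeds the caller the same purity
it simulated with. The synthetic cohort validates the logic, not the
wet-lab pipeline upstream of it.

## Numerical and design choices

* Coordinates: 1-based closed intervals throughout (Sequenza
  convention); a locus equal to a segment boundary is inside the
  segment.
* Chromosome names are normalized by stripping `chr`; Y and MT are
  dropped with a warning; non-integer copy numbers are rejected, not
  rounded — the caller owns discretization.
* Default BRCA loci (hg19): BRCA1 17q21 and BRCA2 13q13 gene
  footprints, overridable wherever a locus argument appears.
* Problem sizes in the test suite (a 3-chromosome genome, cohorts of
  50–160, 1000-profile fuzzing, 10⁴-replicate calibration) were chosen
  to make every statistical check reproducible in a routine test run.
* The exact-test semantics of the upstream variant caller this package
  stands in for are not reproduced read-for-read; the Fisher/binomial
  pair defined here is the package's own, documented contract, and the
  ΔAF inversion formula is likewise this package's explicit model of
  "cellularity-corrected allele frequency".

## Limitations

* Single dominant clone assumed; no subclonal deconvolution and no
  reversion-mutation detection.
* No segmentation of raw depth/BAF data and no hg38 support (the
  coordinate defaults are hg19).
* LSTm's ploidy correction is only as good as the ploidy estimate
  supplied in the metadata.
* The generator's distributional choices are explicit stand-ins: the
  source cohort is real tumors, not a generative model, so parameters
  were fixed from its reported summary statistics once and are not
  tuned per analysis.
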