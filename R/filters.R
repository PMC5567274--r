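#' Germline carrier eligibility at the mutation locus
#'
#' A tumor/normal pair qualifies as a germline BRCA1/BRCA2 carrier case
#' when the variant is classified pathogenic, the germline allele
#' fraction strictly exceeds 0.30, and total depth strictly exceeds 30 in
#' both germline and tumor at the locus.
#'
#' @param variants Tibble with columns `classification` (`"pathogenic"`
#'   counts, as do `"D"`/`"LD"`), `germline_af`, `germline_depth`,
#'   `tumor_depth`.
#' @param af_min,depth_min Thresholds (both strict).
#' @return The input with a logical `carrier` column.
#' @export
is_germline_carrier <- function(variants, af_min = 0.30, depth_min = 30) {
  v <- tibble::as_tibble(variants)
  v$carrier <- v$classification %in% c("pathogenic", "D", "LD") &
    v$germline_af > af_min &
    v$germline_depth > depth_min &
    v$tumor_depth > depth_min
  v
}

#' Somatic variant filters with per-rule rejection accounting
#'
#' Applies the somatic-call eligibility rules in a fixed order, so each
#' rejected variant is attributed to the first rule it fails and the
#' tallies partition the input: (1) germline alternate depth under 5
#' reads; (2) population frequency under 1%; (3) segmental-duplication
#' fraction at most 0.89 (the "high (>89%)" regions are excluded);
#' (4) not synonymous; (5) tumor alternate depth strictly over 10 reads;
#' (6) pathogenicity: deleterious (D) and likely deleterious (LD) kept,
#' variants of uncertain significance (VUS) kept only when rare
#' (population frequency under 0.1%), likely benign/benign dropped. A
#' missing value in a rule's field rejects the row under that rule.
#'
#' @param variants Tibble with columns `normal_alt_depth`, `pop_freq`,
#'   `segdup_frac`, `effect` (one of synonymous/missense/truncating/indel),
#'   `tumor_alt_depth`, `pathogenicity` (D/LD/VUS/LB/B).
#' @return List with `kept` (tibble) and `rejections` (tibble
#'   `rule`, `n`, ordered by evaluation).
#' @export
filter_somatic_variants <- function(variants) {
  v <- tibble::as_tibble(variants)
  rules <- list(
    germline_alt_depth = function(d) !is.na(d$normal_alt_depth) & d$normal_alt_depth < 5,
    population_freq    = function(d) !is.na(d$pop_freq) & d$pop_freq < 0.01,
    segmental_dup      = function(d) !is.na(d$segdup_frac) & d$segdup_frac <= 0.89,
    synonymous         = function(d) !is.na(d$effect) & d$effect != "synonymous",
    tumor_alt_depth    = function(d) !is.na(d$tumor_alt_depth) & d$tumor_alt_depth > 10,
    pathogenicity      = function(d) {
      !is.na(d$pathogenicity) & (
        d$pathogenicity %in% c("D", "LD") |
          (d$pathogenicity == "VUS" & !is.na(d$pop_freq) & d$pop_freq < 0.001)
      )
    }
  )
  alive <- rep(TRUE, nrow(v))
  tally <- integer(length(rules))
  names(tally) <- names(rules)
  for (r in names(rules)) {
    pass <- rules[[r]](v)
    newly_dead <- alive & !pass
    tally[[r]] <- sum(newly_dead)
    alive <- alive & pass
  }
  list(
    kept = v[alive, , drop = FALSE],
    rejections = tibble::tibble(rule = names(tally), n = unname(tally))
  )
}

#' Mutational burden in mutations per megabase
#'
#' Somatic nonsynonymous mutations divided by the callable exome
#' footprint. The footprint is not part of the variant table and must be
#' supplied; the default 30 Mb matches the scale of a standard whole-exome
#' capture design and is the constant the synthetic generator uses, so
#' simulated burdens are recovered on the same scale.
#'
#' @param kept_variants Tibble of filtered variants with `sample` and
#'   `effect` columns.
#' @param target_mb Callable footprint in Mb (> 0).
#' @param samples Optional character vector of sample ids so that samples
#'   with zero kept variants still appear with burden 0.
#' @return Tibble `sample`, `n_nonsynonymous`, `burden` (mutations/Mb).
#' @export
mutational_burden <- function(kept_variants, target_mb = 30, samples = NULL) {
  if (target_mb <= 0) stop("target_mb must be > 0", call. = FALSE)
  v <- tibble::as_tibble(kept_variants)
  v <- v[v$effect != "synonymous", , drop = FALSE]
  counts <- dplyr::count(v, .data$sample, name = "n_nonsynonymous")
  if (!is.null(samples)) {
    counts <- dplyr::left_join(tibble::tibble(sample = samples), counts,
      by = "sample")
    counts$n_nonsynonymous[is.na(counts$n_nonsynonymous)] <- 0L
  }
  dplyr::mutate(counts, burden = .data$n_nonsynonymous / target_mb)
}

#' Eligibility of tumors for the non-carrier comparison set
#'
#' Builds the "nonBRCA" comparator: tumors are excluded, with the first
#' matching reason, if they carry a pathogenic somatic BRCA1/2 mutation,
#' a homozygous BRCA1/2 deletion, transcriptional silencing (BRCA1:
#' expression z-score < -1.5 together with promoter methylation beta
#' > 0.5; BRCA2: z-score < -1.5), or (breast) prior neoadjuvant
#' chemotherapy.
#'
#' @param annotations Tibble with columns `sample`,
#'   `somatic_brca_pathogenic` (logical), `brca_homdel` (logical),
#'   `brca1_z`, `brca1_methylation_beta`, `brca2_z`, `neoadjuvant`
#'   (logical).
#' @return Tibble `sample`, `eligible` (logical), `reason` (NA when
#'   eligible).
#' @export
nonbrca_eligible <- function(annotations) {
  a <- tibble::as_tibble(annotations)
  reason <- dplyr::case_when(
    a$somatic_brca_pathogenic %in% TRUE ~ "somatic BRCA",
    a$brca_homdel %in% TRUE ~ "BRCA homozygous deletion",
    !is.na(a$brca1_z) & a$brca1_z < -1.5 &
      !is.na(a$brca1_methylation_beta) & a$brca1_methylation_beta > 0.5 ~
      "BRCA1 silenced",
    !is.na(a$brca2_z) & a$brca2_z < -1.5 ~ "BRCA2 low expression",
    a$neoadjuvant %in% TRUE ~ "neoadjuvant chemotherapy",
    TRUE ~ NA_character_
  )
  tibble::tibble(sample = a$sample, eligible = is.na(reason), reason = reason)
}

#' Exclude samples dominated by sequencing-artifact signatures
#'
#' A sample is excluded from genomic analyses when more than 30% of its
#' mutational-signature weight falls on the artifact signatures
#' (R1-R3, U1-U2). The threshold is strict: exactly 30% is kept.
#'
#' @param signatures Tibble with `sample` and one column per signature
#'   proportion (artifact columns named among
#'   `R1`, `R2`, `R3`, `U1`, `U2`).
#' @param threshold Exclusion threshold on the artifact sum (strict `>`).
#' @return Tibble `sample`, `artifact_fraction`, `excluded` (logical).
#' @export
artifact_fraction_excluded <- function(signatures, threshold = 0.30) {
  s <- tibble::as_tibble(signatures)
  art_cols <- intersect(c("R1", "R2", "R3", "U1", "U2"), names(s))
  frac <- if (length(art_cols) == 0) {
    rep(0, nrow(s))
  } else {
    rowSums(as.matrix(s[art_cols]), na.rm = TRUE)
  }
  # strict ">" with a guard against floating-point noise in the sum, so
  # a fraction of exactly 30% is kept even when 0.20 + 0.10 sums high
  tibble::tibble(
    sample = s$sample,
    artifact_fraction = frac,
    excluded = frac > threshold + 1e-9
  )
}

#' Extrapolate PTEN status from copy number and mutation
#'
#' PTEN loss is extrapolated from copy number loss (total copies under
#' two) or a truncating mutation on a copy-neutral LOH background;
#' retention from wild-type PTEN at copy number two or more with the
#' minor allele present. Copy-neutral LOH without an identified mutation
#' is indeterminate and excluded downstream (IHC concordance for that
#' state is poor).
#'
#' @param cn Total copy number at the PTEN locus.
#' @param b Minor allele copies.
#' @param mutation Effect of a somatic PTEN mutation (`"truncating"`,
#'   `"missense"`, ...) or `NA`/`"none"` for wild type.
#' @return Character vector: `"LOSS"`, `"RETAINED"`, `"INDETERMINATE"`.
#' @export
extrapolate_pten <- function(cn, b, mutation = NA_character_) {
  n <- max(length(cn), length(b), length(mutation))
  cn <- rep_len(cn, n); b <- rep_len(b, n); mutation <- rep_len(mutation, n)
  no_mut <- is.na(mutation) | mutation == "none"
  dplyr::case_when(
    cn < 2 ~ "LOSS",
    !no_mut & mutation == "truncating" & b == 0 ~ "LOSS",
    no_mut & cn >= 2 & b >= 1 ~ "RETAINED",
    no_mut & cn >= 2 & b == 0 ~ "INDETERMINATE",
    TRUE ~ "INDETERMINATE"
  )
}
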