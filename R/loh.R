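#' Configuration for the locus-specific LOH caller
#'
#' @param alpha Significance level for both exact tests (the variant-caller
#'   convention of 0.05).
#' @param delta_af_threshold Purity-corrected allele-fraction difference
#'   above which a discordant call is resolved LOH-positive (strict `>`).
#' @param round_ties_up When the purity-corrected mutant copy estimate
#'   lands exactly halfway between integers, ties round away from
#'   heterozygosity, toward the nearer of 0 or the total copy number;
#'   at exactly `cn/2` the tie goes up when `TRUE` (default).
#' @return Named list of class `loh_config`.
#' @export
loh_config <- function(alpha = 0.05, delta_af_threshold = 0.20,
                       round_ties_up = TRUE) {
  structure(
    list(alpha = alpha, delta_af_threshold = delta_af_threshold,
      round_ties_up = round_ties_up),
    class = "loh_config"
  )
}

#' Exact tests of tumor vs normal allele counts at a germline site
#'
#' The read-count evidence route of the LOH caller. `p_diff` is the
#' two-sided Fisher exact test of independence on the 2x2 table
#' (normal ref/alt vs tumor ref/alt) — significant when the tumor allele
#' fraction has shifted away from the blood fraction. `p_het` is the
#' two-sided exact binomial test of the tumor alt count against rate 0.5.
#' The verdict is `POSITIVE` (shift toward the mutant allele),
#' `WILDTYPE_RETAINED` (shift toward the wild-type allele), `NEGATIVE`
#' (no significant shift), or `INDETERMINATE` (zero tumor depth: the
#' mutation was only observed in the normal, and the allele-specific
#' copy number route must decide).
#'
#' @param normal_ref,normal_alt,tumor_ref,tumor_alt Read counts.
#' @param alpha Significance level.
#' @return Tibble: `p_diff`, `p_het`, `tumor_af`, `blood_af`, `verdict`.
#' @examples
#' fisher_allele_test(30, 30, 5, 55)
#' @export
fisher_allele_test <- function(normal_ref, normal_alt, tumor_ref, tumor_alt,
                               alpha = 0.05) {
  n <- vctrs_size(normal_ref, normal_alt, tumor_ref, tumor_alt)
  purrr::pmap_dfr(
    list(normal_ref, normal_alt, tumor_ref, tumor_alt),
    function(nr, na, tr, ta) {
      if (any(c(nr, na, tr, ta) < 0)) stop("negative read count", call. = FALSE)
      blood_af <- if (nr + na > 0) na / (nr + na) else NA_real_
      if (tr + ta == 0) {
        return(tibble::tibble(
          p_diff = NA_real_, p_het = NA_real_, tumor_af = NA_real_,
          blood_af = blood_af, verdict = "INDETERMINATE"
        ))
      }
      tumor_af <- ta / (tr + ta)
      p_diff <- stats::fisher.test(matrix(c(nr, na, tr, ta), nrow = 2,
        byrow = TRUE))$p.value
      p_het <- stats::binom.test(ta, tr + ta, p = 0.5)$p.value
      verdict <- if (p_diff < alpha && tumor_af > blood_af) {
        "POSITIVE"
      } else if (p_diff < alpha && tumor_af < blood_af) {
        "WILDTYPE_RETAINED"
      } else {
        "NEGATIVE"
      }
      tibble::tibble(p_diff = p_diff, p_het = p_het, tumor_af = tumor_af,
        blood_af = blood_af, verdict = verdict)
    }
  )
}

vctrs_size <- function(...) max(lengths(list(...)))

#' Purity-corrected allele fraction and its difference from blood
#'
#' In a specimen of purity `p`, the normal contamination carries the
#' germline variant heterozygously (1 mutant of 2 copies), so the
#' expected tumor alt fraction at a locus with total copy number `cn` and
#' `m` mutant copies is `f = (p*m + (1-p)) / (p*cn + 2*(1-p))`. This
#' function inverts that relation: from the observed fraction it returns
#' the continuous mutant-copy estimate `m_cont` (clamped to `[0, cn]`),
#' the corrected fraction `f_corr = m_cont / cn`, and
#' `delta_af = f_corr - blood_af`, the caller's tie-breaking statistic.
#'
#' @param f_obs Observed tumor alt fraction.
#' @param p Purity in (0, 1].
#' @param cn Total copy number at the locus (integer >= 1).
#' @param blood_af Germline allele fraction (observed, not assumed 0.5).
#' @return Tibble: `m_cont`, `f_corr`, `delta_af`.
#' @examples
#' purity_corrected_af(0.75, 0.5, 2, 0.5) # m_cont = 2, delta_af = 0.5
#' @export
purity_corrected_af <- function(f_obs, p, cn, blood_af) {
  if (any(p <= 0)) stop("purity must be > 0 (no tumor content)", call. = FALSE)
  if (any(p > 1)) stop("purity must be <= 1", call. = FALSE)
  if (any(cn < 1)) stop("cn must be >= 1", call. = FALSE)
  m_cont <- (f_obs * (p * cn + 2 * (1 - p)) - (1 - p)) / p
  m_cont <- pmin(pmax(m_cont, 0), cn)
  f_corr <- m_cont / cn
  tibble::tibble(m_cont = m_cont, f_corr = f_corr,
    delta_af = f_corr - blood_af)
}

#' Classify the allele-specific copy number state at the mutation locus
#'
#' The mechanism taxonomy: copy number one with one mutant allele is LOH
#' with deletion; copy number two with two mutant alleles is copy-neutral
#' LOH; copy number three or more with all alleles mutant is LOH in gain;
#' copy number two or more with at least one wild-type allele is absent
#' locus-specific LOH; zero mutant copies means the mutant allele itself
#' was lost (wild-type-retained LOH, an LOH-negative state for the
#' biomarker since the functional allele remains).
#'
#' @param cn Total copy number (integer >= 0).
#' @param m_hat Estimated mutant copies (integer, `0 <= m_hat <= cn`).
#' @return Character vector of mechanism labels.
#' @examples
#' classify_ascn_state(2, 2) # copy-neutral LOH
#' classify_ascn_state(4, 2) # absent (wildtype allele retained)
#' @export
classify_ascn_state <- function(cn, m_hat) {
  n <- max(length(cn), length(m_hat))
  cn <- rep_len(cn, n); m_hat <- rep_len(m_hat, n)
  if (any(m_hat > cn)) stop("m_hat exceeds cn", call. = FALSE)
  if (any(m_hat < 0) || any(cn < 0)) stop("negative copy state", call. = FALSE)
  dplyr::case_when(
    m_hat == 0               ~ "WILDTYPE_RETAINED_LOH",
    cn == 1 & m_hat == 1     ~ "LOH_DELETION",
    cn == 2 & m_hat == 2     ~ "CN_LOH",
    cn >= 3 & m_hat == cn    ~ "LOH_GAIN",
    cn >= 2 & m_hat < cn     ~ "ABSENT",
    TRUE                     ~ "INDETERMINATE"  # cn = 0
  )
}

mechanism_is_loh <- function(mechanism) {
  mechanism %in% c("LOH_DELETION", "CN_LOH", "LOH_GAIN")
}

#' Call locus-specific LOH for carrier mutations
#'
#' Combines the two evidence routes with the decision ladder: (i) the
#' exact-test verdict ([fisher_allele_test()]) and the allele-specific
#' copy number state ([classify_ascn_state()] on the segment covering the
#' locus, with mutant copies estimated by [purity_corrected_af()]) each
#' imply a status; (ii) when they agree that status is final; (iii) when
#' they disagree the purity-corrected allele-fraction difference decides —
#' positive iff `delta_af` strictly exceeds the threshold (default 0.20);
#' (iv) when the read-count route is indeterminate (mutation seen only in
#' the normal), positive iff the copy number route is positive *and*
#' `delta_af` exceeds the threshold. The mechanism label always comes from
#' the copy number route; `rule_path` records which branch fired.
#'
#' @param observations Tibble with columns `sample`, `gene`, `chromosome`,
#'   `position`, `normal_ref`, `normal_alt`, `tumor_ref`, `tumor_alt`, and
#'   optionally `classification` (non-pathogenic rows trigger a warning
#'   but are still called).
#' @param cohort A `tumor_cohort` from [read_segments()] (or the
#'   simulator) covering the same samples.
#' @param config A [loh_config()].
#' @return A `loh_calls` tibble: one row per observation with `status`
#'   (`LOH_POSITIVE`/`LOH_NEGATIVE`/`INDETERMINATE`), `mechanism`,
#'   `rule_path`, and the evidence columns (`p_diff`, `p_het`, `cn`,
#'   `m_hat`, `f_corr`, `delta_af`, `purity`).
#' @export
call_locus_loh <- function(observations, cohort, config = loh_config()) {
  obs <- tibble::as_tibble(observations)
  needed <- c("sample", "gene", "chromosome", "position",
    "normal_ref", "normal_alt", "tumor_ref", "tumor_alt")
  missing <- setdiff(needed, names(obs))
  if (length(missing) > 0) {
    stop("observations lack column(s): ", paste(missing, collapse = ", "),
      call. = FALSE)
  }
  if ("classification" %in% names(obs)) {
    notpath <- !obs$classification %in% c("pathogenic", "D", "LD")
    if (any(notpath)) {
      warning(sum(notpath), " observation(s) with non-pathogenic ",
        "classification; calls produced anyway", call. = FALSE)
    }
  }
  meta <- cohort$meta
  out <- purrr::pmap_dfr(
    list(seq_len(nrow(obs))),
    function(i) {
      o <- obs[i, ]
      if (!o$sample %in% meta$sample) {
        stop("no purity/ploidy metadata for sample ", o$sample, call. = FALSE)
      }
      p <- meta$purity[meta$sample == o$sample]
      ft <- fisher_allele_test(o$normal_ref, o$normal_alt,
        o$tumor_ref, o$tumor_alt, alpha = config$alpha)
      seg <- segment_at(cohort$segments, o$chromosome, o$position,
        sample = o$sample)
      if (nrow(seg) == 0) {
        return(tibble::tibble(
          sample = o$sample, gene = o$gene, status = "INDETERMINATE",
          mechanism = "INDETERMINATE", rule_path = "no_segment_at_locus",
          p_diff = ft$p_diff, p_het = ft$p_het, cn = NA_real_,
          m_hat = NA_real_, f_corr = NA_real_, delta_af = NA_real_,
          purity = p
        ))
      }
      cn <- seg$cnt
      if (cn < 1) {
        # homozygous deletion of the locus: no alleles left to type
        return(tibble::tibble(
          sample = o$sample, gene = o$gene, status = "INDETERMINATE",
          mechanism = "INDETERMINATE", rule_path = "cn_zero",
          p_diff = ft$p_diff, p_het = ft$p_het, cn = cn, m_hat = 0,
          f_corr = NA_real_, delta_af = NA_real_, purity = p
        ))
      }
      blood_af <- ft$blood_af
      f_obs <- ft$tumor_af
      if (is.na(f_obs)) {
        # Mutect-normal branch: no tumor reads; ASCN + delta_af decide.
        # b = 0 means all remaining copies are one allele; under the
        # carrier model that is the mutant allele, so f_corr = 1. b > 0
        # means heterozygosity is retained: absent LOH.
        if (seg$b == 0) {
          m_hat <- cn
          mech <- classify_ascn_state(cn, m_hat)
          f_corr <- 1
          delta <- f_corr - blood_af
        } else {
          m_hat <- NA_real_
          mech <- "ABSENT"
          f_corr <- NA_real_
          delta <- NA_real_
        }
        pos <- !is.na(delta) && mechanism_is_loh(mech) &&
          delta > config$delta_af_threshold
        return(tibble::tibble(
          sample = o$sample, gene = o$gene,
          status = if (isTRUE(pos)) "LOH_POSITIVE" else "LOH_NEGATIVE",
          mechanism = mech, rule_path = "indeterminate:ascn+deltaAF",
          p_diff = ft$p_diff, p_het = ft$p_het, cn = cn,
          m_hat = m_hat, f_corr = f_corr, delta_af = delta, purity = p
        ))
      }
      pc <- purity_corrected_af(f_obs, p, cn, blood_af)
      m_hat <- round_mutant_copies(pc$m_cont, cn, config$round_ties_up)
      mech <- classify_ascn_state(cn, m_hat)
      ascn_pos <- mechanism_is_loh(mech)
      fisher_pos <- ft$verdict == "POSITIVE"
      fisher_neg <- ft$verdict %in% c("NEGATIVE", "WILDTYPE_RETAINED")
      if (fisher_pos && ascn_pos) {
        status <- "LOH_POSITIVE"; path <- "concordant"
      } else if (fisher_neg && !ascn_pos) {
        status <- "LOH_NEGATIVE"; path <- "concordant"
      } else {
        status <- if (pc$delta_af > config$delta_af_threshold) {
          "LOH_POSITIVE"
        } else {
          "LOH_NEGATIVE"
        }
        path <- "discordant:deltaAF"
      }
      tibble::tibble(
        sample = o$sample, gene = o$gene, status = status, mechanism = mech,
        rule_path = path, p_diff = ft$p_diff, p_het = ft$p_het, cn = cn,
        m_hat = m_hat, f_corr = pc$f_corr, delta_af = pc$delta_af, purity = p
      )
    }
  )
  class(out) <- c("loh_calls", class(out))
  out
}

# Round the continuous mutant-copy estimate to an integer in [0, cn].
# Exact .5 ties round away from heterozygosity (toward the nearer of
# 0 or cn); a tie at exactly cn/2 goes up when ties_up.
round_mutant_copies <- function(m_cont, cn, ties_up = TRUE) {
  purrr::map2_dbl(m_cont, cn, function(m, k) {
    lower <- floor(m)
    frac <- m - lower
    if (isTRUE(all.equal(frac, 0.5))) {
      half <- k / 2
      if (m < half) {
        r <- lower          # toward 0
      } else if (m > half) {
        r <- lower + 1      # toward cn
      } else {
        r <- if (ties_up) lower + 1 else lower
      }
    } else {
      r <- round(m)
    }
    min(max(r, 0), k)
  })
}

#' Assign the biallelic-inactivation group used for genomic analyses
#'
#' LOH-positive tumors are biallelic. An LOH-negative tumor with a
#' pathogenic somatic mutation in the same gene has its second hit by
#' mutation rather than LOH: its mechanism becomes
#' `ABSENT_PLUS_SOMATIC` and it joins the biallelic group. Promoter
#' methylation does *not* move an LOH-negative tumor into the biallelic
#' group (methylation cannot be phased to the wild-type allele by bulk
#' assays, and protein is often retained).
#'
#' @param calls An `loh_calls` tibble from [call_locus_loh()].
#' @param somatic_variants Optional tibble of filtered somatic variants
#'   (`sample`, `gene`, `pathogenicity`); rows with pathogenicity `D` or
#'   `LD` in the carrier's gene count as somatic second hits.
#' @param methylation Optional tibble `sample`, `methylated` (logical).
#'   Recorded but never changes the group.
#' @return The calls tibble with `group_for_genomics`
#'   (`BIALLELIC`/`NON_BIALLELIC`) and updated `mechanism`.
#' @export
assign_biallelic_group <- function(calls, somatic_variants = NULL,
                                   methylation = NULL) {
  out <- tibble::as_tibble(calls)
  hit <- rep(FALSE, nrow(out))
  if (!is.null(somatic_variants) && nrow(somatic_variants) > 0) {
    sv <- somatic_variants
    if (!"pathogenicity" %in% names(sv)) sv$pathogenicity <- "D"
    sv <- sv[sv$pathogenicity %in% c("D", "LD", "pathogenic"), , drop = FALSE]
    key <- paste(sv$sample, sv$gene)
    hit <- paste(out$sample, out$gene) %in% key
  }
  somatic_second <- out$status == "LOH_NEGATIVE" & hit
  out$mechanism[somatic_second] <- "ABSENT_PLUS_SOMATIC"
  out$group_for_genomics <- dplyr::if_else(
    out$status == "LOH_POSITIVE" | somatic_second,
    "BIALLELIC", "NON_BIALLELIC"
  )
  if (!is.null(methylation)) {
    out <- dplyr::left_join(out, methylation, by = "sample")
  }
  class(out) <- c("loh_calls", class(out))
  out
}
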