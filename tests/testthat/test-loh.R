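one_segment_cohort <- function(a, b, purity, id = "s1", genome = mini) {
  seg <- tibble::tibble(sample = id, chromosome = "1", start = 1,
    end = genome$length[1], cnt = a + b, a = a, b = b,
    length = genome$length[1], loh = b == 0 & (a + b) >= 1, ai = a != b)
  meta <- tibble::tibble(sample = id, purity = purity, ploidy = 2)
  lohscar:::new_tumor_cohort(seg, meta, genome)
}

obs_row <- function(nr, na, tr, ta, id = "s1", gene = "BRCA1") {
  tibble::tibble(sample = id, gene = gene, chromosome = "1", position = 50e6,
    classification = "pathogenic",
    normal_ref = nr, normal_alt = na, tumor_ref = tr, tumor_alt = ta)
}

test_that("exact allele test distinguishes shift direction", {
  r <- fisher_allele_test(30, 30, 5, 55)
  expect_lt(r$p_diff, 1e-4)
  expect_equal(r$verdict, "POSITIVE")
  expect_equal(r$tumor_af, 55 / 60)

  r <- fisher_allele_test(30, 30, 30, 30)
  expect_equal(r$p_diff, 1)
  expect_equal(r$verdict, "NEGATIVE")

  # mirror image of the positive case: wild-type allele enriched
  r <- fisher_allele_test(30, 30, 55, 5)
  expect_lt(r$p_diff, 1e-4)
  expect_equal(r$verdict, "WILDTYPE_RETAINED")

  r <- fisher_allele_test(30, 30, 0, 0)
  expect_equal(r$verdict, "INDETERMINATE")

  expect_error(fisher_allele_test(-1, 30, 5, 5), "negative")
})

test_that("exact test p-value matches hypergeometric enumeration", {
  set.seed(5)
  for (i in 1:50) {
    m <- matrix(sample(0:20, 4, replace = TRUE), 2)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) next
    r <- fisher_allele_test(m[1, 1], m[1, 2], m[2, 1], m[2, 2])
    expect_equal(r$p_diff, oracle_fisher_2x2(m), tolerance = 1e-8)
  }
})

test_that("purity correction inverts the contamination model exactly", {
  r <- purity_corrected_af(0.75, 0.5, 2, 0.5)
  expect_equal(r$m_cont, 2)
  expect_equal(r$f_corr, 1)
  expect_equal(r$delta_af, 0.5)

  # heterozygous fixed point: f_obs = 0.5 maps to m = 1 at any purity
  for (p in c(0.2, 0.5, 0.9, 1)) {
    expect_equal(purity_corrected_af(0.5, p, 2, 0.5)$m_cont, 1)
    expect_equal(purity_corrected_af(0.5, p, 2, 0.5)$delta_af, 0)
  }

  # inverse of the generative formula for a deletion at half purity
  expect_equal(purity_corrected_af(2 / 3, 0.5, 1, 0.5)$m_cont, 1)
  expect_equal(purity_corrected_af(2 / 3, 0.5, 1, 0.5)$f_corr, 1)

  expect_error(purity_corrected_af(0.5, 0, 2, 0.5), "purity")
  expect_error(purity_corrected_af(0.5, 0.5, 0, 0.5), "cn")

  # clamping
  expect_equal(purity_corrected_af(1, 0.5, 2, 0.5)$m_cont, 2)
  expect_equal(purity_corrected_af(0, 0.5, 2, 0.5)$m_cont, 0)
})

test_that("mechanism taxonomy follows the copy-state definitions", {
  expect_equal(classify_ascn_state(1, 1), "LOH_DELETION")
  expect_equal(classify_ascn_state(2, 2), "CN_LOH")
  expect_equal(classify_ascn_state(3, 3), "LOH_GAIN")
  expect_equal(classify_ascn_state(5, 5), "LOH_GAIN")
  expect_equal(classify_ascn_state(4, 2), "ABSENT")
  expect_equal(classify_ascn_state(2, 1), "ABSENT")
  expect_equal(classify_ascn_state(1, 0), "WILDTYPE_RETAINED_LOH")
  expect_equal(classify_ascn_state(3, 0), "WILDTYPE_RETAINED_LOH")
  expect_error(classify_ascn_state(2, 3), "exceeds")
})

test_that("mutant-copy rounding breaks ties away from heterozygosity", {
  rmc <- lohscar:::round_mutant_copies
  expect_equal(rmc(1.5, 2), 2)   # above cn/2: toward cn
  expect_equal(rmc(0.5, 2), 0)   # below cn/2: toward 0
  expect_equal(rmc(1.5, 3), 2)   # exactly cn/2: up by default
  expect_equal(rmc(1.5, 3, ties_up = FALSE), 1)
  expect_equal(rmc(2.5, 3), 3)
  expect_equal(rmc(1.2, 2), 1)   # ordinary rounding otherwise
  expect_equal(rmc(3.7, 3), 3)   # clamped to cn
})

test_that("concordant evidence produces direct calls", {
  set.seed(21)
  # copy-neutral LOH at purity 0.7: both routes positive
  co <- one_segment_cohort(2, 0, purity = 0.7)
  sim <- simulate_locus_observation("CN_LOH", 0.7)
  obs <- dplyr::bind_cols(obs_row(0, 0, 0, 0)[, 1:5], sim$observation)
  call <- call_locus_loh(obs, co)
  expect_equal(call$status, "LOH_POSITIVE")
  expect_equal(call$mechanism, "CN_LOH")
  expect_equal(call$rule_path, "concordant")

  # retained heterozygosity: both routes negative
  co <- one_segment_cohort(1, 1, purity = 0.7)
  obs <- obs_row(77, 78, 70, 71)
  call <- call_locus_loh(obs, co)
  expect_equal(call$status, "LOH_NEGATIVE")
  expect_equal(call$mechanism, "ABSENT")
  expect_equal(call$rule_path, "concordant")
})

test_that("discordant evidence is resolved by the corrected AF difference", {
  # low purity LOH-in-gain: counts too thin for significance, ASCN positive
  co <- one_segment_cohort(3, 0, purity = 0.3)
  obs <- obs_row(50, 50, 4, 8)
  ft <- fisher_allele_test(50, 50, 4, 8)
  expect_equal(ft$verdict, "NEGATIVE")  # premise of the discordance
  call <- call_locus_loh(obs, co)
  expect_equal(call$rule_path, "discordant:deltaAF")
  expect_equal(call$mechanism, "LOH_GAIN")
  expect_gt(call$delta_af, 0.2)
  expect_equal(call$status, "LOH_POSITIVE")

  # delta exactly at the threshold stays negative (strict >)
  co <- one_segment_cohort(1, 1, purity = 1)
  obs <- obs_row(50, 50, 30, 70)
  call <- call_locus_loh(obs, co)
  expect_equal(call$rule_path, "discordant:deltaAF")
  expect_equal(call$delta_af, 0.2)
  expect_equal(call$status, "LOH_NEGATIVE")

  # a hair above the threshold flips it
  obs <- obs_row(50, 50, 29, 71)
  call <- call_locus_loh(obs, co)
  expect_equal(call$status, "LOH_POSITIVE")
})

test_that("zero tumor depth falls back to ASCN plus corrected AF", {
  co <- one_segment_cohort(2, 0, purity = 0.8)
  obs <- obs_row(50, 50, 0, 0)
  call <- call_locus_loh(obs, co)
  expect_equal(call$rule_path, "indeterminate:ascn+deltaAF")
  expect_equal(call$status, "LOH_POSITIVE")
  expect_equal(call$mechanism, "CN_LOH")

  co <- one_segment_cohort(1, 1, purity = 0.8)
  call <- call_locus_loh(obs, co)
  expect_equal(call$status, "LOH_NEGATIVE")
  expect_equal(call$mechanism, "ABSENT")
})

test_that("locus in a segment gap yields an indeterminate call", {
  seg <- tibble::tibble(sample = "s1", chromosome = "1", start = 1,
    end = 10e6, cnt = 2, a = 1, b = 1, length = 10e6, loh = FALSE, ai = FALSE)
  meta <- tibble::tibble(sample = "s1", purity = 0.7, ploidy = 2)
  co <- lohscar:::new_tumor_cohort(seg, meta, mini)
  call <- call_locus_loh(obs_row(50, 50, 40, 60), co)
  expect_equal(call$status, "INDETERMINATE")
  expect_equal(call$rule_path, "no_segment_at_locus")
})

test_that("non-pathogenic classification warns but still calls", {
  co <- one_segment_cohort(2, 0, purity = 0.7)
  obs <- obs_row(50, 50, 10, 90)
  obs$classification <- "VUS"
  expect_warning(call <- call_locus_loh(obs, co), "non-pathogenic")
  expect_equal(call$status, "LOH_POSITIVE")
})

test_that("somatic second hits join the biallelic group; methylation does not", {
  co <- one_segment_cohort(1, 1, purity = 0.9, id = "s1")
  calls <- call_locus_loh(obs_row(60, 60, 55, 55, id = "s1", gene = "BRCA2"), co)
  expect_equal(calls$status, "LOH_NEGATIVE")

  somatic <- tibble::tibble(sample = "s1", gene = "BRCA2",
    pathogenicity = "D", af = 0.35)
  out <- assign_biallelic_group(calls, somatic)
  expect_equal(out$mechanism, "ABSENT_PLUS_SOMATIC")
  expect_equal(out$group_for_genomics, "BIALLELIC")

  meth <- tibble::tibble(sample = "s1", methylated = TRUE)
  out2 <- assign_biallelic_group(calls, somatic_variants = NULL,
    methylation = meth)
  expect_equal(out2$group_for_genomics, "NON_BIALLELIC")

  # a somatic hit in the *other* gene does not rescue
  other <- tibble::tibble(sample = "s1", gene = "BRCA1", pathogenicity = "D")
  out3 <- assign_biallelic_group(calls, other)
  expect_equal(out3$group_for_genomics, "NON_BIALLELIC")

  # LOH-positive tumors are biallelic regardless
  co <- one_segment_cohort(2, 0, purity = 0.9)
  pos <- call_locus_loh(obs_row(60, 60, 10, 110), co)
  out4 <- assign_biallelic_group(pos)
  expect_equal(out4$group_for_genomics, "BIALLELIC")
})

test_that("purity one and extreme depth recover every mechanism exactly", {
  set.seed(8)
  for (mech in c("LOH_DELETION", "CN_LOH", "LOH_GAIN", "ABSENT",
                 "ABSENT_PLUS_SOMATIC")) {
    st <- lohscar:::mechanism_state(mech)
    co <- one_segment_cohort(st$a, st$b, purity = 1)
    sim <- simulate_locus_observation(mech, 1, depth_tumor = 1e6,
      depth_normal = 1e6)
    obs <- dplyr::bind_cols(obs_row(0, 0, 0, 0)[, 1:5], sim$observation)
    call <- call_locus_loh(obs, co)
    somatic <- if (mech == "ABSENT_PLUS_SOMATIC") {
      tibble::tibble(sample = "s1", gene = "BRCA1", pathogenicity = "D")
    } else {
      NULL
    }
    call <- assign_biallelic_group(call, somatic)
    expect_equal(call$mechanism, mech)
    expect_equal(call$status == "LOH_POSITIVE",
      lohscar:::mechanism_is_loh(mech))
  }
})
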