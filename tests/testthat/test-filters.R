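test_that("carrier criteria are strict at the stated boundaries", {
  v <- tibble::tibble(
    classification = c("pathogenic", "pathogenic", "VUS", "pathogenic",
      "pathogenic"),
    germline_af = c(0.45, 0.30, 0.50, 0.31, 0.45),
    germline_depth = c(100, 100, 200, 30, 100),
    tumor_depth = c(120, 120, 200, 100, 31)
  )
  out <- is_germline_carrier(v)
  expect_equal(out$carrier, c(TRUE, FALSE, FALSE, FALSE, TRUE))
})

pass_variant <- function(n = 1) {
  tibble::tibble(
    sample = "s1", gene = "G", effect = "missense", pathogenicity = "D",
    pop_freq = 0, segdup_frac = 0.1, normal_alt_depth = 0,
    tumor_alt_depth = 40, af = 0.3
  )[rep(1, n), ]
}

test_that("somatic filters apply each rule with quoted strictness", {
  v <- pass_variant()
  expect_equal(nrow(filter_somatic_variants(v)$kept), 1)

  boundary <- function(col, val) {
    x <- pass_variant(); x[[col]] <- val; x
  }
  # tumor alt exactly 10 fails; 11 passes
  expect_equal(nrow(filter_somatic_variants(
    boundary("tumor_alt_depth", 10))$kept), 0)
  expect_equal(nrow(filter_somatic_variants(
    boundary("tumor_alt_depth", 11))$kept), 1)
  # germline alt 5 fails; 4 passes
  expect_equal(nrow(filter_somatic_variants(
    boundary("normal_alt_depth", 5))$kept), 0)
  expect_equal(nrow(filter_somatic_variants(
    boundary("normal_alt_depth", 4))$kept), 1)
  # population frequency 1% fails; segdup 0.89 passes, 0.90 fails
  expect_equal(nrow(filter_somatic_variants(
    boundary("pop_freq", 0.01))$kept), 0)
  expect_equal(nrow(filter_somatic_variants(
    boundary("segdup_frac", 0.89))$kept), 1)
  expect_equal(nrow(filter_somatic_variants(
    boundary("segdup_frac", 0.90))$kept), 0)
  # synonymous always drops
  expect_equal(nrow(filter_somatic_variants(
    boundary("effect", "synonymous"))$kept), 0)
  # VUS kept only when population frequency < 0.1%
  vus <- pass_variant(); vus$pathogenicity <- "VUS"; vus$pop_freq <- 0.005
  expect_equal(nrow(filter_somatic_variants(vus)$kept), 0)
  vus$pop_freq <- 0.0005
  expect_equal(nrow(filter_somatic_variants(vus)$kept), 1)
  # benign always drops
  expect_equal(nrow(filter_somatic_variants(
    boundary("pathogenicity", "B"))$kept), 0)
})

test_that("rejections partition the input by first failing rule", {
  set.seed(31)
  sim <- simulate_cohort(sim_params(), seed = 77)
  out <- filter_somatic_variants(sim$somatic_variants)
  expect_equal(nrow(out$kept) + sum(out$rejections$n),
    nrow(sim$somatic_variants))
  # every decoy class appears
  expect_true(all(out$rejections$n > 0))
})

test_that("missing filter fields reject under their own rule", {
  x <- pass_variant(); x$pop_freq <- NA
  out <- filter_somatic_variants(x)
  expect_equal(nrow(out$kept), 0)
  expect_equal(out$rejections$n[out$rejections$rule == "population_freq"], 1)
})

test_that("mutational burden is kept nonsynonymous count over footprint", {
  v <- pass_variant(30)
  expect_equal(mutational_burden(v, 30)$burden, 1)
  expect_equal(
    mutational_burden(v[0, ], 30, samples = "s1")$burden, 0)
  expect_error(mutational_burden(v, 0), "target_mb")
  # synonymous rows never count even if present in the input
  v2 <- dplyr::bind_rows(v, {
    s <- pass_variant(5); s$effect <- "synonymous"; s
  })
  expect_equal(mutational_burden(v2, 30)$burden, 1)
})

test_that("simulated cohort burden recovers the configured rate", {
  p <- sim_params(
    burden_rate = tibble::tibble(
      gene = c("BRCA1", "BRCA1", "BRCA2", "BRCA2"),
      group = c("BIALLELIC", "NON_BIALLELIC", "BIALLELIC", "NON_BIALLELIC"),
      rate = 1.0
    )
  )
  sim <- simulate_cohort(p, seed = 123)
  kept <- filter_somatic_variants(sim$somatic_variants)$kept
  b <- mutational_burden(kept, p$target_mb, samples = sim$cohort$meta$sample)
  se <- stats::sd(b$burden) / sqrt(nrow(b))
  expect_lt(abs(mean(b$burden) - 1.0), 3 * se)
})

test_that("non-carrier comparator exclusions fire in documented order", {
  ann <- tibble::tibble(
    sample = paste0("n", 1:6),
    somatic_brca_pathogenic = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
    brca_homdel = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
    brca1_z = c(0, 0, -2.0, -2.0, 0, 0),
    brca1_methylation_beta = c(0, 0, 0.7, 0.3, 0, 0),
    brca2_z = c(0, 0, 0, -2.0, 0, 0),
    neoadjuvant = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE)
  )
  out <- nonbrca_eligible(ann)
  expect_equal(out$eligible, c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_equal(out$reason[1], "somatic BRCA")
  expect_equal(out$reason[2], "BRCA homozygous deletion")
  expect_equal(out$reason[3], "BRCA1 silenced")
  # z low but methylation beta low: the BRCA1 rule needs both; BRCA2 fires
  expect_equal(out$reason[4], "BRCA2 low expression")
  expect_equal(out$reason[5], "neoadjuvant chemotherapy")
  expect_true(is.na(out$reason[6]))
})

test_that("artifact-signature exclusion is strict at 30%", {
  s <- tibble::tibble(
    sample = c("a", "b", "c"),
    signature_3 = c(0.5, 0.5, 0.9),
    R1 = c(0.25, 0.20, 0),
    U1 = c(0.10, 0.10, 0)
  )
  out <- artifact_fraction_excluded(s)
  expect_equal(out$artifact_fraction, c(0.35, 0.30, 0))
  expect_equal(out$excluded, c(TRUE, FALSE, FALSE))
  # no artifact columns at all: kept
  out2 <- artifact_fraction_excluded(
    tibble::tibble(sample = "x", signature_3 = 1))
  expect_false(out2$excluded)
})

test_that("PTEN extrapolation follows the copy-state rules", {
  expect_equal(extrapolate_pten(1, 0), "LOSS")
  expect_equal(extrapolate_pten(0, 0), "LOSS")
  expect_equal(extrapolate_pten(2, 0, "truncating"), "LOSS")
  expect_equal(extrapolate_pten(2, 1), "RETAINED")
  expect_equal(extrapolate_pten(3, 1), "RETAINED")
  expect_equal(extrapolate_pten(2, 0), "INDETERMINATE")  # CN-LOH, no mutation
  expect_equal(extrapolate_pten(2, 1, "missense"), "INDETERMINATE")
  expect_equal(
    extrapolate_pten(c(1, 2, 2), c(0, 1, 0)),
    c("LOSS", "RETAINED", "INDETERMINATE")
  )
})
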