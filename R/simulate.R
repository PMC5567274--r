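#' Parameters for the synthetic carrier cohort
#'
#' Defines the generative model of a germline BRCA1/BRCA2 carrier cohort
#' with known ground truth: matched tumor/normal summaries whose
#' statistical structure matches what the downstream analysis assumes.
#' Defaults emulate a 160-tumor breast/ovarian cohort (93 BRCA1, 67
#' BRCA2; group sizes 41/52/35/32 for BRCA1-breast/BRCA1-ovary/
#' BRCA2-breast/BRCA2-ovary), with absent-LOH fractions of 10/7/46/16%
#' by gene and site, a 2% absent-plus-somatic-second-hit rate in breast,
#' the remaining probability split over LOH mechanisms in the observed
#' ratios (BRCA1 17:36:31 deletion:copy-neutral:gain; BRCA2 14:20:11),
#' purity ~ Beta(6, 3), mean coverage 141x tumor / 155x normal,
#' mutational burden and TP53 mutation rates per gene-by-LOH group, and
#' exponential survival with hazard ratio 2.5 for non-biallelic ovarian
#' tumors around a 45-month baseline median.
#'
#' @param genome Build name for [genome_build()]; `"mini-test"` (fast,
#'   used by the tests) or `"hg19"` (realism runs).
#' @param group_sizes Tibble `gene`, `site`, `n`.
#' @param absent_frac Named numeric: absent-LOH probability per
#'   `gene.site`.
#' @param somatic_second_frac Probability of the absent-plus-somatic
#'   mechanism per `gene.site`.
#' @param mechanism_ratio List per gene: unnormalized weights for
#'   deletion / copy-neutral / gain among LOH-positive tumors.
#' @param purity_shape Beta shape parameters for purity.
#' @param ploidy Backbone ploidy (constant; ploidy variation is not
#'   simulated — see the methods vignette).
#' @param depth_tumor,depth_normal Mean sequencing depths (Poisson).
#' @param scar_intensity List with numeric `biallelic` and `absent`
#'   vectors of Poisson event-count means, elements `tai` (telomeric
#'   allelic imbalance), `loh` (interstitial large LOH), `lst`
#'   (interstitial state-change blocks).
#' @param burden_rate Tibble `gene`, `group` (`BIALLELIC`/
#'   `NON_BIALLELIC`), `rate` (nonsynonymous mutations per Mb).
#' @param target_mb Callable footprint used to convert rates to counts;
#'   shared with [mutational_burden()].
#' @param tp53_prob Tibble `gene`, `group`, `prob` of a TP53 mutation.
#' @param baseline_median_os Median overall survival (months) of the
#'   biallelic ovarian group.
#' @param hr_non_biallelic Hazard ratio of non-biallelic vs biallelic
#'   ovarian tumors (breast hazard is group-independent).
#' @param censor_range Uniform administrative censoring window (months).
#' @param artifact_prob Probability a sample's mutational-signature
#'   profile is dominated (> 30%) by sequencing-artifact signatures.
#' @param loh_gain_cn Total copies simulated for the LOH-in-gain state
#'   (all mutant).
#' @return Named list of class `sim_params`.
#' @export
sim_params <- function(genome = "mini-test",
                       group_sizes = NULL,
                       absent_frac = c(
                         BRCA1.breast = 0.10, BRCA1.ovary = 0.07,
                         BRCA2.breast = 0.46, BRCA2.ovary = 0.16
                       ),
                       somatic_second_frac = c(
                         BRCA1.breast = 0.02, BRCA1.ovary = 0,
                         BRCA2.breast = 0.02, BRCA2.ovary = 0
                       ),
                       mechanism_ratio = list(
                         BRCA1 = c(LOH_DELETION = 17, CN_LOH = 36, LOH_GAIN = 31),
                         BRCA2 = c(LOH_DELETION = 14, CN_LOH = 20, LOH_GAIN = 11)
                       ),
                       purity_shape = c(6, 3),
                       ploidy = 2,
                       depth_tumor = 141,
                       depth_normal = 155,
                       scar_intensity = list(
                         biallelic = c(tai = 6, loh = 6, lst = 6),
                         absent = c(tai = 0.5, loh = 0.5, lst = 1)
                       ),
                       burden_rate = NULL,
                       target_mb = 30,
                       tp53_prob = NULL,
                       baseline_median_os = 45,
                       hr_non_biallelic = 2.5,
                       censor_range = c(24, 120),
                       artifact_prob = 0.03,
                       loh_gain_cn = 3) {
  if (is.null(group_sizes)) {
    group_sizes <- tibble::tibble(
      gene = c("BRCA1", "BRCA1", "BRCA2", "BRCA2"),
      site = c("breast", "ovary", "breast", "ovary"),
      n = c(41, 52, 35, 32)
    )
  }
  if (is.null(burden_rate)) {
    burden_rate <- tibble::tibble(
      gene = c("BRCA1", "BRCA1", "BRCA2", "BRCA2"),
      group = c("BIALLELIC", "NON_BIALLELIC", "BIALLELIC", "NON_BIALLELIC"),
      rate = c(0.78, 1.00, 1.41, 0.37)
    )
  }
  if (is.null(tp53_prob)) {
    tp53_prob <- tibble::tibble(
      gene = c("BRCA1", "BRCA1", "BRCA2", "BRCA2"),
      group = c("BIALLELIC", "NON_BIALLELIC", "BIALLELIC", "NON_BIALLELIC"),
      prob = c(0.84, 0.44, 0.68, 0.24)
    )
  }
  structure(
    list(
      genome = genome, group_sizes = group_sizes,
      absent_frac = absent_frac, somatic_second_frac = somatic_second_frac,
      mechanism_ratio = mechanism_ratio, purity_shape = purity_shape,
      ploidy = ploidy, depth_tumor = depth_tumor,
      depth_normal = depth_normal, scar_intensity = scar_intensity,
      burden_rate = burden_rate, target_mb = target_mb,
      tp53_prob = tp53_prob, baseline_median_os = baseline_median_os,
      hr_non_biallelic = hr_non_biallelic, censor_range = censor_range,
      artifact_prob = artifact_prob, loh_gain_cn = loh_gain_cn
    ),
    class = "sim_params"
  )
}

mechanism_levels <- function() {
  c("LOH_DELETION", "CN_LOH", "LOH_GAIN", "ABSENT", "ABSENT_PLUS_SOMATIC")
}

#' Mechanism probabilities per gene and site
#'
#' Expands a [sim_params()] object into the full categorical distribution
#' over mechanisms for each gene-by-site stratum.
#'
#' @param params A [sim_params()] object.
#' @return Tibble `gene`, `site`, `mechanism`, `prob` (sums to 1 within
#'   each stratum).
#' @export
mechanism_probs <- function(params) {
  purrr::pmap_dfr(params$group_sizes, function(gene, site, n) {
    key <- paste(gene, site, sep = ".")
    absent <- params$absent_frac[[key]]
    som <- params$somatic_second_frac[[key]]
    pos <- 1 - absent - som
    ratio <- params$mechanism_ratio[[gene]]
    w <- pos * ratio / sum(ratio)
    tibble::tibble(
      gene = gene, site = site,
      mechanism = mechanism_levels(),
      prob = c(unname(w[c("LOH_DELETION", "CN_LOH", "LOH_GAIN")]), absent, som)
    )
  })
}

# (cn, m) implied by each mechanism; the ASCN segment state at the locus
# has b = 0 for the LOH states and retains the minor allele otherwise.
mechanism_state <- function(mechanism, loh_gain_cn = 3) {
  switch(mechanism,
    LOH_DELETION = list(cn = 1, m = 1, a = 1, b = 0),
    CN_LOH = list(cn = 2, m = 2, a = 2, b = 0),
    LOH_GAIN = list(cn = loh_gain_cn, m = loh_gain_cn, a = loh_gain_cn, b = 0),
    ABSENT = list(cn = 2, m = 1, a = 1, b = 1),
    ABSENT_PLUS_SOMATIC = list(cn = 2, m = 1, a = 1, b = 1),
    stop("invalid mechanism: ", mechanism, call. = FALSE)
  )
}

#' Simulate one tumor's allele-specific copy number profile
#'
#' Places scar events on a diploid balanced backbone: telomeric
#' allelic-imbalance segments (12-35 Mb, anchored at a free chromosome
#' end, confined to one arm), interstitial LOH segments (16-30 Mb), and
#' interstitial state-change blocks (10-18 Mb) that create large-scale
#' state transitions at both edges. Event counts are Poisson with the
#' per-class means in `scar`; placement draws fresh coordinates up to a
#' bounded number of attempts and, once the genome's capacity is
#' saturated, remaining events are dropped (the truth records what was
#' placed). Ploidy is the length-weighted mean copy number of the
#' finished profile. Deterministic given the RNG state.
#'
#' @param sample_id Sample label.
#' @param genome A [genome_build()].
#' @param scar Named numeric: Poisson means for `tai`, `loh`, `lst`.
#' @param locus Optional list/row with `chromosome`, `position`, `a`,
#'   `b`: a reserved segment of this state is carved around the position
#'   first (the carrier-gene locus).
#' @return List: `segments` (tibble), `ploidy`, `truth` (tibble of
#'   placed event counts).
#' @export
simulate_profile <- function(sample_id, genome, scar, locus = NULL) {
  # plain parallel vectors: this runs once per simulated tumor
  ev_chrom <- character(0)
  ev_start <- ev_end <- ev_a <- ev_b <- numeric(0)
  reserve <- function(chrom, start, end, a, b) {
    ev_chrom[[length(ev_chrom) + 1]] <<- chrom
    ev_start[[length(ev_start) + 1]] <<- floor(start)
    ev_end[[length(ev_end) + 1]] <<- floor(end)
    ev_a[[length(ev_a) + 1]] <<- a
    ev_b[[length(ev_b) + 1]] <<- b
  }
  overlaps <- function(chrom, start, end) {
    any(ev_chrom == chrom & ev_start <= end & ev_end >= start)
  }

  if (!is.null(locus)) {
    g <- genome[genome$chromosome == locus$chromosome, ]
    half <- 5e6
    reserve(locus$chromosome,
      max(1, locus$position - half),
      min(g$length, locus$position + half),
      locus$a, locus$b)
  }

  tai_states <- list(c(2, 1), c(1, 0), c(2, 0), c(3, 1))
  loh_states <- list(c(2, 0), c(1, 0))
  lst_states <- list(c(2, 2), c(3, 1))

  n_tai <- stats::rpois(1, scar[["tai"]])
  n_loh <- stats::rpois(1, scar[["loh"]])
  n_lst <- stats::rpois(1, scar[["lst"]])
  placed_counts <- c(tai = 0L, loh = 0L, lst = 0L)

  g_chrom <- genome$chromosome
  g_len <- genome$length
  g_cs <- genome$centromere_start
  g_ce <- genome$centromere_end
  place_event <- function(kind) {
    for (attempt in 1:40) {
      gi <- sample.int(length(g_chrom), 1)
      arm <- sample(c("p", "q"), 1)
      arm_lo <- if (arm == "p") 1 else g_ce[gi] + 1
      arm_hi <- if (arm == "p") g_cs[gi] - 1 else g_len[gi]
      arm_len <- arm_hi - arm_lo + 1
      if (kind == "tai") {
        len <- stats::runif(1, 12e6, 35e6)
        if (len > arm_len - 2e6) next
        if (arm == "p") {
          start <- 1; end <- len
        } else {
          start <- g_len[gi] - len + 1; end <- g_len[gi]
        }
        st <- tai_states[[sample.int(length(tai_states), 1)]]
      } else {
        len <- if (kind == "loh") stats::runif(1, 16e6, 30e6)
          else stats::runif(1, 10e6, 18e6)
        margin <- 2e6
        lo <- arm_lo + margin
        hi <- arm_hi - margin - len
        if (hi <= lo) next
        start <- stats::runif(1, lo, hi)
        end <- start + len - 1
        st <- if (kind == "loh") loh_states[[sample.int(2, 1)]]
          else lst_states[[sample.int(2, 1)]]
      }
      if (!overlaps(g_chrom[gi], start, end)) {
        reserve(g_chrom[gi], start, end, st[1], st[2])
        return(TRUE)
      }
    }
    FALSE
  }

  for (i in seq_len(n_tai)) {
    if (place_event("tai")) placed_counts[["tai"]] <- placed_counts[["tai"]] + 1L
  }
  for (i in seq_len(n_loh)) {
    if (place_event("loh")) placed_counts[["loh"]] <- placed_counts[["loh"]] + 1L
  }
  for (i in seq_len(n_lst)) {
    if (place_event("lst")) placed_counts[["lst"]] <- placed_counts[["lst"]] + 1L
  }

  # fill the rest of every chromosome with the balanced diploid backbone
  o_chrom <- character(0)
  o_start <- o_end <- o_a <- o_b <- numeric(0)
  emit <- function(chrom, start, end, a, b) {
    o_chrom[[length(o_chrom) + 1]] <<- chrom
    o_start[[length(o_start) + 1]] <<- start
    o_end[[length(o_end) + 1]] <<- end
    o_a[[length(o_a) + 1]] <<- a
    o_b[[length(o_b) + 1]] <<- b
  }
  for (i in seq_len(nrow(genome))) {
    chrom <- genome$chromosome[i]
    idx <- which(ev_chrom == chrom)
    idx <- idx[order(ev_start[idx])]
    cursor <- 1
    for (j in idx) {
      if (ev_start[j] > cursor) emit(chrom, cursor, ev_start[j] - 1, 1, 1)
      emit(chrom, ev_start[j], ev_end[j], ev_a[j], ev_b[j])
      cursor <- ev_end[j] + 1
    }
    if (cursor <= genome$length[i]) emit(chrom, cursor, genome$length[i], 1, 1)
  }
  seg <- tibble::tibble(
    sample = sample_id, chromosome = o_chrom, start = o_start, end = o_end,
    cnt = o_a + o_b, a = o_a, b = o_b,
    length = o_end - o_start + 1,
    loh = o_b == 0 & (o_a + o_b) >= 1, ai = o_a != o_b
  )
  ploidy <- sum(seg$cnt * seg$length) / sum(seg$length)
  list(
    segments = seg,
    ploidy = ploidy,
    truth = tibble::tibble(
      sample = sample_id,
      n_tai_events = placed_counts[["tai"]],
      n_loh_events = placed_counts[["loh"]],
      n_lst_events = placed_counts[["lst"]]
    )
  )
}

#' Simulate tumor/normal allele counts at the carrier mutation
#'
#' Under purity `p`, the locus has `cn` total copies with `m` mutant in
#' tumor cells while the contaminating normal carries the germline
#' variant heterozygously, so the expected tumor alt fraction is
#' `f = (p*m + (1-p)) / (p*cn + 2*(1-p))`. Depths are Poisson around the
#' configured means; alt counts are Binomial at `f` (tumor) and 0.5
#' (normal).
#'
#' @param mechanism One of the five mechanism labels.
#' @param purity Tumor purity in (0, 1].
#' @param depth_tumor,depth_normal Mean depths.
#' @param loh_gain_cn Copy number of the LOH-in-gain state.
#' @return List: `observation` (one-row tibble of counts) and `truth`
#'   (`cn`, `m`, `f_expected`).
#' @export
simulate_locus_observation <- function(mechanism, purity,
                                       depth_tumor = 141,
                                       depth_normal = 155,
                                       loh_gain_cn = 3) {
  if (purity <= 0 || purity > 1) stop("purity must be in (0,1]", call. = FALSE)
  st <- mechanism_state(mechanism, loh_gain_cn)
  p <- purity
  f <- (p * st$m + (1 - p)) / (p * st$cn + 2 * (1 - p))
  dt <- max(1L, stats::rpois(1, depth_tumor))
  dn <- max(1L, stats::rpois(1, depth_normal))
  ta <- stats::rbinom(1, dt, f)
  na <- stats::rbinom(1, dn, 0.5)
  list(
    observation = tibble::tibble(
      normal_ref = dn - na, normal_alt = na,
      tumor_ref = dt - ta, tumor_alt = ta
    ),
    truth = tibble::tibble(cn = st$cn, m = st$m, f_expected = f)
  )
}

#' Simulate a full carrier cohort with ground truth
#'
#' Draws every sample's mechanism, purity, segment profile, locus read
#' counts, somatic variant table (including decoy rows that each violate
#' one filter rule), TP53 status, mutational-signature proportions, and
#' survival record from the model in [sim_params()]. All tables
#' round-trip through the package readers; a fixed seed gives a
#' byte-identical bundle.
#'
#' @param params A [sim_params()] object.
#' @param seed Integer seed.
#' @param dir Optional directory: when given, writes `segments.tsv`,
#'   `meta.tsv`, `locus_counts.tsv`, `somatic_variants.tsv`,
#'   `signatures.tsv`, `clinical.tsv`, `truth.tsv`.
#' @return List: `cohort` (a `tumor_cohort`), `locus_observations`,
#'   `somatic_variants`, `signatures`, `clinical`, `truth` tibbles.
#' @export
simulate_cohort <- function(params = sim_params(), seed = 1, dir = NULL) {
  stopifnot(inherits(params, "sim_params"))
  if (sum(params$group_sizes$n) == 0) stop("zero samples requested", call. = FALSE)
  set.seed(seed)
  genome <- genome_build(params$genome)
  loci <- gene_loci(genome)
  probs <- mechanism_probs(params)

  plan <- purrr::pmap_dfr(params$group_sizes, function(gene, site, n) {
    pr <- probs[probs$gene == gene & probs$site == site, ]
    tibble::tibble(
      gene = gene, site = site,
      mechanism = sample(pr$mechanism, n, replace = TRUE, prob = pr$prob)
    )
  })
  n_total <- nrow(plan)
  plan$sample <- sprintf("S%03d", seq_len(n_total))
  plan$purity <- stats::rbeta(n_total, params$purity_shape[1],
    params$purity_shape[2])
  plan$purity <- pmin(pmax(plan$purity, 0.05), 0.99)
  plan$loh_truth <- mechanism_is_loh(plan$mechanism)
  plan$group_truth <- dplyr::if_else(
    plan$loh_truth | plan$mechanism == "ABSENT_PLUS_SOMATIC",
    "BIALLELIC", "NON_BIALLELIC")

  seg_list <- list(); meta_list <- list(); obs_list <- list()
  truth_prof <- list(); truth_obs <- list()
  for (i in seq_len(n_total)) {
    row <- plan[i, ]
    locus <- loci[loci$gene == row$gene, ]
    st <- mechanism_state(row$mechanism, params$loh_gain_cn)
    scar <- if (row$group_truth == "BIALLELIC") {
      params$scar_intensity$biallelic
    } else {
      params$scar_intensity$absent
    }
    prof <- simulate_profile(row$sample, genome, scar,
      locus = list(chromosome = locus$chromosome, position = locus$position,
        a = st$a, b = st$b))
    seg_list[[i]] <- prof$segments
    meta_list[[i]] <- tibble::tibble(sample = row$sample, purity = row$purity,
      ploidy = prof$ploidy)
    truth_prof[[i]] <- prof$truth
    ob <- simulate_locus_observation(row$mechanism, row$purity,
      params$depth_tumor, params$depth_normal, params$loh_gain_cn)
    obs_list[[i]] <- dplyr::bind_cols(
      tibble::tibble(sample = row$sample, gene = row$gene,
        chromosome = locus$chromosome, position = locus$position,
        ref = "A", alt = "T", classification = "pathogenic"),
      ob$observation
    )
    truth_obs[[i]] <- dplyr::bind_cols(tibble::tibble(sample = row$sample),
      ob$truth)
  }

  segments <- dplyr::bind_rows(seg_list)
  meta <- dplyr::bind_rows(meta_list)
  cohort <- new_tumor_cohort(segments, meta, genome)
  observations <- dplyr::bind_rows(obs_list)

  somatic <- simulate_somatic_variants(plan, params)
  signatures <- simulate_signatures(plan, params)
  clinical <- simulate_clinical(plan, params)

  truth <- plan |>
    dplyr::left_join(dplyr::bind_rows(truth_obs), by = "sample") |>
    dplyr::left_join(dplyr::bind_rows(truth_prof), by = "sample") |>
    dplyr::left_join(meta[, c("sample", "ploidy")], by = "sample") |>
    dplyr::left_join(
      dplyr::distinct(somatic$per_sample[, c("sample", "tp53_mut", "burden_rate")]),
      by = "sample"
    ) |>
    dplyr::rename(loh_status_truth = "loh_truth",
      group_for_genomics_truth = "group_truth")

  out <- list(
    cohort = cohort,
    locus_observations = observations,
    somatic_variants = somatic$variants,
    signatures = signatures,
    clinical = clinical,
    truth = truth
  )
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_segments(cohort, file.path(dir, "segments.tsv"))
    readr::write_tsv(meta, file.path(dir, "meta.tsv"), progress = FALSE)
    readr::write_tsv(observations, file.path(dir, "locus_counts.tsv"),
      progress = FALSE)
    readr::write_tsv(somatic$variants, file.path(dir, "somatic_variants.tsv"),
      progress = FALSE)
    readr::write_tsv(signatures, file.path(dir, "signatures.tsv"),
      progress = FALSE)
    readr::write_tsv(clinical, file.path(dir, "clinical.tsv"), progress = FALSE)
    readr::write_tsv(truth, file.path(dir, "truth.tsv"), progress = FALSE)
  }
  out
}

# Somatic variant table: per-sample Poisson counts of filter-passing
# nonsynonymous variants at the group's burden rate, decoy rows that each
# fail exactly one filter, a TP53 hit with the group's probability, and
# the same-gene somatic second hit for ABSENT_PLUS_SOMATIC tumors.
simulate_somatic_variants <- function(plan, params) {
  background_genes <- sprintf("GENE%02d", 1:40)
  per_sample <- list(); rows <- list()
  for (i in seq_len(nrow(plan))) {
    row <- plan[i, ]
    rate <- params$burden_rate$rate[
      params$burden_rate$gene == row$gene &
        params$burden_rate$group == row$group_truth]
    tp53_p <- params$tp53_prob$prob[
      params$tp53_prob$gene == row$gene &
        params$tp53_prob$group == row$group_truth]
    tp53 <- stats::runif(1) < tp53_p
    n_kept <- stats::rpois(1, rate * params$target_mb)
    n_kept_other <- max(0, n_kept - as.integer(tp53))
    make_pass <- function(n, genes) {
      if (n == 0) return(NULL)
      tibble::tibble(
        sample = row$sample,
        gene = sample(genes, n, replace = TRUE),
        effect = sample(c("missense", "truncating", "indel"), n,
          replace = TRUE, prob = c(0.6, 0.3, 0.1)),
        pathogenicity = sample(c("D", "LD", "VUS"), n, replace = TRUE,
          prob = c(0.5, 0.3, 0.2)),
        pop_freq = 0,
        segdup_frac = stats::runif(n, 0, 0.5),
        normal_alt_depth = sample(0:4, n, replace = TRUE),
        tumor_alt_depth = 11 + stats::rpois(n, 30),
        af = stats::runif(n, 0.1, 0.6)
      )
    }
    rows[[length(rows) + 1]] <- make_pass(n_kept_other, background_genes)
    if (tp53) {
      tp <- make_pass(1, "TP53")
      tp$effect <- "truncating"; tp$pathogenicity <- "D"
      rows[[length(rows) + 1]] <- tp
    }
    if (row$mechanism == "ABSENT_PLUS_SOMATIC") {
      hit <- make_pass(1, row$gene)
      hit$effect <- "truncating"; hit$pathogenicity <- "D"
      hit$af <- stats::runif(1, 0.1, 0.5)
      rows[[length(rows) + 1]] <- hit
    }
    # decoys: each fails exactly one rule, in known proportion
    n_decoy <- stats::rpois(1, 0.4 * max(n_kept, 1))
    if (n_decoy > 0) {
      dec <- make_pass(n_decoy, background_genes)
      fail <- sample(c("germline", "popfreq", "segdup", "synonymous",
        "tumordepth", "benign"), n_decoy, replace = TRUE)
      dec$normal_alt_depth[fail == "germline"] <- 5 + stats::rpois(
        sum(fail == "germline"), 10)
      dec$pop_freq[fail == "popfreq"] <- stats::runif(sum(fail == "popfreq"),
        0.02, 0.3)
      dec$segdup_frac[fail == "segdup"] <- stats::runif(sum(fail == "segdup"),
        0.9, 1)
      dec$effect[fail == "synonymous"] <- "synonymous"
      dec$tumor_alt_depth[fail == "tumordepth"] <- sample(0:10,
        sum(fail == "tumordepth"), replace = TRUE)
      dec$pathogenicity[fail == "benign"] <- sample(c("LB", "B"),
        sum(fail == "benign"), replace = TRUE)
      rows[[length(rows) + 1]] <- dec
    }
    per_sample[[i]] <- tibble::tibble(sample = row$sample, tp53_mut = tp53,
      burden_rate = rate)
  }
  list(
    variants = dplyr::bind_rows(rows),
    per_sample = dplyr::bind_rows(per_sample)
  )
}

simulate_signatures <- function(plan, params) {
  n <- nrow(plan)
  heavy <- stats::runif(n) < params$artifact_prob
  art_total <- ifelse(heavy, stats::runif(n, 0.35, 0.60),
    stats::runif(n, 0, 0.12))
  w <- matrix(stats::runif(3 * n), ncol = 3)
  w <- w / rowSums(w)
  sig3 <- ifelse(plan$group_truth == "BIALLELIC",
    stats::runif(n, 0.30, 0.60), stats::runif(n, 0.00, 0.20))
  rest <- pmax(0, 1 - art_total - sig3)
  frac1 <- stats::runif(n, 0.5, 0.9)
  tibble::tibble(
    sample = plan$sample,
    signature_1 = rest * frac1,
    signature_3 = sig3,
    signature_5 = rest * (1 - frac1),
    R1 = art_total * w[, 1], R2 = art_total * w[, 2], U1 = art_total * w[, 3],
    R3 = 0, U2 = 0
  )
}

simulate_clinical <- function(plan, params) {
  n <- nrow(plan)
  h0 <- log(2) / params$baseline_median_os
  hr <- ifelse(plan$site == "ovary" & plan$group_truth == "NON_BIALLELIC",
    params$hr_non_biallelic, 1)
  t_event <- stats::rexp(n, h0 * hr)
  t_censor <- stats::runif(n, params$censor_range[1], params$censor_range[2])
  tibble::tibble(
    sample = plan$sample,
    site_source = sample(c("TCGA", "Penn"), n, replace = TRUE),
    gene = plan$gene,
    tumor_type = plan$site,
    stage = sample(c("I", "II", "III", "IV"), n, replace = TRUE,
      prob = c(0.15, 0.3, 0.4, 0.15)),
    receptor_status = sample(c("ER+", "TNBC", "other"), n, replace = TRUE),
    os_months = pmin(t_event, t_censor),
    os_event = as.integer(t_event <= t_censor)
  )
}
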