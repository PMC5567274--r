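#' Configuration for the genomic scar scores
#'
#' Central registry of the numeric thresholds behind the three
#' exome-based homologous-recombination-deficiency (HRD) scar scores.
#' Defaults are the published construction this package implements:
#' telomeric allelic-imbalance segments `> 11` Mb that do not span the
#' centromere; large-scale state transitions between `>= 10` Mb segments
#' after smoothing away `< 3` Mb segments, ploidy-corrected as
#' `LSTm = LST - 15.5 * ploidy`; and LOH segments `> 15` Mb excluding
#' chromosome 17.
#'
#' @param ntai_min_mb Minimum telomeric-AI segment length, Mb (strict `>`).
#' @param telomere_tol_mb A segment "reaches" the chromosome terminus if it
#'   is the first/last segment of its chromosome and lies within this many
#'   Mb of the end.
#' @param lst_small_mb Segments strictly shorter than this are smoothed out
#'   before counting state transitions.
#' @param lst_large_mb Both segments flanking a counted transition must be
#'   at least this long.
#' @param lst_ploidy_factor Multiplier in the ploidy correction.
#' @param hrd_loh_min_mb Minimum LOH segment length, Mb (strict `>`).
#' @param hrd_loh_exclude_chrom Chromosome(s) excluded from the LOH score.
#' @param exclude_whole_chromosome_loh Drop LOH segments spanning an entire
#'   chromosome from the LOH score (the score's original formulation does;
#'   the variant implemented here by default does not).
#' @param include_x Include chromosome X in all three scores. Off by
#'   default: allele states on X are ill-defined in males.
#' @param hrd_mean_use_lstm Use the ploidy-corrected LSTm (default) rather
#'   than raw LST in the three-score mean.
#' @return A named list of class `hrd_config`.
#' @export
hrd_config <- function(ntai_min_mb = 11,
                       telomere_tol_mb = 1,
                       lst_small_mb = 3,
                       lst_large_mb = 10,
                       lst_ploidy_factor = 15.5,
                       hrd_loh_min_mb = 15,
                       hrd_loh_exclude_chrom = "17",
                       exclude_whole_chromosome_loh = FALSE,
                       include_x = FALSE,
                       hrd_mean_use_lstm = TRUE) {
  structure(
    list(
      ntai_min_mb = ntai_min_mb,
      telomere_tol_mb = telomere_tol_mb,
      lst_small_mb = lst_small_mb,
      lst_large_mb = lst_large_mb,
      lst_ploidy_factor = lst_ploidy_factor,
      hrd_loh_min_mb = hrd_loh_min_mb,
      hrd_loh_exclude_chrom = hrd_loh_exclude_chrom,
      exclude_whole_chromosome_loh = exclude_whole_chromosome_loh,
      include_x = include_x,
      hrd_mean_use_lstm = hrd_mean_use_lstm
    ),
    class = "hrd_config"
  )
}

score_chroms <- function(seg, config) {
  if (!config$include_x) seg <- seg[seg$chromosome != "X", , drop = FALSE]
  seg
}

single_sample <- function(segments) {
  seg <- if (inherits(segments, "tumor_cohort")) segments$segments else segments
  if (length(unique(seg$sample)) > 1) {
    stop("expected a single sample; use score_hrd() for cohorts", call. = FALSE)
  }
  seg
}

#' Telomeric allelic-imbalance score (NtAI)
#'
#' Counts allelic-imbalance segments (major != minor allele count) longer
#' than `ntai_min_mb` that reach a chromosome terminus without spanning
#' the centromere — i.e. imbalance running from a post-centromeric
#' position out to the sub-telomeric region. "Reaching the terminus" means
#' the segment is the first (or last) segment of its chromosome and lies
#' within `telomere_tol_mb` of the chromosome end.
#'
#' @param segments Single-sample segments tibble (see [read_segments()]).
#' @param genome A [genome_build()].
#' @param config An [hrd_config()].
#' @return Integer count.
#' @export
score_ntai <- function(segments, genome, config = hrd_config()) {
  seg <- score_chroms(single_sample(segments), config)
  if (nrow(seg) == 0) return(0L)
  n <- 0L
  for (chrom in unique(seg$chromosome)) {
    s <- seg[seg$chromosome == chrom, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    g <- genome[genome$chromosome == chrom, ]
    tol <- config$telomere_tol_mb * 1e6
    first_ok <- s$start == s$start[1] & (s$start - 1) <= tol
    last_ok <- s$end == s$end[nrow(s)] & (g$length - s$end) <= tol
    spans_cen <- s$start < g$centromere_start & s$end > g$centromere_end
    qual <- s$ai &
      s$length > config$ntai_min_mb * 1e6 &
      (first_ok | last_ok) &
      !spans_cen
    n <- n + sum(qual)
  }
  as.integer(n)
}

#' Large-scale state transition score (LST and LSTm)
#'
#' Per chromosome arm, segments shorter than `lst_small_mb` are smoothed
#' out (removed shortest-first, merging equal-state neighbours, until
#' stable); a transition is counted at each junction whose two flanking
#' smoothed segments are each at least `lst_large_mb` long and differ in
#' allele-specific state `(a, b)`. Segments overlapping the centromere are
#' split at its midpoint so no transition is counted across it. The raw
#' count is ploidy-corrected: `LSTm = LST - lst_ploidy_factor * ploidy`
#' (LSTm may be negative; the formula is applied literally).
#'
#' @inheritParams score_ntai
#' @param ploidy Mean tumor copy number for the sample.
#' @return A list with integer `lst` and real `lstm`.
#' @export
score_lst <- function(segments, genome, ploidy, config = hrd_config()) {
  seg <- score_chroms(single_sample(segments), config)
  lst <- 0L
  if (nrow(seg) > 0) {
    for (chrom in unique(seg$chromosome)) {
      g <- genome[genome$chromosome == chrom, ]
      mid <- floor((g$centromere_start + g$centromere_end) / 2)
      s <- seg[seg$chromosome == chrom, , drop = FALSE]
      s <- s[order(s$start), , drop = FALSE]
      for (arm in c("p", "q")) {
        if (arm == "p") {
          a <- clip_segments(s, 1, mid)
        } else {
          a <- clip_segments(s, mid + 1, g$length)
        }
        lst <- lst + arm_lst(a, config)
      }
    }
  }
  list(lst = as.integer(lst), lstm = lst - config$lst_ploidy_factor * ploidy)
}

# Restrict segments to [lo, hi], truncating boundary-straddling ones.
clip_segments <- function(s, lo, hi) {
  keep <- s$end >= lo & s$start <= hi
  s <- s[keep, , drop = FALSE]
  if (nrow(s) == 0) return(s)
  s$start <- pmax(s$start, lo)
  s$end <- pmin(s$end, hi)
  s$length <- s$end - s$start + 1
  s
}

# Smooth sub-threshold segments within one arm and count state transitions.
arm_lst <- function(a, config) {
  if (nrow(a) < 2) return(0L)
  sm <- smooth_arm(
    data.frame(start = a$start, end = a$end, a = a$a, b = a$b),
    config$lst_small_mb * 1e6
  )
  if (nrow(sm) < 2) return(0L)
  len <- sm$end - sm$start + 1
  big <- len >= config$lst_large_mb * 1e6
  diff_state <- sm$a[-1] != sm$a[-nrow(sm)] | sm$b[-1] != sm$b[-nrow(sm)]
  sum(big[-length(big)] & big[-1] & diff_state)
}

# Iterative smoothing: merge equal-state neighbours, then drop the
# shortest segment under `min_len`, until stable. Adjacency is positional
# (consecutive rows); merging absorbs any intervening gap.
smooth_arm <- function(d, min_len) {
  repeat {
    d <- merge_equal_neighbours(d)
    len <- d$end - d$start + 1
    small <- which(len < min_len)
    if (length(small) == 0 || nrow(d) == 1) return(d)
    drop <- small[which.min(len[small])]
    d <- d[-drop, , drop = FALSE]
  }
}

merge_equal_neighbours <- function(d) {
  if (nrow(d) < 2) return(d)
  keep <- rep(TRUE, nrow(d))
  i <- 1
  while (i < nrow(d)) {
    j <- i + 1
    if (d$a[i] == d$a[j] && d$b[i] == d$b[j]) {
      d$end[i] <- d$end[j]
      d <- d[-j, , drop = FALSE]
    } else {
      i <- j
    }
  }
  d
}

#' Genomic LOH score (HRD-LOH)
#'
#' Counts LOH segments (minor allele copies `b == 0`, total copy number
#' `>= 1`) longer than `hrd_loh_min_mb`, excluding chromosome 17 (the
#' BRCA1-bearing chromosome, excluded in this score variant because
#' 17 LOH is near-universal in the tumors of interest).
#'
#' @inheritParams score_ntai
#' @return Integer count.
#' @export
score_hrd_loh <- function(segments, genome, config = hrd_config()) {
  seg <- score_chroms(single_sample(segments), config)
  if (nrow(seg) == 0) return(0L)
  seg <- seg[!seg$chromosome %in% config$hrd_loh_exclude_chrom, , drop = FALSE]
  qual <- seg$b == 0 & seg$cnt >= 1 & seg$length > config$hrd_loh_min_mb * 1e6
  if (config$exclude_whole_chromosome_loh && any(qual)) {
    g_len <- genome$length[match(seg$chromosome, genome$chromosome)]
    tol <- config$telomere_tol_mb * 1e6
    whole <- (seg$start - 1) <= tol & (g_len - seg$end) <= tol
    qual <- qual & !whole
  }
  as.integer(sum(qual))
}

#' All HRD scar scores for a cohort
#'
#' Computes NtAI, LST, LSTm, HRD-LOH and their mean per sample. The mean
#' (`hrd_mean`) averages NtAI, LSTm (or raw LST if
#' `hrd_mean_use_lstm = FALSE`) and HRD-LOH.
#'
#' @param cohort A `tumor_cohort` from [read_segments()], or a segments
#'   tibble plus `meta`/`genome`.
#' @param config An [hrd_config()].
#' @param meta,genome Required when `cohort` is a bare segments tibble.
#' @return A tibble: `sample`, `ntai`, `lst`, `lstm`, `hrd_loh`,
#'   `hrd_mean`, `ploidy`.
#' @examples
#' g <- genome_build("mini-test")
#' seg <- data.frame(sample = "s1", chromosome = "2",
#'                   start.pos = 45e6, end.pos = 80e6, CNt = 2, A = 2, B = 0)
#' meta <- data.frame(sample = "s1", purity = 0.6, ploidy = 2)
#' score_hrd(read_segments(seg, meta, g))
#' @export
score_hrd <- function(cohort, config = hrd_config(), meta = NULL, genome = NULL) {
  if (inherits(cohort, "tumor_cohort")) {
    seg <- cohort$segments
    meta <- cohort$meta
    genome <- cohort$genome
  } else {
    seg <- cohort
    if (is.null(meta) || is.null(genome)) {
      stop("supply `meta` and `genome` with a bare segments table", call. = FALSE)
    }
  }
  out <- purrr::map_dfr(meta$sample, function(id) {
    s <- seg[seg$sample == id, , drop = FALSE]
    pl <- meta$ploidy[meta$sample == id]
    ntai <- score_ntai(s, genome, config)
    ls_res <- score_lst(s, genome, pl, config)
    hl <- score_hrd_loh(s, genome, config)
    lst_term <- if (config$hrd_mean_use_lstm) ls_res$lstm else ls_res$lst
    tibble::tibble(
      sample = id, ntai = ntai, lst = ls_res$lst, lstm = ls_res$lstm,
      hrd_loh = hl, hrd_mean = (ntai + lst_term + hl) / 3, ploidy = pl
    )
  })
  class(out) <- c("hrd_scores", class(out))
  out
}

#' Boxplot of HRD-Mean scores by group
#'
#' @param object An `hrd_scores` tibble from [score_hrd()].
#' @param groups Optional tibble `sample`, `group` to stratify by; without
#'   it all samples form one group.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot hrd_scores
#' @export
autoplot.hrd_scores <- function(object, groups = NULL, ...) {
  d <- tibble::as_tibble(object)
  if (!is.null(groups)) {
    d <- dplyr::left_join(d, groups, by = "sample")
  } else {
    d$group <- "all"
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data$hrd_mean)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6) +
    ggplot2::labs(x = NULL, y = "HRD-Mean") +
    ggplot2::theme_minimal()
}
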