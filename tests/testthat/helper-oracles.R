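# Independent brute-force oracles for the scar scores and the exact test.
# Deliberately naive: explicit row-by-row loops, lengths recomputed from
# scratch at every step, no vectorized shortcuts.

mini <- genome_build("mini-test")

oracle_ntai <- function(seg, genome, min_mb = 11, tol_mb = 1, include_x = FALSE) {
  if (!include_x) seg <- seg[seg$chromosome != "X", , drop = FALSE]
  count <- 0
  for (chrom in unique(seg$chromosome)) {
    s <- seg[seg$chromosome == chrom, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    gi <- which(genome$chromosome == chrom)
    chrom_len <- genome$length[gi]
    cs <- genome$centromere_start[gi]
    ce <- genome$centromere_end[gi]
    for (i in seq_len(nrow(s))) {
      len <- s$end[i] - s$start[i] + 1
      is_ai <- s$a[i] != s$b[i]
      at_start <- i == 1 && (s$start[i] - 1) <= tol_mb * 1e6
      at_end <- i == nrow(s) && (chrom_len - s$end[i]) <= tol_mb * 1e6
      spans <- s$start[i] < cs && s$end[i] > ce
      if (is_ai && len > min_mb * 1e6 && (at_start || at_end) && !spans) {
        count <- count + 1
      }
    }
  }
  count
}

oracle_hrd_loh <- function(seg, genome, min_mb = 15, exclude = "17",
                           include_x = FALSE) {
  if (!include_x) seg <- seg[seg$chromosome != "X", , drop = FALSE]
  count <- 0
  for (i in seq_len(nrow(seg))) {
    len <- seg$end[i] - seg$start[i] + 1
    if (seg$b[i] == 0 && seg$cnt[i] >= 1 && len > min_mb * 1e6 &&
        !(seg$chromosome[i] %in% exclude)) {
      count <- count + 1
    }
  }
  count
}

# LST oracle: arms split at the centromere midpoint; smoothing removes the
# single globally shortest sub-3Mb segment, then merges any adjacent
# equal-state pair, until stable; transitions counted between >=10 Mb
# neighbours differing in (a, b).
oracle_lst <- function(seg, genome, small_mb = 3, large_mb = 10,
                       include_x = FALSE) {
  if (!include_x) seg <- seg[seg$chromosome != "X", , drop = FALSE]
  total <- 0
  for (chrom in unique(seg$chromosome)) {
    gi <- which(genome$chromosome == chrom)
    mid <- floor((genome$centromere_start[gi] + genome$centromere_end[gi]) / 2)
    s <- seg[seg$chromosome == chrom, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    for (arm_bounds in list(c(1, mid), c(mid + 1, genome$length[gi]))) {
      rows <- list()
      for (i in seq_len(nrow(s))) {
        st <- max(s$start[i], arm_bounds[1])
        en <- min(s$end[i], arm_bounds[2])
        if (st <= en) rows[[length(rows) + 1]] <- c(st, en, s$a[i], s$b[i])
      }
      if (length(rows) < 2) next
      repeat {
        # merge any adjacent equal-state pair
        merged <- TRUE
        while (merged && length(rows) > 1) {
          merged <- FALSE
          for (i in seq_len(length(rows) - 1)) {
            if (rows[[i]][3] == rows[[i + 1]][3] &&
                rows[[i]][4] == rows[[i + 1]][4]) {
              rows[[i]][2] <- rows[[i + 1]][2]
              rows[[i + 1]] <- NULL
              merged <- TRUE
              break
            }
          }
        }
        lens <- vapply(rows, function(r) r[2] - r[1] + 1, numeric(1))
        small <- which(lens < small_mb * 1e6)
        if (length(small) == 0 || length(rows) == 1) break
        rows[[small[which.min(lens[small])]]] <- NULL
      }
      if (length(rows) < 2) next
      lens <- vapply(rows, function(r) r[2] - r[1] + 1, numeric(1))
      for (i in seq_len(length(rows) - 1)) {
        state_differs <- rows[[i]][3] != rows[[i + 1]][3] ||
          rows[[i]][4] != rows[[i + 1]][4]
        if (lens[i] >= large_mb * 1e6 && lens[i + 1] >= large_mb * 1e6 &&
            state_differs) {
          total <- total + 1
        }
      }
    }
  }
  total
}

# Two-sided Fisher exact p by full hypergeometric enumeration.
oracle_fisher_2x2 <- function(m) {
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  lo <- max(0, r1 + c1 - n); hi <- min(r1, c1)
  probs <- vapply(lo:hi, function(x) {
    choose(c1, x) * choose(n - c1, r1 - x) / choose(n, r1)
  }, numeric(1))
  p_obs <- probs[m[1, 1] - lo + 1]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Random segment profile on a genome: random tiling with occasional gaps,
# small segments, and arbitrary (a, b) states with a >= b.
fuzz_profile <- function(genome, sample_id = "fz", max_breaks = 10) {
  rows <- list()
  for (i in seq_len(nrow(genome))) {
    len <- genome$length[i]
    k <- sample(0:max_breaks, 1)
    cuts <- sort(sample.int(len - 1, k))
    starts <- c(1, cuts + 1)
    ends <- c(cuts, len)
    for (j in seq_along(starts)) {
      if (stats::runif(1) < 0.12) next  # gap
      a <- sample(0:3, 1)
      b <- sample(0:a, 1)
      if (a == 0) b <- 0
      rows[[length(rows) + 1]] <- tibble::tibble(
        sample = sample_id, chromosome = genome$chromosome[i],
        start = starts[j], end = ends[j], cnt = a + b, a = a, b = b
      )
    }
  }
  seg <- dplyr::bind_rows(rows)
  if (nrow(seg) == 0) {
    seg <- tibble::tibble(sample = sample_id, chromosome = genome$chromosome[1],
      start = 1, end = genome$length[1], cnt = 2, a = 1, b = 1)
  }
  seg
}

fuzz_cohort <- function(genome, sample_id = "fz") {
  seg <- fuzz_profile(genome, sample_id)
  meta <- tibble::tibble(sample = sample_id, purity = 0.7, ploidy = 2)
  read_segments(seg, meta, genome)
}

# Longhand log-rank: O - E and hypergeometric variance accumulated over
# event times, group A as the "observed" arm.
oracle_logrank <- function(time, event, group) {
  stopifnot(length(unique(group)) == 2)
  g1 <- sort(unique(group))[1]
  o_minus_e <- 0; v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g1)
    o_minus_e <- o_minus_e + (d1 - d * n1 / n)
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chi2 <- o_minus_e^2 / v
  list(chi2 = chi2, p = stats::pchisq(chi2, 1, lower.tail = FALSE))
}
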