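#' Read and validate allele-specific copy number segment tables
#'
#' Ingests Sequenza-dialect segment tables — one row per segment with total
#' copy number `CNt` decomposed into major (`A`) and minor (`B`) allele
#' copies — together with per-sample purity (cellularity) and ploidy, and
#' returns a validated tumor cohort. Coordinates are 1-based, fully closed
#' intervals (the Sequenza convention). A leading `"chr"` prefix is
#' stripped; chromosomes Y and MT are dropped with a warning; rows whose
#' `A + B` does not equal `CNt` are dropped with a diagnostic warning.
#'
#' @param segments A TSV path or data frame with columns `chromosome`,
#'   `start.pos`, `end.pos`, `CNt`, `A`, `B` (or the normalized names
#'   `start`, `end`, `cnt`, `a`, `b`) and, for multi-sample tables, a
#'   `sample` column.
#' @param meta A TSV path or data frame with columns `sample`, `purity`
#'   (in (0, 1]) and `ploidy` (> 0).
#' @param genome A [genome_build()].
#'
#' @return A `tumor_cohort`: a list with `$segments` (tibble: `sample`,
#'   `chromosome`, `start`, `end`, `cnt`, `a`, `b`, plus derived `length`,
#'   `loh`, `ai` flags), `$meta`, and `$genome`. Segment invariants
#'   (sorted, non-overlapping, inside the chromosome, `a >= b >= 0`,
#'   `a + b == cnt`) are enforced.
#' @examples
#' g <- genome_build("mini-test")
#' seg <- data.frame(sample = "s1", chromosome = "1",
#'                   start.pos = 1, end.pos = 50e6, CNt = 2, A = 2, B = 0)
#' meta <- data.frame(sample = "s1", purity = 0.6, ploidy = 2)
#' cohort <- read_segments(seg, meta, g)
#' cohort$segments$loh
#' @export
read_segments <- function(segments, meta, genome) {
  seg <- read_table_arg(segments)
  met <- read_table_arg(meta)
  seg <- normalize_segment_columns(seg)
  met <- validate_meta(met)

  missing_samples <- setdiff(met$sample, unique(seg$sample))
  if (length(missing_samples) > 0) {
    stop("sample(s) in metadata absent from segment table: ",
      paste(missing_samples, collapse = ", "), call. = FALSE)
  }
  orphan <- setdiff(unique(seg$sample), met$sample)
  if (length(orphan) > 0) {
    stop("sample(s) in segment table absent from metadata: ",
      paste(orphan, collapse = ", "), call. = FALSE)
  }
  seg <- validate_segments(seg, genome)
  new_tumor_cohort(seg, met, genome)
}

new_tumor_cohort <- function(segments, meta, genome) {
  structure(
    list(segments = segments, meta = meta, genome = genome),
    class = "tumor_cohort"
  )
}

#' @export
print.tumor_cohort <- function(x, ...) {
  cat("<tumor_cohort> ", nrow(x$meta), " sample(s), ",
    nrow(x$segments), " segments, genome ", attr(x$genome, "name"),
    "\n", sep = "")
  invisible(x)
}

read_table_arg <- function(x) {
  if (is.character(x) && length(x) == 1) {
    readr::read_tsv(x, show_col_types = FALSE, progress = FALSE)
  } else if (is.data.frame(x)) {
    tibble::as_tibble(x)
  } else {
    stop("expected a file path or data frame", call. = FALSE)
  }
}

normalize_segment_columns <- function(seg) {
  ren <- c(start = "start.pos", end = "end.pos", cnt = "CNt", a = "A", b = "B")
  for (new in names(ren)) {
    if (!new %in% names(seg) && ren[[new]] %in% names(seg)) {
      names(seg)[names(seg) == ren[[new]]] <- new
    }
  }
  if (!"sample" %in% names(seg)) seg$sample <- "sample_1"
  needed <- c("sample", "chromosome", "start", "end", "cnt", "a", "b")
  missing <- setdiff(needed, names(seg))
  if (length(missing) > 0) {
    stop("segment table lacks column(s): ", paste(missing, collapse = ", "),
      call. = FALSE)
  }
  seg$chromosome <- normalize_chrom(seg$chromosome)
  drop <- seg$chromosome %in% c("Y", "MT", "M")
  if (any(drop)) {
    warning(sum(drop), " segment(s) on Y/MT dropped (not modelled)",
      call. = FALSE)
    seg <- seg[!drop, , drop = FALSE]
  }
  seg[needed]
}

validate_meta <- function(met) {
  needed <- c("sample", "purity", "ploidy")
  missing <- setdiff(needed, names(met))
  if (length(missing) > 0) {
    stop("metadata lacks column(s): ", paste(missing, collapse = ", "),
      call. = FALSE)
  }
  met$sample <- as.character(met$sample)
  if (anyDuplicated(met$sample)) stop("duplicated sample in metadata", call. = FALSE)
  bad <- !(met$purity > 0 & met$purity <= 1)
  if (any(bad)) {
    stop("purity outside (0,1] for sample(s): ",
      paste(met$sample[bad], collapse = ", "), call. = FALSE)
  }
  if (any(met$ploidy <= 0)) stop("ploidy must be > 0", call. = FALSE)
  tibble::as_tibble(met[needed])
}

validate_segments <- function(seg, genome) {
  seg$sample <- as.character(seg$sample)
  num <- c("start", "end", "cnt", "a", "b")
  for (col in num) {
    v <- seg[[col]]
    if (!is.numeric(v) || any(is.na(v)) || any(v != round(v))) {
      stop("column `", col, "` must be integer-valued with no missing entries",
        call. = FALSE)
    }
    seg[[col]] <- as.numeric(v)
  }
  if (any(seg$start > seg$end)) {
    stop("segment with start > end", call. = FALSE)
  }
  # A+B must decompose CNt; offending rows are dropped, not patched.
  bad_sum <- seg$a + seg$b != seg$cnt
  if (any(bad_sum)) {
    warning(sum(bad_sum), " segment(s) with A + B != CNt dropped",
      call. = FALSE)
    seg <- seg[!bad_sum, , drop = FALSE]
  }
  if (any(seg$b < 0) || any(seg$a < seg$b)) {
    stop("allele copies must satisfy a >= b >= 0", call. = FALSE)
  }
  unknown <- setdiff(unique(seg$chromosome), genome$chromosome)
  if (length(unknown) > 0) {
    stop("chromosome(s) not in genome build: ",
      paste(unknown, collapse = ", "), call. = FALSE)
  }
  len <- genome$length[match(seg$chromosome, genome$chromosome)]
  if (any(seg$end > len) || any(seg$start < 1)) {
    stop("segment outside chromosome bounds", call. = FALSE)
  }
  seg <- dplyr::arrange(seg, .data$sample,
    match(.data$chromosome, genome$chromosome), .data$start)
  overlap <- seg |>
    dplyr::group_by(.data$sample, .data$chromosome) |>
    dplyr::summarise(
      bad = any(.data$start[-1] <= .data$end[-length(.data$end)]),
      .groups = "drop"
    )
  if (any(overlap$bad, na.rm = TRUE)) {
    stop("overlapping segments within a chromosome", call. = FALSE)
  }
  seg |>
    dplyr::mutate(
      length = .data$end - .data$start + 1,
      loh = .data$b == 0 & .data$cnt >= 1,
      ai = .data$a != .data$b
    )
}

#' Write a segment table in the Sequenza dialect
#'
#' Inverse of [read_segments()]: valid tables round-trip exactly.
#'
#' @param x A `tumor_cohort` or a segments tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_segments <- function(x, path) {
  seg <- if (inherits(x, "tumor_cohort")) x$segments else tibble::as_tibble(x)
  out <- tibble::tibble(
    sample = seg$sample, chromosome = seg$chromosome,
    `start.pos` = seg$start, `end.pos` = seg$end,
    CNt = seg$cnt, A = seg$a, B = seg$b
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Find the segment covering a genomic position
#'
#' Segments use 1-based closed intervals, so a locus equal to a segment's
#' `start` or `end` is inside it. A locus falling between segments is a
#' gap: a zero-row tibble is returned (callers treat gaps as indeterminate
#' evidence, not errors).
#'
#' @param segments A segments tibble (from a `tumor_cohort`) or a
#'   `tumor_cohort`.
#' @param chromosome,position The locus.
#' @param sample Restrict to one sample (required when `segments` holds
#'   several).
#' @return A tibble with 0 or 1 rows.
#' @export
segment_at <- function(segments, chromosome, position, sample = NULL) {
  seg <- if (inherits(segments, "tumor_cohort")) segments$segments else segments
  if (!is.null(sample)) {
    seg <- seg[seg$sample == sample, , drop = FALSE]
  } else if (length(unique(seg$sample)) > 1) {
    stop("multiple samples present; supply `sample`", call. = FALSE)
  }
  chromosome <- normalize_chrom(chromosome)
  hit <- seg$chromosome == chromosome & seg$start <= position & seg$end >= position
  seg[hit, , drop = FALSE]
}
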