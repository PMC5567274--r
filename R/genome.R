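#' Genome builds: chromosome lengths and centromere intervals
#'
#' A genome build anchors every coordinate operation in the package: which
#' chromosomes exist, how long they are, and where the centromere lies.
#' Centromere intervals are what separate "post-centromeric" (single-arm)
#' segments from centromere-spanning ones in the telomeric allelic-imbalance
#' score, and define the arm boundaries used by the state-transition score.
#'
#' Two builds ship with the package:
#' * `"hg19"` — autosomes 1-22 plus X, with cytoband/gap-table-derived
#'   centromere intervals. Y and MT are not modelled (allele-specific copy
#'   number on them is ill-defined for this application).
#' * `"mini-test"` — a deterministic 3-chromosome toy genome (100/80/60 Mb,
#'   centromeres at 40-42, 30-32 and 25-27 Mb) used throughout the test
#'   suite and as the synthetic generator's fast default.
#'
#' Alternatively supply a data frame with columns `chromosome`, `length`,
#' `centromere_start`, `centromere_end` to define a custom build.
#'
#' @param source `"hg19"`, `"mini-test"`, or a data frame (see above).
#' @param name Label for a custom build (ignored for packaged builds).
#'
#' @return A `genome_build` object: a tibble with columns `chromosome`
#'   (character, no `"chr"` prefix), `length`, `centromere_start`,
#'   `centromere_end` (base pairs, 1-based), and a `name` attribute.
#' @examples
#' g <- genome_build("mini-test")
#' g$length
#' @export
genome_build <- function(source = "hg19", name = NULL) {
  if (is.character(source) && length(source) == 1) {
    tab <- switch(source,
      "hg19"      = hg19_table(),
      "mini-test" = mini_test_table(),
      stop("unknown genome build: ", source, call. = FALSE)
    )
    name <- source
  } else if (is.data.frame(source)) {
    needed <- c("chromosome", "length", "centromere_start", "centromere_end")
    missing <- setdiff(needed, names(source))
    if (length(missing) > 0) {
      stop("genome table lacks columns: ", paste(missing, collapse = ", "),
        call. = FALSE)
    }
    tab <- tibble::as_tibble(source[needed])
    tab$chromosome <- normalize_chrom(tab$chromosome)
    if (is.null(name)) name <- "custom"
  } else {
    stop("`source` must be a build name or a data frame", call. = FALSE)
  }
  validate_genome_build(tab)
  structure(tab, name = name, class = c("genome_build", class(tab)))
}

validate_genome_build <- function(tab) {
  if (anyDuplicated(tab$chromosome)) {
    stop("duplicated chromosome names in genome build", call. = FALSE)
  }
  if (any(tab$length <= 0)) stop("chromosome lengths must be > 0", call. = FALSE)
  bad <- tab$centromere_start <= 1 | tab$centromere_end >= tab$length |
    tab$centromere_start >= tab$centromere_end
  if (any(bad)) {
    stop("centromere interval must lie strictly inside chromosome: ",
      paste(tab$chromosome[bad], collapse = ", "), call. = FALSE)
  }
  invisible(tab)
}

#' @export
print.genome_build <- function(x, ...) {
  cat("<genome_build>", attr(x, "name"), "-", nrow(x), "chromosomes\n")
  NextMethod()
}

# Strip a leading "chr"; keep X; Y/MT are rejected upstream with a warning.
normalize_chrom <- function(x) {
  sub("^chr", "", as.character(x))
}

mini_test_table <- function() {
  tibble::tibble(
    chromosome       = c("1", "2", "3"),
    length           = c(100e6, 80e6, 60e6),
    centromere_start = c(40e6, 30e6, 25e6),
    centromere_end   = c(42e6, 32e6, 27e6)
  )
}

# hg19 (GRCh37) chromosome lengths with centromere intervals taken from the
# UCSC gap/cytoband tables (acen bands). Coordinates in bp, 1-based.
hg19_table <- function() {
  tibble::tibble(
    chromosome = c(as.character(1:22), "X"),
    length = c(
      249250621, 243199373, 198022430, 191154276, 180915260, 171115067,
      159138663, 146364022, 141213431, 135534747, 135006516, 133851895,
      115169878, 107349540, 102531392, 90354753, 81195210, 78077248,
      59128983, 63025520, 48129895, 51304566, 155270560
    ),
    centromere_start = c(
      121535434, 92326171, 90504854, 49660117, 46405641, 58830166,
      58054331, 43838887, 47367679, 39254935, 51644205, 34856694,
      16000000, 16000000, 17000000, 35335801, 22263006, 15460898,
      24681782, 26369569, 11288129, 13000000, 58632012
    ),
    centromere_end = c(
      124535434, 95326171, 93504854, 52660117, 49405641, 61830166,
      61054331, 46838887, 50367679, 42254935, 54644205, 37856694,
      19000000, 19000000, 20000000, 38335801, 25263006, 18460898,
      27681782, 29369569, 14288129, 16000000, 61632012
    )
  )
}

#' Default BRCA1/BRCA2 locus coordinates per genome build
#'
#' For `"hg19"` these are the RefSeq gene footprints
#' (BRCA1 17:41,196,312-41,277,500; BRCA2 13:32,889,617-32,973,809).
#' For `"mini-test"` two arbitrary q-arm loci on chromosomes 1 and 2 stand
#' in so that cohort simulations on the toy genome are self-contained.
#' Override by passing your own tibble wherever a `loci` argument appears.
#'
#' @param genome A [genome_build()].
#' @return Tibble with columns `gene`, `chromosome`, `position`.
#' @export
gene_loci <- function(genome) {
  build <- attr(genome, "name")
  if (identical(build, "mini-test")) {
    tibble::tibble(
      gene = c("BRCA1", "BRCA2"),
      chromosome = c("1", "2"),
      position = c(70e6, 55e6)
    )
  } else {
    tibble::tibble(
      gene = c("BRCA1", "BRCA2"),
      chromosome = c("17", "13"),
      position = c(41236906, 32931713)  # gene-footprint midpoints
    )
  }
}
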