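#' Pipeline configuration
#'
#' Bundles every tunable constant of the simulate / score / call /
#' filter / analyze pipeline in one serializable object with the
#' published defaults.
#'
#' @param params A [sim_params()] object (the cohort model, or the
#'   conditions under which supplied input files were produced).
#' @param hrd An [hrd_config()].
#' @param loh A [loh_config()].
#' @param carrier_af_min,carrier_depth_min Carrier eligibility
#'   thresholds (strict).
#' @param artifact_threshold Artifact-signature exclusion threshold
#'   (strict).
#' @param seed Integer seed for the simulate stage.
#' @return Named list of class `pipeline_config`.
#' @export
pipeline_config <- function(params = sim_params(),
                            hrd = hrd_config(),
                            loh = loh_config(),
                            carrier_af_min = 0.30,
                            carrier_depth_min = 30,
                            artifact_threshold = 0.30,
                            seed = 1) {
  structure(
    list(params = params, hrd = hrd, loh = loh,
      carrier_af_min = carrier_af_min,
      carrier_depth_min = carrier_depth_min,
      artifact_threshold = artifact_threshold, seed = seed),
    class = "pipeline_config"
  )
}

#' Run the full analysis pipeline
#'
#' Simulates (or accepts) a carrier cohort, computes per-sample HRD scar
#' scores, calls locus-specific LOH and biallelic groups, applies the
#' somatic-variant and artifact-signature filters, computes mutational
#' burden, and runs the group and survival comparisons: HRD-Mean
#' biallelic vs non-biallelic per gene (Grubbs-screened pooled t-test),
#' TP53 mutation rate by group (Fisher exact), ovarian overall survival
#' by group (Kaplan-Meier/log-rank), and a Cox model adjusting the group
#' effect for site and stage. Identical config and seed give identical
#' results.
#'
#' @param config A [pipeline_config()].
#' @param inputs Optional list with pre-made `cohort`,
#'   `locus_observations`, `somatic_variants`, `signatures`, `clinical`
#'   (and optionally `truth`); when absent the simulate stage runs.
#' @param out_dir Optional directory for a TSV/JSON report bundle.
#' @return List: `calls`, `scores`, `burden`, `artifact`, `stats`
#'   (list of test results), `recovery` (vs truth, when truth is
#'   available), `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), inputs = NULL,
                         out_dir = NULL) {
  sim <- if (is.null(inputs)) {
    simulate_cohort(config$params, seed = config$seed)
  } else {
    inputs
  }
  cohort <- sim$cohort

  scores <- score_hrd(cohort, config$hrd)

  filt <- filter_somatic_variants(sim$somatic_variants)
  brca_somatic <- filt$kept[filt$kept$gene %in% c("BRCA1", "BRCA2"), ,
    drop = FALSE]

  calls <- call_locus_loh(sim$locus_observations, cohort, config$loh)
  calls <- assign_biallelic_group(calls, brca_somatic)

  artifact <- artifact_fraction_excluded(sim$signatures,
    threshold = config$artifact_threshold)
  analysis_samples <- artifact$sample[!artifact$excluded]

  burden <- mutational_burden(filt$kept, target_mb = config$params$target_mb,
    samples = cohort$meta$sample)

  merged <- calls |>
    dplyr::select("sample", "gene", "status", "mechanism",
      "group_for_genomics") |>
    dplyr::left_join(scores, by = "sample") |>
    dplyr::left_join(burden, by = "sample") |>
    dplyr::left_join(sim$clinical, by = c("sample", "gene")) |>
    dplyr::filter(.data$sample %in% analysis_samples)

  stats_out <- list()
  for (g in unique(merged$gene)) {
    d <- merged[merged$gene == g, ]
    a <- d$hrd_mean[d$group_for_genomics == "BIALLELIC"]
    b <- d$hrd_mean[d$group_for_genomics == "NON_BIALLELIC"]
    if (length(a) >= 3 && length(b) >= 3) {
      stats_out[[paste0("hrd_mean_ttest_", g)]] <-
        compare_means_ttest(a, b, grubbs = TRUE)
    }
    tp53 <- filt$kept$sample[filt$kept$gene == "TP53"]
    tab <- table(
      factor(d$group_for_genomics, c("BIALLELIC", "NON_BIALLELIC")),
      factor(d$sample %in% tp53, c(TRUE, FALSE))
    )
    stats_out[[paste0("tp53_fisher_", g)]] <- tibble::tibble(
      p = fisher_exact_2x2(tab),
      rate_biallelic = tab[1, 1] / max(1, sum(tab[1, ])),
      rate_non_biallelic = tab[2, 1] / max(1, sum(tab[2, ]))
    )
  }

  ov <- merged[merged$tumor_type == "ovary", ]
  if (length(unique(ov$group_for_genomics)) == 2) {
    surv_rec <- tibble::tibble(time = ov$os_months, event = ov$os_event,
      group = ov$group_for_genomics)
    stats_out$ovary_logrank <- km_logrank(surv_rec)
    cox_rec <- tibble::tibble(time = ov$os_months, event = ov$os_event,
      non_biallelic = as.integer(ov$group_for_genomics == "NON_BIALLELIC"),
      site_penn = as.integer(ov$site_source == "Penn"),
      stage_late = as.integer(ov$stage %in% c("III", "IV")))
    stats_out$ovary_cox <- tryCatch(
      cox_adjust(cox_rec, c("non_biallelic", "site_penn", "stage_late")),
      error = function(e) e
    )
  }

  recovery <- NULL
  if (!is.null(sim$truth)) {
    tr <- dplyr::left_join(
      calls[, c("sample", "status", "mechanism", "group_for_genomics")],
      sim$truth, by = "sample")
    recovery <- tibble::tibble(
      n = nrow(tr),
      status_recovery = mean(
        (tr$status == "LOH_POSITIVE") == tr$loh_status_truth),
      mechanism_recovery = mean(tr$mechanism.x == tr$mechanism.y),
      group_recovery = mean(
        tr$group_for_genomics == tr$group_for_genomics_truth)
    )
  }

  manifest <- list(
    seed = config$seed,
    config_hash = rlang::hash(config),
    package_version = as.character(utils::packageVersion("lohscar"))
  )

  out <- list(calls = calls, scores = scores, burden = burden,
    artifact = artifact, merged = merged, stats = stats_out,
    recovery = recovery, manifest = manifest)

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    readr::write_tsv(tibble::as_tibble(calls),
      file.path(out_dir, "loh_calls.tsv"), progress = FALSE)
    readr::write_tsv(tibble::as_tibble(scores),
      file.path(out_dir, "hrd_scores.tsv"), progress = FALSE)
    readr::write_tsv(burden, file.path(out_dir, "burden.tsv"),
      progress = FALSE)
    if (!is.null(stats_out$ovary_logrank)) {
      readr::write_tsv(tidy.km_logrank(stats_out$ovary_logrank),
        file.path(out_dir, "km_curves.tsv"), progress = FALSE)
    }
    stats_json <- purrr::map(stats_out, function(x) {
      if (inherits(x, "km_logrank")) {
        as.list(glance.km_logrank(x))
      } else if (inherits(x, "cox_adjust")) {
        list(terms = tidy.cox_adjust(x), summary = as.list(glance.cox_adjust(x)))
      } else if (inherits(x, "condition")) {
        list(error = conditionMessage(x))
      } else {
        x
      }
    })
    jsonlite::write_json(
      list(stats = stats_json, recovery = recovery, manifest = manifest),
      file.path(out_dir, "report.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  out
}
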