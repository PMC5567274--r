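#' Grubbs outlier screen (extreme studentized deviate)
#'
#' Iteratively removes the single most extreme value while the Grubbs
#' statistic `G = max|x - mean| / sd` exceeds the two-sided critical
#' value at level `alpha`,
#' `G_crit = ((n-1)/sqrt(n)) * sqrt(t^2 / (n - 2 + t^2))` with
#' `t = qt(1 - alpha/(2n), n - 2)`. Applied per group before mean
#' comparisons. With fewer than three values, or zero variance, nothing
#' is removed.
#'
#' @param values Numeric vector.
#' @param alpha Significance level per iteration.
#' @return List with `kept` (values) and `removed` (indices into the
#'   original vector, in removal order).
#' @examples
#' grubbs_screen(c(1, 1.1, 0.9, 1.05, 9))$removed
#' @export
grubbs_screen <- function(values, alpha = 0.05) {
  x <- values
  idx <- seq_along(x)
  removed <- integer(0)
  if (length(x) < 3) {
    warning("fewer than 3 values; Grubbs screen skipped", call. = FALSE)
    return(list(kept = x, removed = removed))
  }
  repeat {
    n <- length(x)
    if (n < 3) break
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) break
    dev <- abs(x - mean(x))
    G <- max(dev) / s
    tcrit <- stats::qt(1 - alpha / (2 * n), df = n - 2)
    Gcrit <- ((n - 1) / sqrt(n)) * sqrt(tcrit^2 / (n - 2 + tcrit^2))
    if (G > Gcrit) {
      i <- which.max(dev)
      removed <- c(removed, idx[i])
      x <- x[-i]
      idx <- idx[-i]
    } else {
      break
    }
  }
  list(kept = x, removed = removed)
}

#' Two-tailed pooled-variance Student's t-test
#'
#' Classic Student's t with a single pooled variance (not Welch),
#' `n_a + n_b - 2` degrees of freedom. Optionally Grubbs-screens each
#' group first. Two identical degenerate groups (zero pooled variance,
#' equal means) give `t = 0`, `p = 1`.
#'
#' @param a,b Numeric vectors (each `n >= 2` after screening).
#' @param grubbs Apply [grubbs_screen()] per group first.
#' @param alpha Screening level.
#' @return Tibble: `t`, `df`, `p`, `mean_a`, `mean_b`, `n_a`, `n_b`.
#' @export
compare_means_ttest <- function(a, b, grubbs = FALSE, alpha = 0.05) {
  if (grubbs) {
    a <- grubbs_screen(a, alpha)$kept
    b <- grubbs_screen(b, alpha)$kept
  }
  if (length(a) < 2 || length(b) < 2) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  sp2 <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
    (length(a) + length(b) - 2)
  if (sp2 == 0) {
    eq <- isTRUE(all.equal(mean(a), mean(b)))
    return(tibble::tibble(
      t = if (eq) 0 else Inf * sign(mean(a) - mean(b)),
      df = length(a) + length(b) - 2, p = if (eq) 1 else 0,
      mean_a = mean(a), mean_b = mean(b), n_a = length(a), n_b = length(b)
    ))
  }
  ht <- stats::t.test(a, b, var.equal = TRUE)
  tibble::tibble(
    t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value,
    mean_a = mean(a), mean_b = mean(b), n_a = length(a), n_b = length(b)
  )
}

#' Two-tailed Fisher exact test on a 2x2 table
#'
#' Exact p by summing hypergeometric probabilities no larger than the
#' observed table's. A table with an empty margin carries no information:
#' `p = 1`.
#'
#' @param table A 2x2 matrix (or something coercible) of nonnegative
#'   integer counts.
#' @return The two-sided p-value.
#' @export
fisher_exact_2x2 <- function(table) {
  m <- as.matrix(table)
  if (!all(dim(m) == c(2, 2))) stop("need a 2x2 table", call. = FALSE)
  if (any(m < 0) || any(m != round(m))) {
    stop("counts must be nonnegative integers", call. = FALSE)
  }
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) return(1)
  stats::fisher.test(m)$p.value
}

#' One-way ANOVA with Tukey HSD pairwise comparisons
#'
#' Ordinary one-way ANOVA (single pooled variance) followed by Tukey's
#' honest significant difference for all pairwise group contrasts.
#'
#' @param values Numeric vector.
#' @param groups Group labels (at least 3 levels, each with `n >= 2`).
#' @return List with `anova` (tibble `f`, `df1`, `df2`, `p`) and
#'   `pairwise` (tibble `contrast`, `diff`, `lwr`, `upr`, `p_adj`).
#' @export
anova_tukey <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 3) stop("need at least 3 groups", call. = FALSE)
  if (any(table(groups) < 2)) stop("every group needs n >= 2", call. = FALSE)
  fit <- stats::aov(values ~ groups)
  an <- summary(fit)[[1]]
  total_ss <- an[1, "Sum Sq"] + an[2, "Sum Sq"]
  if (total_ss <= 1e-10 * (1 + mean(values)^2) * length(values)) {
    # all values identical: no variance anywhere
    lev <- levels(groups)
    pairs <- utils::combn(lev, 2)
    return(list(
      anova = tibble::tibble(f = 0, df1 = an[1, "Df"], df2 = an[2, "Df"], p = 1),
      pairwise = tibble::tibble(
        contrast = paste(pairs[2, ], pairs[1, ], sep = "-"),
        diff = 0, lwr = 0, upr = 0, p_adj = 1
      )
    ))
  }
  tk <- stats::TukeyHSD(fit)$groups
  list(
    anova = tibble::tibble(
      f = an[1, "F value"], df1 = an[1, "Df"], df2 = an[2, "Df"],
      p = an[1, "Pr(>F)"]
    ),
    pairwise = tibble::tibble(
      contrast = rownames(tk), diff = tk[, "diff"], lwr = tk[, "lwr"],
      upr = tk[, "upr"], p_adj = tk[, "p adj"]
    )
  )
}

#' Kaplan-Meier curves and log-rank test
#'
#' Standard log-rank (Mantel-Cox) chi-square across groups, with the
#' Kaplan-Meier step functions returned for plotting. Subjects alive at
#' last follow-up are censored.
#'
#' @param records Tibble with columns `time` (months), `event` (1/TRUE =
#'   death), `group`.
#' @return A `km_logrank` object; see [tidy.km_logrank()] (curve table)
#'   and [glance.km_logrank()] (`chi2`, `df`, `p`).
#' @export
km_logrank <- function(records) {
  r <- tibble::as_tibble(records)
  r$group <- factor(r$group)
  if (nlevels(r$group) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(table(r$group) == 0)) stop("empty group", call. = FALSE)
  sd_fit <- survival::survdiff(
    survival::Surv(time, event) ~ group, data = r)
  km <- survival::survfit(survival::Surv(time, event) ~ group, data = r)
  chi2 <- sd_fit$chisq
  df <- length(sd_fit$n) - 1
  structure(
    list(
      chi2 = unname(chi2), df = df,
      p = stats::pchisq(chi2, df, lower.tail = FALSE),
      survfit = km,
      n = nrow(r)
    ),
    class = "km_logrank"
  )
}

#' @export
print.km_logrank <- function(x, ...) {
  cat("Log-rank test: chi2 =", format(x$chi2, digits = 4),
    "on", x$df, "df, p =", format(x$p, digits = 4), "\n")
  invisible(x)
}

#' Tidy the Kaplan-Meier curves of a log-rank fit
#'
#' @param x A `km_logrank` object.
#' @param ... Unused.
#' @return Tibble: `group`, `time`, `n_risk`, `n_event`, `survival`,
#'   `std_err`.
#' @method tidy km_logrank
#' @export
tidy.km_logrank <- function(x, ...) {
  km <- x$survfit
  strata <- rep(names(km$strata), km$strata)
  tibble::tibble(
    group = sub("^group=", "", strata),
    time = km$time, n_risk = km$n.risk, n_event = km$n.event,
    survival = km$surv, std_err = km$std.err
  )
}

#' One-row summary of a log-rank fit
#'
#' @inheritParams tidy.km_logrank
#' @return Tibble: `chi2`, `df`, `p`, `n`.
#' @method glance km_logrank
#' @export
glance.km_logrank <- function(x, ...) {
  tibble::tibble(chi2 = x$chi2, df = x$df, p = x$p, n = x$n)
}

#' Kaplan-Meier plot
#'
#' @param object A `km_logrank` object.
#' @param ... Unused.
#' @return A ggplot of the survival step functions, annotated with the
#'   log-rank p-value.
#' @method autoplot km_logrank
#' @export
autoplot.km_logrank <- function(object, ...) {
  d <- tidy.km_logrank(object)
  d0 <- dplyr::distinct(d, .data$group) |>
    dplyr::mutate(time = 0, survival = 1)
  d <- dplyr::bind_rows(d0, d)
  ggplot2::ggplot(d, ggplot2::aes(.data$time, .data$survival,
    colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      x = "Months", y = "Overall survival",
      subtitle = paste0("log-rank p = ", format(object$p, digits = 3))
    ) +
    ggplot2::theme_minimal()
}

#' Cox proportional hazards adjustment
#'
#' Partial-likelihood hazard ratios with Wald confidence intervals,
#' delegated to [survival::coxph()]. Non-convergence and covariate
#' degeneracy are raised as errors, never silently dropped.
#'
#' @param records Tibble with `time`, `event`, and the covariate columns.
#' @param covariates Character vector of covariate column names.
#' @return A `cox_adjust` object; [tidy.cox_adjust()] gives per-term
#'   hazard ratios and CIs, [glance.cox_adjust()] the model summary.
#' @export
cox_adjust <- function(records, covariates) {
  r <- tibble::as_tibble(records)
  missing <- setdiff(covariates, names(r))
  if (length(missing) > 0) {
    stop("missing covariate column(s): ", paste(missing, collapse = ", "),
      call. = FALSE)
  }
  for (cv in covariates) {
    if (length(unique(r[[cv]])) < 2) {
      stop("covariate `", cv, "` is constant", call. = FALSE)
    }
  }
  if (sum(r$event) < length(covariates)) {
    stop("fewer events than covariates", call. = FALSE)
  }
  fml <- stats::as.formula(paste(
    "survival::Surv(time, event) ~",
    paste(covariates, collapse = " + ")
  ))
  fit <- survival::coxph(fml, data = r)
  if (!is.null(fit$info) || any(!is.finite(stats::coef(fit)))) {
    stop("Cox model failed to converge (possible separation)", call. = FALSE)
  }
  structure(list(fit = fit, n = nrow(r), n_event = sum(r$event)),
    class = "cox_adjust")
}

#' @export
print.cox_adjust <- function(x, ...) {
  print(tidy.cox_adjust(x))
  invisible(x)
}

#' Tidy hazard ratios from a Cox adjustment
#'
#' @param x A `cox_adjust` object.
#' @param conf_level Confidence level for the Wald interval.
#' @param ... Unused.
#' @return Tibble: `term`, `hr`, `conf_low`, `conf_high`, `p`.
#' @method tidy cox_adjust
#' @export
tidy.cox_adjust <- function(x, conf_level = 0.95, ...) {
  sm <- summary(x$fit, conf.int = conf_level)
  co <- sm$coefficients
  ci <- sm$conf.int
  tibble::tibble(
    term = rownames(co),
    hr = unname(co[, "exp(coef)"]),
    conf_low = unname(ci[, 3]),
    conf_high = unname(ci[, 4]),
    p = unname(co[, "Pr(>|z|)"])
  )
}

#' One-row summary of a Cox adjustment
#'
#' @inheritParams tidy.cox_adjust
#' @return Tibble: `n`, `n_event`, `logrank_p` (score test),
#'   `concordance`.
#' @method glance cox_adjust
#' @export
glance.cox_adjust <- function(x, ...) {
  sm <- summary(x$fit)
  tibble::tibble(
    n = x$n, n_event = x$n_event,
    logrank_p = unname(sm$sctest["pvalue"]),
    concordance = unname(sm$concordance["C"])
  )
}
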