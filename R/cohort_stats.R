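# Cohort-level statistics: attrition accounting, group comparisons from
# summary statistics, empirical AUC with DeLong CIs, cutoff classification.

#' Filter a cohort to the analysis set
#'
#' Removes non-attenders, lost-to-follow-up, operator-error,
#' development-phase and indicated-preterm subjects, leaving the validation
#' subjects with sPTB/term outcome labels. Checks that the accounting sums
#' are consistent before filtering.
#'
#' @param cohort A `cm_cohort` from [generate_cohort()] (or a compatible data
#'   frame with a `group` column).
#' @return The analysis subset (sPTB + term rows) with an `accounting`
#'   attribute reporting enrolled through analyzed counts.
#' @export
filter_analysis_set <- function(cohort) {
  stopifnot(is.data.frame(cohort), "group" %in% names(cohort))
  counts <- table(cohort$group)
  get <- function(g) if (g %in% names(counts)) as.integer(counts[[g]]) else 0L
  acc <- attr(cohort, "accounting")
  if (!is.null(acc)) {
    stated <- c(acc$not_attending, acc$lost_follow_up, acc$operator_error,
                acc$development, acc$sptb, acc$term, acc$indicated_preterm)
    observed <- c(get("excluded_not_attending"), get("excluded_lost_follow_up"),
                  get("excluded_operator_error"), get("development"),
                  get("sptb"), get("term"), get("indicated_preterm"))
    if (sum(stated) != nrow(cohort) || any(stated != observed)) {
      stop("cohort accounting is inconsistent with the group labels")
    }
  }
  analysis <- cohort[cohort$group %in% c("sptb", "term"), , drop = FALSE]
  attr(analysis, "accounting") <- list(
    enrolled = nrow(cohort),
    excluded_pre_exam = get("excluded_not_attending") +
      get("excluded_lost_follow_up") + get("excluded_operator_error"),
    development = get("development"),
    indicated_preterm = get("indicated_preterm"),
    analyzed = nrow(analysis),
    sptb = get("sptb"),
    term = get("term")
  )
  class(analysis) <- class(cohort)
  analysis
}

#' Two-sample t-test from summary statistics
#'
#' Pooled-variance Student t-test (default) or Welch test computed from group
#' means, SDs and sizes, for comparing published group summaries.
#'
#' @param m1,s1,n1 Mean, SD and size of group 1.
#' @param m2,s2,n2 Mean, SD and size of group 2.
#' @param welch Use the Welch (unequal-variance) statistic?
#' @return An object of class `group_comparison`: `t_statistic`,
#'   `degrees_of_freedom`, `p_value` (two-sided), `method`, and the inputs.
#' @examples
#' # average-elasticity comparison, preterm (n = 8) vs term (n = 119)
#' pooled_t_test(0.70, 0.26, 8, 1.63, 0.65, 119)$p_value
#' @export
pooled_t_test <- function(m1, s1, n1, m2, s2, n2, welch = FALSE) {
  if (n1 < 2 || n2 < 2) stop("both groups need n >= 2")
  if (s1 < 0 || s2 < 0) stop("SDs must be >= 0")
  if (welch) {
    se2 <- s1^2 / n1 + s2^2 / n2
    if (se2 == 0) {
      if (m1 == m2) return(.gc_obj(0, n1 + n2 - 2, 1, "welch", m1, s1, n1, m2, s2, n2))
      stop("zero variance with unequal means")
    }
    t_stat <- (m2 - m1) / sqrt(se2)
    df <- se2^2 / ((s1^2 / n1)^2 / (n1 - 1) + (s2^2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
    df <- n1 + n2 - 2
    if (sp2 == 0) {
      if (m1 == m2) return(.gc_obj(0, df, 1, "pooled", m1, s1, n1, m2, s2, n2))
      stop("zero pooled variance with unequal means")
    }
    t_stat <- (m2 - m1) / sqrt(sp2 * (1 / n1 + 1 / n2))
  }
  p <- 2 * stats::pt(-abs(t_stat), df)
  .gc_obj(t_stat, df, p, if (welch) "welch" else "pooled",
          m1, s1, n1, m2, s2, n2)
}

.gc_obj <- function(t_stat, df, p, method, m1, s1, n1, m2, s2, n2) {
  structure(list(t_statistic = t_stat, degrees_of_freedom = df,
                 p_value = p, method = method,
                 group1 = c(mean = m1, sd = s1, n = n1),
                 group2 = c(mean = m2, sd = s2, n = n2)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Two-sample t-test (%s): t = %.3f, df = %.1f, p = %.3g\n",
              x$method, x$t_statistic, x$degrees_of_freedom, x$p_value))
  invisible(x)
}

.check_labels <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  ok <- is.finite(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  if (!any(labels) || all(labels)) stop("both classes must be present")
  list(scores = scores, labels = labels)
}

#' Empirical AUC by Mann-Whitney pair counting
#'
#' The probability that a random positive scores above a random negative,
#' ties counted half: `AUC = (concordant + 0.5 ties) / (n_pos n_neg)`.
#' Computed via midranks; exactly equal to exhaustive pair enumeration.
#' Higher score must mean "more likely positive" (for an elasticity
#' classifier of sPTB, pass the negated elasticity).
#'
#' @param scores Numeric classifier scores.
#' @param labels Logical (or 0/1) outcome, `TRUE` = positive.
#' @return AUC as a fraction in \[0, 1\].
#' @export
empirical_auc <- function(scores, labels) {
  z <- .check_labels(scores, labels)
  n_pos <- sum(z$labels); n_neg <- sum(!z$labels)
  r <- rank(z$scores)   # midranks
  (sum(r[z$labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# DeLong structural components: for each positive, the mean of
# psi(pos, neg) over negatives, and vice versa; psi = 1, 1/2, 0 for
# pos > / = / < neg.
.delong_components <- function(scores, labels) {
  x <- scores[labels]    # positives
  y <- scores[!labels]   # negatives
  m <- length(x); n <- length(y)
  psi <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  list(v10 = rowMeans(psi), v01 = colMeans(psi), auc = mean(psi),
       m = m, n = n)
}

#' DeLong confidence interval and test for the empirical AUC
#'
#' Nonparametric variance of the empirical AUC from DeLong's structural
#' components, the Wald 95% (or `1 - alpha`) confidence interval clipped to
#' \[0, 1\], and a normal-approximation p-value against AUC = 0.5.
#'
#' @inheritParams empirical_auc
#' @param alpha Two-sided error level (default 0.05).
#' @return List with `auc`, `se`, `ci_low`, `ci_high`, `p_value` and a
#'   `degenerate` flag (variance 0, e.g. perfect separation; the CI is then
#'   a clipped point).
#' @export
delong_ci <- function(scores, labels, alpha = 0.05) {
  z <- .check_labels(scores, labels)
  if (sum(z$labels) < 2 || sum(!z$labels) < 2) {
    stop("DeLong variance needs at least 2 subjects per class")
  }
  comp <- .delong_components(z$scores, z$labels)
  v <- stats::var(comp$v10) / comp$m + stats::var(comp$v01) / comp$n
  se <- sqrt(max(v, 0))
  degenerate <- se == 0
  if (degenerate) {
    warning("degenerate AUC variance (perfect or null separation); CI clipped")
  }
  zq <- stats::qnorm(1 - alpha / 2)
  p <- if (se > 0) 2 * stats::pnorm(-abs(comp$auc - 0.5) / se) else
    as.numeric(comp$auc == 0.5)
  list(auc = comp$auc, se = se,
       ci_low = max(0, comp$auc - zq * se),
       ci_high = min(1, comp$auc + zq * se),
       p_value = p, degenerate = degenerate)
}

#' Sensitivity and specificity at an elasticity cutoff
#'
#' Classifies a subject as predicted sPTB when the average cervical
#' elasticity is strictly below the cutoff (ties at the cutoff are negative).
#' Exact binomial (Clopper-Pearson) 95% confidence intervals.
#'
#' @param elasticities Average cervical elasticity, kPa/mm.
#' @param labels Logical outcome, `TRUE` = sPTB.
#' @param cutoff Decision threshold, kPa/mm (default 1.0).
#' @param conf_level Confidence level for the exact intervals.
#' @return List with `sensitivity`, `specificity`, their `ci` vectors
#'   (`c(low, high)`), and the underlying counts.
#' @export
sens_spec_at_cutoff <- function(elasticities, labels, cutoff = 1.0,
                                conf_level = 0.95) {
  z <- .check_labels(elasticities, labels)
  pred_pos <- z$scores < cutoff
  tp <- sum(pred_pos & z$labels); fn <- sum(!pred_pos & z$labels)
  tn <- sum(!pred_pos & !z$labels); fp <- sum(pred_pos & !z$labels)
  sens_test <- stats::binom.test(tp, tp + fn, conf.level = conf_level)
  spec_test <- stats::binom.test(tn, tn + fp, conf.level = conf_level)
  list(sensitivity = tp / (tp + fn),
       specificity = tn / (tn + fp),
       sensitivity_ci = as.numeric(sens_test$conf.int),
       specificity_ci = as.numeric(spec_test$conf.int),
       counts = c(tp = tp, fn = fn, tn = tn, fp = fp),
       cutoff = cutoff)
}

#' ROC analysis of an elasticity classifier
#'
#' Bundles the empirical AUC (on negated elasticity, so lower elasticity
#' means higher sPTB risk), the DeLong interval and test, and the cutoff
#' operating point into one result.
#'
#' @inheritParams sens_spec_at_cutoff
#' @param alpha Error level for the AUC confidence interval.
#' @return An object of class `cm_roc`.
#' @export
roc_analysis <- function(elasticities, labels, cutoff = 1.0, alpha = 0.05) {
  scores <- -elasticities
  dl <- delong_ci(scores, labels, alpha)
  op <- sens_spec_at_cutoff(elasticities, labels, cutoff)
  structure(c(dl, op, list(scores = scores, labels = as.logical(labels))),
            class = "cm_roc")
}

#' @export
print.cm_roc <- function(x, ...) {
  cat(sprintf("ROC analysis: AUC = %.1f%% (95%% CI %.1f - %.1f), p = %.2g\n",
              100 * x$auc, 100 * x$ci_low, 100 * x$ci_high, x$p_value))
  cat(sprintf("  at cutoff %.2f kPa/mm: sensitivity %.1f%% (%.1f - %.1f), specificity %.1f%% (%.1f - %.1f)\n",
              x$cutoff, 100 * x$sensitivity, 100 * x$sensitivity_ci[1],
              100 * x$sensitivity_ci[2], 100 * x$specificity,
              100 * x$specificity_ci[1], 100 * x$specificity_ci[2]))
  invisible(x)
}

#' Plot an empirical ROC curve
#'
#' @param x A [roc_analysis()] result.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.cm_roc <- function(x, ...) {
  th <- sort(unique(x$scores), decreasing = TRUE)
  sens <- vapply(th, function(t) mean(x$scores[x$labels] >= t), numeric(1))
  fpr <- vapply(th, function(t) mean(x$scores[!x$labels] >= t), numeric(1))
  graphics::plot(c(0, fpr, 1), c(0, sens, 1), type = "s",
                 xlab = "1 - specificity", ylab = "Sensitivity", ...)
  graphics::abline(0, 1, lty = 3, col = "grey")
  invisible(x)
}

#' Group-comparison table of subject characteristics
#'
#' Builds the standard characteristics table: per-variable group means and
#' SDs with pooled t-test p-values for maternal age, height, weight,
#' gestational age at exam and at birth, and the anterior/posterior/average
#' cervical length and elasticity; parity and prior preterm birth are
#' reported as counts without a test.
#'
#' @param subjects Analysis-set data frame (see [filter_analysis_set()])
#'   with measured columns `elasticity_*_kpa_mm` / `length_*_mm` (or the
#'   `true_*` columns as fallback for purely synthetic tables) and a `group`
#'   column with `"sptb"`/`"term"`.
#' @param welch Use Welch rather than pooled t-tests.
#' @return A data frame with one row per characteristic: group means/SDs (or
#'   counts), and the p-value where a test applies.
#' @export
summarize_characteristics <- function(subjects, welch = FALSE) {
  stopifnot(is.data.frame(subjects))
  g1 <- subjects[subjects$group == "sptb", , drop = FALSE]
  g2 <- subjects[subjects$group == "term", , drop = FALSE]
  if (nrow(g1) < 2 || nrow(g2) < 2) stop("need >= 2 subjects per group")

  pick <- function(cols) {
    hit <- cols[cols %in% names(subjects)]
    if (length(hit)) hit[1] else NA_character_
  }
  vars <- list(
    c("Maternal age, years", "maternal_age_years"),
    c("Height, cm", "height_cm"),
    c("Weight, kg", "weight_kg"),
    c("Gestational age at exam, days", "ga_exam_days"),
    c("Gestational age at birth, days", "ga_birth_days"),
    c("Anterior cervical length, mm",
      pick(c("length_anterior_mm", "true_length_anterior_mm"))),
    c("Posterior cervical length, mm",
      pick(c("length_posterior_mm", "true_length_posterior_mm"))),
    c("Average cervical length, mm",
      pick(c("avg_length_mm", "true_length_avg_mm"))),
    c("Anterior cervical elasticity, kPa/mm",
      pick(c("elasticity_anterior_kpa_mm", "true_elasticity_anterior_kpa_mm"))),
    c("Posterior cervical elasticity, kPa/mm",
      pick(c("elasticity_posterior_kpa_mm", "true_elasticity_posterior_kpa_mm"))),
    c("Average cervical elasticity, kPa/mm",
      pick(c("avg_elasticity_kpa_mm", "true_elasticity_avg_kpa_mm")))
  )

  rows <- list()
  add <- function(row) rows[[length(rows) + 1L]] <<- row
  miss <- character(0)
  num_row <- function(label, col) {
    if (is.na(col) || !col %in% names(subjects)) {
      miss <<- c(miss, label)
      return(NULL)
    }
    x1 <- g1[[col]][is.finite(g1[[col]])]
    x2 <- g2[[col]][is.finite(g2[[col]])]
    cmp <- pooled_t_test(mean(x1), stats::sd(x1), length(x1),
                         mean(x2), stats::sd(x2), length(x2), welch = welch)
    add(data.frame(characteristic = label,
                   sptb_mean = mean(x1), sptb_sd = stats::sd(x1),
                   term_mean = mean(x2), term_sd = stats::sd(x2),
                   p_value = cmp$p_value))
  }
  count_row <- function(label, flag1, flag2) {
    add(data.frame(characteristic = label,
                   sptb_mean = sum(flag1), sptb_sd = NA_real_,
                   term_mean = sum(flag2), term_sd = NA_real_,
                   p_value = NA_real_))
  }
  num_row("Maternal age, years", vars[[1]][2])
  num_row("Height, cm", vars[[2]][2])
  num_row("Weight, kg", vars[[3]][2])
  if ("parity" %in% names(subjects)) {
    count_row("Parous women", g1$parity > 0, g2$parity > 0)
  } else miss <- c(miss, "Parous women")
  if ("prior_ptb" %in% names(subjects)) {
    count_row("Prior history of PTB", g1$prior_ptb, g2$prior_ptb)
  } else miss <- c(miss, "Prior history of PTB")
  for (v in vars[4:11]) num_row(v[1], v[2])

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "missing_variables") <- miss
  out
}
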