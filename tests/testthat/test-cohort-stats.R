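# Cohort statistics: summary-statistic t-tests, empirical AUC, DeLong
# variance, exact binomial operating points and the characteristics table.

test_that("pooled t-test matches t.test on raw data with exact moments", {
  # construct raw samples whose mean/sd equal the requested summaries exactly
  exact_sample <- function(m, s, n) {
    z <- seq_len(n)
    m + s * scale(z)[, 1]
  }
  set.seed(5)
  cases <- list(c(0.70, 0.26, 8, 1.63, 0.65, 119),
                c(82.7, 13.8, 8, 81.1, 17.9, 119),
                c(10, 2, 12, 11, 3, 40))
  for (cs in cases) {
    x1 <- exact_sample(cs[1], cs[2], cs[3])
    x2 <- exact_sample(cs[4], cs[5], cs[6])
    ours <- pooled_t_test(cs[1], cs[2], cs[3], cs[4], cs[5], cs[6])
    ref <- stats::t.test(x2, x1, var.equal = TRUE)
    expect_equal(ours$t_statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
    ours_w <- pooled_t_test(cs[1], cs[2], cs[3], cs[4], cs[5], cs[6],
                            welch = TRUE)
    ref_w <- stats::t.test(x2, x1)
    expect_equal(ours_w$t_statistic, unname(ref_w$statistic),
                 tolerance = 1e-10)
    expect_equal(ours_w$p_value, ref_w$p.value, tolerance = 1e-12)
  }
})

test_that("published group summaries reproduce their printed p-values", {
  # average elasticity 0.70 +/- 0.26 (n=8) vs 1.63 +/- 0.65 (n=119)
  el <- pooled_t_test(0.70, 0.26, 8, 1.63, 0.65, 119)
  expect_equal(el$t_statistic, 4.013, tolerance = 1e-3)
  expect_lt(abs(el$p_value - 1.1e-4), 1e-5)
  # weight row is a null comparison
  wt <- pooled_t_test(82.7, 13.8, 8, 81.1, 17.9, 119)
  expect_lt(abs(wt$p_value - 0.80), 0.01)
  # anterior elasticity: printed 3.6e-3, recomputes to ~3.7e-3
  ant <- pooled_t_test(0.73, 0.44, 8, 1.67, 0.89, 119)
  expect_lt(abs(ant$p_value - 3.6e-3), 2e-4)
})

test_that("degenerate t-test inputs behave per contract", {
  same <- pooled_t_test(5, 2, 10, 5, 2, 10)
  expect_identical(same$t_statistic, 0)
  zero <- pooled_t_test(5, 0, 10, 5, 0, 10)
  expect_identical(zero$p_value, 1)
  expect_error(pooled_t_test(4, 0, 10, 5, 0, 10), "zero")
  expect_error(pooled_t_test(4, 1, 1, 5, 1, 10), "n >= 2")
})

test_that("empirical AUC equals the exhaustive pair-counting oracle", {
  # worked pair-counting case: positives soft, negatives stiff, negated scores
  pos_e <- c(0.5, 0.9); neg_e <- c(0.8, 1.2, 1.5)
  scores <- -c(pos_e, neg_e)
  labels <- c(TRUE, TRUE, FALSE, FALSE, FALSE)
  expect_equal(empirical_auc(scores, labels), 5 / 6)
  expect_equal(auc_bruteforce(scores, labels), 5 / 6)

  set.seed(31)
  for (rep in 1:25) {
    n <- sample(5:50, 1)
    n_pos <- sample(2:(n - 2), 1)
    scores <- round(rnorm(n), sample(0:2, 1))  # rounding induces ties
    labels <- sample(c(rep(TRUE, n_pos), rep(FALSE, n - n_pos)))
    expect_identical(empirical_auc(scores, labels),
                     auc_bruteforce(scores, labels))
  }

  expect_equal(empirical_auc(c(3, 4, 1, 2), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(empirical_auc(rep(1, 6), c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE)),
               0.5)
  expect_error(empirical_auc(1:4, rep(TRUE, 4)), "both classes")
})

test_that("DeLong variance agrees with pROC and with the bootstrap", {
  skip_if_not_installed("pROC")
  set.seed(19)
  scores <- c(rnorm(12, 1), rnorm(25, 0))
  labels <- c(rep(TRUE, 12), rep(FALSE, 25))
  ours <- delong_ci(scores, labels)
  ref <- pROC::ci.auc(pROC::roc(labels, scores, quiet = TRUE,
                                direction = "<"), method = "delong")
  expect_equal(ours$auc, as.numeric(pROC::auc(pROC::roc(labels, scores,
                                                        quiet = TRUE,
                                                        direction = "<"))),
               tolerance = 1e-12)
  expect_equal(ours$ci_low, as.numeric(ref[1]), tolerance = 1e-10)
  expect_equal(ours$ci_high, as.numeric(ref[3]), tolerance = 1e-10)

  # bootstrap oracle for the standard error on a 30-point set
  set.seed(23)
  sc <- c(rnorm(10, 1.2), rnorm(20, 0))
  lb <- c(rep(TRUE, 10), rep(FALSE, 20))
  dl <- delong_ci(sc, lb)
  boots <- replicate(10000, {
    i <- sample(which(lb), replace = TRUE)
    j <- sample(which(!lb), replace = TRUE)
    empirical_auc(c(sc[i], sc[j]), c(lb[i], lb[j]))
  })
  expect_lt(abs(dl$se - sd(boots)) / sd(boots), 0.15)
})

test_that("duplicating every subject keeps the AUC and shrinks its SE", {
  set.seed(3)
  sc <- c(rnorm(8, 1), rnorm(15))
  lb <- c(rep(TRUE, 8), rep(FALSE, 15))
  one <- delong_ci(sc, lb)
  two <- delong_ci(c(sc, sc), c(lb, lb))
  expect_equal(two$auc, one$auc, tolerance = 1e-12)
  expect_lt(two$se, one$se)
})

test_that("perfect separation clips the interval at one", {
  sc <- c(2, 3, 4, 0, 1, -1)
  lb <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  expect_warning(res <- delong_ci(sc, lb), "degenerate")
  expect_identical(res$auc, 1)
  expect_identical(res$ci_high, 1)
})

test_that("DeLong intervals cover the true AUC at their nominal rate", {
  # binormal model: positives N(1,1), negatives N(0,1);
  # true AUC = pnorm(1/sqrt(2))
  true_auc <- pnorm(1 / sqrt(2))
  set.seed(57)
  hits <- 0
  n_sim <- 500
  for (s in seq_len(n_sim)) {
    sc <- c(rnorm(40, 1), rnorm(40, 0))
    lb <- c(rep(TRUE, 40), rep(FALSE, 40))
    ci <- delong_ci(sc, lb)
    if (ci$ci_low <= true_auc && true_auc <= ci$ci_high) hits <- hits + 1
  }
  expect_gte(hits / n_sim, 0.92)
  expect_lte(hits / n_sim, 0.98)
})

test_that("cutoff classification counts and exact intervals are right", {
  res <- sens_spec_at_cutoff(c(0.5, 0.9, 1.2, 1.4, 1.8, 0.8),
                             c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
                             cutoff = 1.0)
  expect_equal(res$sensitivity, 2 / 3)
  expect_equal(res$specificity, 2 / 3)
  # cutoff below every value: nothing is called positive
  low <- sens_spec_at_cutoff(c(0.5, 0.9, 1.2, 1.4), c(TRUE, TRUE, FALSE, FALSE),
                             cutoff = 0.1)
  expect_identical(low$sensitivity, 0)
  # ties at the cutoff are negative calls (strict inequality)
  tie <- sens_spec_at_cutoff(c(1.0, 0.9, 1.5, 1.0), c(TRUE, TRUE, FALSE, FALSE),
                             cutoff = 1.0)
  expect_equal(tie$sensitivity, 0.5)
  expect_equal(tie$specificity, 1)
  # Clopper-Pearson for 7 of 8 against the beta-quantile closed form
  sevens <- sens_spec_at_cutoff(c(rep(0.5, 7), 1.5, rep(1.5, 5)),
                                c(rep(TRUE, 8), rep(FALSE, 5)))
  expect_equal(sevens$sensitivity_ci[1], qbeta(0.025, 7, 2),
               tolerance = 1e-10)
  expect_equal(round(sevens$sensitivity_ci[1], 3), 0.473)
  expect_equal(sevens$sensitivity_ci[2], qbeta(0.975, 8, 1),
               tolerance = 1e-10)
})

test_that("sensitivity rises and specificity falls with the cutoff", {
  set.seed(101)
  e <- c(rnorm(40, 0.8, 0.3), rnorm(120, 1.6, 0.5))
  lb <- c(rep(TRUE, 40), rep(FALSE, 120))
  cuts <- seq(0.2, 2.5, by = 0.1)
  sens <- vapply(cuts, function(ct) sens_spec_at_cutoff(e, lb, ct)$sensitivity,
                 numeric(1))
  spec <- vapply(cuts, function(ct) sens_spec_at_cutoff(e, lb, ct)$specificity,
                 numeric(1))
  expect_true(all(diff(sens) >= 0))
  expect_true(all(diff(spec) <= 0))
})

test_that("normal-model sensitivity at the 1.0 kPa/mm cutoff converges", {
  cfg <- cohort_config()
  set.seed(11)
  draws <- draw_group_elasticity(cfg, "sptb", 100000)
  sens <- mean(draws < 1.0)
  closed_form <- truncnorm_cdf(1.0, 0.70, 0.26, cfg$elasticity_min)
  expect_lt(abs(sens - closed_form), 0.005)
})

test_that("analysis-set filtering removes the study's exclusions", {
  coh <- generate_cohort(cohort_config(), seed = 3)
  ana <- filter_analysis_set(coh)
  expect_identical(nrow(ana), 127L)
  expect_setequal(unique(ana$group), c("sptb", "term"))
  acc <- attr(ana, "accounting")
  expect_identical(acc$enrolled, 166L)
  expect_identical(acc$analyzed, 127L)
  # 132-subject validation-only cohort loses its 5 indicated-preterm cases
  cc_val <- cohort_config(attrition = c(not_attending = 0, lost_follow_up = 0,
                                        operator_error = 0, development = 0))
  val <- generate_cohort(cc_val, seed = 4)
  expect_identical(nrow(val), 132L)
  expect_identical(nrow(filter_analysis_set(val)), 127L)
  # a cohort with nothing to exclude passes through unchanged
  plain <- generate_cohort(mini_cohort_config(3, 5), seed = 5)
  expect_identical(nrow(filter_analysis_set(plain)), 8L)
  # tampered labels break the accounting contract
  bad <- coh
  bad$group[bad$group == "development"][1] <- "term"
  expect_error(filter_analysis_set(bad), "accounting")
})

test_that("characteristics table has the full row set and sane tests", {
  coh <- generate_cohort(cohort_config(), seed = 6)
  ana <- filter_analysis_set(coh)
  tab <- summarize_characteristics(ana)
  expect_identical(nrow(tab), 13L)
  expect_identical(tab$characteristic[1], "Maternal age, years")
  expect_true("Average cervical elasticity, kPa/mm" %in% tab$characteristic)
  expect_true(all(is.na(tab$p_value[tab$characteristic %in%
                                      c("Parous women",
                                        "Prior history of PTB")])))
  # the group separation designed into the generator shows up in the test
  el_p <- tab$p_value[tab$characteristic == "Average cervical elasticity, kPa/mm"]
  expect_lt(el_p, 0.05)
  # sPTB prevalence in the analysis set
  expect_equal(round(100 * sum(ana$group == "sptb") / nrow(ana), 1), 6.3)
})

test_that("two identical subjects per group give null comparisons", {
  df <- data.frame(
    group = c("sptb", "sptb", "term", "term"),
    maternal_age_years = c(30, 32, 30, 32),
    height_cm = c(160, 165, 160, 165),
    weight_kg = c(70, 80, 70, 80),
    parity = c(1, 0, 1, 0),
    prior_ptb = c(TRUE, FALSE, TRUE, FALSE),
    ga_exam_days = c(180, 190, 180, 190),
    ga_birth_days = c(250, 255, 250, 255),
    true_length_anterior_mm = c(30, 34, 30, 34),
    true_length_posterior_mm = c(31, 33, 31, 33),
    true_length_avg_mm = c(30.5, 33.5, 30.5, 33.5),
    true_elasticity_anterior_kpa_mm = c(1, 2, 1, 2),
    true_elasticity_posterior_kpa_mm = c(1, 2, 1, 2),
    true_elasticity_avg_kpa_mm = c(1, 2, 1, 2))
  tab <- summarize_characteristics(df)
  tested <- !is.na(tab$p_value)
  expect_true(all(tab$p_value[tested] == 1))
})
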