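# Synthetic cohort generation: group sizes, attrition accounting and
# per-subject ground-truth tissue parameters.

# Truncated-normal draws by rejection; lower bound only.
.rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (n == 0) return(numeric(0))
  x <- stats::rnorm(n, mean, sd)
  for (it in 1:1000) {
    bad <- x < lower | x > upper
    if (!any(bad)) break
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  x
}

.group_row <- function(n, el_avg, el_ant, el_post, len_avg, len_ant, len_post,
                       age, height, weight, parous_frac, prior_ptb_frac,
                       ga_birth) {
  list(n = as.integer(n), el_avg = el_avg, el_ant = el_ant, el_post = el_post,
       len_avg = len_avg, len_ant = len_ant, len_post = len_post,
       age = age, height = height, weight = weight,
       parous_frac = parous_frac, prior_ptb_frac = prior_ptb_frac,
       ga_birth = ga_birth)
}

#' Cohort configuration
#'
#' Group sizes, attrition counts and per-group distributions of true cervical
#' elasticity, length, demographics and gestational age at birth. Defaults
#' describe a 166-subject enrolment: 5 non-attenders, 7 lost to follow-up,
#' 2 operator errors, a development phase (20 subjects, so the accounting
#' sums: enrolled minus exclusions minus development equals the validation
#' size), and a 132-subject validation cohort of 8 sPTB, 119 term and 5
#' indicated-preterm subjects, of whom 127 form the analysis set.
#' Elasticity and length distributions are truncated normals
#' (elasticity > 0.05 kPa/mm, length > 10 mm, preventing unphysical draws);
#' the indicated-preterm group draws its cervical parameters from the sPTB
#' distributions, matching the observation that medically indicated preterm
#' cases show similarly softened cervixes.
#'
#' Each group's distribution is given as `c(mean, sd)` for the
#' subject-average value and for the anterior/posterior sectors. Sector
#' values are generated as `avg +/- delta` with `delta` normal around half
#' the anterior-posterior mean gap and with variance set to the average
#' excess of the sector variances over the subject-average variance, so the
#' generated sector rows track the configured ones.
#'
#' @param sptb,term,indicated Per-group settings; see Details/defaults.
#' @param attrition Named counts: `not_attending`, `lost_follow_up`,
#'   `operator_error`, `development`.
#' @param elasticity_min,length_min Truncation bounds.
#' @param ga_exam_range Gestational age at exam, days (uniform integer draw).
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(
    sptb = .group_row(8, c(0.70, 0.26), c(0.73, 0.44), c(0.68, 0.21),
                      c(34.9, 7.7), c(34.9, 9.8), c(34.8, 8.8),
                      c(32.0, 5.3), c(161.5, 8.4), c(82.7, 13.8),
                      0.50, 0.25, c(243, 12)),
    term = .group_row(119, c(1.63, 0.65), c(1.67, 0.89), c(1.58, 0.59),
                      c(30.4, 6.8), c(30.8, 8.5), c(30.1, 7.2),
                      c(30.8, 6.2), c(162.7, 6.7), c(81.1, 17.9),
                      0.38, 0.09, c(274, 9)),
    indicated = list(n = 5L),
    attrition = c(not_attending = 5, lost_follow_up = 7, operator_error = 2,
                  development = 20),
    elasticity_min = 0.05,
    length_min = 10,
    ga_exam_range = c(168, 202)) {
  cfg <- list(sptb = sptb, term = term, indicated = indicated,
              attrition = attrition, elasticity_min = elasticity_min,
              length_min = length_min, ga_exam_range = ga_exam_range)
  counts <- c(sptb$n, term$n, indicated$n, attrition)
  if (any(counts < 0)) stop("group and attrition counts must be >= 0")
  for (g in list(sptb, term)) {
    sds <- c(g$el_avg[2], g$el_ant[2], g$el_post[2], g$len_avg[2],
             g$len_ant[2], g$len_post[2], g$age[2], g$height[2], g$weight[2],
             g$ga_birth[2])
    if (any(sds <= 0)) stop("all group SDs must be > 0")
  }
  structure(cfg, class = "cohort_config")
}

# Sector values around a subject-average vector: avg +/- delta, rejecting
# deltas that push either sector below `lower`.
.sector_pair <- function(avg, d_mean, d_sd, lower) {
  n <- length(avg)
  d <- stats::rnorm(n, d_mean, d_sd)
  for (it in 1:100) {
    bad <- (avg - abs(d)) <= lower
    if (!any(bad)) break
    d[bad] <- stats::rnorm(sum(bad), d_mean, d_sd)
  }
  d[(avg - abs(d)) <= lower] <- 0
  cbind(anterior = avg + d, posterior = avg - d)
}

.sector_excess_sd <- function(avg_sd, ant_sd, post_sd) {
  sqrt(max(0, mean(c(ant_sd^2 - avg_sd^2, post_sd^2 - avg_sd^2))))
}

#' Draw true subject-average elasticities for one group
#'
#' Convenience access to the configured truncated-normal group distribution,
#' used both by [generate_cohort()] and for large normal-model checks.
#'
#' @param config A [cohort_config()].
#' @param group `"sptb"`, `"term"` or `"indicated"`.
#' @param n Number of draws.
#' @return Numeric vector of elasticities, kPa/mm.
#' @export
draw_group_elasticity <- function(config, group = c("sptb", "term", "indicated"),
                                  n) {
  stopifnot(inherits(config, "cohort_config"))
  group <- match.arg(group)
  g <- if (group == "term") config$term else config$sptb
  .rtruncnorm(n, g$el_avg[1], g$el_avg[2], lower = config$elasticity_min)
}

# One block of subjects from a group's distributions.
.draw_group <- function(cfg, g, n, label, with_outcome = TRUE) {
  n <- as.integer(n)
  el_avg <- .rtruncnorm(n, g$el_avg[1], g$el_avg[2], cfg$elasticity_min)
  el_sec <- .sector_pair(el_avg, (g$el_ant[1] - g$el_post[1]) / 2,
                         .sector_excess_sd(g$el_avg[2], g$el_ant[2], g$el_post[2]),
                         cfg$elasticity_min)
  len_avg <- .rtruncnorm(n, g$len_avg[1], g$len_avg[2], cfg$length_min)
  len_sec <- .sector_pair(len_avg, (g$len_ant[1] - g$len_post[1]) / 2,
                          .sector_excess_sd(g$len_avg[2], g$len_ant[2],
                                            g$len_post[2]),
                          cfg$length_min)
  parous <- stats::rbinom(n, 1, g$parous_frac)
  data.frame(
    group = rep(label, n),
    maternal_age_years = round(.rtruncnorm(n, g$age[1], g$age[2], 16, 50), 1),
    height_cm = round(.rtruncnorm(n, g$height[1], g$height[2], 140, 190), 1),
    weight_kg = round(.rtruncnorm(n, g$weight[1], g$weight[2], 40, 180), 1),
    parity = parous * (1 + stats::rpois(n, 0.6)),
    prior_ptb = stats::rbinom(n, 1, g$prior_ptb_frac) == 1,
    ga_exam_days = sample(seq(cfg$ga_exam_range[1], cfg$ga_exam_range[2]),
                          n, replace = TRUE),
    ga_birth_days = if (with_outcome) {
      preterm <- g$ga_birth[1] < 259
      round(.rtruncnorm(n, g$ga_birth[1], g$ga_birth[2],
                        if (preterm) max(210, cfg$ga_exam_range[2] + 1) else 259,
                        if (preterm) 258 else 294))
    } else rep(NA_real_, n),
    true_elasticity_anterior_kpa_mm = el_sec[, "anterior"],
    true_elasticity_posterior_kpa_mm = el_sec[, "posterior"],
    true_elasticity_avg_kpa_mm = el_avg,
    true_length_anterior_mm = len_sec[, "anterior"],
    true_length_posterior_mm = len_sec[, "posterior"],
    true_length_avg_mm = len_avg,
    comfort = sample(1:3, n, replace = TRUE, prob = c(0.425, 0.512, 0.063))
  )
}

#' Generate a synthetic study cohort
#'
#' Draws a full enrolment with ground-truth per-sector tissue parameters,
#' demographics, outcome labels and attrition accounting. Subjects excluded
#' before examination (non-attenders, lost to follow-up, operator error)
#' carry no measurements; development-phase subjects carry ground truth but
#' are excluded from analysis, as are indicated-preterm subjects.
#'
#' @param config A [cohort_config()].
#' @param seed Optional integer seed fixing all randomness.
#' @return A `cm_cohort` data frame, one row per enrolled subject, with an
#'   `accounting` attribute summing enrolment to the analyzed set.
#' @examples
#' coh <- generate_cohort(cohort_config(), seed = 1)
#' nrow(coh)                       # 166 enrolled
#' attr(coh, "accounting")$analyzed  # 127
#' @export
generate_cohort <- function(config = cohort_config(), seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (!is.null(seed)) set.seed(seed)
  att <- config$attrition
  term_like <- config$term

  # indicated-preterm: cervix from the sPTB distributions, outcome preterm
  ind_group <- config$sptb
  ind_group$n <- config$indicated$n

  excl <- .draw_group(config, term_like,
                      sum(att[c("not_attending", "lost_follow_up",
                                "operator_error")]),
                      "excluded", with_outcome = FALSE)
  excl$group <- rep(c("excluded_not_attending", "excluded_lost_follow_up",
                      "excluded_operator_error"),
                    times = att[c("not_attending", "lost_follow_up",
                                  "operator_error")])
  if (nrow(excl)) {
    excl[, grep("^true_", names(excl))] <- NA_real_
    excl$comfort <- NA_integer_
  }
  cohort <- rbind(
    excl,
    .draw_group(config, term_like, att[["development"]], "development",
                with_outcome = FALSE),
    .draw_group(config, config$sptb, config$sptb$n, "sptb"),
    .draw_group(config, config$term, config$term$n, "term"),
    .draw_group(config, ind_group, ind_group$n, "indicated_preterm")
  )
  cohort <- cbind(subject_id = sprintf("S%03d", seq_len(nrow(cohort))),
                  cohort, stringsAsFactors = FALSE)
  rownames(cohort) <- NULL
  n_val <- config$sptb$n + config$term$n + config$indicated$n
  attr(cohort, "accounting") <- list(
    enrolled = nrow(cohort),
    not_attending = unname(att[["not_attending"]]),
    lost_follow_up = unname(att[["lost_follow_up"]]),
    operator_error = unname(att[["operator_error"]]),
    development = unname(att[["development"]]),
    validation = n_val,
    sptb = config$sptb$n,
    term = config$term$n,
    indicated_preterm = config$indicated$n,
    analyzed = config$sptb$n + config$term$n
  )
  class(cohort) <- c("cm_cohort", "data.frame")
  cohort
}

#' @export
print.cm_cohort <- function(x, ...) {
  acc <- attr(x, "accounting")
  cat(sprintf("Synthetic cohort: %d enrolled\n", nrow(x)))
  if (!is.null(acc)) {
    cat(sprintf("  validation %d (sPTB %d, term %d, indicated %d); analyzed %d\n",
                acc$validation, acc$sptb, acc$term, acc$indicated_preterm,
                acc$analyzed))
  }
  invisible(x)
}
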