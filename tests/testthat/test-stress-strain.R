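# Stress-strain slope fitting: exact cases, recovery accuracy, invariances,
# subject summaries and the amplitude map.

test_that("an exact two-point line gives the textbook slope and length", {
  d <- data.frame(pressure_kpa = c(0, 21), depth_mm = c(43, 25))
  fit <- fit_stress_strain(d, quality = list(min_frames = 2))
  expect_equal(fit$elasticity, 21 / 18, tolerance = 1e-12)
  expect_equal(fit$zero_pressure_length, 43, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1)
  expect_true(fit$valid)
  expect_equal(unname(coef(fit)["elasticity_kpa_mm"]), 21 / 18,
               tolerance = 1e-12)
})

test_that("r-squared is exactly one for collinear frames", {
  d <- data.frame(depth_mm = seq(40, 20, length.out = 25))
  d$pressure_kpa <- 30 - 0.7 * d$depth_mm
  fit <- fit_stress_strain(d)
  expect_identical(fit$r_squared, 1)
  expect_equal(fit$elasticity, 0.7, tolerance = 1e-12)
})

test_that("constant depth is a degenerate no-compression fit", {
  d <- data.frame(pressure_kpa = seq(1, 21, length.out = 30),
                  depth_mm = rep(35, 30))
  fit <- fit_stress_strain(d)
  expect_false(fit$valid)
  expect_identical(fit$reason, "no_compression")
  # depth increasing with pressure is equally unusable
  d2 <- data.frame(pressure_kpa = seq(1, 21, length.out = 30),
                   depth_mm = seq(30, 40, length.out = 30))
  expect_identical(fit_stress_strain(d2)$reason, "positive_slope")
  expect_error(fit_stress_strain(d[1, , drop = FALSE]), "at least 2")
})

test_that("noise-free exams recover the mapped slopes to under one percent", {
  # the two slope scenarios shown on the example stress-strain maps
  for (E in c(3.5, 0.44)) {
    tis <- tissue_model(E, 43, scatterer_density = 0)
    rec <- simulate_exam(tis, probe_spec(), compression_protocol(), seed = 13,
                         snr_db = Inf, pressure_noise = FALSE)
    fit <- fit_stress_strain(track_exam(rec))
    expect_true(fit$valid)
    expect_lt(abs(fit$elasticity - E) / E, 0.01)
    expect_lt(abs(fit$elasticity - E), 0.02)
    expect_lt(abs(fit$zero_pressure_length - 43), 0.5)
  }
})

test_that("fit is invariant to time reversal of the frames", {
  tis <- tissue_model(1.2, 36, scatterer_density = 0)
  rec <- simulate_exam(tis, fast_probe(), fast_protocol(), seed = 6,
                       snr_db = Inf, pressure_noise = FALSE)
  tr <- track_exam(rec)
  fit_fwd <- fit_stress_strain(tr, quality = fast_quality)
  fit_rev <- fit_stress_strain(tr[rev(seq_len(nrow(tr))), ],
                               quality = fast_quality)
  expect_equal(fit_rev$elasticity, fit_fwd$elasticity, tolerance = 1e-12)
  expect_equal(fit_rev$zero_pressure_length, fit_fwd$zero_pressure_length,
               tolerance = 1e-12)
})

test_that("noisy exams recover elasticity with small median error", {
  set.seed(77)
  n_cases <- 200
  es <- exp(runif(n_cases, log(0.3), log(4.0)))
  rel_err <- numeric(n_cases)
  pr <- fast_probe()
  proto <- fast_protocol()
  for (i in seq_len(n_cases)) {
    tis <- tissue_model(es[i], runif(1, 25, 43))
    rec <- simulate_exam(tis, pr, proto, seed = 1000 + i,
                         snr_db = 20, pressure_noise = TRUE)
    fit <- fit_stress_strain(track_exam(rec), quality = fast_quality)
    rel_err[i] <- abs(fit$elasticity - es[i]) / es[i]
  }
  expect_lt(median(rel_err), 0.05)
})

test_that("model methods are coherent", {
  d <- data.frame(pressure_kpa = c(1, 6, 11, 16, 21),
                  depth_mm = c(40, 36, 32, 28, 24))
  fit <- fit_stress_strain(d, quality = list(min_frames = 5))
  expect_equal(predict(fit, data.frame(depth_mm = fit$zero_pressure_length)),
               0, tolerance = 1e-9)
  expect_equal(fitted(fit) + residuals(fit), d$pressure_kpa)
  s <- summary(fit)
  expect_s3_class(s, "summary.stress_strain_fit")
  recs <- simulate(fit, nsim = 2, seed = 3,
                   probe = fast_probe(), protocol = fast_protocol(),
                   snr_db = Inf, pressure_noise = FALSE)
  expect_length(recs, 2)
  refit <- fit_stress_strain(track_exam(recs[[1]]), quality = fast_quality)
  expect_lt(abs(refit$elasticity - fit$elasticity) / fit$elasticity, 0.02)
})

test_that("robust variant shrugs off a pressure outlier", {
  d <- data.frame(depth_mm = seq(40, 25, length.out = 31))
  d$pressure_kpa <- 42 - d$depth_mm  # slope -1 exactly
  d$pressure_kpa[16] <- d$pressure_kpa[16] + 15
  lad <- fit_stress_strain(d, method = "lad")
  expect_lt(abs(lad$elasticity - 1), 0.01)
})

test_that("subject summary averages the valid sectors", {
  mk <- function(E, L, valid = TRUE) {
    d <- data.frame(pressure_kpa = seq(1, 21, length.out = 30))
    d$depth_mm <- L - d$pressure_kpa / E
    f <- fit_stress_strain(d)
    if (!valid) f$valid <- FALSE
    f
  }
  s <- subject_summary(mk(0.73, 35), mk(0.68, 34))
  expect_equal(s$avg_elasticity, 0.705, tolerance = 1e-9)
  expect_false(s$single_sector)
  s1 <- subject_summary(mk(1.2, 30), mk(0.9, 30, valid = FALSE))
  expect_equal(s1$avg_elasticity, 1.2, tolerance = 1e-9)
  expect_true(s1$single_sector)
  s2 <- subject_summary(mk(1.5, 30), mk(1.5, 30))
  expect_equal(s2$avg_elasticity, 1.5, tolerance = 1e-9)
  expect_error(subject_summary(mk(1, 30, valid = FALSE),
                               mk(1, 30, valid = FALSE)),
               "unusable")
})

test_that("stress-strain map traces the compression line", {
  tis <- tissue_model(21 / 18, 43, scatterer_density = 0)
  rec <- simulate_exam(tis, probe_spec(), compression_protocol(), seed = 8,
                       snr_db = Inf, pressure_noise = FALSE)
  tr <- track_exam(rec)
  m <- build_map(rec, tr)
  expect_s3_class(m, "stress_strain_map")
  # row at 21 kPa has its brightest bin at ~25 mm
  r21 <- which.min(abs(m$pressure_bins - 21))
  d_at_21 <- m$depth_bins[which.max(m$amplitude[r21, ])]
  expect_lt(abs(d_at_21 - 25), 0.5)
  # per-row argmax depths fall on a line of slope -E
  d_star <- m$depth_bins[apply(m$amplitude, 1, which.max)]
  slope <- stats::coef(stats::lm(m$pressure_bins ~ d_star))[2]
  expect_lt(abs(abs(slope) - 21 / 18) / (21 / 18), 0.05)
  # misaligned track is rejected
  expect_error(build_map(rec, tr[-1, ]), "lengths differ")
})

test_that("a single-frame recording maps to a single pressure row", {
  tis <- tissue_model(2, 30, scatterer_density = 0)
  pr <- fast_probe(40)
  rec <- simulate_exam(tis, pr,
                       compression_protocol(ramp_duration = 1 / pr$frame_rate),
                       seed = 2, snr_db = Inf, pressure_noise = FALSE)
  expect_identical(ncol(rec$samples), 1L)
  m <- build_map(rec)
  expect_identical(nrow(m$amplitude), 1L)
})
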