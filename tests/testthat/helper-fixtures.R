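# Shared fixtures: small, fast acquisition settings and independent signal
# oracles used across the test files.

# Reduced-depth probe keeps A-lines short so simulated exams stay cheap.
fast_probe <- function(record_depth = 50) probe_spec(record_depth = record_depth)

fast_protocol <- function(peak = 21, ramp = 0.5) {
  compression_protocol(peak_pressure = peak, ramp_duration = ramp)
}

# Relaxed gates for short test exams (the defaults expect 3 s ramps).
fast_quality <- list(min_frames = 10, min_span_kpa = 3, min_r2 = 0.8)

# Independent Gabor burst generator (not the package's synthesis path):
# amplitude `amp`, centre `t0` seconds, Gaussian envelope sd `sigma` seconds.
make_burst <- function(n, fs, t0, sigma, f0 = 5e6, amp = 1) {
  t <- (seq_len(n) - 1) / fs
  amp * exp(-(t - t0)^2 / (2 * sigma^2)) * cos(2 * pi * f0 * (t - t0))
}

# Analytic-signal (quadrature) envelope via FFT: the textbook oracle for
# envelope detection of a real narrowband signal.
hilbert_envelope <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE) / n)
}

# Exhaustive pair-counting AUC (ties count half): the brute-force oracle.
auc_bruteforce <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  total <- 0
  for (x in pos) for (y in neg) {
    total <- total + (x > y) + 0.5 * (x == y)
  }
  total / (length(pos) * length(neg))
}

# Mean of a normal truncated below at `a`.
truncnorm_mean <- function(mean, sd, lower) {
  a <- (lower - mean) / sd
  mean + sd * stats::dnorm(a) / (1 - stats::pnorm(a))
}

# P(X < q) for a normal truncated below at `lower`.
truncnorm_cdf <- function(q, mean, sd, lower) {
  a <- stats::pnorm((lower - mean) / sd)
  (stats::pnorm((q - mean) / sd) - a) / (1 - a)
}

# A tiny all-validation cohort configuration for pipeline tests.
mini_cohort_config <- function(n_sptb = 4, n_term = 8) {
  base <- cohort_config()
  cohort_config(
    sptb = utils::modifyList(base$sptb, list(n = as.integer(n_sptb))),
    term = utils::modifyList(base$term, list(n = as.integer(n_term))),
    indicated = list(n = 0L),
    attrition = c(not_attending = 0, lost_follow_up = 0,
                  operator_error = 0, development = 0)
  )
}
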