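test_that("band and interval selection follow half-open conventions", {
  # 1 Hz resolution, band [0, 10): 9 bins once DC is excluded
  vals <- array(rexp(9 * 21 * 4) + 0.1, dim = c(9, 21, 4))
  spec <- toy_spectrogram(vals, seq(0.1, 0.9, 0.1), freqs_hz = 0:20,
                          window_starts_min = c(120, 125, 130, 135),
                          window_min = 5)
  bv <- band_values(spec, c(0, 10), 0.5, c(120, 130))
  expect_equal(length(bv), 2L)                  # windows at 120 and 125
  expect_equal(length(bv[[1]]), 9L)
  expect_equal(names(bv), c("120", "125"))

  # 15-min windows from 120: interval [165, 240) selects 5 windows
  spec2 <- toy_spectrogram(array(1, dim = c(1, 3, 24)), 0.5, 0:2,
                           window_starts_min = seq(120, 465, 15),
                           window_min = 15)
  bv2 <- band_values(spec2, c(1, 3), 0.5, c(165, 240))
  expect_equal(as.numeric(names(bv2)), c(165, 180, 195, 210, 225))

  expect_error(band_values(spec, c(30, 40), 0.5, c(120, 130)), "no frequency")
  expect_error(band_values(spec, c(0, 10), 0.5, c(500, 600)), "no windows")
})

test_that("spikiness is max/median, scale-free, and guards its domain", {
  expect_equal(spikiness(rep(3.3, 8)), 1)
  expect_equal(spikiness(c(1, 1, 1, 9)), 9)
  expect_equal(spikiness(c(1, 1, 1, 9) * 1e4), 9)   # scale invariance
  expect_error(spikiness(c(1, 0, 2)), "positive")
  expect_error(spikiness(5), "at least 2")

  # a band-interior sinusoid raises expected spikiness over white noise
  set.seed(6)
  fs <- 200
  t <- (0:(fs * 60 - 1)) / fs
  sp <- function(x) {
    pg <- segment_periodograms(x, fs, welch_params(1, 0))
    qs <- quantile_spectrum(pg, 0.5)
    bins <- attr(pg, "freqs_hz") >= 10 & attr(pg, "freqs_hz") < 50
    spikiness(qs[1, bins])
  }
  plain <- replicate(20, sp(rnorm(length(t))))
  tone <- replicate(20, sp(rnorm(length(t)) + 0.5 * sin(2 * pi * 30 * t)))
  expect_gt(mean(tone), mean(plain))
})

test_that("js_chi2 matches its closed forms and detects the chi-squared law", {
  k <- 16
  # one sample per equal-probability reference bin -> exact identity
  x <- qchisq(((1:k) - 0.5) / k, df = 2) * 3.7
  expect_equal(js_chi2(x), 0)

  # identical values put all mass in one bin: closed-form point mass vs
  # uniform over 16 bins
  p <- c(1, rep(0, k - 1)); q <- rep(1 / k, k); m <- (p + q) / 2
  kl <- function(a, b) sum(ifelse(a > 0, a * log2(a / b), 0))
  expect_equal(js_chi2(rep(5, 16)), sqrt(0.5 * kl(p, m) + 0.5 * kl(q, m)))

  # draws from a scaled chi-squared(2) sit close to the reference
  set.seed(14)
  expect_lt(js_chi2(7.3 * rchisq(10000, 2)), 0.05)
  # scale invariance
  set.seed(14)
  y <- rchisq(500, 2)
  expect_equal(js_chi2(y), js_chi2(1000 * y))

  expect_error(js_chi2(rexp(10)), "at least 16")
  expect_error(js_chi2(c(rep(1, 20), -1)), "positive")
})

test_that("summaries pool windows and combinators compare intervals", {
  spec <- powers_spectrogram(c(3, 1, 2), window_starts_min = c(0, 5, 10))
  # 10th percentile of pooled {3,1,2} under linear interpolation
  d <- feature_descriptor("band_power", c(0, 2), 0.5, c(0, 15),
                          summary_pct = 10)
  expect_equal(summarize_feature(d, spec), 1.2)

  # single-window interval: any percentile returns that window's value
  for (pct in c(10, 50, 95)) {
    d1 <- feature_descriptor("band_power", c(0, 2), 0.5, c(5, 10), pct)
    expect_equal(summarize_feature(d1, spec), 1)
  }

  # ratio of identical intervals is exactly 1; difference is 0
  dr <- feature_descriptor("band_power", c(0, 2), 0.5, c(0, 15), 50,
                           "ratio", c(0, 15))
  expect_equal(summarize_feature(dr, spec), 1)
  dd <- feature_descriptor("band_power", c(0, 2), 0.5, c(0, 15), 50,
                           "difference", c(0, 15))
  expect_equal(summarize_feature(dd, spec), 0)

  # ratio orientation: second interval over first
  dr2 <- feature_descriptor("band_power", c(0, 2), 0.5, c(0, 5), 50,
                            "ratio", c(5, 15))
  expect_equal(summarize_feature(dr2, spec), 1.5 / 3)
})

test_that("descriptor grammar enumerates a deterministic Cartesian product", {
  g <- feature_grammar(kinds = c("band_power", "spikiness"),
                       bands = list(c(0, 10), c(10, 100), c(100, 400)),
                       levels = c(0.1, 0.9),
                       intervals = list(c(0, 120), c(120, 240)),
                       summary_pcts = c(10, 95),
                       combinators = "value")
  ds <- enumerate_grammar(g)
  expect_length(ds, 48L)                        # 2 x 3 x 2 x 2 x 2
  nms <- vapply(ds, function(d) d$name, character(1))
  expect_false(anyDuplicated(nms) > 0)          # canonical names are unique
  expect_identical(nms, vapply(enumerate_grammar(g), function(d) d$name,
                               character(1)))   # stable across calls

  # pair combinators add one ratio per interval pair
  g2 <- feature_grammar(kinds = "band_power", bands = list(c(0, 10)),
                        levels = 0.5, intervals = list(c(0, 10), c(10, 20)),
                        summary_pcts = 50, combinators = c("value", "ratio"))
  expect_length(enumerate_grammar(g2), 3L)
})

test_that("feature matrix assembly is deterministic, order-equivariant and strict", {
  cfg <- quiet_config(seed = 2, effect = list(band_lo_hz = 10,
                                              band_hi_hz = 50,
                                              power_ratio = 0.25,
                                              tau_min = 1),
                      medium_min = 4, drug_min = 4)
  cs <- cohort_spectrograms(3, 3, cfg, seed = 55, window_min = 2,
                            welch = welch_params(overlap_frac = 0))
  g <- feature_grammar(kinds = c("band_power", "spikiness"),
                       bands = list(c(0, 10), c(10, 50), c(50, 100)),
                       levels = 0.5,
                       intervals = list(c(0, 4), c(4, 8)),
                       summary_pcts = 50,
                       combinators = c("value", "ratio"))
  fm <- build_feature_matrix(cs$spectrograms, g, labels = cs$labels)
  expect_equal(dim(fm$values), c(6L, 2L * 3L * 3L))
  expect_true(all(is.finite(fm$values)))

  # permuting the cohort permutes rows only
  perm <- c(4, 1, 6, 2, 5, 3)
  fm2 <- build_feature_matrix(cs$spectrograms[perm], g,
                              labels = cs$labels[perm])
  expect_equal(fm2$values, fm$values[perm, ])

  # the injected band/interval carries the strongest label correlation
  # among band_power features (brute force over the grammar)
  bp_cols <- grep("^band_power", colnames(fm$values), value = TRUE)
  y <- as.integer(fm$labels == "positive")
  cors <- abs(vapply(bp_cols, function(cn) cor(fm$values[, cn], y),
                     numeric(1)))
  best <- names(which.max(cors))
  expect_match(best, "b10-50Hz")
  expect_match(best, "t4-8min")   # the drug-phase interval, alone or in a pair

  # axis mismatch across the cohort is an error naming the sample
  other <- cohort_spectrograms(1, 0, cfg, seed = 56, window_min = 4,
                               welch = welch_params(overlap_frac = 0))
  expect_error(
    build_feature_matrix(c(cs$spectrograms, other$spectrograms), g),
    "axes differ.*7")
})

test_that("features are reproducible from spectrogram plus canonical name", {
  cfg <- quiet_config(seed = 40)
  rec <- simulate_recording(cfg)
  qs <- quantile_spectrogram(rec, 2, welch = welch_params(overlap_frac = 0))
  d <- feature_descriptor("js_chi2", c(10, 100), 0.9, c(2, 8), 95)
  v1 <- summarize_feature(d, qs)
  # rebuild the descriptor from scratch and a freshly recomputed spectrogram
  d2 <- feature_descriptor("js_chi2", c(10, 100), 0.9, c(2, 8), 95)
  qs2 <- quantile_spectrogram(simulate_recording(cfg), 2,
                              welch = welch_params(overlap_frac = 0))
  expect_identical(d$name, d2$name)
  expect_identical(v1, summarize_feature(d2, qs2))
})
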