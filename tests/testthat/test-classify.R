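test_that("4:1:1 floor/remainder rule reproduces the published split tables", {
  counts <- function(n_pos, n_neg, seed = 1) {
    labels <- c(rep("positive", n_pos), rep("negative", n_neg))
    split_counts(stratified_split(labels, seed = seed), labels)
  }
  # colon-cancer cohort: 34 treated / 24 untreated
  tab <- counts(34, 24)
  expect_equal(unname(tab["train", "positive"]), 22)
  expect_equal(unname(tab["validation", "positive"]), 5)
  expect_equal(unname(tab["test", "positive"]), 7)
  expect_equal(unname(tab["train", "negative"]), 16)
  expect_equal(unname(tab["validation", "negative"]), 4)
  expect_equal(unname(tab["test", "negative"]), 4)
  # ovarian cohort: 38 susceptible / 36 resistant
  tab2 <- counts(38, 36)
  expect_equal(unname(tab2[, "positive"]), c(25, 6, 7))
  expect_equal(unname(tab2[, "negative"]), c(24, 6, 6))
  # exact divisibility
  tab3 <- counts(6, 6)
  expect_equal(unname(tab3[, "positive"]), c(4, 1, 1))
  expect_equal(unname(tab3[, "negative"]), c(4, 1, 1))

  # counts are seed-invariant, membership is seed-dependent
  s1 <- stratified_split(c(rep("positive", 34), rep("negative", 24)), seed = 1)
  s2 <- stratified_split(c(rep("positive", 34), rep("negative", 24)), seed = 2)
  expect_equal(table(s1$subset), table(s2$subset))
  expect_false(identical(s1$subset, s2$subset))

  expect_warning(stratified_split(c(rep("positive", 3), rep("negative", 2))),
                 "test subset may be empty")
})

test_that("splits can stratify on label x concentration jointly", {
  labels <- rep(c("positive", "negative"), each = 12)
  conc <- rep(c(0.01, 0.1, 10), times = 8)
  sp <- stratified_split(labels, strata = paste(labels, conc), seed = 3)
  tab <- table(sp$subset, paste(labels, conc))
  expect_true(all(tab["train", ] == 2))   # 4 per stratum -> 2/0/2
  expect_true(all(tab["test", ] == 2))
})

test_that("logistic fitting is deterministic, antisymmetric, and guarded", {
  set.seed(8)
  X <- cbind(a = rnorm(40), b = rnorm(40))
  y <- ifelse(X[, 1] + rnorm(40, sd = 0.5) > 0, "positive", "negative")
  fm <- toy_feature_matrix(X, y)
  sp <- stratified_split(y, seed = 1)

  m1 <- fit_classifier(fm, sp, c("a", "b"))
  m2 <- fit_classifier(fm, sp, c("a", "b"))
  expect_identical(m1$coef, m2$coef)

  # label swap negates every score
  fm_sw <- fm
  fm_sw$labels <- ifelse(y == "positive", "negative", "positive")
  m_sw <- fit_classifier(fm_sw, sp, c("a", "b"))
  expect_equal(m_sw$coef, -m1$coef, tolerance = 1e-8)
  expect_equal(m_sw$intercept, -m1$intercept, tolerance = 1e-8)

  expect_error(fit_classifier(fm, sp, "nope"), "unknown feature")
  fm_one <- fm
  fm_one$labels <- rep("positive", 40)
  expect_error(fit_classifier(fm_one, sp, "a"), "single class")
})

test_that("weakly penalized fit matches glm when the penalty vanishes", {
  set.seed(15)
  X <- cbind(f = rnorm(200))
  y <- ifelse(X[, 1] + rnorm(200, sd = 2) > 0, "positive", "negative")
  fm <- toy_feature_matrix(X, y)
  sp <- structure(list(subset = factor(rep("train", 200),
                                       levels = c("train", "validation",
                                                  "test")),
                       strata = y), class = "split_assignment")
  m <- fit_classifier(fm, sp, "f", lambda = 1e-10)
  xs <- scale(X[, 1])
  ref <- glm(I(y == "positive") ~ xs, family = binomial())
  expect_equal(m$intercept, unname(coef(ref)[1]), tolerance = 1e-5)
  expect_equal(unname(m$coef), unname(coef(ref)[2]), tolerance = 1e-5)
})

test_that("the sign rule assigns the boundary to the positive class", {
  set.seed(2)
  X <- cbind(f = c(runif(20, -3, -1), runif(20, 1, 3)))  # separable by design
  y <- rep(c("negative", "positive"), each = 20)
  fm <- toy_feature_matrix(X, y)
  sp <- stratified_split(y, seed = 5)
  m <- fit_classifier(fm, sp, "f")

  sc <- score_and_classify(m, fm)
  # separable 1-D feature: the sign rule reproduces the labels
  expect_equal(sc$class, y)
  # decision boundary: solve for the feature value with score exactly 0
  x0 <- m$mu + m$sigma * (-m$intercept / m$coef)
  sc0 <- score_and_classify(m, matrix(x0, 1, dimnames = list(NULL, "f")))
  expect_equal(sc0$score, 0, tolerance = 1e-12)
  expect_equal(sc0$class, "positive")          # >= 0 means positive
  expect_equal(sc0$prob, 0.5, tolerance = 1e-12)
})

test_that("forward selection is greedy, capped, and matches brute force", {
  set.seed(33)
  n <- 60
  y <- rep(c("positive", "negative"), each = n / 2)
  X <- matrix(rnorm(n * 11), n, 11,
              dimnames = list(NULL, sprintf("noise%02d", 1:11)))
  X <- cbind(X, signal = ifelse(y == "positive", 1, -1) + rnorm(n, sd = 0.1))
  fm <- toy_feature_matrix(X, y)
  sp <- stratified_split(y, seed = 9)

  sel <- forward_select(fm, sp, max_features = 2)
  expect_equal(sel$selected[1], "signal")       # separable feature wins
  expect_equal(sel$accuracy[1], 1)
  expect_lte(length(sel$selected), 2)

  # exhaustive single-feature oracle over all 12 candidates
  pool <- which(sp$subset %in% c("train", "validation"))
  accs <- vapply(colnames(X), function(cn) {
    m <- fit_classifier(fm, sp, cn)
    mean(score_and_classify(m, fm)$class[pool] == y[pool])
  }, numeric(1))
  expect_equal(sel$selected[1], names(which.max(accs)))

  # zero-variance candidates are skipped with a message
  X2 <- cbind(X, flat = rep(1, n))
  expect_message(forward_select(toy_feature_matrix(X2, y), sp),
                 "zero-variance")
})

test_that("test rows never influence standardization, selection, or fit", {
  set.seed(44)
  n <- 36
  y <- rep(c("positive", "negative"), each = n / 2)
  X <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("f", 1:5)))
  X[, 1] <- ifelse(y == "positive", 1, -1) + rnorm(n, sd = 0.3)
  fm <- toy_feature_matrix(X, y)
  sp <- stratified_split(y, seed = 2)

  sel <- forward_select(fm, sp)
  m <- fit_classifier(fm, sp, sel$selected)

  # corrupt every test row; development artefacts must be identical
  fm2 <- fm
  fm2$values[sp$subset == "test", ] <- 1e6
  sel2 <- forward_select(fm2, sp)
  m2 <- fit_classifier(fm2, sp, sel2$selected)
  expect_identical(sel2$selected, sel$selected)
  expect_identical(m2$coef, m$coef)
  expect_identical(m2$mu, m$mu)
})

test_that("evaluation reports accuracy, recalls, AP and the prevalence baseline", {
  # the printed test partitions: 7/4 -> baseline 0.64, 7/6 -> 0.54
  for (case in list(list(pos = 34, neg = 24, baseline = 0.64),
                    list(pos = 38, neg = 36, baseline = 0.54))) {
    y <- c(rep("positive", case$pos), rep("negative", case$neg))
    set.seed(10)
    X <- cbind(f = ifelse(y == "positive", 1, -1) + rnorm(length(y)))
    fm <- toy_feature_matrix(X, y)
    sp <- stratified_split(y, seed = 4)
    m <- fit_classifier(fm, sp, "f")
    rep_ <- evaluate_classifier(m, fm, sp, "test")
    expect_equal(round(rep_$baseline_ap, 2), case$baseline)
    expect_true(all(c(rep_$accuracy, rep_$recall_positive,
                      rep_$recall_negative, rep_$average_precision) >= 0))
    expect_true(all(c(rep_$accuracy, rep_$average_precision) <= 1))
  }

  # perfect ranking gives AP = 1
  expect_equal(average_precision(c(5, 4, 3, 2, 1),
                                 c(TRUE, TRUE, TRUE, FALSE, FALSE)), 1)
  # hand-checked imperfect ranking: TP at ranks 1 and 3
  expect_equal(average_precision(c(4, 3, 2, 1), c(TRUE, FALSE, TRUE, FALSE)),
               (1 / 2) * (1 + 2 / 3))
  expect_error(average_precision(1:3, rep(FALSE, 3)), "no positive")
})

test_that("random scores yield AP near the prevalence baseline", {
  set.seed(20)
  y <- rep(c(TRUE, FALSE), times = c(300, 700))
  aps <- replicate(300, average_precision(rnorm(1000), y))
  expect_equal(mean(aps), mean(y), tolerance = 0.02)
})

test_that("plateau detection follows the first-no-later-gain rule", {
  grid <- c(15, 30, 45, 60)
  # strictly increasing curve: plateau at the last point
  expect_equal(plateau_point(grid, c(0.5, 0.6, 0.7, 0.8), 0)$plateau_min, 60)
  # constant curve: plateau at the first point
  expect_equal(plateau_point(grid, rep(0.8, 4), 0)$plateau_min, 15)
  # rise then flat: plateau where the curve saturates
  expect_equal(plateau_point(grid, c(0.5, 0.84, 0.84, 0.84), 0)$plateau_min,
               30)
  # tolerance forgives small later gains
  expect_equal(plateau_point(grid, c(0.80, 0.81, 0.82, 0.82), 0.05)$plateau_min,
               15)
})

test_that("exposure sweep: accuracy stops improving once the effect saturates", {
  tau <- 5
  cfg <- simulation_config(
    sampling_rate = 400, blank_min = 0, medium_min = 5, drug_min = 40,
    noise = list(white_sigma = 1, pink_amplitude = 0.2),
    resonance = list(amplitude = 0), spikes = list(rate_hz = 0),
    effect = list(band_lo_hz = 10, band_hi_hz = 14, power_ratio = 0.55,
                  tau_min = tau), seed = 1)
  cs <- cohort_spectrograms(9, 9, cfg, seed = 71, window_min = 5,
                            welch = welch_params(overlap_frac = 0),
                            phases = "drug")
  sp <- stratified_split(cs$labels, seed = 11)
  g <- feature_grammar(kinds = "band_power",
                       bands = list(c(0, 10), c(10, 14), c(14, 50)),
                       levels = c(0.1, 0.5, 0.9), summary_pcts = 50)
  sw <- exposure_sweep(cs$spectrograms, cs$labels, sp, drug_onset_min = 5,
                       grid_min = seq(5, 40, by = 5), grammar = g,
                       folds = 6, tolerance = 0, seed = 5)
  expect_true(all(sw$accuracy >= 0 & sw$accuracy <= 1))
  expect_true(sw$plateau_min %in% sw$grid_min)
  # the strong injected effect is learnable from the sweep's features
  expect_gte(sw$plateau_accuracy, 0.9)

  # oracle from the generator's analytic onset profile: the cumulative
  # injected separation reaches 95% of its final value by this grid point,
  # so accuracy must not keep improving past it (it may — and with a
  # homogeneous cohort does — saturate earlier)
  mean_factor <- function(d) {
    1 - 0.45 * (1 - tau * (1 - exp(-d / tau)) / d)
  }
  sep <- 1 - mean_factor(seq(5, 40, by = 5))
  sat <- seq(5, 40, by = 5)[which(sep >= 0.95 * max(sep))[1]]
  expect_lte(sw$plateau_min, sat + 5)

  # durations shorter than one window are skipped, not fatal
  expect_message(
    sw2 <- exposure_sweep(cs$spectrograms, cs$labels, sp, 5,
                          grid_min = c(2, 10), grammar = g, folds = 3,
                          seed = 5),
    "skipped")
  expect_equal(sw2$grid_min, 10)
})
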