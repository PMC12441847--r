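#' Describe one scalar quantile feature
#'
#' A feature descriptor names, completely and reproducibly, one scalar
#' summary of a quantile spectrogram: a per-window band statistic (`kind`)
#' computed at one quantile level over one frequency band, pooled across the
#' windows of a time interval and reduced to a percentile, optionally
#' combined (difference or ratio) with the same summary over a second
#' interval. Bands are half-open `[f_lo, f_hi)` in Hz with the DC bin always
#' excluded; intervals are half-open `[t_lo, t_hi)` in recording-clock
#' minutes, with windows identified by their start time.
#'
#' @param kind One of `"band_power"` (mean PSD over band bins),
#'   `"spikiness"` (max/median over band bins), `"js_chi2"` (Jensen–Shannon
#'   distance of the band-bin values to a mean-matched chi-squared
#'   reference), `"quantile_ratio"`, `"quantile_difference"` (mean band
#'   power at `level[1]` vs `level[2]`).
#' @param band_hz Numeric `c(f_lo, f_hi)`.
#' @param level Quantile fraction; a pair for the `quantile_*` kinds.
#' @param interval_min Numeric `c(t_lo, t_hi)` in clock minutes.
#' @param summary_pct Percentile in (0, 100) applied across the pooled
#'   per-window values.
#' @param combinator `"value"`, `"difference"` or `"ratio"`; the latter two
#'   compare `interval2_min` against `interval_min`
#'   (`s(interval2) - s(interval1)` and `s(interval2)/s(interval1)`).
#' @param interval2_min Second interval, required for pair combinators.
#' @return A list of class `feature_descriptor`.
#' @export
feature_descriptor <- function(kind = c("band_power", "spikiness", "js_chi2",
                                        "quantile_ratio",
                                        "quantile_difference"),
                               band_hz, level, interval_min,
                               summary_pct = 50,
                               combinator = c("value", "difference", "ratio"),
                               interval2_min = NULL) {
  kind <- match.arg(kind)
  combinator <- match.arg(combinator)
  stopifnot(length(band_hz) == 2L, band_hz[1L] < band_hz[2L],
            length(interval_min) == 2L, interval_min[1L] < interval_min[2L],
            summary_pct > 0, summary_pct < 100)
  pair_kind <- kind %in% c("quantile_ratio", "quantile_difference")
  if (pair_kind) {
    stopifnot(length(level) == 2L)
  } else {
    stopifnot(length(level) == 1L)
  }
  if (combinator != "value" && is.null(interval2_min)) {
    stop("feature_descriptor: combinator '", combinator,
         "' needs interval2_min")
  }
  if (!is.null(interval2_min)) {
    stopifnot(length(interval2_min) == 2L,
              interval2_min[1L] < interval2_min[2L])
  }
  d <- structure(
    list(kind = kind, band_hz = as.numeric(band_hz),
         level = as.numeric(level),
         interval_min = as.numeric(interval_min),
         summary_pct = as.numeric(summary_pct), combinator = combinator,
         interval2_min = if (is.null(interval2_min)) NULL
                         else as.numeric(interval2_min)),
    class = "feature_descriptor"
  )
  d$name <- descriptor_name(d)
  d
}

#' Canonical name of a feature descriptor
#'
#' Serializes a descriptor to a unique, stable string; selection
#' tie-breaking and feature provenance both rest on this name.
#'
#' @param d A `feature_descriptor`.
#' @return A character scalar.
#' @export
descriptor_name <- function(d) {
  lev <- paste(format(d$level, trim = TRUE), collapse = "/")
  t1 <- paste0(format(d$interval_min[1L], trim = TRUE), "-",
               format(d$interval_min[2L], trim = TRUE))
  tpart <- if (d$combinator == "value") {
    paste0("t", t1, "min")
  } else {
    paste0("t", t1, "min_vs_t",
           format(d$interval2_min[1L], trim = TRUE), "-",
           format(d$interval2_min[2L], trim = TRUE), "min")
  }
  paste(d$kind,
        paste0("b", format(d$band_hz[1L], trim = TRUE), "-",
               format(d$band_hz[2L], trim = TRUE), "Hz"),
        paste0("q", lev), tpart,
        paste0("p", format(d$summary_pct, trim = TRUE)),
        d$combinator, sep = "|")
}

band_bin_idx <- function(spec, band_hz) {
  which(spec$freqs_hz >= band_hz[1L] & spec$freqs_hz < band_hz[2L] &
          spec$freqs_hz > 0)
}

level_idx <- function(spec, level) {
  i <- which(abs(spec$levels - level) < 1e-9)
  if (length(i) != 1L) {
    stop("level ", level, " not present in spectrogram levels (",
         paste(spec$levels, collapse = ", "), ")")
  }
  i
}

interval_win_idx <- function(spec, interval_min) {
  which(spec$window_starts_min >= interval_min[1L] - 1e-9 &
          spec$window_starts_min < interval_min[2L] - 1e-9)
}

#' Raw band values feeding a descriptor
#'
#' For each spectrogram window whose start lies in `[t_lo, t_hi)`, returns
#' the vector of quantile-spectrum values at one level over the band's
#' frequency bins (`f_lo <= f < f_hi`, DC excluded) — the raw material every
#' descriptor kind reduces.
#'
#' @param spec A `quantile_spectrogram`.
#' @param band_hz `c(f_lo, f_hi)` in Hz.
#' @param level One quantile fraction present in `spec$levels`.
#' @param interval_min `c(t_lo, t_hi)` in clock minutes.
#' @return A named list (one element per selected window, named by window
#'   start) of numeric bin-value vectors.
#' @export
band_values <- function(spec, band_hz, level, interval_min) {
  bins <- band_bin_idx(spec, band_hz)
  if (!length(bins)) {
    stop("band_values: band [", band_hz[1L], ", ", band_hz[2L],
         ") Hz contains no frequency bins")
  }
  wins <- interval_win_idx(spec, interval_min)
  if (!length(wins)) {
    stop("band_values: interval [", interval_min[1L], ", ", interval_min[2L],
         ") min contains no windows")
  }
  li <- level_idx(spec, level)
  out <- lapply(wins, function(j) spec$values[li, bins, j])
  names(out) <- format(spec$window_starts_min[wins])
  out
}

#' Spikiness of a band
#'
#' Peakedness of the quantile spectrum over a band: the maximum bin value
#' divided by the median bin value. Scale-invariant, robust to the overall
#' power level, and `>= 1` whenever the maximum is at least the median.
#'
#' @param band_powers Vector of `>= 2` strictly positive PSD values.
#' @return Scalar spikiness.
#' @export
spikiness <- function(band_powers) {
  if (length(band_powers) < 2L) stop("spikiness: need at least 2 values")
  if (any(band_powers <= 0)) stop("spikiness: band powers must be positive")
  max(band_powers) / stats::median(band_powers)
}

#' Jensen–Shannon distance to the chi-squared periodogram law
#'
#' Distance between the distribution of band power values and the scaled
#' chi-squared law that periodogram ordinates of Gaussian noise follow. The
#' chi-squared(df) reference is scaled so its mean matches the empirical
#' mean, the positive axis is partitioned into `k` equal-probability bins of
#' that reference, and the Jensen–Shannon divergence (base-2 logs) between
#' the empirical bin frequencies and the uniform `1/k` reference masses is
#' computed; its square root is returned — a metric in `[0, 1]`, 0 when the
#' data match the reference bin-for-bin.
#'
#' @param band_powers Vector of at least `k` strictly positive values.
#' @param df Degrees of freedom of the reference (default 2, the raw
#'   Gaussian-periodogram law; configurable because quantile-spectrum values
#'   are order statistics rather than raw ordinates).
#' @param k Number of equal-probability bins (default 16).
#' @return Scalar distance in `[0, 1]`.
#' @export
js_chi2 <- function(band_powers, df = 2, k = 16L) {
  n <- length(band_powers)
  if (n < k) stop("js_chi2: need at least ", k, " values, got ", n)
  if (any(band_powers <= 0)) stop("js_chi2: band powers must be positive")
  scale <- mean(band_powers) / df
  edges <- scale * stats::qchisq(seq(0, 1, length.out = k + 1L), df)
  counts <- tabulate(findInterval(band_powers, edges,
                                  rightmost.closed = TRUE,
                                  all.inside = TRUE), nbins = k)
  p <- counts / n
  q <- rep(1 / k, k)
  m <- (p + q) / 2
  kl <- function(a, b) sum(ifelse(a > 0, a * log2(a / b), 0))
  jsd <- 0.5 * kl(p, m) + 0.5 * kl(q, m)
  sqrt(min(max(jsd, 0), 1))
}

per_window_values <- function(spec, kind, band_hz, level, wins) {
  bins <- band_bin_idx(spec, band_hz)
  if (!length(bins)) {
    stop("band [", band_hz[1L], ", ", band_hz[2L], ") Hz has no bins")
  }
  vapply(wins, function(j) {
    switch(kind,
      band_power = mean(spec$values[level_idx(spec, level[1L]), bins, j]),
      spikiness = spikiness(spec$values[level_idx(spec, level[1L]), bins, j]),
      js_chi2 = js_chi2(spec$values[level_idx(spec, level[1L]), bins, j]),
      quantile_ratio = mean(spec$values[level_idx(spec, level[1L]), bins, j]) /
        mean(spec$values[level_idx(spec, level[2L]), bins, j]),
      quantile_difference =
        mean(spec$values[level_idx(spec, level[1L]), bins, j]) -
        mean(spec$values[level_idx(spec, level[2L]), bins, j])
    )
  }, numeric(1L))
}

interval_summary <- function(spec, d, interval_min) {
  wins <- interval_win_idx(spec, interval_min)
  if (!length(wins)) {
    stop("summarize_feature: interval [", interval_min[1L], ", ",
         interval_min[2L], ") min selects no windows for descriptor ",
         d$name)
  }
  vals <- per_window_values(spec, d$kind, d$band_hz, d$level, wins)
  unname(stats::quantile(vals, d$summary_pct / 100, type = 7))
}

#' Evaluate a feature descriptor on a spectrogram
#'
#' Per-window descriptor values are pooled over all windows of the
#' descriptor's interval and reduced to the `summary_pct` percentile
#' (type 7); pair combinators then compare the second interval's summary
#' against the first (`s2 - s1` or `s2 / s1`).
#'
#' @param d A `feature_descriptor`.
#' @param spec A `quantile_spectrogram`.
#' @return Scalar feature value.
#' @export
summarize_feature <- function(d, spec) {
  s1 <- interval_summary(spec, d, d$interval_min)
  if (d$combinator == "value") return(s1)
  s2 <- interval_summary(spec, d, d$interval2_min)
  if (d$combinator == "difference") s2 - s1 else s2 / s1
}

#' Define a feature grammar
#'
#' The Cartesian descriptor grammar: every combination of kind x band x
#' level x interval x summary percentile yields a `value` feature, and,
#' when pair combinators are requested, every ordered interval pair
#' `(i, j), i < j` additionally yields the difference and/or ratio of the
#' later interval's summary over the earlier one's. Enumeration order is
#' deterministic. The full grammar of the method is combinatorially large;
#' the coarse default grids used in examples keep desk-scale runs to a few
#' hundred columns.
#'
#' @param kinds Character vector of descriptor kinds.
#' @param bands List of `c(f_lo, f_hi)` bands in Hz.
#' @param levels Quantile fractions for scalar-level kinds.
#' @param intervals List of `c(t_lo, t_hi)` clock-minute intervals.
#' @param summary_pcts Percentiles in (0, 100).
#' @param combinators Subset of `c("value", "difference", "ratio")`.
#' @param level_pairs List of level pairs, used only by the
#'   `quantile_ratio` / `quantile_difference` kinds.
#' @return A list of class `feature_grammar`.
#' @export
feature_grammar <- function(kinds = c("band_power", "spikiness", "js_chi2"),
                            bands = list(c(0, 10), c(10, 100)),
                            levels = c(0.1, 0.5, 0.9),
                            intervals = list(c(0, 120), c(120, 240)),
                            summary_pcts = c(10, 50, 90),
                            combinators = "value",
                            level_pairs = list(c(0.9, 0.1))) {
  stopifnot(all(combinators %in% c("value", "difference", "ratio")))
  structure(list(kinds = kinds, bands = bands, levels = levels,
                 intervals = intervals, summary_pcts = summary_pcts,
                 combinators = combinators, level_pairs = level_pairs),
            class = "feature_grammar")
}

#' Enumerate all descriptors of a grammar
#'
#' @param grammar A [feature_grammar()].
#' @return List of `feature_descriptor`s in canonical deterministic order.
#' @export
enumerate_grammar <- function(grammar) {
  out <- list()
  pair_combs <- intersect(grammar$combinators, c("difference", "ratio"))
  for (kind in grammar$kinds) {
    levs <- if (kind %in% c("quantile_ratio", "quantile_difference")) {
      grammar$level_pairs
    } else {
      as.list(grammar$levels)
    }
    for (band in grammar$bands) for (lev in levs) {
      for (pct in grammar$summary_pcts) {
        if ("value" %in% grammar$combinators) {
          for (iv in grammar$intervals) {
            out[[length(out) + 1L]] <- feature_descriptor(
              kind, band, lev, iv, pct, "value")
          }
        }
        if (length(pair_combs) && length(grammar$intervals) > 1L) {
          n_iv <- length(grammar$intervals)
          for (i in seq_len(n_iv - 1L)) for (j in seq((i + 1L), n_iv)) {
            for (cb in pair_combs) {
              out[[length(out) + 1L]] <- feature_descriptor(
                kind, band, lev, grammar$intervals[[i]], pct, cb,
                interval2_min = grammar$intervals[[j]])
            }
          }
        }
      }
    }
  }
  out
}

#' Assemble the cohort feature matrix
#'
#' Evaluates every descriptor of the grammar on every spectrogram. All
#' spectrograms must share levels, frequency and window axes; any non-finite
#' feature value is an error (never silently imputed).
#'
#' @param spectrograms List of `quantile_spectrogram`s with identical axes.
#' @param grammar A [feature_grammar()] or a list of `feature_descriptor`s.
#' @param sample_ids,labels,concentrations_uM Optional per-sample
#'   annotations carried along (labels as `"positive"`/`"negative"`).
#' @return An object of class `feature_matrix`: list with `values`
#'   (`n_samples x n_features`), `descriptors`, `sample_ids`, `labels`,
#'   `concentrations_uM`.
#' @export
build_feature_matrix <- function(spectrograms, grammar, sample_ids = NULL,
                                 labels = NULL, concentrations_uM = NULL) {
  stopifnot(length(spectrograms) >= 1L)
  ref <- spectrograms[[1L]]
  bad <- which(!vapply(spectrograms, function(s) {
    isTRUE(all.equal(s$levels, ref$levels)) &&
      isTRUE(all.equal(s$freqs_hz, ref$freqs_hz)) &&
      isTRUE(all.equal(s$window_starts_min, ref$window_starts_min))
  }, logical(1L)))
  if (length(bad)) {
    stop("build_feature_matrix: spectrogram axes differ from sample 1 for ",
         "sample(s) ", paste(bad, collapse = ", "))
  }
  descriptors <- if (inherits(grammar, "feature_grammar")) {
    enumerate_grammar(grammar)
  } else {
    grammar
  }
  nm <- vapply(descriptors, function(d) d$name, character(1L))
  vals <- matrix(NA_real_, nrow = length(spectrograms),
                 ncol = length(descriptors), dimnames = list(NULL, nm))
  for (i in seq_along(spectrograms)) {
    for (j in seq_along(descriptors)) {
      vals[i, j] <- summarize_feature(descriptors[[j]], spectrograms[[i]])
    }
  }
  if (!all(is.finite(vals))) {
    bad_cols <- unique(which(!is.finite(vals), arr.ind = TRUE)[, 2L])
    stop("build_feature_matrix: non-finite feature values in column(s) ",
         paste(utils::head(nm[bad_cols], 5L), collapse = "; "))
  }
  if (is.null(sample_ids)) sample_ids <- as.character(seq_along(spectrograms))
  structure(
    list(values = vals, descriptors = descriptors, sample_ids = sample_ids,
         labels = labels, concentrations_uM = concentrations_uM),
    class = "feature_matrix"
  )
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d samples x %d features\n",
              nrow(x$values), ncol(x$values)))
  if (!is.null(x$labels)) {
    cat("  labels:", paste(names(table(x$labels)), table(x$labels),
                           sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}
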