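#' Three-noise-level demonstration
#'
#' Simulates one ensemble per noise level at a fixed interaction strength,
#' summarizes each against its pooled surrogate null, and compares every
#' pair of ensembles with the permutation test. Mirrors the canonical
#' demonstration layout: matched ensembles whose only difference is the
#' noise level, so that low-noise ensembles separate sharply from null while
#' fully noisy ones do not. The default noise levels `c(0.1, 0.5, 1.0)` are
#' a package choice spanning low, medium, and fully noisy regimes.
#'
#' @param a_levels Numeric vector of noise levels, one ensemble each.
#' @param s Interaction strength shared by all ensembles.
#' @param n_sources,nobs,n_mc Ensemble size, observations per source, and
#'   surrogates per source.
#' @param n_perm Permutations for the pairwise ensemble comparisons.
#' @param seed Master seed; child seeds are derived per ensemble.
#' @param sd_method Weighted-SD convention, see [weighted_sd_info()].
#' @return A list with `ensembles` (list of `info_ensemble`), `summaries`
#'   (one data-frame row per noise level), and `comparisons` (one row per
#'   ensemble pair).
#' @export
run_noise_demo <- function(a_levels = c(0.1, 0.5, 1.0), s = 0.4,
                           n_sources = 40, nobs = 60, n_mc = 100,
                           n_perm = 1000, seed = NULL,
                           sd_method = "weighted-deviation") {
  stopifnot(length(a_levels) >= 1L)
  seeds <- derive_seeds(seed, length(a_levels) + 1L)
  ensembles <- lapply(seq_along(a_levels), function(i) {
    simulate_ensemble(n_sources, s = s, a = a_levels[i], nobs = nobs,
                      n_mc = n_mc, seed = seeds[i],
                      label = sprintf("a=%g", a_levels[i]))
  })
  summaries <- do.call(rbind, lapply(seq_along(a_levels), function(i) {
    sm <- summary(ensembles[[i]], sd_method = sd_method)
    data.frame(a = a_levels[i], s = s, n_sources = n_sources, nobs = nobs,
               n_mc = n_mc, weighted_mean = sm$weighted_mean,
               weighted_sem = sm$weighted_sem, weighted_sd = sm$weighted_sd,
               ks_statistic = sm$ks_statistic, ks_p_value = sm$ks_p_value)
  }))
  pairs <- utils::combn(seq_along(a_levels), 2L)
  cmp_seeds <- derive_seeds(seeds[length(a_levels) + 1L], ncol(pairs))
  comparisons <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    cmp <- compare_ensembles(ensembles[[i]], ensembles[[j]], n_perm = n_perm,
                             seed = cmp_seeds[k])
    data.frame(a_1 = a_levels[i], a_2 = a_levels[j],
               observed_difference = cmp$observed_difference,
               p_value = cmp$p_value, n_permutations = n_perm)
  }))
  list(ensembles = ensembles, summaries = summaries, comparisons = comparisons)
}

#' Significance sweep over model parameters
#'
#' For every combination of interaction strength, noise level, ensemble
#' size, and observation count, simulates `n_replicates` ensembles and
#' records the weighted summaries and the ensemble-versus-null KS test,
#' flagging cells significant at `threshold`. Useful for power analysis:
#' how do signal, noise, and the two sample-size knobs trade off against
#' detectability?
#'
#' @param s_grid,a_grid,n_sources_grid,nobs_grid Numeric vectors of
#'   parameter values; the sweep covers their full cross product.
#' @param n_mc Surrogates per source.
#' @param n_replicates Ensembles per parameter cell.
#' @param threshold Significance threshold on the KS p-value (default 0.01).
#' @param seed Master seed; every (cell, replicate) gets a derived child seed.
#' @param sd_method Weighted-SD convention.
#' @return A tidy data frame with one row per (cell, replicate):
#'   all parameters plus `weighted_mean`, `weighted_sem`, `weighted_sd`,
#'   `ks_statistic`, `ks_p_value`, and logical `significant`.
#' @export
run_significance_sweep <- function(s_grid, a_grid, n_sources_grid = 40,
                                   nobs_grid = 60, n_mc = 100,
                                   n_replicates = 1, threshold = 0.01,
                                   seed = NULL,
                                   sd_method = "weighted-deviation") {
  cells <- expand.grid(s = s_grid, a = a_grid, n_sources = n_sources_grid,
                       nobs = nobs_grid, replicate = seq_len(n_replicates),
                       KEEP.OUT.ATTRS = FALSE)
  seeds <- derive_seeds(seed, nrow(cells))
  rows <- lapply(seq_len(nrow(cells)), function(r) {
    cell <- cells[r, ]
    ens <- suppressWarnings(
      simulate_ensemble(cell$n_sources, s = cell$s, a = cell$a,
                        nobs = cell$nobs, n_mc = n_mc, seed = seeds[r]))
    sm <- suppressWarnings(summary(ens, sd_method = sd_method))
    data.frame(cell,
               n_mc = n_mc,
               weighted_mean = sm$weighted_mean,
               weighted_sem = sm$weighted_sem,
               weighted_sd = sm$weighted_sd,
               ks_statistic = sm$ks_statistic,
               ks_p_value = sm$ks_p_value,
               significant = sm$ks_p_value < threshold)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Low-information sweep: detecting suppressed information
#'
#' Sweeps a (typically fine) grid of interaction strengths at fixed small
#' noise levels and classifies each ensemble as significantly *above* null,
#' significantly *below* null, or not significant. Significance comes from
#' the two-sided ensemble-versus-null KS test; the direction is the sign of
#' the ensemble's weighted mean minus the mean of its pooled surrogate null.
#' At very low `s` and low `a` the generative model is less variable than
#' its fully randomized surrogate, so information values sit *below* the
#' null — the suppressed-information regime.
#'
#' @inheritParams run_significance_sweep
#' @param a_levels Noise levels to scan (default `c(0.2, 0.3)`).
#' @param n_sources,nobs Ensemble size and observations per source.
#' @return A tidy data frame with one row per (cell, replicate), including
#'   `weighted_mean`, `null_mean`, `ks_p_value`, and `classification`
#'   (`"above"`, `"below"`, or `"ns"`).
#' @export
run_low_information_sweep <- function(s_grid, a_levels = c(0.2, 0.3),
                                      n_sources = 40, nobs = 60, n_mc = 100,
                                      n_replicates = 1, threshold = 0.01,
                                      seed = NULL) {
  cells <- expand.grid(s = s_grid, a = a_levels,
                       replicate = seq_len(n_replicates),
                       KEEP.OUT.ATTRS = FALSE)
  seeds <- derive_seeds(seed, nrow(cells))
  rows <- lapply(seq_len(nrow(cells)), function(r) {
    cell <- cells[r, ]
    ens <- suppressWarnings(
      simulate_ensemble(n_sources, s = cell$s, a = cell$a, nobs = nobs,
                        n_mc = n_mc, seed = seeds[r]))
    sm <- suppressWarnings(summary(ens))
    null_mean <- mean(unlist(ens$nulls, use.names = FALSE))
    cls <- if (sm$ks_p_value >= threshold) {
      "ns"
    } else if (sm$weighted_mean >= null_mean) "above" else "below"
    data.frame(cell, n_sources = n_sources, nobs = nobs, n_mc = n_mc,
               weighted_mean = sm$weighted_mean, null_mean = null_mean,
               ks_p_value = sm$ks_p_value, classification = cls)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Between-ensemble comparison sweep
#'
#' For every pair of a reference interaction strength and a test interaction
#' strength, simulates `n_pairs` independent ensemble pairs at a fixed noise
#' level and runs the permutation test on the difference of weighted means.
#' Summarize per-cell medians and interquartile ranges of the p-values with
#' [comparison_sweep_summary()].
#'
#' @param s_ref,s_test Numeric vectors of reference and test interaction
#'   strengths; the sweep covers their cross product.
#' @param a Shared noise level (default 0.5, a moderate-noise regime).
#' @param n_sources,nobs,n_mc Ensemble size, observations, surrogates.
#' @param n_perm Permutations per comparison.
#' @param n_pairs Replicate ensemble pairs per cell.
#' @param seed Master seed.
#' @param alternative Sidedness of the permutation p-value, see
#'   [compare_ensembles()].
#' @return A tidy data frame with one row per (cell, pair): parameters plus
#'   `observed_difference` and `p_value`.
#' @export
run_comparison_sweep <- function(s_ref, s_test, a = 0.5, n_sources = 40,
                                 nobs = 60, n_mc = 100, n_perm = 1000,
                                 n_pairs = 50, seed = NULL,
                                 alternative = "directional") {
  cells <- expand.grid(s_ref = s_ref, s_test = s_test,
                       pair = seq_len(n_pairs), KEEP.OUT.ATTRS = FALSE)
  seeds <- derive_seeds(seed, 3L * nrow(cells))
  rows <- lapply(seq_len(nrow(cells)), function(r) {
    cell <- cells[r, ]
    ea <- suppressWarnings(
      simulate_ensemble(n_sources, s = cell$s_ref, a = a, nobs = nobs,
                        n_mc = n_mc, seed = seeds[3L * r - 2L]))
    eb <- suppressWarnings(
      simulate_ensemble(n_sources, s = cell$s_test, a = a, nobs = nobs,
                        n_mc = n_mc, seed = seeds[3L * r - 1L]))
    cmp <- compare_ensembles(ea, eb, n_perm = n_perm, seed = seeds[3L * r],
                             alternative = alternative)
    data.frame(cell, a = a, n_sources = n_sources, nobs = nobs, n_mc = n_mc,
               n_permutations = n_perm,
               observed_difference = cmp$observed_difference,
               p_value = cmp$p_value)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize a comparison sweep per parameter cell
#'
#' @param sweep A data frame from [run_comparison_sweep()].
#' @return One row per (s_ref, s_test) cell with the median and
#'   interquartile range of the comparison p-values.
#' @export
comparison_sweep_summary <- function(sweep) {
  stopifnot(is.data.frame(sweep), all(c("s_ref", "s_test", "p_value")
                                      %in% names(sweep)))
  agg <- stats::aggregate(p_value ~ s_ref + s_test, data = sweep,
                          FUN = function(p) {
                            c(median = stats::median(p),
                              q25 = unname(stats::quantile(p, 0.25)),
                              q75 = unname(stats::quantile(p, 0.75)),
                              n = length(p))
                          })
  out <- cbind(agg[c("s_ref", "s_test")], as.data.frame(agg$p_value))
  names(out) <- c("s_ref", "s_test", "p_median", "p_q25", "p_q75", "n_pairs")
  out
}
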