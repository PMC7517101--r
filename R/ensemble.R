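#' Assemble an ensemble of information sources
#'
#' The central container and "fit" of the package: an ensemble of `nens`
#' information sources, each carrying an information value \eqn{I_i} (bits),
#' a set of surrogate null values \eqn{I_{null,i,j}}, a Monte Carlo p-value
#' \eqn{p_i}, and a significance weight \eqn{w_i = -\log_{10} p_i}
#' (normalized to sum to 1 across the ensemble). Methods [summary.info_ensemble()],
#' [coef.info_ensemble()], [weights.info_ensemble()], and
#' [plot.info_ensemble()] present the ensemble; [compare_ensembles()] tests
#' two ensembles against each other.
#'
#' Values may come from the built-in binary-pair model (see
#' [simulate_ensemble()]) or from any external information-theoretic
#' analysis (entropy, mutual information, transfer entropy, ...), as long as
#' every source brings a null set from which a p-value can be computed. The
#' ensemble-versus-null KS test assumes sources generated under a common
#' regime (a homogeneous ensemble).
#'
#' @param values Numeric vector of per-source information values in bits.
#' @param nulls Surrogate null values: a matrix with one row per source, or a
#'   list of numeric vectors (one per source, each non-empty).
#' @param p_values Optional per-source p-values in `(0, 1]`. If omitted they
#'   are recomputed from `nulls` with [mc_pvalue()].
#' @param label Optional free-text label for printing.
#' @param provenance Optional named list recording generation/analysis
#'   settings (kept with the object and serialized by [write_ensemble()]).
#' @return An `info_ensemble` object: a list with `values`, `nulls` (list of
#'   numeric vectors), `p_values`, `raw_weights` (\eqn{-\log_{10} p_i}),
#'   `weights` (normalized), `n_sources`, `label`, and `provenance`.
#' @seealso [simulate_ensemble()], [summary.info_ensemble()],
#'   [compare_ensembles()], [read_ensemble()]
#' @export
info_ensemble <- function(values, nulls, p_values = NULL, label = NULL,
                          provenance = list()) {
  if (!is.numeric(values) || length(values) < 1L || anyNA(values)) {
    stop_input("`values` must be a non-empty numeric vector without NA")
  }
  if (is.matrix(nulls)) {
    nulls <- lapply(seq_len(nrow(nulls)), function(i) as.numeric(nulls[i, ]))
  }
  if (!is.list(nulls) || length(nulls) != length(values)) {
    stop_input("`nulls` must be a matrix or list with one entry per source")
  }
  ok <- vapply(nulls, function(v) is.numeric(v) && length(v) >= 1L && !anyNA(v),
               logical(1))
  if (!all(ok)) {
    stop_input("every source needs a non-empty numeric null set (source ",
               paste(which(!ok), collapse = ", "), " invalid)")
  }
  if (is.null(p_values)) {
    p_values <- vapply(seq_along(values),
                       function(i) mc_pvalue(values[i], nulls[[i]]),
                       numeric(1))
  } else {
    if (!is.numeric(p_values) || length(p_values) != length(values) ||
        anyNA(p_values)) {
      stop_input("`p_values` must be numeric, one per source, without NA")
    }
    if (any(p_values <= 0) || any(p_values > 1)) {
      stop_input("p-values must lie in (0, 1]; the Monte Carlo estimator is ",
                 "floored at 1/(2*n_mc) and never reaches 0")
    }
  }
  raw <- -log10(p_values)
  structure(list(values = as.numeric(values),
                 nulls = nulls,
                 p_values = as.numeric(p_values),
                 raw_weights = raw,
                 weights = normalize_weights(raw),
                 n_sources = length(values),
                 label = label,
                 provenance = provenance),
            class = "info_ensemble")
}

#' Simulate an ensemble from the binary-pair model
#'
#' Generates `n_sources` independent information sources from the
#' binary-pair model with interaction strength `s`, noise level `a`, and
#' `nobs` joint observations each, computes their mutual information, builds
#' a surrogate null of `n_mc` values per source, and assembles the result
#' into an [info_ensemble()]. Each source draws from an independent child
#' seed derived from `seed`, so ensembles are exactly reproducible.
#'
#' @param n_sources Number of information sources in the ensemble (>= 2).
#' @inheritParams simulate_observations
#' @inheritParams null_mi
#' @param label Optional label (defaults to a description of the parameters).
#' @return An `info_ensemble` object with provenance recording the model
#'   parameters and seed.
#' @examples
#' ens <- simulate_ensemble(10, s = 0.4, a = 0.1, nobs = 60, n_mc = 50, seed = 1)
#' summary(ens)
#' @export
simulate_ensemble <- function(n_sources, s, a, nobs, n_mc = 1000, seed = NULL,
                              label = NULL, allow_any_nobs = FALSE) {
  if (!is.numeric(n_sources) || length(n_sources) != 1L || n_sources < 2) {
    stop_input("`n_sources` must be a single integer >= 2")
  }
  n_sources <- as.integer(n_sources)
  check_model_params(nobs = nobs, s = s, a = a, allow_any_nobs = allow_any_nobs)
  seeds <- derive_seeds(seed, 2L * n_sources)
  values <- numeric(n_sources)
  nulls <- vector("list", n_sources)
  for (i in seq_len(n_sources)) {
    obs <- simulate_observations(nobs, s, a, seed = seeds[2L * i - 1L],
                                 allow_any_nobs = allow_any_nobs)
    values[i] <- mutual_information(obs)
    nulls[[i]] <- null_mi(obs, n_mc, seed = seeds[2L * i])
  }
  if (is.null(label)) {
    label <- sprintf("model ensemble (s=%g, a=%g, nobs=%d)", s, a, as.integer(nobs))
  }
  info_ensemble(values, nulls, label = label,
                provenance = list(model = "binary_pair",
                                  s = s, a = a, nobs = as.integer(nobs),
                                  n_sources = n_sources,
                                  n_mc = as.integer(n_mc),
                                  seed = seed))
}

#' Significance weights from p-values
#'
#' Converts per-source Monte Carlo p-values into weights
#' \eqn{w_i = -\log_{10} p_i}, optionally normalized to sum to 1, so that
#' sources more likely to be significant dominate the weighted ensemble
#' summaries. If every p-value equals 1 (all raw weights zero) the weights
#' fall back to uniform with a warning, so fully null ensembles remain
#' summarizable.
#'
#' @param p_values Numeric vector of p-values in `(0, 1]`.
#' @param normalize If `TRUE` (default) the weights are divided by their sum.
#' @return Numeric weight vector.
#' @examples
#' compute_weights(c(0.03, 0.5, 1))
#' compute_weights(0.03, normalize = FALSE)  # -log10(0.03) = 1.5229
#' @export
compute_weights <- function(p_values, normalize = TRUE) {
  if (!is.numeric(p_values) || length(p_values) == 0L || anyNA(p_values)) {
    stop_input("`p_values` must be a non-empty numeric vector without NA")
  }
  if (any(p_values <= 0) || any(p_values > 1)) {
    stop_input("p-values must lie in (0, 1]")
  }
  raw <- -log10(p_values)
  if (normalize) normalize_weights(raw) else raw
}

normalize_weights <- function(raw, warn = TRUE) {
  total <- sum(raw)
  if (total <= 0) {
    if (warn) {
      warning("all p-values equal 1; falling back to uniform weights",
              call. = FALSE)
    }
    return(rep(1 / length(raw), length(raw)))
  }
  raw / total
}

#' Weighted mean information
#'
#' \eqn{\bar{I} = \sum_i w_i I_i} with normalized weights; with uniform
#' weights this is the arithmetic mean.
#'
#' @param values Numeric vector of information values (bits).
#' @param weights Normalized weights (same length, summing to 1).
#' @return Weighted mean in bits.
#' @export
weighted_mean_info <- function(values, weights) {
  check_values_weights(values, weights)
  sum(weights * values)
}

#' Weighted standard error of the mean
#'
#' The unweighted sample standard deviation of the information values scaled
#' by the root of the sum of squared normalized weights:
#' \deqn{\sigma_{\bar I} = \sqrt{\frac{1}{n-1}\sum_i (I_i - \bar I_u)^2
#'   \cdot \sum_i w_i^2},}
#' where \eqn{\bar I_u} is the unweighted mean. Under uniform weights
#' \eqn{\sum w_i^2 = 1/n} and the classical standard error is recovered.
#'
#' @inheritParams weighted_mean_info
#' @return Weighted SEM in bits (requires at least 2 values).
#' @export
weighted_sem_info <- function(values, weights) {
  check_values_weights(values, weights)
  if (length(values) < 2L) stop_input("weighted SEM needs at least 2 values")
  stats::sd(values) * sqrt(sum(weights^2))
}

#' Weighted standard deviation
#'
#' Two conventions are available for the spread of an ensemble about its
#' weighted mean \eqn{\bar I = \sum_i w_i I_i}:
#' \describe{
#'   \item{`"weighted-deviation"` (default)}{\eqn{\sqrt{\sum_i
#'     \left(w_i (I_i - \bar I)\right)^2}} — the root sum of squared
#'     weighted deviations.}
#'   \item{`"weighted-variance"`}{\eqn{\sqrt{\sum_i w_i (I_i - \bar I)^2}} —
#'     the conventional weighted standard deviation.}
#' }
#' With a single dominant weight the default convention returns 0, since the
#' weighted mean coincides with the dominant value.
#'
#' @inheritParams weighted_mean_info
#' @param method Which convention to use (see Details).
#' @return Weighted SD in bits (requires at least 2 values).
#' @export
weighted_sd_info <- function(values, weights,
                             method = c("weighted-deviation",
                                        "weighted-variance")) {
  method <- match.arg(method)
  check_values_weights(values, weights)
  if (length(values) < 2L) stop_input("weighted SD needs at least 2 values")
  dev <- values - sum(weights * values)
  switch(method,
         "weighted-deviation" = sqrt(sum((weights * dev)^2)),
         "weighted-variance" = sqrt(sum(weights * dev^2)))
}

check_values_weights <- function(values, weights) {
  if (!is.numeric(values) || !is.numeric(weights) ||
      length(values) != length(weights)) {
    stop_input("`values` and `weights` must be numeric vectors of equal length")
  }
  if (anyNA(values) || anyNA(weights)) {
    stop_input("`values` and `weights` must not contain NA")
  }
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-8) {
    stop_input("`weights` must be non-negative and sum to 1")
  }
  invisible(TRUE)
}

#' Kolmogorov-Smirnov test of an ensemble against its pooled surrogate null
#'
#' Two-sample, two-sided KS test between the `nens` observed information
#' values and the pooled set of all `nens * n_mc` surrogate null values.
#' Being two-sided, the test detects ensembles whose information values are
#' skewed either above *or below* the null — the latter flags suppression of
#' information. Because information values from finite discrete data are
#' heavily tied, the asymptotic p-value is used by default (the tie-induced
#' discreteness makes it conservative).
#'
#' @param ensemble An `info_ensemble` object.
#' @param exact Passed to [stats::ks.test()]; default `FALSE` (asymptotic).
#' @return A list with `statistic` (KS D in `[0, 1]`) and `p_value`.
#' @export
ks_vs_null <- function(ensemble, exact = FALSE) {
  stopifnot(inherits(ensemble, "info_ensemble"))
  pooled <- unlist(ensemble$nulls, use.names = FALSE)
  if (length(pooled) == 0L) stop_input("ensemble carries no null values")
  kt <- suppressWarnings(
    stats::ks.test(ensemble$values, pooled, alternative = "two.sided",
                   exact = exact))
  list(statistic = unname(kt$statistic), p_value = unname(kt$p.value))
}

#' Summarize an ensemble of information sources
#'
#' Computes the p-value-weighted mean, standard error, and standard
#' deviation of the ensemble's information values, together with the
#' ensemble-versus-null KS test of [ks_vs_null()].
#'
#' @param object An `info_ensemble` object.
#' @param sd_method Convention for the weighted SD (see [weighted_sd_info()]).
#' @param exact Passed to [ks_vs_null()].
#' @param ... Unused.
#' @return A `summary.info_ensemble` object: a list with `weighted_mean`,
#'   `weighted_sem`, `weighted_sd`, `sd_method`, `ks_statistic`,
#'   `ks_p_value`, `n_sources`, `n_null`, `weights`, and `label`.
#' @export
summary.info_ensemble <- function(object,
                                  sd_method = c("weighted-deviation",
                                                "weighted-variance"),
                                  exact = FALSE, ...) {
  sd_method <- match.arg(sd_method)
  w <- object$weights
  ks <- ks_vs_null(object, exact = exact)
  structure(list(weighted_mean = weighted_mean_info(object$values, w),
                 weighted_sem = weighted_sem_info(object$values, w),
                 weighted_sd = weighted_sd_info(object$values, w,
                                                method = sd_method),
                 sd_method = sd_method,
                 ks_statistic = ks$statistic,
                 ks_p_value = ks$p_value,
                 n_sources = object$n_sources,
                 n_null = length(unlist(object$nulls, use.names = FALSE)),
                 weights = w,
                 label = object$label),
            class = "summary.info_ensemble")
}

#' @export
print.summary.info_ensemble <- function(x, digits = 4, ...) {
  cat("Ensemble summary", if (!is.null(x$label)) paste0(" [", x$label, "]"),
      "\n", sep = "")
  cat("  sources:            ", x$n_sources,
      "  (pooled null values: ", x$n_null, ")\n", sep = "")
  cat("  weighted mean:      ", format(x$weighted_mean, digits = digits),
      " bits\n", sep = "")
  cat("  weighted SEM:       ", format(x$weighted_sem, digits = digits),
      " bits\n", sep = "")
  cat("  weighted SD:        ", format(x$weighted_sd, digits = digits),
      " bits (", x$sd_method, ")\n", sep = "")
  cat("  KS vs pooled null:  D = ", format(x$ks_statistic, digits = digits),
      ", p = ", format(x$ks_p_value, digits = digits), "\n", sep = "")
  invisible(x)
}

#' @export
print.info_ensemble <- function(x, digits = 4, ...) {
  cat("Ensemble of ", x$n_sources, " information sources",
      if (!is.null(x$label)) paste0(" [", x$label, "]"), "\n", sep = "")
  cat("  information values (bits): ",
      paste(format(range(x$values), digits = digits), collapse = " to "),
      "\n", sep = "")
  cat("  p-values: ",
      paste(format(range(x$p_values), digits = digits), collapse = " to "),
      "\n", sep = "")
  cat("  surrogates per source: ",
      paste(unique(range(lengths(x$nulls))), collapse = " to "), "\n", sep = "")
  invisible(x)
}

#' @describeIn info_ensemble The weighted mean information value of the
#'   ensemble (in bits), named `"weighted_mean"`.
#' @param object,... Method arguments.
#' @export
coef.info_ensemble <- function(object, ...) {
  c(weighted_mean = weighted_mean_info(object$values, object$weights))
}

#' @describeIn info_ensemble Normalized significance weights of the sources.
#' @export
weights.info_ensemble <- function(object, ...) {
  object$weights
}

#' Plot an ensemble against its pooled surrogate null
#'
#' Two base-graphics panels: overlaid histograms of the observed information
#' values and the pooled surrogate null values, and their empirical
#' cumulative distributions.
#'
#' @param x An `info_ensemble` object.
#' @param ... Passed to [graphics::hist()].
#' @return `x`, invisibly.
#' @export
plot.info_ensemble <- function(x, ...) {
  pooled <- unlist(x$nulls, use.names = FALSE)
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old))
  brk <- pretty(c(x$values, pooled), n = 20)
  hn <- graphics::hist(pooled, breaks = brk, plot = FALSE)
  ho <- graphics::hist(x$values, breaks = brk, plot = FALSE)
  graphics::plot(hn, freq = FALSE, col = grDevices::grey(0.8), border = NA,
                 main = x$label %||% "ensemble vs null",
                 xlab = "information (bits)", ...)
  graphics::plot(ho, freq = FALSE, col = grDevices::adjustcolor("firebrick", 0.5),
                 border = NA, add = TRUE)
  graphics::plot(stats::ecdf(pooled), main = "cumulative distributions",
                 xlab = "information (bits)", col = "grey40")
  graphics::plot(stats::ecdf(x$values), add = TRUE, col = "firebrick")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Permutation test for a difference between two ensembles
#'
#' Tests whether two ensembles of information sources differ by comparing
#' the difference of their weighted means, \eqn{\Delta = \bar I_A - \bar
#' I_B}, against a permutation null built by pooling all (information value,
#' raw weight) pairs, dealing them back at random into groups of the
#' original sizes, re-normalizing the weights within each permuted group,
#' and recomputing the weighted-mean difference.
#'
#' With `alternative = "directional"` (default) the p-value is the
#' proportion of permuted differences at least as large as \eqn{\Delta} in
#' \eqn{\Delta}'s own direction — it answers "how surprising is a difference
#' this large, in the direction observed". Because the direction is chosen
#' after seeing the data, this p-value used as a fixed-level two-group test
#' roughly doubles the nominal type-I rate; `alternative = "two.sided"`
#' (proportion of permuted \eqn{|\Delta^*| \ge |\Delta|}) is the calibrated
#' choice for significance statements. Ties count as "at least as large",
#' and the p-value is floored at `1/(2 * n_perm)` when no permutation
#' reaches the observed difference. When \eqn{\Delta = 0} every permutation
#' is at least as extreme and the p-value is 1.
#'
#' @param a,b `info_ensemble` objects.
#' @param n_perm Number of random permutations (>= 1).
#' @param seed Optional integer seed.
#' @param alternative `"directional"` (one-sided in the observed direction,
#'   the default) or `"two.sided"`.
#' @return An `ensemble_comparison` object: a list with
#'   `observed_difference` (bits, A minus B), `p_value`, `n_permutations`,
#'   `alternative`, `direction` (`"A > B"`, `"B > A"`, or `"equal"`), and
#'   the vector `perm_differences`.
#' @export
compare_ensembles <- function(a, b, n_perm = 1000, seed = NULL,
                              alternative = c("directional", "two.sided")) {
  stopifnot(inherits(a, "info_ensemble"), inherits(b, "info_ensemble"))
  alternative <- match.arg(alternative)
  if (!is.numeric(n_perm) || length(n_perm) != 1L || n_perm < 1) {
    stop_input("`n_perm` must be a single integer >= 1")
  }
  n_perm <- as.integer(n_perm)
  na <- a$n_sources
  nb <- b$n_sources
  delta <- weighted_mean_info(a$values, a$weights) -
    weighted_mean_info(b$values, b$weights)
  pool_v <- c(a$values, b$values)
  pool_w <- c(a$raw_weights, b$raw_weights)
  n <- na + nb
  perm <- with_seed(seed, vapply(seq_len(n_perm), function(j) {
    idx <- sample.int(n)
    ia <- idx[seq_len(na)]
    ib <- idx[(na + 1L):n]
    wa <- normalize_weights(pool_w[ia], warn = FALSE)
    wb <- normalize_weights(pool_w[ib], warn = FALSE)
    sum(wa * pool_v[ia]) - sum(wb * pool_v[ib])
  }, numeric(1)))
  exceed <- if (alternative == "two.sided") {
    sum(abs(perm) >= abs(delta))
  } else if (delta > 0) {
    sum(perm >= delta)
  } else if (delta < 0) {
    sum(perm <= delta)
  } else {
    n_perm
  }
  p <- if (exceed == 0L) 1 / (2 * n_perm) else exceed / n_perm
  structure(list(observed_difference = delta,
                 p_value = p,
                 n_permutations = n_perm,
                 alternative = alternative,
                 direction = if (delta > 0) "A > B" else if (delta < 0)
                   "B > A" else "equal",
                 labels = c(a$label %||% "A", b$label %||% "B"),
                 perm_differences = perm),
            class = "ensemble_comparison")
}

#' @export
print.ensemble_comparison <- function(x, digits = 4, ...) {
  cat("Ensemble comparison: ", x$labels[1L], " vs ", x$labels[2L], "\n",
      sep = "")
  cat("  observed difference in weighted means: ",
      format(x$observed_difference, digits = digits), " bits (",
      x$direction, ")\n", sep = "")
  cat("  permutation p-value (", x$alternative, ", ",
      x$n_permutations, " permutations): ",
      format(x$p_value, digits = digits), "\n", sep = "")
  invisible(x)
}
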