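#' Surrogate null mutual information values
#'
#' Generates `n_mc` null MI values for a set of paired observations by
#' uniformly permuting all Y states (one independent permutation per
#' surrogate) and recomputing the plug-in mutual information. Each surrogate
#' preserves the number of observations and both marginal distributions
#' exactly; in effect the null surrogates are draws from a fully noisy
#' (`a = 1`) system with the same marginals.
#'
#' For binary data the per-surrogate MI is computed from the joint counts
#' directly via a vectorized path; general `k x m` data fall back to a
#' per-permutation computation. Both paths consume the identical RNG stream
#' (one permutation per surrogate), so results do not depend on the path.
#'
#' @param obs A `joint_obs` object (or list with `x` and `y`).
#' @param n_mc Number of surrogate data sets (at least 1). Typical choices
#'   are 100, 500, or 1000 for per-source p-values; as few as 10 per source
#'   can suffice when only the pooled ensemble-versus-null KS test is needed.
#' @param seed Optional integer seed for reproducibility.
#' @return Numeric vector of `n_mc` null MI values in bits.
#' @export
null_mi <- function(obs, n_mc, seed = NULL) {
  obs <- as_joint_obs(obs)
  if (!is.numeric(n_mc) || length(n_mc) != 1L || is.na(n_mc) || n_mc < 1) {
    stop_input("`n_mc` must be a single integer >= 1")
  }
  n_mc <- as.integer(n_mc)
  binary <- all(obs$x %in% c(0L, 1L)) && all(obs$y %in% c(0L, 1L))
  with_seed(seed, {
    if (binary) {
      ix1 <- obs$x == 1L
      n11 <- vapply(seq_len(n_mc),
                    function(j) sum(sample(obs$y)[ix1]),
                    numeric(1))
      mi_binary_counts(n11, nx1 = sum(ix1), ny1 = sum(obs$y),
                       n = length(obs$x))
    } else {
      vapply(seq_len(n_mc), function(j) {
        mutual_information(new_joint_obs(obs$x, sample(obs$y)))
      }, numeric(1))
    }
  })
}

# Vectorized plug-in MI (bits) for 2x2 tables parameterized by the count
# n11 = #{x=1, y=1} and fixed marginals nx1, ny1 out of n observations.
mi_binary_counts <- function(n11, nx1, ny1, n) {
  counts <- cbind(n - nx1 - ny1 + n11,  # x=0, y=0
                  ny1 - n11,            # x=0, y=1
                  nx1 - n11,            # x=1, y=0
                  n11)                  # x=1, y=1
  px <- c(1 - nx1 / n, 1 - nx1 / n, nx1 / n, nx1 / n)
  py <- c(1 - ny1 / n, ny1 / n, 1 - ny1 / n, ny1 / n)
  p <- counts / n
  term <- p * log2(sweep(p, 2L, px * py, "/"))
  term[counts == 0L] <- 0
  rowSums(term)
}

#' Monte Carlo p-value from surrogate null values
#'
#' The p-value of an observed information value is the fraction of surrogate
#' null values greater than or equal to it (ties count toward the null). If
#' no surrogate reaches the observed value, the p-value is estimated as
#' `1/(2 * n_mc)`, the resolution floor of the Monte Carlo test; the observed
#' value itself is never added to the null set.
#'
#' @param info_value Observed information value in bits.
#' @param null_values Non-empty numeric vector of surrogate null values.
#' @return A p-value in `[1/(2*length(null_values)), 1]`.
#' @examples
#' mc_pvalue(0.2, c(rep(0.25, 30), rep(0.1, 970)))  # 0.03
#' mc_pvalue(0.5, rep(0.1, 1000))                   # floored at 0.0005
#' @export
mc_pvalue <- function(info_value, null_values) {
  if (!is.numeric(null_values) || length(null_values) == 0L ||
      anyNA(null_values)) {
    stop_input("`null_values` must be a non-empty numeric vector without NA")
  }
  if (!is.numeric(info_value) || length(info_value) != 1L || is.na(info_value)) {
    stop_input("`info_value` must be a single number")
  }
  n_mc <- length(null_values)
  exceed <- sum(null_values >= info_value)
  if (exceed == 0L) 1 / (2 * n_mc) else exceed / n_mc
}

#' Build one information source: value, surrogate null, and p-value
#'
#' Computes the plug-in mutual information of the observations, generates
#' `n_mc` surrogate null values with [null_mi()], and derives the Monte Carlo
#' p-value with [mc_pvalue()]. The source's weight is left unset until it is
#' placed in an ensemble (weights are normalized across an ensemble).
#'
#' @inheritParams null_mi
#' @return An `info_source` object: a list with `info_value`, `null_values`,
#'   `p_value`, and `weight` (`NA` until ensemble weighting).
#' @export
info_source <- function(obs, n_mc = 1000, seed = NULL) {
  obs <- as_joint_obs(obs)
  value <- mutual_information(obs)
  nulls <- null_mi(obs, n_mc, seed = seed)
  structure(list(info_value = value,
                 null_values = nulls,
                 p_value = mc_pvalue(value, nulls),
                 weight = NA_real_),
            class = "info_source")
}

#' @export
print.info_source <- function(x, digits = 4, ...) {
  cat("Information source: ", format(x$info_value, digits = digits),
      " bits, p = ", format(x$p_value, digits = digits),
      " (", length(x$null_values), " surrogates)\n", sep = "")
  invisible(x)
}
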