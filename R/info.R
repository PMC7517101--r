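#' Plug-in joint probability distribution
#'
#' Estimates the joint probability distribution of two discrete variables by
#' dividing the table of joint observation counts by the total number of
#' observations. Accepts either a `joint_obs` object or a count matrix of any
#' dimension `k x m`, so discrete data with more than two states per variable
#' plug in unchanged.
#'
#' @param x A `joint_obs` object, or a numeric matrix of non-negative joint
#'   counts (rows: states of one variable, columns: states of the other).
#' @return A `joint_distribution` object: a list with the probability table
#'   `pdist` (summing to 1), and the marginal vectors `marginal_row` and
#'   `marginal_col`.
#' @examples
#' joint_distribution(matrix(c(21, 9, 9, 21), 2))
#' @export
joint_distribution <- function(x) {
  if (inherits(x, "joint_distribution")) return(x)
  counts <- if (inherits(x, "joint_obs") ||
                (is.list(x) && all(c("x", "y") %in% names(x)))) {
    obs <- as_joint_obs(x)
    as.matrix(table(factor(obs$y), factor(obs$x)))
  } else if (is.matrix(x) && is.numeric(x)) {
    x
  } else {
    stop_input("`x` must be a joint_obs object or a numeric count matrix")
  }
  if (any(is.na(counts)) || any(counts < 0)) {
    stop_input("joint counts must be non-negative and non-missing")
  }
  total <- sum(counts)
  if (total <= 0) stop_input("joint counts must contain at least one observation")
  p <- counts / total
  structure(list(pdist = p,
                 marginal_row = rowSums(p),
                 marginal_col = colSums(p)),
            class = "joint_distribution")
}

#' Mutual information of a discrete joint distribution, in bits
#'
#' Plug-in mutual information
#' \deqn{I(X;Y) = \sum_{x,y} p(x,y) \log_2 \frac{p(x,y)}{p(x)\,p(y)},}
#' computed in bits with the convention that cells with `p(x,y) = 0`
#' contribute zero. The input may be a `joint_distribution`, a count matrix,
#' a probability matrix (detected by its sum being 1), or raw paired
#' observations; any `k x m` table is accepted.
#'
#' @param x A `joint_distribution`, `joint_obs`, or numeric matrix of joint
#'   counts or probabilities.
#' @return Mutual information in bits (a non-negative scalar, up to floating
#'   point error).
#' @examples
#' mutual_information(matrix(c(0.5, 0, 0, 0.5), 2))  # 1 bit
#' mutual_information(matrix(1, 2, 2))               # independent: 0 bits
#' @export
mutual_information <- function(x) {
  dist <- joint_distribution(x)
  p <- dist$pdist
  expected <- outer(dist$marginal_row, dist$marginal_col)
  nz <- p > 0
  sum(p[nz] * log2(p[nz] / expected[nz]))
}

# Shannon entropy in bits of a probability vector (zeros contribute zero).
entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' @export
print.joint_distribution <- function(x, digits = 4, ...) {
  cat("Joint probability distribution (",
      nrow(x$pdist), "x", ncol(x$pdist), "):\n", sep = "")
  print(round(x$pdist, digits))
  cat("Mutual information:", format(mutual_information(x), digits = digits),
      "bits\n")
  invisible(x)
}
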