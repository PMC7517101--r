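#' Expected joint-count table for the binary-pair model
#'
#' Builds the 2x2 table of joint observation counts for a single information
#' source: two binary variables X and Y observed `nobs` times, with balanced
#' marginals (half the observations of each variable in state 0, half in
#' state 1) and an interaction of strength `s`. The matched diagonal cells
#' (x = y) each hold `nobs/4 + Round(nobs*s/4)` observations and the
#' off-diagonal cells `nobs/4 - Round(nobs*s/4)`, where `Round()` rounds
#' half-up (0.5 goes to the next larger integer). At `s = 0` all four joint
#' states are equally likely; at `s = 1` the state of one variable completely
#' determines the other.
#'
#' @param nobs Number of joint observations; a positive integer, at least 4.
#'   By default it must be a multiple of 4 so the balanced-marginal table is
#'   exact.
#' @param s Interaction strength in `[0, 1]`.
#' @param allow_any_nobs If `TRUE`, `nobs` need not be a multiple of 4: the
#'   remainder over the uniform base table is distributed deterministically
#'   (diagonal cells first), so marginals are as close to balanced as the
#'   count allows.
#' @return An integer 2x2 matrix with rows indexed by `y` (0, 1) and columns
#'   by `x` (0, 1), summing to `nobs`.
#' @examples
#' count_table(60, 0.4)
#' count_table(8, 1)
#' @export
count_table <- function(nobs, s, allow_any_nobs = FALSE) {
  check_model_params(nobs = nobs, s = s, a = 0, allow_any_nobs = allow_any_nobs)
  base <- rep(nobs %/% 4, 4L)  # cell order: (y0,x0), (y1,x1), (y0,x1), (y1,x0)
  rem <- nobs %% 4L
  if (rem > 0L) base[seq_len(rem)] <- base[seq_len(rem)] + 1L
  d <- round_half_up(nobs * s / 4)
  d <- min(d, base[3L], base[4L])  # keep off-diagonal cells non-negative
  counts <- c(base[1L] + d, base[2L] + d, base[3L] - d, base[4L] - d)
  tab <- matrix(as.integer(counts[c(1L, 4L, 3L, 2L)]), nrow = 2L,
                dimnames = list(y = c("0", "1"), x = c("0", "1")))
  tab
}

#' Simulate joint observations from the binary-pair model
#'
#' Draws `nobs` paired binary observations of (X, Y) for a single information
#' source: the joint-state counts before noise exactly match
#' [count_table()], the observation order is randomized, and noise is then
#' applied with [apply_noise()], which re-permutes the Y states of
#' `Round(nobs*a)` randomly selected observations. Marginal distributions of
#' X and Y are preserved exactly at every noise level.
#'
#' @inheritParams count_table
#' @param a Noise level in `[0, 1]`: the fraction of observations whose Y
#'   state is randomly re-permuted. `a = 0` leaves the model governed purely
#'   by `s`; at `a = 1` the interaction is destroyed entirely.
#' @param seed Optional integer seed; the same seed reproduces the same
#'   observations without touching the caller's RNG state.
#' @return A `joint_obs` object: a list with integer vectors `x` and `y`
#'   (each 0/1, length `nobs`).
#' @examples
#' obs <- simulate_observations(60, s = 0.4, a = 0.1, seed = 1)
#' table(obs$x, obs$y)
#' @export
simulate_observations <- function(nobs, s, a, seed = NULL,
                                  allow_any_nobs = FALSE) {
  check_model_params(nobs = nobs, s = s, a = a, allow_any_nobs = allow_any_nobs)
  tab <- count_table(nobs, s, allow_any_nobs = allow_any_nobs)
  # Expand the table into index-aligned state vectors (canonical cell order),
  # then shuffle the observation order and inject noise.
  y <- rep(rep(c(0L, 1L), each = 2L), times = as.vector(t(tab)))
  x <- rep(rep(c(0L, 1L), times = 2L), times = as.vector(t(tab)))
  with_seed(seed, {
    ord <- sample.int(nobs)
    obs <- new_joint_obs(x[ord], y[ord])
    apply_noise(obs, a)
  })
}

#' Apply observation noise by re-permuting Y states
#'
#' Selects `Round(nobs * a)` observation indices uniformly without
#' replacement and applies a uniform random permutation to the Y values at
#' those indices (which may leave some values in place). X values are never
#' touched, and since the multiset of Y values is preserved, both marginal
#' distributions survive exactly.
#'
#' @param obs A `joint_obs` object.
#' @param a Noise level in `[0, 1]`.
#' @param seed Optional integer seed (see [simulate_observations()]).
#' @return A `joint_obs` object of the same length.
#' @export
apply_noise <- function(obs, a, seed = NULL) {
  obs <- as_joint_obs(obs)
  if (!is.numeric(a) || length(a) != 1L || is.na(a) || a < 0 || a > 1) {
    stop_input("`a` must be a single number in [0, 1]")
  }
  n <- length(obs$x)
  k <- round_half_up(n * a)
  if (k == 0L) return(obs)
  with_seed(seed, {
    idx <- sample.int(n, k)
    obs$y[idx] <- obs$y[idx][sample.int(k)]
  })
  obs
}

new_joint_obs <- function(x, y) {
  structure(list(x = as.integer(x), y = as.integer(y)), class = "joint_obs")
}

as_joint_obs <- function(obs) {
  if (inherits(obs, "joint_obs")) return(obs)
  if (is.list(obs) && all(c("x", "y") %in% names(obs))) {
    return(validate_joint_obs(new_joint_obs(obs$x, obs$y)))
  }
  stop_input("`obs` must be a joint_obs object or a list with `x` and `y`")
}

validate_joint_obs <- function(obs) {
  if (length(obs$x) != length(obs$y)) {
    stop_input("`x` and `y` must have the same length")
  }
  if (length(obs$x) == 0L) stop_input("observations must be non-empty")
  if (anyNA(obs$x) || anyNA(obs$y)) stop_input("observations must not contain NA")
  obs
}

#' @export
print.joint_obs <- function(x, ...) {
  cat("Joint observations:", length(x$x), "paired samples\n")
  print(stats::xtabs(~ y + x, data.frame(x = x$x, y = x$y)))
  invisible(x)
}

check_model_params <- function(nobs, s, a, allow_any_nobs = FALSE) {
  if (!is.numeric(nobs) || length(nobs) != 1L || is.na(nobs) ||
      nobs != as.integer(nobs) || nobs < 4) {
    stop_input("`nobs` must be a single integer >= 4")
  }
  if (!allow_any_nobs && nobs %% 4 != 0) {
    stop_input("`nobs` must be a multiple of 4 (set `allow_any_nobs = TRUE` ",
               "to distribute the remainder deterministically)")
  }
  if (!is.numeric(s) || length(s) != 1L || is.na(s) || s < 0 || s > 1) {
    stop_input("`s` must be a single number in [0, 1]")
  }
  if (!is.numeric(a) || length(a) != 1L || is.na(a) || a < 0 || a > 1) {
    stop_input("`a` must be a single number in [0, 1]")
  }
  invisible(TRUE)
}
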