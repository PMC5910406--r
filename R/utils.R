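#' Wilson score confidence interval for a binomial proportion
#'
#' Computes the Wilson score interval, which remains well-behaved at small
#' counts and at proportions near 0 or 1. Non-integer success counts are
#' accepted (the formula is algebraic in \code{x}), which is used when
#' hit-count-weighted read fractions are treated as effective successes.
#'
#' @param x Number of successes (may be non-integer, \code{0 <= x <= n}).
#' @param n Number of trials (positive).
#' @param conf Confidence level, default 0.95.
#' @return Numeric vector \code{c(point, lower, upper)}.
#' @export
wilson_ci <- function(x, n, conf = 0.95) {
  stopifnot(n > 0, x >= -1e-9, x <= n + 1e-9)
  x <- min(max(x, 0), n)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(point = p, lower = max(0, centre - half), upper = min(1, centre + half))
}

#' Exact Poisson confidence interval on a rate
#'
#' Exact (chi-square / gamma) interval for a Poisson count \code{k} observed
#' over an exposure \code{width}, returned on the per-base rate scale.
#'
#' @param k Observed count (non-negative integer).
#' @param width Exposure (locus width in bases, positive).
#' @param conf Confidence level, default 0.95.
#' @return Numeric vector \code{c(point, lower, upper)} of rates per base.
#' @export
poisson_rate_ci <- function(k, width, conf = 0.95) {
  stopifnot(k >= 0, width > 0)
  a <- 1 - conf
  lower <- if (k == 0) 0 else stats::qchisq(a / 2, 2 * k) / 2
  upper <- stats::qchisq(1 - a / 2, 2 * k + 2) / 2
  c(point = k / width, lower = lower / width, upper = upper / width)
}

#' Hungarian (Munkres) assignment
#'
#' Solves the linear assignment problem minimising total cost for a square
#' cost matrix. Used to match bootstrap-resample clusters to reference
#' clusters by maximum agreement.
#'
#' @param cost Square numeric cost matrix.
#' @return Integer vector \code{a} with \code{a[i]} the column assigned to
#'   row \code{i}.
#' @export
solve_assignment <- function(cost) {
  stopifnot(is.matrix(cost), nrow(cost) == ncol(cost))
  n <- nrow(cost)
  # Shortest augmenting path algorithm, O(n^3). Column index 0 is a virtual
  # column; all 0..n column arrays are stored at R index j + 1.
  u <- numeric(n)           # row potentials, u[i]
  v <- numeric(n + 1)       # column potentials, v[j + 1], j = 0..n
  p <- integer(n + 1)       # p[j + 1]: row assigned to column j (0 = none)
  way <- integer(n + 1)
  INF <- sum(abs(cost)) + 1
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0
    minv <- rep(INF, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      delta <- INF
      j1 <- 0
      for (j in seq_len(n)) {
        if (!used[j + 1]) {
          cur <- cost[i0, j] - u[i0] - v[j + 1]
          if (cur < minv[j + 1]) {
            minv[j + 1] <- cur
            way[j + 1] <- j0
          }
          if (minv[j + 1] < delta) {
            delta <- minv[j + 1]
            j1 <- j
          }
        }
      }
      for (j in 0:n) {
        if (used[j + 1]) {
          if (p[j + 1] > 0) u[p[j + 1]] <- u[p[j + 1]] + delta
          v[j + 1] <- v[j + 1] - delta
        } else {
          minv[j + 1] <- minv[j + 1] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1] == 0) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0) break
    }
  }
  ans <- integer(n)
  for (j in seq_len(n)) if (p[j + 1] > 0) ans[p[j + 1]] <- j
  ans
}

# Derive a 32-bit-safe integer seed from a base seed and a label.
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647L)
}

# Internal: stop() with a class so callers can distinguish validation errors.
srnaloc_error <- function(msg, class) {
  stop(structure(class = c(class, "srnaloc_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
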