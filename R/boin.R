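#' BOIN escalation and de-escalation boundaries
#'
#' The optimal-interval boundaries for target rate `phi`, with `phi1` the
#' highest rate considered subtherapeutic and `phi2` the lowest considered
#' overly toxic:
#' `lambda_e = log((1 - phi1)/(1 - phi)) / log(phi (1 - phi1) / (phi1 (1 - phi)))`
#' and
#' `lambda_d = log((1 - phi)/(1 - phi2)) / log(phi2 (1 - phi) / (phi (1 - phi2)))`.
#'
#' @param phi Target DLT rate.
#' @param phi1,phi2 Interval endpoints, `0 < phi1 < phi < phi2 < 1`.
#' @return An object of class `boin_boundaries` with `lambda_e` and
#'   `lambda_d` (`lambda_e < phi < lambda_d` always holds).
#' @examples
#' boin_boundaries(0.30, 0.18, 0.42)
#' @export
boin_boundaries <- function(phi, phi1 = 0.6 * phi, phi2 = 1.4 * phi) {
  if (!(0 < phi1 && phi1 < phi && phi < phi2 && phi2 < 1))
    stop("need 0 < phi1 < phi < phi2 < 1", call. = FALSE)
  lambda_e <- log((1 - phi1) / (1 - phi)) /
    log(phi * (1 - phi1) / (phi1 * (1 - phi)))
  lambda_d <- log((1 - phi) / (1 - phi2)) /
    log(phi2 * (1 - phi) / (phi * (1 - phi2)))
  structure(list(phi = phi, phi1 = phi1, phi2 = phi2,
                 lambda_e = lambda_e, lambda_d = lambda_d),
            class = "boin_boundaries")
}

#' @export
print.boin_boundaries <- function(x, ...) {
  cat(sprintf("<boin_boundaries> phi %.3f: escalate if phat <= %.4f, de-escalate if phat >= %.4f\n",
              x$phi, x$lambda_e, x$lambda_d))
  invisible(x)
}

#' Per-row state of an interval or rule-based design
#'
#' @param n_levels Number of levels in the row.
#' @return A list with per-level counts `n` (treated) and `x` (DLTs), the
#'   `current` level, the `eliminated` logical vector, and a
#'   `stopped_safety` flag.
#' @export
row_state <- function(n_levels) {
  list(n = integer(n_levels), x = integer(n_levels), current = 1L,
       eliminated = logical(n_levels), stopped_safety = FALSE)
}

#' BOIN dose decision for the next patient
#'
#' Compares the observed DLT rate at the current level with the interval
#' boundaries: escalate below `lambda_e`, de-escalate at or above
#' `lambda_d`, otherwise stay. Escalation is capped at the highest
#' non-eliminated level and de-escalation floored at level 1; an eliminated
#' level is never assigned. The decision depends on the history only
#' through the current level's counts.
#'
#' @param rs A [row_state()] whose current level has at least one patient.
#' @param b A [boin_boundaries()].
#' @return The level for the next patient.
#' @export
boin_next <- function(rs, b) {
  cur <- rs$current
  if (rs$n[cur] < 1L) stop("current level has no patients", call. = FALSE)
  phat <- rs$x[cur] / rs$n[cur]
  K <- length(rs$n)
  if (phat <= b$lambda_e) {
    up <- cur + 1L
    if (up <= K && !rs$eliminated[up]) up else cur
  } else if (phat >= b$lambda_d) {
    max(cur - 1L, 1L)
  } else cur
}

#' BOIN overdose elimination rule
#'
#' A level with at least three patients is eliminated, together with all
#' higher levels, when the posterior probability that its DLT rate exceeds
#' the target -- under a uniform Beta(1, 1) prior, i.e.
#' `Pr(p > phi)` with `p ~ Beta(1 + x, 1 + n - x)` -- exceeds `threshold`.
#' Eliminating level 1 marks the row stopped for safety.
#'
#' @param rs A [row_state()].
#' @param phi Target DLT rate.
#' @param threshold Posterior probability threshold (default 0.95).
#' @return The updated `row_state`.
#' @export
boin_eliminate <- function(rs, phi, threshold = 0.95) {
  K <- length(rs$n)
  for (j in seq_len(K)) {
    if (rs$n[j] >= 3L && !rs$eliminated[j]) {
      post <- 1 - pbeta(phi, 1 + rs$x[j], 1 + rs$n[j] - rs$x[j])
      if (post > threshold) {
        rs$eliminated[j:K] <- TRUE
        if (j == 1L) rs$stopped_safety <- TRUE
        break
      }
    }
  }
  rs
}

#' Weighted isotonic regression by pool-adjacent-violators
#'
#' The weighted least-squares monotone (nondecreasing) fit to `values`.
#'
#' @param values Numeric vector.
#' @param weights Positive weights of the same length.
#' @return Nondecreasing numeric vector of the same length.
#' @examples
#' pava_isotonic(c(0.5, 0.1), c(1, 1))
#' @export
pava_isotonic <- function(values, weights = rep(1, length(values))) {
  if (length(values) != length(weights) || any(weights <= 0))
    stop("`weights` must be positive and match `values`", call. = FALSE)
  k <- length(values)
  if (k <= 1L) return(values)
  # blocks as (mean, weight, size) stacks
  vm <- numeric(k); vw <- numeric(k); vn <- integer(k)
  top <- 0L
  for (i in seq_len(k)) {
    top <- top + 1L
    vm[top] <- values[i]; vw[top] <- weights[i]; vn[top] <- 1L
    while (top > 1L && vm[top - 1L] > vm[top]) {
      w <- vw[top - 1L] + vw[top]
      vm[top - 1L] <- (vw[top - 1L] * vm[top - 1L] + vw[top] * vm[top]) / w
      vw[top - 1L] <- w
      vn[top - 1L] <- vn[top - 1L] + vn[top]
      top <- top - 1L
    }
  }
  rep(vm[seq_len(top)], vn[seq_len(top)])
}

#' BOIN MTD selection for a finished row
#'
#' No MTD when the row stopped for safety. Otherwise posterior mean DLT
#' rates under the quasi-uniform Beta(0.05, 0.05) selection prior,
#' `(x + 0.05)/(n + 0.1)`, at the tried, non-eliminated levels are made
#' monotone by [pava_isotonic()] (inverse-posterior-variance weights), and
#' the level with the adjusted rate closest to the target is selected,
#' equidistant ties going to the lower level. (The near-flat selection
#' prior keeps sparsely tried levels from looking artificially close to
#' the target; the uniform Beta(1, 1) prior is used only for the
#' elimination rule.)
#'
#' @param rs A finished [row_state()].
#' @param phi Target DLT rate.
#' @return The selected level, or `NA` when none is selected.
#' @export
boin_select_mtd <- function(rs, phi) {
  if (rs$stopped_safety) return(NA_integer_)
  ok <- which(rs$n > 0L & !rs$eliminated)
  if (length(ok) == 0L) return(NA_integer_)
  a <- rs$x[ok] + 0.05
  b <- rs$n[ok] - rs$x[ok] + 0.05
  pm <- a / (a + b)
  w <- (a + b)^2 * (a + b + 1) / (a * b)  # 1 / posterior variance
  adj <- pava_isotonic(pm, w)
  ok[which.min(abs(adj - phi))]
}
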