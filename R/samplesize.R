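#' CRM sample size for a desired average probability of correct selection
#'
#' Computes the number of participants a one-parameter CRM needs so that
#' its average probability of correct MTD selection (PCS) across possible
#' MTD locations reaches `pcs_goal`. The calculation works through the
#' complete-information (nonparametric benchmark) design: dose-toxicity
#' scenarios are calibrated so adjacent doses differ by the odds ratio
#' `effect_size` around `target`, with the true MTD placed at each of the
#' `n_levels` positions in turn; the benchmark's average PCS is evaluated
#' by a normal approximation to the joint distribution of the empirical
#' toxicity rates at the MTD's neighbors, and its continuous crossing
#' `n*` of `pcs_goal` is found by root-finding. The CRM, which learns the
#' curve one patient at a time instead of observing complete tolerance
#' profiles, requires about twice the benchmark's sample size to match its
#' PCS, so the returned value is `ceiling(2 n*)`.
#'
#' The returned N is nonincreasing in `effect_size` and nondecreasing in
#' `pcs_goal` and `n_levels`.
#'
#' @param pcs_goal Desired average PCS, in (0, 1) (e.g. 0.50).
#' @param target Target DLT rate (e.g. 0.30).
#' @param n_levels Total number of test doses (e.g. 14 for 7 levels in each
#'   of 2 rows).
#' @param effect_size Odds ratio between the DLT probabilities of adjacent
#'   doses in the calibrated scenarios (psi > 1; e.g. 1.78).
#' @return Integer number of participants.
#' @examples
#' crm_sample_size(0.50, 0.30, 14, 1.78)
#' @export
crm_sample_size <- function(pcs_goal, target, n_levels, effect_size) {
  if (pcs_goal <= 0 || pcs_goal >= 1)
    stop("`pcs_goal` must be in (0, 1)", call. = FALSE)
  if (target <= 0 || target >= 1)
    stop("`target` must be in (0, 1)", call. = FALSE)
  n_levels <- as.integer(n_levels)
  if (n_levels < 2L) stop("`n_levels` must be >= 2", call. = FALSE)
  if (effect_size <= 1) stop("`effect_size` must exceed 1", call. = FALSE)
  f <- function(n) benchmark_avg_pcs(n, n_levels, target, effect_size) -
    pcs_goal
  # bracket the crossing; PCS is increasing in n
  lo <- 2; hi <- 64
  while (f(hi) < 0 && hi < 1e6) hi <- hi * 2
  if (f(hi) < 0)
    stop("requested PCS goal is out of the calculator's domain",
         call. = FALSE)
  if (f(lo) > 0) return(as.integer(ceiling(2 * lo)))
  nstar <- uniroot(f, c(lo, hi), tol = 1e-6)$root
  as.integer(ceiling(2 * nstar))
}

#' Average PCS of the complete-information benchmark design
#'
#' The benchmark observes every patient's full tolerance profile, so the
#' empirical DLT rate at dose d is the empirical CDF of n uniform
#' tolerances evaluated at the true probability `p_d`, and the estimated
#' MTD is the dose whose empirical rate is closest to the target. Under a
#' scenario with the MTD at position `nu` and odds-ratio spacing `psi`,
#' correct selection reduces to two (correlated) linear conditions on the
#' empirical CDF at the MTD and its neighbors; their joint probability is
#' evaluated under the normal approximation, integrating the conditional
#' normal over the first condition. The average over `nu = 1..n_levels` is
#' returned. `n` may be non-integral (the approximation is continuous in
#' n), which is what allows root-finding in [crm_sample_size()].
#'
#' @param n Number of patients (positive, possibly non-integer).
#' @param n_levels Number of doses.
#' @param target Target DLT rate.
#' @param psi Adjacent-dose odds ratio.
#' @return Average probability of correct selection.
#' @export
benchmark_avg_pcs <- function(n, n_levels, target, psi) {
  pdose <- function(d, nu) plogis(qlogis(target) + (d - nu) * log(psi))
  th2 <- 2 * target
  per_nu <- vapply(seq_len(n_levels), function(nu) {
    pm <- target
    if (nu == 1L) {
      pr <- pdose(2, 1)
      mu <- pm + pr
      v <- (pm * (1 - pm) + pr * (1 - pr) + 2 * pm * (1 - pr)) / n
      1 - pnorm(th2, mu, sqrt(v))
    } else if (nu == n_levels) {
      pl <- pdose(n_levels - 1, n_levels)
      mu <- pl + pm
      v <- (pl * (1 - pl) + pm * (1 - pm) + 2 * pl * (1 - pm)) / n
      pnorm(th2, mu, sqrt(v))
    } else {
      pl <- pdose(nu - 1, nu); pr <- pdose(nu + 1, nu)
      muA <- pl + pm; muB <- pm + pr
      vA <- (pl * (1 - pl) + pm * (1 - pm) + 2 * pl * (1 - pm)) / n
      vB <- (pm * (1 - pm) + pr * (1 - pr) + 2 * pm * (1 - pr)) / n
      cAB <- (pl * (1 - pm) + pl * (1 - pr) + pm * (1 - pm) +
                pm * (1 - pr)) / n
      # P(A < 2 theta, B > 2 theta) for bivariate normal (A, B)
      sA <- sqrt(vA)
      integrate(function(z) {
        a <- muA + sA * z
        mu_cond <- muB + cAB / vA * (a - muA)
        v_cond <- vB - cAB^2 / vA
        dnorm(z) * pnorm((mu_cond - th2) / sqrt(v_cond))
      }, lower = -Inf, upper = (th2 - muA) / sA,
      rel.tol = 1e-9)$value
    }
  }, numeric(1))
  mean(per_nu)
}
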