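#' The CRM shift-model design
#'
#' Configures the two-stage CRM that concurrently finds the MTD of the
#' agent alone (row 1) and with the second agent (row 2). One working model
#' is built per allowed MTD shift from a common Lee-Cheung base skeleton of
#' length `n_levels + max(|shifts|)`; all accumulated data refit every model
#' by maximum likelihood, the best model is selected (exact ties broken at
#' random), and the next patient is randomized with probability 1/2 between
#' the two rows' recommended levels.
#'
#' @param target Target DLT rate theta (default 0.30).
#' @param n_max Total sample size (default 39, see [crm_sample_size()]).
#' @param shifts Allowed row-2 minus row-1 MTD offsets (default `c(0, -1)`).
#' @param n_levels Dose levels per row (default 7).
#' @param halfwidth,prior_mtd Skeleton calibration parameters passed to
#'   [lee_cheung_skeleton()] (defaults 0.05 and 4).
#' @param model_weights Prior weights over working models; the default gives
#'   every model equal weight, i.e. pure maximum-likelihood comparison.
#' @param safety_conf One-sided confidence level of the Clopper-Pearson
#'   lower bound used by the safety stopping rule (default 0.90).
#' @param safety_min_n Minimum number of patients at the lowest combination
#'   before the safety rule can fire (default 3).
#' @param escalation_cap If `TRUE`, model recommendations in the modeling
#'   stage may escalate at most one level per row above the highest level
#'   tried in that row (off by default: recommendations are followed as-is).
#' @param grid Optional [dose_grid()]; defaults to a 2 x `n_levels` grid.
#' @return An object of class `c("shift_crm_design", "dose_design")`.
#' @examples
#' shift_crm_design()
#' @export
shift_crm_design <- function(target = 0.30, n_max = 39L, shifts = c(0L, -1L),
                             n_levels = 7L, halfwidth = 0.05, prior_mtd = 4L,
                             model_weights = NULL, safety_conf = 0.90,
                             safety_min_n = 3L, escalation_cap = FALSE,
                             grid = NULL) {
  if (target <= 0 || target >= 1)
    stop("`target` must be in (0, 1)", call. = FALSE)
  n_levels <- as.integer(n_levels); n_max <- as.integer(n_max)
  if (is.null(grid)) grid <- dose_grid(n_levels)
  if (n_max < grid$n_rows) stop("`n_max` too small", call. = FALSE)
  base <- lee_cheung_skeleton(target, halfwidth, prior_mtd,
                              n_levels + max(abs(as.integer(shifts))))
  models <- shift_working_models(base, shifts, n_levels)
  if (is.null(model_weights)) model_weights <- rep(1, length(models))
  if (length(model_weights) != length(models) || any(model_weights <= 0))
    stop("`model_weights` must be positive, one per shift", call. = FALSE)
  structure(list(design = "shift_crm", target = target, n_max = n_max,
                 shifts = as.integer(shifts), n_levels = n_levels,
                 halfwidth = halfwidth, prior_mtd = as.integer(prior_mtd),
                 base = base, models = models,
                 model_weights = model_weights / sum(model_weights),
                 safety_conf = safety_conf,
                 safety_min_n = as.integer(safety_min_n),
                 escalation_cap = isTRUE(escalation_cap), grid = grid),
            class = c("shift_crm_design", "dose_design"))
}

#' Parallel independent per-row 3+3 design
#'
#' Classic 3+3 escalation run independently in each row: cohorts of three;
#' 0/3 DLT escalates, 1/3 expands to six, at most 1/6 escalates, two or more
#' DLTs stop the row with the next-lower level as its MTD (no MTD if that
#' happens at level 1). Clean escalation past the top level takes the top
#' level as the MTD.
#'
#' @param n_levels Dose levels per row (default 7).
#' @param grid Optional [dose_grid()].
#' @return An object of class `c("three_plus_three_design", "dose_design")`.
#' @export
three_plus_three_design <- function(n_levels = 7L, grid = NULL) {
  n_levels <- as.integer(n_levels)
  if (is.null(grid)) grid <- dose_grid(n_levels)
  structure(list(design = "3p3", n_levels = n_levels, grid = grid),
            class = c("three_plus_three_design", "dose_design"))
}

#' Parallel independent per-row BOIN design
#'
#' Bayesian optimal interval conduct run independently in each row with
#' cohorts of size one: the observed DLT rate at the current level is
#' compared with precomputed escalation/de-escalation boundaries; levels
#' whose posterior probability of excessive toxicity exceeds the elimination
#' threshold are removed (elimination of level 1 stops the row for safety);
#' the row's MTD is the tried, non-eliminated level whose isotonically
#' adjusted posterior mean DLT rate is closest to the target.
#'
#' @param target Target DLT rate phi (default 0.30).
#' @param n_per_row Patients per row (default 20, total 40).
#' @param phi1,phi2 Subtherapeutic and overly-toxic rates defining the
#'   optimal interval (defaults `0.6 * target` and `1.4 * target`).
#' @param elim_threshold Posterior probability threshold for dose
#'   elimination (default 0.95, Beta(1, 1) prior).
#' @param n_levels Dose levels per row (default 7).
#' @param grid Optional [dose_grid()].
#' @return An object of class `c("boin_design", "dose_design")`.
#' @export
parallel_boin_design <- function(target = 0.30, n_per_row = 20L,
                                 phi1 = 0.6 * target, phi2 = 1.4 * target,
                                 elim_threshold = 0.95, n_levels = 7L,
                                 grid = NULL) {
  n_levels <- as.integer(n_levels)
  if (is.null(grid)) grid <- dose_grid(n_levels)
  structure(list(design = "boin", target = target,
                 n_per_row = as.integer(n_per_row),
                 boundaries = boin_boundaries(target, phi1, phi2),
                 elim_threshold = elim_threshold,
                 n_levels = n_levels, grid = grid),
            class = c("boin_design", "dose_design"))
}

#' @export
print.dose_design <- function(x, ...) {
  cat(sprintf("<%s design>\n", x$design))
  if (x$design == "shift_crm") {
    cat(sprintf("  target %.2f, N = %d, shifts {%s}, %d levels/row\n",
                x$target, x$n_max, paste(x$shifts, collapse = ", "),
                x$n_levels))
    cat(sprintf("  skeleton: delta = %.2f, prior MTD = %d\n",
                x$halfwidth, x$prior_mtd))
  } else if (x$design == "boin") {
    b <- x$boundaries
    cat(sprintf("  target %.2f, n = %d per row, lambda_e %.4f, lambda_d %.4f\n",
                x$target, x$n_per_row, b$lambda_e, b$lambda_d))
  } else {
    cat(sprintf("  %d levels per row, cohorts of 3\n", x$n_levels))
  }
  invisible(x)
}
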