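#' Log-likelihood of the one-parameter power model
#'
#' For skeleton value `p_i` at patient i's combination and DLT indicator
#' `y_i`, the empiric model states `Pr(DLT) = p_i^exp(a)`, giving
#' `sum_i [ y_i log(p_i^exp(a)) + (1 - y_i) log(1 - p_i^exp(a)) ]`.
#' The exponent is parameterized as `exp(a)` so it stays positive and `a`
#' can be optimized on an unconstrained interval.
#'
#' @param model A `working_model`.
#' @param state A non-empty `trial_state`.
#' @param a Power parameter on the log scale.
#' @return The log-likelihood (scalar).
#' @export
power_model_loglik <- function(model, state, a) {
  stopifnot(inherits(model, "working_model"), inherits(state, "trial_state"))
  r <- state$records
  if (nrow(r) == 0L) stop("`state` must contain data", call. = FALSE)
  p <- model$skeleton[cbind(r$row, r$level)]
  if (any(p <= 0) || any(p >= 1))
    stop("skeleton values must lie in (0, 1)", call. = FALSE)
  .loglik_counts(p, r$dlt, rep(1L, nrow(r)), a)
}

# aggregated form: skeleton values p with x DLT out of n at each value
.loglik_counts <- function(p, x, n, a) {
  lam <- exp(a)
  pf <- p^lam
  sum(x * lam * log(p) + (n - x) * log1p(-pf))
}

.fit_a <- function(p, x, n, interval = c(-10, 10), tol = 1e-6) {
  optimize(function(a) .loglik_counts(p, x, n, a),
           interval = interval, maximum = TRUE, tol = tol)
}

#' Fit one working model by maximum likelihood
#'
#' Estimates the power parameter of the empiric model by maximizing the
#' likelihood over `a` in `[-10, 10]` (the exponent `exp(a)` spans roughly
#' `5e-5` to `2e4`). Requires heterogeneous data: with only DLTs or only
#' non-DLTs the likelihood is monotone in `a` and no interior MLE exists.
#'
#' @param model A `working_model`.
#' @param state A `trial_state` in the modeling stage.
#' @return An object of class `crm_fit` with fields `model`, `a_hat`,
#'   `loglik`, and `dlt_estimates` (the fitted probability matrix
#'   `skeleton^exp(a_hat)`).
#' @export
fit_working_model <- function(model, state) {
  stopifnot(inherits(model, "working_model"), inherits(state, "trial_state"))
  if (state$stage != "modeling")
    stop(paste("heterogeneity required: need at least one DLT and one",
               "non-DLT before the model can be fitted"), call. = FALSE)
  cc <- .cell_counts(state)
  idx <- which(cc$n > 0)
  p <- model$skeleton[idx]; x <- cc$x[idx]; n <- cc$n[idx]
  opt <- .fit_a(p, x, n)
  structure(list(model = model, a_hat = opt$maximum, loglik = opt$objective,
                 dlt_estimates = model$skeleton^exp(opt$maximum)),
            class = "crm_fit")
}

#' @export
print.crm_fit <- function(x, digits = 3, ...) {
  cat(sprintf("<crm_fit> shift %d: a_hat = %.4f, logLik = %.4f\n",
              x$model$shift, x$a_hat, x$loglik))
  print(round(x$dlt_estimates, digits))
  invisible(x)
}

#' @export
coef.crm_fit <- function(object, ...) c(a_hat = object$a_hat)

#' @export
logLik.crm_fit <- function(object, ...) {
  structure(object$loglik, df = 1L, class = "logLik")
}

#' @export
predict.crm_fit <- function(object, ...) object$dlt_estimates

#' @export
summary.crm_fit <- function(object, ...) {
  print(object)
  invisible(object)
}

#' Select the working model with the largest likelihood
#'
#' Exact ties (within a relative tolerance of 1e-9, which captures the
#' structural ties that occur when the data cannot distinguish two models)
#' are broken by a uniform random draw among the tied models.
#'
#' @param fits List of `crm_fit` objects.
#' @param weights Optional positive prior weights; the log-weight is added
#'   to each log-likelihood before comparison (equal weights by default).
#' @return The selected index into `fits`.
#' @export
select_working_model <- function(fits, weights = NULL) {
  if (length(fits) == 0L) stop("no fits supplied", call. = FALSE)
  ll <- vapply(fits, function(f) f$loglik, numeric(1))
  if (!is.null(weights)) ll <- ll + log(weights)
  tol <- 1e-9 * max(1, abs(max(ll)))
  tied <- which(ll >= max(ll) - tol)
  if (length(tied) == 1L) tied else tied[sample.int(length(tied), 1L)]
}

#' Per-row dose recommendations from a fitted model
#'
#' For each row, the level whose fitted DLT probability is closest to the
#' target; equidistant ties go to the lower level.
#'
#' @param fit A `crm_fit`.
#' @param target Target DLT rate.
#' @return Integer vector, one recommended level per row.
#' @export
row_recommendations <- function(fit, target) {
  stopifnot(inherits(fit, "crm_fit"))
  apply(fit$dlt_estimates, 1L, function(p) which.min(abs(p - target)))
}

#' Next assignment during the initial escalation stage
#'
#' Before the data contain both a DLT and a non-DLT, patients follow a
#' prespecified path in cohorts of one: start at (row 1, level 1), escalate
#' along row 1, and -- if row 1 is exhausted without a DLT -- continue from
#' (row 2, level 1) along row 2, holding at the highest combination once
#' the path is exhausted. If a DLT has occurred but no non-DLT (so the
#' model is still inestimable and no lower dose exists to fall back to),
#' the current combination is repeated.
#'
#' @param state A `trial_state` with `stage == "initial"`.
#' @return A [combination()].
#' @export
initial_escalation_next <- function(state) {
  stopifnot(inherits(state, "trial_state"))
  if (state$stage != "initial")
    stop("wrong stage: state is already in the modeling stage",
         call. = FALSE)
  r <- state$records
  g <- state$grid
  if (nrow(r) == 0L) return(combination(1L, 1L, g))
  last <- r[nrow(r), ]
  if (sum(r$dlt) > 0L)  # DLT but no non-DLT: repeat
    return(combination(last$row, last$level, g))
  if (last$level < g$n_levels) combination(last$row, last$level + 1L, g)
  else if (last$row < g$n_rows) combination(last$row + 1L, 1L, g)
  else combination(last$row, last$level, g)
}

#' Next assignment under the shift-model CRM
#'
#' In the initial stage this delegates to [initial_escalation_next()]. In
#' the modeling stage every working model is refitted on all accumulated
#' data, the best model selected (ties at random), the per-row
#' recommendations computed, and the returned combination is the
#' recommended level of a row drawn with probability 1/2 each.
#'
#' @param state A `trial_state`.
#' @param design A [shift_crm_design()].
#' @return A [combination()], or `NULL` when `n_max` is reached
#'   (trial complete).
#' @export
next_assignment <- function(state, design) {
  stopifnot(inherits(state, "trial_state"),
            inherits(design, "shift_crm_design"))
  if (nrow(state$records) >= design$n_max) return(NULL)
  if (state$stage == "initial") return(initial_escalation_next(state))
  fits <- lapply(design$models, fit_working_model, state = state)
  sel <- select_working_model(fits, design$model_weights)
  rec <- .capped_recommendations(fits[[sel]], state, design)
  row <- if (runif(1) < 0.5) 1L else 2L
  combination(row, rec[row], state$grid)
}

.capped_recommendations <- function(fit, state, design) {
  rec <- row_recommendations(fit, design$target)
  if (design$escalation_cap) {
    cc <- .cell_counts(state)
    for (r in seq_along(rec)) {
      top <- if (any(cc$n[r, ] > 0)) max(which(cc$n[r, ] > 0)) else 0L
      rec[r] <- min(rec[r], top + 1L)
    }
    rec <- pmax(rec, 1L)
  }
  rec
}

#' Safety stopping rule at the lowest combination
#'
#' The trial stops for safety when at least `safety_min_n` patients have
#' been treated at (row 1, level 1) and the exact one-sided lower
#' Clopper-Pearson confidence bound (level `safety_conf`) on the DLT rate
#' there exceeds the target: even the lowest dose is then deemed too toxic.
#'
#' @param state A `trial_state`.
#' @param design A [shift_crm_design()].
#' @return Logical.
#' @export
safety_stop <- function(state, design) {
  stopifnot(inherits(state, "trial_state"),
            inherits(design, "shift_crm_design"))
  r <- state$records
  at11 <- r$row == 1L & r$level == 1L
  n <- sum(at11)
  if (n < design$safety_min_n) return(FALSE)
  x <- sum(r$dlt[at11])
  lb <- if (x == 0L) 0 else qbeta(1 - design$safety_conf, x, n - x + 1L)
  lb > design$target
}

#' Final MTD selection
#'
#' On a safety-stopped trial no MTD is selected in either row. Otherwise
#' all working models are refitted on the complete data, the best model
#' selected, and its per-row recommendations returned. Because every
#' working model places the row-2 skeleton at or above the row-1 skeleton,
#' the returned pair always satisfies `level[2] <= level[1]`: a reversal is
#' structurally impossible. If the final data are still homogeneous (no
#' DLT, or nothing but DLTs) the model is inestimable and no MTD is
#' selected.
#'
#' @param state A `trial_state` at trial completion.
#' @param design A [shift_crm_design()].
#' @param stopped Logical: was the trial stopped early for safety?
#' @return Integer vector `c(row1, row2)` of selected levels, `NA` where no
#'   MTD is selected.
#' @export
final_selection <- function(state, design, stopped = FALSE) {
  if (stopped || state$stage != "modeling")
    return(c(NA_integer_, NA_integer_))
  fits <- lapply(design$models, fit_working_model, state = state)
  sel <- select_working_model(fits, design$model_weights)
  .capped_recommendations(fits[[sel]], state, design)
}
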