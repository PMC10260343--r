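#' Simulate one trial under a design
#'
#' Runs a complete patient-by-patient trial: each assignment's DLT outcome
#' is a Bernoulli draw with the scenario's true probability at the assigned
#' combination, and the design's escalation, stopping and final-selection
#' rules are applied exactly as in live conduct. Fully reproducible from
#' `seed` (the RNG state of the session is left untouched).
#'
#' @param design A [shift_crm_design()], [three_plus_three_design()] or
#'   [parallel_boin_design()].
#' @param scenario A [tox_scenario()] on the same grid.
#' @param seed Integer seed, or `NULL` to consume the current RNG stream.
#' @return An object of class `trial_result`: a list with `design`, the
#'   per-patient `rows`, `levels` and `dlt`, the allocation count matrix
#'   `alloc`, the selected `mtd` per row (`NA` = none), `stopped_early`
#'   (for the shift design) or `stopped_by_row` (per-row designs), and the
#'   sample size `n`.
#' @export
run_trial <- function(design, scenario, seed = NULL) {
  UseMethod("run_trial")
}

#' @export
run_trial.shift_crm_design <- function(design, scenario, seed = NULL) {
  stopifnot(inherits(scenario, "tox_scenario"))
  probs <- scenario$probs
  if (nrow(probs) != 2L || ncol(probs) != design$n_levels)
    stop("scenario does not match the design grid", call. = FALSE)
  with_local_seed(seed, .run_shift_trial(design, probs))
}

.run_shift_trial <- function(design, probs) {
  L <- design$n_levels
  nmat <- xmat <- matrix(0L, 2L, L)
  rows <- levels <- dlt <- integer(design$n_max)
  n <- 0L
  stopped <- FALSE
  skels <- lapply(design$models, `[[`, "skeleton")
  lw <- log(design$model_weights)

  fit_all <- function() {
    idx <- which(nmat > 0)
    x <- xmat[idx]; nn <- nmat[idx]
    fits <- lapply(skels, function(sk) .fit_a(sk[idx], x, nn))
    ll <- vapply(fits, `[[`, numeric(1), "objective") + lw
    tol <- 1e-9 * max(1, abs(max(ll)))
    tied <- which(ll >= max(ll) - tol)
    sel <- if (length(tied) == 1L) tied else tied[sample.int(length(tied), 1L)]
    fitted <- skels[[sel]]^exp(fits[[sel]]$maximum)
    rec <- apply(fitted, 1L, function(p) which.min(abs(p - design$target)))
    if (design$escalation_cap) {
      for (r in 1:2) {
        top <- if (any(nmat[r, ] > 0L)) max(which(nmat[r, ] > 0L)) else 0L
        rec[r] <- max(1L, min(rec[r], top + 1L))
      }
    }
    rec
  }

  while (n < design$n_max) {
    # safety check at the lowest combination before each assignment
    if (nmat[1L, 1L] >= design$safety_min_n && xmat[1L, 1L] > 0L) {
      lb <- qbeta(1 - design$safety_conf, xmat[1L, 1L],
                  nmat[1L, 1L] - xmat[1L, 1L] + 1L)
      if (lb > design$target) { stopped <- TRUE; break }
    }
    heterogeneous <- sum(xmat) > 0L && sum(xmat) < n
    if (!heterogeneous) {
      if (n == 0L) { r <- 1L; l <- 1L }
      else if (sum(xmat) > 0L) { r <- rows[n]; l <- levels[n] }  # DLT only
      else if (levels[n] < L) { r <- rows[n]; l <- levels[n] + 1L }
      else if (rows[n] < 2L) { r <- rows[n] + 1L; l <- 1L }
      else { r <- rows[n]; l <- levels[n] }
    } else {
      rec <- fit_all()
      r <- if (runif(1) < 0.5) 1L else 2L
      l <- rec[r]
    }
    y <- as.integer(runif(1) < probs[r, l])
    n <- n + 1L
    rows[n] <- r; levels[n] <- l; dlt[n] <- y
    nmat[r, l] <- nmat[r, l] + 1L
    xmat[r, l] <- xmat[r, l] + y
  }
  rows <- rows[seq_len(n)]; levels <- levels[seq_len(n)]
  dlt <- dlt[seq_len(n)]
  mtd <- c(NA_integer_, NA_integer_)
  if (!stopped && sum(dlt) > 0L && sum(dlt) < n) {
    rec <- fit_all()
    mtd <- as.integer(rec)
  }
  structure(list(design = "shift_crm", rows = rows, levels = levels,
                 dlt = dlt, alloc = nmat, mtd = mtd,
                 stopped_early = stopped, n = n),
            class = "trial_result")
}

#' @export
run_trial.three_plus_three_design <- function(design, scenario, seed = NULL) {
  stopifnot(inherits(scenario, "tox_scenario"))
  probs <- scenario$probs
  with_local_seed(seed, {
    L <- design$n_levels
    alloc <- matrix(0L, 2L, L)
    rows <- levels <- dlt <- integer(0)
    mtd <- integer(2); stopped <- logical(2)
    for (r in 1:2) {
      rs <- row_state(L)
      rs$stop_level <- NA_integer_
      repeat {
        y <- as.integer(runif(3) < probs[r, rs$current])
        rs$n[rs$current] <- rs$n[rs$current] + 3L
        rs$x[rs$current] <- rs$x[rs$current] + sum(y)
        alloc[r, rs$current] <- alloc[r, rs$current] + 3L
        rows <- c(rows, rep(r, 3L)); levels <- c(levels, rep(rs$current, 3L))
        dlt <- c(dlt, y)
        act <- three_plus_three_next(rs)
        if (act == "expand") {
          y <- as.integer(runif(3) < probs[r, rs$current])
          rs$n[rs$current] <- rs$n[rs$current] + 3L
          rs$x[rs$current] <- rs$x[rs$current] + sum(y)
          alloc[r, rs$current] <- alloc[r, rs$current] + 3L
          rows <- c(rows, rep(r, 3L)); levels <- c(levels, rep(rs$current, 3L))
          dlt <- c(dlt, y)
          act <- three_plus_three_next(rs)
        }
        if (act == "stop") { rs$stop_level <- rs$current; break }
        if (rs$current == L) break  # clean escalation past the top
        rs$current <- rs$current + 1L
      }
      mtd[r] <- three_plus_three_mtd(rs)
      stopped[r] <- !is.na(rs$stop_level) && rs$stop_level == 1L
    }
    structure(list(design = "3p3", rows = rows, levels = levels, dlt = dlt,
                   alloc = alloc, mtd = mtd, stopped_by_row = stopped,
                   n = length(rows)),
              class = "trial_result")
  })
}

#' @export
run_trial.boin_design <- function(design, scenario, seed = NULL) {
  stopifnot(inherits(scenario, "tox_scenario"))
  probs <- scenario$probs
  with_local_seed(seed, {
    L <- design$n_levels
    alloc <- matrix(0L, 2L, L)
    rows <- levels <- dlt <- integer(0)
    mtd <- integer(2); stopped <- logical(2)
    for (r in 1:2) {
      rs <- row_state(L)
      for (i in seq_len(design$n_per_row)) {
        cur <- rs$current
        y <- as.integer(runif(1) < probs[r, cur])
        rs$n[cur] <- rs$n[cur] + 1L
        rs$x[cur] <- rs$x[cur] + y
        alloc[r, cur] <- alloc[r, cur] + 1L
        rows <- c(rows, r); levels <- c(levels, cur); dlt <- c(dlt, y)
        rs <- boin_eliminate(rs, design$target, design$elim_threshold)
        if (rs$stopped_safety) break
        rs$current <- if (rs$eliminated[cur]) max(cur - 1L, 1L)
                      else boin_next(rs, design$boundaries)
      }
      mtd[r] <- boin_select_mtd(rs, design$target)
      stopped[r] <- rs$stopped_safety
    }
    structure(list(design = "boin", rows = rows, levels = levels, dlt = dlt,
                   alloc = alloc, mtd = mtd, stopped_by_row = stopped,
                   n = length(rows)),
              class = "trial_result")
  })
}

#' @export
print.trial_result <- function(x, ...) {
  cat(sprintf("<trial_result> %s: n = %d, DLTs = %d, MTD = (%s)\n",
              x$design, x$n, sum(x$dlt),
              paste(ifelse(is.na(x$mtd), "none", x$mtd), collapse = ", ")))
  invisible(x)
}

#' Operating characteristics of a design under one scenario
#'
#' Aggregates [run_trial()] over independent per-trial seeds derived from
#' `base_seed` by a counter scheme (trial `i` uses `base_seed + i`, modulo
#' 2^31 - 1), so any single trial can be re-run in isolation. Trials with
#' no selected MTD in a row count as incorrect for that row's PCR.
#'
#' @param design A design object.
#' @param scenario A [tox_scenario()].
#' @param n_trials Number of simulated trials.
#' @param base_seed Integer base seed.
#' @return An object of class `dose_ocs`: percentages of correct
#'   recommendation per row (`pcr_by_row`, and their mean `avg_pcr`),
#'   proportions of correct allocation (`pca_by_row`, and their sum
#'   `overall_pca`), `mean_sample_size`, `early_stop_pct`, `reversal_pct`,
#'   and the partition `pct_zero` / `pct_one` / `pct_both` /
#'   `pct_at_least_one` of trials by how many true MTDs they recovered.
#' @export
simulate_ocs <- function(design, scenario, n_trials, base_seed = 1L) {
  stopifnot(n_trials >= 1L)
  results <- lapply(seq_len(n_trials), function(i) {
    run_trial(design, scenario, seed = .trial_seed(base_seed, i))
  })
  ocs_from_results(results, scenario)
}

#' Summarize a list of trial results into operating characteristics
#'
#' @param results List of `trial_result` objects from one design.
#' @param scenario The [tox_scenario()] they were simulated under.
#' @return A `dose_ocs` object (see [simulate_ocs()]).
#' @export
ocs_from_results <- function(results, scenario) {
  if (length(results) == 0L) stop("no trial results", call. = FALSE)
  true <- scenario$true_mtd
  m <- t(vapply(results, `[[`, integer(2), "mtd"))
  correct <- cbind(!is.na(m[, 1]) & m[, 1] == true[1],
                   !is.na(m[, 2]) & m[, 2] == true[2])
  nsel <- rowSums(correct)
  ntot <- vapply(results, `[[`, integer(1), "n")
  pca <- t(vapply(results, function(tr) {
    c(tr$alloc[1L, true[1]], tr$alloc[2L, true[2]]) / tr$n
  }, numeric(2)))
  rev <- vapply(results, function(tr) reversal(tr$mtd[1], tr$mtd[2]),
                logical(1))
  des <- results[[1]]$design
  if (des == "shift_crm") {
    early <- 100 * mean(vapply(results, `[[`, logical(1), "stopped_early"))
  } else {
    early <- 100 * colMeans(t(vapply(results, `[[`, logical(2),
                                     "stopped_by_row")))
  }
  structure(list(design = des, n_trials = length(results),
                 true_mtd = true,
                 pcr_by_row = 100 * colMeans(correct),
                 avg_pcr = mean(100 * colMeans(correct)),
                 pca_by_row = colMeans(pca),
                 overall_pca = sum(colMeans(pca)),
                 mean_sample_size = mean(ntot),
                 early_stop_pct = early,
                 reversal_pct = 100 * mean(rev),
                 pct_zero = 100 * mean(nsel == 0),
                 pct_one = 100 * mean(nsel == 1),
                 pct_both = 100 * mean(nsel == 2),
                 pct_at_least_one = 100 * mean(nsel >= 1)),
            class = "dose_ocs")
}

#' @export
print.dose_ocs <- function(x, ...) {
  cat(sprintf("<dose_ocs> %s over %d trials (true MTD %s)\n", x$design,
              x$n_trials, paste(x$true_mtd, collapse = ", ")))
  cat(sprintf("  PCR by row: %s%%  (avg %.2f%%)\n",
              paste(sprintf("%.1f", x$pcr_by_row), collapse = ", "),
              x$avg_pcr))
  cat(sprintf("  PCA by row: %s   (overall %.3f)\n",
              paste(sprintf("%.3f", x$pca_by_row), collapse = ", "),
              x$overall_pca))
  cat(sprintf("  mean n: %.1f   early stop: %s%%   reversal: %.1f%%\n",
              x$mean_sample_size,
              paste(sprintf("%.1f", x$early_stop_pct), collapse = ", "),
              x$reversal_pct))
  cat(sprintf("  MTDs correct: zero %.1f%% / one %.1f%% / both %.1f%% (at least one %.1f%%)\n",
              x$pct_zero, x$pct_one, x$pct_both, x$pct_at_least_one))
  invisible(x)
}

#' Ensemble operating characteristics over many random curves
#'
#' Runs every design on every curve and collects, per design and curve,
#' the zero / at-least-one / both correct-selection percentages, the
#' reversal rate and the mean sample size, plus pooled means across
#' curves. Curve `c` of the ensemble uses trial seeds offset by
#' `100000 * c` from `base_seed`.
#'
#' @param designs Named list of design objects.
#' @param curves A [scenario_ensemble()] or list of `tox_scenario`s.
#' @param n_trials Trials per design per curve.
#' @param base_seed Integer base seed.
#' @return An object of class `curve_ensemble_summary` with elements
#'   `per_curve` (data frame) and `summary` (one row per design).
#' @export
aggregate_over_curves <- function(designs, curves, n_trials,
                                  base_seed = 1L) {
  if (length(curves) == 0L) stop("no curves supplied", call. = FALSE)
  if (is.null(names(designs)))
    names(designs) <- vapply(designs, `[[`, character(1), "design")
  rows <- list()
  for (ci in seq_along(curves)) {
    sc <- curves[[ci]]
    for (dn in names(designs)) {
      oc <- simulate_ocs(designs[[dn]], sc, n_trials,
                         base_seed = .trial_seed(base_seed, ci, 100000L))
      rows[[length(rows) + 1L]] <- data.frame(
        design = dn, curve = ci,
        pct_zero = oc$pct_zero, pct_at_least_one = oc$pct_at_least_one,
        pct_both = oc$pct_both, reversal_pct = oc$reversal_pct,
        mean_sample_size = oc$mean_sample_size,
        avg_pcr = oc$avg_pcr, overall_pca = oc$overall_pca)
    }
  }
  per_curve <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(per_curve, per_curve$design),
    function(d) data.frame(
      design = d$design[1], n_curves = nrow(d),
      pct_zero = mean(d$pct_zero),
      pct_at_least_one = mean(d$pct_at_least_one),
      pct_both = mean(d$pct_both),
      reversal_pct = mean(d$reversal_pct),
      mean_sample_size = mean(d$mean_sample_size))))
  rownames(summ) <- NULL
  structure(list(per_curve = per_curve, summary = summ,
                 n_trials = n_trials),
            class = "curve_ensemble_summary")
}

#' @export
print.curve_ensemble_summary <- function(x, ...) {
  cat(sprintf("<curve_ensemble_summary> %d curves x %d trials per design\n",
              max(x$per_curve$curve), x$n_trials))
  print(x$summary, digits = 4)
  invisible(x)
}

#' @export
plot.curve_ensemble_summary <- function(x, ...) {
  pc <- x$per_curve
  old <- graphics::par(mfrow = c(2, 2), mar = c(3, 4, 2, 1))
  on.exit(graphics::par(old))
  for (metric in c("pct_zero", "pct_at_least_one", "pct_both")) {
    graphics::boxplot(pc[[metric]] ~ pc$design, ylab = metric,
                      xlab = "", main = metric)
  }
  rev_means <- tapply(pc$reversal_pct, pc$design, mean)
  graphics::barplot(rev_means, ylab = "reversal %", main = "reversal_pct")
  invisible(x)
}

#' Write a machine- and human-readable comparison report
#'
#' Writes one tidy CSV row per (design, scenario, metric) and a short text
#' summary of the selection, allocation, sample-size, early-stop and
#' reversal behavior of each design.
#'
#' @param results Named list of `dose_ocs` objects (one per design), or a
#'   list of such lists (one per scenario, named).
#' @param dir Output directory (created if needed).
#' @return The tidy data frame, invisibly. Files `ocs.csv` and
#'   `summary.txt` are written under `dir`.
#' @export
compare_report <- function(results, dir) {
  if (length(results) == 0L) stop("no results to report", call. = FALSE)
  if (inherits(results[[1]], "dose_ocs")) results <- list(scenario = results)
  if (is.null(names(results)))
    names(results) <- paste0("scenario", seq_along(results))
  rows <- list()
  for (sn in names(results)) {
    for (oc in results[[sn]]) {
      stopifnot(inherits(oc, "dose_ocs"))
      vals <- c(pcr_row1 = unname(oc$pcr_by_row[1]),
                pcr_row2 = unname(oc$pcr_by_row[2]),
                avg_pcr = oc$avg_pcr,
                pca_row1 = unname(oc$pca_by_row[1]),
                pca_row2 = unname(oc$pca_by_row[2]),
                overall_pca = oc$overall_pca,
                mean_sample_size = oc$mean_sample_size,
                reversal_pct = oc$reversal_pct,
                pct_zero = oc$pct_zero, pct_one = oc$pct_one,
                pct_both = oc$pct_both,
                pct_at_least_one = oc$pct_at_least_one,
                early_stop_pct = mean(oc$early_stop_pct))
      rows[[length(rows) + 1L]] <- data.frame(
        design = oc$design, scenario = sn,
        metric = names(vals), value = unname(vals))
    }
  }
  out <- do.call(rbind, rows)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write.csv(out, file.path(dir, "ocs.csv"), row.names = FALSE, quote = FALSE)
  txt <- file.path(dir, "summary.txt")
  con <- file(txt, "w"); on.exit(close(con))
  for (sn in names(results)) {
    writeLines(sprintf("== %s ==", sn), con)
    for (oc in results[[sn]]) {
      writeLines(utils::capture.output(print(oc)), con)
    }
  }
  invisible(out)
}
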