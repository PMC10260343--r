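#' True MTD of one row of a dose-toxicity curve
#'
#' The MTD is the level whose true DLT probability is closest to the target
#' rate; when two levels are equidistant the lower (safer) level is taken.
#'
#' @param probs Nondecreasing vector of DLT probabilities.
#' @param target Target DLT rate.
#' @return Integer level index.
#' @examples
#' true_mtd_row(c(0.01, 0.12, 0.18, 0.21, 0.22, 0.31, 0.60), 0.30)
#' @export
true_mtd_row <- function(probs, target) {
  if (length(probs) < 1L) stop("`probs` must be non-empty", call. = FALSE)
  which.min(abs(probs - target))
}

#' Construct and validate a dose-toxicity scenario
#'
#' A scenario holds the true DLT probability matrix over the 2 x L grid and
#' the derived true MTD per row. Validation enforces the ordering
#' assumptions the designs rely on: probabilities nondecreasing in dose
#' level within each row, row 2 at least as toxic as row 1 at every level
#' (the second agent can only add toxicity), and the two rows' MTDs no more
#' than `max_shift` levels apart.
#'
#' @param probs Numeric matrix (2 x L, or `n_rows` x L) of true DLT
#'   probabilities in `[0, 1)`.
#' @param target Target DLT rate defining the MTD (default 0.30).
#' @param max_shift Largest allowed difference between the rows' MTD levels.
#' @return An object of class `tox_scenario` with fields `probs`, `target`,
#'   and `true_mtd` (one level per row).
#' @examples
#' tox_scenario(rbind(c(0.05, 0.15, 0.30, 0.45),
#'                    c(0.10, 0.30, 0.45, 0.60)), target = 0.30)
#' @export
tox_scenario <- function(probs, target = 0.30, max_shift = 1L) {
  probs <- as.matrix(probs)
  if (nrow(probs) < 2L || ncol(probs) < 2L)
    stop("`probs` must be a matrix with >= 2 rows and >= 2 levels",
         call. = FALSE)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs >= 1))
    stop("probabilities must lie in [0, 1)", call. = FALSE)
  if (target <= 0 || target >= 1)
    stop("`target` must be in (0, 1)", call. = FALSE)
  for (r in seq_len(nrow(probs)))
    if (any(diff(probs[r, ]) < 0))
      stop(sprintf("row %d is not nondecreasing in dose level", r),
           call. = FALSE)
  for (r in seq_len(nrow(probs) - 1L))
    if (any(probs[r + 1L, ] < probs[r, ]))
      stop(sprintf(paste0("column ordering violated: row %d is less toxic ",
                          "than row %d at some level"), r + 1L, r),
           call. = FALSE)
  mtd <- vapply(seq_len(nrow(probs)),
                function(r) true_mtd_row(probs[r, ], target), integer(1))
  if (any(abs(diff(mtd)) > max_shift))
    stop(sprintf("true MTDs %s are more than %d level(s) apart",
                 paste(mtd, collapse = ", "), max_shift), call. = FALSE)
  structure(list(probs = unname(probs), target = target,
                 true_mtd = mtd, max_shift = as.integer(max_shift)),
            class = "tox_scenario")
}

#' Re-validate a scenario against a shift constraint
#'
#' @param scenario A `tox_scenario` or probability matrix.
#' @param max_shift Largest allowed MTD offset between adjacent rows.
#' @param target Target DLT rate (taken from the scenario when present).
#' @return The validated `tox_scenario` with `true_mtd` filled.
#' @export
validate_scenario <- function(scenario, max_shift = 1L, target = NULL) {
  if (inherits(scenario, "tox_scenario")) {
    tox_scenario(scenario$probs,
                 target = if (is.null(target)) scenario$target else target,
                 max_shift = max_shift)
  } else {
    tox_scenario(scenario, target = if (is.null(target)) 0.30 else target,
                 max_shift = max_shift)
  }
}

#' @export
print.tox_scenario <- function(x, digits = 3, ...) {
  cat(sprintf("<tox_scenario> %d x %d, target %.2f, true MTD (%s)\n",
              nrow(x$probs), ncol(x$probs), x$target,
              paste(x$true_mtd, collapse = ", ")))
  print(round(x$probs, digits))
  invisible(x)
}

#' The worked-example dose-toxicity scenario
#'
#' The 2 x 7 set of true DLT probabilities used to illustrate the shift
#' design: row 1 (agent alone) has its MTD at level 6 and row 2 (with the
#' second agent) at level 5, a one-level shift.
#'
#' @return A `tox_scenario` with target 0.30 and `true_mtd = c(6, 5)`.
#' @examples
#' illustration_scenario()
#' @export
illustration_scenario <- function() {
  tox_scenario(rbind(c(0.01, 0.12, 0.18, 0.21, 0.22, 0.31, 0.60),
                     c(0.09, 0.14, 0.22, 0.25, 0.32, 0.40, 0.64)),
               target = 0.30, max_shift = 1L)
}

#' Randomly generate a constrained dose-toxicity curve
#'
#' Emulates the kind of random curve ensemble used to stress dose-finding
#' designs. The row-1 MTD position is uniform over the levels and the row-2
#' offset uniform over the allowed shifts (clipped so the row-2 MTD stays
#' at level 1 or above); both are drawn once per curve, so intended MTD
#' locations stay uniform. A single extended monotone base curve of length
#' `n_levels + 1` is built with its anchor probability near the target and
#' the remaining levels filled by cumulative positive increments whose
#' sizes vary (moderate near the MTD, heavy-tailed farther away, so both
#' steep and flat stretches occur). Row 1 is the base curve; row 2 is the
#' base curve displaced by the intended shift plus small level-wise jitter,
#' mirroring how closely the two strategies' curves track each other when
#' the second agent adds a roughly constant toxicity increment. Base and
#' jitter are redrawn until the scenario passes [validate_scenario()] and
#' the closest-to-target level in each row equals the intended MTD.
#'
#' @param n_levels Levels per row (default 7).
#' @param target Target DLT rate (default 0.30).
#' @param shifts Allowed row-2 minus row-1 MTD offsets (default `c(0, -1)`).
#' @param mtd_halfwidth Half-range of the uniform draw for the MTD
#'   probability around `target` (default 0.05).
#' @param near_gap Mean probability increment for the two steps adjacent to
#'   a row's MTD (gamma-distributed, shape 2; default 0.08).
#' @param far_gap Median increment farther from the MTD, drawn from a
#'   heavy-tailed lognormal (sdlog 1.2): most steps are small, so long flat
#'   stretches occur, with occasional large jumps giving steep curves
#'   (default 0.05).
#' @param row2_jitter Standard deviation of the level-wise displacement of
#'   row 2 around the shifted base curve (default 0.03).
#' @param max_tries Rejection budget before failing (default 10000).
#' @return A `tox_scenario`.
#' @examples
#' set.seed(1)
#' random_scenario()
#' @export
random_scenario <- function(n_levels = 7L, target = 0.30, shifts = c(0L, -1L),
                            mtd_halfwidth = 0.05, near_gap = 0.08,
                            far_gap = 0.05, row2_jitter = 0.03,
                            max_tries = 10000L) {
  n_levels <- as.integer(n_levels)
  shifts <- as.integer(shifts)
  if (any(shifts > 0L)) stop("shifts must be <= 0", call. = FALSE)
  max_shift <- max(abs(shifts), 1L)
  # the intended MTD location and shift are drawn once, so they stay
  # uniform over the allowed set; only the curves are rejection-sampled
  m1 <- sample.int(n_levels, 1L)
  s <- sample(shifts, 1L)
  if (m1 + s < 1L) s <- 0L
  m2 <- m1 + s
  for (try in seq_len(max_tries)) {
    base <- .fill_curve(n_levels + 1L, m1, target, mtd_halfwidth, near_gap,
                        far_gap)
    row1 <- base[seq_len(n_levels)]
    shifted <- base[seq_len(n_levels) - s]  # s = 0 or negative
    row2 <- shifted + rnorm(n_levels, 0, row2_jitter)
    row2 <- pmin(pmax(pmax(row2, row1), 1e-4), 0.97)
    if (any(diff(row2) < 0)) next
    if (true_mtd_row(row1, target) != m1) next
    if (true_mtd_row(row2, target) != m2) next
    sc <- tryCatch(tox_scenario(rbind(row1, row2), target = target,
                                max_shift = max_shift),
                   error = function(e) NULL)
    if (!is.null(sc)) return(sc)
  }
  stop("random_scenario: rejection budget exhausted", call. = FALSE)
}

# One monotone curve with the level closest to the target pinned near it.
.fill_curve <- function(n_levels, mtd, target, mtd_halfwidth, near_gap,
                        far_gap) {
  p <- numeric(n_levels)
  p[mtd] <- runif(1, target - mtd_halfwidth, target + mtd_halfwidth)
  gap <- function(dist) {
    if (dist <= 1L) rgamma(1, shape = 2, scale = near_gap / 2)
    else far_gap * exp(rnorm(1, 0, 1.2))
  }
  if (mtd < n_levels)
    for (j in (mtd + 1L):n_levels)
      p[j] <- p[j - 1L] + gap(j - mtd)
  if (mtd > 1L)
    for (j in (mtd - 1L):1L)
      p[j] <- p[j + 1L] - gap(mtd - j)
  pmin(pmax(p, 1e-4), 0.97)
}

#' Generate an ensemble of random constrained curves
#'
#' @param n_curves Number of curves (the reported ensembles use 50).
#' @param seed Integer seed; curves are drawn sequentially after one
#'   `set.seed(seed)`, so the ensemble is reproducible as a whole.
#' @param ... Passed to [random_scenario()].
#' @return A list of `tox_scenario` objects, class `scenario_ensemble`.
#' @export
scenario_ensemble <- function(n_curves = 50L, seed = 1L, ...) {
  curves <- with_local_seed(seed, {
    lapply(seq_len(n_curves), function(i) random_scenario(...))
  })
  structure(curves, class = "scenario_ensemble")
}

#' @export
print.scenario_ensemble <- function(x, ...) {
  cat(sprintf("<scenario_ensemble> %d curves; true MTDs:\n", length(x)))
  m <- t(vapply(x, function(s) s$true_mtd, integer(2)))
  colnames(m) <- c("row1", "row2")
  print(table(row1 = m[, 1], row2 = m[, 2]))
  invisible(x)
}

#' Read / write scenario CSV files
#'
#' Scenario files are plain CSV with header `row,level,prob`, one record per
#' grid cell, 1-based indices; the grid shape is inferred.
#'
#' @param path File path.
#' @param target,max_shift Passed to [tox_scenario()] when reading.
#' @return `read_scenario_csv()` returns a `tox_scenario`;
#'   `write_scenario_csv()` returns `path` invisibly.
#' @export
read_scenario_csv <- function(path, target = 0.30, max_shift = 1L) {
  d <- read.csv(path)
  if (!all(c("row", "level", "prob") %in% names(d)))
    stop("scenario CSV needs columns row, level, prob", call. = FALSE)
  nr <- max(d$row); nl <- max(d$level)
  if (nrow(d) != nr * nl || anyDuplicated(d[c("row", "level")]))
    stop("scenario CSV must contain each grid cell exactly once",
         call. = FALSE)
  m <- matrix(NA_real_, nr, nl)
  m[cbind(d$row, d$level)] <- d$prob
  tox_scenario(m, target = target, max_shift = max_shift)
}

#' @rdname read_scenario_csv
#' @param scenario A `tox_scenario` to write.
#' @export
write_scenario_csv <- function(scenario, path) {
  stopifnot(inherits(scenario, "tox_scenario"))
  p <- scenario$probs
  d <- data.frame(row = rep(seq_len(nrow(p)), each = ncol(p)),
                  level = rep(seq_len(ncol(p)), nrow(p)),
                  prob = as.vector(t(p)))
  write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
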