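#' Calibrate a CRM skeleton by the indifference-interval recursion
#'
#' Generates the vector of prior DLT probability guesses ("skeleton") for the
#' one-parameter empiric (power) model `p = q^exp(a)` using the
#' indifference-interval recursion of Lee and Cheung. The skeleton is
#' anchored at the prior MTD, `q[prior_mtd] = target`, and spaced so that
#' adjacent doses sit just outside an indifference interval
#' `target +/- halfwidth`: moving up from the anchor, `q[k+1]` solves
#' `q[k+1]^a* = target + halfwidth` where `a*` solves
#' `q[k]^a* = target - halfwidth`; moving down the roles of
#' `target + halfwidth` and `target - halfwidth` are exchanged.
#'
#' @param target Target DLT probability (theta), in (0, 1).
#' @param halfwidth Indifference-interval halfwidth (delta), in
#'   `[0, min(target, 1 - target))`. `halfwidth = 0` collapses every entry
#'   to `target`.
#' @param prior_mtd Index of the prior guess of the MTD (nu).
#' @param n_levels Length of the skeleton.
#' @return Numeric vector of length `n_levels`, strictly increasing when
#'   `halfwidth > 0`, with element `prior_mtd` equal to `target`.
#' @examples
#' lee_cheung_skeleton(0.30, 0.05, 4, 8)
#' @export
lee_cheung_skeleton <- function(target, halfwidth, prior_mtd, n_levels) {
  if (!is.numeric(target) || length(target) != 1L || target <= 0 || target >= 1)
    stop("`target` must be a probability in (0, 1)", call. = FALSE)
  if (!is.numeric(halfwidth) || length(halfwidth) != 1L || halfwidth < 0 ||
      halfwidth >= min(target, 1 - target))
    stop("`halfwidth` must lie in [0, min(target, 1 - target))",
         call. = FALSE)
  n_levels <- as.integer(n_levels); prior_mtd <- as.integer(prior_mtd)
  if (n_levels < 1L || prior_mtd < 1L || prior_mtd > n_levels)
    stop("`prior_mtd` must index into 1..n_levels", call. = FALSE)

  q <- numeric(n_levels)
  q[prior_mtd] <- target
  up <- target + halfwidth; lo <- target - halfwidth
  if (prior_mtd < n_levels) {
    for (k in prior_mtd:(n_levels - 1L)) {
      # a* with q[k]^a* = lo; then q[k+1] = up^(1/a*)
      q[k + 1L] <- exp(log(up) * log(q[k]) / log(lo))
    }
  }
  if (prior_mtd > 1L) {
    for (k in prior_mtd:2L) {
      q[k - 1L] <- exp(log(lo) * log(q[k]) / log(up))
    }
  }
  if (any(!is.finite(q)) || any(q <= 0) || any(q >= 1))
    stop("skeleton calibration failed: recursion left (0, 1)", call. = FALSE)
  q
}

#' Build shift-structured working models from a common base skeleton
#'
#' Each working model encodes one hypothesized offset (shift) between the
#' MTD of row 2 (with the second agent) and row 1 (agent alone). All models
#' share a single strictly increasing base skeleton: row 1 always takes
#' `base[1..n_levels]`; for shift `s <= 0`, row 2 takes
#' `base[(1 - s)..(n_levels - s)]`, i.e. its values are pushed `|s|`
#' positions up the base vector, placing its prior MTD `|s|` levels lower.
#'
#' @param base Strictly increasing vector of probabilities in (0, 1), of
#'   length at least `n_levels + max(abs(shifts))`.
#' @param shifts Integer vector of non-positive shifts (e.g. `c(0, -1)`).
#' @param n_levels Number of dose levels per row.
#' @return A list of `working_model` objects, one per shift, each with
#'   fields `shift` and `skeleton` (a 2 x `n_levels` matrix).
#' @examples
#' base <- lee_cheung_skeleton(0.30, 0.05, 4, 8)
#' mods <- shift_working_models(base, c(0, -1), 7)
#' mods[[2]]$skeleton
#' @export
shift_working_models <- function(base, shifts = c(0L, -1L), n_levels) {
  if (any(diff(base) <= 0) || any(base <= 0) || any(base >= 1))
    stop("`base` must be strictly increasing within (0, 1)", call. = FALSE)
  shifts <- as.integer(shifts)
  if (any(shifts > 0L)) stop("shifts must be <= 0", call. = FALSE)
  n_levels <- as.integer(n_levels)
  need <- n_levels + max(abs(shifts))
  if (length(base) < need)
    stop(sprintf("`base` must have length >= %d for the requested shifts",
                 need), call. = FALSE)
  lapply(shifts, function(s) {
    skel <- rbind(base[seq_len(n_levels)],
                  base[seq.int(1L - s, n_levels - s)])
    rownames(skel) <- c("row1", "row2")
    structure(list(shift = s, skeleton = skel), class = "working_model")
  })
}

#' @export
print.working_model <- function(x, digits = 3, ...) {
  cat(sprintf("<working_model> shift = %d\n", x$shift))
  print(round(x$skeleton, digits))
  invisible(x)
}
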