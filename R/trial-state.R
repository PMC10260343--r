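#' Accumulated trial data
#'
#' Holds the ordered per-patient records of a running (or finished) trial on
#' a dose grid, together with the conduct stage. The stage is `"modeling"`
#' exactly when the data are heterogeneous -- at least one DLT and one
#' non-DLT -- which is when the one-parameter power model has a maximum
#' likelihood estimate; before that the trial is in its `"initial"`
#' escalation stage.
#'
#' @param records Data frame with columns `patient`, `row`, `level`, `dlt`
#'   (1-based indices, `dlt` in 0/1), or `NULL` for an empty state.
#' @param grid A [dose_grid()].
#' @return An object of class `trial_state` with fields `records`, `grid`,
#'   and `stage`.
#' @examples
#' st <- trial_state(data.frame(patient = 1:2, row = 1, level = 1:2,
#'                              dlt = c(0, 1)), dose_grid(7))
#' st$stage
#' @export
trial_state <- function(records = NULL, grid = dose_grid()) {
  stopifnot(inherits(grid, "dose_grid"))
  if (is.null(records) || nrow(records) == 0L) {
    records <- data.frame(patient = integer(), row = integer(),
                          level = integer(), dlt = integer())
  } else {
    need <- c("patient", "row", "level", "dlt")
    if (!all(need %in% names(records)))
      stop("records need columns patient, row, level, dlt", call. = FALSE)
    records <- records[order(records$patient), need]
    if (anyDuplicated(records$patient))
      stop("duplicate patient index in trial records", call. = FALSE)
    if (!identical(as.integer(records$patient), seq_len(nrow(records))))
      stop("patient indices must be consecutive from 1", call. = FALSE)
    if (any(records$row < 1L | records$row > grid$n_rows |
            records$level < 1L | records$level > grid$n_levels))
      stop("combination outside the dose grid", call. = FALSE)
    if (!all(records$dlt %in% c(0L, 1L)))
      stop("`dlt` must be 0 or 1", call. = FALSE)
    records$patient <- as.integer(records$patient)
    records$row <- as.integer(records$row)
    records$level <- as.integer(records$level)
    records$dlt <- as.integer(records$dlt)
  }
  structure(list(records = records, grid = grid,
                 stage = .stage_of(records$dlt)),
            class = "trial_state")
}

.stage_of <- function(dlt) {
  if (length(dlt) > 0L && any(dlt == 1L) && any(dlt == 0L)) "modeling"
  else "initial"
}

#' Append one patient record to a trial state
#'
#' @param state A `trial_state`.
#' @param row,level Assigned combination (1-based).
#' @param dlt Observed DLT indicator (0/1).
#' @return The updated `trial_state`.
#' @export
add_record <- function(state, row, level, dlt) {
  stopifnot(inherits(state, "trial_state"))
  rec <- rbind(state$records,
               data.frame(patient = nrow(state$records) + 1L,
                          row = as.integer(row), level = as.integer(level),
                          dlt = as.integer(dlt)))
  trial_state(rec, state$grid)
}

#' @export
print.trial_state <- function(x, ...) {
  n <- nrow(x$records)
  cat(sprintf("<trial_state> %d patient(s), %d DLT, stage: %s\n",
              n, sum(x$records$dlt), x$stage))
  if (n > 0) print(utils::tail(x$records, 5L))
  invisible(x)
}

# per-cell (n treated, x DLT) count matrices
.cell_counts <- function(state) {
  g <- state$grid
  n <- x <- matrix(0L, g$n_rows, g$n_levels)
  r <- state$records
  if (nrow(r) > 0L) {
    for (i in seq_len(nrow(r))) {
      n[r$row[i], r$level[i]] <- n[r$row[i], r$level[i]] + 1L
      x[r$row[i], r$level[i]] <- x[r$row[i], r$level[i]] + r$dlt[i]
    }
  }
  list(n = n, x = x)
}
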