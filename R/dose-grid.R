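#' Define a two-row dose grid
#'
#' A dose grid crosses the dose levels of the primary agent (columns) with
#' the treatment strategy (rows). Row 1 is always the less-toxic strategy
#' (the agent alone); row 2 adds the second agent, which can only increase
#' the DLT probability at a fixed dose of the primary agent.
#'
#' @param n_levels Number of dose levels of the primary agent per row.
#' @param n_rows Number of treatment rows (the designs here use 2).
#' @param row_labels Optional character labels, least-toxic row first.
#' @param dose_labels Optional character labels for the dose levels.
#' @return An object of class `dose_grid`.
#' @examples
#' dose_grid(7, dose_labels = c("60 mg", "120 mg", "240 mg", "480 mg",
#'                              "800 mg", "1200 mg", "1800 mg"))
#' @export
dose_grid <- function(n_levels = 7, n_rows = 2, row_labels = NULL,
                      dose_labels = NULL) {
  if (!is.numeric(n_rows) || n_rows < 2)
    stop("`n_rows` must be at least 2", call. = FALSE)
  if (!is.numeric(n_levels) || n_levels < 2)
    stop("`n_levels` must be at least 2", call. = FALSE)
  n_rows <- as.integer(n_rows); n_levels <- as.integer(n_levels)
  if (is.null(row_labels))
    row_labels <- c("monotherapy", paste("combination", seq_len(n_rows - 1L)))
  if (is.null(dose_labels))
    dose_labels <- paste("level", seq_len(n_levels))
  if (length(row_labels) != n_rows || length(dose_labels) != n_levels)
    stop("label lengths must match the grid dimensions", call. = FALSE)
  structure(list(n_rows = n_rows, n_levels = n_levels,
                 row_labels = as.character(row_labels),
                 dose_labels = as.character(dose_labels)),
            class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf("<dose_grid> %d rows x %d levels\n", x$n_rows, x$n_levels))
  for (r in seq_len(x$n_rows))
    cat(sprintf("  row %d (%s): %s\n", r, x$row_labels[r],
                paste(x$dose_labels, collapse = ", ")))
  invisible(x)
}

#' A single (row, level) combination on a dose grid
#'
#' @param row Row index (1-based; row 1 is the less-toxic strategy).
#' @param level Dose-level index (1-based).
#' @param grid Optional `dose_grid` used to bound-check the indices.
#' @return An object of class `combination`: a list with `row` and `level`.
#' @export
combination <- function(row, level, grid = NULL) {
  row <- as.integer(row); level <- as.integer(level)
  if (length(row) != 1L || length(level) != 1L || is.na(row) || is.na(level) ||
      row < 1L || level < 1L)
    stop("`row` and `level` must be positive scalar indices", call. = FALSE)
  if (!is.null(grid)) {
    stopifnot(inherits(grid, "dose_grid"))
    if (row > grid$n_rows || level > grid$n_levels)
      stop("combination outside the dose grid", call. = FALSE)
  }
  structure(list(row = row, level = level), class = "combination")
}

#' @export
print.combination <- function(x, ...) {
  cat(sprintf("<combination> row %d, level %d\n", x$row, x$level))
  invisible(x)
}
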