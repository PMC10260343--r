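#' 3+3 decision after a completed cohort
#'
#' Classic rules at the current level: 0/3 DLT escalates; 1/3 expands to a
#' second cohort of three at the same level; at most 1/6 escalates; two or
#' more DLTs (out of 3 or 6) stop the row.
#'
#' @param rs A [row_state()] whose current level holds a completed cohort
#'   (3 or 6 patients).
#' @return One of `"escalate"`, `"expand"`, `"stop"`.
#' @export
three_plus_three_next <- function(rs) {
  cur <- rs$current
  n <- rs$n[cur]; x <- rs$x[cur]
  if (!n %in% c(3L, 6L))
    stop("current level must hold a completed cohort of 3 or 6",
         call. = FALSE)
  if (x >= 2L) "stop"
  else if (n == 3L && x == 1L) "expand"
  else "escalate"
}

#' 3+3 MTD for a finished row
#'
#' When the row stopped after two or more DLTs at level `L`, the MTD is
#' `L - 1` (none if `L` is 1, a safety stop). Escalation past the top level
#' declares the top level the MTD.
#'
#' @param rs A finished [row_state()] with field `stop_level` (`NA` if the
#'   row escalated through the top level cleanly).
#' @return The MTD level or `NA`.
#' @export
three_plus_three_mtd <- function(rs) {
  K <- length(rs$n)
  if (is.null(rs$stop_level) || is.na(rs$stop_level)) return(K)
  if (rs$stop_level <= 1L) return(NA_integer_)
  rs$stop_level - 1L
}

#' Did the two rows' MTD selections reverse the toxicity order?
#'
#' A reversal: both rows selected an MTD and the more-toxic row (row 2,
#' with the second agent) received a strictly higher level than row 1.
#' Pairs with a missing selection in either row do not count.
#'
#' @param mtd_row1,mtd_row2 Selected levels (or `NA`).
#' @return Logical.
#' @examples
#' reversal(5, 6)  # TRUE
#' reversal(6, 5)  # FALSE
#' reversal(NA, 4) # FALSE
#' @export
reversal <- function(mtd_row1, mtd_row2) {
  !is.na(mtd_row1) && !is.na(mtd_row2) && mtd_row2 > mtd_row1
}
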