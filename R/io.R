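#' Load and validate a design configuration file
#'
#' Configurations are YAML or JSON with keys among `target`, `halfwidth`,
#' `prior_mtd`, `shifts`, `n_levels`, `n_rows`, `n_max`, `safety_conf`,
#' `safety_min_n`, `escalation_cap`. Missing keys take the package
#' defaults; unknown keys are rejected.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A named list of resolved settings, class `run_config`, suitable
#'   for `do.call(shift_crm_design, config[design_keys])`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  defaults <- list(target = 0.30, halfwidth = 0.05, prior_mtd = 4L,
                   shifts = c(0L, -1L), n_levels = 7L, n_rows = 2L,
                   n_max = 39L, safety_conf = 0.90, safety_min_n = 3L,
                   escalation_cap = FALSE)
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown) > 0L)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- utils::modifyList(defaults, raw)
  num1 <- function(key) {
    v <- cfg[[key]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop(sprintf("config key `%s` must be a single number", key),
           call. = FALSE)
    v
  }
  if (num1("target") <= 0 || cfg$target >= 1)
    stop("config: `target` must be in (0, 1)", call. = FALSE)
  if (num1("halfwidth") < 0 ||
      cfg$halfwidth >= min(cfg$target, 1 - cfg$target))
    stop("config: `halfwidth` out of range", call. = FALSE)
  if (!is.numeric(cfg$shifts) || any(cfg$shifts > 0))
    stop("config: `shifts` must be non-positive integers", call. = FALSE)
  for (key in c("prior_mtd", "n_levels", "n_rows", "n_max", "safety_min_n"))
    if (num1(key) < 1) stop(sprintf("config: `%s` must be positive", key),
                            call. = FALSE)
  cfg$shifts <- as.integer(cfg$shifts)
  for (key in c("prior_mtd", "n_levels", "n_rows", "n_max", "safety_min_n"))
    cfg[[key]] <- as.integer(cfg[[key]])
  cfg$escalation_cap <- isTRUE(cfg$escalation_cap)
  structure(cfg, class = "run_config")
}

#' Read patient-level trial data from CSV
#'
#' The file needs a header `patient,row,level,dlt` with 1-based indices and
#' `dlt` in 0/1; the conduct stage is derived from the heterogeneity rule
#' (modeling once the data contain at least one DLT and one non-DLT).
#'
#' @param path CSV path.
#' @param grid A [dose_grid()] to validate against.
#' @return A [trial_state()].
#' @export
read_trial_csv <- function(path, grid = dose_grid()) {
  d <- read.csv(path)
  need <- c("patient", "row", "level", "dlt")
  if (!all(need %in% names(d)))
    stop("trial CSV needs columns patient, row, level, dlt", call. = FALSE)
  trial_state(d, grid)
}

#' @rdname read_trial_csv
#' @param state A `trial_state` to write.
#' @export
write_trial_csv <- function(state, path) {
  stopifnot(inherits(state, "trial_state"))
  write.csv(state$records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
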