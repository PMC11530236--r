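#' Study table schemas
#'
#' The pipeline consumes three tidy CSV tables, one row per rat
#' (`rats.csv`), per operant session (`sessions.csv`) and per bottle-brush
#' assay (`irritability.csv`).
#'
#' @section Columns:
#' * `rats.csv`: `rat_id`, `sex` (`F`/`M`), `cohort` (integer), `group`
#'   (`cocaine`/`naive`), `excluded` (0/1, catheter-patency failure).
#' * `sessions.csv`: `rat_id`, `phase` (`ShA`, `LgA`, `PreShock`, `Shock`,
#'   `PR`), `day_index` (1-based within phase, session order not calendar
#'   date), `duration_h`, `infusions`, `hour1_infusions`, `active_presses`,
#'   `inactive_presses`, `missing` (0/1, session failure).
#' * `irritability.csv`: `rat_id`, `timepoint` (`baseline`/`withdrawal`),
#'   `aggressive`, `defensive`, `total` (must equal aggressive + defensive).
#'
#' @name study-tables
NULL

.phases <- c("ShA", "LgA", "PreShock", "Shock", "PR")
.phase_days <- c(ShA = 10, LgA = 14, PreShock = 1, Shock = 1, PR = 3)
.phase_duration <- c(ShA = 2, LgA = 6, PreShock = 1, Shock = 1, PR = 6)

rats_cols <- function() {
  readr::cols(
    rat_id = readr::col_character(),
    sex = readr::col_character(),
    cohort = readr::col_integer(),
    group = readr::col_character(),
    excluded = readr::col_integer()
  )
}

sessions_cols <- function() {
  readr::cols(
    rat_id = readr::col_character(),
    phase = readr::col_character(),
    day_index = readr::col_integer(),
    duration_h = readr::col_double(),
    infusions = readr::col_integer(),
    hour1_infusions = readr::col_integer(),
    active_presses = readr::col_integer(),
    inactive_presses = readr::col_integer(),
    missing = readr::col_integer()
  )
}

irritability_cols <- function() {
  readr::cols(
    rat_id = readr::col_character(),
    timepoint = readr::col_character(),
    aggressive = readr::col_double(),
    defensive = readr::col_double(),
    total = readr::col_double()
  )
}

fail_rows <- function(bad, what) {
  if (any(bad)) {
    abort_addix(
      sprintf("%s (rows: %s)", what, paste(which(bad), collapse = ", ")),
      "addix_schema_error"
    )
  }
  invisible(NULL)
}

#' Validate the rat metadata table
#'
#' Checks uniqueness of `rat_id`, the sex/group factor levels, and that
#' cohort identifiers are positive integers.
#'
#' @param rats tibble with the `rats.csv` columns.
#' @return `rats`, invisibly, with `excluded` coerced to logical.
#' @export
validate_rats <- function(rats) {
  rats <- tibble::as_tibble(rats)
  fail_rows(is.na(rats$rat_id) | rats$rat_id == "", "missing rat_id")
  fail_rows(duplicated(rats$rat_id), "duplicate rat_id")
  fail_rows(!rats$sex %in% c("F", "M"), "sex must be F or M")
  fail_rows(!rats$group %in% c("cocaine", "naive"), "group must be cocaine or naive")
  fail_rows(is.na(rats$cohort) | rats$cohort < 1, "cohort must be a positive integer")
  rats$excluded <- as.logical(rats$excluded)
  invisible(rats)
}

#' Validate the session table
#'
#' Enforces the design invariants: known phase labels, day indices within
#' the phase's session count (10 ShA, 14 LgA, 3 PR, 1 pre-shock/shock), no
#' duplicate (rat, phase, day), `hour1_infusions <= infusions <=
#' active_presses`, and non-negative counts. Counts may be `NA` only on
#' rows flagged `missing`.
#'
#' @param sessions tibble with the `sessions.csv` columns.
#' @param rats optional validated rat table; if given, every `rat_id` must
#'   be present and naive rats must have no sessions.
#' @return `sessions`, invisibly, with `missing` coerced to logical.
#' @export
validate_sessions <- function(sessions, rats = NULL) {
  sessions <- tibble::as_tibble(sessions)
  sessions$missing <- as.logical(sessions$missing)
  fail_rows(!sessions$phase %in% .phases,
            sprintf("unknown phase label (expected %s)", paste(.phases, collapse = "/")))
  fail_rows(is.na(sessions$day_index) | sessions$day_index < 1 |
              sessions$day_index > .phase_days[sessions$phase],
            "day_index outside the phase's session count")
  key <- paste(sessions$rat_id, sessions$phase, sessions$day_index)
  dup <- key %in% key[duplicated(key)]
  fail_rows(dup & duplicated(key) | dup & !duplicated(key),
            "duplicate (rat_id, phase, day_index)")
  ok_dur <- abs(sessions$duration_h - .phase_duration[sessions$phase]) < 1e-9
  fail_rows(!ok_dur, "duration_h inconsistent with phase")
  present <- !sessions$missing
  cnt <- function(x) present & (is.na(x) | x < 0)
  fail_rows(cnt(sessions$infusions), "infusions missing or negative on a non-missing session")
  fail_rows(cnt(sessions$hour1_infusions), "hour1_infusions missing or negative")
  fail_rows(cnt(sessions$active_presses), "active_presses missing or negative")
  fail_rows(cnt(sessions$inactive_presses), "inactive_presses missing or negative")
  fail_rows(present & sessions$hour1_infusions > sessions$infusions,
            "hour1_infusions exceeds infusions")
  fail_rows(present & sessions$infusions > sessions$active_presses,
            "infusions exceed active_presses")
  if (!is.null(rats)) {
    fail_rows(!sessions$rat_id %in% rats$rat_id, "session rat_id absent from rat table")
    naive <- rats$rat_id[rats$group == "naive"]
    fail_rows(sessions$rat_id %in% naive, "naive rats cannot have self-administration sessions")
  }
  invisible(sessions)
}

#' Validate the irritability table
#'
#' @param irritability tibble with the `irritability.csv` columns.
#' @param rats optional validated rat table for referential checks.
#' @return `irritability`, invisibly.
#' @export
validate_irritability <- function(irritability, rats = NULL) {
  irritability <- tibble::as_tibble(irritability)
  fail_rows(!irritability$timepoint %in% c("baseline", "withdrawal"),
            "timepoint must be baseline or withdrawal")
  fail_rows(irritability$aggressive < 0 | irritability$defensive < 0,
            "negative irritability score")
  fail_rows(abs(irritability$total - (irritability$aggressive + irritability$defensive)) > 1e-9,
            "total must equal aggressive + defensive")
  key <- paste(irritability$rat_id, irritability$timepoint)
  dup <- key %in% key[duplicated(key)]
  fail_rows(dup, "duplicate (rat_id, timepoint)")
  if (!is.null(rats)) {
    fail_rows(!irritability$rat_id %in% rats$rat_id,
              "irritability rat_id absent from rat table")
  }
  invisible(irritability)
}

#' Read and validate the three study tables
#'
#' @param rats_csv,sessions_csv,irritability_csv file paths. `sessions_csv`
#'   and `irritability_csv` may be `NULL` when absent (e.g. metadata-only
#'   runs); validated empty tables are returned in their place.
#' @return list with validated tibbles `rats`, `sessions`, `irritability`.
#' @examples
#' dir <- tempfile(); dir.create(dir)
#' cohort <- simulate_cohort(generator_config(n_rats = 12, n_cohorts = 2), seed = 1)
#' write_study_tables(cohort, dir)
#' tabs <- read_study_tables(
#'   file.path(dir, "rats.csv"), file.path(dir, "sessions.csv"),
#'   file.path(dir, "irritability.csv")
#' )
#' nrow(tabs$rats)
#' @export
read_study_tables <- function(rats_csv, sessions_csv = NULL, irritability_csv = NULL) {
  rats <- validate_rats(readr::read_csv(rats_csv, col_types = rats_cols(),
                                        progress = FALSE))
  sessions <- if (is.null(sessions_csv)) empty_sessions() else {
    readr::read_csv(sessions_csv, col_types = sessions_cols(), progress = FALSE)
  }
  sessions <- validate_sessions(sessions, rats)
  irritability <- if (is.null(irritability_csv)) empty_irritability() else {
    readr::read_csv(irritability_csv, col_types = irritability_cols(), progress = FALSE)
  }
  irritability <- validate_irritability(irritability, rats)
  list(rats = rats, sessions = sessions, irritability = irritability)
}

empty_sessions <- function() {
  tibble::tibble(
    rat_id = character(), phase = character(), day_index = integer(),
    duration_h = double(), infusions = integer(), hour1_infusions = integer(),
    active_presses = integer(), inactive_presses = integer(), missing = logical()
  )
}

empty_irritability <- function() {
  tibble::tibble(
    rat_id = character(), timepoint = character(),
    aggressive = double(), defensive = double(), total = double()
  )
}

#' Write study tables (and simulation ground truth) to CSV
#'
#' @param tables list with elements `rats`, `sessions`, `irritability` and
#'   optionally `truth` (as returned by [simulate_cohort()]).
#' @param dir output directory, created if needed.
#' @return invisibly, the paths written.
#' @export
write_study_tables <- function(tables, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  out <- character()
  for (nm in intersect(c("rats", "sessions", "irritability", "truth"), names(tables))) {
    tab <- tables[[nm]]
    if (nm %in% c("rats", "sessions")) {
      # store logical flags as 0/1 per the documented schema
      flag <- if (nm == "rats") "excluded" else "missing"
      tab[[flag]] <- as.integer(tab[[flag]])
    }
    path <- file.path(dir, paste0(nm, ".csv"))
    readr::write_csv(tab, path, progress = FALSE)
    out <- c(out, path)
  }
  invisible(out)
}

#' Impute isolated missing sessions
#'
#' Session failures are rare (<2% in the motivating cohorts); an isolated
#' interior gap is filled with the arithmetic mean of the adjacent days.
#' Runs of two or more consecutive missing days and missing first/last days
#' have no defined rule: they are left `NA`, flagged unresolved, and a
#' warning is emitted so downstream summaries can exclude the rat.
#'
#' @param values numeric per-day values ordered by consecutive `day_index`.
#' @param missing logical vector marking gaps; defaults to `is.na(values)`.
#' @return list with `values` (gaps filled where possible), `imputed`
#'   (logical), and `unresolved` (logical).
#' @examples
#' impute_missing_sessions(c(10, NA, 20))$values  # 10 15 20
#' @export
impute_missing_sessions <- function(values, missing = is.na(values)) {
  stopifnot(length(missing) == length(values))
  n <- length(values)
  values[missing] <- NA_real_
  imputed <- logical(n)
  unresolved <- logical(n)
  for (i in seq_len(n)) {
    if (!missing[i]) next
    interior <- i > 1 && i < n
    isolated <- interior && !missing[i - 1] && !missing[i + 1]
    if (isolated) {
      values[i] <- (values[i - 1] + values[i + 1]) / 2
      imputed[i] <- TRUE
    } else {
      unresolved[i] <- TRUE
    }
  }
  if (any(unresolved)) {
    rlang::warn(sprintf(
      "%d missing day(s) not imputable (consecutive or terminal gap): positions %s",
      sum(unresolved), paste(which(unresolved), collapse = ", ")
    ), class = "addix_imputation_warning")
  }
  list(values = values, imputed = imputed, unresolved = unresolved)
}
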