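#' @title Trial-table schema
#' @description Column names and types of the trial-level data format.  One
#'   row is one completed trial; timed-out attempts appear only through the
#'   `timeout_redraws` count.  A trial whose ten redraw attempts all timed
#'   out is emitted with `timeout_redraws = 10` and `rt` equal to the
#'   response window; downstream stages drop such censored trials by
#'   default.
#' @details Header (comma-separated, UTF-8):
#'   `subject_id,group,session_index,session_role,effector,difficulty,stimulus,choice,correct,rt,timeout_redraws`.
#'   `difficulty` is the unsigned orientation offset in degrees; the sign of
#'   the tilt lives in `stimulus` (`CW`/`CCW`, or `neutral` exactly when
#'   `difficulty == 0`, in which case `correct` is undefined).  `rt` is in
#'   seconds and written with microsecond precision so that write/read
#'   round-trips are exact.
#' @name trial_schema
NULL

TRIAL_COLUMNS <- c(
  subject_id = "character", group = "character", session_index = "integer",
  session_role = "character", effector = "character", difficulty = "numeric",
  stimulus = "character", choice = "character", correct = "logical",
  rt = "numeric", timeout_redraws = "integer"
)

GROUP_LEVELS <- c("trained", "control")
ROLE_LEVELS <- c("training", "transfer", "effector_block")
EFFECTOR_LEVELS <- c("hand", "eye")
STIM_LEVELS <- c("CW", "CCW", "neutral")
CHOICE_LEVELS <- c("CW", "CCW")

trial_error <- function(row, column, what) {
  stop(sprintf("trial schema violation at row %s, column '%s': %s",
               paste(row, collapse = ","), column, what), call. = FALSE)
}

#' Validate a trial table
#'
#' Enforces the invariants of the trial schema: enum levels, positive
#' reaction times (optionally bounded by the response window), `neutral`
#' stimuli exactly at zero difficulty with undefined `correct`, and
#' `correct == (choice == stimulus)` elsewhere.
#'
#' @param trials Data frame in the [trial_schema] layout.
#' @param response_window Optional upper bound for `rt` in seconds.
#' @return The validated table, invisibly usable in a pipeline.
#' @export
validate_trials <- function(trials, response_window = NULL) {
  missing_cols <- setdiff(names(TRIAL_COLUMNS), names(trials))
  if (length(missing_cols))
    stop("missing required columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  extra <- setdiff(names(trials), names(TRIAL_COLUMNS))
  if (length(extra))
    stop("unknown columns: ", paste(extra, collapse = ", "), call. = FALSE)
  trials <- trials[, names(TRIAL_COLUMNS)]
  if (nrow(trials) == 0) return(trials)

  check_enum <- function(col, levels, allow_na = FALSE) {
    x <- trials[[col]]
    bad <- !(x %in% levels) & !(allow_na & is.na(x))
    if (any(bad)) trial_error(which(bad)[1], col,
      sprintf("'%s' not one of {%s}", x[which(bad)[1]],
              paste(levels, collapse = ", ")))
  }
  check_enum("group", GROUP_LEVELS)
  check_enum("session_role", ROLE_LEVELS)
  check_enum("effector", EFFECTOR_LEVELS)
  check_enum("stimulus", STIM_LEVELS)
  check_enum("choice", CHOICE_LEVELS)

  if (any(bad <- !is.finite(trials$rt) | trials$rt <= 0))
    trial_error(which(bad)[1], "rt", "must be a positive finite number")
  if (!is.null(response_window) && any(bad <- trials$rt > response_window))
    trial_error(which(bad)[1], "rt",
                sprintf("exceeds the %g s response window", response_window))
  if (any(bad <- !is.finite(trials$difficulty) | trials$difficulty < 0))
    trial_error(which(bad)[1], "difficulty", "must be >= 0")
  if (any(bad <- is.na(trials$session_index) | trials$session_index < 1))
    trial_error(which(bad)[1], "session_index", "must be an integer >= 1")
  if (any(bad <- is.na(trials$timeout_redraws) | trials$timeout_redraws < 0))
    trial_error(which(bad)[1], "timeout_redraws", "must be an integer >= 0")

  neutral <- trials$stimulus == "neutral"
  if (any(bad <- neutral & trials$difficulty != 0))
    trial_error(which(bad)[1], "stimulus",
                "neutral stimulus requires difficulty = 0")
  if (any(bad <- !neutral & trials$difficulty == 0))
    trial_error(which(bad)[1], "stimulus",
                "difficulty = 0 requires a neutral stimulus")
  if (any(bad <- neutral & !is.na(trials$correct)))
    trial_error(which(bad)[1], "correct",
                "must be undefined (NA) on neutral trials")
  expected <- trials$choice == trials$stimulus
  if (any(bad <- !neutral & (is.na(trials$correct) |
                             trials$correct != expected)))
    trial_error(which(bad)[1], "correct",
                "must equal (choice == stimulus) on non-neutral trials")
  trials
}

#' Read a trial table from delimited text
#'
#' @param path Path to a comma-separated trial file with the
#'   [trial_schema] header.
#' @param response_window Optional response window (s) to validate `rt`
#'   against.
#' @return Validated trial data frame, row order preserved.
#' @seealso [write_trials()]
#' @export
read_trials <- function(path, response_window = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  header <- names(read.csv(path, nrows = 0, check.names = FALSE))
  missing_cols <- setdiff(names(TRIAL_COLUMNS), header)
  extra <- setdiff(header, names(TRIAL_COLUMNS))
  if (length(missing_cols) || length(extra))
    stop("header mismatch; missing: {", paste(missing_cols, collapse = ", "),
         "}, unknown: {", paste(extra, collapse = ", "), "}", call. = FALSE)
  trials <- read.csv(path, colClasses = unname(TRIAL_COLUMNS[header]),
                     check.names = FALSE)
  validate_trials(trials, response_window = response_window)
}

#' Write a trial table to delimited text
#'
#' Writes the canonical comma-separated format.  `rt` is formatted with six
#' decimal places so that `read_trials(write_trials(x))` reproduces `x`
#' exactly and re-writing reproduces the file byte for byte.
#'
#' @param trials Valid trial table.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  trials <- validate_trials(trials)
  out <- trials
  if (nrow(out)) {
    out$rt <- sprintf("%.6f", out$rt)
    out$difficulty <- vapply(out$difficulty, format, "", digits = 15)
    out$correct <- ifelse(is.na(out$correct), "NA",
                          ifelse(out$correct, "TRUE", "FALSE"))
  }
  lines <- c(paste(names(TRIAL_COLUMNS), collapse = ","),
             if (nrow(out)) do.call(paste, c(unname(as.list(out)), sep = ",")))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}
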