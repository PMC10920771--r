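#' Parse a model-space string
#'
#' The model space is written as underscore-separated terms
#' `p(deps)` with `p` one of `v` (drift), `a` (boundary), `t`
#' (non-decision time), `z` (start-point bias) and `deps` one of `ses`,
#' `diff`, `ses*diff`, or `const`.  `v`, `a` and `t` are required; leaving
#' `z` out fixes the start point at 0.5 (the no-bias model).  Examples:
#' `"v(ses*diff)_a(ses)_t(ses)_z(ses)"` (full model) and
#' `"v(ses*diff)_a(ses)_t(ses)"` (no bias).
#'
#' @param text Model string.
#' @return Object of class `"ddm_model_spec"`: a named list mapping each
#'   parameter to its dependence set (`character(0)` for `const`,
#'   `"absent"` for an omitted `z`).
#' @export
parse_model_spec <- function(text) {
  if (inherits(text, "ddm_model_spec")) return(text)
  stopifnot(is.character(text), length(text) == 1)
  tokens <- strsplit(text, "_", fixed = TRUE)[[1]]
  pos <- cumsum(c(1, nchar(tokens) + 1))  # character offset of each token
  spec <- list()
  for (i in seq_along(tokens)) {
    tok <- tokens[i]
    m <- regmatches(tok, regexec("^([a-z])\\(([a-z*]+)\\)$", tok))[[1]]
    if (length(m) != 3)
      stop(sprintf("malformed model term '%s' at position %d", tok, pos[i]),
           call. = FALSE)
    par <- m[2]
    if (!par %in% c("v", "a", "t", "z"))
      stop(sprintf("unknown parameter letter '%s' at position %d (expected v, a, t or z)",
                   par, pos[i]), call. = FALSE)
    if (par %in% names(spec))
      stop(sprintf("duplicate parameter '%s' at position %d", par, pos[i]),
           call. = FALSE)
    deps <- m[3]
    known <- c("ses", "diff", "ses*diff", "diff*ses", "const")
    if (!deps %in% known)
      stop(sprintf("unknown dependence '%s' at position %d (expected ses, diff, ses*diff or const)",
                   deps, pos[i] + 2L), call. = FALSE)
    spec[[par]] <- switch(deps,
      "ses" = "session",
      "diff" = "difficulty",
      "ses*diff" = , "diff*ses" = c("session", "difficulty"),
      "const" = character(0))
  }
  for (req in c("v", "a", "t"))
    if (!req %in% names(spec))
      stop(sprintf("model must specify parameter '%s'", req), call. = FALSE)
  if (!"z" %in% names(spec)) spec$z <- "absent"
  structure(spec[c("v", "a", "t", "z")], class = "ddm_model_spec")
}

#' @export
format.ddm_model_spec <- function(x, ...) {
  term <- function(par) {
    deps <- x[[par]]
    if (identical(deps, "absent")) return(NULL)
    lab <- if (length(deps) == 0) "const"
      else paste(c(session = "ses", difficulty = "diff")[deps], collapse = "*")
    sprintf("%s(%s)", par, lab)
  }
  paste(unlist(lapply(c("v", "a", "t", "z"), term)), collapse = "_")
}

#' @export
print.ddm_model_spec <- function(x, ...) {
  cat("DDM model space:", format(x), "\n")
  if (identical(x$z, "absent")) cat("  (start point fixed at 0.5)\n")
  invisible(x)
}

# factor cells for one parameter given session/difficulty levels;
# returns a data.frame(session, difficulty) with NA for unused factors
param_cells <- function(deps, sessions, difficulties) {
  if (identical(deps, "absent")) return(NULL)
  has_ses <- "session" %in% deps
  has_diff <- "difficulty" %in% deps
  if (has_diff && length(difficulties) < 2)
    stop("difficulty dependence requires >= 2 nonzero difficulty levels",
         call. = FALSE)
  expand.grid(
    difficulty = if (has_diff) difficulties else NA_real_,
    session = if (has_ses) sessions else NA_integer_
  )[, c("session", "difficulty")]
}

par_name <- function(par, level, session, difficulty, subject = NULL) {
  tag <- c(if (!is.na(session)) sprintf("s%s", session),
           if (!is.na(difficulty)) sprintf("d%g", difficulty))
  suffix <- switch(level, group_mean = "_mu", group_sd = "_sd", subject = "")
  inner <- paste(c(tag, if (!is.null(subject)) subject), collapse = ",")
  if (nzchar(inner)) sprintf("%s%s[%s]", par, suffix, inner)
  else sprintf("%s%s", par, suffix)
}

#' Enumerate the parameters implied by a model spec
#'
#' Expands a model spec over the factor levels of a design into the full
#' parameter table of the hierarchical model: one group-level mean per
#' factor cell, a matching group-level SD, and one subject-level value per
#' subject and cell.  With a single subject the hierarchy degenerates:
#' subject level collapses onto the group means and SDs are dropped.
#'
#' @param spec [parse_model_spec()] result or model string.
#' @param design [experiment_design()] (sessions = training sessions plus
#'   transfer if present; difficulties = nonzero levels).
#' @param n_subjects Number of subjects.
#' @return Data frame: `name`, `level` (`group_mean`/`group_sd`/`subject`),
#'   `param`, `session`, `difficulty`, `subject_id`.
#' @export
build_parameter_index <- function(spec, design, n_subjects) {
  spec <- parse_model_spec(spec)
  stopifnot(inherits(design, "experiment_design"), n_subjects >= 1)
  sessions <- seq_len(design$n_training_sessions +
                      as.integer(design$has_transfer))
  difficulties <- design$difficulties[design$difficulties > 0]
  subjects <- sprintf("S%02d", seq_len(n_subjects))
  parameter_index(spec, sessions, difficulties, subjects)
}

parameter_index <- function(spec, sessions, difficulties, subjects) {
  n_subjects <- length(subjects)
  blocks <- list()
  add <- function(level, par, cells, subject = NA_character_) {
    if (is.null(cells)) return()
    blocks[[length(blocks) + 1L]] <<- data.frame(
      name = vapply(seq_len(nrow(cells)), function(i)
        par_name(par, level, cells$session[i], cells$difficulty[i],
                 if (!is.na(subject)) subject), ""),
      level = level, param = par,
      session = cells$session, difficulty = cells$difficulty,
      subject_id = subject, stringsAsFactors = FALSE)
  }
  for (par in c("v", "a", "t", "z"))
    add("group_mean", par, param_cells(spec[[par]], sessions, difficulties))
  if (n_subjects > 1) {
    for (par in c("v", "a", "t", "z"))
      add("group_sd", par, param_cells(spec[[par]], sessions, difficulties))
    for (s in subjects)
      for (par in c("v", "a", "t", "z"))
        add("subject", par, param_cells(spec[[par]], sessions, difficulties),
            subject = s)
  }
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out
}
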