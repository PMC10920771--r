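#' Posterior probability that one sample set exceeds another
#'
#' Fraction of matched posterior draws with `a > b`; exact ties count
#' one half, so `prob_greater(a, b) + prob_greater(b, a) = 1`.
#'
#' @param samples_a,samples_b Numeric vectors of equal length with the
#'   same (chain, draw) indexing.
#' @return Probability in `[0, 1]`.
#' @export
prob_greater <- function(samples_a, samples_b) {
  if (length(samples_a) != length(samples_b))
    stop("sample vectors must have equal length (matched draws)", call. = FALSE)
  mean(samples_a > samples_b) + 0.5 * mean(samples_a == samples_b)
}

#' Define a condition contrast on a fitted parameter
#'
#' A contrast names a parameter and two condition cells, e.g. drift at the
#' last training session versus the transfer session.  When the parameter
#' varies by difficulty and no difficulty is given, downstream functions
#' evaluate the contrast at every difficulty level.
#'
#' @param param `"v"`, `"a"`, `"t"` or `"z"`.
#' @param session_a,session_b The two condition levels being contrasted
#'   (session indices, or 1 = hand / 2 = eye for effector-conditioned
#'   fits).
#' @param difficulty Optional difficulty level.
#' @return List of class `"ddm_contrast"`.
#' @export
ddm_contrast <- function(param, session_a, session_b, difficulty = NULL) {
  stopifnot(param %in% c("v", "a", "t", "z"))
  structure(list(param = param, session_a = session_a,
                 session_b = session_b, difficulty = difficulty),
            class = "ddm_contrast")
}

#' @export
format.ddm_contrast <- function(x, ...) {
  sprintf("%s(s%s) > %s(s%s)%s", x$param, x$session_a, x$param, x$session_b,
          if (is.null(x$difficulty)) "" else sprintf(" at %g deg", x$difficulty))
}

contrast_difficulties <- function(fit, contrast) {
  varies <- "difficulty" %in% fit$spec[[contrast$param]]
  if (!is.null(contrast$difficulty)) contrast$difficulty
  else if (varies) fit$levels$difficulties
  else NA_real_
}

check_contrastable <- function(fit, contrast) {
  deps <- fit$spec[[contrast$param]]
  if (identical(deps, "absent"))
    stop(sprintf("parameter '%s' is absent from model %s", contrast$param,
                 format(fit$spec)), call. = FALSE)
  if (!"session" %in% deps)
    stop(sprintf("parameter '%s' is constant across conditions in model %s; the contrast is undefined",
                 contrast$param, format(fit$spec)), call. = FALSE)
  invisible(TRUE)
}

fit_diff_samples <- function(fit, contrast, level, subject = NULL) {
  check_contrastable(fit, contrast)
  get <- function(ses, dif) {
    posterior_samples(fit, contrast$param, level = level, session = ses,
                      difficulty = if (is.na(dif)) NULL else dif,
                      subject = subject, transform = FALSE)
  }
  lapply_named <- function(difs, f) {
    out <- lapply(difs, f)
    names(out) <- ifelse(is.na(difs), "pooled", sprintf("%g", difs))
    out
  }
  lapply_named(contrast_difficulties(fit, contrast), function(dd)
    get(contrast$session_a, dd) - get(contrast$session_b, dd))
}

# deterministically thin the longer vector to the shorter one's length
match_length <- function(x, n) {
  if (length(x) == n) return(x)
  x[round(seq(1, length(x), length.out = n))]
}

#' Group-level condition contrast within one fit
#'
#' Posterior probability, over matched draws of the group-level means,
#' that the parameter is larger in one condition than another; one value
#' per difficulty when the parameter varies by difficulty.
#'
#' @param fit `ddm_fit`.
#' @param contrast [ddm_contrast()].
#' @return Named numeric vector of probabilities.
#' @export
group_prob <- function(fit, contrast) {
  diffs <- fit_diff_samples(fit, contrast, "group_mean")
  vapply(diffs, function(d) prob_greater(d, rep(0, length(d))), 0)
}

#' Between-group comparison of condition differences
#'
#' Computes, within each group's posterior, the group-level difference
#' `Delta = param(condition a) - param(condition b)`, then reports
#' `P(Delta_A > Delta_B)` across the two fits.  Draws are matched by index
#' within a fit (parameters are correlated across draws) and paired
#' independently across fits (thinned to a common length when the chains
#' differ in size).
#'
#' @param fit_A,fit_B `ddm_fit` objects whose model spaces both contain
#'   the contrast.
#' @param contrast [ddm_contrast()].
#' @return Named numeric vector of probabilities (per difficulty when the
#'   parameter varies by difficulty).
#' @export
group_diff_prob <- function(fit_A, fit_B, contrast) {
  dA <- fit_diff_samples(fit_A, contrast, "group_mean")
  dB <- fit_diff_samples(fit_B, contrast, "group_mean")
  if (!identical(names(dA), names(dB)))
    stop("the contrast resolves to different difficulty grids in the two fits",
         call. = FALSE)
  vapply(seq_along(dA), function(i) {
    n <- min(length(dA[[i]]), length(dB[[i]]))
    prob_greater(match_length(dA[[i]], n), match_length(dB[[i]], n))
  }, 0, USE.NAMES = FALSE) |> setNames(names(dA))
}

#' Subject-level contrast summary
#'
#' Evaluates the contrast on each subject's posterior draws and reports
#' the mean and SD of the per-subject probabilities (one row per
#' difficulty when the parameter varies by difficulty).  With a single
#' subject the SD is undefined and flagged.
#'
#' @param fit `ddm_fit` with subject-level samples.
#' @param contrast [ddm_contrast()].
#' @return Data frame: `difficulty`, `mean_p`, `sd_p`, `n_subjects`,
#'   `sd_undefined`.
#' @export
subject_level_summary <- function(fit, contrast) {
  check_contrastable(fit, contrast)
  subjects <- fit$levels$subjects
  if (!any(fit$param_table$level == "subject"))
    stop("fit has no subject-level samples (single-subject fits collapse onto the group level)",
         call. = FALSE)
  diffs <- contrast_difficulties(fit, contrast)
  rows <- lapply(diffs, function(dd) {
    ct_d <- ddm_contrast(contrast$param, contrast$session_a,
                         contrast$session_b,
                         difficulty = if (is.na(dd)) NULL else dd)
    p <- vapply(subjects, function(s) {
      d <- fit_diff_samples(fit, ct_d, "subject", subject = s)[[1]]
      prob_greater(d, rep(0, length(d)))
    }, 0)
    data.frame(difficulty = dd, mean_p = mean(p),
               sd_p = if (length(p) > 1) sd(p) else NA_real_,
               n_subjects = length(p), sd_undefined = length(p) < 2)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

report_contrast_block <- function(fit, param, session_a, session_b) {
  ct <- ddm_contrast(param, session_a, session_b)
  ok <- tryCatch({ check_contrastable(fit, ct); TRUE },
                 error = function(e) FALSE)
  if (!ok) return(list(contrast = format(ct), status = "not estimable"))
  subj <- subject_level_summary(fit, ct)
  list(contrast = format(ct), p_group = as.list(group_prob(fit, ct)),
       p_subj_mean = as.list(setNames(subj$mean_p,
                                      ifelse(is.na(subj$difficulty), "pooled",
                                             sprintf("%g", subj$difficulty)))),
       p_subj_sd = as.list(setNames(subj$sd_p,
                                    ifelse(is.na(subj$difficulty), "pooled",
                                           sprintf("%g", subj$difficulty)))))
}

#' Assemble the final analysis report
#'
#' Bundles the behavioral summary, DIC model comparison, convergence
#' diagnostics, and the four parameter contrast blocks (drift, boundary,
#' non-decision time, bias; last training vs first training and last
#' training vs transfer) into one machine-readable structure, optionally
#' written to disk as JSON plus a human-readable text summary.  Components
#' that were not computed are marked `"not run"`.
#'
#' @param fits Named list of `ddm_fit` objects; contrasts are computed on
#'   the first (best) fit.
#' @param behavior [behavioral_summary()] result.
#' @param diagnostics Optional named list of [diagnose()] results aligned
#'   with `fits` (DIC entries feed the model-comparison table).
#' @param out_dir Optional directory to write `results.json` and
#'   `summary.txt` into.
#' @return Report list (invisibly when written to disk).
#' @export
build_report <- function(fits, behavior, diagnostics = NULL, out_dir = NULL) {
  stopifnot(is.list(fits), length(fits) >= 1,
            all(vapply(fits, inherits, TRUE, "ddm_fit")))
  if (is.null(names(fits))) names(fits) <- sprintf("model_%d", seq_along(fits))

  si_block <- if (!is.null(behavior$si)) {
    ok <- behavior$si$si[!is.na(behavior$si$si)]
    list(median_si = median(ok), n_positive = sum(ok > 0),
         n_negative = sum(ok < 0), n_subjects = length(ok),
         sign_test_p = sign_test_onesided(sum(ok > 0), sum(ok < 0)))
  } else "not run"

  dic_block <- if (!is.null(diagnostics)) {
    tab <- do.call(rbind, lapply(names(diagnostics), function(nm) {
      d <- diagnostics[[nm]]$dic
      if (is.null(d)) return(NULL)
      data.frame(model = nm, dic = d$dic, mean_deviance = d$mean_deviance,
                 pd = d$pd, stringsAsFactors = FALSE)
    }))
    if (is.null(tab)) "not run" else tab[order(tab$dic), ]
  } else "not run"

  conv_block <- if (!is.null(diagnostics)) {
    lapply(diagnostics, function(d) list(
      max_psrf = max(d$gelman_rubin$psrf, na.rm = TRUE),
      frac_psrf_le_1.2 = mean(d$gelman_rubin$psrf <= 1.2, na.rm = TRUE),
      geweke_mean_frac_in_2 = mean(d$geweke$frac_in_2, na.rm = TRUE)))
  } else "not run"

  best <- fits[[1]]
  ses <- best$levels$sessions
  roles <- NULL
  contrasts <- if (length(ses) >= 2) {
    last_tr <- ses[length(ses) - 1]; first_tr <- ses[1]; transfer <- ses[length(ses)]
    lapply(setNames(nm = c("v", "a", "t", "z")), function(p) list(
      learning = report_contrast_block(best, p, last_tr, first_tr),
      transfer = report_contrast_block(best, p, last_tr, transfer)))
  } else "not run"

  report <- list(
    specificity = si_block,
    model_comparison = dic_block,
    convergence = conv_block,
    parameter_contrasts = contrasts,
    models = lapply(fits, function(f) format(f$spec))
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "results.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows", force = TRUE)
    txt <- c("Analysis report", "===============", "",
             if (is.list(si_block))
               sprintf("Median Specificity Index: %.3f (%d/%d subjects > 0; one-sided sign test p = %.3g)",
                       si_block$median_si, si_block$n_positive,
                       si_block$n_subjects, si_block$sign_test_p)
             else "Specificity: not run",
             "",
             if (is.data.frame(dic_block)) c("DIC (ascending):",
               sprintf("  %s: %.1f", dic_block$model, dic_block$dic))
             else "Model comparison: not run")
    writeLines(txt, file.path(out_dir, "summary.txt"))
    return(invisible(report))
  }
  report
}
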