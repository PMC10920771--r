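#' Sensitivity (d-prime) with the loglinear correction
#'
#' `d' = probit((hits + 0.5) / (n_signal + 1)) -
#' probit((fas + 0.5) / (n_noise + 1))`.  Adding 0.5 to each count and 1
#' to each total keeps the statistic finite at 0% and 100% rates.  By
#' convention clockwise stimuli are the signal class and clockwise
#' responses are hits.
#'
#' @param hits,misses,fas,crs Nonnegative trial counts (vectorized).
#' @return d-prime value(s), always finite.
#' @export
#' @examples
#' dprime_loglinear(15, 5, 5, 15)
dprime_loglinear <- function(hits, misses, fas, crs) {
  counts <- cbind(hits, misses, fas, crs)
  if (any(counts < 0)) stop("counts must be nonnegative", call. = FALSE)
  n_signal <- hits + misses
  n_noise <- fas + crs
  if (any(n_signal == 0) || any(n_noise == 0))
    stop("signal and noise totals must be nonzero", call. = FALSE)
  qnorm((hits + 0.5) / (n_signal + 1)) - qnorm((fas + 0.5) / (n_noise + 1))
}

#' Specificity Index
#'
#' `SI = (d'_last - d'_transfer) / (d'_last - d'_first)`: 0 means the
#' learning gain fully transferred to the new effector, 1 means it was
#' fully specific to the trained effector.  Values outside `[0, 1]`
#' (over-transfer / over-specificity) are permitted.
#'
#' @param d_first,d_last,d_transfer d-prime at the first training, last
#'   training, and transfer session (vectorized).
#' @return SI value(s); `NA` with a warning where the denominator is zero.
#' @export
specificity_index <- function(d_first, d_last, d_transfer) {
  denom <- d_last - d_first
  out <- (d_last - d_transfer) / denom
  if (any(zero <- denom == 0)) {
    warning(sum(zero), " subject(s) with d'_last == d'_first: SI undefined",
            call. = FALSE)
    out[zero] <- NA_real_
  }
  out
}

#' One-sided exact sign test
#'
#' Exact binomial upper tail `P(X >= n_positive | n, 1/2)` for the
#' hypothesis that positive outcomes are more likely than negative ones
#' (zeros are excluded before the call).
#'
#' @param n_positive,n_negative Nonnegative counts, summing to >= 1.
#' @return Exact p-value.
#' @export
#' @examples
#' sign_test_onesided(17, 2)  # 191/2^19
sign_test_onesided <- function(n_positive, n_negative) {
  if (n_positive < 0 || n_negative < 0)
    stop("counts must be nonnegative", call. = FALSE)
  n <- n_positive + n_negative
  if (n < 1) stop("need at least one nonzero difference", call. = FALSE)
  pbinom(n_positive - 1, n, 0.5, lower.tail = FALSE)
}

#' Paired t-test with Hedges' g
#'
#' Two-sided paired t-test on `d = x - y` with the difference-score
#' effect size `g = J * mean(d) / sd(d)`, where
#' `J = 1 - 3 / (4 df - 1)` is the small-sample bias correction.
#' Zero-variance differences give an infinite t and are flagged.
#'
#' @param x,y Paired per-subject values (equal length >= 2).
#' @return List: `t`, `df`, `p`, `g`, `mean_diff`, `degenerate`.
#' @export
ttest_paired <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  d <- x - y
  n <- length(d)
  df <- n - 1
  s <- sd(d)
  J <- 1 - 3 / (4 * df - 1)
  if (s == 0) {
    t <- if (mean(d) == 0) 0 else Inf * sign(mean(d))
    return(list(t = t, df = df, p = if (mean(d) == 0) 1 else 0,
                g = if (mean(d) == 0) 0 else Inf * sign(mean(d)),
                mean_diff = mean(d), degenerate = TRUE))
  }
  t <- mean(d) / (s / sqrt(n))
  list(t = t, df = df, p = 2 * pt(-abs(t), df), g = J * mean(d) / s,
       mean_diff = mean(d), degenerate = FALSE)
}

#' Two-way repeated-measures ANOVA with partial eta-squared
#'
#' Full within-subject decomposition of a complete, balanced
#' subject-by-factor1-by-factor2 table of cell means.  Each effect is
#' tested against its own subject-interaction error term;
#' `partial eta^2 = SS_effect / (SS_effect + SS_error_of_that_effect)`.
#'
#' @param data Long-format data frame of cell means.
#' @param value,subject,factor1,factor2 Column names.
#' @return Data frame (one row per effect: factor1, factor2, interaction)
#'   with `SS`, `df1`, `df2`, `F`, `p`, `pes`; the full sums-of-squares
#'   decomposition is attached as attribute `"ss"`.
#' @export
rm_anova2 <- function(data, value = "dprime", subject = "subject_id",
                      factor1 = "session_index", factor2 = "difficulty") {
  y <- data[[value]]
  s <- factor(data[[subject]])
  A <- factor(data[[factor1]])
  B <- factor(data[[factor2]])
  n <- nlevels(s); p <- nlevels(A); q <- nlevels(B)
  if (length(y) != n * p * q || anyNA(y) ||
      any(table(s, A, B) != 1))
    stop("rm_anova2 needs a complete balanced table of cell means (one row per subject x factor1 x factor2)",
         call. = FALSE)

  G <- mean(y)
  mA <- tapply(y, A, mean); mB <- tapply(y, B, mean); mS <- tapply(y, s, mean)
  mAB <- tapply(y, list(A, B), mean)
  mAS <- tapply(y, list(A, s), mean)
  mBS <- tapply(y, list(B, s), mean)

  ss_total <- sum((y - G)^2)
  ss_A <- n * q * sum((mA - G)^2)
  ss_B <- n * p * sum((mB - G)^2)
  ss_S <- p * q * sum((mS - G)^2)
  ss_AB <- n * sum((mAB - outer(mA, mB, "+") + G)^2)
  ss_AS <- q * sum((mAS - outer(mA, mS, "+") + G)^2)
  ss_BS <- p * sum((mBS - outer(mB, mS, "+") + G)^2)
  ss_ABS <- ss_total - ss_A - ss_B - ss_S - ss_AB - ss_AS - ss_BS

  eff <- function(label, ss_eff, df1, ss_err, df2) {
    ms_eff <- ss_eff / df1; ms_err <- ss_err / df2
    Fv <- if (ms_err == 0) 0 else ms_eff / ms_err
    data.frame(effect = label, SS = ss_eff, df1 = df1, df2 = df2, F = Fv,
               p = stats::pf(Fv, df1, df2, lower.tail = FALSE),
               pes = if (ss_eff + ss_err == 0) 0 else ss_eff / (ss_eff + ss_err),
               stringsAsFactors = FALSE)
  }
  out <- rbind(
    eff(factor1, ss_A, p - 1, ss_AS, (p - 1) * (n - 1)),
    eff(factor2, ss_B, q - 1, ss_BS, (q - 1) * (n - 1)),
    eff(paste0(factor1, ":", factor2), ss_AB, (p - 1) * (q - 1),
        ss_ABS, (p - 1) * (q - 1) * (n - 1)))
  attr(out, "ss") <- c(total = ss_total, subject = ss_S,
                       f1 = ss_A, f2 = ss_B, f1f2 = ss_AB,
                       f1_error = ss_AS, f2_error = ss_BS,
                       interaction_error = ss_ABS)
  out
}

#' Mean reaction time by subject, session, and correctness
#'
#' Means over completed (non-censored) trials; neutral trials are excluded
#' because correctness is undefined for them.  Empty cells are reported
#' with `NA` and flagged.
#'
#' @param trials Trial table.
#' @return Data frame: `subject_id`, `session_index`, `correct`,
#'   `mean_rt`, `n`, `empty`.
#' @export
rt_summary <- function(trials) {
  trials <- validate_trials(trials)
  keep <- trials$timeout_redraws < 10 & trials$stimulus != "neutral"
  tr <- trials[keep, ]
  grid <- expand.grid(subject_id = unique(trials$subject_id),
                      session_index = unique(trials$session_index),
                      correct = c(TRUE, FALSE), stringsAsFactors = FALSE)
  key <- paste(tr$subject_id, tr$session_index, tr$correct)
  gkey <- paste(grid$subject_id, grid$session_index, grid$correct)
  grid$mean_rt <- vapply(gkey, function(k) {
    x <- tr$rt[key == k]
    if (length(x)) mean(x) else NA_real_
  }, 0, USE.NAMES = FALSE)
  grid$n <- vapply(gkey, function(k) sum(key == k), 0L, USE.NAMES = FALSE)
  grid$empty <- grid$n == 0L
  grid[order(grid$subject_id, grid$session_index, -grid$correct), ,
       drop = FALSE]
}

#' Behavioral summary: d-prime, RT, and Specificity Index
#'
#' The full behavioral layer over a trial table: signal-detection counts
#' and loglinear-corrected d-prime per (subject, session, difficulty)
#' cell; session-level d-prime pooled over the nonzero difficulty levels;
#' RT means by correctness; and, when the table contains training and
#' transfer sessions, the Specificity Index per subject — from pooled
#' session d-prime and also per difficulty level.  Zero-difficulty trials
#' never enter d-prime (no defined correct response), and censored trials
#' (`timeout_redraws >= 10`) are dropped.
#'
#' @param trials Trial table.
#' @return List of class `"behavioral_summary"`: `by_cell`, `by_session`,
#'   `rt`, `si`, `si_by_difficulty`.
#' @export
behavioral_summary <- function(trials) {
  trials <- validate_trials(trials)
  tr <- trials[trials$timeout_redraws < 10 & trials$stimulus != "neutral", ]
  if (nrow(tr) == 0) stop("no scorable trials", call. = FALSE)

  counts <- function(df) {
    data.frame(
      hits = sum(df$stimulus == "CW" & df$choice == "CW"),
      misses = sum(df$stimulus == "CW" & df$choice == "CCW"),
      fas = sum(df$stimulus == "CCW" & df$choice == "CW"),
      crs = sum(df$stimulus == "CCW" & df$choice == "CCW"))
  }
  split_by <- function(df, cols) {
    keys <- unique(df[, cols, drop = FALSE])
    out <- lapply(seq_len(nrow(keys)), function(i) {
      sel <- rep(TRUE, nrow(df))
      for (cl in cols) sel <- sel & df[[cl]] == keys[[cl]][i]
      cbind(keys[i, , drop = FALSE], counts(df[sel, ]))
    })
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out
  }

  by_cell <- split_by(tr, c("subject_id", "session_index", "session_role",
                            "difficulty"))
  by_cell$dprime <- dprime_loglinear(by_cell$hits, by_cell$misses,
                                     by_cell$fas, by_cell$crs)
  by_session <- split_by(tr, c("subject_id", "session_index", "session_role"))
  by_session$dprime <- dprime_loglinear(by_session$hits, by_session$misses,
                                        by_session$fas, by_session$crs)

  si <- NULL; si_by_difficulty <- NULL
  training <- by_session$session_role == "training"
  if (any(training) && any(by_session$session_role == "transfer")) {
    first_s <- min(by_session$session_index[training])
    last_s <- max(by_session$session_index[training])
    pick <- function(df, ses, role) {
      idx <- df$session_role == role & df$session_index == ses
      df[idx, , drop = FALSE]
    }
    subj <- sort(unique(by_session$subject_id))
    d_at <- function(df, ses, role, extra_key = NULL) {
      sub <- pick(df, ses, role)
      key <- if (is.null(extra_key)) sub$subject_id
             else paste(sub$subject_id, sub[[extra_key]])
      setNames(sub$dprime, key)
    }
    d_first <- d_at(by_session, first_s, "training")[subj]
    d_last <- d_at(by_session, last_s, "training")[subj]
    d_tr <- d_at(by_session,
                 unique(by_session$session_index[by_session$session_role == "transfer"]),
                 "transfer")[subj]
    si <- data.frame(subject_id = subj,
                     d_first = unname(d_first), d_last = unname(d_last),
                     d_transfer = unname(d_tr),
                     si = specificity_index(unname(d_first), unname(d_last),
                                            unname(d_tr)),
                     stringsAsFactors = FALSE)
    diffs <- sort(unique(by_cell$difficulty))
    rows <- lapply(diffs, function(dd) {
      sub <- by_cell[by_cell$difficulty == dd, ]
      df1 <- d_at(sub, first_s, "training")[subj]
      dl <- d_at(sub, last_s, "training")[subj]
      dt <- d_at(sub, unique(sub$session_index[sub$session_role == "transfer"]),
                 "transfer")[subj]
      # ties at single difficulties are common and simply flagged NA here;
      # only the pooled SI warns
      data.frame(subject_id = subj, difficulty = dd,
                 si = suppressWarnings(
                   specificity_index(unname(df1), unname(dl), unname(dt))),
                 stringsAsFactors = FALSE)
    })
    si_by_difficulty <- do.call(rbind, rows)
  }

  structure(list(by_cell = by_cell, by_session = by_session,
                 rt = rt_summary(trials), si = si,
                 si_by_difficulty = si_by_difficulty),
            class = "behavioral_summary")
}

#' @export
print.behavioral_summary <- function(x, ...) {
  cat(sprintf("behavioral summary: %d subject-session cells\n",
              nrow(x$by_session)))
  if (!is.null(x$si)) {
    ok <- x$si$si[!is.na(x$si$si)]
    cat(sprintf("  Specificity Index: median %.3f (%d/%d subjects > 0)\n",
                median(ok), sum(ok > 0), length(ok)))
  }
  invisible(x)
}
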