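#' Gelman-Rubin potential scale reduction
#'
#' Classic between/within-chain variance comparison, computed per
#' parameter: with `m` chains of length `n`, within-chain variance `W`,
#' between-chain variance `B = n var(chain means)`, the pooled estimate is
#' `(n-1)/n W + B/n` and the statistic is `sqrt(pooled / W)`.  Values
#' above 1.2 (1.1 under strict conditions) indicate non-convergence;
#' both flags are reported.
#'
#' @param fit A `ddm_fit`, or a list of draws matrices (chains) with
#'   identical dimensions and column names.
#' @return Data frame: `parameter`, `psrf`, `undefined` (zero within-chain
#'   variance), `flag_1.2`, `flag_1.1`.
#' @export
gelman_rubin <- function(fit) {
  chains <- if (inherits(fit, "ddm_fit")) fit$chains else fit
  if (!is.list(chains) || length(chains) < 2)
    stop("Gelman-Rubin needs >= 2 chains", call. = FALSE)
  n <- nrow(chains[[1]])
  stopifnot(all(vapply(chains, nrow, 0L) == n))
  params <- colnames(chains[[1]])
  psrf <- vapply(seq_along(params), function(k) {
    draws <- vapply(chains, function(m) m[, k], numeric(n))
    W <- mean(apply(draws, 2, var))
    if (W == 0) return(NA_real_)
    B <- n * var(colMeans(draws))
    sqrt(((n - 1) / n * W + B / n) / W)
  }, 0)
  data.frame(parameter = params, psrf = psrf, undefined = is.na(psrf),
             flag_1.2 = !is.na(psrf) & psrf > 1.2,
             flag_1.1 = !is.na(psrf) & psrf > 1.1,
             stringsAsFactors = FALSE)
}

# autocorrelation-robust variance of a segment mean via batch means
batch_mean_var <- function(x, n_batches = 20) {
  n_batches <- min(n_batches, max(2, floor(length(x) / 2)))
  size <- floor(length(x) / n_batches)
  if (size < 1) return(NA_real_)
  bm <- vapply(seq_len(n_batches),
               function(b) mean(x[((b - 1) * size + 1):(b * size)]), 0)
  var(bm) / n_batches
}

#' Geweke within-chain stationarity z-scores
#'
#' Compares the mean of the initial chain segment (first `first` fraction)
#' with each of `segments` consecutive segments of the final `last`
#' fraction: `z = (mean_first - mean_segment) /
#' sqrt(var_first + var_segment)`, with segment-mean variances estimated
#' by batch means (autocorrelation-robust).  A converged chain has most
#' `|z| <= 2`.
#'
#' @param chain Numeric vector of one chain's draws for one parameter
#'   (length >= 200).
#' @param first Fraction used for the initial segment.
#' @param last Fraction of the chain end that is segmented.
#' @param segments Number of late segments.
#' @return Data frame: `segment`, `z`, `undefined` (zero-variance
#'   segments).
#' @export
geweke <- function(chain, first = 0.1, last = 0.5, segments = 20) {
  chain <- as.numeric(chain)
  n <- length(chain)
  if (n < 200) stop("Geweke diagnostic needs a chain of length >= 200", call. = FALSE)
  stopifnot(first > 0, last > 0, first + last <= 1, segments >= 1)
  head_seg <- chain[seq_len(floor(first * n))]
  m0 <- mean(head_seg)
  v0 <- batch_mean_var(head_seg)
  tail_start <- n - floor(last * n) + 1
  tail_seg <- chain[tail_start:n]
  bounds <- floor(seq(0, length(tail_seg), length.out = segments + 1))
  z <- vapply(seq_len(segments), function(s) {
    seg <- tail_seg[(bounds[s] + 1):bounds[s + 1]]
    vs <- batch_mean_var(seg)
    if (is.na(v0) || is.na(vs) || v0 + vs == 0) return(NA_real_)
    (m0 - mean(seg)) / sqrt(v0 + vs)
  }, 0)
  data.frame(segment = seq_len(segments), z = z, undefined = is.na(z))
}

#' Geweke summary across all parameters of a fit
#'
#' @param fit `ddm_fit`.
#' @param ... Passed to [geweke()].
#' @return Data frame per (parameter, chain): mean z and the fraction of
#'   segment z-scores inside `[-2, 2]`.
#' @export
geweke_fractions <- function(fit, ...) {
  stopifnot(inherits(fit, "ddm_fit"))
  out <- lapply(seq_along(fit$chains), function(ch) {
    m <- fit$chains[[ch]]
    res <- lapply(colnames(m), function(p) {
      g <- geweke(m[, p], ...)
      data.frame(parameter = p, chain = ch,
                 mean_z = mean(g$z, na.rm = TRUE),
                 frac_in_2 = mean(abs(g$z) <= 2, na.rm = TRUE),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, res)
  })
  do.call(rbind, out)
}

# rebuild the fit's per-trial parameter resolution for a trial table
fit_trial_values <- function(fit, trials, theta) {
  lv <- fit$levels
  trials <- validate_trials(trials)
  trials <- trials[trials$timeout_redraws < 10, ]
  if (!fit$mcmc$include_neutral) trials <- trials[trials$stimulus != "neutral", ]
  cond_vals <- if (lv$condition == "session") trials$session_index
               else match(trials$effector, EFFECTOR_LEVELS)
  cond_idx <- match(cond_vals, lv$sessions)
  diff_idx <- match(trials$difficulty, lv$difficulties)
  diff_idx[is.na(diff_idx)] <- 1L
  if (anyNA(cond_idx) || anyNA(match(trials$subject_id, lv$subjects)))
    stop("trials contain levels absent from the fit", call. = FALSE)

  pt <- fit$param_table
  value_level <- if (length(lv$subjects) > 1) "subject" else "group_mean"
  n_tr <- nrow(trials)
  per_trial <- function(par) {
    sel <- pt$level == value_level & pt$param == par
    sub <- pt[sel, ]
    if (nrow(sub) == 0) return(NULL)  # absent z
    skey <- if (value_level == "subject") sub$subject_id
            else rep("", nrow(sub))
    tkey <- if (value_level == "subject") trials$subject_id
            else rep("", n_tr)
    ses_t <- if (all(is.na(sub$session))) rep(NA, n_tr)
             else lv$sessions[cond_idx]
    dif_t <- if (all(is.na(sub$difficulty))) rep(NA, n_tr)
             else lv$difficulties[diff_idx]
    idx <- match(paste(tkey, ses_t, dif_t),
                 paste(skey, sub$session, sub$difficulty))
    unname(theta[sub$name][idx])
  }
  xv <- per_trial("v"); xa <- per_trial("a"); xt <- per_trial("t")
  xz <- per_trial("z")
  z <- if (is.null(xz)) rep(0.5, nrow(trials)) else plogis(xz)
  sign <- ifelse(trials$stimulus == "CW", 1,
                 ifelse(trials$stimulus == "CCW", -1, 0))
  upper_choice <- if (lv$coding == "cw_upper") "CW" else "CCW"
  list(rt = trials$rt, upper = as.integer(trials$choice == upper_choice),
       v = sign * xv, a = xa, t0 = xt, z = z, n = nrow(trials))
}

#' Deviance information criterion (conditional)
#'
#' `DIC = mean(D) + pD` with `D = -2 log L` evaluated at the subject-level
#' parameters of each retained draw (the deviance trace stored during
#' sampling) and `pD = mean(D) - D(theta_bar)`, where `theta_bar` is the
#' posterior mean of the conditioned-on parameters (on the sampled scale;
#' logit for z).  Lower is better.
#'
#' @param fit `ddm_fit`.
#' @param trials The trial table the model was fitted to.
#' @return List: `dic`, `mean_deviance`, `pd`, `dhat`.
#' @export
dic <- function(fit, trials) {
  stopifnot(inherits(fit, "ddm_fit"))
  dbar <- mean(fit$deviance)
  pooled <- do.call(rbind, fit$chains)
  theta_bar <- colMeans(pooled)
  tv <- fit_trial_values(fit, trials, theta_bar)
  if (tv$n != fit$n_trials)
    stop("trial table does not match the fitted data (", tv$n, " vs ",
         fit$n_trials, " usable trials)", call. = FALSE)
  res <- trialset_loglik_cpp(tv$rt, tv$upper, tv$v, tv$a, tv$t0, tv$z,
                             fit$mcmc$err, fit$mcmc$loglik_floor)
  dhat <- -2 * res$loglik
  pd <- dbar - dhat
  list(dic = dbar + pd, mean_deviance = dbar, pd = pd, dhat = dhat)
}

#' Posterior predictive check
#'
#' For each of `n_replicates` retained posterior draws, simulates a full
#' dataset at the subject-level parameters of that draw under the given
#' design (with timed-out draws redrawn, as in the generator) and
#' summarizes accuracy and RT mean/10th/90th percentile per
#' session-by-difficulty cell.  Reports 95% predictive intervals and, for
#' the empirical cell values stored at fit time, the fraction covered.
#'
#' @param fit `ddm_fit` (a warning is issued if Gelman-Rubin flags
#'   non-convergence).
#' @param design [experiment_design()] used for cell trial counts and the
#'   response window.
#' @param n_replicates Number of posterior draws to simulate (>= 1; a
#'   warning below 50, where intervals are unstable).
#' @param seed Optional seed.
#' @param dt Euler step for the predictive simulations.
#' @return List: `summary` (per cell and statistic: mean, lower, upper,
#'   observed, covered) and `coverage` (overall fraction).
#' @export
posterior_predictive <- function(fit, design, n_replicates, seed = NULL,
                                 dt = 1e-3) {
  stopifnot(inherits(fit, "ddm_fit"), inherits(design, "experiment_design"))
  if (n_replicates < 1) stop("n_replicates must be >= 1", call. = FALSE)
  if (n_replicates < 50)
    warning("fewer than 50 replicates: predictive intervals are unstable",
            call. = FALSE)
  if (fit$mcmc$chains >= 2) {
    gr <- gelman_rubin(fit)
    if (any(gr$flag_1.2, na.rm = TRUE))
      warning("fit has Gelman-Rubin values > 1.2; predictive check may be unreliable",
              call. = FALSE)
  }
  maybe_seed(seed)
  lv <- fit$levels
  pt <- fit$param_table
  value_level <- if (length(lv$subjects) > 1) "subject" else "group_mean"
  diffs <- lv$difficulties
  tps <- design$trials_per_signed_level
  window <- design$response_window

  cell_value <- function(draw, par, subj, ses, dif) {
    sel <- pt$level == value_level & pt$param == par &
      (value_level == "group_mean" | pt$subject_id == subj)
    sub <- pt[sel, ]
    if (nrow(sub) == 0) return(NA_real_)
    if (!all(is.na(sub$session))) sub <- sub[sub$session == ses, ]
    if (!all(is.na(sub$difficulty)))
      sub <- sub[abs(sub$difficulty - dif) < 1e-9, ]
    draw[sub$name[1]]
  }

  reps <- vector("list", n_replicates)
  chain_pick <- sample.int(length(fit$chains), n_replicates, replace = TRUE)
  draw_pick <- sample.int(nrow(fit$chains[[1]]), n_replicates, replace = TRUE)
  for (r in seq_len(n_replicates)) {
    draw <- fit$chains[[chain_pick[r]]][draw_pick[r], ]
    cells <- list()
    for (ses in lv$sessions) for (dif in diffs) {
      acc <- integer(0); rts <- numeric(0)
      for (subj in lv$subjects) {
        v <- cell_value(draw, "v", subj, ses, dif)
        a <- cell_value(draw, "a", subj, ses, dif)
        t0 <- cell_value(draw, "t", subj, ses, dif)
        zl <- cell_value(draw, "z", subj, ses, dif)
        z <- if (is.na(zl)) 0.5 else plogis(zl)
        cw <- simulate_cell(tps, v, a, t0, z, window, dt)
        ccw <- simulate_cell(tps, -v, a, t0, z, window, dt)
        ok_cw <- cw$redraws < 10; ok_ccw <- ccw$redraws < 10
        acc <- c(acc, cw$upper[ok_cw] == 1, ccw$upper[ok_ccw] == 0)
        rts <- c(rts, cw$rt[ok_cw], ccw$rt[ok_ccw])
      }
      cells[[paste(ses, dif)]] <- data.frame(
        session = ses, difficulty = dif, accuracy = mean(acc),
        mean = mean(rts), q10 = unname(quantile(rts, 0.1)),
        q90 = unname(quantile(rts, 0.9)))
    }
    reps[[r]] <- do.call(rbind, cells)
  }

  stat_names <- c("accuracy", "mean", "q10", "q90")
  template <- reps[[1]][, c("session", "difficulty")]
  rows <- list()
  for (i in seq_len(nrow(template))) {
    for (stat in stat_names) {
      vals <- vapply(reps, function(d) d[[stat]][i], 0)
      obs_row <- fit$observed[
        fit$observed$session == template$session[i] &
        abs(fit$observed$difficulty - template$difficulty[i]) < 1e-9, ]
      obs <- if (nrow(obs_row)) obs_row[[stat]][1] else NA_real_
      lo <- unname(quantile(vals, 0.025)); hi <- unname(quantile(vals, 0.975))
      rows[[length(rows) + 1L]] <- data.frame(
        session = template$session[i], difficulty = template$difficulty[i],
        statistic = stat, predicted = mean(vals), lower = lo, upper = hi,
        observed = obs, covered = !is.na(obs) & obs >= lo & obs <= hi,
        stringsAsFactors = FALSE)
    }
  }
  summary <- do.call(rbind, rows)
  list(summary = summary,
       coverage = mean(summary$covered[!is.na(summary$observed)]))
}

#' Convergence and fit-quality report
#'
#' Bundles Gelman-Rubin statistics, Geweke fractions, and (when the
#' fitted trials are supplied) the conditional DIC into one report.
#'
#' @param fit `ddm_fit` (>= 2 chains).
#' @param trials Optional trial table for the DIC.
#' @return List of class `"ddm_diagnostics"`.
#' @export
diagnose <- function(fit, trials = NULL) {
  stopifnot(inherits(fit, "ddm_fit"))
  if (fit$mcmc$chains < 2)
    stop("diagnostics need at least 2 chains", call. = FALSE)
  out <- list(gelman_rubin = gelman_rubin(fit),
              geweke = geweke_fractions(fit),
              dic = if (!is.null(trials)) dic(fit, trials))
  class(out) <- "ddm_diagnostics"
  out
}

#' @export
print.ddm_diagnostics <- function(x, ...) {
  gr <- x$gelman_rubin
  cat(sprintf("Gelman-Rubin: max %.4f; %d/%d parameter(s) > 1.2, %d > 1.1\n",
              max(gr$psrf, na.rm = TRUE), sum(gr$flag_1.2), nrow(gr),
              sum(gr$flag_1.1)))
  cat(sprintf("Geweke: mean fraction of |z| <= 2 across parameters: %.3f\n",
              mean(x$geweke$frac_in_2, na.rm = TRUE)))
  if (!is.null(x$dic))
    cat(sprintf("DIC %.1f (mean deviance %.1f, pD %.1f)\n",
                x$dic$dic, x$dic$mean_deviance, x$dic$pd))
  invisible(x)
}
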