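#' Group-level generating values implied by a ground truth
#'
#' Expands a [ground_truth()] over the sessions and nonzero difficulties of
#' a design into the group-level parameter values the hierarchical fit
#' estimates (start point on the logit scale, matching the sampling
#' scale), including the transfer session's specificity-reduced drifts and
#' shifted non-decision time.
#'
#' @param truth [ground_truth()].
#' @param design [experiment_design()].
#' @return Data frame: `param`, `session`, `difficulty`, `value`.
#' @export
truth_group_values <- function(truth, design) {
  S <- design$n_training_sessions
  sessions <- seq_len(S + as.integer(design$has_transfer))
  diffs <- design$difficulties[design$difficulties > 0]
  a_s <- rep_len(truth$a, S)
  t_s <- rep_len(truth$t0, S)
  z_s <- rep_len(truth$z, S)
  rows <- list()
  for (s in sessions) {
    transfer <- s > S
    v <- if (!transfer) truth$beta[s] * diffs^truth$gamma
         else {
           v1 <- truth$beta[1] * diffs^truth$gamma
           vS <- truth$beta[S] * diffs^truth$gamma
           v1 + (1 - truth$rho) * (vS - v1)
         }
    rows[[length(rows) + 1L]] <- data.frame(
      param = "v", session = s, difficulty = diffs, value = v)
    rows[[length(rows) + 1L]] <- data.frame(
      param = c("a", "t", "z"), session = s, difficulty = NA_real_,
      value = c(if (transfer) a_s[S] else a_s[s],
                if (transfer) max(t_s[S] - truth$delta_t, 0.05) else t_s[s],
                qlogis(if (transfer) z_s[S] else z_s[s])))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Design used by the estimation-validation studies
#'
#' The scaled-down recovery design: four training sessions plus transfer,
#' the five nonzero difficulty levels, 10 trials per signed level (100
#' trials per session), and no effective response deadline.  The deadline
#' is dropped on purpose: the fitting likelihood deliberately ignores the
#' redraw truncation that a deadline induces (as the study pipeline it
#' reproduces did), so recovery under a tight deadline measures that
#' documented truncation bias rather than the estimator.  The deadline's
#' effect is assessed separately in the methods vignette.
#'
#' @param trials_per_signed_level Trials per signed difficulty level.
#' @param response_window Response window (s); the default is effectively
#'   no deadline.
#' @return [experiment_design()].
#' @export
recovery_design <- function(trials_per_signed_level = 10,
                            response_window = 10) {
  experiment_design(
    n_training_sessions = 4L, has_transfer = TRUE,
    difficulties = c(0.31, 0.56, 1, 1.77, 3.16),
    trials_per_signed_level = trials_per_signed_level,
    response_window = response_window)
}

#' Parameter-recovery study
#'
#' Simulates one cohort from known ground truth, fits the full model, and
#' reports how many group-level 95% credible intervals cover the
#' generating group values, along with Gelman-Rubin convergence over all
#' parameters.
#'
#' @param seed Seed for the whole study (split across generation and
#'   fitting).
#' @param n_subjects Cohort size.
#' @param design [experiment_design()]; defaults to [recovery_design()].
#' @param truth [ground_truth()].
#' @param spec Model string.
#' @param mcmc [mcmc_settings()].
#' @return List: `coverage` (fraction), `table` (per-parameter), `psrf`
#'   summary, `fit`.
#' @export
recovery_study <- function(seed, n_subjects = 8,
                           design = recovery_design(),
                           truth = ground_truth(),
                           spec = "v(ses*diff)_a(ses)_t(ses)_z(ses)",
                           mcmc = mcmc_settings()) {
  seeds <- split_seed(seed, 3)
  pars <- generate_subject_params(truth, design, n_subjects, seed = seeds[1])
  trials <- simulate_experiment(design, pars, seed = seeds[2])
  fit <- fit_hddm(trials, spec, mcmc = mcmc, seed = seeds[3])

  tv <- truth_group_values(truth, design)
  pool <- do.call(rbind, fit$chains)
  gm <- fit$param_table[fit$param_table$level == "group_mean", ]
  key <- function(p, s, d) paste(p, s, ifelse(is.na(d), "-", d))
  idx <- match(key(gm$param, gm$session, gm$difficulty),
               key(tv$param, tv$session, tv$difficulty))
  rows <- lapply(seq_len(nrow(gm)), function(i) {
    ci <- quantile(pool[, gm$name[i]], c(0.025, 0.975))
    val <- tv$value[idx[i]]
    data.frame(parameter = gm$name[i], truth = val,
               lower = unname(ci[1]), upper = unname(ci[2]),
               covered = val >= ci[1] & val <= ci[2])
  })
  table <- do.call(rbind, rows)
  gr <- gelman_rubin(fit)
  list(coverage = mean(table$covered), table = table,
       psrf = list(max = max(gr$psrf, na.rm = TRUE),
                   frac_le_1.2 = mean(gr$psrf <= 1.2, na.rm = TRUE)),
       fit = fit)
}

#' DIC model-identification study
#'
#' Generates data with a genuine start-point bias, fits the bias model
#' (`z(ses)`) and the no-bias model (z fixed at 0.5), and compares their
#' conditional DICs.  When the generating bias is real the bias model
#' should win (lower DIC).
#'
#' @param seed Study seed.
#' @param z_truth Generating start point (all sessions).
#' @param n_subjects Cohort size.
#' @param design [experiment_design()].
#' @param mcmc [mcmc_settings()]; the default is lighter than the recovery
#'   study since only the deviance summaries are needed.
#' @return List: `dic_bias`, `dic_nobias`, `delta` (nobias - bias; positive
#'   means the bias model is preferred), and the two fits.
#' @export
model_identification_study <- function(seed, z_truth = 0.42, n_subjects = 8,
                                       design = recovery_design(),
                                       mcmc = mcmc_settings(chains = 2,
                                                            samples = 1500,
                                                            burnin = 500)) {
  truth <- ground_truth(z = rep(z_truth, design$n_training_sessions))
  seeds <- split_seed(seed, 4)
  pars <- generate_subject_params(truth, design, n_subjects, seed = seeds[1])
  trials <- simulate_experiment(design, pars, seed = seeds[2])
  fit_a <- fit_hddm(trials, "v(ses*diff)_a(ses)_t(ses)_z(ses)",
                    mcmc = mcmc, seed = seeds[3])
  fit_b <- fit_hddm(trials, "v(ses*diff)_a(ses)_t(ses)",
                    mcmc = mcmc, seed = seeds[4])
  dic_a <- dic(fit_a, trials)
  dic_b <- dic(fit_b, trials)
  list(dic_bias = dic_a$dic, dic_nobias = dic_b$dic,
       delta = dic_b$dic - dic_a$dic, fit_bias = fit_a, fit_nobias = fit_b)
}

#' Specificity-recovery study
#'
#' Runs the full behavioral pipeline (simulate cohort, score d-prime,
#' compute Specificity Indices) at each requested specificity factor and
#' returns the median SI per `rho`.  The median SI should track `rho`:
#' near 0 at full transfer, near 1 at full specificity.
#'
#' @param seed Study seed.
#' @param rho_values Specificity factors to probe.
#' @param n_subjects Cohort size (19 matches the emulated experiment).
#' @param design [experiment_design()] (the default keeps the 1-s response
#'   window of the emulated task).
#' @return Data frame: `rho`, `median_si`, `n_positive`, `n_subjects`.
#' @export
specificity_curve <- function(seed, rho_values = c(0, 0.3, 1),
                              n_subjects = 19,
                              design = experiment_design()) {
  seeds <- split_seed(seed, 2 * length(rho_values))
  rows <- lapply(seq_along(rho_values), function(i) {
    truth <- ground_truth(rho = rho_values[i])
    pars <- generate_subject_params(truth, design, n_subjects,
                                    seed = seeds[2 * i - 1])
    trials <- simulate_experiment(design, pars, seed = seeds[2 * i])
    beh <- behavioral_summary(trials)
    si <- beh$si$si[!is.na(beh$si$si)]
    data.frame(rho = rho_values[i], median_si = median(si),
               n_positive = sum(si > 0), n_subjects = length(si))
  })
  do.call(rbind, rows)
}
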