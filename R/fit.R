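#' MCMC settings for the hierarchical fit
#'
#' Desk-scale defaults: 4 chains, 3000 retained draws each after 1000
#' burn-in sweeps, no thinning.  `full_scale = TRUE` restores the
#' long-run regime of 4 chains of 30,000 sweeps with 10,000 burn-in and
#' thinning by 5 (4000 retained draws per chain).
#'
#' @param chains Number of chains (>= 2 for convergence diagnostics).
#' @param samples Retained draws per chain (after burn-in and thinning).
#' @param burnin Burn-in sweeps (proposal scales adapt here, then freeze).
#' @param thin Keep every `thin`-th post-burn-in sweep.
#' @param err Wiener density truncation tolerance.
#' @param loglik_floor Density floor before logs.
#' @param include_neutral Include zero-difficulty trials at drift 0?
#' @param full_scale Override with the long-run regime.
#' @return List of class `"mcmc_settings"`.
#' @export
mcmc_settings <- function(chains = 4L, samples = 3000L, burnin = 1000L,
                          thin = 1L, err = 1e-7, loglik_floor = 1e-12,
                          include_neutral = FALSE, full_scale = FALSE) {
  if (full_scale) {
    chains <- 4L; burnin <- 10000L; thin <- 5L; samples <- 4000L
  }
  stopifnot(chains >= 1, samples >= 1, burnin >= 0, thin >= 1,
            err > 0, loglik_floor > 0)
  structure(list(chains = as.integer(chains), samples = as.integer(samples),
                 burnin = as.integer(burnin), thin = as.integer(thin),
                 err = err, loglik_floor = loglik_floor,
                 include_neutral = isTRUE(include_neutral)),
            class = "mcmc_settings")
}

# map each trial to 0-based factor-cell indices for one parameter
cell_index0 <- function(deps, cond_idx, diff_idx, n_diff) {
  if (identical(deps, "absent") || length(deps) == 0)
    return(rep(0L, length(cond_idx)))
  has_ses <- "session" %in% deps
  has_diff <- "difficulty" %in% deps
  if (has_ses && has_diff) (cond_idx - 1L) * n_diff + (diff_idx - 1L)
  else if (has_ses) cond_idx - 1L
  else diff_idx - 1L
}

n_cells <- function(deps, n_ses, n_diff) {
  if (identical(deps, "absent")) return(0L)
  if (length(deps) == 0) return(1L)
  out <- 1L
  if ("session" %in% deps) out <- out * n_ses
  if ("difficulty" %in% deps) out <- out * n_diff
  out
}

#' Fit the hierarchical drift-diffusion model
#'
#' Bayesian estimation by adaptive Metropolis-within-Gibbs: group-level
#' means and SDs constrain subject-level parameters, which carry the
#' Wiener first-passage likelihood of the trials.  Clockwise stimuli
#' accumulate at `+v`, counterclockwise at `-v`; the upper boundary maps
#' to clockwise choices by default.  The start point is sampled on the
#' logit scale.  Censored trials (`timeout_redraws >= 10`) are dropped,
#' and zero-difficulty trials are excluded unless
#' `mcmc$include_neutral = TRUE`.
#'
#' Group-mean priors: `v ~ N(2, 3^2)`, `a ~ N(1.5, 1^2)` truncated above
#' 0.1, `t0 ~ N(0.4, 0.25^2)` truncated at 0, `logit(z) ~ N(0, 0.5^2)`;
#' group SDs are half-normal (scale 1 for v, 0.3 for a and t0, 0.25 for
#' logit z); subject values are normal around the group means (truncated
#' for a and t0, logit-normal for z).
#'
#' @param trials Trial table.
#' @param spec Model string or [parse_model_spec()] result.
#' @param mcmc [mcmc_settings()].
#' @param condition Factor the `ses` dependence refers to:
#'   `"session"` (session_index) or `"effector"` (hand/eye blocks, e.g.
#'   for the untrained control group).
#' @param coding Boundary-to-choice map, `"cw_upper"` or `"cw_lower"`.
#' @param prior_only Drop the likelihood and sample from the prior alone
#'   (the trials still define the factor levels); mainly for validating
#'   the sampler against its own prior.
#' @param fixed Optional named list clamping whole parameter types at
#'   known values, e.g. `list(a = 1.6, t = 0.45, z = 0.5)` (`z` on the
#'   probability scale); clamped types are excluded from sampling.
#' @param seed Optional seed (chains continue one RNG stream, so a fixed
#'   seed makes the whole fit reproducible).
#' @return Object of class `"ddm_fit"`; see [posterior_samples()],
#'   [gelman_rubin()], [dic()].
#' @export
fit_hddm <- function(trials, spec, mcmc = mcmc_settings(),
                     condition = c("session", "effector"),
                     coding = c("cw_upper", "cw_lower"),
                     fixed = NULL, prior_only = FALSE, seed = NULL) {
  condition <- match.arg(condition)
  coding <- match.arg(coding)
  spec <- parse_model_spec(spec)
  if (!inherits(mcmc, "mcmc_settings")) mcmc <- do.call(mcmc_settings, mcmc)
  trials <- validate_trials(trials)

  trials <- trials[trials$timeout_redraws < 10, ]
  if (!mcmc$include_neutral) trials <- trials[trials$stimulus != "neutral", ]
  if (nrow(trials) == 0) stop("no usable trials after filtering", call. = FALSE)

  cond_vals <- if (condition == "session") trials$session_index
               else match(trials$effector, EFFECTOR_LEVELS)
  sessions <- sort(unique(cond_vals))
  difficulties <- sort(unique(trials$difficulty[trials$difficulty > 0]))
  subjects <- sort(unique(trials$subject_id))
  if (("difficulty" %in% spec$v || "difficulty" %in% spec$a ||
       "difficulty" %in% spec$t) && length(difficulties) < 2)
    stop("difficulty dependence requires >= 2 nonzero difficulty levels",
         call. = FALSE)

  cond_idx <- match(cond_vals, sessions)
  diff_idx <- match(trials$difficulty, difficulties)
  diff_idx[is.na(diff_idx)] <- 1L  # neutral trials: drift sign is 0 anyway
  nd <- length(difficulties)
  cells <- lapply(spec, cell_index0, cond_idx = cond_idx,
                  diff_idx = diff_idx, n_diff = nd)
  ncell <- vapply(c("v", "a", "t", "z"), function(p)
    n_cells(spec[[p]], length(sessions), nd), 0L)

  drift_sign <- ifelse(trials$stimulus == "CW", 1,
                       ifelse(trials$stimulus == "CCW", -1, 0))
  upper_choice <- if (coding == "cw_upper") "CW" else "CCW"
  resp_upper <- as.integer(trials$choice == upper_choice)
  subj_idx <- match(trials$subject_id, subjects) - 1L

  fixed_vec <- rep(NA_real_, 4)
  if (!is.null(fixed)) {
    bad <- setdiff(names(fixed), c("v", "a", "t", "z"))
    if (length(bad)) stop("unknown fixed parameter(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
    for (p in names(fixed)) {
      val <- fixed[[p]]
      fixed_vec[match(p, c("v", "a", "t", "z"))] <-
        if (p == "z") qlogis(val) else val
    }
  }

  ptab <- parameter_index(spec, sessions, difficulties, subjects)
  n_sweeps <- mcmc$burnin + mcmc$samples * mcmc$thin

  keep <- if (prior_only) integer(0) else seq_len(nrow(trials))

  maybe_seed(seed)
  chains <- vector("list", mcmc$chains)
  deviance <- matrix(NA_real_, mcmc$samples, mcmc$chains)
  accept <- matrix(NA_real_, nrow(ptab), mcmc$chains,
                   dimnames = list(ptab$name, NULL))
  for (ch in seq_len(mcmc$chains)) {
    res <- hddm_gibbs_cpp(trials$rt[keep], resp_upper[keep], drift_sign[keep],
                          subj_idx[keep],
                          cells$v[keep], cells$a[keep], cells$t[keep],
                          cells$z[keep],
                          length(subjects), ncell,
                          n_sweeps, mcmc$burnin, mcmc$thin,
                          mcmc$err, mcmc$loglik_floor, fixed_vec)
    colnames(res$draws) <- ptab$name
    chains[[ch]] <- res$draws
    deviance[, ch] <- res$deviance
    accept[, ch] <- res$accept_rate
  }

  obs_df <- data.frame(session = cond_vals, difficulty = trials$difficulty,
                       accuracy = as.numeric(trials$correct), rt = trials$rt)
  obs_df <- obs_df[trials$stimulus != "neutral", ]
  observed <- stats::aggregate(accuracy ~ session + difficulty, obs_df, mean)
  rts <- stats::aggregate(rt ~ session + difficulty, obs_df,
    FUN = function(x) c(mean = mean(x), q10 = unname(quantile(x, 0.1)),
                        q90 = unname(quantile(x, 0.9))))
  observed <- cbind(observed, as.data.frame(rts$rt))

  structure(list(
    chains = chains, deviance = deviance, param_table = ptab,
    spec = spec, mcmc = mcmc, accept = accept,
    levels = list(sessions = sessions, difficulties = difficulties,
                  subjects = subjects, condition = condition,
                  coding = coding),
    observed = observed,
    n_trials = nrow(trials), seed = seed
  ), class = "ddm_fit")
}

#' @export
print.ddm_fit <- function(x, ...) {
  cat(sprintf("hierarchical DDM fit: %s\n", format(x$spec)))
  cat(sprintf("  %d subjects, %d trials, %d %s level(s), %d difficulty level(s)\n",
              length(x$levels$subjects), x$n_trials, length(x$levels$sessions),
              x$levels$condition, length(x$levels$difficulties)))
  cat(sprintf("  %d chain(s) x %d draws (burn-in %d, thin %d); %d parameters\n",
              x$mcmc$chains, x$mcmc$samples, x$mcmc$burnin, x$mcmc$thin,
              nrow(x$param_table)))
  cat(sprintf("  mean deviance %.1f; median acceptance %.2f\n",
              mean(x$deviance), median(x$accept, na.rm = TRUE)))
  invisible(x)
}

#' Extract posterior samples
#'
#' Pools draws across chains for the parameters matching the query.
#' Start-point (`z`) samples are mapped from the sampled logit scale back
#' to (0, 1) unless `transform = FALSE`.
#'
#' @param fit `ddm_fit`.
#' @param param `"v"`, `"a"`, `"t"` or `"z"`.
#' @param level `"group_mean"`, `"group_sd"` or `"subject"`.
#' @param session,difficulty,subject Optional factor filters.
#' @param transform Map z back to the probability scale?
#' @return Matrix (draws x matching parameters) with column names, or a
#'   vector if exactly one parameter matches.
#' @export
posterior_samples <- function(fit, param, level = "group_mean",
                              session = NULL, difficulty = NULL,
                              subject = NULL, transform = TRUE) {
  stopifnot(inherits(fit, "ddm_fit"))
  pt <- fit$param_table
  sel <- pt$param == param & pt$level == level
  if (!is.null(session)) sel <- sel & !is.na(pt$session) & pt$session == session
  if (!is.null(difficulty))
    sel <- sel & !is.na(pt$difficulty) & abs(pt$difficulty - difficulty) < 1e-9
  if (!is.null(subject)) sel <- sel & pt$subject_id == subject
  if (!any(sel))
    stop(sprintf("no %s-level '%s' parameter matches the query (model %s)",
                 level, param, format(fit$spec)), call. = FALSE)
  out <- do.call(rbind, lapply(fit$chains, function(m) m[, pt$name[sel], drop = FALSE]))
  if (param == "z" && transform && level != "group_sd") out <- plogis(out)
  if (ncol(out) == 1) drop(out) else out
}
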