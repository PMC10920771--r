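#' Draw subject-level generating parameters
#'
#' Inverts the hierarchical estimation model as a generator: each subject's
#' session-wise parameters are drawn around the group-level ground truth
#' (normal for the drift slope and logit start point, truncated-at-zero
#' normal for boundary separation and non-decision time), then expanded to
#' per-difficulty drift rates `v = beta * delta^gamma`.  The transfer
#' session applies the specificity rule to each subject's own drifts and
#' shifts that subject's non-decision time down by `delta_t` (floored at
#' 0.05 s).
#'
#' @param truth [ground_truth()] parameters.
#' @param design [experiment_design()].
#' @param n_subjects Number of subjects (>= 1).
#' @param seed Optional seed for the parameter draws.
#' @return Data frame with one row per (subject, session, difficulty):
#'   `subject_id`, `group`, `session_index`, `session_role`, `effector`,
#'   `difficulty`, `v`, `a`, `t0`, `z`.
#' @export
generate_subject_params <- function(truth, design, n_subjects, seed = NULL) {
  stopifnot(inherits(truth, "ground_truth"), inherits(design, "experiment_design"),
            n_subjects >= 1)
  maybe_seed(seed)
  S <- design$n_training_sessions
  if (length(truth$beta) != S)
    stop("truth$beta must supply one drift slope per training session", call. = FALSE)
  a_s <- rep_len(truth$a, S)
  t_s <- rep_len(truth$t0, S)
  z_s <- rep_len(truth$z, S)
  diffs <- design$difficulties
  subj_ids <- sprintf("S%02d", seq_len(n_subjects))

  rtruncnorm_pos <- function(n, mean, sd, lower = 0) {
    if (sd == 0) return(rep(mean, n))
    x <- rnorm(n, mean, sd)
    while (any(bad <- x <= lower)) x[bad] <- rnorm(sum(bad), mean, sd)
    x
  }

  rows <- list()
  for (j in seq_len(n_subjects)) {
    beta_j <- truth$beta + rnorm(S, 0, truth$sd_beta)
    a_j <- rtruncnorm_pos(S, a_s, truth$sd_a)
    t_j <- rtruncnorm_pos(S, t_s, truth$sd_t0)
    z_j <- plogis(rnorm(S, qlogis(z_s), truth$sd_zlogit))
    v_j <- outer(beta_j, diffs^truth$gamma)   # S x length(diffs)
    v_j[, diffs == 0] <- 0

    for (s in seq_len(S)) {
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = subj_ids[j], group = "trained",
        session_index = s, session_role = "training", effector = "hand",
        difficulty = diffs, v = v_j[s, ], a = a_j[s], t0 = t_j[s], z = z_j[s],
        stringsAsFactors = FALSE)
    }
    if (design$has_transfer) {
      v_tr <- v_j[1, ] + (1 - truth$rho) * (v_j[S, ] - v_j[1, ])
      v_tr[diffs == 0] <- 0
      t_group_tr <- max(t_s[S] - truth$delta_t, 0.05)
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = subj_ids[j], group = "trained",
        session_index = S + 1L, session_role = "transfer", effector = "eye",
        difficulty = diffs, v = v_tr,
        a = rtruncnorm_pos(1, a_s[S], truth$sd_a),
        t0 = max(rtruncnorm_pos(1, t_group_tr, truth$sd_t0), 0.05),
        z = plogis(rnorm(1, qlogis(z_s[S]), truth$sd_zlogit)),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# simulate one cell of n trials with redraw-on-timeout (max 10 attempts,
# then the trial is censored: rt set to the window, timeout_redraws = 10)
simulate_cell <- function(n, v, a, t0, z, window, dt) {
  res <- ddm_sample_cpp(n, v, a, t0, z, dt)
  upper <- res$upper
  rt <- res$rt
  redraws <- integer(n)
  for (attempt in 1:10) {
    late <- which(rt > window)
    if (!length(late)) break
    redraws[late] <- redraws[late] + 1L
    if (attempt == 10) {
      rt[late] <- window
      break
    }
    res <- ddm_sample_cpp(length(late), v, a, t0, z, dt)
    upper[late] <- res$upper
    rt[late] <- res$rt
  }
  list(upper = upper, rt = round(rt, 6), redraws = redraws)
}

cell_trials <- function(par_row, n_per_sign, window, dt,
                        upper_choice = "CW") {
  lower_choice <- setdiff(CHOICE_LEVELS, upper_choice)
  d <- par_row$difficulty
  mk <- function(stim, drift, n) {
    cell <- simulate_cell(n, drift, par_row$a, par_row$t0, par_row$z, window, dt)
    choice <- ifelse(cell$upper == 1, upper_choice, lower_choice)
    data.frame(
      subject_id = par_row$subject_id, group = par_row$group,
      session_index = par_row$session_index,
      session_role = par_row$session_role, effector = par_row$effector,
      difficulty = d, stimulus = stim, choice = choice,
      correct = if (stim == "neutral") NA else choice == stim,
      rt = cell$rt, timeout_redraws = cell$redraws,
      stringsAsFactors = FALSE)
  }
  if (d == 0) {
    mk("neutral", 0, n_per_sign)
  } else {
    rbind(mk("CW", par_row$v, n_per_sign), mk("CCW", -par_row$v, n_per_sign))
  }
}

#' Simulate a full experiment from a parameter map
#'
#' Draws `(choice, rt)` pairs from the diffusion process for every design
#' cell: clockwise stimuli accumulate at `+v`, counterclockwise at `-v`,
#' and zero-difficulty trials use drift 0 with a `neutral` stimulus label.
#' Draws slower than the response window are redrawn (emulating the
#' repetition of timed-out trials), so cell counts match the design
#' exactly.
#'
#' @param design [experiment_design()].
#' @param params Parameter map from [generate_subject_params()] (or the
#'   same layout); must cover every (subject, session, difficulty) cell.
#' @param seed Optional seed.
#' @param dt Euler step of the path sampler (s).
#' @return Validated trial table.
#' @export
simulate_experiment <- function(design, params, seed = NULL, dt = 1e-4) {
  stopifnot(inherits(design, "experiment_design"))
  maybe_seed(seed)
  need <- expand.grid(subject_id = unique(params$subject_id),
                      session_index = unique(params$session_index),
                      difficulty = design$difficulties,
                      stringsAsFactors = FALSE)
  key <- function(d) paste(d$subject_id, d$session_index, d$difficulty)
  missing_cells <- setdiff(key(need), key(params))
  if (length(missing_cells))
    stop("parameter map lacks cell(s): ",
         paste(head(missing_cells, 3), collapse = "; "), call. = FALSE)
  params <- params[params$difficulty %in% design$difficulties, ]
  out <- lapply(seq_len(nrow(params)), function(i)
    cell_trials(params[i, ], design$trials_per_signed_level,
                design$response_window, dt))
  trials <- do.call(rbind, out)
  rownames(trials) <- NULL
  validate_trials(trials, response_window = design$response_window)
}

#' Simulate an untrained two-effector control group
#'
#' Each control subject performs one block per effector at session-1
#' (untrained) drift levels, so the generating drift difference between
#' effectors is zero; the eye block's non-decision time is lower by
#' `delta_t` (floored at 0.05 s).  Block order is counterbalanced across
#' subjects (odd subjects hand-first).
#'
#' @inheritParams generate_subject_params
#' @param seed Optional seed.
#' @param dt Euler step (s).
#' @return Validated trial table with `session_role = "effector_block"`,
#'   `session_index` 1/2 encoding block order.
#' @export
simulate_control_group <- function(design, truth, n_subjects, seed = NULL,
                                   dt = 1e-4) {
  stopifnot(inherits(truth, "ground_truth"), inherits(design, "experiment_design"))
  if (n_subjects < 2)
    stop("counterbalancing block order needs at least 2 subjects", call. = FALSE)
  maybe_seed(seed)
  diffs <- design$difficulties
  a1 <- rep_len(truth$a, 1)
  t1 <- rep_len(truth$t0, 1)
  z1 <- rep_len(truth$z, 1)
  t_eye <- max(t1 - truth$delta_t, 0.05)

  rtrunc <- function(mean, sd, lower = 0) {
    if (sd == 0) return(mean)
    x <- rnorm(1, mean, sd)
    while (x <= lower) x <- rnorm(1, mean, sd)
    x
  }

  rows <- list()
  for (j in seq_len(n_subjects)) {
    sid <- sprintf("C%02d", j)
    order_eff <- if (j %% 2 == 1) c("hand", "eye") else c("eye", "hand")
    for (b in 1:2) {
      eff <- order_eff[b]
      beta_jb <- truth$beta[1] + rnorm(1, 0, truth$sd_beta)
      v <- beta_jb * diffs^truth$gamma
      v[diffs == 0] <- 0
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = sid, group = "control", session_index = b,
        session_role = "effector_block", effector = eff,
        difficulty = diffs, v = v,
        a = rtrunc(a1, truth$sd_a),
        t0 = max(rtrunc(if (eff == "eye") t_eye else t1, truth$sd_t0), 0.0),
        z = plogis(rnorm(1, qlogis(z1), truth$sd_zlogit)),
        stringsAsFactors = FALSE)
    }
  }
  params <- do.call(rbind, rows)
  out <- lapply(seq_len(nrow(params)), function(i)
    cell_trials(params[i, ], design$trials_per_signed_level,
                design$response_window, dt))
  trials <- do.call(rbind, out)
  rownames(trials) <- NULL
  validate_trials(trials, response_window = design$response_window)
}
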