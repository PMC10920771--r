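#' Experiment design
#'
#' Describes the session/trial structure the simulator emulates: a number
#' of training sessions with one effector, optionally followed by a
#' transfer session with the other effector, each session presenting every
#' signed difficulty level equally often under a fixed response window.
#' With the defaults this yields `20 * (1 + 2 * 5) = 220` trials per
#' session (20 neutral plus 20 clockwise and 20 counterclockwise at each of
#' the five nonzero difficulties).
#'
#' @param n_training_sessions Number of training sessions.
#' @param has_transfer Append an effector-change transfer session?
#' @param difficulties Unsigned orientation offsets in degrees, strictly
#'   increasing; a leading 0 adds neutral trials.
#' @param trials_per_signed_level Trials per signed difficulty level per
#'   session.
#' @param response_window Response window in seconds; slower first-passage
#'   draws are redrawn.
#' @return List of class `"experiment_design"`.
#' @export
experiment_design <- function(n_training_sessions = 4L,
                              has_transfer = TRUE,
                              difficulties = c(0, 0.31, 0.56, 1, 1.77, 3.16),
                              trials_per_signed_level = 20L,
                              response_window = 1.0) {
  stopifnot(n_training_sessions >= 1, trials_per_signed_level >= 1,
            response_window > 0, length(difficulties) >= 1)
  if (any(difficulties < 0) || any(diff(difficulties) <= 0))
    stop("difficulties must be nonnegative and strictly increasing", call. = FALSE)
  structure(list(
    n_training_sessions = as.integer(n_training_sessions),
    has_transfer = isTRUE(has_transfer),
    difficulties = as.numeric(difficulties),
    trials_per_signed_level = as.integer(trials_per_signed_level),
    response_window = response_window
  ), class = "experiment_design")
}

#' @export
print.experiment_design <- function(x, ...) {
  nz <- sum(x$difficulties > 0)
  per_session <- x$trials_per_signed_level *
    (sum(x$difficulties == 0) + 2L * nz)
  cat(sprintf(
    "experiment design: %d training session(s)%s, %d trials/session\n",
    x$n_training_sessions,
    if (x$has_transfer) " + transfer" else "", per_session))
  cat(sprintf("  difficulties (deg): %s; response window %.2g s\n",
              paste(x$difficulties, collapse = ", "), x$response_window))
  invisible(x)
}

n_trials_per_session <- function(design) {
  design$trials_per_signed_level *
    (sum(design$difficulties == 0) + 2L * sum(design$difficulties > 0))
}

#' Generating (ground-truth) parameters for the simulator
#'
#' Group-level diffusion parameters from which subject-level parameters are
#' drawn.  Drift for session `s` at difficulty `delta` follows the power
#' law `v = beta[s] * delta^gamma`; learning is expressed as `beta` growing
#' over sessions.  At transfer, the drift gain acquired during training is
#' reduced by the specificity factor `rho`:
#' `v_transfer = v_first + (1 - rho) * (v_last - v_first)` per difficulty,
#' so `rho = 0` carries the full gain to the new effector and `rho = 1`
#' none of it.  The transfer non-decision time drops by `delta_t` (saccades
#' are faster than hand responses), floored at 0.05 s.
#'
#' @param beta Drift slope per training session (1/(s deg)).
#' @param gamma Drift-difficulty exponent (dimensionless).
#' @param a Boundary separation (evidence units), recycled over sessions.
#' @param t0 Non-decision time (s), recycled over sessions.
#' @param z Relative start point in (0,1), recycled over sessions.
#' @param rho Specificity factor in `[0, 1]`.
#' @param delta_t Transfer non-decision shift (s).
#' @param sd_beta,sd_a,sd_t0,sd_zlogit Between-subject SDs (the z SD is on
#'   the logit scale).
#' @return List of class `"ground_truth"`.
#' @export
ground_truth <- function(beta = c(0.55, 0.75, 0.9, 1.0), gamma = 1,
                         a = 1.6, t0 = 0.45, z = c(0.47, 0.5, 0.5, 0.5),
                         rho = 0.3, delta_t = 0.14,
                         sd_beta = 0.15, sd_a = 0.15, sd_t0 = 0.05,
                         sd_zlogit = 0.15) {
  if (rho < 0 || rho > 1) stop("rho must lie in [0, 1]", call. = FALSE)
  if (any(a <= 0)) stop("boundary separation a must be positive", call. = FALSE)
  if (any(t0 < 0)) stop("non-decision time t0 must be >= 0", call. = FALSE)
  if (any(z <= 0 | z >= 1)) stop("start point z must lie in (0, 1)", call. = FALSE)
  if (any(c(sd_beta, sd_a, sd_t0, sd_zlogit) < 0))
    stop("between-subject SDs must be >= 0", call. = FALSE)
  structure(list(beta = beta, gamma = gamma, a = a, t0 = t0, z = z,
                 rho = rho, delta_t = delta_t, sd_beta = sd_beta,
                 sd_a = sd_a, sd_t0 = sd_t0, sd_zlogit = sd_zlogit),
            class = "ground_truth")
}
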