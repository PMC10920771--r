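#' Four-parameter diffusion process point
#'
#' One parameter point of the diffusion process with diffusion coefficient
#' fixed at 1 (scaling convention): signed drift `v` (evidence/s),
#' boundary separation `a` (> 0), non-decision time `t0` (s, >= 0), and
#' relative start point `z` in (0, 1) (fraction of `a`).  Inter-trial
#' variability parameters are deliberately not part of this process.
#'
#' @param v Drift rate (signed).
#' @param a Boundary separation.
#' @param t0 Non-decision time.
#' @param z Relative start point.
#' @return List of class `"ddm_params"`.
#' @export
#' @examples
#' ddm_params(v = 1, a = 2, z = 0.5)
ddm_params <- function(v, a, t0 = 0, z = 0.5) {
  stopifnot(is.finite(v), is.finite(a), is.finite(t0), is.finite(z))
  if (a <= 0) stop("boundary separation a must be > 0", call. = FALSE)
  if (z <= 0 || z >= 1) stop("start point z must lie in (0, 1)", call. = FALSE)
  if (t0 < 0) stop("non-decision time t0 must be >= 0", call. = FALSE)
  structure(list(v = v, a = a, t0 = t0, z = z), class = "ddm_params")
}

as_ddm_params <- function(x) {
  if (inherits(x, "ddm_params")) return(x)
  ddm_params(x$v, x$a, if (is.null(x$t0)) 0 else x$t0,
             if (is.null(x$z)) 0.5 else x$z)
}

#' Probability of absorption at the upper boundary
#'
#' Closed form for a drift-diffusion process with unit diffusion
#' coefficient: `P(upper) = (1 - exp(-2 v a z)) / (1 - exp(-2 v a))` for
#' `v != 0`, and `z` in the zero-drift limit.
#'
#' @param params A [ddm_params()] object (or list with `v`, `a`, `z`).
#' @return Probability in (0, 1).
#' @export
#' @examples
#' absorption_prob_upper(ddm_params(v = 1, a = 2, z = 0.5))  # 0.8808
absorption_prob_upper <- function(params) {
  p <- as_ddm_params(params)
  absorb_upper_cpp(p$v, p$a, p$z)
}

#' Wiener first-passage-time density
#'
#' Density (1/s) of the first passage through one boundary at clock time
#' `t` (decision time `t - t0`).  Evaluated with complementary series
#' expansions — the large-time sine series and the small-time Gaussian
#' image series — using whichever needs fewer terms for truncation error
#' `<= err`; returns 0 for `t <= t0`.
#'
#' @param t Vector of times (s).
#' @param params [ddm_params()].
#' @param boundary `"upper"` or `"lower"`.
#' @param err Series truncation tolerance (> 0).
#' @return Nonnegative density values, same length as `t`.
#' @export
wfpt_density <- function(t, params, boundary = c("upper", "lower"),
                         err = 1e-7) {
  boundary <- match.arg(boundary)
  if (!is.numeric(err) || length(err) != 1 || err <= 0)
    stop("err must be a positive tolerance", call. = FALSE)
  p <- as_ddm_params(params)
  wfpt_pdf_cpp(as.numeric(t), p$v, p$a, p$t0, p$z, boundary == "upper", err)
}

#' Sample choices and reaction times from the diffusion process
#'
#' Euler-Maruyama walk from `z * a` with increments
#' `v dt + sqrt(dt) N(0,1)` until crossing 0 or `a`.  A Brownian-bridge
#' crossing test between consecutive points removes the `O(sqrt(dt))`
#' first-passage discretization bias.  Reaction time is crossing time plus
#' `t0`.
#'
#' @param params [ddm_params()].
#' @param n Number of trials (> 0).
#' @param dt Euler step (s, > 0).
#' @param seed Optional seed.
#' @return Data frame with `boundary` (`"upper"`/`"lower"`) and `rt` (s).
#' @export
sample_ddm <- function(params, n, dt = 1e-4, seed = NULL) {
  if (!is.numeric(n) || length(n) != 1 || n <= 0)
    stop("n must be a positive integer", call. = FALSE)
  if (dt <= 0) stop("dt must be > 0", call. = FALSE)
  p <- as_ddm_params(params)
  maybe_seed(seed)
  res <- ddm_sample_cpp(as.integer(n), p$v, p$a, p$t0, p$z, dt)
  data.frame(boundary = ifelse(res$upper == 1, "upper", "lower"),
             rt = res$rt, stringsAsFactors = FALSE)
}

# resolve one diffusion parameter value per trial from a parameter map
# keyed by (subject_id, session_index, difficulty)
resolve_trial_params <- function(trials, params_map) {
  key_t <- paste(trials$subject_id, trials$session_index, trials$difficulty)
  key_p <- paste(params_map$subject_id, params_map$session_index,
                 params_map$difficulty)
  idx <- match(key_t, key_p)
  if (anyNA(idx))
    stop("parameter map lacks cell(s): ",
         paste(head(unique(key_t[is.na(idx)]), 3), collapse = "; "),
         call. = FALSE)
  params_map[idx, c("v", "a", "t0", "z")]
}

#' Log-likelihood of a trial set under a parameter map
#'
#' Sums the log first-passage density over trials.  Stimulus coding: drift
#' is `+v` for clockwise stimuli, `-v` for counterclockwise, 0 for neutral
#' trials (if any are passed).  The boundary-to-choice map defaults to
#' upper = clockwise and is configurable.  Densities are floored at
#' `floor` before the log; trials at or below the floor (including
#' `rt <= t0`) are counted and reported in a warning.
#'
#' @param trials Trial table slice.
#' @param params_map Data frame with columns `subject_id`, `session_index`,
#'   `difficulty`, `v`, `a`, `t0`, `z` covering every trial.
#' @param coding `"cw_upper"` (default) or `"cw_lower"`.
#' @param err Density truncation tolerance.
#' @param floor Density floor before taking logs.
#' @return Log-likelihood (scalar) with attribute `n_floored`.
#' @export
wfpt_logpdf_trials <- function(trials, params_map, coding = c("cw_upper", "cw_lower"),
                               err = 1e-7, floor = 1e-12) {
  coding <- match.arg(coding)
  if (nrow(trials) == 0) return(structure(0, n_floored = 0L))
  par <- resolve_trial_params(trials, params_map)
  sign <- ifelse(trials$stimulus == "CW", 1,
                 ifelse(trials$stimulus == "CCW", -1, 0))
  upper_choice <- if (coding == "cw_upper") "CW" else "CCW"
  res <- trialset_loglik_cpp(trials$rt,
                             as.integer(trials$choice == upper_choice),
                             sign * par$v, par$a, par$t0, par$z, err, floor)
  if (res$n_floored > 0)
    warning(sprintf("%d trial(s) hit the density floor (rt <= t0 or underflow)",
                    res$n_floored), call. = FALSE)
  structure(res$loglik, n_floored = res$n_floored)
}
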