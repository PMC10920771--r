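#' Default run configuration
#'
#' The defaults reproduce the emulated study design: four training sessions
#' plus a transfer session with an effector change, 220 trials per session
#' over six signed difficulty levels, a 1-s response window, and
#' desk-scale MCMC settings (4 chains, 3000 retained draws after 1000
#' burn-in sweeps).
#'
#' @return Nested list with components `design`, `truth`, `model`, `mcmc`,
#'   `seed`, `out_dir`, `log_level`.
#' @export
default_config <- function() {
  list(
    design = list(
      n_training_sessions = 4L,
      has_transfer = TRUE,
      difficulties = c(0, 0.31, 0.56, 1, 1.77, 3.16),
      trials_per_signed_level = 20L,
      response_window = 1.0
    ),
    truth = list(
      beta = c(0.55, 0.75, 0.9, 1.0),
      gamma = 1.0,
      a = 1.6,
      t0 = 0.45,
      z = c(0.47, 0.5, 0.5, 0.5),
      rho = 0.3,
      delta_t = 0.14,
      sd_beta = 0.15,
      sd_a = 0.15,
      sd_t0 = 0.05,
      sd_zlogit = 0.15
    ),
    model = "v(ses*diff)_a(ses)_t(ses)_z(ses)",
    mcmc = list(
      chains = 4L, samples = 3000L, burnin = 1000L, thin = 1L,
      err = 1e-7, loglik_floor = 1e-12, include_neutral = FALSE,
      full_scale = FALSE
    ),
    seed = 1L,
    out_dir = ".",
    log_level = "info"
  )
}

nearest_key <- function(key, valid) {
  valid[which.min(adist(key, valid, ignore.case = TRUE))]
}

merge_config <- function(base, override, path = character()) {
  for (key in names(override)) {
    if (!key %in% names(base)) {
      where <- if (length(path)) paste0(" in '", paste(path, collapse = "$"), "'") else ""
      stop(sprintf("unknown config key '%s'%s; did you mean '%s'?",
                   key, where, nearest_key(key, names(base))), call. = FALSE)
    }
    if (is.list(base[[key]]) && !is.null(names(base[[key]]))) {
      if (!is.list(override[[key]]))
        stop(sprintf("config key '%s' must be a mapping", key), call. = FALSE)
      base[[key]] <- merge_config(base[[key]], override[[key]], c(path, key))
    } else {
      base[[key]] <- override[[key]]
    }
  }
  base
}

validate_config <- function(cfg) {
  d <- cfg$design
  counts <- c(d$n_training_sessions, d$trials_per_signed_level,
              cfg$mcmc$chains, cfg$mcmc$samples, cfg$mcmc$burnin, cfg$mcmc$thin)
  if (any(counts <= 0)) stop("all design/MCMC counts must be positive", call. = FALSE)
  diffs <- d$difficulties
  if (length(diffs) < 2 || diffs[1] < 0 || any(diff(diffs) <= 0))
    stop("difficulty list must be strictly increasing from 0", call. = FALSE)
  if (is.null(cfg$seed)) stop("config must carry a seed", call. = FALSE)
  parse_model_spec(cfg$model)  # surfaces model-string errors with position
  cfg
}

#' Load a run configuration
#'
#' Reads a YAML configuration, fills unspecified values with
#' [default_config()], rejects unknown keys (with a nearest-key hint), and
#' validates the result.  Every resolved value is echoed to the log at
#' `log_level: info`.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @param overrides Named list merged on top of the file (e.g. CLI flags).
#' @return Validated configuration list.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
    cfg <- merge_config(cfg, user)
  }
  if (length(overrides)) cfg <- merge_config(cfg, overrides)
  cfg <- validate_config(cfg)
  if (identical(cfg$log_level, "info")) {
    flat <- unlist(cfg)
    message("resolved configuration:\n",
            paste(sprintf("  %s = %s", names(flat), flat), collapse = "\n"))
  }
  cfg
}
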