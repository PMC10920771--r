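test_that("prob_greater obeys the tie rule and its symmetry", {
  b <- rnorm(100)
  expect_equal(prob_greater(b + 1, b), 1)
  expect_equal(prob_greater(b, b), 0.5)
  expect_error(prob_greater(1:3, 1:4), "equal length")
  for (s in 1:5) {
    set.seed(600 + s)
    x <- rnorm(300); y <- rnorm(300)
    expect_equal(prob_greater(x, y) + prob_greater(y, x), 1)
  }
  set.seed(77)
  a <- rnorm(1e5); c <- rnorm(1e5)
  expect_lt(abs(prob_greater(a, c) - 0.5), 0.01)
})

make_learning_fit <- function(seed, n_subjects = 4, tps = 8) {
  des <- quick_design(response_window = 10)
  des$trials_per_signed_level <- as.integer(tps)
  pars <- generate_subject_params(quick_truth(), des, n_subjects, seed = seed)
  tr <- simulate_experiment(des, pars, seed = seed + 1)
  fit_hddm(tr, "v(ses*diff)_a(ses)_t(ses)_z(ses)",
           mcmc = mcmc_settings(chains = 2, samples = 600, burnin = 400),
           seed = seed + 2)
}

test_that("drift learning and transfer contrasts recover the generator", {
  # enough trials per cell that the learning signal dominates MCMC noise
  fit <- make_learning_fit(610, n_subjects = 6, tps = 25)
  # beta grows 0.6 -> 1.0 from session 1 to 2: drift must increase
  learn <- subject_level_summary(fit, ddm_contrast("v", 2, 1))
  expect_equal(nrow(learn), 2)  # one row per difficulty
  expect_true(all(learn$mean_p >= 0.8))
  pg <- group_prob(fit, ddm_contrast("v", 2, 1))
  expect_true(all(pg >= 0.8))
  # contrasts on parameters without session dependence are errors
  fitc <- fit_hddm(
    simulate_experiment(quick_design(), generate_subject_params(
      quick_truth(), quick_design(), 2, seed = 650), seed = 651),
    "v(ses)_a(const)_t(const)",
    mcmc = mcmc_settings(chains = 2, samples = 100, burnin = 50), seed = 652)
  expect_error(subject_level_summary(fitc, ddm_contrast("a", 2, 1)),
               "constant across conditions")
  expect_error(group_prob(fitc, ddm_contrast("z", 2, 1)), "absent")
})

test_that("a fit compared against its own copy yields 0.5 everywhere", {
  fit <- make_learning_fit(620)
  fit_copy <- fit
  p <- group_diff_prob(fit, fit_copy, ddm_contrast("v", 2, 1))
  expect_true(all(p == 0.5))
})

test_that("mismatched model spaces are rejected in group comparisons", {
  fit <- make_learning_fit(630)
  des <- quick_design()
  pars <- generate_subject_params(quick_truth(), des, 2, seed = 640)
  tr <- simulate_experiment(des, pars, seed = 641)
  fit_d <- fit_hddm(tr, "v(ses)_a(const)_t(const)",
                    mcmc = mcmc_settings(chains = 2, samples = 100, burnin = 50),
                    seed = 642)
  # v varies by difficulty in one fit only: difficulty grids disagree
  expect_error(group_diff_prob(fit, fit_d, ddm_contrast("v", 2, 1)),
               "different difficulty grids")
})

test_that("identical subject posteriors give SD exactly 0", {
  # clamping all types makes every subject's posterior identical
  des <- quick_design(response_window = 10)
  pars <- generate_subject_params(quick_truth(), des, 3, seed = 660)
  tr <- simulate_experiment(des, pars, seed = 661)
  fit <- fit_hddm(tr, "v(ses)_a(const)_t(const)",
                  mcmc = mcmc_settings(chains = 2, samples = 100, burnin = 50),
                  fixed = list(v = 1, a = 1.6, t = 0.3), seed = 662)
  s <- subject_level_summary(fit, ddm_contrast("v", 2, 1))
  expect_equal(s$sd_p, 0)
  expect_false(s$sd_undefined)
})

test_that("the assembled report is complete and deterministic", {
  fit <- make_learning_fit(670)
  des <- quick_design(response_window = 10)
  pars <- generate_subject_params(quick_truth(), des, 4, seed = 670)
  tr <- simulate_experiment(des, pars, seed = 671)
  beh <- behavioral_summary(tr)
  dg <- diagnose(fit, tr)
  rep1 <- build_report(list(full = fit), beh, diagnostics = list(full = dg))
  expect_true(is.data.frame(rep1$model_comparison))
  expect_true(is.numeric(rep1$specificity$median_si))
  expect_named(rep1$parameter_contrasts, c("v", "a", "t", "z"))

  # missing diagnostics are marked, not fabricated
  rep2 <- build_report(list(full = fit), beh)
  expect_identical(rep2$model_comparison, "not run")

  # byte-identical machine-readable output for identical inputs
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  build_report(list(full = fit), beh, diagnostics = list(full = dg),
               out_dir = d1)
  build_report(list(full = fit), beh, diagnostics = list(full = dg),
               out_dir = d2)
  expect_identical(readLines(file.path(d1, "results.json")),
                   readLines(file.path(d2, "results.json")))
})
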