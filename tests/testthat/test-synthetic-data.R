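test_that("the default design yields 220 trials per session, 20 neutral", {
  des <- experiment_design()
  truth <- ground_truth()
  pars <- generate_subject_params(truth, des, 1, seed = 1)
  tr <- simulate_experiment(des, pars, seed = 2)
  s1 <- tr[tr$session_index == 1 & tr$session_role == "training", ]
  expect_equal(nrow(s1), 220L)
  expect_equal(sum(s1$stimulus == "neutral"), 20L)
  # 5 sessions in total (4 training + transfer)
  expect_equal(nrow(tr), 5L * 220L)
  expect_true(all(tr$rt <= des$response_window))
  expect_equal(unique(tr$effector[tr$session_role == "transfer"]), "eye")
})

test_that("timeout redraws conserve the design cell counts", {
  des <- quick_design(response_window = 0.6)  # harsh deadline, many redraws
  truth <- quick_truth()
  pars <- generate_subject_params(truth, des, 2, seed = 3)
  tr <- simulate_experiment(des, pars, seed = 4)
  counts <- table(tr$subject_id, tr$session_index, tr$difficulty)
  expect_true(all(counts[, , "0"] == des$trials_per_signed_level))
  expect_true(all(counts[, , "2"] == 2 * des$trials_per_signed_level))
  expect_gt(sum(tr$timeout_redraws), 0)
})

test_that("specificity factor limits collapse the transfer drifts", {
  des <- quick_design()
  base <- list(beta = c(0.6, 1.0), z = c(0.47, 0.5),
               sd_beta = 0, sd_a = 0, sd_t0 = 0, sd_zlogit = 0)
  p0 <- generate_subject_params(do.call(ground_truth, c(base, rho = 0)),
                                des, 1, seed = 5)
  p1 <- generate_subject_params(do.call(ground_truth, c(base, rho = 1)),
                                des, 1, seed = 5)
  v_of <- function(p, ses) p$v[p$session_index == ses & p$difficulty > 0]
  expect_equal(v_of(p0, 3), v_of(p0, 2))  # full transfer = last training
  expect_equal(v_of(p1, 3), v_of(p1, 1))  # no transfer = first session
})

test_that("zero between-subject SDs make all subjects identical", {
  des <- quick_design()
  truth <- quick_truth(sd_beta = 0, sd_a = 0, sd_t0 = 0, sd_zlogit = 0)
  pars <- generate_subject_params(truth, des, 3, seed = 6)
  cols <- c("session_index", "difficulty", "v", "a", "t0", "z")
  split_p <- split(pars[, cols], pars$subject_id)
  for (i in 2:3) expect_equal(split_p[[i]], split_p[[1]],
                              ignore_attr = TRUE)
})

test_that("invalid ground truth is rejected", {
  expect_error(ground_truth(rho = 1.5), "rho")
  expect_error(ground_truth(a = -1), "positive")
  expect_error(ground_truth(z = 1.2), "z")
})

test_that("a missing parameter cell is reported by name", {
  des <- quick_design()
  pars <- generate_subject_params(quick_truth(), des, 1, seed = 7)
  expect_error(simulate_experiment(des, pars[pars$difficulty != 2, ]),
               "lacks cell")
})

test_that("generation is deterministic given the seed", {
  des <- quick_design()
  truth <- quick_truth()
  run <- function() {
    pars <- generate_subject_params(truth, des, 2, seed = 8)
    simulate_experiment(des, pars, seed = 9)
  }
  expect_identical(run(), run())
})

test_that("cell accuracy converges to the analytic absorption probability", {
  # one strong-drift cell, many trials, wide window: empirical P(correct)
  # must approach the closed-form upper-boundary probability
  par <- ddm_params(v = 1.2, a = 1.6, t0 = 0.3, z = 0.47)
  n <- 2e4
  s <- sample_ddm(par, n, dt = 1e-4, seed = 10)
  targ <- absorption_prob_upper(par)
  expect_lt(abs(mean(s$boundary == "upper") - targ),
            3 * sqrt(targ * (1 - targ) / n))
})

test_that("control group is counterbalanced with untrained drifts", {
  des <- quick_design()
  truth <- quick_truth()
  tr <- simulate_control_group(des, truth, 10, seed = 11)
  expect_equal(unique(tr$group), "control")
  expect_equal(unique(tr$session_role), "effector_block")
  per_subj <- table(tr$subject_id)
  expect_true(all(per_subj == 2 * n_trials_per_session_for_test(des)))
  first_block <- tr[tr$session_index == 1, ]
  order_eff <- tapply(first_block$effector, first_block$subject_id, unique)
  expect_equal(sum(order_eff == "hand"), 5L)
  expect_equal(sum(order_eff == "eye"), 5L)
  expect_error(simulate_control_group(des, truth, 1), "at least 2")
})
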