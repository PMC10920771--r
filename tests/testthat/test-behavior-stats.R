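test_that("loglinear d-prime matches the probit oracle and stays finite", {
  expect_equal(dprime_loglinear(10, 10, 10, 10), 0)
  # frozen from qnorm((h+.5)/(n+1)) - qnorm((f+.5)/(n+1))
  expect_equal(dprime_loglinear(15, 5, 5, 15), 1.274968, tolerance = 1e-6)
  expect_equal(dprime_loglinear(20, 0, 0, 20), 3.961505, tolerance = 1e-6)
  expect_true(is.finite(dprime_loglinear(0, 20, 20, 0)))
  expect_error(dprime_loglinear(-1, 5, 5, 5), "nonnegative")
  expect_error(dprime_loglinear(0, 0, 5, 5), "totals")
})

test_that("d-prime is antisymmetric under class swap", {
  for (cnt in list(c(15, 5, 5, 15), c(18, 2, 7, 13), c(9, 11, 3, 17))) {
    expect_equal(dprime_loglinear(cnt[1], cnt[2], cnt[3], cnt[4]),
                 -dprime_loglinear(cnt[3], cnt[4], cnt[1], cnt[2]))
  }
})

test_that("Specificity Index endpoints and arithmetic", {
  expect_equal(specificity_index(1.0, 2.0, 2.0), 0)  # full transfer
  expect_equal(specificity_index(1.0, 2.0, 1.0), 1)  # no transfer
  expect_equal(specificity_index(1.0, 2.25, 1.93), 0.256)
  expect_warning(si <- specificity_index(1.5, 1.5, 1.0), "undefined")
  expect_true(is.na(si))
})

test_that("one-sided sign test is the exact binomial tail", {
  expect_equal(sign_test_onesided(17, 2), 191 / 2^19)
  expect_equal(sign_test_onesided(10, 10), 0.5880985, tolerance = 1e-6)
  expect_equal(sign_test_onesided(5, 0), 1 / 32)
  expect_error(sign_test_onesided(0, 0), "at least one")
})

test_that("paired t-test with Hedges g matches direct computation", {
  r <- ttest_paired(c(1, 2, 3, 4), c(2, 3, 5, 6))
  expect_equal(r$t, -5.196152, tolerance = 1e-6)
  expect_equal(r$df, 3)
  expect_equal(r$p, 0.01384683, tolerance = 1e-6)
  expect_equal(r$g, -1.889510, tolerance = 1e-6)
  # cross-check against stats::t.test
  ref <- t.test(c(1, 2, 3, 4), c(2, 3, 5, 6), paired = TRUE)
  expect_equal(r$t, unname(ref$statistic))
  expect_equal(r$p, ref$p.value)

  same <- ttest_paired(1:5, 1:5)
  expect_equal(same$t, 0)
  expect_equal(same$g, 0)
  shifted <- ttest_paired(2:6, 1:5)
  expect_true(shifted$degenerate)
  expect_true(is.infinite(shifted$t))
})

test_that("two-way repeated-measures ANOVA agrees with aov and conserves SS", {
  set.seed(71)
  toy <- expand.grid(subject_id = paste0("S", 1:3),
                     session_index = 1:3, difficulty = c(0.5, 1, 2))
  toy$dprime <- with(toy, 0.4 * session_index + 0.8 * log(difficulty) +
                     rnorm(nrow(toy), sd = 0.3))
  res <- rm_anova2(toy)
  ref <- summary(aov(dprime ~ factor(session_index) * factor(difficulty) +
                       Error(factor(subject_id) /
                               (factor(session_index) * factor(difficulty))),
                     data = toy))
  get_ref <- function(stratum, row) {
    tab <- ref[[stratum]][[1]]
    c(F = tab$`F value`[row], p = tab$`Pr(>F)`[row], SS = tab$`Sum Sq`[row])
  }
  r1 <- get_ref("Error: factor(subject_id):factor(session_index)", 1)
  expect_equal(res$F[1], unname(r1["F"]), tolerance = 1e-10)
  expect_equal(res$p[1], unname(r1["p"]), tolerance = 1e-10)
  expect_equal(res$SS[1], unname(r1["SS"]), tolerance = 1e-10)
  r2 <- get_ref("Error: factor(subject_id):factor(difficulty)", 1)
  expect_equal(res$F[2], unname(r2["F"]), tolerance = 1e-10)
  r3 <- get_ref("Error: factor(subject_id):factor(session_index):factor(difficulty)", 1)
  expect_equal(res$F[3], unname(r3["F"]), tolerance = 1e-10)

  # conservation: components sum to the total SS
  ss <- attr(res, "ss")
  expect_equal(sum(ss[-1]), ss["total"], ignore_attr = TRUE, tolerance = 1e-10)

  # partial eta^2 identity for each effect
  expect_equal(res$pes,
               res$F * res$df1 / (res$F * res$df1 + res$df2),
               tolerance = 1e-10)
})

test_that("ANOVA degenerate cases: additive data and flat data", {
  toy <- expand.grid(subject_id = paste0("S", 1:3),
                     session_index = 1:3, difficulty = c(1, 2))
  toy$dprime <- with(toy, as.numeric(session_index) + 2 * (difficulty == 2))
  res <- rm_anova2(toy)
  expect_equal(res$SS[res$effect == "session_index:difficulty"], 0,
               tolerance = 1e-12)
  toy$dprime <- 1
  res0 <- rm_anova2(toy)
  expect_true(all(res0$F == 0))
  toy2 <- toy[-1, ]
  expect_error(rm_anova2(toy2), "complete balanced")
})

test_that("RT summaries average completed trials and flag empty cells", {
  tr <- tiny_trials()
  rs <- rt_summary(tr)
  one <- rs[rs$subject_id == "S01" & rs$session_index == 1 & rs$correct, ]
  expect_equal(one$mean_rt, 0.43)  # single correct non-neutral trial
  # an all-censored session has no completed trials: flagged empty
  tr2 <- tr
  tr2$timeout_redraws[tr2$session_index == 2] <- 10L
  rs2 <- rt_summary(tr2)
  expect_true(all(rs2$empty[rs2$session_index == 2]))
})

test_that("transfer sessions are faster when the generator shifts t0 down", {
  des <- quick_design()
  truth <- quick_truth(delta_t = 0.2)
  pars <- generate_subject_params(truth, des, 4, seed = 72)
  tr <- simulate_experiment(des, pars, seed = 73)
  rs <- rt_summary(tr)
  m_train <- mean(rs$mean_rt[rs$session_index <= 2], na.rm = TRUE)
  m_transfer <- mean(rs$mean_rt[rs$session_index == 3], na.rm = TRUE)
  expect_lt(m_transfer, m_train)
})

test_that("behavioral summary pools counts and computes per-subject SI", {
  des <- quick_design()
  pars <- generate_subject_params(quick_truth(), des, 3, seed = 74)
  tr <- simulate_experiment(des, pars, seed = 75)
  beh <- behavioral_summary(tr)
  # pooled session counts equal the design: 2 nonzero levels x 8 per sign
  expect_true(all(beh$by_session$hits + beh$by_session$misses == 16))
  expect_equal(nrow(beh$si), 3)
  expect_true(all(c("d_first", "d_last", "d_transfer") %in% names(beh$si)))
  # per-difficulty SI table covers each nonzero difficulty
  expect_setequal(unique(beh$si_by_difficulty$difficulty), c(0.5, 2))
})
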