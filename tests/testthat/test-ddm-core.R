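test_that("absorption probability matches the closed form and its limits", {
  expect_equal(absorption_prob_upper(ddm_params(0, 2, 0, 0.5)), 0.5)
  expect_equal(absorption_prob_upper(ddm_params(0, 2, 0, 0.3)), 0.3)
  # frozen closed-form value, cross-checked against path simulation below
  expect_equal(absorption_prob_upper(ddm_params(1, 2, 0, 0.5)),
               0.8807971, tolerance = 1e-6)
  # strong drift must not overflow
  expect_equal(absorption_prob_upper(ddm_params(40, 3, 0, 0.5)), 1,
               tolerance = 1e-9)
  expect_lt(absorption_prob_upper(ddm_params(-40, 3, 0, 0.5)), 1e-15)
})

test_that("density vanishes before t0 and obeys reflection symmetry", {
  p <- ddm_params(1.3, 1.8, 0.3, 0.4)
  expect_equal(wfpt_density(c(0.29, 0.3), p, "upper"), c(0, 0))
  tt <- seq(0.35, 2.5, by = 0.05)
  expect_identical(
    wfpt_density(tt, ddm_params(1.3, 1.8, 0.3, 0.4), "upper"),
    wfpt_density(tt, ddm_params(-1.3, 1.8, 0.3, 0.6), "lower"))
})

test_that("density integrates to the absorption probabilities", {
  for (par in list(ddm_params(1, 2, 0.3, 0.5), ddm_params(-0.8, 1.2, 0.2, 0.35),
                   ddm_params(0, 1.6, 0.45, 0.47))) {
    up <- integrate(function(t) wfpt_density(t, par, "upper"),
                    par$t0, Inf, rel.tol = 1e-9)$value
    lo <- integrate(function(t) wfpt_density(t, par, "lower"),
                    par$t0, Inf, rel.tol = 1e-9)$value
    expect_equal(up + lo, 1, tolerance = 1e-4)
    expect_equal(up, absorption_prob_upper(par), tolerance = 1e-4)
  }
})

test_that("small-time and large-time series agree across the switch point", {
  p <- ddm_params(1, 2, 0, 0.5)
  err <- 1e-7
  # scaled time tt = t/a^2 near 1 is where the preferred series flips
  tt <- seq(0.05, 8, by = 0.05)
  coarse <- wfpt_density(tt, p, "upper", err = err)
  fine <- wfpt_density(tt, p, "upper", err = 1e-12)
  expect_lt(max(abs(coarse - fine)), 10 * err)
})

test_that("density evaluation rejects a nonpositive tolerance", {
  expect_error(wfpt_density(1, ddm_params(1, 2, 0, 0.5), err = 0), "positive")
})

test_that("sampler matches zero-drift closed forms", {
  p <- ddm_params(0, 2, 0, 0.5)
  s <- sample_ddm(p, 1e5, dt = 1e-4, seed = 81)
  # mean decision time a^2 z (1 - z) = 1.0
  expect_lt(abs(mean(s$rt) - 1.0), 3 * sd(s$rt) / sqrt(nrow(s)))
  # symmetric splitting
  frac <- mean(s$boundary == "upper")
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / nrow(s)))
})

test_that("sampler boundary fractions match the absorption probability", {
  p <- ddm_params(1, 2, 0, 0.5)
  s <- sample_ddm(p, 4e4, dt = 1e-4, seed = 82)
  targ <- absorption_prob_upper(p)
  expect_lt(abs(mean(s$boundary == "upper") - targ),
            3 * sqrt(targ * (1 - targ) / nrow(s)))
})

test_that("sampled RT distribution matches the series density (KS)", {
  p <- ddm_params(0.8, 1.6, 0.2, 0.45)
  n <- 4e4
  s <- sample_ddm(p, n, dt = 1e-4, seed = 83)
  # build the marginal RT cdf by quadrature of upper + lower densities
  grid <- seq(p$t0, 12, length.out = 4000)
  dens <- wfpt_density(grid, p, "upper") + wfpt_density(grid, p, "lower")
  cdf <- cumsum((dens[-1] + dens[-length(dens)]) / 2 * diff(grid))
  cdf_at <- approxfun(grid[-1], cdf, yleft = 0, yright = 1)
  ks <- max(abs(sort(cdf_at(s$rt)) - (seq_len(n) - 0.5) / n))
  crit_1pct <- 1.628 / sqrt(n)
  expect_lt(ks, crit_1pct)
})

test_that("trial-set log-likelihood sums per-trial log densities", {
  pm <- data.frame(subject_id = "S01", session_index = 1, difficulty = 1,
                   v = 1.2, a = 1.8, t0 = 0.2, z = 0.45)
  one <- tiny_trials()[2, ]  # CW stimulus, CW choice
  one$difficulty <- 1
  d <- wfpt_density(one$rt, ddm_params(1.2, 1.8, 0.2, 0.45), "upper")
  expect_equal(as.numeric(wfpt_logpdf_trials(one, pm)), log(d))
  # CCW stimulus flips the drift sign; CCW choice is the lower boundary
  two <- tiny_trials()[5, ]
  two$difficulty <- 1; two$session_index <- 1
  d2 <- wfpt_density(two$rt, ddm_params(-1.2, 1.8, 0.2, 0.45), "lower")
  expect_equal(as.numeric(wfpt_logpdf_trials(two, pm)), log(d2))
  expect_equal(as.numeric(wfpt_logpdf_trials(one[0, ], pm)), 0)
})

test_that("log-likelihood floors impossible trials and warns", {
  pm <- data.frame(subject_id = "S01", session_index = 1, difficulty = 1,
                   v = 1, a = 1.8, t0 = 0.9, z = 0.5)
  one <- tiny_trials()[2, ]
  one$difficulty <- 1
  one$rt <- 0.5  # below t0
  expect_warning(ll <- wfpt_logpdf_trials(one, pm), "floor")
  expect_equal(as.numeric(ll), log(1e-12))
})

test_that("likelihood at the generating parameters beats gross perturbations", {
  wins <- 0L
  n_rep <- 6
  for (s in seq_len(n_rep)) {
    pm <- data.frame(subject_id = "S01", group = "trained", session_index = 1,
                     session_role = "training", effector = "hand",
                     difficulty = 1, v = 1.5, a = 1.6, t0 = 0.3, z = 0.5)
    des <- experiment_design(1, FALSE, c(0.5, 1), trials_per_signed_level = 125,
                             response_window = 20)
    pm <- rbind(pm, transform(pm, difficulty = 0.5, v = 0.75))
    tr <- simulate_experiment(des, pm, seed = 400 + s)
    ll_truth <- as.numeric(wfpt_logpdf_trials(tr, pm))
    up <- transform(pm, v = v * 1.5)
    dn <- transform(pm, v = v * 0.5)
    if (ll_truth > as.numeric(wfpt_logpdf_trials(tr, up)) &&
        ll_truth > as.numeric(wfpt_logpdf_trials(tr, dn))) wins <- wins + 1L
  }
  expect_gte(wins, ceiling(0.95 * n_rep) - 1L)
})
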