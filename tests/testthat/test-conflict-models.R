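test_that("attention weights normalise and narrow onto the target", {
  p <- ssp_params(sd_a = 1.8, r_d = 18)
  w <- ssp_attention_weights(seq(0, 0.5, by = 0.01), p)
  expect_equal(w$w_target + w$w_outer, rep(1, nrow(w)))
  expect_true(all(diff(w$w_target) >= 0))
  # floor regime: spotlight fully on the target
  t_floor <- (1.8 - 0.001) / 18 + 0.01
  expect_gt(ssp_attention_weights(t_floor, p)$w_target, 1 - 1e-10)
})

test_that("initial target weight matches an independent Gaussian-mass oracle", {
  p <- ssp_params(sd_a = 1.8, r_d = 18)
  oracle <- integrate(function(x) dnorm(x, 0, 1.8), -0.5, 0.5)$value
  expect_equal(ssp_attention_weights(0, p)$w_target, oracle,
               tolerance = 1e-8)
  # and composes into the incongruent drift
  w0 <- ssp_attention_weights(0, ssp_params(sd_a = 1.8, p = 0.4))$w_target
  expect_equal(ssp_drift(0, ssp_params(sd_a = 1.8, p = 0.4), "incongruent"),
               0.4 * (2 * w0 - 1))
})

test_that("congruent drift is time-constant and equals p for random parameters", {
  set.seed(1)
  for (i in 1:25) {
    p <- ssp_params(boundary = runif(1, .02, .2), p = runif(1, .1, .8),
                    sd_a = runif(1, .5, 3), r_d = runif(1, 5, 50),
                    t_er = runif(1, 0, .5))
    drift <- ssp_drift(seq(0, 1, by = .05), p, "congruent")
    expect_equal(drift, rep(p$p, length(drift)))
  }
  expect_error(ssp_drift(0, ssp_params(), "catch"), "arg")
})

test_that("noiseless simulators match closed-form first-passage times", {
  dt <- 0.001
  # SSP, congruent: constant drift p, crossing at boundary/p
  p <- ssp_params(boundary = 0.07, p = 0.4, t_er = 0.3)
  got <- simulate_conflict_trials(p, "congruent", 1, noise_sd = 0)$rt_s
  expect_lt(abs(got - (0.07 / 0.4 + 0.3)), dt + 1e-12)
  # DSTP, congruent, response selection beats stimulus selection
  d <- dstp_params(boundary = 0.09, boundary_C = 0.12, mu_t = 0.12,
                   mu_fl = 0.18, mu_ss = 0.40, mu_rs2 = 1.4, t_er = 0.30)
  # response selection reaches its boundary no later than stimulus
  # selection (ties resolve in favour of responding)
  expect_lte(0.09 / (0.12 + 0.18), 0.12 / 0.40)
  got <- simulate_conflict_trials(d, "congruent", 1, noise_sd = 0)$rt_s
  expect_lt(abs(got - (0.09 / 0.30 + 0.30)), dt + 1e-12)
  # DSTP, incongruent with mu_fl > mu_t: negative phase 1 until stimulus
  # selection completes at C/mu_ss, then drift +mu_rs2 from the current value
  t1 <- 0.12 / 0.40
  closed <- t1 + (0.09 + (0.18 - 0.12) * t1) / 1.4 + 0.30
  got <- simulate_conflict_trials(d, "incongruent", 1, noise_sd = 0)$rt_s
  # two boundary crossings each round up to the next grid point
  expect_lt(abs(got - closed), 2.5 * dt)
})

test_that("non-decision time bounds every simulated RT", {
  x <- simulate_conflict_trials(ssp_params(t_er = 0.25), "incongruent", 500,
                                seed = 3)
  expect_true(all(x$rt_s >= 0.25))
  y <- simulate_conflict_trials(dstp_params(t_er = 0.4), "congruent", 500,
                                seed = 3)
  expect_true(all(y$rt_s >= 0.4))
})

test_that("identical seeds give identical trial streams", {
  a <- simulate_conflict_trials(ssp_params(), "incongruent", 200, seed = 11)
  b <- simulate_conflict_trials(ssp_params(), "incongruent", 200, seed = 11)
  expect_identical(a, b)
  d1 <- simulate_conflict_trials(dstp_params(), "congruent", 200, seed = 11)
  d2 <- simulate_conflict_trials(dstp_params(), "congruent", 200, seed = 11)
  expect_identical(d1, d2)
})

test_that("congruency produces the expected accuracy and speed ordering", {
  con <- simulate_conflict_trials(ssp_params(), "congruent", 20000, seed = 5)
  inc <- simulate_conflict_trials(ssp_params(), "incongruent", 20000,
                                  seed = 6)
  expect_gt(mean(con$correct), mean(inc$correct))
  expect_lt(mean(con$rt_s), mean(inc$rt_s))
})

test_that("DSTP incongruent errors are fast errors", {
  inc <- simulate_conflict_trials(dstp_params(), "incongruent", 20000,
                                  seed = 7)
  expect_lt(mean(inc$rt_s[!inc$correct]), mean(inc$rt_s[inc$correct]))
})

test_that("simulated RT distributions are right-skewed across parameter draws", {
  set.seed(8)
  skewed <- vapply(1:20, function(i) {
    p <- ssp_params(boundary = runif(1, .05, .1), p = runif(1, .3, .5),
                    sd_a = runif(1, 1, 2), r_d = runif(1, 15, 35),
                    t_er = runif(1, .2, .4))
    x <- simulate_conflict_trials(p, "congruent", 5000)
    mean(x$rt_s) > median(x$rt_s)
  }, logical(1))
  expect_gte(mean(skewed), 0.95)
})

test_that("interference time is the width/rate (SSP) or foil/selection (DSTP) ratio", {
  expect_equal(interference_time(ssp_params(sd_a = 1.8, r_d = 0.018 * 1000)),
               1.8 / 18)
  expect_equal(1.8 / 0.018, 100)  # same ratio on a per-ms rate scale
  expect_equal(interference_time(dstp_params(mu_fl = 0)), 0)
  # homogeneity: doubling the narrowing rate halves interference time
  expect_equal(interference_time(ssp_params(sd_a = 1.8, r_d = 36)),
               interference_time(ssp_params(sd_a = 1.8, r_d = 18)) / 2)
  expect_error(ssp_params(r_d = 0), "domain")
  expect_error(dstp_params(mu_ss = 0), "domain")
})
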