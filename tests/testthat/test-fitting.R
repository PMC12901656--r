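sim_both <- function(params, n, seed) {
  set.seed(seed)
  rbind(simulate_conflict_trials(params, "congruent", n),
        simulate_conflict_trials(params, "incongruent", n))
}

test_that("quantile bins carry their defining masses", {
  d <- data.frame(rt_s = seq(0.3, 0.8, length.out = 100), correct = TRUE,
                  congruency = "congruent")
  b <- bin_trials(d)$congruent
  expect_equal(b$correct_bin_props, c(.1, .2, .2, .2, .2, .1))
  expect_equal(b$error_bin_props, 0)
  expect_equal(b$accuracy, 1)
  expect_equal(length(b$correct_quantiles_s), 5)
})

test_that("bin proportions split by accuracy and the error-count rule", {
  d <- data.frame(rt_s = runif(100, .3, .9),
                  correct = rep(c(TRUE, FALSE), c(80, 20)),
                  congruency = "incongruent")
  b <- bin_trials(d)$incongruent
  expect_equal(sum(b$correct_bin_props), 0.8)
  expect_equal(sum(b$error_bin_props), 0.2)
  expect_equal(length(b$error_bin_props), 6)  # >= 11 errors: quantile bins
  # exactly 10 errors: single pooled error bin
  d2 <- data.frame(rt_s = runif(100, .3, .9),
                   correct = rep(c(TRUE, FALSE), c(90, 10)),
                   congruency = "incongruent")
  b2 <- bin_trials(d2)$incongruent
  expect_null(b2$error_quantiles_s)
  expect_equal(b2$error_bin_props, 10 / 100)
  expect_error(bin_trials(data.frame(rt_s = numeric(0), correct = logical(0),
                                     congruency = character(0))), "no congruent")
})

test_that("G-squared matches hand evaluation and its basic identities", {
  expect_equal(g_squared(c(.5, .5), c(.5, .5), 100), 0)
  hand <- 2 * 100 * (.5 * log(.5 / .25) + .5 * log(.5 / .75))
  expect_equal(g_squared(c(.5, .5), c(.25, .75), 100), hand)
  expect_equal(round(hand, 2), 28.77)
  # zero observed mass contributes nothing
  expect_equal(g_squared(c(1, 0), c(1, 0), 50, sim_n = 100),
               2 * 50 * log(1 / 1))
  # flooring predicted props never reduces the statistic
  loose <- g_squared(c(.5, .5), c(.001, .999), 100, sim_n = 1000)
  tight <- g_squared(c(.5, .5), c(.001, .999), 100, sim_n = 100)
  expect_gte(loose, tight)
  expect_error(g_squared(c(.5, .5), c(1), 100), "shape")
})

test_that("binned BIC penalises free parameters", {
  expect_equal(binned_bic(0, 5, 100), 5 * log(100))
  expect_equal(binned_bic(12.3, 0, 50), 12.3)
  expect_lt(binned_bic(10, 5, 1000), binned_bic(10, 7, 1000))
})

test_that("predicted proportions sum to one per condition", {
  obs <- bin_trials(sim_both(ssp_params(), 500, 1))
  sim <- simulate_conflict_trials(ssp_params(), "incongruent", 2000, seed = 2)
  pred <- condiff:::predicted_props(sim, obs$incongruent)
  expect_equal(sum(pred$correct_props) + sum(pred$error_props), 1,
               tolerance = 1e-9)
})

test_that("the objective discriminates gross misfit at common random numbers", {
  truth <- ssp_params()
  trials <- sim_both(truth, 2000, 3)
  obs <- bin_trials(trials)
  gof <- function(params, crn) {
    total <- 0
    for (cond in names(obs)) {
      sim <- simulate_conflict_trials(params, cond, 5000, seed = crn)
      pred <- condiff:::predicted_props(sim, obs[[cond]])
      total <- total + g_squared(
        c(obs[[cond]]$correct_bin_props, obs[[cond]]$error_bin_props),
        c(pred$correct_props, pred$error_props),
        obs[[cond]]$n_trials, 5000)
    }
    total
  }
  wrong <- ssp_params(p = truth$p * 2)
  expect_lte(gof(truth, 99), gof(wrong, 99))
})

test_that("fits are deterministic under identical settings and seed", {
  trials <- sim_both(ssp_params(), 400, 4)
  f1 <- fit_conflict_model(trials, "ssp", n_starts = 2, sim_n_step1 = 200,
                           sim_n_step2 = 500, seed = 7, maxit = c(60, 60))
  f2 <- fit_conflict_model(trials, "ssp", n_starts = 2, sim_n_step1 = 200,
                           sim_n_step2 = 500, seed = 7, maxit = c(60, 60))
  expect_identical(f1$par, f2$par)
  expect_identical(f1$g_squared, f2$g_squared)
  expect_s3_class(f1, "conflict_fit")
  expect_named(coef(f1), c("boundary", "p", "sd_a", "r_d", "t_er"))
  expect_equal(f1$binned_bic, f1$g_squared + 5 * log(f1$n_trials))
})

test_that("refinement does not typically worsen the objective", {
  worse <- 0
  for (i in 1:5) {
    trials <- sim_both(ssp_params(), 800, 100 + i)
    f <- fit_conflict_model(trials, "ssp", n_starts = 3, sim_n_step1 = 300,
                            sim_n_step2 = 3000, seed = i, maxit = c(80, 80))
    if (f$g_squared > f$step1_best_value) worse <- worse + 1
  }
  expect_lte(worse, 1)
})

test_that("QQ data pairs observed and predicted with ordered percentiles", {
  trials <- sim_both(ssp_params(), 800, 5)
  f <- fit_conflict_model(trials, "ssp", n_starts = 2, sim_n_step1 = 300,
                          sim_n_step2 = 2000, seed = 8, maxit = c(100, 100))
  qq <- qq_data(f, trials, sim_n = 5000, seed = 9)
  expect_equal(nrow(qq), 8)
  for (cond in c("congruent", "incongruent")) {
    rtq <- qq[qq$condition == cond & qq$measure != "accuracy", ]
    expect_true(all(diff(rtq$observed) >= 0))
    expect_true(all(diff(rtq$predicted) >= 0))
  }
  # a fit at this scale already tracks the observed median reasonably
  med <- qq[qq$measure == "q50", ]
  expect_true(all(abs(med$predicted - med$observed) / med$observed < 0.10))
})

test_that("binned BIC selects the generating model", {
  set.seed(41)
  dat_dstp <- sim_both(dstp_params(), 2000, 42)
  dat_ssp <- sim_both(ssp_params(), 2000, 43)
  pick <- function(trials) {
    fits <- lapply(c("ssp", "dstp"), function(m)
      fit_conflict_model(trials, m, n_starts = 2, sim_n_step1 = 500,
                         sim_n_step2 = 3000, seed = 11, maxit = c(150, 150)))
    c("ssp", "dstp")[which.min(vapply(fits, `[[`, numeric(1), "binned_bic"))]
  }
  expect_equal(pick(dat_dstp), "dstp")
  expect_equal(pick(dat_ssp), "ssp")
})
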