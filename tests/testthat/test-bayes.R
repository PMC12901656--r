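test_that("cell means average correct trimmed trials per design cell", {
  tr <- rbind(make_trials("p1", c(400, 600)),
              make_trials("p1", c(500, 700), congruency = "incongruent"))
  cm <- cell_means(tr)
  expect_equal(cm$mean_rt_ms, c(500, 600))
  # permuting trial order leaves means unchanged
  cm2 <- cell_means(tr[sample(nrow(tr)), ])
  expect_equal(cm2, cm, ignore_attr = TRUE)
  # a full 2x2 cohort yields 4 rows per participant
  cells <- sim_cells(30, seed = 2)
  tr3 <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i)
    make_trials(cells$participant_id[i], cells$mean_rt_ms[i],
                congruency = cells$congruency[i], cue = cells$cue[i])))
  expect_equal(nrow(cell_means(tr3)), 120)
})

test_that("the HDI is the shortest interval with the requested mass", {
  set.seed(1)
  x <- rnorm(20000)
  h <- hdi(x, 0.89)
  expect_equal(mean(x >= h[1] & x <= h[2]), 0.89, tolerance = 0.01)
  expect_equal(h, c(-1.6, 1.6), tolerance = 0.05)
  expect_equal(hdi(rep(2, 1000)), c(2, 2))
})

test_that("HDI+ROPE verdicts follow the >89% rule", {
  sd_y <- 30  # ROPE half-width 3 ms
  expect_equal(hdi_rope(rep(0, 2000), sd_y)$verdict, "accept_equivalence")
  expect_equal(hdi_rope(rep(0, 2000), sd_y)$pct_hdi_in_rope, 100)
  far <- hdi_rope(rnorm(5000, 50, 1), sd_y)
  expect_equal(far$pct_hdi_in_rope, 0)
  expect_equal(far$verdict, "reject_equivalence")
  # uniform on [-R, 3R]: about half the HDI mass sits inside the ROPE
  R <- 0.1 * sd_y
  set.seed(2)
  u <- runif(50000, -R, 3 * R)
  hr <- hdi_rope(u, sd_y)
  expect_equal(hr$pct_hdi_in_rope, 50, tolerance = 3)
  expect_equal(hr$verdict, "inconclusive")
})

test_that("HDI+ROPE percentage is invariant to joint rescaling", {
  set.seed(3)
  x <- rnorm(5000, 2, 4)
  a <- hdi_rope(x, 30)
  b <- hdi_rope(x * 7, 30 * 7)
  expect_equal(a$pct_hdi_in_rope, b$pct_hdi_in_rope)
  expect_equal(a$verdict, b$verdict)
})

test_that("evidence ratios report the favoured model to two decimals", {
  expect_equal(evidence_ratio(0.11), 9.09)
  expect_equal(evidence_ratio(0.30), 3.33)
  expect_equal(evidence_ratio(1.0), 1.00)
  for (bf in c(0.02, 0.5, 3, 40)) {
    expect_equal(evidence_ratio(bf), evidence_ratio(1 / bf))
  }
  expect_error(evidence_ratio(0), "> 0")
  expect_error(evidence_ratio(-2), "> 0")
})

test_that("the JZS Bayes factor matches a Monte-Carlo g-mixture oracle", {
  set.seed(4)
  r <- sqrt(2) / 2
  mc_oracle <- function(t, n) {
    g <- 1 / rgamma(2e6, shape = 0.5, rate = 0.5)
    w <- 1 + n * g * r^2
    nu <- n - 1
    mean(w^-0.5 * (1 + t^2 / (w * nu))^(-(nu + 1) / 2)) /
      (1 + t^2 / nu)^(-(nu + 1) / 2)
  }
  for (case in list(c(0.5, 50), c(2.5, 80), c(4, 120))) {
    expect_equal(condiff:::jzs_bf10(case[1], case[2], r),
                 mc_oracle(case[1], case[2]), tolerance = 0.02)
  }
  # no effect, large n: evidence favours the null
  expect_lt(condiff:::jzs_bf10(0, 200, r), 0.2)
})

test_that("the interaction Bayes factor is deterministic and calibrated", {
  cells <- sim_cells(60, b_interaction = 0, seed = 5)
  b1 <- interaction_bf(cells)
  b2 <- interaction_bf(cells, seed = 99)
  expect_identical(as.numeric(b1), as.numeric(b2))
  expect_match(attr(b1, "method"), "JZS")
  # direction under null and alternative (few replicates; the acceptance
  # suite runs the calibrated version)
  bf_null <- vapply(1:6, function(i)
    as.numeric(interaction_bf(sim_cells(100, b_interaction = 0, seed = i))),
    numeric(1))
  bf_alt <- vapply(1:6, function(i)
    as.numeric(interaction_bf(sim_cells(100, b_interaction = 30,
                                        seed = 50 + i))), numeric(1))
  expect_gte(mean(bf_null < 1), 0.5)
  expect_gte(mean(bf_alt > 10), 0.8)
  # participants with missing cells are dropped, not fatal
  cells_miss <- cells[-1, ]
  expect_equal(attr(interaction_bf(cells_miss), "dropped_participants"),
               cells$participant_id[1])
})

test_that("the mixed model recovers simulated fixed effects", {
  cells <- sim_cells(200, b_congruency = 40, seed = 6)
  fit <- fit_mixed_model(cells, chains = 2, iter = 2500, warmup = 1000,
                         seed = 7)
  expect_s3_class(fit, "mixed_posterior")
  expect_lt(abs(fit$summary["beta_congruency", "mean"] - 40), 3)
  expect_lt(fit$rhat_max, 1.05)
  expect_equal(colnames(fit$draws)[4], "beta_interaction")
  # determinism under the seed
  fit2 <- fit_mixed_model(cells, chains = 2, iter = 2500, warmup = 1000,
                          seed = 7)
  expect_identical(fit$summary, fit2$summary)
})

test_that("the interaction credible interval covers a true null", {
  covered <- vapply(1:5, function(i) {
    cells <- sim_cells(60, b_interaction = 0, seed = 400 + i)
    fit <- fit_mixed_model(cells, chains = 2, iter = 1500, warmup = 600,
                           seed = i)
    ci <- fit$summary["beta_interaction", c("ci_lower", "ci_upper")]
    ci[1] <= 0 && 0 <= ci[2]
  }, logical(1))
  expect_gte(mean(covered), 0.8)
})

test_that("the sequential controller stops at the first threshold crossing", {
  cells <- sim_cells(200, seed = 8)
  script <- function(values) {
    calls <- 0
    function(sub) {
      calls <<- calls + 1
      n <- length(unique(sub$participant_id))
      values[[as.character(n)]]
    }
  }
  bf_fun <- script(list(`80` = 0.5, `100` = 12))
  tr <- sequential_controller(cells, bf_fun = bf_fun)
  expect_equal(tr$decision, "stop_evidence_h1")
  expect_equal(tr$final_n, 100)
  expect_equal(tr$interim_ns, c(80, 100))
  expect_equal(tr$interim_bfs, c(0.5, 12))

  flat <- sequential_controller(cells, bf_fun = function(sub) 1)
  expect_equal(flat$decision, "stop_nmax")
  expect_equal(flat$final_n, 200)
  expect_equal(flat$interim_ns, seq(80, 200, by = 20))

  h0 <- sequential_controller(cells, bf_fun = function(sub) 0.05)
  expect_equal(h0$decision, "stop_evidence_h0")
  expect_equal(h0$final_n, 80)
  expect_equal(length(h0$interim_bfs), 1)

  expect_error(sequential_controller(sim_cells(50, seed = 9)), "exhausted")
})

test_that("the controller never evaluates past the first stopping point", {
  cells <- sim_cells(200, seed = 10)
  calls <- 0
  bf_fun <- function(sub) { calls <<- calls + 1; 100 }
  sequential_controller(cells, bf_fun = bf_fun)
  expect_equal(calls, 1)
})

test_that("a null cohort run through the full chain favours the main-effects model", {
  # reduced-scale version of the headline: majority of null cohorts give
  # BF10 < 1 through schedule -> simulate -> trim -> cell means -> BF
  wins <- vapply(1:3, function(i) {
    coh <- generate_cohort(cohort_spec(n_participants = 40, seed = 600 + i),
                           gaze = FALSE)
    cm <- cell_means(trim_rts(coh$trials)$trials)
    as.numeric(interaction_bf(cm)) < 1
  }, logical(1))
  expect_gte(sum(wins), 2)
})
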