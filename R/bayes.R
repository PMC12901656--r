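#' Participant-averaged cell means
#'
#' Arithmetic mean RT per participant x congruency x cue on correct,
#' non-catch trials (supply trimmed data, see [trim_rts()]). These cell
#' means are the outcome variable of the mixed-model analysis.
#'
#' @param trials trimmed trial data.
#' @return A data.frame `participant_id`, `congruency`, `cue`, `mean_rt_ms`
#'   (one row per non-empty cell; empty cells are simply absent).
#' @export
cell_means <- function(trials) {
  d <- trials[!trials$is_catch & trials$correct & !is.na(trials$rt_ms) &
                trials$congruency != "catch", ]
  out <- aggregate(rt_ms ~ participant_id + congruency + cue, data = d,
                   FUN = mean)
  names(out)[4] <- "mean_rt_ms"
  out[order(out$participant_id, out$congruency, out$cue), , drop = FALSE]
}

#' Bayesian random-intercept mixed model on cell means
#'
#' Fits `mean_rt ~ congruency * cue + (1 | participant)` by Gibbs sampling
#' (JAGS), with treatment coding (reference: congruent, informative) so the
#' fixed effects are the incongruent effect, the non-informative-cue effect
#' and their interaction, all in ms. Priors are weakly informative and
#' data-scaled: slopes ~ Normal(0, (2.5 sd(y))^2), intercept ~
#' Normal(mean(y), (5 sd(y))^2), residual and intercept sds ~ Uniform(0,
#' 5 sd(y)).
#'
#' @param cells output of [cell_means()].
#' @param chains,iter,warmup MCMC settings: `iter` draws per chain of which
#'   the first `warmup` are discarded.
#' @param seed integer seed (per-chain RNGs are derived from it).
#' @return An object of class `mixed_posterior`: `$draws` (matrix of
#'   retained draws across chains: `beta0`, `beta_congruency`, `beta_cue`,
#'   `beta_interaction`, `sigma`, `sigma_participant`), `$summary` (mean and
#'   95% credible intervals), `$hdi89_interaction`, `$rhat_max`,
#'   `$outcome_sd_ms`.
#' @export
fit_mixed_model <- function(cells, chains = 4, iter = 5000, warmup = 2000,
                            seed = 1) {
  if (length(unique(cells$participant_id)) < 2)
    stop_domain("at least 2 participants are required")
  pid <- as.integer(factor(cells$participant_id))
  y <- cells$mean_rt_ms
  xc <- as.numeric(cells$congruency == "incongruent")
  xq <- as.numeric(cells$cue == "non_informative")
  sdy <- sd(y)
  model <- "
  model {
    for (i in 1:N) {
      y[i] ~ dnorm(b0 + b1*xc[i] + b2*xq[i] + b3*xc[i]*xq[i] + u[pid[i]],
                   tau_e)
    }
    for (j in 1:J) { u[j] ~ dnorm(0, tau_u) }
    b0 ~ dnorm(mu_y, prec0)
    b1 ~ dnorm(0, prec_b)
    b2 ~ dnorm(0, prec_b)
    b3 ~ dnorm(0, prec_b)
    sigma_e ~ dunif(0, sd_cap)
    sigma_u ~ dunif(0, sd_cap)
    tau_e <- pow(sigma_e, -2)
    tau_u <- pow(sigma_u, -2)
  }"
  data <- list(y = y, xc = xc, xq = xq, pid = pid, N = length(y),
               J = max(pid), mu_y = mean(y), prec0 = (5 * sdy)^-2,
               prec_b = (2.5 * sdy)^-2, sd_cap = 5 * sdy)
  inits <- lapply(seq_len(chains), function(k)
    list(.RNG.name = "base::Mersenne-Twister", .RNG.seed = seed * 1000 + k))
  jm <- rjags::jags.model(textConnection(model), data = data, inits = inits,
                          n.chains = chains, quiet = TRUE)
  stats::update(jm, warmup, progress.bar = "none")
  samp <- rjags::coda.samples(jm, c("b0", "b1", "b2", "b3", "sigma_e",
                                    "sigma_u"),
                              iter - warmup, progress.bar = "none")
  rhat <- tryCatch(
    max(coda::gelman.diag(samp, autoburnin = FALSE,
                          multivariate = FALSE)$psrf[, 1]),
    error = function(e) NA_real_)
  draws <- as.matrix(samp)
  colnames(draws) <- c("beta0", "beta_congruency", "beta_cue",
                       "beta_interaction", "sigma", "sigma_participant")
  qs <- t(apply(draws, 2, function(v) c(mean = mean(v),
                                        quantile(v, c(.025, .975)))))
  colnames(qs) <- c("mean", "ci_lower", "ci_upper")
  out <- structure(list(
    draws = draws,
    summary = qs,
    hdi89_interaction = hdi(draws[, "beta_interaction"], 0.89),
    rhat_max = rhat,
    rhat_warning = is.finite(rhat) && rhat > 1.05,
    outcome_sd_ms = sdy,
    n_participants = max(pid),
    n_obs = length(y),
    chains = chains, iter = iter, warmup = warmup, seed = seed
  ), class = "mixed_posterior")
  out
}

#' @export
print.mixed_posterior <- function(x, ...) {
  cat("Bayesian mixed model: mean_rt ~ congruency * cue + (1 | participant)\n")
  cat(sprintf("  %d participants, %d cell means; %d chains x %d draws (%d warmup)\n",
              x$n_participants, x$n_obs, x$chains, x$iter, x$warmup))
  print(round(x$summary, 2))
  cat(sprintf("  89%% HDI (interaction): [%.2f, %.2f]   max Rhat = %.3f\n",
              x$hdi89_interaction[1], x$hdi89_interaction[2], x$rhat_max))
  if (isTRUE(x$rhat_warning)) cat("  warning: Rhat > 1.05\n")
  invisible(x)
}

#' @export
coef.mixed_posterior <- function(object, ...) object$summary[, "mean"]

#' Highest-density interval
#'
#' Shortest interval containing `prob` of the draws (sorted-window method).
#'
#' @param x numeric draws.
#' @param prob interval mass.
#' @return Length-2 vector `c(lower, upper)`.
#' @export
hdi <- function(x, prob = 0.89) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  k <- max(1L, ceiling(prob * n))
  if (k >= n) return(c(x[1], x[n]))
  widths <- x[(k + 1):n] - x[1:(n - k)]
  i <- which.min(widths)
  c(x[i], x[i + k])
}

#' Default-prior Bayes factor for the congruency x cue interaction
#'
#' In the balanced 2 x 2 within-participant design the interaction is
#' carried entirely by the per-participant double difference
#' `(incongruent - congruent | non-informative) - (incongruent - congruent |
#' informative)`; the random intercept and both main effects are orthogonal
#' to it and common to both models being compared. The Bayes factor for the
#' interaction-vs-main-effects comparison therefore reduces to a one-sample
#' default Bayes factor on these contrasts, computed here with the
#' Jeffreys-Zellner-Siow prior (Cauchy scale `rscale` on the standardized
#' effect) by numerical integration over the g-mixture representation. The
#' computation is deterministic.
#'
#' @param cells output of [cell_means()]; participants lacking any of the
#'   four cells are dropped (their ids are recorded in the
#'   `dropped_participants` attribute).
#' @param rscale Cauchy prior scale on the standardized effect.
#' @param seed accepted for interface symmetry; unused (the estimate is
#'   deterministic).
#' @return `bf10` as a single number with attributes `method`, `t_stat`,
#'   `n`.
#' @export
interaction_bf <- function(cells, rscale = sqrt(2) / 2, seed = NULL) {
  cc <- interaction_contrasts(cells)
  if (length(cc$contrast) < 2)
    stop_domain("need at least 2 participants with complete cells")
  t_stat <- mean(cc$contrast) / (sd(cc$contrast) / sqrt(length(cc$contrast)))
  bf <- jzs_bf10(t_stat, length(cc$contrast), rscale)
  if (!is.finite(bf)) stop_domain("non-finite Bayes factor")
  structure(bf, method = "JZS one-sample BF on interaction contrasts",
            t_stat = t_stat, n = length(cc$contrast),
            dropped_participants = cc$dropped)
}

interaction_contrasts <- function(cells) {
  sp <- split(cells, cells$participant_id)
  pull <- function(d, cong, cue) {
    v <- d$mean_rt_ms[d$congruency == cong & d$cue == cue]
    if (length(v) == 1) v else NA_real_
  }
  con <- vapply(sp, function(d)
    (pull(d, "incongruent", "non_informative") -
       pull(d, "congruent", "non_informative")) -
      (pull(d, "incongruent", "informative") -
         pull(d, "congruent", "informative")), numeric(1))
  list(contrast = unname(con[!is.na(con)]), dropped = names(con)[is.na(con)])
}

# JZS one-sample BF10 (Cauchy prior scale r on the standardized effect):
# marginal likelihood ratio integrated over g ~ InverseGamma(1/2, 1/2)
jzs_bf10 <- function(t, n, r = sqrt(2) / 2) {
  nu <- n - 1
  log_null <- -(nu + 1) / 2 * log1p(t^2 / nu)
  f <- function(g) {
    w <- 1 + n * g * r^2
    exp(-0.5 * log(w) - (nu + 1) / 2 * log1p(t^2 / (w * nu)) - log_null) *
      (2 * pi)^-0.5 * g^-1.5 * exp(-1 / (2 * g))
  }
  integrate(f, 0, Inf, rel.tol = 1e-8)$value
}

#' HDI + ROPE equivalence decision
#'
#' The region of practical equivalence is `+/- rope_scale` standardized
#' units, realized on the outcome scale as `+/- rope_scale *
#' outcome_sd_ms`. The reported percentage is the share of posterior draws
#' inside the 89% HDI that fall within the ROPE; equivalence is accepted
#' when more than 89% of the HDI lies inside the ROPE and rejected when
#' more than 89% lies outside, otherwise the decision is inconclusive.
#'
#' @param draws posterior draws of the interaction coefficient (ms).
#' @param outcome_sd_ms sd of the model's outcome variable (cell-mean RTs).
#' @param rope_scale standardized half-width of the ROPE.
#' @param hdi_prob HDI mass.
#' @return A list: `hdi89`, `rope_bounds_ms`, `pct_hdi_in_rope` (0-100),
#'   `verdict` ("accept_equivalence", "reject_equivalence",
#'   "inconclusive").
#' @export
hdi_rope <- function(draws, outcome_sd_ms, rope_scale = 0.1,
                     hdi_prob = 0.89) {
  stopifnot(length(draws) >= 1000)
  h <- hdi(draws, hdi_prob)
  rope <- c(-1, 1) * rope_scale * outcome_sd_ms
  inside_hdi <- draws >= h[1] & draws <= h[2]
  pct <- 100 * mean(draws[inside_hdi] >= rope[1] &
                      draws[inside_hdi] <= rope[2])
  verdict <- if (pct > 89) "accept_equivalence"
             else if (100 - pct > 89) "reject_equivalence"
             else "inconclusive"
  list(hdi89 = h, rope_bounds_ms = rope, pct_hdi_in_rope = pct,
       verdict = verdict)
}

#' Evidence ratio for the favoured model
#'
#' Expresses a Bayes factor as "times more likely" for whichever model the
#' data favour: `bf10` itself when it is at least 1, otherwise `1/bf10`,
#' rounded to two decimals (e.g. BF10 = 0.11 reports the main-effects model
#' as 9.09 times more likely).
#'
#' @param bf10 Bayes factor (> 0) for the interaction model.
#' @export
evidence_ratio <- function(bf10) {
  bf10 <- as.numeric(bf10)
  if (!is.finite(bf10) || bf10 <= 0) stop_domain("bf10 must be > 0")
  round(if (bf10 >= 1) bf10 else 1 / bf10, 2)
}

#' Sequential Bayes-factor design controller
#'
#' Replays the registered sequential design over an ordered participant
#' stream: the interaction Bayes factor is evaluated at `n_min` participants
#' and every `step` thereafter, stopping at the first interim where
#' `bf > thresholds[1]` (evidence for the interaction) or
#' `bf < thresholds[2]` (evidence for the main-effects model), else at
#' `n_max`. No interim beyond the first stopping point is evaluated.
#'
#' @param cells cell means ([cell_means()]) for the full stream;
#'   participants enter in order of first appearance.
#' @param n_min,n_max,step design bounds and interim spacing.
#' @param thresholds stopping thresholds `c(upper, lower)`.
#' @param bf_fun function mapping a cell-mean subset to a Bayes factor
#'   (defaults to [interaction_bf()]).
#' @return An object of class `sequential_trace`: `interim_ns`,
#'   `interim_bfs`, `decision` ("stop_evidence_h1", "stop_evidence_h0",
#'   "stop_nmax"), `final_n`.
#' @export
sequential_controller <- function(cells, n_min = 80, n_max = 200, step = 20,
                                  thresholds = c(10, 1 / 10),
                                  bf_fun = interaction_bf) {
  ids <- unique(cells$participant_id)
  if (length(ids) < n_min)
    stop_domain("participant stream exhausted before n_min (have ",
                length(ids), ", need ", n_min, ")")
  n_cap <- min(n_max, length(ids))
  ns <- unique(c(seq(n_min, n_cap, by = step), n_cap))
  interim_ns <- integer(0)
  interim_bfs <- numeric(0)
  decision <- "stop_nmax"
  for (n in ns) {
    sub <- cells[cells$participant_id %in% ids[seq_len(n)], , drop = FALSE]
    bf <- as.numeric(bf_fun(sub))
    interim_ns <- c(interim_ns, n)
    interim_bfs <- c(interim_bfs, bf)
    if (bf > thresholds[1]) { decision <- "stop_evidence_h1"; break }
    if (bf < thresholds[2]) { decision <- "stop_evidence_h0"; break }
  }
  structure(list(interim_ns = interim_ns, interim_bfs = interim_bfs,
                 decision = decision, final_n = interim_ns[length(interim_ns)]),
            class = "sequential_trace")
}

#' @export
print.sequential_trace <- function(x, ...) {
  cat("Sequential BF design:\n")
  print(data.frame(n = x$interim_ns, bf10 = signif(x$interim_bfs, 3)))
  cat("decision:", x$decision, " final n:", x$final_n, "\n")
  invisible(x)
}

#' One-call interaction inference
#'
#' Convenience wrapper running the full inferential chain on cell means:
#' mixed-model posterior ([fit_mixed_model()]), interaction Bayes factor
#' ([interaction_bf()]) and the HDI + ROPE decision ([hdi_rope()]).
#'
#' @inheritParams fit_mixed_model
#' @param rscale Cauchy prior scale for the Bayes factor.
#' @return A list of class `posterior_summary`: the fixed-effect summaries
#'   with 95% credible intervals, `hdi89_interaction`, `rope_bounds_ms`,
#'   `pct_hdi_in_rope`, `rope_verdict`, `bf10_interaction`,
#'   `evidence_ratio`, `rhat_max`, and the underlying `model` object.
#' @export
infer_interaction <- function(cells, chains = 4, iter = 5000, warmup = 2000,
                              seed = 1, rscale = sqrt(2) / 2) {
  fit <- fit_mixed_model(cells, chains = chains, iter = iter,
                         warmup = warmup, seed = seed)
  bf <- interaction_bf(cells, rscale = rscale)
  hr <- hdi_rope(fit$draws[, "beta_interaction"], fit$outcome_sd_ms)
  structure(list(
    beta_congruency = fit$summary["beta_congruency", ],
    beta_cue = fit$summary["beta_cue", ],
    beta_interaction = fit$summary["beta_interaction", ],
    hdi89_interaction = hr$hdi89,
    rope_bounds_ms = hr$rope_bounds_ms,
    pct_hdi_in_rope = hr$pct_hdi_in_rope,
    rope_verdict = hr$verdict,
    bf10_interaction = as.numeric(bf),
    bf_method = attr(bf, "method"),
    evidence_ratio = evidence_ratio(bf),
    rhat_max = fit$rhat_max,
    model = fit
  ), class = "posterior_summary")
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat("Interaction inference on participant-averaged RTs\n")
  b <- rbind(congruency = x$beta_congruency, cue = x$beta_cue,
             interaction = x$beta_interaction)
  print(round(b, 2))
  cat(sprintf("  BF10(interaction) = %.3g (%s times more likely: %s)\n",
              x$bf10_interaction, x$evidence_ratio,
              if (x$bf10_interaction >= 1) "interaction" else "main effects"))
  cat(sprintf("  89%% HDI [%.2f, %.2f], ROPE [%.2f, %.2f], %.0f%% in ROPE -> %s\n",
              x$hdi89_interaction[1], x$hdi89_interaction[2],
              x$rope_bounds_ms[1], x$rope_bounds_ms[2], x$pct_hdi_in_rope,
              x$rope_verdict))
  invisible(x)
}
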