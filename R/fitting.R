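#' Quantile-bin RT/accuracy summaries
#'
#' Summarises one condition's RT distribution into the quantile-binned form
#' used by the G-squared objective: RT quantiles of correct trials (defaults
#' .1/.3/.5/.7/.9, linear interpolation), the six inter-quantile bin
#' proportions scaled by overall accuracy, and error-trial bins built the
#' same way when at least `min_errors` errors are available, otherwise a
#' single pooled error bin.
#'
#' @param trials data.frame with columns `rt_s` (or `rt_ms`), `correct` and
#'   `congruency`; only "congruent"/"incongruent" rows are summarised.
#' @param quantiles correct-RT quantile set.
#' @param min_errors minimum error count for error-quantile binning.
#' @return A named list (one element per condition) of `binned_summary`
#'   objects with fields `condition`, `correct_quantiles_s`,
#'   `correct_bin_props`, `error_quantiles_s`, `error_bin_props`,
#'   `n_trials`, `n_correct`, `n_error`, `accuracy`.
#' @export
bin_trials <- function(trials, quantiles = c(.1, .3, .5, .7, .9),
                       min_errors = 11) {
  if (is.null(trials$rt_s)) trials$rt_s <- trials$rt_ms / 1000
  conds <- intersect(c("congruent", "incongruent"), unique(trials$congruency))
  if (!length(conds)) stop_domain("no congruent/incongruent trials to bin")
  mass <- diff(c(0, quantiles, 1))
  out <- lapply(conds, function(cond) {
    d <- trials[trials$congruency == cond & !is.na(trials$rt_s), ]
    if (!nrow(d)) stop_domain("zero trials in condition ", cond)
    corr <- d$rt_s[d$correct]
    errs <- d$rt_s[!d$correct]
    if (!length(corr)) stop_domain("no correct trials in condition ", cond)
    acc <- length(corr) / nrow(d)
    eq <- NULL
    ep <- 1 - acc
    if (length(errs) >= min_errors) {
      eq <- unname(quantile(errs, quantiles, type = 7))
      ep <- mass * (1 - acc)
    }
    structure(list(
      condition = cond,
      correct_quantiles_s = unname(quantile(corr, quantiles, type = 7)),
      correct_bin_props = mass * acc,
      error_quantiles_s = eq,
      error_bin_props = ep,
      n_trials = nrow(d),
      n_correct = length(corr),
      n_error = length(errs),
      accuracy = acc
    ), class = "binned_summary")
  })
  names(out) <- conds
  out
}

# predicted bin proportions for one condition: fraction of simulated trials
# that are correct/error AND fall into the observed quantile bins
predicted_props <- function(sim, summary) {
  edges_c <- c(-Inf, summary$correct_quantiles_s, Inf)
  n <- nrow(sim)
  pc <- as.vector(table(cut(sim$rt_s[sim$correct], edges_c))) / n
  if (!is.null(summary$error_quantiles_s)) {
    edges_e <- c(-Inf, summary$error_quantiles_s, Inf)
    pe <- as.vector(table(cut(sim$rt_s[!sim$correct], edges_e))) / n
  } else {
    pe <- sum(!sim$correct) / n
  }
  list(correct_props = pc, error_props = pe)
}

#' Likelihood-ratio chi-square statistic
#'
#' `G^2 = 2 * sum(n * p_obs * log(p_obs / p_pred))` over matching bins.
#' Observed bins with zero mass contribute nothing; predicted proportions
#' are floored at `1 / (10 * sim_n)` to guard against log(0) from finite
#' simulation.
#'
#' @param p_obs,p_pred observed and predicted bin proportions (same length).
#' @param n number of observed trials behind `p_obs`.
#' @param sim_n number of simulated trials behind `p_pred` (sets the floor);
#'   `NULL` for exact predictions (floor at machine epsilon).
#' @return Non-negative statistic.
#' @examples
#' g_squared(c(.5, .5), c(.25, .75), n = 100)  # ~28.77
#' @export
g_squared <- function(p_obs, p_pred, n, sim_n = NULL) {
  if (length(p_obs) != length(p_pred))
    stop_domain("observed and predicted proportions differ in shape")
  floor_p <- if (is.null(sim_n)) .Machine$double.eps else 1 / (10 * sim_n)
  p_pred <- pmax(p_pred, floor_p)
  keep <- p_obs > 0
  2 * sum(n * p_obs[keep] * log(p_obs[keep] / p_pred[keep]))
}

#' Binned Bayesian information criterion
#'
#' `G^2 + k * log(N)`: the G-squared fit statistic penalised by the number
#' of free parameters, used to compare SSP (k = 5) and DSTP (k = 7) fits.
#'
#' @param g2 G-squared statistic.
#' @param k_params number of free model parameters.
#' @param n_trials number of trials the model was fitted to.
#' @export
binned_bic <- function(g2, k_params, n_trials) {
  stopifnot(n_trials >= 1)
  g2 + k_params * log(n_trials)
}

par_info <- function(model) {
  if (model == "ssp") {
    list(names = c("boundary", "p", "sd_a", "r_d", "t_er"),
         lower_open = c(TRUE, TRUE, TRUE, TRUE, FALSE),
         make = function(v) ssp_params(v[1], v[2], v[3], v[4], v[5]))
  } else {
    list(names = c("boundary", "boundary_C", "mu_t", "mu_fl", "mu_ss",
                   "mu_rs2", "t_er"),
         lower_open = c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, FALSE),
         make = function(v) dstp_params(v[1], v[2], v[3], v[4], v[5], v[6],
                                        v[7]))
  }
}

in_domain <- function(v, info) {
  ok <- ifelse(info$lower_open, v > 0, v >= 0)
  # mu_t may take any sign in principle, but fits are anchored to positive
  # target input; keep it non-negative like the start distribution
  all(ok) && all(is.finite(v))
}

#' Fit a conflict diffusion model by simulation-based G-squared minimisation
#'
#' Implements the two-step fitting routine: a broad search running
#' Nelder-Mead from `n_starts` random starting points (each parameter drawn
#' from a normal with the default start value as mean and 1/`start_sd_divisor`
#' of it as sd, truncated to its domain) with `sim_n_step1` simulated trials
#' per condition per objective evaluation, followed by a refinement run from
#' the step-1 best with `sim_n_step2` simulated trials. Common random
#' numbers are used across objective evaluations within one Nelder-Mead run
#' (re-drawn per start) to damp stochastic-objective jitter.
#'
#' @param trials trimmed trial data (columns `rt_s` or `rt_ms`, `correct`,
#'   `congruency`; both congruency conditions must be present).
#' @param model "ssp" or "dstp".
#' @param n_starts number of random starting points for step 1.
#' @param sim_n_step1,sim_n_step2 simulated trials per condition per
#'   objective evaluation in each step.
#' @param start_means optional named start means; defaults to the shipped
#'   model defaults ([ssp_params()]/[dstp_params()]).
#' @param start_sd_divisor start sd = start mean / this divisor.
#' @param seed integer seed making the whole fit reproducible.
#' @param quantiles correct-RT quantile set for the binned objective.
#' @param dt_s,noise_sd simulator settings (see
#'   [simulate_conflict_trials()]).
#' @param maxit Nelder-Mead iteration caps for steps 1 and 2.
#' @return An object of class `conflict_fit` with the fitted parameter
#'   object (`$params`), `$g_squared`, `$binned_bic` and the fit settings.
#' @seealso [qq_data()] for observed-vs-predicted diagnostics.
#' @export
fit_conflict_model <- function(trials, model = c("ssp", "dstp"),
                               n_starts = 50, sim_n_step1 = 1000,
                               sim_n_step2 = 50000, start_means = NULL,
                               start_sd_divisor = 5, seed = NULL,
                               quantiles = c(.1, .3, .5, .7, .9),
                               dt_s = 0.001, noise_sd = 0.1,
                               maxit = c(500, 500)) {
  model <- match.arg(model)
  info <- par_info(model)
  observed <- bin_trials(trials, quantiles)
  if (!all(c("congruent", "incongruent") %in% names(observed)))
    stop_domain("both congruency conditions are required for fitting")
  defaults <- if (model == "ssp") unlist(ssp_params()) else unlist(dstp_params())
  if (!is.null(start_means)) defaults[names(start_means)] <- start_means
  mu0 <- defaults[info$names]

  objective <- function(theta, sim_n, crn_seed) {
    if (!in_domain(theta, info)) return(1e10)
    params <- info$make(theta)
    g2 <- 0
    for (k in seq_along(observed)) {
      obs <- observed[[k]]
      sim <- simulate_conflict_trials(params, obs$condition, sim_n,
                                      seed = crn_seed + k, dt_s = dt_s,
                                      noise_sd = noise_sd)
      pred <- predicted_props(sim, obs)
      g2 <- g2 + g_squared(c(obs$correct_bin_props, obs$error_bin_props),
                           c(pred$correct_props, pred$error_props),
                           obs$n_trials, sim_n)
    }
    g2
  }

  draw_start <- function() {
    for (i in 1:1000) {
      v <- rnorm(length(mu0), mu0, abs(mu0) / start_sd_divisor)
      if (in_domain(v, info)) return(v)
    }
    stop_domain("could not draw an in-domain starting point after 1000 ",
                "attempts")
  }

  with_seed(seed, {
    step1 <- lapply(seq_len(n_starts), function(i) {
      start <- draw_start()
      crn <- sample.int(2^30, 1)
      o <- optim(start, objective, sim_n = sim_n_step1, crn_seed = crn,
                 method = "Nelder-Mead",
                 control = list(maxit = maxit[1], reltol = 1e-6))
      list(par = o$par, value = o$value)
    })
    vals <- vapply(step1, `[[`, numeric(1), "value")
    best <- step1[[which.min(vals)]]
    crn2 <- sample.int(2^30, 1)
    o2 <- optim(best$par, objective, sim_n = sim_n_step2, crn_seed = crn2,
                method = "Nelder-Mead",
                control = list(maxit = maxit[2], reltol = 1e-6))
    n_total <- sum(vapply(observed, `[[`, numeric(1), "n_trials"))
    g2 <- o2$value
    fit <- structure(list(
      model = model,
      params = info$make(o2$par),
      par = setNames(o2$par, info$names),
      g_squared = g2,
      binned_bic = binned_bic(g2, length(info$names), n_total),
      n_starts = n_starts,
      sim_n_step1 = sim_n_step1,
      sim_n_step2 = sim_n_step2,
      seed = seed,
      converged = o2$convergence == 0 || o2$value <= min(vals),
      step1_values = vals,
      step1_best_value = min(vals),
      start_means = mu0,
      start_sd_divisor = start_sd_divisor,
      observed = observed,
      n_trials = n_total,
      settings = list(quantiles = quantiles, dt_s = dt_s,
                      noise_sd = noise_sd, maxit = maxit)
    ), class = "conflict_fit")
    fit
  })
}

#' @export
print.conflict_fit <- function(x, ...) {
  cat("Conflict diffusion model fit (", toupper(x$model), ")\n", sep = "")
  cat("  parameters:\n")
  print(round(x$par, 4))
  cat(sprintf("  G^2 = %.2f   binned BIC = %.2f   (N = %d trials)\n",
              x$g_squared, x$binned_bic, x$n_trials))
  cat(sprintf("  interference time = %.4f\n", interference_time(x$params)))
  cat(sprintf("  %d starts, %d / %d simulated trials per evaluation\n",
              x$n_starts, x$sim_n_step1, x$sim_n_step2))
  invisible(x)
}

#' @export
coef.conflict_fit <- function(object, ...) object$par

#' @export
summary.conflict_fit <- function(object, ...) {
  out <- list(model = object$model, par = object$par,
              interference_time = interference_time(object$params),
              g_squared = object$g_squared, binned_bic = object$binned_bic,
              n_trials = object$n_trials, converged = object$converged)
  class(out) <- "summary.conflict_fit"
  out
}

#' @export
print.summary.conflict_fit <- function(x, ...) {
  cat(toupper(x$model), "fit:",
      paste(names(x$par), round(x$par, 4), sep = "=", collapse = " "), "\n")
  cat(sprintf("interference=%.4f G2=%.2f bBIC=%.2f N=%d converged=%s\n",
              x$interference_time, x$g_squared, x$binned_bic, x$n_trials,
              x$converged))
  invisible(x)
}

#' @export
simulate.conflict_fit <- function(object, nsim = 1000, seed = NULL, ...) {
  out <- with_seed(seed, {
    do.call(rbind, lapply(c("congruent", "incongruent"), function(cond)
      simulate_conflict_trials(object$params, cond, nsim,
                               dt_s = object$settings$dt_s,
                               noise_sd = object$settings$noise_sd)))
  })
  out
}

#' Observed versus predicted QQ data
#'
#' For each condition, pairs the observed accuracy and the 25th/50th/75th
#' percentiles of correct RTs with the same quantities computed from trials
#' simulated at the fitted parameters.
#'
#' @param fit a [fit_conflict_model()] result.
#' @param trials the observed trials the fit was computed on.
#' @param sim_n simulated trials per condition (defaults to the fit's
#'   refinement size).
#' @param seed optional seed for the predictive simulation.
#' @return A data.frame with columns `condition`, `measure` ("accuracy",
#'   "q25", "q50", "q75"), `observed`, `predicted`.
#' @export
qq_data <- function(fit, trials, sim_n = fit$sim_n_step2, seed = NULL) {
  stopifnot(inherits(fit, "conflict_fit"))
  if (is.null(trials$rt_s)) trials$rt_s <- trials$rt_ms / 1000
  probs <- c(.25, .5, .75)
  rows <- with_seed(seed, lapply(c("congruent", "incongruent"), function(cond) {
    d <- trials[trials$congruency == cond & !is.na(trials$rt_s), ]
    sim <- simulate_conflict_trials(fit$params, cond, sim_n,
                                    dt_s = fit$settings$dt_s,
                                    noise_sd = fit$settings$noise_sd)
    data.frame(
      condition = cond,
      measure = c("accuracy", "q25", "q50", "q75"),
      observed = c(mean(d$correct),
                   unname(quantile(d$rt_s[d$correct], probs))),
      predicted = c(mean(sim$correct),
                    unname(quantile(sim$rt_s[sim$correct], probs)))
    )
  }))
  do.call(rbind, rows)
}
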