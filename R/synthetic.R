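#' Synthetic cohort specification
#'
#' Describes a complete synthetic experiment with known ground truth:
#' per-participant conflict-model parameters are drawn from a truncated
#' normal population, every scheduled trial is simulated from the generator
#' model, and gaze streams, cue-association ratings and coder labels are
#' generated alongside. The defaults emulate the standard design: 304-trial
#' schedules, SSP-generated behaviour with flanker-typical accuracy and RT,
#' a small fraction of fast-guess and slow contaminant responses (which the
#' 200-1,200 ms trimming rule removes by construction), highly reliable
#' catch-trial withholding, and no cue-association learning in the ratings.
#'
#' @param n_participants cohort size.
#' @param design a [design_spec()].
#' @param model generator model, "ssp" or "dstp".
#' @param param_means named population means; defaults to the shipped model
#'   defaults ([ssp_params()]/[dstp_params()]).
#' @param param_sds named population sds; default 10% of the means.
#' @param cue_effect "null" (informative and non-informative trials
#'   exchangeable) or "suppression" (informative cues shorten interference:
#'   `sd_a` (SSP) or `mu_fl` (DSTP) reduced by `effect_size`
#'   proportionally).
#' @param effect_size proportional parameter reduction under "suppression".
#' @param contamination_fast,contamination_slow fractions of non-catch
#'   trials replaced by fast guesses (uniform 80-199 ms, 50% accuracy) and
#'   slow outliers (uniform 1,201-2,500 ms).
#' @param catch_withhold_prob probability a catch trial is (correctly)
#'   withheld.
#' @param gaze_sd sd of Gaussian gaze noise around screen centre
#'   (screen-normalised units).
#' @param gaze_excursion_rate fraction of trials with gaze displaced away
#'   from centre.
#' @param seed master seed; everything downstream derives from it.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_participants = 50,
                        design = design_spec(1),
                        model = c("ssp", "dstp"),
                        param_means = NULL,
                        param_sds = NULL,
                        cue_effect = c("null", "suppression"),
                        effect_size = 0.3,
                        contamination_fast = 0.02,
                        contamination_slow = 0.02,
                        catch_withhold_prob = 0.95,
                        gaze_sd = 0.06,
                        gaze_excursion_rate = 0.05,
                        seed = 1) {
  model <- match.arg(model)
  cue_effect <- match.arg(cue_effect)
  defaults <- if (model == "ssp") unlist(ssp_params()) else unlist(dstp_params())
  means <- defaults
  if (!is.null(param_means)) means[names(param_means)] <- param_means
  sds <- 0.1 * abs(means)
  if (!is.null(param_sds)) sds[names(param_sds)] <- param_sds
  stopifnot(contamination_fast >= 0, contamination_slow >= 0,
            contamination_fast + contamination_slow <= 1,
            catch_withhold_prob >= 0, catch_withhold_prob <= 1)
  structure(list(
    n_participants = as.integer(n_participants), design = design,
    model = model, param_means = means, param_sds = sds,
    cue_effect = cue_effect, effect_size = effect_size,
    contamination_fast = contamination_fast,
    contamination_slow = contamination_slow,
    catch_withhold_prob = catch_withhold_prob,
    gaze_sd = gaze_sd, gaze_excursion_rate = gaze_excursion_rate,
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

draw_participant_params <- function(spec) {
  info <- par_info(spec$model)
  for (i in 1:1000) {
    v <- rnorm(length(spec$param_means), spec$param_means, spec$param_sds)
    names(v) <- names(spec$param_means)
    if (in_domain(v[info$names], info)) return(v)
  }
  stop_domain("could not draw in-domain participant parameters after 1000 ",
              "attempts; check param_means/param_sds")
}

make_params <- function(model, v) {
  if (model == "ssp")
    ssp_params(v["boundary"], v["p"], v["sd_a"], v["r_d"], v["t_er"])
  else
    dstp_params(v["boundary"], v["boundary_C"], v["mu_t"], v["mu_fl"],
                v["mu_ss"], v["mu_rs2"], v["t_er"])
}

apply_cue_effect <- function(spec, v, cue) {
  if (spec$cue_effect == "suppression" && cue == "informative") {
    k <- if (spec$model == "ssp") "sd_a" else "mu_fl"
    v[k] <- v[k] * (1 - spec$effect_size)
  }
  v
}

#' Generate a complete synthetic cohort
#'
#' Simulates every scheduled trial of every participant from the generator
#' model (RTs converted to ms), injects contaminant responses, draws catch
#' responses, and produces 60 Hz gaze streams, cue-association ratings
#' (no-learning model: all four questions share one Beta-scaled
#' distribution) and two coders' content-analysis labels. All drawn
#' parameters and injected effects are returned as ground truth.
#'
#' @param spec a [cohort_spec()].
#' @param out_dir optional directory: writes `trials.csv`, `gaze.csv`,
#'   `ratings.csv`, `codes.csv` and `ground_truth.json` (requires
#'   jsonlite).
#' @param gaze whether to generate gaze streams (the bulkiest component).
#' @return A list `trials`, `gaze`, `ratings`, `codes`, `ground_truth`.
#' @export
generate_cohort <- function(spec, out_dir = NULL, gaze = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    ids <- sprintf("p%03d", seq_len(spec$n_participants))
    truth <- list()
    trial_list <- vector("list", spec$n_participants)
    gaze_list <- vector("list", spec$n_participants)
    for (i in seq_len(spec$n_participants)) {
      v <- draw_participant_params(spec)
      truth[[i]] <- v
      sched <- build_schedule(spec$design, seed = sample.int(2^30, 1),
                              participant_id = ids[i])
      # simulate per cue x congruency group for speed
      for (cue in c("informative", "non_informative")) {
        for (cong in c("congruent", "incongruent")) {
          rows <- which(sched$cue == cue & sched$congruency == cong)
          if (!length(rows)) next
          params <- make_params(spec$model, apply_cue_effect(spec, v, cue))
          sim <- simulate_conflict_trials(params, cong, length(rows))
          sched$rt_ms[rows] <- sim$rt_s * 1000
          sched$correct[rows] <- sim$correct
        }
      }
      # contamination on non-catch trials
      nc <- which(!sched$is_catch)
      u <- runif(length(nc))
      fast <- nc[u < spec$contamination_fast]
      slow <- nc[u >= spec$contamination_fast &
                   u < spec$contamination_fast + spec$contamination_slow]
      sched$rt_ms[fast] <- runif(length(fast), 80, 199)
      sched$correct[fast] <- runif(length(fast)) < 0.5
      sched$rt_ms[slow] <- runif(length(slow), 1201, 2500)
      # catch responses
      ca <- which(sched$is_catch)
      withheld <- runif(length(ca)) < spec$catch_withhold_prob
      sched$rt_ms[ca] <- ifelse(withheld, NA_real_, runif(length(ca), 300, 800))
      sched$correct[ca] <- withheld
      trial_list[[i]] <- sched
      if (gaze) gaze_list[[i]] <- generate_gaze(spec, sched, ids[i])
    }
    trials <- do.call(rbind, trial_list)
    gaze_df <- if (gaze) do.call(rbind, gaze_list) else NULL
    ratings <- generate_ratings(ids)
    codes <- generate_codes(spec$n_participants)
    truth_df <- cbind(data.frame(participant_id = ids,
                                 stringsAsFactors = FALSE),
                      as.data.frame(do.call(rbind, truth)))
    truth_df$interference_time <- if (spec$model == "ssp")
      truth_df$sd_a / truth_df$r_d else truth_df$mu_fl / truth_df$mu_ss
    ground_truth <- list(model = spec$model, cue_effect = spec$cue_effect,
                         effect_size = if (spec$cue_effect == "suppression")
                           spec$effect_size else 0,
                         contamination = spec$contamination_fast +
                           spec$contamination_slow,
                         catch_withhold_prob = spec$catch_withhold_prob,
                         participants = truth_df)
    out <- list(trials = trials, gaze = gaze_df, ratings = ratings,
                codes = codes, ground_truth = ground_truth)
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      write_trials(trials, file.path(out_dir, "trials.csv"))
      if (gaze) write.csv(gaze_df, file.path(out_dir, "gaze.csv"),
                          row.names = FALSE)
      write.csv(ratings, file.path(out_dir, "ratings.csv"), row.names = FALSE)
      write.csv(codes, file.path(out_dir, "codes.csv"), row.names = FALSE)
      if (requireNamespace("jsonlite", quietly = TRUE))
        jsonlite::write_json(ground_truth,
                             file.path(out_dir, "ground_truth.json"),
                             auto_unbox = TRUE, digits = NA, dataframe = "rows")
    }
    out
  })
}

# 60 Hz gaze over the first 500 ms of each trial; excursion trials wander
# away from centre
generate_gaze <- function(spec, sched, id) {
  n_samp <- 30L  # 500 ms at 60 Hz
  n_tr <- nrow(sched)
  exc <- runif(n_tr) < spec$gaze_excursion_rate
  cx <- ifelse(exc, 0.5 + sample(c(-1, 1), n_tr, TRUE) * runif(n_tr, .2, .4),
               0.5)
  cy <- ifelse(exc, 0.5 + sample(c(-1, 1), n_tr, TRUE) * runif(n_tr, .2, .4),
               0.5)
  data.frame(
    participant_id = id,
    trial_index = rep(seq_len(n_tr), each = n_samp),
    t_ms = rep(round(seq(0, by = 1000 / 60, length.out = n_samp), 2), n_tr),
    x_norm = pmin(1, pmax(0, rnorm(n_tr * n_samp, rep(cx, each = n_samp),
                                   spec$gaze_sd))),
    y_norm = pmin(1, pmax(0, rnorm(n_tr * n_samp, rep(cy, each = n_samp),
                                   spec$gaze_sd))),
    stringsAsFactors = FALSE
  )
}

# no-learning model: every question from the same Beta-scaled distribution
generate_ratings <- function(ids) {
  qs <- c("informative_valid", "informative_invalid", "noninformative_top",
          "noninformative_bottom")
  data.frame(
    participant_id = rep(ids, each = length(qs)),
    question = rep(qs, length(ids)),
    rating = round(100 * rbeta(length(ids) * length(qs), 1.5, 3.5)),
    stringsAsFactors = FALSE
  )
}

# two coders over a nominal codebook; coder B agrees with probability 0.8
generate_codes <- function(n, agreement = 0.8) {
  codebook <- c("correct_answer", "cues_distract", "no_association",
                "random", "target_location", "other")
  probs <- c(0.05, 0.35, 0.32, 0.04, 0.04, 0.20)
  a <- sample(codebook, n, replace = TRUE, prob = probs)
  flip <- runif(n) >= agreement
  b <- a
  b[flip] <- sample(codebook, sum(flip), replace = TRUE, prob = probs)
  data.frame(response_id = seq_len(n), coder_a = a, coder_b = b,
             stringsAsFactors = FALSE)
}

#' Parameter-recovery report against ground truth
#'
#' Joins fitted parameters to the generator's ground truth and reports
#' per-parameter bias and relative error, plus the detected versus injected
#' cue effect on interference time when fits are available per cue
#' condition.
#'
#' @param ground_truth the `ground_truth` element of [generate_cohort()].
#' @param fits data.frame of fitted parameters with `participant_id`,
#'   optionally `cue`, and one column per model parameter.
#' @return A list: `per_parameter` (data.frame `parameter`, `mean_truth`,
#'   `mean_fit`, `bias`, `mean_relative_error`), `interference`, and (when
#'   `cue` is present) `cue_effect_detected`.
#' @export
ground_truth_report <- function(ground_truth, fits) {
  truth <- ground_truth$participants
  if (!all(fits$participant_id %in% truth$participant_id))
    stop_domain("fits contain participant ids absent from ground truth")
  pars <- intersect(names(truth), names(fits))
  pars <- setdiff(pars, "participant_id")
  m <- merge(truth, fits, by = "participant_id",
             suffixes = c("_truth", "_fit"))
  per_par <- do.call(rbind, lapply(pars, function(p) {
    tv <- m[[paste0(p, "_truth")]]
    fv <- m[[paste0(p, "_fit")]]
    data.frame(parameter = p, mean_truth = mean(tv), mean_fit = mean(fv),
               bias = mean(fv - tv),
               mean_relative_error = mean(abs(fv - tv) / abs(tv)),
               stringsAsFactors = FALSE)
  }))
  out <- list(per_parameter = per_par)
  if ("cue" %in% names(fits) && "interference_time" %in% pars) {
    it <- aggregate(interference_time_fit ~ cue, data = m, FUN = mean)
    diff_it <- it$interference_time_fit[it$cue == "non_informative"] -
      it$interference_time_fit[it$cue == "informative"]
    out$cue_effect_detected <- diff_it
    out$cue_effect_injected <- ground_truth$effect_size
  }
  out
}
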