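#' Gaze area-of-interest occupancy
#'
#' A trial counts as centrally fixated when at least `sample_threshold` of
#' its gaze samples recorded during the first `window_ms` of the search
#' array fall inside the central AOI (closed box, screen-normalised
#' coordinates). Returns the proportion of such trials per participant and
#' cue condition; trials with no samples in the window are dropped from the
#' denominator (their count is reported).
#'
#' @param gaze gaze samples: `participant_id`, `trial_index`, `t_ms`,
#'   `x_norm`, `y_norm`.
#' @param trials trial data carrying `cue`; joined on participant and
#'   `trial_index` (computed as `(block - 1) * trials_per_block +
#'   trial_in_block` when absent).
#' @param aoi AOI box `c(x_min, x_max, y_min, y_max)`.
#' @param window_ms analysis window from array onset.
#' @param sample_threshold fraction of in-window samples that must be
#'   inside the AOI.
#' @return A data.frame `participant_id`, `cue`, `prop_fixated`, `n_trials`;
#'   attribute `n_dropped` counts sample-less trials.
#' @export
aoi_occupancy <- function(gaze, trials, aoi = c(0.35, 0.65, 0.35, 0.65),
                          window_ms = 500, sample_threshold = 0.5) {
  if (is.null(trials$trial_index)) {
    tpb <- max(trials$trial_in_block)
    trials$trial_index <- (trials$block - 1) * tpb + trials$trial_in_block
  }
  g <- gaze[gaze$t_ms < window_ms, ]
  g$inside <- g$x_norm >= aoi[1] & g$x_norm <= aoi[2] &
    g$y_norm >= aoi[3] & g$y_norm <= aoi[4]
  key <- paste(g$participant_id, g$trial_index, sep = "\r")
  flagged <- tapply(g$inside, key, mean) >= sample_threshold
  parts <- strsplit(names(flagged), "\r", fixed = TRUE)
  flag_df <- data.frame(
    participant_id = vapply(parts, `[[`, character(1), 1),
    trial_index = as.integer(vapply(parts, `[[`, character(1), 2)),
    flagged = as.logical(flagged),
    stringsAsFactors = FALSE
  )
  m <- merge(trials[, c("participant_id", "trial_index", "cue")], flag_df,
             by = c("participant_id", "trial_index"))
  n_dropped <- nrow(trials) - nrow(m)
  agg <- aggregate(flagged ~ participant_id + cue, data = m, FUN = mean)
  names(agg)[3] <- "prop_fixated"
  cnt <- aggregate(flagged ~ participant_id + cue, data = m, FUN = length)
  agg$n_trials <- cnt$flagged
  attr(agg, "n_dropped") <- n_dropped
  agg
}

#' Cue-association rating summaries
#'
#' Summarises end-of-experiment ratings of how often the foil appeared at a
#' probed location (0 = never, 100 = always), asked for four cue questions:
#' `informative_valid`, `informative_invalid`, `noninformative_top`,
#' `noninformative_bottom`. A participant who learnt the association should
#' rate the informative-valid question high and the informative-invalid
#' question low; the learning index is the mean difference between the two,
#' and learning is declared when the index exceeds `margin`.
#'
#' @param ratings data.frame `participant_id`, `question`, `rating`
#'   (0-100; out-of-range rows are rejected with a count reported).
#' @param margin learning-index threshold (rating points).
#' @return A list: `by_question` (mean/median/quartiles per question),
#'   `learning_index`, `verdict` ("learned"/"not_learned"), `n_rejected`.
#' @export
rating_summary <- function(ratings, margin = 10) {
  bad <- is.na(ratings$rating) | ratings$rating < 0 | ratings$rating > 100
  ratings <- ratings[!bad, ]
  sp <- split(ratings$rating, ratings$question)
  by_q <- do.call(rbind, lapply(names(sp), function(q) data.frame(
    question = q, n = length(sp[[q]]), mean = mean(sp[[q]]),
    median = median(sp[[q]]),
    q25 = unname(quantile(sp[[q]], .25)), q75 = unname(quantile(sp[[q]], .75)),
    stringsAsFactors = FALSE)))
  idx <- mean(sp[["informative_valid"]] %||% NA_real_) -
    mean(sp[["informative_invalid"]] %||% NA_real_)
  list(by_question = by_q, learning_index = idx,
       verdict = if (isTRUE(idx > margin)) "learned" else "not_learned",
       n_rejected = sum(bad))
}

#' Content-analysis code percentages
#'
#' Converts per-code tallies into percentages of all coded responses
#' (denominator: the sum of the tallies), rounded to two decimals.
#'
#' @param tallies data.frame with `code_label` and `count` (all >= 0, not
#'   all zero).
#' @return The input with a `pct` column added.
#' @export
code_percentages <- function(tallies) {
  stopifnot(all(tallies$count >= 0))
  total <- sum(tallies$count)
  if (total == 0) stop_domain("all code counts are zero")
  tallies$pct <- round(100 * tallies$count / total, 2)
  tallies
}

#' Cohen's kappa for two coders
#'
#' Unweighted kappa over nominal codes: `(p_o - p_e) / (1 - p_e)` with
#' observed agreement `p_o` and chance agreement `p_e` from the marginal
#' label frequencies of the two coders. When both coders apply a single
#' identical label throughout (`p_e = 1`), kappa is defined as 1.
#'
#' @param coder_a,coder_b equal-length label vectors.
#' @return Kappa in \[-1, 1\].
#' @export
cohens_kappa <- function(coder_a, coder_b) {
  if (length(coder_a) != length(coder_b))
    stop_domain("coder label sequences differ in length")
  labels <- union(coder_a, coder_b)
  a <- factor(coder_a, levels = labels)
  b <- factor(coder_b, levels = labels)
  p_o <- mean(a == b)
  p_e <- sum(table(a) / length(a) * table(b) / length(b))
  if (p_e >= 1) return(1)
  (p_o - p_e) / (1 - p_e)
}
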