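#' Response-time trimming
#'
#' Removes anticipations and misses: non-catch trials are kept iff
#' `200 <= rt_ms <= 1200` (the rule removes RTs strictly below 200 ms or
#' strictly above 1,200 ms); non-catch trials without a recorded response
#' are also removed. Catch trials pass through untouched. The trimmed
#' fraction is computed per participant over non-catch trials.
#'
#' @param trials trial data.frame (see [read_trials()] for columns).
#' @param lower_ms,upper_ms trimming bounds in ms.
#' @return A list with `trials` (kept rows) and `prop_trimmed` (data.frame
#'   `participant_id`, `prop_trimmed`).
#' @export
trim_rts <- function(trials, lower_ms = 200, upper_ms = 1200) {
  noncatch <- !trials$is_catch
  keep <- trials$is_catch |
    (!is.na(trials$rt_ms) & trials$rt_ms >= lower_ms & trials$rt_ms <= upper_ms)
  pt <- stats::aggregate(trimmed ~ participant_id,
                         data = data.frame(participant_id = trials$participant_id[noncatch],
                                           trimmed = !keep[noncatch]),
                         FUN = mean)
  names(pt)[2] <- "prop_trimmed"
  list(trials = trials[keep, , drop = FALSE], prop_trimmed = pt)
}

#' Participant summaries and exclusion rules
#'
#' `participant_summaries()` computes, per participant: total trials, the
#' fraction of non-catch trials removed by [trim_rts()], overall accuracy on
#' non-catch trials (before trimming), and the fraction of failed catch
#' trials (a catch trial is failed by any keypress, i.e. a recorded RT).
#' `apply_exclusions()` then flags participants using the pre-registered
#' criteria, evaluated in order: (1) failing at least 50% of catch trials,
#' (2) overall accuracy strictly below 85%, (3) trimming removing more than
#' 40% of trials. The first matching criterion is recorded.
#'
#' @param trials raw (untrimmed) trial data for the cohort.
#' @return A data.frame with one row per participant; after
#'   `apply_exclusions()` it carries `excluded` and `exclusion_reason`
#'   ("none", "catch", "accuracy" or "trimming").
#' @export
participant_summaries <- function(trials) {
  sp <- split(trials, trials$participant_id)
  rows <- lapply(sp, function(d) {
    nc <- d[!d$is_catch, ]
    ca <- d[d$is_catch, ]
    trimmed <- is.na(nc$rt_ms) | nc$rt_ms < 200 | nc$rt_ms > 1200
    data.frame(
      participant_id = d$participant_id[1],
      n_trials_total = nrow(d),
      prop_trimmed = if (nrow(nc)) mean(trimmed) else 0,
      overall_accuracy = if (nrow(nc)) mean(nc$correct) else NA_real_,
      catch_fail_prop = if (nrow(ca)) mean(!is.na(ca$rt_ms)) else 0,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @rdname participant_summaries
#' @param summaries output of `participant_summaries()`.
#' @export
apply_exclusions <- function(summaries) {
  reason <- rep("none", nrow(summaries))
  reason[summaries$prop_trimmed > 0.40] <- "trimming"
  reason[summaries$overall_accuracy < 0.85] <- "accuracy"
  reason[summaries$catch_fail_prop >= 0.5] <- "catch"
  summaries$excluded <- reason != "none"
  summaries$exclusion_reason <- reason
  summaries
}

#' Congruency effect and positive control
#'
#' The congruency effect (CE) is `median(incongruent RT) - median(congruent
#' RT)` on correct, trimmed trials. The positive control -- foils must
#' demonstrably interfere before any suppression question is meaningful --
#' passes when more than 75% of participants show CE > 0 (pooled over cue
#' conditions). Participants lacking correct trials in a cell yield `NA`
#' for that cell and drop out of the control denominator.
#'
#' @param trials trimmed trial data.
#' @param control_threshold fraction of participants that must show a
#'   positive pooled CE.
#' @return A list: `ce` (data.frame `participant_id`, `cue`, `ce_ms`),
#'   `ce_pooled` (per participant), `prop_positive`, `control_passed`.
#' @export
congruency_effect <- function(trials, control_threshold = 0.75) {
  d <- trials[!trials$is_catch & trials$correct & !is.na(trials$rt_ms), ]
  ce_cell <- function(x) {
    m_inc <- median(x$rt_ms[x$congruency == "incongruent"])
    m_con <- median(x$rt_ms[x$congruency == "congruent"])
    m_inc - m_con
  }
  sp <- split(d, list(d$participant_id, d$cue), drop = TRUE)
  ce <- do.call(rbind, lapply(sp, function(x) data.frame(
    participant_id = x$participant_id[1], cue = x$cue[1], ce_ms = ce_cell(x),
    stringsAsFactors = FALSE)))
  rownames(ce) <- NULL
  spp <- split(d, d$participant_id)
  pooled <- data.frame(
    participant_id = names(spp),
    ce_ms = vapply(spp, ce_cell, numeric(1)),
    stringsAsFactors = FALSE
  )
  rownames(pooled) <- NULL
  ok <- !is.na(pooled$ce_ms)
  prop_pos <- mean(pooled$ce_ms[ok] > 0)
  list(ce = ce, ce_pooled = pooled, prop_positive = prop_pos,
       control_passed = prop_pos > control_threshold)
}

#' Conditional accuracy functions
#'
#' Sorts each cue x congruency cell's trimmed RTs (correct and error) into
#' `n_bins` quantile bins and reports per-bin accuracy. A rising accuracy
#' profile on incongruent trials is the signature of fast errors.
#'
#' @param trials trimmed trial data.
#' @param n_bins number of RT bins (default five).
#' @return A data.frame with columns `cue`, `congruency`, `bin`,
#'   `bin_lower_ms`, `bin_upper_ms`, `bin_accuracy`, `bin_n`.
#' @export
conditional_accuracy <- function(trials, n_bins = 5) {
  d <- trials[!trials$is_catch & !is.na(trials$rt_ms), ]
  sp <- split(d, list(d$cue, d$congruency), drop = TRUE)
  rows <- lapply(sp, function(x) {
    if (nrow(x) < n_bins)
      stop_domain("fewer trials (", nrow(x), ") than bins in cell ",
                  x$cue[1], "/", x$congruency[1])
    edges <- quantile(x$rt_ms, seq(0, 1, length.out = n_bins + 1), type = 7)
    bin <- cut(x$rt_ms, unique(edges), include.lowest = TRUE, labels = FALSE)
    # unique() guards duplicate edges from ties; re-pad to n_bins if needed
    acc <- tapply(x$correct, bin, mean)
    n <- tapply(x$correct, bin, length)
    k <- length(acc)
    data.frame(
      cue = x$cue[1], congruency = x$congruency[1], bin = seq_len(k),
      bin_lower_ms = unname(unique(edges))[seq_len(k)],
      bin_upper_ms = unname(unique(edges))[1 + seq_len(k)],
      bin_accuracy = as.numeric(acc), bin_n = as.integer(n),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
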