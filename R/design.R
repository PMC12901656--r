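#' Experiment design specification
#'
#' Encodes the three experiment designs of the cued-suppression paradigm:
#' 16 blocks of 19 trials (304 in total, 16 of them catch trials), with the
#' cue condition interleaved trial-by-trial (Experiments 1 and 3) or blocked
#' in four epochs of 76 trials (Experiment 2). Experiment 3 uses foil
#' locations spatially separated from the four target locations.
#'
#' Location coding: target locations are indexed 0--3. In Experiments 1 and
#' 2 foils occupy one of the remaining target locations; in Experiment 3
#' foils occupy dedicated locations indexed 4--7.
#'
#' @param experiment 1, 2 or 3.
#' @param n_blocks,trials_per_block,n_catch design counts; defaults follow
#'   the standard design (16 x 19, 16 catch trials).
#' @param cue_regime "interleaved" or "blocked". Defaults to "blocked" for
#'   experiment 2, "interleaved" otherwise.
#' @param epoch_length trials per cue epoch under the blocked regime
#'   (must divide the total trial count evenly); ignored when interleaved.
#' @param cue_duration_ms,fixation_duration_ms display durations in ms.
#' @return An object of class `design_spec`.
#' @examples
#' d <- design_spec(1)
#' d$n_blocks * d$trials_per_block  # 304
#' @export
design_spec <- function(experiment = 1,
                        n_blocks = 16,
                        trials_per_block = 19,
                        n_catch = 16,
                        cue_regime = if (experiment == 2) "blocked" else "interleaved",
                        epoch_length = if (cue_regime == "blocked") 76 else NA_integer_,
                        cue_duration_ms = 1500,
                        fixation_duration_ms = 500) {
  experiment <- as.integer(experiment)
  if (!experiment %in% 1:3) stop_domain("experiment must be 1, 2 or 3")
  cue_regime <- match.arg(cue_regime, c("interleaved", "blocked"))
  total <- n_blocks * trials_per_block
  if (n_catch > total) stop_domain("n_catch exceeds total trial count")
  if (cue_regime == "blocked") {
    if (is.na(epoch_length) || total %% epoch_length != 0)
      stop_domain("blocked regime requires epoch_length dividing the total ",
                  "trial count evenly (", total, ")")
    n_epochs <- total %/% epoch_length
    if (n_epochs %% 2 != 0)
      stop_domain("blocked regime requires an even number of epochs")
    if (n_catch %% n_epochs != 0)
      stop_domain("n_catch must divide evenly across epochs")
  }
  structure(list(
    experiment_id = experiment,
    n_blocks = as.integer(n_blocks),
    trials_per_block = as.integer(trials_per_block),
    n_catch = as.integer(n_catch),
    cue_regime = cue_regime,
    epoch_length = if (cue_regime == "blocked") as.integer(epoch_length) else NA_integer_,
    cue_duration_ms = cue_duration_ms,
    fixation_duration_ms = fixation_duration_ms,
    foil_locations_separated = experiment == 3
  ), class = "design_spec")
}

#' @export
print.design_spec <- function(x, ...) {
  cat("Design: experiment", x$experiment_id, "-", x$n_blocks, "blocks x",
      x$trials_per_block, "trials (", x$n_blocks * x$trials_per_block,
      "total,", x$n_catch, "catch ),", x$cue_regime, "cues\n")
  invisible(x)
}

# balanced, seed-shuffled labels for n non-catch trials:
# cue x congruency crossed as evenly as possible
balanced_cells <- function(n) {
  cells <- expand.grid(cue = c("informative", "non_informative"),
                       congruency = c("congruent", "incongruent"),
                       stringsAsFactors = FALSE)
  idx <- rep(seq_len(4), length.out = n)  # n %% 4 == 0 in the shipped designs
  cells[sample(idx), , drop = FALSE]
}

#' Build a trial schedule
#'
#' Lays out one participant's trial sequence for a given design: positions of
#' catch trials, cue and congruency labels balanced 50/50 over non-catch
#' trials, target identity and target/foil locations. Response fields
#' (`rt_ms`, `correct`) are `NA` in the returned skeleton.
#'
#' Under the interleaved regime cue and congruency are fully crossed and
#' shuffled across all non-catch trials; catch trials are placed uniformly at
#' random. Under the blocked regime the schedule is partitioned into cue-
#' homogeneous epochs (epoch order randomised), catch trials are spread
#' evenly across epochs, and congruency is balanced within each epoch, so
#' that cue x congruency cell counts do not depend on the seed.
#'
#' @param design a [design_spec()].
#' @param seed integer seed; the same seed reproduces the schedule exactly.
#' @param participant_id optional id stored on every row.
#' @return A data.frame with one row per trial: `participant_id`, `block`,
#'   `trial_in_block`, `cue`, `congruency` ("congruent", "incongruent" or
#'   "catch"), `target_identity` ("B"/"F", `NA` on catch trials),
#'   `target_location`, `foil_location`, `is_catch`, `rt_ms`, `correct`.
#' @examples
#' sched <- build_schedule(design_spec(1), seed = 1)
#' nrow(sched)            # 304
#' sum(sched$is_catch)    # 16
#' @export
build_schedule <- function(design, seed, participant_id = NA_character_) {
  stopifnot(inherits(design, "design_spec"))
  total <- design$n_blocks * design$trials_per_block
  with_seed(seed, {
    is_catch <- rep(FALSE, total)
    if (design$cue_regime == "blocked") {
      n_epochs <- total %/% design$epoch_length
      per_epoch <- design$n_catch %/% n_epochs
      for (e in seq_len(n_epochs)) {
        off <- (e - 1) * design$epoch_length
        is_catch[off + sample.int(design$epoch_length, per_epoch)] <- TRUE
      }
    } else {
      is_catch[sample.int(total, design$n_catch)] <- TRUE
    }

    cue <- rep(NA_character_, total)
    congruency <- rep("catch", total)
    if (design$cue_regime == "blocked") {
      n_epochs <- total %/% design$epoch_length
      epoch_cue <- sample(rep(c("informative", "non_informative"),
                              each = n_epochs / 2))
      epoch_of <- rep(seq_len(n_epochs), each = design$epoch_length)
      cue <- epoch_cue[epoch_of]
      for (e in seq_len(n_epochs)) {
        slots <- which(epoch_of == e & !is_catch)
        m <- length(slots)
        cong <- sample(rep(c("congruent", "incongruent"), length.out = m))
        congruency[slots] <- cong
      }
    } else {
      slots <- which(!is_catch)
      cells <- balanced_cells(length(slots))
      cue[slots] <- cells$cue
      congruency[slots] <- cells$congruency
    }
    if (design$cue_regime == "interleaved")
      cue[is_catch] <- sample(c("informative", "non_informative"),
                              design$n_catch, replace = TRUE)

    target_identity <- ifelse(is_catch, NA_character_,
                              sample(c("B", "F"), total, replace = TRUE))
    target_location <- ifelse(is_catch, NA_integer_,
                              sample(0:3, total, replace = TRUE))
    foil_location <- rep(NA_integer_, total)
    nc <- which(!is_catch)
    if (design$foil_locations_separated) {
      foil_location[nc] <- sample(4:7, length(nc), replace = TRUE)
    } else {
      # foil occupies one of the three remaining target locations
      foil_location[nc] <- vapply(target_location[nc], function(tl)
        sample(setdiff(0:3, tl), 1L), integer(1))
    }

    data.frame(
      participant_id = participant_id,
      block = rep(seq_len(design$n_blocks), each = design$trials_per_block),
      trial_in_block = rep(seq_len(design$trials_per_block), design$n_blocks),
      cue = cue,
      congruency = congruency,
      target_identity = target_identity,
      target_location = target_location,
      foil_location = foil_location,
      is_catch = is_catch,
      rt_ms = NA_real_,
      correct = NA,
      stringsAsFactors = FALSE
    )
  })
}
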