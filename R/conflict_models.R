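#' Conflict diffusion model parameters
#'
#' Parameter containers for the two conflict diffusion models. Both models
#' run on the conventional diffusion scaling with within-trial noise
#' sd = 0.1 and an Euler step of 1 ms; boundaries are symmetric (a single
#' height `A` means absorbing boundaries at +A and -A).
#'
#' The shrinking spotlight model (SSP) weights target and foil drift by the
#' mass of a zero-mean Gaussian attention window (initial sd `sd_a`,
#' narrowing at `r_d` spatial units per second) over the target region
#' \[-0.5, +0.5\]. The dual-stage two-phase model (DSTP) runs a response
#' selection diffusion (early drift `mu_t` +/- `mu_fl`) in parallel with a
#' stimulus selection diffusion (drift `mu_ss`, boundaries +/-`C`); when
#' stimulus selection finishes first, response selection switches to the
#' late selective drift `mu_rs2`.
#'
#' @param boundary response selection boundary height (evidence units > 0).
#' @param p perceptual input from the target (drift units > 0).
#' @param sd_a initial spotlight width (spatial sd > 0).
#' @param r_d spotlight narrowing rate (spatial units per second > 0).
#' @param t_er non-decision time in seconds (>= 0).
#' @return An object of class `ssp_params` or `dstp_params`.
#' @export
ssp_params <- function(boundary = 0.07, p = 0.4, sd_a = 1.5, r_d = 26,
                       t_er = 0.3) {
  if (boundary <= 0 || p <= 0 || sd_a <= 0 || r_d <= 0 || t_er < 0)
    stop_domain("ssp_params out of domain: boundary, p, sd_a, r_d must be ",
                "> 0 and t_er >= 0")
  structure(list(boundary = boundary, p = p, sd_a = sd_a, r_d = r_d,
                 t_er = t_er), class = "ssp_params")
}

#' @rdname ssp_params
#' @param boundary_C stimulus selection boundary height (> 0).
#' @param mu_t target drift rate.
#' @param mu_fl foil drift-rate magnitude (>= 0; its sign is applied by
#'   congruency).
#' @param mu_ss stimulus selection drift rate (> 0).
#' @param mu_rs2 phase-2 response selection drift magnitude (> 0).
#' @export
dstp_params <- function(boundary = 0.09, boundary_C = 0.12, mu_t = 0.12,
                        mu_fl = 0.18, mu_ss = 0.40, mu_rs2 = 1.4,
                        t_er = 0.30) {
  if (boundary <= 0 || boundary_C <= 0 || mu_fl < 0 || mu_ss <= 0 ||
      mu_rs2 <= 0 || t_er < 0)
    stop_domain("dstp_params out of domain: boundaries, mu_ss, mu_rs2 must ",
                "be > 0, mu_fl >= 0, t_er >= 0")
  structure(list(boundary = boundary, boundary_C = boundary_C, mu_t = mu_t,
                 mu_fl = mu_fl, mu_ss = mu_ss, mu_rs2 = mu_rs2, t_er = t_er),
            class = "dstp_params")
}

#' @export
print.ssp_params <- function(x, ...) {
  cat("SSP parameters:\n")
  print(unlist(x))
  invisible(x)
}

#' @export
print.dstp_params <- function(x, ...) {
  cat("DSTP parameters:\n")
  print(unlist(x))
  invisible(x)
}

SIGMA_FLOOR <- 0.001

cong_sign <- function(congruency) {
  congruency <- match.arg(congruency, c("congruent", "incongruent"))
  if (congruency == "congruent") 1L else -1L
}

#' SSP attention weights and drift
#'
#' `ssp_attention_weights()` returns the attentional weight on the target
#' region and on the outer (foil) region at time `t_s` after array onset:
#' the spotlight sd is `max(sd_a - r_d * t, 0.001)` and the target weight is
#' the Gaussian mass over \[-0.5, +0.5\]. `ssp_drift()` composes the weights
#' into the momentary drift `p * w_target + s * p * w_outer` with s = +1 on
#' congruent and -1 on incongruent trials.
#'
#' @param t_s time since array onset in seconds (vectorised, >= 0).
#' @param params an [ssp_params()] object.
#' @return For weights, a data.frame with columns `w_target` and `w_outer`
#'   (summing to 1); for drift, a numeric vector.
#' @examples
#' ssp_attention_weights(0, ssp_params(sd_a = 1.8))
#' ssp_drift(0, ssp_params(), "incongruent")
#' @export
ssp_attention_weights <- function(t_s, params) {
  stopifnot(inherits(params, "ssp_params"), all(t_s >= 0))
  sig <- pmax(params$sd_a - params$r_d * t_s, SIGMA_FLOOR)
  w <- pnorm(0.5, 0, sig) - pnorm(-0.5, 0, sig)
  data.frame(w_target = w, w_outer = 1 - w)
}

#' @rdname ssp_attention_weights
#' @param congruency "congruent" or "incongruent".
#' @export
ssp_drift <- function(t_s, params, congruency) {
  s <- cong_sign(congruency)
  w <- ssp_attention_weights(t_s, params)
  params$p * w$w_target + s * params$p * w$w_outer
}

#' Simulate conflict-model trials
#'
#' Euler-Maruyama simulation of first-passage times for the SSP and DSTP
#' models. Decision processes still running after `max_decision_s` seconds
#' are resampled (their count is returned in the `n_resampled` attribute);
#' with `noise_sd = 0` a non-terminating trial yields `NA` instead.
#'
#' @param params an [ssp_params()] or [dstp_params()] object.
#' @param congruency "congruent" or "incongruent".
#' @param n number of trials.
#' @param seed optional integer seed for a reproducible trial stream.
#' @param dt_s Euler step in seconds.
#' @param noise_sd within-trial diffusion noise (0 gives the deterministic
#'   mean path).
#' @param max_decision_s non-termination guard on decision time.
#' @return A data.frame with columns `rt_s`, `correct`, `congruency`;
#'   attribute `n_resampled` counts guarded restarts.
#' @examples
#' simulate_conflict_trials(ssp_params(), "incongruent", n = 5, seed = 1)
#' @export
simulate_conflict_trials <- function(params, congruency, n, seed = NULL,
                                     dt_s = 0.001, noise_sd = 0.1,
                                     max_decision_s = 10) {
  stopifnot(dt_s > 0, noise_sd >= 0, n >= 1)
  s <- cong_sign(congruency)
  out <- with_seed(seed, {
    if (inherits(params, "ssp_params")) {
      sim_ssp_cpp(as.integer(n), params$boundary, params$p, params$sd_a,
                  params$r_d, params$t_er, s, dt_s, noise_sd,
                  max_decision_s, SIGMA_FLOOR)
    } else if (inherits(params, "dstp_params")) {
      sim_dstp_cpp(as.integer(n), params$boundary, params$boundary_C,
                   params$mu_t, params$mu_fl, params$mu_ss, params$mu_rs2,
                   params$t_er, s, dt_s, noise_sd, max_decision_s)
    } else stop_domain("params must be ssp_params or dstp_params")
  })
  out$congruency <- congruency
  out
}

#' Model-derived interference time
#'
#' The duration of foil influence on response selection: `sd_a / r_d` for
#' the SSP (time for the spotlight to shrink onto the target) and
#' `mu_fl / mu_ss` for the DSTP (foil drift relative to the speed of
#' stimulus selection). Units follow the parameter units (seconds when
#' `r_d` is per second).
#'
#' @param params an [ssp_params()] or [dstp_params()] object.
#' @return A scalar interference time.
#' @examples
#' interference_time(ssp_params(sd_a = 1.8, r_d = 18))  # 0.1 s
#' @export
interference_time <- function(params) UseMethod("interference_time")

#' @export
interference_time.ssp_params <- function(params) {
  if (params$r_d <= 0) stop_domain("r_d must be > 0")
  params$sd_a / params$r_d
}

#' @export
interference_time.dstp_params <- function(params) {
  if (params$mu_ss <= 0) stop_domain("mu_ss must be > 0")
  params$mu_fl / params$mu_ss
}
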