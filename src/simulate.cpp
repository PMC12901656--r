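#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Euler-Maruyama first-passage simulators for the two conflict diffusion
// models. Both use R's RNG (norm_rand) so set.seed() on the R side makes
// trial streams reproducible. Trials whose decision process has not
// terminated after max_t seconds are resampled; the count of resampled
// trials is returned as an attribute. In the noiseless case (noise_sd = 0)
// a non-terminating trial cannot be resampled, so rt is NA instead.

// [[Rcpp::export]]
DataFrame sim_ssp_cpp(int n, double boundary, double p, double sd_a,
                      double r_d, double t_er, int sign, double dt,
                      double noise_sd, double max_t, double sigma_floor) {
  const int nstep = (int)std::ceil(max_t / dt);
  // drift depends on time only, not on the accumulator state: precompute
  std::vector<double> drift(nstep);
  for (int j = 0; j < nstep; ++j) {
    double sig = sd_a - r_d * (j * dt);
    if (sig < sigma_floor) sig = sigma_floor;
    double wt = R::pnorm(0.5, 0.0, sig, 1, 0) - R::pnorm(-0.5, 0.0, sig, 1, 0);
    drift[j] = p * wt + sign * p * (1.0 - wt);
  }
  NumericVector rt(n);
  LogicalVector correct(n);
  const double sq = noise_sd * std::sqrt(dt);
  int resampled = 0;
  for (int i = 0; i < n; ++i) {
    for (;;) {
      double x = 0.0;
      int j = 0;
      int hit = 0;  // 0 none, 1 upper, -1 lower
      while (j < nstep) {
        x += drift[j] * dt + (noise_sd > 0.0 ? sq * norm_rand() : 0.0);
        ++j;
        if (x >= boundary) { hit = 1; break; }
        if (x <= -boundary) { hit = -1; break; }
      }
      if (hit != 0) {
        rt[i] = j * dt + t_er;
        correct[i] = (hit == 1);
        break;
      }
      if (noise_sd <= 0.0) { rt[i] = NA_REAL; correct[i] = NA_LOGICAL; break; }
      ++resampled;
    }
  }
  DataFrame out = DataFrame::create(_["rt_s"] = rt, _["correct"] = correct);
  out.attr("n_resampled") = resampled;
  return out;
}

// [[Rcpp::export]]
DataFrame sim_dstp_cpp(int n, double boundary_A, double boundary_C,
                       double mu_t, double mu_fl, double mu_ss,
                       double mu_rs2, double t_er, int sign, double dt,
                       double noise_sd, double max_t) {
  const int nstep = (int)std::ceil(max_t / dt);
  const double mu_rs1 = mu_t + sign * mu_fl;
  const double sq = noise_sd * std::sqrt(dt);
  NumericVector rt(n);
  LogicalVector correct(n);
  int resampled = 0;
  for (int i = 0; i < n; ++i) {
    for (;;) {
      double x = 0.0, y = 0.0;
      bool phase2 = false;
      double mu = mu_rs1;
      int j = 0;
      int hit = 0;
      while (j < nstep) {
        x += mu * dt + (noise_sd > 0.0 ? sq * norm_rand() : 0.0);
        ++j;
        if (x >= boundary_A) { hit = 1; break; }
        if (x <= -boundary_A) { hit = -1; break; }
        if (!phase2) {
          y += mu_ss * dt + (noise_sd > 0.0 ? sq * norm_rand() : 0.0);
          if (y >= boundary_C) {
            // target selected: late drift heads to the correct boundary
            phase2 = true;
            mu = mu_rs2;
          } else if (y <= -boundary_C) {
            // foil selected: drift is selective for the foil's response
            phase2 = true;
            mu = (sign > 0) ? mu_rs2 : -mu_rs2;
          }
        }
      }
      if (hit != 0) {
        rt[i] = j * dt + t_er;
        correct[i] = (hit == 1);
        break;
      }
      if (noise_sd <= 0.0) { rt[i] = NA_REAL; correct[i] = NA_LOGICAL; break; }
      ++resampled;
    }
  }
  DataFrame out = DataFrame::create(_["rt_s"] = rt, _["correct"] = correct);
  out.attr("n_resampled") = resampled;
  return out;
}
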