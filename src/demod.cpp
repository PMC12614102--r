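// Core PLL demodulator loop.
//
// Per baseband step: mix D raw samples against the NCO, decimate through a
// short FIR (delay-minimal CIC-style taps supplied by the R wrapper), sum the
// four compensated baseband vectors into the main vector, unwrap its phase
// (clamped to +/- unwrap_turns), run a PID with conditional-integration
// anti-windup and a limiting range, and every `block` samples update the
// per-antenna compensation phases by a fraction gamma of the rotated-vector
// angles.  The arithmetic here is mirrored operation-for-operation by the
// pure-R reference implementation used as an equivalence oracle in the tests.

#include <Rcpp.h>
#include <complex>
#include <vector>
#include <cmath>

using namespace Rcpp;
typedef std::complex<double> cplx;

static inline double wrap_phase(double phi) {
  return phi - 2.0 * M_PI * std::round(phi / (2.0 * M_PI));
}

// [[Rcpp::export(name = ".demod_core")]]
List demod_core(ComplexVector zA, ComplexVector zB, ComplexVector zC,
                ComplexVector zD, double fz, double f_center, double limit,
                int D, NumericVector fir, int block, double gamma,
                int unwrap_turns, double kp, double ki, double kd,
                int log_dec, NumericVector probe) {
  const int n_raw = zA.size();
  if (zB.size() != n_raw || zC.size() != n_raw || zD.size() != n_raw)
    stop("antenna sequences must have equal length");
  const int n_bb = n_raw / D;
  const int K = fir.size();
  const int n_blocks = n_bb / block;
  const int n_log = (n_bb + log_dec - 1) / log_dec;
  const double T = D / fz;
  const double two_pi = 2.0 * M_PI;
  const bool have_probe = probe.size() > 0;
  if (have_probe && probe.size() < n_bb)
    stop("probe must have at least n_bb samples");

  const ComplexVector* zs[4] = { &zA, &zB, &zC, &zD };

  // ring buffers of mixed (NCO-rotated) samples, one per antenna
  std::vector<std::vector<cplx>> ring(4, std::vector<cplx>(K, cplx(0, 0)));
  int pos = K - 1;  // index of most recent sample

  NumericVector omega_log(n_log), theta_log(n_log);
  LogicalVector lock_log(n_log);
  NumericMatrix alpha_out(n_blocks, 4), dphi_out(n_blocks, 4);
  ComplexMatrix r_mean(n_blocks, 5);
  NumericMatrix r_pow(n_blocks, 5);

  double dphi[4] = {0, 0, 0, 0};
  double omega = f_center;      // tracking frequency (relative to LO)
  double integ = 0.0, e_prev = 0.0, theta_u_prev = 0.0;
  double phi = 0.0;             // NCO phase accumulator
  cplx acc_sum[5];
  double acc_pow[5] = {0, 0, 0, 0, 0};
  for (int s = 0; s < 5; ++s) acc_sum[s] = cplx(0, 0);
  const double hi = f_center + limit, lo = f_center - limit;

  for (int n = 0; n < n_bb; ++n) {
    double f_nco = omega + (have_probe ? probe[n] : 0.0);
    double dphi_inc = two_pi * f_nco / fz;
    for (int j = 0; j < D; ++j) {
      phi = wrap_phase(phi + dphi_inc);
      cplx m(std::cos(phi), -std::sin(phi));
      pos = (pos + 1) % K;
      int idx = n * D + j;
      for (int a = 0; a < 4; ++a) {
        Rcomplex z = (*zs[a])[idx];
        ring[a][pos] = cplx(z.r, z.i) * m;
      }
    }
    cplx u[4], uM(0, 0);
    for (int a = 0; a < 4; ++a) {
      cplx acc(0, 0);
      for (int k = 0; k < K; ++k)
        acc += fir[k] * ring[a][(pos - k + K) % K];
      // compensation phase acts as an offset to the NCO accumulator:
      // u = exp(-i*dphi) * filtered(z * exp(-i*phi)); with the update
      // dphi += gamma * alpha this drives the rotated angles to zero.
      u[a] = cplx(std::cos(dphi[a]), -std::sin(dphi[a])) * acc;
      uM += u[a];
    }
    double theta_raw = (uM == cplx(0, 0)) ? 0.0
                       : std::atan2(uM.imag(), uM.real());
    double kturn = std::round((theta_u_prev - theta_raw) / two_pi);
    if (kturn > unwrap_turns) kturn = unwrap_turns;
    if (kturn < -unwrap_turns) kturn = -unwrap_turns;
    double theta_u = theta_raw + two_pi * kturn;

    double e = theta_u;
    double i_cand = integ + ki * e * T;
    double d_term = (kd != 0.0) ? kd * (e - e_prev) / T : 0.0;
    double omega_unclip = f_center + kp * e + i_cand + d_term;
    bool clipped;
    if (omega_unclip >= hi) {
      omega = hi; clipped = true;
      if (e <= 0) integ = i_cand;          // only integrate back inward
    } else if (omega_unclip <= lo) {
      omega = lo; clipped = true;
      if (e >= 0) integ = i_cand;
    } else {
      omega = omega_unclip; clipped = false;
      integ = i_cand;
    }
    e_prev = e;
    theta_u_prev = theta_u;

    if (n % log_dec == 0) {
      int il = n / log_dec;
      omega_log[il] = omega;
      theta_log[il] = theta_u;
      lock_log[il] = !clipped;
    }

    // block statistics of the baseband vectors; the rotation by the main
    // vector's phase is applied at block level (block-mean phase), so the
    // reported rotated-vector statistics are not correlated with the
    // per-sample noise they summarize
    for (int a = 0; a < 4; ++a) {
      acc_sum[a] += u[a];
      acc_pow[a] += std::norm(u[a]);
    }
    acc_sum[4] += uM;
    acc_pow[4] += std::norm(uM);

    if ((n + 1) % block == 0) {
      int bi = (n + 1) / block - 1;
      if (bi < n_blocks) {
        cplx meanM = acc_sum[4] / (double)block;
        double thetaB = (meanM == cplx(0, 0)) ? 0.0
                        : std::atan2(meanM.imag(), meanM.real());
        cplx erB(std::cos(thetaB), -std::sin(thetaB));
        for (int s = 0; s < 5; ++s) {
          cplx mean = (acc_sum[s] / (double)block) * erB;
          Rcomplex rc; rc.r = mean.real(); rc.i = mean.imag();
          r_mean(bi, s) = rc;
          r_pow(bi, s) = acc_pow[s] / (double)block;
          if (s < 4) {
            double alpha = (mean == cplx(0, 0)) ? 0.0
                           : std::atan2(mean.imag(), mean.real());
            alpha_out(bi, s) = alpha;
            dphi[s] += gamma * alpha;
            dphi_out(bi, s) = dphi[s];
          }
        }
      }
      for (int s = 0; s < 5; ++s) { acc_sum[s] = cplx(0, 0); acc_pow[s] = 0.0; }
    }
  }

  return List::create(_["omega"] = omega_log, _["theta"] = theta_log,
                      _["lock"] = lock_log, _["alpha"] = alpha_out,
                      _["dphi"] = dphi_out, _["r_mean"] = r_mean,
                      _["r_pow"] = r_pow, _["n_bb"] = n_bb);
}
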