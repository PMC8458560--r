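#include <Rcpp.h>
using namespace Rcpp;

// Roughness bookkeeping for the step-exchange algorithm. "Roughness" of a
// sequence is the mean squared difference of consecutive values; the
// exchange reorders a sampled triplet sequence until both the speed and the
// turning-angle roughness are at or below the measured targets.

static inline double sq(double x) { return x * x; }

static double pair_sum(const std::vector<double>& v, int k) {
  // contribution of pair (k, k+1), 0-based
  return sq(v[k + 1] - v[k]);
}

// Objective: summed normalised excess of roughness over target.
static inline double objective(double rs, double rt,
                               double ts, double tt, double eps) {
  double o = 0.0;
  if (rs > ts) o += (rs - ts) / std::max(ts, eps);
  if (rt > tt) o += (rt - tt) / std::max(tt, eps);
  return o;
}

// [[Rcpp::export(name = ".remix_exchange_cpp")]]
List remix_exchange_cpp(NumericVector speeds, NumericVector turns,
                        double target_speed, double target_turn,
                        int max_proposals) {
  const int n = speeds.size();
  if (n != turns.size()) stop("speed and turn sequences differ in length");
  if (n < 2) stop("need at least 2 steps to exchange");
  const int np = n - 1;          // number of consecutive pairs
  const double eps = 1e-12;

  std::vector<double> sp(speeds.begin(), speeds.end());
  std::vector<double> tu(turns.begin(), turns.end());
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;

  double ss = 0.0, st = 0.0;     // sums of squared consecutive differences
  for (int k = 0; k < np; ++k) {
    ss += pair_sum(sp, k);
    st += pair_sum(tu, k);
  }
  double rs = ss / np, rt = st / np;
  double obj = objective(rs, rt, target_speed, target_turn, eps);

  std::vector<double> trace;     // objective after each accepted swap
  int accepted = 0, proposals = 0;
  bool done = (rs <= target_speed && rt <= target_turn);

  while (!done && proposals < max_proposals) {
    ++proposals;
    int i = (int)(unif_rand() * n); if (i >= n) i = n - 1;
    int j = (int)(unif_rand() * n); if (j >= n) j = n - 1;
    if (i == j) continue;
    if (i > j) std::swap(i, j);

    // pairs touching positions i and j (0-based pair index k = (k, k+1))
    int cand[4] = { i - 1, i, j - 1, j };
    double old_s = 0.0, old_t = 0.0;
    int used[4]; int nu = 0;
    for (int c = 0; c < 4; ++c) {
      int k = cand[c];
      if (k < 0 || k >= np) continue;
      bool dup = false;
      for (int d = 0; d < nu; ++d) if (used[d] == k) dup = true;
      if (dup) continue;
      used[nu++] = k;
      old_s += pair_sum(sp, k);
      old_t += pair_sum(tu, k);
    }
    std::swap(sp[i], sp[j]);
    std::swap(tu[i], tu[j]);
    double new_s = 0.0, new_t = 0.0;
    for (int d = 0; d < nu; ++d) {
      new_s += pair_sum(sp, used[d]);
      new_t += pair_sum(tu, used[d]);
    }
    double ss2 = ss + new_s - old_s;
    double st2 = st + new_t - old_t;
    double obj2 = objective(ss2 / np, st2 / np, target_speed, target_turn,
                            eps);
    if (obj2 < obj) {            // strict decrease; ties rejected
      std::swap(ord[i], ord[j]);
      ss = ss2; st = st2;
      rs = ss / np; rt = st / np;
      obj = obj2;
      ++accepted;
      trace.push_back(obj);
      done = (rs <= target_speed && rt <= target_turn);
    } else {                     // revert
      std::swap(sp[i], sp[j]);
      std::swap(tu[i], tu[j]);
    }
  }

  IntegerVector order(ord.begin(), ord.end());
  return List::create(_["order"] = order + 1,   // 1-based for R
                      _["converged"] = done,
                      _["n_proposals"] = proposals,
                      _["n_accepted"] = accepted,
                      _["speed_roughness"] = rs,
                      _["turn_roughness"] = rt,
                      _["objective_trace"] = NumericVector(trace.begin(),
                                                           trace.end()));
}

// Rodrigues rotation of v about unit axis k by angle theta (right-hand rule)
static void rotate3(const double v[3], const double k[3], double theta,
                    double out[3]) {
  double c = std::cos(theta), s = std::sin(theta);
  double kv = k[0] * v[0] + k[1] * v[1] + k[2] * v[2];
  double cx[3] = { k[1] * v[2] - k[2] * v[1],
                   k[2] * v[0] - k[0] * v[2],
                   k[0] * v[1] - k[1] * v[0] };
  for (int d = 0; d < 3; ++d)
    out[d] = v[d] * c + cx[d] * s + k[d] * kv * (1.0 - c);
}

// Rebuild positions from (speed, turning angle, plane angle) triplets.
// State: direction u (unit) and plane normal nrm (unit, orthogonal to u).
// Each triplet first rotates nrm about u by the plane angle, then rotates u
// about the new normal by the turning angle, then advances speed * dt.
// [[Rcpp::export(name = ".reconstruct_track_cpp")]]
NumericMatrix reconstruct_track_cpp(NumericVector speeds,
                                    NumericVector turns_deg,
                                    NumericVector planes_deg,
                                    double dt,
                                    NumericVector u0, NumericVector n0) {
  const int n = speeds.size();
  if (turns_deg.size() != n || planes_deg.size() != n)
    stop("triplet components differ in length");
  const double d2r = M_PI / 180.0;
  double u[3] = { u0[0], u0[1], u0[2] };
  double nrm[3] = { n0[0], n0[1], n0[2] };
  NumericMatrix pos(n + 1, 3);
  double p[3] = { 0.0, 0.0, 0.0 };
  for (int s = 0; s < n; ++s) {
    double n2[3], u2[3];
    rotate3(nrm, u, planes_deg[s] * d2r, n2);
    rotate3(u, n2, turns_deg[s] * d2r, u2);
    for (int d = 0; d < 3; ++d) {
      nrm[d] = n2[d];
      u[d] = u2[d];
    }
    // re-orthonormalise the frame: rounding errors otherwise feed back
    // through the rotation axes and grow exponentially over long tracks
    double lu = std::sqrt(u[0] * u[0] + u[1] * u[1] + u[2] * u[2]);
    for (int d = 0; d < 3; ++d) u[d] /= lu;
    double nu = nrm[0] * u[0] + nrm[1] * u[1] + nrm[2] * u[2];
    for (int d = 0; d < 3; ++d) nrm[d] -= nu * u[d];
    double ln = std::sqrt(nrm[0] * nrm[0] + nrm[1] * nrm[1] +
                          nrm[2] * nrm[2]);
    for (int d = 0; d < 3; ++d) nrm[d] /= ln;
    for (int d = 0; d < 3; ++d) {
      p[d] += u[d] * speeds[s] / 60.0 * dt;
      pos(s + 1, d) = p[d];
    }
  }
  return pos;
}
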