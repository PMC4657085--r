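#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// ---- small 3-vector helpers -------------------------------------------------

static inline void vsub(const double* a, const double* b, double* out) {
  out[0] = a[0] - b[0]; out[1] = a[1] - b[1]; out[2] = a[2] - b[2];
}
static inline double vdot(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
static inline void vcross(const double* a, const double* b, double* out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}
static inline double vnorm(const double* a) { return std::sqrt(vdot(a, a)); }
static inline bool vunit(double* a) {
  double n = vnorm(a);
  if (n < 1e-12) return false;
  a[0] /= n; a[1] /= n; a[2] /= n;
  return true;
}
static inline double clamp1(double x) {
  return x > 1.0 ? 1.0 : (x < -1.0 ? -1.0 : x);
}

// Signed solid-angle contribution of one ordered segment pair to the writhe
// (exact polygon formula; the full writhe is sum over unordered pairs / 2*pi).
static double pair_omega(const double* p1, const double* p2,
                         const double* p3, const double* p4) {
  double r12[3], r34[3], r13[3], r14[3], r23[3], r24[3];
  vsub(p2, p1, r12); vsub(p4, p3, r34);
  vsub(p3, p1, r13); vsub(p4, p1, r14);
  vsub(p3, p2, r23); vsub(p4, p2, r24);

  double n1[3], n2[3], n3[3], n4[3];
  vcross(r13, r14, n1); vcross(r14, r24, n2);
  vcross(r24, r23, n3); vcross(r23, r13, n4);
  if (!vunit(n1) || !vunit(n2) || !vunit(n3) || !vunit(n4)) return 0.0;

  double omega = std::asin(clamp1(vdot(n1, n2))) +
                 std::asin(clamp1(vdot(n2, n3))) +
                 std::asin(clamp1(vdot(n3, n4))) +
                 std::asin(clamp1(vdot(n4, n1)));
  double cr[3];
  vcross(r34, r12, cr);
  double s = vdot(cr, r13);
  if (s > 0) return omega;
  if (s < 0) return -omega;
  return 0.0;
}

// Minimum distance between segments (p1,p2) and (p3,p4).
static double seg_seg_distance(const double* p1, const double* p2,
                               const double* p3, const double* p4) {
  double d1[3], d2[3], r[3];
  vsub(p2, p1, d1); vsub(p4, p3, d2); vsub(p1, p3, r);
  double a = vdot(d1, d1), e = vdot(d2, d2), f = vdot(d2, r);
  double s = 0.0, t = 0.0;
  if (a <= 1e-15 && e <= 1e-15) {
    // both degenerate
  } else if (a <= 1e-15) {
    t = clamp1(f / e) * 0.5 + 0.5; // not exact clamp; handled below
    t = f / e; t = t < 0 ? 0 : (t > 1 ? 1 : t);
  } else {
    double c = vdot(d1, r);
    if (e <= 1e-15) {
      s = -c / a; s = s < 0 ? 0 : (s > 1 ? 1 : s);
    } else {
      double b = vdot(d1, d2);
      double denom = a * e - b * b;
      if (denom > 1e-15) {
        s = (b * f - c * e) / denom;
        s = s < 0 ? 0 : (s > 1 ? 1 : s);
      }
      t = (b * s + f) / e;
      if (t < 0) { t = 0; s = -c / a; s = s < 0 ? 0 : (s > 1 ? 1 : s); }
      else if (t > 1) { t = 1; s = (b - c) / a; s = s < 0 ? 0 : (s > 1 ? 1 : s); }
    }
  }
  double q1[3], q2[3], d[3];
  for (int k = 0; k < 3; ++k) {
    q1[k] = p1[k] + s * d1[k];
    q2[k] = p3[k] + t * d2[k];
    d[k] = q1[k] - q2[k];
  }
  return vnorm(d);
}

struct ChainView {
  const double* x; const double* y; const double* z; int n;
  void pt(int i, double* out) const {
    i = ((i % n) + n) % n;
    out[0] = x[i]; out[1] = y[i]; out[2] = z[i];
  }
};

static double full_writhe(const std::vector<double>& vx,
                          const std::vector<double>& vy,
                          const std::vector<double>& vz) {
  int n = (int)vx.size();
  double wr = 0.0;
  double p1[3], p2[3], p3[3], p4[3];
  for (int i = 0; i < n; ++i) {
    p1[0] = vx[i]; p1[1] = vy[i]; p1[2] = vz[i];
    int i1 = (i + 1) % n;
    p2[0] = vx[i1]; p2[1] = vy[i1]; p2[2] = vz[i1];
    for (int j = i + 2; j < n; ++j) {
      if (i == 0 && j == n - 1) continue; // cyclically adjacent
      p3[0] = vx[j]; p3[1] = vy[j]; p3[2] = vz[j];
      int j1 = (j + 1) % n;
      p4[0] = vx[j1]; p4[1] = vy[j1]; p4[2] = vz[j1];
      wr += pair_omega(p1, p2, p3, p4);
    }
  }
  return wr / (2.0 * M_PI);
}

// [[Rcpp::export]]
double writhe_gauss_cpp(NumericMatrix verts) {
  int n = verts.nrow();
  std::vector<double> vx(n), vy(n), vz(n);
  for (int i = 0; i < n; ++i) {
    vx[i] = verts(i, 0); vy[i] = verts(i, 1); vz[i] = verts(i, 2);
  }
  return full_writhe(vx, vy, vz);
}

// [[Rcpp::export]]
double min_nonadjacent_distance_cpp(NumericMatrix verts) {
  int n = verts.nrow();
  double best = R_PosInf;
  double p1[3], p2[3], p3[3], p4[3];
  for (int i = 0; i < n; ++i) {
    p1[0] = verts(i, 0); p1[1] = verts(i, 1); p1[2] = verts(i, 2);
    int i1 = (i + 1) % n;
    p2[0] = verts(i1, 0); p2[1] = verts(i1, 1); p2[2] = verts(i1, 2);
    for (int j = i + 2; j < n; ++j) {
      if (i == 0 && j == n - 1) continue;
      p3[0] = verts(j, 0); p3[1] = verts(j, 1); p3[2] = verts(j, 2);
      int j1 = (j + 1) % n;
      p4[0] = verts(j1, 0); p4[1] = verts(j1, 1); p4[2] = verts(j1, 2);
      double d = seg_seg_distance(p1, p2, p3, p4);
      if (d < best) best = d;
    }
  }
  return best;
}

// Bend/kink energy at one junction (junction v sits between segments v-1 and v).
static double junction_energy(const std::vector<double>& vx,
                              const std::vector<double>& vy,
                              const std::vector<double>& vz,
                              int v, double A_over_b,
                              const std::vector<double>& kink_pref,
                              const std::vector<double>& kink_stiff,
                              bool* is_kink = nullptr) {
  int n = (int)vx.size();
  int vm = (v - 1 + n) % n, vp = (v + 1) % n;
  double u1[3] = { vx[v] - vx[vm], vy[v] - vy[vm], vz[v] - vz[vm] };
  double u2[3] = { vx[vp] - vx[v], vy[vp] - vy[v], vz[vp] - vz[v] };
  vunit(u1); vunit(u2);
  double theta = std::acos(clamp1(vdot(u1, u2)));
  if (kink_pref[v] >= 0.0) {
    if (is_kink) *is_kink = true;
    return kink_stiff[v] * A_over_b * (1.0 - std::cos(theta - kink_pref[v]));
  }
  if (is_kink) *is_kink = false;
  return A_over_b * (1.0 - std::cos(theta));
}

// [[Rcpp::export]]
List chain_energy_cpp(NumericMatrix verts, double b, double A, double C,
                      double L, double tw, double tw0,
                      IntegerVector kink_idx, NumericVector kink_pref_deg,
                      NumericVector kink_stiff, double excluded) {
  int n = verts.nrow();
  std::vector<double> vx(n), vy(n), vz(n);
  for (int i = 0; i < n; ++i) {
    vx[i] = verts(i, 0); vy[i] = verts(i, 1); vz[i] = verts(i, 2);
  }
  std::vector<double> kp(n, -1.0), ks(n, 1.0);
  for (int k = 0; k < kink_idx.size(); ++k) {
    kp[kink_idx[k]] = kink_pref_deg[k] * M_PI / 180.0;
    ks[kink_idx[k]] = kink_stiff[k];
  }
  double Aob = A / b;
  double e_bend = 0.0, e_kink = 0.0;
  for (int v = 0; v < n; ++v) {
    bool isk = false;
    double e = junction_energy(vx, vy, vz, v, Aob, kp, ks, &isk);
    if (isk) e_kink += e; else e_bend += e;
  }
  double dtw = tw - tw0;
  double e_twist = 2.0 * M_PI * M_PI * C * dtw * dtw / L;
  double e_overlap = 0.0;
  if (excluded > 0.0) {
    double dmin = min_nonadjacent_distance_cpp(verts);
    if (dmin < excluded) e_overlap = R_PosInf;
  }
  return List::create(_["bend"] = e_bend, _["twist"] = e_twist,
                      _["kink"] = e_kink, _["overlap"] = e_overlap);
}

// Writhe sum over pairs (moved segment, unmoved segment), used for
// incremental updates during crankshaft moves. `moved` marks segments.
static double cross_writhe(const std::vector<double>& vx,
                           const std::vector<double>& vy,
                           const std::vector<double>& vz,
                           const std::vector<char>& moved) {
  int n = (int)vx.size();
  double acc = 0.0;
  double p1[3], p2[3], p3[3], p4[3];
  for (int i = 0; i < n; ++i) {
    if (!moved[i]) continue;
    p1[0] = vx[i]; p1[1] = vy[i]; p1[2] = vz[i];
    int i1 = (i + 1) % n;
    p2[0] = vx[i1]; p2[1] = vy[i1]; p2[2] = vz[i1];
    for (int j = 0; j < n; ++j) {
      if (moved[j]) continue;
      int lo = i < j ? i : j, hi = i < j ? j : i;
      if (hi - lo <= 1 || (lo == 0 && hi == n - 1)) continue; // adjacent
      p3[0] = vx[j]; p3[1] = vy[j]; p3[2] = vz[j];
      int j1 = (j + 1) % n;
      p4[0] = vx[j1]; p4[1] = vy[j1]; p4[2] = vz[j1];
      acc += pair_omega(p1, p2, p3, p4);
    }
  }
  return acc / (2.0 * M_PI);
}

// Metropolis crankshaft Monte Carlo on a closed, inextensible chain.
// Vertices strictly between two pivot vertices are rotated about the chord.
// In torsionally constrained mode Lk is fixed and Tw = Lk - Wr after each
// accepted move; in nicked mode Tw stays relaxed (tw = tw0) and twist
// energy is zero.
// [[Rcpp::export]]
List mc_relax_cpp(NumericMatrix verts, double b, double A, double C, double L,
                  double tw_init, double lk, bool constrained,
                  IntegerVector kink_idx, NumericVector kink_pref_deg,
                  NumericVector kink_stiff,
                  int steps, double max_angle_deg, double excluded,
                  int record_every, double temp_factor, bool snapshots) {
  int n = verts.nrow();
  std::vector<double> vx(n), vy(n), vz(n);
  for (int i = 0; i < n; ++i) {
    vx[i] = verts(i, 0); vy[i] = verts(i, 1); vz[i] = verts(i, 2);
  }
  std::vector<double> kp(n, -1.0), ks(n, 1.0);
  for (int k = 0; k < kink_idx.size(); ++k) {
    kp[kink_idx[k]] = kink_pref_deg[k] * M_PI / 180.0;
    ks[kink_idx[k]] = kink_stiff[k];
  }
  double Aob = A / b;
  double max_angle = max_angle_deg * M_PI / 180.0;
  double twist_k = 2.0 * M_PI * M_PI * C / L; // per (turns)^2

  double wr = constrained ? full_writhe(vx, vy, vz) : 0.0;
  double tw = constrained ? (lk - wr) : tw_init;

  auto twist_energy = [&](double wr_now) -> double {
    if (!constrained) return 0.0;
    double dtw = (lk - wr_now) - tw_init; // tw_init holds relaxed turns
    return twist_k * dtw * dtw;
  };

  long accepted = 0;
  int n_rec = steps / record_every + 1;
  NumericVector rec_step(n_rec), rec_wr(n_rec), rec_tw(n_rec), rec_lk(n_rec),
      rec_eb(n_rec), rec_et(n_rec), rec_ek(n_rec), rec_acc(n_rec);
  List snaps(snapshots ? n_rec : 0);
  int ri = 0;

  std::vector<char> moved(n, 0);
  std::vector<double> sx(n), sy(n), sz(n);

  auto record = [&](int step) {
    double wr_now = constrained ? wr : full_writhe(vx, vy, vz);
    double tw_now = constrained ? (lk - wr_now) : tw_init;
    double eb = 0.0, ek = 0.0;
    for (int v = 0; v < n; ++v) {
      bool isk = false;
      double e = junction_energy(vx, vy, vz, v, Aob, kp, ks, &isk);
      if (isk) ek += e; else eb += e;
    }
    rec_step[ri] = step;
    rec_wr[ri] = wr_now;
    rec_tw[ri] = tw_now;
    rec_lk[ri] = constrained ? lk : (tw_now + wr_now);
    rec_eb[ri] = eb;
    rec_et[ri] = constrained ? twist_energy(wr_now) : 0.0;
    rec_ek[ri] = ek;
    rec_acc[ri] = step > 0 ? (double)accepted / step : 0.0;
    if (snapshots) {
      NumericMatrix sm(n, 3);
      for (int i = 0; i < n; ++i) {
        sm(i, 0) = vx[i]; sm(i, 1) = vy[i]; sm(i, 2) = vz[i];
      }
      snaps[ri] = sm;
    }
    ++ri;
  };

  record(0);

  for (int step = 1; step <= steps; ++step) {
    // pivot vertices i and j = i + sep (cyclic); interior vertices rotate
    int i = (int)(unif_rand() * n);
    if (i >= n) i = n - 1;
    int sep = 2 + (int)(unif_rand() * (n - 3)); // 2 .. n-2
    if (sep > n - 2) sep = n - 2;
    int j = (i + sep) % n;
    double angle = (2.0 * unif_rand() - 1.0) * max_angle;

    // rotation axis: chord i -> j
    double ax[3] = { vx[j] - vx[i], vy[j] - vy[i], vz[j] - vz[i] };
    if (!vunit(ax)) continue;
    double ca = std::cos(angle), sa = std::sin(angle);

    // old local energy at the two hinge junctions
    double e_old = junction_energy(vx, vy, vz, i, Aob, kp, ks) +
                   junction_energy(vx, vy, vz, j, Aob, kp, ks);

    std::fill(moved.begin(), moved.end(), 0);
    // moved vertices: i+1 .. j-1 (cyclic); moved segments: i .. j-1 (cyclic)
    for (int s = 0; s < sep; ++s) moved[(i + s) % n] = 1;

    double dwr_old = 0.0;
    if (constrained) dwr_old = cross_writhe(vx, vy, vz, moved);

    // apply rotation to a scratch copy of the moved vertices (Rodrigues)
    for (int s = 1; s < sep; ++s) {
      int v = (i + s) % n;
      double r[3] = { vx[v] - vx[i], vy[v] - vy[i], vz[v] - vz[i] };
      double axr[3];
      vcross(ax, r, axr);
      double ad = vdot(ax, r);
      sx[v] = vx[i] + r[0] * ca + axr[0] * sa + ax[0] * ad * (1 - ca);
      sy[v] = vy[i] + r[1] * ca + axr[1] * sa + ax[1] * ad * (1 - ca);
      sz[v] = vz[i] + r[2] * ca + axr[2] * sa + ax[2] * ad * (1 - ca);
    }
    // swap in proposal
    std::vector<double> ox(sep - 1), oy(sep - 1), oz(sep - 1);
    for (int s = 1; s < sep; ++s) {
      int v = (i + s) % n;
      ox[s - 1] = vx[v]; oy[s - 1] = vy[v]; oz[s - 1] = vz[v];
      vx[v] = sx[v]; vy[v] = sy[v]; vz[v] = sz[v];
    }

    bool reject = false;

    // excluded volume: moved vs unmoved, non-adjacent
    if (excluded > 0.0) {
      double p1[3], p2[3], p3[3], p4[3];
      for (int s = 0; s < sep && !reject; ++s) {
        int sm_ = (i + s) % n;
        p1[0] = vx[sm_]; p1[1] = vy[sm_]; p1[2] = vz[sm_];
        int s1 = (sm_ + 1) % n;
        p2[0] = vx[s1]; p2[1] = vy[s1]; p2[2] = vz[s1];
        for (int t = 0; t < n; ++t) {
          if (moved[t]) continue;
          int lo = sm_ < t ? sm_ : t, hi = sm_ < t ? t : sm_;
          if (hi - lo <= 1 || (lo == 0 && hi == n - 1)) continue;
          p3[0] = vx[t]; p3[1] = vy[t]; p3[2] = vz[t];
          int t1 = (t + 1) % n;
          p4[0] = vx[t1]; p4[1] = vy[t1]; p4[2] = vz[t1];
          if (seg_seg_distance(p1, p2, p3, p4) < excluded) { reject = true; break; }
        }
      }
    }

    double de = 0.0, dwr = 0.0;
    if (!reject) {
      double e_new = junction_energy(vx, vy, vz, i, Aob, kp, ks) +
                     junction_energy(vx, vy, vz, j, Aob, kp, ks);
      de = e_new - e_old;
      if (constrained) {
        double dwr_new = cross_writhe(vx, vy, vz, moved);
        dwr = dwr_new - dwr_old;
        de += twist_energy(wr + dwr) - twist_energy(wr);
      }
      if (de > 0.0 && unif_rand() >= std::exp(-de / temp_factor)) reject = true;
    }

    if (reject) {
      for (int s = 1; s < sep; ++s) {
        int v = (i + s) % n;
        vx[v] = ox[s - 1]; vy[v] = oy[s - 1]; vz[v] = oz[s - 1];
      }
    } else {
      ++accepted;
      if (constrained) {
        wr += dwr;
        tw = lk - wr;
      }
    }

    if (constrained && step % 2000 == 0) wr = full_writhe(vx, vy, vz); // kill drift
    if (step % record_every == 0) record(step);
  }

  NumericMatrix out_verts(n, 3);
  for (int i = 0; i < n; ++i) {
    out_verts(i, 0) = vx[i]; out_verts(i, 1) = vy[i]; out_verts(i, 2) = vz[i];
  }
  DataFrame traj = DataFrame::create(
      _["step"] = rec_step, _["writhe"] = rec_wr, _["twist"] = rec_tw,
      _["lk"] = rec_lk, _["e_bend"] = rec_eb, _["e_twist"] = rec_et,
      _["e_kink"] = rec_ek, _["accept_rate"] = rec_acc);
  return List::create(_["vertices"] = out_verts, _["trajectory"] = traj,
                      _["accepted"] = (double)accepted,
                      _["twist"] = constrained ? (lk - wr) : tw_init,
                      _["snapshots"] = snaps);
}
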