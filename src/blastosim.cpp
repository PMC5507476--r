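// Core numerics for the blastocyst agent model: pairwise forces from the
// interaction potential V(d) = exp(-d) - S*exp(-d/beta), with a
// polarity-dependent attraction factor for TE-TE pairs, overdamped Euler
// integration of positions and polarity vectors, and the halfway-point
// true-nearest-neighbour rule used in 3D.
//
// All randomness goes through R's RNG (norm_rand), so simulations are
// reproducible from set.seed() on the R side.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// lineage codes shared with the R side
static const int L_UNDET = 0, L_TE = 1, L_EPI = 2, L_PRE = 3;

struct ModelP {
  double S_def, S_pre, S_neutral, beta, polar_pref;
  double global_cutoff, te_te_cutoff, te_icm_cutoff;
  double dt, noise_pos, noise_ang, pol_mob;
  int adhesion_mode;   // 0 uniform, 1 differential (PrE weaker), 2 neutralized ICM
  bool icm_global;     // ICM-ICM potential without distance cutoff
};

static ModelP parse_params(const List& par) {
  ModelP p;
  p.S_def        = as<double>(par["S_default"]);
  p.S_pre        = as<double>(par["S_pre"]);
  p.S_neutral    = as<double>(par["S_neutral_adhesion"]);
  p.beta         = as<double>(par["beta"]);
  p.polar_pref   = as<double>(par["polar_prefactor"]);
  p.global_cutoff= as<double>(par["global_cutoff"]);
  p.te_te_cutoff = as<double>(par["te_te_cutoff"]);
  p.te_icm_cutoff= as<double>(par["te_icm_cutoff"]);
  p.dt           = as<double>(par["dt"]);
  p.noise_pos    = as<double>(par["noise_sd_position"]);
  p.noise_ang    = as<double>(par["noise_sd_angle"]);
  p.pol_mob      = as<double>(par["polarity_mobility"]);
  p.adhesion_mode= as<int>(par["adhesion_mode"]);
  p.icm_global   = as<bool>(par["icm_global_potential"]);
  return p;
}

// attraction factor for pairs that do not involve two TE cells
static inline double pair_S(int li, int lj, const ModelP& p) {
  bool has_pre = (li == L_PRE) || (lj == L_PRE);
  bool te = (li == L_TE) || (lj == L_TE);
  if (!te) { // ICM-ICM
    if (p.adhesion_mode == 2) return p.S_neutral;
    if (p.adhesion_mode == 1 && has_pre) return p.S_pre;
    return p.S_def;
  }
  // TE-ICM
  if (p.adhesion_mode == 1 && has_pre) return p.S_pre;
  return p.S_def;
}

// ---------------------------------------------------------------------------
// halfway-point true-nearest-neighbour rule (any dimension)
//
// For each point i take its k closest points; candidate j is kept when no
// other candidate lies strictly closer to the midpoint of (i, j) than i
// itself (ties retained). An edge requires retention from both endpoints.
// ---------------------------------------------------------------------------
static std::vector<std::vector<bool>> true_nn_adj(const NumericMatrix& pos, int k) {
  const int n = pos.nrow(), D = pos.ncol();
  std::vector<std::vector<bool>> keep(n, std::vector<bool>(n, false));
  std::vector<double> d2(n);
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      double s = 0.0;
      for (int d = 0; d < D; ++d) { double t = pos(i,d) - pos(j,d); s += t*t; }
      d2[j] = s;
    }
    for (int j = 0; j < n; ++j) ord[j] = j;
    std::sort(ord.begin(), ord.end(), [&](int a, int b){ return d2[a] < d2[b]; });
    int ncand = std::min(k, n - 1);
    // candidates are ord[1..ncand] (ord[0] == i)
    for (int a = 1; a <= ncand; ++a) {
      int j = ord[a];
      double half2 = d2[j] / 4.0; // squared distance midpoint -> i
      bool ok = true;
      for (int b = 1; b <= ncand && ok; ++b) {
        int m = ord[b];
        if (m == j) continue;
        double s = 0.0;
        for (int d = 0; d < D; ++d) {
          double mid = 0.5 * (pos(i,d) + pos(j,d));
          double t = mid - pos(m,d);
          s += t*t;
        }
        if (s < half2 - 1e-12) ok = false;
      }
      keep[i][j] = ok;
    }
  }
  return keep;
}

// TE partner adjacency in 2D: each TE circle is linked to its 2 nearest TE
// circles (union of both directions), giving the chain topology of a
// single-file sheet. Non-TE rows are left unlinked.
static std::vector<std::vector<bool>> te_top2_adj(const NumericMatrix& pos,
                                                  const IntegerVector& lin) {
  const int n = pos.nrow(), D = pos.ncol();
  std::vector<int> te;
  for (int i = 0; i < n; ++i) if (lin[i] == L_TE) te.push_back(i);
  std::vector<std::vector<bool>> adj(n, std::vector<bool>(n, false));
  const int m = (int) te.size();
  for (int a = 0; a < m; ++a) {
    int i = te[a];
    int b1 = -1, b2 = -1;
    double d1 = R_PosInf, d2 = R_PosInf;
    for (int b = 0; b < m; ++b) {
      if (b == a) continue;
      int j = te[b];
      double s = 0.0;
      for (int d = 0; d < D; ++d) { double t = pos(i,d)-pos(j,d); s += t*t; }
      if (s < d1) { d2 = d1; b2 = b1; d1 = s; b1 = j; }
      else if (s < d2) { d2 = s; b2 = j; }
    }
    if (b1 >= 0) { adj[i][b1] = true; adj[b1][i] = true; }
    if (b2 >= 0) { adj[i][b2] = true; adj[b2][i] = true; }
  }
  return adj;
}

// [[Rcpp::export]]
LogicalMatrix cpp_te_partners(NumericMatrix pos, IntegerVector lineage) {
  std::vector<std::vector<bool>> adj = te_top2_adj(pos, lineage);
  const int n = pos.nrow();
  LogicalMatrix out(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) out(i, j) = adj[i][j];
  return out;
}

// [[Rcpp::export]]
LogicalMatrix cpp_true_nn(NumericMatrix pos, int k = 20) {
  const int n = pos.nrow();
  std::vector<std::vector<bool>> keep = true_nn_adj(pos, k);
  LogicalMatrix adj(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      adj(i, j) = (i != j) && keep[i][j] && keep[j][i];
  return adj;
}

// ---------------------------------------------------------------------------
// force / energy kernel
// ---------------------------------------------------------------------------

// symmetric TE-TE interaction adjacency: 2-nearest-partner chain in 2D,
// mutual halfway-point true nearest neighbours in 3D
static std::vector<std::vector<bool>> te_adjacency(const NumericMatrix& pos,
                                                   const IntegerVector& lin,
                                                   int D, int k) {
  if (D == 2) return te_top2_adj(pos, lin);
  std::vector<std::vector<bool>> keep = true_nn_adj(pos, k);
  const int n = pos.nrow();
  std::vector<std::vector<bool>> adj(n, std::vector<bool>(n, false));
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) adj[i][j] = keep[i][j] && keep[j][i];
  return adj;
}

// accumulate force of pair (i,j) into F; returns pair energy.
// te_nn: symmetric TE-TE interaction adjacency (null => distance only).
static inline double pair_accumulate(int i, int j, const NumericMatrix& pos,
                                     const IntegerVector& lin,
                                     const NumericMatrix& pol,
                                     const ModelP& p, int D,
                                     const std::vector<std::vector<bool>>* te_nn,
                                     NumericMatrix* F) {
  double r[3], d2 = 0.0;
  for (int d = 0; d < D; ++d) { r[d] = pos(i,d) - pos(j,d); d2 += r[d]*r[d]; }
  int li = lin[i], lj = lin[j];
  bool both_te = (li == L_TE && lj == L_TE);
  bool te_repulse_only = false;
  if (both_te) {
    if (d2 >= p.te_te_cutoff * p.te_te_cutoff) return 0.0;
    // polar bonds (tight junctions) only with the nearest TE partners;
    // other TE pairs in range keep the soft volume exclusion (S = 0)
    if (te_nn && !(*te_nn)[i][j]) te_repulse_only = true;
  } else if (li == L_TE || lj == L_TE) {
    if (d2 > p.te_icm_cutoff * p.te_icm_cutoff) return 0.0;
  } else {
    if (!p.icm_global && d2 > p.global_cutoff * p.global_cutoff) return 0.0;
  }
  double dd = std::sqrt(d2);
  if (dd < 1e-9) stop("coincident cells (zero pairwise distance)");
  double u[3]; // unit vector from j to i: grad_i d
  for (int d = 0; d < D; ++d) u[d] = r[d] / dd;
  double ed = std::exp(-dd), eb = std::exp(-dd / p.beta);

  if (te_repulse_only) {
    double dVdd = -ed;
    if (F) for (int d = 0; d < D; ++d) {
      (*F)(i,d) -= dVdd * u[d];
      (*F)(j,d) += dVdd * u[d];
    }
    return ed;
  }

  if (!both_te) {
    double S = pair_S(li, lj, p);
    double dVdd = -ed + (S / p.beta) * eb;
    if (F) for (int d = 0; d < D; ++d) {
      (*F)(i,d) -= dVdd * u[d];
      (*F)(j,d) += dVdd * u[d];
    }
    return ed - S * eb;
  }

  // TE-TE: S = pref * (e_i . e_j - (e_i . rhat)(e_j . rhat)),  rhat = unit i->j = -u
  double rh[3];
  for (int d = 0; d < D; ++d) rh[d] = -u[d];
  double ee = 0.0, a = 0.0, b = 0.0;
  for (int d = 0; d < D; ++d) {
    ee += pol(i,d) * pol(j,d);
    a  += pol(i,d) * rh[d];
    b  += pol(j,d) * rh[d];
  }
  double S = p.polar_pref * (ee - a * b);
  double dVdd = -ed + (S / p.beta) * eb;
  if (F) {
    // full gradient: the dependence of S on the separation direction gives
    // the tangential term that makes the TE sheet stiff against bending
    // (cells position themselves perpendicular to the polarity axis)
    double gS[3];
    for (int d = 0; d < D; ++d) {
      double Mei = (a * rh[d] - pol(i,d)) / dd;
      double Mej = (b * rh[d] - pol(j,d)) / dd;
      gS[d] = -p.polar_pref * (b * Mei + a * Mej);
    }
    for (int d = 0; d < D; ++d) {
      double Fi = -dVdd * u[d] + eb * gS[d]; // -grad_i V
      (*F)(i,d) += Fi;
      (*F)(j,d) -= Fi;
    }
  }
  return ed - S * eb;
}

// [[Rcpp::export]]
NumericMatrix cpp_forces(NumericMatrix pos, IntegerVector lineage,
                         NumericMatrix pol, List params, int nn_k = 20) {
  const int n = pos.nrow(), D = pos.ncol();
  ModelP p = parse_params(params);
  NumericMatrix F(n, D);
  std::vector<std::vector<bool>> nn;
  const std::vector<std::vector<bool>>* nnp = nullptr;
  bool has_te = false;
  for (int i = 0; i < n; ++i) if (lineage[i] == L_TE) { has_te = true; break; }
  if (has_te) { nn = te_adjacency(pos, lineage, D, nn_k); nnp = &nn; }
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      pair_accumulate(i, j, pos, lineage, pol, p, D, nnp, &F);
  return F;
}

// [[Rcpp::export]]
double cpp_energy(NumericMatrix pos, IntegerVector lineage,
                  NumericMatrix pol, List params, int nn_k = 20) {
  const int n = pos.nrow(), D = pos.ncol();
  ModelP p = parse_params(params);
  double E = 0.0;
  std::vector<std::vector<bool>> nn;
  const std::vector<std::vector<bool>>* nnp = nullptr;
  bool has_te = false;
  for (int i = 0; i < n; ++i) if (lineage[i] == L_TE) { has_te = true; break; }
  if (has_te) { nn = te_adjacency(pos, lineage, D, nn_k); nnp = &nn; }
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      E += pair_accumulate(i, j, pos, lineage, pol, p, D, nnp, nullptr);
  return E;
}

// ---------------------------------------------------------------------------
// relaxation: Euler steps of positions and polarity vectors with a Verlet
// pair list. Early exit when the largest deterministic displacement per step
// (dt * max|F|) drops below conv_tol.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_relax(NumericMatrix pos_in, IntegerVector lineage, NumericMatrix pol_in,
               List params, int max_steps, int min_steps = 20,
               double conv_tol = 1e-3, bool noise = true,
               bool do_positions = true, bool do_polarities = true,
               int nn_every = 10, int nn_k = 20) {
  NumericMatrix pos = clone(pos_in), pol = clone(pol_in);
  const int n = pos.nrow(), D = pos.ncol();
  ModelP p = parse_params(params);
  RNGScope rng;

  if (n == 0) return List::create(_["pos"] = pos, _["pol"] = pol,
                                  _["steps"] = 0, _["max_force"] = 0.0);

  const double skin = 0.8;
  const double list_cut = std::max(p.global_cutoff, p.te_icm_cutoff) + skin;
  const double list_cut2 = list_cut * list_cut;

  std::vector<int> pi, pj;           // Verlet pair list
  NumericMatrix pos_build(n, D);     // positions at last list build
  std::vector<std::vector<bool>> te_nn;
  bool has_te = false;
  for (int i = 0; i < n; ++i) if (lineage[i] == L_TE) { has_te = true; break; }
  bool need_nn = has_te;

  auto build_list = [&]() {
    pi.clear(); pj.clear();
    for (int i = 0; i < n; ++i) {
      for (int j = i + 1; j < n; ++j) {
        bool icm_pair = (lineage[i] != L_TE) && (lineage[j] != L_TE);
        if (p.icm_global && icm_pair) { pi.push_back(i); pj.push_back(j); continue; }
        double s = 0.0;
        for (int d = 0; d < D; ++d) { double t = pos(i,d)-pos(j,d); s += t*t; }
        if (s <= list_cut2) { pi.push_back(i); pj.push_back(j); }
      }
    }
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < D; ++d) pos_build(i,d) = pos(i,d);
  };

  build_list();
  if (need_nn) te_nn = te_adjacency(pos, lineage, D, nn_k);

  NumericMatrix F(n, D);
  NumericMatrix tq(n, D); // polarity alignment "torque"
  double maxF = 0.0;
  int step = 0;

  for (step = 1; step <= max_steps; ++step) {
    // rebuild the pair list when any particle moved more than skin/2
    double maxdisp2 = 0.0;
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      for (int d = 0; d < D; ++d) { double t = pos(i,d)-pos_build(i,d); s += t*t; }
      if (s > maxdisp2) maxdisp2 = s;
    }
    if (maxdisp2 > 0.25 * skin * skin) build_list();
    if (need_nn && (step % nn_every == 1 || nn_every == 1))
      te_nn = te_adjacency(pos, lineage, D, nn_k);

    std::fill(F.begin(), F.end(), 0.0);
    const std::vector<std::vector<bool>>* nnp = need_nn ? &te_nn : nullptr;
    for (size_t q = 0; q < pi.size(); ++q)
      pair_accumulate(pi[q], pj[q], pos, lineage, pol, p, D, nnp, &F);

    maxF = 0.0;
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      for (int d = 0; d < D; ++d) s += F(i,d) * F(i,d);
      if (s > maxF) maxF = s;
    }
    maxF = std::sqrt(maxF);

    if (do_positions) {
      for (int i = 0; i < n; ++i)
        for (int d = 0; d < D; ++d) {
          pos(i,d) += p.dt * F(i,d);
          if (noise) pos(i,d) += p.noise_pos * norm_rand();
        }
    }

    if (do_polarities && has_te) {
      std::fill(tq.begin(), tq.end(), 0.0);
      // alignment over TE-TE in-range pairs (same pair set as the forces)
      for (size_t q = 0; q < pi.size(); ++q) {
        int i = pi[q], j = pj[q];
        if (lineage[i] != L_TE || lineage[j] != L_TE) continue;
        double d2 = 0.0;
        for (int d = 0; d < D; ++d) { double t = pos(i,d)-pos(j,d); d2 += t*t; }
        if (d2 >= p.te_te_cutoff * p.te_te_cutoff) continue;
        if (need_nn && !te_nn[i][j]) continue;
        double ee = 0.0;
        for (int d = 0; d < D; ++d) ee += pol(i,d) * pol(j,d);
        for (int d = 0; d < D; ++d) {
          tq(i,d) += pol(j,d) - ee * pol(i,d);
          tq(j,d) += pol(i,d) - ee * pol(j,d);
        }
      }
      for (int i = 0; i < n; ++i) {
        if (lineage[i] != L_TE) continue;
        double nrm = 0.0;
        for (int d = 0; d < D; ++d) {
          pol(i,d) += p.dt * p.pol_mob * tq(i,d);
          if (noise) pol(i,d) += p.noise_ang * norm_rand();
          nrm += pol(i,d) * pol(i,d);
        }
        nrm = std::sqrt(nrm);
        if (nrm > 1e-12) for (int d = 0; d < D; ++d) pol(i,d) /= nrm;
      }
    }

    if (step >= min_steps && p.dt * maxF < conv_tol) break;
  }
  if (step > max_steps) step = max_steps;

  return List::create(_["pos"] = pos, _["pol"] = pol,
                      _["steps"] = step, _["max_force"] = maxF);
}
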