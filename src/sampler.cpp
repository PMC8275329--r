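// Collapsed Gibbs sampler for joint motif + exonuclease-footprint binding
// modes. PWM columns, window Bernoullis and mixture weights are integrated
// out under conjugate Dirichlet/Beta priors; the chain samples, per original
// region, the motif position Z, orientation O (forward or reverse-complement
// copy) and mode label I, and per mode the read-window offsets tau+/tau- and
// the motif width w. All likelihoods are ratios against precomputed
// background log-probabilities supplied by R as per-position prefix sums.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

struct Data {
  int npair, ncopy;
  std::vector<int> off, off2;
  std::vector<int> seq, rp, rn, nN;
  std::vector<double> ps, pp, pn; // prefix sums of per-position log bg probs

  int len(int c) const { return off[c + 1] - off[c]; }
  int base(int c, int j) const { return seq[off[c] + j - 1]; }     // j 1-based
  int rpos(int c, int j) const { return rp[off[c] + j - 1]; }
  int rneg(int c, int j) const { return rn[off[c] + j - 1]; }
  double bgs(int c, int a, int b) const { return ps[off2[c] + b] - ps[off2[c] + a - 1]; }
  double bgp(int c, int a, int b) const { return pp[off2[c] + b] - pp[off2[c] + a - 1]; }
  double bgn(int c, int a, int b) const { return pn[off2[c] + b] - pn[off2[c] + a - 1]; }
  bool hasN(int c, int a, int b) const { return (nN[off2[c] + b] - nN[off2[c] + a - 1]) > 0; }
};

struct Cfg {
  int wwin, wmin, wmax, maxoff, stop_mult, max_sweeps, max_passes, warm_sweeps;
  double alpha, a0, b0, delta, tol;
};

struct State {
  int m;
  std::vector<int> Z, O, I;      // per pair: Z 1-based in active copy, O 0/1, I 0-based
  std::vector<int> w, tp, tn;    // per mode
};

static Data parse_data(const List& d) {
  Data D;
  D.npair = as<int>(d["npair"]);
  D.off  = as<std::vector<int> >(d["off"]);
  D.off2 = as<std::vector<int> >(d["off2"]);
  D.seq  = as<std::vector<int> >(d["seq"]);
  D.rp   = as<std::vector<int> >(d["rpos"]);
  D.rn   = as<std::vector<int> >(d["rneg"]);
  D.nN   = as<std::vector<int> >(d["nN"]);
  D.ps   = as<std::vector<double> >(d["pseq"]);
  D.pp   = as<std::vector<double> >(d["ppos"]);
  D.pn   = as<std::vector<double> >(d["pneg"]);
  D.ncopy = 2 * D.npair;
  return D;
}

static Cfg parse_cfg(const List& c) {
  Cfg C;
  C.wwin = as<int>(c["window_width"]);
  C.wmin = as<int>(c["w_min"]);
  C.wmax = as<int>(c["w_max"]);
  C.maxoff = as<int>(c["max_offset"]);
  C.stop_mult = as<int>(c["stop_mult"]);
  C.max_sweeps = as<int>(c["max_sweeps"]);
  C.max_passes = as<int>(c["max_passes"]);
  C.warm_sweeps = as<int>(c["warm_sweeps"]);
  C.alpha = as<double>(c["alpha"]);
  C.a0 = as<double>(c["beta_a"]);
  C.b0 = as<double>(c["beta_b"]);
  C.delta = as<double>(c["delta"]);
  C.tol = as<double>(c["tol"]);
  return C;
}

static State parse_state(const List& s) {
  State S;
  S.m = as<int>(s["m"]);
  S.Z = as<std::vector<int> >(s["Z"]);
  S.O = as<std::vector<int> >(s["O"]);
  IntegerVector I = s["I"];
  S.I.resize(I.size());
  for (int i = 0; i < I.size(); i++) S.I[i] = I[i] - 1;
  S.w  = as<std::vector<int> >(s["w"]);
  S.tp = as<std::vector<int> >(s["tau_pos"]);
  S.tn = as<std::vector<int> >(s["tau_neg"]);
  return S;
}

static List state_to_list(const State& S) {
  IntegerVector I(S.I.size());
  for (size_t i = 0; i < S.I.size(); i++) I[i] = S.I[i] + 1;
  return List::create(_["m"] = S.m, _["Z"] = wrap(S.Z), _["O"] = wrap(S.O),
                      _["I"] = I, _["w"] = wrap(S.w),
                      _["tau_pos"] = wrap(S.tp), _["tau_neg"] = wrap(S.tn));
}

class Gibbs {
public:
  Data D; Cfg C; State S;
  // integer-count lgamma tables: lgX[c] = lgamma(c + x)
  std::vector<double> lgA, lg4A, lgA0, lgB0, lgAB, lgD;
  // collapsed counts
  std::vector<std::vector<int> > pc;        // per mode: w*4 base counts
  std::vector<std::vector<int> > c1p, c1n;  // per mode: wwin one-counts
  std::vector<int> nk;
  std::vector<double> bsite, bwp, bwn;      // per mode: summed member bg log-probs
  std::vector<double> dlt;                  // cached per-mode marginal ratio terms
  double bgconst, score;
  // membership pseudo-count used in the SAMPLING weights only; flattened
  // (large) during warm sweeps so weak modes can re-acquire members, always
  // equal to the prior delta in the score and in hill climbing
  double dmemb;

  Gibbs(const List& data, const List& state, const List& cfg) {
    D = parse_data(data); C = parse_cfg(cfg); S = parse_state(state);
    dmemb = C.delta;
    int n = D.npair;
    lgA.resize(n + 2); lg4A.resize(n + 2); lgA0.resize(n + 2);
    lgB0.resize(n + 2); lgAB.resize(n + 2); lgD.resize(n + 2);
    for (int c = 0; c <= n + 1; c++) {
      lgA[c]  = ::lgamma(c + C.alpha);
      lg4A[c] = ::lgamma(c + 4.0 * C.alpha);
      lgA0[c] = ::lgamma(c + C.a0);
      lgB0[c] = ::lgamma(c + C.b0);
      lgAB[c] = ::lgamma(c + C.a0 + C.b0);
      lgD[c]  = ::lgamma(c + C.delta);
    }
    bgconst = 0.0;
    for (int c = 0; c < D.ncopy; c++) {
      int L = D.len(c);
      bgconst += D.bgs(c, 1, L) + D.bgp(c, 1, L) + D.bgn(c, 1, L);
    }
    rebuild();
  }

  int cp(int i, int o) const { return o ? i + D.npair : i; }

  void rebuild() {
    int m = S.m;
    pc.assign(m, std::vector<int>());
    c1p.assign(m, std::vector<int>(C.wwin, 0));
    c1n.assign(m, std::vector<int>(C.wwin, 0));
    nk.assign(m, 0);
    bsite.assign(m, 0.0); bwp.assign(m, 0.0); bwn.assign(m, 0.0);
    for (int k = 0; k < m; k++) pc[k].assign(S.w[k] * 4, 0);
    for (int i = 0; i < D.npair; i++) add_pair(i);
    dlt.assign(m, 0.0);
    for (int k = 0; k < m; k++) dlt[k] = delta_k(k);
    score = total_score();
  }

  void add_pair(int i) { pair_counts(i, +1); }
  void rm_pair(int i)  { pair_counts(i, -1); }

  void pair_counts(int i, int sgn) {
    int k = S.I[i], z = S.Z[i], c = cp(i, S.O[i]), w = S.w[k];
    for (int a = 0; a < w; a++) pc[k][a * 4 + D.base(c, z + a)] += sgn;
    bsite[k] += sgn * D.bgs(c, z, z + w - 1);
    int zp = z + S.tp[k], zn = z + S.tn[k];
    for (int a = 0; a < C.wwin; a++) {
      c1p[k][a] += sgn * D.rpos(c, zp + a);
      c1n[k][a] += sgn * D.rneg(c, zn + a);
    }
    bwp[k] += sgn * D.bgp(c, zp, zp + C.wwin - 1);
    bwn[k] += sgn * D.bgn(c, zn, zn + C.wwin - 1);
    nk[k] += sgn;
  }

  // collapsed marginal ratio term of mode k (Dirichlet-multinomial columns and
  // Beta-Bernoulli window positions over their background probabilities)
  double delta_k(int k) const {
    double d = 0.0;
    int w = S.w[k], n = nk[k];
    for (int a = 0; a < w; a++) {
      d += lg4A[0] - lg4A[n];
      const int* col = &pc[k][a * 4];
      for (int b = 0; b < 4; b++) d += lgA[col[b]] - lgA[0];
    }
    d -= bsite[k];
    for (int a = 0; a < C.wwin; a++) {
      d += lgA0[c1p[k][a]] - lgA0[0] + lgB0[n - c1p[k][a]] - lgB0[0] - (lgAB[n] - lgAB[0]);
      d += lgA0[c1n[k][a]] - lgA0[0] + lgB0[n - c1n[k][a]] - lgB0[0] - (lgAB[n] - lgAB[0]);
    }
    d -= bwp[k] + bwn[k];
    return d;
  }

  double memb_term() const {
    double d = ::lgamma(S.m * C.delta) - ::lgamma((double)D.npair + S.m * C.delta);
    for (int k = 0; k < S.m; k++) d += lgD[nk[k]] - lgD[0];
    return d;
  }

  double total_score() const {
    double s = bgconst + memb_term();
    for (int k = 0; k < S.m; k++) s += dlt[k];
    return s;
  }

  void refresh(int k) { dlt[k] = delta_k(k); }

  bool validZ(int i, int o, int k, int z) const {
    int c = cp(i, o), L = D.len(c), w = S.w[k];
    if (z < 1 || z + w - 1 > L) return false;
    if (D.hasN(c, z, z + w - 1)) return false;
    int a = z + S.tp[k];
    if (a < 1 || a + C.wwin - 1 > L) return false;
    int b = z + S.tn[k];
    if (b < 1 || b + C.wwin - 1 > L) return false;
    return true;
  }

  // ---- (Z, O, I) update -------------------------------------------------

  struct Cand { int k, o, z; double lw; };

  // collapsed predictive weights for pair i over all (mode, orientation,
  // position) candidates; call with pair i's counts REMOVED
  void zi_weights(int i, std::vector<Cand>& out) const {
    out.clear();
    int m = S.m;
    // per-mode predictive log tables
    std::vector<std::vector<double> > lpw(m), l1p(m), l0p(m), l1n(m), l0n(m);
    std::vector<double> lmb(m);
    for (int k = 0; k < m; k++) {
      int w = S.w[k], n = nk[k];
      lpw[k].resize(w * 4);
      double den = std::log(n + 4.0 * C.alpha);
      for (int a = 0; a < w; a++)
        for (int b = 0; b < 4; b++)
          lpw[k][a * 4 + b] = std::log(pc[k][a * 4 + b] + C.alpha) - den;
      l1p[k].resize(C.wwin); l0p[k].resize(C.wwin);
      l1n[k].resize(C.wwin); l0n[k].resize(C.wwin);
      double denw = std::log(n + C.a0 + C.b0);
      for (int a = 0; a < C.wwin; a++) {
        l1p[k][a] = std::log(c1p[k][a] + C.a0) - denw;
        l0p[k][a] = std::log(n - c1p[k][a] + C.b0) - denw;
        l1n[k][a] = std::log(c1n[k][a] + C.a0) - denw;
        l0n[k][a] = std::log(n - c1n[k][a] + C.b0) - denw;
      }
      lmb[k] = std::log(n + dmemb) - std::log(D.npair - 1.0 + S.m * dmemb);
    }
    for (int k = 0; k < m; k++) {
      int w = S.w[k];
      for (int o = 0; o < 2; o++) {
        int c = cp(i, o), L = D.len(c);
        int zmax = L - w + 1;
        for (int z = 1; z <= zmax; z++) {
          if (!validZ(i, o, k, z)) continue;
          double lw = lmb[k];
          for (int a = 0; a < w; a++) lw += lpw[k][a * 4 + D.base(c, z + a)];
          lw -= D.bgs(c, z, z + w - 1);
          int zp = z + S.tp[k], zn = z + S.tn[k];
          for (int a = 0; a < C.wwin; a++) {
            lw += D.rpos(c, zp + a) ? l1p[k][a] : l0p[k][a];
            lw += D.rneg(c, zn + a) ? l1n[k][a] : l0n[k][a];
          }
          lw -= D.bgp(c, zp, zp + C.wwin - 1) + D.bgn(c, zn, zn + C.wwin - 1);
          Cand cd; cd.k = k; cd.o = o; cd.z = z; cd.lw = lw;
          out.push_back(cd);
        }
      }
    }
  }

  static int sample_from(const std::vector<Cand>& cands) {
    double mx = -INFINITY;
    for (size_t j = 0; j < cands.size(); j++) if (cands[j].lw > mx) mx = cands[j].lw;
    if (!std::isfinite(mx)) return -1;
    double tot = 0.0;
    std::vector<double> p(cands.size());
    for (size_t j = 0; j < cands.size(); j++) { p[j] = std::exp(cands[j].lw - mx); tot += p[j]; }
    double u = unif_rand() * tot, cum = 0.0;
    for (size_t j = 0; j < cands.size(); j++) { cum += p[j]; if (u <= cum) return (int)j; }
    return (int)cands.size() - 1;
  }

  void set_pair(int i, int k, int o, int z) {
    S.I[i] = k; S.O[i] = o; S.Z[i] = z;
    add_pair(i);
  }

  // one Gibbs update of (Z_i, O_i, I_i); returns nothing, updates score
  void update_zi(int i) {
    int kold = S.I[i];
    rm_pair(i);
    std::vector<Cand> cands;
    zi_weights(i, cands);
    int j = sample_from(cands);
    if (j < 0) { // no valid candidate anywhere: restore
      add_pair(i);
      return;
    }
    set_pair(i, cands[j].k, cands[j].o, cands[j].z);
    refresh(kold); if (cands[j].k != kold) refresh(cands[j].k);
    score = total_score();
  }

  // greedy argmax update; returns true if the pair moved
  bool climb_zi(int i) {
    int kold = S.I[i], oold = S.O[i], zold = S.Z[i];
    rm_pair(i);
    std::vector<Cand> cands;
    zi_weights(i, cands);
    int best = -1, cur = -1;
    for (size_t j = 0; j < cands.size(); j++) {
      if (best < 0 || cands[j].lw > cands[best].lw) best = (int)j;
      if (cands[j].k == kold && cands[j].o == oold && cands[j].z == zold) cur = (int)j;
    }
    bool move = best >= 0 && (cur < 0 || cands[best].lw > cands[cur].lw + C.tol);
    if (!move) { add_pair(i); return false; }
    set_pair(i, cands[best].k, cands[best].o, cands[best].z);
    refresh(kold); if (cands[best].k != kold) refresh(cands[best].k);
    score = total_score();
    return true;
  }

  // ---- tau update -------------------------------------------------------

  void tau_grid(int k, int strand, int& lo, int& hi) const {
    if (strand == 0) { lo = -C.maxoff - C.wwin; hi = S.w[k] - 1; }
    else             { lo = -C.wwin + 1;        hi = S.w[k] + C.maxoff; }
  }

  // collapsed weights for tau_k^s over the grid; all member windows move
  // together; a tau any member's window cannot accommodate is invalid
  void tau_weights(int k, int strand, std::vector<int>& taus,
                   std::vector<double>& wts) const {
    taus.clear(); wts.clear();
    int lo, hi; tau_grid(k, strand, lo, hi);
    std::vector<int> mem;
    for (int i = 0; i < D.npair; i++) if (S.I[i] == k) mem.push_back(i);
    int n = nk[k];
    for (int tau = lo; tau <= hi; tau++) {
      bool ok = true;
      for (size_t j = 0; j < mem.size() && ok; j++) {
        int i = mem[j], c = cp(i, S.O[i]), a = S.Z[i] + tau;
        if (a < 1 || a + C.wwin - 1 > D.len(c)) ok = false;
      }
      if (!ok) continue;
      std::vector<int> ones(C.wwin, 0);
      double bgsum = 0.0;
      for (size_t j = 0; j < mem.size(); j++) {
        int i = mem[j], c = cp(i, S.O[i]), a = S.Z[i] + tau;
        if (strand == 0) {
          for (int t = 0; t < C.wwin; t++) ones[t] += D.rpos(c, a + t);
          bgsum += D.bgp(c, a, a + C.wwin - 1);
        } else {
          for (int t = 0; t < C.wwin; t++) ones[t] += D.rneg(c, a + t);
          bgsum += D.bgn(c, a, a + C.wwin - 1);
        }
      }
      double lw = -bgsum;
      for (int t = 0; t < C.wwin; t++)
        lw += lgA0[ones[t]] - lgA0[0] + lgB0[n - ones[t]] - lgB0[0] - (lgAB[n] - lgAB[0]);
      taus.push_back(tau); wts.push_back(lw);
    }
  }

  void apply_tau(int k, int strand, int tau) {
    if (strand == 0) S.tp[k] = tau; else S.tn[k] = tau;
    // rebuild this mode's window counts
    if (strand == 0) { c1p[k].assign(C.wwin, 0); bwp[k] = 0.0; }
    else             { c1n[k].assign(C.wwin, 0); bwn[k] = 0.0; }
    for (int i = 0; i < D.npair; i++) {
      if (S.I[i] != k) continue;
      int c = cp(i, S.O[i]), a = S.Z[i] + tau;
      if (strand == 0) {
        for (int t = 0; t < C.wwin; t++) c1p[k][t] += D.rpos(c, a + t);
        bwp[k] += D.bgp(c, a, a + C.wwin - 1);
      } else {
        for (int t = 0; t < C.wwin; t++) c1n[k][t] += D.rneg(c, a + t);
        bwn[k] += D.bgn(c, a, a + C.wwin - 1);
      }
    }
    refresh(k);
    score = total_score();
  }

  bool update_tau(int k, int strand, bool greedy) {
    std::vector<int> taus; std::vector<double> wts;
    tau_weights(k, strand, taus, wts);
    if (taus.empty()) return false;     // no valid offset: leave unchanged
    int cur = strand == 0 ? S.tp[k] : S.tn[k];
    int j;
    if (greedy) {
      j = 0;
      int curj = -1;
      for (size_t t = 0; t < taus.size(); t++) {
        if (wts[t] > wts[j]) j = (int)t;
        if (taus[t] == cur) curj = (int)t;
      }
      if (curj >= 0 && wts[j] <= wts[curj] + C.tol) return false;
    } else {
      std::vector<Cand> cd(taus.size());
      for (size_t t = 0; t < taus.size(); t++) { cd[t].lw = wts[t]; }
      j = sample_from(cd);
      if (j < 0 || taus[j] == cur) { return false; }
    }
    apply_tau(k, strand, taus[j]);
    return true;
  }

  // ---- width update -----------------------------------------------------

  // candidate edge moves: {dw, shift of motif start}
  // stay, grow-left, grow-right, shrink-left, shrink-right
  // windows keep their absolute positions: tau is re-expressed as tau - shift
  void width_weights(int k, std::vector<int>& dws, std::vector<int>& shifts,
                     std::vector<double>& wts) const {
    static const int DW[5] = {0, 1, 1, -1, -1};
    static const int SH[5] = {0, -1, 0, 1, 0};
    dws.clear(); shifts.clear(); wts.clear();
    std::vector<int> mem;
    for (int i = 0; i < D.npair; i++) if (S.I[i] == k) mem.push_back(i);
    int n = nk[k];
    for (int c5 = 0; c5 < 5; c5++) {
      int wn = S.w[k] + DW[c5], sh = SH[c5];
      if (wn < C.wmin || wn > C.wmax) continue;
      int tpn = S.tp[k] - sh, tnn = S.tn[k] - sh;
      // offsets must stay on the allowed grid for the new width
      if (tpn < -C.maxoff - C.wwin || tpn > wn - 1) continue;
      if (tnn < -C.wwin + 1 || tnn > wn + C.maxoff) continue;
      bool ok = true;
      std::vector<int> cnt(wn * 4, 0);
      double bgsum = 0.0;
      for (size_t j = 0; j < mem.size() && ok; j++) {
        int i = mem[j], c = cp(i, S.O[i]), zn = S.Z[i] + sh;
        if (zn < 1 || zn + wn - 1 > D.len(c) || D.hasN(c, zn, zn + wn - 1)) { ok = false; break; }
        for (int a = 0; a < wn; a++) cnt[a * 4 + D.base(c, zn + a)]++;
        bgsum += D.bgs(c, zn, zn + wn - 1);
      }
      if (!ok) continue;
      double lw = -bgsum;
      for (int a = 0; a < wn; a++) {
        lw += lg4A[0] - lg4A[n];
        for (int b = 0; b < 4; b++) lw += lgA[cnt[a * 4 + b]] - lgA[0];
      }
      dws.push_back(DW[c5]); shifts.push_back(sh); wts.push_back(lw);
    }
  }

  void apply_width(int k, int dw, int sh) {
    S.w[k] += dw; S.tp[k] -= sh; S.tn[k] -= sh;
    int w = S.w[k];
    pc[k].assign(w * 4, 0); bsite[k] = 0.0;
    for (int i = 0; i < D.npair; i++) {
      if (S.I[i] != k) continue;
      S.Z[i] += sh;
      int c = cp(i, S.O[i]), z = S.Z[i];
      for (int a = 0; a < w; a++) pc[k][a * 4 + D.base(c, z + a)]++;
      bsite[k] += D.bgs(c, z, z + w - 1);
    }
    refresh(k);
    score = total_score();
  }

  bool update_width(int k, bool greedy) {
    std::vector<int> dws, shifts; std::vector<double> wts;
    width_weights(k, dws, shifts, wts);
    if (dws.empty()) return false;
    int j;
    if (greedy) {
      j = 0; int curj = -1;
      for (size_t t = 0; t < dws.size(); t++) {
        if (wts[t] > wts[j]) j = (int)t;
        if (dws[t] == 0) curj = (int)t;
      }
      if (curj >= 0 && wts[j] <= wts[curj] + C.tol) return false;
    } else {
      std::vector<Cand> cd(dws.size());
      for (size_t t = 0; t < dws.size(); t++) cd[t].lw = wts[t];
      j = sample_from(cd);
      if (j < 0 || dws[j] == 0) return false;
    }
    apply_width(k, dws[j], shifts[j]);
    return true;
  }

  // ---- counts export ----------------------------------------------------

  List counts_list() const {
    List pwm(S.m), wp(S.m), wn(S.m);
    for (int k = 0; k < S.m; k++) {
      IntegerMatrix m4(4, S.w[k]);
      for (int a = 0; a < S.w[k]; a++)
        for (int b = 0; b < 4; b++) m4(b, a) = pc[k][a * 4 + b];
      pwm[k] = m4;
      wp[k] = wrap(c1p[k]);
      wn[k] = wrap(c1n[k]);
    }
    return List::create(_["pwm_counts"] = pwm, _["win_pos"] = wp, _["win_neg"] = wn,
                        _["nk"] = wrap(nk), _["bsite"] = wrap(bsite),
                        _["bwpos"] = wrap(bwp), _["bwneg"] = wrap(bwn));
  }
};

// [[Rcpp::export]]
List cg_run_chain(List data, List state, List cfg, bool record_trace = true) {
  Gibbs G(data, state, cfg);
  double best = G.score;
  State bestS = G.S;
  std::vector<double> trace;
  long since = 0, updates = 0;
  long stop = (long)G.C.stop_mult * G.D.ncopy;
  int sweeps = 0;
  bool done = false;
  while (!done && sweeps < G.C.max_sweeps) {
    sweeps++;
    G.dmemb = sweeps <= G.C.warm_sweeps ?
      std::max(1.0, (double)G.D.npair / G.S.m) : G.C.delta;
    for (int i = 0; i < G.D.npair && !done; i++) {
      G.update_zi(i);
      updates++;
      if (record_trace) trace.push_back(G.score);
      if (G.score > best + G.C.tol) { best = G.score; bestS = G.S; since = 0; }
      else if (++since >= stop) done = true;
    }
    for (int k = 0; k < G.S.m && !done; k++)
      for (int s = 0; s < 2 && !done; s++) {
        G.update_tau(k, s, false);
        updates++;
        if (record_trace) trace.push_back(G.score);
        if (G.score > best + G.C.tol) { best = G.score; bestS = G.S; since = 0; }
        else if (++since >= stop) done = true;
      }
    for (int k = 0; k < G.S.m && !done; k++) {
      G.update_width(k, false);
      updates++;
      if (record_trace) trace.push_back(G.score);
      if (G.score > best + G.C.tol) { best = G.score; bestS = G.S; since = 0; }
      else if (++since >= stop) done = true;
    }
  }
  return List::create(_["best_state"] = state_to_list(bestS),
                      _["best_score"] = best,
                      _["final_state"] = state_to_list(G.S),
                      _["final_score"] = G.score,
                      _["trace"] = wrap(trace),
                      _["sweeps"] = sweeps, _["updates"] = (double)updates);
}

// [[Rcpp::export]]
List cg_hill_climb(List data, List state, List cfg) {
  Gibbs G(data, state, cfg);
  G.dmemb = G.C.delta;
  int passes = 0;
  long moves_total = 0;
  while (passes < G.C.max_passes) {
    passes++;
    long moves = 0;
    for (int i = 0; i < G.D.npair; i++) if (G.climb_zi(i)) moves++;
    for (int k = 0; k < G.S.m; k++)
      for (int s = 0; s < 2; s++) if (G.update_tau(k, s, true)) moves++;
    for (int k = 0; k < G.S.m; k++) if (G.update_width(k, true)) moves++;
    moves_total += moves;
    if (moves == 0) break;
  }
  return List::create(_["state"] = state_to_list(G.S), _["score"] = G.score,
                      _["passes"] = passes, _["moves"] = (double)moves_total);
}

// [[Rcpp::export]]
double cg_score(List data, List state, List cfg) {
  Gibbs G(data, state, cfg);
  return G.score;
}

// [[Rcpp::export]]
List cg_counts(List data, List state, List cfg) {
  Gibbs G(data, state, cfg);
  return G.counts_list();
}

// [[Rcpp::export]]
DataFrame cg_zi_weights(List data, List state, List cfg, int i) {
  Gibbs G(data, state, cfg);
  G.rm_pair(i - 1);
  std::vector<Gibbs::Cand> cands;
  G.zi_weights(i - 1, cands);
  IntegerVector k(cands.size()), o(cands.size()), z(cands.size());
  NumericVector lw(cands.size());
  for (size_t j = 0; j < cands.size(); j++) {
    k[j] = cands[j].k + 1; o[j] = cands[j].o; z[j] = cands[j].z; lw[j] = cands[j].lw;
  }
  return DataFrame::create(_["k"] = k, _["o"] = o, _["z"] = z, _["logw"] = lw);
}

// [[Rcpp::export]]
List cg_tau_weights(List data, List state, List cfg, int k, int strand) {
  Gibbs G(data, state, cfg);
  std::vector<int> taus; std::vector<double> wts;
  G.tau_weights(k - 1, strand, taus, wts);
  return List::create(_["tau"] = wrap(taus), _["logw"] = wrap(wts));
}

// [[Rcpp::export]]
List cg_width_weights(List data, List state, List cfg, int k) {
  Gibbs G(data, state, cfg);
  std::vector<int> dws, shifts; std::vector<double> wts;
  G.width_weights(k - 1, dws, shifts, wts);
  return List::create(_["dw"] = wrap(dws), _["shift"] = wrap(shifts),
                      _["logw"] = wrap(wts));
}

// Performs a random sequence of incremental updates (for count-integrity
// audits): returns the final state, the incrementally maintained counts and
// a from-scratch recount of the same state.
// [[Rcpp::export]]
List cg_random_updates(List data, List state, List cfg, int n_updates) {
  Gibbs G(data, state, cfg);
  for (int t = 0; t < n_updates; t++) {
    double u = unif_rand();
    if (u < 0.8) {
      int i = (int)(unif_rand() * G.D.npair); if (i >= G.D.npair) i = G.D.npair - 1;
      G.update_zi(i);
    } else if (u < 0.9) {
      int k = (int)(unif_rand() * G.S.m); if (k >= G.S.m) k = G.S.m - 1;
      G.update_tau(k, unif_rand() < 0.5 ? 0 : 1, false);
    } else {
      int k = (int)(unif_rand() * G.S.m); if (k >= G.S.m) k = G.S.m - 1;
      G.update_width(k, false);
    }
  }
  List inc = G.counts_list();
  double inc_score = G.score;
  List st = state_to_list(G.S);
  Gibbs G2(data, st, cfg);
  return List::create(_["state"] = st, _["incremental"] = inc,
                      _["recount"] = G2.counts_list(),
                      _["incremental_score"] = inc_score,
                      _["recount_score"] = G2.score);
}
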