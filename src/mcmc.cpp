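// Metropolis-Hastings sampler over branch placements and mixture
// proportions. The target is the damage-aware mixture likelihood under
// flat priors. Per-base damage/error factors (W), unsupported-base
// probabilities (u) and constant event probabilities are precomputed in
// R; only the HKY transition matrices depend on the proposed placement
// and are recomputed per move.
//
// Likelihood kernel: bases whose damage/error vector W and graph base
// coincide contribute identical factors, so each (fragment, path) pair
// is reduced at start-up to count-weighted classes plus a constant term
// (unsupported bases, indels, softclips). With few distinct quality and
// damage values (the usual case) this makes a proposal one multiply-add
// per class; data with many distinct W vectors fall back to the direct
// per-base product.

#include <Rcpp.h>
#include <vector>
#include <map>
#include <array>
#include <cmath>
using namespace Rcpp;

namespace {

const double PROB_FLOOR = 1e-12;
const double RESCALE = 1e-280;
const double LOG_RESCALE = 280.0 * M_LN10;

// Closed-form HKY85 transition matrix, row-major, rows = ancestral base,
// A,C,G,T order; mirrors hky_transition_matrix() in R exactly.
void hky_pt(double t, const double* pi, double kappa, double* P) {
  const double piR = pi[0] + pi[2], piY = pi[1] + pi[3];
  const double mu = 2.0 * kappa * (pi[0] * pi[2] + pi[1] * pi[3]) +
                    2.0 * piR * piY;
  const double bt = t / mu;
  const double e2 = std::exp(-bt);
  const double eR = std::exp(-bt * (1.0 + piR * (kappa - 1.0)));
  const double eY = std::exp(-bt * (1.0 + piY * (kappa - 1.0)));
  for (int i = 0; i < 4; ++i) {
    const bool iR = (i == 0 || i == 2);
    for (int j = 0; j < 4; ++j) {
      const bool jR = (j == 0 || j == 2);
      const double piC = jR ? piR : piY;
      const double eC = jR ? eR : eY;
      double v;
      if (iR == jR) {
        if (i == j) {
          v = pi[j] + pi[j] * (1.0 / piC - 1.0) * e2 +
              ((piC - pi[j]) / piC) * eC;
        } else {
          v = pi[j] + pi[j] * (1.0 / piC - 1.0) * e2 - (pi[j] / piC) * eC;
        }
      } else {
        v = pi[j] * (1.0 - e2);
      }
      P[4 * i + j] = v;
    }
  }
}

inline double lse2(double a, double b) {
  if (a == R_NegInf) return b;
  if (b == R_NegInf) return a;
  const double m = a > b ? a : b;
  return m + std::log(std::exp(a - m) + std::exp(b - m));
}

struct Sampler {
  // raw per-base data
  int nfrag = 0, nbase = 0, npath = 0;
  const int* frag_ptr = nullptr;
  const int* kind = nullptr;
  const int* bg = nullptr;
  const double* W = nullptr;
  const double* u = nullptr;
  const double* cprob = nullptr;
  const int* support = nullptr;

  double pi[4];
  double kappa = 2.0;
  std::vector<int> br_anc, br_dec;
  std::vector<double> br_len;
  std::vector<std::vector<int>> nbs;

  // grouped representation
  bool grouped = false;
  int nwid = 0;
  std::vector<double> Wd;        // 4 * nwid
  std::vector<int> grp_gid;      // class id = wid * 4 + bg
  std::vector<int> grp_cnt;
  std::vector<size_t> grp_ptr;   // per (path, fragment), npath*nfrag + 1
  std::vector<double> lconst;    // per (path, fragment)

  void build_groups() {
    std::map<std::array<double, 4>, int> wmap;
    std::vector<int> wid(nbase, -1);
    for (int b = 0; b < nbase; ++b) {
      if (kind[b] != 0) continue;
      std::array<double, 4> key = {W[4 * (size_t)b], W[4 * (size_t)b + 1],
                                   W[4 * (size_t)b + 2],
                                   W[4 * (size_t)b + 3]};
      auto it = wmap.find(key);
      if (it == wmap.end()) {
        it = wmap.emplace(key, (int)wmap.size()).first;
      }
      wid[b] = it->second;
    }
    nwid = (int)wmap.size();
    if (nwid * 4 > 2 * nbase) return;   // grouping would not pay off
    Wd.resize(4 * (size_t)nwid);
    for (const auto& kv : wmap) {
      for (int q = 0; q < 4; ++q) Wd[4 * (size_t)kv.second + q] = kv.first[q];
    }
    grp_ptr.assign((size_t)npath * nfrag + 1, 0);
    lconst.assign((size_t)npath * nfrag, 0.0);
    std::vector<std::pair<int, int>> acc;
    for (int p = 0; p < npath; ++p) {
      const int* supcol = support + (size_t)p * nbase;
      for (int f = 0; f < nfrag; ++f) {
        acc.clear();
        double lc = 0.0;
        for (int b = frag_ptr[f]; b < frag_ptr[f + 1]; ++b) {
          if (kind[b] == 1) {
            lc += std::log(std::max(cprob[b], PROB_FLOOR));
          } else if (!supcol[b]) {
            lc += std::log(std::max(u[b], PROB_FLOOR));
          } else {
            const int gid = wid[b] * 4 + bg[b];
            bool found = false;
            for (auto& pr : acc) {
              if (pr.first == gid) { ++pr.second; found = true; break; }
            }
            if (!found) acc.emplace_back(gid, 1);
          }
        }
        const size_t cell = (size_t)p * nfrag + f;
        lconst[cell] = lc;
        grp_ptr[cell + 1] = acc.size();
        for (const auto& pr : acc) {
          grp_gid.push_back(pr.first);
          grp_cnt.push_back(pr.second);
        }
      }
    }
    for (size_t i = 1; i < grp_ptr.size(); ++i) grp_ptr[i] += grp_ptr[i - 1];
    grouped = true;
  }

  // log-probability table per class for a given transition matrix
  void class_logprobs(const double* P, std::vector<double>& G) const {
    G.resize(4 * (size_t)nwid);
    for (int w = 0; w < nwid; ++w) {
      const double* wv = &Wd[4 * (size_t)w];
      for (int bgi = 0; bgi < 4; ++bgi) {
        const double* row = P + 4 * bgi;
        double dot = row[0] * wv[0] + row[1] * wv[1] + row[2] * wv[2] +
                     row[3] * wv[3];
        if (dot < PROB_FLOOR) dot = PROB_FLOOR;
        G[4 * (size_t)w + bgi] = std::log(dot);
      }
    }
  }

  double frag_path_direct(int f, int pn, const double* P) const {
    const int* supcol = support + (size_t)pn * nbase;
    double acc = 1.0;
    int scale = 0;
    for (int b = frag_ptr[f]; b < frag_ptr[f + 1]; ++b) {
      double p;
      if (kind[b] == 1) {
        p = cprob[b];
      } else if (!supcol[b]) {
        p = u[b];
      } else {
        const double* row = P + 4 * bg[b];
        const double* w = W + 4 * (size_t)b;
        p = row[0] * w[0] + row[1] * w[1] + row[2] * w[2] + row[3] * w[3];
      }
      if (p < PROB_FLOOR) p = PROB_FLOOR;
      acc *= p;
      if (acc < RESCALE) { acc /= RESCALE; ++scale; }
    }
    return std::log(acc) - scale * LOG_RESCALE;
  }

  // log P(fr | branch, beta) for every fragment
  void logvec(int branch, double beta, std::vector<double>& out) const {
    const int anc = br_anc[branch], dec = br_dec[branch];
    const double len = br_len[branch];
    double PA[16], PD[16];
    const bool useA = beta < 1.0, useD = beta > 0.0;
    if (useA) hky_pt(beta * len, pi, kappa, PA);
    if (useD) hky_pt((1.0 - beta) * len, pi, kappa, PD);
    const double lw_a = useA ? std::log1p(-beta) : R_NegInf;
    const double lw_d = useD ? std::log(beta) : R_NegInf;
    out.resize(nfrag);
    if (grouped) {
      static thread_local std::vector<double> GA, GD;
      if (useA) class_logprobs(PA, GA);
      if (useD) class_logprobs(PD, GD);
      for (int f = 0; f < nfrag; ++f) {
        double la = R_NegInf, ld = R_NegInf;
        if (useA) {
          const size_t cell = (size_t)anc * nfrag + f;
          double s = lconst[cell];
          for (size_t g = grp_ptr[cell]; g < grp_ptr[cell + 1]; ++g) {
            s += grp_cnt[g] * GA[grp_gid[g]];
          }
          la = s;
        }
        if (useD) {
          const size_t cell = (size_t)dec * nfrag + f;
          double s = lconst[cell];
          for (size_t g = grp_ptr[cell]; g < grp_ptr[cell + 1]; ++g) {
            s += grp_cnt[g] * GD[grp_gid[g]];
          }
          ld = s;
        }
        out[f] = lse2(lw_a + la, lw_d + ld);
      }
    } else {
      for (int f = 0; f < nfrag; ++f) {
        const double la = useA ? frag_path_direct(f, anc, PA) : R_NegInf;
        const double ld = useD ? frag_path_direct(f, dec, PD) : R_NegInf;
        out[f] = lse2(lw_a + la, lw_d + ld);
      }
    }
  }

  double mixture_ll(const std::vector<double>& ltheta,
                    const std::vector<std::vector<double>>& lv) const {
    const int k = (int)ltheta.size();
    double total = 0.0;
    for (int f = 0; f < nfrag; ++f) {
      double m = R_NegInf;
      for (int i = 0; i < k; ++i) {
        const double v = ltheta[i] + lv[i][f];
        if (v > m) m = v;
      }
      if (m == R_NegInf) return R_NegInf;
      double s = 0.0;
      for (int i = 0; i < k; ++i) {
        s += std::exp(ltheta[i] + lv[i][f] - m);
      }
      total += m + std::log(s);
    }
    return total;
  }
};

void init_sampler(Sampler& S, List lik, List treec, NumericVector pi,
                  double kappa) {
  IntegerVector frag_ptr = lik["frag_ptr"];
  IntegerVector kind = lik["kind"];
  IntegerVector bg = lik["bg"];
  NumericMatrix W = lik["W"];
  NumericVector u = lik["u"];
  NumericVector cprob = lik["cprob"];
  IntegerMatrix support = lik["support"];
  S.nfrag = frag_ptr.size() - 1;
  S.nbase = kind.size();
  S.npath = support.ncol();
  S.frag_ptr = INTEGER(frag_ptr);
  S.kind = INTEGER(kind);
  S.bg = INTEGER(bg);
  S.W = REAL(W);
  S.u = REAL(u);
  S.cprob = REAL(cprob);
  S.support = INTEGER(support);
  for (int i = 0; i < 4; ++i) S.pi[i] = pi[i];
  S.kappa = kappa;
  IntegerVector anc = treec["anc"], dec = treec["dec"];
  NumericVector len = treec["length"];
  S.br_anc.assign(anc.begin(), anc.end());
  S.br_dec.assign(dec.begin(), dec.end());
  S.br_len.assign(len.begin(), len.end());
  if (treec.containsElementNamed("neighbors")) {
    List nbl = treec["neighbors"];
    S.nbs.resize(nbl.size());
    for (int b = 0; b < nbl.size(); ++b) {
      IntegerVector v = nbl[b];
      S.nbs[b].assign(v.begin(), v.end());
    }
  }
  S.build_groups();
}

} // namespace

// [[Rcpp::export(name = ".run_mcmc_cpp")]]
List run_mcmc_cpp(List lik, List treec, NumericVector pi, double kappa,
                  int iterations, IntegerVector init_branch,
                  NumericVector init_beta, NumericVector init_theta,
                  double p_hop, double sigma_beta, double sigma_theta) {
  Sampler S;
  init_sampler(S, lik, treec, pi, kappa);

  const int k = init_branch.size();
  std::vector<int> branch(init_branch.begin(), init_branch.end()); // 0-based
  std::vector<double> beta(init_beta.begin(), init_beta.end());
  std::vector<double> theta(init_theta.begin(), init_theta.end());
  std::vector<double> ltheta(k);
  for (int i = 0; i < k; ++i) {
    ltheta[i] = theta[i] > 0 ? std::log(theta[i]) : R_NegInf;
  }
  std::vector<std::vector<double>> lv(k);
  for (int i = 0; i < k; ++i) S.logvec(branch[i], beta[i], lv[i]);
  double cur_ll = S.mixture_ll(ltheta, lv);

  NumericMatrix trace(iterations, 4 + 3 * k);
  std::vector<double> prop_lv;
  for (int it = 0; it < iterations; ++it) {
    const double u1 = unif_rand();
    bool accepted = false;
    double proposed_ll = cur_ll;
    int move = -1;
    if (u1 < p_hop) {
      move = 0;
      // branch hop: one source moves to an adjacent branch, beta fresh
      const int j = (int)std::floor(unif_rand() * k);
      const std::vector<int>& cur_nb = S.nbs[branch[j]];
      if (!cur_nb.empty()) {
        const int nb = cur_nb[(int)std::floor(unif_rand() * cur_nb.size())];
        const double nbeta = unif_rand();
        const double loghr = std::log((double)cur_nb.size()) -
                             std::log((double)S.nbs[nb].size());
        S.logvec(nb, nbeta, prop_lv);
        std::swap(lv[j], prop_lv);
        const double new_ll = S.mixture_ll(ltheta, lv);
        proposed_ll = new_ll;
        if (std::log(unif_rand()) < new_ll - cur_ll + loghr) {
          branch[j] = nb;
          beta[j] = nbeta;
          cur_ll = new_ll;
          accepted = true;
        } else {
          std::swap(lv[j], prop_lv);   // restore
        }
      }
    } else if (k > 1 && unif_rand() < 0.5) {
      move = 1;
      // logistic-normal random walk on theta (additive log-ratio space)
      std::vector<double> y(k - 1);
      for (int i = 0; i < k - 1; ++i) {
        y[i] = std::log(theta[i] / theta[k - 1]) + sigma_theta * norm_rand();
      }
      double mx = 0.0;
      for (double v : y) if (v > mx) mx = v;
      double denom = std::exp(0.0 - mx);
      for (double v : y) denom += std::exp(v - mx);
      std::vector<double> ntheta(k);
      for (int i = 0; i < k - 1; ++i) ntheta[i] = std::exp(y[i] - mx) / denom;
      ntheta[k - 1] = std::exp(0.0 - mx) / denom;
      double logjac = 0.0;
      bool ok = true;
      for (int i = 0; i < k; ++i) {
        if (ntheta[i] <= 0 || theta[i] <= 0) { ok = false; break; }
        logjac += std::log(ntheta[i]) - std::log(theta[i]);
      }
      if (ok) {
        std::vector<double> nltheta(k);
        for (int i = 0; i < k; ++i) nltheta[i] = std::log(ntheta[i]);
        const double new_ll = S.mixture_ll(nltheta, lv);
        proposed_ll = new_ll;
        if (std::log(unif_rand()) < new_ll - cur_ll + logjac) {
          theta = ntheta;
          ltheta = nltheta;
          cur_ll = new_ll;
          accepted = true;
        }
      }
    } else {
      move = 2;
      // reflected Gaussian random walk on one beta (symmetric)
      const int j = (int)std::floor(unif_rand() * k);
      double nb = beta[j] + sigma_beta * norm_rand();
      while (nb < 0.0 || nb > 1.0) {
        if (nb < 0.0) nb = -nb;
        if (nb > 1.0) nb = 2.0 - nb;
      }
      S.logvec(branch[j], nb, prop_lv);
      std::swap(lv[j], prop_lv);
      const double new_ll = S.mixture_ll(ltheta, lv);
      proposed_ll = new_ll;
      if (std::log(unif_rand()) < new_ll - cur_ll) {
        beta[j] = nb;
        cur_ll = new_ll;
        accepted = true;
      } else {
        std::swap(lv[j], prop_lv);
      }
    }
    trace(it, 0) = cur_ll;
    trace(it, 1) = proposed_ll;
    trace(it, 2) = accepted ? 1.0 : 0.0;
    trace(it, 3) = move;
    for (int i = 0; i < k; ++i) {
      trace(it, 4 + i) = branch[i] + 1;            // back to 1-based
      trace(it, 4 + k + i) = beta[i];
      trace(it, 4 + 2 * k + i) = theta[i];
    }
  }
  return List::create(_["trace"] = trace, _["final_ll"] = cur_ll,
                      _["grouped"] = S.grouped);
}

// [[Rcpp::export(name = ".frag_logliks_cpp")]]
NumericVector frag_logliks_cpp(List lik, List treec, NumericVector pi,
                               double kappa, int branch, double beta) {
  Sampler S;
  init_sampler(S, lik, treec, pi, kappa);
  std::vector<double> out;
  S.logvec(branch, beta, out);
  return NumericVector(out.begin(), out.end());
}
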