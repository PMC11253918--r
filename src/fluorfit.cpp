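#include <Rcpp.h>
#include <cmath>
#include <map>
#include <string>
#include <vector>

using namespace Rcpp;

namespace {

struct Fac {
  std::vector<int> i, j;   // 0-based
  std::vector<double> p;
};

Fac as_fac(const List& trip) {
  Fac f;
  IntegerVector i = trip["i"], j = trip["j"];
  NumericVector p = trip["p"];
  f.i.resize(i.size());
  f.j.resize(j.size());
  f.p.resize(p.size());
  for (int k = 0; k < i.size(); ++k) {
    f.i[k] = i[k] - 1;
    f.j[k] = j[k] - 1;
    f.p[k] = p[k];
  }
  return f;
}

inline double log_dnorm(double x, double m, double sd) {
  double z = (x - m) / sd;
  return -0.918938533204672742 - std::log(sd) - 0.5 * z * z;
}

}  // namespace

// Batch forward-backward over all reads, accumulating posterior flow
// totals per transition-matrix factor (summed over cycles and reads,
// optionally weighted per read). Reads are processed in blocks so the
// sparse factor applications run as contiguous vectorizable loops over
// the block dimension.
// [[Rcpp::export]]
List fb_batch_cpp(NumericMatrix intens, IntegerMatrix state_counts,
                  LogicalVector blocked, LogicalVector detached,
                  int intact, int detached_idx,
                  List f_dud, List f_init_block, List f_detach,
                  List f_cblock, List f_edman, List f_dyeloss,
                  int n_cycles, NumericVector mu, NumericVector sigma,
                  NumericVector bg_sigma, NumericVector bg_mu,
                  bool linear_var, NumericVector read_weights) {
  const int n_reads = intens.nrow();
  const int S = state_counts.nrow();
  const int C = state_counts.ncol();
  const int n_obs = n_cycles + 1;
  const int intact0 = intact - 1;
  const int B = 64;  // read block size

  Fac Fdud = as_fac(f_dud), Fib = as_fac(f_init_block), Fdet = as_fac(f_detach),
      Fcb = as_fac(f_cblock), Fed = as_fac(f_edman);
  std::vector<Fac> Fdl;
  for (int ch = 0; ch < C; ++ch) Fdl.push_back(as_fac(f_dyeloss[ch]));

  // schedule: op codes >= 0 are factors, -1 - t is emission of observation t
  std::vector<int> ops;
  ops.push_back(0);   // dud
  ops.push_back(1);   // init_block
  ops.push_back(-1);  // emit obs 0
  for (int t = 1; t <= n_cycles; ++t) {
    ops.push_back(2);  // detach
    for (int ch = 0; ch < C; ++ch) ops.push_back(3 + ch);  // dye loss
    ops.push_back(3 + C);  // cyclic block
    ops.push_back(4 + C);  // edman
    ops.push_back(-1 - t);
  }
  const int n_ops = (int)ops.size();

  std::vector<const Fac*> fac_for_code(5 + C);
  fac_for_code[0] = &Fdud;
  fac_for_code[1] = &Fib;
  fac_for_code[2] = &Fdet;
  for (int ch = 0; ch < C; ++ch) fac_for_code[3 + ch] = &Fdl[ch];
  fac_for_code[3 + C] = &Fcb;
  fac_for_code[4 + C] = &Fed;

  // per-channel count range and emission sds
  std::vector<int> maxK(C, 0);
  for (int s = 0; s < S; ++s)
    for (int ch = 0; ch < C; ++ch)
      if (state_counts(s, ch) > maxK[ch]) maxK[ch] = state_counts(s, ch);
  std::vector<std::vector<double>> sd_k(C);
  for (int ch = 0; ch < C; ++ch) {
    sd_k[ch].resize(maxK[ch] + 1);
    for (int k = 0; k <= maxK[ch]; ++k) {
      double v = bg_sigma[ch] * bg_sigma[ch];
      if (linear_var) v += k * sigma[ch] * sigma[ch];
      else if (k > 0) v += sigma[ch] * sigma[ch];
      sd_k[ch][k] = std::sqrt(v);
    }
  }
  std::vector<std::vector<int>> eff(S, std::vector<int>(C));
  for (int s = 0; s < S; ++s)
    for (int ch = 0; ch < C; ++ch)
      eff[s][ch] = detached[s] ? 0 : state_counts(s, ch);

  // flow accumulators, one dense matrix per factor type
  NumericMatrix A_dud(S, S), A_ib(S, S), A_det(S, S), A_cb(S, S), A_ed(S, S);
  std::vector<NumericMatrix> A_dl;
  for (int ch = 0; ch < C; ++ch) A_dl.push_back(NumericMatrix(S, S));
  std::vector<NumericMatrix*> acc_for_code(5 + C);
  acc_for_code[0] = &A_dud;
  acc_for_code[1] = &A_ib;
  acc_for_code[2] = &A_det;
  for (int ch = 0; ch < C; ++ch) acc_for_code[3 + ch] = &A_dl[ch];
  acc_for_code[3 + C] = &A_cb;
  acc_for_code[4 + C] = &A_ed;

  const bool weighted = read_weights.size() == n_reads;
  NumericVector loglik(n_reads);

  // block workspaces (layout: [state * B + read-in-block])
  std::vector<std::vector<double>> Aafter(n_ops, std::vector<double>(S * B));
  std::vector<std::vector<double>> W(n_obs, std::vector<double>(S * B));
  std::vector<std::vector<double>> M0(n_obs, std::vector<double>(B));
  std::vector<double> alpha(S * B), beta(S * B), tmp(S * B);
  std::vector<double> ssum(B), tot(B), inv(B), ll(B), wgt(B);
  size_t max_nnz = 0;
  for (int c = 0; c < 5 + C; ++c)
    max_nnz = std::max(max_nnz, fac_for_code[c]->p.size());
  std::vector<double> prod(max_nnz * B);
  int maxKmax = 0;
  for (int ch = 0; ch < C; ++ch) maxKmax = std::max(maxKmax, maxK[ch]);
  std::vector<double> tab(C * (maxKmax + 1));  // per (ch, k) log-densities

  for (int r0 = 0; r0 < n_reads; r0 += B) {
    const int bs = std::min(B, n_reads - r0);

    for (int b = 0; b < bs; ++b)
      wgt[b] = weighted ? read_weights[r0 + b] : 1.0;

    // emission weights for the block
    for (int t = 0; t < n_obs; ++t) {
      std::vector<double>& Wt = W[t];
      for (int b = 0; b < bs; ++b) {
        double m0 = R_NegInf;
        // log-density per (ch, count) for this read/observation
        for (int ch = 0; ch < C; ++ch) {
          double x = intens(r0 + b, t * C + ch);
          for (int k = 0; k <= maxK[ch]; ++k)
            tab[ch * (maxKmax + 1) + k] =
                log_dnorm(x, bg_mu[ch] + k * mu[ch], sd_k[ch][k]);
        }
        for (int s = 0; s < S; ++s) {
          double v = 0.0;
          for (int ch = 0; ch < C; ++ch)
            v += tab[ch * (maxKmax + 1) + eff[s][ch]];
          Wt[s * B + b] = v;
          if (v > m0) m0 = v;
        }
        M0[t][b] = m0;
        for (int s = 0; s < S; ++s)
          Wt[s * B + b] = std::exp(Wt[s * B + b] - m0);
      }
    }

    // forward
    std::fill(alpha.begin(), alpha.end(), 0.0);
    for (int b = 0; b < bs; ++b) alpha[intact0 * B + b] = 1.0;
    std::fill(ll.begin(), ll.end(), 0.0);
    for (int k = 0; k < n_ops; ++k) {
      const int code = ops[k];
      if (code >= 0) {
        const Fac& f = *fac_for_code[code];
        std::fill(tmp.begin(), tmp.begin() + S * B, 0.0);
        for (size_t z = 0; z < f.p.size(); ++z) {
          const double pz = f.p[z];
          const double* src = &alpha[f.i[z] * B];
          double* dst = &tmp[f.j[z] * B];
          for (int b = 0; b < bs; ++b) dst[b] += pz * src[b];
        }
        std::swap(alpha, tmp);
      } else {
        const int t = -1 - code;
        const std::vector<double>& Wt = W[t];
        std::fill(ssum.begin(), ssum.begin() + bs, 0.0);
        for (int s = 0; s < S; ++s) {
          double* as = &alpha[s * B];
          const double* ws = &Wt[s * B];
          for (int b = 0; b < bs; ++b) {
            as[b] *= ws[b];
            ssum[b] += as[b];
          }
        }
        for (int b = 0; b < bs; ++b) {
          if (!(ssum[b] > 0.0) || !std::isfinite(ssum[b]))
            stop("non-finite forward likelihood at read %d", r0 + b + 1);
          ll[b] += std::log(ssum[b]) + M0[t][b];
          inv[b] = 1.0 / ssum[b];
        }
        for (int s = 0; s < S; ++s) {
          double* as = &alpha[s * B];
          for (int b = 0; b < bs; ++b) as[b] *= inv[b];
        }
      }
      std::copy(alpha.begin(), alpha.begin() + S * B, Aafter[k].begin());
    }
    for (int b = 0; b < bs; ++b) loglik[r0 + b] = ll[b];

    // backward with per-sub-step normalized flow accumulation
    std::fill(beta.begin(), beta.begin() + S * B, 1.0);
    for (int k = n_ops - 1; k >= 0; --k) {
      const int code = ops[k];
      if (code < 0) {
        const int t = -1 - code;
        const std::vector<double>& Wt = W[t];
        std::fill(ssum.begin(), ssum.begin() + bs, 0.0);
        for (int s = 0; s < S; ++s) {
          double* bsv = &beta[s * B];
          const double* ws = &Wt[s * B];
          for (int b = 0; b < bs; ++b) {
            bsv[b] *= ws[b];
            if (bsv[b] > ssum[b]) ssum[b] = bsv[b];
          }
        }
        for (int b = 0; b < bs; ++b) {
          if (!(ssum[b] > 0.0)) stop("backward underflow at read %d", r0 + b + 1);
          inv[b] = 1.0 / ssum[b];
        }
        for (int s = 0; s < S; ++s) {
          double* bsv = &beta[s * B];
          for (int b = 0; b < bs; ++b) bsv[b] *= inv[b];
        }
      } else {
        const Fac& f = *fac_for_code[code];
        const double* apre;
        if (k > 0) {
          apre = Aafter[k - 1].data();
        } else {
          std::fill(tmp.begin(), tmp.begin() + S * B, 0.0);
          for (int b = 0; b < bs; ++b) tmp[intact0 * B + b] = 1.0;
          apre = tmp.data();
        }
        std::fill(tot.begin(), tot.begin() + bs, 0.0);
        for (size_t z = 0; z < f.p.size(); ++z) {
          const double pz = f.p[z];
          const double* ai = &apre[f.i[z] * B];
          const double* bj = &beta[f.j[z] * B];
          double* pr = &prod[z * B];
          for (int b = 0; b < bs; ++b) {
            pr[b] = pz * ai[b] * bj[b];
            tot[b] += pr[b];
          }
        }
        for (int b = 0; b < bs; ++b)
          inv[b] = (tot[b] > 0.0) ? wgt[b] / tot[b] : 0.0;
        NumericMatrix& A = *acc_for_code[code];
        for (size_t z = 0; z < f.p.size(); ++z) {
          const double* pr = &prod[z * B];
          double acc = 0.0;
          for (int b = 0; b < bs; ++b) acc += pr[b] * inv[b];
          A(f.i[z], f.j[z]) += acc;
        }
        // beta_pre[i] = sum_j P[i,j] beta_post[j]
        std::fill(tmp.begin(), tmp.begin() + S * B, 0.0);
        for (size_t z = 0; z < f.p.size(); ++z) {
          const double pz = f.p[z];
          const double* bj = &beta[f.j[z] * B];
          double* ti = &tmp[f.i[z] * B];
          for (int b = 0; b < bs; ++b) ti[b] += pz * bj[b];
        }
        std::swap(beta, tmp);
      }
    }
  }

  List dl(C);
  for (int ch = 0; ch < C; ++ch) dl[ch] = A_dl[ch];
  return List::create(
      _["loglik"] = loglik,
      _["flows"] = List::create(A_dud, A_ib, A_det, A_cb, A_ed),
      _["dyeloss"] = dl);
}

namespace {

// Core molecule simulation against a per-molecule uniform buffer with a
// fixed draw layout: per label a dud draw, one initial-block draw, then per
// cycle one detachment draw, per-label dye-loss draws, one cyclic-block
// draw and one Edman draw. Draw positions are fixed offsets regardless of
// outcomes, so common-random-number evaluations stay aligned across nearby
// parameter values; once the molecule is detached or carries no live
// fluorophore its remaining counts are zero and the cycle loop exits early.
// Event order within a cycle: detachment, dye loss, cyclic block, Edman.
inline bool simulate_one(const double* u, const IntegerVector& label_pos,
                         const IntegerVector& label_ch, int C, double e_fail,
                         const NumericVector& dye_loss, double p_det,
                         const NumericVector& dud, double b_init,
                         double c_block, int n_cycles, std::vector<bool>& alive,
                         std::vector<int>& counts) {
  const int nl = label_pos.size();
  long long z = 0;
  int n_alive = 0;
  std::fill(counts.begin(), counts.end(), 0);
  for (int l = 0; l < nl; ++l) {
    alive[l] = !(u[z++] < dud[label_ch[l]]);
    if (alive[l]) {
      ++n_alive;
      counts[label_ch[l]] += 1;  // observation 0 (pre-Edman, post-dud)
    }
  }
  bool blocked = u[z++] < b_init;
  bool observed = n_alive > 0;
  int n_cleaved = 0;

  for (int t = 1; t <= n_cycles && n_alive > 0; ++t) {
    // draw offsets within the cycle are fixed by the layout
    const double* uc = u + (long long)nl + 1 + (long long)(t - 1) * (nl + 3);
    if (uc[0] < p_det) break;  // detached: background-only from here on
    for (int l = 0; l < nl; ++l) {
      if (alive[l] && uc[1 + l] < dye_loss[label_ch[l]]) {
        alive[l] = false;
        --n_alive;
      }
    }
    if (!blocked && uc[1 + nl] < c_block) blocked = true;
    if (!blocked && uc[2 + nl] >= e_fail) {
      ++n_cleaved;
      for (int l = 0; l < nl; ++l)
        if (label_pos[l] == n_cleaved && alive[l]) {
          alive[l] = false;
          --n_alive;
        }
    }
    for (int l = 0; l < nl; ++l)
      if (alive[l]) counts[t * C + label_ch[l]] += 1;
  }
  return observed;
}

std::string track_key(const std::vector<int>& counts) {
  std::string key;
  key.reserve(2 * counts.size());
  for (size_t z = 0; z < counts.size(); ++z) {
    if (z) key.push_back(',');
    key += std::to_string(counts[z]);
  }
  return key;
}

// Histogram of integer tracks. Tracks are coded in a mixed radix (count
// range per channel); when the code space is small a dense table is used,
// otherwise an ordered map on the string key.
struct TrackHist {
  std::vector<long long> radix;
  long long space = 1;
  bool dense = false;
  std::vector<int> table;
  std::map<std::string, int> map;
  int n_obs, C;

  TrackHist(int n_obs_, int C_, const std::vector<int>& maxc)
      : n_obs(n_obs_), C(C_) {
    radix.resize(n_obs * C);
    for (int t = 0; t < n_obs; ++t)
      for (int ch = 0; ch < C; ++ch) radix[t * C + ch] = maxc[ch] + 1;
    for (size_t z = 0; z < radix.size(); ++z) {
      if (space > (4 << 20)) break;
      space *= radix[z];
    }
    dense = space <= (4 << 20);
    if (dense) table.assign(space, 0);
  }

  inline void add(const std::vector<int>& counts) {
    if (dense) {
      long long code = 0;
      for (size_t z = 0; z < counts.size(); ++z)
        code = code * radix[z] + counts[z];
      ++table[code];
    } else {
      ++map[track_key(counts)];
    }
  }

  List to_list(int n_observed, long long attempts) const {
    std::vector<std::pair<std::string, int>> out;
    if (dense) {
      std::vector<int> counts(n_obs * C);
      for (long long code = 0; code < space; ++code) {
        if (table[code] == 0) continue;
        long long c = code;
        for (int z = n_obs * C - 1; z >= 0; --z) {
          counts[z] = (int)(c % radix[z]);
          c /= radix[z];
        }
        out.emplace_back(track_key(counts), table[code]);
      }
    } else {
      out.assign(map.begin(), map.end());
    }
    IntegerVector cnt(out.size());
    CharacterVector keys(out.size());
    for (size_t z = 0; z < out.size(); ++z) {
      keys[z] = out[z].first;
      cnt[z] = out[z].second;
    }
    cnt.names() = keys;
    return List::create(_["counts"] = cnt, _["n_observed"] = n_observed,
                        _["attempts"] = attempts);
  }
};

std::vector<int> per_channel_max(const IntegerVector& label_ch, int C) {
  std::vector<int> maxc(C, 0);
  for (int l = 0; l < label_ch.size(); ++l) ++maxc[label_ch[l]];
  return maxc;
}

}  // namespace

// Monte Carlo dye-track simulator drawing from R's random number stream.
// fixed_attempts = true: simulate exactly n_target molecules and keep the
// observed ones. fixed_attempts = false: draw until n_target observed
// molecules exist (error if max_attempts is exhausted first).
// [[Rcpp::export]]
List sim_tracks_cpp(IntegerVector label_pos, IntegerVector label_ch,
                    int n_channels, double e_fail, NumericVector dye_loss,
                    double p_det, NumericVector dud, double b_init,
                    double c_block, int n_cycles, int n_target,
                    bool fixed_attempts, int max_attempts, bool histogram) {
  const int C = n_channels;
  const int nl = label_pos.size();
  const int n_obs = n_cycles + 1;
  const long long per = nl + 1 + (long long)n_cycles * (nl + 3);
  std::vector<bool> alive(nl);
  std::vector<int> counts(n_obs * C);
  std::vector<double> buf(per);
  std::vector<int> track_buf;
  TrackHist hist(n_obs, C, per_channel_max(label_ch, C));
  int n_observed = 0;
  long long attempts = 0;
  const long long cap = fixed_attempts ? (long long)n_target
                                       : (long long)max_attempts;
  while (attempts < cap) {
    ++attempts;
    // the full fixed layout is always drawn, so the stream position is a
    // function of the attempt number only
    for (long long z = 0; z < per; ++z) buf[z] = unif_rand();
    bool observed =
        simulate_one(buf.data(), label_pos, label_ch, C, e_fail, dye_loss,
                     p_det, dud, b_init, c_block, n_cycles, alive, counts);
    if (!observed) continue;
    ++n_observed;
    if (histogram) hist.add(counts);
    else track_buf.insert(track_buf.end(), counts.begin(), counts.end());
    if (!fixed_attempts && n_observed >= n_target) break;
  }
  if (!fixed_attempts && n_observed < n_target)
    stop("exceeded max_attempts while drawing observed molecules");

  if (histogram) return hist.to_list(n_observed, attempts);
  IntegerMatrix tracks(n_observed, n_obs * C);
  for (int r = 0; r < n_observed; ++r)
    for (int z = 0; z < n_obs * C; ++z)
      tracks(r, z) = track_buf[r * n_obs * C + z];
  return List::create(_["tracks"] = tracks, _["n_observed"] = n_observed,
                      _["attempts"] = attempts);
}

// Same generative model, but consuming a pre-drawn uniform pool; with a
// pool held fixed, the result is a deterministic function of the
// parameters, which the common-random-numbers RMSE objective exploits
// (the pool is drawn once per fit and shared by all evaluations).
// When a standard-normal pool `zpool` (one draw per molecule, observation
// and channel) is supplied, each observed molecule's track is passed
// through the emission channel and re-reduced by per-value density argmax
// — the same integer approximation applied to the real reads — so the
// simulated histogram suffers the identical count-misassignment noise as
// the observed one. An empty zpool gives noise-free (truth-level) tracks.
// Censoring is decided on the true counts (no functioning fluorophore at
// observation 0) in either mode.
// [[Rcpp::export]]
List sim_tracks_pool_cpp(NumericVector pool, NumericVector zpool,
                         IntegerVector label_pos, IntegerVector label_ch,
                         int n_channels, double e_fail,
                         NumericVector dye_loss, double p_det,
                         NumericVector dud, double b_init, double c_block,
                         int n_cycles, NumericVector mu, NumericVector sigma,
                         NumericVector bg_sigma, NumericVector bg_mu,
                         bool linear_var) {
  const int C = n_channels;
  const int nl = label_pos.size();
  const int n_obs = n_cycles + 1;
  const long long per = nl + 1 + (long long)n_cycles * (nl + 3);
  const long long n_mol = pool.size() / per;
  const bool noisy = zpool.size() > 0;
  if (noisy && zpool.size() < n_mol * n_obs * C)
    stop("zpool too small for the uniform pool");

  std::vector<int> maxc = per_channel_max(label_ch, C);
  // per-channel emission sd and log-sd per fluorophore count
  std::vector<std::vector<double>> sd_k(C), lsd_k(C);
  for (int ch = 0; ch < C; ++ch) {
    sd_k[ch].resize(maxc[ch] + 1);
    lsd_k[ch].resize(maxc[ch] + 1);
    for (int k = 0; k <= maxc[ch]; ++k) {
      double v = bg_sigma[ch] * bg_sigma[ch];
      if (linear_var) v += k * sigma[ch] * sigma[ch];
      else if (k > 0) v += sigma[ch] * sigma[ch];
      sd_k[ch][k] = std::sqrt(v);
      lsd_k[ch][k] = 0.5 * std::log(v);
    }
  }

  std::vector<bool> alive(nl);
  std::vector<int> counts(n_obs * C), red(n_obs * C);
  TrackHist hist(n_obs, C, maxc);
  int n_observed = 0;
  const double* u = pool.begin();
  const double* zp = zpool.begin();
  for (long long m = 0; m < n_mol; ++m) {
    bool observed =
        simulate_one(u + m * per, label_pos, label_ch, C, e_fail, dye_loss,
                     p_det, dud, b_init, c_block, n_cycles, alive, counts);
    if (!observed) continue;
    ++n_observed;
    if (!noisy) {
      hist.add(counts);
      continue;
    }
    const double* zm = zp + m * (long long)n_obs * C;
    for (int t = 0; t < n_obs; ++t) {
      for (int ch = 0; ch < C; ++ch) {
        const int k_true = counts[t * C + ch];
        const double x = bg_mu[ch] + k_true * mu[ch] +
                         sd_k[ch][k_true] * zm[t * C + ch];
        // argmax_k of the emission density; ties keep the smaller count
        int best = 0;
        double zb = (x - bg_mu[ch]) / sd_k[ch][0];
        double bd = -lsd_k[ch][0] - 0.5 * zb * zb;
        for (int k = 1; k <= maxc[ch]; ++k) {
          double zk = (x - bg_mu[ch] - k * mu[ch]) / sd_k[ch][k];
          double d = -lsd_k[ch][k] - 0.5 * zk * zk;
          if (d > bd) {
            bd = d;
            best = k;
          }
        }
        red[t * C + ch] = best;
      }
    }
    hist.add(red);
  }
  return hist.to_list(n_observed, n_mol);
}
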