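#include <Rcpp.h>
using namespace Rcpp;

// One-occurrence-per-sequence Gibbs sampling core.
//
// codes:  per sequence, integer base codes 1..4 (0 = masked)
// starts: per sequence, legal (fully unmasked) 1-based window starts
// Uses R's RNG throughout, so set.seed() in R makes the trajectory
// reproducible. Returns the best-scoring site configuration seen.

static inline void site_counts(const std::vector<const int *> &seqp,
                               const IntegerVector &site_start,
                               int ns, int width, double *counts) {
  std::fill(counts, counts + 4 * width, 0.0);
  for (int i = 0; i < ns; ++i) {
    const int *code = seqp[i];
    int s0 = site_start[i] - 1;
    for (int j = 0; j < width; ++j) {
      counts[j * 4 + (code[s0 + j] - 1)] += 1.0;
    }
  }
}

static inline double config_score(const std::vector<const int *> &seqp,
                                  const IntegerVector &site_start,
                                  int ns, int width, double beta,
                                  const double *bg, const double *lbg,
                                  std::vector<double> &cnt_buf) {
  site_counts(seqp, site_start, ns, width, cnt_buf.data());
  double score = 0.0;
  for (int i = 0; i < ns; ++i) {
    const int *code = seqp[i];
    int s0 = site_start[i] - 1;
    for (int j = 0; j < width; ++j) {
      int a = code[s0 + j] - 1;
      double f = (cnt_buf[j * 4 + a] + beta * bg[a]) / (ns + beta);
      score += std::log(f) - lbg[a];
    }
  }
  return score;
}

// [[Rcpp::export(name = ".gibbs_core")]]
List gibbs_core(List codes, List starts, int width, double beta,
                NumericVector background, int max_iter, int patience,
                int shift_every) {
  int ns = codes.size();
  std::vector<IntegerVector> seqs(ns);
  std::vector<IntegerVector> wins(ns);
  std::vector<const int *> seqp(ns);
  for (int i = 0; i < ns; ++i) {
    seqs[i] = as<IntegerVector>(codes[i]);
    wins[i] = as<IntegerVector>(starts[i]);
    seqp[i] = INTEGER(seqs[i]);
  }
  double bg[4], lbg[4];
  for (int a = 0; a < 4; ++a) {
    bg[a] = background[a];
    lbg[a] = std::log(bg[a]);
  }

  // initialization: uniform over legal windows
  IntegerVector pick(ns);      // index into wins[i] (0-based)
  IntegerVector site_start(ns); // 1-based sequence positions
  for (int i = 0; i < ns; ++i) {
    int k = (int)std::floor(unif_rand() * wins[i].size());
    if (k >= wins[i].size()) k = wins[i].size() - 1;
    pick[i] = k;
    site_start[i] = wins[i][k];
  }

  std::vector<double> counts(4 * width);
  std::vector<double> cnt_buf(4 * width);
  std::vector<double> lr(4 * width);
  std::vector<double> cw;
  std::vector<int> order(ns);
  site_counts(seqp, site_start, ns, width, counts.data());

  double best_score = R_NegInf;
  IntegerVector best_pick = clone(pick);
  int unchanged = 0, stalled = 0, sweeps = 0;
  bool converged = false;

  for (int it = 1; it <= max_iter; ++it) {
    sweeps = it;
    bool moved = false;

    // random visiting order (Fisher-Yates with R RNG)
    for (int i = 0; i < ns; ++i) order[i] = i;
    for (int i = ns - 1; i > 0; --i) {
      int j = (int)std::floor(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(order[i], order[j]);
    }

    for (int oi = 0; oi < ns; ++oi) {
      int i = order[oi];
      const int *code = seqp[i];
      int s0 = site_start[i] - 1;
      // hold sequence i out of the counts
      for (int j = 0; j < width; ++j)
        counts[j * 4 + (code[s0 + j] - 1)] -= 1.0;
      // predictive PWM log-odds
      for (int j = 0; j < width; ++j) {
        for (int a = 0; a < 4; ++a) {
          double f = (counts[j * 4 + a] + beta * bg[a]) / (ns - 1 + beta);
          lr[j * 4 + a] = std::log(f) - lbg[a];
        }
      }
      // window scores and inverse-CDF sampling
      int nw = wins[i].size();
      cw.resize(nw);
      double mx = R_NegInf;
      for (int k = 0; k < nw; ++k) {
        int w0 = wins[i][k] - 1;
        double sc = 0.0;
        for (int j = 0; j < width; ++j)
          sc += lr[j * 4 + (code[w0 + j] - 1)];
        cw[k] = sc;
        if (sc > mx) mx = sc;
      }
      double acc = 0.0;
      for (int k = 0; k < nw; ++k) {
        acc += std::exp(cw[k] - mx);
        cw[k] = acc;
      }
      double u = unif_rand() * acc;
      int new_k = (int)(std::lower_bound(cw.begin(), cw.end(), u) - cw.begin());
      if (new_k >= nw) new_k = nw - 1;
      if (new_k != pick[i]) {
        moved = true;
        pick[i] = new_k;
        site_start[i] = wins[i][new_k];
      }
      int s1 = site_start[i] - 1;
      for (int j = 0; j < width; ++j)
        counts[j * 4 + (code[s1 + j] - 1)] += 1.0;
    }

    // deterministic phase move: shift all sites together if it improves
    if (shift_every > 0 && it % shift_every == 0) {
      double cur = config_score(seqp, site_start, ns, width, beta, bg, lbg,
                                cnt_buf);
      int best_off = 0;
      double best_val = cur;
      for (int off = -3; off <= 3; ++off) {
        if (off == 0) continue;
        bool legal = true;
        IntegerVector cand(ns);
        for (int i = 0; i < ns; ++i) {
          int target = site_start[i] + off;
          // legal only if target is itself a legal window start
          IntegerVector &w = wins[i];
          const int *wp = INTEGER(w);
          const int *hit = std::lower_bound(wp, wp + w.size(), target);
          if (hit == wp + w.size() || *hit != target) {
            legal = false;
            break;
          }
          cand[i] = target;
        }
        if (!legal) continue;
        double val = config_score(seqp, cand, ns, width, beta, bg, lbg,
                                  cnt_buf);
        if (val > best_val + 1e-9) {
          best_val = val;
          best_off = off;
        }
      }
      if (best_off != 0) {
        moved = true;
        for (int i = 0; i < ns; ++i) {
          int target = site_start[i] + best_off;
          IntegerVector &w = wins[i];
          const int *wp = INTEGER(w);
          pick[i] = (int)(std::lower_bound(wp, wp + w.size(), target) - wp);
          site_start[i] = target;
        }
        site_counts(seqp, site_start, ns, width, counts.data());
      }
    }

    double sweep_score = config_score(seqp, site_start, ns, width, beta, bg,
                                      lbg, cnt_buf);
    if (sweep_score > best_score + 1e-9) {
      best_score = sweep_score;
      best_pick = clone(pick);
      stalled = 0;
    } else {
      ++stalled;
    }
    unchanged = moved ? 0 : unchanged + 1;
    if (unchanged >= patience || stalled >= patience) {
      converged = true;
      break;
    }
  }

  return List::create(
    _["pick"] = best_pick, _["best_score"] = best_score,
    _["sweeps"] = sweeps, _["converged"] = converged
  );
}
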