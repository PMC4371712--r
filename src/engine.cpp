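#include <Rcpp.h>
#include <vector>
#include <utility>
using namespace Rcpp;

// Binary threshold with the boundary convention theta(0) = 1, used everywhere.
static inline int theta(double v) { return v >= 0.0 ? 1 : 0; }

// Reward for the generation task: tail holds the most recent output symbols
// (1-based indices, at most n of them). The two target words are 1..n and
// n..1. The reward is L/n for the longest tail suffix that is a prefix of
// either word; a doubled word-initial symbol ("11" or "nn") is punished.
static double generation_reward(const std::vector<int> &tail, int n,
                                double punishment) {
  int len = (int)tail.size();
  if (len >= 2 && tail[len - 1] == tail[len - 2] &&
      (tail[len - 1] == 1 || tail[len - 1] == n))
    return -punishment;
  int best = 0;
  int maxp = len < n ? len : n;
  for (int p = 1; p <= maxp; ++p) {
    bool asc = true, desc = true;
    for (int i = 0; i < p; ++i) {
      int s = tail[len - p + i];
      if (s != i + 1) asc = false;
      if (s != n - i) desc = false;
      if (!asc && !desc) break;
    }
    if (asc || desc) best = p;
  }
  return (double)best / (double)n;
}

// Core simulation loop. One call advances the network by length(inputs)
// steps; weights, thresholds and dynamic state are cloned on entry so the
// caller's network is never mutated. Per step, the order of events is:
// recurrent update (x, y) -> readout update (o, with optional bit-flip
// noise) -> reward and modulation -> STDP -> synaptic normalization ->
// intrinsic plasticity. All randomness (noise, random-baseline scattering)
// draws from R's RNG so set.seed() controls the trajectory.
// [[Rcpp::export]]
List cpp_sim(List net, List state, List cfg, IntegerVector inputs,
             IntegerVector targets, LogicalVector excluded,
             NumericMatrix input_map) {
  NumericMatrix W_EE = clone(as<NumericMatrix>(net["W_EE"]));
  LogicalMatrix mask = as<LogicalMatrix>(net["mask"]);
  NumericMatrix W_EI = as<NumericMatrix>(net["W_EI"]);
  NumericMatrix W_IE = as<NumericMatrix>(net["W_IE"]);
  NumericMatrix W_OE = clone(as<NumericMatrix>(net["W_OE"]));
  NumericVector T_E = clone(as<NumericVector>(net["T_E"]));
  NumericVector T_I = as<NumericVector>(net["T_I"]);
  NumericVector T_O = clone(as<NumericVector>(net["T_O"]));
  IntegerVector x0 = as<IntegerVector>(net["x"]);
  IntegerVector y0 = as<IntegerVector>(net["y"]);
  IntegerVector o0 = as<IntegerVector>(net["o"]);
  bool wta = as<bool>(net["wta"]);

  const int NE = W_EE.nrow();
  const int NI = T_I.size();
  const int NO = T_O.size();

  double *wEE = W_EE.begin();
  double *wEI = W_EI.begin();
  double *wIE = W_IE.begin();
  double *wOE = W_OE.begin();
  double *imap = input_map.begin();

  const bool plastic_rec = as<bool>(cfg["plastic_rec"]);
  const bool plastic_out = as<bool>(cfg["plastic_out"]);
  const bool update_output = as<bool>(cfg["update_output"]);
  const bool ip_output = as<bool>(cfg["ip_output"]);
  const bool sn_output = as<bool>(cfg["sn_output"]);
  const bool modulate_recurrent = as<bool>(cfg["modulate_recurrent"]);
  const bool is_generation = as<bool>(cfg["is_generation"]);
  const bool random_baseline = as<bool>(cfg["random_baseline"]);
  const bool record_x = as<bool>(cfg["record_x"]);
  const bool record_thresholds = as<bool>(cfg["record_thresholds"]);
  const double eta_stdp = as<double>(cfg["eta_stdp"]);
  const double eta_ip = as<double>(cfg["eta_ip"]);
  const double mu_ip_rec = as<double>(cfg["mu_ip_rec"]);
  const double eta_ip_out = as<double>(cfg["eta_ip_out"]);
  NumericVector mu_ip_out = as<NumericVector>(cfg["mu_ip_out"]);
  const int strategy = as<int>(cfg["strategy"]); // 0 = M0, 1 = Mk
  const int kwin = as<int>(cfg["k"]);
  const double wrong_reward = as<double>(cfg["wrong_reward"]);
  const double gen_punishment = as<double>(cfg["gen_punishment"]);
  const double noise_prob = as<double>(cfg["noise_prob"]);
  // plain (unmodulated) plasticity: m_o fixed at 1, rewards ignored
  const bool unmodulated = as<bool>(cfg["unmodulated"]);

  std::vector<double> hist = as<std::vector<double>>(state["history"]);
  std::vector<int> tail = as<std::vector<int>>(state["tail"]);
  int last_out = as<int>(state["last_out"]);

  const int L = inputs.size();
  IntegerVector pred(L);
  NumericVector rewards(L, NA_REAL);
  NumericMatrix Xrec, TOrec;
  if (record_x) Xrec = NumericMatrix(L, NE);
  if (record_thresholds) TOrec = NumericMatrix(L, NO);

  const bool learning = plastic_rec || plastic_out;

  std::vector<int> x(x0.begin(), x0.end());
  std::vector<int> y(y0.begin(), y0.end());
  std::vector<int> o(o0.begin(), o0.end());
  std::vector<int> xn(NE), yn(NI), on(NO);
  std::vector<double> dx(NE), dy(NI), dout(NO);
  std::vector<int> act_x, act_xn, act_y;
  act_x.reserve(NE);
  act_xn.reserve(NE);
  act_y.reserve(NI);
  std::vector<double> rsum(NE);

  // eligible recurrent positions (fixed support of W_EE), as column-major
  // flat indices alongside (row, col) pairs
  std::vector<std::pair<int, int>> maskpos;
  std::vector<int> rec_idx, out_idx;
  if (plastic_rec) {
    for (int j = 0; j < NE; ++j)
      for (int i = 0; i < NE; ++i)
        if (mask(i, j)) maskpos.push_back(std::make_pair(i, j));
    if (random_baseline) {
      rec_idx.resize(maskpos.size());
      for (size_t i = 0; i < rec_idx.size(); ++i) rec_idx[i] = (int)i;
    }
  }
  if (plastic_out && random_baseline) {
    out_idx.resize((size_t)NO * NE);
    for (size_t i = 0; i < out_idx.size(); ++i) out_idx[i] = (int)i;
  }
  std::vector<double> scatter_val;

  for (int t = 0; t < L; ++t) {
    int sym = is_generation ? last_out : inputs[t];

    act_x.clear();
    for (int j = 0; j < NE; ++j)
      if (x[j]) act_x.push_back(j);
    act_y.clear();
    for (int k = 0; k < NI; ++k)
      if (y[k]) act_y.push_back(k);

    // Eqs. 1-2: recurrent layer update from the previous state
    for (int i = 0; i < NE; ++i) dx[i] = -T_E[i];
    for (size_t a = 0; a < act_x.size(); ++a) {
      const double *col = wEE + (size_t)act_x[a] * NE;
      for (int i = 0; i < NE; ++i) dx[i] += col[i];
    }
    for (size_t a = 0; a < act_y.size(); ++a) {
      const double *col = wEI + (size_t)act_y[a] * NE;
      for (int i = 0; i < NE; ++i) dx[i] -= col[i];
    }
    if (sym != NA_INTEGER && sym > 0) {
      const double *col = imap + (size_t)(sym - 1) * NE;
      for (int i = 0; i < NE; ++i) dx[i] += col[i];
    }
    for (int i = 0; i < NE; ++i) xn[i] = theta(dx[i]);

    for (int i = 0; i < NI; ++i) dy[i] = -T_I[i];
    for (size_t a = 0; a < act_x.size(); ++a) {
      const double *col = wIE + (size_t)act_x[a] * NI;
      for (int i = 0; i < NI; ++i) dy[i] += col[i];
    }
    for (int i = 0; i < NI; ++i) yn[i] = theta(dy[i]);

    act_xn.clear();
    for (int j = 0; j < NE; ++j)
      if (xn[j]) act_xn.push_back(j);

    // Eq. 3: readout from the fresh excitatory state
    int winner = -1;
    if (update_output) {
      for (int i = 0; i < NO; ++i) dout[i] = -T_O[i];
      for (size_t a = 0; a < act_xn.size(); ++a) {
        const double *col = wOE + (size_t)act_xn[a] * NO;
        for (int i = 0; i < NO; ++i) dout[i] += col[i];
      }
      if (wta) {
        double bestd = R_NegInf;
        for (int i = 0; i < NO; ++i)
          if (dout[i] > bestd) { bestd = dout[i]; winner = i; } // ties: lowest index
        if (noise_prob > 0.0 && unif_rand() < noise_prob && NO > 1) {
          int r = (int)(unif_rand() * (NO - 1));
          if (r >= NO - 1) r = NO - 2;
          winner = (r >= winner) ? r + 1 : r; // any neuron but the winner
        }
        for (int i = 0; i < NO; ++i) on[i] = (i == winner) ? 1 : 0;
        pred[t] = winner + 1;
      } else {
        on[0] = theta(dout[0]);
        if (noise_prob > 0.0 && unif_rand() < noise_prob) on[0] = 1 - on[0];
        pred[t] = on[0];
      }
    } else {
      pred[t] = NA_INTEGER;
    }

    // reward and modulation factor
    double m_o = 0.0;
    if (learning && update_output && unmodulated) {
      m_o = 1.0;
      if (is_generation) {
        tail.push_back(winner + 1);
        if ((int)tail.size() > NO) tail.erase(tail.begin());
      }
    } else if (learning && update_output) {
      bool skip = false;
      double r = 0.0;
      if (is_generation) {
        tail.push_back(winner + 1);
        if ((int)tail.size() > NO) tail.erase(tail.begin());
        r = generation_reward(tail, NO, gen_punishment);
      } else if (excluded[t]) {
        skip = true; // unpredictable position: no learning signal
      } else if (!wta && on[0] == 0) {
        // a silent Heaviside output emits nothing to reward or punish;
        // learning happens only when the output neuron spikes
        skip = true;
      } else {
        r = (pred[t] == targets[t]) ? 1.0 : wrong_reward;
      }
      if (!skip) {
        if (strategy == 0) {
          m_o = r;
        } else {
          double rbar = 0.0;
          if (!hist.empty()) {
            for (size_t i = 0; i < hist.size(); ++i) rbar += hist[i];
            rbar /= (double)hist.size();
          }
          m_o = r - rbar;
        }
        hist.push_back(r);
        if ((int)hist.size() > kwin) hist.erase(hist.begin());
        rewards[t] = r;
      }
    }
    double m_r = plastic_rec ? (modulate_recurrent ? m_o : 1.0) : 0.0;

    // Eq. 5: STDP on the eligible recurrent weights
    // The random ("lucky guessing") control scatters only reward-modulated
    // updates; unmodulated recurrent STDP (m_r = 1) is left intact.
    bool rec_changed = false;
    if (plastic_rec && m_r != 0.0) {
      rec_changed = true;
      if (!random_baseline || !modulate_recurrent) {
        for (size_t p = 0; p < maskpos.size(); ++p) {
          const int i = maskpos[p].first, j = maskpos[p].second;
          const int a = x[j] * xn[i] - xn[j] * x[i];
          if (a != 0) {
            double *w = wEE + (size_t)j * NE + i;
            *w += m_r * eta_stdp * (double)a;
            if (*w < 0.0) *w = 0.0;
          }
        }
      } else {
        scatter_val.clear();
        for (size_t p = 0; p < maskpos.size(); ++p) {
          const int i = maskpos[p].first, j = maskpos[p].second;
          const int a = x[j] * xn[i] - xn[j] * x[i];
          if (a != 0) scatter_val.push_back(m_r * eta_stdp * (double)a);
        }
        const int d = (int)scatter_val.size(), M = (int)rec_idx.size();
        for (int i = 0; i < d; ++i) { // partial Fisher-Yates
          int j = i + (int)(unif_rand() * (M - i));
          if (j >= M) j = M - 1;
          std::swap(rec_idx[i], rec_idx[j]);
          const std::pair<int, int> &pos = maskpos[rec_idx[i]];
          double *w = wEE + (size_t)pos.second * NE + pos.first;
          *w += scatter_val[i];
          if (*w < 0.0) *w = 0.0;
        }
      }
    }

    // Eq. 6: STDP on the readout weights (purely pre->post, gated by o)
    bool out_changed = false;
    if (plastic_out && m_o != 0.0) {
      out_changed = true;
      if (!random_baseline) {
        const double v = m_o * eta_stdp;
        for (int i = 0; i < NO; ++i)
          if (on[i])
            for (size_t a = 0; a < act_xn.size(); ++a) {
              double *w = wOE + (size_t)act_xn[a] * NO + i;
              *w += v;
              if (*w < 0.0) *w = 0.0;
            }
      } else {
        int no_act = 0;
        for (int i = 0; i < NO; ++i) no_act += on[i];
        int d = (int)act_xn.size() * no_act;
        const int M = (int)out_idx.size();
        if (d > M) d = M;
        const double v = m_o * eta_stdp;
        for (int i = 0; i < d; ++i) {
          int j = i + (int)(unif_rand() * (M - i));
          if (j >= M) j = M - 1;
          std::swap(out_idx[i], out_idx[j]);
          const int oi = out_idx[i] % NO, oj = out_idx[i] / NO;
          double *w = wOE + (size_t)oj * NO + oi;
          *w += v;
          if (*w < 0.0) *w = 0.0;
        }
      }
    }

    // Eq. 7: synaptic normalization restores unit row sums (a no-op when no
    // weight changed this step, so it is skipped then)
    if (rec_changed) {
      std::fill(rsum.begin(), rsum.end(), 0.0);
      for (size_t p = 0; p < maskpos.size(); ++p)
        rsum[maskpos[p].first] += wEE[(size_t)maskpos[p].second * NE + maskpos[p].first];
      for (size_t p = 0; p < maskpos.size(); ++p) {
        const double s = rsum[maskpos[p].first];
        if (s > 0.0) wEE[(size_t)maskpos[p].second * NE + maskpos[p].first] /= s;
      }
    }
    if (out_changed && sn_output) {
      for (int i = 0; i < NO; ++i) dout[i] = 0.0; // reuse as row sums
      for (int j = 0; j < NE; ++j) {
        const double *col = wOE + (size_t)j * NO;
        for (int i = 0; i < NO; ++i) dout[i] += col[i];
      }
      for (int j = 0; j < NE; ++j) {
        double *col = wOE + (size_t)j * NO;
        for (int i = 0; i < NO; ++i)
          if (dout[i] > 0.0) col[i] /= dout[i];
      }
    }

    // Eq. 4: intrinsic plasticity on the thresholds
    if (plastic_rec)
      for (int i = 0; i < NE; ++i)
        T_E[i] += eta_ip * ((double)xn[i] - mu_ip_rec);
    if (plastic_out && ip_output && update_output)
      for (int i = 0; i < NO; ++i)
        T_O[i] += eta_ip_out * ((double)on[i] - mu_ip_out[i]);

    x = xn;
    y = yn;
    if (update_output) {
      o = on;
      if (wta) last_out = winner + 1;
    }
    if (record_x)
      for (int j = 0; j < NE; ++j) Xrec(t, j) = (double)x[j];
    if (record_thresholds)
      for (int i = 0; i < NO; ++i) TOrec(t, i) = T_O[i];
  }

  List net_out = clone(net);
  net_out["W_EE"] = W_EE;
  net_out["W_OE"] = W_OE;
  net_out["T_E"] = T_E;
  net_out["T_O"] = T_O;
  net_out["x"] = IntegerVector(x.begin(), x.end());
  net_out["y"] = IntegerVector(y.begin(), y.end());
  net_out["o"] = IntegerVector(o.begin(), o.end());

  List state_out = List::create(
      _["history"] = NumericVector(hist.begin(), hist.end()),
      _["tail"] = IntegerVector(tail.begin(), tail.end()),
      _["last_out"] = last_out);

  List res = List::create(_["net"] = net_out, _["state"] = state_out,
                          _["pred"] = pred, _["rewards"] = rewards);
  if (record_x) res["x_history"] = Xrec;
  if (record_thresholds) res["threshold_history"] = TOrec;
  return res;
}
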