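#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Shannon entropy (nats) of a 16-cell dinucleotide count vector
static double dinuc_entropy(const std::vector<int>& dc, double n) {
  double h = 0.0;
  for (int i = 0; i < 16; ++i) {
    if (dc[i] > 0) {
      double p = dc[i] / n;
      h -= p * std::log(p);
    }
  }
  return h;
}

// Metropolis simulated annealing over single-base substitutions, maximizing
// w_freq * mean(log freq) + w_enr * mean(enr) + w_ent * dinucleotide entropy.
// seq0: bases coded 0..3; locked: positions protected from mutation;
// logfreq/enr: 4^wl x n_bins tables; binmap: 0-based bin per k-mer start
// (already offset into the model window). Geometric cooling from t_init to
// t_final over n_steps. Uses R's RNG, so results are reproducible under
// set.seed(). Returns the best sequence visited and a score trace.
// [[Rcpp::export]]
List anneal_design_cpp(IntegerVector seq0, LogicalVector locked,
                       NumericMatrix logfreq, NumericMatrix enr,
                       IntegerVector binmap, int wl, NumericVector weights,
                       int n_steps, double t_init, double t_final,
                       int moves_per_step, int trace_every) {
  const int L = seq0.size();
  const int n_kpos = L - wl + 1;
  if (binmap.size() != n_kpos) stop("binmap length must be L - wl + 1");
  if (n_kpos < 1) stop("sequence shorter than word length");

  std::vector<int> seq(seq0.begin(), seq0.end());
  std::vector<int> pow4(wl);
  pow4[wl - 1] = 1;
  for (int j = wl - 2; j >= 0; --j) pow4[j] = pow4[j + 1] * 4;

  std::vector<int> unlocked;
  for (int i = 0; i < L; ++i) if (!locked[i]) unlocked.push_back(i);
  if (unlocked.empty()) stop("all positions are locked");

  // k-mer codes and running sums
  std::vector<int> kc(n_kpos);
  double sum_lf = 0.0, sum_enr = 0.0;
  for (int p = 0; p < n_kpos; ++p) {
    int code = 0;
    for (int j = 0; j < wl; ++j) code = code * 4 + seq[p + j];
    kc[p] = code;
    sum_lf += logfreq(code, binmap[p]);
    sum_enr += enr(code, binmap[p]);
  }
  std::vector<int> dc(16, 0);
  for (int i = 0; i + 1 < L; ++i) dc[seq[i] * 4 + seq[i + 1]]++;
  const double n_dinuc = L - 1;

  const double wf = weights[0], we = weights[1], wh = weights[2];
  double cur = wf * sum_lf / n_kpos + we * sum_enr / n_kpos +
               wh * dinuc_entropy(dc, n_dinuc);
  double best = cur;
  std::vector<int> best_seq(seq);

  const double cool = (n_steps > 1)
      ? std::pow(t_final / t_init, 1.0 / (n_steps - 1)) : 1.0;
  int n_trace = n_steps / trace_every + 2;
  NumericMatrix trace(n_trace, 3);
  int tr = 0;

  double T = t_init;
  for (int step = 0; step < n_steps; ++step) {
    for (int mv = 0; mv < moves_per_step; ++mv) {
      int pos = unlocked[(int)(unif_rand() * unlocked.size())];
      int oldb = seq[pos];
      int newb = (oldb + 1 + (int)(unif_rand() * 3.0)) % 4;

      double d_lf = 0.0, d_enr = 0.0;
      int p_lo = std::max(0, pos - wl + 1);
      int p_hi = std::min(pos, n_kpos - 1);
      for (int p = p_lo; p <= p_hi; ++p) {
        int nc = kc[p] + (newb - oldb) * pow4[pos - p];
        d_lf += logfreq(nc, binmap[p]) - logfreq(kc[p], binmap[p]);
        d_enr += enr(nc, binmap[p]) - enr(kc[p], binmap[p]);
      }
      double d_ent = 0.0;
      if (wh != 0.0) {
        double h_old = dinuc_entropy(dc, n_dinuc);
        if (pos > 0) { dc[seq[pos - 1] * 4 + oldb]--; dc[seq[pos - 1] * 4 + newb]++; }
        if (pos + 1 < L) { dc[oldb * 4 + seq[pos + 1]]--; dc[newb * 4 + seq[pos + 1]]++; }
        d_ent = dinuc_entropy(dc, n_dinuc) - h_old;
        // provisional; roll back below if rejected
        if (pos > 0) { dc[seq[pos - 1] * 4 + oldb]++; dc[seq[pos - 1] * 4 + newb]--; }
        if (pos + 1 < L) { dc[oldb * 4 + seq[pos + 1]]++; dc[newb * 4 + seq[pos + 1]]--; }
      }
      double delta = wf * d_lf / n_kpos + we * d_enr / n_kpos + wh * d_ent;

      bool accept = delta > 0 || unif_rand() < std::exp(delta / T);
      if (accept) {
        if (pos > 0) { dc[seq[pos - 1] * 4 + oldb]--; dc[seq[pos - 1] * 4 + newb]++; }
        if (pos + 1 < L) { dc[oldb * 4 + seq[pos + 1]]--; dc[newb * 4 + seq[pos + 1]]++; }
        for (int p = p_lo; p <= p_hi; ++p) kc[p] += (newb - oldb) * pow4[pos - p];
        seq[pos] = newb;
        sum_lf += d_lf;
        sum_enr += d_enr;
        cur += delta;
        if (cur > best) {
          best = cur;
          best_seq = seq;
        }
      }
    }
    if (step % trace_every == 0 && tr < n_trace) {
      trace(tr, 0) = step + 1;
      trace(tr, 1) = cur;
      trace(tr, 2) = best;
      ++tr;
    }
    T *= cool;
  }
  if (tr < n_trace) {
    trace(tr, 0) = n_steps;
    trace(tr, 1) = cur;
    trace(tr, 2) = best;
    ++tr;
  }

  return List::create(
    _["best_seq"] = IntegerVector(best_seq.begin(), best_seq.end()),
    _["best_total"] = best,
    _["current_total"] = cur,
    _["trace"] = trace(Range(0, tr - 1), _));
}
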