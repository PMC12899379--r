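#include <Rcpp.h>
#include <algorithm>
#include <limits>
#include <vector>
using namespace Rcpp;

// Band partitions are cut vectors c_1 < ... < c_{L-1} on {2..M}, with
// implicit c_0 = 1 and c_L = M + 1; band l covers Fourier indices
// [c_{l-1}, c_l). CS is the K x (M+1) matrix of row cumulative sums of the
// power matrix with a leading zero column, so the sum of power over band
// [a, b) for series k is CS(k, b-1) - CS(k, a-1) in 0-based columns.

static inline int runif_int(int n) {
  // uniform on {0, ..., n-1} using R's RNG
  int v;
  do {
    v = (int)(unif_rand() * n);
  } while (v >= n);
  return v;
}

// Loss via the within-cell identity:
// sum_(k in j, w in W_jl) (g - ybar)^2 = sum g^2 - n_cell * ybar^2,
// accumulated over all cells and divided by T. sum g^2 is constant across
// solutions (total_ss).
static double loss_impl(const NumericMatrix& CS, double total_ss, double Tlen,
                        const int* labels, const int* cuts, int K, int J,
                        int L) {
  const int M = CS.ncol() - 1;
  std::vector<double> band_sum((size_t)J * L, 0.0);
  std::vector<int> group_size(J, 0);
  for (int k = 0; k < K; ++k) {
    int j = labels[k] - 1;
    ++group_size[j];
    const int* cj = cuts + (size_t)j * (L - 1);
    int prev = 1;
    for (int l = 0; l < L; ++l) {
      int next = (l == L - 1) ? (M + 1) : cj[l];
      band_sum[(size_t)j * L + l] += CS(k, next - 1) - CS(k, prev - 1);
      prev = next;
    }
  }
  double explained = 0.0;
  for (int j = 0; j < J; ++j) {
    const int* cj = cuts + (size_t)j * (L - 1);
    int prev = 1;
    for (int l = 0; l < L; ++l) {
      int next = (l == L - 1) ? (M + 1) : cj[l];
      double n_cell = (double)group_size[j] * (next - prev);
      double s = band_sum[(size_t)j * L + l];
      if (n_cell > 0) explained += s * s / n_cell;
      prev = next;
    }
  }
  return (total_ss - explained) / Tlen;
}

// [[Rcpp::export]]
double cpp_solution_loss(NumericMatrix CS, double total_ss, double Tlen,
                         IntegerVector labels, IntegerVector cuts, int J,
                         int L) {
  return loss_impl(CS, total_ss, Tlen, labels.begin(),
                   L > 1 ? cuts.begin() : (int*)nullptr, labels.size(), J, L);
}

// Sample a uniformly ordered set of L-1 valid cuts respecting w_min, via
// the transform u_l = c_l - 1 - l * w_min (u nondecreasing in {0..M-L*w_min}).
static void random_cuts(int* out, int M, int L, int w_min) {
  if (L <= 1) return;
  int free_span = M - L * w_min;
  std::vector<int> u(L - 1);
  for (int l = 0; l < L - 1; ++l) u[l] = runif_int(free_span + 1);
  std::sort(u.begin(), u.end());
  for (int l = 0; l < L - 1; ++l) out[l] = u[l] + 1 + (l + 1) * w_min;
}

// [[Rcpp::export]]
IntegerVector cpp_random_cuts(int M, int L, int w_min) {
  IntegerVector out(std::max(L - 1, 0));
  random_cuts(out.begin(), M, L, w_min);
  return out;
}

// Repair labels so all J groups are nonempty: move a random member of the
// (a) largest group into each empty one.
static void repair_labels(int* labels, int K, int J) {
  std::vector<int> count(J, 0);
  for (int k = 0; k < K; ++k) ++count[labels[k] - 1];
  for (int j = 0; j < J; ++j) {
    while (count[j] == 0) {
      int big = (int)(std::max_element(count.begin(), count.end()) -
                      count.begin());
      // pick a uniformly random member of the largest group
      int pick = runif_int(count[big]);
      for (int k = 0; k < K; ++k) {
        if (labels[k] - 1 == big) {
          if (pick == 0) {
            labels[k] = j + 1;
            --count[big];
            ++count[j];
            break;
          }
          --pick;
        }
      }
    }
  }
}

// Jitter-and-repair for one group's cut vector. Returns false if the greedy
// repair could not restore feasibility (caller resamples uniformly).
static bool repair_cuts(int* c, int M, int L, int w_min) {
  int n = L - 1;
  std::sort(c, c + n);
  int prev = 1;
  for (int l = 0; l < n; ++l) {
    if (c[l] < prev + w_min) c[l] = prev + w_min;
    prev = c[l];
  }
  if (c[n - 1] > M + 1 - w_min) {
    int nxt = M + 1;
    for (int l = n - 1; l >= 0; --l) {
      if (c[l] > nxt - w_min) c[l] = nxt - w_min;
      nxt = c[l];
    }
    if (c[0] < 1 + w_min) return false;
  }
  return true;
}

// Mutation: each label resampled over {1..J} w.p. pm (then nonempty-group
// repair). Each cut is modified w.p. pm: half the time by a local nonzero
// uniform jitter in [-jit, jit] (fine positioning), half the time by a
// uniform resample over {2..M} (mode hopping across a multimodal cut
// landscape); cut sets are then sorted/clamped with w_min enforced, and
// irreparable ones fully resampled.
static void mutate_impl(int* labels, int* cuts, int K, int J, int L, int M,
                        double pm, int jit, int w_min) {
  for (int k = 0; k < K; ++k) {
    if (unif_rand() < pm) labels[k] = 1 + runif_int(J);
  }
  repair_labels(labels, K, J);
  if (L > 1) {
    for (int j = 0; j < J; ++j) {
      int* cj = cuts + (size_t)j * (L - 1);
      bool touched = false;
      for (int l = 0; l < L - 1; ++l) {
        if (unif_rand() < pm) {
          if (unif_rand() < 0.5) {
            int off = 1 + runif_int(jit);
            if (unif_rand() < 0.5) off = -off;
            cj[l] += off;
          } else {
            cj[l] = 2 + runif_int(M - 1);
          }
          touched = true;
        }
      }
      if (touched && !repair_cuts(cj, M, L, w_min)) {
        random_cuts(cj, M, L, w_min);
      }
    }
  }
}

// [[Rcpp::export]]
List cpp_mutate(IntegerVector labels, IntegerVector cuts, int J, int L, int M,
                double pm, int jit, int w_min) {
  IntegerVector lab = clone(labels);
  IntegerVector cc = clone(cuts);
  mutate_impl(lab.begin(), L > 1 ? cc.begin() : (int*)nullptr, lab.size(), J,
              L, M, pm, jit, w_min);
  return List::create(_["labels"] = lab, _["cuts"] = cc);
}

// Evolve one island for n_gen generations of (mu + lambda) truncation with
// an elitist step: each parent yields n_off mutated offspring; parents and
// offspring are ranked by loss and the best pop_size survive; the previous
// generation's elite then replaces the current worst; the elite is updated.
// Exact optimal L-band segmentation for one group's summed spectra, by
// segmented least squares DP with a minimum band width. s1/s2 are the
// group-summed cumulative sums of power and squared power (length M+1,
// leading 0); cell cost of band [a, b) is q - s^2 / (Kj * (b - a)).
static double dp_segment(const std::vector<double>& s1,
                         const std::vector<double>& s2, int Kj, int M, int L,
                         int w_min, int* cuts_out) {
  auto cost = [&](int a, int b) {
    double w = b - a;
    double s = s1[b - 1] - s1[a - 1];
    double q = s2[b - 1] - s2[a - 1];
    return q - s * s / (Kj * w);
  };
  const double INF = std::numeric_limits<double>::infinity();
  // D[l][b] = min cost of covering [1, b) with l bands (b is 1..M+1)
  std::vector<std::vector<double>> D(L + 1,
                                     std::vector<double>(M + 2, INF));
  std::vector<std::vector<int>> back(L + 1, std::vector<int>(M + 2, -1));
  D[0][1] = 0.0;
  for (int l = 1; l <= L; ++l) {
    for (int b = 1 + l * w_min; b <= M + 1; ++b) {
      double best = INF;
      int arg = -1;
      for (int a = 1 + (l - 1) * w_min; a <= b - w_min; ++a) {
        if (D[l - 1][a] == INF) continue;
        double v = D[l - 1][a] + cost(a, b);
        if (v < best) {
          best = v;
          arg = a;
        }
      }
      D[l][b] = best;
      back[l][b] = arg;
    }
  }
  int b = M + 1;
  for (int l = L; l >= 1; --l) {
    int a = back[l][b];
    if (l > 1) cuts_out[l - 2] = a;
    b = a;
  }
  return D[L][M + 1];
}

// Deterministic local refinement (memetic step): alternate exact DP band
// segmentation given the clustering with k-means-style reassignment of
// replicates to the subpopulation whose mean collapsed spectrum fits them
// best. Monotone decrease is enforced by accepting a pass only if the total
// loss improves.
// [[Rcpp::export]]
List cpp_refine(NumericMatrix CS, NumericMatrix CS2, double total_ss,
                double Tlen, IntegerVector labels0, IntegerVector cuts0,
                int J, int L, int w_min, int max_pass) {
  const int K = labels0.size();
  const int M = CS.ncol() - 1;
  const int nc = (L > 1) ? J * (L - 1) : 0;
  std::vector<int> labels(labels0.begin(), labels0.end());
  std::vector<int> cuts(std::max(nc, 1), 0);
  for (int i = 0; i < nc; ++i) cuts[i] = cuts0[i];
  double cur = loss_impl(CS, total_ss, Tlen, labels.data(),
                         nc > 0 ? cuts.data() : nullptr, K, J, L);

  for (int pass = 0; pass < max_pass; ++pass) {
    bool changed = false;
    // exact cuts per group given labels
    if (L > 1) {
      std::vector<int> trial(cuts);
      for (int j = 0; j < J; ++j) {
        std::vector<double> s1(M + 1, 0.0), s2(M + 1, 0.0);
        int Kj = 0;
        for (int k = 0; k < K; ++k) {
          if (labels[k] - 1 != j) continue;
          ++Kj;
          for (int m = 0; m <= M; ++m) {
            s1[m] += CS(k, m);
            s2[m] += CS2(k, m);
          }
        }
        dp_segment(s1, s2, Kj, M, L, w_min, trial.data() + (size_t)j * (L - 1));
      }
      double v = loss_impl(CS, total_ss, Tlen, labels.data(), trial.data(),
                           K, J, L);
      if (v < cur - 1e-12) {
        cuts = trial;
        cur = v;
        changed = true;
      }
    }
    // reassignment pass given cuts: move each replicate to the group whose
    // current mean collapsed spectrum it fits best (never emptying a group)
    if (J > 1) {
      std::vector<int> trial(labels);
      // group band means under current trial labels
      std::vector<double> band_sum((size_t)J * L, 0.0);
      std::vector<int> gsize(J, 0);
      auto band_edges = [&](int j, int l, int& a, int& b) {
        const int* cj = cuts.data() + (size_t)j * (L - 1);
        a = (l == 0) ? 1 : cj[l - 1];
        b = (l == L - 1) ? (M + 1) : cj[l];
      };
      for (int k = 0; k < K; ++k) {
        int j = trial[k] - 1;
        ++gsize[j];
        for (int l = 0; l < L; ++l) {
          int a, b;
          band_edges(j, l, a, b);
          band_sum[(size_t)j * L + l] += CS(k, b - 1) - CS(k, a - 1);
        }
      }
      std::vector<double> ybar((size_t)J * L, 0.0);
      for (int j = 0; j < J; ++j) {
        for (int l = 0; l < L; ++l) {
          int a, b;
          band_edges(j, l, a, b);
          ybar[(size_t)j * L + l] =
              band_sum[(size_t)j * L + l] / ((double)gsize[j] * (b - a));
        }
      }
      for (int k = 0; k < K; ++k) {
        if (gsize[trial[k] - 1] <= 1) continue;
        double best = std::numeric_limits<double>::infinity();
        int arg = trial[k];
        for (int j = 0; j < J; ++j) {
          double r = 0.0;
          for (int l = 0; l < L; ++l) {
            int a, b;
            band_edges(j, l, a, b);
            double w = b - a;
            double sk = CS(k, b - 1) - CS(k, a - 1);
            double qk = CS2(k, b - 1) - CS2(k, a - 1);
            double y = ybar[(size_t)j * L + l];
            r += qk - 2.0 * y * sk + w * y * y;
          }
          if (r < best - 1e-12) {
            best = r;
            arg = j + 1;
          }
        }
        if (arg != trial[k]) {
          --gsize[trial[k] - 1];
          ++gsize[arg - 1];
          trial[k] = arg;
        }
      }
      double v = loss_impl(CS, total_ss, Tlen, trial.data(),
                           nc > 0 ? cuts.data() : nullptr, K, J, L);
      if (v < cur - 1e-12) {
        labels = trial;
        cur = v;
        changed = true;
      }
    }
    if (!changed) break;
  }
  IntegerVector out_lab(labels.begin(), labels.end());
  IntegerVector out_cut(nc);
  for (int i = 0; i < nc; ++i) out_cut[i] = cuts[i];
  return List::create(_["labels"] = out_lab, _["cuts"] = out_cut,
                      _["loss"] = cur);
}

// [[Rcpp::export]]
List cpp_evolve_island(NumericMatrix CS, double total_ss, double Tlen,
                       IntegerMatrix labels_pop, IntegerMatrix cuts_pop,
                       NumericVector losses, int J, int L, double pm,
                       int n_off, int jit, int w_min,
                       IntegerVector elite_labels, IntegerVector elite_cuts,
                       double elite_loss, int n_gen) {
  const int pop = labels_pop.nrow();
  const int K = labels_pop.ncol();
  const int nc = (L > 1) ? J * (L - 1) : 0;
  const int M = CS.ncol() - 1;
  const int total = pop * (1 + n_off);

  std::vector<int> lab((size_t)total * K), cut((size_t)total * std::max(nc, 1));
  std::vector<double> fit(total);
  std::vector<int> e_lab(elite_labels.begin(), elite_labels.end());
  std::vector<int> e_cut(nc);
  for (int i = 0; i < nc; ++i) e_cut[i] = elite_cuts[i];
  double e_loss = elite_loss;

  // load current population into slots 0..pop-1
  for (int p = 0; p < pop; ++p) {
    for (int k = 0; k < K; ++k) lab[(size_t)p * K + k] = labels_pop(p, k);
    for (int i = 0; i < nc; ++i)
      cut[(size_t)p * std::max(nc, 1) + i] = cuts_pop(p, i);
    fit[p] = losses[p];
  }

  std::vector<int> ord(total);
  const int stride = std::max(nc, 1);
  for (int gen = 0; gen < n_gen; ++gen) {
    // offspring
    int slot = pop;
    for (int p = 0; p < pop; ++p) {
      for (int o = 0; o < n_off; ++o, ++slot) {
        int* lt = &lab[(size_t)slot * K];
        int* ct = &cut[(size_t)slot * stride];
        std::copy(&lab[(size_t)p * K], &lab[(size_t)p * K] + K, lt);
        std::copy(&cut[(size_t)p * stride], &cut[(size_t)p * stride] + stride,
                  ct);
        mutate_impl(lt, nc > 0 ? ct : nullptr, K, J, L, M, pm, jit, w_min);
        fit[slot] = loss_impl(CS, total_ss, Tlen, lt, nc > 0 ? ct : nullptr,
                              K, J, L);
      }
    }
    // rank parents + offspring, keep best pop (stable for determinism);
    // collapse runs of identical chromosomes so unmutated offspring do not
    // flood the population with copies of their parent
    for (int i = 0; i < total; ++i) ord[i] = i;
    std::stable_sort(ord.begin(), ord.end(),
                     [&](int a, int b) { return fit[a] < fit[b]; });
    std::vector<int> keep;
    keep.reserve(pop);
    std::vector<int> skipped;
    int last = -1;
    for (int i = 0; i < total && (int)keep.size() < pop; ++i) {
      int src = ord[i];
      bool dup = false;
      if (last >= 0 && fit[src] == fit[last]) {
        dup = std::equal(&lab[(size_t)src * K], &lab[(size_t)src * K] + K,
                         &lab[(size_t)last * K]) &&
              std::equal(&cut[(size_t)src * stride],
                         &cut[(size_t)src * stride] + stride,
                         &cut[(size_t)last * stride]);
      }
      if (dup) {
        skipped.push_back(src);
      } else {
        keep.push_back(src);
        last = src;
      }
    }
    for (size_t i = 0; keep.size() < (size_t)pop; ++i) keep.push_back(skipped[i]);
    std::vector<int> new_lab((size_t)pop * K), new_cut((size_t)pop * stride);
    std::vector<double> new_fit(pop);
    for (int p = 0; p < pop; ++p) {
      int src = keep[p];
      std::copy(&lab[(size_t)src * K], &lab[(size_t)src * K] + K,
                &new_lab[(size_t)p * K]);
      std::copy(&cut[(size_t)src * stride], &cut[(size_t)src * stride] + stride,
                &new_cut[(size_t)p * stride]);
      new_fit[p] = fit[src];
    }
    // elitist step: previous elite replaces the current worst, unless it
    // already survived as the current best
    bool elite_present =
        new_fit[0] == e_loss &&
        std::equal(e_lab.begin(), e_lab.end(), &new_lab[0]) &&
        (nc == 0 || std::equal(e_cut.begin(), e_cut.end(), &new_cut[0]));
    if (!elite_present && e_loss < new_fit[pop - 1]) {
      std::copy(e_lab.begin(), e_lab.end(), &new_lab[(size_t)(pop - 1) * K]);
      if (nc > 0)
        std::copy(e_cut.begin(), e_cut.end(),
                  &new_cut[(size_t)(pop - 1) * stride]);
      new_fit[pop - 1] = e_loss;
    }
    // update elite to the best seen this generation
    int best = 0;
    for (int p = 1; p < pop; ++p)
      if (new_fit[p] < new_fit[best]) best = p;
    if (new_fit[best] < e_loss) {
      e_loss = new_fit[best];
      std::copy(&new_lab[(size_t)best * K], &new_lab[(size_t)best * K] + K,
                e_lab.begin());
      if (nc > 0)
        std::copy(&new_cut[(size_t)best * stride],
                  &new_cut[(size_t)best * stride] + stride, e_cut.begin());
    }
    std::copy(new_lab.begin(), new_lab.end(), lab.begin());
    std::copy(new_cut.begin(), new_cut.end(), cut.begin());
    std::copy(new_fit.begin(), new_fit.end(), fit.begin());
  }

  IntegerMatrix out_lab(pop, K);
  IntegerMatrix out_cut(pop, nc);
  NumericVector out_fit(pop);
  for (int p = 0; p < pop; ++p) {
    for (int k = 0; k < K; ++k) out_lab(p, k) = lab[(size_t)p * K + k];
    for (int i = 0; i < nc; ++i) out_cut(p, i) = cut[(size_t)p * stride + i];
    out_fit[p] = fit[p];
  }
  IntegerVector out_elab(e_lab.begin(), e_lab.end());
  IntegerVector out_ecut(e_cut.begin(), e_cut.end());
  return List::create(_["labels"] = out_lab, _["cuts"] = out_cut,
                      _["losses"] = out_fit, _["elite_labels"] = out_elab,
                      _["elite_cuts"] = out_ecut, _["elite_loss"] = e_loss);
}
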