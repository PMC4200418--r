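#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// MIC of the grid defined by sorted cut vectors xc, yc on ranks xr, yr
// (each a permutation of 1..n). Bins are (prev_cut, cut] in rank space.
static double grid_mic(const std::vector<int>& xr, const std::vector<int>& yr,
                       const std::vector<int>& xc, const std::vector<int>& yc,
                       std::vector<int>& xbin, std::vector<int>& ybin,
                       std::vector<double>& counts,
                       std::vector<double>& rowsum, std::vector<double>& colsum) {
  const int n = (int)xr.size();
  const int nx = (int)xc.size() + 1;
  const int ny = (int)yc.size() + 1;

  // bin of each rank value (1..n), 0-based bins
  {
    int b = 0;
    for (int r = 1; r <= n; ++r) {
      while (b < (int)xc.size() && xc[b] < r) ++b;
      xbin[r - 1] = b;
    }
    b = 0;
    for (int r = 1; r <= n; ++r) {
      while (b < (int)yc.size() && yc[b] < r) ++b;
      ybin[r - 1] = b;
    }
  }

  std::fill(counts.begin(), counts.begin() + nx * ny, 0.0);
  for (int i = 0; i < n; ++i) {
    counts[xbin[xr[i] - 1] * ny + ybin[yr[i] - 1]] += 1.0;
  }

  std::fill(rowsum.begin(), rowsum.begin() + nx, 0.0);
  std::fill(colsum.begin(), colsum.begin() + ny, 0.0);
  for (int i = 0; i < nx; ++i)
    for (int j = 0; j < ny; ++j) {
      rowsum[i] += counts[i * ny + j];
      colsum[j] += counts[i * ny + j];
    }
  double mi = 0.0;
  const double dn = (double)n;
  for (int i = 0; i < nx; ++i)
    for (int j = 0; j < ny; ++j) {
      const double c = counts[i * ny + j];
      if (c > 0.0)
        mi += (c / dn) * std::log2(c * dn / (rowsum[i] * colsum[j]));
    }
  if (mi < 0.0) mi = 0.0;
  double s = mi / std::log2((double)std::min(nx, ny));
  if (s > 1.0) s = 1.0;  // floating guard; mathematically s <= 1
  return s;
}

// uniform integer in lo..hi inclusive, from R's RNG stream
static int runif_int(int lo, int hi) {
  int v = lo + (int)(unif_rand() * (double)(hi - lo + 1));
  if (v > hi) v = hi;
  return v;
}

// k distinct sorted values from 1..m
static std::vector<int> sample_sorted(int m, int k) {
  std::vector<int> out;
  out.reserve(k);
  while ((int)out.size() < k) {
    int v = runif_int(1, m);
    if (std::find(out.begin(), out.end(), v) == out.end()) out.push_back(v);
  }
  std::sort(out.begin(), out.end());
  return out;
}

// move one randomly chosen gene within its neighbor bounds (lone gene roams
// the whole axis); preserves strict ordering and gene count
static void move_one_gene(std::vector<int>& g, int n) {
  const int k = (int)g.size();
  const int j = (k == 1) ? 0 : runif_int(0, k - 1);
  const int lo = (j == 0) ? 1 : g[j - 1] + 1;
  const int hi = (j == k - 1) ? n - 1 : g[j + 1] - 1;
  if (hi >= lo) g[j] = runif_int(lo, hi);
}

// swap tails after a uniform crossover point in 0..k, then sort and repair
// duplicates by resampling from free positions
static void cross_axis(std::vector<int>& a, std::vector<int>& b, int n) {
  const int k = (int)a.size();
  const int cpt = runif_int(0, k);
  for (int i = cpt; i < k; ++i) std::swap(a[i], b[i]);
  std::sort(a.begin(), a.end());
  std::sort(b.begin(), b.end());
  for (std::vector<int>* gp : {&a, &b}) {
    std::vector<int>& g = *gp;
    bool dup = true;
    while (dup) {
      dup = false;
      for (int i = 1; i < k; ++i) {
        if (g[i] == g[i - 1]) {
          std::vector<int> free_pos;
          for (int v = 1; v <= n - 1; ++v)
            if (std::find(g.begin(), g.end(), v) == g.end())
              free_pos.push_back(v);
          g[i] = free_pos[runif_int(0, (int)free_pos.size() - 1)];
          std::sort(g.begin(), g.end());
          dup = true;
          break;
        }
      }
    }
  }
}

struct Chrom {
  std::vector<int> x, y;
  double fit;
};

// One GA run for one grid shape (kx x-genes, ky y-genes): proportional
// selection, adaptive same-axis crossover, adaptive mutation with the
// literal trigger (mutate iff u >= pm), Metropolis replacement against the
// selected parent, elitism, champion-stall termination. Uses R's RNG, so
// runs are reproducible under set.seed().
// [[Rcpp::export(name = "sg_run_shape_cpp")]]
List sg_run_shape_cpp(IntegerVector xr, IntegerVector yr, int kx, int ky,
                      int pop_size, double pm1, double pm2,
                      double pc1, double pc2,
                      double t0, double cooling,
                      int stall_limit, int max_generations) {
  const int n = xr.size();
  std::vector<int> xrv(xr.begin(), xr.end()), yrv(yr.begin(), yr.end());
  const int nx = kx + 1, ny = ky + 1;
  std::vector<int> xbin(n), ybin(n);
  std::vector<double> counts(nx * ny), rowsum(nx), colsum(ny);
  long evals = 0;

  auto score = [&](const std::vector<int>& xg, const std::vector<int>& yg) {
    ++evals;
    return grid_mic(xrv, yrv, xg, yg, xbin, ybin, counts, rowsum, colsum);
  };

  std::vector<Chrom> pop(pop_size);
  for (int i = 0; i < pop_size; ++i) {
    pop[i].x = sample_sorted(n - 1, kx);
    pop[i].y = sample_sorted(n - 1, ky);
    pop[i].fit = score(pop[i].x, pop[i].y);
  }

  Chrom best = pop[0];
  for (int i = 1; i < pop_size; ++i)
    if (pop[i].fit > best.fit) best = pop[i];

  std::vector<double> best_by_gen;
  double temp = t0;
  int stall = 0, gen = 0;
  long worse = 0;

  std::vector<Chrom> parents(pop_size), children(pop_size);
  std::vector<int> idx(pop_size);

  while (gen < max_generations && stall < stall_limit) {
    ++gen;

    // proportional selection (uniform fallback when all fitness is 0)
    double total = 0.0;
    for (int i = 0; i < pop_size; ++i) total += pop[i].fit;
    for (int i = 0; i < pop_size; ++i) {
      if (total <= 0.0) {
        idx[i] = runif_int(0, pop_size - 1);
      } else {
        double u = unif_rand() * total, cum = 0.0;
        int j = 0;
        for (; j < pop_size; ++j) {
          cum += pop[j].fit;
          if (u <= cum) break;
        }
        idx[i] = std::min(j, pop_size - 1);
      }
    }
    for (int i = 0; i < pop_size; ++i) {
      parents[i] = pop[idx[i]];
      children[i] = parents[i];
    }

    // adaptive same-axis crossover on consecutive pairs
    double f_max = parents[0].fit, f_sum = 0.0;
    for (int i = 0; i < pop_size; ++i) {
      f_max = std::max(f_max, parents[i].fit);
      f_sum += parents[i].fit;
    }
    double f_ave = f_sum / pop_size;
    auto adapt = [](double f, double fmax, double fave,
                    double hi, double lo) {
      if (fmax <= fave || f < fave) return hi;
      double p = hi - (hi - lo) * (f - fave) / (fmax - fave);
      return std::max(p, lo);
    };
    for (int p = 0; p + 1 < pop_size; p += 2) {
      double fprime = std::max(children[p].fit, children[p + 1].fit);
      double pc = adapt(fprime, f_max, f_ave, pc1, pc2);
      if (unif_rand() < pc) {
        cross_axis(children[p].x, children[p + 1].x, n);
        cross_axis(children[p].y, children[p + 1].y, n);
        children[p].fit = score(children[p].x, children[p].y);
        children[p + 1].fit = score(children[p + 1].x, children[p + 1].y);
      }
    }

    // adaptive mutation, literal trigger: mutate iff u >= pm
    f_max = children[0].fit;
    f_sum = 0.0;
    for (int i = 0; i < pop_size; ++i) {
      f_max = std::max(f_max, children[i].fit);
      f_sum += children[i].fit;
    }
    f_ave = f_sum / pop_size;
    for (int i = 0; i < pop_size; ++i) {
      double pm = adapt(children[i].fit, f_max, f_ave, pm1, pm2);
      if (unif_rand() >= pm) {
        move_one_gene(children[i].x, n);
        move_one_gene(children[i].y, n);
        children[i].fit = score(children[i].x, children[i].y);
      }
    }

    // Metropolis-filtered replacement against the selected parent
    for (int i = 0; i < pop_size; ++i) {
      double delta = children[i].fit - parents[i].fit;
      if (delta >= 0.0) continue;
      if (unif_rand() < std::exp(delta / temp)) {
        ++worse;
      } else {
        children[i] = parents[i];
      }
    }

    // champion tracking and elitist re-insertion
    int ib = 0, iw = 0;
    for (int i = 1; i < pop_size; ++i) {
      if (children[i].fit > children[ib].fit) ib = i;
      if (children[i].fit < children[iw].fit) iw = i;
    }
    if (children[ib].fit > best.fit) {
      best = children[ib];
      stall = 0;
    } else {
      ++stall;
    }
    children[iw] = best;
    pop.swap(children);
    best_by_gen.push_back(best.fit);
    temp *= cooling;
  }

  return List::create(
    _["xgenes"] = IntegerVector(best.x.begin(), best.x.end()),
    _["ygenes"] = IntegerVector(best.y.begin(), best.y.end()),
    _["fitness"] = best.fit,
    _["generations"] = gen,
    _["evaluations"] = (double)evals,
    _["accepted_worse"] = (double)worse,
    _["best_by_generation"] = NumericVector(best_by_gen.begin(),
                                            best_by_gen.end())
  );
}

// Fast scorer used for cross-checking the compiled path against the pure-R
// scorer on arbitrary grids.
// [[Rcpp::export(name = "mic_score_cpp")]]
double mic_score_cpp(IntegerVector xr, IntegerVector yr,
                     IntegerVector x_cuts, IntegerVector y_cuts) {
  const int n = xr.size();
  std::vector<int> xrv(xr.begin(), xr.end()), yrv(yr.begin(), yr.end());
  std::vector<int> xc(x_cuts.begin(), x_cuts.end());
  std::vector<int> yc(y_cuts.begin(), y_cuts.end());
  const int nx = (int)xc.size() + 1, ny = (int)yc.size() + 1;
  std::vector<int> xbin(n), ybin(n);
  std::vector<double> counts(nx * ny), rowsum(nx), colsum(ny);
  return grid_mic(xrv, yrv, xc, yc, xbin, ybin, counts, rowsum, colsum);
}
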