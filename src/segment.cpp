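#include <Rcpp.h>
#include <vector>
#include <array>
#include <cmath>
#include <cstdlib>
using namespace Rcpp;

// 3-D connected-component labelling by iterative flood fill.
// connectivity: 6 (face) or 26 (face+edge+corner). Labels are 1..n_components
// in raster-scan discovery order; background stays 0.
// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  IntegerVector labels(n, 0);

  std::vector<std::array<int, 3>> nb;
  for (int dk = -1; dk <= 1; ++dk)
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di) {
        if (di == 0 && dj == 0 && dk == 0) continue;
        if (connectivity == 6 &&
            std::abs(di) + std::abs(dj) + std::abs(dk) != 1)
          continue;
        nb.push_back({di, dj, dk});
      }

  int cur = 0;
  std::vector<int> stack;
  for (int idx = 0; idx < n; ++idx) {
    if (!mask[idx] || labels[idx]) continue;
    labels[idx] = ++cur;
    stack.push_back(idx);
    while (!stack.empty()) {
      const int v = stack.back();
      stack.pop_back();
      const int k = v / (nx * ny);
      const int r = v % (nx * ny);
      const int j = r / nx;
      const int i = r % nx;
      for (const auto& d : nb) {
        const int ii = i + d[0], jj = j + d[1], kk = k + d[2];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
          continue;
        const int w = ii + nx * (jj + ny * kk);
        if (mask[w] && !labels[w]) {
          labels[w] = cur;
          stack.push_back(w);
        }
      }
    }
  }
  return labels;
}

// Two-phase piecewise-constant region competition restricted to a domain
// mask, minimised by slice-wise ICM sweeps (sequential single-voxel moves,
// each accepted only if it lowers the energy at the current region means)
// alternating with exact mean updates. Both step types are non-increasing in
//   E = lambda_in * sum_in (v - c_in)^2 + lambda_out * sum_out (v - c_out)^2
//       + mu * (# unlike 4-neighbour in-slice pairs within the domain)
// so the recorded energy trace is monotone by construction.
// A move that would empty either phase is rejected.
// [[Rcpp::export]]
List chanvese_icm_cpp(NumericVector vol, LogicalVector domain,
                      LogicalVector init, IntegerVector dims,
                      double lambda_in, double lambda_out, double mu,
                      int max_iters, double tol) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;

  std::vector<char> in(n, 0);
  long n_in = 0, n_out = 0;
  double s_in = 0.0, s_out = 0.0;
  for (int i = 0; i < n; ++i) {
    if (!domain[i]) continue;
    if (init[i]) { in[i] = 1; s_in += vol[i]; ++n_in; }
    else         { s_out += vol[i]; ++n_out; }
  }
  if (n_in == 0 || n_out == 0)
    stop("initial contour must leave both phases non-empty within the domain");

  const int di4[4] = {-1, 1, 0, 0};
  const int dj4[4] = {0, 0, -1, 1};

  auto energy = [&](double cin, double cout) {
    double e = 0.0;
    for (int idx = 0; idx < n; ++idx) {
      if (!domain[idx]) continue;
      const double d = vol[idx] - (in[idx] ? cin : cout);
      e += (in[idx] ? lambda_in : lambda_out) * d * d;
    }
    // unlike in-slice 4-neighbour pairs, each counted once
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          const int idx = i + nx * (j + ny * k);
          if (!domain[idx]) continue;
          if (i + 1 < nx) {
            const int w = idx + 1;
            if (domain[w] && in[idx] != in[w]) e += mu;
          }
          if (j + 1 < ny) {
            const int w = idx + nx;
            if (domain[w] && in[idx] != in[w]) e += mu;
          }
        }
    return e;
  };

  std::vector<double> etrace;
  double cin = s_in / n_in, cout = s_out / n_out;
  bool converged = false;
  int iter = 0;
  for (iter = 1; iter <= max_iters; ++iter) {
    long flips = 0;
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          const int idx = i + nx * (j + ny * k);
          if (!domain[idx]) continue;
          const char cur = in[idx];
          if (cur && n_in <= 1) continue;    // keep phases non-empty
          if (!cur && n_out <= 1) continue;
          const double v = vol[idx];
          const double d_in = v - cin, d_out = v - cout;
          // energy change of moving this voxel to the opposite phase
          double delta = cur
            ? lambda_out * d_out * d_out - lambda_in * d_in * d_in
            : lambda_in * d_in * d_in - lambda_out * d_out * d_out;
          for (int t = 0; t < 4; ++t) {
            const int ii = i + di4[t], jj = j + dj4[t];
            if (ii < 0 || ii >= nx || jj < 0 || jj >= ny) continue;
            const int w = ii + nx * (jj + ny * k);
            if (!domain[w]) continue;
            delta += mu * ((cur == in[w]) ? 1.0 : -1.0);
          }
          if (delta < 0) {
            in[idx] = !cur;
            ++flips;
            if (cur) { --n_in; ++n_out; s_in -= v; s_out += v; }
            else     { ++n_in; --n_out; s_in += v; s_out -= v; }
          }
        }
    const double cin_new = s_in / n_in, cout_new = s_out / n_out;
    const double scale = std::max(std::abs(cin) + std::abs(cout), 1e-12);
    const double dmeans = (std::abs(cin_new - cin) + std::abs(cout_new - cout)) / scale;
    cin = cin_new;
    cout = cout_new;
    etrace.push_back(energy(cin, cout));
    if (flips == 0 && dmeans < tol) { converged = true; break; }
  }

  LogicalVector mask(n);
  for (int i = 0; i < n; ++i) mask[i] = in[i] != 0;
  return List::create(_["mask"] = mask,
                      _["energy"] = NumericVector(etrace.begin(), etrace.end()),
                      _["iterations"] = std::min(iter, max_iters),
                      _["converged"] = converged,
                      _["c_in"] = cin, _["c_out"] = cout);
}
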