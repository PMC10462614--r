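#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Shared layout conventions (0-based in C++, converted at the R boundary):
//   input spike times  : int array (C, H, W), NA_INTEGER = silent, else 1..T
//   synaptic weights   : double array (K, C, kh, kw)
//   output site (k,y,x): y in [0, Ho), Ho = H + 2*pad - kh + 1 (same for x)
// Voltage update follows v(t) = v(t-1) + sum_j w_j * s_j(t-1): a spike at
// input step t contributes at step t+1, so firing can occur at steps 2..T.

struct Event {
  int t, k, y, x;
  double pot;
};

static inline int widx(int k, int c, int dy, int dx, int K, int C, int kh) {
  return k + K * (c + C * (dy + kh * dx));
}

// Simulate the IF layer for one stimulus; returns per-site first firing
// time (-1 if none) and potential at firing.
static void if_simulate(const int* times, int C, int H, int W,
                        const double* wts, int K, int kh, int kw, int pad,
                        double vth, int T,
                        std::vector<int>& ft, std::vector<double>& fp) {
  const int Ho = H + 2 * pad - kh + 1;
  const int Wo = W + 2 * pad - kw + 1;
  const int nsites = K * Ho * Wo;
  std::vector<double> v(nsites, 0.0);
  ft.assign(nsites, -1);
  fp.assign(nsites, 0.0);

  // bucket input spikes by time step
  std::vector<std::vector<int> > by_t(T + 1);
  for (int x = 0; x < W; ++x)
    for (int y = 0; y < H; ++y)
      for (int c = 0; c < C; ++c) {
        int tv = times[c + C * (y + H * x)];
        if (tv != NA_INTEGER) by_t[tv].push_back(c + C * (y + H * x));
      }

  for (int t = 2; t <= T; ++t) {
    // integrate spikes emitted at step t-1
    for (size_t s = 0; s < by_t[t - 1].size(); ++s) {
      int lin = by_t[t - 1][s];
      int c = lin % C, y = (lin / C) % H, x = lin / (C * H);
      for (int dy = 0; dy < kh; ++dy) {
        int yo = y - dy + pad;
        if (yo < 0 || yo >= Ho) continue;
        for (int dx = 0; dx < kw; ++dx) {
          int xo = x - dx + pad;
          if (xo < 0 || xo >= Wo) continue;
          for (int k = 0; k < K; ++k)
            v[k + K * (yo + Ho * xo)] += wts[widx(k, c, dy, dx, K, C, kh)];
        }
      }
    }
    // threshold crossing; each site fires at most once, reset to 0
    for (int i = 0; i < nsites; ++i) {
      if (ft[i] < 0 && v[i] >= vth) {
        ft[i] = t;
        fp[i] = v[i];
        v[i] = 0.0;
      }
    }
  }
}

// [[Rcpp::export]]
DataFrame cpp_if_events(IntegerVector times, NumericVector wts,
                        int pad, double vth, int T) {
  IntegerVector dt = times.attr("dim");
  IntegerVector dw = wts.attr("dim");
  int C = dt[0], H = dt[1], W = dt[2];
  int K = dw[0], kh = dw[2], kw = dw[3];
  if (dw[1] != C) stop("layer expects %d input channels, got %d", dw[1], C);
  std::vector<int> ft; std::vector<double> fp;
  if_simulate(INTEGER(times), C, H, W, REAL(wts), K, kh, kw, pad, vth, T,
              ft, fp);
  const int Ho = H + 2 * pad - kh + 1, Wo = W + 2 * pad - kw + 1;
  std::vector<Event> ev;
  for (int x = 0; x < Wo; ++x)
    for (int y = 0; y < Ho; ++y)
      for (int k = 0; k < K; ++k) {
        int i = k + K * (y + Ho * x);
        if (ft[i] > 0) ev.push_back(Event{ft[i], k, y, x, fp[i]});
      }
  std::sort(ev.begin(), ev.end(), [](const Event& a, const Event& b) {
    if (a.t != b.t) return a.t < b.t;
    if (a.k != b.k) return a.k < b.k;
    if (a.y != b.y) return a.y < b.y;
    return a.x < b.x;
  });
  int n = ev.size();
  IntegerVector t(n), k(n), y(n), x(n); NumericVector pot(n);
  for (int i = 0; i < n; ++i) {
    t[i] = ev[i].t; k[i] = ev[i].k + 1; y[i] = ev[i].y + 1;
    x[i] = ev[i].x + 1; pot[i] = ev[i].pot;
  }
  return DataFrame::create(_["t"] = t, _["channel"] = k, _["row"] = y,
                           _["col"] = x, _["potential"] = pot);
}

// [[Rcpp::export]]
NumericVector cpp_extract_features(NumericVector counts, NumericVector wts,
                                   int pad) {
  IntegerVector dc = counts.attr("dim");
  IntegerVector dw = wts.attr("dim");
  int C = dc[0], H = dc[1], W = dc[2];
  int K = dw[0], kh = dw[2], kw = dw[3];
  if (dw[1] != C) stop("layer expects %d input channels, got %d", dw[1], C);
  const int Ho = H + 2 * pad - kh + 1, Wo = W + 2 * pad - kw + 1;
  if (Ho < 1 || Wo < 1) stop("kernel larger than padded input");
  NumericVector out(K * Ho * Wo);
  out.attr("dim") = IntegerVector::create(K, Ho, Wo);
  const double* cn = REAL(counts);
  const double* w = REAL(wts);
  double* o = REAL(out);
  for (int x = 0; x < W; ++x)
    for (int y = 0; y < H; ++y)
      for (int c = 0; c < C; ++c) {
        double cv = cn[c + C * (y + H * x)];
        if (cv == 0.0) continue;
        for (int dy = 0; dy < kh; ++dy) {
          int yo = y - dy + pad;
          if (yo < 0 || yo >= Ho) continue;
          for (int dx = 0; dx < kw; ++dx) {
            int xo = x - dx + pad;
            if (xo < 0 || xo >= Wo) continue;
            for (int k = 0; k < K; ++k)
              o[k + K * (yo + Ho * xo)] += cv * w[widx(k, c, dy, dx, K, C, kh)];
          }
        }
      }
  return out;
}

// Lateral inhibition + k-winners-take-all + STDP for one stimulus.
// Returns the number of winners applied; modifies weights in place.
static int train_one(const int* times, int C, int H, int W,
                     double* w, int K, int kh, int kw, int pad,
                     double vth, int T, double apos, double aneg,
                     int kwin, int radius) {
  std::vector<int> ft; std::vector<double> fp;
  if_simulate(times, C, H, W, w, K, kh, kw, pad, vth, T, ft, fp);
  const int Ho = H + 2 * pad - kh + 1, Wo = W + 2 * pad - kw + 1;

  // lateral inhibition: earliest spike per position; tie -> lowest channel
  std::vector<Event> surv;
  for (int x = 0; x < Wo; ++x)
    for (int y = 0; y < Ho; ++y) {
      int best = -1, bt = 0;
      for (int k = 0; k < K; ++k) {
        int t = ft[k + K * (y + Ho * x)];
        if (t > 0 && (best < 0 || t < bt)) { best = k; bt = t; }
      }
      if (best >= 0)
        surv.push_back(Event{bt, best, y, x, fp[best + K * (y + Ho * x)]});
    }

  // winner ranking: earliest, then highest potential, then channel, site
  std::sort(surv.begin(), surv.end(), [](const Event& a, const Event& b) {
    if (a.t != b.t) return a.t < b.t;
    if (a.pot != b.pot) return a.pot > b.pot;
    if (a.k != b.k) return a.k < b.k;
    if (a.y != b.y) return a.y < b.y;
    return a.x < b.x;
  });
  std::vector<char> used(K, 0);
  std::vector<Event> winners;
  for (size_t i = 0; i < surv.size() && (int)winners.size() < kwin; ++i) {
    const Event& e = surv[i];
    if (used[e.k]) continue;
    bool suppressed = false;
    for (size_t jw = 0; jw < winners.size(); ++jw) {
      if (winners[jw].k == e.k &&
          std::abs(winners[jw].y - e.y) <= radius &&
          std::abs(winners[jw].x - e.x) <= radius) { suppressed = true; break; }
    }
    if (suppressed) continue;
    winners.push_back(e);
    used[e.k] = 1;
  }

  // simplified STDP on each winner's receptive field
  for (size_t jw = 0; jw < winners.size(); ++jw) {
    const Event& e = winners[jw];
    for (int dy = 0; dy < kh; ++dy) {
      int yi = e.y + dy - pad;
      for (int dx = 0; dx < kw; ++dx) {
        int xi = e.x + dx - pad;
        for (int c = 0; c < C; ++c) {
          int tj = NA_INTEGER;  // out-of-bounds = zero padding, never spikes
          if (yi >= 0 && yi < H && xi >= 0 && xi < W)
            tj = times[c + C * (yi + H * xi)];
          int iw = widx(e.k, c, dy, dx, K, C, kh);
          double wij = w[iw];
          double dwij = (tj != NA_INTEGER && tj <= e.t)
            ? apos * wij * (1.0 - wij)
            : aneg * wij * (1.0 - wij);
          wij += dwij;
          if (wij < 0.0) wij = 0.0;
          if (wij > 1.0) wij = 1.0;
          w[iw] = wij;
        }
      }
    }
  }
  return (int)winners.size();
}

// [[Rcpp::export]]
List cpp_train_scnn(List waves, NumericVector wts, int pad, double vth,
                    int T, double apos, double aneg, double stop_c,
                    IntegerMatrix order, int kwin, int radius) {
  IntegerVector dw = wts.attr("dim");
  int K = dw[0], C = dw[1], kh = dw[2], kw = dw[3];
  NumericVector w = clone(wts);
  double* wp = REAL(w);
  const int N = w.size();
  int n_per_epoch = order.nrow(), epochs = order.ncol();
  std::vector<double> trace;
  trace.reserve((size_t)n_per_epoch * epochs);
  bool converged = false;
  int presentations = 0, epochs_run = 0;
  double cval = 0.0;
  for (int i = 0; i < N; ++i) cval += wp[i] * (1.0 - wp[i]);
  cval /= N;

  for (int ep = 0; ep < epochs && !converged; ++ep) {
    ++epochs_run;
    for (int m = 0; m < n_per_epoch; ++m) {
      IntegerVector tw = waves[order(m, ep) - 1];
      IntegerVector dt = tw.attr("dim");
      train_one(INTEGER(tw), dt[0], dt[1], dt[2], wp, K, kh, kw, pad,
                vth, T, apos, aneg, kwin, radius);
      ++presentations;
      cval = 0.0;
      for (int i = 0; i < N; ++i) cval += wp[i] * (1.0 - wp[i]);
      cval /= N;
      trace.push_back(cval);
      if (cval < stop_c) { converged = true; break; }
    }
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["weights"] = w,
                      _["trace"] = NumericVector(trace.begin(), trace.end()),
                      _["presentations"] = presentations,
                      _["epochs_run"] = epochs_run,
                      _["converged"] = converged,
                      _["final_c"] = cval);
}
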