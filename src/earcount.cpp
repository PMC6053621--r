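#include <Rcpp.h>
#include <vector>
#include <functional>
#include <algorithm>
#include <numeric>
using namespace Rcpp;

// Flood-fill labeling of connected components.
// by_value = true : components are maximal connected sets of EQUAL pixel value
//                   (used for colour-coherence analysis); every pixel gets a label.
// by_value = false: components of non-zero pixels; zero pixels keep label 0.
// connectivity: 4 or 8. Labels are 1..K in scan order of component discovery.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(IntegerMatrix img, int connectivity,
                                   bool by_value) {
  const int H = img.nrow(), W = img.ncol();
  IntegerMatrix lab(H, W);
  std::fill(lab.begin(), lab.end(), 0);
  const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int nn = (connectivity == 8) ? 8 : 4;
  std::vector<int> stack;
  int next = 0;
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      if (lab(r, c) != 0) continue;
      if (!by_value && img(r, c) == 0) continue;
      const int v = img(r, c);
      lab(r, c) = ++next;
      stack.clear();
      stack.push_back(r + c * H);
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int rr = idx % H, cc = idx / H;
        for (int t = 0; t < nn; ++t) {
          int r2 = rr + dr8[t], c2 = cc + dc8[t];
          if (r2 < 0 || r2 >= H || c2 < 0 || c2 >= W) continue;
          if (lab(r2, c2) != 0) continue;
          if (img(r2, c2) != v) continue;
          lab(r2, c2) = next;
          stack.push_back(r2 + c2 * H);
        }
      }
    }
  }
  return lab;
}

// SLIC local k-means: windowed assignment with D^2 = dlab^2 + (dxy/S)^2 m^2,
// followed by a centre update; `centers` is K x 5 (row, col, L, a, b), 0-based
// coordinates. Returns the 0-based label image after max_iter iterations.
// [[Rcpp::export]]
IntegerMatrix cpp_slic_iterate(NumericMatrix L, NumericMatrix A, NumericMatrix B,
                               NumericMatrix centers, double S, double m,
                               int max_iter) {
  const int H = L.nrow(), W = L.ncol();
  const int K = centers.nrow();
  IntegerMatrix lab(H, W);
  NumericMatrix dist(H, W);
  const double invS2m2 = (m * m) / (S * S);

  for (int it = 0; it < max_iter; ++it) {
    std::fill(dist.begin(), dist.end(), R_PosInf);
    std::fill(lab.begin(), lab.end(), -1);
    for (int k = 0; k < K; ++k) {
      const double cr = centers(k, 0), cc = centers(k, 1);
      const double cL = centers(k, 2), ca = centers(k, 3), cb = centers(k, 4);
      const int r0 = std::max(0, (int)std::floor(cr - S));
      const int r1 = std::min(H - 1, (int)std::ceil(cr + S));
      const int c0 = std::max(0, (int)std::floor(cc - S));
      const int c1 = std::min(W - 1, (int)std::ceil(cc + S));
      for (int c = c0; c <= c1; ++c) {
        for (int r = r0; r <= r1; ++r) {
          const double dL = L(r, c) - cL, da = A(r, c) - ca, db = B(r, c) - cb;
          const double dxy = (r - cr) * (r - cr) + (c - cc) * (c - cc);
          const double d = dL * dL + da * da + db * db + dxy * invS2m2;
          if (d < dist(r, c)) {
            dist(r, c) = d;
            lab(r, c) = k;
          }
        }
      }
    }
    // pixels outside every window (possible after centres drift): nearest centre
    for (int c = 0; c < W; ++c)
      for (int r = 0; r < H; ++r)
        if (lab(r, c) < 0) {
          double best = R_PosInf;
          int bk = 0;
          for (int k = 0; k < K; ++k) {
            const double dxy = (r - centers(k, 0)) * (r - centers(k, 0)) +
                               (c - centers(k, 1)) * (c - centers(k, 1));
            if (dxy < best) { best = dxy; bk = k; }
          }
          lab(r, c) = bk;
        }
    // centre update: mean position and colour of assigned pixels
    std::vector<double> sr(K, 0), sc(K, 0), sL(K, 0), sa(K, 0), sb(K, 0);
    std::vector<int> n(K, 0);
    for (int c = 0; c < W; ++c)
      for (int r = 0; r < H; ++r) {
        const int k = lab(r, c);
        sr[k] += r; sc[k] += c;
        sL[k] += L(r, c); sa[k] += A(r, c); sb[k] += B(r, c);
        n[k]++;
      }
    for (int k = 0; k < K; ++k)
      if (n[k] > 0) {
        centers(k, 0) = sr[k] / n[k];
        centers(k, 1) = sc[k] / n[k];
        centers(k, 2) = sL[k] / n[k];
        centers(k, 3) = sa[k] / n[k];
        centers(k, 4) = sb[k] / n[k];
      }
  }
  return lab;
}

// Connectivity enforcement: components (4-connected) of the label image are
// found; each component smaller than min_size is merged into its largest
// adjacent component. Merging runs in O(N) passes (a small component joins
// its largest neighbour; strict (size, id) ordering prevents merge cycles)
// until no undersized component remains. Returns a label image with
// consecutive labels 1..K' whose regions are all 4-connected.
// [[Rcpp::export]]
IntegerMatrix cpp_enforce_connectivity(IntegerMatrix lab, int min_size) {
  const int H = lab.nrow(), W = lab.ncol();
  IntegerMatrix cur = clone(lab);
  IntegerMatrix comp;
  for (int pass = 0; pass < 20; ++pass) {
    comp = cpp_label_components(cur, 4, true);
    int ncomp = 0;
    for (int i = 0; i < H * W; ++i) ncomp = std::max(ncomp, comp[i]);
    std::vector<int> size(ncomp + 1, 0);
    for (int i = 0; i < H * W; ++i) size[comp[i]]++;

    // largest neighbouring component of each component ((size, id) order)
    std::vector<int> best(ncomp + 1, 0);
    auto better = [&](int cand, int incumbent) {
      if (incumbent == 0) return true;
      if (size[cand] != size[incumbent]) return size[cand] > size[incumbent];
      return cand > incumbent;
    };
    auto consider = [&](int a, int b) {
      if (a == b) return;
      if (better(b, best[a])) best[a] = b;
      if (better(a, best[b])) best[b] = a;
    };
    for (int c = 0; c < W; ++c)
      for (int r = 0; r < H; ++r) {
        if (r + 1 < H) consider(comp(r, c), comp(r + 1, c));
        if (c + 1 < W) consider(comp(r, c), comp(r, c + 1));
      }

    // small components merge into their best neighbour, but only "uphill"
    // in (size, id) order so chains terminate and cycles cannot form
    std::vector<int> target(ncomp + 1);
    std::iota(target.begin(), target.end(), 0);
    bool any = false;
    for (int cid = 1; cid <= ncomp; ++cid)
      if (size[cid] < min_size && best[cid] != 0 && better(best[cid], cid)) {
        target[cid] = best[cid];
        any = true;
      }
    if (!any) break;
    std::vector<int> final_id(ncomp + 1);
    for (int cid = 1; cid <= ncomp; ++cid) {
      int x = cid;
      while (target[x] != x) x = target[x];
      final_id[cid] = x;
    }
    for (int i = 0; i < H * W; ++i) cur[i] = final_id[comp[i]];
  }
  return cpp_label_components(cur, 4, true);
}

// Channel-plane median filter with reflected borders (odd window).
// [[Rcpp::export]]
NumericMatrix cpp_median_filter(NumericMatrix x, int window) {
  const int H = x.nrow(), W = x.ncol();
  const int p = (window - 1) / 2;
  NumericMatrix out(H, W);
  std::vector<double> buf(window * window);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      int n = 0;
      for (int dc = -p; dc <= p; ++dc)
        for (int dr = -p; dr <= p; ++dr) {
          int rr = r + dr, cc = c + dc;
          if (rr < 0) rr = -rr; else if (rr >= H) rr = 2 * H - 2 - rr;
          if (cc < 0) cc = -cc; else if (cc >= W) cc = 2 * W - 2 - cc;
          buf[n++] = x(rr, cc);
        }
      std::nth_element(buf.begin(), buf.begin() + n / 2, buf.begin() + n);
      out(r, c) = buf[n / 2];
    }
  return out;
}

// Coordinate descent for the box-constrained QP
//   min 0.5 a' Q a - lin' a   s.t.  0 <= a <= upper
// (Q symmetric PSD with positive diagonal). Exact per-coordinate minimisation;
// returns alpha, the achieved KKT residual and the sweep count.
// [[Rcpp::export]]
List cpp_qp_box_cd(NumericMatrix Q, NumericVector lin, double upper,
                   double tol, int max_sweeps) {
  const int n = Q.nrow();
  NumericVector alpha(n);
  std::vector<double> g(n);  // gradient Q a - lin
  for (int i = 0; i < n; ++i) g[i] = -lin[i];
  double kkt = R_PosInf;
  int sweep = 0;
  for (sweep = 0; sweep < max_sweeps; ++sweep) {
    for (int i = 0; i < n; ++i) {
      const double qii = Q(i, i);
      if (qii <= 0) continue;
      double ai = alpha[i] - g[i] / qii;
      ai = std::min(upper, std::max(0.0, ai));
      const double delta = ai - alpha[i];
      if (delta != 0.0) {
        for (int j = 0; j < n; ++j) g[j] += delta * Q(j, i);
        alpha[i] = ai;
      }
    }
    kkt = 0.0;
    for (int i = 0; i < n; ++i) {
      double v;
      if (alpha[i] <= 0)           v = std::max(0.0, -g[i]);
      else if (alpha[i] >= upper)  v = std::max(0.0, g[i]);
      else                         v = std::fabs(g[i]);
      kkt = std::max(kkt, v);
    }
    if (kkt <= tol) { ++sweep; break; }
  }
  return List::create(_["alpha"] = alpha, _["kkt"] = kkt,
                      _["sweeps"] = sweep);
}
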