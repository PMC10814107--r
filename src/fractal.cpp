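#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Union-find over box cells for Hoshen-Kopelman labeling.
static int uf_find(std::vector<int>& parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

static void uf_union(std::vector<int>& parent, int a, int b) {
  int ra = uf_find(parent, a), rb = uf_find(parent, b);
  if (ra != rb) parent[std::max(ra, rb)] = std::min(ra, rb);
}

// Scan every r x r gliding-box position of an RGB image (values 0..255).
// A pixel is a pore of the box when its 5-D Chebyshev distance to the central
// pixel is <= r; spatial offsets are bounded by (r-1)/2 < r, so the criterion
// reduces to max(|dR|,|dG|,|dB|) <= r.  Returns the frequency table N(m,r)
// plus per-scale percolation summaries (mean cluster count, mean largest
// cluster, fraction of percolating boxes).
// [[Rcpp::export]]
List box_scan_cpp(NumericVector img, int r, double threshold, int connectivity) {
  IntegerVector dims = img.attr("dim");
  int H = dims[0], W = dims[1];
  if (dims.size() != 3 || dims[2] != 3) stop("image must be an H x W x 3 array");
  if (r % 2 == 0) stop("box side must be odd");
  if (H < r || W < r) stop("image too small for scale r=%d", r);

  const double* R = img.begin();
  const double* G = img.begin() + (R_xlen_t)H * W;
  const double* B = img.begin() + 2 * (R_xlen_t)H * W;

  int h = (r - 1) / 2;
  int nbr = H - r + 1, nbc = W - r + 1;
  double n_boxes = (double)nbr * nbc;
  int r2 = r * r;

  std::vector<double> freq(r2, 0.0);
  double sum_clusters = 0.0, sum_qratio = 0.0, n_percolating = 0.0;

  std::vector<char> pore(r2);
  std::vector<int> parent(r2), csize(r2);

  for (int bj = 0; bj < nbc; ++bj) {
    for (int bi = 0; bi < nbr; ++bi) {
      int ci = bi + h, cj = bj + h;
      double Rc = R[ci + (R_xlen_t)H * cj];
      double Gc = G[ci + (R_xlen_t)H * cj];
      double Bc = B[ci + (R_xlen_t)H * cj];
      int m = 0;
      // pore mask in box-local coordinates (u = row, v = col), column-major
      for (int v = 0; v < r; ++v) {
        R_xlen_t col = (R_xlen_t)H * (bj + v);
        for (int u = 0; u < r; ++u) {
          R_xlen_t px = (bi + u) + col;
          double d = std::fabs(R[px] - Rc);
          double dg = std::fabs(G[px] - Gc);
          if (dg > d) d = dg;
          double db = std::fabs(B[px] - Bc);
          if (db > d) d = db;
          bool p = d <= (double)r;
          pore[u + r * v] = p;
          if (p) ++m;
        }
      }
      freq[m - 1] += 1.0;

      // Hoshen-Kopelman on the pore mask
      for (int k = 0; k < r2; ++k) parent[k] = k;
      for (int v = 0; v < r; ++v) {
        for (int u = 0; u < r; ++u) {
          int k = u + r * v;
          if (!pore[k]) continue;
          if (u > 0 && pore[k - 1]) uf_union(parent, k, k - 1);
          if (v > 0 && pore[k - r]) uf_union(parent, k, k - r);
          if (connectivity == 8 && v > 0) {
            if (u > 0 && pore[k - r - 1]) uf_union(parent, k, k - r - 1);
            if (u < r - 1 && pore[k - r + 1]) uf_union(parent, k, k - r + 1);
          }
        }
      }
      int n_clusters = 0, largest = 0;
      std::fill(csize.begin(), csize.end(), 0);
      for (int k = 0; k < r2; ++k) {
        if (!pore[k]) continue;
        int root = uf_find(parent, k);
        if (csize[root] == 0) ++n_clusters;
        if (++csize[root] > largest) largest = csize[root];
      }
      sum_clusters += n_clusters;
      sum_qratio += (double)largest / (double)r2;
      if ((double)m / (double)r2 >= threshold) n_percolating += 1.0;
    }
  }

  return List::create(
    _["frequency"] = NumericVector(freq.begin(), freq.end()),
    _["n_boxes"] = n_boxes,
    _["mean_clusters"] = sum_clusters / n_boxes,
    _["mean_largest_ratio"] = sum_qratio / n_boxes,
    _["percolating_fraction"] = n_percolating / n_boxes);
}

// Hoshen-Kopelman connected-component labeling of a binary mask.
// Labels are contiguous 1..K in raster (column-major) order of first occurrence.
// [[Rcpp::export]]
List hk_label_cpp(LogicalMatrix mask, int connectivity) {
  int H = mask.nrow(), W = mask.ncol();
  int n = H * W;
  std::vector<int> parent(n);
  for (int k = 0; k < n; ++k) parent[k] = k;

  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      int k = i + H * j;
      if (!mask(i, j)) continue;
      if (i > 0 && mask(i - 1, j)) uf_union(parent, k, k - 1);
      if (j > 0 && mask(i, j - 1)) uf_union(parent, k, k - H);
      if (connectivity == 8 && j > 0) {
        if (i > 0 && mask(i - 1, j - 1)) uf_union(parent, k, k - H - 1);
        if (i < H - 1 && mask(i + 1, j - 1)) uf_union(parent, k, k - H + 1);
      }
    }
  }

  IntegerMatrix labels(H, W);
  std::vector<int> relabel(n, 0);
  std::vector<int> sizes;
  int next = 0;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      int k = i + H * j;
      if (!mask(i, j)) { labels(i, j) = 0; continue; }
      int root = uf_find(parent, k);
      if (relabel[root] == 0) {
        relabel[root] = ++next;
        sizes.push_back(0);
      }
      labels(i, j) = relabel[root];
      sizes[relabel[root] - 1] += 1;
    }
  }
  return List::create(_["labels"] = labels,
                      _["sizes"] = IntegerVector(sizes.begin(), sizes.end()));
}

// Quick-shift mode-seeking segmentation on (ratio*R, ratio*G, ratio*B, x, y)
// features; img values expected in [0,1].  Returns labels 1..S.
// [[Rcpp::export]]
IntegerMatrix quickshift_cpp(NumericVector img, double ratio, double kernel_size,
                             double max_dist) {
  IntegerVector dims = img.attr("dim");
  int H = dims[0], W = dims[1];
  const double* R = img.begin();
  const double* G = img.begin() + (R_xlen_t)H * W;
  const double* B = img.begin() + 2 * (R_xlen_t)H * W;
  int n = H * W;

  auto dist2 = [&](int i1, int j1, int i2, int j2) {
    R_xlen_t a = i1 + (R_xlen_t)H * j1, b = i2 + (R_xlen_t)H * j2;
    double dr = ratio * (R[a] - R[b]);
    double dg = ratio * (G[a] - G[b]);
    double db = ratio * (B[a] - B[b]);
    double dx = (double)(i1 - i2), dy = (double)(j1 - j2);
    return dr * dr + dg * dg + db * db + dx * dx + dy * dy;
  };

  // Parzen density estimate over a spatial window
  int wd = (int)std::ceil(3.0 * kernel_size);
  if (wd < 1) wd = 1;
  std::vector<double> density(n, 0.0);
  double inv2k2 = 1.0 / (2.0 * kernel_size * kernel_size);
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      double d = 0.0;
      for (int jj = std::max(0, j - wd); jj <= std::min(W - 1, j + wd); ++jj)
        for (int ii = std::max(0, i - wd); ii <= std::min(H - 1, i + wd); ++ii)
          d += std::exp(-dist2(i, j, ii, jj) * inv2k2);
      density[i + H * j] = d;
    }
  }

  // Link each pixel to the nearest higher-density pixel within max_dist
  int wl = (int)std::ceil(max_dist);
  std::vector<int> parent(n);
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      int k = i + H * j;
      parent[k] = k;
      double best = max_dist * max_dist;
      int best_k = k;
      for (int jj = std::max(0, j - wl); jj <= std::min(W - 1, j + wl); ++jj) {
        for (int ii = std::max(0, i - wl); ii <= std::min(H - 1, i + wl); ++ii) {
          int k2 = ii + H * jj;
          if (density[k2] <= density[k]) continue;
          double d2 = dist2(i, j, ii, jj);
          if (d2 <= best) { best = d2; best_k = k2; }
        }
      }
      parent[k] = best_k;
    }
  }

  // Follow links to the root of each tree
  IntegerMatrix labels(H, W);
  std::vector<int> root(n, -1);
  std::vector<int> relabel(n, 0);
  int next = 0;
  for (int k = 0; k < n; ++k) {
    int p = k;
    std::vector<int> path;
    while (root[p] < 0 && parent[p] != p) {
      path.push_back(p);
      p = parent[p];
    }
    int rt = root[p] >= 0 ? root[p] : p;
    root[p] = rt;
    for (int q : path) root[q] = rt;
  }
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      int rt = root[i + H * j];
      if (relabel[rt] == 0) relabel[rt] = ++next;
      labels(i, j) = relabel[rt];
    }
  }
  return labels;
}
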