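#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Mean-shift filtering in the joint spatial (x, y) x range (L*, a*, b*) domain.
// Each pixel's state is iterated towards the local mode: the mean of all image
// samples within the spatial window (radius hs, Chebyshev for the candidate set,
// Euclidean for the weight cut) whose colour lies within range bandwidth hr of
// the current state. Convergence: joint shift below tol or maxIter reached.
// [[Rcpp::export(name = ".msFilterCpp")]]
List msFilterCpp(NumericMatrix L, NumericMatrix A, NumericMatrix B,
                 int hs, double hr, int maxIter, double tol) {
  const int nr = L.nrow(), nc = L.ncol();
  NumericMatrix fL(nr, nc), fA(nr, nc), fB(nr, nc);
  const double hr2 = hr * hr, hs2 = (double)hs * hs;
  for (int col = 0; col < nc; ++col) {
    for (int row = 0; row < nr; ++row) {
      double cx = row, cy = col;
      double cL = L(row, col), cA = A(row, col), cB = B(row, col);
      for (int it = 0; it < maxIter; ++it) {
        int r0 = std::max(0, (int)std::floor(cx) - hs);
        int r1 = std::min(nr - 1, (int)std::ceil(cx) + hs);
        int c0 = std::max(0, (int)std::floor(cy) - hs);
        int c1 = std::min(nc - 1, (int)std::ceil(cy) + hs);
        double sx = 0, sy = 0, sL = 0, sA = 0, sB = 0;
        int n = 0;
        for (int cc = c0; cc <= c1; ++cc) {
          for (int rr = r0; rr <= r1; ++rr) {
            double dx = rr - cx, dy = cc - cy;
            if (dx * dx + dy * dy > hs2) continue;
            double dL = L(rr, cc) - cL, dA = A(rr, cc) - cA, dB = B(rr, cc) - cB;
            if (dL * dL + dA * dA + dB * dB > hr2) continue;
            sx += rr; sy += cc; sL += L(rr, cc); sA += A(rr, cc); sB += B(rr, cc);
            ++n;
          }
        }
        if (n == 0) break;
        double nx = sx / n, ny = sy / n, nL = sL / n, nA = sA / n, nB = sB / n;
        double shift = std::sqrt((nx - cx) * (nx - cx) + (ny - cy) * (ny - cy) +
                                 (nL - cL) * (nL - cL) + (nA - cA) * (nA - cA) +
                                 (nB - cB) * (nB - cB));
        cx = nx; cy = ny; cL = nL; cA = nA; cB = nB;
        if (shift < tol) break;
      }
      fL(row, col) = cL; fA(row, col) = cA; fB(row, col) = cB;
    }
  }
  return List::create(_["L"] = fL, _["a"] = fA, _["b"] = fB);
}

static int uf_find(std::vector<int> &parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

// Label 4-connected components of the filtered image, merging neighbours whose
// colour distance is <= hr, then fuse regions smaller than minSize into the
// adjacent region with the closest mean colour. Labels are 1..K in raster
// order of first occurrence; every pixel is labelled.
// [[Rcpp::export(name = ".msLabelCpp")]]
IntegerMatrix msLabelCpp(NumericMatrix L, NumericMatrix A, NumericMatrix B,
                         double hr, int minSize) {
  const int nr = L.nrow(), nc = L.ncol(), n = nr * nc;
  const double hr2 = hr * hr;
  std::vector<int> parent(n);
  for (int i = 0; i < n; ++i) parent[i] = i;
  // column-major linear index: i = row + col * nr
  for (int col = 0; col < nc; ++col) {
    for (int row = 0; row < nr; ++row) {
      int i = row + col * nr;
      if (row + 1 < nr) {
        double dL = L(row, col) - L(row + 1, col);
        double dA = A(row, col) - A(row + 1, col);
        double dB = B(row, col) - B(row + 1, col);
        if (dL * dL + dA * dA + dB * dB <= hr2) {
          int a = uf_find(parent, i), b = uf_find(parent, i + 1);
          if (a != b) parent[b] = a;
        }
      }
      if (col + 1 < nc) {
        double dL = L(row, col) - L(row, col + 1);
        double dA = A(row, col) - A(row, col + 1);
        double dB = B(row, col) - B(row, col + 1);
        if (dL * dL + dA * dA + dB * dB <= hr2) {
          int a = uf_find(parent, i), b = uf_find(parent, i + nr);
          if (a != b) parent[b] = a;
        }
      }
    }
  }
  // compress to component ids
  std::vector<int> comp(n);
  std::vector<int> id(n, -1);
  int K = 0;
  for (int col = 0; col < nc; ++col)
    for (int row = 0; row < nr; ++row) {
      int i = row + col * nr;
      int r = uf_find(parent, i);
      if (id[r] < 0) id[r] = K++;
      comp[i] = id[r];
    }
  // region stats
  std::vector<double> mL(K, 0), mA(K, 0), mB(K, 0);
  std::vector<int> size(K, 0);
  for (int col = 0; col < nc; ++col)
    for (int row = 0; row < nr; ++row) {
      int k = comp[row + col * nr];
      mL[k] += L(row, col); mA[k] += A(row, col); mB[k] += B(row, col);
      ++size[k];
    }
  for (int k = 0; k < K; ++k) { mL[k] /= size[k]; mA[k] /= size[k]; mB[k] /= size[k]; }
  // iterative fusion of undersized regions into the most similar neighbour
  std::vector<int> alias(K);
  for (int k = 0; k < K; ++k) alias[k] = k;
  bool changed = true;
  while (changed) {
    changed = false;
    // adjacency under current aliasing
    std::vector< std::vector<int> > adj(K);
    for (int col = 0; col < nc; ++col)
      for (int row = 0; row < nr; ++row) {
        int a = alias[comp[row + col * nr]];
        if (row + 1 < nr) {
          int b = alias[comp[row + 1 + col * nr]];
          if (a != b) { adj[a].push_back(b); adj[b].push_back(a); }
        }
        if (col + 1 < nc) {
          int b = alias[comp[row + (col + 1) * nr]];
          if (a != b) { adj[a].push_back(b); adj[b].push_back(a); }
        }
      }
    for (int k = 0; k < K; ++k) {
      if (alias[k] != k) continue;
      if (size[k] >= minSize || adj[k].empty()) continue;
      // closest neighbouring region by mean colour
      int best = -1; double bestD = 0;
      for (size_t j = 0; j < adj[k].size(); ++j) {
        int b = adj[k][j];
        if (b == k) continue;
        double dL = mL[k] - mL[b], dA = mA[k] - mA[b], dB = mB[k] - mB[b];
        double d = dL * dL + dA * dA + dB * dB;
        if (best < 0 || d < bestD) { best = b; bestD = d; }
      }
      if (best >= 0) {
        // merge k into best
        double tot = size[k] + size[best];
        mL[best] = (mL[best] * size[best] + mL[k] * size[k]) / tot;
        mA[best] = (mA[best] * size[best] + mA[k] * size[k]) / tot;
        mB[best] = (mB[best] * size[best] + mB[k] * size[k]) / tot;
        size[best] += size[k];
        size[k] = 0;
        for (int j = 0; j < K; ++j) if (alias[j] == k) alias[j] = best;
        changed = true;
      }
    }
  }
  // final contiguous labels in raster order of first occurrence
  std::vector<int> lab(K, 0);
  int nlab = 0;
  IntegerMatrix out(nr, nc);
  for (int col = 0; col < nc; ++col)
    for (int row = 0; row < nr; ++row) {
      int k = alias[comp[row + col * nr]];
      if (lab[k] == 0) lab[k] = ++nlab;
      out(row, col) = lab[k];
    }
  return out;
}
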