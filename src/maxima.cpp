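#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <unordered_map>
#include <string>
using namespace Rcpp;

// Topographic-prominence local maxima on a 2D image, 8-connectivity.
// Descending flood with union-find: pixels are activated level by level
// (distinct intensity values, highest first); a component with no higher
// neighbour registers a new regional-maximum plateau; when two components
// carrying maxima merge, the lower peak dies with
//   prominence = peak - saddle_level.
// The surviving (global) maximum gets prominence = peak - min(image) and is
// always emitted for a non-constant image.

static inline int uf_find(std::vector<int> &parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

// [[Rcpp::export]]
DataFrame find_maxima_cpp(NumericMatrix img, double prominence) {
  const int ny = img.nrow(), nx = img.ncol(), n = ny * nx;
  std::vector<double> v(n);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) v[y + (size_t)x * ny] = img(y, x);

  double vmin = v[0], vmax = v[0];
  for (int i = 1; i < n; ++i) {
    if (v[i] < vmin) vmin = v[i];
    if (v[i] > vmax) vmax = v[i];
  }
  if (vmax == vmin) {
    // constant image: no maxima
    return DataFrame::create(_["y"] = IntegerVector(0), _["x"] = IntegerVector(0),
                             _["peak_value"] = NumericVector(0),
                             _["prominence_value"] = NumericVector(0),
                             _["on_border"] = LogicalVector(0),
                             _["is_global"] = LogicalVector(0));
  }

  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (v[a] != v[b]) return v[a] > v[b];
    return a < b;
  });

  std::vector<int> parent(n, -1);       // -1 = inactive
  std::vector<int> comp_max(n, -1);     // root -> maximum id (-1 = none yet)

  // per-maximum records
  std::vector<double> mx_peak, mx_prom;
  std::vector<int> mx_rep;              // representative pixel (linear index)

  const int dyy[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dxx[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

  int pos = 0;
  while (pos < n) {
    int lev_end = pos;
    const double lev = v[ord[pos]];
    while (lev_end < n && v[ord[lev_end]] == lev) ++lev_end;

    // activate all pixels of this level
    for (int k = pos; k < lev_end; ++k) {
      const int i = ord[k];
      parent[i] = i;
      comp_max[i] = -1;
    }
    // union with active neighbours (value >= lev)
    for (int k = pos; k < lev_end; ++k) {
      const int i = ord[k];
      const int y = i % ny, x = i / ny;
      for (int d = 0; d < 8; ++d) {
        const int yy = y + dyy[d], xx = x + dxx[d];
        if (yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
        const int j = yy + xx * ny;
        if (parent[j] < 0) continue;
        int ra = uf_find(parent, i), rb = uf_find(parent, j);
        if (ra == rb) continue;
        const int ma = comp_max[ra], mb = comp_max[rb];
        int keep = -1;
        if (ma >= 0 && mb >= 0) {
          // the lower peak dies at this saddle level; ties keep the
          // earlier-registered (higher or first-seen) maximum
          int lose;
          if (mx_peak[ma] > mx_peak[mb]) { keep = ma; lose = mb; }
          else if (mx_peak[mb] > mx_peak[ma]) { keep = mb; lose = ma; }
          else { keep = std::min(ma, mb); lose = std::max(ma, mb); }
          mx_prom[lose] = mx_peak[lose] - lev;
        } else if (ma >= 0) keep = ma;
        else if (mb >= 0) keep = mb;
        parent[rb] = ra;
        comp_max[ra] = keep;
      }
    }
    // any level component still without a maximum is a new regional-max plateau
    std::unordered_map<int, std::vector<int>> plateau;
    for (int k = pos; k < lev_end; ++k) {
      const int i = ord[k];
      const int r = uf_find(parent, i);
      if (comp_max[r] == -1) plateau[r].push_back(i);
    }
    std::vector<int> roots;
    roots.reserve(plateau.size());
    for (auto &kv : plateau) roots.push_back(kv.first);
    // deterministic registration order: by smallest member pixel
    std::sort(roots.begin(), roots.end(), [&](int a, int b) {
      return plateau[a].front() < plateau[b].front();
    });
    for (int r : roots) {
      std::vector<int> &px = plateau[r];
      long long sy = 0, sx = 0;
      const long long cnt = (long long)px.size();
      for (int i : px) { sy += i % ny; sx += i / ny; }
      // round centroid half toward smaller coordinate
      const long long ry = (2 * sy + cnt - 1) / (2 * cnt);
      const long long rx = (2 * sx + cnt - 1) / (2 * cnt);
      int rep = -1;
      long long best = -1;
      for (int i : px) {
        const long long dy = (i % ny) - ry, dx = (i / ny) - rx;
        const long long d2 = dy * dy + dx * dx;
        if (rep < 0 || d2 < best ||
            (d2 == best && (i % ny < rep % ny ||
                            (i % ny == rep % ny && i / ny < rep / ny)))) {
          rep = i;
          best = d2;
        }
      }
      const int id = (int)mx_peak.size();
      mx_peak.push_back(lev);
      mx_prom.push_back(NA_REAL);
      mx_rep.push_back(rep);
      comp_max[r] = id;
    }
    pos = lev_end;
  }

  // survivor = global maximum
  int gmax = -1;
  for (size_t m = 0; m < mx_peak.size(); ++m)
    if (R_IsNA(mx_prom[m])) {
      mx_prom[m] = mx_peak[m] - vmin;
      gmax = (int)m;
    }

  std::vector<int> keep;
  for (size_t m = 0; m < mx_peak.size(); ++m)
    if (mx_prom[m] >= prominence || (int)m == gmax) keep.push_back((int)m);
  std::sort(keep.begin(), keep.end(), [&](int a, int b) {
    if (mx_peak[a] != mx_peak[b]) return mx_peak[a] > mx_peak[b];
    const int ya = mx_rep[a] % ny, yb = mx_rep[b] % ny;
    if (ya != yb) return ya < yb;
    return mx_rep[a] / ny < mx_rep[b] / ny;
  });

  const int m = (int)keep.size();
  IntegerVector oy(m), ox(m);
  NumericVector opk(m), opr(m);
  LogicalVector obd(m), ogl(m);
  for (int k = 0; k < m; ++k) {
    const int id = keep[k];
    const int y = mx_rep[id] % ny, x = mx_rep[id] / ny;
    oy[k] = y;
    ox[k] = x;
    opk[k] = mx_peak[id];
    opr[k] = mx_prom[id];
    obd[k] = (y == 0 || y == ny - 1 || x == 0 || x == nx - 1);
    ogl[k] = (id == gmax);
  }
  return DataFrame::create(_["y"] = oy, _["x"] = ox, _["peak_value"] = opk,
                           _["prominence_value"] = opr, _["on_border"] = obd,
                           _["is_global"] = ogl);
}

// Exhaustive ungapped Hamming scan: best (fewest-mismatch) alignment of each
// query against a set of subject sequences. Returns, per query, the minimum
// mismatch count over all subjects/positions plus the first subject/position
// achieving it. Sequences must be plain A/C/G/T/N strings.

// [[Rcpp::export]]
DataFrame hamming_scan_cpp(CharacterVector queries, CharacterVector subjects) {
  const int nq = queries.size(), ns = subjects.size();
  IntegerVector best_mm(nq), best_subject(nq), best_pos(nq);
  std::vector<std::string> subj(ns);
  for (int s = 0; s < ns; ++s) subj[s] = as<std::string>(subjects[s]);
  for (int q = 0; q < nq; ++q) {
    const std::string qs = as<std::string>(queries[q]);
    const int L = (int)qs.size();
    int best = L + 1, bs = NA_INTEGER, bp = NA_INTEGER;
    for (int s = 0; s < ns; ++s) {
      const std::string &S = subj[s];
      const int np = (int)S.size() - L;
      for (int p = 0; p <= np; ++p) {
        int mm = 0;
        for (int k = 0; k < L; ++k) {
          if (S[p + k] != qs[k] && ++mm >= best) break;
        }
        if (mm < best) {
          best = mm;
          bs = s + 1;
          bp = p;
          if (best == 0) break;
        }
      }
      if (best == 0) break;
    }
    best_mm[q] = (best > L) ? NA_INTEGER : best;
    best_subject[q] = bs;
    best_pos[q] = bp;
  }
  return DataFrame::create(_["best_mismatches"] = best_mm,
                           _["subject_index"] = best_subject,
                           _["position"] = best_pos);
}
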