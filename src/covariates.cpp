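#include <Rcpp.h>
using namespace Rcpp;

// Grid convention (stated once, used everywhere): origin (x0, y0) is the
// lower-left corner; cell (r, c) with 0-based indices has its center at
// x = x0 + (c + 0.5) * res, y = y0 + (nrow - r - 0.5) * res, i.e. row 0 is
// the top row of the matrix.

static inline void point_cell(double x, double y, double x0, double ytop,
                              double res, int nr, int nc, int &r, int &c) {
  c = (int)std::floor((x - x0) / res);
  r = (int)std::floor((ytop - y) / res);
  if (c < 0) c = 0;
  if (c >= nc) c = nc - 1;
  if (r < 0) r = 0;
  if (r >= nr) r = nr - 1;
}

// Exact Euclidean distance from arbitrary points to the nearest TRUE cell
// center, capped at `cap`. Ring (spiral) search: a cell at Chebyshev ring k
// around the query point's own cell has its center at least (k - 0.5) * res
// away from the point, so the scan can stop once that bound exceeds the
// best distance found.
// [[Rcpp::export]]
NumericVector dist_to_mask_cpp(NumericMatrix pts, LogicalMatrix mask,
                               double x0, double y0, double res, double cap) {
  const int nr = mask.nrow(), nc = mask.ncol(), n = pts.nrow();
  const double ytop = y0 + nr * res;
  const int kmax = (int)std::ceil(cap / res) + 1;
  NumericVector out(n);

  for (int i = 0; i < n; ++i) {
    const double x = pts(i, 0), y = pts(i, 1);
    int r0, c0;
    point_cell(x, y, x0, ytop, res, nr, nc, r0, c0);
    double best = cap;
    for (int k = 0; k <= kmax; ++k) {
      if ((k - 0.5) * res > best) break;
      const int rlo = r0 - k, rhi = r0 + k, clo = c0 - k, chi = c0 + k;
      for (int r = rlo; r <= rhi; ++r) {
        if (r < 0 || r >= nr) continue;
        const bool edge_row = (r == rlo || r == rhi);
        if (edge_row) {
          for (int c = std::max(clo, 0); c <= std::min(chi, nc - 1); ++c) {
            if (mask(r, c)) {
              const double dx = x - (x0 + (c + 0.5) * res);
              const double dy = y - (ytop - (r + 0.5) * res);
              const double d = std::sqrt(dx * dx + dy * dy);
              if (d < best) best = d;
            }
          }
        } else {
          for (int s = 0; s < 2; ++s) {
            const int c = s == 0 ? clo : chi;
            if (c < 0 || c >= nc || (s == 1 && chi == clo)) continue;
            if (mask(r, c)) {
              const double dx = x - (x0 + (c + 0.5) * res);
              const double dy = y - (ytop - (r + 0.5) * res);
              const double d = std::sqrt(dx * dx + dy * dy);
              if (d < best) best = d;
            }
          }
        }
      }
    }
    out[i] = best;
  }
  return out;
}

// Buffer counts for one mask: per point, number of TRUE cells and total
// number of in-extent cells whose centers fall within `radius` of the point.
// [[Rcpp::export]]
IntegerMatrix buffer_counts_cpp(NumericMatrix pts, LogicalMatrix mask,
                                double x0, double y0, double res,
                                double radius) {
  const int nr = mask.nrow(), nc = mask.ncol(), n = pts.nrow();
  const double ytop = y0 + nr * res, r2 = radius * radius;
  const int w = (int)std::ceil(radius / res) + 1;
  IntegerMatrix out(n, 2);

  for (int i = 0; i < n; ++i) {
    const double x = pts(i, 0), y = pts(i, 1);
    int r0, c0;
    point_cell(x, y, x0, ytop, res, nr, nc, r0, c0);
    int hit = 0, tot = 0;
    for (int r = std::max(r0 - w, 0); r <= std::min(r0 + w, nr - 1); ++r) {
      const double dy = y - (ytop - (r + 0.5) * res);
      for (int c = std::max(c0 - w, 0); c <= std::min(c0 + w, nc - 1); ++c) {
        const double dx = x - (x0 + (c + 0.5) * res);
        if (dx * dx + dy * dy <= r2) {
          ++tot;
          if (mask(r, c)) ++hit;
        }
      }
    }
    out(i, 0) = hit;
    out(i, 1) = tot;
  }
  return out;
}

// One-pass buffer counts over a coded cover grid plus overlay masks: returns
// per point the count of cells of each cover code (1..ncodes), the count of
// TRUE cells per overlay, and the total in-extent cells in the buffer.
// [[Rcpp::export]]
List cover_density_counts_cpp(NumericMatrix pts, IntegerMatrix cover,
                              int ncodes, List overlays, double x0, double y0,
                              double res, double radius) {
  const int nr = cover.nrow(), nc = cover.ncol(), n = pts.nrow();
  const int nov = overlays.size();
  const double ytop = y0 + nr * res, r2 = radius * radius;
  const int w = (int)std::ceil(radius / res) + 1;

  std::vector<LogicalMatrix> ov;
  for (int m = 0; m < nov; ++m) ov.push_back(as<LogicalMatrix>(overlays[m]));

  IntegerMatrix poly(n, ncodes), over(n, std::max(nov, 1));
  IntegerVector total(n);

  for (int i = 0; i < n; ++i) {
    const double x = pts(i, 0), y = pts(i, 1);
    int r0, c0;
    point_cell(x, y, x0, ytop, res, nr, nc, r0, c0);
    int tot = 0;
    for (int r = std::max(r0 - w, 0); r <= std::min(r0 + w, nr - 1); ++r) {
      const double dy = y - (ytop - (r + 0.5) * res);
      for (int c = std::max(c0 - w, 0); c <= std::min(c0 + w, nc - 1); ++c) {
        const double dx = x - (x0 + (c + 0.5) * res);
        if (dx * dx + dy * dy <= r2) {
          ++tot;
          const int code = cover(r, c);
          if (code >= 1 && code <= ncodes) ++poly(i, code - 1);
          for (int m = 0; m < nov; ++m)
            if (ov[m](r, c)) ++over(i, m);
        }
      }
    }
    total[i] = tot;
  }
  return List::create(_["poly"] = poly, _["overlay"] = over,
                      _["total"] = total);
}
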