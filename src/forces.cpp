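#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Forces histograms between the four tissue classes by angular line sweep.
//
// Conventions (shared with the pure-R oracle):
//  * 0-based row/col, origin top-left; x = col, y = -row (so +y is up);
//  * angle theta measured counter-clockwise from the +x axis;
//  * direction vector d = (drow, dcol) = (-sin theta, cos theta);
//  * digital lines: for |cos| >= |sin| a line is indexed by its
//    row-intercept b and holds pixels (b + round(s*c), c), s = drow/dcol;
//    otherwise by column-intercept with the roles of row/col swapped.
//    round(x) = floor(x + 0.5).  Every pixel is on exactly one line;
//  * position of a pixel along its line is the projection
//    t = c*cos(theta) - r*sin(theta); a pixel is "ahead" of another when
//    its t is larger;
//  * the histogram for the ordered pair (i, j) at angle theta accumulates
//    1/d^2 over pixel pairs with the region-i pixel ahead of the region-j
//    pixel, d the projection distance.

static inline int iround(double x) {
  return (int)std::floor(x + 0.5);
}

// Accumulate all 16 ordered label-pair histograms in one pass.
// labels: integer matrix with 0 = outside, 1..4 = tissue classes.
// Returns a 16 x a matrix; row index (li-1)*4 + (lj-1) is the force with
// the region-li pixel ahead of the region-lj pixel.
// [[Rcpp::export(name = ".fh_all_pairs_cpp")]]
NumericMatrix fh_all_pairs_cpp(IntegerMatrix labels, int a) {
  const int nr = labels.nrow(), nc = labels.ncol();
  NumericMatrix H(16, a);
  const double two_pi = 2.0 * M_PI;

  std::vector<double> tbuf;
  std::vector<int> lbuf;
  std::vector<int> line_start;

  for (int k = 0; k < a; ++k) {
    const double theta = two_pi * k / a;
    const double ct = std::cos(theta), st = std::sin(theta);
    const double drow = -st, dcol = ct;
    const bool byCol = std::fabs(dcol) >= std::fabs(drow);

    // collect pixels per line, appended in increasing-t order
    // (the parameter axis is scanned in the direction of travel)
    int npar = byCol ? nc : nr;   // parameter axis length
    int nsec = byCol ? nr : nc;   // secondary axis length
    double s = byCol ? (drow / dcol) : (dcol / drow);

    // line id b = sec - round(s * par); range of b:
    int ro_min = 0, ro_max = 0;
    std::vector<int> ro(npar);
    for (int p = 0; p < npar; ++p) {
      ro[p] = iround(s * p);
      if (ro[p] < ro_min) ro_min = ro[p];
      if (ro[p] > ro_max) ro_max = ro[p];
    }
    int bmin = 0 - ro_max, bmax = (nsec - 1) - ro_min;
    int nlines = bmax - bmin + 1;
    if (nlines <= 0) continue;

    // bucket sizes, then fill (counting sort by line id, keeping
    // parameter order within each line)
    std::vector<int> cnt(nlines, 0);
    bool fwd = byCol ? (dcol > 0) : (drow > 0);
    for (int step = 0; step < npar; ++step) {
      int p = fwd ? step : (npar - 1 - step);
      int r0 = ro[p];
      for (int sidx = 0; sidx < nsec; ++sidx) {
        int r = byCol ? sidx : p;
        int c = byCol ? p : sidx;
        if (labels(r, c) > 0) cnt[sidx - r0 - bmin]++;
      }
    }
    line_start.assign(nlines + 1, 0);
    for (int b = 0; b < nlines; ++b) line_start[b + 1] = line_start[b] + cnt[b];
    int ntot = line_start[nlines];
    tbuf.assign(ntot, 0.0);
    lbuf.assign(ntot, 0);
    std::vector<int> fill(nlines, 0);
    for (int step = 0; step < npar; ++step) {
      int p = fwd ? step : (npar - 1 - step);
      int r0 = ro[p];
      for (int sidx = 0; sidx < nsec; ++sidx) {
        int r = byCol ? sidx : p;
        int c = byCol ? p : sidx;
        int lab = labels(r, c);
        if (lab <= 0) continue;
        int b = sidx - r0 - bmin;
        int pos = line_start[b] + fill[b]++;
        tbuf[pos] = c * ct - r * st;
        lbuf[pos] = lab;
      }
    }

    // per line: all ordered pairs, later (larger t) pixel is ahead
    double *Hk = &H(0, k);
    for (int b = 0; b < nlines; ++b) {
      int lo = line_start[b], hi = line_start[b + 1];
      for (int jj = lo + 1; jj < hi; ++jj) {
        const double tj = tbuf[jj];
        const int ahead = (lbuf[jj] - 1) * 4;
        for (int ii = lo; ii < jj; ++ii) {
          const double d = tj - tbuf[ii];
          Hk[ahead + (lbuf[ii] - 1)] += 1.0 / (d * d);
        }
      }
    }
  }
  return H;
}
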