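// Semi-global block matching core: SAD block cost volume, multi-direction
// dynamic-programming path aggregation, and winner-take-all disparity
// selection with uniqueness / left-right validity checks and parabolic
// sub-pixel refinement. All arithmetic on costs is integer so results are
// exactly reproducible (and comparable pixel-for-pixel against a plain-R
// reference on small instances).

#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

static inline int block_lo(int block) { return -((block - 1) / 2); }
static inline int block_hi(int block) { return block / 2; }

// Cost volume dimensioned [H, W, D], d = dmin + di. A candidate whose
// matching x-coordinate falls off the right image gets a sentinel cost of
// block^2 * 255 + 1 (worse than any achievable SAD over the block).
// [[Rcpp::export]]
IntegerVector sgm_cost_volume_cpp(IntegerMatrix left, IntegerMatrix right,
                                  int dmin, int dmax, int block) {
  const int H = left.nrow(), W = left.ncol();
  if (right.nrow() != H || right.ncol() != W)
    stop("left/right image size mismatch");
  if (block < 1) stop("block size must be >= 1");
  if (dmax < dmin || dmin < 0) stop("invalid disparity range");
  const int D = dmax - dmin + 1;
  const int lo = block_lo(block), hi = block_hi(block);
  const int sentinel = block * block * 255 + 1;

  IntegerVector out(static_cast<R_xlen_t>(H) * W * D);
  // integral image of |L - shifted R| per disparity; excluded cells are 0
  std::vector<int64_t> sat(static_cast<size_t>(H + 1) * (W + 1));
  auto SAT = [&](int y, int x) -> int64_t & {
    return sat[static_cast<size_t>(y) * (W + 1) + x];
  };

  for (int di = 0; di < D; ++di) {
    const int d = dmin + di;
    for (int y = 0; y <= H; ++y) SAT(y, 0) = 0;
    for (int x = 0; x <= W; ++x) SAT(0, x) = 0;
    for (int y = 1; y <= H; ++y) {
      for (int x = 1; x <= W; ++x) {
        int ad = 0;
        if (x - 1 - d >= 0)
          ad = std::abs(left(y - 1, x - 1) - right(y - 1, x - 1 - d));
        SAT(y, x) = ad + SAT(y - 1, x) + SAT(y, x - 1) - SAT(y - 1, x - 1);
      }
    }
    for (int x = 0; x < W; ++x) {
      const bool feasible = (x - d) >= 0;
      const int x0 = std::max(0, x + lo), x1 = std::min(W - 1, x + hi);
      for (int y = 0; y < H; ++y) {
        int64_t c;
        if (!feasible) {
          c = sentinel;
        } else {
          const int y0 = std::max(0, y + lo), y1 = std::min(H - 1, y + hi);
          c = SAT(y1 + 1, x1 + 1) - SAT(y0, x1 + 1) - SAT(y1 + 1, x0) +
              SAT(y0, x0);
        }
        out[static_cast<R_xlen_t>(di) * H * W +
            static_cast<R_xlen_t>(x) * H + y] = static_cast<int>(c);
      }
    }
  }
  out.attr("dim") = IntegerVector::create(H, W, D);
  return out;
}

// Per-pixel block texture statistic: standard deviation of the left image
// over the same truncated window as the cost. Textureless open-water
// blocks have no matchable signal (their deviation is just the sensor
// noise sigma); thresholding this statistic invalidates them regardless
// of how confidently the smoothness term fills them in.
// [[Rcpp::export]]
NumericMatrix sgm_texture_cpp(IntegerMatrix left, int block) {
  const int H = left.nrow(), W = left.ncol();
  const int lo = block_lo(block), hi = block_hi(block);
  std::vector<int64_t> s1(static_cast<size_t>(H + 1) * (W + 1), 0);
  std::vector<int64_t> s2(static_cast<size_t>(H + 1) * (W + 1), 0);
  auto at = [&](std::vector<int64_t> &s, int y, int x) -> int64_t & {
    return s[static_cast<size_t>(y) * (W + 1) + x];
  };
  for (int y = 1; y <= H; ++y)
    for (int x = 1; x <= W; ++x) {
      const int64_t v = left(y - 1, x - 1);
      at(s1, y, x) = v + at(s1, y - 1, x) + at(s1, y, x - 1) -
                     at(s1, y - 1, x - 1);
      at(s2, y, x) = v * v + at(s2, y - 1, x) + at(s2, y, x - 1) -
                     at(s2, y - 1, x - 1);
    }
  NumericMatrix out(H, W);
  for (int y = 0; y < H; ++y) {
    const int y0 = std::max(0, y + lo), y1 = std::min(H - 1, y + hi);
    for (int x = 0; x < W; ++x) {
      const int x0 = std::max(0, x + lo), x1 = std::min(W - 1, x + hi);
      const double n = (y1 - y0 + 1) * (x1 - x0 + 1);
      const double sum1 = static_cast<double>(
          at(s1, y1 + 1, x1 + 1) - at(s1, y0, x1 + 1) - at(s1, y1 + 1, x0) +
          at(s1, y0, x0));
      const double sum2 = static_cast<double>(
          at(s2, y1 + 1, x1 + 1) - at(s2, y0, x1 + 1) - at(s2, y1 + 1, x0) +
          at(s2, y0, x0));
      const double var = sum2 / n - (sum1 / n) * (sum1 / n);
      out(y, x) = std::sqrt(var > 0 ? var : 0);
    }
  }
  return out;
}

// One scan direction (dy, dx): predecessor of p is p - (dy, dx).
// `C` and `agg` use the internal disparity-contiguous layout
// idx = (y * W + x) * D + d so the inner recurrence streams through cache.
static void aggregate_dir(const int *C, int64_t *agg, int H, int W, int D,
                          int P1, int P2, int dy, int dx) {
  std::vector<int> L(static_cast<size_t>(H) * W * D);
  const int ys = dy >= 0 ? 0 : H - 1, ye = dy >= 0 ? H : -1,
            yi = dy >= 0 ? 1 : -1;
  const int xs = dx >= 0 ? 0 : W - 1, xe = dx >= 0 ? W : -1,
            xi = dx >= 0 ? 1 : -1;
  for (int y = ys; y != ye; y += yi) {
    for (int x = xs; x != xe; x += xi) {
      const size_t at = (static_cast<size_t>(y) * W + x) * D;
      const int py = y - dy, px = x - dx;
      if (py < 0 || py >= H || px < 0 || px >= W) {
        for (int d = 0; d < D; ++d) L[at + d] = C[at + d];
      } else {
        const int *Lp = L.data() + (static_cast<size_t>(py) * W + px) * D;
        int minprev = Lp[0];
        for (int d = 1; d < D; ++d) minprev = std::min(minprev, Lp[d]);
        const int cap = minprev + P2;
        for (int d = 0; d < D; ++d) {
          int best = Lp[d];
          if (d > 0) best = std::min(best, Lp[d - 1] + P1);
          if (d < D - 1) best = std::min(best, Lp[d + 1] + P1);
          best = std::min(best, cap);
          L[at + d] = C[at + d] + best - minprev;
        }
      }
    }
  }
  for (size_t i = 0; i < L.size(); ++i) agg[i] += L[i];
}

// [H, W, D] R array -> internal d-contiguous layout and back.
static std::vector<int> to_dfast(const int *v, int H, int W, int D) {
  std::vector<int> out(static_cast<size_t>(H) * W * D);
  for (int d = 0; d < D; ++d)
    for (int x = 0; x < W; ++x) {
      const int *src = v + (static_cast<size_t>(d) * W + x) * H;
      for (int y = 0; y < H; ++y)
        out[(static_cast<size_t>(y) * W + x) * D + d] = src[y];
    }
  return out;
}

// [[Rcpp::export]]
IntegerVector sgm_aggregate_cpp(IntegerVector cost, int P1, int P2,
                                int n_paths) {
  IntegerVector dim = cost.attr("dim");
  const int H = dim[0], W = dim[1], D = dim[2];
  if (!(P2 > P1 && P1 > 0)) stop("require P2 > P1 > 0");
  if (n_paths != 4 && n_paths != 8) stop("n_paths must be 4 or 8");
  static const int dirs[8][2] = {{0, 1},  {0, -1}, {1, 0},  {-1, 0},
                                 {1, 1},  {1, -1}, {-1, 1}, {-1, -1}};
  std::vector<int> vol = to_dfast(INTEGER(cost), H, W, D);
  std::vector<int64_t> agg(vol.size(), 0);
  for (int r = 0; r < n_paths; ++r)
    aggregate_dir(vol.data(), agg.data(), H, W, D, P1, P2, dirs[r][0],
                  dirs[r][1]);
  IntegerVector out(static_cast<R_xlen_t>(H) * W * D);
  int *o = INTEGER(out);
  for (int d = 0; d < D; ++d)
    for (int x = 0; x < W; ++x)
      for (int y = 0; y < H; ++y)
        o[(static_cast<size_t>(d) * W + x) * H + y] =
            static_cast<int>(agg[(static_cast<size_t>(y) * W + x) * D + d]);
  out.attr("dim") = dim;
  return out;
}

// Winner-take-all selection. Ties break to the lowest disparity. A pixel is
// invalid when no candidate is feasible (x - d < 0 for all d), when it
// fails the uniqueness ratio (some non-adjacent candidate is within
// uniqueness_pct percent of the minimum), or when the left-right
// consistency check (optional) disagrees by more than 1 px.
// [[Rcpp::export]]
List sgm_wta_cpp(IntegerVector agg, int dmin, int uniqueness_pct,
                 bool subpixel, bool lr_check) {
  IntegerVector dim = agg.attr("dim");
  const int H = dim[0], W = dim[1], D = dim[2];
  const int *A = INTEGER(agg);
  auto AV = [&](int y, int x, int d) {
    return A[static_cast<size_t>(d) * H * W + static_cast<size_t>(x) * H + y];
  };
  NumericMatrix values(H, W);
  LogicalMatrix valid(H, W);
  IntegerMatrix ibest(H, W);
  std::fill(values.begin(), values.end(), NA_REAL);
  std::fill(ibest.begin(), ibest.end(), NA_INTEGER);

  // right-view argmin map for the consistency check
  IntegerMatrix rbest;
  if (lr_check) {
    rbest = IntegerMatrix(H, W);
    std::fill(rbest.begin(), rbest.end(), NA_INTEGER);
    for (int y = 0; y < H; ++y) {
      for (int xr = 0; xr < W; ++xr) {
        int bd = NA_INTEGER;
        int64_t bc = 0;
        for (int di = 0; di < D; ++di) {
          const int xl = xr + dmin + di;
          if (xl >= W) break;
          const int64_t c = AV(y, xl, di);
          if (bd == NA_INTEGER || c < bc) { bd = di; bc = c; }
        }
        rbest(y, xr) = bd;
      }
    }
  }

  for (int y = 0; y < H; ++y) {
    for (int x = 0; x < W; ++x) {
      int nfeas = x - dmin + 1;  // candidates with x - d >= 0
      if (nfeas > D) nfeas = D;
      if (nfeas < 1) continue;
      int bd = 0;
      int64_t bc = AV(y, x, 0);
      for (int di = 1; di < nfeas; ++di) {
        const int64_t c = AV(y, x, di);
        if (c < bc) { bc = c; bd = di; }
      }
      bool ok = true;
      if (uniqueness_pct > 0) {
        for (int di = 0; di < nfeas && ok; ++di) {
          if (di >= bd - 1 && di <= bd + 1) continue;
          if (static_cast<int64_t>(AV(y, x, di)) * 100 <=
              bc * (100 + uniqueness_pct))
            ok = false;
        }
        // a lone candidate offers no evidence of a unique match
        if (nfeas <= 1) ok = false;
      }
      if (ok && lr_check) {
        const int xr = x - (dmin + bd);
        const int rb = rbest(y, xr);
        if (rb == NA_INTEGER || std::abs(rb - bd) > 1) ok = false;
      }
      if (!ok) continue;
      double dval = dmin + bd;
      if (subpixel && bd > 0 && bd < nfeas - 1) {
        const double cm = AV(y, x, bd - 1), c0 = bc, cp = AV(y, x, bd + 1);
        const double denom = cm + cp - 2.0 * c0;
        if (denom > 0) dval += (cm - cp) / (2.0 * denom);
      }
      values(y, x) = dval;
      valid(y, x) = true;
      ibest(y, x) = dmin + bd;
    }
  }
  return List::create(_["values"] = values, _["valid"] = valid,
                      _["integer_disparity"] = ibest);
}
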