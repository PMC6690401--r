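#include <Rcpp.h>
using namespace Rcpp;

// Sequential placement of square dots on a pair of id rasters.
//
// Coordinates are 1-based on the R side; internally 0-based. A dot occupies
// a k x k square whose top-left corner is the dot position; footprints are
// clipped at the image borders. Positions are drawn from R's global RNG
// (unif_rand) so that set.seed() on the R side makes placement reproducible.

static inline int draw_pos(int n) {
  int v = (int)(unif_rand() * n);
  if (v >= n) v = n - 1;
  return v;
}

static inline bool region_occupied(const IntegerMatrix &id, int H, int W,
                                   int r1, int r2, int c1, int c2) {
  if (c1 < 0) c1 = 0;
  if (c2 > W - 1) c2 = W - 1;
  if (r1 < 0) r1 = 0;
  if (r2 > H - 1) r2 = H - 1;
  if (c1 > c2 || r1 > r2) return false;
  for (int c = c1; c <= c2; ++c)
    for (int r = r1; r <= r2; ++r)
      if (id(r, c) != 0) return true;
  return false;
}

static inline void stamp(IntegerMatrix &id, int H, int W,
                         int r1, int r2, int c1, int c2, int val) {
  if (c1 < 0) c1 = 0;
  if (c2 > W - 1) c2 = W - 1;
  if (r1 < 0) r1 = 0;
  if (r2 > H - 1) r2 = H - 1;
  if (c1 > c2 || r1 > r2) return;
  for (int c = c1; c <= c2; ++c)
    for (int r = r1; r <= r2; ++r)
      id(r, c) = val;
}

static inline void clear_id(IntegerMatrix &id, int H, int W, int val) {
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r)
      if (id(r, c) == val) id(r, c) = 0;
}

// [[Rcpp::export]]
List place_dots_cpp(int W, int H, int k,
                    IntegerVector sl, IntegerVector sr,
                    LogicalVector dec,
                    bool no_overlap, bool check_nominal,
                    bool dec_check_both, int cap) {
  int N = sl.size();
  IntegerMatrix idL(H, W), idR(H, W);
  // nominal-position occupancy map, used only when check_nominal = TRUE
  IntegerMatrix idN(check_nominal ? H : 1, check_nominal ? W : 1);
  IntegerVector x(N), y(N);
  int ndec = 0;
  for (int i = 0; i < N; ++i) if (dec[i]) ++ndec;
  IntegerVector xl(ndec), yl(ndec), xr(ndec), yr(ndec);

  // Pass 1: correlated dots. In Overlap mode, decorrelated slots draw
  // independent positions per eye at their original place in the drawing
  // order, so the per-eye images remain an i.i.d. dot sequence.
  int placed = 0;
  for (int i = 0; i < N; ++i) {
    if (dec[i] && !no_overlap) {
      // handled in this pass: independent per-eye draws, no rejection
      int j = 0;
      for (int q = 0; q < i; ++q) if (dec[q]) ++j;
      int px = draw_pos(W), py = draw_pos(H);
      stamp(idL, H, W, py, py + k - 1, px, px + k - 1, i + 1);
      xl[j] = px + 1; yl[j] = py + 1;
      px = draw_pos(W); py = draw_pos(H);
      stamp(idR, H, W, py, py + k - 1, px, px + k - 1, N + j + 1);
      xr[j] = px + 1; yr[j] = py + 1;
      x[i] = NA_INTEGER; y[i] = NA_INTEGER;
      ++placed;
      continue;
    }
    int fails = 0;
    for (;;) {
      int px = draw_pos(W), py = draw_pos(H);
      int r1 = py, r2 = py + k - 1;
      int lc1 = px + sl[i], lc2 = lc1 + k - 1;
      int rc1 = px + sr[i], rc2 = rc1 + k - 1;
      bool ok = true;
      if (no_overlap) {
        if (check_nominal) {
          ok = !region_occupied(idN, H, W, r1, r2, px, px + k - 1);
        } else {
          ok = !region_occupied(idL, H, W, r1, r2, lc1, lc2) &&
               !region_occupied(idR, H, W, r1, r2, rc1, rc2);
        }
      }
      if (ok) {
        stamp(idL, H, W, r1, r2, lc1, lc2, i + 1);
        stamp(idR, H, W, r1, r2, rc1, rc2, i + 1);
        if (check_nominal) stamp(idN, H, W, r1, r2, px, px + k - 1, i + 1);
        x[i] = px + 1; y[i] = py + 1;
        ++placed;
        break;
      }
      if (++fails >= cap)
        stop("dot packing infeasible: %d consecutive rejected placements after %d of %d dots (achieved density %.3f)",
             cap, placed, N, (double)placed * k * k / ((double)W * H));
    }
  }

  // Passes 2-3 (No-overlap decorrelation): remove the selected correlated
  // dots, then re-place one independent dot per eye with rejection.
  if (no_overlap && ndec > 0) {
    int j = 0;
    for (int i = 0; i < N; ++i) {
      if (!dec[i]) continue;
      clear_id(idL, H, W, i + 1);
      clear_id(idR, H, W, i + 1);
      if (check_nominal) clear_id(idN, H, W, i + 1);
      ++j;
    }
    j = 0;
    for (int i = 0; i < N; ++i) {
      if (!dec[i]) continue;
      // left-eye replacement (id = slot index), then right-eye (id = N + j + 1)
      for (int eye = 0; eye < 2; ++eye) {
        int fails = 0;
        for (;;) {
          int px = draw_pos(W), py = draw_pos(H);
          int r1 = py, r2 = py + k - 1, c1 = px, c2 = px + k - 1;
          IntegerMatrix &own = (eye == 0) ? idL : idR;
          IntegerMatrix &oth = (eye == 0) ? idR : idL;
          bool ok = !region_occupied(own, H, W, r1, r2, c1, c2);
          if (ok && dec_check_both)
            ok = !region_occupied(oth, H, W, r1, r2, c1, c2);
          if (ok) {
            stamp(own, H, W, r1, r2, c1, c2, eye == 0 ? i + 1 : N + j + 1);
            if (eye == 0) { xl[j] = px + 1; yl[j] = py + 1; }
            else          { xr[j] = px + 1; yr[j] = py + 1; }
            break;
          }
          if (++fails >= cap)
            stop("dot packing infeasible while re-placing decorrelated dots (cap %d reached)", cap);
        }
      }
      x[i] = NA_INTEGER; y[i] = NA_INTEGER;
      ++j;
    }
  }

  return List::create(_["left_ids"] = idL, _["right_ids"] = idR,
                      _["x"] = x, _["y"] = y,
                      _["xl"] = xl, _["yl"] = yl,
                      _["xr"] = xr, _["yr"] = yr);
}
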