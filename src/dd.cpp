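// Double description method for pointed cones
//   { x in R^n : x >= 0, E x = 0, D x >= 0 }
// with exact integer arithmetic: rays are gcd-reduced int64 vectors and all
// products/combinations run in 128-bit intermediates with overflow checks,
// so results are exact or the computation aborts loudly. Adjacency of rays
// is decided combinatorially from tight-constraint sets (valid here because
// the cone is pointed: it is a subset of the nonnegative orthant, and the
// ray list is maintained as the exact extreme-ray set at every step); a
// rank-based cardinality pre-filter keeps the pair loop fast.
#include <Rcpp.h>
#include <vector>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

namespace {

typedef long long i64;
typedef __int128 i128;

const double DOUBLE_SAFE = 9007199254740992.0; // 2^53

i64 gcd2(i64 a, i64 b) {
  if (a < 0) a = -a;
  if (b < 0) b = -b;
  while (b) { i64 t = b; b = a % b; a = t; }
  return a;
}

// entries kept below 2^62 so 128-bit combinations can never wrap
const i128 I64_LIMIT = ((i128)1) << 62;

// reduce an int128 vector by its gcd and store into int64, checking range
void reduceStore(const std::vector<i128> &w, std::vector<i64> &out) {
  i128 g = 0;
  for (i128 x : w) {
    if (x != 0) {
      i128 a = g, b = x < 0 ? -x : x;
      while (b) { i128 t = b; b = a % b; a = t; }
      g = a;
    }
    if (g == 1) break;
  }
  out.resize(w.size());
  for (size_t j = 0; j < w.size(); ++j) {
    i128 v = w[j];
    if (g > 1) v /= g;
    if (v >= I64_LIMIT || v <= -I64_LIMIT)
      Rcpp::stop("exact integer arithmetic overflow in double description");
    out[j] = (i64)v;
  }
}

typedef std::vector<uint64_t> Bits;

inline void setBit(Bits &b, int i) { b[i >> 6] |= (uint64_t(1) << (i & 63)); }

inline bool subsetOf(const Bits &a, const Bits &b) {
  for (size_t w = 0; w < a.size(); ++w)
    if (a[w] & ~b[w]) return false;
  return true;
}

// numeric rank of the ray matrix (rows = rays), Gaussian elimination with
// partial pivoting on max-norm-scaled rows
int rankOfRays(const std::vector<std::vector<i64> > &rays, int n) {
  int R = (int)rays.size();
  if (R == 0) return 0;
  std::vector<std::vector<double> > M;
  M.reserve(R);
  for (int r = 0; r < R; ++r) {
    double mx = 0.0;
    for (int j = 0; j < n; ++j)
      mx = std::max(mx, std::fabs((double)rays[r][j]));
    if (mx == 0.0) continue;
    std::vector<double> row(n);
    for (int j = 0; j < n; ++j) row[j] = (double)rays[r][j] / mx;
    M.push_back(row);
  }
  R = (int)M.size();
  int rank = 0;
  std::vector<bool> used(R, false);
  for (int col = 0; col < n && rank < R; ++col) {
    int piv = -1; double best = 1e-9;
    for (int r = 0; r < R; ++r)
      if (!used[r] && std::fabs(M[r][col]) > best) {
        best = std::fabs(M[r][col]); piv = r;
      }
    if (piv < 0) continue;
    used[piv] = true; ++rank;
    for (int r = 0; r < R; ++r) {
      if (r == piv || std::fabs(M[r][col]) < 1e-12) continue;
      double f = M[r][col] / M[piv][col];
      for (int j = col; j < n; ++j) M[r][j] -= f * M[piv][j];
    }
  }
  return rank;
}

} // namespace

// cons: rows are constraints over n coords (integer-valued); isEq[i] = 1 for
// equality rows. Rows are processed in the given order. Returns extreme rays.
// [[Rcpp::export(name = ".ddCore")]]
List ddCore(NumericMatrix cons, IntegerVector isEq, int n, double maxRays) {
  int nc = cons.nrow();
  int nIneq = 0;
  for (int i = 0; i < nc; ++i) if (!isEq[i]) ++nIneq;
  int nbits = n + nIneq;
  int nwords = (nbits + 63) / 64;

  std::vector<std::vector<i64> > A(nc, std::vector<i64>(n));
  for (int i = 0; i < nc; ++i)
    for (int j = 0; j < n; ++j) {
      double v = cons(i, j);
      if (std::fabs(v) >= DOUBLE_SAFE) stop("constraint coefficient overflow");
      A[i][j] = (i64)v;
    }

  std::vector<std::vector<i64> > rays(n);
  std::vector<Bits> tight(n);
  for (int j = 0; j < n; ++j) {
    rays[j].assign(n, 0);
    rays[j][j] = 1;
    tight[j].assign(nwords, 0);
    for (int k = 0; k < n; ++k) if (k != j) setBit(tight[j], k);
  }
  int ineqSeen = 0;
  bool truncated = false;

  for (int ci = 0; ci < nc && !truncated; ++ci) {
    Rcpp::checkUserInterrupt();
    bool eq = isEq[ci] != 0;
    int R = (int)rays.size();
    std::vector<i128> s(R);
    bool anyPos = false, anyNeg = false;
    for (int r = 0; r < R; ++r) {
      i128 acc = 0;
      for (int j = 0; j < n; ++j)
        acc += (i128)A[ci][j] * (i128)rays[r][j];
      s[r] = acc;
      if (acc > 0) anyPos = true;
      else if (acc < 0) anyNeg = true;
    }
    int tbit = eq ? -1 : (n + ineqSeen);
    if (!eq) ++ineqSeen;
    if (!anyPos && !anyNeg) {
      if (!eq) for (int r = 0; r < R; ++r) setBit(tight[r], tbit);
      continue;
    }

    std::vector<int> pos, neg, zer;
    for (int r = 0; r < R; ++r) {
      if (s[r] > 0) pos.push_back(r);
      else if (s[r] < 0) neg.push_back(r);
      else zer.push_back(r);
    }

    int dim = rankOfRays(rays, n);

    std::vector<std::vector<i64> > newRays;
    std::vector<Bits> newTight;
    for (int r : zer) {
      newRays.push_back(rays[r]);
      Bits b = tight[r];
      if (!eq) setBit(b, tbit);
      newTight.push_back(b);
    }
    if (!eq) {
      for (int r : pos) {
        newRays.push_back(rays[r]);
        newTight.push_back(tight[r]);
      }
    }

    std::vector<i128> comb(n);
    std::vector<i64> vred;
    for (int p : pos) {
      for (int q : neg) {
        Bits common(nwords);
        int cnt = 0;
        for (int w = 0; w < nwords; ++w) {
          common[w] = tight[p][w] & tight[q][w];
#if defined(__GNUC__) || defined(__clang__)
          cnt += __builtin_popcountll(common[w]);
#else
          uint64_t x = common[w]; while (x) { x &= x - 1; ++cnt; }
#endif
        }
        if (cnt < dim - 2) continue;
        bool adjacent = true;
        for (int r = 0; r < R; ++r) {
          if (r == p || r == q) continue;
          if (subsetOf(common, tight[r])) { adjacent = false; break; }
        }
        if (!adjacent) continue;
        // combine: (-s_q) * ray_p + s_p * ray_q, both multipliers positive;
        // reduce multipliers by their gcd first to limit growth
        i128 a = s[p], b = -s[q];
        {
          i128 x = a, y = b;
          while (y) { i128 t = y; y = x % y; x = t; }
          if (x > 1) { a /= x; b /= x; }
        }
        if (a >= I64_LIMIT || b >= I64_LIMIT)
          stop("exact integer arithmetic overflow in double description");
        for (int j = 0; j < n; ++j)
          comb[j] = b * (i128)rays[p][j] + a * (i128)rays[q][j];
        reduceStore(comb, vred);
        Bits tb(nwords);
        for (int j = 0; j < n; ++j) if (vred[j] == 0) setBit(tb, j);
        for (int w = 0; w < nwords; ++w) tb[w] |= common[w];
        if (!eq) setBit(tb, tbit);
        newRays.push_back(vred);
        newTight.push_back(tb);
        if ((double)newRays.size() > maxRays) { truncated = true; break; }
      }
      if (truncated) break;
    }
    rays.swap(newRays);
    tight.swap(newTight);
    if (rays.empty()) break;
  }

  NumericMatrix out((int)rays.size(), n);
  for (size_t r = 0; r < rays.size(); ++r)
    for (int j = 0; j < n; ++j) {
      double v = (double)rays[r][j];
      if (std::fabs(v) >= DOUBLE_SAFE)
        stop("ray coefficient exceeds exact double range");
      out(r, j) = v;
    }
  return List::create(_["rays"] = out, _["truncated"] = truncated);
}
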