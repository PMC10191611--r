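// Bitvector approximate-string-matching core.
//
// Conventions (shared with the R layer, see R/core.R):
//  * A bitvector of width m covers pattern positions j = 0..m-1 with j = 0
//    at the MOST significant position. In a uint64_t, bit j lives at machine
//    bit (m-1-j), so a machine left shift moves bit j+1 into bit j and fills
//    the vacated j = m-1 position with 0, truncated to m bits.
//  * The DP table R has k+1 rows (edit counts d = 0..k, k fixed to the
//    window size W) and n+1 columns (text offsets i = 0..n, column n being
//    the boundary column). Bit j of R[d][i] is 0 iff some prefix of
//    text[i:n) is within d edits of pattern[j:m).
//  * Storage modes: 0 = edges (I, D, M per cell; S regenerable as D<<1),
//    1 = entries (ANDed entry per cell), 2 = entries-dent (entry bits
//    j <= W-O for columns i <= W-O only). Traffic counters count exactly
//    the bits crossing the store boundary; the forefront rows held in local
//    arrays ("registers") are not counted.

#include <Rcpp.h>
#include <cstdint>
#include <string>
#include <vector>
#include <algorithm>

using namespace Rcpp;

static const int MAXW = 64;

static inline uint64_t ones_w(int w) {
  return w >= 64 ? ~0ULL : ((1ULL << w) - 1ULL);
}
static inline uint64_t shl_w(uint64_t x, int w) {
  if (w == 0) return 0;
  return (x << 1) & ones_w(w);
}
static inline int bit_w(uint64_t x, int w, int j) {
  return (int)((x >> (w - 1 - j)) & 1ULL);
}
// bit j is 0 exactly when m - j <= d: the d least significant bits are 0
static uint64_t boundary_w(int d, int m) {
  if (m == 0) return 0;
  if (d >= m) return 0;
  return ones_w(m) & ~((1ULL << d) - 1ULL);
}

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return 4; // ambiguous: matches nothing
  }
}

static std::vector<int> encode(const std::string& s) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = base_code(s[i]);
  return v;
}

// masks[c] has bit i == 0 exactly where pattern[i] encodes c; masks[4] is
// the all-ones catch-all so ambiguous characters never match.
static void pattern_masks(const std::vector<int>& pc, int m, uint64_t pm[5]) {
  for (int c = 0; c < 5; ++c) pm[c] = ones_w(m);
  for (int i = 0; i < m; ++i) {
    int c = pc[i];
    if (c < 4) pm[c] &= ~(1ULL << (m - 1 - i));
  }
}

struct Win {
  int n = 0, m = 0, W = 0, O = 0, k = 0, mode = 1;
  bool et = true;
  std::vector<int> tc, pc;
  uint64_t pm[5];
  int cols = 0, bstore = 0;
  std::vector<uint64_t> ent, eI, eD, eM;
  std::vector<uint64_t> rowvals; // full-width computed rows, row-major
  int d_opt = -1, rows_computed = 0;
  long long bits_written = 0, cells_written = 0, bits_read = 0;

  long long capacity_bits() const {
    long long per = (mode == 0) ? 3LL * m : (long long)bstore;
    return (long long)(k + 1) * cols * per;
  }
};

static void win_setup(Win& w, const std::vector<int>& tc, const std::vector<int>& pc,
                      int W, int O, int mode, bool et) {
  if (W < 1 || W > MAXW) stop("window size W must be in [1, 64]");
  if (O < 0 || O >= W) stop("window overlap O must satisfy 0 <= O < W");
  if ((int)tc.size() > W || (int)pc.size() > W)
    stop("window sequences must not exceed W characters");
  w.tc = tc; w.pc = pc;
  w.n = (int)tc.size(); w.m = (int)pc.size();
  w.W = W; w.O = O; w.k = W; w.mode = mode; w.et = et;
  pattern_masks(w.pc, w.m, w.pm);
  if (mode == 2) {
    w.cols = std::min(w.n, W - O) + 1;
    w.bstore = std::min(w.m, W - O + 1);
  } else {
    w.cols = w.n + 1;
    w.bstore = w.m;
  }
  if (mode == 0) {
    size_t sz = (size_t)(w.k + 1) * (w.n + 1);
    w.eI.assign(sz, 0); w.eD.assign(sz, 0); w.eM.assign(sz, 0);
  } else {
    w.ent.assign((size_t)(w.k + 1) * w.cols, 0);
  }
}

static void win_store(Win& w, int d, int i, uint64_t entry,
                      uint64_t I, uint64_t D, uint64_t M) {
  if (w.mode == 0) {
    size_t idx = (size_t)d * (w.n + 1) + i;
    w.eI[idx] = I; w.eD[idx] = D; w.eM[idx] = M;
    w.bits_written += 3LL * w.m; w.cells_written++;
  } else if (w.mode == 1) {
    w.ent[(size_t)d * (w.n + 1) + i] = entry;
    w.bits_written += w.m; w.cells_written++;
  } else {
    if (i < w.cols) {
      w.ent[(size_t)d * w.cols + i] =
        (w.bstore == w.m) ? entry : (entry >> (w.m - w.bstore));
      w.bits_written += w.bstore; w.cells_written++;
    }
  }
}

static void win_fill(Win& w) {
  const int n = w.n, m = w.m, k = w.k;
  const uint64_t ones = ones_w(m);
  w.rowvals.clear();
  w.rowvals.reserve((size_t)(k + 1) * (n + 1));
  if (m == 0) { // width-0 bitvectors: the empty pattern is reachable at cost 0
    for (int i = n; i >= 0; --i) win_store(w, 0, i, 0, 0, 0, 0);
    for (int i = 0; i <= n; ++i) w.rowvals.push_back(0);
    w.rows_computed = 1; w.d_opt = 0;
    return;
  }
  std::vector<uint64_t> prev(n + 1), cur(n + 1);
  // row d = 0: match-only, seeded from the boundary column
  cur[n] = boundary_w(0, m);
  win_store(w, 0, n, cur[n], ones, ones, ones);
  for (int i = n - 1; i >= 0; --i) {
    uint64_t M0 = shl_w(cur[i + 1], m) | w.pm[w.tc[i]];
    cur[i] = M0;
    win_store(w, 0, i, M0, ones, ones, M0);
  }
  for (int i = 0; i <= n; ++i) w.rowvals.push_back(cur[i]);
  w.rows_computed = 1;
  if (bit_w(cur[0], m, 0) == 0) w.d_opt = 0;
  for (int d = 1; d <= k; ++d) {
    if (w.et && w.d_opt >= 0) break;
    prev.swap(cur);
    cur[n] = boundary_w(d, m);
    win_store(w, d, n, cur[n], shl_w(boundary_w(d - 1, m), m), ones, ones);
    for (int i = n - 1; i >= 0; --i) {
      uint64_t I = shl_w(prev[i], m);
      uint64_t D = prev[i + 1];
      uint64_t S = shl_w(D, m);
      uint64_t M = shl_w(cur[i + 1], m) | w.pm[w.tc[i]];
      uint64_t E = I & D & S & M;
      cur[i] = E;
      win_store(w, d, i, E, I, D, M);
    }
    for (int i = 0; i <= n; ++i) w.rowvals.push_back(cur[i]);
    w.rows_computed = d + 1;
    if (w.d_opt < 0 && bit_w(cur[0], m, 0) == 0) w.d_opt = d;
  }
  if (w.d_opt < 0)
    stop("fill: no zero reached the leftmost column within k = W rows "
         "(internal error; unreachable for n, m <= W)");
}

struct Edges { uint64_t I, D, S, M; int w; };

static uint64_t store_read_entry(Win& w, int d, int i) {
  if (w.mode == 1) {
    w.bits_read += w.m;
    return w.ent[(size_t)d * (w.n + 1) + i];
  }
  w.bits_read += w.bstore;
  return w.ent[(size_t)d * w.cols + i];
}

// Edge bitvectors at interior cell (d >= 1, i < n). Mode 0 reads the stored
// edges; modes 1 and 2 regenerate them from the stored neighbor entries by
// re-applying the update rules (SENE). In mode 2 all arithmetic happens in
// the trimmed width; only bits j <= bstore-2 of the result are meaningful,
// which covers everything a truncated traceback may query.
static Edges edges_at(Win& w, int d, int i) {
  Edges e;
  if (w.mode == 0) {
    size_t idx = (size_t)d * (w.n + 1) + i;
    w.bits_read += 3LL * w.m;
    e.I = w.eI[idx]; e.D = w.eD[idx]; e.S = shl_w(w.eD[idx], w.m); e.M = w.eM[idx];
    e.w = w.m;
    return e;
  }
  int wd = (w.mode == 1) ? w.m : w.bstore;
  uint64_t north = store_read_entry(w, d - 1, i);
  uint64_t ne    = store_read_entry(w, d - 1, i + 1);
  uint64_t east  = store_read_entry(w, d, i + 1);
  uint64_t mask  = w.pm[w.tc[i]];
  if (w.mode == 2 && w.bstore < w.m) mask >>= (w.m - w.bstore);
  e.I = shl_w(north, wd);
  e.D = ne;
  e.S = shl_w(ne, wd);
  e.M = shl_w(east, wd) | mask;
  e.w = wd;
  return e;
}

struct TBOut {
  std::string ops;
  int ti = 0, pj = 0, d_start = 0, padded = 0;
};

// Walk the path of 0s from (d_opt, i = 0, j = 0) toward the north-east
// corner. Edge priority M > S > D > I (fixed, documented tie-break).
static TBOut win_traceback(Win& w, bool terminal) {
  TBOut o;
  int d = w.d_opt, i = 0, j = 0;
  o.d_start = d;
  const int n = w.n, m = w.m, lim = w.W - w.O;
  if (m == 0) {
    if (terminal && n > 0) { o.ops.assign(n, 'D'); o.padded = n; }
  } else {
    while (true) {
      if (terminal) {
        if (i == n && j == m) break;
        if (j == m) { o.ops.append(n - i, 'D'); o.padded = n - i; break; }
        if (i == n) {
          if (d <= 0) { o.ops.append(m - j, 'I'); o.padded += m - j; break; }
          o.ops.push_back('I'); d--; j++; continue; // boundary-column insertion
        }
      } else {
        if (i >= lim || j >= lim || i >= n || j >= m) break;
      }
      if (d == 0) { // match row: only M edges are eligible
        uint64_t e0;
        int wd;
        if (w.mode == 0) {
          w.bits_read += 3LL * m;
          e0 = w.eM[(size_t)i]; wd = m;
        } else {
          e0 = store_read_entry(w, 0, i);
          wd = (w.mode == 2) ? w.bstore : m;
        }
        if (bit_w(e0, wd, j) != 0)
          stop("traceback: zero-path invariant violated at the match row");
        o.ops.push_back('='); i++; j++; continue;
      }
      Edges e = edges_at(w, d, i);
      uint64_t entry = e.I & e.D & e.S & e.M;
      if (bit_w(entry, e.w, j) != 0)
        stop("traceback: zero-path invariant violated");
      if (bit_w(e.M, e.w, j) == 0)      { o.ops.push_back('='); i++; j++; }
      else if (bit_w(e.S, e.w, j) == 0) { o.ops.push_back('X'); d--; i++; j++; }
      else if (bit_w(e.D, e.w, j) == 0) { o.ops.push_back('D'); d--; i++; }
      else                              { o.ops.push_back('I'); d--; j++; }
    }
  }
  for (char c : o.ops) {
    if (c == '=' || c == 'X' || c == 'D') o.ti++;
    if (c == '=' || c == 'X' || c == 'I') o.pj++;
  }
  return o;
}

static std::string bits_to_string(uint64_t x, int w) {
  std::string s(w, '0');
  for (int j = 0; j < w; ++j) s[j] = bit_w(x, w, j) ? '1' : '0';
  return s;
}

static int mode_from_string(const std::string& mode) {
  if (mode == "edges") return 0;
  if (mode == "entries") return 1;
  if (mode == "entries-dent") return 2;
  stop("unknown storage mode '%s'", mode.c_str());
}

// [[Rcpp::export]]
List cpp_fill_table(std::string text, std::string pattern, int W, int O,
                    std::string mode, bool et) {
  Win w;
  win_setup(w, encode(text), encode(pattern), W, O, mode_from_string(mode), et);
  win_fill(w);
  const int rows = w.rows_computed, n = w.n, m = w.m;
  CharacterMatrix table(rows, n + 1);
  for (int d = 0; d < rows; ++d)
    for (int i = 0; i <= n; ++i)
      table(d, i) = bits_to_string(w.rowvals[(size_t)d * (n + 1) + i], m);
  List stored;
  if (w.mode == 0) {
    CharacterMatrix I(rows, n + 1), D(rows, n + 1), M(rows, n + 1);
    for (int d = 0; d < rows; ++d)
      for (int i = 0; i <= n; ++i) {
        size_t idx = (size_t)d * (n + 1) + i;
        I(d, i) = bits_to_string(w.eI[idx], m);
        D(d, i) = bits_to_string(w.eD[idx], m);
        M(d, i) = bits_to_string(w.eM[idx], m);
      }
    stored = List::create(_["I"] = I, _["D"] = D, _["M"] = M);
  } else {
    CharacterMatrix E(rows, w.cols);
    for (int d = 0; d < rows; ++d)
      for (int i = 0; i < w.cols; ++i)
        E(d, i) = bits_to_string(w.ent[(size_t)d * w.cols + i], w.bstore);
    stored = List::create(_["entries"] = E);
  }
  return List::create(
    _["n"] = n, _["m"] = m, _["W"] = W, _["O"] = O, _["k"] = w.k,
    _["mode"] = mode, _["et"] = et,
    _["d_opt"] = w.d_opt, _["rows_computed"] = rows,
    _["cols_stored"] = w.cols, _["bits_per_entry"] = w.bstore,
    _["bits_written"] = (double)w.bits_written,
    _["cells_written"] = (double)w.cells_written,
    _["capacity_bits"] = (double)w.capacity_bits(),
    _["table"] = table, _["stored"] = stored);
}

// [[Rcpp::export]]
List cpp_traceback(std::string text, std::string pattern, int W, int O,
                   std::string mode, bool et, bool terminal) {
  Win w;
  win_setup(w, encode(text), encode(pattern), W, O, mode_from_string(mode), et);
  win_fill(w);
  TBOut t = win_traceback(w, terminal);
  return List::create(
    _["ops"] = t.ops, _["text_consumed"] = t.ti, _["pattern_consumed"] = t.pj,
    _["d_start"] = t.d_start, _["padded_tail"] = t.padded,
    _["d_opt"] = w.d_opt, _["rows_computed"] = w.rows_computed,
    _["bits_written"] = (double)w.bits_written,
    _["bits_read"] = (double)w.bits_read);
}

// [[Rcpp::export]]
List cpp_align(std::string text, std::string pattern, int W, int O,
               bool sene, bool dent, bool et) {
  if (dent && !sene) stop("dent requires sene");
  std::vector<int> tc = encode(text), pc = encode(pattern);
  long long N = (long long)tc.size(), M = (long long)pc.size();
  long long a = 0, b = 0, windows = 0;
  long long bw = 0, br = 0, cw = 0;
  std::string ops;
  long long guard = 2 * (N + M) + 16;
  while (true) {
    long long nr = N - a, mr = M - b;
    if (nr == 0 && mr == 0) break;
    if (mr == 0) { ops.append((size_t)nr, 'D'); break; }
    if (nr == 0) { ops.append((size_t)mr, 'I'); break; }
    bool terminal = (nr <= W && mr <= W);
    int n = (int)std::min((long long)W, nr);
    int m = (int)std::min((long long)W, mr);
    // DENT only applies to truncated tracebacks; terminal windows need the
    // full table to trace to the corner.
    int mode = sene ? ((dent && !terminal) ? 2 : 1) : 0;
    Win w;
    win_setup(w, std::vector<int>(tc.begin() + a, tc.begin() + a + n),
              std::vector<int>(pc.begin() + b, pc.begin() + b + m),
              W, O, mode, et);
    win_fill(w);
    TBOut t = win_traceback(w, terminal);
    bw += w.bits_written; br += w.bits_read; cw += w.cells_written;
    windows++;
    ops += t.ops;
    a += t.ti; b += t.pj;
    if (terminal) {
      if (a != N || b != M) stop("terminal window did not consume the remainder");
      break;
    }
    if (t.ti == 0 && t.pj == 0) stop("windowing stalled (internal error)");
    if (--guard < 0) stop("windowing did not terminate (internal error)");
  }
  long long edits = 0;
  for (char c : ops) if (c != '=') edits++;
  return List::create(
    _["ops"] = ops, _["edits"] = (double)edits,
    _["text_len"] = (double)N, _["pattern_len"] = (double)M,
    _["windows_used"] = (double)windows,
    _["bits_written"] = (double)bw, _["bits_read"] = (double)br,
    _["cells_written"] = (double)cw);
}

// ---------------------------------------------------------------------------
// Exact oracles: full Levenshtein DP with traceback, and the min-over-text-
// prefixes distance that the bitvector semantics realize. These are
// independent of the bitvector path above.

// [[Rcpp::export]]
List cpp_levenshtein(std::string a, std::string b, bool want_cigar) {
  // a plays the text (reference) role, b the pattern (read): D consumes a,
  // I consumes b.
  const long long n = (long long)a.size(), m = (long long)b.size();
  if (!want_cigar) {
    std::vector<int> prev(m + 1), cur(m + 1);
    for (long long j = 0; j <= m; ++j) prev[j] = (int)j;
    for (long long i = 1; i <= n; ++i) {
      cur[0] = (int)i;
      for (long long j = 1; j <= m; ++j) {
        int sub = prev[j - 1] + (a[i - 1] != b[j - 1]);
        cur[j] = std::min(sub, std::min(prev[j] + 1, cur[j - 1] + 1));
      }
      prev.swap(cur);
    }
    return List::create(_["distance"] = prev[m], _["ops"] = R_NilValue);
  }
  if ((n + 1) * (m + 1) > 200000000LL)
    stop("sequences too long for traceback oracle; use want_cigar = FALSE");
  std::vector<int> dp((size_t)(n + 1) * (m + 1));
  auto at = [&](long long i, long long j) -> int& {
    return dp[(size_t)i * (m + 1) + j];
  };
  for (long long j = 0; j <= m; ++j) at(0, j) = (int)j;
  for (long long i = 0; i <= n; ++i) at(i, 0) = (int)i;
  for (long long i = 1; i <= n; ++i)
    for (long long j = 1; j <= m; ++j) {
      int sub = at(i - 1, j - 1) + (a[i - 1] != b[j - 1]);
      at(i, j) = std::min(sub, std::min(at(i - 1, j) + 1, at(i, j - 1) + 1));
    }
  // deterministic tie-break: diagonal over deletion over insertion
  std::string rev;
  long long i = n, j = m;
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        at(i, j) == at(i - 1, j - 1) + (a[i - 1] != b[j - 1])) {
      rev.push_back(a[i - 1] == b[j - 1] ? '=' : 'X'); i--; j--;
    } else if (i > 0 && at(i, j) == at(i - 1, j) + 1) {
      rev.push_back('D'); i--;
    } else {
      rev.push_back('I'); j--;
    }
  }
  std::reverse(rev.begin(), rev.end());
  return List::create(_["distance"] = at(n, m), _["ops"] = rev);
}

static int prefix_min_dist(const std::string& pat, const std::string& txt) {
  const int m = (int)pat.size(), n = (int)txt.size();
  // dp[j] = Lev(pat[0:j), txt[0:t)) rolling over t; answer min_t dp[m]
  std::vector<int> prev(m + 1), cur(m + 1);
  for (int j = 0; j <= m; ++j) prev[j] = j;
  int best = prev[m];
  for (int t = 1; t <= n; ++t) {
    cur[0] = t;
    for (int j = 1; j <= m; ++j) {
      int sub = prev[j - 1] + (txt[t - 1] != pat[j - 1]);
      cur[j] = std::min(sub, std::min(prev[j] + 1, cur[j - 1] + 1));
    }
    prev.swap(cur);
    best = std::min(best, prev[m]);
  }
  return best;
}

// [[Rcpp::export]]
int cpp_prefix_min(std::string pattern_suffix, std::string text_suffix) {
  return prefix_min_dist(pattern_suffix, text_suffix);
}

// Exhaustive per-pair check of the bit semantics: bit j of R[d][i] == 0
// iff min over t of Lev(pattern[j:m), text[i:i+t)) <= d, for every computed
// row d, every column i and every bit j. Fills with et off so all k+1 rows
// are checked.
// [[Rcpp::export]]
List cpp_bit_semantics_check(std::string text, std::string pattern, int W) {
  Win w;
  win_setup(w, encode(text), encode(pattern), W, 0, 1, false);
  win_fill(w);
  const int n = w.n, m = w.m;
  for (int i = 0; i <= n; ++i) {
    for (int j = 0; j < m; ++j) {
      int pmin = prefix_min_dist(pattern.substr(j), text.substr(i));
      for (int d = 0; d < w.rows_computed; ++d) {
        int b = bit_w(w.rowvals[(size_t)d * (n + 1) + i], m, j);
        if ((b == 0) != (pmin <= d))
          return List::create(_["ok"] = false, _["d"] = d, _["i"] = i,
                              _["j"] = j, _["bit"] = b, _["oracle"] = pmin);
      }
    }
  }
  return List::create(_["ok"] = true);
}
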