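#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline char comp(char b) {
  switch (b) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    case 'a': return 't';
    case 'c': return 'g';
    case 'g': return 'c';
    case 't': return 'a';
    default: return 'N';
  }
}

// Build as-read sequences and qualities for one haplotype batch: slice the
// haplotype, reverse-complement minus-strand reads, append adapter
// read-through, inject substitution errors and N bases, and draw Phred
// qualities from a linearly declining per-cycle profile. Uses the R RNG,
// so results are reproducible under set.seed().
// [[Rcpp::export(name = ".build_reads")]]
List build_reads(std::string hap, IntegerVector start, IntegerVector part_len,
                 LogicalVector rc, std::string adapter, IntegerVector ad_len,
                 double err_rate, double n_rate,
                 double q_start, double q_end, double q_sd,
                 double lowq_frac, double lowq_mean) {
  int n = start.size();
  CharacterVector seqs(n), quals(n);
  std::string buf, qbuf;
  const char *bases = "ACGT";
  // Quality jitter is drawn from a pre-sampled normal pool indexed by a
  // fast internal generator seeded from the R RNG (still deterministic
  // under set.seed); rare events (errors, N bases) are skip-sampled, so
  // the R RNG is consulted only O(events) times rather than per base.
  const int POOL = 8192;
  std::vector<double> pool(POOL);
  for (int i = 0; i < POOL; i++) pool[i] = norm_rand();
  uint64_t rng = 0x9E3779B97F4A7C15ULL ^
                 (uint64_t)(unif_rand() * 9007199254740992.0);
  auto next_pool = [&]() {
    rng ^= rng >> 12;
    rng ^= rng << 25;
    rng ^= rng >> 27;
    return (int)((rng * 0x2545F4914F6CDD1DULL >> 33) & (POOL - 1));
  };
  auto skip_draw = [&](double rate) -> long long {
    if (rate <= 0) return -1;
    return (long long)std::floor(std::log(unif_rand()) /
                                 std::log1p(-rate));
  };
  long long base_i = 0;
  long long next_err = skip_draw(err_rate);
  long long next_n = skip_draw(n_rate);

  // pre-computed quality characters per (cycle, pool index)
  int max_total = 0;
  for (int i = 0; i < n; i++) {
    int t = part_len[i] + ad_len[i];
    if (t > max_total) max_total = t;
  }
  auto clampq = [](double q) {
    int qi = (int)std::lround(q);
    if (qi < 2) qi = 2;
    if (qi > 40) qi = 40;
    return (char)(qi + 33);
  };
  std::vector<char> qtab((size_t)max_total * POOL);
  std::vector<char> qlow(POOL);
  for (int j = 0; j < max_total; j++) {
    double slope = (max_total > 1) ? (q_end - q_start) / (max_total - 1) : 0;
    double base_q = q_start + slope * j;
    for (int p = 0; p < POOL; p++) {
      qtab[(size_t)j * POOL + p] = clampq(base_q + pool[p] * q_sd);
    }
  }
  for (int p = 0; p < POOL; p++) qlow[p] = clampq(lowq_mean + pool[p] * 2.0);
  for (int i = 0; i < n; i++) {
    int pl = part_len[i];
    int al = ad_len[i];
    int total = pl + al;
    buf.resize(total);
    qbuf.resize(total);
    const char *src = hap.data() + (start[i] - 1);
    if (rc[i]) {
      for (int j = 0; j < pl; j++) buf[j] = comp(src[pl - 1 - j]);
    } else {
      for (int j = 0; j < pl; j++) buf[j] = src[j];
    }
    for (int j = 0; j < al; j++) buf[pl + j] = adapter[j % adapter.size()];
    bool lowq = lowq_frac > 0 && unif_rand() < lowq_frac;
    for (int j = 0; j < total; j++, base_i++) {
      if (base_i == next_err) {
        char cur = buf[j];
        char sub;
        do {
          sub = bases[(int)(unif_rand() * 4.0) & 3];
        } while (sub == cur);
        buf[j] = sub;
        next_err += 1 + skip_draw(err_rate);
      }
      if (base_i == next_n) {
        buf[j] = 'N';
        next_n += 1 + skip_draw(n_rate);
      }
      qbuf[j] = lowq ? qlow[next_pool()]
                     : qtab[(size_t)j * POOL + next_pool()];
    }
    seqs[i] = buf;
    quals[i] = qbuf;
  }
  return List::create(_["seq"] = seqs, _["qual"] = quals);
}

// Per-read mean quality and fraction of bases below a threshold, straight
// from Phred+33 strings.
// [[Rcpp::export(name = ".qual_stats")]]
List qual_stats_cpp(CharacterVector qual, int thresh) {
  int n = qual.size();
  NumericVector means(n), frac(n);
  for (int i = 0; i < n; i++) {
    const char *q = CHAR(STRING_ELT(qual, i));
    int len = LENGTH(STRING_ELT(qual, i));
    long sum = 0;
    int below = 0;
    for (int j = 0; j < len; j++) {
      int v = q[j] - 33;
      sum += v;
      if (v < thresh) below++;
    }
    means[i] = len ? (double)sum / len : NA_REAL;
    frac[i] = len ? (double)below / len : NA_REAL;
  }
  return List::create(_["mean"] = means, _["frac_below"] = frac);
}

// Summed base quality per read (Phred+33).
// [[Rcpp::export(name = ".qual_sums")]]
NumericVector qual_sums_cpp(CharacterVector qual) {
  int n = qual.size();
  NumericVector out(n);
  for (int i = 0; i < n; i++) {
    const char *q = CHAR(STRING_ELT(qual, i));
    int len = LENGTH(STRING_ELT(qual, i));
    long sum = 0;
    for (int j = 0; j < len; j++) sum += q[j] - 33;
    out[i] = (double)sum;
  }
  return out;
}

// Vectorised reverse complement over ACGTN strings.
// [[Rcpp::export(name = ".revcomp")]]
CharacterVector revcomp_cpp(CharacterVector x) {
  int n = x.size();
  CharacterVector out(n);
  std::string buf;
  for (int i = 0; i < n; i++) {
    const char *s = CHAR(STRING_ELT(x, i));
    int len = LENGTH(STRING_ELT(x, i));
    buf.resize(len);
    for (int j = 0; j < len; j++) buf[j] = comp(s[len - 1 - j]);
    out[i] = buf;
  }
  return out;
}

// Reverse strings (for quality strings of minus-strand reads).
// [[Rcpp::export(name = ".strrev")]]
CharacterVector strrev_cpp(CharacterVector x) {
  int n = x.size();
  CharacterVector out(n);
  std::string buf;
  for (int i = 0; i < n; i++) {
    const char *s = CHAR(STRING_ELT(x, i));
    int len = LENGTH(STRING_ELT(x, i));
    buf.assign(s, len);
    std::reverse(buf.begin(), buf.end());
    out[i] = buf;
  }
  return out;
}
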