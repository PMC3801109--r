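#include <Rcpp.h>
#include <map>
#include <string>
#include <cmath>
using namespace Rcpp;

// Accumulate a per-position pileup for one chromosome from SAM-style
// alignments (forward-strand SEQ, 1-based POS, CIGAR with M/I/D/S ops).
//
// Per base observation with quality Q and error rate e = 10^(-Q/10) three
// log-likelihood accumulators are kept per (base, position), so diploid
// genotype likelihoods can be assembled later without per-read storage:
//   s1: log(1 - e)              (observation matches a homozygous allele)
//   s2: log(((1-e) + e/3) / 2)  (observation matches one het allele)
//   s3: log(e / 3)              (observation matches neither allele)
// Insertions are attributed to the preceding reference position, deletions
// to their first deleted position. N observations are skipped entirely.
// [[Rcpp::export(name = ".pileup_chrom")]]
List pileup_chrom(IntegerVector pos, CharacterVector cigar,
                  CharacterVector seq, CharacterVector qual, int L) {
  IntegerMatrix counts(4, L);
  NumericMatrix s1(4, L), s2(4, L), s3(4, L);

  // quality lookup tables (Phred 0..60)
  const int QMAX = 61;
  double l1[QMAX], l2[QMAX], l3[QMAX];
  for (int q = 0; q < QMAX; q++) {
    double e = std::pow(10.0, -q / 10.0);
    if (e > 0.75) e = 0.75;  // cap: a base can't be worse than random
    l1[q] = std::log(1.0 - e);
    l2[q] = std::log(((1.0 - e) + e / 3.0) / 2.0);
    l3[q] = std::log(e / 3.0);
  }

  std::map<std::pair<int, std::string>, int> indels;

  int n = pos.size();
  for (int r = 0; r < n; r++) {
    const char *cg = CHAR(STRING_ELT(cigar, r));
    const char *sq = CHAR(STRING_ELT(seq, r));
    const char *ql = CHAR(STRING_ELT(qual, r));
    int p = pos[r] - 1;  // 0-based reference cursor
    int qi = 0;          // read cursor
    int num = 0;
    for (const char *c = cg; *c; c++) {
      if (*c >= '0' && *c <= '9') {
        num = num * 10 + (*c - '0');
        continue;
      }
      char op = *c;
      if (op == 'M') {
        for (int k = 0; k < num; k++, p++, qi++) {
          if (p < 0 || p >= L) continue;
          int b;
          switch (sq[qi]) {
            case 'A': b = 0; break;
            case 'C': b = 1; break;
            case 'G': b = 2; break;
            case 'T': b = 3; break;
            default: continue;
          }
          int q = ql[qi] - 33;
          if (q < 0) q = 0;
          if (q >= QMAX) q = QMAX - 1;
          counts(b, p)++;
          s1(b, p) += l1[q];
          s2(b, p) += l2[q];
          s3(b, p) += l3[q];
        }
      } else if (op == 'I') {
        std::string allele = "+";
        allele.append(sq + qi, num);
        if (p - 1 >= 0 && p - 1 < L) {
          indels[std::make_pair(p, allele)]++;  // 1-based preceding pos
        }
        qi += num;
      } else if (op == 'D') {
        std::string allele = "-" + std::to_string(num);
        if (p >= 0 && p < L) {
          indels[std::make_pair(p + 1, allele)]++;  // 1-based first deleted
        }
        p += num;
      } else if (op == 'S') {
        qi += num;
      } else if (op == 'N') {
        p += num;
      } else {
        stop("unsupported CIGAR op '%s' in '%s'", std::string(1, op), cg);
      }
      num = 0;
    }
  }

  int ni = indels.size();
  IntegerVector ipos(ni), icount(ni);
  CharacterVector iallele(ni);
  int k = 0;
  for (auto &kv : indels) {
    ipos[k] = kv.first.first;
    iallele[k] = kv.first.second;
    icount[k] = kv.second;
    k++;
  }
  return List::create(
    _["counts"] = counts, _["s1"] = s1, _["s2"] = s2, _["s3"] = s3,
    _["indel_pos"] = ipos, _["indel_allele"] = iallele,
    _["indel_count"] = icount
  );
}
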