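#include <Rcpp.h>
using namespace Rcpp;

// Pairwise nucleotide match counts between copies stored as codon-index
// columns (values 1..64).  `ntm` is the flattened 64x64 table of identical
// nucleotide positions between two codons (0..3), so each codon pair costs
// one table lookup instead of three base comparisons.  Hot path of hit
// emission and identity-table construction.
// [[Rcpp::export(name = ".codon_match_cpp")]]
IntegerMatrix codon_match_cpp(const IntegerMatrix& A, const IntegerMatrix& B,
                              const IntegerVector& ntm) {
  const int L = A.nrow();
  if (B.nrow() != L) stop("matrices differ in row count");
  const int nA = A.ncol(), nB = B.ncol();
  const int* t = INTEGER(ntm);
  IntegerMatrix out(nA, nB);
  for (int j = 0; j < nB; ++j) {
    const int* bj = &B(0, j);
    for (int i = 0; i < nA; ++i) {
      const int* ai = &A(0, i);
      int m = 0;
      for (int k = 0; k < L; ++k) m += t[(ai[k] - 1) * 64 + (bj[k] - 1)];
      out(i, j) = m;
    }
  }
  return out;
}
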