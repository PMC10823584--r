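#include <Rcpp.h>
using namespace Rcpp;

// BLOSUM62 k-mer peptide kernel.
//
// Raw kernel K(a, b) sums, over window lengths k = kmin..min(kmax, |a|, |b|)
// and over every pair of k-mer windows (one from each peptide), the product
// over aligned positions of E[x, y], where E = exp(beta * BLOSUM62).
// A dynamic programme over window start pairs reuses the length-(k-1)
// products, so one pair costs O(|a| * |b| * kmax).
//
// Sequences arrive as 0-based integer encodings of the 20-letter alphabet;
// E is the 20 x 20 exponentiated substitution table built on the R side.

static double kernel_raw(const std::vector<int>& a, const std::vector<int>& b,
                         const NumericMatrix& E, int kmin, int kmax) {
  const int la = a.size(), lb = b.size();
  int kmx = std::min(kmax, std::min(la, lb));
  if (kmx < kmin) return 0.0;
  // prod[i*lb + j] holds the product for the window of the current length
  // starting at (i, j)
  std::vector<double> prod((size_t)la * lb);
  for (int i = 0; i < la; ++i)
    for (int j = 0; j < lb; ++j)
      prod[(size_t)i * lb + j] = E(a[i], b[j]);
  double total = 0.0;
  for (int k = 2; k <= kmx; ++k) {
    for (int i = 0; i + k <= la; ++i) {
      for (int j = 0; j + k <= lb; ++j) {
        double p = prod[(size_t)i * lb + j] * E(a[i + k - 1], b[j + k - 1]);
        prod[(size_t)i * lb + j] = p;
        if (k >= kmin) total += p;
      }
    }
  }
  if (kmin == 1) {
    // include the single-residue windows (not used at defaults)
    for (int i = 0; i < la; ++i)
      for (int j = 0; j < lb; ++j) total += E(a[i], b[j]);
  }
  return total;
}

static std::vector<int> as_vec(SEXP s) {
  IntegerVector v(s);
  std::vector<int> out(v.size());
  for (int i = 0; i < v.size(); ++i) {
    if (v[i] == NA_INTEGER) stop("non-canonical residue in peptide");
    out[i] = v[i] - 1; // to 0-based
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_kernel_self(List seqs, NumericMatrix E, int kmin, int kmax) {
  const int n = seqs.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    std::vector<int> a = as_vec(seqs[i]);
    out[i] = kernel_raw(a, a, E, kmin, kmax);
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_kernel_elementwise(List sa, List sb, NumericMatrix E,
                                     int kmin, int kmax) {
  if (sa.size() != sb.size()) stop("length mismatch");
  const int n = sa.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    std::vector<int> a = as_vec(sa[i]), b = as_vec(sb[i]);
    double kab = kernel_raw(a, b, E, kmin, kmax);
    double kaa = kernel_raw(a, a, E, kmin, kmax);
    double kbb = kernel_raw(b, b, E, kmin, kmax);
    out[i] = kab / std::sqrt(kaa * kbb);
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_kernel_matrix(List sa, List sb, NumericMatrix E,
                                int kmin, int kmax) {
  const int na = sa.size(), nb = sb.size();
  std::vector< std::vector<int> > A(na), B(nb);
  std::vector<double> selfA(na), selfB(nb);
  for (int i = 0; i < na; ++i) {
    A[i] = as_vec(sa[i]);
    selfA[i] = kernel_raw(A[i], A[i], E, kmin, kmax);
  }
  for (int j = 0; j < nb; ++j) {
    B[j] = as_vec(sb[j]);
    selfB[j] = kernel_raw(B[j], B[j], E, kmin, kmax);
  }
  NumericMatrix out(na, nb);
  for (int i = 0; i < na; ++i)
    for (int j = 0; j < nb; ++j)
      out(i, j) = kernel_raw(A[i], B[j], E, kmin, kmax) /
        std::sqrt(selfA[i] * selfB[j]);
  return out;
}

// Hobohm-1 greedy redundancy scan in input order. A peptide joins the
// cluster of the maximum-similarity representative among those exceeding
// the threshold, otherwise becomes a new representative.
// Returns (1-based) representative index per peptide (own index for
// representatives) and the similarity to that representative (1 for reps).
// [[Rcpp::export]]
List cpp_hobohm1(List seqs, NumericMatrix E, int kmin, int kmax,
                 double threshold) {
  const int n = seqs.size();
  std::vector< std::vector<int> > S(n);
  std::vector<double> selfK(n);
  IntegerVector rep(n);
  NumericVector sim(n);
  std::vector<int> reps;
  for (int i = 0; i < n; ++i) {
    S[i] = as_vec(seqs[i]);
    selfK[i] = kernel_raw(S[i], S[i], E, kmin, kmax);
    double best = -1.0;
    int besr = -1;
    for (size_t r = 0; r < reps.size(); ++r) {
      int j = reps[r];
      double s = kernel_raw(S[i], S[j], E, kmin, kmax) /
        std::sqrt(selfK[i] * selfK[j]);
      if (s > threshold && s > best) { best = s; besr = j; }
    }
    if (besr >= 0) {
      rep[i] = besr + 1;
      sim[i] = best;
    } else {
      reps.push_back(i);
      rep[i] = i + 1;
      sim[i] = 1.0;
    }
  }
  return List::create(_["rep"] = rep, _["sim"] = sim);
}
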