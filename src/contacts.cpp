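#include <Rcpp.h>
using namespace Rcpp;

// Residue-pair contact detection over trajectory frames.
//
// Coordinates are passed transposed (3*A x F) so each frame is one
// contiguous column.  Atom membership of each residue "slot" is given in
// CSR layout: atoms[offs[s] .. offs[s+1]-1] are the 0-based atom indices of
// slot s.  pairs holds 0-based slot indices.  A pair is in contact in a
// frame iff the minimum distance over its atom pairs is <= cutoff
// (inclusive, matching the <= 4.5 A convention).

// [[Rcpp::export(rng = false)]]
LogicalMatrix pair_contact_frames(const NumericMatrix& xyzT,
                                  const IntegerVector& atoms,
                                  const IntegerVector& offs,
                                  const IntegerMatrix& pairs,
                                  const double cutoff) {
  const int F = xyzT.ncol();
  const int np = pairs.nrow();
  const double c2 = cutoff * cutoff;
  LogicalMatrix out(np, F);

  for (int f = 0; f < F; ++f) {
    const double* p = &xyzT(0, f);
    for (int k = 0; k < np; ++k) {
      const int s1 = pairs(k, 0), s2 = pairs(k, 1);
      bool hit = false;
      for (int ia = offs[s1]; ia < offs[s1 + 1] && !hit; ++ia) {
        const double* A = p + 3 * atoms[ia];
        for (int ib = offs[s2]; ib < offs[s2 + 1]; ++ib) {
          const double* B = p + 3 * atoms[ib];
          const double dx = A[0] - B[0];
          const double dy = A[1] - B[1];
          const double dz = A[2] - B[2];
          if (dx * dx + dy * dy + dz * dz <= c2) { hit = true; break; }
        }
      }
      out(k, f) = hit;
    }
  }
  return out;
}

// Minimum heavy-atom distance per residue pair per frame (same layout as
// above); used for pocket definition and diagnostics.

// [[Rcpp::export(rng = false)]]
NumericMatrix pair_min_dist_frames(const NumericMatrix& xyzT,
                                   const IntegerVector& atoms,
                                   const IntegerVector& offs,
                                   const IntegerMatrix& pairs) {
  const int F = xyzT.ncol();
  const int np = pairs.nrow();
  NumericMatrix out(np, F);

  for (int f = 0; f < F; ++f) {
    const double* p = &xyzT(0, f);
    for (int k = 0; k < np; ++k) {
      const int s1 = pairs(k, 0), s2 = pairs(k, 1);
      double best = R_PosInf;
      for (int ia = offs[s1]; ia < offs[s1 + 1]; ++ia) {
        const double* A = p + 3 * atoms[ia];
        for (int ib = offs[s2]; ib < offs[s2 + 1]; ++ib) {
          const double* B = p + 3 * atoms[ib];
          const double dx = A[0] - B[0];
          const double dy = A[1] - B[1];
          const double dz = A[2] - B[2];
          const double d2 = dx * dx + dy * dy + dz * dz;
          if (d2 < best) best = d2;
        }
      }
      out(k, f) = std::sqrt(best);
    }
  }
  return out;
}
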