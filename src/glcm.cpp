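#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Moving-window GLCM Haralick features.
//
// q: quantised grid (values in 0..levels-1, NA_INTEGER = nodata)
// offsets: k x 2 integer matrix of (dr, dc) displacements
// Border cells whose window leaves the grid are NA. Within a full window,
// pairs are accumulated over all offsets (both endpoints inside the window
// and non-NA), symmetrised if requested, and normalised to probabilities.
// [[Rcpp::export(name = ".glcmStackCpp")]]
List glcmStackCpp(IntegerMatrix q, int levels, int window,
                  IntegerMatrix offsets, bool symmetric) {
  const int nr = q.nrow(), nc = q.ncol();
  const int half = window / 2;
  const int L = levels;
  const int nOff = offsets.nrow();

  NumericMatrix fMean(nr, nc), fVar(nr, nc), fHom(nr, nc), fCon(nr, nc),
      fDis(nr, nc), fEnt(nr, nc), fAsm(nr, nc), fCor(nr, nc);
  std::fill(fMean.begin(), fMean.end(), NA_REAL);
  std::fill(fVar.begin(), fVar.end(), NA_REAL);
  std::fill(fHom.begin(), fHom.end(), NA_REAL);
  std::fill(fCon.begin(), fCon.end(), NA_REAL);
  std::fill(fDis.begin(), fDis.end(), NA_REAL);
  std::fill(fEnt.begin(), fEnt.end(), NA_REAL);
  std::fill(fAsm.begin(), fAsm.end(), NA_REAL);
  std::fill(fCor.begin(), fCor.end(), NA_REAL);

  std::vector<double> P((size_t)L * L, 0.0);
  std::vector<int> touched;
  touched.reserve((size_t)window * window * nOff * 2);
  std::vector<double> pi(L), pj(L);

  for (int r = half; r < nr - half; ++r) {
    for (int c = half; c < nc - half; ++c) {
      // reset touched entries only
      for (size_t t = 0; t < touched.size(); ++t) P[touched[t]] = 0.0;
      touched.clear();
      double total = 0.0;
      const int r0 = r - half, r1 = r + half, c0 = c - half, c1 = c + half;
      for (int i = r0; i <= r1; ++i) {
        for (int j = c0; j <= c1; ++j) {
          const int a = q(i, j);
          if (a == NA_INTEGER) continue;
          for (int k = 0; k < nOff; ++k) {
            const int i2 = i + offsets(k, 0), j2 = j + offsets(k, 1);
            if (i2 < r0 || i2 > r1 || j2 < c0 || j2 > c1) continue;
            const int b = q(i2, j2);
            if (b == NA_INTEGER) continue;
            int idx = a * L + b;
            if (P[idx] == 0.0) touched.push_back(idx);
            P[idx] += 1.0; total += 1.0;
            if (symmetric) {
              idx = b * L + a;
              if (P[idx] == 0.0) touched.push_back(idx);
              P[idx] += 1.0; total += 1.0;
            }
          }
        }
      }
      if (total <= 0.0) continue;
      std::fill(pi.begin(), pi.end(), 0.0);
      std::fill(pj.begin(), pj.end(), 0.0);
      double hom = 0, con = 0, dis = 0, ent = 0, asm_ = 0;
      for (size_t t = 0; t < touched.size(); ++t) {
        const int idx = touched[t];
        const double p = P[idx] / total;
        const int a = idx / L, b = idx % L;
        const double d = (double)(a - b);
        pi[a] += p; pj[b] += p;
        hom += p / (1.0 + d * d);
        con += d * d * p;
        dis += std::fabs(d) * p;
        ent -= p * std::log(p);
        asm_ += p * p;
      }
      double mi = 0, mj = 0;
      for (int a = 0; a < L; ++a) { mi += a * pi[a]; mj += a * pj[a]; }
      double vi = 0, vj = 0;
      for (int a = 0; a < L; ++a) {
        vi += (a - mi) * (a - mi) * pi[a];
        vj += (a - mj) * (a - mj) * pj[a];
      }
      double cor = NA_REAL;
      const double sisj = std::sqrt(vi) * std::sqrt(vj);
      if (sisj > 0) {
        double s = 0;
        for (size_t t = 0; t < touched.size(); ++t) {
          const int idx = touched[t];
          const double p = P[idx] / total;
          const int a = idx / L, b = idx % L;
          s += (a - mi) * (b - mj) * p;
        }
        cor = s / sisj;
      }
      // GLCM mean/variance follow the i-marginal convention
      fMean(r, c) = mi;
      fVar(r, c) = vi;
      fHom(r, c) = hom;
      fCon(r, c) = con;
      fDis(r, c) = dis;
      fEnt(r, c) = ent;
      fAsm(r, c) = asm_;
      fCor(r, c) = cor;
    }
  }
  return List::create(
      _["mean"] = fMean, _["variance"] = fVar, _["homogeneity"] = fHom,
      _["contrast"] = fCon, _["dissimilarity"] = fDis, _["entropy"] = fEnt,
      _["second_moment"] = fAsm, _["correlation"] = fCor);
}
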