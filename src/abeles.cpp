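#include <Rcpp.h>
#include <complex>
#include <vector>
using namespace Rcpp;

typedef std::complex<double> cd;

// Specular reflectivity of a slab stack by the Abeles transfer-matrix
// method with Nevot-Croce roughness damping.
//
// Layers run from the incident (fronting) medium in row 0 to the backing
// medium in the last row; the first and last thicknesses are ignored
// (semi-infinite media).  rough[j] is the rms roughness of the interface
// between layer j-1 and layer j (rough[0] is unused).
//
// k_{z,j} = sqrt((Q/2)^2 - 4 pi (sld_j - sld_0)), principal branch, so
// evanescent waves get a positive imaginary part.
// [[Rcpp::export]]
NumericVector abeles_c(NumericVector q, NumericVector thickness,
                       NumericVector sld, NumericVector rough) {
  const int nq = q.size();
  const int nl = sld.size();
  if (nl < 2) stop("need at least fronting and backing media");
  NumericVector out(nq);
  const double sld0 = sld[0];
  std::vector<cd> k(nl);

  for (int iq = 0; iq < nq; ++iq) {
    const double k0sq = 0.25 * q[iq] * q[iq];
    for (int j = 0; j < nl; ++j) {
      k[j] = std::sqrt(cd(k0sq - 4.0 * M_PI * (sld[j] - sld0), 0.0));
    }
    cd m00(1.0, 0.0), m01(0.0, 0.0), m10(0.0, 0.0), m11(1.0, 0.0);
    for (int j = 0; j < nl - 1; ++j) {
      const double sig = rough[j + 1];
      cd r = (k[j] - k[j + 1]) / (k[j] + k[j + 1]);
      if (sig > 0.0) r *= std::exp(-2.0 * k[j] * k[j + 1] * sig * sig);
      cd beta = (j == 0) ? cd(0.0, 0.0) : cd(0.0, 1.0) * k[j] * thickness[j];
      const cd ep = std::exp(beta), em = std::exp(-beta);
      // layer characteristic matrix [[ep, r*ep], [r*em, em]]
      const cd c00 = ep, c01 = r * ep, c10 = r * em, c11 = em;
      const cd n00 = m00 * c00 + m01 * c10;
      const cd n01 = m00 * c01 + m01 * c11;
      const cd n10 = m10 * c00 + m11 * c10;
      const cd n11 = m10 * c01 + m11 * c11;
      m00 = n00; m01 = n01; m10 = n10; m11 = n11;
    }
    const double rr = std::norm(m10 / m00);
    out[iq] = (rr < 1.0) ? rr : 1.0;
  }
  return out;
}
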