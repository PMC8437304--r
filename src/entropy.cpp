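#include <Rcpp.h>
#include <complex>
#include <cmath>
using namespace Rcpp;

typedef std::complex<double> cplx;

// Eigenvalues of a 4x4 Hermitian matrix (column-major A[16]) by cyclic
// complex Jacobi rotations; accurate to machine precision at this size.
static inline void eig4_hermitian(cplx* A, double ev[4], double scale) {
  // convergence is judged against the problem scale (trace of the
  // uncorrected coherency), so near-zero matrices exit immediately
  const double thresh = 1e-30 * scale * scale + 1e-300;
  for (int sweep = 0; sweep < 50; ++sweep) {
    double off = 0.0;
    for (int p = 0; p < 4; ++p)
      for (int q = p + 1; q < 4; ++q) off += std::norm(A[p + 4 * q]);
    if (off <= thresh) break;
    for (int p = 0; p < 4; ++p) {
      for (int q = p + 1; q < 4; ++q) {
        const cplx b = A[p + 4 * q];
        const double beta = std::abs(b);
        if (beta == 0.0) continue;
        const cplx phase = b / beta;
        const double a = A[p + 4 * p].real(), d = A[q + 4 * q].real();
        const double tau = (d - a) / (2.0 * beta);
        const double t = (tau >= 0 ? 1.0 : -1.0) /
          (std::fabs(tau) + std::sqrt(1.0 + tau * tau));
        const double c = 1.0 / std::sqrt(1.0 + t * t);
        const cplx s = t * c * phase;
        for (int r = 0; r < 4; ++r) {
          if (r == p || r == q) continue;
          const cplx arp = A[r + 4 * p], arq = A[r + 4 * q];
          A[r + 4 * p] = c * arp - std::conj(s) * arq;
          A[r + 4 * q] = s * arp + c * arq;
          A[p + 4 * r] = std::conj(A[r + 4 * p]);
          A[q + 4 * r] = std::conj(A[r + 4 * q]);
        }
        const double app = c * c * a + t * t * c * c * d -
          2.0 * t * c * c * beta;
        A[q + 4 * q] = a + d - app;
        A[p + 4 * p] = app;
        A[p + 4 * q] = 0.0;
        A[q + 4 * p] = 0.0;
      }
    }
  }
  for (int i = 0; i < 4; ++i) ev[i] = A[i + 4 * i].real();
}

// Per-voxel polarimetric entropy from a Jones target-vector volume.
//
// jdata: complex array (nz, nx, ny, 4); element e holds component e of the
//        4-vector c = vec(J) (row-major: J11, J12, J21, J22).
// The local coherency matrix T = <c c^H> is averaged over a kz x kx window
// (axial x lateral, within one B-scan; truncated at volume edges), computed
// by integral images over the 10 unique Hermitian entries. Noise-bias
// correction subtracts sigma2 * I4 before eigen-decomposition; negative
// eigenvalues are clamped to zero. Entropy uses log base 4 so a completely
// random field has H = 1.
//
// Returns H (NA where the clamped spectrum sums to <= 0), the eigenvalue
// sum, and optionally the averaged (uncorrected) coherency (4, 4, ...).
// [[Rcpp::export]]
List entropy_jones_cpp(ComplexVector jdata, IntegerVector dims, int kz, int kx,
                       double sigma2, bool keep_coherency) {
  const int nz = dims[0], nx = dims[1], ny = dims[2];
  const R_xlen_t nvox = (R_xlen_t)nz * nx * ny;
  if (jdata.size() != 4 * nvox) stop("jones data length mismatch");
  const cplx* J = reinterpret_cast<const cplx*>(COMPLEX(jdata));

  NumericVector H(nvox), lsum(nvox);
  ComplexVector Tout(keep_coherency ? 16 * nvox : 0);
  cplx* Tp = keep_coherency ? reinterpret_cast<cplx*>(COMPLEX(Tout)) : nullptr;

  const int hz = kz / 2, hx = kx / 2;
  const double l4 = std::log(4.0);
  // index pairs (e1 <= e2) of the upper triangle
  const int P1[10] = {0, 0, 0, 0, 1, 1, 1, 2, 2, 3};
  const int P2[10] = {0, 1, 2, 3, 1, 2, 3, 2, 3, 3};

  // integral images, one per unique entry: (nz + 1) x (nx + 1)
  const int sz = (nz + 1) * (nx + 1);
  std::vector<cplx> S(10 * sz);

  for (int y = 0; y < ny; ++y) {
    const R_xlen_t ybase = (R_xlen_t)nz * nx * y;
    for (int t = 0; t < 10; ++t) {
      cplx* St = &S[t * sz];
      const cplx* Ja = J + ybase + nvox * P1[t];
      const cplx* Jb = J + ybase + nvox * P2[t];
      for (int i = 0; i <= nz; ++i) St[i] = 0.0;
      for (int x = 0; x < nx; ++x) {
        const cplx* col_a = Ja + (R_xlen_t)nz * x;
        const cplx* col_b = Jb + (R_xlen_t)nz * x;
        cplx* Sc = St + (x + 1) * (nz + 1);
        const cplx* Sp = St + x * (nz + 1);
        cplx run = 0.0;
        Sc[0] = 0.0;
        for (int z = 0; z < nz; ++z) {
          run += col_a[z] * std::conj(col_b[z]);
          Sc[z + 1] = Sp[z + 1] + run;
        }
      }
    }
    for (int x = 0; x < nx; ++x) {
      const int x0 = std::max(0, x - hx), x1 = std::min(nx - 1, x + hx);
      for (int z = 0; z < nz; ++z) {
        const int z0 = std::max(0, z - hz), z1 = std::min(nz - 1, z + hz);
        const double n = (double)(z1 - z0 + 1) * (x1 - x0 + 1);
        cplx A[16];
        for (int t = 0; t < 10; ++t) {
          const cplx* St = &S[t * sz];
          const cplx w = (St[(x1 + 1) * (nz + 1) + z1 + 1]
                          - St[x0 * (nz + 1) + z1 + 1]
                          - St[(x1 + 1) * (nz + 1) + z0]
                          + St[x0 * (nz + 1) + z0]) / n;
          A[P1[t] + 4 * P2[t]] = w;
          A[P2[t] + 4 * P1[t]] = std::conj(w);
        }
        // keep diagonals exactly real
        for (int i = 0; i < 4; ++i) A[i + 4 * i] = A[i + 4 * i].real();

        const R_xlen_t vox = z + (R_xlen_t)nz * (x + (R_xlen_t)nx * y);
        if (keep_coherency)
          for (int k = 0; k < 16; ++k) Tp[16 * vox + k] = A[k];

        double scale = 4.0 * sigma2;
        for (int i = 0; i < 4; ++i) {
          scale += A[i + 4 * i].real();
          A[i + 4 * i] -= sigma2;
        }
        double ev4[4];
        eig4_hermitian(A, ev4, scale);
        double s = 0.0;
        for (int i = 0; i < 4; ++i) {
          if (ev4[i] < 0) ev4[i] = 0;
          s += ev4[i];
        }
        lsum[vox] = s;
        if (!(s > 0)) {
          H[vox] = NA_REAL;
          continue;
        }
        double h = 0.0;
        for (int i = 0; i < 4; ++i) {
          const double p = ev4[i] / s;
          if (p > 0) h -= p * std::log(p);
        }
        H[vox] = h / l4;
      }
    }
  }
  List out = List::create(_["H"] = H, _["lambda_sum"] = lsum);
  if (keep_coherency) out["T"] = Tout;
  return out;
}

// Separable running-median smoothing of a surface map (window truncated at
// the edges). Columns first, then rows.
// [[Rcpp::export]]
NumericMatrix median_smooth_cpp(NumericMatrix m, int window) {
  const int nr = m.nrow(), nc = m.ncol(), h = window / 2;
  NumericMatrix a(nr, nc), out(nr, nc);
  std::vector<double> buf;
  buf.reserve(window);
  auto med = [&buf]() {
    const size_t n = buf.size(), k = n / 2;
    std::nth_element(buf.begin(), buf.begin() + k, buf.end());
    double v = buf[k];
    if (n % 2 == 0) {
      std::nth_element(buf.begin(), buf.begin() + k - 1, buf.begin() + k);
      v = 0.5 * (v + buf[k - 1]);
    }
    return v;
  };
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      buf.clear();
      for (int r = std::max(0, i - h); r <= std::min(nr - 1, i + h); ++r)
        buf.push_back(m(r, j));
      a(i, j) = med();
    }
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < nc; ++j) {
      buf.clear();
      for (int c = std::max(0, j - h); c <= std::min(nc - 1, j + h); ++c)
        buf.push_back(a(i, c));
      out(i, j) = med();
    }
  return out;
}
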