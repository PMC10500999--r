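// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Matching Pursuit with a real Gabor dictionary.
//
// Dictionary atoms are Gaussian-windowed cosines
//   g(t) = w(t - tau) * cos(xi (t - tau) + phi),  w(s) = exp(-pi s^2 / sigma^2)
// with tau at every sample, sigma from the supplied ladder and carrier
// frequencies from the supplied grid.  Each iteration screens every
// (sigma, xi) pair over all centers tau at once through an FFT
// cross-correlation of the residual with the complex kernel
// w(s) exp(i xi s); the best candidate is then re-projected exactly in the
// time domain (two-dimensional projection onto the cosine and sine
// quadratures over the truncated support), so the energy bookkeeping
// Sum(atom energies) + residual energy = signal energy holds to float
// precision even for atoms clipped by the signal edges.
//
// Returns an atom table ordered by extraction (energy non-increasing for
// well-separated features), the residual, and the per-iteration residual
// energies.  tau is returned in samples (0-based); sigma in samples;
// freq in cycles per sample (multiply by the sampling rate for Hz).

static int next_pow2(int n) {
  int L = 1;
  while (L < n) L <<= 1;
  return L;
}

// single-entry cache of kernel FFTs and Gram diagonals: resampling
// procedures call the decomposition thousands of times with one
// dictionary, and rebuilding the kernel transforms dominates otherwise
struct DictCache {
  bool valid = false;
  int n = -1;
  std::vector<double> sig, frq;
  std::vector<int> half;
  arma::cx_mat Kfft;
  arma::vec Guu, Gvv, Guv;
};
static DictCache g_cache;

static bool cache_matches(int n, const NumericVector& s,
                          const NumericVector& f) {
  if (!g_cache.valid || g_cache.n != n ||
      (int) g_cache.sig.size() != s.size() ||
      (int) g_cache.frq.size() != f.size())
    return false;
  for (int i = 0; i < s.size(); ++i)
    if (g_cache.sig[i] != s[i]) return false;
  for (int i = 0; i < f.size(); ++i)
    if (g_cache.frq[i] != f[i]) return false;
  return true;
}

// [[Rcpp::export]]
List mp_decompose_cpp(NumericVector signal, NumericVector sigmaSamp,
                      NumericVector freqPerSamp, int maxAtoms,
                      double residFrac) {
  const int n = signal.size();
  if (n < 8) stop("signal too short");
  const int nSig = sigmaSamp.size(), nFrq = freqPerSamp.size();
  const int nCombo = nSig * nFrq;
  const int L = next_pow2(2 * n);

  arma::vec res(signal.begin(), n);
  const double sigEnergy = arma::dot(res, res);
  if (sigEnergy <= 0.0) {
    return List::create(_["atoms"] = NumericMatrix(0, 7),
                        _["residual"] = signal,
                        _["signalEnergy"] = 0.0,
                        _["residEnergy"] = NumericVector(0));
  }

  // kernel construction: support half-width per sigma, kernels and their
  // FFTs (reused from the cache when the dictionary is unchanged)
  if (!cache_matches(n, sigmaSamp, freqPerSamp)) {
    g_cache.valid = false;
    g_cache.n = n;
    g_cache.sig.assign(sigmaSamp.begin(), sigmaSamp.end());
    g_cache.frq.assign(freqPerSamp.begin(), freqPerSamp.end());
    g_cache.half.assign(nSig, 0);
    g_cache.Kfft.set_size(L, nCombo);
    g_cache.Guu.set_size(nCombo);
    g_cache.Gvv.set_size(nCombo);
    g_cache.Guv.set_size(nCombo);
    for (int si = 0; si < nSig; ++si) {
      const double sg = sigmaSamp[si];
      int S = (int) std::ceil(2.5 * sg);
      if (S > n - 1) S = n - 1;
      g_cache.half[si] = S;
      for (int fi = 0; fi < nFrq; ++fi) {
        const int ci = si * nFrq + fi;
        const double om = 2.0 * M_PI * freqPerSamp[fi];
        arma::cx_vec k(L, arma::fill::zeros);
        double guu = 0.0, gvv = 0.0, guv = 0.0;
        for (int s = -S; s <= S; ++s) {
          const double w = std::exp(-M_PI * (double) s * s / (sg * sg));
          const double c = std::cos(om * s), sn = std::sin(om * s);
          k[(s + L) % L] = std::complex<double>(w * c, w * sn);
          guu += w * w * c * c;
          gvv += w * w * sn * sn;
          guv += w * w * c * sn;
        }
        g_cache.Kfft.col(ci) = arma::fft(k);
        g_cache.Guu(ci) = guu; g_cache.Gvv(ci) = gvv; g_cache.Guv(ci) = guv;
      }
    }
    g_cache.valid = true;
  }
  const std::vector<int>& half = g_cache.half;
  const arma::cx_mat& Kfft = g_cache.Kfft;

  std::vector<double> aTau, aSig, aFrq, aAmp, aPhi, aEn;
  NumericVector residEn;
  double curEnergy = sigEnergy;

  for (int it = 0; it < maxAtoms; ++it) {
    // screen: FFT of residual, cross-correlate with every kernel
    arma::cx_vec rPad(L, arma::fill::zeros);
    for (int i = 0; i < n; ++i) rPad[i] = res[i];
    arma::cx_vec Rf = arma::fft(rPad);

    // cross-correlate the residual with every kernel in one batched
    // inverse transform
    arma::cx_mat M = arma::conj(Kfft);
    M.each_col() %= Rf;
    M = arma::ifft(M);

    double bestGain = -1.0;
    int bestCombo = -1, bestTau = -1;
    for (int ci = 0; ci < nCombo; ++ci) {
      const arma::cx_double* d = M.colptr(ci);
      const double guu = g_cache.Guu(ci), gvv = g_cache.Gvv(ci),
                   guv = g_cache.Guv(ci);
      const double det = guu * gvv - guv * guv;
      const bool twoD = det > 1e-10 * guu * (gvv > 0 ? gvv : 1.0);
      for (int tau = 0; tau < n; ++tau) {
        const double u = d[tau].real();
        const double v = -d[tau].imag();
        double gain;
        if (twoD) {
          gain = (gvv * u * u - 2.0 * guv * u * v + guu * v * v) / det;
        } else {
          gain = u * u / guu;
        }
        if (gain > bestGain) { bestGain = gain; bestCombo = ci; bestTau = tau; }
      }
    }
    if (bestCombo < 0) break;

    // exact projection at the winner on the truncated support
    const int si = bestCombo / nFrq, fi = bestCombo % nFrq;
    const double sg = sigmaSamp[si];
    const double om = 2.0 * M_PI * freqPerSamp[fi];
    const int S = half[si];
    const int lo = std::max(0, bestTau - S), hi = std::min(n - 1, bestTau + S);
    const int len = hi - lo + 1;
    arma::vec u(len), v(len);
    for (int t = lo; t <= hi; ++t) {
      const double s = (double) (t - bestTau);
      const double w = std::exp(-M_PI * s * s / (sg * sg));
      u[t - lo] = w * std::cos(om * s);
      v[t - lo] = w * std::sin(om * s);
    }
    arma::vec rloc = res.subvec(lo, hi);
    const double guu = arma::dot(u, u), gvv = arma::dot(v, v),
                 guv = arma::dot(u, v);
    const double cu = arma::dot(rloc, u), cv = arma::dot(rloc, v);
    const double det = guu * gvv - guv * guv;
    double alpha, beta;
    if (det > 1e-12 * std::max(guu, 1e-300) * std::max(gvv, 1e-300)) {
      alpha = (gvv * cu - guv * cv) / det;
      beta = (guu * cv - guv * cu) / det;
    } else {
      alpha = guu > 0 ? cu / guu : 0.0;
      beta = 0.0;
    }
    const double removed = alpha * cu + beta * cv;
    if (!(removed > 0.0)) break;

    res.subvec(lo, hi) -= alpha * u + beta * v;
    curEnergy -= removed;

    aTau.push_back((double) bestTau);
    aSig.push_back(sg);
    aFrq.push_back(freqPerSamp[fi]);
    aAmp.push_back(std::sqrt(alpha * alpha + beta * beta));
    aPhi.push_back(std::atan2(-beta, alpha));
    aEn.push_back(removed);
    residEn.push_back(curEnergy);

    if (curEnergy < residFrac * sigEnergy) break;
  }

  const int na = aTau.size();
  NumericMatrix atoms(na, 6);
  for (int i = 0; i < na; ++i) {
    atoms(i, 0) = aTau[i]; atoms(i, 1) = aSig[i]; atoms(i, 2) = aFrq[i];
    atoms(i, 3) = aAmp[i]; atoms(i, 4) = aPhi[i]; atoms(i, 5) = aEn[i];
  }
  colnames(atoms) = CharacterVector::create("tau", "sigma", "freq",
                                            "amplitude", "phase", "energy");
  return List::create(_["atoms"] = atoms,
                      _["residual"] = NumericVector(res.begin(), res.end()),
                      _["signalEnergy"] = sigEnergy,
                      _["residEnergy"] = residEn);
}
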