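#include <Rcpp.h>
using namespace Rcpp;

// Series evaluation of the compound Poisson-gamma (Tweedie, 1 < p < 2)
// log-density, following the Dunn & Smyth expansion
//   f(y) = (1/y) * sum_{j>=1} W_j(y, phi, p) * exp((y*theta - kappa(theta))/phi)
// with
//   log W_j = j*z(y) - lgamma(1 + j) - lgamma(j*alpha),
//   z(y)    = alpha*log(y) - alpha*log(p-1) - (1+alpha)*log(phi) - log(2-p),
//   alpha   = (2-p)/(p-1).
// At y = 0 the density has an atom exp(-lambda), lambda = mu^(2-p)/(phi*(2-p)).
// The series is summed outward from its largest term until terms fall below
// exp(-37) of the running maximum (relative tolerance well under 1e-10).

// cumulative lgamma tables over the series index j; alpha is constant within
// a call, so lgamma(1 + j) + lgamma(j * alpha) is tabulated once
struct LgammaTab {
  std::vector<double> lg;  // lg[j-1] = lgamma(1+j) + lgamma(j*alpha)
  double alpha;
  explicit LgammaTab(double a) : alpha(a) { extend(64); }
  void extend(size_t jmax) {
    size_t j = lg.size() + 1;
    lg.reserve(jmax);
    for (; j <= jmax; ++j)
      lg.push_back(lgamma(1.0 + (double) j) + lgamma((double) j * alpha));
  }
  inline double operator()(int j) {
    if ((size_t) j > lg.size()) extend(2 * (size_t) j);
    return lg[j - 1];
  }
};

// [[Rcpp::export(name = ".tw_logdens_cpp")]]
NumericVector tw_logdens_cpp(NumericVector y, NumericVector mu,
                             double phi, double p) {
  const int n = y.size();
  if (mu.size() != n) stop("y and mu must have equal length");
  if (!(p > 1.0 && p < 2.0)) stop("p must lie strictly in (1, 2)");
  if (!(phi > 0.0)) stop("phi must be positive");
  const double alpha = (2.0 - p) / (p - 1.0);
  const double zc = -alpha * std::log(p - 1.0)
                    - (1.0 + alpha) * std::log(phi) - std::log(2.0 - p);
  LgammaTab tab(alpha);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    const double mui = mu[i];
    if (!(mui > 0.0)) stop("mu must be positive");
    const double m2p = std::pow(mui, 2.0 - p);
    const double lambda = m2p / (phi * (2.0 - p));
    const double yi = y[i];
    if (yi < 0.0) { out[i] = R_NegInf; continue; }
    if (yi == 0.0) { out[i] = -lambda; continue; }
    // exponential-family part (y*theta - kappa(theta))/phi, theta tilted at mu
    const double logy = std::log(yi);
    const double dev = (yi * m2p / (mui * (1.0 - p)) - m2p / (2.0 - p)) / phi;
    const double z = alpha * logy + zc;
    // index of the dominant series term
    double jhat = std::pow(yi, 2.0 - p) / (phi * (2.0 - p));
    if (jhat < 1.0) jhat = 1.0;
    int j0 = (int) std::floor(jhat + 0.5);
    if (j0 < 1) j0 = 1;
    const double lwmax = (double) j0 * z - tab(j0);
    const double drop = 37.0;
    double sum = 1.0;  // terms rescaled by exp(-lwmax); j0 contributes 1
    for (int j = j0 + 1; ; ++j) {
      const double lw = (double) j * z - tab(j) - lwmax;
      sum += std::exp(lw);
      if (lw < -drop) break;
      if (j > 100000) stop("series failed to converge");
    }
    for (int j = j0 - 1; j >= 1; --j) {
      const double lw = (double) j * z - tab(j) - lwmax;
      sum += std::exp(lw);
      if (lw < -drop) break;
    }
    out[i] = lwmax + std::log(sum) - logy + dev;
  }
  return out;
}

// Total log-likelihood; avoids allocating the per-observation vector in the
// inner loop of the profile-likelihood fitter.
// [[Rcpp::export(name = ".tw_loglik_cpp")]]
double tw_loglik_cpp(NumericVector y, NumericVector mu, double phi, double p) {
  NumericVector ld = tw_logdens_cpp(y, mu, phi, p);
  double s = 0.0;
  for (int i = 0; i < ld.size(); ++i) s += ld[i];
  return s;
}
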