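#include <Rcpp.h>
using namespace Rcpp;

// One MCMC chain for the hierarchical %HRR-on-%VO2 model
//   y_ij ~ N(b0_i + b1_i x_ij, sigma2)
//   b0_i ~ N(muB0, sigma2Int),  b1_i ~ N(muB1, sigma2Slope)
// with normal hyperpriors on (muB0, muB1) and Gamma(shape, rate) priors
// on the dispersion components, placed on precisions (conjugate Gibbs)
// or literally on variances (slice sampling on the log variance).
// Operates on per-subject sufficient statistics; uses R's RNG so chains
// are reproducible via set.seed() on the R side.

static inline double gammaPrecDraw(double shape, double rate) {
  double tau = R::rgamma(shape, 1.0 / rate);
  if (tau < 1e-12) tau = 1e-12;  // numerical floor, no other regularization
  return tau;
}

// log target for a variance component under a Gamma(shape, rate) prior on
// the VARIANCE itself, with nEff Gaussian contributions of summed squares
// ss, as a function of u = log(s2) (Jacobian term included)
static inline double logVarTargetU(double u, double shape, double rate,
                                   double nEff, double ss) {
  const double s2 = exp(u);
  return shape * u - rate * s2 - 0.5 * nEff * u - 0.5 * ss * exp(-u);
}

// slice sampler on log(s2) (stepping out + shrinkage); w is the initial
// bracket width on the log scale
static inline double sliceVarStep(double s2, double shape, double rate,
                                  double nEff, double ss, double w) {
  const double u0 = log(s2);
  const double logy = logVarTargetU(u0, shape, rate, nEff, ss)
                    - R::exp_rand();
  double L = u0 - w * R::unif_rand();
  double Rr = L + w;
  for (int k = 0; k < 100 && logVarTargetU(L, shape, rate, nEff, ss) > logy;
       ++k) L -= w;
  for (int k = 0; k < 100 && logVarTargetU(Rr, shape, rate, nEff, ss) > logy;
       ++k) Rr += w;
  for (int k = 0; k < 200; ++k) {
    const double u1 = L + (Rr - L) * R::unif_rand();
    if (logVarTargetU(u1, shape, rate, nEff, ss) > logy) return exp(u1);
    if (u1 < u0) L = u1; else Rr = u1;
  }
  return s2;  // unreachable for a continuous target; defensive
}

// [[Rcpp::export(name = ".gibbsHierChain")]]
List gibbsHierChain(NumericVector ni, NumericVector Sx, NumericVector Sy,
                    NumericVector Sxx, NumericVector Sxy, NumericVector Syy,
                    int nIter, int burnIn, int thin,
                    double muB0PriorMean, double muB0PriorVar,
                    double muB1PriorMean, double muB1PriorVar,
                    double aResid, double rResid,
                    double aInt, double rInt,
                    double aSlope, double rSlope,
                    bool gammaOnVariance,
                    NumericVector b0Init, NumericVector b1Init,
                    double muB0Init, double muB1Init,
                    double sigma2Init, double sigma2IntInit,
                    double sigma2SlopeInit,
                    bool fixMuB0, bool fixMuB1, bool fixSigma2,
                    bool fixSigma2Int, bool fixSigma2Slope,
                    double sliceWidth) {
  const int m = ni.size();
  double Ntot = 0.0;
  for (int i = 0; i < m; ++i) Ntot += ni[i];

  std::vector<double> b0(b0Init.begin(), b0Init.end());
  std::vector<double> b1(b1Init.begin(), b1Init.end());
  double muB0 = muB0Init, muB1 = muB1Init;
  double s2 = sigma2Init, s2I = sigma2IntInit, s2S = sigma2SlopeInit;

  const int nSave = (nIter - burnIn) / thin;
  NumericMatrix pop(nSave, 5);
  NumericMatrix sb0(nSave, m), sb1(nSave, m);
  // unthinned post-burn-in population draws, kept for run-length
  // diagnostics that are defined on raw sampler output
  NumericMatrix raw(nIter - burnIn, 5);
  int row = 0;

  RNGScope scope;
  for (int it = 1; it <= nIter; ++it) {
    const double tau = 1.0 / s2, tauI = 1.0 / s2I, tauS = 1.0 / s2S;

    // joint bivariate update of each subject's (b0_i, b1_i)
    for (int i = 0; i < m; ++i) {
      const double p11 = tau * ni[i] + tauI;
      const double p12 = tau * Sx[i];
      const double p22 = tau * Sxx[i] + tauS;
      const double h1 = tau * Sy[i] + tauI * muB0;
      const double h2 = tau * Sxy[i] + tauS * muB1;
      const double det = p11 * p22 - p12 * p12;
      const double c11 = p22 / det, c22 = p11 / det, c12 = -p12 / det;
      const double m0 = c11 * h1 + c12 * h2;
      const double m1 = c12 * h1 + c22 * h2;
      const double l11 = sqrt(c11);
      const double l21 = c12 / l11;
      double l22sq = c22 - l21 * l21;
      if (l22sq < 0) l22sq = 0;
      const double z1 = R::norm_rand(), z2 = R::norm_rand();
      b0[i] = m0 + l11 * z1;
      b1[i] = m1 + l21 * z1 + sqrt(l22sq) * z2;
    }

    double sumB0 = 0, sumB1 = 0;
    for (int i = 0; i < m; ++i) { sumB0 += b0[i]; sumB1 += b1[i]; }

    if (!fixMuB0) {
      const double prec = m * tauI + 1.0 / muB0PriorVar;
      const double mean = (tauI * sumB0 + muB0PriorMean / muB0PriorVar) / prec;
      muB0 = mean + R::norm_rand() / sqrt(prec);
    }
    if (!fixMuB1) {
      const double prec = m * tauS + 1.0 / muB1PriorVar;
      const double mean = (tauS * sumB1 + muB1PriorMean / muB1PriorVar) / prec;
      muB1 = mean + R::norm_rand() / sqrt(prec);
    }

    double sse = 0, ssI = 0, ssS = 0;
    for (int i = 0; i < m; ++i) {
      sse += Syy[i] - 2.0 * b0[i] * Sy[i] - 2.0 * b1[i] * Sxy[i]
           + 2.0 * b0[i] * b1[i] * Sx[i]
           + b0[i] * b0[i] * ni[i] + b1[i] * b1[i] * Sxx[i];
      ssI += (b0[i] - muB0) * (b0[i] - muB0);
      ssS += (b1[i] - muB1) * (b1[i] - muB1);
    }
    if (sse < 0) sse = 0;

    if (!fixSigma2) {
      if (gammaOnVariance)
        s2 = sliceVarStep(s2, aResid, rResid, Ntot, sse, sliceWidth);
      else
        s2 = 1.0 / gammaPrecDraw(aResid + 0.5 * Ntot, rResid + 0.5 * sse);
    }
    if (!fixSigma2Int) {
      if (gammaOnVariance)
        s2I = sliceVarStep(s2I, aInt, rInt, (double)m, ssI, sliceWidth);
      else
        s2I = 1.0 / gammaPrecDraw(aInt + 0.5 * m, rInt + 0.5 * ssI);
    }
    if (!fixSigma2Slope) {
      if (gammaOnVariance)
        s2S = sliceVarStep(s2S, aSlope, rSlope, (double)m, ssS, sliceWidth);
      else
        s2S = 1.0 / gammaPrecDraw(aSlope + 0.5 * m, rSlope + 0.5 * ssS);
    }

    if (it > burnIn) {
      const int r = it - burnIn - 1;
      raw(r, 0) = muB0; raw(r, 1) = muB1;
      raw(r, 2) = s2;   raw(r, 3) = s2I; raw(r, 4) = s2S;
      if ((it - burnIn) % thin == 0) {
        pop(row, 0) = muB0; pop(row, 1) = muB1;
        pop(row, 2) = s2;   pop(row, 3) = s2I; pop(row, 4) = s2S;
        for (int i = 0; i < m; ++i) {
          sb0(row, i) = b0[i]; sb1(row, i) = b1[i];
        }
        ++row;
      }
    }
  }

  return List::create(_["pop"] = pop, _["b0"] = sb0, _["b1"] = sb1,
                      _["raw"] = raw);
}

// One MCMC chain for a single group mean with its own variance:
//   y_i ~ N(mu, sigma2), mu ~ N(m0, v0), Gamma(shape, rate) dispersion
//   prior on the precision (conjugate) or on the variance (slice-sampled).
// [[Rcpp::export(name = ".gibbsGroupChain")]]
List gibbsGroupChain(double n, double ybar, double ss,
                     int nIter, int burnIn, int thin,
                     double m0, double v0, double shape, double rate,
                     bool gammaOnVariance, bool fixSigma2,
                     double muInit, double sigma2Init, double sliceWidth) {
  double mu = muInit, s2 = sigma2Init;
  const int nSave = (nIter - burnIn) / thin;
  NumericVector muOut(nSave), s2Out(nSave);
  int row = 0;
  RNGScope scope;
  for (int it = 1; it <= nIter; ++it) {
    const double tau = 1.0 / s2;
    const double prec = n * tau + 1.0 / v0;
    const double mean = (tau * n * ybar + m0 / v0) / prec;
    mu = mean + R::norm_rand() / sqrt(prec);
    if (!fixSigma2) {
      const double dev = ss + n * (ybar - mu) * (ybar - mu);
      if (gammaOnVariance)
        s2 = sliceVarStep(s2, shape, rate, n, dev, sliceWidth);
      else
        s2 = 1.0 / gammaPrecDraw(shape + 0.5 * n, rate + 0.5 * dev);
    }
    if (it > burnIn && (it - burnIn) % thin == 0) {
      muOut[row] = mu; s2Out[row] = s2; ++row;
    }
  }
  return List::create(_["mu"] = muOut, _["sigma2"] = s2Out);
}
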