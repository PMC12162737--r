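// Texture-matrix feature engines. All functions take an integer level matrix
// `L` with values in 1..ng inside the region and NA outside, matching the
// DiscretizedRegion contract on the R side. Undefined features are returned
// as NaN and mapped to validity flags in R.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double LOG2 = std::log(2.0);

static inline double log2d(double x) { return std::log(x) / LOG2; }

// 8-neighbourhood offsets (Chebyshev distance 1)
static const int NB8R[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
static const int NB8C[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

static inline bool inside(const IntegerMatrix &L, int r, int c) {
  return r >= 0 && c >= 0 && r < L.nrow() && c < L.ncol() &&
         L(r, c) != NA_INTEGER;
}

// ---------------------------------------------------------------------------
// GLCM
// ---------------------------------------------------------------------------

// 24 features per offset row; NaN row when the offset yields no pixel pair.
// [[Rcpp::export]]
NumericMatrix cpp_glcm_features(IntegerMatrix L, int ng, IntegerMatrix offsets,
                                int dist, bool symmetric) {
  int na = offsets.nrow();
  NumericMatrix out(na, 24);
  for (int a = 0; a < na; a++) {
    int dr = offsets(a, 0) * dist, dc = offsets(a, 1) * dist;
    arma::mat C(ng, ng, arma::fill::zeros);
    double tot = 0.0;
    for (int r = 0; r < L.nrow(); r++) {
      for (int c = 0; c < L.ncol(); c++) {
        if (L(r, c) == NA_INTEGER) continue;
        int r2 = r + dr, c2 = c + dc;
        if (!inside(L, r2, c2)) continue;
        int i = L(r, c) - 1, j = L(r2, c2) - 1;
        C(i, j) += 1.0; tot += 1.0;
        if (symmetric) { C(j, i) += 1.0; tot += 1.0; }
      }
    }
    if (tot <= 0) {
      for (int f = 0; f < 24; f++) out(a, f) = NA_REAL;
      continue;
    }
    arma::mat p = C / tot;
    arma::vec px = arma::sum(p, 1);      // marginal over rows (level i)
    arma::rowvec py = arma::sum(p, 0);   // marginal over cols (level j)
    double mux = 0, muy = 0;
    for (int i = 0; i < ng; i++) { mux += (i + 1) * px(i); muy += (i + 1) * py(i); }
    double sigx2 = 0, sigy2 = 0;
    for (int i = 0; i < ng; i++) {
      sigx2 += px(i) * std::pow(i + 1 - mux, 2);
      sigy2 += py(i) * std::pow(i + 1 - muy, 2);
    }
    // diagonal (|i-j|) and cross-diagonal (i+j) distributions
    arma::vec km(ng, arma::fill::zeros);          // k = 0..ng-1
    arma::vec kp(2 * ng - 1, arma::fill::zeros);  // k = 2..2ng
    double autoc = 0, contrast = 0, shade = 0, prom = 0, tend = 0,
           id = 0, idm = 0, idmn = 0, idn = 0, energy = 0, hxy = 0,
           hxy1 = 0, maxp = 0, ssq = 0;
    for (int i = 0; i < ng; i++) {
      for (int j = 0; j < ng; j++) {
        double pij = p(i, j);
        if (pij <= 0) continue;
        double li = i + 1, lj = j + 1, d = li - lj, s = li + lj;
        km((int)std::abs(d)) += pij;
        kp((int)s - 2) += pij;
        autoc += pij * li * lj;
        contrast += pij * d * d;
        double cs = s - mux - muy;
        tend += pij * cs * cs;
        shade += pij * cs * cs * cs;
        prom += pij * cs * cs * cs * cs;
        id += pij / (1.0 + std::abs(d));
        idm += pij / (1.0 + d * d);
        idmn += pij / (1.0 + d * d / ((double)ng * ng));
        idn += pij / (1.0 + std::abs(d) / (double)ng);
        energy += pij * pij;
        hxy -= pij * log2d(pij);
        hxy1 -= pij * log2d(px(i) * py(j));
        if (pij > maxp) maxp = pij;
        ssq += pij * std::pow(li - mux, 2);
      }
    }
    double diffavg = 0, diffent = 0, invvar = 0;
    for (int k = 0; k < ng; k++) {
      if (km(k) <= 0) continue;
      diffavg += k * km(k);
      diffent -= km(k) * log2d(km(k));
      if (k >= 1) invvar += km(k) / ((double)k * k);
    }
    double diffvar = 0;
    for (int k = 0; k < ng; k++)
      if (km(k) > 0) diffvar += km(k) * std::pow(k - diffavg, 2);
    double sumavg = 0, sument = 0;
    for (int k = 0; k < 2 * ng - 1; k++) {
      if (kp(k) <= 0) continue;
      sumavg += (k + 2) * kp(k);
      sument -= kp(k) * log2d(kp(k));
    }
    double hx = 0, hy = 0, hxy2 = 0;
    for (int i = 0; i < ng; i++) {
      if (px(i) > 0) hx -= px(i) * log2d(px(i));
      if (py(i) > 0) hy -= py(i) * log2d(py(i));
      for (int j = 0; j < ng; j++)
        if (px(i) * py(j) > 0) hxy2 -= px(i) * py(j) * log2d(px(i) * py(j));
    }
    double corr = (sigx2 > 0 && sigy2 > 0)
                    ? (autoc - mux * muy) / std::sqrt(sigx2 * sigy2)
                    : NA_REAL;
    double hmax = std::max(hx, hy);
    double imc1 = (hmax > 0) ? (hxy - hxy1) / hmax : NA_REAL;
    double e2 = 1.0 - std::exp(-2.0 * (hxy2 - hxy));
    double imc2 = std::sqrt(std::max(e2, 0.0));
    // maximal correlation coefficient via second-largest eigenvalue of Q
    double mcc;
    std::vector<int> occ;
    for (int i = 0; i < ng; i++) if (px(i) > 0 && py(i) > 0) occ.push_back(i);
    int m = (int)occ.size();
    if (m <= 1) {
      mcc = 1.0;
    } else {
      arma::mat Q(m, m, arma::fill::zeros);
      for (int ii = 0; ii < m; ii++)
        for (int jj = 0; jj < m; jj++) {
          double q = 0;
          for (int kk = 0; kk < m; kk++)
            q += p(occ[ii], occ[kk]) * p(occ[jj], occ[kk]) /
                 (px(occ[ii]) * py(occ[kk]));
          Q(ii, jj) = q;
        }
      arma::cx_vec ev;
      bool ok = arma::eig_gen(ev, Q);
      if (ok) {
        arma::vec re = arma::sort(arma::real(ev), "descend");
        mcc = std::sqrt(std::max(re(1), 0.0));
      } else {
        mcc = NA_REAL;
      }
    }
    // alphabetical order within the class
    out(a, 0) = autoc;      out(a, 1) = prom;       out(a, 2) = shade;
    out(a, 3) = tend;       out(a, 4) = contrast;   out(a, 5) = corr;
    out(a, 6) = diffavg;    out(a, 7) = diffent;    out(a, 8) = diffvar;
    out(a, 9) = id;         out(a, 10) = idm;       out(a, 11) = idmn;
    out(a, 12) = idn;       out(a, 13) = imc1;      out(a, 14) = imc2;
    out(a, 15) = invvar;    out(a, 16) = mux;       out(a, 17) = energy;
    out(a, 18) = hxy;       out(a, 19) = mcc;       out(a, 20) = maxp;
    out(a, 21) = sumavg;    out(a, 22) = sument;    out(a, 23) = ssq;
  }
  return out;
}

// ---------------------------------------------------------------------------
// GLRLM
// ---------------------------------------------------------------------------

static void rl_features(const arma::mat &P, double np, double *out) {
  double nr = arma::accu(P);
  int ng = P.n_rows, ml = P.n_cols;
  arma::vec Ri = arma::sum(P, 1);
  arma::rowvec Cj = arma::sum(P, 0);
  double sre = 0, lre = 0, gln = 0, rln = 0, lgl = 0, hgl = 0,
         srlgl = 0, srhgl = 0, lrlgl = 0, lrhgl = 0, rent = 0;
  for (int i = 0; i < ng; i++) {
    double li2 = (double)(i + 1) * (i + 1);
    gln += Ri(i) * Ri(i);
    lgl += Ri(i) / li2;
    hgl += Ri(i) * li2;
    for (int j = 0; j < ml; j++) {
      double v = P(i, j);
      if (v <= 0) continue;
      double lj2 = (double)(j + 1) * (j + 1);
      srlgl += v / (li2 * lj2);
      srhgl += v * li2 / lj2;
      lrlgl += v * lj2 / li2;
      lrhgl += v * li2 * lj2;
      double pr = v / nr;
      rent -= pr * log2d(pr);
    }
  }
  for (int j = 0; j < ml; j++) {
    double lj2 = (double)(j + 1) * (j + 1);
    sre += Cj(j) / lj2;
    lre += Cj(j) * lj2;
    rln += Cj(j) * Cj(j);
  }
  double mug = 0, muj = 0;
  for (int i = 0; i < ng; i++) mug += (i + 1) * Ri(i) / nr;
  for (int j = 0; j < ml; j++) muj += (j + 1) * Cj(j) / nr;
  double glv = 0, rv = 0;
  for (int i = 0; i < ng; i++) glv += Ri(i) / nr * std::pow(i + 1 - mug, 2);
  for (int j = 0; j < ml; j++) rv += Cj(j) / nr * std::pow(j + 1 - muj, 2);
  // alphabetical order
  out[0] = gln / nr;        out[1] = gln / (nr * nr);  out[2] = glv;
  out[3] = hgl / nr;        out[4] = lre / nr;         out[5] = lrhgl / nr;
  out[6] = lrlgl / nr;      out[7] = lgl / nr;         out[8] = rent;
  out[9] = rln / nr;        out[10] = rln / (nr * nr); out[11] = nr / np;
  out[12] = rv;             out[13] = sre / nr;        out[14] = srhgl / nr;
  out[15] = srlgl / nr;
}

// 16 features per offset row.
// [[Rcpp::export]]
NumericMatrix cpp_glrlm_features(IntegerMatrix L, int ng,
                                 IntegerMatrix offsets) {
  int na = offsets.nrow();
  int nr_ = L.nrow(), nc_ = L.ncol();
  double np = 0;
  for (int r = 0; r < nr_; r++)
    for (int c = 0; c < nc_; c++)
      if (L(r, c) != NA_INTEGER) np += 1.0;
  int maxlen = std::max(nr_, nc_);
  NumericMatrix out(na, 16);
  for (int a = 0; a < na; a++) {
    int dr = offsets(a, 0), dc = offsets(a, 1);
    arma::mat P(ng, maxlen, arma::fill::zeros);
    for (int r = 0; r < nr_; r++) {
      for (int c = 0; c < nc_; c++) {
        if (L(r, c) == NA_INTEGER) continue;
        int pr = r - dr, pc = c - dc;  // run start iff predecessor differs
        if (inside(L, pr, pc) && L(pr, pc) == L(r, c)) continue;
        int len = 1, rr = r + dr, cc = c + dc;
        while (inside(L, rr, cc) && L(rr, cc) == L(r, c)) {
          len++; rr += dr; cc += dc;
        }
        P(L(r, c) - 1, len - 1) += 1.0;
      }
    }
    double f[16];
    rl_features(P, np, f);
    for (int k = 0; k < 16; k++) out(a, k) = f[k];
  }
  return out;
}

// ---------------------------------------------------------------------------
// connected components (8-connectivity) -- shared by GLSZM and segmentation
// ---------------------------------------------------------------------------

// Label 8-connected components of equal value among non-NA cells; 0 outside.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(IntegerMatrix L) {
  int nr = L.nrow(), nc = L.ncol();
  IntegerMatrix lab(nr, nc);
  std::fill(lab.begin(), lab.end(), 0);
  int next = 0;
  std::vector<std::pair<int, int> > stack;
  for (int r = 0; r < nr; r++) {
    for (int c = 0; c < nc; c++) {
      if (L(r, c) == NA_INTEGER || lab(r, c) != 0) continue;
      next++;
      int lev = L(r, c);
      stack.clear();
      stack.push_back(std::make_pair(r, c));
      lab(r, c) = next;
      while (!stack.empty()) {
        std::pair<int, int> q = stack.back();
        stack.pop_back();
        for (int k = 0; k < 8; k++) {
          int rr = q.first + NB8R[k], cc = q.second + NB8C[k];
          if (rr < 0 || cc < 0 || rr >= nr || cc >= nc) continue;
          if (L(rr, cc) == NA_INTEGER || lab(rr, cc) != 0) continue;
          if (L(rr, cc) != lev) continue;
          lab(rr, cc) = next;
          stack.push_back(std::make_pair(rr, cc));
        }
      }
    }
  }
  return lab;
}

// 16 GLSZM features (orientation-free).
// [[Rcpp::export]]
NumericVector cpp_glszm_features(IntegerMatrix L, int ng) {
  IntegerMatrix lab = cpp_label_components(L);
  int nr = L.nrow(), nc = L.ncol();
  int nzones = 0;
  for (int i = 0; i < nr * nc; i++) nzones = std::max(nzones, lab[i]);
  if (nzones == 0) {
    NumericVector bad(16, NA_REAL);
    return bad;
  }
  std::vector<int> zsize(nzones, 0), zlev(nzones, 0);
  double np = 0;
  for (int r = 0; r < nr; r++)
    for (int c = 0; c < nc; c++)
      if (lab(r, c) > 0) {
        zsize[lab(r, c) - 1]++;
        zlev[lab(r, c) - 1] = L(r, c);
        np += 1.0;
      }
  int maxsz = 0;
  for (int z = 0; z < nzones; z++) maxsz = std::max(maxsz, zsize[z]);
  arma::mat P(ng, maxsz, arma::fill::zeros);
  for (int z = 0; z < nzones; z++) P(zlev[z] - 1, zsize[z] - 1) += 1.0;
  double f[16];
  rl_features(P, np, f);  // identical algebra on (level, size) counts
  NumericVector out(16);
  for (int k = 0; k < 16; k++) out[k] = f[k];
  return out;
}

// ---------------------------------------------------------------------------
// GLDM
// ---------------------------------------------------------------------------

// 14 features; dependence = number of 8-neighbours with |level diff| <= alpha,
// matrix column index = dependence + 1.
// [[Rcpp::export]]
NumericVector cpp_gldm_features(IntegerMatrix L, int ng, int alpha) {
  int nr = L.nrow(), nc = L.ncol();
  arma::mat P(ng, 9, arma::fill::zeros);
  double nz = 0;
  for (int r = 0; r < nr; r++) {
    for (int c = 0; c < nc; c++) {
      if (L(r, c) == NA_INTEGER) continue;
      int dep = 0;
      for (int k = 0; k < 8; k++) {
        int rr = r + NB8R[k], cc = c + NB8C[k];
        if (inside(L, rr, cc) && std::abs(L(rr, cc) - L(r, c)) <= alpha) dep++;
      }
      P(L(r, c) - 1, dep) += 1.0;
      nz += 1.0;
    }
  }
  if (nz == 0) return NumericVector(14, NA_REAL);
  arma::vec Ri = arma::sum(P, 1);
  arma::rowvec Cj = arma::sum(P, 0);
  double sde = 0, lde = 0, gln = 0, dn = 0, lgl = 0, hgl = 0,
         sdlgl = 0, sdhgl = 0, ldlgl = 0, ldhgl = 0, dent = 0;
  for (int i = 0; i < ng; i++) {
    double li2 = (double)(i + 1) * (i + 1);
    gln += Ri(i) * Ri(i);
    lgl += Ri(i) / li2;
    hgl += Ri(i) * li2;
    for (int j = 0; j < 9; j++) {
      double v = P(i, j);
      if (v <= 0) continue;
      double lj2 = (double)(j + 1) * (j + 1);
      sdlgl += v / (li2 * lj2);
      sdhgl += v * li2 / lj2;
      ldlgl += v * lj2 / li2;
      ldhgl += v * li2 * lj2;
      double pv = v / nz;
      dent -= pv * log2d(pv);
    }
  }
  for (int j = 0; j < 9; j++) {
    double lj2 = (double)(j + 1) * (j + 1);
    sde += Cj(j) / lj2;
    lde += Cj(j) * lj2;
    dn += Cj(j) * Cj(j);
  }
  double mug = 0, muj = 0;
  for (int i = 0; i < ng; i++) mug += (i + 1) * Ri(i) / nz;
  for (int j = 0; j < 9; j++) muj += (j + 1) * Cj(j) / nz;
  double glv = 0, dv = 0;
  for (int i = 0; i < ng; i++) glv += Ri(i) / nz * std::pow(i + 1 - mug, 2);
  for (int j = 0; j < 9; j++) dv += Cj(j) / nz * std::pow(j + 1 - muj, 2);
  NumericVector out(14);
  // alphabetical order
  out[0] = dent;            out[1] = dn / nz;        out[2] = dn / (nz * nz);
  out[3] = dv;              out[4] = gln / nz;       out[5] = glv;
  out[6] = hgl / nz;        out[7] = lde / nz;       out[8] = ldhgl / nz;
  out[9] = ldlgl / nz;      out[10] = lgl / nz;      out[11] = sde / nz;
  out[12] = sdhgl / nz;     out[13] = sdlgl / nz;
  return out;
}

// ---------------------------------------------------------------------------
// NGTDM
// ---------------------------------------------------------------------------

// 5 features; pixels with no in-region neighbour are excluded from Nvp.
// [[Rcpp::export]]
NumericVector cpp_ngtdm_features(IntegerMatrix L, int ng) {
  int nr = L.nrow(), nc = L.ncol();
  arma::vec ni(ng, arma::fill::zeros), si(ng, arma::fill::zeros);
  double nvp = 0;
  for (int r = 0; r < nr; r++) {
    for (int c = 0; c < nc; c++) {
      if (L(r, c) == NA_INTEGER) continue;
      double sum = 0; int cnt = 0;
      for (int k = 0; k < 8; k++) {
        int rr = r + NB8R[k], cc = c + NB8C[k];
        if (inside(L, rr, cc)) { sum += L(rr, cc); cnt++; }
      }
      if (cnt == 0) continue;
      int i = L(r, c) - 1;
      ni(i) += 1.0;
      si(i) += std::abs((double)L(r, c) - sum / cnt);
      nvp += 1.0;
    }
  }
  NumericVector out(5);
  if (nvp == 0) {
    for (int k = 0; k < 5; k++) out[k] = NA_REAL;
    return out;
  }
  arma::vec pi = ni / nvp;
  int ngp = 0;
  for (int i = 0; i < ng; i++) if (pi(i) > 0) ngp++;
  double sum_ps = 0, sum_s = 0;
  for (int i = 0; i < ng; i++) { sum_ps += pi(i) * si(i); sum_s += si(i); }
  double coarse = (sum_ps > 0) ? 1.0 / sum_ps : 1e6;
  double contrast = 0;
  if (ngp > 1) {
    double acc = 0;
    for (int i = 0; i < ng; i++)
      for (int j = 0; j < ng; j++)
        if (pi(i) > 0 && pi(j) > 0)
          acc += pi(i) * pi(j) * std::pow((double)(i - j), 2);
    contrast = acc / (ngp * (ngp - 1.0)) * (sum_s / nvp);
  }
  double bden = 0, cplx = 0, sacc = 0;
  for (int i = 0; i < ng; i++) {
    if (pi(i) <= 0) continue;
    for (int j = 0; j < ng; j++) {
      if (pi(j) <= 0) continue;
      bden += std::abs((i + 1) * pi(i) - (j + 1) * pi(j));
      cplx += std::abs((double)(i - j)) *
              (pi(i) * si(i) + pi(j) * si(j)) / (pi(i) + pi(j));
      sacc += (pi(i) + pi(j)) * std::pow((double)(i - j), 2);
    }
  }
  double busy = (bden > 0) ? sum_ps / bden : 0.0;
  double strength = (sum_s > 0) ? sacc / sum_s : 0.0;
  out[0] = busy; out[1] = coarse; out[2] = cplx / nvp;
  out[3] = contrast; out[4] = strength;
  return out;
}
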