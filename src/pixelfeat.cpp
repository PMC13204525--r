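// Single-pass per-pixel feature extraction for the 2D intratumoral-
// heterogeneity branch: for every in-mask pixel, the 104 descriptors of its
// 3x3 in-mask neighborhood (19 first-order, 24 GLCM, 16 GLRLM, 16 GLSZM,
// 14 GLDM, 5 NGTDM, 10 2D shape). Formulas mirror the package's R feature
// functions exactly (the R path serves as the reference implementation in
// tests); this C++ path exists because the score needs hundreds of window
// evaluations per case.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static const double LOG2 = std::log(2.0);

// R quantile type 7 on a sorted vector
static double q7(const std::vector<double> &s, double p) {
  int n = s.size();
  if (n == 1) return s[0];
  double h = (n - 1) * p;
  int lo = (int)std::floor(h);
  int hi = lo + 1 < n ? lo + 1 : lo;
  return s[lo] + (h - lo) * (s[hi] - s[lo]);
}

struct Win {
  double v[9];      // window values (in-mask only)
  int lx[9], ly[9]; // local coords 0..2
  int n;
  int bin[9];       // discretized 1..nbins
  int grid[9];      // 3x3 local grid of bins, 0 = outside
};

static void discretize(Win &w, int nbins) {
  double lo = w.v[0], hi = w.v[0];
  for (int i = 1; i < w.n; ++i) { lo = std::min(lo, w.v[i]); hi = std::max(hi, w.v[i]); }
  for (int i = 0; i < 9; ++i) w.grid[i] = 0;
  if (hi - lo <= 0) {
    for (int i = 0; i < w.n; ++i) w.bin[i] = 1;
  } else {
    double step = (hi - lo) / nbins;
    for (int i = 0; i < w.n; ++i) {
      int b = (int)std::floor((w.v[i] - lo) / step) + 1;
      if (b > nbins) b = nbins;
      w.bin[i] = b;
    }
  }
  for (int i = 0; i < w.n; ++i) w.grid[w.lx[i] + 3 * w.ly[i]] = w.bin[i];
}

static void first_order(const Win &w, int nbins, double pixel_area, double *out) {
  int n = w.n;
  std::vector<double> s(w.v, w.v + n);
  std::sort(s.begin(), s.end());
  double sum = 0, sum2 = 0;
  for (int i = 0; i < n; ++i) { sum += w.v[i]; sum2 += w.v[i] * w.v[i]; }
  double mu = sum / n;
  double m2 = 0, m3 = 0, m4 = 0, mad = 0;
  for (int i = 0; i < n; ++i) {
    double d = w.v[i] - mu;
    m2 += d * d; m3 += d * d * d; m4 += d * d * d * d; mad += std::fabs(d);
  }
  m2 /= n; m3 /= n; m4 /= n; mad /= n;
  double p10 = q7(s, 0.10), p25 = q7(s, 0.25), p75 = q7(s, 0.75), p90 = q7(s, 0.90);
  double med = q7(s, 0.5);
  double lo = s[0], hi = s[n - 1];
  // binned probabilities
  double ent = 0, unif = 1;
  if (hi - lo > 0) {
    std::vector<int> cnt(nbins, 0);
    double step = (hi - lo) / nbins;
    for (int i = 0; i < n; ++i) {
      int b = (int)std::floor((w.v[i] - lo) / step);
      if (b >= nbins) b = nbins - 1;
      cnt[b]++;
    }
    ent = 0; unif = 0;
    for (int b = 0; b < nbins; ++b)
      if (cnt[b]) {
        double p = (double)cnt[b] / n;
        ent -= p * std::log(p) / LOG2;
        unif += p * p;
      }
  }
  // robust MAD over [p10, p90]
  double rsum = 0; int rn = 0;
  for (int i = 0; i < n; ++i) if (w.v[i] >= p10 && w.v[i] <= p90) { rsum += w.v[i]; ++rn; }
  double rmad = 0;
  if (rn > 0) {
    double rmu = rsum / rn;
    for (int i = 0; i < n; ++i)
      if (w.v[i] >= p10 && w.v[i] <= p90) rmad += std::fabs(w.v[i] - rmu);
    rmad /= rn;
  }
  int k = 0;
  out[k++] = sum2;                       // Energy
  out[k++] = pixel_area * sum2;          // TotalEnergy
  out[k++] = ent;                        // Entropy
  out[k++] = lo;                         // Minimum
  out[k++] = p10;                        // Percentile10
  out[k++] = p90;                        // Percentile90
  out[k++] = hi;                         // Maximum
  out[k++] = mu;                         // Mean
  out[k++] = med;                        // Median
  out[k++] = p75 - p25;                  // InterquartileRange
  out[k++] = hi - lo;                    // Range
  out[k++] = mad;                        // MeanAbsoluteDeviation
  out[k++] = rmad;                       // RobustMeanAbsoluteDeviation
  out[k++] = std::sqrt(sum2 / n);        // RootMeanSquared
  out[k++] = m2 > 0 ? m3 / std::pow(m2, 1.5) : 0; // Skewness
  out[k++] = m2 > 0 ? m4 / (m2 * m2) : 0;         // Kurtosis
  out[k++] = m2;                         // Variance
  out[k++] = unif;                       // Uniformity
  out[k++] = std::sqrt(m2);              // StandardDeviation
}

static void glcm_feats(const Win &w, int nbins, double *out) {
  const int D[4][2] = {{1, 0}, {0, 1}, {1, 1}, {1, -1}};
  arma::mat P(nbins, nbins, arma::fill::zeros);
  for (int d = 0; d < 4; ++d)
    for (int y = 0; y < 3; ++y)
      for (int x = 0; x < 3; ++x) {
        int a = w.grid[x + 3 * y];
        if (a <= 0) continue;
        int x2 = x + D[d][0], y2 = y + D[d][1];
        if (x2 < 0 || x2 > 2 || y2 < 0 || y2 > 2) continue;
        int b = w.grid[x2 + 3 * y2];
        if (b <= 0) continue;
        P(a - 1, b - 1) += 1; P(b - 1, a - 1) += 1;
      }
  double tot = arma::accu(P);
  if (tot <= 0) { for (int i = 0; i < 24; ++i) out[i] = 0; return; }
  P /= tot;
  arma::vec px = arma::sum(P, 1);
  double mux = 0, sx2 = 0;
  for (int i = 0; i < nbins; ++i) mux += (i + 1) * px(i);
  for (int i = 0; i < nbins; ++i) sx2 += (i + 1 - mux) * (i + 1 - mux) * px(i);
  std::vector<double> pd(nbins, 0.0), ps(2 * nbins + 1, 0.0);
  double autoc = 0, clp = 0, cls = 0, clt = 0, contrast = 0, corr_num = 0;
  double je = 0, jent = 0, idm = 0, idmn = 0, idn = 0, id_ = 0, invvar = 0, maxp = 0;
  double hxy1 = 0;
  for (int i = 0; i < nbins; ++i)
    for (int j = 0; j < nbins; ++j) {
      double p = P(i, j);
      int di = i - j;
      if (p > 0) {
        double ii = i + 1, jj = j + 1;
        autoc += ii * jj * p;
        double cc = ii + jj - 2 * mux;
        clp += cc * cc * cc * cc * p; cls += cc * cc * cc * p; clt += cc * cc * p;
        contrast += di * di * p;
        corr_num += ii * jj * p;
        je += p * p;
        jent -= p * std::log(p) / LOG2;
        double pp = px(i) * px(j);
        if (pp > 0) hxy1 -= p * std::log(pp) / LOG2;
        if (p > maxp) maxp = p;
        pd[std::abs(di)] += p;
        ps[i + j + 2] += p;
        if (di != 0) invvar += p / (di * di);
      }
      idm += p / (1.0 + di * di);
      idmn += p / (1.0 + (double)di * di / (nbins * nbins));
      id_ += p / (1.0 + std::abs(di));
      idn += p / (1.0 + (double)std::abs(di) / nbins);
    }
  double da = 0, dent = 0, dvar = 0;
  for (int q = 0; q < nbins; ++q) da += q * pd[q];
  for (int q = 0; q < nbins; ++q) {
    if (pd[q] > 0) dent -= pd[q] * std::log(pd[q]) / LOG2;
    dvar += (q - da) * (q - da) * pd[q];
  }
  double sa = 0, sent = 0;
  for (int q = 2; q <= 2 * nbins; ++q) {
    sa += q * ps[q];
    if (ps[q] > 0) sent -= ps[q] * std::log(ps[q]) / LOG2;
  }
  double hx = 0, hxy2 = 0;
  for (int i = 0; i < nbins; ++i)
    if (px(i) > 0) hx -= px(i) * std::log(px(i)) / LOG2;
  for (int i = 0; i < nbins; ++i)
    for (int j = 0; j < nbins; ++j) {
      double pp = px(i) * px(j);
      if (pp > 0) hxy2 -= pp * std::log(pp) / LOG2;
    }
  double imc1 = hx > 0 ? (jent - hxy1) / hx : 0;
  double imc2 = 0;
  {
    double dd = 1 - std::exp(-2 * (hxy2 - jent));
    if (dd > 0) imc2 = std::sqrt(dd);
  }
  double corr = sx2 > 1e-12 ? (corr_num - mux * mux) / sx2 : 1.0;
  // MCC: sqrt of second-largest eigenvalue of Q
  double mcc = 1.0;
  {
    arma::uvec keep = arma::find(px > 0);
    if (keep.n_elem >= 2) {
      arma::mat Ps = P.submat(keep, keep);
      arma::vec pxs = px(keep);
      arma::mat A = Ps.each_col() / pxs;       // P(i,k)/px_i
      arma::mat Bm = Ps.each_row() / pxs.t();  // P(j,k)/px_k
      arma::mat Q = A * Bm.t();
      arma::cx_vec ev = arma::eig_gen(Q);
      arma::vec evr = arma::sort(arma::real(ev), "descend");
      mcc = (evr.n_elem > 1 && evr(1) > 0) ? std::sqrt(evr(1)) : 0.0;
    }
  }
  int k = 0;
  out[k++] = autoc; out[k++] = mux; out[k++] = clp; out[k++] = cls;
  out[k++] = clt; out[k++] = contrast; out[k++] = corr; out[k++] = da;
  out[k++] = dent; out[k++] = dvar; out[k++] = je; out[k++] = jent;
  out[k++] = imc1; out[k++] = imc2; out[k++] = idm; out[k++] = idmn;
  out[k++] = id_; out[k++] = idn; out[k++] = invvar; out[k++] = maxp;
  out[k++] = sa; out[k++] = sent; out[k++] = sx2; out[k++] = mcc;
}

static void glrlm_feats(const Win &w, int nbins, double *out) {
  const int D[4][2] = {{1, 0}, {0, 1}, {1, 1}, {1, -1}};
  // runs up to length 3
  double R[8][3];
  for (int i = 0; i < nbins; ++i) for (int l = 0; l < 3; ++l) R[i][l] = 0;
  for (int d = 0; d < 4; ++d)
    for (int y = 0; y < 3; ++y)
      for (int x = 0; x < 3; ++x) {
        int a = w.grid[x + 3 * y];
        if (a <= 0) continue;
        int xp = x - D[d][0], yp = y - D[d][1];
        if (xp >= 0 && xp <= 2 && yp >= 0 && yp <= 2 && w.grid[xp + 3 * yp] == a)
          continue;
        int len = 1, xc = x + D[d][0], yc = y + D[d][1];
        while (xc >= 0 && xc <= 2 && yc >= 0 && yc <= 2 &&
               w.grid[xc + 3 * yc] == a) { ++len; xc += D[d][0]; yc += D[d][1]; }
        if (len > 3) len = 3;
        R[a - 1][len - 1] += 1;
      }
  double nr = 0;
  for (int i = 0; i < nbins; ++i) for (int l = 0; l < 3; ++l) nr += R[i][l];
  if (nr <= 0) { for (int i = 0; i < 16; ++i) out[i] = 0; return; }
  double sre = 0, lre = 0, gln = 0, rln = 0, rp, glv = 0, rv = 0, rent = 0;
  double lgl = 0, hgl = 0, srl = 0, srh = 0, lrl = 0, lrh = 0;
  double mug = 0, mul = 0;
  for (int i = 0; i < nbins; ++i) {
    double ri = 0;
    for (int l = 0; l < 3; ++l) ri += R[i][l];
    gln += ri * ri;
  }
  for (int l = 0; l < 3; ++l) {
    double rl = 0;
    for (int i = 0; i < nbins; ++i) rl += R[i][l];
    rln += rl * rl;
  }
  for (int i = 0; i < nbins; ++i)
    for (int l = 0; l < 3; ++l) {
      double r = R[i][l];
      if (r <= 0) continue;
      double ii = i + 1, ll = l + 1, p = r / nr;
      sre += r / (ll * ll); lre += r * ll * ll;
      lgl += r / (ii * ii); hgl += r * ii * ii;
      srl += r / (ii * ii * ll * ll); srh += r * ii * ii / (ll * ll);
      lrl += r * ll * ll / (ii * ii); lrh += r * ii * ii * ll * ll;
      mug += ii * p; mul += ll * p;
      rent -= p * std::log(p) / LOG2;
    }
  for (int i = 0; i < nbins; ++i)
    for (int l = 0; l < 3; ++l) {
      double p = R[i][l] / nr;
      glv += (i + 1 - mug) * (i + 1 - mug) * p;
      rv += (l + 1 - mul) * (l + 1 - mul) * p;
    }
  rp = nr / (w.n * 4.0);
  int k = 0;
  out[k++] = sre / nr; out[k++] = lre / nr; out[k++] = gln / nr;
  out[k++] = gln / (nr * nr); out[k++] = rln / nr; out[k++] = rln / (nr * nr);
  out[k++] = rp; out[k++] = glv; out[k++] = rv; out[k++] = rent;
  out[k++] = lgl / nr; out[k++] = hgl / nr; out[k++] = srl / nr;
  out[k++] = srh / nr; out[k++] = lrl / nr; out[k++] = lrh / nr;
}

static void zones_8conn(const Win &w, std::vector<int> &zg, std::vector<int> &zs) {
  int lab[9] = {0};
  int stack[9];
  int cur = 0;
  for (int p = 0; p < 9; ++p) {
    if (w.grid[p] <= 0 || lab[p]) continue;
    int v = w.grid[p];
    ++cur;
    int top = 0;
    stack[top++] = p; lab[p] = cur;
    int size = 0;
    while (top) {
      int q = stack[--top];
      ++size;
      int qx = q % 3, qy = q / 3;
      for (int oy = -1; oy <= 1; ++oy)
        for (int ox = -1; ox <= 1; ++ox) {
          if (!ox && !oy) continue;
          int x2 = qx + ox, y2 = qy + oy;
          if (x2 < 0 || x2 > 2 || y2 < 0 || y2 > 2) continue;
          int r = x2 + 3 * y2;
          if (w.grid[r] == v && !lab[r]) { lab[r] = cur; stack[top++] = r; }
        }
    }
    zg.push_back(v); zs.push_back(size);
  }
}

static void glszm_feats(const Win &w, double *out) {
  std::vector<int> zg, zs;
  zones_8conn(w, zg, zs);
  int nz = zg.size();
  if (nz == 0) { for (int i = 0; i < 16; ++i) out[i] = 0; return; }
  double sae = 0, lae = 0, lgl = 0, hgl = 0, sal = 0, sah = 0, lal = 0, lah = 0;
  double mug = 0, mus = 0;
  for (int z = 0; z < nz; ++z) {
    double g = zg[z], s = zs[z];
    sae += 1 / (s * s); lae += s * s; lgl += 1 / (g * g); hgl += g * g;
    sal += 1 / (g * g * s * s); sah += g * g / (s * s);
    lal += s * s / (g * g); lah += g * g * s * s;
    mug += g; mus += s;
  }
  mug /= nz; mus /= nz;
  double glv = 0, zv = 0;
  for (int z = 0; z < nz; ++z) {
    glv += (zg[z] - mug) * (zg[z] - mug);
    zv += (zs[z] - mus) * (zs[z] - mus);
  }
  // gray / size marginal counts and cell entropy
  double gln = 0, szn = 0, zent = 0;
  for (int z = 0; z < nz; ++z) {
    int cg = 0, cs = 0, cell = 0;
    bool first_cell = true;
    for (int q = 0; q < nz; ++q) {
      if (zg[q] == zg[z]) ++cg;
      if (zs[q] == zs[z]) ++cs;
      if (zg[q] == zg[z] && zs[q] == zs[z]) {
        ++cell;
        if (q < z) first_cell = false;
      }
    }
    gln += cg; szn += cs; // sums counts once per zone -> sum of counts^2
    if (first_cell) {
      double p = (double)cell / nz;
      zent -= p * std::log(p) / LOG2;
    }
  }
  int k = 0;
  out[k++] = sae / nz; out[k++] = lae / nz; out[k++] = gln / nz;
  out[k++] = gln / ((double)nz * nz); out[k++] = szn / nz;
  out[k++] = szn / ((double)nz * nz); out[k++] = (double)nz / w.n;
  out[k++] = glv / nz; out[k++] = zv / nz; out[k++] = zent;
  out[k++] = lgl / nz; out[k++] = hgl / nz; out[k++] = sal / nz;
  out[k++] = sah / nz; out[k++] = lal / nz; out[k++] = lah / nz;
}

static void gldm_feats(const Win &w, double *out) {
  // alpha = 0, 8-neighborhood; dependence size = count + 1
  double D[8][9];
  for (int i = 0; i < 8; ++i) for (int j = 0; j < 9; ++j) D[i][j] = 0;
  for (int y = 0; y < 3; ++y)
    for (int x = 0; x < 3; ++x) {
      int a = w.grid[x + 3 * y];
      if (a <= 0) continue;
      int dep = 0;
      for (int oy = -1; oy <= 1; ++oy)
        for (int ox = -1; ox <= 1; ++ox) {
          if (!ox && !oy) continue;
          int x2 = x + ox, y2 = y + oy;
          if (x2 < 0 || x2 > 2 || y2 < 0 || y2 > 2) continue;
          if (w.grid[x2 + 3 * y2] == a) ++dep;
        }
      D[a - 1][dep] += 1;
    }
  double nd = 0;
  for (int i = 0; i < 8; ++i) for (int j = 0; j < 9; ++j) nd += D[i][j];
  if (nd <= 0) { for (int i = 0; i < 14; ++i) out[i] = 0; return; }
  double sde = 0, lde = 0, gln = 0, dn = 0, glv = 0, dv = 0, dent = 0;
  double lgl = 0, hgl = 0, sdl = 0, sdh = 0, ldl = 0, ldh = 0;
  double mug = 0, muj = 0;
  for (int i = 0; i < 8; ++i) {
    double ri = 0;
    for (int j = 0; j < 9; ++j) ri += D[i][j];
    gln += ri * ri;
  }
  for (int j = 0; j < 9; ++j) {
    double rj = 0;
    for (int i = 0; i < 8; ++i) rj += D[i][j];
    dn += rj * rj;
  }
  for (int i = 0; i < 8; ++i)
    for (int j = 0; j < 9; ++j) {
      double d = D[i][j];
      if (d <= 0) continue;
      double ii = i + 1, jj = j + 1, p = d / nd;
      sde += d / (jj * jj); lde += d * jj * jj;
      lgl += d / (ii * ii); hgl += d * ii * ii;
      sdl += d / (ii * ii * jj * jj); sdh += d * ii * ii / (jj * jj);
      ldl += d * jj * jj / (ii * ii); ldh += d * ii * ii * jj * jj;
      mug += ii * p; muj += jj * p;
      dent -= p * std::log(p) / LOG2;
    }
  for (int i = 0; i < 8; ++i)
    for (int j = 0; j < 9; ++j) {
      double p = D[i][j] / nd;
      glv += (i + 1 - mug) * (i + 1 - mug) * p;
      dv += (j + 1 - muj) * (j + 1 - muj) * p;
    }
  int k = 0;
  out[k++] = sde / nd; out[k++] = lde / nd; out[k++] = gln / nd;
  out[k++] = dn / nd; out[k++] = dn / (nd * nd); out[k++] = glv;
  out[k++] = dv; out[k++] = dent; out[k++] = lgl / nd; out[k++] = hgl / nd;
  out[k++] = sdl / nd; out[k++] = sdh / nd; out[k++] = ldl / nd;
  out[k++] = ldh / nd;
}

static void ngtdm_feats(const Win &w, int nbins, double *out) {
  std::vector<double> si(nbins, 0.0), ni(nbins, 0.0);
  for (int y = 0; y < 3; ++y)
    for (int x = 0; x < 3; ++x) {
      int a = w.grid[x + 3 * y];
      if (a <= 0) continue;
      double sum = 0; int cnt = 0;
      for (int oy = -1; oy <= 1; ++oy)
        for (int ox = -1; ox <= 1; ++ox) {
          if (!ox && !oy) continue;
          int x2 = x + ox, y2 = y + oy;
          if (x2 < 0 || x2 > 2 || y2 < 0 || y2 > 2) continue;
          int b = w.grid[x2 + 3 * y2];
          if (b > 0) { sum += b; ++cnt; }
        }
      ni[a - 1] += 1;
      if (cnt > 0) si[a - 1] += std::fabs(a - sum / cnt);
    }
  double N = 0;
  for (int i = 0; i < nbins; ++i) N += ni[i];
  if (N <= 0) { for (int i = 0; i < 5; ++i) out[i] = 0; return; }
  std::vector<double> p(nbins);
  std::vector<int> act;
  double stot = 0, denom_coarse = 0;
  for (int i = 0; i < nbins; ++i) {
    p[i] = ni[i] / N;
    stot += si[i];
    denom_coarse += p[i] * si[i];
    if (p[i] > 0) act.push_back(i);
  }
  int ngp = act.size();
  double coarse = denom_coarse > 0 ? 1 / denom_coarse : 1e6;
  double contrast = 0;
  if (ngp > 1) {
    double s1 = 0;
    for (size_t a = 0; a < act.size(); ++a)
      for (size_t b = 0; b < act.size(); ++b) {
        double di = act[a] - (double)act[b];
        s1 += p[act[a]] * p[act[b]] * di * di;
      }
    contrast = s1 / (ngp * (ngp - 1.0)) * stot / N;
  }
  double denom_busy = 0, cmplx = 0, strength = 0;
  for (size_t a = 0; a < act.size(); ++a)
    for (size_t b = 0; b < act.size(); ++b) {
      int i = act[a], j = act[b];
      double ii = i + 1, jj = j + 1;
      denom_busy += std::fabs(ii * p[i] - jj * p[j]);
      cmplx += std::fabs(ii - jj) * (p[i] * si[i] + p[j] * si[j]) / (p[i] + p[j]);
      strength += (p[i] + p[j]) * (ii - jj) * (ii - jj);
    }
  double busy = denom_busy > 0 ? denom_coarse / denom_busy : 0;
  cmplx /= N;
  strength = (stot > 0 && ngp > 1) ? strength / stot : 0;
  out[0] = coarse; out[1] = contrast; out[2] = busy; out[3] = cmplx;
  out[4] = strength;
}

static void shape2d(const Win &w, double sx, double sy, double *out) {
  int n = w.n;
  double area = n * sx * sy;
  // perimeter: exposed edges of the in-window mask
  double per = 0;
  bool m[9] = {false};
  for (int i = 0; i < n; ++i) m[w.lx[i] + 3 * w.ly[i]] = true;
  for (int y = 0; y < 3; ++y)
    for (int x = 0; x < 3; ++x) {
      if (!m[x + 3 * y]) continue;
      if (x == 0 || !m[x - 1 + 3 * y]) per += sy;
      if (x == 2 || !m[x + 1 + 3 * y]) per += sy;
      if (y == 0 || !m[x + 3 * (y - 1)]) per += sx;
      if (y == 2 || !m[x + 3 * (y + 1)]) per += sx;
    }
  // covariance eigenvalues of physical coordinates
  double mx = 0, my = 0;
  for (int i = 0; i < n; ++i) { mx += w.lx[i] * sx; my += w.ly[i] * sy; }
  mx /= n; my /= n;
  double cxx = 0, cyy = 0, cxy = 0;
  for (int i = 0; i < n; ++i) {
    double dx = w.lx[i] * sx - mx, dy = w.ly[i] * sy - my;
    cxx += dx * dx; cyy += dy * dy; cxy += dx * dy;
  }
  double e1 = 0, e2 = 0;
  if (n > 2) {
    cxx /= (n - 1); cyy /= (n - 1); cxy /= (n - 1);
    double tr = cxx + cyy, det = cxx * cyy - cxy * cxy;
    double disc = std::sqrt(std::max(tr * tr / 4 - det, 0.0));
    e1 = std::max(tr / 2 + disc, 0.0); e2 = std::max(tr / 2 - disc, 0.0);
  }
  double dia = 0;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double dx = (w.lx[i] - w.lx[j]) * sx, dy = (w.ly[i] - w.ly[j]) * sy;
      double d = dx * dx + dy * dy;
      if (d > dia) dia = d;
    }
  double sph = per > 0 ? 2 * std::sqrt(M_PI * area) / per : 0;
  int k = 0;
  out[k++] = area; out[k++] = area; out[k++] = per; out[k++] = per / area;
  out[k++] = sph; out[k++] = sph > 0 ? 1 / sph : 0;
  out[k++] = std::sqrt(dia);
  out[k++] = 4 * std::sqrt(e1); out[k++] = 4 * std::sqrt(e2);
  out[k++] = e1 > 0 ? std::sqrt(e2 / e1) : 0;
}

// [[Rcpp::export]]
NumericMatrix cpp_pixel_features(NumericVector img, IntegerVector mask,
                                 IntegerVector dims, int nbins,
                                 NumericVector spacing) {
  int nx = dims[0], ny = dims[1];
  std::vector<int> px, py;
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x)
      if (mask[x + nx * y] > 0) { px.push_back(x); py.push_back(y); }
  int np = px.size();
  NumericMatrix out(np, 104);
  double pixel_area = spacing[0] * spacing[1];
  for (int t = 0; t < np; ++t) {
    Win w; w.n = 0;
    for (int oy = -1; oy <= 1; ++oy)
      for (int ox = -1; ox <= 1; ++ox) {
        int x2 = px[t] + ox, y2 = py[t] + oy;
        if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny) continue;
        if (mask[x2 + nx * y2] <= 0) continue;
        w.v[w.n] = img[x2 + nx * y2];
        w.lx[w.n] = ox + 1; w.ly[w.n] = oy + 1;
        ++w.n;
      }
    discretize(w, nbins);
    double *row = new double[104];
    first_order(w, nbins, pixel_area, row);
    glcm_feats(w, nbins, row + 19);
    glrlm_feats(w, nbins, row + 43);
    glszm_feats(w, row + 59);
    gldm_feats(w, row + 75);
    ngtdm_feats(w, nbins, row + 89);
    shape2d(w, spacing[0], spacing[1], row + 94);
    for (int j = 0; j < 104; ++j) out(t, j) = row[j];
    delete[] row;
  }
  return out;
}
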