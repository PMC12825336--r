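#include <Rcpp.h>
using namespace Rcpp;

// Explicit conservative Cahn-Hilliard sub-steps on an nx x nz order-parameter
// field. Matrix rows index the channel axis x (periodic), columns the channel
// cross-section z (no-flux walls, mirror ghost cells for both eta and mu so
// the wall flux vanishes identically and global mass is conserved to
// round-off).
//
// Per sub-step:
//   mu  = RT*log(eta/(1-eta)) + L*(1-2*eta) - alpha*lap(eta)
//   eta += dtau*Mc/dx^2 * div(grad mu)          (flux-difference form)
//
// eta is updated IN PLACE (the R caller passes a private copy). Values
// leaving (0,1) are clamped back to the guard interval and counted when the
// excursion is below 10*eps; a larger excursion aborts and reports the
// offending sub-step (1-based), leaving eta at the last completed sub-step.
// [[Rcpp::export]]
List ch_substeps_cpp(NumericMatrix eta, int nsub, double dtau, double Mc,
                     double RT, double L, double alpha, double dxm,
                     double eps) {
  const int nx = eta.nrow(), nz = eta.ncol();
  NumericMatrix mu(nx, nz), etan(nx, nz);
  const double inv_dx2 = 1.0 / (dxm * dxm);
  const double coef = dtau * Mc * inv_dx2;
  int clamped = 0, abort_sub = 0;

  for (int s = 0; s < nsub; ++s) {
    for (int j = 0; j < nz; ++j) {
      const int jm = (j == 0) ? 0 : j - 1;          // mirror ghost at walls
      const int jp = (j == nz - 1) ? nz - 1 : j + 1;
      for (int i = 0; i < nx; ++i) {
        const int im = (i == 0) ? nx - 1 : i - 1;   // periodic along x
        const int ip = (i == nx - 1) ? 0 : i + 1;
        const double e = eta(i, j);
        const double ec =
            e < eps ? eps : (e > 1.0 - eps ? 1.0 - eps : e);
        const double lap =
            (eta(im, j) + eta(ip, j) + eta(i, jm) + eta(i, jp) - 4.0 * e) *
            inv_dx2;
        mu(i, j) =
            RT * std::log(ec / (1.0 - ec)) + L * (1.0 - 2.0 * e) - alpha * lap;
      }
    }
    bool bad = false;
    for (int j = 0; j < nz && !bad; ++j) {
      const int jm = (j == 0) ? 0 : j - 1;
      const int jp = (j == nz - 1) ? nz - 1 : j + 1;
      for (int i = 0; i < nx; ++i) {
        const int im = (i == 0) ? nx - 1 : i - 1;
        const int ip = (i == nx - 1) ? 0 : i + 1;
        // sum of face fluxes; ghost mirror makes wall-face terms vanish
        const double div = (mu(ip, j) - mu(i, j)) - (mu(i, j) - mu(im, j)) +
                           (mu(i, jp) - mu(i, j)) - (mu(i, j) - mu(i, jm));
        double e = eta(i, j) + coef * div;
        if (e <= 0.0 || e >= 1.0) {
          if (e > -10.0 * eps && e < 1.0 + 10.0 * eps) {
            e = (e <= 0.0) ? eps : 1.0 - eps;
            ++clamped;
          } else {
            bad = true;
            break;
          }
        }
        etan(i, j) = e;
      }
    }
    if (bad) {
      abort_sub = s + 1;
      break;
    }
    std::copy(etan.begin(), etan.end(), eta.begin());
  }
  return List::create(_["clamped"] = clamped, _["abort_sub"] = abort_sub);
}

static int uf_find(std::vector<int> &parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]];
    x = parent[x];
  }
  return x;
}

static void uf_union(std::vector<int> &parent, int a, int b) {
  int ra = uf_find(parent, a), rb = uf_find(parent, b);
  if (ra != rb) parent[rb] = ra;
}

// 8-connected component labelling of a binary mask (two-pass union-find).
// Rows are the channel axis x; with periodic_x the first and last rows are
// treated as adjacent (including diagonals). Labels are consecutive integers
// starting at 1, 0 is background.
// [[Rcpp::export]]
IntegerMatrix label8_cpp(LogicalMatrix mask, bool periodic_x) {
  const int nx = mask.nrow(), nz = mask.ncol();
  IntegerMatrix lab(nx, nz);
  std::vector<int> parent(1, 0);  // parent[0] unused
  int next = 0;

  for (int j = 0; j < nz; ++j) {
    for (int i = 0; i < nx; ++i) {
      if (!mask(i, j)) continue;
      int l = 0;
      if (i > 0 && lab(i - 1, j)) l = lab(i - 1, j);
      if (j > 0) {
        for (int di = -1; di <= 1; ++di) {
          const int ii = i + di;
          if (ii < 0 || ii >= nx) continue;
          const int ln = lab(ii, j - 1);
          if (ln) {
            if (l)
              uf_union(parent, l, ln);
            else
              l = ln;
          }
        }
      }
      if (!l) {
        l = ++next;
        parent.push_back(l);
      }
      lab(i, j) = l;
    }
  }
  if (periodic_x && nx > 1) {
    for (int j = 0; j < nz; ++j) {
      if (!lab(nx - 1, j)) continue;
      for (int dj = -1; dj <= 1; ++dj) {
        const int jj = j + dj;
        if (jj < 0 || jj >= nz) continue;
        if (lab(0, jj)) uf_union(parent, lab(nx - 1, j), lab(0, jj));
      }
    }
  }
  std::vector<int> remap(next + 1, 0);
  int nfinal = 0;
  for (int k = 0; k < nx * nz; ++k) {
    if (!lab[k]) continue;
    const int r = uf_find(parent, lab[k]);
    if (!remap[r]) remap[r] = ++nfinal;
    lab[k] = remap[r];
  }
  return lab;
}
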