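#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Moore neighborhood (26 offsets), fixed order so runs are reproducible.
static const int NOFF = 26;
static int OFFX[NOFF], OFFY[NOFF], OFFZ[NOFF];
static bool offs_ready = false;
static void init_offsets() {
  if (offs_ready) return;
  int k = 0;
  for (int dx = -1; dx <= 1; ++dx)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dz = -1; dz <= 1; ++dz) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        OFFX[k] = dx; OFFY[k] = dy; OFFZ[k] = dz; ++k;
      }
  offs_ready = true;
}

static inline int lin(int x, int y, int z, int nx) {
  return x + nx * (y + nx * z);
}

// Fisher-Yates shuffle of 0..n-1 driven by R's RNG.
static std::vector<int> shuffled_indices(int n) {
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  for (int i = n - 1; i > 0; --i) {
    int j = (int)std::floor(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(idx[i], idx[j]);
  }
  return idx;
}

// One iteration of the cell phase: divisions, migrations, senescent death.
// Cells are parallel vectors; positions are 0-based coarse-lattice indices.
// phenotype: 0 = stem, 1 = progenitor. oxy is the oxygenated-site mask
// (length nx^3); a cell is hypoxic iff !oxy at its site.
// [[Rcpp::export]]
List cpp_cells_phase(IntegerVector x, IntegerVector y, IntegerVector z,
                     IntegerVector phenotype, IntegerVector divs,
                     IntegerVector high_mig, IntegerVector senescent,
                     IntegerVector hypoxic,
                     LogicalVector oxy, int nx,
                     double p_div, double stem_div_prob,
                     double stem_symmetric_prob, double p_high_mig_daughter,
                     int div_lim, double hypoxic_div_factor,
                     double steps_high, double steps_low,
                     double senescent_death_prob,
                     bool do_divide, bool do_migrate, bool do_death) {
  init_offsets();
  int n0 = x.size();
  std::vector<int> cx(x.begin(), x.end()), cy(y.begin(), y.end()),
      cz(z.begin(), z.end()), ph(phenotype.begin(), phenotype.end()),
      dv(divs.begin(), divs.end()), hm(high_mig.begin(), high_mig.end()),
      sn(senescent.begin(), senescent.end()),
      hx(hypoxic.begin(), hypoxic.end());

  std::vector<char> occ((size_t)nx * nx * nx, 0);
  for (int i = 0; i < n0; ++i) occ[lin(cx[i], cy[i], cz[i], nx)] = 1;

  int n_divisions = 0;

  // --- divisions (snapshot of cells present at phase start, shuffled order)
  std::vector<int> order;
  int empt[NOFF];
  if (do_divide) order = shuffled_indices(n0);
  for (int oi = 0; oi < (do_divide ? n0 : 0); ++oi) {
    int i = order[oi];
    if (sn[i]) continue;
    double p = (ph[i] == 0) ? stem_div_prob : p_div;
    if (hx[i]) p *= hypoxic_div_factor;
    if (p <= 0.0 || unif_rand() >= p) continue;
    int ne = 0;
    for (int k = 0; k < NOFF; ++k) {
      int tx = cx[i] + OFFX[k], ty = cy[i] + OFFY[k], tz = cz[i] + OFFZ[k];
      if (tx < 0 || ty < 0 || tz < 0 || tx >= nx || ty >= nx || tz >= nx)
        continue;
      int l = lin(tx, ty, tz, nx);
      if (!occ[l]) empt[ne++] = k;
    }
    if (ne == 0) continue;  // spatial inhibition: no room, no division
    int k = empt[(int)std::floor(unif_rand() * ne) % ne];
    int tx = cx[i] + OFFX[k], ty = cy[i] + OFFY[k], tz = cz[i] + OFFZ[k];

    int d_ph, d_dv;
    if (ph[i] == 0) {  // stem parent
      bool symmetric = unif_rand() < stem_symmetric_prob;
      d_ph = symmetric ? 0 : 1;
      d_dv = 0;
    } else {  // progenitor parent: symmetric division, shared division count
      dv[i] += 1;
      if (dv[i] >= div_lim) sn[i] = 1;
      d_ph = 1;
      d_dv = dv[i];
    }
    int d_sn = (d_ph == 1 && d_dv >= div_lim) ? 1 : 0;
    int d_hm = (unif_rand() < p_high_mig_daughter) ? 1 : 0;
    int l = lin(tx, ty, tz, nx);
    occ[l] = 1;
    cx.push_back(tx); cy.push_back(ty); cz.push_back(tz);
    ph.push_back(d_ph); dv.push_back(d_dv); hm.push_back(d_hm);
    sn.push_back(d_sn); hx.push_back(oxy[l] ? 0 : 1);
    ++n_divisions;
  }

  // --- migrations (all cells incl. new daughters, fresh shuffled order)
  int n1 = (int)cx.size();
  if (do_migrate) order = shuffled_indices(n1);
  for (int oi = 0; oi < (do_migrate ? n1 : 0); ++oi) {
    int i = order[oi];
    double e = (hm[i] || hx[i]) ? steps_high : steps_low;
    int k_steps = (int)std::floor(e);
    double frac = e - k_steps;
    if (frac > 0 && unif_rand() < frac) ++k_steps;
    for (int s = 0; s < k_steps; ++s) {
      int k = (int)std::floor(unif_rand() * NOFF) % NOFF;
      int tx = cx[i] + OFFX[k], ty = cy[i] + OFFY[k], tz = cz[i] + OFFZ[k];
      if (tx < 0 || ty < 0 || tz < 0 || tx >= nx || ty >= nx || tz >= nx)
        continue;  // would leave the domain: rejected
      int l = lin(tx, ty, tz, nx);
      if (occ[l]) continue;  // occupied: rejected
      occ[lin(cx[i], cy[i], cz[i], nx)] = 0;
      occ[l] = 1;
      cx[i] = tx; cy[i] = ty; cz[i] = tz;
    }
  }

  // --- senescent death
  int n_deaths = 0;
  std::vector<char> keep(n1, 1);
  for (int i = 0; i < (do_death ? n1 : 0); ++i) {
    if (sn[i] && unif_rand() < senescent_death_prob) {
      keep[i] = 0;
      ++n_deaths;
    }
  }
  int n2 = n1 - n_deaths;
  IntegerVector rx(n2), ry(n2), rz(n2), rph(n2), rdv(n2), rhm(n2), rsn(n2),
      rhx(n2);
  int j = 0;
  for (int i = 0; i < n1; ++i) {
    if (!keep[i]) continue;
    rx[j] = cx[i]; ry[j] = cy[i]; rz[j] = cz[i]; rph[j] = ph[i];
    rdv[j] = dv[i]; rhm[j] = hm[i]; rsn[j] = sn[i]; rhx[j] = hx[i];
    ++j;
  }
  return List::create(
      _["x"] = rx, _["y"] = ry, _["z"] = rz, _["phenotype"] = rph,
      _["divs"] = rdv, _["high_mig"] = rhm, _["senescent"] = rsn,
      _["hypoxic"] = rhx, _["n_divisions"] = n_divisions,
      _["n_deaths"] = n_deaths);
}

// Mark coarse-lattice sites within radius_um (Euclidean, physical units) of
// any of the given fine-lattice vessel sites. Coarse site i sits at
// coarse_um * i; fine site j at fine_um * j. Returns the updated mask.
// [[Rcpp::export]]
LogicalVector cpp_oxy_dilate(IntegerVector vx, IntegerVector vy,
                             IntegerVector vz, LogicalVector oxy, int nx,
                             double coarse_um, double fine_um,
                             double radius_um) {
  LogicalVector out = clone(oxy);
  double r2 = radius_um * radius_um;
  int m = vx.size();
  for (int s = 0; s < m; ++s) {
    double px = fine_um * vx[s], py = fine_um * vy[s], pz = fine_um * vz[s];
    int xlo = (int)std::ceil((px - radius_um) / coarse_um);
    int xhi = (int)std::floor((px + radius_um) / coarse_um);
    int ylo = (int)std::ceil((py - radius_um) / coarse_um);
    int yhi = (int)std::floor((py + radius_um) / coarse_um);
    int zlo = (int)std::ceil((pz - radius_um) / coarse_um);
    int zhi = (int)std::floor((pz + radius_um) / coarse_um);
    if (xlo < 0) xlo = 0; if (ylo < 0) ylo = 0; if (zlo < 0) zlo = 0;
    if (xhi > nx - 1) xhi = nx - 1;
    if (yhi > nx - 1) yhi = nx - 1;
    if (zhi > nx - 1) zhi = nx - 1;
    for (int ix = xlo; ix <= xhi; ++ix) {
      double ddx = coarse_um * ix - px; ddx *= ddx;
      if (ddx > r2) continue;
      for (int iy = ylo; iy <= yhi; ++iy) {
        double ddy = coarse_um * iy - py; ddy *= ddy;
        if (ddx + ddy > r2) continue;
        for (int iz = zlo; iz <= zhi; ++iz) {
          double ddz = coarse_um * iz - pz;
          if (ddx + ddy + ddz * ddz <= r2) out[lin(ix, iy, iz, nx)] = true;
        }
      }
    }
  }
  return out;
}
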