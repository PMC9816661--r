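#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Angiogenesis engine for one iteration: sprout initiation along mature
// vessels, chemotactic tip migration, anastomosis. Positions are 0-based:
// cells on the coarse (tumor) lattice, vessel sites on the fine lattice.
// All distances are physical (um). Deterministic given R's RNG state: the
// only random draws are the per-site branching Bernoullis, taken in mature
// site order.

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Nearest cell (subset given by `eligible`) to a physical point, by ring
// search over the coarse occupancy grid. Returns cell index or -1. Exact:
// keeps scanning rings until no closer cell is geometrically possible.
// Ties broken by lowest (x, y, z) lexicographic order of the cell site.
static int nearest_cell(double px, double py, double pz,
                        const std::vector<int> &occ, int nx, double coarse_um,
                        const IntegerMatrix &cells,
                        const std::vector<char> &eligible, double max_um,
                        double *dist_out) {
  int cx = clampi((int)std::floor(px / coarse_um + 0.5), 0, nx - 1);
  int cy = clampi((int)std::floor(py / coarse_um + 0.5), 0, nx - 1);
  int cz = clampi((int)std::floor(pz / coarse_um + 0.5), 0, nx - 1);
  int best = -1;
  double best_d2 = R_PosInf;
  int bx = 0, by = 0, bz = 0;
  int rmax = nx;  // full lattice worst case
  for (int r = 0; r <= rmax; ++r) {
    double ring_min = (r - 1) * coarse_um;  // conservative lower bound
    if (best >= 0 && ring_min * ring_min > best_d2) break;
    if (best < 0 && ring_min > max_um) break;
    int xlo = clampi(cx - r, 0, nx - 1), xhi = clampi(cx + r, 0, nx - 1);
    int ylo = clampi(cy - r, 0, nx - 1), yhi = clampi(cy + r, 0, nx - 1);
    int zlo = clampi(cz - r, 0, nx - 1), zhi = clampi(cz + r, 0, nx - 1);
    for (int x = xlo; x <= xhi; ++x) {
      for (int y = ylo; y <= yhi; ++y) {
        for (int z = zlo; z <= zhi; ++z) {
          int ring = std::max(std::max(std::abs(x - cx), std::abs(y - cy)),
                              std::abs(z - cz));
          if (ring != r) continue;
          int ci = occ[x + nx * (y + nx * z)];
          if (ci < 0 || !eligible[ci]) continue;
          double dx = coarse_um * x - px, dy = coarse_um * y - py,
                 dz = coarse_um * z - pz;
          double d2 = dx * dx + dy * dy + dz * dz;
          bool better = d2 < best_d2;
          if (!better && d2 == best_d2 && best >= 0) {
            // lexicographic tie-break on the cell site
            if (x < bx || (x == bx && (y < by || (y == by && z < bz))))
              better = true;
          }
          if (better) {
            best_d2 = d2;
            best = ci;
            bx = x; by = y; bz = z;
          }
        }
      }
    }
  }
  if (dist_out) *dist_out = best >= 0 ? std::sqrt(best_d2) : R_PosInf;
  return best;
}

// [[Rcpp::export]]
List cpp_vasc_iter(IntegerMatrix mat_sites, IntegerVector mat_line,
                   IntegerMatrix csites, IntegerVector csite_chain,
                   IntegerVector ch_parent, IntegerMatrix ch_origin,
                   LogicalVector ch_open, IntegerMatrix ch_tip,
                   IntegerMatrix cell_pos, IntegerVector cell_hyp,
                   int nx, int nf, double coarse_um, double fine_um,
                   double max_branch_prob, double vegf_um, int tip_steps,
                   double anast_um,
                   bool do_branch, bool do_migrate, bool do_anast) {
  int n_mat = mat_sites.nrow();
  int n_cell = cell_pos.nrow();
  int k0 = ch_parent.size();

  // coarse occupancy: cell index per coarse site (-1 empty)
  std::vector<int> occ((size_t)nx * nx * nx, -1);
  std::vector<char> any_cell(n_cell, 1), hyp_cell(n_cell, 0);
  bool have_hyp = false;
  for (int i = 0; i < n_cell; ++i) {
    occ[cell_pos(i, 0) + nx * (cell_pos(i, 1) + nx * cell_pos(i, 2))] = i;
    if (cell_hyp[i]) { hyp_cell[i] = 1; have_hyp = true; }
  }

  // --- working copies of chain state
  std::vector<int> parent(ch_parent.begin(), ch_parent.end());
  std::vector<int> orx, ory, orz, tpx, tpy, tpz;
  std::vector<char> open_fl;
  orx.reserve(k0); ory.reserve(k0); orz.reserve(k0);
  for (int i = 0; i < k0; ++i) {
    orx.push_back(ch_origin(i, 0)); ory.push_back(ch_origin(i, 1));
    orz.push_back(ch_origin(i, 2));
    tpx.push_back(ch_tip(i, 0)); tpy.push_back(ch_tip(i, 1));
    tpz.push_back(ch_tip(i, 2));
    open_fl.push_back(ch_open[i] ? 1 : 0);
  }

  // new sites appended this iteration (chain ids are 1-based)
  std::vector<int> nsx, nsy, nsz, ns_chain;

  // --- branching: one attempt per mature fine-lattice site.
  // d_min per site is computed bucket-wise: mature sites grouped by coarse
  // cell, hypoxic candidates gathered by ring search around the bucket, and
  // the exact per-site minimum taken over the candidates.
  if (do_branch && have_hyp && max_branch_prob > 0 && n_mat > 0) {
    int refine = nf / nx;
    // hypoxic bounding box (coarse coords) for a cheap reject
    int hlo[3] = {nx, nx, nx}, hhi[3] = {-1, -1, -1};
    for (int i = 0; i < n_cell; ++i) {
      if (!hyp_cell[i]) continue;
      for (int a = 0; a < 3; ++a) {
        hlo[a] = std::min(hlo[a], cell_pos(i, a));
        hhi[a] = std::max(hhi[a], cell_pos(i, a));
      }
    }
    double offmax = coarse_um;  // site-to-bucket-centre slack
    int ring_cap = (int)std::ceil(vegf_um / coarse_um) + 3;
    std::vector<double> dmin(n_mat, R_PosInf);
    // bucket sites by coarse cell
    std::vector<int> bkey(n_mat);
    for (int s = 0; s < n_mat; ++s) {
      int cx = clampi((int)std::floor((double)mat_sites(s, 0) / refine + 0.5),
                      0, nx - 1);
      int cy = clampi((int)std::floor((double)mat_sites(s, 1) / refine + 0.5),
                      0, nx - 1);
      int cz = clampi((int)std::floor((double)mat_sites(s, 2) / refine + 0.5),
                      0, nx - 1);
      bkey[s] = cx + nx * (cy + nx * cz);
    }
    std::vector<int> sort_idx(n_mat);
    for (int s = 0; s < n_mat; ++s) sort_idx[s] = s;
    std::stable_sort(sort_idx.begin(), sort_idx.end(),
                     [&](int a, int b) { return bkey[a] < bkey[b]; });
    std::vector<int> cand;
    int u = 0;
    while (u < n_mat) {
      int v = u;
      while (v < n_mat && bkey[sort_idx[v]] == bkey[sort_idx[u]]) ++v;
      int key = bkey[sort_idx[u]];
      int cx = key % nx, cy = (key / nx) % nx, cz = key / (nx * nx);
      // cheap reject: bucket far from the hypoxic bounding box
      int gap = 0;
      gap = std::max(gap, hlo[0] - cx); gap = std::max(gap, cx - hhi[0]);
      gap = std::max(gap, hlo[1] - cy); gap = std::max(gap, cy - hhi[1]);
      gap = std::max(gap, hlo[2] - cz); gap = std::max(gap, cz - hhi[2]);
      if ((gap - 1) * coarse_um > vegf_um + 2 * offmax) { u = v; continue; }
      cand.clear();
      double dmin_center = R_PosInf;
      for (int r = 0; r <= ring_cap + nx; ++r) {
        double ring_min = (r - 1) * coarse_um;
        if (std::isfinite(dmin_center) && ring_min > dmin_center + 2 * offmax)
          break;
        if (!std::isfinite(dmin_center) && ring_min > vegf_um + 2 * offmax)
          break;
        int xlo = clampi(cx - r, 0, nx - 1), xhi = clampi(cx + r, 0, nx - 1);
        int ylo = clampi(cy - r, 0, nx - 1), yhi = clampi(cy + r, 0, nx - 1);
        int zlo = clampi(cz - r, 0, nx - 1), zhi = clampi(cz + r, 0, nx - 1);
        for (int x = xlo; x <= xhi; ++x)
          for (int y = ylo; y <= yhi; ++y)
            for (int z = zlo; z <= zhi; ++z) {
              int ring = std::max(std::max(std::abs(x - cx), std::abs(y - cy)),
                                  std::abs(z - cz));
              if (ring != r) continue;
              int ci = occ[x + nx * (y + nx * z)];
              if (ci < 0 || !hyp_cell[ci]) continue;
              cand.push_back(ci);
              double ddx = coarse_um * (x - cx), ddy = coarse_um * (y - cy),
                     ddz = coarse_um * (z - cz);
              double dc = std::sqrt(ddx * ddx + ddy * ddy + ddz * ddz);
              dmin_center = std::min(dmin_center, dc);
            }
      }
      if (!cand.empty()) {
        for (int w = u; w < v; ++w) {
          int s = sort_idx[w];
          double px = fine_um * mat_sites(s, 0),
                 py = fine_um * mat_sites(s, 1),
                 pz = fine_um * mat_sites(s, 2);
          double best = R_PosInf;
          for (size_t q = 0; q < cand.size(); ++q) {
            int ci = cand[q];
            double ddx = coarse_um * cell_pos(ci, 0) - px,
                   ddy = coarse_um * cell_pos(ci, 1) - py,
                   ddz = coarse_um * cell_pos(ci, 2) - pz;
            double d2 = ddx * ddx + ddy * ddy + ddz * ddz;
            if (d2 < best) best = d2;
          }
          dmin[s] = std::sqrt(best);
        }
      }
      u = v;
    }
    // Bernoulli attempts in mature-site order (fixed RNG draw order)
    for (int s = 0; s < n_mat; ++s) {
      double d = dmin[s];
      if (!(d < vegf_um)) continue;
      double p = max_branch_prob * (1.0 - d / vegf_um);
      if (unif_rand() >= p) continue;
      parent.push_back(mat_line[s]);
      orx.push_back(mat_sites(s, 0)); ory.push_back(mat_sites(s, 1));
      orz.push_back(mat_sites(s, 2));
      tpx.push_back(mat_sites(s, 0)); tpy.push_back(mat_sites(s, 1));
      tpz.push_back(mat_sites(s, 2));
      open_fl.push_back(1);
      int id = (int)parent.size();  // 1-based chain id
      nsx.push_back(mat_sites(s, 0)); nsy.push_back(mat_sites(s, 1));
      nsz.push_back(mat_sites(s, 2)); ns_chain.push_back(id);
    }
  }
  int k1 = (int)parent.size();
  int n_new_chains = k1 - k0;

  // --- tip migration along the discrete ray toward the nearest cancer cell
  if (do_migrate && n_cell > 0) {
    int refine = nf / nx;
    for (int i = 0; i < k1; ++i) {
      if (!open_fl[i]) continue;
      double px = fine_um * tpx[i], py = fine_um * tpy[i],
             pz = fine_um * tpz[i];
      int ci = nearest_cell(px, py, pz, occ, nx, coarse_um, cell_pos,
                            any_cell, R_PosInf, NULL);
      if (ci < 0) continue;
      double gx = (double)cell_pos(ci, 0) * refine,
             gy = (double)cell_pos(ci, 1) * refine,
             gz = (double)cell_pos(ci, 2) * refine;
      double dx = gx - tpx[i], dy = gy - tpy[i], dz = gz - tpz[i];
      double len = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (len <= 0) continue;
      double ux = dx / len, uy = dy / len, uz = dz / len;
      int cx = tpx[i], cy = tpy[i], cz = tpz[i];
      for (int s = 1; s <= tip_steps; ++s) {
        double t = std::min((double)s, len);
        int qx = clampi((int)std::floor(tpx[i] + ux * t + 0.5), 0, nf - 1);
        int qy = clampi((int)std::floor(tpy[i] + uy * t + 0.5), 0, nf - 1);
        int qz = clampi((int)std::floor(tpz[i] + uz * t + 0.5), 0, nf - 1);
        if (qx == cx && qy == cy && qz == cz) continue;
        cx = qx; cy = qy; cz = qz;
        nsx.push_back(cx); nsy.push_back(cy); nsz.push_back(cz);
        ns_chain.push_back(i + 1);
      }
      tpx[i] = cx; tpy[i] = cy; tpz[i] = cz;
    }
  }

  // --- anastomosis via counting-sort buckets over all vessel sites
  std::vector<int> closed_chain, closed_type, closed_id;
  if (do_anast) {
    int n_cs = csites.nrow();
    int n_ns = (int)nsx.size();
    long n_all = (long)n_mat + n_cs + n_ns;
    double r2 = (anast_um / fine_um) * (anast_um / fine_um);
    int bs = std::max(1, (int)std::floor(anast_um / fine_um));
    int nb = (nf + bs - 1) / bs;
    // flattened site arrays: [mature | old chain sites | new sites]
    // owner: type 0 mature (id = line), type 1 chain (id = chain, 1-based)
    std::vector<int> bucket_of(n_all);
    std::vector<int> count((size_t)nb * nb * nb + 1, 0);
    auto site_xyz = [&](long t, int *x, int *y, int *z, int *type, int *id) {
      if (t < n_mat) {
        *x = mat_sites(t, 0); *y = mat_sites(t, 1); *z = mat_sites(t, 2);
        *type = 0; *id = mat_line[t];
      } else if (t < n_mat + n_cs) {
        long u = t - n_mat;
        *x = csites(u, 0); *y = csites(u, 1); *z = csites(u, 2);
        *type = 1; *id = csite_chain[u];
      } else {
        long u = t - n_mat - n_cs;
        *x = nsx[u]; *y = nsy[u]; *z = nsz[u];
        *type = 1; *id = ns_chain[u];
      }
    };
    for (long t = 0; t < n_all; ++t) {
      int x, y, z, ty, id;
      site_xyz(t, &x, &y, &z, &ty, &id);
      int b = (x / bs) + nb * ((y / bs) + nb * (z / bs));
      bucket_of[t] = b;
      count[b + 1] += 1;
    }
    for (size_t b = 1; b < count.size(); ++b) count[b] += count[b - 1];
    std::vector<int> order(n_all);
    {
      std::vector<int> cursor(count.begin(), count.end() - 1);
      for (long t = 0; t < n_all; ++t) order[cursor[bucket_of[t]]++] = (int)t;
    }

    for (int i = 0; i < k1; ++i) {
      if (!open_fl[i]) continue;
      int tx = tpx[i], ty = tpy[i], tz = tpz[i];
      int bx = tx / bs, by = ty / bs, bz = tz / bs;
      double best_d2 = R_PosInf;
      int best_type = -1, best_id = -1;
      for (int ddx = -1; ddx <= 1; ++ddx) {
        int qx = bx + ddx;
        if (qx < 0 || qx >= nb) continue;
        for (int ddy = -1; ddy <= 1; ++ddy) {
          int qy = by + ddy;
          if (qy < 0 || qy >= nb) continue;
          for (int ddz = -1; ddz <= 1; ++ddz) {
            int qz = bz + ddz;
            if (qz < 0 || qz >= nb) continue;
            int b = qx + nb * (qy + nb * qz);
            for (int u = count[b]; u < count[b + 1]; ++u) {
              int x, y, z, ty2, id2;
              site_xyz(order[u], &x, &y, &z, &ty2, &id2);
              if (ty2 == 1 && id2 == i + 1) continue;  // own chain
              double dx = x - tx, dy = y - ty, dz = z - tz;
              double d2 = dx * dx + dy * dy + dz * dz;
              if (d2 > r2) continue;
              if (ty2 == 0 && id2 == parent[i]) {
                // ignore the branch-point neighborhood of the parent vessel
                double ex = x - orx[i], ey = y - ory[i], ez = z - orz[i];
                if (ex * ex + ey * ey + ez * ez <= r2) continue;
              }
              if (d2 < best_d2) {
                best_d2 = d2;
                best_type = ty2;
                best_id = id2;
              }
            }
          }
        }
      }
      if (best_type >= 0) {
        open_fl[i] = 0;
        closed_chain.push_back(i + 1);
        closed_type.push_back(best_type);  // 0 mature, 1 chain
        closed_id.push_back(best_id);
      }
    }
  }

  int n_ns = (int)nsx.size();
  IntegerMatrix new_sites(n_ns, 3);
  IntegerVector new_site_chain(n_ns);
  for (int t = 0; t < n_ns; ++t) {
    new_sites(t, 0) = nsx[t]; new_sites(t, 1) = nsy[t];
    new_sites(t, 2) = nsz[t];
    new_site_chain[t] = ns_chain[t];
  }
  IntegerMatrix tips_out(k1, 3);
  IntegerMatrix origin_out(n_new_chains, 3);
  IntegerVector parent_out(n_new_chains);
  LogicalVector open_out(k1);
  for (int i = 0; i < k1; ++i) {
    tips_out(i, 0) = tpx[i]; tips_out(i, 1) = tpy[i]; tips_out(i, 2) = tpz[i];
    open_out[i] = open_fl[i] == 1;
  }
  for (int i = k0; i < k1; ++i) {
    origin_out(i - k0, 0) = orx[i];
    origin_out(i - k0, 1) = ory[i];
    origin_out(i - k0, 2) = orz[i];
    parent_out[i - k0] = parent[i];
  }
  return List::create(
      _["new_sites"] = new_sites, _["new_site_chain"] = new_site_chain,
      _["new_chain_parent"] = parent_out, _["new_chain_origin"] = origin_out,
      _["tips"] = tips_out, _["open"] = open_out,
      _["closed_chain"] = wrap(closed_chain),
      _["closed_type"] = wrap(closed_type),
      _["closed_id"] = wrap(closed_id));
}
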