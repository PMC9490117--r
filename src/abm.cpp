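// Agent-lattice kernels for the daily regeneration step.
//
// Phenotype codes: 0 EMPTY, 1 PROGENITOR, 2 FIBROBLAST, 3 CHONDROCYTE,
// 4 IMMATURE_OSTEOBLAST, 5 MATURE_OSTEOBLAST.
// Region codes follow VOXEL_LABELS (0 OUTSIDE, 1 SCAFFOLD, 2 PORE, 3 CALLUS,
// 4 CORTICAL, 5 MARROW). Cells may occupy PORE, CALLUS and MARROW sites.
// Stimulus class codes: 0 RESORPTION, 1 MATURE, 2 IMMATURE, 3 CARTILAGE,
// 4 FIBROUS.
//
// All randomness comes from R's RNG (unif_rand), so runs are reproducible
// under set.seed().

#include <Rcpp.h>
using namespace Rcpp;

static inline bool occupiable(int region) {
  return region == 2 || region == 3 || region == 5;
}

// uniformly chosen empty 6-neighbour of site i, or -1
static inline int pick_empty_neighbor(int i, const IntegerVector& phen,
                                      const IntegerVector& region,
                                      int nx, int ny, int nz) {
  int plane = nx * ny;
  int x = i % nx, y = (i / nx) % ny, z = i / plane;
  int cand[6]; int ncand = 0;
  if (x > 0)      cand[ncand++] = i - 1;
  if (x < nx - 1) cand[ncand++] = i + 1;
  if (y > 0)      cand[ncand++] = i - nx;
  if (y < ny - 1) cand[ncand++] = i + nx;
  if (z > 0)      cand[ncand++] = i - plane;
  if (z < nz - 1) cand[ncand++] = i + plane;
  int ok[6]; int nok = 0;
  for (int c = 0; c < ncand; ++c) {
    int j = cand[c];
    if (phen[j] == 0 && occupiable(region[j])) ok[nok++] = j;
  }
  if (nok == 0) return -1;
  int pick = (int)(unif_rand() * nok);
  if (pick == nok) pick = nok - 1;
  return ok[pick];
}

// [[Rcpp::export]]
IntegerVector cpp_migrate(IntegerVector phen, IntegerVector region,
                          IntegerVector dims, int base_steps,
                          double extra_prob) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int n = phen.size();
  IntegerVector out = clone(phen);
  std::vector<char> moved(n, 0);
  for (int i = 0; i < n; ++i) {
    if (out[i] != 1 || moved[i]) continue;
    int steps = base_steps + ((extra_prob > 0 && unif_rand() < extra_prob) ? 1 : 0);
    int pos = i;
    for (int s = 0; s < steps; ++s) {
      // move to a uniformly chosen empty 6-neighbour; stay if fully blocked
      int tgt = pick_empty_neighbor(pos, out, region, nx, ny, nz);
      if (tgt >= 0) {
        out[pos] = 0;
        out[tgt] = 1;
        pos = tgt;
      }
    }
    if (pos != i) moved[pos] = 1;
  }
  return out;
}

// surface-guided differentiation: a progenitor 26-adjacent to scaffold,
// cortical bone or a non-progenitor tissue cell converts with probability
// p_diff to the phenotype favored by the local stimulus class
// [[Rcpp::export]]
IntegerVector cpp_differentiate(IntegerVector phen, IntegerVector region,
                                IntegerVector sclass, NumericVector p_diff,
                                IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  IntegerVector out = clone(phen);
  int plane = nx * ny;
  static const int target[5] = {-1, 5, 4, 3, 2};
  for (int i = 0; i < phen.size(); ++i) {
    if (phen[i] != 1) continue;
    int x = i % nx, y = (i / nx) % ny, z = i / plane;
    bool surface = false;
    for (int dz = -1; dz <= 1 && !surface; ++dz) {
      int zz = z + dz; if (zz < 0 || zz >= nz) continue;
      for (int dy = -1; dy <= 1 && !surface; ++dy) {
        int yy = y + dy; if (yy < 0 || yy >= ny) continue;
        for (int dx = -1; dx <= 1 && !surface; ++dx) {
          int xx = x + dx; if (xx < 0 || xx >= nx) continue;
          if (dx == 0 && dy == 0 && dz == 0) continue;
          int j = xx + nx * yy + plane * zz;
          int rg = region[j];
          if (rg == 1 || rg == 4) { surface = true; break; }
          if (phen[j] >= 2) { surface = true; break; }
        }
      }
    }
    if (!surface) continue;
    int cls = sclass[i];
    if (cls <= 0) continue;               // resorption bin: no differentiation
    if (unif_rand() < p_diff[i]) out[i] = target[cls];
  }
  return out;
}

// favorable-stimulus check per phenotype
static inline bool favorable(int ph, int cls) {
  switch (ph) {
    case 1: return cls != 0;              // progenitor: any non-resorption
    case 2: return cls == 4;              // fibroblast
    case 3: return cls == 3;              // chondrocyte
    case 4:
    case 5: return cls == 1 || cls == 2;  // osteoblasts: either bone bin
  }
  return false;
}

// [[Rcpp::export]]
IntegerVector cpp_proliferate_apoptose(IntegerVector phen, IntegerVector region,
                                       IntegerVector sclass,
                                       NumericVector p_prolif,
                                       NumericVector p_apopt,
                                       IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int n = phen.size();
  IntegerVector out = clone(phen);
  std::vector<char> newborn(n, 0);
  for (int i = 0; i < n; ++i) {
    int ph = out[i];
    if (ph == 0 || newborn[i]) continue;
    if (favorable(ph, sclass[i])) {
      if (unif_rand() < p_prolif[i]) {
        int j = pick_empty_neighbor(i, out, region, nx, ny, nz);
        if (j >= 0) { out[j] = ph; newborn[j] = 1; }
      }
    } else {
      if (unif_rand() < p_apopt[i]) out[i] = 0;
    }
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_resorb(IntegerVector phen, NumericVector S,
                         double threshold, double p_resorb) {
  IntegerVector out = clone(phen);
  for (int i = 0; i < phen.size(); ++i) {
    if ((out[i] == 4 || out[i] == 5) && S[i] < threshold) {
      if (p_resorb >= 1.0 || unif_rand() < p_resorb) out[i] = 0;
    }
  }
  return out;
}

// callus sites within one site-layer of cortical bone (periosteal layer)
// [[Rcpp::export]]
LogicalVector cpp_periosteal(IntegerVector region, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int plane = nx * ny;
  LogicalVector out(region.size(), false);
  for (int i = 0; i < region.size(); ++i) {
    if (region[i] != 3) continue;         // CALLUS only
    int x = i % nx, y = (i / nx) % ny, z = i / plane;
    bool adj = false;
    for (int dz = -1; dz <= 1 && !adj; ++dz) {
      int zz = z + dz; if (zz < 0 || zz >= nz) continue;
      for (int dy = -1; dy <= 1 && !adj; ++dy) {
        int yy = y + dy; if (yy < 0 || yy >= ny) continue;
        for (int dx = -1; dx <= 1 && !adj; ++dx) {
          int xx = x + dx; if (xx < 0 || xx >= nx) continue;
          if (region[xx + nx * yy + plane * zz] == 4) { adj = true; break; }
        }
      }
    }
    out[i] = adj;
  }
  return out;
}
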