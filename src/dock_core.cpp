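// Numerical core: internal-coordinate chain building (NeRF), pairwise
// energy terms, receptor interaction fields, trilinear interpolation and
// Shrake-Rupley surface areas. All functions are stateless and
// deterministic; randomness lives on the R side.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double DEG = M_PI / 180.0;

// C1 smoothstep switch: 1 for r <= on, 0 for r >= off.
static inline double sw(double r, double on, double off) {
  if (r <= on) return 1.0;
  if (r >= off) return 0.0;
  double t = (r - on) / (off - on);
  return 1.0 - t * t * (3.0 - 2.0 * t);
}

// Smooth saturation: identity below onset, asymptote at cap (C1).
static inline double saturate(double e, double onset, double cap) {
  if (e <= onset) return e;
  double span = cap - onset;
  return onset + span * (1.0 - std::exp(-(e - onset) / span));
}

// Heavy-atom hydrogen-bond distance well, minimum -depth at d0.
static inline double hb_well(double d, double d0, double depth, double cap) {
  double x = d0 / std::max(d, 0.5 * d0);
  double x6 = x * x * x;
  x6 *= x6;
  double e = depth * (x6 * x6 - 2.0 * x6);
  return e > cap ? cap : e;
}

// Donor-side angular factor: ideal antecedent-donor-acceptor angle ~115 deg.
static inline double hb_ang(double px, double py, double pz, double dx,
                            double dy, double dz, double ax, double ay,
                            double az) {
  double v1x = px - dx, v1y = py - dy, v1z = pz - dz;
  double v2x = ax - dx, v2y = ay - dy, v2z = az - dz;
  double n1 = std::sqrt(v1x * v1x + v1y * v1y + v1z * v1z);
  double n2 = std::sqrt(v2x * v2x + v2y * v2y + v2z * v2z);
  if (n1 < 1e-9 || n2 < 1e-9) return 1.0;
  double c = (v1x * v2x + v1y * v2y + v1z * v2z) / (n1 * n2);
  c = std::max(-1.0, std::min(1.0, c));
  double f = std::cos(std::acos(c) - 115.0 * DEG);
  return f > 0.0 ? f * f : 0.0;
}

// Build Cartesian coordinates from a z-matrix by natural extension
// (NeRF). Parent indices are 1-based; 0 means "no parent" (seed atoms).
// dihedral(row) = dih0[row] + torsions[tidx[row]] when tidx > 0.
// Finally applies the rigid-body placement x -> R x + t.
// [[Rcpp::export]]
NumericMatrix build_coords_cpp(IntegerVector ai, IntegerVector aj,
                               IntegerVector ak, NumericVector bond,
                               NumericVector ang, NumericVector dih0,
                               IntegerVector tidx, NumericVector torsions,
                               NumericMatrix rot, NumericVector trans) {
  int n = ai.size();
  std::vector<double> X(3 * n, 0.0);
  for (int r = 0; r < n; ++r) {
    int i = ai[r] - 1, j = aj[r] - 1, k = ak[r] - 1;
    double b = bond[r];
    if (i < 0) continue;  // first atom at local origin
    if (j < 0) {          // second atom along +x
      X[3 * r] = X[3 * i] + b;
      X[3 * r + 1] = X[3 * i + 1];
      X[3 * r + 2] = X[3 * i + 2];
      continue;
    }
    double th = ang[r] * DEG;
    if (k < 0) {  // third atom in the local xy-plane
      double wx = X[3 * j] - X[3 * i], wy = X[3 * j + 1] - X[3 * i + 1],
             wz = X[3 * j + 2] - X[3 * i + 2];
      double nw = std::sqrt(wx * wx + wy * wy + wz * wz);
      wx /= nw; wy /= nw; wz /= nw;
      double px = -wy, py = wx, pz = 0.0;
      double np = std::sqrt(px * px + py * py);
      if (np < 1e-8) { px = 0.0; py = 0.0; pz = 1.0; np = 1.0; }
      px /= np; py /= np; pz /= np;
      X[3 * r] = X[3 * i] + b * (std::cos(th) * wx + std::sin(th) * px);
      X[3 * r + 1] = X[3 * i + 1] + b * (std::cos(th) * wy + std::sin(th) * py);
      X[3 * r + 2] = X[3 * i + 2] + b * (std::cos(th) * wz + std::sin(th) * pz);
      continue;
    }
    double phi = dih0[r];
    if (tidx[r] > 0) phi += torsions[tidx[r] - 1];
    phi *= DEG;
    // NeRF frame from A=k, B=j, C=i; places D with angle(D,C,B)=th and
    // torsion(D,C,B,A)=phi.
    double bcx = X[3 * i] - X[3 * j], bcy = X[3 * i + 1] - X[3 * j + 1],
           bcz = X[3 * i + 2] - X[3 * j + 2];
    double nbc = std::sqrt(bcx * bcx + bcy * bcy + bcz * bcz);
    bcx /= nbc; bcy /= nbc; bcz /= nbc;
    double abx = X[3 * j] - X[3 * k], aby = X[3 * j + 1] - X[3 * k + 1],
           abz = X[3 * j + 2] - X[3 * k + 2];
    double nx = aby * bcz - abz * bcy, ny = abz * bcx - abx * bcz,
           nz = abx * bcy - aby * bcx;
    double nn = std::sqrt(nx * nx + ny * ny + nz * nz);
    if (nn < 1e-10) { nx = 0; ny = 0; nz = 1; nn = 1; }
    nx /= nn; ny /= nn; nz /= nn;
    double mx = ny * bcz - nz * bcy, my = nz * bcx - nx * bcz,
           mz = nx * bcy - ny * bcx;
    double d1 = -b * std::cos(th);
    double d2 = b * std::sin(th) * std::cos(phi);
    double d3 = b * std::sin(th) * std::sin(phi);
    X[3 * r] = X[3 * i] + d1 * bcx + d2 * mx + d3 * nx;
    X[3 * r + 1] = X[3 * i + 1] + d1 * bcy + d2 * my + d3 * ny;
    X[3 * r + 2] = X[3 * i + 2] + d1 * bcz + d2 * mz + d3 * nz;
  }
  NumericMatrix out(n, 3);
  for (int r = 0; r < n; ++r) {
    double x = X[3 * r], y = X[3 * r + 1], z = X[3 * r + 2];
    out(r, 0) = rot(0, 0) * x + rot(0, 1) * y + rot(0, 2) * z + trans[0];
    out(r, 1) = rot(1, 0) * x + rot(1, 1) * y + rot(1, 2) * z + trans[1];
    out(r, 2) = rot(2, 0) * x + rot(2, 1) * y + rot(2, 2) * z + trans[2];
  }
  return out;
}

// Pairwise nonbonded terms over one atom set (used for intra-ligand
// energies and for interface subsystems during refinement).
// excl[i,j] = TRUE suppresses the vdW/electrostatic/h-bond terms for the
// pair (bonded, 1-3 and 1-4 neighbours; also fixed receptor bookkeeping).
// Neighbour counts (heavy atoms within burial_radius, exclusions ignored)
// are returned for burial-based solvation/entropy estimates.
// [[Rcpp::export]]
List intra_terms_cpp(NumericMatrix xyz, IntegerVector cls, NumericVector q,
                     IntegerVector don, IntegerVector donp, IntegerVector acc,
                     LogicalMatrix excl, List ff) {
  int n = xyz.nrow();
  NumericVector r0 = ff["r0"], eps = ff["eps"];
  double nbcut = ff["nb_cutoff"], swon = nbcut - as<double>(ff["switch_width"]);
  double ccap = ff["clash_cap"], ck = ff["coulomb_k"];
  double ecap = ff["elec_cap"];
  double hbd0 = ff["hb_d0"], hbdepth = ff["hb_depth"];
  double hbcut = ff["hb_cutoff"], hbon = ff["hb_switch"];
  double brad = ff["burial_radius"];
  double nbcut2 = nbcut * nbcut, brad2 = brad * brad;
  double Evw = 0.0, Eel = 0.0, Ehb = 0.0;
  IntegerVector nbr(n);
  for (int i = 0; i < n - 1; ++i) {
    int ci = cls[i] - 1;
    for (int j = i + 1; j < n; ++j) {
      double dx = xyz(i, 0) - xyz(j, 0), dy = xyz(i, 1) - xyz(j, 1),
             dz = xyz(i, 2) - xyz(j, 2);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 < brad2) { nbr[i]++; nbr[j]++; }
      if (r2 > nbcut2 || excl(i, j)) continue;
      double r = std::sqrt(r2);
      double s = sw(r, swon, nbcut);
      int cj = cls[j] - 1;
      double R0 = r0[ci] + r0[cj];
      double x = R0 / std::max(r, 0.1);
      double x6 = x * x * x; x6 *= x6;
      double e = std::sqrt(eps[ci] * eps[cj]) * (x6 * x6 - 2.0 * x6);
      if (e > ccap) e = ccap;
      Evw += e * s;
      double qq = q[i] * q[j];
      if (qq != 0.0) {
        double v = ck * qq / (4.0 * std::max(r2, 0.25));
        if (v > ecap) v = ecap;
        if (v < -ecap) v = -ecap;
        Eel += v * s;
      }
      if (r <= hbcut) {
        double shb = sw(r, hbon, hbcut);
        if (don[i] && acc[j]) {
          double f = 1.0;
          if (donp[i] > 0) {
            int p = donp[i] - 1;
            f = hb_ang(xyz(p, 0), xyz(p, 1), xyz(p, 2), xyz(i, 0), xyz(i, 1),
                       xyz(i, 2), xyz(j, 0), xyz(j, 1), xyz(j, 2));
          }
          Ehb += hb_well(r, hbd0, hbdepth, ccap) * f * shb;
        }
        if (don[j] && acc[i]) {
          double f = 1.0;
          if (donp[j] > 0) {
            int p = donp[j] - 1;
            f = hb_ang(xyz(p, 0), xyz(p, 1), xyz(p, 2), xyz(j, 0), xyz(j, 1),
                       xyz(j, 2), xyz(i, 0), xyz(i, 1), xyz(i, 2));
          }
          Ehb += hb_well(r, hbd0, hbdepth, ccap) * f * shb;
        }
      }
    }
  }
  return List::create(_["vw"] = Evw, _["el"] = Eel, _["hb"] = Ehb,
                      _["nbr"] = nbr);
}

// Receptor interaction field sampled at arbitrary points. One row per
// point; columns: vdw_attractive, vdw_repulsive, electrostatic (per unit
// probe charge), hbond_donor (probe as donor), hbond_acceptor (probe as
// acceptor), hydrophobic (apolar probe), burial (heavy-atom count within
// burial_radius). The steric wall is smoothly capped so the field
// interpolates stably on a 1 A grid; full 6-12 repulsion is used off-grid
// during refinement.
// [[Rcpp::export]]
NumericMatrix receptor_field_cpp(NumericMatrix pts, NumericMatrix rxyz,
                                 IntegerVector rcls, NumericVector rq,
                                 IntegerVector rdon, IntegerVector rdonp,
                                 IntegerVector racc, IntegerVector rapol,
                                 List ff) {
  int m = pts.nrow(), n = rxyz.nrow();
  NumericVector r0 = ff["r0"], eps = ff["eps"];
  double nbcut = ff["nb_cutoff"], swon = nbcut - as<double>(ff["switch_width"]);
  double ck = ff["coulomb_k"], ecap = ff["clash_cap"];
  double elec_cap = ff["elec_cap"];
  double hbd0 = ff["hb_d0"], hbdepth = ff["hb_depth"];
  double hbcut = ff["hb_cutoff"], hbon = ff["hb_switch"];
  double hpfull = ff["hp_full"], hpcut = ff["vdw_contact_cutoff"];
  double hpstr = ff["hp_strength"];
  double sat_on = ff["sat_onset"], sat_cap = ff["sat_cap"];
  double pr0 = ff["probe_r0"], peps = ff["probe_eps"];
  double brad = ff["burial_radius"];
  double nbcut2 = nbcut * nbcut, brad2 = brad * brad;
  NumericMatrix out(m, 7);
  for (int p = 0; p < m; ++p) {
    double px = pts(p, 0), py = pts(p, 1), pz = pts(p, 2);
    double attr = 0, rep = 0, elec = 0, edon = 0, eacc = 0, ehp = 0;
    int bur = 0;
    for (int a = 0; a < n; ++a) {
      double dx = px - rxyz(a, 0), dy = py - rxyz(a, 1), dz = pz - rxyz(a, 2);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 < brad2) bur++;
      if (r2 > nbcut2) continue;
      double r = std::sqrt(r2);
      double s = sw(r, swon, nbcut);
      int ca = rcls[a] - 1;
      double R0 = r0[ca] + pr0;
      double epsij = std::sqrt(eps[ca] * peps);
      double xr = R0 / std::max(r, 0.85 * R0);  // clamped attractive core
      double x6a = xr * xr * xr; x6a *= x6a;
      attr += -2.0 * epsij * x6a * s;
      double xf = R0 / std::max(r, 0.1);
      double x6 = xf * xf * xf; x6 *= x6;
      rep += saturate(epsij * x6 * x6, sat_on, sat_cap) * s;
      if (rq[a] != 0.0) {
        double v = ck * rq[a] / (4.0 * std::max(r2, 0.25));
        if (v > elec_cap) v = elec_cap;
        if (v < -elec_cap) v = -elec_cap;
        elec += v * s;
      }
      if (r <= hbcut) {
        double shb = sw(r, hbon, hbcut);
        double well = hb_well(r, hbd0, hbdepth, ecap) * shb;
        if (racc[a]) edon += well;  // probe donates to receptor acceptor
        if (rdon[a]) {              // receptor donates to probe acceptor
          double f = 1.0;
          if (rdonp[a] > 0) {
            int pp = rdonp[a] - 1;
            f = hb_ang(rxyz(pp, 0), rxyz(pp, 1), rxyz(pp, 2), rxyz(a, 0),
                       rxyz(a, 1), rxyz(a, 2), px, py, pz);
          }
          eacc += well * f;
        }
      }
      if (rapol[a] && r <= hpcut) {
        ehp += (r <= hpfull) ? -hpstr : -hpstr * (hpcut - r) / (hpcut - hpfull);
      }
    }
    out(p, 0) = attr; out(p, 1) = rep; out(p, 2) = elec;
    out(p, 3) = edon; out(p, 4) = eacc; out(p, 5) = ehp;
    out(p, 6) = bur;
  }
  return out;
}

// Trilinear interpolation of the channel stack at arbitrary points.
// Returns one row per point: the interpolated channels plus an inside
// flag (0 when the point falls outside the grid support).
// [[Rcpp::export]]
NumericMatrix trilinear_cpp(List chans, IntegerVector dims,
                            NumericVector origin, double spacing,
                            NumericMatrix pts) {
  int nc = chans.size(), m = pts.nrow();
  int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<NumericVector> maps;
  for (int c = 0; c < nc; ++c) maps.push_back(chans[c]);
  NumericMatrix out(m, nc + 1);
  for (int p = 0; p < m; ++p) {
    double gx = (pts(p, 0) - origin[0]) / spacing;
    double gy = (pts(p, 1) - origin[1]) / spacing;
    double gz = (pts(p, 2) - origin[2]) / spacing;
    int ix = (int)std::floor(gx), iy = (int)std::floor(gy),
        iz = (int)std::floor(gz);
    // points exactly on the upper boundary belong to the last cell
    if (ix == nx - 1 && gx == (double)ix) ix--;
    if (iy == ny - 1 && gy == (double)iy) iy--;
    if (iz == nz - 1 && gz == (double)iz) iz--;
    if (ix < 0 || iy < 0 || iz < 0 || ix > nx - 2 || iy > ny - 2 ||
        iz > nz - 2) {
      for (int c = 0; c < nc; ++c) out(p, c) = 0.0;
      out(p, nc) = 0.0;
      continue;
    }
    double fx = gx - ix, fy = gy - iy, fz = gz - iz;
    int i000 = ix + nx * (iy + ny * iz);
    int i100 = i000 + 1, i010 = i000 + nx, i110 = i010 + 1;
    int i001 = i000 + nx * ny, i101 = i001 + 1, i011 = i001 + nx,
        i111 = i011 + 1;
    double w000 = (1 - fx) * (1 - fy) * (1 - fz), w100 = fx * (1 - fy) * (1 - fz);
    double w010 = (1 - fx) * fy * (1 - fz), w110 = fx * fy * (1 - fz);
    double w001 = (1 - fx) * (1 - fy) * fz, w101 = fx * (1 - fy) * fz;
    double w011 = (1 - fx) * fy * fz, w111 = fx * fy * fz;
    for (int c = 0; c < nc; ++c) {
      const NumericVector& M = maps[c];
      out(p, c) = w000 * M[i000] + w100 * M[i100] + w010 * M[i010] +
                  w110 * M[i110] + w001 * M[i001] + w101 * M[i101] +
                  w011 * M[i011] + w111 * M[i111];
    }
    out(p, nc) = 1.0;
  }
  return out;
}

// Shrake-Rupley solvent-accessible surface area with a golden-spiral
// point set. Areas are returned for the atoms in `subset` (1-based);
// every atom in `xyz` acts as an occluder.
// [[Rcpp::export]]
NumericVector sasa_cpp(NumericMatrix xyz, NumericVector rad, double probe,
                       int npts, IntegerVector subset) {
  int n = xyz.nrow(), ns = subset.size();
  std::vector<double> sx(npts), sy(npts), sz(npts);
  double ga = M_PI * (3.0 - std::sqrt(5.0));
  for (int k = 0; k < npts; ++k) {
    double zk = 1.0 - 2.0 * (k + 0.5) / npts;
    double rk = std::sqrt(std::max(0.0, 1.0 - zk * zk));
    sx[k] = rk * std::cos(ga * k);
    sy[k] = rk * std::sin(ga * k);
    sz[k] = zk;
  }
  NumericVector out(ns);
  for (int s = 0; s < ns; ++s) {
    int a = subset[s] - 1;
    double Ra = rad[a] + probe;
    double ax = xyz(a, 0), ay = xyz(a, 1), az = xyz(a, 2);
    std::vector<int> nb;
    std::vector<double> nbx, nby, nbz, nbr2;
    for (int b = 0; b < n; ++b) {
      if (b == a) continue;
      double Rb = rad[b] + probe;
      double dx = xyz(b, 0) - ax, dy = xyz(b, 1) - ay, dz = xyz(b, 2) - az;
      double r2 = dx * dx + dy * dy + dz * dz;
      double lim = Ra + Rb;
      if (r2 < lim * lim) {
        nbx.push_back(xyz(b, 0)); nby.push_back(xyz(b, 1));
        nbz.push_back(xyz(b, 2)); nbr2.push_back(Rb * Rb);
      }
    }
    int acc = 0, nn = (int)nbx.size();
    for (int k = 0; k < npts; ++k) {
      double qx = ax + Ra * sx[k], qy = ay + Ra * sy[k], qz = az + Ra * sz[k];
      bool free_pt = true;
      for (int b = 0; b < nn; ++b) {
        double dx = qx - nbx[b], dy = qy - nby[b], dz = qz - nbz[b];
        if (dx * dx + dy * dy + dz * dz < nbr2[b]) { free_pt = false; break; }
      }
      if (free_pt) acc++;
    }
    out[s] = 4.0 * M_PI * Ra * Ra * (double)acc / npts;
  }
  return out;
}

// Count of heavy-atom pairs across two sets closer than `cutoff`.
// [[Rcpp::export]]
int contact_count_cpp(NumericMatrix a, NumericMatrix b, double cutoff) {
  int n = a.nrow(), m = b.nrow(), cnt = 0;
  double c2 = cutoff * cutoff;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j) {
      double dx = a(i, 0) - b(j, 0), dy = a(i, 1) - b(j, 1),
             dz = a(i, 2) - b(j, 2);
      if (dx * dx + dy * dy + dz * dz < c2) cnt++;
    }
  return cnt;
}
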