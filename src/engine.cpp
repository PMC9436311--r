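// Core 3D hybrid cellular automaton: lattice occupancy, growth-factor
// quasi-steady diffusion, GF-governed division/death, knock-on displacement,
// shedding, NOTCH1 displacement veto, UV kill days, and per-division
// base-pair mutation drawing on a gene panel.
//
// All randomness goes through R's RNG (unif_rand / R::rpois) so that
// set.seed() in R fully determines a trajectory.

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

static inline int idx3(int x, int y, int z, int Lx, int Ly) {
  return x + Lx * (y + Ly * z);
}

// ---------------------------------------------------------------------------
// Growth-factor quasi-steady solver.
// Dirichlet source u = s0 on the whole z = 0 layer, periodic lateral faces,
// absorbing top (u = 0 above z = Lz-1). Linear uptake c*u in occupied voxels,
// first-order decay lambda*u everywhere; rates are expressed relative to the
// diffusion coefficient (dx = 1 voxel).
static int gf_steady(std::vector<double> &u, const int *occ,
                     int Lx, int Ly, int Lz,
                     double s0, double lam, double cons,
                     double tol, int max_sweeps) {
  const int nxy = Lx * Ly;
  for (int i = 0; i < nxy; ++i) u[i] = s0;
  double maxd = 0.0;
  int sweep = 0;
  do {
    maxd = 0.0;
    for (int z = 1; z < Lz; ++z) {
      for (int y = 0; y < Ly; ++y) {
        const int yp = (y + 1) % Ly, ym = (y + Ly - 1) % Ly;
        for (int x = 0; x < Lx; ++x) {
          const int xp = (x + 1) % Lx, xm = (x + Lx - 1) % Lx;
          const int i = idx3(x, y, z, Lx, Ly);
          double nb = u[idx3(xp, y, z, Lx, Ly)] + u[idx3(xm, y, z, Lx, Ly)] +
                      u[idx3(x, yp, z, Lx, Ly)] + u[idx3(x, ym, z, Lx, Ly)] +
                      u[i - nxy] + (z + 1 < Lz ? u[i + nxy] : 0.0);
          double denom = 6.0 + lam + (occ[i] > 0 ? cons : 0.0);
          double unew = nb / denom;
          double d = std::fabs(unew - u[i]);
          if (d > maxd) maxd = d;
          u[i] = unew;
        }
      }
    }
    ++sweep;
  } while (maxd > tol * s0 && sweep < max_sweeps);
  if (maxd > tol * s0)
    stop("growth-factor solver did not converge: residual %g (scaled) after %d sweeps",
         maxd / s0, sweep);
  return sweep;
}

// [[Rcpp::export]]
List solve_gf_cpp(IntegerVector occ, int Lx, int Ly, int Lz,
                  double s0, double lam, double cons,
                  double tol, int max_sweeps) {
  std::vector<double> u((size_t)Lx * Ly * Lz, 0.0);
  int sweeps = gf_steady(u, INTEGER(occ), Lx, Ly, Lz, s0, lam, cons, tol, max_sweeps);
  NumericVector out(u.begin(), u.end());
  return List::create(_["gf"] = out, _["sweeps"] = sweeps);
}

// ---------------------------------------------------------------------------
// Mutation model on the gene panel (per-division Poisson superposition).

struct Panel {
  int n_genes;
  std::vector<double> gene_cum;     // cumulative sum of mu_g * L_g
  double lam_tot;                   // total expected mutations per division
  NumericMatrix base_cum;           // n_genes x 4 cumulative ref-base probs (A,C,G,T)
  std::vector<std::vector<std::vector<int> > > pos; // gene -> base -> coords
  std::vector<int> driver;          // 0 passenger, 1 NOTCH1-like, 2 TP53-like
  double alt_ct;                    // P(alt = T | ref = C)
};

static Panel panel_from_list(List p) {
  Panel P;
  NumericVector lam = p["lambda"];
  P.n_genes = lam.size();
  P.gene_cum.resize(P.n_genes);
  double s = 0.0;
  for (int g = 0; g < P.n_genes; ++g) { s += lam[g]; P.gene_cum[g] = s; }
  P.lam_tot = s;
  P.base_cum = as<NumericMatrix>(p["base_cum"]);
  List posl = p["pos_by_base"];
  P.pos.resize(P.n_genes);
  for (int g = 0; g < P.n_genes; ++g) {
    List pb = posl[g];
    P.pos[g].resize(4);
    for (int b = 0; b < 4; ++b) {
      IntegerVector v = pb[b];
      P.pos[g][b].assign(v.begin(), v.end());
    }
  }
  IntegerVector drv = p["driver"];
  P.driver.assign(drv.begin(), drv.end());
  P.alt_ct = as<double>(p["alt_ct"]);
  return P;
}

struct Genos {
  std::vector<int> parent, n1, p53;
  std::vector<std::vector<int> > own; // 0-based mutation rows arising in each genotype
};

struct Muts {
  std::vector<int> gene, pos, ref, alt, geno;
  std::vector<double> bday;
};

static inline double runif01() { return unif_rand(); }

// Draw de novo mutations for one daughter cell; returns the (possibly new)
// genotype id. Positions already mutated along this lineage are redrawn
// (infinite sites within a lineage).
static int mutate_from(int g, double day, const Panel &P, Genos &G, Muts &M) {
  int n = (int)R::rpois(P.lam_tot);
  if (n <= 0) return g;
  G.parent.push_back(g);
  G.n1.push_back(g > 0 ? G.n1[g - 1] : 0);
  G.p53.push_back(g > 0 ? G.p53[g - 1] : 0);
  G.own.push_back(std::vector<int>());
  int gid = (int)G.parent.size(); // 1-based id of the new genotype
  for (int k = 0; k < n; ++k) {
    int gene = -1, posi = -1, ref = -1;
    for (int tries = 0; tries < 100; ++tries) {
      // gene by mutation-mass weight
      double r = runif01() * P.lam_tot;
      int lo = 0, hi = P.n_genes - 1;
      while (lo < hi) { int mid = (lo + hi) / 2; if (P.gene_cum[mid] < r) lo = mid + 1; else hi = mid; }
      gene = lo;
      // ref base via the (renormalised) cytosine-enriched multinomial
      double u = runif01();
      ref = 3;
      for (int b = 0; b < 4; ++b) if (u <= P.base_cum(gene, b)) { ref = b; break; }
      const std::vector<int> &pv = P.pos[gene][ref];
      if (pv.empty()) continue; // cannot happen on valid panels
      int j = (int)(runif01() * pv.size());
      if (j >= (int)pv.size()) j = (int)pv.size() - 1;
      posi = pv[j];
      // infinite sites within the lineage: reject previously hit positions
      bool hit = false;
      int anc = gid;
      while (anc > 0 && !hit) {
        const std::vector<int> &mo = G.own[anc - 1];
        for (size_t q = 0; q < mo.size(); ++q)
          if (M.gene[mo[q]] == gene && M.pos[mo[q]] == posi) { hit = true; break; }
        anc = G.parent[anc - 1];
      }
      if (!hit) break;
      posi = -1;
    }
    if (posi < 0) continue;
    int alt;
    if (ref == 1) { // cytosine: enriched C>T
      if (runif01() < P.alt_ct) alt = 3;
      else alt = (runif01() < 0.5) ? 0 : 2;
    } else {
      int a = (int)(runif01() * 3.0);
      if (a > 2) a = 2;
      alt = (a >= ref) ? a + 1 : a; // uniform over the three non-ref bases
    }
    M.gene.push_back(gene + 1);
    M.pos.push_back(posi);
    M.ref.push_back(ref);
    M.alt.push_back(alt);
    M.geno.push_back(gid);
    M.bday.push_back(day);
    G.own[gid - 1].push_back((int)M.gene.size() - 1);
    if (P.driver[gene] == 1) G.n1[gid - 1] = 1;
    if (P.driver[gene] == 2) G.p53[gid - 1] = 1;
  }
  if (G.own[gid - 1].empty()) {
    // every event was rejected (astronomically rare): drop the empty genotype
    G.parent.pop_back(); G.n1.pop_back(); G.p53.pop_back(); G.own.pop_back();
    return g;
  }
  return gid;
}

// ---------------------------------------------------------------------------
// Engine proper.

struct Params {
  int Lx, Ly, Lz;
  double s0, gf_lambda, gf_cons, gf_tol;
  int gf_max_sweeps;
  double p_max, K_div, h_div, d_max, K_die, h_die;
  double place_w[5]; // +x, -x, +y, -y, above
  double f0, theta_s;
  bool uv_basal_only;
};

static Params params_from_list(List par) {
  Params q;
  q.Lx = as<int>(par["Lx"]); q.Ly = as<int>(par["Ly"]); q.Lz = as<int>(par["Lz"]);
  q.s0 = as<double>(par["s0"]);
  q.gf_lambda = as<double>(par["gf_lambda"]);
  q.gf_cons = as<double>(par["gf_consumption"]);
  q.gf_tol = as<double>(par["gf_tol"]);
  q.gf_max_sweeps = as<int>(par["gf_max_sweeps"]);
  q.p_max = as<double>(par["p_max"]); q.K_div = as<double>(par["K_div"]);
  q.h_div = as<double>(par["h_div"]);
  q.d_max = as<double>(par["d_max"]); q.K_die = as<double>(par["K_die"]);
  q.h_die = as<double>(par["h_die"]);
  NumericVector w = par["place_w"];
  for (int k = 0; k < 5; ++k) q.place_w[k] = w[k];
  q.f0 = as<double>(par["f0"]);
  q.theta_s = as<double>(par["theta_s"]);
  q.uv_basal_only = as<bool>(par["uv_basal_only"]);
  return q;
}

static inline double hill_up(double u, double K, double h) {
  double a = std::pow(u, h);
  return a / (a + std::pow(K, h));
}
static inline double hill_down(double u, double K, double h) {
  double b = std::pow(K, h);
  return b / (std::pow(u, h) + b);
}

struct Engine {
  Params q;
  Panel P;
  Genos G;
  Muts M;
  std::vector<int> occ, lin, acted;
  std::vector<double> birth, gf;
  int nxy, ntot;
  // per-day ledger
  long births, deaths, sheds, uv_deaths, basal_losses;

  void reset_ledger() { births = deaths = sheds = uv_deaths = basal_losses = 0; }

  // Shift the whole occupied run of column (x,y) starting at z up by one,
  // shedding the top cell if the column is full to the lid; then place the
  // daughter (genotype gid, lineage ln) at (x,y,z).
  void place_at(int x, int y, int z, int gid, int ln, double day, int dstamp) {
    int j = idx3(x, y, z, q.Lx, q.Ly);
    if (occ[j] > 0) {
      int ztop = z;
      while (ztop < q.Lz && occ[idx3(x, y, ztop, q.Lx, q.Ly)] > 0) ++ztop;
      if (ztop == q.Lz) { // full to the lid: shed the surface cell
        ++sheds;
        ztop = q.Lz - 1;
      }
      for (int zz = ztop; zz > z; --zz) {
        int a = idx3(x, y, zz, q.Lx, q.Ly), b = idx3(x, y, zz - 1, q.Lx, q.Ly);
        occ[a] = occ[b]; lin[a] = lin[b]; birth[a] = birth[b]; acted[a] = acted[b];
      }
      if (z == 0) ++basal_losses; // the basal occupant was displaced upward
    }
    occ[j] = gid; lin[j] = ln; birth[j] = day; acted[j] = dstamp;
    ++births;
  }

  // One division attempt by the occupied cell at (x,y,z): target choice among
  // the four lateral neighbours and the site directly above, NOTCH1 veto
  // (which aborts the division outright: the blocked birth is the cost that
  // couples the persistence advantage to homeostasis), knock-on displacement,
  // and de novo mutation of both daughters.
  // Returns 0 = aborted (vetoed), 1 = placed, 2 = shed at lid.
  int divide_at(int x, int y, int z, double day, int dstamp) {
    const int i = idx3(x, y, z, q.Lx, q.Ly);
    const int parent_geno = occ[i];
    const int ln = lin[i];
    int tx[5], ty[5], tz[5];
    tx[0] = (x + 1) % q.Lx; ty[0] = y; tz[0] = z;
    tx[1] = (x + q.Lx - 1) % q.Lx; ty[1] = y; tz[1] = z;
    tx[2] = x; ty[2] = (y + 1) % q.Ly; tz[2] = z;
    tx[3] = x; ty[3] = (y + q.Ly - 1) % q.Ly; tz[3] = z;
    tx[4] = x; ty[4] = y; tz[4] = z + 1;
    double w[5];
    for (int k = 0; k < 5; ++k) w[k] = q.place_w[k];
    for (;;) {
      double tot = w[0] + w[1] + w[2] + w[3] + w[4];
      if (tot <= 0.0) return 0; // every candidate vetoed: division aborted
      double r = runif01() * tot;
      int k = 0;
      for (; k < 4; ++k) { if (r < w[k]) break; r -= w[k]; }
      if (k < 4) { // lateral
        int j = idx3(tx[k], ty[k], tz[k], q.Lx, q.Ly);
        if (occ[j] > 0 && q.f0 > 0.0 && G.n1[occ[j] - 1]) {
          if (runif01() < q.f0) return 0; // vetoed: division aborted
        }
        occ[i] = mutate_from(parent_geno, day, P, G, M);
        int gid = mutate_from(parent_geno, day, P, G, M);
        place_at(tx[k], ty[k], tz[k], gid, ln, day, dstamp);
        return 1;
      }
      // above
      if (z + 1 >= q.Lz) { // daughter emerges past the lid: shed immediately
        occ[i] = mutate_from(parent_geno, day, P, G, M);
        ++births; ++sheds;
        return 2;
      }
      occ[i] = mutate_from(parent_geno, day, P, G, M);
      int gid = mutate_from(parent_geno, day, P, G, M);
      place_at(tx[4], ty[4], tz[4], gid, ln, day, dstamp);
      return 1;
    }
  }

  void uv_kill() {
    if (q.theta_s <= 0.0) return;
    int zmax = q.uv_basal_only ? 1 : q.Lz;
    for (int z = 0; z < zmax; ++z)
      for (int y = 0; y < q.Ly; ++y)
        for (int x = 0; x < q.Lx; ++x) {
          int i = idx3(x, y, z, q.Lx, q.Ly);
          if (occ[i] == 0) continue;
          if (G.p53[occ[i] - 1]) continue; // TP53 mutants are spared
          if (runif01() < q.theta_s) {
            occ[i] = 0; lin[i] = 0;
            ++deaths; ++uv_deaths;
            if (z == 0) ++basal_losses;
          }
        }
  }
};

static void fill_engine_state(Engine &E, IntegerVector occ, NumericVector gf,
                              IntegerVector lin, NumericVector birth,
                              List geno, List mut) {
  E.nxy = E.q.Lx * E.q.Ly;
  E.ntot = E.nxy * E.q.Lz;
  E.occ.assign(occ.begin(), occ.end());
  E.lin.assign(lin.begin(), lin.end());
  E.birth.assign(birth.begin(), birth.end());
  E.gf.assign(gf.begin(), gf.end());
  E.acted.assign(E.ntot, -1);
  IntegerVector gp = geno["parent"], gn = geno["has_notch1"], gt = geno["has_tp53"];
  E.G.parent.assign(gp.begin(), gp.end());
  E.G.n1.assign(gn.begin(), gn.end());
  E.G.p53.assign(gt.begin(), gt.end());
  IntegerVector mg = mut["gene"], mp = mut["pos"], mr = mut["ref"], ma = mut["alt"],
                mgen = mut["genotype"];
  NumericVector mb = mut["birth_day"];
  E.M.gene.assign(mg.begin(), mg.end());
  E.M.pos.assign(mp.begin(), mp.end());
  E.M.ref.assign(mr.begin(), mr.end());
  E.M.alt.assign(ma.begin(), ma.end());
  E.M.geno.assign(mgen.begin(), mgen.end());
  E.M.bday.assign(mb.begin(), mb.end());
  E.G.own.assign(E.G.parent.size(), std::vector<int>());
  for (size_t m = 0; m < E.M.gene.size(); ++m)
    E.G.own[E.M.geno[m] - 1].push_back((int)m);
}

static List engine_to_list(Engine &E, NumericMatrix series, NumericMatrix lineage_weekly) {
  return List::create(
    _["occ"] = IntegerVector(E.occ.begin(), E.occ.end()),
    _["gf"] = NumericVector(E.gf.begin(), E.gf.end()),
    _["lineage"] = IntegerVector(E.lin.begin(), E.lin.end()),
    _["birth"] = NumericVector(E.birth.begin(), E.birth.end()),
    _["geno_parent"] = IntegerVector(E.G.parent.begin(), E.G.parent.end()),
    _["geno_notch1"] = IntegerVector(E.G.n1.begin(), E.G.n1.end()),
    _["geno_tp53"] = IntegerVector(E.G.p53.begin(), E.G.p53.end()),
    _["mut_gene"] = IntegerVector(E.M.gene.begin(), E.M.gene.end()),
    _["mut_pos"] = IntegerVector(E.M.pos.begin(), E.M.pos.end()),
    _["mut_ref"] = IntegerVector(E.M.ref.begin(), E.M.ref.end()),
    _["mut_alt"] = IntegerVector(E.M.alt.begin(), E.M.alt.end()),
    _["mut_genotype"] = IntegerVector(E.M.geno.begin(), E.M.geno.end()),
    _["mut_birth_day"] = NumericVector(E.M.bday.begin(), E.M.bday.end()),
    _["series"] = series,
    _["lineage_weekly"] = lineage_weekly);
}

// [[Rcpp::export]]
List run_epidermis_cpp(IntegerVector occ, NumericVector gf, IntegerVector lin,
                       NumericVector birth, List geno, List mut, List panel,
                       List par, double day0, int n_days, LogicalVector sun,
                       int n_labels) {
  RNGScope rng;
  Engine E;
  E.q = params_from_list(par);
  E.P = panel_from_list(panel);
  fill_engine_state(E, occ, gf, lin, birth, geno, mut);

  NumericMatrix series(n_days, 12);
  colnames(series) = CharacterVector::create(
    "day", "total", "basal", "n_notch1", "n_tp53", "births", "deaths",
    "sheds", "uv_deaths", "basal_losses", "gf_sweeps", "divisions");
  int n_weeks = n_days / 7;
  NumericMatrix lineage_weekly(n_weeks, 2);
  colnames(lineage_weekly) = CharacterVector::create("day", "n_surviving");
  int wk = 0;

  std::vector<int> perm;
  perm.reserve(E.ntot);

  for (int d = 0; d < n_days; ++d) {
    double day = day0 + d + 1; // events of this step carry the end-of-day clock
    E.reset_ledger();
    long divisions = 0;

    if (sun[d]) E.uv_kill();

    int sweeps = gf_steady(E.gf, E.occ.data(), E.q.Lx, E.q.Ly, E.q.Lz,
                           E.q.s0, E.q.gf_lambda, E.q.gf_cons,
                           E.q.gf_tol, E.q.gf_max_sweeps);

    // visit cells in a fresh random permutation of the occupied sites
    perm.clear();
    for (int i = 0; i < E.ntot; ++i) if (E.occ[i] > 0) perm.push_back(i);
    for (int i = (int)perm.size() - 1; i > 0; --i) {
      int j = (int)(runif01() * (i + 1));
      if (j > i) j = i;
      std::swap(perm[i], perm[j]);
    }
    const int dstamp = d;
    for (size_t pi = 0; pi < perm.size(); ++pi) {
      int i = perm[pi];
      if (E.occ[i] == 0 || E.acted[i] == dstamp) continue;
      E.acted[i] = dstamp;
      int z = i / E.nxy, rem = i % E.nxy;
      int y = rem / E.q.Lx, x = rem % E.q.Lx;
      double u = E.gf[i];
      if (runif01() < E.q.d_max * hill_down(u, E.q.K_die, E.q.h_die)) {
        E.occ[i] = 0; E.lin[i] = 0;
        ++E.deaths;
        if (z == 0) ++E.basal_losses;
        continue;
      }
      if (runif01() < E.q.p_max * hill_up(u, E.q.K_div, E.q.h_div)) {
        if (E.divide_at(x, y, z, day, dstamp) > 0) ++divisions;
      }
    }

    // daily census
    long total = 0, basal = 0, nn1 = 0, np53 = 0;
    for (int i = 0; i < E.ntot; ++i) {
      if (E.occ[i] == 0) continue;
      ++total;
      if (i < E.nxy) ++basal;
      if (E.G.n1[E.occ[i] - 1]) ++nn1;
      if (E.G.p53[E.occ[i] - 1]) ++np53;
    }
    series(d, 0) = day;
    series(d, 1) = total; series(d, 2) = basal;
    series(d, 3) = nn1; series(d, 4) = np53;
    series(d, 5) = E.births; series(d, 6) = E.deaths; series(d, 7) = E.sheds;
    series(d, 8) = E.uv_deaths; series(d, 9) = E.basal_losses;
    series(d, 10) = sweeps; series(d, 11) = divisions;

    if ((d + 1) % 7 == 0 && wk < n_weeks) {
      long nsurv = 0;
      if (n_labels > 0) {
        std::vector<char> seen(n_labels + 1, 0);
        for (int i = 0; i < E.nxy; ++i)
          if (E.occ[i] > 0 && E.lin[i] > 0 && !seen[E.lin[i]]) {
            seen[E.lin[i]] = 1; ++nsurv;
          }
      }
      lineage_weekly(wk, 0) = day;
      lineage_weekly(wk, 1) = nsurv;
      ++wk;
    }
  }
  return engine_to_list(E, series, lineage_weekly);
}

// Single daughter-placement attempt for the cell at 1-based lattice coords
// (x, y, z); exposes the knock-on displacement and NOTCH1 veto machinery.
// [[Rcpp::export]]
List place_daughter_cpp(IntegerVector occ, NumericVector gf, IntegerVector lin,
                        NumericVector birth, List geno, List mut, List panel,
                        List par, int x, int y, int z, double day) {
  RNGScope rng;
  Engine E;
  E.q = params_from_list(par);
  E.P = panel_from_list(panel);
  fill_engine_state(E, occ, gf, lin, birth, geno, mut);
  E.reset_ledger();
  if (x < 1 || x > E.q.Lx || y < 1 || y > E.q.Ly || z < 1 || z > E.q.Lz)
    stop("parent site outside the lattice");
  int i = idx3(x - 1, y - 1, z - 1, E.q.Lx, E.q.Ly);
  if (E.occ[i] == 0) stop("parent site is empty");
  int outcome = E.divide_at(x - 1, y - 1, z - 1, day, 0);
  NumericMatrix series(0, 12), lw(0, 2);
  List out = engine_to_list(E, series, lw);
  out["outcome"] = outcome == 0 ? "aborted" : (outcome == 2 ? "shed" : "placed");
  out["births"] = (double)E.births;
  out["sheds"] = (double)E.sheds;
  out["basal_losses"] = (double)E.basal_losses;
  return out;
}

// Stand-alone UV kill (one sun day) on a lattice state.
// [[Rcpp::export]]
List uv_kill_cpp(IntegerVector occ, IntegerVector lin, List geno,
                 double theta_s, bool basal_only, int Lx, int Ly, int Lz) {
  RNGScope rng;
  std::vector<int> o(occ.begin(), occ.end()), l(lin.begin(), lin.end());
  IntegerVector gt = geno["has_tp53"];
  long deaths = 0, basal_losses = 0;
  if (theta_s > 0.0) {
    int zmax = basal_only ? 1 : Lz;
    for (int z = 0; z < zmax; ++z)
      for (int y = 0; y < Ly; ++y)
        for (int x = 0; x < Lx; ++x) {
          int i = idx3(x, y, z, Lx, Ly);
          if (o[i] == 0) continue;
          if (gt[o[i] - 1]) continue;
          if (unif_rand() < theta_s) {
            o[i] = 0; l[i] = 0;
            ++deaths;
            if (z == 0) ++basal_losses;
          }
        }
  }
  return List::create(_["occ"] = IntegerVector(o.begin(), o.end()),
                      _["lineage"] = IntegerVector(l.begin(), l.end()),
                      _["deaths"] = (double)deaths,
                      _["basal_losses"] = (double)basal_losses);
}
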