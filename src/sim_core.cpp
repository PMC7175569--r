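#include <Rcpp.h>
#include <queue>
#include <unordered_map>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Habitat class codes shared with the R side (see R/landscape.R).
static const int HAB_MATRIX = 0, HAB_DISP = 1, HAB_BREED = 2, HAB_BARRIER = 3;

// Compass directions 0..7 clockwise from north; angular deviation between
// two directions is the circular distance on this ring (0..4).
static const int DR[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
static const int DC[8] = {0, 1, 1, 1, 0, -1, -1, -1};

// --- RNG -------------------------------------------------------------------
// Exported single-step helpers draw from R's stream directly; the season
// loop uses a fast xorshift128+ stream seeded from R's stream, so a run is
// still fully determined by set.seed().

struct RRng {
  double operator()() { return unif_rand(); }
};

struct FastRng {
  uint64_t s0, s1;
  explicit FastRng(uint64_t seed) {
    // splitmix64 expansion of the seed into two non-zero state words
    uint64_t z = seed;
    for (int i = 0; i < 2; ++i) {
      z += 0x9E3779B97F4A7C15ULL;
      uint64_t t = z;
      t = (t ^ (t >> 30)) * 0xBF58476D1CE4E5B9ULL;
      t = (t ^ (t >> 27)) * 0x94D049BB133111EBULL;
      t = t ^ (t >> 31);
      if (i == 0) s0 = t | 1ULL; else s1 = t | 1ULL;
    }
  }
  double operator()() {
    uint64_t x = s0, y = s1;
    s0 = y;
    x ^= x << 23;
    s1 = x ^ y ^ (x >> 17) ^ (y >> 26);
    return (double)((s1 + y) >> 11) * (1.0 / 9007199254740992.0);
  }
};

template <class RNG>
static inline int rng_int(RNG &rng, int n) {
  int k = (int)(rng() * n);
  return (k >= n) ? n - 1 : k;
}

// --- step candidates -------------------------------------------------------
// For a non-barrier cell, the step candidates are the cell itself (staying
// put) plus the in-grid, non-barrier Moore neighbours (reflective boundary =
// off-grid cells simply excluded). Dispersal/breeding candidates are stored
// first so the habitat-preference set can be built without rescanning.

struct Cand {
  int tgt;        // 0-based linear index of the candidate cell
  int8_t dir;     // -1 for staying put
  int8_t matrix;  // 1 if the candidate is matrix habitat
};

struct CellCand {
  int n;        // total candidates
  int n_pref;   // leading candidates that are dispersal/breeding habitat
  bool uniform; // admitted set is always all candidates (no mixed habitat)
  Cand c[9];
  // for uniform cells: candidates minimising angular deviation from each
  // previous direction, precomputed (ties listed)
  int8_t nbest[8];
  int8_t best[8][9];
};

static void build_cell_cand(const IntegerMatrix &hab, int r, int c,
                            CellCand &out) {
  const int nr = hab.nrow(), nc = hab.ncol();
  Cand pref[9], rest[9];
  int np = 0, nm = 0;
  int h0 = hab(r, c);
  Cand self; self.tgt = c * nr + r; self.dir = -1;
  self.matrix = (h0 == HAB_MATRIX);
  if (h0 == HAB_DISP || h0 == HAB_BREED) pref[np++] = self;
  else rest[nm++] = self;
  for (int d = 0; d < 8; ++d) {
    int rr = r + DR[d], cc = c + DC[d];
    if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
    int h = hab(rr, cc);
    if (h == HAB_BARRIER) continue;
    Cand cd; cd.tgt = cc * nr + rr; cd.dir = (int8_t)d;
    cd.matrix = (h == HAB_MATRIX);
    if (h == HAB_DISP || h == HAB_BREED) pref[np++] = cd;
    else rest[nm++] = cd;
  }
  out.n = np + nm;
  out.n_pref = np;
  for (int i = 0; i < np; ++i) out.c[i] = pref[i];
  for (int i = 0; i < nm; ++i) out.c[np + i] = rest[i];
  // the admitted set equals the full candidate list when the neighbourhood
  // is not a dispersal/matrix mixture, so the correlation argmin can be
  // precomputed per previous direction
  int n_matrix = 0;
  for (int i = 0; i < out.n; ++i) if (out.c[i].matrix) ++n_matrix;
  out.uniform = (np == 0) || (n_matrix == 0);
  if (out.uniform) {
    for (int pd = 0; pd < 8; ++pd) {
      int bdev = 99, nb = 0;
      for (int i = 0; i < out.n; ++i) {
        int d = out.c[i].dir;
        if (d < 0) continue;
        int dev = d - pd; if (dev < 0) dev = -dev; dev %= 8;
        if (dev > 4) dev = 8 - dev;
        if (dev < bdev) { bdev = dev; nb = 0; out.best[pd][nb++] = (int8_t)i; }
        else if (dev == bdev) out.best[pd][nb++] = (int8_t)i;
      }
      out.nbest[pd] = (int8_t)nb;
    }
  }
}

static std::vector<CellCand> build_cand_table(const IntegerMatrix &hab) {
  const int nr = hab.nrow(), nc = hab.ncol();
  std::vector<CellCand> tab(nr * nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (hab(r, c) != HAB_BARRIER)
        build_cell_cand(hab, r, c, tab[c * nr + r]);
  return tab;
}

// One movement decision: habitat preference first (dispersal/breeding
// candidates always admitted, each matrix candidate independently with
// probability p_matrix; if no dispersal/breeding cell is available all
// candidates stand, giving the uniform choice among equals), then with
// probability p_corr — and only when a previous direction exists — the
// choice is restricted to moving candidates minimising angular deviation
// from the previous direction (ties uniform); otherwise the choice is
// uniform over the admitted set. Returns the index of the chosen candidate.
template <class RNG>
static int select_step(const CellCand &cc, int prev_dir, double p_matrix,
                       double p_corr, RNG &rng) {
  int set[9], nset = 0;
  if (cc.n_pref > 0) {
    for (int i = 0; i < cc.n_pref; ++i) set[nset++] = i;
    for (int i = cc.n_pref; i < cc.n; ++i)
      if (cc.c[i].matrix && rng() < p_matrix) set[nset++] = i;
  } else {
    for (int i = 0; i < cc.n; ++i) set[nset++] = i;
  }
  if (prev_dir >= 0 && rng() < p_corr) {
    int best = 99, bidx[9], nbest = 0;
    for (int j = 0; j < nset; ++j) {
      int d = cc.c[set[j]].dir;
      if (d < 0) continue; // staying put has no direction
      int dev = d - prev_dir; if (dev < 0) dev = -dev; dev %= 8;
      if (dev > 4) dev = 8 - dev;
      if (dev < best) { best = dev; nbest = 0; bidx[nbest++] = set[j]; }
      else if (dev == best) bidx[nbest++] = set[j];
    }
    if (nbest > 0) return bidx[rng_int(rng, nbest)];
  }
  return set[rng_int(rng, nset)];
}

struct WalkState {
  int run;  // consecutive matrix cells since last non-matrix cell
  int last; // 0-based linear index of last non-matrix cell occupied
};

// One day of movement: the first step's reference direction is drawn
// uniformly, then nsteps decisions are made. Entering matrix habitat
// increments the consecutive-matrix counter; exceeding max_run sends the
// agent back to its last non-matrix cell and resets the counter.
template <class RNG>
static void walk_day(int &cell, WalkState &ws, int nsteps,
                     const std::vector<CellCand> &tab,
                     const std::vector<int8_t> &is_matrix,
                     double p_matrix, double p_corr, int max_run,
                     RNG &rng, std::vector<int> *traj) {
  int dir = rng_int(rng, 8);
  for (int s = 0; s < nsteps; ++s) {
    const CellCand &cc = tab[cell];
    int pick;
    if (cc.uniform) {
      if (rng() < p_corr && cc.nbest[dir] > 0) {
        int nb = cc.nbest[dir];
        pick = cc.best[dir][nb == 1 ? 0 : rng_int(rng, nb)];
      } else {
        pick = rng_int(rng, cc.n);
      }
    } else {
      pick = select_step(cc, dir, p_matrix, p_corr, rng);
    }
    cell = cc.c[pick].tgt;
    if (cc.c[pick].dir >= 0) dir = cc.c[pick].dir;
    if (is_matrix[cell]) {
      if (++ws.run > max_run) {
        cell = ws.last;
        ws.run = 0;
      }
    } else {
      ws.run = 0;
      ws.last = cell;
    }
    if (traj) traj->push_back(cell);
  }
}

// Region growing for a female territory: breadth-first accumulation of
// unoccupied breeding cells (4-connectivity) from the seed cell, stopping
// once `target` cells are collected. Returns collected cells (0-based linear
// indices) if at least `minsz` were found, else an empty vector.
static std::vector<int> settle_female_core(const IntegerMatrix &hab,
                                           const IntegerMatrix &fem_occ,
                                           int r, int c, int target,
                                           int minsz,
                                           std::vector<int> &mark, int stamp) {
  std::vector<int> cells;
  const int nr = hab.nrow(), nc = hab.ncol();
  if (hab(r, c) != HAB_BREED || fem_occ(r, c) != 0) return cells;
  std::queue<int> q;
  int seed = c * nr + r;
  mark[seed] = stamp;
  q.push(seed);
  static const int R4[4] = {-1, 1, 0, 0}, C4[4] = {0, 0, -1, 1};
  while (!q.empty() && (int)cells.size() < target) {
    int cur = q.front(); q.pop();
    cells.push_back(cur);
    int rr = cur % nr, ccur = cur / nr;
    for (int k = 0; k < 4; ++k) {
      int r2 = rr + R4[k], c2 = ccur + C4[k];
      if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
      int idx = c2 * nr + r2;
      if (mark[idx] == stamp) continue;
      if (hab(r2, c2) != HAB_BREED || fem_occ(r2, c2) != 0) continue;
      mark[idx] = stamp;
      q.push(idx);
    }
  }
  if ((int)cells.size() < minsz) cells.clear();
  return cells;
}

// Male territory claim: from his current cell the male searches the
// surrounding breeding habitat closest-first (breadth-first over
// 4-connected breeding cells, visiting at most search_max cells — the
// extent of a large male range) and claims the first up to max_f resident
// female territories without a resident male that he encounters. His
// territory is the union of the claimed females' territories.
static std::vector<int> settle_male_core(
    const IntegerMatrix &hab,
    const IntegerMatrix &fem_occ,
    const std::unordered_map<int, int> &claimed_by,
    int r, int c, int max_f, int search_max,
    std::vector<int> &mark, int stamp) {
  std::vector<int> claimed;
  const int nr = hab.nrow(), nc = hab.ncol();
  if (hab(r, c) != HAB_BREED) return claimed;
  std::queue<int> q;
  int seed = c * nr + r;
  mark[seed] = stamp;
  q.push(seed);
  int visited = 0;
  static const int R4[4] = {-1, 1, 0, 0}, C4[4] = {0, 0, -1, 1};
  while (!q.empty() && visited < search_max &&
         (int)claimed.size() < max_f) {
    int cur = q.front(); q.pop();
    ++visited;
    int fid = fem_occ[cur];
    if (fid > 0 && !claimed_by.count(fid) &&
        std::find(claimed.begin(), claimed.end(), fid) == claimed.end())
      claimed.push_back(fid);
    int rr = cur % nr, ccur = cur / nr;
    for (int k = 0; k < 4; ++k) {
      int r2 = rr + R4[k], c2 = ccur + C4[k];
      if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
      int idx = c2 * nr + r2;
      if (mark[idx] == stamp) continue;
      if (hab(r2, c2) != HAB_BREED) continue;
      mark[idx] = stamp;
      q.push(idx);
    }
  }
  return claimed;
}

// Nearest resident male with spare claim capacity, searching breadth-first
// over breeding cells from a newly settled female's seed cell. Returns the
// male id, or 0 when none is within reach.
static int find_nearest_male(const IntegerMatrix &hab,
                             const IntegerMatrix &male_occ,
                             const std::unordered_map<int, int> &mcount,
                             int r, int c, int search_max, int max_claims,
                             std::vector<int> &mark, int stamp) {
  const int nr = hab.nrow(), nc = hab.ncol();
  if (hab(r, c) != HAB_BREED) return 0;
  std::queue<int> q;
  int seed = c * nr + r;
  mark[seed] = stamp;
  q.push(seed);
  int visited = 0;
  static const int R4[4] = {-1, 1, 0, 0}, C4[4] = {0, 0, -1, 1};
  while (!q.empty() && visited < search_max) {
    int cur = q.front(); q.pop();
    ++visited;
    int mid = male_occ[cur];
    if (mid > 0) {
      std::unordered_map<int, int>::const_iterator it = mcount.find(mid);
      int cnt = (it == mcount.end()) ? 0 : it->second;
      if (cnt < max_claims) return mid;
    }
    int rr = cur % nr, ccur = cur / nr;
    for (int k = 0; k < 4; ++k) {
      int r2 = rr + R4[k], c2 = ccur + C4[k];
      if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
      int idx = c2 * nr + r2;
      if (mark[idx] == stamp) continue;
      if (hab(r2, c2) != HAB_BREED) continue;
      mark[idx] = stamp;
      q.push(idx);
    }
  }
  return 0;
}

// [[Rcpp::export]]
List cpp_choose_step(int r, int c, int prev_dir, IntegerMatrix hab,
                     double p_matrix, double p_corr) {
  if (hab(r - 1, c - 1) == HAB_BARRIER)
    stop("trapped agent: current cell is barrier");
  CellCand cc;
  build_cell_cand(hab, r - 1, c - 1, cc);
  RRng rng;
  int pick = select_step(cc, prev_dir, p_matrix, p_corr, rng);
  const int nr = hab.nrow();
  int tgt = cc.c[pick].tgt;
  bool moved = cc.c[pick].dir >= 0;
  return List::create(_["row"] = tgt % nr + 1, _["col"] = tgt / nr + 1,
                      _["direction"] = moved ? (int)cc.c[pick].dir : prev_dir,
                      _["moved"] = moved);
}

// [[Rcpp::export]]
List cpp_walk_one_day(int r, int c, int nsteps, IntegerMatrix hab,
                      double p_matrix, double p_corr, int max_run,
                      int run, int last_r, int last_c) {
  if (hab(r - 1, c - 1) == HAB_BARRIER)
    stop("trapped agent: current cell is barrier");
  const int nr = hab.nrow();
  std::vector<CellCand> tab = build_cand_table(hab);
  std::vector<int8_t> is_matrix(hab.size());
  for (int i = 0; i < hab.size(); ++i) is_matrix[i] = (hab[i] == HAB_MATRIX);
  std::vector<int> traj;
  WalkState ws;
  ws.run = run;
  ws.last = (last_c - 1) * nr + (last_r - 1);
  int cell = (c - 1) * nr + (r - 1);
  RRng rng;
  walk_day(cell, ws, nsteps, tab, is_matrix, p_matrix, p_corr, max_run,
           rng, &traj);
  IntegerMatrix tm(traj.size(), 2);
  for (size_t i = 0; i < traj.size(); ++i) {
    tm(i, 0) = traj[i] % nr + 1;
    tm(i, 1) = traj[i] / nr + 1;
  }
  return List::create(_["trajectory"] = tm,
                      _["row"] = cell % nr + 1, _["col"] = cell / nr + 1,
                      _["run"] = ws.run,
                      _["last_row"] = ws.last % nr + 1,
                      _["last_col"] = ws.last / nr + 1);
}

// [[Rcpp::export]]
IntegerVector cpp_settle_female(IntegerMatrix hab, IntegerMatrix fem_occ,
                                int r, int c, int target, int minsz) {
  std::vector<int> mark(hab.nrow() * hab.ncol(), 0);
  std::vector<int> cells =
      settle_female_core(hab, fem_occ, r - 1, c - 1, target, minsz, mark, 1);
  IntegerVector out(cells.size());
  for (size_t i = 0; i < cells.size(); ++i) out[i] = cells[i] + 1;
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_settle_male(IntegerMatrix hab, IntegerMatrix fem_occ,
                              IntegerVector fem_ids,
                              IntegerVector fem_claimed,
                              int r, int c, int max_claims, int search_max) {
  std::unordered_map<int, int> claimed_by;
  for (int i = 0; i < fem_ids.size(); ++i)
    if (fem_claimed[i] > 0) claimed_by[fem_ids[i]] = fem_claimed[i];
  std::vector<int> mark(fem_occ.nrow() * fem_occ.ncol(), 0);
  std::vector<int> got = settle_male_core(hab, fem_occ, claimed_by,
                                          r - 1, c - 1, max_claims,
                                          search_max, mark, 1);
  return wrap(got);
}

// Full dispersal season: for `days` days, every still-dispersing individual
// (in input order) draws a daily step count, walks, survives the day with
// probability 1 - p_md, and then attempts settlement at its end-of-day
// location. Females found territories (region growing over unoccupied
// breeding habitat) and are assigned to the nearest resident male with
// spare claim capacity; males claim up to `max_claims` unclaimed resident
// female territories. Settlements take effect immediately, so females
// settling early in the season are claimable later in the same season.
// [[Rcpp::export]]
List cpp_dispersal_season(IntegerMatrix hab, IntegerMatrix patch,
                          IntegerMatrix fem_occ_in, IntegerMatrix male_occ_in,
                          IntegerVector d_id, IntegerVector d_sex,
                          IntegerVector d_row, IntegerVector d_col,
                          IntegerVector rf_id, IntegerVector rf_claimed,
                          List rf_cells,
                          double p_matrix, double p_corr, int max_run,
                          NumericVector step_cum,
                          double p_md, int days,
                          int target_terr, int min_terr, int max_claims,
                          int male_search_max) {
  const int nr = hab.nrow(), nc = hab.ncol();
  const int nd = d_id.size();
  IntegerMatrix fem_occ = clone(fem_occ_in);
  IntegerMatrix male_occ = clone(male_occ_in);

  std::vector<CellCand> tab = build_cand_table(hab);
  std::vector<int8_t> is_matrix(hab.size());
  for (int i = 0; i < hab.size(); ++i) is_matrix[i] = (hab[i] == HAB_MATRIX);

  // fast stream seeded from R's stream: a run stays fully determined by
  // set.seed while the inner loop avoids per-draw R RNG overhead
  FastRng rng((uint64_t)(unif_rand() * 9007199254740992.0));

  std::unordered_map<int, int> claimed_by;         // female id -> male id
  std::unordered_map<int, int> mcount;             // male id -> n females
  std::unordered_map<int, std::vector<int> > terr; // female id -> cells
  int n_unclaimed = 0; // resident females without a male, gates male search
  for (int i = 0; i < rf_id.size(); ++i) {
    if (rf_claimed[i] > 0) {
      claimed_by[rf_id[i]] = rf_claimed[i];
      mcount[rf_claimed[i]] += 1;
    } else {
      ++n_unclaimed;
    }
    IntegerVector cl = rf_cells[i];
    std::vector<int> v(cl.size());
    for (int j = 0; j < cl.size(); ++j) v[j] = cl[j] - 1;
    terr[rf_id[i]] = v;
  }

  // per-disperser state: 0 dispersing, 1 dead, 2 settled
  IntegerVector status(nd, 0), death_patch(nd, 0);
  std::vector<int> cell(nd);
  std::vector<WalkState> ws(nd);
  for (int i = 0; i < nd; ++i) {
    cell[i] = (d_col[i] - 1) * nr + (d_row[i] - 1);
    if (hab[cell[i]] == HAB_BARRIER) stop("disperser on a barrier cell");
    ws[i].run = 0;
    ws[i].last = cell[i];
  }

  std::vector<int> mark(nr * nc, 0);
  int stamp = 0;
  const int smax = step_cum.size();

  std::vector<int> nsf_id;                 // newly settled females
  std::vector<std::vector<int> > nsf_cells;
  std::vector<int> nsm_id;                 // newly settled males
  std::vector<std::vector<int> > nsm_fems;
  std::vector<int> asg_fem, asg_male;      // in-season female -> male claims

  for (int day = 0; day < days; ++day) {
    bool active = false;
    for (int i = 0; i < nd; ++i) {
      if (status[i] != 0) continue;
      active = true;
      // daily step count from the intraday step distribution
      double u = rng();
      int nsteps = smax;
      for (int s = 0; s < smax; ++s)
        if (u <= step_cum[s]) { nsteps = s + 1; break; }
      walk_day(cell[i], ws[i], nsteps, tab, is_matrix, p_matrix, p_corr,
               max_run, rng, (std::vector<int> *)NULL);
      // daily mortality
      if (rng() < p_md) {
        status[i] = 1;
        death_patch[i] = patch[cell[i]];
        continue;
      }
      // settlement attempt at end-of-day location
      int r = cell[i] % nr, c = cell[i] / nr;
      if (d_sex[i] == 1) { // female
        ++stamp;
        std::vector<int> cells = settle_female_core(hab, fem_occ, r, c,
                                                    target_terr, min_terr,
                                                    mark, stamp);
        if (!cells.empty()) {
          status[i] = 2;
          for (size_t k = 0; k < cells.size(); ++k)
            fem_occ[cells[k]] = d_id[i];
          terr[d_id[i]] = cells;
          nsf_id.push_back(d_id[i]);
          nsf_cells.push_back(cells);
          // a female settling within reach of a resident male with spare
          // capacity is overlapped by (assigned to) that male
          ++stamp;
          int mid = find_nearest_male(hab, male_occ, mcount, r, c,
                                      male_search_max, max_claims,
                                      mark, stamp);
          if (mid > 0) {
            claimed_by[d_id[i]] = mid;
            mcount[mid] += 1;
            for (size_t k = 0; k < cells.size(); ++k)
              male_occ[cells[k]] = mid;
            asg_fem.push_back(d_id[i]);
            asg_male.push_back(mid);
          } else {
            ++n_unclaimed;
          }
        }
      } else if (n_unclaimed > 0) { // male; search only if a female is free
        ++stamp;
        std::vector<int> got = settle_male_core(hab, fem_occ, claimed_by,
                                                r, c, max_claims,
                                                male_search_max, mark, stamp);
        if (!got.empty()) {
          n_unclaimed -= (int)got.size();
          status[i] = 2;
          for (size_t k = 0; k < got.size(); ++k) {
            claimed_by[got[k]] = d_id[i];
            std::vector<int> &fc = terr[got[k]];
            for (size_t j = 0; j < fc.size(); ++j) male_occ[fc[j]] = d_id[i];
          }
          mcount[d_id[i]] = (int)got.size();
          nsm_id.push_back(d_id[i]);
          nsm_fems.push_back(got);
        }
      }
    }
    if (!active) break;
  }

  List nsf(nsf_cells.size()), nsm(nsm_fems.size());
  for (size_t i = 0; i < nsf_cells.size(); ++i) {
    IntegerVector v(nsf_cells[i].size());
    for (size_t j = 0; j < nsf_cells[i].size(); ++j) v[j] = nsf_cells[i][j] + 1;
    nsf[i] = v;
  }
  for (size_t i = 0; i < nsm_fems.size(); ++i) nsm[i] = wrap(nsm_fems[i]);

  IntegerVector row(nd), col(nd);
  for (int i = 0; i < nd; ++i) {
    row[i] = cell[i] % nr + 1;
    col[i] = cell[i] / nr + 1;
  }
  return List::create(_["status"] = status, _["row"] = row, _["col"] = col,
                      _["death_patch"] = death_patch,
                      _["fem_occ"] = fem_occ, _["male_occ"] = male_occ,
                      _["settled_female_id"] = wrap(nsf_id),
                      _["settled_female_cells"] = nsf,
                      _["settled_male_id"] = wrap(nsm_id),
                      _["settled_male_females"] = nsm,
                      _["assigned_female"] = wrap(asg_fem),
                      _["assigned_male"] = wrap(asg_male));
}

// Connected-component labelling of a logical mask (4-connectivity), used for
// habitat patch statistics and for deriving patch labels from rasters.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  static const int R4[4] = {-1, 1, 0, 0}, C4[4] = {0, 0, -1, 1};
  for (int c0 = 0; c0 < nc; ++c0)
    for (int r0 = 0; r0 < nr; ++r0) {
      if (!mask(r0, c0) || lab(r0, c0) != 0) continue;
      ++next;
      std::queue<std::pair<int, int> > q;
      lab(r0, c0) = next;
      q.push(std::make_pair(r0, c0));
      while (!q.empty()) {
        std::pair<int, int> cur = q.front(); q.pop();
        for (int k = 0; k < 4; ++k) {
          int r2 = cur.first + R4[k], c2 = cur.second + C4[k];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          if (!mask(r2, c2) || lab(r2, c2) != 0) continue;
          lab(r2, c2) = next;
          q.push(std::make_pair(r2, c2));
        }
      }
    }
  return lab;
}
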