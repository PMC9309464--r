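#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Greedy stochastic-movement step on the Moore (8-cell) neighbourhood:
// move to the on-grid, non-nodata neighbour whose AGC is closest to the
// mover's AGC optimum; ties broken uniformly. Exactly one uniform deviate is
// consumed per step (also for a unique minimum), so a step stream is fully
// determined by the R RNG state.
//
// Cells are row-major, 0-based: cell = row * ncol + col.

static const int DR[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
static const int DC[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

// returns chosen neighbour index in 0..7, or -1 if no valid neighbour
static int greedy_neighbour(const NumericVector& agc, int nrow, int ncol,
                            int row, int col, double o) {
  int cand[8];
  double best = R_PosInf;
  int ncand = 0;
  for (int k = 0; k < 8; ++k) {
    int r = row + DR[k], c = col + DC[k];
    if (r < 0 || r >= nrow || c < 0 || c >= ncol) continue;
    double a = agc[r * ncol + c];
    if (ISNAN(a)) continue;
    double d = fabs(a - o);
    if (d < best) {
      best = d;
      cand[0] = k;
      ncand = 1;
    } else if (d == best) {
      cand[ncand++] = k;
    }
  }
  double u = unif_rand(); // always consume one deviate per step
  if (ncand == 0) return -1;
  int pick = (int)(u * ncand);
  if (pick >= ncand) pick = ncand - 1;
  return cand[pick];
}

// [[Rcpp::export]]
IntegerVector sms_step_cpp(NumericVector agc, int nrow, int ncol,
                           int row0, int col0, double o) {
  // row0/col0 are 0-based; returns c(row, col) 0-based or c(-1, -1)
  int k = greedy_neighbour(agc, nrow, ncol, row0, col0, o);
  if (k < 0) return IntegerVector::create(-1, -1);
  return IntegerVector::create(row0 + DR[k], col0 + DC[k]);
}

struct Registry {
  // unpaired adults (and same-year territory settlers), per cell
  std::vector<int> head;   // first candidate index per cell, -1 = none
  std::vector<int> nxt;
  std::vector<int> cell, sex, species, weight, src;
  std::vector<char> active;

  Registry(int ncell) : head(ncell, -1) {}

  void push(int cl, int sx, int sp, int wt, int source) {
    int idx = (int)cell.size();
    cell.push_back(cl); sex.push_back(sx); species.push_back(sp);
    weight.push_back(wt); src.push_back(source); active.push_back(1);
    nxt.push_back(head[cl]);
    head[cl] = idx;
  }
};

// [[Rcpp::export]]
List disperse_cpp(NumericVector agc, IntegerVector cap, IntegerVector slots_in,
                  int nrow, int ncol,
                  IntegerVector res_cell, IntegerVector res_sex,
                  IntegerVector res_species, IntegerVector res_weight,
                  IntegerVector juv_cell, IntegerVector juv_sex,
                  IntegerVector juv_species, NumericVector juv_o,
                  NumericVector juv_tau, NumericVector juv_maxd,
                  double h) {
  const int ncell = nrow * ncol;
  const int nres = res_cell.size();
  const int njuv = juv_cell.size();
  std::vector<int> slots(slots_in.begin(), slots_in.end());

  Registry reg(ncell);
  for (int i = 0; i < nres; ++i) {
    reg.push(res_cell[i], res_sex[i], res_species[i], res_weight[i], i + 1);
  }

  IntegerVector status(njuv);        // 0 dead, 1 territory, 2 join
  IntegerVector settle_cell(njuv, -1);
  IntegerVector partner_src(njuv);   // >0 resident index, <0 -(juvenile index)
  IntegerVector steps(njuv);
  NumericVector distance(njuv);
  const double SQRT2 = std::sqrt(2.0);

  for (int j = 0; j < njuv; ++j) {
    int row = juv_cell[j] / ncol, col = juv_cell[j] % ncol;
    double o = juv_o[j], tau = juv_tau[j], maxd = juv_maxd[j];
    double dist = 0.0;
    int nstep = 0;
    int st = 0, scell = -1, psrc = 0;

    while (true) {
      int k = greedy_neighbour(agc, nrow, ncol, row, col, o);
      if (k < 0) break; // isolated: dies
      row += DR[k]; col += DC[k];
      dist += (DR[k] != 0 && DC[k] != 0) ? SQRT2 : 1.0;
      ++nstep;
      if (dist > maxd + 1e-9) break; // exceeded the kernel draw: dies

      int cl = row * ncol + col;
      if (fabs(agc[cl] - o) > tau) continue; // outside tolerance band

      // join: resident unpaired opposite-sex bird; conspecifics first.
      // a weight-1 single (founder without a reserved slot) is only
      // joinable while the patch has a free slot.
      int ncon = 0, nhet = 0;
      int con[64], het[64];
      for (int ci = reg.head[cl]; ci != -1; ci = reg.nxt[ci]) {
        if (!reg.active[ci]) continue;
        if (reg.sex[ci] == juv_sex[j]) continue;
        if (reg.weight[ci] == 1 && slots[cl] >= cap[cl]) continue;
        if (reg.species[ci] == juv_species[j]) {
          if (ncon < 64) con[ncon++] = ci;
        } else {
          if (nhet < 64) het[nhet++] = ci;
        }
      }
      // mate-seeking precedes territory-staking: a disperser always tries
      // to pair first (conspecific unconditionally, heterospecific with
      // probability h), and only otherwise claims a free territory.
      int mate = -1;
      if (ncon > 0) {
        int pick = (int)(unif_rand() * ncon);
        if (pick >= ncon) pick = ncon - 1;
        mate = con[pick];
      } else if (nhet > 0 && h > 0 && unif_rand() < h) {
        int pick = (int)(unif_rand() * nhet);
        if (pick >= nhet) pick = nhet - 1;
        mate = het[pick];
      }
      if (mate >= 0) {
        reg.active[mate] = 0;
        if (reg.weight[mate] == 1) slots[cl] += 1;
        st = 2; scell = cl; psrc = reg.src[mate];
        break;
      }
      if (slots[cl] + 2 <= cap[cl]) {
        // stake out a territory: two slots, one reserved for a future mate
        slots[cl] += 2;
        reg.push(cl, juv_sex[j], juv_species[j], 2, -(j + 1));
        st = 1; scell = cl;
        break;
      }
    }

    status[j] = st;
    settle_cell[j] = scell;
    partner_src[j] = psrc;
    steps[j] = nstep;
    distance[j] = dist;
  }

  return List::create(
    _["status"] = status, _["settle_cell"] = settle_cell,
    _["partner_src"] = partner_src, _["steps"] = steps,
    _["distance"] = distance,
    _["slots"] = IntegerVector(slots.begin(), slots.end()));
}
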