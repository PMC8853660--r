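#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Shared 8-neighbourhood, cardinal moves first so a cardinal neighbour wins
// elevation ties against a diagonal one of equal drop/distance.
static const int DR[8] = {-1, 0, 1, 0, -1, 1, 1, -1};
static const int DC[8] = {0, 1, 0, -1, 1, 1, -1, -1};

struct HeapNode {
  double key;
  int idx;   // 0-based linear (column-major) cell index
  bool operator>(const HeapNode& o) const {
    if (key != o.key) return key > o.key;
    return idx > o.idx; // deterministic tie-break: lower cell index first
  }
};

typedef std::priority_queue<HeapNode, std::vector<HeapNode>, std::greater<HeapNode> > MinHeap;

// Priority-flood depression filling (optionally with an epsilon gradient so
// every filled cell keeps a strictly descending exit path, which D8 routing
// needs across filled flats). NA cells are off-landscape and act as drains.
// [[Rcpp::export]]
NumericMatrix pflood_cpp(NumericMatrix elev, double eps) {
  int nr = elev.nrow(), nc = elev.ncol(), n = nr * nc;
  NumericMatrix out(nr, nc);
  std::vector<char> closed(n, 0);
  MinHeap open;
  int n_valid = 0;

  for (int i = 0; i < n; ++i) {
    if (NumericMatrix::is_na(elev[i])) { out[i] = NA_REAL; closed[i] = 1; }
    else { out[i] = elev[i]; ++n_valid; }
  }
  if (n_valid == 0) stop("DEM contains no data cells");

  // Seed: grid-edge cells plus cells adjacent to nodata.
  for (int c = 0; c < nc; ++c) for (int r = 0; r < nr; ++r) {
    int i = c * nr + r;
    if (closed[i]) continue;
    bool edge = (r == 0 || r == nr - 1 || c == 0 || c == nc - 1);
    if (!edge) {
      for (int d = 0; d < 8 && !edge; ++d) {
        int rr = r + DR[d], cc = c + DC[d];
        if (NumericMatrix::is_na(elev[cc * nr + rr])) edge = true;
      }
    }
    if (edge) { open.push(HeapNode{out[i], i}); closed[i] = 2; } // 2 = queued
  }

  while (!open.empty()) {
    HeapNode top = open.top(); open.pop();
    int i = top.idx;
    if (closed[i] == 1) continue;
    closed[i] = 1;
    int r = i % nr, c = i / nr;
    for (int d = 0; d < 8; ++d) {
      int rr = r + DR[d], cc = c + DC[d];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      int j = cc * nr + rr;
      if (closed[j]) continue;
      double spill = top.key + (eps > 0 ? eps : 0.0);
      if (out[j] < spill) out[j] = (eps > 0) ? spill : top.key;
      open.push(HeapNode{out[j], j});
      closed[j] = 2;
    }
  }
  return out;
}

// D8 steepest-descent receiver of each cell: 1-based linear index of the
// lowest-cost downslope neighbour (max drop/distance), 0 when the cell has no
// strictly lower neighbour (terminal/pit), NA for nodata cells.
// [[Rcpp::export]]
IntegerMatrix d8_receiver_cpp(NumericMatrix elev) {
  int nr = elev.nrow(), nc = elev.ncol();
  IntegerMatrix rec(nr, nc);
  const double SQRT2 = std::sqrt(2.0);
  for (int c = 0; c < nc; ++c) for (int r = 0; r < nr; ++r) {
    int i = c * nr + r;
    if (NumericMatrix::is_na(elev[i])) { rec[i] = NA_INTEGER; continue; }
    double best = 0.0;
    int bestj = 0;
    for (int d = 0; d < 8; ++d) {
      int rr = r + DR[d], cc = c + DC[d];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      int j = cc * nr + rr;
      if (NumericMatrix::is_na(elev[j])) continue;
      double drop = (elev[i] - elev[j]) / (d < 4 ? 1.0 : SQRT2);
      if (drop > best) { best = drop; bestj = j + 1; }
    }
    rec[i] = bestj;
  }
  return rec;
}

static inline double move_cost(double zi, double zj, double dist_m,
                               int strategy, double k, double cpen,
                               double gmax_i, double zmin, double zrange) {
  double dz = zj - zi;
  double w = dist_m * (1.0 + k * (dz > 0 ? dz : 0.0));
  if (strategy == 2) {
    // steepness-deficit penalty: the move along the cell's steepest descent
    // is cheapest (deficit 0), moves deviating from the drainage direction
    // pay in proportion to the gradient they give up
    double grad = dz < 0 ? (-dz / dist_m) : 0.0;
    double deficit = gmax_i - grad;
    if (deficit > 0) w *= (1.0 + cpen * deficit);
  } else if (strategy == 3 && zrange > 0) {
    double relz = ((zi + zj) * 0.5 - zmin) / zrange;
    if (relz < 0) relz = 0;
    w *= (1.0 + cpen * relz);
  }
  return w;
}

// Deterministic Dijkstra on the 8-connected lattice with elevation-derived
// directed move costs. start/goals are 1-based linear indices; returns the
// cost-to-start vector and the predecessor vector (0 = none). Stops once all
// goals are settled when early_stop is true.
// [[Rcpp::export]]
List dijkstra_grid_cpp(NumericMatrix elev, int start, IntegerVector goals,
                       double cellsize, int strategy, double k, double cpen,
                       bool early_stop) {
  int nr = elev.nrow(), nc = elev.ncol(), n = nr * nc;
  if (start < 1 || start > n) stop("start cell off grid");
  if (NumericMatrix::is_na(elev[start - 1])) stop("start cell is nodata");

  double zmin = R_PosInf, zmax = R_NegInf;
  for (int i = 0; i < n; ++i) {
    if (NumericMatrix::is_na(elev[i])) continue;
    if (elev[i] < zmin) zmin = elev[i];
    if (elev[i] > zmax) zmax = elev[i];
  }
  double zrange = zmax - zmin;

  std::vector<double> dist(n, R_PosInf);
  std::vector<int> pred(n, 0);
  std::vector<char> done(n, 0);
  std::vector<char> is_goal(n, 0);
  int n_goal = 0;
  for (int g = 0; g < goals.size(); ++g) {
    int gi = goals[g];
    if (gi >= 1 && gi <= n && !is_goal[gi - 1]) { is_goal[gi - 1] = 1; ++n_goal; }
  }

  const double SQRT2 = std::sqrt(2.0);
  MinHeap open;
  dist[start - 1] = 0.0;
  open.push(HeapNode{0.0, start - 1});
  int goals_left = n_goal;

  while (!open.empty()) {
    HeapNode top = open.top(); open.pop();
    int i = top.idx;
    if (done[i]) continue;
    done[i] = 1;
    if (is_goal[i] && --goals_left == 0 && early_stop) break;
    int r = i % nr, c = i / nr;
    double zi = elev[i];
    double gmax_i = 0.0;
    if (strategy == 2) {
      for (int d = 0; d < 8; ++d) {
        int rr = r + DR[d], cc = c + DC[d];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        int j = cc * nr + rr;
        if (NumericMatrix::is_na(elev[j])) continue;
        double g = (zi - elev[j]) / (cellsize * (d < 4 ? 1.0 : SQRT2));
        if (g > gmax_i) gmax_i = g;
      }
    }
    for (int d = 0; d < 8; ++d) {
      int rr = r + DR[d], cc = c + DC[d];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      int j = cc * nr + rr;
      if (done[j] || NumericMatrix::is_na(elev[j])) continue;
      double dm = cellsize * (d < 4 ? 1.0 : SQRT2);
      double nd = dist[i] + move_cost(zi, elev[j], dm, strategy, k, cpen, gmax_i, zmin, zrange);
      double tol = 1e-12 * (1.0 + std::fabs(nd));
      if (nd < dist[j] - tol) {
        dist[j] = nd; pred[j] = i + 1;
        open.push(HeapNode{nd, j});
      } else if (std::fabs(nd - dist[j]) <= tol && pred[j] > 0 && (i + 1) < pred[j]) {
        pred[j] = i + 1; // lexicographic predecessor tie-break
      }
    }
  }
  return List::create(_["dist"] = NumericVector(dist.begin(), dist.end()),
                      _["pred"] = IntegerVector(pred.begin(), pred.end()));
}
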