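// Compartmental Cellular Potts Model engine.
//
// Lattice layout matches the R matrix passed in: H rows (y), W columns (x),
// column-major, site index = x*H + y (0-based). Coordinates reported to R
// (centroids, spring anchors) are 1-based, consistent with R indexing.
//
// Codes shared with the R side:
//   cell class:   1 mesenchymal, 2 epithelial, 3 ecm
//   comp role:    0 body, 1 apical, 2 lateral, 3 basal, 4 ecm
//   contact type: 0 medium, 1 mesenchymal, 2 ecm, 3 apical, 4 lateral,
//                 5 basal, 6 met-apical, 7 met-lateral, 8 met-basal
//                 (6-8: nascent epithelium created by MET)
//   spring kind:  1 junction (snaps), 2 cytoskeleton, 3 anchor/mesh,
//                 4 matrix tether (snaps)
//   scenario:     0 none, 1 ecm-contact MET, 2 lateral/basal-contact MET

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <algorithm>
using namespace Rcpp;

namespace {

// xoshiro256++ with splitmix64 seeding: fast, seed-deterministic,
// independent of R's RNG state.
struct RNG {
  uint64_t s[4];
  explicit RNG(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; i++) {
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }
  inline int below(int n) { return (int)(next() % (uint64_t)n); }
};

const int DX8[8] = { 1, -1, 0, 0, 1, 1, -1, -1 };
const int DY8[8] = { 0, 0, 1, -1, 1, -1, 1, -1 };
const int DX4[4] = { 1, -1, 0, 0 };
const int DY4[4] = { 0, 0, 1, -1 };

struct Spring {
  int a, b;          // compartment labels; b == 0 => fixed anchor point
  double ax, ay;     // anchor point (1-based coords) when b == 0
  double rest, k, snap; // snap = absolute length threshold (Inf: never)
  int kind, side;    // side: -1 fixed strip, +1 pulled strip, 0 free,
                     //       +2 vertical rail (y-only anchor, x follows)
  bool alive;
};

struct Event { int mcs, type, id; double extra; }; // type: 1 snap, 2 met

struct Engine {
  int W = 0, H = 0;
  std::vector<int> grid;

  int nComp = 0;
  std::vector<int> compCell, compRole, compType, compArea;
  std::vector<double> compTarget, compLam, compSumX, compSumY;
  std::vector<std::vector<int>> compSites;
  std::vector<int> sitePos;

  int nCell = 0;
  std::vector<int> cellClass, cellMet, cellStreak, cellBody;

  std::vector<Spring> springs;
  std::vector<double> sprLen;  // cached current lengths, kept in sync
  std::vector<std::vector<int>> compSprings;
  int activeRight = 0;         // rightmost non-medium column + 2 (0-based)

  double J[9][9];
  double Jintra = 0.0, temp = 1.0;
  double captureRadius = 8.0, junctionRest = 4.0, snapExt = 5.0;
  double kJunction = 1.0, kCyto = 1.0;
  int metThreshold = 600, metMinContact = 3;

  double somSumX = 0, somSumY = 0;
  long somN = 0;
  double anchorShift = 0;

  std::vector<Event> events;

  inline bool somitic(int type) const {
    return type == 1 || type >= 3;   // all epithelial types 3-8 included
  }
  inline int idx(int x, int y) const { return x * H + y; }

  // ---- import / export -------------------------------------------------

  void load(const List& state) {
    IntegerMatrix g = state["grid"];
    H = g.nrow(); W = g.ncol();
    grid.assign(g.begin(), g.end());

    List comp = state["comp"];
    IntegerVector cc = comp["cell"], cr = comp["role"], ct = comp["ctype"];
    NumericVector tgt = comp["target"], lam = comp["lam"];
    nComp = cc.size();
    compCell.assign(cc.begin(), cc.end());
    compRole.assign(cr.begin(), cr.end());
    compType.assign(ct.begin(), ct.end());
    compTarget.assign(tgt.begin(), tgt.end());
    compLam.assign(lam.begin(), lam.end());
    // +1 sentinel slot so label indexing is 1-based without offsets
    compCell.insert(compCell.begin(), 0);
    compRole.insert(compRole.begin(), 0);
    compType.insert(compType.begin(), 0);
    compTarget.insert(compTarget.begin(), 0.0);
    compLam.insert(compLam.begin(), 0.0);

    compArea.assign(nComp + 1, 0);
    compSumX.assign(nComp + 1, 0.0);
    compSumY.assign(nComp + 1, 0.0);
    compSites.assign(nComp + 1, {});
    sitePos.assign(W * H, -1);
    somSumX = somSumY = 0; somN = 0;
    activeRight = 0;
    for (int x = 0; x < W; x++) {
      for (int y = 0; y < H; y++) {
        int lab = grid[idx(x, y)];
        if (lab == 0) continue;
        if (x + 2 > activeRight) activeRight = std::min(x + 2, W - 2);
        if (lab < 0 || lab > nComp)
          stop("integrity error: unregistered label %d in grid", lab);
        sitePos[idx(x, y)] = (int)compSites[lab].size();
        compSites[lab].push_back(idx(x, y));
        compArea[lab]++;
        compSumX[lab] += x + 1;
        compSumY[lab] += y + 1;
        if (somitic(compType[lab])) {
          somSumX += x + 1; somSumY += y + 1; somN++;
        }
      }
    }
    for (int l = 1; l <= nComp; l++)
      if (compArea[l] == 0)
        stop("integrity error: compartment %d has no sites in grid", l);

    IntegerVector cls = state["cellClass"], met = state["cellMet"],
                  stk = state["cellStreak"];
    nCell = cls.size();
    cellClass.assign(cls.begin(), cls.end()); cellClass.insert(cellClass.begin(), 0);
    cellMet.assign(met.begin(), met.end());   cellMet.insert(cellMet.begin(), 0);
    cellStreak.assign(stk.begin(), stk.end()); cellStreak.insert(cellStreak.begin(), 0);
    cellBody.assign(nCell + 1, 0);
    for (int l = 1; l <= nComp; l++)
      if (compRole[l] == 0 || compRole[l] == 4) cellBody[compCell[l]] = l;

    List spr = state["spr"];
    IntegerVector sa = spr["a"], sb = spr["b"], skind = spr["kind"],
                  sside = spr["side"];
    NumericVector sax = spr["ax"], say = spr["ay"], srest = spr["rest"],
                  sk = spr["k"], ssnap = spr["snap"];
    LogicalVector salive = spr["alive"];
    int nS = sa.size();
    springs.clear(); springs.reserve(nS);
    compSprings.assign(nComp + 1, {});
    for (int i = 0; i < nS; i++) {
      Spring s;
      s.a = sa[i]; s.b = sb[i]; s.ax = sax[i]; s.ay = say[i];
      s.rest = srest[i]; s.k = sk[i]; s.snap = ssnap[i];
      s.kind = skind[i]; s.side = sside[i]; s.alive = salive[i];
      if (s.a < 1 || s.a > nComp || s.b < 0 || s.b > nComp)
        stop("integrity error: spring %d references unknown compartment", i + 1);
      springs.push_back(s);
      if (s.alive) {
        compSprings[s.a].push_back(i);
        if (s.b > 0) compSprings[s.b].push_back(i);
      }
    }
    sprLen.resize(springs.size());
    for (size_t i = 0; i < springs.size(); i++)
      sprLen[i] = springs[i].alive ? springLen(springs[i]) : 0.0;

    List par = state["params"];
    NumericMatrix Jm = par["J"];
    if (Jm.nrow() != 9 || Jm.ncol() != 9)
      stop("contact-energy matrix must be 9x9");
    for (int i = 0; i < 9; i++)
      for (int j = 0; j < 9; j++) J[i][j] = Jm(i, j);
    Jintra = as<double>(par["Jintra"]);
    temp = as<double>(par["temp"]);
    snapExt = as<double>(par["snapExt"]);
    captureRadius = as<double>(par["captureRadius"]);
    junctionRest = as<double>(par["junctionRest"]);
    kJunction = as<double>(par["kJunction"]);
    kCyto = as<double>(par["kCyto"]);
    metThreshold = as<int>(par["metThreshold"]);
    metMinContact = as<int>(par["metMinContact"]);
    anchorShift = as<double>(state["anchorShift"]);
  }

  List dump(const List& stateIn) const {
    IntegerMatrix g(H, W);
    std::copy(grid.begin(), grid.end(), g.begin());
    List comp = List::create(
      _["cell"] = IntegerVector(compCell.begin() + 1, compCell.end()),
      _["role"] = IntegerVector(compRole.begin() + 1, compRole.end()),
      _["ctype"] = IntegerVector(compType.begin() + 1, compType.end()),
      _["area"] = IntegerVector(compArea.begin() + 1, compArea.end()),
      _["target"] = NumericVector(compTarget.begin() + 1, compTarget.end()),
      _["lam"] = NumericVector(compLam.begin() + 1, compLam.end()),
      _["sumx"] = NumericVector(compSumX.begin() + 1, compSumX.end()),
      _["sumy"] = NumericVector(compSumY.begin() + 1, compSumY.end()));
    int nS = springs.size();
    IntegerVector sa(nS), sb(nS), skind(nS), sside(nS);
    NumericVector sax(nS), say(nS), srest(nS), sk(nS), ssnap(nS);
    LogicalVector salive(nS);
    for (int i = 0; i < nS; i++) {
      const Spring& s = springs[i];
      sa[i] = s.a; sb[i] = s.b; sax[i] = s.ax; say[i] = s.ay;
      srest[i] = s.rest; sk[i] = s.k; ssnap[i] = s.snap;
      skind[i] = s.kind; sside[i] = s.side; salive[i] = s.alive;
    }
    List spr = List::create(
      _["a"] = sa, _["b"] = sb, _["ax"] = sax, _["ay"] = say,
      _["rest"] = srest, _["k"] = sk, _["snap"] = ssnap,
      _["kind"] = skind, _["side"] = sside, _["alive"] = salive);
    return List::create(
      _["grid"] = g, _["comp"] = comp,
      _["cellClass"] = IntegerVector(cellClass.begin() + 1, cellClass.end()),
      _["cellMet"] = IntegerVector(cellMet.begin() + 1, cellMet.end()),
      _["cellStreak"] = IntegerVector(cellStreak.begin() + 1, cellStreak.end()),
      _["spr"] = spr,
      _["anchorShift"] = anchorShift,
      _["params"] = stateIn["params"]);
  }

  // ---- energies --------------------------------------------------------

  inline double contactJ(int a, int b) const {
    if (a == b) return 0.0;
    if (a > 0 && b > 0 && compCell[a] == compCell[b]) return Jintra;
    int ta = (a == 0) ? 0 : compType[a];
    int tb = (b == 0) ? 0 : compType[b];
    return J[ta][tb];
  }

  inline void endpointA(const Spring& s, int hypT, int hypS,
                        double dx, double dy, int lab,
                        double& px, double& py) const {
    // centroid of compartment `lab`, hypothetically moving one site worth
    // (dx,dy) from compartment hypT to hypS
    double sx = compSumX[lab], sy = compSumY[lab];
    double n = compArea[lab];
    if (lab == hypT) { sx -= dx; sy -= dy; n -= 1; }
    else if (lab == hypS) { sx += dx; sy += dy; n += 1; }
    px = sx / n; py = sy / n;
  }

  double springLen(const Spring& s) const {
    double ax = compSumX[s.a] / compArea[s.a];
    double ay = compSumY[s.a] / compArea[s.a];
    double bx, by;
    if (s.b > 0) { bx = compSumX[s.b] / compArea[s.b]; by = compSumY[s.b] / compArea[s.b]; }
    else if (s.side == 2) { bx = ax; by = s.ay; }  // rail: y-deviation only
    else { bx = s.ax; by = s.ay; }
    return std::sqrt((ax - bx) * (ax - bx) + (ay - by) * (ay - by));
  }

  double springEnergyHyp(const Spring& s, int hypT, int hypS,
                         double dx, double dy) const {
    double ax, ay, bx, by;
    endpointA(s, hypT, hypS, dx, dy, s.a, ax, ay);
    if (s.b > 0) endpointA(s, hypT, hypS, dx, dy, s.b, bx, by);
    else if (s.side == 2) { bx = ax; by = s.ay; }
    else { bx = s.ax; by = s.ay; }
    double d = std::sqrt((ax - bx) * (ax - bx) + (ay - by) * (ay - by));
    return 0.5 * s.k * (d - s.rest) * (d - s.rest);
  }

  double totalEnergy() const {
    double E = 0;
    // contact: each unordered in-grid neighbour pair once (orders 1+2)
    for (int x = 0; x < W; x++) {
      for (int y = 0; y < H; y++) {
        int a = grid[idx(x, y)];
        // forward half of the 8-neighbourhood
        static const int FDX[4] = { 1, 0, 1, 1 };
        static const int FDY[4] = { 0, 1, 1, -1 };
        for (int d = 0; d < 4; d++) {
          int nx = x + FDX[d], ny = y + FDY[d];
          if (nx < 0 || nx >= W || ny < 0 || ny >= H) continue;
          E += contactJ(a, grid[idx(nx, ny)]);
        }
      }
    }
    for (int l = 1; l <= nComp; l++) {
      double dv = compArea[l] - compTarget[l];
      E += compLam[l] * dv * dv;
    }
    for (const Spring& s : springs) {
      if (!s.alive) continue;
      double d = springLen(s);
      E += 0.5 * s.k * (d - s.rest) * (d - s.rest);
    }
    return E;
  }

  // status: 0 ok, 1 no-op (s == t), 2 forbidden (would annihilate)
  double deltaEnergy(int x, int y, int s, int& status) const {
    int t = grid[idx(x, y)];
    if (s == t) { status = 1; return 0.0; }
    if (t > 0 && compArea[t] == 1) { status = 2; return 0.0; }
    status = 0;
    double dE = 0;
    for (int d = 0; d < 8; d++) {
      int nx = x + DX8[d], ny = y + DY8[d];
      if (nx < 0 || nx >= W || ny < 0 || ny >= H) continue;
      int nb = grid[idx(nx, ny)];
      dE += contactJ(s, nb) - contactJ(t, nb);
    }
    if (t > 0) {
      double dv = compArea[t] - compTarget[t];
      dE += compLam[t] * ((dv - 1) * (dv - 1) - dv * dv);
    }
    if (s > 0) {
      double dv = compArea[s] - compTarget[s];
      dE += compLam[s] * ((dv + 1) * (dv + 1) - dv * dv);
    }
    // springs attached to t or s: centroids shift
    double cx = x + 1, cy = y + 1;
    if (t > 0) {
      for (int si : compSprings[t]) {
        const Spring& sp = springs[si];
        if (!sp.alive) continue;
        double d0 = sprLen[si];
        dE += springEnergyHyp(sp, t, s, cx, cy)
              - 0.5 * sp.k * (d0 - sp.rest) * (d0 - sp.rest);
      }
    }
    if (s > 0) {
      for (int si : compSprings[s]) {
        const Spring& sp = springs[si];
        if (!sp.alive) continue;
        if (t > 0 && (sp.a == t || sp.b == t)) continue; // already counted
        double d0 = sprLen[si];
        dE += springEnergyHyp(sp, t, s, cx, cy)
              - 0.5 * sp.k * (d0 - sp.rest) * (d0 - sp.rest);
      }
    }
    return dE;
  }

  // ---- dynamics --------------------------------------------------------

  void applyCopy(int x, int y, int s) {
    int p = idx(x, y);
    int t = grid[p];
    double cx = x + 1, cy = y + 1;
    if (t > 0) {
      int pos = sitePos[p];
      std::vector<int>& v = compSites[t];
      int last = v.back();
      v[pos] = last; sitePos[last] = pos;
      v.pop_back();
      compArea[t]--; compSumX[t] -= cx; compSumY[t] -= cy;
      if (somitic(compType[t])) { somSumX -= cx; somSumY -= cy; somN--; }
    }
    grid[p] = s;
    if (s > 0) {
      sitePos[p] = (int)compSites[s].size();
      compSites[s].push_back(p);
      compArea[s]++; compSumX[s] += cx; compSumY[s] += cy;
      if (somitic(compType[s])) { somSumX += cx; somSumY += cy; somN++; }
    } else {
      sitePos[p] = -1;
    }
    if (s > 0 && x + 2 > activeRight) activeRight = std::min(x + 2, W - 2);
    if (t > 0)
      for (int si : compSprings[t])
        if (springs[si].alive) sprLen[si] = springLen(springs[si]);
    if (s > 0)
      for (int si : compSprings[s])
        if (springs[si].alive) sprLen[si] = springLen(springs[si]);
  }

  long mcsSweep(RNG& rng) {
    long accepted = 0;
    int nAttempt = W * H;
    int iw = W - 2, ih = H - 2;
    for (int k = 0; k < nAttempt; k++) {
      int x = 1 + rng.below(iw);
      int y = 1 + rng.below(ih);
      int d = rng.below(4);
      if (x > activeRight) continue;
      int nx = x + DX4[d], ny = y + DY4[d];
      int s = grid[idx(nx, ny)];
      int t = grid[idx(x, y)];
      if (s == t) continue;
      if (t > 0 && compArea[t] == 1) continue;
      int status;
      double dE = deltaEnergy(x, y, s, status);
      if (dE <= 0 || rng.unif() < std::exp(-dE / temp)) {
        applyCopy(x, y, s);
        accepted++;
      }
    }
    return accepted;
  }

  std::vector<int> updateSprings(int mcs) {
    std::vector<int> snapped;
    for (size_t i = 0; i < springs.size(); i++) {
      Spring& s = springs[i];
      if (!s.alive || (s.kind != 1 && s.kind != 4)) continue;
      if (springLen(s) > s.snap) {
        s.alive = false;
        dropFromIndex((int)i);
        snapped.push_back((int)i + 1);
        events.push_back({ mcs, 1, (int)i + 1, springLen(s) });
      }
    }
    return snapped;
  }

  void dropFromIndex(int si) {
    const Spring& s = springs[si];
    auto rm = [&](int lab) {
      std::vector<int>& v = compSprings[lab];
      v.erase(std::remove(v.begin(), v.end(), si), v.end());
    };
    rm(s.a);
    if (s.b > 0) rm(s.b);
  }

  // qualifying boundary site-pairs this MCS for a mesenchymal cell
  int contactCount(int cell, int scenario) const {
    int body = cellBody[cell];
    int count = 0;
    for (int p : compSites[body]) {
      int x = p / H, y = p % H;
      for (int d = 0; d < 8; d++) {
        int nx = x + DX8[d], ny = y + DY8[d];
        if (nx < 0 || nx >= W || ny < 0 || ny >= H) continue;
        int nb = grid[idx(nx, ny)];
        if (nb == 0 || nb == body) continue;
        int ty = compType[nb];
        if (scenario == 1 && ty == 2) count++;
        else if (scenario == 2 && (ty == 4 || ty == 5 || ty == 7 || ty == 8))
          count++;
      }
    }
    return count;
  }

  void updateTimersAndMet(int mcs, int scenario) {
    if (scenario == 0) return;
    std::vector<int> ready;
    for (int c = 1; c <= nCell; c++) {
      if (cellClass[c] != 1) continue;
      if (contactCount(c, scenario) >= metMinContact) {
        cellStreak[c]++;
        if (cellStreak[c] >= metThreshold && !cellMet[c]) ready.push_back(c);
      } else {
        cellStreak[c] = 0;
      }
    }
    for (int c : ready) executeMet(c, mcs, scenario);
  }

  void executeMet(int c, int mcs, int trigger) {
    if (cellClass[c] != 1)
      stop("precondition error: cell %d is not mesenchymal", c);
    if (cellStreak[c] < metThreshold)
      stop("precondition error: cell %d contact streak %d below threshold %d",
           c, cellStreak[c], metThreshold);
    int q = cellBody[c];
    // outward normal from somite-cluster centroid to cell centroid
    double ccx = compSumX[q] / compArea[q], ccy = compSumY[q] / compArea[q];
    double scx = somSumX / somN, scy = somSumY / somN;
    double nx = ccx - scx, ny = ccy - scy;
    double nn = std::sqrt(nx * nx + ny * ny);
    if (nn < 1e-9) { nx = 1; ny = 0; } else { nx /= nn; ny /= nn; }

    // partition sites 1:2:1 by projection on the outward normal
    std::vector<int> sites = compSites[q];
    std::vector<std::pair<double, int>> proj;
    proj.reserve(sites.size());
    for (int p : sites) {
      double x = p / H + 1, y = p % H + 1;
      proj.push_back({ x * nx + y * ny, p });
    }
    std::sort(proj.begin(), proj.end());
    int n = (int)proj.size();
    int nA = std::max(1, (int)std::lround(n * 0.25));
    int nB = std::max(1, (int)std::lround(n * 0.25));
    if (nA + nB >= n) { nA = 1; nB = (n > 2) ? 1 : 0; }

    int labL = ++nComp; // lateral (nascent)
    compCell.push_back(c); compRole.push_back(2); compType.push_back(7);
    int labB = (nB > 0) ? ++nComp : 0; // basal (nascent)
    if (nB > 0) {
      compCell.push_back(c); compRole.push_back(3); compType.push_back(8);
    }
    double tq = compTarget[q];
    compTarget[q] = tq * 0.25;
    compTarget.push_back(tq * 0.5);
    if (nB > 0) compTarget.push_back(tq * 0.25);
    compLam.push_back(compLam[q]);
    if (nB > 0) compLam.push_back(compLam[q]);
    compArea.push_back(0); compSumX.push_back(0); compSumY.push_back(0);
    compSites.push_back({});
    compSprings.push_back({});
    if (nB > 0) {
      compArea.push_back(0); compSumX.push_back(0); compSumY.push_back(0);
      compSites.push_back({});
      compSprings.push_back({});
    }
    // innermost quarter stays as label q -> apical (nascent)
    compRole[q] = 1; compType[q] = 6;
    for (int i = nA; i < n; i++) {
      int p = proj[i].second;
      int dst = (nB > 0 && i >= n - nB) ? labB : labL;
      // move site p from q to dst (both somitic: cluster sums unchanged)
      int pos = sitePos[p];
      std::vector<int>& v = compSites[q];
      int last = v.back();
      v[pos] = last; sitePos[last] = pos; v.pop_back();
      double cx = p / H + 1, cy = p % H + 1;
      compArea[q]--; compSumX[q] -= cx; compSumY[q] -= cy;
      grid[p] = dst;
      sitePos[p] = (int)compSites[dst].size();
      compSites[dst].push_back(p);
      compArea[dst]++; compSumX[dst] += cx; compSumY[dst] += cy;
    }

    cellClass[c] = 2; cellMet[c] = 1;

    auto addSpring = [&](int a, int b, double rest, double k, double snap,
                         int kind) {
      Spring s;
      s.a = a; s.b = b; s.ax = 0; s.ay = 0;
      s.rest = rest; s.k = k; s.snap = snap; s.kind = kind; s.side = 0;
      s.alive = true;
      int si = (int)springs.size();
      springs.push_back(s);
      sprLen.push_back(springLen(s));
      compSprings[a].push_back(si);
      if (b > 0) compSprings[b].push_back(si);
    };
    double inf = R_PosInf;
    auto cdist = [&](int a, int b) {
      double dx = compSumX[a] / compArea[a] - compSumX[b] / compArea[b];
      double dy = compSumY[a] / compArea[a] - compSumY[b] / compArea[b];
      return std::sqrt(dx * dx + dy * dy);
    };
    addSpring(q, labL, cdist(q, labL), kCyto, inf, 2);
    if (nB > 0) {
      addSpring(labL, labB, cdist(labL, labB), kCyto, inf, 2);
      addSpring(q, labB, cdist(q, labB), kCyto, inf, 2);
    }
    // junctions to the <=2 nearest apical compartments of other cells
    std::vector<std::pair<double, int>> cand;
    for (int l = 1; l <= nComp; l++) {
      if (compRole[l] != 1 || compCell[l] == c) continue;
      double d = cdist(q, l);
      if (d <= captureRadius) cand.push_back({ d, l });
    }
    std::sort(cand.begin(), cand.end());
    for (int i = 0; i < (int)cand.size() && i < 2; i++)
      addSpring(q, cand[i].second, junctionRest, kJunction,
                junctionRest + snapExt, 1);

    events.push_back({ mcs, 2, c, (double)trigger });
  }

  void applyStrain(double d) {
    if (d == 0) return;
    for (size_t i = 0; i < springs.size(); i++) {
      Spring& s = springs[i];
      if (s.side != 1) continue;
      if (s.ax + d > W - 1)
        stop("domain-overflow error: anchor displacement exceeds lattice");
      s.ax += d;
      if (s.alive) sprLen[i] = springLen(s);
    }
    anchorShift += d;
  }
};

Engine makeEngine(const List& state) {
  Engine e;
  e.load(state);
  return e;
}

DataFrame eventsToDf(const std::vector<Event>& ev) {
  int n = ev.size();
  IntegerVector mcs(n), type(n), id(n);
  NumericVector extra(n);
  CharacterVector what(n);
  for (int i = 0; i < n; i++) {
    mcs[i] = ev[i].mcs; type[i] = ev[i].type; id[i] = ev[i].id;
    extra[i] = ev[i].extra;
    what[i] = (ev[i].type == 1) ? "snap" : "met";
  }
  return DataFrame::create(_["mcs"] = mcs, _["event"] = what, _["id"] = id,
                           _["extra"] = extra);
}

} // namespace

// [[Rcpp::export]]
double cppTotalEnergy(List state) {
  Engine e = makeEngine(state);
  return e.totalEnergy();
}

// [[Rcpp::export]]
List cppDeltaEnergy(List state, int x, int y, int srcLabel) {
  Engine e = makeEngine(state);
  if (x < 1 || x > e.W || y < 1 || y > e.H)
    stop("site (%d, %d) outside grid", x, y);
  int status;
  double dE = e.deltaEnergy(x - 1, y - 1, srcLabel, status);
  return List::create(_["delta"] = dE, _["status"] = status);
}

// [[Rcpp::export]]
List cppAcceptanceTrials(List state, int x, int y, int srcLabel, int n,
                         int seed) {
  Engine e = makeEngine(state);
  int status;
  double dE = e.deltaEnergy(x - 1, y - 1, srcLabel, status);
  if (status != 0) stop("attempt is a no-op or forbidden");
  RNG rng((uint64_t)seed);
  int acc = 0;
  for (int i = 0; i < n; i++)
    if (dE <= 0 || rng.unif() < std::exp(-dE / e.temp)) acc++;
  return List::create(_["delta"] = dE, _["accepted"] = acc, _["trials"] = n);
}

// [[Rcpp::export]]
List cppUpdateSprings(List state) {
  Engine e = makeEngine(state);
  std::vector<int> snapped = e.updateSprings(0);
  return List::create(_["state"] = e.dump(state),
                      _["snapped"] = IntegerVector(snapped.begin(), snapped.end()));
}

// [[Rcpp::export]]
List cppUpdateTimers(List state, int scenario) {
  Engine e = makeEngine(state);
  if (scenario < 0 || scenario > 2) stop("unknown scenario code %d", scenario);
  // timer update only; MET execution is a separate call
  if (scenario > 0) {
    for (int c = 1; c <= e.nCell; c++) {
      if (e.cellClass[c] != 1) continue;
      if (e.contactCount(c, scenario) >= e.metMinContact) e.cellStreak[c]++;
      else e.cellStreak[c] = 0;
    }
  }
  return List::create(_["state"] = e.dump(state));
}

// [[Rcpp::export]]
List cppContactCounts(List state, int scenario) {
  Engine e = makeEngine(state);
  IntegerVector cells, counts;
  for (int c = 1; c <= e.nCell; c++) {
    if (e.cellClass[c] != 1) continue;
    cells.push_back(c);
    counts.push_back(e.contactCount(c, scenario));
  }
  return List::create(_["cell"] = cells, _["count"] = counts);
}

// [[Rcpp::export]]
List cppExecuteMet(List state, int cellId) {
  Engine e = makeEngine(state);
  if (cellId < 1 || cellId > e.nCell) stop("unknown cell id %d", cellId);
  e.executeMet(cellId, 0, 0);
  return List::create(_["state"] = e.dump(state));
}

// [[Rcpp::export]]
List cppApplyStrain(List state, double displacement) {
  Engine e = makeEngine(state);
  e.applyStrain(displacement);
  return List::create(_["state"] = e.dump(state));
}

// [[Rcpp::export]]
List cppRun(List state, int nMcs, IntegerVector pullStart,
            IntegerVector pullEnd, NumericVector pullRate, int scenario,
            int snapInterval, int seed, int mcsOffset) {
  Engine e = makeEngine(state);
  if (scenario < 0 || scenario > 2) stop("unknown scenario code %d", scenario);
  RNG rng((uint64_t)seed);
  long accepted = 0;
  int nPulls = pullStart.size();
  List snaps;
  auto takeSnap = [&](int mcs) {
    IntegerMatrix g(e.H, e.W);
    std::copy(e.grid.begin(), e.grid.end(), g.begin());
    snaps.push_back(List::create(
      _["mcs"] = mcs,
      _["grid"] = g,
      _["compCell"] = IntegerVector(e.compCell.begin() + 1, e.compCell.end()),
      _["compRole"] = IntegerVector(e.compRole.begin() + 1, e.compRole.end()),
      _["compType"] = IntegerVector(e.compType.begin() + 1, e.compType.end()),
      _["cellClass"] = IntegerVector(e.cellClass.begin() + 1, e.cellClass.end()),
      _["cellMet"] = IntegerVector(e.cellMet.begin() + 1, e.cellMet.end()),
      _["anchorShift"] = e.anchorShift));
  };
  if (snapInterval > 0) takeSnap(mcsOffset);
  for (int m = 1; m <= nMcs; m++) {
    int mcs = mcsOffset + m;
    for (int p = 0; p < nPulls; p++)
      if (mcs > pullStart[p] && mcs <= pullEnd[p]) e.applyStrain(pullRate[p]);
    accepted += e.mcsSweep(rng);
    e.updateSprings(mcs);
    e.updateTimersAndMet(mcs, scenario);
    if (snapInterval > 0 && mcs % snapInterval == 0) takeSnap(mcs);
    if (m % 2000 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(
    _["state"] = e.dump(state),
    _["snapshots"] = snaps,
    _["events"] = eventsToDf(e.events),
    _["accepted"] = (double)accepted);
}

// [[Rcpp::export]]
List cppLabelClusters(IntegerMatrix grid, LogicalVector isSomiticLabel,
                      int minSize) {
  // 8-connected components of somitic sites; labels 1..K by discovery order,
  // components smaller than minSize are dropped (set to 0).
  int H = grid.nrow(), W = grid.ncol();
  IntegerMatrix out(H, W);
  std::vector<int> stack;
  int K = 0;
  std::vector<int> sizes;
  auto somitic = [&](int lab) {
    return lab > 0 && lab <= isSomiticLabel.size() && isSomiticLabel[lab - 1];
  };
  for (int x = 0; x < W; x++) {
    for (int y = 0; y < H; y++) {
      if (out(y, x) != 0 || !somitic(grid(y, x))) continue;
      K++;
      int sz = 0;
      stack.push_back(x * H + y);
      out(y, x) = K;
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int px = p / H, py = p % H;
        sz++;
        for (int d = 0; d < 8; d++) {
          int nx = px + DX8[d], ny = py + DY8[d];
          if (nx < 0 || nx >= W || ny < 0 || ny >= H) continue;
          if (out(ny, nx) == 0 && somitic(grid(ny, nx))) {
            out(ny, nx) = K;
            stack.push_back(nx * H + ny);
          }
        }
      }
      sizes.push_back(sz);
    }
  }
  // drop small components and compact ids
  std::vector<int> remap(K + 1, 0);
  int K2 = 0;
  std::vector<int> keptSizes;
  for (int k = 1; k <= K; k++) {
    if (sizes[k - 1] >= minSize) {
      remap[k] = ++K2;
      keptSizes.push_back(sizes[k - 1]);
    }
  }
  for (int i = 0; i < W * H; i++) out[i] = remap[out[i]];
  return List::create(_["clusters"] = out,
                      _["sizes"] = IntegerVector(keptSizes.begin(), keptSizes.end()));
}
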