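// Bright-polarity MSER detection on a quantized integer image.
//
// Semantics (implemented independently by the pure-R oracle mserOracle):
// level sets S_t = {p : I(p) >= t} with 4-connected components; every
// distinct component pixel set is a node of the max-tree with
// hi(N) = min intensity over N (the highest threshold at which the exact
// set appears). seed(N) = max-intensity pixel, ties by smallest
// column-major index. Variation
//   q(N) = (|comp(seed, max(hi-delta, 0))| - |comp(seed, min(hi+delta,
//           I(seed)))|) / |N|
// where comp(s, t) is the component of S_t containing s. A node is a
// candidate iff q <= maxVariation, minArea <= |N| <= maxArea, and q is a
// local minimum along the seed chain (missing neighbours count as
// satisfied). Candidates are accepted greedily by (q, area, seed); a
// candidate nested with an accepted one at relative area difference
// < minDiversity is suppressed.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <climits>
using namespace Rcpp;

namespace {

struct DSU {
  std::vector<int> parent;
  explicit DSU(int n) : parent(n, -1) {}
  int find(int x) {
    int r = x;
    while (parent[r] != r) r = parent[r];
    while (parent[x] != r) { int nx = parent[x]; parent[x] = r; x = nx; }
    return r;
  }
};

inline bool betterSeed(int va, int a, int vb, int b) {
  // is (va, a) a better seed than (vb, b)?
  if (va != vb) return va > vb;
  return a < b;
}

} // namespace

// [[Rcpp::export(name = ".mser_detect_cpp")]]
List mser_detect_cpp(IntegerMatrix img, int delta, int minArea, int maxArea,
                     double maxVariation, double minDiversity) {
  const int nr = img.nrow(), nc = img.ncol(), npix = nr * nc;
  const int *vals = INTEGER(img);

  // pixels grouped by level, descending
  int vmax = vals[0], vmin = vals[0];
  for (int i = 1; i < npix; ++i) {
    if (vals[i] > vmax) vmax = vals[i];
    if (vals[i] < vmin) vmin = vals[i];
  }
  const int nlev = vmax - vmin + 1;
  std::vector<int> count(nlev, 0);
  for (int i = 0; i < npix; ++i) count[vals[i] - vmin]++;
  std::vector<int> start(nlev + 1, 0);
  for (int l = nlev - 1; l >= 0; --l) start[l] = start[l + 1] + count[l];
  // start[l] = first slot of level l+vmin when ordered descending
  std::vector<int> bucket(npix);
  {
    std::vector<int> pos(nlev);
    for (int l = 0; l < nlev; ++l) pos[l] = start[l + 1];
    for (int i = 0; i < npix; ++i) bucket[pos[vals[i] - vmin]++] = i;
  }

  DSU dsu(npix);
  std::vector<int> area(npix, 0), seed(npix, -1), lastNode(npix, -1),
      stamp(npix, INT_MIN), attach(npix, -1);
  std::vector<std::vector<int> > orphans(npix);

  std::vector<int> nodeHi, nodeArea, nodeSeed, nodeParent;
  nodeHi.reserve(npix); nodeArea.reserve(npix);
  nodeSeed.reserve(npix); nodeParent.reserve(npix);

  const int drow[4] = {-1, 1, 0, 0};
  const int dcol[4] = {0, 0, -1, 1};

  for (int lev = vmax; lev >= vmin; --lev) {
    const int l = lev - vmin;
    const int b0 = start[l + 1], b1 = start[l + 1] + count[l];
    if (b0 == b1) continue;
    for (int bi = b0; bi < b1; ++bi) {
      const int p = bucket[bi];
      dsu.parent[p] = p; area[p] = 1; seed[p] = p;
      const int pr = p % nr, pc = p / nr;
      for (int d = 0; d < 4; ++d) {
        const int qr = pr + drow[d], qc = pc + dcol[d];
        if (qr < 0 || qr >= nr || qc < 0 || qc >= nc) continue;
        const int q = qr + qc * nr;
        if (dsu.parent[q] == -1) continue;
        int ra = dsu.find(p), rb = dsu.find(q);
        if (ra == rb) continue;
        int win = (area[ra] >= area[rb]) ? ra : rb;
        int lose = win == ra ? rb : ra;
        area[win] += area[lose];
        if (betterSeed(vals[seed[lose]], seed[lose], vals[seed[win]],
                       seed[win]))
          seed[win] = seed[lose];
        if (lastNode[lose] != -1) orphans[win].push_back(lastNode[lose]);
        if (!orphans[lose].empty()) {
          orphans[win].insert(orphans[win].end(), orphans[lose].begin(),
                              orphans[lose].end());
          orphans[lose].clear();
        }
        dsu.parent[lose] = win;
      }
    }
    // snapshot every changed root
    for (int bi = b0; bi < b1; ++bi) {
      const int r = dsu.find(bucket[bi]);
      if (stamp[r] == lev) continue;
      stamp[r] = lev;
      const int id = (int)nodeHi.size();
      nodeHi.push_back(lev);
      nodeArea.push_back(area[r]);
      nodeSeed.push_back(seed[r]);
      nodeParent.push_back(-1);
      if (lastNode[r] != -1) nodeParent[lastNode[r]] = id;
      for (size_t oi = 0; oi < orphans[r].size(); ++oi)
        nodeParent[orphans[r][oi]] = id;
      orphans[r].clear();
      lastNode[r] = id;
    }
    for (int bi = b0; bi < b1; ++bi) {
      const int p = bucket[bi];
      attach[p] = lastNode[dsu.find(p)];
    }
  }

  const int nn = (int)nodeHi.size();

  // component of S_t containing pixel s
  auto nodeAt = [&](int s, int t) {
    int m = attach[s];
    while (nodeParent[m] != -1 && nodeHi[nodeParent[m]] >= t)
      m = nodeParent[m];
    return m;
  };

  std::vector<double> qvar(nn);
  for (int n = 0; n < nn; ++n) {
    const int s = nodeSeed[n], vs = vals[s];
    int tl = nodeHi[n] - delta; if (tl < vmin) tl = vmin;
    int th = nodeHi[n] + delta; if (th > vs) th = vs;
    const double aMinus = nodeArea[nodeAt(s, tl)];
    const double aPlus = nodeArea[nodeAt(s, th)];
    qvar[n] = (aMinus - aPlus) / (double)nodeArea[n];
  }

  // child of n along its seed chain (or -1)
  auto chainChild = [&](int n) {
    int m = attach[nodeSeed[n]];
    if (m == n) return -1;
    while (nodeParent[m] != n) m = nodeParent[m];
    return m;
  };

  std::vector<int> cand;
  for (int n = 0; n < nn; ++n) {
    if (nodeArea[n] < minArea || nodeArea[n] > maxArea) continue;
    if (qvar[n] > maxVariation) continue;
    const int p = nodeParent[n];
    if (p != -1 && qvar[n] > qvar[p]) continue;
    const int c = chainChild(n);
    if (c != -1 && qvar[n] > qvar[c]) continue;
    cand.push_back(n);
  }

  std::sort(cand.begin(), cand.end(), [&](int a, int b) {
    if (qvar[a] != qvar[b]) return qvar[a] < qvar[b];
    if (nodeArea[a] != nodeArea[b]) return nodeArea[a] < nodeArea[b];
    return nodeSeed[a] < nodeSeed[b];
  });

  // ancestor test: is `anc` an ancestor of (or equal to) `des`?
  auto isAncestor = [&](int anc, int des) {
    int m = des;
    while (m != -1 && nodeArea[m] <= nodeArea[anc]) {
      if (m == anc) return true;
      m = nodeParent[m];
    }
    return false;
  };

  std::vector<int> accepted;
  for (size_t ci = 0; ci < cand.size(); ++ci) {
    const int n = cand[ci];
    bool ok = true;
    for (size_t ai = 0; ai < accepted.size() && ok; ++ai) {
      const int a = accepted[ai];
      int big, small;
      if (nodeArea[a] >= nodeArea[n]) { big = a; small = n; }
      else { big = n; small = a; }
      if (isAncestor(big, small)) {
        const double div =
            (nodeArea[big] - nodeArea[small]) / (double)nodeArea[big];
        if (div < minDiversity) ok = false;
      }
    }
    if (ok) accepted.push_back(n);
  }

  std::sort(accepted.begin(), accepted.end(),
            [&](int a, int b) { return nodeSeed[a] < nodeSeed[b]; });

  // extract pixel sets by BFS over {I >= hi} from the seed
  List out(accepted.size());
  std::vector<int> visitMark(npix, -1);
  for (size_t ai = 0; ai < accepted.size(); ++ai) {
    const int n = accepted[ai];
    const int t = nodeHi[n];
    std::vector<int> pix;
    std::vector<int> stack;
    stack.push_back(nodeSeed[n]);
    visitMark[nodeSeed[n]] = n;
    while (!stack.empty()) {
      const int p = stack.back(); stack.pop_back();
      pix.push_back(p);
      const int pr = p % nr, pc = p / nr;
      for (int d = 0; d < 4; ++d) {
        const int qr = pr + drow[d], qc = pc + dcol[d];
        if (qr < 0 || qr >= nr || qc < 0 || qc >= nc) continue;
        const int q = qr + qc * nr;
        if (visitMark[q] != n && vals[q] >= t) {
          visitMark[q] = n;
          stack.push_back(q);
        }
      }
    }
    std::sort(pix.begin(), pix.end());
    IntegerMatrix pm(pix.size(), 2);
    for (size_t i = 0; i < pix.size(); ++i) {
      pm(i, 0) = pix[i] % nr + 1;
      pm(i, 1) = pix[i] / nr + 1;
    }
    out[ai] = List::create(_["pixels"] = pm, _["level"] = nodeHi[n],
                           _["stability"] = qvar[n],
                           _["area"] = (int)pix.size(),
                           _["seed"] = nodeSeed[n] + 1);
  }
  return out;
}
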