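#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Bytecode for compiled logical rules (postfix):
//   0 idx : push state[idx]
//   1 c   : push constant c (0/1)
//   2     : NOT
//   3 n   : AND over top n values
//   4 n   : OR  over top n values

namespace {

struct SplitMix64 {
  uint64_t s;
  explicit SplitMix64(uint64_t seed) : s(seed) {}
  uint64_t next() {
    uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  // uniform in (0, 1)
  double unif() {
    return (static_cast<double>(next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double expo() { return -std::log(unif()); }
};

// per-trajectory substream: reproducible and independent of execution order
inline SplitMix64 stream_for(uint64_t seed, uint64_t idx) {
  SplitMix64 boot(seed ^ (0xD1B54A32D192ED03ULL * (idx + 1)));
  uint64_t s0 = boot.next();
  return SplitMix64(s0);
}

inline int eval_rule(const std::vector<int>& code, const std::vector<uint8_t>& st) {
  int stack[64];
  int sp = 0;
  size_t i = 0, n = code.size();
  while (i < n) {
    switch (code[i]) {
    case 0: stack[sp++] = st[code[i + 1]]; i += 2; break;
    case 1: stack[sp++] = code[i + 1]; i += 2; break;
    case 2: stack[sp - 1] = 1 - stack[sp - 1]; ++i; break;
    case 3: {
      int k = code[i + 1], v = 1;
      for (int j = 0; j < k; ++j) v = v && stack[sp - 1 - j];
      sp -= k; stack[sp++] = v; i += 2; break;
    }
    case 4: {
      int k = code[i + 1], v = 0;
      for (int j = 0; j < k; ++j) v = v || stack[sp - 1 - j];
      sp -= k; stack[sp++] = v; i += 2; break;
    }
    default: Rcpp::stop("corrupt rule bytecode");
    }
  }
  return stack[0];
}

std::vector<std::vector<int>> unpack_code(const List& bytecode) {
  std::vector<std::vector<int>> code(bytecode.size());
  for (R_xlen_t i = 0; i < bytecode.size(); ++i) {
    IntegerVector v = bytecode[i];
    code[i].assign(v.begin(), v.end());
  }
  return code;
}

} // namespace

// Deterministic substream seed derivation shared with the R side.
// [[Rcpp::export]]
int cpp_mix_seed(double seed, double index) {
  SplitMix64 boot(static_cast<uint64_t>(seed) ^
                  (0xD1B54A32D192ED03ULL * (static_cast<uint64_t>(index) + 1)));
  return static_cast<int>(boot.next() % 2147483647ULL);
}

// Ensemble simulation of the asynchronous Boolean CTMC.
// clampMask: -1 free, 0/1 forced. Returns per-grid-point marginal counts,
// joint phenotype counts, and the count of trajectories absorbed by tMax.
// [[Rcpp::export]]
List cpp_simulate_ensemble(List bytecode, IntegerVector init, IntegerVector clampMask,
                           NumericVector randProb,
                           NumericVector rateUp, NumericVector rateDown,
                           NumericVector grid, int nTraj, double seed,
                           IntegerVector phenIdx) {
  const int nNodes = init.size();
  const int nGrid = grid.size();
  const int nPhen = phenIdx.size();
  const int nCat = 1 << nPhen;
  const double tMax = nGrid > 0 ? grid[nGrid - 1] : 0.0;
  std::vector<std::vector<int>> code = unpack_code(bytecode);
  if ((int)code.size() != nNodes) stop("bytecode/init length mismatch");

  NumericMatrix marg(nNodes, nGrid);
  NumericMatrix joint(nCat, nGrid);
  int absorbed = 0;

  std::vector<uint8_t> st(nNodes);
  std::vector<int> enabled(nNodes);
  std::vector<double> erate(nNodes);

  for (int traj = 0; traj < nTraj; ++traj) {
    SplitMix64 rng = stream_for(static_cast<uint64_t>(seed), traj);
    for (int i = 0; i < nNodes; ++i) {
      if (clampMask[i] >= 0) st[i] = (uint8_t)clampMask[i];
      else if (randProb[i] >= 0.0) st[i] = rng.unif() < randProb[i] ? 1 : 0;
      else st[i] = (uint8_t)init[i];
    }
    double t = 0.0;
    int g = 0;
    bool stuck = false;
    while (true) {
      int ne = 0;
      double tot = 0.0;
      for (int i = 0; i < nNodes; ++i) {
        if (clampMask[i] >= 0) continue;
        int target = eval_rule(code[i], st);
        if (target != st[i]) {
          enabled[ne] = i;
          erate[ne] = target ? rateUp[i] : rateDown[i];
          tot += erate[ne];
          ++ne;
        }
      }
      if (ne == 0) { stuck = true; break; }
      double tNext = t + rng.expo() / tot;
      while (g < nGrid && grid[g] < tNext) {
        for (int i = 0; i < nNodes; ++i) marg(i, g) += st[i];
        int cat = 0;
        for (int p = 0; p < nPhen; ++p) cat |= (st[phenIdx[p]] << p);
        joint(cat, g) += 1.0;
        ++g;
      }
      if (tNext > tMax && g >= nGrid) break;
      t = tNext;
      double u = rng.unif() * tot, acc = 0.0;
      int pick = ne - 1;
      for (int j = 0; j < ne; ++j) { acc += erate[j]; if (u <= acc) { pick = j; break; } }
      st[enabled[pick]] ^= 1;
    }
    if (stuck) ++absorbed;
    // state no longer changes (absorbed) or horizon reached: fill remaining grid
    for (; g < nGrid; ++g) {
      for (int i = 0; i < nNodes; ++i) marg(i, g) += st[i];
      int cat = 0;
      for (int p = 0; p < nPhen; ++p) cat |= (st[phenIdx[p]] << p);
      joint(cat, g) += 1.0;
    }
  }
  return List::create(_["marginalCounts"] = marg,
                      _["jointCounts"] = joint,
                      _["absorbed"] = absorbed);
}

// Single stochastic trajectory: piecewise-constant path as jump times and
// flipped node indices (1-based). Stops at tMax or absorption.
// [[Rcpp::export]]
List cpp_gillespie_path(List bytecode, IntegerVector init, IntegerVector clampMask,
                        NumericVector rateUp, NumericVector rateDown,
                        double tMax, double seed, double streamIndex) {
  const int nNodes = init.size();
  std::vector<std::vector<int>> code = unpack_code(bytecode);
  SplitMix64 rng = stream_for(static_cast<uint64_t>(seed),
                              static_cast<uint64_t>(streamIndex));
  std::vector<uint8_t> st(nNodes);
  for (int i = 0; i < nNodes; ++i)
    st[i] = clampMask[i] >= 0 ? (uint8_t)clampMask[i] : (uint8_t)init[i];
  std::vector<double> times;
  std::vector<int> flips;
  std::vector<int> enabled(nNodes);
  std::vector<double> erate(nNodes);
  double t = 0.0;
  bool absorbed = false;
  while (true) {
    int ne = 0; double tot = 0.0;
    for (int i = 0; i < nNodes; ++i) {
      if (clampMask[i] >= 0) continue;
      int target = eval_rule(code[i], st);
      if (target != st[i]) {
        enabled[ne] = i; erate[ne] = target ? rateUp[i] : rateDown[i];
        tot += erate[ne]; ++ne;
      }
    }
    if (ne == 0) { absorbed = true; break; }
    t += rng.expo() / tot;
    if (t > tMax) break;
    double u = rng.unif() * tot, acc = 0.0;
    int pick = ne - 1;
    for (int j = 0; j < ne; ++j) { acc += erate[j]; if (u <= acc) { pick = j; break; } }
    st[enabled[pick]] ^= 1;
    times.push_back(t);
    flips.push_back(enabled[pick] + 1);
  }
  IntegerVector fin(nNodes);
  for (int i = 0; i < nNodes; ++i) fin[i] = st[i];
  return List::create(_["times"] = NumericVector(times.begin(), times.end()),
                      _["flips"] = IntegerVector(flips.begin(), flips.end()),
                      _["finalState"] = fin,
                      _["absorbed"] = absorbed);
}
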