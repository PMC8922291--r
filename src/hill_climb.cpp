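#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
#include <limits>
using namespace Rcpp;

// Greedy steepest-ascent structure search over add/delete/reverse moves,
// maximizing sum of per-family BIC terms plus an edge-decomposable graph
// log-prior (log-odds per unordered pair, applied when the skeleton contains
// the pair). Deterministic: among equal-gain moves the scan order decides
// (delete > reverse > add, then row-major arc order over the column order of
// the data matrix).
//
// Gains of all single-arc moves are cached and recomputed only for moves
// touching a family that the last applied move changed; acyclicity is
// verified lazily, only when a candidate beats the current best.

static const double TOL = 1e-10;
static const double MAXQ = 1e6;  // guard on parent-configuration count
static const double NEG_INF = -std::numeric_limits<double>::infinity();

// BIC family term: MLE log-likelihood of child v given parent set, minus
// (log N / 2) * (r_v - 1) * q free parameters. Natural log; 0*log 0 = 0.
static double family_score(const std::vector<int> &d, int N,
                           const std::vector<int> &arity, int n, int v,
                           const std::vector<int> &parents, double half_logN) {
    const int r = arity[v];
    double qd = 1.0;
    for (size_t i = 0; i < parents.size(); ++i) qd *= arity[parents[i]];
    if (qd > MAXQ) return NEG_INF;
    const long q = (long)qd;
    std::vector<double> njk((size_t)r * q, 0.0), nj((size_t)q, 0.0);
    const int *dv = &d[(size_t)v * N];
    for (int i = 0; i < N; ++i) {
        long cfg = 0, mult = 1;
        for (size_t k = 0; k < parents.size(); ++k) {
            cfg += mult * d[(size_t)parents[k] * N + i];
            mult *= arity[parents[k]];
        }
        njk[(size_t)cfg * r + dv[i]] += 1.0;
        nj[(size_t)cfg] += 1.0;
    }
    double ll = 0.0;
    for (long j = 0; j < q; ++j) {
        if (nj[j] == 0.0) continue;
        for (int k = 0; k < r; ++k) {
            double c = njk[(size_t)j * r + k];
            if (c > 0.0) ll += c * std::log(c / nj[(size_t)j]);
        }
    }
    return ll - half_logN * (double)(r - 1) * (double)q;
}

struct Search {
    int n, N;
    std::vector<int> data;        // column-major, n columns of length N
    std::vector<int> arity;
    double half_logN;
    std::vector<char> adj;        // n x n, row-major: adj[u*n+v] = u -> v
    std::vector<double> fam;      // current family score per node
    // cached absolute family scores after a hypothetical move (prior and
    // the subtraction of fam[v] happen at scan time, so applying a move can
    // install the exact recomputed family score)
    std::vector<double> addG;     // add u->v    : score(v, par(v) + u)
    std::vector<double> delG;     // delete u->v : score(v, par(v) - u)

    double famWith(int v, int addP, int delP) {
        std::vector<int> ps;
        for (int u = 0; u < n; ++u)
            if (adj[(size_t)u * n + v] && u != delP) ps.push_back(u);
        if (addP >= 0) ps.push_back(addP);
        return family_score(data, N, arity, n, v, ps, half_logN);
    }

    void refreshColumn(int v) {
        // recompute all cached gains whose target family is v's
        for (int u = 0; u < n; ++u) {
            if (u == v) { addG[(size_t)u * n + v] = NEG_INF; continue; }
            if (adj[(size_t)u * n + v]) {
                delG[(size_t)u * n + v] = famWith(v, -1, u);
                addG[(size_t)u * n + v] = NEG_INF;
            } else {
                addG[(size_t)u * n + v] = famWith(v, u, -1);
                delG[(size_t)u * n + v] = NEG_INF;
            }
        }
    }

    bool hasPath(int from, int to) {
        if (from == to) return true;
        std::vector<char> seen(n, 0);
        std::vector<int> stack(1, from);
        seen[from] = 1;
        while (!stack.empty()) {
            int u = stack.back();
            stack.pop_back();
            const char *row = &adj[(size_t)u * n];
            for (int w = 0; w < n; ++w) {
                if (row[w] && !seen[w]) {
                    if (w == to) return true;
                    seen[w] = 1;
                    stack.push_back(w);
                }
            }
        }
        return false;
    }
};

// [[Rcpp::export(name = ".hc_search_cpp")]]
List hc_search_cpp(IntegerMatrix data, IntegerVector arity,
                   NumericMatrix priorLogOdds, IntegerMatrix start,
                   int maxIter) {
    Search S;
    S.n = data.ncol();
    S.N = data.nrow();
    const int n = S.n;
    S.data.resize((size_t)n * S.N);
    for (int v = 0; v < n; ++v)
        for (int i = 0; i < S.N; ++i) S.data[(size_t)v * S.N + i] = data(i, v);
    S.arity.assign(arity.begin(), arity.end());
    S.half_logN = 0.5 * std::log((double)S.N);
    S.adj.assign((size_t)n * n, 0);
    for (int u = 0; u < n; ++u)
        for (int v = 0; v < n; ++v)
            if (start(u, v)) S.adj[(size_t)u * n + v] = 1;
    S.fam.resize(n);
    for (int v = 0; v < n; ++v) S.fam[v] = S.famWith(v, -1, -1);
    S.addG.assign((size_t)n * n, NEG_INF);
    S.delG.assign((size_t)n * n, NEG_INF);
    for (int v = 0; v < n; ++v) S.refreshColumn(v);

    int iter = 0;
    bool converged = false;
    while (iter < maxIter) {
        double bestGain = TOL;
        int bestType = -1, bestU = -1, bestV = -1;

        // deletes (always legal)
        for (int u = 0; u < n; ++u)
            for (int v = 0; v < n; ++v) {
                if (!S.adj[(size_t)u * n + v]) continue;
                double g = S.delG[(size_t)u * n + v] - S.fam[v] -
                           priorLogOdds(u, v);
                if (g > bestGain) {
                    bestGain = g; bestType = 0; bestU = u; bestV = v;
                }
            }
        // reverses: delete-part for v plus add-part for u; prior unchanged
        for (int u = 0; u < n; ++u)
            for (int v = 0; v < n; ++v) {
                if (!S.adj[(size_t)u * n + v]) continue;
                double g = (S.delG[(size_t)u * n + v] - S.fam[v]) +
                           (S.addG[(size_t)v * n + u] - S.fam[u]);
                if (g > bestGain) {
                    S.adj[(size_t)u * n + v] = 0;
                    bool cyc = S.hasPath(u, v);
                    S.adj[(size_t)u * n + v] = 1;
                    if (!cyc) {
                        bestGain = g; bestType = 1; bestU = u; bestV = v;
                    }
                }
            }
        // adds
        for (int u = 0; u < n; ++u)
            for (int v = 0; v < n; ++v) {
                if (u == v || S.adj[(size_t)u * n + v] ||
                    S.adj[(size_t)v * n + u])
                    continue;
                double g = S.addG[(size_t)u * n + v] - S.fam[v] +
                           priorLogOdds(u, v);
                if (g > bestGain && !S.hasPath(v, u)) {
                    bestGain = g; bestType = 2; bestU = u; bestV = v;
                }
            }

        if (bestType < 0) { converged = true; break; }
        if (bestType == 0) {            // delete u -> v
            S.fam[bestV] = S.delG[(size_t)bestU * n + bestV];
            S.adj[(size_t)bestU * n + bestV] = 0;
            S.refreshColumn(bestV);
        } else if (bestType == 1) {     // reverse u -> v
            S.fam[bestV] = S.delG[(size_t)bestU * n + bestV];
            S.fam[bestU] = S.addG[(size_t)bestV * n + bestU];
            S.adj[(size_t)bestU * n + bestV] = 0;
            S.adj[(size_t)bestV * n + bestU] = 1;
            S.refreshColumn(bestV);
            S.refreshColumn(bestU);
        } else {                        // add u -> v
            S.fam[bestV] = S.addG[(size_t)bestU * n + bestV];
            S.adj[(size_t)bestU * n + bestV] = 1;
            S.refreshColumn(bestV);
        }
        ++iter;
    }

    double score = 0.0;
    for (int v = 0; v < n; ++v) score += S.fam[v];
    for (int u = 0; u < n; ++u)
        for (int v = 0; v < n; ++v)
            if (S.adj[(size_t)u * n + v]) score += priorLogOdds(u, v);

    IntegerMatrix out(n, n);
    for (int u = 0; u < n; ++u)
        for (int v = 0; v < n; ++v) out(u, v) = S.adj[(size_t)u * n + v];
    return List::create(_["adj"] = out, _["score"] = score,
                        _["iterations"] = iter, _["converged"] = converged);
}
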