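// Classification random forest with class-balanced bootstrap sampling,
// per-node feature subsampling, out-of-bag vote tracking and OOB
// permutation importance.  Kept deliberately small: binary response only,
// numeric features, Gini splits.  Determinism: one mt19937 stream per
// forest seeds one stream per tree, so results do not depend on thread
// scheduling (everything is single-threaded).
#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <random>
#include <vector>

using namespace Rcpp;

namespace {

struct Tree {
    // node arrays; feat == -1 marks a leaf
    std::vector<int> feat;
    std::vector<double> thr;
    std::vector<int> left;
    std::vector<int> right;
    std::vector<double> prob;  // P(y == 1) among training samples in node
};

struct Grower {
    const NumericMatrix &X;
    const IntegerVector &y;
    int mtry, min_node, max_depth;
    std::mt19937 &rng;
    Tree tree;
    std::vector<char> used_feat;  // features appearing in any split

    Grower(const NumericMatrix &X_, const IntegerVector &y_, int mtry_,
           int min_node_, int max_depth_, std::mt19937 &rng_)
        : X(X_), y(y_), mtry(mtry_), min_node(min_node_),
          max_depth(max_depth_), rng(rng_), used_feat(X_.ncol(), 0) {}

    int grow(std::vector<int> &idx, int depth) {
        const int node = static_cast<int>(tree.feat.size());
        tree.feat.push_back(-1);
        tree.thr.push_back(0.0);
        tree.left.push_back(-1);
        tree.right.push_back(-1);
        const int n = static_cast<int>(idx.size());
        int n1 = 0;
        for (int i : idx) n1 += y[i];
        tree.prob.push_back(static_cast<double>(n1) / n);
        if (depth >= max_depth || n < 2 * min_node || n1 == 0 || n1 == n)
            return node;

        // sample mtry candidate features without replacement
        const int p = X.ncol();
        std::vector<int> cand(p);
        for (int j = 0; j < p; ++j) cand[j] = j;
        const int m = std::min(mtry, p);
        for (int j = 0; j < m; ++j) {
            std::uniform_int_distribution<int> pick(j, p - 1);
            std::swap(cand[j], cand[pick(rng)]);
        }

        const double parent_gini =
            1.0 - std::pow(static_cast<double>(n1) / n, 2) -
            std::pow(static_cast<double>(n - n1) / n, 2);
        double best_gain = 1e-12;
        int best_f = -1;
        double best_thr = 0.0;

        std::vector<std::pair<double, int>> vals(n);
        for (int jj = 0; jj < m; ++jj) {
            const int f = cand[jj];
            for (int k = 0; k < n; ++k)
                vals[k] = std::make_pair(X(idx[k], f), y[idx[k]]);
            std::sort(vals.begin(), vals.end());
            if (vals.front().first == vals.back().first) continue;
            int l_n = 0, l_n1 = 0;
            for (int k = 0; k < n - 1; ++k) {
                ++l_n;
                l_n1 += vals[k].second;
                if (vals[k].first == vals[k + 1].first) continue;
                const int r_n = n - l_n, r_n1 = n1 - l_n1;
                if (l_n < min_node || r_n < min_node) continue;
                const double gl =
                    1.0 - std::pow(static_cast<double>(l_n1) / l_n, 2) -
                    std::pow(static_cast<double>(l_n - l_n1) / l_n, 2);
                const double gr =
                    1.0 - std::pow(static_cast<double>(r_n1) / r_n, 2) -
                    std::pow(static_cast<double>(r_n - r_n1) / r_n, 2);
                const double gain =
                    parent_gini -
                    (l_n * gl + r_n * gr) / static_cast<double>(n);
                if (gain > best_gain) {
                    best_gain = gain;
                    best_f = f;
                    best_thr = 0.5 * (vals[k].first + vals[k + 1].first);
                }
            }
        }
        if (best_f < 0) return node;

        std::vector<int> lidx, ridx;
        lidx.reserve(n);
        ridx.reserve(n);
        for (int i : idx)
            (X(i, best_f) <= best_thr ? lidx : ridx).push_back(i);
        if (lidx.empty() || ridx.empty()) return node;

        tree.feat[node] = best_f;
        tree.thr[node] = best_thr;
        used_feat[best_f] = 1;
        tree.left[node] = grow(lidx, depth + 1);
        tree.right[node] = grow(ridx, depth + 1);
        return node;
    }
};

inline int tree_vote(const Tree &t, const NumericMatrix &X, int row,
                     int perm_feat, double perm_val) {
    int node = 0;
    while (t.feat[node] >= 0) {
        const double v = (t.feat[node] == perm_feat)
                             ? perm_val
                             : X(row, t.feat[node]);
        node = (v <= t.thr[node]) ? t.left[node] : t.right[node];
    }
    return t.prob[node] > 0.5 ? 1 : 0;
}

List tree_to_list(const Tree &t) {
    return List::create(Named("feat") = wrap(t.feat),
                        Named("thr") = wrap(t.thr),
                        Named("left") = wrap(t.left),
                        Named("right") = wrap(t.right),
                        Named("prob") = wrap(t.prob));
}

Tree tree_from_list(const List &l) {
    Tree t;
    t.feat = as<std::vector<int>>(l["feat"]);
    t.thr = as<std::vector<double>>(l["thr"]);
    t.left = as<std::vector<int>>(l["left"]);
    t.right = as<std::vector<int>>(l["right"]);
    t.prob = as<std::vector<double>>(l["prob"]);
    return t;
}

}  // namespace

// [[Rcpp::export(name = ".rf_build")]]
List rf_build(NumericMatrix X, IntegerVector y, int ntree, int mtry,
              int sampsize_per_class, int min_node, int max_depth, int seed,
              bool importance) {
    const int n = X.nrow(), p = X.ncol();
    std::vector<int> idx0, idx1;
    for (int i = 0; i < n; ++i) (y[i] == 1 ? idx1 : idx0).push_back(i);
    if (idx0.empty() || idx1.empty())
        stop("both classes must be present to train a forest");

    std::mt19937 master(static_cast<unsigned int>(seed));
    List trees(ntree);
    IntegerVector oob_votes1(n), oob_count(n), inbag_count(n);
    NumericMatrix imp_sum(importance ? p : 1, 1);
    NumericMatrix imp_sumsq(importance ? p : 1, 1);
    std::vector<double> imp_s(p, 0.0), imp_ss(p, 0.0);

    for (int t = 0; t < ntree; ++t) {
        std::mt19937 rng(master());
        std::vector<char> inbag(n, 0);
        std::vector<int> bag;
        bag.reserve(2 * sampsize_per_class);
        std::uniform_int_distribution<int> d0(0, (int)idx0.size() - 1);
        std::uniform_int_distribution<int> d1(0, (int)idx1.size() - 1);
        for (int k = 0; k < sampsize_per_class; ++k) {
            const int a = idx0[d0(rng)], b = idx1[d1(rng)];
            bag.push_back(a);
            bag.push_back(b);
            inbag[a] = 1;
            inbag[b] = 1;
            inbag_count[a] += 1;
            inbag_count[b] += 1;
        }

        Grower g(X, y, mtry, min_node, max_depth, rng);
        g.grow(bag, 0);
        trees[t] = tree_to_list(g.tree);

        std::vector<int> oob;
        for (int i = 0; i < n; ++i)
            if (!inbag[i]) oob.push_back(i);
        if (oob.empty()) continue;

        std::vector<int> votes(oob.size());
        int correct = 0;
        for (size_t k = 0; k < oob.size(); ++k) {
            votes[k] = tree_vote(g.tree, X, oob[k], -1, 0.0);
            oob_votes1[oob[k]] += votes[k];
            oob_count[oob[k]] += 1;
            if (votes[k] == y[oob[k]]) ++correct;
        }

        if (importance) {
            const double base_acc =
                static_cast<double>(correct) / oob.size();
            // permute each used feature among the OOB rows
            std::vector<int> perm(oob.size());
            for (size_t k = 0; k < oob.size(); ++k) perm[k] = (int)k;
            for (int f = 0; f < p; ++f) {
                if (!g.used_feat[f]) continue;  // decrease is exactly 0
                std::shuffle(perm.begin(), perm.end(), rng);
                int corr_p = 0;
                for (size_t k = 0; k < oob.size(); ++k) {
                    const double pv = X(oob[perm[k]], f);
                    const int v = tree_vote(g.tree, X, oob[k], f, pv);
                    if (v == y[oob[k]]) ++corr_p;
                }
                const double dec =
                    base_acc - static_cast<double>(corr_p) / oob.size();
                imp_s[f] += dec;
                imp_ss[f] += dec * dec;
            }
        }
    }

    NumericVector imp_mean(p), imp_sd(p);
    if (importance) {
        for (int f = 0; f < p; ++f) {
            const double m = imp_s[f] / ntree;
            imp_mean[f] = m;
            const double var =
                ntree > 1 ? (imp_ss[f] - ntree * m * m) / (ntree - 1) : 0.0;
            imp_sd[f] = var > 0 ? std::sqrt(var) : 0.0;
        }
    }
    return List::create(Named("trees") = trees,
                        Named("oob_votes1") = oob_votes1,
                        Named("oob_count") = oob_count,
                        Named("inbag_count") = inbag_count,
                        Named("imp_mean") = imp_mean,
                        Named("imp_sd") = imp_sd);
}

// [[Rcpp::export(name = ".rf_predict")]]
NumericVector rf_predict(List trees, NumericMatrix X) {
    const int n = X.nrow(), ntree = trees.size();
    NumericVector votes1(n);
    for (int t = 0; t < ntree; ++t) {
        Tree tr = tree_from_list(trees[t]);
        for (int i = 0; i < n; ++i) votes1[i] += tree_vote(tr, X, i, -1, 0.0);
    }
    for (int i = 0; i < n; ++i) votes1[i] /= ntree;
    return votes1;
}
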