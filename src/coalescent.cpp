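#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Censored multispecies-coalescent simulation over a species tree whose
// branch lengths are in ms time units (4*Ne generations), so k lineages
// coalesce at total rate k*(k-1) per unit time (pair rate 2).
//
// Species-tree encoding (prepared in R, all 0-based):
//   parent[v]  : parent node id, -1 for root
//   height[v]  : node time before present (tips 0); finite
//   order      : node processing order, children before parents
//   samples[i] : chromosomes sampled in tip i
// Chromosome ids are assigned contiguously per tip in tip-id order.

struct GeneTree {
    int n_chrom;
    std::vector<int> left, right;     // children of merge nodes (size n_chrom-1)
    std::vector<double> ntime;        // node times, size 2*n_chrom-1 (tips 0)
    std::vector<uint64_t> mask;       // descendant-chromosome bitmask per node
};

static void sim_one(const int *parent, const double *height, const int *order,
                    int n_nodes, int n_tip, const int *samples, const int *offset,
                    int n_chrom, std::vector<std::vector<int> > &buf, GeneTree &G)
{
    for (int v = 0; v < n_nodes; ++v) buf[v].clear();
    for (int i = 0; i < n_chrom; ++i) { G.mask[i] = 1ULL << i; G.ntime[i] = 0.0; }
    int next_node = n_chrom;
    for (int oi = 0; oi < n_nodes; ++oi) {
        int v = order[oi];
        std::vector<int> &lin = buf[v];
        if (v < n_tip)
            for (int j = 0; j < samples[v]; ++j) lin.push_back(offset[v] + j);
        double t = height[v];
        double t_end = (parent[v] < 0) ? R_PosInf : height[parent[v]];
        int k = (int)lin.size();
        while (k > 1) {
            double rate = (double)k * (double)(k - 1);
            double dt = exp_rand() / rate;
            if (t + dt > t_end) break;
            t += dt;
            int i = (int)(unif_rand() * k); if (i >= k) i = k - 1;
            int j = (int)(unif_rand() * (k - 1)); if (j >= k - 1) j = k - 2;
            if (j >= i) ++j;
            int a = lin[i], b = lin[j];
            int m = next_node++;
            G.left[m - n_chrom] = a;
            G.right[m - n_chrom] = b;
            G.ntime[m] = t;
            G.mask[m] = G.mask[a] | G.mask[b];
            lin[i] = m;
            lin[j] = lin.back();
            lin.pop_back();
            --k;
        }
        if (parent[v] >= 0) {
            std::vector<int> &up = buf[parent[v]];
            up.insert(up.end(), lin.begin(), lin.end());
        }
    }
}

struct SpTree {
    std::vector<int> parent, order, samples, offset;
    std::vector<double> height;
    int n_nodes, n_tip, n_chrom;
};

static SpTree make_sptree(IntegerVector parent, NumericVector height,
                          IntegerVector order, int n_tip, IntegerVector samples)
{
    SpTree S;
    S.n_nodes = parent.size();
    S.n_tip = n_tip;
    S.parent.assign(parent.begin(), parent.end());
    S.height.assign(height.begin(), height.end());
    S.order.assign(order.begin(), order.end());
    S.samples.assign(samples.begin(), samples.end());
    S.offset.resize(n_tip);
    int off = 0;
    for (int i = 0; i < n_tip; ++i) { S.offset[i] = off; off += S.samples[i]; }
    S.n_chrom = off;
    if (S.n_chrom < 1) stop("at least one chromosome must be sampled");
    if (S.n_chrom > 63) stop("more than 63 chromosomes are not supported");
    return S;
}

static GeneTree make_genetree(int n_chrom)
{
    GeneTree G;
    G.n_chrom = n_chrom;
    G.left.resize(n_chrom - 1);
    G.right.resize(n_chrom - 1);
    G.ntime.resize(2 * n_chrom - 1);
    G.mask.resize(2 * n_chrom - 1);
    return G;
}

// [[Rcpp::export]]
List cpp_sim_trees(IntegerVector parent, NumericVector height, IntegerVector order,
                   int n_tip, IntegerVector samples, int n_trees)
{
    SpTree S = make_sptree(parent, height, order, n_tip, samples);
    GeneTree G = make_genetree(S.n_chrom);
    std::vector<std::vector<int> > buf(S.n_nodes);
    List out(n_trees);
    for (int r = 0; r < n_trees; ++r) {
        sim_one(S.parent.data(), S.height.data(), S.order.data(), S.n_nodes,
                S.n_tip, S.samples.data(), S.offset.data(), S.n_chrom, buf, G);
        int nm = S.n_chrom - 1;
        IntegerVector L(nm), R(nm);
        NumericVector T(nm);
        for (int m = 0; m < nm; ++m) {
            L[m] = G.left[m]; R[m] = G.right[m]; T[m] = G.ntime[S.n_chrom + m];
        }
        out[r] = List::create(_["left"] = L, _["right"] = R, _["time"] = T);
    }
    return out;
}

// [[Rcpp::export]]
int cpp_clade_count(IntegerVector parent, NumericVector height, IntegerVector order,
                    int n_tip, IntegerVector samples, IntegerVector target_chroms,
                    int n_trees)
{
    SpTree S = make_sptree(parent, height, order, n_tip, samples);
    GeneTree G = make_genetree(S.n_chrom);
    std::vector<std::vector<int> > buf(S.n_nodes);
    uint64_t target = 0;
    for (int i = 0; i < target_chroms.size(); ++i)
        target |= 1ULL << target_chroms[i];
    int count = 0;
    for (int r = 0; r < n_trees; ++r) {
        sim_one(S.parent.data(), S.height.data(), S.order.data(), S.n_nodes,
                S.n_tip, S.samples.data(), S.offset.data(), S.n_chrom, buf, G);
        for (int m = S.n_chrom; m < 2 * S.n_chrom - 1; ++m)
            if (G.mask[m] == target) { ++count; break; }
    }
    return count;
}

// Rooted-triplet topologies: counts of first-coalescing pair (ab, ac, bc).
// [[Rcpp::export]]
IntegerVector cpp_triplet_counts(IntegerVector parent, NumericVector height,
                                 IntegerVector order, int n_tip, IntegerVector samples,
                                 int a, int b, int c, int n_trees)
{
    SpTree S = make_sptree(parent, height, order, n_tip, samples);
    GeneTree G = make_genetree(S.n_chrom);
    std::vector<std::vector<int> > buf(S.n_nodes);
    uint64_t trip = (1ULL << a) | (1ULL << b) | (1ULL << c);
    uint64_t pab = (1ULL << a) | (1ULL << b);
    uint64_t pac = (1ULL << a) | (1ULL << c);
    IntegerVector counts(3);
    for (int r = 0; r < n_trees; ++r) {
        sim_one(S.parent.data(), S.height.data(), S.order.data(), S.n_nodes,
                S.n_tip, S.samples.data(), S.offset.data(), S.n_chrom, buf, G);
        for (int m = S.n_chrom; m < 2 * S.n_chrom - 1; ++m) {
            uint64_t rm = G.mask[m] & trip;
            if (__builtin_popcountll(rm) == 2) {
                if (rm == pab) ++counts[0];
                else if (rm == pac) ++counts[1];
                else ++counts[2];
                break;
            }
        }
    }
    return counts;
}

// Unrooted-quartet topologies: counts of (ab|cd, ac|bd, ad|bc).
// [[Rcpp::export]]
IntegerVector cpp_quartet_counts(IntegerVector parent, NumericVector height,
                                 IntegerVector order, int n_tip, IntegerVector samples,
                                 int a, int b, int c, int d, int n_trees)
{
    SpTree S = make_sptree(parent, height, order, n_tip, samples);
    GeneTree G = make_genetree(S.n_chrom);
    std::vector<std::vector<int> > buf(S.n_nodes);
    uint64_t quart = (1ULL << a) | (1ULL << b) | (1ULL << c) | (1ULL << d);
    uint64_t pab = (1ULL << a) | (1ULL << b), pcd = (1ULL << c) | (1ULL << d);
    uint64_t pac = (1ULL << a) | (1ULL << c), pbd = (1ULL << b) | (1ULL << d);
    IntegerVector counts(3);
    for (int r = 0; r < n_trees; ++r) {
        sim_one(S.parent.data(), S.height.data(), S.order.data(), S.n_nodes,
                S.n_tip, S.samples.data(), S.offset.data(), S.n_chrom, buf, G);
        for (int m = S.n_chrom; m < 2 * S.n_chrom - 1; ++m) {
            uint64_t rm = G.mask[m] & quart;
            if (__builtin_popcountll(rm) == 2) {
                if (rm == pab || rm == pcd) ++counts[0];
                else if (rm == pac || rm == pbd) ++counts[1];
                else ++counts[2];
                break;
            }
        }
    }
    return counts;
}

// Single-mutation (infinite-sites, one segregating site) patterns: simulate a
// gene tree, drop one mutation on a branch chosen with probability
// proportional to branch length, return the derived-chromosome set.
// [[Rcpp::export]]
List cpp_site_patterns(IntegerVector parent, NumericVector height, IntegerVector order,
                       int n_tip, IntegerVector samples, int n_sims, bool full)
{
    SpTree S = make_sptree(parent, height, order, n_tip, samples);
    if (S.n_chrom < 2) stop("site patterns need at least two chromosomes");
    GeneTree G = make_genetree(S.n_chrom);
    std::vector<std::vector<int> > buf(S.n_nodes);
    std::vector<int> gparent(2 * S.n_chrom - 1);
    NumericVector maskv(n_sims);
    IntegerVector branchv(n_sims);
    IntegerMatrix M = full ? IntegerMatrix(n_sims, S.n_chrom) : IntegerMatrix(0, 0);
    int n_gn = 2 * S.n_chrom - 1;
    for (int r = 0; r < n_sims; ++r) {
        sim_one(S.parent.data(), S.height.data(), S.order.data(), S.n_nodes,
                S.n_tip, S.samples.data(), S.offset.data(), S.n_chrom, buf, G);
        for (int m = 0; m < S.n_chrom - 1; ++m) {
            gparent[G.left[m]] = S.n_chrom + m;
            gparent[G.right[m]] = S.n_chrom + m;
        }
        double total = 0.0;
        for (int u = 0; u < n_gn - 1; ++u)
            total += G.ntime[gparent[u]] - G.ntime[u];
        double x = unif_rand() * total;
        int chosen = n_gn - 2;
        for (int u = 0; u < n_gn - 1; ++u) {
            x -= G.ntime[gparent[u]] - G.ntime[u];
            if (x <= 0) { chosen = u; break; }
        }
        maskv[r] = (double)G.mask[chosen];
        branchv[r] = chosen;
        if (full)
            for (int i = 0; i < S.n_chrom; ++i)
                M(r, i) = (G.mask[chosen] >> i) & 1ULL;
    }
    return List::create(_["mask"] = maskv, _["branch"] = branchv, _["pattern"] = M);
}

// Monte-Carlo estimate of the probability that a single-mutation site
// pattern produces a group-shared fixed difference, per missing-taxa
// configuration. Species roles: 0 = focal (all chromosomes one state),
// 1 = contrast (all chromosomes the other state), 2 = free (must be fixed
// for the site to be testable, but may take either state — e.g. an
// outgroup excluded from the contrast). A simulated site is "testable"
// under a configuration iff every non-ignored species is fixed (no
// within-species polymorphism, which the fixed-nucleotide consensus turns
// into missing data) and the site still segregates between species.
// With condition_tested, probabilities are reported per testable site —
// the scale on which the excess test's n_var denominator counts.
// [[Rcpp::export]]
List cpp_pattern_prob(IntegerVector parent, NumericVector height, IntegerVector order,
                      int n_tip, IntegerVector samples, int n_sims,
                      IntegerVector chrom_species, IntegerVector species_role,
                      List config_ignored, NumericVector weights, bool either,
                      bool condition_tested, bool indicators)
{
    SpTree S = make_sptree(parent, height, order, n_tip, samples);
    if (S.n_chrom < 2) stop("site patterns need at least two chromosomes");
    GeneTree G = make_genetree(S.n_chrom);
    std::vector<std::vector<int> > buf(S.n_nodes);
    std::vector<int> gparent(2 * S.n_chrom - 1);
    int n_gn = 2 * S.n_chrom - 1;
    int n_sp = species_role.size();
    std::vector<uint64_t> spmask(n_sp, 0);
    for (int i = 0; i < chrom_species.size(); ++i)
        spmask[chrom_species[i]] |= 1ULL << i;
    int n_conf = config_ignored.size();
    std::vector<std::vector<int> > ign(n_conf);
    for (int c = 0; c < n_conf; ++c) {
        IntegerVector ig = config_ignored[c];
        std::vector<char> flag(n_sp, 0);
        for (int i = 0; i < ig.size(); ++i) {
            if (species_role[ig[i]] == 0)
                stop("a missingness configuration ignores a focal species");
            flag[ig[i]] = 1;
        }
        for (int s = 0; s < n_sp; ++s) if (flag[s]) ign[c].push_back(s);
    }
    std::vector<double> cum(n_conf);
    double wsum = 0.0;
    for (int c = 0; c < n_conf; ++c) { wsum += weights[c]; cum[c] = wsum; }
    IntegerVector match_counts(n_conf), tested_counts(n_conf);
    std::vector<int> ind;
    if (indicators) ind.reserve(n_sims);
    std::vector<char> is_ign(n_sp);
    for (int r = 0; r < n_sims; ++r) {
        sim_one(S.parent.data(), S.height.data(), S.order.data(), S.n_nodes,
                S.n_tip, S.samples.data(), S.offset.data(), S.n_chrom, buf, G);
        for (int m = 0; m < S.n_chrom - 1; ++m) {
            gparent[G.left[m]] = S.n_chrom + m;
            gparent[G.right[m]] = S.n_chrom + m;
        }
        double total = 0.0;
        for (int u = 0; u < n_gn - 1; ++u)
            total += G.ntime[gparent[u]] - G.ntime[u];
        double x = unif_rand() * total;
        int chosen = n_gn - 2;
        for (int u = 0; u < n_gn - 1; ++u) {
            x -= G.ntime[gparent[u]] - G.ntime[u];
            if (x <= 0) { chosen = u; break; }
        }
        uint64_t D = G.mask[chosen];
        // per-species state: 1 = all chromosomes derived, 0 = none,
        // -1 = polymorphic (missing after consensus)
        int conf_pick = -1;
        if (indicators) {
            double u = unif_rand() * wsum;
            conf_pick = 0;
            while (conf_pick < n_conf - 1 && u > cum[conf_pick]) ++conf_pick;
        }
        for (int c = 0; c < n_conf; ++c) {
            std::fill(is_ign.begin(), is_ign.end(), 0);
            for (size_t k = 0; k < ign[c].size(); ++k) is_ign[ign[c][k]] = 1;
            bool tested = true;
            bool focal_all1 = true, focal_all0 = true;
            bool contr_all1 = true, contr_all0 = true;
            bool any1 = false, any0 = false;
            for (int s = 0; s < n_sp && tested; ++s) {
                if (is_ign[s]) continue;
                uint64_t ds = D & spmask[s];
                int st;
                if (ds == spmask[s]) st = 1;
                else if (ds == 0) st = 0;
                else { tested = false; break; }
                if (st) any1 = true; else any0 = true;
                if (species_role[s] == 0) {
                    if (st) focal_all0 = false; else focal_all1 = false;
                } else if (species_role[s] == 1) {
                    if (st) contr_all0 = false; else contr_all1 = false;
                }
            }
            tested = tested && any1 && any0;
            bool ok = tested &&
                ((focal_all1 && contr_all0) ||
                 (either && focal_all0 && contr_all1));
            if (tested) ++tested_counts[c];
            if (ok) ++match_counts[c];
            if (indicators && c == conf_pick) {
                if (condition_tested) {
                    if (tested) ind.push_back(ok ? 1 : 0);
                } else {
                    ind.push_back(ok ? 1 : 0);
                }
            }
        }
    }
    return List::create(_["match"] = match_counts,
                        _["tested"] = tested_counts,
                        _["indicators"] = wrap(ind));
}
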