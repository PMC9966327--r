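#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

// Union-find with group tags: each root carries the marker-group id its
// component touches (0 = none). Merging two roots with different non-zero
// tags is the "reconnection" event.
struct UF {
    std::vector<int> parent, rank_, tag;
    UF(int n) : parent(n), rank_(n, 0), tag(n, 0) {
        for (int i = 0; i < n; ++i) parent[i] = i;
    }
    int find(int x) {
        while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
        return x;
    }
    // returns false if the union would merge two distinct marker groups
    // (and does not perform it when dryRun)
    bool unite(int a, int b) {
        a = find(a); b = find(b);
        if (a == b) return true;
        if (rank_[a] < rank_[b]) std::swap(a, b);
        parent[b] = a;
        if (rank_[a] == rank_[b]) ++rank_[a];
        if (tag[a] == 0) tag[a] = tag[b];
        return true;
    }
};

static void neighborOffsets(int conn, const int *dims,
                            std::vector<int64_t> &offs,
                            std::vector<int> &di, std::vector<int> &dj,
                            std::vector<int> &dk) {
    for (int a = -1; a <= 1; ++a)
        for (int b = -1; b <= 1; ++b)
            for (int c = -1; c <= 1; ++c) {
                if (a == 0 && b == 0 && c == 0) continue;
                int nz = std::abs(a) + std::abs(b) + std::abs(c);
                if (conn == 6 && nz != 1) continue;
                offs.push_back((int64_t)a + (int64_t)b * dims[0] +
                               (int64_t)c * dims[0] * dims[1]);
                di.push_back(a); dj.push_back(b); dk.push_back(c);
            }
}

// Marker-driven fragment splitting: iteratively remove the in-mask voxel
// with the highest gradient (ties: smallest lexicographic (i,j,k) index)
// until no two marker groups are connected, then re-add, in removal order,
// every voxel whose re-addition does not reconnect two groups. The minimal
// removal prefix is found by reverse union-find, which yields the same set
// as the literal one-at-a-time loop because connectivity is monotone in
// the removed prefix.
// mask: integer vector (0/1) of length prod(dims); grad: gradient per
// voxel; markerIdx: 1-based linear indices; markerGroup: positive ints.
// [[Rcpp::export(name = ".cppSplitFragment")]]
List cppSplitFragment(IntegerVector dimsIn, IntegerVector mask,
                      NumericVector grad, IntegerVector markerIdx,
                      IntegerVector markerGroup, int connectivity) {
    int dims[3] = {dimsIn[0], dimsIn[1], dimsIn[2]};
    int64_t n = (int64_t)dims[0] * dims[1] * dims[2];
    std::vector<int64_t> offs; std::vector<int> di, dj, dk;
    neighborOffsets(connectivity, dims, offs, di, dj, dk);
    int no = (int)offs.size();

    std::vector<int> groupOf(n, 0);
    for (int m = 0; m < markerIdx.size(); ++m)
        groupOf[markerIdx[m] - 1] = markerGroup[m];

    // candidates: in-mask non-marker voxels sorted by descending gradient,
    // ties by ascending lexicographic (i,j,k)
    std::vector<int64_t> cand;
    cand.reserve(n / 4);
    for (int64_t v = 0; v < n; ++v)
        if (mask[v] && groupOf[v] == 0) cand.push_back(v);
    std::vector<int64_t> lexkey(cand.size());
    for (size_t q = 0; q < cand.size(); ++q) {
        int64_t v = cand[q];
        int i = (int)(v % dims[0]);
        int j = (int)((v / dims[0]) % dims[1]);
        int k = (int)(v / ((int64_t)dims[0] * dims[1]));
        lexkey[q] = ((int64_t)i * dims[1] + j) * dims[2] + k;
    }
    std::vector<size_t> ord(cand.size());
    for (size_t q = 0; q < ord.size(); ++q) ord[q] = q;
    std::sort(ord.begin(), ord.end(), [&](size_t a, size_t b) {
        if (grad[cand[a]] != grad[cand[b]]) return grad[cand[a]] > grad[cand[b]];
        return lexkey[a] < lexkey[b];
    });
    std::vector<int64_t> order(cand.size());
    for (size_t q = 0; q < ord.size(); ++q) order[q] = cand[ord[q]];
    int64_t M = (int64_t)order.size();

    auto inBounds = [&](int64_t v, int o) {
        int i = (int)(v % dims[0]);
        int j = (int)((v / dims[0]) % dims[1]);
        int k = (int)(v / ((int64_t)dims[0] * dims[1]));
        int ii = i + di[o], jj = j + dj[o], kk = k + dk[o];
        return ii >= 0 && ii < dims[0] && jj >= 0 && jj < dims[1] &&
               kk >= 0 && kk < dims[2];
    };

    // reverse union-find: start with markers only, add candidates back in
    // reverse removal order; the step at which two distinct groups first
    // join gives the minimal removal prefix
    std::vector<char> present(n, 0);
    for (int m = 0; m < markerIdx.size(); ++m) present[markerIdx[m] - 1] = 1;
    {
        UF uf((int)n);
        for (int64_t v = 0; v < n; ++v)
            if (groupOf[v] > 0) uf.tag[v] = groupOf[v];
        // connect marker voxels to each other where adjacent
        bool connected = false;
        for (int64_t v = 0; v < n; ++v) {
            if (!present[v]) continue;
            for (int o = 0; o < no; ++o) {
                if (!inBounds(v, o)) continue;
                int64_t w = v + offs[o];
                if (!present[w]) continue;
                int ra = uf.find((int)v), rb = uf.find((int)w);
                if (ra != rb) {
                    int ta = uf.tag[ra], tb = uf.tag[rb];
                    if (ta > 0 && tb > 0 && ta != tb) connected = true;
                    uf.unite(ra, rb);
                }
            }
        }
        bool markersAdjacent = connected;
        int64_t mStar = 0;
        if (!connected) {
            for (int64_t q = M - 1; q >= 0; --q) {
                int64_t v = order[q];
                present[v] = 1;
                int rv = uf.find((int)v);
                for (int o = 0; o < no && !connected; ++o) {
                    if (!inBounds(v, o)) continue;
                    int64_t w = v + offs[o];
                    if (!present[w]) continue;
                    int rw = uf.find((int)w);
                    rv = uf.find((int)v);
                    if (rv == rw) continue;
                    int ta = uf.tag[rv], tb = uf.tag[rw];
                    if (ta > 0 && tb > 0 && ta != tb) { connected = true; break; }
                    uf.unite(rv, rw);
                }
                if (connected) { mStar = q + 1; break; }
            }
        }
        // rebuild `present` = mask minus removal prefix [0, mStar)
        std::fill(present.begin(), present.end(), 0);
        for (int64_t v = 0; v < n; ++v) if (mask[v]) present[v] = 1;
        for (int64_t q = 0; q < mStar; ++q) present[order[q]] = 0;
        M = mStar;
        if (markersAdjacent) {
            return List::create(_["labels"] = R_NilValue,
                                _["removed"] = R_NilValue,
                                _["infeasible"] = true);
        }
    }

    // re-add scan in removal order with a fresh union-find over kept voxels
    UF uf((int)n);
    for (int64_t v = 0; v < n; ++v)
        if (groupOf[v] > 0) uf.tag[v] = groupOf[v];
    for (int64_t v = 0; v < n; ++v) {
        if (!present[v]) continue;
        for (int o = 0; o < no; ++o) {
            if (!inBounds(v, o)) continue;
            int64_t w = v + offs[o];
            if (present[w]) uf.unite((int)v, (int)w);
        }
    }
    std::vector<int64_t> removedFinal;
    for (int64_t q = 0; q < M; ++q) {
        int64_t v = order[q];
        // distinct neighbor roots and their tags
        int tagSeen = 0; bool conflict = false;
        int roots[26]; int nr = 0;
        for (int o = 0; o < no; ++o) {
            if (!inBounds(v, o)) continue;
            int64_t w = v + offs[o];
            if (!present[w]) continue;
            int r = uf.find((int)w);
            bool dup = false;
            for (int s = 0; s < nr; ++s) if (roots[s] == r) { dup = true; break; }
            if (dup) continue;
            roots[nr++] = r;
            int t = uf.tag[r];
            if (t > 0) {
                if (tagSeen == 0) tagSeen = t;
                else if (tagSeen != t) { conflict = true; break; }
            }
        }
        if (conflict) { removedFinal.push_back(v); continue; }
        present[v] = 1;
        for (int s = 0; s < nr; ++s) uf.unite((int)v, roots[s]);
    }

    // labels: group tag of each kept voxel's component
    IntegerVector labels(n);
    for (int64_t v = 0; v < n; ++v)
        if (present[v]) labels[v] = uf.tag[uf.find((int)v)];
    IntegerVector removedOut(removedFinal.size());
    for (size_t q = 0; q < removedFinal.size(); ++q)
        removedOut[q] = (int)(removedFinal[q] + 1);  // 1-based
    return List::create(_["labels"] = labels, _["removed"] = removedOut,
                        _["infeasible"] = false);
}
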