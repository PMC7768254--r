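#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Gillespie simulation of the general geometric indel process with
// alignment tracking.
//
// State: the L ancestral residues interleaved with L+1 insertion junctions.
// Slot layout (left to right): junction 0, residue 1, junction 1, ...,
// residue L, junction L.  Slot 2*i is junction i (holds the count of
// surviving inserted residues); slot 2*i-1 is ancestral residue i (1 while
// matched, 0 once deleted).  A Fenwick tree over the slot counts gives
// O(log L) lookup of the k-th descendant residue; insertions pool into
// junction counts and deletions walk rightward across slots, so each event
// costs O(log L + event length).
//
// Inserted residues attach to the junction immediately right of the chosen
// descendant residue (left-edge insertions to junction 0), matching the
// immortal-link picture of single-residue models so that the x = y = 0
// limit is exact.  Deletions start at a uniformly chosen descendant residue
// and extend rightward; the sampled geometric length is truncated at the
// sequence end (per-residue total deletion rate exactly mu).
//
// Draw protocol per event, all via unif_rand() so an expanded-column
// reference implementation can reproduce the stream draw-for-draw:
//   u1 waiting time, u2 event type, u3 site, u4 length.

struct Fenwick {
    int n;
    std::vector<long long> tree;
    Fenwick(int n_) : n(n_), tree(n_ + 1, 0) {}
    void update(int pos, long long delta) {  // 1-based
        for (; pos <= n; pos += pos & -pos) tree[pos] += delta;
    }
    long long prefix(int pos) const {        // sum of slots 1..pos
        long long s = 0;
        for (; pos > 0; pos -= pos & -pos) s += tree[pos];
        return s;
    }
    // smallest pos with prefix(pos) >= k (k >= 1)
    int find_kth(long long k) const {
        int pos = 0;
        int log2n = 1;
        while ((1 << log2n) <= n) ++log2n;
        for (int pw = 1 << log2n; pw > 0; pw >>= 1) {
            int next = pos + pw;
            if (next <= n && tree[next] < k) {
                pos = next;
                k -= tree[next];
            }
        }
        return pos + 1;
    }
};

static int geom_len(double ext, double u) {
    if (ext <= 0.0) return 1;
    double n = 1.0 + std::floor(std::log(u) / std::log(ext));
    if (n > 1e7) n = 1e7;
    return (int)n;
}

// [[Rcpp::export]]
IntegerVector cpp_evolve(double lambda, double mu, double x, double y,
                         int L, double t) {
    // slots 1..2L+1 (Fenwick 1-based): slot s holds junction (s odd) or
    // ancestral residue (s even); junction i -> slot 2i+1, residue i ->
    // slot 2i
    int nslots = 2 * L + 1;
    Fenwick fen(nslots);
    std::vector<long long> icount(L + 1, 0);  // insertions per junction
    std::vector<char> anc(L + 1, 1);          // residue i alive? (1-based)
    for (int i = 1; i <= L; ++i) fen.update(2 * i, 1);
    long long len = L;                        // current descendant length

    double now = 0.0;
    while (true) {
        double rate = (double)(len + 1) * lambda + (double)len * mu;
        if (rate <= 0.0) break;
        double u1 = unif_rand();
        now += -std::log(u1) / rate;
        if (now > t) break;
        double u2 = unif_rand();
        bool is_ins = (u2 * rate < (double)(len + 1) * lambda);
        double u3 = unif_rand();
        double u4 = unif_rand();
        if (is_ins) {
            long long nsites = len + 1;
            long long k = (long long)(u3 * nsites);
            if (k >= nsites) k = nsites - 1;  // site 0 = left edge
            int n = geom_len(x, u4);
            int junction;
            if (k == 0) {
                junction = 0;
            } else {
                int slot = fen.find_kth(k);   // slot of k-th descendant residue
                if (slot % 2 == 1) junction = (slot - 1) / 2;   // inside junction
                else junction = slot / 2;     // right of ancestral residue
            }
            icount[junction] += n;
            fen.update(2 * junction + 1, n);
            len += n;
        } else {
            long long k = 1 + (long long)(u3 * len);
            if (k > len) k = len;
            long long m = geom_len(y, u4);    // truncated at sequence end
            int slot = fen.find_kth(k);
            long long before = fen.prefix(slot - 1);
            long long offset = k - before;    // 1-based within slot
            while (m > 0 && slot <= nslots) {
                if (slot % 2 == 1) {          // junction
                    int j = (slot - 1) / 2;
                    long long avail = icount[j] - (offset - 1);
                    if (avail > 0) {
                        long long d = avail < m ? avail : m;
                        icount[j] -= d;
                        fen.update(slot, -d);
                        len -= d;
                        m -= d;
                    }
                } else {                      // ancestral residue
                    int i = slot / 2;
                    if (offset <= 1 && anc[i]) {
                        anc[i] = 0;
                        fen.update(slot, -1);
                        --len;
                        --m;
                    }
                }
                offset = 1;
                ++slot;
            }
        }
    }

    // expanded M/I/D column sequence: 0 = M, 1 = I, 2 = D
    std::vector<int> cols;
    cols.reserve((size_t)(L + len + 1));
    for (int i = 0; i <= L; ++i) {
        for (long long j = 0; j < icount[i]; ++j) cols.push_back(1);
        if (i < L) cols.push_back(anc[i + 1] ? 0 : 2);
    }
    return wrap(cols);
}
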