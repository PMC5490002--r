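// Forward Wright-Fisher simulator for a two-population split with
// recombination, recurrent mutation on a fixed site grid, symmetric
// migration after the split, and multiplicative (genic, h = 0.5)
// selection.  All randomness goes through R's RNG so a single
// set.seed() on the R side makes runs reproducible.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstring>

using namespace Rcpp;

namespace {

struct PopState {
    int N;                       // diploid size
    std::vector<uint8_t> hap;    // 2N x L, haplotype-major
    std::vector<uint8_t> buf;    // next generation
    std::vector<double> cumw;    // cumulative fitness weights

    void init(int n, int L) {
        N = n;
        hap.assign(static_cast<size_t>(2 * n) * L, 0);
        buf.assign(static_cast<size_t>(2 * n) * L, 0);
        cumw.assign(n, 0.0);
    }
};

struct GenomeMap {
    std::vector<int> chrom_start, chrom_end;   // [start, end) site index
    std::vector<double> gpos;                  // cumulative Morgans
    std::vector<double> chrom_morgans;
};

// cumulative fitness weights; returns total weight
double fitness_weights(PopState &pop, int L,
                       const std::vector<int> &sel_sites,
                       const std::vector<double> &s) {
    double tot = 0.0;
    for (int i = 0; i < pop.N; ++i) {
        const uint8_t *h1 = &pop.hap[static_cast<size_t>(2 * i) * L];
        const uint8_t *h2 = &pop.hap[static_cast<size_t>(2 * i + 1) * L];
        double logw = 0.0;
        for (size_t k = 0; k < sel_sites.size(); ++k) {
            int j = sel_sites[k];
            int dose = h1[j] + h2[j];
            if (dose) logw += 0.5 * s[j] * dose;  // genic selection, h = 0.5
        }
        tot += std::exp(logw);
        pop.cumw[i] = tot;
    }
    return tot;
}

inline int pick_parent(const PopState &pop, bool neutral, double totw) {
    if (neutral) {
        int i = static_cast<int>(unif_rand() * pop.N);
        return i >= pop.N ? pop.N - 1 : i;
    }
    double u = unif_rand() * totw;
    int lo = 0, hi = pop.N - 1;
    while (lo < hi) {
        int mid = (lo + hi) / 2;
        if (pop.cumw[mid] < u) lo = mid + 1; else hi = mid;
    }
    return lo;
}

// produce one gamete from parent haplotypes (h1, h2) into dst
void meiosis(const uint8_t *h1, const uint8_t *h2, uint8_t *dst, int L,
             const GenomeMap &gm) {
    int n_chrom = static_cast<int>(gm.chrom_start.size());
    for (int c = 0; c < n_chrom; ++c) {
        int a = gm.chrom_start[c], b = gm.chrom_end[c];
        int phase = unif_rand() < 0.5 ? 0 : 1;     // independent assortment
        int ncx = static_cast<int>(R::rpois(gm.chrom_morgans[c]));
        if (ncx == 0) {
            std::memcpy(dst + a, (phase == 0 ? h1 : h2) + a, b - a);
            continue;
        }
        std::vector<double> cx(ncx);
        for (int k = 0; k < ncx; ++k)
            cx[k] = gm.gpos[a] + unif_rand() * gm.chrom_morgans[c];
        std::sort(cx.begin(), cx.end());
        int pos = a;
        for (int k = 0; k <= ncx; ++k) {
            int stop = (k == ncx)
                ? b
                : static_cast<int>(std::upper_bound(gm.gpos.begin() + a,
                                                    gm.gpos.begin() + b,
                                                    cx[k]) - gm.gpos.begin());
            if (stop > pos) {
                std::memcpy(dst + pos, (phase == 0 ? h1 : h2) + pos,
                            stop - pos);
                pos = stop;
            }
            phase ^= 1;
        }
    }
}

void mutate(PopState &pop, int L, double mu_site,
            const std::vector<double> &s, std::vector<int> &active,
            std::vector<uint8_t> &active_flag) {
    double lambda = 2.0 * pop.N * static_cast<double>(L) * mu_site;
    int nmut = static_cast<int>(R::rpois(lambda));
    for (int k = 0; k < nmut; ++k) {
        int h = static_cast<int>(unif_rand() * 2 * pop.N);
        if (h >= 2 * pop.N) h = 2 * pop.N - 1;
        int j = static_cast<int>(unif_rand() * L);
        if (j >= L) j = L - 1;
        pop.hap[static_cast<size_t>(h) * L + j] = 1;  // derived allele
        if (s[j] != 0.0 && !active_flag[j]) {
            active_flag[j] = 1;
            active.push_back(j);
        }
    }
}

}  // namespace

// [[Rcpp::export(name = ".wf_simulate")]]
List wf_simulate(int n_anc, int n_general, int n_isolate,
                 int burnin, int tdg, double mig, double mu_site,
                 NumericVector gpos_in, IntegerVector chrom_id,
                 NumericVector s_in,
                 int sample_general, int sample_isolate) {
    const int L = gpos_in.size();
    if (chrom_id.size() != L || s_in.size() != L)
        stop("site vectors must have equal length");

    GenomeMap gm;
    gm.gpos.assign(gpos_in.begin(), gpos_in.end());
    std::vector<double> s(s_in.begin(), s_in.end());
    std::vector<int> sel_sites;
    for (int j = 0; j < L; ++j)
        if (s[j] != 0.0) sel_sites.push_back(j);

    for (int j = 0; j < L; ++j) {
        if (j == 0 || chrom_id[j] != chrom_id[j - 1]) {
            if (j > 0) gm.chrom_end.push_back(j);
            gm.chrom_start.push_back(j);
        }
    }
    gm.chrom_end.push_back(L);
    for (size_t c = 0; c < gm.chrom_start.size(); ++c) {
        double span = gm.gpos[gm.chrom_end[c] - 1] - gm.gpos[gm.chrom_start[c]];
        gm.chrom_morgans.push_back(span > 0 ? span : 1e-9);
    }

    RNGScope scope;
    const bool neutral = sel_sites.empty();

    // selection only needs sites segregating somewhere: globally fixed or
    // absent sites multiply every fitness by the same constant.  The list
    // is refreshed periodically; mutation inserts new sites immediately,
    // so staleness only ever costs time, never exactness.
    std::vector<uint8_t> active_flag(L, 0);
    std::vector<int> active;
    auto rebuild_active = [&](std::initializer_list<PopState *> pops) {
        active.clear();
        std::fill(active_flag.begin(), active_flag.end(), 0);
        for (size_t k = 0; k < sel_sites.size(); ++k) {
            int j = sel_sites[k];
            bool seen0 = false, seen1 = false;
            for (PopState *pp : pops) {
                size_t n = static_cast<size_t>(2 * pp->N);
                for (size_t r = 0; r < n && !(seen0 && seen1); ++r) {
                    if (pp->hap[r * L + j]) seen1 = true;
                    else seen0 = true;
                }
                if (seen0 && seen1) break;
            }
            if (seen0 && seen1) {
                active.push_back(j);
                active_flag[j] = 1;
            }
        }
    };

    PopState anc;
    anc.init(n_anc, L);
    for (int g = 0; g < burnin; ++g) {
        if (!neutral && g % 16 == 0) rebuild_active({&anc});
        double totw = neutral ? 0.0 : fitness_weights(anc, L, active, s);
        for (int i = 0; i < anc.N; ++i) {
            for (int k = 0; k < 2; ++k) {
                int par = pick_parent(anc, neutral, totw);
                meiosis(&anc.hap[static_cast<size_t>(2 * par) * L],
                        &anc.hap[static_cast<size_t>(2 * par + 1) * L],
                        &anc.buf[static_cast<size_t>(2 * i + k) * L], L, gm);
            }
        }
        std::swap(anc.hap, anc.buf);
        mutate(anc, L, mu_site, s, active, active_flag);
        if (g % 256 == 0) Rcpp::checkUserInterrupt();
    }

    // split: found both daughter populations from the ancestral gene pool
    PopState gen, iso;
    gen.init(n_general, L);
    iso.init(n_isolate, L);
    {
        if (!neutral) rebuild_active({&anc});
        double totw = neutral ? 0.0 : fitness_weights(anc, L, active, s);
        PopState *dst[2] = {&gen, &iso};
        for (int d = 0; d < 2; ++d) {
            for (int i = 0; i < dst[d]->N; ++i) {
                for (int k = 0; k < 2; ++k) {
                    int par = pick_parent(anc, neutral, totw);
                    meiosis(&anc.hap[static_cast<size_t>(2 * par) * L],
                            &anc.hap[static_cast<size_t>(2 * par + 1) * L],
                            &dst[d]->hap[static_cast<size_t>(2 * i + k) * L],
                            L, gm);
                }
            }
        }
    }

    for (int g = 0; g < tdg; ++g) {
        if (!neutral && g % 16 == 0) rebuild_active({&gen, &iso});
        double tw_gen = neutral ? 0.0 : fitness_weights(gen, L, active, s);
        double tw_iso = neutral ? 0.0 : fitness_weights(iso, L, active, s);
        PopState *pops[2] = {&gen, &iso};
        double tws[2] = {tw_gen, tw_iso};
        for (int d = 0; d < 2; ++d) {
            PopState &p = *pops[d];
            PopState &other = *pops[1 - d];
            for (int i = 0; i < p.N; ++i) {
                for (int k = 0; k < 2; ++k) {
                    PopState *src = &p;
                    double tw = tws[d];
                    if (mig > 0 && unif_rand() < mig) {
                        src = &other;
                        tw = tws[1 - d];
                    }
                    int par = pick_parent(*src, neutral, tw);
                    meiosis(&src->hap[static_cast<size_t>(2 * par) * L],
                            &src->hap[static_cast<size_t>(2 * par + 1) * L],
                            &p.buf[static_cast<size_t>(2 * i + k) * L], L, gm);
                }
            }
        }
        std::swap(gen.hap, gen.buf);
        std::swap(iso.hap, iso.buf);
        mutate(gen, L, mu_site, s, active, active_flag);
        mutate(iso, L, mu_site, s, active, active_flag);
        if (g % 64 == 0) Rcpp::checkUserInterrupt();
    }

    // sample individuals without replacement (R RNG, input-order stable)
    auto draw_sample = [&](PopState &p, int n_samp) {
        std::vector<int> idx(p.N);
        for (int i = 0; i < p.N; ++i) idx[i] = i;
        for (int i = 0; i < n_samp; ++i) {
            int r = i + static_cast<int>(unif_rand() * (p.N - i));
            if (r >= p.N) r = p.N - 1;
            std::swap(idx[i], idx[r]);
        }
        std::sort(idx.begin(), idx.begin() + n_samp);
        IntegerMatrix out(2 * n_samp, L);
        for (int i = 0; i < n_samp; ++i) {
            const uint8_t *h1 = &p.hap[static_cast<size_t>(2 * idx[i]) * L];
            const uint8_t *h2 = &p.hap[static_cast<size_t>(2 * idx[i] + 1) * L];
            for (int j = 0; j < L; ++j) {
                out(2 * i, j) = h1[j];
                out(2 * i + 1, j) = h2[j];
            }
        }
        return out;
    };

    IntegerMatrix hap_gen = draw_sample(gen, sample_general);
    IntegerMatrix hap_iso = draw_sample(iso, sample_isolate);

    return List::create(_["hap_general"] = hap_gen,
                        _["hap_isolate"] = hap_iso);
}
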