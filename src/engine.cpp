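// Forward-in-time simulation core for the PRDM9 Red Queen model.
//
// The population is N diploid individuals, one chromosome each, encoded as an
// array of L slots. Each PRDM9 allele owns h slots (its binding targets) with
// exponentially distributed rescaled affinities y; occupancy at chemical
// equilibrium is x = c*y/(1+c*y), with c the dosage multiplier (c_hom for
// homozygotes, 1 otherwise). A haplotype carries one PRDM9 allele plus the
// active/inactive state of every live allele's targets, stored as one
// contiguous byte buffer indexed through per-allele offsets. Meiosis:
// binding on 4 chromatids, DSB thinning p = min(1, d/k), symmetric-DSB
// requirement (or the no-symmetry control), one CO, repair of all DSBs off
// the homologue (= biased gene conversion), uniform gamete choice.
//
// All randomness flows through one xoshiro256+ generator seeded from R; draws
// are consumed in a fixed documented order so runs are reproducible.

#include <Rcpp.h>
#include <cstdint>
#include <cstring>
#include <cmath>
#include <vector>
#include <algorithm>
#include <map>
#include <unordered_set>

using namespace Rcpp;

// ---------------------------------------------------------------- RNG -------

struct RQRng {
  uint64_t s[4];

  explicit RQRng(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) { // splitmix64 expansion of the seed
      x += 0x9E3779B97F4A7C15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }

  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }

  inline uint64_t next() {
    const uint64_t result = s[0] + s[3];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }

  // uniform double in [0, 1)
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }

  inline int below(int n) { return (int)(unif() * n); }

  inline double rexp(double mean) { return -mean * std::log1p(-unif()); }

  // exact Binomial(n, p) by geometric skipping; efficient for small n*p
  inline long long rbinom(long long n, double p) {
    if (p <= 0.0 || n <= 0) return 0;
    if (p >= 1.0) return n;
    const double logq = std::log1p(-p);
    long long count = 0;
    double i = std::floor(std::log1p(-unif()) / logq);
    while (i < (double)n) {
      ++count;
      i += 1.0 + std::floor(std::log1p(-unif()) / logq);
    }
    return count;
  }
};

// ------------------------------------------------------------ structures ----

struct Allele {
  int id;                    // stable public id, never recycled
  int birth;                 // generation of creation
  std::vector<int> pos;      // slot positions, length h
  std::vector<double> y;     // rescaled affinities
  std::vector<double> x1;    // occupancy at c = 1
  std::vector<double> xc;    // occupancy at c = c_hom
  std::vector<uint32_t> th1; // binding thresholds on 16-bit uniforms, c = 1
  std::vector<uint32_t> thc; // and at c = c_hom
  int carriers = 0;          // haplotypes carrying the allele
  bool dead = false;         // extinct; its column space awaits reuse

  // occupancies are quantised to multiples of 2^-16 (nearest) for sampling:
  // one 64-bit RNG word then yields the four chromatid Bernoulli draws
  void set_occupancy(int j, double c_hom) {
    x1[j] = y[j] / (1.0 + y[j]);
    xc[j] = c_hom * y[j] / (1.0 + c_hom * y[j]);
    th1[j] = (uint32_t)std::llround(x1[j] * 65536.0);
    thc[j] = (uint32_t)std::llround(xc[j] * 65536.0);
  }
  void resize(int h) {
    pos.resize(h); y.resize(h); x1.resize(h); xc.resize(h);
    th1.resize(h); thc.resize(h);
  }
  int size() const { return (int)pos.size(); }
};

struct Hap {
  int al;                    // registry index of the carried PRDM9 allele
  std::vector<uint8_t> act;  // concatenated active flags of all alleles' sites
};

struct Config {
  int N;
  double u, v;
  int h;
  double d;
  double ybar;
  double c_hom;
  int n_mei;
  bool symmetry;             // false = control (>=1 DSB suffices)
  int generations;
  int burn_in;
  int L;
  int prdm9_slot;
  int record_every;
  int s0_every;              // 0 disables probe-based s0
  int s0_probes;
  uint64_t seed;
};

struct MeiOut {
  bool success = false;
  int reason = 0;            // 0 ok, 1 no_binding, 2 no_symmetric_dsb, 3 no_dsb
  int k = 0;
  int ndsb = 0;
  int nsym = 0;
  int co_a = -1, co_j = -1, co_t = -1, partner_t = -1;
  Hap gam;
};

struct DSB { int t, a, j; };

// -------------------------------------------------------------- engine ------

class Sim {
public:
  Config cfg;
  RQRng rng;
  int gen = 0;
  int next_id = 0;
  std::vector<Allele> reg;
  std::vector<size_t> off;            // off[a]: byte offset of allele a's column
  size_t tot = 0;                     // total bytes per haplotype buffer
  std::vector<int> free_cols;         // registry slots of extinct alleles
  std::vector<Hap> haps;              // 2N haplotypes; individual i = (2i, 2i+1)
  std::vector<uint8_t> slot_used;
  int used_count = 0;

  // per-meiosis scratch
  std::vector<uint8_t> bm[2];
  std::vector<DSB> dsbs;
  std::vector<int> sym_idx;

  // meiosis bookkeeping
  long long n_attempts = 0, n_success = 0, n_no_binding = 0, n_no_sym = 0,
            n_no_dsb = 0;

  // trajectory accumulators
  std::vector<int> tr_gen, tr_id;
  std::vector<double> tr_f, tr_theta, tr_aff, tr_q, tr_w;
  std::vector<int> sc_gen, sc_nal;
  std::vector<double> sc_D, sc_theta, sc_q, sc_w, sc_sigma, sc_succ;
  std::vector<int> s0_gen;
  std::vector<double> s0_val;

  explicit Sim(const Config& c) : cfg(c), rng(c.seed) {
    slot_used.assign(cfg.L, 0);
    slot_used[cfg.prdm9_slot] = 1;
    used_count = 1;
    dsbs.reserve(64);
    sym_idx.reserve(64);
  }

  void reserve_scratch() {
    size_t mh = 0;
    for (const auto& a : reg) mh = std::max(mh, (size_t)a.size());
    if (bm[0].size() < mh) { bm[0].resize(mh); bm[1].resize(mh); }
  }

  const uint8_t* col(const Hap& hp, int a) const { return hp.act.data() + off[a]; }
  uint8_t* col(Hap& hp, int a) { return hp.act.data() + off[a]; }

  // ---- allele / slot management ----

  int create_allele() {
    const int h = cfg.h;
    if (cfg.L - used_count < h)
      stop("slot pool exhausted: fewer than h free slots remain (increase L)");
    Allele a;
    a.id = next_id++;
    a.birth = gen;
    a.resize(h);
    // draw order: all slots (uniform over free slots), then all affinities.
    // sites are kept sorted by slot position, so a CO arm exchange is a
    // suffix copy; affinities are i.i.d., so sorting the slots first leaves
    // the joint distribution unchanged
    for (int j = 0; j < h; ++j) {
      int p;
      do { p = rng.below(cfg.L); } while (slot_used[p]);
      slot_used[p] = 1;
      ++used_count;
      a.pos[j] = p;
    }
    std::sort(a.pos.begin(), a.pos.end());
    for (int j = 0; j < h; ++j) {
      a.y[j] = rng.rexp(cfg.ybar);
      a.set_occupancy(j, cfg.c_hom);
    }
    // population monomorphic for the active variant at allele birth; the
    // column space of an extinct allele is reused when available, so the
    // per-haplotype buffers are bounded by the concurrent-allele high water
    // mark and never need compacting
    int idx;
    if (!free_cols.empty()) {
      idx = free_cols.back();
      free_cols.pop_back();
      reg[idx] = std::move(a);
      for (auto& hp : haps)
        std::memset(hp.act.data() + off[idx], 1, (size_t)h);
    } else {
      idx = (int)reg.size();
      reg.push_back(std::move(a));
      off.push_back(tot);
      tot += h;
      for (auto& hp : haps) {
        if (hp.act.capacity() < tot)
          hp.act.reserve(std::max(tot, 2 * hp.act.capacity()));
        hp.act.resize(tot, 1);
      }
    }
    reserve_scratch();
    return idx;
  }

  void free_allele_slots(const Allele& a) {
    for (int p : a.pos) { slot_used[p] = 0; --used_count; }
  }

  void init_monomorphic() {
    haps.assign(2 * cfg.N, Hap{0, {}});
    create_allele();
    for (auto& hp : haps) hp.al = 0;
    reg[0].carriers = 2 * cfg.N;
  }

  // ---- mutation ----

  void mutate_prdm9() {
    if (cfg.u <= 0.0) return;
    for (auto& hp : haps)
      if (rng.unif() < cfg.u) hp.al = create_allele();
  }

  void mutate_targets() {
    // each target site of each diploid individual mutates with prob v; the
    // inactivating hit lands on one of the two haploid copies at random (a
    // hit on an already-inactive copy is a no-op). One Binomial(N*tot, v)
    // draw split uniformly over distinct (individual, site) pairs is
    // exactly equivalent to the per-pair Bernoulli trials.
    if (cfg.v <= 0.0 || tot == 0) return;
    const long long total = (long long)cfg.N * (long long)tot;
    const long long m = rng.rbinom(total, cfg.v);
    if (m == 0) return;
    std::unordered_set<long long> hit;
    hit.reserve((size_t)(m * 13 / 10) + 8);
    while ((long long)hit.size() < m) {
      long long idx = (long long)(rng.unif() * (double)total);
      if (idx >= total) idx = total - 1;
      if (!hit.insert(idx).second) continue;
      const long long ind = idx / (long long)tot;
      const long long at = idx % (long long)tot;
      haps[2 * ind + (rng.next() & 1)].act[at] = 0;
    }
  }

  // ---- meiosis ----

  MeiOut meiosis(int ia, int ib, bool want_gamete) {
    ++n_attempts;
    MeiOut out;
    const Hap& A = haps[ia];
    const Hap& B = haps[ib];
    const int als[2] = {A.al, B.al};
    const int nal = (A.al == B.al) ? 1 : 2;
    const bool hom = (nal == 1);

    // 1) binding: chromatids 0,1 replicate A; 2,3 replicate B. One RNG word
    //    yields four 16-bit uniforms, one per chromatid; a site instance is
    //    bound when its slice falls below the occupancy threshold.
    int k = 0;
    {
      RQRng ra = rng;                // local copy keeps the state in registers
      for (int s = 0; s < nal; ++s) {
        const Allele& al = reg[als[s]];
        const int h = al.size();
        const uint32_t* th = hom ? al.thc.data() : al.th1.data();
        const uint8_t* aA = col(A, als[s]);
        const uint8_t* aB = col(B, als[s]);
        uint8_t* b = bm[s].data();
        for (int j = 0; j < h; ++j) {
          uint8_t m = 0;
          if (aA[j] | aB[j]) {
            const uint64_t r = ra.next();
            const uint32_t t = th[j];
            const uint8_t full =
                (uint8_t)((uint32_t)(r & 0xFFFF) < t) |
                (uint8_t)(((uint32_t)((r >> 16) & 0xFFFF) < t) << 1) |
                (uint8_t)(((uint32_t)((r >> 32) & 0xFFFF) < t) << 2) |
                (uint8_t)(((uint32_t)((r >> 48) & 0xFFFF) < t) << 3);
            m = full & ((aA[j] ? 0x03 : 0) | (aB[j] ? 0x0C : 0));
          }
          b[j] = m;
          k += __builtin_popcount(m);
        }
      }
      rng = ra;
    }
    out.k = k;
    if (k == 0) { out.reason = 1; ++n_no_binding; return out; }

    // 2) DSB induction: each bound instance breaks with prob min(1, d/k);
    //    sampled by geometric skipping along the bound instances, enumerated
    //    in (allele, site, chromatid) order
    const double p = (cfg.d >= k) ? 1.0 : cfg.d / (double)k;
    dsbs.clear();
    if (p >= 1.0) {
      for (int s = 0; s < nal; ++s) {
        const int h = reg[als[s]].size();
        const uint8_t* b = bm[s].data();
        for (int j = 0; j < h; ++j)
          for (uint8_t m = b[j]; m; m &= m - 1)
            dsbs.push_back({__builtin_ctz(m), s, j});
      }
    } else {
      const double logq = std::log1p(-p);
      long long idx = (long long)std::floor(std::log1p(-rng.unif()) / logq);
      long long acc = 0;
      for (int s = 0; s < nal && idx < k; ++s) {
        const int h = reg[als[s]].size();
        const uint8_t* b = bm[s].data();
        for (int j = 0; j < h; ++j) {
          const int c = __builtin_popcount(b[j]);
          if (!c) continue;
          while (idx < acc + c) {
            int rank = (int)(idx - acc);
            uint8_t m = b[j];
            while (rank--) m &= m - 1;         // drop lowest set bits
            dsbs.push_back({__builtin_ctz(m), s, j});
            idx += 1 + (long long)std::floor(std::log1p(-rng.unif()) / logq);
          }
          acc += c;
          if (idx >= k) break;
        }
      }
    }
    out.ndsb = (int)dsbs.size();
    if (!cfg.symmetry && dsbs.empty()) { out.reason = 3; ++n_no_dsb; return out; }

    // 3) symmetry scan: a DSB is symmetric if its locus is bound on at least
    //    one chromatid of the other homologue
    sym_idx.clear();
    for (int i = 0; i < (int)dsbs.size(); ++i) {
      const DSB& D = dsbs[i];
      const uint8_t hom_mask = (D.t < 2) ? 0x0C : 0x03;
      if (bm[D.a][D.j] & hom_mask) sym_idx.push_back(i);
    }
    out.nsym = (int)sym_idx.size();

    int co_i, partner;
    if (cfg.symmetry) {
      if (sym_idx.empty()) { out.reason = 2; ++n_no_sym; return out; }
      co_i = sym_idx[rng.below((int)sym_idx.size())];
      // CO partner: uniformly among homologue chromatids bound at the CO locus
      const DSB& C = dsbs[co_i];
      const uint8_t hom_mask = (C.t < 2) ? 0x0C : 0x03;
      const uint8_t bound = bm[C.a][C.j] & hom_mask;
      int cand[2], nc = 0;
      for (int t = 0; t < 4; ++t)
        if (bound & (1 << t)) cand[nc++] = t;
      partner = cand[nc == 1 ? 0 : rng.below(nc)];
    } else {
      co_i = rng.below((int)dsbs.size());
      const DSB& C = dsbs[co_i];
      partner = (C.t < 2) ? 2 + rng.below(2) : rng.below(2);
    }
    const DSB& C = dsbs[co_i];
    out.co_a = C.a; out.co_j = C.j; out.co_t = C.t; out.partner_t = partner;
    out.success = true;
    ++n_success;

    // 4) gamete: uniform over the tetrad; materialise only the chosen one
    const int g = rng.below(4);
    if (!want_gamete) return out;

    const Hap& own = (g < 2) ? A : B;
    const Hap& oth = (g < 2) ? B : A;
    const int co_pos = reg[als[C.a]].pos[C.j];
    const bool in_co = (g == C.t) || (g == partner);

    Hap gam;
    gam.al = own.al;
    gam.act.reserve(tot + 8 * (size_t)cfg.h);  // slack for upcoming alleles
    gam.act.assign(own.act.begin(), own.act.end());
    if (in_co) {
      // exchange of flanking arms: slots strictly beyond the CO locus come
      // from the other homologue (incl. the PRDM9 locus if on that side);
      // with sites sorted by position this is a suffix copy per allele
      const int R = (int)reg.size();
      for (int a = 0; a < R; ++a) {
        if (reg[a].dead) continue;
        const std::vector<int>& pos = reg[a].pos;
        const int h = (int)pos.size();
        const int i0 = (int)(std::upper_bound(pos.begin(), pos.end(), co_pos)
                             - pos.begin());
        if (i0 < h)
          std::memcpy(col(gam, a) + i0, col(oth, a) + i0, (size_t)(h - i0));
      }
      if (cfg.prdm9_slot > co_pos) gam.al = oth.al;
    }
    // conversion: every DSB on the transmitted chromatid copies the
    // (pre-meiosis) homologue state at the broken locus; for the CO pair the
    // exchanged arm carries the partner chromatid's repairs instead
    for (const DSB& D : dsbs) {
      const int dpos = reg[als[D.a]].pos[D.j];
      const bool takes = in_co
        ? ((D.t == g && dpos <= co_pos) ||
           (D.t == (g == C.t ? partner : C.t) && dpos > co_pos))
        : (D.t == g);
      if (takes) {
        const Hap& tmpl = (D.t < 2) ? B : A;  // homologue of the broken chromatid
        gam.act[off[als[D.a]] + D.j] = tmpl.act[off[als[D.a]] + D.j];
      }
    }
    out.gam = std::move(gam);
    return out;
  }

  // ---- reproduction ----

  Hap make_gamete() {
    long guard = 0;
    for (;;) {
      if (++guard > 1000000L)
        stop("make_gamete: 1e6 consecutive parent draws failed at generation %d "
             "(population effectively sterile)", gen);
      const int par = rng.below(cfg.N);
      for (int m = 0; m < cfg.n_mei; ++m) {
        MeiOut out = meiosis(2 * par, 2 * par + 1, true);
        if (out.success) return std::move(out.gam);
      }
    }
  }

  void reproduce() {
    std::vector<Hap> next(2 * cfg.N);
    for (int i = 0; i < 2 * cfg.N; ++i) next[i] = make_gamete();
    haps.swap(next);
  }

  // mark extinct alleles dead, reclaim their genome slots and queue their
  // column space for reuse; registry indices of live alleles never move
  void garbage_collect() {
    const int R = (int)reg.size();
    for (auto& a : reg) a.carriers = 0;
    for (auto& hp : haps) ++reg[hp.al].carriers;
    for (int a = 0; a < R; ++a) {
      if (reg[a].carriers == 0 && !reg[a].dead) {
        free_allele_slots(reg[a]);
        reg[a].dead = true;
        free_cols.push_back(a);
      }
    }
  }

  // ---- closed-form per-genotype statistics (monitoring layer) ----

  // exact symmetric-binding rate q for a diploid genotype, from the realized
  // active patterns of its two haplotypes; reduces to the textbook moment
  // ratios when both haplotypes share the same active set
  double genotype_q(const Hap& A, const Hap& B) const {
    const int als[2] = {A.al, B.al};
    const int nal = (A.al == B.al) ? 1 : 2;
    double num = 0.0, den = 0.0;
    for (int s = 0; s < nal; ++s) {
      const Allele& al = reg[als[s]];
      const int h = al.size();
      const double* x = (nal == 1) ? al.xc.data() : al.x1.data();
      const uint8_t* a = col(A, als[s]);
      const uint8_t* b = col(B, als[s]);
      for (int j = 0; j < h; ++j) {
        const double xj = x[j];
        const double sym = xj * (2.0 - xj);   // bound on >=1 of 2 chromatids
        if (a[j]) { den += xj; if (b[j]) num += xj * sym; }
        if (b[j]) { den += xj; if (a[j]) num += xj * sym; }
      }
    }
    return den > 0.0 ? num / den : 0.0;
  }

  inline double fitness_from_w(double w) const {
    return 1.0 - std::pow(1.0 - w, (double)cfg.n_mei);
  }

  // haplo-insufficiency of allele a from its population-mean site activity
  double allele_sigma(int a, const std::vector<double>& abar) const {
    const Allele& al = reg[a];
    const int h = al.size();
    double m1h = 0, m2h = 0, m3h = 0, m1l = 0, m2l = 0, m3l = 0;
    for (int j = 0; j < h; ++j) {
      const double w = abar[j];
      const double xh = al.xc[j], xl = al.x1[j];
      m1h += w * xh; m2h += w * xh * xh; m3h += w * xh * xh * xh;
      m1l += w * xl; m2l += w * xl * xl; m3l += w * xl * xl * xl;
    }
    if (m1h <= 0.0 || m1l <= 0.0) return NA_REAL;
    const double qh = (2.0 * m2h - m3h) / m1h;
    const double ql = (2.0 * m2l - m3l) / m1l;
    const double wh = 1.0 - std::exp(-cfg.d * qh);
    const double wl = 1.0 - std::exp(-cfg.d * ql);
    return wl > 0.0 ? (wh - wl) / wl : NA_REAL;
  }

  // ---- per-generation records ----

  void record() {
    const int R = (int)reg.size();
    const int twoN = 2 * cfg.N;
    std::vector<int> cnt(R, 0);
    for (auto& hp : haps) ++cnt[hp.al];

    // per-allele site activity scans (extinct alleles awaiting compaction
    // are skipped everywhere below)
    std::vector<std::vector<double>> abar(R);
    std::vector<double> theta(R, 0.0), aff(R, 0.0);
    for (int a = 0; a < R; ++a) {
      if (cnt[a] == 0) continue;
      const int h = reg[a].size();
      std::vector<double> s(h, 0.0);
      for (auto& hp : haps) {
        const uint8_t* c = col(hp, a);
        for (int j = 0; j < h; ++j) s[j] += c[j];
      }
      double totact = 0.0, ysum = 0.0;
      for (int j = 0; j < h; ++j) {
        s[j] /= twoN;
        totact += s[j];
        ysum += s[j] * reg[a].y[j];
      }
      theta[a] = totact / h;
      aff[a] = totact > 0 ? ysum / totact : NA_REAL;
      abar[a] = std::move(s);
    }

    // background-averaged q and w per allele (weight 2 for homozygotes)
    std::vector<double> qsum(R, 0.0), wsum(R, 0.0), wt(R, 0.0);
    for (int i = 0; i < cfg.N; ++i) {
      const Hap& A = haps[2 * i];
      const Hap& B = haps[2 * i + 1];
      const double q = genotype_q(A, B);
      const double w = 1.0 - std::exp(-cfg.d * q);
      if (A.al == B.al) { qsum[A.al] += 2 * q; wsum[A.al] += 2 * w; wt[A.al] += 2; }
      else {
        qsum[A.al] += q; wsum[A.al] += w; wt[A.al] += 1;
        qsum[B.al] += q; wsum[B.al] += w; wt[B.al] += 1;
      }
    }

    double D = 0.0, tbar = 0.0, qbar = 0.0, wbar = 0.0, sbar = 0.0;
    double sw = 0.0;
    int live = 0;
    for (int a = 0; a < R; ++a) {
      if (cnt[a] == 0) continue;
      ++live;
      const double f = cnt[a] / (double)twoN;
      const double qa = wt[a] > 0 ? qsum[a] / wt[a] : NA_REAL;
      const double wa = wt[a] > 0 ? wsum[a] / wt[a] : NA_REAL;
      D += f * f;
      tbar += f * theta[a];
      if (wt[a] > 0) { qbar += f * qa; wbar += f * wa; }
      const double sg = allele_sigma(a, abar[a]);
      if (!ISNA(sg)) { sbar += f * sg; sw += f; }
      tr_gen.push_back(gen); tr_id.push_back(reg[a].id);
      tr_f.push_back(f); tr_theta.push_back(theta[a]); tr_aff.push_back(aff[a]);
      tr_q.push_back(qa); tr_w.push_back(wa);
    }
    sc_gen.push_back(gen);
    sc_nal.push_back(live);
    sc_D.push_back(1.0 / D);
    sc_theta.push_back(tbar);
    sc_q.push_back(qbar);
    sc_w.push_back(wbar);
    sc_sigma.push_back(sw > 0 ? sbar / sw : NA_REAL);
    sc_succ.push_back(n_attempts > 0 ? (double)n_success / n_attempts : NA_REAL);
  }

  // mean selection coefficient on fresh probe alleles: mean log fitness of a
  // probe combined with each individual's background, minus the population
  // mean log fitness
  void record_s0() {
    const double eps = 1e-300;
    double pop_lw = 0.0;
    for (int i = 0; i < cfg.N; ++i) {
      const double q = genotype_q(haps[2 * i], haps[2 * i + 1]);
      const double w = fitness_from_w(1.0 - std::exp(-cfg.d * q));
      pop_lw += std::log(w + eps);
    }
    pop_lw /= cfg.N;

    double probe_lw = 0.0;
    const int h = cfg.h;
    for (int pr = 0; pr < cfg.s0_probes; ++pr) {
      // probe allele: affinities only; all sites active population-wide
      double s1 = 0.0, s2 = 0.0;
      for (int j = 0; j < h; ++j) {
        const double y = rng.rexp(cfg.ybar);
        const double x = y / (1.0 + y);       // probe always heterozygous, c = 1
        s1 += x;
        s2 += x * x * (2.0 - x);
      }
      for (int i = 0; i < cfg.N; ++i) {
        // the probe replaces the PRDM9 allele of the first haplotype; target
        // states of the resident allele are kept as they stand
        const Hap& A = haps[2 * i];
        const Hap& B = haps[2 * i + 1];
        double num = 2.0 * s2, den = 2.0 * s1; // probe sites active on both haps
        const int ral = B.al;
        const Allele& al = reg[ral];
        const int hh = al.size();
        const uint8_t* a = col(A, ral);
        const uint8_t* b = col(B, ral);
        for (int j = 0; j < hh; ++j) {
          const double xj = al.x1[j];
          const double sym = xj * (2.0 - xj);
          if (a[j]) { den += xj; if (b[j]) num += xj * sym; }
          if (b[j]) { den += xj; if (a[j]) num += xj * sym; }
        }
        const double q = den > 0 ? num / den : 0.0;
        const double w = fitness_from_w(1.0 - std::exp(-cfg.d * q));
        probe_lw += std::log(w + eps);
      }
    }
    probe_lw /= (double)cfg.s0_probes * cfg.N;
    s0_gen.push_back(gen);
    s0_val.push_back(probe_lw - pop_lw);
  }

  // ---- main loop ----

  void step() {
    ++gen;
    mutate_prdm9();
    mutate_targets();
    reproduce();
    garbage_collect();
  }

  void run() {
    garbage_collect();
    record();
    if (cfg.s0_every > 0) record_s0();
    for (int g = 1; g <= cfg.generations; ++g) {
      step();
      if (gen % cfg.record_every == 0) record();
      if (cfg.s0_every > 0 && gen % cfg.s0_every == 0) record_s0();
      if ((g & 0x3FF) == 0) Rcpp::checkUserInterrupt();
    }
  }
};

// ------------------------------------------------------- R conversions ------

static Config parse_config(List cfg) {
  Config c;
  c.N = as<int>(cfg["N"]);
  c.u = as<double>(cfg["u"]);
  c.v = as<double>(cfg["v"]);
  c.h = as<int>(cfg["h"]);
  c.d = as<double>(cfg["d"]);
  c.ybar = as<double>(cfg["mean_affinity"]);
  c.c_hom = as<double>(cfg["c_hom"]);
  c.n_mei = as<int>(cfg["n_mei"]);
  c.symmetry = as<std::string>(cfg["mode"]) == "symmetry_required";
  c.generations = as<int>(cfg["generations"]);
  c.burn_in = as<int>(cfg["burn_in"]);
  c.L = as<int>(cfg["L"]);
  c.prdm9_slot = as<int>(cfg["prdm9_slot"]) - 1;   // R side is 1-based
  c.record_every = as<int>(cfg["record_every"]);
  c.s0_every = as<int>(cfg["s0_every"]);
  c.s0_probes = as<int>(cfg["s0_probes"]);
  double seed = as<double>(cfg["seed"]);
  c.seed = (uint64_t)seed;
  return c;
}

static List snapshot(const Sim& sim) {
  // extinct alleles awaiting column reuse are not part of the population
  std::vector<int> live;
  for (int a = 0; a < (int)sim.reg.size(); ++a)
    if (!sim.reg[a].dead) live.push_back(a);
  const int R = (int)live.size();
  List alleles(R);
  for (int i = 0; i < R; ++i) {
    const Allele& al = sim.reg[live[i]];
    IntegerVector pos(al.pos.begin(), al.pos.end());
    alleles[i] = List::create(
      _["id"] = al.id, _["birth"] = al.birth,
      _["loci"] = pos + 1,
      _["affinities"] = NumericVector(al.y.begin(), al.y.end()));
  }
  List hl(sim.haps.size());
  for (size_t i = 0; i < sim.haps.size(); ++i) {
    const Hap& hp = sim.haps[i];
    List inact(R);
    for (int ai = 0; ai < R; ++ai) {
      const int a = live[ai];
      std::vector<int> idx;
      const uint8_t* c = sim.col(hp, a);
      for (int j = 0; j < sim.reg[a].size(); ++j)
        if (!c[j]) idx.push_back(j + 1);
      inact[ai] = IntegerVector(idx.begin(), idx.end());
    }
    hl[i] = List::create(_["allele"] = sim.reg[hp.al].id, _["inactive"] = inact);
  }
  return List::create(
    _["generation"] = sim.gen, _["N"] = sim.cfg.N, _["L"] = sim.cfg.L,
    _["prdm9_slot"] = sim.cfg.prdm9_slot + 1, _["next_id"] = sim.next_id,
    _["alleles"] = alleles, _["haplotypes"] = hl);
}

static void restore(Sim& sim, List snap) {
  List alleles = snap["alleles"];
  List hl = snap["haplotypes"];
  const int R = alleles.size();
  if ((int)hl.size() != 2 * sim.cfg.N)
    stop("snapshot has %d haplotypes but config expects %d",
         (int)hl.size(), 2 * sim.cfg.N);
  sim.reg.clear();
  sim.off.clear();
  sim.tot = 0;
  std::map<int, int> id2idx;
  for (int a = 0; a < R; ++a) {
    List e = alleles[a];
    Allele al;
    al.id = as<int>(e["id"]);
    al.birth = as<int>(e["birth"]);
    IntegerVector pos = e["loci"];
    NumericVector y = e["affinities"];
    if (pos.size() != y.size())
      stop("allele %d: loci/affinities length mismatch", al.id);
    al.resize((int)pos.size());
    for (int j = 1; j < (int)pos.size(); ++j)
      if (pos[j] <= pos[j - 1])
        stop("allele %d: loci must be strictly increasing", al.id);
    for (int j = 0; j < (int)pos.size(); ++j) {
      int p = pos[j] - 1;
      if (p < 0 || p >= sim.cfg.L) stop("allele locus outside [1, L]");
      if (sim.slot_used[p]) stop("overlapping target slots in snapshot");
      sim.slot_used[p] = 1;
      ++sim.used_count;
      al.pos[j] = p;
      al.y[j] = y[j];
      al.set_occupancy(j, sim.cfg.c_hom);
    }
    id2idx[al.id] = a;
    sim.next_id = std::max(sim.next_id, al.id + 1);
    sim.off.push_back(sim.tot);
    sim.tot += al.size();
    sim.reg.push_back(std::move(al));
  }
  if (snap.containsElementNamed("next_id"))
    sim.next_id = std::max(sim.next_id, as<int>(snap["next_id"]));
  if (snap.containsElementNamed("generation"))
    sim.gen = as<int>(snap["generation"]);
  sim.haps.assign(2 * sim.cfg.N, Hap{0, {}});
  for (int i = 0; i < (int)hl.size(); ++i) {
    List e = hl[i];
    const int id = as<int>(e["allele"]);
    auto it = id2idx.find(id);
    if (it == id2idx.end()) stop("haplotype carries unregistered allele id %d", id);
    Hap& hp = sim.haps[i];
    hp.al = it->second;
    List inact = e["inactive"];
    if (inact.size() != R) stop("haplotype inactive-state list length mismatch");
    hp.act.assign(sim.tot, 1);
    for (int a = 0; a < R; ++a) {
      IntegerVector idx = inact[a];
      for (int j : idx) {
        if (j < 1 || j > sim.reg[a].size())
          stop("inactive site index out of range");
        hp.act[sim.off[a] + j - 1] = 0;
      }
    }
  }
  for (auto& a : sim.reg) a.carriers = 0;
  for (auto& hp : sim.haps) ++sim.reg[hp.al].carriers;
  sim.reserve_scratch();
}

// [[Rcpp::export(rng = false)]]
List rq_run_cpp(List cfg, Nullable<List> init = R_NilValue,
                bool return_population = false) {
  Config c = parse_config(cfg);
  Sim sim(c);
  if (init.isNotNull()) restore(sim, init.get());
  else sim.init_monomorphic();
  sim.run();

  DataFrame traj = DataFrame::create(
    _["generation"] = sim.tr_gen, _["allele_id"] = sim.tr_id,
    _["f"] = sim.tr_f, _["theta"] = sim.tr_theta,
    _["mean_affinity"] = sim.tr_aff, _["q"] = sim.tr_q, _["w"] = sim.tr_w);
  DataFrame scalars = DataFrame::create(
    _["generation"] = sim.sc_gen, _["n_alleles"] = sim.sc_nal,
    _["D"] = sim.sc_D, _["theta_bar"] = sim.sc_theta, _["q_bar"] = sim.sc_q,
    _["w_bar"] = sim.sc_w, _["sigma_bar"] = sim.sc_sigma,
    _["success_rate"] = sim.sc_succ);
  DataFrame s0 = DataFrame::create(_["generation"] = sim.s0_gen,
                                   _["s0"] = sim.s0_val);
  List out = List::create(
    _["trajectory"] = traj, _["scalars"] = scalars, _["s0"] = s0,
    _["counters"] = List::create(
      _["attempts"] = (double)sim.n_attempts,
      _["successes"] = (double)sim.n_success,
      _["no_binding"] = (double)sim.n_no_binding,
      _["no_symmetric_dsb"] = (double)sim.n_no_sym,
      _["no_dsb"] = (double)sim.n_no_dsb));
  if (return_population) out["population"] = snapshot(sim);
  return out;
}

// Build a two-haplotype fixture world and run repeated meiosis attempts on it.
// genotype: list(alleles = list(list(loci, affinities)...),
//                hap_a = list(allele = <1-based index>, active = list(<logical>...)),
//                hap_b = likewise), prdm9_slot optional.
// [[Rcpp::export(rng = false)]]
List rq_meiosis_cpp(List genotype, double d, double c_hom, bool symmetry,
                    int n, double seed, int trace = 0) {
  List alleles = genotype["alleles"];
  const int R = alleles.size();
  int maxpos = 1;
  for (int a = 0; a < R; ++a) {
    IntegerVector pos = as<List>(alleles[a])["loci"];
    for (int p : pos) maxpos = std::max(maxpos, p);
  }
  int prdm9_slot = genotype.containsElementNamed("prdm9_slot")
    ? as<int>(genotype["prdm9_slot"]) : maxpos + 1;
  maxpos = std::max(maxpos, prdm9_slot);

  Config c;
  c.N = 1; c.u = 0; c.v = 0;
  c.h = 1;
  c.d = d; c.ybar = 1.0; c.c_hom = c_hom; c.n_mei = 1;
  c.symmetry = symmetry; c.generations = 0; c.burn_in = 0;
  c.L = maxpos + 1; c.prdm9_slot = prdm9_slot - 1;
  c.record_every = 1; c.s0_every = 0; c.s0_probes = 1;
  c.seed = (uint64_t)seed;
  Sim sim(c);

  for (int a = 0; a < R; ++a) {
    List e = alleles[a];
    IntegerVector pos = e["loci"];
    NumericVector y = e["affinities"];
    if (pos.size() != y.size()) stop("loci/affinities length mismatch");
    Allele al;
    al.id = a; al.birth = 0;
    al.resize((int)pos.size());
    for (int j = 1; j < (int)pos.size(); ++j)
      if (pos[j] <= pos[j - 1]) stop("loci must be strictly increasing");
    for (int j = 0; j < (int)pos.size(); ++j) {
      al.pos[j] = pos[j] - 1;
      al.y[j] = y[j];
      al.set_occupancy(j, c_hom);
    }
    sim.off.push_back(sim.tot);
    sim.tot += al.size();
    sim.reg.push_back(std::move(al));
  }
  sim.next_id = R;
  sim.reserve_scratch();

  auto build_hap = [&](List spec) {
    Hap hp;
    hp.al = as<int>(spec["allele"]) - 1;
    if (hp.al < 0 || hp.al >= R) stop("hap allele index out of range");
    List act = spec["active"];
    if ((int)act.size() != R)
      stop("active-state list must have one entry per allele");
    hp.act.assign(sim.tot, 1);
    for (int a = 0; a < R; ++a) {
      LogicalVector v = act[a];
      if ((int)v.size() != sim.reg[a].size())
        stop("active vector length mismatch for allele %d", a + 1);
      for (int j = 0; j < (int)v.size(); ++j)
        hp.act[sim.off[a] + j] = v[j] ? 1 : 0;
    }
    return hp;
  };
  sim.haps.clear();
  sim.haps.push_back(build_hap(genotype["hap_a"]));
  sim.haps.push_back(build_hap(genotype["hap_b"]));

  int succ = 0;
  double ksum = 0, dsum = 0, ssum = 0;
  List traces(trace);
  for (int i = 0; i < n; ++i) {
    MeiOut out = sim.meiosis(0, 1, i < trace);
    if (out.success) ++succ;
    ksum += out.k; dsum += out.ndsb; ssum += out.nsym;
    if (i < trace) {
      List gam = R_NilValue;
      if (out.success) {
        List inact(R);
        for (int a = 0; a < R; ++a) {
          std::vector<int> idx;
          for (int j = 0; j < sim.reg[a].size(); ++j)
            if (!out.gam.act[sim.off[a] + j]) idx.push_back(j + 1);
          inact[a] = IntegerVector(idx.begin(), idx.end());
        }
        gam = List::create(_["allele"] = out.gam.al + 1, _["inactive"] = inact);
      }
      const char* reasons[] = {"ok", "no_binding", "no_symmetric_dsb", "no_dsb"};
      traces[i] = List::create(
        _["success"] = out.success,
        _["failure_reason"] = std::string(reasons[out.reason]),
        _["n_bound"] = out.k, _["n_dsb"] = out.ndsb,
        _["n_symmetric"] = out.nsym,
        _["co_allele"] = out.co_a >= 0 ? out.co_a + 1 : NA_INTEGER,
        _["co_site"] = out.co_j >= 0 ? out.co_j + 1 : NA_INTEGER,
        _["co_chromatid"] = out.co_t >= 0 ? out.co_t + 1 : NA_INTEGER,
        _["partner_chromatid"] = out.partner_t >= 0 ? out.partner_t + 1 : NA_INTEGER,
        _["gamete"] = gam);
    }
  }
  return List::create(
    _["attempts"] = n, _["successes"] = succ,
    _["no_binding"] = (double)sim.n_no_binding,
    _["no_symmetric_dsb"] = (double)sim.n_no_sym,
    _["no_dsb"] = (double)sim.n_no_dsb,
    _["mean_bound"] = n > 0 ? ksum / n : NA_REAL,
    _["mean_dsb"] = n > 0 ? dsum / n : NA_REAL,
    _["mean_symmetric"] = n > 0 ? ssum / n : NA_REAL,
    _["traces"] = traces);
}
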