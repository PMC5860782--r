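// Network-free stochastic simulator for multi-site protein assembly.
//
// Molecules are typed site-graphs; complexes are connected components of the
// bond graph, materialized lazily as they form (the species space of
// multi-site assembly is combinatorial, so no reaction network is ever
// enumerated).  Bimolecular rules join sites in *distinct* complexes, so
// aggregates are acyclic unless explicit intra-complex ring-closure rules
// are enabled (cooperative closure of correct trimers).
//
// Two compartments: cytosol and plasma membrane.  A complex is
// membrane-associated iff it contains a lipid.  Lipids are a pooled
// membrane population; a lipid molecule is materialized when bound and
// dissolved back into the pool when released.  Every bimolecular rule has a
// base (3D) rate applying to all reactant pairs plus an extra rate applied
// when both partners are membrane-associated, implementing the 2D rate
// enhancement KD_2D = KD_3D / (2 sigma).
//
// Vesicle completion: any membrane complex holding at least `threshold`
// "full" molecules of the designated type (all sites of a designated site
// class bound; for clathrin, a triskelion carrying all three light chains)
// is deleted at rate k_dump; its proteins re-enter the cytosol one at a
// time at rate k_recyc and its lipids return to the membrane pool.
//
// Reactant pairs are drawn from global free-site pools; draws landing in a
// single molecule or complex are exact null events (self-loop transitions
// of the chain) and are discarded.  Complex membership uses intrusive
// doubly-linked member lists, and splits locate the smaller fragment by
// bidirectional search, so the cost of an event scales with the smaller
// fragment, not the aggregate.

#include <Rcpp.h>
#include <random>
#include <vector>
#include <array>
#include <cstdint>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

namespace {

struct Fenw {
  int n = 0;
  std::vector<double> t;
  void init(int n_) { n = n_; t.assign(n_ + 1, 0.0); }
  void add(int i, double d) { for (++i; i <= n; i += i & -i) t[i] += d; }
  double total() const {
    double s = 0; for (int i = n; i > 0; i -= i & -i) s += t[i]; return s;
  }
  int find(double u) const {
    int pos = 0, logn = 1;
    while ((1 << logn) <= n) ++logn;
    for (int pw = 1 << (logn - 1); pw > 0; pw >>= 1)
      if (pos + pw <= n && t[pos + pw] <= u) { pos += pw; u -= t[pos]; }
    return pos;
  }
};

struct SiteRef { int mol, site; };

struct Site {
  int cls = -1;
  int pmol = -1, psite = -1;   // bound partner
  int rule = -1, bidx = -1;    // bond bookkeeping (valid when bound)
  int pool = -1, pidx = -1;    // free-site pool membership
};

struct Mol {
  int type = -1, comp = -1;
  int next = -1, prev = -1;    // intrusive complex member list
  bool alive = false, queued = false, ever_mem = false;
  int full_bound = 0;
  std::vector<Site> sites;
};

struct Bond { int ma, sa, mb, sb; };
struct RingEnt { int ma, sa, mb, sb, comp; };

struct Cplx {
  int head = -1, size = 0;
  int n_lipid = 0, n_full = 0, n_bonds = 0;
  int n_ring = 0;                // ring-closure entries owned by this complex
  bool alive = false;
  int qual = -1;
  bool mem() const { return n_lipid > 0; }
};

struct Engine {
  // model ----------------------------------------------------------------
  int n_types = 0, n_classes = 0, n_rules = 0;
  std::vector<std::vector<int>> type_sites;  // class id per site, per type
  int lipid_type = -1;
  double lipid_pool = 0;
  std::vector<int> r_ca, r_cb;               // cb = -1: lipid pool partner
  std::vector<double> r_kon, r_extra, r_koff, r_ring;
  std::vector<char> r_specific, r_poly;
  std::vector<int> lipid_rules;
  int ves_type = -1, ves_cls = -1, ves_threshold = -1;
  double k_dump = 0, k_recyc = 0;
  // ring closure is only evaluated for complexes up to this size: the
  // cooperative trimer closures it implements concern near-native complexes,
  // and the eligibility scan is quadratic in complex size
  int ring_cap = 16;
  bool any_ring = false;

  // state ----------------------------------------------------------------
  std::vector<Mol> mols;
  std::vector<int> free_mols;
  std::vector<Cplx> cplx;
  std::vector<int> free_cplx;
  std::vector<std::array<std::vector<SiteRef>, 2>> pools;  // [class][cyt|mem]
  std::vector<std::vector<Bond>> bonds;
  std::vector<std::vector<RingEnt>> rings;
  std::vector<int> qual;                      // dump-qualified complex ids
  std::vector<int> queue;                     // molecules awaiting recycle
  std::vector<std::vector<int>> rules_of_cls;
  Fenw fw;
  std::vector<double> cur;
  std::mt19937_64 rng;
  double t = 0, n_null = 0, n_events = 0;

  // outputs --------------------------------------------------------------
  std::vector<double> ves_time;
  std::vector<std::vector<int>> ves_comp;
  std::vector<int> ves_full;
  double adaptor_first = 0, poly_first = 0;

  double runif() {
    return std::uniform_real_distribution<double>(0.0, 1.0)(rng);
  }
  int rint(int n) {
    return std::uniform_int_distribution<int>(0, n - 1)(rng);
  }

  // --- member list -------------------------------------------------------
  void link_member(int c, int m) {
    Mol& M = mols[m];
    M.comp = c;
    M.prev = -1;
    M.next = cplx[c].head;
    if (cplx[c].head >= 0) mols[cplx[c].head].prev = m;
    cplx[c].head = m;
    cplx[c].size += 1;
  }
  void unlink_member(int c, int m) {
    Mol& M = mols[m];
    if (M.prev >= 0) mols[M.prev].next = M.next; else cplx[c].head = M.next;
    if (M.next >= 0) mols[M.next].prev = M.prev;
    M.prev = M.next = -1;
    cplx[c].size -= 1;
  }

  // --- free-site pools ---------------------------------------------------
  void pool_add(int m, int s) {
    Mol& M = mols[m];
    int k = cplx[M.comp].mem() ? 1 : 0;
    auto& v = pools[M.sites[s].cls][k];
    M.sites[s].pool = k;
    M.sites[s].pidx = (int)v.size();
    v.push_back({m, s});
    mark_cls(M.sites[s].cls);
  }
  void pool_rm(int m, int s) {
    Site& S = mols[m].sites[s];
    auto& v = pools[S.cls][S.pool];
    int i = S.pidx;
    v[i] = v.back();
    mols[v[i].mol].sites[v[i].site].pidx = i;
    v.pop_back();
    mark_cls(S.cls);
    S.pool = -1; S.pidx = -1;
  }
  // move the free sites of molecule m into compartment k
  void pool_move(int m, int k) {
    Mol& M = mols[m];
    for (int s = 0; s < (int)M.sites.size(); ++s) {
      Site& S = M.sites[s];
      if (S.pool < 0 || S.pool == k) continue;
      auto& from = pools[S.cls][S.pool];
      int i = S.pidx;
      from[i] = from.back();
      mols[from[i].mol].sites[from[i].site].pidx = i;
      from.pop_back();
      auto& to = pools[S.cls][k];
      S.pool = k; S.pidx = (int)to.size();
      to.push_back({m, s});
      mark_cls(S.cls);
    }
  }

  // --- propensities ------------------------------------------------------
  std::vector<char> dirty;
  std::vector<int> dirty_list;
  bool all_dirty = false;
  void mark_rule(int r) {
    if (all_dirty || dirty[r]) return;
    dirty[r] = 1; dirty_list.push_back(r);
  }
  void mark_cls(int c) {
    if (all_dirty) return;
    for (int r : rules_of_cls[c]) mark_rule(r);
  }
  void mark_lipid_rules() { for (int r : lipid_rules) mark_rule(r); }
  void set_entry(int e, double p) {
    if (p != cur[e]) { fw.add(e, p - cur[e]); cur[e] = p; }
  }
  double cls_n(int c, int k) const { return (double)pools[c][k].size(); }
  void refresh_rule(int r) {
    double na0 = cls_n(r_ca[r], 0), na1 = cls_n(r_ca[r], 1);
    double base, extra;
    if (r_cb[r] < 0) {
      base = r_kon[r] * (na0 + na1) * lipid_pool;
      extra = r_extra[r] * na1 * lipid_pool;
    } else if (r_cb[r] == r_ca[r]) {
      double n = na0 + na1;
      base = r_kon[r] * n * (n - 1.0) * 0.5;
      extra = r_extra[r] * na1 * (na1 - 1.0) * 0.5;
    } else {
      double nb0 = cls_n(r_cb[r], 0), nb1 = cls_n(r_cb[r], 1);
      base = r_kon[r] * (na0 + na1) * (nb0 + nb1);
      extra = r_extra[r] * na1 * nb1;
    }
    set_entry(r, base);
    set_entry(n_rules + r, extra);
    set_entry(2 * n_rules + r, r_koff[r] * (double)bonds[r].size());
    set_entry(3 * n_rules + r, r_ring[r] * (double)rings[r].size());
  }
  void flush_dirty() {
    if (all_dirty) {
      for (int r = 0; r < n_rules; ++r) refresh_rule(r);
      all_dirty = false;
      for (int r : dirty_list) dirty[r] = 0;
      dirty_list.clear();
    } else if (!dirty_list.empty()) {
      for (int r : dirty_list) { refresh_rule(r); dirty[r] = 0; }
      dirty_list.clear();
    }
    set_entry(4 * n_rules, k_dump * (double)qual.size());
    set_entry(4 * n_rules + 1, k_recyc * (double)queue.size());
  }

  // --- vesicle qualification ---------------------------------------------
  void update_qual(int c) {
    Cplx& C = cplx[c];
    bool q = C.alive && ves_threshold > 0 && C.mem() &&
             C.n_full >= ves_threshold;
    if (q && C.qual < 0) {
      C.qual = (int)qual.size();
      qual.push_back(c);
    } else if (!q && C.qual >= 0) {
      int i = C.qual;
      qual[i] = qual.back();
      cplx[qual[i]].qual = i;
      qual.pop_back();
      C.qual = -1;
    }
  }

  // --- allocation --------------------------------------------------------
  int new_cplx() {
    int c;
    if (!free_cplx.empty()) { c = free_cplx.back(); free_cplx.pop_back(); }
    else { c = (int)cplx.size(); cplx.emplace_back(); }
    cplx[c] = Cplx();
    cplx[c].alive = true;
    return c;
  }
  void drop_cplx(int c) {
    cplx[c].alive = false;
    update_qual(c);
    clear_rings(c);
    cplx[c].head = -1;
    cplx[c].size = 0;
    free_cplx.push_back(c);
  }
  int new_mol(int type) {
    int m;
    if (!free_mols.empty()) { m = free_mols.back(); free_mols.pop_back(); }
    else { m = (int)mols.size(); mols.emplace_back(); }
    Mol& M = mols[m];
    M = Mol();
    M.type = type;
    M.alive = true;
    M.sites.resize(type_sites[type].size());
    for (size_t s = 0; s < M.sites.size(); ++s)
      M.sites[s].cls = type_sites[type][s];
    return m;
  }

  // --- ring-closure eligibility -------------------------------------------
  // Entries are indexed only by owning complex; clearing scans the (small)
  // global ring lists, so no per-entry backreferences are needed.
  void clear_rings(int c) {
    if (!any_ring || cplx[c].n_ring == 0) return;
    for (int r = 0; r < n_rules; ++r) {
      if (r_ring[r] <= 0) continue;
      auto& v = rings[r];
      size_t i = 0;
      bool changed = false;
      while (i < v.size()) {
        if (v[i].comp == c) { v[i] = v.back(); v.pop_back(); changed = true; }
        else ++i;
      }
      if (changed) mark_rule(r);
    }
    cplx[c].n_ring = 0;
  }
  bool share_bonded_neighbor(int u, int v) {
    for (auto& su : mols[u].sites) {
      if (su.pmol < 0 || su.pmol == v) continue;
      for (auto& sv : mols[v].sites)
        if (sv.pmol == su.pmol) return true;
    }
    return false;
  }
  void recompute_rings(int c) {
    if (!cplx[c].alive) return;
    clear_rings(c);
    if (!any_ring) return;
    Cplx& C = cplx[c];
    if (C.size > ring_cap || C.size < 3) return;
    std::vector<int> mem;
    mem.reserve(C.size);
    for (int m = C.head; m >= 0; m = mols[m].next) mem.push_back(m);
    for (int r = 0; r < n_rules; ++r) {
      if (r_ring[r] <= 0) continue;
      for (size_t iu = 0; iu < mem.size(); ++iu)
        for (size_t iv = 0; iv < mem.size(); ++iv) {
          if (iu == iv) continue;
          if (r_ca[r] == r_cb[r] && iu > iv) continue;
          int u = mem[iu], v = mem[iv];
          if (!share_bonded_neighbor(u, v)) continue;
          bool done = false;
          for (int su = 0; su < (int)mols[u].sites.size() && !done; ++su) {
            Site& SU = mols[u].sites[su];
            if (SU.cls != r_ca[r] || SU.pmol >= 0) continue;
            for (int sv = 0; sv < (int)mols[v].sites.size(); ++sv) {
              Site& SV = mols[v].sites[sv];
              if (SV.cls != r_cb[r] || SV.pmol >= 0) continue;
              rings[r].push_back({u, su, v, sv, c});
              cplx[c].n_ring += 1;
              mark_rule(r);
              done = true;  // one eligible pair per molecule pair per rule
              break;
            }
          }
        }
    }
  }

  // --- triskelion completeness tracking ------------------------------------
  // only specific bonds (e.g. a real light-chain association) advance a
  // molecule toward "full"; a misinteraction occupying the site does not
  void note_bind(int m, int s, int delta, int rule) {
    Mol& M = mols[m];
    if (!r_specific[rule]) return;
    if (M.type != ves_type || ves_cls < 0 || M.sites[s].cls != ves_cls) return;
    int tot = 0;
    for (auto& st : M.sites) if (st.cls == ves_cls) ++tot;
    bool was_full = (M.full_bound == tot);
    M.full_bound += delta;
    bool is_full = (M.full_bound == tot);
    if (was_full != is_full) {
      cplx[M.comp].n_full += is_full ? 1 : -1;
      update_qual(M.comp);
    }
  }

  // --- membrane-arrival attribution ----------------------------------------
  void attribute_mem(int c, int rule) {
    if (ves_type < 0) return;
    for (int m = cplx[c].head; m >= 0; m = mols[m].next) {
      Mol& M = mols[m];
      if (M.type != ves_type || M.ever_mem) continue;
      M.ever_mem = true;
      if (r_poly[rule]) ++poly_first; else ++adaptor_first;
    }
  }

  // --- bond creation --------------------------------------------------------
  void merge_into(int keep, int lose, int rule) {
    Cplx& K = cplx[keep];
    Cplx& L = cplx[lose];
    bool mem_new = K.mem() || L.mem();
    bool k_changed = (K.mem() != mem_new);
    bool l_changed = (L.mem() != mem_new);
    if (mem_new && l_changed) attribute_mem(lose, rule);
    if (mem_new && k_changed) attribute_mem(keep, rule);
    if (k_changed)
      for (int m = K.head; m >= 0; m = mols[m].next)
        pool_move(m, mem_new ? 1 : 0);
    K.n_lipid += L.n_lipid;
    K.n_full += L.n_full;
    K.n_bonds += L.n_bonds;
    // concat member lists; reassign comp on the losing (smaller) side
    int tail = -1;
    for (int m = L.head; m >= 0; m = mols[m].next) {
      mols[m].comp = keep;
      if (l_changed) pool_move(m, mem_new ? 1 : 0);
      tail = m;
    }
    if (tail >= 0) {
      mols[tail].next = K.head;
      if (K.head >= 0) mols[K.head].prev = tail;
      K.head = L.head;
      K.size += L.size;
    }
    L.head = -1; L.size = 0; L.n_lipid = 0; L.n_full = 0; L.n_bonds = 0;
    drop_cplx(lose);
    update_qual(keep);
  }

  void form_bond(int r, int ma, int sa, int mb, int sb, bool intra) {
    if (mols[ma].sites[sa].pool >= 0) pool_rm(ma, sa);
    if (mols[mb].sites[sb].pool >= 0) pool_rm(mb, sb);
    {
      Site& A = mols[ma].sites[sa];
      Site& B = mols[mb].sites[sb];
      A.pmol = mb; A.psite = sb; A.rule = r; A.bidx = (int)bonds[r].size();
      B.pmol = ma; B.psite = sa; B.rule = r; B.bidx = (int)bonds[r].size();
    }
    bonds[r].push_back({ma, sa, mb, sb});
    mark_rule(r);
    note_bind(ma, sa, +1, r);
    note_bind(mb, sb, +1, r);
    int ca = mols[ma].comp, cb = mols[mb].comp;
    if (intra) {
      cplx[ca].n_bonds += 1;
      if (any_ring) recompute_rings(ca);
      return;
    }
    int keep = ca, lose = cb;
    if (cplx[keep].size < cplx[lose].size) std::swap(keep, lose);
    cplx[keep].n_bonds += 1;  // the new bond itself
    merge_into(keep, lose, r);
    if (any_ring) recompute_rings(keep);
  }

  void remove_bond_entry(int r, int bi) {
    int last = (int)bonds[r].size() - 1;
    bonds[r][bi] = bonds[r][last];
    if (bi != last) {
      Bond& mv = bonds[r][bi];
      mols[mv.ma].sites[mv.sa].bidx = bi;
      mols[mv.mb].sites[mv.sb].bidx = bi;
    }
    bonds[r].pop_back();
    mark_rule(r);
  }

  // --- split detection: bidirectional search --------------------------------
  std::vector<int> markA, markB;
  int epoch = 0;
  std::vector<int> outA, outB;
  // after removing a bond between ma and mb: 0 = still connected,
  // 1 = component of ma is in outA, 2 = component of mb is in outB
  int bi_component(int ma, int mb) {
    if ((int)markA.size() < (int)mols.size()) {
      markA.resize(mols.size(), 0);
      markB.resize(mols.size(), 0);
    }
    ++epoch;
    outA.clear(); outB.clear();
    outA.push_back(ma); markA[ma] = epoch;
    outB.push_back(mb); markB[mb] = epoch;
    size_t ha = 0, hb = 0;
    while (true) {
      if (ha < outA.size()) {
        int u = outA[ha++];
        for (auto& S : mols[u].sites) {
          if (S.pmol < 0) continue;
          int w = S.pmol;
          if (markB[w] == epoch) return 0;
          if (markA[w] != epoch) { markA[w] = epoch; outA.push_back(w); }
        }
      } else return 1;
      if (hb < outB.size()) {
        int u = outB[hb++];
        for (auto& S : mols[u].sites) {
          if (S.pmol < 0) continue;
          int w = S.pmol;
          if (markA[w] == epoch) return 0;
          if (markB[w] != epoch) { markB[w] = epoch; outB.push_back(w); }
        }
      } else return 2;
    }
  }

  void dissolve_lipid(int m) {
    Mol& M = mols[m];
    int c = M.comp;
    for (int s = 0; s < (int)M.sites.size(); ++s)
      if (M.sites[s].pool >= 0) pool_rm(m, s);
    unlink_member(c, m);
    M.alive = false;
    free_mols.push_back(m);
    lipid_pool += 1;
    mark_lipid_rules();
    if (cplx[c].size == 0) drop_cplx(c);
  }

  void break_bond(int r, int bi) {
    Bond b = bonds[r][bi];
    remove_bond_entry(r, bi);
    {
      Site& A = mols[b.ma].sites[b.sa];
      Site& B = mols[b.mb].sites[b.sb];
      A.pmol = -1; A.psite = -1; A.rule = -1; A.bidx = -1;
      B.pmol = -1; B.psite = -1; B.rule = -1; B.bidx = -1;
    }
    note_bind(b.ma, b.sa, -1, r);
    note_bind(b.mb, b.sb, -1, r);
    int c = mols[b.ma].comp;
    cplx[c].n_bonds -= 1;
    int side = bi_component(b.ma, b.mb);
    if (side == 0) {
      pool_add(b.ma, b.sa);
      pool_add(b.mb, b.sb);
      finish_break(b, c, c);
      if (any_ring) recompute_rings(c);
      return;
    }
    std::vector<int>& small = (side == 1) ? outA : outB;
    Cplx& C = cplx[c];
    bool old_mem = C.mem();
    // move the detected fragment into a fresh complex
    int c2 = new_cplx();
    int s_lipid = 0, s_full = 0, s_bonds = 0;
    for (int m : small) {
      Mol& M = mols[m];
      unlink_member(c, m);
      link_member(c2, m);
      if (M.type == lipid_type) ++s_lipid;
      if (M.type == ves_type && ves_cls >= 0) {
        int tot = 0;
        for (auto& st : M.sites) if (st.cls == ves_cls) ++tot;
        if (tot > 0 && M.full_bound == tot) ++s_full;
      }
      for (auto& st : M.sites)
        if (st.pmol >= 0 && st.pmol > m) ++s_bonds;
    }
    Cplx& C2 = cplx[c2];
    C2.n_lipid = s_lipid; C2.n_full = s_full; C2.n_bonds = s_bonds;
    C.n_lipid -= s_lipid; C.n_full -= s_full; C.n_bonds -= s_bonds;
    if (C.mem() != old_mem)
      for (int m = C.head; m >= 0; m = mols[m].next)
        pool_move(m, C.mem() ? 1 : 0);
    if (C2.mem() != old_mem)
      for (int m = C2.head; m >= 0; m = mols[m].next)
        pool_move(m, C2.mem() ? 1 : 0);
    pool_add(b.ma, b.sa);
    pool_add(b.mb, b.sb);
    update_qual(c);
    update_qual(c2);
    finish_break(b, c, c2);
    if (any_ring) {
      recompute_rings(c);
      recompute_rings(c2);
    }
  }

  void finish_break(const Bond& b, int ca, int cb) {
    (void)ca; (void)cb;
    if (lipid_type < 0) return;
    if (mols[b.ma].alive && mols[b.ma].type == lipid_type &&
        cplx[mols[b.ma].comp].size == 1)
      dissolve_lipid(b.ma);
    if (mols[b.mb].alive && mols[b.mb].type == lipid_type &&
        cplx[mols[b.mb].comp].size == 1)
      dissolve_lipid(b.mb);
  }

  // --- vesicle dump / recycle -----------------------------------------------
  void dump_complex(int c) {
    Cplx& C = cplx[c];
    std::vector<int> comp_counts(n_types, 0);
    std::vector<int> members;
    members.reserve(C.size);
    for (int m = C.head; m >= 0; m = mols[m].next) {
      comp_counts[mols[m].type] += 1;
      members.push_back(m);
    }
    ves_time.push_back(t);
    ves_comp.push_back(comp_counts);
    ves_full.push_back(C.n_full);
    for (int m : members) {
      Mol& M = mols[m];
      for (int s = 0; s < (int)M.sites.size(); ++s) {
        Site& S = M.sites[s];
        if (S.pool >= 0) pool_rm(m, s);
        if (S.pmol >= 0) {
          if (S.pmol > m) remove_bond_entry(S.rule, S.bidx);
          S.pmol = -1; S.psite = -1; S.rule = -1; S.bidx = -1;
        }
      }
      M.full_bound = 0;
      M.prev = M.next = -1;
      if (M.type == lipid_type) {
        M.alive = false;
        free_mols.push_back(m);
        lipid_pool += 1;
      } else {
        M.queued = true;
        M.comp = -1;
        queue.push_back(m);
      }
    }
    mark_lipid_rules();
    C.head = -1; C.size = 0;
    C.n_lipid = 0; C.n_full = 0; C.n_bonds = 0;
    drop_cplx(c);
  }

  void recycle_one() {
    int i = rint((int)queue.size());
    int m = queue[i];
    queue[i] = queue.back();
    queue.pop_back();
    Mol& M = mols[m];
    M.queued = false;
    int c = new_cplx();
    link_member(c, m);
    for (int s = 0; s < (int)M.sites.size(); ++s) pool_add(m, s);
  }

  // --- sampling ---------------------------------------------------------------
  bool sample_site(int c, int scope, SiteRef& out) {
    int k = scope;  // 0 cytosol, 1 membrane, 2 either (count-weighted)
    if (scope == 2) {
      double n0 = cls_n(c, 0), n1 = cls_n(c, 1);
      double tot = n0 + n1;
      if (tot <= 0) return false;
      k = (runif() * tot < n0) ? 0 : 1;
      if (pools[c][k].empty()) k = 1 - k;
    }
    if (pools[c][k].empty()) return false;
    out = pools[c][k][rint((int)pools[c][k].size())];
    return true;
  }

  void fire_bind(int r, bool mem_only) {
    int scope = mem_only ? 1 : 2;
    SiteRef a;
    if (!sample_site(r_ca[r], scope, a)) { ++n_null; return; }
    if (r_cb[r] < 0) {  // pooled lipid partner
      if (lipid_pool < 1) { ++n_null; return; }
      int lm = new_mol(lipid_type);
      lipid_pool -= 1;
      mark_lipid_rules();
      int lc = new_cplx();
      link_member(lc, lm);
      cplx[lc].n_lipid = 1;
      form_bond(r, a.mol, a.site, lm, 0, false);
      return;
    }
    SiteRef b;
    if (r_cb[r] == r_ca[r]) {
      // uniform unordered distinct-site pair within the class
      int guard = 0;
      do {
        if (!sample_site(r_cb[r], scope, b)) { ++n_null; return; }
        if (++guard > 64) { ++n_null; return; }
      } while (b.mol == a.mol && b.site == a.site);
    } else {
      if (!sample_site(r_cb[r], scope, b)) { ++n_null; return; }
    }
    if (a.mol == b.mol || mols[a.mol].comp == mols[b.mol].comp) {
      ++n_null;
      return;
    }
    form_bond(r, a.mol, a.site, b.mol, b.site, false);
  }

  void fire_ring(int r) {
    if (rings[r].empty()) { ++n_null; return; }
    RingEnt e = rings[r][rint((int)rings[r].size())];
    Site& A = mols[e.ma].sites[e.sa];
    Site& B = mols[e.mb].sites[e.sb];
    if (A.pmol >= 0 || B.pmol >= 0 ||
        mols[e.ma].comp != mols[e.mb].comp) { ++n_null; return; }
    form_bond(r, e.ma, e.sa, e.mb, e.sb, true);
  }

  // --- main loop ----------------------------------------------------------
  void run(double t_end, double max_events) {
    all_dirty = true;
    flush_dirty();
    double rebuild_at = 1e6;
    while (t < t_end && n_events < max_events) {
      double a0 = fw.total();
      if (a0 <= 1e-300) break;
      t += -std::log(std::max(runif(), 1e-300)) / a0;
      if (t > t_end) break;
      double u = runif() * a0;
      int e = fw.find(u);
      if (e >= 4 * n_rules + 2) e = 4 * n_rules + 1;
      if (e < n_rules) fire_bind(e, false);
      else if (e < 2 * n_rules) fire_bind(e - n_rules, true);
      else if (e < 3 * n_rules) {
        int r = e - 2 * n_rules;
        if (bonds[r].empty()) ++n_null;
        else break_bond(r, rint((int)bonds[r].size()));
      } else if (e < 4 * n_rules) fire_ring(e - 3 * n_rules);
      else if (e == 4 * n_rules) {
        if (qual.empty()) ++n_null;
        else dump_complex(qual[rint((int)qual.size())]);
      } else {
        if (queue.empty()) ++n_null;
        else recycle_one();
      }
      flush_dirty();
      n_events += 1;
      if (n_events >= rebuild_at) {  // guard against FP drift in the tree
        all_dirty = true;
        flush_dirty();
        rebuild_at += 1e6;
      }
    }
  }
};

}  // namespace

// [[Rcpp::export]]
List rulesim_cpp(List types, List rules, List vesicle,
                 double t_end, double max_events, int seed,
                 bool census = true) {
  Engine E;
  CharacterVector tnames = types["name"];
  List tclasses = types["site_class"];
  IntegerVector tcopies = types["copies"];
  IntegerVector tlipid = types["is_lipid"];
  E.n_types = tnames.size();
  E.n_classes = as<int>(types["n_classes"]);
  E.type_sites.resize(E.n_types);
  for (int i = 0; i < E.n_types; ++i) {
    IntegerVector sc = tclasses[i];
    E.type_sites[i].assign(sc.begin(), sc.end());
    if (tlipid[i]) {
      if (sc.size() != 1) stop("lipid type must have exactly one site");
      E.lipid_type = i;
      E.lipid_pool = tcopies[i];
    }
  }
  IntegerVector ca = rules["class_a"], cb = rules["class_b"];
  NumericVector kon = rules["kon"], extra = rules["kon_extra"],
                koff = rules["koff"], ringr = rules["ring_rate"];
  IntegerVector rspec = rules["specific"], rpoly = rules["poly"];
  E.n_rules = ca.size();
  E.r_ca.assign(ca.begin(), ca.end());
  E.r_cb.assign(cb.begin(), cb.end());
  E.r_kon.assign(kon.begin(), kon.end());
  E.r_extra.assign(extra.begin(), extra.end());
  E.r_koff.assign(koff.begin(), koff.end());
  E.r_ring.assign(ringr.begin(), ringr.end());
  E.r_specific.resize(E.n_rules);
  E.r_poly.resize(E.n_rules);
  for (int r = 0; r < E.n_rules; ++r) {
    E.r_specific[r] = (char)rspec[r];
    E.r_poly[r] = (char)rpoly[r];
    if (E.r_ring[r] > 0) E.any_ring = true;
    if (E.r_cb[r] < 0) E.lipid_rules.push_back(r);
  }
  E.ves_type = as<int>(vesicle["type"]);
  E.ves_cls = as<int>(vesicle["full_class"]);
  E.ves_threshold = as<int>(vesicle["threshold"]);
  E.k_dump = as<double>(vesicle["k_dump"]);
  E.k_recyc = as<double>(vesicle["k_recyc"]);

  E.pools.resize(E.n_classes);
  E.bonds.resize(E.n_rules);
  E.rings.resize(E.n_rules);
  E.dirty.assign(E.n_rules, 0);
  E.rules_of_cls.resize(E.n_classes);
  for (int r = 0; r < E.n_rules; ++r) {
    E.rules_of_cls[E.r_ca[r]].push_back(r);
    if (E.r_cb[r] >= 0 && E.r_cb[r] != E.r_ca[r])
      E.rules_of_cls[E.r_cb[r]].push_back(r);
  }
  E.fw.init(4 * E.n_rules + 2);
  E.cur.assign(4 * E.n_rules + 2, 0.0);
  E.rng.seed(static_cast<uint64_t>(seed) * 6364136223846793005ULL +
             1442695040888963407ULL);

  for (int ty = 0; ty < E.n_types; ++ty) {
    if (ty == E.lipid_type) continue;
    for (int k = 0; k < tcopies[ty]; ++k) {
      int m = E.new_mol(ty);
      int c = E.new_cplx();
      E.link_member(c, m);
      for (int s = 0; s < (int)E.mols[m].sites.size(); ++s)
        E.pool_add(m, s);
    }
  }
  E.run(t_end, max_events);

  int nv = (int)E.ves_time.size();
  IntegerMatrix vcomp(nv, E.n_types);
  IntegerVector vfull(nv);
  NumericVector vtime(nv);
  for (int i = 0; i < nv; ++i) {
    vtime[i] = E.ves_time[i];
    vfull[i] = E.ves_full[i];
    for (int ty = 0; ty < E.n_types; ++ty) vcomp(i, ty) = E.ves_comp[i][ty];
  }
  colnames(vcomp) = tnames;

  IntegerMatrix cm(0, E.n_types);
  IntegerVector csize, cbonds, cbonds_ns;
  if (census) {
    std::vector<int> live;
    for (int c = 0; c < (int)E.cplx.size(); ++c)
      if (E.cplx[c].alive && E.cplx[c].size > 0) live.push_back(c);
    cm = IntegerMatrix((int)live.size(), E.n_types);
    csize = IntegerVector((int)live.size());
    cbonds = IntegerVector((int)live.size());
    cbonds_ns = IntegerVector((int)live.size());
    for (size_t i = 0; i < live.size(); ++i) {
      Cplx& C = E.cplx[live[i]];
      int nb = 0, nns = 0;
      for (int m = C.head; m >= 0; m = E.mols[m].next) {
        cm((int)i, E.mols[m].type) += 1;
        for (auto& S : E.mols[m].sites)
          if (S.pmol > m) {
            ++nb;
            if (!E.r_specific[S.rule]) ++nns;
          }
      }
      csize[(int)i] = C.size;
      cbonds[(int)i] = nb;
      cbonds_ns[(int)i] = nns;
    }
    colnames(cm) = tnames;
  }

  std::vector<long> totals(E.n_types, 0);
  for (int c = 0; c < (int)E.cplx.size(); ++c)
    if (E.cplx[c].alive)
      for (int m = E.cplx[c].head; m >= 0; m = E.mols[m].next)
        totals[E.mols[m].type] += 1;
  for (int m : E.queue) totals[E.mols[m].type] += 1;
  bool conserved = true;
  for (int ty = 0; ty < E.n_types; ++ty) {
    long have = totals[ty] +
        (ty == E.lipid_type ? (long)llround(E.lipid_pool) : 0);
    if (have != (long)tcopies[ty]) conserved = false;
  }

  return List::create(
      _["t_final"] = E.t,
      _["n_events"] = E.n_events,
      _["n_null"] = E.n_null,
      _["vesicle_time"] = vtime,
      _["vesicle_comp"] = vcomp,
      _["vesicle_full"] = vfull,
      _["first_mem_adaptor"] = E.adaptor_first,
      _["first_mem_poly"] = E.poly_first,
      _["census"] = cm,
      _["census_size"] = csize,
      _["census_bonds"] = cbonds,
      _["census_bonds_nonspecific"] = cbonds_ns,
      _["lipid_pool"] = E.lipid_pool,
      _["queued"] = (int)E.queue.size(),
      _["conserved"] = conserved);
}
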