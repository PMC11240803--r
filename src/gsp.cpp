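#include <Rcpp.h>
#include <vector>
#include <map>
#include <set>
using namespace Rcpp;

typedef std::vector<int> Enc;  // 0 = element separator

// Greedy subsequence embedding of one pattern element into one window.
static bool elem_in(const std::vector<int>& window, const std::vector<int>& el) {
    size_t i = 0;
    if (el.empty()) return true;
    for (size_t k = 0; k < window.size(); ++k) {
        if (window[k] == el[i]) {
            if (++i == el.size()) return true;
        }
    }
    return false;
}

// Count, for each encoded pattern (integer codes, 0 = element separator),
// the number of database sequences containing it. A sequence contains a
// pattern when its elements embed into strictly increasing windows; the
// greedy earliest-window scan is exact because element matches are
// independent across windows.
// [[Rcpp::export]]
IntegerVector count_supports_cpp(List db, List patterns) {
    // materialise the database once
    std::vector< std::vector< std::vector<int> > > seqs;
    seqs.reserve(db.size());
    for (R_xlen_t s = 0; s < db.size(); ++s) {
        List windows = db[s];
        std::vector< std::vector<int> > sq;
        sq.reserve(windows.size());
        for (R_xlen_t w = 0; w < windows.size(); ++w) {
            IntegerVector win = windows[w];
            sq.push_back(std::vector<int>(win.begin(), win.end()));
        }
        seqs.push_back(sq);
    }

    IntegerVector out(patterns.size());
    for (R_xlen_t p = 0; p < patterns.size(); ++p) {
        IntegerVector enc = patterns[p];
        std::vector< std::vector<int> > els;
        els.push_back(std::vector<int>());
        for (R_xlen_t i = 0; i < enc.size(); ++i) {
            if (enc[i] == 0) els.push_back(std::vector<int>());
            else els.back().push_back(enc[i]);
        }
        int cnt = 0;
        for (size_t s = 0; s < seqs.size(); ++s) {
            const std::vector< std::vector<int> >& sq = seqs[s];
            size_t w = 0;
            bool ok = true;
            for (size_t e = 0; e < els.size(); ++e) {
                while (w < sq.size() && !elem_in(sq[w], els[e])) ++w;
                if (w >= sq.size()) { ok = false; break; }
                ++w;
            }
            if (ok) ++cnt;
        }
        out[p] = cnt;
    }
    return out;
}

static Enc drop_first(const Enc& e) {
    Enc out(e.begin() + 1, e.end());
    if (!out.empty() && out.front() == 0) out.erase(out.begin());
    return out;
}

static Enc drop_last(const Enc& e) {
    Enc out(e.begin(), e.end() - 1);
    if (!out.empty() && out.back() == 0) out.pop_back();
    return out;
}

// Delete the item at position p. Returns false when the deletion leaves a
// pattern outside the mined language (adjacent duplicate codes within an
// element); those subpatterns are never candidates, so their absence from
// the frequent set is uninformative for pruning.
static bool delete_item(const Enc& e, size_t p, Enc& out) {
    size_t n = e.size();
    bool left_sep = (p == 0) || e[p - 1] == 0;
    bool right_sep = (p == n - 1) || e[p + 1] == 0;
    out.clear();
    if (left_sep && right_sep) {
        // singleton element: drop it and one adjoining separator
        for (size_t i = 0; i < n; ++i) {
            if (i == p) continue;
            if (p + 1 < n && i == p + 1) continue;
            if (p + 1 >= n && p >= 1 && i == p - 1) continue;
            out.push_back(e[i]);
        }
        return true;
    }
    if (!left_sep && !right_sep && e[p - 1] == e[p + 1]) return false;
    for (size_t i = 0; i < n; ++i) if (i != p) out.push_back(e[i]);
    return true;
}

// GSP join + Apriori prune over encoded patterns of equal item count.
// [[Rcpp::export]]
List join_prune_cpp(List frequent) {
    std::vector<Enc> seeds;
    seeds.reserve(frequent.size());
    int k = -1;
    for (R_xlen_t i = 0; i < frequent.size(); ++i) {
        IntegerVector v = frequent[i];
        Enc e(v.begin(), v.end());
        int items = 0;
        for (size_t j = 0; j < e.size(); ++j) if (e[j] != 0) ++items;
        if (k < 0) k = items;
        else if (items != k) stop("candidate generation requires seeds of identical item count");
        seeds.push_back(e);
    }
    std::set<Enc> cands;
    if (k == 1) {
        for (size_t i = 0; i < seeds.size(); ++i) {
            for (size_t j = 0; j < seeds.size(); ++j) {
                int a = seeds[i][0], b = seeds[j][0];
                Enc two_el; two_el.push_back(a); two_el.push_back(0); two_el.push_back(b);
                cands.insert(two_el);
                if (a != b) {
                    Enc one_el; one_el.push_back(a); one_el.push_back(b);
                    cands.insert(one_el);
                }
            }
        }
    } else if (k > 1) {
        std::map<Enc, std::vector<size_t> > by_dropped_last;
        for (size_t j = 0; j < seeds.size(); ++j)
            by_dropped_last[drop_last(seeds[j])].push_back(j);
        for (size_t i = 0; i < seeds.size(); ++i) {
            std::map<Enc, std::vector<size_t> >::const_iterator it =
                by_dropped_last.find(drop_first(seeds[i]));
            if (it == by_dropped_last.end()) continue;
            for (size_t m = 0; m < it->second.size(); ++m) {
                const Enc& s2 = seeds[it->second[m]];
                int last = s2.back();
                bool last_alone = s2.size() >= 2 && s2[s2.size() - 2] == 0;
                Enc cand = seeds[i];
                if (last_alone) {
                    cand.push_back(0); cand.push_back(last);
                    cands.insert(cand);
                } else if (seeds[i].back() != last) {
                    cand.push_back(last);
                    cands.insert(cand);
                }
            }
        }
    }
    // Apriori prune
    std::set<Enc> seedset(seeds.begin(), seeds.end());
    std::vector<const Enc*> kept;
    Enc sub;
    for (std::set<Enc>::const_iterator c = cands.begin(); c != cands.end(); ++c) {
        bool ok = true;
        for (size_t p = 0; p < c->size() && ok; ++p) {
            if ((*c)[p] == 0) continue;
            if (!delete_item(*c, p, sub)) continue;  // out of language
            if (seedset.find(sub) == seedset.end()) ok = false;
        }
        if (ok) kept.push_back(&(*c));
    }
    List out(kept.size());
    for (size_t i = 0; i < kept.size(); ++i)
        out[i] = IntegerVector(kept[i]->begin(), kept[i]->end());
    return out;
}

static void split_elements(const Enc& e, std::vector<Enc>& els) {
    els.clear();
    els.push_back(Enc());
    for (size_t i = 0; i < e.size(); ++i) {
        if (e[i] == 0) els.push_back(Enc());
        else els.back().push_back(e[i]);
    }
}

static bool pattern_in(const std::vector<Enc>& q_els, const std::vector<Enc>& p_els) {
    size_t w = 0;
    for (size_t e = 0; e < p_els.size(); ++e) {
        while (w < q_els.size() && !elem_in(q_els[w], p_els[e])) ++w;
        if (w >= q_els.size()) return false;
        ++w;
    }
    return true;
}

// Maximality flags for a set of distinct patterns: a pattern is maximal when
// it is contained in no other pattern of the set. Patterns are scanned in
// decreasing item count; by transitivity of containment it suffices to test
// against the maximal patterns found so far.
// [[Rcpp::export]]
LogicalVector maximal_flags_cpp(List patterns) {
    R_xlen_t m = patterns.size();
    std::vector<Enc> encs(m);
    std::vector<int> items(m, 0);
    for (R_xlen_t i = 0; i < m; ++i) {
        IntegerVector v = patterns[i];
        encs[i] = Enc(v.begin(), v.end());
        for (size_t j = 0; j < encs[i].size(); ++j) if (encs[i][j] != 0) ++items[i];
    }
    std::vector<R_xlen_t> ord(m);
    for (R_xlen_t i = 0; i < m; ++i) ord[i] = i;
    std::stable_sort(ord.begin(), ord.end(),
                     [&](R_xlen_t a, R_xlen_t b) { return items[a] > items[b]; });
    LogicalVector out(m);
    std::vector< std::vector<Enc> > maximal_els;
    std::vector<int> maximal_items;
    std::vector<Enc> p_els;
    for (R_xlen_t r = 0; r < m; ++r) {
        R_xlen_t i = ord[r];
        split_elements(encs[i], p_els);
        bool is_max = true;
        for (size_t j = 0; j < maximal_els.size(); ++j) {
            if (maximal_items[j] <= items[i]) continue;
            if (pattern_in(maximal_els[j], p_els)) { is_max = false; break; }
        }
        out[i] = is_max;
        if (is_max) {
            maximal_els.push_back(p_els);
            maximal_items.push_back(items[i]);
        }
    }
    return out;
}
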