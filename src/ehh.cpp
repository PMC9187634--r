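#include <Rcpp.h>
using namespace Rcpp;

// Extended haplotype homozygosity machinery.
//
// A "grouping" partitions haplotypes into classes identical at every site
// from the core to the current extension site (inclusive). Extending by one
// site can only split groups, so EHH = sum_g C(k_g,2) / C(n,2) is
// non-increasing outward. Group labels are kept compact in [0, ngroups).

struct Grouping {
    std::vector<int> g;   // group label per haplotype
    int ngroups;

    void init_from_allele(const IntegerMatrix &hap, int site) {
        int n = hap.nrow();
        g.assign(n, 0);
        bool seen0 = false, seen1 = false;
        for (int i = 0; i < n; ++i) {
            g[i] = hap(i, site) ? 1 : 0;
            if (g[i]) seen1 = true; else seen0 = true;
        }
        if (seen0 && seen1) {
            ngroups = 2;
        } else {
            // single allele: one group, relabel to 0
            for (int i = 0; i < n; ++i) g[i] = 0;
            ngroups = 1;
        }
    }

    // split groups on the allele at `site`
    void extend(const IntegerMatrix &hap, int site) {
        int n = (int)g.size();
        std::vector<int> relabel(2 * ngroups, -1);
        int next = 0;
        for (int i = 0; i < n; ++i) {
            int code = 2 * g[i] + (hap(i, site) ? 1 : 0);
            if (relabel[code] < 0) relabel[code] = next++;
            g[i] = relabel[code];
        }
        ngroups = next;
    }

    double ehh() const {
        int n = (int)g.size();
        if (n < 2) return 0.0;
        std::vector<int> cnt(ngroups, 0);
        for (int i = 0; i < n; ++i) cnt[g[i]]++;
        double pairs = 0.0;
        for (int k = 0; k < ngroups; ++k)
            pairs += (double)cnt[k] * (cnt[k] - 1) / 2.0;
        return pairs / ((double)n * (n - 1) / 2.0);
    }
};

// EHH decay curve for one panel around one core, one chromosome.
// Curve includes the core point (distance 0). Each side stops when the
// panel's own EHH drops below `cutoff` (that first below-cutoff point is
// included so the integrator can interpolate the crossing), when the next
// inter-site gap exceeds `maxGap`, or at the chromosome end.
// [[Rcpp::export(name = ".ehh_curve_cpp")]]
List ehh_curve_cpp(IntegerMatrix hap, int core, NumericVector pos,
                   double cutoff, double maxGap) {
    int S = hap.ncol();
    if (core < 1 || core > S) stop("core index out of range");
    if (hap.nrow() < 2) stop("need at least 2 haplotypes");
    int c0 = core - 1;

    List sides(2);
    CharacterVector reasons(2);
    for (int s = 0; s < 2; ++s) {
        int dir = (s == 0) ? -1 : +1;
        Grouping grp;
        grp.init_from_allele(hap, c0);
        std::vector<double> ps, es;
        ps.push_back(pos[c0]);
        es.push_back(grp.ehh());
        std::string reason = "chromosome-end";
        if (es[0] < cutoff) {
            reason = "cutoff";
        } else {
            int j = c0 + dir;
            double prevpos = pos[c0];
            while (j >= 0 && j < S) {
                if (std::abs(pos[j] - prevpos) > maxGap) {
                    reason = "max-gap";
                    break;
                }
                grp.extend(hap, j);
                double e = grp.ehh();
                ps.push_back(pos[j]);
                es.push_back(e);
                if (e < cutoff) { reason = "cutoff"; break; }
                prevpos = pos[j];
                j += dir;
            }
        }
        sides[s] = DataFrame::create(_["pos"] = wrap(ps),
                                     _["ehh"] = wrap(es));
        reasons[s] = reason;
    }
    return List::create(_["left"] = sides[0], _["right"] = sides[1],
                        _["truncation"] = reasons);
}

// iHH pair for every core of one chromosome under the pooled stopping
// rule: extension on each side continues while the EHH of the pooled
// (target + reference) panel stays >= cutoff; both populations' EHH
// curves are integrated (trapezoids over bp) over that shared span, with
// the cutoff crossing located by linear interpolation on the pooled curve.
// [[Rcpp::export(name = ".xpehh_ihh_cpp")]]
DataFrame xpehh_ihh_cpp(IntegerMatrix tgt, IntegerMatrix ref,
                        NumericVector pos, double cutoff, double maxGap) {
    int S = tgt.ncol();
    if (ref.ncol() != S) stop("panels must share sites");
    int nT = tgt.nrow(), nR = ref.nrow();
    IntegerMatrix pooled(nT + nR, S);
    for (int j = 0; j < S; ++j) {
        for (int i = 0; i < nT; ++i) pooled(i, j) = tgt(i, j);
        for (int i = 0; i < nR; ++i) pooled(nT + i, j) = ref(i, j);
    }
    NumericVector ihhT(S), ihhR(S);

    for (int c0 = 0; c0 < S; ++c0) {
        double accT = 0.0, accR = 0.0;
        for (int s = 0; s < 2; ++s) {
            int dir = (s == 0) ? -1 : +1;
            Grouping gp, gt, gr;
            gp.init_from_allele(pooled, c0);
            gt.init_from_allele(tgt, c0);
            gr.init_from_allele(ref, c0);
            double eP = gp.ehh(), eT = gt.ehh(), eR = gr.ehh();
            if (eP < cutoff) continue;
            double prevpos = pos[c0];
            int j = c0 + dir;
            while (j >= 0 && j < S) {
                double d = std::abs(pos[j] - prevpos);
                if (d > maxGap) break;
                gp.extend(pooled, j);
                gt.extend(tgt, j);
                gr.extend(ref, j);
                double nP = gp.ehh(), nT2 = gt.ehh(), nR2 = gr.ehh();
                if (nP < cutoff) {
                    // pooled curve crosses the cutoff inside this interval
                    double t = (eP - cutoff) / (eP - nP);
                    double dd = d * t;
                    double tC = eT + (nT2 - eT) * t;
                    double rC = eR + (nR2 - eR) * t;
                    accT += (eT + tC) / 2.0 * dd;
                    accR += (eR + rC) / 2.0 * dd;
                    break;
                }
                accT += (eT + nT2) / 2.0 * d;
                accR += (eR + nR2) / 2.0 * d;
                eP = nP; eT = nT2; eR = nR2;
                prevpos = pos[j];
                j += dir;
            }
        }
        ihhT[c0] = accT;
        ihhR[c0] = accR;
    }
    return DataFrame::create(_["ihh_target"] = ihhT, _["ihh_ref"] = ihhR);
}
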