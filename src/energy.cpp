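// Pairwise energy kernel for the threading engine.
//
// Atoms are passed as parallel vectors.  Each atom carries xyz coordinates,
// a van der Waals radius, an attraction well depth (eps), a desolvation
// parameter (solv; >0 polar, <0 apolar), hydrogen-bond donor/acceptor flags,
// the acceptor's bonded-parent coordinates (for the H-bond angle test),
// a strand id, a residue number within the strand, and a backbone name code
// used for covalent exclusions:
//   1 = N, 2 = CA, 3 = C, 4 = O, 5 = CB, 0 = any other (side-chain) atom.
//
// Pairs excluded from scoring:
//   - same strand, same residue (intra-residue geometry is fixed);
//   - same strand, sequence-adjacent residues, when the atom pair is within
//     three covalent bonds of each other (1-2/1-3/1-4 across the peptide
//     bond), enumerated in EXCL below.
//
// Energy model (raw, unweighted terms; weights applied by the caller):
//   rep  : soft clash, ((rsum - d)/rsum)^2 * 20 for d < rsum       (>= 0)
//   att  : -sqrt(eps_i*eps_j) * well(d), well = 1 inside contact,
//          quadratic fade to 0 at rsum + 1.5 A                     (<= 0)
//   solv : 0.5*(solv_i + solv_j) * (1 - (d/6)^2) for d < 6 A
//   hb   : -1 per donor/acceptor pair with heavy-atom distance in
//          [2.6, 3.5] A and parent-acceptor-donor angle >= 90 deg  (<= 0)

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// EXCL[a][b]: a = name code in residue i, b = name code in residue i+1
static const bool EXCL[6][6] = {
    // other   N     CA     C      O     CB      (residue i+1 atom)
    {false, false, false, false, false, false},  // other (residue i)
    {false, true,  false, false, false, false},  // N
    {false, true,  true,  false, false, false},  // CA
    {false, true,  true,  true,  false, true },  // C
    {false, true,  true,  false, false, false},  // O
    {false, true,  false, false, false, false},  // CB
};

struct AtomSet {
    NumericVector x, y, z, radius, eps, solv, px, py, pz;
    LogicalVector donor, acceptor, has_parent;
    IntegerVector strand, resno, namecode;
    int n;
};

static AtomSet unpack(const List& s) {
    AtomSet a;
    a.x = s["x"]; a.y = s["y"]; a.z = s["z"];
    a.radius = s["radius"]; a.eps = s["eps"]; a.solv = s["solv"];
    a.px = s["px"]; a.py = s["py"]; a.pz = s["pz"];
    a.donor = s["donor"]; a.acceptor = s["acceptor"];
    a.has_parent = s["has_parent"];
    a.strand = s["strand"]; a.resno = s["resno"]; a.namecode = s["namecode"];
    a.n = a.x.size();
    return a;
}

static inline bool excluded(const AtomSet& A, int i, const AtomSet& B, int j) {
    if (A.strand[i] != B.strand[j]) return false;
    int dr = A.resno[i] - B.resno[j];
    if (dr == 0) return true;
    if (dr == -1) return EXCL[A.namecode[i]][B.namecode[j]];
    if (dr == 1) return EXCL[B.namecode[j]][A.namecode[i]];
    return false;
}

static inline bool hb_geom_ok(const AtomSet& D, int di, const AtomSet& A, int ai) {
    // angle parent-acceptor-donor must be >= 90 degrees; if the acceptor has
    // no recorded parent the distance criterion alone applies
    if (!A.has_parent[ai]) return true;
    double v1x = A.px[ai] - A.x[ai], v1y = A.py[ai] - A.y[ai], v1z = A.pz[ai] - A.z[ai];
    double v2x = D.x[di] - A.x[ai], v2y = D.y[di] - A.y[ai], v2z = D.z[di] - A.z[ai];
    double dot = v1x * v2x + v1y * v2y + v1z * v2z;
    return dot <= 0.0;  // cos(angle) <= 0  <=>  angle >= 90 deg
}

static inline void pair_terms(const AtomSet& A, int i, const AtomSet& B, int j,
                              double& rep, double& att, double& solv, double& hb) {
    double dx = A.x[i] - B.x[j], dy = A.y[i] - B.y[j], dz = A.z[i] - B.z[j];
    double d2 = dx * dx + dy * dy + dz * dz;
    if (d2 > 49.0) return;  // 7 A cutoff covers every term
    if (excluded(A, i, B, j)) return;
    double d = std::sqrt(d2);
    double rsum = A.radius[i] + B.radius[j];
    if (d < rsum) {
        double f = (rsum - d) / rsum;
        rep += 20.0 * f * f;
        att -= std::sqrt(A.eps[i] * B.eps[j]);
    } else if (d < rsum + 1.5) {
        double f = (d - rsum) / 1.5;
        att -= std::sqrt(A.eps[i] * B.eps[j]) * (1.0 - f * f);
    }
    if (d < 6.0) {
        solv += 0.5 * (A.solv[i] + B.solv[j]) * (1.0 - d2 / 36.0);
    }
    if (d >= 2.6 && d <= 3.5) {
        if ((A.donor[i] && B.acceptor[j] && hb_geom_ok(A, i, B, j)) ||
            (B.donor[j] && A.acceptor[i] && hb_geom_ok(B, j, A, i))) {
            hb -= 1.0;
        }
    }
}

// [[Rcpp::export(name = ".energy_between")]]
NumericVector energy_between(List setA, List setB) {
    AtomSet A = unpack(setA), B = unpack(setB);
    double rep = 0, att = 0, solv = 0, hb = 0;
    for (int i = 0; i < A.n; ++i)
        for (int j = 0; j < B.n; ++j)
            pair_terms(A, i, B, j, rep, att, solv, hb);
    return NumericVector::create(_["rep"] = rep, _["att"] = att,
                                 _["solv"] = solv, _["hb"] = hb);
}

// [[Rcpp::export(name = ".energy_within")]]
NumericVector energy_within(List setA) {
    AtomSet A = unpack(setA);
    double rep = 0, att = 0, solv = 0, hb = 0;
    for (int i = 0; i < A.n; ++i)
        for (int j = i + 1; j < A.n; ++j)
            pair_terms(A, i, A, j, rep, att, solv, hb);
    return NumericVector::create(_["rep"] = rep, _["att"] = att,
                                 _["solv"] = solv, _["hb"] = hb);
}
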