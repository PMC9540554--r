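/* Hot per-iteration kernels of the deconstructed assembly formulation.
 *
 * All kernels are pure functions of the community summaries maintained by
 * the R driver: the attack matrix H (SR x SC, column-major), the column
 * sums S_k, the column sums of squares Q_k, and the cross-product matrix
 * D_kl = sum_j H_jk H_jl.  Conditions are evaluated on a snapshot; removal
 * is left to the driver.
 */

#include <R.h>
#include <Rinternals.h>

/* Exploitative competitive exclusion sweep: consumer k is marked iff some
 * other consumer l has (S_k - 1) < D_kl * (S_l - 1) / Q_l.
 * Returns 1-based indices of marked consumers. */
SEXP C_excl_sweep(SEXP S_, SEXP Q_, SEXP D_)
{
    const int SC = LENGTH(S_);
    const double *S = REAL(S_), *Q = REAL(Q_), *D = REAL(D_);
    int *mark = (int *) R_alloc(SC, sizeof(int));
    int nkill = 0;

    for (int k = 0; k < SC; k++) {
        const double Ck = S[k] - 1.0;
        mark[k] = 0;
        for (int l = 0; l < SC; l++) {
            if (l == k) continue;
            if (S[l] <= 1.0) continue;  /* resident must itself be viable */
            if (Ck < D[k + (size_t) l * SC] * (S[l] - 1.0) / Q[l]) {
                mark[k] = 1;
                nkill++;
                break;
            }
        }
    }
    SEXP out = PROTECT(allocVector(INTSXP, nkill));
    int *o = INTEGER(out);
    for (int k = 0, i = 0; k < SC; k++)
        if (mark[k]) o[i++] = k + 1;
    UNPROTECT(1);
    return out;
}

/* Pyrrhic competition sweep: consumer k loses its main resource i (the row
 * with the largest H_ik; first maximum on ties) to the pair (k, l) iff the
 * joint equilibrium is feasible, Q_k Q_l - D_kl^2 > 0, and
 *   Q_k Q_l - D_kl^2 < C_k (H_ik Q_l - H_il D_kl) + A_l (H_il Q_k - H_ik D_kl)
 * with C_k = S_k - 1, A_l = S_l - 1.  Returns the sorted unique 1-based
 * rows of the main resources of all consumers marked by the sweep. */
SEXP C_pyrrhic_sweep(SEXP H_, SEXP S_, SEXP Q_, SEXP D_)
{
    const int SR = nrows(H_), SC = ncols(H_);
    const double *H = REAL(H_), *S = REAL(S_), *Q = REAL(Q_), *D = REAL(D_);
    int *mi = (int *) R_alloc(SC, sizeof(int));
    int *rowflag = (int *) R_alloc(SR, sizeof(int));
    int nrr = 0;

    for (int j = 0; j < SR; j++) rowflag[j] = 0;
    for (int k = 0; k < SC; k++) {
        const double *h = H + (size_t) k * SR;
        int best = 0;
        for (int j = 1; j < SR; j++)
            if (h[j] > h[best]) best = j;
        mi[k] = best;
    }
    for (int k = 0; k < SC; k++) {
        const double Ck = S[k] - 1.0;
        if (Ck <= 0.0) continue;        /* both members must be viable */
        const double Hik = H[mi[k] + (size_t) k * SR];
        for (int l = 0; l < SC; l++) {
            if (l == k) continue;
            if (S[l] <= 1.0) continue;
            const double Dkl = D[k + (size_t) l * SC];
            const double lhs = Q[k] * Q[l] - Dkl * Dkl;
            if (lhs <= 0.0) continue;  /* infeasible: left to exploitative logic */
            const double Hil = H[mi[k] + (size_t) l * SR];
            const double rhs = Ck * (Hik * Q[l] - Hil * Dkl)
                + (S[l] - 1.0) * (Hil * Q[k] - Hik * Dkl);
            if (lhs < rhs) {
                if (!rowflag[mi[k]]) { rowflag[mi[k]] = 1; nrr++; }
                break;
            }
        }
    }
    SEXP out = PROTECT(allocVector(INTSXP, nrr));
    int *o = INTEGER(out);
    for (int j = 0, i = 0; j < SR; j++)
        if (rowflag[j]) o[i++] = j + 1;
    UNPROTECT(1);
    return out;
}

/* Consumers currently satisfying the apparent-competition condition
 * S_k - 1 > Q_k / max_j H_jk.  Returns 1-based consumer indices. */
SEXP C_eq16_set(SEXP H_, SEXP S_, SEXP Q_)
{
    const int SR = nrows(H_), SC = ncols(H_);
    const double *H = REAL(H_), *S = REAL(S_), *Q = REAL(Q_);
    int *mark = (int *) R_alloc(SC, sizeof(int));
    int nsat = 0;

    for (int k = 0; k < SC; k++) {
        const double *h = H + (size_t) k * SR;
        double m = h[0];
        for (int j = 1; j < SR; j++)
            if (h[j] > m) m = h[j];
        mark[k] = (S[k] - 1.0 > Q[k] / m);
        if (mark[k]) nsat++;
    }
    SEXP out = PROTECT(allocVector(INTSXP, nsat));
    int *o = INTEGER(out);
    for (int k = 0, i = 0; k < SC; k++)
        if (mark[k]) o[i++] = k + 1;
    UNPROTECT(1);
    return out;
}
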