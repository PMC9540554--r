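/* Compiled right-hand side and extirpation root function for the
 * dimensionless two-level Lotka-Volterra system, in the calling convention
 * of deSolve's compiled models.  The model data (attack matrix and rates)
 * are installed by C_lv_set_model before each integration segment; the
 * state vector is y = (B_R[1..SR], B_C[1..SC]).
 */

#include <R.h>
#include <Rinternals.h>
#include <stdlib.h>
#include <string.h>

static double *H_buf = NULL;
static int SR_g = 0, SC_g = 0;
static double r_g = 1.0, rho_g = 0.1, thresh_g = 0.0;

SEXP C_lv_set_model(SEXP H, SEXP r, SEXP rho, SEXP thresh)
{
    const int SR = nrows(H), SC = ncols(H);
    if (H_buf) { free(H_buf); H_buf = NULL; }
    if ((size_t) SR * SC > 0) {
        H_buf = (double *) malloc(sizeof(double) * (size_t) SR * SC);
        if (!H_buf) error("allocation failure in C_lv_set_model");
        memcpy(H_buf, REAL(H), sizeof(double) * (size_t) SR * SC);
    }
    SR_g = SR; SC_g = SC;
    r_g = asReal(r); rho_g = asReal(rho); thresh_g = asReal(thresh);
    return R_NilValue;
}

/* dB_jR/dt = r (1 - B_jR - sum_k H_jk B_kC) B_jR
 * dB_kC/dt = rho (sum_j H_jk B_jR - 1) B_kC */
void C_lv_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    const int SR = SR_g, SC = SC_g;
    for (int j = 0; j < SR; j++) ydot[j] = 0.0;
    for (int k = 0; k < SC; k++) {
        const double *h = H_buf + (size_t) k * SR;
        const double bc = y[SR + k];
        double gain = 0.0;
        for (int j = 0; j < SR; j++) {
            gain += h[j] * y[j];
            ydot[j] += h[j] * bc;
        }
        ydot[SR + k] = rho_g * (gain - 1.0) * bc;
    }
    for (int j = 0; j < SR; j++)
        ydot[j] = r_g * (1.0 - y[j] - ydot[j]) * y[j];
}

/* Analytic Jacobian (full, column-major in pd):
 *   d(dB_jR)/dB_jR = r (1 - 2 B_jR - sum_k H_jk B_kC)
 *   d(dB_jR)/dB_kC = -r H_jk B_jR
 *   d(dB_kC)/dB_jR =  rho H_jk B_kC
 *   d(dB_kC)/dB_kC =  rho (sum_j H_jk B_jR - 1)
 * (within-level off-diagonal entries are zero) */
void C_lv_jac(int *neq, double *t, double *y, int *ml, int *mu,
              double *pd, int *nrowpd, double *yout, int *ip)
{
    const int SR = SR_g, SC = SC_g, n = *neq, nr = *nrowpd;
    for (size_t j = 0; j < (size_t) nr * n; j++) pd[j] = 0.0;
    for (int j = 0; j < SR; j++) {
        double cons = 0.0;
        for (int k = 0; k < SC; k++)
            cons += H_buf[j + (size_t) k * SR] * y[SR + k];
        pd[j + (size_t) j * nr] = r_g * (1.0 - 2.0 * y[j] - cons);
    }
    for (int k = 0; k < SC; k++) {
        const double *h = H_buf + (size_t) k * SR;
        const double bc = y[SR + k];
        double gain = 0.0;
        for (int j = 0; j < SR; j++) {
            gain += h[j] * y[j];
            pd[j + (size_t) (SR + k) * nr] = -r_g * h[j] * y[j];
            pd[(SR + k) + (size_t) j * nr] = rho_g * h[j] * bc;
        }
        pd[(SR + k) + (size_t) (SR + k) * nr] = rho_g * (gain - 1.0);
    }
}

/* One root per species: biomass crossing the extirpation threshold. */
void C_lv_root(int *neq, double *t, double *y, int *ng, double *gout,
               double *out, int *ip)
{
    for (int i = 0; i < *neq; i++)
        gout[i] = y[i] - thresh_g;
}
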