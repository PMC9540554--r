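#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

extern SEXP C_excl_sweep(SEXP, SEXP, SEXP);
extern SEXP C_pyrrhic_sweep(SEXP, SEXP, SEXP, SEXP);
extern SEXP C_eq16_set(SEXP, SEXP, SEXP);
extern SEXP C_lv_set_model(SEXP, SEXP, SEXP, SEXP);
extern void C_lv_derivs(int *, double *, double *, double *, double *, int *);
extern void C_lv_jac(int *, double *, double *, int *, int *, double *, int *,
                     double *, int *);
extern void C_lv_root(int *, double *, double *, int *, double *, double *, int *);

static const R_CallMethodDef call_entries[] = {
    {"C_excl_sweep",    (DL_FUNC) &C_excl_sweep,    3},
    {"C_pyrrhic_sweep", (DL_FUNC) &C_pyrrhic_sweep, 4},
    {"C_eq16_set",      (DL_FUNC) &C_eq16_set,      3},
    {"C_lv_set_model",  (DL_FUNC) &C_lv_set_model,  4},
    {NULL, NULL, 0}
};

static const R_CMethodDef c_entries[] = {
    {"C_lv_derivs", (DL_FUNC) &C_lv_derivs, 6},
    {"C_lv_jac",    (DL_FUNC) &C_lv_jac,    9},
    {"C_lv_root",   (DL_FUNC) &C_lv_root,   7},
    {NULL, NULL, 0}
};

void R_init_prudentweb(DllInfo *dll)
{
    R_registerRoutines(dll, c_entries, call_entries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
    R_forceSymbols(dll, FALSE); /* deSolve looks up C_lv_derivs/C_lv_root by name */
}
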