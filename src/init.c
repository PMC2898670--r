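#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

SEXP C_ssa_run(SEXP, SEXP, SEXP, SEXP, SEXP, SEXP, SEXP);

static const R_CallMethodDef CallEntries[] = {
    {"C_ssa_run", (DL_FUNC) &C_ssa_run, 7},
    {NULL, NULL, 0}
};

void R_init_oscdesign(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, CallEntries, NULL, NULL);
    /* osc_derivs / osc_initmod are looked up by name from deSolve */
    R_useDynamicSymbols(dll, TRUE);
}
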