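#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

void init_insilico4(void (*odeparms)(int *, double *));
void deriv_insilico4(int *, double *, double *, double *, double *, int *);
void init_dsalina(void (*odeparms)(int *, double *));
void deriv_dsalina(int *, double *, double *, double *, double *, int *);

static const R_CMethodDef CEntries[] = {
    {"deriv_insilico4", (DL_FUNC) &deriv_insilico4, 6},
    {"deriv_dsalina",   (DL_FUNC) &deriv_dsalina,   6},
    {NULL, NULL, 0}
};

void R_init_plsens(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE); /* deSolve looks initfunc/derivs up by name */
}
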