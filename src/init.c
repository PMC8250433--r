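#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

void denit_initparms(void (*odeparms)(int *, double *));
void derivs_enzyme(int *, double *, double *, double *, double *, int *);
void derivs_monod(int *, double *, double *, double *, double *, int *);
void derivs_simplified(int *, double *, double *, double *, double *, int *);

static const R_CMethodDef CEntries[] = {
    {"denit_initparms", (DL_FUNC) &denit_initparms, 1},
    {"derivs_enzyme", (DL_FUNC) &derivs_enzyme, 6},
    {"derivs_monod", (DL_FUNC) &derivs_monod, 6},
    {"derivs_simplified", (DL_FUNC) &derivs_simplified, 6},
    {NULL, NULL, 0}
};

void R_init_denitrodyn(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
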