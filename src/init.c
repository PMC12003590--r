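#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

void simeoni_init(void (*odeparms)(int *, double *));
void simeoni_forc(void (*odeforcs)(int *, double *));
void simeoni_deriv(int *neq, double *t, double *y, double *ydot,
                   double *yout, int *ip);

static const R_CMethodDef CEntries[] = {
    {"simeoni_init",  (DL_FUNC) &simeoni_init,  1},
    {"simeoni_forc",  (DL_FUNC) &simeoni_forc,  1},
    {"simeoni_deriv", (DL_FUNC) &simeoni_deriv, 5},
    {NULL, NULL, 0}
};

void R_init_xenoscale(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
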