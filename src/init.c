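#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

void ssys_init(void (*odeparms)(int *, double *));
void ssys_deriv(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip);
void ssys_root(int *neq, double *t, double *y, int *ng, double *gout,
               double *rpar, int *ipar);

/* deSolve looks these up by name via getNativeSymbolInfo(); registering
 * them keeps the lookup working with useDynLib(.registration = TRUE). */
static const R_CMethodDef CEntries[] = {
    {"ssys_init",  (DL_FUNC) &ssys_init,  1},
    {"ssys_deriv", (DL_FUNC) &ssys_deriv, 6},
    {"ssys_root",  (DL_FUNC) &ssys_root,  7},
    {NULL, NULL, 0}
};

void R_init_ssysnet(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
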