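#include <R.h>
#include <R_ext/Rdynload.h>

void usp4_init(void (*odeparms)(int *, double *));
void usp4_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip);

static const R_CMethodDef CEntries[] = {
    {"usp4_init",   (DL_FUNC) &usp4_init,   1},
    {"usp4_derivs", (DL_FUNC) &usp4_derivs, 6},
    {NULL, NULL, 0}
};

void R_init_usp4pbpk(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
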