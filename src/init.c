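#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

extern SEXP _antbattle_ssa_cpp(SEXP, SEXP, SEXP, SEXP, SEXP, SEXP);

void battle_initparms(void (*odeparms)(int *, double *));
void battle_derivs(int *, double *, double *, double *, double *, int *);
void battle_root(int *, double *, double *, int *, double *, double *, int *);

static const R_CallMethodDef CallEntries[] = {
  {"_antbattle_ssa_cpp", (DL_FUNC) &_antbattle_ssa_cpp, 6},
  {NULL, NULL, 0}
};

/* The ODE routines are registered so deSolve can look them up by name. */
static const R_CMethodDef CEntries[] = {
  {"battle_initparms", (DL_FUNC) &battle_initparms, 1},
  {"battle_derivs",    (DL_FUNC) &battle_derivs,    6},
  {"battle_root",      (DL_FUNC) &battle_root,      7},
  {NULL, NULL, 0}
};

void R_init_antbattle(DllInfo *dll) {
  R_registerRoutines(dll, CEntries, CallEntries, NULL, NULL);
  R_useDynamicSymbols(dll, FALSE);
}
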