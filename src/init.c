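#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

void bilecirc_initmod(void (*odeparms)(int *, double *));
void bilecirc_derivs(int *neq, double *t, double *y, double *ydot,
                     double *yout, int *ip);

/* direct evaluation of the rhs (used by tests and flux diagnostics) */
SEXP bilecirc_rhs_eval(SEXP t_, SEXP y_, SEXP p_)
{
  extern void bilecirc_set_parms(double *);
  int neq = LENGTH(y_);
  double t = REAL(t_)[0];
  SEXP out = PROTECT(allocVector(REALSXP, neq));
  if (LENGTH(p_) != 35) error("expected 35 parameters");
  bilecirc_set_parms(REAL(p_));
  bilecirc_derivs(&neq, &t, REAL(y_), REAL(out), NULL, NULL);
  UNPROTECT(1);
  return out;
}

static const R_CallMethodDef callMethods[] = {
  {"bilecirc_rhs_eval", (DL_FUNC) &bilecirc_rhs_eval, 3},
  {NULL, NULL, 0}
};

static const R_CMethodDef cMethods[] = {
  {"bilecirc_derivs", (DL_FUNC) &bilecirc_derivs, 6},
  {NULL, NULL, 0}
};

void R_init_bilecirc(DllInfo *info)
{
  R_registerRoutines(info, cMethods, callMethods, NULL, NULL);
  R_useDynamicSymbols(info, TRUE);
}
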