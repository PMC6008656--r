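/* Right-hand side of the enterohepatic bile acid circulation model.
 *
 * State layout (407 entries, micromoles):
 *   y[j*21 + c], j = compartment 0..17, c = configuration 0..20
 *     compartments: 0 li, 1 gb, 2 pl, 3..12 si_1..si_10, 13..17 co_1..co_5
 *     configurations: c = species*3 + conj for unsulfated
 *       (species 0 CA, 1 CDCA, 2 DCA, 3 UDCA, 4 LCA, 5 other; conj 0 u, 1 g, 2 t)
 *       c = 18 + conj for sulfated LCA
 *   y[378..397]  cumulative fecal output per configuration
 *   y[399]       cumulative duodenal secretion (liver direct + gallbladder)
 *   y[400]       cumulative si_10 -> co_1 flux
 *   y[401]       cumulative small-intestinal uptake (passive + active)
 *   y[402]       cumulative colonic uptake
 *   y[403..406]  cumulative transformation fluxes CA->DCA, CDCA->LCA,
 *                CDCA->UDCA, UDCA->LCA
 *
 * Parameters (35): the 33 free kinetic parameters in canonical order,
 * then t_last_meal (h) and a forcing flag (0 before the first meal).
 * All rates are first-order mass action except active ileal uptake,
 * which is Michaelis-Menten with competition for the shared carrier.
 */

#include <R.h>
#include <math.h>

#define N_CONFIG 21
#define N_COMP   18
#define N_CORE   (N_CONFIG * N_COMP)
#define N_STATE  407
#define N_PARMS  35

/* compartment indices */
#define C_LI 0
#define C_GB 1
#define C_PL 2
#define C_SI(i) (3 + (i))   /* i = 0..9 for si_1..si_10 */
#define C_CO(i) (13 + (i))  /* i = 0..4 for co_1..co_5  */

/* aux state indices */
#define A_FECAL   N_CORE          /* + c */
#define A_SECR    399
#define A_COIN    400
#define A_UPSI    401
#define A_UPCO    402
#define A_TRANS   403             /* + edge 0..3 */

/* parameter indices (canonical order, mirrored in R/parameters.R) */
enum {
  P_K_SI_ALPHA, P_K_SI_BETA, P_K_CO,
  P_DELTA_SI, P_BETA_SI, P_DELTA_GB, P_BETA_GB,
  P_GAMMA_GB, P_K_XG, P_EPS_GB,
  P_K_XL, P_K_PL, P_K_U,
  P_F_CA, P_F_CDCA, P_F_GLY, P_K_CONJ, P_K_SULF,
  P_PSI_TRI, P_PSI_DI, P_PSI_MONO, P_PSI_U, P_PSI_SULF,
  P_VMAX, P_KM, P_K_UP, P_K_UP_CO,
  P_K_DEC_SI, P_K_DEC_CO,
  P_K_CA_DCA, P_K_CDCA_LCA, P_K_CDCA_UDCA, P_K_UDCA_LCA,
  P_T_LAST_MEAL, P_FORCING_ON
};

static double parms[N_PARMS];

void bilecirc_initmod(void (*odeparms)(int *, double *))
{
  int n = N_PARMS;
  odeparms(&n, parms);
}

/* copy a parameter vector into the static block (direct rhs evaluation) */
void bilecirc_set_parms(double *p)
{
  int i;
  for (i = 0; i < N_PARMS; i++) parms[i] = p[i];
}

/* species of configuration c: 0..5, sulfated LCA -> 4 */
static int cfg_species(int c) { return c < 18 ? c / 3 : 4; }
/* conjugation of configuration c: 0 u, 1 g, 2 t */
static int cfg_conj(int c)    { return c < 18 ? c % 3 : c - 18; }
static int cfg_sulf(int c)    { return c >= 18; }

/* hepatic extraction fraction of configuration c, clamped to [0,1] */
static double psi_cfg(int c, const double *p)
{
  int s = cfg_species(c);
  double psi;
  if (s == 0)      psi = p[P_PSI_TRI];   /* CA: tri-hydroxylated */
  else if (s == 4) psi = p[P_PSI_MONO];  /* LCA: mono-hydroxylated */
  else             psi = p[P_PSI_DI];    /* CDCA, DCA, UDCA, other */
  if (cfg_conj(c) == 0) psi *= p[P_PSI_U];
  if (cfg_sulf(c))      psi *= p[P_PSI_SULF];
  if (psi < 0.0) psi = 0.0;
  if (psi > 1.0) psi = 1.0;
  return psi;
}

/* route an absorbed flux: psi*F to liver, (1-psi)*F spills to plasma */
static void absorb(double *dy, int c, double flux, const double *p)
{
  double psi = psi_cfg(c, p);
  dy[C_LI * N_CONFIG + c] += psi * flux;
  dy[C_PL * N_CONFIG + c] += (1.0 - psi) * flux;
}

void bilecirc_derivs(int *neq, double *t, double *y, double *ydot,
                     double *yout, int *ip)
{
  const double *p = parms;
  double m, s_gb, gb_frac, k_empty, dt_meal;
  int c, i, j;

  if (*neq != N_STATE)
    error("bilecirc rhs: expected %d states, got %d", N_STATE, *neq);

  for (i = 0; i < N_STATE; i++) ydot[i] = 0.0;
  for (i = 0; i < N_CORE; i++) {
    if (!R_FINITE(y[i]))
      error("non-finite amount in compartment %d, configuration %d at t=%g",
            i / N_CONFIG, i % N_CONFIG, *t);
  }

  /* meal forcing: propulsion multiplier and gallbladder emptying signal */
  if (p[P_FORCING_ON] > 0.5) {
    dt_meal = *t - p[P_T_LAST_MEAL];
    if (dt_meal < 0.0) dt_meal = 0.0;
    m    = 1.0 + p[P_DELTA_SI] * exp(-p[P_BETA_SI] * dt_meal);
    s_gb = p[P_DELTA_GB] * exp(-p[P_BETA_GB] * dt_meal);
  } else {
    m = 1.0;
    s_gb = 0.0;
  }
  gb_frac = p[P_GAMMA_GB] * (1.0 - s_gb);          /* hepatic output to gb */
  k_empty = p[P_K_XG] * (p[P_EPS_GB] + (1.0 - p[P_EPS_GB]) * s_gb);

  /* (a) synthesis: unconjugated CA, CDCA and other enter the liver */
  {
    double f_o = 1.0 - p[P_F_CA] - p[P_F_CDCA];
    if (f_o < 0.0) f_o = 0.0;
    ydot[C_LI * N_CONFIG + 0]  += p[P_K_U] * p[P_F_CA];    /* uCA  */
    ydot[C_LI * N_CONFIG + 3]  += p[P_K_U] * p[P_F_CDCA];  /* uCDCA */
    ydot[C_LI * N_CONFIG + 15] += p[P_K_U] * f_o;          /* uO   */
  }

  /* (b) hepatic conjugation and LCA sulfation */
  for (c = 0; c < N_CONFIG; c += 3) {           /* c = each unconjugated cfg */
    int base = (c < 18) ? c : 18;
    double flux = p[P_K_CONJ] * y[C_LI * N_CONFIG + c];
    ydot[C_LI * N_CONFIG + c]        -= flux;
    ydot[C_LI * N_CONFIG + base + 1] += p[P_F_GLY] * flux;
    ydot[C_LI * N_CONFIG + base + 2] += (1.0 - p[P_F_GLY]) * flux;
  }
  for (i = 0; i < 3; i++) {                     /* uLCA,gLCA,tLCA -> sulfated */
    double flux = p[P_K_SULF] * y[C_LI * N_CONFIG + 12 + i];
    ydot[C_LI * N_CONFIG + 12 + i] -= flux;
    ydot[C_LI * N_CONFIG + 18 + i] += flux;
  }

  /* (c) liver -> bile secretion, split to gallbladder and duodenum */
  for (c = 0; c < N_CONFIG; c++) {
    double flux = p[P_K_XL] * y[C_LI * N_CONFIG + c];
    ydot[C_LI * N_CONFIG + c]     -= flux;
    ydot[C_GB * N_CONFIG + c]     += gb_frac * flux;
    ydot[C_SI(0) * N_CONFIG + c]  += (1.0 - gb_frac) * flux;
    ydot[A_SECR]                  += (1.0 - gb_frac) * flux;
  }

  /* (d) gallbladder emptying into the duodenum */
  for (c = 0; c < N_CONFIG; c++) {
    double flux = k_empty * y[C_GB * N_CONFIG + c];
    ydot[C_GB * N_CONFIG + c]    -= flux;
    ydot[C_SI(0) * N_CONFIG + c] += flux;
    ydot[A_SECR]                 += flux;
  }

  /* (e) intestinal transit; SI rates carry the postprandial multiplier */
  for (i = 0; i < 10; i++) {
    double rate = m * (i < 5 ? p[P_K_SI_ALPHA] : p[P_K_SI_BETA]);
    int from = C_SI(i), to = (i < 9) ? C_SI(i + 1) : C_CO(0);
    for (c = 0; c < N_CONFIG; c++) {
      double flux = rate * y[from * N_CONFIG + c];
      ydot[from * N_CONFIG + c] -= flux;
      ydot[to * N_CONFIG + c]   += flux;
      if (i == 9) ydot[A_COIN]  += flux;
    }
  }
  for (i = 0; i < 5; i++) {
    int from = C_CO(i);
    for (c = 0; c < N_CONFIG; c++) {
      double flux = p[P_K_CO] * y[from * N_CONFIG + c];
      ydot[from * N_CONFIG + c] -= flux;
      if (i < 4) ydot[C_CO(i + 1) * N_CONFIG + c] += flux;
      else       ydot[A_FECAL + c]                += flux;   /* co_5 -> feces */
    }
  }

  /* (f) passive uptake of unconjugated bile acids; halved when sulfated */
  for (c = 0; c < N_CONFIG; c++) {
    double k_pass, fac;
    if (cfg_conj(c) != 0) continue;
    fac = cfg_sulf(c) ? 0.5 : 1.0;
    for (j = 0; j < 10; j++) {
      k_pass = fac * p[P_K_UP];
      double flux = k_pass * y[C_SI(j) * N_CONFIG + c];
      ydot[C_SI(j) * N_CONFIG + c] -= flux;
      ydot[A_UPSI] += flux;
      absorb(ydot, c, flux, p);
    }
    for (j = 0; j < 5; j++) {
      k_pass = fac * p[P_K_UP_CO];
      double flux = k_pass * y[C_CO(j) * N_CONFIG + c];
      ydot[C_CO(j) * N_CONFIG + c] -= flux;
      ydot[A_UPCO] += flux;
      absorb(ydot, c, flux, p);
    }
  }

  /* (g) active ileal uptake (si_9, si_10): shared Michaelis-Menten carrier */
  for (j = 8; j <= 9; j++) {
    double tot = 0.0;
    for (c = 0; c < N_CONFIG; c++) tot += y[C_SI(j) * N_CONFIG + c];
    if (tot <= 0.0) continue;
    for (c = 0; c < N_CONFIG; c++) {
      double flux = p[P_VMAX] * y[C_SI(j) * N_CONFIG + c] / (p[P_KM] + tot);
      ydot[C_SI(j) * N_CONFIG + c] -= flux;
      ydot[A_UPSI] += flux;
      absorb(ydot, c, flux, p);
    }
  }

  /* (h) deconjugation in terminal small intestine and colon */
  for (j = 5; j < 15; j++) {                    /* si_6..si_10, co_1..co_5 */
    int comp = (j < 10) ? C_SI(j) : C_CO(j - 10);
    double k_dec = (j < 10) ? p[P_K_DEC_SI] : p[P_K_DEC_CO];
    for (c = 0; c < N_CONFIG; c++) {
      int u_cfg;
      if (cfg_conj(c) == 0) continue;
      u_cfg = (c < 18) ? 3 * (c / 3) : 18;
      double flux = k_dec * y[comp * N_CONFIG + c];
      ydot[comp * N_CONFIG + c]     -= flux;
      ydot[comp * N_CONFIG + u_cfg] += flux;
    }
  }

  /* (i) colonic transformation of unconjugated primaries and UDCA */
  for (j = 0; j < 5; j++) {
    int comp = C_CO(j);
    double f;
    f = p[P_K_CA_DCA] * y[comp * N_CONFIG + 0];        /* uCA  -> uDCA */
    ydot[comp * N_CONFIG + 0] -= f; ydot[comp * N_CONFIG + 6]  += f;
    ydot[A_TRANS + 0] += f;
    f = p[P_K_CDCA_LCA] * y[comp * N_CONFIG + 3];      /* uCDCA -> uLCA */
    ydot[comp * N_CONFIG + 3] -= f; ydot[comp * N_CONFIG + 12] += f;
    ydot[A_TRANS + 1] += f;
    f = p[P_K_CDCA_UDCA] * y[comp * N_CONFIG + 3];     /* uCDCA -> uUDCA */
    ydot[comp * N_CONFIG + 3] -= f; ydot[comp * N_CONFIG + 9]  += f;
    ydot[A_TRANS + 2] += f;
    f = p[P_K_UDCA_LCA] * y[comp * N_CONFIG + 9];      /* uUDCA -> uLCA */
    ydot[comp * N_CONFIG + 9] -= f; ydot[comp * N_CONFIG + 12] += f;
    ydot[A_TRANS + 3] += f;
  }

  /* (k) plasma return toward the liver, faster for well-extracted forms */
  for (c = 0; c < N_CONFIG; c++) {
    double flux = p[P_K_PL] * psi_cfg(c, p) * y[C_PL * N_CONFIG + c];
    ydot[C_PL * N_CONFIG + c] -= flux;
    ydot[C_LI * N_CONFIG + c] += flux;
  }

  for (i = 0; i < N_STATE; i++) {
    if (!R_FINITE(ydot[i]))
      error("non-finite derivative in compartment %d, configuration %d at t=%g",
            i / N_CONFIG, i % N_CONFIG, *t);
  }
}
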