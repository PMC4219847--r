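/* Compiled mean-field right-hand side for deSolve.
 *
 * Species order: y[0]=A, y[1]=B, y[2]=AB, y[3]=ABB, y[4]=ABBB.
 * parms holds k1..k15 followed by the stationarity tolerance used by the
 * root function.  Mirrors the R-level registry/ode_rhs; a unit test
 * asserts the agreement of the two routes.
 */
#include <R.h>

static double parms[16];

void battle_initparms(void (*odeparms)(int *, double *)) {
  int n = 16;
  odeparms(&n, parms);
}

static void rates(const double *y, double *ydot) {
  double a  = y[0] > 0 ? y[0] : 0;
  double b  = y[1] > 0 ? y[1] : 0;
  double c1 = y[2] > 0 ? y[2] : 0;
  double c2 = y[3] > 0 ? y[3] : 0;
  double c3 = y[4] > 0 ? y[4] : 0;
  const double *k = parms;  /* k[0] = k1 */
  double r1 = k[0] * a * b,   r2 = k[1] * c1,  r3 = k[2] * c1,
         r4 = k[3] * c1,      r5 = k[4] * c1 * b,
         r6 = k[5] * c2,      r7 = k[6] * c2,  r8 = k[7] * c2,
         r9 = k[8] * c2,      r10 = k[9] * a * b * b,
         r11 = k[10] * c2 * b, r12 = k[11] * c3, r13 = k[12] * c3,
         r14 = k[13] * c3,    r15 = k[14] * c1 * b * b;
  ydot[0] = -r1 + r2 + r4 + r9 - r10;
  ydot[1] = -r1 + r2 + r3 - r5 + r6 + 2 * r8 + 2 * r9 - 2 * r10
            - r11 + r12 + 3 * r13 + 2 * r14 - 2 * r15;
  ydot[2] = r1 - r2 - r3 - r4 - r5 + r6 + r7 + r14 - r15;
  ydot[3] = r5 - r6 - r7 - r8 - r9 + r10 - r11 + r12;
  ydot[4] = r11 - r12 - r13 - r14 + r15;
}

/* With neq = 7 the last two states are the cumulative casualty counters
 * deadA and deadB, integrated alongside the species. */
void battle_derivs(int *neq, double *t, double *y, double *ydot,
                   double *yout, int *ip) {
  rates(y, ydot);
  if (*neq >= 7) {
    double c1 = y[2] > 0 ? y[2] : 0;
    double c2 = y[3] > 0 ? y[3] : 0;
    double c3 = y[4] > 0 ? y[4] : 0;
    const double *k = parms;
    ydot[5] = k[2] * c1 + k[7] * c2 + k[12] * c3;   /* A deaths */
    ydot[6] = k[3] * c1 + k[6] * c2;                /* B deaths */
  }
}

/* Root: infinity norm of the derivative drops below the stationarity
 * tolerance (parms[15]).  Guarded so the root cannot fire at t = 0. */
void battle_root(int *neq, double *t, double *y, int *ng, double *gout,
                 double *out, int *ip) {
  double ydot[5];
  rates(y, ydot);
  double m = 0;
  for (int i = 0; i < 5; ++i) {
    double v = ydot[i] < 0 ? -ydot[i] : ydot[i];
    if (v > m) m = v;
  }
  gout[0] = (*t <= 0) ? 1.0 : m - parms[15];
}
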