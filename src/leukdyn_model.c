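/* Compiled right-hand side of the four-compartment AML competition models,
 * in the calling convention expected by deSolve's compiled-model interface.
 *
 * State: y[0] = c1 healthy mitotic, y[1] = c2 healthy post-mitotic,
 *        y[2] = l1 leukemic mitotic, y[3] = l2 leukemic post-mitotic
 *        (all densities in cells per kg body weight; time in days).
 */
#include <R.h>

static double parms[12];
#define A_C   parms[0]  /* healthy fraction of self-renewal        */
#define P_C   parms[1]  /* healthy proliferation rate (1/day)      */
#define D_C   parms[2]  /* healthy post-mitotic death rate (1/day) */
#define A_L   parms[3]  /* leukemic fraction of self-renewal       */
#define P_L   parms[4]  /* leukemic proliferation rate (1/day)     */
#define D_L   parms[5]  /* leukemic post-mitotic death rate (1/day)*/
#define K     parms[6]  /* feedback strength (kg/cells)            */
#define DBAR  parms[7]  /* crowding death coefficient              */
#define MOD2  parms[8]  /* 1 = cytokine-independent leukemia       */
#define STIM  parms[9]  /* 1 = signal clamped to maximum           */
#define THR   parms[10] /* blast-fraction root threshold           */
#define TRIG  parms[11] /* mature-cell root level (cells/kg)       */

void leuk_initmod(void (*odeparms)(int *, double *))
{
    int n = 12;
    odeparms(&n, parms);
}

void leuk_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    /* guard against tiny solver undershoot below zero */
    double c1 = y[0] > 0.0 ? y[0] : 0.0;
    double c2 = y[1] > 0.0 ? y[1] : 0.0;
    double l1 = y[2] > 0.0 ? y[2] : 0.0;
    double l2 = y[3] > 0.0 ? y[3] : 0.0;

    /* Model 1: both lineages consume the cytokine; Model 2: healthy only */
    double consumers = (MOD2 > 0.5) ? c2 : (c2 + l2);
    double s  = (STIM > 0.5) ? 1.0 : 1.0 / (1.0 + K * consumers);
    double sl = (MOD2 > 0.5) ? 1.0 : s; /* leukemic signal */
    double crowd = DBAR * (c1 + l1);    /* niche-competition death */

    ydot[0] = (2.0 * A_C * s - 1.0) * P_C * c1 - crowd * c1;
    ydot[1] = 2.0 * (1.0 - A_C * s) * P_C * c1 - D_C * c2;
    ydot[2] = (2.0 * A_L * sl - 1.0) * P_L * l1 - crowd * l1;
    ydot[3] = 2.0 * (1.0 - A_L * sl) * P_L * l1 - D_L * l2;

    if (ip[0] >= 1) yout[0] = s;
}

/* root: marrow blast fraction l1/(c1+l1) crosses THR */
void leuk_root_blast(int *neq, double *t, double *y, int *ng,
                     double *gout, double *out, int *ip)
{
    gout[0] = y[2] - THR * (y[0] + y[2]);
}

/* root: healthy post-mitotic (mature) cells fall to TRIG */
void leuk_root_mature(int *neq, double *t, double *y, int *ng,
                      double *gout, double *out, int *ip)
{
    gout[0] = y[1] - TRIG;
}
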