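/* Compiled right-hand side of the coupled CIDNP polarization equations,
 * in the form deSolve expects for dllname-based models.
 *
 *   y[0] = P_R (polarization in radicals), y[1] = P (in products)
 *   r(t) = 1 / (1 + k t)          second-order radical decay, relative units
 *   dP_R/dt = -k r P_R - k gamma P_G r^2 - P_R / T1
 *   dP/dt   = +k r P_R + k gamma P_G r^2
 *
 * parms = (k = kt*R0, 1/T1, gamma*P_G)
 */
#include <R.h>

static double parms[3];

void cidnp_polarization_init(void (*odeparms)(int *, double *))
{
    int n = 3;
    odeparms(&n, parms);
}

void cidnp_polarization_rhs(int *neq, double *t, double *y, double *ydot,
                            double *yout, int *ip)
{
    double r = 1.0 / (1.0 + parms[0] * (*t));
    double pump = parms[0] * parms[2] * r * r;
    double transfer = parms[0] * r * y[0];
    ydot[0] = -transfer - pump - y[0] * parms[1];
    ydot[1] = transfer + pump;
}

/* Stacked variant: several independent (P_R, P) systems with their own
 * (k, 1/T1, gamma*P_G) triples integrated in one call, so a joint fit over
 * many traces costs one solver invocation per residual evaluation.
 *
 * mparms = (npairs, k_1, invT1_1, gPG_1, k_2, ...), padded to MAXPAIRS.
 */
#define CIDNP_MAXPAIRS 16

static double mparms[1 + 3 * CIDNP_MAXPAIRS];

void cidnp_polarization_multi_init(void (*odeparms)(int *, double *))
{
    int n = 1 + 3 * CIDNP_MAXPAIRS;
    odeparms(&n, mparms);
}

void cidnp_polarization_multi_rhs(int *neq, double *t, double *y,
                                  double *ydot, double *yout, int *ip)
{
    int npairs = (int) mparms[0];
    for (int j = 0; j < npairs; j++) {
        double k = mparms[1 + 3 * j];
        double invT1 = mparms[2 + 3 * j];
        double gPG = mparms[3 + 3 * j];
        double r = 1.0 / (1.0 + k * (*t));
        double pump = k * gPG * r * r;
        double transfer = k * r * y[2 * j];
        ydot[2 * j] = -transfer - pump - y[2 * j] * invT1;
        ydot[2 * j + 1] = transfer + pump;
    }
}
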