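/* S-system right-hand side for deSolve's compiled-code interface.
 *
 * dX_i/dt = alpha_i * prod_j X_j^{g_ij} - beta_i * prod_j X_j^{h_ij}
 *
 * Parameter vector layout (passed from R as `parms`):
 *   p[0]      n (number of state variables)
 *   p[1]      positivity floor applied to states before exponentiation
 *   p[2]      divergence ceiling (root function terminates integration)
 *   p[3..]    alpha (n), beta (n), g (n*n, column-major), h (n*n, column-major)
 *
 * Power terms are computed in log space: states are clamped at the floor,
 * so real-valued exponents always act on a strictly positive base.
 */

#include <R.h>
#include <Rinternals.h>
#include <math.h>

/* The R side pads `parms` to the fixed length SSYS_PARMS_LEN so the standard
 * deSolve odeparms callback (which requires a compile-time length) can be
 * used; unused tail entries are zero. */

#define SSYS_MAX_N 16
#define SSYS_PARMS_LEN (3 + 2 * SSYS_MAX_N + 2 * SSYS_MAX_N * SSYS_MAX_N)

static double ssys_parms[SSYS_PARMS_LEN];

void ssys_init(void (*odeparms)(int *, double *))
{
    int len = SSYS_PARMS_LEN;
    odeparms(&len, ssys_parms);
}

void ssys_deriv(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    const double *p = ssys_parms;
    const int n = (int) p[0];
    const double floor_ = p[1];
    const double *alpha = p + 3;
    const double *beta  = p + 3 + n;
    const double *g     = p + 3 + 2 * n;          /* column-major n x n */
    const double *h     = p + 3 + 2 * n + n * n;  /* column-major n x n */
    double ly[SSYS_MAX_N];
    int i, j;

    for (j = 0; j < n; j++) {
        double yj = y[j];
        if (!R_FINITE(yj) || yj < floor_) yj = floor_;
        ly[j] = log(yj);
    }
    for (i = 0; i < n; i++) {
        double sg = 0.0, sh = 0.0;
        for (j = 0; j < n; j++) {
            sg += g[i + n * j] * ly[j];
            sh += h[i + n * j] * ly[j];
        }
        ydot[i] = alpha[i] * exp(sg) - beta[i] * exp(sh);
    }
}

/* Root: fires (and terminates lsodar) when any state reaches the ceiling. */
void ssys_root(int *neq, double *t, double *y, int *ng, double *gout,
               double *rpar, int *ipar)
{
    const double ceiling = ssys_parms[2];
    double m = y[0];
    int j;
    for (j = 1; j < *neq; j++)
        if (y[j] > m) m = y[j];
    gout[0] = ceiling - m;
}
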