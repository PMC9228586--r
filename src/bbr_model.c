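/* Compiled right-hand side of the dimensionless burnt-bridge ratchet model,
 * in the deSolve compiled-model convention (initfunc + derivs).
 *
 * State vector: y[0] = xh (hub position, continuous),
 *               y[1 .. n]   = a_s at each node,
 *               y[n+1..2n]  = a_c at each node.
 * Parameter vector (see R/integrator.R):
 *   [0] n nodes, [1] xc (domain centre), [2] dx, [3] nu', [4] koff',
 *   [5] replenishment source koff'*atot/(1+K), [6] omega', [7] delta,
 *   [8] quadrature flag (0 rectangle, 1 trapezoid),
 *   [9] cap on the force-amplified unbinding rate omega'*exp(delta*|d|).
 *
 * The rate cap bounds the spectral radius of the kinetics: far from the
 * hub the Bell factor grows without limit while the complex held there is
 * kernel-suppressed to negligible mass, and uncapped rates only stiffen
 * the system without changing any observable.  Rates at the default cap
 * (500 in formation-rate units) are instantaneous relative to every other
 * process in the model.
 *
 * Node i sits at (i - (n-1)/2) * dx + xc, so mirror-image nodes are exact
 * floating-point negatives of each other about the centre, and the force
 * integral is accumulated over mirror pairs.  When the hub sits exactly at
 * the centre of a symmetric state the force is then exactly zero and the
 * stalled (symmetric) solution is preserved bitwise for all time -- the
 * symmetric state is a genuinely unstable equilibrium of the model, and
 * without this the round-off seed grows into spurious spontaneous motion
 * on long stall runs.
 *
 * Two global outputs are returned at every sample time: the instantaneous
 * hub velocity v (identical to dxh/dtau, never a finite difference) and
 * the consumption rate b = nu' * integral a_c dx.
 */
#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>

#define N_PARMS 10
static double parms[N_PARMS];

void bbr_initmod(void (*odeparms)(int *, double *))
{
    int n = N_PARMS;
    odeparms(&n, parms);
}

void bbr_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    const int n = (int) parms[0];
    const double xc = parms[1], dx = parms[2];
    const double nu = parms[3], koff = parms[4], src = parms[5];
    const double omega = parms[6], delta = parms[7];
    const int trap = (int) parms[8];
    const double rate_cap = parms[9];

    const double xh = y[0];
    const double *as = y + 1;
    const double *ac = y + 1 + n;
    double *das = ydot + 1;
    double *dac = ydot + 1 + n;

    const double c = 0.5 * (n - 1);
    const double off = xc - xh;          /* 0 when hub sits at the centre */

    double mass = 0.0;
    for (int i = 0; i < n; i++) {
        const double d = (i - c) * dx + off;      /* x_i - xh */
        double w = dx;
        if (trap && (i == 0 || i == n - 1)) w = 0.5 * dx;

        const double g = exp(-0.5 * d * d);
        const double form = g * as[i];
        double unb = 0.0;
        if (omega > 0.0) {
            double arg = delta * fabs(d);
            if (arg > 700.0) arg = 700.0;     /* avoid overflow to Inf */
            double rate = omega * exp(arg);
            if (rate > rate_cap) rate = rate_cap;
            unb = rate * ac[i];
        }
        dac[i] = form - nu * ac[i] - unb;
        das[i] = src - koff * as[i] - form + unb;

        mass += ac[i] * w;
    }

    /* force = -integral (xh - x) a_c dx, accumulated over mirror pairs so a
     * symmetric complex field about the hub cancels exactly */
    double force = 0.0;
    for (int i = 0, j = n - 1; i < j; i++, j--) {
        double wi = dx, wj = dx;
        if (trap && i == 0) { wi = 0.5 * dx; wj = 0.5 * dx; }
        const double di = (i - c) * dx + off;
        const double dj = (j - c) * dx + off;
        force += di * ac[i] * wi + dj * ac[j] * wj;
    }
    if (n % 2 == 1) {
        const int m = (n - 1) / 2;
        force += off * ac[m] * dx;       /* (m - c) == 0 */
    }
    ydot[0] = force;

    if (ip[0] >= 2) {
        yout[0] = force;       /* v */
        yout[1] = nu * mass;   /* b */
    }
}

static const R_CMethodDef c_entries[] = {
    {NULL, NULL, 0}
};

void R_init_bbrmotor(DllInfo *dll)
{
    R_registerRoutines(dll, c_entries, NULL, NULL, NULL);
    /* deSolve looks bbr_derivs / bbr_initmod up in the symbol table */
    R_useDynamicSymbols(dll, TRUE);
}
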