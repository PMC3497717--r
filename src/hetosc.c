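/* Compiled right-hand side of the reduced pre-Botzinger network for use
 * with deSolve's compiled-model interface.  Per-neuron parameters are
 * passed through deSolve's `rpar` mechanism: inside the solver they are
 * appended to the output vector `yout` after the `nout` output slots.
 *
 * rpar layout:
 *   [0] N (number of collocation nodes)
 *   [1] Poincare section level (weighted mean voltage), used by net_root
 *   [2 .. 2+10N) ten per-node blocks of length N, in order:
 *       C, gNa, gl, VNa, Vl, Vsyn, gsyn, eps, Iapp, w
 *
 * State layout: y = (V_1..V_N, h_1..h_N).
 */

#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>

static double sgate(double V)
{
    return 1.0 / (1.0 + exp(-(V + 40.0) / 5.0));
}

void net_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    int nout = ip[0];
    double *rp = yout + nout;
    int N = (int) rp[0];
    double *Cm   = rp + 2;
    double *gNa  = Cm   + N;
    double *gl   = gNa  + N;
    double *VNa  = gl   + N;
    double *Vl   = VNa  + N;
    double *Vsyn = Vl   + N;
    double *gsyn = Vsyn + N;
    double *eps  = gsyn + N;
    double *Iapp = eps  + N;
    double *w    = Iapp + N;
    double *V = y, *h = y + N;
    double *dV = ydot, *dh = ydot + N;
    double S = 0.0;
    int i;

    /* quadrature approximation of the population coupling integral */
    for (i = 0; i < N; i++)
        S += w[i] * sgate(V[i]);

    for (i = 0; i < N; i++) {
        double m    = 1.0 / (1.0 + exp(-(V[i] + 37.0) / 6.0));
        double hinf = 1.0 / (1.0 + exp((V[i] + 44.0) / 6.0));
        dV[i] = (-gNa[i] * m * h[i] * (V[i] - VNa[i])
                 - gl[i] * (V[i] - Vl[i])
                 + gsyn[i] * (Vsyn[i] - V[i]) * S
                 + Iapp[i]) / Cm[i];
        /* dh/dt = (hinf - h)/tau with tau = 1/(eps*cosh((V+44)/12)) */
        dh[i] = (hinf - h[i]) * eps[i] * cosh((V[i] + 44.0) / 12.0);
    }
    if (nout > 0)
        yout[0] = S;
}

/* Root function: weighted mean voltage crossing the section level. */
void net_root(int *neq, double *t, double *y, int *ng, double *gout,
              double *out, int *ip)
{
    double *rp = out + ip[0];
    int N = (int) rp[0];
    double level = rp[1];
    double *w = rp + 2 + 9 * N;
    double vbar = 0.0;
    int i;
    for (i = 0; i < N; i++)
        vbar += w[i] * y[i];
    gout[0] = vbar - level;
}

/* No-op event: lets lsodar continue through section crossings while
 * recording every root time. */
void net_event(int *n, double *t, double *y)
{
}

static const R_CMethodDef cMethods[] = {
    {"net_derivs", (DL_FUNC) &net_derivs, 6},
    {"net_root",   (DL_FUNC) &net_root,   7},
    {"net_event",  (DL_FUNC) &net_event,  3},
    {NULL, NULL, 0}
};

void R_init_hetosc(DllInfo *dll)
{
    R_registerRoutines(dll, cMethods, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
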