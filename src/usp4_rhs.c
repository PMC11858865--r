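/* Compiled right-hand side for the open-loop flow-through dissolution
 * simulator: per-bin solid mass (mg), dissolved mass in the cell (mg),
 * collected effluent (mg).  Diffusion-layer rate with h = min(r, hmax),
 * bulk concentration from the mixed cell, first-order washout.
 *
 * parms layout: [0] nb, [1] scalar, [2] Cs (mg/mL), [3] kw = Q/V (1/min),
 * [4] D (cm2/min), [5] hmax (cm), [6] density (mg/cm3), [7] V (mL),
 * [8..] particle counts per bin (padded to MAXBINS).
 */
#include <R.h>
#include <math.h>

#define MAXBINS 32
static double parms[8 + MAXBINS];

void usp4_init(void (*odeparms)(int *, double *))
{
    int N = 8 + MAXBINS;
    odeparms(&N, parms);
}

void usp4_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    int nb = (int) parms[0];
    double scalar = parms[1], Cs = parms[2], kw = parms[3];
    double D = parms[4], hmax = parms[5], dens = parms[6], V = parms[7];
    double Mcell = y[nb];
    double Cb = (Mcell > 0 ? Mcell : 0) / V;
    double driving = Cs - Cb;
    double tot = 0.0;
    for (int i = 0; i < nb; i++) {
        double m = y[i], Ni = parms[8 + i], rate = 0.0;
        if (m > 0 && Ni > 0 && driving > 0 && scalar > 0) {
            double r = cbrt(3.0 * m / (4.0 * M_PI * dens * Ni));
            double h = r < hmax ? r : hmax;
            rate = scalar * Ni * 4.0 * M_PI * r * (r + h) * (D / h) * driving;
        }
        ydot[i] = -rate;
        tot += rate;
    }
    ydot[nb] = tot - kw * Mcell;
    ydot[nb + 1] = kw * Mcell;
}
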