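/* Generic mass-action network right-hand side for deSolve.
 *
 * The model structure is flattened into the parms vector (padded to a
 * fixed length so it can be copied by odeparms):
 *   parms[0] = n_species, parms[1] = n_reactions, then per reaction:
 *   k_eff (rate constant x constant stimulus gate level), substrate index,
 *   product index, n_catalysts, catalyst indices... (all 1-based).
 * Rate law: v = k_eff * (sum of catalyst amounts, 1 if none) * [substrate].
 * Stimulus gates are constant step levels for t >= 0, so they are folded
 * into k_eff at setup time and the system is autonomous.
 */
#include <R.h>

#define MTORAA_PARMS_LEN 1024

static double parms[MTORAA_PARMS_LEN];

void mtoraa_initmod(void (*odeparms)(int *, double *))
{
    int N = MTORAA_PARMS_LEN;
    odeparms(&N, parms);
}

void mtoraa_derivs(int *neq, double *t, double *y, double *ydot,
                   double *yout, int *ip)
{
    int ns = (int) parms[0];
    int nr = (int) parms[1];
    int off = 2, i, r, c;

    for (i = 0; i < ns; i++)
        ydot[i] = 0.0;

    for (r = 0; r < nr; r++) {
        double k = parms[off++];
        int sub = (int) parms[off++] - 1;
        int prod = (int) parms[off++] - 1;
        int ncat = (int) parms[off++];
        double cat = 1.0;
        if (ncat > 0) {
            cat = 0.0;
            for (c = 0; c < ncat; c++)
                cat += y[(int) parms[off++] - 1];
        }
        {
            double v = k * cat * y[sub];
            ydot[sub] -= v;
            ydot[prod] += v;
        }
    }
}
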