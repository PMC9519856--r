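/* Compiled right-hand sides for the five MMTT insulin-kinetics models,
 * in the standard deSolve compiled-model layout. Forcing inputs (plasma
 * glucose, plasma amino acids, and a model-specific third signal) are
 * interpolated by deSolve at C level.
 *
 * Parameter slots (see R/kinetic_models.R for the model equations):
 *   parms[0] model id (1..5)        parms[4] p1 (k_gl or k_gl1)
 *   parms[1] k_i                    parms[5] p2 (k_aa, k_gl2 or k_glrem)
 *   parms[2] BR_I                   parms[6] p3 (k_aa for M2/M3/M5)
 *   parms[3] G_b                    parms[7] p4 (M5 remote elimination rate)
 *
 * Forcing slots:
 *   forc[0] G(t)   forc[1] AA(t)
 *   forc[2] dG/dt (M2), k_AA(t) (M4), unused otherwise
 */

#include <R.h>
#include <math.h>

static double parms[8];
static double forc[3];

#define MODEL parms[0]
#define KI    parms[1]
#define BRI   parms[2]
#define GB    parms[3]
#define P1    parms[4]
#define P2    parms[5]
#define P3    parms[6]
#define P4    parms[7]

#define GLU   forc[0]
#define AAC   forc[1]
#define AUX   forc[2]

void insukin_initmod(void (*odeparms)(int *, double *))
{
    int n = 8;
    odeparms(&n, parms);
}

void insukin_initforc(void (*odeforcs)(int *, double *))
{
    int n = 3;
    odeforcs(&n, forc);
}

void insukin_deriv(int *neq, double *t, double *y, double *ydot,
                   double *yout, int *ip)
{
    double I = y[0];

    switch ((int) MODEL) {
    case 1: /* dI = k_gl*G + k_aa*AA - k_i*I + BR_I */
        ydot[0] = P1 * GLU + P2 * AAC - KI * I + BRI;
        break;
    case 2: /* dI = k_gl1*G + k_gl2*dG + k_aa*AA - k_i*I + BR_I */
        ydot[0] = P1 * GLU + P2 * AUX + P3 * AAC - KI * I + BRI;
        break;
    case 3: /* dI = k_gl1*G^k_gl2 + k_aa*AA - k_i*I + BR_I */
        ydot[0] = P1 * pow(GLU, P2) + P3 * AAC - KI * I + BRI;
        break;
    case 4: /* dI = k_gl*G + k_aa(t)*AA - k_i*I + BR_I */
        ydot[0] = P1 * GLU + AUX * AAC - KI * I + BRI;
        break;
    case 5: /* remote glucose compartment, suprabasal */
        ydot[0] = P1 * y[1] + P3 * AAC - KI * I + BRI;
        ydot[1] = -P4 * y[1] + P2 * (GLU - GB);
        break;
    default:
        ydot[0] = 0.0;
    }
}
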