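/* Right-hand sides of the nondimensional two-gene oscillator families,
 * in the compiled-function form expected by deSolve.
 *
 * State: y[0] = x (activator), y[1] = y (repressor), time in units of
 * 1/delta_R.  Parameter vector (set through osc_initmod):
 *   p[0] design code: 1 competition, 2 post-translational, 3 non-competition,
 *        4 generalized non-competition, 5 Atkinson full competition,
 *        6 Smolen shared-promoter competition
 *   p[1] alpha, p[2] beta, p[3] gamma, p[4] sigma, p[5] sigma_prime,
 *   p[6] delta (= delta_A/delta_R), p[7] n, p[8] m
 */

#include <R.h>
#include <Rmath.h>

static double parms[9];

void osc_initmod(void (*odeparms)(int *, double *))
{
    int n = 9;
    odeparms(&n, parms);
}

void osc_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    const int    design = (int) parms[0];
    const double a  = parms[1], b = parms[2], g = parms[3];
    const double s  = parms[4], sp = parms[5], D = parms[6];
    const double n  = parms[7], m = parms[8];

    double x  = y[0], yy = y[1];
    double xn = R_pow(x, n), ym = R_pow(yy, m);
    double num  = 1.0 + a * xn;
    double satx = 1.0 + xn;
    double H, G;

    switch (design) {
    case 2:  /* repressor catalyses activator degradation */
        H = num / satx;
        G = num / satx;
        ydot[0] = D * (b * H - x * (1.0 + sp * yy));
        break;
    case 3:  /* independent binding sites: occupancies multiply */
    case 4:
        H = num / (satx * (1.0 + s * ym));
        G = num / satx;
        ydot[0] = D * (b * H - x);
        break;
    case 6:  /* both genes read the same competitive promoter */
        H = num / (satx + s * ym);
        G = H;
        ydot[0] = D * (b * H - x);
        break;
    default: /* 1, 5: mutually exclusive binding: occupancies sum */
        H = num / (satx + s * ym);
        G = num / satx;
        ydot[0] = D * (b * H - x);
        break;
    }
    ydot[1] = D * g * G - yy;
}
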