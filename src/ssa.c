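/* Exact (Gillespie direct-method) simulation of the birth-death reaction
 * network realizing one oscillator design.
 *
 * Species: A (activator molecules), R (repressor molecules); x = A/Omega,
 * y = R/Omega.  Time is in units of 1/delta_R; propensities are Omega times
 * the nondimensional macroscopic rates, so the Omega -> Inf mean field is
 * the deterministic ODE system:
 *   A birth:  Omega * D * beta * H(x, y)
 *   A death:  D * A              (design 2: D * A * (1 + sigma' * y))
 *   R birth:  Omega * D * gamma * G(x)
 *   R death:  R
 * The trajectory is recorded on a regular grid of step dt; uses R's RNG so
 * set.seed() gives bit-identical runs.
 */

#include <R.h>
#include <Rmath.h>
#include <Rinternals.h>

/* small-integer powers: the Hill exponents are multimer degrees */
static double ipow(double x, int k)
{
    double r = 1.0;
    while (k-- > 0) r *= x;
    return r;
}

static void rates(int design, const double *p, double x, double y,
                  double omega, double *prop)
{
    const double a = p[0], b = p[1], g = p[2], s = p[3], sp = p[4],
                 D = p[5];
    const int n = (int) p[6], m = (int) p[7];
    double xn = ipow(x, n), ym = ipow(y, m);
    double num = 1.0 + a * xn, satx = 1.0 + xn;
    double H, G;

    switch (design) {
    case 2:
        H = num / satx; G = H;
        prop[1] = D * x * omega * (1.0 + sp * y);
        break;
    case 3: case 4:
        H = num / (satx * (1.0 + s * ym)); G = num / satx;
        prop[1] = D * x * omega;
        break;
    case 6:
        H = num / (satx + s * ym); G = H;
        prop[1] = D * x * omega;
        break;
    default:
        H = num / (satx + s * ym); G = num / satx;
        prop[1] = D * x * omega;
        break;
    }
    prop[0] = omega * D * b * H;
    prop[2] = omega * D * g * G;
    prop[3] = y * omega;
}

SEXP C_ssa_run(SEXP s_design, SEXP s_params, SEXP s_omega, SEXP s_init,
               SEXP s_tend, SEXP s_dt, SEXP s_maxevents)
{
    const int    design = asInteger(s_design);
    const double omega  = asReal(s_omega);
    const double tend   = asReal(s_tend);
    const double dt     = asReal(s_dt);
    const double maxev  = asReal(s_maxevents);
    const double *p     = REAL(s_params);

    double A = REAL(s_init)[0], R_ = REAL(s_init)[1];
    int nsamp = (int) floor(tend / dt) + 1;

    SEXP s_time = PROTECT(allocVector(REALSXP, nsamp));
    SEXP s_A    = PROTECT(allocVector(REALSXP, nsamp));
    SEXP s_R    = PROTECT(allocVector(REALSXP, nsamp));
    double *Ts = REAL(s_time), *As = REAL(s_A), *Rs = REAL(s_R);

    GetRNGstate();
    double t = 0.0, nev = 0.0, prop[4];
    int isamp = 0;

    while (isamp < nsamp) {
        rates(design, p, A / omega, R_ / omega, omega, prop);
        double tot = prop[0] + prop[1] + prop[2] + prop[3];
        double tnext = (tot > 0.0) ? t + exp_rand() / tot : R_PosInf;

        while (isamp < nsamp && isamp * dt < tnext) {
            Ts[isamp] = isamp * dt;
            As[isamp] = A;
            Rs[isamp] = R_;
            isamp++;
        }
        if (isamp >= nsamp || tnext > tend) break;
        t = tnext;

        double u = unif_rand() * tot;
        if      (u < prop[0])                     A  += 1.0;
        else if (u < prop[0] + prop[1])           A  -= 1.0;
        else if (u < prop[0] + prop[1] + prop[2]) R_ += 1.0;
        else                                      R_ -= 1.0;

        nev += 1.0;
        if (nev >= maxev) break;
    }
    PutRNGstate();

    /* pad any remaining grid points with the final state */
    for (; isamp < nsamp; isamp++) {
        Ts[isamp] = isamp * dt;
        As[isamp] = A;
        Rs[isamp] = R_;
    }

    SEXP out = PROTECT(allocVector(VECSXP, 4));
    SET_VECTOR_ELT(out, 0, s_time);
    SET_VECTOR_ELT(out, 1, s_A);
    SET_VECTOR_ELT(out, 2, s_R);
    SET_VECTOR_ELT(out, 3, ScalarReal(nev));
    SEXP nm = PROTECT(allocVector(STRSXP, 4));
    SET_STRING_ELT(nm, 0, mkChar("time"));
    SET_STRING_ELT(nm, 1, mkChar("A"));
    SET_STRING_ELT(nm, 2, mkChar("R"));
    SET_STRING_ELT(nm, 3, mkChar("n_events"));
    setAttrib(out, R_NamesSymbol, nm);
    UNPROTECT(5);
    return out;
}
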