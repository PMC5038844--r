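/* Compiled right-hand side of the four-state dynamic gas-exchange model,
 * in the deSolve compiled-model interface. State vector:
 *   y[0] = a   pore area (um^2)
 *   y[1] = Ci  intercellular CO2 (umol mol^-1)
 *   y[2] = Cc  carboxylation-site CO2 (umol mol^-1)
 *   y[3] = L   efficiency state (dimensionless)
 * One forcing: PPFD(t) (umol m^-2 s^-1).
 * Parameter order must match .stomdyn_parm_vector() in R/simulate.R.
 */
#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>

#define N_PARMS 26

static double parms[N_PARMS];
static double forc[1];

#define amin    parms[0]
#define amax    parms[1]
#define alphaL  parms[2]
#define ki      parms[3]
#define kd      parms[4]
#define Vcmax   parms[5]
#define Jmax    parms[6]
#define Rd      parms[7]
#define alphaP  parms[8]
#define Se      parms[9]
#define Sa      parms[10]
#define gm      parms[11]
#define thetaL  parms[12]
#define thetaJ  parms[13]
#define SDsi    parms[14]
#define lsi     parms[15]
#define Dw      parms[16]
#define Vair    parms[17]
#define gb      parms[18]
#define Ca      parms[19]
#define O2f     parms[20]
#define KcT     parms[21]
#define KoT     parms[22]
#define GstarT  parms[23]
#define convda  parms[24]
#define convdp  parms[25]

#define PPFD forc[0]

void stomdyn_initparms(void (*odeparms)(int *, double *))
{
    int n = N_PARMS;
    odeparms(&n, parms);
}

void stomdyn_initforcs(void (*odeforcs)(int *, double *))
{
    int n = 1;
    odeforcs(&n, forc);
}

/* lower root of theta*y^2 - (x+asym)*y + x*asym = 0 */
static double nrh(double x, double asym, double theta)
{
    double s, disc;
    if (theta < 1e-12) return x * asym / (x + asym);
    s = x + asym;
    disc = s * s - 4.0 * theta * x * asym;
    if (disc < 0.0) disc = 0.0;
    return (s - sqrt(disc)) / (2.0 * theta);
}

void stomdyn_derivs(int *neq, double *t, double *y, double *ydot,
                    double *yout, int *ip)
{
    double a, Ci, Cc, L, I, as, gs, gt, J, Wc, Wj, AG, a_si;

    a = y[0]; Ci = y[1]; Cc = y[2]; L = y[3];
    if (!R_FINITE(a) || !R_FINITE(Ci) || !R_FINITE(Cc) || !R_FINITE(L))
        Rf_error("non-finite state at t = %g: a=%g Ci=%g Cc=%g L=%g",
                 *t, a, Ci, Cc, L);

    /* the drift confines L to [0,1] and a, Ci, Cc to >= 0; clamp transient
     * solver overshoot for the algebraic sub-expressions only */
    if (L < 0.0) L = 0.0;
    if (L > 1.0) L = 1.0;
    if (a < 0.0) a = 0.0;
    if (Cc < 0.0) Cc = 0.0;
    I = PPFD > 0.0 ? PPFD : 0.0;

    as = (amin + nrh(alphaL * I, amax - amin, thetaL)) * L;
    ydot[0] = (y[0] < as) ? (as - y[0]) / ki : (as - y[0]) / kd;

    a_si = a * 1e-12;
    gs = SDsi * Dw * a_si / (Vair * (lsi + M_PI_2 * sqrt(a_si / M_PI)));
    gt = (gs > 0.0) ? 1.0 / (1.6 / gs + 1.37 / gb) : 0.0;

    J = nrh(alphaP * I, Jmax, thetaJ);
    Wc = Vcmax * (Cc - GstarT) / (Cc + KcT * (1.0 + O2f / KoT));
    Wj = (J / 4.0) * (Cc - GstarT) / (Cc + 2.0 * GstarT);
    AG = Wc < Wj ? Wc : Wj;
    if (AG < 0.0) AG = 0.0;

    ydot[1] = (gt * (Ca - Ci) - gm * (Ci - Cc)) * convda;
    ydot[2] = (gm * (Ci - Cc) + Rd - AG * L) * convdp;
    ydot[3] = Se * (1.0 - L) - Sa * AG * L;

    if (ip[0] >= 3) {
        yout[0] = gs;
        yout[1] = AG;
        yout[2] = as;
    }
}

static const R_CMethodDef CEntries[] = {
    {"stomdyn_initparms", (DL_FUNC) &stomdyn_initparms, 1},
    {"stomdyn_initforcs", (DL_FUNC) &stomdyn_initforcs, 1},
    {"stomdyn_derivs",    (DL_FUNC) &stomdyn_derivs,    6},
    {NULL, NULL, 0}
};

void R_init_stomdyn(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);  /* deSolve looks the symbols up by name */
}
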