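/* Compiled right-hand side of the coupled bone adaptation / microdamage ODE
 * for use with deSolve (lsodar). State: y[0] = fBM, y[1] = D.
 *
 * Parameter vector (see .parms_vector in R/parameters.R):
 *  0 sigma  1 strain_rate  2 vn  3 a  4 b  5 alpha  6 E0  7 gammaE
 *  8 AOBL_min  9 AOBL_max  10 deltaB  11 gammaB
 * 12 AOCL_min 13 AOCL_max  14 deltaC  15 gammaC
 * 16 sigma0  17 sigma1  18 Enom  19 Fs
 */
#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>

#define N_PARMS 20
static double p[N_PARMS];

void bone_init(void (*odeparms)(int *, double *))
{
    int n = N_PARMS;
    odeparms(&n, p);
}

void bone_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    double fBM = y[0];
    double D = y[1];
    /* keep the surface law defined if the solver probes slightly outside */
    if (fBM > 1.0 - 1e-9) fBM = 1.0 - 1e-9;
    if (fBM < 1e-9)       fBM = 1e-9;

    double Sv   = p[3] * sqrt(1.0 - fBM) * (1.0 - p[4] * (1.0 - fBM));
    double E    = p[6] * pow(p[1], p[7]) * fBM * fBM * fBM;
    double psi  = p[0] * p[0] / (2.0 * E);
    double hb   = (psi <= 0.0) ? 0.0
                  : pow(psi, p[11]) / (pow(p[10], p[11]) + pow(psi, p[11]));
    double AOBL = p[8] + (p[9] - p[8]) * hb;
    double hc   = pow(p[14], p[15]) / (pow(p[14], p[15]) + pow(psi, p[15]));
    double AOCL = p[12] + (p[13] - p[12]) * hc;
    double vD   = pow(10.0, (p[0] - p[16]) / p[17]) * p[18] / E;
    double Df   = vD * p[2];
    double Dr   = (AOBL + (p[19] - 1.0) * AOCL) * p[5] * Sv * D / fBM;

    ydot[0] = (AOBL - AOCL) * p[5] * Sv;
    ydot[1] = Df - Dr;
}

/* root at D = 1: failure of the bone pocket terminates the integration */
void bone_root(int *neq, double *t, double *y, int *ng, double *gout,
               double *out, int *ip)
{
    gout[0] = y[1] - 1.0;
}

static const R_CMethodDef CEntries[] = {
    {"bone_init",   (DL_FUNC) &bone_init,   1},
    {"bone_derivs", (DL_FUNC) &bone_derivs, 6},
    {"bone_root",   (DL_FUNC) &bone_root,   7},
    {NULL, NULL, 0}
};

void R_init_equibone(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
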