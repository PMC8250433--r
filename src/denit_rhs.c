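/* Compiled right-hand sides for the denitrification batch models.
 *
 * Mirrors the reference R implementations in R/rates.R; the two are
 * cross-checked in the test suite. States are integrated either in linear
 * space or as u = ln(x + eps) (log-state transform for positivity); the
 * transform flag and the floor eps are passed with the parameters.
 *
 * Parameter vector layout (must match .pack_parms in R/simulate.R):
 *  0 a_NarR_NO3   1 a_NarR_NO2   2 kdec_NarR   3 I_FnrP    4 p
 *  5 a_NNR        6 kdec_NNR     7 I_NNR       8 q         9 K_FnrP
 * 10 K_NarR      11 K_NNR       12 beta_E     13 kdec_E   14 kmax_NAR
 * 15 kmax_NIR    16 numax_NAR   17 numax_NIR  18 K_NO3    19 K_NO2
 * 20 Ireac_NAR   21 Ireac_NIR   22 numax_O2   23 K_O2     24 Y_O2
 * 25 kLa_O2      26 kLa_N2      27 H_O2       28 H_N2     29 Vl_over_Vg
 * 30 eps         31 logspace    32 K_N        33 K_N2
 *
 * State layouts:
 *  core (monod):      0 C_O2  1 C_NO3  2 C_NO2  3 C_N2  4 G_O2  5 G_N2  6 B
 *  enzyme:            core + 7 X_NarR  8 Xhat_NNR  9 E_NAR  10 E_NIR
 *  simplified:        core + 7 E_NAR  8 E_NIR
 */

#include <R.h>
#include <math.h>

#define N_PARMS 34
static double parms[N_PARMS];

#define A_NARR_NO3 parms[0]
#define A_NARR_NO2 parms[1]
#define KDEC_NARR  parms[2]
#define I_FNRP     parms[3]
#define HILL_P     parms[4]
#define A_NNR      parms[5]
#define KDEC_NNR   parms[6]
#define I_NNR      parms[7]
#define HILL_Q     parms[8]
#define K_FNRP     parms[9]
#define K_NARR     parms[10]
#define K_NNR      parms[11]
#define BETA_E     parms[12]
#define KDEC_E     parms[13]
#define KMAX_NAR   parms[14]
#define KMAX_NIR   parms[15]
#define NUMAX_NAR  parms[16]
#define NUMAX_NIR  parms[17]
#define K_NO3      parms[18]
#define K_NO2      parms[19]
#define IREAC_NAR  parms[20]
#define IREAC_NIR  parms[21]
#define NUMAX_O2   parms[22]
#define K_O2       parms[23]
#define Y_O2       parms[24]
#define KLA_O2     parms[25]
#define KLA_N2     parms[26]
#define H_O2       parms[27]
#define H_N2       parms[28]
#define VL_OVER_VG parms[29]
#define EPS_FLOOR  parms[30]
#define LOGSPACE   parms[31]
#define K_N_SIMPL  parms[32]
#define K_N2_SIMPL parms[33]

static const double N_AVOGADRO = 6.02214076e23;

void denit_initparms(void (*odeparms)(int *, double *))
{
    int n = N_PARMS;
    odeparms(&n, parms);
}

static double hill_inhib(double c, double i, double n)
{
    return 1.0 / (1.0 + pow(c / i, n));
}

/* decode integrated variable into physical value (>= 0) */
static double decode(double u)
{
    if (LOGSPACE > 0.5) {
        double x = exp(u) - EPS_FLOOR;
        return x > 0.0 ? x : 0.0;
    }
    return u > 0.0 ? u : 0.0;
}

/* chain rule back onto the integrated variable */
static double encode_deriv(double dx, double u)
{
    if (LOGSPACE > 0.5)
        return dx * exp(-u);
    return dx;
}

/* shared solute/gas/biomass block; x holds decoded core states */
static void core_derivs(const double *x, double r_NO3, double r_NO2,
                        double *dx)
{
    double C_O2 = x[0], C_N2 = x[3], G_O2 = x[4], G_N2 = x[5], B = x[6];
    double r_O2 = NUMAX_O2 * B * C_O2 / (C_O2 + K_O2);
    double tr_O2 = KLA_O2 * (G_O2 / H_O2 - C_O2);
    double tr_N2 = KLA_N2 * (G_N2 / H_N2 - C_N2);

    dx[0] = -r_O2 + tr_O2;
    dx[1] = -r_NO3;
    dx[2] = r_NO3 - r_NO2;
    dx[3] = 0.5 * r_NO2 + tr_N2;
    dx[4] = -VL_OVER_VG * tr_O2;
    dx[5] = -VL_OVER_VG * tr_N2;
    dx[6] = Y_O2 * (2.0 / 7.0) * r_O2;
}

static double reduction(double C_sub, double C_O2, double rmax,
                        double K_sub, double I_reac)
{
    return rmax * C_sub / (C_sub + K_sub) * I_reac / (I_reac + C_O2);
}

void derivs_enzyme(int *neq, double *t, double *y, double *ydot,
                   double *yout, int *ip)
{
    double x[11], dx[11];
    int i;
    for (i = 0; i < 11; i++) x[i] = decode(y[i]);
    {
        double C_O2 = x[0], C_NO3 = x[1], C_NO2 = x[2], B = x[6];
        double X_NarR = x[7], Xhat = x[8], E_NAR = x[9], E_NIR = x[10];
        double X_FnrP = hill_inhib(C_O2, I_FNRP, HILL_P);
        double X_NNR = hill_inhib(C_O2, I_NNR, HILL_Q) * Xhat;
        double u = X_FnrP / K_FNRP, v = X_NarR / K_NARR;
        double f_nar = (u * v) / (1.0 + u + v + u * v);
        double f_nir = X_NNR / (X_NNR + K_NNR);
        double r_NO3 = reduction(C_NO3, C_O2, KMAX_NAR * E_NAR / N_AVOGADRO,
                                 K_NO3, IREAC_NAR);
        double r_NO2 = reduction(C_NO2, C_O2, KMAX_NIR * E_NIR / N_AVOGADRO,
                                 K_NO2, IREAC_NIR);
        core_derivs(x, r_NO3, r_NO2, dx);
        dx[7] = (A_NARR_NO3 * C_NO3 + A_NARR_NO2 * C_NO2) * (1.0 - X_NarR)
                - KDEC_NARR * X_NarR;
        dx[8] = A_NNR * C_NO2 * (1.0 - Xhat) - KDEC_NNR * Xhat;
        dx[9] = KDEC_E * (BETA_E * f_nar * B - E_NAR);
        dx[10] = KDEC_E * (BETA_E * f_nir * B - E_NIR);
    }
    for (i = 0; i < 11; i++) ydot[i] = encode_deriv(dx[i], y[i]);
}

void derivs_monod(int *neq, double *t, double *y, double *ydot,
                  double *yout, int *ip)
{
    double x[7], dx[7];
    int i;
    for (i = 0; i < 7; i++) x[i] = decode(y[i]);
    {
        double C_O2 = x[0], C_NO3 = x[1], C_NO2 = x[2], B = x[6];
        double r_NO3 = reduction(C_NO3, C_O2, NUMAX_NAR * B, K_NO3, IREAC_NAR);
        double r_NO2 = reduction(C_NO2, C_O2, NUMAX_NIR * B, K_NO2, IREAC_NIR);
        core_derivs(x, r_NO3, r_NO2, dx);
    }
    for (i = 0; i < 7; i++) ydot[i] = encode_deriv(dx[i], y[i]);
}

void derivs_simplified(int *neq, double *t, double *y, double *ydot,
                       double *yout, int *ip)
{
    double x[9], dx[9];
    int i;
    for (i = 0; i < 9; i++) x[i] = decode(y[i]);
    {
        double C_O2 = x[0], C_NO3 = x[1], C_NO2 = x[2], B = x[6];
        double E_NAR = x[7], E_NIR = x[8];
        double N_ox = C_NO3 + C_NO2;
        double f_nar = hill_inhib(C_O2, I_FNRP, HILL_P) *
                       N_ox / (N_ox + K_N_SIMPL);
        double f_nir = hill_inhib(C_O2, I_NNR, HILL_Q) *
                       C_NO2 / (C_NO2 + K_N2_SIMPL);
        double r_NO3 = reduction(C_NO3, C_O2, KMAX_NAR * E_NAR / N_AVOGADRO,
                                 K_NO3, IREAC_NAR);
        double r_NO2 = reduction(C_NO2, C_O2, KMAX_NIR * E_NIR / N_AVOGADRO,
                                 K_NO2, IREAC_NIR);
        core_derivs(x, r_NO3, r_NO2, dx);
        dx[7] = KDEC_E * (BETA_E * f_nar * B - E_NAR);
        dx[8] = KDEC_E * (BETA_E * f_nir * B - E_NIR);
    }
    for (i = 0; i < 9; i++) ydot[i] = encode_deriv(dx[i], y[i]);
}
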