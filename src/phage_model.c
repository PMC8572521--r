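/* Chemostat ODE right-hand side: two bacterial species, their phages and a
 * shared nutrient pool, with strategy-dependent lysis (constant, PtW, PtL),
 * a lysogenic/lytic growth switch, viral-shunt recycling and optional
 * sinusoidal forcing of the turnover rate.
 *
 * State vector y (normalized biovolume densities):
 *   y[0] B1, y[1] B2  uninfected bacteria (fast / slow grower)
 *   y[2] I1, y[3] I2  infected bacteria
 *   y[4] P1, y[5] P2  free phages
 *   y[6] N            dissolved nutrient
 *
 * Parameter vector (filled by phagestrat_init, order fixed; see R/model.R):
 *   0 x        metabolic rate [1/h]
 *   1 y1       metabolic scaling, fast grower
 *   2 y2       metabolic scaling, slow grower
 *   3 N_H      half-saturation density (normalized, == 1)
 *   4 i_norm   normalized adsorption rate [1/h]
 *   5 c        phage/bacteria biovolume conversion factor
 *   6 n        phage burst volume fraction
 *   7 s_max    maximum lysis rate [1/h]
 *   8 d        phage decay rate [1/h]
 *   9 D        mean turnover rate [1/h]
 *  10 N0       supply concentration (normalized)
 *  11 SH       PtL half-saturation (squared-density offset)
 *  12 r        PtW correction parameter
 *  13 H        PtW correction parameter
 *  14 s_switch growth-switch lysis rate [1/h]
 *  15 a        fluctuation amplitude fraction (< 1)
 *  16 T        fluctuation period [h]
 *  17 shunt    viral-shunt term on/off (1/0)
 *  18 strategy 0 none, 1 lytic, 2 ptw, 3 ptl
 */

#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>

#define NPAR 19
static double parms[NPAR];

void phagestrat_init(void (*odeparms)(int *, double *))
{
    int n = NPAR;
    odeparms(&n, parms);
}

static double lysis(int strategy, double host, double s_max,
                    double SH, double r, double H)
{
    double h2;
    switch (strategy) {
    case 1:                     /* lytic: constant rate */
        return s_max;
    case 2:                     /* PtW: decreasing in host density */
        h2 = host * r;
        return s_max / (h2 * h2 + H);
    case 3:                     /* PtL: increasing sigmoid */
        h2 = host * host;
        return s_max * h2 / (h2 + SH);
    default:                    /* none: no phage compartment */
        return 0.0;
    }
}

void phagestrat_derivs(int *neq, double *t, double *y, double *ydot,
                       double *yout, int *ip)
{
    const double x = parms[0], NH = parms[3], i_ads = parms[4];
    const double c = parms[5], n = parms[6], s_max = parms[7];
    const double d = parms[8], D = parms[9], N0 = parms[10];
    const double SH = parms[11], r = parms[12], H = parms[13];
    const double s_sw = parms[14], a = parms[15], T = parms[16];
    const int shunt = (int) parms[17];
    const int strategy = (int) parms[18];

    double yk[2] = { parms[1], parms[2] };
    double s[7];
    int k;

    /* negative excursions from the integrator are treated as zero density
     * when evaluating rates; the solution itself is not floored */
    for (k = 0; k < 7; k++)
        s[k] = y[k] > 0.0 ? y[k] : 0.0;

    double N = s[6];
    double Dt = (a > 0.0) ? a * D * sin(2.0 * M_PI * (*t) / T) + D : D;

    double dN = Dt * (N0 - N);

    for (k = 0; k < 2; k++) {
        double B = s[k], I = s[2 + k], P = s[4 + k];
        double G = x * yk[k] * N / (N + NH);
        double inf = i_ads * B * P;

        if (strategy == 0) {
            ydot[k] = G * B - x * B;
            ydot[2 + k] = 0.0;
            ydot[4 + k] = 0.0;
            dN -= G * B;
            continue;
        }

        double sk = lysis(strategy, B + I, s_max, SH, r, H);
        /* lysogenic growth switch: infected cells grow (and consume) only
         * while the induction rate is at or below the switching point;
         * purely lytic infections never grow */
        int grow = (strategy >= 2 && sk <= s_sw) ? 1 : 0;

        ydot[k] = G * B - x * B - inf;
        ydot[2 + k] = (1.0 + c) * inf + (grow ? G * I : 0.0) - x * I - sk * I;
        ydot[4 + k] = n * sk * I - c * inf - d * P;

        dN -= G * B;
        if (grow)
            dN -= G * I;
        if (shunt)
            dN += (1.0 - n) * sk * I;
    }
    ydot[6] = dN;
}

static const R_CMethodDef cMethods[] = {
    {"phagestrat_derivs", (DL_FUNC) &phagestrat_derivs, 6},
    {NULL, NULL, 0}
};

void R_init_phagestrat(DllInfo *dll)
{
    R_registerRoutines(dll, cMethods, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
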