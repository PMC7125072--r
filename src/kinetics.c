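/* Compiled right-hand sides for the batch-culture kinetic models.
 *
 * Parameter vector layout (passed from R, see pack_parms()):
 *   parms[0]      structure id: 1 monod, 2 first_order, 3 t1, 4 t2, 5 t3,
 *                 6 t1_nonlinear, 7 t2_nonlinear
 *   parms[1..7]   structure parameters (order documented per case below)
 *   parms[8]      yeast-extract extension flag (0/1)
 *   parms[9..11]  eta_E, Y_E, b_EP
 *
 * State y = (H, P, X, E) in mM, mM, g/L, mM.  Negative components caused
 * by integrator overshoot are clipped to zero before evaluation.
 */
#include <R.h>
#include <math.h>

static double parms[12];

void acetokin_init(void (*odeparms)(int *, double *))
{
    int n = 12;
    odeparms(&n, parms);
}

void acetokin_derivs(int *neq, double *t, double *y, double *ydot,
                     double *yout, int *ip)
{
    double H = y[0] > 0 ? y[0] : 0;
    double P = y[1] > 0 ? y[1] : 0;
    double X = y[2] > 0 ? y[2] : 0;
    double E = y[3] > 0 ? y[3] : 0;
    int structure = (int) parms[0];
    double dH = 0, Y = 1, kd = 0;

    switch (structure) {
    case 1: {                   /* monod: mu_max, K_H, Y, k_d */
        double mu = parms[1], KH = parms[2];
        Y = parms[3]; kd = parms[4];
        dH = -(mu * X / Y) * H / (KH + H);
        break;
    }
    case 2: {                   /* first_order: eta, Y, k_d */
        double eta = parms[1];
        Y = parms[2]; kd = parms[3];
        dH = -eta * X * H / Y;
        break;
    }
    case 3: {                   /* t1: eta, Y, k_d, H_t */
        double eta = parms[1], Ht = parms[4];
        Y = parms[2]; kd = parms[3];
        double Hs = H > Ht ? H - Ht : 0;
        dH = -eta * Hs * X / Y;
        break;
    }
    case 4: {                   /* t2: eta, Y, k_d, A, T */
        double eta = parms[1], A = parms[4], T = parms[5];
        Y = parms[2]; kd = parms[3];
        double F = 1.0 / (1.0 + exp(A * (T - H)));
        dH = -eta * X * H * F / Y;
        break;
    }
    case 5: {                   /* t3: mu_max_H, mu_max_R, K_H, K_R, Y, k_d */
        double muH = parms[1], muR = parms[2], KH = parms[3], KR = parms[4];
        Y = parms[5]; kd = parms[6];
        double num = muH * H / KH - muR * P / KR;
        double den = 1.0 + H / KH + P / KR;
        dH = -(X / Y) * num / den;
        break;
    }
    case 6: {                   /* t1_nonlinear: mu_max, K_H, Y, k_d, H_t */
        double mu = parms[1], KH = parms[2], Ht = parms[5];
        Y = parms[3]; kd = parms[4];
        double Hs = H > Ht ? H - Ht : 0;
        dH = -(mu * X / Y) * Hs / (KH + Hs);
        break;
    }
    case 7: {           /* t2_nonlinear: mu_max, K_H, Y, k_d, H_t, A, T */
        double mu = parms[1], KH = parms[2], Ht = parms[5];
        double A = parms[6], T = parms[7];
        Y = parms[3]; kd = parms[4];
        double f = 1.0 / (1.0 + exp(A * (Ht - H)));
        double F = 1.0 / (1.0 + exp(A * (T - H)));
        double Hf = H - Ht * f;
        dH = -(mu * X / Y) * (Hf / (KH + Hf)) * F;
        break;
    }
    default:
        error("unknown model structure id %d", structure);
    }

    double dP = -0.25 * dH;
    double dX = -Y * dH - kd * X;
    double dE = 0;

    if (parms[8] > 0.5) {       /* yeast-extract extension */
        double etaE = parms[9], YE = parms[10], bEP = parms[11];
        dE = -etaE * X * E / YE;
        dP += -bEP * dE;
        dX += -YE * dE;
    }

    ydot[0] = dH;
    ydot[1] = dP;
    ydot[2] = dX;
    ydot[3] = dE;
}
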