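/* Two-compartment (vitreous / aqueous humor) mass-action system for an
 * anti-VEGF antibody R binding homodimeric VEGF V at two identical sites:
 *   V + R  <-> VR   (forward 2*kon, reverse koff)
 *   R + VR <-> RVR  (forward kon,   reverse 2*koff)
 * Unidirectional vitreous -> aqueous transfer kel_i per species (amount
 * conserving, hence the V_vit/V_aq ratio on concentrations) and aqueous
 * clearance CL/V_aq. All concentrations in pM, time in days.
 *
 * State order: v_vit, r_vit, c_vit, h_vit, v_aq, r_aq, c_aq, h_aq
 * Parameters:  kel_r, kel_v, kel_c, kel_h, k_on, k_off, CL, V_in,
 *              V_vit, V_aq
 */
#include <R.h>

static double parms[10];
#define kel_r parms[0]
#define kel_v parms[1]
#define kel_c parms[2]
#define kel_h parms[3]
#define k_on  parms[4]
#define k_off parms[5]
#define CL    parms[6]
#define V_in  parms[7]
#define V_vit parms[8]
#define V_aq  parms[9]

void ocular_init(void (*odeparms)(int *, double *))
{
    int n = 10;
    odeparms(&n, parms);
}

/* analytic full Jacobian, column-major in pd (nrowpd x neq) */
void ocular_jac(int *neq, double *t, double *y, int *ml, int *mu,
                double *pd, int *nrowpd, double *yout, int *ip)
{
    double vv = y[0], rv = y[1], cv = y[2];
    double va = y[4], ra = y[5], ca = y[6];
    double ratio = V_vit / V_aq;
    double kcl   = CL / V_aq;
    int n = *nrowpd;
    for (int j = 0; j < (*neq) * n; j++) pd[j] = 0.0;
#define PD(i, j) pd[(j) * n + (i)]
    /* vitreous block */
    PD(0, 0) = -2.0 * k_on * rv - kel_v;
    PD(0, 1) = -2.0 * k_on * vv;
    PD(0, 2) = k_off;
    PD(1, 0) = -2.0 * k_on * rv;
    PD(1, 1) = -2.0 * k_on * vv - k_on * cv - kel_r;
    PD(1, 2) = k_off - k_on * rv;
    PD(1, 3) = 2.0 * k_off;
    PD(2, 0) = 2.0 * k_on * rv;
    PD(2, 1) = 2.0 * k_on * vv - k_on * cv;
    PD(2, 2) = -k_off - k_on * rv - kel_c;
    PD(2, 3) = 2.0 * k_off;
    PD(3, 1) = k_on * cv;
    PD(3, 2) = k_on * rv;
    PD(3, 3) = -2.0 * k_off - kel_h;
    /* vitreous -> aqueous transfer */
    PD(4, 0) = kel_v * ratio;
    PD(5, 1) = kel_r * ratio;
    PD(6, 2) = kel_c * ratio;
    PD(7, 3) = kel_h * ratio;
    /* aqueous block */
    PD(4, 4) = -2.0 * k_on * ra - kcl;
    PD(4, 5) = -2.0 * k_on * va;
    PD(4, 6) = k_off;
    PD(5, 4) = -2.0 * k_on * ra;
    PD(5, 5) = -2.0 * k_on * va - k_on * ca - kcl;
    PD(5, 6) = k_off - k_on * ra;
    PD(5, 7) = 2.0 * k_off;
    PD(6, 4) = 2.0 * k_on * ra;
    PD(6, 5) = 2.0 * k_on * va - k_on * ca;
    PD(6, 6) = -k_off - k_on * ra - kcl;
    PD(6, 7) = 2.0 * k_off;
    PD(7, 5) = k_on * ca;
    PD(7, 6) = k_on * ra;
    PD(7, 7) = -2.0 * k_off - kcl;
#undef PD
}

void ocular_derivs(int *neq, double *t, double *y, double *ydot,
                   double *yout, int *ip)
{
    double vv = y[0], rv = y[1], cv = y[2], hv = y[3];
    double va = y[4], ra = y[5], ca = y[6], ha = y[7];

    double ratio = V_vit / V_aq;   /* amount-conserving transfer factor */
    double kcl   = CL / V_aq;      /* aqueous clearance rate, 1/day */

    /* vitreous */
    ydot[0] = V_in / V_vit - 2.0 * k_on * vv * rv + k_off * cv - kel_v * vv;
    ydot[1] = -2.0 * k_on * vv * rv + k_off * cv
              - k_on * rv * cv + 2.0 * k_off * hv - kel_r * rv;
    ydot[2] = 2.0 * k_on * vv * rv - k_off * cv
              - k_on * rv * cv + 2.0 * k_off * hv - kel_c * cv;
    ydot[3] = k_on * rv * cv - 2.0 * k_off * hv - kel_h * hv;

    /* aqueous humor */
    ydot[4] = -2.0 * k_on * va * ra + k_off * ca
              + kel_v * vv * ratio - kcl * va;
    ydot[5] = -2.0 * k_on * va * ra + k_off * ca
              - k_on * ra * ca + 2.0 * k_off * ha
              + kel_r * rv * ratio - kcl * ra;
    ydot[6] = 2.0 * k_on * va * ra - k_off * ca
              - k_on * ra * ca + 2.0 * k_off * ha
              + kel_c * cv * ratio - kcl * ca;
    ydot[7] = k_on * ra * ca - 2.0 * k_off * ha
              + kel_h * hv * ratio - kcl * ha;
}
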