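/* Compiled right-hand side of the preBotC pacemaker-neuron model for
 * deSolve.  Must stay in exact agreement with the reference R
 * implementation in R/model_core.R (cross-checked by the test suite).
 *
 * States: V, h, n, ca_i, ca_tot, l.
 * Parameter vector layout is fixed; see .rhs_param_order in R/simulate.R.
 */
#include <R.h>
#include <math.h>

#define N_PAR 45
static double parms[N_PAR];

#define Cm        parms[0]
#define gNaP      parms[1]
#define gNa       parms[2]
#define gK        parms[3]
#define gL        parms[4]
#define gCAN      parms[5]
#define gCa       parms[6]
#define gh        parms[7]
#define VNaP      parms[8]
#define VNa       parms[9]
#define VK        parms[10]
#define VL        parms[11]
#define VCa       parms[12]
#define Vh        parms[13]
#define vm        parms[14]
#define sm        parms[15]
#define vh        parms[16]
#define sh        parms[17]
#define tau_h_bar parms[18]
#define vm_na     parms[19]
#define sm_na     parms[20]
#define vn        parms[21]
#define sn        parms[22]
#define tau_n_bar parms[23]
#define KCAN      parms[24]
#define lam       parms[25]
#define fi        parms[26]
#define Vi        parms[27]
#define sigma     parms[28]
#define IP3       parms[29]
#define Apar      parms[30]
#define Kd        parms[31]
#define KI        parms[32]
#define Ka        parms[33]
#define LIP3R     parms[34]
#define PIP3R     parms[35]
#define VSERCA    parms[36]
#define KSERCA    parms[37]
#define alpha     parms[38]
#define VPMCA     parms[39]
#define KPMCA     parms[40]
#define flux_scale parms[41]
#define I_app     parms[42]
#define clampV    parms[43]
#define as_printed parms[44]

void prebotsim_initmod(void (*odeparms)(int *, double *))
{
    int n = N_PAR;
    odeparms(&n, parms);
}

static double sigmoid(double V, double Vx, double sx)
{
    return 1.0 / (1.0 + exp((V - Vx) / sx));
}

void prebotsim_derivs(int *neq, double *t, double *y, double *ydot,
                      double *yout, int *ip)
{
    double V = y[0], h = y[1], n = y[2], ca = y[3], ca_tot = y[4], l = y[5];

    double minf = sigmoid(V, vm, sm);
    double ninf = sigmoid(V, vn, sn);
    double INaP = gNaP * minf * h * (V - VNaP);
    double ICa  = gCa * minf * (V - VCa);
    double ICAN = gCAN * ca / (ca + KCAN) * (V - VNaP);
    double Ih   = gh * ninf * (V - Vh);
    double INa, IK, IL;
    if (as_printed > 0.5) {
        INa = 0.0;
        IK  = gK * (V - VK);
        IL  = 0.0;
    } else {
        double mna = sigmoid(V, vm_na, sm_na);
        INa = gNa * mna * mna * mna * (1.0 - n) * (V - VNa);
        IK  = gK * n * n * n * n * (V - VK);
        IL  = gL * (V - VL);
    }
    double Itot = INaP + INa + IK + IL + ICa + ICAN + Ih;

    double ca_er = (ca_tot - ca) / sigma;
    double q = IP3 * ca * l / ((IP3 + KI) * (ca + Ka));
    double JERin  = (LIP3R + PIP3R * q * q * q) * (ca_er - ca);
    double JERout = VSERCA * ca * ca / (KSERCA * KSERCA + ca * ca);
    double JPMin  = -alpha * ICa;
    double JPMout = VPMCA * ca * ca / (KPMCA * KPMCA + ca * ca);
    double fv = fi / Vi * flux_scale;
    double dpm = (JPMin - JPMout) / lam;

    ydot[0] = (clampV > 0.5) ? 0.0 : (-Itot + I_app) / Cm;
    ydot[1] = (sigmoid(V, vh, sh) - h) * cosh((V - vh) / (2.0 * sh)) / tau_h_bar;
    ydot[2] = (sigmoid(V, vn, sn) - n) * cosh((V - vn) / (2.0 * sn)) / tau_n_bar;
    ydot[3] = fv * (dpm + (JERin - JERout));
    ydot[4] = fv * dpm;
    ydot[5] = Apar * (Kd - l * (ca + Kd));
}
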