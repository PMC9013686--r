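/* PBK model for chlorpyrifos (CPF), chlorpyrifos-oxon (CPO) and TCPy.
 *
 * Flow-limited compartments. CPF: gut lumen (first-order absorption into
 * the liver), liver, blood, fat, richly and slowly perfused tissue. CPO:
 * liver, blood, rapidly equilibrating rest. TCPy: one body compartment with
 * first-order urinary elimination. Hepatic metabolism (pathways 1-3) acts on
 * liver venous concentration; plasma PON1 (pathway 4) acts on blood CPO.
 *
 * Pathway 1 and 2 are sums of up to four Michaelis-Menten terms so that the
 * same right-hand side serves the recombinant-CYP (four isoforms), biphasic
 * HLM (two phases) and single-MM descriptions; unused slots carry Vmax = 0.
 *
 * Amounts in umol, volumes in L, flows in L/h, concentrations umol/L = uM.
 */

#include <R.h>

#define N_PARMS 41

static double p[N_PARMS];

/* parameter layout (0-based):
   0  ka            1/h
   1  vl  2 vb  3 vf  4 vr  5 vs          L
   6  ql  7 qf  8 qr  9 qs               L/h
   10 pl_cpf 11 pf_cpf 12 pr_cpf 13 ps_cpf
   14 pl_cpo 15 px_cpo
   16 vx (CPO rest volume, L)  17 qx (CPO rest flow, L/h)
   18..21 pathway-1 Vmax[4]  umol/h
   22..25 pathway-1 Km[4]    uM
   26..29 pathway-2 Vmax[4]
   30..33 pathway-2 Km[4]
   34 p3 Vmax  35 p3 Km
   36 p4 Vmax  37 p4 Km
   38 p4 acts on free CPO (1) or total (0)
   39 fu_cpo_blood
   40 ke_tcpy 1/h
*/

void pbk_init(void (*odeparms)(int *, double *))
{
    int n = N_PARMS;
    odeparms(&n, p);
}

static double mm_sum(const double *vmax, const double *km, double s)
{
    double v = 0.0;
    int i;
    for (i = 0; i < 4; i++)
        if (vmax[i] > 0.0)
            v += vmax[i] * s / (km[i] + s);
    return v;
}

void pbk_deriv(int *neq, double *t, double *y, double *ydot,
               double *yout, int *ip)
{
    /* states: 0 AGI, 1 AL, 2 AB, 3 AF, 4 AR, 5 AS   (CPF)
               6 ALo, 7 ABo, 8 AXo                    (CPO)
               9 ATC, 10 AUR                          (TCPy) */
    double ka = p[0];
    double vl = p[1], vb = p[2], vf = p[3], vr = p[4], vs = p[5];
    double ql = p[6], qf = p[7], qr = p[8], qs = p[9];
    double qx = p[17], vx = p[16];

    double cb  = y[2] / vb;
    double cvl = y[1] / (vl * p[10]);
    double cvf = y[3] / (vf * p[11]);
    double cvr = y[4] / (vr * p[12]);
    double cvs = y[5] / (vs * p[13]);

    double cbo  = y[7] / vb;
    double cvlo = y[6] / (vl * p[14]);
    double cvxo = y[8] / (vx * p[15]);

    double s1 = cvl > 0.0 ? cvl : 0.0;
    double v1 = mm_sum(p + 18, p + 22, s1);
    double v2 = mm_sum(p + 26, p + 30, s1);

    double s3 = cvlo > 0.0 ? cvlo : 0.0;
    double v3 = p[34] > 0.0 ? p[34] * s3 / (p[35] + s3) : 0.0;

    double s4 = cbo > 0.0 ? cbo : 0.0;
    if (p[38] > 0.5)
        s4 *= p[39];
    double v4 = p[36] > 0.0 ? p[36] * s4 / (p[37] + s4) : 0.0;

    ydot[0] = -ka * y[0];
    ydot[1] = ql * (cb - cvl) + ka * y[0] - v1 - v2;
    ydot[2] = ql * cvl + qf * cvf + qr * cvr + qs * cvs
              - (ql + qf + qr + qs) * cb;
    ydot[3] = qf * (cb - cvf);
    ydot[4] = qr * (cb - cvr);
    ydot[5] = qs * (cb - cvs);

    ydot[6] = ql * (cbo - cvlo) + v1 - v3;
    ydot[7] = ql * cvlo + qx * cvxo - (ql + qx) * cbo - v4;
    ydot[8] = qx * (cbo - cvxo);

    ydot[9]  = v2 + v3 + v4 - p[40] * y[9];
    ydot[10] = p[40] * y[9];

    if (*ip > 0) {
        yout[0] = cbo;               /* total blood CPO, uM */
        if (*ip > 1) yout[1] = cb;   /* total blood CPF, uM */
    }
}
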