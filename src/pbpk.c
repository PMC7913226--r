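/* Whole-body PBPK right-hand side.
 *
 * 14 perfusion-limited organs (lung in series with the circulation),
 * arterial / venous / portal blood pools, and a 12-segment gastrointestinal
 * lumen with dissolved and solid sub-compartments, Weibull or spherical-
 * particle dissolution under a solubility cap, and first-order segment
 * transit. Amounts in mg, volumes in L (lumen fluid in mL), time in h.
 *
 * Parameter and state layouts are mirrored in R/model.R.
 */
#include <R.h>
#include <math.h>

#define NPAR 96
#define NORG 14
#define I_LUNG 5
#define I_KIDNEY 8
#define I_LIVER 9

/* parameter offsets */
#define P_V 0        /* organ volumes, L           [14] */
#define P_Q 14       /* organ blood flows, L/h     [14] */
#define P_KPB 28     /* tissue:blood partition     [14] */
#define P_VART 42
#define P_VVEN 43
#define P_VPOR 44
#define P_FU 45
#define P_BP 46
#define P_CLFILT 47  /* L/h on unbound plasma */
#define P_CLSEC 48
#define P_CLHEP 49
#define P_VMAX 50    /* mg/h */
#define P_KM 51      /* mg/L unbound */
#define P_CLBILE 52
#define P_BILEGUT 53
#define P_INFRATE 54 /* mg/h */
#define P_INFTEND 55
#define P_KT 56      /* transit rate, 1/h          [12] */
#define P_VFL 68     /* lumen fluid, mL            [12] */
#define P_KABS 80    /* absorption coeff, mL/h     [12] */
#define P_SOL 92     /* solubility, mg/mL (<=0: none) */
#define P_DISS 93    /* 0 none, 1 weibull, 2 particle */
#define P_D1 94      /* weibull scale (h) or particle k */
#define P_D2 95      /* weibull shape or dose^(1/3) */

/* state offsets */
#define Y_ART 14
#define Y_VEN 15
#define Y_POR 16
#define Y_DISS 17    /* [12] */
#define Y_SOLID 29   /* [12] */
#define Y_RENAL 41
#define Y_HEP 42
#define Y_BILE 43
#define Y_FECAL 44
#define Y_ABS 45

static double p[NPAR];

void pbpk_initmod(void (*odeparms)(int *, double *))
{
    int n = NPAR;
    odeparms(&n, p);
}

void pbpk_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    static const int is_portal[NORG] =
        {0, 0, 0, 0, 1, 0, 1, 0, 0, 0, 0, 1, 0, 1};
    int i;
    double co = 0.0, qpor = 0.0, cout[NORG];

    for (i = 0; i < *neq; i++) ydot[i] = 0.0;

    double cart = fmax(y[Y_ART] / p[P_VART], 0.0);
    double cven = fmax(y[Y_VEN] / p[P_VVEN], 0.0);
    double cpor = fmax(y[Y_POR] / p[P_VPOR], 0.0);

    for (i = 0; i < NORG; i++) {
        cout[i] = fmax(y[i] / (p[P_V + i] * p[P_KPB + i]), 0.0);
        if (i != I_LUNG) co += p[P_Q + i];
        if (is_portal[i]) qpor += p[P_Q + i];
    }
    double qliv = p[P_Q + I_LIVER] + qpor;

    /* lung in series: venous -> lung -> arterial */
    ydot[I_LUNG] = co * (cven - cout[I_LUNG]);
    ydot[Y_ART] = co * cout[I_LUNG];
    ydot[Y_VEN] -= co * cven;

    for (i = 0; i < NORG; i++) {
        if (i == I_LUNG || i == I_LIVER) continue;
        ydot[i] += p[P_Q + i] * (cart - cout[i]);
        ydot[Y_ART] -= p[P_Q + i] * cart;
        if (is_portal[i]) ydot[Y_POR] += p[P_Q + i] * cout[i];
        else ydot[Y_VEN] += p[P_Q + i] * cout[i];
    }
    ydot[Y_POR] -= qpor * cpor;

    /* liver: hepatic artery + portal inflow, metabolic + biliary loss */
    double cu_liv = p[P_FU] * cout[I_LIVER] / p[P_BP];
    double met = p[P_CLHEP] * cu_liv;
    if (p[P_VMAX] > 0.0)
        met += p[P_VMAX] * cu_liv / (p[P_KM] + cu_liv);
    double bile = p[P_CLBILE] * cu_liv;
    ydot[I_LIVER] = p[P_Q + I_LIVER] * cart + qpor * cpor
        - qliv * cout[I_LIVER] - met - bile;
    ydot[Y_ART] -= p[P_Q + I_LIVER] * cart;
    ydot[Y_VEN] += qliv * cout[I_LIVER];
    ydot[Y_HEP] = met;
    ydot[Y_BILE] = bile;
    if (p[P_BILEGUT] > 0.5)
        ydot[Y_DISS + 1] += bile; /* secreted into the duodenum */

    /* kidney: filtration + secretion on unbound plasma */
    double cu_kid = p[P_FU] * cout[I_KIDNEY] / p[P_BP];
    double ren = (p[P_CLFILT] + p[P_CLSEC]) * cu_kid;
    ydot[I_KIDNEY] -= ren;
    ydot[Y_RENAL] = ren;

    /* intravenous infusion into the venous pool */
    if (*t < p[P_INFTEND]) ydot[Y_VEN] += p[P_INFRATE];

    /* gastrointestinal lumen */
    double absorbed = 0.0;
    for (i = 0; i < 12; i++) {
        int di = Y_DISS + i, si = Y_SOLID + i;
        double conc = fmax(y[di], 0.0) / p[P_VFL + i]; /* mg/mL */
        double fabs = p[P_KABS + i] * conc;
        double diss = 0.0;
        if (p[P_DISS] > 0.5 && y[si] > 0.0) {
            double sat = 1.0;
            if (p[P_SOL] > 0.0) {
                sat = 1.0 - conc / p[P_SOL];
                if (sat < 0.0) sat = 0.0;
            }
            if (p[P_DISS] < 1.5) { /* Weibull hazard */
                double tt = (*t > 1e-9) ? *t : 1e-9;
                diss = p[P_D2] / p[P_D1] * pow(tt / p[P_D1], p[P_D2] - 1.0)
                    * y[si] * sat;
            } else {               /* spherical particles */
                double cs = (p[P_SOL] > 0.0) ? p[P_SOL] : 1.0;
                double gap = cs - conc;
                if (gap < 0.0) gap = 0.0;
                /* m^(2/3) regularized near zero to keep the rhs Lipschitz */
                double m = y[si];
                diss = p[P_D1] * p[P_D2] * m / cbrt(m + 1e-9) * gap;
            }
        }
        ydot[di] += -fabs - p[P_KT + i] * y[di] + diss;
        ydot[si] += -p[P_KT + i] * y[si] - diss;
        if (i > 0) {
            ydot[di] += p[P_KT + i - 1] * y[di - 1];
            ydot[si] += p[P_KT + i - 1] * y[si - 1];
        }
        absorbed += fabs;
    }
    ydot[Y_FECAL] = p[P_KT + 11] * (y[Y_DISS + 11] + y[Y_SOLID + 11]);
    ydot[Y_POR] += absorbed; /* splanchnic uptake drains to the portal vein */
    ydot[Y_ABS] = absorbed;
}
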