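/* Compiled right-hand side for the GI absorption / disposition model.
 *
 * State layout (matching the R driver):
 *   y[0 .. nc*nb-1]          solid mass per (compartment, bin), column-major
 *   y[nc*nb .. 2*nc*nb-1]    particle count per (compartment, bin)
 *   y[2*nc*nb .. +nc-1]      dissolved amount per compartment (mg)
 *   then: central R, central S, eliminated, excreted
 *
 * Parameter vector (fixed length GI_PLEN, padded):
 *   p[0] = nc, p[1] = nb,
 *   p[2 + c]                 k_solid
 *   p[2 + GI_MAXC + c]       k_fluid
 *   p[2 + 2*GI_MAXC + c]     ka
 *   p[2 + 3*GI_MAXC + c]     volume (mL)
 *   p[2 + 4*GI_MAXC + 0..7]  keR, keS, kinv, S_surf (g/cm^3),
 *                            D (cm^2/h), rho (g/cm^3), h_max (cm), m_eps (mg)
 */
#include <R.h>
#include <math.h>

#define GI_MAXC 16
#define GI_PLEN (2 + 4 * GI_MAXC + 8)

static double gi_p[GI_PLEN];

void gi_initmod(void (*odeparms)(int *, double *))
{
    int n = GI_PLEN;
    odeparms(&n, gi_p);
}

void gi_derivs(int *neq, double *t, double *y, double *ydot,
               double *yout, int *ip)
{
    const int nc = (int) gi_p[0];
    const int nb = (int) gi_p[1];
    const double *k_solid = gi_p + 2;
    const double *k_fluid = gi_p + 2 + GI_MAXC;
    const double *ka      = gi_p + 2 + 2 * GI_MAXC;
    const double *vol     = gi_p + 2 + 3 * GI_MAXC;
    const double *sc      = gi_p + 2 + 4 * GI_MAXC;
    const double keR = sc[0], keS = sc[1], kinv = sc[2];
    const double S_surf = sc[3], D = sc[4], rho = sc[5];
    const double h_max = sc[6], m_eps = sc[7];

    const int off_n = nc * nb;
    const int off_A = 2 * nc * nb;
    const int iR = off_A + nc, iS = iR + 1, iE = iS + 1, iX = iE + 1;
    const double mass_c = rho * (4.0 / 3.0) * M_PI * 1e3; /* mg per cm^3 */

    double grad[GI_MAXC];
    for (int c = 0; c < nc; c++) {
        double A = y[off_A + c];
        if (A < 0) A = 0;
        double g = S_surf - A / vol[c] * 1e-3;
        grad[c] = g > 0 ? g : 0;
        ydot[off_A + c] = 0.0;
    }

    for (int i = 0; i < off_A; i++) ydot[i] = 0.0;

    double abs_flux = 0.0, excr = 0.0;
    for (int b = 0; b < nb; b++) {
        for (int c = 0; c < nc; c++) {
            const int im = c + nc * b;
            const int in = off_n + im;
            double m = y[im] > 0 ? y[im] : 0;
            double n = y[in] > 0 ? y[in] : 0;
            double flux = 0.0;
            if (m > 0 && n > 1e-12) {
                double r = cbrt(m / (mass_c * n));
                double h = r < h_max ? r : h_max;
                if (h < 1e-12) h = 1e-12;
                flux = n * 4.0 * M_PI * r * r * 1e3 * D * grad[c] / h;
                flux *= m / (m + m_eps);
            }
            double tr_m = m * k_solid[c];
            double tr_n = n * k_solid[c];
            ydot[im] += -flux - tr_m;
            ydot[in] += -tr_n;
            if (c + 1 < nc) {
                ydot[im + 1] += tr_m;
                ydot[in + 1] += tr_n;
            } else {
                excr += tr_m;
            }
            ydot[off_A + c] += flux;
        }
    }
    for (int c = 0; c < nc; c++) {
        double A = y[off_A + c] > 0 ? y[off_A + c] : 0;
        double tr_A = A * k_fluid[c];
        double ab = A * ka[c];
        ydot[off_A + c] += -tr_A - ab;
        if (c + 1 < nc) ydot[off_A + c + 1] += tr_A;
        else excr += tr_A;
        abs_flux += ab;
    }
    ydot[iR] = 0.5 * abs_flux - (keR + kinv) * y[iR];
    ydot[iS] = 0.5 * abs_flux + kinv * y[iR] - keS * y[iS];
    ydot[iE] = keR * y[iR] + keS * y[iS];
    ydot[iX] = excr;
}
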