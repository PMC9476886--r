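/* Compiled right-hand sides for the AWA GPCR negative-feedback model,
 * in the deSolve compiled-code calling convention (initfunc/initforc/derivs).
 * The ligand concentration L(t) enters as forcing number one.
 *
 * States (simple model):   y = (S, C, I)
 * States (detailed model): y = (S, C, I, V, n)
 *
 * Clamping contract: S in [S_floor, 1], C >= 0, I >= 0.  Outward
 * derivatives taper linearly to zero across a narrow boundary layer at
 * each clamp (and are zero at/beyond it), keeping the vector field
 * continuous so the adaptive integrator does not chatter at the bounds.
 */

#include <R.h>
#include <math.h>

/* linear taper to 0 over [bound, bound + layer] */
static double taper(double x, double bound, double layer)
{
    double r = (x - bound) / layer;
    if (r < 0.0) return 0.0;
    if (r > 1.0) return 1.0;
    return r;
}

/* ---------------------------------------------------------------- simple */

static double p[13];
#define K1     p[0]
#define K2     p[1]
#define K3     p[2]
#define K4     p[3]
#define K5     p[4]
#define K6     p[5]
#define L0     p[6]
#define RT     p[7]
#define TAUC   p[8]
#define TAUI   p[9]
#define CBASE  p[10]
#define SFLOOR p[11]
#define LMIN   p[12]

static double forc[1];
#define LIG forc[0]

void awa_init(void (*odeparms)(int *, double *))
{
    int n = 13;
    odeparms(&n, p);
}

void awa_forc(void (*odeforcs)(int *, double *))
{
    int n = 1;
    odeforcs(&n, forc);
}

static double receptor(double L, double I)
{
    double Lc = (L < LMIN) ? LMIN : L;
    return 1.0 / (1.0 + exp(-K1 * log(Lc / L0) + K2 * I));
}

void awa_deriv(int *neq, double *t, double *y, double *ydot,
               double *yout, int *ip)
{
    double S = y[0], C = y[1], I = y[2];
    if (S < SFLOOR) S = SFLOOR;
    if (S > 1.0)    S = 1.0;
    if (C < 0.0)    C = 0.0;
    if (I < 0.0)    I = 0.0;

    double Ra = receptor(LIG, I);
    double dS = K3 * (Ra - RT) * S;
    double dC = K4 * S - (C - CBASE) / TAUC;
    double dI = K5 * (C - CBASE) * Ra + K6 * Ra - (1.0 - Ra) * I / TAUI;

    if (dS > 0.0) dS *= taper(1.0 - y[0], 0.0, 1e-3);
    else          dS *= taper(y[0], SFLOOR, SFLOOR);
    if (dC < 0.0) dC *= taper(y[1], 0.0, 1e-9);
    if (dI < 0.0) dI *= taper(y[2], 0.0, 1e-9);

    ydot[0] = dS;
    ydot[1] = dC;
    ydot[2] = dI;
    if (ip[0] >= 1) yout[0] = Ra;
}

/* -------------------------------------------------------------- detailed */
/* Adds a minimal two-conductance membrane module: a TRPV-like drive
 * proportional to the switch S, a voltage-gated calcium conductance with
 * sigmoidal instantaneous activation, a delayed-rectifier potassium
 * conductance, and a leak.  Calcium influx blends the abstract switch and
 * the voltage-gated pathway with weight W (W = 0 recovers the simple
 * model exactly; V and n become inert).
 *
 * parameter layout: p (13 entries, as above) followed by
 *   CM, GS, ES, GCA, ECA, VMH, KM, GK, EK, VNH, KN, TAUN, GL, EL, W
 */

static double pd[28];
#define DK1     pd[0]
#define DK2     pd[1]
#define DK3     pd[2]
#define DK4     pd[3]
#define DK5     pd[4]
#define DK6     pd[5]
#define DL0     pd[6]
#define DRT     pd[7]
#define DTAUC   pd[8]
#define DTAUI   pd[9]
#define DCBASE  pd[10]
#define DSFLOOR pd[11]
#define DLMIN   pd[12]
#define CM      pd[13]
#define GS      pd[14]
#define ES      pd[15]
#define GCA     pd[16]
#define ECA     pd[17]
#define VMH     pd[18]
#define KM      pd[19]
#define GK      pd[20]
#define EK      pd[21]
#define VNH     pd[22]
#define KN      pd[23]
#define TAUN    pd[24]
#define GL      pd[25]
#define EL      pd[26]
#define WMEM    pd[27]

static double forcd[1];

void awa_det_init(void (*odeparms)(int *, double *))
{
    int n = 28;
    odeparms(&n, pd);
}

void awa_det_forc(void (*odeforcs)(int *, double *))
{
    int n = 1;
    odeforcs(&n, forcd);
}

void awa_det_deriv(int *neq, double *t, double *y, double *ydot,
                   double *yout, int *ip)
{
    double S = y[0], C = y[1], I = y[2], V = y[3], nK = y[4];
    if (S < DSFLOOR) S = DSFLOOR;
    if (S > 1.0)     S = 1.0;
    if (C < 0.0)     C = 0.0;
    if (I < 0.0)     I = 0.0;
    if (nK < 0.0)    nK = 0.0;
    if (nK > 1.0)    nK = 1.0;

    double L  = (forcd[0] < DLMIN) ? DLMIN : forcd[0];
    double Ra = 1.0 / (1.0 + exp(-DK1 * log(L / DL0) + DK2 * I));

    double minf = 1.0 / (1.0 + exp(-(V - VMH) / KM));
    double ninf = 1.0 / (1.0 + exp(-(V - VNH) / KN));
    /* voltage-gated calcium drive, normalized to ~1 when depolarized */
    double dca  = ECA - V;
    if (dca < 0.0) dca = 0.0;
    double phi  = minf * dca / (ECA - EL);

    double dS = DK3 * (Ra - DRT) * S;
    double dC = DK4 * ((1.0 - WMEM) * S + WMEM * phi) - (C - DCBASE) / DTAUC;
    double dI = DK5 * (C - DCBASE) * Ra + DK6 * Ra - (1.0 - Ra) * I / DTAUI;
    double dV = (GS * S * (ES - V) + GCA * minf * (ECA - V) +
                 GK * nK * (EK - V) + GL * (EL - V)) / CM;
    double dn = (ninf - nK) / TAUN;

    if (dS > 0.0) dS *= taper(1.0 - y[0], 0.0, 1e-3);
    else          dS *= taper(y[0], DSFLOOR, DSFLOOR);
    if (dC < 0.0) dC *= taper(y[1], 0.0, 1e-9);
    if (dI < 0.0) dI *= taper(y[2], 0.0, 1e-9);
    if (dn > 0.0) dn *= taper(1.0 - y[4], 0.0, 1e-6);
    else          dn *= taper(y[4], 0.0, 1e-6);

    ydot[0] = dS;
    ydot[1] = dC;
    ydot[2] = dI;
    ydot[3] = dV;
    ydot[4] = dn;
    if (ip[0] >= 1) yout[0] = Ra;
}
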