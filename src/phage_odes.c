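/* Compiled right-hand sides for the resident host-phage-arbitrium system
 * and for the linearised (rare-mutant / adjoint) viral dynamics, in the
 * deSolve compiled-model calling convention.
 *
 * Parameter vector layout (shared by both systems, see parms_vector() in R):
 *   [0] r       [1] kappa  [2] a        [3] sigma   [4] gamma
 *   [5] dS      [6] dL     [7] dSstar   [8] dLstar  [9] B
 *  [10] dV     [11] piV   [12] piL     [13] dA     [14] delta
 *  [15] k      [16] theta [17] plastic flag (0 fixed / 1 plastic)
 *  [18] phi    [19] phiStar [20] alpha [21] alphaStar
 *  [22] alphaMax [23] phiMax [24] alphaMaxStar [25] phiMaxStar
 *  [26] Aalpha [27] Aphi  [28] AalphaStar [29] AphiStar
 *  [30] mode (linear system only: 0 forward mutant, 1 reversed-time adjoint)
 */
#include <R.h>
#include <R_ext/Rdynload.h>
#include <math.h>

#define NPAR 31

static double pr[NPAR]; /* resident system parameters */
static double pl[NPAR]; /* linear system parameters   */
static double fl[5];    /* linear system forcings: S, Sstar, N, A, rw */

void lys_resident_init(void (*odeparms)(int *, double *))
{
    int n = NPAR;
    odeparms(&n, pr);
}

void lys_linear_init(void (*odeparms)(int *, double *))
{
    int n = NPAR;
    odeparms(&n, pl);
}

void lys_linear_forc(void (*odeforcs)(int *, double *))
{
    int n = 5;
    odeforcs(&n, fl);
}

static double hk(double x, double k)
{
    return 0.5 + atan(k * x) / M_PI;
}

/* lysogenisation probabilities and reactivation rates at arbitrium A */
static void rates(const double *p, double A, double *phi, double *phis,
                  double *al, double *als)
{
    if (p[17] > 0.5) {
        double k = p[15];
        if (A < 0) A = 0.0; /* integrator may undershoot by < atol */
        *al   = p[22] > 0 ? p[22] * (1.0 - hk(A / p[26] - 1.0, k)) : 0.0;
        *phi  = p[23] > 0 ? p[23] * hk(A / p[27] - 1.0, k) : 0.0;
        *als  = p[24] > 0 ? p[24] * (1.0 - hk(A / p[28] - 1.0, k)) : 0.0;
        *phis = p[25] > 0 ? p[25] * hk(A / p[29] - 1.0, k) : 0.0;
    } else {
        *phi  = p[18];
        *phis = p[19];
        *al   = p[20];
        *als  = p[21];
    }
}

/* Resident dynamics: y = (S, Sstar, L, Lstar, V, A) */
void lys_resident_derivs(int *neq, double *t, double *y, double *ydot,
                         double *yout, int *ip)
{
    double S = y[0], Ss = y[1], L = y[2], Ls = y[3], V = y[4], A = y[5];
    double N = S + Ss + L + Ls;
    double phi, phis, al, als;
    rates(pr, A, &phi, &phis, &al, &als);
    double grow = pr[0] * (1.0 - pr[1] * N);
    double a = pr[2], sig = pr[3], gam = pr[4], B = pr[9];

    ydot[0] = pr[16] + grow * S - (a * V + pr[5] + sig) * S + gam * Ss;
    ydot[1] = sig * S - (a * V + pr[7] + gam) * Ss;
    ydot[2] = grow * L + a * phi * V * S - (al + pr[6] + sig) * L + gam * Ls;
    ydot[3] = sig * L + a * phis * V * Ss - (als + pr[8] + gam) * Ls;
    ydot[4] = a * B * V * ((1.0 - phi) * S + (1.0 - phis) * Ss)
              + (al * L + als * Ls) * B - (a * N + pr[10]) * V;
    ydot[5] = pr[11] * a * V * (S + Ss) + pr[12] * (L + Ls)
              - (pr[13] + pr[14] * N) * A;
}

/* Projection matrix among viral classes (L, Lstar, V) at given resident
 * densities; traits evaluated at the resident arbitrium concentration. */
static void mmat(const double *p, double S, double Ss, double N, double A,
                 double M[3][3])
{
    double phi, phis, al, als;
    rates(p, A, &phi, &phis, &al, &als);
    double a = p[2], sig = p[3], gam = p[4], B = p[9];

    M[0][0] = p[0] * (1.0 - p[1] * N) - (al + p[6] + sig);
    M[0][1] = gam;
    M[0][2] = a * phi * S;
    M[1][0] = sig;
    M[1][1] = -(als + p[8] + gam);
    M[1][2] = a * phis * Ss;
    M[2][0] = al * B;
    M[2][1] = als * B;
    M[2][2] = a * ((1.0 - phi) * S + (1.0 - phis) * Ss) * B
              - (a * N + p[10]);
}

/* Linear viral dynamics with resident densities supplied as forcings.
 * mode 0: forward rare-mutant abundances, n' = M(t) n
 * mode 1: reproductive values in reversed time tau = t_end - t,
 *         dv/dtau = (M(t)^T - rw(t) I) v
 */
void lys_linear_derivs(int *neq, double *t, double *y, double *ydot,
                       double *yout, int *ip)
{
    double M[3][3];
    mmat(pl, fl[0], fl[1], fl[2], fl[3], M);
    if (pl[30] < 0.5) {
        for (int i = 0; i < 3; i++)
            ydot[i] = M[i][0] * y[0] + M[i][1] * y[1] + M[i][2] * y[2];
    } else {
        double rw = fl[4];
        for (int i = 0; i < 3; i++)
            ydot[i] = M[0][i] * y[0] + M[1][i] * y[1] + M[2][i] * y[2]
                      - rw * y[i];
    }
}

/* Augmented system: resident state (6) plus the 3x3 fundamental matrix
 * (column-major, states 6..14) of the linearised class dynamics
 * x' = M(t) x, with M evaluated exactly at the current resident state.
 * Parameters: [0..30] resident block, [31..61] mutant block (the mutant
 * block parameterises M; set it to the resident strategy for resident
 * class dynamics / reproductive values). */
static double pa[2 * NPAR];

void lys_aug_init(void (*odeparms)(int *, double *))
{
    int n = 2 * NPAR;
    odeparms(&n, pa);
}

void lys_aug_derivs(int *neq, double *t, double *y, double *ydot,
                    double *yout, int *ip)
{
    double S = y[0], Ss = y[1], L = y[2], Ls = y[3], V = y[4], A = y[5];
    double N = S + Ss + L + Ls;
    double phi, phis, al, als;
    rates(pa, A, &phi, &phis, &al, &als);
    double grow = pa[0] * (1.0 - pa[1] * N);
    double a = pa[2], sig = pa[3], gam = pa[4], B = pa[9];

    ydot[0] = pa[16] + grow * S - (a * V + pa[5] + sig) * S + gam * Ss;
    ydot[1] = sig * S - (a * V + pa[7] + gam) * Ss;
    ydot[2] = grow * L + a * phi * V * S - (al + pa[6] + sig) * L + gam * Ls;
    ydot[3] = sig * L + a * phis * V * Ss - (als + pa[8] + gam) * Ls;
    ydot[4] = a * B * V * ((1.0 - phi) * S + (1.0 - phis) * Ss)
              + (al * L + als * Ls) * B - (a * N + pa[10]) * V;
    ydot[5] = pa[11] * a * V * (S + Ss) + pa[12] * (L + Ls)
              - (pa[13] + pa[14] * N) * A;

    double M[3][3];
    mmat(pa + NPAR, S, Ss, N, A, M);
    for (int j = 0; j < 3; j++) {
        const double *x = y + 6 + 3 * j;
        double *dx = ydot + 6 + 3 * j;
        for (int i = 0; i < 3; i++)
            dx[i] = M[i][0] * x[0] + M[i][1] * x[1] + M[i][2] * x[2];
    }
}

void R_init_lysogeny(DllInfo *dll)
{
    R_useDynamicSymbols(dll, TRUE);
}
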