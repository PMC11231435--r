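/* Compiled right-hand sides for the swim-interneuron (adapted Plant) model,
 * synapse gate kinetics, and the 2-cell network, in the deSolve
 * compiled-model interface (initfunc + derivs pairs).
 *
 * Unit conventions: voltage mV, time in model units (millisecond-scale Plant
 * clock), conductances nS, rates per model unit.
 */
#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>

/* ---- cell parameter vector layout (shared by all models) ---- */
#define P_CM    0
#define P_GI    1
#define P_GK    2
#define P_GT    3
#define P_GKCA  4
#define P_GH    5
#define P_GL    6
#define P_EI    7
#define P_EK    8
#define P_EH    9
#define P_EL   10
#define P_ECA  11
#define P_RHO  12
#define P_KC   13
#define P_TAUX 14
#define P_DX   15
#define P_DCA  16
#define P_IAPP 17
#define NCP    18          /* core cell parameters */

/* single-cell extras (appended after the core block) */
#define P_GPULSE  18       /* constant synaptic-pulse conductance */
#define P_EPULSE  19       /* its reversal potential */
#define P_FREEZE  20       /* 1 -> x' = Ca' = 0 (frozen fast subsystem) */
#define P_RAMP    21       /* 1 -> delta_Ca ramps linearly in time */
#define P_DCAEND  22
#define P_TRAMP0  23
#define P_TRAMP1  24
#define NPCELL    25

/* voltage-shifted Hodgkin-Huxley kinetics of the original Plant model;
 * TAU_HH scales the h/n time constants and thereby the spike width */
#define TAU_HH 12.5
static double vshift(double V) { return (127.0 * V + 8265.0) / 105.0; }

static double safe_exprel(double z)
{   /* z / (exp(z) - 1), continuous through z = 0 */
    if (fabs(z) < 1e-7) return 1.0 - z / 2.0;
    return z / (exp(z) - 1.0);
}

static double m_inf_c(double V)
{
    double Vs = vshift(V);
    double am = safe_exprel((50.0 - Vs) / 10.0);            /* = 0.1*(50-Vs)/(exp((50-Vs)/10)-1) */
    double bm = 4.0 * exp((25.0 - Vs) / 18.0);
    return am / (am + bm);
}

static void h_kin(double V, double *hinf, double *tauh)
{
    double Vs = vshift(V);
    double ah = 0.07 * exp((25.0 - Vs) / 20.0);
    double bh = 1.0 / (1.0 + exp((55.0 - Vs) / 10.0));
    *hinf = ah / (ah + bh);
    *tauh = TAU_HH / (ah + bh);
}

static void n_kin(double V, double *ninf, double *taun)
{
    double Vs = vshift(V);
    double an = 0.1 * safe_exprel((55.0 - Vs) / 10.0);      /* = 0.01*(55-Vs)/(exp((55-Vs)/10)-1) */
    double bn = 0.125 * exp((45.0 - Vs) / 80.0);
    *ninf = an / (an + bn);
    *taun = TAU_HH / (an + bn);
}

static void y_kin(double V, double *yinf, double *tauy)
{
    *yinf = 1.0 / (1.0 + exp(10.0 * (V - 50.0)));
    *tauy = 7.1 + 10.4 / (1.0 + exp((V + 68.0) / 2.2));
}

static double sigma_h_c(double V)
{   /* activation of the depolarizing h-current below about -50 mV */
    return 1.0 / (1.0 + exp((V + 63.0) / 7.83));
}

static double x_inf_c(double V, double dx)
{
    return 1.0 / (1.0 + exp(-0.15 * (V + 50.0 - dx)));
}

/* full single-cell derivative; Isyn is the total synaptic current entering
 * the voltage equation with the same sign convention as the intrinsic
 * currents (positive = outward/hyperpolarizing). */
static void cell_rhs(const double *p, double dCa_eff, int freeze,
                     const double *y, double Isyn, double *ydot)
{
    double V = y[0], h = y[1], n = y[2], yy = y[3], x = y[4], Ca = y[5];
    double minf = m_inf_c(V);
    double II   = p[P_GI] * h * minf * minf * minf * (V - p[P_EI]);
    double IK   = p[P_GK] * n * n * n * n * (V - p[P_EK]);
    double Ih   = p[P_GH] * yy * sigma_h_c(V) * (V - p[P_EH]);
    double IL   = p[P_GL] * (V - p[P_EL]);
    double IT   = p[P_GT] * x * (V - p[P_EI]);
    double Cap  = Ca > 0.0 ? Ca : 0.0;      /* KCa activation clamps at zero */
    double IKCa = p[P_GKCA] * Cap / (0.5 + Cap) * (V - p[P_EK]);
    double hinf, tauh, ninf, taun, yinf, tauy;
    h_kin(V, &hinf, &tauh);
    n_kin(V, &ninf, &taun);
    y_kin(V, &yinf, &tauy);
    ydot[0] = (-II - IK - Ih - IL - IT - IKCa - Isyn + p[P_IAPP]) / p[P_CM];
    ydot[1] = (hinf - h) / tauh;
    ydot[2] = (ninf - n) / taun;
    ydot[3] = (yinf - yy) / tauy;
    if (freeze) {
        ydot[4] = 0.0;
        ydot[5] = 0.0;
    } else {
        ydot[4] = (x_inf_c(V, p[P_DX]) - x) / p[P_TAUX];
        ydot[5] = p[P_RHO] * (p[P_KC] * x * (p[P_ECA] - V + dCa_eff) - Ca);
    }
}

static double dca_at(const double *p, double t)
{
    if (p[P_RAMP] == 0.0) return p[P_DCA];
    double u = (t - p[P_TRAMP0]) / (p[P_TRAMP1] - p[P_TRAMP0]);
    if (u < 0.0) u = 0.0;
    if (u > 1.0) u = 1.0;
    return p[P_DCA] + u * (p[P_DCAEND] - p[P_DCA]);
}

/* ================= model 1: isolated cell ================= */
static double pcell[NPCELL];

void sinet_initcell(void (*odeparms)(int *, double *))
{
    int N = NPCELL;
    odeparms(&N, pcell);
}

void sinet_dcell(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    double Isyn = pcell[P_GPULSE] * (y[0] - pcell[P_EPULSE]);
    cell_rhs(pcell, dca_at(pcell, *t), pcell[P_FREEZE] != 0.0, y, Isyn, ydot);
}

/* ============ model 2: cell + bank of synapse gates ============
 * State: 6 cell states, then S_alpha, S_c1, S_c2, S_c3, S_dyn, M_dyn, S_log.
 * All five gate models listen to the same presynaptic voltage, so a single
 * (optionally Delta_Ca-ramped) run yields every frequency-response curve. */
#define PG_K     (NPCELL + 0)
#define PG_TH    (NPCELL + 1)
#define PG_AA    (NPCELL + 2)
#define PG_BA    (NPCELL + 3)
#define PG_AC    (NPCELL + 4)
#define PG_BC    (NPCELL + 5)
#define PG_NST   (NPCELL + 6)
#define PG_AD    (NPCELL + 7)
#define PG_BD    (NPCELL + 8)
#define PG_TAUM  (NPCELL + 9)
#define PG_AL    (NPCELL + 10)
#define PG_BL    (NPCELL + 11)
#define PG_S0    (NPCELL + 12)
#define NPCG     (NPCELL + 13)

static double pcg[NPCG];

static double f_inf_c(double V, double k, double th)
{
    return 1.0 / (1.0 + exp(-k * (V - th)));
}

void sinet_initcellgate(void (*odeparms)(int *, double *))
{
    int N = NPCG;
    odeparms(&N, pcg);
}

void sinet_dcellgate(int *neq, double *t, double *y, double *ydot,
                     double *yout, int *ip)
{
    cell_rhs(pcg, dca_at(pcg, *t), 0, y, 0.0, ydot);
    double f = f_inf_c(y[0], pcg[PG_K], pcg[PG_TH]);
    int nst = (int) pcg[PG_NST];
    /* alpha */
    ydot[6] = pcg[PG_AA] * (1.0 - y[6]) * f - pcg[PG_BA] * y[6];
    /* cascade (feed-forward, shared per-stage rates) */
    double drive = f;
    for (int i = 0; i < 3; i++) {
        if (i < nst) {
            ydot[7 + i] = pcg[PG_AC] * (1.0 - y[7 + i]) * drive - pcg[PG_BC] * y[7 + i];
            drive = y[7 + i];
        } else ydot[7 + i] = 0.0;
    }
    /* dynamic: fast alpha-form gate + slow modulation */
    ydot[10] = pcg[PG_AD] * (1.0 - y[10]) * f - pcg[PG_BD] * y[10];
    ydot[11] = (f - y[11]) / pcg[PG_TAUM];
    /* logistic */
    ydot[12] = pcg[PG_AL] * y[12] * (1.0 - y[12]) * f - pcg[PG_BL] * (y[12] - pcg[PG_S0]);
}

/* ================= model 3: two-cell network =================
 * State: cell1 (0..5), cell2 (6..11), syn12 gate slots (12..15),
 * syn21 gate slots (16..19).
 * Synapse spec block (15 doubles): kind, g, Erev, k, theta,
 * a1,b1, a2,b2, a3,b3, n_stages, tauM, S0, p.
 * kind: 0 ftm, 1 alpha, 2 cascade, 3 dynamic, 4 logistic. */
#define NSP 15
#define NPNET (2 * NCP + 2 * NSP + 1)
static double pnet[NPNET];

void sinet_initnet(void (*odeparms)(int *, double *))
{
    int N = NPNET;
    odeparms(&N, pnet);
}

/* gate derivatives for one synapse; s points at its 4 state slots */
static void syn_gate_rhs(const double *sp, const double *s, double Vpre,
                         double *sdot)
{
    double f = f_inf_c(Vpre, sp[3], sp[4]);
    int kind = (int) sp[0];
    sdot[0] = sdot[1] = sdot[2] = sdot[3] = 0.0;
    switch (kind) {
    case 0: /* ftm: no gate states */
        break;
    case 1: /* alpha */
        sdot[0] = sp[5] * (1.0 - s[0]) * f - sp[6] * s[0];
        break;
    case 2: { /* cascade, per-stage rates */
        int nst = (int) sp[11];
        double drive = f;
        for (int i = 0; i < nst && i < 3; i++) {
            sdot[i] = sp[5 + 2 * i] * (1.0 - s[i]) * drive - sp[6 + 2 * i] * s[i];
            drive = s[i];
        }
        break;
    }
    case 3: /* dynamic: alpha-form S + slow M */
        sdot[0] = sp[5] * (1.0 - s[0]) * f - sp[6] * s[0];
        sdot[1] = (f - s[1]) / sp[12];
        break;
    case 4: /* logistic */
        sdot[0] = sp[5] * s[0] * (1.0 - s[0]) * f - sp[6] * (s[0] - sp[13]);
        break;
    }
}

/* effective gate value entering the synaptic current */
static double syn_gate_val(const double *sp, const double *s, double Vpre)
{
    int kind = (int) sp[0];
    switch (kind) {
    case 0: return f_inf_c(Vpre, sp[3], sp[4]);
    case 2: { int nst = (int) sp[11]; return s[nst - 1 < 3 ? nst - 1 : 2]; }
    case 3: return s[0] * s[1];
    default: return s[0];
    }
}

void sinet_dnet(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    const double *p1 = pnet, *p2 = pnet + NCP;
    const double *s12 = pnet + 2 * NCP, *s21 = pnet + 2 * NCP + NSP;
    double gel = pnet[2 * NCP + 2 * NSP];
    double V1 = y[0], V2 = y[6];

    double g12 = syn_gate_val(s12, y + 12, V1);
    double g21 = syn_gate_val(s21, y + 16, V2);
    double I_12 = s12[1] * pow(g12, s12[14]) * (V2 - s12[2]); /* onto cell 2 */
    double I_21 = s21[1] * pow(g21, s21[14]) * (V1 - s21[2]); /* onto cell 1 */
    double Iel1 = gel * (V1 - V2);
    double Iel2 = gel * (V2 - V1);

    cell_rhs(p1, p1[P_DCA], 0, y,     I_21 + Iel1, ydot);
    cell_rhs(p2, p2[P_DCA], 0, y + 6, I_12 + Iel2, ydot + 6);
    syn_gate_rhs(s12, y + 12, V1, ydot + 12);
    syn_gate_rhs(s21, y + 16, V2, ydot + 16);
}

/* ---- registration ---- */
static const R_CMethodDef cMethods[] = {
    {"sinet_initcell",     (DL_FUNC) &sinet_initcell,     1},
    {"sinet_dcell",        (DL_FUNC) &sinet_dcell,        6},
    {"sinet_initcellgate", (DL_FUNC) &sinet_initcellgate, 1},
    {"sinet_dcellgate",    (DL_FUNC) &sinet_dcellgate,    6},
    {"sinet_initnet",      (DL_FUNC) &sinet_initnet,      1},
    {"sinet_dnet",         (DL_FUNC) &sinet_dnet,         6},
    {NULL, NULL, 0}
};

void R_init_sinet(DllInfo *dll)
{
    R_registerRoutines(dll, cMethods, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
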