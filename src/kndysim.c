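/* Right-hand side of the 12-current KNDy neuron model, in the form expected
 * by deSolve's compiled-code interface (initmod_kndysim / derivs_kndysim).
 *
 * Units package-wide: mV, ms, nS, pA, pF, uM.  With these, nS*mV = pA and
 * pA/pF = mV/ms, so no conversion constants appear below.
 *
 * State vector (16):
 *   0 V     membrane potential (mV); ignored while voltage-clamped
 *   1 hNa   NaT inactivation
 *   2 bA    A-current inactivation
 *   3 mCa   HVA Ca activation
 *   4 hCa   HVA Ca inactivation
 *   5 mT    T-type activation
 *   6 hT    T-type inactivation
 *   7 s     SK activation
 *   8 mM    M-current activation
 *   9 r     h-current activation
 *  10 c     TRPC5 activation
 *  11 aN    NKB receptor drive
 *  12 aD    Dyn receptor drive
 *  13 Cad   submembrane Ca pool (VGCC-coupled, drives SK/BK/CDI), uM
 *  14 Cab   bulk Ca pool (drives TRPC5), uM
 *  15 dtr   TRPC5 desensitization
 *
 * Extra outputs (15): the 12 per-channel currents (pA, outward positive),
 * their sum, the applied current, and the membrane potential actually used.
 */
#include <R.h>
#include <math.h>

#define NP 145
static double p[NP];

/* global parameter slots */
#define P_CM        0
#define P_MODE      1   /* 0 current clamp, 1 voltage clamp */
#define P_CMDKIND   2   /* 0 constant, 1 ramp */
#define P_CMDVAL    3
#define P_CMDRATE   4   /* per ms */
#define P_T0        5   /* segment start time */
#define P_NKBMODE   6   /* 0 constant, 1 pulse train */
#define P_NKBLEV    7
#define P_NKBPER    8
#define P_NKBWID    9
#define P_DYNMODE  10
#define P_DYNLEV   11
#define P_DYNPER   12
#define P_DYNWID   13

/* channel blocks: 12 channels x 10 slots starting at 14
 * slot 0 gbar, 1 block fraction, 2 Erev, 3..9 kinetic constants k1..k7 */
#define CH(i, s) p[14 + 10 * (i) + (s)]
#define CH_NAT   0
#define CH_NAP   1
#define CH_A     2
#define CH_BK    3
#define CH_H     4
#define CH_SK    5
#define CH_M     6
#define CH_T     7
#define CH_CA    8
#define CH_TRPC5 9
#define CH_GIRK 10
#define CH_LEAK 11

/* calcium handling and receptor kinetics, after the channel blocks */
#define P_KD      134  /* submembrane influx gain, uM/(pA ms) */
#define P_TAUD    135
#define P_KB      136  /* bulk influx gain */
#define P_TAUB    137
#define P_CA0     138  /* resting Ca, uM */
#define P_KCDI    139  /* Ca-dependent inactivation half-point, uM */
#define P_TNKON   140
#define P_TNKOFF  141
#define P_TDYON   142
#define P_TDYOFF  143
#define P_CA0D    144  /* submembrane-domain resting Ca, uM */

static double boltz_act(double v, double vh, double k)
{
    return 1.0 / (1.0 + exp((vh - v) / k));
}

static double boltz_inact(double v, double vh, double k)
{
    return 1.0 / (1.0 + exp((v - vh) / k));
}

static double geff(int ch)
{
    double g = CH(ch, 0) * (1.0 - CH(ch, 1));
    return g > 0.0 ? g : 0.0;
}

static double drive_level(double trel, double mode, double lev,
                          double period, double width)
{
    if (mode < 0.5) return lev;
    if (period <= 0.0) return 0.0;
    return fmod(trel, period) < width ? lev : 0.0;
}

void initmod_kndysim(void (*odeparms)(int *, double *))
{
    int n = NP;
    odeparms(&n, p);
}

void derivs_kndysim(int *neq, double *t, double *y, double *ydot,
                    double *yout, int *ip)
{
    if (*ip < 15) error("nout must be >= 15");

    double trel = *t - p[P_T0];
    double cmd = p[P_CMDVAL] + (p[P_CMDKIND] > 0.5 ? p[P_CMDRATE] * trel : 0.0);
    int vclamp = p[P_MODE] > 0.5;

    double v   = vclamp ? cmd : y[0];
    double hNa = y[1], bA = y[2], mCa = y[3], hCa = y[4];
    double mT  = y[5], hT = y[6], s = y[7], mM = y[8], r = y[9];
    double c   = y[10], aN = y[11], aD = y[12];
    double cad = y[13] > 0.0 ? y[13] : 0.0;
    double cab = y[14] > 0.0 ? y[14] : 0.0;
    double dtr = y[15];

    double eca = CH(CH_CA, 2);

    /* transient Na: instantaneous cubic activation, dynamic inactivation */
    double mna = boltz_act(v, CH(CH_NAT, 3), CH(CH_NAT, 4));
    double i_nat = geff(CH_NAT) * mna * mna * mna * hNa * (v - CH(CH_NAT, 2));

    /* persistent Na: instantaneous */
    double i_nap = geff(CH_NAP) * boltz_act(v, CH(CH_NAP, 3), CH(CH_NAP, 4)) *
                   (v - CH(CH_NAP, 2));

    /* A-type K: instantaneous activation, dynamic inactivation */
    double i_a = geff(CH_A) * boltz_act(v, CH(CH_A, 3), CH(CH_A, 4)) * bA *
                 (v - CH(CH_A, 2));

    /* BK: voltage gate x submembrane-Ca gate (Hill 4), instantaneous */
    double kbk = CH(CH_BK, 5);
    double cad2 = cad * cad, kbk2 = kbk * kbk;
    double wca = cad2 * cad2 / (cad2 * cad2 + kbk2 * kbk2);
    double i_bk = geff(CH_BK) * boltz_act(v, CH(CH_BK, 3), CH(CH_BK, 4)) *
                  wca * (v - CH(CH_BK, 2));

    /* HCN (h) */
    double i_h = geff(CH_H) * r * (v - CH(CH_H, 2));

    /* SK: purely Ca-gated (submembrane pool), Hill 4 */
    double i_sk = geff(CH_SK) * s * (v - CH(CH_SK, 2));

    /* Gq/PLC signaling downstream of NKB depletes PIP2, closing
     * PIP2-dependent KCNQ (M) and GIRK channels */
    double pip2 = 1.0 - CH(CH_GIRK, 6) * aN;

    /* M (KCNQ) */
    double i_m = geff(CH_M) * mM * pip2 * (v - CH(CH_M, 2));

    /* T-type Ca */
    double i_t = geff(CH_T) * mT * mT * hT * (v - CH(CH_T, 2));

    /* HVA Ca with Ca-dependent inactivation from the submembrane pool */
    double fcdi = p[P_KCDI] / (p[P_KCDI] + cad);
    double i_ca = geff(CH_CA) * mCa * hCa * fcdi * (v - eca);

    /* TRPC5: activated by NKB drive OR bulk Ca (autocatalytic) */
    double kt5 = CH(CH_TRPC5, 3);
    double cca = cab * cab / (cab * cab + kt5 * kt5);
    double g_t5 = geff(CH_TRPC5) * c * (1.0 - dtr);
    double i_t5 = g_t5 * (v - CH(CH_TRPC5, 2));

    /* GIRK: basal + Dyn-driven, inwardly rectifying */
    double rect = boltz_inact(v, CH(CH_GIRK, 4), CH(CH_GIRK, 5));
    double a0 = CH(CH_GIRK, 3);
    double i_girk = geff(CH_GIRK) * (a0 + (1.0 - a0) * aD) * rect * pip2 *
                    (v - CH(CH_GIRK, 2));

    double i_leak = geff(CH_LEAK) * (v - CH(CH_LEAK, 2));

    double i_net = i_nat + i_nap + i_a + i_bk + i_h + i_sk + i_m + i_t +
                   i_ca + i_t5 + i_girk + i_leak;

    double i_inj = vclamp ? 0.0 : cmd;

    /* membrane equation (current clamp) or ideal clamp */
    ydot[0] = vclamp ? 0.0 : (i_inj - i_net) / p[P_CM];

    /* gating kinetics */
    double dv60 = (v + 60.0) / 25.0;
    double tau_hna = CH(CH_NAT, 7) + CH(CH_NAT, 8) * exp(-dv60 * dv60);
    ydot[1] = (boltz_inact(v, CH(CH_NAT, 5), CH(CH_NAT, 6)) - hNa) / tau_hna;

    ydot[2] = (boltz_inact(v, CH(CH_A, 5), CH(CH_A, 6)) - bA) / CH(CH_A, 7);

    ydot[3] = (boltz_act(v, CH(CH_CA, 3), CH(CH_CA, 4)) - mCa) / CH(CH_CA, 7);
    double hfloor = CH(CH_CA, 9);
    double hca_inf = hfloor + (1.0 - hfloor) *
                     boltz_inact(v, CH(CH_CA, 5), CH(CH_CA, 6));
    ydot[4] = (hca_inf - hCa) / CH(CH_CA, 8);

    ydot[5] = (boltz_act(v, CH(CH_T, 3), CH(CH_T, 4)) - mT) / CH(CH_T, 7);
    /* T inactivation is fast at depolarized and slow at hyperpolarized V */
    double flT = CH(CH_T, 9);
    double tau_ht = CH(CH_T, 8) *
        (flT + (1.0 - flT) * boltz_inact(v, -60.0, 6.0));
    ydot[6] = (boltz_inact(v, CH(CH_T, 5), CH(CH_T, 6)) - hT) / tau_ht;

    double ksk = CH(CH_SK, 3);
    double c4 = cad * cad * cad * cad;
    double k4 = ksk * ksk * ksk * ksk;
    ydot[7] = (c4 / (c4 + k4) - s) / CH(CH_SK, 5);

    ydot[8] = (boltz_act(v, CH(CH_M, 3), CH(CH_M, 4)) - mM) / CH(CH_M, 5);

    ydot[9] = (boltz_inact(v, CH(CH_H, 3), CH(CH_H, 4)) - r) / CH(CH_H, 5);

    double cinf = 1.0 - (1.0 - aN) * (1.0 - cca);
    ydot[10] = (cinf - c) / CH(CH_TRPC5, 4);

    double uN = drive_level(trel, p[P_NKBMODE], p[P_NKBLEV],
                            p[P_NKBPER], p[P_NKBWID]);
    double uD = drive_level(trel, p[P_DYNMODE], p[P_DYNLEV],
                            p[P_DYNPER], p[P_DYNWID]);
    ydot[11] = uN * (1.0 - aN) / p[P_TNKON] - aN / p[P_TNKOFF];
    ydot[12] = uD * (1.0 - aD) / p[P_TDYON] - aD / p[P_TDYOFF];

    /* calcium pools: inward Ca currents are negative, hence the minus sign */
    double i_t5_ca = CH(CH_TRPC5, 5) * g_t5 * (v - eca);
    ydot[13] = -p[P_KD] * i_ca - (y[13] - p[P_CA0D]) / p[P_TAUD];
    ydot[14] = -p[P_KB] * (i_ca + i_t + i_t5_ca) -
               (y[14] - p[P_CA0]) / p[P_TAUB];

    ydot[15] = (CH(CH_TRPC5, 6) * c - dtr) / CH(CH_TRPC5, 7);

    yout[0]  = i_nat;  yout[1]  = i_nap; yout[2]  = i_a;   yout[3] = i_bk;
    yout[4]  = i_h;    yout[5]  = i_sk;  yout[6]  = i_m;   yout[7] = i_t;
    yout[8]  = i_ca;   yout[9]  = i_t5;  yout[10] = i_girk;
    yout[11] = i_leak; yout[12] = i_net; yout[13] = i_inj; yout[14] = v;
}
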