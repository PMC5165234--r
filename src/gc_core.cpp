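// Agent-based germinal center core: lattice movement with transient
// chemotaxis, two-step LZ selection, Hill-controlled division numbers,
// antibody feedback, founder influx.  All randomness goes through R's RNG
// so runs are reproducible from set.seed() on the R side.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstring>
using namespace Rcpp;

static const int DIRX[6] = { 1, -1, 0, 0, 0, 0 };
static const int DIRY[6] = { 0, 0, 1, -1, 0, 0 };
static const int DIRZ[6] = { 0, 0, 0, 0, 1, -1 };

// ---------------------------------------------------------------- geometry

struct Grid {
  int nx, ny, nz;
  double dx;                  // um per node
  inline int idx(int x, int y, int z) const { return x + nx * (y + ny * z); }
};

// ------------------------------------------------------------- small utils

static inline double norm3(double x, double y, double z) {
  return std::sqrt(x * x + y * y + z * z);
}

// Draw a unit vector at polar angle theta from u, uniform azimuth.
static void rotate_from(const double u[3], double theta, double out[3]) {
  double a[3];
  if (std::fabs(u[0]) < 0.9) { a[0] = 1; a[1] = 0; a[2] = 0; }
  else                        { a[0] = 0; a[1] = 1; a[2] = 0; }
  // e1 = normalize(a x u), e2 = u x e1
  double e1[3] = { a[1] * u[2] - a[2] * u[1],
                   a[2] * u[0] - a[0] * u[2],
                   a[0] * u[1] - a[1] * u[0] };
  double n1 = norm3(e1[0], e1[1], e1[2]);
  if (n1 < 1e-12) { e1[0] = 0; e1[1] = 1; e1[2] = 0; n1 = 1; }
  e1[0] /= n1; e1[1] /= n1; e1[2] /= n1;
  double e2[3] = { u[1] * e1[2] - u[2] * e1[1],
                   u[2] * e1[0] - u[0] * e1[2],
                   u[0] * e1[1] - u[1] * e1[0] };
  double phi = unif_rand() * 2.0 * M_PI;
  double ct = std::cos(theta), st = std::sin(theta);
  double cp = std::cos(phi),  sp = std::sin(phi);
  for (int k = 0; k < 3; ++k)
    out[k] = ct * u[k] + st * (cp * e1[k] + sp * e2[k]);
}

static void random_unit(double out[3]) {
  // Marsaglia
  double x1, x2, s;
  do {
    x1 = 2.0 * unif_rand() - 1.0;
    x2 = 2.0 * unif_rand() - 1.0;
    s = x1 * x1 + x2 * x2;
  } while (s >= 1.0 || s == 0.0);
  double f = 2.0 * std::sqrt(1.0 - s);
  out[0] = x1 * f; out[1] = x2 * f; out[2] = 1.0 - 2.0 * s;
}

// Turning angle (radians): Gaussian around mean, folded into [0, pi].
static double draw_turn_angle(double mean_deg, double sd_deg) {
  double th = mean_deg + sd_deg * norm_rand();
  th = std::fabs(th);
  while (th > 360.0) th -= 360.0;
  if (th > 180.0) th = 360.0 - th;
  return th * M_PI / 180.0;
}

// New polarity: persistent random turn, plus (if sensitive) the normalized
// chemokine gradient added with weight w, renormalized.
static void new_polarity(const double old_[3], const double grad[3],
                         bool sensitive, double w,
                         double mean_deg, double sd_deg, double out[3]) {
  double u[3] = { old_[0], old_[1], old_[2] };
  double nu = norm3(u[0], u[1], u[2]);
  double rdir[3];
  if (nu < 1e-12) {
    random_unit(rdir);
  } else {
    u[0] /= nu; u[1] /= nu; u[2] /= nu;
    double th = draw_turn_angle(mean_deg, sd_deg);
    rotate_from(u, th, rdir);
  }
  double g = norm3(grad[0], grad[1], grad[2]);
  if (sensitive && g > 1e-300) {
    double v[3] = { rdir[0] + w * grad[0] / g,
                    rdir[1] + w * grad[1] / g,
                    rdir[2] + w * grad[2] / g };
    double nv = norm3(v[0], v[1], v[2]);
    if (nv > 1e-12) {
      out[0] = v[0] / nv; out[1] = v[1] / nv; out[2] = v[2] / nv;
      return;
    }
  }
  out[0] = rdir[0]; out[1] = rdir[1]; out[2] = rdir[2];
}

// Pick one of the 6 lattice directions with probability proportional to the
// positive projection of the polarity; -1 if polarity is zero-projected.
static int choose_direction(const double pol[3]) {
  double p[6]; double tot = 0.0;
  p[0] = std::max(0.0,  pol[0]); p[1] = std::max(0.0, -pol[0]);
  p[2] = std::max(0.0,  pol[1]); p[3] = std::max(0.0, -pol[1]);
  p[4] = std::max(0.0,  pol[2]); p[5] = std::max(0.0, -pol[2]);
  for (int k = 0; k < 6; ++k) tot += p[k];
  if (tot <= 0.0) {
    int k = (int)std::floor(unif_rand() * 6.0);
    return k > 5 ? 5 : k;
  }
  double r = unif_rand() * tot;
  for (int k = 0; k < 6; ++k) { r -= p[k]; if (r <= 0.0) return k; }
  return 5;
}

// Hysteretic sensitivity switch.
static inline bool update_sensitive(bool sensitive, double c,
                                    double cD, double cR) {
  if (sensitive && c >= cD) return false;
  if (!sensitive && c <= cR) return true;
  return sensitive;
}

// Hill function for the dynamic number of divisions.
static inline double hill_divisions(double a, double pmin, double pmax,
                                    double np, double kp) {
  if (a <= 0.0) return pmin;
  double an = std::pow(a, np);
  return pmin + (pmax - pmin) * an / (an + std::pow(kp, np));
}

static inline int stochastic_round(double x) {
  int n = (int)std::floor(x);
  double f = x - n;
  if (f > 0.0 && unif_rand() < f) ++n;
  return n;
}

// ------------------------------------------------------------------ agents

enum State { ST_CB = 0,        // DZ phenotype, dividing (or deferring)
             ST_CB_WAIT = 1,   // division program done, awaiting cohort
             ST_CC_COLLECT = 2,// LZ phenotype, collecting antigen on FDCs
             ST_CC_TFH = 3,    // LZ phenotype, seeking Tfh help
             ST_DEAD = 4,      // apoptotic corpse, visible until cleared
             ST_MOTILE = 5 };  // motility-only walker

struct Agent {
  int x, y, z;
  double pol[3];
  int repolAt;            // next repolarization step
  int tauSteps;           // per-cell persistence interval in steps
  int type;               // 0 = B cell, 1 = Tfh
  int state;
  int pheno;              // 0 = DZ phenotype (CXCR4/CXCL12), 1 = LZ phenotype
  bool sens;              // sensitivity for the phenotype's chemokine
  int shape[4];
  double affinity;
  double antigen;
  int divisionsLeft;
  int cohort;             // -1 founder expansion, else cohort id
  int cycleEnd;           // absolute step of next division
  int deadlineAt;         // collect deadline / tfh deadline / corpse clearing
  double tfhSignal;       // accumulated help, minutes
  int frozenUntil;        // absolute step; frozen while t < frozenUntil
  bool alive;
  bool dec205;
  bool photo;
  bool tracked;
};

struct Cohort {
  int expected;
  int finished;
  int bestIdx;
  double bestAg;
  std::vector<int> members;   // finished members awaiting resolution
};

// ------------------------------------------------------------------- parms

struct Par {
  double dt;              // min
  int nSteps;
  // motility
  double pMoveB, pMoveT;
  double meanTurn, sdTurn, wChemo;
  double tauMin, tauMax;  // min
  double cD12, cR12, cD13, cR13;
  // gc
  double ratePerStep;     // founder influx per step
  int influxEndStep;
  int initialDivisions;
  int cycleSteps; double cycleJitter; int mphaseSteps;
  int collectSteps, contactSteps, tfhWindowSteps;
  double captureEff;      // per-contact capture probability scale
  double tfhRequiredMin;
  int corpseSteps;
  double pAsym, fAsym;
  double pMut;
  int nTfh;
  // shape/affinity
  double gamma;
  int shapeBound;
  // dnd
  double pmin, pmax, np, kp; bool dndOn;
  // feedback
  bool fbOn;
  double kon;             // 1/(M*min)
  double abRate;          // M/min per plasma cell (already / volume * nGC)
  double abDecay;         // 1/min antibody elimination
  double koff[4];         // per affinity class
  // dec205
  bool decOn; double decFrac; int decStep; int decWindowSteps;
  double decAntigen;
  // modes
  bool motilityOnly; int nMotile;
  // tracking
  int trackStart, trackEnd, trackEvery;
  // photoactivation
  bool paOn; int paStep; int paZone; double paCx, paCy, paCz, paRad; int paEvery;
  // recording
  int tsEvery;
};

// -------------------------------------------------------------------- sim

struct Sim {
  Grid g;
  std::vector<int> occ;       // -9 blocked, -1 free, else agent index
  std::vector<int> zone;      // 0 DZ, 1 LZ, -1 outside
  std::vector<int> fdcSite;   // -1 or site id (contact node)
  std::vector<double> fdcFree;
  std::vector<double> c12, c13, g12[3], g13[3];
  std::vector<int> inside;    // node indices inside the GC
  NumericMatrix founderShapes;
  Par p;

  std::vector<Agent> ag;
  std::vector<Cohort> cohorts;
  int t = 0;

  // bookkeeping
  double fdcTotal0 = 0;
  long collectedEvents = 0;
  double grantedExo = 0;
  double sinkRecycled = 0, sinkDead = 0, sinkPlasma = 0;
  long founders = 0;
  long plasma = 0; double plasmaAffSum = 0;
  long selections = 0; double divisionsGrantedSum = 0;
  std::vector<int> selDivisions;
  std::vector<double> selAntigen;
  double Ab[4] = {0, 0, 0, 0};
  double bound[4] = {0, 0, 0, 0};
  long plasmaClass[4] = {0, 0, 0, 0};
  long exchAttempt = 0, exchDone = 0;
  long diedCollect = 0, diedTfh = 0, enteredTfhPhase = 0;
  double tfhContactMin = 0, maxTfhSignal = 0;

  // outputs
  std::vector<double> tsRows;
  int tsNcol = 0;
  std::vector<double> trackRows;
  std::vector<double> paRows;
  long paN0 = 0;

  double affinity_of(const int s[4]) const {
    int d = std::abs(s[0]) + std::abs(s[1]) + std::abs(s[2]) + std::abs(s[3]);
    double q = (double)d / p.gamma;
    return std::exp(-q * q);
  }

  int aff_class(double a) const {
    int c = (int)std::floor(a * 4.0);
    if (c > 3) c = 3;
    if (c < 0) c = 0;
    return c;
  }

  void mutate(int s[4]) {
    if (unif_rand() >= p.pMut) return;
    int moves[8][2]; int nm = 0;
    for (int ax = 0; ax < 4; ++ax)
      for (int d = -1; d <= 1; d += 2)
        if (std::abs(s[ax] + d) <= p.shapeBound) { moves[nm][0] = ax; moves[nm][1] = d; ++nm; }
    if (nm == 0) return;
    int k = (int)std::floor(unif_rand() * nm);
    if (k >= nm) k = nm - 1;
    s[moves[k][0]] += moves[k][1];
  }

  int random_free_node() {
    for (int tries = 0; tries < 400; ++tries) {
      int i = (int)std::floor(unif_rand() * inside.size());
      if (i >= (int)inside.size()) i = inside.size() - 1;
      int node = inside[i];
      if (occ[node] == -1) return node;
    }
    return -1;
  }

  int new_cycle_end() {
    double j = 1.0 + p.cycleJitter * (2.0 * unif_rand() - 1.0);
    int n = (int)std::lround(p.cycleSteps * j);
    if (n < 2) n = 2;
    return t + n;
  }

  int draw_tau_steps() {
    double tau = p.tauMin + (p.tauMax - p.tauMin) * unif_rand();
    int n = (int)std::lround(tau / p.dt);
    if (n < 1) n = 1;
    return n;
  }

  void place_agent(Agent &a, int node) {
    a.x = node % g.nx;
    a.y = (node / g.nx) % g.ny;
    a.z = node / (g.nx * g.ny);
    occ[node] = (int)(&a - &ag[0]);
  }

  void spawn_founder() {
    int node = random_free_node();
    if (node < 0) return;
    Agent a;
    std::memset(&a, 0, sizeof(Agent));
    a.type = 0; a.state = ST_CB; a.pheno = 0; a.sens = true;
    int row = (int)std::floor(unif_rand() * founderShapes.nrow());
    if (row >= founderShapes.nrow()) row = founderShapes.nrow() - 1;
    for (int k = 0; k < 4; ++k) a.shape[k] = (int)founderShapes(row, k);
    a.affinity = affinity_of(a.shape);
    a.antigen = 0;
    a.divisionsLeft = p.initialDivisions;
    a.cohort = -1;
    a.cycleEnd = new_cycle_end();
    a.tauSteps = draw_tau_steps();
    a.repolAt = t + (int)std::floor(unif_rand() * a.tauSteps);
    random_unit(a.pol);
    a.frozenUntil = -1; a.deadlineAt = -1;
    a.alive = true;
    a.dec205 = p.decOn && (unif_rand() < p.decFrac);
    ag.push_back(a);
    place_agent(ag.back(), node);
    ++founders;
  }

  void spawn_tfh() {
    int node = random_free_node();
    if (node < 0) return;
    Agent a;
    std::memset(&a, 0, sizeof(Agent));
    a.type = 1; a.state = ST_MOTILE; a.pheno = 1; a.sens = true;
    a.tauSteps = draw_tau_steps();
    a.repolAt = t + (int)std::floor(unif_rand() * a.tauSteps);
    random_unit(a.pol);
    a.frozenUntil = -1; a.alive = true;
    ag.push_back(a);
    place_agent(ag.back(), node);
  }

  void spawn_motile_b() {
    int node = random_free_node();
    if (node < 0) return;
    Agent a;
    std::memset(&a, 0, sizeof(Agent));
    a.type = 0; a.state = ST_MOTILE;
    a.pheno = (zone[node] == 1) ? 1 : 0;
    a.sens = true;
    a.tauSteps = draw_tau_steps();
    a.repolAt = t + (int)std::floor(unif_rand() * a.tauSteps);
    random_unit(a.pol);
    a.frozenUntil = -1; a.alive = true;
    ag.push_back(a);
    place_agent(ag.back(), node);
  }

  void die(int i) {
    Agent &a = ag[i];
    a.state = ST_DEAD;
    a.pheno = 1;            // apoptotic centrocytes keep the LZ phenotype
    a.sens = false;
    a.deadlineAt = t + p.corpseSteps;
  }

  void clear_corpse(int i) {
    Agent &a = ag[i];
    sinkDead += a.antigen;
    a.antigen = 0;
    int node = g.idx(a.x, a.y, a.z);
    if (occ[node] == i) occ[node] = -1;
    a.alive = false;
  }

  void become_cc(int i) {
    Agent &a = ag[i];
    a.state = ST_CC_COLLECT;
    a.pheno = 1;
    a.sens = true;          // fresh CXCL13 sensitivity
    sinkRecycled += a.antigen;
    a.antigen = 0;
    a.deadlineAt = t + p.collectSteps;
    if (p.decOn && a.dec205 && t >= p.decStep && t < p.decStep + p.decWindowSteps) {
      // targeted antigen delivery: antigen arrives without FDC collection
      a.antigen = p.decAntigen;
      grantedExo += p.decAntigen;
      a.state = ST_CC_TFH;
      a.tfhSignal = 0;
      a.deadlineAt = t + p.tfhWindowSteps;
    }
  }

  void select_cell(int i) {
    Agent &a = ag[i];
    double P = p.dndOn
      ? hill_divisions(a.antigen, p.pmin, p.pmax, p.np, p.kp)
      : 2.0;                 // fixed division number when DND is off
    int n = stochastic_round(P);
    if (n < 1) n = 1;
    ++selections;
    divisionsGrantedSum += n;
    selDivisions.push_back(n);
    selAntigen.push_back(a.antigen);
    a.state = ST_CB;
    a.pheno = 0;
    a.sens = true;           // CXCR4 sensitivity reset on recycling
    a.divisionsLeft = n;
    Cohort c; c.expected = 1 << n; c.finished = 0; c.bestIdx = -1; c.bestAg = -1;
    cohorts.push_back(c);
    a.cohort = (int)cohorts.size() - 1;
    a.cycleEnd = new_cycle_end();
  }

  void finish_division_program(int i) {
    Agent &a = ag[i];
    if (a.cohort < 0) {       // founder expansion ends in LZ differentiation
      become_cc(i);
      return;
    }
    a.state = ST_CB_WAIT;
    Cohort &c = cohorts[a.cohort];
    ++c.finished;
    c.members.push_back(i);
    if (a.antigen > c.bestAg) { c.bestAg = a.antigen; c.bestIdx = i; }
    if (c.finished >= c.expected) resolve_cohort(a.cohort);
  }

  void resolve_cohort(int cid) {
    Cohort &c = cohorts[cid];
    for (size_t k = 0; k < c.members.size(); ++k) {
      int i = c.members[k];
      Agent &a = ag[i];
      if (!a.alive || a.cohort != cid || a.state != ST_CB_WAIT) continue;
      if (i == c.bestIdx) {
        // highest-antigen sibling leaves as a plasma cell
        sinkPlasma += a.antigen;
        ++plasma;
        plasmaAffSum += a.affinity;
        ++plasmaClass[aff_class(a.affinity)];
        int node = g.idx(a.x, a.y, a.z);
        if (occ[node] == i) occ[node] = -1;
        a.alive = false;
      } else {
        a.cohort = -2;
        become_cc(i);
      }
    }
  }

  void try_divide(int i) {
    Agent &a = ag[i];
    int order[6] = {0, 1, 2, 3, 4, 5};
    for (int k = 5; k > 0; --k) {
      int j = (int)std::floor(unif_rand() * (k + 1));
      int tmp = order[k]; order[k] = order[j]; order[j] = tmp;
    }
    int target = -1;
    for (int k = 0; k < 6; ++k) {
      int nx_ = a.x + DIRX[order[k]], ny_ = a.y + DIRY[order[k]], nz_ = a.z + DIRZ[order[k]];
      if (nx_ < 0 || ny_ < 0 || nz_ < 0 || nx_ >= g.nx || ny_ >= g.ny || nz_ >= g.nz) continue;
      int node = g.idx(nx_, ny_, nz_);
      if (occ[node] == -1) { target = node; break; }
    }
    if (target < 0) return;   // crowded: division deferred, retry next step
    Agent d;
    std::memset(&d, 0, sizeof(Agent));
    d.type = 0; d.state = ST_CB; d.pheno = 0; d.sens = a.sens;
    d.cohort = a.cohort;
    d.dec205 = a.dec205;
    d.photo = false;          // the photoactivated label stays with the parent
    d.tracked = false;
    for (int k = 0; k < 4; ++k) d.shape[k] = a.shape[k];
    // asymmetric antigen inheritance
    double a1;
    if (unif_rand() < p.pAsym) {
      double f = (unif_rand() < 0.5) ? p.fAsym : (1.0 - p.fAsym);
      a1 = a.antigen * f;
    } else a1 = a.antigen * 0.5;
    d.antigen = a.antigen - a1;
    a.antigen = a1;
    d.divisionsLeft = a.divisionsLeft - 1;
    a.divisionsLeft -= 1;
    mutate(a.shape); a.affinity = affinity_of(a.shape);
    mutate(d.shape); d.affinity = affinity_of(d.shape);
    d.tauSteps = draw_tau_steps();
    d.repolAt = t; // polarize at birth
    random_unit(d.pol);
    d.frozenUntil = -1; d.alive = true;
    a.cycleEnd = new_cycle_end();
    int ii = (int)ag.size();
    ag.push_back(d);
    Agent &dd = ag[ii];
    dd.cycleEnd = new_cycle_end();
    dd.x = target % g.nx; dd.y = (target / g.nx) % g.ny; dd.z = target / (g.nx * g.ny);
    occ[target] = ii;
    // agents that completed their program differentiate
    if (ag[i].divisionsLeft <= 0) finish_division_program(i);
    if (ag[ii].divisionsLeft <= 0) finish_division_program(ii);
  }

  void move_agent(int i) {
    Agent &a = ag[i];
    // repolarization: sense chemokine, update sensitivity, new polarity
    if (t >= a.repolAt) {
      int node = g.idx(a.x, a.y, a.z);
      double c, grad[3]; double cD, cR;
      if (a.pheno == 0) {
        c = c12[node];
        grad[0] = g12[0][node]; grad[1] = g12[1][node]; grad[2] = g12[2][node];
        cD = p.cD12; cR = p.cR12;
      } else {
        c = c13[node];
        grad[0] = g13[0][node]; grad[1] = g13[1][node]; grad[2] = g13[2][node];
        cD = p.cD13; cR = p.cR13;
      }
      a.sens = update_sensitive(a.sens, c, cD, cR);
      double np_[3];
      new_polarity(a.pol, grad, a.sens, p.wChemo, p.meanTurn, p.sdTurn, np_);
      a.pol[0] = np_[0]; a.pol[1] = np_[1]; a.pol[2] = np_[2];
      a.repolAt = t + a.tauSteps;
    }
    double pMove = (a.type == 1) ? p.pMoveT : p.pMoveB;
    if (unif_rand() >= pMove) return;
    int d = choose_direction(a.pol);
    int nx_ = a.x + DIRX[d], ny_ = a.y + DIRY[d], nz_ = a.z + DIRZ[d];
    if (nx_ < 0 || ny_ < 0 || nz_ < 0 || nx_ >= g.nx || ny_ >= g.ny || nz_ >= g.nz) return;
    int to = g.idx(nx_, ny_, nz_);
    int from = g.idx(a.x, a.y, a.z);
    int o = occ[to];
    if (o == -9) return;               // outside GC or FDC soma: stay
    if (o == -1) {
      occ[from] = -1; occ[to] = i;
      a.x = nx_; a.y = ny_; a.z = nz_;
      return;
    }
    // occupied: exchange only if the resident is motile and opposing
    Agent &b = ag[o];
    if (b.state == ST_DEAD || t < b.frozenUntil) return;
    double dp = a.pol[0] * b.pol[0] + a.pol[1] * b.pol[1] + a.pol[2] * b.pol[2];
    if (dp < 0.0) {
      ++exchAttempt;
      if (unif_rand() < 0.5) {
        ++exchDone;
        occ[from] = o; occ[to] = i;
        b.x = a.x; b.y = a.y; b.z = a.z;
        a.x = nx_; a.y = ny_; a.z = nz_;
      }
    }
  }

  void feedback_step() {
    if (!p.fbOn) return;
    double B = bound[0] + bound[1] + bound[2] + bound[3];
    for (int c = 0; c < 4; ++c) {
      Ab[c] += (plasmaClass[c] * p.abRate - p.abDecay * Ab[c]) * p.dt;
      double db = p.kon * Ab[c] * (1.0 - B) - p.koff[c] * bound[c];
      bound[c] += db * p.dt;
      if (bound[c] < 0) bound[c] = 0;
    }
    double Bt = bound[0] + bound[1] + bound[2] + bound[3];
    if (Bt > 1.0) for (int c = 0; c < 4; ++c) bound[c] /= Bt;
  }

  double masked() const {
    double B = bound[0] + bound[1] + bound[2] + bound[3];
    return (B > 1.0) ? 1.0 : B;
  }

  void record_ts() {
    int nB = 0, nDZpos = 0, nLZpos = 0, nCB = 0, nCC = 0, nCorpse = 0;
    int decP_DZ = 0, decP_LZ = 0, decN_DZ = 0, decN_LZ = 0;
    double affSum = 0;
    for (int i = 0; i < (int)ag.size(); ++i) {
      const Agent &a = ag[i];
      if (!a.alive || a.type != 0) continue;
      int zn = zone[g.idx(a.x, a.y, a.z)];
      if (a.state == ST_DEAD) { ++nCorpse; continue; }
      ++nB; affSum += a.affinity;
      if (zn == 0) ++nDZpos; else ++nLZpos;
      if (a.state == ST_CB || a.state == ST_CB_WAIT) ++nCB; else ++nCC;
      if (p.decOn) {
        if (a.dec205) { if (zn == 0) ++decP_DZ; else ++decP_LZ; }
        else          { if (zn == 0) ++decN_DZ; else ++decN_LZ; }
      }
    }
    double freeAg = 0;
    for (size_t s = 0; s < fdcFree.size(); ++s) freeAg += fdcFree[s];
    double row[] = {
      t * p.dt / 1440.0,                    // day
      (double)nB, (double)nDZpos, (double)nLZpos,
      (double)nCB, (double)nCC, (double)nCorpse,
      (double)plasma,
      plasma > 0 ? plasmaAffSum / plasma : NA_REAL,
      nB > 0 ? affSum / nB : NA_REAL,
      fdcTotal0 > 0 ? (freeAg / fdcTotal0) * (1.0 - masked()) : NA_REAL,
      masked(),
      (double)founders,
      (double)selections,
      selections > 0 ? divisionsGrantedSum / selections : NA_REAL,
      (double)decP_DZ, (double)decP_LZ, (double)decN_DZ, (double)decN_LZ
    };
    tsNcol = sizeof(row) / sizeof(double);
    for (int k = 0; k < tsNcol; ++k) tsRows.push_back(row[k]);
  }

  void record_tracks() {
    for (int i = 0; i < (int)ag.size(); ++i) {
      const Agent &a = ag[i];
      if (!a.tracked || !a.alive || a.type != 0 || a.state == ST_DEAD) continue;
      int node = g.idx(a.x, a.y, a.z);
      trackRows.push_back((double)i);
      trackRows.push_back(t * p.dt);
      trackRows.push_back(a.x * g.dx);
      trackRows.push_back(a.y * g.dx);
      trackRows.push_back(a.z * g.dx);
      trackRows.push_back((double)zone[node]);
      trackRows.push_back((t < a.frozenUntil) ? 1.0 : 0.0);
    }
  }

  void record_pa() {
    long inDZ = 0, inLZ = 0, corpses = 0, gone = paN0;
    for (int i = 0; i < (int)ag.size(); ++i) {
      const Agent &a = ag[i];
      if (!a.photo) continue;
      if (!a.alive) continue;
      --gone;
      int zn = zone[g.idx(a.x, a.y, a.z)];
      if (a.state == ST_DEAD) { ++corpses; if (zn == 0) ++inDZ; else ++inLZ; continue; }
      if (zn == 0) ++inDZ; else ++inLZ;
    }
    paRows.push_back(t * p.dt);
    paRows.push_back((double)inDZ);
    paRows.push_back((double)inLZ);
    paRows.push_back((double)corpses);
    paRows.push_back((double)gone);
  }

  void photoactivate() {
    for (int i = 0; i < (int)ag.size(); ++i) {
      Agent &a = ag[i];
      if (!a.alive || a.type != 0 || a.state == ST_DEAD) continue;
      int node = g.idx(a.x, a.y, a.z);
      if (zone[node] != p.paZone) continue;
      double dx_ = (a.x - p.paCx) * g.dx, dy_ = (a.y - p.paCy) * g.dx,
             dz_ = (a.z - p.paCz) * g.dx;
      if (dx_ * dx_ + dy_ * dy_ + dz_ * dz_ <= p.paRad * p.paRad) {
        a.photo = true;
        ++paN0;
      }
    }
  }

  void run() {
    if (p.motilityOnly) {
      for (int i = 0; i < p.nMotile; ++i) spawn_motile_b();
    } else {
      for (int i = 0; i < p.nTfh; ++i) spawn_tfh();
    }
    std::vector<int> active;
    size_t known = 0;            // agents already entered into the list
    for (t = 0; t < p.nSteps; ++t) {
      if (!p.motilityOnly && t < p.influxEndStep) {
        int n = (int)R::rpois(p.ratePerStep);
        for (int k = 0; k < n; ++k) spawn_founder();
      }
      if (p.paOn && t == p.paStep) photoactivate();
      if (p.trackEvery > 0 && t == p.trackStart) {
        for (int i = 0; i < (int)ag.size(); ++i)
          if (ag[i].alive && ag[i].type == 0 && ag[i].state != ST_DEAD)
            ag[i].tracked = true;
      }
      feedback_step();

      // incremental active list: drop the dead, append the newly created
      size_t w = 0;
      for (size_t r = 0; r < active.size(); ++r)
        if (ag[active[r]].alive) active[w++] = active[r];
      active.resize(w);
      for (; known < ag.size(); ++known)
        if (ag[known].alive) active.push_back((int)known);
      // shuffle for unbiased conflict resolution
      for (int k = (int)active.size() - 1; k > 0; --k) {
        int j = (int)std::floor(unif_rand() * (k + 1));
        int tmp = active[k]; active[k] = active[j]; active[j] = tmp;
      }

      for (size_t ii = 0; ii < active.size(); ++ii) {
        int i = active[ii];
        Agent &a = ag[i];
        if (!a.alive) continue;

        if (a.state == ST_DEAD) {
          if (t >= a.deadlineAt) clear_corpse(i);
          continue;
        }

        if (!p.motilityOnly && a.type == 0) {
          switch (a.state) {
          case ST_CB:
            if (t >= a.cycleEnd && a.divisionsLeft > 0) try_divide(i);
            break;
          case ST_CC_COLLECT:
            if (t >= a.deadlineAt) {
              if (a.antigen <= 0) { ++diedCollect; die(i); continue; }
              a.state = ST_CC_TFH;
              a.tfhSignal = 0;
              a.deadlineAt = t + p.tfhWindowSteps;
              ++enteredTfhPhase;
            } else if (t >= a.frozenUntil) {
              int node = g.idx(a.x, a.y, a.z);
              int s = fdcSite[node];
              if (s >= 0 && fdcFree[s] >= 1.0) {
                double pSucc = p.captureEff * a.affinity * (1.0 - masked());
                if (unif_rand() < pSucc) {
                  fdcFree[s] -= 1.0;
                  a.antigen += 1.0;
                  ++collectedEvents;
                  a.frozenUntil = t + p.contactSteps;
                }
              }
            }
            break;
          case ST_CC_TFH:
            if (a.tfhSignal >= p.tfhRequiredMin) { select_cell(i); break; }
            if (t >= a.deadlineAt) { ++diedTfh; die(i); continue; }
            break;
          default: break;
          }
          if (!ag[i].alive || ag[i].state == ST_DEAD) continue;
        }

        Agent &a2 = ag[i];
        bool mphase = (!p.motilityOnly && a2.type == 0 &&
                       (a2.state == ST_CB) && a2.divisionsLeft > 0 &&
                       (a2.cycleEnd - t) <= p.mphaseSteps);
        if (mphase) a2.frozenUntil = std::max(a2.frozenUntil, t + 1);
        if (t < a2.frozenUntil) continue;   // frozen: skip polarity + move
        move_agent(i);
      }

      // Tfh help: each Tfh polarizes to the neighboring B cell presenting
      // the most antigen and delivers signal for this step.
      if (!p.motilityOnly) {
        for (size_t ii = 0; ii < active.size(); ++ii) {
          int i = active[ii];
          Agent &a = ag[i];
          if (!a.alive || a.type != 1) continue;
          int best = -1; double bestAg = -1; int nbest = 0;
          for (int k = 0; k < 6; ++k) {
            int nx_ = a.x + DIRX[k], ny_ = a.y + DIRY[k], nz_ = a.z + DIRZ[k];
            if (nx_ < 0 || ny_ < 0 || nz_ < 0 || nx_ >= g.nx || ny_ >= g.ny || nz_ >= g.nz) continue;
            int o = occ[g.idx(nx_, ny_, nz_)];
            if (o < 0) continue;
            Agent &b = ag[o];
            if (!b.alive || b.type != 0 || b.state != ST_CC_TFH) continue;
            if (b.antigen > bestAg) { bestAg = b.antigen; best = o; nbest = 1; }
            else if (b.antigen == bestAg) {
              ++nbest;
              if (unif_rand() < 1.0 / nbest) best = o;   // uniform tie-break
            }
          }
          if (best >= 0) {
            // stable conjugate: both cells pause while the Tfh is polarized
            Agent &b = ag[best];
            b.tfhSignal += p.dt;
            tfhContactMin += p.dt;
            if (b.tfhSignal > maxTfhSignal) maxTfhSignal = b.tfhSignal;
            // the pass runs after movement, so the freeze must cover the
            // following step for the conjugate to persist
            b.frozenUntil = std::max(b.frozenUntil, t + 2);
            a.frozenUntil = std::max(a.frozenUntil, t + 2);
          }
        }
      }

      if (p.trackEvery > 0 && t >= p.trackStart && t <= p.trackEnd &&
          (t - p.trackStart) % p.trackEvery == 0)
        record_tracks();
      if (p.paOn && t >= p.paStep && (t - p.paStep) % p.paEvery == 0)
        record_pa();
      if (t % p.tsEvery == 0) record_ts();
    }
    if ((p.nSteps - 1) % p.tsEvery != 0) record_ts();
  }
};

// ------------------------------------------------------------- R interface

static std::vector<double> as_dvec(SEXP x) {
  NumericVector v(x);
  return std::vector<double>(v.begin(), v.end());
}
static std::vector<int> as_ivec(SEXP x) {
  IntegerVector v(x);
  return std::vector<int>(v.begin(), v.end());
}

// [[Rcpp::export]]
List cpp_run(List arena, List par) {
  Sim s;
  s.g.nx = as<int>(arena["nx"]);
  s.g.ny = as<int>(arena["ny"]);
  s.g.nz = as<int>(arena["nz"]);
  s.g.dx = as<double>(arena["dx"]);
  s.occ = as_ivec(arena["occ"]);
  s.zone = as_ivec(arena["zone"]);
  s.fdcSite = as_ivec(arena["fdc_site"]);
  s.fdcFree = as_dvec(arena["fdc_free"]);
  s.c12 = as_dvec(arena["c12"]);
  s.c13 = as_dvec(arena["c13"]);
  List G12 = arena["g12"], G13 = arena["g13"];
  for (int k = 0; k < 3; ++k) {
    s.g12[k] = as_dvec(G12[k]);
    s.g13[k] = as_dvec(G13[k]);
  }
  s.inside = as_ivec(arena["inside"]);
  s.founderShapes = as<NumericMatrix>(arena["founder_shapes"]);
  for (size_t k = 0; k < s.fdcFree.size(); ++k) s.fdcTotal0 += s.fdcFree[k];

  Par &p = s.p;
  p.dt = as<double>(par["dt"]);
  p.nSteps = as<int>(par["n_steps"]);
  p.pMoveB = as<double>(par["p_move_b"]);
  p.pMoveT = as<double>(par["p_move_t"]);
  p.meanTurn = as<double>(par["mean_turn"]);
  p.sdTurn = as<double>(par["sd_turn"]);
  p.wChemo = as<double>(par["w_chemo"]);
  p.tauMin = as<double>(par["tau_min"]);
  p.tauMax = as<double>(par["tau_max"]);
  p.cD12 = as<double>(par["cD12"]); p.cR12 = as<double>(par["cR12"]);
  p.cD13 = as<double>(par["cD13"]); p.cR13 = as<double>(par["cR13"]);
  p.ratePerStep = as<double>(par["influx_per_step"]);
  p.influxEndStep = as<int>(par["influx_end_step"]);
  p.initialDivisions = as<int>(par["initial_divisions"]);
  p.cycleSteps = as<int>(par["cycle_steps"]);
  p.cycleJitter = as<double>(par["cycle_jitter"]);
  p.mphaseSteps = as<int>(par["mphase_steps"]);
  p.collectSteps = as<int>(par["collect_steps"]);
  p.contactSteps = as<int>(par["contact_steps"]);
  p.captureEff = as<double>(par["capture_eff"]);
  p.tfhWindowSteps = as<int>(par["tfh_window_steps"]);
  p.tfhRequiredMin = as<double>(par["tfh_required_min"]);
  p.corpseSteps = as<int>(par["corpse_steps"]);
  p.pAsym = as<double>(par["p_asym"]);
  p.fAsym = as<double>(par["f_asym"]);
  p.pMut = as<double>(par["p_mut"]);
  p.nTfh = as<int>(par["n_tfh"]);
  p.gamma = as<double>(par["gamma"]);
  p.shapeBound = as<int>(par["shape_bound"]);
  p.pmin = as<double>(par["p_min"]);
  p.pmax = as<double>(par["p_max"]);
  p.np = as<double>(par["n_p"]);
  p.kp = as<double>(par["k_p"]);
  p.dndOn = as<bool>(par["dnd_on"]);
  p.fbOn = as<bool>(par["feedback_on"]);
  p.kon = as<double>(par["k_on"]);
  p.abRate = as<double>(par["ab_rate"]);
  p.abDecay = as<double>(par["ab_decay"]);
  NumericVector koff = par["k_off"];
  for (int k = 0; k < 4; ++k) p.koff[k] = koff[k];
  p.decOn = as<bool>(par["dec_on"]);
  p.decFrac = as<double>(par["dec_frac"]);
  p.decStep = as<int>(par["dec_step"]);
  p.decWindowSteps = as<int>(par["dec_window_steps"]);
  p.decAntigen = as<double>(par["dec_antigen"]);
  p.motilityOnly = as<bool>(par["motility_only"]);
  p.nMotile = as<int>(par["n_motile"]);
  p.trackStart = as<int>(par["track_start"]);
  p.trackEnd = as<int>(par["track_end"]);
  p.trackEvery = as<int>(par["track_every"]);
  p.paOn = as<bool>(par["pa_on"]);
  p.paStep = as<int>(par["pa_step"]);
  p.paZone = as<int>(par["pa_zone"]);
  p.paCx = as<double>(par["pa_cx"]);
  p.paCy = as<double>(par["pa_cy"]);
  p.paCz = as<double>(par["pa_cz"]);
  p.paRad = as<double>(par["pa_rad"]);
  p.paEvery = as<int>(par["pa_every"]);
  p.tsEvery = as<int>(par["ts_every"]);

  s.ag.reserve(200000);
  s.run();

  int nts = s.tsRows.size() / s.tsNcol;
  NumericMatrix ts(nts, s.tsNcol);
  for (int r = 0; r < nts; ++r)
    for (int c = 0; c < s.tsNcol; ++c)
      ts(r, c) = s.tsRows[r * s.tsNcol + c];

  int ntr = s.trackRows.size() / 7;
  NumericMatrix tr(ntr, 7);
  for (int r = 0; r < ntr; ++r)
    for (int c = 0; c < 7; ++c)
      tr(r, c) = s.trackRows[r * 7 + c];

  int npa = s.paRows.size() / 5;
  NumericMatrix pa(npa, 5);
  for (int r = 0; r < npa; ++r)
    for (int c = 0; c < 5; ++c)
      pa(r, c) = s.paRows[r * 5 + c];

  // live-agent summary for conservation checks
  double heldLive = 0, heldCorpse = 0;
  int nLive = 0;
  for (size_t i = 0; i < s.ag.size(); ++i) {
    const Agent &a = s.ag[i];
    if (!a.alive || a.type != 0) continue;
    if (a.state == ST_DEAD) heldCorpse += a.antigen;
    else { heldLive += a.antigen; ++nLive; }
  }
  double fdcLeft = 0;
  for (size_t k = 0; k < s.fdcFree.size(); ++k) fdcLeft += s.fdcFree[k];

  return List::create(
    _["ts"] = ts,
    _["tracks"] = tr,
    _["photo"] = pa,
    _["photo_n0"] = (double)s.paN0,
    _["founders"] = (double)s.founders,
    _["plasma"] = (double)s.plasma,
    _["plasma_mean_affinity"] = s.plasma > 0 ? s.plasmaAffSum / s.plasma : NA_REAL,
    _["selections"] = (double)s.selections,
    _["sel_divisions"] = IntegerVector(s.selDivisions.begin(), s.selDivisions.end()),
    _["sel_antigen"] = NumericVector(s.selAntigen.begin(), s.selAntigen.end()),
    _["collected_events"] = (double)s.collectedEvents,
    _["granted_exogenous"] = s.grantedExo,
    _["antigen_held_live"] = heldLive,
    _["antigen_held_corpse"] = heldCorpse,
    _["antigen_sink_recycled"] = s.sinkRecycled,
    _["antigen_sink_dead"] = s.sinkDead,
    _["antigen_sink_plasma"] = s.sinkPlasma,
    _["fdc_antigen_initial"] = s.fdcTotal0,
    _["fdc_antigen_left"] = fdcLeft,
    _["masked_final"] = s.masked(),
    _["died_collect"] = (double)s.diedCollect,
    _["died_tfh"] = (double)s.diedTfh,
    _["entered_tfh_phase"] = (double)s.enteredTfhPhase,
    _["tfh_contact_min"] = s.tfhContactMin,
    _["max_tfh_signal"] = s.maxTfhSignal,
    _["exchange_attempts"] = (double)s.exchAttempt,
    _["exchange_done"] = (double)s.exchDone,
    _["n_live_final"] = (double)nLive
  );
}

// ----------------------------------------------------- unit-test wrappers

// [[Rcpp::export]]
LogicalVector cpp_update_sensitivity(LogicalVector sensitive, NumericVector c,
                                     double cD, double cR) {
  int n = sensitive.size();
  LogicalVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = update_sensitive(sensitive[i], c[i], cD, cR);
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_new_polarity(NumericVector old_, NumericVector grad,
                               bool sensitive, double w,
                               double mean_deg, double sd_deg, int n) {
  NumericMatrix out(n, 3);
  double o[3] = { old_[0], old_[1], old_[2] };
  double g[3] = { grad[0], grad[1], grad[2] };
  double res[3];
  for (int i = 0; i < n; ++i) {
    new_polarity(o, g, sensitive, w, mean_deg, sd_deg, res);
    out(i, 0) = res[0]; out(i, 1) = res[1]; out(i, 2) = res[2];
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_choose_direction(NumericVector pol, int n) {
  IntegerVector out(n);
  double p[3] = { pol[0], pol[1], pol[2] };
  for (int i = 0; i < n; ++i) out[i] = choose_direction(p);
  return out;
}

// Two adjacent cells with given polarities; returns the fraction of trials
// in which they swap under the exchange rule (movement probability 1).
// [[Rcpp::export]]
double cpp_exchange_fraction(NumericVector polA, NumericVector polB, int n) {
  double dp = polA[0] * polB[0] + polA[1] * polB[1] + polA[2] * polB[2];
  if (dp >= 0) return 0.0;
  int done = 0;
  for (int i = 0; i < n; ++i) if (unif_rand() < 0.5) ++done;
  return (double)done / n;
}

// [[Rcpp::export]]
NumericVector cpp_hill_divisions(NumericVector a, double pmin, double pmax,
                                 double np, double kp) {
  int n = a.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = hill_divisions(a[i], pmin, pmax, np, kp);
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_stochastic_round(NumericVector x) {
  int n = x.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = stochastic_round(x[i]);
  return out;
}

// [[Rcpp::export]]
int cpp_pick_max_antigen(NumericVector antigen) {
  int best = -1; double bestAg = -1; int nbest = 0;
  for (int i = 0; i < antigen.size(); ++i) {
    if (antigen[i] > bestAg) { bestAg = antigen[i]; best = i; nbest = 1; }
    else if (antigen[i] == bestAg) {
      ++nbest;
      if (unif_rand() < 1.0 / nbest) best = i;
    }
  }
  return best + 1;  // 1-based for R
}

// Antibody-antigen masking ODE used in the main loop, integrated at fixed Ab
// concentration; returns the bound (masked) fraction over time.
// [[Rcpp::export]]
NumericVector cpp_masking_ode(double Ab, double kon, double koff,
                              double dt, int n_steps) {
  NumericVector out(n_steps);
  double b = 0;
  for (int i = 0; i < n_steps; ++i) {
    b += (kon * Ab * (1.0 - b) - koff * b) * dt;
    if (b < 0) b = 0;
    if (b > 1) b = 1;
    out[i] = b;
  }
  return out;
}
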