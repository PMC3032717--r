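// Lattice agent-based model of the immune response to a viral tissue
// infection: three square zones (tissue / lymphoid / blood), diffusing signal
// fields, nine agent types driven by finite-state automata (one edge per
// agent per tick), portal-mediated migration, and per-agent ledgers of
// "meaningful" contacts (contacts that change a state or an internal
// variable).  The engine is C++ for speed; all randomness is drawn from R's
// RNG so set.seed() makes full trajectories bit-reproducible.

#include <Rcpp.h>
#include <deque>
#include <vector>
#include <array>
#include <cstring>
using namespace Rcpp;

// ---------------------------------------------------------------- constants

enum AType { T_PC = 0, T_PORTAL, T_DC, T_MAC, T_NK, T_GRAN, T_T, T_B, T_CTL };
static const int NTYPE = 9;
static const char* TYPE_NAMES[NTYPE] = {
  "Parenchymal", "Portal", "Dendritic", "Macrophage", "NaturalKiller",
  "Granulocyte", "TCell", "BCell", "CTL" };

enum SState {
  PC_Healthy = 0, PC_Stressed, PC_Infected, PC_DeadNecrotic, PC_DeadApoptotic,
  Portal_Open,
  DC_Immature, DC_Activated, DC_Presenting, DC_DeadApoptotic,
  M_Resting, M_M1, M_M2, M_DeadApoptotic,
  NK_Patrol, NK_DeadApoptotic,
  G_Resting, G_Active, G_DeadApoptotic,
  T_Naive, T_Activated, T_Effector, T_Memory, T_DeadApoptotic,
  B_Naive, B_Activated, B_Plasma, B_Memory, B_DeadApoptotic,
  C_Naive, C_Activated, C_Effector, C_Memory, C_DeadApoptotic,
  N_STATES
};
static const char* STATE_NAMES[N_STATES] = {
  "PC_Healthy", "PC_Stressed", "PC_Infected", "PC_DeadNecrotic", "PC_DeadApoptotic",
  "Portal_Open",
  "DC_Immature", "DC_Activated", "DC_Presenting", "DC_DeadApoptotic",
  "M_Resting", "M_M1", "M_M2", "M_DeadApoptotic",
  "NK_Patrol", "NK_DeadApoptotic",
  "G_Resting", "G_Active", "G_DeadApoptotic",
  "T_Naive", "T_Activated", "T_Effector", "T_Memory", "T_DeadApoptotic",
  "B_Naive", "B_Activated", "B_Plasma", "B_Memory", "B_DeadApoptotic",
  "C_Naive", "C_Activated", "C_Effector", "C_Memory", "C_DeadApoptotic" };

enum Sig { SIG_VIRUS = 0, SIG_PK1, SIG_CKPRO, SIG_CKANTI, SIG_CHT, SIG_CHL,
           SIG_AB1, SIG_AB2, SIG_AB5 };
static const int NSIG = 9;
static const char* SIG_NAMES[NSIG] = {
  "Virus", "PK1", "CK_pro", "CK_anti", "CH_tissue", "CH_lymph",
  "Ab1", "Ab2", "Ab5" };

enum Trig {
  TR_virus_threshold = 0, TR_adjacent_infected, TR_stress_recovered,
  TR_viral_lysis, TR_killed_nk, TR_killed_ctl, TR_killed_mac, TR_killed_gran,
  TR_activation_infected_pc, TR_activation_apoptotic_debris, TR_arrived_zone2,
  TR_lifespan, TR_pk1_threshold, TR_resolution, TR_necrotic_contact,
  TR_burst_exhausted, TR_antigen_presented, TR_tcell_help,
  TR_division_complete, N_TRIG
};
static const char* TRIG_NAMES[N_TRIG] = {
  "virus_threshold", "adjacent_infected", "stress_recovered", "viral_lysis",
  "killed_nk", "killed_ctl", "killed_mac", "killed_gran",
  "activation_infected_pc", "activation_apoptotic_debris", "arrived_zone2",
  "lifespan", "pk1_threshold", "resolution", "necrotic_contact",
  "burst_exhausted", "antigen_presented", "tcell_help", "division_complete" };

// phenotype labels
enum Phen { PH_NONE = 0, PH_DC1, PH_DC2, PH_TH1, PH_TREG };

static inline double ru() { return unif_rand(); }
static inline int ri(int n) {           // uniform integer in 0..n-1
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

// -------------------------------------------------------------- diffusion

// One diffusion step: c' = e * (c + D * (mean of Moore(1) neighbours - c)).
// Bounded grids average over existing neighbours only; periodic grids wrap
// (used for the mass-conservation property).  Values below `eps` are zeroed.
static void diffuse_grid(std::vector<double>& g, int side, double D, double e,
                         double eps, bool periodic) {
  std::vector<double> out(g.size());
  for (int y = 0; y < side; ++y) {
    for (int x = 0; x < side; ++x) {
      double s = 0.0;
      int n = 0;
      for (int dy = -1; dy <= 1; ++dy) {
        for (int dx = -1; dx <= 1; ++dx) {
          if (dx == 0 && dy == 0) continue;
          int nx = x + dx, ny = y + dy;
          if (periodic) {
            nx = (nx + side) % side;
            ny = (ny + side) % side;
          } else if (nx < 0 || ny < 0 || nx >= side || ny >= side) {
            continue;
          }
          s += g[(size_t)ny * side + nx];
          ++n;
        }
      }
      double c = g[(size_t)y * side + x];
      double m = (n > 0) ? s / n : c;
      double v = e * (c + D * (m - c));
      out[(size_t)y * side + x] = (v < eps) ? 0.0 : v;
    }
  }
  g.swap(out);
}

// ------------------------------------------------------------------ agents

struct Agent {
  int id;
  int type;
  int state;
  int phen;
  bool specific;
  int zone;
  int x, y;
  int state_tick;     // tick of last FSM transition (one-edge-per-tick guard)
  int t_state;        // ticks spent since entering current state
  int life;           // remaining lifespan in ticks
  int ctr;            // granulocyte burst budget
  int prolif_left;    // remaining descendant budget (lymphocytes)
  int div_cd;         // division cooldown
  int class_sw;       // plasma class-switch countdown
  int death_tick;
  bool alive;
  bool removed;       // corpse cleared / agent replaced: no longer on a grid
  bool cleared;       // dead PC whose debris was phagocytosed
  bool in_queue;
  bool engaged;
  std::array<int, NTYPE * 3> led;  // ledger: partner type x zone -> count
};

struct TraceRow { int tick, id, type, from, to, trig; };

// ------------------------------------------------------------------ engine

struct Engine {
  // geometry
  int side[4];           // index by zone 1..3
  int blockSide, blockOff;
  int stopTick, ckInt;
  int nPCinit;

  // parameters
  std::map<std::string, double> P;
  double par(const char* k) const {
    auto it = P.find(k);
    if (it == P.end()) stop("missing rule parameter '%s'", k);
    return it->second;
  }
  // cached rule constants (looked up once; the tick loop is hot)
  struct Pars {
    double theta_inf, virus_dep, pk1_dep, ch_tissue_dep_pc, L_lyse,
      stress_recover, d_regen, k_regen, infect_p, init_virus, chemo_threshold, floor_eps,
      portal_frac, dc_sense_radius, dc_act_lifespan, dc_imm_lifespan,
      dc_influx, dc2_pk1_max, chl_dep_dc, mac_pk1_thresh, mac_kill_p,
      mac_lifespan, mac_capacity, mac_digest, nk_capacity, dc_influx_cap,
      dc_crowd_min,
      m1_ckpro_dep, m1_ch_dep, m2_ckanti_dep, nk_kill_p,
      nk_ckanti_thresh, nk_lifespan, gran_pk1_thresh, gran_burst,
      gran_kill_p, gran_ckpro_dep, gran_lifespan, prolif_cap,
      division_interval, treg_frac, class_switch, t_eff_lifespan,
      plasma_lifespan, naive_lifespan, memory_lifespan, eff_ck_dep,
      eff_ch_dep, ab_dep, ab_neut, ctl_kill_p, corpse_decay,
      resolution_lag, memory_conv_p;
  } pr;
  void cachePars() {
#define GETP(f) pr.f = par(#f)
    GETP(theta_inf); GETP(virus_dep); GETP(pk1_dep); GETP(ch_tissue_dep_pc);
    GETP(L_lyse); GETP(stress_recover); GETP(d_regen); GETP(k_regen);
    GETP(infect_p); GETP(init_virus);
    GETP(chemo_threshold); GETP(floor_eps); GETP(portal_frac);
    GETP(dc_sense_radius); GETP(dc_act_lifespan); GETP(dc_imm_lifespan);
    GETP(dc_influx); GETP(dc2_pk1_max); GETP(chl_dep_dc);
    GETP(mac_pk1_thresh); GETP(mac_kill_p); GETP(mac_lifespan);
    GETP(mac_capacity); GETP(mac_digest); GETP(nk_capacity);
    GETP(dc_influx_cap); GETP(dc_crowd_min);
    GETP(m1_ckpro_dep); GETP(m1_ch_dep); GETP(m2_ckanti_dep);
    GETP(nk_kill_p); GETP(nk_ckanti_thresh); GETP(nk_lifespan);
    GETP(gran_pk1_thresh); GETP(gran_burst); GETP(gran_kill_p);
    GETP(gran_ckpro_dep); GETP(gran_lifespan); GETP(prolif_cap);
    GETP(division_interval); GETP(treg_frac); GETP(class_switch);
    GETP(t_eff_lifespan); GETP(plasma_lifespan); GETP(naive_lifespan);
    GETP(memory_lifespan); GETP(eff_ck_dep); GETP(eff_ch_dep);
    GETP(ab_dep); GETP(ab_neut); GETP(ctl_kill_p); GETP(corpse_decay);
    GETP(resolution_lag); GETP(memory_conv_p);
#undef GETP
  }

  // signal fields
  double sigD[NSIG], sigE[NSIG];
  bool sigAct[4][NSIG];
  std::vector<double> field[4][NSIG];
  bool hasMass[4][NSIG];
  double eps;

  // portal signal routes and entry conditions
  struct Route { int sig, from, to; bool perfuse; };
  std::vector<Route> routes;
  int entrySig[4];        // signal id required at a destination portal, -1 none
  double entryThr[4];
  double portalFrac;

  // grids
  std::vector<int> mob[4];   // mobile-layer occupancy: agent index + 1
  std::vector<int> pcg;      // zone-1 stationary layer (PCs): agent index + 1

  std::deque<Agent> A;
  std::vector<int> portals[4];
  std::deque<int> migQueue[4];  // keyed by destination zone

  // bookkeeping
  long pairLive[NTYPE][NTYPE];
  long pairOne[NTYPE][NTYPE];
  int prevInfected;
  int resolvedStreak;
  bool resolved;
  int tick;
  long qEnqueued, qPlaced;
  long occViolations;
  bool doTrace;
  std::vector<TraceRow> trace;

  // checkpoint accumulator
  std::vector<int> ckTick, ckId, ckType, ckAlive, ckPartner, ckZone, ckCount;

  int idx(int z, int x, int y) const { return y * side[z] + x; }
  bool inb(int z, int x, int y) const {
    return x >= 0 && y >= 0 && x < side[z] && y < side[z];
  }

  // ---------------------------------------------------------------- setup
  void configure(List cfg) {
    List zones = cfg["zones"];
    IntegerVector zs = zones["side"];
    side[1] = zs[0]; side[2] = zs[1]; side[3] = zs[2];
    blockSide = as<int>(zones["pc_block_side"]);
    if (blockSide < 4 || blockSide > side[1] - 2)
      stop("pc_block_side must be in [4, zone1 side - 2]");
    blockOff = (side[1] - blockSide) / 2;
    stopTick = as<int>(cfg["stop_tick"]);
    ckInt = as<int>(cfg["checkpoint_interval"]);
    if (stopTick < ckInt) stop("stop_tick must be >= checkpoint_interval");

    NumericVector pars = cfg["pars"];
    CharacterVector pn = pars.names();
    for (int i = 0; i < pars.size(); ++i)
      P[std::string(pn[i])] = pars[i];
    cachePars();
    eps = pr.floor_eps;
    portalFrac = pr.portal_frac;

    DataFrame sig = as<DataFrame>(cfg["signals"]);
    CharacterVector sn = sig["name"];
    NumericVector sD = sig["D"], sE = sig["e"];
    LogicalVector z1 = sig["z1"], z2 = sig["z2"], z3 = sig["z3"];
    if (sn.size() != NSIG) stop("signal registry must have %d rows", NSIG);
    for (int i = 0; i < NSIG; ++i) {
      if (std::string(sn[i]) != SIG_NAMES[i])
        stop("signal registry row %d must be '%s'", i + 1, SIG_NAMES[i]);
      if (sD[i] <= 0 || sD[i] > 1 || sE[i] <= 0 || sE[i] > 1)
        stop("signal diffusion/evaporation constants must lie in (0, 1]");
      sigD[i] = sD[i]; sigE[i] = sE[i];
      sigAct[1][i] = z1[i]; sigAct[2][i] = z2[i]; sigAct[3][i] = z3[i];
    }
    for (int z = 1; z <= 3; ++z) {
      mob[z].assign((size_t)side[z] * side[z], 0);
      for (int s = 0; s < NSIG; ++s) {
        hasMass[z][s] = false;
        if (sigAct[z][s]) field[z][s].assign((size_t)side[z] * side[z], 0.0);
      }
    }
    pcg.assign((size_t)side[1] * side[1], 0);

    DataFrame rt = as<DataFrame>(cfg["portal_routes"]);
    CharacterVector rsig = rt["signal"], rmode = rt["mode"];
    IntegerVector rfrom = rt["from"], rto = rt["to"];
    for (int i = 0; i < rsig.size(); ++i) {
      int s = -1;
      for (int j = 0; j < NSIG; ++j)
        if (std::string(rsig[i]) == SIG_NAMES[j]) s = j;
      if (s < 0) stop("unknown signal in portal_routes");
      routes.push_back({s, rfrom[i], rto[i],
                        std::string(rmode[i]) == "perfuse"});
    }

    DataFrame pe = as<DataFrame>(cfg["portal_entry"]);
    CharacterVector pes = pe["signal"];
    NumericVector pet = pe["threshold"];
    for (int z = 1; z <= 3; ++z) {
      entrySig[z] = -1;
      entryThr[z] = pet[z - 1];
      if (pes[z - 1] != NA_STRING) {
        for (int j = 0; j < NSIG; ++j)
          if (std::string(pes[z - 1]) == SIG_NAMES[j]) entrySig[z] = j;
      }
    }

    std::memset(pairLive, 0, sizeof(pairLive));
    std::memset(pairOne, 0, sizeof(pairOne));
    prevInfected = 0; resolvedStreak = 0; resolved = false;
    qEnqueued = qPlaced = 0; occViolations = 0; tick = 0;
    doTrace = false;

    buildWorld(cfg);
  }

  Agent mk(int type, int state, int zone, int x, int y) {
    Agent a{};
    a.id = (int)A.size() + 1;
    a.type = type; a.state = state; a.phen = PH_NONE;
    a.specific = false; a.zone = zone; a.x = x; a.y = y;
    a.state_tick = -1; a.t_state = 0;
    a.life = 1 << 30; a.ctr = 0; a.prolif_left = 0; a.div_cd = 0;
    a.class_sw = -1; a.death_tick = -1;
    a.alive = true; a.removed = false; a.cleared = false;
    a.in_queue = false; a.engaged = false;
    a.led.fill(0);
    return a;
  }

  void placeMobile(int i) {
    Agent& a = A[i];
    int c = idx(a.zone, a.x, a.y);
    if (mob[a.zone][c] != 0) ++occViolations;
    mob[a.zone][c] = i + 1;
  }

  // sample n distinct free mobile-layer cells in a zone
  std::vector<int> sampleFree(int z, int n) {
    std::vector<int> free;
    for (size_t c = 0; c < mob[z].size(); ++c)
      if (mob[z][c] == 0) free.push_back((int)c);
    if ((int)free.size() < n)
      stop("agent counts exceed free cells in zone %d", z);
    // partial Fisher-Yates
    std::vector<int> out(n);
    int m = (int)free.size();
    for (int k = 0; k < n; ++k) {
      int j = k + ri(m - k);
      std::swap(free[k], free[j]);
      out[k] = free[k];
    }
    return out;
  }

  void buildWorld(List cfg) {
    // fixed stationary layout in Zone 1: PC block + 4 portals just outside
    // the block edge midpoints
    int o = blockOff, b = blockSide;
    if (pr.k_regen < 0) stop("k_regen must be >= 0");
    for (int y = o; y < o + b; ++y)
      for (int x = o; x < o + b; ++x) {
        A.push_back(mk(T_PC, PC_Healthy, 1, x, y));
        pcg[idx(1, x, y)] = (int)A.size();
      }
    nPCinit = b * b;
    int mid = o + b / 2;
    int p1[4][2] = { {o - 1, mid}, {o + b, mid}, {mid, o - 1}, {mid, o + b} };
    for (auto& p : p1) {
      A.push_back(mk(T_PORTAL, Portal_Open, 1, p[0], p[1]));
      portals[1].push_back((int)A.size() - 1);
      mob[1][idx(1, p[0], p[1])] = (int)A.size();  // portals block the cell
    }
    // zones 2 and 3 get two portals per edge (at 1/3 and 2/3), matching the
    // multiple afferent/efferent vessels of lymphoid tissue and blood
    for (int z = 2; z <= 3; ++z) {
      int s = side[z], a3 = s / 3, b3 = 2 * s / 3;
      int pp[8][2] = { {0, a3}, {0, b3}, {s - 1, a3}, {s - 1, b3},
                       {a3, 0}, {b3, 0}, {a3, s - 1}, {b3, s - 1} };
      for (auto& p : pp) {
        A.push_back(mk(T_PORTAL, Portal_Open, z, p[0], p[1]));
        portals[z].push_back((int)A.size() - 1);
        mob[z][idx(z, p[0], p[1])] = (int)A.size();
      }
    }

    // four initial infection sites: block-centre cell + its three lattice
    // neighbours forming the centre 2x2 (same pattern every run)
    int c0 = o + b / 2 - 1;
    int inf[4][2] = { {c0, c0}, {c0 + 1, c0}, {c0, c0 + 1}, {c0 + 1, c0 + 1} };
    for (auto& p : inf) {
      int ai = pcg[idx(1, p[0], p[1])] - 1;
      A[ai].state = PC_Infected;
      // inoculum: the infection is established when the simulation starts
      dep(1, SIG_VIRUS, p[0], p[1], pr.init_virus);
    }
    prevInfected = 4;

    // mobile agents, placed uniformly at random in their home zones
    IntegerVector counts = cfg["counts"];
    IntegerVector nspec = cfg["specific"];
    if (as<int>(counts["Dendritic"]) < 0) stop("negative agent count");
    struct Init { const char* nm; int type; int zone; int state; };
    Init inits[] = {
      {"Dendritic", T_DC, 1, DC_Immature},
      {"Macrophage", T_MAC, 1, M_Resting},
      {"NaturalKiller", T_NK, 1, NK_Patrol},
      {"Granulocyte", T_GRAN, 1, G_Resting},
      {"TCell", T_T, 2, T_Naive},
      {"BCell", T_B, 2, B_Naive},
      {"CTL", T_CTL, 2, C_Naive} };
    for (auto& in : inits) {
      int n = as<int>(counts[in.nm]);
      int ns = 0;
      if (in.type == T_T) ns = nspec["TCell"];
      if (in.type == T_B) ns = nspec["BCell"];
      if (in.type == T_CTL) ns = nspec["CTL"];
      std::vector<int> cells = sampleFree(in.zone, n);
      for (int k = 0; k < n; ++k) {
        int x = cells[k] % side[in.zone], y = cells[k] / side[in.zone];
        Agent a = mk(in.type, in.state, in.zone, x, y);
        a.life = lifespanFor(in.type, in.state);
        if (in.type == T_MAC) a.ctr = (int)pr.mac_capacity;
        if (in.type == T_NK) a.ctr = (int)pr.nk_capacity;
        a.specific = (k < ns);  // cells were drawn at random, so the first
                                // ns occupy randomly chosen empty coords
        A.push_back(a);
        placeMobile((int)A.size() - 1);
      }
    }

    // optional scenario hook: dendritic agents started directly in the
    // presenting state in Zone 2 (used by unit scenarios)
    int ndp = cfg.containsElementNamed("dc_presenting_z2")
                ? as<int>(cfg["dc_presenting_z2"]) : 0;
    if (ndp > 0) {
      std::vector<int> cells = sampleFree(2, ndp);
      for (int k = 0; k < ndp; ++k) {
        int x = cells[k] % side[2], y = cells[k] / side[2];
        Agent a = mk(T_DC, DC_Presenting, 2, x, y);
        a.phen = PH_DC1;
        a.life = (int)pr.dc_act_lifespan;
        A.push_back(a);
        placeMobile((int)A.size() - 1);
      }
    }
  }

  int lifespanFor(int type, int state) {
    switch (type) {
      case T_DC:  return (int)pr.dc_imm_lifespan;
      case T_MAC: return (int)pr.mac_lifespan;
      case T_NK:  return (int)pr.nk_lifespan;
      case T_GRAN: return (int)pr.gran_lifespan;
      case T_T: case T_B: case T_CTL: return (int)pr.naive_lifespan;
    }
    return 1 << 30;
  }

  // ------------------------------------------------------------ mechanics

  void dep(int z, int s, int x, int y, double amt) {
    if (!sigAct[z][s]) return;
    field[z][s][idx(z, x, y)] += amt;
    hasMass[z][s] = true;
  }
  double sig(int z, int s, int x, int y) const {
    if (!sigAct[z][s]) return 0.0;
    return field[z][s][idx(z, x, y)];
  }

  bool transition(int i, int to, int trig) {
    Agent& a = A[i];
    if (!a.alive) return false;
    if (a.state_tick == tick) return false;  // one FSM edge per tick
    if (doTrace)
      trace.push_back({tick, a.id, a.type, a.state, to, trig});
    a.state = to;
    a.state_tick = tick;
    a.t_state = 0;
    return true;
  }

  void markDead(int i) {
    Agent& a = A[i];
    a.alive = false;
    a.death_tick = tick;
    a.in_queue = false;  // lazily dropped from queues
  }

  void die(int i, int deadState, int trig) {
    if (transition(i, deadState, trig)) markDead(i);
  }

  // meaningful contact: both live participants record; if one participant is
  // dead only the live one records; portals never record.
  void recordContact(int ia, int ib) {
    Agent& a = A[ia];
    Agent& b = A[ib];
    if (a.type == T_PORTAL || b.type == T_PORTAL) return;
    int z = a.zone;
    if (a.alive && b.alive) {
      a.led[b.type * 3 + (z - 1)]++;
      b.led[a.type * 3 + (z - 1)]++;
      a.engaged = b.engaged = true;
      pairLive[a.type][b.type]++;
      pairLive[b.type][a.type]++;
    } else if (a.alive) {
      a.led[b.type * 3 + (z - 1)]++;
      a.engaged = true;
      pairOne[a.type][b.type]++;
    } else if (b.alive) {
      b.led[a.type * 3 + (z - 1)]++;
      b.engaged = true;
      pairOne[b.type][a.type]++;
    }
  }

  // kill a live parenchymal cell by direct cytotoxic contact
  bool killPC(int killer, int victim, int deadState, int trig) {
    Agent& v = A[victim];
    if (!v.alive || v.state_tick == tick) return false;
    recordContact(killer, victim);
    transition(victim, deadState, trig);
    markDead(victim);
    return true;
  }

  // --------------------------------------------------------- neighbourhood

  template <typename F>
  void forMoore(int z, int x, int y, int r, F f) const {
    for (int dy = -r; dy <= r; ++dy)
      for (int dx = -r; dx <= r; ++dx) {
        if (dx == 0 && dy == 0) continue;
        int nx = x + dx, ny = y + dy;
        if (inb(z, nx, ny)) f(nx, ny);
      }
  }

  // chemotactic target: Moore(1) neighbour of maximal concentration, if that
  // maximum reaches `thr` and exceeds the centre cell; ties uniform at random
  bool gradTarget(int z, int s, int x, int y, double thr, int& tx, int& ty) {
    if (!sigAct[z][s] || !hasMass[z][s]) return false;
    double best = -1.0;
    int nb = 0, bx[8], by[8];
    forMoore(z, x, y, 1, [&](int nx, int ny) {
      double v = field[z][s][idx(z, nx, ny)];
      if (v > best + 1e-15) { best = v; nb = 0; }
      if (v >= best - 1e-15) { bx[nb] = nx; by[nb] = ny; ++nb; }
    });
    if (nb == 0 || best < thr || best <= field[z][s][idx(z, x, y)]) return false;
    int k = (nb == 1) ? 0 : ri(nb);
    tx = bx[k]; ty = by[k];
    return true;
  }

  void moveTo(int i, int x, int y) {
    Agent& a = A[i];
    mob[a.zone][idx(a.zone, a.x, a.y)] = 0;
    a.x = x; a.y = y;
    int c = idx(a.zone, x, y);
    if (mob[a.zone][c] != 0) ++occViolations;
    mob[a.zone][c] = i + 1;
  }

  bool moveRandom(int i) {
    Agent& a = A[i];
    int nb = 0, bx[8], by[8];
    forMoore(a.zone, a.x, a.y, 1, [&](int nx, int ny) {
      if (mob[a.zone][idx(a.zone, nx, ny)] == 0) { bx[nb] = nx; by[nb] = ny; ++nb; }
    });
    if (nb == 0) return false;
    int k = ri(nb);
    moveTo(i, bx[k], by[k]);
    return true;
  }

  // chemotaxis with fall-back to a uniform-random free neighbour
  void moveChemo(int i, int s) {
    Agent& a = A[i];
    int tx, ty;
    double thr = pr.chemo_threshold;
    if (gradTarget(a.zone, s, a.x, a.y, thr, tx, ty) &&
        mob[a.zone][idx(a.zone, tx, ty)] == 0) {
      moveTo(i, tx, ty);
      return;
    }
    moveRandom(i);
  }

  // greedy step towards a target coordinate (portal homing): prefer a
  // strictly closer free cell, else sidestep at equal distance (skirting
  // crowds), else move randomly
  void moveToward(int i, int tx, int ty) {
    Agent& a = A[i];
    int cur = std::max(std::abs(a.x - tx), std::abs(a.y - ty));
    int nbC = 0, bxC[8], byC[8], nbE = 0, bxE[8], byE[8];
    forMoore(a.zone, a.x, a.y, 1, [&](int nx, int ny) {
      if (mob[a.zone][idx(a.zone, nx, ny)] != 0) return;
      int d = std::max(std::abs(nx - tx), std::abs(ny - ty));
      if (d < cur) { bxC[nbC] = nx; byC[nbC] = ny; ++nbC; }
      else if (d == cur) { bxE[nbE] = nx; byE[nbE] = ny; ++nbE; }
    });
    if (nbC > 0) { int k = ri(nbC); moveTo(i, bxC[k], byC[k]); }
    else if (nbE > 0) { int k = ri(nbE); moveTo(i, bxE[k], byE[k]); }
    else moveRandom(i);
  }

  // egress portal for an agent: fixed per agent (id hash) to spread the
  // traffic over the zone's portals
  int homePortal(int z, int aid) {
    return portals[z][aid % (int)portals[z].size()];
  }

  bool adjacentToPortal(int i) {
    Agent& a = A[i];
    for (int pi : portals[a.zone])
      if (std::max(std::abs(A[pi].x - a.x), std::abs(A[pi].y - a.y)) <= 1)
        return true;
    return false;
  }

  // try to place agent i next to an eligible portal of zone `dz`
  bool tryEnterZone(int i, int dz) {
    std::vector<int> ps = portals[dz];
    for (int k = (int)ps.size() - 1; k > 0; --k)
      std::swap(ps[k], ps[ri(k + 1)]);
    for (int pi : ps) {
      Agent& p = A[pi];
      if (entrySig[dz] >= 0 &&
          sig(dz, entrySig[dz], p.x, p.y) < entryThr[dz]) continue;
      int nb = 0, bx[8], by[8];
      forMoore(dz, p.x, p.y, 1, [&](int nx, int ny) {
        if (mob[dz][idx(dz, nx, ny)] == 0) { bx[nb] = nx; by[nb] = ny; ++nb; }
      });
      if (nb == 0) continue;
      int k = ri(nb);
      Agent& a = A[i];
      mob[a.zone][idx(a.zone, a.x, a.y)] = 0;
      a.zone = dz; a.x = bx[k]; a.y = by[k];
      mob[dz][idx(dz, a.x, a.y)] = i + 1;
      ++qPlaced;
      return true;
    }
    return false;
  }

  // migration attempt for an agent standing next to a portal of its own zone;
  // queues (FIFO, retried each tick) when no destination portal is eligible
  void migrate(int i, int dz) {
    if (!adjacentToPortal(i)) return;
    if (!tryEnterZone(i, dz)) {
      A[i].in_queue = true;
      migQueue[dz].push_back(i);
      ++qEnqueued;
    }
  }

  int destZone(const Agent& a) const {
    if (a.type == T_DC) return 2;
    if (a.state == B_Plasma) return a.zone == 2 ? 3 : -1;
    // effector T / CTL: zone 2 -> 3 -> 1
    if (a.zone == 2) return 3;
    if (a.zone == 3) return 1;
    return -1;
  }

  // ------------------------------------------------------- agent behaviour

  bool anyAdjacentInfected(const Agent& a) {
    bool found = false;
    forMoore(1, a.x, a.y, 1, [&](int nx, int ny) {
      int pi = pcg[idx(1, nx, ny)];
      if (pi && A[pi - 1].alive && A[pi - 1].state == PC_Infected) found = true;
    });
    return found;
  }

  void stepPC(int i) {
    Agent& a = A[i];
    if (!a.alive) {
      // dead tissue cell: regeneration when the debris has aged and enough
      // uninfected live neighbours surround the site ("replacement")
      if (a.removed) return;
      a.t_state++;
      if (a.t_state >= (int)pr.d_regen) {
        int good = 0;
        forMoore(1, a.x, a.y, 1, [&](int nx, int ny) {
          int pi = pcg[idx(1, nx, ny)];
          if (pi && A[pi - 1].alive && A[pi - 1].state != PC_Infected) ++good;
        });
        if (good >= (int)pr.k_regen) {
          a.removed = true;
          Agent fresh = mk(T_PC, PC_Healthy, 1, a.x, a.y);
          A.push_back(fresh);
          pcg[idx(1, a.x, a.y)] = (int)A.size();
        }
      }
      return;
    }
    switch (a.state) {
      case PC_Infected: {
        dep(1, SIG_VIRUS, a.x, a.y, pr.virus_dep);
        dep(1, SIG_PK1, a.x, a.y, pr.pk1_dep);
        dep(1, SIG_CHT, a.x, a.y, pr.ch_tissue_dep_pc);
        a.t_state++;
        if (a.t_state >= (int)pr.L_lyse) {
          die(i, PC_DeadNecrotic, TR_viral_lysis);
        }
        break;
      }
      case PC_Healthy: {
        if (sig(1, SIG_VIRUS, a.x, a.y) >= pr.theta_inf &&
            ru() < pr.infect_p) {
          transition(i, PC_Infected, TR_virus_threshold);
        } else {
          // stress induced by receptor contact with an infected neighbour
          int infNb = -1;
          forMoore(1, a.x, a.y, 1, [&](int nx, int ny) {
            int pi = pcg[idx(1, nx, ny)];
            if (pi && A[pi - 1].alive && A[pi - 1].state == PC_Infected &&
                infNb < 0)
              infNb = pi - 1;
          });
          if (infNb >= 0 && transition(i, PC_Stressed, TR_adjacent_infected))
            recordContact(i, infNb);
        }
        break;
      }
      case PC_Stressed: {
        if (sig(1, SIG_VIRUS, a.x, a.y) >= pr.theta_inf &&
            ru() < pr.infect_p) {
          transition(i, PC_Infected, TR_virus_threshold);
        } else if (anyAdjacentInfected(a)) {
          a.t_state = 0;
        } else {
          a.t_state++;
          if (a.t_state >= (int)pr.stress_recover)
            transition(i, PC_Healthy, TR_stress_recovered);
        }
        break;
      }
      default: break;
    }
  }

  // find a corpse (not yet cleared) within radius r; apoMode: 0 any dead,
  // 1 apoptotic only, 2 necrotic only
  int findCorpse(const Agent& a, int r, int apoMode) {
    int found = -1;
    forMoore(a.zone, a.x, a.y, r, [&](int nx, int ny) {
      if (found >= 0) return;
      int mi = mob[a.zone][idx(a.zone, nx, ny)];
      if (mi) {
        Agent& m = A[mi - 1];
        if (!m.alive && !m.removed && m.type != T_PORTAL) {
          bool nec = (m.state == PC_DeadNecrotic);
          if (apoMode == 0 || (apoMode == 1 && !nec) || (apoMode == 2 && nec))
            found = mi - 1;
        }
      }
      if (found < 0 && a.zone == 1) {
        int pi = pcg[idx(1, nx, ny)];
        if (pi) {
          Agent& p = A[pi - 1];
          if (!p.alive && !p.removed && !p.cleared) {
            bool nec = (p.state == PC_DeadNecrotic);
            if (apoMode == 0 || (apoMode == 1 && !nec) || (apoMode == 2 && nec))
              found = pi - 1;
          }
        }
      }
    });
    return found;
  }

  void phagocytose(int mac, int corpse) {
    Agent& c = A[corpse];
    recordContact(mac, corpse);  // one-sided: partner is dead
    if (c.type == T_PC) {
      c.cleared = true;          // debris removed; site still dead
    } else {
      mob[c.zone][idx(c.zone, c.x, c.y)] = 0;
      c.removed = true;
    }
  }

  void stepDC(int i) {
    Agent& a = A[i];
    // activated dendritic agents are sustained by the ongoing inflammatory
    // response; they age (and eventually die) once the infection is cleared
    bool aging = (a.state == DC_Immature) || (prevInfected == 0);
    if (aging && --a.life <= 0) { die(i, DC_DeadApoptotic, TR_lifespan); return; }
    int r = (int)pr.dc_sense_radius;
    switch (a.state) {
      case DC_Immature: {
        // activation by contact with infected (or necrotic) tissue cells in
        // the presence of the danger signal -> pro-inflammatory DC1;
        // by apoptotic debris without danger signal -> DC2
        int infN = -1, apoN = -1;
        forMoore(1, a.x, a.y, r, [&](int nx, int ny) {
          int pi = pcg[idx(1, nx, ny)];
          if (!pi) return;
          Agent& p = A[pi - 1];
          if (p.alive && p.state == PC_Infected && infN < 0) infN = pi - 1;
          if (!p.alive && !p.removed && !p.cleared && infN < 0 &&
              p.state == PC_DeadNecrotic) infN = pi - 1;
        });
        if (infN < 0) apoN = findCorpse(a, r, 1);
        double pk1 = sig(1, SIG_PK1, a.x, a.y);
        if (infN >= 0 && pk1 > 0) {
          if (transition(i, DC_Activated, TR_activation_infected_pc)) {
            a.phen = PH_DC1;
            a.life = (int)pr.dc_act_lifespan;
            recordContact(i, infN);
          }
        } else if (apoN >= 0 && pk1 < pr.dc2_pk1_max) {
          if (transition(i, DC_Activated, TR_activation_apoptotic_debris)) {
            a.phen = PH_DC2;
            a.life = (int)pr.dc_act_lifespan;
            recordContact(i, apoN);
          }
        } else {
          moveChemo(i, SIG_CHT);
        }
        break;
      }
      case DC_Activated: {
        if (a.zone == 2) { transition(i, DC_Presenting, TR_arrived_zone2); break; }
        if (adjacentToPortal(i)) { migrate(i, 2); break; }
        int pi = homePortal(1, a.id);
        moveToward(i, A[pi].x, A[pi].y);
        break;
      }
      case DC_Presenting: {
        dep(2, SIG_CHL, a.x, a.y, pr.chl_dep_dc);
        // probe radius 2 for lymphocytes: present antigen to naive
        // antigen-matched cells, restimulate cells it has activated
        forMoore(2, a.x, a.y, r, [&](int nx, int ny) {
          int mi = mob[2][idx(2, nx, ny)];
          if (!mi) return;
          Agent& m = A[mi - 1];
          if (!m.alive || !m.specific) return;
          if (m.type == T_T && m.state == T_Naive) {
            if (transition(mi - 1, T_Activated, TR_antigen_presented)) {
              m.phen = (ru() < pr.treg_frac) ? PH_TREG : PH_TH1;
              m.prolif_left = (int)pr.prolif_cap;
              m.div_cd = (int)pr.division_interval;
              recordContact(i, mi - 1);
            }
          } else if (m.type == T_B && m.state == B_Naive) {
            if (transition(mi - 1, B_Activated, TR_antigen_presented)) {
              m.prolif_left = (int)pr.prolif_cap;
              m.div_cd = (int)pr.division_interval;
              recordContact(i, mi - 1);
            }
          } else if (m.type == T_CTL && m.state == C_Naive) {
            if (transition(mi - 1, C_Activated, TR_antigen_presented)) {
              m.prolif_left = (int)pr.prolif_cap;
              m.div_cd = (int)pr.division_interval;
              recordContact(i, mi - 1);
            }
          } else if (m.state == T_Activated || m.state == B_Activated ||
                     m.state == C_Activated) {
            recordContact(i, mi - 1);  // sustained presentation contact
          }
        });
        // movement with open-space search: pick a random direction; if it is
        // blocked by another dendritic agent the cell "steps over" the
        // cluster, contacting every adjacent dendritic agent, and relocates
        // to a free cell within radius 2.  In an uncrowded zone this almost
        // never happens; in an engorged zone it happens constantly.
        {
          int dirs = 0, dx8[8], dy8[8];
          forMoore(2, a.x, a.y, 1, [&](int nx, int ny) {
            dx8[dirs] = nx; dy8[dirs] = ny; ++dirs;
          });
          if (dirs > 0) {
            int k = ri(dirs);
            int tc = mob[2][idx(2, dx8[k], dy8[k])];
            if (tc == 0) {
              moveTo(i, dx8[k], dy8[k]);
            } else if (A[tc - 1].alive && A[tc - 1].type == T_DC) {
              // blocked by another dendritic agent: contact it and clamber
              // to a free cell within radius 2
              recordContact(i, tc - 1);
              int nf = 0, fx[24], fy[24];
              forMoore(2, a.x, a.y, 2, [&](int nx, int ny) {
                if (mob[2][idx(2, nx, ny)] == 0 && nf < 24) {
                  fx[nf] = nx; fy[nf] = ny; ++nf;
                }
              });
              if (nf > 0) { int j = ri(nf); moveTo(i, fx[j], fy[j]); }
            }
          }
          // in an engorged zone (several dendritic neighbours) the search
          // for open space means traversing the whole cluster
          int nadj = 0, adj[8];
          forMoore(2, a.x, a.y, 1, [&](int nx, int ny) {
            int mi = mob[2][idx(2, nx, ny)];
            if (!mi) return;
            Agent& m = A[mi - 1];
            if (m.alive && m.type == T_DC && (mi - 1) != i && nadj < 8)
              adj[nadj++] = mi - 1;
          });
          if (nadj >= (int)pr.dc_crowd_min)
            for (int q = 0; q < nadj; ++q) recordContact(i, adj[q]);
        }
        break;
      }
      default: break;
    }
  }

  // a macrophage can handle (phagocytose or kill) a limited number of
  // targets, with a digestion pause between events; engulfment capacity
  // saturates and heavily-fed macrophages polarise towards resolution
  bool macCanHandle(Agent& a) { return a.ctr > 0 && a.div_cd <= 0; }
  void macHandled(int i) {
    Agent& a = A[i];
    a.ctr--;
    a.div_cd = (int)pr.mac_digest;
  }

  void stepMAC(int i) {
    Agent& a = A[i];
    if (--a.life <= 0) { die(i, M_DeadApoptotic, TR_lifespan); return; }
    if (a.div_cd > 0) a.div_cd--;
    double pk1 = sig(1, SIG_PK1, a.x, a.y);
    switch (a.state) {
      case M_Resting: {
        if (pk1 >= pr.mac_pk1_thresh) {
          transition(i, M_M1, TR_pk1_threshold);
        } else {
          int c = macCanHandle(a) ? findCorpse(a, 1, 0) : -1;
          if (c >= 0) { phagocytose(i, c); macHandled(i); }
          else moveRandom(i);
        }
        break;
      }
      case M_M1: {
        dep(1, SIG_CKPRO, a.x, a.y, pr.m1_ckpro_dep);
        dep(1, SIG_CHT, a.x, a.y, pr.m1_ch_dep);
        if ((resolved || a.ctr <= 0) && transition(i, M_M2, TR_resolution))
          break;
        int tgt = -1;
        if (macCanHandle(a)) {
          forMoore(1, a.x, a.y, 1, [&](int nx, int ny) {
            int pi = pcg[idx(1, nx, ny)];
            if (pi && A[pi - 1].alive && A[pi - 1].state == PC_Infected &&
                tgt < 0)
              tgt = pi - 1;
          });
        }
        if (tgt >= 0 && ru() < pr.mac_kill_p) {
          if (killPC(i, tgt, PC_DeadApoptotic, TR_killed_mac)) macHandled(i);
        } else {
          int c = macCanHandle(a) ? findCorpse(a, 1, 0) : -1;
          if (c >= 0) { phagocytose(i, c); macHandled(i); }
          else moveRandom(i);
        }
        break;
      }
      case M_M2: {
        dep(1, SIG_CKANTI, a.x, a.y, pr.m2_ckanti_dep);
        if (a.ctr > 0 && pk1 >= pr.mac_pk1_thresh) {
          transition(i, M_M1, TR_pk1_threshold);
          break;
        }
        int c = macCanHandle(a) ? findCorpse(a, 1, 0) : -1;
        if (c >= 0) { phagocytose(i, c); macHandled(i); }
        else moveRandom(i);
        break;
      }
      default: break;
    }
  }

  void stepNK(int i) {
    Agent& a = A[i];
    if (--a.life <= 0) { die(i, NK_DeadApoptotic, TR_lifespan); return; }
    if (a.state != NK_Patrol) return;
    // innate killing of infected or stressed tissue cells, suppressed by the
    // anti-inflammatory signal
    // cytotoxic granule budget: an NK cell kills a limited number of targets
    if (a.ctr > 0 && sig(1, SIG_CKANTI, a.x, a.y) < pr.nk_ckanti_thresh) {
      int tgt = -1;
      forMoore(1, a.x, a.y, 1, [&](int nx, int ny) {
        int pi = pcg[idx(1, nx, ny)];
        if (!pi || tgt >= 0) return;
        Agent& p = A[pi - 1];
        if (p.alive && (p.state == PC_Infected || p.state == PC_Stressed))
          tgt = pi - 1;
      });
      if (tgt >= 0 && ru() < pr.nk_kill_p) {
        if (killPC(i, tgt, PC_DeadApoptotic, TR_killed_nk)) a.ctr--;
        return;
      }
    }
    moveChemo(i, SIG_PK1);
  }

  void stepGRAN(int i) {
    Agent& a = A[i];
    if (--a.life <= 0) { die(i, G_DeadApoptotic, TR_lifespan); return; }
    switch (a.state) {
      case G_Resting: {
        if (sig(1, SIG_PK1, a.x, a.y) >= pr.gran_pk1_thresh) {
          if (transition(i, G_Active, TR_pk1_threshold))
            a.ctr = (int)pr.gran_burst;
        } else {
          int nec = findCorpse(a, 1, 2);
          if (nec >= 0) {
            if (transition(i, G_Active, TR_necrotic_contact)) {
              a.ctr = (int)pr.gran_burst;
              recordContact(i, nec);  // one-sided: debris is dead
            }
          } else {
            moveChemo(i, SIG_PK1);
          }
        }
        break;
      }
      case G_Active: {
        dep(1, SIG_CKPRO, a.x, a.y, pr.gran_ckpro_dep);
        int tgt = -1;
        forMoore(1, a.x, a.y, 1, [&](int nx, int ny) {
          int pi = pcg[idx(1, nx, ny)];
          if (pi && A[pi - 1].alive && A[pi - 1].state == PC_Infected && tgt < 0)
            tgt = pi - 1;
        });
        if (tgt >= 0 && ru() < pr.gran_kill_p) {
          // killing by released reactive oxygen species and proteases:
          // environmentally mediated, so no receptor contact is recorded
          Agent& v = A[tgt];
          if (v.alive && v.state_tick != tick) {
            transition(tgt, PC_DeadNecrotic, TR_killed_gran);
            markDead(tgt);
          }
        } else moveChemo(i, SIG_PK1);
        if (--a.ctr <= 0) die(i, G_DeadApoptotic, TR_burst_exhausted);
        break;
      }
      default: break;
    }
  }

  bool tregAdjacent(const Agent& a) {
    bool found = false;
    forMoore(a.zone, a.x, a.y, 1, [&](int nx, int ny) {
      int mi = mob[a.zone][idx(a.zone, nx, ny)];
      if (mi && A[mi - 1].alive && A[mi - 1].phen == PH_TREG) found = true;
    });
    return found;
  }

  // clonal expansion: spawn one descendant into a free neighbouring cell
  void divide(int i, int childState, int childLife) {
    Agent& a = A[i];
    if (a.prolif_left <= 0) return;
    if (tregAdjacent(a)) return;  // regulatory suppression
    if (--a.div_cd > 0) return;
    a.div_cd = (int)pr.division_interval;
    int nb = 0, bx[8], by[8];
    forMoore(a.zone, a.x, a.y, 1, [&](int nx, int ny) {
      if (mob[a.zone][idx(a.zone, nx, ny)] == 0) { bx[nb] = nx; by[nb] = ny; ++nb; }
    });
    if (nb == 0) return;
    int k = ri(nb);
    int zone = a.zone, type = a.type;
    bool spec = a.specific;
    a.prolif_left--;
    Agent c = mk(type, childState, zone, bx[k], by[k]);
    c.specific = spec;
    c.life = childLife;
    c.phen = (type == T_T) ? PH_TH1 : PH_NONE;
    if (childState == B_Activated) {
      c.prolif_left = 0;
      c.div_cd = 0;
    }
    A.push_back(c);
    placeMobile((int)A.size() - 1);
  }

  void stepT(int i) {
    Agent& a = A[i];
    if (--a.life <= 0) { die(i, T_DeadApoptotic, TR_lifespan); return; }
    switch (a.state) {
      case T_Naive:
        moveChemo(i, SIG_CHL);
        break;
      case T_Activated: {
        // stationary while conjugated/dividing
        divide(i, T_Effector, (int)pr.t_eff_lifespan);
        Agent& a2 = A[i];
        if (a2.prolif_left <= 0) {
          if (transition(i, T_Effector, TR_division_complete))
            a2.life = (int)pr.t_eff_lifespan;
        } else if (resolved) {
          if (transition(i, T_Memory, TR_resolution))
            a2.life = (int)pr.memory_lifespan;
        }
        break;
      }
      case T_Effector: {
        if (resolved && ru() < pr.memory_conv_p) {
          if (transition(i, T_Memory, TR_resolution)) {
            a.life = (int)pr.memory_lifespan;
            break;
          }
        }
        if (a.zone == 1) {
          dep(1, SIG_CKPRO, a.x, a.y, pr.eff_ck_dep);
          dep(1, SIG_CHT, a.x, a.y, pr.eff_ch_dep);
          moveChemo(i, SIG_CHT);
        } else {
          int dz = destZone(a);
          if (adjacentToPortal(i)) migrate(i, dz);
          else {
            int pi = homePortal(a.zone, a.id);
            moveToward(i, A[pi].x, A[pi].y);
          }
        }
        break;
      }
      case T_Memory:
        moveRandom(i);
        break;
      default: break;
    }
  }

  void stepB(int i) {
    Agent& a = A[i];
    if (--a.life <= 0) { die(i, B_DeadApoptotic, TR_lifespan); return; }
    switch (a.state) {
      case B_Naive:
        moveChemo(i, SIG_CHL);
        break;
      case B_Activated: {
        // full activation requires contact with an activated helper T cell
        int helper = -1;
        forMoore(a.zone, a.x, a.y, 1, [&](int nx, int ny) {
          int mi = mob[a.zone][idx(a.zone, nx, ny)];
          if (!mi || helper >= 0) return;
          Agent& m = A[mi - 1];
          if (m.alive && m.type == T_T &&
              (m.state == T_Activated || m.state == T_Effector) &&
              m.phen != PH_TREG)
            helper = mi - 1;
        });
        if (helper >= 0) {
          if (transition(i, B_Plasma, TR_tcell_help)) {
            a.class_sw = (int)pr.class_switch;
            a.life = (int)pr.plasma_lifespan;
            recordContact(i, helper);
          }
          break;
        }
        divide(i, B_Activated, (int)pr.naive_lifespan);
        if (resolved) {
          if (transition(i, B_Memory, TR_resolution))
            A[i].life = (int)pr.memory_lifespan;
        } else {
          moveChemo(i, SIG_CHL);  // roams the lymphoid zone seeking T help
        }
        break;
      }
      case B_Plasma: {
        // antibody secretion: IgM (Ab5) first, IgG (Ab1/Ab2) after the
        // class-switch delay
        if (a.class_sw > 0) {
          a.class_sw--;
          dep(a.zone, SIG_AB5, a.x, a.y, pr.ab_dep);
        } else {
          dep(a.zone, SIG_AB1, a.x, a.y, pr.ab_dep / 2.0);
          dep(a.zone, SIG_AB2, a.x, a.y, pr.ab_dep / 2.0);
        }
        // antibody-secreting cells stay resident in the lymphoid tissue;
        // their antibody drains to the blood through the efferent lymph
        moveRandom(i);
        break;
      }
      case B_Memory:
        moveRandom(i);
        break;
      default: break;
    }
  }

  void stepCTL(int i) {
    Agent& a = A[i];
    if (--a.life <= 0) { die(i, C_DeadApoptotic, TR_lifespan); return; }
    switch (a.state) {
      case C_Naive:
        moveChemo(i, SIG_CHL);
        break;
      case C_Activated: {
        divide(i, C_Effector, (int)pr.t_eff_lifespan);
        Agent& a2 = A[i];
        if (a2.prolif_left <= 0) {
          if (transition(i, C_Effector, TR_division_complete))
            a2.life = (int)pr.t_eff_lifespan;
        } else if (resolved) {
          if (transition(i, C_Memory, TR_resolution))
            a2.life = (int)pr.memory_lifespan;
        }
        break;
      }
      case C_Effector: {
        if (resolved && ru() < pr.memory_conv_p) {
          if (transition(i, C_Memory, TR_resolution)) {
            a.life = (int)pr.memory_lifespan;
            break;
          }
        }
        if (a.zone == 1) {
          int tgt = -1;
          forMoore(1, a.x, a.y, 1, [&](int nx, int ny) {
            int pi = pcg[idx(1, nx, ny)];
            if (pi && A[pi - 1].alive && A[pi - 1].state == PC_Infected &&
                tgt < 0)
              tgt = pi - 1;
          });
          if (tgt >= 0 && ru() < pr.ctl_kill_p)
            killPC(i, tgt, PC_DeadApoptotic, TR_killed_ctl);
          else moveChemo(i, SIG_CHT);
        } else {
          int dz = destZone(a);
          if (adjacentToPortal(i)) migrate(i, dz);
          else {
            int pi = homePortal(a.zone, a.id);
            moveToward(i, A[pi].x, A[pi].y);
          }
        }
        break;
      }
      case C_Memory:
        moveRandom(i);
        break;
      default: break;
    }
  }

  void stepAgent(int i) {
    Agent& a = A[i];
    if (a.type == T_PC) { stepPC(i); return; }
    if (!a.alive || a.removed || a.in_queue) {
      if (a.in_queue && a.alive && --a.life <= 0) {
        switch (a.type) {  // agents can die of old age while queued
          case T_DC: die(i, DC_DeadApoptotic, TR_lifespan); break;
          case T_T: die(i, T_DeadApoptotic, TR_lifespan); break;
          case T_B: die(i, B_DeadApoptotic, TR_lifespan); break;
          case T_CTL: die(i, C_DeadApoptotic, TR_lifespan); break;
          default: break;
        }
      }
      return;
    }
    switch (a.type) {
      case T_DC: stepDC(i); break;
      case T_MAC: stepMAC(i); break;
      case T_NK: stepNK(i); break;
      case T_GRAN: stepGRAN(i); break;
      case T_T: stepT(i); break;
      case T_B: stepB(i); break;
      case T_CTL: stepCTL(i); break;
      default: break;  // portals do nothing
    }
  }

  // --------------------------------------------------------------- physics

  void diffuseAll() {
    for (int z = 1; z <= 3; ++z)
      for (int s = 0; s < NSIG; ++s) {
        if (!sigAct[z][s] || !hasMass[z][s]) continue;
        diffuse_grid(field[z][s], side[z], sigD[s], sigE[s], eps, false);
        double tot = 0.0;
        for (double v : field[z][s]) tot += v;
        hasMass[z][s] = tot > 0.0;
      }
    // antibody neutralisation of free virus in the tissue; binding consumes
    // antibody stoichiometrically, so the humoral response has finite local
    // capacity and a large enough lesion can exhaust it
    if (hasMass[1][SIG_VIRUS]) {
      double kn = pr.ab_neut;
      std::vector<double>& v = field[1][SIG_VIRUS];
      for (size_t c = 0; c < v.size(); ++c) {
        if (v[c] <= 0) continue;
        double a1 = field[1][SIG_AB1][c], a2 = field[1][SIG_AB2][c],
               a5 = field[1][SIG_AB5][c];
        double ab = a1 + a2 + a5;
        if (ab <= 0) continue;
        double remove = std::min(v[c], kn * ab);
        v[c] -= remove;
        if (v[c] < eps) v[c] = 0.0;
        double used = remove / kn;         // bound antibody, per unit virus
        double f = 1.0 - used / ab;
        if (f < 0) f = 0;
        field[1][SIG_AB1][c] = a1 * f;
        field[1][SIG_AB2][c] = a2 * f;
        field[1][SIG_AB5][c] = a5 * f;
      }
    }
  }

  // portals carry signals between zones: a fraction of the concentration in
  // the source portals' neighbourhoods appears at the destination portals
  void portalSignals() {
    for (auto& r : routes) {
      if (!sigAct[r.from][r.sig] || !sigAct[r.to][r.sig]) continue;
      if (!hasMass[r.from][r.sig]) continue;
      double moved = 0.0;
      if (r.perfuse) {
        // well-mixed transfer: the circulation samples the whole zone
        for (double& c : field[r.from][r.sig]) {
          double take = c * portalFrac;
          c -= take;
          moved += take;
        }
      } else {
        for (int pi : portals[r.from]) {
          Agent& p = A[pi];
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              int nx = p.x + dx, ny = p.y + dy;
              if (!inb(r.from, nx, ny)) continue;
              double& c = field[r.from][r.sig][idx(r.from, nx, ny)];
              double take = c * portalFrac;
              c -= take;
              moved += take;
            }
        }
      }
      if (moved > 0) {
        if (r.perfuse) {
          // blood-borne signal perfusing the destination tissue uniformly
          std::vector<double>& g = field[r.to][r.sig];
          double share = moved / (double)g.size();
          for (double& v : g) v += share;
        } else {
          double share = moved / portals[r.to].size();
          for (int pi : portals[r.to]) {
            Agent& p = A[pi];
            field[r.to][r.sig][idx(r.to, p.x, p.y)] += share;
          }
        }
        hasMass[r.to][r.sig] = true;
      }
    }
  }

  void processQueues() {
    for (int dz = 1; dz <= 3; ++dz) {
      std::deque<int>& q = migQueue[dz];
      size_t n = q.size();
      for (size_t k = 0; k < n; ++k) {
        int i = q.front();
        q.pop_front();
        if (!A[i].alive || !A[i].in_queue) continue;  // died while waiting
        if (tryEnterZone(i, dz)) A[i].in_queue = false;
        else q.push_back(i);  // FIFO retry next tick
      }
    }
  }

  void influx() {
    // monocyte-derived dendritic agents are recruited into inflamed tissue
    // at a rate scaling with the extent of infection
    if (prevInfected <= 0) return;
    double lambda = std::min(pr.dc_influx_cap,
                             pr.dc_influx * prevInfected / 250.0);
    int n = (int)lambda;
    if (ru() < lambda - n) ++n;
    for (int k = 0; k < n; ++k) {
      int pi = portals[1][ri((int)portals[1].size())];
      Agent& p = A[pi];
      int nb = 0, bx[8], by[8];
      forMoore(1, p.x, p.y, 1, [&](int nx, int ny) {
        if (mob[1][idx(1, nx, ny)] == 0) { bx[nb] = nx; by[nb] = ny; ++nb; }
      });
      if (nb > 0) {
        int j = ri(nb);
        Agent a = mk(T_DC, DC_Immature, 1, bx[j], by[j]);
        a.life = (int)pr.dc_imm_lifespan;
        A.push_back(a);
        placeMobile((int)A.size() - 1);
      }
    }
  }

  void decayCorpses() {
    int cd = (int)pr.corpse_decay;
    for (size_t i = 0; i < A.size(); ++i) {
      Agent& a = A[i];
      if (a.alive || a.removed || a.type == T_PC || a.type == T_PORTAL) continue;
      if (tick - a.death_tick >= cd) {
        mob[a.zone][idx(a.zone, a.x, a.y)] = 0;
        a.removed = true;
      }
    }
  }

  // --------------------------------------------------------------- census

  enum { CEN_FIXED = NTYPE * 3 + 5 + 2 + 12 + 3, NCEN = CEN_FIXED + NSIG * 3 };

  void censusRow(NumericMatrix& cen, int ri0) {
    double rowbuf[NCEN];
    double* row = rowbuf;
    for (int c = 0; c < NCEN; ++c) row[c] = 0.0;
    int infected = 0;
    for (size_t i = 0; i < A.size(); ++i) {
      Agent& a = A[i];
      if (a.type == T_PC) {
        if (a.removed) continue;
        if (a.alive) {
          row[a.type * 3 + (a.zone - 1)] += 1;
          if (a.state == PC_Healthy) row[27] += 1;
          if (a.state == PC_Stressed) row[28] += 1;
          if (a.state == PC_Infected) { row[29] += 1; ++infected; }
        } else {
          if (a.state == PC_DeadNecrotic) row[30] += 1;
          if (a.state == PC_DeadApoptotic) row[31] += 1;
        }
        continue;
      }
      if (!a.alive) continue;
      row[a.type * 3 + (a.zone - 1)] += 1;
      if (a.type == T_DC && a.zone == 2) {
        if (a.phen == PH_DC1) row[32] += 1;
        if (a.phen == PH_DC2) row[33] += 1;
      }
      switch (a.state) {
        case T_Naive: row[34] += 1; break;
        case T_Activated: row[35] += 1; break;
        case T_Effector: row[36] += 1; break;
        case T_Memory: row[37] += 1; break;
        case B_Naive: row[38] += 1; break;
        case B_Activated: row[39] += 1; break;
        case B_Plasma: row[40] += 1; break;
        case B_Memory: row[41] += 1; break;
        case C_Naive: row[42] += 1; break;
        case C_Activated: row[43] += 1; break;
        case C_Effector: row[44] += 1; break;
        case C_Memory: row[45] += 1; break;
        case M_M1: row[46] += 1; break;
        case M_M2: row[47] += 1; break;
        case G_Active: row[48] += 1; break;
        default: break;
      }
    }
    for (int s = 0; s < NSIG; ++s)
      for (int z = 1; z <= 3; ++z) {
        double tot = 0.0;
        if (sigAct[z][s] && hasMass[z][s])
          for (double v : field[z][s]) tot += v;
        row[CEN_FIXED + s * 3 + (z - 1)] = tot;
      }
    prevInfected = infected;
    for (int c = 0; c < NCEN; ++c) cen(ri0, c) = row[c];
  }

  static CharacterVector censusNames() {
    CharacterVector nm(NCEN);
    int k = 0;
    for (int t = 0; t < NTYPE; ++t)
      for (int z = 1; z <= 3; ++z)
        nm[k++] = std::string(TYPE_NAMES[t]) + "_z" + std::to_string(z);
    const char* extra[] = {
      "pc_healthy", "pc_stressed", "pc_infected", "pc_dead_necrotic",
      "pc_dead_apoptotic", "dc1_z2", "dc2_z2",
      "t_naive", "t_activated", "t_effector", "t_memory",
      "b_naive", "b_activated", "b_plasma", "b_memory",
      "ctl_naive", "ctl_activated", "ctl_effector", "ctl_memory",
      "mac_m1", "mac_m2", "gran_active" };
    for (auto& s : extra) nm[k++] = s;
    for (int s = 0; s < NSIG; ++s)
      for (int z = 1; z <= 3; ++z)
        nm[k++] = std::string("sig_") + SIG_NAMES[s] + "_z" + std::to_string(z);
    return nm;
  }

  void checkpoint(int atTick) {
    for (size_t i = 0; i < A.size(); ++i) {
      Agent& a = A[i];
      if (a.type == T_PORTAL) continue;  // structures, never network nodes
      bool any = false;
      for (int k = 0; k < NTYPE * 3; ++k) {
        if (a.led[k] == 0) continue;
        any = true;
        ckTick.push_back(atTick);
        ckId.push_back(a.id);
        ckType.push_back(a.type);
        ckAlive.push_back(a.alive ? 1 : 0);
        ckPartner.push_back(k / 3);
        ckZone.push_back(k % 3 + 1);
        ckCount.push_back(a.led[k]);
      }
      if (!any) {  // unengaged agents keep the denominators computable
        ckTick.push_back(atTick);
        ckId.push_back(a.id);
        ckType.push_back(a.type);
        ckAlive.push_back(a.alive ? 1 : 0);
        ckPartner.push_back(-1);
        ckZone.push_back(0);
        ckCount.push_back(0);
      }
    }
  }

  // ------------------------------------------------------------------ run

  List run(bool withTrace) {
    doTrace = withTrace;
    NumericMatrix census(stopTick, NCEN);
    checkpoint(0);  // tick-0 table: nothing engaged yet
    std::vector<int> order;
    for (tick = 1; tick <= stopTick; ++tick) {
      // update the resolution flag from the previous tick's census
      if (tick > 1 && prevInfected == 0) ++resolvedStreak;
      else if (tick > 1) resolvedStreak = 0;
      resolved = resolvedStreak >= (int)pr.resolution_lag;

      // (1) reshuffle activation order to emulate concurrency
      size_t nAct = A.size();
      order.resize(nAct);
      for (size_t k = 0; k < nAct; ++k) order[k] = (int)k;
      for (size_t k = nAct - 1; k > 0; --k)
        std::swap(order[k], order[ri((int)k + 1)]);

      // (2) one FSM step per agent
      for (size_t k = 0; k < nAct; ++k) stepAgent(order[k]);
      influx();
      decayCorpses();

      // (3) signal diffusion, (4) portal signal transfer + queues
      diffuseAll();
      portalSignals();
      processQueues();

      // (5) census, (6) checkpoint
      censusRow(census, tick - 1);
      if (ckInt > 0 && tick % ckInt == 0) checkpoint(tick);
      if (tick % 200 == 0) Rcpp::checkUserInterrupt();
    }
    colnames(census) = censusNames();

    List ck = List::create(
      _["tick"] = wrap(ckTick), _["agent_id"] = wrap(ckId),
      _["agent_type"] = wrap(ckType), _["alive"] = wrap(ckAlive),
      _["partner_type"] = wrap(ckPartner), _["zone"] = wrap(ckZone),
      _["count"] = wrap(ckCount));

    IntegerMatrix pl(NTYPE, NTYPE), po(NTYPE, NTYPE);
    for (int a = 0; a < NTYPE; ++a)
      for (int b = 0; b < NTYPE; ++b) {
        pl(a, b) = (int)pairLive[a][b];
        po(a, b) = (int)pairOne[a][b];
      }

    int stillQueued = 0;
    for (int z = 1; z <= 3; ++z)
      for (int i : migQueue[z])
        if (A[i].alive && A[i].in_queue) ++stillQueued;

    List out = List::create(
      _["census"] = census,
      _["checkpoints"] = ck,
      _["pair_live"] = pl,
      _["pair_onesided"] = po,
      _["n_pc_init"] = nPCinit,
      _["portal_audit"] = List::create(
        _["enqueued"] = (double)qEnqueued, _["placed"] = (double)qPlaced,
        _["still_queued"] = stillQueued),
      _["occ_violations"] = (double)occViolations,
      _["agents_final"] = finalAgents());
    if (withTrace) {
      int n = (int)trace.size();
      IntegerVector tt(n), ti(n), ty(n), fr(n), to(n), tg(n);
      for (int k = 0; k < n; ++k) {
        tt[k] = trace[k].tick; ti[k] = trace[k].id; ty[k] = trace[k].type;
        fr[k] = trace[k].from; to[k] = trace[k].to; tg[k] = trace[k].trig;
      }
      out["trace"] = List::create(
        _["tick"] = tt, _["agent_id"] = ti, _["agent_type"] = ty,
        _["from"] = fr, _["to"] = to, _["trigger"] = tg);
    }
    return out;
  }

  DataFrame finalAgents() {
    size_t n = A.size();
    IntegerVector id(n), ty(n), st(n), ph(n), zn(n), xx(n), yy(n);
    LogicalVector sp(n), al(n), rm(n), iq(n), en(n);
    for (size_t i = 0; i < n; ++i) {
      id[i] = A[i].id; ty[i] = A[i].type; st[i] = A[i].state;
      ph[i] = A[i].phen; zn[i] = A[i].zone; xx[i] = A[i].x; yy[i] = A[i].y;
      sp[i] = A[i].specific; al[i] = A[i].alive; rm[i] = A[i].removed;
      iq[i] = A[i].in_queue; en[i] = A[i].engaged;
    }
    return DataFrame::create(
      _["id"] = id, _["type"] = ty, _["state"] = st, _["phenotype"] = ph,
      _["specific"] = sp, _["zone"] = zn, _["x"] = xx, _["y"] = yy,
      _["alive"] = al, _["removed"] = rm, _["in_queue"] = iq,
      _["engaged"] = en);
  }

  // initial-world snapshot for inspection without running
  List snapshot() {
    size_t n = A.size();
    IntegerVector id(n), ty(n), st(n), ph(n), zn(n), xx(n), yy(n);
    LogicalVector sp(n), al(n);
    for (size_t i = 0; i < n; ++i) {
      id[i] = A[i].id; ty[i] = A[i].type; st[i] = A[i].state;
      ph[i] = A[i].phen; zn[i] = A[i].zone; xx[i] = A[i].x; yy[i] = A[i].y;
      sp[i] = A[i].specific; al[i] = A[i].alive;
    }
    IntegerMatrix pc(side[1], side[1]);
    for (int y = 0; y < side[1]; ++y)
      for (int x = 0; x < side[1]; ++x) {
        int pi = pcg[idx(1, x, y)];
        pc(y, x) = pi ? A[pi - 1].state + 1 : 0;
      }
    return List::create(
      _["agents"] = List::create(
        _["id"] = id, _["type"] = ty, _["state"] = st, _["phenotype"] = ph,
        _["specific"] = sp, _["zone"] = zn, _["x"] = xx, _["y"] = yy,
        _["alive"] = al),
      _["pc_grid"] = pc,
      _["zone_side"] = IntegerVector::create(side[1], side[2], side[3]),
      _["n_pc_init"] = nPCinit);
  }
};

// ------------------------------------------------------------- R interface

// [[Rcpp::export]]
List cpp_run(List config, bool trace = false) {
  Engine e;
  e.configure(config);
  return e.run(trace);
}

// [[Rcpp::export]]
List cpp_build_world(List config) {
  Engine e;
  e.configure(config);
  return e.snapshot();
}

// [[Rcpp::export]]
NumericMatrix cpp_diffuse(NumericMatrix grid, double D, double e,
                          double eps = 1e-6, bool periodic = false) {
  if (D <= 0 || D > 1 || e <= 0 || e > 1)
    stop("diffusion and evaporation constants must lie in (0, 1]");
  int side = grid.nrow();
  if (grid.ncol() != side) stop("grid must be square");
  std::vector<double> g((size_t)side * side);
  for (int y = 0; y < side; ++y)
    for (int x = 0; x < side; ++x) g[(size_t)y * side + x] = grid(y, x);
  diffuse_grid(g, side, D, e, eps, periodic);
  NumericMatrix out(side, side);
  for (int y = 0; y < side; ++y)
    for (int x = 0; x < side; ++x) out(y, x) = g[(size_t)y * side + x];
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_gradient_target(NumericMatrix grid, int x, int y,
                                  double threshold) {
  int side = grid.nrow();
  if (x < 0 || y < 0 || x >= grid.ncol() || y >= side)
    stop("coordinate out of bounds");
  double best = -1.0;
  int nb = 0, bx[8], by[8];
  for (int dy = -1; dy <= 1; ++dy)
    for (int dx = -1; dx <= 1; ++dx) {
      if (dx == 0 && dy == 0) continue;
      int nx = x + dx, ny = y + dy;
      if (nx < 0 || ny < 0 || nx >= grid.ncol() || ny >= side) continue;
      double v = grid(ny, nx);
      if (v > best + 1e-15) { best = v; nb = 0; }
      if (v >= best - 1e-15) { bx[nb] = nx; by[nb] = ny; ++nb; }
    }
  if (nb == 0 || best < threshold || best <= grid(y, x))
    return IntegerVector(0);
  int k = (nb == 1) ? 0 : ri(nb);
  return IntegerVector::create(bx[k], by[k]);
}

// [[Rcpp::export]]
CharacterVector cpp_type_names() {
  return CharacterVector(TYPE_NAMES, TYPE_NAMES + NTYPE);
}

// [[Rcpp::export]]
CharacterVector cpp_state_names() {
  return CharacterVector(STATE_NAMES, STATE_NAMES + N_STATES);
}

// [[Rcpp::export]]
CharacterVector cpp_trigger_names() {
  return CharacterVector(TRIG_NAMES, TRIG_NAMES + N_TRIG);
}

// [[Rcpp::export]]
CharacterVector cpp_signal_names() {
  return CharacterVector(SIG_NAMES, SIG_NAMES + NSIG);
}
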