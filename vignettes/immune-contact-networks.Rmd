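---
title: "An agent-based immune simulator and its dynamic contact network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An agent-based immune simulator and its dynamic contact network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`immunet` simulates the innate and adaptive immune response to a viral
infection of a generic tissue as an agent-based model on three square
lattices: Zone 1 is the functional organ tissue, Zone 2 the secondary
lymphoid tissue (lymph nodes/spleen), and Zone 3 the blood.  The default
areas, 12321 : 2500 : 62500 cells (111^2, 50^2, 250^2), approximate the
~1000 : 200 : 5000 ml volume ratios of an organ such as the lungs, the
thoracic lymphoid tissue, and blood, with the lymphoid zone fixed at
50 x 50.

Nine agent types populate the zones.  Parenchymal Agents (the tissue
cells) and Portal Agents (vessel entry/exit points) are stationary;
Dendritic, Macrophage, Natural Killer and Granulocyte Agents (innate
leukocytes) and TCell, BCell and CTL Agents (adaptive lymphocytes) move
one lattice cell per tick, randomly unless a chemokine gradient attracts
them.  Each agent is a finite-state automaton: at every tick it senses the
signals at its cell and the agents within its contact radius (Chebyshev 1;
2 for dendritic agents, reflecting their long processes) and follows **at
most one automaton edge**.  Time is a sequence of discrete ticks; agent
activation order is reshuffled every tick to emulate concurrency, and all
randomness comes from R's RNG, so a seed fixes the entire trajectory.

Nine diffusing scalar fields carry the indirect (stigmergic)
communication: free `Virus`, the danger signal `PK1`, pro- and
anti-inflammatory cytokines (`CK_pro`, `CK_anti`), tissue and lymphoid
chemokines (`CH_tissue`, `CH_lymph`), and three antibody classes (`Ab5` =
IgM, `Ab1`/`Ab2` = IgG).  The diffusion kernel per tick is

c' = e * (c + D * (mean of Moore(1) neighbours − c)),

with evaporation `e` and diffusion constant `D` in (0, 1], truncated
neighbourhoods at the zone edges, and a floor of 1e−6 below which a
concentration is zeroed (this bounds runtime without affecting any
threshold behaviour; thresholds are all far above the floor).  On a
periodic lattice with `e = 1` the kernel conserves mass exactly, which the
test suite uses as an oracle.

### The infection and the response

A run starts with a fixed layout: a centred 71 x 71 block of healthy
parenchymal cells, four Zone-1 portals just outside the block edge
midpoints, and the same four infection sites (the centre 2 x 2 of the
block) every run, with a small viral inoculum deposited there.  Mobile
agents are placed uniformly at random in their home zones; the few
antigen-specific lymphocytes (5 each of T, B and CTL) land at random empty
Zone-2 coordinates.

Infected parenchymal cells deposit `Virus`, `PK1` and `CH_tissue` every
tick and die by lysis (necrotic) after 20 ticks.  A healthy cell whose
local virus concentration reaches the threshold becomes infected with
probability 0.45 per tick — the probabilistic step makes the infection
front ragged, which is what gives replicate runs genuinely different
fates.  Healthy cells next to an infected one become stressed (a
receptor-mediated, hence "meaningful", contact).  Dead tissue regenerates
10 ticks after death when at least two live uninfected neighbours remain.

The innate arm acts immediately: NK agents kill adjacent infected or
stressed cells (a cytotoxic-granule budget of 8 kills each; suppressed
where the anti-inflammatory signal is high), macrophages phagocytose
corpses and kill infected neighbours (a handling capacity of 2 targets
with a 30-tick digestion pause; saturated macrophages polarise to the
anti-inflammatory M2 state), and granulocytes activated by the danger
signal or necrotic debris kill through released toxins — an
environmentally mediated kill that is *not* a receptor contact, so it is
never recorded in the contact ledgers.

The adaptive arm must be assembled: immature dendritic agents that touch
infected tissue under the danger signal become pro-inflammatory DC1 (DC2
when they find apoptotic debris without danger), walk to a portal and
migrate to Zone 2, where they probe a radius of two cells and present
antigen to naive antigen-matched lymphocytes.  Activated T/B/CTL clones
divide (up to 17 descendants, every tick, suppressed next to regulatory T
cells); B cells additionally need contact with an activated helper T cell
to become plasma cells, which stay resident in the lymphoid tissue and
secrete IgM first and IgG after a 30-tick class switch.  Antibody drains
through the efferent lymph to the blood and perfuses the tissue through
the capillaries (modelled as well-mixed "perfuse" portal routes), where it
neutralises free virus *stoichiometrically* — binding consumes antibody,
so the humoral response has a finite capacity.  Effector T and CTL agents
migrate Zone 2 → Zone 3 → Zone 1 through portals (FIFO queues when no
entry is possible); CTLs kill infected cells on contact, effector T cells
amplify the local cytokine and chemokine fields.  When the infection has
been cleared for 20 ticks the response resolves: effectors convert to
memory cells and M1 macrophages to M2.

A *win* is a run that ends with zero infected parenchymal agents **and**
more than half of the initial tissue alive (survivors plus regenerated
cells); everything else — persisting infection, total tissue death, or
clearance with half or fewer survivors — is a *loss*.  The win/loss split
is an emergent race: if the antibody/CTL wave arrives while the lesion is
still within its capacity the infection collapses, tissue regenerates and
the run is a win; if the ragged front outruns it, the response saturates
and exhausts (fixed clone budgets, finite effector lifespans) and the
infection either smoulders chronically — regeneration keeps feeding
susceptible cells — or consumes the tissue.

### Meaningful contacts

Every agent keeps a cumulative ledger of its *meaningful* contacts —
contacts that changed a state or an internal variable of a participant —
keyed by partner type and by the zone where the interaction happened
(counts are never reset on migration).  Random collisions are not counted;
both live participants record; if one participant is dead only the live
one records (e.g. a macrophage engulfing a corpse); portals, being
structures, never record.  Repeated contacts between the same pair at
successive ticks count again while the recognising state persists.
Dendritic agents searching for open space in a crowded lymphoid zone
"step over" one another: a move blocked by another dendritic agent is a
contact, and an agent hemmed in by three or more dendritic neighbours
contacts the whole cluster.  In an uncrowded (win) lymph node this is
rare; in an engorged (loss) node it dominates the network — this is the
model's mechanism for the striking dendritic self-interaction excess in
losses.

Ledgers are checkpointed every 100 ticks to a plain CSV table
(`tick, agent_id, agent_type, alive, partner_type, zone, count`) in which
zero-contact agents appear with partner `none`, so engagement denominators
stay computable.

## Parameters

The geometry (zone ratios), the near-optimal initial condition of 200
dendritic agents, the run length (1001 ticks, checkpoints every 100), the
meaningful-contact criteria and radii, and the win/loss definition are
fixed study conditions.  The remaining rule constants — the full parameter
panel is not published — are this package's reconstruction.  They were
calibrated, once, so that the model reproduces the published summary
behaviour at the default condition: a win fraction near 100/146, a
win-class infected-tissue peak near 4.3 days at 64 minutes/tick, a steady
engaged-macrophage median of ~2 links, dendritic agents dominating every
other type's median links from 300 ticks on, a lymphoid-zone dendritic
self-contact median more than tenfold higher in losses than in wins, and
a scale-free (power-law) combined degree distribution.  The calibrated
defaults live in `default_config()` and every one of them can be
overridden per run; the tests pin the emergent behaviour, not the
constants.

Key defaults (units are ticks, lattice cells, or arbitrary concentration
units): virus deposition 2.1/tick with infection threshold 1.0 and
infection probability 0.45; lysis at 20 ticks; regeneration after 10
ticks with ≥2 live uninfected neighbours; diffusion/evaporation per
signal as in `default_config()$signals` (chemokines reach far, `e =
0.995`; virus is short-range, `e = 0.90`); clone cap 17 with division
every tick; class switch 30 ticks; antibody secretion 29/tick per plasma
cell with stoichiometric neutralisation factor 1.5; NK kill probability
0.6 with budget 8; macrophage capacity 2; granulocyte burst 10 ticks;
dendritic recruitment scales with the number of infected cells (0.6 per
250 infected, capped at 4 per tick), and activated dendritic agents do
not age while infection persists (inflammatory survival), dying 300 ticks
after clearance.

Two structural choices deserve note.  Zones 2 and 3 carry eight portals
(two per edge) rather than four: lymphoid tissue and blood have many
vessels, and a single bottleneck portal ring otherwise throttles effector
export at high cell densities.  And plasma cells remain lymphoid-resident
while their antibody travels — the transport is in the signal routes, not
the agents.

## Tick-to-time calibration

Ticks are mapped to physical time through immune-response hallmarks with
known human timing.  For a hallmark peaking at day *d* in humans and tick
*T* in the simulation, one tick represents 1440·d/T minutes.  The shipped
registry fixes only the serum IgM peak (day 8.5, the midpoint of the 7–10
day literature window; its simulation correlate is the Zone-3 `Ab5`
peak); other hallmark days are supplied by the user.  With a peak at 159
ticks this gives 18.7 ticks/day and 77 minutes/tick (rounded
half-away-from-zero from 76.98); the package-wide conversions use the
64 minutes/tick consensus value when converting the infected-tissue peak
to days.  `calibrate()` automates the computation from census files, and
`minutes_per_tick()`/`ticks_to_days()` are exact inverses.

## Statistics

All win-vs-loss contrasts use the two-tailed Mann-Whitney U test
(`stats::wilcox.test` underneath: exact when the pooled sample is ≤ 12
and tie-free, otherwise the normal approximation with tie and continuity
corrections) at a Bonferroni-adjusted level 0.05/m.  Degree
distributions are histograms of cumulative links per node over engaged
agents pooled across the runs of an outcome class; the scale-free check
is the Spearman correlation between node counts and links per node plus
a linear regression on the log10–log10 points, reported as undetermined
below three distinct degrees.  Spearman p-values come from
`stats::cor.test` (exact for small tie-free samples, t-approximation
otherwise); full permutation enumeration beyond n ≈ 10 is computationally
infeasible and the t-approximation is standard.  Quartiles everywhere use
linear interpolation between order statistics (R's default quantile
type).  Late in loss-dominated pooled distributions a high-degree
dendritic "lump" departs from the pure power law; the scale-free
signature is therefore assessed at the 400-tick checkpoint, where agent
activity has approached its end-point value.

## What the simulations do and do not show

Runs are self-generated; there is no external data.  The generator
emulates the *structure* of an immune response — compartments, migration,
presentation, clonal expansion, humoral and cytotoxic effector phases,
resolution — with abstract space and time and generic virus and tissue.
It does not model receptor-level biochemistry, affinity maturation, MHC
restriction, blood flow, or continuous space, and tick-to-time mapping is
an order-of-magnitude calibration, not a claim of biological time
fidelity.  Passing tests therefore show that the implemented rules
reproduce the emergent regularities listed above under the reconstructed
parameter panel; they are not evidence about any particular pathogen or
patient.

## Numerical and design notes

* Concentrations are floored at 1e−6 to keep diffusion sparse; all
  behavioural thresholds are ≥ 5e−3.
* Ties anywhere (movement targets, gradient maxima, portal choice) break
  uniformly at random from the run's single RNG stream.
* Coordinates are 0-based; ticks are 1-based; the census has one row per
  tick and the tick-0 ledger state appears as the `tick == 0` checkpoint
  rows.
* An agent whose state already changed in a tick cannot be changed again
  in the same tick (one-edge-per-tick also under induced transitions such
  as cytotoxic kills; the blocked attempt records no contact and can
  succeed next tick).
* Dead agents never act; killed/lysed tissue cells are *replaced* on
  regeneration by fresh agents with new ids and empty ledgers, so
  engagement denominators stay honest.
* "Links per node" counts repeated contacts (the default); a
  distinct-partner variant exists (`links_per_node(distinct_partners =
  TRUE)`).  Median-links tables are computed over engaged agents by
  default with an over-all-agents variant, since published granulocyte
  medians of 0 suggest the all-agents convention for that type while the
  headline tables read as engaged-only.
* Per-agent pairwise contact medians restrict, by default, to recorders
  with at least one contact with that partner/zone (`engaged_on =
  "pair"`); `engaged_on = "any"` keeps zeros for pair-less but otherwise
  engaged recorders.
* Problem sizes in the shipped tests: unit tests run reduced worlds
  (41/21/31 zone sides); the acceptance checks run 24 full-scale
  default-configuration replicates, which reproduce the win fraction,
  peak timing, median-links and degree-distribution regularities.

## Reproducing the study figures

```{r, eval = FALSE}
library(immunet)

b <- batch(default_config(), n_runs = 24, seed_base = 1001)

# infected-tissue time course with 95% confidence band, per outcome
head(census_band(b, "pc_infected", "win"))

# engagement time courses with win-vs-loss Mann-Whitney comparisons
tc <- engagement_timecourse(b)

# median links per node per type, and the hub at each checkpoint
ht <- hub_table(b)
ht$hub

# log-log degree distribution of all leukocytes pooled, at 400 ticks
f <- degree_distribution(b$pooled_checkpoints, "combined", at_tick = 400)
plot_degree_fit(f)

# dendritic self-contacts in the lymphoid zone, by outcome
pc <- b$pooled_checkpoints
pairwise_contact_stats(pc[pc$outcome == "loss", ], "Dendritic", "Dendritic",
                       zone = 2, at_tick = 1000)

# tick-to-time calibration from the win-class censuses
calibrate(lapply(b$runs[b$outcomes == "win"], `[[`, "census"))
```
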