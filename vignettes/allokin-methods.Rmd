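---
title: "Models and methods in allokin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in allokin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allokin)
```

# Scope

`allokin` analyses intramolecular communication in the two-cassette RNA
helicase Brr2 along two complementary routes: pre-steady-state nucleotide
binding kinetics measured by stopped-flow FRET, and hydrogen-bond
communication networks extracted from molecular-dynamics trajectories.
This vignette documents the models, their assumptions, the tunable
parameters, the numerical choices, and what the synthetic-data generators
do and do not emulate.

# The kinetic model

## One-step reversible binding

Each nucleotide-binding cassette is modelled as an independent one-step
reversible binding site, P + N ⇌ PN, with association rate constant
`k_on` (µM⁻¹s⁻¹) and dissociation rate constant `k_off` (s⁻¹). Under
pseudo-first-order conditions — nucleotide in large excess over protein —
the site occupancy relaxes as a single exponential with apparent rate

```
k_app = k_on · [N] + k_off
```

so the observed fluorescence is

```
F(t) = F∞ + Σ_i F_i · exp(−k_app,i · t)
```

with one term per site. Association traces rise towards `F∞`
(amplitudes enter negatively); chase traces — preformed labelled complex
mixed with excess unlabelled competitor — decay with rate equal to
`k_off` per site, because rebinding of the labelled nucleotide is
negligible under competitor excess.

Assumptions worth stating explicitly:

* **Site independence.** The two cassettes are simulated without any
  thermodynamic coupling term; a sum of independent exponentials is also
  what the fitting model assumes. Allosteric effects are represented only
  through changes in the per-cassette rate constants supplied by the
  user, which is exactly how such effects manifest in the fitted tables.
* **Pseudo-first-order validity.** The closed form is an approximation.
  `model_association_ode()` integrates the full mass-action system
  (`deSolve::lsoda`, `rtol = 1e-8`, `atol = 1e-10·[P]₀`) as a fidelity
  check; at a 20-fold nucleotide excess the two agree within 2% of the
  signal amplitude across the full published parameter range, while at
  equimolar concentrations the deviation is large — which is why the
  experimental design keeps ligand at ≥ 10× protein (a warning, not an
  error, below that).
* **Units.** Seconds and µM throughout; `Kd = k_off/k_on` is reported in
  µM.

## Fitting

`fit_exponentials()` performs Levenberg–Marquardt nonlinear least squares
(`minpack.lm::nlsLM`, `ftol = 1e-10`, bounded below so rates stay
positive). Starting values are deterministic functions of the trace:
`F∞` from the mean of the last 5% of points, the rate seed from a
log-linear regression of |signal − F∞| against time (robust on
logarithmic grids spanning several decades), and two-phase seeds obtained
by splitting the one-phase seed ×10 and ÷10. Two-phase results are always
reported fast phase first. Degenerate inputs (constant traces,
non-convergence, rates at bounds) yield flagged results, never silent
failures.

The number of phases is chosen by `select_phase_count()`: the two-phase
model is accepted only when the extra-sum-of-squares F-test rejects the
one-phase model at α = 0.01 **and** the two rates differ by at least
3-fold. The published account of model choice ("best fits, lowest
standard errors") is informal; the F-test plus separation guard is this
package's operationalisation, and both statistics are retained in the
result so the decision can be audited. On pure-noise traces the guard
keeps the one-phase model in ≥ 95% of seeds (property-tested).

`regress_kapp()` is an ordinary least-squares line through the mean
`k_app` values (optional 1/SD² weighting); the slope estimates `k_on`,
the intercept `k_off`. A negative fitted intercept is flagged but
retained. Where both exist, the chase-derived `k_off` is authoritative
over the titration intercept — chase experiments measure dissociation
directly, while the intercept is an extrapolation to zero concentration —
and the pipeline reports chase values in the `k_minus1` column with the
intercepts kept alongside for comparison.

Phase-to-cassette assignment follows the isolated-cassette calibration
logic: the faster phase is the NC (rapid binding and release), the slower
the CC (slow release). Rates within 3-fold trigger an ambiguity warning,
and when a calibration table and the nucleotide concentration are
available the assignment is validated against a ten-fold window around
the isolated-cassette prediction.

## Affinities and fold ratios

`derive_affinity_table()` computes `Kd = k_minus1/k1` with uncertainties
propagated in quadrature, and three named fold families: CC-vs-NC
affinity folds per nucleotide, ADP-vs-ATPγS preference folds per
cassette, and NC-vs-CC dissociation-rate folds. The two isolated-cassette
constructs are paired as one "isolated" group for cross-cassette
comparisons. `affinity_folds()` computes the same ratios directly from a
printed Kd table; this matters because published Kd tables are typically
computed from unrounded rate constants, so re-deriving them from rounded
rates can disagree in the last digit (e.g. 1.9/1.0 = 1.9 µM against a
printed 2.0 µM). Fold checks against printed affinities therefore use the
printed table, not re-derived ratios.

# The synthetic kinetics generator

`generate_kinetics_dataset()` reproduces the published experimental
design: association experiments at {1, 2.5, 5, 10, 20} µM labelled
nucleotide, 7 replicates per condition, chase experiments against 100 µM
unlabelled competitor, 1000 points per trace in logarithmic sampling, and
additive i.i.d. Gaussian noise with σ equal to 1% of the total signal
amplitude. Defaults mirror the published conditions (0.2 µM protein,
generating rate constants taken from the published tables via
`brr2_rate_constants()`). Acquisition windows span five half-lives of the
slowest phase, which is how an experimenter sets spans — for the
slow-release CC this automatically extends chase acquisition to 2500 s or
more. Replicates are normalised to their initial signal `F₀` and averaged
before fitting, mirroring the instrument work-up.

What the generator does **not** emulate: instrument dead time,
photobleaching, inner-filter effects, correlated (1/f) noise, and
baseline drift. Passing recovery tests therefore demonstrates that the
analysis pipeline is unbiased and precise under the idealised noise
model at the published design, not that it is robust to every instrument
pathology. Amplitudes per cassette are free parameters (default 1 each);
the structural argument that the CC pocket sits near two tryptophans
suggests a larger CC amplitude but does not quantify it, and recovery is
insensitive to the ratio at the tested noise level.

# The communication-network model

## Hydrogen bonds and occupancy

A donor–hydrogen–acceptor triplet is a hydrogen bond when the heavy-atom
D–A distance is ≤ 3.2 Å and the deviation of the D–H···A angle from
linearity is ≤ 42°. Both cutoffs are inclusive (the definition says
"maximal"), with a 10⁻⁹ floating-point guard so exact-boundary geometries
are not lost to rounding. The angle convention is deviation = 180° −
angle(D–H···A) measured at the hydrogen — stated explicitly to avoid the
complementary-angle trap. Donors are N/O heavy atoms with a covalently
bonded hydrogen (one (D,H) pair per hydrogen), acceptors all N/O heavy
atoms; sulfur participation is available but off by default. Intra-residue
pairs are excluded: they cannot bridge graph nodes.

`occupancy_matrix()` aggregates per-frame detections into residue-pair
probabilities over the analysis window. Two modes exist because the
source procedure does not specify one: **frame-union** (default; a frame
counts for pair (i,j) if *any* bond bridges the residues — communication
exists if any bond does) and **max-single-bond** (per-(D,H,A)-triplet
occupancies, report the maximum). Union-mode probabilities dominate
max-mode ones pairwise, a tested invariant. No periodic-boundary imaging
is performed; the analysed systems are solvated monomers and the fixture
format is non-periodic, so PBC handling is documented as unsupported.

## Graph, costs and paths

Residues are nodes; hydrogen-bond edges carry cost `C_ij = −ln(HB_ij)`
(probable bonds are cheap), covalently consecutive residues are connected
at cost zero, and a pair with both keeps the covalent zero. A pair with
`HB_ij = 0` simply has no edge — no probability floor is applied, and
probabilities are never clamped below 1, so zero-cost hydrogen-bond edges
are legal. The graph is undirected: hydrogen bonds define mutual
communication and the source procedure gives no directionality. Only
protein residues enter the graph by default; the published endpoint pairs
are protein residues, and whether nucleotide/ion nodes belonged in the
original graphs is unstated, so non-protein nodes are excluded and the
choice is flagged here.

Zero-cost covalent edges create massive cost ties, so determinism
requires a total order on paths: cost first, then path length in
residues, then lexicographic comparison of the residue sequence (residues
ordered by chain, then author number). This comparator is
extension-invariant, so a label-setting Dijkstra remains exact under it;
`k_shortest_paths()` runs a Yen-type deviation search on top. The
implementation is validated behaviourally: on 100 seeded random graphs
with ≤ 8 nodes (with and without zero-cost backbones) the ranked output
equals brute-force enumeration of *all* simple paths under the same
comparator, and shortest-path costs agree with an independent graph
library. Disconnected endpoint pairs return an explicit empty result.

Path statistics follow the block logic of the source analyses: occupancy
matrices per temporal block (five 20-ns blocks of a 100-ns window by
default) give block-wise graphs and path sets; `path_length_statistics()`
reports the mean ± SEM over blocks of the per-block average path length,
excluding and reporting blocks with no path. Whether the original
path-set figures used block-wise or whole-window occupancies is
ambiguous, so both are supported (`run_allostery()` takes either a whole
window or per-block matrices). `interface_crossings()` tallies
partition-spanning edges per path; the default cassette partition splits
Brr2 author numbering at residue 1282 (the CC construct boundary), and a
chain-based partition is available for synthetic systems.

## The synthetic network generator

`generate_occupancy_network()` (probability-space fast path) and
`generate_synthetic_trajectory()` (geometric realisation whose frames
toggle planted bonds between bonded and broken placements) build a
two-chain toy system with a planted communication route and random
background bonds. Because consecutive residues communicate at zero cost,
any intra-cassette detour is free; the only necessarily paid cost is the
interface crossing. The planted route is therefore defined as the
backbone runs from each endpoint to a designated interface residue pair,
joined by one high-occupancy interface hydrogen bond (occupancy 0.95 by
default against a background ceiling of 0.3) — with this structure the
route is the provable rank-1 path whenever the planted crossing is the
cheapest one, which is what the recovery experiments test.

Two generator choices deserve justification:

* **Interface scarcity.** Background bonds are placed mostly within
  cassettes (`f_interface = 0.15` of them may cross). In a folded tandem
  enzyme the intercassette contact area is a small fraction of all
  contacts, and the published crossing analysis identifies only a
  handful of interface pairs; a generator that made half of all random
  bonds interface crossings would be structurally unrealistic.
* **Negative control.** When `p_path ≤ p_bg` the planted bond's occupancy
  is drawn from the background distribution instead of being pinned at
  the ceiling — the planted route is then statistically
  indistinguishable from background and recovery collapses towards
  chance, which is the behaviour a negative control must show. Pinning
  it at the ceiling value would leave it deterministically the cheapest
  crossing and the control would be vacuous.

Cassette sizes default to 30+30 residues: large enough for nontrivial
paths, small enough that exhaustive path enumeration remains a usable
oracle. The geometric generator gives each residue a minimal N/H/CA/C/O
atom set on a rigid lattice with 0.05 Å Gaussian jitter; planted bonds are
realised at a 2.9 Å donor–acceptor distance and 0° deviation, leaving
0.3 Å / 42° of margin to the criterion so jitter cannot flip detection.
Each residue takes part in at most one switchable bond; infeasible
requests are rejected. These toys are geometric, not physical — they
validate detection, aggregation and graph logic, not force-field realism.

# Flexibility measures

`superpose()` removes global rigid-body motion by least-squares fitting
(proper rotations only, via `bio3d::fit.xyz`; chirality is preserved and
reflections cannot reach zero RMSD). `rmsf()` computes per-atom
root-mean-square fluctuation of the 3D deviation from the mean position,
with errors from block averaging: the window is cut into `n_blocks = 5`
contiguous blocks and the profile reports mean ± SEM over blocks. By
default each block is referenced to its own mean structure, so the SEM
measures the sampling error of a stationary process; referencing all
blocks to the whole-window mean is available by flag
(`reference = "global"`), since the original choice is unstated.
`cross_correlation()` uses the standard dynamic cross-correlation
definition on 3D displacement dot products, `C_ij = ⟨Δr_i·Δr_j⟩ /
√(⟨|Δr_i|²⟩⟨|Δr_j|²⟩)`; "linear correlation of positional fluctuations"
is not more specific than this, and the per-coordinate alternative would
not be rotation-equivariant. Zero-variance atoms yield flagged undefined
rows rather than NaN surprises. `pocket_width()` is the per-frame
distance between the Cα atoms of two flanking residues (G506–G854 for
the NC pocket, G1353–G1689 for the CC in Brr2 numbering), with block
SEM.

Tested closed-form anchors: static input gives RMSF 0; isotropic Gaussian
jitter of SD σ per coordinate gives RMSF → σ√3; RMSF is invariant under
per-frame rigid motions after superposition; in-phase/anti-phase
sinusoidal motion gives correlations of exactly ±1.

# Problem sizes and determinism

The test-suite and acceptance computations use the published kinetics
design at full size (5 concentrations × 7 replicates × 1000 points, 50
seeds per recovered constant) — small enough to run in seconds per
target — and network sizes of 30+30 residues with exhaustive-oracle
graphs capped at 8 nodes. All generators are pure functions of
(design, seed): the RNG state is saved and restored around every
generation, per-seed streams are derived from a base seed, and optimizer
settings are fixed, so identical configurations reproduce results
byte-identically.

# Known limitations

* The kinetics arm fits traces independently; no global multi-trace
  fitting or Bayesian uncertainty propagation.
* Amplitude-based stoichiometry inference is out of scope; amplitudes are
  nuisance parameters.
* The hydrogen-bond stage has no energetic scoring, no salt-bridge or
  van-der-Waals contact networks, and no PBC imaging.
* The graph stage offers no betweenness/community analyses and no
  correlation- or mutual-information-weighted edges.
* Published per-residue path memberships from the original 200-ns
  trajectories cannot be reproduced desk-side (the trajectories are not
  deposited); the graph machinery is therefore validated by property
  (exhaustive-oracle equivalence, planted-route recovery) rather than by
  table lookup.
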