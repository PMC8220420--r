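# allokin

Tools for dissecting intramolecular communication in the spliceosomal RNA
helicase Brr2 — a tandem enzyme whose N-terminal helicase cassette (NC)
hydrolyses ATP and unwinds RNA while its C-terminal cassette (CC) binds
nucleotide without hydrolysing it, some 70 Å away. The package implements
the two quantitative procedures such a study rests on:

1. **Pre-steady-state binding kinetics.** Stopped-flow FRET traces of
   mant-nucleotide binding are modelled as sums of exponentials,
   `F(t) = F∞ + Σᵢ Fᵢ·exp(−k_app,i·t)`, one phase per binding site. Under
   pseudo-first-order conditions each apparent rate is affine in ligand
   concentration, `k_app = k₁[N] + k₋₁`, so the association rate constant
   `k₁` comes from the slope of a titration and the dissociation rate
   constant `k₋₁` from chase experiments (where the fluorescence decay
   rate equals the off-rate). Equilibrium affinity follows as
   `K_d = k₋₁ / k₁`. The package simulates the full experimental design,
   fits one- and two-phase models with an F-test/rate-separation model
   choice, assigns the fast phase to the NC and the slow phase to the CC,
   and derives affinity tables with propagated uncertainties and named
   fold ratios.

2. **Hydrogen-bond communication networks.** From molecular-dynamics
   trajectories, hydrogen bonds are detected geometrically (donor–acceptor
   distance ≤ 3.2 Å and D–H···A deviation from linearity ≤ 42°) and
   aggregated into residue-pair occupancy probabilities `HB_ij` over an
   analysis window. Residues form a weighted graph with communication
   costs `C_ij = −ln(HB_ij)` on hydrogen-bond edges and zero cost between
   covalently consecutive residues; the k lowest-cost loopless paths
   between the two nucleotide-binding pockets (Dijkstra / Yen with a
   deterministic tie-break) expose the residues and interface contacts
   that carry intercassette communication. Block-averaged RMSF, dynamic
   cross-correlation maps and pocket-width distances quantify the
   accompanying flexibility changes.

Because neither instrument traces nor the long trajectories are publicly
deposited, the package ships synthetic-data generators that emulate both
experiments at desk scale — the published concentration series, replicate
counts, logarithmic sampling and noise level for the kinetics arm, and
planted hydrogen-bond networks with known ground truth for the graph arm —
so every stage of the pipeline is testable end to end.

## Worked example

Simulate the truncated two-cassette construct hBrr2^T1 binding mant-ATPγS
under the published design (five nucleotide concentrations, seven
replicates, 1% noise), then run the complete work-up — average, fit double
exponentials, assign phases, regress `k_app` against concentration, fit
the chase decay:

```r
library(allokin)
run <- run_kinetics(list(construct = "hBrr2T1", nucleotide = "mant-ATPgS",
                         seed = 42))
print(run$analysis$rates, digits = 3)
#>   construct nucleotide cassette   k1    k1_se k_minus1 k_minus1_se
#> 1   hBrr2T1 mant-ATPgS       NC 2.51 0.004709 1.206370    2.92e-03
#> 2   hBrr2T1 mant-ATPgS       CC 0.10 0.000122 0.000903    3.40e-06
```

The recovered constants match the generating (published) values — `k₁` of
2.5 and 0.1 µM⁻¹s⁻¹, `k₋₁` of 1.2 and 0.9×10⁻³ s⁻¹ for NC and CC — and the
derived affinities show the CC binding ~50-fold tighter than the NC
(`K_d` 0.48 µM vs 9 nM here), the signature of the high-turnover catalytic
pocket versus the slow-release regulatory pocket.

For the structural arm, generate a two-cassette network with a planted
high-occupancy interface hydrogen bond (occupancy 0.95 against background
≤ 0.3) and extract the k-shortest communication paths between the pocket
residues:

```r
al <- run_allostery(list(network = list(n_residues = 30), k = 10, seed = 1))
key <- paste(al$truth$endpoints, collapse = "-")
print(al$paths[[key]][[1]])
#> <residue_path> A:15 - A:16 - ... - A:23 - B:38 - ... - B:45 (cost 0.05129, 17 residues)
head(al$crossings[[key]]$tally, 1)
#>   res_i res_j count
#> 1  A:23  B:38     7
```

The rank-1 path runs along each cassette's backbone and crosses the
interface exactly at the planted bond (cost −ln 0.95 ≈ 0.051), and that
pair carries 7 of the 10 best paths — the behaviour the method is designed
to expose on real trajectories.

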