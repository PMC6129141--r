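---
title: "Methods: binding-site analysis of ATP-sensor ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: binding-site analysis of ATP-sensor ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atpsense)
```

# Scope and data model

atpsense analyses conformational ensembles of the bacterial ATP-synthase
ε subunit (and similar nucleotide-binding proteins). An *ensemble* is a set
of replicate runs, each an ordered series of frames over one fixed topology
— the desk-scale stand-in for a set of MD trajectories. Frames carry no
physical time axis; they are treated as samples from the conformational
distribution, and nothing in the package assumes a frame spacing. The
consequences are deliberate:

* **Equilibration is a frame fraction.** Trajectory practice discards the
  first nanoseconds of each run; with no timestamps the package discards
  the leading `floor(f * m)` frames of every run (`f` =
  `equilibration_fraction`, `m` = frames in the run). A user who knows
  "10 ns of 150 ns" supplies `f = 1/15`.
* **Replicate statistics are run-level.** Every ensemble statistic is the
  mean of per-run means, with the *sample* (n − 1) standard deviation of
  the run means as spread; with one run the SD is defined as 0. The n − 1
  choice is a convention fixed here once — with three runs either estimator
  is defensible, and the sample SD is the one a replicate-based error bar
  normally means.
* **No periodic imaging.** Frames are whole-molecule coordinates; minimum-
  image corrections belong upstream in trajectory post-processing.

Multi-model PDB is the only ensemble format (one file per replicate run,
`MODEL`/`ENDMDL` delimited). It is text, diff-able, and sufficient for
geometric analysis; binary trajectory formats are out of scope. ATP, Mg²⁺
and waters travel as HETATM records with residue names `ATP`, `MG`, `HOH`;
phosphate oxygens use the PDB chemical-component names `O1A…O3G`, with the
α/β/γ sets remappable in configuration for force fields that name them
differently.

# Hydrogen bonds

A bond is recorded for a (hydrogen, acceptor) pair when

* the H···acceptor distance is ≤ `d_max` (default 2.7 Å, inclusive), and
* the deviation from donor–H–acceptor linearity is ≤ `angle_max`
  (default 30°, inclusive).

Donor/acceptor chemistry is declared in a registry (per residue name: donor
heavy atom + attached hydrogen; acceptor atoms), because the artifact has no
force field to infer it from. The default registry covers backbone amides,
the polar side chains of the ε-subunit binding site, water, and the ATP
phosphate/ribose/adenine acceptors.

Two conventions required a decision:

* **Angle convention.** "Angle between donor, hydrogen and acceptor" can be
  read as the interior D–Ĥ–A angle (180° when linear) or as the deviation
  from linearity (0° when linear). The package implements
  deviation-from-linearity ≤ 30°, the standard in trajectory analysis
  tools; the criterion object is a plain pair of numbers, so the interior
  convention can be expressed as `angle_max = 180 - x` by a user who needs
  it.
* **Energy distance.** The empirical bond energy
  `E(d) = -A * exp(-B * d)` (defaults A = 25300 kJ/mol, B = 3.6 Å⁻¹, both
  configurable) is evaluated on the H···acceptor distance, consistent with
  the relation's origin in H···O distances; a config switch
  (`energy_distance = "D-A"`) evaluates it on the donor–acceptor distance
  instead for sensitivity checks. The energy is negative and strictly
  increasing towards zero in distance, so shorter bonds dominate the
  network sum.

Interface statistics (e.g. protein ↔ ATP) merge bonds donated in either
direction and de-duplicate on the (hydrogen, acceptor) pair. The
second-helix analysis is the same operation with the helix residue range
(112–133) on one side and the remaining protein residues on the other, so
only bonds crossing that boundary are counted.

# Repulsive contacts and Mg²⁺ coordination

Positively charged moieties — the guanidinium nitrogens NE/NH1/NH2 of the
six binding-site arginines, and Mg²⁺ — are in *repulsive contact* when the
minimum inter-atom distance between two moieties is ≤ 4.5 Å. Counting is at
the **pair level**: two arginines touching through several atom pairs count
once. Published contact counts of order one to two per frame are consistent
with pair-level counting, and the per-frame table still exposes the
atom-pair count for transparency. Mutated arginines simply resolve to no
atoms in an alanine-mutant topology, so their pairs contribute nothing —
mutants are represented by topology, never by flags.

Mg²⁺ coordination is classified per frame:

* `FIRST_SPHERE_OA_OB` — at least one α **and** one β phosphate oxygen
  within the first-sphere cutoff (default 2.6 Å); `FIRST_SPHERE_OB_OG`
  symmetrically for β+γ; `FIRST_SPHERE_OTHER` for any other direct-ligation
  pattern (single-oxygen, α+γ, tridentate).
* `SECOND_SPHERE` — no phosphate oxygen in the first sphere, but a water
  oxygen within the first-sphere cutoff of the ion and within the
  water-bridge cutoff (default 3.5 Å) of some phosphate oxygen.
* `UNBOUND` otherwise.

The 2.6 Å and 3.5 Å defaults are standard Mg–O coordination geometry, not
measurements from any particular study; both are configurable. Occupancies
are fractions of post-discard frames pooled over runs and always form a
probability distribution.

# Geometry

The helix–helix centre-of-mass distance uses **unit masses by default** —
the mass convention is a choice, not a measurement, and unit masses make
the metric a pure geometry statement; element masses are available. The
package deliberately ships **no default helix residue ranges**: the
C-terminal domain bounds (residues 112–133) are well defined, but the split
between "the two α-helices" is not, so the two ranges must be supplied in
configuration and the documented example splits 112–133 at a user-chosen
point. Refusing to invent an unstated range silently is the design choice.

Superposition RMSD uses the Kabsch algorithm: centre both selections,
take the SVD of the cross-covariance, and flip the smallest singular
direction if the best orthogonal map would be a reflection, so the rotation
is always proper (det = +1). Degenerate (collinear) configurations follow
base R's SVD sign convention. Congruent inputs give RMSD 0 to ≈ 1e-15;
tests assert 1e-6.

# Thermodynamic-integration curves

The TI module analyses *tables* — λ grids with window means of ∂H/∂λ — and
never runs alchemical simulations. Integration is trapezoidal over the
tabulated range with no endpoint extrapolation; composite Simpson is
available for smooth integrands. The forward/backward combination reports
their mean, the two-point sample SD (|forward − backward| / √2, the n − 1
estimator for n = 2, matching a "standard deviation of the forward and
backward calculations") and the hysteresis as a convergence diagnostic.
Pairwise placement comparisons propagate errors in quadrature and declare a
tie when the top two placements are inseparable within the combined error.
Any per-window equilibration discard happens upstream by whatever produced
the table; the reader records the declared fraction as metadata only. A
manual additive correction term (default 0) is exposed for restraint-release
contributions computed elsewhere.

# Sequence scan

Redundancy filtering is greedy first-come clustering: scanning in file
order, a sequence is kept only when its identity to every already-kept
sequence is **below** the threshold (default 0.95). Identity is matches
over mutually non-gap columns (alignment-length denominator available).
Greedy first-come is deterministic, idempotent, and keeps the first
representative of each cluster.

Column mapping ties alignment columns to PS3 residue numbering through the
reference row: the k-th non-gap reference column is residue k (+ optional
offset). Profiles then read the residues at positions 83, 92, 99, 103, 115,
122, 126 and apply ordinal rules: a substitution at 103 or 115 with the
ligand-binding set (E83/R92/R99/R122/R126) intact suggests
*increased-affinity* (by analogy with the alanine mutants, which enhance
the hydrogen-bond network); a 103/115 substitution co-occurring with a
binding-set substitution is *indeterminate* (the binding-set change may
dominate); everything else is *baseline*. A gap at a scored position counts
as a substitution and flags the profile as confounded. Histidine at 103
keeps the increased-affinity label but carries a caveat string — its
imidazole is titratable near neutral pH, so the effect may be pH-dependent.
Reported substitutions at 103 in related organisms include both leucine and
isoleucine readings for the same species; the fixture generator plants one
consistently and the discrepancy is a documentation note, not something the
code resolves.

# Affinity ranking

The comparative verdict is deliberately **ordinal**. Variants are ordered
by mean hydrogen-bond network energy (most negative first). Against the
reference variant, the class *higher-than-reference* requires both a more
favourable network energy **and** fewer repulsive contacts, each separated
beyond the combined SD (quadrature sum of the two run-level SDs); *lower*
symmetrically; *similar* otherwise. The combined-SD gate is a heuristic
significance filter, not a statistical test — with n = 3 runs a formal test
would be theatre. Experimental dissociation constants (4.3 µM wild type,
52 nM double mutant) can be attached as pass-through metadata for the
report, but no energy→Kd mapping exists in the package: the literature
provides none, and inventing one would overstate what ensemble enthalpies
can say. The helix hydrogen-bond network and the helix centre-of-mass
distance are reported alongside but never used in ranking — whether they
stabilise the bound state is an open experimental question.

# Synthetic data: what it does and does not emulate

The generator plants features with known ground truth:

* each planted hydrogen bond, contact or Mg²⁺ coordination state lives in
  its own spatial block on a coarse grid (25 Å spacing), so features cannot
  interfere;
* planted events satisfy their criterion with a safety margin (default
  0.1 Å / 5°) and non-events violate it by at least as much, so detector
  output is predictable from the truth alone and tests never sit on a
  floating-point knife edge;
* decoy atoms stay ≥ 8 Å from every planted atom;
* every feature draws from its own seeded stream, so adding a feature never
  shifts another feature's realisation;
* TI tables come from polynomial integrands with known analytic integrals,
  plus optional i.i.d. Gaussian window noise;
* alignment fixtures plant substitutions at named PS3 positions, gap-column
  insertions with known column shifts (four then three gap columns
  reproduce the 103→107 and 115→122 mapping), near-duplicates with exact
  mismatch counts for the redundancy filter, and ~20 background mutations
  per substitution row away from the scored positions — without that
  divergence a single-substitution homolog would be >95 % identical to the
  reference and be eaten by the very filter under test.

What passing these tests shows: the detectors implement their geometric
definitions exactly, statistics recover planted occupancies at binomial
accuracy, quadrature recovers known integrals, and the pipeline's inference
follows its stated rules. What it does **not** show: anything about real
MD ensembles — correlated frames, force-field physics, water structure,
conformational strain. Synthetic frames are i.i.d. by construction and
geometrically sparse; published trajectory statistics are not recomputable
from them and are used only as formatting/inference examples.

# Problem sizes and numerical choices

The validation suite uses sizes chosen to exercise the statistics while
staying interactive: oracle comparisons on 100 random 50-atom frames,
occupancy recovery on 3 × 200 frames, TI recovery on 85 windows with 100
seeded replicates, and a full pipeline run on 3 × 6-frame ensembles per
variant. Cutoff comparisons are inclusive (≤) everywhere; distances are
never computed below machine-zero (squared-distance matrices are clamped at
0 before the square root); the redundancy threshold uses strict < for
"kept", so a pair at exactly the threshold is filtered. Ties in the
affinity ranking preserve input order (stable sort).

# Known limitations

* No mmCIF or binary trajectory input; no bond perception from CONECT.
* Hydrogens must be present and named by convention — no placement of
  missing hydrogens.
* The hydrogen-bond energy relation is an empirical exponential in one
  distance; it ignores angular weakening and cooperativity.
* Coordination classification assumes exactly one Mg²⁺ of interest per
  frame (selectable when several ions are present).
* The affinity verdict is ordinal and relative to the chosen reference; it
  does not predict measurable constants.
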