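# atpsense

Analysis toolkit for structural ensembles of the bacterial F₁Fₒ-ATP-synthase
**ε subunit**, the small regulatory protein whose C-terminal two-helix domain
acts as a cellular ATP sensor. When ATP (with its Mg²⁺ counter-ion) binds,
the domain folds into a contracted, non-inhibitory "down" state; when ATP is
released the domain extends and inhibits ATP hydrolysis. Variants of the
thermophilic *Bacillus* PS3 ε subunit — notably alanine substitutions of the
non-ligand-binding arginines R103 and R115 — shift the ATP affinity by orders
of magnitude, and the structural signature of that shift is visible in
ensemble geometry: the hydrogen-bond network with the nucleotide, repulsive
crowding of positively charged groups in the binding site, and the Mg²⁺
coordination mode.

The package is written for structural bioinformaticians and simulation
scientists who have conformational ensembles (multi-model PDB files standing
in for MD trajectory frames, in replicate runs) and want the quantitative
binding-site readout:

* **Hydrogen-bond analysis** — geometric detection with inclusive cutoffs
  *d*(H···A) ≤ 2.7 Å and deviation-from-linearity ≤ 30°, and an empirical
  per-bond energy from the H···acceptor distance,
  *E*(d) = −A·e^(−B·d) with A = 25 300 kJ/mol, B = 3.6 Å⁻¹
  (the exponential distance–energy relation of Espinosa-type topological
  analyses); network energy is the sum over detected bonds.
* **Repulsive electrostatic contacts** — pair-level co-location (minimum
  inter-atom distance ≤ 4.5 Å) of arginine guanidinium groups
  (R92/R99/R103/R115/R122/R126) and the Mg²⁺ ion.
* **Mg²⁺–ATP coordination classification** — first-sphere states by direct
  ligation of α/β- or β/γ-phosphate oxygens (≤ 2.6 Å), second-sphere via a
  bridging water (water-O ≤ 2.6 Å of Mg²⁺ and ≤ 3.5 Å of a phosphate
  oxygen), otherwise unbound; occupancies over post-equilibration frames.
* **Geometry metrics** — helix–helix centre-of-mass distance, per-interaction
  distance series against crystal reference distances, and Kabsch
  least-squares superposition RMSD (proper rotations only).
* **Thermodynamic-integration curve analysis** — trapezoidal integration of
  ⟨∂H/∂λ⟩ window tables, forward/backward combination with the two-point SD
  and hysteresis diagnostic, and pairwise comparison of ion placements.
* **Sequence conservation scan** — greedy redundancy filtering of an ε-subunit
  alignment (95 % identity threshold), mapping of alignment columns to PS3
  residue numbering, and per-sequence affinity hypotheses from the
  substitution pattern at positions 103/115 versus the ligand-binding set
  (E83, R92, R99, R122, R126).
* **Comparative affinity ranking** — variants ordered by hydrogen-bond
  network energy; a variant is classed *higher-than-reference* only when
  both its network energy is more favourable **and** its repulsive-contact
  count is lower, each beyond the combined replicate SD. The verdict is
  strictly ordinal — no dissociation constant is ever computed.

Replicate statistics throughout follow the triplicate-run convention: the
reported mean is the mean of per-run means (after discarding a configurable
leading fraction of frames as equilibration) and the spread is the sample SD
of the run means.

A synthetic-ensemble generator (`gen_ensemble`, `gen_ti_tables`,
`gen_alignment`) plants hydrogen bonds, contacts, coordination states, TI
integrands and alignment substitutions with known ground truth, and backs
the package's property-based validation.

## Worked example

Generate a wild-type-like ensemble with planted interactions, analyse it,
and rank a mutant-like ensemble against it:

```r
library(atpsense)

gen <- gen_ensemble(
  hbonds   = list(plant_hbond(201, 301, p = 0.7, d_mean = 2.0, d_sd = 0.15),
                  plant_hbond(202, 302, p = 1.0, d_mean = 1.9, d_sd = 0.10)),
  contacts = list(plant_contact(92, 122, p = 0.4)),
  mg_states = "FIRST_SPHERE_OA_OB",
  n_runs = 3, frames_per_run = 100, seed = 42, label = "WT")

hb <- ensemble_hbond_stats(gen$ensemble)
ct <- ensemble_contact_stats(gen$ensemble)
cat("h-bonds:",  format_stat(hb$count), "\n")
cat("E_HB   :",  format_stat(hb$energy), "kJ/mol\n")
cat("contacts:", format_stat(ct$count), "\n")
```

```
h-bonds: 1.68 ± 0.04
E_HB   : -43.59 ± 1.15 kJ/mol
contacts: 0.43 ± 0.05
```

The bond count recovers the planted occupancies (0.7 + 1.0), the network
energy is the summed per-bond exponential energies, and the contact count
recovers the planted Bernoulli rate 0.4 — each as mean ± SD over the three
replicate runs. Feeding two variants' statistics to the ranking stage:

```r
wt  <- variant_stats("WT", "Oa/Ob", hbond_count = hb$count,
                     hbond_energy = hb$energy, repulsive_contacts = ct$count)
# ... analyse the mutant ensemble the same way -> `mut` ...
rank_variants(list(wt, mut), "WT")
```

```
<affinity_verdict> ranking (most favourable first): R103A > WT
  R103A: higher-than-reference
  WT: reference
```

The mutant ranks above the wild type because its hydrogen-bond network
energy is more favourable and its repulsive contacts fewer, each beyond the
combined replicate SD — the same reasoning pattern that links an enhanced
binding-site network to an increased ATP affinity in the ε-subunit
literature.

For file-based workflows, `run_pipeline("config.yaml", "out/")` drives all
stages (hydrogen bonds → contacts → coordination → geometry → TI → report →
sequence scan) from a YAML configuration, writing per-frame and summary TSVs
plus Markdown/JSON reports; `inst/scripts/atpsense` exposes the same
functionality as a shell command with `run`, `simulate`, `ti` and `seqscan`
subcommands.

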