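# Example pipeline configuration.
#
# The ensemble and table paths below refer to the files written by
#   atpsense simulate --seed 42 --out <dir>
# run in the same directory as this config.  Relative paths resolve
# against the config file's own directory.

equilibration_fraction: 0.0667   # e.g. 10 ns of 150 ns

criteria:
  d_max: 2.7        # H...acceptor cutoff, Angstrom (inclusive)
  angle_max: 30     # deviation from linearity, degrees (inclusive)

espinosa:
  A: 25300          # kJ/mol
  B: 3.6            # 1/Angstrom
energy_distance: H-A  # or D-A

contacts:
  cutoff: 4.5       # Angstrom, pair-level counting

coordination:
  first_sphere: 2.6 # Mg-O direct ligation, Angstrom
  water_bridge: 3.5 # water-O to phosphate-O, Angstrom

# The C-terminal domain spans residues 112-133; the split between the two
# helices must be chosen by the user (no silent default).
helix:
  helix_a: [112, 125]
  helix_b: [126, 133]

variants:
  - label: WT
    coordination: Oa/Ob
    paths: [synthetic_run1.pdb, synthetic_run2.pdb, synthetic_run3.pdb]

ti:
  - label: site Oa/Ob
    forward: ti_forward.dat
    backward: ti_backward.dat

alignment:
  path: alignment.fasta
  format: fasta
  reference_id: PS3
  threshold: 0.95

reference_label: WT
reference_kd:
  WT: "4.3 uM"
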