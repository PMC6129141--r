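# build a small but complete input set: two variants (wild-type-like and a
# mutant-like ensemble with stronger planted bonding and fewer contacts),
# TI tables and an alignment, plus the YAML config tying them together
build_pipeline_inputs <- function(dir, seed = 17) {
  wt <- gen_ensemble(
    hbonds = list(
      plant_hbond(10L, 401L, p = 1, d_mean = 2.2, d_sd = 0.05),
      plant_hbond(11L, 402L, p = 1, d_mean = 2.2, d_sd = 0.05)),
    contacts = list(plant_contact(92L, 122L, p = 1),
                    plant_contact(99L, "MG", p = 1)),
    mg_states = "FIRST_SPHERE_OA_OB",
    n_runs = 3, frames_per_run = 6, seed = seed, label = "WT")
  mut <- gen_ensemble(
    hbonds = list(
      plant_hbond(10L, 401L, p = 1, d_mean = 1.8, d_sd = 0.05),
      plant_hbond(11L, 402L, p = 1, d_mean = 1.8, d_sd = 0.05),
      plant_hbond(12L, 403L, p = 1, d_mean = 1.8, d_sd = 0.05)),
    contacts = list(plant_contact(92L, 122L, p = 0)),
    mg_states = "FIRST_SPHERE_OA_OB",
    n_runs = 3, frames_per_run = 6, seed = seed + 1, label = "R103A/R115A")
  # planted bonds donate from SER residues: rename acceptor waters to ATP
  # oxygens so the protein->ligand interface analysis sees them
  retag <- function(gen) {
    topo <- gen$ensemble$topology
    w <- topo$residue_id %in% 401:403 & topo$residue_name == "HOH"
    topo$residue_name[w] <- "ATP"
    topo$atom_name[w] <- c("O1A", "O2A", "O3A")[seq_len(sum(w))]
    md_ensemble(topo, gen$ensemble$runs, gen$ensemble$equilibration_fraction,
                gen$ensemble$label)
  }
  wt_paths <- write_ensemble(retag(wt), file.path(dir, "wt"))
  mut_paths <- write_ensemble(retag(mut), file.path(dir, "mut"))
  ti <- gen_ti_tables(c(0, 0, 3), noise_sd = 0, seed = seed)
  write_ti_table(ti$forward, file.path(dir, "ti_f.dat"))
  write_ti_table(ti$backward, file.path(dir, "ti_b.dat"))
  ti2 <- gen_ti_tables(c(2, 0, 3), noise_sd = 0, seed = seed)
  write_ti_table(ti2$forward, file.path(dir, "ti2_f.dat"))
  write_ti_table(ti2$backward, file.path(dir, "ti2_b.dat"))
  gen_alignment(seed = seed, path = file.path(dir, "aln.fasta"),
                substitutions = data.frame(id = "L103", position = 103L,
                                           residue = "L"))
  cfg <- list(
    equilibration_fraction = 0,
    variants = list(
      list(label = "WT", coordination = "Oa/Ob",
           paths = as.list(basename(wt_paths))),
      list(label = "R103A/R115A", coordination = "Oa/Ob",
           paths = as.list(basename(mut_paths)))
    ),
    ti = list(
      list(label = "site Oa/Ob", forward = "ti_f.dat", backward = "ti_b.dat"),
      list(label = "bulk", forward = "ti2_f.dat", backward = "ti2_b.dat")
    ),
    alignment = list(path = "aln.fasta", format = "fasta",
                     reference_id = "PS3", threshold = 0.95),
    reference_distances = list(
      list(name = "S10:HG-ATP:O1A", reference = 2.2,
           a = list(residue_id = 10L, atoms = "HG"),
           b = list(residue_id = 401L, atoms = "O1A"))),
    reference_label = "WT",
    reference_kd = list(WT = "4.3 uM", `R103A/R115A` = "52 nM")
  )
  cfg_path <- file.path(dir, "config.yaml")
  yaml::write_yaml(cfg, cfg_path)
  cfg_path
}
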