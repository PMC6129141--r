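two_group_frame <- function(xyz_a, xyz_b) {
  na <- nrow(xyz_a); nb <- nrow(xyz_b)
  topo <- atom_topology(rep("CA", na + nb), "ALA",
                        c(seq_len(na), 100L + seq_len(nb)))
  md_frame(topo, rbind(xyz_a, xyz_b))
}

test_that("centre-of-mass distance does centroid arithmetic and rejects overlap", {
  fr <- two_group_frame(rbind(c(0, 0, 0)), rbind(c(3, 4, 0)))
  a <- selection("a", residue_ids = 1L)
  b <- selection("b", residue_ids = 101L)
  expect_equal(com_distance(fr, a, b), 5)
  fr2 <- two_group_frame(rbind(c(0, 0, 0), c(2, 0, 0)),
                         rbind(c(10, 0, 0), c(12, 0, 0)))
  expect_equal(com_distance(fr2, selection("a", residue_ids = 1:2),
                            selection("b", residue_ids = 101:102)), 10)
  expect_error(com_distance(fr, a, a), "overlap")
  expect_error(com_distance(fr, selection("x", residue_ids = 999L), b),
               "no atoms")
})

test_that("centre-of-mass distance is invariant under rigid motion and supports element masses", {
  set.seed(4)
  xyz_a <- matrix(rnorm(9), 3)
  xyz_b <- matrix(rnorm(9, 5), 3)
  topo <- atom_topology(c("N", "CA", "O", "N", "CA", "O"), "GLY",
                        c(1L, 1L, 1L, 2L, 2L, 2L))
  fr <- md_frame(topo, rbind(xyz_a, xyz_b))
  a <- selection("a", residue_ids = 1L); b <- selection("b", residue_ids = 2L)
  d0 <- com_distance(fr, a, b)
  motion <- random_rigid_motion(5)
  fr2 <- md_frame(topo, apply_rigid(fr$xyz, motion))
  expect_equal(com_distance(fr2, a, b), d0, tolerance = 1e-10)
  # element masses shift the centroid unless the composition is symmetric
  d_elem <- com_distance(fr, a, b, mass = "element")
  expect_true(is.finite(d_elem))
  # direct hand computation with N/C/O masses
  w <- c(14.007, 12.011, 15.999)
  com_a <- colSums(xyz_a * w) / sum(w)
  com_b <- colSums(xyz_b * w) / sum(w)
  expect_equal(d_elem, sqrt(sum((com_a - com_b)^2)))
})

test_that("superposition RMSD is zero for rigid copies and matches the 1-D closed form", {
  set.seed(10)
  A <- matrix(rnorm(30), 10)
  expect_equal(superpose_rmsd(A, A), 0, tolerance = 1e-6)
  motion <- random_rigid_motion(11)
  expect_equal(superpose_rmsd(A, apply_rigid(A, motion)), 0, tolerance = 1e-6)
  # two atoms {(0,0,0),(1,0,0)} vs {(0,0,0),(3,0,0)}: centred configs
  # (-0.5, 0.5) vs (-1.5, 1.5), optimal alignment leaves residuals 1 and 1
  A2 <- rbind(c(0, 0, 0), c(1, 0, 0))
  B2 <- rbind(c(0, 0, 0), c(3, 0, 0))
  expect_equal(superpose_rmsd(A2, B2), 1.0, tolerance = 1e-9)
  expect_equal(superpose_rmsd(B2, A2), superpose_rmsd(A2, B2))
  expect_error(superpose_rmsd(A, A[1:5, ]), "atom counts")
})

test_that("superposition matches bio3d's fitting as an independent oracle", {
  set.seed(12)
  A <- matrix(rnorm(45), 15)
  B <- A + matrix(rnorm(45, 0, 0.4), 15)
  got <- superpose_rmsd(A, B)
  fitted <- suppressWarnings( # bio3d notes it defaults to all positions
    bio3d::fit.xyz(fixed = as.numeric(t(A)), mobile = as.numeric(t(B))))
  want <- sqrt(mean(rowSums((matrix(fitted, ncol = 3, byrow = TRUE) - A)^2)))
  expect_equal(got, want, tolerance = 1e-6)
})

test_that("the optimal rotation is proper even for mirror-image inputs", {
  set.seed(13)
  A <- matrix(rnorm(24), 8)
  B <- A %*% diag(c(-1, 1, 1)) # reflected copy
  # a reflection is not a rigid motion: RMSD must stay positive
  expect_gt(superpose_rmsd(A, B), 1e-3)
})

test_that("interaction distance series tracks planted geometry with histogram conservation", {
  gen <- gen_ensemble(hbonds = list(plant_hbond(201L, 301L, p = 1,
                                                d_mean = 2.0, d_sd = 0.15)),
                      n_runs = 3, frames_per_run = 30, seed = 21,
                      equilibration_fraction = 0.2)
  res <- interaction_distance_series(
    gen$ensemble,
    selection("H", residue_ids = 201L, atom_names = "HG"),
    selection("A", residue_ids = 301L, atom_names = "O"),
    reference = 2.0)
  n_analysis <- sum(analysis_frames(gen$ensemble))
  expect_equal(sum(res$histogram$count), n_analysis)
  expect_length(unlist(res$series), n_analysis)
  expect_lt(abs(res$mean_deviation), 0.2)
  # constant series vs matching reference: zero deviation
  topo <- atom_topology(c("CA", "CA"), "ALA", c(1L, 2L))
  ens <- md_ensemble(topo, list(replicate(4, rbind(c(0, 0, 0), c(2.8, 0, 0)),
                                          simplify = FALSE)))
  cs <- interaction_distance_series(ens, selection("a", residue_ids = 1L),
                                    selection("b", residue_ids = 2L),
                                    reference = 2.8)
  expect_equal(cs$mean_deviation, 0)
  expect_equal(cs$mean, 2.8)
})

test_that("min-distance mode takes the per-frame minimum over a multi-atom group", {
  topo <- atom_topology(c("NH1", "NH2", "O"), c("ARG", "ARG", "HOH"),
                        c(122L, 122L, 400L))
  xyz <- rbind(c(0, 0, 0), c(5, 0, 0), c(3, 0, 0))
  ens <- md_ensemble(topo, list(list(xyz)))
  res <- interaction_distance_series(
    ens, selection("NHx", residue_ids = 122L, atom_names = c("NH1", "NH2")),
    selection("O", residue_ids = 400L), mode = "min")
  expect_equal(res$mean, 2) # min(3, 2)
  expect_error(interaction_distance_series(
    ens, selection("NHx", residue_ids = 122L, atom_names = c("NH1", "NH2")),
    selection("O", residue_ids = 400L), mode = "single"), "exactly one")
})
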