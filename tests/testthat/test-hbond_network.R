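# frame with one serine hydroxyl donating to a water oxygen at chosen
# geometry: d = H...A distance, dev = deviation from linearity in degrees
triplet_frame <- function(d, dev = 0) {
  topo <- atom_topology(c("OG", "HG", "O"), c("SER", "SER", "HOH"),
                        c(1L, 1L, 2L))
  theta <- dev * pi / 180
  xyz <- rbind(c(0, 0, 0),
               c(1, 0, 0),
               c(1, 0, 0) + d * c(cos(theta), sin(theta), 0))
  md_frame(topo, xyz)
}

test_that("detection honours inclusive distance and angle cutoffs", {
  crit <- hbond_criteria()
  expect_equal(nrow(detect_hbonds(triplet_frame(1.8, 0), criteria = crit)), 1)
  expect_equal(nrow(detect_hbonds(triplet_frame(2.70, 0), criteria = crit)), 1)
  expect_equal(nrow(detect_hbonds(triplet_frame(2.71, 0), criteria = crit)), 0)
  expect_equal(nrow(detect_hbonds(triplet_frame(1.8, 30), criteria = crit)), 1)
  expect_equal(nrow(detect_hbonds(triplet_frame(1.8, 31), criteria = crit)), 0)
  ev <- detect_hbonds(triplet_frame(1.8, 12), criteria = crit)
  expect_equal(ev$d_HA, 1.8, tolerance = 1e-12)
  expect_equal(ev$angle_DHA, 12, tolerance = 1e-9)
})

test_that("a hydrogen without its registered parent donor is an error", {
  topo <- atom_topology(c("HG", "O"), c("SER", "HOH"), c(1L, 2L))
  fr <- md_frame(topo, rbind(c(0, 0, 0), c(1.8, 0, 0)))
  expect_error(detect_hbonds(fr), "parent donor")
})

test_that("detection equals the all-pairs brute-force oracle on random frames", {
  reg <- default_registry()
  crit <- hbond_criteria()
  for (s in 1:100) {
    fr <- random_polar_frame(n = 50, seed = s)
    expect_events_equal_oracle(fr, reg, crit)
  }
})

test_that("empirical bond energy matches its closed form and is monotone", {
  expect_equal(espinosa_energy(1.8), -25300 * exp(-3.6 * 1.8),
               tolerance = 1e-12)
  expect_equal(espinosa_energy(1.8), -38.79, tolerance = 1e-3)
  expect_equal(espinosa_energy(2.0), -18.89, tolerance = 1e-3)
  d <- seq(0.8, 4.0, by = 0.01)
  e <- espinosa_energy(d)
  expect_true(all(e < 0))
  expect_true(all(diff(e) > 0)) # strictly increasing toward zero
  expect_error(espinosa_energy(0), "positive")
  # constants are configurable
  expect_equal(espinosa_energy(1, const = espinosa_constants(100, 1)),
               -100 * exp(-1))
})

test_that("network energy is additive, order-invariant and zero when empty", {
  ev <- detect_hbonds(triplet_frame(1.8))
  expect_equal(network_energy(ev[0, ]), 0)
  two <- rbind(ev, ev)
  expect_equal(network_energy(two), 2 * espinosa_energy(1.8))
  expect_equal(network_energy(two[2:1, ]), network_energy(two))
})

test_that("energy can be computed on the donor-acceptor distance instead", {
  fr <- triplet_frame(1.8, 0) # collinear: D-A distance is 2.8
  ha <- detect_hbonds(fr, energy_distance = "H-A")
  da <- detect_hbonds(fr, energy_distance = "D-A")
  expect_equal(ha$energy, espinosa_energy(1.8))
  expect_equal(da$energy, espinosa_energy(2.8))
})

test_that("detection statistics are invariant under rigid motion and monotone in d_max", {
  gen <- gen_ensemble(
    hbonds = list(plant_hbond(201L, 301L, p = 0.6, d_mean = 2.0, d_sd = 0.2),
                  plant_hbond(202L, 302L, p = 1.0)),
    n_runs = 2, frames_per_run = 10, seed = 11
  )
  stats <- ensemble_hbond_stats(gen$ensemble)
  moved <- transform_ensemble(gen$ensemble, random_rigid_motion(3))
  stats2 <- ensemble_hbond_stats(moved)
  expect_equal(stats2$count$mean, stats$count$mean)
  expect_equal(stats2$energy$mean, stats$energy$mean, tolerance = 1e-8)
  tight <- ensemble_hbond_stats(gen$ensemble,
                                criteria = hbond_criteria(d_max = 1.9))
  expect_lte(tight$count$mean, stats$count$mean)
  expect_lte(stats$energy$mean, 0)
})

test_that("planted per-frame bonds are counted exactly and cross-subset analysis works", {
  gen <- gen_ensemble(hbonds = lapply(1:9, function(i)
    plant_hbond(200L + i, 300L + i, p = 1)),
    n_runs = 3, frames_per_run = 5, seed = 5)
  stats <- ensemble_hbond_stats(gen$ensemble)
  expect_equal(stats$count$mean, 9)
  expect_equal(stats$count$sd, 0)
  # restricting the acceptor side to a subset counts only those bonds
  sub <- ensemble_hbond_stats(
    gen$ensemble,
    set_a = selection("donors", residue_ids = 201:209),
    set_b = selection("three", residue_ids = c(301L, 302L, 303L)))
  expect_equal(sub$count$mean, 3)
})

test_that("cross-boundary analysis counts only bonds spanning the two sets", {
  # donor residues 201/202 donate to acceptors 301/302; grouping each donor
  # with its own acceptor keeps nothing (no bond crosses the boundary),
  # while {201, 202} vs {301, 302} keeps both
  gen <- gen_ensemble(hbonds = list(plant_hbond(201L, 301L, p = 1),
                                    plant_hbond(202L, 302L, p = 1)),
                      n_runs = 1, frames_per_run = 3, seed = 2)
  same_side <- ensemble_hbond_stats(
    gen$ensemble,
    set_a = selection("a", residue_ids = c(201L, 301L)),
    set_b = selection("b", residue_ids = c(202L, 302L)))
  expect_equal(same_side$count$mean, 0)
  cross <- ensemble_hbond_stats(
    gen$ensemble,
    set_a = selection("a", residue_ids = c(201L, 202L)),
    set_b = selection("b", residue_ids = c(301L, 302L)))
  expect_equal(cross$count$mean, 2)
})
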