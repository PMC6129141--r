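# frame with arginine guanidinium groups / Mg2+ at controlled separations
contact_frame <- function(groups) {
  rows <- list(); xyz <- list()
  for (g in groups) {
    if (identical(g$type, "MG")) {
      rows[[length(rows) + 1L]] <- atom_topology("MG", "MG", g$resid,
                                                 element = "MG")
      xyz[[length(xyz) + 1L]] <- matrix(g$at, 1, 3)
    } else {
      rows[[length(rows) + 1L]] <- atom_topology(c("NE", "NH1", "NH2"),
                                                 "ARG", g$resid)
      xyz[[length(xyz) + 1L]] <-
        rbind(g$at, g$at + c(0.3, 0, 0), g$at + c(0, 0.3, 0))
    }
  }
  md_frame(do.call(rbind, rows), do.call(rbind, xyz))
}

test_that("contact counting is pair-level with an inclusive cutoff", {
  # Mg 4.4 A from R122's nearest nitrogen, everything else far
  fr <- contact_frame(list(
    list(type = "ARG", resid = 122L, at = c(0, 0, 0)),
    list(type = "ARG", resid = 92L, at = c(40, 40, 0)),
    list(type = "MG", resid = 151L, at = c(-4.4, 0, 0))))
  res <- count_repulsive_contacts(fr)
  expect_equal(res$count, 1)
  expect_setequal(c(res$pairs$group_a, res$pairs$group_b), c("R122", "MG"))
  # just outside
  fr2 <- contact_frame(list(
    list(type = "ARG", resid = 122L, at = c(0, 0, 0)),
    list(type = "MG", resid = 151L, at = c(-4.6, 0, 0))))
  expect_equal(count_repulsive_contacts(fr2)$count, 0)
  # two atom pairs within cutoff still count as one pair-level contact
  fr3 <- contact_frame(list(
    list(type = "ARG", resid = 92L, at = c(0, 0, 0)),
    list(type = "ARG", resid = 99L, at = c(3.0, 0, 0))))
  res3 <- count_repulsive_contacts(fr3)
  expect_equal(res3$count, 1)
  expect_gt(res3$pairs$n_atom_pairs, 1)
})

test_that("contacts equal the brute-force oracle and grow with the cutoff", {
  set.seed(42)
  for (rep in 1:20) {
    pos <- lapply(1:5, function(i) runif(3, 0, 10))
    fr <- contact_frame(list(
      list(type = "ARG", resid = 92L, at = pos[[1]]),
      list(type = "ARG", resid = 99L, at = pos[[2]]),
      list(type = "ARG", resid = 122L, at = pos[[3]]),
      list(type = "ARG", resid = 126L, at = pos[[4]]),
      list(type = "MG", resid = 151L, at = pos[[5]])))
    for (cutoff in c(3, 4.5, 6)) {
      spec <- contact_spec(cutoff = cutoff)
      expect_equal(count_repulsive_contacts(fr, spec)$count,
                   oracle_contacts(fr, spec$groups, cutoff))
    }
    counts <- vapply(c(2, 4, 6, 8), function(co)
      count_repulsive_contacts(fr, contact_spec(cutoff = co))$count,
      numeric(1))
    expect_true(all(diff(counts) >= 0))
  }
})

test_that("mutant ensembles lacking an arginine contribute no contacts for it", {
  # only R92 and Mg present: the R103 selection resolves empty
  fr <- contact_frame(list(
    list(type = "ARG", resid = 92L, at = c(0, 0, 0)),
    list(type = "MG", resid = 151L, at = c(3, 0, 0))))
  res <- count_repulsive_contacts(fr)
  expect_equal(res$count, 1)
  expect_false(any(grepl("R103", unlist(res$pairs[c("group_a", "group_b")]))))
  # fewer than two resolvable groups: warning and count 0
  fr2 <- contact_frame(list(list(type = "MG", resid = 151L, at = c(0, 0, 0))))
  expect_warning(res2 <- count_repulsive_contacts(fr2), "fewer than two")
  expect_equal(res2$count, 0)
})

test_that("ensemble contact statistics recover a planted Bernoulli occupancy", {
  gen <- gen_ensemble(contacts = list(plant_contact(92L, 122L, p = 0.5)),
                      n_runs = 3, frames_per_run = 200, seed = 42)
  stats <- ensemble_contact_stats(gen$ensemble)
  truth_mean <- mean(vapply(gen$truth, function(tr) mean(tr$contact_on),
                            numeric(1)))
  expect_equal(stats$count$mean, truth_mean) # detector matches ground truth
  se <- sqrt(0.5 * 0.5 / 600)
  expect_lt(abs(stats$count$mean - 0.5), 3 * se)
})

test_that("Mg coordination classification covers all states by construction", {
  mk <- function(state) {
    gen <- gen_ensemble(mg_states = state, n_runs = 1, frames_per_run = 1,
                        n_decoys = 0, seed = 1)
    classify_mg_coordination(get_frame(gen$ensemble, 1, 1))
  }
  for (state in c("FIRST_SPHERE_OA_OB", "FIRST_SPHERE_OB_OG",
                  "FIRST_SPHERE_OTHER", "SECOND_SPHERE", "UNBOUND"))
    expect_identical(mk(state), state)
})

test_that("coordination classification is rigid-motion invariant and errors without a unique ion", {
  gen <- gen_ensemble(mg_states = "SECOND_SPHERE", n_runs = 1,
                      frames_per_run = 1, n_decoys = 0, seed = 3)
  fr <- get_frame(gen$ensemble, 1, 1)
  motion <- random_rigid_motion(9)
  fr2 <- md_frame(fr$topology, apply_rigid(fr$xyz, motion))
  expect_identical(classify_mg_coordination(fr2), "SECOND_SPHERE")
  no_mg <- md_frame(fr$topology[fr$topology$residue_name != "MG", ],
                    fr$xyz[fr$topology$residue_name != "MG", , drop = FALSE])
  expect_error(classify_mg_coordination(no_mg), "exactly one")
})

test_that("coordination occupancy is a probability distribution matching the schedule", {
  gen <- gen_ensemble(mg_states = c("FIRST_SPHERE_OA_OB", "SECOND_SPHERE"),
                      n_runs = 2, frames_per_run = 10, n_decoys = 0, seed = 8)
  occ <- coordination_occupancy(gen$ensemble)
  expect_equal(sum(occ), 1)
  expect_equal(unname(occ["FIRST_SPHERE_OA_OB"]), 0.5)
  expect_equal(unname(occ["SECOND_SPHERE"]), 0.5)
  all_one <- gen_ensemble(mg_states = "FIRST_SPHERE_OA_OB", n_runs = 1,
                          frames_per_run = 4, n_decoys = 0, seed = 8)
  occ1 <- coordination_occupancy(all_one$ensemble)
  expect_equal(unname(occ1["FIRST_SPHERE_OA_OB"]), 1)
})
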