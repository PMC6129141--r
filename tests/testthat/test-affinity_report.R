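mk_stats <- function(label, coordination = "Oa/Ob",
                     hb = c(9, 0.5), e = c(-300, 5), ct = c(2, 0.5),
                     helix = NULL, com = NULL) {
  variant_stats(
    label, coordination,
    hbond_count = summary_stat(hb[1], hb[2], 3),
    hbond_energy = summary_stat(e[1], e[2], 3),
    repulsive_contacts = summary_stat(ct[1], ct[2], 3),
    helix_hbond_count = if (!is.null(helix)) summary_stat(helix[1], helix[2], 3),
    com_distance = if (!is.null(com)) summary_stat(com[1], com[2], 3)
  )
}

test_that("preferred coordination picks the more favourable energy with a tie rule", {
  a <- mk_stats("R103A", "Oa/Ob", e = c(-300, 5))
  b <- mk_stats("R103A", "Ob/Og", e = c(-250, 5))
  pick <- preferred_coordination(a, b)
  expect_identical(pick$tag, "Oa/Ob")
  tie <- preferred_coordination(mk_stats("X", "Oa/Ob", e = c(-300, 5)),
                                mk_stats("X", "Ob/Og", e = c(-298, 5)))
  expect_identical(tie$tag, "tie")
  expect_error(preferred_coordination(a, mk_stats("R115A", "Ob/Og")),
               "same variant")
})

test_that("coordination rationale records agreement with the free-energy verdict", {
  f <- ti_table(c(0, 1), c(-420, -420), "forward")
  b <- ti_table(c(0, 1), c(-420, -420), "backward")
  site <- combine_directions(f, b)
  bulk <- combine_directions(ti_table(c(0, 1), c(-400, -400), "forward"),
                             ti_table(c(0, 1), c(-400, -400), "backward"))
  comp <- compare_placements(list(`Oa/Ob` = site, `Ob/Og` = bulk))
  pick <- preferred_coordination(mk_stats("R103A", "Oa/Ob", e = c(-300, 5)),
                                 mk_stats("R103A", "Ob/Og", e = c(-250, 5)),
                                 ti_comparison = comp)
  expect_true(any(grepl("agreement", pick$rationale)))
})

test_that("table-style statistics rank the double mutant above wild type", {
  wt <- mk_stats("WT", hb = c(9.38, 0.48), e = c(-300, 5), ct = c(1.96, 0.51))
  dm <- mk_stats("R103A/R115A", hb = c(10.4, 0.60), e = c(-330, 5),
                 ct = c(1.08, 0.51))
  v <- rank_variants(list(wt, dm), "WT",
                     reference_kd = list(WT = "4.3 uM",
                                        `R103A/R115A` = "52 nM"))
  expect_identical(v$ranking[1], "R103A/R115A")
  expect_identical(unname(v$classes[["R103A/R115A"]]), "higher-than-reference")
  md <- render_report(v, "markdown")
  expect_true(grepl("9.38 ± 0.48", md, fixed = TRUE))
  expect_true(grepl("1.08 ± 0.51", md, fixed = TRUE))
})

test_that("class assignment needs BOTH criteria to separate beyond the combined SD", {
  wt <- mk_stats("WT", e = c(-300, 5), ct = c(2.0, 0.5))
  # energy separates, contacts do not
  only_e <- mk_stats("M1", e = c(-330, 5), ct = c(1.9, 0.5))
  v <- rank_variants(list(wt, only_e), "WT")
  expect_identical(unname(v$classes[["M1"]]), "similar")
  # both separate, in the unfavourable direction
  worse <- mk_stats("M2", e = c(-250, 5), ct = c(3.5, 0.5))
  v2 <- rank_variants(list(wt, worse), "WT")
  expect_identical(unname(v2$classes[["M2"]]), "lower")
  expect_identical(v2$ranking, c("WT", "M2"))
})

test_that("identical statistics give a stable order and the 'similar' class", {
  wt <- mk_stats("WT")
  twin <- mk_stats("TWIN")
  v <- rank_variants(list(wt, twin), "WT")
  expect_identical(v$ranking, c("WT", "TWIN")) # input order preserved on ties
  expect_identical(unname(v$classes[["TWIN"]]), "similar")
  expect_error(rank_variants(list(wt, wt), "WT"), "duplicate")
  expect_error(rank_variants(list(wt), "NOPE"), "not among")
})

test_that("three strictly ordered energies rank in energy order and permutation-invariantly", {
  s <- list(mk_stats("A", e = c(-200, 1)), mk_stats("B", e = c(-300, 1)),
            mk_stats("C", e = c(-250, 1)))
  v1 <- rank_variants(s, "A")
  expect_identical(v1$ranking, c("B", "C", "A"))
  v2 <- rank_variants(s[c(3, 1, 2)], "A")
  expect_identical(v2$ranking, v1$ranking)
  expect_identical(v2$classes[order(names(v2$classes))],
                   v1$classes[order(names(v1$classes))])
})

test_that("report rendering is deterministic and ordinal-only", {
  wt <- mk_stats("WT", helix = c(5.27, 0.20), com = c(8.7, 0.1))
  v <- rank_variants(list(wt), "WT")
  md1 <- render_report(v, "markdown")
  md2 <- render_report(v, "markdown")
  expect_identical(md1, md2)
  expect_false(grepl("Ranking", md1)) # single variant: no ranking section
  # ordinal verdict: no concentration units unless Kd metadata is passed
  expect_false(grepl("nM|uM|µM|mM", md1))
  tsv <- render_report(v, "tsv")
  expect_identical(tsv$label, "WT")
  expect_identical(tsv$com_distance_A, "8.70 ± 0.10")
  js <- render_report(v, "json")
  expect_identical(js, render_report(v, "json"))
  expect_true(jsonlite::validate(js))
})
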