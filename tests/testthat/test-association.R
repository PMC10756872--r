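test_that("subgroup assignment groups multiplex families and pools singletons", {
  sg <- assignSubgroups(pedigree(taFixture()))
  expect_equal(length(unique(sg$subgroup_id)), 4)  # F1-F3 + sporadic pool
  expect_setequal(unique(sg$subgroup_id),
                  c("F1", "F2", "F3", "sporadic_pool"))
  expect_equal(sum(sg$kind == "multiplex"), 8)       # 2 + 3 + 3 members
  expect_equal(sum(sg$subgroup_id == "sporadic_pool"), 6)
  # multiplex members share one family
  for (f in c("F1", "F2", "F3"))
    expect_true(all(startsWith(sg$sample[sg$subgroup_id == f],
                               paste0(f, "_"))))
})

test_that("all-singleton cohorts pool into one subgroup and empty families warn", {
  ped <- generatePedigrees(cohortSpec(nMultiplex = 0, nSporadic = 4,
                                      seed = 1))
  sg <- assignSubgroups(ped)
  expect_equal(unique(sg$subgroup_id), "sporadic_pool")
  ped2 <- rbind(ped, data.frame(family = "FAMX", id = "I-1",
                                father = NA, mother = NA, sex = 1,
                                affected = FALSE, sequenced = FALSE,
                                sample = "FAMX_I-1"))
  expect_warning(assignSubgroups(ped2), "FAMX")
  # one family with 3 affected forms a single multiplex subgroup of 3
  ped3 <- generatePedigrees(cohortSpec(1, 0, membersPerFamily = c(6, 6),
                                       seed = 4))
  ped3$affected[ped3$family == "FAM1"][1:3] <- TRUE
  ped3$sequenced <- ped3$affected
  sg3 <- assignSubgroups(ped3)
  expect_equal(unique(sg3$kind), "multiplex")
  expect_gte(nrow(sg3), 3)
})

test_that("allele tables count two alleles per genotyped member", {
  coh <- taFixture()
  # MAST4 in F1: both members het
  tab <- alleleTable(coh, "5:65892764:C:CGCT", c("F1_II-2", "F1_III-2"))
  expect_equal(unname(tab),
               c(2L, 2L, 3L, 197L))
  # three members het/het/hom-alt
  tab <- alleleTable(coh, "4:111542154:G:A",
                     c("F7_II-1", "F4_II-1", "F8_II-3"))
  expect_equal(tab[["case_alt"]], 5L)
  expect_equal(tab[["case_ref"]], 1L)
  # missing genotypes contribute no alleles
  tab <- alleleTable(coh, "5:65892764:C:CGCT", c("F1_II-2", "F1_I-2"))
  expect_equal(tab[["case_alt"]] + tab[["case_ref"]], 2L)
  expect_error(alleleTable(taFixture(), "1:1:A:T", "F1_II-2"), "unknown")
})

test_that("Fisher exact p matches enumeration, fisher.test and conventions", {
  # degenerate margins
  expect_equal(fisherExactTwoSided(0, 6, 0, 200), 1)
  expect_equal(fisherExactTwoSided(1, 1, 100, 100), 1)
  # oracle agreement on the planted-variant table and random tables
  expect_equal(fisherExactTwoSided(2, 2, 1, 199), fisherOracle(2, 2, 1, 199),
               tolerance = 1e-12)
  set.seed(7)
  for (i in 1:50) {
    t <- rpois(4, 6)
    expect_equal(fisherExactTwoSided(t[1], t[2], t[3], t[4]),
                 do.call(fisherOracle, as.list(t)), tolerance = 1e-12)
    m <- matrix(t, 2, byrow = TRUE)
    if (sum(t) > 0)
      expect_equal(fisherExactTwoSided(t[1], t[2], t[3], t[4]),
                   stats::fisher.test(m)$p.value, tolerance = 1e-9)
  }
})

test_that("Fisher p is invariant under simultaneous row and column swaps", {
  set.seed(11)
  for (i in 1:30) {
    t <- rpois(4, 5)
    p <- fisherExactTwoSided(t[1], t[2], t[3], t[4])
    expect_equal(fisherExactTwoSided(t[3], t[4], t[1], t[2]), p)  # rows
    expect_equal(fisherExactTwoSided(t[2], t[1], t[4], t[3]), p)  # cols
  }
})

test_that("odds ratios follow the cross-product and Haldane-Anscombe rules", {
  expect_equal(oddsRatio(1, 1, 1, 1), 1)
  expect_equal(oddsRatio(3, 25, 1, 199), 3 * 199 / 25, tolerance = 1e-12)
  expect_equal(round(oddsRatio(3, 25, 1, 199), 2), 23.88)
  # zero cell: all cells + 0.5
  expect_equal(oddsRatio(2, 0, 1, 199), 2.5 * 199.5 / (0.5 * 1.5))
  # adding case alt alleles never decreases OR
  or <- vapply(0:10, function(a) oddsRatio(a, 10, 5, 195), numeric(1))
  expect_true(all(diff(or) >= 0))
})

test_that("association screen passes exactly p < alpha & OR > 1, any subgroup", {
  coh <- taFixture(decoysPerGate = 2)
  assoc <- associationFilter(coh)
  r <- assoc$results
  expect_equal(r$passes, r$p_value < 0.05 & r$odds_ratio > 1)
  for (k in names(assoc$pass))
    expect_equal(unname(assoc$pass[k]), any(r$passes[r$key == k]))
  # all five printed candidates pass; association decoys fail
  v <- variants(coh)
  expect_true(all(assoc$pass[rownames(v)[is.na(v$fails_gate)]]))
  expect_false(any(assoc$pass[rownames(v)[!is.na(v$fails_gate) &
                                            v$fails_gate == "association"]]))
  # planted dominant construction: 2 het carriers of 2 vs AC 1/200
  expect_lt(fisherExactTwoSided(2, 2, 1, 199), 0.05)
  expect_gt(oddsRatio(2, 2, 1, 199), 1)
  expect_error(associationFilter(taFixture(), alpha = 0), "alpha")
})

test_that("a variant absent from every control table errors by name", {
  coh <- taFixture()
  coh@controls <- controls(coh)[-1, ]
  expect_error(associationFilter(coh), "5:65892764:C:CGCT")
})
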