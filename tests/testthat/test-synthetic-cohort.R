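test_that("cohort specs validate their domains", {
  expect_s4_class(cohortSpec(), "CohortSpec")
  expect_error(cohortSpec(nMultiplex = -1), "non-negative")
  expect_error(cohortSpec(controlN = 0), "controlN")
  expect_error(cohortSpec(controlAfRange = c(0.2, 0.8)), "0, 0.5")
  expect_error(cohortSpec(membersPerFamily = c(5, 3)), "ascending")
})

test_that("generated pedigrees have the study's family structure", {
  ped <- generatePedigrees(cohortSpec(seed = 3))
  expect_equal(length(unique(ped$family)), 9)
  affPerFam <- tapply(ped$affected & ped$sequenced, ped$family, sum)
  expect_true(all(affPerFam[sprintf("FAM%d", 1:3)] >= 2))
  expect_true(all(affPerFam[sprintf("FAM%d", 4:9)] == 1))
  # connected nuclear families: every child's parents exist in-family
  kids <- ped[!is.na(ped$father), ]
  expect_true(all(paste(kids$family, kids$father) %in%
                    paste(ped$family, ped$id)))
  # empty case and determinism
  expect_equal(nrow(generatePedigrees(cohortSpec(0, 0))), 0)
  expect_identical(generatePedigrees(cohortSpec(seed = 5)),
                   generatePedigrees(cohortSpec(seed = 5)))
})

test_that("allele transmission obeys the law of segregation", {
  ped <- bigNuclearPed(3)
  founders <- setNames(c(0L, 0L), ped$sample[1:2])
  dos <- transmitGenotypes(ped, 0.5, founderDosage = founders)
  expect_true(all(dos == 0))  # both parents hom-ref
  founders <- setNames(c(2L, 0L), ped$sample[1:2])
  dos <- transmitGenotypes(ped, 0.5, founderDosage = founders)
  expect_true(all(dos[-(1:2)] == 1))  # hom-alt x hom-ref forces het
  # het x het over 10,000 children: 1:2:1
  ped <- bigNuclearPed(10000)
  founders <- setNames(c(1L, 1L), ped$sample[1:2])
  set.seed(42)
  dos <- transmitGenotypes(ped, 0.5, founderDosage = founders)[-(1:2)]
  chi <- chisq.test(tabulate(dos + 1, 3), p = c(0.25, 0.5, 0.25))
  expect_gt(chi$p.value, 0.001)
})

test_that("cyclic pedigrees are rejected", {
  ped <- data.frame(family = "X", id = c("A", "B"),
                    father = c("B", "A"), mother = c("B", "A"),
                    sex = 1L, affected = FALSE, sequenced = TRUE)
  ped$sample <- paste(ped$family, ped$id, sep = "_")
  expect_error(transmitGenotypes(ped, 0.1), "cyclic")
})

test_that("planted variants respect their inheritance model", {
  ped <- generatePedigrees(cohortSpec(seed = 8))
  set.seed(8)
  dom <- plantCausal(ped, "dominant", "FAM1")
  aff <- ped$sample[ped$family == "FAM1" & ped$affected]
  expect_true(all(dom[aff] >= 1))
  rec <- plantCausal(ped, "recessive", "FAM5")
  case <- ped$sample[ped$family == "FAM5" & ped$affected]
  expect_true(all(rec[case] == 2))
  # model/family-type mismatch
  expect_error(plantCausal(ped, "dominant", "FAM5"), "multiplex")
  expect_error(plantCausal(ped, "recessive", "FAM1"), "sporadic")
})

test_that("full penetrance leaves no affected non-carriers in target families", {
  for (s in 1:100) {
    ped <- generatePedigrees(cohortSpec(seed = s))
    set.seed(s)
    dom <- plantCausal(ped, "dominant", c("FAM1", "FAM2"), penetrance = 1)
    aff <- ped$sample[ped$family %in% c("FAM1", "FAM2") & ped$affected]
    expect_true(all(dom[aff] >= 1))
    una <- ped$sample[ped$family %in% c("FAM1", "FAM2") & !ped$affected]
    expect_true(all(dom[una] == 0))
  }
})

test_that("control tables conserve allele number and match binomial draws", {
  spec <- cohortSpec(seed = 1)
  vt <- data.frame(chrom = "1", pos = 1:3, ref = "G", alt = "T",
                   control_af = c(0.25, 0, NA))
  set.seed(1)
  ctl <- generateControls(spec, vt)
  expect_true(all(ctl$an == 200))
  expect_true(all(ctl$ac >= 0 & ctl$ac <= ctl$an))
  expect_equal(ctl$ac[2], 0)  # af = 0 gives zero alt alleles
  # af = 0.25 over 100 controls: mean alt count across 500 draws near 50
  acs <- vapply(1:500, function(s) {
    set.seed(s)
    generateControls(spec, vt[1, ])$ac
  }, numeric(1))
  se <- sqrt(200 * 0.25 * 0.75) / sqrt(500)
  expect_lt(abs(mean(acs) - 50), 3 * se)
})

test_that("simulated cohorts are seed-deterministic and Mendelian-consistent", {
  a <- simulateCohort(cohortSpec(seed = 21))
  b <- simulateCohort(cohortSpec(seed = 21))
  expect_identical(variants(a), variants(b))
  expect_identical(genotypes(a), genotypes(b))
  expect_identical(controls(a), controls(b))
  expect_false(identical(genotypes(a),
                         genotypes(simulateCohort(cohortSpec(seed = 22)))))
  for (s in c(5, 17, 31))
    expect_true(isTRUE(mendelianConsistent(
      simulateCohort(cohortSpec(seed = s), maskUnsequenced = FALSE))))
  # masked cohort hides unsequenced relatives
  ped <- pedigree(a)
  expect_true(all(genotypes(a)[, ped$sample[!ped$sequenced]] == "./."))
})

test_that("the built-in fixture reproduces the published tables", {
  coh <- taFixture()
  ped <- pedigree(coh)
  expect_equal(sum(ped$affected & ped$sequenced), 14)
  expect_equal(length(unique(ped$family)), 9)
  v <- variants(coh)
  expect_equal(nrow(v), 5)
  expect_equal(length(unique(v$gene)), 5)
  expect_setequal(v$gene, c("MAST4", "ITGA6", "PITX2", "CACNA1S", "CDON"))
  # spot genotypes as printed
  g <- genotypes(coh)
  expect_equal(g["4:111542154:G:A", "F2_III-2"], "G/A")
  expect_equal(g["5:65892764:C:CGCT", "F1_II-2"], "C/CGCT")
  # printed annotations
  expect_equal(v["1:201016296:G:A", "maf_asn"], 0.041958)
  expect_equal(v["5:65892764:C:CGCT", "maf_asn"], 0.01434)
  expect_equal(v["5:65892764:C:CGCT", "loeuf"], 0.38)
  expect_equal(v["4:111542154:G:A", "impact"], "HIGH")
  expect_equal(v["11:125871715:G:A", "sift"], "T,D,T")
  # gene lists cover all candidates
  expect_true(all(v$gene %in% toupper(unlist(taGeneLists()))))
  expect_true(isTRUE(mendelianConsistent(coh)))
})

test_that("fixture decoys each fail exactly their named gate", {
  coh <- taFixture(decoysPerGate = 2)
  lists <- taGeneLists(decoysPerGate = 2)
  res <- runCascade(coh, lists, shortCircuit = FALSE)
  v <- variants(coh)
  dec <- v[!is.na(v$fails_gate), ]
  stageOf <- c(association = "association", impact = "impact",
               prediction_maf = "impact", ontology = "ontology",
               segregation = "segregation")
  for (k in rownames(dec)) {
    tr <- res$trace[res$trace$key == k, ]
    expect_equal(tr$decision[tr$stage == stageOf[dec[k, "fails_gate"]]],
                 "fail", info = k)
    expect_equal(sum(tr$decision == "fail"), 1, info = k)
  }
  expect_false(any(rownames(dec) %in% res$retained))
})

test_that("control alt counts never exceed allele number in simulations", {
  for (s in 1:10) {
    ctl <- controls(simulateCohort(cohortSpec(seed = s)))
    expect_true(all(ctl$ac <= ctl$an & ctl$ac >= 0))
  }
})
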