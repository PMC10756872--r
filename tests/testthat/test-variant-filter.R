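test_that("damaging-prediction aggregation spans transcripts and tools", {
  expect_true(damagingAny("D,D", "B"))        # SIFT damaging, PolyPhen benign
  expect_true(damagingAny("T,D,T", "P,P,P"))  # any transcript suffices
  expect_true(damagingAny("", "P"))           # possibly damaging counts
  expect_false(damagingAny("T,T", "B"))
  expect_false(damagingAny("", ""))
  expect_error(damagingAny("X", ""), "unknown SIFT")
  expect_error(damagingAny("", "Q"), "unknown PolyPhen")
})

test_that("impact gate passes HIGH, rescues MODERATE, fails LOW/MODIFIER", {
  hi <- list(impact = "HIGH", sift = "", polyphen = "", maf_asn = NA)
  expect_equal(impactGate(hi)$decision, "pass")
  # MODERATE rescued by rare Asian MAF with no predictions
  mast4 <- list(impact = "MODERATE", sift = "", polyphen = "",
                maf_asn = 0.01434)
  expect_equal(impactGate(mast4)$decision, "pass")
  # MODERATE rescued by a damaging call despite no MAF
  dmg <- list(impact = "MODERATE", sift = "D,T", polyphen = "",
              maf_asn = NA)
  expect_equal(impactGate(dmg)$decision, "pass")
  # both rescue routes closed
  tol <- list(impact = "MODERATE", sift = "T,T", polyphen = "B",
              maf_asn = 0.30)
  expect_equal(impactGate(tol)$decision, "fail")
  # boundary is strict: MAF exactly at the threshold fails
  expect_equal(impactGate(list(impact = "MODERATE", sift = "",
                               polyphen = "", maf_asn = 0.1))$decision,
               "fail")
  expect_equal(impactGate(list(impact = "LOW", sift = "", polyphen = "",
                               maf_asn = NA))$decision, "fail")
  expect_equal(impactGate(list(impact = "MODIFIER", sift = "",
                               polyphen = "", maf_asn = NA))$decision,
               "fail")
  # MODERATE with no evidence fails closed
  none <- impactGate(list(impact = "MODERATE", sift = "", polyphen = "",
                          maf_asn = NA))
  expect_equal(none$decision, "fail")
  expect_match(none$reason, "insufficient evidence")
  expect_error(impactGate(list(impact = "BAD")), "unknown impact")
})

test_that("ontology gate takes the union of sources and names matches", {
  lists <- taGeneLists()
  g <- ontologyGate("MAST4", lists)  # HPO only
  expect_equal(g$decision, "pass")
  expect_equal(g$reason, "HPO")
  expect_equal(ontologyGate("PITX2", lists)$reason, "OT,GO,HPO")
  expect_equal(ontologyGate("NOTAGENE", lists)$decision, "fail")
  for (gene in variants(taFixture())$gene)
    expect_equal(ontologyGate(gene, lists)$decision, "pass")
})

test_that("the cascade retains the five printed candidates among 20 decoys", {
  coh <- taFixture(decoysPerGate = 4)
  res <- runCascade(coh, taGeneLists(4))
  expect_equal(length(res$retained), 5)
  expect_setequal(variants(coh)[res$retained, "gene"],
                  c("MAST4", "ITGA6", "PITX2", "CACNA1S", "CDON"))
  # retained variants have all-pass traces; excluded have exactly one fail
  for (k in variantKeys(coh)) {
    tr <- res$trace[res$trace$key == k, ]
    expect_equal(tr$stage, c("association", "impact", "ontology",
                             "segregation"))
    if (k %in% res$retained) {
      expect_true(all(tr$decision == "pass"))
    } else {
      expect_equal(sum(tr$decision == "fail"), 1)
      # later stages after the failure are not evaluated
      f <- which(tr$decision == "fail")
      if (f < nrow(tr))
        expect_true(all(tr$decision[(f + 1):nrow(tr)] == "not_evaluated"))
    }
  }
})

test_that("cascade retention is identical with and without short-circuiting", {
  coh <- taFixture(decoysPerGate = 3)
  lists <- taGeneLists(3)
  a <- runCascade(coh, lists, shortCircuit = TRUE)
  b <- runCascade(coh, lists, shortCircuit = FALSE)
  expect_setequal(a$retained, b$retained)
  expect_false(any(b$trace$decision == "not_evaluated"))
})

test_that("empty cohorts yield empty retention and traces", {
  coh <- simulateCohort(cohortSpec(nPlantedDominant = 0,
                                   nPlantedRecessive = 0, nDecoys = 0,
                                   seed = 2))
  res <- runCascade(coh, taGeneLists())
  expect_equal(length(res$retained), 0)
  expect_equal(nrow(res$trace), 0)
})

test_that("relaxing the MAF rescue threshold never shrinks the retained set", {
  coh <- taFixture(decoysPerGate = 3)
  lists <- taGeneLists(3)
  prev <- character()
  for (thr in c(0.01, 0.05, 0.1, 0.5, 1)) {
    ret <- runCascade(coh, lists, mafThreshold = thr)$retained
    expect_true(all(prev %in% ret), info = paste("threshold", thr))
    prev <- ret
  }
})
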