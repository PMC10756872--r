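mkAln <- function(seqs) Biostrings::AAStringSet(seqs)

test_that("conservation fraction counts matching non-gap ortholog residues", {
  orth <- setNames(rep("MKLV", 8), paste0("sp", 1:8))
  aln <- mkAln(c(human = "MKLV", orth))
  cs <- conservationScore(aln, "human", 3)
  expect_equal(cs$fraction, 1)
  expect_true(cs$conserved)
  expect_equal(cs$residue, "L")
  # 6 of 8 match
  orth[7:8] <- "MKAV"
  cs <- conservationScore(mkAln(c(human = "MKLV", orth)), "human", 3)
  expect_equal(cs$fraction, 0.75)
  expect_false(cs$conserved)  # below the 0.8 default
  expect_true(conservationScore(mkAln(c(human = "MKLV", orth)), "human", 3,
                                threshold = 0.7)$conserved)
  # ortholog gaps are excluded from the denominator
  orth[1] <- "MK-V"
  cs <- conservationScore(mkAln(c(human = "MKLV", orth)), "human", 3)
  expect_equal(cs$n_orthologs, 7)
  expect_equal(cs$fraction, 5 / 7)
})

test_that("human gaps are skipped when mapping residue positions", {
  aln <- mkAln(c(human = "M-KLV", sp1 = "MAKLV", sp2 = "MAKLV"))
  cs <- conservationScore(aln, "human", 2)  # K: second human residue
  expect_equal(cs$column, 3)
  expect_equal(cs$residue, "K")
  # round trip: ungapping the column recovers the residue position
  human <- strsplit("M-KLV", "")[[1]]
  expect_equal(sum(human[seq_len(cs$column)] != "-"), 2)
  expect_error(conservationScore(aln, "human", 5), "beyond")
  expect_error(conservationScore(aln, "yeti", 2), "absent")
})

test_that("conservation is invariant to row order and all-gap columns", {
  orth <- setNames(c("MKLV", "MKLV", "MKAV"), paste0("sp", 1:3))
  base <- conservationScore(mkAln(c(human = "MKLV", orth)), "human", 3)
  shuf <- conservationScore(mkAln(c(orth[c(2, 3, 1)], human = "MKLV")),
                            "human", 3)
  expect_equal(shuf$fraction, base$fraction)
  padded <- mkAln(c(human = "MKLV--", vapply(orth, paste0, character(1),
                                             "--")))
  expect_equal(conservationScore(padded, "human", 3)$fraction,
               base$fraction)
})

test_that("fixture ortholog alignments are conserved at the mutated residues", {
  aln <- fixtureAlignments()
  sites <- c(MAST4 = 95, CACNA1S = 1520, CDON = 63)
  res <- c(MAST4 = "L", CACNA1S = "R", CDON = "A")
  for (gene in names(sites)) {
    cs <- conservationScore(aln[[gene]], "human", sites[[gene]],
                            threshold = 0.8)
    expect_true(cs$conserved, info = gene)
    expect_equal(cs$residue, res[[gene]], info = gene)
  }
  expect_identical(as.character(fixtureAlignments()$MAST4),
                   as.character(aln$MAST4))  # deterministic
})

test_that("LOEUF joins report constraint evidence without dropping genes", {
  v <- annotateTolerance(variants(taFixture()), taLoeufTable())
  expect_equal(v$loeuf[v$gene == "MAST4"], 0.38)
  expect_true(v$constraint_evidence[v$gene == "MAST4"])
  expect_equal(v$loeuf[v$gene == "CDON"], 0.96)
  expect_true(v$constraint_evidence[v$gene == "CDON"])
  expect_true(is.na(v$loeuf[v$gene == "PITX2"]))
  expect_false(v$constraint_evidence[v$gene == "PITX2"])
  expect_equal(nrow(v), 5)
  expect_error(annotateTolerance(v, data.frame(gene = "X", loeuf = -1)),
               "negative")
})

test_that("prediction summaries print per-transcript calls in order", {
  expect_equal(summarizeCalls("D,D", "sift"), "D, D")
  expect_equal(summarizeCalls("T,D,T", "sift"), "T, D, T")
  expect_equal(summarizeCalls("P,P,P", "polyphen"), "P, P, P")
  expect_equal(summarizeCalls("", "sift"), "--")
  expect_error(summarizeCalls("Z", "sift"), "unknown")
  v <- summarizePredictions(variants(taFixture()))
  expect_equal(v$sift_summary[v$gene == "CACNA1S"], "D, D")
  expect_equal(v$polyphen_summary[v$gene == "MAST4"], "--")
})
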