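# Independent oracles used across the suite.  They deliberately take
# different computational routes from the package (lchoose enumeration vs
# dhyper; draw enumeration vs phyper; literal step-up vs p.adjust).

# two-sided Fisher p for all first cells of fixed margins, via log-choose
fisherOracleAll <- function(K, N, n) {
  lo <- max(0, n - (N - K))
  hi <- min(n, K)
  lp <- lchoose(K, lo:hi) + lchoose(N - K, n - (lo:hi)) - lchoose(N, n)
  p <- exp(lp)
  vapply(seq_along(p),
         function(i) min(1, sum(p[p <= p[i] * (1 + 1e-7)])),
         numeric(1))
}

fisherOracle <- function(a, b, c2, d) {
  N <- a + b + c2 + d
  K <- a + c2
  n <- a + b
  if (K == 0 || K == N || n == 0 || n == N) return(1)
  fisherOracleAll(K, N, n)[a - max(0, n - (N - K)) + 1]
}

# P(overlap >= kObs) by exhaustive enumeration of every possible query draw
hyperEnumOracle <- function(termIdx, qSize, uSize, kObs) {
  if (kObs == 0) return(1)
  draws <- utils::combn(uSize, qSize)
  mean(apply(draws, 2, function(d) sum(d %in% termIdx) >= kObs))
}

# literal Benjamini-Hochberg step-up
bhOracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

# pedigree of one nuclear family with many children, for transmission laws
bigNuclearPed <- function(nKids) {
  ped <- data.frame(
    family = "T",
    id = c("I-1", "I-2", sprintf("II-%d", seq_len(nKids))),
    father = c(NA, NA, rep("I-1", nKids)),
    mother = c(NA, NA, rep("I-2", nKids)),
    sex = c(1L, 2L, rep(1L, nKids)),
    affected = FALSE, sequenced = TRUE)
  ped$sample <- paste(ped$family, ped$id, sep = "_")
  ped
}

# the published 14 x 5 genotype table, frozen independently of the fixture
# construction code
expectedGenotypeTable <- function() {
  as.matrix(read.table(header = TRUE, row.names = 1, check.names = FALSE,
                       stringsAsFactors = FALSE, text = "
sample    MAST4  ITGA6 PITX2 CACNA1S CDON
F1_II-2   C/CGCT G/GA  G/A   G/G     G/A
F1_III-2  C/CGCT G/GA  G/A   G/G     G/G
F2_I-2    C/C    G/G   G/A   G/G     G/G
F2_II-1   C/CGCT G/G   G/A   G/G     G/A
F2_III-2  C/CGCT G/G   G/A   G/G     G/A
F3_I-1    C/C    G/G   G/G   G/A     G/G
F3_II-1   C/CGCT G/G   G/A   G/A     G/G
F3_II-2   C/CGCT G/G   G/A   G/A     G/G
F4_II-1   C/C    G/G   A/A   G/G     G/A
F5_II-7   C/C    G/G   G/G   G/G     G/G
F6_II-1   C/C    G/G   G/G   G/G     G/G
F7_II-1   C/C    G/G   G/A   G/G     G/G
F8_II-3   C/C    G/G   A/A   G/G     A/A
F9_II-1   C/C    G/G   G/G   G/G     G/A
"))
}
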