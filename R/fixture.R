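#' Built-in nine-family tooth agenesis study fixture
#'
#' A fully in-memory cohort transcribed from a published nine-family
#' non-syndromic tooth agenesis WES study: 3 multiplex ("inherited") and 6
#' sporadic families, 14 sequenced affected individuals, and the five
#' candidate variants (MAST4, ITGA6, PITX2, CACNA1S, CDON) with their
#' printed genotypes, SnpEff impact classes, per-transcript SIFT/PolyPhen
#' calls, global and Asian MAFs and LOEUF scores.
#'
#' The study published no per-variant control allele counts; the fixture
#' assigns them by scaling each variant's printed Asian MAF to the
#' 100-control allele number (AN = 200), and gives the two HIGH-impact
#' variants without a printed MAF counts of 1 (ITGA6, a novel frameshift)
#' and 2 (PITX2).  This is a fixture convention, not study data.
#'
#' With \code{decoysPerGate > 0} the cohort is augmented with synthetic
#' decoy variants, each constructed to fail exactly one named pipeline gate
#' (association, impact class, prediction/MAF rescue, ontology, segregation)
#' while passing all others, enabling stage-level tests.
#'
#' @param decoysPerGate decoy variants to add per failure class (5 classes).
#' @return a \linkS4class{VariantCohort}.
#' @seealso [taGeneLists()], [taLoeufTable()], [taTermSets()], [taPpiEdges()],
#'   [fixtureAlignments()]
#' @examples
#' coh <- taFixture()
#' genotypes(coh)[, "F2_III-2"]
#' @export
taFixture <- function(decoysPerGate = 0) {
  ped <- .fixturePedigree()
  v <- .fixtureVariants()
  g <- .fixtureGenotypes(ped)
  ctl <- data.frame(
    key = variantKey(v$chrom, v$pos, v$ref, v$alt),
    # round(ASN MAF * 200) for Table-3 variants; convention for the rest
    ac = c(3L, 1L, 2L, 8L, 13L),
    an = 200L
  )
  coh <- VariantCohort(v, g, ped, ctl)
  if (decoysPerGate > 0) coh <- .addFixtureDecoys(coh, decoysPerGate)
  coh
}

.fixturePedigree <- function() {
  p <- read.table(header = TRUE, stringsAsFactors = FALSE, text = "
family id    father mother sex affected sequenced
F1     I-1   NA     NA     1   FALSE    FALSE
F1     I-2   NA     NA     2   TRUE     FALSE
F1     II-1  NA     NA     1   FALSE    FALSE
F1     II-2  I-1    I-2    2   TRUE     TRUE
F1     III-2 II-1   II-2   1   TRUE     TRUE
F2     I-1   NA     NA     1   FALSE    FALSE
F2     I-2   NA     NA     2   TRUE     TRUE
F2     II-1  I-1    I-2    1   TRUE     TRUE
F2     II-2  NA     NA     2   FALSE    FALSE
F2     III-2 II-1   II-2   2   TRUE     TRUE
F3     I-1   NA     NA     1   TRUE     TRUE
F3     I-2   NA     NA     2   FALSE    FALSE
F3     II-1  I-1    I-2    2   TRUE     TRUE
F3     II-2  I-1    I-2    2   TRUE     TRUE
F4     I-1   NA     NA     1   FALSE    FALSE
F4     I-2   NA     NA     2   FALSE    FALSE
F4     II-1  I-1    I-2    2   TRUE     TRUE
F5     I-1   NA     NA     1   FALSE    FALSE
F5     I-2   NA     NA     2   FALSE    FALSE
F5     II-7  I-1    I-2    1   TRUE     TRUE
F6     I-1   NA     NA     1   FALSE    FALSE
F6     I-2   NA     NA     2   FALSE    FALSE
F6     II-1  I-1    I-2    1   TRUE     TRUE
F7     I-1   NA     NA     1   FALSE    FALSE
F7     I-2   NA     NA     2   FALSE    FALSE
F7     II-1  I-1    I-2    2   TRUE     TRUE
F8     I-1   NA     NA     1   FALSE    FALSE
F8     I-2   NA     NA     2   FALSE    FALSE
F8     II-3  I-1    I-2    2   TRUE     TRUE
F9     I-1   NA     NA     1   FALSE    FALSE
F9     I-2   NA     NA     2   FALSE    FALSE
F9     II-1  I-1    I-2    1   TRUE     TRUE
")
  p$sample <- paste(p$family, p$id, sep = "_")
  p
}

.fixtureVariants <- function() {
  v <- data.frame(
    chrom = c("5", "2", "4", "1", "11"),
    pos = c(65892764L, 173337540L, 111542154L, 201016296L, 125871715L),
    ref = c("C", "G", "G", "G", "G"),
    alt = c("CGCT", "GA", "A", "A", "A"),
    rsid = c("rs201910335", NA, "rs2278782", "rs3850625", "rs12274923"),
    gene = c("MAST4", "ITGA6", "PITX2", "CACNA1S", "CDON"),
    impact = c("MODERATE", "HIGH", "HIGH", "MODERATE", "MODERATE"),
    effect = c("disruptive_inframe_insertion", "frameshift_variant",
               "stop_gained", "missense_variant", "missense_variant"),
    protein_change = c("Leu95dup", "Asp114fs", "Gln193*", "Arg1520Cys",
                       "Ala63Val"),
    transcript = c("ENST00000404260", "ENST00000409532", "ENST00000557119",
                   "ENST00000367338", "ENST00000531738"),
    sift = c("", "", "", "D,D", "T,D,T"),
    polyphen = c("", "", "", "B", "P,P,P"),
    maf_global = c(0.005814, NA, NA, 0.070971, 0.125916),
    maf_asn = c(0.01434, NA, NA, 0.041958, 0.062937),
    loeuf = c(0.38, NA, NA, 0.56, 0.96)
  )
  rownames(v) <- variantKey(v$chrom, v$pos, v$ref, v$alt)
  v
}

# published 14 x 5 genotype table; unsequenced relatives are missing
.fixtureGenotypes <- function(ped) {
  tab <- read.table(header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, text = "
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
")
  v <- .fixtureVariants()
  g <- matrix("./.", nrow = nrow(v), ncol = nrow(ped),
              dimnames = list(rownames(v), ped$sample))
  for (i in seq_len(nrow(v)))
    g[i, tab$sample] <- tab[[v$gene[i]]]
  g
}

#' Gene-phenotype ontology lists for the fixture
#'
#' Stand-in gene lists for the three gene-phenotype sources the pipeline
#' gates on: Open Targets (tooth agenesis, EFO_0005410), Gene Ontology
#' (odontogenesis, GO:0042476) and Human Phenotype Ontology (oligodontia,
#' HP:0000677).  Memberships are synthetic but cover the five candidate
#' genes together with established tooth agenesis genes as background.
#' With \code{decoysPerGate > 0}, genes of decoys that must pass the
#' ontology gate are appended (matching [taFixture()]).
#'
#' @param decoysPerGate decoy variants per failure class, as in [taFixture()].
#' @return named list of uppercase gene-symbol vectors (OT, GO, HPO).
#' @export
taGeneLists <- function(decoysPerGate = 0) {
  lists <- list(
    OT  = c("PITX2", "CACNA1S", "MSX1", "PAX9", "AXIN2", "WNT10A", "EDA"),
    GO  = c("PITX2", "CDON", "ITGA6", "BMP4", "SHH", "LRP6"),
    HPO = c("PITX2", "MAST4", "WNT10B", "EDAR", "EDARADD")
  )
  if (decoysPerGate > 0) {
    dec <- .fixtureDecoyTable(decoysPerGate)
    lists$GO <- c(lists$GO, dec$gene[dec$fails_gate != "ontology"])
  }
  lists
}

#' LOEUF constraint scores for the fixture candidate genes
#'
#' The published loss-of-function observed/expected upper bound fraction
#' (LOEUF) scores of the candidate genes that have one; lower means more
#' intolerant to loss-of-function variation.
#'
#' @return data.frame with columns \code{gene}, \code{loeuf}.
#' @export
taLoeufTable <- function() {
  data.frame(gene = c("MAST4", "CACNA1S", "CDON"),
             loeuf = c(0.38, 0.56, 0.96))
}

.DECOY_GATES <- c("association", "impact", "prediction_maf", "ontology",
                  "segregation")

# deterministic decoy variant table; genotype patterns are filled in by
# .addFixtureDecoys
.fixtureDecoyTable <- function(perGate) {
  idx <- expand.grid(i = seq_len(perGate), gate = .DECOY_GATES,
                     stringsAsFactors = FALSE)
  letter <- c(association = "A", impact = "I", prediction_maf = "P",
              ontology = "O", segregation = "S")
  data.frame(
    chrom = "20",
    pos = 1000000L + 50000L * match(idx$gate, .DECOY_GATES) + 100L * idx$i,
    ref = "G", alt = "T", rsid = NA_character_,
    gene = sprintf("DEC%s%02d", letter[idx$gate], idx$i),
    impact = c(association = "HIGH", impact = "LOW",
               prediction_maf = "MODERATE", ontology = "HIGH",
               segregation = "HIGH")[idx$gate],
    effect = c(association = "stop_gained", impact = "synonymous_variant",
               prediction_maf = "missense_variant", ontology = "stop_gained",
               segregation = "stop_gained")[idx$gate],
    protein_change = NA_character_, transcript = NA_character_,
    sift = ifelse(idx$gate == "prediction_maf", "T,T", ""),
    polyphen = ifelse(idx$gate == "prediction_maf", "B", ""),
    maf_global = ifelse(idx$gate == "prediction_maf", 0.30, NA_real_),
    maf_asn = ifelse(idx$gate == "prediction_maf", 0.35, NA_real_),
    loeuf = NA_real_,
    fails_gate = idx$gate
  )
}

.addFixtureDecoys <- function(coh, perGate) {
  dec <- .fixtureDecoyTable(perGate)
  ped <- pedigree(coh)
  g <- matrix("G/G", nrow = nrow(dec), ncol = nrow(ped),
              dimnames = list(variantKey(dec$chrom, dec$pos, dec$ref, dec$alt),
                              ped$sample))
  g[, !ped$sequenced] <- "./."
  seqAff <- ped$sample[ped$affected & ped$sequenced]
  fam <- function(f) intersect(seqAff, ped$sample[ped$family == f])
  sporadics <- seqAff[ped$family[match(seqAff, ped$sample)] %in%
                        paste0("F", 4:9)]
  ac <- integer(nrow(dec))
  for (r in seq_len(nrow(dec))) {
    carriers <- switch(dec$fails_gate[r],
      # one affected het against a common control frequency: OR <= 1
      association = fam("F1")[1],
      impact = fam("F1"),
      prediction_maf = fam("F2"),
      ontology = fam("F3"),
      segregation = sporadics  # het only: no recessive-consistent carrier
    )
    g[r, carriers] <- "G/T"
    ac[r] <- if (dec$fails_gate[r] == "association") 100L else 1L
  }
  base <- variants(coh)
  if (!"fails_gate" %in% names(base)) base$fails_gate <- NA_character_
  v <- rbind(base, `rownames<-`(dec, rownames(g)))
  ctl <- rbind(controls(coh),
               data.frame(key = rownames(g), ac = ac, an = 200L))
  VariantCohort(v, rbind(genotypes(coh), g), ped, ctl)
}

#' Functional term sets for the fixture enrichment analysis
#'
#' Synthetic stand-ins for the GO / KEGG / Reactome term memberships used in
#' the study's over-representation analysis, built so that focal adhesion and
#' voltage-gated calcium channel terms are enriched for the candidate genes
#' and their PPI neighbors, over a background of unrelated filler genes.
#'
#' @return list with elements \code{sets} (named list of gene vectors),
#'   \code{source} (named character vector of source labels) and
#'   \code{description} (named character vector of term names).
#' @export
taTermSets <- function() {
  filler <- sprintf("BKG%03d", 1:60)
  sets <- list(
    "GO:0005245" = c("CACNA1S", "CACNB1", "CACNA2D1", "RYR1", "CACNA1C",
                     filler[1:3]),
    "GO:0005178" = c("ITGA6", "ITGB1", "ITGB4", "FN1", filler[4:6]),
    "GO:0050839" = c("ITGA6", "ITGB1", "FN1", "CDON", "BOC", filler[7:10]),
    "GO:0007155" = c("ITGA6", "ITGB1", "FN1", "CDON", "BOC", "PTK2",
                     filler[11:15]),
    "GO:0005891" = c("CACNA1S", "CACNB1", "CACNA2D1", "RYR1", filler[16:17]),
    "GO:0098797" = c("CACNA1S", "CACNB1", "ITGB1", "ITGB4", filler[18:23]),
    "GO:0030054" = c("ITGA6", "ITGB1", "PTK2", "CDON", filler[24:29]),
    "KEGG:04510" = c("ITGA6", "ITGB1", "ITGB4", "FN1", "PTK2", "SRC",
                     filler[30:33]),
    "REAC:R-HSA-1474244" = c("ITGA6", "ITGB1", "FN1", filler[34:38]),
    "GO:0016055" = c("PITX2", "LEF1", "CTNNB1", "AXIN2", "WNT10A",
                     filler[39:42]),
    "KEGG:04340" = c("CDON", "BOC", "SHH", "GAS1", filler[43:46]),
    "GO:0099999" = filler[21:50],
    "KEGG:00000" = filler[31:58],
    "REAC:R-HSA-0000000" = filler[c(1:10, 51:60)]
  )
  src <- sub("[:].*$", "", names(sets))
  src[grep("^GO:00(05245|05178|50839)$", names(sets))] <- "GO:MF"
  src[names(sets) == "GO:0007155"] <- "GO:BP"
  src[names(sets) %in% c("GO:0005891", "GO:0098797", "GO:0030054")] <- "GO:CC"
  src[names(sets) %in% c("GO:0016055", "GO:0099999")] <- "GO:BP"
  desc <- c("voltage-gated calcium channel activity", "integrin binding",
            "cell adhesion molecule binding", "cell adhesion",
            "voltage-gated calcium channel complex",
            "plasma membrane protein complex", "cell junction",
            "Focal adhesion", "Extracellular matrix organization",
            "Wnt signaling pathway", "Hedgehog signaling pathway",
            "background term A", "background term B", "background term C")
  list(sets = sets, source = setNames(src, names(sets)),
       description = setNames(desc, names(sets)))
}

#' STRING-style PPI edges around the fixture candidate genes
#'
#' Synthetic protein-protein interaction edge list (0-1000 combined scores)
#' linking the five candidate genes to plausible interactors, including
#' sub-threshold edges and a neighbor-of-neighbor edge so that the one-hop
#' expansion rule is exercised.
#'
#' @return data.frame with columns \code{gene_a}, \code{gene_b},
#'   \code{combined_score}.
#' @export
taPpiEdges <- function() {
  read.table(header = TRUE, stringsAsFactors = FALSE, text = "
gene_a   gene_b   combined_score
MAST4    MAST2    810
MAST4    PTK2     720
ITGA6    ITGB1    950
ITGA6    ITGB4    930
ITGA6    FN1      820
PITX2    LEF1     760
PITX2    CTNNB1   740
CACNA1S  CACNB1   900
CACNA1S  CACNA2D1 880
CACNA1S  RYR1     840
CDON     BOC      870
CDON     SHH      830
CDON     GAS1     750
PITX2    WNT10A   650
MAST4    DVL1     500
PTK2     SRC      900
ITGB1    FN1      910
")
}
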