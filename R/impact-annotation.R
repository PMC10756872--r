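#' Ortholog-alignment conservation of a human residue
#'
#' Maps a 1-based residue position of the (ungapped) human protein sequence
#' to its alignment column and computes the fraction of ortholog sequences
#' whose residue at that column matches the human one.  Ortholog gaps at
#' the column are excluded from the denominator; the human sequence itself
#' is not counted.
#'
#' @param alignment an aligned \code{Biostrings::AAStringSet} (equal
#'   widths, \code{-} gaps) or path to an aligned FASTA file.
#' @param humanId name of the human record in the alignment.
#' @param residuePos 1-based position in the ungapped human sequence.
#' @param threshold conservation call threshold on the match fraction
#'   (default 0.8).
#' @return list of class \code{ConservationAssessment}: \code{gene} (the
#'   human record id), \code{column}, \code{residue}, \code{fraction},
#'   \code{n_orthologs} (non-gap orthologs at the column) and
#'   \code{conserved} (\code{fraction >= threshold}).
#' @examples
#' aln <- fixtureAlignments()$MAST4
#' conservationScore(aln, "human", 95)
#' @export
conservationScore <- function(alignment, humanId, residuePos,
                              threshold = 0.8) {
  if (is.character(alignment) && length(alignment) == 1)
    alignment <- Biostrings::readAAStringSet(alignment)
  nm <- names(alignment)
  if (!humanId %in% nm) stop("human sequence '", humanId,
                             "' absent from alignment")
  chars <- strsplit(as.character(alignment), "")
  human <- chars[[which(nm == humanId)]]
  ungapped <- cumsum(human != "-")
  if (residuePos < 1 || residuePos > max(ungapped))
    stop("residue position ", residuePos,
         " beyond ungapped human length ", max(ungapped))
  column <- which(ungapped == residuePos & human != "-")[1]
  residue <- human[column]
  orth <- vapply(chars[nm != humanId], `[`, character(1), column)
  orth <- orth[orth != "-"]
  fraction <- if (length(orth)) mean(orth == residue) else NA_real_
  structure(list(gene = humanId, column = column, residue = residue,
                 fraction = fraction, n_orthologs = length(orth),
                 conserved = !is.na(fraction) && fraction >= threshold),
            class = "ConservationAssessment")
}

#' @export
print.ConservationAssessment <- function(x, ...) {
  cat(sprintf(
    "%s residue %s at alignment column %d: %.3f of %d orthologs match (%s)\n",
    x$gene, x$residue, x$column, x$fraction, x$n_orthologs,
    if (x$conserved) "conserved" else "not conserved"))
  invisible(x)
}

#' Join LOEUF constraint scores onto a variant table
#'
#' Adds per-gene LOEUF (loss-of-function observed/expected upper bound
#' fraction) scores and a qualitative \code{constraint_evidence} flag set
#' when LOEUF < 1.  LOEUF is reported, never used as a filter gate.  Genes
#' absent from the table keep a missing score and an unset flag; they are
#' never dropped.
#'
#' @param variants variant data.frame with a \code{gene} column.
#' @param loeufTable data.frame with columns \code{gene}, \code{loeuf}.
#' @return the variant table with \code{loeuf} and
#'   \code{constraint_evidence} columns.
#' @examples
#' annotateTolerance(variants(taFixture()), taLoeufTable())[,
#'   c("gene", "loeuf", "constraint_evidence")]
#' @export
annotateTolerance <- function(variants, loeufTable) {
  stopifnot(all(c("gene", "loeuf") %in% names(loeufTable)))
  if (any(loeufTable$loeuf < 0, na.rm = TRUE))
    stop("negative LOEUF score")
  hit <- match(variants$gene, loeufTable$gene)
  variants$loeuf <- loeufTable$loeuf[hit]
  variants$constraint_evidence <- !is.na(variants$loeuf) & variants$loeuf < 1
  variants
}

#' Compact per-tool prediction summary strings
#'
#' Formats ordered per-transcript SIFT/PolyPhen calls the way published
#' mutation-impact tables print them: \code{"D, D"}, \code{"P, P, P"},
#' and \code{"--"} when a tool made no call.
#'
#' @param calls comma-separated call string (as stored in the variant
#'   table) or character vector of labels.
#' @param tool \code{"sift"} (labels D/T) or \code{"polyphen"} (B/P/D).
#' @return a single formatted string.
#' @examples
#' summarizeCalls("D,D", "sift")
#' summarizeCalls("", "polyphen")
#' @export
summarizeCalls <- function(calls, tool = c("sift", "polyphen")) {
  tool <- match.arg(tool)
  valid <- if (tool == "sift") c("D", "T") else c("B", "P", "D")
  if (length(calls) > 1) calls <- paste(calls, collapse = ",")
  parsed <- .parseCalls(calls, valid, tool)
  if (!length(parsed)) "--" else paste(parsed, collapse = ", ")
}

#' Add prediction summary columns to a variant table
#'
#' @param variants variant data.frame with \code{sift}, \code{polyphen}.
#' @return the table with \code{sift_summary} and \code{polyphen_summary}.
#' @export
summarizePredictions <- function(variants) {
  variants$sift_summary <-
    vapply(variants$sift, summarizeCalls, character(1), tool = "sift")
  variants$polyphen_summary <-
    vapply(variants$polyphen, summarizeCalls, character(1),
           tool = "polyphen")
  variants
}

.AA <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
         "F", "P", "S", "T", "W", "Y", "V")

#' Synthetic ortholog alignments for the fixture missense/indel sites
#'
#' Deterministic, clearly synthetic stand-ins for the mammalian ortholog
#' alignments of MAST4 (Leu95), CACNA1S (Arg1520) and CDON (Ala63): a
#' human sequence of the required length plus eight mammal orthologs that
#' diverge randomly away from the site but are conserved in a window
#' around the mutated residue, with occasional gaps.  They satisfy the
#' qualitative claim that the mutated residues lie at well-conserved
#' positions; they are not biological sequences.
#'
#' @return named list of aligned \code{Biostrings::AAStringSet} objects
#'   (\code{MAST4}, \code{CACNA1S}, \code{CDON}); the human record is
#'   named \code{"human"}.
#' @export
fixtureAlignments <- function() {
  species <- c("chimpanzee", "macaque", "mouse", "rat", "dog", "cow",
               "horse", "elephant")
  sites <- c(MAST4 = 95L, CACNA1S = 1520L, CDON = 63L)
  residues <- c(MAST4 = "L", CACNA1S = "R", CDON = "A")
  .withSeed(20231229, {
    out <- lapply(names(sites), function(gene) {
      pos <- sites[[gene]]
      len <- pos + 12L
      human <- sample(.AA, len, replace = TRUE)
      human[pos] <- residues[[gene]]
      window <- max(1, pos - 4):min(len, pos + 4)
      seqs <- c(list(human = human), setNames(lapply(species, function(sp) {
        s <- human
        mut <- runif(len) < 0.15
        mut[window] <- FALSE
        s[mut] <- sample(.AA, sum(mut), replace = TRUE)
        gap <- runif(len) < 0.02
        gap[window] <- FALSE
        s[gap] <- "-"
        s
      }), species))
      Biostrings::AAStringSet(vapply(seqs, paste, character(1),
                                     collapse = ""))
    })
    names(out) <- names(sites)
    out
  })
}
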