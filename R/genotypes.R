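#' Classify allele-pair genotype strings
#'
#' Genotypes are stored as unphased ref/alt allele strings in the dialect of
#' published segregation tables (e.g. \code{"C/CGCT"} for a heterozygous
#' insertion carrier), with \code{"./."} for missing.  This maps each string
#' to a genotype class relative to the variant's ref and alt alleles.
#'
#' @param gt character vector of allele-pair strings.
#' @param ref,alt the variant's reference and alternative allele strings.
#' @return character vector in \code{hom_ref, het, hom_alt, missing}.
#' @examples
#' genotypeClass(c("G/A", "A/A", "G/G", "./."), "G", "A")
#' @export
genotypeClass <- function(gt, ref, alt) {
  vapply(gt, function(g) {
    if (is.na(g) || g %in% c("./.", ".", "")) return("missing")
    al <- strsplit(g, "/", fixed = TRUE)[[1]]
    if (length(al) != 2 || !all(al %in% c(ref, alt, ".")))
      stop("genotype '", g, "' does not match alleles ", ref, "/", alt)
    if (any(al == ".")) return("missing")
    c("hom_ref", "het", "hom_alt")[sum(al == alt) + 1L]
  }, character(1), USE.NAMES = FALSE)
}

#' Alt-allele dosage of genotype strings
#'
#' @inheritParams genotypeClass
#' @return integer vector of alt-allele counts (0, 1, 2) with \code{NA} for
#'   missing genotypes.
#' @examples
#' altDosage(c("G/A", "A/A", "./."), "G", "A")
#' @export
altDosage <- function(gt, ref, alt) {
  cls <- genotypeClass(gt, ref, alt)
  unname(c(hom_ref = 0L, het = 1L, hom_alt = 2L, missing = NA_integer_)[cls])
}

# dosage (0/1/2, NA) -> allele-pair string
.dosageToGt <- function(dosage, ref, alt) {
  out <- rep("./.", length(dosage))
  out[!is.na(dosage) & dosage == 0] <- paste(ref, ref, sep = "/")
  out[!is.na(dosage) & dosage == 1] <- paste(ref, alt, sep = "/")
  out[!is.na(dosage) & dosage == 2] <- paste(alt, alt, sep = "/")
  out
}

#' Check Mendelian consistency of a genotype matrix
#'
#' Verifies that no child carries an allele absent from both parents, for
#' every variant and every parent-child trio with non-missing genotypes.
#' Used as a property check on simulated cohorts.
#'
#' @param cohort a \linkS4class{VariantCohort}.
#' @return \code{TRUE}, or a character vector describing violations.
#' @export
mendelianConsistent <- function(cohort) {
  ped <- pedigree(cohort)
  v <- variants(cohort)
  g <- genotypes(cohort)
  bad <- character()
  kids <- ped[!is.na(ped$father) & !is.na(ped$mother), , drop = FALSE]
  if (!nrow(kids) || !nrow(v)) return(TRUE)
  for (i in seq_len(nrow(v))) {
    key <- rownames(v)[i]
    dos <- altDosage(g[i, ], v$ref[i], v$alt[i])
    names(dos) <- colnames(g)
    for (j in seq_len(nrow(kids))) {
      kid <- kids$sample[j]
      fa <- paste(kids$family[j], kids$father[j], sep = "_")
      mo <- paste(kids$family[j], kids$mother[j], sep = "_")
      if (!all(c(kid, fa, mo) %in% names(dos))) next
      dk <- dos[kid]; df <- dos[fa]; dm <- dos[mo]
      if (any(is.na(c(dk, df, dm)))) next
      # each parent contributes one allele: child alt dosage is bounded by
      # the number of parents able to transmit alt, and a parent that can
      # only transmit alt forces at least that many alt alleles
      maxAlt <- sum(df > 0) + sum(dm > 0)
      minAlt <- sum(df == 2) + sum(dm == 2)
      if (dk > maxAlt || dk < minAlt)
        bad <- c(bad, paste0(key, ": child ", kid, " dosage ", dk,
                             " incompatible with parents ", df, "/", dm))
    }
  }
  if (length(bad)) bad else TRUE
}
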