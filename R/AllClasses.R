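#' CohortSpec: parameters of the synthetic cohort generator
#'
#' Describes a simulated family cohort: how many multiplex (two or more
#' sequenced affected members) and sporadic (single affected) families, the
#' family size range, how many causal variants to plant under dominant
#' (multiplex) and recessive (sporadic) models, how many gate-specific decoy
#' variants to add, the control-cohort size and the allele-frequency ranges
#' used for control counts.
#'
#' Defaults mirror the nine-family TA study design: 3 multiplex + 6 sporadic
#' families and a 100-individual control cohort.  `plantedControlAf` is the
#' control-population frequency of planted causal alleles (rare, 0.005);
#' `controlAfRange` is the frequency interval for the common
#' association-failing decoy sites.
#'
#' @slot nMultiplex,nSporadic number of families of each kind.
#' @slot membersPerFamily integer range (min, max) of family size including
#'   both founders; multiplex families need at least 3 members.
#' @slot nPlantedDominant,nPlantedRecessive,nDecoys planted/decoy variant counts.
#' @slot controlN number of diploid control individuals (default 100).
#' @slot controlAfRange allele-frequency interval in [0, 0.5] for common
#'   decoy sites.
#' @slot plantedControlAf control allele frequency of planted variants.
#' @slot seed integer seed; identical spec + seed gives identical cohorts.
#' @export
setClass("CohortSpec",
  representation(
    nMultiplex = "numeric", nSporadic = "numeric",
    membersPerFamily = "numeric",
    nPlantedDominant = "numeric", nPlantedRecessive = "numeric",
    nDecoys = "numeric",
    controlN = "numeric", controlAfRange = "numeric",
    plantedControlAf = "numeric", seed = "numeric"
  )
)

setValidity("CohortSpec", function(object) {
  msg <- character()
  cnt <- c(
    nMultiplex = object@nMultiplex, nSporadic = object@nSporadic,
    nPlantedDominant = object@nPlantedDominant,
    nPlantedRecessive = object@nPlantedRecessive, nDecoys = object@nDecoys
  )
  if (any(cnt < 0) || any(cnt != floor(cnt)))
    msg <- c(msg, "family/variant counts must be non-negative integers")
  if (object@controlN < 1)
    msg <- c(msg, "controlN must be >= 1")
  if (length(object@membersPerFamily) != 2 ||
      any(object@membersPerFamily < 1) ||
      object@membersPerFamily[1] > object@membersPerFamily[2])
    msg <- c(msg, "membersPerFamily must be an ascending range with min >= 1")
  if (object@nMultiplex > 0 && object@membersPerFamily[1] < 3)
    msg <- c(msg, "multiplex families need membersPerFamily min >= 3")
  if (length(object@controlAfRange) != 2 ||
      any(object@controlAfRange < 0) || any(object@controlAfRange > 0.5) ||
      object@controlAfRange[1] > object@controlAfRange[2])
    msg <- c(msg, "controlAfRange must be an ascending interval within [0, 0.5]")
  if (object@plantedControlAf < 0 || object@plantedControlAf > 0.5)
    msg <- c(msg, "plantedControlAf must lie in [0, 0.5]")
  if (length(msg)) msg else TRUE
})

#' Construct a CohortSpec
#'
#' @param nMultiplex,nSporadic family counts (defaults 3 and 6).
#' @param membersPerFamily length-2 family-size range including founders.
#' @param nPlantedDominant dominant causal variants, planted round-robin
#'   across multiplex families.
#' @param nPlantedRecessive recessive causal variants, planted round-robin
#'   across sporadic families.
#' @param nDecoys decoy variants cycling through the failure taxonomy
#'   (association, impact, prediction/MAF, ontology, segregation).
#' @param controlN diploid control-cohort size.
#' @param controlAfRange allele-frequency interval for common decoy sites.
#' @param plantedControlAf control allele frequency of planted variants.
#' @param seed integer seed.
#' @return a validated \linkS4class{CohortSpec}.
#' @examples
#' cohortSpec(seed = 7)
#' @export
cohortSpec <- function(nMultiplex = 3, nSporadic = 6,
                       membersPerFamily = c(3, 6),
                       nPlantedDominant = 3, nPlantedRecessive = 2,
                       nDecoys = 10, controlN = 100,
                       controlAfRange = c(0.25, 0.45),
                       plantedControlAf = 0.005, seed = 1) {
  new("CohortSpec",
    nMultiplex = nMultiplex, nSporadic = nSporadic,
    membersPerFamily = as.numeric(membersPerFamily),
    nPlantedDominant = nPlantedDominant,
    nPlantedRecessive = nPlantedRecessive, nDecoys = nDecoys,
    controlN = controlN, controlAfRange = as.numeric(controlAfRange),
    plantedControlAf = plantedControlAf, seed = as.numeric(seed)
  )
}

setMethod("show", "CohortSpec", function(object) {
  cat("CohortSpec:", object@nMultiplex, "multiplex +", object@nSporadic,
      "sporadic families,", object@nPlantedDominant, "dominant /",
      object@nPlantedRecessive, "recessive planted,", object@nDecoys,
      "decoys,", object@controlN, "controls, seed", object@seed, "\n")
})

#' VariantCohort: annotated genotypes with pedigree and controls
#'
#' The single internal representation every pipeline stage consumes.
#'
#' @slot variants data.frame of one row per alt allele with columns
#'   \code{chrom, pos, ref, alt, rsid, gene, impact, effect, protein_change,
#'   sift, polyphen, maf_global, maf_asn, loeuf} and, for synthetic cohorts,
#'   \code{model} (planted inheritance model) and \code{fails_gate} (decoy
#'   taxonomy label); row names are variant keys.  \code{sift}/\code{polyphen}
#'   hold ordered per-transcript call strings such as \code{"T,D,T"}.
#' @slot genotypes character matrix of unphased allele-pair strings
#'   (\code{"G/A"}, missing \code{"./."}); rows = variant keys, columns =
#'   sample identifiers (\code{FAMILY_INDIVIDUAL}).
#' @slot pedigree data.frame with columns \code{family, id, father, mother,
#'   sex, affected, sequenced, sample}.
#' @slot controls data.frame with columns \code{key, ac, an}: control-cohort
#'   alt allele count and total allele number per variant.
#' @export
setClass("VariantCohort",
  representation(
    variants = "data.frame", genotypes = "matrix",
    pedigree = "data.frame", controls = "data.frame"
  )
)

.VARIANT_COLS <- c(
  "chrom", "pos", "ref", "alt", "rsid", "gene", "impact", "effect",
  "protein_change", "sift", "polyphen", "maf_global", "maf_asn", "loeuf"
)

setValidity("VariantCohort", function(object) {
  v <- object@variants
  g <- object@genotypes
  p <- object@pedigree
  ctl <- object@controls
  msg <- character()
  miss <- setdiff(.VARIANT_COLS, names(v))
  if (length(miss))
    msg <- c(msg, paste("variants lacks columns:", paste(miss, collapse = ", ")))
  else {
    if (nrow(v) && any(v$pos < 1)) msg <- c(msg, "variant pos must be >= 1")
    if (nrow(v) && !all(v$impact %in% .IMPACTS))
      msg <- c(msg, "impact must be one of HIGH/MODERATE/LOW/MODIFIER")
    for (fc in c("maf_global", "maf_asn"))
      if (nrow(v) && any(v[[fc]] < 0 | v[[fc]] > 1, na.rm = TRUE))
        msg <- c(msg, paste(fc, "must lie in [0, 1]"))
    if (nrow(v) && any(v$loeuf < 0, na.rm = TRUE))
      msg <- c(msg, "loeuf must be non-negative")
    key <- variantKey(v$chrom, v$pos, v$ref, v$alt)
    if (anyDuplicated(key)) msg <- c(msg, "duplicate variant keys")
    if (!identical(as.character(rownames(g)), as.character(key)))
      msg <- c(msg, "genotype rows must match variant keys in order")
  }
  need <- c("family", "id", "father", "mother", "sex", "affected",
            "sequenced", "sample")
  if (!all(need %in% names(p)))
    msg <- c(msg, "pedigree lacks required columns")
  else {
    if (anyDuplicated(p$sample)) msg <- c(msg, "duplicate sample ids")
    for (par in c("father", "mother")) {
      ok <- is.na(p[[par]]) |
        paste(p$family, p[[par]]) %in% paste(p$family, p$id)
      if (!all(ok))
        msg <- c(msg, paste(par, "ids must exist within the same family"))
    }
    if (ncol(g) && !all(colnames(g) %in% p$sample))
      msg <- c(msg, "genotype columns must be pedigree samples")
  }
  if (!all(c("key", "ac", "an") %in% names(ctl)))
    msg <- c(msg, "controls needs columns key, ac, an")
  else if (nrow(ctl) && any(ctl$ac < 0 | ctl$ac > ctl$an))
    msg <- c(msg, "control alt counts must satisfy 0 <= ac <= an")
  if (length(msg)) msg else TRUE
})

#' Construct a VariantCohort
#'
#' @param variants,genotypes,pedigree,controls see \linkS4class{VariantCohort}.
#' @return a validated \linkS4class{VariantCohort}.
#' @export
VariantCohort <- function(variants, genotypes, pedigree,
                          controls = data.frame(key = character(),
                                                ac = integer(),
                                                an = integer())) {
  for (cc in setdiff(.VARIANT_COLS, names(variants))) {
    variants[[cc]] <- if (cc %in% c("maf_global", "maf_asn", "loeuf"))
      NA_real_ else NA_character_
  }
  rownames(variants) <-
    variantKey(variants$chrom, variants$pos, variants$ref, variants$alt)
  genotypes <- as.matrix(genotypes)
  if (nrow(variants) && is.null(rownames(genotypes)))
    rownames(genotypes) <- rownames(variants)
  new("VariantCohort", variants = variants, genotypes = genotypes,
      pedigree = pedigree, controls = controls)
}

setMethod("show", "VariantCohort", function(object) {
  p <- object@pedigree
  cat("VariantCohort:", nrow(object@variants), "variants x",
      ncol(object@genotypes), "genotyped samples\n")
  cat("  families:", length(unique(p$family)),
      "| sequenced affected:", sum(p$affected & p$sequenced),
      "| controls:", nrow(object@controls), "sites\n")
})

#' @rdname VariantCohort-accessors
#' @export
setGeneric("variants", function(x) standardGeneric("variants"))
#' @rdname VariantCohort-accessors
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))
#' @rdname VariantCohort-accessors
#' @export
setGeneric("pedigree", function(x) standardGeneric("pedigree"))
#' @rdname VariantCohort-accessors
#' @export
setGeneric("controls", function(x) standardGeneric("controls"))
#' @rdname VariantCohort-accessors
#' @export
setGeneric("variantKeys", function(x) standardGeneric("variantKeys"))

#' Accessors for VariantCohort slots
#'
#' @param x a \linkS4class{VariantCohort}.
#' @return the annotated variant table, genotype matrix, pedigree table,
#'   control allele-count table or variant key vector.
#' @name VariantCohort-accessors
#' @aliases variants genotypes pedigree controls variantKeys
#' @examples
#' coh <- taFixture()
#' head(variants(coh))
#' @export
setMethod("variants", "VariantCohort", function(x) x@variants)
#' @rdname VariantCohort-accessors
#' @export
setMethod("genotypes", "VariantCohort", function(x) x@genotypes)
#' @rdname VariantCohort-accessors
#' @export
setMethod("pedigree", "VariantCohort", function(x) x@pedigree)
#' @rdname VariantCohort-accessors
#' @export
setMethod("controls", "VariantCohort", function(x) x@controls)
#' @rdname VariantCohort-accessors
#' @export
setMethod("variantKeys", "VariantCohort", function(x) rownames(x@variants))
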