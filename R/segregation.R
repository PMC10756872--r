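#' Inheritance model implied by a subgroup's kind
#'
#' Multiplex families showed autosomal dominant inheritance in the study
#' design this pipeline reproduces, sporadic (non-inherited) cases autosomal
#' recessive; segregation support is therefore scored under
#' \code{dominant} for multiplex subgroups and \code{recessive} for the
#' sporadic pool.
#'
#' @param kind character vector of subgroup kinds.
#' @return character vector: \code{"dominant"} or \code{"recessive"}.
#' @examples
#' modelForSubgroup(c("multiplex", "sporadic_pool"))
#' @export
modelForSubgroup <- function(kind) {
  stopifnot(all(kind %in% c("multiplex", "sporadic_pool")))
  as.character(ifelse(kind == "multiplex", "dominant", "recessive"))
}

#' Count model-consistent affected carriers
#'
#' Dominant support counts affected members who are heterozygous or
#' homozygous alt; recessive support counts homozygous alt only.  Missing
#' genotypes contribute nothing.
#'
#' @param classes character vector of genotype classes
#'   (\code{hom_ref/het/hom_alt/missing}) of the affected subgroup members.
#' @param model \code{"dominant"} or \code{"recessive"}.
#' @return integer support count.
#' @examples
#' genotypeSupport(c("het", "het", "hom_ref"), "dominant")
#' @export
genotypeSupport <- function(classes, model = c("dominant", "recessive")) {
  model <- match.arg(model)
  ok <- if (model == "dominant") c("het", "hom_alt") else "hom_alt"
  stopifnot(all(classes %in% c("hom_ref", "het", "hom_alt", "missing")))
  sum(classes %in% ok)
}

#' Count carriers of a variant across the sequenced cohort
#'
#' @param cohort a \linkS4class{VariantCohort}.
#' @param key variant key.
#' @param classes genotype class set to count (default carriers:
#'   \code{het} and \code{hom_alt}).
#' @return integer count over all sequenced individuals.
#' @examples
#' coh <- taFixture()
#' carrierCount(coh, variantKeys(coh)[1])  # MAST4 risk-allele carriers
#' @export
carrierCount <- function(cohort, key,
                         classes = c("het", "hom_alt")) {
  valid <- c("hom_ref", "het", "hom_alt", "missing")
  if (!all(classes %in% valid))
    stop("unknown genotype class: ",
         paste(setdiff(classes, valid), collapse = ", "))
  if (!length(classes)) return(0L)
  v <- variants(cohort)[key, , drop = FALSE]
  ped <- pedigree(cohort)
  gts <- genotypes(cohort)[key, ped$sample[ped$sequenced]]
  sum(genotypeClass(gts, v$ref, v$alt) %in% classes)
}

#' Segregation scoring of variants under subgroup inheritance models
#'
#' Scores every variant's genotype support in every subgroup under the
#' subgroup's model and flags the variant as passing when some subgroup
#' reaches \code{minSupport} model-consistent affected carriers.  Strict
#' co-segregation is deliberately not required: published family data show
#' affected non-carriers and heterozygous sporadic carriers, so the rule is
#' support counting with the full genotype matrix reported for human
#' review.  Heterozygous carriers in recessive subgroups are reported as
#' model-inconsistent carriers rather than support.
#'
#' @param cohort a \linkS4class{VariantCohort}.
#' @param subgroups subgroup table from [assignSubgroups()] (default:
#'   derived from the pedigree).
#' @param minSupport minimum support count (default 1).
#' @return list with \code{results} (variant x subgroup data.frame:
#'   \code{model}, \code{support}, \code{inconsistent_carriers}) and
#'   \code{pass} (named logical per variant key).
#' @export
segregationFilter <- function(cohort, subgroups = NULL, minSupport = 1) {
  stopifnot(minSupport >= 1)
  if (is.null(subgroups)) subgroups <- assignSubgroups(pedigree(cohort))
  v <- variants(cohort)
  g <- genotypes(cohort)
  ids <- unique(subgroups$subgroup_id)
  rows <- list()
  for (i in seq_len(nrow(v))) {
    key <- rownames(v)[i]
    for (sg in ids) {
      members <- subgroups$sample[subgroups$subgroup_id == sg]
      model <- modelForSubgroup(
        subgroups$kind[subgroups$subgroup_id == sg][1])
      cls <- genotypeClass(g[key, members], v$ref[i], v$alt[i])
      supp <- genotypeSupport(cls, model)
      incons <- if (model == "recessive") sum(cls == "het") else 0L
      rows[[length(rows) + 1]] <- data.frame(
        key = key, subgroup_id = sg, model = model,
        support = supp, inconsistent_carriers = incons)
    }
  }
  results <- if (length(rows)) do.call(rbind, rows) else
    data.frame(key = character(), subgroup_id = character(),
               model = character(), support = integer(),
               inconsistent_carriers = integer())
  pass <- vapply(rownames(v), function(k) {
    supp <- results$support[results$key == k]
    length(supp) > 0 && max(supp) >= minSupport
  }, logical(1))
  list(results = results, pass = pass)
}

#' Genotype-by-participant matrix in segregation-table layout
#'
#' @param cohort a \linkS4class{VariantCohort}.
#' @param sequencedOnly keep sequenced individuals only (default TRUE).
#' @return character matrix, rows = samples (family order), columns =
#'   gene-labelled variants, cells = allele-pair strings.
#' @examples
#' genotypeMatrix(taFixture())
#' @export
genotypeMatrix <- function(cohort, sequencedOnly = TRUE) {
  ped <- pedigree(cohort)
  if (sequencedOnly) ped <- ped[ped$sequenced, , drop = FALSE]
  m <- t(genotypes(cohort)[, ped$sample, drop = FALSE])
  colnames(m) <- variants(cohort)$gene
  m
}
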