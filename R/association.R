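#' Assign patient subgroups from pedigrees
#'
#' Patients from the same family are grouped into one subgroup to enhance
#' the family inheritance signal: every family with two or more sequenced
#' affected members forms its own \emph{multiplex} subgroup, and all
#' families with a single sequenced affected member are pooled into one
#' \emph{sporadic_pool} subgroup.  Families contributing no sequenced
#' affected individual are excluded with a warning.
#'
#' @param ped pedigree data.frame (see \linkS4class{VariantCohort}).
#' @return data.frame in long form with columns \code{subgroup_id},
#'   \code{kind} (\code{multiplex} / \code{sporadic_pool}), \code{sample}.
#' @examples
#' assignSubgroups(pedigree(taFixture()))
#' @export
assignSubgroups <- function(ped) {
  seqAff <- ped[ped$affected & ped$sequenced, , drop = FALSE]
  counts <- table(seqAff$family)
  empty <- setdiff(unique(ped$family), names(counts))
  if (length(empty))
    warning("families with no sequenced affected member excluded: ",
            paste(empty, collapse = ", "))
  out <- list()
  for (f in names(counts)[counts >= 2]) {
    out[[length(out) + 1]] <- data.frame(
      subgroup_id = f, kind = "multiplex",
      sample = seqAff$sample[seqAff$family == f])
  }
  singles <- names(counts)[counts == 1]
  if (length(singles)) {
    out[[length(out) + 1]] <- data.frame(
      subgroup_id = "sporadic_pool", kind = "sporadic_pool",
      sample = seqAff$sample[seqAff$family %in% singles])
  }
  if (!length(out)) {
    return(data.frame(subgroup_id = character(), kind = character(),
                      sample = character()))
  }
  do.call(rbind, out)
}

#' Build the 2x2 allele contingency table for one variant and subgroup
#'
#' Case counts come from the subgroup members' non-missing genotypes (each
#' genotyped individual contributes two alleles; missing genotypes
#' contribute none).  Control counts are taken from the cohort's control
#' allele-count table.
#'
#' @param cohort a \linkS4class{VariantCohort}.
#' @param key variant key (\code{CHROM:POS:REF:ALT}).
#' @param members sample ids of the subgroup.
#' @return named integer vector \code{case_alt, case_ref, ctrl_alt,
#'   ctrl_ref}.
#' @export
alleleTable <- function(cohort, key, members) {
  v <- variants(cohort)[key, , drop = FALSE]
  if (!nrow(v) || is.na(v$chrom[1])) stop("unknown variant: ", key)
  ctl <- controls(cohort)
  hit <- match(key, ctl$key)
  if (is.na(hit)) stop("no control allele counts for variant ", key)
  dos <- altDosage(genotypes(cohort)[key, members], v$ref, v$alt)
  caseAlt <- sum(dos, na.rm = TRUE)
  caseRef <- 2L * sum(!is.na(dos)) - caseAlt
  c(case_alt = as.integer(caseAlt), case_ref = as.integer(caseRef),
    ctrl_alt = as.integer(ctl$ac[hit]),
    ctrl_ref = as.integer(ctl$an[hit] - ctl$ac[hit]))
}

# two-sided Fisher p for every possible first cell given fixed margins:
# alt-allele margin K, total N, case margin n.  Point-probability method:
# sum all hypergeometric probabilities not exceeding the observed one
# (with the customary 1 + 1e-7 relative tolerance for ties).
.fisherPAll <- function(K, N, n) {
  lo <- max(0, n - (N - K))
  hi <- min(n, K)
  d <- dhyper(lo:hi, K, N - K, n)
  vapply(seq_along(d),
         function(i) min(1, sum(d[d <= d[i] * (1 + 1e-7)])),
         numeric(1))
}

#' Two-sided Fisher exact test on a 2x2 allele table
#'
#' Exact two-sided p-value by summation of all hypergeometric probabilities
#' less than or equal to that of the observed table under fixed margins
#' (point-probability method).  A zero margin gives p = 1 by convention.
#'
#' @param caseAlt,caseRef,ctrlAlt,ctrlRef non-negative integer allele
#'   counts; alternatively pass a named vector from [alleleTable()] as
#'   \code{caseAlt}.
#' @return p-value in (0, 1].
#' @examples
#' fisherExactTwoSided(2, 2, 1, 199)
#' @export
fisherExactTwoSided <- function(caseAlt, caseRef, ctrlAlt, ctrlRef) {
  if (length(caseAlt) == 4 && missing(caseRef)) {
    ctrlRef <- caseAlt[["ctrl_ref"]]; ctrlAlt <- caseAlt[["ctrl_alt"]]
    caseRef <- caseAlt[["case_ref"]]; caseAlt <- caseAlt[["case_alt"]]
  }
  cnt <- c(caseAlt, caseRef, ctrlAlt, ctrlRef)
  stopifnot(all(cnt >= 0), all(cnt == floor(cnt)))
  N <- sum(cnt)
  K <- caseAlt + ctrlAlt   # alt-allele margin
  n <- caseAlt + caseRef   # case-allele margin
  if (K == 0 || K == N || n == 0 || n == N) return(1)
  lo <- max(0, n - (N - K))
  .fisherPAll(K, N, n)[caseAlt - lo + 1]
}

#' Allele-count odds ratio with Haldane-Anscombe correction
#'
#' \code{(case_alt * ctrl_ref) / (case_ref * ctrl_alt)}; when any cell is
#' zero, 0.5 is first added to all four cells so the ratio is always
#' finite and positive.
#'
#' @inheritParams fisherExactTwoSided
#' @return non-negative odds ratio.
#' @examples
#' oddsRatio(3, 25, 1, 199)
#' @export
oddsRatio <- function(caseAlt, caseRef, ctrlAlt, ctrlRef) {
  if (length(caseAlt) == 4 && missing(caseRef)) {
    ctrlRef <- caseAlt[["ctrl_ref"]]; ctrlAlt <- caseAlt[["ctrl_alt"]]
    caseRef <- caseAlt[["case_ref"]]; caseAlt <- caseAlt[["case_alt"]]
  }
  cnt <- c(caseAlt, caseRef, ctrlAlt, ctrlRef)
  stopifnot(all(cnt >= 0))
  if (any(cnt == 0)) cnt <- cnt + 0.5
  (cnt[1] * cnt[4]) / (cnt[2] * cnt[3])
}

#' Allele-association screen of every variant against the controls
#'
#' For every variant and every subgroup, builds the 2x2 allele table, runs
#' the two-sided Fisher exact test and the odds ratio, and flags the pair
#' as passing when \code{p < alpha} and \code{OR > 1}.  A variant passes
#' the screen when it passes in at least one subgroup; every per-subgroup
#' result is retained for the filter trace.  No multiple-testing correction
#' is applied: this reproduces a raw screening step, not an inference.
#'
#' @param cohort a \linkS4class{VariantCohort} with control counts.
#' @param subgroups subgroup table from [assignSubgroups()] (default:
#'   derived from the cohort's pedigree).
#' @param alpha significance threshold in (0, 1), default 0.05.
#' @return list with \code{results} (per variant x subgroup data.frame:
#'   counts, \code{odds_ratio}, \code{p_value}, \code{passes}) and
#'   \code{pass} (named logical per variant key).
#' @examples
#' assoc <- associationFilter(taFixture())
#' subset(assoc$results, passes)
#' @export
associationFilter <- function(cohort, subgroups = NULL, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  if (is.null(subgroups)) subgroups <- assignSubgroups(pedigree(cohort))
  keys <- variantKeys(cohort)
  ids <- unique(subgroups$subgroup_id)
  rows <- vector("list", length(keys) * length(ids))
  r <- 0
  for (key in keys) {
    for (sg in ids) {
      members <- subgroups$sample[subgroups$subgroup_id == sg]
      tab <- alleleTable(cohort, key, members)
      p <- fisherExactTwoSided(tab)
      or <- oddsRatio(tab)
      r <- r + 1
      rows[[r]] <- data.frame(
        key = key, subgroup_id = sg,
        case_alt = tab[["case_alt"]], case_ref = tab[["case_ref"]],
        ctrl_alt = tab[["ctrl_alt"]], ctrl_ref = tab[["ctrl_ref"]],
        odds_ratio = or, p_value = p,
        passes = p < alpha & or > 1
      )
    }
  }
  results <- if (r) do.call(rbind, rows[seq_len(r)]) else
    data.frame(key = character(), subgroup_id = character(),
               case_alt = integer(), case_ref = integer(),
               ctrl_alt = integer(), ctrl_ref = integer(),
               odds_ratio = numeric(), p_value = numeric(),
               passes = logical())
  pass <- vapply(keys, function(k) any(results$passes[results$key == k]),
                 logical(1))
  list(results = results, pass = pass)
}
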