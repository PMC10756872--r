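#' Any-transcript damaging prediction
#'
#' A variant counts as predicted damaging when any per-transcript SIFT call
#' is \code{D} (damaging) or any PolyPhen call is \code{P} (possibly
#' damaging) or \code{D} (probably damaging).  Possibly-damaging calls count:
#' retained published candidates carry only \code{P} PolyPhen calls.
#'
#' @param sift,polyphen per-transcript call strings, comma separated
#'   (e.g. \code{"T,D,T"}); empty or \code{NA} means no calls.
#' @return logical.
#' @examples
#' damagingAny("T,D,T", "B")
#' damagingAny("", "")
#' @export
damagingAny <- function(sift = "", polyphen = "") {
  s <- .parseCalls(sift, c("D", "T"), "SIFT")
  p <- .parseCalls(polyphen, c("B", "P", "D"), "PolyPhen")
  any(s == "D") || any(p %in% c("P", "D"))
}

.parseCalls <- function(calls, valid, tool) {
  if (length(calls) == 0 || is.na(calls) || !nzchar(calls)) return(character())
  out <- trimws(strsplit(calls, ",", fixed = TRUE)[[1]])
  bad <- setdiff(out, valid)
  if (length(bad))
    stop("unknown ", tool, " label: ", paste(bad, collapse = ", "))
  out
}

#' Impact-class gate with prediction/MAF rescue
#'
#' HIGH-impact variants pass outright.  MODERATE variants pass only when
#' predicted damaging by some transcript-level SIFT/PolyPhen call
#' ([damagingAny()]) or when their Asian-population minor allele frequency
#' is strictly below \code{mafThreshold} (default 0.1).  LOW and MODIFIER
#' variants fail.  MODERATE variants with neither predictions nor an Asian
#' MAF fail closed with reason "insufficient evidence".
#'
#' @param variant one-row data.frame (or list) with \code{impact},
#'   \code{sift}, \code{polyphen}, \code{maf_asn}.
#' @param mafThreshold Asian MAF rescue threshold, default 0.1.
#' @return list with \code{decision} (\code{"pass"}/\code{"fail"}) and
#'   \code{reason}.
#' @export
impactGate <- function(variant, mafThreshold = 0.1) {
  imp <- variant$impact
  if (!imp %in% .IMPACTS) stop("unknown impact class: ", imp)
  if (imp == "HIGH")
    return(list(decision = "pass", reason = "HIGH impact"))
  if (imp %in% c("LOW", "MODIFIER"))
    return(list(decision = "fail", reason = paste(imp, "impact")))
  hasCalls <- (!is.na(variant$sift) && nzchar(variant$sift)) ||
    (!is.na(variant$polyphen) && nzchar(variant$polyphen))
  if (hasCalls && damagingAny(variant$sift, variant$polyphen))
    return(list(decision = "pass",
                reason = "MODERATE, predicted damaging"))
  if (!is.na(variant$maf_asn)) {
    if (variant$maf_asn < mafThreshold)
      return(list(decision = "pass",
                  reason = sprintf("MODERATE, ASN MAF %.6g < %g",
                                   variant$maf_asn, mafThreshold)))
    return(list(decision = "fail",
                reason = sprintf(
                  "MODERATE, %s, ASN MAF %.6g >= %g",
                  if (hasCalls) "no damaging call" else "no predictions",
                  variant$maf_asn, mafThreshold)))
  }
  if (hasCalls)
    return(list(decision = "fail",
                reason = "MODERATE, no damaging call, no ASN MAF"))
  list(decision = "fail", reason = "insufficient evidence")
}

#' Ontology gene-list gate
#'
#' Passes when the variant's gene is in the union of the supplied
#' gene-phenotype lists; the reason names every matching source.
#'
#' @param gene gene symbol.
#' @param geneLists named list of gene-symbol vectors (e.g. OT, GO, HPO).
#' @return list with \code{decision} and \code{reason}.
#' @examples
#' ontologyGate("PITX2", taGeneLists())
#' @export
ontologyGate <- function(gene, geneLists) {
  hits <- names(geneLists)[vapply(geneLists,
                                  function(gl) toupper(gene) %in% toupper(gl),
                                  logical(1))]
  if (length(hits))
    list(decision = "pass", reason = paste(hits, collapse = ","))
  else
    list(decision = "fail", reason = "gene in no phenotype list")
}

#' Run the full variant filter cascade
#'
#' Applies the pipeline's gates in order — allele association, impact
#' class (with prediction/MAF rescue), ontology gene lists, segregation —
#' and returns the retained variant keys plus a complete per-variant
#' \emph{filter trace}: one record per stage with decision
#' (\code{pass}/\code{fail}/\code{not_evaluated}) and reason.  A variant is
#' retained iff every evaluated stage passes.  With
#' \code{shortCircuit = TRUE} (default) stages after the first failure are
#' recorded as \code{not_evaluated}; gate decisions are independent given
#' their inputs, so the retained set is identical either way.
#'
#' @param cohort a \linkS4class{VariantCohort} with controls.
#' @param geneLists named list of ontology gene sets.
#' @param alpha association significance threshold (default 0.05).
#' @param mafThreshold MODERATE-impact Asian MAF rescue threshold (0.1).
#' @param minSupport minimum segregation support (default 1).
#' @param shortCircuit stop evaluating a variant after its first failure.
#' @return list with \code{retained} (variant keys), \code{trace}
#'   (long data.frame \code{key, stage, decision, reason}),
#'   \code{association}, \code{segregation} (stage result lists) and
#'   \code{subgroups}.
#' @examples
#' res <- runCascade(taFixture(decoysPerGate = 4), taGeneLists(4))
#' variants(taFixture())[res$retained, "gene"]
#' @export
runCascade <- function(cohort, geneLists, alpha = 0.05, mafThreshold = 0.1,
                       minSupport = 1, shortCircuit = TRUE) {
  subgroups <- assignSubgroups(pedigree(cohort))
  assoc <- associationFilter(cohort, subgroups, alpha)
  seg <- segregationFilter(cohort, subgroups, minSupport)
  v <- variants(cohort)
  trace <- list()
  retained <- character()
  for (key in rownames(v)) {
    row <- v[key, , drop = FALSE]
    assocReason <- {
      hits <- assoc$results[assoc$results$key == key & assoc$results$passes, ]
      if (nrow(hits))
        paste0("p<", alpha, " & OR>1 in ",
               paste(hits$subgroup_id, collapse = ","))
      else "no subgroup with p < alpha and OR > 1"
    }
    segReason <- {
      s <- seg$results[seg$results$key == key, ]
      if (nrow(s)) paste0("max support ", max(s$support)) else "no subgroups"
    }
    stage <- list(
      association = list(
        decision = if (isTRUE(assoc$pass[[key]])) "pass" else "fail",
        reason = assocReason),
      impact = impactGate(row, mafThreshold),
      ontology = ontologyGate(row$gene, geneLists),
      segregation = list(
        decision = if (isTRUE(seg$pass[[key]])) "pass" else "fail",
        reason = segReason)
    )
    failed <- FALSE
    for (st in .STAGES) {
      if (failed && shortCircuit)
        stage[[st]] <- list(decision = "not_evaluated", reason = "")
      else if (stage[[st]]$decision == "fail") failed <- TRUE
    }
    if (!failed &&
        all(vapply(stage, `[[`, character(1), "decision") == "pass"))
      retained <- c(retained, key)
    if (failed && !shortCircuit) {
      # all-run mode: keep every real decision, retention unchanged
    }
    trace[[key]] <- data.frame(
      key = key, stage = .STAGES,
      decision = vapply(stage, `[[`, character(1), "decision")[.STAGES],
      reason = vapply(stage, `[[`, character(1), "reason")[.STAGES])
  }
  retainedAll <- if (shortCircuit) retained else {
    rownames(v)[vapply(trace, function(tr) all(tr$decision == "pass"),
                       logical(1))]
  }
  list(retained = retainedAll,
       trace = if (length(trace)) do.call(rbind, c(trace,
                                                   make.row.names = FALSE))
               else data.frame(key = character(), stage = character(),
                               decision = character(), reason = character()),
       association = assoc, segregation = seg, subgroups = subgroups)
}
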