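#' Generate family pedigrees for a synthetic cohort
#'
#' Builds one connected pedigree per family: a founder couple plus children.
#' Multiplex families carry an affected founder and at least one affected
#' child (all affected are flagged sequenced); sporadic families have exactly
#' one affected, sequenced child.  Family sizes are drawn from the spec's
#' range under the spec's seed.
#'
#' @param spec a \linkS4class{CohortSpec}.
#' @return pedigree data.frame (columns \code{family, id, father, mother,
#'   sex, affected, sequenced, sample}).
#' @examples
#' ped <- generatePedigrees(cohortSpec(seed = 1))
#' table(ped$family, ped$affected)
#' @export
generatePedigrees <- function(spec) {
  validObject(spec)
  if (spec@membersPerFamily[1] < 1)
    stop("members_per_family must be >= 1")
  nFam <- spec@nMultiplex + spec@nSporadic
  if (nFam == 0) {
    return(data.frame(family = character(), id = character(),
                      father = character(), mother = character(),
                      sex = integer(), affected = logical(),
                      sequenced = logical(), sample = character()))
  }
  .withSeed(spec@seed, {
    rows <- lapply(seq_len(nFam), function(f) {
      multiplex <- f <= spec@nMultiplex
      size <- sample(seq(spec@membersPerFamily[1], spec@membersPerFamily[2]),
                     1)
      nKids <- max(1L, size - 2L)
      kidSex <- sample(1:2, nKids, replace = TRUE)
      if (multiplex) {
        kidAff <- runif(nKids) < 0.5
        if (!any(kidAff)) kidAff[1] <- TRUE
        founderAff <- c(FALSE, TRUE)  # affected founder mother
      } else {
        kidAff <- rep(FALSE, nKids)
        kidAff[sample(nKids, 1)] <- TRUE
        founderAff <- c(FALSE, FALSE)
      }
      aff <- c(founderAff, kidAff)
      data.frame(
        family = sprintf("FAM%d", f),
        id = c("I-1", "I-2", sprintf("II-%d", seq_len(nKids))),
        father = c(NA, NA, rep("I-1", nKids)),
        mother = c(NA, NA, rep("I-2", nKids)),
        sex = c(1L, 2L, kidSex),
        affected = aff,
        sequenced = aff  # the study sequenced affected individuals only
      )
    })
    ped <- do.call(rbind, rows)
    ped$sample <- paste(ped$family, ped$id, sep = "_")
    ped
  })
}

# order individuals so parents precede children; errors on cycles
.topoOrder <- function(ped) {
  placed <- character()
  pending <- seq_len(nrow(ped))
  ord <- integer()
  while (length(pending)) {
    ready <- pending[vapply(pending, function(i) {
      pa <- ped$father[i]; ma <- ped$mother[i]
      (is.na(pa) || paste(ped$family[i], pa, sep = "_") %in% placed) &&
        (is.na(ma) || paste(ped$family[i], ma, sep = "_") %in% placed)
    }, logical(1))]
    if (!length(ready)) stop("cyclic pedigree: no resolvable parent order")
    ord <- c(ord, ready)
    placed <- c(placed, ped$sample[ready])
    pending <- setdiff(pending, ready)
  }
  ord
}

#' Transmit a biallelic variant through pedigrees
#'
#' Founders draw each of their two alleles independently at \code{founderAf};
#' every child receives one uniformly chosen allele from each parent (the law
#' of segregation).  Founder dosages can be pinned via \code{founderDosage}
#' to study fixed crosses.
#'
#' @param ped pedigree data.frame as from [generatePedigrees()].
#' @param founderAf founder population alt-allele frequency in [0, 1].
#' @param founderDosage optional named integer vector (sample -> 0/1/2)
#'   overriding the random founder draw.
#' @return named integer vector of alt dosages (0/1/2) for every individual.
#' @examples
#' ped <- generatePedigrees(cohortSpec(seed = 2))
#' dos <- transmitGenotypes(ped, founderAf = 0.2)
#' @export
transmitGenotypes <- function(ped, founderAf, founderDosage = NULL) {
  stopifnot(founderAf >= 0, founderAf <= 1)
  dos <- setNames(rep(NA_integer_, nrow(ped)), ped$sample)
  ord <- .topoOrder(ped)
  for (i in ord) {
    s <- ped$sample[i]
    if (is.na(ped$father[i]) && is.na(ped$mother[i])) {
      dos[s] <- if (!is.null(founderDosage) && s %in% names(founderDosage))
        as.integer(founderDosage[[s]]) else rbinom(1, 2, founderAf)
    } else {
      pa <- dos[paste(ped$family[i], ped$father[i], sep = "_")]
      ma <- dos[paste(ped$family[i], ped$mother[i], sep = "_")]
      dos[s] <- rbinom(1, 1, pa / 2) + rbinom(1, 1, ma / 2)
    }
  }
  dos
}

#' Plant a causal variant into target families
#'
#' Dominant variants go to multiplex families: the affected founder is made
#' heterozygous and every affected member carries at least one alt allele.
#' Recessive variants go to sporadic families: the affected individual is
#' made homozygous alt and both parents obligate heterozygous carriers.
#' Unaffected members of target families become carriers at a rate governed
#' by \code{penetrance} (with full penetrance there are none beyond the
#' obligate recessive parents).
#'
#' @param ped pedigree data.frame.
#' @param model \code{"dominant"} or \code{"recessive"}.
#' @param targetFamilies family ids to plant into.
#' @param penetrance probability that a model-consistent carrier genotype is
#'   affected (default 1).
#' @return named integer dosage vector over all individuals.
#' @export
plantCausal <- function(ped, model = c("dominant", "recessive"),
                        targetFamilies, penetrance = 1) {
  model <- match.arg(model)
  stopifnot(penetrance >= 0, penetrance <= 1)
  dos <- setNames(rep(0L, nrow(ped)), ped$sample)
  for (f in targetFamilies) {
    fam <- ped[ped$family == f, , drop = FALSE]
    if (!nrow(fam)) stop("unknown target family: ", f)
    nAff <- sum(fam$affected & fam$sequenced)
    if (model == "dominant" && nAff < 2)
      stop("dominant variants target multiplex families; ", f,
           " has ", nAff, " sequenced affected")
    if (model == "recessive" && nAff != 1)
      stop("recessive variants target sporadic families; ", f,
           " has ", nAff, " sequenced affected")
    if (model == "dominant") {
      dos[fam$sample[fam$affected]] <- 1L
      una <- fam$sample[!fam$affected]
      # incomplete penetrance leaks carrier genotypes into unaffecteds of
      # the transmitting lineage (mother I-2 side in generated pedigrees)
      leak <- runif(length(una)) < 0.5 * (1 - penetrance)
      dos[una[leak]] <- 1L
    } else {
      case <- fam$sample[fam$affected]
      dos[case] <- 2L
      pids <- unique(c(fam$father[fam$affected], fam$mother[fam$affected]))
      pids <- pids[!is.na(pids)]
      parents <- setdiff(intersect(paste(f, pids, sep = "_"), fam$sample),
                         case)
      dos[parents] <- 1L
      sibs <- setdiff(fam$sample[!fam$affected &
                                   !is.na(fam$father)], case)
      for (s in sibs) {
        d <- rbinom(1, 2, 0.5)  # both parents het
        if (d == 2 && runif(1) < penetrance) d <- 1L
        dos[s] <- as.integer(d)
      }
    }
  }
  dos
}

#' Control-cohort allele counts for a variant table
#'
#' Draws per-variant control alt-allele counts for a diploid control cohort
#' of \code{controlN} individuals (allele number AN = 2 * controlN at every
#' site).  Planted variants draw from the spec's rare
#' \code{plantedControlAf}; association-failing decoys draw from the common
#' \code{controlAfRange} (clamped to at least AN/20 so the constructed
#' failure is deterministic); other decoys are rare like planted variants.
#'
#' @param spec a \linkS4class{CohortSpec}.
#' @param variantTable data.frame with at least \code{chrom, pos, ref, alt}
#'   and optional \code{model} / \code{fails_gate} / \code{control_af}
#'   columns.
#' @return data.frame with columns \code{key, ac, an}.
#' @export
generateControls <- function(spec, variantTable) {
  validObject(spec)
  an <- 2L * as.integer(spec@controlN)
  n <- nrow(variantTable)
  key <- variantKey(variantTable$chrom, variantTable$pos,
                    variantTable$ref, variantTable$alt)
  af <- rep(spec@plantedControlAf, n)
  if (!is.null(variantTable$control_af)) {
    given <- !is.na(variantTable$control_af)
    af[given] <- variantTable$control_af[given]
  }
  common <- if (is.null(variantTable$fails_gate)) rep(FALSE, n)
            else !is.na(variantTable$fails_gate) &
                 variantTable$fails_gate == "association"
  af[common] <- runif(sum(common), spec@controlAfRange[1],
                      spec@controlAfRange[2])
  ac <- rbinom(n, an, af)
  ac[common] <- pmax(ac[common], ceiling(an / 20))
  data.frame(key = key, ac = as.integer(ac), an = an)
}

# a directly assigned carrier child needs a transmitting parent: make the
# mother an (unaffected, typically unsequenced) het carrier when neither
# parent carries the allele, so decoy genotypes stay Mendelian-consistent
.propagateObligateCarriers <- function(dos, ped) {
  kids <- which(!is.na(ped$father) & !is.na(ped$mother))
  for (i in kids) {
    if (dos[ped$sample[i]] == 0) next
    fa <- paste(ped$family[i], ped$father[i], sep = "_")
    mo <- paste(ped$family[i], ped$mother[i], sep = "_")
    if (dos[fa] == 0 && dos[mo] == 0) dos[mo] <- 1L
  }
  dos
}

# pool of established tooth agenesis genes used for planted variants and
# ontology lists in simulated cohorts
.TA_GENES <- c("MSX1", "PAX9", "BMP4", "AXIN2", "EDA", "EDAR", "EDARADD",
               "WNT10A", "WNT10B", "LRP6", "PITX2", "FGFR2", "CACNA1S",
               "MAST4", "ITGA6", "CDON")

#' Simulate a complete pedigreed exome cohort
#'
#' Generates pedigrees, plants dominant causal variants in multiplex
#' families and recessive ones in sporadic families (round-robin), adds
#' gate-specific decoy variants cycling through the failure taxonomy, draws
#' control allele counts, and assembles everything into a
#' \linkS4class{VariantCohort}.  Planted variants cycle through three
#' annotation profiles, each passing the impact gate by a stated route:
#' \code{high_impact} (HIGH class), \code{moderate_damaging} (MODERATE with
#' a damaging SIFT call) and \code{moderate_rare} (MODERATE with Asian MAF
#' below the rescue threshold).
#'
#' Identical spec (including seed) yields identical cohorts.
#'
#' @param spec a \linkS4class{CohortSpec}.
#' @param penetrance carrier penetrance for planted variants (default 1).
#' @param maskUnsequenced replace genotypes of unsequenced individuals with
#'   missing, as in real affected-only sequencing (default TRUE; disable to
#'   inspect full transmissions, e.g. for Mendelian-consistency checks).
#' @return a \linkS4class{VariantCohort} whose variant table carries
#'   \code{model} (planted) and \code{fails_gate} (decoy) columns.
#' @examples
#' coh <- simulateCohort(cohortSpec(seed = 42))
#' variants(coh)[, c("gene", "impact", "model", "fails_gate")]
#' @export
simulateCohort <- function(spec, penetrance = 1, maskUnsequenced = TRUE) {
  validObject(spec)
  ped <- generatePedigrees(spec)
  .withSeed(spec@seed + 1e6, {
    profiles <- c("high_impact", "moderate_damaging", "moderate_rare")
    mkVariant <- function(i, gene, model, fails = NA_character_,
                          profile = NA_character_) {
      hi <- !is.na(profile) && profile == "high_impact"
      dmg <- !is.na(profile) && profile == "moderate_damaging"
      rare <- !is.na(profile) && profile == "moderate_rare"
      data.frame(
        chrom = as.character(sample(1:22, 1)),
        pos = sample.int(2e8, 1), ref = "G", alt = "T",
        rsid = NA_character_, gene = gene,
        impact = if (hi || is.na(profile)) "HIGH" else "MODERATE",
        effect = if (hi) "stop_gained" else "missense_variant",
        protein_change = NA_character_,
        sift = if (dmg) "D,T" else "",
        polyphen = if (dmg) "P" else "",
        maf_global = NA_real_,
        maf_asn = if (rare) spec@plantedControlAf else NA_real_,
        loeuf = round(runif(1, 0.2, 0.9), 2),
        model = model, fails_gate = fails,
        annotation_profile = profile
      )
    }
    multiplexFams <- unique(ped$family)[seq_len(spec@nMultiplex)]
    sporadicFams <- setdiff(unique(ped$family), multiplexFams)
    rows <- list(); dosages <- list()
    genePool <- c(.TA_GENES, sprintf("TAG%03d", 1:50))
    gi <- 0
    nextGene <- function() { gi <<- gi + 1; genePool[gi] }
    for (i in seq_len(spec@nPlantedDominant)) {
      fam <- multiplexFams[(i - 1) %% length(multiplexFams) + 1]
      v <- mkVariant(i, nextGene(), "dominant",
                     profile = profiles[(i - 1) %% 3 + 1])
      rows[[length(rows) + 1]] <- v
      dosages[[length(dosages) + 1]] <-
        plantCausal(ped, "dominant", fam, penetrance)
    }
    for (i in seq_len(spec@nPlantedRecessive)) {
      fam <- sporadicFams[(i - 1) %% length(sporadicFams) + 1]
      v <- mkVariant(i, nextGene(), "recessive",
                     profile = profiles[(i - 1) %% 3 + 1])
      rows[[length(rows) + 1]] <- v
      dosages[[length(dosages) + 1]] <-
        plantCausal(ped, "recessive", fam, penetrance)
    }
    seqAff <- ped$sample[ped$affected & ped$sequenced]
    for (i in seq_len(spec@nDecoys)) {
      gate <- .DECOY_GATES[(i - 1) %% length(.DECOY_GATES) + 1]
      v <- mkVariant(i, sprintf("SIM%s%02d", toupper(substr(gate, 1, 2)), i),
                     NA_character_, fails = gate)
      if (gate == "impact") {
        v$impact <- "LOW"; v$effect <- "synonymous_variant"
      } else if (gate == "prediction_maf") {
        v$impact <- "MODERATE"; v$sift <- "T,T"; v$polyphen <- "B"
        v$maf_asn <- 0.35
      }
      dos <- setNames(rep(0L, nrow(ped)), ped$sample)
      if (gate == "association") {
        dos[intersect(seqAff, ped$sample[ped$family == multiplexFams[1]])[1]] <- 1L
      } else if (gate == "segregation") {
        dos[intersect(seqAff, ped$sample[ped$family %in% sporadicFams])] <- 1L
      } else {
        fam <- multiplexFams[(i - 1) %% length(multiplexFams) + 1]
        dos[intersect(seqAff, ped$sample[ped$family == fam])] <- 1L
      }
      rows[[length(rows) + 1]] <- v
      dosages[[length(dosages) + 1]] <- .propagateObligateCarriers(dos, ped)
    }
    if (!length(rows)) {
      return(VariantCohort(
        .fixtureVariants()[0, ],
        matrix(character(), 0, nrow(ped),
               dimnames = list(NULL, ped$sample)),
        ped
      ))
    }
    v <- do.call(rbind, rows)
    # resolve rare chrom/pos collisions deterministically
    while (anyDuplicated(variantKey(v$chrom, v$pos, v$ref, v$alt)))
      v$pos[duplicated(variantKey(v$chrom, v$pos, v$ref, v$alt))] <-
        v$pos[duplicated(variantKey(v$chrom, v$pos, v$ref, v$alt))] + 1L
    g <- t(vapply(seq_len(nrow(v)), function(i)
      .dosageToGt(dosages[[i]], v$ref[i], v$alt[i]),
      character(nrow(ped))))
    colnames(g) <- ped$sample
    rownames(g) <- variantKey(v$chrom, v$pos, v$ref, v$alt)
    if (maskUnsequenced) g[, !ped$sequenced] <- "./."
    ctl <- generateControls(spec, v)
    VariantCohort(v, g, ped, ctl)
  })
}

#' Ontology gene lists matching a simulated cohort
#'
#' Builds the three gene-phenotype lists (OT, GO, HPO) a simulated cohort is
#' filtered against: planted causal genes plus genes of every decoy that is
#' meant to pass the ontology gate, spread over the three sources, together
#' with the established tooth agenesis gene pool as background.  Genes of
#' ontology-failing decoys are excluded by construction.
#'
#' @param cohort a simulated \linkS4class{VariantCohort}.
#' @return named list of gene-symbol vectors (OT, GO, HPO).
#' @export
simulatedGeneLists <- function(cohort) {
  v <- variants(cohort)
  planted <- v$gene[!is.na(v$model)]
  passDecoys <- if ("fails_gate" %in% names(v))
    v$gene[!is.na(v$fails_gate) & v$fails_gate != "ontology"] else character()
  core <- unique(c(planted, passDecoys))
  list(OT = unique(c(core, .TA_GENES[1:6])),
       GO = unique(c(core, .TA_GENES[7:12])),
       HPO = unique(c(core, .TA_GENES[13:16])))
}
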