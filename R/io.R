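#' Write a cohort to standard interchange files
#'
#' Emits VCF v4.2 (one record per alt allele, GT genotypes, annotations in
#' INFO keys \code{GENE, IMPACT, EFFECT, PCHANGE, TRANSCRIPT, SIFT,
#' POLYPHEN, MAF, MAF_ASN, LOEUF}; per-transcript call lists use \code{|}
#' inside INFO), a 6-column PED file (phenotype 2 = affected,
#' 1 = unaffected), a control allele-count TSV (\code{variant_key, AC, AN})
#' and a sidecar annotation TSV keyed by \code{CHROM/POS/REF/ALT}.
#' Only sequenced individuals appear as VCF sample columns.
#'
#' @param cohort a \linkS4class{VariantCohort}.
#' @param dir output directory (created if needed).
#' @return invisibly, the named file paths.
#' @seealso [readCohort()] for the inverse.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(vcf = file.path(dir, "cohort.vcf"),
             ped = file.path(dir, "cohort.ped"),
             controls = file.path(dir, "controls.tsv"),
             annotation = file.path(dir, "annotation.tsv"))
  v <- variants(cohort)
  ped <- pedigree(cohort)
  keep <- ped$sample[ped$sequenced & ped$sample %in%
                       colnames(genotypes(cohort))]
  g <- genotypes(cohort)[, keep, drop = FALSE]

  info <- vapply(seq_len(nrow(v)), function(i) {
    enc <- function(key, val) {
      if (is.null(val) || length(val) == 0 || is.na(val) ||
          (is.character(val) && !nzchar(val))) return(NULL)
      paste0(key, "=", gsub(",", "|", as.character(val), fixed = TRUE))
    }
    fields <- c(enc("GENE", v$gene[i]), enc("IMPACT", v$impact[i]),
                enc("EFFECT", v$effect[i]),
                enc("PCHANGE", v$protein_change[i]),
                enc("TRANSCRIPT", v$transcript[i]),
                enc("SIFT", v$sift[i]), enc("POLYPHEN", v$polyphen[i]),
                enc("MAF", v$maf_global[i]), enc("MAF_ASN", v$maf_asn[i]),
                enc("LOEUF", v$loeuf[i]))
    if (is.null(fields)) "." else paste(fields, collapse = ";")
  }, character(1))
  gtNum <- vapply(seq_len(nrow(v)), function(i) {
    dos <- altDosage(g[i, ], v$ref[i], v$alt[i])
    out <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")[as.character(dos)]
    out[is.na(out)] <- "./."
    paste(out, collapse = "\t")
  }, character(1))
  infoMeta <- c(
    GENE = "gene symbol", IMPACT = "SnpEff impact class",
    EFFECT = "variant effect", PCHANGE = "protein change",
    TRANSCRIPT = "transcript id",
    SIFT = "per-transcript SIFT calls (| separated)",
    POLYPHEN = "per-transcript PolyPhen calls (| separated)",
    MAF = "global minor allele frequency",
    MAF_ASN = "Asian-population minor allele frequency",
    LOEUF = "gene LOEUF constraint score")
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf(
      '##INFO=<ID=%s,Number=1,Type=%s,Description="%s">',
      names(infoMeta),
      ifelse(names(infoMeta) %in% c("MAF", "MAF_ASN", "LOEUF"),
             "Float", "String"),
      infoMeta),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", keep), collapse = "\t"))
  body <- if (nrow(v)) paste(v$chrom, v$pos,
                             ifelse(is.na(v$rsid), ".", v$rsid),
                             v$ref, v$alt, ".", "PASS", info, "GT", gtNum,
                             sep = "\t") else character()
  writeLines(c(header, body), paths["vcf"])

  pedOut <- data.frame(ped$family, ped$id,
                       ifelse(is.na(ped$father), "0", ped$father),
                       ifelse(is.na(ped$mother), "0", ped$mother),
                       ped$sex, ifelse(ped$affected, 2L, 1L))
  write.table(pedOut, paths["ped"], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)

  ctl <- controls(cohort)
  write.table(data.frame(variant_key = ctl$key, AC = ctl$ac, AN = ctl$an),
              paths["controls"], sep = "\t", quote = FALSE,
              row.names = FALSE)

  annCols <- intersect(c("chrom", "pos", "ref", "alt", "rsid", "gene",
                         "impact", "effect", "protein_change", "transcript",
                         "sift", "polyphen", "maf_global", "maf_asn",
                         "loeuf", "model", "fails_gate"), names(v))
  write.table(v[, annCols, drop = FALSE], paths["annotation"], sep = "\t",
              quote = FALSE, row.names = FALSE, na = "")
  invisible(paths)
}

# light structural check so malformed VCF lines fail with a line number
.checkVcfLines <- function(path) {
  lines <- readLines(path)
  dataIdx <- which(!startsWith(lines, "#"))
  nf <- lengths(strsplit(lines[dataIdx], "\t", fixed = TRUE))
  bad <- dataIdx[nf < 8]
  if (length(bad))
    stop("malformed VCF line ", bad[1], " in ", path,
         ": fewer than 8 fields")
  invisible(TRUE)
}

#' Read a cohort from VCF + PED (+ optional annotation sidecar)
#'
#' Parses the VCF with \pkg{vcfR}, decomposing multiallelic sites into one
#' record per alt allele (alleles of other alts are counted as reference
#' for the biallelic analysis).  Annotations come from the INFO keys
#' written by [writeCohort()] and/or a sidecar TSV keyed by
#' \code{chrom/pos/ref/alt}; on conflict the sidecar wins with a warning.
#' Individuals are marked sequenced iff they have a VCF sample column;
#' every VCF sample must exist in the PED file (as
#' \code{FAMILY_INDIVIDUAL}).  PED phenotype 2 is affected; 1, 0 and -9
#' are treated as unaffected for grouping.
#'
#' @param vcfPath,pedPath,annotationPath,controlsPath input files
#'   (annotation and controls optional).
#' @return a \linkS4class{VariantCohort}.
#' @export
readCohort <- function(vcfPath, pedPath, annotationPath = NULL,
                       controlsPath = NULL) {
  for (p in c(vcfPath, pedPath, annotationPath, controlsPath))
    if (!is.null(p) && !file.exists(p)) stop("file not found: ", p)
  .checkVcfLines(vcfPath)
  vcf <- vcfR::read.vcfR(vcfPath, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  ped <- .readPed(pedPath)
  gtRaw <- if (ncol(vcf@gt) > 1) vcf@gt[, -1, drop = FALSE] else
    matrix(character(), nrow(fix), 0)
  if (is.null(dim(gtRaw)))
    gtRaw <- matrix(gtRaw, nrow = nrow(fix),
                    dimnames = list(NULL, colnames(vcf@gt)[-1]))
  unknown <- setdiff(colnames(gtRaw), ped$sample)
  if (length(unknown))
    stop("VCF sample(s) absent from PED: ", paste(unknown, collapse = ", "))
  ped$sequenced <- ped$sample %in% colnames(gtRaw)

  getInfo <- function(key) {
    val <- vcfR::extract.info(vcf, element = key)
    if (is.null(val)) rep(NA_character_, nrow(fix)) else val
  }
  infoKeys <- c("GENE", "IMPACT", "EFFECT", "PCHANGE", "TRANSCRIPT",
                "SIFT", "POLYPHEN", "MAF", "MAF_ASN", "LOEUF")
  info <- lapply(setNames(infoKeys, infoKeys), getInfo)

  rows <- list(); gts <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    for (k in seq_along(alts)) {
      pick <- function(key) {
        val <- info[[key]][i]
        if (is.na(val)) return(NA_character_)
        parts <- strsplit(val, ",", fixed = TRUE)[[1]]
        if (length(parts) == length(alts)) parts[k] else val
      }
      num <- function(key) suppressWarnings(as.numeric(pick(key)))
      calls <- function(key) {
        val <- pick(key)
        if (is.na(val)) "" else gsub("|", ",", val, fixed = TRUE)
      }
      rows[[length(rows) + 1]] <- data.frame(
        chrom = fix[i, "CHROM"], pos = as.integer(fix[i, "POS"]),
        ref = fix[i, "REF"], alt = alts[k],
        rsid = if (is.na(fix[i, "ID"]) || fix[i, "ID"] == ".")
          NA_character_ else fix[i, "ID"],
        gene = pick("GENE"),
        impact = if (is.na(pick("IMPACT"))) "MODIFIER" else pick("IMPACT"),
        effect = pick("EFFECT"), protein_change = pick("PCHANGE"),
        transcript = pick("TRANSCRIPT"),
        sift = calls("SIFT"), polyphen = calls("POLYPHEN"),
        maf_global = num("MAF"), maf_asn = num("MAF_ASN"),
        loeuf = num("LOEUF"))
      gtCodes <- sub(":.*$", "", gtRaw[i, ])
      dos <- vapply(strsplit(gtCodes, "[/|]"), function(al) {
        if (any(al == ".")) return(NA_integer_)
        sum(al == as.character(k))
      }, integer(1))
      gts[[length(gts) + 1]] <-
        .dosageToGt(dos, fix[i, "REF"], alts[k])
    }
  }
  v <- do.call(rbind, rows)
  g <- matrix("./.", nrow = nrow(v), ncol = nrow(ped),
              dimnames = list(variantKey(v$chrom, v$pos, v$ref, v$alt),
                              ped$sample))
  for (r in seq_along(gts)) g[r, colnames(gtRaw)] <- gts[[r]]

  if (!is.null(annotationPath))
    v <- .applySidecar(v, annotationPath)
  ctl <- if (is.null(controlsPath))
    data.frame(key = character(), ac = integer(), an = integer())
  else readControls(controlsPath)
  VariantCohort(v, g, ped, ctl)
}

.readPed <- function(path) {
  raw <- read.table(path, header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("family", "id", "father", "mother",
                                  "sex", "phenotype"))
  data.frame(
    family = as.character(raw$family), id = as.character(raw$id),
    father = ifelse(raw$father %in% c("0", 0), NA_character_,
                    as.character(raw$father)),
    mother = ifelse(raw$mother %in% c("0", 0), NA_character_,
                    as.character(raw$mother)),
    sex = raw$sex, affected = raw$phenotype == 2,
    sequenced = FALSE,
    sample = paste(raw$family, raw$id, sep = "_"))
}

.applySidecar <- function(v, path) {
  side <- read.table(path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE, na.strings = c("NA", ""))
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(side)))
    stop("annotation sidecar must have columns chrom, pos, ref, alt")
  key <- variantKey(v$chrom, v$pos, v$ref, v$alt)
  sideKey <- variantKey(side$chrom, side$pos, side$ref, side$alt)
  hit <- match(key, sideKey)
  for (cc in setdiff(names(side), need)) {
    new <- side[[cc]][hit]
    if (cc %in% c("sift", "polyphen")) new[is.na(new)] <- ""
    if (cc %in% names(v)) {
      old <- v[[cc]]
      conflict <- !is.na(hit) & !is.na(new) &
        !is.na(old) & as.character(new) != as.character(old) &
        !(cc %in% c("maf_global", "maf_asn", "loeuf") &
            abs(suppressWarnings(as.numeric(new)) -
                  suppressWarnings(as.numeric(old))) < 1e-9)
      if (any(conflict))
        warning("sidecar overrides INFO for ", cc, " at ",
                paste(key[conflict], collapse = ", "))
      v[[cc]][!is.na(hit) & !is.na(new)] <- new[!is.na(hit) & !is.na(new)]
      if (cc %in% c("maf_global", "maf_asn", "loeuf"))
        v[[cc]] <- as.numeric(v[[cc]])
    } else {
      v[[cc]] <- new
    }
  }
  v
}

#' Read a control allele-count table
#'
#' @param path TSV with header columns \code{variant_key, AC, AN}.
#' @return data.frame with columns \code{key, ac, an}.
#' @export
readControls <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  if (!all(c("variant_key", "AC", "AN") %in% names(tab)))
    stop("controls table needs columns variant_key, AC, AN")
  data.frame(key = tab$variant_key, ac = as.integer(tab$AC),
             an = as.integer(tab$AN))
}

#' Read gene-phenotype gene lists
#'
#' Each file is either one gene symbol per line or a GMT file (in which
#' case the union of its sets is used).  Symbols are uppercased and
#' deduplicated; empty lines are ignored; an empty file yields a warning
#' and an empty set; a missing file is an error naming the path.
#'
#' @param paths named character vector of file paths; names become the
#'   source labels.
#' @return named list of gene-symbol vectors.
#' @export
readGeneLists <- function(paths) {
  if (is.null(names(paths)) || any(!nzchar(names(paths))))
    names(paths) <- basename(paths)
  lapply(setNames(paths, names(paths)), function(p) {
    if (!file.exists(p)) stop("gene list file not found: ", p)
    genes <- if (grepl("\\.gmt$", p, ignore.case = TRUE))
      unique(unlist(readGmt(p)$sets)) else {
        lines <- trimws(readLines(p))
        lines[nzchar(lines)]
      }
    genes <- unique(toupper(genes))
    if (!length(genes)) warning("empty gene list: ", p)
    genes
  })
}

#' Read a GMT term-set file
#'
#' Tab-separated: term id, description, then member genes.  The
#' description column carries the source label in files written by
#' [writeGmt()].
#'
#' @param path GMT file path.
#' @return list with \code{sets} (named list of uppercase gene vectors)
#'   and \code{description} (named character vector).
#' @export
readGmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad))
    stop("malformed GMT line ", bad[1], ": needs id, description, genes")
  ids <- vapply(parts, `[`, character(1), 1)
  if (anyDuplicated(ids)) stop("duplicate GMT term ids")
  sets <- setNames(lapply(parts, function(x) unique(toupper(x[-(1:2)]))),
                   ids)
  desc <- setNames(vapply(parts, `[`, character(1), 2), ids)
  list(sets = sets, description = desc)
}

#' Write term sets as GMT
#'
#' @param sets named list of gene vectors.
#' @param path output path.
#' @param description named character vector (defaults to the term ids).
#' @export
writeGmt <- function(sets, path, description = NULL) {
  if (is.null(description)) description <- setNames(names(sets), names(sets))
  writeLines(vapply(names(sets), function(id)
    paste(c(id, description[[id]], sets[[id]]), collapse = "\t"),
    character(1)), path)
}

#' Read a STRING-style PPI edge list
#'
#' TSV with header \code{gene_a, gene_b, combined_score} (integer scores
#' 0-1000).  Edges scoring strictly below \code{minScore} are dropped;
#' the result is an undirected simple graph (duplicate and reversed edges
#' stored once).
#'
#' @param path edge-list file.
#' @param minScore confidence threshold (default 700).
#' @return an \code{igraph} graph; see [expandGeneSet()].
#' @export
readPpi <- function(path, minScore = 700) {
  if (!file.exists(path)) stop("file not found: ", path)
  edges <- read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  ppiGraph(edges, minScore)
}

#' Write pipeline reports
#'
#' Emits the pipeline's deliverables as TSV: the retained
#' candidate-variant table, the genotype-by-participant matrix, the
#' per-variant filter trace, per-stage association/segregation results,
#' the enrichment table and a structured run summary (YAML).  Variant
#' tables are ordered by (chrom, pos, alt); reruns are byte-identical.
#'
#' @param results a result list from [runPipeline()] (or [runCascade()]
#'   output augmented with \code{cohort}).
#' @param dir output directory.
#' @return invisibly, the named file paths.
#' @export
writeReport <- function(results, dir) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    if (!ok) stop("cannot create output directory: ", dir)
  }
  if (file.access(dir, 2) != 0) stop("output directory not writable: ", dir)
  cohort <- results$cohort
  v <- variants(cohort)
  ord <- order(v$chrom, v$pos, v$alt, method = "radix")
  tsv <- function(d, f) {
    write.table(d, file.path(dir, f), sep = "\t", quote = FALSE,
                row.names = FALSE, na = "")
    file.path(dir, f)
  }
  cand <- summarizePredictions(v[ord, , drop = FALSE])
  cand <- cand[rownames(cand) %in% results$retained, , drop = FALSE]
  cand$key <- rownames(cand)
  keep <- intersect(c("key", "gene", "rsid", "chrom", "pos", "ref", "alt",
                      "transcript", "protein_change", "impact", "effect",
                      "sift_summary", "polyphen_summary", "maf_global",
                      "maf_asn", "loeuf", "constraint_evidence"),
                    names(cand))
  paths <- c(candidates = tsv(cand[, keep, drop = FALSE], "candidates.tsv"))

  gm <- genotypeMatrix(cohort)
  gmd <- data.frame(sample = rownames(gm), gm, check.names = FALSE)
  paths["genotype_matrix"] <- tsv(gmd, "genotype_matrix.tsv")
  paths["filter_trace"] <- tsv(results$trace, "filter_trace.tsv")
  paths["association"] <- tsv(results$association$results,
                              "association.tsv")
  paths["segregation"] <- tsv(results$segregation$results,
                              "segregation.tsv")
  if (!is.null(results$enrichment))
    paths["enrichment"] <- tsv(results$enrichment, "enrichment.tsv")
  summary <- list(
    n_variants = nrow(v),
    n_sequenced = sum(pedigree(cohort)$sequenced),
    n_subgroups = length(unique(results$subgroups$subgroup_id)),
    stage_pass = list(
      association = sum(results$association$pass),
      impact = sum(results$trace$decision[results$trace$stage ==
                                            "impact"] == "pass"),
      ontology = sum(results$trace$decision[results$trace$stage ==
                                              "ontology"] == "pass"),
      segregation = sum(results$segregation$pass)),
    n_retained = length(results$retained),
    retained = as.list(sort(results$retained)),
    thresholds = results$thresholds
  )
  yaml::write_yaml(summary, file.path(dir, "run_summary.yaml"))
  paths["run_summary"] <- file.path(dir, "run_summary.yaml")
  invisible(paths)
}
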