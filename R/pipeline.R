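#' Pipeline configuration
#'
#' Collects every input path and numeric gate of the pipeline.  The default
#' thresholds are the study's printed gates: association \code{alpha} 0.05
#' with OR > 1, MODERATE-impact Asian MAF rescue below 0.1, PPI confidence
#' 700, enrichment adjusted-p 0.01, segregation support 1, conservation
#' call 0.8.
#'
#' @param vcf,ped,controls,annotation,geneLists,gmt,ppi,loeuf input paths
#'   (\code{geneLists} is a named vector of list files; \code{annotation},
#'   \code{gmt}, \code{ppi}, \code{loeuf} optional).
#' @param alpha,mafThreshold,ppiMinScore,padjThreshold,minSupport,conservationThreshold
#'   numeric gates (see above).
#' @param seed integer seed recorded with the run.
#' @param outDir report output directory.
#' @return a \code{pipelineConfig} list.
#' @export
pipelineConfig <- function(vcf, ped, controls, geneLists,
                           annotation = NULL, gmt = NULL, ppi = NULL,
                           loeuf = NULL, alpha = 0.05, mafThreshold = 0.1,
                           ppiMinScore = 700, padjThreshold = 0.01,
                           minSupport = 1, conservationThreshold = 0.8,
                           seed = 1, outDir = "pedexome-out") {
  cfg <- list(vcf = vcf, ped = ped, controls = controls,
              annotation = annotation, geneLists = as.list(geneLists),
              gmt = gmt, ppi = ppi, loeuf = loeuf,
              alpha = alpha, mafThreshold = mafThreshold,
              ppiMinScore = ppiMinScore, padjThreshold = padjThreshold,
              minSupport = minSupport,
              conservationThreshold = conservationThreshold,
              seed = seed, outDir = outDir)
  class(cfg) <- "pipelineConfig"
  validatePipelineConfig(cfg)
  cfg
}

#' Validate a pipeline configuration
#'
#' Checks that every referenced path exists and every threshold lies in
#' its domain.
#'
#' @param cfg a \code{pipelineConfig} (or plain list, e.g. from
#'   [readPipelineConfig()]).
#' @return the config, invisibly; errors otherwise.
#' @export
validatePipelineConfig <- function(cfg) {
  req <- c(cfg$vcf, cfg$ped, cfg$controls, unlist(cfg$geneLists),
           cfg$annotation, cfg$gmt, cfg$ppi, cfg$loeuf)
  missing <- req[!file.exists(req)]
  if (length(missing))
    stop("input path(s) not found: ", paste(missing, collapse = ", "))
  stopifnot(cfg$alpha > 0, cfg$alpha < 1,
            cfg$mafThreshold >= 0, cfg$mafThreshold <= 1,
            cfg$ppiMinScore >= 0, cfg$ppiMinScore <= 1000,
            cfg$padjThreshold > 0, cfg$padjThreshold <= 1,
            cfg$minSupport >= 1,
            cfg$conservationThreshold >= 0, cfg$conservationThreshold <= 1)
  invisible(cfg)
}

#' Read a pipeline configuration from YAML
#'
#' Paths in the file are interpreted relative to the file's directory.
#'
#' @param path YAML file with the fields of [pipelineConfig()].
#' @return a \code{pipelineConfig} list.
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  rel <- function(p) if (is.null(p)) NULL else
    ifelse(startsWith(p, "/"), p, file.path(base, p))
  do.call(pipelineConfig, c(
    list(vcf = rel(raw$vcf), ped = rel(raw$ped),
         controls = rel(raw$controls),
         geneLists = setNames(vapply(raw$geneLists, rel, character(1)),
                              names(raw$geneLists)),
         annotation = rel(raw$annotation), gmt = rel(raw$gmt),
         ppi = rel(raw$ppi), loeuf = rel(raw$loeuf)),
    raw[intersect(names(raw),
                  c("alpha", "mafThreshold", "ppiMinScore",
                    "padjThreshold", "minSupport",
                    "conservationThreshold", "seed", "outDir"))]))
}

#' Run the full prioritization pipeline
#'
#' Reads the cohort and resources, runs the filter cascade
#' (association, impact, ontology, segregation), annotates tolerance and
#' prediction summaries, performs PPI-expanded enrichment of the retained
#' genes when term sets are configured, and writes the report set.
#'
#' @param cfg a \code{pipelineConfig}, or path to a YAML config.
#' @param writeReports write TSV/YAML reports to \code{cfg$outDir}
#'   (default TRUE).
#' @return result list: \code{cohort}, \code{retained}, \code{trace},
#'   \code{association}, \code{segregation}, \code{subgroups},
#'   \code{enrichment} (or NULL), \code{thresholds}, and \code{paths} when
#'   reports were written.
#' @export
runPipeline <- function(cfg, writeReports = TRUE) {
  if (is.character(cfg)) cfg <- readPipelineConfig(cfg)
  validatePipelineConfig(cfg)
  cohort <- readCohort(cfg$vcf, cfg$ped, cfg$annotation, cfg$controls)
  geneLists <- readGeneLists(unlist(cfg$geneLists))
  res <- runCascade(cohort, geneLists, alpha = cfg$alpha,
                    mafThreshold = cfg$mafThreshold,
                    minSupport = cfg$minSupport)
  v <- variants(cohort)
  if (!is.null(cfg$loeuf))
    v <- annotateTolerance(v, read.table(cfg$loeuf, header = TRUE,
                                         sep = "\t",
                                         stringsAsFactors = FALSE))
  cohort@variants <- summarizePredictions(v)
  res$cohort <- cohort
  res$enrichment <- NULL
  if (!is.null(cfg$gmt)) {
    gmt <- readGmt(cfg$gmt)
    ppi <- if (!is.null(cfg$ppi)) readPpi(cfg$ppi, cfg$ppiMinScore)
           else NULL
    query <- expandGeneSet(v[res$retained, "gene"], ppi)
    res$enrichment <- enrichTerms(query, gmt$sets,
                                  padjThreshold = cfg$padjThreshold,
                                  source = gmt$description)
    res$expanded_query <- query
  }
  res$thresholds <- cfg[c("alpha", "mafThreshold", "ppiMinScore",
                          "padjThreshold", "minSupport",
                          "conservationThreshold", "seed")]
  if (writeReports) res$paths <- writeReport(res, cfg$outDir)
  res
}

#' Write a simulated cohort to disk
#'
#' Generates a cohort from a \linkS4class{CohortSpec} and writes the full
#' interchange file set (VCF, PED, controls, annotation sidecar, ontology
#' gene lists) plus a YAML manifest recording the spec and seed.
#'
#' @param spec a \linkS4class{CohortSpec}.
#' @param dir output directory.
#' @param force overwrite a non-empty existing directory (default FALSE).
#' @return invisibly, the named file paths.
#' @export
simulateCohortFiles <- function(spec, dir, force = FALSE) {
  if (dir.exists(dir) && length(dir(dir)) && !force)
    stop("output directory not empty (use force = TRUE): ", dir)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- simulateCohort(spec)
  paths <- writeCohort(cohort, dir)
  lists <- simulatedGeneLists(cohort)
  for (src in names(lists)) {
    p <- file.path(dir, paste0("genes_", src, ".txt"))
    writeLines(lists[[src]], p)
    paths[paste0("genes_", src)] <- p
  }
  manifest <- list(
    generator = "pedexome simulateCohortFiles",
    seed = spec@seed,
    families = list(multiplex = spec@nMultiplex,
                    sporadic = spec@nSporadic),
    planted = list(dominant = spec@nPlantedDominant,
                   recessive = spec@nPlantedRecessive),
    decoys = spec@nDecoys, controls = spec@controlN)
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  paths["manifest"] <- file.path(dir, "manifest.yaml")
  invisible(paths)
}

#' Write the built-in study fixture to disk
#'
#' Materializes the nine-family fixture ([taFixture()]) and its resources
#' (gene lists, LOEUF table, GMT term sets, PPI edges, ortholog
#' alignments) as plain-text files, ready for [runPipeline()].
#' Deterministic: reruns are byte-identical.
#'
#' @param dir output directory.
#' @param decoysPerGate decoys per failure class (default 4, i.e. 20).
#' @return invisibly, the named file paths.
#' @export
writeFixtureFiles <- function(dir, decoysPerGate = 4) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- taFixture(decoysPerGate)
  paths <- writeCohort(cohort, dir)
  lists <- taGeneLists(decoysPerGate)
  for (src in names(lists)) {
    p <- file.path(dir, paste0("genes_", src, ".txt"))
    writeLines(lists[[src]], p)
    paths[paste0("genes_", src)] <- p
  }
  write.table(taLoeufTable(), file.path(dir, "loeuf.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  paths["loeuf"] <- file.path(dir, "loeuf.tsv")
  ts <- taTermSets()
  writeGmt(ts$sets, file.path(dir, "terms.gmt"), description = ts$source)
  paths["gmt"] <- file.path(dir, "terms.gmt")
  write.table(taPpiEdges(), file.path(dir, "ppi.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  paths["ppi"] <- file.path(dir, "ppi.tsv")
  aln <- fixtureAlignments()
  for (gene in names(aln)) {
    p <- file.path(dir, paste0("ortholog_", gene, "_synthetic.fasta"))
    Biostrings::writeXStringSet(aln[[gene]], p)
    paths[paste0("alignment_", gene)] <- p
  }
  cfg <- list(vcf = "cohort.vcf", ped = "cohort.ped",
              controls = "controls.tsv", annotation = "annotation.tsv",
              geneLists = list(OT = "genes_OT.txt", GO = "genes_GO.txt",
                               HPO = "genes_HPO.txt"),
              gmt = "terms.gmt", ppi = "ppi.tsv", loeuf = "loeuf.tsv",
              outDir = "reports")
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  paths["config"] <- file.path(dir, "config.yaml")
  invisible(paths)
}
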