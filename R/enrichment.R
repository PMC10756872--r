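#' One-hop PPI neighbor expansion of a gene set
#'
#' Expands a query gene set with the direct neighbors of its members in a
#' protein-protein interaction network (edges already thresholded on their
#' confidence score, see [readPpi()]).  Expansion is one hop only:
#' neighbors of neighbors are not added, so expanding an expanded set may
#' grow it further.  The query is always a subset of the result.
#'
#' @param genes character vector of query gene symbols.
#' @param ppi an \code{igraph} PPI graph (as from [readPpi()]), or
#'   \code{NULL} for no expansion.
#' @return character vector: query genes plus their direct neighbors.
#' @examples
#' ppi <- ppiGraph(taPpiEdges(), minScore = 700)
#' expandGeneSet(c("MAST4", "PITX2"), ppi)
#' @export
expandGeneSet <- function(genes, ppi = NULL) {
  genes <- unique(toupper(genes))
  if (is.null(ppi) || igraph::vcount(ppi) == 0) return(genes)
  present <- intersect(genes, igraph::V(ppi)$name)
  nb <- unique(unlist(lapply(present, function(g)
    igraph::V(ppi)$name[as.integer(igraph::neighbors(ppi, g))])))
  sort(unique(c(genes, nb)))
}

#' Build a thresholded PPI graph from an edge table
#'
#' @param edges data.frame with columns \code{gene_a}, \code{gene_b},
#'   \code{combined_score} (STRING-style integers 0-1000).
#' @param minScore minimum combined score; edges strictly below are
#'   dropped (default 700).
#' @return undirected simple \code{igraph} graph.
#' @export
ppiGraph <- function(edges, minScore = 700) {
  stopifnot(all(c("gene_a", "gene_b", "combined_score") %in% names(edges)))
  if (any(edges$combined_score < 0 | edges$combined_score > 1000))
    stop("combined_score outside 0-1000")
  if (any(edges$gene_a == edges$gene_b))
    stop("self-loop PPI edge")
  keep <- edges[edges$combined_score >= minScore, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    data.frame(from = toupper(keep$gene_a), to = toupper(keep$gene_b)),
    directed = FALSE)
  igraph::simplify(g)
}

#' Hypergeometric over-representation p-value
#'
#' Probability of observing at least the seen overlap between the query
#' and a term's gene set when drawing \code{|query|} genes without
#' replacement from the universe.  The term is first intersected with the
#' universe; query genes outside the universe are ignored.
#'
#' @param termGenes,queryGenes,universe character vectors of gene symbols.
#' @return upper-tail p-value in (0, 1].
#' @examples
#' hypergeomTest(LETTERS[1:5], LETTERS[1:5], LETTERS)
#' @export
hypergeomTest <- function(termGenes, queryGenes, universe) {
  universe <- unique(toupper(universe))
  if (!length(universe)) stop("empty universe")
  term <- intersect(unique(toupper(termGenes)), universe)
  query <- intersect(unique(toupper(queryGenes)), universe)
  k <- length(intersect(term, query))
  if (k == 0) return(1)
  phyper(k - 1, length(term), length(universe) - length(term),
         length(query), lower.tail = FALSE)
}

#' Multiple-testing adjustment of enrichment p-values
#'
#' Benjamini-Hochberg step-up by default; output has the same length and
#' order as the input and is clipped to [0, 1].
#'
#' @param pvals numeric vector of raw p-values in [0, 1].
#' @param method an adjustment method of [stats::p.adjust()] (default
#'   \code{"BH"}).
#' @return adjusted p-values.
#' @examples
#' adjustPvalues(c(0.01, 0.02, 0.03, 0.04))
#' @export
adjustPvalues <- function(pvals, method = "BH") {
  stopifnot(all(pvals >= 0 & pvals <= 1, na.rm = TRUE))
  pmin(p.adjust(pvals, method = method), 1)
}

#' Gene-set over-representation analysis
#'
#' Tests every term for over-representation of the query genes by the
#' hypergeometric upper-tail test, adjusts p-values (pooled across all
#' terms, and additionally within each source), and ranks by pooled
#' adjusted p then term id.  Both the term's size in the universe and its
#' overlap with the query are reported as separate columns.
#'
#' @param query character vector of (already expanded) query genes.
#' @param termSets named list of term gene-symbol vectors.
#' @param universe gene universe; default the union of all term sets.
#' @param padjThreshold significance threshold on the pooled adjusted p
#'   (default 0.01).
#' @param source optional named character vector (term id -> source
#'   label); default the prefix of the term id before the first colon.
#' @param method adjustment method recorded in the result's
#'   \code{"adjust_method"} attribute (default \code{"BH"}).
#' @return data.frame with columns \code{term_id, source, term_size,
#'   overlap, p_value, p_adj, p_adj_source, significant}, ordered by
#'   \code{p_adj} then \code{term_id}.
#' @examples
#' ts <- taTermSets()
#' enr <- enrichTerms(expandGeneSet(variants(taFixture())$gene,
#'                                  ppiGraph(taPpiEdges())),
#'                    ts$sets, source = ts$source)
#' head(enr)
#' @export
enrichTerms <- function(query, termSets, universe = NULL,
                        padjThreshold = 0.01, source = NULL,
                        method = "BH") {
  stopifnot(padjThreshold > 0, padjThreshold <= 1)
  if (is.null(universe)) universe <- unique(toupper(unlist(termSets)))
  universe <- unique(toupper(universe))
  query <- intersect(unique(toupper(query)), universe)
  if (is.null(source))
    source <- setNames(sub(":.*$", "", names(termSets)), names(termSets))
  res <- data.frame(
    term_id = names(termSets),
    source = unname(source[names(termSets)]),
    term_size = vapply(termSets, function(tg)
      length(intersect(unique(toupper(tg)), universe)), integer(1)),
    overlap = vapply(termSets, function(tg)
      length(intersect(intersect(unique(toupper(tg)), universe), query)),
      integer(1)),
    p_value = vapply(termSets, hypergeomTest, numeric(1),
                     queryGenes = query, universe = universe),
    row.names = NULL
  )
  res$p_adj <- adjustPvalues(res$p_value, method)
  res$p_adj_source <- res$p_value
  for (src in unique(res$source)) {
    i <- res$source == src
    res$p_adj_source[i] <- adjustPvalues(res$p_value[i], method)
  }
  res$significant <- res$p_adj < padjThreshold
  res <- res[order(res$p_adj, res$term_id, method = "radix"), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "adjust_method") <- method
  attr(res, "query_size") <- length(query)
  attr(res, "universe_size") <- length(universe)
  res
}
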