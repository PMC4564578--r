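#' Bipartite gene-pathway network from significant enrichment results
#'
#' Connects each significantly enriched pathway term to the genes of the
#' input list it overlaps. Pathway vertices carry `type = TRUE`, gene
#' vertices `type = FALSE` (igraph bipartite convention); a pathway's
#' degree equals its overlap size, and a gene shared by several pathways
#' accumulates degree accordingly.
#'
#' @param enrichment an [enrich_library()] table computed on a
#'   pathway-category library.
#' @param gene_list the (human-symbol) gene list the enrichment was run on.
#' @param library the [gene_set_library()] behind the enrichment table.
#' @return an [igraph::graph] object (empty if nothing is significant).
#' @export
build_gene_pathway_network <- function(enrichment, gene_list, library) {
  stopifnot(inherits(enrichment, "enrichment_table"),
            inherits(library, "gene_set_library"))
  sig <- enrichment$term[enrichment$significant]
  edges <- do.call(rbind, lapply(sig, function(tm) {
    genes <- intersect(library$terms[[tm]], gene_list)
    if (length(genes) == 0) return(NULL)
    data.frame(pathway = tm, gene = genes, stringsAsFactors = FALSE)
  }))
  if (is.null(edges)) {
    g <- igraph::make_empty_graph(directed = FALSE)
    return(g)
  }
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(
      name = c(unique(edges$pathway), unique(edges$gene)),
      type = c(rep(TRUE, length(unique(edges$pathway))),
               rep(FALSE, length(unique(edges$gene))))))
  g
}

#' Write a network as GraphML and as an edge-list TSV
#'
#' @param graph an igraph object.
#' @param graphml_file,edges_file output paths.
#' @return `graphml_file`, invisibly.
#' @export
write_network <- function(graph, graphml_file, edges_file = NULL) {
  igraph::write_graph(graph, graphml_file, format = "graphml")
  if (!is.null(edges_file)) {
    el <- igraph::as_edgelist(graph)
    write_tsv(data.frame(pathway = el[, 1], gene = el[, 2],
                         stringsAsFactors = FALSE), edges_file)
  }
  invisible(graphml_file)
}
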