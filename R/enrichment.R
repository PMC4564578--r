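#' Map rat gene symbols to human orthologs
#'
#' Symbols absent from the map are dropped (with a message); many-to-one
#' collisions collapse to a single occurrence; the result is a deduplicated
#' character vector of upper-case human symbols, in first-occurrence order.
#'
#' @param rat_symbols character vector of rat symbols.
#' @param map data.frame with columns `rat_symbol`, `human_symbol`.
#' @param quiet suppress the dropped-symbol message.
#' @return character vector of human symbols.
#' @export
map_orthologs <- function(rat_symbols, map, quiet = FALSE) {
  if (is.null(map) || nrow(map) == 0) {
    stop("ortholog map is empty", call. = FALSE)
  }
  human <- map$human_symbol[match(rat_symbols, map$rat_symbol)]
  # symbols already on the human side pass through (idempotence)
  direct <- is.na(human) & rat_symbols %in% map$human_symbol
  human[direct] <- rat_symbols[direct]
  n_dropped <- sum(is.na(human))
  if (n_dropped > 0 && !quiet) {
    message(n_dropped, " symbol(s) without a human ortholog dropped")
  }
  unique(toupper(human[!is.na(human)]))
}

#' Fisher over-representation test of a gene list against one term
#'
#' One-sided hypergeometric upper tail: with universe size `N`, term size
#' `K` (after intersecting the term with the universe), list size `n` and
#' overlap `k`, `p = P(X >= k)` for `X ~ Hypergeometric(N, K, n)`.
#'
#' @param gene_list character vector (must be a subset of `universe` - the
#'   background must match the tested population).
#' @param term_set character vector of term member genes.
#' @param universe background gene symbols (the expressed-gene universe).
#' @return list with `overlap`, `pvalue`, `term_size`, `list_size`,
#'   `universe_size`.
#' @export
fisher_enrich <- function(gene_list, term_set, universe) {
  universe <- unique(universe)
  gene_list <- unique(gene_list)
  if (!all(gene_list %in% universe)) {
    stop("gene list is not a subset of the universe", call. = FALSE)
  }
  term <- intersect(unique(term_set), universe)
  k <- length(intersect(gene_list, term))
  N <- length(universe)
  K <- length(term)
  n <- length(gene_list)
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  list(overlap = k, pvalue = p, term_size = K, list_size = n,
       universe_size = N)
}

# Precomputed index of a library against a universe: term members as
# positions in the universe, flattened with a parallel term-id vector so a
# single tabulate() yields every term's overlap with a list.
library_index <- function(library, universe) {
  idx <- lapply(library$terms, function(g) which(universe %in% g))
  list(all_idx = unlist(idx, use.names = FALSE),
       term_id = rep.int(seq_along(idx), lengths(idx)),
       K = lengths(idx),
       n_terms = length(idx))
}

# Overlap of every term with a list given as a logical vector over the
# universe; used by both the observed pass and the null-rank draws.
term_overlaps <- function(lix, in_list) {
  tabulate(lix$term_id[in_list[lix$all_idx]], nbins = lix$n_terms)
}

#' Null rank statistics of a library's terms under random gene lists
#'
#' The rank-deviation correction for set-size bias: large gene sets reach
#' small Fisher p-values even for random input lists, so each term's
#' expected p-value rank is estimated empirically. For each of `B` uniform
#' random lists of the given size, Fisher p-values are computed for every
#' term and the terms are ranked ascending by p (ties receive their average
#' rank); the per-term mean and standard deviation of these ranks form the
#' reference for [rank_zscore()].
#'
#' @param library a [gene_set_library()].
#' @param universe background gene symbols.
#' @param list_size size of each random list.
#' @param B number of null draws (>= 20).
#' @param seed integer seed making the draws reproducible.
#' @return data.frame of class `null_rank_stats` with columns `term`,
#'   `mean_rank`, `sd_rank`; `B` and `seed` are stored as attributes.
#' @export
null_rank_stats <- function(library, universe, list_size, B = 800,
                            seed = 1L) {
  stopifnot(inherits(library, "gene_set_library"))
  universe <- unique(universe)
  if (B < 20) stop("B must be >= 20", call. = FALSE)
  if (list_size > length(universe)) {
    stop("list_size exceeds the universe", call. = FALSE)
  }
  lix <- library_index(library, universe)
  N <- length(universe)
  K <- lix$K
  ranks <- with_seed(derive_seed(seed, "null_ranks"), {
    vapply(seq_len(B), function(b) {
      in_list <- logical(N)
      in_list[sample.int(N, list_size)] <- TRUE
      k <- term_overlaps(lix, in_list)
      p <- stats::phyper(k - 1, K, N - K, list_size, lower.tail = FALSE)
      rank(p, ties.method = "average")
    }, numeric(lix$n_terms))
  })
  out <- data.frame(term = names(library$terms),
                    mean_rank = rowMeans(ranks),
                    sd_rank = apply(ranks, 1, stats::sd),
                    stringsAsFactors = FALSE)
  attr(out, "n_draws") <- B
  attr(out, "seed") <- seed
  class(out) <- c("null_rank_stats", "data.frame")
  out
}

#' Rank-deviation Z-score
#'
#' `z = (observed_rank - mean_rank) / sd_rank` per term: a term ranking
#' better (smaller) than its null expectation gets a negative z. Terms with
#' `sd_rank = 0` get `NA` (degenerate null).
#'
#' @param observed_ranks numeric vector of observed p-value ranks, in the
#'   order of `null$term`.
#' @param null a [null_rank_stats()] table.
#' @return numeric vector of z-scores.
#' @export
rank_zscore <- function(observed_ranks, null) {
  stopifnot(length(observed_ranks) == nrow(null))
  z <- (observed_ranks - null$mean_rank) / null$sd_rank
  z[null$sd_rank == 0] <- NA_real_
  z
}

#' Combined enrichment score
#'
#' `c = ln(p) * z` (natural log): for a small p-value and a negative
#' z-score the combined score is large and positive, ranking terms by
#' joint evidence from both statistics. `p = 0` is clamped to the smallest
#' positive double with a warning.
#'
#' @param pvalue Fisher p-value(s) in (0, 1].
#' @param z rank-deviation z-score(s).
#' @return numeric combined score(s).
#' @export
combined_score <- function(pvalue, z) {
  if (any(pvalue < 0 | pvalue > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  if (any(pvalue == 0, na.rm = TRUE)) {
    warning("p-value of 0 clamped to the smallest positive double")
    pvalue[pvalue == 0] <- .Machine$double.xmin
  }
  log(pvalue) * z
}

#' Enrichment of a gene list against a whole library
#'
#' For every term: Fisher over-representation p-value, Benjamini-Hochberg
#' adjustment across the library's terms, rank-deviation z-score against
#' [null_rank_stats()], and the combined score `ln(p) * z`. A term is
#' significant iff `padj < p_cutoff` and `z < z_cutoff` (both strict). Rows
#' are ordered by combined score, descending.
#'
#' @param gene_list character vector of (human) gene symbols, a subset of
#'   `universe`.
#' @param library a [gene_set_library()].
#' @param universe background gene symbols.
#' @param p_cutoff adjusted p-value cutoff (default 0.05).
#' @param z_cutoff z-score cutoff (default -1.5).
#' @param B,seed null-draw parameters, see [null_rank_stats()].
#' @return data.frame of class `enrichment_table` with columns `term`,
#'   `factor_group`, `overlap`, `term_size`, `list_size`, `universe_size`,
#'   `pvalue`, `padj`, `zscore`, `combined`, `significant`.
#' @export
enrich_library <- function(gene_list, library, universe,
                           p_cutoff = 0.05, z_cutoff = -1.5,
                           B = 800, seed = 1L) {
  stopifnot(inherits(library, "gene_set_library"))
  universe <- unique(universe)
  gene_list <- unique(gene_list)
  empty <- length(gene_list) == 0
  if (empty) {
    warning("empty gene list: returning empty enrichment table")
  }
  if (!empty && !all(gene_list %in% universe)) {
    stop("gene list is not a subset of the universe", call. = FALSE)
  }
  lix <- library_index(library, universe)
  N <- length(universe)
  K <- lix$K
  n <- length(gene_list)
  in_list <- universe %in% gene_list
  k <- term_overlaps(lix, in_list)
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)

  if (empty) {
    out <- data.frame(term = character(0), factor_group = character(0),
                      overlap = integer(0), term_size = integer(0),
                      list_size = integer(0), universe_size = integer(0),
                      pvalue = numeric(0), padj = numeric(0),
                      zscore = numeric(0), combined = numeric(0),
                      significant = logical(0), stringsAsFactors = FALSE)
    class(out) <- c("enrichment_table", "data.frame")
    return(out)
  }

  null <- null_rank_stats(library, universe, n, B = B, seed = seed)
  obs_rank <- rank(p, ties.method = "average")
  z <- rank_zscore(obs_rank, null)
  padj <- adjust_bh(p)
  comb <- suppressWarnings(combined_score(pmax(p, .Machine$double.xmin), z))
  sig <- !is.na(z) & padj < p_cutoff & z < z_cutoff

  out <- data.frame(term = names(library$terms),
                    factor_group = unname(library$factor_group),
                    overlap = k,
                    term_size = K,
                    list_size = n,
                    universe_size = N,
                    pvalue = p,
                    padj = padj,
                    zscore = z,
                    combined = comb,
                    significant = sig,
                    stringsAsFactors = FALSE)
  out <- out[order(out$combined, decreasing = TRUE), ]
  rownames(out) <- NULL
  attr(out, "library_id") <- library$library_id
  attr(out, "cutoffs") <- c(p_cutoff = p_cutoff, z_cutoff = z_cutoff)
  attr(out, "B") <- B
  attr(out, "seed") <- seed
  class(out) <- c("enrichment_table", "data.frame")
  out
}

#' Genes of the significantly enriched terms of given factor groups
#'
#' @param enrichment an [enrich_library()] table.
#' @param library the library the table was computed from.
#' @param groups factor-group labels to aggregate over.
#' @return list with `genes` (union of member genes over significant terms)
#'   and `terms` (the significant term ids).
#' @export
significant_target_genes <- function(enrichment, library, groups) {
  stopifnot(inherits(enrichment, "enrichment_table"),
            inherits(library, "gene_set_library"))
  missing_groups <- setdiff(groups, enrichment$factor_group)
  if (length(missing_groups) > 0) {
    stop("factor group(s) absent from the enrichment table: ",
         paste(missing_groups, collapse = ", "), call. = FALSE)
  }
  sig_terms <- enrichment$term[enrichment$significant &
                                 enrichment$factor_group %in% groups]
  genes <- unique(unlist(library$terms[sig_terms], use.names = FALSE))
  list(genes = genes %||% character(0), terms = sig_terms)
}
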