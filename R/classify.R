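CHIP_LEVELS <- c("REST_only", "REST_and_PRC", "PRC_only", "unknown")
ROADMAP_LEVELS <- c("H3K4me1_only", "H3K4me1_and_H3K27me3",
                    "H3K27me3_only", "unknown")

#' Per-gene target calls from enrichment evidence
#'
#' Flags each differentially expressed gene as a potential target of REST,
#' of the Polycomb repressive complex (any of the Suz12/Ezh2/Rnf2/Jarid2
#' subunit groups), and as carrying the H3K4me1 or H3K27me3 mark. A flag is
#' set iff the gene's human ortholog belongs to at least one significantly
#' enriched term of the corresponding factor group - the "immunoprecipitated
#' in at least one cell type and context" rule. Genes without a human
#' ortholog keep all flags `FALSE` (they end up in the `unknown` subfamily)
#' so classification totals match the DE table.
#'
#' @param genes character vector of (rat) DE gene ids, one direction.
#' @param map ortholog map (`rat_symbol`, `human_symbol`).
#' @param chip_enrichment,chip_library enrichment table and library for the
#'   TF ChIP evidence.
#' @param roadmap_enrichment,roadmap_library enrichment table and library
#'   for the histone-mark evidence.
#' @param prc_subunits factor-group names treated as PRC evidence.
#' @return data.frame of class `target_calls`: `gene`, `human_symbol`,
#'   `is_REST_target`, `is_PRC_target`, `has_H3K4me1`, `has_H3K27me3`, and
#'   comma-separated supporting term ids per flag.
#' @export
call_targets <- function(genes, map, chip_enrichment, chip_library,
                         roadmap_enrichment, roadmap_library,
                         prc_subunits = PRC_SUBUNITS) {
  human <- map$human_symbol[match(genes, map$rat_symbol)]
  n_unmapped <- sum(is.na(human))
  if (n_unmapped > 0) {
    message(n_unmapped,
            " gene(s) without ortholog classified as 'unknown'")
  }
  evidence <- list(
    REST = significant_target_genes(chip_enrichment, chip_library, "REST"),
    PRC = significant_target_genes(chip_enrichment, chip_library,
                                   prc_subunits),
    H3K4me1 = significant_target_genes(roadmap_enrichment, roadmap_library,
                                       "H3K4me1"),
    H3K27me3 = significant_target_genes(roadmap_enrichment,
                                        roadmap_library, "H3K27me3"))
  flag <- function(ev) !is.na(human) & human %in% ev$genes
  support <- function(ev, lib) {
    vapply(human, function(h) {
      if (is.na(h)) return("")
      hit <- vapply(ev$terms, function(tm) h %in% lib$terms[[tm]],
                    logical(1))
      paste(ev$terms[hit], collapse = ",")
    }, character(1), USE.NAMES = FALSE)
  }
  out <- data.frame(
    gene = genes,
    human_symbol = human,
    is_REST_target = flag(evidence$REST),
    is_PRC_target = flag(evidence$PRC),
    has_H3K4me1 = flag(evidence$H3K4me1),
    has_H3K27me3 = flag(evidence$H3K27me3),
    rest_terms = support(evidence$REST, chip_library),
    prc_terms = support(evidence$PRC, chip_library),
    h3k4me1_terms = support(evidence$H3K4me1, roadmap_library),
    h3k27me3_terms = support(evidence$H3K27me3, roadmap_library),
    stringsAsFactors = FALSE)
  class(out) <- c("target_calls", "data.frame")
  out
}

#' Partition target calls into the four mechanistic subfamilies
#'
#' Under ChIP evidence the subfamilies are `REST_only`, `REST_and_PRC`,
#' `PRC_only` and `unknown`; under histone-mark (roadmap) evidence they are
#' `H3K4me1_only`, `H3K4me1_and_H3K27me3`, `H3K27me3_only` and `unknown`.
#' The mapping is the plain truth table of the two flags: (A, not B) ->
#' A_only, (A, B) -> A_and_B, (not A, B) -> B_only, (neither) -> unknown.
#' Labels are exhaustive and mutually exclusive, so the subfamily counts
#' always sum to the number of genes.
#'
#' @param calls a [call_targets()] table.
#' @param direction `"down"` or `"up"` (metadata carried on the result).
#' @param evidence `"chip"` or `"roadmap"`.
#' @return data.frame of class `subfamily_partition` with columns `gene`,
#'   `label`; attributes `direction`, `evidence`, `levels`.
#' @export
partition_subfamilies <- function(calls, direction = c("down", "up"),
                                  evidence = c("chip", "roadmap")) {
  stopifnot(inherits(calls, "target_calls"))
  direction <- match.arg(direction)
  evidence <- match.arg(evidence)
  if (evidence == "chip") {
    a <- calls$is_REST_target; b <- calls$is_PRC_target
    lv <- CHIP_LEVELS
  } else {
    a <- calls$has_H3K4me1; b <- calls$has_H3K27me3
    lv <- ROADMAP_LEVELS
  }
  label <- ifelse(a & !b, lv[1],
                  ifelse(a & b, lv[2], ifelse(!a & b, lv[3], lv[4])))
  out <- data.frame(gene = calls$gene,
                    label = factor(label, levels = lv),
                    stringsAsFactors = FALSE)
  attr(out, "direction") <- direction
  attr(out, "evidence") <- evidence
  attr(out, "levels") <- lv
  class(out) <- c("subfamily_partition", "data.frame")
  out
}

#' Subfamily percentages, rounded half-up to one decimal
#'
#' `100 * count / total` per label, following the reporting convention of
#' the two-clone analysis (e.g. 261 targets of 886 downregulated genes are
#' printed as 29.5).
#'
#' @param x a [partition_subfamilies()] result, or a named numeric vector
#'   of counts.
#' @param total denominator; defaults to `sum(x)` for a count vector or the
#'   number of genes for a partition.
#' @return named numeric vector of percentages (one decimal).
#' @export
subfamily_percentages <- function(x, total = NULL) {
  if (inherits(x, "subfamily_partition")) {
    counts <- table(x$label)
  } else if (is.numeric(x)) {
    counts <- x
  } else {
    stop("x must be a subfamily_partition or a named count vector",
         call. = FALSE)
  }
  if (sum(counts) == 0 && is.null(total)) {
    stop("empty partition: percentages undefined", call. = FALSE)
  }
  total <- total %||% sum(counts)
  stats::setNames(round_half_up(100 * as.numeric(counts) / total, 1),
                  names(counts))
}

#' Flow matrix between the ChIP- and histone-mark-based partitions
#'
#' Cross-tabulates, over the same genes, the subfamily label under ChIP
#' evidence (rows) against the label under histone-mark evidence
#' (columns). Cell (i, j) counts genes labeled i by the first partition and
#' j by the second; row and column marginals equal the input subfamily
#' sizes, and the grand total equals the direction's DE gene count.
#'
#' @param chip,roadmap two [partition_subfamilies()] results over the same
#'   gene set.
#' @return integer matrix of class `flow_matrix` with `row_marginals` and
#'   `col_marginals` attributes.
#' @export
flow_matrix <- function(chip, roadmap) {
  stopifnot(inherits(chip, "subfamily_partition"),
            inherits(roadmap, "subfamily_partition"))
  if (!setequal(chip$gene, roadmap$gene) ||
      nrow(chip) != nrow(roadmap)) {
    stop("partitions cover different gene sets", call. = FALSE)
  }
  ord <- match(chip$gene, roadmap$gene)
  tab <- table(chip = chip$label, roadmap = roadmap$label[ord])
  m <- matrix(as.integer(tab), nrow = nrow(tab),
              dimnames = dimnames(tab))
  structure(m,
            row_marginals = stats::setNames(as.integer(rowSums(m)),
                                            rownames(m)),
            col_marginals = stats::setNames(as.integer(colSums(m)),
                                            colnames(m)),
            direction = attr(chip, "direction"),
            class = c("flow_matrix", class(m)))
}

#' @export
print.flow_matrix <- function(x, ...) {
  cat("flow_matrix (", attr(x, "direction") %||% "?", "-regulated, ",
      sum(x), " genes): ChIP rows x histone-mark columns\n", sep = "")
  print(unclass(x))
  invisible(x)
}
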