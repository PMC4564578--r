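#' Median log2 fold change of a gene group
#'
#' Sample median (midpoint of the two central values for even sizes) of
#' the fold changes of the given genes, looked up in a DE table.
#'
#' @param de a [run_de()] table.
#' @param genes character vector of gene ids; must be present in `de`.
#' @return the median log2 fold change.
#' @export
median_log2fc <- function(de, genes) {
  if (length(genes) == 0) stop("gene group is empty", call. = FALSE)
  idx <- match(genes, de$gene)
  if (anyNA(idx)) {
    stop("gene(s) absent from the DE table: ",
         paste(utils::head(genes[is.na(idx)], 5), collapse = ", "),
         call. = FALSE)
  }
  stats::median(de$log2FoldChange[idx])
}

#' Two-sample Wilcoxon/Mann-Whitney rank-sum test
#'
#' Two-sided throughout. The null distribution is exact (full enumeration
#' of rank assignments) when the combined sample size is at most 12 and
#' there are no ties; otherwise the normal approximation with tie and
#' continuity corrections is used. Two identical groups give p = 1.
#'
#' @param valuesA,valuesB numeric vectors, both nonempty.
#' @param exact_max_n largest combined sample size still enumerated.
#' @return two-sided p-value in (0, 1].
#' @export
wilcoxon_rank_sum <- function(valuesA, valuesB, exact_max_n = 12) {
  if (length(valuesA) == 0 || length(valuesB) == 0) {
    stop("both groups must be nonempty", call. = FALSE)
  }
  combined <- c(valuesA, valuesB)
  if (length(unique(combined)) == 1L) return(1)
  ties <- anyDuplicated(combined) > 0
  exact <- !ties && length(combined) <= exact_max_n
  ht <- suppressWarnings(
    stats::wilcox.test(valuesA, valuesB, alternative = "two.sided",
                       exact = exact, correct = TRUE))
  min(1, ht$p.value)
}

#' Group comparison container
#'
#' @param labels group labels.
#' @param n group sizes.
#' @param medians median log2 fold change per group.
#' @param p two-sided Wilcoxon p-value.
#' @return a `group_comparison` object.
#' @keywords internal
group_comparison <- function(labels, n, medians, p) {
  structure(list(groups = data.frame(label = labels, n = n,
                                     median_log2fc = medians,
                                     stringsAsFactors = FALSE),
                 wilcoxon_p = p,
                 test = "two-sample Wilcoxon rank-sum, two-sided"),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  print(x$groups, row.names = FALSE)
  cat("Wilcoxon p value:", format_pvalue(x$wilcoxon_p), "\n")
  invisible(x)
}

#' Compare the median fold change of two gene groups
#'
#' @param de a [run_de()] table.
#' @param groupA,groupB gene id vectors.
#' @param labels length-2 character labels for the groups.
#' @return a `group_comparison` with per-group sizes, medians and the
#'   two-sided Wilcoxon p-value.
#' @export
compare_group_folds <- function(de, groupA, groupB,
                                labels = c("A", "B")) {
  idxA <- match(groupA, de$gene)
  idxB <- match(groupB, de$gene)
  if (anyNA(idxA) || anyNA(idxB)) {
    stop("gene(s) absent from the DE table", call. = FALSE)
  }
  va <- de$log2FoldChange[idxA]
  vb <- de$log2FoldChange[idxB]
  group_comparison(labels, c(length(va), length(vb)),
                   c(stats::median(va), stats::median(vb)),
                   wilcoxon_rank_sum(va, vb))
}

#' Median-fold shift of a transcription factor's targets
#'
#' Splits the upregulated DE genes into potential targets of the given TF
#' (member of at least one significantly enriched term of its factor
#' group) and nontargets, and compares the two groups' median log2 fold
#' changes by Wilcoxon rank-sum test - the targets-versus-nontargets shift
#' analysis used for upregulation-driving activators such as Smad3 and
#' Myod1.
#'
#' @param tf_group the TF's factor-group label (e.g. `"SMAD3"`).
#' @param enrichment enrichment table of the upregulated list on the ChIP
#'   library.
#' @param library the ChIP [gene_set_library()].
#' @param de a [run_de()] table.
#' @param up_genes upregulated gene ids (rat symbols).
#' @param map ortholog map.
#' @return a `group_comparison` (labels `target`/`nontarget`), or `NULL`
#'   with a warning when the TF has no significantly enriched term or the
#'   split is degenerate.
#' @export
tf_target_shift <- function(tf_group, enrichment, library, de, up_genes,
                            map) {
  ev <- significant_target_genes(enrichment, library, tf_group)
  if (length(ev$terms) == 0) {
    warning("no significantly enriched term for ", tf_group,
            ": comparison skipped")
    return(NULL)
  }
  human <- map$human_symbol[match(up_genes, map$rat_symbol)]
  is_target <- !is.na(human) & human %in% ev$genes
  if (all(is_target) || !any(is_target)) {
    warning("degenerate target/nontarget split for ", tf_group,
            ": comparison skipped")
    return(NULL)
  }
  cmp <- compare_group_folds(de, up_genes[is_target], up_genes[!is_target],
                             labels = c("target", "nontarget"))
  cmp$tf <- tf_group
  cmp
}
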