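#' Read and write gene-set libraries in GMT format
#'
#' GMT is the standard tab-separated gene-set format: one term per line,
#' `term <TAB> description <TAB> gene1 <TAB> gene2 ...`. The description
#' column carries the term's factor group, so a round trip preserves the
#' library structure.
#'
#' @param library a [gene_set_library()].
#' @param file path to a `.gmt` file.
#' @param library_id,category metadata for the library being read.
#' @return `write_gmt()` returns `file` invisibly; `read_gmt()` returns a
#'   [gene_set_library()].
#' @export
write_gmt <- function(library, file) {
  stopifnot(inherits(library, "gene_set_library"))
  lines <- vapply(names(library$terms), function(nm) {
    paste(c(nm, library$factor_group[[nm]], library$terms[[nm]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, file)
  invisible(file)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(file, library_id = basename(file),
                     category = "pathway") {
  lines <- readLines(file)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("empty GMT file: ", file, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(fields, length, 1L) < 3L
  if (any(bad)) {
    stop("malformed GMT line(s): ", paste(which(bad), collapse = ", "),
         call. = FALSE)
  }
  terms <- lapply(fields, function(f) f[-(1:2)])
  names(terms) <- vapply(fields, `[[`, character(1), 1L)
  groups <- vapply(fields, `[[`, character(1), 2L)
  gene_set_library(library_id, category, terms, groups)
}

#' Write or read a count matrix as TSV
#'
#' The counts file has gene ids in the first column (`gene`) and one column
#' per sample; the companion samples file maps `sample` to `condition`.
#'
#' @param cm a [count_matrix()].
#' @param counts_file,samples_file TSV paths.
#' @return `read_count_matrix()` returns a [count_matrix()].
#' @export
write_count_matrix <- function(cm, counts_file, samples_file) {
  stopifnot(inherits(cm, "count_matrix"))
  df <- data.frame(gene = rownames(cm$counts), cm$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, counts_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(sample = colnames(cm$counts), condition = cm$condition),
    samples_file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(counts_file)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(counts_file, samples_file) {
  df <- utils::read.delim(counts_file, check.names = FALSE,
                          stringsAsFactors = FALSE)
  samples <- utils::read.delim(samples_file, stringsAsFactors = FALSE)
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- df[[1]]
  ord <- match(colnames(counts), samples$sample)
  if (anyNA(ord)) stop("samples file does not cover all count columns",
                       call. = FALSE)
  count_matrix(counts, factor(samples$condition[ord],
                              levels = unique(samples$condition)))
}

#' Write or read an ortholog map as TSV
#'
#' @param map a data.frame with columns `rat_symbol`, `human_symbol`.
#' @param file TSV path.
#' @export
write_ortholog_map <- function(map, file) {
  stopifnot(all(c("rat_symbol", "human_symbol") %in% names(map)))
  utils::write.table(map[c("rat_symbol", "human_symbol")], file,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_ortholog_map
#' @export
read_ortholog_map <- function(file) {
  map <- utils::read.delim(file, stringsAsFactors = FALSE)
  if (!all(c("rat_symbol", "human_symbol") %in% names(map))) {
    stop("ortholog map must have columns rat_symbol, human_symbol",
         call. = FALSE)
  }
  map
}

write_tsv <- function(df, file) {
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
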