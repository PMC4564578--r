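LIBRARY_CATEGORIES <- c("tf_chip", "histone_mark", "pathway")
PRC_SUBUNITS <- c("SUZ12", "EZH2", "RNF2", "JARID2")

#' Gene-set library container
#'
#' A named collection of gene-set terms (human gene symbols), tagged with a
#' category (`tf_chip`, `histone_mark`, `pathway`) and, per term, a factor
#' group (e.g. `REST`, `SUZ12`, `H3K4me1`, `SMAD3`, `DECOY_TF01`). The
#' factor group is what downstream target calling aggregates over: a gene is
#' a REST target if it sits in at least one significantly enriched term of
#' the `REST` group.
#'
#' @param library_id identifier for the library.
#' @param category one of `tf_chip`, `histone_mark`, `pathway`.
#' @param terms named list of character vectors (upper-case gene symbols).
#' @param factor_group character vector, one group label per term (recycled
#'   from term names if missing); must be named consistently with `terms`.
#' @return an object of class `gene_set_library`.
#' @export
gene_set_library <- function(library_id, category, terms, factor_group) {
  category <- match.arg(category, LIBRARY_CATEGORIES)
  if (length(terms) == 0 || is.null(names(terms)) ||
      anyDuplicated(names(terms))) {
    stop("terms must be a non-empty, uniquely named list", call. = FALSE)
  }
  if (any(vapply(terms, length, 1L) == 0L)) {
    stop("term gene sets must be nonempty", call. = FALSE)
  }
  terms <- lapply(terms, function(g) sort(unique(toupper(as.character(g)))))
  if (length(factor_group) != length(terms)) {
    stop("factor_group must give one group per term", call. = FALSE)
  }
  factor_group <- stats::setNames(as.character(factor_group), names(terms))
  structure(list(library_id = library_id, category = category,
                 terms = terms, factor_group = factor_group),
            class = "gene_set_library")
}

#' @export
print.gene_set_library <- function(x, ...) {
  cat("gene_set_library '", x$library_id, "' (", x$category, "): ",
      length(x$terms), " terms, ",
      length(unique(x$factor_group)), " factor groups\n", sep = "")
  invisible(x)
}

# Union of member genes over the terms of one or more factor groups,
# optionally restricted to significant terms of an enrichment table.
group_term_names <- function(library, groups) {
  names(library$factor_group)[library$factor_group %in% groups]
}

#' Generate synthetic gene-set libraries with planted target structure
#'
#' Builds the three libraries the pipeline consumes, keyed by human symbol:
#' \describe{
#'   \item{tf_chip}{terms for the `REST` group, the four Polycomb subunit
#'     groups (`SUZ12`, `EZH2`, `RNF2`, `JARID2`, sharing one planted PRC
#'     target pool, as subunits of one complex co-bind), decoy TF groups
#'     sampled uniformly, and one group per configured activator TF.}
#'   \item{histone_mark}{`H3K4me1` terms (planted over REST-involving genes,
#'     the mark being a substrate of the REST-complex demethylase LSD1) and
#'     `H3K27me3` terms (planted over PRC-involving genes).}
#'   \item{pathway}{a few terms planted over random subsets of each
#'     direction's regulated genes, plus uniform decoy pathways.}
#' }
#'
#' Membership model: each planted target gene of a factor enters each of the
#' factor's terms independently with probability `library_sensitivity`.
#' Background membership is modeled as systematic per-factor false targets:
#' every gene independently becomes a spurious target of a factor with
#' probability `library_background_rate` and then appears in all of that
#' factor's terms (hyper-ChIPable regions and promiscuous loci recur across
#' datasets of the same factor, they do not resample per dataset). Expected
#' term size is therefore `sensitivity * n_planted + background * n_other`.
#' Decoy terms sample every gene independently at the background rate.
#'
#' @param truth a [generate_truth()] table.
#' @param config the matching [sim_config()].
#' @param ortholog_map optional map from [generate_ortholog_map()]; genes
#'   absent from the map cannot appear in any library (databases only know
#'   mapped symbols). `NULL` upper-cases the rat symbols directly.
#' @return named list of three [gene_set_library()] objects
#'   (`tf_chip`, `histone_mark`, `pathway`).
#' @export
generate_libraries <- function(truth, config, ortholog_map = NULL) {
  validate_sim_config(config)
  stopifnot(inherits(truth, "truth_table"))
  if (nrow(truth) == 0) stop("truth table is empty", call. = FALSE)

  if (is.null(ortholog_map)) {
    sym <- toupper(truth$gene_id)
  } else {
    sym <- ortholog_map$human_symbol[match(truth$gene_id,
                                           ortholog_map$rat_symbol)]
  }
  mapped <- !is.na(sym)
  de <- truth$direction != "null"
  sens <- config$library_sensitivity
  bg <- config$library_background_rate
  tpg <- config$n_terms_per_group

  rest_planted <- mapped & de & truth$subfamily %in%
    c("REST_only", "REST_and_PRC")
  prc_planted <- mapped & de & truth$subfamily %in%
    c("REST_and_PRC", "PRC_only")

  with_seed(derive_seed(config$seed, "libraries"), {
    spurious <- function(planted) {
      mapped & !planted & stats::runif(nrow(truth)) < bg
    }
    planted_terms <- function(group, planted, n_terms = tpg,
                              suffix = "ds") {
      spur <- sym[spurious(planted)]
      core <- sym[planted]
      terms <- lapply(seq_len(n_terms), function(i) {
        members <- c(core[stats::runif(length(core)) < sens], spur)
        if (length(members) == 0) members <- sample(sym[mapped], 1L)
        members
      })
      names(terms) <- paste0(group, "_", suffix, seq_len(n_terms))
      terms
    }
    uniform_terms <- function(group, n_terms = tpg) {
      terms <- lapply(seq_len(n_terms), function(i) {
        members <- sym[mapped & stats::runif(nrow(truth)) < bg]
        if (length(members) == 0) members <- sample(sym[mapped], 1L)
        members
      })
      names(terms) <- paste0(group, "_ds", seq_len(n_terms))
      terms
    }

    # --- TF ChIP library -------------------------------------------------
    chip_terms <- planted_terms("REST", rest_planted)
    chip_groups <- rep("REST", tpg)
    prc_spur <- spurious(prc_planted)  # one spurious pool for the complex
    prc_core <- sym[prc_planted]
    prc_spur_sym <- sym[prc_spur]
    for (su in PRC_SUBUNITS) {
      tt <- lapply(seq_len(tpg), function(i) {
        c(prc_core[stats::runif(length(prc_core)) < sens], prc_spur_sym)
      })
      names(tt) <- paste0(su, "_ds", seq_len(tpg))
      chip_terms <- c(chip_terms, tt)
      chip_groups <- c(chip_groups, rep(su, tpg))
    }
    if (config$n_decoy_tfs > 0) {
      for (d in seq_len(config$n_decoy_tfs)) {
        grp <- sprintf("DECOY_TF%02d", d)
        chip_terms <- c(chip_terms, uniform_terms(grp))
        chip_groups <- c(chip_groups, rep(grp, tpg))
      }
    }
    for (tf in config$tf_activators) {
      tf_planted <- mapped & truth[[paste0("tf_", tf)]]
      chip_terms <- c(chip_terms, planted_terms(tf, tf_planted))
      chip_groups <- c(chip_groups, rep(tf, tpg))
    }
    chip <- gene_set_library("synthetic_tf_chip", "tf_chip",
                             chip_terms, chip_groups)

    # --- histone-mark library -------------------------------------------
    mark_terms <- c(planted_terms("H3K4me1", rest_planted,
                                  suffix = "tissue"),
                    planted_terms("H3K27me3", prc_planted,
                                  suffix = "tissue"))
    mark_groups <- rep(c("H3K4me1", "H3K27me3"), each = tpg)
    if (config$n_decoy_marks > 0) {
      for (d in seq_len(config$n_decoy_marks)) {
        grp <- sprintf("DECOY_MARK%02d", d)
        mark_terms <- c(mark_terms, uniform_terms(grp))
        mark_groups <- c(mark_groups, rep(grp, tpg))
      }
    }
    marks <- gene_set_library("synthetic_roadmap", "histone_mark",
                              mark_terms, mark_groups)

    # --- pathway library -------------------------------------------------
    pw_terms <- list()
    pw_groups <- character(0)
    for (dir in c("down", "up")) {
      idx <- which(mapped & truth$direction == dir)
      if (config$n_pathways_per_direction > 0 && length(idx) > 1) {
        for (i in seq_len(config$n_pathways_per_direction)) {
          covered <- rep(FALSE, nrow(truth))
          covered[sample(idx, max(2L, round(config$pathway_coverage *
                                              length(idx))))] <- TRUE
          nm <- sprintf("PATHWAY_%s_%02d", toupper(dir), i)
          pw_terms <- c(pw_terms, stats::setNames(
            planted_terms(nm, covered, n_terms = 1L), nm))
          pw_groups <- c(pw_groups, paste0("pathway_", dir))
        }
      }
    }
    if (config$n_decoy_pathways > 0) {
      for (i in seq_len(config$n_decoy_pathways)) {
        nm <- sprintf("PATHWAY_DECOY_%02d", i)
        pw_terms <- c(pw_terms, stats::setNames(
          uniform_terms(nm, n_terms = 1L), nm))
        pw_groups <- c(pw_groups, "pathway_decoy")
      }
    }
    pathways <- gene_set_library("synthetic_pathways", "pathway",
                                 pw_terms, pw_groups)

    list(tf_chip = chip, histone_mark = marks, pathway = pathways)
  })
}
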