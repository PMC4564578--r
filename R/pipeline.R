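#' Pipeline configuration
#'
#' Bundles either a synthetic-mode [sim_config()] or paths to real inputs
#' (count matrix, gene-set libraries, ortholog map) with the analysis
#' thresholds. Exactly one of `sim` / `paths` must be given.
#'
#' @param sim a [sim_config()] for synthetic mode.
#' @param paths named list for real-input mode: `counts_file`,
#'   `samples_file`, `chip_gmt`, `roadmap_gmt`, `pathway_gmt`,
#'   `ortholog_map_file`.
#' @param basemean_min,fdr,fc_cutoff differential-expression thresholds,
#'   see [run_de()].
#' @param p_cutoff,z_cutoff,B enrichment thresholds, see
#'   [enrich_library()].
#' @param seed master seed (synthetic mode takes its seed from `sim`).
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = NULL, paths = NULL,
                            basemean_min = 5, fdr = 0.01, fc_cutoff = 2,
                            p_cutoff = 0.05, z_cutoff = -1.5, B = 800,
                            seed = NULL) {
  if (is.null(sim) == is.null(paths)) {
    stop("exactly one of 'sim' (synthetic mode) or 'paths' must be set",
         call. = FALSE)
  }
  if (!is.null(sim)) {
    validate_sim_config(sim)
    seed <- seed %||% sim$seed
  } else {
    need <- c("counts_file", "samples_file", "chip_gmt", "roadmap_gmt",
              "pathway_gmt", "ortholog_map_file")
    missing_paths <- setdiff(need, names(paths))
    if (length(missing_paths) > 0) {
      stop("paths missing: ", paste(missing_paths, collapse = ", "),
           call. = FALSE)
    }
    seed <- seed %||% 1L
  }
  stopifnot(basemean_min >= 0, fdr > 0, fdr <= 1, fc_cutoff >= 0,
            p_cutoff > 0, p_cutoff <= 1, B >= 20)
  structure(list(sim = sim, paths = paths, basemean_min = basemean_min,
                 fdr = fdr, fc_cutoff = fc_cutoff, p_cutoff = p_cutoff,
                 z_cutoff = z_cutoff, B = B, seed = as.integer(seed)),
            class = "pipeline_config")
}

load_pipeline_inputs <- function(config) {
  if (!is.null(config$sim)) {
    truth <- generate_truth(config$sim)
    map <- generate_ortholog_map(truth$gene_id,
                                 collision_rate =
                                   config$sim$ortholog_collision_rate,
                                 drop_rate = config$sim$ortholog_drop_rate,
                                 seed = config$sim$seed)
    cm <- generate_counts(truth, config$sim)
    libraries <- generate_libraries(truth, config$sim, map)
  } else {
    truth <- NULL
    cm <- read_count_matrix(config$paths$counts_file,
                            config$paths$samples_file)
    map <- read_ortholog_map(config$paths$ortholog_map_file)
    libraries <- list(
      tf_chip = read_gmt(config$paths$chip_gmt, "tf_chip", "tf_chip"),
      histone_mark = read_gmt(config$paths$roadmap_gmt, "roadmap",
                              "histone_mark"),
      pathway = read_gmt(config$paths$pathway_gmt, "pathways", "pathway"))
  }
  list(truth = truth, counts = cm, map = map, libraries = libraries)
}

#' Run the full two-clone analysis pipeline
#'
#' Orchestrates simulate (or load) -> differential expression -> ortholog
#' mapping -> enrichment of the down- and upregulated lists against the
#' ChIP, histone-mark and pathway libraries -> per-gene target calls and
#' subfamily partitions under both evidence sources -> flow matrices ->
#' median-fold group comparisons (REST target vs nontarget; the four
#' downregulated subfamilies; activator-TF target shifts) -> gene-pathway
#' network. The enrichment background universe is the set of human
#' orthologs of the genes surviving the expression filter, matching the
#' tested population. All randomness derives from the configured seed, so
#' identical configurations reproduce identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory; when given, every stage's
#'   tables are written there (TSV/GMT/JSON/GraphML) together with a
#'   `manifest.json` and a plain-text `report.txt`. Partial outputs are
#'   removed if a stage fails.
#' @return a named list with every intermediate and final result
#'   (`truth`, `counts`, `map`, `libraries`, `de`, `universe`, `de_genes`,
#'   `enrichment`, `calls`, `partitions`, `percentages`, `flows`,
#'   `comparisons`, `network`, `manifest`), invisibly.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  created_dir <- FALSE
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
    created_dir <- TRUE
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      if (!is.null(out_dir)) {
        unlink(list.files(out_dir, full.names = TRUE), recursive = TRUE)
        if (created_dir) unlink(out_dir, recursive = TRUE)
      }
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  inputs <- run_stage("inputs", load_pipeline_inputs(config))
  truth <- inputs$truth
  cm <- inputs$counts
  map <- inputs$map
  libraries <- inputs$libraries

  de <- run_stage("diffexpr",
                  run_de(cm, basemean_min = config$basemean_min,
                         fdr = config$fdr, fc_cutoff = config$fc_cutoff))

  universe <- run_stage("ortholog_mapping",
                        map_orthologs(de$gene[!de$filtered], map,
                                      quiet = TRUE))
  de_genes <- list(down = de$gene[de$status == "down"],
                   up = de$gene[de$status == "up"])
  lists_h <- lapply(de_genes, function(g) {
    if (length(g) == 0) character(0) else map_orthologs(g, map,
                                                        quiet = TRUE)
  })

  enrichment <- run_stage("enrichment", {
    out <- list()
    for (dir in c("down", "up")) {
      for (lib in names(libraries)) {
        out[[dir]][[lib]] <- enrich_library(
          lists_h[[dir]], libraries[[lib]], universe,
          p_cutoff = config$p_cutoff, z_cutoff = config$z_cutoff,
          B = config$B,
          seed = derive_seed(config$seed, paste0("enrich_", dir, "_", lib)))
      }
    }
    out
  })

  classification <- run_stage("classification", {
    calls <- list(); partitions <- list(); flows <- list()
    percentages <- list()
    for (dir in c("down", "up")) {
      if (length(de_genes[[dir]]) == 0) next
      calls[[dir]] <- suppressMessages(call_targets(
        de_genes[[dir]], map,
        enrichment[[dir]]$tf_chip, libraries$tf_chip,
        enrichment[[dir]]$histone_mark, libraries$histone_mark))
      partitions[[dir]] <- list(
        chip = partition_subfamilies(calls[[dir]], dir, "chip"),
        roadmap = partition_subfamilies(calls[[dir]], dir, "roadmap"))
      flows[[dir]] <- flow_matrix(partitions[[dir]]$chip,
                                  partitions[[dir]]$roadmap)
      percentages[[dir]] <- lapply(partitions[[dir]],
                                   subfamily_percentages)
    }
    list(calls = calls, partitions = partitions, flows = flows,
         percentages = percentages)
  })

  comparisons <- run_stage("group_statistics", {
    out <- list()
    all_de <- c(de_genes$down, de_genes$up)
    calls <- classification$calls
    if (length(all_de) >= 4 && length(calls) > 0) {
      is_target <- unlist(lapply(calls, function(cl) cl$is_REST_target))
      targets <- c(unlist(lapply(calls, function(cl) cl$gene)))[is_target]
      nontargets <- setdiff(all_de, targets)
      if (length(targets) > 0 && length(nontargets) > 0) {
        out$rest_target_vs_nontarget <-
          compare_group_folds(de, targets, nontargets,
                              labels = c("REST_target", "REST_nontarget"))
      }
    }
    if (!is.null(classification$partitions$down)) {
      part <- classification$partitions$down$chip
      rp <- part$gene[part$label == "REST_and_PRC"]
      others <- part$gene[part$label != "REST_and_PRC"]
      if (length(rp) > 0 && length(others) > 0) {
        out$down_rest_prc_vs_others <-
          compare_group_folds(de, rp, others,
                              labels = c("REST_and_PRC",
                                         "other_subfamilies"))
      }
      out$down_subfamily_medians <- vapply(
        split(part$gene, part$label),
        function(g) if (length(g) == 0) NA_real_ else median_log2fc(de, g),
        numeric(1))
    }
    tf_groups <- if (!is.null(config$sim)) config$sim$tf_activators
                 else intersect(c("SMAD3", "MYOD1"),
                                libraries$tf_chip$factor_group)
    if (length(de_genes$up) > 0) {
      for (tf in tf_groups) {
        cmp <- withCallingHandlers(
          tf_target_shift(tf, enrichment$up$tf_chip, libraries$tf_chip,
                          de, de_genes$up, map),
          warning = function(w) invokeRestart("muffleWarning"))
        if (!is.null(cmp)) out[[paste0("tf_shift_", tf)]] <- cmp
      }
    }
    out
  })

  network <- run_stage("network", {
    if (length(lists_h$down) > 0) {
      build_gene_pathway_network(enrichment$down$pathway, lists_h$down,
                                 libraries$pathway)
    } else {
      igraph::make_empty_graph(directed = FALSE)
    }
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("restmech")),
    seed = config$seed,
    mode = if (is.null(config$sim)) "files" else "synthetic",
    thresholds = config[c("basemean_min", "fdr", "fc_cutoff", "p_cutoff",
                          "z_cutoff", "B")],
    n_genes = nrow(de),
    n_filtered = sum(de$filtered),
    n_universe = length(universe),
    n_down = length(de_genes$down),
    n_up = length(de_genes$up),
    timestamp = format(Sys.time(), tz = "UTC"))

  results <- list(config = config, truth = truth, counts = cm, map = map,
                  libraries = libraries, de = de, universe = universe,
                  de_genes = de_genes, de_genes_human = lists_h,
                  enrichment = enrichment,
                  calls = classification$calls,
                  partitions = classification$partitions,
                  percentages = classification$percentages,
                  flows = classification$flows,
                  comparisons = comparisons, network = network,
                  manifest = manifest)

  if (!is.null(out_dir)) {
    run_stage("write_outputs", write_pipeline_outputs(results, out_dir))
  }
  invisible(results)
}

write_pipeline_outputs <- function(results, out_dir) {
  p <- function(...) file.path(out_dir, ...)
  if (!is.null(results$truth)) write_tsv(results$truth, p("truth.tsv"))
  write_count_matrix(results$counts, p("counts.tsv"), p("samples.tsv"))
  write_ortholog_map(results$map, p("ortholog_map.tsv"))
  for (nm in names(results$libraries)) {
    write_gmt(results$libraries[[nm]], p(paste0("library_", nm, ".gmt")))
  }
  write_tsv(results$de, p("de_table.tsv"))
  for (dir in names(results$enrichment)) {
    for (lib in names(results$enrichment[[dir]])) {
      write_tsv(results$enrichment[[dir]][[lib]],
                p(sprintf("enrichment_%s_%s.tsv", dir, lib)))
    }
  }
  for (dir in names(results$calls)) {
    cl <- results$calls[[dir]]
    cl$chip_label <- results$partitions[[dir]]$chip$label
    cl$roadmap_label <- results$partitions[[dir]]$roadmap$label
    cl$direction <- dir
    write_tsv(cl, p(sprintf("classification_%s.tsv", dir)))
    fm <- results$flows[[dir]]
    write_tsv(data.frame(chip = rownames(fm),
                         as.data.frame(unclass(fm)[, , drop = FALSE]),
                         check.names = FALSE),
              p(sprintf("flow_matrix_%s.tsv", dir)))
    jsonlite::write_json(
      list(direction = dir, counts = unclass(fm),
           chip_labels = rownames(fm), roadmap_labels = colnames(fm),
           row_marginals = attr(fm, "row_marginals"),
           col_marginals = attr(fm, "col_marginals")),
      p(sprintf("flow_matrix_%s.json", dir)), matrix = "rowmajor")
  }
  if (length(results$comparisons) > 0) {
    rows <- do.call(rbind, lapply(names(results$comparisons), function(nm) {
      cmp <- results$comparisons[[nm]]
      if (!inherits(cmp, "group_comparison")) return(NULL)
      data.frame(comparison = nm,
                 group = cmp$groups$label, n = cmp$groups$n,
                 median_log2fc = cmp$groups$median_log2fc,
                 wilcoxon_p = cmp$wilcoxon_p,
                 stringsAsFactors = FALSE)
    }))
    if (!is.null(rows)) write_tsv(rows, p("group_comparisons.tsv"))
  }
  write_network(results$network, p("gene_pathway_network.graphml"),
                p("gene_pathway_edges.tsv"))
  jsonlite::write_json(results$manifest, p("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  writeLines(summarize_run(results), p("report.txt"))
  invisible(out_dir)
}

#' Human-readable summary of a pipeline run
#'
#' Formats the run in the reporting style of the study the package models:
#' DE counts by direction, REST target/nontarget percentages, subfamily
#' percentages under both evidence sources, flow-matrix highlights, and
#' group medians with Wilcoxon p-values (values below the double-precision
#' floor are printed as "< 2.2e-16").
#'
#' @param results the list returned by [run_pipeline()].
#' @return character vector of report lines.
#' @export
summarize_run <- function(results) {
  lines <- c("Two-clone REST transcriptome analysis - run summary",
             strrep("=", 51))
  man <- results$manifest
  lines <- c(lines,
             sprintf("Genes: %d (%d filtered; universe of %d mapped symbols)",
                     man$n_genes, man$n_filtered, man$n_universe),
             sprintf("DE genes: %d downregulated, %d upregulated",
                     man$n_down, man$n_up))
  if (man$n_down + man$n_up == 0) {
    return(c(lines, "No differentially expressed genes: no enrichment or",
             "classification sections."))
  }
  for (dir in names(results$percentages)) {
    part <- results$partitions[[dir]]$chip
    n <- nrow(part)
    counts <- table(part$label)
    rest_n <- sum(counts[c(1, 2)])
    pct <- subfamily_percentages(c(target = rest_n, nontarget = n - rest_n))
    dir_label <- if (dir == "down") "Downregulated" else "Upregulated"
    lines <- c(lines, "",
               sprintf("%s genes (%d):", dir_label, n),
               sprintf("  REST targets: %.1f%% (%d/%d); nontargets: %.1f%% (%d/%d)",
                       pct[["target"]], rest_n, n,
                       pct[["nontarget"]], n - rest_n, n))
    for (ev in c("chip", "roadmap")) {
      pcts <- results$percentages[[dir]][[ev]]
      lines <- c(lines, sprintf("  %s subfamilies: %s",
                                ifelse(ev == "chip", "ChIP", "Histone-mark"),
                                paste(sprintf("%s %.1f%%", names(pcts), pcts),
                                      collapse = ", ")))
    }
    fm <- results$flows[[dir]]
    if (!is.null(fm)) {
      off <- unclass(fm); diag(off) <- 0L
      i <- which(off == max(off), arr.ind = TRUE)[1, ]
      lines <- c(lines, sprintf(
        "  Largest subfamily flow: %s -> %s (%d genes)",
        rownames(fm)[i[1]], colnames(fm)[i[2]], max(off)))
    }
  }
  if (length(results$comparisons) > 0) {
    lines <- c(lines, "", "Group comparisons (median log2 fold change):")
    for (nm in names(results$comparisons)) {
      cmp <- results$comparisons[[nm]]
      if (!inherits(cmp, "group_comparison")) next
      lines <- c(lines, sprintf(
        "  %s: %s (Wilcoxon p %s)", nm,
        paste(sprintf("%s %.2f (n=%d)", cmp$groups$label,
                      cmp$groups$median_log2fc, cmp$groups$n),
              collapse = " vs "),
        format_pvalue(cmp$wilcoxon_p)))
    }
  }
  lines
}
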