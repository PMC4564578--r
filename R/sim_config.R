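#' Configuration for the synthetic two-clone experiment
#'
#' Builds and validates the configuration object consumed by
#' [generate_truth()], [generate_counts()], [generate_libraries()] and
#' [run_pipeline()]. The defaults emulate the study conditions of the
#' two-clone PC12 comparison the package models: roughly 15,500 expressed
#' genes, two replicates per clone, close to 900 genes per direction passing
#' the differential-expression cascade, and down-/upregulated subfamily
#' fractions matching the reported mechanistic partition (REST only,
#' REST and PRC, PRC only, unknown).
#'
#' @param n_genes number of simulated genes.
#' @param n_reps_per_condition replicates per condition (clone).
#' @param frac_down,frac_up fraction of genes planted as down-/upregulated
#'   (condition B over condition A); the remainder are null genes.
#' @param subfamily_down,subfamily_up length-4 numeric vectors summing to 1:
#'   within-direction fractions for the subfamilies
#'   `REST_only`, `REST_and_PRC`, `PRC_only`, `unknown`.
#' @param log2fc_min,log2fc_max range of absolute planted log2 fold changes
#'   (uniformly drawn).
#' @param log2fc_boost_rest_prc extra absolute log2 fold change added to
#'   downregulated `REST_and_PRC` genes, emulating the stronger repression
#'   observed when both silencing systems co-occupy a gene.
#' @param nb_dispersion negative-binomial dispersion alpha, with
#'   `variance = mu + alpha * mu^2`, shared across genes.
#' @param size_factor_spread per-sample size factors are drawn uniformly on
#'   `[1 - spread/2, 1 + spread/2]`.
#' @param base_expression_meanlog,base_expression_sdlog log-normal
#'   parameters for mean normalized expression.
#' @param planted_min_base floor applied to the base expression of planted
#'   differentially expressed genes (keeps planted effects above the
#'   detection limit of a 2 vs 2 design).
#' @param library_sensitivity probability that a planted target gene enters
#'   any one gene-set term of its factor group.
#' @param library_background_rate probability that a gene becomes a
#'   systematic false target of a factor (included in that factor's terms).
#' @param n_terms_per_group gene-set terms ("ChIP datasets"/"tissues") per
#'   factor group.
#' @param n_decoy_tfs number of decoy transcription-factor groups whose
#'   terms are sampled uniformly at random. The default keeps the library
#'   at the scale of real TF ChIP compendia (several hundred datasets);
#'   the rank-based z-score is only informative when enriched terms occupy
#'   a small leading fraction of the ranking, because the z-score of the
#'   best possible rank is bounded near `-sqrt(12)/2` for any library size.
#' @param n_decoy_marks decoy histone-mark groups (other marks/tissues),
#'   same rationale.
#' @param tf_activators names of upregulation-driving transcription factors
#'   with planted target sets (median-fold shift analysis).
#' @param tf_target_fraction fraction of upregulated genes planted as
#'   targets of each activator.
#' @param tf_extra_log2fc extra log2 fold change added to planted activator
#'   targets.
#' @param n_pathways_per_direction planted pathway terms per direction.
#' @param n_decoy_pathways uniformly sampled decoy pathway terms.
#' @param pathway_coverage fraction of a direction's planted genes covered
#'   by each planted pathway term.
#' @param ortholog_drop_rate fraction of rat symbols without a human
#'   ortholog in the synthetic map.
#' @param ortholog_collision_rate fraction of mapped rat symbols sharing
#'   their human symbol with another rat gene.
#' @param seed master seed; each generator stage derives its own stream.
#'
#' @return an object of class `sim_config` (a validated named list).
#' @seealso [generate_truth()], [run_pipeline()]
#' @export
sim_config <- function(n_genes = 15500,
                       n_reps_per_condition = 2,
                       frac_down = 0.057,
                       frac_up = 0.057,
                       subfamily_down = c(REST_only = 0.051,
                                          REST_and_PRC = 0.244,
                                          PRC_only = 0.343,
                                          unknown = 0.362),
                       subfamily_up = c(REST_only = 0.092,
                                        REST_and_PRC = 0.080,
                                        PRC_only = 0.229,
                                        unknown = 0.599),
                       log2fc_min = 2.5,
                       log2fc_max = 5.0,
                       log2fc_boost_rest_prc = 0.85,
                       nb_dispersion = 0.05,
                       size_factor_spread = 0.4,
                       base_expression_meanlog = log(100),
                       base_expression_sdlog = 1.3,
                       planted_min_base = 20,
                       library_sensitivity = 0.9,
                       library_background_rate = 0.02,
                       n_terms_per_group = 5,
                       n_decoy_tfs = 300,
                       n_decoy_marks = 80,
                       tf_activators = c("SMAD3", "MYOD1"),
                       tf_target_fraction = 0.25,
                       tf_extra_log2fc = 1.0,
                       n_pathways_per_direction = 4,
                       n_decoy_pathways = 150,
                       pathway_coverage = 0.4,
                       ortholog_drop_rate = 0.02,
                       ortholog_collision_rate = 0.01,
                       seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes),
    n_reps_per_condition = as.integer(n_reps_per_condition),
    frac_down = frac_down, frac_up = frac_up,
    subfamily_down = subfamily_down, subfamily_up = subfamily_up,
    log2fc_min = log2fc_min, log2fc_max = log2fc_max,
    log2fc_boost_rest_prc = log2fc_boost_rest_prc,
    nb_dispersion = nb_dispersion,
    size_factor_spread = size_factor_spread,
    base_expression_meanlog = base_expression_meanlog,
    base_expression_sdlog = base_expression_sdlog,
    planted_min_base = planted_min_base,
    library_sensitivity = library_sensitivity,
    library_background_rate = library_background_rate,
    n_terms_per_group = as.integer(n_terms_per_group),
    n_decoy_tfs = as.integer(n_decoy_tfs),
    n_decoy_marks = as.integer(n_decoy_marks),
    tf_activators = toupper(tf_activators),
    tf_target_fraction = tf_target_fraction,
    tf_extra_log2fc = tf_extra_log2fc,
    n_pathways_per_direction = as.integer(n_pathways_per_direction),
    n_decoy_pathways = as.integer(n_decoy_pathways),
    pathway_coverage = pathway_coverage,
    ortholog_drop_rate = ortholog_drop_rate,
    ortholog_collision_rate = ortholog_collision_rate,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_genes, "genes,",
      x$n_reps_per_condition, "reps/condition,",
      sprintf("%.1f%% down / %.1f%% up planted,", 100 * x$frac_down,
              100 * x$frac_up),
      "seed", x$seed, "\n")
  invisible(x)
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_genes < 1L) stop("n_genes must be positive", call. = FALSE)
  if (cfg$n_reps_per_condition < 1L) {
    stop("n_reps_per_condition must be >= 1", call. = FALSE)
  }
  fr <- c(cfg$frac_down, cfg$frac_up)
  if (any(fr < 0)) stop("direction fractions must be nonnegative", call. = FALSE)
  if (sum(fr) > 1 + 1e-9) {
    stop("frac_down + frac_up exceeds 1: no room for null genes",
         call. = FALSE)
  }
  for (nm in c("subfamily_down", "subfamily_up")) {
    sf <- cfg[[nm]]
    if (length(sf) != 4L || any(sf < 0)) {
      stop(nm, " must be 4 nonnegative fractions", call. = FALSE)
    }
    if (abs(sum(sf) - 1) > 1e-6) {
      stop(nm, " must sum to 1", call. = FALSE)
    }
  }
  if (cfg$log2fc_min <= 0 || cfg$log2fc_max < cfg$log2fc_min) {
    stop("invalid planted log2 fold-change range", call. = FALSE)
  }
  if (cfg$nb_dispersion < 0) stop("nb_dispersion must be >= 0", call. = FALSE)
  if (cfg$size_factor_spread < 0 || cfg$size_factor_spread >= 2) {
    stop("size_factor_spread must lie in [0, 2)", call. = FALSE)
  }
  if (cfg$library_sensitivity <= 0 || cfg$library_sensitivity > 1) {
    stop("library_sensitivity must lie in (0, 1]", call. = FALSE)
  }
  if (cfg$library_background_rate < 0 || cfg$library_background_rate >= 1) {
    stop("library_background_rate must lie in [0, 1)", call. = FALSE)
  }
  if (cfg$library_sensitivity <= cfg$library_background_rate) {
    stop("library_sensitivity must exceed library_background_rate, ",
         "otherwise planted enrichment is undetectable", call. = FALSE)
  }
  if (cfg$tf_target_fraction < 0 || cfg$tf_target_fraction > 1) {
    stop("tf_target_fraction must lie in [0, 1]", call. = FALSE)
  }
  invisible(cfg)
}

#' Read or write a simulation configuration as YAML
#'
#' @param cfg a [sim_config()] object.
#' @param file path to a YAML file.
#' @return `read_sim_config()` returns a `sim_config`;
#'   `write_sim_config()` returns `file` invisibly.
#' @export
write_sim_config <- function(cfg, file) {
  stopifnot(inherits(cfg, "sim_config"))
  yaml::write_yaml(unclass(cfg), file)
  invisible(file)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(file) {
  vals <- yaml::read_yaml(file)
  # YAML loses names on the subfamily vectors when written from R; restore.
  for (nm in c("subfamily_down", "subfamily_up")) {
    vals[[nm]] <- stats::setNames(
      unlist(vals[[nm]]),
      c("REST_only", "REST_and_PRC", "PRC_only", "unknown"))
  }
  do.call(sim_config, vals)
}
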