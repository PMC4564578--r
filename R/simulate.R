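SUBFAMILY_LEVELS <- c("REST_only", "REST_and_PRC", "PRC_only", "unknown")

# Integer apportionment by largest remainder: class counts match n * fractions
# up to the unavoidable +/-1 rounding, and sum exactly to n. Ties broken by
# class order, so results are fully deterministic.
apportion_largest_remainder <- function(n, fractions) {
  stopifnot(n >= 0, all(fractions >= -1e-12))
  fractions <- pmax(fractions, 0)
  if (abs(sum(fractions) - 1) > 1e-6) {
    stop("fractions must sum to 1", call. = FALSE)
  }
  exact <- n * fractions
  base <- floor(exact)
  k <- n - sum(base)
  if (k > 0) {
    idx <- order(exact - base, decreasing = TRUE)[seq_len(k)]
    base[idx] <- base[idx] + 1
  }
  as.integer(base)
}

#' Generate the ground-truth gene table for a synthetic experiment
#'
#' Assigns each simulated gene a regulation direction (`down`, `up`, `null`),
#' a mechanistic subfamily (`REST_only`, `REST_and_PRC`, `PRC_only`,
#' `unknown`, or `none` for null genes), a planted log2 fold change
#' (condition B over condition A; 0 for null genes) and a base expression
#' level. Class sizes follow the configured fractions by largest-remainder
#' apportionment, so expected counts are exact up to +/-1. Downregulated
#' `REST_and_PRC` genes receive `log2fc_boost_rest_prc` extra repression;
#' planted targets of the configured activator TFs (columns `tf_<NAME>`)
#' receive `tf_extra_log2fc` extra activation.
#'
#' @param config a [sim_config()].
#' @return a `data.frame` of class `truth_table` with columns `gene_id`,
#'   `direction`, `subfamily`, `planted_log2fc`, `base_expression`, plus one
#'   logical `tf_<NAME>` column per activator TF.
#' @export
generate_truth <- function(config) {
  validate_sim_config(config)
  n <- config$n_genes
  abs_frac <- c(config$frac_down * config$subfamily_down,
                config$frac_up * config$subfamily_up)
  counts <- apportion_largest_remainder(n, c(abs_frac, 1 - sum(abs_frac)))
  # classes 1:4 = down subfamilies, 5:8 = up subfamilies, 9 = null
  class_of <- rep.int(seq_len(9L), counts)
  gene_id <- sprintf("Gene%05d", seq_len(n))

  truth <- with_seed(derive_seed(config$seed, "truth"), {
    cls <- integer(n)
    cls[sample.int(n)] <- class_of
    direction <- c(rep("down", 4), rep("up", 4), "null")[cls]
    subfamily <- c(rep(SUBFAMILY_LEVELS, 2), "none")[cls]
    is_de <- direction != "null"

    lfc <- numeric(n)
    lfc[is_de] <- stats::runif(sum(is_de), config$log2fc_min, config$log2fc_max)
    boost <- direction == "down" & subfamily == "REST_and_PRC"
    lfc[boost] <- lfc[boost] + config$log2fc_boost_rest_prc
    lfc[direction == "down"] <- -lfc[direction == "down"]

    base <- stats::rlnorm(n, config$base_expression_meanlog,
                          config$base_expression_sdlog)
    base[is_de] <- pmax(base[is_de], config$planted_min_base)

    out <- data.frame(gene_id = gene_id,
                      direction = direction,
                      subfamily = subfamily,
                      planted_log2fc = lfc,
                      base_expression = base,
                      stringsAsFactors = FALSE)
    for (tf in config$tf_activators) {
      hit <- direction == "up" &
        stats::runif(n) < config$tf_target_fraction
      out[[paste0("tf_", tf)]] <- hit
      out$planted_log2fc[hit] <- out$planted_log2fc[hit] +
        config$tf_extra_log2fc
    }
    out
  })
  class(truth) <- c("truth_table", "data.frame")
  truth
}

#' Two-condition count matrix
#'
#' Lightweight container pairing an integer count matrix (genes x samples)
#' with a two-level condition factor. Fold changes throughout the package
#' are expressed as the second factor level over the first.
#'
#' @param counts integer matrix with rownames (gene ids) and colnames
#'   (sample ids).
#' @param condition factor of length `ncol(counts)` with exactly two levels.
#' @return an object of class `count_matrix`.
#' @export
count_matrix <- function(counts, condition) {
  counts <- as.matrix(counts)
  condition <- as.factor(condition)
  if (is.null(rownames(counts)) || anyDuplicated(rownames(counts))) {
    stop("counts must have unique rownames (gene ids)", call. = FALSE)
  }
  if (is.null(colnames(counts)) || anyDuplicated(colnames(counts))) {
    stop("counts must have unique colnames (sample ids)", call. = FALSE)
  }
  if (length(condition) != ncol(counts)) {
    stop("condition must label every sample", call. = FALSE)
  }
  if (nlevels(condition) != 2L || any(tabulate(condition) < 1L)) {
    stop("condition must have two levels with >= 1 sample each",
         call. = FALSE)
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be nonnegative integers", call. = FALSE)
  }
  structure(list(counts = counts, condition = condition),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "genes x", ncol(x$counts),
      "samples (", paste(levels(x$condition), collapse = " vs "), ")\n")
  invisible(x)
}

#' Simulate negative-binomial counts from a truth table
#'
#' Counts for gene g in sample j are drawn from a negative binomial with
#' mean `sf_j * base_g * 2^(+/- planted_log2fc/2)` (minus for condition A,
#' plus for condition B, so the planted effect is split symmetrically and
#' the overall base mean is effect-invariant) and dispersion alpha with
#' `variance = mu + alpha * mu^2`. `alpha = 0` gives Poisson counts.
#' Per-sample size factors are drawn uniformly within the configured spread.
#'
#' @param truth a [generate_truth()] table.
#' @param config the matching [sim_config()].
#' @return a [count_matrix()]; condition levels are `A` (reference, the
#'   low-REST clone analogue) and `B` (the high-REST clone analogue).
#' @export
generate_counts <- function(truth, config) {
  validate_sim_config(config)
  stopifnot(inherits(truth, "truth_table"))
  if (any(truth$base_expression <= 0)) {
    stop("base_expression must be positive", call. = FALSE)
  }
  m <- config$n_reps_per_condition
  n <- nrow(truth)
  with_seed(derive_seed(config$seed, "counts"), {
    sf <- stats::runif(2 * m, 1 - config$size_factor_spread / 2,
                       1 + config$size_factor_spread / 2)
    half <- truth$planted_log2fc / 2
    mu_cond <- cbind(A = truth$base_expression * 2^(-half),
                     B = truth$base_expression * 2^(half))
    cond <- rep(c("A", "B"), each = m)
    mu <- mu_cond[, cond] * rep(sf, each = n)
    counts <- if (config$nb_dispersion < 1e-12) {
      stats::rpois(length(mu), lambda = mu)
    } else {
      stats::rnbinom(length(mu), mu = mu, size = 1 / config$nb_dispersion)
    }
    counts <- matrix(counts, nrow = n,
                     dimnames = list(truth$gene_id,
                                     paste0(cond, "_", rep(seq_len(m), 2))))
    cm <- count_matrix(counts, factor(cond, levels = c("A", "B")))
    attr(cm, "size_factors_true") <- stats::setNames(sf, colnames(counts))
    cm
  })
}

#' Generate a synthetic rat-to-human ortholog symbol map
#'
#' Emulates a one-column ortholog lookup: each rat symbol maps to an
#' upper-cased human symbol, a configurable fraction of rat symbols have no
#' ortholog and are absent from the map, and a configurable fraction of the
#' mapped symbols collide onto the human symbol of another rat gene
#' (many-to-one mappings, as happens for paralog families).
#'
#' @param genes character vector of rat gene symbols.
#' @param collision_rate fraction of mapped symbols redirected onto another
#'   gene's human symbol.
#' @param drop_rate fraction of rat symbols without an ortholog.
#' @param seed integer seed.
#' @return a `data.frame` with columns `rat_symbol`, `human_symbol`.
#' @export
generate_ortholog_map <- function(genes, collision_rate = 0,
                                  drop_rate = 0, seed = 1L) {
  if (length(genes) == 0) stop("gene list is empty", call. = FALSE)
  stopifnot(collision_rate >= 0, collision_rate < 1,
            drop_rate >= 0, drop_rate < 1)
  with_seed(derive_seed(seed, "orthologs"), {
    keep <- stats::runif(length(genes)) >= drop_rate
    rat <- genes[keep]
    human <- toupper(rat)
    if (collision_rate > 0 && length(rat) > 1) {
      hit <- which(stats::runif(length(rat)) < collision_rate)
      for (i in hit) {
        human[i] <- human[sample(setdiff(seq_along(rat), i), 1L)]
      }
    }
    data.frame(rat_symbol = rat, human_symbol = human,
               stringsAsFactors = FALSE)
  })
}
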