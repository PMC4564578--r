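#' Median-of-ratios size factors
#'
#' Per-sample normalization constants: for each gene with all-positive
#' counts, the ratio of the sample's count to the gene's geometric mean
#' across samples is formed; the size factor of a sample is the median of
#' these ratios. Genes with a zero in any sample are excluded from the
#' median (their geometric mean would degenerate).
#'
#' @param counts integer matrix, genes x samples.
#' @return named numeric vector of positive size factors.
#' @export
estimate_size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be nonnegative", call. = FALSE)
  usable <- rowSums(counts == 0) == 0
  if (!any(usable)) {
    stop("no gene with all-positive counts: size factors undefined",
         call. = FALSE)
  }
  loggeo <- rowMeans(log(counts[usable, , drop = FALSE]))
  sf <- apply(counts[usable, , drop = FALSE], 2, function(k) {
    exp(stats::median(log(k) - loggeo))
  })
  stats::setNames(sf, colnames(counts))
}

# Gamma-family fit of the dispersion-mean trend alpha(mu) = a0 + a1/mu,
# with an ordinary least-squares fallback; coefficients clamped so the
# fitted trend stays positive.
fit_dispersion_trend <- function(mu, alpha, min_disp = 1e-8) {
  ok <- is.finite(mu) & mu > 0 & is.finite(alpha)
  mu <- mu[ok]; alpha <- pmax(alpha[ok], min_disp)
  if (length(mu) < 3) return(c(a0 = min_disp, a1 = 0))
  x <- 1 / mu
  ls <- stats::coef(stats::lm(alpha ~ x))
  co <- tryCatch({
    start <- pmax(ls, c(min_disp, 0))
    stats::coef(stats::glm(alpha ~ x, family = Gamma(link = "identity"),
                           start = start))
  }, error = function(e) ls, warning = function(w) ls)
  c(a0 = max(co[[1]], min_disp), a1 = max(co[[2]], 0))
}

#' Per-gene negative-binomial dispersion estimates with trend sharing
#'
#' Method-of-moments dispersions from normalized counts: the pooled
#' within-condition variance of a gene's normalized counts, corrected for
#' the shot-noise term `baseMean * mean(1/sf)`, is converted to the
#' dispersion alpha of `variance = mu + alpha * mu^2` and floored at
#' `min_disp`. A mean-dispersion trend `alpha(mu) = a0 + a1/mu` is fitted
#' across genes, and the final dispersion is the maximum of the per-gene
#' estimate and the fitted trend - a conservative sharing mode suited to
#' designs with very few replicates. All-zero genes get `NA` and are
#' flagged.
#'
#' @param counts integer matrix, genes x samples.
#' @param size_factors from [estimate_size_factors()].
#' @param condition two-level factor over samples; at least one condition
#'   must have >= 2 replicates.
#' @param min_disp floor for per-gene estimates.
#' @return data.frame with columns `base_mean`, `disp_gene`, `disp_fit`,
#'   `dispersion`, `all_zero`; the trend coefficients are in
#'   `attr(, "trend")`.
#' @export
estimate_dispersions <- function(counts, size_factors, condition,
                                 min_disp = 1e-8) {
  counts <- as.matrix(counts)
  condition <- as.factor(condition)
  reps <- table(condition)
  if (!any(reps >= 2)) {
    stop("need >= 2 replicates in some condition to estimate dispersions",
         call. = FALSE)
  }
  q <- sweep(counts, 2, size_factors, "/")
  base_mean <- rowMeans(q)

  v <- matrix(0, nrow(counts), 0)
  dfs <- numeric(0)
  for (lv in names(reps)[reps >= 2]) {
    qc <- q[, condition == lv, drop = FALSE]
    v <- cbind(v, apply(qc, 1, stats::var))
    dfs <- c(dfs, reps[[lv]] - 1)
  }
  w <- as.vector(v %*% dfs) / sum(dfs)

  xim <- mean(1 / size_factors)
  disp_gene <- (w - xim * base_mean) / base_mean^2
  disp_gene[base_mean == 0] <- NA_real_
  disp_gene <- pmax(disp_gene, min_disp)

  trend <- fit_dispersion_trend(base_mean, disp_gene, min_disp)
  disp_fit <- trend[["a0"]] + trend[["a1"]] / base_mean
  disp_fit[base_mean == 0] <- NA_real_

  out <- data.frame(base_mean = base_mean,
                    disp_gene = disp_gene,
                    disp_fit = disp_fit,
                    dispersion = pmax(disp_gene, disp_fit),
                    all_zero = base_mean == 0,
                    row.names = rownames(counts))
  attr(out, "trend") <- trend
  out
}

#' Conditional negative-binomial exact test for a two-condition comparison
#'
#' Tests whether the split of the pooled count of a gene between the two
#' conditions is more extreme than expected. Replicate counts are summed
#' per condition; under the null, the summed counts are negative binomial
#' with a common normalized mean, and the p-value is the probability,
#' conditional on the pooled total, of all splits at most as probable as
#' the observed one:
#' `p = sum over {(a,b): a+b=S, P(a,b) <= P(kA,kB)} P(a,b) / sum over all splits P(a,b)`.
#' With `dispersion = 0` the negative binomial degenerates to Poisson and
#' the conditional law is binomial. Pooled totals above `exact_threshold`
#' use a normal approximation of the split distribution (enumeration cost
#' grows linearly with the total).
#'
#' @param kA,kB nonnegative integer counts (one per replicate) in
#'   conditions A and B.
#' @param sfA,sfB size factors for the corresponding samples.
#' @param dispersion shared dispersion alpha (`variance = mu + alpha*mu^2`).
#' @param exact_threshold largest pooled total still enumerated exactly.
#' @return two-sided p-value in (0, 1]; symmetric in the two conditions.
#' @export
nb_exact_test <- function(kA, kB, sfA = rep(1, length(kA)),
                          sfB = rep(1, length(kB)), dispersion = 0,
                          exact_threshold = 1000) {
  if (any(c(kA, kB) < 0)) stop("counts must be nonnegative", call. = FALSE)
  if (dispersion < 0) stop("dispersion must be >= 0", call. = FALSE)
  KA <- sum(kA); KB <- sum(kB); S <- KA + KB
  if (S == 0) return(1)
  sA <- sum(sfA); sB <- sum(sfB)
  qhat <- S / (sA + sB)
  muA <- qhat * sA
  muB <- qhat * sB
  poisson <- dispersion < 1e-12
  if (!poisson) {
    # variance of a sum of NB replicates sharing alpha:
    # var = mu + alpha * q^2 * sum(sf^2)  =>  size = (sum sf)^2/(alpha sum sf^2)
    sizeA <- sA^2 / (dispersion * sum(sfA^2))
    sizeB <- sB^2 / (dispersion * sum(sfB^2))
  }
  if (S <= exact_threshold) {
    a <- 0:S
    lp <- if (poisson) {
      stats::dpois(a, muA, log = TRUE) + stats::dpois(S - a, muB, log = TRUE)
    } else {
      stats::dnbinom(a, mu = muA, size = sizeA, log = TRUE) +
        stats::dnbinom(S - a, mu = muB, size = sizeB, log = TRUE)
    }
    lp_obs <- lp[KA + 1]
    w <- exp(lp - max(lp))
    min(1, sum(w[lp <= lp_obs + 1e-7]) / sum(w))
  } else {
    varA <- if (poisson) muA else muA + muA^2 / sizeA
    varB <- if (poisson) muB else muB + muB^2 / sizeB
    # conditional on the total, the A-sum is approximately normal around
    # muA (qhat makes muA + muB = S exactly) with pooled variance
    sd_a <- sqrt(varA * varB / (varA + varB))
    lower <- stats::pnorm(KA + 0.5, muA, sd_a)
    upper <- stats::pnorm(KA - 0.5, muA, sd_a, lower.tail = FALSE)
    min(1, 2 * min(lower, upper))
  }
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' The single audited multiple-testing implementation used throughout the
#' package (differential expression and every enrichment table): sort
#' ascending, form `p_i * m / i`, enforce monotonicity from the largest
#' rank down, cap at 1, restore input order.
#'
#' @param pvalues numeric vector in \[0, 1\].
#' @return adjusted p-values, same order as the input.
#' @export
adjust_bh <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  m <- length(pvalues)
  o <- order(pvalues, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m / (m:1) * pvalues[o]))[ro]
}

#' Differential-expression analysis with the strict filter cascade
#'
#' Runs the full per-gene pipeline on a two-condition count matrix:
#' median-of-ratios normalization, trend-shared dispersion estimation, the
#' conditional negative-binomial exact test, and the filter cascade applied
#' in this fixed order:
#' \enumerate{
#'   \item expression filter: genes with overall `baseMean < basemean_min`
#'     are removed (`low_expression`), as are genes with a zero baseMean in
#'     either condition (`zero_in_condition`, which would give infinite or
#'     zero fold changes);
#'   \item Benjamini-Hochberg adjustment across the surviving genes only;
#'   \item FDR cutoff `padj <= fdr`;
#'   \item effect cutoff `|log2 fold change| > fc_cutoff`, strictly.
#' }
#' Fold changes are the second condition level over the first
#' (the high-REST clone over the low-REST reference in the model system).
#'
#' @param cm a [count_matrix()].
#' @param basemean_min expression filter on the overall mean of normalized
#'   counts (default 5).
#' @param fdr adjusted p-value cutoff (default 0.01, inclusive).
#' @param fc_cutoff absolute log2 fold-change cutoff (default 2, strict).
#' @param exact_threshold passed to [nb_exact_test()].
#' @return data.frame of class `de_table` with one row per gene: `gene`,
#'   `baseMean`, `baseMeanA`, `baseMeanB`, `log2FoldChange`, `pval`,
#'   `padj`, `filtered`, `reason`, `status` (`down`/`up`/`not_de`).
#' @export
run_de <- function(cm, basemean_min = 5, fdr = 0.01, fc_cutoff = 2,
                   exact_threshold = 1000) {
  stopifnot(inherits(cm, "count_matrix"))
  counts <- cm$counts
  condition <- cm$condition
  sf <- estimate_size_factors(counts)
  disp <- estimate_dispersions(counts, sf, condition)
  q <- sweep(counts, 2, sf, "/")
  A <- levels(condition)[1]
  B <- levels(condition)[2]
  selA <- condition == A
  selB <- condition == B
  baseMeanA <- rowMeans(q[, selA, drop = FALSE])
  baseMeanB <- rowMeans(q[, selB, drop = FALSE])
  baseMean <- rowMeans(q)
  log2fc <- log2(baseMeanB / baseMeanA)

  reason <- rep(NA_character_, nrow(counts))
  reason[baseMeanA == 0 | baseMeanB == 0] <- "zero_in_condition"
  reason[baseMean < basemean_min] <- "low_expression"
  filtered <- !is.na(reason)

  pval <- rep(NA_real_, nrow(counts))
  keep <- which(!filtered)
  disp_use <- disp$dispersion
  disp_use[is.na(disp_use)] <- 0
  for (i in keep) {
    pval[i] <- nb_exact_test(counts[i, selA], counts[i, selB],
                             sf[selA], sf[selB], disp_use[i],
                             exact_threshold = exact_threshold)
  }

  padj <- rep(NA_real_, nrow(counts))
  padj[keep] <- adjust_bh(pval[keep])

  status <- rep("not_de", nrow(counts))
  sig <- !filtered & !is.na(padj) & padj <= fdr & abs(log2fc) > fc_cutoff
  status[sig & log2fc < -fc_cutoff] <- "down"
  status[sig & log2fc > fc_cutoff] <- "up"

  out <- data.frame(gene = rownames(counts),
                    baseMean = baseMean,
                    baseMeanA = baseMeanA,
                    baseMeanB = baseMeanB,
                    log2FoldChange = log2fc,
                    pval = pval,
                    padj = padj,
                    filtered = filtered,
                    reason = reason,
                    status = status,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "size_factors") <- sf
  attr(out, "dispersion_trend") <- attr(disp, "trend")
  attr(out, "thresholds") <- c(basemean_min = basemean_min, fdr = fdr,
                               fc_cutoff = fc_cutoff)
  class(out) <- c("de_table", "data.frame")
  out
}
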