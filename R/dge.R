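# Stage 1: differential expression between a reference strain and an
# anti-sigma deletion strain. Deliberately simple: median-of-ratios
# normalization, per-gene method-of-moments NB dispersion, a Wald test on
# the log2 fold change, and Benjamini-Hochberg adjustment. No dispersion
# shrinkage across genes.

#' Median-of-ratios normalization
#'
#' Size factor of sample j is the median, over genes with all-positive
#' counts, of count_ij divided by the gene's geometric mean across
#' samples; normalized counts are counts divided by the sample's factor.
#'
#' @param counts Genes x samples matrix of non-negative integers.
#' @return A list with `size_factors` (one per sample) and `normalized`
#'   (matrix of the same shape as `counts`).
#' @export
normalize_median_of_ratios <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(all(counts >= 0))
  all_pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(all_pos)) {
    stop("no gene has positive counts in every sample; ",
         "median-of-ratios is undefined (consider a pseudo-reference ",
         "fallback or filtering)")
  }
  log_geo <- rowMeans(log(counts[all_pos, , drop = FALSE]))
  ratios <- counts[all_pos, , drop = FALSE] / exp(log_geo)
  size_factors <- apply(ratios, 2L, stats::median)
  list(size_factors = size_factors,
       normalized = sweep(counts, 2L, size_factors, "/"))
}

#' Compute per-gene A and M values
#'
#' A is the log2 mean of normalized counts over all samples; M is the
#' log2 fold change of the deletion-condition mean over the
#' reference-condition mean. A pseudocount keeps both finite for
#' zero-count groups.
#'
#' @param normalized Genes x samples matrix of normalized counts.
#' @param conditions Data.frame with columns `sample` and `condition`.
#' @param reference,treatment Condition labels; M is
#'   log2(treatment / reference).
#' @param pseudocount Added to each group mean before taking logs
#'   (default 0.5).
#' @return Data.frame with columns `gene_id`, `a_value`, `m_value`,
#'   `mean_reference`, `mean_treatment`.
#' @export
compute_ma <- function(normalized, conditions, reference = "reference",
                       treatment = "deletion", pseudocount = 0.5) {
  normalized <- as.matrix(normalized)
  unknown <- setdiff(c(reference, treatment), conditions$condition)
  if (length(unknown)) {
    stop("condition label(s) not present in the condition map: ",
         paste(unknown, collapse = ", "))
  }
  cond <- conditions$condition[match(colnames(normalized), conditions$sample)]
  if (anyNA(cond)) stop("sample(s) missing from the condition map")
  ref_mean <- rowMeans(normalized[, cond == reference, drop = FALSE])
  trt_mean <- rowMeans(normalized[, cond == treatment, drop = FALSE])
  data.frame(
    gene_id = rownames(normalized),
    a_value = log2(rowMeans(normalized) + pseudocount),
    m_value = log2((trt_mean + pseudocount) / (ref_mean + pseudocount)),
    mean_reference = ref_mean,
    mean_treatment = trt_mean,
    stringsAsFactors = FALSE
  )
}

#' Per-gene negative-binomial Wald test
#'
#' Counts are normalized with [normalize_median_of_ratios()]; the NB
#' dispersion of each gene is estimated by method of moments within each
#' condition (alpha = (s^2 - mu) / mu^2, pooled across conditions with
#' degrees-of-freedom weights and floored at `dispersion_floor`). The
#' Wald statistic is the M value divided by its delta-method standard
#' error from the NB variance; p-values are two-sided standard normal.
#' Genes with zero counts in every sample get p = 1.
#'
#' @param counts Genes x samples matrix of raw counts.
#' @param conditions Data.frame with columns `sample` and `condition`.
#' @param reference,treatment Condition labels.
#' @param pseudocount Pseudocount for the log-fold-change (default 0.5).
#' @param dispersion_floor Lower bound on the dispersion (default 1e-8).
#' @return Data.frame with columns `gene_id`, `a_value`, `m_value`,
#'   `dispersion`, `stat`, `p`.
#' @export
nb_wald_test <- function(counts, conditions, reference = "reference",
                         treatment = "deletion", pseudocount = 0.5,
                         dispersion_floor = 1e-8) {
  counts <- as.matrix(counts)
  norm <- normalize_median_of_ratios(counts)$normalized
  ma <- compute_ma(norm, conditions, reference, treatment, pseudocount)
  cond <- conditions$condition[match(colnames(norm), conditions$sample)]

  group_stats <- function(label) {
    m <- norm[, cond == label, drop = FALSE]
    list(n = ncol(m), mean = rowMeans(m), var = apply(m, 1L, stats::var))
  }
  g_ref <- group_stats(reference)
  g_trt <- group_stats(treatment)

  mom_alpha <- function(g) {
    a <- (g$var - g$mean) / g$mean^2
    a[!is.finite(a)] <- NA_real_
    a
  }
  a_ref <- mom_alpha(g_ref)
  a_trt <- mom_alpha(g_trt)
  w_ref <- g_ref$n - 1L
  w_trt <- g_trt$n - 1L
  pooled <- ifelse(
    is.na(a_ref) & is.na(a_trt), NA_real_,
    (ifelse(is.na(a_ref), 0, w_ref * a_ref) +
       ifelse(is.na(a_trt), 0, w_trt * a_trt)) /
      (ifelse(is.na(a_ref), 0, w_ref) + ifelse(is.na(a_trt), 0, w_trt))
  )
  alpha <- pmax(dispersion_floor, pooled)
  alpha[is.na(alpha)] <- dispersion_floor

  # delta-method variance of M = log2(trt_mean + eps) - log2(ref_mean + eps)
  var_mean <- function(g) (g$mean + alpha * g$mean^2) / g$n
  se2 <- (var_mean(g_trt) / (g_trt$mean + pseudocount)^2 +
            var_mean(g_ref) / (g_ref$mean + pseudocount)^2) / log(2)^2
  stat <- ifelse(se2 > 0, ma$m_value / sqrt(se2), 0)
  p <- 2 * stats::pnorm(-abs(stat))
  all_zero <- rowSums(counts) == 0
  p[all_zero] <- 1
  stat[all_zero] <- 0

  data.frame(gene_id = ma$gene_id, a_value = ma$a_value,
             m_value = ma$m_value, dispersion = alpha, stat = stat, p = p,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement,
#' order-preserving.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Vector of adjusted p-values in the input order.
#' @export
bh_adjust <- function(p) {
  stopifnot(is.numeric(p))
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must all lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Label genes as up-, down-regulated or non-significant
#'
#' A gene is `up` iff its M value is at least `m_cutoff` and its adjusted
#' p at most `padj_cutoff` (both boundaries inclusive); `down`
#' symmetrically; otherwise `ns`.
#'
#' @param records Data.frame with columns `m_value` and `padj`.
#' @param m_cutoff Absolute M-value cutoff (default 1).
#' @param padj_cutoff Adjusted-p cutoff (default 0.01).
#' @return `records` with a `status` column added.
#' @export
classify_dge <- function(records, m_cutoff = 1.0, padj_cutoff = 0.01) {
  stopifnot(m_cutoff > 0, all(c("m_value", "padj") %in% names(records)))
  sig <- records$padj <= padj_cutoff
  records$status <- ifelse(sig & records$m_value >= m_cutoff, "up",
                           ifelse(sig & records$m_value <= -m_cutoff,
                                  "down", "ns"))
  records
}

#' Run the full differential-expression stage
#'
#' Normalization, M/A computation, NB Wald test, BH adjustment and
#' classification in one call.
#'
#' @inheritParams nb_wald_test
#' @inheritParams classify_dge
#' @return Data.frame with columns `gene_id`, `a_value`, `m_value`,
#'   `dispersion`, `stat`, `p`, `padj`, `status`.
#' @export
run_dge <- function(counts, conditions, reference = "reference",
                    treatment = "deletion", m_cutoff = 1.0,
                    padj_cutoff = 0.01, pseudocount = 0.5,
                    dispersion_floor = 1e-8) {
  res <- nb_wald_test(counts, conditions, reference, treatment,
                      pseudocount, dispersion_floor)
  res$padj <- bh_adjust(res$p)
  classify_dge(res, m_cutoff = m_cutoff, padj_cutoff = padj_cutoff)
}
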