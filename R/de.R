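# Naive differential-expression surrogate for synthetic data.
#
# Real analyses should use DESeq2 (or similar); this Welch-t on log2(x+1)
# exists only so the synthetic pipeline is self-contained, and is NOT
# statistically equivalent to a negative-binomial GLM.

#' Naive two-group differential expression (synthetic-data surrogate)
#'
#' Computes `log2FC = mean(log2(b+1)) - mean(log2(a+1))` per gene and a Welch
#' t-test p-value on the log scale. `status` is `"up"` / `"down"` when
#' `|log2FC| > min_abs_log2fc` and `p < max_p` (up = higher in group `b`),
#' else `"ns"`.
#'
#' @param expr numeric matrix, genes x samples, rownames = gene ids.
#' @param samples_a,samples_b column names (or indices) of the two groups.
#' @param min_abs_log2fc fold-change threshold on log2 scale (default 1).
#' @param max_p p-value threshold (default 0.05).
#' @return `data.table`: `gene_id`, `log2fc`, `p`, `status`.
#' @export
naive_de <- function(expr, samples_a, samples_b, min_abs_log2fc = 1,
                     max_p = 0.05) {
  a <- log2(as.matrix(expr[, samples_a, drop = FALSE]) + 1)
  b <- log2(as.matrix(expr[, samples_b, drop = FALSE]) + 1)
  if (ncol(a) < 2 || ncol(b) < 2) stop("need >= 2 samples per group")
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- apply(a, 1, stats::var); vb <- apply(b, 1, stats::var)
  na <- ncol(a); nb <- ncol(b)
  se2 <- va / na + vb / nb
  t <- (mb - ma) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  p[is.nan(t)] <- 1          # zero variance, identical means
  p[is.infinite(t)] <- 0     # zero variance, different means
  lfc <- mb - ma
  status <- ifelse(abs(lfc) > min_abs_log2fc & p < max_p,
                   ifelse(lfc > 0, "up", "down"), "ns")
  data.table(gene_id = rownames(expr), log2fc = lfc, p = p, status = status)
}

#' Read an expression matrix from TSV (first column gene id)
#' @param path TSV path.
#' @return numeric matrix with gene-id rownames.
#' @export
read_expression <- function(path) {
  dt <- fread(path, sep = "\t")
  m <- as.matrix(dt[, -1, with = FALSE])
  rownames(m) <- dt[[1]]
  m
}
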