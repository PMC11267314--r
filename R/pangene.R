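# Pan-gene analysis: presence/absence matrix, core/softcore/shell/cloud
# classification, per-assembly composition and saturation curves.

.pan_categories <- c("core", "softcore", "shell", "cloud")

#' Build a presence matrix from an orthogroup table
#'
#' @param og nested list from [read_orthogroups()].
#' @return list of class `"presence_matrix"` with `clusters` (character),
#'   `haplotypes` (character), `present` (logical matrix clusters x
#'   haplotypes) and `gene_counts` (integer matrix, same shape).
#' @export
presence_matrix <- function(og) {
  haps <- attr(og, "haplotypes") %||% names(og[[1]])
  counts <- t(vapply(og, function(cl)
    vapply(haps, function(h) length(cl[[h]]), 0L), integer(length(haps))))
  dimnames(counts) <- list(names(og), haps)
  pm <- structure(list(clusters = names(og), haplotypes = haps,
                       present = counts > 0L, gene_counts = counts),
                  class = "presence_matrix")
  validate_presence_matrix(pm)
  pm
}

validate_presence_matrix <- function(pm) {
  if (!identical(pm$present, pm$gene_counts > 0L)) {
    stop("present must equal gene_counts > 0")
  }
  zero <- rowSums(pm$present) == 0
  if (any(zero)) {
    stop("cluster(s) present in no haplotype: ",
         paste(head(pm$clusters[zero], 5), collapse = ", "))
  }
  invisible(pm)
}

#' Classify clusters into core / softcore / shell / cloud
#'
#' With `N` assemblies: core = present in all `N`; cloud = present in exactly
#' one; softcore = present in `1 < k < N` with `k / N` strictly greater than
#' `softcore_fraction`; shell = the remainder. Core is checked before
#' softcore, so `k = N` is never softcore.
#'
#' @param pm a `presence_matrix`.
#' @param softcore_fraction strict lower presence fraction for softcore
#'   (default 0.80).
#' @return list of class `"pan_classification"`: `category` (named character
#'   per cluster), `presence_count` (named integer), and `summary`
#'   (`data.table` with per-category cluster counts, cluster-level fractions,
#'   gene totals and gene-level fractions).
#' @export
classify_clusters <- function(pm, softcore_fraction = 0.80) {
  validate_presence_matrix(pm)
  n <- length(pm$haplotypes)
  if (n < 2) stop("need at least 2 haplotypes to classify")
  k <- rowSums(pm$present)
  category <- ifelse(k == n, "core",
              ifelse(k == 1, "cloud",
              ifelse(k / n > softcore_fraction, "softcore", "shell")))
  names(category) <- pm$clusters
  genes_per_cluster <- rowSums(pm$gene_counts)
  summary <- data.table(category = .pan_categories)
  summary$n_clusters <- vapply(.pan_categories,
                               function(cat) sum(category == cat), 0L)
  summary$cluster_fraction <- summary$n_clusters / length(category)
  summary$n_genes <- vapply(.pan_categories, function(cat)
    sum(genes_per_cluster[category == cat]), 0)
  summary$gene_fraction <- summary$n_genes / sum(genes_per_cluster)
  structure(list(category = category, presence_count = setNames(k, pm$clusters),
                 summary = summary, softcore_fraction = softcore_fraction,
                 n_haplotypes = n),
            class = "pan_classification")
}

#' Per-assembly pan-category composition
#'
#' For each haplotype assembly, the fraction of its genes that belong to
#' clusters of each category (gene-level weighting; fractions sum to 1).
#'
#' @param pm a `presence_matrix`.
#' @param classification matching [classify_clusters()] result.
#' @return `data.table`: `haplotype_id`, `n_genes`, and one fraction column
#'   per category.
#' @export
per_assembly_composition <- function(pm, classification) {
  if (!identical(names(classification$category), pm$clusters)) {
    stop("classification does not match the presence matrix")
  }
  cat <- classification$category
  out <- data.table(haplotype_id = pm$haplotypes)
  totals <- colSums(pm$gene_counts)
  out[, n_genes := as.integer(totals)]
  for (cc in .pan_categories) {
    out[[cc]] <- colSums(pm$gene_counts[cat == cc, , drop = FALSE]) / totals
  }
  out
}

#' Pan/core saturation curve over random assembly orderings
#'
#' For each ordering and each prefix size `k`, `pan` counts clusters present
#' in at least one of the first `k` assemblies and `core` counts clusters
#' present in all of them; means and standard deviations are taken across
#' orderings. All `N!` orderings are enumerated when `N <= 8` (or when
#' `exhaustive = TRUE`); otherwise `n_permutations` seeded random orderings
#' are sampled.
#'
#' @param pm a `presence_matrix`.
#' @param n_permutations number of random orderings (default 100).
#' @param seed RNG seed for the orderings.
#' @param exhaustive force/disable exhaustive enumeration (default: auto,
#'   `N <= 8`).
#' @return `data.table` of class `"saturation_curve"`: `k`, `pan_mean`,
#'   `pan_sd`, `core_mean`, `core_sd`, with attributes `n_orderings` and
#'   `exhaustive`.
#' @export
saturation_curve <- function(pm, n_permutations = 100L, seed = 1L,
                             exhaustive = NULL) {
  validate_presence_matrix(pm)
  n <- length(pm$haplotypes)
  if (is.null(exhaustive)) exhaustive <- n <= 8
  orderings <- if (exhaustive) {
    all_permutations(n)
  } else {
    if (n_permutations < 1) stop("n_permutations must be >= 1")
    with_seed(seed, replicate(n_permutations, sample.int(n), simplify = FALSE))
  }
  pres <- pm$present
  pan <- matrix(0L, length(orderings), n)
  core <- matrix(0L, length(orderings), n)
  for (i in seq_along(orderings)) {
    ord <- orderings[[i]]
    seen <- rep(FALSE, nrow(pres))
    all_in <- rep(TRUE, nrow(pres))
    for (k in seq_len(n)) {
      col <- pres[, ord[k]]
      seen <- seen | col
      all_in <- all_in & col
      pan[i, k] <- sum(seen)
      core[i, k] <- sum(all_in)
    }
  }
  sd0 <- function(x) if (length(x) > 1) stats::sd(x) else 0
  out <- data.table(k = seq_len(n),
                    pan_mean = colMeans(pan),
                    pan_sd = apply(pan, 2, sd0),
                    core_mean = colMeans(core),
                    core_sd = apply(core, 2, sd0))
  setattr(out, "n_orderings", length(orderings))
  setattr(out, "exhaustive", exhaustive)
  setattr(out, "class", c("saturation_curve", class(out)))
  out
}

all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  idx <- 1L
  for (p in sub) {
    for (pos in seq_len(n)) {
      out[[idx]] <- append(p, n, after = pos - 1L)
      idx <- idx + 1L
    }
  }
  out
}

#' New-cluster increments along one assembly ordering
#'
#' Step `k` counts clusters present in assembly `ordering[k]` but in none of
#' the previous ones; increments sum to the total cluster count.
#'
#' @param pm a `presence_matrix`.
#' @param ordering permutation of `seq_along(pm$haplotypes)` or of the
#'   haplotype ids.
#' @return integer vector of per-step increments.
#' @export
new_cluster_increments <- function(pm, ordering) {
  n <- length(pm$haplotypes)
  if (is.character(ordering)) ordering <- match(ordering, pm$haplotypes)
  if (anyNA(ordering) || !setequal(ordering, seq_len(n)) ||
      length(ordering) != n) {
    stop("ordering is not a permutation of the haplotypes")
  }
  seen <- rep(FALSE, length(pm$clusters))
  out <- integer(n)
  for (k in seq_len(n)) {
    col <- pm$present[, ordering[k]]
    out[k] <- sum(col & !seen)
    seen <- seen | col
  }
  out
}
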