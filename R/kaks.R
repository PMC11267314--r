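# NG86 Ka/Ks for codon-aligned CDS pairs, plus nonparametric category
# contrasts for CDS length / expression / Ka-Ks comparisons.

.codon_bases <- c("T", "C", "A", "G")

codon_translate <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}

# per-codon synonymous site fraction (sum over the 3 positions of the
# fraction of the 3 possible single-base changes that preserve the amino
# acid; changes to stop codons count as nonsynonymous)
syn_sites_of_codon <- function(codon) {
  aa <- codon_translate(codon)
  s <- 0
  for (p in 1:3) {
    base <- substr(codon, p, p)
    for (alt in setdiff(.codon_bases, base)) {
      mut <- codon
      substr(mut, p, p) <- alt
      if (identical(codon_translate(mut), aa)) s <- s + 1 / 3
    }
  }
  s
}

syn_sites_table <- function() {
  if (is.null(.kiwipan_env$syn_sites)) {
    codons <- names(Biostrings::GENETIC_CODE)
    .kiwipan_env$syn_sites <- setNames(
      vapply(codons, syn_sites_of_codon, 0), codons)
  }
  .kiwipan_env$syn_sites
}

# average syn/nonsyn substitution counts over all mutational pathways
# between two codons (equal pathway weighting, stop-passing paths included)
codon_path_diffs <- function(ca, cb) {
  pos <- which(strsplit(ca, "")[[1]] != strsplit(cb, "")[[1]])
  d <- length(pos)
  if (d == 0) return(c(Nd = 0, Sd = 0))
  perms <- all_permutations(d)
  nd <- 0; sd_ <- 0
  for (ord in perms) {
    cur <- ca
    for (step in ord) {
      p <- pos[step]
      nxt <- cur
      substr(nxt, p, p) <- substr(cb, p, p)
      if (identical(codon_translate(nxt), codon_translate(cur))) {
        sd_ <- sd_ + 1
      } else {
        nd <- nd + 1
      }
      cur <- nxt
    }
  }
  c(Nd = nd / length(perms), Sd = sd_ / length(perms))
}

#' NG86 Ka/Ks for one codon-aligned CDS pair
#'
#' Nei–Gojobori (1986) counting: per-codon synonymous/nonsynonymous site
#' fractions averaged over both sequences; observed differences in
#' multi-difference codons averaged with equal weight over every mutational
#' pathway; Jukes–Cantor correction `d = -(3/4) * log(1 - 4p/3)` applied to
#' both proportions. When a proportion reaches 3/4 the correction is
#' undefined and the corresponding rate is `NA` with a warning.
#'
#' @param cds_a,cds_b equal-length coding sequences (character or
#'   `DNAString`), length a multiple of 3, codon-aligned, no internal stops,
#'   gap columns pre-removed.
#' @return list of class `"kaks_result"`: `ka`, `ks`, `ratio` (`NA` unless
#'   `ks > 0`), `n_sites = c(N, S)` (summing to the alignment length) and
#'   `n_diffs = c(Nd, Sd)`.
#' @export
ng86_kaks <- function(cds_a, cds_b) {
  a <- toupper(as.character(cds_a))
  b <- toupper(as.character(cds_b))
  if (nchar(a) != nchar(b)) stop("sequences must have equal length")
  if (nchar(a) %% 3 != 0) stop("sequence length must be a multiple of 3")
  n_codons <- nchar(a) %/% 3
  starts <- 3L * seq_len(n_codons) - 2L
  cod_a <- substring(a, starts, starts + 2L)
  cod_b <- substring(b, starts, starts + 2L)
  if (any(codon_translate(cod_a) == "*") || any(codon_translate(cod_b) == "*")) {
    stop("internal stop codon in input")
  }
  tab <- syn_sites_table()
  s_sites <- (sum(tab[cod_a]) + sum(tab[cod_b])) / 2
  n_sites <- 3 * n_codons - s_sites
  diff_idx <- which(cod_a != cod_b)
  nd <- 0; sd_ <- 0
  for (i in diff_idx) {
    d <- codon_path_diffs(cod_a[i], cod_b[i])
    nd <- nd + d[["Nd"]]
    sd_ <- sd_ + d[["Sd"]]
  }
  jc <- function(p) {
    if (p >= 3 / 4) {
      warning("proportion of differences >= 3/4; Jukes-Cantor undefined",
              call. = FALSE)
      return(NA_real_)
    }
    -3 / 4 * log(1 - 4 * p / 3) + 0  # + 0 normalizes -0 at p = 0
  }
  pn <- if (n_sites > 0) nd / n_sites else 0
  ps <- if (s_sites > 0) sd_ / s_sites else 0
  ka <- jc(pn)
  ks <- jc(ps)
  ratio <- if (!is.na(ka) && !is.na(ks) && ks > 0) ka / ks else NA_real_
  structure(list(ka = ka, ks = ks, ratio = ratio,
                 n_sites = c(N = n_sites, S = s_sites),
                 n_diffs = c(Nd = nd, Sd = sd_)),
            class = "kaks_result")
}

#' Two-category rank-sum contrast (Mann–Whitney U)
#'
#' Two-sided test of `values` between the two levels of `labels`. When both
#' group sizes are at most 10 the p-value is computed by exact enumeration of
#' all rank assignments (ties handled through midranks, identical groups give
#' p = 1); otherwise a normal approximation with tie correction and
#' continuity correction is used.
#'
#' @param values numeric vector.
#' @param labels factor/character of the same length with exactly two levels,
#'   each holding at least two values.
#' @param metric optional name carried into the result.
#' @return list: `metric`, `groups`, `medians`, `U` (for the first level),
#'   `p`, `method`.
#' @export
category_contrast <- function(values, labels, metric = "value") {
  keep <- !is.na(values)
  values <- values[keep]
  labels <- as.character(labels)[keep]
  lv <- sort(unique(labels))
  if (length(lv) != 2) stop("need exactly two non-empty categories")
  x <- values[labels == lv[1]]
  y <- values[labels == lv[2]]
  if (length(x) < 2 || length(y) < 2) {
    stop("each category needs at least two values")
  }
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (n1 <= 10 && n2 <= 10) {
    idx <- combn(n1 + n2, n1)
    us <- apply(idx, 2, function(ii) sum(r[ii]) - n1 * (n1 + 1) / 2)
    p <- mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
    method <- "exact enumeration"
  } else {
    n <- n1 + n2
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (u_obs - mu - sign(u_obs - mu) * 0.5) / sqrt(sigma2)
    p <- if (sigma2 == 0) 1 else 2 * pnorm(-abs(z))
    p <- min(1, p)
    method <- "normal approximation with tie correction"
  }
  list(metric = metric, groups = lv,
       medians = setNames(c(median(x), median(y)), lv),
       U = u_obs, p = p, method = method)
}

# -- CDS extraction and within-accession haplotype pairs ----------------------

#' Extract spliced CDS sequences for gene models
#'
#' Concatenates exon sequences in genomic order and reverse-complements for
#' minus-strand genes.
#'
#' @param seqs chromosome sequences (named character or `DNAStringSet`).
#' @param models a `gene_models` object.
#' @return named character vector, one CDS per gene id.
#' @export
extract_cds <- function(seqs, models) {
  if (!methods::is(seqs, "DNAStringSet")) {
    seqs <- Biostrings::DNAStringSet(seqs)
  }
  g <- models$genes
  e <- copy(models$exons)
  e[, chrom := g$chrom[match(gene_id, g$gene_id)]]
  setorder(e, gene_id, start)
  e[, piece := ""]
  for (ch in unique(e$chrom)) {
    idx <- which(e$chrom == ch)
    pieces <- Biostrings::extractAt(
      seqs[[ch]], IRanges::IRanges(e$start[idx], e$end[idx]))
    e[idx, piece := as.character(pieces)]
  }
  cds <- e[, .(cds = paste(piece, collapse = "")), by = gene_id]
  out <- setNames(cds$cds, cds$gene_id)[g$gene_id]
  minus <- g$strand == "-"
  if (any(minus)) {
    out[minus] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(out[minus])))
  }
  setNames(out, g$gene_id)
}

#' NG86 Ka/Ks for within-accession haplotype gene pairs
#'
#' For every accession and every cluster with exactly one gene in each of the
#' accession's two haplotypes, computes NG86 Ka/Ks between the two CDS copies
#' (terminal stop codon removed; unequal-length pairs are skipped with a log
#' entry, since pre-aligned input is required).
#'
#' @param og orthogroup table ([read_orthogroups()]).
#' @param cds_by_hap named list: haplotype id -> named character vector of
#'   CDS per gene id ([extract_cds()]).
#' @param cohort `cohort_labels`.
#' @param clusters optional subset of cluster ids.
#' @return `data.table`: `cluster_id`, `accession`, `ka`, `ks`, `ratio`.
#' @export
kaks_pairs <- function(og, cds_by_hap, cohort, clusters = NULL) {
  co <- as.data.table(cohort)
  accs <- unique(co$accession)
  if (is.null(clusters)) clusters <- names(og)
  drop_stop <- function(s) {
    if (nchar(s) %% 3 == 0 && nchar(s) >= 3 &&
        codon_translate(substr(s, nchar(s) - 2, nchar(s))) == "*") {
      substr(s, 1, nchar(s) - 3)
    } else s
  }
  rows <- list()
  n_skipped <- 0L
  for (cl in clusters) {
    for (acc in accs) {
      haps <- co[accession == acc]$haplotype_id
      if (length(haps) != 2) next
      ga <- og[[cl]][[haps[1]]]
      gb <- og[[cl]][[haps[2]]]
      if (length(ga) != 1 || length(gb) != 1) next
      sa <- cds_by_hap[[haps[1]]][[ga]]
      sb <- cds_by_hap[[haps[2]]][[gb]]
      if (is.null(sa) || is.null(sb)) next
      sa <- drop_stop(sa); sb <- drop_stop(sb)
      if (nchar(sa) != nchar(sb)) {
        n_skipped <- n_skipped + 1L
        next
      }
      k <- ng86_kaks(sa, sb)
      rows[[length(rows) + 1L]] <- data.table(
        cluster_id = cl, accession = acc,
        ka = k$ka, ks = k$ks, ratio = k$ratio)
    }
  }
  if (n_skipped) {
    kp_log("info", sprintf("kaks_pairs: skipped %d unequal-length pairs",
                           n_skipped))
  }
  if (!length(rows)) {
    return(data.table(cluster_id = character(), accession = character(),
                      ka = numeric(), ks = numeric(), ratio = numeric()))
  }
  rbindlist(rows)
}
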