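# Shared fixtures, all built in code.

random_sv_records <- function(n, chroms = c("Chr1", "Chr2"), max_pos = 100000,
                              types = c("INS", "DEL"), haps = paste0("h", 1:4)) {
  kiwipan::sv_records(
    chrom = sample(chroms, n, replace = TRUE),
    pos = sample(max_pos, n, replace = TRUE),
    svtype = sample(types, n, replace = TRUE),
    length = sample(50:500, n, replace = TRUE),
    alt_seq = NA_character_,
    source_haplotype = sample(haps, n, replace = TRUE))
}

toy_presence <- function(counts_matrix) {
  # build a presence_matrix from an integer gene-count matrix
  og <- lapply(seq_len(nrow(counts_matrix)), function(i) {
    setNames(lapply(seq_len(ncol(counts_matrix)), function(h) {
      nn <- counts_matrix[i, h]
      if (nn > 0) sprintf("c%d.h%d.g%d", i, h, seq_len(nn)) else character()
    }), colnames(counts_matrix))
  })
  names(og) <- rownames(counts_matrix) %||%
    sprintf("OG%03d", seq_len(nrow(counts_matrix)))
  attr(og, "haplotypes") <- colnames(counts_matrix)
  kiwipan::presence_matrix(og)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_presence <- function(n_clusters, n_haps, p = 0.5) {
  m <- matrix(rbinom(n_clusters * n_haps, 3, p), n_clusters, n_haps)
  empty <- rowSums(m) == 0
  m[cbind(which(empty), sample(n_haps, sum(empty), replace = TRUE))] <- 1L
  colnames(m) <- paste0("hap", seq_len(n_haps))
  rownames(m) <- sprintf("OG%04d", seq_len(n_clusters))
  toy_presence(m)
}

toy_gene_models <- function() {
  # two + genes and one - gene on Chr1, one gene on Chr2
  kiwipan::gene_models(
    genes = data.frame(
      gene_id = c("gA", "gB", "gC", "gD"),
      chrom = c("Chr1", "Chr1", "Chr1", "Chr2"),
      start = c(10000, 30000, 50000, 5000),
      end = c(12000, 33000, 52000, 7000),
      strand = c("+", "-", "+", "+")),
    exons = data.frame(
      gene_id = c("gA", "gA", "gB", "gB", "gC", "gD"),
      start = c(10000, 11500, 30000, 32000, 50000, 5000),
      end = c(10800, 12000, 31000, 33000, 52000, 7000)))
}

random_gene_models <- function(n_genes, chrom_len = 200000,
                               chroms = c("Chr1", "Chr2")) {
  slot <- floor(chrom_len / ceiling(n_genes / length(chroms)) )
  rows <- list(); exrows <- list()
  gi <- 0
  for (ch in chroms) {
    n_ch <- ceiling(n_genes / length(chroms))
    for (k in seq_len(n_ch)) {
      gi <- gi + 1
      s <- (k - 1) * slot + sample(2000:3000, 1)
      len <- sample(800:2000, 1)
      e <- min(s + len, chrom_len)
      id <- sprintf("g%03d", gi)
      rows[[gi]] <- data.frame(gene_id = id, chrom = ch, start = s, end = e,
                               strand = sample(c("+", "-"), 1))
      mid <- s + (e - s) %/% 2
      exrows[[gi]] <- data.frame(gene_id = id,
                                 start = c(s, mid + 50),
                                 end = c(mid - 50, e))
    }
  }
  kiwipan::gene_models(do.call(rbind, rows), do.call(rbind, exrows))
}

small_cohort_spec <- function(...) {
  kiwipan::cohort_spec(n_clusters = 60L, chrom_len = 300000L,
                       n_svs_per_haplotype = 60L, n_hotspots = 0L,
                       seed = 7L, ...)
}

# one shared small bundle per test run (generation ~2 s)
small_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dir <- file.path(tempdir(), "kiwipan_small_bundle")
      cache <<- kiwipan::generate_cohort(small_cohort_spec(), dir)
    }
    cache
  }
})

# the default-scale cohort used by the acceptance suite (~1 min)
default_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dir <- file.path(tempdir(), "kiwipan_default_bundle")
      cache <<- kiwipan::generate_cohort(kiwipan::cohort_spec(), dir)
    }
    cache
  }
})

read_bundle_records <- function(bundle) {
  files <- list.files(file.path(bundle$dir, "vcf"), full.names = TRUE)
  data.table::rbindlist(lapply(files, function(f) {
    kiwipan::read_sv_vcf(f, sub("\\.vcf$", "", basename(f)))
  }))
}
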