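# Independent brute-force oracles. These re-derive expected results from
# first principles and deliberately share no code with the implementation.

# pairwise-transitive-from-the-left clustering with the join rule applied to
# cluster representatives (leftmost member)
oracle_merge <- function(records, max_distance = 50, max_size_difference = 20) {
  df <- as.data.frame(records)
  df <- df[order(df$chrom, df$svtype, df$pos, df$length, df$source_haplotype), ]
  clusters <- list()
  for (r in seq_len(nrow(df))) {
    placed <- FALSE
    for (ci in seq_along(clusters)) {
      rep_row <- clusters[[ci]][1, ]
      if (rep_row$chrom == df$chrom[r] && rep_row$svtype == df$svtype[r] &&
          abs(df$pos[r] - rep_row$pos) <= max_distance &&
          abs(df$length[r] - rep_row$length) <= max_size_difference) {
        clusters[[ci]] <- rbind(clusters[[ci]], df[r, ])
        placed <- TRUE
        break
      }
    }
    if (!placed) clusters[[length(clusters) + 1]] <- df[r, ]
  }
  clusters
}

# explicit interval-algebra context classification: tests the SV interval
# against every exon, gene body, and strand-aware flank of every gene
oracle_context <- function(sv_start, sv_end, sv_chrom, genes, exons,
                           promoter_len = 2000, downstream_len = 2000) {
  overlaps <- function(a1, a2, b1, b2) a1 <= b2 && b1 <= a2
  hit_gene <- function(test_fun) {
    hits <- c()
    for (gi in seq_len(nrow(genes))) {
      if (genes$chrom[gi] != sv_chrom) next
      if (test_fun(gi)) hits <- c(hits, gi)
    }
    hits
  }
  ex_hits <- hit_gene(function(gi) {
    ee <- exons[exons$gene_id == genes$gene_id[gi], ]
    any(vapply(seq_len(nrow(ee)), function(k)
      overlaps(sv_start, sv_end, ee$start[k], ee$end[k]), TRUE))
  })
  pick <- function(hits) {
    # leftmost overlapping feature start, then gene id (same tie-break rule)
    hits[order(genes$start[hits], genes$gene_id[hits])][1]
  }
  if (length(ex_hits)) {
    return(list(context = "exonic", gene = genes$gene_id[pick(ex_hits)]))
  }
  g_hits <- hit_gene(function(gi)
    overlaps(sv_start, sv_end, genes$start[gi], genes$end[gi]))
  if (length(g_hits)) {
    return(list(context = "intronic", gene = genes$gene_id[pick(g_hits)]))
  }
  prom <- function(gi) {
    if (genes$strand[gi] == "+") {
      c(max(1, genes$start[gi] - promoter_len), genes$start[gi] - 1)
    } else {
      c(genes$end[gi] + 1, genes$end[gi] + promoter_len)
    }
  }
  p_hits <- hit_gene(function(gi) {
    iv <- prom(gi); iv[1] <= iv[2] && overlaps(sv_start, sv_end, iv[1], iv[2])
  })
  if (length(p_hits)) {
    starts <- vapply(p_hits, function(gi) prom(gi)[1], 0)
    best <- p_hits[order(starts, genes$gene_id[p_hits])][1]
    return(list(context = "promoter", gene = genes$gene_id[best]))
  }
  down <- function(gi) {
    if (genes$strand[gi] == "+") {
      c(genes$end[gi] + 1, genes$end[gi] + downstream_len)
    } else {
      c(max(1, genes$start[gi] - downstream_len), genes$start[gi] - 1)
    }
  }
  d_hits <- hit_gene(function(gi) {
    iv <- down(gi); iv[1] <= iv[2] && overlaps(sv_start, sv_end, iv[1], iv[2])
  })
  if (length(d_hits)) {
    starts <- vapply(d_hits, function(gi) down(gi)[1], 0)
    best <- d_hits[order(starts, genes$gene_id[d_hits])][1]
    return(list(context = "downstream", gene = genes$gene_id[best]))
  }
  on_chrom <- which(genes$chrom == sv_chrom)
  if (!length(on_chrom)) return(list(context = "intergenic", gene = NA))
  dists <- vapply(on_chrom, function(gi) {
    if (overlaps(sv_start, sv_end, genes$start[gi], genes$end[gi])) 0
    else min(abs(genes$start[gi] - sv_end), abs(sv_start - genes$end[gi]))
  }, 0)
  list(context = "intergenic", gene = genes$gene_id[on_chrom[which.min(dists)]])
}

# per-window brute-force count of SV start positions
oracle_window_counts <- function(positions, chrom_len, window, step) {
  starts <- seq(1, chrom_len, by = step)
  vapply(starts, function(s) {
    e <- min(s + window - 1, chrom_len)
    sum(positions >= s & positions <= e)
  }, 0)
}

# exhaustive NG86: every single-base mutation per site for site counts,
# recursive enumeration of every mutational pathway for difference counts
oracle_ng86 <- function(a, b) {
  gc <- Biostrings::GENETIC_CODE
  trans <- function(codon) unname(gc[codon])
  n_cod <- nchar(a) / 3
  s_sites_of <- function(seqx) {
    total <- 0
    for (ci in seq_len(n_cod)) {
      codon <- substr(seqx, 3 * ci - 2, 3 * ci)
      for (p in 1:3) {
        for (nt in c("A", "C", "G", "T")) {
          if (nt == substr(codon, p, p)) next
          mut <- codon
          substr(mut, p, p) <- nt
          if (trans(mut) == trans(codon)) total <- total + 1 / 3
        }
      }
    }
    total
  }
  s_sites <- (s_sites_of(a) + s_sites_of(b)) / 2
  paths <- function(ca, cb) {
    if (ca == cb) return(list(c(s = 0, n = 0)))
    pos <- which(strsplit(ca, "")[[1]] != strsplit(cb, "")[[1]])
    out <- list()
    for (p in pos) {
      nxt <- ca
      substr(nxt, p, p) <- substr(cb, p, p)
      syn <- as.numeric(trans(nxt) == trans(ca))
      for (rest in paths(nxt, cb)) {
        out[[length(out) + 1]] <- c(s = syn + rest[["s"]],
                                    n = (1 - syn) + rest[["n"]])
      }
    }
    out
  }
  sd_ <- 0; nd <- 0
  for (ci in seq_len(n_cod)) {
    ca <- substr(a, 3 * ci - 2, 3 * ci)
    cb <- substr(b, 3 * ci - 2, 3 * ci)
    pp <- paths(ca, cb)
    sd_ <- sd_ + mean(vapply(pp, `[[`, 0, "s"))
    nd <- nd + mean(vapply(pp, `[[`, 0, "n"))
  }
  list(S_sites = s_sites, N_sites = 3 * n_cod - s_sites, Sd = sd_, Nd = nd)
}

# recursive permutation enumeration (independent of the package's version)
oracle_permutations <- function(n) {
  if (n == 1) return(list(1))
  out <- list()
  for (p in oracle_permutations(n - 1)) {
    for (pos in 0:(n - 1)) {
      out[[length(out) + 1]] <- append(p, n, after = pos)
    }
  }
  out
}

random_cds_pair <- function(n_codons, n_mut) {
  sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  a <- paste(sample(sense, n_codons, replace = TRUE), collapse = "")
  b <- a
  for (i in seq_len(n_mut)) {
    repeat {
      p <- sample(nchar(b), 1)
      nt <- sample(c("A", "C", "G", "T"), 1)
      cand <- b
      substr(cand, p, p) <- nt
      ci <- (p - 1) %/% 3 + 1
      codon <- substr(cand, 3 * ci - 2, 3 * ci)
      if (unname(Biostrings::GENETIC_CODE[codon]) != "*") {
        b <- cand
        break
      }
    }
  }
  list(a = a, b = b)
}
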