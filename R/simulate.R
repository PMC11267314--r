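# Synthetic 14-haplotype cohort generator with planted truth.
#
# The generator writes the full input bundle the analysis consumes (per-
# haplotype FASTA + GFF3 + SV VCF, an orthogroup table, an expression matrix,
# group labels, pathway gene lists) plus a truth table recording every
# planted label, so downstream recovery is testable without any downloads.

.default_accessions <- c("Hongyang", "Zps18", "Hort16A", "Huangyang",
                         "Jinmi", "Biyu", "Jinpai")
.default_groups <- c(Hongyang = "RF", Zps18 = "RF", Hort16A = "YF",
                     Huangyang = "YF", Jinmi = "YF", Biyu = "GF",
                     Jinpai = "GF")

#' Synthetic cohort specification
#'
#' Defaults describe a desk-scale analogue of a 7-accession, 14-haplotype
#' kiwifruit cohort in three flesh-colour groups (2 RF, 3 YF, 2 GF), with
#' cluster category proportions 46.6/12.6/40.7/0.1 (core/softcore/shell/
#' cloud), two planted SV hotspots, and one GF-exclusive 51 bp deletion in
#' the promoter of a conserved chlorophyll-pathway ("BCM-like") gene carried
#' by `Biyu.hap2` and `Jinpai.hap1` only, coupled to a late-stage expression
#' increase in the GF accessions.
#'
#' @param n_accessions,haplotypes_per_accession cohort shape (7 x 2).
#' @param accession_names,group_assignment accession names and their
#'   RF/YF/GF groups.
#' @param n_chroms,chrom_len genome shape (3 x 2 Mb).
#' @param n_clusters number of orthogroup clusters (2000).
#' @param category_proportions named numeric (core, softcore, shell, cloud),
#'   summing to 1.
#' @param n_svs_per_haplotype expected SV calls per haplotype (500).
#' @param n_hotspots,hotspot_sv_multiplier planted hotspot windows and their
#'   density multiplier.
#' @param planted_gf_sv list: `svtype`, `length`, `carriers` (must be GF
#'   haplotypes).
#' @param expression list: `meanlog`, `sdlog` (log-normal per-gene means),
#'   `dispersion` (NB), `planted_fold_change` (>= 4, applied to the BCM-like
#'   gene in late-stage GF samples), `core_mean_boost`.
#' @param n_replicates RNA replicates per accession and stage (3).
#' @param seed RNG seed; the whole bundle is a deterministic function of it.
#' @return list of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_accessions = 7L,
                        haplotypes_per_accession = 2L,
                        accession_names = .default_accessions,
                        group_assignment = .default_groups,
                        n_chroms = 3L,
                        chrom_len = 2000000L,
                        n_clusters = 2000L,
                        category_proportions = c(core = 0.466,
                                                 softcore = 0.126,
                                                 shell = 0.407,
                                                 cloud = 0.001),
                        n_svs_per_haplotype = 500L,
                        n_hotspots = 2L,
                        hotspot_sv_multiplier = 5,
                        planted_gf_sv = list(svtype = "DEL", length = 51L,
                                             carriers = c("Biyu.hap2",
                                                          "Jinpai.hap1")),
                        expression = list(meanlog = 4, sdlog = 1,
                                          dispersion = 0.1,
                                          planted_fold_change = 6,
                                          core_mean_boost = 2),
                        n_replicates = 3L,
                        seed = 42L) {
  spec <- list(n_accessions = n_accessions,
               haplotypes_per_accession = haplotypes_per_accession,
               accession_names = accession_names[seq_len(n_accessions)],
               group_assignment = group_assignment,
               n_chroms = n_chroms, chrom_len = as.integer(chrom_len),
               n_clusters = as.integer(n_clusters),
               category_proportions = category_proportions,
               n_svs_per_haplotype = as.integer(n_svs_per_haplotype),
               n_hotspots = as.integer(n_hotspots),
               hotspot_sv_multiplier = hotspot_sv_multiplier,
               planted_gf_sv = planted_gf_sv,
               expression = expression,
               n_replicates = as.integer(n_replicates),
               seed = as.integer(seed))
  validate_cohort_spec(spec)
  class(spec) <- "cohort_spec"
  spec
}

validate_cohort_spec <- function(spec) {
  if (abs(sum(spec$category_proportions) - 1) > 1e-9) {
    stop("category_proportions must sum to 1")
  }
  counts <- c(spec$n_accessions, spec$haplotypes_per_accession, spec$n_chroms,
              spec$chrom_len, spec$n_clusters, spec$n_svs_per_haplotype,
              spec$n_replicates)
  if (any(counts <= 0)) stop("all cohort counts must be positive")
  gf_acc <- names(spec$group_assignment)[spec$group_assignment == "GF"]
  gf_haps <- as.vector(outer(gf_acc, seq_len(spec$haplotypes_per_accession),
                             function(a, k) paste0(a, ".hap", k)))
  bad <- setdiff(spec$planted_gf_sv$carriers, gf_haps)
  if (length(bad)) {
    stop("planted SV carriers must be GF haplotypes; offending: ",
         paste(bad, collapse = ", "))
  }
  invisible(spec)
}

spec_cohort_labels <- function(spec) {
  acc <- rep(spec$accession_names, each = spec$haplotypes_per_accession)
  hapn <- rep(seq_len(spec$haplotypes_per_accession),
              times = spec$n_accessions)
  cohort_labels(paste0(acc, ".hap", hapn), acc,
                unname(spec$group_assignment[acc]))
}

# non-stop codons for CDS simulation
.sense_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}

random_cds <- function(n_internal_codons) {
  paste0("ATG",
         paste(sample(.sense_codons(), n_internal_codons, replace = TRUE),
               collapse = ""),
         "TAA")
}

# codon-aware point mutations: synonymous changes always accepted,
# nonsynonymous accepted with `p_nonsyn`, stops never introduced;
# first (ATG) and last (stop) codons untouched
mutate_cds <- function(cds, n_target, p_nonsyn) {
  n_codons <- nchar(cds) %/% 3
  if (n_codons <= 2 || n_target == 0) return(cds)
  done <- 0L
  attempts <- 0L
  while (done < n_target && attempts < 50L * n_target) {
    attempts <- attempts + 1L
    ci <- sample(2:(n_codons - 1L), 1L)
    p_in <- sample(1:3, 1L)
    pos <- (ci - 1L) * 3L + p_in
    base <- substr(cds, pos, pos)
    alt <- sample(setdiff(.codon_bases, base), 1L)
    mut <- cds
    substr(mut, pos, pos) <- alt
    codon_new <- substr(mut, (ci - 1L) * 3L + 1L, ci * 3L)
    codon_old <- substr(cds, (ci - 1L) * 3L + 1L, ci * 3L)
    if (codon_translate(codon_new) == "*") next
    syn <- codon_translate(codon_new) == codon_translate(codon_old)
    if (!syn && runif(1) > p_nonsyn) next
    cds <- mut
    done <- done + 1L
  }
  cds
}

#' Generate a synthetic cohort bundle on disk
#'
#' Writes, under `out_dir`: `fasta/<hap>.fa`, `gff/<hap>.gff3`,
#' `vcf/<hap>.vcf`, `orthogroups.tsv`, `expression.tsv`, `cohort.tsv`,
#' `groups.tsv`, `chrom_lengths.tsv`, `pathways/chlorophyll.txt`,
#' `pathways/anthocyanin.txt` and `truth.tsv`. The bundle is a deterministic,
#' byte-identical function of `spec` (including its seed).
#'
#' Planted structure: cluster presence counts drawn per category band
#' (core = N, softcore uniform on the > softcore-fraction band, shell uniform
#' on 2..band, cloud = 1) with category counts apportioned exactly by largest
#' remainder; SV positions uniform except multiplier-weighted hotspot
#' windows; the GF deletion placed inside the BCM-like gene's promoter with
#' a geneless slot upstream so its context is unambiguous; the BCM-like gene
#' up-regulated in late-stage GF samples.
#'
#' @param spec a [cohort_spec()].
#' @param out_dir output directory (created if needed).
#' @return list with the main file paths, the truth `data.table`, the cohort
#'   labels and the reference haplotype id, invisibly usable by callers.
#' @export
generate_cohort <- function(spec, out_dir) {
  validate_cohort_spec(spec)
  with_seed(spec$seed, generate_cohort_impl(spec, out_dir))
}

generate_cohort_impl <- function(spec, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (d in c("fasta", "gff", "vcf", "pathways")) {
    dir.create(file.path(out_dir, d), showWarnings = FALSE)
  }
  cohort <- spec_cohort_labels(spec)
  haps <- cohort$haplotype_id
  n_hap <- length(haps)
  ref_hap <- haps[1]
  chroms <- paste0("Chr", seq_len(spec$n_chroms))
  chrom_lengths <- setNames(rep(spec$chrom_len, spec$n_chroms), chroms)
  truth <- list()

  ## 1. cluster categories and presence patterns -----------------------------
  n_cat <- largest_remainder(spec$n_clusters, spec$category_proportions)
  category <- rep(names(spec$category_proportions), n_cat)
  category <- sample(category)  # shuffle across cluster ids
  cluster_ids <- sprintf("OG%05d", seq_len(spec$n_clusters))
  softcore_band <- which(seq_len(n_hap) / n_hap > 0.80 &
                         seq_len(n_hap) < n_hap & seq_len(n_hap) > 1)
  shell_band <- setdiff(which(seq_len(n_hap) / n_hap <= 0.80), 1L)
  if (n_cat[["softcore"]] > 0 && !length(softcore_band)) {
    stop("no presence count satisfies 1 < k < N with k/N > 0.8 for N = ",
         n_hap, "; softcore proportion must be 0 for this cohort size")
  }
  if (n_cat[["shell"]] > 0 && !length(shell_band)) {
    stop("no presence count satisfies 2 <= k <= 0.8N for N = ", n_hap)
  }
  presence <- matrix(FALSE, spec$n_clusters, n_hap,
                     dimnames = list(cluster_ids, haps))
  # the BCM-like gene must exist in every haplotype: pick a core cluster
  bcm_idx <- which(category == "core")[1]
  if (is.na(bcm_idx)) stop("spec has no core cluster to host the planted gene")
  for (i in seq_len(spec$n_clusters)) {
    k <- switch(category[i],
                core = n_hap,
                cloud = 1L,
                softcore = if (length(softcore_band) == 1) softcore_band
                           else sample(softcore_band, 1L),
                shell = sample(shell_band, 1L))
    presence[i, sample(n_hap, k)] <- TRUE
  }
  presence[category == "core", ] <- TRUE
  truth$clusters <- data.table(entity_type = "cluster", id = cluster_ids,
                               planted_label = category)

  ## 2. gene geometry on a shared coordinate grid ----------------------------
  # one extra, geneless slot directly upstream of the BCM-like gene keeps its
  # promoter clear of neighbouring genes and their flanks
  n_slots <- spec$n_clusters + 1L
  per_chrom <- largest_remainder(n_slots, rep(1 / spec$n_chroms,
                                              spec$n_chroms))
  slot_len <- as.integer(spec$chrom_len %/% max(per_chrom))
  offset <- min(2000L, slot_len - 1300L)
  if (offset < 300L) stop("chromosomes too short for this many clusters")
  slot_tab <- rbindlist(lapply(seq_len(spec$n_chroms), function(ci) {
    data.table(chrom = chroms[ci],
               slot_start = as.integer((seq_len(per_chrom[ci]) - 1L) *
                                         slot_len + 1L))
  }))
  # slot assignment: cluster i -> slot i, except the slot before the
  # BCM-like cluster stays empty
  slot_of <- seq_len(spec$n_clusters)
  empty_slot <- bcm_idx  # slots are 1-based; shift clusters >= bcm_idx by 1
  slot_of[seq(bcm_idx, spec$n_clusters)] <-
    slot_of[seq(bcm_idx, spec$n_clusters)] + 1L

  max_span <- slot_len - offset - 80L
  n_internal <- ifelse(category == "core",
                       sample(140:220, spec$n_clusters, replace = TRUE),
                       sample(90:150, spec$n_clusters, replace = TRUE))
  cds_len <- 3L * (n_internal + 2L)
  intron_len <- sample(100:300, spec$n_clusters, replace = TRUE)
  too_big <- cds_len + intron_len > max_span
  if (any(too_big)) {
    intron_len[too_big] <- pmax(60L, max_span - cds_len[too_big])
  }
  strand <- sample(c("+", "-"), spec$n_clusters, replace = TRUE,
                   prob = c(0.5, 0.5))
  strand[bcm_idx] <- "+"
  g_chrom <- slot_tab$chrom[slot_of]
  g_start <- slot_tab$slot_start[slot_of] + offset
  g_end <- g_start + cds_len + intron_len - 1L
  e1_len <- 3L * pmax(1L, (cds_len %/% 6L))
  exon1 <- data.table(start = g_start, end = g_start + e1_len - 1L)
  exon2 <- data.table(start = g_start + e1_len + intron_len, end = g_end)

  ## 3. base CDS and per-haplotype copies ------------------------------------
  base_cds <- vapply(n_internal, random_cds, "")
  p_nonsyn <- ifelse(category == "core", 0.15, 0.7)
  sub_rate <- 0.01

  ## 4. SV loci ---------------------------------------------------------------
  planted <- spec$planted_gf_sv
  planted_pos <- as.integer(g_start[bcm_idx] - 600L)
  hot_start <- as.integer(max(0L, (spec$chrom_len * 0.4) %/% 200000L) *
                            200000L + 1L)
  hot <- data.table(chrom = chroms[rep_len(seq_len(spec$n_chroms),
                                           spec$n_hotspots)],
                    start = hot_start)
  hot[, end := pmin(start + 400000L - 1L, spec$chrom_len)]
  if (spec$n_hotspots > 0) {
    truth$hotspots <- data.table(
      entity_type = "hotspot", id = sprintf("hotspot%d", seq_len(nrow(hot))),
      planted_label = sprintf("chrom=%s;start=%d;end=%d", hot$chrom,
                              hot$start, hot$end))
  }
  mean_k <- mean(1:12)
  n_loci <- round(n_hap * spec$n_svs_per_haplotype / mean_k)
  loci <- draw_sv_loci(n_loci, chroms, chrom_lengths, hot,
                       spec$hotspot_sv_multiplier, planted_pos,
                       g_chrom[bcm_idx], planted$length)
  loci[, k := sample(1:12, .N, replace = TRUE)]
  loci[, carriers := lapply(k, function(kk) sort(sample(haps, kk)))]
  # planted GF-exclusive promoter deletion
  planted_locus <- data.table(chrom = g_chrom[bcm_idx], pos = planted_pos,
                              svtype = planted$svtype,
                              length = as.integer(planted$length),
                              alt_seq = NA_character_, k = NA_integer_,
                              carriers = list(sort(planted$carriers)))
  loci <- rbind(loci, planted_locus, fill = TRUE)
  setorder(loci, chrom, pos)
  loci[, locus_id := sprintf("locus%05d", seq_len(.N))]
  planted_id <- loci[pos == planted_pos & chrom == g_chrom[bcm_idx]]$locus_id
  truth$loci <- data.table(
    entity_type = "sv_locus", id = loci$locus_id,
    planted_label = sprintf("svtype=%s;chrom=%s;pos=%d;length=%d;carriers=%s",
                            loci$svtype, loci$chrom, loci$pos, loci$length,
                            vapply(loci$carriers, paste, "", collapse = "|")))

  ## 5. per-haplotype outputs -------------------------------------------------
  ref_seqs <- setNames(vapply(chroms, function(ch)
    random_dna(spec$chrom_len), ""), chroms)
  og <- vector("list", spec$n_clusters)
  gene_id_of <- matrix(NA_character_, spec$n_clusters, n_hap,
                       dimnames = list(cluster_ids, haps))
  for (h in seq_len(n_hap)) {
    gene_id_of[presence[, h], h] <-
      sprintf("%s.g%04d", haps[h], which(presence[, h]))
  }
  cds_store <- list()  # per-haplotype named CDS vectors (for truth/debug)
  for (h in seq_len(n_hap)) {
    hap <- haps[h]
    idx <- which(presence[, h])
    cds_h <- vapply(idx, function(i) {
      mutate_cds(base_cds[i], stats::rpois(1, sub_rate * cds_len[i]),
                 p_nonsyn[i])
    }, "")
    names(cds_h) <- gene_id_of[idx, h]
    cds_store[[hap]] <- cds_h
    # write CDS into the shared backbone, strand aware
    seqs_h <- ref_seqs
    by_chrom <- split(seq_along(idx), g_chrom[idx])
    for (ch in names(by_chrom)) {
      jj <- by_chrom[[ch]]
      ii <- idx[jj]
      genomic <- ifelse(strand[ii] == "+", cds_h[jj],
                        vapply(cds_h[jj], function(s)
                          as.character(Biostrings::reverseComplement(
                            Biostrings::DNAString(s))), ""))
      at <- IRanges::IRanges(
        start = c(exon1$start[ii], exon2$start[ii]),
        end = c(exon1$end[ii], exon2$end[ii]))
      piece1 <- substr(genomic, 1L, e1_len[ii])
      piece2 <- substr(genomic, e1_len[ii] + 1L, cds_len[ii])
      repl <- Biostrings::DNAStringSet(c(piece1, piece2))
      seqs_h[[ch]] <- as.character(Biostrings::replaceAt(
        Biostrings::DNAString(seqs_h[[ch]]), at, repl))
    }
    write_fasta(seqs_h, file.path(out_dir, "fasta", paste0(hap, ".fa")))
    models_h <- gene_models(
      genes = data.table(gene_id = gene_id_of[idx, h], chrom = g_chrom[idx],
                         start = g_start[idx], end = g_end[idx],
                         strand = strand[idx]),
      exons = rbind(
        data.table(gene_id = gene_id_of[idx, h], start = exon1$start[idx],
                   end = exon1$end[idx]),
        data.table(gene_id = gene_id_of[idx, h], start = exon2$start[idx],
                   end = exon2$end[idx])))
    write_gff3_genes(models_h, file.path(out_dir, "gff",
                                         paste0(hap, ".gff3")))
    mine <- which(vapply(loci$carriers, function(x) hap %in% x, TRUE))
    recs <- sv_records(loci$chrom[mine], loci$pos[mine], loci$svtype[mine],
                       loci$length[mine], loci$alt_seq[mine], hap)
    write_sv_vcf(recs, file.path(out_dir, "vcf", paste0(hap, ".vcf")),
                 chrom_lengths)
  }
  for (i in seq_len(spec$n_clusters)) {
    og[[i]] <- setNames(lapply(seq_len(n_hap), function(h) {
      if (presence[i, h]) gene_id_of[i, h] else character()
    }), haps)
  }
  names(og) <- cluster_ids
  attr(og, "haplotypes") <- haps
  write_orthogroups(og, file.path(out_dir, "orthogroups.tsv"))

  ## 6. expression and pathway lists ------------------------------------------
  ref_idx <- which(presence[, 1])
  ref_genes <- gene_id_of[ref_idx, 1]
  ex <- spec$expression
  mu <- stats::rlnorm(length(ref_idx), ex$meanlog, ex$sdlog)
  mu[category[ref_idx] == "core"] <- mu[category[ref_idx] == "core"] *
    ex$core_mean_boost
  stages <- c("early", "late")
  sample_meta <- CJ(accession = spec$accession_names, stage = stages,
                    rep = seq_len(spec$n_replicates), sorted = FALSE)
  sample_meta[, sample_id := sprintf("%s_%s_r%d", accession, stage, rep)]
  gf_acc <- names(spec$group_assignment)[spec$group_assignment == "GF"]
  counts <- sapply(seq_len(nrow(sample_meta)), function(s) {
    mu_s <- mu
    if (sample_meta$stage[s] == "late" && sample_meta$accession[s] %in%
        gf_acc) {
      bcm_row <- which(ref_idx == bcm_idx)
      mu_s[bcm_row] <- mu_s[bcm_row] * ex$planted_fold_change
    }
    stats::rnbinom(length(mu_s), mu = mu_s, size = 1 / ex$dispersion)
  })
  rownames(counts) <- ref_genes
  colnames(counts) <- sample_meta$sample_id
  expr_dt <- data.table(gene_id = ref_genes)
  expr_dt <- cbind(expr_dt, as.data.table(counts))
  fwrite(expr_dt, file.path(out_dir, "expression.tsv"), sep = "\t")
  fwrite(sample_meta, file.path(out_dir, "samples.tsv"), sep = "\t")

  bcm_gene_ref <- gene_id_of[bcm_idx, 1]
  other_ref <- setdiff(ref_genes, bcm_gene_ref)
  chlorophyll <- c(bcm_gene_ref,
                   sample(other_ref, min(15L, length(other_ref))))
  remaining <- setdiff(other_ref, chlorophyll)
  anthocyanin <- sample(remaining, min(20L, length(remaining)))
  writeLines(chlorophyll, file.path(out_dir, "pathways", "chlorophyll.txt"))
  writeLines(anthocyanin, file.path(out_dir, "pathways", "anthocyanin.txt"))

  ## 7. labels and truth -------------------------------------------------------
  write_cohort_labels(cohort, file.path(out_dir, "cohort.tsv"))
  fwrite(unique(as.data.table(cohort)[, .(accession, group)]),
         file.path(out_dir, "groups.tsv"), sep = "\t")
  write_chrom_lengths(chrom_lengths, file.path(out_dir, "chrom_lengths.tsv"))
  truth$planted <- data.table(
    entity_type = "planted_sv", id = planted_id,
    planted_label = sprintf(
      "chrom=%s;pos=%d;svtype=%s;length=%d;carriers=%s;gene=%s;cluster=%s",
      g_chrom[bcm_idx], planted_pos, planted$svtype, planted$length,
      paste(sort(planted$carriers), collapse = "|"), bcm_gene_ref,
      cluster_ids[bcm_idx]))
  truth$de <- data.table(entity_type = "de_gene", id = bcm_gene_ref,
                         planted_label = "up")
  truth_dt <- rbindlist(truth)
  fwrite(truth_dt, file.path(out_dir, "truth.tsv"), sep = "\t")

  invisible(list(dir = out_dir, truth = truth_dt, cohort = cohort,
                 reference_haplotype = ref_hap,
                 chrom_lengths = chrom_lengths,
                 bcm = list(cluster = cluster_ids[bcm_idx],
                            gene = bcm_gene_ref, sv_id = planted_id,
                            pos = planted_pos, chrom = g_chrom[bcm_idx])))
}

# weighted placement of SV loci: uniform along the genome except hotspot
# windows (weight = multiplier); intervals kept disjoint with a 100 bp gap
# and clear of a 250 bp exclusion zone around the planted deletion
draw_sv_loci <- function(n_loci, chroms, chrom_lengths, hot, multiplier,
                         planted_pos, planted_chrom, planted_len) {
  type_prob <- c(DEL = 0.44, INS = 0.44, INV = 0.08, TRA = 0.04)
  svtype <- sample(names(type_prob), n_loci, replace = TRUE,
                   prob = type_prob)
  len <- pmin(2000L, 50L + as.integer(stats::rexp(n_loci, 1 / 150)))
  # piecewise-constant position weights per chromosome
  segs <- rbindlist(lapply(chroms, function(ch) {
    L <- as.integer(chrom_lengths[[ch]])
    h <- hot[chrom == ch]
    cuts <- sort(unique(c(1L, h$start, h$end + 1L, L + 1L)))
    cuts <- cuts[cuts <= L + 1L]
    s <- head(cuts, -1L); e <- tail(cuts, -1L) - 1L
    w <- rep(1, length(s))
    for (j in seq_len(nrow(h))) {
      w[s >= h$start[j] & e <= h$end[j]] <- multiplier
    }
    data.table(chrom = ch, start = s, end = e, w = w * (e - s + 1))
  }))
  occupied <- data.table(chrom = character(), start = integer(),
                         end = integer())
  excl <- data.table(chrom = planted_chrom,
                     start = planted_pos - 250L,
                     end = planted_pos + planted_len + 250L)
  occupied <- rbind(occupied, excl)
  pos <- integer(n_loci)
  chrom <- character(n_loci)
  for (i in seq_len(n_loci)) {
    for (try in 1:200) {
      seg <- sample.int(nrow(segs), 1L, prob = segs$w)
      p <- as.integer(segs$start[seg] +
                        floor(runif(1) * (segs$end[seg] - segs$start[seg] + 1)))
      span_end <- if (svtype[i] %in% c("DEL", "INV")) p + len[i] - 1L else p
      if (span_end > chrom_lengths[[segs$chrom[seg]]]) next
      clash <- occupied[chrom == segs$chrom[seg] &
                          start <= span_end + 100L & end >= p - 100L]
      if (nrow(clash)) next
      pos[i] <- p
      chrom[i] <- segs$chrom[seg]
      occupied <- rbind(occupied, data.table(chrom = chrom[i], start = p,
                                             end = span_end))
      break
    }
    if (pos[i] == 0L) stop("could not place SV locus ", i,
                           " without overlap; genome too crowded")
  }
  alt_seq <- ifelse(svtype == "INS",
                    vapply(len, random_dna, ""), NA_character_)
  data.table(chrom = chrom, pos = pos, svtype = svtype, length = len,
             alt_seq = alt_seq)
}
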