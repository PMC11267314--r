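# Orthogroup tables, BED, GFF3 gene models and FASTA plumbing.
# BED is 0-based half-open on disk; everything in memory is 1-based inclusive.

#' Read an orthogroup cluster table
#'
#' Parses the OrthoFinder `Orthogroups.tsv` dialect: first column the cluster
#' id, one column per haplotype assembly, cells comma-separated gene ids (or
#' empty). Every gene id must appear in exactly one cluster.
#'
#' @param path TSV path.
#' @param cohort optional `cohort_labels`; when given, header haplotypes are
#'   cross-checked against the registry and unknown columns are an error.
#' @return named list: `cluster_id -> named list: haplotype_id -> character
#'   vector of gene ids`, with attribute `"haplotypes"` (column order).
#' @export
read_orthogroups <- function(path, cohort = NULL) {
  dt <- fread(path, sep = "\t", colClasses = "character", header = TRUE)
  haps <- names(dt)[-1]
  if (!is.null(cohort)) {
    unknown <- setdiff(haps, as.data.table(cohort)$haplotype_id)
    if (length(unknown)) {
      stop("orthogroup columns absent from cohort labels: ",
           paste(unknown, collapse = ", "))
    }
  }
  split_cell <- function(x) {
    if (is.na(x) || !nzchar(trimws(x))) return(character())
    trimws(strsplit(x, ",", fixed = TRUE)[[1]])
  }
  og <- lapply(seq_len(nrow(dt)), function(i) {
    row <- as.character(dt[i, -1, with = FALSE])
    setNames(lapply(row, split_cell), haps)
  })
  names(og) <- dt[[1]]
  all_genes <- unlist(og, use.names = FALSE)
  dup <- unique(all_genes[duplicated(all_genes)])
  if (length(dup)) {
    stop("gene id(s) present in more than one cluster: ",
         paste(head(dup, 10), collapse = ", "))
  }
  attr(og, "haplotypes") <- haps
  og
}

#' Write an orthogroup cluster table
#' @param og nested list as returned by [read_orthogroups()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_orthogroups <- function(og, path) {
  haps <- attr(og, "haplotypes") %||% names(og[[1]])
  rows <- vapply(names(og), function(cl) {
    cells <- vapply(haps, function(h) paste(og[[cl]][[h]], collapse = ", "), "")
    paste(c(cl, cells), collapse = "\t")
  }, "")
  writeLines(c(paste(c("Orthogroup", haps), collapse = "\t"), rows), path)
  invisible(path)
}

# -- BED ----------------------------------------------------------------------

#' Write intervals to BED (0-based half-open on disk)
#'
#' @param intervals data.frame with `chrom`, `start`, `end` (1-based
#'   inclusive) and any extra columns, written after the first three.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  dt <- as.data.table(intervals)
  extra <- setdiff(names(dt), c("chrom", "start", "end"))
  hdr <- paste0("#", paste(c("chrom", "start", "end", extra), collapse = "\t"))
  if (!nrow(dt)) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  out <- data.table(chrom = dt$chrom, start = dt$start - 1L, end = dt$end)
  for (col in extra) out[[col]] <- dt[[col]]
  writeLines(c(hdr, do.call(paste, c(out, sep = "\t"))), path)
  invisible(path)
}

#' Read a BED file into 1-based inclusive intervals
#' @param path BED path (may start with `#` header lines).
#' @return `data.table` with `chrom`, `start`, `end` and any extra columns.
#' @export
read_bed <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  cols <- if (length(hdr)) {
    strsplit(sub("^#", "", hdr[1]), "\t", fixed = TRUE)[[1]]
  } else c("chrom", "start", "end")
  if (!length(body)) {
    out <- as.data.table(setNames(rep(list(character()), length(cols)), cols))
    out[, start := integer()][, end := integer()]
    return(out)
  }
  dt <- fread(text = body, sep = "\t", header = FALSE)
  setnames(dt, seq_along(cols), cols)
  dt[, start := as.integer(start) + 1L]
  dt[, end := as.integer(end)]
  dt
}

#' Write a generic TSV table
#' @param table data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(table, path) {
  fwrite(as.data.table(table), path, sep = "\t")
  invisible(path)
}

#' Read a generic TSV table
#' @param path TSV path.
#' @return `data.table`.
#' @export
read_tsv <- function(path) fread(path, sep = "\t")

# -- GFF3 gene models ---------------------------------------------------------

#' Build a gene model set
#'
#' @param genes data.frame with `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @param exons data.frame with `gene_id`, `start`, `end` (1-based inclusive;
#'   sorted, pairwise disjoint, within the gene span).
#' @return list of class `"gene_models"` with `genes` and `exons`
#'   `data.table`s.
#' @export
gene_models <- function(genes, exons) {
  g <- as.data.table(genes)[, .(gene_id = as.character(gene_id),
                                chrom = as.character(chrom),
                                start = as.integer(start),
                                end = as.integer(end),
                                strand = as.character(strand))]
  e <- as.data.table(exons)[, .(gene_id = as.character(gene_id),
                                start = as.integer(start),
                                end = as.integer(end))]
  if (nrow(g)) {
    if (any(g$start > g$end)) stop("gene start > end")
    if (!all(g$strand %in% c("+", "-"))) stop("strand must be + or -")
    if (!all(e$gene_id %in% g$gene_id)) stop("exon with unknown gene_id")
    missing_ex <- setdiff(g$gene_id, e$gene_id)
    if (length(missing_ex)) {
      stop("gene(s) without exons: ", paste(head(missing_ex, 5), collapse = ", "))
    }
    setorder(e, gene_id, start)
    ov <- e[, .(bad = any(start[-1] <= end[-.N])), by = gene_id][bad == TRUE]
    if (nrow(ov)) {
      stop("overlapping exons in gene(s): ", paste(ov$gene_id, collapse = ", "))
    }
  }
  structure(list(genes = g, exons = e), class = "gene_models")
}

#' Read gene models from GFF3
#'
#' Uses `rtracklayer`; keeps `gene` features and their `exon` children
#' (via the `Parent` attribute, with any intermediate mRNA level collapsed).
#'
#' @param path GFF3 path.
#' @return a `gene_models` object.
#' @export
read_gff3_genes <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  meta <- S4Vectors::mcols(gr)
  type <- as.character(meta$type)
  ids <- as.character(meta$ID)
  parent <- vapply(as.list(meta$Parent), function(p)
    if (length(p)) as.character(p[1]) else NA_character_, "")
  gene_idx <- which(type == "gene")
  genes <- data.table(gene_id = ids[gene_idx],
                      chrom = as.character(GenomicRanges::seqnames(gr))[gene_idx],
                      start = GenomicRanges::start(gr)[gene_idx],
                      end = GenomicRanges::end(gr)[gene_idx],
                      strand = as.character(GenomicRanges::strand(gr))[gene_idx])
  # map features to their owning gene through at most one mRNA level
  owner <- setNames(ids[gene_idx], ids[gene_idx])
  mrna_idx <- which(type == "mRNA")
  owner[ids[mrna_idx]] <- parent[mrna_idx]
  exon_idx <- which(type == "exon")
  exons <- data.table(gene_id = unname(owner[parent[exon_idx]]),
                      start = GenomicRanges::start(gr)[exon_idx],
                      end = GenomicRanges::end(gr)[exon_idx])
  gene_models(genes, exons)
}

#' Write gene models to GFF3
#' @param models a `gene_models` object.
#' @param path output path.
#' @param source source column value.
#' @return `path`, invisibly.
#' @export
write_gff3_genes <- function(models, path, source = "kiwipan") {
  g <- models$genes
  e <- copy(models$exons)
  strand <- setNames(g$strand, g$gene_id)
  chrom <- setNames(g$chrom, g$gene_id)
  gl <- sprintf("%s\t%s\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                g$chrom, source, g$start, g$end, g$strand, g$gene_id)
  e[, n := seq_len(.N), by = gene_id]
  el <- sprintf("%s\t%s\texon\t%d\t%d\t.\t%s\t.\tID=%s.exon%d;Parent=%s",
                chrom[e$gene_id], source, e$start, e$end, strand[e$gene_id],
                e$gene_id, e$n, e$gene_id)
  # interleave: gene line then its exons, grouped, ordered by coordinate
  ord <- order(g$chrom, g$start)
  lines <- unlist(lapply(ord, function(i) {
    c(gl[i], el[e$gene_id == g$gene_id[i]])
  }))
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Read chromosome sequences from FASTA
#' @param path FASTA path.
#' @return a `Biostrings::DNAStringSet`.
#' @export
read_fasta <- function(path) Biostrings::readDNAStringSet(path)

#' Write chromosome sequences to FASTA
#' @param seqs named character vector or `DNAStringSet`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (!methods::is(seqs, "DNAStringSet")) {
    seqs <- Biostrings::DNAStringSet(seqs)
  }
  Biostrings::writeXStringSet(seqs, path, width = 80L)
  invisible(path)
}
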