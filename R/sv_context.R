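# Genomic context of SVs, promoter-SV / expression intersection, and
# group-specific / pathway-associated SV detection.

.contexts <- c("exonic", "intronic", "promoter", "downstream", "intergenic")

sv_interval <- function(dt) {
  # DEL/INV occupy [pos, pos+len-1]; INS and TRA are points at pos
  wide <- dt$svtype %in% c("DEL", "INV")
  data.table(start = dt$pos,
             end = ifelse(wide, dt$pos + dt$length - 1L, dt$pos))
}

#' Classify the genomic context of each SV
#'
#' Each SV gets exactly one label with priority `exonic > intronic >
#' promoter > downstream > intergenic` (>= 1 bp overlap). The promoter is the
#' `promoter_len` bp immediately upstream of the annotated gene start (ATG
#' side), strand-aware; `downstream_len` bp past the gene end likewise.
#' Intergenic SVs are linked to the nearest gene on the same chromosome
#' (`NA` if the chromosome has no genes).
#'
#' @param svs a `nonredundant_svs` or `sv_records` table.
#' @param models a `gene_models` object.
#' @param promoter_len,downstream_len flank sizes in bp (defaults 2000).
#' @param chrom_lengths optional named vector used to clip flank intervals.
#' @return `data.table` of class `"sv_contexts"`: `sv_id`, `chrom`, `pos`,
#'   `svtype`, `context`, `linked_gene`, `distance_to_gene`.
#' @export
classify_context <- function(svs, models, promoter_len = 2000L,
                             downstream_len = 2000L, chrom_lengths = NULL) {
  dt <- as.data.table(svs)
  iv <- sv_interval(dt)
  sv_id <- if (!is.null(dt$id)) dt$id else sprintf("sv%05d", seq_len(nrow(dt)))
  g <- models$genes
  e <- models$exons
  gchrom <- setNames(g$chrom, g$gene_id)

  clip <- function(chrom, start, end) {
    start <- pmax(start, 1L)
    if (!is.null(chrom_lengths)) {
      end <- pmin(end, as.integer(chrom_lengths[chrom]))
    }
    list(start = start, end = end)
  }
  plus <- g$strand == "+"
  prom <- clip(g$chrom,
               ifelse(plus, g$start - promoter_len, g$end + 1L),
               ifelse(plus, g$start - 1L, g$end + promoter_len))
  down <- clip(g$chrom,
               ifelse(plus, g$end + 1L, g$start - downstream_len),
               ifelse(plus, g$end + downstream_len, g$start - 1L))

  lv <- sort(unique(c(dt$chrom, g$chrom)))
  chr_of <- function(x) factor(x, levels = lv)
  sv_gr <- GenomicRanges::GRanges(chr_of(dt$chrom),
                                  IRanges::IRanges(iv$start, iv$end))
  feature_sets <- list(
    exonic = GenomicRanges::GRanges(chr_of(gchrom[e$gene_id]),
                                    IRanges::IRanges(e$start, e$end),
                                    gene_id = e$gene_id),
    intronic = GenomicRanges::GRanges(chr_of(g$chrom),
                                      IRanges::IRanges(g$start, g$end),
                                      gene_id = g$gene_id),
    promoter = GenomicRanges::GRanges(chr_of(g$chrom),
                                      IRanges::IRanges(prom$start, prom$end),
                                      gene_id = g$gene_id),
    downstream = GenomicRanges::GRanges(chr_of(g$chrom),
                                        IRanges::IRanges(down$start, down$end),
                                        gene_id = g$gene_id)
  )
  context <- rep("intergenic", nrow(dt))
  linked <- rep(NA_character_, nrow(dt))
  unassigned <- rep(TRUE, nrow(dt))
  for (ctx in names(feature_sets)) {
    if (!any(unassigned) || !nrow(g)) break
    fs <- feature_sets[[ctx]]
    keep <- IRanges::width(fs) > 0
    fs <- fs[keep]
    hits <- GenomicRanges::findOverlaps(sv_gr[unassigned], fs)
    if (!length(hits)) next
    hdt <- data.table(sv = which(unassigned)[S4Vectors::queryHits(hits)],
                      gene = S4Vectors::mcols(fs)$gene_id[
                        S4Vectors::subjectHits(hits)],
                      gstart = GenomicRanges::start(fs)[
                        S4Vectors::subjectHits(hits)])
    # deterministic tie-break: leftmost overlapping feature, then gene id
    setorder(hdt, sv, gstart, gene)
    first <- hdt[!duplicated(sv)]
    context[first$sv] <- ctx
    linked[first$sv] <- first$gene
    unassigned[first$sv] <- FALSE
  }
  dist <- ifelse(unassigned, NA_integer_, 0L)
  if (any(unassigned) && nrow(g)) {
    gene_gr <- GenomicRanges::GRanges(chr_of(g$chrom),
                                      IRanges::IRanges(g$start, g$end))
    idx <- which(unassigned)
    near <- GenomicRanges::nearest(sv_gr[idx], gene_gr)
    ok <- !is.na(near)
    linked[idx[ok]] <- g$gene_id[near[ok]]
    dist[idx[ok]] <- GenomicRanges::distance(sv_gr[idx][ok], gene_gr[near[ok]])
  }
  out <- data.table(sv_id = sv_id, chrom = dt$chrom, pos = dt$pos,
                    svtype = dt$svtype, context = context,
                    linked_gene = linked, distance_to_gene = dist)
  setattr(out, "class", c("sv_contexts", class(out)))
  out
}

#' Collapse the 5-way context split to a 3-way view
#'
#' Promoter and downstream SVs are folded into `intergenic`, matching the
#' coarser exonic/intronic/intergenic accounting some reports use.
#'
#' @param contexts an `sv_contexts` table.
#' @return the table with an added `context3` column.
#' @export
collapse_context <- function(contexts) {
  out <- copy(as.data.table(contexts))
  out[, context3 := ifelse(context %in% c("promoter", "downstream"),
                           "intergenic", context)]
  out
}

#' Group-specific SVs (presence- and absence-specific)
#'
#' An SV is `presence_specific` to the focal group when its carriers are
#' non-empty and all belong to the focal group's haplotypes (a proper subset
#' qualifies); `absence_specific` when its non-carriers are non-empty and all
#' belong to the focal group.
#'
#' @param catalog a `nonredundant_svs` table.
#' @param cohort `cohort_labels`.
#' @param focal_group one of `"RF"`, `"YF"`, `"GF"`.
#' @return `data.table`: `sv_id`, `focal_group`, `mode`, `carriers` (list).
#' @export
group_specific_svs <- function(catalog, cohort, focal_group) {
  focal <- haplotypes_of(cohort, group = focal_group)
  all_h <- haplotypes_of(cohort)
  dt <- as.data.table(catalog)
  res <- lapply(seq_len(nrow(dt)), function(i) {
    car <- dt$carriers[[i]]
    non <- setdiff(all_h, car)
    mode <- if (length(car) && all(car %in% focal)) "presence_specific"
      else if (length(non) && all(non %in% focal)) "absence_specific"
      else NA_character_
    if (is.na(mode)) return(NULL)
    data.table(sv_id = dt$id[i], focal_group = focal_group, mode = mode,
               carriers = list(car))
  })
  res <- res[!vapply(res, is.null, TRUE)]
  if (!length(res)) {
    return(data.table(sv_id = character(), focal_group = character(),
                      mode = character(), carriers = list()))
  }
  rbindlist(res)
}

#' Fractions of promoter-SV genes that are DE between two accessions
#'
#' Restricts the catalog to SVs polymorphic between the accession pair
#' (carried by at least one haplotype of exactly one of the two accessions)
#' whose context is `promoter`, collects their linked genes, and splits them
#' by differential-expression status.
#'
#' @param catalog a `nonredundant_svs` table.
#' @param contexts matching `sv_contexts` (same `sv_id`s).
#' @param accession_pair length-2 character vector of accession names.
#' @param de_table `data.table` with `gene_id` and `status` in
#'   `c("up", "down", "ns")`; genes absent from it are counted as `ns`.
#' @param cohort `cohort_labels`.
#' @return list: `n_genes`, `genes` (`data.table` gene_id/status), and
#'   `fractions` (named up/down/ns, summing to 1) — or `empty = TRUE` with
#'   `n_genes = 0` when no gene qualifies.
#' @export
promoter_de_overlap <- function(catalog, contexts, accession_pair, de_table,
                                cohort) {
  if (length(accession_pair) != 2) stop("accession_pair must have length 2")
  co <- as.data.table(cohort)
  missing_acc <- setdiff(accession_pair, co$accession)
  if (length(missing_acc)) {
    stop("accession(s) not in cohort: ", paste(missing_acc, collapse = ", "))
  }
  h1 <- haplotypes_of(cohort, accession = accession_pair[1])
  h2 <- haplotypes_of(cohort, accession = accession_pair[2])
  dt <- as.data.table(catalog)
  poly <- vapply(dt$carriers, function(car) {
    xor(any(car %in% h1), any(car %in% h2))
  }, TRUE)
  ctx <- as.data.table(contexts)
  prom_ids <- ctx[context == "promoter"]$sv_id
  qual <- dt[poly & id %in% prom_ids]
  genes <- unique(ctx[sv_id %in% qual$id]$linked_gene)
  genes <- genes[!is.na(genes)]
  if (!length(genes)) {
    return(list(empty = TRUE, n_genes = 0L))
  }
  de <- as.data.table(de_table)
  status <- de$status[match(genes, de$gene_id)]
  status[is.na(status)] <- "ns"
  frac <- vapply(c(up = "up", down = "down", ns = "ns"),
                 function(s) mean(status == s), 0)
  list(empty = FALSE, n_genes = length(genes),
       genes = data.table(gene_id = genes, status = status),
       fractions = frac)
}

#' SVs associated with a pathway gene list
#'
#' Associates every SV whose `linked_gene` (including intergenic-nearest
#' links) is in `pathway_genes`, with a per-context breakdown. Pathway ids
#' absent from the gene models are skipped with a warning.
#'
#' @param catalog a `nonredundant_svs` (or `sv_records`) table.
#' @param contexts matching `sv_contexts`.
#' @param pathway_genes character vector of gene ids (the list is an input;
#'   homolog identification is out of scope).
#' @param models `gene_models` used to validate the list.
#' @return list: `associations` (`data.table` sv_id/linked_gene/context) and
#'   `by_context` (counts per context).
#' @export
pathway_sv_association <- function(catalog, contexts, pathway_genes, models) {
  known <- models$genes$gene_id
  absent <- setdiff(pathway_genes, known)
  if (length(absent)) {
    warning("pathway gene id(s) absent from gene models, skipped: ",
            paste(absent, collapse = ", "), call. = FALSE)
    pathway_genes <- setdiff(pathway_genes, absent)
  }
  ctx <- as.data.table(contexts)
  assoc <- ctx[linked_gene %in% pathway_genes,
               .(sv_id, linked_gene, context, distance_to_gene)]
  by_ctx <- setNames(vapply(.contexts, function(cc)
    sum(assoc$context == cc), 0L), .contexts)
  list(associations = assoc, by_context = by_ctx)
}
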