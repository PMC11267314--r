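# Non-redundant SV catalog: merge per-haplotype calls, carrier sets,
# accession frequency spectrum and per-accession counts.

#' Merge INS/DEL calls into a non-redundant catalog
#'
#' Records are sorted by `(chrom, svtype, pos)` and scanned left to right.
#' A record joins the earliest existing cluster (same chrom and svtype) whose
#' representative — the cluster's leftmost member — satisfies both
#' `|pos - rep.pos| <= max_distance` and `|length - rep.length| <=
#' max_size_difference`; otherwise it opens a new cluster. First-match over
#' representative order makes the operation deterministic and idempotent
#' (no two representatives can satisfy the join rule with each other).
#' Distances are start-to-start; the size tolerance is absolute bp.
#'
#' @param records an `sv_records` table restricted to `INS`/`DEL` types.
#' @param max_distance maximum representative start distance (default 50 bp).
#' @param max_size_difference maximum absolute length difference (default
#'   20 bp).
#' @param chrom_lengths optional named vector; records on chromosomes absent
#'   from it are an error.
#' @return `data.table` of class `"nonredundant_svs"`, sorted by
#'   `(chrom, pos)`: `id`, `chrom`, `pos`, `svtype`, `length`, `alt_seq`
#'   (representative fields), `nmembers`, `carriers` (list column of
#'   haplotype ids) and `members` (list column of member row data.tables).
#' @export
merge_svs <- function(records, max_distance = 50L, max_size_difference = 20L,
                      chrom_lengths = NULL) {
  dt <- as.data.table(records)
  if (nrow(dt) && !all(dt$svtype %in% c("INS", "DEL"))) {
    stop("merge_svs takes INS/DEL records only; catalog INV/TRA separately")
  }
  if (!is.null(chrom_lengths)) {
    bad <- setdiff(unique(dt$chrom), names(chrom_lengths))
    if (length(bad)) {
      stop("record(s) on unknown chromosome(s): ", paste(bad, collapse = ", "))
    }
  }
  if (!nrow(dt)) {
    out <- data.table(id = character(), chrom = character(), pos = integer(),
                      svtype = character(), length = integer(),
                      alt_seq = character(), nmembers = integer(),
                      carriers = list(), members = list())
    setattr(out, "class", c("nonredundant_svs", class(out)))
    return(out)
  }
  dt <- copy(dt)
  setorder(dt, chrom, svtype, pos, length, source_haplotype)
  cluster_of <- integer(nrow(dt))
  rep_pos <- integer(0)
  rep_len <- integer(0)
  rep_chrom <- character(0)
  rep_type <- character(0)
  n_cl <- 0L
  for (i in seq_len(nrow(dt))) {
    p <- dt$pos[i]; l <- dt$length[i]
    assigned <- 0L
    if (n_cl > 0L) {
      # earliest matching representative wins
      for (j in seq_len(n_cl)) {
        if (rep_chrom[j] == dt$chrom[i] && rep_type[j] == dt$svtype[i] &&
            abs(p - rep_pos[j]) <= max_distance &&
            abs(l - rep_len[j]) <= max_size_difference) {
          assigned <- j
          break
        }
      }
    }
    if (assigned == 0L) {
      n_cl <- n_cl + 1L
      rep_pos[n_cl] <- p
      rep_len[n_cl] <- l
      rep_chrom[n_cl] <- dt$chrom[i]
      rep_type[n_cl] <- dt$svtype[i]
      assigned <- n_cl
    }
    cluster_of[i] <- assigned
  }
  dt[, .cl := cluster_of]
  out <- dt[, {
    .(chrom = chrom[1], pos = pos[1], svtype = svtype[1], length = length[1],
      alt_seq = alt_seq[1], nmembers = .N,
      carriers = list(sort(unique(source_haplotype))),
      members = list(data.table(chrom, pos, svtype, length, alt_seq,
                                source_haplotype)))
  }, by = .cl][, .cl := NULL]
  setorder(out, chrom, pos, svtype)
  out[, id := sprintf("nrSV%05d", seq_len(.N))]
  setcolorder(out, c("id", "chrom", "pos", "svtype", "length", "alt_seq",
                     "nmembers", "carriers", "members"))
  setattr(out, "class", c("nonredundant_svs", class(out)))
  out
}

#' Accession frequency spectrum of a merged catalog
#'
#' Each non-redundant SV is counted once at the number of distinct accessions
#' carrying it (both haplotypes of one accession still count as one).
#'
#' @param catalog a `nonredundant_svs` table.
#' @param cohort `cohort_labels` mapping haplotypes to accessions.
#' @return `data.table` with `n_accessions` (1..number of accessions) and
#'   `n_svs`; `sum(n_svs)` equals the catalog size.
#' @export
frequency_spectrum <- function(catalog, cohort) {
  n_acc <- length(unique(as.data.table(cohort)$accession))
  freq <- vapply(catalog$carriers, function(h)
    length(unique(accession_of(cohort, h))), 0L)
  data.table(n_accessions = seq_len(n_acc),
             n_svs = vapply(seq_len(n_acc), function(a) sum(freq == a), 0L))
}

#' Pre-merge SV counts per accession and type
#'
#' @param records an `sv_records` table (all four types allowed).
#' @param cohort `cohort_labels`.
#' @return `data.table`: `accession`, one column per svtype, and `total`.
#' @export
per_accession_counts <- function(records, cohort) {
  co <- as.data.table(cohort)
  dt <- copy(as.data.table(records))
  out <- data.table(accession = unique(co$accession))
  if (nrow(dt)) dt[, accession := accession_of(cohort, source_haplotype)]
  for (tp in .sv_types) {
    cnt <- if (nrow(dt)) dt[svtype == tp, .N, by = accession] else NULL
    set(out, j = tp, value = 0L)
    if (!is.null(cnt) && nrow(cnt)) {
      out[cnt, on = "accession", (tp) := i.N]
    }
  }
  out[, total := INS + DEL + INV + TRA]
  out
}

#' Write a merged catalog as VCF (with CARRIERS/NMEMBERS INFO)
#' @param catalog a `nonredundant_svs` table.
#' @param path output path.
#' @param chrom_lengths optional named vector for `##contig` lines.
#' @return `path`, invisibly.
#' @export
write_merged_vcf <- function(catalog, path, chrom_lengths = NULL) {
  dt <- copy(as.data.table(catalog))
  dt[, carriers_str := vapply(carriers, paste, "", collapse = ",")]
  dt[, members := NULL]
  dt[, carriers := NULL]
  dt[, source_haplotype := NA_character_]
  write_sv_vcf(dt, path, chrom_lengths)
  invisible(path)
}

#' Read a merged catalog VCF written by [write_merged_vcf()]
#' @param path VCF path.
#' @return a `nonredundant_svs` table (without `members` detail).
#' @export
read_merged_vcf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- lines[!startsWith(lines, "#")]
  recs <- lapply(seq_along(body), function(i) {
    f <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
    info <- parse_info(f[8])
    symbolic <- grepl("^<.+>$", f[5])
    svtype <- info$SVTYPE
    len <- if (!is.null(info$SVLEN)) abs(as.integer(info$SVLEN))
      else abs(nchar(f[5]) - nchar(f[4]))
    alt_seq <- if (!symbolic && svtype == "INS") substr(f[5], 2L, nchar(f[5]))
      else NA_character_
    data.table(id = f[3], chrom = f[1], pos = as.integer(f[2]),
               svtype = svtype, length = len, alt_seq = alt_seq,
               nmembers = as.integer(info$NMEMBERS %||% NA),
               carriers = list(strsplit(info$CARRIERS %||% "", ",")[[1]]))
  })
  out <- rbindlist(recs)
  setattr(out, "class", c("nonredundant_svs", class(out)))
  out
}
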