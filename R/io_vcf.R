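# SV record container and VCF 4.x reading/writing.
#
# Internal coordinates are 1-based inclusive throughout. A DEL/INV occupies
# [pos, pos + length - 1]; an INS sits between pos and pos + 1 (its own
# interval is the point {pos}). Symbolic DEL records are written with
# END = POS + SVLEN - 1 to match that convention; explicit-allele DELs (POS at
# the base before the event, VCF style) are shifted on input to POS + 1.

.sv_types <- c("INS", "DEL", "INV", "TRA")

#' Construct an SV record table
#'
#' @param chrom,pos,svtype,length,alt_seq,source_haplotype vectors (recycled
#'   where scalar). `svtype` one of `INS`, `DEL`, `INV`, `TRA`; `length` in bp
#'   (>= 1); `alt_seq` the inserted sequence for INS (may be `NA`).
#' @return a `data.table` of class `"sv_records"`.
#' @export
sv_records <- function(chrom, pos, svtype, length, alt_seq = NA_character_,
                       source_haplotype = NA_character_) {
  dt <- data.table(chrom = as.character(chrom), pos = as.integer(pos),
                   svtype = as.character(svtype), length = as.integer(length),
                   alt_seq = as.character(alt_seq),
                   source_haplotype = as.character(source_haplotype))
  bad <- setdiff(unique(dt$svtype), .sv_types)
  if (length(bad)) stop("unknown svtype(s): ", paste(bad, collapse = ", "))
  if (nrow(dt) && any(dt$length < 1)) stop("SV length must be >= 1")
  if (nrow(dt) && any(dt$pos < 1)) stop("SV pos must be >= 1")
  setattr(dt, "class", c("sv_records", class(dt)))
  dt
}

parse_info <- function(info) {
  if (info == "." || info == "") return(list())
  parts <- strsplit(info, ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  out <- lapply(kv, function(x) if (length(x) > 1) x[2] else TRUE)
  names(out) <- vapply(kv, `[[`, "", 1)
  out
}

#' Read structural variants from a VCF 4.x file
#'
#' Accepts symbolic ALT alleles (`<DEL>`, `<INS>`, `<INV>`, `<TRA>`) with
#' `SVTYPE` / `SVLEN` (and `END` for DEL/INV) INFO keys, as well as explicit
#' REF/ALT alleles whose length difference defines the SV. Insertions and
#' deletions shorter than `sv_min_len` are dropped and counted in the skip
#' log (attribute `"skip_log"`); records whose type cannot be determined are
#' skipped with a record-level warning and the file continues.
#'
#' @param path VCF file.
#' @param haplotype_id value for the `source_haplotype` column.
#' @param sv_min_len minimum INS/DEL length to count as an SV (default 50 bp).
#' @return an `sv_records` table with attribute `skip_log` (list with
#'   `n_below_min` and `n_bad_records`).
#' @export
read_sv_vcf <- function(path, haplotype_id, sv_min_len = 50L) {
  lines <- readLines(path, warn = FALSE)
  body_idx <- which(!startsWith(lines, "#"))
  recs <- vector("list", length(body_idx))
  n_below <- 0L
  n_bad <- 0L
  for (i in seq_along(body_idx)) {
    lineno <- body_idx[i]
    f <- strsplit(lines[lineno], "\t", fixed = TRUE)[[1]]
    if (length(f) < 8) {
      stop(sprintf("malformed VCF line %d in %s: expected >= 8 fields, got %d",
                   lineno, path, length(f)))
    }
    pos <- suppressWarnings(as.integer(f[2]))
    if (is.na(pos)) {
      stop(sprintf("malformed VCF line %d in %s: non-integer POS '%s'",
                   lineno, path, f[2]))
    }
    ref <- f[4]; alt <- f[5]
    info <- parse_info(f[8])
    symbolic <- grepl("^<.+>$", alt)
    svtype <- if (!is.null(info$SVTYPE)) info$SVTYPE
      else if (symbolic) gsub("[<>]", "", alt)
      else if (nchar(alt) > nchar(ref)) "INS"
      else if (nchar(alt) < nchar(ref)) "DEL"
      else NA_character_
    if (is.na(svtype) || !svtype %in% .sv_types) {
      warning(sprintf("line %d in %s: SVTYPE missing or unknown, record skipped",
                      lineno, path), call. = FALSE)
      n_bad <- n_bad + 1L
      next
    }
    alt_seq <- NA_character_
    if (symbolic) {
      len <- if (!is.null(info$SVLEN)) abs(as.integer(info$SVLEN))
        else if (!is.null(info$END)) as.integer(info$END) - pos + 1L
        else NA_integer_
      if (svtype == "INS" && !is.null(info$SEQ)) alt_seq <- info$SEQ
    } else {
      len <- abs(nchar(alt) - nchar(ref))
      if (svtype == "INS") {
        alt_seq <- substr(alt, nchar(ref) + 1L, nchar(alt))
      } else if (svtype == "DEL") {
        # VCF explicit DEL anchors POS on the base before the event
        pos <- pos + 1L
      }
    }
    if (is.na(len) || len < 1L) {
      warning(sprintf("line %d in %s: SV length not determinable, record skipped",
                      lineno, path), call. = FALSE)
      n_bad <- n_bad + 1L
      next
    }
    if (svtype %in% c("INS", "DEL") && len < sv_min_len) {
      n_below <- n_below + 1L
      next
    }
    recs[[i]] <- list(chrom = f[1], pos = pos, svtype = svtype,
                      length = as.integer(len), alt_seq = alt_seq)
  }
  recs <- recs[!vapply(recs, is.null, TRUE)]
  out <- if (length(recs)) {
    dt <- rbindlist(recs)
    sv_records(dt$chrom, dt$pos, dt$svtype, dt$length, dt$alt_seq,
               haplotype_id)
  } else {
    sv_records(character(), integer(), character(), integer(), character(),
               character())
  }
  if (n_below > 0) {
    kp_log("info", sprintf("%s: dropped %d INS/DEL below %d bp", path,
                           n_below, sv_min_len))
  }
  setattr(out, "skip_log", list(n_below_min = n_below, n_bad_records = n_bad))
  out
}

format_sv_vcf_lines <- function(records) {
  dt <- copy(as.data.table(records))
  setorder(dt, chrom, pos, svtype, length)
  apply_one <- function(i) {
    r <- dt[i]
    extra <- character()
    if (!is.null(dt$id)) id <- r$id else id <- sprintf("sv%06d", i)
    if (!is.null(dt$carriers_str) && !is.na(r$carriers_str)) {
      extra <- c(extra, paste0("CARRIERS=", r$carriers_str),
                 paste0("NMEMBERS=", r$nmembers))
    }
    if (r$svtype == "INS" && !is.na(r$alt_seq)) {
      info <- paste(c(sprintf("SVTYPE=INS;SVLEN=%d", r$length), extra),
                    collapse = ";")
      sprintf("%s\t%d\t%s\tN\t%s\t.\tPASS\t%s",
              r$chrom, r$pos, id, paste0("N", r$alt_seq), info)
    } else {
      info <- paste(c(sprintf("SVTYPE=%s;SVLEN=%s%d;END=%d", r$svtype,
                              if (r$svtype == "DEL") "-" else "", r$length,
                              if (r$svtype == "TRA") r$pos
                              else r$pos + r$length - 1L), extra),
                    collapse = ";")
      sprintf("%s\t%d\t%s\tN\t<%s>\t.\tPASS\t%s",
              r$chrom, r$pos, id, r$svtype, info)
    }
  }
  vapply(seq_len(nrow(dt)), apply_one, "")
}

#' Write SV records (or a merged catalog) as VCF
#'
#' DEL/INV/TRA are written as symbolic alleles with `SVTYPE`, `SVLEN`, `END`;
#' INS with an available `alt_seq` as an explicit allele (anchor base `N`).
#' Merged catalogs additionally carry `CARRIERS` (comma-joined haplotype ids)
#' and `NMEMBERS` INFO fields.
#'
#' @param records an `sv_records` table or `nonredundant_svs` catalog.
#' @param path output path.
#' @param chrom_lengths optional named vector, emitted as `##contig` lines.
#' @return `path`, invisibly.
#' @export
write_sv_vcf <- function(records, path, chrom_lengths = NULL) {
  dt <- as.data.table(records)
  hdr <- c("##fileformat=VCFv4.2",
           "##source=kiwipan",
           '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="SV type">',
           '##INFO=<ID=SVLEN,Number=1,Type=Integer,Description="SV length">',
           '##INFO=<ID=END,Number=1,Type=Integer,Description="Last affected base (POS+|SVLEN|-1)">',
           '##INFO=<ID=CARRIERS,Number=1,Type=String,Description="Carrier haplotypes">',
           '##INFO=<ID=NMEMBERS,Number=1,Type=Integer,Description="Merged member calls">')
  if (!is.null(chrom_lengths)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", names(chrom_lengths),
                          as.integer(chrom_lengths)))
  }
  hdr <- c(hdr, "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- if (nrow(dt)) format_sv_vcf_lines(dt) else character()
  writeLines(c(hdr, body), path)
  invisible(path)
}
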