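# Cohort bookkeeping: which haplotype assemblies exist, which accession each
# belongs to, and which flesh-colour group each accession is in.

.valid_groups <- c("RF", "YF", "GF")

#' Build a cohort label table
#'
#' @param haplotype_id character, e.g. `"Biyu.hap1"`; unique.
#' @param accession character accession (cultivar/line) name.
#' @param group character, one of `"RF"`, `"YF"`, `"GF"` (red-, yellow-,
#'   green-fleshed fruit groups).
#' @return a `data.table` of class `"cohort_labels"` with those three columns.
#' @export
cohort_labels <- function(haplotype_id, accession, group) {
  dt <- data.table(haplotype_id = as.character(haplotype_id),
                   accession = as.character(accession),
                   group = as.character(group))
  validate_cohort(dt)
  setattr(dt, "class", c("cohort_labels", class(dt)))
  dt
}

validate_cohort <- function(dt) {
  if (anyDuplicated(dt$haplotype_id)) {
    stop("duplicate haplotype_id in cohort: ",
         paste(unique(dt$haplotype_id[duplicated(dt$haplotype_id)]),
               collapse = ", "))
  }
  bad <- setdiff(unique(dt$group), .valid_groups)
  if (length(bad)) stop("unknown group label(s): ", paste(bad, collapse = ", "))
  amb <- dt[, .(n = uniqueN(group)), by = accession][n > 1]
  if (nrow(amb)) {
    stop("accession(s) assigned to more than one group: ",
         paste(amb$accession, collapse = ", "))
  }
  invisible(dt)
}

#' Read cohort labels from TSV
#'
#' Expects columns `haplotype_id`, `accession`, `group`.
#'
#' @param path TSV file path.
#' @return a `cohort_labels` table.
#' @export
read_cohort_labels <- function(path) {
  dt <- fread(path, sep = "\t", colClasses = "character")
  need <- c("haplotype_id", "accession", "group")
  if (!all(need %in% names(dt))) {
    stop("cohort label file must have columns: ", paste(need, collapse = ", "))
  }
  cohort_labels(dt$haplotype_id, dt$accession, dt$group)
}

#' Write cohort labels to TSV
#' @param cohort a `cohort_labels` table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort_labels <- function(cohort, path) {
  fwrite(as.data.table(cohort)[, .(haplotype_id, accession, group)],
         path, sep = "\t")
  invisible(path)
}

#' Haplotypes of one accession or group
#' @param cohort a `cohort_labels` table.
#' @param accession,group select by accession name or group label.
#' @return character vector of haplotype ids.
#' @export
haplotypes_of <- function(cohort, accession = NULL, group = NULL) {
  dt <- as.data.table(cohort)
  if (!is.null(accession)) {
    if (!accession %in% dt$accession) stop("unknown accession: ", accession)
    return(dt[accession, on = "accession"]$haplotype_id)
  }
  if (!is.null(group)) {
    out <- dt[group, on = "group"]$haplotype_id
    if (!length(out) || all(is.na(out))) stop("group has zero haplotypes: ", group)
    return(out)
  }
  dt$haplotype_id
}

#' Map haplotype ids to accession names
#' @param cohort a `cohort_labels` table.
#' @param haplotype_ids character vector.
#' @return character vector of accessions, same length.
#' @export
accession_of <- function(cohort, haplotype_ids) {
  dt <- as.data.table(cohort)
  idx <- match(haplotype_ids, dt$haplotype_id)
  if (anyNA(idx)) {
    stop("unknown haplotype id(s): ",
         paste(haplotype_ids[is.na(idx)], collapse = ", "))
  }
  dt$accession[idx]
}

#' Read chromosome lengths from a two-column TSV (chrom, length)
#' @param path TSV path.
#' @return named integer vector of lengths.
#' @export
read_chrom_lengths <- function(path) {
  dt <- fread(path, sep = "\t")
  if (ncol(dt) < 2) stop("chromosome length file needs 2 columns")
  setnames(dt, 1:2, c("chrom", "length"))
  if (any(dt$length <= 0)) stop("chromosome lengths must be positive")
  setNames(as.integer(dt$length), dt$chrom)
}

#' Write chromosome lengths TSV
#' @param lengths named integer vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_chrom_lengths <- function(lengths, path) {
  fwrite(data.table(chrom = names(lengths), length = as.integer(lengths)),
         path, sep = "\t")
  invisible(path)
}
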