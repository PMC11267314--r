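# SV hotspot scan: sliding-window SV counts and threshold-based calling.

#' Sliding-window SV counts
#'
#' Windows start at 1, 1 + step, 1 + 2*step, ... and span `window` bp (the
#' final windows are truncated at the chromosome end and flagged). An SV is
#' assigned to every window containing its `pos` (membership by start
#' position only, not span), so with `step < window` one SV can hit
#' `ceiling(window/step)` windows.
#'
#' @param catalog a `nonredundant_svs` (or `sv_records`) table.
#' @param chrom_lengths named vector of chromosome lengths; every catalog
#'   chromosome must be present.
#' @param window window size in bp (default 400 kb).
#' @param step step size in bp (default 200 kb; must be `<= window`).
#' @return `data.table` of class `"window_counts"`: `chrom`, `start`, `end`,
#'   `sv_count`, `truncated`.
#' @export
windowed_counts <- function(catalog, chrom_lengths, window = 400000L,
                            step = 200000L) {
  if (step < 1 || window < step) stop("need window >= step >= 1")
  dt <- as.data.table(catalog)
  bad <- setdiff(unique(dt$chrom), names(chrom_lengths))
  if (length(bad)) {
    stop("chromosome(s) absent from lengths: ", paste(bad, collapse = ", "))
  }
  wins <- rbindlist(lapply(names(chrom_lengths), function(ch) {
    len <- as.integer(chrom_lengths[[ch]])
    starts <- seq.int(1L, len, by = as.integer(step))
    data.table(chrom = ch, start = starts,
               end = pmin(starts + as.integer(window) - 1L, len))
  }))
  wins[, truncated := (end - start + 1L) < window]
  if (nrow(dt)) {
    lv <- names(chrom_lengths)
    w_gr <- GenomicRanges::GRanges(factor(wins$chrom, levels = lv),
                                   IRanges::IRanges(wins$start, wins$end))
    s_gr <- GenomicRanges::GRanges(factor(dt$chrom, levels = lv),
                                   IRanges::IRanges(dt$pos, dt$pos))
    wins[, sv_count := GenomicRanges::countOverlaps(w_gr, s_gr)]
  } else {
    wins[, sv_count := 0L]
  }
  setcolorder(wins, c("chrom", "start", "end", "sv_count", "truncated"))
  setattr(wins, "class", c("window_counts", class(wins)))
  wins
}

#' Call SV hotspots from window counts
#'
#' Windows whose count is strictly greater than `min_count` qualify;
#' overlapping or directly adjacent qualifying windows on one chromosome are
#' merged into maximal spans (unless `merge_contiguous = FALSE`).
#'
#' @param counts a `window_counts` table.
#' @param min_count count threshold, strict (default 80).
#' @param merge_contiguous merge touching qualifying windows (default TRUE).
#' @param catalog optional SV table; when given, `n_svs` reports the distinct
#'   SVs (by `pos`) inside each merged span.
#' @return `data.table` of class `"hotspots"`: `chrom`, `start`, `end`,
#'   `n_windows`, `max_window_count` and (optionally) `n_svs`.
#' @export
call_hotspots <- function(counts, min_count = 80L, merge_contiguous = TRUE,
                          catalog = NULL) {
  sel <- as.data.table(counts)[sv_count > min_count]
  if (!nrow(sel)) {
    out <- data.table(chrom = character(), start = integer(), end = integer(),
                      n_windows = integer(), max_window_count = integer())
    if (!is.null(catalog)) out[, n_svs := integer()]
    setattr(out, "class", c("hotspots", class(out)))
    return(out)
  }
  if (merge_contiguous) {
    gr <- GenomicRanges::GRanges(sel$chrom,
                                 IRanges::IRanges(sel$start, sel$end))
    red <- GenomicRanges::reduce(gr, min.gapwidth = 1L)
    hit <- GenomicRanges::findOverlaps(red, gr)
    agg <- data.table(span = S4Vectors::queryHits(hit),
                      win = S4Vectors::subjectHits(hit))
    stats <- agg[, .(n_windows = .N,
                     max_window_count = max(sel$sv_count[win])), by = span]
    out <- data.table(chrom = as.character(GenomicRanges::seqnames(red)),
                      start = GenomicRanges::start(red),
                      end = GenomicRanges::end(red))
    out <- cbind(out, stats[order(span), .(n_windows, max_window_count)])
  } else {
    out <- sel[, .(chrom, start, end, n_windows = 1L,
                   max_window_count = sv_count)]
  }
  if (!is.null(catalog)) {
    cdt <- as.data.table(catalog)
    out[, n_svs := vapply(seq_len(.N), function(i)
      cdt[chrom == out$chrom[i] & pos >= out$start[i] & pos <= out$end[i],
          uniqueN(paste(chrom, pos, svtype))], 0L)]
  }
  setorder(out, chrom, start)
  setattr(out, "class", c("hotspots", class(out)))
  out
}
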