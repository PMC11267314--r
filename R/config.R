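# Pipeline configuration: every fixed threshold used across the stages lives
# here, so one object documents the whole parameterization.

#' Default pipeline configuration
#'
#' Central bundle of the analysis thresholds:
#' \describe{
#'   \item{classification}{`softcore_fraction = 0.80`: a dispensable cluster is
#'     softcore when present in strictly more than this fraction of
#'     assemblies.}
#'   \item{merge}{`max_distance = 50` bp start-to-start, `max_size_difference
#'     = 20` bp (absolute) for joining SV calls into one non-redundant SV.}
#'   \item{hotspot}{sliding window `window = 400000` bp, `step = 200000` bp;
#'     windows with SV count strictly greater than `min_count = 80` are
#'     hotspots; contiguous qualifying windows are merged.}
#'   \item{annotation}{`promoter_len = 2000` bp upstream of the annotated gene
#'     start (ATG side, strand-aware); `downstream_len = 2000` bp.}
#'   \item{de}{differential-expression calls require `|log2 fold change| >
#'     min_abs_log2fc = 1` and `p < max_p = 0.05`.}
#'   \item{saturation}{`n_permutations = 100` random assembly orderings.}
#'   \item{sv_min_len}{insertions/deletions shorter than 50 bp are not SVs.}
#' }
#'
#' @param ... named overrides using dotted keys (e.g.
#'   `merge.max_distance = 30`) or top-level lists.
#' @return a nested list of class `"pipeline_config"`.
#' @export
#' @examples
#' cfg <- pipeline_config(hotspot.min_count = 10)
#' cfg$hotspot$min_count
pipeline_config <- function(...) {
  cfg <- list(
    classification = list(softcore_fraction = 0.80),
    merge = list(max_distance = 50L, max_size_difference = 20L),
    hotspot = list(window = 400000L, step = 200000L, min_count = 80L,
                   merge_contiguous = TRUE),
    annotation = list(promoter_len = 2000L, downstream_len = 2000L),
    de = list(min_abs_log2fc = 1.0, max_p = 0.05),
    saturation = list(n_permutations = 100L, seed = 1L),
    sv_min_len = 50L
  )
  overrides <- list(...)
  for (key in names(overrides)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    if (length(parts) == 1) {
      cfg[[parts]] <- overrides[[key]]
    } else if (length(parts) == 2) {
      cfg[[parts[1]]][[parts[2]]] <- overrides[[key]]
    } else {
      stop("unsupported config key: ", key)
    }
  }
  validate_config(cfg)
  class(cfg) <- "pipeline_config"
  cfg
}

validate_config <- function(cfg) {
  lens <- c(cfg$merge$max_distance, cfg$merge$max_size_difference,
            cfg$hotspot$window, cfg$hotspot$step,
            cfg$annotation$promoter_len, cfg$annotation$downstream_len,
            cfg$sv_min_len)
  if (any(lens <= 0)) stop("all config lengths must be positive")
  if (cfg$hotspot$step > cfg$hotspot$window) {
    stop("hotspot step must be <= window")
  }
  sf <- cfg$classification$softcore_fraction
  if (!(sf > 0 && sf < 1)) stop("softcore_fraction must lie in (0, 1)")
  invisible(cfg)
}

#' Read a flat key-value configuration file
#'
#' Accepts a minimal format common to YAML and TOML scalars: one
#' `dotted.key: value` or `dotted.key = value` pair per line; `#` comments and
#' blank lines ignored. Values are parsed as numbers where possible, `true` /
#' `false` as logicals, everything else as strings.
#'
#' @param path file path.
#' @return a `pipeline_config` with the file's overrides applied.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_.]+)\\s*[:=]\\s*(.*)$", ln))[[1]]
    if (length(m) != 3) stop("cannot parse config line: ", ln)
    val <- trimws(gsub('^"|"$', "", m[3]))
    num <- suppressWarnings(as.numeric(val))
    kv[[m[2]]] <- if (!is.na(num)) num
      else if (tolower(val) %in% c("true", "false")) tolower(val) == "true"
      else val
  }
  do.call(pipeline_config, kv)
}
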