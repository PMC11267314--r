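# Coordinate-preserving variation graph: reference segments + SV branches,
# haplotype paths, GFA 1.0 serialization.
#
# Breakpoint convention (consistent with the VCF reader/writer): a DEL
# removes [pos, pos + len - 1]; an INS inserts its allele between pos and
# pos + 1. INV and TRA are excluded from the graph.

#' Build a variation graph from a reference and an SV catalog
#'
#' The reference of each chromosome is split at every SV breakpoint into
#' segments that tile it exactly (linear coordinates stay recoverable). Each
#' DEL contributes an edge bypassing the deleted segment(s); each INS
#' contributes an alternate node between its flanking segments. One path per
#' chromosome spells the reference; one path per haplotype traverses the
#' alternate branch of every SV it carries (all chromosomes concatenated in
#' order).
#'
#' @param reference named character vector or `DNAStringSet` of chromosome
#'   sequences.
#' @param catalog a `nonredundant_svs` table (INS/DEL only; INS must carry
#'   `alt_seq`). Overlapping DEL intervals on one chromosome are rejected.
#' @param haplotypes character vector of haplotype ids to build paths for
#'   (defaults to the union of catalog carriers).
#' @return list of class `"variation_graph"`: `nodes` (`data.table`:
#'   `node_id`, `type` ref/alt, `chrom`, `start`, `end`, `seq`), `edges`
#'   (`from`, `to`) and `paths` (named list of node-id vectors).
#' @export
build_graph <- function(reference, catalog, haplotypes = NULL) {
  if (methods::is(reference, "DNAStringSet")) {
    reference <- setNames(as.character(reference), names(reference))
  }
  dt <- as.data.table(catalog)
  if (nrow(dt) && !all(dt$svtype %in% c("INS", "DEL"))) {
    stop("only INS/DEL enter the graph; filter INV/TRA first")
  }
  if (nrow(dt)) {
    if (any(dt$svtype == "INS" & (is.na(dt$alt_seq) | !nzchar(dt$alt_seq)))) {
      stop("INS record(s) without alt_seq cannot be placed in the graph")
    }
    bad_chrom <- setdiff(unique(dt$chrom), names(reference))
    if (length(bad_chrom)) {
      stop("SV on chromosome absent from reference: ",
           paste(bad_chrom, collapse = ", "))
    }
    dels <- dt[svtype == "DEL"]
    if (nrow(dels) > 1) {
      setorder(dels, chrom, pos)
      ov <- dels[, .(bad = any(pos[-1] <= (pos + length - 1L)[-.N]),
                     where = if (.N > 1) pos[c(FALSE, pos[-1] <=
                       (pos + length - 1L)[-.N])][1] else NA_integer_),
                 by = chrom][bad == TRUE]
      if (nrow(ov)) {
        stop("overlapping DEL intervals on ", ov$chrom[1], " near pos ",
             ov$where[1])
      }
    }
  }
  if (is.null(haplotypes)) {
    haplotypes <- sort(unique(unlist(dt$carriers)))
  }
  if (!is.null(dt$carriers)) {
    carried <- dt$carriers
  } else {
    carried <- rep(list(character()), nrow(dt))
  }

  nodes <- list(); edges <- list(); paths <- list()
  node_n <- 0L
  for (ch in names(reference)) {
    seq_ch <- reference[[ch]]
    L <- nchar(seq_ch)
    sv_ch <- if (nrow(dt)) which(dt$chrom == ch) else integer()
    # boundaries: a cut after position b means segments [.., b], [b+1, ..]
    cuts <- integer()
    for (i in sv_ch) {
      if (dt$svtype[i] == "DEL") {
        cuts <- c(cuts, dt$pos[i] - 1L, dt$pos[i] + dt$length[i] - 1L)
      } else {
        cuts <- c(cuts, dt$pos[i])
      }
    }
    cuts <- sort(unique(cuts[cuts >= 1L & cuts < L]))
    seg_start <- c(1L, cuts + 1L)
    seg_end <- c(cuts, L)
    seg_id <- integer(length(seg_start))
    chrom_nodes <- list()
    # alt INS nodes must follow their left flank in numbering
    ins_after <- split(sv_ch[dt$svtype[sv_ch] == "INS"],
                       dt$pos[sv_ch[dt$svtype[sv_ch] == "INS"]])
    ins_node_of <- integer(nrow(dt))
    for (s in seq_along(seg_start)) {
      node_n <- node_n + 1L
      seg_id[s] <- node_n
      chrom_nodes[[length(chrom_nodes) + 1L]] <- data.table(
        node_id = node_n, type = "ref", chrom = ch,
        start = seg_start[s], end = seg_end[s],
        seq = substr(seq_ch, seg_start[s], seg_end[s]))
      here <- ins_after[[as.character(seg_end[s])]]
      for (i in here %||% integer()) {
        node_n <- node_n + 1L
        ins_node_of[i] <- node_n
        chrom_nodes[[length(chrom_nodes) + 1L]] <- data.table(
          node_id = node_n, type = "alt", chrom = ch,
          start = NA_integer_, end = NA_integer_, seq = dt$alt_seq[i])
      }
    }
    nodes[[ch]] <- rbindlist(chrom_nodes)
    seg_at_start <- setNames(seg_id, seg_start)
    seg_at_end <- setNames(seg_id, seg_end)
    ed <- list()
    if (length(seg_id) > 1) {
      ed[[length(ed) + 1L]] <- data.table(from = seg_id[-length(seg_id)],
                                          to = seg_id[-1])
    }
    for (i in sv_ch) {
      if (dt$svtype[i] == "DEL") {
        to_seg <- seg_at_start[[as.character(dt$pos[i] + dt$length[i])]] %||%
          NA_integer_
        from_seg <- if (dt$pos[i] > 1L)
          seg_at_end[[as.character(dt$pos[i] - 1L)]] else NA_integer_
        if (!is.na(from_seg) && !is.na(to_seg)) {
          ed[[length(ed) + 1L]] <- data.table(from = from_seg, to = to_seg)
        }
      } else {
        left <- seg_at_end[[as.character(dt$pos[i])]] %||% NA_integer_
        right <- seg_at_start[[as.character(dt$pos[i] + 1L)]] %||% NA_integer_
        if (!is.na(left)) {
          ed[[length(ed) + 1L]] <- data.table(from = left, to = ins_node_of[i])
        }
        if (!is.na(right)) {
          ed[[length(ed) + 1L]] <- data.table(from = ins_node_of[i], to = right)
        }
      }
    }
    edges[[ch]] <- if (length(ed)) unique(rbindlist(ed)) else
      data.table(from = integer(), to = integer())
    paths[[ch]] <- seg_id

    # haplotype sub-paths for this chromosome
    for (h in haplotypes) {
      mine <- sv_ch[vapply(carried[sv_ch], function(x) h %in% x, TRUE)]
      hp <- haplotype_walk(dt, mine, seg_start, seg_end, seg_id,
                           ins_node_of, h, ch, L)
      paths[[paste0(".hap.", h)]] <- c(paths[[paste0(".hap.", h)]], hp)
    }
  }
  nodes <- rbindlist(nodes)
  edges <- if (length(edges)) unique(rbindlist(edges)) else
    data.table(from = integer(), to = integer())
  # assemble path list: reference per chrom, then one per haplotype
  out_paths <- paths[names(reference)]
  for (h in haplotypes) out_paths[[h]] <- paths[[paste0(".hap.", h)]]
  structure(list(nodes = nodes, edges = edges, paths = out_paths),
            class = "variation_graph")
}

haplotype_walk <- function(dt, mine, seg_start, seg_end, seg_id, ins_node_of,
                           hap, chrom, L) {
  if (length(mine) > 1) {
    iv <- data.table(pos = dt$pos[mine], svtype = dt$svtype[mine],
                     len = dt$length[mine])
    iv[, start := ifelse(svtype == "DEL", pos, pos)]
    iv[, end := ifelse(svtype == "DEL", pos + len - 1L, pos)]
    setorder(iv, start)
    # an INS strictly inside a carried DEL (or two carried DELs overlapping)
    # has no consistent branch choice
    if (any(iv$start[-1] <= iv$end[-nrow(iv)])) {
      stop(sprintf("haplotype %s carries overlapping SVs on %s", hap, chrom))
    }
  }
  dels <- mine[dt$svtype[mine] == "DEL"]
  del_span <- if (length(dels))
    data.table(start = dt$pos[dels], end = dt$pos[dels] + dt$length[dels] - 1L)
  else data.table(start = integer(), end = integer())
  ins_at <- setNames(ins_node_of[mine[dt$svtype[mine] == "INS"]],
                     dt$pos[mine[dt$svtype[mine] == "INS"]])
  path <- integer()
  for (s in seq_along(seg_id)) {
    deleted <- nrow(del_span) && any(del_span$start <= seg_start[s] &
                                     del_span$end >= seg_end[s])
    if (!deleted) path <- c(path, seg_id[s])
    node <- unname(ins_at[match(as.character(seg_end[s]), names(ins_at))])
    if (length(node) && !is.na(node)) path <- c(path, node)
  }
  path
}

#' Spell the sequence of a graph path
#' @param graph a `variation_graph`.
#' @param name path name (chromosome or haplotype id).
#' @return the concatenated node sequences.
#' @export
spell_path <- function(graph, name) {
  ids <- graph$paths[[name]]
  if (is.null(ids)) stop("no path named ", name)
  paste(graph$nodes$seq[match(ids, graph$nodes$node_id)], collapse = "")
}

#' Write a variation graph as GFA 1.0
#'
#' S-lines carry sequences; L-lines use `0M` overlaps; P-lines are written
#' for every reference chromosome and every haplotype. Node numbering is
#' stable: by chromosome, then coordinate, alternate nodes directly after
#' their left flank.
#'
#' @param graph a `variation_graph`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gfa <- function(graph, path) {
  n <- graph$nodes
  s_lines <- sprintf("S\ts%d\t%s", n$node_id, n$seq)
  l_lines <- if (nrow(graph$edges))
    sprintf("L\ts%d\t+\ts%d\t+\t0M", graph$edges$from, graph$edges$to)
  else character()
  p_lines <- vapply(names(graph$paths), function(nm) {
    sprintf("P\t%s\t%s\t*", nm,
            paste0("s", graph$paths[[nm]], "+", collapse = ","))
  }, "")
  writeLines(c("H\tVN:Z:1.0", s_lines, l_lines, p_lines), path)
  invisible(path)
}

#' Read a GFA 1.0 file written by [write_gfa()]
#' @param path GFA file.
#' @return a `variation_graph`-shaped list with `nodes` (`node_id`, `seq`),
#'   `edges` and `paths` (coordinates are not stored in GFA and come back
#'   `NA`).
#' @export
read_gfa <- function(path) {
  lines <- readLines(path, warn = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  tag <- vapply(parts, `[[`, "", 1)
  s <- parts[tag == "S"]
  nodes <- data.table(
    node_id = as.integer(sub("^s", "", vapply(s, `[[`, "", 2))),
    type = NA_character_, chrom = NA_character_,
    start = NA_integer_, end = NA_integer_,
    seq = vapply(s, `[[`, "", 3))
  l <- parts[tag == "L"]
  edges <- data.table(
    from = as.integer(sub("^s", "", vapply(l, `[[`, "", 2))),
    to = as.integer(sub("^s", "", vapply(l, `[[`, "", 4))))
  p <- parts[tag == "P"]
  paths <- setNames(lapply(p, function(x) {
    as.integer(sub("^s", "", sub("\\+$", "",
      strsplit(x[3], ",", fixed = TRUE)[[1]])))
  }), vapply(p, `[[`, "", 2))
  structure(list(nodes = nodes, edges = edges, paths = paths),
            class = "variation_graph")
}

#' Apply SVs to a linear sequence (independent of the graph)
#'
#' Edits a chromosome string directly: deletes each DEL interval and inserts
#' each INS allele after its position. Used as the spelling oracle for
#' haplotype paths.
#'
#' @param seq chromosome sequence (character scalar).
#' @param svs `data.table` with `pos`, `svtype` (INS/DEL), `length`,
#'   `alt_seq`; intervals must not overlap.
#' @return the edited sequence.
#' @export
apply_svs_to_sequence <- function(seq, svs) {
  dt <- as.data.table(svs)
  if (!nrow(dt)) return(seq)
  setorder(dt, -pos)
  for (i in seq_len(nrow(dt))) {
    p <- dt$pos[i]
    if (dt$svtype[i] == "DEL") {
      seq <- paste0(substr(seq, 1L, p - 1L),
                    substr(seq, p + dt$length[i], nchar(seq)))
    } else {
      seq <- paste0(substr(seq, 1L, p), dt$alt_seq[i],
                    substr(seq, p + 1L, nchar(seq)))
    }
  }
  seq
}
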