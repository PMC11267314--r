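mk_catalog <- function(chrom, pos, svtype, length, alt_seq, carriers) {
  data.table::data.table(
    id = sprintf("sv%02d", seq_along(pos)), chrom = chrom, pos = pos,
    svtype = svtype, length = length, alt_seq = alt_seq,
    nmembers = 1L, carriers = carriers)
}

test_that("zero SVs give one node per chromosome and a reference path", {
  ref <- c(Chr1 = "ACGTACGTAC", Chr2 = "GGGGCCCC")
  g <- build_graph(ref, mk_catalog(character(), integer(), character(),
                                   integer(), character(), list()),
                   haplotypes = "h1")
  expect_equal(nrow(g$nodes), 2L)
  expect_equal(nrow(g$edges), 0L)
  expect_equal(spell_path(g, "Chr1"), ref[["Chr1"]])
  expect_equal(spell_path(g, "Chr2"), ref[["Chr2"]])
  expect_equal(spell_path(g, "h1"), paste0(ref, collapse = ""))
})

test_that("a middle deletion spells the string-edit result", {
  ref <- c(Chr1 = "AAAACCCCGGGG")
  cat_ <- mk_catalog("Chr1", 5L, "DEL", 4L, NA_character_, list("h1"))
  g <- build_graph(ref, cat_, haplotypes = c("h1", "h2"))
  expect_equal(spell_path(g, "Chr1"), "AAAACCCCGGGG")
  expect_equal(spell_path(g, "h1"), "AAAAGGGG")
  expect_equal(spell_path(g, "h2"), "AAAACCCCGGGG")
  # reference segments tile the chromosome without overlap
  segs <- g$nodes[g$nodes$type == "ref", ]
  segs <- segs[order(segs$start), ]
  expect_equal(segs$start[1], 1L)
  expect_equal(segs$end[nrow(segs)], nchar(ref[["Chr1"]]))
  expect_true(all(segs$start[-1] == segs$end[-nrow(segs)] + 1L))
})

test_that("insertions branch between flanking segments", {
  ref <- c(Chr1 = "AAAATTTT")
  cat_ <- mk_catalog("Chr1", 4L, "INS", 3L, "GGG", list("h1"))
  g <- build_graph(ref, cat_, haplotypes = c("h1", "h2"))
  expect_equal(spell_path(g, "h1"), "AAAAGGGTTTT")
  expect_equal(spell_path(g, "h2"), "AAAATTTT")
  expect_equal(spell_path(g, "Chr1"), "AAAATTTT")
  # alt node numbered right after its left flank
  alt <- g$nodes[g$nodes$type == "alt", ]
  left <- g$nodes[g$nodes$type == "ref" & !is.na(g$nodes$end) &
                    g$nodes$end == 4L, ]
  expect_equal(alt$node_id, left$node_id + 1L)
})

test_that("graph construction rejects inconsistent input", {
  ref <- c(Chr1 = paste(rep("ACGT", 100), collapse = ""))
  expect_error(build_graph(ref, mk_catalog("Chr1", 10L, "INS", 5L,
                                           NA_character_, list("h1"))),
               "alt_seq")
  expect_error(build_graph(ref, mk_catalog("Chr1", c(10L, 15L), "DEL",
                                           c(20L, 20L), NA_character_,
                                           list("h1", "h2"))),
               "overlapping DEL")
  expect_error(build_graph(ref, mk_catalog("Chr9", 10L, "DEL", 20L,
                                           NA_character_, list("h1"))),
               "absent from reference")
  expect_error(build_graph(ref, mk_catalog("Chr1", 10L, "INV", 20L,
                                           NA_character_, list("h1"))),
               "INS/DEL")
  # INS strictly inside a DEL carried by the same haplotype
  expect_error(build_graph(ref, mk_catalog("Chr1", c(10L, 15L),
                                           c("DEL", "INS"), c(20L, 3L),
                                           c(NA, "AAA"),
                                           list("h1", "h1"))),
               "overlapping SVs")
})

test_that("random non-overlapping SV sets spell like the edit oracle", {
  set.seed(51)
  for (rep in 1:3) {
    L <- 10000L
    ref <- c(Chr1 = paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                          collapse = ""))
    # 20 disjoint SVs with >= 2 bp gaps
    bounds <- sort(sample(seq(10L, L - 10L, by = 40L), 20L))
    svt <- sample(c("DEL", "INS"), 20L, replace = TRUE)
    len <- sample(5:30, 20L, replace = TRUE)
    len[svt == "DEL"] <- pmin(len[svt == "DEL"], 30L)
    alt <- ifelse(svt == "INS", vapply(len, function(n)
      paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = ""),
      ""), NA_character_)
    haps <- paste0("h", 1:4)
    carriers <- lapply(1:20, function(i) sample(haps, sample(1:3, 1)))
    cat_ <- mk_catalog("Chr1", bounds, svt, len, alt, carriers)
    g <- build_graph(ref, cat_, haplotypes = haps)
    for (h in haps) {
      mine <- cat_[vapply(cat_$carriers, function(x) h %in% x, TRUE), ]
      expect_equal(spell_path(g, h),
                   apply_svs_to_sequence(ref[["Chr1"]], mine),
                   info = h)
    }
    # acyclic by construction: every edge goes to a higher node id
    expect_true(all(g$edges$to > g$edges$from))
  }
})

test_that("GFA round-trip preserves nodes, edges and path spellings", {
  set.seed(52)
  L <- 5000L
  ref <- c(Chr1 = paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                        collapse = ""),
           Chr2 = paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                        collapse = ""))
  cat_ <- mk_catalog(c("Chr1", "Chr1", "Chr2"), c(1000L, 3000L, 2000L),
                     c("DEL", "INS", "DEL"), c(100L, 20L, 60L),
                     c(NA, "ACGTACGTACGTACGTACGT", NA),
                     list("h1", c("h1", "h2"), "h2"))
  g <- build_graph(ref, cat_, haplotypes = c("h1", "h2"))
  path <- file.path(tempdir(), "pan.gfa")
  write_gfa(g, path)
  back <- read_gfa(path)
  expect_equal(nrow(back$nodes), nrow(g$nodes))
  expect_equal(nrow(back$edges), nrow(g$edges))
  expect_equal(names(back$paths), names(g$paths))
  for (nm in names(g$paths)) {
    expect_equal(spell_path(back, nm), spell_path(g, nm), info = nm)
  }
  # P-line count = n_haplotypes + n_chroms
  p_lines <- grep("^P\t", readLines(path), value = TRUE)
  expect_length(p_lines, 2L + 2L)
  # header declares GFA 1.0
  expect_equal(readLines(path)[1], "H\tVN:Z:1.0")
})

test_that("reference coordinates are recoverable from the segment tiling", {
  b <- small_bundle()
  ref <- read_fasta(file.path(b$dir, "fasta",
                              paste0(b$reference_haplotype, ".fa")))
  recs <- read_bundle_records(b)
  cat_ <- merge_svs(recs[recs$svtype %in% c("INS", "DEL"), ])
  g <- build_graph(ref, cat_)
  for (ch in names(ref)) {
    segs <- g$nodes[g$nodes$type == "ref" & g$nodes$chrom == ch, ]
    segs <- segs[order(segs$start), ]
    expect_equal(segs$start[1], 1L)
    expect_equal(segs$end[nrow(segs)], nchar(as.character(ref[[ch]])))
    expect_true(all(segs$start[-1] == segs$end[-nrow(segs)] + 1L))
    expect_equal(spell_path(g, ch), as.character(ref[[ch]]))
  }
})
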