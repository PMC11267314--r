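test_that("context priority and promoter geometry on hand-built models", {
  m <- toy_gene_models()  # gA +:10000-12000, gB -:30000-33000, gC +:50000-52000
  # DEL fully inside a gA exon -> exonic
  svs <- sv_records("Chr1", 10100L, "DEL", 100L, NA, "h")
  ctx <- classify_context(svs, m)
  expect_equal(ctx$context, "exonic")
  expect_equal(ctx$linked_gene, "gA")
  expect_equal(ctx$distance_to_gene, 0L)
  # 51 bp DEL inside [gC.start-2000, gC.start-1] of a + gene -> promoter
  svs <- sv_records("Chr1", 49000L, "DEL", 51L, NA, "h")
  ctx <- classify_context(svs, m)
  expect_equal(ctx$context, "promoter")
  expect_equal(ctx$linked_gene, "gC")
  # minus-strand gene gB: promoter is downstream-in-genome [33001, 35000]
  svs <- sv_records("Chr1", 34000L, "INS", 60L, "A", "h")
  ctx <- classify_context(svs, m)
  expect_equal(ctx$context, "promoter")
  expect_equal(ctx$linked_gene, "gB")
  # ... and [28000, 29999] is gB's downstream flank
  svs <- sv_records("Chr1", 28050L, "DEL", 80L, NA, "h")
  expect_equal(classify_context(svs, m)$context, "downstream")
  # intronic beats promoter: gA intron is 10801-11499
  svs <- sv_records("Chr1", 10900L, "INS", 55L, "A", "h")
  expect_equal(classify_context(svs, m)$context, "intronic")
  # intergenic links the nearest gene on the chromosome
  svs <- sv_records("Chr1", 20000L, "DEL", 60L, NA, "h")
  ctx <- classify_context(svs, m)
  expect_equal(ctx$context, "intergenic")
  expect_equal(ctx$linked_gene, "gA")
  expect_gt(ctx$distance_to_gene, 0L)
  # chromosome with no genes -> intergenic, no link
  m2 <- gene_models(m$genes[m$genes$chrom == "Chr2", ],
                    m$exons[m$exons$gene_id == "gD", ])
  svs <- sv_records("Chr1", 500L, "DEL", 60L, NA, "h")
  ctx <- classify_context(svs, m2)
  expect_equal(ctx$context, "intergenic")
  expect_true(is.na(ctx$linked_gene))
})

test_that("context labels equal the interval-algebra oracle on random input", {
  set.seed(31)
  m <- random_gene_models(30)
  svs <- random_sv_records(150, max_pos = 200000,
                           types = c("INS", "DEL", "INV"))
  ctx <- classify_context(svs, m)
  g <- as.data.frame(m$genes)
  e <- as.data.frame(m$exons)
  for (i in seq_len(nrow(svs))) {
    s <- svs$pos[i]
    eend <- if (svs$svtype[i] %in% c("DEL", "INV"))
      svs$pos[i] + svs$length[i] - 1L else svs$pos[i]
    oc <- oracle_context(s, eend, svs$chrom[i], g, e)
    expect_equal(ctx$context[i], oc$context,
                 info = sprintf("sv %d (%s:%d)", i, svs$chrom[i], s))
    if (!is.na(oc$gene)) expect_equal(ctx$linked_gene[i], oc$gene)
  }
  # each SV gets exactly one label and fractions sum to 1
  expect_equal(nrow(ctx), nrow(svs))
  expect_equal(sum(table(ctx$context)), nrow(svs))
})

test_that("context labels are invariant under coordinate reflection", {
  set.seed(32)
  L <- 200000L
  m <- random_gene_models(20, chrom_len = L, chroms = "Chr1")
  svs <- random_sv_records(80, chroms = "Chr1", max_pos = L - 600,
                           types = c("DEL", "INS"))
  ctx <- classify_context(svs, m, chrom_lengths = c(Chr1 = L))
  # reflect: x -> L + 1 - x, strands flip, intervals swap ends
  g <- m$genes
  refl_g <- data.frame(gene_id = g$gene_id, chrom = g$chrom,
                       start = L + 1L - g$end, end = L + 1L - g$start,
                       strand = ifelse(g$strand == "+", "-", "+"))
  e <- m$exons
  refl_e <- data.frame(gene_id = e$gene_id, start = L + 1L - e$end,
                       end = L + 1L - e$start)
  m_r <- gene_models(refl_g, refl_e)
  sv_end <- ifelse(svs$svtype == "DEL", svs$pos + svs$length - 1L, svs$pos)
  svs_r <- sv_records(svs$chrom, L + 1L - sv_end, svs$svtype, svs$length,
                      svs$alt_seq, svs$source_haplotype)
  ctx_r <- classify_context(svs_r, m_r, chrom_lengths = c(Chr1 = L))
  expect_equal(ctx_r$context, ctx$context)
})

test_that("group-specific detection: spec examples and subset-test oracle", {
  co <- cohort_labels(
    paste0(rep(c("Hongyang", "Zps18", "Hort16A", "Huangyang", "Jinmi",
                 "Biyu", "Jinpai"), each = 2), ".hap", 1:2),
    rep(c("Hongyang", "Zps18", "Hort16A", "Huangyang", "Jinmi", "Biyu",
          "Jinpai"), each = 2),
    rep(c("RF", "RF", "YF", "YF", "YF", "GF", "GF"), each = 2))
  mk_cat <- function(carrier_sets) {
    n <- length(carrier_sets)
    d <- data.table::data.table(
      id = sprintf("sv%02d", seq_len(n)), chrom = "Chr1",
      pos = seq_len(n) * 1000L, svtype = "DEL", length = 60L,
      alt_seq = NA_character_, nmembers = lengths(carrier_sets),
      carriers = carrier_sets)
    d
  }
  # carried only by Biyu.hap2 and Jinpai.hap1 (both GF, not all of GF)
  cat_ <- mk_cat(list(c("Biyu.hap2", "Jinpai.hap1")))
  gs <- group_specific_svs(cat_, co, "GF")
  expect_equal(gs$mode, "presence_specific")
  expect_equal(gs$carriers[[1]], c("Biyu.hap2", "Jinpai.hap1"))
  # carried by every haplotype -> specific to no group
  all_h <- haplotypes_of(co)
  expect_equal(nrow(group_specific_svs(mk_cat(list(all_h)), co, "GF")), 0L)
  expect_equal(nrow(group_specific_svs(mk_cat(list(all_h)), co, "RF")), 0L)
  # absent only from one GF haplotype -> GF absence_specific
  gs2 <- group_specific_svs(mk_cat(list(setdiff(all_h, "Biyu.hap1"))), co,
                            "GF")
  expect_equal(gs2$mode, "absence_specific")
  # random carrier sets vs brute-force subset test, all groups
  set.seed(33)
  sets <- lapply(1:40, function(i) sort(sample(all_h, sample(1:13, 1))))
  cat_r <- mk_cat(sets)
  for (grp in c("RF", "YF", "GF")) {
    focal <- haplotypes_of(co, group = grp)
    gs_r <- group_specific_svs(cat_r, co, grp)
    for (i in seq_along(sets)) {
      pres <- length(sets[[i]]) > 0 && all(sets[[i]] %in% focal)
      non <- setdiff(all_h, sets[[i]])
      abs_ <- length(non) > 0 && all(non %in% focal)
      in_out <- cat_r$id[i] %in% gs_r$sv_id
      expect_equal(in_out, pres || abs_)
    }
  }
  expect_error(group_specific_svs(cat_, cohort_labels("x.hap1", "x", "RF"),
                                  "GF"),
               "zero haplotypes")
})

test_that("promoter-DE overlap fractions and edge cases", {
  co <- cohort_labels(c("A.hap1", "A.hap2", "B.hap1", "B.hap2"),
                      c("A", "A", "B", "B"), c("RF", "RF", "GF", "GF"))
  m <- gene_models(
    genes = data.frame(gene_id = paste0("g", 1:5), chrom = "Chr1",
                       start = (1:5) * 20000L, end = (1:5) * 20000L + 1000L,
                       strand = "+"),
    exons = data.frame(gene_id = paste0("g", 1:5),
                       start = (1:5) * 20000L, end = (1:5) * 20000L + 1000L))
  # promoter SVs for g1..g4, polymorphic A-vs-B; plus one shared (not poly)
  carr <- list("B.hap1", "B.hap2", c("B.hap1", "B.hap2"), "A.hap1",
               c("A.hap1", "B.hap1"))
  cat_ <- data.table::data.table(
    id = sprintf("sv%d", 1:5), chrom = "Chr1",
    pos = (1:5) * 20000L - 300L, svtype = "DEL", length = 60L,
    alt_seq = NA_character_, nmembers = 1L, carriers = carr)
  ctx <- classify_context(cat_, m)
  expect_equal(ctx$context, rep("promoter", 5))
  de <- data.table::data.table(gene_id = c("g1", "g2", "g3", "g4"),
                               status = c("up", "ns", "ns", "ns"))
  res <- promoter_de_overlap(cat_, ctx, c("A", "B"), de, co)
  # g5's SV is carried in both accessions -> excluded; 4 genes, 1 up
  expect_equal(res$n_genes, 4L)
  expect_equal(unname(res$fractions), c(0.25, 0, 0.75))
  expect_equal(sum(res$fractions), 1)
  # no qualifying promoter SVs -> explicit empty flag, no division by zero
  none <- promoter_de_overlap(cat_[0], ctx[0], c("A", "B"), de, co)
  expect_true(none$empty)
  expect_equal(none$n_genes, 0L)
  expect_error(promoter_de_overlap(cat_, ctx, c("A", "Z"), de, co),
               "not in cohort")
})

test_that("pathway association includes nearest-intergenic links", {
  m <- toy_gene_models()
  svs <- sv_records("Chr1", c(10100L, 20000L, 49000L), "DEL",
                    c(100L, 60L, 51L), NA, "h")
  cat_ <- merge_svs(svs)
  ctx <- classify_context(cat_, m)
  # gA is hit exonic by sv1 and nearest-intergenic by sv2
  res <- pathway_sv_association(cat_, ctx, "gA", m)
  expect_equal(nrow(res$associations), 2L)
  expect_equal(unname(res$by_context[c("exonic", "intergenic")]), c(1L, 1L))
  expect_equal(nrow(pathway_sv_association(cat_, ctx, character(),
                                           m)$associations), 0L)
  expect_warning(res2 <- pathway_sv_association(cat_, ctx, c("gA", "nope"),
                                                m),
                 "nope")
  expect_equal(nrow(res2$associations), 2L)
})

test_that("naive DE surrogate flags a strong planted effect only", {
  set.seed(34)
  expr <- matrix(rnbinom(200 * 6, mu = 50, size = 10), 200, 6,
                 dimnames = list(sprintf("g%03d", 1:200), paste0("s", 1:6)))
  expr[1, 4:6] <- rnbinom(3, mu = 50 * 8, size = 10)  # planted up in group b
  de <- naive_de(expr, paste0("s", 1:3), paste0("s", 4:6))
  expect_equal(de$status[1], "up")
  expect_lt(mean(de$status != "ns"), 0.2)  # few false calls
  expect_error(naive_de(expr, "s1", paste0("s", 4:6)), ">= 2 samples")
})
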