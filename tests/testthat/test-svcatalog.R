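test_that("merge thresholds: join rule arithmetic on the stated defaults", {
  one <- sv_records("Chr1", 100L, "DEL", 60L, NA, "h1")
  expect_equal(nrow(merge_svs(one)), 1L)
  # dpos 40 <= 50 and dlen 10 <= 20 -> merged
  r <- sv_records("Chr1", c(100L, 140L), "DEL", c(60L, 70L), NA,
                  c("h1", "h2"))
  m <- merge_svs(r)
  expect_equal(nrow(m), 1L)
  expect_equal(m$pos, 100L)        # representative = leftmost member
  expect_equal(m$length, 60L)
  expect_equal(m$carriers[[1]], c("h1", "h2"))
  expect_equal(m$nmembers, 2L)
  # dpos 60 > 50 -> not merged
  r2 <- sv_records("Chr1", c(100L, 160L), "DEL", c(60L, 60L), NA,
                   c("h1", "h2"))
  expect_equal(nrow(merge_svs(r2)), 2L)
  # dlen 25 > 20 -> not merged even at identical pos
  r3 <- sv_records("Chr1", c(100L, 100L), "DEL", c(60L, 85L), NA,
                   c("h1", "h2"))
  expect_equal(nrow(merge_svs(r3)), 2L)
  # cross-type merging forbidden at identical coordinates
  r4 <- sv_records("Chr1", c(100L, 100L), c("DEL", "INS"), c(60L, 60L), NA,
                   c("h1", "h2"))
  expect_equal(nrow(merge_svs(r4)), 2L)
  expect_error(merge_svs(sv_records("Chr9", 1L, "DEL", 60L, NA, "h"),
                         chrom_lengths = c(Chr1 = 1000L)),
               "unknown")
  expect_error(merge_svs(sv_records("Chr1", 1L, "INV", 60L, NA, "h")),
               "INS/DEL")
})

test_that("merge equals the O(n^2) left-transitive oracle on random records", {
  set.seed(21)
  for (rep in 1:3) {
    recs <- random_sv_records(200, max_pos = 5000)  # dense -> many merges
    m <- merge_svs(recs)
    oc <- oracle_merge(recs)
    expect_equal(nrow(m), length(oc))
    key <- function(df) paste(df$chrom[1], df$svtype[1], df$pos[1],
                              df$length[1])
    m_keys <- sort(paste(m$chrom, m$svtype, m$pos, m$length))
    o_keys <- sort(vapply(oc, key, ""))
    expect_equal(m_keys, o_keys)
    # member multisets match too
    o_sizes <- sort(vapply(oc, nrow, 0L))
    expect_equal(sort(m$nmembers), o_sizes)
  }
})

test_that("merging is idempotent, order-invariant and size-bounded", {
  set.seed(22)
  recs <- random_sv_records(300, max_pos = 8000)
  m1 <- merge_svs(recs)
  expect_lte(nrow(m1), nrow(recs))
  # idempotence: re-merging the representatives changes nothing
  reps <- sv_records(m1$chrom, m1$pos, m1$svtype, m1$length, NA, "rep")
  expect_equal(nrow(merge_svs(reps)), nrow(m1))
  # permuting input order does not change the catalog
  m2 <- merge_svs(recs[sample(nrow(recs)), ])
  expect_equal(m2$pos, m1$pos)
  expect_equal(m2$nmembers, m1$nmembers)
})

test_that("frequency spectrum collapses haplotypes to accessions", {
  co <- cohort_labels(c("A.hap1", "A.hap2", "B.hap1", "B.hap2"),
                      c("A", "A", "B", "B"), c("RF", "RF", "GF", "GF"))
  r <- sv_records("Chr1", c(100L, 100L, 5000L), "DEL", c(60L, 60L, 90L), NA,
                  c("A.hap1", "A.hap2", "B.hap1"))
  cat_ <- merge_svs(r)
  spec <- frequency_spectrum(cat_, co)
  # both SVs are single-accession: the shared-hap one still counts once
  expect_equal(spec$n_svs, c(2L, 0L))
  expect_equal(sum(spec$n_svs), nrow(cat_))
})

test_that("per-accession counts match a hand count and handle empties", {
  co <- cohort_labels(c("A.hap1", "A.hap2", "B.hap1"), c("A", "A", "B"),
                      c("RF", "RF", "GF"))
  empty <- per_accession_counts(
    sv_records(character(), integer(), character(), integer()), co)
  expect_equal(empty$total, c(0L, 0L))
  r <- sv_records("Chr1", c(1, 2, 3, 4, 5, 6) * 1000L,
                  c("DEL", "DEL", "INS", "INV", "TRA", "DEL"),
                  c(60L, 70L, 80L, 90L, 100L, 110L), NA,
                  c("A.hap1", "A.hap2", "A.hap1", "B.hap1", "B.hap1",
                    "B.hap1"))
  tab <- per_accession_counts(r, co)
  expect_equal(tab[tab$accession == "A", ]$DEL, 2L)
  expect_equal(tab[tab$accession == "A", ]$INS, 1L)
  expect_equal(tab[tab$accession == "B", ]$total, 3L)
  expect_equal(tab[tab$accession == "B", ]$INV, 1L)
})

test_that("merged catalog VCF round-trips ids, carriers and members", {
  set.seed(23)
  recs <- random_sv_records(60)
  cat_ <- merge_svs(recs)
  path <- file.path(tempdir(), "merged.vcf")
  write_merged_vcf(cat_, path, c(Chr1 = 100000L, Chr2 = 100000L))
  back <- read_merged_vcf(path)
  expect_equal(back$id, cat_$id)
  expect_equal(back$pos, cat_$pos)
  expect_equal(back$length, cat_$length)
  expect_equal(back$nmembers, cat_$nmembers)
  expect_equal(back$carriers, cat_$carriers)
})

test_that("synthetic cohort SV totals match the generator truth file", {
  b <- small_bundle()
  truth <- read_tsv(file.path(b$dir, "truth.tsv"))
  loci <- truth[truth$entity_type == "sv_locus", ]
  recs <- read_bundle_records(b)
  # per-record totals: sum of carrier-set sizes over loci
  carriers <- regmatches(loci$planted_label,
                         regexpr("carriers=[^;]+", loci$planted_label))
  n_rec_truth <- sum(lengths(strsplit(sub("carriers=", "", carriers), "|",
                                      fixed = TRUE)))
  expect_equal(nrow(recs), n_rec_truth)
  # merged catalog reproduces the INS/DEL locus count exactly
  cat_ <- merge_svs(recs[recs$svtype %in% c("INS", "DEL"), ])
  expect_equal(nrow(cat_),
               sum(grepl("svtype=(INS|DEL)", loci$planted_label)))
  # accession frequency spectrum equals the truth-file spectrum
  co <- read_cohort_labels(file.path(b$dir, "cohort.tsv"))
  spec <- frequency_spectrum(cat_, co)
  hap2acc <- setNames(co$accession, co$haplotype_id)
  indel <- grepl("svtype=(INS|DEL)", loci$planted_label)
  truth_freq <- vapply(strsplit(sub("carriers=", "", carriers[indel]), "|",
                                fixed = TRUE),
                       function(h) length(unique(hap2acc[h])), 0L)
  expect_equal(spec$n_svs, vapply(seq_len(7), function(a)
    sum(truth_freq == a), 0L))
})
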