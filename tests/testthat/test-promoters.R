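make_tss <- function(chrom, pos0, strand, name) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(pos0 + 1L, pos0 + 1L),
                         strand = strand, name = name, score = 0L)
}

test_that("promoter windows follow the strand-aware coordinate rules", {
  set.seed(5)
  genome <- Biostrings::DNAStringSet(c(chrA = random_dna(7000)))
  tss <- make_tss("chrA", 5000L, "+", "gplus")
  pr <- extract_promoter_windows(tss, genome, NULL)
  expect_equal(pr$meta$start, 3000L)
  expect_equal(pr$meta$end, 6000L)
  expect_equal(Biostrings::width(pr$seqs)[[1]], 3000L)
  expect_equal(as.character(pr$seqs[[1]]),
               as.character(Biostrings::subseq(genome[[1]], 3001, 6000)))

  # clipping at the chromosome edge
  pr2 <- extract_promoter_windows(make_tss("chrA", 100L, "+", "edge"),
                                  genome, NULL)
  expect_equal(pr2$meta$start, 0L)
  expect_equal(pr2$meta$end, 1100L)
  expect_equal(Biostrings::width(pr2$seqs)[[1]], 1100L)

  # minus strand: window [t - 999, t + 2001), reverse-complemented
  pr3 <- extract_promoter_windows(make_tss("chrA", 5000L, "-", "gminus"),
                                  genome, NULL)
  expect_equal(pr3$meta$start, 4001L)
  expect_equal(pr3$meta$end, 7000L)  # [4001, 7001) clipped at chrom end
  slice <- Biostrings::subseq(genome[[1]], 4002, 7000)
  expect_equal(as.character(pr3$seqs[[1]]),
               as.character(Biostrings::reverseComplement(slice)))

  expect_error(
    extract_promoter_windows(make_tss("chrZ", 10L, "+", "x"), genome, NULL),
    "absent from FASTA"
  )
})

test_that("conservation aligns to promoter orientation with zero default", {
  set.seed(6)
  genome <- Biostrings::DNAStringSet(c(c1 = random_dna(60)))
  cons <- GenomicRanges::GRanges("c1", IRanges::IRanges(11:20, 11:20),
                                 score = seq(0.1, 1, by = 0.1))
  plus <- extract_promoter_windows(make_tss("c1", 20L, "+", "p"), genome,
                                   cons, upstream = 10L, downstream = 5L)
  # genomic interval [10, 25): bases 11..20 carry 0.1..1, rest 0
  expect_equal(plus$cons[["p"]], c(seq(0.1, 1, 0.1), rep(0, 5)))
  minus <- extract_promoter_windows(make_tss("c1", 20L, "-", "m"), genome,
                                    cons, upstream = 10L, downstream = 5L)
  # genomic interval [16, 31): 0-based 16..19 carry 0.7..1.0, rest 0
  expect_equal(minus$cons[["m"]], rev(c(0.7, 0.8, 0.9, 1.0, rep(0, 11))))
})

test_that("extraction is pure and promoter FASTA round-trips exactly", {
  p <- random_pwm(8, seed = 2)
  gs <- simulate_genome(10, 20, p, upstream = 60, downstream = 20, seed = 4)
  a <- extract_promoter_windows(gs$tss, gs$genome, gs$conservation,
                                upstream = 60, downstream = 20)
  b <- extract_promoter_windows(gs$tss, gs$genome, gs$conservation,
                                upstream = 60, downstream = 20)
  expect_identical(a$meta, b$meta)
  expect_identical(as.character(a$seqs), as.character(b$seqs))
  expect_identical(a$cons, b$cons)

  dir <- tempfile()
  write_promoters(a, dir)
  back <- read_promoters(dir)
  expect_identical(back$meta, a$meta)
  expect_identical(as.character(back$seqs), as.character(a$seqs))
  expect_equal(back$cons, a$cons)
})

test_that("file-based inputs (FASTA, BED, bedGraph) reproduce in-memory extraction", {
  p <- random_pwm(8, seed = 2)
  gs <- simulate_genome(8, 12, p, upstream = 60, downstream = 20, seed = 9)
  dir <- tempfile()
  write_genome_files(gs, dir)
  mem <- extract_promoter_windows(gs$tss, gs$genome, gs$conservation,
                                  upstream = 60, downstream = 20)
  fil <- extract_promoter_windows(file.path(dir, "tss.bed"),
                                  file.path(dir, "genome.fa"),
                                  file.path(dir, "conservation.bedGraph"),
                                  upstream = 60, downstream = 20)
  expect_identical(as.character(fil$seqs), as.character(mem$seqs))
  expect_equal(fil$cons, mem$cons)
  expect_identical(fil$meta, mem$meta)
})

test_that("deduplication enforces the strict >1500 bp overlap rule", {
  # 1501 bp overlap: one survivor
  ps <- interval_promoters(c(0L, 1499L), c(3000L, 4499L))
  out <- dedupe_overlapping(ps, seed = 1)
  expect_equal(length(out), 1L)
  # exactly 1500 bp overlap: both survive
  ps2 <- interval_promoters(c(0L, 1500L), c(3000L, 4500L))
  out2 <- dedupe_overlapping(ps2, seed = 1)
  expect_equal(length(out2), 2L)
  # determinism under a fixed seed
  ps3 <- interval_promoters(c(0L, 100L, 200L, 5000L),
                            c(3000L, 3100L, 3200L, 8000L))
  r1 <- dedupe_overlapping(ps3, seed = 42)
  r2 <- dedupe_overlapping(ps3, seed = 42)
  expect_identical(r1$meta, r2$meta)
  expect_equal(length(dedupe_overlapping(ps3[0], seed = 1)), 0L)
})

test_that("chain deduplication yields a maximal retention subset", {
  set.seed(17)
  for (rep_i in 1:25) {
    n <- sample(3:6, 1)
    starts <- sort(sample(0:4000, n))
    ends <- starts + 3000L
    ps <- interval_promoters(starts, ends)
    out <- dedupe_overlapping(ps, seed = rep_i)
    got <- sort(out$meta$gene_id)
    fams <- maximal_retention_sets(ps$meta, 1500L)
    expect_true(any(vapply(fams, identical, NA, y = got)),
                info = paste("starts:", paste(starts, collapse = ","),
                             "got:", paste(got, collapse = ",")))
    # no violating pair remains
    m <- out$meta
    if (nrow(m) > 1L) {
      for (i in seq_len(nrow(m) - 1L)) {
        for (j in (i + 1L):nrow(m)) {
          expect_lte(overlap_bp(m$start[i], m$end[i], m$start[j], m$end[j]),
                     1500L)
        }
      }
    }
  }
})
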