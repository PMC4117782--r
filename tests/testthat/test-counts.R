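make_reads <- function(chrom, start, end, strand = "+", unique = TRUE) {
  data.frame(chrom = chrom, start = start, end = end, strand = strand,
             unique = unique, stringsAsFactors = FALSE)
}

test_that("reads are assigned to the fragment holding their 5' end", {
  lib <- toy_library()
  # chrA fragments: [0,1001), [1001,3007), [3007,4006)
  r <- make_reads("chrA", 100, 150)
  cnt <- assign_reads(r, lib)
  expect_equal(unname(cnt$counts[lib$fragment_id[1]]), 1L)
  expect_equal(cnt$total, 1L)

  # minus-strand read: 5' end is end - 1
  r2 <- make_reads("chrA", 990, 1040, strand = "-")
  cnt2 <- assign_reads(r2, lib)
  expect_equal(unname(cnt2$counts[lib$fragment_id[2]]), 1L)

  # plus-strand read spanning a cut site belongs to its 5' fragment
  r3 <- make_reads("chrA", 990, 1040, strand = "+")
  cnt3 <- assign_reads(r3, lib)
  expect_equal(unname(cnt3$counts[lib$fragment_id[1]]), 1L)
})

test_that("duplicates collapse and non-unique reads are discarded", {
  lib <- toy_library()
  r <- rbind(make_reads("chrA", 100, 150),
             make_reads("chrA", 100, 150),
             make_reads("chrA", 100, 150),
             make_reads("chrA", 100, 180),   # same 5'/strand: duplicate
             make_reads("chrA", 100, 150, strand = "-"),  # distinct
             make_reads("chrA", 500, 550, unique = FALSE))
  cnt <- assign_reads(r, lib)
  expect_equal(cnt$total, 2L)
  expect_equal(cnt$retained, 2L)
})

test_that("counts match a brute-force interval tally and are conserved", {
  setup <- small_4c_setup()
  lib <- setup$library
  set.seed(99)
  n <- 1000L
  chroms <- sample(c(unique(lib$chrom), "chrUn"), n, replace = TRUE,
                   prob = c(0.45, 0.45, 0.1))
  maxlen <- attr(lib, "chrom_sizes")[chroms]
  maxlen[is.na(maxlen)] <- 50000L
  start <- floor(runif(n) * (maxlen - 60))
  reads <- make_reads(chroms, start, start + 50L,
                      strand = sample(c("+", "-"), n, replace = TRUE))
  cnt <- assign_reads(reads, lib)

  # oracle: dedupe then count 5' positions per fragment by interval test
  p5 <- ifelse(reads$strand == "+", reads$start, reads$end - 1)
  dedup <- !duplicated(paste(reads$chrom, p5, reads$strand))
  rd <- reads[dedup, ]; p5 <- p5[dedup]
  oracle <- sapply(seq_len(nrow(lib)), function(i) {
    sum(rd$chrom == lib$chrom[i] & p5 >= lib$start[i] & p5 < lib$end[i])
  })
  expect_equal(unname(cnt$counts[lib$fragment_id]), oracle)
  expect_equal(cnt$unplaced, sum(rd$chrom == "chrUn"))
  expect_identical(cnt$total + cnt$unplaced, cnt$retained)
})

test_that("assignment is invariant to read order", {
  setup <- small_4c_setup()
  set.seed(5)
  start <- sort(sample.int(150000L, 300))
  reads <- make_reads("chr1", start, start + 40L)
  a <- assign_reads(reads, setup$library)
  b <- assign_reads(reads[sample(nrow(reads)), ], setup$library)
  expect_identical(a$counts, b$counts)
})

test_that("bait-zone masking equals a brute-force distance filter", {
  setup <- small_4c_setup()
  lib <- setup$library
  bait <- setup$bait
  cnt <- assign_reads(make_reads("chr1", 10, 60), lib)

  m0 <- exclude_bait_zone(cnt, bait, radius = 0)
  expect_identical(m0$masked, bait)

  m_all <- exclude_bait_zone(cnt, bait, radius = 1e9)
  expect_setequal(m_all$masked, lib$fragment_id[lib$chrom == "chr1"])

  m10 <- exclude_bait_zone(cnt, bait, radius = 10000)
  b <- lib[lib$fragment_id == bait, ]
  gap <- ifelse(lib$chrom != b$chrom, NA,
                pmax(0, pmax(lib$start - b$end, b$start - lib$end)))
  oracle <- lib$fragment_id[!is.na(gap) &
                              (gap < 10000 | lib$fragment_id == bait)]
  expect_setequal(m10$masked, oracle)

  expect_error(exclude_bait_zone(cnt, "FRAG_NOPE"), "not in library")
})

test_that("track normalization conserves total signal mass", {
  # one read, L = 200: a single interval of height R_target
  tr <- make_track(make_reads("chr1", 1000, 1036), L = 200, R_target = 2e7)
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$start, 1000)
  expect_equal(tr$end, 1200)
  expect_equal(tr$value, 2e7)

  # per-read weight R_target / retained
  set.seed(21)
  start <- sample.int(100000L, 5000)
  reads <- make_reads("chr1", start, start + 36L,
                      strand = sample(c("+", "-"), 5000, replace = TRUE))
  reads <- reads[start > 300, ]  # avoid clipping at position 0
  tr <- make_track(reads, L = 150, R_target = 2e7)
  expect_equal(attr(tr, "weight"), 2e7 / nrow(reads))
  mass <- sum((tr$end - tr$start) * tr$value)
  expect_equal(mass, 2e7 * 150, tolerance = 1e-6)

  # doubling the input at distinct positions leaves total mass unchanged
  reads2 <- rbind(reads, make_reads("chr2", start + 7L, start + 43L)[
    seq_len(nrow(reads)), ])
  tr2 <- make_track(reads2, L = 150, R_target = 2e7)
  expect_equal(sum((tr2$end - tr2$start) * tr2$value), mass,
               tolerance = 1e-6)

  expect_error(make_track(make_reads("chr1", 1, 10, unique = FALSE),
                          L = 100), "zero retained")
})

test_that("counts and read tables round-trip through their TSV formats", {
  setup <- small_4c_setup()
  reads <- make_reads("chr1", c(10, 20, 30), c(60, 70, 80))
  rp <- withr::local_tempfile(fileext = ".tsv")
  write_read_table(reads, rp)
  expect_equal(read_read_table(rp), reads)

  cnt <- exclude_bait_zone(assign_reads(reads, setup$library), setup$bait)
  cp <- withr::local_tempfile(fileext = ".tsv")
  write_counts(cnt, cp)
  tab <- utils::read.table(cp, header = TRUE, sep = "\t")
  expect_equal(sum(tab$count), cnt$total)
  expect_equal(tab$fragment_id[tab$masked], setup$bait)
})
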