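# Build an estimates table directly (bypassing counting) so calling rules
# can be checked against brute-force oracles.
fake_estimates <- function(n, chrom = "chr1", counts = NULL, seed = 1) {
  set.seed(seed)
  counts <- counts %||% sample(0:100, n, replace = TRUE)
  start <- seq(0L, by = 1000L, length.out = n)
  structure(data.frame(
    fragment_id = sprintf("F%04d", seq_len(n)),
    chrom = chrom, start = start, end = start + 1000L,
    count = counts,
    elog2p = log2((counts + 0.5) / sum(counts + 0.5)) +
      runif(n, -1e-3, 1e-3),
    mc_sd = 0.01, interacting = counts >= 1
  ), class = c("interaction_estimates", "data.frame"))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("the top decile of interacting sites is called, exactly", {
  est <- fake_estimates(100, counts = sample(1:500, 100))
  calls <- call_strong(est, q = 0.10)
  expect_equal(nrow(calls), 10L)
  # brute-force oracle: the ten largest elog2p
  oracle <- est$fragment_id[order(-est$elog2p)][1:10]
  expect_setequal(calls$fragment_id, oracle)

  # called fraction is exactly floor(q * |universe|) for any q
  est2 <- fake_estimates(1000, counts = sample(0:50, 1000, replace = TRUE))
  U <- sum(est2$interacting)
  for (q in c(0.05, 0.10, 0.25, 0.5, 0.999)) {
    expect_equal(nrow(call_strong(est2, q = q)), floor(q * U))
  }

  # zero-count fragments are outside the universe
  z <- fake_estimates(50, counts = rep(0L, 50))
  expect_warning(cz <- call_strong(z, q = 0.10), "empty universe")
  expect_equal(nrow(cz), 0L)
})

test_that("boundary ties break by count then genomic coordinate", {
  est <- fake_estimates(6, counts = c(5L, 5L, 5L, 5L, 9L, 2L))
  est$elog2p <- c(-2, -2, -2, -2, -1, -3)  # four-way tie at the boundary
  est$count <- c(5L, 5L, 7L, 5L, 9L, 2L)
  est$start <- c(5000L, 3000L, 1000L, 2000L, 0L, 4000L)
  calls <- call_strong(est, q = 0.5)       # 3 calls from universe of 6
  # best elog2p first, then among the tie: higher count, then lower start
  expect_equal(calls$fragment_id[1], "F0005")
  expect_equal(calls$fragment_id[2], "F0003")
  expect_equal(calls$start[3], 2000L)
})

test_that("cis/trans labels follow the bait chromosome", {
  est <- rbind(fake_estimates(5, chrom = "chr7"),
               fake_estimates(5, chrom = "chr12", seed = 2))
  est$fragment_id <- sprintf("F%04d", 1:10)
  calls <- call_strong(est, q = 0.5)
  bait <- bait_spec("bait", "chr7", 0, 1000)
  lab <- classify_cis_trans(calls, bait)
  expect_setequal(unique(lab$label[lab$chrom == "chr7"]), "cis")
  expect_setequal(unique(lab$label[lab$chrom == "chr12"]), "trans")
})

test_that("replicate intersection is a true set intersection", {
  cs <- function(ids) {
    structure(data.frame(fragment_id = ids, chrom = "chr1",
                         start = seq_along(ids) * 1000L,
                         end = seq_along(ids) * 1000L + 500L),
              class = c("call_set", "data.frame"))
  }
  common <- intersect_replicates(list(cs(c("f1", "f2", "f3")),
                                      cs(c("f2", "f3", "f4"))))
  expect_setequal(common$fragment_id, c("f2", "f3"))
  # idempotence and order invariance
  a <- cs(c("f1", "f5", "f9"))
  expect_setequal(intersect_replicates(list(a, a))$fragment_id,
                  a$fragment_id)
  sets <- list(cs(paste0("f", 1:8)), cs(paste0("f", 4:10)),
               cs(paste0("f", c(1, 4, 5, 6, 11))))
  out1 <- intersect_replicates(sets)
  out2 <- intersect_replicates(rev(sets))
  expect_setequal(out1$fragment_id, out2$fragment_id)
  expect_setequal(out1$fragment_id,
                  Reduce(intersect, lapply(sets, `[[`, "fragment_id")))
  # common set is a subset of every input
  for (s in sets) expect_true(all(out1$fragment_id %in% s$fragment_id))
})

test_that("three seeded replicate call sets intersect like brute force", {
  setup <- small_4c_setup()
  truth <- contact_truth(setup$library, setup$bait, n_cis = 5, n_trans = 5,
                         min_cis_gap = 2e4, seed = 3)
  reps <- simulate_4c_replicates(truth, setup$library, n_reads = 2e4,
                                 n_reps = 3, seed = 3)
  callsets <- lapply(seq_along(reps), function(r) {
    cnt <- exclude_bait_zone(assign_reads(reps[[r]], setup$library),
                             setup$bait, radius = 2e4)
    call_strong(posterior_log2_proportions(cnt, M = 64, seed = r), q = 0.10)
  })
  common <- intersect_replicates(callsets)
  expect_setequal(common$fragment_id,
                  Reduce(intersect, lapply(callsets, `[[`, "fragment_id")))
})

test_that("distance strata partition cis calls by gap to the bait", {
  bait <- bait_spec("bait", "chr1", 100000, 104000)
  calls <- structure(data.frame(
    fragment_id = paste0("f", 1:5),
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr9"),
    start = c(104000L, 140000L, 900000L, 2200000L, 5000L),
    end = c(110000L, 144000L, 904000L, 2204000L, 9000L)),
    class = c("call_set", "data.frame"))
  strata <- distance_summary(calls, bait)
  expect_equal(strata$n, c(2L, 1L, 1L))   # adjacent gap 0 is <=50kb
  expect_equal(sum(strata$n), sum(calls$chrom == "chr1"))

  # seeded call set against a brute-force filter
  set.seed(12)
  start <- sort(sample.int(3e6, 200)) * 1L
  calls2 <- structure(data.frame(fragment_id = paste0("g", 1:200),
                                 chrom = "chr1", start = start,
                                 end = start + 2000L),
                      class = c("call_set", "data.frame"))
  strata2 <- distance_summary(calls2, bait)
  gap <- pmax(0, pmax(calls2$start - bait$end, bait$start - calls2$end))
  expect_equal(strata2$n, c(sum(gap <= 5e4), sum(gap > 5e4 & gap <= 1e6),
                            sum(gap > 1e6)))
})

test_that("binned profiles conserve counts and use midpoint assignment", {
  g <- simulate_genome(c(chrM = 2500000L), site_density = 1 / 3000,
                       seed = 10)
  lib <- digest(g$genome, "EcoRI")
  set.seed(10)
  start <- sample.int(2400000L, 5000)
  reads <- data.frame(chrom = "chrM", start = start, end = start + 40L,
                      strand = "+", unique = TRUE)
  cnt <- assign_reads(reads, lib)
  bp <- bin_profile(cnt, W = 1e6, M = 32)
  expect_equal(nrow(bp), 3L)               # bins tile the chromosome
  expect_equal(bp$end[3], 2500000)
  expect_equal(sum(bp$count), sum(cnt$counts))
  # oracle: counts aggregated by fragment midpoint
  mid <- (lib$start + lib$end) %/% 2
  oracle <- sapply(c(0, 1e6, 2e6), function(b) {
    sum(cnt$counts[lib$fragment_id[mid >= b & mid < b + 1e6]])
  })
  expect_equal(bp$count, as.integer(oracle))

  # a midpoint exactly on a boundary goes to the right-hand bin
  lib2 <- structure(data.frame(chrom = "c", start = c(0L, 997000L),
                               end = c(997000L, 1003000L),
                               fragment_id = c("a", "b")),
                    chrom_sizes = c(c = 1003000L),
                    class = c("fragment_library", "data.frame"))
  cnt2 <- list(library = lib2, counts = c(a = 3L, b = 4L))
  class(cnt2) <- "fragment_counts"
  bp2 <- bin_profile(cnt2, W = 1e6, M = 16)
  expect_equal(bp2$count, c(3L, 4L))  # midpoint of b sits exactly at 1 Mb
})
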