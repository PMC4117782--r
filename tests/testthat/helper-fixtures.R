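# Shared fixtures built in code.

# Exhaustive window-scan oracle for recognition-site cut positions,
# independent of the package's Biostrings-based implementation.
scan_cuts_oracle <- function(sequence, site, cut_offset) {
  chars <- strsplit(sequence, "")[[1]]
  w <- nchar(site)
  hits <- integer(0)
  for (s in seq_len(max(0L, length(chars) - w + 1L))) {
    if (paste(chars[s:(s + w - 1L)], collapse = "") == site) {
      hits <- c(hits, s - 1L + cut_offset)
    }
  }
  sort(unique(hits))
}

# Random DNA string (may contain chance recognition sites).
random_dna <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# A small two-chromosome library with deterministic EcoRI sites.
toy_genome <- function() {
  spacer <- function(n) strrep("AC", n / 2)
  c(chrA = paste0(spacer(1000), "GAATTC", spacer(2000), "GAATTC",
                  spacer(1000)),
    chrB = paste0(spacer(1500), "GAATTC", spacer(1500)))
}

toy_library <- function() digest(toy_genome(), "EcoRI")

# A compact synthetic 4C setup reused by the call-level tests: one 200 kb
# bait chromosome plus one 100 kb trans chromosome.
small_4c_setup <- function(seed = 7L) {
  sim <- simulate_genome(c(chr1 = 200000L, chr2 = 100000L),
                         site_density = 1 / 2000, seed = seed)
  library <- digest(sim$genome, "EcoRI")
  mid <- 100000L
  sel <- library$chrom == "chr1" & library$start <= mid & library$end > mid
  list(library = library, bait = library$fragment_id[sel])
}
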