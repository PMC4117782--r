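#' Read placements and per-fragment unique-read counts
#'
#' 4C and ChIP-style read placements are tabular records
#' (`chrom`, `start`, `end`, `strand`, `unique`) with 0-based half-open
#' coordinates. Counting keeps only uniquely aligned reads, collapses PCR
#' duplicates defined by the (chrom, 5' position, strand) triple, and
#' assigns each retained read to the restriction fragment containing its 5'
#' end — 4C reads begin at ligation junctions, so the 5' coordinate is the
#' informative one even when a read spans a cut site.
#'
#' @name fourc-counts
NULL

#' Read / write an aligned-read table
#'
#' Tab-separated with header columns `chrom`, `start`, `end`, `strand`,
#' `unique`.
#'
#' @param path File path.
#' @param reads A read `data.frame`.
#' @return `read_read_table` returns the read `data.frame`.
#' @export
read_read_table <- function(path) {
  reads <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "strand", "unique")
  if (!all(need %in% names(reads))) {
    stop("read table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  reads$unique <- as.logical(reads$unique)
  validate_reads(reads)
  reads
}

#' @rdname read_read_table
#' @export
write_read_table <- function(reads, path) {
  utils::write.table(reads, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

validate_reads <- function(reads) {
  if (any(reads$start >= reads$end)) stop("read with start >= end",
                                          call. = FALSE)
  if (!all(reads$strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'", call. = FALSE)
  }
  invisible(reads)
}

read_5prime <- function(reads) {
  ifelse(reads$strand == "+", reads$start, reads$end - 1L)
}

#' Count unique reads per restriction fragment
#'
#' Discards non-unique alignments, collapses duplicates (same chrom, 5'
#' position and strand) to a single read, and assigns every retained read
#' to the fragment containing its 5' coordinate. Reads on chromosomes
#' absent from the library are tallied as `unplaced`, never silently
#' dropped: `sum(counts) + unplaced == retained reads`, exactly.
#'
#' @param reads Read `data.frame` (see [read_read_table()]).
#' @param library A `fragment_library` from [digest()].
#' @param replicate_id Label carried through to downstream call sets.
#' @return A `fragment_counts` object: list with `library`, `counts`
#'   (named integer vector over all fragment ids), `total`, `unplaced`,
#'   `retained`, `replicate_id` and `masked` (character vector of masked
#'   fragment ids, empty until [exclude_bait_zone()]).
#' @export
assign_reads <- function(reads, library, replicate_id = "rep1") {
  validate_library(library)
  validate_reads(reads)
  reads <- reads[reads$unique, , drop = FALSE]
  p5 <- read_5prime(reads)
  dup_key <- paste(reads$chrom, p5, reads$strand)
  keep <- !duplicated(dup_key)
  reads <- reads[keep, , drop = FALSE]
  p5 <- p5[keep]
  retained <- nrow(reads)

  counts <- stats::setNames(integer(nrow(library)), library$fragment_id)
  unplaced <- 0L
  for (ch in unique(reads$chrom)) {
    sel <- reads$chrom == ch
    frags <- library[library$chrom == ch, , drop = FALSE]
    if (nrow(frags) == 0L) {
      unplaced <- unplaced + sum(sel)
      next
    }
    frags <- frags[order(frags$start), , drop = FALSE]
    pos <- p5[sel]
    inside <- pos >= 0L & pos < max(frags$end)
    unplaced <- unplaced + sum(!inside)
    idx <- findInterval(pos[inside], frags$start)
    tab <- tabulate(idx, nbins = nrow(frags))
    counts[frags$fragment_id] <- counts[frags$fragment_id] + tab
  }
  structure(list(library = library, counts = counts,
                 total = sum(counts), unplaced = unplaced,
                 retained = retained, replicate_id = replicate_id,
                 masked = character(0)),
            class = "fragment_counts")
}

#' @export
print.fragment_counts <- function(x, ...) {
  cat("<fragment_counts> ", x$replicate_id, ": ", x$total,
      " reads on ", sum(x$counts > 0), "/", length(x$counts),
      " fragments (", x$unplaced, " unplaced, ", length(x$masked),
      " masked)\n", sep = "")
  invisible(x)
}

#' Mask the bait fragment and its neighbourhood
#'
#' The bait fragment (dominated by the self-ligation product) and, with
#' `radius > 0`, every fragment whose genomic gap to the bait fragment is
#' smaller than `radius`, are masked out of the statistical universe used
#' for estimation and calling. Counts are kept, only the mask changes.
#'
#' @param counts A `fragment_counts` object.
#' @param bait Fragment id of the bait fragment.
#' @param radius Bases; default 0 masks the bait fragment only.
#' @return The `fragment_counts` with an updated `masked` set.
#' @export
exclude_bait_zone <- function(counts, bait, radius = 0) {
  lib <- counts$library
  b <- lib[lib$fragment_id == bait, , drop = FALSE]
  if (nrow(b) != 1L) stop("bait fragment '", bait, "' not in library",
                          call. = FALSE)
  cis <- lib[lib$chrom == b$chrom, , drop = FALSE]
  gap <- pmax(0L, pmax(cis$start - b$end, b$start - cis$end))
  masked <- cis$fragment_id[cis$fragment_id == bait | gap < radius]
  counts$masked <- sort(unique(c(counts$masked, masked)))
  counts
}

#' Write per-fragment counts as TSV
#'
#' Columns `fragment_id`, `chrom`, `start`, `end`, `count`, `masked`.
#'
#' @param counts A `fragment_counts`.
#' @param path Output path.
#' @export
write_counts <- function(counts, path) {
  lib <- counts$library
  out <- data.frame(fragment_id = lib$fragment_id, chrom = lib$chrom,
                    start = lib$start, end = lib$end,
                    count = as.integer(counts$counts[lib$fragment_id]),
                    masked = lib$fragment_id %in% counts$masked)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Build a normalized coverage track from read placements
#'
#' Each (unique-filtered) read is extended 3'-ward to length `L` from its
#' 5' end and per-base coverage is scaled by `R_target / retained reads`,
#' the convention used for browser tracks normalized to a fixed library
#' size (default 20 million reads). Total signal mass after normalization
#' is `R_target * L` (up to clipping at position 0).
#'
#' @param reads Read `data.frame`; non-unique reads are discarded first.
#' @param L Extension length in bases (> 0), the presumed fragment length.
#' @param R_target Normalization target in reads; default 2e7.
#' @return A `coverage_track`: data.frame `chrom`, `start`, `end`, `value`
#'   (bedGraph intervals, values rounded to 4 decimals) with attributes
#'   `R_target`, `L`, `n_reads`, `weight`.
#' @export
make_track <- function(reads, L, R_target = 2e7) {
  if (L <= 0) stop("extension length L must be > 0", call. = FALSE)
  validate_reads(reads)
  reads <- reads[reads$unique, , drop = FALSE]
  if (nrow(reads) == 0L) stop("zero retained reads", call. = FALSE)
  w <- R_target / nrow(reads)
  p5 <- read_5prime(reads)
  ext_start <- ifelse(reads$strand == "+", p5, p5 - L + 1L)
  ext_start <- pmax(ext_start, 0L)
  ext_end <- ifelse(reads$strand == "+", p5 + L, p5 + 1L)
  rows <- lapply(unique(reads$chrom), function(ch) {
    sel <- reads$chrom == ch
    cov <- IRanges::coverage(IRanges::IRanges(start = ext_start[sel] + 1L,
                                              end = ext_end[sel]))
    run_end <- cumsum(S4Vectors::runLength(cov))
    run_start <- run_end - S4Vectors::runLength(cov)
    val <- S4Vectors::runValue(cov) * w
    keep <- val > 0
    data.frame(chrom = ch, start = run_start[keep], end = run_end[keep],
               value = round(val[keep], 4))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, R_target = R_target, L = L, n_reads = nrow(reads),
            weight = w, class = c("coverage_track", "data.frame"))
}

#' Write a track (or any chrom/start/end/value table) as bedGraph
#'
#' @param track A `coverage_track` or data.frame with columns `chrom`,
#'   `start`, `end`, `value`.
#' @param path Output path.
#' @param name Track name for the bedGraph header line.
#' @export
write_bedgraph <- function(track, path, name = "track") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("track type=bedGraph name=\"%s\"", name), con)
  utils::write.table(track[, c("chrom", "start", "end", "value")], con,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
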