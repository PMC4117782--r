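#' In-silico restriction digestion
#'
#' Tools to find recognition-site cut positions in DNA sequences and to build
#' the restriction-fragment library that 4C read counting operates on. All
#' coordinates are 0-based half-open (BED convention); a fragment library
#' tiles each chromosome exactly: per chromosome the fragments are sorted,
#' non-overlapping, adjacent fragments share a boundary, and they cover
#' `[0, chromosome length)`.
#'
#' @name restriction-map
NULL

#' Find top-strand cut positions of an enzyme in a sequence
#'
#' Scans `sequence` for every occurrence of the enzyme's recognition site
#' (overlapping occurrences included) and returns the sorted, de-duplicated
#' top-strand cut coordinates, i.e. match start + cut offset, 0-based.
#' Ambiguous bases (`N`) never match.
#'
#' @param sequence A character string or [Biostrings::DNAString] to scan.
#' @param enzyme An [enzyme()] object or built-in enzyme name.
#' @return Sorted integer vector of 0-based cut coordinates.
#' @examples
#' find_cut_positions("AAGAATTCAA", "EcoRI")  # 3
#' @export
find_cut_positions <- function(sequence, enzyme) {
  enz <- as_enzyme(enzyme)
  if (is.character(sequence)) {
    if (length(sequence) != 1L || nchar(sequence) == 0L) {
      stop("sequence must be a single non-empty DNA string", call. = FALSE)
    }
    sequence <- Biostrings::DNAString(sequence)
  }
  if (length(sequence) == 0L) stop("sequence is empty", call. = FALSE)
  m <- Biostrings::matchPattern(enz$site, sequence, fixed = TRUE)
  cuts <- BiocGenerics::start(m) - 1L + enz$cut_offset
  sort(unique(as.integer(cuts)))
}

#' Digest a genome into a restriction-fragment library
#'
#' Cuts every sequence at the enzyme's top-strand cut positions and returns
#' the intervals between consecutive cuts (plus the chromosome ends) as an
#' ordered fragment library. Cut coordinates falling on a chromosome
#' boundary, and duplicate cut coordinates from overlapping site
#' occurrences, are merged so no zero-length fragment is produced.
#'
#' @param genome A named character vector of sequences, a named
#'   [Biostrings::DNAStringSet], or a path to a (multi-record, line-wrapped)
#'   FASTA file.
#' @param enzyme An [enzyme()] or built-in enzyme name. This is the primary
#'   digestion enzyme; read counting uses this library.
#' @param secondary Optional secondary digestion enzyme (an [enzyme()] or
#'   name), recorded as library metadata only.
#' @return A `fragment_library`: a `data.frame` with columns `chrom`,
#'   `start`, `end`, `fragment_id` and attributes `chrom_sizes` (named
#'   integer vector), `enzyme` and `secondary_enzyme` (names).
#' @examples
#' lib <- digest(c(chrA = "AAGAATTCAAAAGAATTCAA"), "EcoRI")
#' lib
#' @export
digest <- function(genome, enzyme, secondary = NULL) {
  enz <- as_enzyme(enzyme)
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
  }
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  if (length(genome) == 0L) stop("empty genome", call. = FALSE)
  nms <- names(genome)
  if (is.null(nms) || anyDuplicated(nms) || any(nms == "")) {
    stop("genome sequences must be uniquely named", call. = FALSE)
  }
  lens <- Biostrings::width(genome)
  per_chrom <- lapply(seq_along(genome), function(i) {
    len <- lens[[i]]
    cuts <- find_cut_positions(genome[[i]], enz)
    cuts <- cuts[cuts > 0L & cuts < len]
    bounds <- c(0L, cuts, len)
    data.frame(chrom = nms[[i]],
               start = bounds[-length(bounds)],
               end = bounds[-1L],
               stringsAsFactors = FALSE)
  })
  frags <- do.call(rbind, per_chrom)
  frags$fragment_id <- sprintf("FRAG_%05d", seq_len(nrow(frags)))
  chrom_sizes <- stats::setNames(as.integer(lens), nms)
  new_fragment_library(frags, chrom_sizes, enzyme = enz$name,
                       secondary = if (!is.null(secondary)) as_enzyme(secondary)$name)
}

new_fragment_library <- function(frags, chrom_sizes, enzyme = NA_character_,
                                 secondary = NULL) {
  rownames(frags) <- NULL
  lib <- structure(frags,
                   chrom_sizes = chrom_sizes,
                   enzyme = enzyme,
                   secondary_enzyme = secondary %||% NA_character_,
                   class = c("fragment_library", "data.frame"))
  validate_library(lib)
  lib
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate the tiling invariant of a fragment library
#'
#' Checks that per chromosome the fragments are sorted, non-overlapping,
#' share boundaries with their neighbours and tile `[0, chromosome length)`
#' exactly, and that fragment ids are unique.
#'
#' @param library A `fragment_library`.
#' @return The library, invisibly; errors if any invariant is violated.
#' @export
validate_library <- function(library) {
  stopifnot(is.data.frame(library))
  need <- c("chrom", "start", "end", "fragment_id")
  if (!all(need %in% names(library))) {
    stop("fragment library must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(library$start >= library$end)) {
    stop("fragment with start >= end", call. = FALSE)
  }
  if (anyDuplicated(library$fragment_id)) {
    stop("fragment_id values must be unique", call. = FALSE)
  }
  sizes <- attr(library, "chrom_sizes")
  for (ch in unique(library$chrom)) {
    f <- library[library$chrom == ch, , drop = FALSE]
    f <- f[order(f$start), , drop = FALSE]
    if (f$start[1L] != 0L) stop("chromosome ", ch, " does not start at 0",
                                call. = FALSE)
    if (nrow(f) > 1L && any(f$start[-1L] != f$end[-nrow(f)])) {
      stop("gap or overlap between fragments on ", ch, call. = FALSE)
    }
    if (!is.null(sizes) && !is.na(sizes[ch]) &&
        f$end[nrow(f)] != sizes[[ch]]) {
      stop("fragments on ", ch, " do not reach the chromosome end",
           call. = FALSE)
    }
  }
  invisible(library)
}

#' @export
print.fragment_library <- function(x, ...) {
  cat("<fragment_library> ", nrow(x), " fragments on ",
      length(unique(x$chrom)), " sequence(s); enzyme ",
      attr(x, "enzyme"), "\n", sep = "")
  NextMethod()
}

#' Write / read a fragment library as BED4
#'
#' The library is serialized as BED (`chrom`, `start`, `end`,
#' `fragment_id`), tab-separated, no header. Reading re-sorts fragments by
#' chromosome and start and re-validates the tiling invariant; chromosome
#' sizes are recovered from the rightmost fragment end.
#'
#' @param library A `fragment_library`.
#' @param path File path.
#' @param enzyme Enzyme name to record on the loaded library (metadata
#'   only).
#' @return `write_library` returns `path` invisibly; `read_library` returns
#'   a `fragment_library`.
#' @export
write_library <- function(library, path) {
  validate_library(library)
  utils::write.table(library[, c("chrom", "start", "end", "fragment_id")],
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_library
#' @export
read_library <- function(path, enzyme = NA_character_) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty BED file: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 4L) {
      stop("malformed BED line ", i, " in ", path, ": expected 4 fields",
           call. = FALSE)
    }
    if (is.na(suppressWarnings(as.integer(f[2L]))) ||
        is.na(suppressWarnings(as.integer(f[3L])))) {
      stop("malformed BED line ", i, " in ", path,
           ": non-integer coordinates", call. = FALSE)
    }
    if (as.integer(f[2L]) >= as.integer(f[3L])) {
      stop("malformed BED line ", i, " in ", path, ": start >= end",
           call. = FALSE)
    }
  }
  frags <- data.frame(
    chrom = vapply(fields, `[`, "", 1L),
    start = as.integer(vapply(fields, `[`, "", 2L)),
    end = as.integer(vapply(fields, `[`, "", 3L)),
    fragment_id = vapply(fields, `[`, "", 4L),
    stringsAsFactors = FALSE
  )
  frags <- frags[order(match(frags$chrom, unique(frags$chrom)), frags$start), ,
                 drop = FALSE]
  sizes <- vapply(split(frags$end, frags$chrom), max, 0L)
  new_fragment_library(frags, sizes[unique(frags$chrom)], enzyme = enzyme)
}
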