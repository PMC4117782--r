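#' 3D DNA-FISH co-localization analysis
#'
#' Paired FISH signal centers are physical coordinates in micrometres
#' (confocal stacks are converted with the xy pixel size and the z step
#' between optical sections, 0.3 um by default). A pair of loci is
#' scored as co-localized (interacting) when the 3D center-to-center
#' distance is strictly below the threshold, 1 um by default.
#'
#' @name fish-coloc
NULL

#' Euclidean center-to-center distance in 3D
#'
#' @param a,b Numeric length-3 vectors `(x, y, z)` in micrometres.
#' @return Distance in micrometres.
#' @examples
#' pair_distance(c(0, 0, 0), c(0.6, 0.8, 0))  # 1
#' @export
pair_distance <- function(a, b) {
  stopifnot(length(a) == 3L, length(b) == 3L, all(is.finite(c(a, b))))
  sqrt(sum((a - b)^2))
}

#' Convert pixel/slice coordinates to micrometres
#'
#' @param px,py Pixel coordinates.
#' @param slice Optical-section index (1-based).
#' @param xy_size Pixel size in um.
#' @param z_step Spacing between optical sections in um; default 0.3.
#' @return A length-3 numeric `(x, y, z)` in um.
#' @export
voxel_to_um <- function(px, py, slice, xy_size, z_step = 0.3) {
  stopifnot(xy_size > 0, z_step > 0)
  c(px * xy_size, py * xy_size, (slice - 1) * z_step)
}

#' Classify a pair distance as co-localized
#'
#' Strict inequality: a distance exactly at the threshold is not
#' co-localized.
#'
#' @param distance Distance(s) in um.
#' @param threshold Co-localization threshold in um; default 1.0.
#' @return Logical vector.
#' @export
classify_pair <- function(distance, threshold = 1.0) {
  stopifnot(all(distance >= 0), threshold > 0)
  distance < threshold
}

#' Read a FISH pair table
#'
#' Tab-separated with header columns `cell_id`, `genotype`, `x1`, `y1`,
#' `z1`, `x2`, `y2`, `z2` (um).
#'
#' @param path File path.
#' @return The pair `data.frame`.
#' @export
read_fish_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("cell_id", "genotype", "x1", "y1", "z1", "x2", "y2", "z2")
  if (!all(need %in% names(df))) {
    stop("FISH table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' Derive distances and co-localization states for a pair table
#'
#' @param pairs A FISH pair `data.frame` (see [read_fish_table()]).
#' @param threshold Co-localization threshold in um.
#' @return The table with `distance` and `colocalized` columns added.
#' @export
fish_distances <- function(pairs, threshold = 1.0) {
  pairs$distance <- sqrt((pairs$x1 - pairs$x2)^2 +
                           (pairs$y1 - pairs$y2)^2 +
                           (pairs$z1 - pairs$z2)^2)
  pairs$colocalized <- classify_pair(pairs$distance, threshold)
  pairs
}

#' Per-genotype co-localization frequency with a two-sided comparison
#'
#' Frequency is co-localized pairs over total pairs per genotype. With
#' exactly two genotypes the frequencies are compared by Fisher's exact
#' test on the 2x2 table (chi-square available via `test = "chisq"`); the
#' assay asks whether genotypes differ in how often the two loci sit
#' within the interaction distance.
#'
#' @param pairs A FISH pair table; `distance`/`colocalized` are derived
#'   with `threshold` if absent.
#' @param threshold Co-localization threshold in um.
#' @param test `"fisher"` (default) or `"chisq"` for the two-genotype
#'   comparison.
#' @return A list: `summary` (data.frame `genotype`, `n`, `colocalized`,
#'   `frequency`) and, for two genotypes, `p` and `test`.
#' @export
coloc_frequency <- function(pairs, threshold = 1.0,
                            test = c("fisher", "chisq")) {
  test <- match.arg(test)
  if (is.null(pairs$colocalized)) pairs <- fish_distances(pairs, threshold)
  if (any(table(pairs$genotype) == 0L) || nrow(pairs) == 0L) {
    stop("empty genotype group", call. = FALSE)
  }
  groups <- split(pairs$colocalized, pairs$genotype)
  smry <- data.frame(
    genotype = names(groups),
    n = vapply(groups, length, 1L),
    colocalized = vapply(groups, sum, 1L),
    stringsAsFactors = FALSE
  )
  smry$frequency <- smry$colocalized / smry$n
  rownames(smry) <- NULL
  out <- list(summary = smry)
  if (nrow(smry) == 2L) {
    tab <- cbind(smry$colocalized, smry$n - smry$colocalized)
    out$p <- if (test == "fisher") {
      stats::fisher.test(tab)$p.value
    } else {
      stats::chisq.test(tab, correct = FALSE)$p.value
    }
    out$test <- test
  }
  out
}
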