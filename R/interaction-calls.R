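#' Calling, classifying and intersecting strong interactions
#'
#' Strongly positive interactions are defined as the top decile of
#' interacting sites: fragments with at least one read (bait zone
#' excluded) ranked by expected log2-proportion. Calls are labelled cis or
#' trans relative to the bait chromosome, intersected across biological
#' replicates to retain reproducible contacts, summarized by distance to
#' the bait, and optionally aggregated into fixed-width genomic bins.
#'
#' @name interaction-calls
NULL

#' Bait specification
#'
#' @param name Bait label (e.g. the regulatory element the viewpoint
#'   primer sits in).
#' @param chrom,start,end Coordinates of the bait restriction fragment
#'   (0-based half-open); must correspond to a library fragment.
#' @param fragment_id Optional fragment id; filled in by [locate_bait()].
#' @return A `bait_spec` list.
#' @export
bait_spec <- function(name, chrom, start, end, fragment_id = NA_character_) {
  stopifnot(start < end)
  structure(list(name = name, chrom = chrom, start = as.integer(start),
                 end = as.integer(end), fragment_id = fragment_id),
            class = "bait_spec")
}

#' Resolve a bait against a fragment library
#'
#' @param library A `fragment_library`.
#' @param bait A `bait_spec`, or a fragment id.
#' @return A `bait_spec` with `fragment_id` set; errors if the bait does
#'   not match a library fragment.
#' @export
locate_bait <- function(library, bait) {
  if (is.character(bait)) {
    f <- library[library$fragment_id == bait, , drop = FALSE]
    if (nrow(f) != 1L) stop("bait fragment '", bait, "' not in library",
                            call. = FALSE)
    return(bait_spec(bait, f$chrom, f$start, f$end, fragment_id = bait))
  }
  f <- library[library$chrom == bait$chrom & library$start == bait$start &
                 library$end == bait$end, , drop = FALSE]
  if (nrow(f) != 1L) {
    stop("bait does not correspond to a library fragment", call. = FALSE)
  }
  bait$fragment_id <- f$fragment_id
  bait
}

#' Call strongly positive interactions (top decile of interacting sites)
#'
#' The universe is the set of interacting sites: unmasked fragments with
#' `count >= 1`. Exactly `floor(q * |universe|)` fragments with the
#' highest expected log2-proportion are called; ties at the boundary are
#' broken by higher count, then lower genomic coordinate, so calls are
#' stable across runs.
#'
#' @param estimates An `interaction_estimates` data.frame (scaled or not).
#' @param q Threshold quantile in (0, 1); default 0.10.
#' @param replicate_id Label stored on the call set.
#' @return A `call_set` data.frame (subset of the estimate rows, ranked)
#'   with attributes `q`, `universe_size`, `replicate_id`.
#' @export
call_strong <- function(estimates, q = 0.10, replicate_id = NULL) {
  if (q <= 0 || q >= 1) stop("q must be in (0, 1)", call. = FALSE)
  uni <- estimates[estimates$interacting, , drop = FALSE]
  n_call <- floor(q * nrow(uni))
  if (nrow(uni) == 0L) {
    warning("empty universe: no interacting sites to call")
  }
  ord <- order(-uni$elog2p, -uni$count,
               match(uni$chrom, unique(estimates$chrom)), uni$start)
  calls <- uni[ord[seq_len(n_call)], , drop = FALSE]
  rownames(calls) <- NULL
  structure(calls, q = q, universe_size = nrow(uni),
            replicate_id = replicate_id,
            class = c("call_set", "data.frame"))
}

#' Label calls cis or trans relative to the bait
#'
#' A call is `cis` when it lies on the bait chromosome, `trans` otherwise.
#'
#' @param callset A `call_set`.
#' @param bait A `bait_spec`.
#' @return The call set with a `label` column.
#' @export
classify_cis_trans <- function(callset, bait) {
  callset$label <- ifelse(callset$chrom == bait$chrom, "cis", "trans")
  callset
}

#' Intersect replicate call sets into the reproducible common set
#'
#' By default the intersection is by fragment identity (all replicates
#' share one fragment library). With `tolerance > 0` a proximity mode is
#' used instead: a fragment belongs to the common set when every replicate
#' has a call whose genomic gap to it is at most `tolerance`; membership is
#' then reported against the union of calls. Identity mode is symmetric,
#' associative and idempotent, and the common set is a subset of every
#' input call set.
#'
#' @param callsets A list of two or more `call_set` objects.
#' @param tolerance Bases; 0 (default) selects identity mode.
#' @return A `common_set` data.frame: the rows of the first call set (or
#'   of the union, in proximity mode) that are common to all replicates,
#'   with a `label` count summary in attribute `label_counts` when labels
#'   are present.
#' @export
intersect_replicates <- function(callsets, tolerance = 0) {
  stopifnot(is.list(callsets), length(callsets) >= 2L)
  if (tolerance == 0) {
    ids <- Reduce(intersect, lapply(callsets, function(cs) cs$fragment_id))
    out <- callsets[[1L]][callsets[[1L]]$fragment_id %in% ids, , drop = FALSE]
  } else {
    pool <- unique(do.call(rbind, lapply(callsets, function(cs) {
      as.data.frame(cs)[, intersect(names(cs), c("fragment_id", "chrom",
                                                 "start", "end", "count",
                                                 "elog2p", "label"))]
    })))
    pool <- pool[!duplicated(pool$fragment_id), , drop = FALSE]
    near_all <- vapply(seq_len(nrow(pool)), function(i) {
      all(vapply(callsets, function(cs) {
        same <- cs$chrom == pool$chrom[i]
        if (!any(same)) return(FALSE)
        gap <- pmax(0L, pmax(cs$start[same] - pool$end[i],
                             pool$start[i] - cs$end[same]))
        any(gap <= tolerance)
      }, logical(1)))
    }, logical(1))
    out <- pool[near_all, , drop = FALSE]
  }
  rownames(out) <- NULL
  lab <- if (!is.null(out$label)) table(out$label)
  structure(out, n_replicates = length(callsets), tolerance = tolerance,
            label_counts = lab, class = c("common_set", "data.frame"))
}

#' Stratify cis calls by distance to the bait
#'
#' Distance is the genomic gap between the call fragment and the bait
#' fragment (0 when they touch or overlap). Strata follow the usual
#' viewpoint-profile summary: within 50 kb, within 1 Mb, beyond 1 Mb.
#'
#' @param calls A `call_set` or `common_set` (labelled or not).
#' @param bait A `bait_spec`.
#' @param breaks Named upper stratum bounds in bases.
#' @return A data.frame with `stratum`, `n`; counts sum to the number of
#'   cis calls.
#' @export
distance_summary <- function(calls, bait,
                             breaks = c(`50kb` = 5e4, `1Mb` = 1e6)) {
  cis <- calls[calls$chrom == bait$chrom, , drop = FALSE]
  gap <- pmax(0L, pmax(cis$start - bait$end, bait$start - cis$end))
  edges <- c(sort(breaks), Inf)
  labs <- c(paste0("<=", names(sort(breaks))),
            paste0(">", names(which.max(breaks))))
  idx <- vapply(gap, function(g) which(g <= edges)[1L], 1L)
  data.frame(stratum = labs,
             n = as.integer(table(factor(labs[idx], levels = labs))))
}

#' Aggregate fragment counts into fixed-width genomic bins
#'
#' Each fragment's count is added to the bin containing its midpoint
#' (half-open bins, so a midpoint exactly on a boundary goes to the
#' right-hand bin); expected log2-proportions are then re-estimated on the
#' binned counts with the same Dirichlet model.
#'
#' @param counts A `fragment_counts` object.
#' @param W Bin width in bases; default 1 Mb.
#' @param gamma,M,seed Passed to [posterior_log2_proportions()] for the
#'   per-bin estimates.
#' @return A `bin_profile` data.frame: `chrom`, `start`, `end`, `count`,
#'   `elog2p`. Bins tile each chromosome; bin counts sum to the fragment
#'   counts.
#' @export
bin_profile <- function(counts, W = 1e6, gamma = 0.5, M = 128L, seed = 1L) {
  stopifnot(W >= 1)
  lib <- counts$library
  sizes <- attr(lib, "chrom_sizes")
  bins <- do.call(rbind, lapply(names(sizes), function(ch) {
    starts <- seq(0, sizes[[ch]] - 1, by = W)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + W, sizes[[ch]]))
  }))
  mid <- (lib$start + lib$end) %/% 2L
  key <- paste(lib$chrom, mid %/% as.integer(W))
  bins$key <- paste(bins$chrom, bins$start %/% as.integer(W))
  agg <- tapply(as.numeric(counts$counts[lib$fragment_id]), key, sum)
  bins$count <- as.integer(ifelse(is.na(agg[bins$key]), 0L, agg[bins$key]))
  bins$key <- NULL
  est <- posterior_log2_proportions(
    stats::setNames(bins$count, sprintf("BIN_%05d", seq_len(nrow(bins)))),
    gamma = gamma, M = M, seed = seed)
  bins$elog2p <- est$elog2p
  rownames(bins) <- NULL
  structure(bins, W = W, class = c("bin_profile", "data.frame"))
}

#' Write a call set or common set as BED
#'
#' BED5: chrom, start, end, name = fragment_id, score = `linear_scaled`
#' when present (else 0).
#'
#' @param calls A `call_set` or `common_set`.
#' @param path Output path.
#' @export
write_calls <- function(calls, path) {
  score <- calls$linear_scaled %||% rep(0L, nrow(calls))
  out <- data.frame(calls$chrom, calls$start, calls$end,
                    calls$fragment_id, score)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
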