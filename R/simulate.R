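#' Seeded synthetic data with the statistical structure of each assay
#'
#' Generators for (a) genomes with Poisson-placed restriction sites, (b)
#' 4C read tables with a power-law cis distance decay around the bait,
#' planted strong contacts, uniform trans background, an inflated
#' self-ligation bait fragment and Dirichlet-multinomial between-replicate
#' overdispersion, (c) qPCR Ct tables under exponential amplification with
#' configurable primer efficiency and Gaussian Ct noise, and (d) paired 3D
#' FISH centers with genotype-dependent co-localization rates. Every
#' generator is bit-reproducible given its seed, and each one records the
#' planted truth so that simulate-then-analyze round trips can assert
#' parameter recovery.
#'
#' @name synthetic-data
NULL

#' Simulate a genome with Poisson-placed restriction sites
#'
#' Background bases are uniform random; recognition sites are planted at
#' Poisson-distributed positions with the requested per-base density, and
#' chance occurrences of the site arising from the random background are
#' mutated away, so the recorded site positions are exactly the sites
#' present.
#'
#' @param lengths Named integer vector of chromosome lengths.
#' @param site_density Expected recognition sites per base; default
#'   1/4096, the genome-average density of a 6-cutter.
#' @param enzyme An [enzyme()] or name; default EcoRI.
#' @param seed Integer seed.
#' @return A list: `genome` (named [Biostrings::DNAStringSet]) and
#'   `sites` (list of 0-based site start positions per chromosome).
#' @export
simulate_genome <- function(lengths, site_density = 1 / 4096,
                            enzyme = "EcoRI", seed = 1L) {
  stopifnot(length(lengths) >= 1L, all(lengths > 0),
            !is.null(names(lengths)), site_density >= 0)
  enz <- as_enzyme(enzyme)
  site <- strsplit(enz$site, "")[[1L]]
  w <- length(site)
  set.seed(as.integer(seed))
  bases <- c("A", "C", "G", "T")
  out_seqs <- character(length(lengths))
  out_sites <- vector("list", length(lengths))
  names(out_sites) <- names(lengths)
  for (i in seq_along(lengths)) {
    len <- lengths[[i]]
    x <- sample(bases, len, replace = TRUE)
    n_sites <- stats::rpois(1L, site_density * max(0L, len - w))
    pos <- sort(sample.int(max(1L, len - w), n_sites))
    if (length(pos) > 1L) pos <- pos[c(TRUE, diff(pos) >= w)]  # no overlaps
    planted <- pos - 1L                  # 0-based site starts
    for (p in planted) x[(p + 1L):(p + w)] <- site
    x <- .scrub_chance_sites(x, site, planted)
    out_seqs[i] <- paste(x, collapse = "")
    out_sites[[i]] <- planted
  }
  genome <- Biostrings::DNAStringSet(out_seqs)
  names(genome) <- names(lengths)
  list(genome = genome, sites = out_sites)
}

# Mutate away chance occurrences of the recognition site so that only the
# planted sites remain; mutations never touch a base inside a planted site.
.scrub_chance_sites <- function(x, site, planted) {
  w <- length(site)
  in_planted <- rep(FALSE, length(x))
  for (p in planted) in_planted[(p + 1L):(p + w)] <- TRUE
  flip <- c(A = "C", C = "G", G = "T", T = "A")
  for (iter in 1:50) {
    m <- Biostrings::matchPattern(paste(site, collapse = ""),
                                  Biostrings::DNAString(paste(x, collapse = "")))
    starts0 <- BiocGenerics::start(m) - 1L
    chance <- setdiff(starts0, planted)
    if (length(chance) == 0L) return(x)
    for (s in chance) {
      span <- (s + 1L):(s + w)
      free <- span[!in_planted[span]]
      if (length(free) == 0L) next  # fully inside planted sites; keep
      x[free[1L]] <- flip[[x[free[1L]]]]
    }
  }
  x
}

#' Planted-contact truth for a synthetic 4C experiment
#'
#' Defines the expected per-fragment contact weight around a bait: cis
#' fragments decay as `(1 + d/d0)^-alpha` with genomic gap `d` to the bait
#' fragment, trans fragments sit at a uniform background weight, the bait
#' fragment itself carries an inflated self-ligation weight, and a chosen
#' set of cis and trans fragments is enriched by a multiplier — the
#' planted strong contacts the pipeline should recover. Setting
#' `alpha = 0`, `trans_weight = 1` and `bait_weight = 1` gives a uniform
#' null with no contact structure.
#'
#' @param library A `fragment_library`.
#' @param bait Bait fragment id.
#' @param n_cis,n_trans Numbers of planted cis / trans strong contacts.
#' @param multiplier Enrichment of planted contacts over their local
#'   baseline (> 1); default 20.
#' @param alpha Cis distance-decay exponent; default 1.
#' @param d0 Cis decay scale in bases; default 10 kb.
#' @param trans_weight Uniform trans background weight; default 0.01.
#' @param bait_weight Self-ligation weight of the bait fragment; default
#'   50 (the self-ligation product dominates a real 4C library).
#' @param phi Dirichlet-multinomial overdispersion; a fragment with weight
#'   `w` receives Gamma shape `w / phi`, so smaller `phi` means tighter
#'   replicate agreement. Default 0.01.
#' @param min_cis_gap Planted cis contacts are drawn at least this far
#'   from the bait (distal contacts, outside the masked bait zone);
#'   default 100 kb.
#' @param seed Seed for choosing the planted fragments.
#' @return A `contact_truth` list: `bait`, `planted` (data.frame
#'   `fragment_id`, `label`, `multiplier`), `weights` (named per-fragment
#'   expected weights) and the parameters.
#' @export
contact_truth <- function(library, bait, n_cis = 30L, n_trans = 20L,
                          multiplier = 20, alpha = 1, d0 = 1e4,
                          trans_weight = 0.01, bait_weight = 50,
                          phi = 0.01, min_cis_gap = 1e5, seed = 1L) {
  stopifnot(alpha >= 0, multiplier > 1 || (n_cis + n_trans) == 0,
            trans_weight >= 0, phi > 0, d0 > 0)
  b <- library[library$fragment_id == bait, , drop = FALSE]
  if (nrow(b) != 1L) stop("bait fragment '", bait, "' not in library",
                          call. = FALSE)
  cis <- library$chrom == b$chrom
  gap <- rep(NA_real_, nrow(library))
  gap[cis] <- pmax(0, pmax(library$start[cis] - b$end,
                           b$start - library$end[cis]))
  w <- ifelse(cis, (1 + gap / d0)^(-alpha), trans_weight)
  w[library$fragment_id == bait] <- bait_weight
  names(w) <- library$fragment_id

  set.seed(as.integer(seed))
  cis_pool <- library$fragment_id[cis & gap >= min_cis_gap &
                                    library$fragment_id != bait]
  trans_pool <- library$fragment_id[!cis]
  if (length(cis_pool) < n_cis || length(trans_pool) < n_trans) {
    stop("library too small for the requested planted contacts",
         call. = FALSE)
  }
  planted <- data.frame(
    fragment_id = c(sample(cis_pool, n_cis), sample(trans_pool, n_trans)),
    label = rep(c("cis", "trans"), c(n_cis, n_trans)),
    multiplier = rep(multiplier, length.out = n_cis + n_trans),
    stringsAsFactors = FALSE
  )
  w[planted$fragment_id] <- w[planted$fragment_id] * planted$multiplier
  structure(list(bait = bait, planted = planted, weights = w,
                 alpha = alpha, d0 = d0, trans_weight = trans_weight,
                 bait_weight = bait_weight, phi = phi,
                 multiplier = multiplier, min_cis_gap = min_cis_gap),
            class = "contact_truth")
}

#' Simulate 4C replicate read tables around a planted truth
#'
#' Per replicate a Dirichlet-multinomial draw around the truth weights
#' produces per-fragment read counts (Gamma shape `w_i / phi`, normalized,
#' then multinomial with `n_reads`); reads are placed uniformly within
#' their fragment with random strand. A configurable fraction of
#' additional multi-mapping reads (`unique = FALSE`) is appended to
#' exercise the unique-read filter.
#'
#' @param truth A `contact_truth`.
#' @param library The `fragment_library` the truth was built on.
#' @param n_reads Unique reads per replicate; default 1e5.
#' @param n_reps Number of replicates; default 2.
#' @param read_len Read length in bases (clipped to the fragment).
#' @param multi_frac Fraction of extra non-unique reads; default 0.05.
#' @param seed Integer seed.
#' @return A list of `n_reps` read `data.frame`s (columns `chrom`,
#'   `start`, `end`, `strand`, `unique`), with the per-replicate true
#'   counts in attribute `true_counts`.
#' @export
simulate_4c_replicates <- function(truth, library, n_reads = 1e5,
                                   n_reps = 2L, read_len = 50L,
                                   multi_frac = 0.05, seed = 1L) {
  stopifnot(inherits(truth, "contact_truth"), n_reads >= 1, n_reps >= 1)
  w <- truth$weights[library$fragment_id]
  set.seed(as.integer(seed))
  lapply(seq_len(n_reps), function(r) {
    g <- stats::rgamma(length(w), shape = w / truth$phi)
    cnt <- as.integer(stats::rmultinom(1L, n_reads, g / sum(g)))
    idx <- rep.int(seq_along(cnt), cnt)
    flen <- library$end[idx] - library$start[idx]
    rl <- pmin(read_len, flen)
    start <- library$start[idx] +
      floor(stats::runif(length(idx)) * (flen - rl + 1))
    reads <- data.frame(
      chrom = library$chrom[idx],
      start = as.integer(start),
      end = as.integer(start + rl),
      strand = sample(c("+", "-"), length(idx), replace = TRUE),
      unique = TRUE,
      stringsAsFactors = FALSE
    )
    n_multi <- round(multi_frac * n_reads)
    if (n_multi > 0L) {
      j <- sample.int(nrow(library), n_multi, replace = TRUE)
      mlen <- pmin(read_len, library$end[j] - library$start[j])
      mstart <- library$start[j] +
        floor(stats::runif(n_multi) * (library$end[j] - library$start[j] -
                                         mlen + 1))
      reads <- rbind(reads, data.frame(
        chrom = library$chrom[j], start = as.integer(mstart),
        end = as.integer(mstart + mlen),
        strand = sample(c("+", "-"), n_multi, replace = TRUE),
        unique = FALSE, stringsAsFactors = FALSE))
    }
    reads <- reads[sample.int(nrow(reads)), , drop = FALSE]
    rownames(reads) <- NULL
    structure(reads,
              true_counts = stats::setNames(cnt, library$fragment_id))
  })
}

#' Simulate a qPCR Ct table from true template quantities
#'
#' `Ct = -log_E(quantity) + N(0, noise_sd)`; at zero noise the Ct-based
#' quantification formulas invert the simulation exactly.
#'
#' @param quantities A data.frame with columns `target`, `condition`,
#'   `quantity` (> 0).
#' @param efficiency Amplification factor per cycle (scalar or named by
#'   target); default 2.
#' @param noise_sd Gaussian Ct noise standard deviation; default 0.
#' @param n_replicates Replicates per (target, condition); default 3.
#' @param seed Integer seed.
#' @return A Ct `data.frame` (`target`, `condition`, `replicate`, `Ct`).
#' @export
simulate_ct_table <- function(quantities, efficiency = 2, noise_sd = 0,
                              n_replicates = 3L, seed = 1L) {
  stopifnot(all(quantities$quantity > 0), noise_sd >= 0, n_replicates >= 1)
  set.seed(as.integer(seed))
  eff_of <- function(tgt) {
    if (length(efficiency) == 1L && is.null(names(efficiency))) {
      efficiency
    } else {
      efficiency[[tgt]]
    }
  }
  rows <- lapply(seq_len(nrow(quantities)), function(i) {
    q <- quantities[i, ]
    ct0 <- -log(q$quantity) / log(eff_of(q$target))
    data.frame(target = q$target, condition = q$condition,
               replicate = seq_len(n_replicates),
               Ct = ct0 + stats::rnorm(n_replicates, 0, noise_sd),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate paired 3D FISH signal centers
#'
#' Per genotype, `round(frequency * n_cells)` pairs are drawn co-localized
#' (distance uniform on `(0, threshold)`) and the rest separated (uniform
#' on `(threshold, 5 * threshold)`), so the realized frequency matches the
#' request exactly by construction. The first center is uniform in a
#' nuclear volume and the second is placed at the drawn distance in a
#' random direction.
#'
#' @param freq_by_genotype Named numeric vector of co-localization
#'   frequencies in `[0, 1]`.
#' @param n_cells Cells per genotype (scalar or named).
#' @param threshold Co-localization threshold in um; default 1.
#' @param seed Integer seed.
#' @return A FISH pair `data.frame` (`cell_id`, `genotype`, `x1` ... `z2`).
#' @export
simulate_fish <- function(freq_by_genotype, n_cells = 100L, threshold = 1,
                          seed = 1L) {
  stopifnot(all(freq_by_genotype >= 0), all(freq_by_genotype <= 1),
            threshold > 0)
  set.seed(as.integer(seed))
  if (length(n_cells) == 1L) {
    n_cells <- stats::setNames(rep(n_cells, length(freq_by_genotype)),
                               names(freq_by_genotype))
  }
  rows <- lapply(names(freq_by_genotype), function(g) {
    n <- n_cells[[g]]
    k <- round(freq_by_genotype[[g]] * n)
    d <- c(stats::runif(k, 0, threshold),
           stats::runif(n - k, threshold, 5 * threshold))
    c1 <- matrix(stats::runif(3L * n, 0, 10), ncol = 3L)
    u <- matrix(stats::rnorm(3L * n), ncol = 3L)
    u <- u / sqrt(rowSums(u^2))
    c2 <- c1 + d * u
    data.frame(cell_id = paste0(g, "_", seq_len(n)), genotype = g,
               x1 = c1[, 1], y1 = c1[, 2], z1 = c1[, 3],
               x2 = c2[, 1], y2 = c2[, 2], z2 = c2[, 3],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
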