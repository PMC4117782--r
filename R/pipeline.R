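#' End-to-end 4C analysis runs from a single config
#'
#' [run_pipeline()] chains simulate -> digest -> count -> estimate ->
#' call -> intersect -> report with one seed controlling every stochastic
#' stage, writes every stage output under a run directory and finishes
#' with a manifest (parameters, seeds, package version, per-file MD5
#' checksums), so a rerun with the same config is bit-identical and a run
#' directory documents the analysis on its own.
#'
#' @name pipeline
NULL

#' Default run configuration
#'
#' A complete demo configuration: a four-chromosome synthetic genome
#' (1 Mb bait chromosome plus three 0.45 Mb trans chromosomes at
#' six-cutter site density), a bait fragment at the middle of the first
#' chromosome, 30 cis + 20 trans planted contacts at 20x their local
#' background, two replicates of 1e5 unique reads, a 100 kb masked bait
#' zone, and the estimator/calling defaults (gamma 0.5, M 128, scale 1e6,
#' top decile).
#'
#' @param seed Master seed; every stage seed is derived from it.
#' @return A named list understood by [run_pipeline()].
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    genome = list(lengths = c(chr1 = 1000000L, chr2 = 450000L,
                              chr3 = 450000L, chr4 = 450000L),
                  site_density = 1 / 4096),
    enzyme = "EcoRI",
    secondary_enzyme = "MseI",
    bait = NULL,            # fragment id; NULL = fragment at mid-chr1
    truth = list(n_cis = 30L, n_trans = 20L, multiplier = 20,
                 alpha = 1, d0 = 1e4, trans_weight = 0.01,
                 bait_weight = 50, phi = 0.01, min_cis_gap = 1e5),
    n_reads = 100000L,
    n_reps = 2L,
    mask_radius = 1e5,
    gamma = 0.5,
    M = 128L,
    S = 1e6,
    q = 0.10,
    bin_width = 1e6
  )
}

#' Read a run configuration from a YAML file
#'
#' Plain-markup configs only (no code-valued options); missing keys fall
#' back to [default_config()].
#'
#' @param path YAML file path.
#' @return A config list.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_config(cfg$seed %||% 1L)
  for (k in names(cfg)) {
    if (is.list(cfg[[k]]) && is.list(base[[k]])) {
      for (kk in names(cfg[[k]])) base[[k]][[kk]] <- cfg[[k]][[kk]]
    } else {
      base[[k]] <- cfg[[k]]
    }
  }
  if (!is.null(base$genome$lengths)) {
    base$genome$lengths <- unlist(base$genome$lengths)
  }
  base
}

#' Run the full synthetic 4C analysis pipeline
#'
#' Stages: simulate genome, digest, simulate replicate reads, count,
#' mask the bait zone, estimate log2-proportions, scale to browser
#' values, call the top decile, label cis/trans, intersect replicates,
#' stratify distances, bin the profile, write the manifest. Any stage
#' failure aborts with the stage name and cause.
#'
#' @param config A config list (see [default_config()]) or a YAML path.
#' @param out_dir Run directory; created if missing.
#' @return Invisibly, a list with the in-memory stage results (`library`,
#'   `counts`, `estimates`, `callsets`, `common`, `strata`, `bins`,
#'   `truth`, `manifest`).
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempfile("run")) {
  if (is.character(config)) config <- read_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  path <- function(...) file.path(out_dir, ...)
  log_line <- function(...) message("[loopcall4c] ", ...)

  log_line("simulate genome (seed ", seed + 1L, ")")
  sim <- stage("simulate_genome",
               simulate_genome(config$genome$lengths,
                               config$genome$site_density,
                               config$enzyme, seed = seed + 1L))
  Biostrings::writeXStringSet(sim$genome, path("genome.fa"))

  log_line("digest with ", config$enzyme)
  library <- stage("digest",
                   digest(sim$genome, config$enzyme,
                          secondary = config$secondary_enzyme))
  write_library(library, path("fragments.bed"))

  bait_id <- config$bait
  if (is.null(bait_id)) {
    ch1 <- names(config$genome$lengths)[1L]
    mid <- config$genome$lengths[[1L]] %/% 2L
    sel <- library$chrom == ch1 & library$start <= mid & library$end > mid
    bait_id <- library$fragment_id[sel]
  }
  bait <- locate_bait(library, bait_id)
  log_line("bait fragment ", bait_id, " (", bait$chrom, ":", bait$start,
           "-", bait$end, ")")

  tr <- config$truth
  truth <- stage("contact_truth",
                 contact_truth(library, bait_id, n_cis = tr$n_cis,
                               n_trans = tr$n_trans,
                               multiplier = tr$multiplier,
                               alpha = tr$alpha, d0 = tr$d0,
                               trans_weight = tr$trans_weight,
                               bait_weight = tr$bait_weight, phi = tr$phi,
                               min_cis_gap = tr$min_cis_gap,
                               seed = seed + 2L))
  log_line("simulate ", config$n_reps, " replicates x ", config$n_reads,
           " reads (seed ", seed + 3L, ")")
  replicates <- stage("simulate_4c_replicates",
                      simulate_4c_replicates(truth, library,
                                             n_reads = config$n_reads,
                                             n_reps = config$n_reps,
                                             seed = seed + 3L))

  callsets <- vector("list", config$n_reps)
  counts_list <- vector("list", config$n_reps)
  estimates_list <- vector("list", config$n_reps)
  for (r in seq_len(config$n_reps)) {
    rep_id <- paste0("rep", r)
    write_read_table(replicates[[r]], path(paste0("reads_", rep_id, ".tsv")))
    log_line(rep_id, ": count, mask ", config$mask_radius, " b, estimate")
    cnt <- stage("assign_reads",
                 assign_reads(replicates[[r]], library, replicate_id = rep_id))
    cnt <- stage("exclude_bait_zone",
                 exclude_bait_zone(cnt, bait_id, radius = config$mask_radius))
    write_counts(cnt, path(paste0("counts_", rep_id, ".tsv")))
    est <- stage("posterior_log2_proportions",
                 posterior_log2_proportions(cnt, gamma = config$gamma,
                                            M = config$M,
                                            seed = seed + 10L + r))
    est <- scale_linear(est, S = config$S)
    write_estimates(est, path(paste0("estimates_", rep_id, ".tsv")),
                    bedgraph = path(paste0("track_", rep_id, ".bedGraph")))
    calls <- stage("call_strong",
                   call_strong(est, q = config$q, replicate_id = rep_id))
    calls <- classify_cis_trans(calls, bait)
    write_calls(calls, path(paste0("calls_", rep_id, ".bed")))
    counts_list[[r]] <- cnt
    estimates_list[[r]] <- est
    callsets[[r]] <- calls
    log_line(rep_id, ": |universe| = ", attr(calls, "universe_size"),
             ", |calls| = ", nrow(calls))
  }

  common <- stage("intersect_replicates", intersect_replicates(callsets))
  write_calls(common, path("common.bed"))
  strata <- distance_summary(common, bait)
  utils::write.table(strata, path("distance_strata.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  log_line("common set: ", nrow(common), " fragments (",
           sum(common$label == "cis"), " cis / ",
           sum(common$label == "trans"), " trans)")

  bins <- stage("bin_profile",
                bin_profile(counts_list[[1L]], W = config$bin_width,
                            gamma = config$gamma, M = config$M,
                            seed = seed + 20L))
  utils::write.table(as.data.frame(bins), path("bins_rep1.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  files <- sort(list.files(out_dir, full.names = FALSE))
  files <- setdiff(files, "manifest.json")
  manifest <- list(
    package = "loopcall4c",
    version = as.character(utils::packageVersion("loopcall4c")),
    config = config,
    bait = bait_id,
    universe_sizes = vapply(callsets, attr, 0L, "universe_size"),
    files = lapply(stats::setNames(files, files), function(f) {
      list(md5 = unname(tools::md5sum(file.path(out_dir, f))))
    })
  )
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  invisible(list(library = library, bait = bait, truth = truth,
                 counts = counts_list, estimates = estimates_list,
                 callsets = callsets, common = common, strata = strata,
                 bins = bins, manifest = manifest, out_dir = out_dir))
}
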