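#' Ct-based quantification for 3C, digestion QC and nucleosome occupancy
#'
#' All quantities derive from the exponential-amplification relation
#' `quantity proportional to E^-Ct`, where `E` is the per-cycle
#' amplification factor of the primer pair (2 for perfect doubling).
#' Primer efficiencies come from dilution standard curves; 3C interaction
#' frequencies are efficiency-corrected and normalized to a
#' ligation-independent reference amplicon; restriction-digestion QC and
#' allele-specific nucleosome occupancy use the delta(-delta) Ct method.
#' Group comparisons are two-tailed t-tests on fold changes, matching the
#' small litter-matched designs these assays are run on.
#'
#' @name qpcr-quant
NULL

#' Read a Ct table
#'
#' Tab-separated with header columns `target`, `condition`, `replicate`,
#' `Ct` (finite, > 0).
#'
#' @param path File path.
#' @return The Ct `data.frame`.
#' @export
read_ct_table <- function(path) {
  ct <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("target", "condition", "replicate", "Ct")
  if (!all(need %in% names(ct))) {
    stop("Ct table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(ct$Ct))) stop("non-finite Ct value", call. = FALSE)
  ct
}

#' Primer efficiency from a dilution standard curve
#'
#' Fits Ct against log10 input by least squares; the amplification factor
#' per cycle is `E = 10^(-1/slope)` (slope -3.3219 gives E = 2, perfect
#' doubling). Also reports the largest Ct spread among replicates at equal
#' input and flags curves whose spread exceeds 2 Ct, the usual primer
#' optimization bound.
#'
#' @param log10_input Numeric vector of log10 template amounts (>= 3
#'   distinct dilution points).
#' @param ct Matching Ct values.
#' @param target Amplicon name for the report.
#' @return A `primer_efficiency` list: `target`, `efficiency`, `slope`,
#'   `r_squared`, `max_spread`, `within_2ct`.
#' @examples
#' eff <- efficiency_from_standard(c(0, -1, -2), c(20, 23.3219, 26.6439))
#' eff$efficiency  # 2.0
#' @export
efficiency_from_standard <- function(log10_input, ct, target = "target") {
  stopifnot(length(log10_input) == length(ct))
  if (length(unique(log10_input)) < 3L) {
    stop("need at least 3 dilution points", call. = FALSE)
  }
  fit <- stats::lm(ct ~ log10_input)
  m <- unname(stats::coef(fit)[2L])
  if (!is.finite(m) || abs(m) < 1) {
    stop("standard-curve slope ", format(m),
         " is too shallow for exponential amplification", call. = FALSE)
  }
  spread <- max(vapply(split(ct, log10_input),
                       function(x) diff(range(x)), 0))
  ss_tot <- sum((ct - mean(ct))^2)
  r2 <- if (ss_tot == 0) NA_real_ else 1 - sum(stats::resid(fit)^2) / ss_tot
  structure(list(target = target,
                 efficiency = 10^(-1 / m),
                 slope = m,
                 r_squared = r2,
                 max_spread = spread,
                 within_2ct = spread <= 2),
            class = "primer_efficiency")
}

#' Restriction-digestion efficiency from Ct across a cut site
#'
#' Amplicons spanning a restriction site only amplify from intact
#' template, so the intact fraction after digestion is
#' `E^-(Ct_digested - Ct_undigested)` and percent digested is
#' `100 * (1 - intact)`. QC passes when every assayed site is at least 96%
#' digested.
#'
#' @param ct_digested,ct_undigested Ct vectors over the assayed sites.
#' @param efficiency Amplification factor(s) per cycle; default 2.
#' @param threshold QC threshold in percent; default 96.
#' @return A list: `percent` (per site), `qc_pass`.
#' @examples
#' digestion_efficiency(30, 25)$percent  # 96.875
#' @export
digestion_efficiency <- function(ct_digested, ct_undigested,
                                 efficiency = 2, threshold = 96) {
  stopifnot(length(ct_digested) == length(ct_undigested))
  if (any(efficiency <= 1)) stop("efficiency must be > 1", call. = FALSE)
  intact <- efficiency^(-(ct_digested - ct_undigested))
  pct <- 100 * (1 - intact)
  list(percent = pct, qc_pass = all(pct >= threshold))
}

#' Efficiency-corrected 3C relative interaction frequency
#'
#' `frequency = E_target^-Ct_target / E_reference^-Ct_reference`, the
#' ligation-product quantity relative to a ligation-independent reference
#' amplicon (a housekeeping locus such as XPB/ERCC3), each corrected to
#' its own primer efficiency. An optional per-primer correction factor
#' (from a random-ligation control template) divides the result.
#'
#' @param ct_target,ct_reference Ct values (vectors are averaged after
#'   transforming to quantities, i.e. replicate frequencies are averaged).
#' @param e_target,e_reference Primer amplification factors; default 2.
#' @param bac_factor Optional per-primer random-ligation template
#'   correction divisor; default 1 (no correction).
#' @return Mean relative interaction frequency.
#' @examples
#' threec_frequency(25, 22)  # 2^-3 = 0.125
#' @export
threec_frequency <- function(ct_target, ct_reference, e_target = 2,
                             e_reference = 2, bac_factor = 1) {
  if (any(c(e_target, e_reference) <= 1)) {
    stop("efficiencies must be > 1", call. = FALSE)
  }
  freq <- (e_target^-ct_target) / (e_reference^-ct_reference) / bac_factor
  mean(freq)
}

#' Fold change with a two-tailed t-test
#'
#' `fold = mean(mutant) / mean(control)`; p-value from a two-sample
#' two-tailed Student t-test (pooled variance by default, Welch with
#' `welch = TRUE`). Zero-variance degenerate groups are handled
#' explicitly: identical groups give p = 1, separated constant groups give
#' p = 0.
#'
#' @param control,mutant Numeric vectors, each with >= 2 finite values.
#' @param welch Use the Welch unequal-variance test instead of pooled.
#' @return A list: `fold`, `sem_control`, `sem_mutant`, `t`, `df`, `p`.
#' @export
fold_change_test <- function(control, mutant, welch = FALSE) {
  if (length(control) < 2L || length(mutant) < 2L ||
      any(!is.finite(c(control, mutant)))) {
    stop("each group needs >= 2 finite values", call. = FALSE)
  }
  if (mean(control) == 0) stop("zero control mean", call. = FALSE)
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  fold <- mean(mutant) / mean(control)
  if (stats::sd(control) == 0 && stats::sd(mutant) == 0) {
    p <- if (mean(control) == mean(mutant)) 1 else 0
    t_stat <- if (p == 1) 0 else Inf * sign(mean(mutant) - mean(control))
    df <- length(control) + length(mutant) - 2L
  } else {
    tt <- stats::t.test(mutant, control, var.equal = !welch,
                        alternative = "two.sided")
    p <- tt$p.value
    t_stat <- unname(tt$statistic)
    df <- unname(tt$parameter)
  }
  list(fold = fold, sem_control = sem(control), sem_mutant = sem(mutant),
       t = t_stat, df = df, p = p)
}

#' Allele-specific nucleosome-occupancy fold change (delta-delta Ct)
#'
#' Per replicate and condition the target amplicon is normalized to the
#' arithmetic mean Ct of the reference genes (the geometric mean of their
#' quantities): `q = E^-(Ct_target - mean(Ct_refs))`. The occupancy fold
#' change is `mean(q_mutant) / mean(q_control)` per target; fold > 1 means
#' increased nuclease protection (higher nucleosome occupancy) in the
#' mutant. When both conditions have >= 2 replicates a two-tailed t-test
#' on the per-replicate quantities is reported.
#'
#' @param ct A Ct table (see [read_ct_table()]) holding target and
#'   reference amplicons for both conditions; replicates are matched by
#'   the `replicate` column.
#' @param targets Target amplicon names; default all non-reference
#'   targets.
#' @param references Reference gene amplicons; default `Gapdh` and
#'   `Actb`.
#' @param control,mutant Condition labels.
#' @param efficiency Amplification factor; default 2.
#' @return An `occupancy_profile` data.frame: `target`, `fold`, `sem`,
#'   `p`.
#' @export
occupancy_fold <- function(ct, targets = NULL,
                           references = c("Gapdh", "Actb"),
                           control = "control", mutant = "mutant",
                           efficiency = 2) {
  stopifnot(all(references %in% ct$target))
  targets <- targets %||% setdiff(unique(ct$target), references)
  norm_quantities <- function(cond, tgt) {
    sub <- ct[ct$condition == cond, , drop = FALSE]
    reps <- sort(unique(sub$replicate[sub$target == tgt]))
    vapply(reps, function(r) {
      ct_t <- sub$Ct[sub$target == tgt & sub$replicate == r]
      ct_r <- vapply(references, function(g) {
        mean(sub$Ct[sub$target == g & sub$replicate == r])
      }, 0)
      if (length(ct_t) == 0L || any(!is.finite(ct_r))) {
        stop("missing target or reference Ct for replicate ", r,
             call. = FALSE)
      }
      efficiency^(-(mean(ct_t) - mean(ct_r)))
    }, 0)
  }
  rows <- lapply(targets, function(tgt) {
    qc <- norm_quantities(control, tgt)
    qm <- norm_quantities(mutant, tgt)
    if (length(qc) >= 2L && length(qm) >= 2L) {
      ft <- fold_change_test(qc, qm)
      data.frame(target = tgt, fold = ft$fold, sem = ft$sem_mutant,
                 p = ft$p)
    } else {
      data.frame(target = tgt, fold = mean(qm) / mean(qc), sem = NA_real_,
                 p = NA_real_)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, references = references, efficiency = efficiency,
            class = c("occupancy_profile", "data.frame"))
}

#' Allele-specificity check for a methylation-dependent digestion assay
#'
#' A McrBC digestion removes the methylated (paternal) allele before
#' amplification; residual paternal template leaks into the signal in
#' proportion to the retention fraction. The post-digestion signal is
#' `maternal + retention * paternal` and maternal purity is
#' `maternal / (maternal + retention * paternal)`; assays below
#' `min_purity` are flagged as not allele-specific.
#'
#' @param maternal_signal,paternal_signal Template quantities per allele.
#' @param mcrbc_retention Fraction of the methylated allele surviving
#'   digestion, in `[0, 1]`.
#' @param min_purity Flagging threshold; default 0.9.
#' @return A list: `post_digestion_signal`, `purity`, `allele_specific`.
#' @examples
#' mcrbc_allele_check(1, 1, 0.04)$purity  # 1/1.04
#' @export
mcrbc_allele_check <- function(maternal_signal, paternal_signal,
                               mcrbc_retention, min_purity = 0.9) {
  stopifnot(maternal_signal >= 0, paternal_signal >= 0,
            mcrbc_retention >= 0, mcrbc_retention <= 1)
  post <- maternal_signal + mcrbc_retention * paternal_signal
  purity <- if (post == 0) NA_real_ else maternal_signal / post
  list(post_digestion_signal = post, purity = purity,
       allele_specific = isTRUE(purity >= min_purity))
}
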