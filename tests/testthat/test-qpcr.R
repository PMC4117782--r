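test_that("standard curves give the textbook efficiencies", {
  d <- c(0, -1, -2, -3)
  eff <- efficiency_from_standard(d, 20 + 3.321928 * -d)
  expect_equal(eff$efficiency, 2.0, tolerance = 1e-6)
  eff_half <- efficiency_from_standard(d, 20 + 6.643856 * -d)
  expect_equal(eff_half$efficiency, sqrt(2), tolerance = 1e-6)

  # perfect duplicates at each dilution: spread 0, passes the 2-Ct check
  dd <- rep(d, each = 2)
  e2 <- efficiency_from_standard(dd, 20 + 3.321928 * -dd)
  expect_equal(e2$max_spread, 0)
  expect_true(e2$within_2ct)

  # spread above 2 Ct is flagged but still fitted
  ct <- 20 + 3.321928 * -dd + rep(c(-1.5, 1.5), times = 4)
  expect_false(efficiency_from_standard(dd, ct)$within_2ct)

  expect_error(efficiency_from_standard(c(0, -1), c(20, 23)), "3 dilution")
  expect_error(efficiency_from_standard(d, c(20, 20.1, 20.2, 20.3)),
               "too shallow")
})

test_that("digestion efficiency follows the intact-fraction closed form", {
  r <- digestion_efficiency(30, 25)           # delta Ct = 5, E = 2
  expect_equal(r$percent, 100 * (1 - 2^-5))   # 96.875
  expect_true(r$qc_pass)
  expect_equal(digestion_efficiency(25, 25)$percent, 0)
  expect_false(digestion_efficiency(25, 25)$qc_pass)

  # pass set over a delta-Ct sweep equals the algebraic threshold log2(25)
  dct <- seq(3, 7, by = 0.1)
  pass <- vapply(dct, function(d) {
    digestion_efficiency(20 + d, 20)$qc_pass
  }, logical(1))
  expect_equal(pass, dct >= log2(25))
  # monotone increasing in delta Ct
  pct <- digestion_efficiency(20 + dct, rep(20, length(dct)))$percent
  expect_true(all(diff(pct) > 0))
  # multi-site QC: every site must reach the threshold
  expect_false(digestion_efficiency(c(30, 24), c(25, 20))$qc_pass)
})

test_that("3C frequencies are efficiency-corrected reference ratios", {
  expect_equal(threec_frequency(25, 25), 1)
  expect_equal(threec_frequency(25, 22), 0.125)
  # independent closed-form evaluation with unequal efficiencies
  expect_equal(threec_frequency(25, 22, e_target = 1.9, e_reference = 2.0),
               1.9^-25 / 2.0^-22, tolerance = 1e-12)
  # invariant to a shared Ct shift when efficiencies match
  expect_equal(threec_frequency(25 + 3, 22 + 3), threec_frequency(25, 22),
               tolerance = 1e-12)
  # replicate frequencies are averaged; BAC factor divides
  expect_equal(threec_frequency(c(25, 24), c(22, 22)),
               mean(c(2^-3, 2^-2)))
  expect_equal(threec_frequency(25, 22, bac_factor = 0.5), 0.25)
})

test_that("fold-change t-tests match the pooled-variance textbook formula", {
  ctl <- c(1.0, 1.2, 0.8)
  mut <- c(0.5, 0.6, 0.4)
  r <- fold_change_test(ctl, mut)
  # hand-computed pooled t statistic
  sp2 <- (2 * var(ctl) + 2 * var(mut)) / 4
  t_hand <- (mean(mut) - mean(ctl)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  expect_equal(r$t, t_hand, tolerance = 1e-12)
  expect_equal(r$p, 2 * pt(-abs(t_hand), df = 4), tolerance = 1e-12)
  expect_equal(r$fold, 0.5)
  expect_equal(r$sem_control, sd(ctl) / sqrt(3))

  # symmetry under group exchange; fold inverts
  rr <- fold_change_test(mut, ctl)
  expect_equal(rr$p, r$p)
  expect_equal(rr$fold, 1 / r$fold)

  # degenerate zero-variance groups
  sep <- fold_change_test(c(1, 1, 1), c(2, 2, 2))
  expect_equal(sep$fold, 2)
  expect_lt(sep$p, 1e-6)
  expect_equal(fold_change_test(c(1, 1), c(1, 1))$p, 1)

  # Welch option reproduces stats::t.test
  w <- fold_change_test(ctl, mut, welch = TRUE)
  expect_equal(w$p, t.test(mut, ctl)$p.value)

  expect_error(fold_change_test(c(0, 0, 0), c(1, 1, 1)), "zero control")
  expect_error(fold_change_test(1, c(1, 2)), ">= 2 finite")
})

test_that("occupancy folds reproduce a spreadsheet delta-delta-Ct", {
  ct <- expand.grid(target = c("siteB", "Gapdh", "Actb"),
                    condition = c("control", "mutant"),
                    replicate = 1:3, stringsAsFactors = FALSE)
  ct$Ct <- 25
  # all Cts equal: fold 1
  prof <- occupancy_fold(ct, targets = "siteB")
  expect_equal(prof$fold, 1)

  # target drops one cycle in the mutant, references unchanged: fold 2
  ct2 <- ct
  sel <- ct2$target == "siteB" & ct2$condition == "mutant"
  ct2$Ct[sel] <- 24
  expect_equal(occupancy_fold(ct2, targets = "siteB")$fold, 2)

  # full seeded table against a brute-force spreadsheet computation
  set.seed(33)
  ct3 <- ct
  ct3$Ct <- round(25 + rnorm(nrow(ct3), 0, 1), 3)
  prof3 <- occupancy_fold(ct3, targets = "siteB")
  sheet <- sapply(c("control", "mutant"), function(cond) {
    mean(sapply(1:3, function(r) {
      tgt <- ct3$Ct[ct3$target == "siteB" & ct3$condition == cond &
                      ct3$replicate == r]
      ref <- mean(c(ct3$Ct[ct3$target == "Gapdh" & ct3$condition == cond &
                             ct3$replicate == r],
                    ct3$Ct[ct3$target == "Actb" & ct3$condition == cond &
                             ct3$replicate == r]))
      2^-(tgt - ref)
    }))
  })
  expect_equal(prof3$fold, unname(sheet["mutant"] / sheet["control"]),
               tolerance = 1e-12)
})

test_that("McrBC leak-through determines maternal purity", {
  expect_equal(mcrbc_allele_check(1, 1, 0)$purity, 1)
  r <- mcrbc_allele_check(1, 1, 0.04)
  expect_equal(r$purity, 1 / 1.04, tolerance = 1e-12)
  expect_true(r$allele_specific)
  bad <- mcrbc_allele_check(1, 1, 1)
  expect_equal(bad$purity, 0.5)
  expect_false(bad$allele_specific)
})
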