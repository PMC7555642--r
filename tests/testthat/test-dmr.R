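## DMR caller: chaining, region testing, end-to-end contracts.

## parameters that skip the site-call machinery's subtleties in unit tests:
## deeply methylated sites against error 0.004 are always called
unit_params <- function(...) dmr_params(error_rate = 0.004, ...)

test_that("qualifying sites chain by the gap rule and length bounds", {
  ## 6 sites 100 bp apart, all strongly methylated in A -> one candidate
  p <- dmr_pair(pos = seq(0L, 500L, by = 100L), meth_a = 10L, meth_b = 0L)
  cand <- candidate_regions(p$a, p$b, "CHH", unit_params())
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$start, 0L)
  expect_equal(cand$end, 501L)
  expect_equal(cand$n_sites, 6L)

  ## a 250-bp gap after the third site splits the chain; 3-site chains fail
  ## the five-methylated-cytosines rule
  p2 <- dmr_pair(pos = c(0L, 100L, 200L, 450L, 550L, 650L),
                 meth_a = 10L, meth_b = 0L)
  expect_equal(nrow(candidate_regions(p2$a, p2$b, "CHH", unit_params())), 0L)

  ## two qualifying sites 30 bp apart: chain span 31 < 40 -> dropped even
  ## with relaxed counts
  p3 <- dmr_pair(pos = c(0L, 30L), meth_a = 10L, meth_b = 0L)
  expect_equal(nrow(candidate_regions(p3$a, p3$b, "CHH",
                                      unit_params(min_mC_per_region = 2L))), 0L)

  ## below min_cov in one sample disqualifies the position but the chain
  ## survives while the remaining gaps stay under 200 bp
  p4 <- dmr_pair(pos = seq(0L, 540L, by = 90L), meth_a = 10L, meth_b = 0L)
  p4$b[pos == 180L, total := 3L]
  cand4 <- candidate_regions(p4$a, p4$b, "CHH", unit_params())
  expect_equal(cand4$n_sites, 6L)
  ## ... and when removing the site opens a >= 200 bp gap the chain splits
  p5 <- dmr_pair(pos = seq(0L, 500L, by = 100L), meth_a = 10L, meth_b = 0L)
  p5$b[pos == 200L, total := 3L]
  expect_equal(nrow(candidate_regions(p5$a, p5$b, "CHH", unit_params())), 0L)
})

test_that("over-long chains split at the largest internal gap", {
  ## 120 sites every 100 bp (span ~12 kb) with one 199-bp gap in the middle:
  ## must split into pieces of <= 10 kb at the largest gap
  pos <- c(seq(0L, 5900L, by = 100L), seq(6099L, 12099L, by = 100L))
  p <- dmr_pair(pos = pos, meth_a = 9L, meth_b = 1L, total = 10L)
  cand <- candidate_regions(p$a, p$b, "CHH", unit_params())
  expect_equal(nrow(cand), 2L)
  expect_true(all(cand$end - cand$start <= 10000L))
  expect_equal(cand$end[1], 5901L)
  expect_equal(cand$start[2], 6099L)
})

test_that("region testing applies the closed-form chi-square and fold rule", {
  ## 6 sites, A 9/10 each, B 3/10 each: table [[54,6],[18,42]]
  p <- dmr_pair(pos = seq(0L, 500L, by = 100L), meth_a = 9L, meth_b = 3L)
  cand <- candidate_regions(p$a, p$b, "CHH", unit_params())
  tst <- test_regions(cand, unit_params())
  expect_equal(tst$chi2, 45)
  expect_equal(tst$fold_change, 3)
  expect_equal(tst$direction, "hyper")

  ## fold below two is rejected by call_dmrs regardless of p
  p2 <- dmr_pair(pos = seq(0L, 500L, by = 100L), meth_a = 80L, meth_b = 50L,
                 total = 100L)
  d2 <- suppressMessages(call_dmrs(p2$a, p2$b, unit_params(), contexts = "CHH"))
  expect_equal(nrow(d2), 0L)
  t2 <- test_regions(candidate_regions(p2$a, p2$b, "CHH", unit_params()),
                     unit_params())
  expect_lt(t2$pval, 0.05)          # significant ...
  expect_lt(t2$fold_change, 2)      # ... but under the fold gate

  ## equal counts: chi-square 0, p 1
  p3 <- dmr_pair(pos = seq(0L, 500L, by = 100L), meth_a = 8L, meth_b = 8L)
  t3 <- test_regions(candidate_regions(p3$a, p3$b, "CHH", unit_params()),
                     unit_params())
  expect_equal(t3$chi2, 0)
  expect_equal(t3$pval, 1)

  ## zero level in one sample: pseudocount keeps the fold finite
  p4 <- dmr_pair(pos = seq(0L, 500L, by = 100L), meth_a = 10L, meth_b = 0L)
  t4 <- test_regions(candidate_regions(p4$a, p4$b, "CHH", unit_params()),
                     unit_params())
  expect_true(is.finite(t4$fold_change))
  expect_gt(t4$fold_change, 2)
})

test_that("identical samples yield no DMRs and A/B swap flips directions", {
  p <- dmr_pair(pos = seq(0L, 900L, by = 60L), meth_a = 9L, meth_b = 3L)
  expect_equal(nrow(suppressMessages(
    call_dmrs(p$a, p$a, unit_params(), contexts = "CHH"))), 0L)

  d_ab <- suppressMessages(call_dmrs(p$a, p$b, unit_params(), contexts = "CHH"))
  d_ba <- suppressMessages(call_dmrs(p$b, p$a, unit_params(), contexts = "CHH"))
  expect_equal(d_ab[, .(chrom, start, end, n_sites, pval)],
               d_ba[, .(chrom, start, end, n_sites, pval)])
  expect_equal(d_ab$direction, "hyper")
  expect_equal(d_ba$direction, "hypo")
})

test_that("tightening thresholds never adds a DMR (monotonicity)", {
  set.seed(30)
  pos <- sort(sample(0:20000, 300))
  a <- cyt("chr1", pos, "+", "CHH", meth = rbinom(300, 20, 0.4), total = 20L)
  b <- cyt("chr1", pos, "+", "CHH", meth = rbinom(300, 20, 0.15), total = 20L)
  base <- suppressMessages(call_dmrs(a, b, unit_params(), contexts = "CHH"))
  tight_fold <- suppressMessages(
    call_dmrs(a, b, unit_params(min_fold = 3), contexts = "CHH"))
  tight_p <- suppressMessages(
    call_dmrs(a, b, unit_params(p_cut = 0.001), contexts = "CHH"))
  key <- function(d) paste(d$chrom, d$start, d$end)
  expect_true(all(key(tight_fold) %in% key(base)))
  expect_true(all(key(tight_p) %in% key(base)))
})

test_that("every called DMR passes the independent six-criterion audit", {
  set.seed(31)
  pos <- sort(sample(0:30000, 500))
  lv <- ifelse(pos %/% 3000 %% 2 == 0, 0.5, 0.05)  # alternating blocks
  a <- cyt("chr1", pos, "+", "CHH", meth = rbinom(500, 25, lv), total = 25L)
  b <- cyt("chr1", pos, "+", "CHH", meth = rbinom(500, 25, 0.05), total = 25L)
  d <- suppressMessages(call_dmrs(a, b, unit_params(), contexts = "CHH"))
  expect_gt(nrow(d), 0)
  expect_true(all(suppressMessages(audit_dmrs(d, a, b, unit_params()))))
  ## reported levels are consistent with direction
  expect_true(all((d$level_a >= d$level_b) == (d$direction == "hyper")))
})
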