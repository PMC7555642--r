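## Metagene profiles, expression groups, quintiles, correlation.

test_that("uniform methylome gives a flat profile in every bin", {
  cy <- uniform_cytosines(len = 20000L, by = 7L, level = 0.5)
  ft <- data.table::data.table(id = "g1", chrom = "chr1", start = 8000L,
                               end = 8400L, strand = "+")
  pr <- feature_profile(cy, ft, context = "CG")
  expect_equal(nrow(pr), 60L)  # 20 + 20 + 20 bins
  expect_equal(pr[!is.na(level), unique(level)], 0.5)
  expect_equal(attr(pr, "n_features"), 1L)
})

test_that("minus-strand features are flipped so bin 0 is 5'", {
  ## hypermethylate the plus-coordinate RIGHT flank; for a minus-strand
  ## feature that region is 5' and must appear in the upstream bins
  base <- uniform_cytosines(len = 20000L, by = 11L, level = 0.2)
  right <- base$pos >= 8400
  base[right, meth := as.integer(round(0.9 * total))]
  ft <- data.table::data.table(id = "g1", chrom = "chr1", start = 8000L,
                               end = 8400L, strand = "-")
  pr <- feature_profile(base, ft, context = "CG")
  up <- pr[bin_class == "upstream" & !is.na(level), level]
  dn <- pr[bin_class == "downstream" & !is.na(level), level]
  expect_true(all(up > 0.8))
  expect_true(all(dn < 0.3))
  ## and the upstream bins run 5' -> TSS: bin 0 is the far end
  expect_equal(pr[bin_class == "upstream" & bin_idx == 0, level], 0.9,
               tolerance = 0.01)
})

test_that("profiles are invariant to feature order and chromosome renaming", {
  set.seed(20)
  cy <- uniform_cytosines(len = 30000L, by = 13L, level = 0.4)
  cy[, meth := as.integer(pmin(total, rbinom(.N, total, 0.4)))]
  ft <- data.table::data.table(id = c("a", "b"), chrom = "chr1",
                               start = c(9000L, 21000L), end = c(9800L, 22400L),
                               strand = c("+", "-"))
  p1 <- feature_profile(cy, ft, "CG")
  p2 <- feature_profile(cy, ft[2:1], "CG")
  expect_equal(p1, p2, ignore_attr = TRUE)
  cy2 <- data.table::copy(cy)[, chrom := "renamed"]
  ft2 <- data.table::copy(ft)[, chrom := "renamed"]
  p3 <- feature_profile(cy2, ft2, "CG")
  expect_equal(p1$level, p3$level)
})

test_that("region windows are strand-aware and missing when uncovered", {
  cy <- uniform_cytosines(len = 20000L, by = 9L, level = 0.5)
  rl_plus <- region_levels(cy, data.table::data.table(
    id = "g1", chrom = "chr1", start = 5000L, end = 6000L, strand = "+"))
  ## promoter of a plus gene at [5000,6000) is [3000,5000): check by blanking it
  cy_gap <- cy[pos < 3000 | pos >= 5000]
  rl_gap <- region_levels(cy_gap, data.table::data.table(
    id = "g1", chrom = "chr1", start = 5000L, end = 6000L, strand = "+"))
  expect_equal(rl_plus[region == "promoter" & context == "CG", level], 0.5)
  expect_true(is.na(rl_gap[region == "promoter" & context == "CG", level]))

  ## minus gene: promoter is [6000,8000)
  cy_gap2 <- cy[pos < 6000 | pos >= 8000]
  rl_m <- region_levels(cy_gap2, data.table::data.table(
    id = "g1", chrom = "chr1", start = 5000L, end = 6000L, strand = "-"))
  expect_true(is.na(rl_m[region == "promoter" & context == "CG", level]))
  expect_equal(rl_m[region == "body" & context == "CG", level], 0.5)
})

test_that("expression groups partition genes as none plus ascending quarters", {
  ft <- data.table::data.table(gene_id = paste0("g", 1:5),
                               fpkm = c(0.05, 1, 10, 100, 1000))
  eg <- expression_groups(ft)
  expect_equal(eg[gene_id == "g1", group], "none")
  expect_equal(eg[order(fpkm), group], c("none", "Q1", "Q2", "Q3", "Q4"))

  allnone <- expression_groups(data.table::data.table(
    gene_id = c("a", "b"), fpkm = c(0.01, 0.09)))
  expect_true(all(allnone$group == "none"))

  eight <- expression_groups(data.table::data.table(
    gene_id = sprintf("g%02d", 1:8), fpkm = 2^(1:8)))
  expect_equal(as.vector(table(eight$group)[paste0("Q", 1:4)]), rep(2L, 4))
})

test_that("methylation quintiles partition genes with an unmethylated class", {
  cy <- call_methylated_sites(
    uniform_cytosines(len = 150000L, by = 9L, level = 0.5), 0.004)
  ## 10 genes with increasing body methylation, one fully unmethylated
  genes <- data.table::data.table(id = sprintf("g%02d", 1:11), chrom = "chr1",
                                  start = seq(2000L, 142000L, by = 14000L),
                                  end = seq(4000L, 144000L, by = 14000L),
                                  strand = "+")
  for (i in 1:11) {
    lev <- if (i == 11) 0 else i / 20
    cy[pos >= genes$start[i] & pos < genes$end[i],
       meth := as.integer(round(lev * total))]
  }
  cy <- call_methylated_sites(cy[, -"methylated"], 0.004)
  rl <- region_levels(cy, genes)
  mq <- methylation_quintiles(rl, "body", "CG")
  expect_equal(sort(mq$gene_id), sort(genes$id))  # partition property
  expect_equal(mq[gene_id == "g11", group], "unmethylated")
  expect_equal(as.vector(table(mq$group)[paste0("Q", 1:5)]), rep(2L, 5))
  ## ascending: Q1 holds the lowest-methylation genes
  expect_setequal(mq[group == "Q1", gene_id], c("g01", "g02"))
  expect_setequal(mq[group == "Q5", gene_id], c("g09", "g10"))
})

test_that("methylation-expression correlation degenerate cases", {
  rl <- data.table::data.table(gene_id = paste0("g", 1:5), region = "promoter",
                               context = "CG", level = (1:5) / 10)
  fp <- data.table::data.table(gene_id = paste0("g", 1:5), fpkm = c(50, 20, 10, 5, 1))
  expect_equal(methylation_expression_correlation(rl, fp, "promoter", "CG"), -1)
  fp2 <- data.table::copy(fp)[, fpkm := rev(fpkm)]
  expect_equal(methylation_expression_correlation(rl, fp2, "promoter", "CG"), 1)
  expect_true(is.na(methylation_expression_correlation(rl[1:2], fp[1:2],
                                                       "promoter", "CG")))
})
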