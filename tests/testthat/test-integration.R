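## DMR-feature assignment, set operations, enrichment, DMG expression.

mk_dmrs <- function(chrom, start, end, context = "CG", direction = "hyper") {
  data.table::data.table(chrom = chrom, start = as.integer(start),
                         end = as.integer(end), context = context,
                         direction = direction)
}

test_that("DMR location classes follow overlap and precedence", {
  genes <- data.table::data.table(id = c("gA", "gB"), chrom = "chr1",
                                  start = c(500L, 12000L), end = c(2000L, 13000L),
                                  strand = c("+", "-"))
  tes <- data.table::data.table(id = "t1", chrom = "chr1", start = 6000L,
                                end = 7000L, strand = "+",
                                superfamily = "LTR/Gypsy")
  ann <- feature_annotation(genes, tes, c(chr1 = 30000L))
  d <- mk_dmrs("chr1",
               start = c(1000L, 13500L, 6100L, 20000L),
               end   = c(1200L, 13800L, 6400L, 20300L))
  res <- assign_dmrs(d, ann)
  expect_equal(res$locations$location_class,
               c("gene_body",      # inside gA body
                 "upstream_2kb",   # 5' flank of minus-strand gB is right of it
                 "te", "intergenic"))
  expect_equal(res$locations$feature_id[1:3], c("gA", "gB", "t1"))
  expect_true(is.na(res$locations$feature_id[4]))
  ## partition property: one class per DMR
  expect_equal(nrow(res$locations), nrow(d))
  ## DMG set: genes touched via body or flanks, with direction
  expect_setequal(res$dmg$gene_id, c("gA", "gB"))

  ## largest overlap wins: a DMR touching the gene's downstream flank by
  ## 100 bp but a distant TE by 200 bp is a TE DMR
  genes2 <- data.table::data.table(id = "g", chrom = "c", start = 0L,
                                   end = 1000L, strand = "+")
  tes2 <- data.table::data.table(id = "t", chrom = "c", start = 4000L,
                                 end = 5000L, strand = "+",
                                 superfamily = "DNA/MuDR")
  ann2 <- feature_annotation(genes2, tes2, c(c = 8000L))
  d2 <- mk_dmrs("c", 2900L, 4200L)  # 100 bp downstream flank, 200 bp te
  expect_equal(assign_dmrs(d2, ann2)$locations$location_class, "te")
  ## equal overlap: precedence puts gene_body ahead of its downstream flank
  d3 <- mk_dmrs("c", 900L, 1100L)   # 100 bp body, 100 bp downstream
  expect_equal(assign_dmrs(d3, ann2)$locations$location_class, "gene_body")
})

test_that("differentially methylated TE sets count overlaps per direction", {
  tes <- data.table::data.table(id = c("t1", "t2"), chrom = "chr1",
                                start = c(100L, 5000L), end = c(600L, 5600L),
                                strand = "+",
                                superfamily = c("LTR/Gypsy", "DNA/MuDR"))
  ann <- feature_annotation(
    data.table::data.table(id = character(), chrom = character(),
                           start = integer(), end = integer(),
                           strand = character()),
    tes, c(chr1 = 10000L))
  d <- mk_dmrs("chr1", c(150L, 200L), c(250L, 320L), context = "CHH",
               direction = c("hypo", "hyper"))
  r <- dm_te_sets(d, ann)
  expect_equal(r$sets[te_id == "t1", sort(direction)], c("hyper", "hypo"))
  expect_false("t2" %in% r$sets$te_id)
  expect_equal(r$summary[direction == "hypo" & te_class == "I", n], 1L)
})

test_that("venn decomposition is exact", {
  v <- venn_sets(list(A = c("a", "b", "c"), B = c("b", "c", "d")))
  expect_equal(v[signature == "A&B", n], 2L)
  expect_setequal(v[signature == "A&B", members][[1]], c("b", "c"))
  expect_equal(v[signature == "A", members][[1]], "a")
  v2 <- venn_sets(list(A = "x", B = "y"))
  expect_false("A&B" %in% v2$signature)
  v3 <- venn_sets(list(A = c("p", "q"), B = c("q", "p")))
  expect_equal(v3$signature, "A&B")
  expect_error(venn_sets(list(A = "x")), "two sets")
})

test_that("term enrichment matches the hypergeometric tail and drops aliens", {
  universe <- sprintf("g%02d", 1:20)
  study <- universe[1:5]
  tm <- data.table::data.table(
    term_id = rep(c("T1", "T2"), c(5, 6)),
    gene_id = c(universe[c(1:4, 10)],      # T1: k=4, K=5
                universe[11:16]))          # T2: k=0, K=6
  r <- term_enrichment(study, universe, tm)
  expect_equal(r[term_id == "T1", pval], 76 / choose(20, 5), tolerance = 1e-10)
  expect_equal(r[term_id == "T2", pval], 1)
  ## genes outside the universe are dropped from terms before testing
  tm2 <- rbind(tm, data.table::data.table(term_id = "T1", gene_id = "alien"))
  expect_equal(term_enrichment(study, universe, tm2), r)
  ## study == universe: every term has p 1
  r3 <- term_enrichment(universe, universe, tm)
  expect_true(all(r3$pval == 1))
  ## K floor removes unstable terms
  tm3 <- data.table::data.table(term_id = "tiny", gene_id = universe[1:2])
  expect_equal(nrow(term_enrichment(study, universe, tm3)), 0L)
  expect_error(term_enrichment(study, character(0), tm), "universe")
})

test_that("DMG x DEG overlap classes", {
  dmg <- data.table::data.table(gene_id = c("g1", "g2", "g3", "g4"),
                                context = "CG",
                                direction = c("hyper", "hyper", "hypo", "hypo"))
  degs <- data.table::data.table(
    gene_id = c("g2", "g3", "g5"), status = c("down", "up", "up"))
  ov <- dmg_deg_overlap(dmg, degs)
  expect_equal(ov$hyper_down, "g2")
  expect_equal(ov$hypo_up, "g3")
  expect_equal(length(ov$hyper_up), 0L)
  expect_equal(ov$counts$n, c(1L, 1L, 0L, 0L))
  empty <- dmg_deg_overlap(dmg, degs[0])
  expect_true(all(empty$counts$n == 0L))
})

test_that("DMG expression comparison is symmetric when the class is all genes", {
  fp <- data.table::data.table(gene_id = paste0("g", 1:6),
                               fpkm = c(1, 2, 4, 8, 16, 32))
  dmg <- data.table::data.table(gene_id = paste0("g", 1:6), context = "CG",
                                direction = "hypo")
  r <- dmg_expression_comparison(dmg, fp, "CG")
  expect_equal(r[class == "hypo", pval], 1)           # identical distributions
  expect_equal(r[class == "hypo", median], r[class == "all", median])
  expect_false("hyper" %in% r$class)                   # empty class omitted
})
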