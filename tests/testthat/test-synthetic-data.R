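## Synthetic-data generator: determinism, accounting, truth calibration.

small_cfg <- function(seed = 1L, ...) {
  preset <- list(seed = seed, n_chroms = 1L, chrom_len = 120000L,
                 n_genes = 10L, te_fraction = 0.3, lambda_len = 8000L)
  do.call(sim_config, utils::modifyList(preset, list(...)))
}

test_that("identical configs give byte-identical outputs", {
  cfg <- small_cfg()
  d1 <- tempfile(); d2 <- tempfile()
  simulate_experiment(cfg, out_dir = d1)
  simulate_experiment(cfg, out_dir = d2)
  for (f in c("genome.fa", "annotation.gff3", "HP.cytosines.tsv",
              "LP.cytosines.tsv", "counts.tsv", "sirna_HP.tsv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("genome accounting: TE fraction, gene count, lambda flag", {
  cfg <- small_cfg(seed = 3L)
  sg <- generate_genome(cfg)
  expect_equal(nrow(sg$annotation$genes), 10L)
  te_bp <- sg$annotation$tes[, sum(end - start)]
  expect_lt(abs(te_bp / 120000 - 0.3), 0.02)
  expect_equal(sg$genome$spike_in_chrom, "lambda")
  expect_equal(unname(chrom_lengths(sg$genome)["lambda"]), 8000L)
  ## packing failure is reported
  expect_error(generate_genome(small_cfg(te_fraction = 0.8, n_genes = 60L)),
               "infeasible packing")
})

test_that("generated files pass the package's own validation", {
  cfg <- small_cfg(seed = 4L)
  dir <- tempfile()
  simulate_experiment(cfg, out_dir = dir)
  g <- read_fasta(file.path(dir, "genome.fa"), spike_in_chrom = "lambda")
  cy <- read_cytosine_table(file.path(dir, "HP.cytosines.tsv"), genome = g)
  expect_gt(nrow(cy), 1000)
  ann <- read_annotation(file.path(dir, "annotation.gff3"), "gff3")
  expect_equal(nrow(ann$genes), 10L)
  expect_true(all(ann$tes$te_class %in% c("I", "II")))
})

test_that("site truth is calibrated to the base levels exactly", {
  cfg <- small_cfg(seed = 5L)
  sg <- generate_genome(cfg)
  tr <- site_truth(sg, cfg)
  nuc <- tr[chrom != "lambda"]
  for (ctx in c("CG", "CHG", "CHH")) {
    expect_equal(nuc[context == ctx, mean(level_hp)],
                 unname(cfg$base_levels[[ctx]]), tolerance = 1e-6)
  }
  ## LP truth is the HP truth shifted up (global hypermethylation)
  expect_true(nuc[context == "CG", mean(level_lp) > mean(level_hp)])
  expect_equal(tr[chrom == "lambda", unique(level_hp)], 0)
})

test_that("observed methylome recovers truth within binomial noise", {
  cfg <- small_cfg(seed = 6L)
  sg <- generate_genome(cfg)
  hp <- generate_methylome(sg, cfg, "HP")
  gl <- global_levels(hp$cytosines, exclude_chrom = "lambda")
  nuc <- hp$cytosines[chrom != "lambda"]
  for (ctx in c("CG", "CHG", "CHH")) {
    reads <- nuc[context == ctx, sum(total)]
    base <- unname(cfg$base_levels[[ctx]])
    expected_obs <- base * (1 - 2 * cfg$conversion_failure) + cfg$conversion_failure
    se <- sqrt(base * (1 - base) / reads)
    expect_lt(abs(gl[[paste0("level_", ctx)]] - expected_obs), 4 * se)
  }
  eff <- conversion_efficiency(hp$cytosines, "lambda")
  lam_reads <- hp$cytosines[chrom == "lambda", sum(total)]
  expect_lt(abs(eff - 100 * (1 - cfg$conversion_failure)),
            100 * 4 * sqrt(0.004 * 0.996 / lam_reads))
})

test_that("spiked DMRs are placed legally and recorded in the truth table", {
  cfg <- sim_config_dmr_benchmark(seed = 2L, n_chroms = 1L,
                                  n_genes = 30L, n_spiked_dmrs = 20L)
  sg <- generate_genome(cfg)
  tr <- site_truth(sg, cfg)
  lp <- generate_methylome(sg, cfg, "LP", truth = tr)
  sp <- spike_dmrs(lp, sg, cfg)
  td <- sp$truth_dmrs
  expect_equal(nrow(td), 20L)
  expect_equal(td[direction == "hyper", .N], 12L)  # 60% bias
  ## within chromosome bounds, non-overlapping
  cl <- chrom_lengths(sg$genome)
  expect_true(all(td$start >= 0 & td$end <= cl[td$chrom]))
  data.table::setorder(td, chrom, start)
  expect_true(all(diff(td$start) > 0))
  byc <- td[, all(start[-1] >= head(end, -1)), by = chrom]
  expect_true(all(byc$V1))
  ## LP counts inside a hyper spike reflect the raised level
  h1 <- td[direction == "hyper"][1]
  inside <- sp$cytosines[chrom == h1$chrom & pos >= h1$start & pos < h1$end &
                           context == "CHH"]
  expect_gt(inside[, sum(meth) / sum(total)], 0.25)
  ## requesting more spikes than the genome can host errors out
  cfg_big <- sim_config_dmr_benchmark(seed = 2L, n_chroms = 1L, n_genes = 30L,
                                      n_spiked_dmrs = 2000L)
  sg_big <- generate_genome(cfg_big)
  lp_big <- generate_methylome(sg_big, cfg_big, "LP")
  expect_error(spike_dmrs(lp_big, sg_big, cfg_big), "cannot place")
})

test_that("expression generator couples methylation and spikes DEGs", {
  cfg <- small_cfg(seed = 7L, n_genes = 400L, chrom_len = 3000000L,
                   te_fraction = 0.1, n_true_degs = 20L)
  sg <- generate_genome(cfg)
  hp <- generate_expression(sg, cfg, "HP")
  lp <- generate_expression(sg, cfg, "LP")
  expect_equal(dim(hp$counts), c(400L, 3L))
  expect_equal(hp$truth[deg_status != "none", .N], 20L)
  ## HP and LP share the truth table
  expect_equal(hp$truth, lp$truth)
  ## spiked up-genes have higher LP than HP expected counts
  up <- hp$truth[deg_status == "up", gene_id]
  expect_true(all(hp$truth[gene_id %in% up, mu_lp > mu_hp]))
  ## negative coupling between the methylation latent and expression
  expr <- hp$truth[silent == FALSE]
  expect_lt(spearman_rho(expr$z_m, expr$log2_expr), -0.1)
})

test_that("siRNA generator is 24-nt dominant and TE-coupled", {
  cfg <- small_cfg(seed = 8L)
  sg <- generate_genome(cfg)
  sir <- generate_sirna(sg, cfg, "HP")
  h <- length_distribution(sir$alignments)
  expect_equal(h[which.max(reads), length], 24L)
  ## reads concentrate near TE boundaries
  pr <- sirna_te_profile(filter_24nt(sir$alignments)$alignments,
                         sg$annotation$tes)
  body <- pr[bin_class == "body"]
  expect_gt(mean(body[bin_idx %in% c(0L, 19L), reads]),
            mean(body[bin_idx %in% 8:11, reads]))
})
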