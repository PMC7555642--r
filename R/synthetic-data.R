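## Deterministic synthetic-data generator with truth tables.
##
## The generator emulates the statistical structure of a paired low-P /
## high-P plant root methylome experiment: per-context genome methylation
## near 66.5% CG / 43.6% CHG / 3.7% CHH, TE hypermethylation, gene-body CG
## enrichment with dips at transcript boundaries, CHH methylation
## concentrated in TEs and discrete RdDM-like intergenic islands over a
## near-zero background, a small genome-wide LP hypermethylation shift,
## spiked DMRs with known coordinates, methylation-coupled expression with
## spiked DEGs, and 24-nt-dominant siRNA clusters at TE boundaries coupled
## to CHH methylation. Everything is a deterministic function of the
## config (including its seed).

## derive a reproducible sub-seed (< 2^31) from the master seed and a tag
.sim_seed <- function(seed, tag) {
  v <- utf8ToInt(tag)
  h <- sum(v * seq_along(v)) %% 1000003
  as.integer((as.numeric(seed) * 65537 + h * 97) %% 2147483629)
}

#' Synthetic experiment configuration
#'
#' Defaults are the study conditions the generator emulates; see the
#' vignette for the rationale behind each value.
#'
#' @param seed Master seed; fully determines every output.
#' @param n_chroms,chrom_len Number and length (bp) of nuclear chromosomes.
#' @param gc Genome GC fraction.
#' @param te_fraction Fraction of each chromosome covered by TEs.
#' @param te_len_range,n_genes,gene_len_range Feature geometry.
#' @param base_levels Genome-wide weighted methylation level per context
#'   the generator is calibrated to (CG, CHG, CHH).
#' @param te_level_boost Additive TE boost for CG and CHG.
#' @param gene_body_cg_boost Additive gene-body CG enrichment.
#' @param gene_body_non_cg_drop Multiplier (applied as `1 - drop`) on CHG
#'   and CHH levels inside gene bodies.
#' @param boundary_dip_width,boundary_dip_floor Linear methylation dip
#'   around TSS/TES: factor `floor` at the boundary rising to 1 at
#'   `width` bp.
#' @param meth_sd Per-gene lognormal SD of the promoter+body CG modifier
#'   (the methylation latent used for expression coupling).
#' @param chh_background Background CHH level outside TEs and islands; kept
#'   below the conversion failure rate so background cytosines are
#'   statistically indistinguishable from unmethylated space and
#'   methylated-site chains terminate there.
#' @param te_chh_level Mean CHH level of TE cytosines (before per-TE
#'   intensity and calibration).
#' @param island_level,island_len_range,island_density Intergenic CHH
#'   island geometry (density per bp of eligible intergenic space).
#' @param lp_shift Additive genome-wide LP hypermethylation per context.
#' @param te_chh_lp Apply a per-TE multiplicative LP reduction of TE CHH.
#' @param te_chh_lp_meanlog,te_chh_lp_sdlog Lognormal parameters of that
#'   per-TE LP factor (mean < 1: net CHH loss in TEs under LP).
#' @param n_spiked_dmrs,spike_delta,spike_direction_bias,spike_len_range
#'   Spiked DMR truth: count, absolute level shift, fraction hyper, and
#'   length range; spikes are CHH (hyper in clean intergenic background,
#'   hypo on islands).
#' @param coverage_mean,coverage_dispersion Negative-binomial read coverage.
#' @param conversion_failure Bisulfite conversion failure rate.
#' @param lambda_len Length of the unmethylated spike-in chromosome.
#' @param n_replicates RNA-seq replicates per condition.
#' @param silent_fraction Fraction of genes with near-zero expression.
#' @param silent_coupling Latent correlation between the methylation latent
#'   and the silencing indicator.
#' @param mean_log2_expr,sd_log2_expr Log2 expression distribution of
#'   expressed genes.
#' @param coupling_strength Target magnitude of the (negative) latent
#'   correlation between gene methylation and expression.
#' @param expr_dispersion NB dispersion of replicate counts.
#' @param mean_counts Target mean fragments per gene per replicate.
#' @param n_true_degs,deg_fold Spiked DEG truth (applied in LP).
#' @param sirna_reads_per_te Mean siRNA reads per TE (HP, unit intensity).
#' @param edge_decay Exponential decay (bp) of siRNA positions from TE
#'   boundaries.
#' @param frac_24nt Fraction of siRNA reads that are 24 nt.
#' @param chh_coupling Exponent coupling per-TE siRNA rate to the TE's CHH
#'   intensity (1 = proportional, 0 = uncoupled).
#' @param sirna_background_per_kb Background siRNA reads per kb.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 2L, chrom_len = 500000L, gc = 0.35,
                       te_fraction = 0.4, te_len_range = c(500L, 8000L),
                       n_genes = 200L, gene_len_range = c(1000L, 3000L),
                       base_levels = c(CG = 0.665, CHG = 0.436, CHH = 0.037),
                       te_level_boost = c(CG = 0.15, CHG = 0.20),
                       gene_body_cg_boost = 0.10,
                       gene_body_non_cg_drop = 0.5,
                       boundary_dip_width = 300L, boundary_dip_floor = 0.4,
                       meth_sd = 0.25,
                       chh_background = 0.002, te_chh_level = 0.10,
                       island_level = 0.45, island_len_range = c(400L, 1200L),
                       island_density = 1 / 8000,
                       lp_shift = c(CG = 0.01, CHG = 0.01, CHH = 0.01),
                       te_chh_lp = TRUE, te_chh_lp_meanlog = log(0.75),
                       te_chh_lp_sdlog = 0.55,
                       n_spiked_dmrs = 0L, spike_delta = 0.4,
                       spike_direction_bias = 0.6,
                       spike_len_range = c(200L, 2000L),
                       coverage_mean = 30, coverage_dispersion = 0.2,
                       conversion_failure = 0.004, lambda_len = 48502L,
                       n_replicates = 3L, silent_fraction = 0.25,
                       silent_coupling = 0.35, mean_log2_expr = 3,
                       sd_log2_expr = 2.2, coupling_strength = 0.25,
                       expr_dispersion = 0.05, mean_counts = 200,
                       n_true_degs = 0L, deg_fold = 4,
                       sirna_reads_per_te = 120, edge_decay = 150,
                       frac_24nt = 0.55, chh_coupling = 1,
                       sirna_background_per_kb = 0.05) {
  cfg <- as.list(environment())
  stopifnot(cfg$gc > 0, cfg$gc < 1, cfg$te_fraction >= 0, cfg$te_fraction < 1,
            all(cfg$base_levels > 0), all(cfg$base_levels < 1),
            cfg$conversion_failure > 0, cfg$conversion_failure < 1,
            cfg$coverage_mean > 0, cfg$spike_direction_bias >= 0,
            cfg$spike_direction_bias <= 1)
  structure(cfg, class = "sim_config")
}

#' Preset configuration for the DMR-recovery benchmark
#'
#' A 1-Mb genome with 50 spiked CHH DMRs (delta 0.4, 60% hyper) as the only
#' true between-condition differences: the global LP shift and the TE CHH
#' LP reduction are switched off so spike recovery and false-discovery
#' accounting are exact. Gene count is reduced and island density kept high
#' so enough clean background and islands exist to host the spikes.
#'
#' @param seed Master seed.
#' @param ... Overrides passed to [sim_config()].
#' @return A `sim_config`.
#' @export
sim_config_dmr_benchmark <- function(seed = 1L, ...) {
  preset <- list(seed = seed, n_chroms = 2L, chrom_len = 500000L,
                 te_fraction = 0.3, n_genes = 60L, island_density = 1 / 4000,
                 n_spiked_dmrs = 50L, spike_delta = 0.4,
                 spike_direction_bias = 0.6,
                 lp_shift = c(CG = 0, CHG = 0, CHH = 0), te_chh_lp = FALSE,
                 coverage_mean = 30)
  do.call(sim_config, utils::modifyList(preset, list(...)))
}

## ---------------------------------------------------------------------------
## genome + annotation

## place elements of given lengths left-to-right in [0, space) with random
## gaps; returns start positions (or NULL if they do not fit)
.place_elements <- function(lens, space, min_gap = 100L) {
  total <- sum(lens) + (length(lens) + 1L) * min_gap
  if (total > space) return(NULL)
  slack <- space - total
  cuts <- sort(runif(length(lens) + 1L))
  gaps <- min_gap + floor(slack * diff(c(0, cuts)) / max(cuts[length(cuts)], 1e-9))
  starts <- integer(length(lens))
  at <- 0L
  for (i in seq_along(lens)) {
    at <- at + gaps[i]
    starts[i] <- at
    at <- at + lens[i]
  }
  starts
}

#' Generate a synthetic genome, annotation and latent structure
#'
#' Random sequence at the configured GC, TEs placed to occupy
#' `te_fraction` of each chromosome (class I majority, LTR/Gypsy-dominated),
#' genes placed in the remaining space, CHH islands in clean intergenic
#' space, an unmethylated 48.5-kb "lambda" chromosome appended, and the
#' per-feature latent variables (per-gene methylation latent, per-TE CHH
#' intensity and LP factor) drawn once so both conditions share them.
#'
#' @param config A [sim_config()].
#' @return A `sim_genome` list: `genome` (genome_sequence), `annotation`
#'   (feature_annotation), `latents` (gene/TE/island tables).
#' @export
generate_genome <- function(config) {
  cfg <- config
  set.seed(.sim_seed(cfg$seed, "genome"))
  probs <- c(A = (1 - cfg$gc) / 2, C = cfg$gc / 2, G = cfg$gc / 2,
             T = (1 - cfg$gc) / 2)
  chroms <- paste0("chr", seq_len(cfg$n_chroms))
  seqs <- vapply(chroms, function(ch) {
    paste(sample(names(probs), cfg$chrom_len, replace = TRUE, prob = probs),
          collapse = "")
  }, character(1))
  lambda <- paste(sample(c("A", "C", "G", "T"), cfg$lambda_len, replace = TRUE),
                  collapse = "")
  seqs <- c(seqs, lambda = lambda)

  ## features per chromosome
  sfam <- c("LTR/Gypsy", "LTR/Copia", "LINE/L1", "DNA/MuDR", "DNA/hAT")
  sfam_p <- c(0.40, 0.25, 0.10, 0.15, 0.10)
  genes_per_chrom <- diff(round(seq(0, cfg$n_genes, length.out = cfg$n_chroms + 1)))
  genes <- list(); tes <- list()
  for (ci in seq_len(cfg$n_chroms)) {
    te_target <- cfg$te_fraction * cfg$chrom_len
    te_lens <- integer(0)
    while (sum(te_lens) < te_target) {
      te_lens <- c(te_lens, round(runif(1, cfg$te_len_range[1], cfg$te_len_range[2])))
    }
    if (length(te_lens) > 0) {  # trim the last TE so the fraction is exact
      over <- sum(te_lens) - te_target
      te_lens[length(te_lens)] <- max(cfg$te_len_range[1],
                                      te_lens[length(te_lens)] - round(over))
    }
    g_lens <- round(runif(genes_per_chrom[ci], cfg$gene_len_range[1],
                          cfg$gene_len_range[2]))
    lens <- c(te_lens, g_lens)
    kind <- rep(c("te", "gene"), c(length(te_lens), length(g_lens)))
    o <- sample(length(lens))   # intermix TEs and genes
    starts <- .place_elements(lens[o], cfg$chrom_len)
    if (is.null(starts)) {
      stop("infeasible packing: te_fraction plus gene space exceeds the ",
           "chromosome; reduce te_fraction or n_genes")
    }
    dt <- data.table(kind = kind[o], start = starts, end = starts + lens[o])
    gi <- dt[kind == "gene"]; ti <- dt[kind == "te"]
    genes[[ci]] <- data.table(chrom = chroms[ci], start = gi$start, end = gi$end,
                              strand = sample(c("+", "-"), nrow(gi), TRUE))
    tes[[ci]] <- data.table(chrom = chroms[ci], start = ti$start, end = ti$end,
                            strand = sample(c("+", "-"), nrow(ti), TRUE),
                            superfamily = sample(sfam, nrow(ti), TRUE, sfam_p))
  }
  genes <- rbindlist(genes)[, id := sprintf("gene%04d", .I)]
  tes <- rbindlist(tes)[, id := sprintf("te%05d", .I)]
  cl <- c(stats::setNames(rep(cfg$chrom_len, cfg$n_chroms), chroms),
          lambda = cfg$lambda_len)
  annotation <- feature_annotation(
    genes[, .(id, chrom, start, end, strand)],
    tes[, .(id, chrom, start, end, strand, superfamily)], cl)

  ## latents shared by both conditions
  set.seed(.sim_seed(cfg$seed, "latents"))
  lat_genes <- data.table(id = genes$id, z_m = rnorm(nrow(genes)))
  lat_tes <- data.table(id = tes$id,
                        chh_intensity = exp(rnorm(nrow(tes), 0, 0.4)),
                        lp_factor = if (isTRUE(cfg$te_chh_lp)) {
                          exp(rnorm(nrow(tes), cfg$te_chh_lp_meanlog,
                                    cfg$te_chh_lp_sdlog))
                        } else rep(1, nrow(tes)))

  ## CHH islands in clean intergenic space (>= 300 bp from genes/TEs)
  islands <- .place_islands(annotation, cfg)
  structure(list(
    genome = genome_sequence(seqs, spike_in_chrom = "lambda"),
    annotation = annotation,
    latents = list(genes = lat_genes, tes = lat_tes, islands = islands)),
    class = "sim_genome")
}

## maximal intergenic gaps with a margin around features, nuclear chroms
## only. The margin must comfortably exceed the DMR caller's chaining gap
## (200 bp): a single chance-called background cytosine inside the margin
## must not be able to bridge a feature and a neighbouring truth region.
.clean_gaps <- function(annotation, margin = 600L) {
  cl <- annotation$chrom_lengths
  occ <- rbind(annotation$genes[, .(chrom, start, end)],
               annotation$tes[, .(chrom, start, end)])
  gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    occ$chrom, IRanges::IRanges(pmax(occ$start - margin, 0L) + 1L,
                                occ$end + margin)))
  out <- list()
  for (ch in setdiff(names(cl), "lambda")) {
    sub <- gr[as.character(GenomicRanges::seqnames(gr)) == ch]
    s <- sort(GenomicRanges::start(sub) - 1L); e <- sort(GenomicRanges::end(sub))
    gap_s <- c(0L, e); gap_e <- c(s, cl[[ch]])
    keep <- gap_e > gap_s
    out[[ch]] <- data.table(chrom = ch, start = gap_s[keep], end = gap_e[keep])
  }
  rbindlist(out)
}

.place_islands <- function(annotation, cfg) {
  set.seed(.sim_seed(cfg$seed, "islands"))
  gaps <- .clean_gaps(annotation)
  res <- list()
  k <- 0L
  for (i in seq_len(nrow(gaps))) {
    at <- gaps$start[i]
    limit <- gaps$end[i]
    repeat {
      at <- at + round(rexp(1, cfg$island_density)) + 600L
      len <- round(runif(1, cfg$island_len_range[1], cfg$island_len_range[2]))
      if (at + len + 600L > limit) break
      k <- k + 1L
      res[[k]] <- data.table(chrom = gaps$chrom[i], start = as.integer(at),
                             end = as.integer(at + len),
                             intensity = exp(rnorm(1, 0, 0.25)))
      at <- at + len
    }
  }
  if (k == 0L) {
    return(data.table(chrom = character(), start = integer(), end = integer(),
                      intensity = numeric(), id = character()))
  }
  out <- rbindlist(res)
  out[, id := sprintf("island%04d", .I)]
  out[]
}

## ---------------------------------------------------------------------------
## site-level truth

## first-overlap index of sites in intervals (both 0-based half-open)
.site_in <- function(sites, intervals) {
  if (nrow(intervals) == 0) return(rep(NA_integer_, nrow(sites)))
  s_gr <- GenomicRanges::GRanges(sites$chrom,
                                 IRanges::IRanges(sites$pos + 1L, width = 1L))
  i_gr <- GenomicRanges::GRanges(intervals$chrom,
                                 IRanges::IRanges(intervals$start + 1L, intervals$end))
  GenomicRanges::findOverlaps(s_gr, i_gr, select = "first")
}

#' Per-site true methylation levels for both conditions
#'
#' Deterministic given the `sim_genome` and config: assigns every cytosine
#' its generating level under HP and LP, including TE boosts, gene-body CG
#' enrichment, the per-gene methylation latent, boundary dips, the CHH
#' island/TE/background structure, the LP shift and the per-TE CHH LP
#' factor. Each context is multiplicatively calibrated so its HP
#' genome-wide mean equals `base_levels` exactly (lambda excluded).
#'
#' @param sim_genome Output of [generate_genome()].
#' @param config The [sim_config()].
#' @return data.table chrom, pos, strand, context, level_hp, level_lp.
#' @export
site_truth <- function(sim_genome, config) {
  cfg <- config
  ann <- sim_genome$annotation
  sites <- annotate_contexts(sim_genome$genome, drop_unknown = TRUE)
  nuclear <- sites$chrom != "lambda"
  st <- sites[nuclear]

  te_idx <- .site_in(st, ann$tes)
  gene_idx <- .site_in(st, ann$genes)
  isl_idx <- .site_in(st, sim_genome$latents$islands)
  in_te <- !is.na(te_idx)
  in_gene <- !is.na(gene_idx)
  in_isl <- !is.na(isl_idx)

  lvl <- rep(NA_real_, nrow(st))
  cg <- st$context == "CG"; chg <- st$context == "CHG"; chh <- st$context == "CHH"
  lvl[cg] <- cfg$base_levels[["CG"]]
  lvl[chg] <- cfg$base_levels[["CHG"]]
  ## CHH: structured background / TE / island
  lvl[chh] <- cfg$chh_background
  w <- chh & in_te
  lvl[w] <- cfg$te_chh_level *
    sim_genome$latents$tes$chh_intensity[te_idx[w]]
  w <- chh & in_isl & !in_te
  lvl[w] <- cfg$island_level * sim_genome$latents$islands$intensity[isl_idx[w]]
  ## CG/CHG TE boost
  lvl[cg & in_te] <- lvl[cg & in_te] + cfg$te_level_boost[["CG"]]
  lvl[chg & in_te] <- lvl[chg & in_te] + cfg$te_level_boost[["CHG"]]
  ## gene bodies
  w <- cg & in_gene
  lvl[w] <- lvl[w] + cfg$gene_body_cg_boost
  lvl[(chg | chh) & in_gene] <- lvl[(chg | chh) & in_gene] *
    (1 - cfg$gene_body_non_cg_drop)
  ## per-gene CG methylation latent over promoter + body
  zm <- sim_genome$latents$genes$z_m
  reg <- .gene_region_windows(ann$genes, 2000L)
  regpb <- reg[klass %in% c("gene_body", "upstream_2kb")]
  pb_idx <- .site_in(st, regpb)
  w <- cg & !is.na(pb_idx)
  gene_of <- match(regpb$feature_id[pb_idx[w]], sim_genome$latents$genes$id)
  lvl[w] <- lvl[w] * exp(cfg$meth_sd * zm[gene_of] - cfg$meth_sd^2 / 2)
  ## boundary dips
  dipf <- .boundary_dip_factor(st, ann$genes, cfg$boundary_dip_width,
                               cfg$boundary_dip_floor)
  lvl <- lvl * dipf
  lvl <- pmin(pmax(lvl, 0.002), 0.98)

  ## calibrate each context's mean to the configured base level
  for (ctx in c("CG", "CHG", "CHH")) {
    w <- st$context == ctx
    target <- cfg$base_levels[[ctx]]
    for (it in 1:8) {
      m <- mean(lvl[w])
      if (abs(m - target) < 1e-9) break
      lvl[w] <- pmin(pmax(lvl[w] * target / m, 0.002), 0.98)
    }
  }

  st[, level_hp := lvl]
  lp <- lvl
  if (isTRUE(cfg$te_chh_lp)) {
    w <- chh & in_te
    lp[w] <- lp[w] * sim_genome$latents$tes$lp_factor[te_idx[w]]
  }
  shift <- cfg$lp_shift[st$context]
  lp <- pmin(pmax(lp + shift, 0.002), 0.98)
  st[, level_lp := lp]

  lam <- sites[!nuclear]
  if (nrow(lam) > 0) lam[, `:=`(level_hp = 0, level_lp = 0)]
  out <- rbind(st, lam)
  ## positional coverage propensity, shared by all samples drawn from this
  ## truth: coverage depends on local sequence (mappability, GC), so the
  ## between-library coverage profile is correlated in real WGBS. Marginal
  ## coverage stays NB(coverage_mean, coverage_dispersion) because a
  ## Gamma-mixed Poisson is negative binomial.
  set.seed(.sim_seed(cfg$seed, "coverage_propensity"))
  shp <- 1 / cfg$coverage_dispersion
  out[, cov_propensity := stats::rgamma(.N, shape = shp, rate = shp)]
  out[]
}

## linear dip factor by distance to the nearest gene boundary
.boundary_dip_factor <- function(sites, genes, width, floor_) {
  f <- rep(1, nrow(sites))
  if (nrow(genes) == 0 || width <= 0) return(f)
  for (ch in unique(genes$chrom)) {
    b <- sort(c(genes[chrom == ch, start], genes[chrom == ch, end]))
    w <- which(sites$chrom == ch)
    if (length(w) == 0) next
    p <- sites$pos[w]
    i <- findInterval(p, b)
    d_lo <- ifelse(i >= 1L, p - b[pmax(i, 1L)], Inf)
    d_hi <- ifelse(i < length(b), b[pmin(i + 1L, length(b))] - p, Inf)
    d <- pmin(d_lo, d_hi)
    near <- d < width
    f[w[near]] <- floor_ + (1 - floor_) * d[near] / width
  }
  f
}

## ---------------------------------------------------------------------------
## methylome observation layer

#' Draw an observed methylome from the site truth
#'
#' Coverage is marginally negative-binomial (Poisson around a per-position
#' Gamma propensity that is shared across samples, mirroring the
#' mappability/GC-driven coverage correlation of real WGBS libraries);
#' methylated read counts are binomial with success probability
#' `level (1 - e) + (1 - level) e` where `e` is the conversion failure
#' rate. The lambda chromosome has level 0 throughout.
#'
#' @param sim_genome Output of [generate_genome()].
#' @param config The [sim_config()].
#' @param condition `"HP"` or `"LP"`.
#' @param truth Optional precomputed [site_truth()] (recomputed if NULL).
#' @param replicate Integer tag entering the noise seed, so independent
#'   draws of the same condition can be generated.
#' @return List with `cytosines` (chrom, pos, strand, context, meth, total)
#'   and `truth`.
#' @export
generate_methylome <- function(sim_genome, config, condition = c("HP", "LP"),
                               truth = NULL, replicate = 1L) {
  condition <- match.arg(condition)
  cfg <- config
  if (is.null(truth)) truth <- site_truth(sim_genome, cfg)
  set.seed(.sim_seed(cfg$seed, paste0("methylome_", condition, "_", replicate)))
  n <- nrow(truth)
  lvl <- if (condition == "HP") truth$level_hp else truth$level_lp
  total <- rpois(n, cfg$coverage_mean * truth$cov_propensity)
  e <- cfg$conversion_failure
  meth <- rbinom(n, total, lvl * (1 - e) + (1 - lvl) * e)
  cy <- data.table(chrom = truth$chrom, pos = truth$pos, strand = truth$strand,
                   context = truth$context, meth = meth, total = total)
  list(cytosines = cy, truth = truth)
}

## ---------------------------------------------------------------------------
## spiked DMRs

#' Spike ground-truth DMRs into the LP methylome
#'
#' Chooses `n_spiked_dmrs` non-overlapping CHH regions: hyper spikes are
#' placed in clean intergenic background (>= 300 bp from genes, TEs,
#' islands and each other), hypo spikes consume existing CHH islands, so
#' both directions produce regional changes of at least two-fold. The LP
#' true levels inside each spike are shifted by +/- `spike_delta` (clipped)
#' and the LP methylated read counts are redrawn at unchanged coverage.
#'
#' @param lp_methylome Output of [generate_methylome()] for LP.
#' @param sim_genome Output of [generate_genome()].
#' @param config The [sim_config()] (with `n_spiked_dmrs > 0`).
#' @return List with `cytosines` (modified LP table), `truth` (site truth
#'   with updated `level_lp`) and `truth_dmrs` (chrom, start, end, context,
#'   direction, delta).
#' @export
spike_dmrs <- function(lp_methylome, sim_genome, config) {
  cfg <- config
  if (cfg$n_spiked_dmrs <= 0) stop("config has n_spiked_dmrs = 0")
  truth <- copy(lp_methylome$truth)
  cy <- copy(lp_methylome$cytosines)
  set.seed(.sim_seed(cfg$seed, "spikes"))
  n_hyper <- round(cfg$spike_direction_bias * cfg$n_spiked_dmrs)
  n_hypo <- cfg$n_spiked_dmrs - n_hyper

  islands <- sim_genome$latents$islands
  if (nrow(islands) < n_hypo) {
    stop("cannot place ", n_hypo, " hypo spikes: only ", nrow(islands),
         " CHH islands available; reduce n_spiked_dmrs or raise island_density")
  }
  hypo <- islands[sample(.N, n_hypo)][, .(chrom, start, end)]
  hypo[, direction := "hypo"]

  ## hyper spikes in clean gaps, away from islands too
  occ <- rbind(sim_genome$annotation$genes[, .(chrom, start, end)],
               sim_genome$annotation$tes[, .(chrom, start, end)],
               islands[, .(chrom, start, end)])
  gaps <- .clean_gaps(
    feature_annotation(genes = data.table(id = sprintf("occ%05d", seq_len(nrow(occ))),
                                          occ, strand = "+"),
                       tes = data.table(id = character(), chrom = character(),
                                        start = integer(), end = integer(),
                                        strand = character(),
                                        superfamily = character()),
                       sim_genome$annotation$chrom_lengths))
  gaps <- gaps[end - start >= cfg$spike_len_range[1] + 1200L]
  hyper <- list()
  k <- 0L
  gi <- sample(nrow(gaps))  # visit gaps in random order
  for (g in gi) {
    if (k >= n_hyper) break
    at <- gaps$start[g] + 600L
    limit <- gaps$end[g] - 600L
    while (k < n_hyper) {
      len <- round(runif(1, cfg$spike_len_range[1], cfg$spike_len_range[2]))
      if (at + len > limit) break
      k <- k + 1L
      hyper[[k]] <- data.table(chrom = gaps$chrom[g], start = as.integer(at),
                               end = as.integer(at + len))
      at <- at + len + 800L
    }
  }
  if (k < n_hyper) {
    stop("cannot place ", n_hyper, " hyper spikes in the available clean ",
         "intergenic space; reduce n_spiked_dmrs")
  }
  hyper <- rbindlist(hyper)[, direction := "hyper"]
  spikes <- rbind(hyper, hypo)
  spikes[, `:=`(context = "CHH", delta = ifelse(direction == "hyper",
                                                cfg$spike_delta,
                                                -cfg$spike_delta))]
  setorder(spikes, chrom, start)
  spikes[, truth_id := sprintf("spike%03d", .I)]

  ## require >= 8 target-context cytosines per spike
  chh_sites <- truth[context == "CHH"]
  sp_idx <- .site_in(chh_sites, spikes)
  n_per <- table(factor(sp_idx, levels = seq_len(nrow(spikes))))
  if (any(n_per < 8)) stop("spike with fewer than 8 CHH cytosines; ",
                           "enlarge spike_len_range")

  ## shift LP truth inside spikes and redraw LP meth counts there
  hit <- .site_in(truth, spikes)
  w <- which(!is.na(hit) & truth$context == "CHH")
  truth[w, level_lp := pmin(pmax(level_lp + spikes$delta[hit[w]], 0.002), 0.98)]
  set.seed(.sim_seed(cfg$seed, "spike_counts"))
  e <- cfg$conversion_failure
  lvl <- truth$level_lp[w]
  cy[w, meth := rbinom(length(w), cy$total[w], lvl * (1 - e) + (1 - lvl) * e)]
  list(cytosines = cy, truth = truth,
       truth_dmrs = spikes[, .(truth_id, chrom, start, end, context,
                               direction, delta)])
}

#' True (noise-free) regional methylation levels from a site truth table
#'
#' Aggregates the generating per-site levels over promoter / body /
#' downstream gene regions, giving the ground-truth counterpart of
#' [region_levels()] computed on observed counts.
#'
#' @param truth Output of [site_truth()].
#' @param genes Gene table (id, chrom, start, end, strand).
#' @param condition `"HP"` or `"LP"`.
#' @param flank Flank width in bp.
#' @return data.table gene_id, region, context, level (unweighted mean of
#'   the generating site levels; NA for regions without cytosines).
#' @export
true_region_levels <- function(truth, genes, condition = c("HP", "LP"),
                               flank = 2000L) {
  condition <- match.arg(condition)
  lvl <- if (condition == "HP") truth$level_hp else truth$level_lp
  scale <- 10000L
  pseudo <- data.table(chrom = truth$chrom, pos = truth$pos,
                       strand = truth$strand, context = truth$context,
                       meth = as.integer(round(lvl * scale)), total = scale)
  rl <- region_levels(pseudo, genes, flank = flank)
  rl[, .(gene_id, region, context, level)]
}

## ---------------------------------------------------------------------------
## expression

#' Generate replicate RNA-seq counts with methylation coupling
#'
#' Each gene carries the methylation latent `z_m` drawn in
#' [generate_genome()]. A correlated latent decides silencing
#' (probability `silent_fraction`, tilted towards high-methylation genes by
#' `silent_coupling`) and, for expressed genes, the log2 expression
#' (latent correlation `-coupling_strength` with `z_m`). `n_true_degs`
#' genes among the adequately expressed receive a `deg_fold` shift in LP
#' (sign random). Replicate counts are negative-binomial with
#' gene-length-proportional rates scaled so the mean count per gene is
#' `mean_counts`.
#'
#' @param sim_genome Output of [generate_genome()].
#' @param config The [sim_config()].
#' @param condition `"HP"` or `"LP"`.
#' @return List with `counts` (genes x replicates matrix), `lengths`
#'   (named vector) and `truth` (gene_id, z_m, silent, log2_expr,
#'   deg_status, mu_hp, mu_lp).
#' @export
generate_expression <- function(sim_genome, config, condition = c("HP", "LP")) {
  condition <- match.arg(condition)
  cfg <- config
  g <- sim_genome$annotation$genes
  zm <- sim_genome$latents$genes$z_m[match(g$id, sim_genome$latents$genes$id)]
  n <- nrow(g)
  lens <- stats::setNames(g$end - g$start, g$id)

  ## latent structure shared by both conditions
  set.seed(.sim_seed(cfg$seed, "expr_latents"))
  z_sil <- cfg$silent_coupling * zm +
    sqrt(1 - cfg$silent_coupling^2) * rnorm(n)
  silent <- z_sil > stats::qnorm(1 - cfg$silent_fraction)
  r <- cfg$coupling_strength
  z_e <- -r * zm + sqrt(1 - r^2) * rnorm(n)
  log2_expr <- cfg$mean_log2_expr + cfg$sd_log2_expr * z_e
  rel <- 2^log2_expr
  rel[silent] <- 2^(cfg$mean_log2_expr - 6 * cfg$sd_log2_expr)  # near zero
  ## per-replicate expected counts, scaled to the target mean count
  mu0 <- rel * (lens / 2000)
  mu0 <- mu0 * cfg$mean_counts / mean(mu0)
  deg_status <- rep("none", n)
  mu_lp <- mu0
  if (cfg$n_true_degs > 0) {
    eligible <- which(!silent & mu0 >= 25)
    if (length(eligible) < cfg$n_true_degs) {
      stop("not enough adequately expressed genes for n_true_degs")
    }
    deg <- sample(eligible, cfg$n_true_degs)
    up <- sample(c(TRUE, FALSE), cfg$n_true_degs, replace = TRUE)
    deg_status[deg[up]] <- "up"
    deg_status[deg[!up]] <- "down"
    mu_lp[deg] <- mu0[deg] * ifelse(up, cfg$deg_fold, 1 / cfg$deg_fold)
  }
  mu <- if (condition == "LP") mu_lp else mu0

  set.seed(.sim_seed(cfg$seed, paste0("expr_counts_", condition)))
  counts <- matrix(rnbinom(n * cfg$n_replicates,
                           mu = rep(mu, cfg$n_replicates),
                           size = 1 / cfg$expr_dispersion),
                   nrow = n,
                   dimnames = list(g$id, paste0(condition, "_rep",
                                                seq_len(cfg$n_replicates))))
  truth <- data.table(gene_id = g$id, z_m = zm, silent = silent,
                      log2_expr = log2(rel), deg_status = deg_status,
                      mu_hp = mu0, mu_lp = mu_lp)
  list(counts = counts, lengths = lens, truth = truth)
}

## ---------------------------------------------------------------------------
## small RNA

#' Generate 24-nt-dominant siRNA alignments clustered at TE boundaries
#'
#' Per-TE read numbers are Poisson with rate proportional to
#' `sirna_reads_per_te` times the TE's CHH intensity raised to
#' `chh_coupling` (times the TE's LP factor under LP, mirroring the
#' CHH/siRNA co-reduction). Read positions decay exponentially from the two
#' TE boundaries (mostly inward); read lengths are 24 nt with probability
#' `frac_24nt`, otherwise uniform over the remaining 18-30 nt. A uniform
#' genomic background is added.
#'
#' @param sim_genome Output of [generate_genome()].
#' @param config The [sim_config()].
#' @param condition `"HP"` or `"LP"`.
#' @return List with `alignments` (chrom, start, end, read_count) and
#'   `truth_clusters` (te_id, chrom, start, end, rate).
#' @export
generate_sirna <- function(sim_genome, config, condition = c("HP", "LP")) {
  condition <- match.arg(condition)
  cfg <- config
  te <- sim_genome$annotation$tes
  lat <- sim_genome$latents$tes
  set.seed(.sim_seed(cfg$seed, paste0("sirna_", condition)))
  rate <- cfg$sirna_reads_per_te * lat$chh_intensity^cfg$chh_coupling
  if (condition == "LP") rate <- rate * lat$lp_factor
  n_reads <- rpois(nrow(te), rate)
  cl <- sim_genome$annotation$chrom_lengths

  mk <- function(i) {
    k <- n_reads[i]
    if (k == 0) return(NULL)
    at_end <- runif(k) < 0.5
    edge <- ifelse(at_end, te$end[i], te$start[i])
    inward <- runif(k) < 0.7
    off <- round(rexp(k, 1 / cfg$edge_decay))
    sgn <- ifelse(at_end, ifelse(inward, -1L, 1L), ifelse(inward, 1L, -1L))
    mid <- edge + sgn * off
    len <- ifelse(runif(k) < cfg$frac_24nt, 24L,
                  sample(setdiff(18:30, 24L), k, replace = TRUE))
    start <- pmax(0L, as.integer(mid - len %/% 2L))
    start <- pmin(start, cl[[te$chrom[i]]] - len)
    data.table(chrom = te$chrom[i], start = start,
               end = as.integer(start + len))
  }
  reads <- rbindlist(lapply(seq_len(nrow(te)), mk))

  ## uniform background over nuclear chromosomes
  nuc <- setdiff(names(cl), "lambda")
  nbg <- rpois(1, cfg$sirna_background_per_kb * sum(cl[nuc]) / 1000)
  if (nbg > 0) {
    ch <- sample(nuc, nbg, replace = TRUE, prob = cl[nuc] / sum(cl[nuc]))
    len <- ifelse(runif(nbg) < cfg$frac_24nt, 24L,
                  sample(setdiff(18:30, 24L), nbg, replace = TRUE))
    st <- floor(runif(nbg) * (cl[ch] - len))
    reads <- rbind(reads, data.table(chrom = ch, start = as.integer(st),
                                     end = as.integer(st + len)))
  }
  if (is.null(reads) || nrow(reads) == 0) {
    reads <- data.table(chrom = character(), start = integer(), end = integer())
  }
  al <- reads[, .(read_count = .N), by = .(chrom, start, end)]
  setorder(al, chrom, start)
  truth <- data.table(te_id = te$id, chrom = te$chrom,
                      start = pmax(te$start - 3L * cfg$edge_decay, 0L),
                      end = te$end + 3L * cfg$edge_decay, rate = rate)
  list(alignments = al[], truth_clusters = truth)
}

## ---------------------------------------------------------------------------
## orchestrator

#' Run the full synthetic experiment
#'
#' Generates the genome, both condition methylomes (with spiked DMRs when
#' configured), expression counts and siRNA alignments, and optionally
#' writes everything (genome FASTA, GFF3 annotation, cytosine TSVs, count
#' and siRNA tables, truth tables) to a directory.
#'
#' @param config A [sim_config()].
#' @param out_dir Optional output directory.
#' @return List with sim_genome, truth, methylomes (`HP`, `LP`), truth_dmrs
#'   (NULL when no spikes), expression (`HP`, `LP`), sirna (`HP`, `LP`).
#' @export
simulate_experiment <- function(config, out_dir = NULL) {
  cfg <- config
  sg <- generate_genome(cfg)
  truth <- site_truth(sg, cfg)
  hp <- generate_methylome(sg, cfg, "HP", truth = truth)
  lp <- generate_methylome(sg, cfg, "LP", truth = truth)
  truth_dmrs <- NULL
  if (cfg$n_spiked_dmrs > 0) {
    sp <- spike_dmrs(lp, sg, cfg)
    lp <- list(cytosines = sp$cytosines, truth = sp$truth)
    truth <- sp$truth
    truth_dmrs <- sp$truth_dmrs
  }
  expr_hp <- generate_expression(sg, cfg, "HP")
  expr_lp <- generate_expression(sg, cfg, "LP")
  sir_hp <- generate_sirna(sg, cfg, "HP")
  sir_lp <- generate_sirna(sg, cfg, "LP")
  res <- list(sim_genome = sg, truth = truth,
              methylomes = list(HP = hp$cytosines, LP = lp$cytosines),
              truth_dmrs = truth_dmrs,
              expression = list(HP = expr_hp, LP = expr_lp),
              sirna = list(HP = sir_hp, LP = sir_lp))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(out_dir, "truth"), showWarnings = FALSE)
    Biostrings::writeXStringSet(sg$genome$seq, file.path(out_dir, "genome.fa"))
    write_annotation_gff3(sg$annotation, file.path(out_dir, "annotation.gff3"))
    write_cytosine_table(res$methylomes$HP, file.path(out_dir, "HP.cytosines.tsv"))
    write_cytosine_table(res$methylomes$LP, file.path(out_dir, "LP.cytosines.tsv"))
    cm <- cbind(data.table(gene_id = rownames(expr_hp$counts),
                           length_bp = expr_hp$lengths[rownames(expr_hp$counts)]),
                as.data.table(expr_hp$counts), as.data.table(expr_lp$counts))
    fwrite(cm, file.path(out_dir, "counts.tsv"), sep = "\t")
    fwrite(sir_hp$alignments, file.path(out_dir, "sirna_HP.tsv"), sep = "\t")
    fwrite(sir_lp$alignments, file.path(out_dir, "sirna_LP.tsv"), sep = "\t")
    if (!is.null(truth_dmrs)) {
      fwrite(truth_dmrs, file.path(out_dir, "truth", "dmrs.tsv"), sep = "\t")
    }
    fwrite(expr_hp$truth, file.path(out_dir, "truth", "expression.tsv"), sep = "\t")
    fwrite(sir_hp$truth_clusters, file.path(out_dir, "truth", "sirna_clusters.tsv"),
           sep = "\t")
  }
  res
}
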