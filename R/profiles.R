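## Metagene / TE profiles and methylation-expression association.
##
## One binning engine (bin_positions) maps genomic positions onto the
## upstream-flank / scaled-body / downstream-flank coordinate system of a
## feature set; the methylation profiles and the siRNA abundance profiles
## both go through it.

#' Map genomic positions onto feature-relative profile bins
#'
#' Shared binning engine. Flanks are cut into fixed `flank / flank_bin`
#' bins; the body is cut into `body_bins` equal relative slices. Minus-strand
#' features are flipped so that bin 0 of the upstream class is always the 5'
#' end of the profile. In `"interval"` mode a position is treated as a 1-bp
#' interval and split fractionally across body-slice boundaries; in
#' `"point"` mode it falls entirely in the slice containing it.
#'
#' @param positions data.table with columns chrom, pos (0-based); other
#'   columns are carried through.
#' @param features data.table with columns id, chrom, start, end, strand.
#' @param flank Flank width in bp.
#' @param flank_bin Fixed flank bin width in bp.
#' @param body_bins Number of relative body slices.
#' @param strand_aware Flip minus-strand features (default TRUE).
#' @param mode `"interval"` or `"point"`.
#' @return data.table: one row per (position, feature, bin) assignment with
#'   columns of `positions` plus feature_id, bin_class
#'   ("upstream"/"body"/"downstream"), bin_idx (0-based) and frac.
#' @export
bin_positions <- function(positions, features, flank = 2000L, flank_bin = 100L,
                          body_bins = 20L, strand_aware = TRUE,
                          mode = c("interval", "point")) {
  mode <- match.arg(mode)
  pos_dt <- as.data.table(positions)
  ft <- as.data.table(features)
  if (nrow(ft) == 0) stop("feature set must be non-empty")
  if (!strand_aware) ft <- copy(ft)[, strand := "+"]
  n_flank_bins <- as.integer(flank / flank_bin)

  ## overlap of positions with [start - flank, end + flank)
  ft_gr <- GenomicRanges::GRanges(
    ft$chrom, IRanges::IRanges(pmax(ft$start - flank, 0L) + 1L, ft$end + flank))
  p_gr <- GenomicRanges::GRanges(pos_dt$chrom,
                                 IRanges::IRanges(pos_dt$pos + 1L, width = 1L))
  hits <- GenomicRanges::findOverlaps(p_gr, ft_gr)
  if (length(hits) == 0) {
    return(cbind(pos_dt[0], data.table(feature_id = character(),
                                       bin_class = character(),
                                       bin_idx = integer(), frac = numeric())))
  }
  pi <- S4Vectors::queryHits(hits); fi <- S4Vectors::subjectHits(hits)
  dt <- pos_dt[pi]
  dt[, `:=`(feature_id = ft$id[fi], f_start = ft$start[fi], f_end = ft$end[fi],
            f_strand = ft$strand[fi])]
  ## positions that fall in the clipped-away part of a flank near pos 0 are
  ## genuine members only if within flank of the feature; the GRanges clip
  ## above cannot create false positives on the right, only keep all on the
  ## left, so re-filter exactly:
  dt <- dt[pos >= f_start - flank & pos < f_end + flank]

  minus <- dt$f_strand == "-"
  glen <- dt$f_end - dt$f_start
  before <- dt$pos < dt$f_start          # plus-coordinate left flank
  after <- dt$pos >= dt$f_end            # plus-coordinate right flank
  body <- !before & !after

  bin_class <- character(nrow(dt))
  bin_class[before] <- ifelse(minus[before], "downstream", "upstream")
  bin_class[after] <- ifelse(minus[after], "upstream", "downstream")
  bin_class[body] <- "body"

  bin_idx <- integer(nrow(dt))
  ## left flank: distance from the -flank edge for plus upstream;
  ## for minus features this is the downstream side, bin 0 nearest the TES.
  off_l <- dt$pos - (dt$f_start - flank)
  bin_idx[before & !minus] <- off_l[before & !minus] %/% flank_bin
  bin_idx[before & minus] <- (flank - 1L - off_l[before & minus]) %/% flank_bin
  ## right flank
  off_r <- dt$pos - dt$f_end
  bin_idx[after & !minus] <- off_r[after & !minus] %/% flank_bin
  bin_idx[after & minus] <- (flank - 1L - off_r[after & minus]) %/% flank_bin

  out_flank <- dt[!body]
  out_flank[, `:=`(bin_class = bin_class[!body], bin_idx = bin_idx[!body],
                   frac = 1)]

  ## body: relative coordinates in [0, body_bins)
  bd <- dt[body]
  if (nrow(bd) > 0) {
    gl <- glen[body]; mn <- minus[body]
    r0 <- ifelse(mn, (bd$f_end - (bd$pos + 1)) / gl,
                     (bd$pos - bd$f_start) / gl) * body_bins
    r1 <- r0 + body_bins / gl
    if (mode == "point") {
      b0 <- pmin(as.integer(floor(r0)), body_bins - 1L)
      bd[, `:=`(bin_class = "body", bin_idx = b0, frac = 1)]
      out_body <- bd
    } else {
      b0 <- pmin(as.integer(floor(r0)), body_bins - 1L)
      hi <- pmin(r1, b0 + 1)
      f0 <- (hi - r0) / (r1 - r0)
      first <- copy(bd)[, `:=`(bin_class = "body", bin_idx = b0, frac = f0)]
      spill <- which(r1 > b0 + 1 & b0 + 1 <= body_bins - 1L)
      if (length(spill) > 0) {
        second <- bd[spill]
        second[, `:=`(bin_class = "body", bin_idx = b0[spill] + 1L,
                      frac = ((r1 - (b0 + 1)) / (r1 - r0))[spill])]
        out_body <- rbind(first, second)
      } else out_body <- first
    }
  } else {
    out_body <- dt[0][, `:=`(bin_class = character(0), bin_idx = integer(0),
                             frac = numeric(0))]
  }
  res <- rbind(out_flank, out_body)
  res[, c("f_start", "f_end", "f_strand") := NULL]
  res[]
}

.profile_grid <- function(flank, flank_bin, body_bins) {
  nf <- as.integer(flank / flank_bin)
  rbind(data.table(bin_class = "upstream", bin_idx = seq_len(nf) - 1L),
        data.table(bin_class = "body", bin_idx = seq_len(body_bins) - 1L),
        data.table(bin_class = "downstream", bin_idx = seq_len(nf) - 1L))
}

#' Metagene / TE methylation profile
#'
#' Pools reads across features per profile bin: bin level =
#' `sum(meth * frac) / sum(total * frac)` over all cytosines of the context
#' assigned to the bin. With `average = "features"` the unweighted mean of
#' per-feature bin levels is returned instead.
#'
#' @param cytosines Cytosine table.
#' @param features data.table id, chrom, start, end, strand (genes or TEs).
#' @param context One of "CG", "CHG", "CHH".
#' @param flank,flank_bin,body_bins,strand_aware See [bin_positions()].
#' @param average `"reads"` (pooled, default) or `"features"`.
#' @return data.table context, bin_class, bin_idx, level, n (sites or
#'   features contributing); attribute `n_features`.
#' @export
feature_profile <- function(cytosines, features, context = "CG", flank = 2000L,
                            flank_bin = 100L, body_bins = 20L,
                            strand_aware = TRUE,
                            average = c("reads", "features")) {
  average <- match.arg(average)
  ctx <- context
  cy <- as.data.table(cytosines)[context == ctx & total > 0,
                                 .(chrom, pos, meth, total)]
  b <- bin_positions(cy, features, flank = flank, flank_bin = flank_bin,
                     body_bins = body_bins, strand_aware = strand_aware,
                     mode = "interval")
  if (average == "reads") {
    agg <- b[, .(level = sum(meth * frac) / sum(total * frac), n = .N),
             by = .(bin_class, bin_idx)]
  } else {
    per_ft <- b[, .(level = sum(meth * frac) / sum(total * frac)),
                by = .(feature_id, bin_class, bin_idx)]
    agg <- per_ft[, .(level = mean(level), n = .N), by = .(bin_class, bin_idx)]
  }
  grid <- .profile_grid(flank, flank_bin, body_bins)
  out <- agg[grid, on = c("bin_class", "bin_idx")]
  out[, context := ctx]
  setcolorder(out, c("context", "bin_class", "bin_idx", "level", "n"))
  setattr(out, "n_features", nrow(as.data.table(features)))
  out[]
}

#' Per-gene promoter / body / downstream methylation levels
#'
#' Promoter is the 2-kb region 5' of the TSS (strand-aware), downstream the
#' 2-kb region 3' of the TES; body is the annotated gene interval. Weighted
#' levels are computed per gene, region and context; when the cytosine table
#' carries a `methylated` column (from [call_methylated_sites()]) the number
#' of called mCs per region is reported as `n_mc`.
#'
#' @param cytosines Cytosine table.
#' @param genes data.table id, chrom, start, end, strand.
#' @param flank Flank width (default 2000).
#' @return data.table gene_id, region, context, meth_reads, total_reads,
#'   level (NA when uncovered), n_mc (NA when no site calls available).
#' @export
region_levels <- function(cytosines, genes, flank = 2000L) {
  g <- as.data.table(genes)
  cy <- as.data.table(cytosines)[context %in% c("CG", "CHG", "CHH")]
  has_calls <- "methylated" %in% names(cy)
  minus <- g$strand == "-"
  regions <- rbind(
    data.table(gene_id = g$id, chrom = g$chrom, region = "body",
               start = g$start, end = g$end),
    data.table(gene_id = g$id, chrom = g$chrom, region = "promoter",
               start = ifelse(minus, g$end, pmax(g$start - flank, 0L)),
               end = ifelse(minus, g$end + flank, g$start)),
    data.table(gene_id = g$id, chrom = g$chrom, region = "downstream",
               start = ifelse(minus, pmax(g$start - flank, 0L), g$end),
               end = ifelse(minus, g$start, g$end + flank)))
  regions <- regions[end > start]
  r_gr <- GenomicRanges::GRanges(regions$chrom,
                                 IRanges::IRanges(regions$start + 1L, regions$end))
  c_gr <- GenomicRanges::GRanges(cy$chrom, IRanges::IRanges(cy$pos + 1L, width = 1L))
  hits <- GenomicRanges::findOverlaps(c_gr, r_gr)
  dt <- cy[S4Vectors::queryHits(hits)]
  dt[, `:=`(gene_id = regions$gene_id[S4Vectors::subjectHits(hits)],
            region = regions$region[S4Vectors::subjectHits(hits)])]
  agg <- dt[, .(meth_reads = sum(meth[total > 0]),
                total_reads = sum(total),
                n_mc = if (has_calls) sum(methylated) else NA_integer_),
            by = .(gene_id, region, context)]
  agg[, level := ifelse(total_reads > 0, meth_reads / total_reads, NA_real_)]
  ## complete grid so every gene/region/context appears
  grid <- CJ(gene_id = g$id, region = c("promoter", "body", "downstream"),
             context = c("CG", "CHG", "CHH"))
  out <- agg[grid, on = c("gene_id", "region", "context")]
  out[is.na(total_reads), `:=`(meth_reads = 0L, total_reads = 0L)]
  if (has_calls) out[is.na(n_mc), n_mc := 0L]
  out[]
}

#' Partition genes into expression groups
#'
#' Non-expressed genes (`FPKM < 0.1`) form the `none` group; expressed genes
#' are ranked by FPKM (ties broken by gene id) and split into four
#' equal-size ascending groups `Q1..Q4`.
#'
#' @param fpkm_table data.table with columns gene_id, fpkm.
#' @param none_cut FPKM threshold below which a gene is non-expressed.
#' @param n_groups Number of ascending groups among expressed genes.
#' @return data.table gene_id, fpkm, group; attribute `boundaries` holds the
#'   FPKM cut points between groups.
#' @export
expression_groups <- function(fpkm_table, none_cut = 0.1, n_groups = 4L) {
  ft <- as.data.table(fpkm_table)[, .(gene_id, fpkm)]
  ft[, group := "none"]
  expr <- ft[fpkm >= none_cut]
  if (nrow(expr) > 0) {
    o <- order(expr$fpkm, expr$gene_id)
    grp <- ceiling(seq_along(o) * n_groups / length(o))
    ft[expr[o], on = "gene_id", group := paste0("Q", grp)]
  }
  bounds <- if (nrow(expr) >= n_groups) {
    sorted <- sort(expr$fpkm)
    sorted[ceiling(seq_len(n_groups - 1) * length(sorted) / n_groups)]
  } else numeric(0)
  setattr(ft, "boundaries", bounds)
  ft[]
}

#' Metagene profiles per expression group
#'
#' @param cytosines Cytosine table.
#' @param genes Gene table (id, chrom, start, end, strand).
#' @param groups Output of [expression_groups()].
#' @param contexts Contexts to profile.
#' @param ... Passed to [feature_profile()].
#' @return data.table of profiles with columns group, context, bin_class,
#'   bin_idx, level, n. Empty groups are omitted with a warning.
#' @export
profile_by_group <- function(cytosines, genes, groups,
                             contexts = c("CG", "CHG", "CHH"), ...) {
  g <- as.data.table(genes)
  out <- list()
  for (grp in unique(groups$group)) {
    ids <- groups[group == grp, gene_id]
    sub <- g[id %in% ids]
    if (nrow(sub) == 0) {
      warning("expression group '", grp, "' has no genes; omitted")
      next
    }
    for (ctx in contexts) {
      pr <- feature_profile(cytosines, sub, context = ctx, ...)
      pr[, group := grp]
      out[[paste(grp, ctx)]] <- pr
    }
  }
  rbindlist(out)[]
}

#' Methylation quintiles of genes for one region and context
#'
#' Genes with no called methylated cytosine in the region form the
#' `unmethylated` class; the remaining genes are split into five ascending
#' 20% groups (`Q1` lowest ... `Q5` highest) by weighted region level, ties
#' broken by gene id.
#'
#' @param region_level_table Output of [region_levels()] computed from a
#'   cytosine table that carries site calls.
#' @param region `"promoter"` or `"body"`.
#' @param context Context to use.
#' @param n_groups Number of quantile groups (default 5).
#' @return data.table gene_id, level, group.
#' @export
methylation_quintiles <- function(region_level_table, region = c("promoter", "body"),
                                  context = "CG", n_groups = 5L) {
  region <- match.arg(region)
  reg <- region; ctx <- context
  rl <- as.data.table(region_level_table)[region == reg & context == ctx]
  if (anyNA(rl$n_mc)) {
    stop("region_levels must be computed from a table with site calls ",
         "(run call_methylated_sites first)")
  }
  rl[, group := "unmethylated"]
  meth <- rl[n_mc > 0 & !is.na(level)]
  if (nrow(meth) > 0) {
    o <- order(meth$level, meth$gene_id)
    grp <- ceiling(seq_along(o) * n_groups / length(o))
    rl[meth[o], on = "gene_id", group := paste0("Q", grp)]
  }
  rl[, .(gene_id, level, group)]
}

#' Spearman correlation between regional methylation and expression
#'
#' Correlates the weighted methylation level of one region/context with
#' `log10(FPKM + 1e-3)` across genes with a non-missing level. Only ranks
#' matter, so the pseudocount is inert.
#'
#' @param region_level_table Output of [region_levels()].
#' @param fpkm_table data.table gene_id, fpkm.
#' @param region `"promoter"`, `"body"` or `"downstream"`.
#' @param context Context.
#' @return Spearman rho, or NA with fewer than 3 complete pairs.
#' @export
methylation_expression_correlation <- function(region_level_table, fpkm_table,
                                               region = "promoter",
                                               context = "CG") {
  reg <- region; ctx <- context
  rl <- as.data.table(region_level_table)[region == reg & context == ctx,
                                          .(gene_id, level)]
  m <- as.data.table(fpkm_table)[rl, on = "gene_id"]
  m <- m[!is.na(level) & !is.na(fpkm)]
  if (nrow(m) < 3L) return(NA_real_)
  spearman_rho(m$level, log10(m$fpkm + 1e-3))
}
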