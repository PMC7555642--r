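## Global methylome summaries: sequencing QC arithmetic, conversion
## efficiency from the unmethylated spike-in, methylated-site calling,
## per-context weighted levels and mC proportions, and genome-binned tracks.

#' Sequencing run summary arithmetic
#'
#' @param raw_reads,clean_reads,mapped_reads Read counts with
#'   `mapped <= clean <= raw`.
#' @param conversion_efficiency Optional percent from
#'   [conversion_efficiency()], carried through for reporting.
#' @return List with the counts, `mapped_ratio` (percent of clean reads
#'   mapped, rounded to 2 decimals) and `conversion_efficiency`.
#' @examples
#' sequencing_summary(444676244, 438763364, 387477437)$mapped_ratio  # 88.31
#' @export
sequencing_summary <- function(raw_reads, clean_reads, mapped_reads,
                               conversion_efficiency = NA_real_) {
  if (any(c(raw_reads, clean_reads, mapped_reads) < 0) ||
      mapped_reads > clean_reads || clean_reads > raw_reads) {
    stop("need 0 <= mapped_reads <= clean_reads <= raw_reads")
  }
  list(raw_reads = raw_reads, clean_reads = clean_reads,
       mapped_reads = mapped_reads,
       mapped_ratio = round(100 * mapped_reads / clean_reads, 2),
       conversion_efficiency = conversion_efficiency)
}

#' Bisulfite conversion efficiency from the unmethylated spike-in
#'
#' All apparent methylation on a fully unmethylated control chromosome
#' (e.g. lambda phage DNA) is conversion failure, so the efficiency is
#' `100 * (1 - sum(meth) / sum(total))` over its cytosines, all contexts
#' pooled.
#'
#' @param cytosines Cytosine table including the spike-in chromosome.
#' @param spike_in_chrom Name of the spike-in chromosome.
#' @return Efficiency in percent.
#' @export
conversion_efficiency <- function(cytosines, spike_in_chrom) {
  cy <- as.data.table(cytosines)[chrom == spike_in_chrom & total > 0]
  if (nrow(cy) == 0) {
    stop("no covered cytosines on spike-in chromosome '", spike_in_chrom,
         "'; supply the conversion error rate manually")
  }
  100 * (1 - sum(cy$meth) / sum(cy$total))
}

#' Call methylated cytosines against the conversion error rate
#'
#' A site is testable when covered by at least `min_cov` reads; it is called
#' methylated when its one-sided binomial p-value (observed methylated reads
#' against the conversion failure rate) survives Benjamini-Hochberg
#' correction across all testable sites at level `alpha`.
#'
#' @param cytosines Cytosine table.
#' @param error_rate Conversion failure rate in (0, 1), e.g.
#'   `1 - conversion_efficiency/100`.
#' @param min_cov Minimum coverage for a testable site.
#' @param alpha BH FDR level for the site calls.
#' @return The table with logical column `methylated` added (FALSE for
#'   untestable sites).
#' @export
call_methylated_sites <- function(cytosines, error_rate, min_cov = 4L,
                                  alpha = 0.01) {
  if (error_rate <= 0 || error_rate >= 1) stop("error_rate must be in (0, 1)")
  cy <- as.data.table(cytosines)
  testable <- cy$total >= min_cov
  p <- rep(NA_real_, nrow(cy))
  if (any(testable)) {
    p[testable] <- binomial_sf(cy$meth[testable], cy$total[testable], error_rate)
  }
  q <- bh_fdr(p)
  cy[, methylated := !is.na(q) & q < alpha & cy$meth > 0]
  cy[]
}

#' Global per-context methylation levels and mC proportions
#'
#' The level of context X is the weighted fraction
#' `sum(meth) / sum(total)` over covered context-X cytosines (the mCG/CG
#' style denominator). When `error_rate` is given, sites are additionally
#' called with [call_methylated_sites()] and the proportions of called mCs
#' falling in each context are reported; optionally the levels are corrected
#' for conversion failure via `p = (p_obs - e) / (1 - 2e)`.
#'
#' @param cytosines Cytosine table (UNKNOWN contexts are excluded).
#' @param error_rate Optional conversion failure rate for site calls.
#' @param min_cov,alpha Passed to [call_methylated_sites()].
#' @param correct_nonconversion Apply the error-rate correction to levels.
#' @param exclude_chrom Chromosomes to drop before summarising (the
#'   unmethylated spike-in must not enter genome-level summaries).
#' @return List with `level_CG`, `level_CHG`, `level_CHH` (NA when a context
#'   has no covered site), and `prop_CG`, `prop_CHG`, `prop_CHH` when sites
#'   were called (summing to 1).
#' @export
global_levels <- function(cytosines, error_rate = NULL, min_cov = 4L,
                          alpha = 0.01, correct_nonconversion = FALSE,
                          exclude_chrom = NULL) {
  cy <- as.data.table(cytosines)[context %in% c("CG", "CHG", "CHH")]
  if (!is.null(exclude_chrom)) cy <- cy[!chrom %in% exclude_chrom]
  lv <- cy[total > 0, .(level = sum(meth) / sum(total)), by = context]
  get <- function(ctx) {
    v <- lv[context == ctx, level]
    if (length(v) == 0) NA_real_ else v
  }
  out <- list(level_CG = get("CG"), level_CHG = get("CHG"),
              level_CHH = get("CHH"))
  if (isTRUE(correct_nonconversion)) {
    if (is.null(error_rate)) stop("correction requires error_rate")
    out[1:3] <- lapply(out[1:3], function(p)
      if (is.na(p)) p else min(1, max(0, (p - error_rate) / (1 - 2 * error_rate))))
  }
  if (!is.null(error_rate)) {
    called <- call_methylated_sites(cy, error_rate, min_cov = min_cov,
                                    alpha = alpha)
    nm <- called[methylated == TRUE, .N, by = context]
    tot <- sum(nm$N)
    getp <- function(ctx) {
      v <- nm[context == ctx, N]
      if (tot == 0) NA_real_ else (if (length(v) == 0) 0 else v) / tot
    }
    out$prop_CG <- getp("CG"); out$prop_CHG <- getp("CHG")
    out$prop_CHH <- getp("CHH")
  }
  out
}

#' Genome-binned gene/TE density and methylation tracks
#'
#' Tiles each chromosome with fixed-width bins and reports, per bin, the
#' number of genes and TEs starting in it and the weighted methylation level
#' per context.
#'
#' @param cytosines Cytosine table.
#' @param annotation A `feature_annotation`.
#' @param bin_size Bin width in bp.
#' @return data.table with chrom, bin_start, bin_end, gene_count, te_count,
#'   level_CG, level_CHG, level_CHH.
#' @export
genome_tracks <- function(cytosines, annotation, bin_size = 100000L) {
  if (bin_size <= 0) stop("bin_size must be positive")
  cl <- annotation$chrom_lengths
  bins <- rbindlist(lapply(names(cl), function(ch) {
    s <- seq.int(0L, cl[[ch]] - 1L, by = bin_size)
    data.table(chrom = ch, bin_start = s, bin_end = pmin(s + bin_size, cl[[ch]]))
  }))
  cnt <- function(dt) {
    if (nrow(dt) == 0) return(data.table(chrom = character(), bin_start = integer(), n = integer()))
    dt[, .(n = .N), by = .(chrom, bin_start = (start %/% bin_size) * bin_size)]
  }
  g <- cnt(annotation$genes); t <- cnt(annotation$tes)
  bins <- g[bins, on = c("chrom", "bin_start")]
  setnames(bins, "n", "gene_count")
  bins <- t[bins, on = c("chrom", "bin_start")]
  setnames(bins, "n", "te_count")
  bins[is.na(gene_count), gene_count := 0L]
  bins[is.na(te_count), te_count := 0L]
  cy <- as.data.table(cytosines)[context %in% c("CG", "CHG", "CHH") & total > 0]
  lev <- cy[, .(level = sum(meth) / sum(total)),
            by = .(chrom, bin_start = (pos %/% bin_size) * bin_size, context)]
  wide <- dcast(lev, chrom + bin_start ~ context, value.var = "level")
  for (ctx in c("CG", "CHG", "CHH")) {
    if (!ctx %in% names(wide)) wide[, (ctx) := NA_real_]
  }
  bins <- wide[bins, on = c("chrom", "bin_start")]
  setnames(bins, c("CG", "CHG", "CHH"),
           c("level_CG", "level_CHG", "level_CHH"))
  setcolorder(bins, c("chrom", "bin_start", "bin_end", "gene_count",
                      "te_count", "level_CG", "level_CHG", "level_CHH"))
  setkey(bins, chrom, bin_start)[]
}
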