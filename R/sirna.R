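## Small-RNA association analyses: length distribution, 24-nt selection,
## TE-anchored abundance profiles, and methylation of siRNA-covered regions.

#' Read a small-RNA alignment table
#'
#' BED-like TSV with columns chrom, start, end, read_count (0-based
#' half-open; the alignment length in nt is `end - start`). A header line is
#' detected automatically. Alignments outside 18-30 nt are rejected with a
#' warning.
#'
#' @param path File path.
#' @return data.table chrom, start, end, read_count.
#' @export
read_sirna_table <- function(path) {
  first <- strsplit(readLines(path, n = 1L), "\t")[[1]]
  has_header <- length(first) >= 2L && is.na(suppressWarnings(as.numeric(first[2])))
  dt <- fread(path, header = has_header, sep = "\t")
  if (ncol(dt) < 4L) stop("small-RNA table needs chrom, start, end, read_count")
  setnames(dt, seq_len(4L), c("chrom", "start", "end", "read_count"))
  dt <- dt[, .(chrom = as.character(chrom), start = as.integer(start),
               end = as.integer(end), read_count = as.integer(read_count))]
  if (any(dt$read_count < 1L)) stop("read_count must be >= 1")
  len <- dt$end - dt$start
  bad <- len < 18L | len > 30L
  if (any(bad)) {
    warning(sum(bad), " alignment(s) outside 18-30 nt rejected")
    dt <- dt[!bad]
  }
  dt[]
}

#' Read-count-weighted small-RNA length distribution
#'
#' @param alignments Alignment table (chrom, start, end, read_count).
#' @return data.table length (18..30), reads.
#' @export
length_distribution <- function(alignments) {
  al <- as.data.table(alignments)
  grid <- data.table(length = 18:30)
  if (nrow(al) == 0) {
    grid[, reads := 0L]
    return(grid[])
  }
  al[, len := end - start]
  bad <- al$len < 18L | al$len > 30L
  if (any(bad)) {
    warning(sum(bad), " alignment(s) outside 18-30 nt rejected")
    al <- al[!bad]
  }
  h <- al[, .(reads = sum(read_count)), by = .(length = len)]
  out <- h[grid, on = "length"]
  out[is.na(reads), reads := 0L]
  setorder(out, length)[]
}

#' Select 24-nt siRNA alignments and their covered regions
#'
#' @param alignments Alignment table.
#' @return List with `alignments` (length-24 subset) and `covered` (the
#'   interval union of the retained alignments: data.table chrom, start,
#'   end, disjoint and sorted).
#' @export
filter_24nt <- function(alignments) {
  al <- as.data.table(alignments)
  keep <- al[end - start == 24L]
  if (nrow(keep) == 0) {
    return(list(alignments = keep,
                covered = data.table(chrom = character(), start = integer(),
                                     end = integer())))
  }
  gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    keep$chrom, IRanges::IRanges(keep$start + 1L, keep$end)))
  covered <- data.table(chrom = as.character(GenomicRanges::seqnames(gr)),
                        start = GenomicRanges::start(gr) - 1L,
                        end = GenomicRanges::end(gr))
  setorder(covered, chrom, start)
  list(alignments = keep[], covered = covered[])
}

#' siRNA abundance profile over TEs and flanks
#'
#' Read-count-weighted per-bin totals over the upstream-flank / scaled-body
#' / downstream-flank coordinate system, using the same binning engine as
#' the methylation profiles ([bin_positions()]); alignments are assigned to
#' bins by their midpoint.
#'
#' @param alignments_24 Length-filtered alignments (see [filter_24nt()]).
#' @param tes TE table (id, chrom, start, end, strand).
#' @param flank,flank_bin,body_bins See [bin_positions()].
#' @param strand_aware Flip minus-strand TEs.
#' @return data.table bin_class, bin_idx, reads; attribute `n_features`.
#' @export
sirna_te_profile <- function(alignments_24, tes, flank = 2000L,
                             flank_bin = 100L, body_bins = 20L,
                             strand_aware = TRUE) {
  al <- as.data.table(alignments_24)
  pts <- al[, .(chrom, pos = (start + end) %/% 2L, weight = read_count)]
  b <- bin_positions(pts, tes, flank = flank, flank_bin = flank_bin,
                     body_bins = body_bins, strand_aware = strand_aware,
                     mode = "point")
  agg <- b[, .(reads = sum(weight * frac)), by = .(bin_class, bin_idx)]
  grid <- .profile_grid(flank, flank_bin, body_bins)
  out <- agg[grid, on = c("bin_class", "bin_idx")]
  out[is.na(reads), reads := 0]
  setattr(out, "n_features", nrow(as.data.table(tes)))
  out[]
}

#' Methylation of siRNA-covered versus uncovered regions
#'
#' Per context, the weighted methylation level inside the covered-region
#' union is compared with the level outside it; significance is assessed by
#' a two-sided Wilcoxon rank-sum test of per-region levels against levels
#' of matched random uncovered segments (same number, same length
#' distribution, drawn deterministically from `seed`).
#'
#' @param cytosines Cytosine table.
#' @param covered_regions `covered` component of [filter_24nt()].
#' @param chrom_lengths Named chromosome lengths (sampling space for the
#'   matched segments).
#' @param n_segments Number of matched uncovered segments (resampled with
#'   replacement from the covered length distribution).
#' @param seed RNG seed for segment placement.
#' @return data.table context, level_covered, level_uncovered, pval.
#'   NULL (with a warning) when the covered set is empty or covers
#'   everything.
#' @export
sirna_methylation_association <- function(cytosines, covered_regions,
                                          chrom_lengths, n_segments = 1000L,
                                          seed = 1L) {
  cov_dt <- as.data.table(covered_regions)
  if (nrow(cov_dt) == 0) {
    warning("empty covered set; association undefined")
    return(NULL)
  }
  if (sum(cov_dt$end - cov_dt$start) >= sum(chrom_lengths)) {
    warning("covered regions span the whole genome; comparison skipped")
    return(NULL)
  }
  cy <- as.data.table(cytosines)[context %in% c("CG", "CHG", "CHH") & total > 0]
  cov_gr <- GenomicRanges::GRanges(cov_dt$chrom,
                                   IRanges::IRanges(cov_dt$start + 1L, cov_dt$end))
  cy_gr <- GenomicRanges::GRanges(cy$chrom, IRanges::IRanges(cy$pos + 1L, width = 1L))
  inside <- GenomicRanges::countOverlaps(cy_gr, cov_gr) > 0
  lev <- function(d) d[, .(level = sum(meth) / sum(total)), by = context]
  li <- lev(cy[inside]); lo <- lev(cy[!inside])

  ## per-region levels for the covered set
  hits <- GenomicRanges::findOverlaps(cy_gr, cov_gr)
  per_cov <- cy[S4Vectors::queryHits(hits)][
    , region_id := S4Vectors::subjectHits(hits)][
    , .(level = sum(meth) / sum(total)), by = .(region_id, context)]

  ## matched-length random segments in uncovered space
  set.seed(seed)
  lens <- sample(cov_dt$end - cov_dt$start, n_segments, replace = TRUE)
  chs <- sample(names(chrom_lengths), n_segments, replace = TRUE,
                prob = chrom_lengths / sum(chrom_lengths))
  starts <- floor(runif(n_segments) * pmax(1, chrom_lengths[chs] - lens))
  seg <- data.table(chrom = chs, start = as.integer(starts),
                    end = as.integer(starts + lens))
  seg_gr <- GenomicRanges::GRanges(seg$chrom,
                                   IRanges::IRanges(seg$start + 1L, seg$end))
  ## keep only segments not touching covered space
  clean <- GenomicRanges::countOverlaps(seg_gr, cov_gr) == 0
  seg_gr <- seg_gr[clean]
  sh <- GenomicRanges::findOverlaps(cy_gr, seg_gr)
  per_seg <- cy[S4Vectors::queryHits(sh)][
    , region_id := S4Vectors::subjectHits(sh)][
    , .(level = sum(meth) / sum(total)), by = .(region_id, context)]

  out <- lapply(c("CG", "CHG", "CHH"), function(ctx) {
    x <- per_cov[context == ctx, level]
    y <- per_seg[context == ctx, level]
    p <- if (length(x) >= 1 && length(y) >= 1) {
      wilcoxon_rank_sum(x, y, alternative = "two.sided")$p
    } else NA_real_
    data.table(context = ctx,
               level_covered = if (nrow(li[context == ctx])) li[context == ctx, level] else NA_real_,
               level_uncovered = if (nrow(lo[context == ctx])) lo[context == ctx, level] else NA_real_,
               pval = p)
  })
  rbindlist(out)[]
}
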