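## Differentially methylated region calling between two samples.
##
## The caller follows a six-criterion definition per context:
##   (1) at least `min_mC_per_region` methylated cytosines in at least one
##       sample (optionally in both),
##   (2) every member cytosine covered by >= `min_cov` reads in both samples,
##   (3) region length between `min_len` and `max_len`,
##   (4) adjacent member cytosines less than `max_gap` apart,
##   (5) change of the pooled (weighted) methylation level >= `min_fold`,
##   (6) Pearson chi-square p-value on the pooled 2x2 read-count table at
##       most `p_cut` (and BH FDR < `fdr_cut` across tested regions when
##       `use_fdr` is on).

#' DMR calling parameters
#'
#' @param min_mC_per_region Minimum called methylated cytosines a region
#'   must have in at least one sample.
#' @param min_cov Minimum per-site coverage required in both samples.
#' @param min_len,max_len Region length bounds in bp.
#' @param max_gap Maximum distance (exclusive) between adjacent qualifying
#'   cytosines within a region.
#' @param min_fold Minimum fold change of the pooled level (boundary
#'   inclusive).
#' @param p_cut Chi-square p-value cutoff (boundary inclusive).
#' @param use_fdr Additionally require BH FDR below `fdr_cut`.
#' @param fdr_cut FDR cutoff (strict).
#' @param require_both_samples Require `min_mC_per_region` called mCs in
#'   both samples instead of at least one.
#' @param error_rate Bisulfite conversion failure rate used for the
#'   per-sample methylated-site calls.
#' @param site_alpha BH level for the site calls.
#' @return A `dmr_params` list.
#' @export
dmr_params <- function(min_mC_per_region = 5L, min_cov = 4L, min_len = 40L,
                       max_len = 10000L, max_gap = 200L, min_fold = 2,
                       p_cut = 0.05, use_fdr = TRUE, fdr_cut = 0.05,
                       require_both_samples = FALSE, error_rate = 0.004,
                       site_alpha = 0.01) {
  stopifnot(min_len <= max_len, min_fold > 1, p_cut > 0, p_cut < 1,
            fdr_cut > 0, fdr_cut < 1)
  structure(list(min_mC_per_region = min_mC_per_region, min_cov = min_cov,
                 min_len = min_len, max_len = max_len, max_gap = max_gap,
                 min_fold = min_fold, p_cut = p_cut, use_fdr = use_fdr,
                 fdr_cut = fdr_cut,
                 require_both_samples = require_both_samples,
                 error_rate = error_rate, site_alpha = site_alpha),
            class = "dmr_params")
}

## join the two samples on position and add per-sample site calls
.paired_sites <- function(sample_a, sample_b, params) {
  a <- as.data.table(sample_a)
  b <- as.data.table(sample_b)
  if (!"methylated" %in% names(a)) {
    a <- call_methylated_sites(a, params$error_rate, min_cov = params$min_cov,
                               alpha = params$site_alpha)
  }
  if (!"methylated" %in% names(b)) {
    b <- call_methylated_sites(b, params$error_rate, min_cov = params$min_cov,
                               alpha = params$site_alpha)
  }
  keyc <- c("chrom", "pos", "strand", "context")
  m <- merge(a[, c(keyc, "meth", "total", "methylated"), with = FALSE],
             b[, c(keyc, "meth", "total", "methylated"), with = FALSE],
             by = keyc, suffixes = c("_a", "_b"))
  n_only <- nrow(a) + nrow(b) - 2L * nrow(m)
  if (n_only > 0) {
    message(n_only, " position(s) present in only one sample were skipped")
  }
  setnames(m, c("methylated_a", "methylated_b"), c("called_a", "called_b"))
  m
}

## split an over-long chain at its largest internal gap, recursively
.split_chain <- function(pos_vec, max_len) {
  span <- pos_vec[length(pos_vec)] + 1L - pos_vec[1L]
  if (span <= max_len || length(pos_vec) < 2L) return(list(pos_vec))
  gaps <- diff(pos_vec)
  cut <- which.max(gaps)  # first largest gap
  c(.split_chain(pos_vec[seq_len(cut)], max_len),
    .split_chain(pos_vec[seq.int(cut + 1L, length(pos_vec))], max_len))
}

#' Candidate DMR regions for one context
#'
#' Qualifying cytosines (coverage at least `min_cov` in both samples,
#' called methylated in at least one) are chained whenever adjacent
#' qualifying positions are less than `max_gap` apart; chains shorter than
#' `min_len`, longer than `max_len` (split at the largest internal gap,
#' recursively) or with fewer than `min_mC_per_region` called mCs in every
#' sample are dropped. The pooled read counts reported for each region (and
#' used by [test_regions()]) cover every context cytosine in the region
#' span with adequate coverage in both samples, not only the qualifying
#' sites: the region's average methylation level is a property of the
#' region, and conditioning it on the sites that triggered discovery
#' inflates apparent differences on null data.
#'
#' @param sample_a,sample_b Cytosine tables (sample A is typically the
#'   treatment, e.g. low-P). Tables may carry precomputed `methylated`
#'   columns; otherwise sites are called with the params' error rate.
#' @param context Context to scan.
#' @param params A [dmr_params()] list.
#' @param paired Optional precomputed output of the internal pairing step
#'   (used by [call_dmrs()] to avoid recomputation).
#' @return data.table of candidate regions: chrom, start, end, n_sites,
#'   n_mc_a, n_mc_b, meth_a, total_a, meth_b, total_b.
#' @export
candidate_regions <- function(sample_a, sample_b, context, params = dmr_params(),
                              paired = NULL) {
  ctx <- context
  m <- if (is.null(paired)) .paired_sites(sample_a, sample_b, params) else paired
  q <- m[context == ctx & total_a >= params$min_cov & total_b >= params$min_cov &
           (called_a | called_b)]
  if (nrow(q) == 0) {
    return(data.table(chrom = character(), start = integer(), end = integer(),
                      n_sites = integer(), n_mc_a = integer(), n_mc_b = integer(),
                      meth_a = integer(), total_a = integer(),
                      meth_b = integer(), total_b = integer()))
  }
  setorder(q, chrom, pos)
  q[, chain := cumsum(c(1L, diff(pos) >= params$max_gap | diff(pos) < 0L)),
    by = chrom]
  pieces <- q[, {
    parts <- .split_chain(pos, params$max_len)
    idx <- rep(seq_along(parts), lengths(parts))
    .(pos = unlist(parts), piece = idx,
      called_a = called_a, called_b = called_b)
  }, by = .(chrom, chain)]
  reg <- pieces[, .(start = min(pos), end = max(pos) + 1L, n_sites = .N,
                    n_mc_a = sum(called_a), n_mc_b = sum(called_b)),
                by = .(chrom, chain, piece)]
  reg[, len := end - start]
  keep_mc <- if (isTRUE(params$require_both_samples)) {
    reg$n_mc_a >= params$min_mC_per_region & reg$n_mc_b >= params$min_mC_per_region
  } else {
    reg$n_mc_a >= params$min_mC_per_region | reg$n_mc_b >= params$min_mC_per_region
  }
  reg <- reg[keep_mc & len >= params$min_len & len <= params$max_len]
  reg[, c("chain", "piece", "len") := NULL]
  ## pooled counts over all adequately covered context cytosines in the span
  covered <- m[context == ctx & total_a >= params$min_cov &
                 total_b >= params$min_cov]
  pooled <- covered[reg, on = .(chrom, pos >= start, pos < end),
                    .(meth_a = sum(x.meth_a), total_a = sum(x.total_a),
                      meth_b = sum(x.meth_b), total_b = sum(x.total_b)),
                    by = .EACHI]
  reg[, `:=`(meth_a = pooled$meth_a, total_a = pooled$total_a,
             meth_b = pooled$meth_b, total_b = pooled$total_b)]
  setorder(reg, chrom, start)[]
}

#' Test candidate regions for differential methylation
#'
#' Pools reads across member cytosines per sample into a 2x2 table
#' (methylated vs unmethylated x sample), computes the uncorrected Pearson
#' chi-square and the fold change of the weighted levels. When either pooled
#' level is zero, a pseudocount of 0.5 reads per cell guards the fold
#' change. Regions with a zero marginal are rejected (statistic undefined).
#'
#' @param regions Output of [candidate_regions()].
#' @param params A [dmr_params()] list.
#' @return The regions with level_a, level_b, fold_change, chi2, pval and
#'   direction added; untestable regions are dropped.
#' @export
test_regions <- function(regions, params = dmr_params()) {
  reg <- copy(as.data.table(regions))
  if (nrow(reg) == 0) {
    reg[, `:=`(level_a = numeric(0), level_b = numeric(0),
               fold_change = numeric(0), chi2 = numeric(0), pval = numeric(0),
               direction = character(0))]
    return(reg[])
  }
  a <- reg$meth_a; b <- reg$total_a - reg$meth_a
  c_ <- reg$meth_b; d <- reg$total_b - reg$meth_b
  testable <- reg$total_a > 0 & reg$total_b > 0 &
    (a + c_) > 0 & (b + d) > 0
  n_drop <- sum(!testable)
  if (n_drop > 0) message(n_drop, " region(s) with a zero marginal rejected")
  reg <- reg[testable]
  a <- a[testable]; b <- b[testable]; c_ <- c_[testable]; d <- d[testable]
  cs <- chi_square_2x2_vec(a, b, c_, d)
  la <- reg$meth_a / reg$total_a
  lb <- reg$meth_b / reg$total_b
  zero <- la == 0 | lb == 0
  la_f <- ifelse(zero, (reg$meth_a + 0.5) / (reg$total_a + 1), la)
  lb_f <- ifelse(zero, (reg$meth_b + 0.5) / (reg$total_b + 1), lb)
  ratio <- la_f / lb_f
  reg[, `:=`(level_a = la, level_b = lb,
             fold_change = pmax(ratio, 1 / ratio),
             chi2 = cs$statistic, pval = cs$p,
             direction = ifelse(la >= lb, "hyper", "hypo"))]
  reg[]
}

#' Call DMRs between two samples
#'
#' Runs [candidate_regions()] and [test_regions()] per context, computes BH
#' q-values across all tested regions of a context, and returns the regions
#' passing the fold-change, p-value and (optionally) FDR gates, sorted by
#' coordinate. The `direction` is that of sample A relative to sample B
#' (hyper = higher methylation in A).
#'
#' @param sample_a,sample_b Cytosine tables (A = treatment, B = control).
#' @param params A [dmr_params()] list.
#' @param contexts Contexts to scan.
#' @param keep_tested Also return all tested regions (attribute `tested`).
#' @return data.table of DMRs: chrom, start, end, context, n_sites, n_mc_a,
#'   n_mc_b, level_a, level_b, fold_change, chi2, pval, qval, direction.
#' @export
call_dmrs <- function(sample_a, sample_b, params = dmr_params(),
                      contexts = c("CG", "CHG", "CHH"), keep_tested = FALSE) {
  paired <- .paired_sites(sample_a, sample_b, params)
  tested_all <- list()
  for (ctx in contexts) {
    cand <- candidate_regions(NULL, NULL, ctx, params, paired = paired)
    tst <- test_regions(cand, params)
    if (nrow(tst) > 0) {
      tst[, context := ctx]
      tst[, qval := bh_fdr(pval)]
      tested_all[[ctx]] <- tst
    }
  }
  if (length(tested_all) == 0) {
    empty <- data.table(chrom = character(), start = integer(), end = integer(),
                        context = character(), n_sites = integer(),
                        n_mc_a = integer(), n_mc_b = integer(),
                        meth_a = integer(), total_a = integer(),
                        meth_b = integer(), total_b = integer(),
                        level_a = numeric(), level_b = numeric(),
                        fold_change = numeric(), chi2 = numeric(),
                        pval = numeric(), qval = numeric(),
                        direction = character())
    if (keep_tested) setattr(empty, "tested", copy(empty))
    return(empty)
  }
  tested <- rbindlist(tested_all, use.names = TRUE)
  dmrs <- tested[fold_change >= params$min_fold & pval <= params$p_cut]
  if (isTRUE(params$use_fdr)) dmrs <- dmrs[qval < params$fdr_cut]
  setorder(dmrs, chrom, start)
  setcolorder(dmrs, c("chrom", "start", "end", "context", "n_sites"))
  if (keep_tested) setattr(dmrs, "tested", tested)
  dmrs[]
}

#' Independently audit called DMRs against the six criteria
#'
#' Re-verifies every reported DMR from the raw cytosine tables through a
#' separate code path: member qualification, adjacency gaps, length bounds,
#' mC counts, fold change, and the chi-square via [stats::chisq.test()]
#' (uncorrected). Intended as a correctness harness for the caller.
#'
#' @param dmrs Output of [call_dmrs()].
#' @param sample_a,sample_b The cytosine tables used for calling.
#' @param params The [dmr_params()] used.
#' @return Logical vector, one entry per DMR, TRUE when all criteria hold.
#' @export
audit_dmrs <- function(dmrs, sample_a, sample_b, params = dmr_params()) {
  m <- .paired_sites(sample_a, sample_b, params)
  vapply(seq_len(nrow(dmrs)), function(i) {
    d <- dmrs[i]
    cv <- m[chrom == d$chrom & pos >= d$start & pos < d$end &
              context == d$context &
              total_a >= params$min_cov & total_b >= params$min_cov]
    s <- cv[called_a | called_b]
    if (nrow(s) == 0) return(FALSE)
    len <- d$end - d$start
    ok_len <- len >= params$min_len && len <= params$max_len
    ok_gap <- all(diff(sort(s$pos)) < params$max_gap)
    ok_mc <- if (isTRUE(params$require_both_samples)) {
      sum(s$called_a) >= params$min_mC_per_region &&
        sum(s$called_b) >= params$min_mC_per_region
    } else {
      max(sum(s$called_a), sum(s$called_b)) >= params$min_mC_per_region
    }
    ta <- sum(cv$total_a); tb <- sum(cv$total_b)
    ma <- sum(cv$meth_a); mb <- sum(cv$meth_b)
    la <- ma / ta; lb <- mb / tb
    if (la == 0 || lb == 0) {
      la <- (ma + 0.5) / (ta + 1); lb <- (mb + 0.5) / (tb + 1)
    }
    fold <- max(la / lb, lb / la)
    tab <- rbind(c(ma, ta - ma), c(mb, tb - mb))
    p <- suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
    ok_len && ok_gap && ok_mc && fold >= params$min_fold && p <= params$p_cut
  }, logical(1))
}

#' Write DMRs as a BED6+ table
#'
#' Columns: chrom, start, end, name (`context:direction`), score
#' (`-log10 q`, capped at 1000), strand (`.`), then level_a, level_b,
#' fold_change, pval, qval.
#'
#' @param dmrs Output of [call_dmrs()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_dmr_bed <- function(dmrs, path) {
  d <- as.data.table(dmrs)
  out <- data.table(chrom = d$chrom, start = d$start, end = d$end,
                    name = paste0(d$context, ":", d$direction),
                    score = round(pmin(1000, -log10(pmax(d$qval, 1e-300))), 2),
                    strand = ".",
                    level_a = signif(d$level_a, 6), level_b = signif(d$level_b, 6),
                    fold_change = signif(d$fold_change, 6),
                    pval = signif(d$pval, 6), qval = signif(d$qval, 6))
  fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
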