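## DMR-to-feature assignment, differentially methylated gene/TE sets,
## set overlaps, hypergeometric term enrichment, and expression comparison
## of DMG classes.

.gene_region_windows <- function(genes, flank) {
  g <- as.data.table(genes)
  minus <- g$strand == "-"
  rbind(
    data.table(feature_id = g$id, chrom = g$chrom, klass = "gene_body",
               start = g$start, end = g$end),
    data.table(feature_id = g$id, chrom = g$chrom, klass = "upstream_2kb",
               start = ifelse(minus, g$end, pmax(g$start - flank, 0L)),
               end = ifelse(minus, g$end + flank, g$start)),
    data.table(feature_id = g$id, chrom = g$chrom, klass = "downstream_2kb",
               start = ifelse(minus, pmax(g$start - flank, 0L), g$end),
               end = ifelse(minus, g$start, g$end + flank)))[end > start]
}

#' Assign DMRs to genomic location classes and collect DMG sets
#'
#' A DMR is associated with every gene whose body or strand-aware 2-kb
#' flank it overlaps by at least one bp, and with every TE it overlaps. The
#' single reported location class per DMR is the class with the largest
#' overlap in bp; ties are broken by the precedence
#' `gene_body > upstream_2kb > downstream_2kb > te`; DMRs overlapping
#' nothing are `intergenic`.
#'
#' @param dmrs Output of [call_dmrs()] (needs chrom, start, end, context,
#'   direction).
#' @param annotation A `feature_annotation`.
#' @param flank Flank width (default 2000).
#' @param precedence Tie-break order of location classes.
#' @return List with `locations` (dmr_id, chrom, start, end, context,
#'   direction, location_class, feature_id), `associations` (one row per
#'   DMR-feature pair with klass) and `dmg` (gene_id, context, direction,
#'   unique).
#' @export
assign_dmrs <- function(dmrs, annotation, flank = 2000L,
                        precedence = c("gene_body", "upstream_2kb",
                                       "downstream_2kb", "te")) {
  d <- copy(as.data.table(dmrs))
  d[, dmr_id := seq_len(.N)]
  win <- rbind(.gene_region_windows(annotation$genes, flank),
               if (nrow(annotation$tes) > 0) {
                 data.table(feature_id = annotation$tes$id,
                            chrom = annotation$tes$chrom, klass = "te",
                            start = annotation$tes$start,
                            end = annotation$tes$end)
               })
  if (nrow(d) == 0 || is.null(win) || nrow(win) == 0) {
    locations <- d[, .(dmr_id, chrom, start, end,
                       context = if (nrow(d)) context else character(0),
                       direction = if (nrow(d)) direction else character(0))]
    locations[, `:=`(location_class = rep("intergenic", .N),
                     feature_id = rep(NA_character_, .N))]
    return(list(locations = locations[],
                associations = data.table(dmr_id = integer(),
                                          feature_id = character(),
                                          klass = character(),
                                          overlap_bp = integer()),
                dmg = data.table(gene_id = character(), context = character(),
                                 direction = character())))
  }
  d_gr <- GenomicRanges::GRanges(d$chrom, IRanges::IRanges(d$start + 1L, d$end))
  w_gr <- GenomicRanges::GRanges(win$chrom, IRanges::IRanges(win$start + 1L, win$end))
  hits <- GenomicRanges::findOverlaps(d_gr, w_gr)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  ov <- pmin(d$end[qi], win$end[si]) - pmax(d$start[qi], win$start[si])
  assoc <- data.table(dmr_id = d$dmr_id[qi], feature_id = win$feature_id[si],
                      klass = win$klass[si], overlap_bp = ov)
  ## primary class: largest overlap, ties by precedence
  best <- copy(assoc)
  best[, klass := factor(klass, levels = precedence)]
  setorder(best, dmr_id, -overlap_bp, klass, feature_id)
  best <- best[, .SD[1L], by = dmr_id]
  locations <- best[d, on = "dmr_id"]
  locations[is.na(klass), klass := factor("intergenic",
                                          levels = c(precedence, "intergenic"))]
  locations[, location_class := as.character(klass)]
  locations[location_class == "intergenic", feature_id := NA_character_]
  locations <- locations[, .(dmr_id, chrom, start, end, context, direction,
                             location_class, feature_id)]
  gene_assoc <- assoc[klass != "te"]
  dmg <- unique(gene_assoc[d, on = "dmr_id", nomatch = NULL][
    , .(gene_id = feature_id, context, direction)])
  list(locations = locations[], associations = assoc[], dmg = dmg[])
}

#' Differentially methylated TE sets
#'
#' A TE is hypermethylated (hypomethylated) in a context when it overlaps at
#' least one hyper (hypo) DMR of that context by one bp or more; a TE can be
#' in both sets (different regions), reported separately.
#'
#' @param dmrs Output of [call_dmrs()].
#' @param annotation A `feature_annotation` with a TE track.
#' @return List with `sets` (data.table te_id, context, direction) and
#'   `summary` (counts per context, direction and TE class).
#' @export
dm_te_sets <- function(dmrs, annotation) {
  te <- annotation$tes
  if (nrow(te) == 0) stop("annotation has no TE track")
  d <- as.data.table(dmrs)
  if (nrow(d) == 0) {
    return(list(sets = data.table(te_id = character(), context = character(),
                                  direction = character()),
                summary = data.table(context = character(),
                                     direction = character(),
                                     te_class = character(), n = integer())))
  }
  d_gr <- GenomicRanges::GRanges(d$chrom, IRanges::IRanges(d$start + 1L, d$end))
  t_gr <- GenomicRanges::GRanges(te$chrom, IRanges::IRanges(te$start + 1L, te$end))
  hits <- GenomicRanges::findOverlaps(d_gr, t_gr)
  sets <- unique(data.table(
    te_id = te$id[S4Vectors::subjectHits(hits)],
    context = d$context[S4Vectors::queryHits(hits)],
    direction = d$direction[S4Vectors::queryHits(hits)]))
  cls <- te[, .(te_id = id, te_class)]
  summary <- sets[cls, on = "te_id", nomatch = NULL][
    , .(n = .N), by = .(context, direction, te_class)]
  list(sets = sets[], summary = summary[])
}

#' Exact Venn decomposition of named sets
#'
#' @param sets Named list of at least two vectors.
#' @return data.table with one row per non-empty membership signature:
#'   `signature` (e.g. "A&B"), `n`, and `members` (list column).
#' @export
venn_sets <- function(sets) {
  if (length(sets) < 2L) stop("need at least two sets")
  if (is.null(names(sets)) || any(names(sets) == "")) stop("sets must be named")
  universe <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1,
                                               dimnames = list(NULL, names(sets)))
  sig <- apply(member, 1L, function(r) paste(names(sets)[r], collapse = "&"))
  dt <- data.table(element = universe, signature = sig)
  dt[, .(n = .N, members = list(element)), by = signature][]
}

#' Hypergeometric term enrichment
#'
#' For each term, tests over-representation of the study set within the
#' term's genes against the universe: `k` = study genes with the term,
#' `K` = universe genes with the term, `n` = study size, `N` = universe
#' size, p = upper hypergeometric tail, BH-corrected across terms. Genes
#' absent from the universe are dropped from terms first.
#'
#' @param study_set Character vector of gene ids (subset of the universe).
#' @param universe Character vector of gene ids.
#' @param term_map data.table with columns term_id, gene_id.
#' @param min_K Terms with fewer than this many universe genes are skipped.
#' @param q_cut Enrichment threshold on the q-value (inclusive).
#' @return data.table term_id, k, K, n, N, pval, qval, enriched.
#' @export
term_enrichment <- function(study_set, universe, term_map, min_K = 3L,
                            q_cut = 0.05) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty universe")
  study_set <- unique(study_set)
  if (!all(study_set %in% universe)) stop("study_set must be within the universe")
  tm <- unique(as.data.table(term_map)[, .(term_id, gene_id)])
  tm <- tm[gene_id %in% universe]
  n_study <- length(study_set); n_universe <- length(universe)
  terms <- tm[, .(K = .N, k = sum(gene_id %in% study_set)), by = term_id]
  terms <- terms[K >= min_K]
  if (nrow(terms) == 0) {
    return(data.table(term_id = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), pval = numeric(),
                      qval = numeric(), enriched = logical()))
  }
  terms[, `:=`(n = n_study, N = n_universe)]
  terms[, pval := mapply(hypergeometric_tail, k = terms$k, K = terms$K,
                         MoreArgs = list(n = n_study, N = n_universe))]
  terms[, qval := bh_fdr(pval)]
  terms[, enriched := qval <= q_cut]
  setorder(terms, pval)[]
}

#' Overlap classes between DMGs and DEGs
#'
#' @param dmg data.table gene_id, direction (hyper/hypo), optionally
#'   filtered to one context.
#' @param degs Output of [call_degs()].
#' @return List of gene-id vectors `hyper_down`, `hypo_up`, `hyper_up`,
#'   `hypo_down` and a `counts` data.table.
#' @export
dmg_deg_overlap <- function(dmg, degs) {
  dm <- as.data.table(dmg)
  de <- as.data.table(degs)
  hyper <- unique(dm[direction == "hyper", gene_id])
  hypo <- unique(dm[direction == "hypo", gene_id])
  up <- de[status == "up", gene_id]
  down <- de[status == "down", gene_id]
  out <- list(hyper_down = intersect(hyper, down),
              hypo_up = intersect(hypo, up),
              hyper_up = intersect(hyper, up),
              hypo_down = intersect(hypo, down))
  out$counts <- data.table(class = names(out)[1:4],
                           n = vapply(out[1:4], length, integer(1)))
  out
}

#' Expression-level comparison of DMG classes against all genes
#'
#' Computes boxplot statistics (quartiles) of `log10(FPKM + 1e-3)` for all
#' genes and for the hyper-/hypomethylated gene classes of one context, and
#' a two-sided Wilcoxon rank-sum p-value of each class against all genes.
#'
#' @param dmg data.table gene_id, context, direction.
#' @param fpkm_table data.table gene_id, fpkm (all genes).
#' @param context Context to summarise.
#' @param eps Pseudocount for the log transform.
#' @return data.table class, n, q1, median, q3, pval (NA for the reference
#'   class "all"); empty classes are omitted.
#' @export
dmg_expression_comparison <- function(dmg, fpkm_table, context = "CG",
                                      eps = 1e-3) {
  ctx <- context
  ft <- as.data.table(fpkm_table)
  all_expr <- log10(ft$fpkm + eps)
  dm <- as.data.table(dmg)[context == ctx]
  rows <- list(data.table(class = "all", n = length(all_expr),
                          q1 = unname(stats::quantile(all_expr, 0.25)),
                          median = stats::median(all_expr),
                          q3 = unname(stats::quantile(all_expr, 0.75)),
                          pval = NA_real_))
  for (dir in c("hyper", "hypo")) {
    ids <- unique(dm[direction == dir, gene_id])
    x <- log10(ft[gene_id %in% ids, fpkm] + eps)
    if (length(x) == 0) next
    w <- wilcoxon_rank_sum(x, all_expr, alternative = "two.sided")
    rows[[dir]] <- data.table(class = dir, n = length(x),
                              q1 = unname(stats::quantile(x, 0.25)),
                              median = stats::median(x),
                              q3 = unname(stats::quantile(x, 0.75)),
                              pval = w$p)
  }
  rbindlist(rows)[]
}
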