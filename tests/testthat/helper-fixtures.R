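## Small deterministic fixtures shared across test files.

## genome with one short chromosome from an explicit sequence
tiny_genome <- function(seqs, spike = NULL) {
  genome_sequence(seqs, spike_in_chrom = spike)
}

## cytosine table builder (0-based internal positions)
cyt <- function(chrom, pos, strand = "+", context = "CG", meth, total) {
  data.table::data.table(chrom = chrom, pos = as.integer(pos), strand = strand,
                         context = context, meth = as.integer(meth),
                         total = as.integer(total))
}

## evenly spaced, deeply covered CG sites over [0, len) at a fixed level
uniform_cytosines <- function(chrom = "chr1", len = 1000L, by = 10L,
                              level = 0.5, total = 1000L, context = "CG",
                              strand = "+") {
  pos <- seq.int(0L, len - 1L, by = by)
  cyt(chrom, pos, strand, context, meth = round(level * total), total = total)
}

## a one-gene annotation
one_gene_annotation <- function(start = 5000L, end = 6000L, strand = "+",
                                chrom_len = 20000L, te = NULL) {
  genes <- data.table::data.table(id = "g1", chrom = "chr1", start = start,
                                  end = end, strand = strand)
  tes <- if (is.null(te)) {
    data.table::data.table(id = character(), chrom = character(),
                           start = integer(), end = integer(),
                           strand = character(), superfamily = character())
  } else te
  feature_annotation(genes, tes, c(chr1 = chrom_len))
}

## paired cytosine tables for DMR tests: same positions, given per-sample
## methylated read counts, constant coverage
dmr_pair <- function(pos, meth_a, meth_b, total = 10L, context = "CHH",
                     chrom = "chr1") {
  list(a = cyt(chrom, pos, "+", context, meth = meth_a, total = total),
       b = cyt(chrom, pos, "+", context, meth = meth_b, total = total))
}
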