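## File formats and coordinate conventions.
##
## Internal convention everywhere in the package: 0-based half-open
## intervals, and 0-based cytosine positions. GFF3 (1-based closed) and the
## methratio-style cytosine TSV (1-based positions) are converted at the I/O
## boundary.

#' Read a genome FASTA file
#'
#' Loads all records with [Biostrings::readDNAStringSet()], uppercases the
#' sequence and validates that only A, C, G, T, N occur.
#'
#' @param path FASTA file.
#' @param spike_in_chrom Optional name of a fully unmethylated control
#'   chromosome (e.g. the lambda phage spike-in) present in the file.
#' @return A `genome_sequence` object: list with `seq` (a `DNAStringSet`) and
#'   `spike_in_chrom`.
#' @export
read_fasta <- function(path, spike_in_chrom = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  ## read as raw strings so residue validation is ours, then build DNA
  seq <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                  error = function(e) stop("malformed FASTA in ", path, ": ",
                                           conditionMessage(e)))
  ## first token of the header is the chromosome name
  names(seq) <- sub("\\s.*$", "", names(seq))
  genome_sequence(stats::setNames(as.character(seq), names(seq)),
                  spike_in_chrom = spike_in_chrom)
}

#' Construct a genome_sequence object
#'
#' @param seq A named `DNAStringSet` or named character vector of sequences.
#' @param spike_in_chrom Optional unmethylated control chromosome name.
#' @return A `genome_sequence` object.
#' @export
genome_sequence <- function(seq, spike_in_chrom = NULL) {
  chars <- toupper(as.character(seq))
  names(chars) <- names(seq)
  if (is.null(names(chars)) || anyDuplicated(names(chars)) ||
      any(names(chars) == "")) {
    stop("chromosome names must be present and unique")
  }
  bad <- grepl("[^ACGTN]", chars)
  if (any(bad)) {
    stop("non-ACGTN residue in record(s): ",
         paste(names(chars)[bad], collapse = ", "))
  }
  if (!is.null(spike_in_chrom) && !spike_in_chrom %in% names(chars)) {
    stop("spike_in_chrom '", spike_in_chrom, "' not among chromosome names")
  }
  structure(list(seq = Biostrings::DNAStringSet(chars),
                 spike_in_chrom = spike_in_chrom),
            class = "genome_sequence")
}

#' @export
print.genome_sequence <- function(x, ...) {
  cat("genome_sequence:", length(x$seq), "chromosome(s),",
      sum(Biostrings::width(x$seq)), "bp total\n")
  if (!is.null(x$spike_in_chrom)) {
    cat("  unmethylated spike-in:", x$spike_in_chrom, "\n")
  }
  invisible(x)
}

#' Chromosome lengths of a genome
#' @param genome A `genome_sequence`.
#' @return Named integer vector of lengths.
#' @export
chrom_lengths <- function(genome) {
  stats::setNames(Biostrings::width(genome$seq), names(genome$seq))
}

#' Construct a feature annotation (genes and transposable elements)
#'
#' Coordinates are 0-based half-open. TE class is derived from the
#' superfamily label: retrotransposon superfamilies (`LTR/`, `LINE/`,
#' `SINE/`) are class I, DNA transposon superfamilies (`DNA/`, `RC/`,
#' `TIR/`) are class II.
#'
#' @param genes data.frame with columns id, chrom, start, end, strand.
#' @param tes data.frame with columns id, chrom, start, end, strand,
#'   superfamily (te_class derived if absent).
#' @param chrom_lengths Named vector of chromosome lengths.
#' @return A `feature_annotation` object.
#' @export
feature_annotation <- function(genes, tes, chrom_lengths) {
  genes <- as.data.table(genes)
  tes <- as.data.table(tes)
  if (nrow(tes) > 0 && !"te_class" %in% names(tes)) {
    tes[, te_class := te_class_of(superfamily)]
  }
  for (dt in list(genes, tes)) {
    if (nrow(dt) == 0) next
    if (anyDuplicated(dt$id)) stop("feature ids must be unique within a track")
    if (!all(dt$chrom %in% names(chrom_lengths))) {
      stop("feature chromosome absent from chrom_lengths")
    }
    if (any(dt$start < 0) || any(dt$end <= dt$start) ||
        any(dt$end > chrom_lengths[dt$chrom])) {
      stop("feature interval outside [0, chrom_length) or empty")
    }
  }
  structure(list(genes = genes[], tes = tes[],
                 chrom_lengths = chrom_lengths),
            class = "feature_annotation")
}

#' @export
print.feature_annotation <- function(x, ...) {
  cat("feature_annotation:", nrow(x$genes), "genes,", nrow(x$tes),
      "TEs on", length(x$chrom_lengths), "chromosome(s)\n")
  invisible(x)
}

#' TE class (I/II) from a superfamily label
#'
#' @param superfamily Character vector like `"LTR/Gypsy"`, `"DNA/MuDR"`.
#' @return `"I"` (retrotransposon) or `"II"` (DNA transposon).
#' @export
te_class_of <- function(superfamily) {
  prefix <- toupper(sub("/.*$", "", superfamily))
  cls <- rep(NA_character_, length(superfamily))
  cls[prefix %in% c("LTR", "LINE", "SINE")] <- "I"
  cls[prefix %in% c("DNA", "RC", "TIR")] <- "II"
  if (anyNA(cls)) {
    stop("unknown TE superfamily label(s): ",
         paste(unique(superfamily[is.na(cls)]), collapse = ", "))
  }
  cls
}

#' Read gene/TE annotation from GFF3 or BED
#'
#' GFF3 is read with [rtracklayer::import()] (1-based closed, converted to
#' 0-based half-open); genes come from feature type `gene`, TEs from
#' `transposable_element` with a `superfamily` attribute. The BED dialect is
#' 0-based half-open with columns chrom, start, end, name, score, strand and
#' an optional 7th column carrying `gene` or the TE superfamily.
#'
#' @param path Annotation file.
#' @param format `"gff3"` or `"bed"`.
#' @param chrom_lengths Named lengths; required for BED, inferred from the
#'   `##sequence-region` pragma or feature extents for GFF3 if missing.
#' @return A `feature_annotation`.
#' @export
read_annotation <- function(path, format = c("gff3", "bed"), chrom_lengths = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "gff3") {
    gr <- rtracklayer::import(path, format = "gff3")
    dt <- data.table(
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,   # to 0-based half-open
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      type = as.character(gr$type),
      id = if (!is.null(gr$ID)) as.character(gr$ID) else NA_character_,
      superfamily = if (!is.null(gr$superfamily)) as.character(gr$superfamily)
                    else NA_character_)
    if (is.null(chrom_lengths)) {
      sl <- GenomeInfoDb::seqlengths(gr)
      if (all(!is.na(sl))) chrom_lengths <- sl
      else chrom_lengths <- tapply(dt$end, dt$chrom, max)
    }
    genes <- dt[type == "gene", .(id, chrom, start, end, strand)]
    tes <- dt[type == "transposable_element",
              .(id, chrom, start, end, strand, superfamily)]
    if (nrow(tes) > 0 && anyNA(tes$superfamily)) {
      stop("transposable_element feature without superfamily attribute")
    }
  } else {
    dt <- fread(path, header = FALSE, sep = "\t")
    if (ncol(dt) < 6L) stop("BED annotation needs at least 6 columns")
    setnames(dt, seq_len(6L), c("chrom", "start", "end", "id", "score", "strand"))
    klass <- if (ncol(dt) >= 7L) as.character(dt[[7L]]) else rep("gene", nrow(dt))
    if (any(dt$end <= dt$start)) stop("BED interval with end <= start")
    if (is.null(chrom_lengths)) chrom_lengths <- tapply(dt$end, dt$chrom, max)
    is_gene <- klass == "gene"
    genes <- dt[is_gene, .(id, chrom, start, end, strand)]
    tes <- dt[!is_gene, .(id, chrom, start, end, strand)]
    tes[, superfamily := klass[!is_gene]]
  }
  feature_annotation(genes, tes, chrom_lengths)
}

#' Write annotation as GFF3
#'
#' Inverse of [read_annotation()] for the GFF3 dialect the package emits
#' (types `gene` and `transposable_element`, 1-based closed coordinates).
#'
#' @param annotation A `feature_annotation`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_annotation_gff3 <- function(annotation, path) {
  cl <- annotation$chrom_lengths
  hdr <- c("##gff-version 3",
           sprintf("##sequence-region %s 1 %d", names(cl), as.integer(cl)))
  fmt <- function(dt, type, attr) {
    if (nrow(dt) == 0) return(character(0))
    sprintf("%s\tmethylowp\t%s\t%d\t%d\t.\t%s\t.\t%s",
            dt$chrom, type, dt$start + 1L, dt$end, dt$strand, attr)
  }
  g <- fmt(annotation$genes, "gene", sprintf("ID=%s", annotation$genes$id))
  t <- fmt(annotation$tes, "transposable_element",
           sprintf("ID=%s;superfamily=%s", annotation$tes$id,
                   annotation$tes$superfamily))
  writeLines(c(hdr, g, t), path)
  invisible(path)
}

#' Annotate cytosine contexts from the genome sequence
#'
#' Every C on the plus strand and every G (a minus-strand cytosine) is
#' assigned a context from the two bases 3' of it on its own strand: CG if
#' the next base is G, CHG if the next is H (A/C/T) and the second-next is
#' G, CHH if both are H, and UNKNOWN when fewer than two downstream bases
#' exist or any involved base is N.
#'
#' @param genome A `genome_sequence`.
#' @param drop_unknown Drop UNKNOWN-context sites (default keeps them).
#' @return data.table with columns chrom, pos (0-based), strand, context.
#' @export
annotate_contexts <- function(genome, drop_unknown = FALSE) {
  out <- vector("list", length(genome$seq))
  for (i in seq_along(genome$seq)) {
    ch <- names(genome$seq)[i]
    s <- strsplit(as.character(genome$seq[[i]]), "", fixed = TRUE)[[1]]
    n <- length(s)
    plus <- which(s == "C")
    minus <- which(s == "G")
    ctx_p <- .context_from_followers(
      b1 = s[plus + 1L], b2 = s[plus + 2L],
      g_means_cg = TRUE, beyond1 = plus + 1L > n, beyond2 = plus + 2L > n)
    ## minus strand: own-strand downstream = decreasing plus coordinate,
    ## own-strand base is the complement of the plus-strand base, so the
    ## next base is G on the minus strand iff the plus base is C.
    ctx_m <- .context_from_followers(
      b1 = s[ifelse(minus - 1L >= 1L, minus - 1L, NA_integer_)],
      b2 = s[ifelse(minus - 2L >= 1L, minus - 2L, NA_integer_)],
      g_means_cg = FALSE, beyond1 = minus - 1L < 1L, beyond2 = minus - 2L < 1L)
    out[[i]] <- data.table(
      chrom = ch,
      pos = c(plus, minus) - 1L,
      strand = rep(c("+", "-"), c(length(plus), length(minus))),
      context = c(ctx_p, ctx_m))
  }
  res <- rbindlist(out)
  if (drop_unknown) res <- res[context != "UNKNOWN"]
  setkey(res, chrom, pos, strand)[]
}

## b1/b2: the two plus-strand bases flanking the site in the 3' direction of
## its strand. For the plus strand the own-strand bases ARE b1/b2; for the
## minus strand the own-strand bases are their complements, so "is G" tests
## become "is C" (g_means_cg = FALSE).
.context_from_followers <- function(b1, b2, g_means_cg, beyond1, beyond2) {
  gch <- if (g_means_cg) "G" else "C"
  ctx <- rep("UNKNOWN", length(b1))
  b1[beyond1] <- "N"; b2[beyond2] <- "N"
  b1[is.na(b1)] <- "N"; b2[is.na(b2)] <- "N"
  is_g1 <- b1 == gch
  is_h1 <- b1 != gch & b1 != "N"
  is_g2 <- b2 == gch
  is_h2 <- b2 != gch & b2 != "N"
  ctx[is_g1] <- "CG"                 # next base G: CG regardless of b2
  ctx[is_h1 & is_g2] <- "CHG"
  ctx[is_h1 & is_h2] <- "CHH"
  ctx
}

#' Read a per-cytosine methylation count table
#'
#' Methratio-style TSV with header columns `chrom, pos, strand, context,
#' meth_count, total_count`; positions in the file are 1-based and converted
#' to 0-based. If a genome is supplied the stated contexts are re-derived
#' from the sequence and mismatches are rejected.
#'
#' @param path TSV file.
#' @param genome Optional `genome_sequence` for context validation.
#' @return data.table with columns chrom, pos, strand, context, meth, total.
#' @export
read_cytosine_table <- function(path, genome = NULL) {
  dt <- fread(path, sep = "\t", header = TRUE)
  need <- c("chrom", "pos", "strand", "context", "meth_count", "total_count")
  if (!all(need %in% names(dt))) {
    stop("cytosine table must have header columns: ", paste(need, collapse = ", "))
  }
  out <- data.table(chrom = as.character(dt$chrom),
                    pos = as.integer(dt$pos) - 1L,
                    strand = as.character(dt$strand),
                    context = as.character(dt$context),
                    meth = as.integer(dt$meth_count),
                    total = as.integer(dt$total_count))
  validate_cytosines(out, genome = genome)
  out
}

#' Validate a cytosine table
#'
#' Checks count ordering, strand/context vocabulary and, when a genome is
#' given, agreement of the stated context with [annotate_contexts()].
#'
#' @param cytosines Table as returned by [read_cytosine_table()].
#' @param genome Optional `genome_sequence`.
#' @return The table, invisibly; errors describe offending rows.
#' @export
validate_cytosines <- function(cytosines, genome = NULL) {
  cy <- as.data.table(cytosines)
  if (any(cy$meth < 0) || any(cy$total < 0) || any(cy$meth > cy$total)) {
    bad <- which(cy$meth > cy$total | cy$meth < 0 | cy$total < 0)
    stop("meth_count > total_count (or negative) at row(s): ",
         paste(head(bad, 5), collapse = ", "))
  }
  if (!all(cy$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (!all(cy$context %in% c("CG", "CHG", "CHH", "UNKNOWN"))) {
    stop("context must be CG, CHG, CHH or UNKNOWN")
  }
  if (!is.null(genome)) {
    ref <- annotate_contexts(genome)
    m <- ref[cy, on = c("chrom", "pos", "strand")]
    if (anyNA(m$context)) {
      miss <- m[is.na(context), paste0(chrom, ":", pos + 1L, strand)]
      stop("position(s) are not cytosines in the genome: ",
           paste(head(miss, 5), collapse = ", "))
    }
    bad <- m$context != m$i.context
    if (any(bad)) {
      w <- m[which(bad), paste0(chrom, ":", pos + 1L, strand)]
      stop("stated context disagrees with genome at: ",
           paste(head(w, 5), collapse = ", "))
    }
  }
  invisible(cytosines)
}

#' Write a per-cytosine methylation count table
#'
#' Exact inverse of [read_cytosine_table()]: positions are written 1-based.
#'
#' @param cytosines Cytosine table (internal 0-based form).
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_cytosine_table <- function(cytosines, path) {
  cy <- as.data.table(cytosines)
  out <- data.table(chrom = cy$chrom, pos = cy$pos + 1L, strand = cy$strand,
                    context = cy$context, meth_count = cy$meth,
                    total_count = cy$total)
  fwrite(out, path, sep = "\t")
  invisible(path)
}
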