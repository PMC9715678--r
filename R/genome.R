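#' @import methods
#' @importFrom stats median quantile rpois rnbinom runif rbinom setNames
#'   cor cor.test lm coef p.adjust dbinom ks.test sd complete.cases
#' @importFrom utils head tail write.table read.table
#' @importFrom data.table data.table fread fwrite as.data.table setorder :=
#' @importFrom S4Vectors mcols mcols<- queryHits subjectHits Rle
#' @importFrom IRanges IRanges ranges width start end resize shift
#'   findOverlaps countOverlaps overlapsAny reduce
#' @importFrom GenomicRanges GRanges seqnames strand strand<- granges
#'   GRangesList makeGRangesFromDataFrame
#' @importFrom GenomeInfoDb Seqinfo seqlengths seqlevels keepSeqlevels
#'   seqinfo seqinfo<-
#' @importFrom Biostrings DNAString DNAStringSet readDNAStringSet
#'   writeXStringSet dinucleotideFrequency reverseComplement subseq
NULL

# ---------------------------------------------------------------------------
# Genome layout
# ---------------------------------------------------------------------------

#' Genome layout (chromosome sizes)
#'
#' A minimal description of the reference: a named vector of chromosome
#' lengths in bp. All coordinates handled by the package are validated
#' against it.
#'
#' @param chrom_sizes named numeric/integer vector of chromosome lengths (bp).
#' @return An object of class `GenomeLayout`.
#' @export
genome_layout <- function(chrom_sizes) {
  if (is.null(names(chrom_sizes)) || any(!nzchar(names(chrom_sizes))))
    stop("chrom_sizes must be a named vector")
  if (anyDuplicated(names(chrom_sizes)))
    stop("duplicated chromosome names in layout")
  sizes <- as.numeric(chrom_sizes)
  if (any(!is.finite(sizes)) || any(sizes <= 0))
    stop("all chromosome lengths must be positive")
  structure(list(chrom_sizes = setNames(sizes, names(chrom_sizes))),
            class = "GenomeLayout")
}

#' @export
print.GenomeLayout <- function(x, ...) {
  cat("GenomeLayout:", length(x$chrom_sizes), "chromosome(s),",
      format(sum(x$chrom_sizes), big.mark = ","), "bp total\n")
  invisible(x)
}

#' @rdname genome_layout
#' @param layout a `GenomeLayout`.
#' @export
layout_seqinfo <- function(layout) {
  stopifnot(inherits(layout, "GenomeLayout"))
  Seqinfo(seqnames = names(layout$chrom_sizes),
          seqlengths = as.integer(layout$chrom_sizes))
}

#' Read a two-column chromosome-sizes table
#'
#' Tab-delimited, columns chromosome name and length; no header required.
#'
#' @param path file path.
#' @return A `GenomeLayout`.
#' @export
read_chrom_sizes <- function(path) {
  dt <- fread(path, header = FALSE, sep = "\t")
  if (ncol(dt) < 2L) stop("chromosome sizes file must have two columns")
  genome_layout(setNames(as.numeric(dt[[2L]]), as.character(dt[[1L]])))
}

#' @rdname read_chrom_sizes
#' @param layout a `GenomeLayout`.
#' @export
write_chrom_sizes <- function(layout, path) {
  dt <- data.table(chrom = names(layout$chrom_sizes),
                   size = as.integer(layout$chrom_sizes))
  fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

check_within_layout <- function(gr, layout, what = "interval") {
  cs <- layout$chrom_sizes
  chr <- as.character(seqnames(gr))
  unknown <- setdiff(unique(chr), names(cs))
  if (length(unknown))
    stop("unknown chromosome(s): ", paste(unknown, collapse = ", "))
  bad <- start(gr) < 1L | end(gr) > cs[chr]
  if (any(bad))
    stop(sum(bad), " ", what, "(s) out of chromosome bounds (first: ",
         chr[which(bad)[1L]], ":", start(gr)[which(bad)[1L]], "-",
         end(gr)[which(bad)[1L]], ")")
  invisible(TRUE)
}

# ---------------------------------------------------------------------------
# Window tiling
# ---------------------------------------------------------------------------

#' Tile a genome into adjacent fixed-size windows
#'
#' Windows tile each chromosome from position 0 (BED view): `[0,w)`,
#' `[w,2w)`, ... A trailing window shorter than `window_size` is kept and
#' flagged `partial`; partial windows are excluded from differential
#' testing downstream because their unequal length biases count statistics.
#'
#' @param layout a `GenomeLayout`.
#' @param window_size window width in bp (>= 1).
#' @return `GRanges` in (chromosome, start) order with metadata columns
#'   `window_id` and `partial`.
#' @export
tile_genome <- function(layout, window_size) {
  stopifnot(inherits(layout, "GenomeLayout"))
  window_size <- as.integer(window_size)
  if (is.na(window_size) || window_size < 1L)
    stop("window_size must be a positive integer")
  cs <- layout$chrom_sizes
  per_chrom <- lapply(names(cs), function(chr) {
    len <- cs[[chr]]
    n <- ceiling(len / window_size)
    s <- (seq_len(n) - 1L) * window_size + 1
    e <- pmin(s + window_size - 1, len)
    GRanges(chr, IRanges(s, e), partial = (e - s + 1L) < window_size,
            seqinfo = layout_seqinfo(layout))
  })
  gr <- do.call(c, per_chrom)
  mcols(gr)$window_id <- paste0(as.character(seqnames(gr)), ":",
                                start(gr) - 1L, "-", end(gr))
  gr
}

# ---------------------------------------------------------------------------
# Read containers and counting
# ---------------------------------------------------------------------------

#' Stranded read set
#'
#' One sequenced sample: immunoprecipitated single-stranded fragments as
#' stranded intervals. The read strand is the strand of the modified DNA.
#'
#' @param sample_id character scalar.
#' @param cell_type one of the two compared populations (e.g. "D1", "D2").
#' @param assay one of "5mC", "5hmC", "input", "rna".
#' @param replicate integer replicate index.
#' @param reads `GRanges` with strand "+" or "-".
#' @param layout optional `GenomeLayout` used to bounds-check the reads.
#' @return An object of class `StrandedReadSet`.
#' @export
stranded_read_set <- function(sample_id, cell_type, assay, replicate, reads,
                              layout = NULL) {
  stopifnot(is(reads, "GRanges"))
  if (any(!as.character(strand(reads)) %in% c("+", "-")))
    stop("all reads must be stranded (+ or -)")
  if (!is.null(layout)) check_within_layout(reads, layout, "read")
  structure(list(sample_id = as.character(sample_id),
                 cell_type = as.character(cell_type),
                 assay = as.character(assay),
                 replicate = as.integer(replicate),
                 reads = reads,
                 library_size = length(reads)),
            class = "StrandedReadSet")
}

#' @export
print.StrandedReadSet <- function(x, ...) {
  cat(sprintf("StrandedReadSet %s (%s, %s, rep %d): %s reads\n",
              x$sample_id, x$cell_type, x$assay, x$replicate,
              format(x$library_size, big.mark = ",")))
  invisible(x)
}

# 0-based fragment midpoint of a GRanges (1-based closed internally):
# mid0 = floor((start0 + end0_exclusive) / 2) = floor((start - 1 + end) / 2)
read_midpoints0 <- function(gr) {
  floor((start(gr) - 1 + end(gr)) / 2)
}

#' Count stranded reads in tiled windows
#'
#' Each read is assigned to exactly one window by its fragment midpoint and
#' tallied under its strand, so totals are conserved and strand-decomposable.
#'
#' @param read_sets list of `StrandedReadSet` (same assay).
#' @param windows windows from [tile_genome()].
#' @param layout the `GenomeLayout` the windows were tiled on.
#' @return An object of class `WindowCounts`: window `GRanges`, a
#'   `n_windows x n_samples x 2` integer count array (strands "+","-"),
#'   and a sample table with library sizes and dropped-read counts.
#' @export
count_reads_in_windows <- function(read_sets, windows, layout) {
  if (inherits(read_sets, "StrandedReadSet")) read_sets <- list(read_sets)
  stopifnot(length(read_sets) >= 1L)
  w <- max(width(windows))
  cs <- layout$chrom_sizes
  chroms <- names(cs)
  nwin_per_chrom <- ceiling(cs / w)
  offset <- setNames(cumsum(c(0, head(nwin_per_chrom, -1L))), chroms)
  n_win <- length(windows)
  n_smp <- length(read_sets)
  counts <- array(0L, dim = c(n_win, n_smp, 2L),
                  dimnames = list(NULL,
                                  vapply(read_sets, `[[`, "", "sample_id"),
                                  c("+", "-")))
  dropped <- integer(n_smp)
  for (i in seq_len(n_smp)) {
    rs <- read_sets[[i]]
    check_within_layout(rs$reads, layout, "read")
    chr <- as.character(seqnames(rs$reads))
    mid0 <- read_midpoints0(rs$reads)
    idx <- offset[chr] + (mid0 %/% w) + 1L
    ok <- idx >= 1L & idx <= n_win
    dropped[i] <- sum(!ok)
    sgn <- as.character(strand(rs$reads))
    for (s in c("+", "-")) {
      sel <- ok & sgn == s
      if (any(sel))
        counts[, i, s] <- counts[, i, s] +
          tabulate(idx[sel], nbins = n_win)
    }
  }
  samples <- data.frame(
    sample_id = vapply(read_sets, `[[`, "", "sample_id"),
    cell_type = vapply(read_sets, `[[`, "", "cell_type"),
    assay = vapply(read_sets, `[[`, "", "assay"),
    replicate = vapply(read_sets, function(x) x$replicate, 1L),
    library_size = vapply(read_sets, function(x) x$library_size, 1L),
    dropped = dropped,
    stringsAsFactors = FALSE)
  structure(list(window_size = w, windows = windows, counts = counts,
                 samples = samples),
            class = "WindowCounts")
}

#' @export
print.WindowCounts <- function(x, ...) {
  cat(sprintf("WindowCounts: %d windows of %d bp x %d sample(s)\n",
              length(x$windows), x$window_size, nrow(x$samples)))
  invisible(x)
}

# Sorted midpoint vectors per chromosome x strand; the shared fast-count
# backend: counts in arbitrary (possibly overlapping) regions by binary
# search rather than materialised overlap pairs.
midpoint_index <- function(read_sets) {
  if (inherits(read_sets, "StrandedReadSet")) read_sets <- list(read_sets)
  reads <- lapply(read_sets, `[[`, "reads")
  chr <- unlist(lapply(reads, function(g) as.character(seqnames(g))))
  mid0 <- unlist(lapply(reads, read_midpoints0))
  sgn <- unlist(lapply(reads, function(g) as.character(strand(g))))
  idx <- split(mid0, paste0(chr, sgn))
  lapply(idx, sort)
}

count_index_region <- function(index, chrom, start0, end0, strand) {
  # number of midpoints on [start0, end0) (0-based half-open)
  v <- index[[paste0(chrom, strand)]]
  if (is.null(v)) return(integer(length(start0)))
  findInterval(end0 - 1, v) - findInterval(start0 - 1, v)
}

#' Count stranded reads in arbitrary regions
#'
#' Midpoint rule as in [count_reads_in_windows()], but regions may overlap:
#' a read whose midpoint falls in k regions increments all k.
#'
#' @param read_sets list of `StrandedReadSet` pooled together (counts are
#'   summed over the supplied sets), or a single set.
#' @param regions `GRanges`.
#' @return `data.frame` with one row per region: `plus`, `minus`, `total`.
#' @export
count_reads_in_regions <- function(read_sets, regions) {
  if (length(regions) == 0L)
    return(data.frame(plus = integer(0), minus = integer(0),
                      total = integer(0)))
  index <- midpoint_index(read_sets)
  chr <- as.character(seqnames(regions))
  s0 <- start(regions) - 1
  e0 <- end(regions)
  plus <- integer(length(regions))
  minus <- integer(length(regions))
  for (c in unique(chr)) {
    sel <- chr == c
    plus[sel] <- count_index_region(index, c, s0[sel], e0[sel], "+")
    minus[sel] <- count_index_region(index, c, s0[sel], e0[sel], "-")
  }
  data.frame(plus = plus, minus = minus, total = plus + minus)
}

# ---------------------------------------------------------------------------
# Gene models and feature assignment
# ---------------------------------------------------------------------------

#' Construct a gene model table
#'
#' @param gr stranded `GRanges` of gene bodies (TSS to TTS) with metadata
#'   columns `gene_id`, `biotype` ("coding", "lncRNA", "other") and
#'   optionally `family`; exon structure may be attached as an
#'   `IRanges`-list column `blocks` (BED12-style, relative to gene start).
#' @return the validated `GRanges` (class-tagged in `metadata`).
#' @export
gene_models <- function(gr) {
  stopifnot(is(gr, "GRanges"))
  if (is.null(mcols(gr)$gene_id)) stop("gene models need a gene_id column")
  if (any(!as.character(strand(gr)) %in% c("+", "-")))
    stop("gene models must be stranded")
  if (is.null(mcols(gr)$biotype)) mcols(gr)$biotype <- "coding"
  if (is.null(mcols(gr)$family)) mcols(gr)$family <- NA_character_
  gr
}

#' TSS and TTS positions of gene models
#'
#' TSS is the 5' end in gene orientation (start for "+" genes, end for "-").
#'
#' @param genes gene `GRanges` from [gene_models()].
#' @return integer vector of 1-based positions.
#' @export
gene_tss <- function(genes) {
  ifelse(as.character(strand(genes)) == "+", start(genes), end(genes))
}

#' @rdname gene_tss
#' @export
gene_tts <- function(genes) {
  ifelse(as.character(strand(genes)) == "+", end(genes), start(genes))
}

#' Flanked point regions (e.g. TSS +/- 2 kb), clipped at chromosome ends
#'
#' @param genes gene `GRanges`.
#' @param at "tss" or "tts".
#' @param flank_bp flank on each side.
#' @param layout `GenomeLayout` for clipping.
#' @return `GRanges` parallel to `genes`.
#' @export
point_regions <- function(genes, at = c("tss", "tts"), flank_bp = 2000,
                          layout = NULL) {
  at <- match.arg(at)
  pos <- if (at == "tss") gene_tss(genes) else gene_tts(genes)
  s <- pos - flank_bp
  e <- pos + flank_bp
  if (!is.null(layout)) {
    lens <- layout$chrom_sizes[as.character(seqnames(genes))]
    s <- pmax(s, 1)
    e <- pmin(e, lens)
  } else s <- pmax(s, 1)
  gr <- GRanges(seqnames(genes), IRanges(s, e), strand = strand(genes))
  mcols(gr)$gene_id <- mcols(genes)$gene_id
  gr
}

gene_exons <- function(genes) {
  bl <- mcols(genes)$blocks
  if (is.null(bl)) return(granges(genes, use.mcols = FALSE))
  chr <- rep(as.character(seqnames(genes)), lengths(bl))
  off <- rep(start(genes), lengths(bl))
  b <- unlist(bl, use.names = FALSE)
  GRanges(chr, IRanges(off + start(b) - 1L, off + end(b) - 1L))
}

#' Assign windows to genomic features
#'
#' Fixed precedence: TSS+/-2kb > exon > intron > TTS+/-2kb > lncRNA gene >
#' intergenic; a window takes the highest-precedence label of any feature
#' it overlaps by at least 1 bp. TSS/TTS/exon/intron features come from
#' coding genes; "other"-biotype genes fall through to intergenic.
#'
#' @param windows `GRanges` to label.
#' @param genes gene `GRanges` from [gene_models()] (with optional exon
#'   `blocks`).
#' @param flank_bp TSS/TTS flank (default 2000).
#' @param layout optional `GenomeLayout` for clipping flanks.
#' @return character vector of labels, one per window.
#' @export
assign_feature <- function(windows, genes, flank_bp = 2000, layout = NULL) {
  coding <- genes[mcols(genes)$biotype == "coding"]
  lnc <- genes[mcols(genes)$biotype == "lncRNA"]
  exons <- gene_exons(coding)
  feats <- list(
    TSS = point_regions(coding, "tss", flank_bp, layout),
    exon = exons,
    intron = granges(coding, use.mcols = FALSE),
    TTS = point_regions(coding, "tts", flank_bp, layout),
    lncRNA = granges(lnc, use.mcols = FALSE))
  lab <- rep("intergenic", length(windows))
  # reverse precedence so later (higher-precedence) assignments overwrite;
  # disjoint seqlevels between a window and a feature set are a valid
  # no-overlap outcome, not worth a warning
  for (nm in rev(names(feats))) {
    hit <- suppressWarnings(
      overlapsAny(windows, feats[[nm]], ignore.strand = TRUE))
    lab[hit] <- nm
  }
  # intron label applies where the gene body overlaps but no exon does;
  # the precedence loop above already gives exon priority over intron,
  # and TSS priority over both.
  lab
}

# ---------------------------------------------------------------------------
# BED / FASTA I/O (delegated to rtracklayer / Biostrings)
# ---------------------------------------------------------------------------

#' Read and write BED6 interval files
#'
#' The BED name field carries the family (repeats) or TF name (TFBS).
#'
#' @param path file path.
#' @param layout optional `GenomeLayout` for bounds checking.
#' @return `GRanges` with `name` and `score` columns where present.
#' @export
read_bed6 <- function(path, layout = NULL) {
  gr <- rtracklayer::import(path, format = "BED")
  if (!is.null(layout)) check_within_layout(gr, layout, "record")
  gr
}

#' @rdname read_bed6
#' @param gr `GRanges` to write.
#' @export
write_bed6 <- function(gr, path) {
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read gene models from BED12 + metadata TSV
#'
#' @param bed12_path BED12 with exon blocks; name field = gene_id.
#' @param meta_path TSV with header columns gene_id, biotype, family.
#' @param layout optional `GenomeLayout`.
#' @return gene `GRanges` (see [gene_models()]).
#' @export
read_gene_models <- function(bed12_path, meta_path = NULL, layout = NULL) {
  gr <- rtracklayer::import(bed12_path, format = "BED")
  mcols(gr)$gene_id <- mcols(gr)$name
  if (!is.null(meta_path)) {
    meta <- fread(meta_path, sep = "\t")
    m <- match(mcols(gr)$gene_id, meta$gene_id)
    mcols(gr)$biotype <- meta$biotype[m]
    mcols(gr)$family <- meta$family[m]
  }
  if (!is.null(layout)) check_within_layout(gr, layout, "gene")
  gene_models(gr)
}

#' @rdname read_gene_models
#' @param genes gene `GRanges` to write.
#' @export
write_gene_models <- function(genes, bed12_path, meta_path = NULL) {
  out <- genes
  mcols(out)$name <- mcols(genes)$gene_id
  rtracklayer::export(out, bed12_path, format = "BED")
  if (!is.null(meta_path)) {
    fwrite(data.table(gene_id = mcols(genes)$gene_id,
                      biotype = mcols(genes)$biotype,
                      family = mcols(genes)$family),
           meta_path, sep = "\t")
  }
  invisible(bed12_path)
}

#' Write strand-split bedGraph coverage tracks for browser inspection
#'
#' One track per strand, read-midpoint counts per tiling window.
#'
#' @param read_set a `StrandedReadSet`.
#' @param windows tiling from [tile_genome()].
#' @param layout `GenomeLayout`.
#' @param prefix output path prefix; writes `<prefix>.plus.bedGraph` and
#'   `<prefix>.minus.bedGraph`.
#' @export
write_strand_bedgraph <- function(read_set, windows, layout, prefix) {
  wc <- count_reads_in_windows(read_set, windows, layout)
  for (s in c("+", "-")) {
    gr <- granges(windows, use.mcols = FALSE)
    mcols(gr)$score <- as.numeric(wc$counts[, 1L, s])
    fn <- paste0(prefix, if (s == "+") ".plus" else ".minus", ".bedGraph")
    rtracklayer::export(gr[mcols(gr)$score > 0], fn, format = "bedGraph")
  }
  invisible(prefix)
}

#' Drop reads and flag windows overlapping an exclusion mask
#'
#' Generalizes transgene masking: an optional exclusion BED removes reads
#' (by any overlap) before analysis.
#'
#' @param read_set `StrandedReadSet`.
#' @param mask `GRanges` exclusion regions (NULL = no-op).
#' @return filtered `StrandedReadSet`.
#' @export
apply_exclusion <- function(read_set, mask) {
  if (is.null(mask) || length(mask) == 0L) return(read_set)
  keep <- !overlapsAny(read_set$reads, mask, ignore.strand = TRUE)
  stranded_read_set(read_set$sample_id, read_set$cell_type, read_set$assay,
                    read_set$replicate, read_set$reads[keep])
}
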