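# Shared fixtures, all built in code.

library(GenomicRanges)

toy_layout <- function(sizes = c(chr1 = 100000, chr2 = 50000)) {
  genome_layout(sizes)
}

# reads from a 0-based half-open coordinate table (BED view)
make_reads <- function(chrom, start0, end0, strand,
                       sample_id = "s1", cell_type = "D1",
                       assay = "5mC", replicate = 1L) {
  gr <- if (length(start0) == 0L) GRanges()
        else GRanges(chrom, IRanges(start0 + 1, end0), strand = strand)
  stranded_read_set(sample_id, cell_type, assay, replicate, gr)
}

# n reads with given midpoints (0-based) on one chromosome
reads_at <- function(mid0, strand, chrom = "chr1", len = 100, ...) {
  make_reads(chrom, pmax(0, mid0 - len / 2), pmax(0, mid0 - len / 2) + len,
             strand, ...)
}

# deterministic toy gene set
toy_genes <- function() {
  gr <- GRanges(c("chr1", "chr1", "chr2"),
                IRanges(c(10001, 40001, 5001), c(20000, 60000, 15000)),
                strand = c("+", "-", "+"))
  mcols(gr)$gene_id <- c("gA", "gB", "gC")
  mcols(gr)$biotype <- c("coding", "coding", "lncRNA")
  mcols(gr)$family <- NA_character_
  mcols(gr)$blocks <- IRanges::IRangesList(
    IRanges(c(1, 5001), c(2000, 10000)),     # gA exons
    IRanges(c(1, 15001), c(3000, 20000)),    # gB exons
    IRanges(1, 10000))                       # gC single block
  gene_models(gr)
}

# small, fast simulation config for unit tests (any default overridable)
small_sim_config <- function(seed = 42, ...) {
  defaults <- list(
    seed = seed,
    chrom_sizes = c(chr1 = 2e6, chr2 = 2e6),
    n_genes = 80, n_repeats = 60, n_clusters = 4,
    ribosomal_like_n = 4L, olfactory_like_n = 4L,
    repeat_length_kb = c(1, 4),
    cluster_span_kb = c(4, 40),
    reads_per_sample = c("5mC" = 1e5, "5hmC" = 1e5, "input" = 4e4),
    fragment_length = c("5mC" = 150L, "5hmC" = 250L, "input" = 150L),
    n_de_genes = 20, n_tfs_null = 10, n_tfs_enriched = 2,
    tfbs_sites_per_tf = 100, make_sequence = FALSE)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# brute-force stranded region counts by midpoint scan (independent oracle)
brute_region_counts <- function(read_sets, regions) {
  if (inherits(read_sets, "StrandedReadSet")) read_sets <- list(read_sets)
  plus <- integer(length(regions)); minus <- integer(length(regions))
  for (rs in read_sets) {
    gr <- rs$reads
    mid0 <- floor((start(gr) - 1 + end(gr)) / 2)
    chr <- as.character(seqnames(gr))
    sg <- as.character(strand(gr))
    for (i in seq_along(regions)) {
      inr <- chr == as.character(seqnames(regions)[i]) &
        mid0 >= start(regions)[i] - 1 & mid0 < end(regions)[i]
      plus[i] <- plus[i] + sum(inr & sg == "+")
      minus[i] <- minus[i] + sum(inr & sg == "-")
    }
  }
  data.frame(plus = plus, minus = minus, total = plus + minus)
}
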