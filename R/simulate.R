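# Planted-truth simulator for a miniature two-cell-type experiment.
#
# The generative resolution is the 1-kb cell: gene bodies, planted
# differential clusters, strand-asymmetry domains and repeat elements are
# all aligned to the 1-kb grid, and modification read counts are drawn
# Poisson per cell x strand x replicate from a multiplicative expected
# density (baseline x cluster fold x gene-body/TSS factor). This is a
# deliberately analytic model: every downstream statistic has a closed-form
# or simulation-checkable expectation under it.

#' Simulation configuration
#'
#' Defaults describe the standard validation world: 2 chromosomes x 10 Mb,
#' 2 cell types x 3 replicates, 0.5 M modification reads per sample,
#' 12 planted differential clusters (4 kb - 300 kb, 4-fold), nested
#' strand-asymmetry domains at ~2 kb and ~200 kb scales, gene template-strand
#' fractions rising from 0.50 (silent) to 0.63 (top expression decile), a
#' TSS dip in 5hmC scaled by expression, CH-biased sequence and TFBS sets
#' with a planted-enriched subset.
#'
#' @param seed mandatory integer seed; all stages derive their streams
#'   from it.
#' @param chrom_sizes named chromosome lengths (bp, multiples of 1 kb).
#' @param cell_types,n_replicates experimental grid.
#' @param n_genes,gene_length_kb,biotype_props gene placement parameters.
#' @param ribosomal_like_n,olfactory_like_n counts of the two planted gene
#'   families (forced top-decile / forced silent).
#' @param silent_fraction fraction of genes planted silent (mean 0).
#' @param expr_log2_range,expr_dispersion,n_de_genes,de_log2fc negative
#'   binomial expression grid.
#' @param reads_per_sample,fragment_length per-assay totals and fragment
#'   sizes (bp); fragment length only jitters midpoints.
#' @param n_clusters,cluster_span_kb,cluster_fold,cluster_min_gap_kb
#'   planted differential clusters (directions alternate between the two
#'   cell types).
#' @param asym_small_kb,asym_large_kb,asym_fraction_range,asym_small_jitter
#'   two-scale nested strand-asymmetry domain process (intergenic space).
#' @param asym_5mc_attenuation 5mC plus-fractions are shrunk toward 0.5 by
#'   this factor (5mC asymmetry is weaker than 5hmC).
#' @param template_fraction_silent,template_fraction_deciles planted gene
#'   template-strand fractions by expression stratum.
#' @param tss_dip_depth 5hmC TSS-dip depth for the top stratum (scaled
#'   linearly by expression decile).
#' @param n_repeats,repeat_families,repeat_length_kb repeat annotation;
#'   `repeat_families` is a named vector of planted template-style
#'   fractions per family.
#' @param ch_domain_kb,ch_bias_range CH strand-bias domain process used for
#'   sequence generation (bias = probability mass split between C and G).
#' @param n_tfs_null,n_tfs_enriched,tfbs_sites_per_tf,tfbs_site_width,
#'   tfbs_enriched_fraction TFBS sets; enriched TFs get this fraction of
#'   sites placed inside planted differential windows.
#' @param make_sequence generate the FASTA sequence (disable to save time
#'   when only read-level stages are exercised).
#' @return validated config list of class `SimulationConfig`.
#' @export
sim_config <- function(seed,
                       chrom_sizes = c(chr1 = 10e6, chr2 = 10e6),
                       cell_types = c("D1", "D2"),
                       n_replicates = 3L,
                       n_genes = 400L,
                       gene_length_kb = c(4L, 30L),
                       biotype_props = c(coding = 0.80, lncRNA = 0.15,
                                         other = 0.05),
                       ribosomal_like_n = 12L,
                       olfactory_like_n = 12L,
                       silent_fraction = 0.25,
                       expr_log2_range = c(0, 10),
                       expr_dispersion = 0.1,
                       n_de_genes = 80L,
                       de_log2fc = 2,
                       reads_per_sample = c("5mC" = 5e5, "5hmC" = 5e5,
                                            "input" = 2e5),
                       fragment_length = c("5mC" = 150L, "5hmC" = 250L,
                                           "input" = 150L),
                       n_clusters = 12L,
                       cluster_span_kb = c(4L, 300L),
                       cluster_fold = 4,
                       cluster_min_gap_kb = 100L,
                       asym_small_kb = 2,
                       asym_large_kb = 200,
                       asym_fraction_range = c(0.3, 0.7),
                       asym_small_jitter = 0.15,
                       asym_5mc_attenuation = 0.5,
                       template_fraction_silent = 0.50,
                       template_fraction_deciles =
                         seq(0.50, 0.63, length.out = 10),
                       tss_dip_depth = 0.8,
                       n_repeats = 300L,
                       repeat_families = c(LINE1 = 0.8, LINE2 = 0.7,
                                           SINE = 0.6, LTR = 0.5),
                       repeat_length_kb = c(1L, 6L),
                       ch_domain_kb = 50,
                       ch_bias_range = c(0.35, 0.65),
                       n_tfs_null = 100L,
                       n_tfs_enriched = 8L,
                       tfbs_sites_per_tf = 200L,
                       tfbs_site_width = 15L,
                       tfbs_enriched_fraction = 0.5,
                       make_sequence = TRUE) {
  if (missing(seed) || is.null(seed) || is.na(seed))
    stop("seed is mandatory")
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  if (any(chrom_sizes %% 1000 != 0))
    stop("chromosome sizes must be multiples of 1 kb (the cell size)")
  probs <- c(biotype_props, silent_fraction, tfbs_enriched_fraction,
             asym_fraction_range, ch_bias_range, repeat_families,
             template_fraction_silent, template_fraction_deciles,
             tss_dip_depth, asym_5mc_attenuation)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (abs(sum(biotype_props) - 1) > 1e-8)
    stop("biotype_props must sum to 1")
  if (expr_dispersion <= 0) stop("dispersion must be > 0")
  if (length(template_fraction_deciles) != 10L)
    stop("template_fraction_deciles must have length 10")
  structure(cfg, class = "SimulationConfig")
}

# Seed streams: independent sub-seeds per stage so stages can be re-run in
# isolation deterministically. Kept < 2^31.
stage_seed <- function(cfg, stage) {
  offs <- c(genome = 101, expression = 211, reads = 307, tfbs = 401)
  as.integer((as.numeric(cfg$seed) * 1009 + offs[[stage]]) %%
               .Machine$integer.max)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# kb-aligned non-overlapping interval placement on a cell occupancy map
place_intervals_kb <- function(cfg, occupied, lens_kb, max_tries = 200L) {
  cs_kb <- cfg$chrom_sizes / 1000
  chroms <- names(cs_kb)
  out <- vector("list", length(lens_kb))
  for (i in seq_along(lens_kb)) {
    L <- lens_kb[i]
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      chr <- sample(chroms, 1L, prob = pmax(cs_kb - L + 1, 0))
      if (cs_kb[[chr]] < L) next
      s <- sample.int(cs_kb[[chr]] - L + 1L, 1L) - 1L  # 0-based kb cell
      cells <- (s + 1):(s + L)
      if (any(occupied[[chr]][cells])) next
      occupied[[chr]][cells] <- TRUE
      out[[i]] <- list(chrom = chr, start_kb = s, len_kb = L)
      placed <- TRUE
      break
    }
    if (!placed)
      stop("could not place interval without overlap after ", max_tries,
           " tries; use a larger genome or fewer/smaller features")
  }
  list(placements = out, occupied = occupied)
}

random_exon_blocks <- function(len, k) {
  # k exon blocks spanning the gene (BED12-style: first starts at 1,
  # last ends at len), alternating exon/intron segments
  k <- max(1L, min(k, len %/% 100L))
  if (k == 1L) return(IRanges(1L, len))
  cuts <- sort(sample(seq_len(len - 1L), 2L * k - 2L))
  bounds <- c(0L, cuts, len)
  s <- bounds[seq(1L, 2L * k - 1L, by = 2L)] + 1L
  e <- bounds[seq(2L, 2L * k, by = 2L)]
  IRanges(s, e)
}

#' Simulate the genome: layout, sequence, gene models, repeats
#'
#' Genes and repeats are placed non-overlapping on the 1-kb grid (bounded
#' retries; failure advises a larger genome). Sequence is drawn per
#' CH-bias domain: within a domain with bias b, P(C) = 0.4 b and
#' P(G) = 0.4 (1 - b) so b = 0.5 gives strand-symmetric CH content.
#'
#' @param cfg a `SimulationConfig`.
#' @return list: `layout`, `genome` (`DNAStringSet` or NULL), `genes`,
#'   `repeats`, `ch_domains` (all `GRanges`), `config`.
#' @export
simulate_genome <- function(cfg) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  set.seed(stage_seed(cfg, "genome"))
  layout <- genome_layout(cfg$chrom_sizes)
  si <- layout_seqinfo(layout)
  cs_kb <- cfg$chrom_sizes / 1000
  occupied <- lapply(cs_kb, function(n) logical(n))

  # genes
  glen <- sample(seq(cfg$gene_length_kb[1], cfg$gene_length_kb[2]),
                 cfg$n_genes, replace = TRUE)
  pg <- place_intervals_kb(cfg, occupied, glen)
  occupied <- pg$occupied
  gchrom <- vapply(pg$placements, `[[`, "", "chrom")
  gstart0 <- vapply(pg$placements, function(p) p$start_kb * 1000, 1)
  glen_bp <- glen * 1000
  gstrand <- sample(c("+", "-"), cfg$n_genes, replace = TRUE)
  biotype <- sample(names(cfg$biotype_props), cfg$n_genes, replace = TRUE,
                    prob = cfg$biotype_props)
  family <- rep(NA_character_, cfg$n_genes)
  coding_idx <- which(biotype == "coding")
  fam_n <- cfg$ribosomal_like_n + cfg$olfactory_like_n
  if (fam_n > length(coding_idx))
    stop("not enough coding genes for the requested families")
  fam_pick <- sample(coding_idx, fam_n)
  family[fam_pick[seq_len(cfg$ribosomal_like_n)]] <- "ribosomal_like"
  family[fam_pick[cfg$ribosomal_like_n + seq_len(cfg$olfactory_like_n)]] <-
    "olfactory_like"
  genes <- GRanges(gchrom, IRanges(gstart0 + 1, gstart0 + glen_bp),
                   strand = gstrand, seqinfo = si)
  mcols(genes)$gene_id <- sprintf("gene%04d", seq_len(cfg$n_genes))
  mcols(genes)$biotype <- biotype
  mcols(genes)$family <- family
  nex <- sample(2:8, cfg$n_genes, replace = TRUE)
  mcols(genes)$blocks <- IRanges::IRangesList(
    lapply(seq_len(cfg$n_genes),
           function(i) random_exon_blocks(glen_bp[i], nex[i])))
  genes <- gene_models(genes)

  # repeats (intergenic, non-overlapping)
  rlen <- sample(seq(cfg$repeat_length_kb[1], cfg$repeat_length_kb[2]),
                 cfg$n_repeats, replace = TRUE)
  pr <- place_intervals_kb(cfg, occupied, rlen)
  rchrom <- vapply(pr$placements, `[[`, "", "chrom")
  rstart0 <- vapply(pr$placements, function(p) p$start_kb * 1000, 1)
  repeats <- GRanges(rchrom, IRanges(rstart0 + 1, rstart0 + rlen * 1000),
                     strand = sample(c("+", "-"), cfg$n_repeats,
                                     replace = TRUE),
                     seqinfo = si)
  mcols(repeats)$name <- sample(names(cfg$repeat_families), cfg$n_repeats,
                                replace = TRUE)

  # CH bias domains + sequence
  ch_domains <- domain_tiling(layout, cfg$ch_domain_kb)
  mcols(ch_domains)$bias <- runif(length(ch_domains),
                                  cfg$ch_bias_range[1], cfg$ch_bias_range[2])
  genome <- NULL
  if (isTRUE(cfg$make_sequence)) {
    genome <- DNAStringSet(vapply(names(cfg$chrom_sizes), function(chr) {
      doms <- ch_domains[seqnames(ch_domains) == chr]
      chunks <- vapply(seq_along(doms), function(i) {
        b <- mcols(doms)$bias[i]
        paste(sample(c("A", "C", "G", "T"), width(doms)[i], replace = TRUE,
                     prob = c(0.3, 0.4 * b, 0.4 * (1 - b), 0.3)),
              collapse = "")
      }, "")
      paste(chunks, collapse = "")
    }, ""))
    names(genome) <- names(cfg$chrom_sizes)
  }
  list(config = cfg, layout = layout, genome = genome, genes = genes,
       repeats = repeats, ch_domains = ch_domains)
}

# tile chromosomes into kb-aligned domains with ~exponential lengths
domain_tiling <- function(layout, mean_kb) {
  si <- layout_seqinfo(layout)
  grs <- lapply(names(layout$chrom_sizes), function(chr) {
    len_kb <- layout$chrom_sizes[[chr]] / 1000
    lens <- integer(0)
    tot <- 0
    while (tot < len_kb) {
      l <- max(1L, round(stats::rexp(1L, 1 / mean_kb)))
      lens <- c(lens, l)
      tot <- tot + l
    }
    lens[length(lens)] <- lens[length(lens)] - (tot - len_kb)
    lens <- lens[lens > 0]
    e <- cumsum(lens) * 1000
    s <- c(0, head(e, -1L))
    GRanges(chr, IRanges(s + 1, e), seqinfo = si)
  })
  do.call(c, grs)
}

#' Simulate expression count tables and truth labels
#'
#' Negative binomial counts per gene, cell type and replicate. Planted
#' silent genes (including the olfactory-like family) have mean 0;
#' ribosomal-like genes draw means from the top of the log2 grid. DE genes
#' shift the first cell type's mean by +/- `de_log2fc`. The truth records
#' planted means, DE labels, expression deciles over expressed genes and
#' the per-gene planted template-strand fraction implied by the decile.
#'
#' @param cfg `SimulationConfig`.
#' @param sim output of [simulate_genome()].
#' @return list: `counts` (genes x samples matrix), `samples` table,
#'   `truth` data.frame.
#' @export
simulate_expression <- function(cfg, sim) {
  set.seed(stage_seed(cfg, "expression"))
  genes <- sim$genes
  n <- length(genes)
  fam <- mcols(genes)$family
  silent <- rep(FALSE, n)
  silent[fam %in% "olfactory_like"] <- TRUE
  n_extra <- max(0L, round(cfg$silent_fraction * n) - sum(silent))
  pool <- which(!silent & !(fam %in% "ribosomal_like"))
  silent[sample(pool, min(n_extra, length(pool)))] <- TRUE
  mu <- numeric(n)
  expressed <- which(!silent)
  mu[expressed] <- 2^runif(length(expressed), cfg$expr_log2_range[1],
                           cfg$expr_log2_range[2])
  rib <- which(fam %in% "ribosomal_like")
  de <- rep(FALSE, n)
  l2fc <- numeric(n)
  de_pool <- setdiff(expressed, rib)
  de_idx <- sample(de_pool, min(cfg$n_de_genes, length(de_pool)))
  de[de_idx] <- TRUE
  l2fc[de_idx] <- sample(c(-1, 1), length(de_idx), replace = TRUE) *
    cfg$de_log2fc
  muA <- mu * 2^l2fc  # first cell type
  muB <- mu
  # ribosomal-like genes are forced into the top expression decile: their
  # abundance sits strictly above every other gene's (DE shifts included)
  if (length(rib)) {
    others <- setdiff(expressed, rib)
    top <- max(sqrt(muA[others] * muB[others]), 1)
    mu[rib] <- top * 2^runif(length(rib), 0.1, 0.5)
    muA[rib] <- mu[rib]
    muB[rib] <- mu[rib]
  }
  # deciles over expressed genes by planted abundance (geometric mean)
  decile <- rep(NA_integer_, n)
  ab <- sqrt(muA[expressed] * muB[expressed])
  decile[expressed] <- as.integer(
    cut(rank(ab, ties.method = "first"),
        breaks = seq(0, length(expressed), length.out = 11), labels = FALSE))
  tfrac <- ifelse(silent, cfg$template_fraction_silent,
                  cfg$template_fraction_deciles[decile])
  ct <- cfg$cell_types
  smp <- expand.grid(replicate = seq_len(cfg$n_replicates),
                     cell_type = ct, stringsAsFactors = FALSE)
  smp$sample_id <- sprintf("%s_rna_r%d", smp$cell_type, smp$replicate)
  counts <- sapply(seq_len(nrow(smp)), function(j) {
    m <- if (smp$cell_type[j] == ct[1]) muA else muB
    rnbinom(n, mu = m, size = 1 / cfg$expr_dispersion)
  })
  colnames(counts) <- smp$sample_id
  rownames(counts) <- mcols(genes)$gene_id
  truth <- data.frame(gene_id = mcols(genes)$gene_id,
                      biotype = mcols(genes)$biotype,
                      family = fam,
                      mu_A = muA, mu_B = muB,
                      de = de, log2fc = l2fc,
                      silent = silent, decile = decile,
                      template_fraction = tfrac,
                      stringsAsFactors = FALSE)
  list(counts = counts, samples = smp[, c("sample_id", "cell_type",
                                          "replicate")],
       truth = truth)
}

# per-cell (1-kb) description of the planted modification model
build_cell_model <- function(cfg, sim, expr) {
  layout <- sim$layout
  cells <- tile_genome(layout, 1000L)
  n <- length(cells)
  chr <- as.character(seqnames(cells))
  center <- (start(cells) + end(cells)) / 2
  genes <- sim$genes

  # Planted differential clusters (both modification assays, concordant).
  # Placement: evenly spaced slots along the concatenated genome with
  # alternating direction and positional jitter. The clustering rule's
  # absorption reach is ~(1/density_threshold) x n_sig windows (a cluster
  # may legitimately annex a same-direction significant window while the
  # span density stays above 1/8), so planted same-direction clusters must
  # sit further apart than 8 x the largest span for the planted truth to
  # be identifiable at all; alternating slots guarantee that by
  # construction.
  span_kb <- round(exp(runif(cfg$n_clusters, log(cfg$cluster_span_kb[1]),
                             log(cfg$cluster_span_kb[2]))))
  cs_kb <- cfg$chrom_sizes / 1000
  tot_kb <- sum(cs_kb)
  bnd <- cumsum(cs_kb)
  slot <- if (cfg$n_clusters > 0) tot_kb / cfg$n_clusters else tot_kb
  jitter_kb <- if (cfg$n_clusters > 0)
    max(0, floor((slot - max(span_kb)) / 2) - 10) else 0
  span_order <- sample.int(max(cfg$n_clusters, 1L))
  placements <- vector("list", cfg$n_clusters)
  for (k in seq_len(cfg$n_clusters)) {
    L <- span_kb[span_order[k]]
    cpos <- (k - 0.5) * slot +
      round(runif(1, -min(jitter_kb, cfg$cluster_min_gap_kb),
                  min(jitter_kb, cfg$cluster_min_gap_kb)))
    s <- round(cpos - L / 2)
    s <- clamp(s, 10, tot_kb - L - 10)
    # map concatenated coordinate back to a chromosome, clamped inside it
    ci <- findInterval(s, c(0, bnd), rightmost.closed = TRUE)
    off <- c(0, bnd)[ci]
    s_chr <- clamp(s - off, 5, cs_kb[ci] - L - 5)
    placements[[k]] <- list(chrom = names(cs_kb)[ci], start_kb = s_chr,
                            len_kb = L)
  }
  dirs <- rep(c("A-up", "B-up"), length.out = cfg$n_clusters)
  clusters <- GRanges(
    vapply(placements, `[[`, "", "chrom"),
    IRanges(vapply(placements, function(p) p$start_kb * 1000 + 1, 1),
            vapply(placements, function(p) (p$start_kb + p$len_kb) * 1000,
                   1)),
    seqinfo = layout_seqinfo(layout))
  mcols(clusters)$direction <- dirs
  mcols(clusters)$fold <- rep(cfg$cluster_fold, cfg$n_clusters)

  # nested asymmetry domains: large base fraction + small-scale jitter
  large <- domain_tiling(layout, cfg$asym_large_kb)
  mcols(large)$plus_fraction <- runif(length(large),
                                      cfg$asym_fraction_range[1],
                                      cfg$asym_fraction_range[2])
  mcols(large)$scale <- "large"
  small <- domain_tiling(layout, cfg$asym_small_kb)
  ov <- findOverlaps(small, large, select = "first")
  base <- mcols(large)$plus_fraction[ov]
  mcols(small)$plus_fraction <- clamp(
    base + runif(length(small), -cfg$asym_small_jitter,
                 cfg$asym_small_jitter), 0.05, 0.95)
  mcols(small)$scale <- "small"

  # per-cell plus-strand fraction, highest precedence last:
  # domains < repeats < genes
  cell_pts <- GRanges(chr, IRanges(center, center))
  f_plus <- mcols(small)$plus_fraction[
    findOverlaps(cell_pts, small, select = "first")]
  f_plus[is.na(f_plus)] <- 0.5
  rov <- findOverlaps(cell_pts, sim$repeats, select = "first")
  rsel <- !is.na(rov)
  rfam <- mcols(sim$repeats)$name[rov[rsel]]
  rstrand <- as.character(strand(sim$repeats))[rov[rsel]]
  rfrac <- cfg$repeat_families[rfam]  # antisense-of-element fraction
  f_plus[rsel] <- ifelse(rstrand == "+", 1 - rfrac, rfrac)
  gov <- findOverlaps(cell_pts, genes, select = "first")
  gsel <- !is.na(gov)
  gi <- gov[gsel]
  tf <- expr$truth$template_fraction[gi]
  gstrand <- as.character(strand(genes))[gi]
  f_plus[gsel] <- ifelse(gstrand == "+", 1 - tf, tf)

  # per-cell density factors
  q <- numeric(n)  # expression quantile of covering gene (0 = silent)
  q[gsel] <- ifelse(expr$truth$silent[gi], 0,
                    expr$truth$decile[gi] / 10)
  dens_5mC <- rep(1, n)
  dens_5mC[gsel] <- 1.25 - 0.75 * q[gsel]
  dens_5hmC <- rep(1, n)
  # 5hmC TSS dip: the two cells flanking each TSS, scaled by expression
  tss <- gene_tss(genes)
  dip_cells <- GRanges(as.character(seqnames(genes)),
                       IRanges(pmax(1, tss - 999), tss + 1000))
  dov <- findOverlaps(cells, dip_cells)
  if (length(dov)) {
    gq <- ifelse(expr$truth$silent[subjectHits(dov)], 0,
                 expr$truth$decile[subjectHits(dov)] / 10)
    dip <- 1 - cfg$tss_dip_depth * gq
    # a cell near two TSSs takes the deepest dip
    agg <- tapply(dip, queryHits(dov), min)
    dens_5hmC[as.integer(names(agg))] <-
      dens_5hmC[as.integer(names(agg))] * as.numeric(agg)
  }
  in_cluster <- findOverlaps(cell_pts, clusters, select = "first")

  list(cells = cells, chr = chr, f_plus = f_plus,
       dens = list("5mC" = dens_5mC, "5hmC" = dens_5hmC,
                   "input" = rep(1, n)),
       in_cluster = in_cluster, clusters = clusters,
       domains = c(large, small),
       gene_cell = ifelse(gsel, gi, NA_integer_))
}

emit_cell_reads <- function(counts, cells, strand_char, frag_len, layout) {
  tot <- sum(counts)
  if (tot == 0L)
    return(GRanges(seqinfo = layout_seqinfo(layout)))
  idx <- rep.int(seq_along(counts), counts)
  mid0 <- (start(cells)[idx] - 1L) + floor(runif(tot) * width(cells)[idx])
  s0 <- mid0 - frag_len %/% 2
  chr <- as.character(seqnames(cells))[idx]
  lens <- layout$chrom_sizes[chr]
  s0 <- pmax(0, pmin(s0, lens - frag_len))
  GRanges(chr, IRanges(s0 + 1, s0 + frag_len), strand = strand_char,
          seqinfo = layout_seqinfo(layout))
}

#' Simulate stranded modification (and input) reads with planted truth
#'
#' See the package vignette for the generative model. Reads are emitted as
#' stranded fragments whose midpoints are uniform within their 1-kb cell.
#'
#' @param cfg `SimulationConfig`.
#' @param sim output of [simulate_genome()].
#' @param expr output of [simulate_expression()].
#' @param assays subset of assays to generate (default: all configured).
#' @return list: `read_sets` (named list of `StrandedReadSet`), `truth`
#'   (planted clusters, asymmetry domains, gene template fractions).
#' @export
simulate_modification_reads <- function(cfg, sim, expr,
                                        assays = names(cfg$reads_per_sample)) {
  set.seed(stage_seed(cfg, "reads"))
  model <- build_cell_model(cfg, sim, expr)
  layout <- sim$layout
  ct <- cfg$cell_types
  read_sets <- list()
  for (assay in assays) {
    frag <- cfg$fragment_length[[assay]]
    for (cell in ct) {
      dens <- model$dens[[assay]]
      if (assay != "input") {
        up_dir <- if (cell == ct[1]) "A-up" else "B-up"
        ci <- model$in_cluster
        boost <- !is.na(ci) &
          mcols(model$clusters)$direction[ifelse(is.na(ci), 1L, ci)] == up_dir
        dens <- dens * ifelse(boost, cfg$cluster_fold, 1)
      }
      f <- if (assay == "input") rep(0.5, length(dens))
           else if (assay == "5mC")
             0.5 + cfg$asym_5mc_attenuation * (model$f_plus - 0.5)
           else model$f_plus
      lambda <- dens / sum(dens) * cfg$reads_per_sample[[assay]]
      for (r in seq_len(cfg$n_replicates)) {
        cp <- rpois(length(lambda), lambda * f)
        cm <- rpois(length(lambda), lambda * (1 - f))
        reads <- c(emit_cell_reads(cp, model$cells, "+", frag, layout),
                   emit_cell_reads(cm, model$cells, "-", frag, layout))
        sid <- sprintf("%s_%s_r%d", cell, assay, r)
        read_sets[[sid]] <- stranded_read_set(sid, cell, assay, r, reads)
      }
    }
  }
  truth <- list(clusters = model$clusters,
                domains = model$domains,
                genes = expr$truth)
  list(read_sets = read_sets, truth = truth)
}

#' Simulate TFBS interval sets with a planted enriched subset
#'
#' Enriched TFs place a configured fraction of their sites uniformly inside
#' the planted differential windows; all other sites (and all sites of null
#' TFs) are uniform genome-wide.
#'
#' @param cfg `SimulationConfig`.
#' @param layout `GenomeLayout`.
#' @param diff_windows `GRanges` of differential windows (planted cluster
#'   cells).
#' @return list: `sites` (`GRanges` with `name` = TF), `truth`
#'   (data.frame tf, enriched).
#' @export
simulate_tfbs <- function(cfg, layout, diff_windows) {
  set.seed(stage_seed(cfg, "tfbs"))
  w <- cfg$tfbs_site_width
  cs <- cfg$chrom_sizes
  tfs <- c(sprintf("TFE%02d", seq_len(cfg$n_tfs_enriched)),
           sprintf("TFN%03d", seq_len(cfg$n_tfs_null)))
  enriched <- c(rep(TRUE, cfg$n_tfs_enriched), rep(FALSE, cfg$n_tfs_null))
  uniform_sites <- function(k) {
    chr <- sample(names(cs), k, replace = TRUE, prob = pmax(cs - w + 1, 0))
    s0 <- floor(runif(k) * (cs[chr] - w + 1))
    GRanges(chr, IRanges(s0 + 1, s0 + w), seqinfo = layout_seqinfo(layout))
  }
  in_window_sites <- function(k) {
    if (length(diff_windows) == 0L)
      stop("no differential windows to place enriched sites into")
    fits <- width(diff_windows) >= w
    if (!any(fits)) stop("no differential window fits a site")
    wi <- sample(which(fits), k, replace = TRUE,
                 prob = width(diff_windows)[fits] - w + 1)
    s0 <- start(diff_windows)[wi] - 1L +
      floor(runif(k) * (width(diff_windows)[wi] - w + 1))
    GRanges(as.character(seqnames(diff_windows))[wi],
            IRanges(s0 + 1, s0 + w), seqinfo = layout_seqinfo(layout))
  }
  all_sites <- lapply(seq_along(tfs), function(i) {
    n <- cfg$tfbs_sites_per_tf
    gr <- if (enriched[i]) {
      k_in <- round(cfg$tfbs_enriched_fraction * n)
      c(in_window_sites(k_in), uniform_sites(n - k_in))
    } else uniform_sites(n)
    mcols(gr)$name <- tfs[i]
    gr
  })
  sites <- do.call(c, all_sites)
  list(sites = sites,
       truth = data.frame(tf = tfs, enriched = enriched,
                          stringsAsFactors = FALSE))
}
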