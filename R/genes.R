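# Gene-centric integration: expression strata, metagene profiles, merged
# per-gene modification verdicts and modification/expression correlation.

#' Counts-per-million normalization
#'
#' @param counts genes x samples count matrix.
#' @return CPM matrix (columns scaled by their totals x 1e6).
#' @export
cpm <- function(counts) {
  ls <- colSums(counts)
  if (any(ls == 0)) stop("zero library size")
  sweep(counts, 2L, ls, "/") * 1e6
}

#' Stratify genes by expression level
#'
#' Genes with mean CPM >= `expressed_cpm` are expressed and split into
#' `n_strata` equal-size rank groups ("1" lowest .. as character); genes
#' below `silent_cpm` are "silent"; the in-between band is "excluded".
#' Rank ties are broken by gene order for determinism.
#'
#' @param counts genes x samples expression count matrix (rownames =
#'   gene ids).
#' @param n_strata number of strata (>= 2; 5 = quintiles, 10 = deciles).
#' @param expressed_cpm,silent_cpm thresholds (defaults 1 and 0.2; the
#'   source study defines none, these are declared package defaults).
#' @return character vector of stratum labels parallel to rows.
#' @export
stratify_expression <- function(counts, n_strata = 10, expressed_cpm = 1,
                                silent_cpm = 0.2) {
  if (n_strata < 2) stop("n_strata must be >= 2")
  mean_cpm <- rowMeans(cpm(counts))
  lab <- rep("excluded", nrow(counts))
  lab[mean_cpm < silent_cpm] <- "silent"
  expr <- which(mean_cpm >= expressed_cpm)
  if (length(expr) < n_strata)
    stop("fewer expressed genes (", length(expr), ") than strata")
  rk <- rank(mean_cpm[expr], ties.method = "first")
  lab[expr] <- as.character(
    as.integer(cut(rk, breaks = seq(0, length(expr),
                                    length.out = n_strata + 1),
                   labels = FALSE)))
  lab
}

#' Metagene profile with length-normalized bodies and linear flanks
#'
#' Per gene: `flank_bp/flank_bin_bp` fixed-width upstream bins, `body_bins`
#' length-normalized body bins, and the same number of downstream bins,
#' oriented 5'->3' by gene strand. The profile is mean read density (CPM
#' per bp) over the genes of each stratum. Genes with a body shorter than
#' `body_bins` bp are skipped.
#'
#' @param read_sets list of `StrandedReadSet` (pooled).
#' @param genes stranded gene `GRanges`.
#' @param flank_bp linear flank (default 2000).
#' @param body_bins number of body bins (default 100).
#' @param flank_bin_bp flank bin width (default 50).
#' @param strata optional stratum labels per gene; profiles are averaged
#'   per stratum ("excluded" skipped). Default: one "all" stratum.
#' @param strand_mode "combined", or "template_coding" to split reads by
#'   strand relative to the gene (two profiles per stratum).
#' @return list: `profile` matrix (bins x stratum, or bins x
#'   stratum:strand), `bin` data.frame describing the bins, `n_genes`
#'   per stratum.
#' @export
metagene_profile <- function(read_sets, genes, flank_bp = 2000,
                             body_bins = 100, flank_bin_bp = 50,
                             strata = NULL,
                             strand_mode = c("combined",
                                             "template_coding")) {
  strand_mode <- match.arg(strand_mode)
  if (is.null(strata)) strata <- rep("all", length(genes))
  n_flank <- flank_bp %/% flank_bin_bp
  n_bins <- 2L * n_flank + body_bins
  usable <- width(genes) >= body_bins
  if (any(!usable))
    message(sum(!usable), " gene(s) shorter than body_bins bp skipped")
  if (inherits(read_sets, "StrandedReadSet")) read_sets <- list(read_sets)
  lib <- sum(vapply(read_sets, function(x) x$library_size, 1))
  index <- midpoint_index(read_sets)
  gs <- as.character(strand(genes))
  levs <- setdiff(unique(strata[usable]), "excluded")
  modes <- if (strand_mode == "combined") "combined"
           else c("template", "coding")
  prof <- matrix(0, n_bins,
                 length(levs) * length(modes),
                 dimnames = list(NULL, if (length(modes) == 1L) levs
                                 else as.vector(outer(levs, modes,
                                                      paste, sep = ":"))))
  n_genes <- setNames(integer(length(levs)), levs)
  # per-gene bin densities accumulated stratum-wise
  bin_width <- function(i) c(rep(flank_bin_bp, n_flank),
                             rep(width(genes)[i] / body_bins, body_bins),
                             rep(flank_bin_bp, n_flank))
  count_bins <- function(i, strand_sel) {
    chr <- as.character(seqnames(genes))[i]
    gstart0 <- start(genes)[i] - 1
    gend0 <- end(genes)[i]
    glen <- gend0 - gstart0
    # bin edges in genomic coordinates, 5'->3'
    if (gs[i] == "+") {
      edges <- c(seq(gstart0 - flank_bp, gstart0, by = flank_bin_bp),
                 gstart0 + glen * seq_len(body_bins) / body_bins,
                 gend0 + flank_bin_bp * seq_len(n_flank))
    } else {
      edges <- c(seq(gend0 + flank_bp, gend0, by = -flank_bin_bp),
                 gend0 - glen * seq_len(body_bins) / body_bins,
                 gstart0 - flank_bin_bp * seq_len(n_flank))
    }
    counts <- numeric(n_bins)
    for (s in strand_sel) {
      v <- index[[paste0(chr, s)]]
      if (is.null(v)) next
      # counts in [edges[k], edges[k+1]) (or reversed for minus genes)
      lo <- pmin(edges[-length(edges)], edges[-1L])
      hi <- pmax(edges[-length(edges)], edges[-1L])
      counts <- counts + (findInterval(hi - 1e-9, v) -
                          findInterval(lo - 1e-9, v))
    }
    counts
  }
  for (i in which(usable)) {
    st <- strata[i]
    if (is.na(st) || st == "excluded") next
    n_genes[st] <- n_genes[st] + 1L
    bw <- bin_width(i)
    for (md in modes) {
      ss <- switch(md,
                   combined = c("+", "-"),
                   template = if (gs[i] == "+") "-" else "+",
                   coding = if (gs[i] == "+") "+" else "-")
      dens <- count_bins(i, ss) / bw / lib * 1e6
      col <- if (length(modes) == 1L) st else paste(st, md, sep = ":")
      prof[, col] <- prof[, col] + dens
    }
  }
  for (l in levs) if (n_genes[l] > 0) {
    cols <- if (length(modes) == 1L) l else paste(l, modes, sep = ":")
    prof[, cols] <- prof[, cols] / n_genes[l]
  }
  bin <- data.frame(
    bin = seq_len(n_bins),
    zone = c(rep("upstream", n_flank), rep("body", body_bins),
             rep("downstream", n_flank)))
  list(profile = prof, bin = bin, n_genes = n_genes)
}

#' Merge TSS, gene-body and window differential evidence per gene
#'
#' A gene gains "window" evidence iff at least one significant 1-kb window
#' overlaps the gene body +/- `flank` bp; "TSS"/"body" evidence comes from
#' the respective significant units. Genes with no evidence are absent.
#'
#' @param tss_res,body_res differential tables from
#'   [differential_regions()] whose `unit_id` is the gene id.
#' @param window_res window differential table.
#' @param genes gene `GRanges`.
#' @param flank window-evidence flank in bp (default 2000).
#' @return list: `calls` (gene_id, evidence comma-set, per-evidence flags)
#'   and `venn` (counts per evidence combination).
#' @export
merge_gene_calls <- function(tss_res, body_res, window_res, genes,
                             flank = 2000) {
  gid <- mcols(genes)$gene_id
  ev_tss <- gid %in% tss_res$unit_id[tss_res$significant]
  ev_body <- gid %in% body_res$unit_id[body_res$significant]
  sigw <- window_res[window_res$significant, , drop = FALSE]
  ev_win <- rep(FALSE, length(genes))
  if (nrow(sigw)) {
    wgr <- GRanges(sigw$chrom, IRanges(sigw$start + 1L, sigw$end))
    flanked <- GRanges(seqnames(genes),
                       IRanges(pmax(1L, start(genes) - flank),
                               end(genes) + flank))
    ev_win <- overlapsAny(flanked, wgr, ignore.strand = TRUE)
  }
  any_ev <- ev_tss | ev_body | ev_win
  calls <- data.frame(gene_id = gid[any_ev],
                      tss = ev_tss[any_ev], body = ev_body[any_ev],
                      window = ev_win[any_ev],
                      stringsAsFactors = FALSE)
  calls$evidence <- apply(calls[, c("tss", "body", "window")], 1L,
                          function(x) paste(c("TSS", "body", "window")[x],
                                            collapse = "+"))
  venn <- as.data.frame(table(evidence = calls$evidence),
                        stringsAsFactors = FALSE)
  list(calls = calls, venn = venn)
}

#' Correlation and regression of expression change on modification change
#'
#' @param mod_log2fc per-gene modification log2 fold change.
#' @param mrna_log2fc per-gene mRNA log2 fold change (same genes).
#' @param subset optional logical/integer subset of genes.
#' @return list: pearson, spearman, slope, intercept, n.
#' @export
correlate_mod_expression <- function(mod_log2fc, mrna_log2fc,
                                     subset = NULL) {
  x <- mod_log2fc; y <- mrna_log2fc
  if (!is.null(subset)) { x <- x[subset]; y <- y[subset] }
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 genes")
  if (sd(x) == 0) stop("modification fold changes have zero variance")
  fit <- lm(y ~ x)
  list(pearson = cor(x, y, method = "pearson"),
       spearman = cor(x, y, method = "spearman"),
       slope = unname(coef(fit)[2L]),
       intercept = unname(coef(fit)[1L]),
       n = length(x))
}

#' Classify genes with significant 5hmC windows by expression direction
#'
#' Per gene carrying at least one significant 5hmC 1-kb window (within the
#' body +/- `flank`): "less_expressed_more_5hmC" if its mRNA change opposes
#' the window direction, "more_expressed_more_5hmC" if it follows it,
#' "mixed_windows" if windows disagree, "not_de" if the gene is not
#' differentially expressed. Genes also significant for 5mC can be
#' excluded to isolate the 5hmC association.
#'
#' @param window_res 5hmC window differential table (A = first cell type).
#' @param genes gene `GRanges`.
#' @param de_table data.frame gene_id, de (logical), log2fc (mRNA, A over
#'   B).
#' @param exclude_gene_ids optional gene ids to drop (e.g. 5mC-significant
#'   genes).
#' @param flank bp (default 2000).
#' @return list: `genes` per-gene table, `fractions` named fractions per
#'   category.
#' @export
classify_hmc_expression_direction <- function(window_res, genes, de_table,
                                              exclude_gene_ids = NULL,
                                              flank = 2000) {
  sigw <- window_res[window_res$significant, , drop = FALSE]
  gid <- mcols(genes)$gene_id
  cats <- character(0); ids <- character(0)
  if (nrow(sigw)) {
    wgr <- GRanges(sigw$chrom, IRanges(sigw$start + 1L, sigw$end))
    flanked <- GRanges(seqnames(genes),
                       IRanges(pmax(1L, start(genes) - flank),
                               end(genes) + flank))
    ov <- findOverlaps(flanked, wgr, ignore.strand = TRUE)
    hit_genes <- unique(queryHits(ov))
    for (g in hit_genes) {
      id <- gid[g]
      if (id %in% exclude_gene_ids) next
      dirs <- unique(sigw$direction[subjectHits(ov)[queryHits(ov) == g]])
      d <- de_table[de_table$gene_id == id, , drop = FALSE]
      cat <- if (length(dirs) > 1L) "mixed_windows"
        else if (nrow(d) == 0L || !isTRUE(d$de[1L])) "not_de"
        else {
          mod_up_A <- dirs == "A-up"
          expr_up_A <- d$log2fc[1L] > 0
          if (mod_up_A != expr_up_A) "less_expressed_more_5hmC"
          else "more_expressed_more_5hmC"
        }
      ids <- c(ids, id); cats <- c(cats, cat)
    }
  }
  levs <- c("less_expressed_more_5hmC", "more_expressed_more_5hmC",
            "mixed_windows", "not_de")
  frac <- if (length(cats))
    as.numeric(table(factor(cats, levels = levs))) / length(cats)
  else rep(NA_real_, length(levs))
  list(genes = data.frame(gene_id = ids, category = cats,
                          stringsAsFactors = FALSE),
       fractions = setNames(frac, levs))
}
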