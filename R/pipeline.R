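# End-to-end orchestration: simulate -> count -> differential -> cluster ->
# genes -> asymmetry -> tfbs -> report, as one reproducible, seeded run.

#' Default analysis parameters
#'
#' Window-size ladder, significance and clustering thresholds, and
#' sampling sizes used throughout the pipeline.
#'
#' @param window_sizes tiling sizes in bp (default the tested ladder
#'   100 bp - 50 kb; the 1-kb analysis drives clustering).
#' @param alpha BH-adjusted significance cutoff.
#' @param gap_bp,density,min_sig clustering rule parameters.
#' @param min_reads asymmetry exclusion threshold.
#' @param min_total minimum pooled count for differential testing.
#' @param tss_flank TSS region half-width (bp).
#' @param large_span_bp large-cluster flag threshold.
#' @param asym_sizes window-size ladder for asymmetry sampling.
#' @param n_sample_windows random windows per size.
#' @param n_shuffles TFBS shuffles.
#' @return list of validated parameters.
#' @export
analysis_params <- function(window_sizes = c(100, 500, 1000, 2000, 8000,
                                             20000, 50000),
                            alpha = 0.05, gap_bp = 5000, density = 1 / 8,
                            min_sig = 2, min_reads = 20, min_total = 10,
                            tss_flank = 2000, large_span_bp = 1e5,
                            asym_sizes = c(1e3, 5e3, 2e4, 1e5, 1e6, 2e6),
                            n_sample_windows = 10000, n_shuffles = 100) {
  p <- as.list(environment())
  stopifnot(alpha > 0, alpha < 1, gap_bp > 0, density > 0, min_reads > 0,
            min_total >= 1, tss_flank > 0, n_shuffles >= 2)
  p
}

write_tsv <- function(x, path) {
  fwrite(as.data.table(x), path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Validate a set of pipeline input files
#'
#' Checks BED bounds and strand fields against the layout, chromosome-name
#' consistency, and completeness of the sample grid
#' (cell type x assay x replicate). Violations are reported, never
#' silently corrected.
#'
#' @param layout `GenomeLayout`.
#' @param read_sets named list of `StrandedReadSet`.
#' @param cell_types,assays,n_replicates expected grid.
#' @return data.frame of violations (zero rows when clean).
#' @export
validate_inputs <- function(layout, read_sets, cell_types = c("D1", "D2"),
                            assays = c("5mC", "5hmC", "input"),
                            n_replicates = 3L) {
  v <- list()
  note <- function(kind, msg)
    v[[length(v) + 1L]] <<- data.frame(kind = kind, message = msg,
                                       stringsAsFactors = FALSE)
  for (rs in read_sets) {
    chr <- as.character(seqnames(rs$reads))
    unknown <- setdiff(unique(chr), names(layout$chrom_sizes))
    if (length(unknown))
      note("chromosome", paste0(rs$sample_id, ": unknown chromosome(s) ",
                                paste(unknown, collapse = ",")))
    known <- chr %in% names(layout$chrom_sizes)
    oob <- sum(end(rs$reads)[known] >
                 layout$chrom_sizes[chr[known]]) +
      sum(start(rs$reads) < 1)
    if (oob > 0)
      note("bounds", paste0(rs$sample_id, ": ", oob,
                            " read(s) beyond chromosome end"))
    if (any(!as.character(strand(rs$reads)) %in% c("+", "-")))
      note("strand", paste0(rs$sample_id, ": unstranded read(s)"))
    if (rs$library_size != length(rs$reads))
      note("library", paste0(rs$sample_id, ": library_size mismatch"))
  }
  have <- data.frame(
    cell_type = vapply(read_sets, `[[`, "", "cell_type"),
    assay = vapply(read_sets, `[[`, "", "assay"),
    replicate = vapply(read_sets, function(x) x$replicate, 1L))
  grid <- expand.grid(cell_type = cell_types, assay = assays,
                      replicate = seq_len(n_replicates),
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    hit <- have$cell_type == grid$cell_type[i] &
      have$assay == grid$assay[i] & have$replicate == grid$replicate[i]
    if (!any(hit))
      note("grid", sprintf("missing sample: %s %s replicate %d",
                           grid$cell_type[i], grid$assay[i],
                           grid$replicate[i]))
  }
  if (!length(v))
    return(data.frame(kind = character(0), message = character(0)))
  do.call(rbind, v)
}

#' Run the full synthetic-data pipeline
#'
#' Simulates the experiment, runs every analysis stage for the enabled
#' modification assays, writes one TSV per stage under `outdir` and
#' returns a manifest. Fully deterministic given the config seed.
#'
#' @param cfg a `SimulationConfig`.
#' @param outdir output directory (created).
#' @param params [analysis_params()] list.
#' @param assays modification assays to analyze (default those configured,
#'   minus "input").
#' @return invisible manifest list: config echo, output paths, per-stage
#'   record counts, plus in-memory `results`.
#' @export
run_pipeline <- function(cfg, outdir, params = analysis_params(),
                         assays = setdiff(names(cfg$reads_per_sample),
                                          "input")) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(); log <- list(); results <- list()
  stage <- function(name, path, x) {
    write_tsv(x, file.path(outdir, path))
    paths[[name]] <<- file.path(outdir, path)
    log[[name]] <<- nrow(as.data.frame(x))
  }
  sim <- simulate_genome(cfg)
  expr <- simulate_expression(cfg, sim)
  mods <- simulate_modification_reads(cfg, sim, expr,
                                      assays = intersect(
                                        names(cfg$reads_per_sample),
                                        c(assays, "input")))
  layout <- sim$layout
  ct <- cfg$cell_types
  windows <- tile_genome(layout, 1000L)
  strata <- stratify_expression(expr$counts)
  stage("strata", "expression_strata.tsv",
        data.frame(gene_id = rownames(expr$counts), stratum = strata))
  # mRNA differential (same exact engine, declared substitute for a
  # replicate-aware model)
  rna_tot <- colSums(expr$counts)
  ia <- expr$samples$cell_type == ct[1]
  de_res <- differential_units(
    granges(sim$genes, use.mcols = FALSE),
    as.integer(rowSums(expr$counts[, ia, drop = FALSE])),
    as.integer(rowSums(expr$counts[, !ia, drop = FALSE])),
    sum(rna_tot[ia]), sum(rna_tot[!ia]),
    min_total = params$min_total, alpha = params$alpha,
    unit_ids = rownames(expr$counts))
  stage("rna_diff", "rna_differential.tsv", de_res)
  de_table <- data.frame(gene_id = de_res$unit_id, de = de_res$significant,
                         log2fc = de_res$log2fc)

  truth_cells <- windows[overlapsAny(windows, mods$truth$clusters)]
  per_assay <- list()
  for (assay in assays) {
    sets <- Filter(function(x) x$assay == assay, mods$read_sets)
    wc <- count_reads_in_windows(sets, windows, layout)
    wres <- differential_windows(wc, ct[1], ct[2],
                                 min_total = params$min_total,
                                 alpha = params$alpha)
    stage(paste0(assay, "_windows"),
          paste0(assay, "_window_differential.tsv"), wres)
    sigw <- wres[wres$significant, , drop = FALSE]
    cl <- build_clusters(sigw, gap_bp = params$gap_bp,
                         density_threshold = params$density,
                         min_sig = params$min_sig)
    stage(paste0(assay, "_clusters"), paste0(assay, "_clusters.tsv"), cl)
    tssr <- point_regions(sim$genes, "tss", params$tss_flank, layout)
    tres <- differential_regions(sets, tssr, ct[1], ct[2],
                                 min_total = params$min_total,
                                 alpha = params$alpha)
    tres$unit_id <- mcols(sim$genes)$gene_id
    bres <- differential_regions(sets, sim$genes, ct[1], ct[2],
                                 min_total = params$min_total,
                                 alpha = params$alpha)
    stage(paste0(assay, "_tss"), paste0(assay, "_tss_differential.tsv"),
          tres)
    stage(paste0(assay, "_body"), paste0(assay, "_body_differential.tsv"),
          bres)
    merged <- merge_gene_calls(tres, bres, wres, sim$genes,
                               flank = params$tss_flank)
    stage(paste0(assay, "_gene_calls"), paste0(assay, "_gene_calls.tsv"),
          merged$calls)
    feat <- assign_feature(GRanges(sigw$chrom,
                                   IRanges(sigw$start + 1L, sigw$end)),
                           sim$genes, layout = layout)
    stage(paste0(assay, "_features"), paste0(assay, "_sig_features.tsv"),
          as.data.frame(table(feature = feat), stringsAsFactors = FALSE))
    # strand asymmetry on cell type 1 pooled replicates
    a_sets <- Filter(function(x) x$cell_type == ct[1], sets)
    gtr <- gene_template_ratio(a_sets, sim$genes,
                               min_reads = params$min_reads)
    stage(paste0(assay, "_template"), paste0(assay, "_gene_template.tsv"),
          gtr)
    stage(paste0(assay, "_asym_expr"),
          paste0(assay, "_asymmetry_by_expression.tsv"),
          asymmetry_by_expression(gtr, strata))
    conc <- concordance_curve(a_sets, layout, params$asym_sizes,
                              n = params$n_sample_windows,
                              min_reads = params$min_reads,
                              seed = stage_seed(cfg, "reads") + 17L)
    stage(paste0(assay, "_concordance"), paste0(assay, "_concordance.tsv"),
          conc)
    absz <- asymmetry_by_size(a_sets, layout,
                              params$asym_sizes,
                              n = params$n_sample_windows,
                              min_reads = params$min_reads,
                              seed = stage_seed(cfg, "reads") + 29L)
    stage(paste0(assay, "_asym_size"),
          paste0(assay, "_asymmetry_by_size.tsv"), absz$summary)
    rfa <- repeat_family_asymmetry(a_sets, sim$repeats,
                                   min_reads = params$min_reads)
    stage(paste0(assay, "_repeats"),
          paste0(assay, "_repeat_asymmetry.tsv"), rfa$families)
    # expression-stratified metagene (quintiles) on cell type 1
    mg <- metagene_profile(a_sets, sim$genes,
                           strata = stratify_expression(expr$counts,
                                                        n_strata = 5))
    stage(paste0(assay, "_metagene"), paste0(assay, "_metagene.tsv"),
          cbind(mg$bin, as.data.frame(mg$profile, check.names = FALSE)))
    # replicate/sample correlation matrix on window counts
    flat <- apply(wc$counts, 2L, function(m) rowSums(m))
    stage(paste0(assay, "_sample_cor"),
          paste0(assay, "_sample_correlations.tsv"),
          cbind(sample_id = colnames(flat), as.data.frame(cor(flat))))
    # mRNA change vs gene-body modification change over significant genes
    sig_body <- bres$significant
    if (sum(sig_body) >= 3) {
      co <- correlate_mod_expression(
        bres$log2fc[sig_body],
        de_table$log2fc[match(bres$unit_id[sig_body],
                              de_table$gene_id)])
      stage(paste0(assay, "_mod_expr_cor"),
            paste0(assay, "_mod_expression_correlation.tsv"),
            as.data.frame(co))
    }
    if (assay == "5hmC") {
      hx <- classify_hmc_expression_direction(wres, sim$genes, de_table,
                                              flank = params$tss_flank)
      stage("hmc_expression_direction", "hmc_expression_direction.tsv",
            data.frame(category = names(hx$fractions),
                       fraction = as.numeric(hx$fractions)))
    }
    per_assay[[assay]] <- list(windows = wres, clusters = cl, tss = tres,
                               body = bres, merged = merged,
                               template = gtr, concordance = conc)
  }
  # cross-assay / cross-cell-type asymmetry correlations on gene bodies
  recs <- list()
  for (assay in assays) for (cell in ct) {
    s <- Filter(function(x) x$cell_type == cell & x$assay == assay,
                mods$read_sets)
    recs[[paste(assay, cell, sep = "_")]] <-
      gene_template_ratio(s, sim$genes,
                          min_reads = params$min_reads)$template_ratio
  }
  if (!is.null(sim$genome))
    recs$CH <- ch_region_asymmetry(sim$genome, sim$genes)$template_ratio
  if (length(recs) >= 2L) {
    cm <- asymmetry_correlations(recs)
    stage("asym_correlations", "asymmetry_correlations.tsv",
          cbind(set = rownames(cm), as.data.frame(cm)))
  }
  # cross-assay cluster summary (when both assays present)
  if (length(assays) >= 1L) {
    a1 <- assays[1L]
    other <- if (length(assays) > 1L) per_assay[[assays[2L]]] else NULL
    summ <- summarize_clusters(
      per_assay[[a1]]$clusters,
      per_assay[[a1]]$windows[per_assay[[a1]]$windows$significant, ],
      genes = sim$genes,
      other_clusters = other$clusters,
      other_sig_windows =
        if (!is.null(other))
          other$windows[other$windows$significant, ] else NULL,
      large_span_bp = params$large_span_bp)
    stage("cluster_summary", "cluster_summary.tsv", summ$table)
  }
  # TFBS enrichment on the first assay's significant windows
  tf <- simulate_tfbs(cfg, layout, truth_cells)
  sig1 <- per_assay[[assays[1L]]]$windows
  sig_gr <- GRanges(sig1$chrom[sig1$significant],
                    IRanges(sig1$start[sig1$significant] + 1L,
                            sig1$end[sig1$significant]))
  tfz <- tfbs_zscore(sig_gr, tf$sites, layout,
                     n_shuffles = params$n_shuffles,
                     seed = stage_seed(cfg, "tfbs") + 1L)
  stage("tfbs", "tfbs_enrichment.tsv", tfz)
  # CH asymmetry of gene bodies (when sequence was generated)
  if (!is.null(sim$genome)) {
    chg <- ch_region_asymmetry(sim$genome, sim$genes)
    chg <- cbind(gene_id = mcols(sim$genes)$gene_id, chg)
    stage("ch_genes", "ch_gene_asymmetry.tsv", chg)
  }
  # truth-vs-called cluster recovery
  rec <- cluster_recovery(per_assay[[assays[1L]]]$clusters,
                          mods$truth$clusters)
  stage("cluster_recovery", "cluster_recovery.tsv", rec$table)
  manifest <- list(config = unclass(cfg)[!vapply(unclass(cfg), is.function,
                                                 TRUE)],
                   params = params, outputs = paths, n_records = log,
                   recovery = rec$summary)
  jsonlite::write_json(manifest[c("params", "outputs", "n_records",
                                  "recovery")],
                       file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(c(manifest, list(results = c(per_assay,
                                         list(truth = mods$truth,
                                              tfbs = tfz, de = de_res,
                                              strata = strata,
                                              sim = sim, expr = expr)))))
}

#' Truth-vs-called cluster recovery
#'
#' Matches each planted cluster with the best-overlapping called cluster
#' of the same direction and reports the Jaccard index.
#'
#' @param called cluster table from [build_clusters()].
#' @param truth planted cluster `GRanges` (with `direction`).
#' @return list: `table` per planted cluster, `summary` (recall at
#'   Jaccard >= 0.8, n_called).
#' @export
cluster_recovery <- function(called, truth, jaccard_min = 0.8) {
  cgr <- clusters_granges(called)
  rows <- lapply(seq_along(truth), function(i) {
    t1 <- truth[i]
    best <- 0
    if (length(cgr)) {
      same <- cgr[mcols(cgr)$direction == mcols(t1)$direction &
                    as.character(seqnames(cgr)) ==
                      as.character(seqnames(t1))]
      if (length(same)) {
        inter <- pmax(0, pmin(end(t1), end(same)) -
                        pmax(start(t1), start(same)) + 1)
        uni <- width(t1) + width(same) - inter
        best <- max(inter / uni)
      }
    }
    data.frame(chrom = as.character(seqnames(t1)), start = start(t1) - 1L,
               end = end(t1), direction = mcols(t1)$direction,
               span_bp = width(t1), jaccard = best,
               recovered = best >= jaccard_min)
  })
  tab <- do.call(rbind, rows)
  list(table = tab,
       summary = list(n_truth = length(truth),
                      n_recovered = sum(tab$recovered),
                      n_called = nrow(called)))
}
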