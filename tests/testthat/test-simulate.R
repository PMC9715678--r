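test_that("config validation rejects bad parameters", {
  expect_error(sim_config(), "seed")
  expect_error(sim_config(seed = 1, chrom_sizes = c(chr1 = 1234)),
               "1 kb")
  expect_error(sim_config(seed = 1, expr_dispersion = 0), "dispersion")
  expect_error(sim_config(seed = 1,
                          biotype_props = c(coding = 0.9, lncRNA = 0.3,
                                            other = 0.1)),
               "sum to 1")
  expect_error(sim_config(seed = 1,
                          template_fraction_deciles = c(0.5, 0.6)),
               "length 10")
})

test_that("simulation is deterministic given the seed and varies across seeds", {
  cfg <- small_sim_config(seed = 7,
                          chrom_sizes = c(chr1 = 3e5, chr2 = 3e5),
                          n_genes = 20, n_repeats = 10,
                          make_sequence = TRUE)
  a <- simulate_genome(cfg)
  b <- simulate_genome(cfg)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(as.data.frame(a$genes), as.data.frame(b$genes))
  cfg2 <- small_sim_config(seed = 8,
                           chrom_sizes = c(chr1 = 3e5, chr2 = 3e5),
                           n_genes = 20, n_repeats = 10,
                           make_sequence = TRUE)
  c <- simulate_genome(cfg2)
  expect_false(identical(as.character(a$genome),
                         as.character(c$genome)))
})

test_that("genes and repeats are placed in bounds without overlap", {
  cfg <- small_sim_config(seed = 3)
  sim <- simulate_genome(cfg)
  expect_length(sim$genes, cfg$n_genes)
  expect_true(all(start(sim$genes) >= 1))
  expect_true(all(end(sim$genes) <=
                    cfg$chrom_sizes[as.character(seqnames(sim$genes))]))
  expect_equal(sum(countOverlaps(sim$genes, sim$genes) > 1), 0L)
  expect_equal(sum(countOverlaps(sim$repeats, sim$genes,
                                 ignore.strand = TRUE) > 0), 0L)
  # an impossible placement errors with advice
  tiny <- small_sim_config(seed = 4, chrom_sizes = c(chr1 = 50000),
                           n_genes = 40, n_clusters = 0)
  expect_error(simulate_genome(tiny), "larger genome")
})

test_that("CH bias 0.5 gives strand-symmetric CH content", {
  cfg <- small_sim_config(seed = 5, chrom_sizes = c(chr1 = 4e5),
                          n_genes = 5, n_repeats = 5, n_clusters = 0,
                          ribosomal_like_n = 0, olfactory_like_n = 0,
                          ch_bias_range = c(0.5, 0.5),
                          make_sequence = TRUE)
  sim <- simulate_genome(cfg)
  ch <- ch_asymmetry(sim$genome)
  # binomial noise bound: |CH+ - CH-| ~ sqrt(total) scale
  expect_lt(ch$coefficient, 4 / sqrt(ch$ch_plus + ch$ch_minus))
})

test_that("expression model plants means, DE fold changes and families", {
  cfg <- small_sim_config(seed = 11, n_de_genes = 30, de_log2fc = 2)
  sim <- simulate_genome(cfg)
  expr <- simulate_expression(cfg, sim)
  tr <- expr$truth
  # silent family genes produce zero counts
  olf <- tr$family %in% "olfactory_like"
  expect_true(all(expr$counts[olf, ] == 0))
  expect_true(all(tr$silent[olf]))
  # ribosomal-like genes are in the top decile
  expect_true(all(tr$decile[tr$family %in% "ribosomal_like"] == 10L))
  # DE genes: sample mean ratio ~ 2^log2fc at high planted mean
  hi <- which(tr$de & pmin(tr$mu_A, tr$mu_B) > 100)
  ia <- expr$samples$cell_type == "D1"
  if (length(hi)) {
    obs <- rowMeans(expr$counts[hi, ia, drop = FALSE]) /
      rowMeans(expr$counts[hi, !ia, drop = FALSE])
    expect_equal(unname(log2(obs)), tr$log2fc[hi], tolerance = 0.35)
  }
  # non-DE genes: ratio ~ 1
  nde <- which(!tr$de & tr$mu_B > 100)
  obs0 <- rowMeans(expr$counts[nde, ia, drop = FALSE]) /
    rowMeans(expr$counts[nde, !ia, drop = FALSE])
  expect_lt(abs(median(log2(obs0))), 0.2)
})

test_that("read simulation respects totals, bounds and strand balance", {
  cfg <- small_sim_config(seed = 21, n_clusters = 0,
                          asym_fraction_range = c(0.5, 0.5),
                          asym_small_jitter = 0,
                          template_fraction_silent = 0.5,
                          template_fraction_deciles = rep(0.5, 10),
                          repeat_families = c(LINE1 = 0.5, LINE2 = 0.5,
                                              SINE = 0.5, LTR = 0.5))
  sim <- simulate_genome(cfg)
  expr <- simulate_expression(cfg, sim)
  mods <- simulate_modification_reads(cfg, sim, expr, assays = "5hmC")
  rs <- mods$read_sets[["D1_5hmC_r1"]]
  # library size within 3 sigma of the configured Poisson total
  tot <- cfg$reads_per_sample[["5hmC"]]
  expect_lt(abs(rs$library_size - tot), 3 * sqrt(tot) + 1)
  # all reads in bounds
  expect_true(all(start(rs$reads) >= 1))
  expect_true(all(end(rs$reads) <=
                    cfg$chrom_sizes[as.character(seqnames(rs$reads))]))
  # all planted fractions 0.5 -> genome-wide strand balance
  npl <- sum(strand(rs$reads) == "+")
  expect_lt(abs(npl - rs$library_size / 2), 4 * sqrt(rs$library_size / 2))
})

test_that("planted clusters produce the configured pooled fold change", {
  cfg <- small_sim_config(seed = 31)
  sim <- simulate_genome(cfg)
  expr <- simulate_expression(cfg, sim)
  mods <- simulate_modification_reads(cfg, sim, expr, assays = "5mC")
  truth <- mods$truth$clusters
  d1 <- Filter(function(x) x$cell_type == "D1", mods$read_sets)
  d2 <- Filter(function(x) x$cell_type == "D2", mods$read_sets)
  c1 <- count_reads_in_regions(d1, truth)$total
  c2 <- count_reads_in_regions(d2, truth)$total
  N1 <- sum(vapply(d1, function(x) x$library_size, 1))
  N2 <- sum(vapply(d2, function(x) x$library_size, 1))
  ratio <- (c1 / N1) / (c2 / N2)
  up <- mcols(truth)$direction == "A-up"
  expect_equal(ratio[up], rep(cfg$cluster_fold, sum(up)), tolerance = 0.15)
  expect_equal(1 / ratio[!up], rep(cfg$cluster_fold, sum(!up)),
               tolerance = 0.15)
})

test_that("intergenic 0.5-fraction domains give near-zero asymmetry", {
  cfg <- small_sim_config(seed = 41, n_clusters = 0, n_repeats = 0,
                          n_genes = 4,
                          ribosomal_like_n = 0, olfactory_like_n = 0,
                          asym_fraction_range = c(0.5, 0.5),
                          asym_small_jitter = 0)
  sim <- simulate_genome(cfg)
  expr <- simulate_expression(cfg, sim)
  mods <- simulate_modification_reads(cfg, sim, expr, assays = "5hmC")
  d1 <- Filter(function(x) x$cell_type == "D1", mods$read_sets)
  win <- sample_windows(sim$layout, 1000, n = 500, seed = 1)
  cnt <- count_reads_in_regions(d1, win)
  co <- asymmetry_coefficient(cnt$plus, cnt$minus, 20)
  expect_lt(median(co, na.rm = TRUE), 0.15)
})

test_that("TFBS simulation plants enrichment and respects the null", {
  cfg <- small_sim_config(seed = 51)
  lay <- genome_layout(cfg$chrom_sizes)
  diffw <- GRanges("chr1", IRanges(seq(1, 99001, by = 1000), width = 1000))
  tf <- simulate_tfbs(cfg, lay, diffw)
  expect_equal(nrow(tf$truth), cfg$n_tfs_null + cfg$n_tfs_enriched)
  for (t in tf$truth$tf[tf$truth$enriched]) {
    sites <- tf$sites[mcols(tf$sites)$name == t]
    n_in <- sum(overlapsAny(sites, diffw))
    expect_gte(n_in, cfg$tfbs_enriched_fraction * cfg$tfbs_sites_per_tf)
  }
  # null TF overlap close to the uniform placement expectation
  null_tfs <- tf$truth$tf[!tf$truth$enriched]
  exp_frac <- sum(width(diffw)) / sum(cfg$chrom_sizes)
  n_in_null <- vapply(null_tfs, function(t)
    sum(overlapsAny(tf$sites[mcols(tf$sites)$name == t], diffw)), 1)
  expect_equal(mean(n_in_null) / cfg$tfbs_sites_per_tf, exp_frac,
               tolerance = 0.4)
  # zero enriched TFs supported
  cfg0 <- small_sim_config(seed = 52, n_tfs_enriched = 0)
  tf0 <- simulate_tfbs(cfg0, lay, diffw)
  expect_equal(sum(tf0$truth$enriched), 0L)
})
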