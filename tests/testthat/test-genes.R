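test_that("stratify_expression splits expressed genes into equal strata", {
  # 1000 expressed genes + 50 silent + 20 in-between
  set.seed(2)
  counts <- matrix(0L, 1070, 4)
  counts[1:1000, ] <- rpois(4000,
                            100 * rep(exp(seq(0, 7, length.out = 1000)),
                                      4) + 500)
  counts[1051:1070, ] <- 8L  # CPM in the excluded band (0.2 - 1)
  cp <- cpm(counts)
  lab <- stratify_expression(counts, n_strata = 5)
  expect_equal(as.integer(table(lab)[as.character(1:5)]), rep(200L, 5))
  expect_true(all(lab[1001:1050] == "silent"))
  # zero-count genes are silent
  expect_equal(stratify_expression(rbind(counts, 0L),
                                   n_strata = 5)[1071], "silent")
  # deterministic under rerun (ties broken by order)
  expect_identical(lab, stratify_expression(counts, n_strata = 5))
  expect_error(stratify_expression(counts[1:6, , drop = FALSE],
                                   n_strata = 10), "fewer expressed")
})

test_that("metagene profile is flat for uniform reads and respects strand", {
  lay <- toy_layout(c(chr1 = 100000))
  g <- GRanges("chr1", IRanges(20001, 30000), strand = "+")
  mcols(g)$gene_id <- "g1"
  # uniform read midpoints over gene +/- flank
  mids <- seq(17000, 33000, by = 10)
  rs <- reads_at(mids, rep("+", length(mids)), len = 50)
  mp <- metagene_profile(rs, g, flank_bp = 2000, body_bins = 100,
                         flank_bin_bp = 50)
  prof <- mp$profile[, "all"]
  expect_equal(length(prof), 40 + 100 + 40)
  expect_lt(diff(range(prof)) / mean(prof), 0.02)

  # minus-strand gene: an upstream-of-TSS-only signal lands in early bins
  gm <- GRanges("chr1", IRanges(20001, 30000), strand = "-")
  mcols(gm)$gene_id <- "g2"
  # TSS of a minus gene is at 30000; upstream means > 30000
  rs2 <- reads_at(seq(30500, 31500, by = 10), rep("+", 101), len = 50)
  mp2 <- metagene_profile(rs2, gm)
  prof2 <- mp2$profile[, "all"]
  expect_true(all(which(prof2 > 0) <= 40))
})

test_that("template + coding strand profiles sum to the combined profile", {
  set.seed(3)
  lay <- toy_layout(c(chr1 = 100000))
  g <- GRanges("chr1", IRanges(c(20001, 60001), c(30000, 75000)),
               strand = c("+", "-"))
  mcols(g)$gene_id <- c("g1", "g2")
  mids <- floor(runif(3000) * 95000)
  rs <- reads_at(mids, sample(c("+", "-"), 3000, TRUE), len = 50)
  comb <- metagene_profile(rs, g)$profile[, "all"]
  split <- metagene_profile(rs, g, strand_mode = "template_coding")$profile
  expect_equal(split[, "all:template"] + split[, "all:coding"], comb)
})

test_that("metagene recovers a planted TSS dip in the top stratum", {
  cfg <- small_sim_config(seed = 61, n_clusters = 0, tss_dip_depth = 0.9)
  sim <- simulate_genome(cfg)
  expr <- simulate_expression(cfg, sim)
  mods <- simulate_modification_reads(cfg, sim, expr, assays = "5hmC")
  d1 <- Filter(function(x) x$cell_type == "D1", mods$read_sets)
  strata <- stratify_expression(expr$counts, n_strata = 5)
  genes <- sim$genes[mcols(sim$genes)$biotype == "coding"]
  st <- strata[mcols(sim$genes)$biotype == "coding"]
  mp <- metagene_profile(d1, genes, strata = st)
  top <- mp$profile[, "5"]
  # minimum sits in the TSS-adjacent bins: the planted dip covers
  # [TSS - 1 kb, TSS + 1 kb), i.e. upstream bins 21-40 and the first few
  # body bins
  tss_zone <- 21:46
  expect_true(which.min(top) %in% tss_zone)
  dip_depth <- min(top[tss_zone]) / median(top[90:140])
  expect_lt(dip_depth, 0.6)
})

test_that("merge_gene_calls applies the window flank rule", {
  genes <- toy_genes()
  mk <- function(ids) data.frame(unit_id = ids, significant = TRUE,
                                 stringsAsFactors = FALSE)
  none <- data.frame(unit_id = character(0), significant = logical(0))
  # gA significant at TSS only
  m <- merge_gene_calls(mk("gA"), none,
                        data.frame(chrom = character(0), start = numeric(0),
                                   end = numeric(0),
                                   significant = logical(0)),
                        genes)
  expect_equal(m$calls$gene_id, "gA")
  expect_equal(m$calls$evidence, "TSS")
  # significant window 1.5 kb past gA's TTS (20000): window evidence
  wres <- data.frame(chrom = "chr1", start = 21500, end = 22500,
                     significant = TRUE, stringsAsFactors = FALSE)
  m2 <- merge_gene_calls(none, none, wres, genes)
  expect_equal(m2$calls$gene_id, "gA")
  expect_equal(m2$calls$evidence, "window")
  # 2.5 kb past the TTS: no evidence, gene absent
  wres3 <- data.frame(chrom = "chr1", start = 22500, end = 23500,
                      significant = TRUE, stringsAsFactors = FALSE)
  expect_equal(nrow(merge_gene_calls(none, none, wres3, genes)$calls), 0L)
  # evidence-combination counts match flags
  m4 <- merge_gene_calls(mk(c("gA", "gB")), mk("gA"), wres, genes)
  venn <- setNames(m4$venn$Freq, m4$venn$evidence)
  expect_equal(unname(venn["TSS+body+window"]), 1L)
  expect_equal(unname(venn["TSS"]), 1L)
})

test_that("correlate_mod_expression recovers exact and noisy couplings", {
  x <- c(-2, -1, 0, 1, 2)
  r <- correlate_mod_expression(x, -x)
  expect_equal(r$pearson, -1)
  expect_equal(r$slope, -1)
  expect_equal(r$intercept, 0)
  set.seed(17)
  x2 <- rnorm(200)
  y2 <- -0.8 * x2 + rnorm(200, sd = 0.3)
  r2 <- correlate_mod_expression(x2, y2)
  expect_equal(r2$slope, -0.8, tolerance = 0.12)
  expect_error(correlate_mod_expression(c(1, 2), c(1, 2)), "3 genes")
  expect_error(correlate_mod_expression(rep(1, 5), rnorm(5)),
               "zero variance")
  # null coupling: slope CI covers 0
  y0 <- rnorm(200)
  r0 <- correlate_mod_expression(x2, y0)
  se <- sqrt(sum((y0 - r0$intercept - r0$slope * x2)^2) / 198 /
               sum((x2 - mean(x2))^2))
  expect_lt(abs(r0$slope), 2.5 * se)
})

test_that("5hmC/expression direction classification follows definitions", {
  genes <- toy_genes()
  wres <- data.frame(chrom = c("chr1", "chr1", "chr1"),
                     start = c(11000, 45000, 46000),
                     end = c(12000, 46000, 47000),
                     significant = TRUE,
                     direction = c("A-up", "A-up", "B-up"),
                     stringsAsFactors = FALSE)
  de <- data.frame(gene_id = c("gA", "gB"), de = c(TRUE, TRUE),
                   log2fc = c(-1.5, 2))
  out <- classify_hmc_expression_direction(wres, genes, de)
  got <- setNames(out$genes$category, out$genes$gene_id)
  # gA: window A-up, mRNA B-up -> less expressed where more 5hmC
  expect_equal(unname(got["gA"]), "less_expressed_more_5hmC")
  # gB: windows in both directions -> mixed
  expect_equal(unname(got["gB"]), "mixed_windows")
  # not-DE gene
  de2 <- data.frame(gene_id = c("gA", "gB"), de = c(FALSE, TRUE),
                    log2fc = c(0, 2))
  out2 <- classify_hmc_expression_direction(
    wres[1, ], genes, de2)
  expect_equal(out2$genes$category, "not_de")
  # exclusion of 5mC-significant genes
  out3 <- classify_hmc_expression_direction(wres, genes, de,
                                            exclude_gene_ids = "gA")
  expect_false("gA" %in% out3$genes$gene_id)
})

test_that("planted category fractions are recovered multinomially", {
  # construct 500 genes on a long chromosome with planted categories
  set.seed(23)
  n <- 500
  starts <- seq(1, by = 20000, length.out = n)
  genes <- GRanges("chr1", IRanges(starts, width = 10000), strand = "+")
  mcols(genes)$gene_id <- sprintf("g%03d", seq_len(n))
  probs <- c(0.4, 0.1, 0.1, 0.4)
  cats <- sample(c("less", "more", "mixed", "notde"), n, TRUE, probs)
  wdir <- ifelse(cats %in% c("less", "more"),
                 sample(c("A-up", "B-up"), n, TRUE), "A-up")
  wres <- data.frame(chrom = "chr1", start = starts + 100,
                     end = starts + 1100, significant = TRUE,
                     direction = wdir, stringsAsFactors = FALSE)
  extra <- data.frame(chrom = "chr1", start = starts[cats == "mixed"] + 2000,
                      end = starts[cats == "mixed"] + 3000,
                      significant = TRUE,
                      direction = ifelse(wdir[cats == "mixed"] == "A-up",
                                         "B-up", "A-up"))
  wres <- rbind(wres, extra)
  l2 <- ifelse(cats == "less", ifelse(wdir == "A-up", -1, 1),
               ifelse(cats == "more", ifelse(wdir == "A-up", 1, -1), 0))
  de <- data.frame(gene_id = mcols(genes)$gene_id,
                   de = cats != "notde", log2fc = l2)
  out <- classify_hmc_expression_direction(wres, genes, de)
  expect_equal(unname(out$fractions),
               as.numeric(table(factor(cats, c("less", "more", "mixed",
                                               "notde"))) / n),
               tolerance = 1e-12)
})
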