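test_that("asymmetry coefficient arithmetic and the 20-read rule", {
  expect_equal(asymmetry_coefficient(30, 10), 0.5)
  expect_equal(asymmetry_coefficient(10, 10), 0)
  expect_true(is.na(asymmetry_coefficient(9, 10)))   # total 19 excluded
  expect_true(is.na(asymmetry_coefficient(0, 0)))    # never divides by 0
  expect_equal(asymmetry_coefficient(5, 0, min_reads = 5), 1)
  # vectorized
  expect_equal(asymmetry_coefficient(c(30, 10), c(10, 10)), c(0.5, 0))
})

test_that("coefficients match brute-force recomputation from raw reads", {
  set.seed(4)
  lay <- toy_layout()
  rs <- reads_at(floor(runif(4000) * 99000),
                 sample(c("+", "-"), 4000, TRUE, prob = c(0.65, 0.35)))
  regions <- GRanges("chr1", IRanges(floor(runif(200) * 90000) + 1,
                                     width = 3000))
  cnt <- count_reads_in_regions(rs, regions)
  brute <- brute_region_counts(rs, regions)
  expect_equal(asymmetry_coefficient(cnt$plus, cnt$minus),
               ifelse(brute$total >= 20,
                      abs(brute$plus - brute$minus) / brute$total,
                      NA_real_))
})

test_that("sample_windows respects size, bounds, seed and exclusions", {
  lay <- toy_layout()
  w <- sample_windows(lay, 500, n = 300, seed = 9)
  expect_true(all(width(w) == 500))
  expect_true(all(start(w) >= 1))
  expect_true(all(end(w) <= lay$chrom_sizes[as.character(seqnames(w))]))
  expect_identical(as.data.frame(sample_windows(lay, 500, 300, seed = 9)),
                   as.data.frame(w))
  expect_error(sample_windows(lay, 1e7), "exceeds")
  mask <- GRanges("chr1", IRanges(1, 60000))
  wm <- sample_windows(lay, 500, 200, exclude = mask, seed = 2)
  expect_false(any(overlapsAny(wm, mask)))
})

test_that("asymmetry_by_size shrinks with window size on symmetric data", {
  set.seed(14)
  lay <- toy_layout(c(chr1 = 1e6))
  rs <- reads_at(floor(runif(50000) * 999000),
                 sample(c("+", "-"), 50000, TRUE))
  out <- asymmetry_by_size(rs, lay, sizes = c(500, 5000, 50000),
                           n = 800, seed = 3)
  med <- out$summary$median
  expect_true(all(diff(med) < 0))       # folded-binomial shrinkage
  expect_lt(med[3], 0.02)
  # oversized request reports an empty distribution, not an error
  out2 <- asymmetry_by_size(rs, lay, sizes = c(5000, 2e6), n = 100,
                            seed = 3)
  expect_equal(nrow(out2$summary), 1L)
})

test_that("gene template ratio follows gene orientation", {
  lay <- toy_layout()
  gplus <- GRanges("chr1", IRanges(10001, 20000), strand = "+")
  mcols(gplus)$gene_id <- "gp"
  gminus <- GRanges("chr1", IRanges(10001, 20000), strand = "-")
  mcols(gminus)$gene_id <- "gm"
  rs <- reads_at(c(rep(12000, 30), rep(13000, 70)),
                 c(rep("+", 30), rep("-", 70)))
  expect_equal(gene_template_ratio(rs, gplus)$template_ratio, 0.7)
  expect_equal(gene_template_ratio(rs, gminus)$template_ratio, 0.3)
  # below the read floor -> excluded
  rs15 <- reads_at(rep(12000, 15), rep("-", 15))
  expect_true(is.na(gene_template_ratio(rs15, gplus)$template_ratio))
  expect_false(gene_template_ratio(rs15, gplus)$pass_filter)
})

test_that("global strand swap fixes the coefficient and flips ratios", {
  set.seed(24)
  lay <- toy_layout()
  mids <- floor(runif(2000) * 99000)
  sg <- sample(c("+", "-"), 2000, TRUE, prob = c(0.7, 0.3))
  rs <- reads_at(mids, sg)
  rs_swap <- reads_at(mids, ifelse(sg == "+", "-", "+"))
  regions <- GRanges("chr1", IRanges(seq(1, 90001, 10000), width = 9000))
  a <- count_reads_in_regions(rs, regions)
  b <- count_reads_in_regions(rs_swap, regions)
  expect_equal(asymmetry_coefficient(a$plus, a$minus),
               asymmetry_coefficient(b$plus, b$minus))
  g <- GRanges("chr1", IRanges(30001, 60000), strand = "+")
  mcols(g)$gene_id <- "g"
  r1 <- gene_template_ratio(rs, g)$template_ratio
  r2 <- gene_template_ratio(rs_swap, g)$template_ratio
  expect_equal(r1, 1 - r2)
})

test_that("asymmetry_by_expression summarizes strata medians", {
  ratios <- data.frame(gene_id = sprintf("g%02d", 1:40),
                       plus = 50, minus = 50, total = 100,
                       template_ratio = c(rep(0.5, 10), rep(0.6, 10),
                                          rep(0.7, 10), rep(0.55, 10)),
                       pass_filter = TRUE)
  strata <- c(rep("silent", 10), rep("1", 10), rep("2", 10),
              rep("excluded", 10))
  out <- asymmetry_by_expression(ratios, strata)
  expect_equal(out$stratum, c("silent", "1", "2"))
  expect_equal(out$median, c(0.5, 0.6, 0.7))
  expect_equal(out$n, c(10L, 10L, 10L))
})

test_that("repeat-family asymmetry recovers planted oriented fractions", {
  set.seed(34)
  lay <- toy_layout()
  reps <- GRanges("chr1", IRanges(c(1001, 20001, 40001, 60001),
                                  width = 5000),
                  strand = c("+", "-", "+", "+"))
  mcols(reps)$name <- c("LINE1", "LINE1", "SINE", NA)
  # LINE1 planted at antisense fraction 0.8; SINE at 0.5
  mk <- function(s0, n_anti, n_sense, strand_of_element) {
    anti <- if (strand_of_element == "+") "-" else "+"
    sense <- if (strand_of_element == "+") "+" else "-"
    reads_at(rep(s0 + 2500, n_anti + n_sense),
             c(rep(anti, n_anti), rep(sense, n_sense)))
  }
  sets <- list(mk(1000, 80, 20, "+"), mk(20000, 80, 20, "-"),
               mk(40000, 50, 50, "+"), mk(60000, 5, 5, "+"))
  out <- repeat_family_asymmetry(sets, reps)
  fam <- out$families
  expect_equal(fam$median_oriented[fam$family == "LINE1"], 0.8)
  expect_equal(fam$median_oriented[fam$family == "SINE"], 0.5)
  expect_equal(fam$median_coefficient[fam$family == "LINE1"], 0.6)
  # unlabeled element grouped under "other"; below min reads excluded
  expect_true("other" %in% fam$family)
  expect_equal(fam$n[fam$family == "other"], 0L)
})

test_that("CH content asymmetry matches hand-counted examples", {
  ch <- ch_asymmetry(c("CACACACA", "CATG", "AAAA"))
  expect_equal(ch$ch_plus, c(4, 1, 0))
  expect_equal(ch$ch_minus, c(0, 1, 0))
  expect_equal(ch$coefficient, c(1, 0, NA_real_))
  # N positions are never counted
  expect_equal(ch_asymmetry("CNCA")$ch_plus, 1)
  expect_equal(ch_asymmetry("")$coefficient, NA_real_)
})

test_that("CH reverse-complement duality holds on random sequences", {
  set.seed(44)
  for (i in 1:50) {
    s <- paste(sample(c("A", "C", "G", "T", "N"), 300, TRUE,
                      prob = c(0.24, 0.24, 0.24, 0.24, 0.04)),
               collapse = "")
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(s)))
    a <- ch_asymmetry(s); b <- ch_asymmetry(rc)
    expect_equal(a$ch_plus, b$ch_minus)
    expect_equal(a$ch_minus, b$ch_plus)
  }
})

test_that("region CH asymmetry reports template-style ratios", {
  genome <- Biostrings::DNAStringSet(c(chr1 = "CACACACAGGGGTTTT"))
  g <- GRanges("chr1", IRanges(1, 8), strand = "+")
  out <- ch_region_asymmetry(genome, g)
  expect_equal(out$ch_plus, 4)
  # + gene: template is the minus strand
  expect_equal(out$template_ratio, 0)
  gm <- GRanges("chr1", IRanges(1, 8), strand = "-")
  expect_equal(ch_region_asymmetry(genome, gm)$template_ratio, 1)
})

test_that("concordance separates planted domain scales", {
  # alternating 10-kb domains with fractions 0.3 / 0.7
  set.seed(54)
  lay <- toy_layout(c(chr1 = 1e6))
  n_dom <- 100
  frac <- rep(c(0.3, 0.7), length.out = n_dom)
  mids <- c(); strands <- c()
  for (d in seq_len(n_dom)) {
    k <- 600
    m <- (d - 1) * 10000 + floor(runif(k) * 10000)
    s <- ifelse(runif(k) < frac[d], "+", "-")
    mids <- c(mids, m); strands <- c(strands, s)
  }
  rs <- reads_at(mids, strands)
  cc <- concordance_curve(rs, lay, sizes = c(1000, 100000), n = 1500,
                          seed = 5)
  expect_gt(cc$adjacent_frac[1], 0.8)
  expect_lt(abs(cc$random_frac[1] - 0.5), 0.06)
  expect_lt(abs(cc$adjacent_frac[2] - 0.5), 0.12)
  # fully symmetric data: adjacent ~ random ~ 0.5
  rs0 <- reads_at(floor(runif(40000) * 999000),
                  sample(c("+", "-"), 40000, TRUE))
  cc0 <- concordance_curve(rs0, lay, sizes = 2000, n = 1500, seed = 6)
  expect_lt(abs(cc0$adjacent_frac - 0.5), 0.07)
  expect_lt(abs(cc0$random_frac - 0.5), 0.07)
})

test_that("asymmetry correlations behave on shared and disjoint records", {
  set.seed(64)
  a <- runif(50); b <- a + rnorm(50, sd = 1e-6); c <- runif(50)
  m <- asymmetry_correlations(list(a = a, b = b, c = c))
  expect_equal(m["a", "b"], 1, tolerance = 1e-6)
  expect_lt(abs(m["a", "c"]), 0.35)
  short <- c(0.1, NA, NA, rep(NA, 47))
  expect_warning(m2 <- asymmetry_correlations(list(a = a, s = short)),
                 "fewer than 3")
  expect_true(is.na(m2["a", "s"]))
  expect_error(asymmetry_correlations(list(a = a, b = b[1:10])),
               "parallel")
})
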