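# Strand-asymmetry statistics: the asymmetry coefficient, multi-scale
# random-window sampling, concordance curves for asymmetric-region size
# estimation, gene template/coding ratios, repeat-family asymmetry and
# CH sequence-content asymmetry.

#' Asymmetry coefficient of stranded counts
#'
#' |plus - minus| / (plus + minus); regions with fewer than `min_reads`
#' total reads are excluded (NA), which also covers the 0/0 case.
#'
#' @param plus,minus non-negative counts (vectorized).
#' @param min_reads exclusion threshold on the total (default 20).
#' @return numeric vector in \[0, 1\], NA where excluded.
#' @export
asymmetry_coefficient <- function(plus, minus, min_reads = 20) {
  stopifnot(all(plus >= 0), all(minus >= 0))
  total <- plus + minus
  ifelse(total >= min_reads & total > 0, abs(plus - minus) / total, NA_real_)
}

#' Sample random fixed-size windows across the genome
#'
#' Windows are placed uniformly among all valid positions (chromosome
#' chosen proportional to its number of valid start positions), entirely
#' within bounds and avoiding an optional exclusion mask.
#'
#' @param layout `GenomeLayout`.
#' @param size window size in bp (must fit on some chromosome).
#' @param n number of windows (default 10000); sampling is with
#'   replacement across positions.
#' @param exclude optional `GRanges` exclusion mask (rejection sampling).
#' @param seed optional integer; if given, the RNG is seeded for
#'   reproducibility.
#' @return `GRanges` of `n` windows.
#' @export
sample_windows <- function(layout, size, n = 10000, exclude = NULL,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cs <- layout$chrom_sizes
  valid <- pmax(cs - size + 1, 0)
  if (all(valid == 0)) stop("window size exceeds every chromosome")
  draw <- function(k) {
    chr <- sample(names(cs), k, replace = TRUE, prob = valid)
    s0 <- floor(runif(k) * valid[chr])
    GRanges(chr, IRanges(s0 + 1, s0 + size),
            seqinfo = layout_seqinfo(layout))
  }
  gr <- draw(n)
  if (!is.null(exclude) && length(exclude)) {
    for (i in seq_len(50L)) {
      bad <- overlapsAny(gr, exclude, ignore.strand = TRUE)
      if (!any(bad)) break
      gr[bad] <- draw(sum(bad))
    }
    if (any(overlapsAny(gr, exclude, ignore.strand = TRUE)))
      stop("could not sample windows avoiding the exclusion mask")
  }
  gr
}

#' Asymmetry-coefficient distribution by window size
#'
#' @param read_sets list of `StrandedReadSet` pooled for counting.
#' @param layout `GenomeLayout`.
#' @param sizes window sizes in bp (the published ladder runs 100 bp -
#'   5 Mb; sizes are clipped to the longest chromosome).
#' @param n windows per size (default 10000).
#' @param min_reads exclusion threshold (default 20).
#' @param seed optional reproducibility seed.
#' @param exclude optional exclusion mask.
#' @return list: `summary` data.frame (size, n_pass, median, q25, q75) and
#'   `coefficients` (list of per-size coefficient vectors).
#' @export
asymmetry_by_size <- function(read_sets, layout, sizes, n = 10000,
                              min_reads = 20, seed = NULL, exclude = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sizes <- sizes[sizes <= max(layout$chrom_sizes)]
  coefs <- list()
  rows <- lapply(sizes, function(sz) {
    win <- sample_windows(layout, sz, n, exclude = exclude)
    cnt <- count_reads_in_regions(read_sets, win)
    co <- asymmetry_coefficient(cnt$plus, cnt$minus, min_reads)
    co <- co[!is.na(co)]
    coefs[[as.character(sz)]] <<- co
    data.frame(size = sz, n_pass = length(co),
               median = if (length(co)) median(co) else NA_real_,
               q25 = if (length(co)) quantile(co, 0.25, names = FALSE)
                     else NA_real_,
               q75 = if (length(co)) quantile(co, 0.75, names = FALSE)
                     else NA_real_)
  })
  list(summary = do.call(rbind, rows), coefficients = coefs)
}

majority_strand <- function(plus, minus, min_reads) {
  # +1 / -1 majority; NA for ties or filtered totals
  tot <- plus + minus
  out <- ifelse(tot >= min_reads & plus != minus, sign(plus - minus),
                NA_real_)
  out
}

#' Adjacent-window strand concordance by window size
#'
#' For each randomly sampled window the majority strand is compared with
#' that of the immediately downstream window of the same size (pairs with
#' ties, filtered totals or an out-of-bounds neighbor are skipped), and,
#' as a control, with an independently sampled random window. Adjacent
#' concordance above the random control indicates asymmetric regions
#' larger than the window size.
#'
#' @inheritParams asymmetry_by_size
#' @return data.frame: size, n_adjacent, adjacent_frac, n_random,
#'   random_frac.
#' @export
concordance_curve <- function(read_sets, layout, sizes, n = 10000,
                              min_reads = 20, seed = NULL, exclude = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sizes <- sizes[sizes <= max(layout$chrom_sizes)]
  index <- midpoint_index(read_sets)
  count_gr <- function(gr) {
    chr <- as.character(seqnames(gr))
    s0 <- start(gr) - 1
    e0 <- end(gr)
    plus <- integer(length(gr)); minus <- integer(length(gr))
    for (c in unique(chr)) {
      sel <- chr == c
      plus[sel] <- count_index_region(index, c, s0[sel], e0[sel], "+")
      minus[sel] <- count_index_region(index, c, s0[sel], e0[sel], "-")
    }
    list(plus = plus, minus = minus)
  }
  rows <- lapply(sizes, function(sz) {
    win <- sample_windows(layout, sz, n, exclude = exclude)
    nb_end <- end(win) + sz
    in_bounds <- nb_end <= layout$chrom_sizes[as.character(seqnames(win))]
    nb <- shift(win[in_bounds], sz)
    rnd <- sample_windows(layout, sz, n, exclude = exclude)
    cw <- count_gr(win); cn <- count_gr(nb); cr <- count_gr(rnd)
    mw <- majority_strand(cw$plus, cw$minus, min_reads)
    mn <- majority_strand(cn$plus, cn$minus, min_reads)
    mr <- majority_strand(cr$plus, cr$minus, min_reads)
    adj_ok <- !is.na(mw[in_bounds]) & !is.na(mn)
    rnd_ok <- !is.na(mw) & !is.na(mr)
    data.frame(
      size = sz,
      n_adjacent = sum(adj_ok),
      adjacent_frac = if (any(adj_ok))
        mean(mw[in_bounds][adj_ok] == mn[adj_ok]) else NA_real_,
      n_random = sum(rnd_ok),
      random_frac = if (any(rnd_ok)) mean(mw[rnd_ok] == mr[rnd_ok])
                    else NA_real_)
  })
  do.call(rbind, rows)
}

#' Template-strand modification ratio of gene bodies
#'
#' The template (non-coding) strand is the strand opposite the annotated
#' gene strand. Ratio = template reads / total reads over the gene body;
#' genes below `min_reads` total are excluded (NA).
#'
#' @param read_sets list of `StrandedReadSet`.
#' @param genes stranded gene `GRanges`.
#' @param min_reads exclusion threshold (default 20).
#' @return data.frame: gene_id, plus, minus, total, template_ratio,
#'   pass_filter.
#' @export
gene_template_ratio <- function(read_sets, genes, min_reads = 20) {
  cnt <- count_reads_in_regions(read_sets, genes)
  gs <- as.character(strand(genes))
  if (any(!gs %in% c("+", "-"))) stop("genes must be stranded")
  template <- ifelse(gs == "+", cnt$minus, cnt$plus)
  ratio <- ifelse(cnt$total >= min_reads & cnt$total > 0,
                  template / cnt$total, NA_real_)
  data.frame(gene_id = if (!is.null(mcols(genes)$gene_id))
               mcols(genes)$gene_id else as.character(seq_along(genes)),
             plus = cnt$plus, minus = cnt$minus, total = cnt$total,
             template_ratio = ratio,
             pass_filter = !is.na(ratio),
             stringsAsFactors = FALSE)
}

#' Template-ratio distributions per expression stratum
#'
#' @param ratios output of [gene_template_ratio()].
#' @param strata character vector of stratum labels parallel to `ratios`
#'   (e.g. from [stratify_expression()]: "silent", "1".."10", "excluded").
#' @return data.frame: stratum, n, median, q25, q75.
#' @export
asymmetry_by_expression <- function(ratios, strata) {
  stopifnot(nrow(ratios) == length(strata))
  keep <- ratios$pass_filter & !is.na(strata) & strata != "excluded"
  r <- ratios$template_ratio[keep]
  s <- strata[keep]
  levs <- unique(c("silent", sort(unique(s[s != "silent"]))))
  levs <- levs[levs %in% s]
  rows <- lapply(levs, function(l) {
    v <- r[s == l]
    data.frame(stratum = l, n = length(v), median = median(v),
               q25 = quantile(v, 0.25, names = FALSE),
               q75 = quantile(v, 0.75, names = FALSE))
  })
  do.call(rbind, rows)
}

#' Per-family repeat-element strand asymmetry
#'
#' Elements are oriented by their annotated strand: the oriented
#' (template-style) ratio is antisense-of-element reads over total, so a
#' family can show a directional bias; the unsigned coefficient is also
#' reported. Elements below `min_reads` are excluded; missing family
#' labels group under "other".
#'
#' @param read_sets list of `StrandedReadSet`.
#' @param repeats stranded `GRanges` with family in the `name` column.
#' @param min_reads exclusion threshold (default 20).
#' @return list: `elements` (per-element table) and `families`
#'   (per-family n, median oriented ratio, median coefficient).
#' @export
repeat_family_asymmetry <- function(read_sets, repeats, min_reads = 20) {
  cnt <- count_reads_in_regions(read_sets, repeats)
  fam <- mcols(repeats)$name
  if (is.null(fam)) fam <- rep(NA_character_, length(repeats))
  fam[is.na(fam) | !nzchar(fam)] <- "other"
  rstrand <- as.character(strand(repeats))
  anti <- ifelse(rstrand == "+", cnt$minus, cnt$plus)
  pass <- cnt$total >= min_reads
  oriented <- ifelse(pass, anti / cnt$total, NA_real_)
  coef <- asymmetry_coefficient(cnt$plus, cnt$minus, min_reads)
  elements <- data.frame(family = fam, strand = rstrand,
                         plus = cnt$plus, minus = cnt$minus,
                         total = cnt$total, oriented_ratio = oriented,
                         coefficient = coef, pass_filter = pass,
                         stringsAsFactors = FALSE)
  fams <- sort(unique(fam))
  families <- do.call(rbind, lapply(fams, function(f) {
    sel <- fam == f & pass
    data.frame(family = f, n = sum(sel),
               median_oriented = if (any(sel)) median(oriented[sel])
                                 else NA_real_,
               median_coefficient = if (any(sel)) median(coef[sel])
                                    else NA_real_)
  }))
  list(elements = elements, families = families)
}

# ---------------------------------------------------------------------------
# CH-content asymmetry (sequence-level)
# ---------------------------------------------------------------------------

ch_counts_one <- function(dna) {
  # CH+ = C followed by A/C/T; CH- = G preceded by A/G/T.
  # dinucleotideFrequency ignores pairs containing N, which implements
  # the "N bases never counted" rule.
  f <- dinucleotideFrequency(dna)
  c(plus = unname(f[["CA"]] + f[["CC"]] + f[["CT"]]),
    minus = unname(f[["AG"]] + f[["GG"]] + f[["TG"]]))
}

#' CH-content strand counts and asymmetry coefficient of a sequence
#'
#' CH+ counts cytosines whose 3' neighbor is not G (CH dinucleotides on
#' the plus strand); CH- counts the reverse-complement context (XG with X
#' not C), i.e. CH dinucleotides on the minus strand. The coefficient is
#' |CH+ - CH-| / (CH+ + CH-), NA when the denominator is 0. Positions
#' adjacent to N are never counted.
#'
#' @param seqs a `DNAStringSet`, `DNAString`, or character vector.
#' @return data.frame: ch_plus, ch_minus, coefficient.
#' @export
ch_asymmetry <- function(seqs) {
  if (is.character(seqs)) seqs <- DNAStringSet(seqs)
  if (is(seqs, "DNAString")) seqs <- DNAStringSet(seqs)
  m <- t(vapply(seq_along(seqs), function(i) ch_counts_one(seqs[[i]]),
                c(plus = 0, minus = 0)))
  tot <- m[, "plus"] + m[, "minus"]
  data.frame(ch_plus = m[, "plus"], ch_minus = m[, "minus"],
             coefficient = ifelse(tot > 0,
                                  abs(m[, "plus"] - m[, "minus"]) / tot,
                                  NA_real_))
}

#' CH asymmetry of genomic regions
#'
#' Extracts region sequences and computes CH strand counts; for stranded
#' regions (genes) a template-style ratio (CH on the template strand over
#' total) is reported as well.
#'
#' @param genome `DNAStringSet` (names = chromosomes).
#' @param regions `GRanges`.
#' @return data.frame per region: ch_plus, ch_minus, coefficient,
#'   template_ratio (NA for unstranded regions).
#' @export
ch_region_asymmetry <- function(genome, regions) {
  seqs <- DNAStringSet(lapply(seq_along(regions), function(i) {
    subseq(genome[[as.character(seqnames(regions))[i]]],
           start(regions)[i], end(regions)[i])
  }))
  out <- ch_asymmetry(seqs)
  st <- as.character(strand(regions))
  tot <- out$ch_plus + out$ch_minus
  tmpl <- ifelse(st == "+", out$ch_minus,
                 ifelse(st == "-", out$ch_plus, NA_real_))
  out$template_ratio <- ifelse(tot > 0, tmpl / tot, NA_real_)
  out
}

#' Spearman correlation matrix across asymmetry record sets
#'
#' Correlates per-region ratios between assays, cell types, replicates or
#' against CH ratios, over regions passing filters in both members of
#' each pair. Pairs with fewer than 3 shared regions are set to NA with a
#' warning.
#'
#' @param records named list of numeric vectors (parallel over the same
#'   regions; NA = excluded).
#' @return symmetric matrix of Spearman correlations.
#' @export
asymmetry_correlations <- function(records) {
  stopifnot(is.list(records), length(records) >= 2L)
  n <- length(records)
  len <- unique(lengths(records))
  if (length(len) != 1L) stop("record sets must be parallel (same length)")
  m <- matrix(NA_real_, n, n, dimnames = list(names(records),
                                              names(records)))
  diag(m) <- 1
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- !is.na(records[[i]]) & !is.na(records[[j]])
    if (sum(ok) < 3L) {
      warning("fewer than 3 shared regions for pair ",
              names(records)[i], " / ", names(records)[j])
      next
    }
    m[i, j] <- m[j, i] <- cor(records[[i]][ok], records[[j]][ok],
                              method = "spearman")
  }
  m
}
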