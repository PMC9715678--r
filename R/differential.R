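# Differential modification calling from pooled stranded counts.
#
# The published analysis used MEDIPS (windows) and DESeq2 (TSS/gene bodies);
# this package deliberately replaces both with a single pooled exact
# conditional binomial test so that every differential call is reproducible
# from first principles and checkable against brute-force enumeration.
# Published window counts are therefore not expected to be reproduced
# numerically; the downstream logic (clustering, feature overlap, gene
# integration) is the point.

#' Pool counts over replicates and strands for a two-group comparison
#'
#' @param counts a `WindowCounts`.
#' @param groupA,groupB character vectors of sample ids; disjoint,
#'   non-empty, same assay.
#' @return list with vectors `c1`, `c2` (per-window pooled counts) and
#'   scalars `N1`, `N2` (pooled library sizes).
#' @export
pool_counts <- function(counts, groupA, groupB) {
  stopifnot(inherits(counts, "WindowCounts"))
  if (length(groupA) == 0L || length(groupB) == 0L)
    stop("both groups must be non-empty")
  if (length(intersect(groupA, groupB)))
    stop("sample(s) present in both groups: ",
         paste(intersect(groupA, groupB), collapse = ", "))
  st <- counts$samples
  miss <- setdiff(c(groupA, groupB), st$sample_id)
  if (length(miss)) stop("unknown sample(s): ", paste(miss, collapse = ", "))
  if (length(unique(st$assay[st$sample_id %in% c(groupA, groupB)])) != 1L)
    stop("groups mix assays")
  ia <- match(groupA, st$sample_id)
  ib <- match(groupB, st$sample_id)
  sum_group <- function(ii) {
    m <- counts$counts[, ii, , drop = FALSE]
    as.integer(rowSums(m))
  }
  list(c1 = sum_group(ia), c2 = sum_group(ib),
       N1 = sum(st$library_size[ia]), N2 = sum(st$library_size[ib]))
}

#' Exact conditional binomial test for pooled two-group counts
#'
#' Conditional on the total n = c1 + c2, c1 ~ Binomial(n, N1/(N1+N2)) under
#' the null of equal modification rates. The two-sided p-value is the
#' minimum-likelihood sum: all outcomes no more likely than the observed one
#' (within a 1e-7 relative tolerance) are accumulated. n = 0 is defined as
#' p = 1 (untestable).
#'
#' @param c1,c2 non-negative counts (vectorized).
#' @param N1,N2 positive pooled library sizes.
#' @return numeric vector of two-sided p-values in (0, 1].
#' @export
exact_binomial_test <- function(c1, c2, N1, N2) {
  stopifnot(all(c1 >= 0), all(c2 >= 0), N1 > 0, N2 > 0)
  p0 <- N1 / (N1 + N2)
  n <- c1 + c2
  vapply(seq_along(n), function(i) {
    if (n[i] == 0L) return(1)
    d <- dbinom(0:n[i], n[i], p0)
    min(1, sum(d[d <= d[c1[i] + 1L] * (1 + 1e-7)]))
  }, numeric(1))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param pvalues numeric vector in \[0, 1\] (NA allowed; NAs are carried
#'   through and do not count toward the family size).
#' @return adjusted p-values, capped at 1.
#' @export
bh_adjust <- function(pvalues) {
  p <- pvalues
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  m <- sum(ok)
  if (m == 0L) return(p)
  adj <- rep(NA_real_, length(p))
  o <- order(p[ok], decreasing = TRUE)
  ro <- order(o)
  pv <- p[ok][o]
  adj[ok] <- pmin(1, cummin(pv * m / (m - seq_along(pv) + 1L)))[ro]
  adj
}

#' Differential calls for a set of counting units
#'
#' The same engine serves tiled windows, TSS regions and gene bodies.
#' Units with pooled total below `min_total`, and partial trailing windows,
#' are left untested (NA p-values, excluded from the BH family). The fold
#' change uses a 0.5 pseudocount on both counts (display only; never in
#' the test). Direction is reported only for significant units.
#'
#' @param units `GRanges` of the tested units (windows need a `partial`
#'   column; others are all testable).
#' @param c1,c2 pooled counts from [pool_counts()] or
#'   [count_reads_in_regions()].
#' @param N1,N2 pooled library sizes.
#' @param min_total minimum pooled count to test (default 10).
#' @param alpha BH-adjusted significance cutoff (default 0.05).
#' @param unit_ids optional unit identifiers.
#' @return `data.frame` (one row per unit): counts, `log2fc`, `pvalue`,
#'   `padj`, `tested`, `significant`, `direction` ("A-up", "B-up", "none").
#' @export
differential_units <- function(units, c1, c2, N1, N2, min_total = 10,
                               alpha = 0.05, unit_ids = NULL) {
  stopifnot(length(c1) == length(units), length(c2) == length(units))
  if (min_total < 1) stop("min_total must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  partial <- mcols(units)$partial
  if (is.null(partial)) partial <- rep(FALSE, length(units))
  tested <- (c1 + c2) >= min_total & !partial
  pvalue <- rep(NA_real_, length(units))
  pvalue[tested] <- exact_binomial_test(c1[tested], c2[tested], N1, N2)
  padj <- bh_adjust(pvalue)
  log2fc <- log2(((c1 + 0.5) / N1) / ((c2 + 0.5) / N2))
  significant <- !is.na(padj) & padj < alpha
  direction <- rep("none", length(units))
  direction[significant & log2fc > 0] <- "A-up"
  direction[significant & log2fc < 0] <- "B-up"
  ids <- if (!is.null(unit_ids)) unit_ids
         else if (!is.null(mcols(units)$window_id)) mcols(units)$window_id
         else if (!is.null(mcols(units)$gene_id)) mcols(units)$gene_id
         else paste0(as.character(seqnames(units)), ":", start(units) - 1L,
                     "-", end(units))
  data.frame(unit_id = ids,
             chrom = as.character(seqnames(units)),
             start = start(units) - 1L,  # 0-based in reports
             end = end(units),
             c1 = c1, c2 = c2, N1 = N1, N2 = N2,
             log2fc = log2fc, pvalue = pvalue, padj = padj,
             tested = tested, significant = significant,
             direction = direction,
             stringsAsFactors = FALSE)
}

#' Window-level differential analysis between two cell types
#'
#' Convenience wrapper: pools replicates per cell type and runs
#' [differential_units()] on a tiling.
#'
#' @param counts `WindowCounts` for one assay, both cell types.
#' @param cell_a,cell_b cell-type labels (group A and B).
#' @inheritParams differential_units
#' @return see [differential_units()].
#' @export
differential_windows <- function(counts, cell_a, cell_b, min_total = 10,
                                 alpha = 0.05) {
  st <- counts$samples
  ga <- st$sample_id[st$cell_type == cell_a]
  gb <- st$sample_id[st$cell_type == cell_b]
  pc <- pool_counts(counts, ga, gb)
  differential_units(counts$windows, pc$c1, pc$c2, pc$N1, pc$N2,
                     min_total = min_total, alpha = alpha)
}

#' Region-level differential analysis (TSS or gene bodies)
#'
#' @param read_sets list of `StrandedReadSet` covering both groups.
#' @param regions `GRanges` units (e.g. TSS +/- 2 kb or gene bodies).
#' @param cell_a,cell_b cell-type labels.
#' @inheritParams differential_units
#' @export
differential_regions <- function(read_sets, regions, cell_a, cell_b,
                                 min_total = 10, alpha = 0.05) {
  ct <- vapply(read_sets, `[[`, "", "cell_type")
  a_sets <- read_sets[ct == cell_a]
  b_sets <- read_sets[ct == cell_b]
  if (!length(a_sets) || !length(b_sets)) stop("empty group")
  ca <- count_reads_in_regions(a_sets, regions)
  cb <- count_reads_in_regions(b_sets, regions)
  N1 <- sum(vapply(a_sets, function(x) x$library_size, 1))
  N2 <- sum(vapply(b_sets, function(x) x$library_size, 1))
  differential_units(regions, ca$total, cb$total, N1, N2,
                     min_total = min_total, alpha = alpha)
}
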