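# TFBS enrichment in significant windows by interval-shuffling permutation.

#' Count significant windows overlapping a TFBS set
#'
#' A window counts once if it overlaps at least one site by >= 1 bp,
#' regardless of site multiplicity (the statistic is window-based, so it
#' is bounded by the number of significant windows and invariant to site
#' duplication).
#'
#' @param sig_windows `GRanges` of significant windows.
#' @param sites `GRanges` of binding sites.
#' @return integer count.
#' @export
overlap_count <- function(sig_windows, sites) {
  sum(overlapsAny(sig_windows, sites, ignore.strand = TRUE))
}

#' Shuffle intervals uniformly across the genome
#'
#' Each interval is independently relocated, preserving its length, to a
#' uniform position among all placements where it fits entirely
#' (chromosome chosen proportional to its valid placements), avoiding an
#' optional exclusion mask by rejection.
#'
#' @param sites `GRanges` to shuffle.
#' @param layout `GenomeLayout`.
#' @param exclude optional `GRanges` mask.
#' @param seed optional reproducibility seed.
#' @return shuffled `GRanges` (metadata preserved).
#' @export
shuffle_intervals <- function(sites, layout, exclude = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cs <- layout$chrom_sizes
  w <- width(sites)
  if (any(w > max(cs)))
    stop("interval longer than every chromosome")
  place <- function(wv) {
    chr <- character(length(wv)); s0 <- numeric(length(wv))
    for (uw in unique(wv)) {
      sel <- wv == uw
      valid <- pmax(cs - uw + 1, 0)
      chr[sel] <- sample(names(cs), sum(sel), replace = TRUE, prob = valid)
      s0[sel] <- floor(runif(sum(sel)) * valid[chr[sel]])
    }
    GRanges(chr, IRanges(s0 + 1, s0 + wv),
            seqinfo = layout_seqinfo(layout))
  }
  gr <- place(w)
  if (!is.null(exclude) && length(exclude)) {
    for (i in seq_len(100L)) {
      bad <- overlapsAny(gr, exclude, ignore.strand = TRUE)
      if (!any(bad)) break
      gr[bad] <- place(w[bad])
    }
    if (any(overlapsAny(gr, exclude, ignore.strand = TRUE)))
      stop("could not shuffle intervals off the exclusion mask ",
           "(mask too dense for some interval)")
  }
  mcols(gr) <- mcols(sites)
  gr
}

#' Permutation z-scores for TFBS overlap with significant windows
#'
#' Per TF: the observed window overlap, the null mean and SD over
#' `n_shuffles` genome-wide shuffles of that TF's sites, the z-score and
#' the fraction of significant windows hit.
#'
#' @param sig_windows `GRanges` of significant windows.
#' @param tfbs_sets named list of `GRanges` (one per TF), or a single
#'   `GRanges` with a `name` column to split on.
#' @param layout `GenomeLayout`.
#' @param n_shuffles number of shuffles (>= 2, default 100).
#' @param seed optional reproducibility seed.
#' @param exclude optional exclusion mask.
#' @return data.frame ranked by z: tf, n_sites, observed, null_mean,
#'   null_sd, z (NA if null_sd = 0), pct_windows.
#' @export
tfbs_zscore <- function(sig_windows, tfbs_sets, layout, n_shuffles = 100,
                        seed = NULL, exclude = NULL) {
  if (n_shuffles < 2) stop("n_shuffles must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  if (is(tfbs_sets, "GRanges")) {
    nm <- mcols(tfbs_sets)$name
    if (is.null(nm)) stop("TFBS GRanges needs a name column")
    gr <- tfbs_sets
    tfbs_sets <- lapply(split(seq_along(gr), nm), function(ii) gr[ii])
  }
  if (is.null(names(tfbs_sets))) stop("tfbs_sets must be named")
  nw <- length(sig_windows)
  rows <- lapply(names(tfbs_sets), function(tf) {
    sites <- tfbs_sets[[tf]]
    obs <- overlap_count(sig_windows, sites)
    # all shuffles at once: uniform placements, grouped per shuffle
    wv <- rep(width(sites), n_shuffles)
    shuf_id <- rep(seq_len(n_shuffles), each = length(sites))
    cs <- layout$chrom_sizes
    chr <- character(length(wv)); s0 <- numeric(length(wv))
    for (uw in unique(width(sites))) {
      sel <- wv == uw
      valid <- pmax(cs - uw + 1, 0)
      chr[sel] <- sample(names(cs), sum(sel), replace = TRUE, prob = valid)
      s0[sel] <- floor(runif(sum(sel)) * valid[chr[sel]])
    }
    all_gr <- GRanges(chr, IRanges(s0 + 1, s0 + wv))
    if (!is.null(exclude) && length(exclude)) {
      for (i in seq_len(100L)) {
        bad <- which(overlapsAny(all_gr, exclude, ignore.strand = TRUE))
        if (!length(bad)) break
        repl <- shuffle_intervals(all_gr[bad], layout, exclude = NULL)
        all_gr[bad] <- repl
      }
      if (any(overlapsAny(all_gr, exclude, ignore.strand = TRUE)))
        stop("could not shuffle off the exclusion mask")
    }
    ov <- findOverlaps(all_gr, sig_windows, ignore.strand = TRUE)
    hits <- unique(data.table(shuf = shuf_id[queryHits(ov)],
                              win = subjectHits(ov)))
    null_counts <- tabulate(hits$shuf, nbins = n_shuffles)
    null_mean <- mean(null_counts)
    null_sd <- sd(null_counts)
    data.frame(tf = tf, n_sites = length(sites), observed = obs,
               null_mean = null_mean, null_sd = null_sd,
               z = if (null_sd > 0) (obs - null_mean) / null_sd
                   else NA_real_,
               pct_windows = if (nw > 0) 100 * obs / nw else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-ifelse(is.na(out$z), -Inf, out$z), out$tf), , drop = FALSE]
}
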