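# Differentially modified region construction from significant 1-kb windows.
#
# Two-stage rule: (1) seed groups of same-direction significant windows
# less than `gap_bp` apart; (2) greedy bidirectional extension absorbing
# the nearest same-direction significant window (with its seed) while the
# density of significant windows over the merged span stays strictly above
# `density_threshold`. Clusters need at least `min_sig` significant member
# windows; singletons stay ungrouped.

cluster_index <- function(res, window_size) {
  # kb-grid index of each significant window (0-based start / window_size)
  res$start %/% window_size
}

#' Seed groups of nearby same-direction significant windows
#'
#' Consecutive significant windows of the same direction on the same
#' chromosome are joined when the gap between them (end of one to start of
#' the next) is strictly less than `gap_bp`. Opposite-direction windows are
#' never joined.
#'
#' @param sig_windows `data.frame` of significant rows from
#'   [differential_units()] (columns chrom, start, end, direction).
#' @param gap_bp maximum gap (default 5000, exclusive).
#' @param window_size tiling window size in bp (default 1000).
#' @return list of `data.frame` groups, each sorted by position.
#' @export
seed_clusters <- function(sig_windows, gap_bp = 5000, window_size = 1000) {
  if (nrow(sig_windows) == 0L) return(list())
  sw <- sig_windows[order(sig_windows$chrom, sig_windows$start), ,
                    drop = FALSE]
  out <- list()
  for (key in unique(paste(sw$chrom, sw$direction))) {
    sub <- sw[paste(sw$chrom, sw$direction) == key, , drop = FALSE]
    gap <- sub$start[-1L] - sub$end[-nrow(sub)]
    brk <- cumsum(c(0L, as.integer(gap >= gap_bp)))
    out <- c(out, split(sub, brk))
  }
  names(out) <- NULL
  # deterministic order: by chrom then start of first member
  ord <- order(vapply(out, function(g) g$chrom[1L], ""),
               vapply(out, function(g) g$start[1L], 1))
  out[ord]
}

# Greedy extension engine operating per chromosome x direction on the
# window grid. `pos` are sorted kb-grid indices of significant windows,
# `seed_id` the seed each belongs to. Returns list of [lo, hi] grid spans.
extend_on_grid <- function(pos, seed_id, density_threshold) {
  n <- length(pos)
  absorbed <- logical(max(seed_id))
  spans <- list()
  for (sid in sort(unique(seed_id))) {
    if (absorbed[sid]) next
    members <- pos[seed_id == sid]
    lo <- min(members); hi <- max(members)
    open_left <- TRUE; open_right <- TRUE
    repeat {
      left_cand <- pos[pos < lo]
      right_cand <- pos[pos > hi]
      dl <- if (open_left && length(left_cand)) lo - max(left_cand) else Inf
      dr <- if (open_right && length(right_cand)) min(right_cand) - hi
            else Inf
      if (!is.finite(dl) && !is.finite(dr)) break
      go_left <- dl <= dr  # left first on distance ties
      cand <- if (go_left) max(left_cand) else min(right_cand)
      cand_seed <- seed_id[match(cand, pos)]
      cand_members <- pos[seed_id == cand_seed]
      new_lo <- min(lo, cand_members); new_hi <- max(hi, cand_members)
      n_sig <- sum(pos >= new_lo & pos <= new_hi)
      density <- n_sig / (new_hi - new_lo + 1)
      if (density > density_threshold) {
        lo <- new_lo; hi <- new_hi
        # absorb every seed fully inside the merged span
        inside <- unique(seed_id[pos >= lo & pos <= hi])
        absorbed[setdiff(inside, sid)] <- TRUE
      } else if (go_left) open_left <- FALSE else open_right <- FALSE
    }
    spans[[length(spans) + 1L]] <- c(lo, hi)
  }
  spans
}

#' Extend seeds into final differentially modified clusters
#'
#' @param sig_windows significant window `data.frame` (as for
#'   [seed_clusters()]).
#' @param gap_bp seeding gap (default 5000).
#' @param density_threshold minimum (strict) density of significant windows
#'   over the cluster span (default 1/8). The denominator is the number of
#'   tiling windows spanned.
#' @param min_sig minimum significant windows per emitted cluster
#'   (default 2).
#' @param window_size tiling window size in bp (default 1000).
#' @return `data.frame` of clusters: chrom, start (0-based), end, direction,
#'   n_sig, n_total, density, span_bp, member window ids
#'   (comma-separated).
#' @export
build_clusters <- function(sig_windows, gap_bp = 5000,
                           density_threshold = 1 / 8, min_sig = 2,
                           window_size = 1000) {
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), direction = character(0),
                      n_sig = integer(0), n_total = integer(0),
                      density = numeric(0), span_bp = numeric(0),
                      members = character(0), stringsAsFactors = FALSE)
  if (nrow(sig_windows) == 0L) return(empty)
  sw <- sig_windows[order(sig_windows$chrom, sig_windows$start), ,
                    drop = FALSE]
  rows <- list()
  for (chrom in unique(sw$chrom)) {
    for (dir in unique(sw$direction[sw$chrom == chrom])) {
      sub <- sw[sw$chrom == chrom & sw$direction == dir, , drop = FALSE]
      pos <- cluster_index(sub, window_size)
      # seed ids on the grid (gap rule)
      gap <- sub$start[-1L] - sub$end[-nrow(sub)]
      seed_id <- cumsum(c(1L, as.integer(gap >= gap_bp)))
      spans <- extend_on_grid(pos, seed_id, density_threshold)
      for (sp in spans) {
        sel <- pos >= sp[1L] & pos <= sp[2L]
        n_sig <- sum(sel)
        if (n_sig < min_sig) next
        n_total <- sp[2L] - sp[1L] + 1
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = chrom,
          start = sp[1L] * window_size,
          end = (sp[2L] + 1) * window_size,
          direction = dir,
          n_sig = n_sig,
          n_total = as.integer(n_total),
          density = n_sig / n_total,
          span_bp = (n_total) * window_size,
          members = paste(sub$unit_id[sel], collapse = ","),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Clusters as GRanges
#' @param clusters output of [build_clusters()].
#' @return `GRanges` with direction/density metadata.
#' @export
clusters_granges <- function(clusters) {
  if (nrow(clusters) == 0L) return(GRanges())
  GRanges(clusters$chrom, IRanges(clusters$start + 1L, clusters$end),
          direction = clusters$direction, n_sig = clusters$n_sig,
          density = clusters$density)
}

#' Summarize clusters: spans, gene overlap, large-cluster flags,
#' cross-assay concordance and grouped fraction
#'
#' @param clusters `data.frame` from [build_clusters()].
#' @param sig_windows the significant windows the clusters were built from.
#' @param genes optional gene `GRanges`.
#' @param other_clusters optional cluster table from the other assay.
#' @param other_sig_windows optional significant windows of the other assay.
#' @param large_span_bp span above which a cluster is flagged large
#'   (default 1e5).
#' @return list with `table` (per-cluster summary), `n_large`,
#'   `fraction_grouped` (share of significant windows inside a cluster).
#' @export
summarize_clusters <- function(clusters, sig_windows, genes = NULL,
                               other_clusters = NULL,
                               other_sig_windows = NULL,
                               large_span_bp = 1e5) {
  gr <- clusters_granges(clusters)
  tab <- clusters
  tab$large <- clusters$span_bp > large_span_bp
  if (!is.null(genes) && length(gr)) {
    ov <- findOverlaps(gr, genes, ignore.strand = TRUE)
    gl <- vapply(seq_along(gr), function(i) {
      ids <- mcols(genes)$gene_id[subjectHits(ov)[queryHits(ov) == i]]
      paste(ids, collapse = ",")
    }, "")
    tab$genes <- gl
  }
  if (!is.null(other_clusters) && length(gr)) {
    ogr <- clusters_granges(other_clusters)
    tab$overlaps_other_cluster <- overlapsAny(gr, ogr, ignore.strand = TRUE)
  }
  if (!is.null(other_sig_windows) && length(gr) &&
      nrow(other_sig_windows)) {
    osw <- GRanges(other_sig_windows$chrom,
                   IRanges(other_sig_windows$start + 1L,
                           other_sig_windows$end))
    tab$overlaps_other_windows <- overlapsAny(gr, osw, ignore.strand = TRUE)
  }
  grouped <- if (nrow(sig_windows) == 0L) NA_real_ else {
    sg <- GRanges(sig_windows$chrom,
                  IRanges(sig_windows$start + 1L, sig_windows$end))
    mean(overlapsAny(sg, gr, ignore.strand = TRUE))
  }
  list(table = tab, n_large = sum(tab$large), fraction_grouped = grouped)
}
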