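# ChIP/input enrichment statistics: normalized enrichment per repeat
# cluster and a log2(ChIP/input) track over fixed genomic windows, plus a
# simple run-based caller for enriched segments.

#' Normalized ChIP/input enrichment per repeat cluster
#'
#' Enrichment of a cluster is the ratio of its ChIP read proportion to its
#' input read proportion, with a pseudocount added to both hit counts:
#' `((chip_hits + p) / chip_total) / ((input_hits + p) / input_total)`.
#'
#' @param counts data frame with columns `cluster`, `chip_hits`,
#'   `input_hits` and optionally `genome_proportion`.
#' @param chip_total,input_total library sizes (> 0, >= per-cluster hits).
#' @param pseudocount added to each hit count (default 1).
#' @return `counts` with an `enrichment` column, sorted by enrichment
#'   descending.
#' @export
cluster_enrichment <- function(counts, chip_total, input_total,
                               pseudocount = 1) {
  if (chip_total <= 0 || input_total <= 0) {
    stop("library totals must be > 0", call. = FALSE)
  }
  if (any(counts$chip_hits > chip_total) || any(counts$input_hits > input_total)) {
    stop("per-cluster hits exceed library totals", call. = FALSE)
  }
  counts$enrichment <-
    ((counts$chip_hits + pseudocount) / chip_total) /
    ((counts$input_hits + pseudocount) / input_total)
  counts <- counts[order(-counts$enrichment), , drop = FALSE]
  rownames(counts) <- NULL
  counts
}

#' Windowed log2(ChIP/input) signal track
#'
#' Per-window value is
#' `log2(((chip_w + p) / chip_total) / ((input_w + p) / input_total))`,
#' the depth-normalized log2 ratio over fixed genomic windows.
#'
#' @param chip_counts,input_counts per-window read counts on the same
#'   window grid.
#' @param chip_total,input_total library sizes; default to the respective
#'   count sums.
#' @param pseudocount added per window before forming proportions
#'   (default 1).
#' @param chrom chromosome label for the track.
#' @param window_size window width in bp (default 1000).
#' @return A `window_track` list (chrom, window_size, values).
#' @export
window_log2_track <- function(chip_counts, input_counts,
                              chip_total = sum(chip_counts),
                              input_total = sum(input_counts),
                              pseudocount = 1, chrom = "chr",
                              window_size = 1000) {
  if (length(chip_counts) != length(input_counts)) {
    stop("window grids differ: ", length(chip_counts), " vs ",
         length(input_counts), " windows", call. = FALSE)
  }
  if (chip_total <= 0 || input_total <= 0) {
    stop("library totals must be > 0", call. = FALSE)
  }
  values <- log2(((chip_counts + pseudocount) / chip_total) /
                   ((input_counts + pseudocount) / input_total))
  structure(list(chrom = chrom, window_size = window_size, values = values),
            class = "window_track")
}

#' @export
print.window_track <- function(x, ...) {
  cat("window_track on ", x$chrom, ": ", length(x$values), " windows of ",
      x$window_size, " bp\n", sep = "")
  invisible(x)
}

#' Call enriched segments from a window track
#'
#' Maximal runs of windows at or above `threshold` are reported as
#' segments; runs separated by at most `merge_gap` sub-threshold windows
#' are merged, and merged runs spanning fewer than `min_len` windows are
#' dropped.
#'
#' @param track a `window_track`.
#' @param threshold minimum log2 ratio for an enriched window (default 1).
#' @param merge_gap maximum sub-threshold gap (windows) bridged when
#'   merging (default 1).
#' @param min_len minimum segment length in windows (default 2).
#' @return `genomic_intervals` of enriched segments in bp (0-based
#'   half-open), with an attribute `windows`: a data frame of first/last
#'   window indices (1-based).
#' @export
call_enriched_segments <- function(track, threshold = 1, merge_gap = 1,
                                   min_len = 2) {
  above <- track$values >= threshold
  n <- length(above)
  empty <- genomic_intervals(character(), integer(), integer())
  attr(empty, "windows") <- data.frame(first = integer(), last = integer())
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  segs <- data.frame(first = starts[r$values], last = ends[r$values])
  # merge across short sub-threshold gaps
  if (nrow(segs) > 1L) {
    merged <- segs[1L, , drop = FALSE]
    for (i in 2:nrow(segs)) {
      gap <- segs$first[i] - merged$last[nrow(merged)] - 1L
      if (gap <= merge_gap) {
        merged$last[nrow(merged)] <- segs$last[i]
      } else {
        merged <- rbind(merged, segs[i, ])
      }
    }
    segs <- merged
  }
  segs <- segs[segs$last - segs$first + 1L >= min_len, , drop = FALSE]
  if (nrow(segs) == 0L) return(empty)
  out <- genomic_intervals(track$chrom,
                           (segs$first - 1L) * track$window_size,
                           segs$last * track$window_size,
                           name = sprintf("segment_%d", seq_len(nrow(segs))))
  rownames(segs) <- NULL
  attr(out, "windows") <- segs
  out
}
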