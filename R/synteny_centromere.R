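# Synteny block chaining, rearrangement calling, and cross-genome
# projection of centromere intervals.
#
# Blocks are built by greedy left-to-right chaining of ortholog links over
# per-genome gene ranks: a link extends the open chain iff it keeps the same
# chromosome pair, steps in the chain's genome-B direction, and leaves a
# rank gap of at most `max_gap_genes` skipped links on both genomes.
# Rearrangements are then called against the dominant orientation (for
# inversions) and the dominant partner chromosome (for translocations) of
# each chromosome (pair).

# per-chromosome rank of each link, by position, on one genome
link_ranks <- function(links, side) {
  chrom <- links[[paste0("chrom_", side)]]
  start <- links[[paste0("start_", side)]]
  rank <- integer(nrow(links))
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    rank[i] <- rank(start[i], ties.method = "first")
  }
  rank
}

#' Chain ortholog links into synteny blocks
#'
#' @param links ortholog link data frame sorted by genome-A position
#'   ([build_links()]).
#' @param max_gap_genes maximum number of skipped links tolerated between
#'   consecutive members of a chain, on either genome (default 10).
#' @param min_block_links minimum chain length reported as a block; shorter
#'   chains become unchained leftovers (default 5).
#' @return A `synteny_blocks` object: list with `blocks` (one row per block:
#'   block_id, chrom_a, chrom_b, orientation, n_links and both spans,
#'   1-based inclusive), `membership` (per-link block id, NA for leftovers)
#'   and the input `links` augmented with `rank_a`/`rank_b`.
#' @export
chain_blocks <- function(links, max_gap_genes = 10, min_block_links = 5) {
  if (nrow(links) &&
      any(order(links$chrom_a, links$start_a) != seq_len(nrow(links)))) {
    stop("links must be sorted by genome-A position", call. = FALSE)
  }
  links$rank_a <- link_ranks(links, "a")
  links$rank_b <- link_ranks(links, "b")
  n <- nrow(links)
  membership <- rep(NA_integer_, n)
  # chain within each chromosome pair: links of other pairs interleaved on
  # either genome are invisible to a pair's chains, which makes the result
  # invariant under swapping the two genomes
  pair_key <- paste(links$chrom_a, links$chrom_b, sep = "\r")
  chains <- list()
  for (pk in unique(pair_key)) {
    idx <- which(pair_key == pk)
    cur <- idx[1L]       # indices of the open chain
    cur_dir <- 0L        # 0 until the second link fixes the direction
    pair_chains <- list()
    flush <- function(chain, dir) {
      pair_chains[[length(pair_chains) + 1L]] <<- list(idx = chain, dir = dir)
    }
    for (i in idx[-1L]) {
      last <- cur[length(cur)]
      da <- links$rank_a[i] - links$rank_a[last]
      db <- links$rank_b[i] - links$rank_b[last]
      step_dir <- sign(db)
      gap_ok <- (da - 1L) <= max_gap_genes && (abs(db) - 1L) <= max_gap_genes
      dir_ok <- step_dir != 0L && (cur_dir == 0L || step_dir == cur_dir)
      if (gap_ok && dir_ok) {
        if (cur_dir == 0L) cur_dir <- step_dir
        cur <- c(cur, i)
      } else {
        flush(cur, cur_dir)
        cur <- i
        cur_dir <- 0L
      }
    }
    flush(cur, cur_dir)
    chains <- c(chains, refine_chain_boundaries(pair_chains, links,
                                                max_gap_genes))
  }
  keep <- vapply(chains, function(ch) length(ch$idx) >= min_block_links,
                 logical(1))
  blocks <- chains[keep]
  rows <- lapply(seq_along(blocks), function(k) {
    idx <- blocks[[k]]$idx
    dir <- blocks[[k]]$dir
    if (dir == 0L) dir <- 1L  # single-link chain (only if min_block_links == 1)
    membership[idx] <<- k
    data.frame(
      block_id = k,
      chrom_a = links$chrom_a[idx[1L]], chrom_b = links$chrom_b[idx[1L]],
      orientation = as.integer(dir), n_links = length(idx),
      start_a = min(links$start_a[idx]), end_a = max(links$end_a[idx]),
      start_b = min(links$start_b[idx]), end_b = max(links$end_b[idx]),
      rank_a_min = min(links$rank_a[idx]), rank_a_max = max(links$rank_a[idx]),
      rank_b_min = min(links$rank_b[idx]), rank_b_max = max(links$rank_b[idx]),
      stringsAsFactors = FALSE)
  })
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(block_id = integer(), chrom_a = character(), chrom_b = character(),
               orientation = integer(), n_links = integer(),
               start_a = integer(), end_a = integer(),
               start_b = integer(), end_b = integer(),
               rank_a_min = integer(), rank_a_max = integer(),
               rank_b_min = integer(), rank_b_max = integer(),
               stringsAsFactors = FALSE)
  structure(list(blocks = tab, membership = membership, links = links,
                 link_idx = lapply(blocks, `[[`, "idx")),
            class = "synteny_blocks")
}

# Greedy chaining fixes the genome-B direction of a chain at its second
# link, so the first link of an orientation-reversed run gets absorbed by
# the preceding chain (the direction-setting step is a large rank jump).
# Reassign each boundary link to the neighbouring chain when it fits there
# with a strictly smaller genome-B rank step.
refine_chain_boundaries <- function(chains, links, max_gap_genes) {
  if (length(chains) < 2L) return(chains)
  repeat {
    moved <- FALSE
    for (i in seq_len(length(chains) - 1L)) {
      ca <- chains[[i]]
      cb <- chains[[i + 1L]]
      if (length(ca$idx) < 2L) next
      x <- ca$idx[length(ca$idx)]
      y <- cb$idx[1L]
      if (links$chrom_a[x] != links$chrom_a[y] ||
          links$chrom_b[x] != links$chrom_b[y]) next
      da <- links$rank_a[y] - links$rank_a[x]
      db <- links$rank_b[y] - links$rank_b[x]
      if (db == 0L || (da - 1L) > max_gap_genes ||
          (abs(db) - 1L) > max_gap_genes) next
      dir_b <- if (length(cb$idx) >= 2L) cb$dir else 0L
      if (dir_b != 0L && sign(db) != dir_b) next
      prev <- ca$idx[length(ca$idx) - 1L]
      prev_step <- abs(links$rank_b[x] - links$rank_b[prev])
      if (abs(db) >= prev_step) next
      ca$idx <- ca$idx[-length(ca$idx)]
      if (length(ca$idx) < 2L) ca$dir <- 0L
      cb$idx <- c(x, cb$idx)
      if (cb$dir == 0L) cb$dir <- sign(db)
      chains[[i]] <- ca
      chains[[i + 1L]] <- cb
      moved <- TRUE
    }
    if (!moved) break
  }
  chains[lengths(lapply(chains, `[[`, "idx")) > 0L]
}

#' @export
print.synteny_blocks <- function(x, ...) {
  cat("synteny_blocks: ", nrow(x$blocks), " block(s) over ",
      sum(!is.na(x$membership)), "/", length(x$membership), " links\n", sep = "")
  invisible(x)
}

# majority vote weighted by link count; deterministic tie-break
dominant <- function(keys, weights, tie_levels) {
  tot <- tapply(weights, keys, sum)
  top <- names(tot)[tot == max(tot)]
  if (length(top) > 1L) {
    warning("tie in dominant context; resolved deterministically", call. = FALSE)
    top <- tie_levels(top)
  }
  top[1L]
}

#' Call inversions from synteny blocks
#'
#' For each chromosome pair the dominant orientation is the one carrying the
#' majority of block-assigned links (ties resolve to +1 with a warning); each
#' block on the minority orientation with at least `min_event_links` links is
#' one inversion call.  A chromosome pair that is entirely one orientation
#' yields no calls: it is its own dominant context.
#'
#' @param sb a `synteny_blocks` object.
#' @param min_event_links minimum block size for a call (default 5).
#' @return Data frame of calls (kind, block_id, chromosomes, spans,
#'   reference_context = dominant orientation).
#' @export
call_inversions <- function(sb, min_event_links = 5) {
  b <- sb$blocks
  out <- list()
  for (pair in unique(paste(b$chrom_a, b$chrom_b, sep = "\r"))) {
    i <- which(paste(b$chrom_a, b$chrom_b, sep = "\r") == pair)
    dom <- dominant(as.character(b$orientation[i]), b$n_links[i],
                    function(top) if ("1" %in% top) "1" else sort(top))
    j <- i[b$orientation[i] != as.integer(dom) & b$n_links[i] >= min_event_links]
    if (length(j)) {
      out[[length(out) + 1L]] <- data.frame(
        kind = "inversion", block_id = b$block_id[j],
        chrom_a = b$chrom_a[j], chrom_b = b$chrom_b[j],
        start_a = b$start_a[j], end_a = b$end_a[j],
        start_b = b$start_b[j], end_b = b$end_b[j],
        n_links = b$n_links[j],
        reference_context = paste0("dominant_orientation=", dom),
        stringsAsFactors = FALSE)
    }
  }
  calls <- if (length(out)) do.call(rbind, out) else empty_calls()
  rownames(calls) <- NULL
  calls
}

empty_calls <- function() {
  data.frame(kind = character(), block_id = integer(),
             chrom_a = character(), chrom_b = character(),
             start_a = integer(), end_a = integer(),
             start_b = integer(), end_b = integer(), n_links = integer(),
             reference_context = character(), stringsAsFactors = FALSE)
}

#' Call inter-chromosomal translocations from synteny blocks
#'
#' Each genome-A chromosome's dominant partner is the genome-B chromosome
#' carrying most of its block-assigned links (and symmetrically for genome
#' B).  A block whose chromosome pair disagrees with either dominant
#' partnering, with at least `min_event_links` links, is a translocation;
#' calls on the same chromosome pair whose genome-A rank ranges lie within
#' `merge_gap_ranks` of each other are merged into one event.
#'
#' @param sb a `synteny_blocks` object.
#' @param min_event_links minimum block size for a call (default 5).
#' @param merge_gap_ranks merge adjacent calls separated by at most this
#'   many genome-A ranks (default 10).
#' @return Data frame of calls; `block_id` lists merged blocks separated by
#'   `,`.
#' @export
call_translocations <- function(sb, min_event_links = 5, merge_gap_ranks = 10) {
  b <- sb$blocks
  if (nrow(b) == 0L) return(empty_calls())
  dom_a <- vapply(unique(b$chrom_a), function(ca) {
    i <- which(b$chrom_a == ca)
    dominant(b$chrom_b[i], b$n_links[i], sort)
  }, character(1))
  dom_b <- vapply(unique(b$chrom_b), function(cb) {
    i <- which(b$chrom_b == cb)
    dominant(b$chrom_a[i], b$n_links[i], sort)
  }, character(1))
  off <- b$chrom_b != dom_a[b$chrom_a] | b$chrom_a != dom_b[b$chrom_b]
  cand <- b[off & b$n_links >= min_event_links, , drop = FALSE]
  if (nrow(cand) == 0L) return(empty_calls())
  cand <- cand[order(cand$chrom_a, cand$chrom_b, cand$rank_a_min), , drop = FALSE]
  merged <- list()
  cur <- cand[1L, , drop = FALSE]
  ids <- as.character(cur$block_id)
  flush <- function() {
    merged[[length(merged) + 1L]] <<- data.frame(
      kind = "translocation", block_id = NA_integer_,
      chrom_a = cur$chrom_a, chrom_b = cur$chrom_b,
      start_a = cur$start_a, end_a = cur$end_a,
      start_b = min(cur$start_b), end_b = max(cur$end_b),
      n_links = cur$n_links,
      reference_context = paste0("blocks=", paste(ids, collapse = ",")),
      stringsAsFactors = FALSE)
  }
  if (nrow(cand) > 1L) {
    for (i in 2:nrow(cand)) {
      row <- cand[i, , drop = FALSE]
      contiguous <- row$chrom_a == cur$chrom_a && row$chrom_b == cur$chrom_b &&
        (row$rank_a_min - cur$rank_a_max - 1L) <= merge_gap_ranks
      if (contiguous) {
        cur$end_a <- max(cur$end_a, row$end_a)
        cur$start_b <- min(cur$start_b, row$start_b)
        cur$end_b <- max(cur$end_b, row$end_b)
        cur$rank_a_max <- max(cur$rank_a_max, row$rank_a_max)
        cur$n_links <- cur$n_links + row$n_links
        ids <- c(ids, as.character(row$block_id))
      } else {
        flush()
        cur <- row
        ids <- as.character(row$block_id)
      }
    }
  }
  flush()
  calls <- do.call(rbind, merged)
  rownames(calls) <- NULL
  calls
}

#' Project an interval across genomes through flanking ortholog links
#'
#' The nearest link lying entirely left and the nearest lying entirely right
#' of the interval are its flanks.  When both exist and sit on the same
#' partner chromosome, the projection is the partner-genome interval between
#' the flanks' gene-proximal (inner) edges; otherwise the projection is
#' unresolved.
#'
#' @param interval one-row `genomic_intervals` data frame (0-based
#'   half-open) on genome `side`.
#' @param links ortholog link data frame.
#' @param side `"a"` or `"b"`: the genome the interval lives on.
#' @return List with `projected` (one-row `genomic_intervals` on the other
#'   genome, or `NULL`), `flank_left`, `flank_right` (link row indices or
#'   NA) and `reason` when unresolved.
#' @export
project_interval <- function(interval, links, side = c("b", "a")) {
  side <- match.arg(side)
  other <- if (side == "b") "a" else "b"
  chrom_x <- links[[paste0("chrom_", side)]]
  # gene coordinates are 1-based inclusive; compare in 0-based half-open
  start_x <- links[[paste0("start_", side)]] - 1L
  end_x <- links[[paste0("end_", side)]]
  on_chr <- which(chrom_x == interval$chrom)
  left <- on_chr[end_x[on_chr] <= interval$start]
  right <- on_chr[start_x[on_chr] >= interval$end]
  fl <- if (length(left)) left[which.max(end_x[left])] else NA_integer_
  fr <- if (length(right)) right[which.min(start_x[right])] else NA_integer_
  unresolved <- function(reason) {
    list(projected = NULL, flank_left = fl, flank_right = fr, reason = reason)
  }
  if (is.na(fl) || is.na(fr)) return(unresolved("missing flank"))
  chrom_o <- links[[paste0("chrom_", other)]]
  if (chrom_o[fl] != chrom_o[fr]) {
    return(unresolved("flanks on different partner chromosomes"))
  }
  pl <- c(links[[paste0("start_", other)]][fl] - 1L,
          links[[paste0("end_", other)]][fl])
  pr <- c(links[[paste0("start_", other)]][fr] - 1L,
          links[[paste0("end_", other)]][fr])
  if (pl[2L] <= pr[1L]) {
    proj <- c(pl[2L], pr[1L])
  } else if (pr[2L] <= pl[1L]) {
    proj <- c(pr[2L], pl[1L])
  } else {
    return(unresolved("flank partners overlap"))
  }
  if (proj[1L] >= proj[2L]) return(unresolved("empty projection"))
  list(projected = genomic_intervals(chrom_o[fl], proj[1L], proj[2L],
                                     name = interval$name),
       flank_left = fl, flank_right = fr, reason = NA_character_)
}

# reciprocal overlap fraction of the smaller interval; both 0-based half-open
overlap_frac_smaller <- function(s1, e1, s2, e2) {
  ov <- pmax(0L, pmin(e1, e2) - pmax(s1, s2))
  ov / pmin(e1 - s1, e2 - s2)
}

#' Classify centromere origins by cross-genome projection
#'
#' Each centromere unit on genome B is projected onto genome A through its
#' flanking ortholog links.  A unit is `corresponding` when the projection
#' overlaps a genome-A centromere unit (overlap at least `min_overlap_frac`
#' of the smaller interval); `de_novo_insertion` when the projection
#' resolves, overlaps no genome-A unit, and the flanking links belong to one
#' synteny block or to two blocks that continue each other (same chromosome
#' pair and orientation, adjacent rank ranges) — the unit splits an
#' otherwise contiguous syntenic block; `unresolved` otherwise.
#'
#' @param units_b `genomic_intervals` of centromere units on genome B.
#' @param units_a `genomic_intervals` of centromere units on genome A.
#' @param links ortholog link data frame.
#' @param sb `synteny_blocks` from [chain_blocks()] on the same links.
#' @param min_overlap_frac reciprocal-overlap threshold for
#'   `corresponding` (default 0.1).
#' @return Data frame with one row per genome-B unit: unit coordinates,
#'   projected coordinates (NA when unresolved), flank link indices and
#'   `klass`.
#' @export
classify_centromere_origin <- function(units_b, units_a, links, sb,
                                       min_overlap_frac = 0.1) {
  res <- vector("list", nrow(units_b))
  for (i in seq_len(nrow(units_b))) {
    unit <- units_b[i, , drop = FALSE]
    pr <- project_interval(unit, links, side = "b")
    klass <- "unresolved"
    pchrom <- NA_character_; pstart <- NA_integer_; pend <- NA_integer_
    if (!is.null(pr$projected)) {
      p <- pr$projected
      pchrom <- p$chrom; pstart <- p$start; pend <- p$end
      on_a <- units_a[units_a$chrom == p$chrom, , drop = FALSE]
      corresponding <- nrow(on_a) > 0 &&
        any(overlap_frac_smaller(p$start, p$end, on_a$start, on_a$end) >=
              min_overlap_frac)
      if (corresponding) {
        klass <- "corresponding"
      } else {
        bl <- sb$membership[pr$flank_left]
        br <- sb$membership[pr$flank_right]
        if (!is.na(bl) && !is.na(br)) {
          if (bl == br) {
            klass <- "de_novo_insertion"
          } else {
            b1 <- sb$blocks[sb$blocks$block_id == bl, ]
            b2 <- sb$blocks[sb$blocks$block_id == br, ]
            continuation <- b1$chrom_a == b2$chrom_a &&
              b1$chrom_b == b2$chrom_b &&
              b1$orientation == b2$orientation
            if (continuation) klass <- "de_novo_insertion"
          }
        }
      }
    }
    res[[i]] <- data.frame(
      chrom = unit$chrom, start = unit$start, end = unit$end,
      name = unit$name,
      projected_chrom = pchrom, projected_start = pstart,
      projected_end = pend,
      flank_left = pr$flank_left, flank_right = pr$flank_right,
      klass = klass, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(chrom = character(), start = integer(), end = integer(),
                      name = character(), projected_chrom = character(),
                      projected_start = integer(), projected_end = integer(),
                      flank_left = integer(), flank_right = integer(),
                      klass = character(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}
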