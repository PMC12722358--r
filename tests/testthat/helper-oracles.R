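# Independent brute-force oracles and small random-instance generators.
# Each oracle restates its operation's definition as directly as possible,
# on a different code path from the package implementation.

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

# All maximal dyads by exhaustive enumeration over (i, j, k) triples with a
# containment filter; i/j 1-based here, converted to 0-based on return.
brute_dyads <- function(seq, min_arm, max_loop, max_mismatch) {
  s <- strsplit(seq, "")[[1L]]
  n <- length(s)
  cand <- list()
  for (i in seq_len(n)) {
    for (k in min_arm:n) {
      e <- i + k - 1L
      if (e > n) break
      for (loop in 0:max_loop) {
        j <- e + loop + 1L
        if (j + k - 1L > n) break
        arm1 <- s[i:e]
        arm2 <- s[j:(j + k - 1L)]
        # arm2 must equal the reverse complement of arm1 up to mismatches
        mm <- sum(unname(COMPLEMENT[rev(arm1)]) != arm2 |
                    rev(arm1) == "N" | arm2 == "N")
        if (mm <= max_mismatch) {
          cand[[length(cand) + 1L]] <- c(i = i, e = e, j = j,
                                         j2 = j + k - 1L, k = k,
                                         loop = loop, mm = mm)
        }
      }
    }
  }
  if (!length(cand)) {
    return(data.frame(arm1_start = integer(), arm2_start = integer(),
                      arm_len = integer(), loop_len = integer(),
                      mismatches = integer()))
  }
  m <- do.call(rbind, cand)
  keep <- rep(TRUE, nrow(m))
  for (a in seq_len(nrow(m))) {
    inside <- m[, "i"] >= m[a, "i"] & m[, "e"] <= m[a, "e"] &
      m[, "j"] >= m[a, "j"] & m[, "j2"] <= m[a, "j2"]
    inside[a] <- FALSE
    keep[inside] <- FALSE
  }
  m <- m[keep, , drop = FALSE]
  out <- data.frame(arm1_start = m[, "i"] - 1L, arm2_start = m[, "j"] - 1L,
                    arm_len = m[, "k"], loop_len = m[, "loop"],
                    mismatches = m[, "mm"])
  out <- out[order(-out$arm_len, out$arm1_start, out$arm2_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Longest common substrings via the match-matrix diagonal-run method.
lcs_oracle <- function(a, b) {
  ca <- strsplit(a, "")[[1L]]
  cb <- strsplit(b, "")[[1L]]
  na <- length(ca)
  nb <- length(cb)
  best_len <- 0L
  motifs <- character(0)
  for (d in seq(-(na - 1L), nb - 1L)) {
    i <- max(1L, 1L - d)
    j <- i + d
    len <- min(na - i, nb - j) + 1L
    if (len < 1L) next
    eq <- ca[i:(i + len - 1L)] == cb[j:(j + len - 1L)]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    for (q in which(r$values)) {
      L <- r$lengths[q]
      if (L >= best_len && L > 0L) {
        start_i <- i + ends[q] - r$lengths[q]
        motif <- paste(ca[start_i:(start_i + L - 1L)], collapse = "")
        if (L > best_len) {
          best_len <- L
          motifs <- motif
        } else {
          motifs <- c(motifs, motif)
        }
      }
    }
  }
  list(length = best_len, motifs = sort(unique(motifs)))
}

# Exhaustive hairpin fold search: every (stem end, arm2 start) combination,
# perfect pairing only, scored by the declared weights.
brute_hairpin <- function(seq, min_stem = 3, min_loop = 3, gc_weight = 3,
                          at_weight = 2, loop_penalty = 0.5) {
  s <- strsplit(seq, "")[[1L]]
  n <- length(s)
  best <- NULL
  for (i in seq_len(n)) {       # arm1 start
    for (k in min_stem:n) {     # stem length
      e <- i + k - 1L
      if (e > n) break
      for (j in (e + min_loop + 1L):n) {   # arm2 start
        if (j + k - 1L > n) break
        arm1 <- s[i:e]
        arm2 <- s[j:(j + k - 1L)]
        if (any(unname(COMPLEMENT[rev(arm1)]) != arm2)) next
        gc <- sum(arm1 %in% c("G", "C"))
        score <- gc_weight * gc + at_weight * (k - gc) -
          loop_penalty * max(0, (j - e - 1L) - min_loop)
        cand <- list(stem_len = k, paired_gc = gc, paired_at = k - gc,
                     loop_len = j - e - 1L, score = score,
                     arm1_start = i - 1L, arm2_start = j - 1L)
        better <- is.null(best) || score > best$score ||
          (score == best$score && (k > best$stem_len ||
           (k == best$stem_len && cand$arm1_start < best$arm1_start)))
        if (better) best <- cand
      }
    }
  }
  best
}

# Exhaustive single-copy classification straight from the definition.
brute_single_copy <- function(edges_ab, edges_ba, mode = "reciprocal") {
  partners_of <- function(edges, g) unique(edges$gene_s[edges$gene_q == g])
  out <- list()
  for (a in unique(edges_ab$gene_q)) {
    pa <- partners_of(edges_ab, a)
    if (length(pa) != 1L) next
    b <- pa
    if (mode == "reciprocal") {
      pb <- partners_of(edges_ba, b)
      if (length(pb) == 1L && pb == a) {
        out[[length(out) + 1L]] <- c(a, b)
      }
    } else {
      out[[length(out) + 1L]] <- c(a, b)
    }
  }
  if (!length(out)) {
    return(data.frame(gene_a = character(), gene_b = character(),
                      stringsAsFactors = FALSE))
  }
  m <- do.call(rbind, out)
  df <- data.frame(gene_a = m[, 1L], gene_b = m[, 2L], stringsAsFactors = FALSE)
  if (mode == "one_way") {
    df <- df[!(df$gene_b %in% df$gene_b[duplicated(df$gene_b)]), , drop = FALSE]
  }
  df <- df[order(df$gene_a), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# Random bipartite hit instance in collapsed form (gene_q/gene_s columns);
# the two directions are drawn independently, as separate alignment runs
# would produce.
rand_hit_instance <- function(n_a, n_b, n_edges) {
  genes_a <- sprintf("A%02d", seq_len(n_a))
  genes_b <- sprintf("B%02d", seq_len(n_b))
  draw <- function(from, n_from, to, n_to) {
    unique(data.frame(gene_q = from[sample.int(n_from, n_edges, replace = TRUE)],
                      gene_s = to[sample.int(n_to, n_edges, replace = TRUE)],
                      stringsAsFactors = FALSE))
  }
  list(ab = draw(genes_a, n_a, genes_b, n_b),
       ba = draw(genes_b, n_b, genes_a, n_a))
}

# Manually constructed ortholog link table for chaining tests; ranks_b gives
# the genome-B gene order (1-based ranks), one link per genome-A rank.
mk_links <- function(ranks_b, chrom_a = "cA1", chrom_b = "cB1",
                     strand_b = NULL) {
  n <- length(ranks_b)
  if (is.null(strand_b)) strand_b <- rep("+", n)
  data.frame(
    gene_a = sprintf("a%03d", seq_len(n)),
    chrom_a = rep_len(chrom_a, n),
    start_a = seq_len(n) * 1000L, end_a = seq_len(n) * 1000L + 500L,
    strand_a = rep_len("+", n),
    gene_b = sprintf("b%03d", ranks_b),
    chrom_b = rep_len(chrom_b, n),
    start_b = ranks_b * 1000L, end_b = ranks_b * 1000L + 500L,
    strand_b = strand_b,
    identity = rep_len(99, n), bitscore = rep_len(500, n),
    orientation = ifelse(strand_b == "+", 1L, -1L),
    stringsAsFactors = FALSE)
}
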