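# Satellite monomer and array characterisation: dyad symmetries (inverted
# repeats with a short loop), a transparent stem-loop score as a proxy for
# hairpin-forming potential, shared motifs between monomers, greedy monomer
# tiling of arrays, and higher-order repeat (HOR) period detection.

DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

seq_chars <- function(seq) strsplit(toupper(seq), "", fixed = TRUE)[[1L]]

#' Find dyad symmetries (inverted repeats) in a DNA sequence
#'
#' A dyad is a pair of arms where the second arm equals the reverse
#' complement of the first up to `max_mismatch` mismatches, separated by a
#' loop of at most `max_loop` bases.  All maximal dyads are reported:
#' candidates whose arms are both contained within another reported dyad's
#' arms are suppressed.  `N` never pairs.
#'
#' @param seq DNA string over A/C/G/T/N.
#' @param min_arm minimum arm length in bp (default 4; must be >= 2).
#' @param max_loop maximum loop length in bp (default 12).
#' @param max_mismatch maximum mismatches between the arms (default 0).
#' @return Data frame (arm1_start, arm2_start, arm_len, loop_len,
#'   mismatches), positions 0-based, sorted by arm length descending then
#'   position.
#' @export
find_dyads <- function(seq, min_arm = 4, max_loop = 12, max_mismatch = 0) {
  if (min_arm < 2) stop("min_arm must be >= 2", call. = FALSE)
  s <- seq_chars(seq)
  n <- length(s)
  comp <- unname(DNA_COMPLEMENT[s])
  comp[is.na(comp)] <- "?"          # unknown letters never pair
  comp[s == "N"] <- "?"
  cand <- list()
  # e = 1-based index of the last base of arm1; a2 = first base of arm2
  for (e in seq_len(n)) {
    for (loop in 0:max_loop) {
      a2 <- e + loop + 1L
      if (a2 > n) break
      t_max <- min(e, n - a2 + 1L)
      if (t_max < min_arm) next
      t <- seq_len(t_max)
      mism <- cumsum(comp[e - t + 1L] != s[a2 + t - 1L])
      k <- max(which(mism <= max_mismatch), 0L)
      if (k >= min_arm) {
        cand[[length(cand) + 1L]] <- c(i1 = e - k + 1L, e = e, a2 = a2,
                                       j2 = a2 + k - 1L, k = k,
                                       loop = loop, mm = mism[k])
      }
    }
  }
  if (!length(cand)) return(empty_dyads())
  m <- do.call(rbind, cand)
  keep <- rep(TRUE, nrow(m))
  for (i in seq_len(nrow(m))) {
    contained <- m[, "i1"] >= m[i, "i1"] & m[, "e"] <= m[i, "e"] &
      m[, "a2"] >= m[i, "a2"] & m[, "j2"] <= m[i, "j2"]
    contained[i] <- FALSE
    keep[contained] <- FALSE
  }
  m <- m[keep, , drop = FALSE]
  out <- data.frame(arm1_start = m[, "i1"] - 1L, arm2_start = m[, "a2"] - 1L,
                    arm_len = m[, "k"], loop_len = m[, "loop"],
                    mismatches = m[, "mm"])
  out <- out[order(-out$arm_len, out$arm1_start, out$arm2_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_dyads <- function() {
  data.frame(arm1_start = integer(), arm2_start = integer(),
             arm_len = integer(), loop_len = integer(), mismatches = integer())
}

#' Score the best stem-loop fold of a DNA sequence
#'
#' A transparent proxy for hairpin-forming potential rather than a
#' thermodynamic fold: among all perfect-pairing stems with loop length at
#' least `min_loop`, the fold maximising
#' `gc_weight * paired_gc + at_weight * paired_at -
#'  loop_penalty * max(0, loop_len - min_loop)`
#' is reported.  Ties resolve to the longest stem, then the leftmost fold.
#'
#' @param seq DNA string.
#' @param min_stem minimum stem length in bp (default 3).
#' @param min_loop minimum loop length in bp (default 3).
#' @param gc_weight,at_weight,loop_penalty score weights (defaults 3, 2, 0.5).
#' @return A `hairpin_score` list (stem_len, paired_gc, paired_at, loop_len,
#'   score, arm1_start, arm2_start; positions 0-based), or `NULL` when the
#'   sequence is too short or admits no fold.
#' @export
hairpin_score <- function(seq, min_stem = 3, min_loop = 3,
                          gc_weight = 3, at_weight = 2, loop_penalty = 0.5) {
  s <- seq_chars(seq)
  n <- length(s)
  if (n < 2 * min_stem + min_loop) return(NULL)
  comp <- unname(DNA_COMPLEMENT[s])
  comp[is.na(comp) | s == "N"] <- "?"
  best <- NULL
  for (e in seq_len(n)) {
    if (e + min_loop + 1L > n) break
    for (a2 in (e + min_loop + 1L):n) {
      t_max <- min(e, n - a2 + 1L)
      if (t_max < min_stem) next
      t <- seq_len(t_max)
      ok <- comp[e - t + 1L] == s[a2 + t - 1L]
      k <- if (all(ok)) t_max else which.min(ok) - 1L
      if (k < min_stem) next
      paired <- s[e - seq_len(k) + 1L]
      gc <- sum(paired %in% c("G", "C"))
      at <- k - gc
      loop <- a2 - e - 1L
      score <- gc_weight * gc + at_weight * at -
        loop_penalty * max(0, loop - min_loop)
      cand <- list(stem_len = k, paired_gc = gc, paired_at = at,
                   loop_len = loop, score = score,
                   arm1_start = e - k, arm2_start = a2 - 1L)
      if (is.null(best) || score > best$score ||
          (score == best$score && (k > best$stem_len ||
           (k == best$stem_len && cand$arm1_start < best$arm1_start)))) {
        best <- cand
      }
    }
  }
  if (!is.null(best)) class(best) <- "hairpin_score"
  best
}

#' Longest substring(s) shared by two monomers
#'
#' @param monomer_a,monomer_b DNA strings (non-empty).
#' @param include_revcomp also search the reverse complement of
#'   `monomer_b` (default FALSE).
#' @param circular treat both monomers as circular by searching their
#'   doubled sequences, with match length capped at the shorter monomer
#'   length (default FALSE).
#' @return List with `length` (0 when nothing is shared) and `motifs`
#'   (character vector of all distinct longest shared substrings).
#' @export
shared_motif <- function(monomer_a, monomer_b, include_revcomp = FALSE,
                         circular = FALSE) {
  stopifnot(nchar(monomer_a) > 0, nchar(monomer_b) > 0)
  a <- toupper(monomer_a)
  bs <- toupper(monomer_b)
  if (include_revcomp) bs <- c(bs, revcomp(bs))
  na <- nchar(a)
  nb <- nchar(monomer_b)
  cap <- min(na, nb)
  subs <- function(x, n_starts, L) {
    unique(substring(x, seq_len(n_starts), seq_len(n_starts) + L - 1L))
  }
  a_search <- if (circular) paste0(a, a) else a
  b_search <- if (circular) vapply(bs, function(b) paste0(b, b), "") else bs
  for (L in seq(cap, 1L)) {
    sa <- subs(a_search, if (circular) na else na - L + 1L, L)
    sa <- sa[nchar(sa) == L]
    hits <- character(0)
    for (b in b_search) {
      n_starts <- if (circular) nb else nb - L + 1L
      if (n_starts < 1L) next
      sb <- subs(b, n_starts, L)
      hits <- c(hits, intersect(sa, sb[nchar(sb) == L]))
    }
    if (length(hits)) {
      return(list(length = L, motifs = sort(unique(hits))))
    }
  }
  list(length = 0L, motifs = character(0))
}

# percent identity from Levenshtein distance, normalised by the longer
# string; scalar-vs-vector uses one vectorised adist call, vector-vs-vector
# is elementwise with recycling
edit_identity <- function(a, b) {
  if (length(a) == 1L || length(b) == 1L) {
    d <- drop(utils::adist(a, b))
  } else {
    n <- max(length(a), length(b))
    a <- rep_len(a, n)
    b <- rep_len(b, n)
    d <- mapply(function(x, y) utils::adist(x, y), a, b)
  }
  100 * (1 - d / pmax(nchar(a), nchar(b)))
}

#' Decompose a satellite array into monomer copies
#'
#' Greedy left-to-right tiling against a consensus monomer: at each
#' position, candidate windows of the monomer length +/- 20% are compared
#' with the consensus and its reverse complement by edit distance; the best
#' orientation and window is accepted when its identity reaches
#' `min_identity`, otherwise the scan advances one base through unassigned
#' sequence.
#'
#' @param array_seq DNA string of the array.
#' @param consensus consensus monomer (>= 10 bp).
#' @param min_identity minimum percent identity for an accepted monomer
#'   (default 70, below the identity band of diverged monomer variants but
#'   above the ~60% edit identity of unrelated DNA).
#' @return An `array_profile` list: `tiling` data frame (start, end 0-based
#'   half-open, orientation F/R, identity), `monomer_count`,
#'   `orientation_runs` data frame (orientation, length),
#'   `mean_adjacent_identity`, `coverage` (assigned fraction of the array),
#'   `monomers` (accepted copies oriented to the forward consensus strand)
#'   and `hor_period` (filled by [detect_hor()] when >= 8 monomers).
#' @export
decompose_array <- function(array_seq, consensus, min_identity = 70) {
  if (nchar(consensus) < 10) stop("consensus must be >= 10 bp", call. = FALSE)
  array_seq <- toupper(array_seq)
  consensus <- toupper(consensus)
  m <- nchar(consensus)
  n <- nchar(array_seq)
  band <- max(1L, as.integer(round(0.2 * m)))
  lens <- seq(max(1L, m - band), m + band)
  rc <- revcomp(consensus)
  rows <- list()
  pos <- 1L
  while (pos + min(lens) - 1L <= n) {
    cl <- lens[pos + lens - 1L <= n]
    if (!length(cl)) break
    cands <- substring(array_seq, pos, pos + cl - 1L)
    idF <- edit_identity(consensus, cands)
    idR <- edit_identity(rc, cands)
    bestF <- which.max(idF + 1e-9 * (-abs(cl - m)))
    bestR <- which.max(idR + 1e-9 * (-abs(cl - m)))
    use_f <- idF[bestF] >= idR[bestR]     # ties prefer forward
    bi <- if (use_f) bestF else bestR
    bid <- if (use_f) idF[bestF] else idR[bestR]
    if (bid >= min_identity) {
      rows[[length(rows) + 1L]] <- data.frame(
        start = pos - 1L, end = pos - 1L + cl[bi],
        orientation = if (use_f) "F" else "R",
        identity = bid, stringsAsFactors = FALSE)
      pos <- pos + cl[bi]
    } else {
      pos <- pos + 1L
    }
  }
  tiling <- if (length(rows)) do.call(rbind, rows) else
    data.frame(start = integer(), end = integer(), orientation = character(),
               identity = numeric(), stringsAsFactors = FALSE)
  rownames(tiling) <- NULL
  monomers <- character(nrow(tiling))
  if (nrow(tiling)) {
    monomers <- substring(array_seq, tiling$start + 1L, tiling$end)
    flip <- tiling$orientation == "R"
    if (any(flip)) monomers[flip] <- revcomp(monomers[flip])
  }
  runs <- rle(tiling$orientation)
  mean_adj <- NA_real_
  if (nrow(tiling) >= 2L) {
    mean_adj <- mean(edit_identity(monomers[-length(monomers)], monomers[-1L]))
  }
  profile <- structure(list(
    tiling = tiling, monomer_count = nrow(tiling),
    orientation_runs = data.frame(orientation = runs$values,
                                  length = runs$lengths,
                                  stringsAsFactors = FALSE),
    mean_adjacent_identity = mean_adj,
    coverage = if (n > 0) sum(tiling$end - tiling$start) / n else NA_real_,
    monomers = monomers, hor_period = NA_integer_), class = "array_profile")
  if (profile$monomer_count >= 8L) {
    profile$hor_period <- detect_hor(monomers)
  }
  profile
}

#' @export
print.array_profile <- function(x, ...) {
  cat("array_profile: ", x$monomer_count, " monomers, coverage ",
      round(100 * x$coverage, 1), "%, mean adjacent identity ",
      round(x$mean_adjacent_identity, 1), "%, HOR period ",
      if (is.na(x$hor_period)) "none" else x$hor_period, "\n", sep = "")
  invisible(x)
}

#' Detect the higher-order repeat period of a monomer series
#'
#' Computes the mean pairwise identity between monomers at lag L for
#' L = 1..min(`max_lag`, n/2).  Each candidate period L >= 2 is scored by
#' the contrast between the mean identity at its multiples and at all other
#' lags; in a true period-p array this contrast is maximal at p (larger
#' multiples of p score lower because their complement still contains
#' high-identity lags).  The reported period is the best-scoring L whose
#' contrast reaches `margin` percentage points and whose multiple-lag mean
#' identity reaches `min_hor_identity`; period 1 is reported when no such L
#' exists but the lag-1 identity itself reaches `min_hor_identity`;
#' otherwise `NA` (no periodic structure).
#'
#' @param monomers character vector of monomer sequences in array order,
#'   all on the same strand (e.g. `array_profile$monomers`), or an
#'   `array_profile`.
#' @param max_lag largest lag examined (default 20).
#' @param margin required identity contrast between multiple and
#'   non-multiple lags, percentage points (default 2; lag means are
#'   averages over dozens of monomer pairs, so 2 points is far outside
#'   their sampling noise).
#' @param min_hor_identity minimum mean identity at the period lags
#'   (default 88), separating within-variant from between-variant
#'   identity bands up to ~6% per-copy divergence.
#' @param max_monomers monomers used beyond which the series is truncated,
#'   to bound cost on very long arrays (default 200).
#' @return Integer period (NA for none) with attribute `lag_identity`.
#' @export
detect_hor <- function(monomers, max_lag = 20, margin = 2,
                       min_hor_identity = 88, max_monomers = 200) {
  if (inherits(monomers, "array_profile")) monomers <- monomers$monomers
  n <- length(monomers)
  if (n < 8L) {
    out <- NA_integer_
    attr(out, "reason") <- "fewer than 8 monomers"
    return(out)
  }
  if (n > max_monomers) {
    monomers <- monomers[seq_len(max_monomers)]
    n <- max_monomers
  }
  lags <- seq_len(min(max_lag, n %/% 2L))
  d <- utils::adist(monomers)
  nc <- nchar(monomers)
  idm <- 100 * (1 - d / outer(nc, nc, pmax))
  lag_id <- vapply(lags, function(L) {
    i <- seq_len(n - L)
    mean(idm[cbind(i, i + L)])
  }, numeric(1))
  names(lag_id) <- lags
  period <- NA_integer_
  cand <- lags[lags >= 2L]
  if (length(cand)) {
    stats <- vapply(cand, function(L) {
      mult <- lag_id[lags %% L == 0L]
      rest <- lag_id[lags %% L != 0L]
      c(score = mean(mult) - mean(rest), mult_id = mean(mult))
    }, numeric(2))
    ok <- stats["score", ] >= margin & stats["mult_id", ] >= min_hor_identity
    if (any(ok)) {
      best <- which(ok)[which.max(stats["score", ok])]
      period <- as.integer(cand[best])
    }
  }
  if (is.na(period) && lag_id[1L] >= min_hor_identity) {
    period <- 1L
  }
  attr(period, "lag_identity") <- lag_id
  period
}
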