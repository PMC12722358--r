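# Conserved single-copy ortholog classification.
#
# The pipeline mirrors the standard reciprocal-single-hit recipe for
# cross-genome link building: (1) drop noisy alignments below an identity
# and alignment-length floor, (2) collapse multiple HSPs of a gene pair into
# one best hit, (3) keep genes whose similarity is to a single gene in the
# other genome, (4) attach genomic coordinates from the annotations.

#' Alignment noise-filter thresholds
#'
#' Alignments with identity below `min_identity` percent or aligned length
#' below `min_align_len` amino acids are treated as noise and removed;
#' equality passes.
#'
#' @param min_identity minimum percent identity retained (default 90).
#' @param min_align_len minimum alignment length in aa retained (default 150).
#' @return A `filter_thresholds` list.
#' @export
filter_thresholds <- function(min_identity = 90, min_align_len = 150) {
  stopifnot(min_identity >= 0, min_align_len >= 0)
  structure(list(min_identity = min_identity, min_align_len = min_align_len),
            class = "filter_thresholds")
}

#' Remove noisy alignment hits
#'
#' Retains exactly the hits with `pident >= min_identity` and
#' `length >= min_align_len`; input order is preserved and the operation is
#' idempotent.
#'
#' @param hits alignment hit data frame ([read_tabular_hits()]).
#' @param thresholds a [filter_thresholds()] object.
#' @return The filtered hit data frame.
#' @export
filter_noise <- function(hits, thresholds = filter_thresholds()) {
  keep <- hits$pident >= thresholds$min_identity &
    hits$length >= thresholds$min_align_len
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# map protein ids in hits to gene ids; strict = error on unknown proteins,
# lenient = drop them with one warning
resolve_genes <- function(ids, annot, side, on_unknown) {
  idx <- match(ids, annot$genes$protein_id)
  if (anyNA(idx)) {
    unknown <- unique(ids[is.na(idx)])
    if (on_unknown == "error") {
      stop("unknown ", side, " protein id(s): ",
           paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
    }
    warning(length(unknown), " unknown ", side,
            " protein id(s) dropped", call. = FALSE)
  }
  annot$genes$gene_id[idx]
}

#' Collapse alignment hits to one per gene pair
#'
#' Multiple HSPs between the same pair of genes represent one similarity
#' relationship; the best-scoring hit is kept (highest bitscore, ties by
#' higher identity then smaller subject id).  Query/subject protein ids are
#' resolved to gene ids through the annotations, and the retained rows gain
#' `gene_q`/`gene_s` columns.
#'
#' @param hits noise-filtered hit data frame; queries from `annot_q`,
#'   subjects from `annot_s`.
#' @param annot_q,annot_s `genome_annotation` objects for the query and
#'   subject genomes.
#' @param on_unknown `"error"` (strict, default) or `"drop"` (lenient) for
#'   hits naming proteins absent from the annotations.
#' @return Hit data frame with at most one row per (gene_q, gene_s) pair.
#' @export
collapse_hits_per_gene_pair <- function(hits, annot_q, annot_s,
                                        on_unknown = c("error", "drop")) {
  on_unknown <- match.arg(on_unknown)
  hits <- hits[hits$qseqid != hits$sseqid, , drop = FALSE]  # self-hits ignored
  if (nrow(hits) == 0L) {
    out <- hits
    out$gene_q <- character(0)
    out$gene_s <- character(0)
    return(out)
  }
  hits$gene_q <- resolve_genes(hits$qseqid, annot_q, "query", on_unknown)
  hits$gene_s <- resolve_genes(hits$sseqid, annot_s, "subject", on_unknown)
  hits <- hits[!is.na(hits$gene_q) & !is.na(hits$gene_s), , drop = FALSE]
  ord <- order(hits$gene_q, hits$gene_s,
               -hits$bitscore, -hits$pident, hits$sseqid)
  hits <- hits[ord, , drop = FALSE]
  keep <- !duplicated(hits[, c("gene_q", "gene_s")])
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify conserved single-copy gene pairs
#'
#' A gene qualifies when its similarity (after noise filtering and HSP
#' collapsing) is to a single gene in the other genome.  In `reciprocal`
#' mode (default) a pair (A, B) is emitted iff A's only hit is B and B's
#' only hit is A; `one_way` emits a pair for every query gene with exactly
#' one subject, using the A-to-B direction only.
#'
#' @param hits_ab collapsed hits with genome A as query (`gene_q`) and
#'   genome B as subject (`gene_s`).
#' @param hits_ba same with roles swapped (ignored in `one_way` mode).
#' @param mode `"reciprocal"` or `"one_way"`.
#' @return Data frame with columns `gene_a`, `gene_b`; no gene repeats on
#'   either side.
#' @export
classify_single_copy <- function(hits_ab, hits_ba = NULL,
                                 mode = c("reciprocal", "one_way")) {
  mode <- match.arg(mode)
  single_partner <- function(h) {
    if (nrow(h) == 0L) {
      return(stats::setNames(character(0), character(0)))
    }
    cnt <- table(h$gene_q)
    ok <- names(cnt)[cnt == 1L]
    sub <- h[h$gene_q %in% ok, , drop = FALSE]
    stats::setNames(sub$gene_s, sub$gene_q)
  }
  ab <- single_partner(hits_ab)
  if (mode == "one_way") {
    out <- data.frame(gene_a = names(ab), gene_b = unname(ab),
                      stringsAsFactors = FALSE)
    # one_way can still produce a geneB hit by several unique geneAs; keep
    # the link set single-copy on both sides by dropping contested geneBs
    out <- out[!(out$gene_b %in% out$gene_b[duplicated(out$gene_b)]), ,
               drop = FALSE]
  } else {
    if (is.null(hits_ba)) stop("reciprocal mode needs hits_ba", call. = FALSE)
    ba <- single_partner(hits_ba)
    keep <- names(ab)[!is.na(ba[unname(ab)]) & ba[unname(ab)] == names(ab)]
    out <- data.frame(gene_a = keep, gene_b = unname(ab[keep]),
                      stringsAsFactors = FALSE)
  }
  out <- out[order(out$gene_a), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build positioned ortholog links from classified pairs
#'
#' Attaches both genes' coordinates from the annotations and an orientation
#' equal to +1 when the genes lie on the same strand and -1 otherwise.
#' Identity and bitscore are carried over from the supporting A-to-B hit
#' when available.
#'
#' @param pairs data frame with `gene_a`, `gene_b` ([classify_single_copy()]).
#' @param annot_a,annot_b `genome_annotation` objects.
#' @param hits_ab optional collapsed hits used to annotate identity/bitscore.
#' @return Ortholog link data frame sorted by genome-A position, with
#'   columns gene/chrom/start/end/strand for both sides plus `identity`,
#'   `bitscore` and `orientation`.
#' @export
build_links <- function(pairs, annot_a, annot_b, hits_ab = NULL) {
  ia <- match(pairs$gene_a, annot_a$genes$gene_id)
  ib <- match(pairs$gene_b, annot_b$genes$gene_id)
  if (anyNA(ia)) {
    stop("unknown genome-A gene id: ", pairs$gene_a[which(is.na(ia))[1L]],
         call. = FALSE)
  }
  if (anyNA(ib)) {
    stop("unknown genome-B gene id: ", pairs$gene_b[which(is.na(ib))[1L]],
         call. = FALSE)
  }
  ga <- annot_a$genes[ia, , drop = FALSE]
  gb <- annot_b$genes[ib, , drop = FALSE]
  identity <- rep(NA_real_, nrow(pairs))
  bitscore <- rep(NA_real_, nrow(pairs))
  if (!is.null(hits_ab) && nrow(hits_ab)) {
    key <- paste(hits_ab$gene_q, hits_ab$gene_s, sep = "\r")
    m <- match(paste(pairs$gene_a, pairs$gene_b, sep = "\r"), key)
    identity <- hits_ab$pident[m]
    bitscore <- hits_ab$bitscore[m]
  }
  links <- data.frame(
    gene_a = pairs$gene_a, chrom_a = ga$chrom, start_a = ga$start,
    end_a = ga$end, strand_a = ga$strand,
    gene_b = pairs$gene_b, chrom_b = gb$chrom, start_b = gb$start,
    end_b = gb$end, strand_b = gb$strand,
    identity = identity, bitscore = bitscore,
    orientation = ifelse(ga$strand == gb$strand, 1L, -1L),
    stringsAsFactors = FALSE)
  links <- links[order(links$chrom_a, links$start_a), , drop = FALSE]
  rownames(links) <- NULL
  links
}

#' Classify ortholog links from raw hits in one call
#'
#' Convenience wrapper running noise filtering, HSP collapsing, single-copy
#' classification and link building.
#'
#' @param hits_ab,hits_ba raw hit tables for the two alignment directions.
#' @param annot_a,annot_b `genome_annotation` objects.
#' @param thresholds a [filter_thresholds()] object.
#' @param mode passed to [classify_single_copy()].
#' @return Ortholog link data frame (see [build_links()]).
#' @export
ortholog_links <- function(hits_ab, hits_ba, annot_a, annot_b,
                           thresholds = filter_thresholds(),
                           mode = "reciprocal") {
  ab <- collapse_hits_per_gene_pair(filter_noise(hits_ab, thresholds),
                                    annot_a, annot_b)
  ba <- collapse_hits_per_gene_pair(filter_noise(hits_ba, thresholds),
                                    annot_b, annot_a)
  pairs <- classify_single_copy(ab, ba, mode = mode)
  build_links(pairs, annot_a, annot_b, hits_ab = ab)
}
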