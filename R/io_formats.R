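# Coordinate conventions used throughout the package:
#   * gene models keep GFF3 1-based inclusive coordinates;
#   * every other interval (BED-derived centromere units, projections,
#     enriched segments, satellite tilings) is 0-based half-open.
# Helpers below convert between the two at module boundaries.

#' Convert 1-based inclusive coordinates to 0-based half-open
#'
#' @param start,end 1-based inclusive coordinates.
#' @return A list with elements `start` and `end` in 0-based half-open form.
#' @keywords internal
to_zero_based <- function(start, end) list(start = start - 1L, end = end)

#' Construct a validated genomic interval table
#'
#' Intervals are 0-based half-open, the package-internal convention for all
#' non-gene features (centromere units, projections, enriched segments).
#'
#' @param chrom character chromosome labels.
#' @param start,end integer 0-based half-open coordinates, `start < end`.
#' @param name optional feature names.
#' @param strand `"+"`, `"-"` or `"."`.
#' @return A `data.frame` with class `genomic_intervals`.
#' @export
genomic_intervals <- function(chrom, start, end, name = ".", strand = ".") {
  start <- as.integer(start)
  end <- as.integer(end)
  if (any(start >= end)) {
    bad <- which(start >= end)[1L]
    stop("invalid interval: start >= end (", chrom[bad], ":", start[bad],
         "-", end[bad], ")", call. = FALSE)
  }
  if (!all(strand %in% c("+", "-", "."))) {
    stop("strand must be one of '+', '-', '.'", call. = FALSE)
  }
  df <- data.frame(chrom = as.character(chrom), start = start, end = end,
                   name = rep_len(as.character(name), length(chrom)),
                   strand = rep_len(as.character(strand), length(chrom)),
                   stringsAsFactors = FALSE)
  class(df) <- c("genomic_intervals", "data.frame")
  df
}

#' Read gene models from a GFF3 file
#'
#' Parses gene/mRNA/CDS features and keeps one representative transcript per
#' gene: the one with the longest summed CDS, ties broken by the
#' lexicographically smallest transcript id.  Protein length is the summed
#' CDS length divided by three (stop codon not subtracted; synthetic
#' annotations written by this package encode exact coding spans).
#' Coordinates stay 1-based inclusive as in GFF3.
#'
#' @param path path to a GFF3 file.
#' @param genome_id label for the genome; defaults to the file base name.
#' @return A `genome_annotation` object: a list with `genome_id` and a
#'   `genes` data frame (gene_id, chrom, start, end, strand, protein_id,
#'   protein_len) sorted by (chrom, start).
#' @export
read_gff3_genes <- function(path, genome_id = NULL) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path, call. = FALSE)
  if (is.null(genome_id)) genome_id <- sub("\\.[^.]*$", "", basename(path))

  ## pre-scan for malformed rows so errors can name the offending line
  lines <- readLines(path, warn = FALSE)
  data_lines <- which(!grepl("^\\s*(#|$)", lines))
  nf <- lengths(strsplit(lines[data_lines], "\t", fixed = TRUE))
  if (any(nf != 9L)) {
    bad <- data_lines[which(nf != 9L)[1L]]
    stop("malformed GFF3 at line ", bad, ": expected 9 tab-separated columns, got ",
         nf[which(nf != 9L)[1L]], call. = FALSE)
  }
  gff <- as.data.frame(rtracklayer::readGFF(path))
  gff$type <- as.character(gff$type)

  known <- c("gene", "mRNA", "CDS")
  n_ignored <- sum(!gff$type %in% known)

  genes <- gff[gff$type == "gene", , drop = FALSE]
  mrnas <- gff[gff$type == "mRNA", , drop = FALSE]
  cds <- gff[gff$type == "CDS", , drop = FALSE]
  if (anyDuplicated(genes$ID)) {
    stop("duplicate gene ids in ", path, ": ",
         genes$ID[duplicated(genes$ID)][1L], call. = FALSE)
  }

  cds_parent <- vapply(cds$Parent, function(p) as.character(p)[1L], character(1))
  cds_len <- tapply(cds$end - cds$start + 1L, cds_parent, sum)
  mrna_parent <- vapply(mrnas$Parent, function(p) as.character(p)[1L], character(1))

  n_skipped <- 0L
  rows <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    gid <- genes$ID[i]
    tx <- mrnas$ID[mrna_parent == gid]
    tx <- tx[tx %in% names(cds_len)]
    if (length(tx) == 0L) {
      n_skipped <- n_skipped + 1L
      next
    }
    len <- cds_len[tx]
    best <- tx[order(-len, tx)][1L]
    rows[[i]] <- data.frame(
      gene_id = gid, chrom = as.character(genes$seqid[i]),
      start = as.integer(genes$start[i]), end = as.integer(genes$end[i]),
      strand = as.character(genes$strand[i]), protein_id = best,
      protein_len = as.integer(cds_len[[best]] %/% 3L),
      stringsAsFactors = FALSE)
  }
  if (n_skipped > 0L) {
    warning(n_skipped, " gene(s) without CDS skipped in ", path, call. = FALSE)
  }
  tab <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(tab)) {
    tab <- data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(), strand = character(),
                      protein_id = character(), protein_len = integer(),
                      stringsAsFactors = FALSE)
  }
  tab <- tab[order(tab$chrom, tab$start), , drop = FALSE]
  rownames(tab) <- NULL
  genome_annotation(genome_id, tab, n_ignored_features = n_ignored)
}

#' Construct a genome annotation
#'
#' @param genome_id genome label.
#' @param genes data frame of gene models (gene_id, chrom, start, end, strand,
#'   protein_id, protein_len), 1-based inclusive coordinates.
#' @param n_ignored_features count of unknown GFF3 feature rows skipped during
#'   parsing (bookkeeping only).
#' @return A `genome_annotation` object.
#' @export
genome_annotation <- function(genome_id, genes, n_ignored_features = 0L) {
  stopifnot(is.data.frame(genes))
  if (nrow(genes)) {
    if (anyDuplicated(genes$gene_id)) stop("gene ids must be unique", call. = FALSE)
    if (any(genes$start > genes$end)) stop("gene start > end", call. = FALSE)
    if (!all(genes$strand %in% c("+", "-"))) {
      stop("gene strand must be '+' or '-'", call. = FALSE)
    }
    genes <- genes[order(genes$chrom, genes$start), , drop = FALSE]
    rownames(genes) <- NULL
  }
  structure(list(genome_id = genome_id, genes = genes,
                 n_ignored_features = as.integer(n_ignored_features)),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("genome_annotation '", x$genome_id, "': ", nrow(x$genes), " genes on ",
      length(unique(x$genes$chrom)), " sequence(s)\n", sep = "")
  invisible(x)
}

#' Read 12-column tabular protein alignment hits
#'
#' The format is the standard 12-column tab-separated alignment table
#' (qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore).  Row order is preserved.
#'
#' @param path path to the tab-separated file.
#' @return A data frame of alignment hits with those 12 columns.
#' @export
read_tabular_hits <- function(path) {
  if (!file.exists(path)) stop("hits file not found: ", path, call. = FALSE)
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  info <- file.info(path)
  if (info$size == 0) return(empty_hits())
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character", comment.char = "#",
                           quote = "", stringsAsFactors = FALSE)
  if (ncol(tab) != 12L) {
    stop("expected 12 tab-separated columns, got ", ncol(tab), call. = FALSE)
  }
  names(tab) <- cols
  num <- c("pident", "length", "mismatch", "gapopen", "qstart", "qend",
           "sstart", "send", "evalue", "bitscore")
  for (cl in num) {
    v <- suppressWarnings(as.numeric(tab[[cl]]))
    if (anyNA(v)) {
      stop("non-numeric value '", tab[[cl]][which(is.na(v))[1L]], "' in column ",
           cl, " at row ", which(is.na(v))[1L], call. = FALSE)
    }
    tab[[cl]] <- v
  }
  int_cols <- c("length", "mismatch", "gapopen", "qstart", "qend", "sstart", "send")
  for (cl in int_cols) tab[[cl]] <- as.integer(tab[[cl]])
  if (any(tab$pident < 0 | tab$pident > 100)) stop("pident outside [0,100]", call. = FALSE)
  if (any(tab$length < 1L)) stop("alignment length < 1", call. = FALSE)
  tab
}

empty_hits <- function() {
  data.frame(qseqid = character(), sseqid = character(), pident = numeric(),
             length = integer(), mismatch = integer(), gapopen = integer(),
             qstart = integer(), qend = integer(), sstart = integer(),
             send = integer(), evalue = numeric(), bitscore = numeric(),
             stringsAsFactors = FALSE)
}

#' Write tabular alignment hits
#'
#' @param hits data frame as returned by [read_tabular_hits()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tabular_hits <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED3+ file of genomic intervals
#'
#' Intervals are returned 0-based half-open (the BED convention) and sorted
#' by (chrom, start).
#'
#' @param path path to a BED file.
#' @return A `genomic_intervals` data frame.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path, call. = FALSE)
  if (file.info(path)$size == 0) {
    return(genomic_intervals(character(), integer(), integer()))
  }
  gr <- tryCatch(
    rtracklayer::import(path, format = "BED"),
    error = function(e) {
      stop("invalid BED file ", path, ": ", conditionMessage(e), call. = FALSE)
    })
  start0 <- BiocGenerics::start(gr) - 1L
  end0 <- BiocGenerics::end(gr)
  if (any(start0 >= end0)) stop("invalid BED interval: start >= end", call. = FALSE)
  nm <- if (!is.null(gr$name)) as.character(gr$name) else "."
  nm[is.na(nm)] <- "."
  st <- as.character(BiocGenerics::strand(gr))
  st[st == "*"] <- "."
  out <- genomic_intervals(as.character(GenomicRanges::seqnames(gr)),
                           start0, end0, name = nm, strand = st)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("genomic_intervals", "data.frame")
  out
}

#' Write ortholog links to a TSV file
#'
#' One row per link with both genomes' coordinates (1-based inclusive, as in
#' the source annotations), strands, percent identity, bitscore and
#' orientation; the header line starts with `#`.  [read_links_tsv()] is its
#' inverse.
#'
#' @param links ortholog link table (see [build_links()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_links_tsv <- function(links, path) {
  cols <- c("gene_a", "chrom_a", "start_a", "end_a", "strand_a",
            "gene_b", "chrom_b", "start_b", "end_b", "strand_b",
            "identity", "bitscore", "orientation")
  header <- paste0("#", paste(cols, collapse = "\t"))
  con <- tryCatch(file(path, open = "wt"),
                  error = function(e) stop("cannot write ", path, call. = FALSE))
  on.exit(close(con))
  writeLines(header, con)
  if (nrow(links)) {
    utils::write.table(links[, cols], con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read an ortholog link TSV written by [write_links_tsv()]
#'
#' @param path path to the links file.
#' @return An ortholog link data frame.
#' @export
read_links_tsv <- function(path) {
  if (!file.exists(path)) stop("links file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  cols <- strsplit(sub("^#", "", first), "\t", fixed = TRUE)[[1L]]
  tab <- utils::read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                           quote = "", stringsAsFactors = FALSE,
                           col.names = cols,
                           colClasses = c(gene_a = "character", chrom_a = "character",
                                          start_a = "integer", end_a = "integer",
                                          strand_a = "character",
                                          gene_b = "character", chrom_b = "character",
                                          start_b = "integer", end_b = "integer",
                                          strand_b = "character",
                                          identity = "numeric", bitscore = "numeric",
                                          orientation = "integer")[cols])
  tab
}

#' Write genomic intervals as BED
#'
#' @param intervals a `genomic_intervals` data frame (0-based half-open).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  if (nrow(intervals) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  tab <- data.frame(intervals$chrom, intervals$start, intervals$end,
                    intervals$name, 0L, intervals$strand)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
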