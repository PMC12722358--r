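# End-to-end orchestration: validate a configuration, run ortholog link
# classification and synteny/rearrangement/centromere-origin analysis,
# write every artifact, and return a summary report.

#' Pipeline configuration
#'
#' @param gff_a,gff_b paths to the two genome annotations (GFF3).
#' @param hits_ab,hits_ba paths to the tabular alignment hits for the two
#'   directions.
#' @param cen_a,cen_b optional paths to centromere-unit BED files for the
#'   two genomes; when both are given, centromere origins are classified.
#' @param out_dir output directory.
#' @param min_identity,min_align_len noise-filter thresholds
#'   ([filter_thresholds()]).
#' @param mode ortholog classification mode ([classify_single_copy()]).
#' @param max_gap_genes,min_block_links chaining parameters
#'   ([chain_blocks()]).
#' @param min_event_links minimum block size for a rearrangement call.
#' @param min_overlap_frac overlap threshold for `corresponding`
#'   centromere calls.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(gff_a, gff_b, hits_ab, hits_ba,
                            cen_a = NULL, cen_b = NULL,
                            out_dir = tempfile("centrosynteny_run_"),
                            min_identity = 90, min_align_len = 150,
                            mode = "reciprocal",
                            max_gap_genes = 10, min_block_links = 5,
                            min_event_links = 5, min_overlap_frac = 0.1) {
  cfg <- list(gff_a = gff_a, gff_b = gff_b, hits_ab = hits_ab,
              hits_ba = hits_ba, cen_a = cen_a, cen_b = cen_b,
              out_dir = out_dir, min_identity = min_identity,
              min_align_len = min_align_len, mode = mode,
              max_gap_genes = max_gap_genes,
              min_block_links = min_block_links,
              min_event_links = min_event_links,
              min_overlap_frac = min_overlap_frac)
  required <- c("gff_a", "gff_b", "hits_ab", "hits_ba")
  for (nm in c(required, if (!is.null(cen_a)) "cen_a",
               if (!is.null(cen_b)) "cen_b")) {
    if (is.null(cfg[[nm]]) || !file.exists(cfg[[nm]])) {
      stop("pipeline_config: input '", nm, "' missing or not found: ",
           cfg[[nm]], call. = FALSE)
    }
  }
  class(cfg) <- "pipeline_config"
  cfg
}

config_digest <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, null = "null"),
             tmp)
  unname(tools::md5sum(tmp))
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the comparative centromere-genomics pipeline
#'
#' Reads the annotations, alignment hits and (optionally) centromere BED
#' files, classifies conserved single-copy ortholog links, chains them into
#' synteny blocks, calls inversions and translocations, classifies
#' centromere origins when centromere units are supplied, and writes all
#' artifacts (links, blocks, events, origin calls, summary JSON) to
#' `config$out_dir`.  Progress counts are logged to standard error.
#'
#' @param config a [pipeline_config()].
#' @return A `summary_report` list with the tallies (n_links, n_blocks,
#'   n_collinear_genes, n_inversions, n_translocations, centromere origin
#'   tallies, per-genome gene counts) and the config digest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  annot_a <- stage("read_gff_a", read_gff3_genes(config$gff_a, "A"))
  annot_b <- stage("read_gff_b", read_gff3_genes(config$gff_b, "B"))
  hits_ab <- stage("read_hits_ab", read_tabular_hits(config$hits_ab))
  hits_ba <- stage("read_hits_ba", read_tabular_hits(config$hits_ba))

  thresholds <- filter_thresholds(config$min_identity, config$min_align_len)
  links <- stage("ortholog_links",
                 ortholog_links(hits_ab, hits_ba, annot_a, annot_b,
                                thresholds = thresholds, mode = config$mode))
  message("ortholog_links: ", nrow(links), " links")
  write_links_tsv(links, file.path(config$out_dir, "links.tsv"))

  sb <- stage("chain_blocks",
              chain_blocks(links, config$max_gap_genes,
                           config$min_block_links))
  message("chain_blocks: ", nrow(sb$blocks), " blocks")
  utils::write.table(sb$blocks, file.path(config$out_dir, "blocks.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  inv <- stage("call_inversions", call_inversions(sb, config$min_event_links))
  tra <- stage("call_translocations",
               call_translocations(sb, config$min_event_links,
                                   config$max_gap_genes))
  events <- rbind(inv, tra)
  message("rearrangements: ", nrow(inv), " inversion(s), ",
          nrow(tra), " translocation(s)")
  utils::write.table(events, file.path(config$out_dir, "events.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  origin_tallies <- c(corresponding = 0L, de_novo_insertion = 0L,
                      unresolved = 0L)
  if (!is.null(config$cen_a) && !is.null(config$cen_b)) {
    units_a <- stage("read_cen_a", read_bed(config$cen_a))
    units_b <- stage("read_cen_b", read_bed(config$cen_b))
    calls <- stage("centromere_origin",
                   classify_centromere_origin(units_b, units_a, links, sb,
                                              config$min_overlap_frac))
    utils::write.table(calls,
                       file.path(config$out_dir, "centromere_origin.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    tab <- table(calls$klass)
    origin_tallies[names(tab)] <- as.integer(tab)
    message("centromere origins: ",
            paste(names(origin_tallies), origin_tallies,
                  sep = "=", collapse = ", "))
  }

  report <- structure(list(
    n_links = nrow(links),
    n_blocks = nrow(sb$blocks),
    n_collinear_genes = sum(!is.na(sb$membership)),
    n_inversions = nrow(inv),
    n_translocations = nrow(tra),
    centromere_origin = as.list(origin_tallies),
    genes_a = nrow(annot_a$genes),
    genes_b = nrow(annot_b$genes),
    config_digest = config_digest(config)), class = "summary_report")
  jsonlite::write_json(unclass(report),
                       file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  report
}

#' @export
print.summary_report <- function(x, ...) {
  cat("summary_report:\n",
      "  links:          ", x$n_links, "\n",
      "  blocks:         ", x$n_blocks,
      " (", x$n_collinear_genes, " collinear genes)\n",
      "  inversions:     ", x$n_inversions, "\n",
      "  translocations: ", x$n_translocations, "\n",
      "  centromere origins: ",
      paste(names(x$centromere_origin), unlist(x$centromere_origin),
            sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Mean chromosome size in Mb
#'
#' Divides the 1C genome size by the chromosome number and rounds half-up
#' to one decimal, the precision used for genome summaries.
#'
#' @param genome_size_mb genome size, Mb per 1C (> 0).
#' @param n_chromosomes haploid chromosome number (>= 1).
#' @return Mean chromosome size in Mb, one decimal.
#' @export
genome_summary <- function(genome_size_mb, n_chromosomes) {
  if (n_chromosomes < 1) stop("n_chromosomes must be >= 1", call. = FALSE)
  if (genome_size_mb <= 0) stop("genome_size_mb must be > 0", call. = FALSE)
  floor(genome_size_mb / n_chromosomes * 10 + 0.5) / 10
}
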