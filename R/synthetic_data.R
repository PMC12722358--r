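# Seeded generators for every fixture the pipeline consumes, with full
# truth tables: paired genomes derived from a common ancestor by planted
# inversions, translocations and centromere-interval insertions; proteins
# mutated to a target identity; satellite arrays with planted variants,
# orientation flips and HOR period; ChIP/input window counts with planted
# enrichment.  Every generator is a pure function of (config, seed).

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
DNA_ALPHABET <- c("A", "C", "G", "T")

GENE_GRID_BP <- 10000L    # one gene slot per 10 kb; coordinates are
                          # scale-free for the rank-based synteny logic

# sample one element safely (sample(x, 1) misbehaves for scalar integer x)
sample1 <- function(x) if (length(x) == 1L) x else sample(x, 1L)

random_protein <- function(len) {
  paste(sample(AA_ALPHABET, len, replace = TRUE), collapse = "")
}

random_dna <- function(len) {
  paste(sample(DNA_ALPHABET, len, replace = TRUE), collapse = "")
}

# substitute exactly k positions, chosen without replacement, each to a
# different letter; operates on the current RNG stream
substitute_positions <- function(seq, k, alphabet) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  if (k == 0L) return(seq)
  pos <- sample(length(chars), k)
  for (p in pos) {
    chars[p] <- sample(setdiff(alphabet, chars[p]), 1L)
  }
  paste(chars, collapse = "")
}

mutate_protein_impl <- function(seq, target_identity) {
  n <- nchar(seq)
  k <- n - as.integer(round(n * target_identity))
  substitute_positions(seq, k, AA_ALPHABET)
}

# per-base substitution at `rate`; expected identity 1 - rate
mutate_dna_impl <- function(seq, rate) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  hit <- which(stats::runif(length(chars)) < rate)
  for (p in hit) chars[p] <- sample(setdiff(DNA_ALPHABET, chars[p]), 1L)
  paste(chars, collapse = "")
}

#' Mutate a protein to an exact target identity
#'
#' Substitutes `len - round(len * target_identity)` positions, sampled
#' without replacement, each to a different residue, so the realized
#' identity is exactly `round(len * target_identity) / len`.
#'
#' @param seq amino-acid string (non-empty).
#' @param target_identity fraction in (0, 1].
#' @param seed integer seed; the global RNG state is untouched.
#' @return The mutated protein string.
#' @export
mutate_protein <- function(seq, target_identity, seed) {
  if (nchar(seq) == 0) stop("empty protein sequence", call. = FALSE)
  if (target_identity <= 0 || target_identity > 1) {
    stop("target_identity must be in (0, 1]", call. = FALSE)
  }
  withr::with_seed(seed, mutate_protein_impl(seq, target_identity))
}

#' Simulation configuration for a genome pair
#'
#' Defaults define the reference study conditions: four chromosomes of 60
#' genes on a 10-kb grid, proteins of 180-400 aa mutated to 95% identity,
#' rearranged by non-overlapping inversions and translocations of 5-10
#' genes, with gene-free centromere intervals inserted into genome B and
#' one ancestral centromere interval on genome A.
#'
#' @param seed integer seed (mandatory).
#' @param n_chromosomes chromosomes per genome (default 4).
#' @param genes_per_chromosome genes per chromosome (default 60).
#' @param n_inversions planted inversions (default 0).
#' @param n_translocations planted inter-chromosomal translocations
#'   (default 0).
#' @param inversion_size_genes,translocation_size_genes inclusive size
#'   ranges in genes (default c(5, 10)).
#' @param duplicate_fraction fraction of genome-A genes given an extra
#'   genome-B copy (default 0).
#' @param protein_identity target protein identity between orthologs
#'   (default 0.95).
#' @param centromere_insertions_b gene-free centromere intervals inserted
#'   into genome B (default 0).
#' @param centromere_length_b length of each inserted interval, bp
#'   (default 50000).
#' @param centromere_a place one ancestral centromere interval on genome-A
#'   chromosome 1 (default TRUE when insertions are planted).
#' @param centromere_length_a its length in bp (default 5000; it must fit
#'   an intergenic gap of the gene grid).
#' @param protein_len_range protein lengths, aa (default c(180, 400)).
#' @param n_noise_hits sub-threshold alignment hits added per direction to
#'   exercise the noise filter (default 50).
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(seed,
                              n_chromosomes = 4,
                              genes_per_chromosome = 60,
                              n_inversions = 0,
                              n_translocations = 0,
                              inversion_size_genes = c(5, 10),
                              translocation_size_genes = c(5, 10),
                              duplicate_fraction = 0,
                              protein_identity = 0.95,
                              centromere_insertions_b = 0,
                              centromere_length_b = 50000,
                              centromere_a = centromere_insertions_b > 0,
                              centromere_length_a = 5000,
                              protein_len_range = c(180, 400),
                              n_noise_hits = 50) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  cfg <- list(seed = as.integer(seed),
              n_chromosomes = as.integer(n_chromosomes),
              genes_per_chromosome = as.integer(genes_per_chromosome),
              n_inversions = as.integer(n_inversions),
              n_translocations = as.integer(n_translocations),
              inversion_size_genes = as.integer(inversion_size_genes),
              translocation_size_genes = as.integer(translocation_size_genes),
              duplicate_fraction = duplicate_fraction,
              protein_identity = protein_identity,
              centromere_insertions_b = as.integer(centromere_insertions_b),
              centromere_length_b = as.integer(centromere_length_b),
              centromere_a = isTRUE(centromere_a),
              centromere_length_a = as.integer(centromere_length_a),
              protein_len_range = as.integer(protein_len_range),
              n_noise_hits = as.integer(n_noise_hits))
  stopifnot(cfg$n_chromosomes >= 1, cfg$genes_per_chromosome >= 2,
            cfg$n_inversions >= 0, cfg$n_translocations >= 0,
            cfg$duplicate_fraction >= 0, cfg$duplicate_fraction < 1,
            cfg$protein_identity > 0, cfg$protein_identity <= 1,
            cfg$centromere_insertions_b >= 0)
  if (cfg$n_translocations > 0 && cfg$n_chromosomes < 2) {
    stop("translocations need at least 2 chromosomes", call. = FALSE)
  }
  class(cfg) <- "simulation_config"
  cfg
}

# Reserve a window of `size` ranks on some chromosome, keeping a margin of
# `sep` genes from chromosome ends and from previously reserved windows.
# `reserved` is a list (per chromosome) of rank windows rbind(start, end).
place_window <- function(reserved, n_genes, size, sep, chroms, max_try = 200) {
  for (try in seq_len(max_try)) {
    ch <- sample1(chroms)
    lo <- 1L + sep
    hi <- n_genes - size + 1L - sep
    if (hi < lo) next
    start <- sample1(lo:hi)
    win <- c(start, start + size - 1L)
    clash <- FALSE
    for (w in reserved[[ch]]) {
      if (win[1L] <= w[2L] + sep && w[1L] <= win[2L] + sep) {
        clash <- TRUE
        break
      }
    }
    if (!clash) {
      return(list(chrom = ch, start = win[1L], end = win[2L]))
    }
  }
  NULL
}

#' Simulate a pair of annotated genomes with planted truth
#'
#' Genome B is derived from genome A by applying the configured inversions
#' (gene order reversed, strands flipped), inter-chromosomal translocations
#' (a gene run moved to another chromosome), gene-free centromere-interval
#' insertions, and gene duplications; proteins are mutated to the target
#' identity and alignment hits are emitted directly from the truth (pident
#' = realized identity, alignment length = protein length), plus
#' sub-threshold noise hits.  Deterministic given the config seed.
#'
#' @param config a [simulation_config()].
#' @return A `genome_pair_sim` list: `annot_a`, `annot_b`
#'   (`genome_annotation`), `proteins_a`, `proteins_b` (named character
#'   vectors by protein id), `hits_ab`, `hits_ba` (alignment hit tables)
#'   and `truth` (ortholog_pairs, inversions, translocations, cen_units_a,
#'   cen_units_b, config).
#' @export
simulate_genome_pair <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  withr::with_seed(config$seed, simulate_genome_pair_impl(config))
}

simulate_genome_pair_impl <- function(cfg) {
  nchr <- cfg$n_chromosomes
  G <- cfg$genes_per_chromosome
  n_genes <- nchr * G
  chrom_a <- sprintf("chrA%02d", seq_len(nchr))
  chrom_b <- sprintf("chrB%02d", seq_len(nchr))

  plen_pool <- seq(cfg$protein_len_range[1L], cfg$protein_len_range[2L])
  plen <- plen_pool[sample.int(length(plen_pool), n_genes, replace = TRUE)]
  strand_a <- sample(c("+", "-"), n_genes, replace = TRUE)
  gene_chr <- rep(seq_len(nchr), each = G)
  gene_rank <- rep(seq_len(G), nchr)
  gid_a <- sprintf("gA%04d", seq_len(n_genes))
  gid_b <- sprintf("gB%04d", seq_len(n_genes))
  prot_a <- paste0(gid_a, ".m1")
  prot_b <- paste0(gid_b, ".m1")

  proteins_a <- stats::setNames(vapply(plen, random_protein, ""), prot_a)
  proteins_b <- stats::setNames(
    vapply(proteins_a, mutate_protein_impl, "", cfg$protein_identity), prot_b)

  ## --- plan events in genome-A rank space, pairwise separated by >= 2 genes
  reserved <- rep(list(list()), nchr)
  sep <- 2L
  cen_a_gap <- NULL
  if (cfg$centromere_a) {
    # the ancestral centromere gap and its flanks stay clear of events
    cen_a_gap <- list(chrom = 1L, after = G %/% 2L)
    reserved[[1L]] <- list(c(cen_a_gap$after - 1L, cen_a_gap$after + 2L))
  }
  inv <- list()
  for (k in seq_len(cfg$n_inversions)) {
    size <- sample1(seq(cfg$inversion_size_genes[1L],
                        cfg$inversion_size_genes[2L]))
    w <- place_window(reserved, G, size, sep, seq_len(nchr))
    if (is.null(w)) {
      stop("cannot place inversion ", k, " of ", size,
           " genes without overlap; reduce event count/size", call. = FALSE)
    }
    reserved[[w$chrom]] <- c(reserved[[w$chrom]], list(c(w$start, w$end)))
    inv[[k]] <- w
  }
  tra <- list()
  used_pairs <- character(0)
  for (k in seq_len(cfg$n_translocations)) {
    size <- sample1(seq(cfg$translocation_size_genes[1L],
                        cfg$translocation_size_genes[2L]))
    w <- NULL
    for (try in seq_len(200L)) {
      cand <- place_window(reserved, G, size, sep, seq_len(nchr))
      if (is.null(cand)) break
      dst <- sample1(setdiff(seq_len(nchr), cand$chrom))
      pair <- paste(cand$chrom, dst)
      if (pair %in% used_pairs) next   # distinct source->destination pairs
      w <- cand
      w$dst <- dst
      break
    }
    if (is.null(w)) {
      stop("cannot place translocation ", k, " of ", size,
           " genes; reduce event count/size", call. = FALSE)
    }
    reserved[[w$chrom]] <- c(reserved[[w$chrom]], list(c(w$start, w$end)))
    used_pairs <- c(used_pairs, paste(w$chrom, w$dst))
    # insertion gap in the destination: after rank `after` (0 = start),
    # away from reserved windows there
    ok_gap <- setdiff(seq(sep, G - sep), unlist(lapply(
      reserved[[w$dst]], function(r) seq(r[1L] - 1L, r[2L]))))
    if (!length(ok_gap)) {
      stop("no insertion gap on destination chromosome for translocation ",
           k, call. = FALSE)
    }
    w$after <- sample1(ok_gap)
    # reserve the insertion gap so later events keep clear of it
    reserved[[w$dst]] <- c(reserved[[w$dst]],
                           list(c(w$after, w$after + 1L)))
    tra[[k]] <- w
  }

  ## --- derive genome-B gene orders
  # items: global gene index (positive); strand flips tracked separately
  order_b <- lapply(seq_len(nchr), function(c) which(gene_chr == c))
  strand_b <- strand_a
  touched <- rep(FALSE, n_genes)
  for (w in inv) {
    idx <- order_b[[w$chrom]][w$start:w$end]
    order_b[[w$chrom]][w$start:w$end] <- rev(idx)
    strand_b[idx] <- ifelse(strand_b[idx] == "+", "-", "+")
    touched[idx] <- TRUE
  }
  # translocations: remove from source, insert into destination after the
  # gene that originally sat at rank `after` (events are rank-disjoint, so
  # source removal does not disturb other windows)
  for (w in tra) {
    src <- order_b[[w$chrom]]
    take <- which(gene_chr[src] == w$chrom &
                    gene_rank[src] >= w$start & gene_rank[src] <= w$end)
    seg <- src[take]
    order_b[[w$chrom]] <- src[-take]
    dstv <- order_b[[w$dst]]
    at <- if (w$after == 0L) 0L else
      max(which(gene_rank[dstv] <= w$after & gene_chr[dstv] == w$dst), 0L)
    order_b[[w$dst]] <- append(dstv, seg, after = at)
    touched[seg] <- TRUE
  }

  ## --- duplicates: extra genome-B copies of sampled genome-A genes
  n_dup <- as.integer(floor(cfg$duplicate_fraction * n_genes))
  dup_src <- if (n_dup > 0) sort(sample(n_genes, n_dup)) else integer(0)
  dup_ids <- sprintf("gBdup%03d", seq_along(dup_src))
  dup_prot <- paste0(dup_ids, ".m1")
  for (j in seq_along(dup_src)) {
    src <- dup_src[j]
    ch <- sample1(seq_len(nchr))
    pos <- sample(0:length(order_b[[ch]]), 1L)
    # negative entry marks duplicate copy j
    order_b[[ch]] <- append(order_b[[ch]], -j, after = pos)
    proteins_b[dup_prot[j]] <-
      mutate_protein_impl(proteins_a[[src]], cfg$protein_identity)
  }

  ## --- centromere insertions into genome B (gene-free intervals between
  ##     untouched neighbours, away from the genome-A centromere gap)
  cen_gaps <- list()
  if (cfg$centromere_insertions_b > 0) {
    # insertions emulate centromere units splitting conserved syntenic
    # blocks: the gap must lie inside a run of untouched, A-consecutive
    # genes long enough to chain into a block on its own
    min_run <- 6L
    cand <- list()
    for (c in seq_len(nchr)) {
      v <- order_b[[c]]
      untouched <- v > 0 & !touched[pmax(v, 1L)]
      run_id <- integer(length(v))
      cur <- 0L
      for (p in seq_along(v)) {
        new_run <- p == 1L || !untouched[p] || !untouched[p - 1L] ||
          gene_chr[v[p]] != gene_chr[v[p - 1L]] ||
          gene_rank[v[p]] != gene_rank[v[p - 1L]] + 1L
        if (new_run) cur <- cur + 1L
        run_id[p] <- cur
      }
      run_len <- tabulate(run_id)[run_id]
      for (p in seq_len(length(v) - 1L)) {
        if (!untouched[p] || !untouched[p + 1L]) next
        if (run_id[p] != run_id[p + 1L] || run_len[p] < min_run) next
        l <- v[p]
        if (!is.null(cen_a_gap) && gene_chr[l] == cen_a_gap$chrom &&
            abs(gene_rank[l] - cen_a_gap$after) <= 2L) next
        cand[[length(cand) + 1L]] <- c(c, p)
      }
    }
    if (length(cand) < cfg$centromere_insertions_b) {
      stop("not enough gene-free gaps for ", cfg$centromere_insertions_b,
           " centromere insertions", call. = FALSE)
    }
    cen_gaps <- cand[sample(length(cand), cfg$centromere_insertions_b)]
  }

  ## --- layout genome A (grid: one gene per 10 kb slot)
  genes_a <- data.frame(
    gene_id = gid_a, chrom = chrom_a[gene_chr],
    start = (gene_rank - 1L) * GENE_GRID_BP + 1L,
    end = (gene_rank - 1L) * GENE_GRID_BP + 3L * plen,
    strand = strand_a, protein_id = prot_a, protein_len = plen,
    stringsAsFactors = FALSE)
  annot_a <- genome_annotation("genomeA", genes_a)

  cen_units_a <- genomic_intervals(character(), integer(), integer())
  if (cfg$centromere_a) {
    # inside the intergenic gap after gene rank `after` on chromosome 1
    flank <- which(gene_chr == cen_a_gap$chrom & gene_rank == cen_a_gap$after)
    gap_start <- genes_a$end[flank] + 1500L          # 0-based after padding
    cen_units_a <- genomic_intervals(chrom_a[cen_a_gap$chrom], gap_start,
                                     gap_start + cfg$centromere_length_a,
                                     name = "cenA_1")
  }

  ## --- layout genome B with centromere insertions shifting coordinates
  rows_b <- list()
  cen_rows <- list()
  for (c in seq_len(nchr)) {
    v <- order_b[[c]]
    ins_after <- vapply(cen_gaps, function(g) if (g[1L] == c) g[2L] else -1L,
                        integer(1))
    cursor <- 0L
    for (p in seq_along(v)) {
      it <- v[p]
      if (it > 0) {
        id <- gid_b[it]; pid <- prot_b[it]; pl <- plen[it]; st <- strand_b[it]
      } else {
        j <- -it
        id <- dup_ids[j]; pid <- dup_prot[j]; pl <- plen[dup_src[j]]
        st <- strand_a[dup_src[j]]
      }
      rows_b[[length(rows_b) + 1L]] <- data.frame(
        gene_id = id, chrom = chrom_b[c], start = cursor + 1L,
        end = cursor + 3L * pl, strand = st, protein_id = pid,
        protein_len = pl, stringsAsFactors = FALSE)
      cursor <- cursor + GENE_GRID_BP
      if (any(ins_after == p)) {
        for (rep_k in which(ins_after == p)) {
          cen_rows[[length(cen_rows) + 1L]] <-
            data.frame(chrom = chrom_b[c], start = cursor,
                       end = cursor + cfg$centromere_length_b,
                       stringsAsFactors = FALSE)
          cursor <- cursor + cfg$centromere_length_b
        }
      }
    }
  }
  genes_b <- do.call(rbind, rows_b)
  annot_b <- genome_annotation("genomeB", genes_b)
  cen_units_b <- if (length(cen_rows)) {
    cb <- do.call(rbind, cen_rows)
    cb <- cb[order(cb$chrom, cb$start), , drop = FALSE]
    genomic_intervals(cb$chrom, cb$start, cb$end,
                      name = sprintf("cenB_%d", seq_len(nrow(cb))))
  } else {
    genomic_intervals(character(), integer(), integer())
  }

  ## --- truth tables
  span_on <- function(genes, ids) {
    i <- match(ids, genes$gene_id)
    c(min(genes$start[i]), max(genes$end[i]))
  }
  inv_truth <- do.call(rbind, lapply(seq_along(inv), function(k) {
    w <- inv[[k]]
    ids <- gid_a[gene_chr == w$chrom & gene_rank >= w$start & gene_rank <= w$end]
    sa <- span_on(genes_a, ids)
    sb <- span_on(genes_b, sub("^gA", "gB", ids))
    data.frame(event = k, chrom_a = chrom_a[w$chrom], chrom_b = chrom_b[w$chrom],
               rank_start = w$start, rank_end = w$end, n_genes = length(ids),
               start_a = sa[1L], end_a = sa[2L], start_b = sb[1L], end_b = sb[2L],
               stringsAsFactors = FALSE)
  }))
  tra_truth <- do.call(rbind, lapply(seq_along(tra), function(k) {
    w <- tra[[k]]
    ids <- gid_a[gene_chr == w$chrom & gene_rank >= w$start & gene_rank <= w$end]
    sa <- span_on(genes_a, ids)
    sb <- span_on(genes_b, sub("^gA", "gB", ids))
    data.frame(event = k, chrom_a = chrom_a[w$chrom], chrom_b = chrom_b[w$dst],
               rank_start = w$start, rank_end = w$end, n_genes = length(ids),
               start_a = sa[1L], end_a = sa[2L], start_b = sb[1L], end_b = sb[2L],
               stringsAsFactors = FALSE)
  }))
  realized_id <- function(a, b) {
    ca <- strsplit(a, "")[[1L]]; cb <- strsplit(b, "")[[1L]]
    100 * sum(ca == cb) / length(ca)
  }
  pair_id <- vapply(seq_len(n_genes), function(i) {
    realized_id(proteins_a[[i]], proteins_b[[i]])
  }, numeric(1))
  ortholog_pairs <- data.frame(
    gene_a = gid_a, gene_b = gid_b, identity = pair_id,
    is_single_copy = !(seq_len(n_genes) %in% dup_src),
    stringsAsFactors = FALSE)
  duplicates <- data.frame(
    gene_a = gid_a[dup_src], gene_b_extra = dup_ids, stringsAsFactors = FALSE)

  ## --- alignment hits emitted from truth, plus noise
  mk_hits <- function(q, s, pid, len) {
    data.frame(qseqid = q, sseqid = s, pident = round(pid, 2),
               length = len, mismatch = as.integer(round(len * (1 - pid / 100))),
               gapopen = 0L, qstart = 1L, qend = len, sstart = 1L, send = len,
               evalue = 1e-180, bitscore = round(2 * len * pid / 100, 1),
               stringsAsFactors = FALSE)
  }
  hits_ab <- mk_hits(prot_a, prot_b, pair_id, plen)
  hits_ba <- mk_hits(prot_b, prot_a, pair_id, plen)
  if (n_dup > 0) {
    dup_id <- vapply(seq_along(dup_src), function(j) {
      realized_id(proteins_a[[dup_src[j]]], proteins_b[[dup_prot[j]]])
    }, numeric(1))
    hits_ab <- rbind(hits_ab, mk_hits(prot_a[dup_src], dup_prot, dup_id,
                                      plen[dup_src]))
    hits_ba <- rbind(hits_ba, mk_hits(dup_prot, prot_a[dup_src], dup_id,
                                      plen[dup_src]))
  }
  if (cfg$n_noise_hits > 0) {
    qi <- sample(n_genes, cfg$n_noise_hits, replace = TRUE)
    si <- sample(n_genes, cfg$n_noise_hits, replace = TRUE)
    noise_id <- stats::runif(cfg$n_noise_hits, 40, 85)
    noise_len <- sample(60:300, cfg$n_noise_hits, replace = TRUE)
    hits_ab <- rbind(hits_ab, mk_hits(prot_a[qi], prot_b[si], noise_id, noise_len))
    hits_ba <- rbind(hits_ba, mk_hits(prot_b[si], prot_a[qi], noise_id, noise_len))
  }

  structure(list(
    annot_a = annot_a, annot_b = annot_b,
    proteins_a = proteins_a, proteins_b = proteins_b,
    hits_ab = hits_ab, hits_ba = hits_ba,
    truth = list(ortholog_pairs = ortholog_pairs, duplicates = duplicates,
                 inversions = inv_truth, translocations = tra_truth,
                 cen_units_a = cen_units_a, cen_units_b = cen_units_b,
                 config = cfg)), class = "genome_pair_sim")
}

#' Simulate a satellite array with planted structure
#'
#' Builds `hor_period` divergent monomer variants (variant 1 is the input
#' monomer; the others are mutated copies at `variant_divergence`), cycles
#' them for `copies` monomers, applies per-base mutation at
#' `mutation_rate`, and reverse-complements `flips` non-overlapping runs of
#' copies (reversing copy order within each run).
#'
#' @param monomer DNA string (non-empty).
#' @param copies number of monomer copies (default 100).
#' @param mutation_rate per-base substitution rate in [0, 0.5]
#'   (default 0.02).
#' @param hor_period number of cycling variants (default 1).
#' @param flips number of orientation-flip runs (default 0).
#' @param seed integer seed.
#' @param variant_divergence per-base divergence of variants 2..p from the
#'   monomer (default 0.08, giving between-variant identities near 85%).
#' @param flip_run_genes inclusive run-length range for flips
#'   (default c(3, 6)).
#' @return List with `sequence` (the array), `truth` (per-copy data frame:
#'   start, end 0-based half-open, variant, orientation) and `variants`.
#' @export
simulate_satellite_array <- function(monomer, copies = 100,
                                     mutation_rate = 0.02, hor_period = 1,
                                     flips = 0, seed,
                                     variant_divergence = 0.08,
                                     flip_run_genes = c(3, 6)) {
  stopifnot(nchar(monomer) > 0, copies >= 1, hor_period >= 1)
  if (mutation_rate < 0 || mutation_rate > 0.5) {
    stop("mutation_rate must be in [0, 0.5]", call. = FALSE)
  }
  withr::with_seed(seed, {
    monomer <- toupper(monomer)
    # variants carry an exact substitution count so the planted
    # between-variant divergence is guaranteed, not merely expected
    n_sub <- max(1L, as.integer(round(nchar(monomer) * variant_divergence)))
    variants <- c(monomer, vapply(seq_len(hor_period - 1L), function(k) {
      substitute_positions(monomer, n_sub, DNA_ALPHABET)
    }, ""))
    variant_idx <- ((seq_len(copies) - 1L) %% hor_period) + 1L
    seqs <- vapply(variant_idx, function(v) {
      mutate_dna_impl(variants[v], mutation_rate)
    }, "")
    orientation <- rep("F", copies)
    if (flips > 0) {
      taken <- rep(FALSE, copies)
      placed <- 0L
      for (try in seq_len(500L)) {
        if (placed == flips) break
        len <- sample1(seq(flip_run_genes[1L], flip_run_genes[2L]))
        if (len > copies) next
        s <- sample(copies - len + 1L, 1L)
        run <- s:(s + len - 1L)
        if (any(taken[run])) next
        taken[run] <- TRUE
        seqs[run] <- revcomp(rev(seqs[run]))
        variant_idx[run] <- rev(variant_idx[run])
        orientation[run] <- "R"
        placed <- placed + 1L
      }
      if (placed < flips) {
        stop("could not place ", flips, " non-overlapping flip runs",
             call. = FALSE)
      }
    }
    lens <- nchar(seqs)
    ends <- cumsum(lens)
    truth <- data.frame(copy = seq_len(copies), start = ends - lens,
                        end = ends, variant = variant_idx,
                        orientation = orientation, stringsAsFactors = FALSE)
    list(sequence = paste(seqs, collapse = ""), truth = truth,
         variants = variants)
  })
}

#' Simulate ChIP and input window counts with planted enrichment
#'
#' Input counts are Poisson(`depth`) in every window; ChIP counts are
#' Poisson(`depth * enrichment`) inside the enriched blocks and
#' Poisson(`depth`) outside.
#'
#' @param n_windows number of windows.
#' @param enriched_blocks data frame with `first`/`last` 1-based window
#'   indices (or NULL for a null track).
#' @param depth expected input reads per window (> 0).
#' @param enrichment fold enrichment inside blocks (default 8).
#' @param seed integer seed.
#' @return List with `chip`, `input` (integer vectors) and `truth`
#'   (logical per-window enrichment indicator).
#' @export
simulate_chip_counts <- function(n_windows, enriched_blocks = NULL,
                                 depth, enrichment = 8, seed) {
  stopifnot(depth > 0, n_windows >= 1)
  withr::with_seed(seed, {
    enriched <- rep(FALSE, n_windows)
    if (!is.null(enriched_blocks) && nrow(enriched_blocks)) {
      for (i in seq_len(nrow(enriched_blocks))) {
        enriched[enriched_blocks$first[i]:enriched_blocks$last[i]] <- TRUE
      }
    }
    input <- stats::rpois(n_windows, depth)
    chip <- stats::rpois(n_windows, depth * ifelse(enriched, enrichment, 1))
    list(chip = chip, input = input, truth = enriched)
  })
}

#' Write simulated genome-pair fixtures to disk
#'
#' Writes GFF3 annotations, protein FASTA files, tabular alignment hits,
#' centromere BED files and the truth tables (JSON) for a
#' [simulate_genome_pair()] result, in the formats the readers in this
#' package consume.
#'
#' @param sim a `genome_pair_sim`.
#' @param dir output directory (created if missing).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(gff_a = file.path(dir, "genome_a.gff3"),
             gff_b = file.path(dir, "genome_b.gff3"),
             proteins_a = file.path(dir, "proteins_a.fasta"),
             proteins_b = file.path(dir, "proteins_b.fasta"),
             hits_ab = file.path(dir, "hits_ab.tsv"),
             hits_ba = file.path(dir, "hits_ba.tsv"),
             cen_a = file.path(dir, "cen_a.bed"),
             cen_b = file.path(dir, "cen_b.bed"),
             truth = file.path(dir, "truth.json"))
  write_gff3_genes(sim$annot_a, paths[["gff_a"]])
  write_gff3_genes(sim$annot_b, paths[["gff_b"]])
  Biostrings::writeXStringSet(Biostrings::AAStringSet(sim$proteins_a),
                              paths[["proteins_a"]])
  Biostrings::writeXStringSet(Biostrings::AAStringSet(sim$proteins_b),
                              paths[["proteins_b"]])
  write_tabular_hits(sim$hits_ab, paths[["hits_ab"]])
  write_tabular_hits(sim$hits_ba, paths[["hits_ba"]])
  write_bed(sim$truth$cen_units_a, paths[["cen_a"]])
  write_bed(sim$truth$cen_units_b, paths[["cen_b"]])
  jsonlite::write_json(sim$truth[c("ortholog_pairs", "duplicates",
                                   "inversions", "translocations")],
                       paths[["truth"]], dataframe = "columns", digits = NA)
  invisible(paths)
}

#' Write a genome annotation as GFF3
#'
#' One gene/mRNA/CDS triple per gene; the CDS spans the whole gene and its
#' length is three times the protein length.
#'
#' @param annot a `genome_annotation`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff3_genes <- function(annot, path) {
  g <- annot$genes
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(g))) {
    cds_end <- g$start[i] + 3L * g$protein_len[i] - 1L
    writeLines(c(
      paste(g$chrom[i], "centrosynteny", "gene", g$start[i], g$end[i], ".",
            g$strand[i], ".", paste0("ID=", g$gene_id[i]), sep = "\t"),
      paste(g$chrom[i], "centrosynteny", "mRNA", g$start[i], g$end[i], ".",
            g$strand[i], ".",
            paste0("ID=", g$protein_id[i], ";Parent=", g$gene_id[i]),
            sep = "\t"),
      paste(g$chrom[i], "centrosynteny", "CDS", g$start[i], cds_end, ".",
            g$strand[i], "0",
            paste0("ID=", g$protein_id[i], ".cds;Parent=", g$protein_id[i]),
            sep = "\t")), con)
  }
  invisible(path)
}
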