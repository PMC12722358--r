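mk_hit <- function(q, s, pident, len, bitscore = 2 * len) {
  data.frame(qseqid = q, sseqid = s, pident = pident, length = len,
             mismatch = 0L, gapopen = 0L, qstart = 1L, qend = len,
             sstart = 1L, send = len, evalue = 1e-50, bitscore = bitscore,
             stringsAsFactors = FALSE)
}

mk_annot <- function(id, genes, chrom = "chr1") {
  genome_annotation(id, data.frame(
    gene_id = genes, chrom = chrom,
    start = seq_along(genes) * 10000L,
    end = seq_along(genes) * 10000L + 1200L,
    strand = "+", protein_id = paste0(genes, ".p"),
    protein_len = 400L, stringsAsFactors = FALSE))
}

test_that("noise filter keeps hits at or above both thresholds, order kept", {
  hits <- rbind(mk_hit("q1", "s1", 89.9, 200),   # identity below
                mk_hit("q2", "s2", 90.0, 150),   # both at boundary
                mk_hit("q3", "s3", 95.0, 149),   # length below
                mk_hit("q4", "s4", 97.0, 300))
  out <- filter_noise(hits, filter_thresholds())
  expect_equal(out$qseqid, c("q2", "q4"))
  # subset of input and idempotent
  expect_true(all(out$qseqid %in% hits$qseqid))
  expect_equal(filter_noise(out, filter_thresholds()), out)
  expect_equal(nrow(filter_noise(hits[0, ], filter_thresholds())), 0L)
})

test_that("HSP collapsing keeps the best hit per gene pair", {
  annA <- mk_annot("A", c("A1", "A2"))
  annB <- mk_annot("B", c("B1", "B2"))
  hits <- rbind(mk_hit("A1.p", "B1.p", 92, 300, bitscore = 300),
                mk_hit("A1.p", "B1.p", 95, 200, bitscore = 250),
                mk_hit("A1.p", "B2.p", 91, 250, bitscore = 240))
  out <- collapse_hits_per_gene_pair(hits, annA, annB)
  expect_equal(nrow(out), 2L)
  expect_equal(out$bitscore[out$gene_s == "B1"], 300)
  expect_setequal(out$gene_s, c("B1", "B2"))

  expect_error(
    collapse_hits_per_gene_pair(mk_hit("A1.p", "nope", 95, 200), annA, annB),
    "unknown subject")
  expect_warning(
    out2 <- collapse_hits_per_gene_pair(mk_hit("A1.p", "nope", 95, 200),
                                        annA, annB, on_unknown = "drop"),
    "dropped")
  expect_equal(nrow(out2), 0L)
})

test_that("collapsing equals brute-force group-by-best on random hit sets", {
  annA <- mk_annot("A", sprintf("A%d", 1:10))
  annB <- mk_annot("B", sprintf("B%d", 1:10))
  withr::with_seed(99, {
    hits <- do.call(rbind, lapply(1:100, function(i) {
      mk_hit(sprintf("A%d.p", sample.int(10, 1)),
             sprintf("B%d.p", sample.int(10, 1)),
             round(runif(1, 90, 100), 2), sample(150:400, 1),
             bitscore = round(runif(1, 100, 900), 1))
    }))
  })
  out <- collapse_hits_per_gene_pair(hits, annA, annB)
  # brute force: per pair, max bitscore then max pident
  key <- paste(hits$qseqid, hits$sseqid)
  for (k in unique(key)) {
    sub <- hits[key == k, ]
    best <- sub[order(-sub$bitscore, -sub$pident), ][1, ]
    got <- out[out$qseqid == best$qseqid & out$sseqid == best$sseqid, ]
    expect_equal(nrow(got), 1L)
    expect_equal(got$bitscore, best$bitscore)
    expect_equal(got$pident, best$pident)
  }
})

test_that("single-copy classification follows the one-hit-each-way rule", {
  ab <- data.frame(gene_q = c("A1"), gene_s = c("B1"), stringsAsFactors = FALSE)
  ba <- data.frame(gene_q = c("B1"), gene_s = c("A1"), stringsAsFactors = FALSE)
  expect_equal(classify_single_copy(ab, ba),
               data.frame(gene_a = "A1", gene_b = "B1",
                          stringsAsFactors = FALSE))

  # a gene with similarity to two genes is excluded
  ab2 <- data.frame(gene_q = c("A1", "A1"), gene_s = c("B1", "B2"),
                    stringsAsFactors = FALSE)
  expect_equal(nrow(classify_single_copy(ab2, ba)), 0L)
})

test_that("classification equals brute force on random bipartite graphs", {
  withr::with_seed(123, {
    for (i in 1:40) {
      inst <- rand_hit_instance(sample(3:50, 1), sample(3:50, 1),
                                sample(5:80, 1))
      for (mode in c("reciprocal", "one_way")) {
        got <- classify_single_copy(inst$ab, inst$ba, mode = mode)
        want <- brute_single_copy(inst$ab, inst$ba, mode = mode)
        expect_equal(got, want, info = paste("instance", i, mode))
      }
    }
  })
})

test_that("reciprocal classification is symmetric under genome swap", {
  withr::with_seed(5, {
    for (i in 1:10) {
      inst <- rand_hit_instance(20, 20, 40)
      fwd <- classify_single_copy(inst$ab, inst$ba)
      swp <- classify_single_copy(inst$ba, inst$ab)
      expect_setequal(paste(fwd$gene_a, fwd$gene_b),
                      paste(swp$gene_b, swp$gene_a))
    }
  })
})

test_that("links carry coordinates and strand-product orientation", {
  annA <- mk_annot("A", c("A1", "A2"))
  annB <- mk_annot("B", c("B1", "B2"))
  annB$genes$strand[annB$genes$gene_id == "B2"] <- "-"
  pairs <- data.frame(gene_a = c("A1", "A2"), gene_b = c("B1", "B2"),
                      stringsAsFactors = FALSE)
  links <- build_links(pairs, annA, annB)
  expect_equal(links$orientation, c(1L, -1L))
  expect_equal(links$start_a, annA$genes$start)
  expect_equal(links$start_b, annB$genes$start)
  expect_error(build_links(data.frame(gene_a = "AX", gene_b = "B1"),
                           annA, annB), "AX")
})

test_that("planted duplicates remove exactly their gene's link", {
  cfg <- simulation_config(seed = 31, duplicate_fraction = 0.1)
  sim <- simulate_genome_pair(cfg)
  links <- ortholog_links(sim$hits_ab, sim$hits_ba, sim$annot_a, sim$annot_b)
  truth <- sim$truth$ortholog_pairs
  single <- truth[truth$is_single_copy, ]
  expect_gt(nrow(sim$truth$duplicates), 0L)
  expect_setequal(paste(links$gene_a, links$gene_b),
                  paste(single$gene_a, single$gene_b))
})
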