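test_that("collinear links chain into a single block", {
  links <- mk_links(1:8)
  sb <- chain_blocks(links)
  expect_equal(nrow(sb$blocks), 1L)
  expect_equal(sb$blocks$n_links, 8L)
  expect_equal(sb$blocks$orientation, 1L)
  expect_true(all(sb$membership == 1L))
})

test_that("a reversed middle run splits into blocks of opposite orientation", {
  # genome-B order reversed for genome-A ranks 3..6
  links <- mk_links(c(1, 2, 6, 5, 4, 3, 7, 8))
  sb <- chain_blocks(links, min_block_links = 2)
  expect_gte(nrow(sb$blocks), 2L)
  expect_setequal(unique(sb$blocks$orientation), c(1L, -1L))
  inv_block <- sb$blocks[sb$blocks$orientation == -1L, ]
  expect_equal(inv_block$n_links, 4L)
})

test_that("empty and unsorted inputs are handled", {
  expect_equal(nrow(chain_blocks(mk_links(integer(0)))$blocks), 0L)
  links <- mk_links(1:8)
  expect_error(chain_blocks(links[c(3, 1, 2, 4:8), ]), "sorted")
})

test_that("every link lands in exactly one block or the leftover set", {
  withr::with_seed(17, {
    for (i in 1:10) {
      cfg <- simulation_config(seed = 100 + i, n_inversions = 2,
                               n_translocations = 2)
      sim <- simulate_genome_pair(cfg)
      links <- ortholog_links(sim$hits_ab, sim$hits_ba,
                              sim$annot_a, sim$annot_b)
      sb <- chain_blocks(links)
      counts <- integer(nrow(links))
      for (idx in sb$link_idx) counts[idx] <- counts[idx] + 1L
      expect_true(all(counts[!is.na(sb$membership)] == 1L))
      expect_true(all(counts[is.na(sb$membership)] == 0L))
      expect_equal(sum(sb$blocks$n_links), sum(!is.na(sb$membership)))
    }
  })
})

test_that("chaining is invariant under genome relabeling", {
  cfg <- simulation_config(seed = 77, n_inversions = 2, n_translocations = 1)
  sim <- simulate_genome_pair(cfg)
  links <- ortholog_links(sim$hits_ab, sim$hits_ba, sim$annot_a, sim$annot_b)
  sb <- chain_blocks(links)

  swap <- links
  names(swap) <- sub("_a$", "_x", names(swap))
  names(swap) <- sub("_b$", "_a", names(swap))
  names(swap) <- sub("_x$", "_b", names(swap))
  swap <- swap[order(swap$chrom_a, swap$start_a), ]
  rownames(swap) <- NULL
  sb2 <- chain_blocks(swap)

  block_sets <- function(sb, links_df) {
    sets <- lapply(sb$link_idx, function(i) sort(links_df$gene_a[i]))
    sets[order(vapply(sets, paste, "", collapse = ","))]
  }
  # gene_a of swapped table is the genome-B gene; compare via the pair id
  sets1 <- lapply(sb$link_idx, function(i) sort(paste(links$gene_a[i],
                                                      links$gene_b[i])))
  sets2 <- lapply(sb2$link_idx, function(i) sort(paste(swap$gene_b[i],
                                                       swap$gene_a[i])))
  key <- function(s) vapply(s, paste, "", collapse = "|")
  expect_setequal(key(sets1), key(sets2))
  # orientations match per block
  o1 <- stats::setNames(sb$blocks$orientation, key(sets1))
  o2 <- stats::setNames(sb2$blocks$orientation, key(sets2))
  expect_equal(o1[sort(names(o1))], o2[sort(names(o1))])
})

test_that("inversion calls need a dominant opposite-orientation context", {
  # all blocks forward: nothing to call
  sb <- chain_blocks(mk_links(1:10))
  expect_equal(nrow(call_inversions(sb)), 0L)

  # a chromosome pair that is entirely reversed is its own dominant context
  sb_rev <- chain_blocks(mk_links(10:1))
  expect_equal(sb_rev$blocks$orientation, -1L)
  expect_equal(nrow(call_inversions(sb_rev)), 0L)
})

test_that("translocation calls respect the dominant partner and threshold", {
  # perfect 1:1 correspondence on two chromosome pairs
  links <- rbind(mk_links(1:10),
                 mk_links(1:10, chrom_a = "cA2", chrom_b = "cB2"))
  links <- links[order(links$chrom_a, links$start_a), ]
  rownames(links) <- NULL
  sb <- chain_blocks(links)
  expect_equal(nrow(call_translocations(sb)), 0L)

  # a 2-link stray block below min_event_links is not called
  stray <- mk_links(1:12)
  stray$chrom_b[6:7] <- "cB9"
  stray$gene_b[6:7] <- c("x1", "x2")
  stray$start_b[6:7] <- c(1000L, 2000L)
  stray$end_b[6:7] <- c(1500L, 2500L)
  sb2 <- chain_blocks(stray, min_block_links = 2)
  expect_equal(nrow(call_translocations(sb2, min_event_links = 5)), 0L)
})

test_that("planted rearrangements are recovered exactly (several seeds)", {
  for (s in c(201, 202, 203)) {
    cfg <- simulation_config(seed = s, n_inversions = 3, n_translocations = 4)
    sim <- simulate_genome_pair(cfg)
    links <- ortholog_links(sim$hits_ab, sim$hits_ba,
                            sim$annot_a, sim$annot_b)
    sb <- chain_blocks(links)
    inv <- call_inversions(sb)
    tra <- call_translocations(sb)
    expect_equal(nrow(inv), 3L)
    expect_equal(nrow(tra), 4L)
    for (i in seq_len(nrow(sim$truth$inversions))) {
      tr <- sim$truth$inversions[i, ]
      expect_true(any(inv$chrom_a == tr$chrom_a &
                        inv$start_a <= tr$end_a & inv$end_a >= tr$start_a))
    }
    for (i in seq_len(nrow(sim$truth$translocations))) {
      tr <- sim$truth$translocations[i, ]
      expect_true(any(tra$chrom_a == tr$chrom_a &
                        tra$start_a <= tr$end_a & tra$end_a >= tr$start_a))
    }
  }
})

test_that("interval projection uses inner flank coordinates", {
  # two adjacent links with partner coordinates 100-200 and 500-600 on cB1
  links <- data.frame(
    gene_a = c("a1", "a2"), chrom_a = "cA1",
    start_a = c(1000L, 3000L), end_a = c(1500L, 3500L), strand_a = "+",
    gene_b = c("b1", "b2"), chrom_b = "cB1",
    start_b = c(101L, 501L), end_b = c(200L, 600L), strand_b = "+",
    identity = 99, bitscore = 100, orientation = 1L, stringsAsFactors = FALSE)
  unit <- genomic_intervals("cA1", 1800, 2500, name = "u")
  pr <- project_interval(unit, links, side = "a")
  expect_false(is.null(pr$projected))
  expect_gte(pr$projected$start, 200L)
  expect_lte(pr$projected$end, 500L)

  # interval left of the first link is unresolved
  pr2 <- project_interval(genomic_intervals("cA1", 0, 500, name = "u"),
                          links, side = "a")
  expect_null(pr2$projected)
  expect_equal(pr2$reason, "missing flank")
})

test_that("a linked gene's own interval projects over its ortholog", {
  cfg <- simulation_config(seed = 55)
  sim <- simulate_genome_pair(cfg)
  links <- ortholog_links(sim$hits_ab, sim$hits_ba, sim$annot_a, sim$annot_b)
  withr::with_seed(1, picks <- sample(which(links$chrom_b == "chrB02"), 5))
  for (i in picks) {
    g <- links[i, ]
    unit <- genomic_intervals(g$chrom_b, g$start_b - 1L, g$end_b, name = "g")
    pr <- project_interval(unit, links, side = "b")
    if (is.null(pr$projected)) next   # chromosome-terminal genes
    expect_equal(pr$projected$chrom, g$chrom_a)
    expect_lte(pr$projected$start, g$start_a - 1L)
    expect_gte(pr$projected$end, g$end_a)
  }
})

test_that("projection is order-consistent for nested intervals", {
  cfg <- simulation_config(seed = 56)
  sim <- simulate_genome_pair(cfg)
  links <- ortholog_links(sim$hits_ab, sim$hits_ba, sim$annot_a, sim$annot_b)
  i2 <- genomic_intervals("chrB01", 151000, 190000, name = "outer")
  i1 <- genomic_intervals("chrB01", 155000, 186000, name = "inner")
  p1 <- project_interval(i1, links, side = "b")
  p2 <- project_interval(i2, links, side = "b")
  if (!is.null(p1$projected) && !is.null(p2$projected) &&
      p1$flank_left == p2$flank_left && p1$flank_right == p2$flank_right) {
    expect_gte(p1$projected$start, p2$projected$start)
    expect_lte(p1$projected$end, p2$projected$end)
  } else {
    expect_gte(p1$projected$start, p2$projected$start)
  }
})

test_that("centromere origin classes cover corresponding/de-novo/unresolved", {
  cfg <- simulation_config(seed = 57, centromere_insertions_b = 3)
  sim <- simulate_genome_pair(cfg)
  links <- ortholog_links(sim$hits_ab, sim$hits_ba, sim$annot_a, sim$annot_b)
  sb <- chain_blocks(links)

  # planted insertions are de novo
  calls <- classify_centromere_origin(sim$truth$cen_units_b,
                                      sim$truth$cen_units_a, links, sb)
  expect_equal(calls$klass, rep("de_novo_insertion", 3))

  # a genome-B unit whose projection overlaps the genome-A unit corresponds:
  # take the genome-B interval between the orthologs flanking cenA
  cen_a <- sim$truth$cen_units_a
  la <- links[links$chrom_a == cen_a$chrom, ]
  left <- la[la$end_a <= cen_a$start, ]
  right <- la[la$start_a - 1L >= cen_a$end, ]
  gl <- left[which.max(left$end_a), ]
  gr <- right[which.min(right$start_a), ]
  unit_b <- genomic_intervals(gl$chrom_b, gl$end_b, gr$start_b - 1L,
                              name = "mirror")
  got <- classify_centromere_origin(unit_b, cen_a, links, sb)
  expect_equal(got$klass, "corresponding")

  # a unit beyond the terminal link is unresolved
  last_b <- max(links$end_b[links$chrom_b == "chrB01"])
  edge <- genomic_intervals("chrB01", last_b + 1000L, last_b + 2000L,
                            name = "edge")
  got2 <- classify_centromere_origin(edge, cen_a, links, sb)
  expect_equal(got2$klass, "unresolved")
})
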