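test_that("dyad search finds palindromes and respects pairing rules", {
  d <- find_dyads("GAATTC", min_arm = 3, max_loop = 0)
  expect_equal(nrow(d), 1L)
  expect_equal(d$arm1_start, 0L)
  expect_equal(d$arm2_start, 3L)
  expect_equal(d$arm_len, 3L)
  expect_equal(d$loop_len, 0L)

  expect_equal(nrow(find_dyads("AAAAAAAA", min_arm = 2, max_loop = 4)), 0L)
  expect_equal(nrow(find_dyads("GGGNNNCCC", min_arm = 4, max_loop = 2)), 0L)
  expect_error(find_dyads("ACGT", min_arm = 1), "min_arm")
})

test_that("dyad search equals brute-force enumeration on random sequences", {
  withr::with_seed(301, {
    for (i in 1:60) {
      n <- sample(12:60, 1)
      seq <- rand_dna(n)
      mm <- sample(0:1, 1)
      got <- find_dyads(seq, min_arm = 4, max_loop = 10, max_mismatch = mm)
      want <- brute_dyads(seq, min_arm = 4, max_loop = 10, max_mismatch = mm)
      expect_equal(got, want, info = paste("seq", i, seq, "mm", mm))
    }
  })
})

test_that("hairpin scoring matches the exhaustive fold search", {
  got <- hairpin_score("GGGAAATTTCCC")
  want <- brute_hairpin("GGGAAATTTCCC")
  expect_equal(unclass(got), want)

  withr::with_seed(302, {
    for (i in 1:40) {
      seq <- rand_dna(sample(12:40, 1))
      got <- hairpin_score(seq)
      want <- brute_hairpin(seq)
      expect_equal(unclass(got), want, info = seq)
    }
  })
})

test_that("hairpin closed forms and degenerate inputs", {
  # perfect GC palindrome of 2n with loop allowed down to 0: score 3n
  expect_equal(hairpin_score("GGGGGGCCCCCC", min_loop = 0)$score, 18)
  expect_null(hairpin_score("AAAAAAAAAAAA"))
  expect_null(hairpin_score("ACGT"))     # too short
})

test_that("shared motifs: planted 9-mer, revcomp and circular search", {
  expect_equal(shared_motif("ACGTACGT", "ACGTACGT")$motifs, "ACGTACGT")

  # 60-bp and 23-bp monomers over disjoint alphabets apart from the planted
  # TTCGTACGA shared 9-mer
  withr::with_seed(303, {
    a <- paste0(paste(sample(c("A", "C"), 30, TRUE), collapse = ""),
                "TTCGTACGA",
                paste(sample(c("A", "C"), 21, TRUE), collapse = ""))
    b <- paste0(paste(sample(c("G", "T"), 7, TRUE), collapse = ""),
                "TTCGTACGA",
                paste(sample(c("G", "T"), 7, TRUE), collapse = ""))
  })
  got <- shared_motif(a, b)
  expect_equal(got$length, 9L)
  expect_true("TTCGTACGA" %in% got$motifs)

  rc <- shared_motif("ACACAC", "GTGTGT", include_revcomp = TRUE)
  expect_equal(rc$length, 6L)
  expect_true("ACACAC" %in% rc$motifs)

  # junction-spanning motif appears only in circular mode
  a2 <- "CGTAGGGGGGAT"          # doubled: ...GGATCGTAG... contains ATCGTA
  b2 <- "CCCATCGTACCC"
  lin <- shared_motif(a2, b2)
  circ <- shared_motif(a2, b2, circular = TRUE)
  expect_lt(lin$length, 6L)
  expect_gte(circ$length, 6L)
  expect_true(any(grepl("ATCGTA", circ$motifs)))
})

test_that("shared_motif is symmetric and equals the LCS oracle", {
  withr::with_seed(304, {
    for (i in 1:60) {
      a <- rand_dna(sample(10:100, 1))
      b <- rand_dna(sample(10:100, 1))
      got <- shared_motif(a, b)
      want <- lcs_oracle(a, b)
      expect_equal(got, want, info = paste(a, b))
      expect_lte(got$length, min(nchar(a), nchar(b)))
      rev <- shared_motif(b, a)
      expect_equal(rev$length, got$length)
    }
  })
})

test_that("array decomposition is exact on clean tandems", {
  withr::with_seed(305, mono <- rand_dna(60))
  arr <- strrep(mono, 10)
  prof <- decompose_array(arr, mono)
  expect_equal(prof$monomer_count, 10L)
  expect_equal(prof$coverage, 1)
  expect_true(all(prof$tiling$identity == 100))
  expect_equal(nrow(prof$orientation_runs), 1L)
  expect_equal(prof$orientation_runs$orientation, "F")
  expect_equal(prof$hor_period, 1L, ignore_attr = TRUE)
  expect_error(decompose_array(arr, "ACGT"), ">= 10 bp")
})

test_that("orientation runs follow reverse-complemented copies", {
  withr::with_seed(306, mono <- rand_dna(60))
  arr <- paste0(strrep(mono, 3), strrep(revcomp(mono), 3), strrep(mono, 4))
  prof <- decompose_array(arr, mono)
  expect_equal(prof$orientation_runs$orientation, c("F", "R", "F"))
  expect_equal(prof$orientation_runs$length, c(3L, 3L, 4L))
})

test_that("mutated arrays stay well covered at high identity", {
  withr::with_seed(307, mono <- rand_dna(60))
  sim <- simulate_satellite_array(mono, copies = 50, mutation_rate = 0.02,
                                  seed = 308)
  prof <- decompose_array(sim$sequence, mono)
  expect_gte(prof$coverage, 0.95)
  expect_gte(mean(prof$tiling$identity), 96)
  expect_lte(mean(prof$tiling$identity), 100)
})

test_that("HOR detection recovers planted periods and rejects noise", {
  withr::with_seed(309, mono <- rand_dna(60))
  sim <- simulate_satellite_array(mono, copies = 40, mutation_rate = 0.03,
                                  hor_period = 4, seed = 11)
  prof <- decompose_array(sim$sequence, mono)
  expect_equal(prof$hor_period, 4L, ignore_attr = TRUE)

  # i.i.d. divergent monomers with no cycle: none, across seeds
  for (s in 1:20) {
    withr::with_seed(400 + s, {
      mono2 <- rand_dna(60)
      monomers <- vapply(1:30, function(i) {
        chars <- strsplit(mono2, "")[[1]]
        hit <- which(runif(60) < 0.2)
        for (p in hit) chars[p] <- sample(setdiff(c("A", "C", "G", "T"),
                                                  chars[p]), 1)
        paste(chars, collapse = "")
      }, "")
    })
    expect_true(is.na(detect_hor(monomers)), info = paste("seed", s))
  }
  expect_true(is.na(detect_hor(c("ACGTACGTACGT", "ACGTACGTACGT"))))
})

test_that("reverse-complementing an array flips orientations, keeps period", {
  withr::with_seed(310, mono <- rand_dna(60))
  sim <- simulate_satellite_array(mono, copies = 24, mutation_rate = 0,
                                  hor_period = 2, flips = 1, seed = 311)
  prof <- decompose_array(sim$sequence, mono)
  prof_rc <- decompose_array(revcomp(sim$sequence), mono)
  expect_equal(prof_rc$orientation_runs$orientation,
               rev(ifelse(prof$orientation_runs$orientation == "F", "R", "F")))
  expect_equal(prof_rc$orientation_runs$length,
               rev(prof$orientation_runs$length))
  expect_equal(prof_rc$hor_period, prof$hor_period, ignore_attr = TRUE)
})
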