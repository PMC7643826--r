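test_that("seed index counts positions and finds every k-mer", {
  ix <- build_index(c(s = "ACGTACGT"), k = 4)
  expect_equal(index_n_positions(ix), 5) # L - k + 1
  expect_equal(index_n_positions(build_index(character(0), k = 13)), 0)

  set.seed(21)
  scaf <- random_seq(300)
  ix2 <- build_index(c(sc = scaf), k = 11)
  for (at in sample(300 - 10, 25)) {
    km <- substr(scaf, at, at + 10)
    hits <- index_lookup(ix2, km)
    expect_true(at %in% hits$pos) # exhaustive-scan check at sampled offsets
  }
})

test_that("verbatim substrings align at identity 100 at their true offset", {
  set.seed(22)
  scaf <- random_seq(5000)
  ix <- build_index(c(sc = scaf))
  h <- align_read(c(r = substr(scaf, 1001, 1150)), ix)
  expect_equal(h$identity, 100)
  expect_equal(h$ref_start, 1001)
  expect_equal(h$ref_end, 1150)
  expect_equal(h$strand, "+")
  expect_equal(h$aligned_read_fraction, 1)
})

test_that("identity arithmetic: 15 substitutions over 150 columns gives 90.0", {
  set.seed(23)
  scaf <- random_seq(5000)
  read <- strsplit(substr(scaf, 2001, 2150), "")[[1]]
  # cluster the substitutions in the first 45 bases so clean seeds remain
  pos <- seq(3, by = 3, length.out = 15)
  for (p in pos) read[p] <- setdiff(c("A", "C", "G", "T"), read[p])[1]
  h <- align_read(c(r = paste(read, collapse = "")), build_index(c(sc = scaf)))
  expect_equal(h$matches, 135)
  expect_equal(h$mismatches, 15)
  expect_equal(h$gap_columns, 0)
  expect_equal(h$identity, 90)
})

test_that("oracle handles the trivial strand and identity cases", {
  o <- oracle_align("AAAA", "TTTT")
  expect_equal(o$forward$identity, 0)
  expect_false(o$forward$mapped)
  expect_equal(o$reverse$identity, 100)
  expect_equal(o$best$strand, "-")

  o2 <- oracle_align("ACGTACGTAC", "ACGTACGTAC")
  expect_equal(o2$best$identity, 100)
  expect_equal(o2$best$gap_columns, 0)
  expect_equal(o2$best$score, 10)

  expect_error(oracle_align(paste(rep("A", 10001), collapse = ""), "ACGT"),
               "10 kb")
})

test_that("oracle agrees with hand-worked alignments", {
  # forward: exact 8-mer island, extending into flanking mismatches cannot
  # help; reverse complement (TTACGTACGT) matches 10 bases outright
  o <- oracle_align("ACGTACGTAA", "TTACGTACGTTT")
  expect_equal(o$forward$score, 8)
  expect_equal(o$forward$matches, 8)
  expect_equal(o$forward$mismatches, 0)
  expect_equal(o$forward$identity, 100)
  expect_equal(o$best$strand, "-")
  expect_equal(o$best$score, 10)
  # one inserted read base: 9 matches + 1 gap column, identity 90
  o2 <- oracle_align("ACGTTTACGT", "AACGTTACGTAA")
  expect_equal(o2$best$score, 9 * 1 - 2)
  expect_equal(o2$best$matches, 9)
  expect_equal(o2$best$gap_columns, 1)
  expect_equal(o2$best$identity, 90)
})

test_that("oracle scores match an independent plain-R DP on small instances", {
  set.seed(24)
  for (i in 1:25) {
    a <- random_seq(sample(8:20, 1))
    b <- random_seq(sample(10:40, 1))
    o <- oracle_align(a, b)
    expect_equal(o$forward$score, r_local_score(a, b))
    expect_equal(o$reverse$score, r_local_score(reverse_complement(a), b))
  }
})

test_that("emitted hits satisfy the identity conservation identity", {
  lake <- simulate_lake(tiny_spec(seed = 25))
  res <- recruit(lake$reads$BS$seqs, lake$assemblies$SW)
  h <- res$hits
  expect_gt(nrow(h), 0)
  cols <- h$matches + h$mismatches + h$gap_columns
  expect_equal(h$identity * cols, 100 * h$matches, tolerance = 1e-12)
  expect_true(all(h$identity >= 70 - 1e-9 & h$identity <= 100))
  expect_true(all(h$matches + h$mismatches <= nchar(lake$reads$BS$seqs[h$read_id])))
  expect_lte(nrow(h), res$total_reads)
  expect_equal(anyDuplicated(h$read_id), 0)
})

test_that("raising min_identity never increases the mapped read count", {
  lake <- simulate_lake(tiny_spec(seed = 26))
  ix <- build_index(lake$assemblies$SW)
  reads <- lake$reads$BS$seqs[1:800]
  n_prev <- Inf
  for (mi in c(70, 80, 90, 95)) {
    res <- recruit(reads, ix, recruit_params(min_identity = mi))
    expect_lte(nrow(res$hits), n_prev)
    n_prev <- nrow(res$hits)
  }
})

test_that("recruiting reverse-complemented reads flips strands only", {
  set.seed(27)
  scaf <- c(sc = random_seq(4000))
  reads <- vapply(1:30, function(i) {
    at <- sample(3850, 1)
    mutate_genome(substr(scaf, at, at + 149), 0.02)
  }, "")
  names(reads) <- sprintf("r%02d", 1:30)
  ix <- build_index(scaf)
  fwd <- recruit(reads, ix)
  rev <- recruit(setNames(reverse_complement(reads), names(reads)), ix)
  fwd_h <- fwd$hits[order(fwd$hits$read_id), ]
  rev_h <- rev$hits[order(rev$hits$read_id), ]
  expect_equal(fwd_h$read_id, rev_h$read_id)
  expect_equal(fwd_h$ref_start, rev_h$ref_start)
  expect_equal(fwd_h$identity, rev_h$identity)
  expect_true(all(fwd_h$strand != rev_h$strand))
})

test_that("reads shorter than k are unmapped but counted in the total", {
  ix <- build_index(c(sc = "ACGTACGTACGTACGTACGT"), k = 13)
  res <- recruit(c(short = "ACGTAC"), ix)
  expect_equal(nrow(res$hits), 0)
  expect_equal(res$total_reads, 1)
})

test_that("reads from the assembly map fully; unrelated reads do not", {
  set.seed(28)
  scafs <- c(a = random_seq(3000), b = random_seq(3000))
  starts <- sample(2850, 50)
  reads <- substring(scafs[sample(1:2, 50, TRUE)], starts, starts + 149)
  names(reads) <- sprintf("v%02d", 1:50)
  res <- recruit(reads, scafs, recruit_params(min_identity = 90))
  expect_equal(nrow(res$hits), 50)
  unrel <- vapply(1:50, function(i) random_seq(150), "")
  names(unrel) <- sprintf("u%02d", 1:50)
  res2 <- recruit(unrel, scafs, recruit_params(min_identity = 90))
  expect_equal(nrow(res2$hits), 0)
})

test_that("capture designs are validated inside recruit()", {
  lake <- simulate_lake(tiny_spec(seed = 29))
  expect_error(
    recruit(lake$reads$SW$seqs, lake$assemblies$TS, design = "TS->SW"),
    "capture_design")
  expect_error(capture_design(metagenome_label("L", "TS", "assembly"),
                              metagenome_label("L", "SW", "reads")),
               "downward")
})
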