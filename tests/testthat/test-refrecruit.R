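make_masked_genome <- function(seed = 61, len = 6000) {
  set.seed(seed)
  seq <- random_seq(len)
  feats <- data.frame(
    gene_id = c("cds1", "rrna1", "trna1"),
    scaffold_id = "g", start = c(101L, 2001L, 4001L),
    end = c(1000L, 3500L, 4080L), strand = "+",
    feature_class = c("CDS", "rRNA", "tRNA"),
    lineage = NA_character_, stringsAsFactors = FALSE)
  list(seq = seq, feats = feats)
}

test_that("masking replaces exactly the conserved intervals with N", {
  g <- make_masked_genome()
  mr <- mask_features("g", g$seq, g$feats)
  expect_equal(nchar(mr$sequence), nchar(g$seq)) # lengths preserved
  chars <- strsplit(mr$sequence, "")[[1]]
  masked <- c(2001:3500, 4001:4080)
  expect_true(all(chars[masked] == "N"))
  expect_true(all(chars[-masked] == strsplit(g$seq, "")[[1]][-masked]))
  expect_equal(nrow(mr$mask_intervals), 2) # CDS not masked
  # an unannotated genome is unchanged
  mr2 <- mask_features("g", g$seq, g$feats[g$feats$feature_class == "CDS", ])
  expect_equal(mr2$sequence, g$seq)
  bad <- g$feats; bad$end[2] <- 99999L
  expect_error(mask_features("g", g$seq, bad), "outside genome")
})

test_that("no read is recruited from inside a masked run", {
  g <- make_masked_genome()
  mr <- mask_features("g", g$seq, g$feats)
  # reads drawn from the masked rRNA interval of the unmasked genome
  starts <- seq(2001, 3351, by = 50)
  reads <- substring(g$seq, starts, starts + 149)
  names(reads) <- sprintf("m%03d", seq_along(starts))
  rr <- recruit_to_references(reads, list(mr))
  expect_equal(nrow(rr$result$hits), 0)
  # the same reads recruit perfectly on the unmasked genome
  res <- recruit(reads, c(g = g$seq), recruit_params(min_identity = 90))
  expect_equal(nrow(res$hits), length(reads))
})

test_that("hits partition completely across concatenated genomes", {
  set.seed(62)
  gA <- random_seq(5000); gB <- random_seq(5000)
  no_feats <- data.frame(gene_id = character(), scaffold_id = character(),
                         start = integer(), end = integer(),
                         strand = character(), feature_class = character(),
                         lineage = character(), stringsAsFactors = FALSE)
  refs <- list(mask_features("A", gA, no_feats), mask_features("B", gB, no_feats))
  startsA <- sample(4850, 40); startsB <- sample(4850, 30)
  reads <- c(substring(gA, startsA, startsA + 149),
             substring(gB, startsB, startsB + 149))
  names(reads) <- sprintf("r%03d", seq_along(reads))
  rr <- recruit_to_references(reads, refs)
  expect_equal(nrow(rr$result$hits), 70)
  expect_equal(sum(rr$per_genome$mapped_reads), nrow(rr$result$hits))
  expect_equal(rr$per_genome$mapped_reads, c(40L, 30L))
  # masking/concatenation leaves genome-local coordinates intact
  h <- rr$result$hits
  hA <- h[h$genome_id == "A", ]
  expect_setequal(hA$genome_start, startsA)
  expect_equal(rr$per_genome$mapped_fraction, c(40, 30) / 70)
})

test_that("divergent reads recruit permissively but not at 90%", {
  set.seed(63)
  g <- random_seq(8000)
  no_feats <- data.frame(gene_id = character(), scaffold_id = character(),
                         start = integer(), end = integer(),
                         strand = character(), feature_class = character(),
                         lineage = character(), stringsAsFactors = FALSE)
  ref <- mask_features("G", g, no_feats)
  close_src <- mutate_genome(g, 0.02)
  far_src <- mutate_genome(g, 0.25)
  st <- sample(7800, 60)
  close_reads <- substring(close_src, st, st + 149)
  names(close_reads) <- sprintf("c%03d", seq_along(st))
  far_reads <- substring(far_src, st, st + 149)
  names(far_reads) <- sprintf("f%03d", seq_along(st))
  rc <- recruit_to_references(close_reads, list(ref))
  rf <- recruit_to_references(far_reads, list(ref))
  expect_gt(rc$per_genome$mapped_fraction_ge90, 0.9) # identity mode ~98
  expect_equal(rf$per_genome$mapped_fraction_ge90, 0)
  expect_gt(rf$per_genome$mapped_fraction, 0.5) # visible cloud below 90
  expect_lt(mean(rf$result$hits$identity), 90)
  # empty read set -> empty profiles
  r0 <- recruit_to_references(character(0), list(ref))
  expect_equal(r0$per_genome$mapped_reads, 0L)
})

test_that("windowed profiles match brute-force per-window aggregation", {
  set.seed(64)
  g <- random_seq(5000)
  no_feats <- data.frame(gene_id = character(), scaffold_id = character(),
                         start = integer(), end = integer(),
                         strand = character(), feature_class = character(),
                         lineage = character(), stringsAsFactors = FALSE)
  ref <- mask_features("G", g, no_feats)
  src <- mutate_genome(g, 0.05)
  st <- sample(4850, 120, replace = TRUE)
  reads <- substring(src, st, st + 149)
  names(reads) <- sprintf("r%03d", seq_along(st))
  rr <- recruit_to_references(reads, list(ref))
  prof <- recruitment_profile(rr, "G", window = 1000)
  expect_equal(prof$window_start, seq(1L, 5000L, by = 1000L))
  h <- rr$result$hits
  for (i in seq_len(nrow(prof))) {
    ws <- prof$window_start[i]
    inw <- h$genome_start >= ws & h$genome_start < ws + 1000
    expect_equal(prof$read_count[i], sum(inw))
    if (sum(inw) > 0)
      expect_equal(prof$mean_identity[i], mean(h$identity[inw]))
    else
      expect_true(is.na(prof$mean_identity[i]))
  }
  expect_equal(sum(prof$read_count), nrow(h))
  expect_error(recruitment_profile(rr, "G", window = 0), "positive")
  expect_error(recruitment_profile(rr, "nope"), "unknown genome")
})

test_that("uniform perfect coverage gives all-100 window means", {
  set.seed(65)
  g <- random_seq(3000)
  no_feats <- data.frame(gene_id = character(), scaffold_id = character(),
                         start = integer(), end = integer(),
                         strand = character(), feature_class = character(),
                         lineage = character(), stringsAsFactors = FALSE)
  ref <- mask_features("G", g, no_feats)
  st <- seq(1, 2851, by = 50)
  reads <- substring(g, st, st + 149)
  names(reads) <- sprintf("r%03d", seq_along(st))
  rr <- recruit_to_references(reads, list(ref))
  prof <- recruitment_profile(rr, "G", window = 500)
  expect_true(all(prof$read_count > 0))
  expect_equal(prof$mean_identity, rep(100, nrow(prof)))
})
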