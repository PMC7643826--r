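test_that("simulation is fully deterministic under a fixed seed", {
  a <- simulate_lake(tiny_spec(seed = 71))
  b <- simulate_lake(tiny_spec(seed = 71))
  expect_identical(lapply(a$genomes, `[[`, "sequence"),
                   lapply(b$genomes, `[[`, "sequence"))
  expect_identical(a$reads$BS$seqs, b$reads$BS$seqs)
  expect_identical(a$reads$BS$truth, b$reads$BS$truth)
  expect_identical(a$assemblies$SW$genes, b$assemblies$SW$genes)
  c <- simulate_lake(tiny_spec(seed = 72))
  expect_false(identical(a$reads$BS$seqs, c$reads$BS$seqs))
  expect_error(simulation_spec(), "seed")
})

test_that("the genome sets have the requested structure", {
  spec <- tiny_spec(seed = 73)
  lake <- simulate_lake(spec)
  roles <- vapply(lake$genomes, `[[`, character(1), "role")
  expect_equal(sum(roles == "water"), spec$n_water_taxa)
  expect_equal(sum(roles == "water_close"), spec$n_water_taxa)
  expect_equal(sum(roles == "distant"), spec$n_distant_taxa)
  expect_equal(sum(roles == "sediment"), spec$n_sediment_taxa)
  lins <- vapply(lake$genomes[roles == "water"], `[[`, character(1), "lineage")
  expect_equal(anyDuplicated(lins), 0) # distinct lineages
  # every truth label references an existing genome
  for (cmp in c("SW", "TS", "BS"))
    expect_true(all(lake$reads[[cmp]]$truth$source_genome %in% names(lake$genomes)))
  # decoys are annotated as rRNA in the assemblies
  expect_gt(sum(lake$assemblies$SW$genes$feature_class == "rRNA"), 0)
})

test_that("mutate_genome hits the requested divergence", {
  set.seed(74)
  g <- random_seq(100000)
  m <- mutate_genome(g, 0.03)
  expect_equal(nchar(m), nchar(g))
  frac <- mean(strsplit(g, "")[[1]] != strsplit(m, "")[[1]])
  expect_equal(frac, 0.03, tolerance = 0.002 / 0.03)
  expect_identical(mutate_genome(g, 0), g)
  # indels change length slightly when enabled
  mi <- mutate_genome(substr(g, 1, 20000), 0.1, indels = TRUE)
  expect_false(nchar(mi) == 0)
})

test_that("read shares track abundances within binomial error", {
  set.seed(75)
  spec <- tiny_spec(seed = 75)
  genomes <- setNames(vapply(1:3, function(i) random_seq(10000), ""),
                      c("gA", "gB", "gC"))
  ab <- c(0.6, 0.3, 0.1)
  rs <- simulate_reads(genomes, ab, 5000, spec, tier = "water_close")
  share <- table(rs$truth$source_genome)[names(genomes)] / 5000
  for (i in 1:3) {
    se <- sqrt(ab[i] * (1 - ab[i]) / 5000)
    expect_lt(abs(share[[i]] - ab[i]), 3 * se + 1e-9)
  }
  expect_equal(length(rs$seqs), 5000)
  expect_equal(rs$truth$tier, rep("water_close", 5000))
  r0 <- simulate_reads(genomes, ab, 0, spec, tier = "water_close")
  expect_length(r0$seqs, 0)
})

test_that("historical fragments follow the log-normal truncation model", {
  set.seed(76)
  spec <- tiny_spec(seed = 76)
  g <- setNames(random_seq(20000), "g1")
  rs <- simulate_reads(g, 1, 4000, spec, tier = "historical")
  L <- nchar(rs$seqs)
  expect_true(all(L <= spec$read_length))
  expect_equal(L, rs$truth$length, ignore_attr = TRUE)
  # expected mean of min(read_length, round(lognormal))
  sim <- pmax(30, round(rlnorm(2e5, spec$fragment_meanlog, spec$fragment_sdlog)))
  expected <- mean(pmin(spec$read_length, sim))
  expect_equal(mean(L), expected, tolerance = 3 * sd(L) / sqrt(4000) / expected)
  # regular tiers keep full read length
  rs2 <- simulate_reads(g, 1, 500, spec, tier = "sediment_indigenous")
  expect_true(all(nchar(rs2$seqs) == spec$read_length))
})

test_that("the sediment identity histogram is bimodal with a valley in [85,95]", {
  lake <- simulate_lake(tiny_spec(seed = 77, historical_fraction = 0.05,
                                  n_reads = c(SW = 200, TS = 200, BS = 6000)))
  res <- recruit(lake$reads$BS$seqs, lake$assemblies$SW)
  h <- identity_histogram(res)
  thr <- derive_threshold(h)
  expect_false(attr(thr, "fallback"))
  expect_gte(as.numeric(thr), 85)
  expect_lte(as.numeric(thr), 95)
})

test_that("truth_capture_fraction matches its closed forms at the extremes", {
  lake <- simulate_lake(tiny_spec(seed = 78, historical_fraction = 0.02))
  # threshold 0: every read with an alignable source counts fully
  t0 <- truth_capture_fraction(lake, "SW->BS", 0)
  truth <- lake$reads$BS$truth
  alignable <- mean(truth$tier %in% c("historical", "water_distant"))
  expect_equal(t0, alignable, tolerance = 1e-12)
  # threshold 100 with nonzero error: only error-free close-tier reads
  spec0 <- tiny_spec(seed = 78, historical_fraction = 1, close_divergence = 0,
                     n_reads = c(SW = 100, TS = 100, BS = 500))
  lake0 <- simulate_lake(spec0)
  t100 <- truth_capture_fraction(lake0, "SW->BS", 100)
  L <- lake0$reads$BS$truth$length
  expect_equal(t100, mean((1 - spec0$read_error_rate)^L), tolerance = 1e-9)
  expect_error(truth_capture_fraction(lake, "TS->SW", 90), "invalid")
})

test_that("capture percent tracks the truth oracle on a small lake", {
  spec <- tiny_spec(seed = 79, historical_fraction = 0.03, decoy_count = 0,
                    n_reads = c(SW = 200, TS = 200, BS = 5000))
  lake <- simulate_lake(spec)
  res <- recruit(lake$reads$BS$seqs, lake$assemblies$SW)
  cap <- apply_capture(res, lake$assemblies$SW, 90)
  p <- truth_capture_fraction(lake, "SW->BS", 90)
  obs <- cap$mapped_count / cap$unassembled_count
  se <- sqrt(p * (1 - p) / cap$unassembled_count)
  expect_lt(abs(obs - p), 3 * se + 1e-12)
})

test_that("simulated lakes serialize to standard formats and back", {
  lake <- simulate_lake(tiny_spec(seed = 80,
                                  n_reads = c(SW = 50, TS = 50, BS = 100)))
  dir <- tempfile()
  write_simulated_lake(lake, dir)
  reads <- read_fasta(file.path(dir, "BS_reads.fasta"))
  expect_equal(as.character(reads), lake$reads$BS$seqs, ignore_attr = TRUE)
  asm <- read_fasta(file.path(dir, "SW_assembly.fasta"))
  expect_equal(length(asm), length(lake$assemblies$SW$scaffolds))
  genes <- read_annotations(file.path(dir, "SW_assembly.gff3"),
                            file.path(dir, "SW_taxonomy.tsv"),
                            scaffolds = asm)
  g0 <- lake$assemblies$SW$genes
  rownames(g0) <- NULL
  genes <- genes[order(match(genes$gene_id, g0$gene_id)), ]
  rownames(genes) <- NULL
  expect_equal(genes[, names(g0)], g0)
})
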