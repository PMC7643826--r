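# Shared fixtures, all generated in code.

# desk-scale simulation spec for unit tests (small read counts)
tiny_spec <- function(seed = 101, ...) {
  args <- list(n_water_taxa = 4, n_sediment_taxa = 4, n_distant_taxa = 2,
               n_deep_taxa = 2, genome_length = 20000, scaffold_length = 5000,
               n_reads = c(SW = 500, TS = 500, BS = 2000), seed = seed)
  args[names(list(...))] <- list(...)
  do.call(simulation_spec, args)
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

# small annotated assembly built by hand
toy_assembly <- function() {
  set.seed(9)
  seqs <- c(sc1 = random_seq(1000), sc2 = random_seq(1000), sc3 = random_seq(800))
  genes <- data.frame(
    gene_id = c("g1", "g2", "g3", "g4"),
    scaffold_id = c("sc1", "sc2", "sc2", "sc3"),
    start = c(101L, 1L, 501L, 11L),
    end = c(700L, 400L, 900L, 300L),
    strand = c("+", "-", "+", "+"),
    feature_class = c("CDS", "CDS", "tRNA", "CDS"),
    lineage = c("Bacteria;Cyanobacteria;Cyanophyceae;Synechococcales;f1;g1;s1",
                "Bacteria;Proteobacteria;Betaproteobacteria;Burkholderiales;f2;g2;s2",
                NA,
                "Archaea;Euryarchaeota;Methanomicrobia;Methanomicrobiales;f3;g3;s3"),
    stringsAsFactors = FALSE)
  lake_assembly(metagenome_label("TestLake", "SW", "assembly"), seqs, genes)
}

# plain-R affine local alignment score (independent mini-oracle for scores)
r_local_score <- function(a, b, ma = 1, mi = -1, go = -2, ge = -1) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  m <- length(a); n <- length(b); NEG <- -1e9
  H <- matrix(0, m + 1, n + 1); E <- matrix(NEG, m + 1, n + 1)
  F <- matrix(NEG, m + 1, n + 1); best <- 0
  for (i in 2:(m + 1)) for (j in 2:(n + 1)) {
    E[i, j] <- max(H[i, j - 1] + go, E[i, j - 1] + ge)
    F[i, j] <- max(H[i - 1, j] + go, F[i - 1, j] + ge)
    s <- if (a[i - 1] == b[j - 1] && a[i - 1] %in% c("A", "C", "G", "T")) ma else mi
    H[i, j] <- max(0, H[i - 1, j - 1] + s, E[i, j], F[i, j])
    best <- max(best, H[i, j])
  }
  best
}
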