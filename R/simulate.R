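# Synthetic lake-system generator. Emulates the statistical structure the
# capture method assumes: a water-column community (the SW assembly and
# reads), a taxonomically distinct indigenous sediment community (TS
# assembly; TS/BS reads), a small "historical" fraction of sediment reads
# drawn from close relatives (~3% divergence) of the water genomes, distantly
# related (~25%) background lineages that create the low-identity mode of
# permissive recruitment, and conserved rRNA-like decoy genes shared at high
# identity across distant genomes. Every read carries a truth label.

.TIERS <- c("water_close", "water_distant", "sediment_indigenous", "historical")
.BASES <- c("A", "C", "G", "T")

#' Specify a synthetic lake system
#'
#' Defaults describe a desk-scale lake: communities of 8 water and 8 shared
#' sediment genomes (40 kb each, presented as 5 kb scaffolds), log-normal
#' abundances, 150-base reads with a 0.2% substitution error rate, close
#' relatives at 3% divergence, background lineages at 25%, two conserved
#' decoy copies per compartment class at 99% identity, and a 0.5% historical
#' read fraction in bottom sediments.
#'
#' @param n_water_taxa,n_sediment_taxa,n_distant_taxa,n_deep_taxa Community
#'   sizes: water-column genomes, shared sediment genomes (the TS assembly),
#'   distant background lineages, and bottom-only deep genomes.
#' @param abundance_meanlog,abundance_sdlog Log-normal abundance model.
#' @param genome_length,scaffold_length Genome size and the scaffold size
#'   genomes are split into when presented as assemblies.
#' @param gene_length_mean,gene_length_sd,gene_gap_mean CDS planting model:
#'   genes of normal-distributed length tile each scaffold with geometric
#'   gaps.
#' @param close_divergence Per-site substitution rate separating historical
#'   read sources from the water-column genomes (recoverable at >= 90\%
#'   identity).
#' @param distant_divergence Rate for background lineages (< 90\% identity).
#' @param decoy_count Number of genomes per class (water / shared sediment /
#'   distant) carrying a conserved decoy gene; 0 disables decoys.
#' @param decoy_identity,decoy_length Identity of planted decoy copies to the
#'   decoy master sequence, and decoy gene length.
#' @param historical_fraction Fraction of bottom-sediment reads drawn from
#'   close relatives of water genomes.
#' @param ts_historical_fraction Same for top sediments (intermediate
#'   mixture).
#' @param distant_read_fraction Fraction of non-historical sediment reads
#'   drawn from the distant background lineages.
#' @param bs_shared_fraction Fraction of bottom-sediment indigenous reads
#'   drawn from the shared (TS-assembly) genomes rather than deep genomes.
#' @param read_length,read_error_rate Read model (substitution errors only).
#' @param fragment_meanlog,fragment_sdlog Log-normal fragment-length model
#'   for historical reads (degraded DNA); reads are truncated to the
#'   fragment when it is shorter than `read_length`.
#' @param n_reads Named vector of read counts per compartment (SW, TS, BS).
#' @param seed Mandatory integer seed; the whole simulation is reproducible
#'   from it.
#' @return Object of class `simulation_spec`.
#' @export
simulation_spec <- function(n_water_taxa = 8, n_sediment_taxa = 8,
                            n_distant_taxa = 4, n_deep_taxa = 6,
                            abundance_meanlog = 0, abundance_sdlog = 1,
                            genome_length = 40000, scaffold_length = 5000,
                            gene_length_mean = 900, gene_length_sd = 150,
                            gene_gap_mean = 120,
                            close_divergence = 0.03, distant_divergence = 0.25,
                            decoy_count = 2, decoy_identity = 0.99,
                            decoy_length = 1500,
                            historical_fraction = 0.005,
                            ts_historical_fraction = 0.01,
                            distant_read_fraction = 0.2,
                            bs_shared_fraction = 0.25,
                            read_length = 150, read_error_rate = 0.002,
                            fragment_meanlog = log(120), fragment_sdlog = 0.25,
                            n_reads = c(SW = 20000, TS = 20000, BS = 50000),
                            seed = NULL) {
  if (is.null(seed)) stop("a seed is mandatory for reproducibility")
  rates <- c(close_divergence, distant_divergence, read_error_rate,
             historical_fraction, ts_historical_fraction,
             distant_read_fraction, bs_shared_fraction)
  stopifnot(all(rates >= 0 & rates <= 1), decoy_identity > 0, decoy_identity <= 1,
            n_water_taxa >= 1, n_sediment_taxa >= 1,
            genome_length >= 2 * gene_length_mean,
            scaffold_length >= 2 * gene_length_mean,
            decoy_count <= min(n_water_taxa, n_sediment_taxa),
            read_length >= 30, all(c("SW", "TS", "BS") %in% names(n_reads)))
  if (decoy_count > 0 && n_distant_taxa > 0 && decoy_count > n_distant_taxa)
    stop("decoy_count exceeds n_distant_taxa")
  spec <- as.list(environment())
  structure(spec, class = "simulation_spec")
}

random_dna <- function(n) paste(sample(.BASES, n, replace = TRUE), collapse = "")

#' Mutate a genome by per-site substitution
#'
#' Each unambiguous site is substituted with probability `divergence`,
#' always to a different base. With `indels = TRUE`, insertions and
#' deletions are additionally applied, each at 5% of the substitution rate
#' (10% combined).
#'
#' @param sequence A single DNA string.
#' @param divergence Per-site substitution probability in `[0, 1)`.
#' @param indels Enable indels.
#' @return The mutated sequence (character).
#' @export
mutate_genome <- function(sequence, divergence, indels = FALSE) {
  stopifnot(divergence >= 0, divergence < 1)
  if (divergence == 0 && !indels) return(sequence)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  code <- match(chars, .BASES)
  ok <- !is.na(code)
  hit <- ok & stats::runif(length(chars)) < divergence
  if (any(hit)) {
    shift <- sample.int(3, sum(hit), replace = TRUE)
    code[hit] <- ((code[hit] - 1 + shift) %% 4) + 1
    chars[hit] <- .BASES[code[hit]]
  }
  if (indels) {
    rate <- divergence * 0.05
    del <- stats::runif(length(chars)) < rate
    ins <- stats::runif(length(chars)) < rate
    out <- chars
    out[del] <- ""
    if (any(ins))
      out[ins] <- paste0(out[ins], sample(.BASES, sum(ins), replace = TRUE))
    chars <- out
  }
  paste(chars, collapse = "")
}

# substitution errors over a vector of reads (vectorized)
apply_read_errors <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0) return(seqs)
  lens <- nchar(seqs)
  all <- strsplit(paste(seqs, collapse = ""), "", fixed = TRUE)[[1]]
  code <- match(all, .BASES)
  hit <- which(!is.na(code) & stats::runif(length(all)) < rate)
  if (length(hit)) {
    shift <- sample.int(3, length(hit), replace = TRUE)
    all[hit] <- .BASES[((code[hit] - 1 + shift) %% 4) + 1]
  }
  grp <- rep.int(seq_along(seqs), lens)
  out <- vapply(split(all, grp), paste, character(1), collapse = "")
  names(out) <- NULL
  out
}

# synthetic but ecologically structured lineages; orders nest in phyla
make_lineage <- function(domain, phylum, class, order, genus_id) {
  paste(domain, phylum, class, order, paste0("f_", order),
        paste0("g_", genus_id), paste0("s_", genus_id), sep = ";")
}

water_lineage_pool <- function() {
  list(
    list(domain = "Bacteria", phylum = "Cyanobacteria", class = "Cyanophyceae",
         order = "Synechococcales"),
    list(domain = "Bacteria", phylum = "Actinobacteria", class = "Actinomycetia",
         order = "Nanopelagicales"),
    list(domain = "Bacteria", phylum = "Proteobacteria", class = "Betaproteobacteria",
         order = "Burkholderiales"),
    list(domain = "Bacteria", phylum = "Proteobacteria", class = "Alphaproteobacteria",
         order = "Pelagibacterales"),
    list(domain = "Bacteria", phylum = "Bacteroidetes", class = "Flavobacteriia",
         order = "Flavobacteriales"),
    list(domain = "Viruses", phylum = "Uroviricota", class = "Caudoviricetes",
         order = "Caudovirales"))
}

sediment_lineage_pool <- function() {
  list(
    list(domain = "Archaea", phylum = "Euryarchaeota", class = "Methanomicrobia",
         order = "Methanomicrobiales"),
    list(domain = "Bacteria", phylum = "Proteobacteria", class = "Deltaproteobacteria",
         order = "Syntrophobacterales"),
    list(domain = "Bacteria", phylum = "Proteobacteria", class = "Deltaproteobacteria",
         order = "Desulfobacterales"),
    list(domain = "Bacteria", phylum = "Firmicutes", class = "Clostridia",
         order = "Clostridiales"),
    list(domain = "Bacteria", phylum = "Chloroflexi", class = "Anaerolineae",
         order = "Anaerolineales"))
}

#' Simulate the genome sets of a lake system
#'
#' Generates random water-column genomes with distinct lineages, their close
#' relatives (historical read sources), distant background lineages derived
#' from water genomes at `distant_divergence`, shared sediment genomes and
#' bottom-only deep genomes, and plants conserved decoy copies.
#'
#' @param spec A [simulation_spec()]. The caller controls the RNG state
#'   ([simulate_lake()] seeds it from `spec$seed`).
#' @return List of genome records (`genome_id`, `sequence`, `lineage`,
#'   `role`, `decoy` interval or NULL), plus the decoy master sequence as
#'   attribute `decoy_master`.
#' @export
simulate_genomes <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  wpool <- water_lineage_pool(); spool <- sediment_lineage_pool()
  genomes <- list()
  add <- function(id, seq, lin, role, src = NA_character_) {
    genomes[[id]] <<- list(genome_id = id, sequence = seq, lineage = lin,
                           role = role, source = src, decoy = NULL)
  }
  for (i in seq_len(spec$n_water_taxa)) {
    p <- wpool[[(i - 1) %% length(wpool) + 1]]
    add(sprintf("W%02d", i), random_dna(spec$genome_length),
        make_lineage(p$domain, p$phylum, p$class, p$order, sprintf("W%02d", i)),
        "water")
  }
  for (i in seq_len(spec$n_water_taxa)) {
    wid <- sprintf("W%02d", i)
    add(sprintf("WC%02d", i),
        mutate_genome(genomes[[wid]]$sequence, spec$close_divergence),
        genomes[[wid]]$lineage, "water_close", wid)
  }
  if (spec$n_distant_taxa > 0) {
    src <- sample(spec$n_water_taxa, spec$n_distant_taxa, replace = TRUE)
    for (i in seq_len(spec$n_distant_taxa)) {
      wid <- sprintf("W%02d", src[i])
      p <- wpool[[(src[i] - 1) %% length(wpool) + 1]]
      add(sprintf("D%02d", i),
          mutate_genome(genomes[[wid]]$sequence, spec$distant_divergence),
          make_lineage(p$domain, p$phylum, p$class,
                       paste0(p$order, "_rel"), sprintf("D%02d", i)),
          "distant", wid)
    }
  }
  for (i in seq_len(spec$n_sediment_taxa)) {
    p <- spool[[(i - 1) %% length(spool) + 1]]
    add(sprintf("S%02d", i), random_dna(spec$genome_length),
        make_lineage(p$domain, p$phylum, p$class, p$order, sprintf("S%02d", i)),
        "sediment")
  }
  for (i in seq_len(spec$n_deep_taxa)) {
    p <- spool[[(i - 1) %% length(spool) + 1]]
    add(sprintf("B%02d", i), random_dna(spec$genome_length),
        make_lineage(p$domain, p$phylum, p$class, p$order, sprintf("B%02d", i)),
        "deep")
  }
  # conserved decoys: one copy in the first `decoy_count` genomes of each
  # class, at decoy_identity to a common master sequence
  decoy_master <- NULL
  if (spec$decoy_count > 0) {
    decoy_master <- random_dna(spec$decoy_length)
    plant <- function(id) {
      g <- genomes[[id]]
      at <- sample.int(nchar(g$sequence) - spec$decoy_length, 1)
      copy <- mutate_genome(decoy_master, 1 - spec$decoy_identity)
      g$sequence <- paste0(substr(g$sequence, 1, at - 1), copy,
                           substr(g$sequence, at + spec$decoy_length,
                                  nchar(g$sequence)))
      g$decoy <- c(start = at, end = at + spec$decoy_length - 1)
      genomes[[id]] <<- g
    }
    for (i in seq_len(spec$decoy_count)) plant(sprintf("W%02d", i))
    for (i in seq_len(spec$decoy_count)) plant(sprintf("S%02d", i))
    for (i in seq_len(min(spec$decoy_count, spec$n_distant_taxa)))
      plant(sprintf("D%02d", i))
  }
  structure(genomes, decoy_master = decoy_master)
}

# split a genome into scaffolds and plant CDS genes (plus its decoy as rRNA)
genome_to_scaffolds <- function(g, spec) {
  len <- nchar(g$sequence)
  starts <- seq(1, len, by = spec$scaffold_length)
  ends <- pmin(starts + spec$scaffold_length - 1, len)
  # drop a trailing stub too short to carry genes
  if (length(starts) > 1 && ends[length(ends)] - starts[length(starts)] + 1 <
      spec$gene_length_mean) {
    ends[length(ends) - 1] <- ends[length(ends)]
    starts <- starts[-length(starts)]; ends <- ends[-length(ends)]
  }
  ids <- sprintf("%s_s%02d", g$genome_id, seq_along(starts))
  seqs <- substring(g$sequence, starts, ends)
  names(seqs) <- ids
  genes <- list()
  for (i in seq_along(ids)) {
    slen <- ends[i] - starts[i] + 1
    pos <- 1 + sample.int(spec$gene_gap_mean, 1)
    j <- 0
    while (TRUE) {
      glen <- round(stats::rnorm(1, spec$gene_length_mean, spec$gene_length_sd))
      glen <- max(spec$gene_length_mean %/% 3, min(glen, 2 * spec$gene_length_mean))
      if (pos + glen - 1 > slen) break
      j <- j + 1
      genes[[length(genes) + 1]] <- data.frame(
        gene_id = sprintf("%s_g%02d", ids[i], j), scaffold_id = ids[i],
        start = pos, end = pos + glen - 1,
        strand = sample(c("+", "-"), 1), feature_class = "CDS",
        lineage = g$lineage, stringsAsFactors = FALSE)
      pos <- pos + glen + sample.int(2 * spec$gene_gap_mean, 1)
    }
  }
  genes <- if (length(genes)) do.call(rbind, genes) else
    data.frame(gene_id = character(), scaffold_id = character(),
               start = integer(), end = integer(), strand = character(),
               feature_class = character(), lineage = character(),
               stringsAsFactors = FALSE)
  if (!is.null(g$decoy)) {
    si <- findInterval(g$decoy[["start"]], starts)
    ds <- g$decoy[["start"]] - starts[si] + 1
    de <- min(g$decoy[["end"]] - starts[si] + 1, ends[si] - starts[si] + 1)
    # overwrite CDS genes overlapping the decoy interval on that scaffold
    drop <- genes$scaffold_id == ids[si] & genes$end >= ds & genes$start <= de
    genes <- genes[!drop, , drop = FALSE]
    genes <- rbind(genes, data.frame(
      gene_id = paste0(ids[si], "_rrna"), scaffold_id = ids[si],
      start = ds, end = de, strand = "+", feature_class = "rRNA",
      lineage = NA_character_, stringsAsFactors = FALSE))
  }
  list(seqs = seqs, genes = genes)
}

build_sim_assembly <- function(genomes, ids, label, spec) {
  parts <- lapply(ids, function(id) genome_to_scaffolds(genomes[[id]], spec))
  seqs <- unlist(lapply(parts, `[[`, "seqs"))
  genes <- do.call(rbind, lapply(parts, `[[`, "genes"))
  scaffold_genome <- rep(ids, vapply(parts, function(p) length(p$seqs), integer(1)))
  asm <- lake_assembly(label, seqs, genes)
  attr(asm, "scaffold_genome") <- stats::setNames(scaffold_genome, names(seqs))
  asm
}

#' Draw reads from a genome set
#'
#' Source genomes are drawn multinomially by abundance, start positions
#' uniformly, strands equiprobably; substitution errors are applied at the
#' spec's error rate. Historical-tier reads are truncated to a log-normal
#' fragment length when the fragment is shorter than the read length.
#'
#' @param genomes Named character vector of genome sequences.
#' @param abundances Abundance vector (same order), summing to 1.
#' @param n Number of reads.
#' @param spec A [simulation_spec()].
#' @param tier Truth tier recorded for these reads.
#' @param id_prefix Read-id prefix.
#' @return List with `seqs` (named character) and `truth` (data frame:
#'   `read_id`, `source_genome`, `tier`, `start`, `strand`, `length`).
#' @export
simulate_reads <- function(genomes, abundances, n, spec, tier,
                           id_prefix = tier) {
  stopifnot(inherits(spec, "simulation_spec"), tier %in% .TIERS,
            length(genomes) == length(abundances))
  if (n == 0) {
    return(list(seqs = character(0),
                truth = data.frame(read_id = character(), source_genome = character(),
                                   tier = character(), start = integer(),
                                   strand = character(), length = integer(),
                                   stringsAsFactors = FALSE)))
  }
  abundances <- abundances / sum(abundances)
  counts <- as.integer(stats::rmultinom(1, n, abundances))
  src <- rep(names(genomes), counts)
  src <- sample(src) # interleave
  L <- rep.int(spec$read_length, n)
  if (tier == "historical") {
    frag <- pmax(30L, as.integer(round(stats::rlnorm(n, spec$fragment_meanlog,
                                                     spec$fragment_sdlog))))
    L <- pmin(L, frag)
  }
  glen <- nchar(genomes)[src]
  L <- pmin(L, glen)
  start <- 1L + as.integer(floor(stats::runif(n) * (glen - L + 1)))
  seqs <- substring(genomes[src], start, start + L - 1L)
  seqs <- apply_read_errors(seqs, spec$read_error_rate)
  rc <- stats::runif(n) < 0.5
  if (any(rc)) seqs[rc] <- reverse_complement(seqs[rc])
  ids <- sprintf("%s_%06d", id_prefix, seq_len(n))
  names(seqs) <- ids
  list(seqs = seqs,
       truth = data.frame(read_id = ids, source_genome = src, tier = tier,
                          start = start, strand = ifelse(rc, "-", "+"),
                          length = L, stringsAsFactors = FALSE))
}

lognormal_abundances <- function(k, spec) {
  a <- stats::rlnorm(k, spec$abundance_meanlog, spec$abundance_sdlog)
  a / sum(a)
}

#' Simulate a complete lake system with ground truth
#'
#' Builds the genome sets, presents the water and top-sediment communities
#' as annotated assemblies, and draws reads for all three compartments:
#' surface water (SW) reads from the water genomes; top sediment (TS) and
#' bottom sediment (BS) reads as mixtures of historical (close relatives of
#' water genomes, fragment-length model), indigenous sediment and distant
#' background tiers. All randomness derives from `spec$seed`.
#'
#' @param spec A [simulation_spec()].
#' @return Object of class `simulated_lake`: `spec`, `genomes`, `assemblies`
#'   (`SW`, `TS` as `lake_assembly`), `reads` (per compartment: `seqs`,
#'   `truth`), `abundances` (per community).
#' @export
simulate_lake <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  genomes <- simulate_genomes(spec)
  roles <- vapply(genomes, `[[`, character(1), "role")
  seq_of <- function(ids) stats::setNames(
    vapply(genomes[ids], `[[`, character(1), "sequence"), ids)
  water_ids <- names(roles)[roles == "water"]
  close_ids <- names(roles)[roles == "water_close"]
  distant_ids <- names(roles)[roles == "distant"]
  shared_ids <- names(roles)[roles == "sediment"]
  deep_ids <- names(roles)[roles == "deep"]

  ab <- list(water = lognormal_abundances(length(water_ids), spec),
             distant = if (length(distant_ids))
               lognormal_abundances(length(distant_ids), spec) else numeric(0),
             shared = lognormal_abundances(length(shared_ids), spec),
             deep = if (length(deep_ids))
               lognormal_abundances(length(deep_ids), spec) else numeric(0))
  names(ab$water) <- water_ids; names(ab$distant) <- distant_ids
  names(ab$shared) <- shared_ids; names(ab$deep) <- deep_ids

  lake <- "SimLake"
  asm_sw <- build_sim_assembly(genomes, water_ids,
                               metagenome_label(lake, "SW", "assembly"), spec)
  asm_ts <- build_sim_assembly(genomes, shared_ids,
                               metagenome_label(lake, "TS", "assembly"), spec)

  mix_sediment <- function(n, hist_frac, compartment) {
    dist_frac <- if (length(distant_ids)) spec$distant_read_fraction else 0
    shares <- c(historical = hist_frac,
                distant = (1 - hist_frac) * dist_frac,
                shared = (1 - hist_frac) * (1 - dist_frac) *
                  (if (compartment == "BS") spec$bs_shared_fraction else 1),
                deep = if (compartment == "BS")
                  (1 - hist_frac) * (1 - dist_frac) * (1 - spec$bs_shared_fraction)
                else 0)
    counts <- as.integer(stats::rmultinom(1, n, shares))
    names(counts) <- names(shares)
    parts <- list()
    if (counts[["historical"]] > 0)
      parts$h <- simulate_reads(seq_of(close_ids), ab$water, counts[["historical"]],
                                spec, "historical",
                                paste0(compartment, "_hist"))
    if (counts[["distant"]] > 0)
      parts$d <- simulate_reads(seq_of(distant_ids), ab$distant, counts[["distant"]],
                                spec, "water_distant",
                                paste0(compartment, "_dist"))
    if (counts[["shared"]] > 0)
      parts$s <- simulate_reads(seq_of(shared_ids), ab$shared, counts[["shared"]],
                                spec, "sediment_indigenous",
                                paste0(compartment, "_sed"))
    if (counts[["deep"]] > 0)
      parts$b <- simulate_reads(seq_of(deep_ids), ab$deep, counts[["deep"]],
                                spec, "sediment_indigenous",
                                paste0(compartment, "_deep"))
    list(seqs = do.call(c, lapply(parts, `[[`, "seqs")),
         truth = do.call(rbind, c(lapply(parts, `[[`, "truth"),
                                  list(make.row.names = FALSE))))
  }

  reads <- list(
    SW = simulate_reads(seq_of(water_ids), ab$water, spec$n_reads[["SW"]],
                        spec, "water_close", "SW"),
    TS = mix_sediment(spec$n_reads[["TS"]], spec$ts_historical_fraction, "TS"),
    BS = mix_sediment(spec$n_reads[["BS"]], spec$historical_fraction, "BS"))

  structure(list(spec = spec, genomes = genomes,
                 assemblies = list(SW = asm_sw, TS = asm_ts),
                 reads = reads, abundances = ab, lake = lake),
            class = "simulated_lake")
}

#' @export
print.simulated_lake <- function(x, ...) {
  cat(sprintf("<simulated_lake: %d water + %d sediment genomes; reads SW=%d TS=%d BS=%d>\n",
              x$spec$n_water_taxa, x$spec$n_sediment_taxa,
              length(x$reads$SW$seqs), length(x$reads$TS$seqs),
              length(x$reads$BS$seqs)))
  invisible(x)
}

# per-site probability that a read base mismatches its reference base, when
# genome divergence d and substitution error rate e act independently
# (an error can revert a mutated site with probability 1/3)
compound_mismatch_rate <- function(d, e) {
  1 - (1 - d) * (1 - e) - d * e / 3
}

#' Expected mapped fraction from ground truth (parameter-recovery oracle)
#'
#' Closed-form companion to running [recruit()] + [apply_capture()]: for
#' each focal read, the probability that its identity to the reference
#' assembly reaches the threshold, from the binomial tail of per-read
#' mismatch counts at the tier's compound divergence + error rate. Reads
#' whose true source has no counterpart in the reference assembly
#' contribute 0. Conserved-decoy leakage is not modeled (use decoy-free
#' specs when comparing against this oracle).
#'
#' @param lake A `simulated_lake`.
#' @param design A [capture_design()] or a string like `"SW->BS"`.
#' @param threshold Identity threshold in percent.
#' @return Expected mapped fraction of focal reads (0..1).
#' @export
truth_capture_fraction <- function(lake, design = "SW->BS", threshold = 90) {
  stopifnot(inherits(lake, "simulated_lake"))
  if (inherits(design, "capture_design"))
    design <- paste(design$reference$compartment, design$focal$compartment,
                    sep = "->")
  parts <- strsplit(design, "->", fixed = TRUE)[[1]]
  ref <- trimws(parts[1]); focal <- trimws(parts[2])
  pair <- paste(ref, focal, sep = "->")
  if (!pair %in% c("SW->TS", "SW->BS", "TS->BS"))
    stop("invalid capture direction ", pair)
  truth <- lake$reads[[focal]]$truth
  if (is.null(truth) || nrow(truth) == 0) stop("missing truth labels")
  e <- lake$spec$read_error_rate
  shared_ids <- names(lake$genomes)[vapply(lake$genomes, `[[`, character(1),
                                           "role") == "sediment"]
  d <- rep(NA_real_, nrow(truth))
  if (ref == "SW") {
    d[truth$tier == "historical"] <- lake$spec$close_divergence
    d[truth$tier == "water_close"] <- 0
    d[truth$tier == "water_distant"] <- lake$spec$distant_divergence
  } else { # TS reference: only reads from the shared sediment genomes align
    d[truth$tier == "sediment_indigenous" &
        truth$source_genome %in% shared_ids] <- 0
  }
  p_map <- numeric(nrow(truth))
  ok <- !is.na(d)
  if (any(ok)) {
    L <- truth$length[ok]
    p <- compound_mismatch_rate(d[ok], e)
    mm_max <- floor(L * (1 - threshold / 100))
    p_map[ok] <- stats::pbinom(mm_max, L, p)
  }
  mean(p_map)
}

#' Write a simulated lake to disk in standard formats
#'
#' Reads as FASTA, assemblies as FASTA + GFF3 + taxonomy TSV, truth tables
#' as TSV.
#'
#' @param lake A `simulated_lake`.
#' @param dir Output directory (created).
#' @return `dir`, invisibly.
#' @export
write_simulated_lake <- function(lake, dir) {
  stopifnot(inherits(lake, "simulated_lake"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (cmp in names(lake$reads)) {
    write_fasta(lake$reads[[cmp]]$seqs, file.path(dir, paste0(cmp, "_reads.fasta")))
    write_tsv(lake$reads[[cmp]]$truth, file.path(dir, paste0(cmp, "_truth.tsv")))
  }
  for (cmp in names(lake$assemblies)) {
    asm <- lake$assemblies[[cmp]]
    write_fasta(asm$scaffolds, file.path(dir, paste0(cmp, "_assembly.fasta")))
    write_annotations(asm$genes, file.path(dir, paste0(cmp, "_assembly.gff3")),
                      file.path(dir, paste0(cmp, "_taxonomy.tsv")))
  }
  invisible(dir)
}
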