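make_profile_assembly <- function() {
  set.seed(41)
  seqs <- c(s1 = random_seq(1000), s2 = random_seq(1000))
  genes <- data.frame(
    gene_id = c("gA", "gB"), scaffold_id = c("s1", "s2"),
    start = c(1L, 1L), end = c(600L, 600L), strand = "+",
    feature_class = "CDS",
    lineage = c("Bacteria;X;cX;oX;fX;gX;sX", "Bacteria;Y;cY;oY;fY;gY;sY"),
    stringsAsFactors = FALSE)
  lake_assembly("two-phyla", seqs, genes)
}

test_that("relative coverage weights genes by depth times length", {
  asm <- make_profile_assembly()
  p <- relative_coverage(asm, c(s1 = 2, s2 = 1), rank = "phylum")
  expect_equal(unname(p$values[c("X", "Y")]), c(200 / 3, 100 / 3),
               tolerance = 1e-9)
  expect_equal(sum(p$values), 100, tolerance = 1e-6)
  # a single classified taxon owns the whole profile
  p1 <- relative_coverage(asm, c(s1 = 2, s2 = 0), rank = "phylum")
  expect_equal(unname(p1$values), 100)
})

test_that("unclassified genes are excluded from the denominator", {
  asm <- make_profile_assembly()
  g <- asm$genes
  g <- rbind(g, data.frame(gene_id = "gU", scaffold_id = "s1", start = 700L,
                           end = 900L, strand = "+", feature_class = "CDS",
                           lineage = NA_character_, stringsAsFactors = FALSE))
  asm2 <- lake_assembly("x", asm$scaffolds, g)
  p <- relative_coverage(asm2, c(s1 = 1, s2 = 1), rank = "phylum")
  expect_equal(sum(p$values), 100, tolerance = 1e-9)
  expect_equal(unname(p$values[c("X", "Y")]), c(50, 50))
  expect_warning(
    empty <- relative_coverage(asm2, c(s1 = 0, s2 = 0), rank = "phylum"),
    "empty profile")
  expect_true(empty$empty)
})

test_that("phylum values equal the sum of their orders (coarsening)", {
  lake <- simulate_lake(tiny_spec(seed = 42))
  asm <- lake$assemblies$SW
  depths <- setNames(runif(length(asm$scaffolds), 0.5, 3),
                     names(asm$scaffolds))
  pp <- relative_coverage(asm, depths, rank = "phylum")
  po <- relative_coverage(asm, depths, rank = "order")
  expect_equal(sum(pp$values), 100, tolerance = 1e-6)
  expect_equal(sum(po$values), 100, tolerance = 1e-6)
  lin <- lineage_ranks(asm$genes$lineage)
  map <- unique(data.frame(phylum = lin[, "phylum"], order = lin[, "order"]))
  map <- map[!is.na(map$phylum), ]
  for (ph in names(pp$values)) {
    orders <- map$order[map$phylum == ph]
    expect_equal(unname(pp$values[ph]), sum(po$values[orders]),
                 tolerance = 1e-9)
  }
})

test_that("rank promotion splits Proteobacteria and pools viruses", {
  set.seed(43)
  seqs <- c(a = random_seq(500), b = random_seq(500), c = random_seq(500))
  genes <- data.frame(
    gene_id = c("g1", "g2", "g3"), scaffold_id = c("a", "b", "c"),
    start = 1L, end = 400L, strand = "+", feature_class = "CDS",
    lineage = c("Bacteria;Proteobacteria;Betaproteobacteria;o1;f;g;s",
                "Bacteria;Proteobacteria;Deltaproteobacteria;o2;f;g;s",
                "Viruses;Uroviricota;Caudoviricetes;Caudovirales;f;g;s"),
    stringsAsFactors = FALSE)
  asm <- lake_assembly("x", seqs, genes)
  d <- c(a = 1, b = 1, c = 1)
  plain <- relative_coverage(asm, d, rank = "phylum")
  expect_setequal(names(plain$values), c("Proteobacteria", "Uroviricota"))
  prom <- relative_coverage(asm, d, rank = "phylum",
                            promotion = default_promotion())
  expect_setequal(names(prom$values),
                  c("Betaproteobacteria", "Deltaproteobacteria", "Viruses"))
  expect_equal(sum(prom$values), 100, tolerance = 1e-9)
})

test_that("gene counts are depth-invariant annotation counts", {
  lake <- simulate_lake(tiny_spec(seed = 44))
  asm <- lake$assemblies$SW
  gc <- gene_counts(asm, rank = "genus")
  lin <- lineage_rank(asm$genes$lineage, "genus")
  planted <- table(lin[!is.na(lin)])
  expect_equal(gc$genes, as.integer(planted[gc$taxon]), ignore_attr = TRUE)
  expect_equal(sum(gc$genes), sum(!is.na(lin)))
  one <- gene_counts(asm, rank = "genus", taxa = gc$taxon[1])
  expect_equal(one$genes, gc$genes[1])
  expect_error(gene_counts(asm, rank = "clade"))
})

test_that("prevalence filter keeps exactly the taxa reaching the threshold", {
  mk <- function(lab, v) structure(list(label = lab, rank = "phylum",
                                        values = v, empty = FALSE),
                                   class = "taxonomic_profile")
  profs <- list(mk("p1", c(A = 60, B = 30, C = 10)),
                mk("p2", c(A = 85, C = 5, D = 10)),
                mk("p3", c(B = 95, D = 5)))
  m <- profile_matrix(profs)
  expect_equal(dim(m), c(3L, 4L))
  got <- prevalence_filter(profs, 10)
  # exhaustive check against the matrix
  expect_setequal(got, colnames(m)[apply(m, 2, max) >= 10])
  expect_equal(got, c("B", "A", "C", "D")) # sorted by max value desc
  expect_setequal(prevalence_filter(profs, 0), c("A", "B", "C", "D"))
  expect_lte(length(prevalence_filter(profs, 100)), length(profs))
  expect_equal(prevalence_filter(list(), 5), character(0))
})

test_that("profile matrices are zero-filled and round-trip through TSV", {
  mk <- function(lab, v) structure(list(label = lab, rank = "phylum",
                                        values = v, empty = FALSE),
                                   class = "taxonomic_profile")
  profs <- list(mk("m1", c(A = 70, B = 30)), mk("m2", c(B = 100)))
  m <- profile_matrix(profs)
  expect_equal(m["m2", "A"], 0)
  expect_equal(rowSums(m), c(m1 = 100, m2 = 100))
  f <- tempfile(fileext = ".tsv")
  write_profile_matrix(m, f)
  expect_equal(read_profile_matrix(f), m)
  expect_error(profile_matrix(list(mk("x", c(A = 100)), mk("x", c(A = 100)))),
               "duplicate")
  bad <- mk("y", c(A = 100)); bad$rank <- "order"
  expect_error(profile_matrix(list(mk("x", c(A = 100)), bad)), "mix ranks")
})
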