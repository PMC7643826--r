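# Core domain types: metagenome labels, capture designs, assemblies,
# gene features, lineages. All coordinates are 1-based inclusive, matching
# GFF3 on disk and the Bioconductor convention.

.COMPARTMENTS <- c("SW", "TS", "BS")
.FORMS <- c(assembly = "A", reads = "R")
.FEATURE_CLASSES <- c("CDS", "rRNA", "tRNA")
.RANKS <- c("domain", "phylum", "class", "order", "family", "genus", "species")

#' Label a metagenome by lake, compartment and form
#'
#' Metagenomes are identified by their lake, their compartment (surface water
#' `SW`, top sediment `TS`, bottom sediment `BS`) and whether they enter a
#' capture experiment as an assembly (`A`) or as unassembled reads (`R`).
#' Labels render in the conventional subscript style, e.g. `"SW_A"`.
#'
#' @param lake Lake name (free text).
#' @param compartment One of `"SW"`, `"TS"`, `"BS"`.
#' @param form `"assembly"` or `"reads"`.
#' @return An object of class `metagenome_label`.
#' @examples
#' metagenome_label("Lac Paula", "SW", "assembly")
#' @export
metagenome_label <- function(lake, compartment, form = c("assembly", "reads")) {
  compartment <- match.arg(compartment, .COMPARTMENTS)
  form <- match.arg(form)
  structure(list(lake = lake, compartment = compartment, form = form),
            class = "metagenome_label")
}

#' @export
format.metagenome_label <- function(x, ...) {
  paste0(x$compartment, "_", .FORMS[[x$form]])
}

#' @export
print.metagenome_label <- function(x, ...) {
  cat(sprintf("<%s, %s>\n", format(x), x$lake))
  invisible(x)
}

#' Directional capture design
#'
#' A capture experiment recruits a focal read set to a reference assembly.
#' The direction must track the downward preservation of DNA: only
#' SW -> TS, SW -> BS and TS -> BS are valid; any upward or same-compartment
#' pair is rejected, as is a cross-lake pair.
#'
#' @param reference `metagenome_label` with form `"assembly"`.
#' @param focal `metagenome_label` with form `"reads"`, same lake.
#' @return An object of class `capture_design`.
#' @examples
#' capture_design(metagenome_label("L", "SW", "assembly"),
#'                metagenome_label("L", "BS", "reads"))
#' @export
capture_design <- function(reference, focal) {
  stopifnot(inherits(reference, "metagenome_label"),
            inherits(focal, "metagenome_label"))
  if (reference$form != "assembly" || focal$form != "reads")
    stop("capture designs pair a reference assembly with focal reads")
  if (!identical(reference$lake, focal$lake))
    stop("reference and focal metagenomes must come from the same lake")
  pair <- paste(reference$compartment, focal$compartment, sep = "->")
  allowed <- c("SW->TS", "SW->BS", "TS->BS")
  if (!pair %in% allowed)
    stop(sprintf(
      "invalid capture direction %s: recruitment must track the downward %s",
      pair, "preservation of DNA (allowed: SW->TS, SW->BS, TS->BS)"))
  structure(list(reference = reference, focal = focal), class = "capture_design")
}

#' @export
format.capture_design <- function(x, ...) {
  paste0(format(x$reference), " -> ", format(x$focal))
}

#' @export
print.capture_design <- function(x, ...) {
  cat(sprintf("<capture design %s, %s>\n", format(x), x$reference$lake))
  invisible(x)
}

#' Assemble scaffolds and gene features into an annotated assembly
#'
#' @param label A `metagenome_label` (form `"assembly"`) or a plain string.
#' @param scaffolds Named [Biostrings::DNAStringSet] (names are scaffold ids)
#'   or a named character vector of sequences.
#' @param genes Data frame of gene features with columns `gene_id`,
#'   `scaffold_id`, `start`, `end`, `strand`, `feature_class` and optionally
#'   `lineage` (semicolon-delimited rank labels, `NA` if unclassified).
#'   Coordinates are 1-based inclusive.
#' @return An object of class `lake_assembly`.
#' @export
lake_assembly <- function(label, scaffolds, genes = NULL) {
  if (is.character(scaffolds)) {
    if (is.null(names(scaffolds))) stop("scaffold sequences must be named")
    scaffolds <- Biostrings::DNAStringSet(scaffolds)
  }
  ids <- names(scaffolds)
  if (is.null(ids) || anyNA(ids) || any(ids == ""))
    stop("every scaffold needs an id")
  if (anyDuplicated(ids))
    stop("duplicate scaffold ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (is.null(genes)) {
    genes <- data.frame(gene_id = character(), scaffold_id = character(),
                        start = integer(), end = integer(), strand = character(),
                        feature_class = character(), lineage = character(),
                        stringsAsFactors = FALSE)
  }
  genes <- validate_gene_features(genes, scaffolds)
  structure(list(label = label, scaffolds = scaffolds, genes = genes),
            class = "lake_assembly")
}

validate_gene_features <- function(genes, scaffolds) {
  need <- c("gene_id", "scaffold_id", "start", "end", "strand", "feature_class")
  miss <- setdiff(need, names(genes))
  if (length(miss)) stop("gene feature table lacks columns: ", paste(miss, collapse = ", "))
  if (!"lineage" %in% names(genes)) genes$lineage <- NA_character_
  if (nrow(genes) == 0) return(genes)
  bad_class <- setdiff(unique(genes$feature_class), .FEATURE_CLASSES)
  if (length(bad_class))
    stop("unknown feature class: ", paste(bad_class, collapse = ", "))
  unknown <- setdiff(unique(genes$scaffold_id), names(scaffolds))
  if (length(unknown))
    stop("gene features reference missing scaffolds: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  len <- Biostrings::width(scaffolds)[match(genes$scaffold_id, names(scaffolds))]
  bad <- genes$start < 1 | genes$end > len | genes$start > genes$end
  if (any(bad))
    stop("gene interval outside scaffold bounds: ",
         paste(utils::head(genes$gene_id[bad], 5), collapse = ", "))
  genes
}

#' @export
print.lake_assembly <- function(x, ...) {
  lab <- if (inherits(x$label, "metagenome_label")) format(x$label) else as.character(x$label)
  cat(sprintf("<lake_assembly %s: %d scaffolds (%.1f kb), %d gene features>\n",
              lab, length(x$scaffolds),
              sum(Biostrings::width(x$scaffolds)) / 1000, nrow(x$genes)))
  invisible(x)
}

# ---- lineages --------------------------------------------------------------

#' Split semicolon-delimited lineage strings into rank columns
#'
#' Lineages follow the closest-homolog (phylodist-style) convention:
#' up to seven semicolon-delimited labels ordered
#' domain;phylum;class;order;family;genus;species, possibly truncated from
#' the right. Empty internal ranks are not permitted.
#'
#' @param lineage Character vector of lineage strings (`NA` allowed).
#' @return A character matrix with one column per rank.
#' @export
lineage_ranks <- function(lineage) {
  parts <- strsplit(ifelse(is.na(lineage), "", lineage), ";", fixed = TRUE)
  out <- matrix(NA_character_, nrow = length(lineage), ncol = length(.RANKS),
                dimnames = list(NULL, .RANKS))
  for (i in seq_along(parts)) {
    p <- trimws(parts[[i]])
    if (length(p) == 0 || all(p == "")) next
    if (any(p == ""))
      stop("empty internal rank in lineage: ", lineage[i])
    n <- min(length(p), length(.RANKS))
    out[i, seq_len(n)] <- p[seq_len(n)]
  }
  out
}

#' Extract one rank from lineage strings
#'
#' @param lineage Character vector of semicolon-delimited lineages.
#' @param rank Rank name, one of domain, phylum, class, order, family,
#'   genus, species.
#' @return Character vector of labels at that rank (`NA` where truncated).
#' @export
lineage_rank <- function(lineage, rank) {
  rank <- match.arg(rank, .RANKS)
  lineage_ranks(lineage)[, rank]
}

#' Rank names used throughout the package
#' @return Character vector of the seven rank names, coarsest first.
#' @export
taxonomic_ranks <- function() .RANKS
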