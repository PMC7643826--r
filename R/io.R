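# Readers/writers for the standard formats the pipeline touches:
# FASTA/FASTQ (gzip transparently), GFF3, taxonomy TSV, generic TSV output.

#' Read sequences from FASTA
#'
#' @param path FASTA file, optionally gzip-compressed.
#' @return A named [Biostrings::DNAStringSet]; order preserved. An empty file
#'   yields an empty set with a warning. Duplicate ids are an error.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fasta")
  check_sequence_ids(x, path)
  x
}

#' Read sequences from FASTQ
#'
#' Paired-end mates, if interleaved or read from separate files and combined,
#' are treated as independent reads throughout; counts count each mate once.
#'
#' @param path FASTQ file, optionally gzip-compressed.
#' @return A named [Biostrings::DNAStringSet] with per-base qualities attached
#'   (class `QualityScaledDNAStringSet`).
#' @export
read_fastq <- function(path) {
  # the constructor drops the fastq metadata columns; that is intended here
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  check_sequence_ids(x, path)
  x
}

check_sequence_ids <- function(x, path) {
  if (length(x) == 0) {
    warning("no records in ", path)
    return(invisible(x))
  }
  ids <- sub("\\s.*$", "", names(x))
  names(x) <- ids
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate sequence ids in ", path, ": ",
         paste(utils::head(dup, 5), collapse = ", "))
  invisible(x)
}

#' Write sequences to FASTA
#' @param x Named [Biostrings::DNAStringSet] or named character vector.
#' @param path Output path (`.gz` suffix compresses).
#' @export
write_fasta <- function(x, path) {
  if (is.character(x)) x <- Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(x, path, format = "fasta",
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Write sequences to FASTQ (flat qualities if none attached)
#' @inheritParams write_fasta
#' @export
write_fastq <- function(x, path) {
  if (is.character(x)) x <- Biostrings::DNAStringSet(x)
  if (!methods::is(x, "QualityScaledDNAStringSet")) {
    q <- Biostrings::PhredQuality(vapply(Biostrings::width(x), function(w)
      paste(rep("I", w), collapse = ""), character(1)))
    x <- suppressWarnings(Biostrings::QualityScaledDNAStringSet(x, q))
  }
  Biostrings::writeQualityScaledXStringSet(x, path,
                                           compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read gene annotations from GFF3 plus a taxonomy table
#'
#' Only `CDS`, `rRNA` and `tRNA` features are retained; other feature types
#' are skipped with a warning. The taxonomy table maps gene ids to
#' semicolon-delimited lineages (closest-homolog convention); genes without a
#' row stay unclassified (`NA` lineage).
#'
#' @param gff3_path GFF3 file; feature ids are taken from the `ID` attribute.
#' @param taxonomy_path Optional TSV with columns `gene_id` and `lineage`
#'   (header optional).
#' @param scaffolds Optional named `DNAStringSet`; if given, intervals are
#'   validated against scaffold bounds.
#' @return Gene feature data frame (columns `gene_id`, `scaffold_id`,
#'   `start`, `end`, `strand`, `feature_class`, `lineage`), 1-based inclusive.
#' @export
read_annotations <- function(gff3_path, taxonomy_path = NULL, scaffolds = NULL) {
  gr <- rtracklayer::import(gff3_path, format = "gff3")
  type <- as.character(gr$type)
  keep <- type %in% .FEATURE_CLASSES
  if (any(!keep)) {
    warning("skipping ", sum(!keep), " feature(s) of unknown type: ",
            paste(unique(type[!keep]), collapse = ", "))
    gr <- gr[keep]
    type <- type[keep]
  }
  ids <- if (!is.null(gr$ID)) as.character(gr$ID) else
    paste0("feature", seq_along(gr))
  genes <- data.frame(
    gene_id = ids,
    scaffold_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = ifelse(as.character(GenomicRanges::strand(gr)) == "-", "-", "+"),
    feature_class = type,
    lineage = NA_character_,
    stringsAsFactors = FALSE)
  if (!is.null(taxonomy_path)) {
    tax <- read_taxonomy(taxonomy_path)
    genes$lineage <- tax$lineage[match(genes$gene_id, tax$gene_id)]
  }
  if (!is.null(scaffolds)) genes <- validate_gene_features(genes, scaffolds)
  genes
}

read_taxonomy <- function(path) {
  tax <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("gene_id", "lineage"),
                           colClasses = "character")
  if (nrow(tax) && identical(tolower(tax$gene_id[1]), "gene_id"))
    tax <- tax[-1, , drop = FALSE]
  tax
}

#' Write gene annotations to GFF3 and a taxonomy TSV
#'
#' @param genes Gene feature data frame (see [read_annotations()]).
#' @param gff3_path Output GFF3 path.
#' @param taxonomy_path Optional output TSV path for `gene_id`/`lineage`.
#' @param source Value for the GFF3 source column.
#' @export
write_annotations <- function(genes, gff3_path, taxonomy_path = NULL,
                              source = "sedcapture") {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$scaffold_id,
    ranges = IRanges::IRanges(start = genes$start, end = genes$end),
    strand = genes$strand)
  gr$source <- source
  gr$type <- genes$feature_class
  gr$phase <- ifelse(genes$feature_class == "CDS", 0L, NA_integer_)
  gr$ID <- genes$gene_id
  rtracklayer::export(gr, gff3_path, format = "gff3")
  if (!is.null(taxonomy_path)) {
    cl <- genes[!is.na(genes$lineage), c("gene_id", "lineage")]
    utils::write.table(cl, taxonomy_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(gff3_path)
}

# all tabular outputs are TSV with a header row
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}
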