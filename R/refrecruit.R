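# Reference-genome recruitment for microdiversity profiling: rRNA/tRNA
# interval masking, genome concatenation with N spacers, per-genome
# partitioning of hits and identity-vs-position recruitment profiles.

#' Mask conserved features in a reference genome
#'
#' Replaces the bases of rRNA/tRNA intervals with N, leaving all other bases
#' and all coordinates unchanged; because N never counts as a match, no read
#' can be recruited wholly inside a masked run.
#'
#' @param genome_id Genome identifier.
#' @param sequence Genome sequence (character or length-1 `DNAStringSet`).
#' @param features Gene feature data frame (1-based inclusive `start`/`end`,
#'   `feature_class`); only rRNA and tRNA rows are masked.
#' @return Object of class `masked_reference`: `genome_id`, `sequence`,
#'   `mask_intervals` (two-column matrix, 1-based inclusive), `length`.
#' @export
mask_features <- function(genome_id, sequence, features) {
  seq <- as_sequence_character(sequence)
  stopifnot(length(seq) == 1)
  seq <- unname(seq)
  n <- nchar(seq)
  f <- features[features$feature_class %in% c("rRNA", "tRNA"), , drop = FALSE]
  iv <- matrix(integer(0), ncol = 2, dimnames = list(NULL, c("start", "end")))
  if (nrow(f)) {
    if (any(f$start < 1 | f$end > n | f$start > f$end))
      stop("mask interval outside genome bounds for ", genome_id)
    o <- order(f$start)
    iv <- cbind(start = f$start[o], end = f$end[o])
    chars <- strsplit(seq, "", fixed = TRUE)[[1]]
    for (i in seq_len(nrow(iv))) chars[iv[i, 1]:iv[i, 2]] <- "N"
    seq <- paste(chars, collapse = "")
  }
  structure(list(genome_id = genome_id, sequence = seq,
                 mask_intervals = iv, length = n),
            class = "masked_reference")
}

#' Concatenate masked references into a recruitment composite
#'
#' Genomes are joined in order with a spacer of N bases between them so no
#' alignment can bridge two genomes; each genome keeps its offset within the
#' composite for partitioning hits back.
#'
#' @param refs List of `masked_reference` objects.
#' @param spacer Number of N bases inserted between consecutive genomes.
#' @return List with `sequence` (the composite, one scaffold named
#'   `"composite"`), `offsets` (data frame: `genome_id`, `offset`, `length`),
#'   `spacer`.
#' @export
concat_references <- function(refs, spacer = 200) {
  stopifnot(length(refs) > 0, spacer >= 0)
  ids <- vapply(refs, function(r) r$genome_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate genome ids")
  lens <- vapply(refs, function(r) r$length, numeric(1))
  offsets <- cumsum(c(0, utils::head(lens + spacer, -1)))
  seqs <- vapply(refs, function(r) r$sequence, character(1))
  composite <- paste(seqs, collapse = paste(rep("N", spacer), collapse = ""))
  list(sequence = c(composite = composite),
       offsets = data.frame(genome_id = ids, offset = offsets, length = lens,
                            stringsAsFactors = FALSE),
       spacer = spacer)
}

#' Recruit reads to masked, concatenated reference genomes
#'
#' Runs the standard permissive recruitment against the composite and
#' assigns hits back to their source genomes by offset. Emits the per-genome
#' mapped read counts, mapped fractions (of all reads attempted) and the
#' per-genome identity values for downstream profiling.
#'
#' @param reads Named `DNAStringSet` or character vector.
#' @param refs List of `masked_reference` objects.
#' @param params [recruit_params()]; the permissive default (70) matches the
#'   survey use of reference recruitment.
#' @param spacer Spacer length between genomes.
#' @return Object of class `reference_recruitment`: `result` (the composite
#'   `recruitment` with genome-local coordinates added), `per_genome` (data
#'   frame: `genome_id`, `mapped_reads`, `mapped_fraction`,
#'   `mapped_fraction_ge90`), `offsets`, `total_reads`.
#' @export
recruit_to_references <- function(reads, refs, params = recruit_params(),
                                  spacer = 200) {
  comp <- concat_references(refs, spacer = spacer)
  res <- recruit(reads, comp$sequence, params = params)
  hits <- res$hits
  off <- comp$offsets
  if (nrow(hits)) {
    # assign by midpoint; spacers cannot be hit (all N)
    mid <- (hits$ref_start + hits$ref_end) / 2
    gi <- findInterval(mid, off$offset + 1)
    if (any(gi < 1 | gi > nrow(off))) stop("internal error: hit outside composite")
    local_start <- hits$ref_start - off$offset[gi]
    if (any(local_start < 1 | local_start > off$length[gi]))
      stop("internal error: hit assigned to a spacer region")
    hits$genome_id <- off$genome_id[gi]
    hits$genome_start <- local_start
    hits$genome_end <- hits$ref_end - off$offset[gi]
  } else {
    hits$genome_id <- character(0)
    hits$genome_start <- integer(0)
    hits$genome_end <- integer(0)
  }
  res$hits <- hits
  per <- do.call(rbind, lapply(off$genome_id, function(g) {
    h <- hits[hits$genome_id == g, , drop = FALSE]
    data.frame(genome_id = g, mapped_reads = nrow(h),
               mapped_fraction = nrow(h) / res$total_reads,
               mapped_fraction_ge90 = sum(h$identity >= 90) / res$total_reads,
               stringsAsFactors = FALSE)
  }))
  structure(list(result = res, per_genome = per, offsets = off,
                 total_reads = res$total_reads),
            class = "reference_recruitment")
}

#' @export
print.reference_recruitment <- function(x, ...) {
  cat(sprintf("<reference recruitment: %d reads vs %d genomes>\n",
              x$total_reads, nrow(x$per_genome)))
  print(x$per_genome)
  invisible(x)
}

#' Windowed recruitment profile along one reference genome
#'
#' Tiles the genome with fixed windows and aggregates hit identities by the
#' window containing the hit start. Windows without hits (including fully
#' masked windows) report zero counts.
#'
#' @param refres A `reference_recruitment`.
#' @param genome_id Genome to profile.
#' @param window Window size in bases (> 0).
#' @return Data frame (`window_start` 1-based, `mean_identity` (`NA` where
#'   empty), `read_count`).
#' @export
recruitment_profile <- function(refres, genome_id, window = 1000) {
  stopifnot(inherits(refres, "reference_recruitment"))
  if (window <= 0) stop("window must be positive")
  off <- refres$offsets
  row <- off[off$genome_id == genome_id, , drop = FALSE]
  if (nrow(row) != 1) stop("unknown genome id: ", genome_id)
  len <- row$length
  starts <- seq(1, len, by = window)
  h <- refres$result$hits
  h <- h[h$genome_id == genome_id, , drop = FALSE]
  wi <- findInterval(h$genome_start, starts)
  counts <- tabulate(wi, nbins = length(starts))
  mean_id <- rep(NA_real_, length(starts))
  if (nrow(h)) {
    agg <- tapply(h$identity, wi, mean)
    mean_id[as.integer(names(agg))] <- as.numeric(agg)
  }
  data.frame(window_start = as.integer(starts), mean_identity = mean_id,
             read_count = as.integer(counts))
}
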