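# Read recruitment: seed-and-extend alignment of unassembled reads against an
# assembly, with identity defined as 100 * matches / alignment columns, each
# gap column counted once. The exhaustive DP oracle lives in oracle_align().

#' Recruitment parameters
#'
#' @param k Seed length in bases (exact-match k-mer seeds), `k >= 8`.
#' @param min_identity Minimum percent identity for a hit to be reported.
#'   The permissive survey default is 70; the stringent capture threshold is
#'   typically 90 (usually applied downstream by [apply_capture()]).
#' @param min_aligned_fraction Minimum fraction of the read that must be
#'   inside the alignment (soft ends beyond this are clipped away by the
#'   local alignment).
#' @param band_width Half-width (bases) of the reference window margin placed
#'   around seed diagonals before alignment.
#' @param match,mismatch,gap_open,gap_extend Alignment scores; a gap run of
#'   length L costs `gap_open + (L - 1) * gap_extend`.
#' @return An object of class `recruit_params`.
#' @export
recruit_params <- function(k = 13, min_identity = 70, min_aligned_fraction = 0.9,
                           band_width = 16, match = 1L, mismatch = -1L,
                           gap_open = -2L, gap_extend = -1L) {
  stopifnot(k >= 8, min_identity > 0, min_identity <= 100,
            min_aligned_fraction > 0, min_aligned_fraction <= 1,
            band_width >= 1, match > 0, mismatch < 0, gap_open < 0,
            gap_extend < 0)
  structure(list(k = as.integer(k), min_identity = min_identity,
                 min_aligned_fraction = min_aligned_fraction,
                 band_width = as.integer(band_width),
                 match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend)),
            class = "recruit_params")
}

as_sequence_character <- function(x) {
  if (methods::is(x, "XStringSet")) {
    out <- as.character(x)
    names(out) <- names(x)
    return(out)
  }
  if (is.character(x)) return(x)
  stop("expected a DNAStringSet or character vector of sequences")
}

#' Build an exact k-mer seed index over an assembly
#'
#' Indexes every k-mer of the forward scaffold sequences (k-mers containing N
#' are unseedable); queries are looked up for both the read and its reverse
#' complement. Scaffolds shorter than k contribute no seeds.
#'
#' @param assembly A `lake_assembly`, a named `DNAStringSet`, or a named
#'   character vector of scaffold sequences.
#' @param k Seed length.
#' @return An object of class `seed_index`.
#' @export
build_index <- function(assembly, k = 13) {
  scaffolds <- if (inherits(assembly, "lake_assembly")) assembly$scaffolds else assembly
  seqs <- as_sequence_character(scaffolds)
  if (length(seqs) && (is.null(names(seqs)) || anyDuplicated(names(seqs))))
    stop("scaffolds must carry unique names")
  ptr <- cpp_build_index(unname(seqs), names(seqs) %||% character(0), as.integer(k))
  structure(list(ptr = ptr, k = as.integer(k), scaffold_ids = names(seqs),
                 n_scaffolds = length(seqs)),
            class = "seed_index")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Number of indexed seed positions
#' @param index A `seed_index`.
#' @return Count of k-mer positions in the index.
#' @export
index_n_positions <- function(index) {
  stopifnot(inherits(index, "seed_index"))
  cpp_index_n_positions(index$ptr)
}

#' Look up one exact k-mer in a seed index
#' @param index A `seed_index`.
#' @param kmer A string of length `k` over A/C/G/T.
#' @return Data frame with 1-based `scaffold` index and `pos`.
#' @export
index_lookup <- function(index, kmer) {
  stopifnot(inherits(index, "seed_index"))
  cpp_index_lookup(index$ptr, kmer)
}

#' Align a single read against an indexed assembly
#'
#' @param read A single sequence (character or length-1 `DNAStringSet`).
#' @param index A `seed_index` built over the target assembly.
#' @param params [recruit_params()].
#' @return A one-row hit data frame, or `NULL` if the read does not map at
#'   the given thresholds (including reads shorter than `k`).
#' @export
align_read <- function(read, index, params = recruit_params()) {
  stopifnot(inherits(index, "seed_index"), inherits(params, "recruit_params"))
  seqs <- as_sequence_character(read)
  stopifnot(length(seqs) == 1)
  hits <- cpp_recruit(index$ptr, unname(seqs), names(seqs) %||% "read",
                      params$min_identity, params$min_aligned_fraction,
                      params$band_width, params$match, params$mismatch,
                      params$gap_open, params$gap_extend)
  if (nrow(hits) == 0) NULL else hits
}

#' Recruit a read set against an assembly
#'
#' Each read receives at most one best hit (deterministic tie-breaking:
#' score, then identity, then matches, then scaffold id, position and
#' strand). `total_reads` counts every input read, mapped or not; it is the
#' "unassembled read count" denominator used for capture percentages.
#'
#' @param reads Named `DNAStringSet` or named character vector.
#' @param assembly `lake_assembly` (or sequences) to recruit against, or a
#'   prebuilt `seed_index`.
#' @param params [recruit_params()].
#' @param design Optional [capture_design()]; validated if supplied.
#' @return Object of class `recruitment`: list with `hits` (data frame),
#'   `total_reads`, `params`, `design`.
#' @export
recruit <- function(reads, assembly, params = recruit_params(), design = NULL) {
  stopifnot(inherits(params, "recruit_params"))
  if (!is.null(design) && !inherits(design, "capture_design"))
    stop("design must be a capture_design (constructing one validates the ",
         "downward direction rule)")
  index <- if (inherits(assembly, "seed_index")) assembly else
    build_index(assembly, params$k)
  if (index$k != params$k)
    stop("index was built with k = ", index$k, " but params$k = ", params$k)
  seqs <- as_sequence_character(reads)
  ids <- names(seqs) %||% paste0("read", seq_along(seqs))
  if (anyDuplicated(ids)) stop("duplicate read ids")
  hits <- cpp_recruit(index$ptr, unname(seqs), ids,
                      params$min_identity, params$min_aligned_fraction,
                      params$band_width, params$match, params$mismatch,
                      params$gap_open, params$gap_extend)
  structure(list(design = design, params = params, hits = hits,
                 total_reads = length(seqs)),
            class = "recruitment")
}

#' @export
print.recruitment <- function(x, ...) {
  cat(sprintf("<recruitment: %d / %d reads mapped (%.1f%%) at >= %.0f%% identity>\n",
              nrow(x$hits), x$total_reads,
              if (x$total_reads > 0) 100 * nrow(x$hits) / x$total_reads else 0,
              x$params$min_identity))
  invisible(x)
}

#' Exhaustive dynamic-programming alignment oracle
#'
#' Full-matrix affine-gap local alignment over both strands, written
#' independently of the seeded production path; intended for tests and tiny
#' inputs only (refuses sequences over 10 kb). Shares the scoring scheme and
#' deterministic tie preferences with [align_read()], so on instances where
#' the seeded path finds the optimum the two agree exactly.
#'
#' @param read,scaffold Single sequences (character or `DNAStringSet`).
#' @param params [recruit_params()] (scores are used; seeding fields ignored).
#' @return List with elements `best`, `forward`, `reverse`, each holding
#'   `score`, `matches`, `mismatches`, `gap_columns`, `identity`,
#'   `aligned_read_fraction`, `ref_start`, `ref_end`, `strand`, `mapped`.
#' @export
oracle_align <- function(read, scaffold, params = recruit_params()) {
  r <- as_sequence_character(read); s <- as_sequence_character(scaffold)
  stopifnot(length(r) == 1, length(s) == 1)
  if (nchar(r) == 0 || nchar(s) == 0) stop("sequences must be non-empty")
  cpp_oracle_align(unname(r), unname(s), params$match, params$mismatch,
                   params$gap_open, params$gap_extend)
}

#' Best oracle hit over a whole assembly
#'
#' Applies [oracle_align()] to every scaffold and returns the best hit
#' passing the `params` thresholds under the same tie-breaking as
#' [recruit()], or `NULL`. Quadratic; test use only.
#'
#' @inheritParams align_read
#' @param assembly `lake_assembly` or named sequences.
#' @return One-row data frame like [align_read()]'s, or `NULL`.
#' @export
oracle_best_hit <- function(read, assembly, params = recruit_params()) {
  scaffolds <- if (inherits(assembly, "lake_assembly")) assembly$scaffolds else assembly
  seqs <- as_sequence_character(scaffolds)
  r <- as_sequence_character(read)
  stopifnot(length(r) == 1)
  L <- nchar(unname(r)[1])
  best <- NULL
  best_key <- NULL
  for (sid in names(seqs)) {
    o <- oracle_align(r, seqs[[sid]], params)
    for (str in c("forward", "reverse")) {
      a <- o[[str]]
      if (!a$mapped) next
      if (a$identity < params$min_identity - 1e-9) next
      if (a$aligned_read_fraction < params$min_aligned_fraction - 1e-9) next
      key <- list(score = a$score, identity = a$identity, matches = a$matches,
                  sid = sid, ref_start = a$ref_start, strand = a$strand)
      if (is.null(best) || oracle_key_better(key, best_key)) {
        best_key <- key
        best <- data.frame(read_id = names(r) %||% "read", scaffold_id = sid,
                           ref_start = a$ref_start, ref_end = a$ref_end,
                           strand = a$strand, matches = a$matches,
                           mismatches = a$mismatches, gap_columns = a$gap_columns,
                           identity = a$identity,
                           aligned_read_fraction = a$aligned_read_fraction,
                           score = a$score, stringsAsFactors = FALSE)
      }
    }
  }
  best
}

oracle_key_better <- function(a, b) {
  if (a$score != b$score) return(a$score > b$score)
  if (a$identity != b$identity) return(a$identity > b$identity)
  if (a$matches != b$matches) return(a$matches > b$matches)
  if (a$sid != b$sid) return(a$sid < b$sid)
  if (a$ref_start != b$ref_start) return(a$ref_start < b$ref_start)
  a$strand == "+" && b$strand == "-"
}

#' Reverse complement a DNA string
#' @param x Character vector of sequences.
#' @return Character vector of reverse complements (non-ACGT becomes N).
#' @export
reverse_complement <- function(x) {
  vapply(x, cpp_revcomp, character(1), USE.NAMES = FALSE)
}

#' Write recruitment hits to TSV
#' @param result A `recruitment`.
#' @param path Output path.
#' @export
write_hits <- function(result, path) {
  stopifnot(inherits(result, "recruitment"))
  write_tsv(result$hits, path)
}
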