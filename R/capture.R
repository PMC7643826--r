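# Capture logic: identity histograms, empirical threshold delineation,
# conserved-scaffold (rRNA/tRNA) filtering, and read-count accounting
# normalized by the unassembled read count.

#' Histogram of best-hit identities from a permissive recruitment
#'
#' @param result A `recruitment` run at the permissive identity threshold.
#' @param bin_width Bin width in identity points.
#' @return Object of class `identity_histogram`: list with `edges`, `mids`,
#'   `counts`, `bin_width`, `empty`. Counts sum to the number of hits.
#' @export
identity_histogram <- function(result, bin_width = 0.5) {
  stopifnot(inherits(result, "recruitment"), bin_width > 0)
  lo <- floor(result$params$min_identity)
  edges <- seq(lo, 100, by = bin_width)
  if (edges[length(edges)] < 100) edges <- c(edges, edges[length(edges)] + bin_width)
  id <- result$hits$identity
  empty <- length(id) == 0
  if (empty) {
    counts <- integer(length(edges) - 1)
    warning("recruitment has zero hits; empty identity histogram")
  } else {
    # right-closed top bin so identity 100 lands in the last bin
    bin <- pmin(findInterval(id, edges, rightmost.closed = TRUE),
                length(edges) - 1)
    counts <- tabulate(bin, nbins = length(edges) - 1)
  }
  structure(list(edges = edges, mids = (edges[-1] + edges[-length(edges)]) / 2,
                 counts = counts, bin_width = bin_width, empty = empty),
            class = "identity_histogram")
}

#' Build an identity histogram directly from identity values
#'
#' Convenience for threshold studies where identities come from elsewhere
#' (e.g. simulated mixtures).
#'
#' @param identities Numeric vector of percent identities.
#' @param lo Lower edge of the histogram (permissive floor).
#' @param bin_width Bin width in identity points.
#' @return An `identity_histogram`.
#' @export
identity_histogram_from_values <- function(identities, lo = 70, bin_width = 0.5) {
  stopifnot(bin_width > 0)
  edges <- seq(lo, 100, by = bin_width)
  if (edges[length(edges)] < 100) edges <- c(edges, edges[length(edges)] + bin_width)
  identities <- identities[identities >= lo & identities <= 100]
  empty <- length(identities) == 0
  counts <- if (empty) integer(length(edges) - 1) else
    tabulate(pmin(findInterval(identities, edges, rightmost.closed = TRUE),
                  length(edges) - 1), nbins = length(edges) - 1)
  structure(list(edges = edges, mids = (edges[-1] + edges[-length(edges)]) / 2,
                 counts = counts, bin_width = bin_width, empty = empty),
            class = "identity_histogram")
}

#' Smooth an identity histogram with a Gaussian kernel
#'
#' @param hist An `identity_histogram`.
#' @param bandwidth Kernel standard deviation in identity points.
#' @param grid_step Evaluation grid spacing.
#' @return Data frame with `x` (identity) and `density` (kernel-smoothed,
#'   count-weighted).
#' @export
smooth_histogram <- function(hist, bandwidth = 1.0, grid_step = 0.1) {
  stopifnot(inherits(hist, "identity_histogram"))
  x <- seq(min(hist$edges), max(hist$edges), by = grid_step)
  occ <- which(hist$counts > 0)
  dens <- numeric(length(x))
  for (i in occ)
    dens <- dens + hist$counts[i] * stats::dnorm(x, hist$mids[i], bandwidth)
  data.frame(x = x, density = dens)
}

# local maxima of y with a simple prominence estimate
local_peaks <- function(x, y) {
  n <- length(y)
  if (n < 3) return(data.frame(x = numeric(), y = numeric(), prominence = numeric()))
  is_peak <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n], FALSE)
  idx <- which(is_peak)
  prom <- vapply(idx, function(i) {
    higher_left <- which(y[seq_len(i - 1)] > y[i])
    lo_l <- if (length(higher_left)) min(y[(max(higher_left) + 1):(i - 1)]) else min(y[1:i])
    higher_right <- which(y[(i + 1):n] > y[i]) + i
    lo_r <- if (length(higher_right)) min(y[(i + 1):(min(higher_right) - 1)]) else min(y[i:n])
    y[i] - max(lo_l, lo_r)
  }, numeric(1))
  data.frame(x = x[idx], y = y[idx], prominence = prom)
}

#' Derive the identity threshold delineating close and distant populations
#'
#' Smooths the permissive-recruitment identity histogram with a Gaussian
#' kernel, keeps local maxima whose prominence is at least
#' `min_prominence` of the global smoothed maximum, and returns the identity
#' at the minimum smoothed density strictly between the two highest modes.
#' With fewer than two modes the fixed fallback (90) is returned with
#' attribute `fallback = TRUE`.
#'
#' @param hist An `identity_histogram` spanning the permissive range.
#' @param bandwidth Smoothing bandwidth in identity points.
#' @param min_prominence Minimum peak prominence as a fraction of the global
#'   maximum of the smoothed density.
#' @param fallback Threshold used when the histogram is not bimodal.
#' @return Numeric threshold (percent identity) with attribute `fallback`.
#' @export
derive_threshold <- function(hist, bandwidth = 1.0, min_prominence = 0.05,
                             fallback = 90) {
  stopifnot(inherits(hist, "identity_histogram"))
  if (hist$empty || sum(hist$counts) == 0)
    stop("cannot derive a threshold from an empty histogram")
  sm <- smooth_histogram(hist, bandwidth = bandwidth)
  pk <- local_peaks(sm$x, sm$density)
  pk <- pk[pk$prominence >= min_prominence * max(sm$density), , drop = FALSE]
  if (nrow(pk) < 2) {
    return(structure(fallback, fallback = TRUE))
  }
  pk <- pk[order(-pk$y), , drop = FALSE]
  lohi <- sort(pk$x[1:2])
  between <- sm$x > lohi[1] & sm$x < lohi[2]
  thr <- sm$x[between][which.min(sm$density[between])]
  structure(thr, fallback = FALSE)
}

#' Scaffolds carrying conserved rRNA or tRNA genes
#'
#' Ribosomal and transfer RNA genes are shared at high similarity among
#' distantly related organisms; scaffolds carrying at least one such feature
#' are removed from captured metagenomes to suppress false-positive
#' recruitment.
#'
#' @param assembly A `lake_assembly` with annotations loaded.
#' @return Character vector of scaffold ids (possibly empty).
#' @export
conserved_scaffold_ids <- function(assembly) {
  stopifnot(inherits(assembly, "lake_assembly"))
  g <- assembly$genes
  sort(unique(g$scaffold_id[g$feature_class %in% c("rRNA", "tRNA")]))
}

#' Percentage of mapped reads, normalized by the unassembled read count
#'
#' `100 * mapped / unassembled`, rounded half-up to one decimal, as printed
#' in capture accounting tables.
#'
#' @param mapped Mapped read count, `0 <= mapped <= unassembled`.
#' @param unassembled Unassembled (total input) read count, `> 0`.
#' @return One-decimal percentage.
#' @examples
#' normalized_percentage(1622267, 29740441) # 5.5
#' @export
normalized_percentage <- function(mapped, unassembled) {
  if (any(unassembled <= 0)) stop("unassembled read count must be positive")
  if (any(mapped < 0) || any(mapped > unassembled))
    stop("mapped count must lie in [0, unassembled]")
  round_half_up(100 * mapped / unassembled, 1)
}

round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Apply the capture threshold and conserved-scaffold filter
#'
#' Filters permissive hits to `identity >= threshold`, then removes hits on
#' scaffolds carrying rRNA/tRNA genes. The accounting keeps both the pre-
#' and post-filter mapped counts; the percentage denominator is always the
#' total unassembled read count, unaffected by filtering.
#'
#' @param result A `recruitment` run at the permissive threshold.
#' @param assembly The reference `lake_assembly` (for annotations).
#' @param threshold Stringent identity threshold (percent); must not lie
#'   below the permissive floor the recruitment was run at.
#' @return Object of class `capture_result`.
#' @export
apply_capture <- function(result, assembly, threshold = 90) {
  stopifnot(inherits(result, "recruitment"), inherits(assembly, "lake_assembly"))
  threshold <- as.numeric(threshold)
  if (threshold < result$params$min_identity)
    stop("threshold ", threshold, " lies below the permissive floor ",
         result$params$min_identity, " the recruitment was run at")
  hits <- result$hits
  pass <- hits[hits$identity >= threshold - 1e-9, , drop = FALSE]
  removed_ids <- conserved_scaffold_ids(assembly)
  on_conserved <- pass$scaffold_id %in% removed_ids
  kept <- pass[!on_conserved, , drop = FALSE]
  per_scaffold <- per_scaffold_summary(kept, assembly)
  structure(list(
    design = result$design,
    threshold_used = threshold,
    unassembled_count = result$total_reads,
    mapped_count_prefilter = nrow(pass),
    mapped_count = nrow(kept),
    mapped_percent = normalized_percentage(nrow(kept), result$total_reads),
    removed_scaffold_ids = removed_ids,
    removed_read_count = sum(on_conserved),
    per_scaffold_read_counts = per_scaffold$reads,
    per_scaffold_depth = per_scaffold$depth,
    hits = kept), class = "capture_result")
}

per_scaffold_summary <- function(hits, assembly) {
  ids <- names(assembly$scaffolds)
  reads <- integer(length(ids)); names(reads) <- ids
  bases <- numeric(length(ids)); names(bases) <- ids
  if (nrow(hits)) {
    t1 <- table(hits$scaffold_id)
    reads[names(t1)] <- as.integer(t1)
    aligned_bases <- hits$matches + hits$mismatches # read bases in aligned columns
    ab <- tapply(aligned_bases, hits$scaffold_id, sum)
    bases[names(ab)] <- as.numeric(ab)
  }
  depth <- bases / as.numeric(Biostrings::width(assembly$scaffolds))
  names(depth) <- ids
  list(reads = reads, depth = depth)
}

#' @export
print.capture_result <- function(x, ...) {
  lab <- if (!is.null(x$design)) format(x$design) else "capture"
  cat(sprintf("<capture %s at >= %.1f%% identity>\n", lab, x$threshold_used))
  cat(sprintf("  unassembled reads : %d\n", x$unassembled_count))
  cat(sprintf("  mapped (prefilter): %d\n", x$mapped_count_prefilter))
  cat(sprintf("  removed (rRNA/tRNA scaffolds): %d reads on %d scaffolds\n",
              x$removed_read_count, length(x$removed_scaffold_ids)))
  cat(sprintf("  mapped            : %d (%.1f%%)\n", x$mapped_count, x$mapped_percent))
  invisible(x)
}

#' @export
summary.capture_result <- function(object, ...) {
  data.frame(
    design = if (!is.null(object$design)) format(object$design) else NA_character_,
    threshold = object$threshold_used,
    unassembled_count = object$unassembled_count,
    mapped_count_prefilter = object$mapped_count_prefilter,
    removed_read_count = object$removed_read_count,
    mapped_count = object$mapped_count,
    mapped_percent = object$mapped_percent,
    stringsAsFactors = FALSE)
}

#' Per-scaffold statistics of a captured metagenome
#'
#' One row per scaffold with at least one recruited read: scaffold length,
#' number of annotated genes, average fold (aligned read bases divided by
#' scaffold length) and recruited read count.
#'
#' @param capture A `capture_result`.
#' @param assembly The reference `lake_assembly`.
#' @return Data frame (`scaffold_id`, `length`, `genes_on_scaffold`,
#'   `average_fold`, `recruited_reads`).
#' @export
scaffold_stats <- function(capture, assembly) {
  stopifnot(inherits(capture, "capture_result"), inherits(assembly, "lake_assembly"))
  reads <- capture$per_scaffold_read_counts
  keep <- names(reads)[reads > 0]
  gene_tab <- table(assembly$genes$scaffold_id)
  data.frame(
    scaffold_id = keep,
    length = as.integer(Biostrings::width(assembly$scaffolds)[match(keep, names(assembly$scaffolds))]),
    genes_on_scaffold = as.integer(ifelse(keep %in% names(gene_tab),
                                          gene_tab[keep], 0L)),
    average_fold = as.numeric(capture$per_scaffold_depth[keep]),
    recruited_reads = as.integer(reads[keep]),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Read-count accounting table from a three-lake capture survey
#'
#' Unassembled and mapped read counts for the nine downward capture
#' experiments (three boreal/Atlantic lakes x SW_A->TS_R, SW_A->BS_R,
#' TS_A->BS_R) at the stringent 90\% identity threshold, shipped as example
#' data for the accounting arithmetic.
#'
#' @return Data frame with `lake`, `design`, `unassembled_reads`,
#'   `mapped_reads`.
#' @examples
#' x <- lake_capture_counts()
#' normalized_percentage(x$mapped_reads, x$unassembled_reads)
#' @export
lake_capture_counts <- function() {
  read_tsv(system.file("extdata", "lake_capture_counts.tsv",
                       package = "sedcapture", mustWork = TRUE))
}

#' Write a capture summary TSV (one row per capture experiment)
#' @param captures List of `capture_result` objects.
#' @param path Output path.
#' @export
write_capture_summary <- function(captures, path) {
  rows <- lapply(captures, summary)
  write_tsv(do.call(rbind, rows), path)
}
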