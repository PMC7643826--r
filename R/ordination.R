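# Ordination of composition matrices: chord transformation, PCA with
# variance decomposition, Bray-Curtis dissimilarities, Ward dendrograms.
# Standard steps delegate to vegan / stats / ape.

#' Chord-transform a composition matrix
#'
#' Divides each sample row by its Euclidean norm so all rows have unit norm
#' (vegan's `decostand(method = "norm")`).
#'
#' @param m Non-negative samples x taxa matrix; no all-zero rows.
#' @return Matrix of the same shape with unit-norm rows.
#' @export
chord_transform <- function(m) {
  m <- as.matrix(m)
  if (any(m < 0)) stop("composition matrix must be non-negative")
  zero <- rowSums(m * m) == 0
  if (any(zero))
    stop("all-zero sample row(s): ",
         paste(rownames(m)[zero] %||% which(zero), collapse = ", "))
  out <- as.matrix(vegan::decostand(m, method = "normalize"))
  dimnames(out) <- dimnames(m)
  out
}

#' Principal-component analysis of a (chord-transformed) composition matrix
#'
#' Columns are centered, not scaled; the decomposition uses singular values
#' with an n-1 variance denominator. Signs are fixed deterministically: the
#' largest-magnitude loading of each component is made positive.
#'
#' @param m Samples x taxa matrix with at least two samples.
#' @return Object of class `ordination_result`: `scores` (samples x
#'   components), `loadings` (taxa x components), `variance_fraction`,
#'   `center`.
#' @export
pca_ordination <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 2) stop("PCA needs at least two samples")
  p <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  flip <- apply(p$rotation, 2, function(v) {
    s <- sign(v[which.max(abs(v))]); if (s == 0) 1 else s
  })
  scores <- sweep(p$x, 2, flip, `*`)
  loadings <- sweep(p$rotation, 2, flip, `*`)
  ev <- p$sdev^2
  structure(list(scores = scores, loadings = loadings,
                 variance_fraction = ev / sum(ev),
                 center = p$center),
            class = "ordination_result")
}

#' @export
print.ordination_result <- function(x, ...) {
  vf <- x$variance_fraction
  cat(sprintf("<PCA: %d samples x %d taxa; PC1 %.1f%%, PC2 %.1f%% of variance>\n",
              nrow(x$scores), nrow(x$loadings), 100 * vf[1],
              if (length(vf) > 1) 100 * vf[2] else 0))
  invisible(x)
}

#' Bray-Curtis dissimilarities between sample rows
#'
#' `d(i,j) = sum |x_i - x_j| / sum (x_i + x_j)`; symmetric, zero diagonal,
#' values in `[0, 1]`. A pair of all-zero samples is defined as distance 0
#' with a warning.
#'
#' @param m Non-negative samples x taxa matrix.
#' @return A `dist` object.
#' @export
bray_curtis <- function(m) {
  m <- as.matrix(m)
  if (any(m < 0)) stop("Bray-Curtis requires non-negative data")
  zero <- rowSums(m) == 0
  d <- if (any(zero)) suppressWarnings(vegan::vegdist(m, method = "bray"))
    else vegan::vegdist(m, method = "bray")
  if (any(zero)) {
    warning("all-zero sample(s); pairwise distances involving them set to ",
            "0 (identical emptiness) or 1")
    dm <- as.matrix(d)
    zi <- which(zero)
    for (i in zi) for (j in seq_len(nrow(dm)))
      dm[i, j] <- dm[j, i] <- if (zero[j] && i != j) 0 else if (i == j) 0 else 1
    d <- stats::as.dist(dm)
  }
  d
}

#' Ward hierarchical clustering of a dissimilarity matrix
#'
#' Agglomerative Ward linkage; the default `"ward.D2"` variant applies the
#' Lance-Williams update on squared dissimilarities. Applying Ward to
#' (non-Euclidean) Bray-Curtis dissimilarities follows common practice in
#' community ecology; no correction is applied.
#'
#' @param d A `dist` object (or symmetric matrix) of dissimilarities.
#' @param variant `"ward.D2"` (default) or `"ward.D"`.
#' @return An `hclust` tree with leaves labeled by sample.
#' @export
ward_dendrogram <- function(d, variant = c("ward.D2", "ward.D")) {
  variant <- match.arg(variant)
  if (is.matrix(d)) d <- stats::as.dist(d)
  if (attr(d, "Size") < 2) stop("clustering needs at least two samples")
  stats::hclust(d, method = variant)
}

#' Serialize a dendrogram as Newick with branch lengths
#'
#' @param tree An `hclust` tree (e.g. from [ward_dendrogram()]).
#' @param path Optional output path; if `NULL` the Newick string is returned.
#' @return The Newick string, invisibly when written to a file.
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "hclust"))
  phy <- ape::as.phylo(tree)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}

#' Write PCA scores, loadings and variance fractions as TSVs
#' @param ord An `ordination_result`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Paths written, invisibly.
#' @export
write_ordination <- function(ord, dir, prefix = "pca") {
  stopifnot(inherits(ord, "ordination_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, "_", c("scores", "loadings", "variance"), ".tsv"))
  write_tsv(data.frame(sample = rownames(ord$scores), ord$scores,
                       check.names = FALSE), paths[1])
  write_tsv(data.frame(taxon = rownames(ord$loadings), ord$loadings,
                       check.names = FALSE), paths[2])
  write_tsv(data.frame(component = seq_along(ord$variance_fraction),
                       variance_fraction = ord$variance_fraction), paths[3])
  invisible(paths)
}
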