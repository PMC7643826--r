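# Coverage-weighted taxonomic composition of free and captured metagenomes.
# Gene weight = scaffold depth x gene length (length weighting prevents
# short-gene bias); unclassified genes are excluded from the denominator by
# default. Values are percentages of classified weight and sum to 100.

#' Default rank-promotion map for display
#'
#' At the phylum display level, proteobacterial classes conventionally
#' replace the phylum "Proteobacteria" (so e.g. Betaproteobacteria and
#' Deltaproteobacteria appear alongside phyla), and any gene whose domain is
#' viral is displayed as the single taxon "Viruses".
#'
#' @return List with elements `split_phyla` (phyla replaced by their class)
#'   and `viral_domains` (domains collapsed to "Viruses").
#' @export
default_promotion <- function() {
  list(split_phyla = "Proteobacteria", viral_domains = "Viruses")
}

# resolve the display taxon of each gene at `rank`, applying promotion
display_taxon <- function(lineage, rank, promotion = NULL) {
  ranks <- lineage_ranks(lineage)
  tax <- ranks[, rank]
  if (!is.null(promotion) && rank == "phylum") {
    if (length(promotion$viral_domains)) {
      viral <- !is.na(ranks[, "domain"]) & ranks[, "domain"] %in% promotion$viral_domains
      tax[viral] <- "Viruses"
    }
    if (length(promotion$split_phyla)) {
      split <- !is.na(tax) & tax %in% promotion$split_phyla & !is.na(ranks[, "class"])
      tax[split] <- ranks[split, "class"]
    }
  }
  tax
}

#' Relative coverage-weighted taxonomic profile
#'
#' Each annotated gene contributes weight `depth(scaffold) * gene length`
#' (or depth only, with `weight = "depth"`); a taxon's value is its share of
#' the total classified weight, as a percentage. For a free metagenome,
#' supply the assembly's own per-scaffold depths; for a captured metagenome,
#' supply `capture$per_scaffold_depth`.
#'
#' @param assembly A `lake_assembly` whose genes carry lineages.
#' @param depths Named numeric vector of per-scaffold depths (average fold).
#'   Scaffolds absent from the vector count as depth 0.
#' @param rank Rank at which to aggregate.
#' @param promotion Optional promotion map (see [default_promotion()]);
#'   applied at the phylum display level.
#' @param weight `"depth_length"` (default) or `"depth"`.
#' @param label Optional metagenome label for the profile.
#' @return Object of class `taxonomic_profile`: list with `label`, `rank`,
#'   `values` (named percentages summing to 100), `empty`.
#' @export
relative_coverage <- function(assembly, depths, rank = "phylum",
                              promotion = NULL,
                              weight = c("depth_length", "depth"),
                              label = NULL) {
  stopifnot(inherits(assembly, "lake_assembly"))
  rank <- match.arg(rank, taxonomic_ranks())
  weight <- match.arg(weight)
  g <- assembly$genes
  tax <- display_taxon(g$lineage, rank, promotion)
  keep <- !is.na(tax)
  d <- depths[g$scaffold_id]
  d[is.na(d)] <- 0
  w <- if (weight == "depth_length") d * (g$end - g$start + 1) else d
  w <- w[keep]; tax <- tax[keep]
  tot <- sum(w)
  if (!any(keep) || tot <= 0) {
    warning("no classified weight at rank ", rank, "; empty profile")
    return(structure(list(label = label %||% assembly$label, rank = rank,
                          values = numeric(0), empty = TRUE),
                     class = "taxonomic_profile"))
  }
  v <- c(tapply(w, tax, sum)) / tot * 100
  v <- sort(v[v > 0], decreasing = TRUE)
  structure(list(label = label %||% assembly$label, rank = rank,
                 values = v, empty = FALSE),
            class = "taxonomic_profile")
}

#' @export
print.taxonomic_profile <- function(x, ...) {
  lab <- if (inherits(x$label, "metagenome_label")) format(x$label) else as.character(x$label)
  cat(sprintf("<taxonomic_profile %s at %s rank: %d taxa>\n",
              lab, x$rank, length(x$values)))
  if (length(x$values))
    print(round(utils::head(x$values, 10), 3))
  invisible(x)
}

#' Annotated gene counts for selected taxa
#'
#' Counts annotated genes (not coverage) whose lineage matches each
#' requested taxon at the given rank.
#'
#' @param assembly A `lake_assembly`.
#' @param rank Rank name.
#' @param taxa Character vector of taxa to count; default counts all taxa
#'   observed at that rank.
#' @return Data frame with `taxon` and `genes`.
#' @export
gene_counts <- function(assembly, rank = "genus", taxa = NULL) {
  stopifnot(inherits(assembly, "lake_assembly"))
  rank <- match.arg(rank, taxonomic_ranks())
  tax <- lineage_rank(assembly$genes$lineage, rank)
  tab <- table(tax[!is.na(tax)])
  if (is.null(taxa)) taxa <- names(sort(tab, decreasing = TRUE))
  data.frame(taxon = taxa,
             genes = as.integer(ifelse(taxa %in% names(tab), tab[taxa], 0L)),
             stringsAsFactors = FALSE)
}

#' Prevalence filter over a set of profiles
#'
#' Keeps taxa reaching at least `min_percent` relative coverage in at least
#' one profile, sorted by their maximum value, descending.
#'
#' @param profiles List of `taxonomic_profile` objects sharing a rank.
#' @param min_percent Prevalence threshold in percent.
#' @return Character vector of taxa.
#' @export
prevalence_filter <- function(profiles, min_percent) {
  if (length(profiles) == 0) return(character(0))
  m <- profile_matrix(profiles)
  mx <- apply(m, 2, max)
  names(sort(mx[mx >= min_percent], decreasing = TRUE))
}

#' Stack profiles into a samples x taxa matrix
#'
#' Rows follow the input order; columns are the union of taxa, zero-filled
#' where a taxon is absent from a sample.
#'
#' @param profiles List of `taxonomic_profile` objects sharing a rank.
#' @return Numeric matrix with metagenome labels as row names.
#' @export
profile_matrix <- function(profiles) {
  stopifnot(length(profiles) > 0)
  ranks <- unique(vapply(profiles, function(p) p$rank, character(1)))
  if (length(ranks) > 1)
    stop("profiles mix ranks: ", paste(ranks, collapse = ", "))
  labs <- vapply(profiles, function(p)
    if (inherits(p$label, "metagenome_label")) format(p$label) else as.character(p$label),
    character(1))
  if (anyDuplicated(labs))
    stop("duplicate metagenome labels: ",
         paste(unique(labs[duplicated(labs)]), collapse = ", "))
  taxa <- unique(unlist(lapply(profiles, function(p) names(p$values))))
  m <- matrix(0, nrow = length(profiles), ncol = length(taxa),
              dimnames = list(labs, taxa))
  for (i in seq_along(profiles))
    m[i, names(profiles[[i]]$values)] <- profiles[[i]]$values
  m
}

#' Write a profile matrix as TSV (rows = taxa, columns = metagenomes)
#' @param m Samples x taxa matrix from [profile_matrix()].
#' @param path Output path.
#' @export
write_profile_matrix <- function(m, path) {
  df <- data.frame(taxon = colnames(m), t(m), check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Read a profile matrix written by [write_profile_matrix()]
#' @param path TSV path.
#' @return Samples x taxa matrix.
#' @export
read_profile_matrix <- function(path) {
  df <- read_tsv(path)
  m <- t(as.matrix(df[, -1, drop = FALSE]))
  colnames(m) <- df$taxon
  m
}
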