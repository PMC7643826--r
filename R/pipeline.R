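# Orchestration: run the capture workflow end to end (simulate or load
# inputs, recruit each downward design, capture, profile, ordinate) with a
# declarative YAML config, seed control and a run manifest.

#' Read a run configuration file
#'
#' YAML with (all optional unless noted) keys: `seed` (required unless given
#' on the command line), `out_dir`, `simulate:` (keys of
#' [simulation_spec()]), `recruit:` (keys of [recruit_params()]), `capture:`
#' (`threshold`, `bin_width`), `profile:` (`ranks`), `ordinate:` (`rank`).
#'
#' @param path YAML file.
#' @return A named list (class `run_config`).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  structure(cfg %||% list(), class = "run_config")
}

cfg_get <- function(cfg, key, default = NULL) {
  if (!is.null(cfg[[key]])) cfg[[key]] else default
}

#' Run the full capture pipeline on a simulated lake
#'
#' Simulates the lake system, recruits each downward capture design
#' (SW_A -> TS_R, SW_A -> BS_R, TS_A -> BS_R) at the permissive threshold,
#' applies the stringent capture (empirically derived threshold when the
#' identity histogram is bimodal, fallback otherwise), profiles free and
#' captured metagenomes, ordinates the composition matrix and writes every
#' artifact with a manifest.
#'
#' @param config A `run_config`, a path to one, or a plain list.
#' @param seed Overrides the config seed.
#' @param out_dir Overrides the config output directory.
#' @return Invisible list with the in-memory results (`lake`, `recruitments`,
#'   `captures`, `summary`, `profiles`, `ordination`, `manifest`).
#' @export
run_capture_pipeline <- function(config = list(), seed = NULL, out_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  seed <- seed %||% cfg_get(config, "seed")
  if (is.null(seed)) stop("a seed is required (config `seed:` or argument)")
  out_dir <- out_dir %||% cfg_get(config, "out_dir", "sedcapture_run")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  sim_args <- cfg_get(config, "simulate", list())
  sim_args$seed <- as.integer(seed)
  spec <- do.call(simulation_spec, sim_args)
  lake <- simulate_lake(spec)
  write_simulated_lake(lake, file.path(out_dir, "simulated"))

  params <- do.call(recruit_params, cfg_get(config, "recruit", list()))
  cap_cfg <- cfg_get(config, "capture", list())
  bin_width <- cap_cfg$bin_width %||% 0.5
  fixed_threshold <- cap_cfg$threshold

  designs <- list(
    SW_TS = list(ref = "SW", focal = "TS"),
    SW_BS = list(ref = "SW", focal = "BS"),
    TS_BS = list(ref = "TS", focal = "BS"))

  recruitments <- list(); captures <- list(); thresholds <- list()
  for (nm in names(designs)) {
    d <- designs[[nm]]
    des <- capture_design(metagenome_label(lake$lake, d$ref, "assembly"),
                          metagenome_label(lake$lake, d$focal, "reads"))
    asm <- lake$assemblies[[d$ref]]
    res <- recruit(lake$reads[[d$focal]]$seqs, asm, params, design = des)
    hist <- suppressWarnings(identity_histogram(res, bin_width = bin_width))
    thr <- if (!is.null(fixed_threshold)) structure(fixed_threshold, fallback = FALSE)
      else if (hist$empty) structure(90, fallback = TRUE)
      else derive_threshold(hist)
    cap <- apply_capture(res, asm, as.numeric(thr))
    recruitments[[nm]] <- res
    captures[[nm]] <- cap
    thresholds[[nm]] <- thr
    write_hits(res, file.path(out_dir, paste0("hits_", nm, ".tsv")))
    write_tsv(data.frame(identity = hist$mids, count = hist$counts),
              file.path(out_dir, paste0("identity_histogram_", nm, ".tsv")))
    write_tsv(scaffold_stats(cap, asm),
              file.path(out_dir, paste0("scaffold_stats_", nm, ".tsv")))
  }
  summary_df <- do.call(rbind, lapply(names(captures), function(nm) {
    s <- summary(captures[[nm]])
    s$lake <- lake$lake
    s$derived_threshold_fallback <- isTRUE(attr(thresholds[[nm]], "fallback"))
    s[, c("lake", setdiff(names(s), "lake"))]
  }))
  write_tsv(summary_df, file.path(out_dir, "capture_summary.tsv"))

  # taxonomic profiles: free metagenomes at uniform depth of the source
  # community abundances; captured metagenomes at capture depths
  prof_cfg <- cfg_get(config, "profile", list())
  rank <- prof_cfg$rank %||% "phylum"
  promotion <- default_promotion()
  profiles <- list()
  for (cmp in c("SW", "TS")) {
    asm <- lake$assemblies[[cmp]]
    depth <- free_depths(lake, cmp)
    profiles[[paste0(cmp, "_free")]] <-
      relative_coverage(asm, depth, rank = rank, promotion = promotion,
                        label = paste0(cmp, "_free"))
  }
  for (nm in names(captures)) {
    ref <- designs[[nm]]$ref
    profiles[[paste0(nm, "_captured")]] <-
      relative_coverage(lake$assemblies[[ref]],
                        captures[[nm]]$per_scaffold_depth, rank = rank,
                        promotion = promotion,
                        label = paste0(nm, "_captured"))
  }
  profiles <- Filter(function(p) !p$empty, profiles)
  m <- profile_matrix(profiles)
  write_profile_matrix(m, file.path(out_dir, "profiles.tsv"))

  ord <- NULL
  if (nrow(m) >= 2 && all(rowSums(m) > 0)) {
    ord <- pca_ordination(chord_transform(m))
    write_ordination(ord, out_dir)
    bc <- bray_curtis(m)
    tree <- ward_dendrogram(bc)
    write_newick(tree, file.path(out_dir, "dendrogram.nwk"))
  }

  manifest <- list(
    tool = "sedcapture", version = as.character(utils::packageVersion("sedcapture")),
    seed = as.integer(seed),
    params = unclass(params),
    thresholds = lapply(thresholds, function(t)
      list(value = as.numeric(t), fallback = isTRUE(attr(t, "fallback")))),
    simulation = lapply(unclass(spec), function(x)
      if (is.numeric(x) || is.character(x) || is.logical(x)) x else NULL),
    outputs = list.files(out_dir, recursive = TRUE))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(lake = lake, recruitments = recruitments, captures = captures,
                 summary = summary_df, profiles = profiles, ordination = ord,
                 manifest = manifest))
}

# depth proxy of a free metagenome: community abundance of the scaffold's
# source genome (uniform within genome), scaled to mean 1
free_depths <- function(lake, cmp) {
  asm <- lake$assemblies[[cmp]]
  sg <- attr(asm, "scaffold_genome")
  ab <- if (cmp == "SW") lake$abundances$water else lake$abundances$shared
  d <- ab[sg]
  names(d) <- names(sg)
  d / mean(d)
}
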