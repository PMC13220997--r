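# End-to-end pipeline: sample -> features -> classify -> rank -> group ->
# stability, with a serializable configuration and a run log. A thin
# command-line wrapper over these functions ships in inst/cli/leaftex.R.

#' Pipeline configuration
#'
#' Returns the nested configuration list with the study defaults: 120
#' patches per image on an 80 um window resized to 512 px, a per-species
#' quota of 240 patches, 64-level isotropic GLCM at offsets {1,2,4} x four
#' angles, 64 spectral bins reduced to 25 components, kNN with k = 3 under
#' 4 grouped (leave-image-out) folds, 1000 sampled matches per species
#' pair, Benjamini-Hochberg-adjusted Kruskal-Wallis grouping at alpha =
#' 0.05, and 20 bootstrap replicates at an 80 % resampling fraction.
#'
#' @param manifest,annotations,out_dir file-system paths.
#' @param seed master seed for every random stage.
#' @param ... replacements for any nested default, e.g.
#'   `sampling = list(n_per_image = 60)` (partial lists are merged).
#' @return a `leaftex_config` nested list.
#' @export
leaftex_config <- function(manifest = NULL, annotations = NULL,
                           out_dir = "leaftex_out", seed = 42, ...) {
  cfg <- list(
    paths = list(manifest = manifest, annotations = annotations,
                 out_dir = out_dir),
    sampling = list(n_per_image = 120, patch_size_um = 80,
                    mode = "whole_leaf", per_species = 240),
    features = list(glcm_levels = 64, glcm_distances = c(1, 2, 4),
                    glcm_angles = c(0, 45, 90, 135), spectral_bins = 64,
                    n_components = 25),
    classifier = list(k = 3, n_folds = 4, grouping = "source_image"),
    tournament = list(pairs_per_species_pair = 1000, exhaustive = FALSE,
                      mode = "per_feature"),
    grouping = list(alpha = 0.05, adjust = "BH"),
    stability = list(n_boot = 20, frac = 0.8),
    seed = seed
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(dots[[nm]]) && is.list(cfg[[nm]])) {
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    } else {
      cfg[[nm]] <- dots[[nm]]
    }
  }
  structure(cfg, class = c("leaftex_config", "list"))
}

#' @rdname leaftex_config
#' @param path YAML file.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname leaftex_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) ltx_io_error("config file not found: %s", path)
  raw <- yaml::read_yaml(path)
  cfg <- leaftex_config()
  for (nm in names(raw)) {
    if (is.list(raw[[nm]]) && is.list(cfg[[nm]])) {
      cfg[[nm]][names(raw[[nm]])] <- raw[[nm]]
    } else {
      cfg[[nm]] <- raw[[nm]]
    }
  }
  cfg
}

#' Sample and featurize the whole dataset
#'
#' Streams species by species: loads each micrograph, samples its patches,
#' balances the species to the per-species quota (stratified by source
#' image) and computes the base features immediately, so pixel data never
#' accumulates across species.
#'
#' @param manifest manifest data frame.
#' @param annotations annotation data frame.
#' @param cfg a `leaftex_config`.
#' @return base feature table (see [extract_features()]).
#' @export
pipeline_features <- function(manifest, annotations, cfg = leaftex_config()) {
  sampling <- cfg$sampling; fx <- cfg$features
  out <- NULL
  for (sp in sort(unique(manifest$species))) {
    rows <- which(manifest$species == sp)
    patches <- list()
    for (r in rows) {
      m <- load_micrograph(manifest[r, , drop = FALSE],
                           patch_size_um = sampling$patch_size_um)
      patches <- c(patches, sample_subimages(
        m, annotations, n = sampling$n_per_image,
        patch_size_um = sampling$patch_size_um, mode = sampling$mode,
        seed = derive_seed(cfg$seed, 31L * r)))
    }
    patches <- balance_dataset(patches, per_species = sampling$per_species,
                               seed = derive_seed(cfg$seed, 7L))
    feats <- extract_features(patches, levels = fx$glcm_levels,
                              distances = fx$glcm_distances,
                              angles = fx$glcm_angles,
                              bins = fx$spectral_bins)
    out <- rbind(out, feats)
  }
  out
}

#' Run the full pipeline
#'
#' Executes sample -> features -> classify -> rank -> group -> stability and
#' writes every module's output plus a run log under `cfg$paths$out_dir`.
#' Idempotent given the seed: a rerun reproduces every analysis artifact
#' byte-identically (only the run log's wall time differs).
#'
#' @param cfg a `leaftex_config` whose `paths` entries are set.
#' @param manifest,annotations optional pre-loaded tables (otherwise read
#'   from `cfg$paths`).
#' @return invisibly, a list with `features`, `report`, `scores`, `groups`,
#'   `stability`, `loo` and the output directory.
#' @export
run_pipeline <- function(cfg, manifest = NULL, annotations = NULL) {
  t_start <- Sys.time()
  out_dir <- cfg$paths$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      ltx_stop("pipeline_error", "stage '%s' failed: %s", name,
               conditionMessage(e))
    })
  }
  if (is.null(manifest))
    manifest <- stage("io", read_manifest(cfg$paths$manifest))
  if (is.null(annotations))
    annotations <- stage("io", load_annotations(cfg$paths$annotations,
                                                manifest))
  features <- stage("features", pipeline_features(manifest, annotations, cfg))
  utils::write.csv(features, file.path(out_dir, "features.csv"),
                   row.names = FALSE)

  report <- stage("classify", {
    plan <- make_split(features, grouping = cfg$classifier$grouping,
                       n_folds = cfg$classifier$n_folds,
                       seed = derive_seed(cfg$seed, 101L))
    cross_validated_accuracy(features, plan, k = cfg$classifier$k,
                             n_components = cfg$features$n_components)
  })
  jsonlite::write_json(list(accuracy = report$accuracy,
                            per_fold_accuracy = report$per_fold_accuracy),
                       file.path(out_dir, "classification.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(as.data.frame.matrix(report$confusion),
                   file.path(out_dir, "confusion.csv"))

  rank_out <- stage("rank", {
    trip <- complexity_triplet(features)
    W <- run_tournament(trip,
                        pairs_per_species_pair =
                          cfg$tournament$pairs_per_species_pair,
                        seed = derive_seed(cfg$seed, 202L),
                        exhaustive = cfg$tournament$exhaustive,
                        mode = cfg$tournament$mode)
    list(trip = trip, W = W, scores = fit_bradley_terry(W))
  })
  utils::write.csv(rank_out$W$w, file.path(out_dir, "win_matrix.csv"))

  groups <- stage("group", {
    wf <- rank_out$W$patch_points
    tests <- pairwise_kw(data.frame(species = wf$species,
                                    value = wf$win_fraction),
                         adjust = cfg$grouping$adjust)
    cluster_groups(tests, alpha = cfg$grouping$alpha,
                   scores = rank_out$scores)
  })
  scores <- rank_out$scores
  scores$group <- unname(groups$assignment[scores$species])
  scores <- rank_species(scores)
  utils::write.csv(scores, file.path(out_dir, "scores.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(species = names(groups$assignment),
                              group = unname(groups$assignment)),
                   file.path(out_dir, "groups.csv"), row.names = FALSE)

  stab <- stage("stability", bootstrap_ranks(
    rank_out$trip, n_boot = cfg$stability$n_boot, frac = cfg$stability$frac,
    seed = derive_seed(cfg$seed, 303L),
    pairs_per_species_pair = cfg$tournament$pairs_per_species_pair,
    exhaustive = cfg$tournament$exhaustive))
  loo <- stage("stability", feature_loo(
    rank_out$trip, seed = derive_seed(cfg$seed, 404L),
    pairs_per_species_pair = cfg$tournament$pairs_per_species_pair,
    exhaustive = cfg$tournament$exhaustive))
  jsonlite::write_json(list(
    bootstrap = list(n_boot = stab$n_boot, frac = stab$frac,
                     rho_mean = stab$rho_mean, rho_sd = stab$rho_sd,
                     per_replicate_rho = stab$per_replicate_rho,
                     zero_variance_count = stab$zero_variance_count),
    feature_loo = lapply(loo$configurations, function(cc)
      list(dropped = cc$dropped, rho = cc$rho))
  ), file.path(out_dir, "stability.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(stab$ranks, file.path(out_dir, "bootstrap_ranks.csv"))

  write_config(cfg, file.path(out_dir, "config_resolved.yaml"))
  log <- list(seed = cfg$seed,
              r_version = as.character(getRversion()),
              package_version = as.character(utils::packageVersion("leaftex")),
              n_patches = nrow(features),
              n_species = length(unique(features$species)),
              wall_time_s = as.numeric(difftime(Sys.time(), t_start,
                                                units = "secs")))
  yaml::write_yaml(log, file.path(out_dir, "run_log.yaml"))
  invisible(list(features = features, report = report, scores = scores,
                 groups = groups, stability = stab, loo = loo,
                 out_dir = out_dir))
}
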