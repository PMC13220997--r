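# Rank-stability diagnostics: bootstrap resampling of patches and feature
# leave-one-out reruns of the tournament.

full_ranking <- function(triplets, pairs_per_species_pair, seed, features,
                         exhaustive, pseudocount = 0.5) {
  W <- run_tournament(triplets, pairs_per_species_pair, seed = seed,
                      features = features, exhaustive = exhaustive)
  fit_bradley_terry(W, pseudocount = pseudocount)
}

rank_vector <- function(scores) {
  stats::setNames(scores$rank, scores$species)
}

#' Bootstrap rank stability
#'
#' Each replicate resamples `floor(frac * n)` patches per species without
#' replacement (preserving class balance), reruns the tournament with
#' replicate-derived seeds (match pairings are redrawn) and refits the
#' Bradley-Terry score. Reported are the Spearman correlations between each
#' replicate's species ranking and the full-data ranking, and the
#' per-species rank variance across replicates.
#'
#' @param triplets triplet table (see [run_tournament()]).
#' @param n_boot number of replicates.
#' @param frac fraction of patches kept per species, in (0, 1].
#' @param seed master seed; replicate seeds are derived deterministically.
#' @param pairs_per_species_pair,exhaustive tournament controls.
#' @return a `leaftex_stability_report`: list with `n_boot`, `frac`,
#'   `per_replicate_rho`, `rho_mean`, `rho_sd`, `per_species_rank_variance`,
#'   `zero_variance_count`, `full_ranks` and the replicate rank matrix
#'   `ranks` (species x replicate).
#' @export
bootstrap_ranks <- function(triplets, n_boot = 20, frac = 0.8, seed = 1,
                            pairs_per_species_pair = 1000,
                            exhaustive = FALSE) {
  if (!(frac > 0 && frac <= 1))
    ltx_validation_error("frac must be in (0, 1], got %g", frac)
  full <- full_ranking(triplets, pairs_per_species_pair,
                       seed = derive_seed(seed, 0), features = TRIPLET,
                       exhaustive = exhaustive)
  full_ranks <- rank_vector(full)
  species <- names(full_ranks)
  rows_of <- split(seq_len(nrow(triplets)), triplets$species)
  ranks <- matrix(NA_real_, length(species), n_boot,
                  dimnames = list(species, NULL))
  rho <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    keep <- with_seed(derive_seed(seed, b), {
      unlist(lapply(rows_of, function(rows)
        sample(rows, max(2, floor(frac * length(rows))))), use.names = FALSE)
    })
    rep_fit <- full_ranking(triplets[sort(keep), , drop = FALSE],
                            pairs_per_species_pair,
                            seed = derive_seed(seed, 10000 + b),
                            features = TRIPLET, exhaustive = exhaustive)
    rr <- rank_vector(rep_fit)[species]
    ranks[, b] <- rr
    rho[b] <- spearman_rho(full_ranks, rr)
  }
  rank_var <- apply(ranks, 1, stats::var)
  structure(list(
    n_boot = n_boot, frac = frac, per_replicate_rho = rho,
    rho_mean = mean(rho), rho_sd = stats::sd(rho),
    per_species_rank_variance = rank_var,
    zero_variance_count = sum(rank_var == 0),
    full_ranks = full_ranks, ranks = ranks
  ), class = "leaftex_stability_report")
}

#' @export
print.leaftex_stability_report <- function(x, ...) {
  cat(sprintf(
    "<leaftex_stability_report> n_boot %d, frac %.2f: rho %.4f +/- %.4f; %d/%d species with zero rank variance\n",
    x$n_boot, x$frac, x$rho_mean, x$rho_sd, x$zero_variance_count,
    length(x$per_species_rank_variance)))
  invisible(x)
}

#' Feature leave-one-out rank stability
#'
#' Reruns the tournament three times, each time dropping one triplet
#' feature (two duels per match), refits the ranking and reports its
#' Spearman correlation with the full three-feature ranking. Values near 1
#' for every configuration mean no single feature dominates the ranking.
#'
#' @inheritParams bootstrap_ranks
#' @return a `leaftex_loo_report`: list with `full_ranks` and
#'   `configurations`, one entry per dropped feature holding `features`,
#'   `ranks` and `rho`.
#' @export
feature_loo <- function(triplets, seed = 1, pairs_per_species_pair = 1000,
                        exhaustive = FALSE) {
  full <- full_ranking(triplets, pairs_per_species_pair,
                       seed = derive_seed(seed, 0), features = TRIPLET,
                       exhaustive = exhaustive)
  full_ranks <- rank_vector(full)
  configurations <- lapply(seq_along(TRIPLET), function(i) {
    feats <- TRIPLET[-i]
    fit <- full_ranking(triplets, pairs_per_species_pair,
                        seed = derive_seed(seed, 20000 + i),
                        features = feats, exhaustive = exhaustive)
    rr <- rank_vector(fit)[names(full_ranks)]
    list(dropped = TRIPLET[i], features = feats, ranks = rr,
         rho = spearman_rho(full_ranks, rr))
  })
  names(configurations) <- paste0("drop_", TRIPLET)
  structure(list(full_ranks = full_ranks, configurations = configurations),
            class = "leaftex_loo_report")
}

#' @export
print.leaftex_loo_report <- function(x, ...) {
  rhos <- vapply(x$configurations, `[[`, 0, "rho")
  cat(sprintf("<leaftex_loo_report> Spearman rho %.3f - %.3f across %d configurations\n",
              min(rhos), max(rhos), length(rhos)))
  invisible(x)
}
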