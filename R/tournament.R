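# The pairwise complexity game and the Bradley-Terry species score.
#
# Every match pits one patch of species i against one patch of species j.
# Each of the three triplet features (info_density, heterogeneity,
# variability) is compared independently and contributes one point: the
# strictly greater value wins the point, exact equality splits it. Species
# are the players of the Bradley-Terry model, P(i beats j) = pi_i /
# (pi_i + pi_j); abilities are fitted by minorization-maximization on the
# accumulated win credits, with a small pseudocount so the maximum
# likelihood estimate exists even under total domination.

TRIPLET <- c("info_density", "heterogeneity", "variability")

#' Duel two complexity triplets
#'
#' Three independent comparisons, one per feature; a strictly greater value
#' wins that feature's point, exact equality ties it. The outcome is
#' antisymmetric by construction.
#'
#' @param a,b named vectors/lists or 1-row data frames with finite
#'   `info_density`, `heterogeneity`, `variability`.
#' @param features feature subset to duel on (default all three).
#' @return list `wins_a`, `wins_b`, `ties` summing to `length(features)`.
#' @export
duel <- function(a, b, features = TRIPLET) {
  av <- vapply(features, function(f) as.numeric(a[[f]]), 0)
  bv <- vapply(features, function(f) as.numeric(b[[f]]), 0)
  if (!all(is.finite(av)) || !all(is.finite(bv)))
    ltx_validation_error("non-finite triplet feature in duel")
  list(wins_a = sum(av > bv), wins_b = sum(bv > av), ties = sum(av == bv))
}

#' Run the pairwise complexity tournament
#'
#' For every unordered species pair, draws `pairs_per_species_pair` seeded
#' patch pairs (one patch from each side, uniform with replacement) — or
#' enumerates all cross pairs when `exhaustive = TRUE` — and accumulates the
#' feature points into a species-level win matrix, ties counting half to
#' each side. Within-species matches are not played. Per-patch win
#' fractions (points won / points contested) are retained for the grouping
#' statistics.
#'
#' @param triplets data frame with `patch_id`, `species` and the triplet
#'   columns (see [complexity_triplet()]).
#' @param pairs_per_species_pair sampled matches per species pair.
#' @param seed integer seed.
#' @param features feature subset to duel on.
#' @param exhaustive play every cross pair exactly once instead of sampling.
#' @param mode `"per_feature"` (each feature contributes its own point,
#'   default) or `"majority"` (one point per match to the winner of the
#'   feature majority).
#' @return a `leaftex_winmatrix`: list with `species`, `w` (win credits),
#'   `n_matches` (points contested) and `patch_points` (per-patch
#'   `points_won`, `points_contested`, `win_fraction`).
#' @export
run_tournament <- function(triplets, pairs_per_species_pair = 1000, seed = 1,
                           features = TRIPLET, exhaustive = FALSE,
                           mode = c("per_feature", "majority")) {
  mode <- match.arg(mode)
  stopifnot_cols(triplets, c("patch_id", "species", features),
                 "triplet table")
  if (!all(vapply(features, function(f) all(is.finite(triplets[[f]])), TRUE)))
    ltx_validation_error("non-finite triplet feature values")
  species <- sort(unique(triplets$species))
  if (length(species) < 2)
    ltx_validation_error("tournament needs at least 2 species")
  counts <- table(triplets$species)
  if (any(counts < 2))
    ltx_validation_error("species with < 2 patches: %s",
                         paste(names(counts)[counts < 2], collapse = ", "))
  ns <- length(species)
  w <- matrix(0, ns, ns, dimnames = list(species, species))
  n_matches <- matrix(0L, ns, ns, dimnames = list(species, species))
  pts_won <- stats::setNames(numeric(nrow(triplets)), triplets$patch_id)
  pts_contested <- pts_won
  rows_of <- split(seq_len(nrow(triplets)), triplets$species)
  fmat <- as.matrix(triplets[, features, drop = FALSE])
  with_seed(seed, {
    for (i in seq_len(ns - 1)) for (j in (i + 1):ns) {
      ri <- rows_of[[species[i]]]; rj <- rows_of[[species[j]]]
      if (exhaustive) {
        grid <- expand.grid(a = ri, b = rj)
        ia <- grid$a; ib <- grid$b
      } else {
        ia <- ri[sample.int(length(ri), pairs_per_species_pair,
                            replace = TRUE)]
        ib <- rj[sample.int(length(rj), pairs_per_species_pair,
                            replace = TRUE)]
      }
      A <- fmat[ia, , drop = FALSE]; B <- fmat[ib, , drop = FALSE]
      gt <- A > B; lt <- A < B; eq <- A == B
      if (mode == "per_feature") {
        wa <- rowSums(gt) + 0.5 * rowSums(eq)
        wb <- rowSums(lt) + 0.5 * rowSums(eq)
        per_match_pts <- length(features)
      } else {
        na_ <- rowSums(gt); nb_ <- rowSums(lt)
        wa <- (na_ > nb_) + 0.5 * (na_ == nb_)
        wb <- (nb_ > na_) + 0.5 * (na_ == nb_)
        per_match_pts <- 1
      }
      w[i, j] <- w[i, j] + sum(wa)
      w[j, i] <- w[j, i] + sum(wb)
      n_matches[i, j] <- n_matches[i, j] + length(ia) * per_match_pts
      n_matches[j, i] <- n_matches[i, j]
      add_a <- rowsum(wa, ia); add_b <- rowsum(wb, ib)
      cnt_a <- rowsum(rep(per_match_pts, length(ia)), ia)
      cnt_b <- rowsum(rep(per_match_pts, length(ib)), ib)
      pa <- as.integer(rownames(add_a)); pb <- as.integer(rownames(add_b))
      pts_won[pa] <- pts_won[pa] + add_a[, 1]
      pts_won[pb] <- pts_won[pb] + add_b[, 1]
      pts_contested[pa] <- pts_contested[pa] + cnt_a[, 1]
      pts_contested[pb] <- pts_contested[pb] + cnt_b[, 1]
    }
  })
  patch_points <- data.frame(
    patch_id = triplets$patch_id, species = triplets$species,
    points_won = unname(pts_won), points_contested = unname(pts_contested),
    win_fraction = ifelse(pts_contested > 0, pts_won / pts_contested, NA),
    stringsAsFactors = FALSE)
  structure(list(species = species, w = w, n_matches = n_matches,
                 patch_points = patch_points, mode = mode,
                 features = features),
            class = "leaftex_winmatrix")
}

#' @export
print.leaftex_winmatrix <- function(x, ...) {
  cat(sprintf("<leaftex_winmatrix> %d species, %d points contested\n",
              length(x$species), sum(x$n_matches) / 2))
  invisible(x)
}

#' Fit the Bradley-Terry complexity score
#'
#' Maximizes the Bradley-Terry likelihood over the accumulated win credits
#' by minorization-maximization: `pi_i <- W_i / sum_j n_ij / (pi_i + pi_j)`.
#' A pseudocount is added to every ordered species pair so the maximum
#' likelihood estimate is finite even when one species dominates another
#' completely. Abilities are normalized to `sum(log pi) = 0`; the reported
#' score is the min-max normalization of `log pi` to \[0, 1\] (all 0.5 when
#' the abilities are exactly equal), and rank 1 is the least complex
#' species.
#'
#' @param W a `leaftex_winmatrix`.
#' @param max_iter,tol convergence controls: stop when
#'   `max |delta log pi| < tol`.
#' @param pseudocount win credit added to each ordered pair (0 disables).
#' @return a `leaftex_scores` data frame: `species`, `bt_ability`,
#'   `log_ability`, `score`, `rank`, `group` (NA until grouping).
#' @export
fit_bradley_terry <- function(W, max_iter = 10000, tol = 1e-10,
                              pseudocount = 0.5) {
  stopifnot(inherits(W, "leaftex_winmatrix"))
  ns <- length(W$species)
  w <- W$w + pseudocount
  diag(w) <- 0
  n <- w + t(w)
  if (any(rowSums(w) == 0) || any(colSums(w) == 0))
    ltx_validation_error(
      "comparison graph not connected: a species has no wins or no losses")
  wins <- rowSums(w)
  mm_step <- function(l) {
    pi_ <- exp(l)
    denom <- vapply(seq_len(ns), function(i)
      sum(n[i, -i] / (pi_[i] + pi_[-i])), 0)
    l2 <- log(wins / denom)
    l2 - mean(l2)
  }
  # MM with SQUAREM-style extrapolation: same fixed point, but the plain
  # update converges only linearly (very slowly under near-domination)
  l <- rep(0, ns)
  delta <- Inf
  for (it in seq_len(max_iter)) {
    l1 <- mm_step(l)
    l2 <- mm_step(l1)
    r <- l1 - l; v <- l2 - l1 - r
    alpha <- if (sum(v^2) > 0) -sqrt(sum(r^2) / sum(v^2)) else -1
    cand <- l - 2 * alpha * r + alpha^2 * v
    cand <- if (all(is.finite(cand))) mm_step(cand) else l2
    if (!all(is.finite(cand))) cand <- l2
    delta <- max(abs(cand - l))
    l <- cand
    if (delta < tol) break
  }
  pi_ <- exp(l)
  if (delta >= tol)
    ltx_stop("convergence_error",
             "Bradley-Terry fit did not converge in %d iterations (last max |delta log pi| = %.3g)",
             max_iter, delta)
  logp <- log(pi_)
  rng <- range(logp)
  score <- if (diff(rng) > 0) (logp - rng[1]) / diff(rng) else
    rep(0.5, ns)
  ord <- order(score, W$species)
  rank <- integer(ns); rank[ord] <- seq_len(ns)
  structure(data.frame(species = W$species, bt_ability = pi_,
                       log_ability = logp, score = score, rank = rank,
                       group = NA_character_, stringsAsFactors = FALSE),
            class = c("leaftex_scores", "data.frame"))
}

#' Order the score table by complexity
#'
#' Stable ascending sort by score (rank 1 = least complex), ties broken
#' lexicographically by species name.
#'
#' @param table a `leaftex_scores` data frame.
#' @export
rank_species <- function(table) {
  stopifnot_cols(table, c("species", "score"), "score table")
  out <- table[order(table$score, table$species), , drop = FALSE]
  rownames(out) <- NULL
  out
}
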