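# Complexity grouping: species whose per-patch complexity distributions are
# statistically indistinguishable are merged into one group.
#
# The per-species sample entering the tests is the per-patch tournament win
# fraction, the only per-sample scalar complexity the pipeline defines.

#' Pairwise Kruskal-Wallis tests between species
#'
#' Runs a two-sample Kruskal-Wallis test (rank-based H with tie correction,
#' chi-square approximation, df = 1) on the per-patch values of every
#' species pair and adjusts the p-values by Benjamini-Hochberg across the
#' whole pair family. A parametric one-way ANOVA variant is available for
#' sensitivity analysis.
#'
#' @param per_patch data frame with `species` and `value` columns (e.g.
#'   `patch_points` from [run_tournament()] with `value = win_fraction`).
#' @param adjust `"BH"` (default) or `"none"`.
#' @param test `"kruskal"` (default) or `"anova"`.
#' @return a `leaftex_pairtests`: list with `species`, symmetric matrices
#'   `H` (statistics), `p_raw` and `p_adj` (diagonal p = 1).
#' @export
pairwise_kw <- function(per_patch, adjust = c("BH", "none"),
                        test = c("kruskal", "anova")) {
  adjust <- match.arg(adjust); test <- match.arg(test)
  stopifnot_cols(per_patch, c("species", "value"), "per-patch table")
  per_patch <- per_patch[is.finite(per_patch$value), , drop = FALSE]
  counts <- table(per_patch$species)
  if (any(counts < 3))
    ltx_validation_error("species with < 3 values: %s",
                         paste(names(counts)[counts < 3], collapse = ", "))
  species <- sort(unique(per_patch$species))
  ns <- length(species)
  H <- matrix(0, ns, ns, dimnames = list(species, species))
  p_raw <- matrix(1, ns, ns, dimnames = list(species, species))
  vals <- split(per_patch$value, per_patch$species)
  for (i in seq_len(ns - 1)) for (j in (i + 1):ns) {
    x <- vals[[species[i]]]; y <- vals[[species[j]]]
    res <- if (test == "kruskal")
      stats::kruskal.test(list(x, y)) else
      stats::oneway.test(value ~ g,
                         data = data.frame(value = c(x, y),
                                           g = rep(c("a", "b"),
                                                   c(length(x), length(y)))),
                         var.equal = TRUE)
    H[i, j] <- H[j, i] <- unname(res$statistic)
    p_raw[i, j] <- p_raw[j, i] <- res$p.value
  }
  upper <- upper.tri(p_raw)
  p_adj <- p_raw
  p_adj[upper] <- if (adjust == "BH")
    stats::p.adjust(p_raw[upper], method = "BH") else p_raw[upper]
  p_adj[lower.tri(p_adj)] <- t(p_adj)[lower.tri(p_adj)]
  structure(list(species = species, H = H, p_raw = p_raw, p_adj = p_adj,
                 adjust = adjust, test = test),
            class = "leaftex_pairtests")
}

#' Cluster species into complexity groups
#'
#' Converts adjusted p-values into the dissimilarity `-log10(max(p_adj,
#' 1e-16))`, runs average-linkage agglomerative clustering and cuts the tree
#' at height `-log10(alpha)`: species pairs indistinguishable at level
#' `alpha` tend to co-group. Group labels are ordered by the ascending
#' median complexity score of their members when a score table is supplied
#' (group 1 contains the least complex species).
#'
#' @param tests a `leaftex_pairtests`.
#' @param alpha significance level for the tree cut.
#' @param scores optional `leaftex_scores` table used to order group labels.
#' @return a `leaftex_groups`: list with `assignment` (named character
#'   vector species -> group label), `linkage` (the `hclust` object),
#'   `alpha` and `n_groups`.
#' @export
cluster_groups <- function(tests, alpha = 0.05, scores = NULL) {
  stopifnot(inherits(tests, "leaftex_pairtests"))
  ns <- length(tests$species)
  if (ns == 1) {
    assignment <- stats::setNames("1", tests$species)
    return(structure(list(assignment = assignment, linkage = NULL,
                          alpha = alpha, n_groups = 1L),
                     class = "leaftex_groups"))
  }
  d <- -log10(pmax(tests$p_adj, 1e-16))
  diag(d) <- 0
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  cl <- stats::cutree(hc, h = -log10(alpha))
  key <- if (!is.null(scores)) {
    s <- stats::setNames(scores$score, scores$species)[tests$species]
    vapply(split(s, cl), stats::median, 0)
  } else {
    vapply(split(tests$species, cl), min, "")
  }
  # relabel clusters so group 1 has the smallest ordering key
  new_id <- match(as.character(cl), names(sort(key)))
  assignment <- stats::setNames(as.character(new_id), tests$species)
  structure(list(assignment = assignment, linkage = hc, alpha = alpha,
                 n_groups = length(unique(assignment))),
            class = "leaftex_groups")
}

#' @export
print.leaftex_groups <- function(x, ...) {
  cat(sprintf("<leaftex_groups> %d group(s) at alpha = %g\n", x$n_groups,
              x$alpha))
  invisible(x)
}
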