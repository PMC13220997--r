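# Shared fixtures, built in code and memoised for the session.

.ltx_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .ltx_cache)) assign(key, expr, envir = .ltx_cache)
  get(key, envir = .ltx_cache)
}

const_patch <- function(value = 100L, n = 512) matrix(as.integer(value), n, n)

noise_patch <- function(seed = 1, n = 512) {
  with_test_seed(seed, matrix(sample(0:255, n * n, replace = TRUE), n))
}

with_test_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

blur_patch <- function(patch, sigma = 4) {
  b <- EBImage::gblur(patch / 255, sigma = sigma) * 255
  matrix(as.integer(pmin(pmax(round(b), 0), 255)), nrow(patch))
}

# Brute-force GLCM oracle: explicit pair enumeration on small arrays.
glcm_oracle <- function(patch, levels, dr, dc) {
  q <- matrix(pmin(as.integer(patch) %/% as.integer(ceiling(256 / levels)),
                   levels - 1L), nrow(patch))
  P <- matrix(0, levels, levels)
  H <- nrow(q); W <- ncol(q)
  for (r in seq_len(H)) for (c in seq_len(W)) {
    r2 <- r + dr; c2 <- c + dc
    if (r2 >= 1 && r2 <= H && c2 >= 1 && c2 <= W) {
      i <- q[r, c] + 1; j <- q[r2, c2] + 1
      P[i, j] <- P[i, j] + 1
      P[j, i] <- P[j, i] + 1
    }
  }
  P <- P / sum(P)
  i <- row(P) - 1; j <- col(P) - 1
  nz <- P > 0
  pi_ <- rowSums(P)
  mu <- sum((0:(levels - 1)) * pi_)
  s2 <- sum(((0:(levels - 1)) - mu)^2 * pi_)
  c(glcm_asm = sum(P^2), glcm_contrast = sum(P * (i - j)^2),
    glcm_entropy = -sum(P[nz] * log2(P[nz])),
    glcm_homogeneity = sum(P / (1 + (i - j)^2)),
    glcm_correlation = if (s2 > 0) sum((i - mu) * (j - mu) * P) / s2 else 0)
}

# Bradley-Terry log-likelihood of win matrix w under log-abilities l.
bt_loglik <- function(w, l) {
  ll <- 0
  ns <- nrow(w)
  for (i in seq_len(ns)) for (j in seq_len(ns)) if (i != j)
    ll <- ll + w[i, j] * (l[i] - log(exp(l[i]) + exp(l[j])))
  ll
}

# Coarse-to-fine grid search over sum-zero log-abilities (2 or 3 players);
# final resolution 0.001.
bt_grid_search <- function(w) {
  ns <- nrow(w)
  stopifnot(ns %in% c(2, 3))
  centre <- rep(0, ns - 1)
  width <- 3
  for (step in c(0.05, 0.01, 0.001)) {
    grid1 <- seq(centre[1] - width, centre[1] + width, by = step)
    if (ns == 2) {
      lls <- vapply(grid1, function(a) bt_loglik(w, c(a, -a)), 0)
      centre <- grid1[which.max(lls)]
    } else {
      grid2 <- seq(centre[2] - width, centre[2] + width, by = step)
      best <- -Inf
      for (a in grid1) {
        lls <- vapply(grid2, function(b) bt_loglik(w, c(a, b, -a - b)), 0)
        k <- which.max(lls)
        if (lls[k] > best) { best <- lls[k]; centre <- c(a, grid2[k]) }
      }
    }
    width <- 2 * step
  }
  if (ns == 2) c(centre, -centre) else c(centre, -sum(centre))
}

# Small synthetic benchmark shared across test files: 6 species, 2 images
# each at 512 px, 20 patches per image balanced to 30 per species.
small_bench <- function() memo("small_bench", {
  generate_benchmark(out_dir = file.path(tempdir(), "leaftex_small_bench"),
                     n_species = 6, images_per_species = 2, size_px = 768,
                     seed = 42)
})

small_features <- function() memo("small_features", {
  bench <- small_bench()
  ann <- load_annotations(file.path(bench$dir, "annotations.csv"),
                          bench$manifest)
  cfg <- leaftex_config(seed = 42,
                        sampling = list(n_per_image = 20, per_species = 30))
  pipeline_features(bench$manifest, ann, cfg)
})

# Full default benchmark (10 species x 4 images at 2048 px, seed 42),
# featurized once and shared by the acceptance-grade tests. Expensive
# (minutes), hence memoised.
default_bench_features <- function() memo("default_bench", {
  bench <- generate_benchmark(
    out_dir = file.path(tempdir(), "leaftex_default_bench"), seed = 42)
  ann <- load_annotations(file.path(bench$dir, "annotations.csv"),
                          bench$manifest)
  feats <- pipeline_features(bench$manifest, ann, leaftex_config(seed = 42))
  list(bench = bench, features = feats)
})

# Abstract (non-image) feature table for classifier tests: well-separated
# species in every base feature plus structured spectra.
fake_features <- function(n_species = 10, groups_per_species = 4,
                          patches_per_group = 12, sep = 6, seed = 1,
                          bins = 64) {
  with_test_seed(seed, {
    rows <- list()
    for (s in seq_len(n_species)) {
      for (g in seq_len(groups_per_species)) {
        n <- patches_per_group
        base <- matrix(stats::rnorm(n * 8, mean = s * sep), n, 8)
        colnames(base) <- c("glcm_asm", "glcm_contrast", "glcm_entropy",
                            "glcm_homogeneity", "glcm_correlation",
                            "grad_mean", "grad_std", "compression_bpp")
        spec <- matrix(stats::rnorm(n * bins, mean = sin(s + seq_len(bins) / 8)),
                       n, bins, byrow = FALSE)
        colnames(spec) <- paste0("spec_bin_", seq_len(bins))
        sp_name <- sprintf("sp%02d", s)
        rows[[length(rows) + 1]] <- cbind(
          data.frame(patch_id = sprintf("%s_g%d_p%03d", sp_name, g,
                                        seq_len(n)),
                     image_id = sprintf("%s_img%d", sp_name, g),
                     species = sp_name,
                     tree_id = sprintf("%s_t%d", sp_name, (g - 1) %% 2 + 1),
                     leaf_id = sprintf("%s_leaf%d", sp_name, g),
                     batch_id = "B1", stringsAsFactors = FALSE),
          as.data.frame(base), as.data.frame(spec))
      }
    }
    do.call(rbind, rows)
  })
}

# Simple triplet table: per-species feature levels with optional noise.
fake_triplets <- function(levels, n_per_species = 10, noise = 0.01,
                          seed = 1) {
  with_test_seed(seed, {
    do.call(rbind, lapply(seq_along(levels), function(i) {
      sp <- sprintf("sp%02d", i)
      data.frame(
        patch_id = sprintf("%s_p%03d", sp, seq_len(n_per_species)),
        species = sp,
        info_density = levels[i] + stats::rnorm(n_per_species, sd = noise),
        heterogeneity = levels[i] + stats::rnorm(n_per_species, sd = noise),
        variability = levels[i] + stats::rnorm(n_per_species, sd = noise),
        stringsAsFactors = FALSE)
    }))
  })
}

make_winmatrix <- function(w, n_matches = NULL) {
  species <- rownames(w)
  if (is.null(n_matches)) n_matches <- w + t(w)
  structure(list(species = species, w = w, n_matches = n_matches,
                 patch_points = NULL, mode = "per_feature",
                 features = c("info_density", "heterogeneity",
                              "variability")),
            class = "leaftex_winmatrix")
}

make_pairtests <- function(species, p_adj, H = NULL) {
  dimnames(p_adj) <- list(species, species)
  if (is.null(H)) H <- 0 * p_adj
  structure(list(species = species, H = H, p_raw = p_adj, p_adj = p_adj,
                 adjust = "BH", test = "kruskal"),
            class = "leaftex_pairtests")
}
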