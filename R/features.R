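# Per-patch texture features.
#
# Four families are computed per 512 x 512 patch:
#   * gray-level co-occurrence (GLCM) statistics, isotropically averaged
#     over offsets {1,2,4} px x angles {0,45,90,135} deg at 64 gray levels;
#   * a radially averaged log power spectrum (64 bins) reduced to 25
#     principal components fitted on training patches only;
#   * Sobel gradient magnitude mean and standard deviation;
#   * lossless compression density in bits per pixel (zlib/DEFLATE of the
#     raw row-major bytes, fixed codec so the value is deterministic).
#
# The complexity triplet driving the pairwise game is
#   info_density  = compression_bpp
#   heterogeneity = 1 - glcm_asm      (bounded complement of the angular
#                                      second moment)
#   variability   = grad_std

GLCM_NAMES <- c("glcm_asm", "glcm_contrast", "glcm_entropy",
                "glcm_homogeneity", "glcm_correlation")

# Offset (dr, dc) for a distance and angle, matching the usual image
# convention: 0 deg = along a row, 90 deg = up the columns.
glcm_offset <- function(distance, angle) {
  switch(as.character(angle),
         "0" = c(0L, distance),
         "45" = c(-distance, distance),
         "90" = c(-distance, 0L),
         "135" = c(-distance, -distance),
         ltx_validation_error("unsupported GLCM angle %s", angle))
}

glcm_single <- function(q, levels, dr, dc) {
  H <- nrow(q); W <- ncol(q)
  r1 <- max(1L, 1L - dr):min(H, H - dr)
  c1 <- max(1L, 1L - dc):min(W, W - dc)
  a <- q[r1, c1, drop = FALSE]
  b <- q[r1 + dr, c1 + dc, drop = FALSE]
  counts <- tabulate(as.integer(a) * levels + as.integer(b) + 1L,
                     nbins = levels * levels)
  P <- matrix(counts, levels, levels, byrow = TRUE)
  P <- P + t(P)                      # symmetric pairs
  P / sum(P)
}

glcm_stats <- function(P) {
  L <- nrow(P)
  i <- row(P) - 1; j <- col(P) - 1
  asm <- sum(P^2)
  contrast <- sum(P * (i - j)^2)
  nz <- P > 0
  entropy <- -sum(P[nz] * log2(P[nz]))
  homogeneity <- sum(P / (1 + (i - j)^2))
  pi_ <- rowSums(P)
  mu_i <- sum((0:(L - 1)) * pi_)
  sd_i <- sqrt(sum(((0:(L - 1)) - mu_i)^2 * pi_))
  correlation <- if (sd_i > 0)
    sum((i - mu_i) * (j - mu_i) * P) / sd_i^2 else 0
  c(glcm_asm = asm, glcm_contrast = contrast, glcm_entropy = entropy,
    glcm_homogeneity = homogeneity, glcm_correlation = correlation)
}

#' Gray-level co-occurrence features of a patch
#'
#' Quantizes intensities linearly into `levels` bins, builds a symmetric
#' normalized co-occurrence matrix for every (distance, angle) pair and
#' returns the isotropic (arithmetic mean over pairs) angular second moment,
#' contrast, entropy (bits), homogeneity and correlation. A constant patch
#' is valid input (ASM 1, entropy and contrast 0, correlation 0 by
#' convention).
#'
#' @param patch integer matrix with values in 0-255 (8-bit gray).
#' @param levels number of quantization bins.
#' @param distances pixel offsets.
#' @param angles offsets directions in degrees (subset of 0, 45, 90, 135).
#' @return named numeric vector `glcm_asm`, `glcm_contrast`, `glcm_entropy`,
#'   `glcm_homogeneity`, `glcm_correlation`.
#' @export
glcm_features <- function(patch, levels = 64, distances = c(1, 2, 4),
                          angles = c(0, 45, 90, 135)) {
  stopifnot(is.matrix(patch), levels >= 2)
  q <- matrix(pmin(as.integer(patch) %/% as.integer(ceiling(256 / levels)),
                   levels - 1L), nrow(patch))
  acc <- matrix(0, length(distances) * length(angles), 5)
  k <- 0
  for (d in distances) for (ang in angles) {
    off <- glcm_offset(as.integer(d), ang)
    k <- k + 1
    acc[k, ] <- glcm_stats(glcm_single(q, levels, off[1], off[2]))
  }
  stats::setNames(colMeans(acc), GLCM_NAMES)
}

#' Sobel gradient magnitude statistics
#'
#' Applies 3x3 Sobel operators with reflected borders and returns the mean
#' and population standard deviation of the gradient magnitude.
#'
#' @param patch numeric or integer matrix.
#' @return named vector `grad_mean`, `grad_std`.
#' @export
gradient_features <- function(patch) {
  stopifnot(is.matrix(patch))
  x <- matrix(as.double(patch), nrow(patch))
  H <- nrow(x); W <- ncol(x)
  # reflect-pad by one pixel
  p <- rbind(x[1, , drop = FALSE], x, x[H, , drop = FALSE])
  p <- cbind(p[, 1, drop = FALSE], p, p[, W, drop = FALSE])
  sh <- function(dr, dc) p[(2 + dr):(H + 1 + dr), (2 + dc):(W + 1 + dc)]
  gx <- (sh(-1, 1) + 2 * sh(0, 1) + sh(1, 1)) -
        (sh(-1, -1) + 2 * sh(0, -1) + sh(1, -1))
  gy <- (sh(1, -1) + 2 * sh(1, 0) + sh(1, 1)) -
        (sh(-1, -1) + 2 * sh(-1, 0) + sh(-1, 1))
  mag <- sqrt(gx^2 + gy^2)
  m <- mean(mag)
  c(grad_mean = m, grad_std = sqrt(mean((mag - m)^2)))
}

#' Compression-based information density
#'
#' Compresses the raw row-major byte stream of the patch with the fixed
#' zlib/DEFLATE codec and returns 8 x compressed_bytes / pixel_count (bits
#' per pixel). Low values indicate redundant, simple texture; values near 8
#' indicate incompressible, complex texture.
#'
#' @inheritParams gradient_features
#' @return `compression_bpp`, a scalar in roughly \[0, 8\].
#' @export
compression_feature <- function(patch) {
  stopifnot(is.matrix(patch))
  bytes <- as.raw(as.integer(t(patch)))  # row-major stream
  comp <- memCompress(bytes, type = "gzip")
  8 * length(comp) / length(bytes)
}

#' Radially averaged log power spectrum
#'
#' Subtracts the patch mean, applies the 2-D discrete Fourier transform and
#' averages log10(1 + power) into `bins` equal-width annuli of normalized
#' spatial frequency over (0, 0.5] cycles/pixel (the DC component and
#' corner frequencies beyond Nyquist are excluded). The representation is
#' invariant to 90-degree rotations by construction.
#'
#' @inheritParams gradient_features
#' @param bins number of radial frequency bins.
#' @return numeric vector of length `bins`.
#' @export
radial_spectrum <- function(patch, bins = 64) {
  stopifnot(is.matrix(patch))
  x <- matrix(as.double(patch), nrow(patch))
  x <- x - mean(x)
  P <- Mod(stats::fft(x))^2
  lp <- log10(1 + P)
  H <- nrow(x); W <- ncol(x)
  fr <- fft_freq(H); fc <- fft_freq(W)
  r <- sqrt(outer(fr^2, fc^2, "+"))
  use <- r > 0 & r <= 0.5
  bin <- pmin(ceiling(r[use] / 0.5 * bins), bins)
  sums <- tabulate_sum(bin, lp[use], bins)
  n <- tabulate(bin, bins)
  out <- numeric(bins)
  out[n > 0] <- sums[n > 0] / n[n > 0]
  out
}

fft_freq <- function(n) {
  k <- 0:(n - 1)
  k[k > n / 2] <- k[k > n / 2] - n
  k / n
}

tabulate_sum <- function(bin, values, nbins) {
  out <- numeric(nbins)
  agg <- rowsum(values, bin)  # row names are the sorted unique bins
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' Fit the spectral PCA model
#'
#' Computes the radial log-spectrum of every training patch and fits a
#' principal component analysis, retaining the top `n_components` loadings.
#' The model is frozen after fitting: applying it to new patches is a
#' projection, never a refit, so later batches cannot leak into the
#' representation.
#'
#' @param x list of `leaftex_patch` objects (or bare matrices), or a numeric
#'   matrix of precomputed radial spectra (rows = patches).
#' @param n_components number of components to keep.
#' @param bins radial bins (ignored when `x` is already a spectrum matrix).
#' @return a `leaftex_spectral_model`: list with `radial_bins`,
#'   `mean_spectrum`, `components` (n_components x bins orthonormal rows)
#'   and `explained_variance`.
#' @export
fit_spectral_model <- function(x, n_components = 25, bins = 64) {
  S <- spectra_matrix(x, bins)
  if (nrow(S) < n_components + 1)
    ltx_validation_error(
      "need at least %d training patches to fit %d components (got %d)",
      n_components + 1, n_components, nrow(S))
  pca <- stats::prcomp(S, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pca$rotation))
  structure(list(
    radial_bins = ncol(S),
    mean_spectrum = as.numeric(pca$center),
    components = t(pca$rotation[, seq_len(k), drop = FALSE]),
    explained_variance = pca$sdev[seq_len(k)]^2
  ), class = "leaftex_spectral_model")
}

spectra_matrix <- function(x, bins) {
  if (is.matrix(x) && is.numeric(x)) return(x)
  stopifnot(is.list(x))
  t(vapply(x, function(p) {
    px <- if (inherits(p, "leaftex_patch")) p$pixels else p
    radial_spectrum(px, bins)
  }, numeric(bins)))
}

#' Project patches onto the spectral components
#'
#' @param model a fitted `leaftex_spectral_model`.
#' @inheritParams fit_spectral_model
#' @return numeric matrix (rows = patches, columns = `sp_1 ... sp_k` scores).
#' @export
spectral_transform <- function(model, x) {
  if (!inherits(model, "leaftex_spectral_model"))
    ltx_stop("state_error", "spectral model is not fitted")
  S <- spectra_matrix(x, model$radial_bins)
  if (ncol(S) != model$radial_bins)
    ltx_validation_error("spectrum has %d bins, model expects %d",
                         ncol(S), model$radial_bins)
  scores <- sweep(S, 2, model$mean_spectrum) %*% t(model$components)
  colnames(scores) <- paste0("sp_", seq_len(nrow(model$components)))
  scores
}

#' @rdname fit_spectral_model
#' @param path JSON file.
#' @export
write_spectral_model <- function(model, path) {
  jsonlite::write_json(list(
    radial_bins = model$radial_bins,
    mean_spectrum = model$mean_spectrum,
    components = model$components,
    explained_variance = model$explained_variance
  ), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname fit_spectral_model
#' @export
read_spectral_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(radial_bins = as.integer(obj$radial_bins),
                 mean_spectrum = as.numeric(obj$mean_spectrum),
                 components = as.matrix(obj$components),
                 explained_variance = as.numeric(obj$explained_variance)),
            class = "leaftex_spectral_model")
}

#' Base (spectral-model-free) features of a set of patches
#'
#' Computes the GLCM block, gradient statistics, compression density and the
#' raw radial spectrum (`spec_bin_*` columns) for each patch, together with
#' its provenance. The spectral PCA scores are added separately (see
#' [assemble_features()] / [add_spectral_scores()]) so that the model can be
#' refitted inside training folds without touching the pixels again.
#'
#' @param patches list of `leaftex_patch` objects.
#' @param levels,distances,angles GLCM parameters, see [glcm_features()].
#' @param bins radial spectrum bins.
#' @return data frame: patch provenance, feature columns and
#'   `spec_bin_1 ... spec_bin_bins`.
#' @export
extract_features <- function(patches, levels = 64, distances = c(1, 2, 4),
                             angles = c(0, 45, 90, 135), bins = 64) {
  meta <- patch_manifest(patches)
  feats <- lapply(patches, function(p) {
    tryCatch({
      c(glcm_features(p$pixels, levels, distances, angles),
        gradient_features(p$pixels),
        compression_bpp = compression_feature(p$pixels),
        stats::setNames(radial_spectrum(p$pixels, bins),
                        paste0("spec_bin_", seq_len(bins))))
    }, error = function(e) {
      ltx_stop("feature_error", "feature computation failed for patch '%s': %s",
               p$patch_id, conditionMessage(e))
    })
  })
  cbind(meta, as.data.frame(do.call(rbind, feats)))
}

#' Assemble the full feature table
#'
#' Joins base features, spectral PCA scores and the complexity triplet
#' (`info_density` = compression_bpp, `heterogeneity` = 1 - glcm_asm,
#' `variability` = grad_std) into one row per patch. The model must have
#' been fitted on a training partition disjoint from any test set this table
#' is used to evaluate.
#'
#' @inheritParams extract_features
#' @param model fitted `leaftex_spectral_model`.
#' @return data frame of feature vectors and triplet columns.
#' @export
assemble_features <- function(patches, model, levels = 64,
                              distances = c(1, 2, 4),
                              angles = c(0, 45, 90, 135)) {
  tbl <- extract_features(patches, levels, distances, angles,
                          bins = model$radial_bins)
  add_spectral_scores(tbl, model)
}

#' @rdname assemble_features
#' @param features feature table from [extract_features()].
#' @export
add_spectral_scores <- function(features, model) {
  spec_cols <- grep("^spec_bin_", names(features), value = TRUE)
  if (length(spec_cols) != model$radial_bins)
    ltx_validation_error("feature table has %d spectrum bins, model expects %d",
                         length(spec_cols), model$radial_bins)
  S <- as.matrix(features[, spec_cols])
  scores <- spectral_transform(model, S)
  out <- cbind(features[, setdiff(names(features), colnames(scores)),
                        drop = FALSE], as.data.frame(scores))
  out$info_density <- out$compression_bpp
  out$heterogeneity <- 1 - out$glcm_asm
  out$variability <- out$grad_std
  out
}

#' Extract the complexity triplet
#'
#' @param features feature table containing `compression_bpp`, `glcm_asm`
#'   and `grad_std` (and `species`/`patch_id` provenance).
#' @return data frame `patch_id`, `species`, `info_density`,
#'   `heterogeneity`, `variability`.
#' @export
complexity_triplet <- function(features) {
  stopifnot_cols(features, c("patch_id", "species", "compression_bpp",
                             "glcm_asm", "grad_std"), "feature table")
  data.frame(patch_id = features$patch_id, species = features$species,
             info_density = features$compression_bpp,
             heterogeneity = 1 - features$glcm_asm,
             variability = features$grad_std,
             stringsAsFactors = FALSE)
}
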