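# Synthetic micrograph generator with ground-truth complexity ordering.
#
# A single scalar c in [0, 1] drives every texture parameter monotonically,
# so the true complexity ordering of generated species is unambiguous:
#   spectral slope beta   = 3 - 2c   (steep/smooth -> shallow/rough)
#   papilla density       = 30c per 100 um^2
#   wrinkle amplitude     = 20c gray levels
# Stomata are rendered as dark ellipses (8 x 4 um) so that roi-mode
# sampling sees realistic anchors, and their centres are returned as
# annotations.

#' Parameter bundle of one synthetic species
#'
#' @param name species label.
#' @param complexity_c scalar complexity parameter in \[0, 1\].
#' @param papilla_radius_um papilla radius.
#' @param stomata_density stomata per 10^4 um^2.
#' @param noise_sd i.i.d. sensor noise, gray levels.
#' @param striation_wavelength_um period of the species' cuticular
#'   striation pattern (epicuticular wax folds have a species-typical
#'   spacing); `NULL` disables striations.
#' @param striation_amplitude striation contrast in gray levels.
#' @return list of generator parameters (`spectral_slope_beta`,
#'   `papilla_density`, `wrinkle_amplitude` are derived from
#'   `complexity_c`).
#' @export
species_spec <- function(name, complexity_c, papilla_radius_um = 1.5,
                         stomata_density = 6, noise_sd = 4,
                         striation_wavelength_um = NULL,
                         striation_amplitude = 8) {
  stopifnot(complexity_c >= 0, complexity_c <= 1)
  list(name = name, complexity_c = complexity_c,
       spectral_slope_beta = 3 - 2 * complexity_c,
       papilla_density = 30 * complexity_c,
       papilla_radius_um = papilla_radius_um,
       wrinkle_amplitude = 20 * complexity_c,
       stomata_density = stomata_density,
       noise_sd = noise_sd,
       striation_wavelength_um = striation_wavelength_um,
       striation_amplitude = striation_amplitude)
}

# Narrowband isotropic texture: white noise filtered to a Gaussian ring of
# spatial frequencies around f_ring (cycles/pixel), unit variance. Models
# cuticular striations/wax folds with a species-typical spacing but no
# preferred global orientation.
ring_field <- function(n, f_ring, width_frac = 0.15) {
  w <- matrix(stats::rnorm(n * n), n)
  F <- stats::fft(w)
  f <- fft_freq(n)
  fr <- sqrt(outer(f^2, f^2, "+"))
  filt <- exp(-(fr - f_ring)^2 / (2 * (width_frac * f_ring)^2))
  filt[1, 1] <- 0
  x <- Re(stats::fft(F * filt, inverse = TRUE)) / (n * n)
  s <- stats::sd(x)
  if (s == 0) return(matrix(0, n, n))
  x / s
}

# 1/f^beta Gaussian random field, standardized to mean 128, sd 30.
spectral_field <- function(n, beta) {
  w <- matrix(stats::rnorm(n * n), n)
  F <- stats::fft(w)
  f <- fft_freq(n)
  fr <- sqrt(outer(f^2, f^2, "+"))
  filt <- fr
  filt[1, 1] <- Inf
  filt <- filt^(-beta / 2)
  filt[1, 1] <- 0
  x <- Re(stats::fft(F * filt, inverse = TRUE)) / (n * n)
  s <- stats::sd(x)
  if (s == 0) return(matrix(128, n, n))
  (x - mean(x)) / s * 30 + 128
}

add_bumps <- function(img, n_bumps, sigma_px, amplitude) {
  if (n_bumps == 0) return(img)
  n <- nrow(img)
  hw <- max(1L, as.integer(ceiling(3 * sigma_px)))
  xs <- seq(-hw, hw)
  stamp <- amplitude * exp(-outer(xs^2, xs^2, "+") / (2 * sigma_px^2))
  rs <- sample.int(n, n_bumps, replace = TRUE)
  cs <- sample.int(n, n_bumps, replace = TRUE)
  for (i in seq_len(n_bumps)) {
    r0 <- max(1L, rs[i] - hw); r1 <- min(n, rs[i] + hw)
    c0 <- max(1L, cs[i] - hw); c1 <- min(n, cs[i] + hw)
    img[r0:r1, c0:c1] <- img[r0:r1, c0:c1] +
      stamp[(r0 - rs[i] + hw + 1):(r1 - rs[i] + hw + 1),
            (c0 - cs[i] + hw + 1):(c1 - cs[i] + hw + 1)]
  }
  img
}

draw_stoma <- function(img, r, c, a_px, b_px, theta, depth = 70) {
  n <- nrow(img); m <- ncol(img)
  hw <- as.integer(ceiling(a_px)) + 1L
  r0 <- max(1L, r - hw); r1 <- min(n, r + hw)
  c0 <- max(1L, c - hw); c1 <- min(m, c + hw)
  rr <- (r0:r1) - r; cc <- (c0:c1) - c
  R <- matrix(rr, length(rr), length(cc))
  C <- matrix(cc, length(rr), length(cc), byrow = TRUE)
  u <- (R * cos(theta) + C * sin(theta)) / a_px
  v <- (-R * sin(theta) + C * cos(theta)) / b_px
  d2 <- u^2 + v^2
  # dark rim with a darker pore, soft edge
  mask <- pmax(0, 1 - d2)
  img[r0:r1, c0:c1] <- img[r0:r1, c0:c1] - depth * mask
  img
}

#' Generate one synthetic micrograph with stomata annotations
#'
#' Builds a 1/f^beta Gaussian random field (mean 128, sd 30), adds Gaussian
#' papillae at Poisson locations, low-frequency sinusoidal wrinkles and
#' i.i.d. sensor noise, renders stomata as dark 8 x 4 um ellipses at
#' Poisson locations and clips to 8-bit. Fully deterministic given the
#' seed.
#'
#' @param spec a [species_spec()].
#' @param size_px image side length in pixels.
#' @param pixel_size_um physical pixel size.
#' @param seed integer seed.
#' @param image_id identifier stamped on the output (default derived from
#'   the species name and seed).
#' @param provenance named list overriding `tree_id`, `leaf_id`, `batch_id`.
#' @return list with `micrograph` (a `leaftex_micrograph`) and
#'   `annotations` (data frame with 0-based `center_row`/`center_col`).
#' @export
generate_micrograph <- function(spec, size_px = 2048, pixel_size_um = 0.15625,
                                seed = 1,
                                image_id = sprintf("%s_s%d", spec$name, seed),
                                provenance = list()) {
  n <- as.integer(size_px)
  area_um2 <- (n * pixel_size_um)^2
  with_seed(seed, {
    img <- spectral_field(n, spec$spectral_slope_beta)
    # wrinkles: two low-frequency sinusoids of random orientation and phase
    if (spec$wrinkle_amplitude > 0) {
      coord <- seq_len(n) * pixel_size_um
      for (kk in 1:2) {
        theta <- stats::runif(1, 0, pi)
        lambda <- stats::runif(1, 40, 80)  # um
        phase <- stats::runif(1, 0, 2 * pi)
        wave <- outer(coord * cos(theta), coord * sin(theta), "+")
        img <- img + spec$wrinkle_amplitude / 2 *
          sin(2 * pi * wave / lambda + phase)
      }
    }
    # species-typical cuticular striations: narrowband isotropic texture
    # whose period is a species trait; the realization differs per image
    # but the (rotation-invariant) radial frequency identifies the species
    if (!is.null(spec$striation_wavelength_um) &&
        spec$striation_amplitude > 0) {
      f_ring <- pixel_size_um / spec$striation_wavelength_um
      img <- img + spec$striation_amplitude * ring_field(n, f_ring)
    }
    n_pap <- stats::rpois(1, spec$papilla_density * area_um2 / 100)
    sigma_px <- spec$papilla_radius_um / pixel_size_um / 2
    img <- add_bumps(img, n_pap, sigma_px, amplitude = 25)
    n_stoma <- stats::rpois(1, spec$stomata_density * area_um2 / 1e4)
    a_px <- 4 / pixel_size_um  # semi-major, 8 um major axis
    b_px <- 2 / pixel_size_um
    ann <- NULL
    if (n_stoma > 0) {
      rs <- sample.int(n, n_stoma, replace = TRUE)
      cs <- sample.int(n, n_stoma, replace = TRUE)
      thetas <- stats::runif(n_stoma, 0, pi)
      for (i in seq_len(n_stoma))
        img <- draw_stoma(img, rs[i], cs[i], a_px, b_px, thetas[i])
      ann <- data.frame(image_id = image_id,
                        stoma_index = seq_len(n_stoma) - 1L,
                        center_row = rs - 1L, center_col = cs - 1L,
                        major_axis_um = 8, exclusion = FALSE,
                        stringsAsFactors = FALSE)
    } else {
      ann <- data.frame(image_id = character(0), stoma_index = integer(0),
                        center_row = integer(0), center_col = integer(0),
                        major_axis_um = numeric(0), exclusion = logical(0))
    }
    img <- img + stats::rnorm(n * n, sd = spec$noise_sd)
    mg <- structure(list(
      image_id = image_id,
      pixels = clamp8(img),
      pixel_size_um = pixel_size_um,
      species = spec$name,
      tree_id = provenance$tree_id %||% paste0(spec$name, "_t1"),
      leaf_id = provenance$leaf_id %||% paste0(image_id, "_leaf"),
      batch_id = provenance$batch_id %||% "B1",
      magnification_tag = "1900x"
    ), class = "leaftex_micrograph")
    list(micrograph = mg, annotations = ann)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate the synthetic benchmark dataset
#'
#' Writes `n_species x images_per_species` micrographs (PNG), an annotation
#' CSV and a manifest CSV under `out_dir`, with the complexity parameter
#' evenly spaced over `c_range`. The layout is exactly what [read_manifest()]
#' and [load_annotations()] consume, so synthetic and real data are
#' interchangeable. Per-species provenance alternates two trees, one leaf
#' per image.
#'
#' @param out_dir output directory (created if needed).
#' @param n_species number of species.
#' @param images_per_species micrographs per species.
#' @param c_range range of the complexity parameter.
#' @param size_px,pixel_size_um image geometry.
#' @param seed master seed; per-image seeds are derived deterministically.
#' @return list with `manifest`, `annotations`, `species` (data frame of
#'   name and true complexity c) and `dir`.
#' @export
generate_benchmark <- function(out_dir = tempfile("leaftex_bench"),
                               n_species = 10, images_per_species = 4,
                               c_range = c(0.05, 0.95), size_px = 2048,
                               pixel_size_um = 0.15625, seed = 42) {
  stopifnot(n_species >= 2)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cs <- seq(c_range[1], c_range[2], length.out = n_species)
  species <- sprintf("species_%02d", seq_len(n_species))
  # species-typical striation periods, evenly spaced in spatial frequency
  # (finer folds for the more complex species)
  striation_um <- 1 / seq(1 / 8, 1 / 2, length.out = n_species)
  meta <- NULL
  anns <- list()
  for (s in seq_len(n_species)) {
    spec <- species_spec(species[s], cs[s],
                         striation_wavelength_um = striation_um[s])
    for (im in seq_len(images_per_species)) {
      image_id <- sprintf("%s_img%d", species[s], im)
      g <- generate_micrograph(
        spec, size_px = size_px, pixel_size_um = pixel_size_um,
        seed = derive_seed(seed, s * 1000 + im), image_id = image_id,
        provenance = list(tree_id = sprintf("%s_t%d", species[s],
                                            (im - 1) %% 2 + 1),
                          leaf_id = sprintf("%s_leaf%d", species[s], im),
                          batch_id = "B1"))
      fn <- paste0(image_id, ".png")
      png::writePNG(g$micrograph$pixels / 255, file.path(out_dir, fn))
      meta <- rbind(meta, data.frame(
        image_id = image_id, path = fn, species = species[s],
        tree_id = g$micrograph$tree_id, leaf_id = g$micrograph$leaf_id,
        batch_id = g$micrograph$batch_id, pixel_size_um = pixel_size_um,
        magnification_tag = "1900x", stringsAsFactors = FALSE))
      anns[[image_id]] <- g$annotations
    }
  }
  manifest <- build_manifest(out_dir, meta)
  annotations <- do.call(rbind, anns)
  rownames(annotations) <- NULL
  write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  write_annotations(annotations, file.path(out_dir, "annotations.csv"))
  list(manifest = manifest, annotations = annotations,
       species = data.frame(species = species, complexity_c = cs,
                            stringsAsFactors = FALSE),
       dir = out_dir)
}
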