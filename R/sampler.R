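# Stomata-anchored sub-image sampling and per-species dataset balancing.
#
# A patch covers a fixed physical window (default 80 um per side, the scale
# at which epicuticular wax structure is resolved at 1900x) and is resampled
# to the canonical 512 x 512 pixel raster, so that patches from images with
# different pixel sizes are commensurable.

PATCH_PX <- 512L

#' Sample stomata-anchored sub-images from a micrograph
#'
#' Draws `n` patches anchored at uniformly chosen non-excluded stomata. In
#' `whole_leaf` mode the patch centre is jittered around the stoma by a
#' uniform offset of up to half a patch per axis, so every patch still
#' contains its anchor stoma while covering the surrounding texture; in
#' `roi` mode the patch is centred on the stoma itself. Windows are clipped
#' to lie fully inside the image (never padded) and resized to 512 x 512 by
#' bilinear interpolation (with an anti-alias filter when downscaling).
#' Sampling is with replacement: overlapping patches are expected.
#'
#' @param m a `leaftex_micrograph`.
#' @param annots annotation data frame from [load_annotations()].
#' @param n number of patches to draw.
#' @param patch_size_um physical side length of the source window.
#' @param mode `"whole_leaf"` (jittered) or `"roi"` (stoma-centred).
#' @param seed integer seed; identical inputs and seed give byte-identical
#'   patches.
#' @return list of `leaftex_patch` objects: `patch_id`, `pixels`
#'   (512 x 512 integer matrix), provenance fields, `stoma_index`,
#'   `offset_um` (row, col offset of the patch centre from the stoma) and
#'   `mode`.
#' @export
sample_subimages <- function(m, annots, n = 120, patch_size_um = 80,
                             mode = c("whole_leaf", "roi"), seed = 1) {
  mode <- match.arg(mode)
  stopifnot(inherits(m, "leaftex_micrograph"), n >= 1)
  window <- as.integer(round(patch_size_um / m$pixel_size_um))
  H <- nrow(m$pixels); W <- ncol(m$pixels)
  if (window > H || window > W)
    ltx_validation_error("patch window (%d px) exceeds image '%s' (%d x %d)",
                         window, m$image_id, H, W)
  a <- annots[annots$image_id == m$image_id & !annots$exclusion, ,
              drop = FALSE]
  if (nrow(a) == 0)
    ltx_stop("sampling_error", "no usable (non-excluded) stoma for image '%s'",
             m$image_id)
  half <- window / 2
  with_seed(seed, {
    pick <- sample.int(nrow(a), n, replace = TRUE)
    jitter_r <- if (mode == "whole_leaf") stats::runif(n, -half, half) else
      numeric(n)
    jitter_c <- if (mode == "whole_leaf") stats::runif(n, -half, half) else
      numeric(n)
    lapply(seq_len(n), function(i) {
      sr <- a$center_row[pick[i]] + 1  # 0-based annotation -> 1-based matrix
      sc <- a$center_col[pick[i]] + 1
      r0 <- as.integer(round(sr + jitter_r[i] - half))
      c0 <- as.integer(round(sc + jitter_c[i] - half))
      r0 <- min(max(r0, 1L), H - window + 1L)
      c0 <- min(max(c0, 1L), W - window + 1L)
      win <- m$pixels[r0:(r0 + window - 1L), c0:(c0 + window - 1L)]
      px <- resize_patch(win, PATCH_PX)
      centre_r <- r0 + half - 0.5
      centre_c <- c0 + half - 0.5
      structure(list(
        patch_id = sprintf("%s_p%04d", m$image_id, i),
        pixels = px,
        image_id = m$image_id,
        species = m$species, tree_id = m$tree_id, leaf_id = m$leaf_id,
        batch_id = m$batch_id,
        stoma_index = a$stoma_index[pick[i]],
        offset_um = c(row = (centre_r - sr) * m$pixel_size_um,
                      col = (centre_c - sc) * m$pixel_size_um),
        mode = mode
      ), class = "leaftex_patch")
    })
  })
}

# Bilinear resize of an integer gray matrix to size x size, via EBImage.
resize_patch <- function(win, size = PATCH_PX) {
  if (nrow(win) == size && ncol(win) == size) {
    storage.mode(win) <- "integer"
    return(win)
  }
  out <- EBImage::resize(EBImage::Image(win / 255), w = size, h = size,
                         filter = "bilinear",
                         antialias = nrow(win) > size)
  clamp8(EBImage::imageData(out) * 255)
}

#' Patch provenance manifest
#'
#' @param patches list of `leaftex_patch` objects.
#' @return data frame with one row per patch (patch_id, image_id, species,
#'   tree_id, leaf_id, batch_id, stoma_index, offset_row_um, offset_col_um,
#'   mode).
#' @export
patch_manifest <- function(patches) {
  data.frame(
    patch_id = vapply(patches, `[[`, "", "patch_id"),
    image_id = vapply(patches, `[[`, "", "image_id"),
    species = vapply(patches, `[[`, "", "species"),
    tree_id = vapply(patches, `[[`, "", "tree_id"),
    leaf_id = vapply(patches, `[[`, "", "leaf_id"),
    batch_id = vapply(patches, `[[`, "", "batch_id"),
    stoma_index = vapply(patches, function(p) as.integer(p$stoma_index), 0L),
    offset_row_um = vapply(patches, function(p) p$offset_um[["row"]], 0),
    offset_col_um = vapply(patches, function(p) p$offset_um[["col"]], 0),
    mode = vapply(patches, `[[`, "", "mode"),
    stringsAsFactors = FALSE
  )
}

#' Balance the patch set per species
#'
#' Downsamples to exactly `per_species` patches per species by seeded uniform
#' selection stratified by source image: within each species the patches of
#' each image are shuffled and images are drained round-robin, so per-image
#' counts differ by at most one wherever the supply allows.
#'
#' @param patches list of `leaftex_patch` objects, or a data frame with at
#'   least `species` and `image_id` columns (e.g. a patch manifest); the
#'   return matches the input type.
#' @param per_species target patch count per species (default 480, i.e. the
#'   quota of a 27-species balanced set of 12960 patches).
#' @param seed integer seed.
#' @export
balance_dataset <- function(patches, per_species = 480, seed = 1) {
  is_df <- is.data.frame(patches)
  meta <- if (is_df) patches else patch_manifest(patches)
  counts <- table(meta$species)
  deficit <- counts < per_species
  if (any(deficit))
    ltx_stop("balancing_error",
             "species below the %d-patch quota: %s", per_species,
             paste(sprintf("%s (%d)", names(counts)[deficit],
                           as.integer(counts[deficit])), collapse = ", "))
  keep <- with_seed(seed, {
    unlist(lapply(sort(unique(meta$species)), function(sp) {
      rows <- which(meta$species == sp)
      imgs <- sample(sort(unique(meta$image_id[rows])))
      queues <- lapply(imgs, function(im)
        sample(rows[meta$image_id[rows] == im]))
      sel <- integer(0)
      while (length(sel) < per_species) {
        for (q in seq_along(queues)) {
          if (length(sel) >= per_species) break
          if (length(queues[[q]])) {
            sel <- c(sel, queues[[q]][1])
            queues[[q]] <- queues[[q]][-1]
          }
        }
      }
      sel
    }), use.names = FALSE)
  })
  keep <- sort(keep)
  if (is_df) meta[keep, , drop = FALSE] else patches[keep]
}

#' Write patches to a directory
#'
#' Stores each patch as `{patch_id}.png` plus a `patch_manifest.csv`.
#'
#' @inheritParams patch_manifest
#' @param dir output directory (created if needed).
#' @export
write_patches <- function(patches, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (p in patches)
    png::writePNG(p$pixels / 255, file.path(dir, paste0(p$patch_id, ".png")))
  utils::write.csv(patch_manifest(patches),
                   file.path(dir, "patch_manifest.csv"), row.names = FALSE)
  invisible(dir)
}
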