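# Reading and writing micrographs, stomata annotations and the dataset
# manifest. All physical sizes are in micrometres; all pixel coordinates in
# the CSV interchange formats are 0-based (row, col), addressing pixels[r][c].

MANIFEST_COLS <- c("image_id", "path", "species", "tree_id", "leaf_id",
                   "batch_id", "pixel_size_um", "magnification_tag")

#' Build a dataset manifest
#'
#' Assembles the table that maps micrograph files to their provenance
#' (species, tree, leaf, batch) and physical scale. Image dimensions are read
#' from the files and recorded as `height`/`width` columns so that downstream
#' annotation validation does not need to re-open the images.
#'
#' @param root_dir directory containing the image files; `metadata$path` is
#'   interpreted relative to it (absolute paths are kept as is).
#' @param metadata data frame with columns `image_id`, `path`, `species`,
#'   `tree_id`, `leaf_id`, `batch_id`, `pixel_size_um`, `magnification_tag`.
#' @return the manifest: a data frame with the metadata columns plus
#'   `height` and `width`, ordered lexicographically by `image_id`.
#' @export
build_manifest <- function(root_dir, metadata) {
  if (nrow(metadata) == 0) {
    warning("empty metadata: returning an empty manifest")
    out <- metadata[, intersect(MANIFEST_COLS, names(metadata)), drop = FALSE]
    out$height <- integer(0)
    out$width <- integer(0)
    return(out)
  }
  stopifnot_cols(metadata, MANIFEST_COLS, "manifest metadata")
  if (anyDuplicated(metadata$image_id))
    ltx_validation_error("duplicate image_id in metadata: %s",
                         paste(unique(metadata$image_id[
                           duplicated(metadata$image_id)]), collapse = ", "))
  full <- ifelse(grepl("^(/|[A-Za-z]:)", metadata$path),
                 metadata$path, file.path(root_dir, metadata$path))
  missing <- !file.exists(full)
  if (any(missing))
    ltx_io_error("manifest references missing file(s): %s",
                 paste(full[missing], collapse = ", "))
  dims <- t(vapply(full, image_dimensions, integer(2)))
  out <- metadata[, MANIFEST_COLS]
  out$path <- full
  out$height <- as.integer(dims[, 1])
  out$width <- as.integer(dims[, 2])
  out <- out[order(out$image_id), , drop = FALSE]
  rownames(out) <- NULL
  if (any(out$pixel_size_um <= 0))
    ltx_validation_error("pixel_size_um must be positive for all images")
  out
}

#' @rdname build_manifest
#' @param manifest a manifest data frame.
#' @param path file to write (CSV, UTF-8).
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname build_manifest
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) ltx_io_error("manifest file not found: %s", path)
  m <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  stopifnot_cols(m, MANIFEST_COLS, "manifest")
  for (col in c("species", "tree_id", "leaf_id", "batch_id",
                "magnification_tag", "image_id", "path"))
    m[[col]] <- as.character(m[[col]])
  m
}

# Height/width of a PNG or TIFF without keeping the pixels.
image_dimensions <- function(path) {
  px <- read_gray_image(path, warn_multichannel = FALSE)
  c(nrow(px), ncol(px))
}

# Decode a PNG/TIFF into an 8-bit integer gray matrix. Multi-channel images
# are collapsed by the unweighted channel mean (luminance average); only the
# first page of a multi-page TIFF is used.
read_gray_image <- function(path, warn_multichannel = TRUE) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("png")) {
    arr <- png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    arr <- tiff::readTIFF(path, all = TRUE)
    if (is.list(arr)) {
      if (length(arr) > 1)
        warning(sprintf("multi-page TIFF %s: reading page 1 of %d only",
                        path, length(arr)))
      arr <- arr[[1]]
    }
  } else {
    ltx_io_error("unsupported image format '%s' (%s)", ext, path)
  }
  if (length(dim(arr)) == 3) {
    nch <- dim(arr)[3]
    if (nch >= 3) {
      if (warn_multichannel)
        message(sprintf("%s: multi-channel image converted by luminance average",
                        basename(path)))
      arr <- (arr[, , 1] + arr[, , 2] + arr[, , 3]) / 3
    } else {
      arr <- arr[, , 1]
    }
  }
  clamp8(arr * 255)
}

#' Load a micrograph with its provenance
#'
#' Reads one grayscale micrograph (8-bit PNG or TIFF) and attaches the
#' provenance and physical-scale fields from its manifest row. RGB images of
#' whatever origin are collapsed to gray by the channel average; multi-page
#' TIFFs use page one only.
#'
#' @param path image file; defaults to `manifest_row$path`.
#' @param manifest_row single-row data frame from the manifest.
#' @param patch_size_um patch side length used for the minimum-size check.
#' @return a `leaftex_micrograph`: list with `image_id`, `pixels` (integer
#'   matrix, 0-255), `pixel_size_um`, `species`, `tree_id`, `leaf_id`,
#'   `batch_id`, `magnification_tag`.
#' @export
load_micrograph <- function(manifest_row, path = manifest_row$path,
                            patch_size_um = 80) {
  stopifnot(nrow(manifest_row) == 1)
  if (!file.exists(path)) ltx_io_error("image file not found: %s", path)
  if (is.na(manifest_row$pixel_size_um) || manifest_row$pixel_size_um <= 0)
    ltx_validation_error("pixel_size_um must be > 0 for image '%s'",
                         manifest_row$image_id)
  px <- read_gray_image(path)
  window <- round(patch_size_um / manifest_row$pixel_size_um)
  if (nrow(px) < window || ncol(px) < window)
    ltx_validation_error(
      "image '%s' (%d x %d px) cannot hold one %g um patch (%d px)",
      manifest_row$image_id, nrow(px), ncol(px), patch_size_um, window)
  structure(list(
    image_id = as.character(manifest_row$image_id),
    pixels = px,
    pixel_size_um = manifest_row$pixel_size_um,
    species = as.character(manifest_row$species),
    tree_id = as.character(manifest_row$tree_id),
    leaf_id = as.character(manifest_row$leaf_id),
    batch_id = as.character(manifest_row$batch_id),
    magnification_tag = as.character(manifest_row$magnification_tag)
  ), class = "leaftex_micrograph")
}

#' @export
print.leaftex_micrograph <- function(x, ...) {
  cat(sprintf("<leaftex_micrograph> %s: %d x %d px @ %g um/px, species %s\n",
              x$image_id, nrow(x$pixels), ncol(x$pixels), x$pixel_size_um,
              x$species))
  invisible(x)
}

ANNOTATION_COLS <- c("image_id", "stoma_index", "center_row", "center_col")

#' Load stomata centre annotations
#'
#' Reads a stomata annotation CSV (header `image_id, stoma_index, center_row,
#' center_col[, major_axis_um, exclusion]`; coordinates 0-based row/col) and
#' validates every row against the manifest: the image must exist in the
#' manifest and the centre must lie inside the image. Annotations flagged
#' `exclusion = TRUE` (e.g. inside a fungal-colonization mask) are kept but
#' skipped by the patch sampler.
#'
#' @param path annotation CSV.
#' @param manifest manifest data frame (with `height`/`width` columns when
#'   produced by [build_manifest()]; without them the bounds check is
#'   deferred to sampling time, with a warning).
#' @return data frame of annotations with logical `exclusion` and numeric
#'   `major_axis_um` columns always present.
#' @export
load_annotations <- function(path, manifest) {
  if (!file.exists(path)) ltx_io_error("annotation file not found: %s", path)
  a <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  stopifnot_cols(a, ANNOTATION_COLS, "annotation table")
  if (nrow(a) == 0) {
    warning("annotation file is empty (header only)")
    a$major_axis_um <- numeric(0)
    a$exclusion <- logical(0)
    return(a)
  }
  if (!"major_axis_um" %in% names(a)) a$major_axis_um <- NA_real_
  if (!"exclusion" %in% names(a)) a$exclusion <- FALSE
  a$exclusion <- as.logical(a$exclusion)
  a$exclusion[is.na(a$exclusion)] <- FALSE
  a$image_id <- as.character(a$image_id)
  unknown <- setdiff(a$image_id, manifest$image_id)
  if (length(unknown))
    ltx_validation_error("annotations reference unknown image_id(s): %s",
                         paste(unknown, collapse = ", "))
  if (all(c("height", "width") %in% names(manifest))) {
    idx <- match(a$image_id, manifest$image_id)
    bad <- a$center_row < 0 | a$center_row >= manifest$height[idx] |
      a$center_col < 0 | a$center_col >= manifest$width[idx]
    if (any(bad))
      ltx_validation_error("out-of-bounds stoma centre(s) in row(s): %s",
                           paste(which(bad), collapse = ", "))
  } else {
    warning("manifest lacks height/width columns; bounds check deferred")
  }
  a
}

#' @rdname load_annotations
#' @param annotations annotation data frame.
#' @export
write_annotations <- function(annotations, path) {
  utils::write.csv(annotations, path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
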