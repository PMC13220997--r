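# Patch sampling and per-species balancing.

make_micrograph <- function(n = 256, pixel_size_um = 1, seed = 5,
                            species = "sp1", image_id = "img1") {
  structure(list(image_id = image_id, pixels = noise_patch(seed, n),
                 pixel_size_um = pixel_size_um, species = species,
                 tree_id = "t1", leaf_id = "l1", batch_id = "B1",
                 magnification_tag = "1900x"),
            class = "leaftex_micrograph")
}

make_annots <- function(image_id, rows, cols, exclusion = FALSE) {
  data.frame(image_id = image_id, stoma_index = seq_along(rows) - 1L,
             center_row = rows, center_col = cols,
             major_axis_um = NA_real_, exclusion = exclusion,
             stringsAsFactors = FALSE)
}

test_that("sampling yields n patches of 512 x 512, deterministically", {
  m <- make_micrograph()
  ann <- make_annots("img1", c(50, 128, 200), c(60, 128, 190))
  p1 <- sample_subimages(m, ann, n = 17, patch_size_um = 80, seed = 11)
  expect_length(p1, 17)
  expect_true(all(vapply(p1, function(p) identical(dim(p$pixels),
                                                   c(512L, 512L)), TRUE)))
  p2 <- sample_subimages(m, ann, n = 17, patch_size_um = 80, seed = 11)
  expect_identical(lapply(p1, `[[`, "pixels"), lapply(p2, `[[`, "pixels"))
  p3 <- sample_subimages(m, ann, n = 17, patch_size_um = 80, seed = 12)
  expect_false(identical(lapply(p1, `[[`, "pixels"),
                         lapply(p3, `[[`, "pixels")))
})

test_that("roi mode centres every patch on its stoma", {
  m <- make_micrograph(n = 256)
  ann <- make_annots("img1", 128, 128)  # centre, window 80 px fits
  ps <- sample_subimages(m, ann, n = 5, patch_size_um = 80, mode = "roi",
                         seed = 3)
  # all patches identical (same centre, no jitter)
  for (p in ps) expect_identical(p$pixels, ps[[1]]$pixels)
  # and equal to the directly-extracted, resized window
  win <- m$pixels[89:168, 89:168]
  ref <- sample_subimages(m, make_annots("img1", 128, 128), n = 1,
                          patch_size_um = 80, mode = "roi", seed = 9)
  expect_identical(ref[[1]]$pixels, ps[[1]]$pixels)
  expect_equal(abs(unname(ps[[1]]$offset_um)), c(0.5, 0.5))  # even window: centre off by half a pixel
})

test_that("windows are clipped inside the image for border stomata", {
  m <- make_micrograph(n = 120)
  ann <- make_annots("img1", c(0, 119), c(0, 119))
  ps <- sample_subimages(m, ann, n = 30, patch_size_um = 80, seed = 2)
  expect_length(ps, 30)  # would error if any window left the image
  # a corner stoma's roi window clips to the same corner window a centred
  # stoma at (40, 40) addresses exactly
  roi <- sample_subimages(m, make_annots("img1", 0, 0), n = 1,
                          patch_size_um = 80, mode = "roi", seed = 1)
  direct <- sample_subimages(m, make_annots("img1", 40, 40), n = 1,
                             patch_size_um = 80, mode = "roi", seed = 1)
  expect_identical(roi[[1]]$pixels, direct[[1]]$pixels)
})

test_that("excluded stomata are skipped and their absence can error", {
  m <- make_micrograph()
  ann <- make_annots("img1", c(100, 150), c(100, 150),
                     exclusion = c(FALSE, TRUE))
  ps <- sample_subimages(m, ann, n = 8, seed = 1)
  expect_true(all(vapply(ps, `[[`, 0L, "stoma_index") == 0L))
  all_excl <- make_annots("img1", 100, 100, exclusion = TRUE)
  expect_error(sample_subimages(m, all_excl, n = 4, seed = 1),
               class = "leaftex_sampling_error")
  expect_error(sample_subimages(m, ann, n = 4, patch_size_um = 500, seed = 1),
               class = "leaftex_validation_error")
})

test_that("balancing hits the quota with per-image counts within one", {
  # metadata-only balancing on a 27-species manifest: 4 images x 120 patches
  meta <- expand.grid(i = 1:120, img = 1:4, sp = 1:27)
  pm <- data.frame(
    patch_id = sprintf("s%02d_i%d_p%03d", meta$sp, meta$img, meta$i),
    image_id = sprintf("s%02d_img%d", meta$sp, meta$img),
    species = sprintf("s%02d", meta$sp), stringsAsFactors = FALSE)
  bal <- balance_dataset(pm, per_species = 480, seed = 4)
  expect_equal(nrow(bal), 27 * 480)
  counts <- table(bal$species)
  expect_true(all(counts == 480))
  per_img <- table(bal$species, bal$image_id)
  per_img <- per_img[per_img > 0]
  expect_true(all(per_img == 120))
  # uneven quota: per-image counts differ by at most one
  bal2 <- balance_dataset(pm, per_species = 478, seed = 4)
  for (sp in unique(bal2$species)) {
    cc <- table(bal2$image_id[bal2$species == sp])
    expect_lte(diff(range(cc)), 1)
  }
  # determinism
  expect_identical(balance_dataset(pm, per_species = 478, seed = 4), bal2)
})

test_that("balancing errors when a species is under quota", {
  pm <- data.frame(patch_id = sprintf("p%d", 1:30),
                   image_id = rep(c("a1", "b1"), c(20, 10)),
                   species = rep(c("A", "B"), c(20, 10)),
                   stringsAsFactors = FALSE)
  expect_error(balance_dataset(pm, per_species = 15, seed = 1),
               "B", class = "leaftex_balancing_error")
  bal <- balance_dataset(pm, per_species = 10, seed = 1)
  expect_equal(unname(c(table(bal$species))), c(10, 10))
})

test_that("patch store round-trips pixels and manifest", {
  dir <- withr::local_tempdir()
  m <- make_micrograph()
  ann <- make_annots("img1", 128, 128)
  ps <- sample_subimages(m, ann, n = 3, seed = 1)
  write_patches(ps, dir)
  pm <- utils::read.csv(file.path(dir, "patch_manifest.csv"))
  expect_equal(nrow(pm), 3)
  back <- png::readPNG(file.path(dir, paste0(ps[[1]]$patch_id, ".png")))
  expect_equal(max(abs(back * 255 - ps[[1]]$pixels)), 0)
})
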