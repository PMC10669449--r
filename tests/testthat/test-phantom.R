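test_that("phantom generation is deterministic given its seed", {
  sp <- phantom_spec(image_size = 64, seed = 5)
  expect_identical(generate_phantom(sp), generate_phantom(sp))
  sp2 <- phantom_spec(image_size = 64, seed = 6)
  expect_false(identical(generate_phantom(sp)$image,
                         generate_phantom(sp2)$image))
})

test_that("ROI interior is brighter than the exterior by at least the configured margin", {
  for (seed in 1:5) {
    rec <- generate_phantom(phantom_spec(image_size = 96, seed = seed))
    gain <- mean(rec$image[rec$roi_mask]) - mean(rec$image[!rec$roi_mask])
    expect_gte(gain, rec$meta$spec$roi_margin)
  }
})

test_that("the crack lies inside the ROI ellipse and is thin", {
  for (seed in 1:5) {
    rec <- generate_phantom(phantom_spec(image_size = 96, seed = seed))
    expect_gt(sum(rec$fracture_mask), 0)
    expect_true(all(rec$roi_mask[rec$fracture_mask]))
    expect_lt(mean(rec$fracture_mask), 0.05)
  }
})

test_that("suppressing the crack changes only the crack pixels; the mask survives", {
  sp <- phantom_spec(image_size = 64, crack_contrast = 0.09, seed = 8)
  with_ <- generate_phantom(sp)
  without <- generate_phantom(sp, with_crack = FALSE)
  expect_gt(sum(with_$fracture_mask), 0)
  expect_identical(with_$fracture_mask, without$fracture_mask)
  diffmap <- without$image - with_$image
  expect_gt(mean(diffmap[with_$fracture_mask]), 0.05)
  far <- !dafdnet:::ebi_mat(EBImage::dilate(
    with_$fracture_mask * 1, EBImage::makeBrush(9, "disc"))) > 0
  expect_equal(max(abs(diffmap[far])), 0)
})

test_that("spec validation rejects impossible geometry and contrast", {
  expect_error(phantom_spec(image_size = 16), "image_size")
  expect_error(phantom_spec(crack_width = 5), "crack_width")
  expect_error(phantom_spec(crack_contrast = 0.7), "crack_contrast")
  expect_error(phantom_spec(roi_center = c(5, 5)), "bounds")
})

test_that("identity augmentation reproduces the base record; angles stay in range", {
  rec <- generate_phantom(phantom_spec(image_size = 64, seed = 2))
  idv <- augment(rec, augment_spec(rotation_range = c(0, 0),
                                   scale_factor = 1, n_variants = 2,
                                   seed = 1))
  expect_equal(idv[[1]]$image, rec$image, tolerance = 1e-12)
  expect_identical(idv[[2]]$fracture_mask, rec$fracture_mask)
  vars <- augment(rec, augment_spec(n_variants = 400, seed = 3))
  angs <- vapply(vars, function(v) v$meta$angle, numeric(1))
  expect_length(vars, 400)
  expect_true(all(angs >= -15 & angs <= 15))
  expect_gt(diff(range(angs)), 20)   # actually spread over the range
  expect_true(all(vapply(vars, function(v) v$meta$scale, numeric(1)) ==
                    0.95))
})

test_that("image and masks receive the same geometric transform (inverse-map dice)", {
  rec <- generate_phantom(phantom_spec(image_size = 96, seed = 4))
  vars <- augment(rec, augment_spec(n_variants = 4, seed = 9))
  for (v in vars) {
    back <- dafdnet:::invert_transform_raster(v$fracture_mask * 1,
                                              v$meta$angle, v$meta$scale,
                                              binary = TRUE)
    expect_gte(dice(back, rec$fracture_mask), 0.8)
    back_roi <- dafdnet:::invert_transform_raster(v$roi_mask * 1,
                                                  v$meta$angle,
                                                  v$meta$scale,
                                                  binary = TRUE)
    expect_gte(dice(back_roi, rec$roi_mask), 0.9)
  }
})

test_that("dataset generation splits by base image with no leakage and reproduces exactly", {
  ds <- make_phantom_dataset(n_base = 6, split_fraction = 0.5,
                             image_size = 48,
                             aug = augment_spec(n_variants = 3), seed = 42)
  expect_length(ds$train, 9)
  expect_length(ds$test, 9)
  tr_ids <- unique(vapply(ds$train, function(r) r$meta$base_id, numeric(1)))
  te_ids <- unique(vapply(ds$test, function(r) r$meta$base_id, numeric(1)))
  expect_length(intersect(tr_ids, te_ids), 0)
  ds2 <- make_phantom_dataset(n_base = 6, split_fraction = 0.5,
                              image_size = 48,
                              aug = augment_spec(n_variants = 3), seed = 42)
  expect_identical(ds$train[[1]]$image, ds2$train[[1]]$image)
  expect_identical(ds$manifest, ds2$manifest)
  # n_base = 2 at split 0.5: one base each side
  ds3 <- make_phantom_dataset(n_base = 2, split_fraction = 0.5,
                              image_size = 48,
                              aug = augment_spec(n_variants = 1), seed = 1)
  expect_length(ds3$train, 1)
  expect_length(ds3$test, 1)
  expect_error(make_phantom_dataset(n_base = 1), "n_base")
  expect_error(make_phantom_dataset(n_base = 4, split_fraction = 1), "split")
})
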