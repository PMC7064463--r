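small_dims <- c(64L, 48L)   # (columns, rows) spectral px for fast scenes

test_that("reflectance vectors respect the hemoglobin ordering invariant", {
  refl <- phantom_reflectance(snbi_classes(), contrast = 1)
  expect_true(all(diff(refl[, "415"]) < 0))
  expect_true(all(diff(refl[, "620"]) < 0))
  expect_true(all(diff(refl[, "525"]) >= 0))
  expect_true(all(refl >= 0 & refl <= 1))
  half <- phantom_reflectance(snbi_classes(), contrast = 0.5)
  expect_true(all(diff(half[, "415"]) < 0))
  expect_lt(refl[6, "415"], half[6, "415"])    # contrast widens the spread
})

test_that("scenes are deterministic given the seed", {
  s1 <- make_scene("table1", spectral_pixels = c(120L, 100L), seed = 5)
  s2 <- make_scene("table1", spectral_pixels = c(120L, 100L), seed = 5)
  s3 <- make_scene("table1", spectral_pixels = c(120L, 100L), seed = 6)
  expect_identical(s1$truth_map, s2$truth_map)
  expect_identical(s1$regions, s2$regions)
  expect_false(identical(s1$truth_map, s3$truth_map))
})

test_that("degenerate or disordered reflectance is rejected", {
  expect_error(phantom_reflectance(contrast = 0), "contrast")
  refl <- phantom_reflectance(c("normal", "CIN2"))
  refl["CIN2", ] <- refl["normal", ]
  expect_error(
    phantom_scene(matrix(1L, 4, 4), c("normal", "CIN2"), refl),
    "identical reflectance")
  refl2 <- phantom_reflectance(c("normal", "CIN2"))
  refl2[, "415"] <- rev(refl2[, "415"])
  expect_error(
    phantom_scene(matrix(1L, 4, 4), c("normal", "CIN2"), refl2),
    "415")
})

test_that("table1 scenes hold 24 regions of the stated composition, each >= 100 px", {
  sc <- make_scene("table1", spectral_pixels = c(160L, 135L), seed = 42)
  expect_length(sc$regions, 24L)
  cls <- vapply(sc$regions, `[[`, character(1), "class")
  expect_equal(unname(table(cls)[snbi_classes()]),
               as.integer(c(7, 5, 3, 3, 3, 3)), ignore_attr = TRUE)
  sizes <- vapply(sc$regions, function(r) nrow(r$pixels), integer(1))
  expect_true(all(sizes >= 100L))
})

test_that("rendered frames are deterministic and shaped by the layout", {
  layout <- mosaic_layout(spectral_pixels = small_dims, subpixel_bin = 2L)
  sc <- make_scene("lesion", spectral_pixels = small_dims, seed = 9)
  f1 <- render_frames(sc, layout)
  f2 <- render_frames(sc, layout)
  expect_identical(f1$sample$pixels, f2$sample$pixels)
  expect_identical(f1$dark, f2$dark)
  expect_equal(dim(f1$sample$pixels), layout_raw_dim(layout))
  bad <- mosaic_layout(spectral_pixels = c(10L, 10L), subpixel_bin = 2L)
  expect_error(render_frames(sc, bad), "layout expects")
})

test_that("the pipeline recovers class reflectance exactly at zero noise", {
  layout <- mosaic_layout(spectral_pixels = small_dims, subpixel_bin = 2L)
  sc <- make_scene("lesion", spectral_pixels = small_dims, noise_sd = 0,
                   illumination = "flat", seed = 13)
  f <- render_frames(sc, layout)
  refs <- build_references(lapply(f$dark, demosaic, layout = layout),
                           lapply(f$board, demosaic, layout = layout))
  norm <- normalize_stack(demosaic(f$sample, layout), refs)
  for (w in colnames(sc$class_reflectance)) {
    want <- matrix(sc$class_reflectance[sc$truth_map, w],
                   nrow(sc$truth_map), ncol(sc$truth_map))
    expect_equal(norm$bands[[w]], want, tolerance = 1e-12)
  }
})

test_that("normalized board is 1 and dark maps to 0 at zero noise", {
  layout <- mosaic_layout(spectral_pixels = small_dims, subpixel_bin = 2L)
  sc <- make_scene("lesion", spectral_pixels = small_dims, noise_sd = 0,
                   illumination = "flat", seed = 13)
  f <- render_frames(sc, layout)
  refs <- build_references(lapply(f$dark, demosaic, layout = layout),
                           lapply(f$board, demosaic, layout = layout))
  board_norm <- normalize_stack(demosaic(f$board[[1]], layout), refs)
  dark_norm <- normalize_stack(demosaic(f$dark[[1]], layout), refs)
  for (w in names(board_norm$bands)) {
    expect_equal(board_norm$bands[[w]],
                 matrix(1, nrow(sc$truth_map), ncol(sc$truth_map)))
    expect_equal(dark_norm$bands[[w]],
                 matrix(0, nrow(sc$truth_map), ncol(sc$truth_map)))
  }
})

test_that("noisy recovery stays within the propagated error bound for 95% of pixels", {
  layout <- mosaic_layout(spectral_pixels = small_dims, subpixel_bin = 2L)
  exposure <- 40000
  sc <- make_scene("lesion", spectral_pixels = small_dims, noise_sd = 200,
                   illumination = "flat", seed = 17)
  f <- render_frames(sc, layout, exposure_scale = exposure)
  refs <- build_references(lapply(f$dark, demosaic, layout = layout),
                           lapply(f$board, demosaic, layout = layout))
  norm <- normalize_stack(demosaic(f$sample, layout), refs)
  for (w in colnames(sc$class_reflectance)) {
    want <- matrix(sc$class_reflectance[sc$truth_map, w],
                   nrow(sc$truth_map), ncol(sc$truth_map))
    bound <- 3 * sc$noise_sd / (refs$board_mean[[w]] - refs$dark_mean[[w]])
    frac_ok <- mean(abs(norm$bands[[w]] - want) <= bound)
    expect_gte(frac_ok, 0.95)
  }
})

test_that("mean fused intensity increases strictly with lesion grade at zero noise", {
  layout <- mosaic_layout(spectral_pixels = small_dims, subpixel_bin = 2L)
  sc <- make_scene("lesion", spectral_pixels = small_dims, noise_sd = 0,
                   illumination = "flat", seed = 19)
  f <- render_frames(sc, layout)
  refs <- build_references(lapply(f$dark, demosaic, layout = layout),
                           lapply(f$board, demosaic, layout = layout))
  fused <- fuse_bands(normalize_stack(demosaic(f$sample, layout), refs))
  means <- vapply(seq_along(sc$classes), function(k)
    mean(fused$pixels[sc$truth_map == k]), numeric(1))
  names(means) <- sc$classes
  expect_true(all(diff(means[c("normal", "CIN2", "CIN3",
                               "carcinoma_in_situ")]) > 0))
})

test_that("the color arm renders a compressed-contrast RGB image deterministically", {
  sc <- make_scene("table1", spectral_pixels = c(120L, 100L), seed = 23)
  img1 <- render_color_image(sc)
  img2 <- render_color_image(sc)
  expect_identical(img1, img2)
  expect_equal(dim(img1), c(dim(sc$truth_map), 3L))
  expect_true(all(img1 >= 0 & img1 <= 255))
})

test_that("the reference experiment tallies agree with the evaluation oracle", {
  rep <- run_reference_experiment(seed = 3, spectral_pixels = c(120L, 100L))
  redo_snbi <- evaluate_regions(rep$map_snbi, rep$scene$regions)
  redo_color <- evaluate_regions(rep$map_color, rep$scene$regions)
  expect_equal(rep$snbi$accuracy_pct, redo_snbi$accuracy_pct)
  expect_equal(rep$color$accuracy_pct, redo_color$accuracy_pct)
  expect_equal(rep$snbi$n_regions, 24L)
})

test_that("sum and rms classifier modes agree under equal-size seed patches", {
  rep_sum <- run_reference_experiment(seed = 4, mode = "sum")
  rep_rms <- run_reference_experiment(seed = 4, mode = "rms")
  expect_identical(rep_sum$map_snbi$labels, rep_rms$map_snbi$labels)
})
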