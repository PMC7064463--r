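#' Canonical tissue grades, ordered by severity
#'
#' Normal tissue, inflammation, the three grades of cervical intraepithelial
#' neoplasia (CIN1 < CIN2 < CIN3) and carcinoma in situ.
#'
#' @return Character vector of the six grade names.
#' @export
snbi_classes <- function() {
  c("normal", "inflammation", "CIN1", "CIN2", "CIN3", "carcinoma_in_situ")
}

# Severity rank (0-based) within the canonical grade ladder; unknown class
# names fall back to their position in the supplied vector.
severity_rank <- function(classes) {
  r <- match(classes, snbi_classes()) - 1L
  r[is.na(r)] <- (seq_along(classes) - 1L)[is.na(r)]
  r
}

#' Stipulated per-grade band reflectance vectors
#'
#' Hemoglobin content rises with lesion grade; hemoglobin absorbs strongly
#' near 415 nm and reflects weakly near 620 nm relative to normal mucosa,
#' while 525 nm sits at a reflectance peak. The phantom therefore assigns,
#' for severity rank `k` and contrast level `c`:
#' reflectance at 415 nm `0.50 - 0.05*c*k` (strictly decreasing), at 620 nm
#' `0.60 - 0.05*c*k` (strictly decreasing), at 525 nm `0.50 + 0.01*c*k`
#' (strictly increasing), and a constant 0.65 at the 450 nm background band.
#' These are ordering-constrained stand-ins, not tissue measurements: the
#' band-difference magnitude `|d| = 0.05 + 0.11*c*k` then grows strictly with
#' grade, which is the property the fusion step exploits.
#'
#' @param classes character vector of grade names (see [snbi_classes()]).
#' @param contrast contrast level in `(0, 1]` scaling the inter-grade spacing.
#' @return Numeric matrix, one row per class, columns named 415/450/525/620.
#' @export
phantom_reflectance <- function(classes = snbi_classes(), contrast = 1) {
  if (contrast <= 0 || contrast > 1)
    stop("`contrast` must lie in (0, 1]")
  k <- severity_rank(classes)
  refl <- cbind(
    `415` = 0.50 - 0.05 * contrast * k,
    `450` = rep(0.65, length(k)),
    `525` = 0.50 + 0.01 * contrast * k,
    `620` = 0.60 - 0.05 * contrast * k
  )
  rownames(refl) <- classes
  refl
}

#' Synthetic tissue-phantom scene
#'
#' Ground truth for the pipeline: a class map at spectral-pixel resolution,
#' per-class per-band reflectance, a smooth multiplicative illumination
#' field, sensor dark offset and noise level.
#'
#' The constructor enforces the hemoglobin ordering invariant: with classes
#' sorted by severity, reflectance must be strictly decreasing at 415 and
#' 620 nm and non-decreasing at 525 nm.
#'
#' @param truth_map integer matrix of class indices (1-based into `classes`).
#' @param classes ordered character vector of class names.
#' @param class_reflectance numeric matrix (class x band), values in `[0, 1]`,
#'   columns named 415/450/525/620.
#' @param illumination_field multiplicative field in `(0, 1.5]`, same shape as
#'   `truth_map`.
#' @param dark_offset scalar sensor dark level (counts).
#' @param noise_sd additive Gaussian noise s.d. (counts).
#' @param regions list of ground-truth regions (class + pixel coordinates).
#' @param seed integer seed governing all stochastic rendering.
#' @return An object of class `phantom_scene`.
#' @export
phantom_scene <- function(truth_map, classes, class_reflectance,
                          illumination_field = NULL, dark_offset = 400,
                          noise_sd = 200, regions = list(), seed = 42L) {
  if (any(truth_map < 1L) || any(truth_map > length(classes)))
    stop("truth map uses undeclared class indices")
  refl <- class_reflectance[classes, c("415", "450", "525", "620"), drop = FALSE]
  if (any(refl < 0) || any(refl > 1))
    stop("reflectance values must lie in [0, 1]")
  if (any(duplicated(refl)))
    stop("classes with identical reflectance vectors are not distinguishable")
  k <- order(severity_rank(classes))
  for (b in c("415", "620"))
    if (any(diff(refl[k, b]) >= 0))
      stop(sprintf("reflectance at %s nm must strictly decrease with severity", b))
  if (any(diff(refl[k, "525"]) < 0))
    stop("reflectance at 525 nm must not decrease with severity")
  if (is.null(illumination_field))
    illumination_field <- matrix(1, nrow(truth_map), ncol(truth_map))
  if (!all(dim(illumination_field) == dim(truth_map)))
    stop("illumination field must match the truth map shape")
  if (any(illumination_field <= 0) || any(illumination_field > 1.5))
    stop("illumination field values must lie in (0, 1.5]")
  structure(
    list(truth_map = truth_map, classes = as.character(classes),
         class_reflectance = refl, illumination_field = illumination_field,
         dark_offset = dark_offset, noise_sd = noise_sd,
         regions = regions, seed = as.integer(seed)),
    class = "phantom_scene"
  )
}

#' @export
print.phantom_scene <- function(x, ...) {
  cat(sprintf(
    "<phantom_scene> %d x %d spectral px, %d classes, %d regions, noise_sd = %g\n",
    nrow(x$truth_map), ncol(x$truth_map), length(x$classes),
    length(x$regions), x$noise_sd))
  invisible(x)
}

disk_pixels <- function(center, radius, nr, nc) {
  r0 <- max(1L, floor(center[1L] - radius)); r1 <- min(nr, ceiling(center[1L] + radius))
  c0 <- max(1L, floor(center[2L] - radius)); c1 <- min(nc, ceiling(center[2L] + radius))
  g <- expand.grid(row = r0:r1, col = c0:c1)
  keep <- (g$row - center[1L])^2 + (g$col - center[2L])^2 <= radius^2
  as.matrix(g[keep, , drop = FALSE])
}

radial_field <- function(nr, nc, amplitude) {
  cr <- (nr + 1) / 2; cc <- (nc + 1) / 2
  rr <- matrix(seq_len(nr), nr, nc)
  ccx <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  rho2 <- ((rr - cr) / (nr / 2))^2 / 2 + ((ccx - cc) / (nc / 2))^2 / 2
  1 - amplitude * rho2
}

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  code
}

#' Generate a synthetic tissue scene
#'
#' Two presets:
#' * `"lesion"` — a concentric lesion on a normal background: a carcinoma-in-
#'   situ elliptical core surrounded by a CIN3 ring and a CIN2 ring, the
#'   classic grade topology of an advancing lesion.
#' * `"table1"` — 24 well-separated disk regions in the 6-grade composition
#'   7 normal / 5 inflammation / 3 CIN1 / 3 CIN2 / 3 CIN3 / 3 carcinoma in
#'   situ, laid out on a 6 x 4 grid with seeded jitter, on a normal
#'   background. This is the composition used by the reference comparison
#'   experiment.
#'
#' Regions are sized to hold at least ~100 spectral pixels so that
#' region-level majority voting is stable.
#'
#' @param preset scene preset.
#' @param spectral_pixels `c(columns, rows)` canvas size in spectral pixels.
#' @param contrast contrast level in `(0, 1]`, see [phantom_reflectance()].
#' @param noise_sd sensor noise s.d. in counts.
#' @param dark_offset sensor dark level in counts.
#' @param illumination `"vignette"` (smooth radial falloff of `vignette_amplitude`)
#'   or `"flat"`.
#' @param vignette_amplitude relative falloff from center to corner.
#' @param seed integer seed; identical seeds yield identical scenes.
#' @return A [phantom_scene()].
#' @examples
#' sc <- make_scene("lesion", spectral_pixels = c(64, 48), noise_sd = 0)
#' table(sc$classes[sc$truth_map])
#' @export
make_scene <- function(preset = c("lesion", "table1"),
                       spectral_pixels = c(160L, 135L),
                       contrast = 1, noise_sd = 200, dark_offset = 400,
                       illumination = c("vignette", "flat"),
                       vignette_amplitude = 0.08, seed = 42L) {
  preset <- match.arg(preset)
  illumination <- match.arg(illumination)
  nc <- as.integer(spectral_pixels[1L]); nr <- as.integer(spectral_pixels[2L])
  if (preset == "lesion") {
    classes <- c("normal", "CIN2", "CIN3", "carcinoma_in_situ")
    rad <- round(min(nr, nc) * c(CIN2 = 0.38, CIN3 = 0.26, carcinoma_in_situ = 0.14) / 2)
    if (any(rad < 3L)) stop("canvas too small for the concentric lesion preset")
    truth <- matrix(1L, nr, nc)
    ctr <- c((nr + 1) / 2, (nc + 1) / 2)
    regions <- list()
    for (cls in c("CIN2", "CIN3", "carcinoma_in_situ")) {
      px <- disk_pixels(ctr, rad[[cls]], nr, nc)
      prev <- truth[px]                     # annulus: pixels not yet overwritten
      truth[px] <- match(cls, classes)
    }
    for (k in seq_along(classes)) {
      px <- which(truth == k, arr.ind = TRUE)
      regions[[k]] <- list(class = classes[k],
                           pixels = px[, c("row", "col"), drop = FALSE])
    }
  } else {
    classes <- snbi_classes()
    counts <- c(normal = 7L, inflammation = 5L, CIN1 = 3L, CIN2 = 3L,
                CIN3 = 3L, carcinoma_in_situ = 3L)
    grid_c <- 6L; grid_r <- 4L
    cell_h <- nr / grid_r; cell_w <- nc / grid_c
    radius <- floor(min(cell_h, cell_w) * 0.32)
    if (radius < 6L)
      stop("canvas too small for 24 regions of >= 100 spectral pixels")
    assignment <- with_seed(seed, sample(rep(names(counts), counts)))
    truth <- matrix(1L, nr, nc)
    jit <- with_seed(seed + 1L,
                     matrix(stats::runif(2L * grid_r * grid_c, -2, 2), ncol = 2L))
    regions <- vector("list", grid_r * grid_c)
    i <- 0L
    for (gr in seq_len(grid_r)) for (gc in seq_len(grid_c)) {
      i <- i + 1L
      ctr <- c((gr - 0.5) * cell_h + jit[i, 1L], (gc - 0.5) * cell_w + jit[i, 2L])
      px <- disk_pixels(ctr, radius, nr, nc)
      cls <- assignment[i]
      truth[px] <- match(cls, classes)
      regions[[i]] <- list(class = cls, pixels = px)
    }
  }
  illum <- if (illumination == "flat") matrix(1, nr, nc)
           else radial_field(nr, nc, vignette_amplitude)
  phantom_scene(
    truth_map = truth, classes = classes,
    class_reflectance = phantom_reflectance(classes, contrast),
    illumination_field = illum, dark_offset = dark_offset,
    noise_sd = noise_sd, regions = regions, seed = seed
  )
}

clip_counts <- function(x, bit_depth) pmin(pmax(x, 0), 2^bit_depth - 1)

#' Render raw mosaic frames from a phantom scene
#'
#' Produces the three kinds of frames the calibration pipeline consumes. Per
#' band, the ideal spectral image of the sample is
#' `reflectance(class) * illumination * exposure_scale + dark_offset + noise`;
#' white-board frames use reflectance 1 everywhere; dark frames use
#' reflectance 0 with no illumination (sensor capped). Each spectral image is
#' then laid onto the sensor grid through [mosaic_render()], and values are
#' clipped to the sensor range. Output is deterministic given the scene seed.
#'
#' @param scene a [phantom_scene()] whose truth map matches the layout's
#'   spectral-pixel grid.
#' @param layout a [mosaic_layout()].
#' @param exposure_scale sensor counts corresponding to reflectance 1 under
#'   unit illumination.
#' @param n_dark,n_board number of reference frames to render.
#' @param bit_depth sensor bit depth.
#' @return A list with elements `sample` (a [raw_frame()]), `dark` and
#'   `board` (lists of [raw_frame()]s).
#' @export
render_frames <- function(scene, layout, exposure_scale = 40000,
                          n_dark = 3L, n_board = 3L, bit_depth = 16L) {
  d <- dim(scene$truth_map)
  if (d[1L] != layout$spectral_rows || d[2L] != layout$spectral_cols)
    stop(sprintf("scene is %d x %d spectral px but layout expects %d x %d",
                 d[1L], d[2L], layout$spectral_rows, layout$spectral_cols))
  bands <- as.character(layout$wavelengths)
  if (!all(bands %in% colnames(scene$class_reflectance)))
    stop("scene reflectance does not cover the layout wavelengths")
  noise <- function(n) if (scene$noise_sd > 0)
    stats::rnorm(n, sd = scene$noise_sd) else 0
  npx <- prod(d)
  render_stack <- function(band_fun) {
    b <- lapply(bands, band_fun)
    names(b) <- bands
    mosaic_render(spectral_stack(b), layout, bit_depth = bit_depth)
  }
  with_seed(scene$seed, {
    sample_frame <- render_stack(function(w) {
      refl <- matrix(scene$class_reflectance[scene$truth_map, w], d[1L], d[2L])
      ideal <- refl * scene$illumination_field * exposure_scale +
        scene$dark_offset
      clip_counts(ideal + noise(npx), bit_depth)
    })
    board <- lapply(seq_len(n_board), function(i) render_stack(function(w) {
      ideal <- scene$illumination_field * exposure_scale + scene$dark_offset
      clip_counts(ideal + noise(npx), bit_depth)
    }))
    dark <- lapply(seq_len(n_dark), function(i) render_stack(function(w) {
      clip_counts(matrix(scene$dark_offset, d[1L], d[2L]) + noise(npx),
                  bit_depth)
    }))
    list(sample = sample_frame, dark = dark, board = board)
  })
}

#' Render a conventional color (white-light) image of a scene
#'
#' Emulates what a standard color colposcopy camera would see: mucosa hues
#' with deliberately compressed inter-grade contrast (all grades are shades
#' of pink/red under white light), the same smooth illumination falloff, and
#' sensor noise — with no flat-field correction, as none is available for a
#' conventional color camera. Illumination non-uniformity therefore shifts
#' colors by more than the inter-grade color spacing, which is precisely the
#' contrast limitation of white-light imaging that narrow-band fusion
#' removes.
#'
#' @param scene a [phantom_scene()].
#' @param noise_sd_rgb per-channel noise s.d. on the `[0, 255]` scale.
#' @return Numeric array rows x cols x 3 in `[0, 255]`.
#' @export
render_color_image <- function(scene, noise_sd_rgb = 2) {
  k <- severity_rank(scene$classes)
  pal <- cbind(
    R = 0.80 - 0.010 * k,
    G = 0.55 - 0.012 * k,
    B = 0.55 - 0.012 * k
  )
  d <- dim(scene$truth_map)
  with_seed(scene$seed + 2L, {
    img <- array(0, dim = c(d[1L], d[2L], 3L))
    for (ch in 1:3) {
      plane <- matrix(pal[scene$truth_map, ch], d[1L], d[2L]) *
        scene$illumination_field * 255
      img[, , ch] <- pmin(pmax(plane + stats::rnorm(prod(d), sd = noise_sd_rgb),
                               0), 255)
    }
    img
  })
}

seed_patch <- function(center, half = 2L, nr, nc) {
  r <- pmin(pmax((center[1L] - half):(center[1L] + half), 1L), nr)
  c <- pmin(pmax((center[2L] - half):(center[2L] + half), 1L), nc)
  as.matrix(expand.grid(row = unique(r), col = unique(c)))
}

#' Seed labels from a phantom scene, one small patch per class
#'
#' Emulates the manual labeling step: for each class, a square patch of up to
#' `(2*half+1)^2` pixels centered on the pixel of that class's first
#' ground-truth region nearest the region centroid, restricted to pixels of
#' the class itself (an annular region's centroid can fall outside it). For
#' disk regions wider than the patch — the comparison-experiment layout — the
#' patches are complete and equal-size per class, making the summed and
#' seed-count-corrected classifier modes agree.
#'
#' @param scene a [phantom_scene()] with regions.
#' @param half patch half-width in pixels.
#' @return A [seed_labels()].
#' @export
scene_seed_labels <- function(scene, half = 2L) {
  nr <- nrow(scene$truth_map); nc <- ncol(scene$truth_map)
  seeds <- lapply(scene$classes, function(cls) {
    rg <- Filter(function(r) r$class == cls, scene$regions)
    if (length(rg) == 0L)
      stop(sprintf("scene has no region of class '%s' to seed from", cls))
    px <- rg[[1L]]$pixels
    ctr <- colMeans(px)
    center <- px[which.min((px[, 1L] - ctr[1L])^2 + (px[, 2L] - ctr[2L])^2), ]
    patch <- seed_patch(as.integer(round(center)), half, nr, nc)
    own <- scene$truth_map[patch] == match(cls, scene$classes)
    patch[own, , drop = FALSE]
  })
  names(seeds) <- scene$classes
  seed_labels(scene$classes, seeds,
              source_note = sprintf("phantom centroid patches, seed %d",
                                    scene$seed))
}

#' Run the two-arm reference comparison experiment
#'
#' Builds the 24-region `table1` phantom (7 normal / 5 inflammation / 3 CIN1 /
#' 3 CIN2 / 3 CIN3 / 3 carcinoma-in-situ disk regions), renders sample, dark
#' and board mosaic frames, then runs the full SNBI pipeline — demosaic,
#' flat-field normalization, four-band fusion with auto alpha, and seeded
#' minimum-distance classification with one equal-size seed patch per class —
#' and scores region-level accuracy against ground truth. The same classifier
#' with the same seed coordinates is then run on a synthetic white-light
#' color image of the same scene (compressed inter-grade contrast, no
#' flat-field correction), giving the comparison arm.
#'
#' @param seed integer seed for the scene and all rendering noise.
#' @param contrast contrast level in `(0, 1]`.
#' @param noise_sd sensor noise s.d. in counts.
#' @param spectral_pixels `c(columns, rows)` of the experiment canvas.
#' @param subpixel_bin sensor pixels per sub-spectral pixel.
#' @param mode classifier mode; seed patches are equal-size so `"sum"` and
#'   `"rms"` agree.
#' @return A list of class `snbi_experiment`: `snbi` and `color`
#'   (accuracy reports), `alpha`, `scene`, `seeds`, and the two
#'   classification maps.
#' @examples
#' \donttest{
#' rep <- run_reference_experiment(seed = 42)
#' rep$snbi$accuracy_pct
#' }
#' @export
run_reference_experiment <- function(seed = 42L, contrast = 1, noise_sd = 200,
                                     spectral_pixels = c(160L, 135L),
                                     subpixel_bin = 2L,
                                     mode = c("sum", "rms")) {
  mode <- match.arg(mode)
  layout <- mosaic_layout(spectral_pixels = spectral_pixels,
                          subpixel_bin = subpixel_bin)
  scene <- make_scene("table1", spectral_pixels = spectral_pixels,
                      contrast = contrast, noise_sd = noise_sd, seed = seed)
  frames <- render_frames(scene, layout)
  stack <- demosaic(frames$sample, layout)
  refs <- build_references(lapply(frames$dark, demosaic, layout = layout),
                           lapply(frames$board, demosaic, layout = layout))
  normalized <- normalize_stack(stack, refs)
  fused <- fuse_bands(normalized)
  seeds <- scene_seed_labels(scene)
  cmap_snbi <- classify_pixels(fused, seeds, mode = mode)
  report_snbi <- evaluate_regions(cmap_snbi, scene$regions)
  color_img <- render_color_image(scene)
  cmap_color <- classify_pixels(color_img, seeds, mode = mode)
  report_color <- evaluate_regions(cmap_color, scene$regions)
  structure(
    list(snbi = report_snbi, color = report_color, alpha = fused$alpha,
         scene = scene, seeds = seeds, fused = fused,
         map_snbi = cmap_snbi, map_color = cmap_color),
    class = "snbi_experiment"
  )
}

#' @export
print.snbi_experiment <- function(x, ...) {
  cat(sprintf(
    "<snbi_experiment> %d regions: SNBI arm %.1f%%, color arm %.1f%%\n",
    x$snbi$n_regions, x$snbi$accuracy_pct, x$color$accuracy_pct))
  invisible(x)
}
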