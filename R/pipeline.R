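#' Run the full SNBI pipeline on one raw frame
#'
#' Chains every stage — demosaic, reference building (or loading), flat-field
#' normalization, four-band fusion, seeded classification and contour
#' extraction — and writes the output bundle: one TIFF per band, the fused
#' image (32-bit float TIFF), the label map (indexed PNG + palette JSON), the
#' contour mask (binary PNG) and a JSON manifest recording every parameter
#' that affects the outputs.
#'
#' @param raw_path path to the raw mosaic frame (TIFF/PNG).
#' @param layout_path path to the mosaic layout (YAML/JSON).
#' @param seeds_path path to the seed labels (JSON).
#' @param out_dir output directory, created if needed.
#' @param dark_paths,board_paths reference frame paths (used when
#'   `refs_path` is `NULL`).
#' @param refs_path optional precomputed reference JSON.
#' @param alpha `"auto"` or a positive number.
#' @param mode classifier mode, `"sum"` or `"rms"`.
#' @param contour_method `"label_boundary"` or `"canny"`.
#' @return The manifest list, invisibly; side effect: files under `out_dir`.
#' @export
run_pipeline <- function(raw_path, layout_path, seeds_path, out_dir,
                         dark_paths = NULL, board_paths = NULL,
                         refs_path = NULL, alpha = "auto",
                         mode = c("sum", "rms"),
                         contour_method = c("label_boundary", "canny")) {
  mode <- match.arg(mode)
  contour_method <- match.arg(contour_method)
  for (p in c(raw_path, layout_path, seeds_path, refs_path,
              dark_paths, board_paths))
    if (!file.exists(p)) stop(sprintf("input file not found: %s", p))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  layout <- read_layout(layout_path)
  raw <- read_raster(raw_path)
  stack <- demosaic(raw_frame(raw, attr(raw, "bit_depth") %||% 16L), layout)

  if (!is.null(refs_path)) {
    refs <- read_references(refs_path)
  } else {
    if (is.null(dark_paths) || is.null(board_paths))
      stop("calibration requires either `refs_path` or both `dark_paths` and `board_paths`")
    load_stack <- function(p) {
      r <- read_raster(p)
      demosaic(raw_frame(r, attr(r, "bit_depth") %||% 16L), layout)
    }
    refs <- build_references(lapply(dark_paths, load_stack),
                             lapply(board_paths, load_stack))
  }
  normalized <- normalize_stack(stack, refs)
  fused <- if (identical(alpha, "auto")) fuse_bands(normalized)
           else fuse_bands(normalized, alpha = as.numeric(alpha))
  seeds <- read_seed_labels(seeds_path)
  cmap <- classify_pixels(fused, seeds, mode = mode)
  contours <- extract_contours(cmap, method = contour_method)

  band_dir <- file.path(out_dir, "bands")
  dir.create(band_dir, showWarnings = FALSE)
  band_files <- vapply(names(stack$bands), function(w) {
    f <- file.path(band_dir, sprintf("band_%snm.tif", w))
    write_raster(round(stack$bands[[w]]), f, bits = 16L)
    f
  }, character(1))
  write_raster(fused$pixels, file.path(out_dir, "fused.tif"),
               bits = 32L, scale = 255)
  write_references(refs, file.path(out_dir, "refs.json"))
  write_classification_png(cmap, file.path(out_dir, "labels.png"))
  png::writePNG(contours$boundary_mask * 1,
                file.path(out_dir, "contours.png"))

  manifest <- list(
    package_version = as.character(utils::packageVersion("snbi")),
    inputs = list(raw = basename(raw_path), layout = basename(layout_path),
                  seeds = basename(seeds_path)),
    layout = list(
      wavelengths_nm = layout$wavelengths,
      spectral_pixels = c(layout$spectral_cols, layout$spectral_rows),
      subpixel_bin = layout$subpixel_bin, gap_margin = layout$gap_margin),
    references = list(dark_mean = as.list(refs$dark_mean),
                      board_mean = as.list(refs$board_mean),
                      n_dark_frames = refs$n_dark_frames,
                      n_board_frames = refs$n_board_frames),
    alpha = fused$alpha, alpha_policy = fused$alpha_policy,
    classifier_mode = mode, classes = seeds$classes,
    contour_method = contour_method,
    outputs = c(list(fused = "fused.tif", labels = "labels.png",
                     contours = "contours.png"),
                stats::setNames(as.list(basename(band_files)),
                                paste0("band_", names(stack$bands))))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
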