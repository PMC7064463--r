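#' Read a single-channel raster image
#'
#' Reads an 8- or 16-bit grayscale TIFF or PNG into a numeric matrix of
#' integer sensor counts (0..255 or 0..65535). Multi-channel files are
#' rejected.
#'
#' @param path file path ending in `.tif`, `.tiff` or `.png`.
#' @return Numeric matrix of intensities, plus attribute `bit_depth`.
#' @export
read_raster <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, as.is = TRUE)
    depth <- if (max(img) > 255) 16L else attr(img, "bits.per.sample") %||% 16L
  } else if (ext == "png") {
    img <- png::readPNG(path)
    depth <- 16L
    img <- round(img * (2^depth - 1))
  } else {
    stop(sprintf("unsupported raster format '.%s'", ext))
  }
  if (length(dim(img)) == 3L) {
    if (dim(img)[3L] == 1L) img <- img[, , 1L]
    else stop("expected a single-channel raster")
  }
  structure(as.matrix(img), bit_depth = as.integer(depth))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a single-channel raster image
#'
#' Integer rasters go to 8- or 16-bit TIFF/PNG; continuous rasters (e.g. a
#' fused image) go to 32-bit float TIFF with values scaled by `scale` into
#' `[0, 1]`.
#'
#' @param x numeric matrix.
#' @param path output path (`.tif`/`.tiff`/`.png`).
#' @param bits 8, 16 or 32 (32 = float TIFF).
#' @param scale maximum representable value for the chosen depth; values are
#'   divided by it before writing. Defaults to `2^bits - 1` (255 for float).
#' @return `path`, invisibly.
#' @export
write_raster <- function(x, path, bits = 16L, scale = NULL) {
  ext <- tolower(tools::file_ext(path))
  scale <- scale %||% if (bits == 32L) 255 else 2^bits - 1
  v <- pmin(pmax(x / scale, 0), 1)
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(v, path, bits.per.sample = as.integer(bits))
  } else if (ext == "png") {
    if (bits == 32L) stop("PNG supports 8 or 16 bits only")
    png::writePNG(v, path)
  } else {
    stop(sprintf("unsupported raster format '.%s'", ext))
  }
  invisible(path)
}

#' Read or write a mosaic layout description
#'
#' YAML or JSON with keys `wavelengths_nm`, `positions` (wavelength ->
#' `[row, col]` cell, 0-based), `spectral_pixels` (`[columns, rows]`, the
#' order used in data sheets), `subpixel_bin`, `gap_margin`.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return [read_layout()]: a [mosaic_layout()].
#' @export
read_layout <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else jsonlite::fromJSON(path, simplifyVector = TRUE)
  mosaic_layout(
    spectral_pixels = as.integer(cfg$spectral_pixels),
    subpixel_bin = cfg$subpixel_bin %||% 4L,
    gap_margin = cfg$gap_margin %||% 0L,
    wavelengths_nm = as.numeric(cfg$wavelengths_nm),
    positions = if (!is.null(cfg$positions))
      lapply(cfg$positions, as.integer) else NULL
  )
}

#' @param layout a [mosaic_layout()] to serialize.
#' @rdname read_layout
#' @export
write_layout <- function(layout, path) {
  cfg <- list(
    wavelengths_nm = layout$wavelengths,
    positions = layout$positions,
    spectral_pixels = c(layout$spectral_cols, layout$spectral_rows),
    subpixel_bin = layout$subpixel_bin,
    gap_margin = layout$gap_margin
  )
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) yaml::write_yaml(cfg, path)
  else jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read or write a calibration reference set as JSON
#'
#' @param path JSON file with per-wavelength `dark_mean`/`board_mean` and
#'   frame counts.
#' @return [read_references()]: a [reference_set()].
#' @export
read_references <- function(path) {
  cfg <- jsonlite::fromJSON(path)
  reference_set(unlist(cfg$dark_mean), unlist(cfg$board_mean),
                n_dark_frames = cfg$n_dark_frames %||% 1L,
                n_board_frames = cfg$n_board_frames %||% 1L)
}

#' @param refs a [reference_set()] to serialize.
#' @rdname read_references
#' @export
write_references <- function(refs, path) {
  jsonlite::write_json(
    list(dark_mean = as.list(refs$dark_mean),
         board_mean = as.list(refs$board_mean),
         n_dark_frames = refs$n_dark_frames,
         n_board_frames = refs$n_board_frames),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read or write seed labels as JSON
#'
#' On disk, coordinates are 0-based `[row, col]` pairs (image convention,
#' origin top-left); in memory they are 1-based.
#'
#' @param path JSON file with fields `classes` and `seeds`.
#' @return [read_seed_labels()]: a [seed_labels()].
#' @export
read_seed_labels <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  seeds <- lapply(cfg$seeds, function(px) {
    m <- do.call(rbind, lapply(px, as.integer)) + 1L
    colnames(m) <- c("row", "col")
    m
  })
  seed_labels(unlist(cfg$classes), seeds,
              source_note = cfg$source_note %||% "")
}

#' @param seeds a [seed_labels()] to serialize.
#' @rdname read_seed_labels
#' @export
write_seed_labels <- function(seeds, path) {
  out <- list(
    classes = seeds$classes,
    seeds = lapply(seeds$seeds, function(m) {
      lapply(seq_len(nrow(m)), function(i) as.integer(m[i, ] - 1L))
    }),
    source_note = seeds$source_note
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Default display palette for tissue classes
#'
#' Green for normal, gray for CIN2, pink for CIN3 and red for carcinoma in
#' situ, matching the conventional display of graded classification maps;
#' intermediate grades get intermediate hues.
#'
#' @param classes class names.
#' @return Named character vector of hex colors.
#' @export
class_palette <- function(classes = snbi_classes()) {
  defaults <- c(normal = "#2E8B57", inflammation = "#DAA520",
                CIN1 = "#87CEEB", CIN2 = "#808080",
                CIN3 = "#FFC0CB", carcinoma_in_situ = "#FF0000")
  cols <- defaults[classes]
  if (anyNA(cols))
    cols[is.na(cols)] <- grDevices::hcl.colors(sum(is.na(cols)), "Dark 3")
  stats::setNames(cols, classes)
}

#' Write a classification map as an indexed PNG plus palette JSON
#'
#' The PNG stores the 0-based class index in the 8-bit gray channel; the
#' sidecar JSON maps each class name to its index and display color.
#'
#' @param cmap a [classification_map()].
#' @param path output PNG path; the palette goes to `<path>.palette.json`.
#' @return `path`, invisibly.
#' @export
write_classification_png <- function(cmap, path) {
  png::writePNG((cmap$labels - 1L) / 255, path)
  pal <- class_palette(cmap$classes)
  jsonlite::write_json(
    list(classes = cmap$classes,
         index = as.list(stats::setNames(seq_along(cmap$classes) - 1L,
                                         cmap$classes)),
         color = as.list(pal)),
    paste0(path, ".palette.json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a classification map written by [write_classification_png()]
#'
#' @param path PNG path with its `<path>.palette.json` sidecar.
#' @return A [classification_map()].
#' @export
read_classification_png <- function(path) {
  pal <- jsonlite::fromJSON(paste0(path, ".palette.json"))
  idx <- round(png::readPNG(path) * 255) + 1L
  classification_map(idx, pal$classes)
}
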