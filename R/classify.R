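#' Seed labels for the minimum-distance classifier
#'
#' A few manually marked pixels per tissue type — weak supervision: the expert
#' identifies one or two small regions of each type without delineating their
#' boundaries. Coordinates are 1-based `(row, col)` on the image to be
#' classified.
#'
#' @param classes ordered character vector of tissue-type names (>= 2); the
#'   order defines tie-breaking and label indices.
#' @param seeds named list, class -> integer matrix with columns (row, col).
#' @param source_note free-text provenance of the labels.
#' @return An object of class `seed_labels`.
#' @examples
#' seed_labels(c("normal", "CIN2"),
#'             list(normal = rbind(c(1, 1)), CIN2 = rbind(c(5, 5))))
#' @export
seed_labels <- function(classes, seeds, source_note = "") {
  classes <- as.character(classes)
  if (length(classes) < 2L) stop("at least 2 classes are required")
  if (anyDuplicated(classes)) stop("class names must be distinct")
  if (!setequal(names(seeds), classes))
    stop("`seeds` must name exactly the declared classes")
  seeds <- lapply(seeds[classes], function(m) {
    m <- matrix(as.integer(m), ncol = 2L,
                dimnames = list(NULL, c("row", "col")))
    if (nrow(m) < 1L) stop("every class needs at least one seed pixel")
    m
  })
  all_px <- do.call(rbind, seeds)
  if (anyDuplicated(all_px))
    stop("a pixel may not be labeled with more than one class")
  structure(list(classes = classes, seeds = seeds,
                 source_note = as.character(source_note)),
            class = "seed_labels")
}

#' @export
print.seed_labels <- function(x, ...) {
  n <- vapply(x$seeds, nrow, integer(1))
  cat(sprintf("<seed_labels> %s\n",
              paste(sprintf("%s (%d px)", x$classes, n), collapse = ", ")))
  invisible(x)
}

#' Per-pixel tissue classification map
#'
#' @param labels integer matrix of class indices into `classes`.
#' @param classes ordered character vector of class names.
#' @param distances optional named list of per-class distance rasters.
#' @return An object of class `classification_map`.
#' @export
classification_map <- function(labels, classes, distances = NULL) {
  if (any(labels < 1L) || any(labels > length(classes)))
    stop("label indices must reference the class list")
  structure(list(labels = labels, classes = as.character(classes),
                 distances = distances),
            class = "classification_map")
}

#' @export
print.classification_map <- function(x, ...) {
  tab <- tabulate(x$labels, nbins = length(x$classes))
  cat(sprintf("<classification_map> %d x %d px\n",
              nrow(x$labels), ncol(x$labels)))
  cat(paste(sprintf("  %s: %d px", x$classes, tab), collapse = "\n"), "\n")
  invisible(x)
}

image_channels <- function(image) {
  if (inherits(image, "fused_image")) image <- image$pixels
  if (is.matrix(image)) {
    list(dim = dim(image), mat = matrix(as.numeric(image), ncol = 1L))
  } else if (is.array(image) && length(dim(image)) == 3L) {
    d <- dim(image)
    list(dim = d[1:2], mat = matrix(as.numeric(image), ncol = d[3L]))
  } else {
    stop("image must be a matrix or a rows x cols x channels array")
  }
}

#' Classify every pixel by minimum Euclidean distance to seed pixels
#'
#' For a pixel with intensity (vector) `I` and the seed pixels
#' `S_i^x, i = 1..p` of tissue type `x`, the distance to type `x` is
#' \deqn{D_{Ex} = \sqrt{\sum_{i=1}^{p} (I - S_i^x)^2}}
#' and the pixel is assigned the type with the smallest \eqn{D_{Ex}}.
#' `mode = "sum"` is this summed form verbatim; because the sum grows with the
#' number of seeds `p`, it biases against classes with more seeds when seed
#' counts are unequal — `mode = "rms"` divides by `p` inside the root to
#' remove that bias. With equal seed counts per class the two modes agree.
#'
#' Works on a single-channel image (the fused image, the default use) or a
#' multi-channel image (e.g. an RGB color image, using the per-pixel vector
#' Euclidean norm), which enables like-for-like comparison of the same
#' classifier on both. Ties are broken by class order; seed pixels always
#' retain their own class.
#'
#' @param image numeric matrix, rows x cols x channels array, or a
#'   [fused_image()].
#' @param seeds a [seed_labels()] whose coordinates lie within the image.
#' @param mode `"sum"` (summed distance, faithful to the definition above) or
#'   `"rms"` (seed-count-corrected).
#' @param keep_distances if `TRUE`, attach per-class distance rasters.
#' @return A [classification_map()].
#' @examples
#' img <- matrix(c(10, 30, 100, 90), 2, 2)
#' sl <- seed_labels(c("A", "B"), list(A = rbind(c(1, 1)), B = rbind(c(1, 2))))
#' classify_pixels(img, sl)$labels
#' @export
classify_pixels <- function(image, seeds, mode = c("sum", "rms"),
                            keep_distances = FALSE) {
  mode <- match.arg(mode)
  ch <- image_channels(image)
  nr <- ch$dim[1L]; nc <- ch$dim[2L]
  for (x in seeds$classes) {
    m <- seeds$seeds[[x]]
    if (any(m[, 1L] < 1L) || any(m[, 1L] > nr) ||
        any(m[, 2L] < 1L) || any(m[, 2L] > nc))
      stop(sprintf("seed coordinates of class '%s' fall outside the image", x))
  }
  q <- rowSums(ch$mat^2)                       # ||I||^2 per pixel
  D2 <- matrix(NA_real_, nrow = nr * nc, ncol = length(seeds$classes))
  for (k in seq_along(seeds$classes)) {
    m <- seeds$seeds[[seeds$classes[k]]]
    idx <- m[, 1L] + (m[, 2L] - 1L) * nr
    S <- ch$mat[idx, , drop = FALSE]           # p x channels
    p <- nrow(S)
    # sum_i ||I - S_i||^2 = p ||I||^2 - 2 I . sum(S_i) + sum ||S_i||^2
    d2 <- p * q - 2 * drop(ch$mat %*% colSums(S)) + sum(S^2)
    d2[d2 < 0] <- 0                            # guard float round-off
    if (mode == "rms") d2 <- d2 / p
    D2[, k] <- d2
  }
  lab <- max.col(-D2, ties.method = "first")
  for (k in seq_along(seeds$classes)) {        # seed fidelity
    m <- seeds$seeds[[seeds$classes[k]]]
    lab[m[, 1L] + (m[, 2L] - 1L) * nr] <- k
  }
  distances <- NULL
  if (keep_distances) {
    distances <- lapply(seq_along(seeds$classes),
                        function(k) matrix(sqrt(D2[, k]), nr, nc))
    names(distances) <- seeds$classes
  }
  classification_map(matrix(lab, nr, nc), seeds$classes, distances)
}

#' Region-level accuracy of a classification map
#'
#' Scores each ground-truth region by majority vote: the region's predicted
#' class is the most frequent label over its pixels (ties broken by class
#' order), and the region counts as correct iff that majority class equals its
#' true class. Overall accuracy is correct regions / total regions, in
#' percent.
#'
#' @param cmap a [classification_map()].
#' @param truth_regions list of regions, each a list with elements `class`
#'   (name) and `pixels` (integer matrix with columns row, col) or `mask`
#'   (logical matrix of the map's shape).
#' @return A list of class `accuracy_report`: `n_regions`, `n_correct`,
#'   `accuracy_pct`, `per_class` (data frame with regions/correct per class),
#'   and `region_results`.
#' @export
evaluate_regions <- function(cmap, truth_regions) {
  if (length(truth_regions) < 1L) stop("at least one truth region is required")
  nr <- nrow(cmap$labels); nc <- ncol(cmap$labels)
  results <- lapply(truth_regions, function(rg) {
    if (is.null(rg$class) || !(rg$class %in% cmap$classes))
      stop("every region needs a `class` present in the map's class list")
    if (!is.null(rg$mask)) {
      idx <- which(rg$mask)
    } else {
      m <- rg$pixels
      if (any(m[, 1L] < 1L) || any(m[, 1L] > nr) ||
          any(m[, 2L] < 1L) || any(m[, 2L] > nc))
        stop("truth region pixels fall outside the map")
      idx <- m[, 1L] + (m[, 2L] - 1L) * nr
    }
    counts <- tabulate(cmap$labels[idx], nbins = length(cmap$classes))
    pred <- cmap$classes[which.max(counts)]
    list(truth = rg$class, predicted = pred, correct = pred == rg$class,
         n_pixels = length(idx))
  })
  truth <- vapply(results, `[[`, character(1), "truth")
  correct <- vapply(results, `[[`, logical(1), "correct")
  per_class <- data.frame(
    class = cmap$classes,
    regions = vapply(cmap$classes, function(x) sum(truth == x), integer(1)),
    correct = vapply(cmap$classes, function(x) sum(correct[truth == x]),
                     integer(1)),
    row.names = NULL
  )
  structure(
    list(n_regions = length(results), n_correct = sum(correct),
         accuracy_pct = 100 * sum(correct) / length(results),
         per_class = per_class, region_results = results),
    class = "accuracy_report"
  )
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("<accuracy_report> %d/%d regions correct (%.1f%%)\n",
              x$n_correct, x$n_regions, x$accuracy_pct))
  print(x$per_class, row.names = FALSE)
  invisible(x)
}
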