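#' Dark and white-board reference statistics
#'
#' Per-band scalar means of the dark-current frames and of the white
#' (Teflon-board) reference frames, used for flat-field normalization. The
#' correction is scalar per band — it removes band-dependent illumination
#' strength, sensor quantum efficiency and filter transmittance, the three
#' effects that differ between bands of one snapshot.
#'
#' @param dark_mean named numeric vector, wavelength -> mean dark intensity.
#' @param board_mean named numeric vector, wavelength -> mean board intensity.
#' @param n_dark_frames,n_board_frames number of frames averaged.
#' @return An object of class `reference_set`.
#' @export
reference_set <- function(dark_mean, board_mean,
                          n_dark_frames = 1L, n_board_frames = 1L) {
  if (!setequal(names(dark_mean), names(board_mean)))
    stop("dark and board means must cover the same bands")
  board_mean <- board_mean[names(dark_mean)]
  if (anyNA(dark_mean) || anyNA(board_mean) ||
      any(!is.finite(dark_mean)) || any(!is.finite(board_mean)) ||
      any(dark_mean < 0) || any(board_mean < 0))
    stop("reference means must be finite and >= 0")
  bad <- names(dark_mean)[board_mean <= dark_mean]
  if (length(bad) > 0L)
    stop(sprintf("board mean must exceed dark mean; violated for band(s) %s nm",
                 paste(bad, collapse = ", ")))
  structure(
    list(dark_mean = dark_mean, board_mean = board_mean,
         n_dark_frames = as.integer(n_dark_frames),
         n_board_frames = as.integer(n_board_frames)),
    class = "reference_set"
  )
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("<reference_set> %d dark / %d board frame(s)\n",
              x$n_dark_frames, x$n_board_frames))
  for (w in names(x$dark_mean))
    cat(sprintf("  %s nm: dark %.3f, board %.3f\n",
                w, x$dark_mean[[w]], x$board_mean[[w]]))
  invisible(x)
}

#' Build normalization references from dark and board frames
#'
#' Computes, for every band, the grand mean over all pixels of all supplied
#' dark-current stacks and white-board stacks.
#'
#' @param dark_stacks list of [spectral_stack()]s of the capped/dark sensor.
#' @param board_stacks list of [spectral_stack()]s of the uniform white board.
#' @return A [reference_set()].
#' @export
build_references <- function(dark_stacks, board_stacks) {
  if (inherits(dark_stacks, "spectral_stack")) dark_stacks <- list(dark_stacks)
  if (inherits(board_stacks, "spectral_stack")) board_stacks <- list(board_stacks)
  if (length(dark_stacks) < 1L || length(board_stacks) < 1L)
    stop("at least one dark stack and one board stack are required")
  bands <- names(dark_stacks[[1L]]$bands)
  for (s in c(dark_stacks, board_stacks))
    if (!setequal(names(s$bands), bands))
      stop("all reference stacks must share the same band set")
  grand_mean <- function(stacks, w)
    mean(unlist(lapply(stacks, function(s) s$bands[[w]]), use.names = FALSE))
  dark_mean <- vapply(bands, function(w) grand_mean(dark_stacks, w), numeric(1))
  board_mean <- vapply(bands, function(w) grand_mean(board_stacks, w), numeric(1))
  reference_set(dark_mean, board_mean,
                n_dark_frames = length(dark_stacks),
                n_board_frames = length(board_stacks))
}

#' Flat-field normalization of a spectral stack
#'
#' Applies, per band and pixel,
#' \deqn{I(\lambda) = \frac{I(\lambda)_{sample} - \bar I(\lambda)_{dark}}
#'                         {\bar I(\lambda)_{board} - \bar I(\lambda)_{dark}}}
#' using the scalar per-band reference means. Values below 0 (reflectance is
#' physically non-negative) are clipped to 0; values above 1 are permitted —
#' specular highlights can exceed the matte reference board — but their count
#' is reported via a message.
#'
#' Normalizing an already-normalized stack is refused.
#'
#' @param stack an unnormalized [spectral_stack()].
#' @param refs a [reference_set()] covering the same bands.
#' @return A [spectral_stack()] with `normalized = TRUE`.
#' @examples
#' s <- spectral_stack(list(`415` = matrix(110, 2, 2)))
#' r <- reference_set(c(`415` = 10), c(`415` = 210))
#' normalize_stack(s, r)$bands[["415"]] # 0.5 everywhere
#' @export
normalize_stack <- function(stack, refs) {
  if (stack$normalized)
    stop("stack is already normalized; refusing to normalize twice")
  if (!all(names(stack$bands) %in% names(refs$dark_mean)))
    stop("reference set does not cover all bands of the stack")
  out <- lapply(names(stack$bands), function(w) {
    denom <- refs$board_mean[[w]] - refs$dark_mean[[w]]
    if (denom <= 0)
      stop(sprintf("non-positive normalization denominator for band %s nm", w))
    v <- (stack$bands[[w]] - refs$dark_mean[[w]]) / denom
    v[v < 0] <- 0
    v
  })
  names(out) <- names(stack$bands)
  n_over <- sum(vapply(out, function(v) sum(v > 1), numeric(1)))
  if (n_over > 0L)
    message(sprintf("normalize_stack: %d pixel(s) above 1 (brighter than board)",
                    n_over))
  spectral_stack(out, normalized = TRUE)
}
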