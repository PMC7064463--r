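# Independent brute-force implementations used as oracles. These deliberately
# mirror the definitions pixel by pixel and seed by seed, with none of the
# vectorized algebra of the package code paths they check.

# Naive double-loop minimum-distance classifier: for every pixel, accumulate
# squared differences to every seed pixel of every class, take the argmin.
brute_force_classify <- function(image, seeds, mode = "sum") {
  if (is.matrix(image)) image <- array(image, dim = c(dim(image), 1L))
  nr <- dim(image)[1L]; nc <- dim(image)[2L]; nch <- dim(image)[3L]
  labels <- matrix(NA_integer_, nr, nc)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      best <- Inf; best_k <- NA_integer_
      for (k in seq_along(seeds$classes)) {
        m <- seeds$seeds[[seeds$classes[k]]]
        acc <- 0
        for (i in seq_len(nrow(m))) {
          for (ch in seq_len(nch)) {
            diffv <- image[r, c, ch] - image[m[i, 1L], m[i, 2L], ch]
            acc <- acc + diffv^2
          }
        }
        if (mode == "rms") acc <- acc / nrow(m)
        d <- sqrt(acc)
        if (d < best) { best <- d; best_k <- k }
      }
      labels[r, c] <- best_k
    }
  }
  for (k in seq_along(seeds$classes)) {
    m <- seeds$seeds[[seeds$classes[k]]]
    for (i in seq_len(nrow(m))) labels[m[i, 1L], m[i, 2L]] <- k
  }
  labels
}

# Enumerate 4-neighbor label disagreements pixel by pixel.
brute_force_boundary <- function(labels) {
  nr <- nrow(labels); nc <- ncol(labels)
  out <- matrix(FALSE, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
      rr <- r + d[1L]; cc <- c + d[2L]
      if (rr >= 1L && rr <= nr && cc >= 1L && cc <= nc &&
          labels[rr, cc] != labels[r, c])
        out[r, c] <- TRUE
    }
  }
  out
}

# Random seed labels on an image: k classes, 1..4 distinct seed pixels each.
random_seed_labels <- function(nr, nc, n_classes, equal_counts = FALSE) {
  n_per <- if (equal_counts) rep(sample(1:4, 1L), n_classes)
           else sample(1:4, n_classes, replace = TRUE)
  all_idx <- sample(nr * nc, sum(n_per))
  splits <- rep(seq_len(n_classes), n_per)
  seeds <- lapply(seq_len(n_classes), function(k) {
    idx <- all_idx[splits == k]
    cbind(row = (idx - 1L) %% nr + 1L, col = (idx - 1L) %/% nr + 1L)
  })
  classes <- paste0("class", seq_len(n_classes))
  names(seeds) <- classes
  seed_labels(classes, seeds)
}

# Small random unnormalized stack over the four standard bands.
random_stack <- function(nr = 4L, nc = 5L, max_val = 1000) {
  bands <- lapply(c("415", "450", "525", "620"), function(w)
    matrix(runif(nr * nc, 0, max_val), nr, nc))
  names(bands) <- c("415", "450", "525", "620")
  spectral_stack(bands)
}
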