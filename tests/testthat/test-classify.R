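test_that("a pixel equal to a class's only seed value gets that class", {
  img <- matrix(c(10, 10, 100, 100), 2, 2)
  sl <- seed_labels(c("A", "B"), list(A = rbind(c(1, 1)), B = rbind(c(1, 2))))
  cmap <- classify_pixels(img, sl, keep_distances = TRUE)
  expect_equal(cmap$labels, matrix(c(1L, 1L, 2L, 2L), 2, 2))
  expect_equal(cmap$distances[["A"]][2, 1], 0)
})

test_that("summed distances match the hand computation", {
  # classes A (seed values 10 and 20) and B (seed value 100); pixel value 30:
  # D_A = sqrt(400 + 100) = sqrt(500), D_B = 70 -> A
  img <- matrix(c(10, 20, 100, 30), 1, 4)
  sl <- seed_labels(c("A", "B"),
                    list(A = rbind(c(1, 1), c(1, 2)), B = rbind(c(1, 3))))
  cmap <- classify_pixels(img, sl, mode = "sum", keep_distances = TRUE)
  expect_equal(cmap$distances[["A"]][1, 4], sqrt(500))
  expect_equal(cmap$distances[["B"]][1, 4], 70)
  expect_equal(cmap$classes[cmap$labels[1, 4]], "A")
})

test_that("classifier matches the brute-force double loop on random instances", {
  set.seed(61)
  for (trial in 1:50) {
    nr <- sample(3:12, 1); nc <- sample(3:12, 1)
    n_classes <- sample(2:6, 1)
    nch <- sample(c(1L, 3L), 1)
    img <- if (nch == 1L) matrix(runif(nr * nc, 0, 100), nr, nc)
           else array(runif(nr * nc * 3, 0, 100), dim = c(nr, nc, 3L))
    sl <- random_seed_labels(nr, nc, n_classes)
    for (mode in c("sum", "rms")) {
      got <- classify_pixels(img, sl, mode = mode)$labels
      want <- brute_force_classify(img, sl, mode = mode)
      expect_identical(got, want)
    }
  }
})

test_that("permuting seed order within a class leaves labels unchanged", {
  set.seed(71)
  img <- matrix(runif(64, 0, 10), 8, 8)
  sl <- random_seed_labels(8, 8, 3)
  perm <- sl
  perm$seeds <- lapply(perm$seeds, function(m) m[rev(seq_len(nrow(m))), ,
                                                 drop = FALSE])
  expect_identical(classify_pixels(img, sl)$labels,
                   classify_pixels(img, perm)$labels)
})

test_that("labels are invariant to a positive rescaling of the image", {
  set.seed(81)
  img <- matrix(runif(100, 0, 1), 10, 10)
  sl <- random_seed_labels(10, 10, 4)
  expect_identical(classify_pixels(img, sl)$labels,
                   classify_pixels(img * 37.5, sl)$labels)
})

test_that("seed pixels retain their own class under rms with separated classes", {
  img <- matrix(c(1.0, 1.1, 1.2, 9.0, 9.1, 9.2), 1, 6)
  sl <- seed_labels(c("lo", "hi"),
                    list(lo = rbind(c(1, 1), c(1, 2), c(1, 3)),
                         hi = rbind(c(1, 4), c(1, 5), c(1, 6))))
  cmap <- classify_pixels(img, sl, mode = "rms")
  expect_equal(cmap$labels, matrix(c(1L, 1L, 1L, 2L, 2L, 2L), 1, 6))
})

test_that("ties break toward the first class in declared order", {
  img <- matrix(c(0, 10, 5), 1, 3)            # pixel 5 is equidistant
  sl <- seed_labels(c("A", "B"), list(A = rbind(c(1, 1)), B = rbind(c(1, 2))))
  expect_equal(classify_pixels(img, sl)$labels[1, 3], 1L)
  sl_rev <- seed_labels(c("B", "A"),
                        list(B = rbind(c(1, 2)), A = rbind(c(1, 1))))
  expect_equal(sl_rev$classes[classify_pixels(img, sl_rev)$labels[1, 3]], "B")
})

test_that("invalid seed input is rejected", {
  img <- matrix(0, 4, 4)
  expect_error(seed_labels("A", list(A = rbind(c(1, 1)))), "at least 2")
  expect_error(
    seed_labels(c("A", "B"), list(A = rbind(c(1, 1)), B = rbind(c(1, 1)))),
    "more than one class")
  sl <- seed_labels(c("A", "B"), list(A = rbind(c(1, 1)), B = rbind(c(9, 9))))
  expect_error(classify_pixels(img, sl), "outside the image")
})

test_that("uniform maps have empty boundaries", {
  cmap <- classification_map(matrix(1L, 5, 5), c("A", "B"))
  expect_equal(sum(extract_contours(cmap)$boundary_mask), 0)
})

test_that("a left/right split yields the two-column boundary pair", {
  labels <- cbind(matrix(1L, 4, 3), matrix(2L, 4, 3))
  cmap <- classification_map(labels, c("A", "B"))
  mask <- extract_contours(cmap, "label_boundary")$boundary_mask
  want <- matrix(FALSE, 4, 6); want[, 3:4] <- TRUE
  expect_equal(mask, want)
})

test_that("a nested square produces its perimeter ring plus touching outside pixels", {
  labels <- matrix(1L, 9, 9)
  labels[4:6, 4:6] <- 2L
  cmap <- classification_map(labels, c("A", "B"))
  mask <- extract_contours(cmap)$boundary_mask
  expect_equal(mask, brute_force_boundary(labels))
  ring <- matrix(TRUE, 3, 3); ring[2, 2] <- FALSE
  expect_equal(mask[4:6, 4:6], ring)   # perimeter marked, core interior clear
})

test_that("label_boundary equals the enumerated 4-neighbor disagreement set", {
  set.seed(91)
  for (trial in 1:10) {
    labels <- matrix(sample(1:3, 48, replace = TRUE), 6, 8)
    cmap <- classification_map(labels, c("A", "B", "C"))
    expect_equal(extract_contours(cmap)$boundary_mask,
                 brute_force_boundary(labels))
  }
})

test_that("canny marks edges near a class boundary and nothing on uniform maps", {
  labels <- cbind(matrix(1L, 16, 8), matrix(2L, 16, 8))
  cmap <- classification_map(labels, c("A", "B"))
  mask <- extract_contours(cmap, method = "canny")$boundary_mask
  expect_gt(sum(mask[, 7:10]), 0)
  expect_equal(sum(mask[, c(1:4, 13:16)]), 0)
  flat <- classification_map(matrix(1L, 16, 16), c("A", "B"))
  expect_equal(sum(extract_contours(flat, method = "canny")$boundary_mask), 0)
})

test_that("all-correct regions score 100%", {
  labels <- cbind(matrix(1L, 4, 2), matrix(2L, 4, 2))
  cmap <- classification_map(labels, c("A", "B"))
  regions <- list(list(class = "A", pixels = cbind(1:4, 1L)),
                  list(class = "B", pixels = cbind(1:4, 4L)))
  rep <- evaluate_regions(cmap, regions)
  expect_equal(rep$accuracy_pct, 100)
  expect_equal(rep$n_correct, 2L)
})

test_that("a 24-region six-class composition with 12 correct scores 50%", {
  classes <- snbi_classes()
  counts <- c(7, 5, 3, 3, 3, 3)
  correct_per_class <- c(4, 0, 3, 1, 1, 3)       # sums to 12 of 24
  truth <- rep(seq_along(classes), counts)
  labels <- matrix(0L, 1, length(truth))
  regions <- vector("list", length(truth))
  flip <- unlist(lapply(seq_along(classes), function(k)
    rep(c(TRUE, FALSE), c(correct_per_class[k], counts[k] - correct_per_class[k]))))
  for (i in seq_along(truth)) {
    labels[1, i] <- if (flip[i]) truth[i]
                    else (truth[i] %% length(classes)) + 1L
    regions[[i]] <- list(class = classes[truth[i]],
                         pixels = cbind(1L, i))
  }
  rep <- evaluate_regions(classification_map(labels, classes), regions)
  expect_equal(rep$accuracy_pct, 50)
  expect_equal(rep$per_class$correct, correct_per_class)
  expect_equal(rep$per_class$regions, counts)
})

test_that("region accuracy equals a brute-force tally on random maps", {
  set.seed(101)
  classes <- c("A", "B", "C")
  for (trial in 1:10) {
    labels <- matrix(sample(1:3, 100, replace = TRUE), 10, 10)
    cmap <- classification_map(labels, classes)
    regions <- lapply(1:6, function(i) {
      px <- cbind(sample(10, 4, TRUE), sample(10, 4, TRUE))
      list(class = sample(classes, 1), pixels = px)
    })
    rep <- evaluate_regions(cmap, regions)
    manual <- sum(vapply(regions, function(rg) {
      votes <- labels[cbind(rg$pixels[, 1], rg$pixels[, 2])]
      tab <- tabulate(votes, 3)
      classes[which.max(tab)] == rg$class
    }, logical(1)))
    expect_equal(rep$n_correct, manual)
  }
})
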