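test_that("perimeter estimators follow their stated conventions", {
  sq <- matrix(0L, 14, 14); sq[3:12, 3:12] <- 1L
  # 4-direction Crofton value for a 10x10 square (cross-checked against an
  # independent Cauchy-Crofton implementation)
  expect_equal(perimeter_crofton(sq), 36.8117, tolerance = 1e-4)
  expect_identical(perimeter_naive(sq), 36L)
  d <- make_disc(40)
  expect_equal(perimeter_crofton(d), 2 * pi * 40, tolerance = 0.02 * 2 * pi * 40)
})

test_that("basic features count pixels and average raw intensity", {
  lab <- matrix(0L, 14, 14); lab[3:12, 3:12] <- 1L
  img <- matrix(17, 14, 14)
  b <- basic_features(lab, img, 1L)
  expect_identical(b$area, 100L)
  expect_equal(b$perimeter, 36.8117, tolerance = 1e-4)
  expect_identical(b$mean_intensity, 17)
  single <- matrix(0L, 5, 5); single[3, 3] <- 1L
  expect_identical(basic_features(single, img[1:5, 1:5], 1L)$area, 1L)
  expect_error(basic_features(lab, img, 9L), "not present")
})

test_that("shape descriptors match closed-form values for discs and rectangles", {
  d40 <- make_disc(40)
  s <- shape_features(d40, 1L)
  expect_gte(s$compactness, 0.95); expect_lte(s$compactness, 1.02)
  expect_lte(s$elongation, 0.02)
  expect_equal(s$long_axis, 80, tolerance = 0.03 * 80)
  # 100x10 rectangle: axis ratio ~10, elongation ~0.9
  rect <- matrix(0L, 110, 20); rect[6:105, 6:15] <- 1L
  r <- shape_features(rect, 1L)
  expect_equal(r$long_axis / r$short_axis, 10, tolerance = 0.5)
  expect_equal(r$elongation, 0.9, tolerance = 0.01)
  expect_equal(r$extension, log2(r$long_axis / r$short_axis))
  # disc dispersion baseline: mean radial distance of a disc is 2/3 R_eq
  expect_equal(s$dispersion, log2(2 / 3), tolerance = 0.02)
  expect_error(shape_features(matrix(c(0L, 1L), 1, 2), 1L), "too small")
})

test_that("texture features match their defining expressions", {
  # constant region
  t0 <- texture_features(region_histogram(rep(42, 64)))
  expect_identical(t0$std, 0)
  expect_identical(t0$smoothness, 0)
  expect_identical(t0$uniformity, 1)
  expect_identical(t0$entropy, 0)
  # symmetric two-level histogram about the mean
  t1 <- texture_features(region_histogram(c(rep(0.2, 50), rep(0.8, 50)), bins = 2))
  expect_equal(t1$skewness, 0, tolerance = 1e-12)
  # mass 0.5 at 0.2 and 0.5 at 0.8 on the normalized [0,1] scale:
  # after per-region min-max normalization these sit at 0 and 1
  expect_equal(t1$std, 0.5, tolerance = 1e-12)
  expect_equal(t1$uniformity, 0.5, tolerance = 1e-12)
  expect_equal(t1$entropy, 1, tolerance = 1e-12)     # one bit
  # hand-built histogram at 0.3/0.7 without renormalization
  h <- structure(list(H = c(0.5, 0.5), i = c(0.3, 0.7), mean = 0.5),
                 class = "region_histogram")
  t2 <- texture_features(h)
  expect_equal(t2$std, 0.2, tolerance = 1e-12)
  expect_equal(t2$smoothness, 1 - 1 / (1 + 0.04), tolerance = 1e-12)
  expect_equal(t2$skewness, 0, tolerance = 1e-15)
  bad <- structure(list(H = c(0.7, 0.5), i = c(0, 1), mean = 0.5),
                   class = "region_histogram")
  expect_error(texture_features(bad), "not normalized")
})

test_that("histogram texture equals the brute-force per-pixel moments", {
  set.seed(19)
  vals <- sample(0:40, 400, TRUE)            # 41 distinct levels
  h <- region_histogram(vals, bins = 41)     # one bin per level
  tx <- texture_features(h)
  z <- (vals - min(vals)) / diff(range(vals))
  expect_equal(tx$std, sqrt(mean((z - mean(z))^2)), tolerance = 1e-9)
  expect_equal(tx$skewness, mean((z - mean(z))^3), tolerance = 1e-9)
  expect_equal(tx$entropy,
               -sum(prop.table(table(z)) * log2(prop.table(table(z)))),
               tolerance = 1e-9)
})

test_that("contact fraction counts shared borders; nuclear CV is sd over mean", {
  # isolated cell: no contact
  lab <- matrix(0L, 20, 20); lab[5:15, 5:15] <- 1L
  seeds <- matrix(0L, 20, 20); seeds[9:11, 9:11] <- 1L
  nuc <- matrix(30, 20, 20)
  ct <- contact_features(lab, nuc, seeds, 1L)
  expect_identical(ct$contact_fraction, 0)
  expect_identical(ct$nuclear_cv, 0)         # constant nuclear intensity
  # two half-plane cells split down the middle of a 20x20 image
  half <- matrix(rep(c(1L, 2L), each = 200), 20, 20)
  seeds2 <- matrix(0L, 20, 20); seeds2[10, 5] <- 1L; seeds2[10, 15] <- 2L
  cth <- contact_features(half, nuc, seeds2, 1L)
  # boundary pixels of cell 1: all pixels of columns 1 and 10 plus the
  # image-border rows; only column 10 touches cell 2
  reg <- half == 1L
  bdry <- sum(reg & (row(half) %in% c(1, 20) | col(half) %in% c(1, 10)))
  expect_equal(cth$contact_fraction, 20 / bdry, tolerance = 1e-12)
  # CV on a known nuclear patch
  nuc2 <- nuc; nuc2[9:11, 9:11] <- c(10, 20, 30, 40, 50, 60, 70, 80, 90)
  cv <- contact_features(lab, nuc2, seeds, 1L)$nuclear_cv
  expect_equal(cv, sd(c(10, 20, 30, 40, 50, 60, 70, 80, 90)) / 50)
})

test_that("features are invariant under translation and 90-degree rotation", {
  set.seed(23)
  base <- matrix(0L, 60, 60)
  blob <- make_disc(9)
  base[10:(9 + nrow(blob)), 8:(7 + ncol(blob))] <- blob
  shifted <- matrix(0L, 60, 60)
  shifted[30:(29 + nrow(blob)), 25:(24 + ncol(blob))] <- blob
  s1 <- shape_features(base, 1L); s2 <- shape_features(shifted, 1L)
  expect_equal(unlist(s1), unlist(s2), tolerance = 1e-12)
  rot <- t(base[nrow(base):1, ])
  sr <- shape_features(rot, 1L)
  expect_equal(sum(rot == 1L), sum(base == 1L))
  expect_equal(perimeter_crofton(rot == 1L), perimeter_crofton(base == 1L),
               tolerance = 1e-12)
  expect_equal(sr$compactness, s1$compactness, tolerance = 1e-12)
  # uniform scaling: compactness and elongation stable within 3%
  small <- make_disc(20); bigd <- make_disc(60)
  expect_equal(shape_features(bigd, 1L)$compactness,
               shape_features(small, 1L)$compactness, tolerance = 0.03)
})

test_that("measure_image emits one complete record per cell, deterministically", {
  sc <- generate_scene(scene_params(n_cells = 8, width = 300, height = 300, seed = 4))
  rec <- measure_truth(sc, "im1", "control")
  expect_identical(nrow(rec), nrow(sc$truth$per_cell))
  expect_identical(attr(rec, "cell_number"), nrow(sc$truth$per_cell))
  expect_true(all(feature_registry() %in% names(rec)))
  num <- rec[, setdiff(feature_registry(), "nuclear_cv")]
  expect_true(all(vapply(num, function(x) all(is.finite(x)), logical(1))))
  expect_identical(rec, measure_truth(sc, "im1", "control"))
  # per-cell areas never exceed the image area
  expect_lte(sum(rec$area), 300 * 300)
  # empty mask
  e <- measure_image(matrix(0L, 10, 10),
                     channel_pair(matrix(0, 10, 10), matrix(0, 10, 10)),
                     matrix(0L, 10, 10))
  expect_identical(nrow(e), 0L)
  expect_identical(attr(e, "cell_number"), 0L)
})
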