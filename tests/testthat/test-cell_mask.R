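test_that("image histograms conserve mass and place levels on the data range", {
  img <- matrix(c(rep(0, 8), rep(255, 8)), 4, 4)
  h <- image_histogram(img, 256)
  expect_identical(sum(h$h), 16L)
  expect_identical(which(h$h > 0), c(1L, 256L))
  set.seed(6)
  any_img <- matrix(runif(900, 3, 90), 30, 30)
  expect_identical(sum(image_histogram(any_img, 64)$h), 900L)
  expect_error(image_histogram(matrix(1, 5, 5)), "degenerate")
  # uniform random image: chi-square flatness not rejected at alpha = 0.001
  set.seed(123)
  u <- matrix(runif(65536), 256, 256)
  hu <- image_histogram(u, 64)
  # end bins receive half-width mass under the nearest-level rule
  inner <- hu$h[2:63]
  p <- chisq.test(inner)$p.value
  expect_gt(p, 0.001)
})

test_that("EnFCM reaches the two-delta fixed point with crisp memberships", {
  img <- matrix(c(rep(20, 8), rep(200, 8)), 4, 4)
  h <- image_histogram(img, 181)       # levels coincide with integers
  m <- enfcm_fit(h, C = 2, m = 2)
  expect_equal(m$centers, c(20, 200), tolerance = 1e-9)
  u <- m$memberships
  expect_equal(u[1, which(h$level_values == 20)], 1, tolerance = 1e-9)
  expect_equal(u[2, which(h$level_values == 200)], 1, tolerance = 1e-9)
  expect_true(m$converged)
})

test_that("EnFCM equals pixelwise FCM when levels span the full gray range", {
  set.seed(31)
  for (i in 1:3) {
    img <- matrix(sample(0:255, 4096, TRUE, prob = c(rep(6, 64), rep(1, 192))),
                  64, 64)
    h <- image_histogram(img, 256)
    a <- enfcm_fit(h, C = 2, m = 2)
    b <- fcm_fit_pixelwise(img, C = 2, m = 2)
    expect_lt(max(abs(a$centers - b$centers)), 1e-6)
    expect_lt(abs(a$J - b$J), 1e-6 * max(1, a$J))
    expect_true(all(diff(a$J_trace) <= 1e-9 * max(a$J_trace)))
    expect_true(all(diff(b$J_trace) <= 1e-9 * max(b$J_trace)))
  }
})

test_that("membership columns are a partition of unity", {
  set.seed(7)
  img <- matrix(sample(0:99, 2500, TRUE), 50, 50)
  h <- image_histogram(img, 100)
  for (C in 2:4) {
    m <- enfcm_fit(h, C = C)
    expect_lt(max(abs(colSums(m$memberships) - 1)), 1e-12)
    expect_true(all(m$memberships >= 0 & m$memberships <= 1))
    expect_true(all(diff(m$centers) > 0))
  }
})

test_that("EnFCM centers agree with an established fuzzy C-means implementation", {
  skip_if_not_installed("e1071")
  set.seed(15)
  img <- matrix(sample(0:255, 4096, TRUE, prob = c(rep(8, 64), rep(1, 192))), 64, 64)
  h <- image_histogram(img, 256)
  ours <- enfcm_fit(h, C = 2, m = 2, tol = 1e-8)
  ext <- e1071::cmeans(matrix(as.numeric(img), ncol = 1),
                       centers = matrix(ours$centers + c(5, -5)), m = 2)
  expect_lt(max(abs(sort(ext$centers) - ours$centers)), 0.01)
})

test_that("symmetric bimodal histograms yield centers symmetric about the midpoint", {
  img <- matrix(c(rep(40, 32), rep(60, 18), rep(140, 18), rep(160, 32)), 10, 10)
  h <- image_histogram(img, 121)
  m <- enfcm_fit(h, C = 2)
  expect_equal(mean(m$centers), 100, tolerance = 1e-6)
})

test_that("the membership cut-off reduces to the center midpoint for C = 2", {
  img <- matrix(c(rep(50, 60), rep(150, 40)), 10, 10)
  h <- image_histogram(img, 101)
  m <- enfcm_fit(h, C = 2, m = 2)
  expect_equal(membership_threshold(m, h), mean(m$centers), tolerance = 0.5)
  # m = 3: cut-off equals a brute-force scan over level memberships
  m3 <- enfcm_fit(h, C = 2, m = 3)
  lv <- h$level_values
  d2 <- outer(lv, m3$centers, function(a, b) (a - b)^2)
  u <- d2^(-1 / (3 - 1)); u <- u / rowSums(u)
  scan <- lv[min(which(u[, which.max(m3$centers)] >= 0.5))]
  expect_equal(membership_threshold(m3, h), scan)
  # coincident centers are degenerate
  fake <- structure(list(C = 2L, m = 2, centers = c(50, 50)), class = "fcm_model")
  expect_error(membership_threshold(fake, h), "degenerate")
})

test_that("mask_cells marks the bright population and is duplication-invariant", {
  img <- matrix(c(rep(5, 70), rep(200, 30)), 10, 10)
  mask <- mask_cells(img, C = 2)
  expect_identical(mask == 1L, img == 200)
  tiled <- rbind(cbind(img, img), cbind(img, img))
  expect_equal(attr(mask_cells(tiled, C = 2), "threshold"),
               attr(mask, "threshold"))
  expect_error(mask_cells_otsu(matrix(1, 8, 8)), "degenerate")
})

test_that("EnFCM masking retains weak cells that the Otsu mask drops", {
  sc <- generate_scene(scene_params(seed = 2))
  pre <- preprocess_pair(sc$pair)
  fcm <- mask_cells(pre$cytoplasm)
  ots <- mask_cells_otsu(pre$cytoplasm)
  expect_gt(attr(ots, "threshold"), attr(fcm, "threshold"))
  weak_ids <- sc$truth$per_cell$cell[sc$truth$per_cell$weak_flag]
  wpx <- sc$truth$cell_labels %in% weak_ids
  recall_fcm <- sum(fcm[wpx] == 1) / sum(wpx)
  recall_otsu <- sum(ots[wpx] == 1) / sum(wpx)
  expect_gt(recall_fcm, recall_otsu)
  expect_gt(recall_fcm, 0.8)
  expect_lt(recall_otsu, 0.1)
})

test_that("histogram clustering cost scales with gray levels, not pixels", {
  set.seed(9)
  small <- matrix(sample(0:255, 128 * 128, TRUE), 128, 128)
  big <- rbind(cbind(small, small), cbind(small, small))   # 4x the area
  t_small <- system.time(enfcm_fit(image_histogram(small, 256), C = 2))[["elapsed"]]
  t_big <- system.time(enfcm_fit(image_histogram(big, 256), C = 2))[["elapsed"]]
  # iteration cost is q-bound; allow generous slack for the histogram build
  expect_lt(t_big, 0.2 + 4 * (t_small + 0.2))
})
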