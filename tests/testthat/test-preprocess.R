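test_that("background subtraction removes flat and ramp backgrounds", {
  const <- matrix(37, 40, 40)
  expect_true(all(subtract_background(const, 5) == 0))
  # bright 1-px impulse on zero background survives; background stays 0
  imp <- matrix(0, 41, 41); imp[21, 21] <- 200
  out <- subtract_background(imp, 10)
  expect_gt(out[21, 21], 150)
  expect_true(all(out[imp == 0] <= 1e-9))
  # linear ramp with a small bright disc: ramp removed, disc survives
  nr <- 81
  ramp <- matrix(rep(seq(0, 80, length.out = nr), each = nr), nr, nr)
  disc <- make_disc(4, pad = 2)
  img <- ramp
  img[30:42, 30:42] <- img[30:42, 30:42] + 100 * disc[1:13, 1:13]
  out <- subtract_background(img, 12)
  bgres <- out[img == ramp]
  expect_lt(max(bgres), 15)           # residual far below the 100-unit disc
  expect_gt(max(out), 85)
  # oracle: result equals image minus a brute-force grayscale disc opening
  shift_ref <- function(m, dr, dc) {
    n1 <- nrow(m); n2 <- ncol(m)
    ri <- pmin(pmax(seq_len(n1) + dr, 1), n1)   # replicate at borders is
    ci <- pmin(pmax(seq_len(n2) + dc, 1), n2)   # equivalent for this fixture
    ri[seq_len(n1) + dr < 1] <- 1 - (seq_len(n1) + dr)[seq_len(n1) + dr < 1]
    ri[seq_len(n1) + dr > n1] <- 2 * n1 - (seq_len(n1) + dr)[seq_len(n1) + dr > n1] + 1
    ci[seq_len(n2) + dc < 1] <- 1 - (seq_len(n2) + dc)[seq_len(n2) + dc < 1]
    ci[seq_len(n2) + dc > n2] <- 2 * n2 - (seq_len(n2) + dc)[seq_len(n2) + dc > n2] + 1
    m[ri, ci]
  }
  brute_morph <- function(m, r, op) {
    offs <- subset(expand.grid(dr = -r:r, dc = -r:r),
                   dc^2 <= r^2 - dr^2)          # same chord rule as the filter
    acc <- NULL
    for (k in seq_len(nrow(offs))) {
      sh <- shift_ref(m, offs$dr[k], offs$dc[k])
      acc <- if (is.null(acc)) sh else op(acc, sh)
    }
    acc
  }
  bg_oracle <- brute_morph(brute_morph(img, 12, pmin), 12, pmax)
  expect_equal(out, pmax(img - bg_oracle, 0), ignore_attr = TRUE, tolerance = 1e-12)
  expect_error(subtract_background(matrix(0, 10, 10), 20), "shorter image dimension")
})

test_that("Gaussian smoothing matches the analytic kernel and contracts variance", {
  const <- matrix(5, 30, 30)
  expect_equal(gaussian_smooth(const, 3), const, ignore_attr = TRUE, tolerance = 1e-12)
  # unit impulse -> sampled closed-form 2D Gaussian, radius = sd = 2
  n <- 41; imp <- matrix(0, n, n); imp[21, 21] <- 1
  out <- gaussian_smooth(imp, 2)
  idx <- expand.grid(r = 1:n, c = 1:n)
  g <- matrix(exp(-((idx$r - 21)^2 + (idx$c - 21)^2) / (2 * 2^2)), n, n)
  g <- g / sum(g)
  expect_lt(max(abs(out - g)), 1e-6)
  set.seed(42)
  noise <- matrix(runif(64 * 64, 0, 100), 64, 64)
  expect_lt(var(as.vector(gaussian_smooth(noise, 2))), var(as.vector(noise)))
  expect_equal(mean(gaussian_smooth(noise, 2)), mean(noise), tolerance = 1e-2)
})

test_that("median filtering uses a disc neighbourhood with reflected borders", {
  const <- matrix(9, 20, 20)
  expect_equal(median_smooth(const, 3), const, ignore_attr = TRUE)
  # single-pixel outlier in a constant field is removed
  fld <- matrix(10, 15, 15); fld[8, 8] <- 250
  expect_true(all(median_smooth(fld, 1) == 10))
  # brute-force per-pixel disc median oracle on a random image
  set.seed(3)
  img <- matrix(sample(0:50, 18 * 14, TRUE), 18, 14)
  r <- 2
  out <- median_smooth(img, r)
  offs <- subset(expand.grid(dr = -r:r, dc = -r:r), dr^2 + dc^2 <= r^2)
  refl <- function(i, n) ifelse(i < 1, 1 - i, ifelse(i > n, 2 * n - i + 1, i))
  for (i in c(1, 2, 9, 18)) for (j in c(1, 7, 14)) {
    nb <- mapply(function(dr, dc)
      img[refl(i + dr, 18), refl(j + dc, 14)], offs$dr, offs$dc)
    expect_equal(out[i, j], median(nb))
  }
})

test_that("contrast enhancement is a quantile-anchored linear stretch", {
  const <- structure(matrix(7, 10, 10), bit_depth = 8L)
  expect_identical(enhance_contrast(const, 0.003), const)
  # fraction 0: pure min-max stretch
  img <- structure(matrix(seq(10, 100, length.out = 100), 10, 10), bit_depth = 8L)
  out <- enhance_contrast(img, 0)
  expect_equal(min(out), 0); expect_equal(max(out), 255)
  expect_equal(out[2] - out[1], (img[2] - img[1]) * 255 / 90, tolerance = 1e-9)
  # quantile anchors match a brute-force sorted-pixel quantile
  set.seed(8)
  ramp <- c(seq(0, 200, length.out = 990), runif(10, 3000, 4000))
  img2 <- structure(matrix(ramp, 50, 20), bit_depth = 16L)
  f <- 0.01
  out2 <- enhance_contrast(img2, f)
  qs <- quantile(ramp, c(f / 2, 1 - f / 2), names = FALSE)
  expect_equal(out2[which.min(abs(img2 - qs[2]))], 65535, tolerance = 1)
  # monotone wherever unclipped
  v_in <- as.vector(img2); v_out <- as.vector(out2)
  unclipped <- v_out > 0 & v_out < 65535
  expect_true(all(diff(v_out[unclipped][order(v_in[unclipped])]) >= 0))
})

test_that("every stage preserves shape and non-negativity; opening never adds", {
  set.seed(21)
  img <- structure(matrix(sample(0:255, 60 * 45, TRUE), 60, 45), bit_depth = 8L)
  stages <- list(function(x) subtract_background(x, 10),
                 function(x) gaussian_smooth(x, 2),
                 function(x) median_smooth(x, 2),
                 function(x) enhance_contrast(x, 0.01))
  for (st in stages) {
    out <- st(img)
    expect_identical(dim(out), dim(img))
    expect_true(all(out >= 0))
  }
  expect_true(all(subtract_background(img, 10) <= img))
})

test_that("the full chain treats the two channels with their own parameters", {
  zero <- structure(matrix(0, 120, 120), bit_depth = 8L)
  pair <- channel_pair(zero, zero)
  out <- preprocess_pair(pair, preprocess_params(bg_radius_cyto = 20,
                                                 bg_radius_nuc = 10))
  expect_true(all(out$nuclear == 0) && all(out$cytoplasm == 0))
  sc <- generate_scene(scene_params(n_cells = 6, width = 256, height = 256, seed = 2))
  pre <- preprocess_pair(sc$pair)
  expect_identical(dim(pre$cytoplasm), dim(sc$pair$cytoplasm))
  # chain brightens foreground relative to background: masked fraction of
  # true foreground grows after conditioning
  thr_raw <- mask_cells(sc$pair$cytoplasm)
  thr_pre <- mask_cells(pre$cytoplasm)
  fg <- sc$truth$cell_labels > 0
  expect_gte(mean(thr_pre[fg]), mean(thr_raw[fg]) - 0.02)
})
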