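test_that("flips follow the coordinate formulas and are involutions", {
  img <- random_image(1, 15, 25)
  h <- hflip(img)
  v <- vflip(img)
  # pixel at 0-based column x moves to width - x - 1 (rows untouched)
  expect_identical(h[, 25, ], img[, 1, ])
  expect_identical(h[3, 10, ], img[3, 25 - 10 + 1, ])
  # pixel at 0-based row y moves to height - y - 1
  expect_identical(v[15, , ], img[1, , ])
  expect_identical(unclass(hflip(h)), unclass(img))
  expect_identical(unclass(vflip(v)), unclass(img))
  # one-row / one-column toys
  row <- structure(array(c(1L, 2L, 3L), c(1, 3, 1))[, , c(1, 1, 1), drop = FALSE],
                   dim = c(1, 3, 3), class = "spectrogram_image")
  expect_equal(as.vector(hflip(row)[1, , 1]), c(3, 2, 1))
  col <- structure(array(rep(c(5L, 6L, 7L), 3), c(3, 1, 3)),
                   class = "spectrogram_image")
  expect_equal(as.vector(vflip(col)[, 1, 1]), c(7, 6, 5))
})

test_that("RGB to HSV matches the printed piecewise formulas", {
  red <- rgb_to_hsv_pixel(255, 0, 0)
  expect_equal(unlist(red), c(h = 0, s = 1, v = 1))
  gray <- rgb_to_hsv_pixel(128, 128, 128)
  expect_equal(gray$s, 0)
  expect_equal(gray$v, 128 / 255)
  expect_equal(rgb_to_hsv_pixel(0, 255, 0)$h, 120)
  expect_equal(rgb_to_hsv_pixel(0, 0, 255)$h, 240)
  # cross-check against the independent base-R converter on random pixels
  withr::with_seed(4, {
    px <- matrix(sample(0:255, 60, replace = TRUE), ncol = 3)
  })
  ours <- rgb_to_hsv_pixel(px[, 1], px[, 2], px[, 3])
  ref <- t(grDevices::rgb2hsv(t(px), maxColorValue = 255))
  expect_equal(ours$h, ref[, 1] * 360, tolerance = 1e-9)
  expect_equal(ours$s, ref[, 2], tolerance = 1e-9)
  expect_equal(ours$v, ref[, 3], tolerance = 1e-9)
})

test_that("SV perturbation blends brightness then saturation", {
  img <- random_image(2)
  expect_identical(unclass(sv_perturb(img, 1, 1)), unclass(img))
  halved <- sv_perturb(img, 0.5, 1)
  expect_equal(unclass(halved),
               array(as.integer(round(as.numeric(img) * 0.5)), dim(img)))
  # grayscale images are fixed points of the saturation pass
  g <- img
  g[, , 2] <- g[, , 1]
  g[, , 3] <- g[, , 1]
  expect_identical(unclass(sv_perturb(g, 1, 0.3)), unclass(g))
  # sampled alphas stay inside the stated bounds
  pars <- lapply(1:200, sample_sv_params)
  ab <- vapply(pars, `[[`, numeric(1), "alpha_brightness")
  as_ <- vapply(pars, `[[`, numeric(1), "alpha_saturation")
  expect_true(all(ab >= 0.5 & ab <= 2))
  expect_true(all(as_ >= 0.1 & as_ <= 2))
  # output remains a valid image
  out <- sv_perturb(img, 1.9, 0.2)
  expect_true(min(out) >= 0 && max(out) <= 255)
  expect_equal(dim(out), dim(img))
})

test_that("PCA colour augmentation matches an independent eigen oracle", {
  img <- random_image(3)
  expect_identical(unclass(pca_color_augment(img, 0)), unclass(img))
  const <- img
  const[, , 1] <- 37L; const[, , 2] <- 120L; const[, , 3] <- 200L
  expect_identical(unclass(pca_color_augment(const, 800)), unclass(const))
  # 4-pixel toy vs. a hand-rolled Jacobi eigensolver
  toy <- structure(array(as.integer(c(
    10, 200, 30, 90,    # R
    40, 60, 220, 120,   # G
    5, 30, 100, 250     # B
  )), c(2, 2, 3)), class = "spectrogram_image")
  px <- cbind(as.vector(toy[, , 1]), as.vector(toy[, , 2]), as.vector(toy[, , 3]))
  cv <- crossprod(sweep(px, 2, colMeans(px))) / (nrow(px) - 1)
  e <- jacobi_eigen3(cv)
  alpha <- 650
  shift <- as.numeric(e$vectors %*% (alpha * e$values))
  expected <- array(0L, dim(toy))
  for (ch in 1:3) {
    expected[, , ch] <- as.integer(round(pmin(255, pmax(0, px[, ch] + shift[ch]))))
  }
  expect_equal(unclass(pca_color_augment(toy, alpha)), expected)
  # alpha draws centre on 800 with spread 10
  a <- vapply(1:300, sample_pca_alpha, numeric(1))
  expect_lt(abs(mean(a) - 800), 2)
  expect_lt(abs(sd(a) - 10), 2)
})

test_that("the colour-filter registry holds 150 distinct conversions", {
  reg <- color_filter_registry()
  expect_equal(nrow(reg), 150)
  expect_false(any(duplicated(reg[c("space", "space2", "perm", "inverted")])))
  img <- random_image(5, 12, 16)
  # identity entry
  expect_identical(img_data(apply_color_filter(img, 1)), img_data(img))
  # all 150 mappings give distinct outputs on a random image
  outs <- vapply(reg$filter_id, function(id) {
    rlang::hash(unclass(apply_color_filter(img, id)))
  }, character(1))
  expect_equal(length(unique(outs)), 150)
  # deterministic selection
  a <- random_color_filter(img, seed = 9)
  b <- random_color_filter(img, seed = 9)
  expect_identical(unclass(a), unclass(b))
  expect_identical(attr(a, "filter_id"), attr(b, "filter_id"))
  expect_error(apply_color_filter(img, 151), class = "pcgaug_config_error")
})

test_that("masking fills in-bounds bands and nothing else", {
  rec <- generate_recording(0, pcg_config(duration_range = c(10, 10)), 6)
  mel <- to_mel_db(power_spectrogram(rec), spectrogram_params(), rec$sample_rate)
  # zero-width masks are the identity
  zero_masks <- tibble::tibble(domain = rep(c("frequency", "time"), each = 3),
                               width = 0L, start = 1L)
  expect_equal(unclass(apply_masks(mel, zero_masks)), unclass(mel))
  # determinism + fill contract + coverage bounds over many seeds
  for (seed in c(1, 12, 123)) {
    m1 <- time_frequency_mask(mel, seed)
    m2 <- time_frequency_mask(mel, seed)
    expect_identical(unclass(m1), unclass(m2))
    masks <- sample_mask_params(nrow(mel), ncol(mel), seed)
    band <- function(i) masks$start[i] + seq_len(masks$width[i])
    fmask <- unique(unlist(lapply(which(masks$domain == "frequency"), band)))
    tmask <- unique(unlist(lapply(which(masks$domain == "time"), band)))
    # union bound: 3 masks x max width 20 per domain
    expect_lte(length(fmask), 60)
    expect_lte(length(tmask), 60)
    # every masked cell equals the fill value
    if (length(fmask)) expect_true(all(unclass(m1)[fmask, ] == 0))
    if (length(tmask)) expect_true(all(unclass(m1)[, tmask] == 0))
    # widths stay within [0, 20] and masks inside the matrix
    expect_true(all(masks$width >= 0 & masks$width <= 20))
    f <- masks[masks$domain == "frequency", ]
    expect_true(all(f$start + f$width <= nrow(mel)))
    t <- masks[masks$domain == "time", ]
    expect_true(all(t$start + t$width <= ncol(mel)))
  }
  expect_error(sample_mask_params(15, 15, 1), class = "pcgaug_degenerate_error")
})

test_that("composition applies the printed order and identities", {
  img <- random_image(7)
  expect_identical(unclass(hflip(pca_color_augment(img, 0))), unclass(hflip(img)))
  expect_identical(unclass(hflip(sv_perturb(img, 1, 1))), unclass(hflip(img)))
  # compose_method equals running the two operators in sequence
  seed <- 31L
  direct <- hflip(pca_color_augment(img, sample_pca_alpha(pcgaug:::derive_seed(seed, 1))))
  expect_identical(unclass(compose_method(img, "pca", "hflip", seed)),
                   unclass(direct))
  expect_error(compose_method(img, "noise", "hflip", 1),
               class = "pcgaug_config_error")
})

test_that("hflip commutes with per-pixel colour operations", {
  img <- random_image(8)
  expect_identical(unclass(hflip(sv_perturb(img, 1.4, 0.6))),
                   unclass(sv_perturb(hflip(img), 1.4, 0.6)))
  expect_identical(unclass(hflip(pca_color_augment(img, 500))),
                   unclass(pca_color_augment(hflip(img), 500)))
  expect_identical(img_data(hflip(apply_color_filter(img, 77))),
                   img_data(apply_color_filter(hflip(img), 77)))
})
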