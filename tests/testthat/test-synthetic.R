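test_that("the noiseless phantom is exactly piecewise constant", {
  ph <- make_phantom(shape = c(48, 48), semi_axes = c(12, 12),
                     fg_level = 140, bg_level = 60, sigma_noise = 0, seed = 5)
  img <- unclass(ph$image)
  expect_setequal(unique(as.vector(img)), c(60, 140))
  expect_true(all(img[ph$ground_truth] == 140))
  expect_true(all(img[!ph$ground_truth] == 60))
})

test_that("speckle variance is proportional to the local mean intensity", {
  ph <- make_phantom(shape = c(128, 128), semi_axes = c(10, 10),
                     fg_level = 100, bg_level = 100, sigma_noise = 1, seed = 2)
  v <- unclass(ph$image)
  expect_gte(length(v), 1e4)
  s2 <- stats::var(as.vector(v))
  expect_gt(s2, 90); expect_lt(s2, 110)  # theory: 100 * sigma^2 = 100

  # level 40, sigma 2: variance 160
  ph2 <- make_phantom(shape = c(128, 128), semi_axes = c(10, 10),
                      fg_level = 40, bg_level = 40, sigma_noise = 2, seed = 3)
  s2b <- stats::var(as.vector(unclass(ph2$image)))
  expect_gt(s2b / 160, 0.9); expect_lt(s2b / 160, 1.1)
})

test_that("smoothing correlates the speckle but preserves the variance law", {
  ph <- make_phantom(shape = c(128, 128), semi_axes = c(10, 10),
                     fg_level = 100, bg_level = 100, sigma_noise = 1,
                     smoothing = 2, seed = 7)
  v <- as.vector(unclass(ph$image))
  s2 <- stats::var(v)
  expect_gt(s2, 80); expect_lt(s2, 125)  # wider band: correlation cuts the effective n
  # neighboring pixels are now strongly correlated
  m <- unclass(ph$image)
  r <- stats::cor(as.vector(m[-1, ]), as.vector(m[-nrow(m), ]))
  expect_gt(r, 0.5)
})

test_that("phantom generation is seed-deterministic and seed-sensitive", {
  a <- make_phantom(seed = 4); b <- make_phantom(seed = 4); c <- make_phantom(seed = 5)
  expect_identical(unclass(a$image), unclass(b$image))
  expect_false(identical(unclass(a$image), unclass(c$image)))
})

test_that("the default fixture has consistent geometry and labels", {
  ph <- default_phantom()
  expect_equal(dim(ph$image), c(128, 128))
  # deterministic disk area
  cx <- (128 + 1) / 2
  d2 <- outer((1:128 - cx)^2, (1:128 - cx)^2, "+")
  expect_equal(sum(ph$ground_truth), sum(d2 <= 30^2))
  ls <- to_label_set(ph$label_map)
  expect_true(all(ph$ground_truth[ls$foreground]))
  expect_true(!any(ph$ground_truth[ls$background]))
})

test_that("the texture fixture differs only in speckle statistics across regions", {
  tx <- texture_phantom()
  img <- unclass(tx$image)
  m_in <- mean(img[tx$ground_truth]); m_out <- mean(img[!tx$ground_truth])
  s_in <- stats::sd(img[tx$ground_truth]); s_out <- stats::sd(img[!tx$ground_truth])
  expect_lt(abs(m_in - m_out) / m_out, 0.25)  # means comparable
  expect_gt(s_in / s_out, 5)                  # variance contrast strong
  ls <- to_label_set(tx$label_map)
  expect_true(all(tx$ground_truth[ls$foreground]))
  expect_true(!any(tx$ground_truth[ls$background]))
})

test_that("the ring phantom encodes the head ellipse and its circumference", {
  hp <- head_phantom(semi_axes = c(30, 20), angle = 0, seed = 1)
  expect_equal(hp$hc_mm_true, pi * 50)
  # the bright band lies outside the ground-truth ellipse
  img <- unclass(hp$image)
  expect_lt(mean(img[hp$ground_truth]), 120)
  ls <- to_label_set(hp$label_map)
  expect_true(all(hp$ground_truth[ls$foreground]))
  expect_true(!any(hp$ground_truth[ls$background]))
})

test_that("the noise exponent controls the signal dependence", {
  # exponent 0: additive noise independent of the level
  ph <- make_phantom(shape = c(100, 100), semi_axes = c(5, 5),
                     fg_level = 200, bg_level = 50, sigma_noise = 3,
                     exponent = 0, seed = 9)
  img <- unclass(ph$image)
  s_bg <- stats::sd(img[!ph$ground_truth])
  expect_gt(s_bg / 3, 0.9); expect_lt(s_bg / 3, 1.1)
})
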