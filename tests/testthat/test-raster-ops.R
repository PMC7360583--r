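test_that("flat-field correction normalizes constant and shaded images", {
  img <- blank_img(64, 3.7)
  out <- flatfield_correct(img, 8)
  expect_equal(out, blank_img(64, 1), tolerance = 1e-6)

  # flat pattern x smooth gradient: correction recovers the pattern
  n <- 96
  pattern <- matrix(1, n, n)
  pattern[, seq(1, n, by = 8)] <- 1.4  # thin bright stripes
  grad <- outer(rep(1, n), seq(0.6, 1.4, length.out = n))
  out <- flatfield_correct(pattern * grad, 6)
  ref <- pattern / mean(pattern)
  inner <- 17:(n - 16)
  expect_lt(max(abs(out[inner, inner] / mean(out[inner, inner]) -
                      ref[inner, inner] / mean(ref[inner, inner]))), 0.05)

  expect_error(flatfield_correct(blank_img(32, 0), 5), "degenerate")
})

test_that("shading does not change the segmented bead mask", {
  r_flat <- cached_fba(101, shading_amp = 0)
  r_ramp <- cached_fba(101, shading_amp = 0.5)
  p <- scene_sphere_params()
  m1 <- coarse_sphere_mask(r_flat$image, p)
  m2 <- coarse_sphere_mask(r_ramp$image, p)
  expect_gt(mean(m1 == m2), 0.99)
})

test_that("variance filter matches direct neighborhood computation", {
  expect_equal(variance_filter(blank_img(32, 5), 2), blank_img(32, 0),
               tolerance = 1e-8)

  # single bright pixel: oracle = direct variance over the 13-px disc
  img <- blank_img(21); img[11, 11] <- 7
  out <- variance_filter(img, 2)
  offs <- which(angiomorph:::disc_kernel(2) > 0, arr.ind = TRUE) - 3
  oracle <- function(r, c) {
    vals <- img[cbind(r + offs[, 1], c + offs[, 2])]
    mean(vals^2) - mean(vals)^2
  }
  expect_equal(out[11, 11], oracle(11, 11), tolerance = 1e-8)
  expect_equal(max(out), out[11, 11], tolerance = 1e-8)
  expect_equal(out[11, 12], oracle(11, 12), tolerance = 1e-8)
  expect_equal(out[3, 3], 0, tolerance = 1e-8)

  # two-band image: ridge along the boundary, zero far away
  img <- cbind(blank_img(20, 0), blank_img(20, 1))[1:20, 1:40]
  out <- variance_filter(img, 2)
  expect_gt(out[10, 20], 0.1)
  expect_equal(out[10, 5], 0, tolerance = 1e-8)
  expect_equal(out[10, 35], 0, tolerance = 1e-8)
})

test_that("log enhancement is monotone with an epsilon floor", {
  img <- blank_img(16, 1)
  expect_equal(log_enhance(img)[1, 1], log(1 + 1e-6), tolerance = 1e-9)
  img <- blank_img(16); img[1, 1:3] <- c(1, 50, 99)
  out <- log_enhance(img)
  expect_true(out[1, 1] < out[1, 2] && out[1, 2] < out[1, 3])
  # concavity: equal input steps give shrinking output steps
  expect_lt(out[1, 3] - out[1, 2], out[1, 2] - out[1, 1])
  expect_true(is.finite(log_enhance(blank_img(16))[5, 5]))
})

test_that("FFT band-pass keeps mid-band structure and rejects extremes", {
  v1 <- 2; v2 <- 24
  n <- 256
  # constant image -> flat residual
  out <- fft_bandpass(blank_img(n, 2), v1, v2)
  expect_lt(max(abs(out)), 1e-6)
  amp_ratio <- function(wavelength) {
    img <- outer(rep(1, n), sin(2 * pi * seq_len(n) / wavelength))
    out <- fft_bandpass(img, v1, v2)
    inner <- 33:(n - 32)
    max(abs(out[inner, inner])) / 1
  }
  expect_gt(amp_ratio(12), 0.8)        # mid-band preserved within 20%
  expect_lt(amp_ratio(4 * v2), 0.2)    # large structure suppressed
  expect_error(fft_bandpass(blank_img(32), 5, 5), "v1")

  # linearity
  set.seed(7)
  x <- matrix(runif(64^2), 64, 64); y <- matrix(runif(64^2), 64, 64)
  lhs <- fft_bandpass(2 * x + 3 * y, v1, v2)
  rhs <- 2 * fft_bandpass(x, v1, v2) + 3 * fft_bandpass(y, v1, v2)
  expect_equal(lhs, rhs, tolerance = 1e-8)
})

test_that("modal subtraction zeroes the dominant background", {
  img <- blank_img(32, 7); img[1:4, 1:4] <- 30
  out <- subtract_modal(img)
  expect_equal(out[20, 20], 0, tolerance = 0.1)

  img <- blank_img(32, 10); img[1:3, 1:8] <- 200
  out <- subtract_modal(img)
  expect_equal(out[1, 1], 190, tolerance = 0.5)
  expect_true(all(out >= 0))

  set.seed(3)
  img <- matrix(runif(64^2), 64, 64)
  out <- subtract_modal(img)
  h <- hist(out, breaks = 64, plot = FALSE)
  expect_equal(which.max(h$counts), 1L)  # mode moved to zero
})

test_that("auto-thresholds follow their defining fixed points", {
  img <- blank_img(32, 10); img[, 17:32] <- 200
  m <- auto_threshold(img, "mean")
  expect_equal(attr(m, "threshold"), 105)
  expect_equal(mean(m), 0.5)
  expect_true(all(m[, 17:32] == 1))

  m <- auto_threshold(img, "isodata")
  expect_equal(attr(m, "threshold"), 105, tolerance = 1e-6)

  # Gaussian mixture: Minimum threshold lands in the inter-mode valley
  set.seed(11)
  x <- c(rnorm(5000, 50, 12), rnorm(5000, 180, 12))
  img <- matrix(x[1:10000], 100, 100)
  m <- auto_threshold(img, "minimum")
  thr <- attr(m, "threshold")
  expect_gt(thr, 50 + 0.4 * 130)
  expect_lt(thr, 50 + 0.6 * 130)

  expect_error(auto_threshold(blank_img(16, 1), "isodata"), "distinct")
})

test_that("mean and isodata thresholds are affine invariant", {
  set.seed(5)
  img <- matrix(rnorm(48^2, 10, 3), 48, 48)^2
  for (method in c("mean", "isodata")) {
    m1 <- auto_threshold(img, method)
    m2 <- auto_threshold(3.5 * img + 11, method)
    expect_equal(as.vector(m1), as.vector(m2))
  }
})

test_that("binary morphology: holes, idempotence, duality, growth", {
  disk <- draw_disk(blank_img(41), 21, 21, 10)
  holed <- disk; holed[20:22, 20:22] <- 0
  expect_equal(fill_holes(holed), disk)

  set.seed(9)
  for (i in 1:5) {
    m <- angiomorph:::as_mask(matrix(runif(30^2) < 0.4, 30, 30))
    expect_equal(morph_open(morph_open(m)), morph_open(m))
    expect_equal(morph_close(morph_close(m)), morph_close(m))
    expect_equal(fill_holes(fill_holes(m)), fill_holes(m))
    # duality: dilation of the mask = complement of erosion of complement
    expect_equal(morph_dilate(m), 1 - morph_erode(1 - m))
  }

  grown <- binary_morphology(disk, "dilate", r = 2)
  expect_equal(sum(grown) - sum(disk), pi * (12^2 - 10^2),
               tolerance = 0.1 * pi * (12^2 - 10^2))
})
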