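test_that("grayscale conversion uses BT.601 luma weights", {
  expect_equal(to_grayscale(tiny_rgb(r = 255, g = 255, b = 255))[1, 1], 255L)
  expect_equal(to_grayscale(tiny_rgb(r = 0, g = 0, b = 0))[1, 1], 0L)
  # 0.299*100 + 0.587*150 + 0.114*200 = 140.75 -> 141
  expect_equal(to_grayscale(tiny_rgb(r = 100, g = 150, b = 200))[1, 1], 141L)
  expect_error(to_grayscale(matrix(0, 4, 4)), "RGB")
})

test_that("contrast stretch saturates the configured tails and maps linearly", {
  # 1000 pixels: 10 at 0, 10 at 255, 980 at 128
  img <- matrix(c(rep(0, 10), rep(255, 10), rep(128, 980)), 40, 25)
  out <- stretch_contrast(img)
  expect_identical(out, oracle_stretch(img))
  expect_gte(mean(out == 0), 0.01)
  expect_gte(mean(out == 255), 0.01)
  # the mid level maps onto the new range per the linear map
  q <- quantile(img, c(0.01, 0.99), type = 7, names = FALSE)
  expected_mid <- floor((128 - q[1]) / (q[2] - q[1]) * 255 + 0.5)
  expect_equal(unique(out[img == 128]), as.integer(expected_mid))
})

test_that("constant images pass through the stretch unchanged with a warning", {
  img <- matrix(77L, 10, 10)
  expect_warning(out <- stretch_contrast(img), "Degenerate")
  expect_identical(out, img)
})

test_that("contrast stretch agrees with the sorted-multiset oracle on random images", {
  set.seed(101)
  for (rep in 1:100) {
    h <- sample(5:20, 1)
    w <- sample(5:20, 1)
    img <- matrix(sample(0:255, h * w, replace = TRUE), h, w)
    lo <- sample(c(0.01, 0.05, 0.1), 1)
    hi <- sample(c(0.01, 0.05, 0.1), 1)
    expect_identical(
      suppressWarnings(stretch_contrast(img, lo, hi)),
      suppressWarnings(oracle_stretch(img, lo, hi)),
      info = sprintf("case %d (%dx%d, tails %g/%g)", rep, h, w, lo, hi)
    )
  }
})

test_that("stretching is idempotent once the range is fully used", {
  set.seed(7)
  img <- matrix(sample(0:255, 900, replace = TRUE), 30, 30)
  once <- stretch_contrast(img)
  twice <- stretch_contrast(once)
  expect_lte(max(abs(twice - once)), 1)
})

test_that("resize is identity at the target size and preserves constants", {
  img <- matrix(sample(0:255, 100 * 100, replace = TRUE), 100, 100)
  expect_identical(resize_to_input(img), img)
  const <- matrix(42L, 37, 59)
  out <- resize_to_input(const)
  expect_true(all(out == 42L))
  expect_equal(dim(out), c(100, 100))
})

test_that("bilinear resize agrees with a direct interpolation oracle", {
  set.seed(11)
  # 200x200 image of constant 2x2 blocks
  block <- matrix(sample(0:255, 100 * 100, replace = TRUE), 100, 100)
  img <- block[rep(1:100, each = 2), rep(1:100, each = 2)]
  expect_identical(
    resize_to_input(img, c(100, 100)),
    matrix(as.integer(oracle_bilinear(img, 100, 100)), 100, 100)
  )
  # small irregular case
  img2 <- matrix(sample(0:255, 13 * 17, replace = TRUE), 13, 17)
  expect_identical(
    resize_to_input(img2, c(7, 5)),
    matrix(as.integer(oracle_bilinear(img2, 7, 5)), 7, 5)
  )
  expect_error(resize_to_input(matrix(1, 1, 1)), "2 x 2")
})

test_that("the full chain is deterministic, bounded and 100 x 100", {
  img <- render_well_image(concentration_to_rgb(130),
    size = c(64, 64),
    noise_sigma = 3, seed = 21
  )
  a <- preprocess(img)
  b <- preprocess(img)
  expect_identical(a, b)
  expect_equal(dim(a), c(100, 100))
  expect_true(all(a >= 0 & a <= 255))
})

test_that("stage order matters: stretch-then-resize differs from resize-then-stretch", {
  img <- render_well_image(concentration_to_rgb(90),
    size = c(64, 64),
    noise_sigma = 4, seed = 31
  )
  gray <- to_grayscale(img)
  canonical <- resize_to_input(stretch_contrast(gray), c(32, 32))
  permuted <- stretch_contrast(resize_to_input(gray, c(32, 32)))
  expect_false(identical(
    tabulate(canonical + 1, 256),
    tabulate(permuted + 1, 256)
  ))
})

test_that("preprocess_dataset maps the chain over the image list-column", {
  data <- small_processed_dataset()
  expect_true(all(vapply(data$image, function(m) all(dim(m) == c(32, 32)), logical(1))))
  expect_true(all(vapply(data$image, function(m) all(m >= 0 & m <= 255), logical(1))))
})
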