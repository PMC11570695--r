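test_that("a reduced factorial design yields the product of factor cardinalities", {
  dir <- withr::local_tempdir()
  cfg <- generator_config(
    concentrations = c(50, 200),
    lightings = "artificial",
    locations = 1,
    cameras = camera_profiles()[1, ],
    replicates = 5,
    image_size = c(32, 32),
    master_seed = 3
  )
  man <- suppressMessages(generate_dataset(cfg, dir))
  expect_equal(nrow(man), 2 * 1 * 1 * 1 * 5)
  expect_true(all(file.exists(man$path)))
  expect_setequal(list.dirs(dir, recursive = FALSE, full.names = FALSE), c("50", "200"))
})

test_that("folder names are the concentration labels", {
  dir <- withr::local_tempdir()
  cfg <- generator_config_small(
    concentrations = c(50, 120, 200), replicates = 1,
    lightings = "natural", locations = 1, master_seed = 5
  )
  suppressMessages(generate_dataset(cfg, dir))
  folders <- list.dirs(dir, recursive = FALSE, full.names = FALSE)
  expect_setequal(folders, c("50", "120", "200"))
})

test_that("the manifest records every file exactly once with distinct seeds", {
  dir <- withr::local_tempdir()
  cfg <- generator_config_small(master_seed = 7, replicates = 2)
  man <- suppressMessages(generate_dataset(cfg, dir))
  files <- list.files(dir, pattern = "\\.png$", recursive = TRUE, full.names = TRUE)
  expect_setequal(normalizePath(files), normalizePath(man$path))
  expect_equal(anyDuplicated(man$path), 0)
  key <- paste(man$lighting, man$location, man$camera, man$replicate, man$class_index)
  expect_equal(anyDuplicated(key), 0)
  expect_equal(anyDuplicated(man$seed), 0)
})

test_that("regeneration with the same master seed is byte-identical", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  cfg <- generator_config_small(
    concentrations = c(60, 140), replicates = 2, master_seed = 11
  )
  m1 <- suppressMessages(generate_dataset(cfg, d1))
  m2 <- suppressMessages(generate_dataset(cfg, d2))
  md5 <- function(man) unname(tools::md5sum(man$path))
  expect_identical(md5(m1), md5(m2))
  # and the manifests agree apart from the root path
  m1$path <- basename(m1$path)
  m2$path <- basename(m2$path)
  expect_identical(m1, m2)
})

test_that("a subset of the design regenerates the same images as the full run", {
  d_full <- withr::local_tempdir()
  d_sub <- withr::local_tempdir()
  full <- generator_config_small(master_seed = 13, replicates = 2)
  sub <- generator_config_small(
    master_seed = 13, replicates = 2,
    concentrations = c(80, 150)
  )
  suppressMessages(generate_dataset(full, d_full))
  suppressMessages(generate_dataset(sub, d_sub))
  for (conc in c("80", "150")) {
    f_full <- sort(list.files(file.path(d_full, conc), full.names = TRUE))
    f_sub <- sort(list.files(file.path(d_sub, conc), full.names = TRUE))
    expect_identical(
      unname(tools::md5sum(f_full[f_full != "manifest.csv"])),
      unname(tools::md5sum(f_sub[f_sub != "manifest.csv"]))
    )
  }
})

test_that("noise-free well colour is monotone in concentration after capture", {
  dir <- withr::local_tempdir()
  cfg <- generator_config_small(
    noise_scale = 0, replicates = 1, lightings = "artificial",
    locations = 2, master_seed = 17
  )
  man <- suppressMessages(generate_dataset(cfg, dir))
  man <- man[order(man$concentration), ]
  mean_green <- vapply(man$path, function(p) {
    img <- png::readPNG(p) * 255
    mask <- attr(
      render_well_image(c(0, 0, 0), size = cfg$image_size, noise_sigma = 0),
      "well_mask"
    )
    mean(img[, , 2][mask])
  }, numeric(1))
  expect_true(all(diff(mean_green) <= 0))
})

test_that("degenerate generator configurations are rejected", {
  expect_error(generator_config(concentrations = numeric(0)), "non-empty")
  expect_error(generator_config(replicates = 0), "positive integer")
  blocker <- withr::local_tempfile()
  writeLines("x", blocker)
  expect_error(
    suppressWarnings(suppressMessages(
      generate_dataset(generator_config_small(), dir = file.path(blocker, "sub"))
    )),
    "Cannot create"
  )
})
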