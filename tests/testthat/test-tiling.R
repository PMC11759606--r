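test_that("tile_image cuts the exact anchored grid and discards edge remnants", {
  img <- array(runif(1024 * 1024 * 3, 0, 255), dim = c(1024, 1024, 3))
  tiles <- tile_image(img, tile_size = 512)
  expect_length(tiles, 4)
  expect_equal(lapply(tiles, function(t) c(t$row, t$col)),
               list(c(0, 0), c(0, 1), c(1, 0), c(1, 1)))

  one <- tile_image(array(0, dim = c(512, 512, 3)), tile_size = 512)
  expect_length(one, 1)

  # 1000 x 1537: floor(1000/512) = 1 row, floor(1537/512) = 3 cols
  odd <- tile_image(array(0, dim = c(1000, 1537, 3)), tile_size = 512)
  expect_length(odd, 3)
  expect_equal(max(sapply(odd, `[[`, "row")), 0)
  expect_equal(max(sapply(odd, `[[`, "col")), 2)

  expect_warning(small <- tile_image(array(0, dim = c(100, 100, 3)),
                                     tile_size = 512),
                 "smaller")
  expect_length(small, 0)
})

test_that("tiling an evenly divisible image is a lossless partition", {
  img <- array(sample(0:255, 64 * 64 * 3, replace = TRUE), dim = c(64, 64, 3))
  tiles <- tile_image(img, tile_size = 32)
  recovered <- unlist(lapply(tiles, function(t) as.vector(t$pixels)))
  expect_equal(sort(recovered), sort(as.vector(img)))
})

test_that("is_background applies the strict white-fraction rule", {
  white <- array(255, dim = c(16, 16, 3))
  black <- array(0, dim = c(16, 16, 3))
  expect_true(is_background(white))
  expect_false(is_background(black))

  # exactly half the pixels white: 0.5 does not exceed the default 0.8
  half <- black
  half[1:8, , ] <- 255
  expect_equal(mean(half[, , 1] >= 220 & half[, , 2] >= 220 &
                      half[, , 3] >= 220), 0.5)
  expect_false(is_background(half))
  # ... and a fraction of exactly the threshold is not background either
  expect_false(is_background(half, white_fraction = 0.5))
  expect_true(is_background(half, white_fraction = 0.49))
})

test_that("raising white_fraction never decreases the kept-tile count", {
  tiles <- lapply(1:20, function(i) {
    px <- random_tile(16, seed = i)
    white <- withr::with_seed(100 + i, runif(1))
    n_white <- round(white * 16)
    if (n_white > 0) px[seq_len(n_white), , ] <- 255
    px
  })
  kept <- vapply(c(0.2, 0.5, 0.8), function(wf) {
    sum(!vapply(tiles, is_background, logical(1), white_fraction = wf))
  }, numeric(1))
  expect_true(all(diff(kept) >= 0))
})

test_that("reinhard_normalize matches the reference lab statistics", {
  ref_tile <- random_tile(32, seed = 2) * 0.6 + 60
  ref <- reinhard_reference(ref_tile)
  tile <- random_tile(32, seed = 3)

  out <- reinhard_normalize(tile, ref)
  lab <- rgb_to_lab(out)
  expect_lt(max(abs(apply(lab, 3, mean) - ref$mean_lab)), 1e-2)

  # a tile already matching its reference is (nearly) fixed by the map
  self_ref <- reinhard_reference(tile)
  same <- reinhard_normalize(tile, self_ref)
  drift <- abs(apply(same, 3, mean) - apply(tile, 3, mean))
  expect_lt(max(drift), 1)

  # the map is idempotent up to the stated tolerance
  twice <- reinhard_normalize(out, ref)
  lab2 <- rgb_to_lab(twice)
  expect_lt(max(abs(apply(lab2, 3, mean) - apply(lab, 3, mean))), 1e-2)
})

test_that("a constant tile is shifted to the reference means without blow-up", {
  grey <- array(128, dim = c(16, 16, 3))
  ref <- reinhard_reference(random_tile(16, seed = 9))
  expect_message(out <- reinhard_normalize(grey, ref), "near-constant")
  expect_true(all(is.finite(out)))
  lab <- rgb_to_lab(out)
  expect_lt(max(abs(apply(lab, 3, mean) - ref$mean_lab)), 0.05)
})

test_that("tile_slide_set indexes every tile, filters white slides, and is deterministic", {
  cc <- generate_cohort(cohort_config(n_patients = 2, tiles_per_slide = 4,
                                      tile_size = 32, background_fraction = 0,
                                      seed = 13))
  dir <- withr::local_tempdir()
  write_cohort(cc, dir, overwrite = TRUE)
  m <- read_manifest(file.path(dir, "manifest.csv"))

  out1 <- withr::local_tempdir()
  idx <- tile_slide_set(m, out1, tile_size = 32)
  expect_equal(nrow(idx), 2 * 4)
  expect_false(any(idx$failed))
  expect_false(any(idx$background))

  # a pure-white slide yields zero kept tiles but a clean index
  white_dir <- withr::local_tempdir()
  png::writePNG(array(1, dim = c(64, 64, 3)),
                file.path(white_dir, "white.png"))
  wm <- data.frame(slide_id = "W1", image_path = file.path(white_dir, "white.png"),
                   stringsAsFactors = FALSE)
  wout <- withr::local_tempdir()
  widx <- tile_slide_set(wm, wout, tile_size = 32)
  expect_equal(sum(!widx$background), 0)
  expect_false(any(widx$failed))

  # re-running the same inputs reproduces the index exactly
  out2 <- withr::local_tempdir()
  idx2 <- tile_slide_set(m, out2, tile_size = 32)
  expect_identical(idx$background, idx2$background)
  expect_identical(idx[, c("slide_id", "row", "col")],
                   idx2[, c("slide_id", "row", "col")])

  # an unreadable image is recorded as a failure, not an error
  bm <- data.frame(slide_id = "B1", image_path = "no/such/file.png",
                   stringsAsFactors = FALSE)
  bout <- withr::local_tempdir()
  expect_message(bidx <- tile_slide_set(bm, bout, tile_size = 32), "skipped")
  expect_true(bidx$failed[1])
})
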