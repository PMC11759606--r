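test_that("cosine schedule hits its analytic anchor points", {
  cfg <- train_config()  # T_i = 50, eta_max = 0.01, eta_min = 0
  expect_equal(cosine_lr(0, cfg), 0.01)
  expect_equal(cosine_lr(cfg$epochs, cfg), 0)
  expect_equal(cosine_lr(cfg$epochs / 2, cfg), 0.005)
  expect_error(cosine_lr(-1, cfg), "t_cur")
  expect_error(cosine_lr(cfg$epochs + 1, cfg), "t_cur")
})

test_that("cosine schedule is non-increasing and symmetric about T_i / 2", {
  cfg <- train_config(epochs = 40, eta_max = 0.02, eta_min = 0.001)
  lr <- vapply(0:40, cosine_lr, numeric(1), cfg = cfg)
  expect_true(all(diff(lr) <= 1e-12))
  for (t in 0:40) {
    expect_equal(cosine_lr(t, cfg) + cosine_lr(40 - t, cfg),
                 cfg$eta_min + cfg$eta_max)
  }
})

test_that("Z-score normalization centres and scales each channel", {
  px <- random_tile(32, seed = 4)
  z <- zscore_input(px)
  for (ch in 1:3) {
    expect_lt(abs(mean(z[, , ch])), 1e-6)
    expect_equal(sqrt(mean(z[, , ch]^2)), 1, tolerance = 1e-6)
  }

  # constant channel maps to zeros through the epsilon guard
  px[, , 2] <- 100
  z <- zscore_input(px)
  expect_true(all(z[, , 2] == 0))

  # 0/255 checkerboard: two-point distribution with sd 127.5 gives exactly +-1
  cb <- array(0, dim = c(16, 16, 3))
  idx <- outer(1:16, 1:16, "+") %% 2 == 0
  for (ch in 1:3) {
    m <- cb[, , ch]
    m[idx] <- 255
    cb[, , ch] <- m
  }
  z <- zscore_input(cb)
  expect_true(all(abs(abs(z) - 1) < 1e-12))
})

test_that("augmentation is identity when disabled, seeded, and flip-preserving", {
  px <- random_tile(32, seed = 6)
  expect_identical(augment_tile(px, crop_fraction = 1, flip = FALSE), px)

  a1 <- withr::with_seed(3, augment_tile(px))
  a2 <- withr::with_seed(3, augment_tile(px))
  expect_identical(a1, a2)

  # pure flips are permutations of the pixel multiset
  flipped <- withr::with_seed(5, augment_tile(px, crop_fraction = 1, flip = TRUE))
  expect_equal(sort(as.vector(flipped)), sort(as.vector(px)))
})

test_that("the tiny network learns the planted signal from weak labels", {
  cc <- small_plant_cohort(seed = 21)
  d <- cohort_tissue_tiles(cc)
  cfg <- train_config(epochs = 30, seed = 2, augment = FALSE)
  model <- train_patch_model(d$tiles[d$is_train], d$weak_label[d$is_train], cfg)

  # the schedule starts at the configured maximum learning rate
  expect_equal(model$history$lr[1], 0.01)
  expect_equal(nrow(model$history), 30)
  expect_true(all(is.finite(model$history$loss)))

  preds <- predict_patches(model, d$tiles[!d$is_train])
  expect_true(all(preds$likelihood >= 0 & preds$likelihood <= 1))
  expect_identical(preds$pred_label, as.integer(preds$likelihood >= 0.5))

  auc <- auc_score(preds$likelihood, d$weak_label[!d$is_train])
  expect_gte(auc, 0.85)

  # predictions recover the latent likelihood the tiles were painted from
  rho <- cor(preds$likelihood, d$latent[!d$is_train], method = "spearman")
  expect_gt(rho, 0.5)
})

test_that("a zero-signal cohort yields chance-level patch discrimination", {
  cc <- generate_cohort(cohort_config(
    n_patients = 16, tiles_per_slide = 24, tile_size = 64,
    likelihood_beta_pos = c(2, 2), likelihood_beta_neg = c(2, 2), seed = 33
  ))
  d <- cohort_tissue_tiles(cc)
  model <- train_patch_model(d$tiles[d$is_train], d$weak_label[d$is_train],
                             train_config(epochs = 10, seed = 2, augment = FALSE))
  preds <- predict_patches(model, d$tiles[!d$is_train])
  auc <- auc_score(preds$likelihood, d$weak_label[!d$is_train])
  expect_gt(auc, 0.35)
  expect_lt(auc, 0.65)
})

test_that("training rejects single-class labels and unavailable backbones", {
  tiles <- lapply(1:4, function(i) random_tile(32, seed = i))
  expect_error(train_patch_model(tiles, rep(1, 4), train_config(epochs = 1)),
               "single class")
  expect_error(train_patch_model(tiles, c(0, 1, 0, 1),
                                 train_config(backbone = "resnet50", epochs = 1)),
               "runtime")
})

test_that("evaluation-mode prediction is deterministic for duplicated tiles", {
  cc <- small_plant_cohort(seed = 22, n_patients = 4, tiles_per_slide = 6)
  d <- cohort_tissue_tiles(cc)
  model <- train_patch_model(d$tiles, d$weak_label,
                             train_config(epochs = 2, seed = 1, augment = FALSE))
  p <- predict_patches(model, list(d$tiles[[1]], d$tiles[[1]]))
  expect_equal(p$likelihood[1], p$likelihood[2])
})

test_that("probability_map places likelihoods on the tile grid", {
  preds <- data.frame(
    slide_id = "S1", row = c(0, 0, 1, 1), col = c(0, 1, 0, 1),
    likelihood = c(0, 0.5, 1, 0.25), pred_label = c(0, 1, 1, 0),
    stringsAsFactors = FALSE
  )
  grid <- probability_map(preds, "S1")
  expect_equal(dim(grid), c(2, 2))
  expect_equal(grid[1, 1], 0)
  expect_equal(grid[1, 2], 0.5)
  expect_equal(grid[2, 1], 1)
  expect_equal(grid[2, 2], 0.25)
  expect_equal(mean(grid), mean(preds$likelihood))

  # missing cells are flagged as no-data
  holey <- probability_map(preds[-2, ], "S1")
  expect_true(is.na(holey[1, 2]))
  expect_equal(mean(holey, na.rm = TRUE), mean(preds$likelihood[-2]))

  expect_error(probability_map(preds, "nope"), "no predictions")

  # rendering writes a PNG heat image
  path <- withr::local_tempfile(fileext = ".png")
  render_probability_map(grid, path)
  expect_true(file.exists(path))
  img <- png::readPNG(path)
  expect_equal(dim(img)[3], 3)
})
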