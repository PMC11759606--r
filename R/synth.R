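#' Configuration for a synthetic breast-cancer slide cohort
#'
#' Defines the statistical structure of a simulated cohort of H&E-like slides:
#' a binary slide label (ER status), a latent per-tile class likelihood drawn
#' from a label-dependent Beta distribution and painted into the tile pixels,
#' a metastasis label generated from a logistic model on the slide's mean
#' latent likelihood, and right-censored survival times whose hazard depends
#' on a planted slide-level risk score plus age and Ki-67.
#'
#' The painted signal has two channels: the eosin-like hue of the tissue
#' shifts monotonically with the latent likelihood, and the number of dark
#' nucleus-like blobs grows with it. The hue channel is recoverable by a
#' trivial intensity feature; the blob channel survives per-tile Z-scoring
#' and is what the patch network learns.
#'
#' @param n_patients number of patients (one slide per patient).
#' @param tiles_per_slide tiles making up each slide (the slide image is the
#'   smallest near-square grid holding them; spare grid cells are white).
#' @param tile_size tile side length in pixels. Clinical slides use 512;
#'   the package default (64) is a desk-scale size with the same structure.
#' @param er_prevalence probability that a slide is ER positive (label 1).
#' @param likelihood_beta_pos,likelihood_beta_neg `(alpha, beta)` shape pairs
#'   of the latent tile-likelihood distribution for ER+ and ER- slides.
#' @param background_fraction expected fraction of white background tiles.
#' @param metastasis_logit_coefs `(intercept, slope)` of the logistic model
#'   `logit P(metastasis) = intercept + slope * mean latent likelihood`.
#' @param metastasis_missing_rate fraction of patients whose metastasis label
#'   is unknown (recorded as `NA`, mirroring unreachable follow-up).
#' @param censoring_rate target right-censoring fraction in `[0, 1)`.
#' @param hazard_coefs named vector `(risk, age, ki67)`: log-hazard-ratio per
#'   unit of the planted risk score, per SD of age, and per SD of Ki-67.
#' @param baseline_hazard baseline event rate per month (default gives a
#'   60-month median survival at zero linear predictor).
#' @param weibull_shape Weibull shape of event times; 1 = exponential.
#' @param train_fraction fraction of patients assigned to the training split.
#' @param seed root seed; identical `(config, seed)` pairs are bit-identical.
#'
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 120,
                          tiles_per_slide = 100,
                          tile_size = 64,
                          er_prevalence = 0.5,
                          likelihood_beta_pos = c(8, 2),
                          likelihood_beta_neg = c(2, 8),
                          background_fraction = 0.1,
                          metastasis_logit_coefs = c(intercept = -5, slope = 10),
                          metastasis_missing_rate = 0.25,
                          censoring_rate = 0.3,
                          hazard_coefs = c(risk = 1.0, age = 0.3, ki67 = 0.5),
                          baseline_hazard = log(2) / 60,
                          weibull_shape = 1,
                          train_fraction = 0.7,
                          seed = 1L) {
  assert_that(is_count(n_patients) && n_patients >= 2,
              "n_patients must be an integer >= 2")
  assert_that(is_count(tiles_per_slide), "tiles_per_slide must be a positive integer")
  assert_that(is_count(tile_size) && tile_size >= 16,
              "tile_size must be an integer >= 16")
  assert_that(is_prob(er_prevalence), "er_prevalence must be a probability")
  for (shp in list(likelihood_beta_pos, likelihood_beta_neg)) {
    assert_that(length(shp) == 2 && all(is.finite(shp)) && all(shp > 0),
                "Beta shape pairs must be two finite positive numbers")
  }
  assert_that(is_prob(background_fraction) && background_fraction < 1,
              "background_fraction must be in [0, 1)")
  assert_that(length(metastasis_logit_coefs) == 2 &&
                all(is.finite(metastasis_logit_coefs)),
              "metastasis_logit_coefs must be (intercept, slope)")
  assert_that(is_prob(metastasis_missing_rate), "metastasis_missing_rate must be a probability")
  assert_that(is_prob(censoring_rate) && censoring_rate < 1,
              "censoring_rate must be in [0, 1)")
  assert_that(length(hazard_coefs) == 3 && all(is.finite(hazard_coefs)),
              "hazard_coefs must be (risk, age, ki67)")
  assert_that(is.numeric(baseline_hazard) && baseline_hazard > 0,
              "baseline_hazard must be positive")
  assert_that(is.numeric(weibull_shape) && weibull_shape > 0,
              "weibull_shape must be positive")
  assert_that(is.numeric(train_fraction) && train_fraction > 0 && train_fraction < 1,
              "train_fraction must be in (0, 1)")
  cfg <- list(
    n_patients = as.integer(n_patients),
    tiles_per_slide = as.integer(tiles_per_slide),
    tile_size = as.integer(tile_size),
    er_prevalence = er_prevalence,
    likelihood_beta_pos = as.numeric(likelihood_beta_pos),
    likelihood_beta_neg = as.numeric(likelihood_beta_neg),
    background_fraction = background_fraction,
    metastasis_logit_coefs = as.numeric(metastasis_logit_coefs),
    metastasis_missing_rate = metastasis_missing_rate,
    censoring_rate = censoring_rate,
    hazard_coefs = stats::setNames(as.numeric(hazard_coefs),
                                   c("risk", "age", "ki67")),
    baseline_hazard = baseline_hazard,
    weibull_shape = weibull_shape,
    train_fraction = train_fraction,
    seed = as.integer(seed)
  )
  class(cfg) <- "cohort_config"
  cfg
}

# Tissue tile: eosin-pink base whose red/blue means shift with the latent
# likelihood, plus dark nucleus-like blobs whose count grows with it.
paint_tissue_tile <- function(likelihood, size) {
  base <- c(205, 160, 185)
  px <- array(0, dim = c(size, size, 3))
  for (ch in 1:3) {
    px[, , ch] <- base[ch] + rnorm(size * size, sd = 12)
  }
  px[, , 1] <- px[, , 1] + (likelihood - 0.5) * 50
  px[, , 3] <- px[, , 3] - (likelihood - 0.5) * 30
  n_blobs <- rpois(1, 3 + 27 * likelihood)
  if (n_blobs > 0) {
    blob_col <- c(90, 60, 140)
    cx <- runif(n_blobs, 1, size)
    cy <- runif(n_blobs, 1, size)
    r <- sample(2:4, n_blobs, replace = TRUE)
    for (b in seq_len(n_blobs)) {
      xs <- max(1, floor(cx[b] - r[b])):min(size, ceiling(cx[b] + r[b]))
      ys <- max(1, floor(cy[b] - r[b])):min(size, ceiling(cy[b] + r[b]))
      d2 <- outer((xs - cx[b])^2, (ys - cy[b])^2, "+")
      inside <- d2 <= r[b]^2
      if (any(inside)) {
        for (ch in 1:3) {
          block <- px[xs, ys, ch]
          block[inside] <- blob_col[ch] + rnorm(sum(inside), sd = 8)
          px[xs, ys, ch] <- block
        }
      }
    }
  }
  clamp(px, 0, 255)
}

paint_background_tile <- function(size) {
  px <- array(248 + rnorm(size * size * 3, sd = 3), dim = c(size, size, 3))
  clamp(px, 232, 255)
}

#' Generate a synthetic slide cohort
#'
#' Draws ER labels, latent per-tile likelihoods, painted slide images,
#' metastasis labels, clinical covariates and right-censored survival times
#' according to a [cohort_config()]. All randomness flows from the config's
#' seed; re-running with the same config is bit-identical.
#'
#' @param config a [cohort_config()].
#' @return an object of class `synthetic_cohort` with elements `manifest`
#'   (one row per slide: ids, labels, split), `survival` (time in months,
#'   event indicator, age, Ki-67), `patch_truth` (the latent likelihood each
#'   tile was painted from -- a test oracle, never a model input),
#'   `slide_images` (named list of `H x W x 3` arrays in `[0, 255]`) and
#'   `grid` (tile grid geometry).
#' @export
generate_cohort <- function(config) {
  assert_that(inherits(config, "cohort_config"),
              "config must be built with cohort_config()")
  n <- config$n_patients
  ts <- config$tile_size
  nt <- config$tiles_per_slide
  grid_ncol <- ceiling(sqrt(nt))
  grid_nrow <- ceiling(nt / grid_ncol)

  out <- withr::with_seed(config$seed, {
    er <- rbinom(n, 1, config$er_prevalence)
    slide_ids <- sprintf("S%03d", seq_len(n))
    patient_ids <- sprintf("P%03d", seq_len(n))

    slide_images <- vector("list", n)
    names(slide_images) <- slide_ids
    truth <- vector("list", n)
    mean_lik <- numeric(n)

    for (i in seq_len(n)) {
      shp <- if (er[i] == 1) config$likelihood_beta_pos else config$likelihood_beta_neg
      bg <- rbinom(nt, 1, config$background_fraction) == 1
      if (all(bg)) bg[1] <- FALSE  # every slide keeps >= 1 tissue tile
      lik <- rep(NA_real_, nt)
      lik[!bg] <- rbeta(sum(!bg), shp[1], shp[2])
      img <- array(255, dim = c(grid_nrow * ts, grid_ncol * ts, 3))
      for (k in seq_len(nt)) {
        r <- (k - 1) %/% grid_ncol
        cc <- (k - 1) %% grid_ncol
        tile <- if (bg[k]) paint_background_tile(ts) else paint_tissue_tile(lik[k], ts)
        img[r * ts + 1:ts, cc * ts + 1:ts, ] <- tile
      }
      slide_images[[i]] <- round(img)
      truth[[i]] <- data.frame(
        slide_id = slide_ids[i],
        row = (seq_len(nt) - 1) %/% grid_ncol,
        col = (seq_len(nt) - 1) %% grid_ncol,
        likelihood = lik,
        background = bg,
        stringsAsFactors = FALSE
      )
      mean_lik[i] <- mean(lik, na.rm = TRUE)
    }

    # metastasis: logistic in the slide's mean latent likelihood
    logit_met <- config$metastasis_logit_coefs[1] +
      config$metastasis_logit_coefs[2] * mean_lik
    met <- rbinom(n, 1, plogis(logit_met))
    met[runif(n) < config$metastasis_missing_rate] <- NA_integer_

    # clinical covariates (marginals loosely matching a routine breast cohort)
    age <- clamp(rnorm(n, 52.6, 10.4), 27, 89)
    ki67 <- 0.01 + 0.89 * rbeta(n, 0.62, 1.35)

    # survival: Weibull (default exponential) hazard on a planted linear score
    risk_core <- 2 * (mean_lik - 0.5)
    lp <- config$hazard_coefs[["risk"]] * risk_core +
      config$hazard_coefs[["age"]] * (age - 52.6) / 10.4 +
      config$hazard_coefs[["ki67"]] * (ki67 - 0.29) / 0.24
    u <- runif(n)
    time_event <- (-log(u) / (config$baseline_hazard * exp(lp)))^(1 / config$weibull_shape)
    censored <- runif(n) < config$censoring_rate
    time <- ifelse(censored, runif(n) * time_event, time_event)
    time <- pmax(time, 0.01)
    event <- as.integer(!censored)

    list(er = er, slide_ids = slide_ids, patient_ids = patient_ids,
         slide_images = slide_images, truth = truth, mean_lik = mean_lik,
         met = met, age = age, ki67 = ki67, risk_core = risk_core,
         time = time, event = event)
  })

  split <- split_cohort(n, train_fraction = config$train_fraction,
                        seed = stage_seed(config$seed, "split"))

  manifest <- data.frame(
    slide_id = out$slide_ids,
    patient_id = out$patient_ids,
    er_label = out$er,
    metastasis_label = out$met,
    split = split,
    image_path = NA_character_,
    stringsAsFactors = FALSE
  )
  survival_df <- data.frame(
    patient_id = out$patient_ids,
    time_months = out$time,
    event = out$event,
    age = out$age,
    ki67 = out$ki67,
    stringsAsFactors = FALSE
  )
  cohort <- list(
    config = config,
    manifest = manifest,
    survival = survival_df,
    patch_truth = do.call(rbind, out$truth),
    slide_images = out$slide_images,
    latent_mean_likelihood = stats::setNames(out$mean_lik, out$slide_ids),
    latent_risk = stats::setNames(out$risk_core, out$slide_ids),
    grid = list(nrow = grid_nrow, ncol = grid_ncol, tile_size = ts,
                tiles_per_slide = nt)
  )
  class(cohort) <- "synthetic_cohort"
  cohort
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("synthetic_cohort:", nrow(x$manifest), "slides x",
      x$grid$tiles_per_slide, "tiles of", x$grid$tile_size, "px\n")
  cat("  ER+ slides:", sum(x$manifest$er_label), " metastasis labelled:",
      sum(!is.na(x$manifest$metastasis_label)), "\n")
  cat("  events:", sum(x$survival$event), "/", nrow(x$survival), "\n")
  invisible(x)
}

#' Cut one slide of a cohort into its tiles
#'
#' @param cohort a `synthetic_cohort`.
#' @param slide_id slide identifier.
#' @return list of tiles, each `list(slide_id, row, col, pixels)` with pixels
#'   in `[0, 255]`; only the configured `tiles_per_slide` grid cells are
#'   returned (spare white filler cells are omitted).
#' @export
cohort_tiles <- function(cohort, slide_id) {
  assert_that(slide_id %in% names(cohort$slide_images),
              "unknown slide_id: ", slide_id)
  img <- cohort$slide_images[[slide_id]]
  ts <- cohort$grid$tile_size
  nt <- cohort$grid$tiles_per_slide
  gc <- cohort$grid$ncol
  lapply(seq_len(nt), function(k) {
    r <- (k - 1) %/% gc
    cc <- (k - 1) %% gc
    list(slide_id = slide_id, row = r, col = cc,
         pixels = img[r * ts + 1:ts, cc * ts + 1:ts, , drop = FALSE])
  })
}

#' Write a synthetic cohort to disk
#'
#' Writes per-slide whole-slide PNG images, per-slide tile PNG folders, the
#' manifest and survival tables as CSV, and the latent patch truth under
#' `oracle/` (clearly separated: it is a test oracle, never a model input).
#'
#' @param cohort a `synthetic_cohort`.
#' @param directory output directory.
#' @param overwrite allow writing into an existing non-empty directory.
#' @return path of the written `manifest.csv`, invisibly.
#' @export
write_cohort <- function(cohort, directory, overwrite = FALSE) {
  assert_that(inherits(cohort, "synthetic_cohort"), "not a synthetic_cohort")
  if (dir.exists(directory) && length(list.files(directory)) > 0 && !overwrite) {
    stop("directory ", directory, " is non-empty; set overwrite = TRUE",
         call. = FALSE)
  }
  dir.create(file.path(directory, "slide_images"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(directory, "tiles"), showWarnings = FALSE)
  dir.create(file.path(directory, "oracle"), showWarnings = FALSE)

  manifest <- cohort$manifest
  for (sid in manifest$slide_id) {
    rel <- file.path("slide_images", paste0(sid, ".png"))
    png::writePNG(cohort$slide_images[[sid]] / 255,
                  file.path(directory, rel))
    manifest$image_path[manifest$slide_id == sid] <- rel
    tdir <- file.path(directory, "tiles", sid)
    dir.create(tdir, showWarnings = FALSE)
    for (tl in cohort_tiles(cohort, sid)) {
      png::writePNG(tl$pixels[, , , drop = TRUE] / 255,
                    file.path(tdir, sprintf("r%02d_c%02d.png", tl$row, tl$col)))
    }
  }
  manifest_path <- file.path(directory, "manifest.csv")
  write.csv(manifest, manifest_path, row.names = FALSE)
  write.csv(cohort$survival, file.path(directory, "survival.csv"),
            row.names = FALSE)
  write.csv(cohort$patch_truth, file.path(directory, "oracle", "patch_truth.csv"),
            row.names = FALSE)
  invisible(manifest_path)
}

#' Read a cohort manifest written by [write_cohort()]
#' @param path path to `manifest.csv`.
#' @return the manifest data frame with an attribute `root` (its directory),
#'   against which relative `image_path` entries resolve.
#' @export
read_manifest <- function(path) {
  assert_that(file.exists(path), "manifest not found: ", path)
  m <- read.csv(path, stringsAsFactors = FALSE)
  attr(m, "root") <- dirname(normalizePath(path))
  m
}
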