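#' Partition an image into non-overlapping square tiles
#'
#' Cuts the largest grid of full `tile_size` tiles anchored at the image
#' origin; partial edge tiles are discarded. Tiles are returned in row-major
#' order with 0-based `(row, col)` grid coordinates over half-open pixel
#' intervals `[row * tile_size, (row + 1) * tile_size)`.
#'
#' @param image numeric `H x W x 3` array with values in `[0, 255]`.
#' @param tile_size tile side length in pixels (default 512).
#' @param slide_id optional slide identifier attached to each tile.
#' @return list of tiles `list(slide_id, row, col, pixels)`; empty (with a
#'   warning) if the image is smaller than one tile.
#' @export
tile_image <- function(image, tile_size = 512, slide_id = NA_character_) {
  d <- dim(image)
  assert_that(length(d) == 3 && d[3] == 3, "image must be an H x W x 3 array")
  nr <- d[1] %/% tile_size
  nc <- d[2] %/% tile_size
  if (nr < 1 || nc < 1) {
    warning("image (", d[1], "x", d[2], ") smaller than one ", tile_size,
            "px tile; returning no tiles")
    return(list())
  }
  tiles <- vector("list", nr * nc)
  k <- 0
  for (r in 0:(nr - 1)) {
    for (cc in 0:(nc - 1)) {
      k <- k + 1
      tiles[[k]] <- list(
        slide_id = slide_id, row = r, col = cc,
        pixels = image[r * tile_size + 1:tile_size,
                       cc * tile_size + 1:tile_size, , drop = FALSE]
      )
    }
  }
  tiles
}

#' White-background test for a tile
#'
#' A tile is background iff the fraction of pixels whose three channels are
#' all at least `white_level` strictly exceeds `white_fraction`.
#'
#' @param tile a tile from [tile_image()] or a pixel array in `[0, 255]`.
#' @param white_level per-channel whiteness threshold (default 220).
#' @param white_fraction fraction of white pixels above which the tile is
#'   called background (default 0.8).
#' @return logical scalar.
#' @export
is_background <- function(tile, white_level = 220, white_fraction = 0.8) {
  px <- if (is.list(tile)) tile$pixels else tile
  white <- px[, , 1] >= white_level & px[, , 2] >= white_level &
    px[, , 3] >= white_level
  mean(white) > white_fraction
}

# Ruderman lab colour space (the space of the original Reinhard transfer):
# RGB -> LMS cone response -> log10 -> decorrelated l/alpha/beta axes.
.rgb2lms <- matrix(c(
  0.3811, 0.5783, 0.0402,
  0.1967, 0.7244, 0.0782,
  0.0241, 0.1288, 0.8444
), nrow = 3, byrow = TRUE)
.lms2rgb <- solve(.rgb2lms)
.lms2lab <- matrix(c(
  1 / sqrt(3), 1 / sqrt(3), 1 / sqrt(3),
  1 / sqrt(6), 1 / sqrt(6), -2 / sqrt(6),
  1 / sqrt(2), -1 / sqrt(2), 0
), nrow = 3, byrow = TRUE)
.lab2lms <- solve(.lms2lab)

#' Convert pixels between RGB and Ruderman lab space
#'
#' @param px `H x W x 3` array, RGB in `[0, 255]` (for [rgb_to_lab()]) or
#'   lab channels (for [lab_to_rgb()]).
#' @return `H x W x 3` array in the other space; [lab_to_rgb()] clips to
#'   `[0, 255]`.
#' @export
rgb_to_lab <- function(px) {
  d <- dim(px)
  m <- matrix(px, ncol = 3) / 255
  lms <- m %*% t(.rgb2lms)
  lms <- pmax(lms, 1e-6)  # log-domain guard for pure black
  lab <- log10(lms) %*% t(.lms2lab)
  array(lab, dim = d)
}

#' @rdname rgb_to_lab
#' @export
lab_to_rgb <- function(px) {
  d <- dim(px)
  lab <- matrix(px, ncol = 3)
  lms <- 10^(lab %*% t(.lab2lms))
  rgb <- lms %*% t(.lms2rgb) * 255
  array(clamp(rgb, 0, 255), dim = d)
}

#' Reinhard reference statistics of a tile
#'
#' @param px pixel array in `[0, 255]` (or a tile list).
#' @return object of class `reinhard_reference`: per-channel lab means and
#'   (population) standard deviations.
#' @export
reinhard_reference <- function(px) {
  if (is.list(px)) px <- px$pixels
  lab <- rgb_to_lab(px)
  ref <- list(
    mean_lab = apply(lab, 3, mean),
    std_lab = apply(lab, 3, sd_pop)
  )
  assert_that(all(ref$std_lab >= 0), "invalid reference")
  class(ref) <- "reinhard_reference"
  ref
}

#' Reinhard colour normalization
#'
#' Matches a tile's per-channel mean and standard deviation in Ruderman lab
#' space to a reference: each channel is mapped through
#' `(x - mean_tile) * sd_ref / sd_tile + mean_ref`, then converted back to
#' RGB with clipping. A near-constant channel (sd below `1e-8`) is shifted
#' only (scale 1), with a message.
#'
#' @param tile a tile list or pixel array in `[0, 255]`.
#' @param ref a [reinhard_reference()].
#' @return object of the same kind as `tile` with normalized pixels
#'   (continuous, not yet 8-bit quantized).
#' @export
reinhard_normalize <- function(tile, ref) {
  assert_that(inherits(ref, "reinhard_reference"), "ref must be a reinhard_reference")
  assert_that(all(ref$std_lab > 0), "reference std components must be positive")
  px <- if (is.list(tile)) tile$pixels else tile
  lab <- rgb_to_lab(px)
  for (ch in 1:3) {
    x <- lab[, , ch]
    mu <- mean(x)
    sg <- sd_pop(x)
    if (sg < 1e-8) {
      message("reinhard_normalize: near-constant lab channel ", ch,
              "; shifting without scaling")
      lab[, , ch] <- x - mu + ref$mean_lab[ch]
    } else {
      lab[, , ch] <- (x - mu) * (ref$std_lab[ch] / sg) + ref$mean_lab[ch]
    }
  }
  out <- lab_to_rgb(lab)
  if (is.list(tile)) {
    tile$pixels <- out
    tile
  } else {
    out
  }
}

#' Read tiles back from a tile index
#'
#' @param dir the directory `tiles.csv` paths are relative to (the
#'   `out_dir` of [tile_slide_set()]).
#' @param index rows of the tile index to read (kept tiles only).
#' @return list of tiles `list(slide_id, row, col, pixels)` in `[0, 255]`.
#' @export
read_indexed_tiles <- function(dir, index) {
  lapply(seq_len(nrow(index)), function(i) {
    px <- png::readPNG(file.path(dir, index$path[i])) * 255
    if (length(dim(px)) == 2) px <- array(rep(px, 3), dim = c(dim(px), 3))
    list(slide_id = index$slide_id[i], row = index$row[i],
         col = index$col[i], pixels = px)
  })
}

#' Tile, filter and normalize every slide of a manifest
#'
#' Reads each slide image, cuts it into tiles, flags white-background tiles,
#' Reinhard-normalizes the kept tiles and writes them as PNG files together
#' with a tile index. Unreadable slides are skipped and recorded as failed.
#'
#' @param manifest a manifest data frame from [read_manifest()] (columns
#'   `slide_id`, `image_path`; relative paths resolve against the manifest's
#'   `root` attribute).
#' @param out_dir output directory for kept tile PNGs and `tiles.csv`.
#' @param ref optional [reinhard_reference()]; by default the statistics of
#'   the first non-background tile of the cohort are used and recorded.
#' @param tile_size tile side length (default 512).
#' @param white_level,white_fraction background rule, see [is_background()].
#' @param normalize apply Reinhard normalization to kept tiles.
#' @return the tile index data frame (`slide_id`, `row`, `col`, `path`,
#'   `background`, `failed`), invisibly; also written to
#'   `<out_dir>/tiles.csv`, with the reference in `<out_dir>/reinhard_ref.json`.
#' @export
tile_slide_set <- function(manifest, out_dir, ref = NULL, tile_size = 512,
                           white_level = 220, white_fraction = 0.8,
                           normalize = TRUE) {
  root <- attr(manifest, "root")
  dir.create(file.path(out_dir, "tiles"), recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (i in seq_len(nrow(manifest))) {
    sid <- manifest$slide_id[i]
    ipath <- manifest$image_path[i]
    if (!is.null(root) && !file.exists(ipath)) {
      ipath <- file.path(root, manifest$image_path[i])
    }
    img <- tryCatch(png::readPNG(ipath) * 255, error = function(e) NULL)
    if (is.null(img)) {
      rows[[length(rows) + 1]] <- data.frame(
        slide_id = sid, row = NA_integer_, col = NA_integer_,
        path = NA_character_, background = NA, failed = TRUE,
        stringsAsFactors = FALSE
      )
      message("tile_slide_set: could not read ", ipath, "; slide skipped")
      next
    }
    if (length(dim(img)) == 2) img <- array(rep(img, 3), dim = c(dim(img), 3))
    tiles <- tile_image(img, tile_size = tile_size, slide_id = sid)
    tdir <- file.path(out_dir, "tiles", sid)
    dir.create(tdir, showWarnings = FALSE)
    for (tl in tiles) {
      bg <- is_background(tl, white_level, white_fraction)
      tpath <- NA_character_
      if (!bg) {
        if (is.null(ref)) {
          ref <- reinhard_reference(tl)
        }
        out_px <- if (normalize) reinhard_normalize(tl$pixels, ref) else tl$pixels
        tpath <- file.path("tiles", sid, sprintf("r%02d_c%02d.png", tl$row, tl$col))
        png::writePNG(round(out_px[, , , drop = TRUE]) / 255,
                      file.path(out_dir, tpath))
      }
      rows[[length(rows) + 1]] <- data.frame(
        slide_id = sid, row = tl$row, col = tl$col, path = tpath,
        background = bg, failed = FALSE, stringsAsFactors = FALSE
      )
    }
  }
  index <- do.call(rbind, rows)
  write.csv(index, file.path(out_dir, "tiles.csv"), row.names = FALSE)
  if (!is.null(ref)) {
    jsonlite::write_json(list(mean_lab = ref$mean_lab, std_lab = ref$std_lab),
                         file.path(out_dir, "reinhard_ref.json"),
                         auto_unbox = FALSE, digits = NA)
  }
  invisible(index)
}
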