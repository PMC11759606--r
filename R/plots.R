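#' Render a probability map as a heat image
#'
#' Writes the per-slide likelihood grid as a PNG with a blue-to-red
#' colormap (blue = likelihood 0, red = 1); no-data cells are light grey.
#'
#' @param grid matrix from [probability_map()].
#' @param path output PNG path.
#' @param scale integer pixel upscaling per grid cell (default 16).
#' @return `path`, invisibly.
#' @export
render_probability_map <- function(grid, path, scale = 16) {
  nr <- nrow(grid)
  nc <- ncol(grid)
  img <- array(0.85, dim = c(nr, nc, 3))  # grey for no-data
  v <- clamp(grid, 0, 1)
  ok <- !is.na(v)
  r <- img[, , 1]; g <- img[, , 2]; b <- img[, , 3]
  r[ok] <- v[ok]
  g[ok] <- 0.2
  b[ok] <- 1 - v[ok]
  img[, , 1] <- r; img[, , 2] <- g; img[, , 3] <- b
  big <- img[rep(seq_len(nr), each = scale), rep(seq_len(nc), each = scale), ]
  png::writePNG(big, path)
  invisible(path)
}

#' Kaplan-Meier plot for risk strata
#'
#' @param groups factor of risk groups (e.g. from [stratify_risk()]).
#' @param time follow-up times in months.
#' @param event 0/1 event indicators.
#' @param path output PNG path.
#' @param main plot title.
#' @return `path`, invisibly.
#' @export
plot_km <- function(groups, time, event, path, main = "Kaplan-Meier by risk group") {
  sf <- survival::survfit(survival::Surv(time, event) ~ groups)
  lr <- logrank_test(groups, time, event)
  grDevices::png(path, width = 720, height = 540)
  on.exit(grDevices::dev.off())
  graphics::plot(sf, col = c("steelblue", "firebrick"), lwd = 2,
                 xlab = "Months", ylab = "Survival probability", main = main)
  graphics::legend("bottomleft", legend = levels(droplevels(as.factor(groups))),
                   col = c("steelblue", "firebrick"), lwd = 2, bty = "n")
  graphics::mtext(sprintf("log-rank p = %.3g", lr$p_value), side = 3, line = 0.2)
  invisible(path)
}

#' ROC curve plot for one or more score vectors
#'
#' @param scores named list of numeric score vectors.
#' @param labels 0/1 outcome labels shared by all score vectors.
#' @param path output PNG path.
#' @param main plot title.
#' @return `path`, invisibly.
#' @export
plot_roc <- function(scores, labels, path, main = "ROC") {
  grDevices::png(path, width = 600, height = 600)
  on.exit(grDevices::dev.off())
  cols <- grDevices::hcl.colors(max(3, length(scores)), "Dark 3")
  first <- TRUE
  nms <- names(scores)
  for (i in seq_along(scores)) {
    r <- pROC::roc(labels, scores[[i]], quiet = TRUE, direction = "<")
    pROC::plot.roc(r, col = cols[i], add = !first, main = if (first) main,
                   legacy.axes = TRUE)
    first <- FALSE
  }
  graphics::legend("bottomright", bty = "n", lwd = 2, col = cols[seq_along(scores)],
                   legend = sprintf("%s (AUC %.3f)", nms,
                                    vapply(seq_along(scores), function(i)
                                      as.numeric(auc_score(scores[[i]], labels)),
                                      numeric(1))))
  invisible(path)
}
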