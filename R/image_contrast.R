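#' Image normalization
#'
#' Affine rescaling of a grayscale image so that a low and a high reference
#' level map to 0 and 1, with clipping. The default (`"percentile"`) uses the
#' 0.1 and 99.9 percentiles, which is robust to isolated hot/dead pixels; a
#' plain min-max mode is also available. A constant image cannot define the
#' affine map and is an error.
#'
#' @param image Numeric matrix.
#' @param mode `"percentile"` (default) or `"minmax"`.
#' @param probs Length-2 percentile pair for percentile mode.
#' @return The normalized image, clipped to \[0, 1\]; attributes preserved.
#' @export
normalize_image <- function(image, mode = c("percentile", "minmax"),
                            probs = c(0.001, 0.999)) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(image), is.numeric(image))
  if (mode == "percentile") {
    bounds <- stats::quantile(image, probs = probs, names = FALSE)
  } else {
    bounds <- range(image)
  }
  if (diff(bounds) <= 0) {
    rlang::abort("degenerate input: image is constant, normalization undefined")
  }
  out <- (image - bounds[[1]]) / (bounds[[2]] - bounds[[1]])
  out[] <- pmin(pmax(out, 0), 1)
  out
}

# integral-image box sum: count of TRUE in each roi_size x roi_size window;
# result[i, j] is the count for the window with top-left corner (i, j)
.box_count <- function(mask, roi_size) {
  cum <- apply(apply(mask, 2, cumsum), 1, cumsum)  # transposed cumulative sum
  cum <- t(cum)
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(0, nr + 1, nc + 1)
  pad[2:(nr + 1), 2:(nc + 1)] <- cum
  s <- roi_size
  i <- seq_len(nr - s + 1); j <- seq_len(nc - s + 1)
  pad[i + s, j + s, drop = FALSE] - pad[i, j + s, drop = FALSE] -
    pad[i + s, j, drop = FALSE] + pad[i, j, drop = FALSE]
}

#' Sample paired cell/surround regions of interest
#'
#' Draws `n` ROI pairs from a section label map: each cell ROI is a
#' `roi_size x roi_size` pixel square lying entirely within cell-body labels
#' (cytoplasm, nucleus or nucleolus), and its paired surround ROI is an
#' equal-sized square entirely within neuropil, centred within
#' `max_pair_distance_px` of the cell ROI (the nearest eligible position is
#' taken). Cell ROI centres of different pairs are kept at least
#' `min_separation_px` apart. Sampling is seeded and deterministic.
#'
#' @param labelmap A `section_labelmap`.
#' @param n Number of pairs (default 50).
#' @param roi_size Square side in pixels (default 11).
#' @param min_separation_px Minimum distance between cell ROI centres.
#' @param max_pair_distance_px Maximum cell-to-surround centre distance.
#' @param seed Integer seed.
#' @return A `roi_pairs` tibble listing every ROI pixel, with columns
#'   `pair_id`, `role` (`"cell"`/`"surround"`), `x` (column) and `y` (row),
#'   1-based; `roi_size` is attached as an attribute.
#' @export
sample_roi_pairs <- function(labelmap, n = 50, roi_size = 11,
                             min_separation_px = 2 * roi_size,
                             max_pair_distance_px = 6 * roi_size,
                             seed) {
  stopifnot(inherits(labelmap, "section_labelmap"))
  if (missing(seed)) rlang::abort("`seed` is required for reproducible sampling")
  lab <- labelmap$labels
  empty <- tibble::tibble(pair_id = integer(0), role = character(0),
                          x = integer(0), y = integer(0))
  attr(empty, "roi_size") <- roi_size
  class(empty) <- c("roi_pairs", class(empty))
  if (n == 0) return(empty)
  cell_mask <- lab %in% PHANTOM_LABELS[c("cytoplasm", "nucleus", "nucleolus")]
  dim(cell_mask) <- dim(lab)
  surr_mask <- lab == PHANTOM_LABELS[["neuropil"]]
  s <- roi_size
  if (nrow(lab) < s || ncol(lab) < s) rlang::abort("label map smaller than the ROI")
  full <- s * s
  cell_ok <- .box_count(cell_mask, s) == full   # indexed by top-left corner
  surr_ok <- .box_count(surr_mask, s) == full
  cell_idx <- which(cell_ok, arr.ind = TRUE)
  surr_idx <- which(surr_ok, arr.ind = TRUE)
  if (nrow(cell_idx) == 0 || nrow(surr_idx) == 0) {
    rlang::abort("insufficient eligible regions: 0 achievable ROI pairs")
  }
  half <- (s - 1) / 2
  centers <- function(idx) cbind(idx[, 1] + half, idx[, 2] + half)
  cc <- centers(cell_idx)
  sc <- centers(surr_idx)
  picked <- with_seed(seed, {
    ord <- sample.int(nrow(cc))
    chosen <- integer(0)
    partner <- integer(0)
    for (i in ord) {
      if (length(chosen) >= n) break
      if (length(chosen) > 0) {
        d <- sqrt((cc[chosen, 1] - cc[i, 1])^2 + (cc[chosen, 2] - cc[i, 2])^2)
        if (any(d < min_separation_px)) next
      }
      ds <- sqrt((sc[, 1] - cc[i, 1])^2 + (sc[, 2] - cc[i, 2])^2)
      jbest <- which.min(ds)
      if (ds[[jbest]] > max_pair_distance_px) next
      chosen <- c(chosen, i)
      partner <- c(partner, jbest)
    }
    list(chosen = chosen, partner = partner)
  })
  if (length(picked$chosen) < n) {
    rlang::abort(sprintf(
      "insufficient eligible regions: only %d of %d ROI pairs achievable",
      length(picked$chosen), n))
  }
  roi_pixels <- function(idx_row) {
    xs <- seq(idx_row[[2]], idx_row[[2]] + s - 1L)  # columns
    ys <- seq(idx_row[[1]], idx_row[[1]] + s - 1L)  # rows
    tidyr::expand_grid(y = ys, x = xs)
  }
  out <- purrr::map_dfr(seq_along(picked$chosen), function(p) {
    dplyr::bind_rows(
      dplyr::mutate(roi_pixels(cell_idx[picked$chosen[[p]], ]),
                    pair_id = p, role = "cell"),
      dplyr::mutate(roi_pixels(surr_idx[picked$partner[[p]], ]),
                    pair_id = p, role = "surround"))
  })
  out <- dplyr::select(out, "pair_id", "role", "x", "y")
  attr(out, "roi_size") <- roi_size
  class(out) <- c("roi_pairs", class(out))
  out
}

#' ROI pair CSV import/export
#'
#' The on-disk contract is `pair_id,role,x,y` with 0-based, row-major pixel
#' coordinates; in R the tibble uses 1-based matrix coordinates (`x` = column,
#' `y` = row). These functions convert between the two.
#'
#' @param pairs A `roi_pairs` tibble.
#' @param path CSV path.
#' @return `read_roi_pairs()` returns a `roi_pairs` tibble; `write_roi_pairs()`
#'   returns `path` invisibly.
#' @export
write_roi_pairs <- function(pairs, path) {
  df <- data.frame(pair_id = pairs$pair_id, role = pairs$role,
                   x = pairs$x - 1L, y = pairs$y - 1L)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_roi_pairs
#' @export
read_roi_pairs <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("pair_id", "role", "x", "y") %in% names(df)))
  out <- tibble::tibble(pair_id = as.integer(df$pair_id), role = df$role,
                        x = as.integer(df$x) + 1L, y = as.integer(df$y) + 1L)
  class(out) <- c("roi_pairs", class(out))
  out
}

#' Measure image contrast over ROI pairs
#'
#' For each pair, the mean brightness of the cell and surround regions is
#' computed and the pair's contrast is the brighter over the darker mean
#' (`"ratio"`, default) or the Michelson contrast. The estimate aggregates the
#' per-pair values (per-pair-then-average, not pooled): mean, standard
#' deviation and count. Pairs in which a region mean is exactly 0 are
#' degenerate for the ratio; they are excluded and counted.
#'
#' @param image Numeric matrix (e.g. a rendered `section_image`).
#' @param pairs A `roi_pairs` tibble.
#' @param mode `"ratio"` (default) or `"michelson"`.
#' @return A `contrast_estimate`: list with `pairs` (per-pair tibble),
#'   `mean_contrast`, `sd_contrast`, `n`, `n_excluded`, `mode`.
#' @export
measure_contrast <- function(image, pairs, mode = c("ratio", "michelson")) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(image))
  if (nrow(pairs) == 0) rlang::abort("no ROI pairs supplied")
  if (any(pairs$y < 1 | pairs$y > nrow(image) | pairs$x < 1 | pairs$x > ncol(image))) {
    rlang::abort("ROI pixel outside image bounds")
  }
  vals <- tibble::tibble(pair_id = pairs$pair_id, role = pairs$role,
                         v = image[cbind(pairs$y, pairs$x)])
  means <- vals |>
    dplyr::summarise(mean_v = mean(.data$v), .by = c("pair_id", "role")) |>
    tidyr::pivot_wider(names_from = "role", values_from = "mean_v")
  if (!all(c("cell", "surround") %in% names(means))) {
    rlang::abort("pairs must contain both 'cell' and 'surround' roles")
  }
  hi <- pmax(means$cell, means$surround)
  lo <- pmin(means$cell, means$surround)
  degenerate <- if (mode == "ratio") lo == 0 else (hi + lo) == 0
  contrast <- rep(NA_real_, nrow(means))
  contrast[!degenerate] <- if (mode == "ratio") {
    hi[!degenerate] / lo[!degenerate]
  } else {
    (hi[!degenerate] - lo[!degenerate]) / (hi[!degenerate] + lo[!degenerate])
  }
  per_pair <- tibble::tibble(pair_id = means$pair_id,
                             mean_cell = means$cell,
                             mean_surround = means$surround,
                             contrast = contrast,
                             excluded = degenerate)
  kept <- per_pair$contrast[!per_pair$excluded]
  if (length(kept) == 0) rlang::abort("all ROI pairs are degenerate (zero region mean)")
  if (any(degenerate)) {
    rlang::warn(sprintf("%d degenerate ROI pair(s) excluded from the estimate",
                        sum(degenerate)))
  }
  structure(list(pairs = per_pair,
                 mean_contrast = mean(kept),
                 sd_contrast = stats::sd(kept),
                 n = length(kept),
                 n_excluded = sum(degenerate),
                 mode = mode),
            class = "contrast_estimate")
}

#' @export
print.contrast_estimate <- function(x, ...) {
  cat(sprintf("<contrast_estimate> mean %.4f, sd %.4f over %d pair(s) [%s]%s\n",
              x$mean_contrast, x$sd_contrast, x$n, x$mode,
              if (x$n_excluded > 0) sprintf(" (%d excluded)", x$n_excluded) else ""))
  invisible(x)
}
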