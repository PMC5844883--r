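# grayscale max filter with a disc brush of the given diameter (odd)
max_filter <- function(x, diameter) {
  d <- max(3L, as.integer(diameter))
  if (d %% 2 == 0) d <- d + 1L
  brush <- EBImage::makeBrush(d, shape = "disc")
  as.matrix(EBImage::dilate(EBImage::Image(x), brush))
}

new_label_map <- function(labels, params = list()) {
  structure(list(labels = labels, n = max(labels), params = params),
            class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  cat(sprintf("label map: %d nuclei over a %d x %d field\n",
              x$n, nrow(x$labels), ncol(x$labels)))
  invisible(x)
}

#' Marker-based watershed segmentation of nuclei
#'
#' Standard marker-based recipe on the DAPI channel: Gaussian smoothing,
#' global threshold (Otsu by default), Euclidean distance transform of the
#' foreground, distance-maxima markers with a minimum separation, then
#' marker propagation through the foreground mask to split touching nuclei
#' at ridge lines. Regions below the minimum area are discarded and labels
#' relabeled contiguously.
#'
#' @param dapi 2-D numeric matrix (single channel). Any intensity scale is
#'   accepted; the image is range-normalized internally before thresholding.
#' @param sigma Gaussian smoothing sd in pixels.
#' @param threshold `"otsu"` or a numeric threshold on the normalized
#'   (0-1 range) smoothed image.
#' @param min_dist minimum marker separation in pixels; set this near the
#'   expected nucleus radius.
#' @param min_area minimum region area in pixels.
#' @return object of class `label_map` (`$labels` integer matrix, 0 =
#'   background; `$n` nuclei; `$params` provenance). A blank or constant
#'   image yields an empty map, not an error.
#' @export
segment_nuclei <- function(dapi, sigma = 2, threshold = "otsu",
                           min_dist = 8, min_area = 50) {
  stopifnot(is.matrix(dapi))
  params <- list(sigma = sigma, threshold = threshold,
                 min_dist = min_dist, min_area = min_area)
  rng <- range(dapi)
  if (!is.finite(diff(rng)) || diff(rng) == 0) {
    return(new_label_map(matrix(0L, nrow(dapi), ncol(dapi)), params))
  }
  xn <- (dapi - rng[1]) / diff(rng)
  sm <- as.matrix(EBImage::gblur(EBImage::Image(xn), sigma = sigma))
  th <- if (identical(threshold, "otsu")) {
    EBImage::otsu(EBImage::Image(sm), range = c(0, 1))
  } else as.numeric(threshold)
  mask <- sm > th
  if (!any(mask)) {
    return(new_label_map(matrix(0L, nrow(dapi), ncol(dapi)), params))
  }
  dm <- EBImage::distmap(EBImage::Image(mask))
  dmx <- as.matrix(dm)
  # markers: distance-transform maxima, min separation via max filter
  peaks <- dmx >= (max_filter(dmx, 2 * min_dist + 1) - 1e-9) & dmx > 1
  seeds <- EBImage::bwlabel(EBImage::Image(peaks))
  if (max(seeds) == 0) {
    return(new_label_map(matrix(0L, nrow(dapi), ncol(dapi)), params))
  }
  lab <- EBImage::propagate(EBImage::Image(sm), seeds = seeds,
                            mask = EBImage::Image(mask))
  lab <- as.matrix(EBImage::imageData(lab))
  # drop small regions, relabel contiguously
  sizes <- table(lab[lab > 0])
  keep <- as.integer(names(sizes)[sizes >= min_area])
  relabel <- integer(max(lab) + 1L)
  relabel[keep + 1L] <- seq_along(keep)
  labels <- matrix(relabel[lab + 1L], nrow(lab), ncol(lab))
  new_label_map(labels, params)
}

#' Per-nucleus intensity measurements
#'
#' Uses a label map as a mask to extract, for each nucleus, its area and its
#' mean pixel intensity in the given channel.
#'
#' @param labels a `label_map` (or bare integer matrix).
#' @param channel 2-D numeric matrix of the same shape.
#' @return tibble with columns `label`, `area`, `mean_intensity`
#'   (empty when the map has no nuclei).
#' @export
measure_nuclei <- function(labels, channel) {
  lab <- if (inherits(labels, "label_map")) labels$labels else labels
  if (!all(dim(lab) == dim(channel))) {
    abort("label map and channel shapes differ.")
  }
  if (max(lab) == 0) {
    return(tibble::tibble(label = integer(0), area = integer(0),
                          mean_intensity = numeric(0)))
  }
  fg <- lab > 0
  l <- factor(lab[fg], levels = seq_len(max(lab)))
  tibble::tibble(
    label = seq_len(max(lab)),
    area = as.integer(tabulate(l, nbins = max(lab))),
    mean_intensity = as.numeric(tapply(channel[fg], l, mean)))
}

#' Positivity threshold from control cells
#'
#' The damage-positivity cutoff is the mean plus one standard deviation
#' (sample sd, n-1 denominator) of the control (vehicle-treated) cells' mean
#' nuclear intensities.
#'
#' @param control a tibble of nucleus records with a `mean_intensity` column
#'   (as from [measure_nuclei()]), or a bare numeric vector of intensities;
#'   at least 2 cells.
#' @return object of class `positivity_threshold` with `control_mean`,
#'   `control_sd`, `threshold`, `n_control`.
#' @export
derive_threshold <- function(control) {
  v <- if (is.data.frame(control)) control$mean_intensity else
    as.numeric(control)
  if (length(v) < 2) abort("need >= 2 control cells to derive a threshold.")
  m <- mean(v); s <- sd(v)
  structure(list(control_mean = m, control_sd = s, threshold = m + s,
                 n_control = length(v)),
            class = "positivity_threshold")
}

#' @export
print.positivity_threshold <- function(x, ...) {
  cat(sprintf(
    "positivity threshold %.3f (control mean %.3f + 1 sd %.3f, n = %d)\n",
    x$threshold, x$control_mean, x$control_sd, x$n_control))
  invisible(x)
}

#' Classify nuclei as damage-positive
#'
#' A cell is positive when its mean nuclear intensity is strictly higher
#' than the control-derived threshold.
#'
#' @param records tibble of nucleus records with `mean_intensity`.
#' @param threshold a [derive_threshold()] result.
#' @return list with `records` (input plus logical `positive` column) and
#'   `percent_positive`.
#' @export
classify_positive <- function(records, threshold) {
  stopifnot(inherits(threshold, "positivity_threshold"))
  records <- tibble::as_tibble(records)
  if (nrow(records) == 0) abort("no cells to classify.")
  records$positive <- records$mean_intensity > threshold$threshold
  list(records = records,
       percent_positive = 100 * mean(records$positive))
}

#' Detect damage foci per nucleus
#'
#' Local-maxima detection inside segmented nuclei. The channel is lightly
#' Gaussian-smoothed to stabilize maxima against pixel noise; a pixel is a
#' candidate peak when it attains the maximum of its `min_dist`-radius
#' neighbourhood, and a candidate is kept when it rises at least
#' `prominence` above its nucleus's local background (the median smoothed
#' intensity over the nucleus mask). Plateau peaks are collapsed to one
#' focus per connected component. Each focus is assigned to the nucleus
#' whose mask contains it; peak intensity is reported from the raw channel.
#'
#' @param channel 2-D numeric matrix (max-project stacks first with
#'   [max_project()]).
#' @param labels a `label_map` or integer matrix.
#' @param min_dist minimum peak separation in pixels.
#' @param smooth_sigma Gaussian pre-smoothing sd in pixels (0 disables).
#' @param prominence minimum height above local background; default
#'   3 x the robust (MAD-based) sd of the smoothed channel.
#' @return list with `per_nucleus` (tibble `label`, `foci_count`, one row
#'   per nucleus including zero-count ones) and `foci` (tibble `label`,
#'   `x`, `y`, `peak_intensity`, `area` — the plateau area proxy).
#' @export
detect_foci <- function(channel, labels, min_dist = 3, smooth_sigma = 1,
                        prominence = NULL) {
  lab <- if (inherits(labels, "label_map")) labels$labels else labels
  if (!all(dim(lab) == dim(channel))) {
    abort("label map and channel shapes differ.")
  }
  raw <- channel
  if (smooth_sigma > 0) {
    channel <- as.matrix(EBImage::gblur(EBImage::Image(channel),
                                        sigma = smooth_sigma))
  }
  n <- max(lab)
  empty <- list(per_nucleus = tibble::tibble(label = seq_len(n),
                                             foci_count = rep(0L, n)),
                foci = tibble::tibble(label = integer(0), x = numeric(0),
                                      y = numeric(0),
                                      peak_intensity = numeric(0),
                                      area = integer(0)))
  if (n == 0) return(empty)
  if (is.null(prominence)) prominence <- 3 * mad(channel)

  bg <- rep(NA_real_, n)
  fg <- lab > 0
  l <- factor(lab[fg], levels = seq_len(n))
  bg[] <- as.numeric(tapply(channel[fg], l, median))

  mx <- max_filter(channel, 2 * min_dist + 1)
  peak <- channel >= (mx - 1e-9) & fg
  peak <- peak & (channel > bg[ifelse(fg, lab, 1L)] + prominence)
  if (!any(peak)) return(empty)

  comp <- EBImage::bwlabel(EBImage::Image(peak))
  comp <- as.matrix(EBImage::imageData(comp))
  ids <- seq_len(max(comp))
  foci <- lapply(ids, function(i) {
    w <- which(comp == i, arr.ind = TRUE)
    cx <- mean(w[, 1]); cy <- mean(w[, 2])
    nuc <- lab[w[1, 1], w[1, 2]]
    tibble::tibble(label = nuc, x = cx, y = cy,
                   peak_intensity = max(raw[w]),
                   area = nrow(w))
  })
  foci <- dplyr::bind_rows(foci)
  counts <- tabulate(foci$label, nbins = n)
  list(per_nucleus = tibble::tibble(label = seq_len(n),
                                    foci_count = as.integer(counts)),
       foci = foci)
}

#' Maximum-intensity projection of a z-stack
#'
#' @param stack 3-D numeric array (x, y, z) with at least one plane, or a
#'   2-D matrix (returned unchanged).
#' @return 2-D matrix of per-pixel maxima across planes.
#' @export
max_project <- function(stack) {
  if (is.matrix(stack)) return(stack)
  if (!is.array(stack) || length(dim(stack)) != 3 || dim(stack)[3] < 1) {
    abort("`stack` must be a 2-D matrix or a 3-D array with >= 1 plane.")
  }
  apply(stack, c(1, 2), max)
}
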