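as_image_pair <- function(a, b, pixel_size) {
  stopifnot(all(dim(a) == dim(b)), pixel_size > 0)
  structure(list(a = a, b = b, pixel_size = pixel_size),
            class = "image_pair")
}

## centre-crop a matrix to the largest square
center_crop_square <- function(m) {
  n <- min(dim(m))
  r0 <- (nrow(m) - n) %/% 2
  c0 <- (ncol(m) - n) %/% 2
  m[r0 + seq_len(n), c0 + seq_len(n), drop = FALSE]
}

#' Pearson colocalization with saturation rescale
#'
#' Each channel is contrast-rescaled so that `saturation` percent of its
#' pixels clip (split equally between the low and high tails), linearly
#' mapped to `[0, 1]`; the colocalization is the Pearson correlation over
#' all pixels of the rescaled channels.
#'
#' @param pair An `image_pair` (or list with matrices `a`, `b`).
#' @param saturation Percentage of clipped pixels (default 0.35).
#' @return Pearson correlation coefficient.
#' @export
pearson_colocalization <- function(pair, saturation = 0.35) {
  rescale <- function(m) {
    f <- saturation / 100
    q <- quantile(m, c(f / 2, 1 - f / 2), names = FALSE)
    if (q[2] <= q[1]) stop("constant channel after rescale")
    pmin(pmax((m - q[1]) / (q[2] - q[1]), 0), 1)
  }
  a <- rescale(pair$a); b <- rescale(pair$b)
  if (sd(a) == 0 || sd(b) == 0) stop("constant channel after rescale")
  cor(as.vector(a), as.vector(b))
}

#' Biotinylation radius delta from mask areas
#'
#' Two readings of "RNA area subtracted from the biotinylation area,
#' divided by 2": the literal formula `(area_biotin - area_rna) / 2`
#' (area units), and the difference of circle-equivalent radii
#' `sqrt(area_biotin/pi) - sqrt(area_rna/pi)` (length units). Both are
#' returned; `mode` selects which is reported as `delta`.
#'
#' @param area_biotin,area_rna Mask areas (same units, e.g. px^2); must be
#'   non-negative.
#' @param mode `"literal"` or `"equivalent_radius"`.
#' @param pixel_size Optional um/px to convert the equivalent-radius value
#'   to micrometres (reported additionally as `delta_um`).
#' @return List `delta`, `literal`, `equivalent_radius` (and `delta_um`
#'   when `pixel_size` is given).
#' @export
radius_delta <- function(area_biotin, area_rna,
                         mode = c("literal", "equivalent_radius"),
                         pixel_size = NULL) {
  mode <- match.arg(mode)
  if (area_biotin < 0 || area_rna < 0) stop("negative area")
  lit <- (area_biotin - area_rna) / 2
  eqr <- sqrt(area_biotin / pi) - sqrt(area_rna / pi)
  out <- list(delta = if (mode == "literal") lit else eqr,
              literal = lit, equivalent_radius = eqr)
  if (!is.null(pixel_size)) out$delta_um <- eqr * pixel_size
  out
}

## fluctuation cross-correlation over all lattice displacements via FFT;
## non-periodic (zero-padded), each displacement normalized by its overlap
## count and by the product of channel means
cross_correlation_grid <- function(a, b) {
  n <- nrow(a)
  stopifnot(ncol(a) == n, all(dim(b) == dim(a)))
  da <- a - mean(a); db <- b - mean(b)
  m <- 2L * n
  pa <- matrix(0, m, m); pb <- matrix(0, m, m)
  pa[1:n, 1:n] <- da; pb[1:n, 1:n] <- db
  s <- Re(fft(Conj(fft(pa)) * fft(pb), inverse = TRUE)) / (m * m)
  shifts <- c(0:(n - 1), -(n:1) + 0)[1:m]  # index i -> displacement
  shift_of <- function(i) ifelse(i - 1 < n, i - 1, i - 1 - m)
  dx <- shift_of(row(s)); dy <- shift_of(col(s))
  valid <- abs(dx) < n & abs(dy) < n
  counts <- (n - abs(dx)) * (n - abs(dy))
  g <- matrix(NA_real_, m, m)
  g[valid] <- s[valid] / counts[valid] / (mean(a) * mean(b))
  list(g = g, dx = dx, dy = dy, valid = valid)
}

radial_average <- function(grid, pixel_size, max_d, bin_width) {
  d <- sqrt(grid$dx^2 + grid$dy^2) * pixel_size
  sel <- grid$valid & d <= max_d
  bin <- floor(d[sel] / bin_width)
  val <- tapply(grid$g[sel], bin, mean)
  data.frame(d = (as.numeric(names(val)) + 0.5) * bin_width,
             value = as.numeric(val))
}

#' Radially averaged spatial cross-correlation G(d)
#'
#' `G(delta) = <dA(r) dB(r + delta)> / (<A><B>)` over valid (non-periodic)
#' overlaps, computed for all lattice displacements by FFT and radially
#' averaged into bins of `bin_width` up to `max_d` (same length units as
#' `pixel_size`, micrometres for simulated pairs). Non-square images are
#' centre-cropped. `max_d` beyond half the image is truncated with a
#' warning.
#'
#' @param pair An `image_pair`.
#' @param max_d Largest displacement to report.
#' @param bin_width Radial bin width.
#' @return Object of class `radial_profile`: data.frame `d` (bin centres,
#'   strictly increasing) and `G`.
#' @export
cross_correlation_profile <- function(pair, max_d, bin_width) {
  a <- center_crop_square(pair$a); b <- center_crop_square(pair$b)
  px <- pair$pixel_size
  half <- nrow(a) / 2 * px
  if (max_d > half) {
    warning("max_d exceeds image half-size; truncated")
    max_d <- half
  }
  prof <- radial_average(cross_correlation_grid(a, b), px, max_d, bin_width)
  structure(data.frame(d = prof$d, G = prof$value),
            class = c("radial_profile", "data.frame"))
}

square_symmetries <- function(m) {
  n <- nrow(m)
  list(rot90 = t(m)[n:1, ],
       rot180 = m[n:1, n:1],
       rot270 = t(m)[, n:1],
       flip_v = m[n:1, ],
       flip_h = m[, n:1],
       transpose = t(m),
       anti_transpose = t(m)[n:1, n:1])
}

#' Symmetry-randomized null cross-correlation G_RAND(d)
#'
#' Applies the 7 non-identity symmetries of the square (rotations by 90,
#' 180, 270 degrees; horizontal, vertical and both diagonal reflections)
#' to channel B, computes [cross_correlation_profile()] for each, and
#' averages the 7 profiles pointwise.
#'
#' @inheritParams cross_correlation_profile
#' @return `radial_profile` data.frame `d`, `G_RAND`, with the 7 per-
#'   transform profiles in attribute `per_transform`.
#' @export
randomized_null_profile <- function(pair, max_d, bin_width) {
  a <- center_crop_square(pair$a); b <- center_crop_square(pair$b)
  if (nrow(pair$a) != ncol(pair$a)) stop("non-square image; crop upstream")
  profs <- lapply(square_symmetries(b), function(bt) {
    cross_correlation_profile(as_image_pair(a, bt, pair$pixel_size),
                              max_d, bin_width)
  })
  gmat <- vapply(profs, function(p) p$G, numeric(nrow(profs[[1]])))
  structure(data.frame(d = profs[[1]]$d, G_RAND = rowMeans(gmat),
                       check.names = FALSE),
            per_transform = gmat,
            class = c("radial_profile", "data.frame"))
}

#' Randomization-normalized colocalization measure C(d)
#'
#' `C(d)` is the ratio of the observed to the symmetry-randomized
#' cross-correlation. Profiles are compared in the offset fluctuation form
#' `G* = 1 + <dA dB>/(<A><B>)` (image-correlation-spectroscopy convention)
#' so the ratio is stable when raw correlations cross zero; for random
#' signals C converges to 1, and `C(d) > 1` indicates above-random
#' colocalization.
#'
#' @param g A [cross_correlation_profile()] result.
#' @param g_rand The matching [randomized_null_profile()] result.
#' @return `radial_profile` data.frame `d`, `G`, `G_RAND`, `C`.
#' @export
colocalization_measure <- function(g, g_rand) {
  stopifnot(nrow(g) == nrow(g_rand), all(abs(g$d - g_rand$d) < 1e-9))
  structure(data.frame(d = g$d, G = g$G, G_RAND = g_rand$G_RAND,
                       C = (1 + g$G) / (1 + g_rand$G_RAND)),
            class = c("radial_profile", "data.frame"))
}

#' Full C(d) computation for one image pair
#'
#' @inheritParams cross_correlation_profile
#' @return `radial_profile` with `d`, `G`, `G_RAND`, `C`.
#' @export
coloc_profile <- function(pair, max_d, bin_width) {
  colocalization_measure(cross_correlation_profile(pair, max_d, bin_width),
                         randomized_null_profile(pair, max_d, bin_width))
}

#' Per-condition colocalization statistics
#'
#' Summarizes C(d) profiles of several images of one condition: per-bin
#' median and 80% confidence band (10th-90th percentile across images;
#' suppressed with a warning below 3 images), and a one-sided test of the
#' hypothesis that the median of C in the first bin exceeds 1 (Wilcoxon
#' signed rank against the constant). Two conditions are compared with the
#' one-sided Mann-Whitney test via [scalar_group_test()].
#'
#' @param profiles List of [coloc_profile()] results (one per image).
#' @param reference Optional second condition (list of profiles); when
#'   given, the short-displacement C values of the two conditions are
#'   compared (`alternative = "greater"`: first condition higher).
#' @return List with `summary` (data.frame `d`, `median_C`, `lo80`,
#'   `hi80`), `c0` (per-image first-bin C), `test_above_1` (p-value),
#'   and optionally `test_vs_reference`.
#' @export
coloc_condition_stats <- function(profiles, reference = NULL) {
  cs <- vapply(profiles, function(p) p$C, numeric(nrow(profiles[[1]])))
  d <- profiles[[1]]$d
  if (length(profiles) < 3) {
    warning("fewer than 3 images; confidence bands suppressed")
    lo <- hi <- rep(NA_real_, length(d))
  } else {
    lo <- apply(cs, 1, quantile, 0.1)
    hi <- apply(cs, 1, quantile, 0.9)
  }
  c0 <- cs[1, ]
  test_above_1 <- suppressWarnings(
    wilcox.test(c0, mu = 1, alternative = "greater")$p.value)
  out <- list(summary = data.frame(d = d, median_C = apply(cs, 1, median),
                                   lo80 = lo, hi80 = hi),
              c0 = c0, test_above_1 = test_above_1)
  if (!is.null(reference)) {
    ref0 <- vapply(reference, function(p) p$C[1], numeric(1))
    out$test_vs_reference <-
      scalar_group_test(c0, ref0, alternative = "greater")$p_value
  }
  out
}
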