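#' Composite image container
#'
#' A thin wrapper around a 2-D non-negative intensity matrix plus the pixel
#' size needed to convert pixel coordinates to micrometres. Rows index y,
#' columns index x; the centre of pixel (i, j) sits at
#' x = (j - 0.5) * pixel_size, y = (i - 0.5) * pixel_size.
#'
#' @param intensity Numeric matrix of non-negative intensities.
#' @param pixel_size Pixel size in micrometres per pixel.
#' @return An object of class `"composite_image"`.
#' @export
composite_image <- function(intensity, pixel_size) {
  if (!is.matrix(intensity) || !is.numeric(intensity)) {
    rlang::abort("`intensity` must be a numeric matrix.")
  }
  if (any(intensity < 0, na.rm = TRUE)) {
    rlang::abort("composite intensities must be non-negative.")
  }
  stopifnot_scalar_number(pixel_size, "pixel_size", lower = 0, strict_lower = TRUE)
  structure(list(intensity = intensity, pixel_size = pixel_size),
            class = "composite_image")
}

#' @export
print.composite_image <- function(x, ...) {
  cat(sprintf("<composite_image> %d x %d px, pixel size %.4g um/px\n",
              nrow(x$intensity), ncol(x$intensity), x$pixel_size))
  invisible(x)
}

#' Sum a movie's frames into a composite image
#'
#' Pixelwise sum over all frames of a movie. Long-lived condensate foci
#' accumulate intensity in the sum while transient single molecules
#' average out, so the composite is the natural substrate for focus
#' detection.
#'
#' @param movie Either a list of equally sized numeric matrices or a 3-D
#'   numeric array with the frame index last.
#' @param pixel_size Pixel size in micrometres per pixel.
#' @return A [composite_image()].
#' @export
sum_frames <- function(movie, pixel_size = 1) {
  if (is.array(movie) && length(dim(movie)) == 3) {
    movie <- lapply(seq_len(dim(movie)[3]), function(i) movie[, , i])
  }
  if (!is.list(movie) || length(movie) == 0) {
    rlang::abort("`movie` must be a non-empty list of frames or a 3-D array.")
  }
  dims <- lapply(movie, dim)
  if (any(!vapply(movie, is.matrix, logical(1))) ||
      any(vapply(dims, function(d) !identical(d, dims[[1]]), logical(1)))) {
    rlang::abort("all frames must be matrices of identical dimensions.")
  }
  composite_image(Reduce(`+`, movie), pixel_size)
}

#' Render a composite image from localizations
#'
#' Bins localizations onto the pixel grid and blurs them with a Gaussian
#' point-spread function, emulating the frame-summed image of a movie whose
#' every detected molecule contributes one diffraction-limited spot.
#' Localizations outside the field are dropped.
#'
#' @param tracks Data frame with columns `x_um`, `y_um` (micrometres).
#' @param pixel_size Pixel size in micrometres per pixel.
#' @param field Field extents (width, height) in micrometres.
#' @param psf_sigma_px Gaussian PSF standard deviation in pixels.
#' @return A [composite_image()].
#' @export
render_composite <- function(tracks, pixel_size, field, psf_sigma_px = 1.2) {
  ncol_px <- ceiling(field[1] / pixel_size)
  nrow_px <- ceiling(field[2] / pixel_size)
  col <- floor(tracks$x_um / pixel_size) + 1L
  row <- floor(tracks$y_um / pixel_size) + 1L
  keep <- col >= 1L & col <= ncol_px & row >= 1L & row <= nrow_px
  img <- matrix(0, nrow = nrow_px, ncol = ncol_px)
  if (any(keep)) {
    idx <- (col[keep] - 1L) * nrow_px + row[keep]
    tab <- tabulate(idx, nbins = nrow_px * ncol_px)
    img[] <- tab
  }
  if (psf_sigma_px > 0) {
    kern <- gaussian_kernel(psf_sigma_px)
    img <- conv2_same(img, kern)
    img[img < 0] <- 0
  }
  composite_image(img, pixel_size)
}

gaussian_kernel <- function(sigma) {
  half <- ceiling(3 * sigma)
  ax <- (-half):half
  k1 <- exp(-ax^2 / (2 * sigma^2))
  k <- outer(k1, k1)
  k / sum(k)
}

log_kernel <- function(sigma) {
  half <- ceiling(4 * sigma)
  ax <- (-half):half
  xx <- outer(rep(1, length(ax)), ax^2) + outer(ax^2, rep(1, length(ax)))
  g <- exp(-xx / (2 * sigma^2))
  g <- g / sum(g)
  # Laplacian of Gaussian: (x^2 + y^2 - 2 sigma^2) / sigma^4 * G
  (xx - 2 * sigma^2) / sigma^4 * g
}

#' Detect condensate foci by multiscale Laplacian-of-Gaussian filtering
#'
#' Finds bright blobs in a composite image using the scale-normalized
#' Laplacian-of-Gaussian detector: the image is min-max normalized to
#' \[0, 1\], filtered with LoG kernels over a range of scales, and local
#' maxima of the (sign-flipped, sigma-squared-scaled) response exceeding
#' `threshold` are reported as foci. Overlapping detections are pruned,
#' keeping the stronger response. The blob radius is the conventional
#' sqrt(2) * sigma of the best-responding scale.
#'
#' @param image A [composite_image()].
#' @param min_sigma,max_sigma Scale range in pixels (defaults 3 and 5).
#' @param threshold Response threshold on the normalized image
#'   (default 0.1).
#' @param num_sigma Number of scales examined between `min_sigma` and
#'   `max_sigma`.
#' @param overlap Maximum allowed fractional overlap (of the smaller blob
#'   area) between two reported foci.
#' @return A tibble with one row per focus: `focus_id`, `row`, `col`
#'   (pixel indices), `x_um`, `y_um` (centroid), `sigma_px`, `radius_um`,
#'   `response`, and a `mask` list-column of covered pixels
#'   (data frames with `row`, `col`). Empty tibble if nothing is found.
#' @export
detect_foci <- function(image, min_sigma = 3, max_sigma = 5, threshold = 0.1,
                        num_sigma = 10, overlap = 0.5) {
  if (!inherits(image, "composite_image")) {
    rlang::abort("`image` must be a composite_image.")
  }
  img <- image$intensity
  rng <- range(img)
  empty <- tibble::tibble(
    focus_id = character(), row = integer(), col = integer(),
    x_um = numeric(), y_um = numeric(), sigma_px = numeric(),
    radius_um = numeric(), response = numeric(), mask = list()
  )
  if (diff(rng) == 0) return(empty)
  img <- (img - rng[1]) / diff(rng)

  sigmas <- seq(min_sigma, max_sigma, length.out = num_sigma)
  resp <- array(NA_real_, dim = c(nrow(img), ncol(img), num_sigma))
  for (i in seq_len(num_sigma)) {
    s <- sigmas[i]
    resp[, , i] <- -s^2 * conv2_same(img, log_kernel(s))
  }

  peaks <- local_maxima_3d(resp, threshold)
  if (nrow(peaks) == 0) return(empty)
  peaks$sigma <- sigmas[peaks$scale]
  peaks <- peaks[order(-peaks$value), , drop = FALSE]
  peaks <- prune_overlaps(peaks, overlap)

  ps <- image$pixel_size
  masks <- lapply(seq_len(nrow(peaks)), function(i) {
    disk_mask(peaks$row[i], peaks$col[i], sqrt(2) * peaks$sigma[i],
              nrow(img), ncol(img))
  })
  tibble::tibble(
    focus_id = paste0("focus_", seq_len(nrow(peaks))),
    row = peaks$row, col = peaks$col,
    x_um = (peaks$col - 0.5) * ps,
    y_um = (peaks$row - 0.5) * ps,
    sigma_px = peaks$sigma,
    radius_um = sqrt(2) * peaks$sigma * ps,
    response = peaks$value,
    mask = masks
  )
}

local_maxima_3d <- function(resp, threshold) {
  d <- dim(resp)
  cand <- which(resp > threshold, arr.ind = TRUE)
  if (nrow(cand) == 0) {
    return(data.frame(row = integer(), col = integer(),
                      scale = integer(), value = numeric()))
  }
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    r <- cand[i, 1]; c <- cand[i, 2]; s <- cand[i, 3]
    v <- resp[r, c, s]
    nb <- resp[max(1, r - 1):min(d[1], r + 1),
               max(1, c - 1):min(d[2], c + 1),
               max(1, s - 1):min(d[3], s + 1)]
    keep[i] <- v >= max(nb)
  }
  cand <- cand[keep, , drop = FALSE]
  out <- data.frame(row = cand[, 1], col = cand[, 2], scale = cand[, 3],
                    value = resp[cand])
  # collapse exact ties at adjacent positions by keeping unique (row,col)
  out[!duplicated(out[, c("row", "col")]), , drop = FALSE]
}

prune_overlaps <- function(peaks, overlap) {
  if (nrow(peaks) <= 1) return(peaks)
  keep <- rep(TRUE, nrow(peaks))
  for (i in seq_len(nrow(peaks) - 1)) {
    if (!keep[i]) next
    for (j in (i + 1):nrow(peaks)) {
      if (!keep[j]) next
      d <- sqrt((peaks$row[i] - peaks$row[j])^2 + (peaks$col[i] - peaks$col[j])^2)
      ri <- sqrt(2) * peaks$sigma[i]; rj <- sqrt(2) * peaks$sigma[j]
      if (d >= ri + rj) next
      if (circle_overlap_frac(d, ri, rj) > overlap) keep[j] <- FALSE
    }
  }
  peaks[keep, , drop = FALSE]
}

# fraction of the smaller circle's area shared with the larger
circle_overlap_frac <- function(d, r1, r2) {
  rs <- min(r1, r2); rl <- max(r1, r2)
  if (d <= rl - rs) return(1)
  if (d >= r1 + r2) return(0)
  a1 <- rs^2 * acos(pmin(pmax((d^2 + rs^2 - rl^2) / (2 * d * rs), -1), 1))
  a2 <- rl^2 * acos(pmin(pmax((d^2 + rl^2 - rs^2) / (2 * d * rl), -1), 1))
  a3 <- 0.5 * sqrt(pmax((-d + rs + rl) * (d + rs - rl) * (d - rs + rl) * (d + rs + rl), 0))
  (a1 + a2 - a3) / (pi * rs^2)
}

disk_mask <- function(row0, col0, radius_px, nrow_px, ncol_px) {
  half <- ceiling(radius_px)
  rows <- max(1, row0 - half):min(nrow_px, row0 + half)
  cols <- max(1, col0 - half):min(ncol_px, col0 + half)
  grid <- expand.grid(row = rows, col = cols)
  inside <- (grid$row - row0)^2 + (grid$col - col0)^2 <= radius_px^2
  grid[inside, , drop = FALSE]
}
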