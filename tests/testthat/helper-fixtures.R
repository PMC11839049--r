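# Small fixture builders shared across test files. Everything is built in
# code; no stored data.

# a trajectory laid out explicitly, one row per frame
make_track <- function(id, x, y, frames = seq_along(x)) {
  tibble::tibble(trajectory_id = id, frame = as.integer(frames),
                 x_um = x, y_um = y)
}

# n_frames localizations at a fixed point (useful for focus support)
make_static_track <- function(id, x, y, n_frames = 10) {
  make_track(id, rep(x, n_frames), rep(y, n_frames))
}

# a single circular focus by hand, bypassing detection
make_focus <- function(x, y, radius, id = "focus_1") {
  tibble::tibble(
    focus_id = id, row = NA_integer_, col = NA_integer_,
    x_um = x, y_um = y, sigma_px = radius / sqrt(2),
    radius_um = radius, response = 1,
    mask = list(data.frame(row = integer(), col = integer()))
  )
}

# an image with one or more Gaussian blobs on a quiet background
make_blob_image <- function(dim_px = 64, centers, sigma_px = 4, amplitude = 1,
                            pixel_size = 1) {
  img <- matrix(0, dim_px, dim_px)
  for (i in seq_len(nrow(centers))) {
    rr <- outer((seq_len(dim_px) - centers[i, 1])^2,
                (seq_len(dim_px) - centers[i, 2])^2, "+")
    img <- img + amplitude * exp(-rr / (2 * sigma_px^2))
  }
  composite_image(img, pixel_size)
}

# toy count matrix with spike-ins as a feature-column tibble
make_toy_counts <- function(genomic, ercc, samples = paste0("s", seq_len(ncol(genomic)))) {
  m <- rbind(genomic, ercc)
  tibble::as_tibble(cbind(
    tibble::tibble(feature = rownames(m)),
    stats::setNames(as.data.frame(m), samples)
  ))
}

# direct-summation ZINB log-likelihood, coded independently of the package
# fitting routine: the oracle for likelihood agreement
oracle_zinb_loglik <- function(k, mu, theta, pi) {
  p <- numeric(length(k))
  for (i in seq_along(k)) {
    nb <- dnbinom(k[i], size = theta, mu = mu[i])
    p[i] <- if (k[i] == 0) pi + (1 - pi) * nb else (1 - pi) * nb
  }
  sum(log(p))
}
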