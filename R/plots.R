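# ggplot2 displays for the main result types.

#' @export
autoplot.diffusion_fit <- function(object, r2 = NULL, ...) {
  if (is.null(r2)) {
    r2 <- seq(0, stats::qexp(0.999, 1 / ((8 / 3) * max(object$D) * object$tau)),
              length.out = 400)
  }
  r2 <- sort(r2)
  dat <- tibble::tibble(r2 = r2, cdf = predict_cdf(object, r2))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$r2, y = .data$cdf)) +
    ggplot2::geom_line(colour = "firebrick") +
    ggplot2::labs(
      x = expression(r^2 ~ (mu * m^2)),
      y = expression(P(r^2, tau)),
      title = sprintf("%d-state squared-displacement CDF fit", object$n_states),
      subtitle = paste0(
        "D = ", paste(signif(object$D, 3), collapse = ", "),
        " μm²/s;  α = ",
        paste(signif(object$alpha, 3), collapse = ", ")
      )
    ) +
    ggplot2::theme_minimal()
}

#' Empirical vs fitted squared-displacement CDF
#'
#' @param pool Pool from [pool_squared_displacements()] (or numeric r2).
#' @param fit A `"diffusion_fit"`.
#' @param n_points Number of empirical quantile points displayed.
#' @return A ggplot.
#' @export
plot_displacement_cdf <- function(pool, fit, n_points = 400) {
  r2 <- if (is.numeric(pool)) pool else pool$r2
  r2s <- sort(r2)
  idx <- unique(round(seq(1, length(r2s), length.out = n_points)))
  emp <- tibble::tibble(r2 = r2s[idx], cdf = idx / length(r2s))
  autoplot(fit, r2 = r2s[idx]) +
    ggplot2::geom_point(data = emp, size = 0.6, alpha = 0.6,
                        colour = "grey30")
}

#' Composite image with detected foci
#'
#' @param image A [composite_image()].
#' @param foci Optional focus tibble; circles are drawn at their radii.
#' @return A ggplot.
#' @export
plot_composite <- function(image, foci = NULL) {
  img <- image$intensity
  ps <- image$pixel_size
  dat <- tidyr::expand_grid(row = seq_len(nrow(img)), col = seq_len(ncol(img)))
  dat$intensity <- img[cbind(dat$row, dat$col)]
  dat$x <- (dat$col - 0.5) * ps
  dat$y <- (dat$row - 0.5) * ps
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$x, y = .data$y,
                                         fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (μm)", y = "y (μm)") +
    ggplot2::theme_minimal()
  if (!is.null(foci) && nrow(foci) > 0) {
    ang <- seq(0, 2 * pi, length.out = 90)
    circ <- dplyr::bind_rows(lapply(seq_len(nrow(foci)), function(i) {
      tibble::tibble(focus_id = foci$focus_id[i],
                     x = foci$x_um[i] + foci$radius_um[i] * cos(ang),
                     y = foci$y_um[i] + foci$radius_um[i] * sin(ang))
    }))
    p <- p + ggplot2::geom_path(
      data = circ,
      ggplot2::aes(x = .data$x, y = .data$y, group = .data$focus_id),
      inherit.aes = FALSE, colour = "white", linewidth = 0.4
    )
  }
  p
}

#' @export
autoplot.frap_fit <- function(object, time = NULL, intensity = NULL, ...) {
  if (!object$converged) rlang::abort("cannot plot an unconverged FRAP fit.")
  tmax <- if (is.null(time)) 5 * log(2) / object$k else max(time)
  tt <- seq(0, tmax, length.out = 200)
  curve <- tibble::tibble(
    t = tt,
    y = object$y0 + (object$plateau - object$y0) * (1 - exp(-object$k * tt))
  )
  p <- ggplot2::ggplot(curve, ggplot2::aes(x = .data$t, y = .data$y)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "time after bleach (s)", y = "normalized intensity",
                  subtitle = sprintf("t½ = %.2f s", object$t_half)) +
    ggplot2::theme_minimal()
  if (!is.null(time)) {
    p <- p + ggplot2::geom_point(
      data = tibble::tibble(t = time, y = intensity),
      colour = "grey30"
    )
  }
  p
}

#' Decay curve of one gene with its exponential fit
#'
#' @param normalized Output of [normalize_with_spikeins()].
#' @param samples Sample sheet.
#' @param gene Gene id.
#' @param fit Optional one-row fit (from [fit_decay_curves()]).
#' @return A ggplot.
#' @export
plot_decay_curve <- function(normalized, samples, gene, fit = NULL) {
  dat <- normalized |>
    dplyr::filter(.data$feature == gene) |>
    tidyr::pivot_longer(-"feature", names_to = "sample",
                        values_to = "abundance") |>
    dplyr::inner_join(samples, by = "sample")
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$timepoint_min,
                                         y = .data$abundance)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "time after rifampicin (min)",
                  y = "normalized abundance", title = gene) +
    ggplot2::theme_minimal()
  if (!is.null(fit) && nrow(fit) == 1 && isTRUE(fit$converged)) {
    tt <- seq(0, max(dat$timepoint_min), length.out = 100)
    p <- p + ggplot2::geom_line(
      data = tibble::tibble(timepoint_min = tt,
                            abundance = fit$a * exp(-tt / fit$b)),
      colour = "firebrick"
    )
  }
  p
}

#' Volcano-style display of poly(A) tail shifts
#'
#' @param shifts The `shifts` tibble from [summarize_tail_shifts()].
#' @param fdr Highlighting threshold on the adjusted p-value.
#' @return A ggplot.
#' @export
plot_tail_shift_volcano <- function(shifts, fdr = 0.05) {
  dat <- dplyr::filter(shifts, is.finite(.data$p_adj))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$delta,
                                    y = -log10(.data$p_adj),
                                    colour = .data$p_adj < fdr)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::facet_wrap(~condition) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick"),
                                 name = sprintf("FDR < %g", fdr)) +
    ggplot2::labs(x = "Δ mean tail length (mutant - reference)",
                  y = expression(-log[10] ~ "adjusted p")) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.overlap_permutation <- function(object, ...) {
  null_long <- tibble::as_tibble(object$null) |>
    tidyr::pivot_longer(dplyr::everything(), names_to = "statistic",
                        values_to = "overlap")
  obs <- tibble::tibble(statistic = names(object$observed),
                        overlap = unname(object$observed))
  ggplot2::ggplot(null_long, ggplot2::aes(x = .data$overlap)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70") +
    ggplot2::geom_vline(data = obs,
                        ggplot2::aes(xintercept = .data$overlap),
                        colour = "firebrick") +
    ggplot2::facet_wrap(~statistic, scales = "free") +
    ggplot2::labs(x = "term-set overlap", y = "permutations") +
    ggplot2::theme_minimal()
}
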