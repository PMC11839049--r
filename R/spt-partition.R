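#' Test localizations against focus regions
#'
#' @param x,y Coordinates in micrometres.
#' @param foci Focus tibble from [detect_foci()].
#' @return Logical vector: is each point inside at least one focus?
#' @export
in_any_focus <- function(x, y, foci) {
  inside <- rep(FALSE, length(x))
  if (nrow(foci) == 0) return(inside)
  for (i in seq_len(nrow(foci))) {
    inside <- inside |
      ((x - foci$x_um[i])^2 + (y - foci$y_um[i])^2 <= foci$radius_um[i]^2)
  }
  inside
}

#' Filter candidate foci by trajectory support
#'
#' A detected focus is kept only if it is supported by at least
#' `min_trajs` trajectories of at least `min_len` frames each, where at
#' least `min_overlap` of the trajectory's localizations fall inside the
#' focus. This removes transient intensity fluctuations that are not
#' stable condensates. All thresholds are boundary-inclusive.
#'
#' @param foci Focus tibble from [detect_foci()].
#' @param tracks Data frame with `trajectory_id`, `frame`, `x_um`, `y_um`.
#' @param min_trajs Minimum number of qualifying trajectories (default 10).
#' @param min_len Minimum trajectory length in frames (default 10).
#' @param min_overlap Minimum fraction of a trajectory's localizations
#'   inside the focus for it to count (default 0.7).
#' @return The subset of `foci` that passes, with an extra
#'   `n_supporting_trajs` column.
#' @export
filter_foci <- function(foci, tracks, min_trajs = 10, min_len = 10,
                        min_overlap = 0.7) {
  if (nrow(foci) == 0 || nrow(tracks) == 0) {
    return(dplyr::mutate(foci[0, ], n_supporting_trajs = integer()))
  }
  lens <- dplyr::count(tracks, .data$trajectory_id, name = "n_frames")
  long_ids <- lens$trajectory_id[lens$n_frames >= min_len]
  sub <- tracks[tracks$trajectory_id %in% long_ids, , drop = FALSE]
  n_support <- integer(nrow(foci))
  if (nrow(sub) > 0) {
    for (i in seq_len(nrow(foci))) {
      inside <- (sub$x_um - foci$x_um[i])^2 + (sub$y_um - foci$y_um[i])^2 <=
        foci$radius_um[i]^2
      frac <- tapply(inside, sub$trajectory_id, mean)
      n_support[i] <- sum(frac >= min_overlap)
    }
  }
  out <- foci[n_support >= min_trajs, , drop = FALSE]
  out$n_supporting_trajs <- n_support[n_support >= min_trajs]
  out
}

#' Classify trajectories by overlap with condensate foci
#'
#' Each trajectory's overlap fraction is the fraction of its localizations
#' that fall inside any (filtered) focus. Labels follow the standard
#' scheme: `In` for complete overlap over the whole duration, `In/out`
#' for overlap between 25% (inclusive) and complete, and `Out` below 25%.
#'
#' @param tracks Data frame with `trajectory_id`, `frame`, `x_um`, `y_um`.
#' @param foci Filtered focus tibble.
#' @return Tibble with `trajectory_id`, `n_frames`, `overlap_fraction`,
#'   `label`.
#' @export
classify_trajectories <- function(tracks, foci) {
  if (nrow(tracks) == 0) rlang::abort("`tracks` is empty.")
  inside <- in_any_focus(tracks$x_um, tracks$y_um, foci)
  tracks |>
    dplyr::mutate(.inside = inside) |>
    dplyr::summarise(
      n_frames = dplyr::n(),
      overlap_fraction = mean(.data$.inside),
      .by = "trajectory_id"
    ) |>
    dplyr::mutate(
      label = dplyr::case_when(
        .data$overlap_fraction >= 1 ~ "In",
        .data$overlap_fraction >= 0.25 ~ "In/out",
        TRUE ~ "Out"
      )
    )
}

#' Pool squared displacements across trajectories
#'
#' Computes the per-step squared displacement r2 between localizations in
#' consecutive frames, pooling across all trajectories of at least
#' `min_len` frames. Pairs spanning missing frames are excluded.
#'
#' @param tracks Data frame with `trajectory_id`, `frame`, `x_um`, `y_um`.
#' @param frame_interval Lag time tau between frames, in seconds.
#' @param min_len Minimum trajectory length in frames (default 4).
#' @return A tibble with columns `trajectory_id`, `frame` (the earlier
#'   frame of each pair) and `r2` (micrometres squared), carrying the lag
#'   as attribute `tau`.
#' @export
pool_squared_displacements <- function(tracks, frame_interval, min_len = 4) {
  stopifnot_scalar_number(frame_interval, "frame_interval", lower = 0,
                          strict_lower = TRUE)
  pool <- tracks |>
    dplyr::arrange(.data$trajectory_id, .data$frame) |>
    dplyr::mutate(n_frames = dplyr::n(), .by = "trajectory_id") |>
    dplyr::filter(.data$n_frames >= min_len) |>
    dplyr::mutate(
      dx = dplyr::lead(.data$x_um) - .data$x_um,
      dy = dplyr::lead(.data$y_um) - .data$y_um,
      dframe = dplyr::lead(.data$frame) - .data$frame,
      .by = "trajectory_id"
    ) |>
    dplyr::filter(!is.na(.data$dframe), .data$dframe == 1L) |>
    dplyr::transmute(.data$trajectory_id, .data$frame,
                     r2 = .data$dx^2 + .data$dy^2)
  attr(pool, "tau") <- frame_interval
  pool
}

#' Fit a multi-state model to the squared-displacement CDF
#'
#' Fits the mixture-of-diffusive-states model
#' \deqn{P(r^2, \tau) = 1 - \sum_i \alpha_i \exp\!\big(-r^2 / (\tfrac{8}{3} D_i \tau)\big)}
#' to the empirical cumulative distribution of pooled squared
#' displacements, with the weights constrained to the simplex. The 8/3
#' factor is the motion-blur-corrected per-step mean-squared displacement
#' for full-frame exposure. The objective is the sum of squared deviations
#' between the empirical and model CDF evaluated at the sorted unique r2
#' values, minimized by Levenberg-Marquardt from multiple deterministic
#' starts; label switching is resolved by sorting the diffusion
#' coefficients ascending.
#'
#' @param pool A tibble from [pool_squared_displacements()] or a bare
#'   numeric vector of squared displacements (micrometres squared).
#' @param n_states Number of diffusive states, 2 or 3.
#' @param tau Lag time in seconds; defaults to the pool's `tau` attribute.
#' @param n_starts Number of deterministic multistart initializations.
#' @return An object of class `"diffusion_fit"`: a list with `n_states`,
#'   `D` (ascending, um^2/s), `alpha` (weights summing to 1), `objective`,
#'   `converged`, `n`, `tau`.
#' @export
fit_displacement_cdf <- function(pool, n_states = 3, tau = NULL, n_starts = 8) {
  r2 <- if (is.numeric(pool)) pool else pool$r2
  tau <- tau %||% attr(pool, "tau")
  if (is.null(tau)) rlang::abort("`tau` must be supplied (or carried by the pool).")
  if (!n_states %in% c(2, 3)) rlang::abort("`n_states` must be 2 or 3.")
  r2 <- r2[!is.na(r2)]
  if (length(r2) == 0) rlang::abort("empty displacement pool.")
  if (sd(r2) == 0) rlang::abort("no displacement signal: all squared displacements identical.")

  u <- sort(unique(r2))
  Fhat <- cumsum(tabulate(match(sort(r2), u), nbins = length(u))) / length(r2)

  k <- n_states
  model_cdf <- function(par, x) {
    th <- decode_par(par, k)
    1 - colSums(th$alpha * exp(-outer(1 / ((8 / 3) * th$D * tau), x)))
  }
  resid_fun <- function(par) model_cdf(par, u) - Fhat

  # deterministic starts from quantiles of the implied D = r2 / ((8/3) tau)
  d_imp <- pmax(u / ((8 / 3) * tau), .Machine$double.eps)
  probs <- list(
    c(0.2, 0.5, 0.8), c(0.1, 0.5, 0.9), c(0.05, 0.4, 0.95),
    c(0.3, 0.6, 0.9), c(0.02, 0.2, 0.7), c(0.25, 0.5, 0.75),
    c(0.1, 0.3, 0.6), c(0.4, 0.7, 0.95)
  )
  starts <- lapply(probs[seq_len(max(n_starts, 2))], function(p) {
    Dq <- quantile(d_imp, if (k == 2) p[c(1, 3)] else p, names = FALSE)
    c(log(Dq), rep(0, k - 1))  # equal stick-breaking weights
  })

  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st, fn = resid_fun,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    ssq <- sum(resid_fun(fit$par)^2)
    if (is.null(best) || ssq < best$ssq) {
      best <- list(par = fit$par, ssq = ssq, info = fit$info)
    }
  }
  if (is.null(best)) rlang::abort("displacement CDF fit failed from every start.")

  th <- decode_par(best$par, k)
  ord <- order(th$D)
  structure(
    list(
      n_states = k,
      D = th$D[ord],
      alpha = th$alpha[ord],
      objective = best$ssq,
      converged = best$info %in% 1:3,
      n = length(r2),
      tau = tau
    ),
    class = "diffusion_fit"
  )
}

# parameters: k log-diffusion-coefficients then k-1 stick-breaking logits
decode_par <- function(par, k) {
  D <- exp(par[seq_len(k)])
  u <- stats::plogis(par[k + seq_len(k - 1)])
  alpha <- numeric(k)
  remaining <- 1
  for (i in seq_len(k - 1)) {
    alpha[i] <- remaining * u[i]
    remaining <- remaining - alpha[i]
  }
  alpha[k] <- remaining
  list(D = D, alpha = alpha)
}

#' Evaluate the fitted multi-state CDF
#'
#' @param object A `"diffusion_fit"`.
#' @param r2 Squared displacements (micrometres squared).
#' @return Model CDF values.
#' @export
predict_cdf <- function(object, r2) {
  1 - colSums(object$alpha * exp(-outer(1 / ((8 / 3) * object$D * object$tau), r2)))
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat(sprintf("<diffusion_fit> %d states, n = %d steps, tau = %g s\n",
              x$n_states, x$n, x$tau))
  cat("  D     (um^2/s):", paste(signif(x$D, 4), collapse = ", "), "\n")
  cat("  alpha         :", paste(signif(x$alpha, 4), collapse = ", "), "\n")
  cat(sprintf("  objective %.4g, converged: %s\n", x$objective, x$converged))
  invisible(x)
}

#' Combine diffusion fits and trajectory classes into partition fractions
#'
#' The freely diffusing fraction is the weight of the fastest state of the
#' full-dataset three-state fit (its D is expected to exceed 1 um^2/s; a
#' warning is raised otherwise). The condensate fraction scales the
#' non-free weight of a three-state fit restricted to the In and In/out
#' trajectories by those trajectories' share of pooled displacement steps:
#' \deqn{F_{condensate} = \frac{N_{In} + N_{In/out}}{N_{total}} (\alpha_1 + \alpha_2)}
#' The nucleoid-only fraction is defined by subtraction,
#' F_nucleoid = 1 - F_free - F_condensate, and is reported (with a flag)
#' even if negative.
#'
#' @param full_fit Three-state [fit_displacement_cdf()] on all
#'   trajectories.
#' @param subset_fit Three-state fit on the In + In/out subset, or `NULL`
#'   when that subset is empty (condensate fraction 0).
#' @param classes Classification tibble from [classify_trajectories()].
#' @param tracks The trajectory table used for the fits.
#' @param min_len Minimum trajectory length used when pooling steps
#'   (default 4, matching the displacement pooling).
#' @return A one-row tibble: `F_condensate`, `F_nucleoid`, `F_free`,
#'   `N_in`, `N_inout`, `N_total_steps`, `d_free_ok` (fastest D > 1
#'   um^2/s), `nucleoid_negative` flag.
#' @export
compute_partition_fractions <- function(full_fit, subset_fit, classes, tracks,
                                        min_len = 4) {
  step_count <- function(ids) {
    if (length(ids) == 0) return(0L)
    sub <- tracks[tracks$trajectory_id %in% ids, , drop = FALSE]
    pool <- pool_squared_displacements(sub, frame_interval = full_fit$tau,
                                       min_len = min_len)
    nrow(pool)
  }
  n_in <- step_count(classes$trajectory_id[classes$label == "In"])
  n_inout <- step_count(classes$trajectory_id[classes$label == "In/out"])
  n_out <- step_count(classes$trajectory_id[classes$label == "Out"])
  n_total <- n_in + n_inout + n_out
  if (n_total == 0) rlang::abort("no pooled displacement steps: N_total is zero.")

  f_free <- full_fit$alpha[full_fit$n_states]
  d_free_ok <- full_fit$D[full_fit$n_states] > 1
  if (!d_free_ok) {
    rlang::warn(sprintf(
      "fastest-state D = %.3g um^2/s is not > 1 um^2/s; its weight may not represent freely diffusing molecules.",
      full_fit$D[full_fit$n_states]
    ))
  }
  f_cond <- if (is.null(subset_fit) || (n_in + n_inout) == 0) {
    0
  } else {
    ((n_in + n_inout) / n_total) *
      sum(subset_fit$alpha[-subset_fit$n_states])
  }
  f_nuc <- 1 - f_free - f_cond
  if (f_nuc < 0) {
    rlang::warn("F_nucleoid is negative; reported unclamped with a flag.")
  }
  tibble::tibble(
    F_condensate = f_cond, F_nucleoid = f_nuc, F_free = f_free,
    N_in = n_in, N_inout = n_inout, N_total_steps = n_total,
    d_free_ok = d_free_ok, nucleoid_negative = f_nuc < 0
  )
}

#' Full condensate-partition pipeline
#'
#' Runs detection, filtering, classification, displacement pooling, the
#' two three-state CDF fits and the partition-fraction computation in one
#' call: the end-to-end analysis of one imaging replicate.
#'
#' @param tracks Trajectory table (`trajectory_id`, `frame`, `x_um`,
#'   `y_um`).
#' @param frame_interval Frame interval tau in seconds.
#' @param pixel_size Pixel size in micrometres per pixel.
#' @param image Optional [composite_image()]; if `NULL`, one is rendered
#'   from the localizations over `field`.
#' @param field Field extents in micrometres (needed only when rendering).
#' @param min_sigma,max_sigma,log_threshold Focus-detection parameters.
#' @param min_trajs,min_len_filter,min_overlap Focus-filtering parameters.
#' @param min_len Minimum trajectory length for displacement pooling.
#' @param n_starts Multistart count for the CDF fits.
#' @return A list with `foci`, `classes`, `full_fit`, `subset_fit`,
#'   `fractions`.
#' @export
spt_partition <- function(tracks, frame_interval, pixel_size,
                          image = NULL, field = NULL,
                          min_sigma = 3, max_sigma = 5, log_threshold = 0.1,
                          min_trajs = 10, min_len_filter = 10,
                          min_overlap = 0.7, min_len = 4, n_starts = 8) {
  if (is.null(image)) {
    if (is.null(field)) {
      field <- c(max(tracks$x_um), max(tracks$y_um))
    }
    image <- render_composite(tracks, pixel_size, field)
  }
  foci <- detect_foci(image, min_sigma = min_sigma, max_sigma = max_sigma,
                      threshold = log_threshold)
  foci <- filter_foci(foci, tracks, min_trajs = min_trajs,
                      min_len = min_len_filter, min_overlap = min_overlap)
  classes <- classify_trajectories(tracks, foci)
  pool_all <- pool_squared_displacements(tracks, frame_interval, min_len = min_len)
  full_fit <- fit_displacement_cdf(pool_all, n_states = 3, n_starts = n_starts)
  sub_ids <- classes$trajectory_id[classes$label %in% c("In", "In/out")]
  subset_fit <- NULL
  if (length(sub_ids) > 0) {
    pool_sub <- pool_squared_displacements(
      tracks[tracks$trajectory_id %in% sub_ids, , drop = FALSE],
      frame_interval, min_len = min_len
    )
    if (nrow(pool_sub) > 0 && sd(pool_sub$r2) > 0) {
      subset_fit <- fit_displacement_cdf(pool_sub, n_states = 3,
                                         n_starts = n_starts)
    }
  }
  fractions <- compute_partition_fractions(full_fit, subset_fit, classes,
                                           tracks, min_len = min_len)
  list(foci = foci, classes = classes, full_fit = full_fit,
       subset_fit = subset_fit, fractions = fractions)
}

#' Fit a one-phase association curve to FRAP recovery data
#'
#' Fits y(t) = y0 + (plateau - y0) * (1 - exp(-k t)) to post-bleach
#' fluorescence intensities and reports the recovery half-time
#' t_half = ln(2) / k with a residual-bootstrap confidence interval.
#'
#' @param time Post-bleach times in seconds (>= 4 points).
#' @param intensity Fluorescence normalized to the pre-bleach mean.
#' @param n_boot Bootstrap replicates for the confidence interval
#'   (default 200; 0 disables it).
#' @param conf_level Confidence level (default 0.95).
#' @param seed Seed for the bootstrap resampling.
#' @return An object of class `"frap_fit"`: `y0`, `plateau`, `k`,
#'   `t_half`, `t_half_ci`, `converged`.
#' @export
fit_frap_recovery <- function(time, intensity, n_boot = 200,
                              conf_level = 0.95, seed = 1) {
  if (length(time) != length(intensity)) {
    rlang::abort("`time` and `intensity` must have equal length.")
  }
  if (length(time) < 4) rlang::abort("need at least 4 post-bleach points.")
  dat <- data.frame(t = time, y = intensity)
  fit1 <- fit_one_phase(dat)
  if (is.null(fit1) || fit1$k <= 0) {
    return(structure(
      list(y0 = NA_real_, plateau = NA_real_, k = NA_real_,
           t_half = NA_real_, t_half_ci = c(NA_real_, NA_real_),
           converged = FALSE),
      class = "frap_fit"
    ))
  }
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    res <- dat$y - with(fit1, y0 + (plateau - y0) * (1 - exp(-k * dat$t)))
    th <- with_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        yb <- dat$y - res + sample(res, replace = TRUE)
        fb <- fit_one_phase(data.frame(t = dat$t, y = yb))
        if (is.null(fb) || fb$k <= 0) NA_real_ else log(2) / fb$k
      }, numeric(1))
    })
    th <- th[is.finite(th)]
    if (length(th) >= 20) {
      a <- (1 - conf_level) / 2
      ci <- unname(quantile(th, c(a, 1 - a)))
    }
  }
  structure(
    list(y0 = fit1$y0, plateau = fit1$plateau, k = fit1$k,
         t_half = log(2) / fit1$k, t_half_ci = ci, converged = TRUE),
    class = "frap_fit"
  )
}

fit_one_phase <- function(dat) {
  y0_0 <- dat$y[which.min(dat$t)]
  pl_0 <- mean(dat$y[dat$t >= quantile(dat$t, 0.75)])
  if (pl_0 <= y0_0) pl_0 <- y0_0 + max(diff(range(dat$y)), 1e-3)
  k_0 <- log(2) / max(diff(range(dat$t)) / 4, 1e-6)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ y0 + (plateau - y0) * (1 - exp(-k * t)),
      data = dat,
      start = list(y0 = y0_0, plateau = pl_0, k = k_0),
      lower = c(-Inf, -Inf, 1e-9),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) return(NULL)
  cf <- coef(fit)
  # a flat or decreasing signal degenerates to plateau <= y0: flag it
  if (cf[["plateau"]] <= cf[["y0"]] + 1e-9) return(NULL)
  list(y0 = cf[["y0"]], plateau = cf[["plateau"]], k = cf[["k"]])
}

#' @export
print.frap_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<frap_fit> convergence failure (no recovery signal)\n")
    return(invisible(x))
  }
  cat(sprintf("<frap_fit> k = %.4g /s, t_half = %.3g s (%.3g-%.3g), y0 = %.3g, plateau = %.3g\n",
              x$k, x$t_half, x$t_half_ci[1], x$t_half_ci[2], x$y0, x$plateau))
  invisible(x)
}
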