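#' Configuration for the single-particle-tracking simulator
#'
#' Describes a population of molecules diffusing in a cell-sized field with
#' (optionally) one condensate. Each trajectory carries a single latent
#' diffusive state for its whole life; states are indexed from slowest to
#' fastest. When a condensate is present, molecules in the slowest state
#' start inside it and remain confined to it, while molecules in all other
#' states are excluded from it. This is the population-level mixture that
#' the squared-displacement CDF model assumes: no within-track state
#' switching.
#'
#' @param n_trajectories Number of trajectories to simulate.
#' @param frame_interval Time between frames in seconds (default 0.02 s,
#'   i.e. 50 Hz acquisition).
#' @param pixel_size Camera pixel size in micrometres per pixel; used when
#'   rendering composite images, not during trajectory generation.
#' @param field Numeric length-2, the field of view (width, height) in
#'   micrometres. Start positions are drawn uniformly inside it.
#' @param condensate Either `NULL` (no condensate; all states diffuse
#'   freely) or a list with elements `center` (length-2, micrometres) and
#'   `radius` (micrometres).
#' @param D Diffusion coefficients, one per state, strictly increasing,
#'   in micrometres squared per second.
#' @param weights State weights (probabilities summing to 1), same length
#'   as `D`.
#' @param mean_track_frames Mean trajectory length in frames; lengths are
#'   drawn as 1 + Geometric so the mean is this value (default 10, the
#'   typical median track length for this kind of data).
#' @param localization_noise Standard deviation of Gaussian localization
#'   error added to every coordinate, in micrometres (default 0).
#' @param mode Displacement mode. `"model_exact"` draws each per-step
#'   squared displacement r-squared directly from the exponential law
#'   P(r2 <= x) = 1 - exp(-x / ((8/3) D tau)), the law the CDF fit assumes.
#'   `"physical_blur"` integrates a fine-grained Brownian path and reports
#'   exposure-averaged positions (exposure = frame interval), whose
#'   displacement law converges to the same CDF and demonstrates where the
#'   8/3 motion-blur factor comes from.
#' @param n_substeps Sub-frame integration steps for `"physical_blur"`.
#' @param seed Integer seed; mandatory. Output is byte-identical for a
#'   given seed.
#'
#' @return A list of class `"spt_sim_config"`.
#' @export
spt_sim_config <- function(n_trajectories = 1500,
                           frame_interval = 0.02,
                           pixel_size = 0.1,
                           field = c(3, 1),
                           condensate = list(center = c(0.6, 0.5), radius = 0.35),
                           D = c(0.05, 0.3, 2.0),
                           weights = c(0.45, 0.30, 0.25),
                           mean_track_frames = 10,
                           localization_noise = 0,
                           mode = c("model_exact", "physical_blur"),
                           n_substeps = 20,
                           seed) {
  mode <- match.arg(mode)
  stopifnot_scalar_number(n_trajectories, "n_trajectories", lower = 1)
  stopifnot_scalar_number(frame_interval, "frame_interval", lower = 0, strict_lower = TRUE)
  stopifnot_scalar_number(pixel_size, "pixel_size", lower = 0, strict_lower = TRUE)
  stopifnot_scalar_number(mean_track_frames, "mean_track_frames", lower = 1)
  stopifnot_scalar_number(localization_noise, "localization_noise", lower = 0)
  if (length(field) != 2 || any(field <= 0)) {
    rlang::abort("`field` must be two positive extents in micrometres.")
  }
  if (length(D) != length(weights)) {
    rlang::abort("`D` and `weights` must have the same length.")
  }
  if (any(D < 0)) rlang::abort("diffusion coefficients must be non-negative.")
  if (length(D) > 1 && any(diff(D) <= 0)) {
    rlang::abort("`D` must be strictly increasing (slowest state first).")
  }
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-8) {
    rlang::abort("`weights` must be non-negative and sum to 1.")
  }
  if (!is.null(condensate)) {
    if (!is.list(condensate) || is.null(condensate$center) || is.null(condensate$radius)) {
      rlang::abort("`condensate` must be NULL or list(center = c(x, y), radius = r).")
    }
    if (condensate$radius <= localization_noise) {
      rlang::abort("condensate radius must exceed the localization noise; the geometry is unresolvable otherwise.")
    }
    if (condensate$radius >= min(field) / 2) {
      rlang::abort("condensate radius must be smaller than half the smallest field extent.")
    }
  }
  if (missing(seed)) rlang::abort("`seed` is mandatory for all simulators.")
  structure(
    list(
      n_trajectories = as.integer(n_trajectories),
      frame_interval = frame_interval, pixel_size = pixel_size,
      field = field, condensate = condensate,
      D = D, weights = weights,
      mean_track_frames = mean_track_frames,
      localization_noise = localization_noise,
      mode = mode, n_substeps = as.integer(n_substeps),
      seed = as.integer(seed)
    ),
    class = "spt_sim_config"
  )
}

#' Simulate single-molecule trajectories with known state structure
#'
#' Generates trajectories under the mixture-of-diffusive-states model of
#' [spt_sim_config()] and exports the ground truth needed to validate the
#' downstream partition analysis: the latent state of every trajectory and
#' the per-step state fractions.
#'
#' @param config An [spt_sim_config()].
#' @return A list of class `"spt_sim"` with elements
#'   \describe{
#'     \item{tracks}{tibble with columns `trajectory_id`, `frame`,
#'       `x_um`, `y_um`.}
#'     \item{truth}{list with `per_trajectory` (tibble of
#'       `trajectory_id`, `state`, `n_frames`, `in_condensate`),
#'       `step_counts` (steps per state), and `step_fractions`
#'       (per-step state fractions, the quantity the partition analysis
#'       estimates).}
#'     \item{config}{the configuration used.}
#'   }
#' @export
simulate_spt <- function(config) {
  if (!inherits(config, "spt_sim_config")) {
    rlang::abort("`config` must be created by spt_sim_config().")
  }
  with_seed(config$seed, simulate_spt_impl(config))
}

simulate_spt_impl <- function(config) {
  n <- config$n_trajectories
  k <- length(config$D)
  tau <- config$frame_interval
  states <- sample.int(k, n, replace = TRUE, prob = config$weights)
  # 1 + Geometric(p) with mean = mean_track_frames
  p_len <- 1 / config$mean_track_frames
  lens <- 1L + stats::rgeom(n, prob = p_len)

  cond <- config$condensate
  free_geometry <- is.null(cond)

  if (free_geometry && config$mode == "model_exact") {
    tracks <- simulate_free_exact(states, lens, config)
  } else {
    tracks <- simulate_with_geometry(states, lens, config)
  }

  if (config$localization_noise > 0) {
    tracks$x_um <- tracks$x_um + rnorm(nrow(tracks), sd = config$localization_noise)
    tracks$y_um <- tracks$y_um + rnorm(nrow(tracks), sd = config$localization_noise)
  }

  per_traj <- tibble::tibble(
    trajectory_id = paste0("traj_", seq_len(n)),
    state = states,
    n_frames = lens,
    in_condensate = !free_geometry & states == 1L
  )
  steps_per_state <- vapply(seq_len(k), function(s) {
    sum(pmax(lens[states == s] - 1L, 0L))
  }, numeric(1))
  total_steps <- sum(steps_per_state)
  fr <- if (total_steps > 0) steps_per_state / total_steps else rep(NA_real_, k)
  names(fr) <- if (k == 3) c("condensate", "nucleoid", "free") else paste0("state", seq_len(k))
  if (free_geometry && k == 3) names(fr) <- c("state1", "state2", "free")

  structure(
    list(
      tracks = tracks,
      truth = list(
        per_trajectory = per_traj,
        step_counts = setNames(steps_per_state, names(fr)),
        step_fractions = fr
      ),
      config = config
    ),
    class = "spt_sim"
  )
}

# Fully vectorized path for the common oracle case: no condensate,
# model-exact displacement law.
simulate_free_exact <- function(states, lens, config) {
  n <- length(states)
  tau <- config$frame_interval
  traj <- rep(seq_len(n), lens)
  frame <- sequence(lens)
  is_step <- frame > 1L
  n_steps <- sum(is_step)
  mean_r2 <- (8 / 3) * config$D[states] * tau  # per-step exponential mean
  mr <- rep(mean_r2, lens)[is_step]
  r2 <- ifelse(mr > 0, rexp(n_steps, rate = 1 / pmax(mr, .Machine$double.xmin)), 0)
  r2[mr == 0] <- 0
  ang <- runif(n_steps, 0, 2 * pi)
  dx <- numeric(length(traj)); dy <- numeric(length(traj))
  dx[is_step] <- sqrt(r2) * cos(ang)
  dy[is_step] <- sqrt(r2) * sin(ang)
  x0 <- runif(n, 0, config$field[1])
  y0 <- runif(n, 0, config$field[2])
  dx[!is_step] <- x0
  dy[!is_step] <- y0
  x <- stats::ave(dx, traj, FUN = cumsum)
  y <- stats::ave(dy, traj, FUN = cumsum)
  tibble::tibble(
    trajectory_id = paste0("traj_", traj),
    frame = as.integer(frame),
    x_um = x, y_um = y
  )
}

# Geometry-aware path. The slowest state is confined to the condensate;
# all other states are excluded from it (two-sided partitioning). In
# model-exact mode, invalid proposals are resolved by redrawing the step
# direction, which leaves the marginal r-squared law untouched except for
# confinement itself; in physical-blur mode sub-frame positions are
# reflected radially at the condensate boundary.
simulate_with_geometry <- function(states, lens, config) {
  n <- length(states)
  tau <- config$frame_interval
  cond <- config$condensate
  out <- vector("list", n)
  for (i in seq_len(n)) {
    s <- states[i]
    L <- lens[i]
    confined <- !is.null(cond) && s == 1L
    excluded <- !is.null(cond) && s != 1L
    start <- draw_start(config, confined, excluded)
    if (config$mode == "model_exact") {
      pos <- walk_exact(start, L, config$D[s], tau, cond, confined, excluded)
    } else {
      pos <- walk_blur(start, L, config$D[s], tau, cond, confined, excluded,
                       config$n_substeps)
    }
    out[[i]] <- tibble::tibble(
      trajectory_id = paste0("traj_", i),
      frame = seq_len(L),
      x_um = pos[, 1], y_um = pos[, 2]
    )
  }
  dplyr::bind_rows(out)
}

draw_start <- function(config, confined, excluded) {
  cond <- config$condensate
  if (confined) {
    r <- cond$radius * sqrt(runif(1))
    a <- runif(1, 0, 2 * pi)
    return(cond$center + r * c(cos(a), sin(a)))
  }
  repeat {
    p <- c(runif(1, 0, config$field[1]), runif(1, 0, config$field[2]))
    if (!excluded) return(p)
    if (sum((p - cond$center)^2) > cond$radius^2) return(p)
  }
}

in_disk <- function(p, cond) sum((p - cond$center)^2) <= cond$radius^2

walk_exact <- function(start, L, D, tau, cond, confined, excluded) {
  pos <- matrix(NA_real_, nrow = L, ncol = 2)
  pos[1, ] <- start
  if (L == 1L) return(pos)
  mean_r2 <- (8 / 3) * D * tau
  for (f in 2:L) {
    cur <- pos[f - 1L, ]
    repeat {
      r <- if (mean_r2 > 0) sqrt(rexp(1, rate = 1 / mean_r2)) else 0
      ok <- FALSE
      for (try in seq_len(64L)) {
        a <- runif(1, 0, 2 * pi)
        prop <- cur + r * c(cos(a), sin(a))
        if (confined && in_disk(prop, cond)) { ok <- TRUE; break }
        if (excluded && !in_disk(prop, cond)) { ok <- TRUE; break }
        if (!confined && !excluded) { ok <- TRUE; break }
      }
      if (ok) break
      # no valid direction for this step length (e.g. longer than the
      # condensate diameter): redraw the length as well
    }
    pos[f, ] <- prop
  }
  pos
}

# Radial reflection at the condensate boundary, applied to sub-frame
# positions so the exposure-averaged path respects the geometry.
reflect_radial <- function(p, cond, keep_inside) {
  d <- sqrt(sum((p - cond$center)^2))
  R <- cond$radius
  inside <- d <= R
  if ((keep_inside && inside) || (!keep_inside && !inside)) return(p)
  if (d == 0) return(p)
  d_new <- 2 * R - d
  if (d_new < 0) d_new <- R * runif(1)  # pathological overshoot
  cond$center + (p - cond$center) * d_new / d
}

walk_blur <- function(start, L, D, tau, cond, confined, excluded, n_sub) {
  dt <- tau / n_sub
  step_sd <- sqrt(2 * D * dt)
  n_fine <- L * n_sub
  p <- start
  fine <- matrix(NA_real_, nrow = n_fine, ncol = 2)
  for (j in seq_len(n_fine)) {
    p <- p + rnorm(2, sd = step_sd)
    if (confined) p <- reflect_radial(p, cond, keep_inside = TRUE)
    if (excluded && !is.null(cond)) p <- reflect_radial(p, cond, keep_inside = FALSE)
    fine[j, ] <- p
  }
  # exposure-averaged camera positions, exposure = frame interval
  grp <- rep(seq_len(L), each = n_sub)
  cbind(
    tapply(fine[, 1], grp, mean),
    tapply(fine[, 2], grp, mean)
  )
}
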