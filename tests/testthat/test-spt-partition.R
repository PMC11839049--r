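make_fit <- function(D, alpha, tau = 0.02) {
  structure(list(n_states = length(D), D = D, alpha = alpha,
                 objective = 0, converged = TRUE, n = 1000L, tau = tau),
            class = "diffusion_fit")
}

test_that("focus filtering enforces trajectory support thresholds", {
  focus <- make_focus(5, 5, radius = 1)

  ten_inside <- dplyr::bind_rows(lapply(1:10, function(i) {
    make_static_track(paste0("in", i), 5, 5, n_frames = 10)
  }))
  expect_equal(nrow(filter_foci(focus, ten_inside)), 1)

  nine_inside <- dplyr::filter(ten_inside, trajectory_id != "in10")
  expect_equal(nrow(filter_foci(focus, nine_inside)), 0)

  # 7 of 10 frames inside (overlap exactly 0.7) counts toward the quota
  boundary <- dplyr::bind_rows(lapply(1:10, function(i) {
    make_track(paste0("b", i),
               x = c(rep(5, 7), rep(50, 3)), y = rep(5, 10))
  }))
  expect_equal(nrow(filter_foci(focus, boundary)), 1)

  # 6 of 10 inside (0.6 < 0.7) does not
  below <- dplyr::bind_rows(lapply(1:10, function(i) {
    make_track(paste0("c", i),
               x = c(rep(5, 6), rep(50, 4)), y = rep(5, 10))
  }))
  expect_equal(nrow(filter_foci(focus, below)), 0)

  # short trajectories (9 frames) never qualify
  short <- dplyr::bind_rows(lapply(1:12, function(i) {
    make_static_track(paste0("s", i), 5, 5, n_frames = 9)
  }))
  expect_equal(nrow(filter_foci(focus, short)), 0)

  expect_equal(nrow(filter_foci(focus, ten_inside[0, ])), 0)
})

test_that("trajectory classification follows the In / In-out / Out rules", {
  focus <- make_focus(5, 5, radius = 1)
  frac_track <- function(id, frac, n = 20) {
    k <- round(frac * n)
    make_track(id, x = c(rep(5, k), rep(50, n - k)), y = rep(5, n))
  }
  tracks <- dplyr::bind_rows(
    frac_track("full", 1), frac_track("half", 0.5),
    frac_track("low", 0.10), frac_track("edge", 0.25),
    frac_track("near", 0.95)
  )
  cls <- classify_trajectories(tracks, focus)
  lbl <- setNames(cls$label, cls$trajectory_id)
  expect_equal(unname(lbl["full"]), "In")
  expect_equal(unname(lbl["half"]), "In/out")
  expect_equal(unname(lbl["low"]), "Out")
  expect_equal(unname(lbl["edge"]), "In/out")   # boundary 25% is In/out
  expect_equal(unname(lbl["near"]), "In/out")   # <100% is never In
})

test_that("classification agrees with brute-force membership counting", {
  set.seed(42)
  foci <- dplyr::bind_rows(make_focus(3, 3, 1, "f1"), make_focus(8, 2, 1.5, "f2"))
  tracks <- dplyr::bind_rows(lapply(1:30, function(i) {
    n <- sample(5:15, 1)
    make_track(paste0("t", i), x = runif(n, 0, 10), y = runif(n, 0, 5))
  }))
  cls <- classify_trajectories(tracks, foci)
  for (id in cls$trajectory_id) {
    tr <- tracks[tracks$trajectory_id == id, ]
    inside <- vapply(seq_len(nrow(tr)), function(j) {
      any((tr$x_um[j] - foci$x_um)^2 + (tr$y_um[j] - foci$y_um)^2 <=
            foci$radius_um^2)
    }, logical(1))
    expect_equal(cls$overlap_fraction[cls$trajectory_id == id], mean(inside))
  }
})

test_that("displacement pooling uses consecutive frames in long-enough tracks", {
  short <- make_track("s", x = c(0, 1, 2), y = c(0, 0, 0))
  expect_equal(nrow(pool_squared_displacements(short, 0.02)), 0)

  four <- make_track("f", x = c(0, 0.1, 0.1, 0.2), y = c(0, 0, 0.1, 0.1))
  pool <- pool_squared_displacements(four, 0.02)
  expect_equal(pool$r2, rep(0.01, 3), tolerance = 1e-12)
  expect_equal(attr(pool, "tau"), 0.02)

  # frame gaps are excluded
  gap <- make_track("g", x = c(0, 1, 2, 3, 4), y = rep(0, 5),
                    frames = c(1, 2, 3, 5, 6))
  expect_equal(nrow(pool_squared_displacements(gap, 0.02)), 3)

  # brute-force oracle over random trajectories
  set.seed(7)
  tracks <- dplyr::bind_rows(lapply(1:100, function(i) {
    n <- sample(2:12, 1)
    make_track(paste0("t", i), x = cumsum(rnorm(n)), y = cumsum(rnorm(n)))
  }))
  pool <- pool_squared_displacements(tracks, 0.02, min_len = 4)
  brute <- c()
  for (id in unique(tracks$trajectory_id)) {
    tr <- tracks[tracks$trajectory_id == id, ]
    tr <- tr[order(tr$frame), ]
    if (nrow(tr) < 4) next
    for (j in seq_len(nrow(tr) - 1)) {
      if (tr$frame[j + 1] - tr$frame[j] == 1) {
        brute <- c(brute, (tr$x_um[j + 1] - tr$x_um[j])^2 +
                     (tr$y_um[j + 1] - tr$y_um[j])^2)
      }
    }
  }
  expect_equal(sort(pool$r2), sort(brute))
})

test_that("CDF fitting rejects degenerate pools", {
  expect_error(fit_displacement_cdf(numeric(0), tau = 0.02), "empty")
  expect_error(fit_displacement_cdf(rep(0.05, 200), tau = 0.02),
               "no displacement signal")
})

test_that("the fitted model CDF is a proper CDF for any valid parameters", {
  set.seed(11)
  for (i in 1:20) {
    k <- sample(2:3, 1)
    a <- diff(c(0, sort(runif(k - 1)), 1))
    fit <- make_fit(D = sort(stats::rlnorm(k)), alpha = a)
    x <- seq(0, 5, length.out = 200)
    p <- predict_cdf(fit, x)
    expect_equal(p[1], 0)
    expect_true(all(diff(p) >= -1e-12))
    expect_lt(abs(predict_cdf(fit, 1e6) - 1), 1e-9)
  }
})

test_that("three-state fits on two-state data put little weight elsewhere", {
  cfg <- spt_sim_config(n_trajectories = 11000, condensate = NULL,
                        D = c(0.1, 1.5), weights = c(0.5, 0.5), seed = 12)
  sim <- simulate_spt(cfg)
  pool <- pool_squared_displacements(sim$tracks, 0.02)
  expect_gt(nrow(pool), 9e4)
  fit2 <- fit_displacement_cdf(pool, n_states = 2)
  fit3 <- fit_displacement_cdf(pool, n_states = 3)
  expect_equal(fit2$D, c(0.1, 1.5), tolerance = 0.1)
  expect_equal(fit2$alpha, c(0.5, 0.5), tolerance = 0.05)
  # weight on components not matching a true D stays below 0.05
  spurious <- sum(fit3$alpha[pmin(abs(fit3$D / 0.1 - 1),
                                  abs(fit3$D / 1.5 - 1)) > 0.35])
  expect_lt(spurious, 0.05)
})

test_that("partition fractions follow the stated arithmetic", {
  # 40 In trajectories x 10 steps and 60 Out x 10 steps: N_in = 400 of 1000
  tracks <- dplyr::bind_rows(lapply(1:100, function(i) {
    make_track(paste0("t", i), x = seq(0, 1, length.out = 11) + i,
               y = rep(0, 11))
  }))
  classes <- tibble::tibble(
    trajectory_id = paste0("t", 1:100),
    n_frames = 11,
    overlap_fraction = c(rep(1, 40), rep(0, 60)),
    label = c(rep("In", 40), rep("Out", 60))
  )
  full_fit <- make_fit(D = c(0.05, 0.3, 2), alpha = c(0.35, 0.25, 0.4))
  subset_fit <- make_fit(D = c(0.05, 0.3, 2), alpha = c(0.5, 0.3, 0.2))
  fr <- compute_partition_fractions(full_fit, subset_fit, classes, tracks)
  expect_equal(fr$F_condensate, 0.4 * 0.8)
  expect_equal(fr$F_free, 0.4)
  expect_equal(fr$F_nucleoid, 1 - 0.4 - 0.32)
  expect_equal(fr$N_in, 400L)
  expect_equal(fr$N_total_steps, 1000L)
  expect_equal(fr$F_condensate + fr$F_nucleoid + fr$F_free, 1)

  # all-Out data: condensate fraction is zero by construction
  classes_out <- dplyr::mutate(classes, label = "Out", overlap_fraction = 0)
  fr0 <- compute_partition_fractions(full_fit, NULL, classes_out, tracks)
  expect_equal(fr0$F_condensate, 0)
  expect_equal(fr0$F_nucleoid, 1 - fr0$F_free)

  # slow "free" state triggers the D3 warning
  slow <- make_fit(D = c(0.01, 0.1, 0.5), alpha = c(0.3, 0.3, 0.4))
  expect_warning(compute_partition_fractions(slow, NULL, classes_out, tracks),
                 "not > 1")
})

test_that("partition fractions always sum to one", {
  set.seed(13)
  tracks <- dplyr::bind_rows(lapply(1:30, function(i) {
    make_track(paste0("t", i), x = cumsum(rnorm(8)), y = cumsum(rnorm(8)))
  }))
  for (i in 1:10) {
    a_full <- diff(c(0, sort(runif(2)), 1))
    a_sub <- diff(c(0, sort(runif(2)), 1))
    labels <- sample(c("In", "In/out", "Out"), 30, replace = TRUE)
    classes <- tibble::tibble(trajectory_id = paste0("t", 1:30),
                              n_frames = 8, overlap_fraction = 0.5,
                              label = labels)
    fr <- suppressWarnings(compute_partition_fractions(
      make_fit(c(0.05, 0.3, 2), a_full),
      make_fit(c(0.05, 0.3, 2), a_sub),
      classes, tracks
    ))
    expect_equal(fr$F_condensate + fr$F_nucleoid + fr$F_free, 1)
  }
})

test_that("FRAP one-phase association fits recover known kinetics", {
  tt <- seq(0, 115, by = 5)
  y <- 0.2 + 0.6 * (1 - exp(-0.1 * tt))
  fit <- fit_frap_recovery(tt, y, n_boot = 0)
  expect_true(fit$converged)
  expect_equal(fit$k, 0.1, tolerance = 1e-6)
  expect_equal(fit$t_half, log(2) / 0.1, tolerance = 1e-6)

  flat <- fit_frap_recovery(tt, rep(0.5, length(tt)), n_boot = 0)
  expect_false(flat$converged)

  set.seed(14)
  noisy <- y + rnorm(length(tt), sd = 0.02)
  fitn <- fit_frap_recovery(tt, noisy, n_boot = 100, seed = 15)
  expect_true(fitn$converged)
  expect_lt(abs(fitn$t_half - log(2) / 0.1) / (log(2) / 0.1), 0.15)
  expect_true(fitn$t_half_ci[1] < fitn$t_half & fitn$t_half < fitn$t_half_ci[2])

  expect_error(fit_frap_recovery(1:3, 1:3), "at least 4")
})
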