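# broom-style tidy()/glance() methods for the fitted-object classes.

#' @export
tidy.diffusion_fit <- function(x, ...) {
  tibble::tibble(
    state = seq_len(x$n_states),
    D = x$D,
    alpha = x$alpha
  )
}

#' @export
glance.diffusion_fit <- function(x, ...) {
  tibble::tibble(
    n_states = x$n_states, n = x$n, tau = x$tau,
    objective = x$objective, converged = x$converged
  )
}

#' @export
tidy.frap_fit <- function(x, ...) {
  tibble::tibble(
    term = c("y0", "plateau", "k", "t_half"),
    estimate = c(x$y0, x$plateau, x$k, x$t_half)
  )
}

#' @export
glance.frap_fit <- function(x, ...) {
  tibble::tibble(
    t_half = x$t_half,
    t_half_low = x$t_half_ci[1], t_half_high = x$t_half_ci[2],
    converged = x$converged
  )
}

#' @export
tidy.zinb_fit <- function(x, ...) {
  tibble::tibble(
    cell = x$cells,
    log_mean = unname(x$beta),
    mu = unname(x$mu),
    n = unname(x$n_by_cell)
  )
}

#' @export
glance.zinb_fit <- function(x, ...) {
  tibble::tibble(
    pi = x$pi, theta = x$theta, loglik = x$loglik,
    converged = x$converged, degenerate = x$degenerate, unfit = x$unfit,
    iterations = x$iterations
  )
}

#' @export
tidy.overlap_permutation <- function(x, ...) {
  tibble::tibble(
    statistic = names(x$observed),
    observed = unname(x$observed),
    null_mean = colMeans(x$null),
    p_value = unname(x$p_value)
  )
}

#' @export
glance.overlap_permutation <- function(x, ...) {
  tibble::tibble(n_perm = x$n_perm, seed = x$seed,
                 hp_shared_fraction = x$overlap$hp_shared_fraction)
}
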