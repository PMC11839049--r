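#' Zero-inflated negative binomial log-likelihood
#'
#' The tail-length model: a point mass at zero with probability pi, mixed
#' with a negative binomial (mean mu depending on the genotype-by-
#' condition cell through a log link, shared size theta):
#' \deqn{P(k) = \pi \, 1[k = 0] + (1 - \pi)\, \mathrm{NB}(k; \mu_c, \theta)}
#'
#' @param k Integer observations (tail lengths).
#' @param cell Factor (or character) giving each observation's cell.
#' @param beta Named log-means, one per cell level.
#' @param pi Zero-inflation probability.
#' @param theta Negative-binomial size.
#' @return The total log-likelihood.
#' @export
zinb_loglik <- function(k, cell, beta, pi, theta) {
  cell <- as.character(cell)
  mu <- exp(beta[cell])
  ll_nb <- dnbinom(k, size = theta, mu = mu, log = TRUE)
  is0 <- k == 0
  out <- numeric(length(k))
  out[!is0] <- log1p(-pi) + ll_nb[!is0]
  out[is0] <- log_safe(pi + (1 - pi) * exp(ll_nb[is0]))
  sum(out)
}

#' Fit the per-gene zero-inflated negative binomial tail model
#'
#' Maximizes the [zinb_loglik()] over one gene's tail-length observations:
#' one log-link mean per genotype-by-condition cell (four degrees of
#' freedom in the standard two-genotype, two-condition design) plus a
#' single zero-inflation rate and a single overdispersion parameter.
#' Optimization is BFGS on unconstrained parameters (log means, logit pi,
#' log theta) with an iteration cap; the observed-information matrix is
#' inverted for Wald standard errors.
#'
#' Genes whose observations are all zero are flagged degenerate
#' (pi tends to 1; no parameters are reported), and genes with reads in
#' fewer than two cells are flagged unfit.
#'
#' @param k Integer tail lengths for one gene.
#' @param cell Factor/character of the same length giving each
#'   observation's genotype-by-condition cell.
#' @param max_iter Iteration cap for the optimizer (default 500).
#' @return An object of class `"zinb_fit"`: `cells`, `beta` (log means),
#'   `mu`, `pi`, `theta`, `loglik`, `vcov` (order: betas, logit-pi,
#'   log-theta), `converged`, `iterations`, `n_by_cell`, `degenerate`,
#'   `unfit`.
#' @export
fit_zinb_tail_model <- function(k, cell, max_iter = 500) {
  cell <- as.character(cell)
  if (length(k) != length(cell)) rlang::abort("`k` and `cell` lengths differ.")
  if (any(k < 0)) rlang::abort("tail lengths must be non-negative.")
  lv <- sort(unique(cell))
  n_by_cell <- vapply(lv, function(l) sum(cell == l), numeric(1))

  skeleton <- function(degenerate, unfit) {
    structure(
      list(cells = lv, beta = setNames(rep(NA_real_, length(lv)), lv),
           mu = setNames(rep(NA_real_, length(lv)), lv),
           pi = if (degenerate) 1 else NA_real_, theta = NA_real_,
           loglik = NA_real_, vcov = NULL, converged = FALSE,
           iterations = 0L, n_by_cell = n_by_cell,
           degenerate = degenerate, unfit = unfit),
      class = "zinb_fit"
    )
  }
  if (length(lv) < 2) return(skeleton(degenerate = FALSE, unfit = TRUE))
  if (all(k == 0)) return(skeleton(degenerate = TRUE, unfit = FALSE))

  C <- length(lv)
  cell_f <- factor(cell, levels = lv)
  mu0 <- tapply(k, cell_f, mean)
  mu0 <- pmax(ifelse(is.na(mu0), mean(k), mu0), 0.05)
  mbar <- mean(k); vbar <- stats::var(k)
  theta0 <- if (is.finite(vbar) && vbar > mbar) mbar^2 / (vbar - mbar) else 10
  theta0 <- min(max(theta0, 0.1), 100)
  p0_nb <- mean(dnbinom(0, size = theta0, mu = mu0[cell_f]))
  pi0 <- (mean(k == 0) - p0_nb) / max(1 - p0_nb, 1e-6)
  pi0 <- min(max(pi0, 0.01), 0.95)

  par0 <- c(log(mu0), stats::qlogis(pi0), log(theta0))
  nll <- function(par) {
    beta <- setNames(par[seq_len(C)], lv)
    pi <- stats::plogis(par[C + 1])
    theta <- exp(par[C + 2])
    v <- suppressWarnings(-zinb_loglik(k, cell, beta, pi, theta))
    if (!is.finite(v)) 1e10 else v
  }
  run_bfgs <- function(p) {
    tryCatch(
      optim(p, nll, method = "BFGS",
            control = list(maxit = max_iter, reltol = 1e-12)),
      error = function(e) NULL
    )
  }
  opt <- run_bfgs(par0)
  if (is.null(opt)) {
    opt <- optim(par0, nll, method = "Nelder-Mead",
                 control = list(maxit = max_iter))
  } else {
    # restart from the optimum until the likelihood stops improving; BFGS
    # can stall short of the boundary when pi tends to zero
    for (r in 1:3) {
      again <- run_bfgs(opt$par)
      if (is.null(again) || opt$value - again$value < 1e-9) break
      opt <- again
    }
  }
  # profile fit on the pi = 0 boundary: when the data carry no excess
  # zeros the MLE sits there, where the logit parameterization flattens out
  nb_nll <- function(par) {
    beta <- setNames(par[seq_len(C)], lv)
    v <- suppressWarnings(-zinb_loglik(k, cell, beta, 0, exp(par[C + 1])))
    if (!is.finite(v)) 1e10 else v
  }
  nb_opt <- tryCatch(
    optim(opt$par[c(seq_len(C), C + 2)], nb_nll, method = "BFGS",
          control = list(maxit = max_iter, reltol = 1e-12)),
    error = function(e) NULL
  )
  on_boundary <- !is.null(nb_opt) && nb_opt$value <= opt$value
  if (on_boundary) {
    opt <- list(par = c(nb_opt$par[seq_len(C)], -Inf, nb_opt$par[C + 1]),
                value = nb_opt$value, convergence = nb_opt$convergence,
                counts = nb_opt$counts)
  }
  beta <- setNames(opt$par[seq_len(C)], lv)
  pi_hat <- if (on_boundary) 0 else stats::plogis(opt$par[C + 1])
  theta_hat <- exp(opt$par[C + 2])
  pnames <- c(lv, "logit_pi", "log_theta")
  vc <- tryCatch({
    if (on_boundary) {
      H <- optimHess(c(opt$par[seq_len(C)], opt$par[C + 2]), nb_nll)
      Vnb <- solve(H)
      V <- matrix(NA_real_, C + 2, C + 2, dimnames = list(pnames, pnames))
      V[seq_len(C), seq_len(C)] <- Vnb[seq_len(C), seq_len(C)]
      V["log_theta", "log_theta"] <- Vnb[C + 1, C + 1]
      V[seq_len(C), "log_theta"] <- Vnb[seq_len(C), C + 1]
      V["log_theta", seq_len(C)] <- Vnb[C + 1, seq_len(C)]
      V
    } else {
      H <- optimHess(opt$par, nll)
      V <- solve(H)
      dimnames(V) <- list(pnames, pnames)
      V
    }
  }, error = function(e) NULL)

  structure(
    list(cells = lv, beta = beta, mu = exp(beta),
         pi = pi_hat, theta = theta_hat,
         loglik = -opt$value, vcov = vc,
         converged = opt$convergence == 0L,
         iterations = opt$counts[["function"]],
         n_by_cell = n_by_cell,
         degenerate = FALSE, unfit = FALSE),
    class = "zinb_fit"
  )
}

#' @export
print.zinb_fit <- function(x, ...) {
  if (x$unfit) {
    cat("<zinb_fit> unfit: observations in fewer than two cells\n")
    return(invisible(x))
  }
  if (x$degenerate) {
    cat("<zinb_fit> degenerate: all observations zero (pi -> 1)\n")
    return(invisible(x))
  }
  cat(sprintf("<zinb_fit> pi = %.3f, theta = %.3g, loglik = %.3f, converged: %s\n",
              x$pi, x$theta, x$loglik, x$converged))
  print(signif(x$mu, 4))
  invisible(x)
}

#' Fit the ZINB tail model for every gene in an assignment table
#'
#' @param assignments Output of [assign_reads_to_tail_windows()].
#' @param design Tibble with `sample`, `genotype`, `condition`.
#' @param max_iter Optimizer iteration cap per gene (default 500).
#' @return A tibble with one row per gene: `gene`, `pi`, `theta`,
#'   `loglik`, `converged`, `degenerate`, `unfit`, `n_reads`, plus one
#'   `mu_<cell>` column per genotype-by-condition cell and a `fit`
#'   list-column holding the full `"zinb_fit"` objects.
#' @export
fit_zinb_tails <- function(assignments, design, max_iter = 500) {
  dat <- assignments |>
    dplyr::inner_join(design, by = "sample") |>
    dplyr::mutate(cell = paste(.data$genotype, .data$condition, sep = "."))
  genes <- sort(unique(dat$gene))
  fits <- lapply(genes, function(g) {
    d <- dat[dat$gene == g, ]
    fit_zinb_tail_model(d$tail_length, d$cell, max_iter = max_iter)
  })
  mu_tbl <- dplyr::bind_rows(lapply(fits, function(f) {
    tibble::as_tibble(as.list(setNames(f$mu, paste0("mu_", f$cells))))
  }))
  out <- tibble::tibble(
    gene = genes,
    pi = vapply(fits, `[[`, numeric(1), "pi"),
    theta = vapply(fits, `[[`, numeric(1), "theta"),
    loglik = vapply(fits, `[[`, numeric(1), "loglik"),
    converged = vapply(fits, `[[`, logical(1), "converged"),
    degenerate = vapply(fits, `[[`, logical(1), "degenerate"),
    unfit = vapply(fits, `[[`, logical(1), "unfit"),
    n_reads = vapply(genes, function(g) sum(dat$gene == g), numeric(1))
  )
  out <- dplyr::bind_cols(out, mu_tbl)
  out$fit <- fits
  out
}

#' Summarize genotype effects on poly(A) tail length
#'
#' For each gene and condition, the estimated mean tail length is
#' (1 - pi) * mu_cell; the genotype effect is
#' delta = mean(mutant) - mean(reference), tested by a Wald test on the
#' corresponding log-mean contrast and Benjamini-Hochberg adjusted across
#' genes within each condition. Also returns, per cell, the cumulative
#' distribution over genes of estimated mean tail length.
#'
#' @param fits Output of [fit_zinb_tails()].
#' @param genotypes Reference and mutant genotype (default
#'   `c("WT", "ppk")`).
#' @param conditions Conditions to contrast (default
#'   `c("Nplus", "N24")`).
#' @return A list with `shifts` (tibble: `gene`, `condition`, `mean_ref`,
#'   `mean_mut`, `delta`, `p_value`, `p_adj`) and `cdf` (tibble: `cell`,
#'   `mean_tail`, `cum_fraction`).
#' @export
summarize_tail_shifts <- function(fits, genotypes = c("WT", "ppk"),
                                  conditions = c("Nplus", "N24")) {
  ok <- fits$converged & !fits$degenerate & !fits$unfit
  if (!any(ok)) rlang::abort("no converged ZINB fits to summarize.")
  fits <- fits[ok, , drop = FALSE]

  rows <- list()
  for (i in seq_len(nrow(fits))) {
    f <- fits$fit[[i]]
    for (cond in conditions) {
      c_ref <- paste(genotypes[1], cond, sep = ".")
      c_mut <- paste(genotypes[2], cond, sep = ".")
      if (!all(c(c_ref, c_mut) %in% f$cells)) next
      m_ref <- (1 - f$pi) * f$mu[[c_ref]]
      m_mut <- (1 - f$pi) * f$mu[[c_mut]]
      p <- NA_real_
      if (!is.null(f$vcov)) {
        se2 <- f$vcov[c_mut, c_mut] + f$vcov[c_ref, c_ref] -
          2 * f$vcov[c_mut, c_ref]
        if (is.finite(se2) && se2 > 0) {
          z <- (f$beta[[c_mut]] - f$beta[[c_ref]]) / sqrt(se2)
          p <- 2 * pnorm(-abs(z))
        }
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        gene = fits$gene[i], condition = cond,
        mean_ref = m_ref, mean_mut = m_mut,
        delta = m_mut - m_ref, p_value = p
      )
    }
  }
  shifts <- dplyr::bind_rows(rows) |>
    dplyr::mutate(p_adj = p.adjust(.data$p_value, method = "BH"),
                  .by = "condition")

  cdf <- dplyr::bind_rows(lapply(seq_len(nrow(fits)), function(i) {
    f <- fits$fit[[i]]
    tibble::tibble(gene = fits$gene[i], cell = f$cells,
                   mean_tail = (1 - f$pi) * unname(f$mu))
  })) |>
    dplyr::filter(is.finite(.data$mean_tail)) |>
    dplyr::arrange(.data$cell, .data$mean_tail) |>
    dplyr::mutate(cum_fraction = seq_along(.data$mean_tail) /
                    length(.data$mean_tail),
                  .by = "cell") |>
    dplyr::select("cell", "mean_tail", "cum_fraction")

  list(shifts = shifts, cdf = cdf)
}
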