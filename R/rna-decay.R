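#' Spike-in normalization of a count matrix
#'
#' Two-step normalization anchoring per-cell transcript abundance to the
#' ERCC spike-ins: each feature's count is first divided by the sample's
#' total read count, then genomic features are rescaled by the median
#' relative abundance of the ERCC features in that sample (considering
#' only spike-ins whose relative abundance exceeds
#' `ercc_min_rel_abund`). The result is exactly invariant to uniform
#' rescaling of any sample's raw counts.
#'
#' @param counts A matrix with feature rownames, or a data frame whose
#'   first column `feature` holds feature ids and whose remaining columns
#'   are samples. Spike-in features are recognized by `ercc_prefix`.
#' @param ercc_min_rel_abund Minimum relative abundance for a spike-in to
#'   enter the median (default 5e-4).
#' @param ercc_prefix Prefix identifying spike-in features
#'   (default `"ERCC-"`).
#' @return A tibble of genomic (non-spike-in) features with the same
#'   sample columns, carrying the per-sample ERCC median as attribute
#'   `ercc_median`.
#' @export
normalize_with_spikeins <- function(counts, ercc_min_rel_abund = 5e-4,
                                    ercc_prefix = "ERCC-") {
  m <- as_count_matrix(counts)
  if (any(m < 0)) rlang::abort("counts must be non-negative.")
  is_ercc <- startsWith(rownames(m), ercc_prefix)
  if (!any(is_ercc)) rlang::abort("no spike-in features found in `counts`.")

  totals <- colSums(m)
  if (any(totals == 0)) {
    rlang::abort(sprintf("sample(s) with zero total counts: %s",
                         paste(colnames(m)[totals == 0], collapse = ", ")))
  }
  rel <- sweep(m, 2, totals, "/")
  ercc_median <- vapply(seq_len(ncol(rel)), function(j) {
    v <- rel[is_ercc, j]
    v <- v[v > ercc_min_rel_abund]
    if (length(v) == 0) {
      rlang::abort(sprintf(
        "sample '%s' has no spike-in above the relative-abundance threshold %g.",
        colnames(rel)[j], ercc_min_rel_abund
      ))
    }
    median(v)
  }, numeric(1))
  norm <- sweep(rel[!is_ercc, , drop = FALSE], 2, ercc_median, "/")

  out <- tibble::as_tibble(cbind(
    tibble::tibble(feature = rownames(norm)),
    tibble::as_tibble(norm)
  ))
  attr(out, "ercc_median") <- setNames(ercc_median, colnames(m))
  out
}

#' Fit an exponential decay curve to one abundance time series
#'
#' Least-squares fit of y = a * exp(-t / b) with both parameters bounded
#' below by zero and initialized at a = 0.001, b = 20 (minutes). Decay
#' constants are considered measurable when 5 <= b <= 65 minutes; outside
#' that window the time course carries little information about b at the
#' sampled timepoints.
#'
#' @param t Timepoints in minutes (>= 3 distinct values recommended).
#' @param y Normalized abundances, non-negative.
#' @param a_init,b_init Initial values (defaults 0.001 and 20).
#' @return A one-row tibble: `a`, `b`, `rss`, `converged`, `measurable`.
#' @export
fit_exponential_decay <- function(t, y, a_init = 0.001, b_init = 20) {
  if (length(t) != length(y)) rlang::abort("`t` and `y` must have equal length.")
  if (length(t) < 3) rlang::abort("need at least 3 timepoints.")
  if (any(y < 0)) rlang::abort("abundances must be non-negative.")
  if (all(y == 0)) {
    return(tibble::tibble(a = 0, b = NA_real_, rss = 0,
                          converged = FALSE, measurable = FALSE))
  }
  residual <- function(p) y - p[1] * exp(-t / p[2])
  one_fit <- function(start) {
    tryCatch(
      minpack.lm::nls.lm(
        par = start, fn = residual,
        lower = c(0, 1e-9),
        control = minpack.lm::nls.lm.control(maxiter = 500)
      ),
      error = function(e) NULL
    )
  }
  # the prescribed initialization plus data-driven fallback starts; the
  # least-squares surface has a spurious minimum at b -> 0 that pure
  # Levenberg-Marquardt can fall into from a near-zero baseline start
  starts <- list(c(a = a_init, b = b_init),
                 c(a = max(y), b = b_init))
  pos <- y > 0
  if (sum(pos) >= 2 && sd(t[pos]) > 0) {
    sl <- unname(stats::coef(stats::lm(log(y[pos]) ~ t[pos])))
    if (is.finite(sl[2]) && sl[2] < -1e-9) {
      starts <- c(starts, list(c(a = exp(sl[1]), b = -1 / sl[2])))
    }
  }
  fits <- Filter(function(f) !is.null(f) && f$info %in% 1:4,
                 lapply(starts, one_fit))
  if (length(fits) == 0) {
    return(tibble::tibble(a = NA_real_, b = NA_real_, rss = NA_real_,
                          converged = FALSE, measurable = FALSE))
  }
  fit <- fits[[which.min(vapply(fits, `[[`, numeric(1), "deviance"))]]
  b <- fit$par[["b"]]
  tibble::tibble(
    a = fit$par[["a"]], b = b,
    rss = fit$deviance,
    converged = TRUE,
    measurable = b >= 5 & b <= 65
  )
}

#' Fit per-gene decay curves across a normalized abundance table
#'
#' Joins normalized abundances to the sample sheet and fits
#' [fit_exponential_decay()] per gene (and per genotype when several are
#' present). With `mode = "joint"` (default) all replicate time courses of
#' a genotype enter one objective; with `mode = "per_replicate"` each
#' replicate is fitted separately and reported as its own row. Untreated
#' (rifampicin = FALSE) samples are excluded.
#'
#' @param normalized Output of [normalize_with_spikeins()].
#' @param samples Sample sheet tibble with `sample`, `genotype`,
#'   `timepoint_min`, `replicate`, and optionally `rifampicin`.
#' @param mode `"joint"` or `"per_replicate"`.
#' @return Tibble with one row per gene x genotype (x replicate in
#'   per-replicate mode): `gene`, `genotype`, (`replicate`,) `a`, `b`,
#'   `rss`, `converged`, `measurable`.
#' @export
fit_decay_curves <- function(normalized, samples,
                             mode = c("joint", "per_replicate")) {
  mode <- match.arg(mode)
  if ("rifampicin" %in% names(samples)) {
    samples <- samples[samples$rifampicin, , drop = FALSE]
  }
  long <- normalized |>
    tidyr::pivot_longer(-"feature", names_to = "sample",
                        values_to = "abundance") |>
    dplyr::inner_join(samples, by = "sample")
  grouping <- if (mode == "joint") c("feature", "genotype") else
    c("feature", "genotype", "replicate")
  out <- long |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grouping))) |>
    dplyr::group_modify(~ fit_exponential_decay(.x$timepoint_min, .x$abundance)) |>
    dplyr::ungroup() |>
    dplyr::rename(gene = "feature")
  out
}

#' Classify a gene's stability change between two genotypes
#'
#' Applies the four-category scheme for genotype-dependent stability:
#' a transcript is *stable in X / unstable in Y* when its decay constant
#' exceeds 65 minutes in one genotype and is below 55 minutes in the
#' other; when both decay constants are below 65 minutes, the transcript
#' is called more stable in whichever genotype's constant is at least
#' 10 minutes larger; anything else (including unconverged fits) is
#' `no_call`. All inputs are vectorized.
#'
#' @param tau_wt,tau_ppk Decay constants (minutes) in the two genotypes.
#' @param converged_wt,converged_ppk Convergence flags (default `TRUE`).
#' @param stable_min Stability threshold in minutes (default 65).
#' @param unstable_max Instability threshold in minutes (default 55).
#' @param shift_min Minimum increase in minutes for a directional call
#'   (default 10).
#' @return Character vector of categories:
#'   `stable_WT_unstable_ppk`, `stable_ppk_unstable_WT`, `WT_gt_ppk`,
#'   `ppk_gt_WT`, `no_call`.
#' @export
classify_stability_pair <- function(tau_wt, tau_ppk,
                                    converged_wt = TRUE, converged_ppk = TRUE,
                                    stable_min = 65, unstable_max = 55,
                                    shift_min = 10) {
  dplyr::case_when(
    !converged_wt | !converged_ppk | is.na(tau_wt) | is.na(tau_ppk) ~ "no_call",
    tau_wt > stable_min & tau_ppk < unstable_max ~ "stable_WT_unstable_ppk",
    tau_ppk > stable_min & tau_wt < unstable_max ~ "stable_ppk_unstable_WT",
    tau_wt < stable_min & tau_ppk < stable_min & tau_wt >= tau_ppk + shift_min ~ "WT_gt_ppk",
    tau_wt < stable_min & tau_ppk < stable_min & tau_ppk >= tau_wt + shift_min ~ "ppk_gt_WT",
    TRUE ~ "no_call"
  )
}

#' Classify stability across a table of per-genotype decay fits
#'
#' @param fits Output of [fit_decay_curves()] containing both genotypes.
#' @param genotypes Length-2 character vector naming the reference and
#'   mutant genotype columns (default `c("WT", "ppk")`).
#' @param ... Passed to [classify_stability_pair()].
#' @return Tibble: `gene`, `tau_WT`, `tau_ppk`, `category`.
#' @export
classify_stability <- function(fits, genotypes = c("WT", "ppk"), ...) {
  wide <- fits |>
    dplyr::filter(.data$genotype %in% genotypes) |>
    dplyr::select("gene", "genotype", "b", "converged") |>
    tidyr::pivot_wider(names_from = "genotype",
                       values_from = c("b", "converged"))
  b_wt <- wide[[paste0("b_", genotypes[1])]]
  b_mut <- wide[[paste0("b_", genotypes[2])]]
  cv_wt <- wide[[paste0("converged_", genotypes[1])]]
  cv_mut <- wide[[paste0("converged_", genotypes[2])]]
  tibble::tibble(
    gene = wide$gene,
    tau_WT = b_wt, tau_ppk = b_mut,
    category = classify_stability_pair(b_wt, b_mut, cv_wt, cv_mut, ...)
  )
}

#' Half-life shift of a gene set relative to all other genes
#'
#' For each gene computes the change in decay constant between genotypes,
#' delta = tau_WT - tau_ppk, then compares the gene set against its
#' complement: reports the percent difference of median changes,
#' (median(delta, in set) / median(delta, out of set) - 1) * 100, and a
#' two-sided Wilcoxon rank-sum p-value (normal approximation with tie
#' correction).
#'
#' @param stability Tibble with `gene`, `tau_WT`, `tau_ppk` (e.g. from
#'   [classify_stability()]).
#' @param gene_set Character vector of gene ids; must be a non-empty
#'   strict subset of the genes present.
#' @return A one-row tibble: `percent_shift`, `p_value`, `median_in`,
#'   `median_out`, `n_in`, `n_out`.
#' @export
gene_set_halflife_shift <- function(stability, gene_set) {
  d <- stability |>
    dplyr::mutate(delta = .data$tau_WT - .data$tau_ppk) |>
    dplyr::filter(is.finite(.data$delta))
  in_set <- d$gene %in% gene_set
  if (!any(in_set)) rlang::abort("`gene_set` matches no fitted gene.")
  if (all(in_set)) rlang::abort("`gene_set` must be a strict subset of fitted genes.")
  di <- d$delta[in_set]; do <- d$delta[!in_set]
  wt <- suppressWarnings(
    wilcox.test(di, do, alternative = "two.sided", exact = FALSE)
  )
  tibble::tibble(
    percent_shift = (median(di) / median(do) - 1) * 100,
    p_value = wt$p.value,
    median_in = median(di), median_out = median(do),
    n_in = length(di), n_out = length(do)
  )
}
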