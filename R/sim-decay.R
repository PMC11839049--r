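#' Configuration for the rifampicin-chase count simulator
#'
#' Describes a transcription-shutoff time course: per-gene exponential
#' decay of transcript abundance sampled with Poisson noise, plus ERCC
#' spike-in features whose expected abundance is constant across
#' timepoints (they are added per cell, not per transcriptome, which is
#' what makes spike-in normalization recover absolute decay).
#'
#' @param gene_params Tibble with columns `gene`, `a` (baseline abundance,
#'   arbitrary units, >= 0) and `b` (decay time constant in minutes, > 0).
#'   If `NULL`, `n_genes` genes are generated with log-normal baselines
#'   and decay constants uniform on 5-70 minutes.
#' @param n_genes Number of genes when `gene_params` is `NULL`.
#' @param timepoints Minutes after rifampicin addition (default
#'   0, 10, 30, 60).
#' @param n_replicates Replicate time courses.
#' @param spikein_abund Named numeric vector of constant ERCC abundances;
#'   names must start with `"ERCC-"`. If `NULL`, 30 spike-ins spanning a
#'   log-uniform abundance range are generated.
#' @param depth Expected total reads per sample at t = 0.
#' @param noise `"poisson"` (default) or `"none"` (expected counts,
#'   non-integer; useful for exactness checks).
#' @param genotype Genotype label written into the sample sheet.
#' @param seed Integer seed; mandatory.
#' @return A list of class `"decay_sim_config"`.
#' @export
decay_sim_config <- function(gene_params = NULL, n_genes = 200,
                             timepoints = c(0, 10, 30, 60),
                             n_replicates = 1,
                             spikein_abund = NULL,
                             depth = 1e6,
                             noise = c("poisson", "none"),
                             genotype = "WT",
                             seed) {
  noise <- match.arg(noise)
  if (missing(seed)) rlang::abort("`seed` is mandatory for all simulators.")
  stopifnot_scalar_number(depth, "depth", lower = 0, strict_lower = TRUE)
  if (any(timepoints < 0) || is.unsorted(timepoints, strictly = TRUE)) {
    rlang::abort("`timepoints` must be non-negative and strictly increasing.")
  }
  if (!is.null(gene_params)) {
    if (!all(c("gene", "a", "b") %in% names(gene_params))) {
      rlang::abort("`gene_params` needs columns gene, a, b.")
    }
    if (any(gene_params$a < 0) || any(gene_params$b <= 0)) {
      rlang::abort("require a >= 0 and b > 0 for every gene.")
    }
  }
  if (!is.null(spikein_abund) &&
      (is.null(names(spikein_abund)) || !all(startsWith(names(spikein_abund), "ERCC-")))) {
    rlang::abort("`spikein_abund` must be named, with names starting 'ERCC-'.")
  }
  structure(
    list(gene_params = gene_params, n_genes = as.integer(n_genes),
         timepoints = timepoints, n_replicates = as.integer(n_replicates),
         spikein_abund = spikein_abund, depth = depth, noise = noise,
         genotype = genotype, seed = as.integer(seed)),
    class = "decay_sim_config"
  )
}

#' Simulate a spike-in-bearing rifampicin-chase count table
#'
#' Expected genomic counts follow a_g * exp(-t / b_g) (times a global
#' depth scale, exported in the ground truth); ERCC rows are constant in
#' expectation across timepoints. Counts are Poisson-sampled unless noise
#' is disabled.
#'
#' @param config A [decay_sim_config()].
#' @return A list of class `"decay_sim"` with `counts` (tibble: `feature`
#'   column then one column per sample), `samples` (sample sheet tibble:
#'   `sample`, `genotype`, `timepoint_min`, `replicate`, `rifampicin`) and
#'   `truth` (list with `gene_params`, `spikein_abund`, `scale`).
#' @export
simulate_decay_counts <- function(config) {
  if (!inherits(config, "decay_sim_config")) {
    rlang::abort("`config` must be created by decay_sim_config().")
  }
  with_seed(config$seed, {
    gp <- config$gene_params
    if (is.null(gp)) {
      gp <- tibble::tibble(
        gene = sprintf("gene_%04d", seq_len(config$n_genes)),
        a = stats::rlnorm(config$n_genes, meanlog = log(100), sdlog = 1),
        b = runif(config$n_genes, 5, 70)
      )
    }
    sp <- config$spikein_abund
    if (is.null(sp)) {
      # abundances sit well above the 5e-4 relative-abundance filter at
      # every timepoint, so the median is taken over a stable spike-in set
      total_a <- sum(gp$a)
      sp <- setNames(
        exp(seq(log(total_a * 2e-3), log(total_a * 4e-2), length.out = 30)),
        sprintf("ERCC-%05d", seq_len(30))
      )
    }
    scale <- config$depth / (sum(gp$a) + sum(sp))

    grid <- expand.grid(replicate = seq_len(config$n_replicates),
                        timepoint = config$timepoints)
    sample_ids <- sprintf("%s_t%g_r%d", config$genotype, grid$timepoint,
                          grid$replicate)
    mat <- matrix(0, nrow = nrow(gp) + length(sp), ncol = length(sample_ids),
                  dimnames = list(c(gp$gene, names(sp)), sample_ids))
    for (j in seq_along(sample_ids)) {
      mu <- c(scale * gp$a * exp(-grid$timepoint[j] / gp$b), scale * sp)
      mat[, j] <- if (config$noise == "poisson") rpois(length(mu), mu) else mu
    }
    structure(
      list(
        counts = tibble::as_tibble(cbind(
          tibble::tibble(feature = rownames(mat)),
          tibble::as_tibble(mat)
        )),
        samples = tibble::tibble(
          sample = sample_ids,
          genotype = config$genotype,
          timepoint_min = grid$timepoint,
          replicate = grid$replicate,
          rifampicin = TRUE
        ),
        truth = list(gene_params = gp, spikein_abund = sp, scale = scale)
      ),
      class = "decay_sim"
    )
  })
}
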