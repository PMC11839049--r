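#' Configuration for the 3'-end read simulator
#'
#' Emulates 3'-end sequencing of untemplated poly(A) tails: reads start
#' (in sequencing orientation) with a run of 'T' bases whose length is
#' drawn from a per-gene zero-inflated negative binomial whose mean
#' depends on the genotype-by-condition cell, followed by non-T template
#' bases. Reads anchor inside the gene's 3' tail window and align
#' antisense to the gene.
#'
#' @param gene_models Tibble with columns `gene`, `chrom`, `strand`
#'   (`"+"`/`"-"`), `start`, `end` (0-based half-open). If `NULL`,
#'   `n_genes` well-separated genes are generated on one chromosome.
#' @param n_genes Number of genes when `gene_models` is `NULL`.
#' @param cell_means Matrix (genes x 4) of mean tail lengths per
#'   genotype-by-condition cell, columns named
#'   `WT.Nplus`, `WT.N24`, `ppk.Nplus`, `ppk.N24`. A single row is
#'   recycled. Default: mean 5 everywhere.
#' @param zero_inflation Per-gene zero-inflation probability pi in
#'   \[0, 1\] (recycled).
#' @param overdispersion Per-gene negative-binomial size theta > 0
#'   (recycled).
#' @param reads_per_gene_per_sample Reads simulated per gene per sample.
#' @param replicates_per_cell Biological replicates per cell (default 4,
#'   giving 16 samples over the 4 cells).
#' @param read_length Read length in bases.
#' @param seed Integer seed; mandatory.
#' @return A list of class `"polya_sim_config"`.
#' @export
polya_sim_config <- function(gene_models = NULL, n_genes = 20,
                             cell_means = NULL,
                             zero_inflation = 0.1,
                             overdispersion = 5,
                             reads_per_gene_per_sample = 100,
                             replicates_per_cell = 4,
                             read_length = 50,
                             seed) {
  if (missing(seed)) rlang::abort("`seed` is mandatory for all simulators.")
  cells <- c("WT.Nplus", "WT.N24", "ppk.Nplus", "ppk.N24")
  if (is.null(gene_models)) {
    gene_models <- tibble::tibble(
      gene = sprintf("gene_%03d", seq_len(n_genes)),
      chrom = "chr1",
      strand = rep(c("+", "-"), length.out = n_genes),
      start = 1000L + (seq_len(n_genes) - 1L) * 2000L,
      end = 1000L + (seq_len(n_genes) - 1L) * 2000L + 900L
    )
  }
  if (any(gene_models$start >= gene_models$end)) {
    rlang::abort("gene models must satisfy start < end (0-based half-open).")
  }
  ng <- nrow(gene_models)
  if (is.null(cell_means)) {
    cell_means <- matrix(5, nrow = ng, ncol = 4, dimnames = list(NULL, cells))
  }
  if (is.null(dim(cell_means))) cell_means <- matrix(cell_means, nrow = 1)
  if (nrow(cell_means) == 1) cell_means <- cell_means[rep(1, ng), , drop = FALSE]
  if (is.null(colnames(cell_means))) colnames(cell_means) <- cells
  if (any(cell_means < 0)) rlang::abort("cell means must be non-negative.")
  zero_inflation <- rep_len(zero_inflation, ng)
  overdispersion <- rep_len(overdispersion, ng)
  if (any(zero_inflation < 0 | zero_inflation > 1)) {
    rlang::abort("`zero_inflation` must lie in [0, 1].")
  }
  if (any(overdispersion <= 0)) rlang::abort("`overdispersion` must be > 0.")
  structure(
    list(gene_models = gene_models, cell_means = cell_means,
         zero_inflation = zero_inflation, overdispersion = overdispersion,
         reads_per_gene_per_sample = as.integer(reads_per_gene_per_sample),
         replicates_per_cell = as.integer(replicates_per_cell),
         read_length = as.integer(read_length),
         cells = cells, seed = as.integer(seed)),
    class = "polya_sim_config"
  )
}

#' Draw zero-inflated negative binomial tail lengths
#'
#' @param n Number of draws.
#' @param mu Negative-binomial mean.
#' @param theta Negative-binomial size (overdispersion; variance is
#'   mu + mu^2 / theta).
#' @param pi Zero-inflation probability.
#' @return Integer vector of tail lengths.
#' @export
rzinb <- function(n, mu, theta, pi) {
  k <- rnbinom(n, size = theta, mu = mu)
  zero <- runif(n) < pi
  k[zero] <- 0L
  k
}

#' Simulate 3'-end reads carrying untemplated poly(A) tails
#'
#' @param config A [polya_sim_config()].
#' @return A list of class `"polya_sim"` with `reads` (tibble: `read_id`,
#'   `chrom`, `pos0`, `strand`, `sequence`, `sample`), `genes` (the gene
#'   models), `design` (tibble: `sample`, `genotype`, `condition`,
#'   `replicate`) and `truth` (per-gene `cell_means`, `zero_inflation`,
#'   `overdispersion`, and per-read true tail lengths).
#' @export
simulate_polya_reads <- function(config) {
  if (!inherits(config, "polya_sim_config")) {
    rlang::abort("`config` must be created by polya_sim_config().")
  }
  with_seed(config$seed, simulate_polya_impl(config))
}

simulate_polya_impl <- function(config) {
  genes <- config$gene_models
  wins <- tail_windows(genes)
  # warn on same-strand window overlap (tail assignment is ambiguous there)
  ov <- wins |>
    dplyr::arrange(.data$chrom, .data$strand, .data$w_start) |>
    dplyr::mutate(
      overlap = .data$w_start < dplyr::lag(.data$w_end, default = -Inf),
      .by = c("chrom", "strand")
    )
  if (any(ov$overlap)) {
    rlang::warn("tail windows of same-strand genes overlap; reads there are ambiguous.")
  }

  cells <- config$cells
  design <- tidyr::expand_grid(
    cell = cells, replicate = seq_len(config$replicates_per_cell)
  ) |>
    tidyr::separate_wider_delim("cell", ".", names = c("genotype", "condition"),
                                cols_remove = FALSE) |>
    dplyr::mutate(sample = sprintf("%s_r%d", .data$cell, .data$replicate)) |>
    dplyr::select("sample", "genotype", "condition", "replicate", "cell")

  rl <- config$read_length
  npg <- config$reads_per_gene_per_sample
  out <- vector("list", nrow(genes) * nrow(design))
  idx <- 0L
  for (g in seq_len(nrow(genes))) {
    w <- wins[wins$gene == genes$gene[g], ]
    for (s in seq_len(nrow(design))) {
      idx <- idx + 1L
      if (npg == 0) next
      mu <- config$cell_means[g, design$cell[s]]
      k <- rzinb(npg, mu, config$overdispersion[g], config$zero_inflation[g])
      # a tail longer than the read would leave nothing alignable; keep at
      # least 10 template bases
      k <- pmin(k, rl - 10L)
      anchor <- sample(seq(w$w_start, w$w_end - 1L), npg, replace = TRUE)
      tmpl_len <- rl - k
      tmpl <- vapply(tmpl_len, function(L) {
        paste(sample(c("A", "C", "G"), L, replace = TRUE), collapse = "")
      }, character(1))
      seqs <- paste0(strrep("T", k), tmpl)
      if (genes$strand[g] == "+") {
        read_strand <- "-"
        pos0 <- anchor - tmpl_len
      } else {
        read_strand <- "+"
        pos0 <- anchor
      }
      out[[idx]] <- tibble::tibble(
        read_id = sprintf("%s_%s_%04d", genes$gene[g], design$sample[s], seq_len(npg)),
        chrom = genes$chrom[g],
        pos0 = as.integer(pmax(pos0, 0L)),
        strand = read_strand,
        sequence = seqs,
        sample = design$sample[s],
        true_gene = genes$gene[g],
        true_tail = as.integer(k)
      )
    }
  }
  reads <- dplyr::bind_rows(out)
  if (nrow(reads) == 0) {
    reads <- tibble::tibble(
      read_id = character(), chrom = character(), pos0 = integer(),
      strand = character(), sequence = character(), sample = character(),
      true_gene = character(), true_tail = integer()
    )
  }
  structure(
    list(
      reads = dplyr::select(reads, -"true_gene", -"true_tail"),
      genes = genes,
      design = dplyr::select(design, -"cell"),
      truth = list(
        cell_means = config$cell_means,
        zero_inflation = config$zero_inflation,
        overdispersion = config$overdispersion,
        per_read = dplyr::select(reads, "read_id", "true_gene", "true_tail")
      )
    ),
    class = "polya_sim"
  )
}
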