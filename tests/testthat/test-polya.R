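test_that("terminal-A counting handles the canonical cases", {
  expect_equal(count_terminal_A("TTTTTACGGA"), 5L)
  expect_equal(count_terminal_A("ACGTACGT"), 0L)
  expect_equal(count_terminal_A(strrep("T", 25)), 25L)
  expect_equal(count_terminal_A("ttTTa"), 4L)   # case-insensitive
  expect_equal(count_terminal_A("TTTTTACGGTA", mode = "total_t"), 6L)
  expect_equal(count_terminal_A("TTTTTACGGTA", mode = "terminal_run"), 5L)
  expect_error(count_terminal_A(""), "non-empty")
})

test_that("terminal-A counting satisfies its structural properties", {
  set.seed(30)
  for (i in 1:50) {
    s <- paste(sample(c("A", "C", "G", "T"), sample(5:40, 1), replace = TRUE),
               collapse = "")
    n <- count_terminal_A(s)
    expect_lte(n, nchar(s))
    expect_equal(count_terminal_A(paste0("T", s)), n + 1L)
  }
})

test_that("tail windows span 50 bp before to 250 bp after the gene end", {
  genes <- tibble::tibble(
    gene = c("plus", "minus"), chrom = "chr1",
    strand = c("+", "-"), start = c(1000L, 5000L), end = c(2000L, 6000L)
  )
  w <- tail_windows(genes)
  expect_equal(w$w_start[w$gene == "plus"], 1950)
  expect_equal(w$w_end[w$gene == "plus"], 2250)
  expect_equal(w$w_start[w$gene == "minus"], 4750)
  expect_equal(w$w_end[w$gene == "minus"], 5050)
  expect_true(all(w$w_end - w$w_start == 300))
})

test_that("read assignment respects window boundaries and orientation", {
  genes <- tibble::tibble(gene = "g1", chrom = "chr1", strand = "+",
                          start = 1000L, end = 2000L)
  mk_read <- function(id, anchor, strand = "-", tail = 5, len = 30) {
    seq <- paste0(strrep("T", tail),
                  strrep("C", len - tail))
    pos0 <- if (strand == "-") anchor - (len - tail) else anchor
    tibble::tibble(read_id = id, chrom = "chr1", pos0 = as.integer(pos0),
                   strand = strand, sequence = seq, sample = "s1")
  }
  inside <- mk_read("r_in", 2100)
  outside <- mk_read("r_out", 2300)
  wrong_strand <- mk_read("r_fwd", 2100, strand = "+")
  asg <- suppressMessages(assign_reads_to_tail_windows(
    dplyr::bind_rows(inside, outside, wrong_strand), genes
  ))
  expect_equal(asg$read_id, "r_in")
  expect_equal(asg$tail_length, 5L)
  expect_equal(attr(asg, "n_unassigned"), 2)

  # half-open right boundary: anchor 2250 is out, 2249 is in
  edge <- suppressMessages(assign_reads_to_tail_windows(
    dplyr::bind_rows(mk_read("edge_in", 2249), mk_read("edge_out", 2250)),
    genes
  ))
  expect_equal(edge$read_id, "edge_in")
})

test_that("assignment is strand-symmetric under coordinate mirroring", {
  L <- 10000L
  genes <- tibble::tibble(gene = "g", chrom = "c", strand = "+",
                          start = 1000L, end = 2000L)
  mirror_genes <- tibble::tibble(gene = "g", chrom = "c", strand = "-",
                                 start = L - 2000L, end = L - 1000L)
  set.seed(31)
  anchors <- sample(1900:2300, 30)
  tails <- sample(0:10, 30, replace = TRUE)
  len <- 40L
  reads <- tibble::tibble(
    read_id = paste0("r", 1:30), chrom = "c",
    pos0 = as.integer(anchors - (len - tails)), strand = "-",
    sequence = paste0(strrep("T", tails), strrep("C", len - tails)),
    sample = "s1"
  )
  mirror_reads <- dplyr::mutate(reads, pos0 = as.integer(L - anchors),
                                strand = "+")
  a1 <- suppressMessages(assign_reads_to_tail_windows(reads, genes))
  a2 <- suppressMessages(assign_reads_to_tail_windows(mirror_reads, mirror_genes))
  expect_equal(sort(a1$read_id), sort(a2$read_id))
  expect_equal(a1$tail_length[order(a1$read_id)],
               a2$tail_length[order(a2$read_id)])
})

test_that("simulated reads round-trip to their source genes", {
  cfg <- polya_sim_config(n_genes = 8, reads_per_gene_per_sample = 25, seed = 32)
  sim <- simulate_polya_reads(cfg)
  asg <- assign_reads_to_tail_windows(sim$reads, sim$genes)
  expect_equal(nrow(asg), nrow(sim$reads))
  expect_equal(attr(asg, "n_unassigned"), 0)
  expect_equal(attr(asg, "n_multi"), 0)
  chk <- dplyr::inner_join(asg, sim$truth$per_read, by = "read_id")
  expect_equal(chk$gene, chk$true_gene)
  expect_equal(chk$tail_length, chk$true_tail)
})

test_that("ZINB log-likelihood equals direct summation", {
  set.seed(33)
  cells <- rep(c("WT.Nplus", "WT.N24", "ppk.Nplus", "ppk.N24"), each = 300)
  mu <- c(WT.Nplus = 6, WT.N24 = 9, ppk.Nplus = 5, ppk.N24 = 2)
  k <- rzinb(length(cells), mu[cells], theta = 4, pi = 0.25)
  fit <- fit_zinb_tail_model(k, cells)
  expect_true(fit$converged)
  oracle <- oracle_zinb_loglik(k, fit$mu[cells], fit$theta, fit$pi)
  expect_lt(abs(oracle - fit$loglik), 1e-8)
  # and at arbitrary (non-fitted) parameters too
  beta <- log(c(WT.N24 = 3, WT.Nplus = 4, ppk.N24 = 5, ppk.Nplus = 6))
  expect_lt(abs(zinb_loglik(k, cells, beta, 0.4, 2) -
                  oracle_zinb_loglik(k, exp(beta)[cells], 2, 0.4)), 1e-8)
})

test_that("ZINB fits recover planted parameters", {
  set.seed(34)
  cells <- rep(c("WT.Nplus", "WT.N24", "ppk.Nplus", "ppk.N24"), each = 2000)
  mu_true <- c(WT.Nplus = 8, WT.N24 = 8, ppk.Nplus = 2, ppk.N24 = 2)
  k <- rzinb(length(cells), mu_true[cells], theta = 5, pi = 0.3)
  fit <- fit_zinb_tail_model(k, cells)
  expect_true(fit$converged)
  expect_lt(abs(fit$pi - 0.3), 0.05)
  expect_true(all(abs(fit$mu[names(mu_true)] / mu_true - 1) < 0.10))
  expect_lt(abs(fit$theta / 5 - 1), 0.25)
})

test_that("with no zero inflation the ZINB matches a plain NB fit", {
  set.seed(35)
  cells <- rep(c("WT.Nplus", "WT.N24", "ppk.Nplus", "ppk.N24"), each = 1000)
  k <- rnbinom(length(cells), size = 10, mu = 5)
  fit <- fit_zinb_tail_model(k, cells)
  expect_lt(fit$pi, 0.02)
  # nested-model oracle: NB likelihood maximized independently
  nb_nll <- function(par) {
    -sum(dnbinom(k, size = exp(par[5]),
                 mu = exp(par[as.integer(factor(cells))]), log = TRUE))
  }
  nb_opt <- optim(c(rep(log(5), 4), log(10)), nb_nll, method = "BFGS")
  expect_lt(abs(-nb_opt$value - fit$loglik), 1e-2)
  expect_gte(fit$loglik, -nb_opt$value - 1e-6)
})

test_that("degenerate and underpopulated genes are flagged, not fitted", {
  all_zero <- fit_zinb_tail_model(rep(0L, 40),
                                  rep(c("WT.Nplus", "WT.N24", "ppk.Nplus", "ppk.N24"), 10))
  expect_true(all_zero$degenerate)
  expect_equal(all_zero$pi, 1)
  expect_false(all_zero$converged)

  one_cell <- fit_zinb_tail_model(c(1L, 2L, 3L), rep("WT.N24", 3))
  expect_true(one_cell$unfit)
})

test_that("tail-shift summaries detect planted effects and respect symmetry", {
  cells4 <- c("WT.Nplus", "WT.N24", "ppk.Nplus", "ppk.N24")
  mu_null <- matrix(rep(6, 4), nrow = 1, dimnames = list(NULL, cells4))
  mu_eff <- matrix(c(6, 8, 6, 2), nrow = 1, dimnames = list(NULL, cells4))
  cfg <- polya_sim_config(
    n_genes = 10,
    cell_means = rbind(mu_eff[rep(1, 5), ], mu_null[rep(1, 5), ]),
    zero_inflation = 0.1, overdispersion = 8,
    reads_per_gene_per_sample = 150, seed = 36
  )
  sim <- simulate_polya_reads(cfg)
  asg <- assign_reads_to_tail_windows(sim$reads, sim$genes)
  fits <- fit_zinb_tails(asg, sim$design)
  sm <- summarize_tail_shifts(fits)
  n24 <- dplyr::filter(sm$shifts, condition == "N24")
  eff <- dplyr::filter(n24, gene %in% sprintf("gene_%03d", 1:5))
  null <- dplyr::filter(n24, !gene %in% sprintf("gene_%03d", 1:5))
  expect_true(all(eff$delta < 0))
  expect_true(all(eff$p_adj < 0.05))
  expect_true(all(abs(null$delta) < 1.5))
  # cumulative distributions cover each cell and end at 1
  top <- dplyr::summarise(sm$cdf, m = max(cum_fraction), .by = "cell")
  expect_true(all(top$m == 1))
})

test_that("single-gene summaries leave the adjusted p equal to the raw p", {
  set.seed(37)
  cells <- rep(c("WT.Nplus", "WT.N24", "ppk.Nplus", "ppk.N24"), each = 400)
  k <- rzinb(length(cells), 5, theta = 6, pi = 0.1)
  fit <- fit_zinb_tail_model(k, cells)
  fits <- tibble::tibble(
    gene = "g1", pi = fit$pi, theta = fit$theta, loglik = fit$loglik,
    converged = fit$converged, degenerate = FALSE, unfit = FALSE,
    n_reads = length(k)
  )
  fits$fit <- list(fit)
  sm <- summarize_tail_shifts(fits)
  expect_equal(sm$shifts$p_adj, sm$shifts$p_value)
})
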