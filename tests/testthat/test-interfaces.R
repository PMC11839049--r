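# Round trips through the plain-text interchange formats, plus the tidy()
# / glance() / autoplot() surfaces.

test_that("trajectory tables round-trip through CSV", {
  sim <- simulate_spt(spt_sim_config(n_trajectories = 10, seed = 70))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectories(sim$tracks, path)
  back <- read_trajectories(path)
  expect_equal(as.data.frame(back), as.data.frame(sim$tracks))
})

test_that("count tables and sample sheets round-trip through TSV", {
  sim <- simulate_decay_counts(decay_sim_config(n_genes = 10, seed = 71))
  cpath <- withr::local_tempfile(fileext = ".tsv")
  spath <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(sim$counts, cpath)
  readr::write_tsv(sim$samples, spath)
  expect_equal(as.data.frame(read_counts_tsv(cpath)),
               as.data.frame(sim$counts))
  expect_equal(as.data.frame(read_sample_sheet(spath)),
               as.data.frame(sim$samples))
})

test_that("annotation maps are read from TSV and GAF alike", {
  ann <- tibble::tibble(protein = c("P1", "P2"), term = c("GO:1", "GO:2"))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(ann, tsv, col_names = FALSE)
  expect_equal(as.data.frame(read_annotation(tsv)), as.data.frame(ann))

  gaf <- withr::local_tempfile(fileext = ".gaf")
  writeLines(c(
    "!gaf-version: 2.2",
    "UniProtKB\tP1\tsym1\t\tGO:1\tREF\tIEA\t\tF\t\t\tprotein\ttaxon:83333\t20200101\tUniProt",
    "UniProtKB\tP2\tsym2\t\tGO:2\tREF\tIEA\t\tF\t\t\tprotein\ttaxon:83333\t20200101\tUniProt"
  ), gaf)
  expect_equal(as.data.frame(read_annotation(gaf)), as.data.frame(ann))
})

test_that("reads load identically from the tabular form and from SAM", {
  skip_if_not_installed("Rsamtools")
  sim <- simulate_polya_reads(polya_sim_config(n_genes = 2, seed = 72,
                                               reads_per_gene_per_sample = 5))
  tab <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(sim$reads, tab)
  from_tab <- read_reads_tabular(tab)
  expect_equal(as.data.frame(from_tab), as.data.frame(sim$reads))

  sam <- withr::local_tempfile(fileext = ".sam")
  maxpos <- max(sim$reads$pos0) + 200L
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:chr1\tLN:%d", maxpos))
  body <- vapply(seq_len(nrow(sim$reads)), function(i) {
    r <- sim$reads[i, ]
    flag <- if (r$strand == "-") 16L else 0L
    # store the as-sequenced read; SAM stores reverse-complement for
    # minus-strand alignments
    seq_sam <- if (r$strand == "-") {
      chartr("ACGT", "TGCA", paste(rev(strsplit(r$sequence, "")[[1]]),
                                   collapse = ""))
    } else r$sequence
    sprintf("%s\t%d\tchr1\t%d\t60\t%dM\t*\t0\t0\t%s\t*",
            r$read_id, flag, r$pos0 + 1L, nchar(r$sequence), seq_sam)
  }, character(1))
  writeLines(c(hdr, body), sam)
  from_sam <- read_reads_sam(sam, sample = "s")
  from_sam <- from_sam[match(sim$reads$read_id, from_sam$read_id), ]
  expect_equal(from_sam$pos0, sim$reads$pos0)
  expect_equal(from_sam$strand, sim$reads$strand)
  # Rsamtools returns the stored (reference-strand) sequence; recover the
  # as-sequenced orientation for minus-strand reads before comparing
  seq_back <- ifelse(
    from_sam$strand == "-",
    vapply(from_sam$sequence, function(s) {
      chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
    }, character(1), USE.NAMES = FALSE),
    from_sam$sequence
  )
  expect_equal(seq_back, sim$reads$sequence)
})

test_that("gene models load from GFF3 with converted coordinates", {
  skip_if_not_installed("rtracklayer")
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\ttest\tgene\t1001\t2000\t.\t+\t.\tID=geneA",
    "chr1\ttest\tgene\t5001\t6000\t.\t-\t.\tID=geneB",
    "chr1\ttest\texon\t1001\t1500\t.\t+\t.\tID=exon1"
  ), gff)
  gm <- read_gene_models(gff)
  expect_equal(gm$gene, c("geneA", "geneB"))
  expect_equal(gm$start, c(1000L, 5000L))  # 0-based half-open
  expect_equal(gm$end, c(2000L, 6000L))
  expect_equal(gm$strand, c("+", "-"))
})

test_that("TIFF movies round-trip into composite sums", {
  skip_if_not_installed("tiff")
  frames <- replicate(3, matrix(runif(64, 0, 0.9), 8, 8), simplify = FALSE)
  path <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(frames, path, bits.per.sample = 32L)
  back <- read_movie_tiff(path)
  expect_length(back, 3)
  expect_equal(sum_frames(back)$intensity, Reduce(`+`, frames),
               tolerance = 1e-6)
})

test_that("tidy and glance methods expose the fitted quantities", {
  sim <- simulate_spt(spt_sim_config(n_trajectories = 800, condensate = NULL,
                                     D = 1, weights = 1, seed = 73))
  fit <- fit_displacement_cdf(pool_squared_displacements(sim$tracks, 0.02),
                              n_states = 2)
  td <- tidy(fit)
  expect_named(td, c("state", "D", "alpha"))
  expect_equal(sum(td$alpha), 1, tolerance = 1e-8)
  expect_true(glance(fit)$converged)

  frap <- fit_frap_recovery(seq(0, 60, 5), 0.2 + 0.5 * (1 - exp(-0.08 * seq(0, 60, 5))),
                            n_boot = 0)
  expect_equal(tidy(frap)$estimate[tidy(frap)$term == "k"], 0.08,
               tolerance = 1e-6)

  set.seed(74)
  zf <- fit_zinb_tail_model(
    rzinb(800, 5, 5, 0.2),
    rep(c("WT.Nplus", "WT.N24", "ppk.Nplus", "ppk.N24"), each = 200)
  )
  expect_equal(nrow(tidy(zf)), 4)
  expect_named(glance(zf), c("pi", "theta", "loglik", "converged",
                             "degenerate", "unfit", "iterations"))
})

test_that("autoplot and plot helpers return ggplot objects", {
  sim <- simulate_spt(spt_sim_config(n_trajectories = 500, condensate = NULL,
                                     D = 1, weights = 1, seed = 75))
  pool <- pool_squared_displacements(sim$tracks, 0.02)
  fit <- fit_displacement_cdf(pool, n_states = 2)
  expect_s3_class(autoplot(fit), "ggplot")
  expect_s3_class(plot_displacement_cdf(pool, fit), "ggplot")

  img <- make_blob_image(32, centers = rbind(c(16, 16)), sigma_px = 4)
  expect_s3_class(plot_composite(img, detect_foci(img)), "ggplot")

  go <- simulate_go_universe(go_sim_config(universe_size = 60, n_terms = 80,
                                           set_sizes = c(hp = 10, pb = 12, sg = 12),
                                           seed = 76))
  pt <- permutation_overlap_test(go$sets$hp, go$universe, go$annotation,
                                 go$truth$pb_terms, go$truth$sg_terms,
                                 n_perm = 100, seed = 77)
  expect_s3_class(autoplot(pt), "ggplot")
  expect_named(tidy(pt), c("statistic", "observed", "null_mean", "p_value"))
})
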