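# Readers and writers for the plain-text interchange formats used by the
# pipeline. Standard genomic formats are delegated to Rsamtools /
# rtracklayer / tiff when those packages are available.

#' Read a trajectory table
#'
#' CSV with columns `trajectory_id`, `frame`, `x_um`, `y_um`.
#' @param path File path.
#' @return Tibble.
#' @export
read_trajectories <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           trajectory_id = readr::col_character(),
                           frame = readr::col_integer(),
                           x_um = readr::col_double(),
                           y_um = readr::col_double()
                         ))
  bad <- out |>
    dplyr::summarise(ok = !is.unsorted(.data$frame, strictly = TRUE),
                     .by = "trajectory_id")
  if (any(!bad$ok)) {
    rlang::abort("frames within a trajectory must be strictly increasing.")
  }
  out
}

#' Write a trajectory table
#' @param tracks Tibble with `trajectory_id`, `frame`, `x_um`, `y_um`.
#' @param path File path.
#' @export
write_trajectories <- function(tracks, path) {
  readr::write_csv(tracks[c("trajectory_id", "frame", "x_um", "y_um")], path)
}

#' Read a feature-by-sample count table (TSV, first column `feature`)
#' @param path File path.
#' @return Tibble.
#' @export
read_counts_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Read a sample sheet (TSV)
#'
#' Expected columns: `sample`, `genotype`, `timepoint_min`, `replicate`
#' and optionally `rifampicin`.
#' @param path File path.
#' @return Tibble.
#' @export
read_sample_sheet <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Read aligned reads from a tabular fallback format
#'
#' TSV with columns `read_id`, `chrom`, `pos0`, `strand`, `sequence` and
#' optionally `sample` (defaulting to the file name).
#' @param path File path.
#' @param sample Sample id to attach when the file has no `sample` column.
#' @return Tibble.
#' @export
read_reads_tabular <- function(path, sample = NULL) {
  out <- readr::read_tsv(path, show_col_types = FALSE)
  if (!"sample" %in% names(out)) {
    out$sample <- sample %||% basename(path)
  }
  out
}

#' Read aligned reads from SAM/BAM
#'
#' Requires the Rsamtools package. Soft-clipped bases are retained in the
#' returned sequence (tail bases are soft-clipped under local alignment,
#' and the tail caller needs them).
#' @param path SAM or BAM file.
#' @param sample Sample id to attach.
#' @return Tibble with `read_id`, `chrom`, `pos0`, `strand`, `sequence`,
#'   `sample`.
#' @export
read_reads_sam <- function(path, sample = NULL) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    rlang::abort("reading SAM/BAM requires the Rsamtools package.")
  }
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    path <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE)
  }
  b <- Rsamtools::scanBam(
    path,
    param = Rsamtools::ScanBamParam(
      what = c("qname", "rname", "pos", "strand", "seq")
    )
  )[[1]]
  keep <- !is.na(b$pos)
  tibble::tibble(
    read_id = b$qname[keep],
    chrom = as.character(b$rname)[keep],
    pos0 = b$pos[keep] - 1L,
    strand = as.character(b$strand)[keep],
    sequence = as.character(b$seq)[keep],
    sample = sample %||% basename(path)
  )
}

#' Read gene models from GFF3, BED or TSV
#'
#' GFF3/BED go through rtracklayer; a TSV with columns `gene`, `chrom`,
#' `strand`, `start`, `end` (0-based half-open) is read directly.
#' Coordinates from GFF3/BED are converted to 0-based half-open.
#' @param path File path.
#' @param feature_type For GFF3, which feature type to keep
#'   (default `"gene"`).
#' @return Tibble: `gene`, `chrom`, `strand`, `start`, `end`.
#' @export
read_gene_models <- function(path, feature_type = "gene") {
  if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) {
    return(readr::read_tsv(path, show_col_types = FALSE))
  }
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    rlang::abort("reading GFF3/BED requires the rtracklayer package.")
  }
  gr <- rtracklayer::import(path)
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    md <- S4Vectors::mcols(gr)
    if ("type" %in% names(md)) gr <- gr[md$type == feature_type]
    md <- S4Vectors::mcols(gr)
    ids <- if ("ID" %in% names(md)) md$ID else
      if ("Name" %in% names(md)) md$Name else as.character(seq_along(gr))
  } else {
    md <- S4Vectors::mcols(gr)
    ids <- if ("name" %in% names(md)) md$name else as.character(seq_along(gr))
  }
  tibble::tibble(
    gene = as.character(ids),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
}

#' Read a protein-to-GO annotation map
#'
#' Accepts a two-column TSV (`protein`, `term`, with or without header)
#' or a GAF 2.x file (comment lines starting with `!`; columns 2 and 5
#' hold the object id and GO id).
#' @param path File path.
#' @return Tibble: `protein`, `term`.
#' @export
read_annotation <- function(path) {
  first <- readLines(path, n = 1)
  if (startsWith(first, "!") || grepl("\\.gaf(\\.gz)?$", path)) {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "!")]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    return(tibble::tibble(
      protein = vapply(parts, `[`, character(1), 2),
      term = vapply(parts, `[`, character(1), 5)
    ))
  }
  out <- readr::read_tsv(path, show_col_types = FALSE,
                         col_names = c("protein", "term"))
  if (identical(unname(unlist(out[1, ])), c("protein", "term"))) {
    out <- out[-1, ]
  }
  out
}

#' Read a multi-frame TIFF movie
#'
#' Requires the tiff package.
#' @param path TIFF file.
#' @return List of numeric frame matrices.
#' @export
read_movie_tiff <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    rlang::abort("reading TIFF movies requires the tiff package.")
  }
  frames <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  lapply(frames, function(f) if (length(dim(f)) == 3) f[, , 1] else f)
}

#' Write a ground-truth or results list as JSON
#' @param x A list of numbers/vectors/tables.
#' @param path Output path.
#' @export
write_json_results <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}
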