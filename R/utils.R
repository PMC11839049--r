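# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random-number stream. All exported generators funnel their randomness
# through this so that a given seed yields byte-identical output.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    rlang::abort("`seed` must be a single non-missing integer.")
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

stopifnot_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                    strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    rlang::abort(sprintf("`%s` must be a single number.", name))
  }
  if (strict_lower && x <= lower) {
    rlang::abort(sprintf("`%s` must be > %s.", name, lower))
  }
  if (!strict_lower && x < lower) {
    rlang::abort(sprintf("`%s` must be >= %s.", name, lower))
  }
  if (x > upper) {
    rlang::abort(sprintf("`%s` must be <= %s.", name, upper))
  }
  invisible(x)
}

# Numerically safe log(1 - exp(x)) for x < 0 is not needed; but a safe log
# of possibly tiny mixture densities is.
log_safe <- function(x, floor = 1e-300) log(pmax(x, floor))

# Zero-padded "same"-shape 2-D convolution via FFT.
conv2_same <- function(img, kern) {
  nr <- nrow(img); nc <- ncol(img)
  kr <- nrow(kern); kc <- ncol(kern)
  pr <- nr + kr - 1L; pc <- nc + kc - 1L
  A <- matrix(0, pr, pc); A[seq_len(nr), seq_len(nc)] <- img
  B <- matrix(0, pr, pc); B[seq_len(kr), seq_len(kc)] <- kern
  full <- Re(stats::fft(stats::fft(A) * stats::fft(B), inverse = TRUE)) / (pr * pc)
  r0 <- (kr - 1L) %/% 2L
  c0 <- (kc - 1L) %/% 2L
  full[r0 + seq_len(nr), c0 + seq_len(nc)]
}

as_count_matrix <- function(counts, feature_col = "feature") {
  if (is.matrix(counts)) {
    if (is.null(rownames(counts))) {
      rlang::abort("count matrix must have feature ids as rownames.")
    }
    return(counts)
  }
  if (is.data.frame(counts)) {
    if (!feature_col %in% names(counts)) {
      rlang::abort(sprintf("counts must contain a `%s` column.", feature_col))
    }
    m <- as.matrix(counts[setdiff(names(counts), feature_col)])
    rownames(m) <- as.character(counts[[feature_col]])
    storage.mode(m) <- "double"
    return(m)
  }
  rlang::abort("`counts` must be a matrix or a data frame.")
}
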