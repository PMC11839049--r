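#' Union of GO terms annotated to a protein set
#'
#' @param proteins Character vector of protein ids.
#' @param annotation Tibble with columns `protein`, `term` (one row per
#'   protein-term pair).
#' @return Character vector of term ids (the union over member proteins).
#'   Proteins absent from the annotation are reported and skipped; an
#'   empty result raises a warning.
#' @export
build_term_set <- function(proteins, annotation) {
  missing <- setdiff(proteins, annotation$protein)
  if (length(missing) > 0) {
    rlang::inform(sprintf("%d protein(s) without annotation were skipped.",
                          length(missing)))
  }
  terms <- unique(annotation$term[annotation$protein %in% proteins])
  if (length(terms) == 0) {
    rlang::warn("resulting term set is empty.")
  }
  terms
}

#' Pairwise and three-way overlap of three term sets
#'
#' @param hp,pb,sg Character vectors of GO term ids for the condensate
#'   (HP-body), P-body, and stress-granule protein sets.
#' @return A one-row tibble with set sizes, pairwise intersection sizes
#'   (`hp_pb`, `hp_sg`, `pb_sg`), the three-way intersection size, and
#'   `hp_shared_fraction` = |hp intersect (pb union sg)| / |hp|
#'   (`NA` with a flag when hp is empty).
#' @export
compute_term_overlap <- function(hp, pb, sg) {
  hp <- unique(hp); pb <- unique(pb); sg <- unique(sg)
  hp_pb <- intersect(hp, pb)
  hp_sg <- intersect(hp, sg)
  pb_sg <- intersect(pb, sg)
  three <- intersect(hp_pb, sg)
  frac <- if (length(hp) == 0) NA_real_ else
    length(intersect(hp, union(pb, sg))) / length(hp)
  if (length(hp) == 0) rlang::warn("empty HP term set: shared fraction undefined.")
  tibble::tibble(
    n_hp = length(hp), n_pb = length(pb), n_sg = length(sg),
    hp_pb = length(hp_pb), hp_sg = length(hp_sg), pb_sg = length(pb_sg),
    three_way = length(three),
    hp_shared_fraction = frac
  )
}

#' Term-level intersection membership table
#'
#' One row per term present in any of the three sets, with logical
#' membership columns; the input for Euler/Venn-style displays.
#'
#' @inheritParams compute_term_overlap
#' @return Tibble: `term`, `in_hp`, `in_pb`, `in_sg`.
#' @export
term_overlap_table <- function(hp, pb, sg) {
  terms <- sort(unique(c(hp, pb, sg)))
  tibble::tibble(
    term = terms,
    in_hp = terms %in% hp,
    in_pb = terms %in% pb,
    in_sg = terms %in% sg
  )
}

#' Permutation test for GO-term-set overlap
#'
#' Assesses whether the observed overlap between the condensate protein
#' set's GO terms and the P-body / stress-granule term sets exceeds
#' chance, by resampling the protein set: each permutation draws the same
#' number of proteins uniformly without replacement from the declared
#' universe, rebuilds the term-set union, and recomputes the three
#' overlap statistics (terms shared with P-bodies, with stress granules,
#' and with their union). P-values use the add-one estimator
#' p = (1 + #\{null >= observed\}) / (n_perm + 1), one-sided for
#' enrichment. Proteins without annotations stay drawable and contribute
#' empty term sets.
#'
#' @param hp_proteins Character vector, the observed protein set; must be
#'   a subset of `universe`.
#' @param universe Character vector of resampling candidates.
#' @param annotation Tibble with `protein`, `term`.
#' @param pb_terms,sg_terms Character vectors of comparison term sets.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed; mandatory.
#' @return An object of class `"overlap_permutation"`: `observed` (named
#'   statistics pb, sg, joint), `p_value` (same names), `null` (n_perm x 3
#'   matrix), `n_perm`, `seed`, plus the observed [compute_term_overlap()]
#'   row as `overlap`.
#' @export
permutation_overlap_test <- function(hp_proteins, universe, annotation,
                                     pb_terms, sg_terms, n_perm = 1000,
                                     seed) {
  if (missing(seed)) rlang::abort("`seed` is mandatory.")
  hp_proteins <- unique(hp_proteins)
  universe <- unique(universe)
  if (!all(hp_proteins %in% universe)) {
    rlang::abort("`hp_proteins` must be a subset of `universe`.")
  }
  if (length(hp_proteins) > length(universe)) {
    rlang::abort("protein set larger than the universe.")
  }
  term_list <- split(annotation$term, annotation$protein)
  set_terms <- function(prots) {
    unique(unlist(term_list[prots], use.names = FALSE))
  }
  stat3 <- function(terms) {
    c(pb = length(intersect(terms, pb_terms)),
      sg = length(intersect(terms, sg_terms)),
      joint = length(intersect(terms, union(pb_terms, sg_terms))))
  }
  obs_terms <- set_terms(hp_proteins)
  observed <- stat3(obs_terms)
  m <- length(hp_proteins)
  null <- with_seed(seed, {
    t(vapply(seq_len(n_perm), function(i) {
      stat3(set_terms(sample(universe, m)))
    }, numeric(3)))
  })
  p <- vapply(1:3, function(j) {
    (1 + sum(null[, j] >= observed[j])) / (n_perm + 1)
  }, numeric(1))
  names(p) <- names(observed)
  structure(
    list(observed = observed, p_value = p, null = null,
         n_perm = n_perm, seed = as.integer(seed),
         overlap = compute_term_overlap(obs_terms, pb_terms, sg_terms)),
    class = "overlap_permutation"
  )
}

#' @export
print.overlap_permutation <- function(x, ...) {
  cat(sprintf("<overlap_permutation> %d permutations, seed %d\n",
              x$n_perm, x$seed))
  for (nm in names(x$observed)) {
    cat(sprintf("  %-5s observed %d, p = %.4g\n",
                nm, x$observed[[nm]], x$p_value[[nm]]))
  }
  invisible(x)
}
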