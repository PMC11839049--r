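#' Configuration for the GO-annotation universe simulator
#'
#' Builds an annotation universe with three labeled protein sets whose
#' term-set overlap is planted at a target fraction: the condensate
#' (HP-body-like) set is a subset of the resampling universe, while the
#' P-body-like and stress-granule-like sets live outside it (mirroring a
#' cross-species comparison) and only their term sets matter.
#'
#' @param universe_size Number of proteins in the resampling universe.
#' @param n_terms Size of the GO term vocabulary.
#' @param terms_per_protein Mean number of terms per universe protein
#'   (Poisson, at least 1).
#' @param set_sizes Named integer vector with elements `hp`, `pb`, `sg`:
#'   sizes of the three labeled protein sets.
#' @param planted_overlap Target fraction of the HP term set shared with
#'   the P-body or stress-granule term sets, in \[0, 1\].
#' @param hp_terms_per_protein Terms drawn per HP protein.
#' @param n_perm Default permutation count carried along for downstream
#'   use (default 1000).
#' @param seed Integer seed; mandatory.
#' @return A list of class `"go_sim_config"`.
#' @export
go_sim_config <- function(universe_size = 500, n_terms = 400,
                          terms_per_protein = 4,
                          set_sizes = c(hp = 40, pb = 60, sg = 60),
                          planted_overlap = 0.35,
                          hp_terms_per_protein = 4,
                          n_perm = 1000, seed) {
  if (missing(seed)) rlang::abort("`seed` is mandatory for all simulators.")
  stopifnot_scalar_number(planted_overlap, "planted_overlap", lower = 0, upper = 1)
  if (!all(c("hp", "pb", "sg") %in% names(set_sizes))) {
    rlang::abort("`set_sizes` must name hp, pb and sg.")
  }
  if (set_sizes[["hp"]] > universe_size) {
    rlang::abort("the HP set cannot exceed the universe size.")
  }
  structure(
    list(universe_size = as.integer(universe_size),
         n_terms = as.integer(n_terms),
         terms_per_protein = terms_per_protein,
         set_sizes = set_sizes,
         planted_overlap = planted_overlap,
         hp_terms_per_protein = hp_terms_per_protein,
         n_perm = as.integer(n_perm),
         seed = as.integer(seed)),
    class = "go_sim_config"
  )
}

#' Simulate an annotation universe with planted term-set overlap
#'
#' The P-body and stress-granule protein sets are annotated from the
#' lower half of the term vocabulary; the HP term-set union is then
#' constructed so that exactly the planted fraction of it falls inside
#' the P-body/stress-granule term union, and distributed over the HP
#' proteins. Remaining universe proteins draw terms from the full
#' vocabulary, which gives the permutation null a non-degenerate
#' distribution.
#'
#' @param config A [go_sim_config()].
#' @return A list of class `"go_sim"` with `annotation` (tibble
#'   `protein`, `term` covering the universe and the PB/SG proteins),
#'   `sets` (list of protein-id vectors `hp`, `pb`, `sg`), `universe`
#'   (character vector), and `truth` (list with `realized_overlap`,
#'   `hp_terms`, `pb_terms`, `sg_terms`).
#' @export
simulate_go_universe <- function(config) {
  if (!inherits(config, "go_sim_config")) {
    rlang::abort("`config` must be created by go_sim_config().")
  }
  with_seed(config$seed, simulate_go_impl(config))
}

simulate_go_impl <- function(config) {
  terms <- sprintf("GO:%07d", seq_len(config$n_terms))
  universe <- sprintf("ECP_%04d", seq_len(config$universe_size))
  pb_prot <- sprintf("PB_%03d", seq_len(config$set_sizes[["pb"]]))
  sg_prot <- sprintf("SG_%03d", seq_len(config$set_sizes[["sg"]]))
  hp_prot <- sample(universe, config$set_sizes[["hp"]])

  # PB/SG annotations from the first quarter of the vocabulary, so that a
  # random universe protein set shares roughly a quarter of its terms with
  # the granule sets: a planted fraction above that is a real enrichment
  lower <- terms[seq_len(max(2L, floor(config$n_terms / 4)))]
  draw_terms <- function(pool, mean_n) {
    n <- max(1L, rpois(1, mean_n))
    sample(pool, min(n, length(pool)))
  }
  pb_ann <- lapply(pb_prot, function(p) draw_terms(lower, config$terms_per_protein))
  sg_ann <- lapply(sg_prot, function(p) draw_terms(lower, config$terms_per_protein))
  pb_terms <- unique(unlist(pb_ann))
  sg_terms <- unique(unlist(sg_ann))
  granule_terms <- union(pb_terms, sg_terms)
  outside_terms <- setdiff(terms, granule_terms)

  # plant the HP term-set union with the target shared fraction; size the
  # union like a random protein set's union so permutation statistics
  # compare composition, not set size
  V <- config$n_terms
  draws <- config$set_sizes[["hp"]] * config$terms_per_protein
  target_union <- max(2L, round(V * (1 - (1 - 1 / V)^draws)))
  p <- config$planted_overlap
  # shrink the union if a vocabulary side cannot supply its share
  if (p > 0) target_union <- min(target_union, floor(length(granule_terms) / p))
  if (p < 1) target_union <- min(target_union,
                                 floor(length(outside_terms) / (1 - p)))
  target_union <- max(target_union, 2L)
  n_shared <- round(p * target_union)
  n_own <- target_union - n_shared
  if (n_shared > length(granule_terms) || n_own > length(outside_terms)) {
    rlang::abort("planted_overlap is infeasible for this vocabulary size.")
  }
  hp_union <- c(
    if (n_shared > 0) sample(granule_terms, n_shared) else character(),
    if (n_own > 0) sample(outside_terms, n_own) else character()
  )
  # every union term used at least once, then fill to the per-protein rate
  holders <- sample(hp_prot, length(hp_union), replace = TRUE)
  hp_ann <- split(hp_union, factor(holders, levels = hp_prot))
  hp_ann <- lapply(hp_ann, function(x) {
    extra <- config$hp_terms_per_protein - length(x)
    if (extra > 0) unique(c(x, sample(hp_union, min(extra, length(hp_union)))))
    else x
  })

  # background annotations for the rest of the universe
  bg_prot <- setdiff(universe, hp_prot)
  bg_ann <- lapply(bg_prot, function(p) draw_terms(terms, config$terms_per_protein))

  annotation <- dplyr::bind_rows(
    tibble::tibble(protein = rep(hp_prot, lengths(hp_ann[hp_prot])),
                   term = unlist(hp_ann[hp_prot], use.names = FALSE)),
    tibble::tibble(protein = rep(bg_prot, lengths(bg_ann)),
                   term = unlist(bg_ann, use.names = FALSE)),
    tibble::tibble(protein = rep(pb_prot, lengths(pb_ann)),
                   term = unlist(pb_ann, use.names = FALSE)),
    tibble::tibble(protein = rep(sg_prot, lengths(sg_ann)),
                   term = unlist(sg_ann, use.names = FALSE))
  )

  hp_terms <- unique(unlist(hp_ann))
  realized <- length(intersect(hp_terms, granule_terms)) / length(hp_terms)

  structure(
    list(
      annotation = annotation,
      sets = list(hp = hp_prot, pb = pb_prot, sg = sg_prot),
      universe = universe,
      truth = list(realized_overlap = realized,
                   hp_terms = hp_terms, pb_terms = pb_terms,
                   sg_terms = sg_terms)
    ),
    class = "go_sim"
  )
}
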