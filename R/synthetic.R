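#' Default "disorder-biased" compositions for the synthetic generator
#'
#' Two 20-vectors of residue probabilities. The disordered composition is
#' enriched in E, K, G, S, A and depleted in C, W, F, Y and the other
#' hydrophobics, the qualitative bias observed in disordered regions; the
#' ordered composition emulates a hydrophobic-core-rich structured
#' background. The exact probabilities are declared package defaults, not
#' measurements.
#'
#' @return List with `ordered` and `disordered` named probability vectors
#'   (each summing to 1).
#' @export
fig5_like_compositions <- function() {
  ordered <- c(
    A = 0.050, C = 0.040, D = 0.005, E = 0.005, F = 0.090, G = 0.050,
    H = 0.005, I = 0.180, K = 0.005, L = 0.180, M = 0.050, N = 0.005,
    P = 0.005, Q = 0.005, R = 0.005, S = 0.050, T = 0.060, V = 0.140,
    W = 0.020, Y = 0.050)
  disordered <- c(
    A = 0.080, C = 0.002, D = 0.075, E = 0.190, F = 0.002, G = 0.120,
    H = 0.010, I = 0.003, K = 0.150, L = 0.005, M = 0.003, N = 0.030,
    P = 0.070, Q = 0.040, R = 0.060, S = 0.110, T = 0.040, V = 0.004,
    W = 0.002, Y = 0.004)
  list(ordered = ordered, disordered = disordered)
}

#' Design of a synthetic proteome
#'
#' Describes a seed-reproducible proteome of ordered-composition backbones
#' with planted disordered regions: per protein, a length is drawn
#' uniformly from `length_range`, a region count from `regions_range`
#' (0 allowed) and region lengths from `region_length_range`; regions are
#' placed uniformly at random, non-overlapping and separated by at least
#' one ordered residue, so the ground-truth LDR of a protein equals its
#' longest planted region. Residues inside regions are drawn i.i.d. from
#' `disordered_composition`, the rest from `ordered_composition`.
#'
#' The default ranges are chosen so that the worst-case draw (two maximal
#' regions plus their separating residue) always fits in the shortest
#' protein, keeping rejection sampling well-posed.
#'
#' @param n_proteins Number of proteins (default 150).
#' @param length_range Integer (min, max) protein length, or a single
#'   fixed length (default c(250, 500)).
#' @param ordered_composition,disordered_composition Named 20-vectors of
#'   probabilities summing to 1 (defaults: [fig5_like_compositions()]).
#' @param region_length_range Integer (min, max) planted-region length
#'   (default c(30, 120)).
#' @param regions_range Integer (min, max) regions per protein
#'   (default c(0, 2)).
#' @param seed Integer seed; required, so every generated proteome is
#'   reproducible.
#' @return List of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_proteins = 150, length_range = c(250, 500),
                           ordered_composition = fig5_like_compositions()$ordered,
                           disordered_composition = fig5_like_compositions()$disordered,
                           region_length_range = c(30, 120),
                           regions_range = c(0, 2), seed) {
  if (missing(seed) || is.null(seed) || is.na(suppressWarnings(as.integer(seed)))) {
    stop("`seed` is required for a synthetic spec", call. = FALSE)
  }
  norm_range <- function(r) {
    r <- as.integer(r)
    if (length(r) == 1) r <- c(r, r)
    if (length(r) != 2 || r[1] > r[2]) stop("bad range", call. = FALSE)
    r
  }
  check_comp <- function(p, what) {
    if (!all(sort(names(p)) == amino_acids())) {
      stop(what, " must be named over the 20 amino acids", call. = FALSE)
    }
    if (abs(sum(p) - 1) > 1e-12 || any(p < 0)) {
      stop(what, " must be a probability vector summing to 1", call. = FALSE)
    }
    p[amino_acids()]
  }
  structure(list(
    n_proteins = as.integer(n_proteins),
    length_range = norm_range(length_range),
    ordered_composition = check_comp(ordered_composition, "ordered_composition"),
    disordered_composition = check_comp(disordered_composition,
                                        "disordered_composition"),
    region_length_range = norm_range(region_length_range),
    regions_range = norm_range(regions_range),
    seed = as.integer(seed)
  ), class = "synthetic_spec")
}

# Uniform integer draw on lo..hi that never falls into sample()'s
# scalar-expansion trap when lo == hi.
runif_int <- function(lo, hi, n = 1) {
  lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L
}

# Place k regions of the given lengths in 1..L, non-overlapping and
# non-adjacent (>= 1 free residue between regions). Rejection sampling with
# a cap; returns a list of start positions or errors.
place_regions <- function(L, lens, max_tries = 1000) {
  if (length(lens) == 0) return(integer(0))
  if (all(lens <= L)) {
    for (try in seq_len(max_tries)) {
      starts <- vapply(lens, function(l) sample.int(L - l + 1L, 1L),
                       integer(1))
      o <- order(starts)
      s <- starts[o]
      e <- starts[o] + lens[o] - 1L
      if (length(s) == 1L || all(s[-1] > e[-length(e)] + 1L)) return(starts)
    }
  }
  stop("could not place ", length(lens), " region(s) of lengths ",
       paste(lens, collapse = ","), " in a protein of length ", L,
       " after ", max_tries, " tries; use smaller or fewer regions",
       call. = FALSE)
}

#' Generate a synthetic proteome with ground-truth disorder labels
#'
#' Deterministic given the spec (including its seed): two calls with the
#' same spec produce byte-identical sequences and labels.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `records` (a `protein_set`) and `truth`, a long data
#'   frame in the score-track schema (`protein_id`, `predictor = "truth"`,
#'   `position`, `score` 0/1) marking planted disordered residues.
#' @export
generate_proteome <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  aa <- amino_acids()
  with_seed(spec$seed, {
    seqs <- character(spec$n_proteins)
    labels <- vector("list", spec$n_proteins)
    for (i in seq_len(spec$n_proteins)) {
      L <- runif_int(spec$length_range[1], spec$length_range[2])
      k <- runif_int(spec$regions_range[1], spec$regions_range[2])
      lens <- if (k > 0) {
        runif_int(spec$region_length_range[1], spec$region_length_range[2], k)
      } else integer(0)
      starts <- place_regions(L, lens)
      chars <- sample(aa, L, replace = TRUE, prob = spec$ordered_composition)
      lab <- rep(FALSE, L)
      for (j in seq_along(starts)) {
        idx <- seq(starts[j], starts[j] + lens[j] - 1L)
        chars[idx] <- sample(aa, lens[j], replace = TRUE,
                             prob = spec$disordered_composition)
        lab[idx] <- TRUE
      }
      seqs[i] <- paste(chars, collapse = "")
      labels[[i]] <- lab
    }
    ids <- sprintf("SYN%04d", seq_len(spec$n_proteins))
    records <- protein_records(id = ids, sequence = seqs,
                               description = "synthetic protein")
    truth <- do.call(rbind, c(lapply(seq_along(ids), function(i) {
      data.frame(protein_id = ids[i], predictor = "truth",
                 position = seq_along(labels[[i]]),
                 score = as.integer(labels[[i]]), stringsAsFactors = FALSE)
    }), list(make.row.names = FALSE)))
    list(records = records, truth = truth)
  })
}

#' Disorder summaries of ground-truth labels
#'
#' Applies the same summary semantics as [summarize_disorder()] to the
#' planted truth labels (predictor name `"truth"`).
#'
#' @param truth Truth track data frame from [generate_proteome()].
#' @param records The matching `protein_set`.
#' @return Data frame as from [summarize_disorder()].
#' @export
truth_summary <- function(truth, records) {
  calls <- data.frame(protein_id = truth$protein_id,
                      predictor = truth$predictor,
                      position = truth$position,
                      call = truth$score >= 0.5, stringsAsFactors = FALSE)
  summarize_disorder(calls, records)
}
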