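#' Default pairwise interaction matrix for the energy predictor
#'
#' A transparent biophysical surrogate for statistical contact-propensity
#' matrices: the interaction energy of residues a and b is
#' `-h_a * h_b + charge_weight * |q_a| * |q_b|`, where `h` is the rescaled
#' Kyte-Doolittle hydropathy and `q` the residue charge. Hydrophobic pairs
#' thus stabilise (low energy, order) and charged pairs destabilise (high
#' energy, disorder). The matrix is symmetric by construction; any other
#' symmetric 20x20 matrix — for instance a published estimated-energy
#' matrix — can be supplied instead, directly or via
#' [read_energy_matrix()].
#'
#' @param charge_weight Weight of the charge-pair repulsion term
#'   (default 0.4).
#' @param hydropathy_scale Named hydropathy vector in `[0, 1]`.
#' @param charge_rule Named charge vector.
#' @return Symmetric 20x20 numeric matrix with amino-acid dimnames.
#' @export
default_energy_matrix <- function(charge_weight = 0.4,
                                  hydropathy_scale = default_hydropathy_scale(),
                                  charge_rule = default_charge_rule()) {
  h <- hydropathy_scale[amino_acids()]
  q <- abs(charge_rule[amino_acids()])
  m <- -outer(h, h) + charge_weight * outer(q, q)
  dimnames(m) <- list(amino_acids(), amino_acids())
  m
}

#' Read a pairwise energy matrix from TSV
#'
#' Expects a 20x20 table with amino-acid row and column names; the matrix
#' must be symmetric.
#'
#' @param path TSV file (first column = row names).
#' @return Symmetric 20x20 numeric matrix.
#' @export
read_energy_matrix <- function(path) {
  df <- utils::read.delim(path, row.names = 1, check.names = FALSE,
                          comment.char = "#")
  m <- as.matrix(df)
  aa <- amino_acids()
  if (!all(aa %in% rownames(m)) || !all(aa %in% colnames(m))) {
    stop("energy matrix must cover all 20 amino acids", call. = FALSE)
  }
  m <- m[aa, aa]
  if (max(abs(m - t(m))) > 1e-9) {
    stop("energy matrix must be symmetric", call. = FALSE)
  }
  m
}

#' Write an energy matrix as TSV
#'
#' @param matrix Symmetric 20x20 matrix.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_energy_matrix <- function(matrix, path) {
  df <- data.frame(aa = rownames(matrix), matrix, check.names = FALSE)
  write_lines_atomic(df_to_tsv_lines(df), path)
}

#' Charge-hydropathy (unfoldability) disorder score
#'
#' For each residue the mean rescaled hydropathy `<H>` and mean charge `<q>`
#' are taken over a window centred on that residue (truncated at the
#' sequence ends, no padding; X residues are excluded and the means
#' renormalised over the non-X residues). The per-residue unfoldability is
#'
#' `score_i = coef_h * <H> - coef_q * |<q>| - intercept`
#'
#' with defaults 2.785, 1.0 and 1.151 (the published charge-hydropathy
#' fold/unfold boundary). Negative scores indicate predicted disorder;
#' binarize with `threshold = 0`, `direction = "disordered_if_below"`.
#'
#' @param sequence Amino-acid sequence string (or a single-row
#'   `protein_set`).
#' @param params Parameter list from [charge_hydropathy_params()].
#' @return Numeric vector of per-residue scores (NA where a window contains
#'   only X).
#' @export
charge_hydropathy_score <- function(sequence,
                                    params = charge_hydropathy_params()) {
  if (is.data.frame(sequence)) sequence <- sequence$sequence[1]
  window <- check_odd_window(params$window, minimum = 1)
  chars <- seq_chars(sequence)
  w <- as.numeric(chars != "X")
  h <- params$hydropathy_scale[chars]
  q <- params$charge_rule[chars]
  h[is.na(h)] <- 0
  q[is.na(q)] <- 0
  mean_h <- window_mean(h, w, window)
  mean_q <- window_mean(q, w, window)
  unname(params$coef_h * mean_h - params$coef_q * abs(mean_q) -
           params$intercept)
}

#' Pairwise-energy disorder score
#'
#' Estimates, for each residue, the interaction energy it would experience
#' from its local sequence context: with `f` the amino-acid composition of
#' the window centred at residue i but excluding position i (non-X residues
#' only), the estimated energy is `e_i = sum_b matrix[a_i, b] * f(b)`. The
#' energy is mapped to a disorder probability through a logistic transform,
#' `score_i = 1 / (1 + exp((e_i - midpoint) / (-slope)))`, so scores lie in
#' (0, 1) with higher values meaning more disordered. Binarize with
#' `threshold = 0.5`, `direction = "disordered_if_at_or_above"`.
#'
#' @param sequence Amino-acid sequence string (or a single-row
#'   `protein_set`).
#' @param params Parameter list from [energy_model_params()].
#' @return Numeric vector of per-residue scores in (0, 1); NA for X
#'   residues or empty contexts.
#' @export
pairwise_energy_score <- function(sequence, params = energy_model_params()) {
  if (is.data.frame(sequence)) sequence <- sequence$sequence[1]
  window <- tryCatch(check_odd_window(params$window, minimum = 3),
                     error = function(e) {
                       stop("`window` must be an odd integer >= 3 ",
                            "(a window of size 1 has an empty context)",
                            call. = FALSE)
                     })
  m <- params$matrix
  aa <- amino_acids()
  if (!all(aa %in% rownames(m)) || !all(aa %in% colnames(m))) {
    stop("energy matrix must cover all 20 amino acids", call. = FALSE)
  }
  m <- m[aa, aa]
  if (max(abs(m - t(m))) > 1e-9) {
    stop("energy matrix must be symmetric", call. = FALSE)
  }
  if (!is.numeric(params$slope) || params$slope <= 0) {
    stop("`slope` must be positive", call. = FALSE)
  }
  chars <- seq_chars(sequence)
  L <- length(chars)
  ai <- match(chars, aa)                       # NA for X
  half <- window %/% 2
  ind <- matrix(0, nrow = L, ncol = 20)
  ok <- !is.na(ai)
  ind[cbind(which(ok), ai[ok])] <- 1
  cs <- rbind(0, apply(ind, 2, cumsum))
  lo <- pmax(seq_len(L) - half, 1L)
  hi <- pmin(seq_len(L) + half, L)
  counts <- cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]
  counts <- counts - ind                       # exclude the residue itself
  tot <- rowSums(counts)
  f <- counts / ifelse(tot > 0, tot, 1)
  e <- rowSums(f * m[ifelse(ok, ai, 1L), , drop = FALSE])
  e[!ok | tot == 0] <- NA_real_
  unname(stats::plogis((e - params$midpoint) / params$slope))
}

#' Binarize a score vector into order/disorder calls
#'
#' @param scores Numeric per-residue scores.
#' @param threshold Decision threshold.
#' @param direction `"disordered_if_below"` (strictly below the threshold;
#'   used for unfoldability scores, where the boundary itself is ordered) or
#'   `"disordered_if_at_or_above"` (used for probability-like scores, where
#'   the boundary is disordered).
#' @return Logical vector, `TRUE` = disordered; NA scores become `FALSE`.
#' @export
binarize <- function(scores, threshold,
                     direction = c("disordered_if_below",
                                   "disordered_if_at_or_above")) {
  direction <- match.arg(direction)
  calls <- if (direction == "disordered_if_below") scores < threshold
           else scores >= threshold
  calls[is.na(calls)] <- FALSE
  calls
}

#' Run the built-in predictors over a protein set
#'
#' Computes per-residue scores and order/disorder calls for each requested
#' predictor. The charge-hydropathy predictor is binarized at 0 (disordered
#' strictly below); the pairwise-energy predictor at 0.5 (disordered at or
#' above).
#'
#' @param records A `protein_set` data frame.
#' @param methods Predictors to run (any of `"charge_hydropathy"`,
#'   `"pairwise_energy"`).
#' @param ch_params,pe_params Parameter lists (see
#'   [charge_hydropathy_params()], [energy_model_params()]).
#' @return List with `scores` and `calls`, both long data frames with
#'   columns `protein_id`, `predictor`, `position` and `score`/`call`.
#' @export
predict_disorder <- function(records,
                             methods = c("charge_hydropathy",
                                         "pairwise_energy"),
                             ch_params = charge_hydropathy_params(),
                             pe_params = energy_model_params()) {
  methods <- match.arg(methods, several.ok = TRUE)
  score_list <- list()
  call_list <- list()
  for (meth in methods) {
    for (i in seq_len(nrow(records))) {
      s <- switch(meth,
        charge_hydropathy = charge_hydropathy_score(records$sequence[i],
                                                    ch_params),
        pairwise_energy = pairwise_energy_score(records$sequence[i],
                                                pe_params))
      cl <- switch(meth,
        charge_hydropathy = binarize(s, 0, "disordered_if_below"),
        pairwise_energy = binarize(s, 0.5, "disordered_if_at_or_above"))
      key <- paste(meth, records$id[i])
      score_list[[key]] <- data.frame(
        protein_id = records$id[i], predictor = meth,
        position = seq_along(s), score = s, stringsAsFactors = FALSE)
      call_list[[key]] <- data.frame(
        protein_id = records$id[i], predictor = meth,
        position = seq_along(cl), call = cl, stringsAsFactors = FALSE)
    }
  }
  scores <- do.call(rbind, c(score_list, list(make.row.names = FALSE)))
  calls <- do.call(rbind, c(call_list, list(make.row.names = FALSE)))
  o <- order(scores$protein_id, scores$predictor, scores$position)
  scores <- scores[o, ]
  calls <- calls[o, ]
  rownames(scores) <- rownames(calls) <- NULL
  list(scores = scores, calls = calls)
}
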