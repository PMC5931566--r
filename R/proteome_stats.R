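#' Henderson-Hasselbalch net charge of a protein at a given pH
#'
#' Sums the fractional charges of the N-terminus, C-terminus and the
#' ionizable side chains (D, E, C, Y, H, K, R): a basic group with
#' dissociation constant pKa contributes `+1 / (1 + 10^(pH - pKa))`, an
#' acidic group `-1 / (1 + 10^(pKa - pH))`. H is treated as basic here
#' (its side chain is protonatable) regardless of the predictor charge
#' rule.
#'
#' @param sequence Amino-acid sequence string.
#' @param pH pH value (vectorised).
#' @param pka_table Named pKa vector (see [default_pka_table()]).
#' @return Net charge (same length as `pH`).
#' @export
net_charge <- function(sequence, pH, pka_table = default_pka_table()) {
  chars <- seq_chars(toupper(sequence))
  n_basic <- c(Nterm = 1, K = sum(chars == "K"), R = sum(chars == "R"),
               H = sum(chars == "H"))
  n_acid <- c(Cterm = 1, D = sum(chars == "D"), E = sum(chars == "E"),
              C = sum(chars == "C"), Y = sum(chars == "Y"))
  n_basic <- n_basic[n_basic > 0]
  n_acid <- n_acid[n_acid > 0]
  pka_b <- pka_table[names(n_basic)]
  pka_a <- pka_table[names(n_acid)]
  if (anyNA(pka_b) || anyNA(pka_a)) {
    miss <- c(names(n_basic)[is.na(pka_b)], names(n_acid)[is.na(pka_a)])
    stop("pKa table lacks entries for: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  vapply(pH, function(p) {
    sum(n_basic / (1 + 10^(p - pka_b))) - sum(n_acid / (1 + 10^(pka_a - p)))
  }, numeric(1))
}

#' Theoretical isoelectric point
#'
#' The pH at which the Henderson-Hasselbalch net charge is zero, located by
#' bisection on `[0, 14]` (the net charge is strictly decreasing in pH, and
#' both termini are always ionizable, so a unique root exists). The
#' interval is bisected until it is narrower than `tol` (at most 60
#' iterations); at the returned pH the net charge is far below 1e-4 in
#' magnitude.
#'
#' @param sequence Amino-acid sequence string (or single-row
#'   `protein_set`).
#' @param pka_table Named pKa vector covering `Nterm`, `Cterm` and the
#'   ionizable side chains.
#' @param tol pH convergence tolerance (default 1e-6).
#' @return The pI, a value in (0, 14).
#' @export
theoretical_pI <- function(sequence, pka_table = default_pka_table(),
                           tol = 1e-6) {
  if (is.data.frame(sequence)) sequence <- sequence$sequence[1]
  lo <- 0
  hi <- 14
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (net_charge(sequence, mid, pka_table) > 0) lo <- mid else hi <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

#' Average molecular weight of a protein
#'
#' Sum of average residue masses plus one water (equivalently, residue
#' masses minus one water per formed peptide bond). The ambiguity code X
#' contributes a placeholder mass, by default the mean of the 20 canonical
#' residue masses.
#'
#' @param sequence Amino-acid sequence string (or single-row
#'   `protein_set`).
#' @param mass_table List with `residues` and `water` (see
#'   [default_mass_table()]).
#' @param x_mass Mass used for X (default: mean canonical residue mass).
#' @return Molecular weight in daltons.
#' @export
molecular_weight <- function(sequence, mass_table = default_mass_table(),
                             x_mass = mean(mass_table$residues)) {
  if (is.data.frame(sequence)) sequence <- sequence$sequence[1]
  chars <- seq_chars(toupper(sequence))
  m <- mass_table$residues[chars]
  m[chars == "X"] <- x_mass
  if (anyNA(m)) stop("unknown residue in sequence", call. = FALSE)
  sum(m) + mass_table$water
}

#' Theoretical pI and molecular weight for a protein set
#'
#' @param records A `protein_set` data frame.
#' @inheritParams theoretical_pI
#' @inheritParams molecular_weight
#' @return Data frame `protein_id`, `pI`, `mw`.
#' @export
physchem_table <- function(records, pka_table = default_pka_table(),
                           mass_table = default_mass_table()) {
  data.frame(
    protein_id = records$id,
    pI = vapply(records$sequence, theoretical_pI, numeric(1),
                pka_table = pka_table, USE.NAMES = FALSE),
    mw = vapply(records$sequence, molecular_weight, numeric(1),
                mass_table = mass_table, USE.NAMES = FALSE),
    stringsAsFactors = FALSE
  )
}

#' Linear regression of disordered-residue counts on protein length
#'
#' Ordinary least squares of DR (number of disordered residues, typically
#' reconstructed as `round(percent_disorder * length / 100)`) on protein
#' length, with or without an intercept.
#'
#' @param length Positive protein lengths.
#' @param dr Disordered-residue counts.
#' @param through_origin Fit `DR = a * L` instead of `DR = a * L + b`
#'   (default FALSE). For the through-origin model the reported R-squared
#'   is the standard uncentred one.
#' @return List of class `dr_regression`: `slope`, `intercept` (NA when
#'   through the origin), `r_squared`, `n`, `through_origin`.
#' @export
dr_length_regression <- function(length, dr, through_origin = FALSE) {
  if (length(length) < 2) stop("need at least two points", call. = FALSE)
  if (any(length <= 0)) stop("lengths must be positive", call. = FALSE)
  if (!through_origin && length(unique(length)) == 1) {
    stop("degenerate x: all lengths equal", call. = FALSE)
  }
  fit <- if (through_origin) stats::lm(dr ~ 0 + length)
         else stats::lm(dr ~ length)
  sm <- suppressWarnings(summary(fit))  # exact fits warn harmlessly
  structure(list(
    slope = unname(stats::coef(fit)[["length"]]),
    intercept = if (through_origin) NA_real_
                else unname(stats::coef(fit)[["(Intercept)"]]),
    slope_se = unname(sm$coefficients["length", "Std. Error"]),
    r_squared = sm$r.squared,
    n = length(length),
    through_origin = through_origin
  ), class = "dr_regression")
}

#' Treatment yield as percent of control
#'
#' E.g. milligrams of protein remaining soluble after a heat or acid
#' treatment relative to the untreated control.
#'
#' @param treated_mg Protein content after treatment.
#' @param control_mg Protein content of the control (> 0).
#' @return `100 * treated / control`, half-up rounded to one decimal.
#' @export
yield_percent <- function(treated_mg, control_mg) {
  if (any(control_mg <= 0)) stop("control must be positive", call. = FALSE)
  round_half_up(100 * treated_mg / control_mg, 1)
}

#' Category frequency table over an annotated protein set
#'
#' For `key = "compartment"` each protein counts in exactly one category so
#' percents sum to 100 for a fully annotated set; for `key = "go_terms"` a
#' protein counts once in each of its GO categories, so percents may sum to
#' more than 100. Percents are relative to the set size (unannotated
#' proteins stay in the denominator).
#'
#' @param records A `protein_set`, already subset to the proteins of
#'   interest.
#' @param key `"compartment"` or `"go_terms"`.
#' @return Data frame `category`, `count`, `percent` (half-up rounded to
#'   one decimal), sorted by decreasing count.
#' @export
frequency_by_category <- function(records, key = c("compartment", "go_terms")) {
  key <- match.arg(key)
  n <- nrow(records)
  if (n == 0) {
    return(data.frame(category = character(0), count = integer(0),
                      percent = numeric(0), stringsAsFactors = FALSE))
  }
  cats <- if (key == "compartment") {
    records$compartment[!is.na(records$compartment)]
  } else {
    unlist(lapply(records$go_terms, unique))
  }
  tab <- sort(table(cats), decreasing = TRUE)
  data.frame(category = names(tab), count = as.integer(tab),
             percent = round_half_up(100 * as.integer(tab) / n, 1),
             stringsAsFactors = FALSE)
}
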