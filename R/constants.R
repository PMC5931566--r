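#' The 20 canonical amino acids
#'
#' One-letter codes in fixed alphabetical order. All composition vectors,
#' matrices and report rows in the package use this order.
#'
#' @return Character vector of length 20.
#' @export
amino_acids <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

# Kyte-Doolittle hydropathy values (raw scale, -4.5..4.5)
.kyte_doolittle <- c(
  A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4, H = -3.2,
  I = 4.5, K = -3.9, L = 3.8, M = 1.9, N = -3.5, P = -1.6, Q = -3.5,
  R = -4.5, S = -0.8, T = -0.7, V = 4.2, W = -0.9, Y = -1.3
)

#' Default hydropathy scale
#'
#' Kyte-Doolittle hydropathies affinely rescaled to `[0, 1]` as
#' `(H + 4.5) / 9`, the normalisation used by charge-hydropathy
#' ("unfoldability") disorder boundaries.
#'
#' @return Named numeric vector over the 20 canonical amino acids, in `[0, 1]`.
#' @export
default_hydropathy_scale <- function() {
  (.kyte_doolittle[amino_acids()] + 4.5) / 9
}

#' Default residue charge rule
#'
#' K and R carry +1, D and E carry -1, every other residue 0. Histidine is
#' near-neutral at typical working pH and defaults to 0 but can be assigned
#' a partial or full charge.
#'
#' @param histidine_charge Charge assigned to H (default 0).
#' @return Named numeric vector over the 20 canonical amino acids.
#' @export
default_charge_rule <- function(histidine_charge = 0) {
  q <- setNames(numeric(20), amino_acids())
  q[c("K", "R")] <- 1
  q[c("D", "E")] <- -1
  q["H"] <- histidine_charge
  q
}

#' Default pKa table for net-charge and pI computation
#'
#' Bjellqvist-style values as used by common theoretical-pI tools. Covers
#' both termini and the ionizable side chains D, E, C, Y, H, K, R. The
#' table is data, not code: pass any replacement with the same names to
#' [theoretical_pI()].
#'
#' @return Named numeric vector with entries `Nterm`, `Cterm`, `D`, `E`,
#'   `C`, `Y`, `H`, `K`, `R`.
#' @export
default_pka_table <- function() {
  c(Nterm = 7.50, Cterm = 3.55,
    D = 4.05, E = 4.45, C = 9.00, Y = 10.00, H = 5.98, K = 10.00, R = 12.00)
}

#' Default average residue mass table
#'
#' Average (isotope-abundance weighted) residue masses in daltons, i.e. the
#' mass each amino acid contributes inside a peptide chain; one water mass
#' is added per chain when computing the molecular weight of a protein.
#'
#' @return List with `residues` (named numeric vector, 20 amino acids) and
#'   `water` (mass of H2O, daltons).
#' @export
default_mass_table <- function() {
  list(
    residues = c(
      A = 71.0788, C = 103.1388, D = 115.0886, E = 129.1155, F = 147.1766,
      G = 57.0519, H = 137.1411, I = 113.1594, K = 128.1741, L = 113.1594,
      M = 131.1926, N = 114.1038, P = 97.1167, Q = 128.1307, R = 156.1875,
      S = 87.0782, T = 101.1051, V = 99.1326, W = 186.2132, Y = 163.1760
    ),
    water = 18.01524
  )
}

#' Default parameters of the charge-hydropathy predictor
#'
#' The boundary constants 2.785 and 1.151 are the published
#' charge-hydropathy fold/unfold boundary; the hydropathy scale is
#' Kyte-Doolittle rescaled to `[0, 1]`. All entries can be overridden.
#'
#' @param window Odd sliding-window width in residues (default 51).
#' @param histidine_charge Charge assigned to H (default 0).
#' @return List with elements `window`, `hydropathy_scale`, `charge_rule`,
#'   `coef_h`, `coef_q`, `intercept`.
#' @export
charge_hydropathy_params <- function(window = 51, histidine_charge = 0) {
  list(
    window = window,
    hydropathy_scale = default_hydropathy_scale(),
    charge_rule = default_charge_rule(histidine_charge),
    coef_h = 2.785,
    coef_q = 1.0,
    intercept = 1.151
  )
}

#' Default parameters of the pairwise-energy predictor
#'
#' @param window Odd sliding-window width in residues (default 21).
#' @param matrix Symmetric 20x20 interaction matrix
#'   (default [default_energy_matrix()]).
#' @param midpoint,slope Logistic transform parameters mapping estimated
#'   energies to disorder probabilities.
#' @return List with elements `matrix`, `window`, `midpoint`, `slope`.
#' @export
energy_model_params <- function(window = 21, matrix = default_energy_matrix(),
                                midpoint = -0.15, slope = 0.05) {
  list(matrix = matrix, window = window, midpoint = midpoint, slope = slope)
}
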