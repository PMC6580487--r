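# Versioned physical-constant tables. All residue masses are derived from the
# elemental compositions below and the element mass tables, so monoisotopic and
# average values share a single source of truth.

# Monoisotopic masses of the most abundant isotope (Da).
.element_mono <- c(
  H = 1.0078250319,
  C = 12.0,
  N = 14.0030740052,
  O = 15.9949146221,
  S = 31.97207069
)

# Standard atomic weights, CIAAW conventional values (Da).
.element_avg <- c(
  H = 1.008,
  C = 12.011,
  N = 14.007,
  O = 15.999,
  S = 32.06
)

.proton_mass <- 1.00727646677

# Residue (amino acid minus water) elemental compositions, 20 standard codes.
# Rows: H, C, N, O, S counts.
.aa_composition <- matrix(
  c(
    # H   C  N  O  S
      5,  3, 1, 1, 0,  # A
     12,  6, 4, 1, 0,  # R
      6,  4, 2, 2, 0,  # N
      5,  4, 1, 3, 0,  # D
      5,  3, 1, 1, 1,  # C
      7,  5, 1, 3, 0,  # E
      8,  5, 2, 2, 0,  # Q
      3,  2, 1, 1, 0,  # G
      7,  6, 3, 1, 0,  # H
     11,  6, 1, 1, 0,  # I
     11,  6, 1, 1, 0,  # L
     12,  6, 2, 1, 0,  # K
      9,  5, 1, 1, 1,  # M
      9,  9, 1, 1, 0,  # F
      7,  5, 1, 1, 0,  # P
      5,  3, 1, 2, 0,  # S
      7,  4, 1, 2, 0,  # T
     10, 11, 2, 1, 0,  # W
      9,  9, 1, 2, 0,  # Y
      9,  5, 1, 1, 0   # V
  ),
  ncol = 5, byrow = TRUE,
  dimnames = list(
    c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I",
      "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
    c("H", "C", "N", "O", "S")
  )
)

.aa_codes <- rownames(.aa_composition)

.residue_mass <- function(elements) {
  drop(.aa_composition %*% elements[colnames(.aa_composition)])
}

.residue_mono <- .residue_mass(.element_mono)
.residue_avg <- .residue_mass(.element_avg)

.water_mono <- 2 * .element_mono[["H"]] + .element_mono[["O"]]
.water_avg <- 2 * .element_avg[["H"]] + .element_avg[["O"]]

# Named pKa sets for the Henderson-Hasselbalch net-charge calculation.
# Side-chain entries plus peptide termini.
.pka_tables <- list(
  emboss = c(
    Nterm = 8.6, Cterm = 3.6,
    K = 10.8, R = 12.5, H = 6.5,
    D = 3.9, E = 4.1, C = 8.5, Y = 10.1
  )
)

# Named per-residue hydrophobicity scales (GRAVY convention: arithmetic mean).
.hydro_scales <- list(
  kyte_doolittle = c(
    A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
    E = -3.5, Q = -3.5, G = -0.4, H = -3.2, I = 4.5,
    L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
    S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
  )
)

#' Physical constant tables used by the peptide property calculations
#'
#' Returns the element mass tables, residue elemental compositions, derived
#' residue masses, proton mass, available pKa tables and hydrophobicity
#' scales. Exposed so that the provenance of every computed mass and charge
#' is inspectable.
#'
#' @return A named list with components `element_mono`, `element_avg`,
#'   `proton_mass`, `aa_composition`, `residue_mono`, `residue_avg`,
#'   `water_mono`, `water_avg`, `pka_tables`, `hydro_scales`.
#' @export
#' @examples
#' cdp_constants()$residue_mono[["G"]]
cdp_constants <- function() {
  list(
    element_mono = .element_mono,
    element_avg = .element_avg,
    proton_mass = .proton_mass,
    aa_composition = .aa_composition,
    residue_mono = .residue_mono,
    residue_avg = .residue_avg,
    water_mono = .water_mono,
    water_avg = .water_avg,
    pka_tables = .pka_tables,
    hydro_scales = .hydro_scales
  )
}
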