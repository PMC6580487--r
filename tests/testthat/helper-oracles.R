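# Independent oracles, deliberately coded along different paths from the
# package internals.

# -- peptide mass oracle: whole-peptide atom counting from molecular
#    formula strings, then one multiplication by an element mass table.
.ora_formulas <- c(
  A = "C3H5NO",   R = "C6H12N4O", N = "C4H6N2O2", D = "C4H5NO3",
  C = "C3H5NOS",  E = "C5H7NO3",  Q = "C5H8N2O2", G = "C2H3NO",
  H = "C6H7N3O",  I = "C6H11NO",  L = "C6H11NO",  K = "C6H12N2O",
  M = "C5H9NOS",  F = "C9H9NO",   P = "C5H7NO",   S = "C3H5NO2",
  T = "C4H7NO2",  W = "C11H10N2O", Y = "C9H9NO2", V = "C5H9NO"
)
.ora_mono <- c(C = 12, H = 1.00782503207, N = 14.0030740048,
               O = 15.9949146196, S = 31.97207100)
.ora_avg <- c(C = 12.011, H = 1.008, N = 14.007, O = 15.999, S = 32.06)

.ora_parse_formula <- function(f) {
  m <- gregexpr("([A-Z])([0-9]*)", f)[[1]]
  parts <- regmatches(f, gregexpr("([A-Z])([0-9]*)", f))[[1]]
  counts <- c(C = 0, H = 0, N = 0, O = 0, S = 0)
  for (p in parts) {
    el <- substr(p, 1, 1)
    n <- substr(p, 2, nchar(p))
    counts[el] <- counts[el] + if (nzchar(n)) as.integer(n) else 1L
  }
  counts
}

# mass of a peptide by summing atoms over all residues + water - 2H per
# disulfide bond
oracle_mass <- function(seq, type = c("mono", "avg"), n_disulfides = NULL) {
  type <- match.arg(type)
  chars <- strsplit(toupper(seq), "")[[1]]
  atoms <- c(C = 0, H = 0, N = 0, O = 0, S = 0)
  for (ch in chars) atoms <- atoms + .ora_parse_formula(.ora_formulas[[ch]])
  atoms["H"] <- atoms["H"] + 2  # water
  atoms["O"] <- atoms["O"] + 1
  if (is.null(n_disulfides)) n_disulfides <- sum(chars == "C") %/% 2
  atoms["H"] <- atoms["H"] - 2 * n_disulfides
  masses <- if (type == "mono") .ora_mono else .ora_avg
  sum(atoms * masses[names(atoms)])
}

random_peptide <- function(min_len = 3, max_len = 30) {
  len <- sample(min_len:max_len, 1)
  paste(sample(names(.ora_formulas), len, replace = TRUE), collapse = "")
}

# -- noise-free generator curve for the peaks-module oracles
gauss_mix <- function(rt, apex_rt, height, width_sd) {
  y <- numeric(length(rt))
  for (j in seq_along(apex_rt)) {
    y <- y + height[j] * exp(-(rt - apex_rt[j])^2 / (2 * width_sd[j]^2))
  }
  y
}

# minimal peak-list row constructor for classify_pair tests
pk <- function(rt, h = 100, shoulder = FALSE) {
  n <- length(rt)
  data.frame(apex_rt = rt, apex_height = rep_len(h, n),
             left_rt = rt - 0.3, right_rt = rt + 0.3,
             is_shoulder = rep_len(shoulder, n),
             prominence = rep_len(h, n))
}

no_peak_df <- function() pk(numeric(0))

flat_spec <- function() {
  data.frame(apex_rt = numeric(0), height = numeric(0),
             width_sd = numeric(0))
}
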