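# In-silico molecular properties of peptide sequences: disulfide-corrected
# masses, net charge, hydrophobicity, duplicate detection, and ESI
# charge-state m/z validation.

#' Parse and validate a peptide sequence
#'
#' Strips whitespace, upper-cases, and validates against the 20 standard
#' one-letter amino-acid codes. Under the full-oxidation assumption every
#' available pair of cysteines forms a disulfide bond:
#' `n_disulfides = floor(n_cys / 2)`; an odd cysteine count leaves one
#' free thiol.
#'
#' @param text Amino-acid sequence string (or an already-parsed
#'   `cdp_peptide`, returned unchanged).
#' @return An object of class `cdp_peptide`: list with `sequence`,
#'   `n_cys`, `n_disulfides`.
#' @export
#' @examples
#' parse_sequence("ACDCK")
parse_sequence <- function(text) {
  if (inherits(text, "cdp_peptide")) return(text)
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    stop("`text` must be a single string", call. = FALSE)
  }
  seq <- toupper(gsub("[[:space:]]", "", text))
  if (!nzchar(seq)) stop("empty peptide sequence", call. = FALSE)
  chars <- strsplit(seq, "")[[1L]]
  bad <- setdiff(unique(chars), .aa_codes)
  if (length(bad)) {
    ambiguous <- c(B = "Asx", J = "Leu/Ile", O = "pyrrolysine",
                   U = "selenocysteine", X = "unknown", Z = "Glx")
    desc <- vapply(bad, function(ch) {
      if (ch %in% names(ambiguous))
        sprintf("'%s' (%s)", ch, ambiguous[[ch]]) else sprintf("'%s'", ch)
    }, "")
    stop(sprintf("non-standard residue(s) in sequence: %s",
                 paste(desc, collapse = ", ")), call. = FALSE)
  }
  n_cys <- sum(chars == "C")
  structure(list(sequence = seq, n_cys = n_cys,
                 n_disulfides = n_cys %/% 2L),
            class = "cdp_peptide")
}

#' @export
print.cdp_peptide <- function(x, ...) {
  cat(sprintf("<cdp_peptide> %s (%d aa, %d Cys, %d disulfide%s assumed)\n",
              x$sequence, nchar(x$sequence), x$n_cys, x$n_disulfides,
              if (x$n_disulfides == 1L) "" else "s"))
  invisible(x)
}

.peptide_mass <- function(seq, residue_masses, water, hydrogen,
                          n_disulfides) {
  chars <- strsplit(seq$sequence, "")[[1L]]
  sum(residue_masses[chars]) + water - n_disulfides * 2 * hydrogen
}

#' Monoisotopic mass with disulfide correction
#'
#' Sum of residue monoisotopic masses plus one water, minus two hydrogen
#' atoms per formed disulfide bond (oxidation of a cystine pair removes
#' both thiol hydrogens).
#'
#' @param seq Sequence string or [parse_sequence()] result.
#' @param n_disulfides Number of disulfide bonds to correct for; defaults
#'   to the full-oxidation count `floor(n_cys / 2)`.
#' @return Mass in Da.
#' @export
#' @examples
#' monoisotopic_mass("G")  # glycine, 75.03203 Da
monoisotopic_mass <- function(seq, n_disulfides = NULL) {
  seq <- parse_sequence(seq)
  if (is.null(n_disulfides)) n_disulfides <- seq$n_disulfides
  .peptide_mass(seq, .residue_mono, .water_mono, .element_mono[["H"]],
                n_disulfides)
}

#' Average mass with disulfide correction
#'
#' As [monoisotopic_mass()] but with standard atomic weights.
#'
#' @inheritParams monoisotopic_mass
#' @return Mass in Da.
#' @export
average_mass <- function(seq, n_disulfides = NULL) {
  seq <- parse_sequence(seq)
  if (is.null(n_disulfides)) n_disulfides <- seq$n_disulfides
  .peptide_mass(seq, .residue_avg, .water_avg, .element_avg[["H"]],
                n_disulfides)
}

#' Net charge at a given pH
#'
#' Henderson-Hasselbalch sum over ionizable groups: the N-terminus and the
#' basic side chains (K, R, H) contribute `+1 / (1 + 10^(pH - pKa))`; the
#' C-terminus and the acidic side chains (D, E, Y, and free-thiol
#' cysteines) contribute `-1 / (1 + 10^(pKa - pH))`. Cysteines engaged in
#' the assumed disulfide bonds (2 per bond) are excluded from the acidic
#' set.
#'
#' @inheritParams monoisotopic_mass
#' @param ph pH, in (0, 14). Default 7.4 (physiological).
#' @param pka_table Name of a pKa set; currently `"emboss"`.
#' @return Net charge in elementary charges.
#' @export
#' @examples
#' net_charge("GCCK", ph = 7.4)
net_charge <- function(seq, ph = 7.4, pka_table = "emboss") {
  seq <- parse_sequence(seq)
  if (!is.numeric(ph) || ph <= 0 || ph >= 14) {
    stop("`ph` must lie in (0, 14)", call. = FALSE)
  }
  if (!pka_table %in% names(.pka_tables)) {
    stop(sprintf("unknown pKa table '%s' (available: %s)", pka_table,
                 paste(names(.pka_tables), collapse = ", ")), call. = FALSE)
  }
  pka <- .pka_tables[[pka_table]]
  chars <- strsplit(seq$sequence, "")[[1L]]
  basic <- function(p) 1 / (1 + 10^(ph - p))
  acidic <- function(p) -1 / (1 + 10^(p - ph))
  q <- basic(pka[["Nterm"]]) + acidic(pka[["Cterm"]])
  for (res in c("K", "R", "H")) {
    q <- q + sum(chars == res) * basic(pka[[res]])
  }
  for (res in c("D", "E", "Y")) {
    q <- q + sum(chars == res) * acidic(pka[[res]])
  }
  free_thiols <- seq$n_cys - 2L * seq$n_disulfides
  q + free_thiols * acidic(pka[["C"]])
}

#' Mean residue hydrophobicity (GRAVY)
#'
#' Arithmetic mean of per-residue scale values over the sequence.
#'
#' @inheritParams monoisotopic_mass
#' @param scale Name of a residue scale; currently `"kyte_doolittle"`.
#' @return Dimensionless mean scale value.
#' @export
hydrophobicity <- function(seq, scale = "kyte_doolittle") {
  seq <- parse_sequence(seq)
  if (!scale %in% names(.hydro_scales)) {
    stop(sprintf("unknown hydrophobicity scale '%s' (available: %s)", scale,
                 paste(names(.hydro_scales), collapse = ", ")),
         call. = FALSE)
  }
  sc <- .hydro_scales[[scale]]
  chars <- strsplit(seq$sequence, "")[[1L]]
  mean(sc[chars])
}

#' Theoretical m/z of a peptide at a given charge state
#'
#' `(M + z * m_proton) / z` with `M` the disulfide-corrected monoisotopic
#' mass.
#'
#' @inheritParams monoisotopic_mass
#' @param z Positive integer charge state.
#' @return m/z in Thomson.
#' @export
theoretical_mz <- function(seq, z) {
  z <- as.integer(z)
  if (any(z < 1L)) stop("`z` must be >= 1", call. = FALSE)
  (monoisotopic_mass(seq) + z * .proton_mass) / z
}

#' Validate an observed m/z against a peptide's charge states
#'
#' Compares an observed m/z with the theoretical values of charge states
#' `1..max_charge` computed from the fully disulfide-bonded monoisotopic
#' mass. The match is accepted within a relative tolerance in ppm; the
#' smallest matching charge is reported.
#'
#' @inheritParams monoisotopic_mass
#' @param observed_mz Observed m/z (Th), > 0.
#' @param max_charge Largest charge state considered (default 6, typical
#'   for ESI of cystine-dense peptides).
#' @param tol_ppm Relative tolerance in ppm (default 20).
#' @return A list: `observed_mz`, `matched_charge` (integer or `NA`),
#'   `theoretical_mz` (or `NA`), `valid` (logical), `tol_ppm`.
#' @export
validate_mz <- function(observed_mz, seq, max_charge = 6, tol_ppm = 20) {
  if (!is.numeric(observed_mz) || observed_mz <= 0) {
    stop("`observed_mz` must be > 0", call. = FALSE)
  }
  max_charge <- as.integer(max_charge)
  if (max_charge < 1L) stop("`max_charge` must be >= 1", call. = FALSE)
  z_all <- seq_len(max_charge)
  theo <- theoretical_mz(seq, z_all)
  ppm <- abs(observed_mz - theo) / theo * 1e6
  hit <- which(ppm <= tol_ppm)
  if (length(hit)) {
    z <- z_all[hit[1L]]
    list(observed_mz = observed_mz, matched_charge = z,
         theoretical_mz = theo[hit[1L]], valid = TRUE, tol_ppm = tol_ppm)
  } else {
    list(observed_mz = observed_mz, matched_charge = NA_integer_,
         theoretical_mz = NA_real_, valid = FALSE, tol_ppm = tol_ppm)
  }
}

#' Report duplicated sequences
#'
#' Flags each new sequence that matches (exact string equality after
#' canonicalization) a registry entry or an earlier entry of the same
#' batch — the guard against ordering duplicate DNA syntheses.
#'
#' @param new_seqs Character vector (or list of [parse_sequence()]
#'   results) of candidate sequences, in submission order.
#' @param registry Character vector of already-registered sequences.
#' @return Data frame: `index`, `sequence`, `duplicate` (logical),
#'   `duplicate_of` (`"registry"`, `"batch"` or `NA`).
#' @export
find_duplicates <- function(new_seqs, registry = character(0)) {
  canon <- vapply(new_seqs, function(s) parse_sequence(s)$sequence, "",
                  USE.NAMES = FALSE)
  reg <- vapply(registry, function(s) parse_sequence(s)$sequence, "",
                USE.NAMES = FALSE)
  seen <- character(0)
  dup_of <- rep(NA_character_, length(canon))
  for (i in seq_along(canon)) {
    if (canon[i] %in% reg) {
      dup_of[i] <- "registry"
    } else if (canon[i] %in% seen) {
      dup_of[i] <- "batch"
    }
    seen <- c(seen, canon[i])
  }
  data.frame(index = seq_along(canon), sequence = canon,
             duplicate = !is.na(dup_of), duplicate_of = dup_of,
             stringsAsFactors = FALSE)
}

#' Read peptide sequences from a FASTA file
#'
#' @param path FASTA file path.
#' @return Named character vector of raw sequence strings (not yet
#'   validated; pass through [parse_sequence()]).
#' @export
read_fasta_sequences <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("FASTA file not found: %s", path), call. = FALSE)
  }
  set <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(set), names(set))
}

#' Property table for a batch of sequences
#'
#' One row per input sequence with the four in-silico properties and the
#' duplicate flag; invalid sequences yield an `error` message instead of
#' values, and processing continues.
#'
#' @param seqs Named or unnamed character vector of sequences.
#' @param ph pH for the net-charge column.
#' @param pka_table,scale Constant-set names, see [net_charge()] and
#'   [hydrophobicity()].
#' @param registry Character vector of already-registered sequences for
#'   duplicate flagging.
#' @return Data frame: `id`, `sequence`, `average_mass`,
#'   `monoisotopic_mass`, `net_charge`, `hydrophobicity`, `duplicate`,
#'   `error`.
#' @export
peptide_properties <- function(seqs, ph = 7.4, pka_table = "emboss",
                               scale = "kyte_doolittle",
                               registry = character(0)) {
  ids <- names(seqs)
  if (is.null(ids)) ids <- sprintf("seq%03d", seq_along(seqs))
  rows <- lapply(seq_along(seqs), function(i) {
    tryCatch({
      p <- parse_sequence(seqs[[i]])
      data.frame(id = ids[i], sequence = p$sequence,
                 average_mass = average_mass(p),
                 monoisotopic_mass = monoisotopic_mass(p),
                 net_charge = net_charge(p, ph, pka_table),
                 hydrophobicity = hydrophobicity(p, scale),
                 duplicate = FALSE, error = NA_character_,
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(id = ids[i], sequence = NA_character_,
                 average_mass = NA_real_, monoisotopic_mass = NA_real_,
                 net_charge = NA_real_, hydrophobicity = NA_real_,
                 duplicate = FALSE, error = conditionMessage(e),
                 stringsAsFactors = FALSE)
    })
  })
  out <- do.call(rbind, rows)
  ok <- !is.na(out$sequence)
  if (any(ok)) {
    dup <- find_duplicates(out$sequence[ok], registry)
    out$duplicate[ok] <- dup$duplicate
  }
  rownames(out) <- NULL
  out
}
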