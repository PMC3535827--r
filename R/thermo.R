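# Oligo thermodynamics: Wallace-rule dissociation temperature (with ranges
# over degenerate expansions), GC-content ranges, and nearest-neighbor
# melting temperature for longer oligos.

#' Wallace-rule dissociation temperature
#'
#' Td = 2degC * (#A + #T) + 4degC * (#C + #G), the classic rule of thumb for
#' short hybridization oligos.
#'
#' @param seq non-degenerate DNA string (A/C/G/T only).
#' @return Td in degrees Celsius (integer-valued).
#' @examples
#' wallace_td("ACGT")  # 12
#' @export
wallace_td <- function(seq) {
  ch <- seq_chars(seq)
  if (length(ch) == 0L) stop("empty sequence", call. = FALSE)
  if (!all(ch %in% c("A", "C", "G", "T"))) {
    stop("wallace_td requires a non-degenerate A/C/G/T sequence; ",
         "use td_range() for degenerate oligos", call. = FALSE)
  }
  2 * sum(ch %in% c("A", "T")) + 4 * sum(ch %in% c("C", "G"))
}

#' Td range of a possibly degenerate oligo
#'
#' Minimum and maximum Wallace Td over all concrete expansions. Because the
#' Wallace rule is additive over positions, the extremes are attained
#' positionwise: a position contributes its minimum (2 if its base set
#' contains A or T, else 4) to td_min and its maximum (4 if it contains G
#' or C, else 2) to td_max.
#'
#' @param seq IUPAC DNA string, no gaps.
#' @return numeric vector `c(td_min, td_max)` in degrees Celsius.
#' @examples
#' td_range("ACGR")  # c(12, 14)
#' @export
td_range <- function(seq) {
  m <- char_masks(seq_chars(seq))
  if (length(m) == 0L) stop("empty sequence", call. = FALSE)
  if (anyNA(m)) stop("non-IUPAC character in sequence", call. = FALSE)
  has_at <- bitwAnd(m, 9L) > 0L   # A or T in set
  has_gc <- bitwAnd(m, 6L) > 0L   # C or G in set
  c(td_min = sum(ifelse(has_at, 2, 4)),
    td_max = sum(ifelse(has_gc, 4, 2)))
}

#' GC-content range of a possibly degenerate oligo
#'
#' Positionwise extremes over all expansions: a position is guaranteed GC
#' when its base set is a subset of {G, C}; it can be GC when the set
#' intersects {G, C}.
#'
#' @param seq IUPAC DNA string.
#' @return numeric vector `c(gc_min, gc_max)` in percent.
#' @examples
#' gc_range("ACGR")  # c(50, 75)
#' @export
gc_range <- function(seq) {
  m <- char_masks(seq_chars(seq))
  if (length(m) == 0L) stop("empty sequence", call. = FALSE)
  if (anyNA(m)) stop("non-IUPAC character in sequence", call. = FALSE)
  always_gc <- bitwAnd(m, 9L) == 0L  # no A, no T in set
  maybe_gc <- bitwAnd(m, 6L) > 0L
  c(gc_min = 100 * sum(always_gc) / length(m),
    gc_max = 100 * sum(maybe_gc) / length(m))
}

# Unified nearest-neighbor parameters (Allawi & SantaLucia 1997 /
# SantaLucia 1998 unified set). dH in kcal/mol, dS in cal/(mol K),
# keyed by the 5'->3' top-strand dinucleotide.
NN_DH <- c(AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4,
           CT = -7.8, GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0,
           TT = -7.9, TG = -8.5, AC = -8.4, AG = -7.8, TC = -8.2,
           CC = -8.0)
NN_DS <- c(AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
           CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
           TT = -22.2, TG = -22.7, AC = -22.4, AG = -21.0, TC = -22.2,
           CC = -19.9)
# duplex initiation with a terminal G.C vs terminal A.T pair
NN_INIT_DH <- c(GC = 0.1, AT = 2.3)
NN_INIT_DS <- c(GC = -2.8, AT = 4.1)

#' Nearest-neighbor melting temperature
#'
#' Two-state nearest-neighbor Tm with the unified dinucleotide parameter
#' set, terminal initiation terms, the entropy monovalent-salt correction
#' dS + 0.368 * (N-1) * ln(Na+), and the self-complementarity symmetry
#' correction. Tm = 1000 dH / (dS + R ln(Ct/x)) - 273.15 with R = 1.987
#' cal/(mol K), x = 4 for a non-self-complementary duplex in equimolar
#' strands and x = 1 for a self-complementary one.
#'
#' @param seq non-degenerate DNA string, length >= 8.
#' @param na_molar monovalent cation concentration in mol/L (default 0.05).
#' @param oligo_molar total oligo strand concentration in mol/L
#'   (default 2.5e-7, i.e. 0.25 uM).
#' @return Tm in degrees Celsius.
#' @examples
#' nn_tm("AGCGTAGCTAGCTAGCTAGC")
#' @export
nn_tm <- function(seq, na_molar = 0.05, oligo_molar = 2.5e-7) {
  ch <- seq_chars(seq)
  n <- length(ch)
  if (n < 8L) stop("nearest-neighbor Tm requires length >= 8", call. = FALSE)
  if (!all(ch %in% c("A", "C", "G", "T"))) {
    stop("nn_tm requires a non-degenerate A/C/G/T sequence", call. = FALSE)
  }
  stopifnot(na_molar > 0, oligo_molar > 0)
  steps <- paste0(ch[-n], ch[-1L])
  dH <- sum(NN_DH[steps])
  dS <- sum(NN_DS[steps])
  for (term in c(ch[1L], ch[n])) {
    key <- if (term %in% c("G", "C")) "GC" else "AT"
    dH <- dH + NN_INIT_DH[[key]]
    dS <- dS + NN_INIT_DS[[key]]
  }
  selfcomp <- identical(seq, reverse_complement(seq))
  x <- 4
  if (selfcomp) {
    dS <- dS - 1.4
    x <- 1
  }
  dS <- dS + 0.368 * (n - 1L) * log(na_molar)
  unname(1000 * dH / (dS + 1.987 * log(oligo_molar / x)) - 273.15)
}

#' Thermodynamic summary of a (possibly degenerate) oligo
#'
#' Wallace Td (as a min/max range over expansions) and GC range are always
#' computed; a nearest-neighbor Tm is added for oligos of at least
#' `nn_min_len` nt, computed on the sequence itself when non-degenerate or
#' on `modal_seq` (the modal expansion from the alignment) otherwise.
#'
#' @param seq IUPAC DNA string.
#' @param modal_seq modal concrete expansion (same length), or NA.
#' @param nn_min_len minimum length for reporting the NN Tm (default 14).
#' @inheritParams nn_tm
#' @return list with `length`, `gc_min`, `gc_max`, `td_min`, `td_max`,
#'   `tm_nn` (NA when not computed) and `tm_basis`
#'   (`"exact"`, `"modal"` or NA).
#' @export
thermo_summary <- function(seq, modal_seq = NA_character_, nn_min_len = 14L,
                           na_molar = 0.05, oligo_molar = 2.5e-7) {
  td <- td_range(seq)
  gc <- gc_range(seq)
  n <- nchar(seq)
  tm <- NA_real_
  basis <- NA_character_
  if (n >= nn_min_len) {
    if (degenerate_count(seq) == 0L) {
      tm <- nn_tm(seq, na_molar, oligo_molar)
      basis <- "exact"
    } else if (!is.na(modal_seq) && !grepl("[^ACGT]", modal_seq)) {
      tm <- nn_tm(modal_seq, na_molar, oligo_molar)
      basis <- "modal"
    }
  }
  list(length = n, gc_min = unname(gc[1]), gc_max = unname(gc[2]),
       td_min = unname(td[1]), td_max = unname(td[2]),
       tm_nn = tm, tm_basis = basis)
}
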