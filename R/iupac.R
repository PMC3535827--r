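# IUPAC-IUB nucleotide ambiguity code tables and low-level sequence utilities.
# Bases are encoded as bit masks (A=1, C=2, G=4, T=8) so that set union,
# intersection and code lookup are integer arithmetic.

IUPAC_ALPHABET <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                    "B", "D", "H", "V", "N")

# bit mask per IUPAC code (A=1, C=2, G=4, T=8)
IUPAC_MASK <- c(
  A = 1L, C = 2L, G = 4L, T = 8L,
  R = 5L,  # A|G
  Y = 10L, # C|T
  S = 6L,  # C|G
  W = 9L,  # A|T
  K = 12L, # G|T
  M = 3L,  # A|C
  B = 14L, # C|G|T
  D = 13L, # A|G|T
  H = 11L, # A|C|T
  V = 7L,  # A|C|G
  N = 15L
)

# inverse lookup: mask (1..15) -> code
MASK_TO_CODE <- character(15L)
MASK_TO_CODE[IUPAC_MASK] <- names(IUPAC_MASK)

# number of concrete bases per mask value
MASK_SIZE <- vapply(1:15, function(m) {
  sum(bitwAnd(m, c(1L, 2L, 4L, 8L)) > 0L)
}, integer(1))

IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B", N = "N"
)

#' Split a sequence string into single characters
#' @noRd
seq_chars <- function(seq) {
  strsplit(seq, "", fixed = TRUE)[[1]]
}

#' Map IUPAC characters to bit masks
#'
#' @param chars character vector of single IUPAC letters.
#' @return integer vector of masks; unknown characters give NA.
#' @noRd
char_masks <- function(chars) {
  unname(IUPAC_MASK[chars])
}

#' Concrete bases covered by one IUPAC code
#'
#' @param code a single IUPAC letter.
#' @return character vector drawn from A, C, G, T.
#' @examples
#' iupac_bases("R")  # "A" "G"
#' @export
iupac_bases <- function(code) {
  m <- IUPAC_MASK[[toupper(code)]]
  c("A", "C", "G", "T")[bitwAnd(m, c(1L, 2L, 4L, 8L)) > 0L]
}

#' IUPAC code covering a set of bases
#'
#' @param bases character vector over A, C, G, T (and/or IUPAC codes, which
#'   are expanded first).
#' @return single IUPAC letter covering exactly the union of the inputs.
#' @examples
#' iupac_code(c("A", "G"))  # "R"
#' @export
iupac_code <- function(bases) {
  m <- char_masks(toupper(bases))
  if (anyNA(m)) {
    stop("unknown nucleotide character(s): ",
         paste(unique(bases[is.na(m)]), collapse = ", "), call. = FALSE)
  }
  MASK_TO_CODE[Reduce(bitwOr, m)]
}

#' Number of degenerate positions in an IUPAC string
#'
#' A position is degenerate when its code covers two or more bases.
#'
#' @param seq IUPAC DNA string (no gaps).
#' @return integer count.
#' @examples
#' degenerate_count("ACGR")  # 1
#' @export
degenerate_count <- function(seq) {
  m <- char_masks(seq_chars(seq))
  if (anyNA(m)) stop("non-IUPAC character in sequence", call. = FALSE)
  sum(MASK_SIZE[m] >= 2L)
}

#' Degeneracy (number of concrete expansions) of an IUPAC string
#'
#' The product over positions of the number of bases each code covers;
#' a 25-mer with one R and one N has degeneracy 8.
#'
#' @inheritParams degenerate_count
#' @return numeric count (product of base-set sizes).
#' @examples
#' degeneracy("NRY")  # 16
#' @export
degeneracy <- function(seq) {
  m <- char_masks(seq_chars(seq))
  if (anyNA(m)) stop("non-IUPAC character in sequence", call. = FALSE)
  prod(MASK_SIZE[m])
}

#' Reverse complement of an IUPAC string
#'
#' Complements every code (R<->Y, K<->M, B<->V, D<->H; S, W, N map to
#' themselves) and reverses, so reverse primers can be written 5'->3'.
#'
#' @inheritParams degenerate_count
#' @return IUPAC string.
#' @examples
#' reverse_complement("AAR")  # "YTT"
#' @export
reverse_complement <- function(seq) {
  ch <- seq_chars(seq)
  comp <- IUPAC_COMPLEMENT[ch]
  if (anyNA(comp)) {
    stop("cannot reverse-complement character(s): ",
         paste(unique(ch[is.na(comp)]), collapse = ", "), call. = FALSE)
  }
  paste(rev(comp), collapse = "")
}

#' Enumerate every concrete expansion of a degenerate oligo
#' @noRd
expand_degenerate <- function(seq) {
  sets <- lapply(seq_chars(seq), iupac_bases)
  grid <- expand.grid(rev(sets), stringsAsFactors = FALSE)
  apply(grid[, rev(seq_along(sets)), drop = FALSE], 1L, paste, collapse = "")
}
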