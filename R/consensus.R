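# Collapse an alignment into a degenerate IUPAC consensus with per-position
# conservation, depth and gap tracks.

#' IUPAC code for one alignment column
#'
#' Input characters are first expanded to their base sets (an input R counts
#' as evidence for A and for G). The returned code covers every base whose
#' frequency among non-gap characters exceeds `maf_cutoff`; with the default
#' cutoff of 0 every observed base is covered. If a cutoff excludes every
#' base the maximal-frequency base set is used instead, so a code is always
#' produced.
#'
#' @param bases character vector: one alignment column (IUPAC letters and
#'   `-` gaps).
#' @param maf_cutoff minor-allele-frequency cutoff in `[0, 0.5)`.
#' @return one IUPAC letter.
#' @examples
#' column_code(c("A", "G"))                        # "R"
#' column_code(c(rep("A", 9), "G"), maf_cutoff = 0.15)  # "A"
#' @export
column_code <- function(bases, maf_cutoff = 0) {
  stopifnot(maf_cutoff >= 0, maf_cutoff < 0.5)
  bases <- toupper(bases)
  bases <- bases[bases != "-"]
  if (length(bases) == 0L) {
    stop("all-gap column has no consensus code", call. = FALSE)
  }
  m <- char_masks(bases)
  if (anyNA(m)) stop("non-IUPAC character in column", call. = FALSE)
  cnt <- vapply(c(1L, 2L, 4L, 8L), function(b) sum(bitwAnd(m, b) > 0L),
                numeric(1))
  freq <- cnt / length(bases)
  keep <- freq > maf_cutoff
  if (!any(keep)) keep <- freq == max(freq)
  MASK_TO_CODE[sum(c(1L, 2L, 4L, 8L)[keep])]
}

#' Build a degenerate consensus from an alignment
#'
#' One consensus position per column. Conservation is the frequency of the
#' modal concrete (A/C/G/T) character among non-gap characters; ambiguity
#' codes in the input contribute to the inclusion set but not to the
#' conservation numerator. Columns containing any gap are marked unusable:
#' `has_gap = TRUE` and code `N` (the search layer refuses to span them by
#' default). For a single-record alignment the input is used verbatim as
#' the consensus with conservation 1.
#'
#' @param aln a [read_alignment()] result.
#' @param maf_cutoff see [column_code()].
#' @return object of class `cons_consensus`: list with `code` (character
#'   vector), `conservation`, `code_match` (fraction of non-gap characters
#'   equal to the code letter), `depth`, `has_gap`, `modal` (modal concrete
#'   base, NA where none), `length`, `source` (`"alignment"` or
#'   `"single_sequence"`) and `rna`.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">a", "ACGT", ">b", "ACGA"), fa)
#' cons <- build_consensus(read_alignment(fa))
#' consensus_string(cons)  # "ACGW"
#' @export
build_consensus <- function(aln, maf_cutoff = 0) {
  stopifnot(inherits(aln, "cons_alignment"))
  stopifnot(maf_cutoff >= 0, maf_cutoff < 0.5)
  n <- aln$n
  L <- aln$length
  M <- matrix(unlist(strsplit(aln$seqs, "", fixed = TRUE), use.names = FALSE),
              nrow = n, ncol = L, byrow = TRUE)
  idx <- match(M, c(IUPAC_ALPHABET, "-"))  # 16 = gap
  dim(idx) <- dim(M)
  gap <- idx == 16L
  depth <- n - colSums(gap)
  has_gap <- depth < n

  # inclusion counts: how many non-gap characters cover each base
  mask_of <- c(unname(IUPAC_MASK[IUPAC_ALPHABET]), 0L)[idx]
  dim(mask_of) <- dim(M)
  inc <- matrix(0, nrow = 4L, ncol = L)
  conc <- matrix(0, nrow = 4L, ncol = L)
  bits <- c(1L, 2L, 4L, 8L)
  for (b in 1:4) {
    inc[b, ] <- colSums(matrix(bitwAnd(mask_of, bits[b]) > 0L, nrow = n))
    conc[b, ] <- colSums(mask_of == bits[b])
  }

  code <- character(L)
  ok <- depth > 0L
  freq <- sweep(inc, 2L, pmax(depth, 1L), "/")
  keep <- freq > maf_cutoff
  # columns where the cutoff excluded everything: fall back to modal bases
  none <- ok & colSums(keep) == 0L
  if (any(none)) {
    fmax <- apply(freq[, none, drop = FALSE], 2L, max)
    keep[, none] <- sweep(freq[, none, drop = FALSE], 2L, fmax, "==")
  }
  masks <- colSums(keep * bits)
  code[ok] <- MASK_TO_CODE[masks[ok]]
  code[!ok] <- "N"          # all-gap column
  code[has_gap] <- "N"      # gapped column is unusable

  conservation <- ifelse(ok, apply(conc, 2L, max) / pmax(depth, 1L), 0)
  modal_i <- apply(conc, 2L, which.max)
  modal <- c("A", "C", "G", "T")[modal_i]
  modal[apply(conc, 2L, max) == 0] <- NA_character_

  code_match <- ifelse(ok, colSums(M == rep(code, each = n) & !gap) /
                         pmax(depth, 1L), 0)

  source <- if (n == 1L) "single_sequence" else "alignment"
  if (source == "single_sequence") {
    code <- M[1L, ]
    conservation <- rep(1, L)
    code_match <- rep(1, L)
  }

  structure(
    list(code = code, conservation = conservation, code_match = code_match,
         depth = as.integer(depth), has_gap = has_gap, modal = modal,
         length = L, source = source, rna = isTRUE(aln$rna)),
    class = "cons_consensus"
  )
}

#' Consensus as a single IUPAC string
#' @param cons a `cons_consensus`.
#' @return character scalar.
#' @export
consensus_string <- function(cons) {
  stopifnot(inherits(cons, "cons_consensus"))
  paste(cons$code, collapse = "")
}

#' Write the consensus as single-record FASTA
#' @param cons a `cons_consensus`.
#' @param path output path.
#' @param id FASTA header id.
#' @return `path`, invisibly.
#' @export
write_consensus_fasta <- function(cons, path, id = "consensus") {
  s <- consensus_string(cons)
  if (isTRUE(cons$rna)) s <- chartr("T", "U", s)
  set <- Biostrings::BStringSet(s)
  names(set) <- id
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Write the per-position conservation track as TSV
#'
#' Columns: 1-based position, IUPAC code, conservation (modal-base
#' fraction), code_match (exact-match-to-code fraction), depth, has_gap.
#'
#' @param cons a `cons_consensus`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_conservation_tsv <- function(cons, path) {
  stopifnot(inherits(cons, "cons_consensus"))
  df <- data.frame(
    position = seq_len(cons$length),
    code = cons$code,
    conservation = sprintf("%.4f", cons$conservation),
    code_match = sprintf("%.4f", cons$code_match),
    depth = cons$depth,
    has_gap = cons$has_gap
  )
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("# per-position consensus conservation track (1-based)", con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.cons_consensus <- function(x, ...) {
  nd <- sum(MASK_SIZE[char_masks(x$code)] >= 2L)
  cat(sprintf("<consensus: %d nt, %d degenerate position(s), source=%s>\n",
              x$length, nd, x$source))
  invisible(x)
}
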