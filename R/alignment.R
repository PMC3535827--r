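# Reading and validating FASTA input: either a multiple sequence alignment
# (equal-length records, gaps as '-') or a single, possibly degenerate,
# sequence that is used directly as the consensus.

allowed_chars <- function() c(IUPAC_ALPHABET, "-")

#' Read and validate a FASTA alignment (or single sequence)
#'
#' Accepts wrapped or unwrapped FASTA with LF or CRLF line endings.
#' Sequences are uppercased; with `alphabet = "RNA"` every U is mapped to T
#' (and the report layer maps T back to U on output). IUPAC ambiguity codes
#' are permitted, so a manually curated degenerate consensus can be supplied
#' as a single record. Gap characters (`-`) are only allowed when the file
#' holds two or more records.
#'
#' @param path path to a FASTA file.
#' @param alphabet `"DNA"` (default) or `"RNA"`.
#' @return an object of class `cons_alignment`: a list with elements
#'   `ids`, `descriptions`, `seqs` (uppercase character vector), `length`
#'   (alignment columns), `n` (records) and `rna` (logical).
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1", "ACGT", ">s2", "ACGA"), fa)
#' aln <- read_alignment(fa)
#' aln$length  # 4
#' @export
read_alignment <- function(path, alphabet = c("DNA", "RNA")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) {
    stop("input error: file not found: ", path, call. = FALSE)
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) {
      stop("input error: cannot parse FASTA from ", path, " (",
           conditionMessage(e), ")", call. = FALSE)
    }
  )
  if (length(set) == 0L) {
    stop("input error: FASTA file holds no records: ", path, call. = FALSE)
  }
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  descriptions <- ifelse(grepl("\\s", headers),
                         sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids)) {
    warning("duplicate record id(s): ",
            paste(unique(ids[duplicated(ids)]), collapse = ", "),
            call. = FALSE)
  }
  seqs <- toupper(as.character(set))
  seqs <- gsub("\r", "", seqs, fixed = TRUE)
  if (alphabet == "RNA") seqs <- chartr("U", "T", seqs)
  names(seqs) <- NULL

  lens <- nchar(seqs)
  if (any(lens == 0L)) {
    stop("input error: empty sequence in record '",
         ids[which(lens == 0L)[1]], "'", call. = FALSE)
  }
  if (length(unique(lens)) > 1L) {
    bad <- which(lens != lens[1])[1]
    stop("alignment shape error: record '", ids[bad], "' has length ",
         lens[bad], " but record '", ids[1], "' has length ", lens[1],
         call. = FALSE)
  }

  allowed <- allowed_chars()
  if (length(seqs) == 1L) allowed <- setdiff(allowed, "-")
  for (i in seq_along(seqs)) {
    ch <- seq_chars(seqs[i])
    bad <- which(!(ch %in% allowed))
    if (length(bad) > 0L) {
      if (ch[bad[1]] == "-") {
        stop("alphabet error: gap character in single-sequence input, ",
             "record '", ids[i], "' column ", bad[1], call. = FALSE)
      }
      stop("alphabet error: illegal character '", ch[bad[1]],
           "' in record '", ids[i], "' at column ", bad[1], call. = FALSE)
    }
  }

  structure(
    list(ids = ids, descriptions = descriptions, seqs = seqs,
         length = lens[1], n = length(seqs), rna = (alphabet == "RNA")),
    class = "cons_alignment"
  )
}

#' Write an alignment back to FASTA
#'
#' Inverse of [read_alignment()] up to line wrapping; RNA alignments are
#' written with U restored.
#'
#' @param aln a `cons_alignment`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "cons_alignment"))
  seqs <- aln$seqs
  if (isTRUE(aln$rna)) seqs <- chartr("T", "U", seqs)
  hdr <- ifelse(nzchar(aln$descriptions),
                paste(aln$ids, aln$descriptions), aln$ids)
  set <- Biostrings::BStringSet(seqs)
  names(set) <- hdr
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' @export
print.cons_alignment <- function(x, ...) {
  cat(sprintf("<alignment: %d record(s) x %d column(s)%s>\n",
              x$n, x$length, if (x$rna) ", RNA" else ""))
  invisible(x)
}
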