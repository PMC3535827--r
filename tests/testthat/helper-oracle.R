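# Independent brute-force oracles and small fixture builders. The oracle
# code deliberately shares nothing with the package internals: it spells
# out its own IUPAC tables and applies every search rule literally,
# candidate by candidate.

ORC_SET <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)
ORC_COMP <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
              S = "S", W = "W", K = "M", M = "K", B = "V", D = "H",
              H = "D", V = "B", N = "N")

orc_chars <- function(s) strsplit(s, "")[[1]]

orc_expand <- function(seq) {
  sets <- ORC_SET[orc_chars(seq)]
  out <- ""
  for (set in sets) out <- as.vector(outer(out, set, paste0))
  out
}

orc_wallace <- function(seq) {
  ch <- orc_chars(seq)
  2 * sum(ch == "A" | ch == "T") + 4 * sum(ch == "C" | ch == "G")
}

orc_td_range_brute <- function(seq) {
  tds <- vapply(orc_expand(seq), orc_wallace, numeric(1))
  c(min(tds), max(tds))
}

orc_revcomp <- function(seq) {
  paste(rev(ORC_COMP[orc_chars(seq)]), collapse = "")
}

orc_deg_count <- function(seq) {
  sum(lengths(ORC_SET[orc_chars(seq)]) >= 2)
}

# literal scan oracle: every substring, both strands, every rule applied
# per candidate. Returns data.frame(start, length, strand) sorted by
# (start, length, strand), 1-based inclusive starts.
orc_enumerate <- function(cons, params) {
  codes <- cons$code
  L <- length(codes)
  setsz <- lengths(ORC_SET[codes])
  at_ok <- vapply(ORC_SET[codes], function(s) any(s %in% c("A", "T")),
                  logical(1))
  gc_ok <- vapply(ORC_SET[codes], function(s) any(s %in% c("C", "G")),
                  logical(1))
  res <- list()
  for (start in seq_len(L)) {
    for (len in params$oligo_min_len:params$oligo_max_len) {
      end <- start + len - 1
      if (end > L) next
      i <- start:end
      if (sum(setsz[i] >= 2) > params$max_degenerate) next
      if (!params$allow_gap_columns && any(cons$has_gap[i])) next
      if (any(cons$conservation[i] < params$min_conservation)) next
      tdmin <- sum(ifelse(at_ok[i], 2, 4))
      tdmax <- sum(ifelse(gc_ok[i], 4, 2))
      if (tdmin > params$td_max || tdmax < params$td_min) next
      for (strand in c("forward", "reverse")) {
        cl <- min(params$clamp_len, len)
        if (cl > 0) {
          three <- if (strand == "forward") i[(len - cl + 1):len]
                   else i[1:cl]
          if (any(setsz[three] >= 2)) next
        }
        res[[length(res) + 1]] <-
          data.frame(start = start, length = len, strand = strand)
      }
    }
  }
  if (length(res) == 0) {
    return(data.frame(start = integer(0), length = integer(0),
                      strand = character(0)))
  }
  df <- do.call(rbind, res)
  df <- df[order(df$start, df$length, df$strand), ]
  rownames(df) <- NULL
  df
}

# ---- fixture builders -------------------------------------------------

make_aln <- function(seqs, alphabet = "DNA", ids = NULL) {
  if (is.null(ids)) ids <- paste0("s", seq_along(seqs))
  fa <- tempfile(fileext = ".fasta")
  on.exit(unlink(fa))
  writeLines(as.vector(rbind(paste0(">", ids), seqs)), fa)
  read_alignment(fa, alphabet)
}

# consensus from a single (possibly degenerate) sequence string
cons_of <- function(seq) {
  build_consensus(make_aln(seq))
}

# random alignment with optional IUPAC characters and gaps in the input
rand_aln <- function(n, L, p_mut = 0.2, p_iupac = 0, p_gap = 0) {
  bases <- c("A", "C", "G", "T")
  codes <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N")
  anc <- sample(bases, L, replace = TRUE)
  seqs <- vapply(seq_len(n), function(i) {
    ch <- anc
    mut <- runif(L) < p_mut
    ch[mut] <- sample(bases, sum(mut), replace = TRUE)
    if (p_iupac > 0) {
      amb <- runif(L) < p_iupac
      ch[amb] <- sample(codes, sum(amb), replace = TRUE)
    }
    if (p_gap > 0 && n > 1) {
      gp <- runif(L) < p_gap
      ch[gp] <- "-"
    }
    paste(ch, collapse = "")
  }, character(1))
  make_aln(seqs)
}

# random degenerate oligo with bounded degeneracy (for td_range oracle)
rand_degenerate_oligo <- function(min_len = 6, max_len = 12) {
  len <- sample(min_len:max_len, 1)
  ch <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  # up to three degenerate substitutions keeps degeneracy <= 4^3 = 64
  nd <- sample(0:3, 1)
  if (nd > 0) {
    pos <- sample(len, nd)
    ch[pos] <- sample(c("R", "Y", "S", "W", "K", "M", "B", "D", "H",
                        "V", "N"), nd, replace = TRUE)
  }
  paste(ch, collapse = "")
}

# randomized search parameters for the scan-oracle equivalence checks
rand_params <- function() {
  min_len <- sample(8:14, 1)
  search_params(
    mode = "all_oligos",
    oligo_min_len = min_len,
    oligo_max_len = min_len + sample(0:5, 1),
    max_degenerate = sample(0:4, 1),
    clamp_len = sample(0:4, 1),
    td_min = sample(20:45, 1),
    td_max = sample(46:90, 1),
    allow_gap_columns = sample(c(TRUE, FALSE), 1),
    min_conservation = sample(c(0, 0, 0.5, 0.8), 1)
  )
}

# planted primer/probe triple geometry on the default 20-nt slide grid
triple_blocks <- function(window_starts) {
  do.call(rbind, lapply(window_starts, function(w) {
    rbind(c(w, w + 24L), c(w + 60L, w + 84L), c(w + 126L, w + 150L))
  }))
}
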