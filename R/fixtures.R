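# Synthetic alignment generator: random ancestor, planted conserved blocks,
# independent per-site background substitutions and single-column gaps.
# Gives every search behaviour a ground truth without external data.

#' Specification for a synthetic alignment
#'
#' Describes an alignment drawn from a star-shaped model: one random
#' ancestor copied `n_seqs` times, with every background position mutated
#' independently (uniformly over the three alternative bases) and gapped
#' with small probability. Positions inside `conserved_blocks` are never
#' mutated or gapped, so the blocks are exact ground truth for
#' conserved-region search.
#'
#' @param n_seqs number of sequences.
#' @param length alignment length in nt.
#' @param conserved_blocks two-column integer matrix of 0-based half-open
#'   `[start, end)` intervals (possibly empty), non-overlapping, within
#'   the alignment.
#' @param background_divergence per-site substitution probability outside
#'   the blocks, in `[0, 1]`.
#' @param indel_prob per-site single-column gap probability outside the
#'   blocks, in `[0, 1]`.
#' @param seed integer RNG seed; generation is fully deterministic given
#'   the seed and the other fields.
#' @return object of class `synth_spec`.
#' @export
synth_spec <- function(n_seqs, length, conserved_blocks = NULL,
                       background_divergence = 0.3, indel_prob = 0.002,
                       seed = 1L) {
  if (is.null(conserved_blocks)) {
    conserved_blocks <- matrix(integer(0), ncol = 2)
  }
  conserved_blocks <- matrix(as.integer(conserved_blocks), ncol = 2)
  stopifnot(n_seqs >= 1L, length >= 1L,
            background_divergence >= 0, background_divergence <= 1,
            indel_prob >= 0, indel_prob <= 1)
  if (nrow(conserved_blocks) > 0L) {
    if (any(conserved_blocks[, 1] < 0L) ||
        any(conserved_blocks[, 2] > length) ||
        any(conserved_blocks[, 2] <= conserved_blocks[, 1])) {
      stop("spec error: conserved block outside [0, length) or empty",
           call. = FALSE)
    }
    ord <- order(conserved_blocks[, 1])
    b <- conserved_blocks[ord, , drop = FALSE]
    if (nrow(b) > 1L && any(b[-1L, 1] < b[-nrow(b), 2])) {
      stop("spec error: conserved blocks overlap", call. = FALSE)
    }
  }
  structure(list(n_seqs = as.integer(n_seqs), length = as.integer(length),
                 conserved_blocks = conserved_blocks,
                 background_divergence = background_divergence,
                 indel_prob = indel_prob, seed = as.integer(seed)),
            class = "synth_spec")
}

# run code with a local, restored RNG state seeded from `seed`
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Generate a synthetic alignment with planted conserved blocks
#'
#' @param spec a [synth_spec()].
#' @return list with `alignment` (a `cons_alignment`) and `truth` (the
#'   planted block matrix, 0-based half-open).
#' @examples
#' g <- generate_alignment(synth_spec(8, 200, rbind(c(10, 34)), seed = 42))
#' g$alignment$n  # 8
#' @export
generate_alignment <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  with_local_seed(spec$seed, {
    bases <- c("A", "C", "G", "T")
    L <- spec$length
    n <- spec$n_seqs
    ancestor <- sample(bases, L, replace = TRUE)
    protected <- logical(L)
    for (i in seq_len(nrow(spec$conserved_blocks))) {
      b <- spec$conserved_blocks[i, ]
      protected[(b[1] + 1L):b[2]] <- TRUE
    }
    M <- matrix(rep(ancestor, each = n), nrow = n, ncol = L)
    bg <- which(!protected)
    if (length(bg) > 0L && spec$background_divergence > 0) {
      mut <- matrix(stats::runif(n * length(bg)) < spec$background_divergence,
                    nrow = n)
      nm <- sum(mut)
      if (nm > 0L) {
        # uniform over the three alternatives to the current base
        shift <- sample(1:3, nm, replace = TRUE)
        cur <- match(M[, bg][mut], bases)
        M[, bg][mut] <- bases[((cur - 1L + shift) %% 4L) + 1L]
      }
    }
    if (length(bg) > 0L && spec$indel_prob > 0) {
      gap <- matrix(stats::runif(n * length(bg)) < spec$indel_prob, nrow = n)
      if (n == 1L) gap[] <- FALSE  # a lone record may not carry gaps
      M[, bg][gap] <- "-"
    }
    seqs <- apply(M, 1L, paste, collapse = "")
    aln <- structure(
      list(ids = sprintf("synth_%03d", seq_len(n)),
           descriptions = rep("", n), seqs = unname(seqs),
           length = L, n = n, rna = FALSE),
      class = "cons_alignment"
    )
    list(alignment = aln, truth = spec$conserved_blocks)
  })
}

#' Large divergent-alignment stress preset
#'
#' A synthetic stand-in for a stress test on dozens of aligned full-length
#' viral genomes: 61 sequences of 10,000 nt at 30% background divergence,
#' with four planted primer/probe site triples. Each triple holds three
#' 24-nt conserved blocks (forward site, probe site, reverse site); the
#' reverse block ends exactly 150 nt downstream of the forward block
#' start and the forward start sits on the default 20-nt slide grid, so a
#' windowed real-time PCR search at the defaults (window 150, slide 20,
#' probe on) can recover every triple.
#'
#' @param seed RNG seed.
#' @return the `synth_spec` for the preset.
#' @export
hcv_like_spec <- function(seed = 1L) {
  pair_starts <- c(400L, 2400L, 5000L, 8000L)
  blocks <- do.call(rbind, lapply(pair_starts, function(w) {
    rbind(c(w, w + 24L), c(w + 60L, w + 84L), c(w + 126L, w + 150L))
  }))
  synth_spec(n_seqs = 61L, length = 10000L, conserved_blocks = blocks,
             background_divergence = 0.30, indel_prob = 0.002, seed = seed)
}

#' Generate the stress-preset alignment
#'
#' @param seed RNG seed.
#' @return as [generate_alignment()].
#' @export
hcv_like_stress <- function(seed = 1L) {
  generate_alignment(hcv_like_spec(seed))
}

#' Write a generated fixture to FASTA plus a truth TSV
#'
#' The truth file lists the planted conserved blocks with 1-based
#' inclusive coordinates (the report convention), stated in its header.
#'
#' @param gen a [generate_alignment()] result.
#' @param fasta_path,truth_path output paths.
#' @return invisibly, a list of the two paths.
#' @export
write_fixture <- function(gen, fasta_path, truth_path) {
  write_alignment(gen$alignment, fasta_path)
  con <- file(truth_path, open = "wt")
  on.exit(close(con))
  writeLines(c("# planted conserved blocks; coordinates 1-based inclusive",
               "start\tend"), con)
  if (nrow(gen$truth) > 0L) {
    writeLines(sprintf("%d\t%d", gen$truth[, 1] + 1L, gen$truth[, 2]), con)
  }
  invisible(list(fasta = fasta_path, truth = truth_path))
}
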