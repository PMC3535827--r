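# Conserved-oligo search on the degenerate consensus: windowed primer/probe
# set design (the sliding product window) and exhaustive oligo enumeration.
#
# Coordinates are 0-based half-open internally; everything user-facing
# (returned tables, reports) is 1-based inclusive.

#' Search parameters
#'
#' All user-settable knobs of the search, with the tool's defaults: sliding
#' value 20 nt, at most 3 degenerate positions per oligo, and a 3-position
#' non-degenerate 3' clamp on primers and probes. The default product
#' window is 150 nt when a probe is requested (real-time PCR sizing) and
#' 400 nt otherwise (sequencing-style amplicons).
#'
#' @param mode `"windowed"` (sliding product window, the default) or
#'   `"all_oligos"` (list every valid oligo with coordinates).
#' @param probe search for a hybridization probe between the primers
#'   (real-time PCR mode).
#' @param window_size product size in nt; default 150 if `probe` else 400.
#' @param slide window step in nt (default 20).
#' @param oligo_min_len,oligo_max_len oligo length bounds in nt
#'   (defaults 18 and 25).
#' @param max_degenerate maximum degenerate positions per oligo (default 3).
#' @param clamp_len number of 3'-terminal positions required
#'   non-degenerate (default 3).
#' @param td_min,td_max acceptable Wallace Td band in degrees Celsius
#'   (defaults 50 and 65); an oligo passes when its Td range intersects
#'   the band.
#' @param allow_gap_columns permit oligos spanning alignment columns that
#'   contain gaps (default FALSE).
#' @param min_conservation minimum per-position conservation an oligo may
#'   span (default 0, i.e. no extra filter).
#' @param probe_no_clamp drop the 3' clamp requirement for probes
#'   (hydrolysis probes are not extended by the polymerase).
#' @param probe_both_strands also consider reverse-strand probes
#'   (default FALSE: forward strand only).
#' @param anchor_slack allow the forward primer to start up to this many nt
#'   after the window start and the reverse binding site to end up to this
#'   many nt before the window end (default 0: product size equals
#'   `window_size` exactly).
#' @param all_candidates in windowed mode emit every valid forward/reverse
#'   combination per window instead of only the best-scoring one.
#' @param nn_min_len minimum oligo length for reporting a nearest-neighbor
#'   Tm (default 14).
#' @param na_molar,oligo_molar nearest-neighbor conditions, see [nn_tm()].
#' @return object of class `search_params` (a validated list).
#' @export
search_params <- function(mode = c("windowed", "all_oligos"),
                          probe = FALSE,
                          window_size = NULL,
                          slide = 20L,
                          oligo_min_len = 18L,
                          oligo_max_len = 25L,
                          max_degenerate = 3L,
                          clamp_len = 3L,
                          td_min = 50,
                          td_max = 65,
                          allow_gap_columns = FALSE,
                          min_conservation = 0,
                          probe_no_clamp = FALSE,
                          probe_both_strands = FALSE,
                          anchor_slack = 0L,
                          all_candidates = FALSE,
                          nn_min_len = 14L,
                          na_molar = 0.05,
                          oligo_molar = 2.5e-7) {
  mode <- match.arg(mode)
  if (is.null(window_size)) window_size <- if (probe) 150L else 400L
  p <- list(mode = mode, probe = isTRUE(probe),
            window_size = as.integer(window_size),
            slide = as.integer(slide),
            oligo_min_len = as.integer(oligo_min_len),
            oligo_max_len = as.integer(oligo_max_len),
            max_degenerate = as.integer(max_degenerate),
            clamp_len = as.integer(clamp_len),
            td_min = td_min, td_max = td_max,
            allow_gap_columns = isTRUE(allow_gap_columns),
            min_conservation = min_conservation,
            probe_no_clamp = isTRUE(probe_no_clamp),
            probe_both_strands = isTRUE(probe_both_strands),
            anchor_slack = as.integer(anchor_slack),
            all_candidates = isTRUE(all_candidates),
            nn_min_len = as.integer(nn_min_len),
            na_molar = na_molar, oligo_molar = oligo_molar)
  if (p$slide < 1L) stop("slide must be >= 1", call. = FALSE)
  if (p$max_degenerate < 0L) stop("max_degenerate must be >= 0", call. = FALSE)
  if (p$clamp_len < 0L) stop("clamp_len must be >= 0", call. = FALSE)
  if (p$anchor_slack < 0L) stop("anchor_slack must be >= 0", call. = FALSE)
  if (p$oligo_min_len < 1L || p$oligo_min_len > p$oligo_max_len) {
    stop("need 1 <= oligo_min_len <= oligo_max_len", call. = FALSE)
  }
  if (p$mode == "windowed" && p$oligo_max_len >= p$window_size) {
    stop("oligo_max_len must be smaller than window_size", call. = FALSE)
  }
  if (p$td_min > p$td_max) stop("td_min must be <= td_max", call. = FALSE)
  if (p$min_conservation < 0 || p$min_conservation > 1) {
    stop("min_conservation must be in [0, 1]", call. = FALSE)
  }
  structure(p, class = "search_params")
}

# Per-consensus precomputation: cumulative sums that make every candidate
# check O(1). cum_*[i+1] holds the sum over positions 0..i-1 (0-based).
cons_precompute <- function(cons, params) {
  m <- char_masks(cons$code)
  isdeg <- MASK_SIZE[m] >= 2L
  lowcons <- cons$conservation < params$min_conservation
  tdmin_pos <- ifelse(bitwAnd(m, 9L) > 0L, 2, 4)
  tdmax_pos <- ifelse(bitwAnd(m, 6L) > 0L, 4, 2)
  list(
    cum_deg = c(0L, cumsum(isdeg)),
    cum_gap = c(0L, cumsum(cons$has_gap)),
    cum_low = c(0L, cumsum(lowcons)),
    cum_tdmin = c(0, cumsum(tdmin_pos)),
    cum_tdmax = c(0, cumsum(tdmax_pos))
  )
}

# Vectorized validity over candidates (start0, len, strand). Returns a
# logical vector. `strand` is "forward" or "reverse" per candidate; the
# only orientation-dependent rule is the 3' clamp.
candidate_valid <- function(pre, start0, len, strand, params,
                            is_probe = FALSE) {
  s <- start0
  e <- start0 + len
  deg <- pre$cum_deg[e + 1L] - pre$cum_deg[s + 1L]
  ok <- len >= params$oligo_min_len & len <= params$oligo_max_len
  ok <- ok & deg <= params$max_degenerate
  if (!params$allow_gap_columns) {
    ok <- ok & (pre$cum_gap[e + 1L] - pre$cum_gap[s + 1L]) == 0L
  }
  ok <- ok & (pre$cum_low[e + 1L] - pre$cum_low[s + 1L]) == 0L
  tdmin <- pre$cum_tdmin[e + 1L] - pre$cum_tdmin[s + 1L]
  tdmax <- pre$cum_tdmax[e + 1L] - pre$cum_tdmax[s + 1L]
  ok <- ok & tdmin <= params$td_max & tdmax >= params$td_min
  clamp <- params$clamp_len
  if (is_probe && params$probe_no_clamp) clamp <- 0L
  if (clamp > 0L) {
    cl <- pmin(clamp, len)
    # 3' end is the right edge for forward oligos, the left for reverse
    fwd <- rep(strand == "forward", length.out = length(s))
    cs <- ifelse(fwd, e - cl, s)
    ce <- ifelse(fwd, e, s + cl)
    ok <- ok & (pre$cum_deg[ce + 1L] - pre$cum_deg[cs + 1L]) == 0L
  }
  ok
}

#' Validate a single candidate oligo against the search rules
#'
#' Applies every rule and reports the identifiers of all failed ones:
#' `length_range`, `max_degenerate`, `three_prime_clamp`, `td_band`,
#' `gap_column`, `min_conservation`. Validation never throws on content.
#'
#' @param cons a [build_consensus()] result.
#' @param start,end 1-based inclusive coordinates on the consensus.
#' @param strand `"forward"` or `"reverse"`.
#' @param params a [search_params()] object.
#' @param is_probe apply probe rules (honours `probe_no_clamp`).
#' @return list with `valid` (logical) and `reasons` (character vector of
#'   failed rule identifiers, empty when valid).
#' @export
validate_oligo <- function(cons, start, end, strand = c("forward", "reverse"),
                           params = search_params(), is_probe = FALSE) {
  stopifnot(inherits(cons, "cons_consensus"))
  strand <- match.arg(strand)
  stopifnot(start >= 1L, end >= start, end <= cons$length)
  idx <- start:end
  len <- length(idx)
  codes <- cons$code[idx]
  deg <- MASK_SIZE[char_masks(codes)] >= 2L
  reasons <- character(0)
  if (len < params$oligo_min_len || len > params$oligo_max_len) {
    reasons <- c(reasons, "length_range")
  }
  if (sum(deg) > params$max_degenerate) {
    reasons <- c(reasons, "max_degenerate")
  }
  clamp <- params$clamp_len
  if (is_probe && params$probe_no_clamp) clamp <- 0L
  if (clamp > 0L) {
    cl <- min(clamp, len)
    three_prime <- if (strand == "forward") deg[(len - cl + 1L):len]
                   else deg[1:cl]
    if (any(three_prime)) reasons <- c(reasons, "three_prime_clamp")
  }
  td <- td_range(paste(codes, collapse = ""))
  if (td[1] > params$td_max || td[2] < params$td_min) {
    reasons <- c(reasons, "td_band")
  }
  if (!params$allow_gap_columns && any(cons$has_gap[idx])) {
    reasons <- c(reasons, "gap_column")
  }
  if (any(cons$conservation[idx] < params$min_conservation)) {
    reasons <- c(reasons, "min_conservation")
  }
  list(valid = length(reasons) == 0L, reasons = reasons)
}

# Build the user-facing oligo table (1-based inclusive coordinates,
# sequences written 5'->3') from internal 0-based candidates.
oligo_table <- function(cons, start0, len, strand, role, params) {
  n <- length(start0)
  if (n == 0L) {
    return(data.frame(role = character(0), seq = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), length = integer(0),
                      degenerate_count = integer(0), degeneracy = numeric(0),
                      gc_min = numeric(0), gc_max = numeric(0),
                      td_min = numeric(0), td_max = numeric(0),
                      tm_nn = numeric(0), tm_basis = character(0),
                      stringsAsFactors = FALSE))
  }
  cs <- consensus_string(cons)
  fwd_seq <- substring(cs, start0 + 1L, start0 + len)
  seq <- ifelse(strand == "reverse",
                vapply(fwd_seq, reverse_complement, character(1),
                       USE.NAMES = FALSE),
                fwd_seq)
  modal <- vapply(seq_len(n), function(i) {
    sl <- cons$modal[(start0[i] + 1L):(start0[i] + len[i])]
    if (anyNA(sl)) return(NA_character_)
    s <- paste(sl, collapse = "")
    if (strand[i] == "reverse") reverse_complement(s) else s
  }, character(1))
  th <- lapply(seq_len(n), function(i) {
    thermo_summary(seq[i], modal[i], params$nn_min_len,
                   params$na_molar, params$oligo_molar)
  })
  data.frame(
    role = role,
    seq = seq,
    start = start0 + 1L,
    end = start0 + len,
    strand = strand,
    length = len,
    degenerate_count = vapply(seq, degenerate_count, numeric(1),
                              USE.NAMES = FALSE),
    degeneracy = vapply(seq, degeneracy, numeric(1), USE.NAMES = FALSE),
    gc_min = vapply(th, `[[`, numeric(1), "gc_min"),
    gc_max = vapply(th, `[[`, numeric(1), "gc_max"),
    td_min = vapply(th, `[[`, numeric(1), "td_min"),
    td_max = vapply(th, `[[`, numeric(1), "td_max"),
    tm_nn = vapply(th, `[[`, numeric(1), "tm_nn"),
    tm_basis = vapply(th, `[[`, character(1), "tm_basis"),
    stringsAsFactors = FALSE
  )
}

#' Enumerate every valid oligo along the consensus
#'
#' Tests every consensus substring with length in the configured bounds, in
#' forward orientation and as the reverse complement, against all rules,
#' and returns the valid ones sorted by start, length, then strand
#' (forward before reverse). This is the "all possible oligos" search
#' option; it reports coordinates so primer combinations can be picked
#' manually.
#'
#' @param cons a [build_consensus()] result.
#' @param params a [search_params()] object (its `mode` should be
#'   `"all_oligos"`; `window_size` is ignored).
#' @return data.frame of oligos (one row each; 1-based inclusive `start`
#'   and `end`, `seq` written 5'->3').
#' @export
enumerate_oligos <- function(cons, params = search_params(mode = "all_oligos")) {
  stopifnot(inherits(cons, "cons_consensus"))
  L <- cons$length
  if (L < params$oligo_min_len) {
    warning("consensus (", L, " nt) is shorter than oligo_min_len; ",
            "no oligos can be produced")
    return(oligo_table(cons, integer(0), integer(0), character(0),
                       character(0), params))
  }
  pre <- cons_precompute(cons, params)
  lens <- params$oligo_min_len:min(params$oligo_max_len, L)
  cand_s <- integer(0)
  cand_l <- integer(0)
  for (len in lens) {
    st <- 0:(L - len)
    cand_s <- c(cand_s, st)
    cand_l <- c(cand_l, rep(len, length(st)))
  }
  out_s <- integer(0); out_l <- integer(0); out_strand <- character(0)
  for (strand in c("forward", "reverse")) {
    ok <- candidate_valid(pre, cand_s, cand_l, strand, params)
    out_s <- c(out_s, cand_s[ok])
    out_l <- c(out_l, cand_l[ok])
    out_strand <- c(out_strand, rep(strand, sum(ok)))
  }
  ord <- order(out_s, out_l, out_strand)
  oligo_table(cons, out_s[ord], out_l[ord],
              out_strand[ord], "generic", params)
}

#' Score a candidate oligo (lower is better)
#'
#' Deterministic lexicographic ranking used to pick one candidate per role
#' in windowed mode: fewer degenerate positions first; then Td-range
#' midpoint closest to the centre of the acceptable band; then longer
#' oligos; then smaller start; strand (forward first) breaks any remaining
#' tie, so distinct (start, length, strand) triples never score equal.
#'
#' @param oligo one row of an oligo table (list or single-row data.frame).
#' @param params a [search_params()] object.
#' @return numeric key vector; compare lexicographically.
#' @export
score_candidate <- function(oligo, params) {
  band_centre <- (params$td_min + params$td_max) / 2
  c(oligo$degenerate_count,
    abs((oligo$td_min + oligo$td_max) / 2 - band_centre),
    -oligo$length,
    oligo$start,
    as.integer(oligo$strand == "reverse"))
}

# index of the best-scoring row of an oligo table (NA if empty)
best_candidate <- function(tab, params) {
  if (nrow(tab) == 0L) return(NA_integer_)
  keys <- t(vapply(seq_len(nrow(tab)),
                   function(i) score_candidate(tab[i, ], params),
                   numeric(5)))
  do.call(order, as.data.frame(keys))[1L]
}

#' Find primer (and probe) sets with a sliding product window
#'
#' Slides a window of `window_size` nt (the required PCR product size)
#' along the consensus in steps of `slide` nt. In each window the forward
#' primer must start at the window's first position and the reverse
#' primer's binding site must end at its last position (relaxable with
#' `anchor_slack`), so the product size equals the window size. With
#' `probe = TRUE` a valid probe strictly between the primers is also
#' required (real-time PCR mode). One set per window is returned — the
#' best-scoring candidate per role — unless `all_candidates` is set;
#' windows with no complete set are omitted and duplicate sets arising
#' from overlapping windows are reported once.
#'
#' @param cons a [build_consensus()] result.
#' @param params a [search_params()] object with `mode = "windowed"`.
#' @return object of class `primer_set_list`: a list of sets, each with
#'   elements `forward`, `reverse`, `probe` (single-row oligo data.frames;
#'   `probe` may be NULL), `product_start`, `product_end` (1-based
#'   inclusive), `product_len` and `product_seq`.
#' @export
find_primer_sets <- function(cons, params = search_params()) {
  stopifnot(inherits(cons, "cons_consensus"))
  if (params$mode != "windowed") {
    stop("find_primer_sets requires params$mode == 'windowed'", call. = FALSE)
  }
  L <- cons$length
  W <- params$window_size
  if (W > L) {
    stop("parameter error: window_size (", W,
         ") exceeds consensus length (", L, ")", call. = FALSE)
  }
  pre <- cons_precompute(cons, params)
  lens <- params$oligo_min_len:params$oligo_max_len
  slack <- params$anchor_slack
  sets <- list()
  seen <- character(0)
  for (w in seq(0L, L - W, by = params$slide)) {
    # forward candidates anchored at the window start
    fs <- rep(w + 0:slack, each = length(lens))
    fl <- rep(lens, times = slack + 1L)
    keep <- fs + fl <= w + W
    fs <- fs[keep]; fl <- fl[keep]
    fok <- candidate_valid(pre, fs, fl, "forward", params)
    ftab <- oligo_table(cons, fs[fok], fl[fok],
                        rep("forward", sum(fok)), "forward_primer", params)
    if (nrow(ftab) == 0L) next
    # reverse candidates anchored at the window end
    re <- rep(w + W - 0:slack, each = length(lens))
    rl <- rep(lens, times = slack + 1L)
    rs <- re - rl
    keep <- rs >= w
    rs <- rs[keep]; rl <- rl[keep]
    rok <- candidate_valid(pre, rs, rl, "reverse", params)
    rtab <- oligo_table(cons, rs[rok], rl[rok],
                        rep("reverse", sum(rok)), "reverse_primer", params)
    if (nrow(rtab) == 0L) next

    pairs <- if (params$all_candidates) {
      expand.grid(f = seq_len(nrow(ftab)), r = seq_len(nrow(rtab)))
    } else {
      data.frame(f = best_candidate(ftab, params),
                 r = best_candidate(rtab, params))
    }
    for (k in seq_len(nrow(pairs))) {
      fwd <- ftab[pairs$f[k], , drop = FALSE]
      rev <- rtab[pairs$r[k], , drop = FALSE]
      probe <- NULL
      if (params$probe) {
        p0 <- fwd$end            # 0-based start bound == 1-based fwd end
        p1 <- rev$start - 1L     # 0-based end bound (rev binding start)
        probe <- best_probe(cons, pre, p0, p1, params)
        if (is.null(probe)) next
      }
      key <- paste(fwd$start, fwd$end, rev$start, rev$end, sep = ":")
      if (key %in% seen) next
      seen <- c(seen, key)
      product_start <- fwd$start
      product_end <- rev$end
      sets[[length(sets) + 1L]] <- list(
        forward = fwd, reverse = rev, probe = probe,
        product_start = product_start, product_end = product_end,
        product_len = product_end - product_start + 1L,
        product_seq = substring(consensus_string(cons),
                                product_start, product_end)
      )
    }
  }
  ord <- order(vapply(sets, `[[`, numeric(1), "product_start"))
  structure(sets[ord], class = "primer_set_list")
}

# best valid probe with 0-based footprint within [lo0, hi0)
best_probe <- function(cons, pre, lo0, hi0, params) {
  room <- hi0 - lo0
  if (room < params$oligo_min_len) return(NULL)
  lens <- params$oligo_min_len:min(params$oligo_max_len, room)
  cand_s <- integer(0); cand_l <- integer(0)
  for (len in lens) {
    st <- lo0:(hi0 - len)
    cand_s <- c(cand_s, st)
    cand_l <- c(cand_l, rep(len, length(st)))
  }
  strands <- if (params$probe_both_strands) c("forward", "reverse")
             else "forward"
  out_s <- integer(0); out_l <- integer(0); out_strand <- character(0)
  for (strand in strands) {
    ok <- candidate_valid(pre, cand_s, cand_l, strand, params,
                          is_probe = TRUE)
    out_s <- c(out_s, cand_s[ok])
    out_l <- c(out_l, cand_l[ok])
    out_strand <- c(out_strand, rep(strand, sum(ok)))
  }
  if (length(out_s) == 0L) return(NULL)
  tab <- oligo_table(cons, out_s, out_l, out_strand, "probe", params)
  tab[best_candidate(tab, params), , drop = FALSE]
}

#' @export
print.primer_set_list <- function(x, ...) {
  cat(sprintf("<%d primer set(s)>\n", length(x)))
  for (s in x) {
    cat(sprintf("  product %d-%d (%d nt): F %s  R %s%s\n",
                s$product_start, s$product_end, s$product_len,
                s$forward$seq, s$reverse$seq,
                if (!is.null(s$probe)) paste0("  P ", s$probe$seq) else ""))
  }
  invisible(x)
}
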