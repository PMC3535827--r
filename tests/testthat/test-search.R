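test_that("degeneracy measures and reverse complement follow IUPAC", {
  expect_equal(degenerate_count("ACGT"), 0)
  expect_equal(degenerate_count("ACGR"), 1)
  expect_equal(degenerate_count("RYN"), 3)
  expect_equal(degeneracy("ACGT"), 1)
  expect_equal(degeneracy("ACGR"), 2)
  expect_equal(degeneracy("NRY"), 16)
  expect_equal(reverse_complement("ACGT"), "ACGT")
  expect_equal(reverse_complement("AAR"), "YTT")
  expect_error(reverse_complement("AC-T"), "cannot reverse-complement")
  set.seed(41)
  for (i in 1:25) {
    s <- rand_degenerate_oligo()
    expect_equal(reverse_complement(reverse_complement(s)), s)
    expect_equal(reverse_complement(s), orc_revcomp(s))
    expect_equal(degenerate_count(s), orc_deg_count(s))
  }
})

test_that("validate_oligo reports every violated rule", {
  params <- search_params()
  ok20 <- "ACGGATCAGCATCGACTGCA"          # 20 nt, Td 62, no degeneracy
  cons <- cons_of(paste0(ok20, "RRRRYYYYACGTACGTACGTAAR"))
  expect_equal(wallace_td(ok20), 62)
  v <- validate_oligo(cons, 1, 20, "forward", params)
  expect_true(v$valid)
  expect_length(v$reasons, 0)

  # >3 degenerate positions inside the window
  v2 <- validate_oligo(cons, 12, 31, "forward", params)
  expect_false(v2$valid)
  expect_true("max_degenerate" %in% v2$reasons)

  # 3' end hits the trailing AAR: degenerate clamp violation
  v3 <- validate_oligo(cons, 24, 43, "forward", params)
  expect_false(v3$valid)
  expect_true("three_prime_clamp" %in% v3$reasons)
  # the same window read on the reverse strand has its 3' end at the
  # other edge, inside the YYYY run
  v4 <- validate_oligo(cons, 24, 43, "reverse", params)
  expect_true("three_prime_clamp" %in% v4$reasons)

  # length bounds
  v5 <- validate_oligo(cons, 1, 10, "forward", params)
  expect_true("length_range" %in% v5$reasons)

  # Td band: an all-AT 20-mer has Td 40 < 50
  at_cons <- cons_of(strrep("AT", 15))
  v6 <- validate_oligo(at_cons, 1, 20, "forward", params)
  expect_true("td_band" %in% v6$reasons)

  # gap and conservation rules
  gcons <- build_consensus(make_aln(c(paste0(strrep("A", 10), "-",
                                             strrep("A", 14)),
                                      strrep("A", 25))))
  v7 <- validate_oligo(gcons, 1, 20, "forward", params)
  expect_true("gap_column" %in% v7$reasons)
  v8 <- validate_oligo(gcons, 1, 20, "forward",
                       search_params(allow_gap_columns = TRUE,
                                     min_conservation = 0.9))
  expect_false("gap_column" %in% v8$reasons)

  dcons <- build_consensus(make_aln(c("ACGGATCAGCATCGACTGCA",
                                      "ACGGATCAGCATCGACTGCA",
                                      "TCGGATCAGCATCGACTGCA")))
  v9 <- validate_oligo(dcons, 1, 20, "forward",
                       search_params(min_conservation = 0.9))
  expect_true("min_conservation" %in% v9$reasons)
})

test_that("enumerate_oligos lists exactly the valid substrings", {
  # 24-nt non-degenerate consensus, lengths 18..20, no Td filter:
  # (7 + 6 + 5) starts x 2 strands = 36 oligos
  cons <- cons_of(strrep("ACGT", 6))
  p <- search_params(mode = "all_oligos", oligo_min_len = 18,
                     oligo_max_len = 20, td_min = 0, td_max = 1000)
  ol <- enumerate_oligos(cons, p)
  expect_equal(nrow(ol), 36)
  expect_equal(sum(ol$strand == "forward"), 18)
  expect_true(all(ol$degenerate_count == 0))

  # all-N consensus: everything exceeds max_degenerate
  consN <- cons_of(strrep("N", 60))
  expect_equal(nrow(enumerate_oligos(consN, search_params(mode = "all_oligos"))), 0)

  # planted 20-nt island inside Ns: only the island's sub-oligos survive
  island <- "ACGTACGTACGTACGTACGT"
  consI <- cons_of(paste0(strrep("N", 30), island, strrep("N", 30)))
  olI <- enumerate_oligos(consI, search_params(mode = "all_oligos",
                                               oligo_min_len = 18,
                                               oligo_max_len = 25,
                                               max_degenerate = 0))
  # lengths 18 (3 starts), 19 (2), 20 (1) on each strand
  expect_equal(nrow(olI), 12)
  expect_true(all(olI$start >= 31 & olI$end <= 50))

  # consensus shorter than the minimum oligo length
  expect_warning(res <- enumerate_oligos(cons_of("ACGT"),
                                         search_params(mode = "all_oligos")),
                 "shorter")
  expect_equal(nrow(res), 0)
})

test_that("emitted sequences match their consensus coordinates", {
  set.seed(42)
  aln <- rand_aln(4, 150, p_mut = 0.05)
  cons <- build_consensus(aln)
  cs <- consensus_string(cons)
  ol <- enumerate_oligos(cons, search_params(mode = "all_oligos",
                                             td_min = 0, td_max = 1000))
  expect_gt(nrow(ol), 0)
  for (i in seq_len(nrow(ol))) {
    sub <- substring(cs, ol$start[i], ol$end[i])
    expected <- if (ol$strand[i] == "reverse") reverse_complement(sub) else sub
    expect_equal(ol$seq[i], expected)
  }
})

test_that("windowed design anchors primers to the product window", {
  fblk <- "ACGTACGTACGTACGTACGT"
  rblk <- "TGCATGCATGCATGCATGCA"
  cons <- cons_of(paste0(fblk, strrep("N", 60), rblk))
  p <- search_params(window_size = 100, slide = 20,
                     oligo_min_len = 20, oligo_max_len = 20)
  sets <- find_primer_sets(cons, p)
  expect_length(sets, 1)
  s <- sets[[1]]
  expect_equal(s$forward$seq, fblk)
  expect_equal(s$reverse$seq, reverse_complement(rblk))
  expect_equal(s$product_start, 1)
  expect_equal(s$product_end, 100)
  expect_equal(s$product_len, 100)
  expect_equal(nchar(s$product_seq), 100)

  # probe required but the interior is all N: no sets
  sets2 <- find_primer_sets(cons, search_params(window_size = 100,
                                                slide = 20, probe = TRUE,
                                                oligo_min_len = 20,
                                                oligo_max_len = 20))
  expect_length(sets2, 0)
})

test_that("window arithmetic emits one set per fitting start", {
  set.seed(43)
  s200 <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
                collapse = "")
  cons <- cons_of(s200)
  p <- search_params(window_size = 150, slide = 20, td_min = 0,
                     td_max = 1000)
  sets <- find_primer_sets(cons, p)
  starts <- vapply(sets, `[[`, numeric(1), "product_start")
  expect_equal(starts, c(1, 21, 41))
  for (s in sets) {
    expect_equal(s$product_len, 150)
    expect_equal(s$reverse$end, s$product_end)
    expect_equal(s$forward$start, s$product_start)
  }
  expect_error(find_primer_sets(cons, search_params(window_size = 300)),
               "parameter error")
})

test_that("anchor slack deduplicates identical sets across windows", {
  set.seed(44)
  blk <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                           collapse = "")
  f <- blk(24); r <- blk(24)
  cons <- cons_of(paste0(strrep("N", 30), f, strrep("N", 42), r,
                         strrep("N", 20)))  # blocks at 31..54 and 97..120
  p <- search_params(window_size = 120, slide = 20, anchor_slack = 40,
                     td_min = 0, td_max = 1000)
  sets <- find_primer_sets(cons, p)
  expect_gte(length(sets), 1)
  keys <- vapply(sets, function(s) {
    paste(s$forward$start, s$forward$end, s$reverse$start, s$reverse$end)
  }, character(1))
  expect_equal(anyDuplicated(keys), 0)
  for (s in sets) expect_lte(s$product_len, 120)
})

test_that("probe placement stays strictly between the primers", {
  w <- c(100L, 400L)
  g <- generate_alignment(synth_spec(10, 700, triple_blocks(w),
                                     background_divergence = 0.4,
                                     indel_prob = 0, seed = 7))
  cons <- build_consensus(g$alignment)
  sets <- find_primer_sets(cons, search_params(probe = TRUE))
  expect_gte(length(sets), 1)
  for (s in sets) {
    expect_false(is.null(s$probe))
    expect_gte(s$probe$start, s$forward$end + 1)
    expect_lte(s$probe$end, s$reverse$start - 1)
    expect_equal(s$probe$strand, "forward")
  }
})

test_that("relaxing constraints never shrinks the valid oligo set", {
  set.seed(45)
  for (i in 1:5) {
    aln <- rand_aln(5, 120, p_mut = 0.25)
    cons <- build_consensus(aln)
    key <- function(df) paste(df$start, df$length, df$strand)
    base <- enumerate_oligos(cons, search_params(mode = "all_oligos",
                                                 max_degenerate = 1,
                                                 td_min = 50, td_max = 60))
    relaxed_deg <- enumerate_oligos(cons, search_params(mode = "all_oligos",
                                                        max_degenerate = 4,
                                                        td_min = 50,
                                                        td_max = 60))
    relaxed_td <- enumerate_oligos(cons, search_params(mode = "all_oligos",
                                                       max_degenerate = 1,
                                                       td_min = 40,
                                                       td_max = 75))
    expect_true(all(key(base) %in% key(relaxed_deg)))
    expect_true(all(key(base) %in% key(relaxed_td)))
  }
})

test_that("candidate scoring is a deterministic total order", {
  p <- search_params()  # band [50, 65], centre 57.5
  o1 <- list(degenerate_count = 0, td_min = 55, td_max = 60, length = 20,
             start = 5, strand = "forward")
  o2 <- list(degenerate_count = 1, td_min = 57, td_max = 58, length = 20,
             start = 5, strand = "forward")
  expect_true(all(score_candidate(o1, p) <= score_candidate(o2, p)) ||
              score_candidate(o1, p)[1] < score_candidate(o2, p)[1])
  # equal degeneracy: Td midpoint closest to the band centre wins
  o3 <- list(degenerate_count = 0, td_min = 52, td_max = 52, length = 20,
             start = 5, strand = "forward")
  k1 <- score_candidate(o1, p); k3 <- score_candidate(o3, p)
  expect_lt(k1[2], k3[2])
  # distinct placements always differ somewhere in the key
  o4 <- modifyList(o1, list(start = 6))
  expect_false(identical(score_candidate(o1, p), score_candidate(o4, p)))
})

test_that("every emitted oligo re-passes validate_oligo", {
  set.seed(46)
  aln <- rand_aln(6, 200, p_mut = 0.15, p_gap = 0.01)
  cons <- build_consensus(aln)
  p <- search_params(mode = "all_oligos", td_min = 40, td_max = 80)
  ol <- enumerate_oligos(cons, p)
  for (i in seq_len(nrow(ol))) {
    v <- validate_oligo(cons, ol$start[i], ol$end[i], ol$strand[i], p)
    expect_true(v$valid, label = paste("row", i, ol$seq[i]))
  }
  g <- generate_alignment(synth_spec(10, 500, triple_blocks(100L),
                                     background_divergence = 0.35,
                                     seed = 9))
  cons2 <- build_consensus(g$alignment)
  p2 <- search_params(probe = TRUE)
  for (s in find_primer_sets(cons2, p2)) {
    expect_true(validate_oligo(cons2, s$forward$start, s$forward$end,
                               "forward", p2)$valid)
    expect_true(validate_oligo(cons2, s$reverse$start, s$reverse$end,
                               "reverse", p2)$valid)
    expect_true(validate_oligo(cons2, s$probe$start, s$probe$end,
                               s$probe$strand, p2, is_probe = TRUE)$valid)
  }
})
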