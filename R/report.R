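# Tabulated text (TSV) report: one row per oligo, a '#' comment block with
# the run parameters, deterministic ordering and formatting.

REPORT_COLUMNS <- c("product_id", "role", "sequence", "start", "end",
                    "strand", "length", "degenerate_count", "degeneracy",
                    "gc_min", "gc_max", "td_min", "td_max", "tm_nn",
                    "tm_basis", "product_len", "product_seq")

# oligo data.frame row -> report row (list); sequences get U restored for
# RNA runs
report_row <- function(oligo, product_id, product_len, product_seq, rna) {
  seqout <- if (rna) chartr("T", "U", oligo$seq) else oligo$seq
  list(product_id = product_id,
       role = oligo$role,
       sequence = seqout,
       start = oligo$start,
       end = oligo$end,
       strand = oligo$strand,
       length = oligo$length,
       degenerate_count = oligo$degenerate_count,
       degeneracy = oligo$degeneracy,
       gc_min = oligo$gc_min, gc_max = oligo$gc_max,
       td_min = oligo$td_min, td_max = oligo$td_max,
       tm_nn = oligo$tm_nn,
       tm_basis = oligo$tm_basis,
       product_len = product_len,
       product_seq = product_seq)
}

#' Build the report table
#'
#' Flattens search results into one data.frame row per oligo. Primer sets
#' contribute rows in forward/probe/reverse order sharing a `product_id`;
#' the product sequence appears on the set's first row only. In
#' `all_oligos` mode rows are the enumerated oligos sorted by start,
#' length, strand, with `product_id` NA. RNA inputs are reported with U
#' restored in all sequence fields.
#'
#' @param results a `primer_set_list` or an oligo data.frame from
#'   [enumerate_oligos()].
#' @param cons the consensus the results were computed on.
#' @return data.frame with the report columns.
#' @export
report_table <- function(results, cons) {
  rna <- isTRUE(cons$rna)
  rows <- list()
  if (inherits(results, "primer_set_list")) {
    for (i in seq_along(results)) {
      s <- results[[i]]
      pid <- sprintf("set_%04d", i)
      pseq <- if (rna) chartr("T", "U", s$product_seq) else s$product_seq
      rows[[length(rows) + 1L]] <-
        report_row(s$forward, pid, s$product_len, pseq, rna)
      if (!is.null(s$probe)) {
        rows[[length(rows) + 1L]] <-
          report_row(s$probe, pid, s$product_len, "", rna)
      }
      rows[[length(rows) + 1L]] <-
        report_row(s$reverse, pid, s$product_len, "", rna)
    }
  } else {
    for (i in seq_len(nrow(results))) {
      rows[[length(rows) + 1L]] <-
        report_row(results[i, ], NA_character_, NA_integer_, "", rna)
    }
  }
  if (length(rows) == 0L) {
    df <- data.frame(matrix(nrow = 0, ncol = length(REPORT_COLUMNS)))
    names(df) <- REPORT_COLUMNS
    return(df)
  }
  df <- do.call(rbind, lapply(rows, function(r) {
    as.data.frame(r, stringsAsFactors = FALSE)
  }))
  rownames(df) <- NULL
  df[, REPORT_COLUMNS]
}

fmt_num <- function(x, digits = 1L) {
  ifelse(is.na(x), "", sprintf(paste0("%.", digits, "f"), x))
}

#' Write the tabulated report
#'
#' Tab-separated UTF-8 text: a '#' comment block echoing the run
#' parameters and the consensus length, one header line, then one row per
#' oligo. Temperatures and GC percentages are printed with one decimal,
#' coordinates as integers. Output is byte-identical across reruns on the
#' same input. An empty result still writes the header and comments (with
#' a warning).
#'
#' @param results a `primer_set_list` or oligo data.frame.
#' @param cons the consensus used.
#' @param params the [search_params()] used.
#' @param path output file path, or `"-"` for stdout.
#' @return the report data.frame, invisibly.
#' @export
write_report <- function(results, cons, params, path) {
  df <- report_table(results, cons)
  if (nrow(df) == 0L) {
    warning("no valid oligos or primer sets found; writing empty report")
  }
  out <- df
  for (col in c("gc_min", "gc_max", "td_min", "td_max", "tm_nn")) {
    out[[col]] <- fmt_num(df[[col]])
  }
  out$tm_basis[is.na(out$tm_basis)] <- ""
  out$product_id[is.na(out$product_id)] <- ""
  if (nrow(out) > 0L) {
    out$product_len <- ifelse(is.na(df$product_len), "",
                              as.character(df$product_len))
  }
  comments <- c(
    "# conserved degenerate oligo report",
    sprintf("# consensus_length=%d source=%s alphabet=%s",
            cons$length, cons$source, if (isTRUE(cons$rna)) "RNA" else "DNA"),
    sprintf("# mode=%s probe=%s window_size=%d slide=%d",
            params$mode, params$probe, params$window_size, params$slide),
    sprintf("# oligo_len=[%d,%d] max_degenerate=%d clamp_len=%d",
            params$oligo_min_len, params$oligo_max_len,
            params$max_degenerate, params$clamp_len),
    sprintf("# td_band=[%s,%s] min_conservation=%s allow_gap_columns=%s",
            format(params$td_min), format(params$td_max),
            format(params$min_conservation), params$allow_gap_columns),
    "# coordinates are 1-based inclusive on the consensus"
  )
  con <- if (identical(path, "-")) stdout() else file(path, open = "wt")
  if (!identical(path, "-")) on.exit(close(con))
  writeLines(comments, con)
  writeLines(paste(REPORT_COLUMNS, collapse = "\t"), con)
  if (nrow(out) > 0L) {
    lines <- do.call(paste, c(lapply(out, as.character), sep = "\t"))
    writeLines(lines, con)
  }
  invisible(df)
}

#' Read a report back into a data.frame
#'
#' Parses a [write_report()] file, skipping '#' comments and restoring
#' column types (coordinates integer, temperatures numeric).
#'
#' @param path report file path.
#' @return data.frame with the report columns.
#' @export
read_report <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = "character")
  if (nrow(df) > 0L) {
    for (col in c("start", "end", "length", "degenerate_count",
                  "product_len")) {
      df[[col]] <- suppressWarnings(as.integer(df[[col]]))
    }
    for (col in c("degeneracy", "gc_min", "gc_max", "td_min", "td_max",
                  "tm_nn")) {
      df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
    }
  }
  df
}
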