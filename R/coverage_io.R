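# Coverage summary tables (samtools-coverage dialect) and binned tracks.

coverage_columns <- c("rname", "startpos", "endpos", "numreads", "covbases",
                      "coverage", "meandepth", "meanbaseq", "meanmapq")

#' Validate and class a coverage table
#'
#' One row per reference sequence, in the 9-column samtools-coverage layout
#' (1-based inclusive coordinates). Enforces the record invariants: covered
#' bases cannot exceed the span, the coverage percentage must equal
#' `100 * covbases / span` within 0.01, and read counts are non-negative.
#'
#' @param df Data frame with columns `rname`, `startpos`, `endpos`,
#'   `numreads`, `covbases`, `coverage`, `meandepth`, `meanbaseq`,
#'   `meanmapq`.
#' @return The validated data frame with class `coverage_table`.
#' @export
coverage_table <- function(df) {
  missing_cols <- setdiff(coverage_columns, names(df))
  if (length(missing_cols)) {
    stopf("coverage table lacks column(s): %s",
          paste(missing_cols, collapse = ", "))
  }
  df <- df[, coverage_columns]
  span <- df$endpos - df$startpos + 1
  for (i in seq_len(nrow(df))) {
    if (df$endpos[i] < df$startpos[i]) {
      stopf("record '%s': endpos < startpos", df$rname[i])
    }
    if (df$covbases[i] > span[i]) {
      stopf("record '%s': covbases (%d) exceeds span (%d)", df$rname[i],
            df$covbases[i], span[i])
    }
    if (df$numreads[i] < 0 || df$covbases[i] < 0) {
      stopf("record '%s': negative count", df$rname[i])
    }
    if (abs(df$coverage[i] - 100 * df$covbases[i] / span[i]) > 0.01) {
      stopf("record '%s': coverage %% inconsistent with covbases/span",
            df$rname[i])
    }
  }
  class(df) <- c("coverage_table", "data.frame")
  df
}

#' Read a coverage summary table
#'
#' Expects the samtools-coverage layout: a header line starting `#rname`
#' followed by 9 tab-separated columns. Malformed rows are reported with
#' their line number; invariant violations name the offending record.
#'
#' @param path File path.
#' @return A [coverage_table()].
#' @export
read_coverage_table <- function(path) {
  if (!file.exists(path)) stopf("coverage table not found: %s", path)
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1], "#rname")) {
    stopf("%s: header must begin with '#rname'", path)
  }
  body <- lines[-1]
  body <- body[nzchar(body)]
  rows <- vector("list", length(body))
  for (i in seq_along(body)) {
    fields <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) != 9) {
      stopf("%s: malformed row at line %d (%d fields, expected 9)",
            path, i + 1L, length(fields))
    }
    num <- suppressWarnings(as.numeric(fields[-1]))
    if (anyNA(num)) {
      stopf("%s: non-numeric field at line %d", path, i + 1L)
    }
    rows[[i]] <- data.frame(
      rname = fields[1], startpos = num[1], endpos = num[2],
      numreads = num[3], covbases = num[4], coverage = num[5],
      meandepth = num[6], meanbaseq = num[7], meanmapq = num[8],
      stringsAsFactors = FALSE
    )
  }
  coverage_table(do.call(rbind, rows))
}

#' Write a coverage summary table
#'
#' @param records A [coverage_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coverage_table <- function(records, path) {
  records <- coverage_table(as.data.frame(records))
  header <- paste0("#", paste(coverage_columns, collapse = "\t"))
  body <- vapply(seq_len(nrow(records)), function(i) {
    nums <- vapply(unlist(records[i, -1]), function(x) sprintf("%.10g", x), "")
    paste(c(records$rname[i], nums), collapse = "\t")
  }, "")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Construct a binned genomic track
#'
#' @param rname Sequence identifier.
#' @param bin_size Bin width in bp; the final bin may be partial.
#' @param values Non-negative per-bin values, one per bin.
#' @param value_kind `"reads"` (mapped read counts) or `"depth"` (mean
#'   depth).
#' @param seq_length Sequence length in bp; must satisfy
#'   `length(values) == ceiling(seq_length / bin_size)`.
#' @return A list of class `binned_track`.
#' @export
binned_track <- function(rname, bin_size, values,
                         value_kind = c("reads", "depth"),
                         seq_length = bin_size * length(values)) {
  value_kind <- match.arg(value_kind)
  if (any(values < 0)) stopf("track values must be non-negative")
  n_expected <- ceiling(seq_length / bin_size)
  if (length(values) != n_expected) {
    stopf("track '%s': %d values but %d bins expected for length %g",
          rname, length(values), n_expected, seq_length)
  }
  structure(
    list(rname = rname, bin_size = bin_size, values = as.numeric(values),
         value_kind = value_kind, seq_length = seq_length),
    class = "binned_track"
  )
}

#' Bin read start positions into a track
#'
#' A read starting at 1-based position `p` is assigned to bin
#' `floor((p - 1) / bin_size)`; the final partial bin is retained, and the
#' track total always equals the number of input positions.
#'
#' @param positions 1-based read start positions (bp).
#' @param bin_size Bin width in bp.
#' @param seq_length Sequence length in bp.
#' @param rname Sequence identifier recorded on the track.
#' @return A [binned_track()] of read counts.
#' @export
bin_read_starts <- function(positions, bin_size, seq_length, rname = "seq") {
  if (length(positions) && (any(positions < 1) || any(positions > seq_length))) {
    stopf("read position(s) outside [1, %g]", seq_length)
  }
  n_bins <- ceiling(seq_length / bin_size)
  counts <- tabulate(floor((positions - 1) / bin_size) + 1L, nbins = n_bins)
  binned_track(rname, bin_size, counts, "reads", seq_length)
}

#' Breadth of coverage of a sequence
#'
#' The fraction of bases covered by at least one read:
#' `covbases / (endpos - startpos + 1)`. Vectorized over the rows of a
#' coverage table.
#'
#' @param record A [coverage_table()] (or a subset of its rows).
#' @return Numeric vector of fractions in `[0, 1]`.
#' @export
chromosome_breadth <- function(record) {
  record$covbases / (record$endpos - record$startpos + 1)
}

#' Genome-wide baseline breadth for one line
#'
#' The unweighted mean of [chromosome_breadth()] over all sequences not in
#' `exclude`; the reference point from which arm-sized coverage losses are
#' measured.
#'
#' @param records A [coverage_table()] for one line.
#' @param exclude Character vector of sequence names to leave out.
#' @return A single fraction.
#' @export
line_baseline <- function(records, exclude = character()) {
  keep <- !(records$rname %in% exclude)
  if (!any(keep)) stopf("all sequences excluded from baseline")
  mean(chromosome_breadth(records[keep, , drop = FALSE]))
}

#' Convert a read-count track to a mean-depth track
#'
#' @param track A [binned_track()] with `value_kind = "reads"`.
#' @param read_length Read length in bp.
#' @return A [binned_track()] with `value_kind = "depth"`.
#' @export
reads_to_depth <- function(track, read_length) {
  stopifnot(inherits(track, "binned_track"))
  if (track$value_kind != "reads") stopf("track is not a read-count track")
  n <- length(track$values)
  starts <- (seq_len(n) - 1) * track$bin_size + 1
  ends <- pmin(seq_len(n) * track$bin_size, track$seq_length)
  binned_track(track$rname, track$bin_size,
               track$values * read_length / (ends - starts + 1),
               "depth", track$seq_length)
}

#' Write a binned track as bedgraph
#'
#' Bedgraph uses 0-based half-open intervals; the conversion from the
#' track's 1-based bins happens here at the format boundary.
#'
#' @param track A [binned_track()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "binned_track"))
  n <- length(track$values)
  gr <- GenomicRanges::GRanges(
    seqnames = track$rname,
    ranges = IRanges::IRanges(
      start = (seq_len(n) - 1) * track$bin_size + 1,
      end = pmin(seq_len(n) * track$bin_size, track$seq_length)
    ),
    score = track$values
  )
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read a bedgraph file into a binned track
#'
#' Assumes the file tiles one sequence with constant-width bins (the final
#' bin may be partial), as written by [write_bedgraph()].
#'
#' @param path File path.
#' @param value_kind Value kind to record on the track.
#' @return A [binned_track()].
#' @export
read_bedgraph <- function(path, value_kind = "reads") {
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (!length(gr)) stopf("%s: empty bedgraph", path)
  rname <- as.character(GenomicRanges::seqnames(gr)[1])
  gr <- sort(gr)
  bin_size <- GenomicRanges::width(gr)[1]
  binned_track(rname, bin_size, gr$score, value_kind,
               seq_length = max(GenomicRanges::end(gr)))
}
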