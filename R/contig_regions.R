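# Haplotype contig selection, composite construction, and region mapping.

paf_core_cols <- c("contig_id", "contig_len", "contig_start", "contig_end",
                   "strand", "target", "target_len", "target_start",
                   "target_end", "n_match", "block_len", "mq")

#' Validate and class contig alignment records
#'
#' @param df Data frame with at least `contig_id`, `contig_len`, `target`,
#'   `target_start`, `target_end`, `mq`, `strand` and `blocks`
#'   (comma-separated aligned-block lengths in bp).
#' @return The validated data frame with class `contig_alignments`.
#' @export
contig_alignments <- function(df) {
  needed <- c("contig_id", "contig_len", "target", "target_start",
              "target_end", "mq", "strand", "blocks")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stopf("alignment table lacks column(s): %s",
          paste(missing_cols, collapse = ", "))
  }
  for (i in seq_len(nrow(df))) {
    if (df$target_start[i] >= df$target_end[i]) {
      stopf("alignment '%s': target_start must be < target_end",
            df$contig_id[i])
    }
    blocks <- parse_blocks(df$blocks[i])
    if (sum(blocks) > df$target_end[i] - df$target_start[i]) {
      stopf("alignment '%s': aligned blocks exceed target span",
            df$contig_id[i])
    }
  }
  class(df) <- c("contig_alignments", "data.frame")
  df
}

parse_blocks <- function(s) {
  as.numeric(strsplit(as.character(s), ",", fixed = TRUE)[[1]])
}

#' Write contig alignments as PAF
#'
#' Standard 12-column PAF (query name/length/start/end, strand, target
#' name/length/start/end, matches, alignment block length, MQ) plus a
#' `bl:Z:` tag carrying the aligned-block lengths.
#'
#' @param alignments A [contig_alignments()] table.
#' @param path Output path.
#' @param target_len Target sequence length used in column 7.
#' @return `path`, invisibly.
#' @export
write_paf <- function(alignments, path, target_len = NA) {
  lines <- vapply(seq_len(nrow(alignments)), function(i) {
    a <- alignments[i, ]
    blocks <- parse_blocks(a$blocks)
    paste(c(a$contig_id, sprintf("%.10g", a$contig_len), "0",
            sprintf("%.10g", a$contig_len), a$strand, a$target,
            sprintf("%.10g", if (is.na(target_len)) a$target_end else target_len),
            sprintf("%.10g", a$target_start), sprintf("%.10g", a$target_end),
            sprintf("%.10g", sum(blocks)),
            sprintf("%.10g", a$target_end - a$target_start),
            sprintf("%.10g", a$mq),
            paste0("bl:Z:", a$blocks)),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a PAF file into contig alignment records
#'
#' @param path File path.
#' @return A [contig_alignments()] table. The optional `bl:Z:` tag
#'   restores aligned-block lengths; otherwise the alignment block length
#'   (column 11) is used as a single block.
#' @export
read_paf <- function(path) {
  if (!file.exists(path)) stopf("PAF not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 12) stopf("%s: malformed PAF row at line %d", path, i)
    tags <- f[-(1:12)]
    bl <- grep("^bl:Z:", tags, value = TRUE)
    blocks <- if (length(bl)) sub("^bl:Z:", "", bl[1]) else f[11]
    data.frame(contig_id = f[1], contig_len = as.numeric(f[2]),
               target = f[6], target_start = as.numeric(f[8]),
               target_end = as.numeric(f[9]), mq = as.numeric(f[12]),
               strand = f[5], blocks = blocks, stringsAsFactors = FALSE)
  })
  contig_alignments(do.call(rbind, rows))
}

#' Select haplotype contigs by target window and mapping quality
#'
#' Keeps alignments whose target start and end both fall inside the window
#' and whose mapping quality is strictly greater than `mq_min` (an
#' alignment straddling a window edge is dropped). Input order is
#' preserved; an empty result is allowed.
#'
#' @param alignments A [contig_alignments()] table.
#' @param target Target sequence name of the window.
#' @param window_start,window_end Window interval in bp.
#' @param mq_min Mapping-quality threshold (exclusive; default 20).
#' @return The selected subset, order preserved.
#' @export
select_contigs <- function(alignments, target, window_start, window_end,
                           mq_min = 20) {
  if (window_start >= window_end) stopf("invalid window")
  keep <- alignments$target == target &
    alignments$target_start >= window_start &
    alignments$target_end <= window_end &
    alignments$mq > mq_min
  out <- alignments[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Concatenate selected contigs into a composite contig
#'
#' Contigs are ordered by target start (ties broken by contig id,
#' lexicographically) and laid end-to-end; the composite length is the sum
#' of member contig lengths and each member's half-open interval on the
#' composite is returned.
#'
#' @param selected A [contig_alignments()] table (or any data frame with
#'   `contig_id`, `contig_len`, `target_start`).
#' @return A list of class `composite_contig` with `layout` (data frame:
#'   `contig_id`, `length`, `target_start`, `comp_start`, `comp_end`;
#'   0-based half-open composite coordinates) and `total_length`.
#' @export
build_composite <- function(selected) {
  if (!nrow(selected)) stopf("no contigs to combine")
  if (anyDuplicated(selected$contig_id)) {
    stopf("duplicate contig id(s): %s",
          paste(unique(selected$contig_id[duplicated(selected$contig_id)]),
                collapse = ", "))
  }
  ord <- order(selected$target_start, selected$contig_id)
  layout <- data.frame(
    contig_id = selected$contig_id[ord],
    length = selected$contig_len[ord],
    target_start = selected$target_start[ord],
    stringsAsFactors = FALSE
  )
  layout$comp_end <- cumsum(layout$length)
  layout$comp_start <- layout$comp_end - layout$length
  layout <- layout[, c("contig_id", "length", "target_start",
                       "comp_start", "comp_end")]
  rownames(layout) <- NULL
  structure(list(layout = layout, total_length = sum(layout$length)),
            class = "composite_contig")
}

#' Map composite-contig regions to the reference
#'
#' Computes, for each region with coordinates on both the contig side and
#' the reference side, the two spans (`end - start` on each side) and the
#' gap: the reference bases not covered by any aligned block,
#' `ref_span - sum(aligned block lengths)`. Rows are returned in contig
#' coordinate order.
#'
#' @param regions Data frame with columns `region_id`, `contig_start`,
#'   `contig_end`, `ref_start`, `ref_end` and `blocks` (comma-separated
#'   aligned reference-base counts per block).
#' @return Data frame of class `region_mapping` with `contig_span`,
#'   `ref_span`, `aligned_bases` and `gap` columns.
#' @export
map_regions <- function(regions) {
  needed <- c("region_id", "contig_start", "contig_end", "ref_start",
              "ref_end", "blocks")
  missing_cols <- setdiff(needed, names(regions))
  if (length(missing_cols)) {
    stopf("region table lacks column(s): %s",
          paste(missing_cols, collapse = ", "))
  }
  out <- regions
  out$contig_span <- out$contig_end - out$contig_start
  out$ref_span <- out$ref_end - out$ref_start
  out$aligned_bases <- vapply(out$blocks,
                              function(b) sum(parse_blocks(b)), numeric(1))
  out$gap <- out$ref_span - out$aligned_bases
  for (i in seq_len(nrow(out))) {
    if (out$gap[i] < 0) {
      stopf("region '%s': aligned blocks exceed reference span",
            out$region_id[i])
    }
  }
  out <- out[order(out$contig_start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("region_mapping", "data.frame")
  out
}
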