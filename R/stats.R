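# Per-alignment identity/coverage statistics (the BED dialect the ribbon
# plotter consumes) and record-level filters.
#
# Three percent-identity variants are reported, differing only in the
# denominator:
#   perID_by_matches : 100 * m / (m + x)                       substitutions only
#   perID_by_events  : 100 * m / (m + x + ins_ev + del_ev)     + one per gap event
#   perID_by_all     : 100 * m / (m + x + ins_bp + del_bp)     + every gap base
# with m = matched and x = mismatched bases. The denominators are nested, so
# by_matches >= by_events >= by_all on every record, with equality at 100 only
# for gap- and mismatch-free alignments.

#' Identity statistics for one alignment
#'
#' Computes event counts with [count_events()] and the three percent-identity
#' variants described above, directly from the CIGAR. Records carrying only a
#' cs tag are converted first; ambiguous `M` CIGARs are rejected (re-align
#' with `--eqx`).
#'
#' @param rec a [paf_record()] with a cg (or cs) tag.
#' @return A one-row data frame: `tname, tstart, tend, qname, qstart, qend,
#'   strand`, the three identities, and the six raw counts.
#' @examples
#' alignment_stats(paf_record("q", 100, 0, 100, "+", "t", 100, 0, 100,
#'                            cg = "90=10X"))
#' @export
alignment_stats <- function(rec) {
  cg <- rec$cigar
  if (is.null(cg)) {
    cs <- paf_tag(rec, "cs")
    if (is.null(cs)) paf_error("alignment_stats: record has neither cg nor cs tag")
    cg <- cs_to_cigar(cs)
  }
  ev <- count_events(cg)
  m <- ev$matches
  x <- ev$mismatches
  if (m + x == 0L) {
    warning("alignment_stats: record has no aligned column; identities set to 0")
    pm <- pe <- pa <- 0
  } else {
    pm <- 100 * m / (m + x)
    pe <- 100 * m / (m + x + ev$ins_events + ev$del_events)
    pa <- 100 * m / (m + x + ev$ins_bases + ev$del_bases)
  }
  data.frame(
    tname = rec$tname, tstart = rec$tstart, tend = rec$tend,
    qname = rec$qname, qstart = rec$qstart, qend = rec$qend,
    strand = rec$strand,
    perID_by_matches = pm, perID_by_events = pe, perID_by_all = pa,
    matches = m, mismatches = x,
    ins_events = ev$ins_events, del_events = ev$del_events,
    ins_bases = ev$ins_bases, del_bases = ev$del_bases,
    stringsAsFactors = FALSE
  )
}

#' Identity statistics for a collection
#'
#' @param records a `"paf"` collection.
#' @return A data frame with one [alignment_stats()] row per record.
#' @export
paf_stats <- function(records) {
  if (!length(records)) return(alignment_stats_schema())
  do.call(rbind, lapply(records, alignment_stats))
}

alignment_stats_schema <- function() {
  data.frame(
    tname = character(), tstart = integer(), tend = integer(),
    qname = character(), qstart = integer(), qend = integer(),
    strand = character(),
    perID_by_matches = numeric(), perID_by_events = numeric(),
    perID_by_all = numeric(),
    matches = integer(), mismatches = integer(),
    ins_events = integer(), del_events = integer(),
    ins_bases = integer(), del_bases = integer(),
    stringsAsFactors = FALSE
  )
}

#' Write / read the stats BED dialect
#'
#' Tab-separated with a `#`-prefixed header: six coordinate columns, strand,
#' three identities (4 decimal places) and six raw counts.
#'
#' @param stats a data frame from [paf_stats()].
#' @param file path or connection.
#' @return `write_stats`: `stats` invisibly; `read_stats`: the data frame.
#' @export
write_stats <- function(stats, file = stdout()) {
  cols <- names(alignment_stats_schema())
  header <- paste0("#", paste(cols, collapse = "\t"))
  body <- character(0)
  if (nrow(stats)) {
    id <- vapply(stats[c("perID_by_matches", "perID_by_events", "perID_by_all")],
                 fmt_fixed, character(nrow(stats)), digits = 4L)
    id <- matrix(id, nrow = nrow(stats))
    body <- apply(cbind(
      stats$tname, stats$tstart, stats$tend,
      stats$qname, stats$qstart, stats$qend, stats$strand,
      id,
      stats$matches, stats$mismatches,
      stats$ins_events, stats$del_events,
      stats$ins_bases, stats$del_bases
    ), 1L, paste, collapse = "\t")
  }
  writeLines(c(header, body), con = file)
  invisible(stats)
}

#' @rdname write_stats
#' @export
read_stats <- function(file) {
  lines <- read_text_lines(file)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- alignment_stats_schema()
  if (!length(lines)) return(out)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 16L)) {
    paf_error("read_stats: expected 16 columns per row")
  }
  m <- do.call(rbind, parts)
  data.frame(
    tname = m[, 1L], tstart = as.integer(m[, 2L]), tend = as.integer(m[, 3L]),
    qname = m[, 4L], qstart = as.integer(m[, 5L]), qend = as.integer(m[, 6L]),
    strand = m[, 7L],
    perID_by_matches = as.numeric(m[, 8L]),
    perID_by_events = as.numeric(m[, 9L]),
    perID_by_all = as.numeric(m[, 10L]),
    matches = as.integer(m[, 11L]), mismatches = as.integer(m[, 12L]),
    ins_events = as.integer(m[, 13L]), del_events = as.integer(m[, 14L]),
    ins_bases = as.integer(m[, 15L]), del_bases = as.integer(m[, 16L]),
    stringsAsFactors = FALSE
  )
}

#' Filter alignment pairs by total aligned length
#'
#' Groups records by (query name, target name) and keeps a group iff the sum
#' of its alignment block lengths is at least `min_len`. Record order is
#' preserved.
#'
#' @param records a `"paf"` collection.
#' @param min_len minimum summed `alnlen` in bases (>= 0).
#' @return A `"paf"` collection.
#' @export
filter_paired_len <- function(records, min_len) {
  if (min_len < 0) paf_error("filter_paired_len: min_len must be >= 0")
  if (!length(records)) return(as_paf(list()))
  key <- vapply(records, function(r) paste(r$qname, r$tname, sep = "\r"),
                character(1))
  tot <- rowsum(vapply(records, `[[`, integer(1), "alnlen"), key)
  keep_keys <- rownames(tot)[tot[, 1L] >= min_len]
  as_paf(unclass(records)[key %in% keep_keys])
}
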