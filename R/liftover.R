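# Liftover: project BED intervals through PAF alignments, emitting trimmed
# PAF records rather than bare coordinates, so the output can be piped
# straight into downstream record-level analyses (e.g. identity stats).

#' Project BED intervals through alignments
#'
#' For every (interval, overlapping record) pair one trimmed record is emitted
#' via [subalignment_by_target()] (or [subalignment_by_query()] when
#' `query_space`). The sequence name on the opposite side of the projection is
#' suffixed with `"::chrom:start-end"` of the source interval, so downstream
#' per-record statistics remain attributable to the interval that produced
#' them.
#'
#' Boundary convention at indels: a lifted end is never extended into an
#' insertion -- the emitted record stops at the last aligned base. (Block-based
#' liftover tools that place the end coordinate one base into an insertion
#' report an end exactly 1 bp further.)
#'
#' @param records a `"paf"` collection (records must carry cg CIGARs).
#' @param intervals a BED data frame as returned by [read_bed()]; intervals
#'   are on target names, or on query names when `query_space`. A strand
#'   column, if present in `extra`, is ignored: projection strand comes from
#'   the alignment.
#' @param query_space project from query coordinates instead of target.
#' @param largest_only per interval, keep only the record with the greatest
#'   number of aligned bases in the intersection.
#' @return A `"paf"` collection, ordered by interval then by input record.
#' @examples
#' r <- paf_record("q", 100, 0, 100, "+", "t", 100, 0, 100, cg = "100=")
#' bed <- data.frame(chrom = "t", start = 10, end = 20,
#'                   name = "geneA", extra = "")
#' liftover(as_paf(list(r)), bed)
#' @export
liftover <- function(records, intervals, query_space = FALSE,
                     largest_only = FALSE) {
  side_name <- vapply(records, function(r) {
    if (query_space) r$qname else r$tname
  }, character(1))
  out <- list()
  n_no_chrom <- 0L
  n_empty <- 0L
  for (k in seq_len(nrow(intervals))) {
    iv <- intervals[k, ]
    idx <- which(side_name == iv$chrom)
    if (!length(idx)) {
      n_no_chrom <- n_no_chrom + 1L
      next
    }
    suffix <- sprintf("::%s:%d-%d", iv$chrom, iv$start, iv$end)
    hits <- list()
    for (i in idx) {
      sub <- if (query_space) {
        subalignment_by_query(records[[i]], iv$start, iv$end)
      } else {
        subalignment_by_target(records[[i]], iv$start, iv$end)
      }
      if (is.null(sub)) {
        n_empty <- n_empty + 1L
        next
      }
      if (query_space) {
        sub$tname <- paste0(sub$tname, suffix)
      } else {
        sub$qname <- paste0(sub$qname, suffix)
      }
      hits[[length(hits) + 1L]] <- sub
    }
    if (largest_only && length(hits) > 1L) {
      aligned <- vapply(hits, function(h) {
        sum(h$cigar$len[h$cigar$op %in% c("=", "X", "M")])
      }, numeric(1))
      hits <- hits[which.max(aligned)]
    }
    out <- c(out, hits)
  }
  if (n_no_chrom > 0L) {
    message("liftover: ", n_no_chrom,
            " interval(s) matched no alignment and were skipped")
  }
  if (n_empty > 0L) {
    message("liftover: ", n_empty,
            " interval/record pair(s) had no aligned column and were skipped")
  }
  as_paf(out)
}
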