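# Splitting alignments at large indels: structural-variant-scale insertions
# or deletions are removed and the flanking alignment becomes separate
# records, turning one long alignment into fine-grained segments.

#' Split one record at oversized indels
#'
#' Cuts the CIGAR at every `I` or `D` run whose length strictly exceeds
#' `max_indel` ("exceeding the threshold"). Each maximal run of operations
#' between cuts becomes its own record with recomputed coordinates; segment
#' boundaries are pulled onto aligned bases (sub-threshold indels stranded at
#' a new edge are trimmed too), and the oversized indels themselves appear in
#' no output record. Segments are emitted in target order and tagged
#' `id:Z:{record_index}.{segment_index}` for provenance. A record with no
#' oversized indel is returned unchanged (and untagged).
#'
#' @param rec a [paf_record()] with a cg CIGAR.
#' @param max_indel threshold in bases (>= 1); indels of exactly this length
#'   are kept.
#' @param record_index 1-based index of `rec` in its input stream, used in the
#'   provenance tag.
#' @return A list of [paf_record()]s (possibly of length one).
#' @examples
#' r <- paf_record("q", 200, 0, 200, "+", "t", 6200, 0, 6200,
#'                 cg = "100=6000D100=")
#' break_on_indels(r, 5000)
#' @export
break_on_indels <- function(rec, max_indel, record_index = 1L) {
  if (is.null(rec$cigar)) paf_error("break_on_indels: record has no cg tag")
  if (max_indel < 1) paf_error("break_on_indels: max_indel must be >= 1")
  op <- rec$cigar$op
  len <- rec$cigar$len
  big <- which(op %in% c("I", "D") & len > max_indel)
  if (!length(big)) return(list(rec))
  bounds <- c(0L, big, length(op) + 1L)
  out <- list()
  seg_no <- 0L
  for (s in seq_len(length(bounds) - 1L)) {
    from <- bounds[s] + 1L
    to <- bounds[s + 1L] - 1L
    if (to < from) next
    head_rm <- ifelse(seq_along(op) < from, len, 0L)
    kept <- ifelse(seq_along(op) >= from & seq_along(op) <= to, len, 0L)
    tail_rm <- ifelse(seq_along(op) > to, len, 0L)
    sr <- finish_subrange(op, len, head_rm, kept, tail_rm)
    if (is.null(sr)) next
    seg_no <- seg_no + 1L
    seg <- apply_subrange(rec, sr)
    seg <- set_paf_tag(seg, "id", "Z",
                       sprintf("%d.%d", record_index, seg_no))
    out[[length(out) + 1L]] <- seg
  }
  out
}

#' Split all records at oversized indels
#'
#' Applies [break_on_indels()] to every record of a collection; segment
#' provenance tags use each record's position in the input.
#'
#' @param records a `"paf"` collection.
#' @param max_indel threshold in bases.
#' @return A `"paf"` collection.
#' @export
break_paf <- function(records, max_indel) {
  out <- list()
  for (i in seq_along(records)) {
    out <- c(out, break_on_indels(records[[i]], max_indel, record_index = i))
  }
  as_paf(out)
}
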