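# Coordinate arithmetic on alignments: per-base projection, sub-alignment
# extraction by target or query range, strand flipping, query/target inversion.
#
# Everything here works in "walking" coordinates: the CIGAR is stored in
# target-forward order, target offsets ascend from 0 at tstart, and query
# walking offsets ascend from 0 in CIGAR order -- which for '+' records means
# ascending from qstart and for '-' records descending from qend-1 in
# forward-strand query coordinates.

#' Expand an alignment into per-base columns
#'
#' Produces one row per CIGAR-consumed column, in target-forward order. For
#' insertions the target position is `NA`; for deletions the query position is
#' `NA`. Query positions are forward-strand coordinates: ascending from
#' `qstart` for `+` records, descending from `qend - 1` for `-` records.
#'
#' This exhaustive expansion is the reference backbone against which all
#' interval-arithmetic operations in the package can be checked per base.
#'
#' @param rec a [paf_record()] carrying a cg CIGAR.
#' @return A data frame with columns `tpos`, `qpos` (integer, `NA` = gap) and
#'   `kind` (the CIGAR operation).
#' @export
aligned_columns <- function(rec) {
  cg <- rec$cigar
  if (is.null(cg)) paf_error("aligned_columns: record has no cg tag")
  op <- cg$op
  len <- cg$len
  if (!length(op)) {
    return(data.frame(tpos = integer(), qpos = integer(), kind = character(),
                      stringsAsFactors = FALSE))
  }
  tc <- ifelse(op_consumes_target(op), len, 0L)
  qc <- ifelse(op_consumes_query(op), len, 0L)
  t0 <- cumsum(tc) - tc  # target walking offset at op start
  q0 <- cumsum(qc) - qc  # query walking offset at op start
  opi <- rep(seq_along(op), len)
  within <- sequence(len) - 1L
  tpos <- rec$tstart + t0[opi] + within
  tpos[op[opi] == "I"] <- NA_integer_
  qw <- q0[opi] + within
  qw[op[opi] == "D"] <- NA_integer_
  qpos <- if (rec$strand == "+") rec$qstart + qw else rec$qend - 1L - qw
  data.frame(tpos = as.integer(tpos), qpos = as.integer(qpos),
             kind = op[opi], stringsAsFactors = FALSE)
}

## ---- sub-range machinery ---------------------------------------------------

# Given per-op head/kept/tail partitions (in op-length units), trim dangling
# indels off the kept region and tally what the cut removes on each side.
# Returns NULL when the kept region has no aligned (=/X/M) column.
finish_subrange <- function(op, len, head_rm, kept, tail_rm) {
  ki <- which(kept > 0L)
  if (!length(ki)) return(NULL)
  i <- ki[1L]
  j <- ki[length(ki)]
  while (i <= j && !op_is_aligned(op[i])) {
    head_rm[i] <- head_rm[i] + kept[i]
    kept[i] <- 0L
    i <- i + 1L
  }
  while (j >= i && !op_is_aligned(op[j])) {
    tail_rm[j] <- tail_rm[j] + kept[j]
    kept[j] <- 0L
    j <- j - 1L
  }
  if (j < i) return(NULL)
  cq <- op_consumes_query(op)
  ct <- op_consumes_target(op)
  list(
    op = op[kept > 0L], len = kept[kept > 0L],
    pre_q = sum(head_rm[cq]), pre_t = sum(head_rm[ct]),
    suf_q = sum(tail_rm[cq]), suf_t = sum(tail_rm[ct]),
    ncol_pre = sum(head_rm), ncol_kept = sum(kept)
  )
}

# Cut a CIGAR to the walking window [lo, hi) measured along one axis
# ("target": =/X/D/M consume; "query": =/X/I/M consume). Ops with zero width
# on the axis are kept when they fall inside the window and trimmed away at
# its edges by the no-dangling-indel rule.
cigar_subrange <- function(cg, lo, hi, axis = c("target", "query")) {
  axis <- match.arg(axis)
  op <- cg$op
  len <- cg$len
  cons <- if (axis == "target") op_consumes_target(op) else op_consumes_query(op)
  w <- ifelse(cons, len, 0L)
  start <- cumsum(w) - w
  end <- start + w
  lo <- max(0L, as.integer(lo))
  hi <- min(sum(w), as.integer(hi))
  if (hi <= lo) return(NULL)
  head_rm <- integer(length(op))
  kept <- integer(length(op))
  tail_rm <- integer(length(op))
  consum <- which(cons)
  if (length(consum)) {
    ov <- pmax(0L, pmin(end[consum], hi) - pmax(start[consum], lo))
    hd <- pmin(len[consum], pmax(0L, lo - start[consum]))
    kept[consum] <- ov
    head_rm[consum] <- hd
    tail_rm[consum] <- len[consum] - ov - hd
  }
  zw <- which(!cons)
  if (length(zw)) {
    pos <- start[zw]
    inside <- pos >= lo & pos <= hi
    kept[zw][inside] <- len[zw][inside]
    head_rm[zw][pos < lo] <- len[zw][pos < lo]
    tail_rm[zw][pos > hi] <- len[zw][pos > hi]
  }
  finish_subrange(op, len, head_rm, kept, tail_rm)
}

# Rebuild a record from a finished sub-range: shift coordinates by the
# removed prefix/suffix consumption, recompute nmatch/alnlen, and cut any cs
# tag in lock-step (by alignment-column counts); cs is dropped with a note if
# it cannot be cut.
apply_subrange <- function(rec, sr) {
  cg <- cigar(sr$op, sr$len)
  if (rec$strand == "+") {
    qs <- rec$qstart + sr$pre_q
    qe <- rec$qend - sr$suf_q
  } else {
    qs <- rec$qstart + sr$suf_q
    qe <- rec$qend - sr$pre_q
  }
  out <- rec
  out$tstart <- rec$tstart + sr$pre_t
  out$tend <- rec$tend - sr$suf_t
  out$qstart <- qs
  out$qend <- qe
  out$cigar <- cg
  out$nmatch <- cigar_nmatch(cg)
  out$alnlen <- cigar_ncols(cg)
  cs <- paf_tag(out, "cs")
  if (!is.null(cs)) {
    new_cs <- cs_subcols(cs, sr$ncol_pre, sr$ncol_kept)
    if (is.null(new_cs)) {
      out <- drop_cs_with_note(out, "not trimmable in lock-step")
    } else {
      out$tags[["cs"]]$value <- new_cs
    }
  }
  validate_paf_record(out)
  out
}

#' Extract the sub-alignment covering a target range
#'
#' Cuts the record to the intersection of `[lo, hi)` with its target span,
#' then shrinks it further so the CIGAR begins and ends on an aligned (`=`/`X`)
#' column: a requested boundary inside an indel moves inward to the nearest
#' aligned base, and an end is never extended into an insertion. Query
#' coordinates, `nmatch` and `alnlen` are recomputed from the sub-CIGAR;
#' strand is preserved.
#'
#' @param rec a [paf_record()] with a cg CIGAR.
#' @param lo,hi target coordinates, 0-based half-open.
#' @return A trimmed [paf_record()], or `NULL` when the intersection contains
#'   no aligned column (the empty-result signal, not an error).
#' @export
subalignment_by_target <- function(rec, lo, hi) {
  if (is.null(rec$cigar)) paf_error("subalignment_by_target: record has no cg tag")
  sr <- cigar_subrange(rec$cigar, lo - rec$tstart, hi - rec$tstart, "target")
  if (is.null(sr)) return(NULL)
  apply_subrange(rec, sr)
}

#' Extract the sub-alignment covering a query range
#'
#' Symmetric to [subalignment_by_target()], with `lo`/`hi` in forward-strand
#' query coordinates. For `-` strand records the window is converted to the
#' CIGAR walking direction internally.
#'
#' @param rec a [paf_record()] with a cg CIGAR.
#' @param lo,hi forward-strand query coordinates, 0-based half-open.
#' @return A trimmed [paf_record()], or `NULL` when no aligned column remains.
#' @export
subalignment_by_query <- function(rec, lo, hi) {
  if (is.null(rec$cigar)) paf_error("subalignment_by_query: record has no cg tag")
  if (rec$strand == "+") {
    wlo <- lo - rec$qstart
    whi <- hi - rec$qstart
  } else {
    wlo <- rec$qend - hi
    whi <- rec$qend - lo
  }
  sr <- cigar_subrange(rec$cigar, wlo, whi, "query")
  if (is.null(sr)) return(NULL)
  apply_subrange(rec, sr)
}

## ---- orientation -----------------------------------------------------------

#' Flip the orientation of the query side
#'
#' Toggles the strand and reflects the query interval through the query
#' length: `qstart' = qlen - qend`, `qend' = qlen - qstart`. The CIGAR is
#' unchanged (it stays in target-forward order, which makes the flip purely a
#' coordinate reflection). Applying the flip twice returns the original
#' record. Any cs tag is dropped.
#'
#' @param rec a [paf_record()].
#' @return The flipped record.
#' @export
flip_query_orientation <- function(rec) {
  out <- rec
  out$strand <- if (rec$strand == "+") "-" else "+"
  out$qstart <- rec$qlen - rec$qend
  out$qend <- rec$qlen - rec$qstart
  out <- drop_cs_with_note(out, "query orientation flipped")
  validate_paf_record(out)
  out
}

#' Swap the query and target sides of an alignment
#'
#' Exchanges the query and target fields; in the CIGAR, insertions and
#' deletions swap roles (`I` <-> `D`). For `-` strand records the operation
#' order is additionally reversed so the CIGAR remains forward along the new
#' target. Applying the inversion twice returns the original record. Any cs
#' tag is dropped (its sequence payloads belong to the old orientation).
#'
#' @param rec a [paf_record()].
#' @return The inverted record.
#' @export
invert_record <- function(rec) {
  out <- rec
  out$qname <- rec$tname
  out$qlen <- rec$tlen
  out$qstart <- rec$tstart
  out$qend <- rec$tend
  out$tname <- rec$qname
  out$tlen <- rec$qlen
  out$tstart <- rec$qstart
  out$tend <- rec$qend
  if (!is.null(rec$cigar)) {
    op <- rec$cigar$op
    len <- rec$cigar$len
    op[rec$cigar$op == "I"] <- "D"
    op[rec$cigar$op == "D"] <- "I"
    if (rec$strand == "-") {
      op <- rev(op)
      len <- rev(len)
    }
    out$cigar <- cigar(op, len)
  }
  out <- drop_cs_with_note(out, "query/target inverted")
  validate_paf_record(out)
  out
}
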