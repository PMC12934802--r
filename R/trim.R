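# Overlap resolution: trim overlapping query alignments by cumulative-score
# maximization so that no query base remains aligned to more than one target
# position. Supplemental alignments at duplications and inversion boundaries
# are the typical source of such overlaps.

#' Scoring scheme for overlap resolution
#'
#' Per-base alignment scores used by [best_split()] and [trim_paf()]. Indels
#' are scored per base (a single gap score; no separate open/extend).
#'
#' @param match score of a matching base (> 0).
#' @param mismatch score of a mismatching base (<= 0).
#' @param indel score of each inserted or deleted base (<= 0).
#' @return A list with class `"score_scheme"`.
#' @export
score_scheme <- function(match = 1, mismatch = -1, indel = -1) {
  if (!(match > 0)) paf_error("score_scheme: match score must be > 0")
  if (mismatch > 0) paf_error("score_scheme: mismatch score must be <= 0")
  if (indel > 0) paf_error("score_scheme: indel score must be <= 0")
  structure(list(match = match, mismatch = mismatch, indel = indel),
            class = "score_scheme")
}

#' Find pairs of records overlapping in query coordinates
#'
#' All pairs of records sharing a query name whose `[qstart, qend)` intervals
#' intersect, sorted by overlap length descending (ties: enumeration order).
#' Within each pair, "left" is the record with the smaller `qstart` (ties:
#' smaller `qend`, then list position).
#'
#' @param records a `"paf"` collection or list of records.
#' @return A data frame with columns `li`, `ri` (indices of the left/right
#'   record in `records`), `olo`, `ohi` (the overlap, forward-strand query
#'   coordinates) and `olen`.
#' @export
find_query_overlaps <- function(records) {
  n <- length(records)
  res <- list()
  if (n >= 2L) {
    qn <- vapply(records, `[[`, character(1), "qname")
    qs <- vapply(records, `[[`, integer(1), "qstart")
    qe <- vapply(records, `[[`, integer(1), "qend")
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        if (qn[i] != qn[j]) next
        olo <- max(qs[i], qs[j])
        ohi <- min(qe[i], qe[j])
        if (olo >= ohi) next
        left_first <- qs[i] < qs[j] || (qs[i] == qs[j] && qe[i] <= qe[j])
        res[[length(res) + 1L]] <- data.frame(
          li = if (left_first) i else j,
          ri = if (left_first) j else i,
          olo = olo, ohi = ohi, olen = ohi - olo
        )
      }
    }
  }
  if (!length(res)) {
    return(data.frame(li = integer(), ri = integer(), olo = integer(),
                      ohi = integer(), olen = integer()))
  }
  out <- do.call(rbind, res)
  out[order(-out$olen, seq_len(nrow(out))), , drop = FALSE]
}

# Per-query-base charged scores of one record over [lo, hi).
# Each aligned or inserted column is charged at its own forward-strand query
# position; deleted target bases consume no query base, so each deletion's
# penalty is charged at the query position of the next aligned (=/X) column
# in CIGAR walking order. A split point therefore never lands inside a
# deletion.
charged_scores <- function(rec, lo, hi, scheme) {
  cols <- aligned_columns(rec)
  n <- nrow(cols)
  v <- numeric(hi - lo)
  if (!n) return(v)
  kind <- cols$kind
  if (any(kind == "M")) {
    paf_error("trim scoring: CIGAR contains ambiguous 'M' ops (use --eqx input)")
  }
  charge <- cols$qpos
  del <- which(kind == "D")
  if (length(del)) {
    a <- ifelse(kind %in% c("=", "X"), seq_len(n), n + 1L)
    nxt <- rev(cummin(rev(a)))  # nearest aligned column at or after each row
    ok <- nxt[del] <= n
    charge[del[ok]] <- cols$qpos[nxt[del[ok]]]
    charge[del[!ok]] <- NA_integer_
  }
  sc <- ifelse(kind == "=", scheme$match,
               ifelse(kind == "X", scheme$mismatch, scheme$indel))
  inr <- !is.na(charge) & charge >= lo & charge < hi
  if (!any(inr)) return(v)
  acc <- rowsum(sc[inr], charge[inr] - lo + 1L)
  v[as.integer(rownames(acc))] <- acc[, 1L]
  v
}

#' Optimal split point of an overlapping pair
#'
#' For two records overlapping in query coordinates on `[olo, ohi)`, finds the
#' split `p` in `[olo, ohi]` maximizing `F_left(p) + S_right(p)`, where
#' `F_left` accumulates the left record's per-base scores over `[olo, p)` and
#' `S_right` the right record's over `[p, ohi)`. Ties are broken by the
#' smallest `p` (determinism).
#'
#' @param left,right the two [paf_record()]s (both must carry cg CIGARs).
#' @param olo,ohi the query-coordinate overlap (forward strand).
#' @param scheme a [score_scheme()].
#' @return A list with elements `p` (the split coordinate) and `score` (the
#'   maximal `F + S` value over the overlap).
#' @export
best_split <- function(left, right, olo, ohi, scheme = score_scheme()) {
  if (is.null(left$cigar) || is.null(right$cigar)) {
    paf_error("best_split: both records need a cg tag")
  }
  sl <- charged_scores(left, olo, ohi, scheme)
  sr <- charged_scores(right, olo, ohi, scheme)
  f <- c(0, cumsum(sl))              # F(p) for p = olo..ohi
  s <- c(rev(cumsum(rev(sr))), 0)    # S(p) for p = olo..ohi
  tot <- f + s
  k <- which.max(tot)                # first maximum = smallest p
  list(p = olo + k - 1L, score = tot[k])
}

#' Resolve overlapping query alignments
#'
#' Repeatedly takes the largest remaining query-coordinate overlap, computes
#' the optimal split point with [best_split()], trims the left record to query
#' end `p*` and the right record to query start `p*` (via
#' [subalignment_by_query()]), and recomputes overlaps, until no query base is
#' aligned more than once. Records whose trimmed span retains no aligned
#' column are dropped. Surviving records keep their input order; the result is
#' deterministic and idempotent.
#'
#' @param records a `"paf"` collection.
#' @param scheme a [score_scheme()].
#' @return A `"paf"` collection with pairwise-disjoint query intervals per
#'   query name.
#' @export
trim_paf <- function(records, scheme = score_scheme()) {
  recs <- unclass(as_paf(records))
  repeat {
    keep <- !vapply(recs, is.null, logical(1))
    live <- which(keep)
    ov <- find_query_overlaps(recs[live])
    if (!nrow(ov)) break
    o <- ov[1L, ]
    li <- live[o$li]
    ri <- live[o$ri]
    left <- recs[[li]]
    right <- recs[[ri]]
    p <- best_split(left, right, o$olo, o$ohi, scheme)$p
    recs[li] <- list(subalignment_by_query(left, left$qstart, p))
    recs[ri] <- list(subalignment_by_query(right, p, right$qend))
  }
  as_paf(recs[!vapply(recs, is.null, logical(1))])
}
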