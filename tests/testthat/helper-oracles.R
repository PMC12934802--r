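# Independent brute-force oracles and small fixture builders shared by the
# tests. The oracles work per base on the exhaustive column expansion and
# never reuse the interval-arithmetic code paths they check.

# quick record builder
rec <- function(cg, qstart = 0, tstart = 0, strand = "+",
                qname = "q", tname = "t", qlen = NULL, tlen = NULL,
                tags = list()) {
  cgo <- parse_cigar(cg)
  qspan <- sum(cgo$len[cgo$op %in% c("=", "X", "I", "M")])
  tspan <- sum(cgo$len[cgo$op %in% c("=", "X", "D", "M")])
  paf_record(qname, qlen %||% (qstart + qspan + 10L), qstart, qstart + qspan,
             strand, tname, tlen %||% (tstart + tspan + 10L), tstart,
             tstart + tspan, cg = cgo, tags = tags)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# expected sub-alignment from the per-base expansion: clip columns to the
# window on one axis, shrink to aligned (=/X) boundaries, re-encode
oracle_subalignment <- function(r, lo, hi, axis = c("target", "query")) {
  axis <- match.arg(axis)
  cols <- aligned_columns(r)
  pos <- if (axis == "target") cols$tpos else cols$qpos
  idx <- which(!is.na(pos) & pos >= lo & pos < hi & cols$kind %in% c("=", "X", "M"))
  if (!length(idx)) return(NULL)
  sub <- cols[min(idx):max(idx), , drop = FALSE]
  runs <- rle(sub$kind)
  list(
    tstart = min(sub$tpos, na.rm = TRUE),
    tend = max(sub$tpos, na.rm = TRUE) + 1L,
    qstart = min(sub$qpos, na.rm = TRUE),
    qend = max(sub$qpos, na.rm = TRUE) + 1L,
    cg = paste0(runs$lengths, runs$values, collapse = "")
  )
}

# per-base charged score of one record's columns with charge position in
# [lo, hi): deletions are charged at the query position of the next aligned
# column in walking order
oracle_window_score <- function(r, lo, hi, scheme) {
  cols <- aligned_columns(r)
  n <- nrow(cols)
  charge <- cols$qpos
  nxt <- NA_integer_
  for (i in rev(seq_len(n))) {
    if (cols$kind[i] %in% c("=", "X")) nxt <- cols$qpos[i]
    if (cols$kind[i] == "D") charge[i] <- nxt
  }
  sc <- ifelse(cols$kind == "=", scheme$match,
               ifelse(cols$kind == "X", scheme$mismatch, scheme$indel))
  sum(sc[!is.na(charge) & charge >= lo & charge < hi])
}

# exhaustive split-point search
oracle_best_split <- function(left, right, olo, ohi, scheme = score_scheme()) {
  ps <- olo:ohi
  tot <- vapply(ps, function(p) {
    oracle_window_score(left, olo, p, scheme) +
      oracle_window_score(right, p, ohi, scheme)
  }, numeric(1))
  list(p = ps[which.max(tot)], score = max(tot))
}

# random alignment record with aligned ends, mixed strand, optional big indels
random_record <- function(seed, max_aligned = 2000L, max_indel = 10000L,
                          n_ops = NULL) {
  set.seed(seed)
  n <- n_ops %||% sample(3:15, 1)
  op <- character(n)
  len <- integer(n)
  for (i in seq_len(n)) {
    if (i == 1L || i == n) {
      op[i] <- sample(c("=", "X"), 1, prob = c(0.8, 0.2))
    } else {
      op[i] <- sample(c("=", "X", "I", "D"), 1, prob = c(0.5, 0.2, 0.15, 0.15))
    }
    len[i] <- if (op[i] %in% c("I", "D")) {
      sample.int(max_indel, 1)
    } else {
      sample.int(max_aligned, 1)
    }
  }
  cg <- cigar(op, len)
  qspan <- cigar_query_consumed(cg)
  tspan <- cigar_target_consumed(cg)
  qs <- sample.int(100L, 1)
  ts <- sample.int(100L, 1)
  paf_record("q", qs + qspan + sample.int(100L, 1), qs, qs + qspan,
             sample(c("+", "-"), 1), "t", ts + tspan + sample.int(100L, 1),
             ts, ts + tspan, cg = cg)
}

# test-only cs encoding of a CIGAR (arbitrary but valid base content)
cigar_to_cs <- function(cg) {
  paste(mapply(function(o, l) {
    switch(o,
           "=" = paste0(":", l),
           "X" = paste(rep("*ac", l), collapse = ""),
           "I" = paste0("+", paste(rep("a", l), collapse = "")),
           "D" = paste0("-", paste(rep("g", l), collapse = "")))
  }, cg$op, cg$len), collapse = "")
}

expect_same_record <- function(a, b) {
  expect_equal(format_paf_record(a), format_paf_record(b))
}
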