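# CIGAR strings: run-length encoded alignment operations.
#
# Operations follow the minimap2 --eqx convention:
#   "="  match      (consumes query and target)
#   "X"  mismatch   (consumes query and target)
#   "I"  insertion  (consumes query only)
#   "D"  deletion   (consumes target only)
#   "M"  ambiguous match-or-mismatch (consumes both); accepted on parse but
#        rejected by identity statistics, which need =/X resolution.

CIGAR_OPS <- c("=", "X", "I", "D", "M")

op_consumes_query <- function(op) op %in% c("=", "X", "I", "M")
op_consumes_target <- function(op) op %in% c("=", "X", "D", "M")
op_is_aligned <- function(op) op %in% c("=", "X", "M")

#' Construct a CIGAR object
#'
#' A `cigar` is an ordered run-length encoding of alignment columns, stored as
#' parallel vectors of operation codes and lengths. The constructor normalizes
#' its input: zero-length runs are dropped and adjacent runs of the same
#' operation are merged, so no two neighbouring operations share a kind.
#'
#' @param op character vector of operation codes, each one of
#'   `"="`, `"X"`, `"I"`, `"D"`, `"M"`.
#' @param len integer vector of run lengths (each >= 1), parallel to `op`.
#' @return An object of class `"cigar"` with elements `op` and `len`.
#' @seealso [parse_cigar()], [cs_to_cigar()], [count_events()]
#' @examples
#' cigar(c("=", "X", "="), c(10, 1, 5))
#' cigar(c("=", "="), c(50, 50))  # normalized to a single 100= run
#' @export
cigar <- function(op = character(), len = integer()) {
  op <- as.character(op)
  len <- as.integer(len)
  if (length(op) != length(len)) {
    paf_error("cigar: op and len must have equal length")
  }
  if (anyNA(len) || any(len < 0L)) {
    paf_error("cigar: run lengths must be non-negative integers")
  }
  bad <- setdiff(unique(op), CIGAR_OPS)
  if (length(bad)) {
    paf_error("cigar: unsupported operation(s): ", paste(bad, collapse = ", "))
  }
  cigar_normalize(structure(list(op = op, len = len), class = "cigar"))
}

# merge adjacent same-kind runs, drop zero-length runs; idempotent
cigar_normalize <- function(cg) {
  keep <- cg$len > 0L
  op <- cg$op[keep]
  len <- cg$len[keep]
  if (length(op) > 1L) {
    grp <- cumsum(c(TRUE, op[-1L] != op[-length(op)]))
    len <- as.integer(rowsum(as.numeric(len), grp)[, 1L])
    op <- op[!duplicated(grp)]
  }
  structure(list(op = op, len = len), class = "cigar")
}

#' Parse a CIGAR string
#'
#' @param s a single CIGAR string, e.g. `"50=1X49="`.
#' @return A [cigar()] object (normalized).
#' @examples
#' parse_cigar("10=2I5=3D1X")
#' @export
parse_cigar <- function(s) {
  if (length(s) != 1L || is.na(s)) paf_error("parse_cigar: need one string")
  if (!nzchar(s)) return(cigar())
  m <- gregexpr("([0-9]+)([A-Za-z=])", s, perl = TRUE)[[1L]]
  if (m[1L] == -1L || sum(attr(m, "match.length")) != nchar(s)) {
    paf_error("parse_cigar: malformed CIGAR string: ", s)
  }
  runs <- regmatches(s, gregexpr("([0-9]+)([A-Za-z=])", s, perl = TRUE))[[1L]]
  op <- substr(runs, nchar(runs), nchar(runs))
  len <- as.integer(substr(runs, 1L, nchar(runs) - 1L))
  cigar(op, len)
}

#' @export
format.cigar <- function(x, ...) {
  if (!length(x$op)) return("")
  paste0(x$len, x$op, collapse = "")
}

#' @export
as.character.cigar <- function(x, ...) format(x)

#' @export
print.cigar <- function(x, ...) {
  cat("<cigar> ", format(x), "\n", sep = "")
  invisible(x)
}

# total bases consumed on each side
cigar_query_consumed <- function(cg) sum(cg$len[op_consumes_query(cg$op)])
cigar_target_consumed <- function(cg) sum(cg$len[op_consumes_target(cg$op)])
cigar_ncols <- function(cg) sum(cg$len)

# nmatch for the PAF column; M runs are counted as (presumed) matches
cigar_nmatch <- function(cg) sum(cg$len[cg$op %in% c("=", "M")])

#' Tally alignment events in a CIGAR
#'
#' Counts matches, mismatches and indel events/bases directly from the CIGAR
#' run-length encoding. Ambiguous `"M"` operations are rejected because they
#' cannot be attributed to matches or mismatches; re-align with `minimap2
#' --eqx` to obtain `=`/`X` resolved CIGARs.
#'
#' @param cg a [cigar()] object.
#' @return A named list with integer elements `matches`, `mismatches`,
#'   `ins_events`, `del_events`, `ins_bases`, `del_bases`.
#' @examples
#' count_events(parse_cigar("10=2I5=3D1X"))
#' @export
count_events <- function(cg) {
  stopifnot(inherits(cg, "cigar"))
  if (any(cg$op == "M")) {
    paf_error(
      "count_events: CIGAR contains ambiguous 'M' operations; ",
      "identity statistics need =/X resolution (use minimap2 --eqx)"
    )
  }
  list(
    matches    = sum(cg$len[cg$op == "="]),
    mismatches = sum(cg$len[cg$op == "X"]),
    ins_events = sum(cg$op == "I"),
    del_events = sum(cg$op == "D"),
    ins_bases  = sum(cg$len[cg$op == "I"]),
    del_bases  = sum(cg$len[cg$op == "D"])
  )
}

## ---- cs difference strings --------------------------------------------------

# token pattern for the cs tag (short form ":n", long form "=ACGT")
CS_TOKEN_RE <- ":[0-9]+|\\*[A-Za-z][A-Za-z]|\\+[A-Za-z]+|-[A-Za-z]+|=[A-Za-z]+"

cs_tokenize <- function(cs) {
  if (!nzchar(cs)) return(character())
  m <- gregexpr(CS_TOKEN_RE, cs, perl = TRUE)[[1L]]
  if (m[1L] == -1L || sum(attr(m, "match.length")) != nchar(cs)) {
    paf_error("cs_to_cigar: malformed cs string: ", cs)
  }
  regmatches(cs, gregexpr(CS_TOKEN_RE, cs, perl = TRUE))[[1L]]
}

#' Convert a cs difference string to a CIGAR
#'
#' The minimap2 `cs` tag encodes identical runs (`:n` or `=SEQ`), single-base
#' substitutions (`*ab`), insertions (`+seq`) and deletions (`-seq`). The
#' conversion is lossless at the CIGAR level: `:n`/`=SEQ` become `=` runs,
#' each `*ab` one `X` column, `+seq` an `I` run and `-seq` a `D` run.
#'
#' @param cs a single cs string, e.g. `":10*at:5"`.
#' @return A normalized [cigar()] object.
#' @examples
#' cs_to_cigar(":10*at:5")   # 10=1X5=
#' cs_to_cigar(":4+acg:4")   # 4=3I4=
#' @export
cs_to_cigar <- function(cs) {
  toks <- cs_tokenize(cs)
  if (!length(toks)) return(cigar())
  lead <- substr(toks, 1L, 1L)
  op <- c(":" = "=", "=" = "=", "*" = "X", "+" = "I", "-" = "D")[lead]
  len <- ifelse(
    lead == ":", suppressWarnings(as.integer(substring(toks, 2L))),
    ifelse(lead == "*", 1L, nchar(toks) - 1L)
  )
  cigar(op, as.integer(len))
}

# width of each cs token in alignment columns
cs_token_width <- function(toks) {
  lead <- substr(toks, 1L, 1L)
  ifelse(lead == ":", suppressWarnings(as.integer(substring(toks, 2L))),
         ifelse(lead == "*", 1L, nchar(toks) - 1L))
}

# Trim a cs string to the alignment-column window [skip, skip+keep).
# Columns are counted exactly as in the CIGAR expansion, so a cs tag can be
# cut in lock-step with any CIGAR sub-range. Returns NULL when not cuttable.
cs_subcols <- function(cs, skip, keep) {
  toks <- tryCatch(cs_tokenize(cs), error = function(e) NULL)
  if (is.null(toks)) return(NULL)
  w <- cs_token_width(toks)
  if (anyNA(w)) return(NULL)
  out <- character(0)
  pos <- 0L
  lo <- skip
  hi <- skip + keep
  for (k in seq_along(toks)) {
    t0 <- pos
    t1 <- pos + w[k]
    pos <- t1
    a <- max(t0, lo)
    b <- min(t1, hi)
    if (b <= a) next
    lead <- substr(toks[k], 1L, 1L)
    if (a == t0 && b == t1) {
      out <- c(out, toks[k])
    } else if (lead == ":") {
      out <- c(out, paste0(":", b - a))
    } else if (lead %in% c("+", "-", "=")) {
      seqpart <- substr(toks[k], 2L + (a - t0), 1L + (b - t0))
      out <- c(out, paste0(lead, seqpart))
    } else {
      out <- c(out, toks[k])  # "*ab" has width 1, never split
    }
  }
  paste(out, collapse = "")
}
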