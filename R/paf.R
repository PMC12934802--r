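# PAF records and file I/O.
#
# A paf_record holds the 12 mandatory PAF columns plus SAM-style typed tags.
# All coordinates are 0-based half-open; query coordinates are always given on
# the query's forward strand. The cg tag, when present, is parsed into a
# `cigar` object and re-serialized on output; cg is stored in target-forward
# order, so for '-' strand records the query is walked from high to low
# forward-strand coordinates (the minimap2 PAF convention).

PAF_FIELDS <- c("qname", "qlen", "qstart", "qend", "strand",
                "tname", "tlen", "tstart", "tend",
                "nmatch", "alnlen", "mapq")

#' Construct a PAF alignment record
#'
#' @param qname,tname query/target sequence names.
#' @param qlen,tlen query/target sequence lengths.
#' @param qstart,qend query interval, 0-based half-open, forward strand.
#' @param strand `"+"` or `"-"`.
#' @param tstart,tend target interval, 0-based half-open.
#' @param nmatch number of residue matches.
#' @param alnlen alignment block length (total CIGAR-consumed columns).
#' @param mapq mapping quality, 0--255.
#' @param cg optional [cigar()] object (or CIGAR string).
#' @param tags named list of additional tags; each element is
#'   `list(type = , value = )` with a SAM tag type code.
#' @param validate check record invariants (default `TRUE`).
#' @return An object of class `"paf_record"`.
#' @export
paf_record <- function(qname, qlen, qstart, qend, strand,
                       tname, tlen, tstart, tend,
                       nmatch = NULL, alnlen = NULL, mapq = 60L,
                       cg = NULL, tags = list(), validate = TRUE) {
  if (is.character(cg)) cg <- parse_cigar(cg)
  if (!is.null(cg)) {
    if (is.null(nmatch)) nmatch <- cigar_nmatch(cg)
    if (is.null(alnlen)) alnlen <- cigar_ncols(cg)
  }
  rec <- structure(list(
    qname = as.character(qname), qlen = as.integer(qlen),
    qstart = as.integer(qstart), qend = as.integer(qend),
    strand = as.character(strand),
    tname = as.character(tname), tlen = as.integer(tlen),
    tstart = as.integer(tstart), tend = as.integer(tend),
    nmatch = as.integer(nmatch), alnlen = as.integer(alnlen),
    mapq = as.integer(mapq),
    cigar = cg, tags = tags
  ), class = "paf_record")
  if (validate) validate_paf_record(rec)
  rec
}

#' Validate a PAF record's invariants
#'
#' Checks coordinate ordering, CIGAR/coordinate span agreement, and that the
#' CIGAR neither starts nor ends in an indel (no dangling `I`/`D`).
#'
#' @param rec a `paf_record`.
#' @param where optional context (e.g. a line number) used in error messages.
#' @return `rec`, invisibly; errors on violation.
#' @export
validate_paf_record <- function(rec, where = NULL) {
  ctx <- if (is.null(where)) "" else paste0(where, ": ")
  if (!(rec$strand %in% c("+", "-"))) {
    paf_error(ctx, "strand must be '+' or '-'")
  }
  if (is.na(rec$qstart) || is.na(rec$qend) || is.na(rec$tstart) ||
      is.na(rec$tend) || is.na(rec$qlen) || is.na(rec$tlen)) {
    paf_error(ctx, "non-numeric coordinate")
  }
  if (!(rec$qstart >= 0L && rec$qstart < rec$qend && rec$qend <= rec$qlen)) {
    paf_error(ctx, "query coordinates violate 0 <= qstart < qend <= qlen")
  }
  if (!(rec$tstart >= 0L && rec$tstart < rec$tend && rec$tend <= rec$tlen)) {
    paf_error(ctx, "target coordinates violate 0 <= tstart < tend <= tlen")
  }
  if (!is.null(rec$cigar)) {
    cg <- rec$cigar
    qc <- cigar_query_consumed(cg)
    tc <- cigar_target_consumed(cg)
    if (qc != rec$qend - rec$qstart) {
      paf_error(ctx, "CIGAR consumes ", qc, " query bases but qend-qstart = ",
                rec$qend - rec$qstart)
    }
    if (tc != rec$tend - rec$tstart) {
      paf_error(ctx, "CIGAR consumes ", tc, " target bases but tend-tstart = ",
                rec$tend - rec$tstart)
    }
    n <- length(cg$op)
    if (n > 0L && (!op_is_aligned(cg$op[1L]) || !op_is_aligned(cg$op[n]))) {
      paf_error(ctx, "CIGAR starts or ends in an indel (dangling I/D)")
    }
  }
  invisible(rec)
}

#' @export
print.paf_record <- function(x, ...) {
  cat(format_paf_record(x), "\n")
  invisible(x)
}

# a paf object is a plain list of paf_record with class "paf"
#' Build a PAF record collection
#'
#' @param records a list of [paf_record()] objects.
#' @return The list with class `"paf"`.
#' @export
as_paf <- function(records) {
  stopifnot(all(vapply(records, inherits, TRUE, "paf_record")))
  structure(records, class = "paf")
}

#' @export
`[.paf` <- function(x, i) as_paf(unclass(x)[i])

#' @export
print.paf <- function(x, n = 10L, ...) {
  cat("<paf> ", length(x), " alignment record(s)\n", sep = "")
  for (r in utils::head(x, n)) cat(" ", format_paf_record(r), "\n", sep = "")
  if (length(x) > n) cat("  ... and ", length(x) - n, " more\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.paf <- function(x, ...) {
  do.call(rbind, lapply(x, function(r) {
    data.frame(r[PAF_FIELDS], stringsAsFactors = FALSE)
  }))
}

## ---- parsing ---------------------------------------------------------------

parse_int <- function(x, what, ctx) {
  v <- suppressWarnings(as.integer(x))
  if (anyNA(v)) paf_error(ctx, "non-numeric ", what, ": '", x, "'")
  v
}

#' Parse one PAF line
#'
#' Splits the 12 mandatory tab-separated columns and any trailing SAM-style
#' typed tags. A `cg:Z:` tag is parsed into a [cigar()] (adjacent same-kind
#' runs merged) and checked against the coordinate spans.
#'
#' @param line a single PAF line (no trailing newline needed).
#' @param lineno optional line number used in error messages.
#' @return A [paf_record()].
#' @export
parse_paf_line <- function(line, lineno = NULL) {
  ctx <- if (is.null(lineno)) "PAF" else paste0("PAF line ", lineno)
  f <- strsplit(line, "\t", fixed = TRUE)[[1L]]
  if (length(f) < 12L) {
    paf_error(ctx, ": expected >= 12 tab-separated columns, got ", length(f))
  }
  tags <- list()
  cg <- NULL
  if (length(f) > 12L) {
    for (t in f[-(1:12)]) {
      m <- regmatches(t, regexec("^([A-Za-z][A-Za-z0-9]):([AifZHB]):(.*)$", t))[[1L]]
      if (length(m) != 4L) paf_error(ctx, ": malformed tag '", t, "'")
      if (m[2L] == "cg") {
        cg <- parse_cigar(m[4L])
        tags[["cg"]] <- list(type = "Z", value = NA_character_)
      } else {
        tags[[m[2L]]] <- list(type = m[3L], value = m[4L])
      }
    }
  }
  rec <- paf_record(
    qname = f[1L], qlen = parse_int(f[2L], "qlen", ctx),
    qstart = parse_int(f[3L], "qstart", ctx),
    qend = parse_int(f[4L], "qend", ctx),
    strand = f[5L],
    tname = f[6L], tlen = parse_int(f[7L], "tlen", ctx),
    tstart = parse_int(f[8L], "tstart", ctx),
    tend = parse_int(f[9L], "tend", ctx),
    nmatch = parse_int(f[10L], "nmatch", ctx),
    alnlen = parse_int(f[11L], "alnlen", ctx),
    mapq = parse_int(f[12L], "mapq", ctx),
    cg = cg, tags = tags, validate = FALSE
  )
  validate_paf_record(rec, where = ctx)
  rec
}

#' Serialize a PAF record to one line
#'
#' Mandatory columns first, then tags in their stored (input) order; the cg
#' tag is re-serialized from the record's current `cigar` object, so edits
#' made by trimming or splitting are reflected exactly.
#'
#' @param rec a [paf_record()].
#' @return A single tab-separated PAF line (character scalar).
#' @export
format_paf_record <- function(rec) {
  cols <- c(rec$qname, rec$qlen, rec$qstart, rec$qend, rec$strand,
            rec$tname, rec$tlen, rec$tstart, rec$tend,
            rec$nmatch, rec$alnlen, rec$mapq)
  tagstr <- character(0)
  nm <- names(rec$tags)
  for (k in seq_along(rec$tags)) {
    if (nm[k] == "cg") {
      tagstr <- c(tagstr, paste0("cg:Z:", format(rec$cigar)))
    } else {
      t <- rec$tags[[k]]
      tagstr <- c(tagstr, paste(nm[k], t$type, t$value, sep = ":"))
    }
  }
  # a cigar attached without a cg tag slot still gets emitted
  if (!is.null(rec$cigar) && !("cg" %in% nm)) {
    tagstr <- c(tagstr, paste0("cg:Z:", format(rec$cigar)))
  }
  paste(c(cols, tagstr), collapse = "\t")
}

#' Read a PAF file
#'
#' @param file a file path, `"-"` for standard input, or a connection.
#' @return A `"paf"` collection (possibly empty).
#' @export
read_paf <- function(file) {
  lines <- read_text_lines(file)
  lines <- lines[nzchar(lines)]
  recs <- vector("list", length(lines))
  for (i in seq_along(lines)) recs[[i]] <- parse_paf_line(lines[i], lineno = i)
  as_paf(recs)
}

#' Write PAF records
#'
#' @param records a `"paf"` collection or list of records.
#' @param file a path or connection (default standard output).
#' @return `records`, invisibly.
#' @export
write_paf <- function(records, file = stdout()) {
  lines <- vapply(records, format_paf_record, character(1))
  writeLines(lines, con = file)
  invisible(records)
}

# accept path, "-", or connection
read_text_lines <- function(file) {
  if (inherits(file, "connection")) return(readLines(file, warn = FALSE))
  if (identical(file, "-")) return(readLines(file("stdin"), warn = FALSE))
  readLines(file, warn = FALSE)
}

## ---- tag helpers -----------------------------------------------------------

#' Get or set a tag on a PAF record
#'
#' @param rec a [paf_record()].
#' @param name two-character tag name.
#' @param type SAM type code (set only).
#' @param value tag value as text (set only).
#' @return `paf_tag()` returns the tag value (character) or `NULL`;
#'   `set_paf_tag()` returns the modified record.
#' @export
paf_tag <- function(rec, name) {
  if (name == "cg" && !is.null(rec$cigar)) return(format(rec$cigar))
  t <- rec$tags[[name]]
  if (is.null(t)) NULL else t$value
}

#' @rdname paf_tag
#' @export
set_paf_tag <- function(rec, name, type, value) {
  rec$tags[[name]] <- list(type = type, value = as.character(value))
  rec
}

drop_paf_tag <- function(rec, name) {
  rec$tags[[name]] <- NULL
  rec
}

# drop a stale cs tag with a note; used after edits that cannot keep it
drop_cs_with_note <- function(rec, why) {
  if (!is.null(rec$tags[["cs"]])) {
    message("dropping cs tag (", why, ") on ", rec$qname, " -> ", rec$tname)
    rec <- drop_paf_tag(rec, "cs")
  }
  rec
}

## ---- BED -------------------------------------------------------------------

#' Read a BED file
#'
#' BED3+ with optional name in column 4; remaining columns are preserved
#' verbatim in `extra`. Lines starting with `#` are skipped. Coordinates are
#' 0-based half-open.
#'
#' @param file path, `"-"`, or connection.
#' @return A data frame with columns `chrom`, `start`, `end`, `name`, `extra`.
#' @export
read_bed <- function(file) {
  lines <- read_text_lines(file)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      name = character(), extra = character(),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  out <- data.frame(
    chrom = vapply(parts, `[`, "", 1L),
    start = NA_integer_, end = NA_integer_,
    name = vapply(parts, function(p) if (length(p) >= 4L) p[4L] else NA_character_, ""),
    extra = vapply(parts, function(p) {
      if (length(p) >= 5L) paste(p[-(1:4)], collapse = "\t") else ""
    }, ""),
    stringsAsFactors = FALSE
  )
  for (i in seq_along(parts)) {
    if (length(parts[[i]]) < 3L) {
      paf_error("BED line ", lineno[i], ": expected >= 3 columns")
    }
    s <- parse_int(parts[[i]][2L], "start", paste0("BED line ", lineno[i]))
    e <- parse_int(parts[[i]][3L], "end", paste0("BED line ", lineno[i]))
    if (s < 0L || s >= e) {
      paf_error("BED line ", lineno[i], ": need 0 <= start < end, got [",
                s, ",", e, ")")
    }
    out$start[i] <- s
    out$end[i] <- e
  }
  out
}
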