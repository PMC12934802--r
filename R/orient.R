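# Query-contig orientation and pseudo-scaffolding: flip contigs whose aligned
# bases are mostly reverse-complemented, and optionally merge the contigs of
# each target into one ordered pseudo-scaffold coordinate system.

#' Reorient query contigs to majority-forward
#'
#' Per query name, sums the query-consuming aligned bases (`=`, `X`, `I`; in
#' PAF terms simply `qend - qstart`) over `+` and `-` records. When the
#' reverse total strictly exceeds the forward total, every record of that
#' query is flipped with [flip_query_orientation()]. An exact tie keeps the
#' original orientation (determinism). Record order is preserved; the
#' operation is idempotent.
#'
#' @param records a `"paf"` collection.
#' @return A `"paf"` collection.
#' @export
orient <- function(records) {
  if (!length(records)) return(as_paf(list()))
  qn <- vapply(records, `[[`, character(1), "qname")
  span <- vapply(records, function(r) r$qend - r$qstart, integer(1))
  st <- vapply(records, `[[`, character(1), "strand")
  fwd <- rowsum(as.numeric(span * (st == "+")), qn)
  rev_ <- rowsum(as.numeric(span * (st == "-")), qn)
  flip <- rownames(fwd)[rev_[, 1L] > fwd[, 1L]]
  out <- lapply(records, function(r) {
    if (r$qname %in% flip) flip_query_orientation(r) else r
  })
  as_paf(out)
}

#' Merge query contigs into per-target pseudo-scaffolds
#'
#' First applies [orient()]. Each query contig is then assigned to the target
#' carrying most of its aligned bases, and the contigs of each target are laid
#' out into a single pseudo-scaffold named `"{tname}_scaffold"`, ordered by
#' minimum target start (ties: query name), with `gap` unaligned spacer bases
#' between consecutive contigs. Query coordinates are offset into the
#' scaffold, the scaffold length is the sum of contig lengths plus the gaps,
#' and the original query name is recorded in a `qn:Z:` tag. CIGARs and all
#' per-record identity statistics are untouched -- only names and coordinates
#' shift.
#'
#' @param records a `"paf"` collection.
#' @param gap spacer length in bases between consecutive contigs
#'   (default 1000).
#' @return A `"paf"` collection in the input record order.
#' @export
scaffold <- function(records, gap = 1000L) {
  recs <- orient(records)
  if (!length(recs)) return(recs)
  gap <- as.integer(gap)
  qn <- vapply(recs, `[[`, character(1), "qname")
  tn <- vapply(recs, `[[`, character(1), "tname")
  span <- vapply(recs, function(r) r$qend - r$qstart, integer(1))

  # assign each query wholly to the target with the most aligned bases
  key <- paste(qn, tn, sep = "\r")
  tot <- rowsum(as.numeric(span), key)
  kq <- sub("\r.*$", "", rownames(tot))
  kt <- sub("^.*\r", "", rownames(tot))
  assigned <- vapply(split(seq_along(kq), kq), function(ii) {
    best <- ii[order(-tot[ii, 1L], kt[ii])][1L]  # ties: lexicographic target
    kt[best]
  }, character(1))

  # order contigs within each scaffold by min tstart on the assigned target
  qlen_of <- vapply(recs, `[[`, integer(1), "qlen")
  offsets <- list()   # per qname: offset and scaffold qlen
  for (tgt in unique(assigned)) {
    contigs <- names(assigned)[assigned == tgt]
    first_ts <- vapply(contigs, function(q) {
      ii <- which(qn == q & tn == tgt)
      min(vapply(recs[ii], `[[`, integer(1), "tstart"))
    }, integer(1))
    ord <- contigs[order(first_ts, contigs)]
    lens <- vapply(ord, function(q) qlen_of[which(qn == q)[1L]], integer(1))
    total <- sum(lens) + gap * (length(ord) - 1L)
    off <- cumsum(c(0L, utils::head(lens + gap, -1L)))
    for (k in seq_along(ord)) {
      offsets[[ord[k]]] <- list(target = tgt, offset = off[k], qlen = total)
    }
  }

  out <- lapply(recs, function(r) {
    o <- offsets[[r$qname]]
    new <- r
    new$tags <- c(list(qn = list(type = "Z", value = r$qname)), r$tags)
    new$qname <- paste0(o$target, "_scaffold")
    new$qlen <- as.integer(o$qlen)
    new$qstart <- r$qstart + as.integer(o$offset)
    new$qend <- r$qend + as.integer(o$offset)
    validate_paf_record(new)
    new
  })
  as_paf(out)
}
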