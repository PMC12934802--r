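# Deterministic synthetic-alignment generator.
#
# Plants structural events (substitution noise, insertions, deletions,
# tandem duplications, inversions) on a toy target and emits the PAF records
# an aligner would produce for the corresponding query, together with a
# base-level truth map. Coordinates and CIGARs are generated directly from the
# event list -- no sequence is synthesized and no aligner is run -- which makes
# the truth exact: every planted substitution, indel base and duplicated or
# inverted block is known.
#
# Event semantics on the target axis:
#   SUBST_RATE            per-base substitution probability in plain regions
#   INSERTION(pos, len)   len query-only bases at target position pos
#   DELETION(pos, len)    target bases [pos, pos+len) absent from the query
#   TANDEM_DUP(pos, len)  target carries two adjacent copies [pos, pos+len)
#                         and [pos+len, pos+2*len) of a region the query has
#                         once; the single query copy aligns to both target
#                         copies via two records overlapping in query
#                         coordinates (the overlap-trimming scenario)
#   INVERSION(pos, len)   target region [pos, pos+len) aligns to the query in
#                         reverse orientation (a '-' strand record)

SV_KINDS <- c("SUBST_RATE", "INSERTION", "DELETION", "TANDEM_DUP", "INVERSION")

#' Specify a structural event for the simulator
#'
#' @param kind one of `"SUBST_RATE"`, `"INSERTION"`, `"DELETION"`,
#'   `"TANDEM_DUP"`, `"INVERSION"`.
#' @param pos target coordinate of the event (not used for `SUBST_RATE`).
#' @param len event length in bases (not used for `SUBST_RATE`). A tandem
#'   duplication occupies `2 * len` target bases (the two copies).
#' @param rate substitution probability in `[0, 1)` (only for `SUBST_RATE`).
#' @return A list with class `"sv_spec"`.
#' @export
sv_spec <- function(kind, pos = NA_integer_, len = NA_integer_, rate = NA_real_) {
  kind <- match.arg(kind, SV_KINDS)
  if (kind == "SUBST_RATE") {
    if (is.na(rate) || rate < 0 || rate >= 1) {
      paf_error("sv_spec: SUBST_RATE needs rate in [0, 1)")
    }
  } else {
    if (is.na(pos) || is.na(len) || pos < 0 || len < 1) {
      paf_error("sv_spec: ", kind, " needs pos >= 0 and len >= 1")
    }
  }
  structure(list(kind = kind, pos = as.integer(pos), len = as.integer(len),
                 rate = as.numeric(rate)), class = "sv_spec")
}

# target footprint [lo, hi) of a positional event
sv_footprint <- function(ev) {
  span <- switch(ev$kind,
                 INSERTION = 0L,
                 DELETION = ev$len,
                 TANDEM_DUP = 2L * ev$len,
                 INVERSION = ev$len)
  c(ev$pos, ev$pos + span)
}

#' Simulate an alignment with planted events
#'
#' Walks the target from 0 to `target_len`, emitting CIGAR operations for
#' plain regions (with substitutions planted at `SUBST_RATE`) and the
#' specified events. The alignment chain breaks at inversions (a separate
#' `-` strand record) and at tandem duplications (the second target copy
#' starts a new record re-using the same query bases, so the two records
#' overlap in query coordinates). Event footprints must not overlap and must
#' keep at least one plain target base between events and at both target ends,
#' so no record starts or ends in an indel.
#'
#' The generator is deterministic for a fixed seed; the caller's RNG state is
#' left untouched.
#'
#' @param target_len target length in bases.
#' @param svs list of [sv_spec()] events (at most one `SUBST_RATE`).
#' @param seed integer RNG seed (required).
#' @param qname,tname sequence names for the emitted records.
#' @return A list with elements `records` (a `"paf"` collection) and `truth`
#'   (a `"truth_map"`: homologous blocks, planted substitution positions, and
#'   the two sequence lengths).
#' @examples
#' sim <- simulate_alignment(1000, list(), seed = 1)
#' format(sim$records[[1]]$cigar)  # "1000="
#' @export
simulate_alignment <- function(target_len, svs = list(), seed,
                               qname = "qry", tname = "tgt") {
  target_len <- as.integer(target_len)
  if (missing(seed)) paf_error("simulate_alignment: seed is required")
  rate <- 0
  pos_evs <- list()
  for (ev in svs) {
    stopifnot(inherits(ev, "sv_spec"))
    if (ev$kind == "SUBST_RATE") {
      if (rate > 0) paf_error("simulate_alignment: multiple SUBST_RATE specs")
      rate <- ev$rate
    } else {
      pos_evs[[length(pos_evs) + 1L]] <- ev
    }
  }
  if (length(pos_evs)) {
    fp <- t(vapply(pos_evs, sv_footprint, integer(2)))
    ord <- order(fp[, 1L])
    pos_evs <- pos_evs[ord]
    fp <- fp[ord, , drop = FALSE]
    if (fp[1L, 1L] < 1L || fp[nrow(fp), 2L] > target_len - 1L) {
      paf_error("simulate_alignment: events must leave >= 1 plain base at both target ends")
    }
    if (nrow(fp) > 1L && any(fp[-1L, 1L] < fp[-nrow(fp), 2L] + 1L)) {
      paf_error("simulate_alignment: overlapping or adjacent event footprints")
    }
  }

  with_seed(seed, {
    st <- new.env(parent = emptyenv())
    st$tcur <- 0L
    st$qcur <- 0L
    st$records <- list()
    st$blocks <- list()   # (tstart, tend, qstart, orient)
    st$edits <- integer()
    st$ops <- character()
    st$lens <- integer()
    st$rec_t0 <- 0L
    st$rec_q0 <- 0L

    push_op <- function(op, len) {
      if (len > 0L) {
        st$ops <- c(st$ops, op)
        st$lens <- c(st$lens, len)
      }
    }
    open_rec <- function() {
      st$ops <- character()
      st$lens <- integer()
      st$rec_t0 <- st$tcur
      st$rec_q0 <- st$qcur
    }
    close_rec <- function() {
      if (length(st$ops)) {
        cg <- cigar(st$ops, st$lens)
        st$records[[length(st$records) + 1L]] <- paf_record(
          qname = qname, qlen = NA_integer_,
          qstart = st$rec_q0, qend = st$rec_q0 + cigar_query_consumed(cg),
          strand = "+",
          tname = tname, tlen = target_len,
          tstart = st$rec_t0, tend = st$rec_t0 + cigar_target_consumed(cg),
          cg = cg, validate = FALSE
        )
      }
      open_rec()
    }
    # plain co-linear region of n target bases, optionally with substitutions
    add_run <- function(n, with_subs = TRUE) {
      if (n <= 0L) return(invisible())
      sub_pos <- integer()
      if (with_subs && rate > 0) {
        k <- stats::rbinom(1L, n, rate)
        if (k > 0L) sub_pos <- sort(sample.int(n, k))
      }
      if (length(sub_pos)) {
        st$edits <- c(st$edits, st$tcur + sub_pos - 1L)
        # run lengths between substitution columns
        b <- c(0L, sub_pos, n + 1L)
        for (i in seq_along(sub_pos)) {
          push_op("=", sub_pos[i] - b[i] - 1L)
          push_op("X", 1L)
        }
        push_op("=", n - sub_pos[length(sub_pos)])
      } else {
        push_op("=", n)
      }
      st$blocks[[length(st$blocks) + 1L]] <-
        c(st$tcur, st$tcur + n, st$qcur, 1L)
      st$tcur <- st$tcur + n
      st$qcur <- st$qcur + n
    }

    for (ev in pos_evs) {
      add_run(ev$pos - st$tcur)
      if (ev$kind == "INSERTION") {
        push_op("I", ev$len)
        st$qcur <- st$qcur + ev$len
      } else if (ev$kind == "DELETION") {
        push_op("D", ev$len)
        st$tcur <- st$tcur + ev$len
      } else if (ev$kind == "TANDEM_DUP") {
        q0 <- st$qcur
        add_run(ev$len, with_subs = FALSE)   # copy 1, inside current record
        close_rec()
        st$qcur <- q0                        # copy 2 re-uses the same query bases
        open_rec()
        add_run(ev$len, with_subs = FALSE)
      } else if (ev$kind == "INVERSION") {
        close_rec()
        cg <- cigar("=", ev$len)
        st$records[[length(st$records) + 1L]] <- paf_record(
          qname = qname, qlen = NA_integer_,
          qstart = st$qcur, qend = st$qcur + ev$len, strand = "-",
          tname = tname, tlen = target_len,
          tstart = st$tcur, tend = st$tcur + ev$len,
          cg = cg, validate = FALSE
        )
        st$blocks[[length(st$blocks) + 1L]] <-
          c(st$tcur, st$tcur + ev$len, st$qcur, -1L)
        st$tcur <- st$tcur + ev$len
        st$qcur <- st$qcur + ev$len
        open_rec()
      }
    }
    add_run(target_len - st$tcur)
    close_rec()

    qlen <- st$qcur
    records <- lapply(st$records, function(r) {
      r$qlen <- qlen
      r$tags <- list(cg = list(type = "Z", value = NA_character_))
      validate_paf_record(r)
      r
    })
    blocks <- do.call(rbind, st$blocks)
    truth <- structure(list(
      blocks = data.frame(
        tstart = blocks[, 1L], tend = blocks[, 2L], qstart = blocks[, 3L],
        orient = ifelse(blocks[, 4L] > 0L, "+", "-"),
        stringsAsFactors = FALSE
      ),
      edits = st$edits,
      target_len = target_len, query_len = qlen
    ), class = "truth_map")
    list(records = as_paf(records), truth = truth)
  })
}

#' Expand a truth map to per-base pairs
#'
#' @param truth a `"truth_map"` from [simulate_alignment()].
#' @return A data frame with one row per homologous base pair: `tpos`, `qpos`
#'   (0-based) and `orient`.
#' @export
truth_pairs <- function(truth) {
  b <- truth$blocks
  n <- b$tend - b$tstart
  bi <- rep(seq_len(nrow(b)), n)
  within <- sequence(n) - 1L
  tpos <- b$tstart[bi] + within
  qpos <- ifelse(b$orient[bi] == "+",
                 b$qstart[bi] + within,
                 b$qstart[bi] + (n[bi] - 1L) - within)
  data.frame(tpos = as.integer(tpos), qpos = as.integer(qpos),
             orient = b$orient[bi], stringsAsFactors = FALSE)
}

#' @export
print.truth_map <- function(x, ...) {
  cat("<truth_map> ", nrow(x$blocks), " homologous block(s), ",
      length(x$edits), " planted substitution(s), target ", x$target_len,
      " bp, query ", x$query_len, " bp\n", sep = "")
  invisible(x)
}

#' Draw a random set of non-overlapping event specs
#'
#' Utility for generating randomized test scenarios: places `n_sv` events of
#' random kinds (insertion, deletion, tandem duplication, inversion) at
#' non-overlapping positions with at least one plain base between footprints,
#' plus one `SUBST_RATE` spec.
#'
#' @param target_len target length in bases.
#' @param n_sv number of positional events to attempt (placement failures at
#'   crowded targets reduce the realized count).
#' @param seed integer RNG seed.
#' @param max_event_len maximum event length in bases.
#' @param sub_rate substitution rate for the `SUBST_RATE` spec.
#' @return A list of [sv_spec()]s usable with [simulate_alignment()].
#' @export
random_sv_specs <- function(target_len, n_sv, seed, max_event_len = 10000L,
                            sub_rate = 0.01) {
  with_seed(seed, {
    taken <- matrix(numeric(0), ncol = 2L)
    specs <- list()
    kinds <- c("INSERTION", "DELETION", "TANDEM_DUP", "INVERSION")
    for (i in seq_len(n_sv)) {
      for (attempt in 1:50) {
        kind <- sample(kinds, 1L)
        len <- sample.int(max(1L, as.integer(max_event_len)), 1L)
        span <- switch(kind, INSERTION = 0L, TANDEM_DUP = 2L * len, len)
        if (span + 2L >= target_len) next
        pos <- sample.int(target_len - span - 2L, 1L)  # pos in [1, L-span-2]
        lo <- pos - 1L
        hi <- pos + span + 1L
        if (nrow(taken) && any(pmin(taken[, 2L], hi) > pmax(taken[, 1L], lo))) next
        taken <- rbind(taken, c(lo, hi))
        specs[[length(specs) + 1L]] <- sv_spec(kind, pos = pos, len = len)
        break
      }
    }
    if (sub_rate > 0) {
      specs[[length(specs) + 1L]] <- sv_spec("SUBST_RATE", rate = sub_rate)
    }
    specs
  })
}
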