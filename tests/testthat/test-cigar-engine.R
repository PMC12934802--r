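# Per-base projection, sub-alignment extraction, flipping and inversion

test_that("aligned_columns walks both strands and gaps correctly", {
  r <- paf_record("q", 10, 0, 3, "+", "t", 20, 10, 13, cg = "3=")
  expect_equal(aligned_columns(r),
               data.frame(tpos = 10:12, qpos = 0:2, kind = "="))
  rm <- paf_record("q", 10, 0, 3, "-", "t", 20, 10, 13, cg = "3=")
  expect_equal(aligned_columns(rm),
               data.frame(tpos = 10:12, qpos = 2:0, kind = "="))
  rd <- paf_record("q", 10, 0, 2, "+", "t", 10, 0, 3, cg = "1=1D1=")
  expect_equal(aligned_columns(rd),
               data.frame(tpos = 0:2, qpos = c(0L, NA, 1L),
                          kind = c("=", "D", "=")))
  # the minus-strand expansion describes the same pairs as the
  # reverse-complement mapping q' = qend - 1 - (tpos - tstart) on a 3-bp toy
  expect_equal(aligned_columns(rm)$qpos, rm$qend - 1L - (10:12 - rm$tstart))
})

test_that("column totals tie out against coordinate spans and gap bases", {
  for (seed in 1:30) {
    r <- random_record(seed, max_aligned = 300, max_indel = 200)
    cols <- aligned_columns(r)
    ev <- count_events(r$cigar)
    n_aligned <- sum(cols$kind %in% c("=", "X"))
    expect_equal(n_aligned, (r$qend - r$qstart) - ev$ins_bases)
    expect_equal(n_aligned, (r$tend - r$tstart) - ev$del_bases)
    expect_equal(sum(!is.na(cols$tpos)), r$tend - r$tstart)
    expect_equal(sum(!is.na(cols$qpos)), r$qend - r$qstart)
  }
})

test_that("sub-alignment extraction matches the worked examples", {
  r100 <- rec("100=", tstart = 0, qstart = 0)
  s <- subalignment_by_target(r100, 10, 20)
  expect_equal(c(s$tstart, s$tend, s$qstart, s$qend), c(10, 20, 10, 20))
  expect_equal(format(s$cigar), "10=")

  rdel <- paf_record("q", 100, 0, 100, "+", "t", 110, 0, 110, cg = "50=10D50=")
  s2 <- subalignment_by_target(rdel, 45, 65)
  expect_equal(format(s2$cigar), "5=10D5=")
  expect_equal(c(s2$tstart, s2$tend, s2$qstart, s2$qend), c(45, 65, 45, 55))

  rneg <- paf_record("q", 100, 0, 100, "-", "t", 100, 0, 100, cg = "100=")
  s3 <- subalignment_by_target(rneg, 10, 20)
  expect_equal(c(s3$qstart, s3$qend), c(80, 90))
  expect_equal(s3$strand, "-")
  expect_equal(format(s3$cigar), "10=")

  rins <- paf_record("q", 110, 0, 110, "+", "t", 100, 0, 100, cg = "50=10I50=")
  s4 <- subalignment_by_query(rins, 45, 65)
  expect_equal(format(s4$cigar), "5=10I5=")
  expect_equal(c(s4$qstart, s4$qend, s4$tstart, s4$tend), c(45, 65, 45, 55))
  s5 <- subalignment_by_query(rneg, 10, 20)
  expect_equal(c(s5$tstart, s5$tend), c(80, 90))

  # a window entirely inside a deletion has no aligned column
  expect_null(subalignment_by_target(rdel, 52, 58))
})

test_that("sub-alignments agree with the per-base oracle on random records", {
  set.seed(99)
  for (seed in 1:60) {
    r <- random_record(seed, max_aligned = 400, max_indel = 300)
    for (axis in c("target", "query")) {
      lo0 <- if (axis == "target") r$tstart else r$qstart
      hi0 <- if (axis == "target") r$tend else r$qend
      w <- sort(sample(lo0:hi0, 2))
      if (w[1] == w[2]) next
      got <- if (axis == "target") {
        subalignment_by_target(r, w[1], w[2])
      } else {
        subalignment_by_query(r, w[1], w[2])
      }
      want <- oracle_subalignment(r, w[1], w[2], axis)
      if (is.null(want)) {
        expect_null(got)
      } else {
        expect_equal(format(got$cigar), want$cg)
        expect_equal(c(got$tstart, got$tend, got$qstart, got$qend),
                     c(want$tstart, want$tend, want$qstart, want$qend))
        expect_silent(validate_paf_record(got))
        # no dangling indels
        n <- length(got$cigar$op)
        expect_true(got$cigar$op[1] %in% c("=", "X"))
        expect_true(got$cigar$op[n] %in% c("=", "X"))
      }
    }
  }
})

test_that("full-span extraction is the identity and composition commutes", {
  for (seed in 1:20) {
    r <- random_record(seed, max_aligned = 200, max_indel = 150)
    full <- subalignment_by_target(r, r$tstart, r$tend)
    expect_same_record(full, r)
    # sub by target then by query equals the direct sub on the intersection
    tw <- sort(sample(r$tstart:r$tend, 2))
    if (tw[1] == tw[2]) next
    s1 <- subalignment_by_target(r, tw[1], tw[2])
    if (is.null(s1)) next
    qw <- sort(sample(s1$qstart:s1$qend, 2))
    if (qw[1] == qw[2]) next
    s2 <- subalignment_by_query(s1, qw[1], qw[2])
    s3 <- oracle_subalignment(s1, qw[1], qw[2], "query")
    if (is.null(s2)) {
      expect_null(s3)
    } else {
      expect_equal(format(s2$cigar), s3$cg)
    }
  }
})

test_that("cs tags are cut in lock-step with the CIGAR", {
  for (seed in 1:10) {
    r <- random_record(seed, max_aligned = 60, max_indel = 30)
    r <- set_paf_tag(r, "cs", "Z", cigar_to_cs(r$cigar))
    w <- sort(sample(r$tstart:r$tend, 2))
    if (w[1] == w[2]) next
    s <- subalignment_by_target(r, w[1], w[2])
    if (is.null(s)) next
    expect_equal(format(cs_to_cigar(paf_tag(s, "cs"))), format(s$cigar))
  }
})

test_that("flip_query_orientation reflects coordinates and is an involution", {
  r <- paf_record("q", 100, 10, 30, "+", "t", 100, 0, 20, cg = "20=")
  f <- flip_query_orientation(r)
  expect_equal(f$strand, "-")
  expect_equal(c(f$qstart, f$qend), c(70, 90))
  expect_same_record(flip_query_orientation(f), r)
  # flipped record describes the same base pairs after reflecting query coords
  expect_error(  # guard: a dangling trailing D is invalid
    paf_record("q", 50, 5, 30, "-", "t", 60, 10, 35, cg = "10=5I10=5D"),
    "dangling")
  rneg <- paf_record("q", 50, 5, 30, "-", "t", 60, 10, 35, cg = "10=5I5D10=")
  f2 <- flip_query_orientation(rneg)
  a <- aligned_columns(rneg)
  b <- aligned_columns(f2)
  expect_equal(b$qpos, ifelse(is.na(a$qpos), NA_integer_, rneg$qlen - 1L - a$qpos))
  expect_equal(b$tpos, a$tpos)
})

test_that("invert_record swaps sides, maps I<->D and is an involution", {
  r <- rec("5=3I5=")
  inv <- invert_record(r)
  expect_equal(format(inv$cigar), "5=3D5=")
  expect_equal(c(inv$qname, inv$tname), c(r$tname, r$qname))
  expect_same_record(invert_record(inv), r)
  # identity record: inversion only swaps names
  rid <- rec("10=")
  expect_equal(format(invert_record(rid)$cigar), "10=")
  # per-base columns of the inverse are the column-swapped originals
  for (seed in 1:15) {
    rr <- random_record(seed, max_aligned = 100, max_indel = 60)
    ii <- invert_record(rr)
    expect_same_record(invert_record(ii), rr)
    a <- aligned_columns(rr)
    b <- aligned_columns(ii)
    a_sw <- data.frame(tpos = a$qpos, qpos = a$tpos,
                       kind = chartr("ID", "DI", a$kind))
    ord <- order(a_sw$tpos, na.last = NA)
    b_al <- b[!is.na(b$tpos), ]
    expect_equal(b_al$tpos, a_sw$tpos[ord])
    expect_equal(b_al$qpos, a_sw$qpos[ord])
    expect_equal(b_al$kind, a_sw$kind[ord])
  }
})
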