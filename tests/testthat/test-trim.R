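# Overlap detection and cumulative-score split resolution

test_that("find_query_overlaps enumerates intersecting pairs, largest first", {
  a <- rec("60=", qstart = 0, tstart = 0)
  b <- rec("60=", qstart = 40, tstart = 100)
  ov <- find_query_overlaps(list(a, b))
  expect_equal(unlist(ov[1, c("olo", "ohi")], use.names = FALSE), c(40, 60))
  expect_equal(nrow(find_query_overlaps(list(a, rec("20=", qstart = 70)))), 0)
  # three mutually overlapping records: all pairs, brute-force checked
  recs <- list(rec("50=", qstart = 0), rec("50=", qstart = 20),
               rec("50=", qstart = 40))
  ov3 <- find_query_overlaps(recs)
  expect_equal(nrow(ov3), 3)
  brute <- t(combn(3, 2))
  expect_setequal(paste(ov3$li, ov3$ri), paste(brute[, 1], brute[, 2]))
  expect_true(all(diff(ov3$olen) <= 0))  # sorted descending
  # records on different query names never pair
  expect_equal(nrow(find_query_overlaps(list(a, rec("60=", qname = "other")))), 0)
})

test_that("best_split matches exhaustive search on the worked examples", {
  sch <- score_scheme()
  a <- rec("60=", qstart = 0, tstart = 0)
  b <- rec("60=", qstart = 40, tstart = 100)
  got <- best_split(a, b, 40, 60, sch)
  want <- oracle_best_split(a, b, 40, 60, sch)
  expect_equal(got$p, 40)  # constant total, leftmost tie-break
  expect_equal(got$score, want$score)

  a2 <- rec("50=10X", qstart = 0)
  got2 <- best_split(a2, b, 40, 60, sch)
  expect_equal(got2$p, 40)
  expect_equal(got2$score, oracle_best_split(a2, b, 40, 60, sch)$score)

  # A perfect in [40,50) and mismatching in [50,60); B the other way round
  a3 <- rec("50=10X", qstart = 0)
  b3 <- rec("10X50=", qstart = 40, tstart = 100)
  got3 <- best_split(a3, b3, 40, 60, sch)
  expect_equal(got3$p, 50)
  expect_equal(got3, oracle_best_split(a3, b3, 40, 60, sch))
})

test_that("deletion penalties are charged ahead of the next aligned base", {
  sch <- score_scheme()
  # left record carries a deletion inside the overlap: the D penalty moves
  # with the query position of the next aligned column, so both routes agree
  a <- rec("30=5D30=", qstart = 0)
  b <- rec("40=", qstart = 20, tstart = 200)
  got <- best_split(a, b, 20, 60, sch)
  expect_equal(got, oracle_best_split(a, b, 20, 60, sch))
})

test_that("trim_paf removes all query overlaps and is idempotent", {
  a <- rec("60=", qstart = 0, tstart = 0)
  b <- rec("60=", qstart = 40, tstart = 100)
  out <- trim_paf(as_paf(list(a, b)))
  expect_equal(c(out[[1]]$qstart, out[[1]]$qend), c(0, 40))
  expect_same_record(out[[2]], b)
  # already disjoint input is a fixed point
  out2 <- trim_paf(out)
  for (i in seq_along(out)) expect_same_record(out2[[i]], out[[i]])
})

test_that("containment is resolved by splits or by dropping the inner record", {
  # inner record mismatches everywhere: dropped, outer survives the overlap
  outer <- rec("100=", qstart = 0)
  inner <- rec("20X", qstart = 40, tstart = 300)
  out <- trim_paf(as_paf(list(outer, inner)))
  qn_spans <- lapply(out, function(r) c(r$qstart, r$qend))
  # no query base aligned twice
  covered <- unlist(lapply(out, function(r) seq(r$qstart, r$qend - 1L)))
  expect_equal(anyDuplicated(covered), 0L)
  # inner perfect, outer mismatching inside the overlap: inner keeps its span
  outer2 <- rec("40=20X40=", qstart = 0)
  inner2 <- rec("20=", qstart = 40, tstart = 300)
  out2 <- trim_paf(as_paf(list(outer2, inner2)))
  covered2 <- unlist(lapply(out2, function(r) seq(r$qstart, r$qend - 1L)))
  expect_equal(anyDuplicated(covered2), 0L)
  expect_true(any(vapply(out2, function(r) r$tstart == 300, TRUE)))
})

test_that("random duplication fixtures end up disjoint with truthful pairs", {
  for (seed in 1:15) {
    specs <- random_sv_specs(8000, 3, seed = seed, max_event_len = 400,
                             sub_rate = 0.02)
    sim <- simulate_alignment(8000, specs, seed = seed)
    out <- trim_paf(sim$records)
    # headline post-condition: per query, [qstart,qend) pairwise disjoint
    expect_equal(nrow(find_query_overlaps(out)), 0)
    for (r in out) expect_silent(validate_paf_record(r))
    # every retained aligned pair is present in the truth map
    tp <- truth_pairs(sim$truth)
    key <- paste(tp$tpos, tp$qpos)
    for (r in out) {
      cols <- aligned_columns(r)
      al <- cols[cols$kind %in% c("=", "X"), ]
      expect_true(all(paste(al$tpos, al$qpos) %in% key))
    }
    # idempotence
    out2 <- trim_paf(out)
    expect_equal(length(out2), length(out))
    for (i in seq_along(out)) expect_same_record(out2[[i]], out[[i]])
  }
})

test_that("two-record resolutions achieve the brute-force optimal score", {
  for (seed in 1:25) {
    set.seed(1000 + seed)
    ov_len <- sample(20:200, 1)
    left_extra <- sample(50:300, 1)
    right_extra <- sample(50:300, 1)
    mk <- function(qstart, n) {
      ops <- sample(c("=", "X"), n, replace = TRUE, prob = c(0.85, 0.15))
      rec(paste0(paste0(1, ops), collapse = ""), qstart = qstart,
          tstart = sample(1:500, 1), qlen = 2000)
    }
    a <- mk(0, left_extra + ov_len)
    b <- mk(left_extra, ov_len + right_extra)
    sch <- score_scheme()
    got <- best_split(a, b, left_extra, left_extra + ov_len, sch)
    want <- oracle_best_split(a, b, left_extra, left_extra + ov_len, sch)
    expect_equal(got$p, want$p)
    expect_equal(got$score, want$score)
  }
})
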