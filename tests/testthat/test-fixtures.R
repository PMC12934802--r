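# Synthetic-alignment generator and its truth map

test_that("a plain target yields one identity record and an identity truth", {
  sim <- simulate_alignment(1000, list(), seed = 1)
  expect_length(sim$records, 1)
  expect_equal(format(sim$records[[1]]$cigar), "1000=")
  tp <- truth_pairs(sim$truth)
  expect_equal(tp$qpos, tp$tpos)
  expect_true(all(tp$orient == "+"))
})

test_that("generation is deterministic in the seed", {
  specs <- random_sv_specs(10000, 4, seed = 42)
  sim1 <- simulate_alignment(10000, specs, seed = 42)
  sim2 <- simulate_alignment(10000, specs, seed = 42)
  expect_identical(lapply(sim1$records, format_paf_record),
                   lapply(sim2$records, format_paf_record))
  expect_identical(sim1$truth$edits, sim2$truth$edits)
  sim3 <- simulate_alignment(10000, specs, seed = 43)
  expect_false(identical(sim1$truth$edits, sim3$truth$edits))
})

test_that("tandem duplications create exactly the expected query overlap", {
  sim <- simulate_alignment(5000, list(sv_spec("TANDEM_DUP", pos = 2000,
                                               len = 200)), seed = 3)
  expect_gte(length(sim$records), 2)
  ov <- find_query_overlaps(sim$records)
  expect_equal(nrow(ov), 1)
  expect_equal(ov$ohi - ov$olo, 200)
  # both target copies map to the same query bases in the truth
  tp <- truth_pairs(sim$truth)
  dup_t1 <- tp$qpos[tp$tpos >= 2000 & tp$tpos < 2200]
  dup_t2 <- tp$qpos[tp$tpos >= 2200 & tp$tpos < 2400]
  expect_equal(dup_t1, dup_t2)
  # duplicated target bases are the only ones mapping to a multi-hit query base
  expect_equal(sort(unique(tp$tpos[duplicated(tp$qpos) |
                                     duplicated(tp$qpos, fromLast = TRUE)])),
               2000:2399)
})

test_that("inversions flip orientation exactly inside the inverted block", {
  sim <- simulate_alignment(4000, list(sv_spec("INVERSION", pos = 1500,
                                               len = 400)), seed = 4)
  st <- vapply(sim$records, `[[`, character(1), "strand")
  expect_equal(sum(st == "-"), 1)
  tp <- truth_pairs(sim$truth)
  expect_true(all(tp$orient[tp$tpos >= 1500 & tp$tpos < 1900] == "-"))
  expect_true(all(tp$orient[tp$tpos < 1500 | tp$tpos >= 1900] == "+"))
  inv <- sim$records[[which(st == "-")]]
  cols <- aligned_columns(inv)
  hom <- tp[tp$tpos >= 1500 & tp$tpos < 1900, ]
  expect_equal(cols$qpos, hom$qpos[order(hom$tpos)])
})

test_that("planted deletions produce the break-paf scenario by construction", {
  sim <- simulate_alignment(20000, list(sv_spec("DELETION", pos = 8000,
                                                len = 6000)), seed = 5)
  expect_length(sim$records, 1)
  cg <- sim$records[[1]]$cigar
  expect_true(any(cg$op == "D" & cg$len == 6000))
  segs <- break_on_indels(sim$records[[1]], 5000)
  expect_length(segs, 2)
})

test_that("realized substitutions equal the planted ledger and CIGAR X runs", {
  sim <- simulate_alignment(30000, list(sv_spec("SUBST_RATE", rate = 0.02)),
                            seed = 6)
  x_total <- sum(vapply(sim$records, function(r) {
    count_events(r$cigar)$mismatches
  }, integer(1)))
  expect_equal(x_total, length(sim$truth$edits))
  # each planted edit is an X column at its target position
  cols <- aligned_columns(sim$records[[1]])
  expect_equal(cols$tpos[cols$kind == "X"], sim$truth$edits)
})

test_that("invalid event lists are rejected", {
  expect_error(simulate_alignment(
    1000, list(sv_spec("DELETION", pos = 100, len = 50),
               sv_spec("INSERTION", pos = 120, len = 10)), seed = 1),
    "overlapping")
  expect_error(simulate_alignment(
    1000, list(sv_spec("INVERSION", pos = 900, len = 100)), seed = 1),
    "plain base")
  expect_error(sv_spec("SUBST_RATE", rate = 1.2), "rate")
  expect_error(simulate_alignment(1000, list()), "seed")
})

test_that("random_sv_specs places non-overlapping events inside the target", {
  for (seed in c(2, 9, 27)) {
    specs <- random_sv_specs(50000, 8, seed = seed)
    sim <- simulate_alignment(50000, specs, seed = seed)  # validates placement
    for (r in sim$records) expect_silent(validate_paf_record(r))
  }
})
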