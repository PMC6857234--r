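test_that("reciprocal deletion matching honors the inclusive 50% boundary", {
  ## overlap of 50 bp is exactly 50% of both 100 bp intervals
  m <- match_deletions(del_callset(100, 200), del_callset(150, 250, label = "truth"))
  expect_equal(c(m$tp, m$fp, m$fn), c(1, 0, 0))
  ## one bp less overlap fails
  m2 <- match_deletions(del_callset(100, 200), del_callset(151, 251, label = "truth"))
  expect_equal(c(m2$tp, m2$fp, m2$fn), c(0, 1, 1))
  ## disjoint intervals are FP and missed
  m3 <- match_deletions(del_callset(0, 100), del_callset(200, 300, label = "truth"))
  expect_equal(c(m3$tp, m3$fp, m3$fn), c(0, 1, 1))
  ## one-way mode requires the fraction on the call only
  m4 <- match_deletions(del_callset(100, 200), del_callset(0, 1000, label = "truth"),
                        reciprocal = FALSE)
  expect_equal(m4$tp, 1)
  expect_equal(match_deletions(del_callset(100, 200),
                               del_callset(0, 1000, label = "truth"))$tp, 0)
})

test_that("insertion window matching is inclusive at the window edge", {
  m <- match_insertions(ins_callset(1000), ins_callset(1100, label = "truth"))
  expect_equal(c(m$tp, m$fp, m$fn), c(1, 0, 0))
  m2 <- match_insertions(ins_callset(1000), ins_callset(1101, label = "truth"))
  expect_equal(c(m2$tp, m2$fp, m2$fn), c(0, 1, 1))
  ## records on different chromosomes never match
  m3 <- match_insertions(ins_callset(1000, chrom = "chr1"),
                         ins_callset(1000, chrom = "chr2", label = "truth"))
  expect_equal(m3$tp, 0)
})

test_that("category mismatch between call and truth sets errors", {
  expect_error(match_deletions(ins_callset(10), del_callset(0, 100)), "deletion")
  expect_error(match_insertions(del_callset(0, 100), ins_callset(10)), "insertion")
})

test_that("indexed matching equals the all-pairs brute force on random sets", {
  withr::with_seed(202, {
    for (rep in 1:25) {
      nc <- sample(1:300, 1); nt <- sample(1:300, 1)
      calls <- random_del_callset(nc, label = "c")
      truth <- random_del_callset(nt, label = "t")
      recip <- rep %% 2 == 0
      m <- match_deletions(calls, truth, reciprocal = recip)
      o <- brute_match_deletions(calls$records, truth$records, reciprocal = recip)
      expect_identical(m$call_labels$label == "TP", unname(o$call))
      expect_identical(m$truth_labels$detected, unname(o$truth))

      ic <- random_ins_callset(nc, label = "c")
      it <- random_ins_callset(nt, label = "t")
      mi <- match_insertions(ic, it)
      oi <- brute_match_insertions(ic$records, it$records)
      expect_identical(mi$call_labels$label == "TP", unname(oi$call))
      expect_identical(mi$truth_labels$detected, unname(oi$truth))
    }
  })
})

test_that("matching is symmetric and self-matching is perfect", {
  withr::with_seed(7, {
    a <- random_del_callset(150, label = "a")
    b <- random_del_callset(150, label = "b")
  })
  m_ab <- match_deletions(a, b)
  m_ba <- match_deletions(b, a)
  expect_identical(m_ab$call_labels$label == "TP", m_ba$truth_labels$detected)
  expect_identical(m_ab$truth_labels$detected, m_ba$call_labels$label == "TP")
  self <- compute_metrics(match_deletions(a, a))
  expect_equal(c(self$precision, self$recall, self$f1), c(1, 1, 1))
})

test_that("matches are monotone in the threshold parameters", {
  withr::with_seed(13, {
    calls <- random_del_callset(200, label = "c")
    truth <- random_del_callset(200, label = "t")
    ic <- random_ins_callset(200, label = "c")
    it <- random_ins_callset(200, label = "t")
  })
  tp_by_frac <- vapply(c(0.9, 0.7, 0.5, 0.3, 0.1),
                       function(f) match_deletions(calls, truth, min_frac = f)$tp,
                       numeric(1))
  expect_true(all(diff(tp_by_frac) >= 0))
  tp_by_win <- vapply(c(0, 50, 100, 500, 2000),
                      function(w) match_insertions(ic, it, window = w)$tp,
                      numeric(1))
  expect_true(all(diff(tp_by_win) >= 0))
})

test_that("metric arithmetic and degenerate cases", {
  m <- compute_metrics(list(tp = 8, fp = 2, fn = 2))
  expect_equal(c(m$precision, m$recall, m$f1), c(0.8, 0.8, 0.8))
  expect_false(m$degenerate)
  d <- compute_metrics(list(tp = 0, fp = 0, fn = 5))
  expect_equal(c(d$precision, d$recall, d$f1), c(0, 0, 0))
  expect_true(d$degenerate)
  perfect <- compute_metrics(list(tp = 3, fp = 0, fn = 0))
  expect_equal(perfect$f1, 1)
})

test_that("size stratification uses left-closed bins and conserves counts", {
  calls <- del_callset(c(0, 1000, 2000), c(100, 1100, 2099))   # svlen 100,100,99
  truth <- del_callset(c(0, 5000), c(100, 5400), label = "truth")
  m <- match_deletions(calls, truth)
  sb <- stratify_by_size(m, bins = c(30, 100, 500, 100000))
  ## svlen = 100 falls in the second bin, 99 in the first
  expect_equal(sum(sb$tp + sb$fp), 3)
  expect_equal(sb$fp[1], 1)                       # the 99 bp FP
  expect_equal(sb$tp[2] + sb$fp[2], 2)            # both 100 bp calls
  expect_equal(sum(sb$tp), m$tp)
  expect_equal(sum(sb$fp), m$fp)
  expect_equal(sum(sb$fn), m$fn)
  ## all records in one bin: bin metrics equal global metrics
  one <- stratify_by_size(m, bins = c(30, 100000))
  g <- compute_metrics(m)
  expect_equal(one$f1, g$f1)
  ## conservation on a larger random instance
  withr::with_seed(31, {
    mc <- match_deletions(random_del_callset(300, label = "c"),
                          random_del_callset(300, label = "t"))
  })
  sbr <- stratify_by_size(mc)
  expect_equal(c(sum(sbr$tp), sum(sbr$fp), sum(sbr$fn)), c(mc$tp, mc$fp, mc$fn))
})

test_that("repeat-region filtering matches a brute-force overlap scan", {
  cs <- del_callset(c(100, 300), c(200, 400))
  reps <- data.frame(chrom = "chr1", start = 150, end = 160)
  expect_equal(filter_repeat_regions(cs, reps)$records$start, 300L)
  ## empty repeat set is the identity
  expect_identical(filter_repeat_regions(cs, reps[0, ])$records, cs$records)
  ## insertions drop only when the point itself is covered
  ins <- ins_callset(c(155, 500))
  expect_equal(filter_repeat_regions(ins, reps)$records$start, 500L)
  withr::with_seed(99, {
    cs2 <- random_del_callset(200)
    w <- sample(10:500, 50, replace = TRUE)
    s <- sapply(w, function(wi) sample.int(1e6 - wi, 1) - 1L)
    reps2 <- data.frame(chrom = "chr1", start = s, end = s + w)
  })
  got <- filter_repeat_regions(cs2, reps2)$records$start
  keep <- vapply(seq_len(nrow(cs2$records)), function(i) {
    !any(cs2$records$start[i] < reps2$end & reps2$start < cs2$records$end[i])
  }, logical(1))
  expect_equal(got, cs2$records$start[keep])
})

test_that("pairwise overlap counts: diagonal, disjoint sets, and oracle", {
  a <- del_callset(c(0, 1000), c(100, 1100), label = "a")
  b <- del_callset(c(5000, 7000), c(5100, 7100), label = "b")
  m <- pairwise_overlap_counts(list(a, b), "deletion")
  expect_equal(diag(m), c(a = 2L, b = 2L))
  expect_equal(m["a", "b"], 0L)
  withr::with_seed(55, {
    sets <- lapply(c("x", "y", "z"), function(l) random_del_callset(80, label = l))
  })
  got <- pairwise_overlap_counts(sets, "deletion")
  for (i in 1:3) for (j in 1:3) {
    o <- brute_match_deletions(sets[[i]]$records, sets[[j]]$records)
    expect_equal(unname(got[i, j]), sum(o$call))
  }
})
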