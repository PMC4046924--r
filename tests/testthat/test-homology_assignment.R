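test_that("best hit per query maximises bit score with deterministic tie-breaks", {
  h <- hits(
    hit("t1", "g1", evalue = 1e-50, bits = 500),
    hit("t1", "g2", evalue = 1e-60, bits = 400)
  )
  expect_equal(best_hit_per_query(h)$subject_id, "g1")

  # equal bit scores: smaller e-value wins
  h2 <- hits(
    hit("t1", "g1", evalue = 1e-50, bits = 500),
    hit("t1", "g2", evalue = 1e-60, bits = 500)
  )
  expect_equal(best_hit_per_query(h2)$subject_id, "g2")

  # full tie: lexicographically smallest subject ("g10" < "g2")
  h3 <- hits(
    hit("t1", "g2", evalue = 1e-50, bits = 500),
    hit("t1", "g10", evalue = 1e-50, bits = 500)
  )
  expect_equal(best_hit_per_query(h3)$subject_id, "g10")

  expect_equal(nrow(best_hit_per_query(h[0, ])), 0L)
})

test_that("reciprocal best hits require agreement in both directions", {
  fwd <- hits(hit("t1", "g1"), hit("t2", "g1", bits = 50))
  rev1 <- hits(hit("g1", "t1"))
  rbb <- reciprocal_best_hits(fwd, rev1)
  expect_equal(rbb$transcript_id, "t1")
  expect_equal(rbb$gene_id, "g1")

  # gene's best points elsewhere: no pair
  rev2 <- hits(hit("g1", "t9"))
  expect_equal(nrow(reciprocal_best_hits(fwd, rev2)), 0L)

  # gene monogamy: one pair even when two transcripts prefer the gene
  fwd3 <- hits(hit("t1", "g1", bits = 500), hit("t2", "g1", bits = 400))
  rbb3 <- reciprocal_best_hits(fwd3, rev1)
  expect_equal(nrow(rbb3), 1L)
  expect_equal(rbb3$transcript_id, "t1")
})

test_that("reciprocal best hits are symmetric under role swap", {
  set.seed(7)
  fwd <- hit(
    sprintf("t%02d", sample.int(30, 60, replace = TRUE)),
    sprintf("g%02d", sample.int(20, 60, replace = TRUE)),
    evalue = 10^-runif(60, 5, 100), bits = round(runif(60, 50, 500))
  )
  rev <- hit(
    sprintf("g%02d", sample.int(20, 60, replace = TRUE)),
    sprintf("t%02d", sample.int(30, 60, replace = TRUE)),
    evalue = 10^-runif(60, 5, 100), bits = round(runif(60, 50, 500))
  )
  ab <- reciprocal_best_hits(fwd, rev)
  ba <- reciprocal_best_hits(rev, fwd)
  expect_setequal(
    paste(ab$transcript_id, ab$gene_id),
    paste(ba$gene_id, ba$transcript_id)
  )
})

test_that("length binning applies the nearest-rank percentile and floors zeros", {
  pairs <- data.frame(
    transcript_id = paste0("t", 1:4), gene_id = paste0("g", 1:4),
    fwd_evalue = c(1e-50, 1e-40, 1e-30, 1e-20),
    fwd_bit_score = c(400, 300, 200, 100),
    query_length = c(100, 200, 300, 400)
  )
  b <- suppressWarnings(
    bin_rbb_by_length(pairs, n_bins = 1, percentile = 25, min_per_bin = 1)
  )
  expect_equal(b$percentile_evalue, 1e-50) # rank ceil(0.25*4) = 1
  expect_equal(b$n_hits, 4L)

  pairs0 <- transform(pairs, fwd_evalue = 0)
  b0 <- suppressWarnings(bin_rbb_by_length(pairs0,
    n_bins = 1, percentile = 50,
    evalue_floor = 1e-180, min_per_bin = 1
  ))
  expect_equal(b0$log10_percentile, -180)

  # equal-count binning: 100 pairs over 4 bins of 25
  pairs100 <- data.frame(
    transcript_id = sprintf("t%03d", 1:100), gene_id = sprintf("g%03d", 1:100),
    fwd_evalue = 10^-(1:100), fwd_bit_score = 1:100,
    query_length = seq(100, 1090, by = 10)
  )
  b4 <- bin_rbb_by_length(pairs100, n_bins = 4, min_per_bin = 20)
  expect_equal(b4$n_hits, rep(25L, 4))
  expect_true(all(b4$length_min <= b4$representative_length &
    b4$representative_length <= b4$length_max))

  expect_error(bin_rbb_by_length(pairs[0, ]), "no reciprocal best hits")
})

test_that("quadratic fit interpolates three points exactly and falls back to constants", {
  b3 <- data.frame(
    bin_index = 1:3, length_min = c(90, 190, 290), length_max = c(110, 210, 310),
    representative_length = c(100, 200, 300), n_hits = 10,
    percentile_evalue = 10^c(-10, -30, -60),
    log10_percentile = c(-10, -30, -60)
  )
  cv <- fit_threshold_curve(b3, percentile = 1, evalue_floor = 1e-180)
  expect_equal(cv$a, -5e-4, tolerance = 1e-8)
  expect_equal(cv$b, -0.05, tolerance = 1e-8)
  expect_equal(cv$c, 0, tolerance = 1e-8)

  # all bins at the same value: constant curve
  bflat <- transform(b3, log10_percentile = -25)
  cvf <- fit_threshold_curve(bflat, percentile = 1, evalue_floor = 1e-180)
  expect_equal(c(cvf$a, cvf$b, cvf$c), c(0, 0, -25))

  # two bins: constant fallback
  cv2 <- fit_threshold_curve(b3[1:2, ], percentile = 1, evalue_floor = 1e-180)
  expect_equal(c(cv2$a, cv2$b), c(0, 0))
  expect_equal(cv2$c, -20)

  expect_error(fit_threshold_curve(b3[0, ]), "no bins")
})

test_that("percentile points on a planted quadratic are recovered to 1e-8", {
  L <- seq(200, 2900, length.out = 12)
  planted <- c(a = -5e-6, b = -0.04, c = -10)
  bins <- data.frame(
    bin_index = seq_along(L), length_min = L - 50, length_max = L + 50,
    representative_length = L, n_hits = 30,
    percentile_evalue = NA,
    log10_percentile = planted["a"] * L^2 + planted["b"] * L + planted["c"]
  )
  cv <- fit_threshold_curve(bins, percentile = 50, evalue_floor = 1e-180)
  expect_equal(cv$a, unname(planted["a"]), tolerance = 1e-8)
  expect_equal(cv$b, unname(planted["b"]), tolerance = 1e-8)
  expect_equal(cv$c, unname(planted["c"]), tolerance = 1e-8)
})

test_that("hits are accepted when at least as significant as the curve", {
  cv <- threshold_curve(-5e-4, -0.05, 0, domain_min = 100, domain_max = 300)
  rbb0 <- data.frame(transcript_id = character(0), gene_id = character(0))
  # curve(200) = -30
  acc <- classify_nonrbb_hits(hit("t1", "g1", evalue = 1e-40, qlen = 200), rbb0, cv)
  expect_equal(nrow(acc), 1L)
  rej <- classify_nonrbb_hits(hit("t1", "g1", evalue = 1e-20, qlen = 200), rbb0, cv)
  expect_equal(nrow(rej), 0L)
  # exactly on the curve: accepted
  on <- classify_nonrbb_hits(hit("t1", "g1", evalue = 1e-30, qlen = 200), rbb0, cv)
  expect_equal(nrow(on), 1L)
  # RBB members are excluded from this pass
  rbb1 <- data.frame(transcript_id = "t1", gene_id = "g1")
  expect_equal(nrow(classify_nonrbb_hits(
    hit("t1", "g1", evalue = 1e-40, qlen = 200), rbb1, cv
  )), 0L)
  expect_error(
    classify_nonrbb_hits(hit("tX", "g1", evalue = 1e-40, qlen = NA), rbb0, cv),
    "tX"
  )
})

test_that("curve evaluation clamps lengths to the fitted domain", {
  cv <- threshold_curve(-5e-4, -0.05, 0, domain_min = 100, domain_max = 300)
  expect_equal(predict(cv, c(50, 100)), rep(predict(cv, 100), 2))
  expect_equal(predict(cv, 1e5), predict(cv, 300))
})

test_that("the homology map composes RBB and conditional assignments", {
  lengths <- c(t1 = 200, t2 = 200, t3 = 200, t4 = 200)
  fwd <- hits(
    hit("t1", "g1", evalue = 1e-80, bits = 500, qlen = 200),
    hit("t2", "g2", evalue = 1e-70, bits = 450, qlen = 200),
    # non-RBB transcript with two acceptable hits: best bit score wins
    hit("t3", "g1", evalue = 1e-75, bits = 500, qlen = 200),
    hit("t3", "g2", evalue = 1e-72, bits = 450, qlen = 200),
    # non-RBB transcript whose only hit is far above the threshold
    hit("t4", "g2", evalue = 1e-2, bits = 40, qlen = 200)
  )
  rev <- hits(
    hit("g1", "t1", evalue = 1e-80, bits = 500),
    hit("g2", "t2", evalue = 1e-70, bits = 450)
  )
  map <- suppressWarnings(build_homology_map(fwd, rev,
    lengths = lengths,
    n_bins = 1, percentile = 100, min_per_bin = 1
  ))
  expect_equal(sum(map$method == "rbb"), 2L)
  expect_equal(sum(map$method == "conditional"), 1L)
  expect_equal(map$gene_id[map$transcript_id == "t3"], "g1")
  expect_false("t4" %in% map$transcript_id)
  # RBB assignments are never overwritten by conditional ones
  expect_equal(map$method[map$transcript_id %in% c("t1", "t2")], rep("rbb", 2))
})

test_that("lowering the percentile never enlarges the accepted set", {
  sim <- simulate_homology_truth(n_genes = 120, seed = 5)
  rbb <- reciprocal_best_hits(sim$forward, sim$reverse)
  prev <- NULL
  for (p in c(99, 75, 50, 25, 5)) {
    bins <- suppressWarnings(
      bin_rbb_by_length(rbb, sim$lengths, n_bins = 5, percentile = p)
    )
    acc <- classify_nonrbb_hits(
      sim$forward, rbb, fit_threshold_curve(bins)
    )
    keys <- paste(acc$query_id, acc$subject_id)
    if (!is.null(prev)) expect_true(all(keys %in% prev))
    prev <- keys
  }
})

test_that("a constant curve equals a plain global e-value cutoff", {
  sim <- simulate_homology_truth(n_genes = 80, decoy_rate = 0.3, seed = 9)
  rbb <- reciprocal_best_hits(sim$forward, sim$reverse)
  bins <- suppressWarnings(
    bin_rbb_by_length(rbb, sim$lengths, n_bins = 1, percentile = 50)
  )
  cv <- fit_threshold_curve(bins)
  acc <- classify_nonrbb_hits(sim$forward, rbb, cv)
  # brute-force baseline: fixed cutoff at the same threshold
  pool <- sim$forward[!(sim$forward$query_id %in% rbb$transcript_id), ]
  cutoff <- pool[log10(pmax(pool$evalue, 1e-180)) <= cv$c, ]
  expect_setequal(
    paste(acc$query_id, acc$subject_id, acc$evalue),
    paste(cutoff$query_id, cutoff$subject_id, cutoff$evalue)
  )
})

test_that("assignment evaluation computes precision, recall and F1", {
  truth <- stats::setNames(paste0("g", 1:10), paste0("t", 1:10))
  perfect <- data.frame(
    transcript_id = names(truth), gene_id = unname(truth),
    method = "rbb", evalue = 0, bit_score = 1
  )
  expect_equal(unname(evaluate_assignment(perfect, truth)), c(1, 1, 1))
  empty <- perfect[0, ]
  expect_equal(unname(evaluate_assignment(empty, truth)), c(0, 0, 0))
  # 8 assignments, 6 correct, 10 truths
  partial <- perfect[1:8, ]
  partial$gene_id[7:8] <- "wrong"
  got <- evaluate_assignment(partial, truth)
  expect_equal(unname(got["precision"]), 0.75)
  expect_equal(unname(got["recall"]), 0.6)
  expect_equal(unname(got["f1"]), 2 * 0.75 * 0.6 / 1.35)
})
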