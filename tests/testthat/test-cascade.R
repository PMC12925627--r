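# each cascade rule exercised on crafted candidate sets with hand-derived
# expected removals

test_that("rule 1 keeps only the top candidates by combined score", {
  calls <- do.call(rbind, lapply(1:60, function(i) {
    make_call(contig = sprintf("c%02d", i), combined = 3 - i * 0.01)
  }))
  out <- filter_cascade(calls)
  expect_equal(sum(out$status == "removed:top50"), 10L)
  expect_true(all(out$status[1:50] != "removed:top50"))
  expect_true(all(out$status[51:60] == "removed:top50"))
})

test_that("rule 2 removes lengths far from the top-5 median", {
  # top 5 by score have lengths 80,82,85,88,90 -> median 85; |len-85| > 30
  lens <- c(80L, 82L, 85L, 88L, 90L, 120L, 50L, 116L, 54L)
  scores <- c(3, 2.9, 2.8, 2.7, 2.6, 2.5, 2.4, 2.3, 2.2)
  calls <- do.call(rbind, lapply(seq_along(lens), function(i) {
    make_call(contig = sprintf("c%02d", i), cdeii_length = lens[i],
              combined = scores[i])
  }))
  out <- filter_cascade(calls)
  expect_equal(out$status[6], "removed:cdeii_length") # 120 - 85 = 35 > 30
  expect_equal(out$status[7], "removed:cdeii_length") # 85 - 50 = 35 > 30
  expect_equal(out$status[8], "removed:cdeii_length") # 116 - 85 = 31 > 30
  expect_equal(out$status[9], "removed:cdeii_length") # |54 - 85| = 31 > 30
})

test_that("rule 2 boundary is exactly 30 nucleotides", {
  lens <- c(85L, 85L, 85L, 85L, 85L, 115L, 116L, 55L, 54L)
  calls <- do.call(rbind, lapply(seq_along(lens), function(i) {
    make_call(contig = sprintf("c%02d", i), cdeii_length = lens[i],
              combined = 3 - 0.01 * i)
  }))
  out <- filter_cascade(calls)
  expect_equal(out$status[6], "retained")             # |115-85| = 30, kept
  expect_equal(out$status[7], "removed:cdeii_length") # 31 > 30
  expect_equal(out$status[8], "retained")             # 30
  expect_equal(out$status[9], "removed:cdeii_length") # 31
})

test_that("rule 3 removes AT-poor candidates at the 70% cutoff", {
  ats <- c(95, 85, 70, 69.9, 40)
  calls <- do.call(rbind, lapply(seq_along(ats), function(i) {
    make_call(contig = sprintf("c%02d", i), cdeii_at = ats[i],
              combined = 3 - 0.01 * i)
  }))
  out <- filter_cascade(calls)
  expect_equal(out$status, c("retained", "retained", "retained",
                             "removed:at_content", "removed:at_content"))
})

test_that("rule 4 removes duplicates, keeping the better call", {
  # byte-identical full sequences on different contigs
  a <- make_call(contig = "cA", full_seq = "SAMESEQ", combined = 2.9)
  b <- make_call(contig = "cB", full_seq = "SAMESEQ", combined = 2.5)
  # >50% overlapping span on the same contig and strand
  c1 <- make_call(contig = "cC", start = 1000L, combined = 2.8,
                  full_seq = "X1")
  c2 <- make_call(contig = "cC", start = 1040L, combined = 2.7,
                  full_seq = "X2")
  # distinct calls on the same contig, far apart
  d <- make_call(contig = "cC", start = 5000L, combined = 2.6,
                 full_seq = "X3")
  out <- filter_cascade(rbind(a, b, c1, c2, d))
  expect_equal(out$status, c("retained", "removed:duplicate", "retained",
                             "removed:duplicate", "retained"))

  # score tie: the lexicographically smaller (contig, start) survives
  t1 <- make_call(contig = "cB", start = 50L, full_seq = "T", combined = 2.5)
  t2 <- make_call(contig = "cA", start = 90L, full_seq = "T", combined = 2.5)
  out2 <- filter_cascade(rbind(t1, t2))
  expect_equal(out2$status, c("removed:duplicate", "retained"))
})

test_that("rule 5 requires BOTH length and AT deviation (strict AND)", {
  base <- lapply(1:9, function(i) {
    make_call(contig = sprintf("c%02d", i), cdeii_length = 85L,
              cdeii_at = 95, combined = 2.9)
  })
  # survivors' medians: length 85, AT 95
  dev_len_only <- make_call(contig = "d1", cdeii_length = 97L, cdeii_at = 93,
                            combined = 2.8) # |97-85| = 12 > 10, AT fine
  dev_at_only <- make_call(contig = "d2", cdeii_length = 86L, cdeii_at = 80,
                           combined = 2.8) # AT < 95-7 = 88, length fine
  dev_both <- make_call(contig = "d3", cdeii_length = 97L, cdeii_at = 80,
                        combined = 2.8)
  out <- filter_cascade(do.call(rbind, c(base, list(dev_len_only, dev_at_only,
                                                    dev_both))))
  expect_equal(out$status[10], "retained")
  expect_equal(out$status[11], "retained")
  expect_equal(out$status[12], "removed:joint_length_at")
})

test_that("retained calls violate no rule on independent re-check", {
  set.seed(21)
  calls <- do.call(rbind, lapply(1:70, function(i) {
    make_call(contig = sprintf("c%02d", i %% 23), start = 1000L * i,
              cdeii_length = sample(c(50L, 85L, 90L, 140L), 1),
              cdeii_at = runif(1, 40, 100), combined = runif(1, 1, 3),
              full_seq = sample(c(paste0("S", i), "DUPSEQ"), 1,
                                prob = c(0.9, 0.1)))
  }))
  out <- filter_cascade(calls)
  ret <- out[out$status == "retained", ]
  expect_gt(nrow(ret), 0)
  # rank within top 50
  expect_true(all(rank(-out$combined_score)[out$status == "retained"] <= 50))
  # AT cutoff
  expect_true(all(ret$cdeii_at >= 70))
  # joint rule
  med_len <- median(ret$cdeii_length); med_at <- median(ret$cdeii_at)
  expect_false(any(abs(ret$cdeii_length - med_len) > 10 &
                     ret$cdeii_at < med_at - 7))
  # no duplicate full sequences
  expect_false(any(duplicated(ret$full_seq)))
  # empty input passes through
  expect_equal(nrow(filter_cascade(calls[0, ])), 0L)
})

test_that("planted truths pass and AT-poor decoys are removed by name", {
  truths <- lapply(1:16, function(i) {
    make_call(contig = sprintf("t%02d", i), cdeii_length = 85L,
              cdeii_at = 95, combined = 2.9)
  })
  decoys <- lapply(1:40, function(i) {
    make_call(contig = sprintf("d%02d", i), cdeii_length = 85L,
              cdeii_at = 55, combined = 2.0)
  })
  out <- filter_cascade(do.call(rbind, c(truths, decoys)))
  expect_true(all(out$status[1:16] == "retained"))
  expect_true(all(out$status[17:56] %in%
                    c("removed:at_content", "removed:top50")))
  expect_equal(sum(out$status == "removed:top50"), 6L)
  expect_equal(sum(out$status == "removed:at_content"), 34L)
})
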