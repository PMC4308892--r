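test_that("target_window returns the transcript-sense pairing partner", {
  targets <- sequence_library("T1", "AAAAACGTACGTACGTACGTAAAAA")
  # forward hit covering ACGT at offset 5 (0-based), length 4
  hit <- data.frame(query_id = "q", target_id = "T1", offset = 5L,
                    strand = "+", mismatches = 0L)
  win <- target_window(hit, targets, query_length = 4L)
  expect_equal(win$seq, to_rna(revcomp(substr(targets$seq, 6, 9))))

  # flank clipped at the target start
  hit2 <- data.frame(query_id = "q", target_id = "T1", offset = 2L,
                     strand = "+", mismatches = 0L)
  win2 <- target_window(hit2, targets, query_length = 4L, flank = 5L)
  expect_equal(nchar(win2$seq), 4L + 2L + 5L)   # left flank clipped to 2
  expect_equal(win2$right_clip, 2L)             # revcomp flips the clipped side

  # interior hit: window length = query + both flanks
  hit3 <- data.frame(query_id = "q", target_id = "T1", offset = 10L,
                     strand = "-", mismatches = 0L)
  win3 <- target_window(hit3, targets, query_length = 5L, flank = 3L)
  expect_equal(nchar(win3$seq), 5L + 3L + 3L)

  expect_error(target_window(data.frame(query_id = "q", target_id = "T1",
                                        offset = 23L, strand = "+",
                                        mismatches = 0L),
                             targets, query_length = 4L), "out of bounds")
})

test_that("predict_duplex handles the forced cases", {
  d <- predict_duplex("GGGGGGGGGG", "CCCCCCCCCC")
  expect_equal(d$query_struct, "((((((((((")
  expect_equal(d$target_struct, "))))))))))")
  expect_equal(nrow(d$pairs), 10L)

  d0 <- predict_duplex("AAAA", "AAAA")
  expect_equal(d0$query_struct, "....")
  expect_equal(d0$target_struct, "....")
  expect_equal(nrow(d0$pairs), 0L)
  expect_equal(d0$energy, 0)

  expect_error(predict_duplex("ACGNU", "ACGUA"), "N")
})

test_that("duplex structures satisfy their invariants", {
  qs <- random_library(20, 15, 25, seed = 61)
  ws <- random_library(20, 15, 25, seed = 62)
  wc <- c(A = "U", C = "G", G = "C", U = "A")
  for (i in 1:20) {
    d <- predict_duplex(to_rna(qs$seq[i]), to_rna(ws$seq[i]))
    expect_equal(nchar(d$query_struct), nchar(qs$seq[i]))
    expect_equal(nchar(d$target_struct), nchar(ws$seq[i]))
    n_open <- lengths(regmatches(d$query_struct, gregexpr("(", d$query_struct, fixed = TRUE)))
    n_close <- lengths(regmatches(d$target_struct, gregexpr(")", d$target_struct, fixed = TRUE)))
    expect_equal(unname(n_open), nrow(d$pairs))
    expect_equal(unname(n_close), nrow(d$pairs))
    if (nrow(d$pairs) > 1) {
      # antiparallel non-crossing: target positions decrease as query increases
      o <- order(d$pairs[, 1])
      expect_true(all(diff(d$pairs[o, 2]) < 0))
    }
    # every pair is WC or wobble
    if (nrow(d$pairs) > 0) {
      qn <- strsplit(d$query_seq, "")[[1]][d$pairs[, 1] + 1]
      tn <- strsplit(d$target_seq, "")[[1]][d$pairs[, 2] + 1]
      ok <- (wc[qn] == tn) | (qn == "G" & tn == "U") | (qn == "U" & tn == "G")
      expect_true(all(ok))
    }
  }
})

test_that("DP optimum matches exhaustive matching enumeration on 8-mers", {
  qs <- random_library(50, 8, 8, seed = 63)
  ws <- random_library(50, 8, 8, seed = 64)
  for (i in 1:50) {
    d <- predict_duplex(to_rna(qs$seq[i]), to_rna(ws$seq[i]))
    oracle <- brute_duplex(qs$seq[i], ws$seq[i])
    expect_equal(d$score, oracle$score, info = paste("case", i))
    expect_true(nrow(d$pairs) %in% oracle$npairs, info = paste("case", i))
  }
})

test_that("an exact hit yields a near-perfect duplex and mismatches never help", {
  reads <- random_library(10, 24, 30, seed = 65)
  for (i in 1:10) {
    q <- to_rna(reads$seq[i])
    d <- predict_duplex(q, to_rna(revcomp(reads$seq[i])))
    expect_gte(nrow(d$pairs) / nchar(q), 0.9)

    # degrade the window at 3 positions: optimal pair count cannot increase
    w <- strsplit(revcomp(reads$seq[i]), "")[[1]]
    withr::with_seed(100 + i, {
      pos <- sample(length(w), 3)
      for (p in pos) w[p] <- sample(setdiff(c("A", "C", "G", "T"), w[p]), 1)
    })
    d2 <- predict_duplex(q, to_rna(paste(w, collapse = "")))
    expect_lte(nrow(d2$pairs), nrow(d$pairs))
  }
})

test_that("best_duplex applies the mismatch/energy/lexicographic rule", {
  targets <- random_library(4, 300, 300, seed = 66, prefix = "T")
  idx <- build_index(targets)
  q <- list(id = "q", seq = substr(targets$seq[3], 50, 74))
  h <- align(q, idx)
  expect_gte(nrow(h), 1L)
  bd <- best_duplex(q, h, targets)
  expect_equal(bd$hit$mismatches, min(h$mismatches))

  # single hit -> that hit
  bd1 <- best_duplex(q, h[1, , drop = FALSE], targets)
  expect_equal(bd1$hit$target_id, h$target_id[1])

  # planted two-hit case: 0-mismatch hit wins over 3-mismatch hit
  base <- q$seq
  ch <- strsplit(base, "")[[1]]
  ch[c(5, 10, 15)] <- vapply(ch[c(5, 10, 15)],
                             function(b) setdiff(c("A", "C", "G", "T"), b)[1], "")
  t2 <- sequence_library(c("A1", "B2"),
                         c(paste0("CCCCC", paste(ch, collapse = ""), "CCCCC"),
                           paste0("GGGGG", base, "GGGGG")))
  h2 <- align(q, build_index(t2), strands = "forward")
  bd2 <- best_duplex(q, h2, t2)
  expect_equal(bd2$hit$target_id, "B2")
  expect_equal(bd2$hit$mismatches, 0L)

  # brute-force evaluation of the selection rule over all hits: h is already
  # in (target_id, offset, strand) order, and order() is stable, so ties fall
  # back to lexicographic hit order exactly as the rule requires
  energies <- vapply(seq_len(nrow(h)), function(i) {
    win <- target_window(h[i, ], targets, nchar(q$seq))
    predict_duplex(list(id = "q", seq = to_rna(q$seq)), win)$energy
  }, numeric(1))
  ord <- order(h$mismatches, energies)
  expect_equal(bd$hit$target_id, h$target_id[ord[1]])
  expect_equal(bd$hit$offset, h$offset[ord[1]])

  expect_error(best_duplex(q, h[0, ], targets), "not transposon-associated")
})
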