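test_that("stratified_partition balances both classes across folds", {
  d <- make_labeled_features(10, 10, seed = 91)
  sch <- stratified_partition(d, k = 10, seed = 92)
  for (p in 1:10) {
    idx <- which(sch$assignment == p)
    expect_equal(sum(d$labels[idx] == 1), 1L)
    expect_equal(sum(d$labels[idx] == -1), 1L)
  }

  # union of partitions is the dataset; per-class sizes differ by <= 1
  d2 <- make_labeled_features(97, 83, seed = 93)
  sch2 <- stratified_partition(d2, k = 10, seed = 94)
  expect_setequal(unique(sch2$assignment), 1:10)
  expect_length(sch2$assignment, 180L)
  for (cls in c(1, -1)) {
    sizes <- table(sch2$assignment[d2$labels == cls])
    expect_lte(diff(range(sizes)), 1)
  }

  # reproducible from seed
  sch3 <- stratified_partition(d2, k = 10, seed = 94)
  expect_identical(sch2$assignment, sch3$assignment)

  expect_error(stratified_partition(make_labeled_features(5, 20, seed = 95)),
               "fewer than k")
})

test_that("fold_roles rotates 7/2/1 disjointly and exhaustively", {
  d <- make_labeled_features(30, 30, seed = 96)
  sch <- stratified_partition(d, k = 10, seed = 97)
  for (r in 1:10) {
    roles <- fold_roles(sch, r)
    all_idx <- c(roles$train, roles$validation, roles$test)
    expect_setequal(all_idx, seq_len(60))
    expect_length(all_idx, 60L)
    expect_equal(length(unique(sch$assignment[roles$test])), 1L)
    expect_equal(length(unique(sch$assignment[roles$validation])), 2L)
    expect_equal(length(unique(sch$assignment[roles$train])), 7L)
  }
})

test_that("the SVM separates toy data and is invariant to duplication", {
  # 2-point separable problem
  x <- matrix(c(0, 0, 1, 1), 2, 2, byrow = TRUE)
  m <- svm_train(x, c(-1, 1), C = 10, gamma = 1)
  expect_equal(predict(m, x)$label, c(-1L, 1L))

  # well-separated blobs: decision values change sign across the two centers
  d <- make_labeled_features(50, 50, separation = 3, seed = 98)
  m2 <- svm_train(d$vectors, d$labels, C = 1, gamma = 8)
  centers <- rbind(colMeans(d$vectors[d$labels == 1, ]),
                   colMeans(d$vectors[d$labels == -1, ]))
  sc <- predict(m2, centers)$score
  expect_gt(sc[1], 0)
  expect_lt(sc[2], 0)

  # duplicating every training sample leaves held-out predictions unchanged
  ho <- make_labeled_features(20, 20, separation = 3, seed = 99)
  m_dup <- svm_train(rbind(d$vectors, d$vectors), rep(d$labels, 2),
                     C = 1, gamma = 8)
  expect_equal(predict(m2, ho$vectors)$label, predict(m_dup, ho$vectors)$label)

  # score > 0 <=> label +1, batch equals record-at-a-time
  p <- predict(m2, ho$vectors)
  expect_equal(p$label == 1L, p$score > 0)
  one_at_a_time <- vapply(seq_len(nrow(ho$vectors)), function(i) {
    predict(m2, ho$vectors[i, , drop = FALSE])$score
  }, numeric(1))
  expect_equal(p$score, one_at_a_time)

  expect_error(svm_train(x, c(1, 1)), "both classes")
  expect_error(predict(m2, ho$vectors[, 1:10]), "dimensionality")
})

test_that("grid_search maximizes validation accuracy with smallest-C ties", {
  d <- make_labeled_features(40, 40, separation = 3, seed = 101)
  sch <- stratified_partition(d, k = 10, seed = 102)
  roles <- fold_roles(sch, 1)

  # single-candidate grid -> that candidate
  gs1 <- grid_search(d, roles$train, roles$validation, C_grid = 4, gamma_grid = 2)
  expect_equal(gs1$C, 4)
  expect_equal(gs1$gamma, 2)

  # separable toy: selected parameters reach 100% validation accuracy
  gs2 <- grid_search(d, roles$train, roles$validation,
                     C_grid = c(1, 16), gamma_grid = c(1, 8))
  expect_equal(gs2$val_accuracy, 100)

  # 3x3 grid equals an independent per-cell loop
  Cs <- c(0.5, 2, 8); gs_ <- c(0.25, 1, 4)
  acc <- matrix(NA_real_, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    m <- svm_train(d$vectors[roles$train, ], d$labels[roles$train],
                   C = Cs[i], gamma = gs_[j])
    acc[i, j] <- mean(predict(m, d$vectors[roles$validation, ])$label ==
                        d$labels[roles$validation])
  }
  gs3 <- grid_search(d, roles$train, roles$validation, C_grid = Cs, gamma_grid = gs_)
  best_cells <- which(acc == max(acc), arr.ind = TRUE)
  best_cells <- best_cells[order(best_cells[, 1], best_cells[, 2]), , drop = FALSE]
  expect_equal(gs3$C, Cs[best_cells[1, 1]])
  expect_equal(gs3$gamma, gs_[best_cells[1, 2]])
  expect_equal(max(gs3$grid$accuracy), max(acc) * 100)
})

test_that("evaluate reproduces the metric formulas", {
  # perfect predictions
  r <- evaluate(c(1, 1, -1, -1), c(1, 1, -1, -1))
  expect_equal(c(r$Se, r$Sp, r$Pre, r$ACC), c(100, 100, 100, 100))

  # truth-as-predictions gives 100 everywhere on random labels
  withr::with_seed(103, truth <- sample(c(-1, 1), 50, replace = TRUE))
  r2 <- evaluate(truth, truth)
  expect_equal(r2$ACC, 100)

  # random confusion counts match direct formula evaluation
  withr::with_seed(104, {
    for (i in 1:20) {
      cnt <- sample(0:50, 4, replace = TRUE)
      r3 <- report_from_counts(cnt[1], cnt[2], cnt[3], cnt[4])
      se <- if (cnt[1] + cnt[4] > 0) cnt[1] / (cnt[1] + cnt[4]) * 100 else NA_real_
      sp <- if (cnt[3] + cnt[2] > 0) cnt[3] / (cnt[3] + cnt[2]) * 100 else NA_real_
      pre <- if (cnt[1] + cnt[2] > 0) cnt[1] / (cnt[1] + cnt[2]) * 100 else NA_real_
      acc <- if (sum(cnt) > 0) (cnt[1] + cnt[3]) / sum(cnt) * 100 else NA_real_
      expect_equal(c(r3$Se, r3$Sp, r3$Pre, r3$ACC), c(se, sp, pre, acc))
      if (!anyNA(c(se, sp))) {
        expect_gte(r3$ACC, min(se, sp))
        expect_lte(r3$ACC, max(se, sp))
      }
    }
  })

  # zero-denominator metrics are NA with counts intact
  r4 <- report_from_counts(0, 0, 5, 2)
  expect_true(is.na(r4$Pre))
  expect_equal(r4$TN, 5)

  expect_error(evaluate(c(1, -1), c(1)), "length")
  expect_error(evaluate(c(1, 0), c(1, 1)), "labels")
})

test_that("cross_validate returns k reports aggregated correctly", {
  d <- make_labeled_features(60, 60, separation = 4, concentration = 200,
                             seed = 105)
  cv <- cross_validate(d, C_grid = c(1, 16), gamma_grid = c(1, 8), seed = 106)
  expect_length(cv$reports, 10L)
  # trivially separable: all rotations at 100%, sd 0
  accs <- vapply(cv$reports, `[[`, numeric(1), "ACC")
  expect_true(all(accs == 100))
  expect_equal(cv$summary$sd[cv$summary$metric == "ACC"], 0)

  # mean/sd match independent recomputation from the reports
  for (m in c("Se", "Sp", "Pre", "ACC")) {
    vals <- vapply(cv$reports, `[[`, numeric(1), m)
    expect_equal(cv$summary$mean[cv$summary$metric == m], mean(vals))
    expect_equal(cv$summary$sd[cv$summary$metric == m], sd(vals))
  }
})

test_that("roc_curve sweeps thresholds and equals the rank-statistic AUC", {
  # perfectly ranked scores
  r <- roc_curve(c(0.9, 0.8, 0.2, 0.1), c(1, 1, -1, -1))
  expect_equal(r$auc, 1)

  # all-equal scores -> chance
  r2 <- roc_curve(rep(0.5, 10), rep(c(1, -1), 5))
  expect_equal(r2$auc, 0.5)

  # AUC equals Mann-Whitney U / (n+ n-) on random scores
  withr::with_seed(107, {
    truth <- rep(c(1, -1), c(30, 40))
    scores <- c(rnorm(30, 0.5), rnorm(40))
    scores[c(3, 40)] <- scores[c(4, 41)]  # plant ties
  })
  r3 <- roc_curve(scores, truth)
  rk <- rank(scores)
  u <- sum(rk[truth == 1]) - 30 * 31 / 2
  expect_equal(r3$auc, u / (30 * 40))

  expect_error(roc_curve(1:5, rep(1, 5)), "both classes")
})

test_that("model JSON round trip preserves the decision function", {
  d <- make_labeled_features(30, 30, seed = 108)
  m <- svm_train(d$vectors, d$labels, C = 2, gamma = 4)
  f <- withr::local_tempfile(fileext = ".json")
  save_model(m, f)
  m2 <- load_model(f)
  expect_equal(predict(m2, d$vectors)$score, predict(m, d$vectors)$score,
               tolerance = 1e-12)
})
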