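#' Assemble a labeled dataset
#'
#' @param vectors Feature matrix (rows = samples, typically 32 triplet
#'   frequencies in [triplet_alphabet()] order).
#' @param labels `+1` (real piRNA) / `-1` (pseudo piRNA) per row.
#' @param ids Optional sample ids.
#' @return A `LabeledDataset`.
#' @export
labeled_dataset <- function(vectors, labels, ids = NULL) {
  vectors <- as.matrix(vectors)
  labels <- as.numeric(labels)
  if (!all(labels %in% c(-1, 1))) stop("labels must be +1/-1")
  if (nrow(vectors) != length(labels)) stop("vectors and labels differ in length")
  if (is.null(ids)) ids <- paste0("s", seq_len(nrow(vectors)))
  if (length(ids) != nrow(vectors)) stop("ids and vectors differ in length")
  structure(list(vectors = vectors, labels = labels, ids = as.character(ids)),
            class = "LabeledDataset")
}

#' Stratified k-fold partition
#'
#' Randomly divides the dataset into `k` partitions of (near-)equal size,
#' each preserving the global positive:negative ratio within one sample per
#' class. Reproducible from `seed`.
#'
#' @param data A `LabeledDataset`.
#' @param k Number of partitions (default 10).
#' @param seed Integer seed.
#' @return A `FoldScheme`: list with `assignment` (partition id 1..k per
#'   sample) and `k`.
#' @export
stratified_partition <- function(data, k = 10L, seed = 1L) {
  k <- as.integer(k)
  labs <- data$labels
  for (cls in c(1, -1)) {
    if (sum(labs == cls) < k) {
      stop("class ", cls, " has fewer than k = ", k, " samples")
    }
  }
  assignment <- integer(length(labs))
  withr::with_seed(seed, {
    for (cls in c(1, -1)) {
      idx <- which(labs == cls)
      idx <- sample(idx)
      # round-robin over shuffled partition order so remainders are spread
      part <- rep(sample(k), length.out = length(idx))
      assignment[idx] <- part
    }
  })
  structure(list(assignment = assignment, k = k), class = "FoldScheme")
}

#' The 7/2/1 role rotation for a ten-fold scheme
#'
#' Rotation `r` uses partition `r` as the test set, the following two
#' partitions (cyclically) for validation, and the remaining seven for
#' training.
#'
#' @param scheme A `FoldScheme` with `k = 10`.
#' @param r Rotation number, 1..k.
#' @return List of index vectors `train`, `validation`, `test`.
#' @export
fold_roles <- function(scheme, r) {
  k <- scheme$k
  test_p <- ((r - 1L) %% k) + 1L
  val_p <- c((test_p %% k) + 1L, ((test_p + 1L) %% k) + 1L)
  a <- scheme$assignment
  list(train = which(!(a %in% c(test_p, val_p))),
       validation = which(a %in% val_p),
       test = which(a == test_p))
}

#' Grid search for the SVM penalty and kernel parameters
#'
#' Trains on the training indices for every `(C, gamma)` cell and returns the
#' pair maximizing validation accuracy; ties are broken toward the smallest
#' `C`, then the smallest `gamma`.
#'
#' @param data A `LabeledDataset`.
#' @param train_idx,val_idx Row indices for training and validation.
#' @param C_grid,gamma_grid Candidate values. Defaults follow the
#'   conventional exponential grid `C = 2^(-5), 2^(-3), ..., 2^15` and
#'   `gamma = 2^(-15), 2^(-13), ..., 2^3`.
#' @return List with `C`, `gamma`, `val_accuracy` and the full `grid` of
#'   per-cell accuracies.
#' @export
grid_search <- function(data, train_idx, val_idx,
                        C_grid = 2^seq(-5, 15, by = 2),
                        gamma_grid = 2^seq(-15, 3, by = 2)) {
  stopifnot(length(C_grid) > 0, length(gamma_grid) > 0)
  cells <- expand.grid(C = sort(C_grid), gamma = sort(gamma_grid))
  cells <- cells[order(cells$C, cells$gamma), , drop = FALSE]
  acc <- numeric(nrow(cells))
  xt <- data$vectors[train_idx, , drop = FALSE]
  yt <- data$labels[train_idx]
  xv <- data$vectors[val_idx, , drop = FALSE]
  yv <- data$labels[val_idx]
  for (i in seq_len(nrow(cells))) {
    m <- svm_train(xt, yt, C = cells$C[i], gamma = cells$gamma[i])
    pred <- predict(m, xv)
    acc[i] <- mean(pred$label == yv)
  }
  best <- which.max(acc)  # first max: smallest C then gamma by construction
  list(C = cells$C[best], gamma = cells$gamma[best],
       val_accuracy = acc[best] * 100,
       grid = cbind(cells, accuracy = acc * 100))
}

#' Confusion counts and the four percentage metrics
#'
#' `Se = TP/(TP+FN) x 100`, `Sp = TN/(TN+FP) x 100`, `Pre = TP/(TP+FP) x
#' 100`, `ACC = (TP+TN)/(TP+TN+FP+FN) x 100`. A metric whose denominator is
#' zero is reported as `NA` with the counts intact.
#'
#' @param truth True labels (`+1`/`-1`).
#' @param predicted Predicted labels (`+1`/`-1`), same length.
#' @return An `EvalReport`: list with `TP`, `FP`, `TN`, `FN`, `Se`, `Sp`,
#'   `Pre`, `ACC` (percentages).
#' @export
evaluate <- function(truth, predicted) {
  if (length(truth) != length(predicted)) stop("truth and predicted differ in length")
  if (!all(c(truth, predicted) %in% c(-1, 1))) stop("labels must be +1/-1")
  tp <- sum(truth == 1 & predicted == 1)
  fn <- sum(truth == 1 & predicted == -1)
  tn <- sum(truth == -1 & predicted == -1)
  fp <- sum(truth == -1 & predicted == 1)
  report_from_counts(tp, fp, tn, fn)
}

#' Build an EvalReport directly from confusion counts
#'
#' @param TP,FP,TN,FN Non-negative confusion counts.
#' @return An `EvalReport`.
#' @export
report_from_counts <- function(TP, FP, TN, FN) {
  pct <- function(num, den) if (den > 0) num / den * 100 else NA_real_
  structure(
    list(TP = TP, FP = FP, TN = TN, FN = FN,
         Se = pct(TP, TP + FN),
         Sp = pct(TN, TN + FP),
         Pre = pct(TP, TP + FP),
         ACC = pct(TP + TN, TP + TN + FP + FN)),
    class = "EvalReport"
  )
}

#' @export
print.EvalReport <- function(x, ...) {
  cat(sprintf("TP=%d FP=%d TN=%d FN=%d | Se=%.2f%% Sp=%.2f%% Pre=%.2f%% ACC=%.2f%%\n",
              x$TP, x$FP, x$TN, x$FN, x$Se, x$Sp, x$Pre, x$ACC))
  invisible(x)
}

#' Ten-fold cross-validation with the 7/2/1 rotation
#'
#' For each of the `k` rotations: grid search on the 7 training + 2
#' validation partitions, refit on the 7 training partitions with the
#' selected parameters, and evaluate on the held-out test partition.
#' Aggregates mean and standard deviation (sample sd over the k rotations)
#' of Se/Sp/Pre/ACC.
#'
#' @param data A `LabeledDataset`.
#' @param scheme A `FoldScheme` (made with [stratified_partition()]); if
#'   `NULL`, one is built from `seed`.
#' @param C_grid,gamma_grid Passed to [grid_search()].
#' @param seed Seed used when `scheme` is `NULL`.
#' @param k Folds when `scheme` is `NULL`.
#' @return List with `reports` (k `EvalReport`s), `params` (chosen `(C,
#'   gamma)` per rotation) and `summary` (data frame of mean and sd per
#'   metric).
#' @export
cross_validate <- function(data, scheme = NULL,
                           C_grid = 2^seq(-5, 15, by = 2),
                           gamma_grid = 2^seq(-15, 3, by = 2),
                           seed = 1L, k = 10L) {
  if (is.null(scheme)) scheme <- stratified_partition(data, k = k, seed = seed)
  k <- scheme$k
  reports <- vector("list", k)
  params <- data.frame(rotation = seq_len(k), C = NA_real_, gamma = NA_real_)
  for (r in seq_len(k)) {
    roles <- fold_roles(scheme, r)
    gs <- grid_search(data, roles$train, roles$validation,
                      C_grid = C_grid, gamma_grid = gamma_grid)
    params$C[r] <- gs$C; params$gamma[r] <- gs$gamma
    model <- svm_train(data$vectors[roles$train, , drop = FALSE],
                       data$labels[roles$train], C = gs$C, gamma = gs$gamma)
    pred <- predict(model, data$vectors[roles$test, , drop = FALSE])
    reports[[r]] <- evaluate(data$labels[roles$test], pred$label)
  }
  metrics <- c("Se", "Sp", "Pre", "ACC")
  vals <- sapply(metrics, function(m) vapply(reports, `[[`, numeric(1), m))
  summary <- data.frame(
    metric = metrics,
    mean = colMeans(vals, na.rm = TRUE),
    sd = apply(vals, 2, sd, na.rm = TRUE),
    row.names = NULL
  )
  list(reports = reports, params = params, summary = summary)
}

#' ROC curve and AUC from decision scores
#'
#' Threshold-swept true/false positive rates; AUC computed by the
#' trapezoidal rule (equivalently the tie-corrected Mann-Whitney statistic
#' over score ranks).
#'
#' @param scores Numeric decision scores (larger = more positive).
#' @param truth True labels `+1`/`-1`.
#' @return List with `curve` (data frame `threshold`, `fpr`, `tpr`) and
#'   `auc`.
#' @export
roc_curve <- function(scores, truth) {
  if (length(unique(truth)) < 2L) stop("ROC requires both classes in truth")
  if (!all(truth %in% c(-1, 1))) stop("labels must be +1/-1")
  np <- sum(truth == 1); nn <- sum(truth == -1)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; t <- truth[o]
  # step through distinct thresholds
  brk <- c(which(diff(s) != 0), length(s))
  tp <- cumsum(t == 1)[brk]
  fp <- cumsum(t == -1)[brk]
  curve <- data.frame(threshold = c(Inf, s[brk]),
                      fpr = c(0, fp / nn), tpr = c(0, tp / np))
  auc <- sum(diff(curve$fpr) * (head(curve$tpr, -1) + curve$tpr[-1]) / 2)
  list(curve = curve, auc = auc)
}
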