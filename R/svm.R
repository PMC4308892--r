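#' Train an RBF-kernel support vector machine
#'
#' Soft-margin SVM with Gaussian kernel `K(x, x') = exp(-gamma ||x - x'||^2)`
#' fitted by a built-in sequential minimal optimization (SMO) solver with
#' maximal-violating-pair working-set selection. The decision function is
#' `f(x) = sgn(sum_i alpha_i y_i K(x, x_i) + b)`. Deterministic for a fixed
#' data order and parameter set.
#'
#' @param x Numeric feature matrix (rows = samples).
#' @param y Labels, `+1` (real piRNA) / `-1` (pseudo piRNA).
#' @param C Penalty parameter, > 0.
#' @param gamma RBF kernel width parameter, > 0.
#' @param eps SMO stopping tolerance on the KKT violation gap.
#' @return A `TrainedModel`: support vectors, coefficients `alpha_i y_i`,
#'   bias `b`, kernel parameters and the training feature order.
#' @export
svm_train <- function(x, y, C = 1, gamma = 1, eps = 1e-3) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.numeric(y)
  if (!all(y %in% c(-1, 1))) stop("labels must be +1/-1")
  if (length(unique(y)) < 2L) stop("training data must contain both classes")
  stopifnot(C > 0, gamma > 0)
  fit <- smo_train(x, y, C = C, gamma = gamma, eps = eps)
  sv <- which(fit$alpha > 1e-12)
  structure(
    list(sv = x[sv, , drop = FALSE],
         coef = fit$alpha[sv] * y[sv],
         b = fit$b,
         C = C, gamma = gamma, kernel = "RBF",
         n_sv = length(sv),
         iterations = fit$iterations,
         feature_names = colnames(x)),
    class = "TrainedModel"
  )
}

#' @export
print.TrainedModel <- function(x, ...) {
  cat(sprintf("RBF-SVM: C=%g gamma=%g, %d support vector(s), b=%.4g\n",
              x$C, x$gamma, x$n_sv, x$b))
  invisible(x)
}

#' Predict with a trained SVM
#'
#' @param object A `TrainedModel` from [svm_train()].
#' @param newdata Feature matrix with the training dimensionality (and, if
#'   both are named, the training column order).
#' @param ... Unused.
#' @return Data frame with `score` (decision value) and `label` (`+1` iff
#'   score > 0, else `-1`).
#' @export
predict.TrainedModel <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  storage.mode(newdata) <- "double"
  if (ncol(newdata) != ncol(object$sv)) {
    stop("feature dimensionality mismatch: model expects ", ncol(object$sv),
         " features, got ", ncol(newdata))
  }
  if (!is.null(object$feature_names) && !is.null(colnames(newdata)) &&
      !identical(colnames(newdata), object$feature_names)) {
    if (!all(object$feature_names %in% colnames(newdata))) {
      stop("feature names do not match the training feature order")
    }
    newdata <- newdata[, object$feature_names, drop = FALSE]
  }
  score <- rbf_decision(object$sv, object$coef, object$b, object$gamma, newdata)
  data.frame(score = score, label = ifelse(score > 0, 1L, -1L))
}

#' Save a trained model as a self-contained JSON document
#'
#' @param model A `TrainedModel`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
save_model <- function(model, path) {
  doc <- list(
    format = "tripiR-svm", version = 1L, kernel = model$kernel,
    C = model$C, gamma = model$gamma, b = model$b,
    feature_names = model$feature_names,
    coef = model$coef,
    support_vectors = lapply(seq_len(nrow(model$sv)),
                             function(i) as.numeric(model$sv[i, ]))
  )
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load a trained model from JSON
#'
#' @param path Path written by [save_model()].
#' @return A `TrainedModel`.
#' @export
load_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "tripiR-svm")) stop("not a tripiR SVM model file")
  sv <- doc$support_vectors
  if (is.list(sv)) sv <- do.call(rbind, lapply(sv, as.numeric))
  sv <- matrix(as.numeric(sv), nrow = NROW(sv))
  colnames(sv) <- doc$feature_names
  structure(
    list(sv = sv, coef = as.numeric(doc$coef), b = doc$b, C = doc$C,
         gamma = doc$gamma, kernel = doc$kernel, n_sv = nrow(sv),
         iterations = NA_integer_, feature_names = doc$feature_names),
    class = "TrainedModel"
  )
}
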