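#' The 32-element structure-sequence triplet alphabet
#'
#' Each element combines the pairing pattern of three adjacent query
#' nucleotides (paired = `(`, unpaired = `.`; 2^3 = 8 patterns) with the
#' identity of the middle nucleotide (A, C, G, U), giving 4 x 8 = 32
#' elements such as `"(((U"`. The ordering is fixed: patterns in the order
#' `"((("`, `"((."`, `"(.."`, `"(.("`, `".(("`, `".(."`, `"..("`, `"..."`,
#' each crossed with A, C, G, U.
#'
#' @return Character vector of the 32 element names, in canonical order.
#' @export
triplet_alphabet <- function() {
  patterns <- c("(((", "((.", "(..", "(.(", ".((", ".(.", "..(", "...")
  as.vector(t(outer(patterns, c("A", "C", "G", "U"), paste0)))
}

#' Extract triplet-element frequencies from a duplex structure
#'
#' Slides a width-3 window along the query; each window contributes one count
#' to the element formed by its pairing pattern and its middle nucleotide.
#' The first and last nucleotides are never window centers, so a length-L
#' query yields L-2 windows; with `normalize = TRUE` counts are divided by
#' L-2 and the vector sums to 1. Only the query-side structure matters.
#'
#' @param structure A `DuplexStructure` (or any list with `query_struct`),
#'   or a plain dot-bracket string over `(` and `.`.
#' @param query Query record (list with `seq`) or plain sequence string; `T`
#'   is read as `U`. Must not contain `N`.
#' @param normalize Divide counts by the window count (default TRUE).
#' @return Named numeric vector of length 32 (a `TripletVector`), in
#'   [triplet_alphabet()] order.
#' @export
extract_triplets <- function(structure, query, normalize = TRUE) {
  qs <- if (is.character(structure)) structure else structure$query_struct
  seq <- if (is.character(query)) query else query$seq
  seq <- to_rna(toupper(seq))
  L <- nchar(seq)
  if (L < 3L) stop("sequence too short for triplet extraction (length < 3)")
  if (nchar(qs) != L) stop("structure length must equal query length")
  if (grepl("N", seq, fixed = TRUE)) stop("sequence contains N; excluded from feature extraction")
  if (grepl("[^(.]", qs)) stop("query structure must be over '(' and '.'")
  centers <- 2:(L - 1L)
  pat <- substring(qs, centers - 1L, centers + 1L)
  mid <- substring(seq, centers, centers)
  elems <- paste0(pat, mid)
  v <- setNames(numeric(32L), triplet_alphabet())
  tab <- table(elems)
  v[names(tab)] <- as.numeric(tab)
  if (normalize) v <- v / (L - 2L)
  v
}

#' Rank triplet elements by their F-value discriminative power
#'
#' For each element j, `F_j = |mu_j^+ - mu_j^-| / (sigma_j^+ + sigma_j^-)`
#' with per-class means and standard deviations of the feature across
#' samples. Standard deviations are population (divide by n) by default.
#' Elements are returned sorted by decreasing F, ties broken by canonical
#' alphabet order. A zero denominator yields F = 0 when the class means are
#' equal and `Inf` (ranked first) when they differ.
#'
#' @param pos Numeric matrix of positive-class feature vectors (rows =
#'   samples, 32 columns in [triplet_alphabet()] order).
#' @param neg Matrix of negative-class feature vectors.
#' @param population Use population standard deviation (default TRUE).
#' @return Data frame with columns `element`, `f_value`, `mu_pos`, `mu_neg`,
#'   `sd_pos`, `sd_neg`, sorted by decreasing `f_value`.
#' @export
f_values <- function(pos, neg, population = TRUE) {
  pos <- as.matrix(pos); neg <- as.matrix(neg)
  if (nrow(pos) == 0L || nrow(neg) == 0L) stop("both classes must be nonempty")
  stopifnot(ncol(pos) == ncol(neg))
  elems <- if (!is.null(colnames(pos))) colnames(pos) else triplet_alphabet()[seq_len(ncol(pos))]
  popsd <- function(x) {
    n <- length(x)
    s <- sqrt(sum((x - mean(x))^2) / if (population) n else max(n - 1L, 1L))
    s
  }
  mu_pos <- colMeans(pos); mu_neg <- colMeans(neg)
  sd_pos <- apply(pos, 2, popsd); sd_neg <- apply(neg, 2, popsd)
  denom <- sd_pos + sd_neg
  f <- ifelse(denom > 0, abs(mu_pos - mu_neg) / denom,
              ifelse(mu_pos == mu_neg, 0, Inf))
  out <- data.frame(element = elems, f_value = f, mu_pos = mu_pos,
                    mu_neg = mu_neg, sd_pos = sd_pos, sd_neg = sd_neg,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(-out$f_value, match(out$element, elems)), , drop = FALSE]
}

#' Write a feature matrix as TSV
#'
#' Dense matrix text with a 32-column header of element names.
#'
#' @param mat Feature matrix (rows = samples).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_features <- function(mat, path) {
  df <- as.data.frame(mat)
  if (is.null(colnames(mat))) colnames(df) <- triplet_alphabet()[seq_len(ncol(df))]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
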