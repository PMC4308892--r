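# Align one read, pick its best hit, predict the duplex and extract the
# triplet vector. Returns NULL for unmappable or N-containing reads.
.analyze_read <- function(rec, index, transposons, max_mismatches = 3L) {
  if (grepl("N", rec$seq, fixed = TRUE)) return(NULL)
  hits <- align(rec, index, max_mismatches = max_mismatches)
  if (nrow(hits) == 0L) return(NULL)
  bd <- best_duplex(rec, hits, transposons)
  list(hit = bd$hit, duplex = bd$duplex,
       features = extract_triplets(bd$duplex, rec))
}

#' Triplet-feature matrix for a whole library
#'
#' Runs the align / best-duplex / extract chain on every record and returns
#' the 32-column feature matrix. Unmappable or N-containing records get a
#' row of `NA`.
#'
#' @param lib `SequenceLibrary` (or FASTA path) of small RNAs.
#' @param transposons `SequenceLibrary` (or FASTA path) of targets.
#' @param index Optional prebuilt `TargetIndex`.
#' @param max_mismatches Alignment mismatch cap.
#' @return Numeric matrix, rows named by record id, columns by
#'   [triplet_alphabet()].
#' @export
library_features <- function(lib, transposons, index = NULL, max_mismatches = 3L) {
  if (is.character(lib)) lib <- read_fasta(lib)
  if (is.character(transposons)) transposons <- read_fasta(transposons)
  if (is.null(index)) index <- build_index(transposons)
  feats <- matrix(NA_real_, length(lib), 32,
                  dimnames = list(lib$id, triplet_alphabet()))
  for (i in seq_along(lib$id)) {
    a <- .analyze_read(list(id = lib$id[i], seq = lib$seq[i]), index,
                       transposons, max_mismatches)
    if (!is.null(a)) feats[i, ] <- a$features
  }
  feats
}

#' End-to-end piRNA prediction on a small-RNA library
#'
#' For each unique read: align to the transposon library (at most
#' `max_mismatches` substitutions, both strands); reads with no hit are
#' reported as `not_transposon_associated`; for mappable reads the best hit
#' is selected (fewest mismatches, then lowest duplex energy), the
#' piRNA-transposon duplex is predicted, the 32 triplet-element frequencies
#' extracted, and the SVM applied. Reads are deduplicated first; the number
#' of input copies is kept in the `count` column.
#'
#' @param reads `SequenceLibrary` or FASTA path of candidate small RNAs.
#' @param transposons `SequenceLibrary` or FASTA path of transposons.
#' @param model A `TrainedModel`.
#' @param max_mismatches Alignment mismatch cap (default 3).
#' @param index Optional prebuilt `TargetIndex` over `transposons`.
#' @return Data frame with one row per unique read: `read_id`, `sequence`,
#'   `length`, `count`, `target_id`, `mismatches`, `duplex_query`,
#'   `duplex_target`, `svm_score`, `label` (`piRNA`, `non-piRNA`, or
#'   `not_transposon_associated`).
#' @export
predict_pipeline <- function(reads, transposons, model, max_mismatches = 3L,
                             index = NULL) {
  if (is.character(reads)) reads <- read_fasta(reads)
  if (is.character(transposons)) transposons <- read_fasta(transposons)
  reads <- dedupe(reads)
  mult <- attr(reads, "multiplicity")
  if (is.null(index)) index <- build_index(transposons)
  nr <- length(reads)
  if (nr == 0L) {
    return(data.frame(read_id = character(), sequence = character(),
                      length = integer(), count = integer(),
                      target_id = character(), mismatches = integer(),
                      duplex_query = character(), duplex_target = character(),
                      svm_score = numeric(), label = character(),
                      stringsAsFactors = FALSE))
  }
  out <- data.frame(
    read_id = reads$id, sequence = reads$seq, length = seq_lengths(reads),
    count = as.integer(mult[reads$id]),
    target_id = NA_character_, mismatches = NA_integer_,
    duplex_query = NA_character_, duplex_target = NA_character_,
    svm_score = NA_real_, label = "not_transposon_associated",
    stringsAsFactors = FALSE
  )
  feats <- matrix(NA_real_, nr, 32, dimnames = list(NULL, triplet_alphabet()))
  for (i in seq_len(nr)) {
    a <- .analyze_read(list(id = reads$id[i], seq = reads$seq[i]), index,
                       transposons, max_mismatches)
    if (is.null(a)) next
    out$target_id[i] <- a$hit$target_id
    out$mismatches[i] <- a$hit$mismatches
    out$duplex_query[i] <- a$duplex$query_struct
    out$duplex_target[i] <- a$duplex$target_struct
    feats[i, ] <- a$features
  }
  mapped <- which(!is.na(out$target_id))
  if (length(mapped)) {
    pred <- predict(model, feats[mapped, , drop = FALSE])
    out$svm_score[mapped] <- pred$score
    out$label[mapped] <- ifelse(pred$label == 1L, "piRNA", "non-piRNA")
  }
  out
}

#' Per-length read counts
#'
#' Integer counts per length over 18-35 nt (lengths outside the range get
#' their own bins so that counts always sum to the number of records).
#'
#' @param x A `SequenceLibrary`, a prediction data frame with a `length`
#'   column, or an integer vector of lengths.
#' @param normalize Return proportions instead of counts.
#' @return Named numeric vector of counts (or proportions) per length.
#' @export
length_histogram <- function(x, normalize = FALSE) {
  len <- if (inherits(x, "SequenceLibrary")) seq_lengths(x)
         else if (is.data.frame(x)) x$length
         else as.integer(x)
  if (!length(len)) stop("empty input")
  lev <- sort(unique(c(18:35, len)))
  counts <- as.numeric(table(factor(len, levels = lev)))
  names(counts) <- lev
  if (normalize) counts <- counts / sum(counts)
  counts
}

#' Percentage of reads targeting each transposon class
#'
#' Each read is counted once, through its selected best hit; a target id
#' absent from `class_map` is assigned class `"other"` with a warning.
#'
#' @param hits Data frame with one (best) hit per read: columns `query_id`
#'   and `target_id` (e.g. the mapped rows of a [predict_pipeline()] result,
#'   using `read_id` as `query_id`).
#' @param class_map Named character vector target id -> class (SINE, LINE,
#'   LTR, DNA, ...), e.g. from [transposon_classes()].
#' @return Named numeric vector of percentages summing to 100.
#' @export
target_class_percentages <- function(hits, class_map) {
  if (is.null(hits$target_id) || nrow(hits) == 0L) stop("no hits supplied")
  cls <- class_map[hits$target_id]
  if (anyNA(cls)) {
    warning(sum(is.na(cls)), " target id(s) missing from class_map; counted as 'other'")
    cls[is.na(cls)] <- "other"
  }
  tab <- table(cls)
  setNames(100 * as.numeric(tab) / sum(tab), names(tab))
}
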