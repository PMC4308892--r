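#' Construct a sequence library
#'
#' A `SequenceLibrary` is the package's container for an ordered set of small
#' RNA or transposon sequences: parallel vectors of ids and upper-case
#' sequences plus a source tag and an alphabet (`"dna"` stores `T`, `"rna"`
#' stores `U`). Ids must be unique within a library.
#'
#' @param id Character vector of record ids.
#' @param seq Character vector of sequences over `{A,C,G,T,U,N}` (case
#'   insensitive; canonicalized to `alphabet`).
#' @param source_tag Single string describing provenance.
#' @param alphabet `"dna"` or `"rna"`.
#' @return An object of class `SequenceLibrary`.
#' @export
sequence_library <- function(id = character(), seq = character(),
                             source_tag = "", alphabet = c("dna", "rna")) {
  alphabet <- match.arg(alphabet)
  stopifnot(length(id) == length(seq))
  id <- as.character(id)
  seq <- toupper(as.character(seq))
  seq <- if (alphabet == "dna") to_dna(seq) else to_rna(seq)
  if (anyDuplicated(id)) stop("record ids must be unique within a library")
  structure(
    list(id = id, seq = seq, source_tag = source_tag, alphabet = alphabet),
    class = "SequenceLibrary"
  )
}

#' @export
length.SequenceLibrary <- function(x) length(x$id)

#' @export
print.SequenceLibrary <- function(x, ...) {
  cat(sprintf("SequenceLibrary [%s] with %d record(s) (%s)\n",
              x$alphabet, length(x), if (nzchar(x$source_tag)) x$source_tag else "untagged"))
  n <- min(length(x), 6L)
  if (n > 0L) {
    for (i in seq_len(n)) {
      s <- x$seq[i]
      if (nchar(s) > 50) s <- paste0(substr(s, 1, 47), "...")
      cat(sprintf("  %s  %s (%d nt)\n", x$id[i], s, nchar(x$seq[i])))
    }
    if (length(x) > n) cat(sprintf("  ... and %d more\n", length(x) - n))
  }
  invisible(x)
}

#' @export
`[.SequenceLibrary` <- function(x, i) {
  out <- sequence_library(x$id[i], x$seq[i], source_tag = x$source_tag,
                          alphabet = x$alphabet)
  h <- attr(x, "headers")
  if (!is.null(h)) attr(out, "headers") <- h[names(h) %in% out$id]
  out
}

#' @export
as.data.frame.SequenceLibrary <- function(x, ...) {
  data.frame(id = x$id, sequence = x$seq, length = nchar(x$seq),
             has_n = grepl("N", x$seq, fixed = TRUE),
             stringsAsFactors = FALSE)
}

#' Lengths of the records in a library
#' @param lib A `SequenceLibrary`.
#' @return Integer vector of sequence lengths (nt).
#' @export
seq_lengths <- function(lib) nchar(lib$seq)

#' Read a FASTA file into a SequenceLibrary
#'
#' Accepts wrapped or unwrapped multi-record FASTA. Sequences are upper-cased
#' and canonicalized to the requested alphabet (`"auto"` chooses RNA when the
#' file contains `U` but no `T`, DNA otherwise). Records with characters
#' outside `{A,C,G,T,U,N}` are rejected with a warning reporting the count;
#' records containing `N` are kept but flagged by downstream steps.
#'
#' @param path Path to a FASTA file.
#' @param alphabet_policy One of `"dna"`, `"rna"`, `"auto"`.
#' @param source_tag Optional provenance string; defaults to the file name.
#' @return A `SequenceLibrary` with one record per FASTA entry, in file order.
#' @export
read_fasta <- function(path, alphabet_policy = c("dna", "rna", "auto"),
                       source_tag = basename(path)) {
  alphabet_policy <- match.arg(alphabet_policy)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  seqs <- toupper(as.character(ss))
  bad <- grepl("[^ACGTUN]", seqs)
  if (any(bad)) {
    warning(sum(bad), " record(s) rejected: characters outside {A,C,G,T,U,N}")
    ids <- ids[!bad]; seqs <- seqs[!bad]
  }
  if (alphabet_policy == "auto") {
    alphabet_policy <- if (any(grepl("U", seqs, fixed = TRUE)) &&
                           !any(grepl("T", seqs, fixed = TRUE))) "rna" else "dna"
  }
  lib <- sequence_library(ids, seqs, source_tag = source_tag, alphabet = alphabet_policy)
  attr(lib, "headers") <- setNames(names(ss)[!bad], ids)
  lib
}

#' Write a SequenceLibrary as FASTA
#'
#' Standard multi-record FASTA with 60-column wrapping. An empty library
#' produces an empty file.
#'
#' @param lib A `SequenceLibrary`.
#' @param path Output path.
#' @return The output path, invisibly.
#' @export
write_fasta <- function(lib, path) {
  headers <- attr(lib, "headers")
  nm <- if (!is.null(headers) && all(lib$id %in% names(headers))) {
    unname(headers[lib$id])
  } else lib$id
  ss <- Biostrings::BStringSet(setNames(lib$seq, nm))
  Biostrings::writeXStringSet(ss, filepath = path, width = 60L)
  invisible(path)
}

#' Remove duplicate sequences from a library
#'
#' The default operationalizes redundancy removal as exact-duplicate removal:
#' no two retained records share an identical sequence string, first
#' occurrence wins. The optional near-duplicate mode additionally drops a
#' record whose sequence has the same length as an already-retained one and
#' differs from it in at most `max_hamming` positions.
#'
#' @param lib A `SequenceLibrary`.
#' @param near Logical; enable the near-duplicate mode (off by default).
#' @param max_hamming Hamming threshold for the near-duplicate mode.
#' @return The deduplicated `SequenceLibrary`. The integer attribute
#'   `"multiplicity"` maps each retained id to the number of input records it
#'   absorbed.
#' @export
dedupe <- function(lib, near = FALSE, max_hamming = 2L) {
  keep <- !duplicated(lib$seq)
  mult <- as.integer(table(factor(lib$seq, levels = lib$seq[keep])))
  out <- lib[keep]
  multiplicity <- setNames(mult, out$id)
  if (near && length(out) > 1L) {
    enc <- lapply(out$seq, encode_seq)
    len <- nchar(out$seq)
    retained <- logical(length(out))
    retained[1] <- TRUE
    for (i in seq_along(out$id)[-1]) {
      prev <- which(retained & len == len[i])
      dup_of <- 0L
      for (j in prev) {
        if (sum(enc[[i]] != enc[[j]]) <= max_hamming) { dup_of <- j; break }
      }
      if (dup_of > 0L) {
        multiplicity[dup_of] <- multiplicity[dup_of] + multiplicity[i]
      } else retained[i] <- TRUE
    }
    multiplicity <- multiplicity[retained]
    out <- out[retained]
  }
  attr(out, "multiplicity") <- multiplicity
  out
}

#' Write a prediction table as TSV
#'
#' Columns: `read_id  sequence  length  count  target_id  mismatches
#' duplex_query  duplex_target  svm_score  label`.
#'
#' @param predictions Data frame as returned by [predict_pipeline()].
#' @param path Output path.
#' @return The output path, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  write.table(predictions, file = path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}
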