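#' Build a seed index over a transposon library
#'
#' Hash index of every `seed_length`-mer of every target, used by [align()]
#' for mismatch-limited search with the pigeonhole guarantee: a query split
#' into `k + 1` disjoint seeds must have at least one exact seed in any
#' placement with at most `k` substitutions.
#'
#' @param targets `SequenceLibrary` of target (transposon) sequences.
#' @param seed_length Seed k-mer length (default 8; smaller values are
#'   allowed for toy examples but slow the search down).
#' @return A `TargetIndex` object.
#' @export
build_index <- function(targets, seed_length = 8L) {
  stopifnot(seed_length >= 1L)
  seed_length <- as.integer(seed_length)
  seqs <- to_dna(targets$seq)
  short <- nchar(seqs) < seed_length
  if (any(short)) {
    warning(sum(short), " target(s) shorter than seed_length skipped")
  }
  tab <- new.env(parent = emptyenv(), hash = TRUE)
  enc <- vector("list", length(targets))
  names(enc) <- targets$id
  for (t in seq_along(targets$id)) {
    enc[[t]] <- encode_seq(seqs[t])
    L <- nchar(seqs[t])
    if (L < seed_length) next
    pos <- seq_len(L - seed_length + 1L)
    seeds <- substring(seqs[t], pos, pos + seed_length - 1L)
    bykmer <- split(pos, seeds)
    for (km in names(bykmer)) {
      entry <- list(t = t, pos = bykmer[[km]])
      tab[[km]] <- c(tab[[km]], list(entry))
    }
  }
  structure(
    list(table = tab, seed_length = seed_length, target_ids = targets$id,
         enc = enc, lengths = nchar(seqs)),
    class = "TargetIndex"
  )
}

#' @export
print.TargetIndex <- function(x, ...) {
  cat(sprintf("TargetIndex: %d target(s), seed length %d, %d distinct seed(s)\n",
              length(x$target_ids), x$seed_length, length(ls(x$table))))
  invisible(x)
}

#' Look up exact seed occurrences in a TargetIndex
#'
#' @param index A `TargetIndex`.
#' @param kmer A string of exactly `seed_length` characters (DNA form).
#' @return Data frame with columns `target_id` and `pos` (0-based).
#' @export
index_lookup <- function(index, kmer) {
  stopifnot(nchar(kmer) == index$seed_length)
  hits <- index$table[[to_dna(toupper(kmer))]]
  if (is.null(hits)) {
    return(data.frame(target_id = character(), pos = integer()))
  }
  do.call(rbind, lapply(hits, function(e) {
    data.frame(target_id = index$target_ids[e$t], pos = e$pos - 1L)
  }))
}

# Empty hit table with the TransposonHit columns.
empty_hits <- function() {
  data.frame(query_id = character(), target_id = character(),
             offset = integer(), strand = character(), mismatches = integer(),
             stringsAsFactors = FALSE)
}

# Candidate offsets for one oriented query against the index, via pigeonhole
# seeding. Returns a data.frame(t, off) of 1-based candidate placements; NULL
# means the query is too short for seeding and the caller must brute-force.
seed_candidates <- function(qenc, qseq, index, k) {
  sl <- index$seed_length
  L <- length(qenc)
  nseg <- k + 1L
  if (L %/% nseg < sl) return(NULL)
  starts <- floor((seq_len(nseg) - 1L) * L / nseg) + 1L
  cand_t <- integer(0); cand_off <- integer(0)
  for (q0 in starts) {
    hits <- index$table[[substr(qseq, q0, q0 + sl - 1L)]]
    if (is.null(hits)) next
    for (e in hits) {
      off <- e$pos - q0 + 1L
      ok <- off >= 1L & off + L - 1L <= index$lengths[e$t]
      if (any(ok)) {
        cand_t <- c(cand_t, rep.int(e$t, sum(ok)))
        cand_off <- c(cand_off, off[ok])
      }
    }
  }
  unique(data.frame(t = cand_t, off = cand_off))
}

# Exhaustive scan of one oriented query against one encoded target: mismatch
# count at every valid offset. Used as seeding fallback for short queries.
scan_offsets <- function(qenc, tenc) {
  L <- length(qenc); Lt <- length(tenc)
  if (Lt < L) return(integer(0))
  noff <- Lt - L + 1L
  win <- matrix(tenc[outer(0:(L - 1L), seq_len(noff), `+`)], nrow = L)
  colSums(win != qenc)
}

#' Mismatch-limited alignment of a short query against indexed targets
#'
#' Finds all placements of the query on the indexed targets with Hamming
#' distance at most `max_mismatches` (substitutions only, no indels).
#' Reverse-strand hits place the reverse complement of the query on the
#' target forward sequence; `offset` is always 0-based on the target forward
#' strand. A query containing `N` yields no hits and is flagged via the
#' `"flagged_n"` attribute.
#'
#' @param query A `SmallRNARecord`-like list with `id` and `seq`, or a
#'   single-record `SequenceLibrary`.
#' @param index A `TargetIndex` from [build_index()].
#' @param max_mismatches Maximum substitutions (default 3, as in the
#'   mismatch-limited mapping protocol this package follows).
#' @param strands `"both"`, `"forward"` or `"reverse"`.
#' @return Data frame of hits with columns `query_id`, `target_id`, `offset`,
#'   `strand`, `mismatches`, ordered by `(target_id, offset, strand)`.
#' @export
align <- function(query, index, max_mismatches = 3L,
                  strands = c("both", "forward", "reverse")) {
  strands <- match.arg(strands)
  k <- as.integer(max_mismatches)
  qid <- if (inherits(query, "SequenceLibrary")) query$id[1] else query$id
  qseq <- to_dna(toupper(if (inherits(query, "SequenceLibrary")) query$seq[1] else query$seq))
  out <- empty_hits()
  if (grepl("N", qseq, fixed = TRUE)) {
    attr(out, "flagged_n") <- TRUE
    return(out)
  }
  orientations <- switch(strands,
    both = c("+", "-"), forward = "+", reverse = "-")
  for (st in orientations) {
    oseq <- if (st == "+") qseq else revcomp(qseq)
    oenc <- encode_seq(oseq)
    cand <- seed_candidates(oenc, oseq, index, k)
    if (is.null(cand)) {
      # query too short for pigeonhole seeds at this k: exact full scan
      for (t in seq_along(index$enc)) {
        mm <- scan_offsets(oenc, index$enc[[t]])
        hit <- which(mm <= k)
        if (length(hit)) {
          out <- rbind(out, data.frame(
            query_id = qid, target_id = index$target_ids[t],
            offset = hit - 1L, strand = st, mismatches = as.integer(mm[hit]),
            stringsAsFactors = FALSE))
        }
      }
    } else if (nrow(cand)) {
      L <- length(oenc)
      mm <- integer(nrow(cand))
      for (i in seq_len(nrow(cand))) {
        tenc <- index$enc[[cand$t[i]]]
        mm[i] <- sum(oenc != tenc[cand$off[i]:(cand$off[i] + L - 1L)])
      }
      ok <- mm <= k
      if (any(ok)) {
        out <- rbind(out, data.frame(
          query_id = qid, target_id = index$target_ids[cand$t[ok]],
          offset = cand$off[ok] - 1L, strand = st,
          mismatches = as.integer(mm[ok]), stringsAsFactors = FALSE))
      }
    }
  }
  out <- out[order(out$target_id, out$offset, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Align every record of a library
#'
#' @inheritParams align
#' @param queries A `SequenceLibrary`.
#' @return One hit data frame (rbind of per-query [align()] results, in query
#'   order).
#' @export
align_all <- function(queries, index, max_mismatches = 3L, strands = "both") {
  res <- lapply(seq_along(queries$id), function(i) {
    align(list(id = queries$id[i], seq = queries$seq[i]), index,
          max_mismatches = max_mismatches, strands = strands)
  })
  do.call(rbind, c(list(empty_hits()), res))
}

#' Split a library into transposon-mappable and unmappable records
#'
#' @inheritParams align_all
#' @return List with `SequenceLibrary` elements `mappable` (at least one hit
#'   at `max_mismatches`) and `unmappable`; the partition is exhaustive and
#'   disjoint.
#' @export
partition_mappable <- function(queries, index, max_mismatches = 3L,
                               strands = "both") {
  has_hit <- vapply(seq_along(queries$id), function(i) {
    nrow(align(list(id = queries$id[i], seq = queries$seq[i]), index,
               max_mismatches = max_mismatches, strands = strands)) > 0L
  }, logical(1))
  list(mappable = queries[has_hit], unmappable = queries[!has_hit])
}

#' Export hits as BED6
#'
#' Target as chromosome, 0-based half-open interval, query id as name,
#' mismatch count as score.
#'
#' @param hits Hit data frame from [align()]/[align_all()].
#' @param query_lengths Named integer vector mapping query ids to lengths.
#' @return BED6 data frame.
#' @export
hits_to_bed <- function(hits, query_lengths) {
  data.frame(
    chrom = hits$target_id,
    start = hits$offset,
    end = hits$offset + as.integer(query_lengths[hits$query_id]),
    name = hits$query_id,
    score = hits$mismatches,
    strand = hits$strand,
    stringsAsFactors = FALSE
  )
}
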