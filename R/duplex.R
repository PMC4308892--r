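#' Extract the transcript-sense window a query base-pairs with
#'
#' Given a hit of a small RNA on a transposon, returns the RNA sequence the
#' query would hybridize to: the reverse complement of the matched span in
#' query orientation. For a forward-strand hit that is the reverse complement
#' of the target span; for a reverse-strand hit (where the reverse complement
#' of the query matched the forward target) it is the forward span itself.
#' Flanking target sequence can be added on either side before orientation;
#' flanks are clipped at the target ends.
#'
#' @param hit One-row hit data frame (see [align()]).
#' @param targets `SequenceLibrary` the hit refers to.
#' @param query_length Length of the query placed at the hit.
#' @param flank Non-negative integer flank (nt) on each side, default 0.
#' @return List with `id`, `seq` (RNA window, 5'->3' in pairing orientation),
#'   `left_clip`/`right_clip` (flank actually obtained on each side of the
#'   window as returned).
#' @export
target_window <- function(hit, targets, query_length, flank = 0L) {
  t <- match(hit$target_id, targets$id)
  if (is.na(t)) stop("hit refers to unknown target: ", hit$target_id)
  tseq <- to_dna(targets$seq[t])
  Lt <- nchar(tseq)
  start1 <- hit$offset + 1L
  end1 <- hit$offset + query_length
  if (start1 < 1L || end1 > Lt) stop("hit out of bounds for target ", hit$target_id)
  lo <- max(1L, start1 - flank)
  hi <- min(Lt, end1 + flank)
  span <- substr(tseq, lo, hi)
  left <- start1 - lo   # flank obtained on the target's left
  right <- hi - end1
  if (hit$strand == "+") {
    win <- to_rna(revcomp(span))
    # reverse complement flips the flanks
    lclip <- right; rclip <- left
  } else {
    win <- to_rna(span)
    lclip <- left; rclip <- right
  }
  list(id = paste0(hit$target_id, ":", lo - 1L, "-", hi, ":", hit$strand),
       seq = win, left_clip = lclip, right_clip = rclip)
}

# Pair scores for the duplex engine: GC=3, AU=2, GU wobble=1 (configurable
# off); anything else unpairable. Codes from encode_seq: A=1 C=2 G=3 U/T=4.
pair_score <- function(a, b, wobble = TRUE) {
  if ((a == 3L && b == 2L) || (a == 2L && b == 3L)) return(3)
  if ((a == 1L && b == 4L) || (a == 4L && b == 1L)) return(2)
  if (wobble && ((a == 3L && b == 4L) || (a == 4L && b == 3L))) return(1)
  -Inf
}

#' Predict the intermolecular duplex between a small RNA and a target window
#'
#' Deterministic dynamic program over antiparallel non-crossing base pairings
#' between the query and the window. Watson-Crick pairs score GC=3, AU=2 and
#' (optionally) G.U wobble=1, with a +1 stacking bonus for each pair directly
#' stacked on the previous one; no intramolecular structure is considered.
#' The reported structure maximizes this score; `energy` is the negative of
#' the optimal score (arbitrary units, lower = more stable).
#'
#' @param query List with `id`/`seq` or single-record `SequenceLibrary`
#'   (RNA or DNA; T is read as U).
#' @param window Target window as from [target_window()] (list with
#'   `id`/`seq`), or a plain string.
#' @param wobble Allow G.U pairs (default TRUE).
#' @return A `DuplexStructure`: list with `query_struct` (over `(` and `.`),
#'   `target_struct` (over `)` and `.`), `pairs` (0-based `(query_pos,
#'   target_pos)` matrix), `energy` and `score`.
#' @export
predict_duplex <- function(query, window, wobble = TRUE) {
  qseq <- if (is.character(query)) query else if (inherits(query, "SequenceLibrary")) query$seq[1] else query$seq
  wseq <- if (is.character(window)) window else window$seq
  qseq <- toupper(qseq); wseq <- toupper(wseq)
  if (grepl("N", qseq, fixed = TRUE) || grepl("N", wseq, fixed = TRUE)) {
    stop("sequence contains N; no duplex predicted")
  }
  n <- nchar(qseq); m <- nchar(wseq)
  stopifnot(n >= 4L, m >= 4L)
  q <- encode_seq(to_dna(qseq))
  # reverse the window so the antiparallel matching becomes monotone
  v <- rev(encode_seq(to_dna(wseq)))
  ps <- matrix(-Inf, n, m)
  for (i in seq_len(n)) for (k in seq_len(m)) ps[i, k] <- pair_score(q[i], v[k], wobble)
  # M[i,k]: best score with (i,k) paired; G[i,k]: best score over prefixes
  M <- matrix(-Inf, n + 1L, m + 1L)
  G <- matrix(0, n + 1L, m + 1L)
  for (i in seq_len(n)) {
    for (k in seq_len(m)) {
      if (is.finite(ps[i, k])) {
        stacked <- M[i, k] + 1
        open <- G[i, k]
        M[i + 1L, k + 1L] <- ps[i, k] + max(stacked, open)
      }
      G[i + 1L, k + 1L] <- max(G[i, k + 1L], G[i + 1L, k], M[i + 1L, k + 1L])
    }
  }
  score <- G[n + 1L, m + 1L]
  # traceback (deterministic preference: pair > skip query > skip window)
  pairs <- matrix(integer(0), ncol = 2)
  i <- n; k <- m; in_m <- FALSE
  while (i > 0L && k > 0L) {
    if (!in_m) {
      if (G[i + 1L, k + 1L] == M[i + 1L, k + 1L] && is.finite(M[i + 1L, k + 1L])) {
        in_m <- TRUE
      } else if (G[i + 1L, k + 1L] == G[i, k + 1L]) {
        i <- i - 1L
      } else {
        k <- k - 1L
      }
    } else {
      pairs <- rbind(pairs, c(i, k))
      stacked <- M[i, k] + 1
      open <- G[i, k]
      if (is.finite(M[i, k]) && stacked >= open &&
          M[i + 1L, k + 1L] == ps[i, k] + stacked) {
        i <- i - 1L; k <- k - 1L  # stay in M (stacked pair)
      } else {
        i <- i - 1L; k <- k - 1L; in_m <- FALSE
      }
    }
  }
  qs <- rep(".", n); ts <- rep(".", m)
  if (nrow(pairs)) {
    pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
    wpos <- m + 1L - pairs[, 2]          # back to window coordinates
    qs[pairs[, 1]] <- "("
    ts[wpos] <- ")"
    pairs0 <- cbind(query_pos = pairs[, 1] - 1L, target_pos = wpos - 1L)
  } else {
    pairs0 <- cbind(query_pos = integer(0), target_pos = integer(0))
  }
  structure(
    list(query_struct = paste(qs, collapse = ""),
         target_struct = paste(ts, collapse = ""),
         pairs = pairs0,
         score = score,
         energy = -score,
         query_seq = to_rna(qseq),
         target_seq = to_rna(wseq)),
    class = "DuplexStructure"
  )
}

#' @export
print.DuplexStructure <- function(x, ...) {
  cat(x$query_seq, "\n", x$query_struct, "\n", x$target_struct, "\n",
      x$target_seq, "\n", sprintf("energy: %g\n", x$energy), sep = "")
  invisible(x)
}

#' Serialize a duplex as a three-line text block
#'
#' Query sequence+structure, window sequence+structure, energy -- mirroring
#' the usual visual layout of an RNA-RNA interaction.
#'
#' @param dx A `DuplexStructure`.
#' @return Character vector of three lines.
#' @export
format_duplex <- function(dx) {
  c(paste(dx$query_seq, dx$query_struct),
    paste(dx$target_seq, dx$target_struct),
    sprintf("energy=%g", dx$energy))
}

#' Select the best hit and its duplex for a multi-mapping query
#'
#' Rule: fewest alignment mismatches, then lowest duplex energy, then
#' lexicographic `(target_id, offset, strand)` order.
#'
#' @param query List with `id`/`seq` (query record).
#' @param hits Hit data frame for this query (nonempty).
#' @param targets `SequenceLibrary` of targets.
#' @param flank Flank passed to [target_window()].
#' @return List with elements `hit` (one-row data frame) and `duplex`
#'   (`DuplexStructure`).
#' @export
best_duplex <- function(query, hits, targets, flank = 0L) {
  if (is.null(hits) || nrow(hits) == 0L) {
    stop("not transposon-associated: no hits for query ", query$id)
  }
  qlen <- nchar(query$seq)
  hits <- hits[order(hits$target_id, hits$offset, hits$strand), , drop = FALSE]
  dups <- vector("list", nrow(hits))
  energy <- numeric(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    win <- target_window(hits[i, ], targets, qlen, flank = flank)
    dups[[i]] <- predict_duplex(list(id = query$id, seq = to_rna(query$seq)), win)
    energy[i] <- dups[[i]]$energy
  }
  best <- order(hits$mismatches, energy)[1]
  list(hit = hits[best, , drop = FALSE], duplex = dups[[best]])
}
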