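# Independent oracles and small fixture builders shared across tests.
# These deliberately avoid the package's own search/DP/counting code paths.

random_library <- function(n, min_len = 20, max_len = 30, seed = 1,
                           prefix = "r", alphabet = c("A", "C", "G", "T")) {
  withr::with_seed(seed, {
    lens <- min_len + sample.int(max_len - min_len + 1L, n, replace = TRUE) - 1L
    seqs <- vapply(lens, function(L) {
      paste(sample(alphabet, L, replace = TRUE), collapse = "")
    }, character(1))
  })
  sequence_library(paste0(prefix, seq_len(n)), seqs)
}

# Brute-force Hamming scan over every offset of every target, both strands.
# Matrix-encoded windows; completely independent of the seeded search.
brute_scan <- function(qid, qseq, targets, k, strands = c("+", "-")) {
  code <- c(A = 1L, C = 2L, G = 3L, T = 4L, U = 4L)
  enc <- function(s) unname(code[strsplit(s, "", fixed = TRUE)[[1]]])
  rc <- function(s) chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  res <- list()
  for (st in strands) {
    q <- enc(if (st == "+") qseq else rc(qseq))
    L <- length(q)
    for (t in seq_along(targets$id)) {
      tv <- enc(targets$seq[t])
      if (length(tv) < L) next
      noff <- length(tv) - L + 1L
      win <- matrix(tv[outer(0:(L - 1L), seq_len(noff), `+`)], nrow = L)
      mm <- colSums(win != q)
      hit <- which(mm <= k)
      if (length(hit)) {
        res[[length(res) + 1L]] <- data.frame(
          query_id = qid, target_id = targets$id[t], offset = hit - 1L,
          strand = st, mismatches = as.integer(mm[hit]), stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(query_id = character(), target_id = character(),
                      offset = integer(), strand = character(),
                      mismatches = integer(), stringsAsFactors = FALSE)
  }
  out <- out[order(out$target_id, out$offset, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Exhaustive enumeration of antiparallel non-crossing WC/wobble matchings
# under the duplex scoring (GC=3, AU=2, GU=1, +1 per stacked pair).
# Returns the optimal score and the set of pair counts among optima.
brute_duplex <- function(qseq, wseq, wobble = TRUE) {
  code <- c(A = 1L, C = 2L, G = 3L, T = 4L, U = 4L)
  q <- unname(code[strsplit(toupper(qseq), "")[[1]]])
  w <- unname(code[strsplit(toupper(wseq), "")[[1]]])
  pscore <- function(a, b) {
    if ((a == 3 && b == 2) || (a == 2 && b == 3)) return(3)
    if ((a == 1 && b == 4) || (a == 4 && b == 1)) return(2)
    if (wobble && ((a == 3 && b == 4) || (a == 4 && b == 3))) return(1)
    NA_real_
  }
  n <- length(q); m <- length(w)
  best <- list(score = 0, npairs = integer(0))
  # recurse over query positions; j must strictly decrease (antiparallel)
  rec <- function(i, jmax, score, pairs, last) {
    # last = c(i, j) of the previous pair or NULL
    if (score > best$score) best <<- list(score = score, npairs = length(pairs))
    else if (score == best$score) {
      best$npairs <<- unique(c(best$npairs, length(pairs)))
    }
    if (i > n || jmax < 1) return()
    rec(i + 1L, jmax, score, pairs, last)   # leave i unpaired
    for (j in seq_len(jmax)) {
      ps <- pscore(q[i], w[j])
      if (is.na(ps)) next
      stack <- if (!is.null(last) && last[1] == i - 1L && last[2] == j + 1L) 1 else 0
      rec(i + 1L, j - 1L, score + ps + stack, c(pairs, j), c(i, j))
    }
  }
  rec(1L, m, 0, integer(0), NULL)
  best
}

# Brute-force triplet window tally.
brute_triplets <- function(struct, seq) {
  seq <- chartr("T", "U", toupper(seq))
  L <- nchar(seq)
  v <- setNames(numeric(32), triplet_alphabet())
  for (c in 2:(L - 1)) {
    el <- paste0(substr(struct, c - 1, c + 1), substr(seq, c, c))
    v[el] <- v[el] + 1
  }
  v / (L - 2)
}
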