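#' Empirical length distribution of a library
#'
#' Normalized histogram of record lengths over the 20-30 nt support used by
#' the pseudo-piRNA generator. Records outside 20-30 nt are reported with a
#' warning and excluded from the (renormalized) distribution.
#'
#' @param lib A nonempty `SequenceLibrary`.
#' @return A `LengthDistribution`: named numeric vector of probabilities over
#'   lengths 20..30 summing to 1.
#' @export
length_distribution <- function(lib) {
  if (length(lib) == 0L) stop("library is empty")
  len <- seq_lengths(lib)
  out_of_range <- len < 20L | len > 30L
  if (any(out_of_range)) {
    warning(sum(out_of_range), " record(s) outside 20-30 nt excluded from the length distribution")
    len <- len[!out_of_range]
    if (!length(len)) stop("no records within 20-30 nt")
  }
  counts <- table(factor(len, levels = 20:30))
  p <- as.numeric(counts) / sum(counts)
  structure(setNames(p, 20:30), class = "LengthDistribution")
}

# Largest-remainder apportionment of n into quotas proportional to p.
apportion <- function(n, p) {
  raw <- n * p / sum(p)
  q <- floor(raw)
  rem <- n - sum(q)
  if (rem > 0) {
    extra <- order(raw - q, decreasing = TRUE)[seq_len(rem)]
    q[extra] <- q[extra] + 1
  }
  as.integer(q)
}

#' Generate a pseudo-piRNA negative set by double randomization
#'
#' Emulates the construction of a negative class from an unrelated ncRNA
#' pool: (1) pool sequences identical to an exclusion sequence are removed;
#' (2) repeatedly a random pool sequence is chosen and a random 20-30 nt
#' fragment cut from it (double randomization); (3) fragments are kept only
#' if they map to the transposon index with at most `max_mismatches`
#' substitutions; (4) surviving fragments are deduplicated and fragments
#' identical to an exclusion are dropped; (5) survivors are subsampled per
#' length bin to match `target_dist` (largest-remainder quotas). Fully
#' reproducible from `seed`.
#'
#' @param pool `SequenceLibrary` of donor (ncRNA) sequences.
#' @param exclusions `SequenceLibrary` of sequences that must not appear
#'   (the real piRNAs).
#' @param index `TargetIndex` over the transposon library.
#' @param n Requested number of pseudo piRNAs.
#' @param target_dist `LengthDistribution` to match (e.g. of the real
#'   piRNAs); `NULL` for uniform over 20-30.
#' @param max_mismatches Mappability threshold (default 3).
#' @param seed Integer seed.
#' @param oversample Candidate fragments drawn per requested output record
#'   before filtering (default 20).
#' @return `SequenceLibrary` of at most `n` pseudo piRNAs (ids `pseudo1`,
#'   `pseudo2`, ...). Underfilled length bins trigger a warning and a
#'   shorter output.
#' @export
generate_pseudo <- function(pool, exclusions, index, n,
                            target_dist = NULL, max_mismatches = 3L,
                            seed = 1L, oversample = 20L) {
  excl_set <- unique(to_dna(exclusions$seq))
  keep <- !(to_dna(pool$seq) %in% excl_set)
  pool <- pool[keep]
  if (length(pool) == 0L) stop("pool is empty after exclusion removal")
  if (is.null(target_dist)) {
    target_dist <- structure(setNames(rep(1 / 11, 11), 20:30),
                             class = "LengthDistribution")
  }
  pool_len <- seq_lengths(pool)
  usable <- which(pool_len >= 20L)
  if (!length(usable)) stop("no pool sequence is at least 20 nt")
  n_cand <- n * oversample
  frags <- withr::with_seed(seed, {
    src <- sample(usable, n_cand, replace = TRUE)
    flen <- sample(20:30, n_cand, replace = TRUE)
    flen <- pmin(flen, pool_len[src])
    start <- floor(runif(n_cand) * (pool_len[src] - flen + 1)) + 1L
    substring(pool$seq[src], start, start + flen - 1L)
  })
  frags <- to_dna(frags)
  frags <- unique(frags)
  frags <- frags[!(frags %in% excl_set)]
  frags <- frags[nchar(frags) >= 20L & nchar(frags) <= 30L]
  if (length(frags)) {
    mappable <- vapply(seq_along(frags), function(i) {
      nrow(align(list(id = "f", seq = frags[i]), index,
                 max_mismatches = max_mismatches)) > 0L
    }, logical(1))
    frags <- frags[mappable]
  }
  if (!length(frags)) {
    warning("no candidate fragment mapped to the transposon index; empty output")
    return(sequence_library(character(), character(), source_tag = "pseudo"))
  }
  quotas <- apportion(n, as.numeric(target_dist))
  names(quotas) <- names(target_dist)
  flen <- nchar(frags)
  chosen <- character(0)
  short <- FALSE
  chosen <- withr::with_seed(seed + 1L, {
    sel <- character(0)
    for (l in names(quotas)) {
      q <- quotas[[l]]
      if (q == 0L) next
      bin <- frags[flen == as.integer(l)]
      if (length(bin) < q) {
        short <<- TRUE
        sel <- c(sel, bin)
      } else {
        sel <- c(sel, sample(bin, q))
      }
    }
    sel
  })
  if (short) {
    warning("insufficient mappable fragments in some length bin(s); returning ",
            length(chosen), " of ", n, " requested")
  }
  sequence_library(paste0("pseudo", seq_along(chosen)), chosen,
                   source_tag = "pseudo", alphabet = pool$alphabet)
}
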