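#' Generate a toy transposon library
#'
#' Random uniform-composition DNA sequences with a class label (SINE, LINE,
#' LTR, DNA, ...) assigned round-robin and recorded in the id as
#' `class=NAME`. Byte-identical for identical seeds.
#'
#' @param n Number of transposons.
#' @param length Length of each (nt).
#' @param classes Character vector of class labels to cycle over.
#' @param seed Integer seed.
#' @return A `SequenceLibrary`; the class of each record is available via
#'   [transposon_classes()].
#' @export
make_transposons <- function(n, length = 1000L,
                             classes = c("SINE", "LINE", "LTR", "DNA"),
                             seed = 1L) {
  stopifnot(n > 0, length > 0)
  seqs <- withr::with_seed(seed, {
    vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = "")
    }, character(1))
  })
  cls <- rep(classes, length.out = n)
  ids <- sprintf("TE%03d class=%s", seq_len(n), cls)
  lib <- sequence_library(sub(" .*", "", ids), seqs, source_tag = "synthetic-transposons")
  attr(lib, "headers") <- setNames(ids, lib$id)
  lib
}

#' Transposon class map from FASTA headers
#'
#' Parses the `class=NAME` token from record headers (as produced by
#' [make_transposons()] or present in an input FASTA); ids without the token
#' map to `"other"`.
#'
#' @param lib A `SequenceLibrary` carrying a `"headers"` attribute.
#' @return Named character vector: target id -> class.
#' @export
transposon_classes <- function(lib) {
  headers <- attr(lib, "headers")
  if (is.null(headers)) headers <- setNames(lib$id, lib$id)
  cls <- ifelse(grepl("class=", headers),
                sub(".*class=([^ ]+).*", "\\1", headers), "other")
  setNames(unname(cls), lib$id)
}

#' Plant transposon-derived positive-like reads
#'
#' Reads are substrings of the transposons (half of them reverse
#' complemented) of 24-30 nt with a peaked length distribution, carrying
#' 0-3 substitutions (the per-read substitution count is Binomial(3,
#' `mismatch_rate`), so every read remains mappable at three mismatches).
#' An optional 5'-U bias sets the first nucleotide to T/U with the given
#' probability.
#'
#' @param transposons `SequenceLibrary` of donors.
#' @param n Number of reads.
#' @param length_weights Named numeric vector of sampling weights over
#'   lengths 24..30 (default peaks at 26 nt, the fly-like mode).
#' @param mismatch_rate Per-read substitution intensity in `[0, 1]`.
#' @param five_prime_u Probability that a read starts with U.
#' @param seed Integer seed.
#' @return `SequenceLibrary` of reads (ids `read1`, ...).
#' @export
plant_positive_reads <- function(transposons, n,
                                 length_weights = c(`24` = 1, `25` = 3, `26` = 5,
                                                    `27` = 3, `28` = 2, `29` = 1,
                                                    `30` = 0.5),
                                 mismatch_rate = 0.15,
                                 five_prime_u = 0,
                                 seed = 1L) {
  stopifnot(length(transposons) > 0)
  lens <- as.integer(names(length_weights))
  tlen <- seq_lengths(transposons)
  if (max(lens) > max(tlen)) stop("requested read length exceeds every target length")
  bases <- c("A", "C", "G", "T")
  seqs <- withr::with_seed(seed, {
    out <- character(n)
    for (i in seq_len(n)) {
      L <- sample(lens, 1, prob = length_weights)
      t <- sample(which(tlen >= L), 1)
      start <- sample.int(tlen[t] - L + 1L, 1)
      s <- substr(transposons$seq[t], start, start + L - 1L)
      if (runif(1) < 0.5) s <- revcomp(s)
      nmm <- rbinom(1, 3, mismatch_rate)
      if (nmm > 0) {
        pos <- sample.int(L, nmm)
        ch <- strsplit(s, "", fixed = TRUE)[[1]]
        for (p in pos) ch[p] <- sample(setdiff(bases, ch[p]), 1)
        s <- paste(ch, collapse = "")
      }
      if (five_prime_u > 0 && runif(1) < five_prime_u) {
        substr(s, 1, 1) <- "T"
      }
      out[i] <- s
    }
    out
  })
  sequence_library(paste0("read", seq_len(n)), seqs, source_tag = "planted-positives")
}

# Elements whose concentration is raised in each class; chosen to mimic the
# qualitative class difference seen in real data: fully paired triplets
# (especially with G/C middle nucleotides) enriched in real piRNAs,
# two-paired-one-unpaired patterns enriched in pseudo piRNAs.
.POS_ENRICHED <- c("(((A", "(((C", "(((G", "(((U")
.NEG_ENRICHED <- c("((.A", "((.C", "((.G", "((.U",
                   "(..A", "(..C", "(..G", "(..U")

#' Simulate labeled 32-dimensional triplet-frequency vectors
#'
#' Dirichlet-distributed frequency vectors (rows sum to 1) whose class mean
#' profiles differ along a fixed subset of elements: fully paired triplets
#' are enriched in the positive class, partially paired ones in the negative
#' class, scaled by `separation` (0 = exchangeable classes).
#'
#' @param n_pos,n_neg Samples per class.
#' @param separation Non-negative effect size; the default 1 gives a
#'   well-separated but noisy problem (see the package vignette).
#' @param concentration Total Dirichlet concentration (noise level; larger =
#'   less sample noise). Default 60.
#' @param seed Integer seed.
#' @return A `LabeledDataset` with 32 named feature columns.
#' @export
make_labeled_features <- function(n_pos, n_neg, separation = 1,
                                  concentration = 60, seed = 1L) {
  stopifnot(separation >= 0)
  elems <- triplet_alphabet()
  base <- setNames(rep(1, 32), elems)
  alpha_pos <- base; alpha_neg <- base
  alpha_pos[.POS_ENRICHED] <- alpha_pos[.POS_ENRICHED] + separation
  alpha_neg[.NEG_ENRICHED] <- alpha_neg[.NEG_ENRICHED] + separation / 2
  alpha_pos <- alpha_pos / sum(alpha_pos) * concentration
  alpha_neg <- alpha_neg / sum(alpha_neg) * concentration
  rdirichlet <- function(n, alpha) {
    g <- matrix(rgamma(n * length(alpha), shape = rep(alpha, each = n)),
                nrow = n)
    g / rowSums(g)
  }
  withr::with_seed(seed, {
    xp <- rdirichlet(n_pos, alpha_pos)
    xn <- rdirichlet(n_neg, alpha_neg)
  })
  x <- rbind(xp, xn)
  colnames(x) <- elems
  labeled_dataset(x, c(rep(1, n_pos), rep(-1, n_neg)),
                  ids = c(paste0("pos", seq_len(n_pos)),
                          paste0("neg", seq_len(n_neg))))
}

#' Write the full synthetic fixture set to a directory
#'
#' Writes `transposons.fa`, `positives.fa`, `pool.fa` (random-sequence ncRNA
#' stand-ins for the negative generator) and `classes.tsv`.
#'
#' @param out_dir Output directory (created if missing).
#' @param seed Integer seed.
#' @param n_transposons,n_positives,n_pool Sizes of the three libraries.
#' @return Named list of file paths, invisibly.
#' @export
make_fixtures <- function(out_dir, seed = 42L, n_transposons = 8L,
                          n_positives = 150L, n_pool = 60L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  te <- make_transposons(n_transposons, length = 800L, seed = seed)
  pos <- plant_positive_reads(te, n_positives, seed = seed + 1L)
  # pool: diverged (~12% substituted) transposon fragments embedded in random
  # sequence. Random 20-30mers of these still map at <=3 mismatches often
  # enough to yield pseudo reads, but with more mismatches -- hence weaker
  # duplexes -- than the planted positives, as for genuine ncRNA fragments.
  pool <- withr::with_seed(seed + 2L, {
    bases <- c("A", "C", "G", "T")
    seqs <- vapply(seq_len(n_pool), function(i) {
      t <- sample(length(te$id), 1)
      start <- sample.int(nchar(te$seq[t]) - 200L, 1)
      core <- strsplit(substr(te$seq[t], start, start + 199L), "", fixed = TRUE)[[1]]
      mut <- which(runif(length(core)) < 0.12)
      for (p in mut) core[p] <- sample(setdiff(bases, core[p]), 1)
      pad <- function(k) paste(sample(bases, k, replace = TRUE), collapse = "")
      paste0(pad(30), paste(core, collapse = ""), pad(30))
    }, character(1))
    sequence_library(paste0("ncrna", seq_len(n_pool)), seqs, source_tag = "pool")
  })
  paths <- list(
    transposons = file.path(out_dir, "transposons.fa"),
    positives = file.path(out_dir, "positives.fa"),
    pool = file.path(out_dir, "pool.fa"),
    classes = file.path(out_dir, "classes.tsv")
  )
  write_fasta(te, paths$transposons)
  write_fasta(pos, paths$positives)
  write_fasta(pool, paths$pool)
  cls <- transposon_classes(te)
  write.table(data.frame(target_id = names(cls), class = unname(cls)),
              paths$classes, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
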