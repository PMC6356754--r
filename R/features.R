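#' Canonical k-mer feature names
#'
#' The 84 content features, in canonical order: the 4 mononucleotides
#' `A,C,G,T`, the 16 dinucleotides `AA..TT` and the 64 trinucleotides
#' `AAA..TTT`, each block in lexicographic order.
#'
#' @return Character vector of length 84.
#' @export
kmer_feature_names <- function() {
  b <- c("A", "C", "G", "T")
  k2 <- as.vector(t(outer(b, b, paste0)))
  k3 <- as.vector(aperm(outer(outer(b, b, paste0), b, paste0), c(3, 2, 1)))
  c(b, sort(k2), sort(k3))
}

#' Count k-mers with N-window exclusion
#'
#' Counts every length-`k` window of a normalised base string over the
#' alphabet `{A,C,G,T}`. Windows containing `N` are excluded from both the
#' counts and the valid-window total, so `N` never acts as a fifth symbol.
#'
#' @param bases A single normalised base string (alphabet `ACGTN`).
#' @param k Window width, 1, 2 or 3.
#' @return A list with `counts` (named integer vector over `{A,C,G,T}^k`,
#'   lexicographic) and `valid_windows` (number of N-free windows, at most
#'   `nchar(bases) - k + 1`).
#' @examples
#' count_kmers("ACNG", 2) # only the AC window is valid
#' @export
count_kmers <- function(bases, k) {
  stopifnot(length(bases) == 1L, is.character(bases))
  if (!k %in% 1:3) abort("k must be 1, 2 or 3")
  if (nchar(bases) < k) {
    counts <- stats::setNames(integer(4^k),
                              kmer_feature_names()[kmer_block_index(k)])
    return(list(counts = counts, valid_windows = 0L))
  }
  m <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAStringSet(bases), width = k
  )
  counts <- as.integer(m[1, ])
  names(counts) <- colnames(m)
  list(counts = counts, valid_windows = sum(counts))
}

#' Compute the 84-dimensional content feature vector of one read
#'
#' For each order k in 1..3, a k-mer's content is its count divided by the
#' number of valid (N-free) length-k windows of the read, so that for an
#' N-free read of length >= 3 each order's block sums to 1 and features are
#' comparable across reads of very different lengths. An order with zero
#' valid windows contributes an all-zero block.
#'
#' @param bases A single normalised base string.
#' @return Named numeric vector of length 84 in the [kmer_feature_names()]
#'   order, entries in `[0, 1]`.
#' @examples
#' f <- compute_features("ACG")
#' f[c("A", "AC", "ACG")]
#' @export
compute_features <- function(bases) {
  if (nchar(bases) < 3L) {
    warn(paste0("read of length ", nchar(bases),
                " < 3: trinucleotide features are zero"))
  }
  out <- unlist(lapply(1:3, function(k) {
    kc <- count_kmers(bases, k)
    if (kc$valid_windows == 0L) {
      kc$counts * 0
    } else {
      kc$counts / kc$valid_windows
    }
  }))
  names(out) <- kmer_feature_names()
  out
}

#' Feature matrix for a set of reads
#'
#' Featurises every read of a read tibble, preserving input order. This is
#' the row space of the linear quality model: one 84-column row per read.
#'
#' @param reads Read tibble with columns `read_id` and `bases` (see
#'   [read_sequences()]).
#' @return A tibble with `read_id` followed by the 84 named k-mer content
#'   columns, one row per read in input order.
#' @export
sq_features <- function(reads) {
  stopifnot(is.data.frame(reads), all(c("read_id", "bases") %in% names(reads)))
  if (nrow(reads) == 0L) abort("no reads to featurise")
  nm <- kmer_feature_names()
  short <- nchar(reads$bases) < 3L
  if (any(short)) {
    inform(paste0(sum(short), " read(s) shorter than 3 bases: ",
                  "higher-order features are zero"))
  }
  set <- Biostrings::DNAStringSet(reads$bases)
  blocks <- lapply(1:3, function(k) {
    counts <- Biostrings::oligonucleotideFrequency(set, width = k)
    valid <- rowSums(counts)
    frac <- counts / ifelse(valid == 0, 1, valid)
    frac
  })
  mat <- do.call(cbind, blocks)
  colnames(mat) <- nm
  dplyr::bind_cols(
    tibble::tibble(read_id = reads$read_id),
    tibble::as_tibble(mat)
  )
}

# column indices of the order-k block within the 84-feature layout
kmer_block_index <- function(k) {
  switch(k, `1` = 1:4, `2` = 5:20, `3` = 21:84)
}

# feature tibble -> bare matrix (rows in tibble order)
feature_matrix_of <- function(features) {
  m <- as.matrix(features[, kmer_feature_names(), drop = FALSE])
  rownames(m) <- features$read_id
  m
}
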