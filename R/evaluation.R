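#' Parse read-to-reference alignments from PAF or SAM
#'
#' Normalises aligner output into one row per alignment with the quantities
#' the quality metrics need: matched bases, aligned reference span and
#' mismatch rate.
#'
#' For PAF, matches are column 10 (residue matches), the reference span is
#' `target_end - target_start`, and the mismatch rate is
#' `1 - matches / alignment_block_length` (column 11). For SAM, the same
#' quantities are derived from the CIGAR string and the `NM` tag
#' (mismatches = NM - inserted - deleted bases); unmapped records are
#' skipped and counted.
#'
#' @param path Path to a PAF or SAM file.
#' @param format `"auto"` (from extension), `"paf"` or `"sam"`.
#' @return A tibble with columns `read_id`, `ref_id`, `read_length`,
#'   `overlap_length` (reference span), `matches`, `mismatch_rate` and
#'   `strand`.
#' @export
parse_alignments <- function(path, format = c("auto", "paf", "sam")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (format == "auto") {
    format <- if (grepl("\\.sam$", path, ignore.case = TRUE)) "sam" else "paf"
  }
  switch(format, paf = parse_paf(path), sam = parse_sam(path))
}

parse_paf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    warn(paste0("no alignments in ", path))
    return(empty_alignments())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 12L)) {
    abort(paste0("PAF parse error at line ", which(nf < 12L)[1],
                 ": fewer than 12 columns"))
  }
  num <- function(i) {
    v <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", i)))
    if (anyNA(v)) {
      abort(paste0("PAF parse error at line ", which(is.na(v))[1],
                   ": column ", i, " is not numeric"))
    }
    v
  }
  chr <- function(i) vapply(fields, `[[`, "", i)
  matches <- num(10)
  block <- num(11)
  tstart <- num(8)
  tend <- num(9)
  tibble::tibble(
    read_id = chr(1),
    ref_id = chr(6),
    read_length = num(2),
    overlap_length = tend - tstart,
    matches = matches,
    mismatch_rate = ifelse(block > 0, 1 - matches / block, 1),
    strand = chr(5)
  )
}

parse_sam <- function(path) {
  bam <- Rsamtools::asBam(path,
                          destination = tempfile(),
                          overwrite = TRUE, indexDestination = FALSE)
  on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "strand", "cigar", "qwidth"),
    tag = "NM"
  )
  res <- Rsamtools::scanBam(bam, param = p)[[1]]
  unmapped <- bitwAnd(res$flag, 4L) != 0L
  if (any(unmapped)) {
    inform(paste0("skipped ", sum(unmapped), " unmapped SAM record(s)"))
  }
  keep <- !unmapped
  if (!any(keep)) {
    warn(paste0("no mapped alignments in ", path))
    return(empty_alignments())
  }
  cigar <- res$cigar[keep]
  ops <- cigar_op_lengths(cigar)
  nm <- res$tag$NM[keep]
  if (is.null(nm)) nm <- rep(NA_real_, sum(keep))
  if (anyNA(nm)) {
    warn("NM tag missing on some SAM records; assuming zero mismatches there")
    nm[is.na(nm)] <- ops$ins[is.na(nm)] + ops$del[is.na(nm)]
  }
  mismatches <- pmax(nm - ops$ins - ops$del, 0)
  matches <- ops$aln - mismatches
  block <- ops$aln + ops$ins + ops$del
  tibble::tibble(
    read_id = res$qname[keep],
    ref_id = as.character(res$rname[keep]),
    read_length = res$qwidth[keep],
    overlap_length = ops$aln + ops$del,
    matches = matches,
    mismatch_rate = ifelse(block > 0, 1 - matches / block, 1),
    strand = ifelse(bitwAnd(res$flag[keep], 16L) != 0L, "-", "+")
  )
}

# total lengths of aligned (M/=/X), inserted (I) and deleted (D) bases
cigar_op_lengths <- function(cigar) {
  per <- lapply(regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar)),
                function(tok) {
                  len <- as.numeric(sub("[MIDNSHP=X]$", "", tok))
                  op <- sub("^\\d+", "", tok)
                  c(aln = sum(len[op %in% c("M", "=", "X")]),
                    ins = sum(len[op == "I"]),
                    del = sum(len[op == "D"]))
                })
  m <- do.call(rbind, per)
  list(aln = m[, "aln"], ins = m[, "ins"], del = m[, "del"])
}

empty_alignments <- function() {
  tibble::tibble(read_id = character(), ref_id = character(),
                 read_length = numeric(), overlap_length = numeric(),
                 matches = numeric(), mismatch_rate = numeric(),
                 strand = character())
}

#' Alignment quality filter
#'
#' An alignment counts toward the aligned rate only if its reference overlap
#' exceeds 2,000 bp (strictly) and its mismatch rate is strictly below twice
#' the assumed per-read error rate.
#'
#' @param alignments Alignment tibble from [parse_alignments()] (columns
#'   `overlap_length` and `mismatch_rate`).
#' @param read_error_rate Assumed read error rate, in `(0, 0.5)`. Default
#'   0.15, the midpoint error of 2D Nanopore reads (80–88% accuracy).
#' @return Logical vector, one entry per alignment.
#' @export
passes_alignment_filter <- function(alignments, read_error_rate = 0.15) {
  if (!is.numeric(read_error_rate) || read_error_rate <= 0 ||
      read_error_rate >= 0.5) {
    abort("read_error_rate must be in (0, 0.5)")
  }
  alignments$overlap_length > 2000 &
    alignments$mismatch_rate < 2 * read_error_rate
}

#' Aligned rate
#'
#' The percentage of reads with at least one passing alignment:
#' `n / N * 100`, reported to two decimals.
#'
#' @param n Number of aligned reads.
#' @param N Total number of reads (positive).
#' @return Percentage in `[0, 100]`, rounded to 2 decimals.
#' @examples
#' aligned_rate(27238, 30265)
#' @export
aligned_rate <- function(n, N) {
  if (any(N <= 0)) abort("N must be positive")
  if (any(n < 0 | n > N)) abort("need 0 <= n <= N")
  round(n / N * 100, 2)
}

#' Alignment identity
#'
#' The percentage of the aligned reference span covered by matched bases:
#' `matches / ref_span * 100`. The denominator is the aligned reference span
#' (target end minus target start), not the whole reference length, so the
#' quantity is meaningful per read.
#'
#' @param matches Number of matched bases.
#' @param ref_span Aligned reference span (positive).
#' @return Percentage in `[0, 100]`.
#' @examples
#' alignment_identity(8816, 10000)
#' @export
alignment_identity <- function(matches, ref_span) {
  if (any(ref_span <= 0)) abort("ref_span must be positive")
  if (any(matches < 0 | matches > ref_span)) {
    abort("need 0 <= matches <= ref_span")
  }
  matches / ref_span * 100
}

#' Pearson correlation with validation
#'
#' Definitional Pearson product-moment correlation between two equal-length
#' vectors, with explicit errors for the undefined cases.
#'
#' @param x,y Numeric vectors of equal length >= 2 with nonzero variance.
#' @return Correlation in `[-1, 1]`.
#' @export
sq_pearson <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) < 2L) abort("need at least 2 observations")
  if (anyNA(x) || anyNA(y)) abort("missing values in correlation input")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    abort("undefined correlation: zero variance")
  }
  stats::cor(x, y, method = "pearson")
}

#' Summarise a read set against its alignments
#'
#' Computes the standard per-dataset summary: read count and length range,
#' the number of reads with at least one passing alignment, the aligned rate
#' and the mean/median identity. A read with several passing alignments
#' counts once, and its identity comes from its best (most matched bases)
#' passing alignment.
#'
#' @param reads Read tibble.
#' @param alignments Alignment tibble from [parse_alignments()].
#' @inheritParams passes_alignment_filter
#' @return One-row tibble: `num_reads`, `max_length`, `min_length`,
#'   `mean_length`, `n_aligned`, `aligned_rate`, `mean_identity`,
#'   `median_identity` (identity fields `NA` when nothing aligns).
#' @export
summarize_read_set <- function(reads, alignments, read_error_rate = 0.15) {
  if (!is.data.frame(reads) || nrow(reads) == 0L) abort("empty read set")
  lens <- nchar(reads$bases)
  best <- best_alignments(alignments, read_error_rate)
  best <- best[best$read_id %in% reads$read_id, , drop = FALSE]
  n_aligned <- nrow(best)
  tibble::tibble(
    num_reads = nrow(reads),
    max_length = max(lens),
    min_length = min(lens),
    mean_length = mean(lens),
    n_aligned = n_aligned,
    aligned_rate = aligned_rate(n_aligned, nrow(reads)),
    mean_identity = if (n_aligned > 0) round(mean(best$identity), 2) else NA_real_,
    median_identity = if (n_aligned > 0) round(median(best$identity), 2) else NA_real_
  )
}

# one row per read with >= 1 passing alignment: its best hit + identity
best_alignments <- function(alignments, read_error_rate = 0.15) {
  ok <- passes_alignment_filter(alignments, read_error_rate)
  passing <- alignments[ok, , drop = FALSE]
  if (nrow(passing) == 0L) {
    return(dplyr::mutate(empty_alignments(), identity = numeric()))
  }
  passing |>
    dplyr::group_by(.data$read_id) |>
    dplyr::slice_max(.data$matches, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::mutate(identity = alignment_identity(.data$matches,
                                                .data$overlap_length))
}

#' Relate quality scores to alignment identity
#'
#' Joins a score table to per-read alignment identities and reports the
#' Pearson correlation between score and identity together with the score
#' distribution per 5-point identity bin (bins with no members are reported
#' with zero counts, not dropped).
#'
#' @param scores Score tibble (`read_id`, `sq`) from [cross_score()].
#' @param identities Either an alignment tibble from [parse_alignments()]
#'   (reduced to best passing hits internally) or a tibble with columns
#'   `read_id` and `identity` (percent).
#' @inheritParams passes_alignment_filter
#' @return An `sq_evaluation`: list with `pearson`, `n` (reads joined),
#'   `bins` (tibble: `bin`, `n`, `mean_sq`, `median_sq`, `sd_sq`) and the
#'   joined per-read tibble `data`.
#' @export
evaluate_scores <- function(scores, identities, read_error_rate = 0.15) {
  stopifnot(is.data.frame(scores), all(c("read_id", "sq") %in% names(scores)))
  if (!"identity" %in% names(identities)) {
    identities <- best_alignments(identities, read_error_rate)
  }
  joined <- dplyr::inner_join(
    dplyr::select(scores, "read_id", "sq"),
    dplyr::select(identities, "read_id", "identity"),
    by = "read_id"
  )
  joined <- joined[!is.na(joined$sq) & !is.na(joined$identity), , drop = FALSE]
  if (nrow(joined) < 2L) {
    abort("fewer than 2 reads with both a score and a passing alignment")
  }
  r <- sq_pearson(joined$identity, joined$sq)

  lo <- min(floor(min(joined$identity) / 5) * 5, 95)
  breaks <- seq(lo, 100, by = 5)
  labels <- paste0(head(breaks, -1), "-", breaks[-1], "%")
  joined$bin <- cut(joined$identity, breaks = breaks, labels = labels,
                    include.lowest = TRUE, right = TRUE)
  bins <- joined |>
    dplyr::group_by(.data$bin, .drop = FALSE) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_sq = mean(.data$sq),
      median_sq = median(.data$sq),
      sd_sq = stats::sd(.data$sq),
      .groups = "drop"
    )
  structure(
    list(pearson = r, n = nrow(joined), bins = bins, data = joined),
    class = "sq_evaluation"
  )
}

#' @export
print.sq_evaluation <- function(x, ...) {
  cat("<sq_evaluation> ", x$n, " reads; Pearson(identity, SQ) = ",
      format(x$pearson, digits = 3), "\n", sep = "")
  print(x$bins)
  invisible(x)
}

#' @rdname evaluate_scores
#' @param x An `sq_evaluation`.
#' @param ... Unused.
#' @export
tidy.sq_evaluation <- function(x, ...) x$bins

#' @rdname evaluate_scores
#' @export
glance.sq_evaluation <- function(x, ...) {
  tibble::tibble(pearson = x$pearson, n = x$n)
}

#' @rdname evaluate_scores
#' @param object An `sq_evaluation`.
#' @export
autoplot.sq_evaluation <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$bin, y = .data$sq)) +
    ggplot2::geom_boxplot(outlier.alpha = 0.3) +
    ggplot2::labs(
      x = "alignment identity bin",
      y = "SQ score",
      title = "Quality score vs alignment identity",
      subtitle = paste0("Pearson r = ", format(object$pearson, digits = 3),
                        " over ", object$n, " reads")
    ) +
    ggplot2::theme_minimal()
}
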