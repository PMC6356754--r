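#' Retain the top-scored fraction of reads
#'
#' Ranks reads by quality score (descending, ties broken by input order) and
#' retains the top `top_percent` of them. The retained count is
#' `round_half_up(N * P / 100)` of the `N` scored reads. Reads with a
#' sentinel `NA` score (too short to featurise) rank below every scored read.
#'
#' @param scores Score tibble from [cross_score()] (columns `read_id`, `sq`;
#'   extra columns are carried along).
#' @param top_percent Percentage of reads to retain, in `(0, 100]`.
#' @return An `sq_selection`: the input tibble reordered by descending score
#'   with added columns `rank` and `retained`, and attributes `top_percent`
#'   and `n_retained`.
#' @examples
#' scores <- tibble::tibble(read_id = paste0("r", 1:10), sq = 10:1 / 10)
#' sel <- select_top(scores, 80)
#' sum(sel$retained)
#' @export
select_top <- function(scores, top_percent) {
  stopifnot(is.data.frame(scores), all(c("read_id", "sq") %in% names(scores)))
  if (nrow(scores) == 0L) abort("empty score table")
  if (!is.numeric(top_percent) || length(top_percent) != 1L ||
      top_percent <= 0 || top_percent > 100) {
    abort("top_percent must be in (0, 100]")
  }
  if (anyDuplicated(scores$read_id)) abort("duplicate read ids in score table")

  n <- nrow(scores)
  n_keep <- round_half_up(n * top_percent / 100)
  # order(): stable, NA last; input order breaks ties
  ord <- order(-scores$sq, na.last = TRUE)
  out <- scores[ord, , drop = FALSE]
  out$rank <- seq_len(n)
  out$retained <- out$rank <= n_keep
  out <- tibble::as_tibble(out)
  attr(out, "top_percent") <- top_percent
  attr(out, "n_retained") <- n_keep
  class(out) <- c("sq_selection", class(out))
  out
}

#' @export
print.sq_selection <- function(x, ...) {
  cat("<sq_selection> top ", attr(x, "top_percent"), "% of ", nrow(x),
      " reads: ", attr(x, "n_retained"), " retained\n", sep = "")
  NextMethod()
}

#' Number of reads retained at a given percentage
#'
#' The count formula used by [select_top()]: half-up rounding of
#' `n * top_percent / 100`.
#'
#' @param n Total number of scored reads.
#' @param top_percent Percentage retained.
#' @return Integer count.
#' @examples
#' n_retained(31858, 95)
#' @export
n_retained <- function(n, top_percent) {
  round_half_up(n * top_percent / 100)
}

# round half away from zero at .5 (only called on non-negative inputs)
round_half_up <- function(x) as.integer(floor(x + 0.5))

#' Write the retained reads to FASTA/FASTQ
#'
#' Writes the retained reads of a selection, in descending-score order and
#' with their original bases and qualities, to a sequence file.
#'
#' @param selection An `sq_selection` from [select_top()].
#' @param reads The read tibble the scores were computed from.
#' @param path Output path.
#' @param format Passed to [write_sequences()].
#' @return Invisibly, the number of reads written.
#' @export
write_selected <- function(selection, reads, path,
                           format = c("auto", "fasta", "fastq")) {
  stopifnot(inherits(selection, "sq_selection"))
  kept <- selection$read_id[selection$retained]
  missing <- setdiff(kept, reads$read_id)
  if (length(missing) > 0) {
    abort(paste0("retained read id not present in read set: ", missing[1]))
  }
  sel_reads <- reads[match(kept, reads$read_id), , drop = FALSE]
  write_sequences(sel_reads, path, format = format)
}
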