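#' Contrast mean k-mer content between two read sets
#'
#' Computes per-feature mean content for two read sets (typically raw vs
#' corrected) and their difference — the differential composition signal the
#' linear scorer learns from.
#'
#' @param set_a,set_b Read tibbles.
#' @param labels Length-2 character vector naming the sets.
#' @return Tibble with `kmer`, `k`, the two set means and `diff`
#'   (`set_a - set_b`).
#' @export
feature_contrast <- function(set_a, set_b, labels = c("raw", "corrected")) {
  mean_features <- function(reads) {
    colMeans(feature_matrix_of(sq_features(reads)))
  }
  ma <- mean_features(set_a)
  mb <- mean_features(set_b)
  tibble::tibble(
    kmer = names(ma), k = nchar(names(ma)),
    !!labels[1] := unname(ma),
    !!labels[2] := unname(mb),
    diff = unname(ma - mb)
  )
}

#' Plot the k-mer content contrast between two read sets
#'
#' @param contrast Tibble from [feature_contrast()].
#' @param k Which k-mer order to show (default 3).
#' @return A ggplot object.
#' @export
plot_feature_contrast <- function(contrast, k = 3) {
  d <- contrast[contrast$k == k, , drop = FALSE]
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$kmer, .data$diff),
                                  y = .data$diff)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = paste0(k, "-mer"),
                  y = "mean content difference",
                  title = "Differential nucleotide-combination content") +
    ggplot2::theme_minimal()
}
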