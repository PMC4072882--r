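#' Median-of-ratios size factors
#'
#' Per-library depth factors s_j: for each transcript with strictly positive
#' counts in every library, form the ratio of its count in library j to its
#' geometric mean across libraries; s_j is the median of those ratios.
#' Normalized counts are r_ij = k_ij / s_j.
#'
#' @param counts count matrix, transcripts x libraries.
#' @return named positive numeric vector, one entry per library.
#' @export
size_factors <- function(counts) {
  validate_count_table(counts)
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos))
    stop("no transcript has positive counts in every library; ",
         "median-of-ratios is undefined (a pseudo-reference fallback is ",
         "deliberately not applied)")
  lg <- log(counts[pos, , drop = FALSE])
  loggeo <- rowMeans(lg)
  s <- exp(apply(lg - loggeo, 2L, stats::median))
  stats::setNames(s, colnames(counts))
}

## r_ij = k_ij / s_j
normalized_counts <- function(counts, sf) {
  sweep(counts, 2L, sf, "/")
}
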