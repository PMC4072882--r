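#' Euclidean distances between libraries
#'
#' Pairwise Euclidean distance between libraries over log-transformed
#' normalized counts, `log2(r_ij + 1)`, optionally after excluding a
#' transcript set (e.g. all significantly heterogametic transcripts).
#'
#' @param counts count matrix.
#' @param sf size factors; default [size_factors()] of `counts`.
#' @param exclude transcript ids to drop before computing distances.
#' @return symmetric distance matrix with library dimnames, zero diagonal.
#' @export
library_distances <- function(counts, sf = size_factors(counts),
                              exclude = character(0)) {
  keep <- setdiff(rownames(counts), exclude)
  if (length(keep) == 0L)
    stop("all transcripts excluded; no data left for distances")
  x <- log2(normalized_counts(counts[keep, , drop = FALSE], sf) + 1)
  as.matrix(stats::dist(t(x)))
}

#' Classical 2-D scaling of a library distance matrix
#'
#' Torgerson scaling (double-center the squared distances, top-2
#' eigenpairs). Coordinates are defined up to rotation/reflection; to make
#' runs comparable, axes are ordered by descending eigenvalue and each
#' axis's sign is fixed so that its first nonzero loading is positive.
#' With fewer than two positive eigenvalues a 1-D embedding is returned
#' with a warning.
#'
#' @param d a symmetric distance matrix (or `dist`).
#' @return data.frame with `library_id`, `x`, `y` (`y` absent/zero in the
#'   degenerate 1-D case); attribute `eig` holds the eigenvalues.
#' @export
mds_2d <- function(d) {
  dm <- as.matrix(d)
  fit <- stats::cmdscale(stats::as.dist(dm), k = min(2L, nrow(dm) - 1L),
                         eig = TRUE)
  npos <- sum(fit$eig > sqrt(.Machine$double.eps) * max(abs(fit$eig)))
  pts <- fit$points
  if (npos < 2L) {
    warning("fewer than 2 positive eigenvalues; returning 1-D embedding")
    pts <- pts[, 1L, drop = FALSE]
  }
  for (j in seq_len(ncol(pts))) {
    nz <- which(abs(pts[, j]) > 1e-12)
    if (length(nz) && pts[nz[1L], j] < 0) pts[, j] <- -pts[, j]
  }
  out <- data.frame(library_id = rownames(dm),
                    x = pts[, 1L],
                    y = if (ncol(pts) >= 2L) pts[, 2L] else 0,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "eig") <- fit$eig
  out
}

#' MA-plot data from a DE table
#'
#' One record per tested transcript: mean normalized count, log2 fold
#' change, and a significance flag at `p_adj < alpha`.
#'
#' @param de a `de_table`.
#' @param alpha significance threshold.
#' @return data.frame with `transcript_id`, `base_mean`,
#'   `log2_fold_change`, `significant`.
#' @export
ma_data <- function(de, alpha = 0.05) {
  tested <- !is.na(de$p_value)
  data.frame(transcript_id = de$transcript_id[tested],
             base_mean = de$base_mean[tested],
             log2_fold_change = de$log2_fold_change[tested],
             significant = !is.na(de$p_adj[tested]) &
               de$p_adj[tested] < alpha,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Dispersion-versus-mean data from a dispersion fit
#'
#' Per-transcript base mean, raw and fitted dispersion (for the scatter),
#' plus the fitted trend sampled on a log-spaced grid of means (for the
#' red line).
#'
#' @param fit a [estimate_dispersion()] result.
#' @param grid_n number of grid points for the trend curve.
#' @return list with `points` (per-transcript data.frame, tested
#'   transcripts only) and `trend` (base_mean, fitted_alpha grid).
#' @export
dispersion_mean_data <- function(fit, grid_n = 60L) {
  tab <- fit$table[fit$table$tested, , drop = FALSE]
  rng <- range(tab$base_mean)
  grid <- exp(seq(log(max(rng[1], 1e-3)), log(rng[2]),
                  length.out = grid_n))
  list(points = data.frame(transcript_id = tab$transcript_id,
                           base_mean = tab$base_mean,
                           raw_alpha = tab$raw_alpha,
                           fitted_alpha = tab$fitted_alpha,
                           final_alpha = tab$final_alpha,
                           stringsAsFactors = FALSE, row.names = NULL),
       trend = data.frame(base_mean = grid,
                          fitted_alpha = fit$trend["a1"] / grid +
                            fit$trend["a0"],
                          row.names = NULL))
}

#' Within-gonozooid to gonozooid-to-other distance ratio
#'
#' Mean distance among the gonozooid libraries divided by the mean distance
#' from gonozooid to non-gonozooid libraries. When heterogametic
#' transcripts dominate, male and female gonozooids sit far apart and the
#' ratio is high; after excluding them the libraries cluster by polyp type
#' and the ratio drops.
#'
#' @param d a library distance matrix.
#' @param design a [library_design()].
#' @return a single ratio.
#' @export
gono_distance_ratio <- function(d, design) {
  dm <- as.matrix(d)
  g <- design$library_id[design$polyp == "gonozooid"]
  o <- setdiff(design$library_id, g)
  within <- dm[g, g][upper.tri(dm[g, g])]
  between <- dm[g, o]
  mean(within) / mean(between)
}
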