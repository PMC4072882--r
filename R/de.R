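#' Differential expression between two library groups
#'
#' Runs the NB exact test per transcript between two conditions. Conditions
#' are named by polyp type (`"gastrozooid"`, `"gonozooid"`,
#' `"dactylozooid"`, abbreviations allowed) or, for the heterogametic
#' contrast, by sex (`"male"`, `"female"`, meaning the gonozooid libraries
#' of that sex). The sign convention is anchored to the first-named
#' condition: `log2_fold_change > 0` means higher expression in
#' `comparison[1]`.
#'
#' Dispersion is estimated once from the whole library universe of the call
#' under the declared grouping (`dispersion_scheme`) and reused for every
#' transcript; pass a precomputed [estimate_dispersion()] fit to share one
#' estimate across several pairwise comparisons.
#'
#' @param counts count matrix (the full table; size factors are computed
#'   from all transcripts before any subsetting).
#' @param design a [library_design()].
#' @param comparison length-2 character: the two condition names, first
#'   name = numerator of the fold change.
#' @param engine dispersion engine, `"conservative"` or `"shrinkage"`.
#' @param dispersion_scheme `"split"` (gonozooid libraries divided by sex —
#'   the grouping that removes heterogametic variance from the dispersion)
#'   or `"pooled"` (the three polyp types as-is).
#' @param transcripts optional transcript subset to test (row names).
#' @param use_libraries optional library subset defining the universe of
#'   the analysis (e.g. dropping female gonozooid libraries so that
#'   `"gonozooid"` is represented by male libraries only).
#' @param sf size factors; default computed from the full `counts`.
#' @param dispersion optional precomputed `dispersion_fit`.
#' @param pseudo pseudo-count (normalized counts) in the fold change.
#' @return a `de_table`: data.frame with transcript_id, base_mean,
#'   log2_fold_change, p_value, p_adj; attributes `comparison`, `engine`.
#'   Transcripts with zero counts in both groups are not tested
#'   (`NA` p-values) and are excluded from the BH adjustment.
#' @export
run_de <- function(counts, design,
                   comparison, engine = c("conservative", "shrinkage"),
                   dispersion_scheme = c("split", "pooled"),
                   transcripts = NULL, use_libraries = NULL,
                   sf = NULL, dispersion = NULL, pseudo = 1) {
  engine <- match.arg(engine)
  dispersion_scheme <- match.arg(dispersion_scheme)
  validate_design(design)
  stopifnot(all(design$library_id %in% colnames(counts)))
  if (is.null(sf)) sf <- size_factors(counts[, design$library_id,
                                             drop = FALSE])
  comparison <- vapply(comparison, resolve_condition, "")
  if (is.null(use_libraries)) use_libraries <- design$library_id
  d <- design[design$library_id %in% use_libraries, , drop = FALSE]

  libsA <- condition_libraries(d, comparison[1])
  libsB <- condition_libraries(d, comparison[2])
  if (length(libsA) == 0L || length(libsB) == 0L)
    stop("condition with zero libraries in comparison: ",
         comparison[which(c(length(libsA), length(libsB)) == 0L)[1L]])

  sub <- counts[, d$library_id, drop = FALSE]
  if (!is.null(transcripts)) {
    missing_t <- setdiff(transcripts, rownames(sub))
    if (length(missing_t))
      stop("unknown transcripts requested: ", missing_t[1L])
    sub <- sub[transcripts, , drop = FALSE]
  }
  sfu <- sf[d$library_id]

  if (is.null(dispersion)) {
    conds <- condition_labels(d, dispersion_scheme)
    dispersion <- estimate_dispersion(sub, sfu, conds, engine)
  } else {
    stopifnot(inherits(dispersion, "dispersion_fit"))
    if (dispersion$engine != engine)
      stop("dispersion fit engine does not match requested engine")
  }
  alpha_i <- dispersion$table$final_alpha[
    match(rownames(sub), dispersion$table$transcript_id)]

  kA <- sub[, libsA, drop = FALSE]
  kB <- sub[, libsB, drop = FALSE]
  sA <- sfu[libsA]; sB <- sfu[libsB]
  rA <- rowMeans(normalized_counts(kA, sA))
  rB <- rowMeans(normalized_counts(kB, sB))
  base_mean <- rowMeans(normalized_counts(
    sub[, c(libsA, libsB), drop = FALSE], c(sA, sB)))
  lfc <- log2((rA + pseudo) / (rB + pseudo))

  n <- nrow(sub)
  p <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    a <- if (is.na(alpha_i[i])) 0 else alpha_i[i]
    p[i] <- nb_exact_test(kA[i, ], kB[i, ], sA, sB, a)
  }
  res <- data.frame(transcript_id = rownames(sub),
                    base_mean = base_mean,
                    log2_fold_change = lfc,
                    p_value = p,
                    p_adj = bh_adjust(p),
                    stringsAsFactors = FALSE, row.names = NULL)
  de_table(res, comparison = comparison, engine = engine,
           dispersion = dispersion)
}

resolve_condition <- function(x) {
  choices <- c(POLYP_TYPES, "male", "female")
  hit <- charmatch(x, choices)
  if (is.na(hit) || hit == 0L) stop("unknown condition: ", x)
  choices[hit]
}

condition_libraries <- function(design, condition) {
  if (condition %in% c("male", "female"))
    design$library_id[design$polyp == "gonozooid" &
                      design$sex == condition]
  else design$library_id[design$polyp == condition]
}

de_table <- function(df, comparison, engine, dispersion = NULL,
                     branch = NULL) {
  structure(df,
            comparison = comparison,
            label = paste(comparison, collapse = " vs "),
            engine = engine,
            dispersion = dispersion,
            branch = branch,
            class = c("de_table", "data.frame"))
}

#' @export
print.de_table <- function(x, alpha = 0.05, ...) {
  cat("DE table:", attr(x, "label"), "(", attr(x, "engine"), "engine )\n")
  tested <- !is.na(x$p_value)
  cat(" ", nrow(x), "transcripts,", sum(tested), "tested,",
      sum(x$p_adj < alpha, na.rm = TRUE),
      sprintf("significant at p_adj < %g\n", alpha))
  if ("branch" %in% names(x))
    print(table(branch = x$branch))
  invisible(x)
}

#' @export
#' @method summary de_table
summary.de_table <- function(object, alpha = 0.05, ...) {
  sig <- !is.na(object$p_adj) & object$p_adj < alpha
  out <- data.frame(comparison = attr(object, "label"),
                    engine = attr(object, "engine"),
                    n = nrow(object),
                    tested = sum(!is.na(object$p_value)),
                    significant = sum(sig),
                    up = sum(sig & object$log2_fold_change > 0),
                    down = sum(sig & object$log2_fold_change < 0))
  out
}

#' MA plot of a DE table
#'
#' Mean normalized count (A, log10 axis) against log2 fold change (M);
#' significant transcripts in red.
#'
#' @param x a `de_table`.
#' @param alpha significance threshold on `p_adj`.
#' @param ... passed to [graphics::plot()].
#' @export
#' @method plot de_table
plot.de_table <- function(x, alpha = 0.05, ...) {
  d <- ma_data(x, alpha)
  graphics::plot(pmax(d$base_mean, 0.1), d$log2_fold_change, log = "x",
                 pch = 16, cex = 0.3,
                 col = ifelse(d$significant, "red", "grey50"),
                 xlab = "mean of normalized counts",
                 ylab = "log2 fold change",
                 main = attr(x, "label"), ...)
  graphics::abline(h = 0, col = "grey30")
  invisible(x)
}

#' Write a DE table as TSV
#' @param de a `de_table`.
#' @param path file path.
#' @export
write_de_table <- function(de, path) {
  utils::write.table(as.data.frame(de), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
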