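#' Estimate per-transcript NB dispersions
#'
#' Method-of-moments raw dispersions, a parametric dispersion--mean trend,
#' and a per-transcript final value under one of two engines:
#'
#' * `conservative`: final = max(raw, trend value) — every transcript gets
#'   at least the trend dispersion, mirroring the cautious style of exact
#'   NB testing tools.
#' * `shrinkage`: final maximizes the transcript's own Cox-Reid adjusted
#'   NB profile log-likelihood (condition means profiled out via
#'   normalized-count group means) plus a `prior_df`-weighted average
#'   log-likelihood of a local window of transcripts with similar base
#'   mean — a weighted likelihood shrinkage toward the local trend.
#'
#' Raw dispersion of transcript i: with normalized counts r_ij, base mean
#' q_i = mean_j r_ij, pooled within-condition sample variance w_i and
#' shot-noise term z_i = q_i * mean_j(1 / s_j),
#' `raw_i = max(0, (w_i - z_i) / q_i^2)`. The trend is
#' `alpha(q) = a1 / q + a0` (a0, a1 >= 0), fitted by iterated weighted least
#' squares on transcripts with positive raw dispersion.
#'
#' Conditions with fewer than two libraries contribute nothing to `w_i` and
#' are excluded from the shrinkage likelihood (their fitted mean equals the
#' observation and carries no dispersion information).
#'
#' @param counts count matrix, transcripts x libraries.
#' @param sf size factors (named by library); default [size_factors()].
#' @param conditions named character vector mapping library id to condition
#'   label, e.g. from the design's polyp types with or without the
#'   gonozooid sex split.
#' @param engine `"conservative"` or `"shrinkage"`.
#' @param prior_df prior degrees of freedom of the local-trend likelihood
#'   in the shrinkage engine; the trend term is weighted by
#'   `prior_df / residual_df` pseudo-transcripts.
#' @param window size of the local window (nearest transcripts by base
#'   mean) in the shrinkage engine.
#' @return object of class `dispersion_fit`: list with `table`
#'   (transcript_id, base_mean, raw_alpha, fitted_alpha, final_alpha,
#'   tested), `trend` (a0, a1), `engine`, `conditions`.
#' @export
estimate_dispersion <- function(counts, sf = size_factors(counts),
                                conditions,
                                engine = c("conservative", "shrinkage"),
                                prior_df = 10, window = 500L) {
  engine <- match.arg(engine)
  stopifnot(!is.null(names(conditions)),
            all(colnames(counts) %in% names(conditions)))
  conditions <- conditions[colnames(counts)]
  sf <- sf[colnames(counts)]
  n <- nrow(counts)
  r <- normalized_counts(counts, sf)
  q <- rowMeans(r)
  tested <- q > 0

  ## pooled within-condition variance
  cond_split <- split(seq_len(ncol(counts)), conditions)
  ss <- numeric(n)
  df <- 0L
  for (idx in cond_split) {
    if (length(idx) < 2L) next
    rc <- r[, idx, drop = FALSE]
    ss <- ss + rowSums((rc - rowMeans(rc))^2)
    df <- df + length(idx) - 1L
  }
  if (df == 0L)
    stop("dispersion estimation needs at least one condition with >= 2 ",
         "libraries")
  w <- ss / df
  z <- q * mean(1 / sf)
  raw <- ifelse(tested, pmax(0, (w - z) / q^2), NA_real_)

  trend <- fit_dispersion_trend(q[tested], raw[tested])
  fitted_alpha <- ifelse(tested, trend["a1"] / q + trend["a0"], NA_real_)

  final <- if (engine == "conservative") {
    pmax(raw, fitted_alpha)
  } else {
    shrink_dispersion(counts, sf, conditions, q, tested,
                      prior_df = prior_df, window = window)
  }

  structure(list(
    table = data.frame(transcript_id = rownames(counts),
                       base_mean = q, raw_alpha = raw,
                       fitted_alpha = fitted_alpha, final_alpha = final,
                       tested = tested,
                       stringsAsFactors = FALSE, row.names = NULL),
    trend = trend, engine = engine, conditions = conditions),
    class = "dispersion_fit")
}

## Gamma-style IWLS fit of raw ~ a1/q + a0 with non-negative coefficients;
## falls back to the global mean raw dispersion if the fit degenerates.
fit_dispersion_trend <- function(q, raw) {
  use <- is.finite(raw) & raw > 0 & is.finite(q) & q > 0
  fallback <- c(a0 = mean(raw[is.finite(raw)], na.rm = TRUE), a1 = 0)
  if (!is.finite(fallback["a0"])) fallback["a0"] <- 0.1
  if (sum(use) < 10L) {
    warning("too few positive raw dispersions; using global mean trend")
    return(fallback)
  }
  y <- raw[use]
  X <- cbind(a0 = 1, a1 = 1 / q[use])
  fit <- rep(mean(y), length(y))
  coefs <- fallback
  for (it in 1:10) {
    wgt <- 1 / pmax(fit, 1e-10)^2     # gamma-family variance ~ mean^2
    cf <- tryCatch(stats::lm.wfit(X, y, wgt)$coefficients,
                   error = function(e) NULL)
    if (is.null(cf) || anyNA(cf)) return(fallback)
    if (cf[2] < 0) {                   # no mean-dependence: intercept only
      cf <- c(sum(wgt * y) / sum(wgt), 0)
    } else if (cf[1] < 0) {            # pure 1/q component
      cf <- c(0, sum(wgt * y * X[, 2]) / sum(wgt * X[, 2]^2))
    }
    coefs <- c(a0 = unname(cf[1]), a1 = unname(cf[2]))
    fit <- X %*% cf
    fit <- pmax(fit, 1e-10)
  }
  if (!all(is.finite(coefs)) || all(coefs <= 0)) {
    warning("dispersion trend fit failed; using global mean trend")
    return(fallback)
  }
  coefs
}

## Weighted-likelihood shrinkage on a log-spaced dispersion grid. The local
## trend term is a centered rolling mean (window transcripts, ordered by
## base mean) of the per-transcript grid log-likelihoods.
shrink_dispersion <- function(counts, sf, conditions, q, tested,
                              prior_df = 10, window = 500L,
                              grid = exp(seq(log(1e-4), log(32),
                                             length.out = 80L))) {
  n <- nrow(counts)
  cond_split <- split(seq_len(ncol(counts)), conditions)
  cond_split <- cond_split[lengths(cond_split) >= 2L]
  use_j <- sort(unlist(cond_split, use.names = FALSE))
  r <- normalized_counts(counts, sf)
  mu <- matrix(0, n, length(use_j))
  col_pos <- match(use_j, use_j)
  for (idx in cond_split) {
    qc <- rowMeans(r[, idx, drop = FALSE])
    for (j in idx) mu[, match(j, use_j)] <- qc * sf[j]
  }
  k <- counts[, use_j, drop = FALSE]

  G <- length(grid)
  L <- matrix(-Inf, n, G)
  ok <- tested
  kk <- k[ok, , drop = FALSE]
  mm <- mu[ok, , drop = FALSE]
  mm <- pmax(mm, 1e-10)
  ## Cox-Reid adjusted profile likelihood: subtract half the log Fisher
  ## information of the profiled condition means (log link), condition by
  ## condition; removes the downward bias of plug-in mean estimates.
  cond_cols <- lapply(cond_split, function(idx) match(idx, use_j))
  for (g in seq_len(G)) {
    ll <- rowSums(stats::dnbinom(kk, mu = mm, size = 1 / grid[g],
                                 log = TRUE))
    w <- mm / (1 + grid[g] * mm)          # NB working weights
    cr <- 0
    for (cc in cond_cols)
      cr <- cr + 0.5 * log(rowSums(w[, cc, drop = FALSE]))
    L[ok, g] <- ll - cr
  }

  ## local-trend likelihood: rolling mean over transcripts sorted by q
  o <- order(q)
  Ls <- L[o, , drop = FALSE]
  Ls[!is.finite(Ls)] <- 0
  win <- min(window, n)
  cs <- apply(Ls, 2L, cumsum)
  if (!is.matrix(cs)) cs <- matrix(cs, nrow = n)
  half <- win %/% 2L
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(lo + win - 1L, n)
  lo <- pmax(hi - win + 1L, 1L)
  S <- (cs[hi, , drop = FALSE] -
        rbind(0, cs)[lo, , drop = FALSE]) / (hi - lo + 1)
  Sorig <- matrix(0, n, G)
  Sorig[o, ] <- S

  df_res <- sum(vapply(cond_split, length, 0L)) - length(cond_split)
  prior_weight <- prior_df / max(df_res, 1L)
  obj <- L + prior_weight * Sorig
  best <- max.col(obj, ties.method = "first")
  out <- grid[best]
  out[!tested] <- NA_real_
  out
}

#' @export
print.dispersion_fit <- function(x, ...) {
  tab <- x$table
  cat("NB dispersion fit (", x$engine, " engine), ",
      sum(tab$tested), " of ", nrow(tab), " transcripts tested\n", sep = "")
  cat(sprintf("  trend: alpha(q) = %.4g/q + %.4g\n",
              x$trend["a1"], x$trend["a0"]))
  cat(sprintf("  final dispersion: mean %.4g, median %.4g\n",
              mean(tab$final_alpha, na.rm = TRUE),
              stats::median(tab$final_alpha, na.rm = TRUE)))
  invisible(x)
}

#' Plot dispersion estimates against mean normalized counts
#'
#' Raw per-transcript dispersions (grey), final values (blue) and the
#' fitted trend (red line), on log-log axes.
#'
#' @param x a `dispersion_fit`.
#' @param ... passed to [graphics::plot()].
#' @export
#' @method plot dispersion_fit
plot.dispersion_fit <- function(x, ...) {
  tab <- x$table[x$table$tested, ]
  graphics::plot(tab$base_mean, pmax(tab$raw_alpha, 1e-6), log = "xy",
                 pch = 16, cex = 0.3, col = "grey60",
                 xlab = "mean of normalized counts", ylab = "dispersion",
                 ...)
  graphics::points(tab$base_mean, pmax(tab$final_alpha, 1e-6),
                   pch = 16, cex = 0.3, col = "steelblue")
  qq <- sort(tab$base_mean)
  graphics::lines(qq, x$trend["a1"] / qq + x$trend["a0"], col = "red",
                  lwd = 2)
  invisible(x)
}
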