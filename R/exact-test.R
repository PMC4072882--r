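#' Negative-binomial exact test on group count sums
#'
#' Conditional two-sided test of equal concentration between two groups of
#' libraries. With total K_S = sum(k_A) + sum(k_B) and pooled concentration
#' q = K_S / (sum(s_A) + sum(s_B)), each group sum is modeled NB with mean
#' mu_A = q * sum(s_A) and variance equal to the sum of the per-library NB
#' variances, sum_j (q s_j + alpha (q s_j)^2) — i.e. an effective group
#' dispersion alpha * sum(s_A^2) / sum(s_A)^2 (about alpha / n for equal
#' depths); likewise for B. The p-value is the total probability, among all
#' splits a + b = K_S, of splits no more likely than the observed one,
#' normalized by the probability of the total:
#' p = sum over \{a + b = K_S : P(a) P(b) <= P(K_A) P(K_B)\} of P(a) P(b),
#' divided by sum over all splits of P(a) P(b). Ties (splits exactly as
#' likely as the observed one) are included in the rejection sum. alpha = 0
#' degenerates to the Poisson exact test.
#'
#' Splits are enumerated exactly for K_S up to `enum_cap`; above it a normal
#' approximation to the conditional split distribution is used.
#'
#' @param k_A,k_B integer count vectors for the two groups.
#' @param s_A,s_B size factors of the corresponding libraries.
#' @param alpha NB dispersion (variance = mu + alpha * mu^2), >= 0.
#' @param enum_cap largest total enumerated exactly.
#' @return p-value in (0, 1], or `NA_real_` (not tested) when K_S = 0.
#' @export
nb_exact_test <- function(k_A, k_B, s_A, s_B, alpha, enum_cap = 10000L) {
  stopifnot(alpha >= 0, length(k_A) == length(s_A),
            length(k_B) == length(s_B))
  KA <- sum(k_A); KB <- sum(k_B)
  KS <- KA + KB
  if (KS == 0) return(NA_real_)
  SA <- sum(s_A); SB <- sum(s_B)
  qhat <- KS / (SA + SB)
  muA <- qhat * SA
  muB <- qhat * SB
  alphaA <- alpha * sum(s_A^2) / SA^2   # effective group-sum dispersions
  alphaB <- alpha * sum(s_B^2) / SB^2
  if (KS <= enum_cap) {
    a <- 0:KS
    lpa <- nb_logdens(a, muA, alphaA)
    lpb <- nb_logdens(KS - a, muB, alphaB)
    lp <- lpa + lpb
    M <- max(lp)
    w <- exp(lp - M)
    obs <- lp[KA + 1L]
    ## include ties up to numerical noise
    p <- sum(w[lp <= obs + 1e-12]) / sum(w)
  } else {
    vA <- muA + alphaA * muA^2
    vB <- muB + alphaB * muB^2
    m <- muA + vA / (vA + vB) * (KS - muA - muB)
    v <- vA * vB / (vA + vB)
    z_lo <- stats::pnorm(KA + 0.5, m, sqrt(v))
    z_hi <- stats::pnorm(KA - 0.5, m, sqrt(v), lower.tail = FALSE)
    p <- 2 * min(z_lo, z_hi)
  }
  min(max(p, .Machine$double.xmin), 1)
}

nb_logdens <- function(x, mu, alpha) {
  if (alpha < 1e-12) stats::dpois(x, mu, log = TRUE)
  else stats::dnbinom(x, mu = mu, size = 1 / alpha, log = TRUE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment over the tested transcripts; `NA` entries
#' (not-tested transcripts) are excluded from the number of tests m and
#' returned as `NA`.
#'
#' @param p numeric vector of p-values in (0, 1], possibly with `NA`.
#' @return vector of adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}
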