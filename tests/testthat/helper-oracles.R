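## Independent brute-force oracles used across the suite. These deliberately
## re-derive each quantity by the most literal route available (hash maps,
## double loops, direct enumeration) so they share no code with the package
## internals they check.

## --- SAM fragment counting ------------------------------------------------

## Literal counting rule: hash every record by template, then count template
## t for transcript r iff its primary paired records number exactly two,
## both mapped, and both reference r.
oracle_count_fragments <- function(sam_lines, transcript_ids) {
  out <- stats::setNames(integer(length(transcript_ids)), transcript_ids)
  recs <- list()
  for (ln in sam_lines) {
    if (startsWith(ln, "@") || !nzchar(ln)) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    flag <- as.integer(f[2])
    if (bitwAnd(flag, 1L) == 0L) next                 # unpaired
    if (bitwAnd(flag, 256L) != 0L) next               # secondary
    if (bitwAnd(flag, 2048L) != 0L) next              # supplementary
    recs[[f[1]]] <- c(recs[[f[1]]], list(list(
      mapped = bitwAnd(flag, 4L) == 0L, rname = f[3])))
  }
  for (tmpl in names(recs)) {
    rr <- recs[[tmpl]]
    if (length(rr) != 2L) next
    if (rr[[1]]$mapped && rr[[2]]$mapped &&
        rr[[1]]$rname == rr[[2]]$rname &&
        rr[[1]]$rname %in% transcript_ids)
      out[rr[[1]]$rname] <- out[rr[[1]]$rname] + 1L
  }
  out
}

## Random SAM with concordant pairs and every distractor species; the truth
## vector holds only the concordant pairs.
random_sam <- function(n_templates, transcript_ids, seed) {
  set.seed(seed)
  truth <- stats::setNames(integer(length(transcript_ids)), transcript_ids)
  lines <- c("@HD\tVN:1.6",
             sprintf("@SQ\tSN:%s\tLN:1000", transcript_ids))
  mk <- function(qn, flag, rname) {
    paste(qn, flag, rname, 1L, 42L, "10M", "*", 0L, 0L, "ACGTACGTAC",
          "IIIIIIIIII", sep = "\t")
  }
  for (i in seq_len(n_templates)) {
    qn <- sprintf("t%04d", i)
    kind <- sample(c("pair", "split", "halfmap", "secondary", "single",
                     "pair_extra_secondary"), 1L)
    t1 <- sample(transcript_ids, 1L)
    t2 <- sample(setdiff(transcript_ids, t1), 1L)
    if (kind == "pair") {
      lines <- c(lines, mk(qn, 99L, t1), mk(qn, 147L, t1))
      truth[t1] <- truth[t1] + 1L
    } else if (kind == "split") {
      lines <- c(lines, mk(qn, 97L, t1), mk(qn, 145L, t2))
    } else if (kind == "halfmap") {
      lines <- c(lines, mk(qn, 73L, t1), mk(qn, 133L, "*"))
    } else if (kind == "secondary") {
      lines <- c(lines, mk(qn, 355L, t1), mk(qn, 403L, t1))
    } else if (kind == "single") {
      lines <- c(lines, mk(qn, 0L, t1))                 # unpaired read
    } else {
      lines <- c(lines, mk(qn, 99L, t1), mk(qn, 147L, t1),
                 mk(qn, 355L, t2), mk(qn, 403L, t2))    # pair + secondaries
      truth[t1] <- truth[t1] + 1L
    }
  }
  list(lines = lines, truth = truth)
}

## --- NB exact test --------------------------------------------------------

## Full split enumeration in probability space (not log space), with the
## same group-sum moment model: each group sum NB with mean q*S and variance
## sum_j (q s_j + alpha (q s_j)^2).
oracle_exact_test <- function(k_A, k_B, s_A, s_B, alpha) {
  KS <- sum(k_A) + sum(k_B)
  if (KS == 0) return(NA_real_)
  SA <- sum(s_A); SB <- sum(s_B)
  q <- KS / (SA + SB)
  dens <- function(x, s_vec) {
    mu <- q * sum(s_vec)
    v <- sum(q * s_vec + alpha * (q * s_vec)^2)
    if (v <= mu * (1 + 1e-12)) return(stats::dpois(x, mu))
    size <- mu^2 / (v - mu)
    stats::dnbinom(x, mu = mu, size = size)
  }
  a <- 0:KS
  pa <- dens(a, s_A)
  pb <- dens(KS - a, s_B)
  joint <- pa * pb
  obs <- joint[sum(k_A) + 1L]
  sum(joint[joint <= obs * (1 + 1e-10)]) / sum(joint)
}

## --- BH adjustment --------------------------------------------------------

oracle_bh <- function(p) {
  m <- length(p)
  out <- numeric(m)
  for (i in seq_len(m)) {
    r <- sum(p <= p[i])              # rank with ties
    best <- Inf
    for (j in seq_len(m)) {
      rj <- sum(p <= p[j])
      if (p[j] >= p[i]) best <- min(best, p[j] * m / rj)
    }
    out[i] <- min(best, 1)
  }
  out
}

## --- polyp-specificity rule ----------------------------------------------

## states: per (engine, comparison) one of 0 (nonsig), +1 (sig, first polyp
## higher), -1 (sig, second polyp higher). Literal enumeration of the rule.
oracle_specificity_call <- function(states, comparisons) {
  polyps <- c("gastrozooid", "gonozooid", "dactylozooid")
  for (X in polyps) {
    for (dir in c("up", "down")) {
      ok <- TRUE
      for (e in c("conservative", "shrinkage")) {
        for (ci in seq_along(comparisons)) {
          cmp <- comparisons[[ci]]
          st <- states[[e]][ci]
          if (X %in% cmp) {
            want <- if (cmp[1] == X) 1 else -1
            if (dir == "down") want <- -want
            if (st != want) ok <- FALSE
          } else {
            if (st != 0) ok <- FALSE
          }
        }
      }
      if (ok) return(list(polyp = X, direction = dir))
    }
  }
  list(polyp = NA_character_, direction = NA_character_)
}

## Wrap a significance/sign state into a one-transcript de_table.
state_de_table <- function(state, cmp, engine) {
  p <- if (state == 0) 0.5 else 1e-6
  padj <- p
  lfc <- state * 2
  if (state == 0) lfc <- 0.1                 # sub-threshold wiggle
  polypDE:::de_table(
    data.frame(transcript_id = "T1", base_mean = 100,
               log2_fold_change = lfc, p_value = p, p_adj = padj,
               stringsAsFactors = FALSE),
    comparison = cmp, engine = engine)
}

## --- misc -----------------------------------------------------------------

COMPARISONS <- list(c("dactylozooid", "gastrozooid"),
                    c("dactylozooid", "gonozooid"),
                    c("gastrozooid", "gonozooid"))

split_labels <- function(design) polypDE:::condition_labels(design, "split")
pooled_labels <- function(design) polypDE:::condition_labels(design, "pooled")
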