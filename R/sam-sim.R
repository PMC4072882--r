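#' Simulate a SAM alignment fixture for one library
#'
#' Emits a valid SAM v1 text document containing, per transcript, exactly
#' `target_counts[t]` concordant read pairs (both mates primary-mapped to
#' `t`, flags 99/147), plus `noise` distractor templates that a correct
#' same-transcript pair counter must ignore: pairs with an unmapped mate,
#' pairs whose mates map to different transcripts, and templates carrying
#' only secondary alignments.
#'
#' @param target_counts named non-negative integer vector (one column of a
#'   count table); names are transcript ids.
#' @param noise number of distractor templates to interleave.
#' @param path optional file to write; the document is also returned.
#' @return character vector of SAM lines, invisibly when `path` is given.
#' @export
simulate_alignments <- function(target_counts, noise = 0L, path = NULL) {
  if (anyNA(target_counts) || any(target_counts < 0))
    stop("target_counts must be non-negative")
  tids <- names(target_counts)
  if (is.null(tids) && length(target_counts) > 0)
    stop("target_counts must be named by transcript id")
  header <- c("@HD\tVN:1.6\tSO:unknown",
              if (length(tids)) sprintf("@SQ\tSN:%s\tLN:1000", tids))
  seqs <- "ACGTACGTAC"; quals <- "IIIIIIIIII"
  pair <- function(qname, flag1, flag2, r1, r2, p1 = 1L, p2 = 201L) {
    c(paste(qname, flag1, r1, p1, 42L, "10M", "=", p2, 210L, seqs, quals,
            sep = "\t"),
      paste(qname, flag2, r2, p2, 42L, "10M", "=", p1, -210L, seqs, quals,
            sep = "\t"))
  }
  body <- character(0)
  k <- 0L
  for (t in tids) {
    n_t <- target_counts[[t]]
    for (i in seq_len(n_t)) {
      k <- k + 1L
      body <- c(body, pair(sprintf("frag%06d", k), 99L, 147L, t, t))
    }
  }
  for (i in seq_len(noise)) {
    qn <- sprintf("noise%04d", i)
    kind <- (i - 1L) %% 3L
    if (kind == 1L && length(tids) < 2L) kind <- 0L
    if (kind == 2L && length(tids) < 1L) kind <- 0L
    if (kind == 0L) {                      # unmapped mate (or fully unmapped)
      if (length(tids)) {
        t <- tids[(i - 1L) %% length(tids) + 1L]
        body <- c(body,
          paste(qn, 73L, t, 1L, 42L, "10M", "*", 0L, 0L, seqs, quals,
                sep = "\t"),
          paste(qn, 133L, "*", 0L, 0L, "*", "*", 0L, 0L, seqs, quals,
                sep = "\t"))
      } else {
        body <- c(body,
          paste(qn, 77L, "*", 0L, 0L, "*", "*", 0L, 0L, seqs, quals,
                sep = "\t"),
          paste(qn, 141L, "*", 0L, 0L, "*", "*", 0L, 0L, seqs, quals,
                sep = "\t"))
      }
    } else if (kind == 1L) {               # mates on different transcripts
      t1 <- tids[(i - 1L) %% length(tids) + 1L]
      t2 <- tids[i %% length(tids) + 1L]
      if (t2 == t1) t2 <- tids[tids != t1][1L]
      body <- c(body,
        paste(qn, 97L, t1, 1L, 42L, "10M", t2, 201L, 0L, seqs, quals,
              sep = "\t"),
        paste(qn, 145L, t2, 201L, 42L, "10M", t1, 1L, 0L, seqs, quals,
              sep = "\t"))
    } else {                               # secondary alignments only
      t <- tids[(i - 1L) %% length(tids) + 1L]
      body <- c(body, pair(qn, 355L, 403L, t, t))
    }
  }
  doc <- c(header, body)
  if (!is.null(path)) {
    writeLines(doc, path)
    return(invisible(doc))
  }
  doc
}
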