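#' Consensus polyp-specificity calls
#'
#' A transcript is called specific to polyp X (direction up) when, under
#' BOTH engines, it is significantly higher in X in BOTH pairwise
#' comparisons involving X (p_adj < alpha, X-higher sign) and NOT
#' significant in the third comparison. Down-calls mirror this with
#' X-lower signs; the third comparison's sign is unconstrained. Transcripts
#' significant in all three comparisons get no call and are counted
#' separately (attribute `all_three`).
#'
#' @param de_tables list of two engines (`conservative`, `shrinkage`), each
#'   a list of three `de_table`s for the pairwise polyp comparisons.
#' @param alpha significance threshold on `p_adj`.
#' @param universe optional transcript universe. When omitted, all six
#'   tables must cover exactly the same transcripts (an error otherwise).
#'   When supplied (e.g. after an adjustment that excluded transcripts from
#'   some analyses), transcripts missing from a table are treated as not
#'   significant there.
#' @return object of class `specificity_calls`: data.frame with
#'   `transcript_id`, `polyp` (`NA` = no call), `direction`, and per
#'   engine x comparison provenance columns `sig_*` and `sign_*`.
#' @export
call_polyp_specific <- function(de_tables, alpha = 0.05, universe = NULL) {
  engines <- c("conservative", "shrinkage")
  if (!all(engines %in% names(de_tables)))
    stop("de_tables must be a list with elements 'conservative' and ",
         "'shrinkage'")
  flat <- list()
  for (e in engines) {
    tabs <- de_tables[[e]]
    if (length(tabs) != 3L)
      stop("each engine needs the three pairwise polyp comparisons")
    for (t in tabs) {
      cmp <- attr(t, "comparison")
      if (is.null(cmp) || !all(cmp %in% POLYP_TYPES))
        stop("each table must carry a polyp-type comparison attribute")
      key <- paste(e, paste(substr(cmp, 1, 4), collapse = "_vs_"),
                   sep = ".")
      flat[[key]] <- t
    }
    polys <- sort(unique(unlist(lapply(tabs, attr, "comparison"))))
    if (!identical(polys, sort(POLYP_TYPES)))
      stop("the three comparisons must cover all polyp-type pairs")
  }
  if (is.null(universe)) {
    ids <- lapply(flat, function(t) sort(t$transcript_id))
    if (!all(vapply(ids[-1], identical, TRUE, ids[[1]])))
      stop("DE tables cover different transcript universes; pass an ",
           "explicit `universe` if that is intended")
    universe <- ids[[1]]
  }
  n <- length(universe)

  sig <- sgn <- list()
  for (key in names(flat)) {
    t <- flat[[key]]
    i <- match(universe, t$transcript_id)
    s <- !is.na(t$p_adj[i]) & t$p_adj[i] < alpha
    s[is.na(s)] <- FALSE
    sig[[key]] <- s
    g <- sign(t$log2_fold_change[i])
    g[is.na(g)] <- 0
    sgn[[key]] <- g
  }

  polyp_call <- rep(NA_character_, n)
  dir_call <- rep(NA_character_, n)
  all_three <- logical(n)

  for (e in engines) {
    keys <- grep(paste0("^", e, "\\."), names(flat), value = TRUE)
    all_three <- all_three |
      Reduce(`&`, lapply(keys, function(k) sig[[k]]))
  }

  for (X in POLYP_TYPES) {
    up_ok <- down_ok <- rep(TRUE, n)
    for (e in engines) {
      keys <- grep(paste0("^", e, "\\."), names(flat), value = TRUE)
      involves <- vapply(keys, function(k)
        X %in% attr(flat[[k]], "comparison"), TRUE)
      for (k in keys[involves]) {
        x_first <- attr(flat[[k]], "comparison")[1] == X
        x_sign <- if (x_first) 1 else -1
        up_ok <- up_ok & sig[[k]] & sgn[[k]] == x_sign
        down_ok <- down_ok & sig[[k]] & sgn[[k]] == -x_sign
      }
      k3 <- keys[!involves]
      up_ok <- up_ok & !sig[[k3]]
      down_ok <- down_ok & !sig[[k3]]
    }
    polyp_call[up_ok] <- X; dir_call[up_ok] <- "up"
    polyp_call[down_ok] <- X; dir_call[down_ok] <- "down"
  }

  prov <- c(stats::setNames(sig, paste0("sig_", names(sig))),
            stats::setNames(sgn, paste0("sign_", names(sgn))))
  out <- data.frame(transcript_id = universe, polyp = polyp_call,
                    direction = dir_call, prov,
                    stringsAsFactors = FALSE, check.names = FALSE)
  structure(out, alpha = alpha, all_three = sum(all_three),
            class = c("specificity_calls", "data.frame"))
}

#' @export
print.specificity_calls <- function(x, ...) {
  cat("Polyp-specificity calls (consensus of both engines, p_adj < ",
      attr(x, "alpha"), "):\n", sep = "")
  called <- !is.na(x$polyp)
  cat(" ", sum(called), "of", nrow(x), "transcripts called;",
      attr(x, "all_three"),
      "significant in all three comparisons (no call)\n")
  if (any(called))
    print(table(polyp = x$polyp[called], direction = x$direction[called]))
  invisible(x)
}

#' @export
#' @method summary specificity_calls
summary.specificity_calls <- function(object, ...) {
  summarize_venn(object)
}

#' Venn-style summary of polyp-specificity calls
#'
#' Per-polyp up/down counts plus the pairwise-intersection convention of
#' the three-circle diagram: the intersection of the circles for polyps X
#' and Y holds the transcripts down-regulated in the excluded polyp Z
#' (down in Z is equivocal up-regulation in both X and Y).
#'
#' @param calls a [call_polyp_specific()] result.
#' @return list with `per_polyp` (polyp, n_up, n_down) and `intersections`
#'   (pair, excluded_polyp, count) data.frames.
#' @export
summarize_venn <- function(calls) {
  per <- data.frame(polyp = POLYP_TYPES,
                    n_up = vapply(POLYP_TYPES, function(p)
                      sum(calls$polyp == p & calls$direction == "up",
                          na.rm = TRUE), 0L),
                    n_down = vapply(POLYP_TYPES, function(p)
                      sum(calls$polyp == p & calls$direction == "down",
                          na.rm = TRUE), 0L),
                    row.names = NULL, stringsAsFactors = FALSE)
  pairs <- utils::combn(POLYP_TYPES, 2L)
  inter <- data.frame(
    pair = apply(pairs, 2L, paste, collapse = " & "),
    excluded_polyp = apply(pairs, 2L, function(p) setdiff(POLYP_TYPES, p)),
    stringsAsFactors = FALSE)
  inter$count <- per$n_down[match(inter$excluded_polyp, per$polyp)]
  list(per_polyp = per, intersections = inter)
}

#' Write specificity calls as TSV
#' @param calls a `specificity_calls` object.
#' @param path file path.
#' @export
write_calls <- function(calls, path) {
  utils::write.table(as.data.frame(calls), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
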