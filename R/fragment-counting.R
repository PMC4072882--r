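#' Count same-transcript paired fragments from a SAM document
#'
#' Re-implements the counting stage used to build the expression matrix: a
#' fragment (template) is counted for transcript `t` if and only if both of
#' its mates have primary alignments and both reference `t`. Everything else
#' — unpaired reads, pairs with an unmapped mate, pairs split across
#' transcripts, secondary/supplementary alignments — contributes nothing.
#'
#' @param sam a SAM v1 document: a file path or a character vector of lines.
#' @param transcript_ids transcripts to report (absent ones get count 0).
#' @return named integer vector of length `length(transcript_ids)`.
#' @export
count_fragments <- function(sam, transcript_ids) {
  rec <- parse_sam(sam)
  counts <- stats::setNames(integer(length(transcript_ids)), transcript_ids)
  if (nrow(rec) == 0L) return(counts)

  ## primary, paired records only
  keep <- rec$paired & !rec$secondary & !rec$supplementary
  rec <- rec[keep, , drop = FALSE]
  if (nrow(rec) == 0L) return(counts)

  per <- table(rec$qname)
  if (any(per > 2L))
    stop("malformed pairing: template(s) with >2 primary records: ",
         paste(utils::head(names(per)[per > 2L], 3L), collapse = ", "))
  full <- names(per)[per == 2L]
  if (length(full) == 0L) return(counts)

  rec <- rec[rec$qname %in% full, , drop = FALSE]
  o <- order(rec$qname)
  first <- rec[o[c(TRUE, FALSE)], , drop = FALSE]
  second <- rec[o[c(FALSE, TRUE)], , drop = FALSE]
  ok <- first$mapped & second$mapped & first$rname == second$rname
  hit <- first$rname[ok]
  hit <- hit[hit %in% transcript_ids]
  if (length(hit)) {
    tab <- table(hit)
    counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
  }
  counts
}

## Minimal SAM v1 reader for the fields the counting rule needs. Errors name
## the offending line.
parse_sam <- function(sam) {
  lines <- if (length(sam) == 1L && !grepl("\t", sam)) {
    if (!file.exists(sam)) stop("SAM file not found: ", sam)
    readLines(sam)
  } else as.character(sam)
  body_idx <- which(!startsWith(lines, "@") & nzchar(lines))
  if (length(body_idx) == 0L)
    return(data.frame(qname = character(0), flag = integer(0),
                      rname = character(0), paired = logical(0),
                      mapped = logical(0), secondary = logical(0),
                      supplementary = logical(0)))
  fields <- strsplit(lines[body_idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 11L))
    stop("invalid SAM record (fewer than 11 fields) at line ",
         body_idx[which(nf < 11L)[1L]])
  qname <- vapply(fields, `[[`, "", 1L)
  flag <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  if (anyNA(flag))
    stop("invalid SAM flag at line ", body_idx[which(is.na(flag))[1L]])
  rname <- vapply(fields, `[[`, "", 3L)
  mapped <- bitwAnd(flag, 4L) == 0L
  if (any(mapped & rname == "*"))
    stop("mapped record with no reference at line ",
         body_idx[which(mapped & rname == "*")[1L]])
  data.frame(qname = qname, flag = flag, rname = rname,
             paired = bitwAnd(flag, 1L) != 0L,
             mapped = mapped,
             secondary = bitwAnd(flag, 256L) != 0L,
             supplementary = bitwAnd(flag, 2048L) != 0L,
             stringsAsFactors = FALSE)
}

#' Build a count table from per-library SAM files
#'
#' @param sam_paths SAM file paths (or a list of in-memory SAM documents),
#'   one per library, in design order; names, if present, must match
#'   `design$library_id`.
#' @param transcript_ids row universe of the resulting table.
#' @param design a [library_design()] giving column order and names.
#' @return integer count matrix, transcripts x libraries.
#' @export
build_count_table <- function(sam_paths, transcript_ids, design) {
  validate_design(design)
  if (length(sam_paths) != nrow(design))
    stop("need one SAM document per library")
  if (!is.null(names(sam_paths))) {
    missing_lib <- setdiff(design$library_id, names(sam_paths))
    if (length(missing_lib))
      stop("no SAM document for library ", missing_lib[1L])
    sam_paths <- sam_paths[design$library_id]
  }
  cols <- lapply(seq_along(sam_paths), function(j) {
    s <- if (is.list(sam_paths)) sam_paths[[j]] else sam_paths[[j]]
    if (is.character(s) && length(s) == 1L && !grepl("\t", s) &&
        !file.exists(s))
      stop("missing SAM file for library ", design$library_id[j], ": ", s)
    count_fragments(s, transcript_ids)
  })
  m <- do.call(cbind, cols)
  colnames(m) <- design$library_id
  count_table(m)
}
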