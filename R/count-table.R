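#' Count tables
#'
#' The pipeline's central object is a non-negative integer matrix of fragment
#' counts, transcripts in rows and libraries in columns, with unique dimnames.
#'
#' @param counts integer matrix, transcripts x libraries, with dimnames.
#' @return the validated matrix (invisibly for `validate_count_table`).
#' @export
count_table <- function(counts) {
  validate_count_table(counts)
  counts
}

validate_count_table <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("counts must be a numeric matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have transcript and library dimnames")
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts)))
    stop("transcript and library ids must be unique")
  if (anyNA(counts) || any(counts < 0) || any(counts != floor(counts)))
    stop("counts must be non-negative integers")
  invisible(counts)
}

#' Read / write a count table as TSV
#'
#' The TSV layout has `transcript_id` as the first column and one column per
#' library.
#'
#' @param path file path.
#' @return `read_count_table` returns an integer matrix with dimnames.
#' @export
read_count_table <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  storage.mode(m) <- "double"
  count_table(m)
}

#' @rdname read_count_table
#' @param counts a count matrix.
#' @export
write_count_table <- function(counts, path) {
  d <- data.frame(transcript_id = rownames(counts), counts,
                  check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
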