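#' Transcript catalogs and assembly statistics
#'
#' A transcript catalog is a data.frame with columns `transcript_id` and
#' `length` (bp). Catalogs can be read from a FASTA file or a two-column
#' TSV.
#'
#' @param path FASTA (`.fa/.fasta`, possibly multi-line records; ids are
#'   taken up to the first whitespace) or TSV with columns id, length.
#' @return data.frame with `transcript_id`, `length`.
#' @export
read_catalog <- function(path) {
  first <- readLines(path, n = 1L)
  if (startsWith(first, ">")) {
    len <- Biostrings::fasta.seqlengths(path)
    ids <- sub("\\s.*$", "", names(len))
    cat <- data.frame(transcript_id = ids, length = as.integer(len),
                      stringsAsFactors = FALSE)
  } else {
    d <- utils::read.delim(path, stringsAsFactors = FALSE)
    cat <- data.frame(transcript_id = as.character(d[[1]]),
                      length = as.integer(d[[2]]),
                      stringsAsFactors = FALSE)
  }
  validate_catalog(cat)
}

validate_catalog <- function(catalog) {
  stopifnot(all(c("transcript_id", "length") %in% names(catalog)))
  if (any(catalog$length < 1)) stop("transcript lengths must be >= 1 bp")
  if (anyDuplicated(catalog$transcript_id))
    stop("transcript ids must be unique")
  catalog
}

#' Filter a catalog by minimum transcript length
#'
#' Retains transcripts of length `>= min_bp` (inclusive boundary), preserving
#' order. The default reproduces the standard 200 bp assembly filter.
#'
#' @param catalog a transcript catalog.
#' @param min_bp minimum length in bp.
#' @return the filtered catalog.
#' @export
filter_min_length <- function(catalog, min_bp = 200L) {
  stopifnot(min_bp >= 1)
  catalog[catalog$length >= min_bp, , drop = FALSE]
}

#' Assembly N50
#'
#' The largest length L such that transcripts of length >= L together cover
#' at least half of the total assembled bases.
#'
#' @param catalog a transcript catalog (or a numeric vector of lengths).
#' @return integer length in bp.
#' @export
n50 <- function(catalog) {
  len <- if (is.data.frame(catalog)) catalog$length else catalog
  if (length(len) == 0L) stop("cannot compute N50 of an empty catalog")
  len <- sort(as.numeric(len), decreasing = TRUE)
  len[which(cumsum(len) >= sum(len) / 2)[1L]]
}

#' Transcript length histogram
#'
#' Half-open bins `[lo, lo + width)` starting at the floor of the smallest
#' length to a multiple of `bin_width`.
#'
#' @param catalog a transcript catalog.
#' @param bin_width bin width in bp.
#' @return data.frame with `bin_start`, `bin_end`, `count`; counts sum to the
#'   catalog size.
#' @export
length_histogram <- function(catalog, bin_width = 100L) {
  stopifnot(bin_width >= 1)
  len <- catalog$length
  if (length(len) == 0L)
    return(data.frame(bin_start = integer(0), bin_end = integer(0),
                      count = integer(0)))
  lo <- floor(min(len) / bin_width) * bin_width
  hi <- floor(max(len) / bin_width) * bin_width
  starts <- seq(lo, hi, by = bin_width)
  idx <- floor((len - lo) / bin_width) + 1L
  counts <- tabulate(idx, nbins = length(starts))
  data.frame(bin_start = starts, bin_end = starts + bin_width,
             count = counts)
}

#' Assembly summary
#'
#' @param catalog a transcript catalog.
#' @param min_bp length filter applied before summarizing.
#' @return one-row data.frame: n_transcripts, total_bp, n50, mean_bp,
#'   median_bp, max_bp.
#' @export
assembly_summary <- function(catalog, min_bp = 200L) {
  f <- filter_min_length(catalog, min_bp)
  data.frame(n_transcripts = nrow(f),
             total_bp = sum(as.numeric(f$length)),
             n50 = n50(f),
             mean_bp = mean(f$length),
             median_bp = stats::median(f$length),
             max_bp = max(f$length))
}
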