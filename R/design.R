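#' Library design tables
#'
#' A library design records, for each sequencing library, which polyp type it
#' came from (gastrozooid, gonozooid or dactylozooid) and, for gonozooid
#' libraries only, the sex of the colony. All groupings in the pipeline are
#' driven by this table.
#'
#' @param library_id character vector of unique library identifiers.
#' @param polyp character vector, one of `"gastrozooid"`, `"gonozooid"`,
#'   `"dactylozooid"`.
#' @param sex character vector, one of `"male"`, `"female"`, `"na"`. Must be
#'   `"na"` exactly for non-gonozooid libraries.
#' @return A `data.frame` of class `lib_design` with columns `library_id`,
#'   `polyp`, `sex`.
#' @export
library_design <- function(library_id, polyp, sex) {
  polyp <- match.arg(polyp, POLYP_TYPES, several.ok = TRUE)
  sex <- match.arg(sex, c("male", "female", "na"), several.ok = TRUE)
  if (length(polyp) == 1L) polyp <- rep(polyp, length(library_id))
  if (length(sex) == 1L) sex <- rep(sex, length(library_id))
  d <- data.frame(library_id = as.character(library_id),
                  polyp = polyp, sex = sex,
                  stringsAsFactors = FALSE)
  validate_design(d)
  class(d) <- c("lib_design", "data.frame")
  d
}

POLYP_TYPES <- c("gastrozooid", "gonozooid", "dactylozooid")

validate_design <- function(d) {
  stopifnot(is.data.frame(d),
            all(c("library_id", "polyp", "sex") %in% names(d)))
  if (anyDuplicated(d$library_id))
    stop("library ids must be unique")
  if (!all(d$polyp %in% POLYP_TYPES))
    stop("unknown polyp type in design")
  if (!all(d$sex %in% c("male", "female", "na")))
    stop("sex must be male, female or na")
  bad <- (d$polyp == "gonozooid") != (d$sex != "na")
  if (any(bad))
    stop("sex must be recorded exactly for gonozooid libraries")
  invisible(d)
}

#' Default twelve-library study design
#'
#' Four libraries per polyp type; the four gonozooid libraries comprise two
#' male and two female colonies.
#'
#' @return A `lib_design` with 12 rows.
#' @examples
#' default_design()
#' @export
default_design <- function() {
  library_design(
    library_id = c(paste0("Ga", 1:4), paste0("Da", 1:4), paste0("Go", 1:4)),
    polyp = rep(c("gastrozooid", "dactylozooid", "gonozooid"), each = 4L),
    sex = c(rep("na", 8L), "female", "female", "male", "male")
  )
}

#' @export
print.lib_design <- function(x, ...) {
  cat("Library design:", nrow(x), "libraries\n")
  print(table(polyp = x$polyp, sex = x$sex))
  invisible(x)
}

#' Read / write a design table as TSV
#'
#' @param path file path.
#' @return `read_design` returns a `lib_design`.
#' @export
read_design <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  library_design(d$library_id, d$polyp, d$sex)
}

#' @rdname read_design
#' @param design a `lib_design`.
#' @export
write_design <- function(design, path) {
  utils::write.table(as.data.frame(design), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

## Condition labels used for dispersion estimation and group contrasts.
## scheme "pooled": the three polyp types; "split": gonozooid divided by sex.
condition_labels <- function(design, scheme = c("pooled", "split")) {
  scheme <- match.arg(scheme)
  lab <- design$polyp
  if (scheme == "split") {
    g <- design$polyp == "gonozooid"
    lab[g] <- paste0("gonozooid.", design$sex[g])
  }
  stats::setNames(lab, design$library_id)
}
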