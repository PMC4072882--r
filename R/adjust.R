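#' Partition transcripts by the male/female gonozooid contrast
#'
#' Step 1–2 of the heterogametic adjustment: a DE analysis between male and
#' female gonozooid libraries at `p_adj < alpha` splits the transcript
#' universe into three disjoint sets — `male_up` (higher in males),
#' `female_up` (higher in females, putative maternal transcripts) and
#' `nonsig` (everything else, including not-tested transcripts).
#'
#' @param counts count matrix.
#' @param design a [library_design()] with >= 2 male and >= 2 female
#'   gonozooid libraries.
#' @param engine dispersion engine.
#' @param alpha significance level of the screen.
#' @param sf optional precomputed size factors.
#' @return object of class `gametic_partition`: list with character-vector
#'   sets `nonsig`, `male_up`, `female_up`, plus `alpha`, `engine` and the
#'   sex-contrast `de` table.
#' @export
partition_by_sex <- function(counts, design,
                             engine = c("conservative", "shrinkage"),
                             alpha = 0.05, sf = NULL) {
  engine <- match.arg(engine)
  validate_design(design)
  n_male <- sum(design$polyp == "gonozooid" & design$sex == "male")
  n_female <- sum(design$polyp == "gonozooid" & design$sex == "female")
  if (n_male < 2L || n_female < 2L)
    stop("the sex screen needs >= 2 male and >= 2 female gonozooid ",
         "libraries (found ", n_male, " male, ", n_female, " female)")
  de <- run_de(counts, design, c("male", "female"), engine,
               dispersion_scheme = "split", sf = sf)
  sig <- !is.na(de$p_adj) & de$p_adj < alpha
  male_up <- de$transcript_id[sig & de$log2_fold_change > 0]
  female_up <- de$transcript_id[sig & de$log2_fold_change < 0]
  nonsig <- setdiff(de$transcript_id, c(male_up, female_up))
  structure(list(nonsig = nonsig, male_up = male_up,
                 female_up = female_up, alpha = alpha, engine = engine,
                 de = de),
            class = "gametic_partition")
}

#' @export
print.gametic_partition <- function(x, ...) {
  cat("Gametic partition (", x$engine, " engine, p_adj < ", x$alpha,
      "):\n", sep = "")
  cat("  non-significant:", length(x$nonsig), "\n")
  cat("  male-up        :", length(x$male_up), "\n")
  cat("  female-up      :", length(x$female_up),
      "(putative maternal transcripts)\n")
  invisible(x)
}

#' Heterogametically adjusted cross-polyp DE (two-branch workflow)
#'
#' Step 3 of the adjustment. Transcripts not affected by the sex contrast
#' (black branch) are tested across polyp types with all libraries, the
#' gonozooid condition comprising all four gonozooid libraries and
#' dispersions estimated under the sex-split grouping. Female-up
#' transcripts (putative maternal transcripts, red branch) are re-tested
#' with the female gonozooid libraries removed, so the gonozooid condition
#' is represented by male libraries only and a genuine somatic gonozooid
#' effect is not masked by oogenic expression. Male-up transcripts are
#' excluded from the template pool entirely. Each branch is BH-adjusted
#' within itself and the rows are combined with a `branch` column.
#'
#' @param counts count matrix.
#' @param design a [library_design()].
#' @param partition a [partition_by_sex()] result (same engine).
#' @param comparison length-2 character of polyp types, first name =
#'   numerator of the fold change.
#' @param engine dispersion engine.
#' @param sf optional precomputed size factors (from the full table).
#' @param dispersion_black,dispersion_red optional precomputed
#'   `dispersion_fit`s to reuse across the three pairwise comparisons.
#' @return a `de_table` with a `branch` column (`"black"`/`"red"`);
#'   attribute `excluded_male_up` lists transcripts tested in neither
#'   branch.
#' @export
run_adjusted <- function(counts, design, partition, comparison,
                         engine = c("conservative", "shrinkage"),
                         sf = NULL, dispersion_black = NULL,
                         dispersion_red = NULL) {
  engine <- match.arg(engine)
  stopifnot(inherits(partition, "gametic_partition"))
  validate_design(design)
  comparison <- vapply(comparison, resolve_condition, "")
  if (!all(comparison %in% POLYP_TYPES))
    stop("adjusted comparisons are between polyp types; got ",
         paste(comparison, collapse = ", "))
  if (is.null(sf)) sf <- size_factors(counts[, design$library_id,
                                             drop = FALSE])

  black <- if (length(partition$nonsig)) {
    run_de(counts, design, comparison, engine,
           dispersion_scheme = "split", transcripts = partition$nonsig,
           sf = sf, dispersion = dispersion_black)
  }
  red_libs <- design$library_id[!(design$polyp == "gonozooid" &
                                  design$sex == "female")]
  red <- if (length(partition$female_up)) {
    run_de(counts, design, comparison, engine,
           dispersion_scheme = "split", transcripts = partition$female_up,
           use_libraries = red_libs, sf = sf, dispersion = dispersion_red)
  }
  pieces <- list()
  if (!is.null(black))
    pieces$black <- cbind(as.data.frame(black), branch = "black")
  if (!is.null(red))
    pieces$red <- cbind(as.data.frame(red), branch = "red")
  out <- if (length(pieces)) do.call(rbind, c(pieces, make.row.names = FALSE))
         else data.frame(transcript_id = character(0), base_mean = numeric(0),
                         log2_fold_change = numeric(0),
                         p_value = numeric(0), p_adj = numeric(0),
                         branch = character(0), stringsAsFactors = FALSE)
  res <- de_table(out, comparison = comparison, engine = engine,
                  branch = "combined")
  attr(res, "excluded_male_up") <- partition$male_up
  res
}

#' Unadjusted ("full dataset") cross-polyp DE
#'
#' The baseline analysis: all transcripts, all libraries, dispersions
#' estimated with the three polyp types as conditions (male and female
#' gonozooid libraries binned together). Contrast this with
#' [run_adjusted()] to see the power gained by removing heterogametic
#' variance.
#'
#' @inheritParams run_adjusted
#' @return a `de_table`.
#' @export
run_full <- function(counts, design, comparison,
                     engine = c("conservative", "shrinkage"),
                     sf = NULL, dispersion = NULL) {
  engine <- match.arg(engine)
  run_de(counts, design, comparison, engine,
         dispersion_scheme = "pooled", sf = sf, dispersion = dispersion)
}

#' Write a gametic partition as TSV
#' @param partition a `gametic_partition`.
#' @param path file path.
#' @export
write_partition <- function(partition, path) {
  d <- data.frame(
    transcript_id = c(partition$nonsig, partition$male_up,
                      partition$female_up),
    set = c(rep("nonsig", length(partition$nonsig)),
            rep("male_up", length(partition$male_up)),
            rep("female_up", length(partition$female_up))),
    stringsAsFactors = FALSE)
  d <- d[order(d$transcript_id), , drop = FALSE]
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
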