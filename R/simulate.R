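#' Simulation parameters
#'
#' Parameters for the negative-binomial count simulator. Transcripts are
#' assigned an effect class; counts for transcript i in library j are drawn
#' NB with mean `s_j * q_i * 2^(effect applied to library j)` and variance
#' `mean + alpha_i * mean^2`.
#'
#' Effect classes:
#' \describe{
#'   \item{null}{no effect anywhere.}
#'   \item{gast_up/gast_down, dact_up/dact_down, gono_up/gono_down}{somatic
#'     effect of +/- `log2_effect_magnitude` in all libraries of one polyp.}
#'   \item{male_gametic / female_gametic}{up-regulation by
#'     `log2_effect_magnitude` restricted to gonozooid libraries of the
#'     matching sex (gametogenic expression).}
#'   \item{maternal_somatic}{a maternal transcript: female-gametic
#'     up-regulation of +2 log2 units in female gonozooid libraries, plus a
#'     gonozooid-somatic effect of `log2_effect_magnitude` in all gonozooid
#'     libraries. This is the class the adjustment workflow's red branch
#'     exists to rescue.}
#' }
#'
#' @param n_transcripts number of simulated transcripts.
#' @param class_proportions named numeric vector over the effect classes,
#'   summing to 1.
#' @param log2_effect_magnitude effect size, log2 units.
#' @param depth_factors positive per-library depth multipliers (recycled or
#'   named by library id).
#' @param dispersion_log_mean,dispersion_log_sd log-normal parameters of the
#'   per-transcript dispersion alpha (natural-log scale).
#' @param baseline_mean_log_range baseline means q_i are drawn log-uniform
#'   over `2^range` (log2 units).
#' @param seed integer root seed; all stages derive their streams from it.
#' @return a `sim_params` list.
#' @export
sim_params <- function(n_transcripts = 5000L,
                       class_proportions = c(
                         null = 0.82,
                         gast_up = 0.015, gast_down = 0.015,
                         dact_up = 0.015, dact_down = 0.015,
                         gono_up = 0.015, gono_down = 0.015,
                         male_gametic = 0.03, female_gametic = 0.04,
                         maternal_somatic = 0.02),
                       log2_effect_magnitude = 3,
                       depth_factors = NULL,
                       dispersion_log_mean = log(0.1),
                       dispersion_log_sd = 0.8,
                       baseline_mean_log_range = c(2, 12),
                       seed = 1L) {
  p <- numeric(length(EFFECT_CLASSES))
  names(p) <- EFFECT_CLASSES
  if (is.null(names(class_proportions)))
    stop("class_proportions must be named")
  if (!all(names(class_proportions) %in% EFFECT_CLASSES))
    stop("unknown effect class: ",
         paste(setdiff(names(class_proportions), EFFECT_CLASSES),
               collapse = ", "))
  p[names(class_proportions)] <- class_proportions
  if (anyNA(p) || any(p < 0) || abs(sum(p) - 1) > 1e-8)
    stop("class_proportions must be non-negative and sum to 1")
  if (!is.null(depth_factors) &&
      (anyNA(depth_factors) || any(depth_factors <= 0)))
    stop("depth_factors must be positive")
  stopifnot(n_transcripts >= 1,
            is.finite(log2_effect_magnitude),
            is.finite(dispersion_log_mean), dispersion_log_sd >= 0,
            length(baseline_mean_log_range) == 2L,
            diff(baseline_mean_log_range) >= 0)
  structure(list(n_transcripts = as.integer(n_transcripts),
                 class_proportions = p,
                 log2_effect_magnitude = log2_effect_magnitude,
                 depth_factors = depth_factors,
                 dispersion_log_mean = dispersion_log_mean,
                 dispersion_log_sd = dispersion_log_sd,
                 baseline_mean_log_range = baseline_mean_log_range,
                 seed = as.integer(seed)),
            class = "sim_params")
}

EFFECT_CLASSES <- c("null",
                    "gast_up", "gast_down", "dact_up", "dact_down",
                    "gono_up", "gono_down",
                    "male_gametic", "female_gametic", "maternal_somatic")

## One root seed, per-stage derived streams: draws of stage k never depend on
## how many numbers a later stage consumes, and all per-transcript draws are
## made in transcript order so that growing n_transcripts extends, rather than
## reshuffles, the simulated universe.
stage_seed <- function(seed, stage) {
  as.integer((as.double(seed) * 977 + stage * 7919) %% 2147483647)
}

## Default depth factors: a fixed, mildly asymmetric spread of sequencing
## depths (about 2.7-fold between shallowest and deepest library).
default_depths <- function(m) {
  exp(seq(-0.5, 0.5, length.out = m))
}

#' Simulate a count table with ground truth
#'
#' Draws effect classes, baseline means, dispersions and NB counts under the
#' given design. Identical `(params, design)` (the seed lives in `params`)
#' reproduce identical output bit for bit.
#'
#' @param params a [sim_params()] object.
#' @param design a [library_design()]; default [default_design()].
#' @return list with `counts` (integer matrix, transcripts x libraries),
#'   `truth` (data.frame: transcript_id, effect_class, log2_effect,
#'   true_dispersion), and `design`.
#' @export
simulate_counts <- function(params, design = default_design()) {
  stopifnot(inherits(params, "sim_params"))
  validate_design(design)
  n <- params$n_transcripts
  m <- nrow(design)
  depths <- params$depth_factors
  if (is.null(depths)) depths <- default_depths(m)
  depths <- rep_len(depths, m)

  tid <- sprintf("T%05d", seq_len(n))

  ## stage 1: effect classes via inverse-CDF on uniforms (prefix-stable)
  set.seed(stage_seed(params$seed, 1L))
  u <- stats::runif(n)
  cls <- EFFECT_CLASSES[findInterval(u, cumsum(params$class_proportions),
                                     left.open = TRUE) + 1L]

  ## stage 2: baseline means, log-uniform in log2 units
  set.seed(stage_seed(params$seed, 2L))
  r <- params$baseline_mean_log_range
  q <- 2^stats::runif(n, r[1], r[2])

  ## stage 3: dispersions
  set.seed(stage_seed(params$seed, 3L))
  alpha <- stats::rlnorm(n, params$dispersion_log_mean,
                         params$dispersion_log_sd)

  E <- params$log2_effect_magnitude
  fc <- effect_multipliers(cls, design, E)          # n x m fold-change matrix
  mu <- (q * fc) * rep(depths, each = n)

  ## stage 4: counts, drawn transcript by transcript (prefix-stable)
  set.seed(stage_seed(params$seed, 4L))
  counts <- matrix(0, n, m, dimnames = list(tid, design$library_id))
  poisson_like <- alpha < 1e-8
  for (i in seq_len(n)) {
    counts[i, ] <- if (poisson_like[i]) stats::rpois(m, mu[i, ])
                   else stats::rnbinom(m, mu = mu[i, ], size = 1 / alpha[i])
  }

  sign_of <- c(null = 0, gast_up = 1, gast_down = -1, dact_up = 1,
               dact_down = -1, gono_up = 1, gono_down = -1,
               male_gametic = 1, female_gametic = 1, maternal_somatic = 1)
  truth <- data.frame(transcript_id = tid,
                      effect_class = cls,
                      log2_effect = ifelse(cls == "null", 0,
                                           sign_of[cls] * E),
                      true_dispersion = alpha,
                      stringsAsFactors = FALSE)
  list(counts = count_table(counts), truth = truth, design = design)
}

## Per-library fold-change 2^(log2 effect) for each transcript's class.
effect_multipliers <- function(cls, design, E) {
  n <- length(cls)
  m <- nrow(design)
  lfc <- matrix(0, n, m)   # log2 fold change vs baseline
  polyp_of <- list(gast = design$polyp == "gastrozooid",
                   dact = design$polyp == "dactylozooid",
                   gono = design$polyp == "gonozooid")
  male_gono <- polyp_of$gono & design$sex == "male"
  female_gono <- polyp_of$gono & design$sex == "female"
  add <- function(rows, cols, x) {
    if (any(rows) && any(cols))
      lfc[rows, cols] <<- lfc[rows, cols] + x
  }
  add(cls == "gast_up", polyp_of$gast, E)
  add(cls == "gast_down", polyp_of$gast, -E)
  add(cls == "dact_up", polyp_of$dact, E)
  add(cls == "dact_down", polyp_of$dact, -E)
  add(cls == "gono_up", polyp_of$gono, E)
  add(cls == "gono_down", polyp_of$gono, -E)
  add(cls == "male_gametic", male_gono, E)
  add(cls == "female_gametic", female_gono, E)
  ## maternal transcripts: somatic gonozooid effect plus +2 gametic in females
  add(cls == "maternal_somatic", polyp_of$gono, E)
  add(cls == "maternal_somatic", female_gono, 2)
  2^lfc
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Simulation parameters:", x$n_transcripts, "transcripts, seed",
      x$seed, "\n")
  cat("  log2 effect magnitude:", x$log2_effect_magnitude, "\n")
  nz <- x$class_proportions[x$class_proportions > 0]
  cat("  classes:", paste(sprintf("%s=%.3g", names(nz), nz),
                          collapse = ", "), "\n")
  invisible(x)
}

#' Write a simulation's ground-truth table as TSV
#' @param truth the `truth` data.frame from [simulate_counts()].
#' @param path file path.
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
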