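#' Pipeline configuration
#'
#' Either simulation parameters (counts are generated with ground truth) or
#' paths to an existing count table and design TSV.
#'
#' @param counts_tsv,design_tsv optional input paths; when `NULL`, data are
#'   simulated from `sim`.
#' @param sim a [sim_params()] object used when no input paths are given.
#' @param alpha significance threshold used throughout.
#' @param engines subset of `c("conservative", "shrinkage")`.
#' @param min_length assembly length filter (bp), applied when a catalog is
#'   provided.
#' @param catalog optional FASTA/TSV path for assembly statistics.
#' @param output_dir where results are written.
#' @param seed root seed (overrides the seed inside `sim`).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(counts_tsv = NULL, design_tsv = NULL,
                            sim = sim_params(), alpha = 0.05,
                            engines = c("conservative", "shrinkage"),
                            min_length = 200L, catalog = NULL,
                            output_dir = "polypDE_out", seed = NULL) {
  stopifnot(alpha > 0, alpha <= 1,
            all(engines %in% c("conservative", "shrinkage")))
  if (!is.null(seed)) sim$seed <- as.integer(seed)
  structure(list(counts_tsv = counts_tsv, design_tsv = design_tsv,
                 sim = sim, alpha = alpha, engines = engines,
                 min_length = min_length, catalog = catalog,
                 output_dir = output_dir),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' simulate (or load) counts -> size factors -> sex screen and partition ->
#' full and adjusted pairwise DE under each engine -> consensus
#' polyp-specificity calls and Venn summary -> library-distance, MA and
#' dispersion diagnostics. All results are written as TSV under
#' `config$output_dir` together with a JSON manifest carrying the config
#' echo, seed, per-stage row counts and md5 hashes of every output file.
#' Identical config and seed reproduce identical files.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return (invisibly) a list with the in-memory results and the manifest.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(out, "run.log")
  cat("", file = logfile)
  say <- function(...) {
    msg <- paste0(...)
    cat(msg, "\n", file = logfile, append = TRUE)
    if (!quiet) message(msg)
  }

  ## -- data ----------------------------------------------------------------
  truth <- NULL
  if (is.null(config$counts_tsv)) {
    say("simulating counts: ", config$sim$n_transcripts,
        " transcripts, seed ", config$sim$seed)
    simdat <- simulate_counts(config$sim)
    counts <- simdat$counts; design <- simdat$design; truth <- simdat$truth
    write_truth(truth, file.path(out, "truth.tsv"))
  } else {
    say("loading counts from ", config$counts_tsv)
    counts <- read_count_table(config$counts_tsv)
    design <- read_design(config$design_tsv)
  }
  write_design(design, file.path(out, "design.tsv"))
  write_count_table(counts, file.path(out, "counts.tsv"))
  say("counts: ", nrow(counts), " transcripts x ", ncol(counts),
      " libraries")

  if (!is.null(config$catalog)) {
    cat0 <- read_catalog(config$catalog)
    stats <- assembly_summary(cat0, config$min_length)
    utils::write.table(stats, file.path(out, "assembly_stats.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      length_histogram(filter_min_length(cat0, config$min_length)),
      file.path(out, "length_histogram.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    say("assembly: ", stats$n_transcripts, " transcripts >= ",
        config$min_length, " bp, N50 ", stats$n50)
  }

  sf <- size_factors(counts)
  utils::write.table(
    data.frame(library_id = names(sf), size_factor = sf,
               row.names = NULL),
    file.path(out, "size_factors.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)

  comparisons <- list(c("dactylozooid", "gastrozooid"),
                      c("dactylozooid", "gonozooid"),
                      c("gastrozooid", "gonozooid"))
  cmp_key <- function(cmp) paste(substr(cmp, 1, 4), collapse = "_vs_")

  partitions <- list()
  full_tabs <- adj_tabs <- list()
  counts_stage <- list(n_transcripts = nrow(counts),
                       n_libraries = ncol(counts))
  for (eng in config$engines) {
    say("[", eng, "] sex screen")
    part <- partition_by_sex(counts, design, eng, config$alpha, sf = sf)
    partitions[[eng]] <- part
    write_partition(part, file.path(out, paste0("partition_", eng, ".tsv")))
    counts_stage[[paste0("partition_", eng)]] <-
      list(nonsig = length(part$nonsig), male_up = length(part$male_up),
           female_up = length(part$female_up))

    full_tabs[[eng]] <- list(); adj_tabs[[eng]] <- list()
    for (cmp in comparisons) {
      key <- cmp_key(cmp)
      say("[", eng, "] full DE ", key)
      f <- run_full(counts, design, cmp, eng, sf = sf)
      full_tabs[[eng]][[key]] <- f
      write_de_table(f, file.path(out, paste0("de_full_", eng, "_", key,
                                              ".tsv")))
      say("[", eng, "] adjusted DE ", key)
      a <- run_adjusted(counts, design, part, cmp, eng, sf = sf)
      adj_tabs[[eng]][[key]] <- a
      write_de_table(a, file.path(out, paste0("de_adjusted_", eng, "_",
                                              key, ".tsv")))
      counts_stage[[paste0("de_", eng, "_", key)]] <-
        list(full_sig = sum(f$p_adj < config$alpha, na.rm = TRUE),
             adjusted_sig = sum(a$p_adj < config$alpha, na.rm = TRUE))
    }
  }

  calls <- venn <- NULL
  if (all(c("conservative", "shrinkage") %in% config$engines)) {
    say("consensus polyp-specificity calls")
    calls <- call_polyp_specific(adj_tabs, config$alpha,
                                 universe = rownames(counts))
    write_calls(calls, file.path(out, "specificity_calls.tsv"))
    venn <- summarize_venn(calls)
    utils::write.table(venn$per_polyp,
                       file.path(out, "venn_per_polyp.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(venn$intersections,
                       file.path(out, "venn_intersections.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    counts_stage$specificity <- list(called = sum(!is.na(calls$polyp)))
  }

  ## -- diagnostics ---------------------------------------------------------
  say("diagnostics")
  d_before <- library_distances(counts, sf)
  hetero <- unique(unlist(lapply(partitions, function(p)
    c(p$male_up, p$female_up))))
  d_after <- library_distances(counts, sf, exclude = hetero)
  write_dist <- function(d, path) {
    utils::write.table(data.frame(library_id = rownames(d), d,
                                  check.names = FALSE, row.names = NULL),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_dist(d_before, file.path(out, "distances_before.tsv"))
  write_dist(d_after, file.path(out, "distances_after.tsv"))
  utils::write.table(mds_2d(d_before), file.path(out, "mds_before.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(mds_2d(d_after), file.path(out, "mds_after.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  eng1 <- config$engines[1]
  utils::write.table(ma_data(partitions[[eng1]]$de, config$alpha),
                     file.path(out, "ma_sex_contrast.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  dm_pooled <- estimate_dispersion(counts, sf,
                                   condition_labels(design, "pooled"),
                                   eng1)
  dm_split <- estimate_dispersion(counts, sf,
                                  condition_labels(design, "split"),
                                  eng1)
  utils::write.table(dispersion_mean_data(dm_pooled)$points,
                     file.path(out, "dispersion_pooled.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dispersion_mean_data(dm_split)$points,
                     file.path(out, "dispersion_split.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ## -- manifest ------------------------------------------------------------
  files <- sort(setdiff(list.files(out), c("manifest.json", "run.log")))
  manifest <- list(
    package_version = as.character(utils::packageVersion("polypDE")),
    seed = config$sim$seed,
    alpha = config$alpha,
    engines = config$engines,
    simulated = is.null(config$counts_tsv),
    stage_counts = counts_stage,
    file_md5 = as.list(tools::md5sum(file.path(out, files))))
  names(manifest$file_md5) <- files
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  say("done; outputs in ", out)
  invisible(list(counts = counts, design = design, truth = truth,
                 size_factors = sf, partitions = partitions,
                 full = full_tabs, adjusted = adj_tabs,
                 calls = calls, venn = venn,
                 distances = list(before = d_before, after = d_after),
                 manifest = manifest, output_dir = out))
}
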