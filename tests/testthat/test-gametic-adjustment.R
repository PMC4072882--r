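test_that("the sex screen partitions the universe disjointly", {
  sim <- simulate_counts(sim_params(n_transcripts = 1200, seed = 51))
  sf <- size_factors(sim$counts)
  part <- partition_by_sex(sim$counts, sim$design, "conservative", sf = sf)
  sets <- list(part$nonsig, part$male_up, part$female_up)
  expect_equal(sum(lengths(sets)), nrow(sim$counts))
  expect_equal(length(Reduce(intersect, sets)), 0L)
  expect_setequal(unlist(sets), rownames(sim$counts))
  ## a design without sexed gonozooid replicates errors
  d <- sim$design
  d$sex[d$sex == "male"] <- "female"
  expect_error(partition_by_sex(sim$counts, d, "conservative"),
               "male")
})

test_that("strong planted gametic effects are captured by the screen", {
  ## 16-fold male-gametic transcripts at high expression, 2 vs 2 libraries
  p <- sim_params(n_transcripts = 1500,
                  class_proportions = c(null = 0.9, male_gametic = 0.1),
                  log2_effect_magnitude = 4,
                  baseline_mean_log_range = c(8, 12), seed = 52)
  sim <- simulate_counts(p)
  part <- partition_by_sex(sim$counts, sim$design, "shrinkage")
  planted <- sim$truth$transcript_id[
    sim$truth$effect_class == "male_gametic"]
  expect_gte(mean(planted %in% part$male_up), 0.8)
  ## with no gametic transcripts at all, captures stay near zero
  p0 <- sim_params(n_transcripts = 1500,
                   class_proportions = c(null = 1), seed = 53)
  sim0 <- simulate_counts(p0)
  part0 <- partition_by_sex(sim0$counts, sim0$design, "shrinkage")
  expect_lte(length(part0$male_up) + length(part0$female_up),
             0.05 * 1500)
})

test_that("adjusted analysis unions disjoint branches and drops male-up", {
  sim <- simulate_counts(sim_params(n_transcripts = 1500, seed = 54))
  sf <- size_factors(sim$counts)
  part <- partition_by_sex(sim$counts, sim$design, "conservative", sf = sf)
  adj <- run_adjusted(sim$counts, sim$design, part, c("gono", "gast"),
                      "conservative", sf = sf)
  black <- adj$transcript_id[adj$branch == "black"]
  red <- adj$transcript_id[adj$branch == "red"]
  expect_setequal(black, part$nonsig)
  expect_setequal(red, part$female_up)
  expect_equal(length(intersect(black, red)), 0L)
  expect_setequal(c(black, red, attr(adj, "excluded_male_up")),
                  rownames(sim$counts))
  ## degenerate partition: run_adjusted collapses to split-sex run_de
  empty_part <- structure(list(nonsig = rownames(sim$counts),
                               male_up = character(0),
                               female_up = character(0),
                               alpha = 0.05, engine = "conservative"),
                          class = "gametic_partition")
  adj0 <- run_adjusted(sim$counts, sim$design, empty_part,
                       c("gono", "gast"), "conservative", sf = sf)
  ref <- run_de(sim$counts, sim$design, c("gono", "gast"), "conservative",
                dispersion_scheme = "split", sf = sf)
  expect_equal(adj0$p_value[match(ref$transcript_id, adj0$transcript_id)],
               ref$p_value)
  expect_true(all(adj0$branch == "black"))
})

test_that("maternal transcripts are rescued through the red branch", {
  ## targeted simulation: maternal somatic effect log2 = 3
  p <- sim_params(n_transcripts = 2000,
                  class_proportions = c(null = 0.85, female_gametic = 0.05,
                                        maternal_somatic = 0.1),
                  log2_effect_magnitude = 3,
                  baseline_mean_log_range = c(6, 12), seed = 55)
  sim <- simulate_counts(p)
  sf <- size_factors(sim$counts)
  part <- partition_by_sex(sim$counts, sim$design, "shrinkage", sf = sf)
  mat <- sim$truth$transcript_id[
    sim$truth$effect_class == "maternal_somatic"]
  mat_red <- intersect(mat, part$female_up)
  expect_gt(length(mat_red), 20)
  adj <- run_adjusted(sim$counts, sim$design, part, c("gono", "gast"),
                      "shrinkage", sf = sf)
  red <- adj[adj$branch == "red", ]
  rescued <- red$transcript_id[!is.na(red$p_adj) & red$p_adj < 0.05 &
                                 red$log2_fold_change > 0]
  expect_gte(mean(mat_red %in% rescued), 0.7)
})

test_that("adjustment increases power for somatic effects on average", {
  somatic <- c("gast_up", "gast_down", "dact_up", "dact_down",
               "gono_up", "gono_down", "maternal_somatic")
  gain <- vapply(1:3, function(seed) {
    sim <- simulate_counts(sim_params(n_transcripts = 1200, seed = seed))
    sf <- size_factors(sim$counts)
    part <- partition_by_sex(sim$counts, sim$design, "conservative",
                             sf = sf)
    affected_by <- list(
      c("dact", "gast"), c("dact", "gono"), c("gast", "gono"))
    tp_adj <- tp_full <- 0
    for (cmp in affected_by) {
      cls_map <- list(dact = c("dact_up", "dact_down"),
                      gast = c("gast_up", "gast_down"),
                      gono = c("gono_up", "gono_down", "maternal_somatic"))
      truthset <- sim$truth$transcript_id[
        sim$truth$effect_class %in% unlist(cls_map[cmp])]
      a <- run_adjusted(sim$counts, sim$design, part, cmp, "conservative",
                        sf = sf)
      f <- run_full(sim$counts, sim$design, cmp, "conservative", sf = sf)
      tp_adj <- tp_adj +
        sum(truthset %in% a$transcript_id[!is.na(a$p_adj) & a$p_adj < 0.05])
      tp_full <- tp_full +
        sum(truthset %in% f$transcript_id[!is.na(f$p_adj) & f$p_adj < 0.05])
    }
    tp_adj - tp_full
  }, 0)
  expect_gte(mean(gain), 0)
})

test_that("run_full is the pooled-grouping analysis", {
  sim <- simulate_counts(sim_params(n_transcripts = 600, seed = 56))
  sf <- size_factors(sim$counts)
  f1 <- run_full(sim$counts, sim$design, c("dact", "gast"), "conservative",
                 sf = sf)
  f2 <- run_de(sim$counts, sim$design, c("dact", "gast"), "conservative",
               dispersion_scheme = "pooled", sf = sf)
  expect_equal(f1$p_value, f2$p_value)
  expect_equal(f1$log2_fold_change, f2$log2_fold_change)
})
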