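test_that("size factors follow the median-of-ratios closed form", {
  ## identical libraries
  m <- matrix(rep(c(5, 9, 20, 3), 3), 4, 3,
              dimnames = list(paste0("T", 1:4), paste0("L", 1:3)))
  expect_equal(size_factors(m), c(L1 = 1, L2 = 1, L3 = 1))
  ## exact doubling of one of two libraries
  set.seed(12)
  base <- matrix(rpois(40, 60) + 1, 20, 2,
                 dimnames = list(paste0("T", 1:20), c("a", "b")))
  base[, 2] <- 2 * base[, 1]
  expect_equal(size_factors(base), c(a = 1 / sqrt(2), b = sqrt(2)))
  ## brute-force oracle on random 5x4 matrices
  for (seed in 1:20) {
    set.seed(seed)
    k <- matrix(rpois(20, 40) + 1, 5, 4,
                dimnames = list(paste0("T", 1:5), paste0("L", 1:4)))
    geo <- apply(k, 1, function(x) prod(x)^(1 / length(x)))
    oracle <- apply(k / geo, 2, median)
    expect_equal(size_factors(k), oracle)
  }
  ## no all-positive row
  z <- matrix(c(0, 5, 5, 0), 2, 2,
              dimnames = list(c("T1", "T2"), c("a", "b")))
  expect_error(size_factors(z), "pseudo-reference")
})

test_that("raw dispersions vanish on Poisson data and recover constant NB alpha", {
  ## Poisson-like data: mean raw dispersion near zero
  pp <- sim_params(n_transcripts = 3000, class_proportions = c(null = 1),
                   dispersion_log_mean = log(1e-12), dispersion_log_sd = 0,
                   seed = 31)
  simp <- simulate_counts(pp)
  sfp <- size_factors(simp$counts)
  suppressWarnings(
    fp <- estimate_dispersion(simp$counts, sfp, split_labels(simp$design),
                              "conservative"))
  expect_lte(mean(fp$table$raw_alpha, na.rm = TRUE), 0.01)

  ## constant true alpha = 0.2: median final within [0.1, 0.4], both engines
  pc <- sim_params(n_transcripts = 3000, class_proportions = c(null = 1),
                   dispersion_log_mean = log(0.2), dispersion_log_sd = 0,
                   seed = 32)
  simc <- simulate_counts(pc)
  sfc <- size_factors(simc$counts)
  for (eng in c("conservative", "shrinkage")) {
    f <- estimate_dispersion(simc$counts, sfc, split_labels(simc$design),
                             eng)
    med <- median(f$table$final_alpha, na.rm = TRUE)
    expect_gte(med, 0.1)
    expect_lte(med, 0.4)
    ## conservative-engine invariant: final = max(raw, fitted)
    if (eng == "conservative") {
      tab <- f$table[f$table$tested, ]
      expect_equal(tab$final_alpha, pmax(tab$raw_alpha, tab$fitted_alpha))
    }
  }
})

test_that("splitting gonozooid sexes lowers dispersion on sex-effect data", {
  sim <- simulate_counts(sim_params(n_transcripts = 2000, seed = 33))
  sf <- size_factors(sim$counts)
  for (eng in c("conservative", "shrinkage")) {
    f_pooled <- estimate_dispersion(sim$counts, sf,
                                    pooled_labels(sim$design), eng)
    f_split <- estimate_dispersion(sim$counts, sf,
                                   split_labels(sim$design), eng)
    expect_lt(mean(f_split$table$final_alpha, na.rm = TRUE),
              mean(f_pooled$table$final_alpha, na.rm = TRUE))
  }
})

test_that("exact test matches enumeration oracle and its symmetries", {
  ## symmetric split gives p = 1
  expect_equal(nb_exact_test(c(3, 2), c(2, 3), c(1, 1), c(1, 1), 0), 1)
  ## worked example: 10 vs 0 at equal depth, alpha = 0.1
  p10 <- nb_exact_test(10, 0, 1, 1, 0.1)
  expect_equal(p10, oracle_exact_test(10, 0, 1, 1, 0.1),
               tolerance = 1e-12)
  ## label swap leaves p unchanged
  set.seed(13)
  for (i in 1:25) {
    kA <- rpois(4, 30); kB <- rpois(4, 30)
    sA <- runif(4, 0.5, 2); sB <- runif(4, 0.5, 2)
    a <- runif(1, 0, 1)
    p1 <- nb_exact_test(kA, kB, sA, sB, a)
    p2 <- nb_exact_test(kB, kA, sB, sA, a)
    expect_equal(p1, p2, tolerance = 1e-12)
    expect_gt(p1, 0); expect_lte(p1, 1)
    expect_equal(p1, oracle_exact_test(kA, kB, sA, sB, a),
                 tolerance = 1e-10)
  }
  ## zero total is not tested, never p = 0
  expect_true(is.na(nb_exact_test(c(0, 0), c(0, 0), c(1, 1), c(1, 1), 0.1)))
  ## large totals switch to the normal approximation and stay close
  p_big <- nb_exact_test(6000, 5800, 1, 1, 0.001, enum_cap = 20000)
  p_apx <- nb_exact_test(6000, 5800, 1, 1, 0.001, enum_cap = 100)
  expect_equal(p_apx, p_big, tolerance = 0.1)
})

test_that("BH adjustment equals the step-up oracle and handles NA", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  set.seed(14)
  for (i in 1:10) {
    p <- runif(sample(3:20, 1))
    expect_equal(bh_adjust(p), oracle_bh(p))
  }
  p <- c(0.01, NA, 0.5)
  adj <- bh_adjust(p)
  expect_true(is.na(adj[2]))
  expect_equal(adj[c(1, 3)], oracle_bh(p[c(1, 3)]))
  ## p_adj >= p wherever both defined
  set.seed(15)
  p <- runif(50)
  expect_true(all(bh_adjust(p) >= p))
})

test_that("run_de is calibrated on null data and recovers planted effects", {
  ## identical condition columns: fold changes 0, no significance
  pn <- sim_params(n_transcripts = 1000, class_proportions = c(null = 1),
                   seed = 41)
  simn <- simulate_counts(pn)
  dact <- simn$design$library_id[simn$design$polyp == "dactylozooid"]
  gast <- simn$design$library_id[simn$design$polyp == "gastrozooid"]
  cnt <- simn$counts
  cnt[, gast] <- cnt[, dact]
  sfn <- size_factors(cnt)
  for (eng in c("conservative", "shrinkage")) {
    de <- run_de(cnt, simn$design, c("dact", "gast"), eng, sf = sfn)
    expect_true(all(de$log2_fold_change == 0))
    ## balanced splits are modal, hence p = 1, except when a very large
    ## dispersion makes the conditional split distribution U-shaped
    expect_gte(mean(de$p_value == 1, na.rm = TRUE), 0.99)
    expect_equal(sum(de$p_adj < 0.05, na.rm = TRUE), 0L)
    expect_true(all(de$p_adj >= de$p_value, na.rm = TRUE))
    ## not-tested iff all-zero in the compared groups
    allzero <- rowSums(cnt[, c(dact, gast)]) == 0
    expect_equal(is.na(de$p_value), unname(allzero))
  }
  ## planted 4-fold effects at high expression: sign recovery >= 99%
  pe <- sim_params(n_transcripts = 1500,
                   class_proportions = c(null = 0.8, dact_up = 0.1,
                                         dact_down = 0.1),
                   log2_effect_magnitude = 2,
                   baseline_mean_log_range = c(7, 12), seed = 42)
  sime <- simulate_counts(pe)
  sfe <- size_factors(sime$counts)
  de <- run_de(sime$counts, sime$design, c("dact", "gast"), "shrinkage",
               sf = sfe)
  tr <- sime$truth
  up <- tr$transcript_id[tr$effect_class == "dact_up"]
  dn <- tr$transcript_id[tr$effect_class == "dact_down"]
  sgn <- sign(de$log2_fold_change[match(c(up, dn), de$transcript_id)])
  expect_gte(mean(sgn == rep(c(1, -1), c(length(up), length(dn)))), 0.99)
  ## direction convention: positive log2FC = higher in first-named condition
  de_rev <- run_de(sime$counts, sime$design, c("gast", "dact"),
                   "shrinkage", sf = sfe)
  expect_equal(de_rev$log2_fold_change, -de$log2_fold_change)
})

test_that("conservative engine calls no more than shrinkage on average", {
  diffs <- vapply(1:3, function(seed) {
    sim <- simulate_counts(sim_params(n_transcripts = 1200, seed = seed))
    sf <- size_factors(sim$counts)
    n_sig <- vapply(c("conservative", "shrinkage"), function(eng) {
      de <- run_de(sim$counts, sim$design, c("dact", "gast"), eng,
                   sf = sf)
      sum(de$p_adj < 0.05, na.rm = TRUE)
    }, 0)
    n_sig["shrinkage"] - n_sig["conservative"]
  }, 0)
  expect_gte(mean(diffs), 0)
})

test_that("exact-test p-values track an established NB exact test", {
  sim <- simulate_counts(sim_params(
    n_transcripts = 600,
    class_proportions = c(null = 0.8, gast_up = 0.1, gast_down = 0.1),
    seed = 44))
  keep <- sim$design$polyp %in% c("gastrozooid", "dactylozooid")
  cnt <- sim$counts[, sim$design$library_id[keep]]
  grp <- sim$design$polyp[keep]
  y <- edgeR::DGEList(counts = cnt, group = grp)
  y <- edgeR::calcNormFactors(y)
  y <- edgeR::estimateDisp(y)
  et <- edgeR::exactTest(y, pair = c("dactylozooid", "gastrozooid"))
  de <- run_de(sim$counts, sim$design, c("gast", "dact"), "shrinkage")
  common <- intersect(rownames(et$table), de$transcript_id)
  rho <- cor(et$table[common, "PValue"],
             de$p_value[match(common, de$transcript_id)],
             method = "spearman")
  expect_gt(rho, 0.9)
})
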