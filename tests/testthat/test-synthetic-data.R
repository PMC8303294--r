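test_that("all generators are bit-identical under a fixed seed", {
  expect_identical(simulate_cohort(seed = 7), simulate_cohort(seed = 7))
  expect_identical(simulate_design(seed = 7), simulate_design(seed = 7))
  expect_identical(simulate_ct_table(seed = 7), simulate_ct_table(seed = 7))
  mir <- "UGAGGUAGUAGGUUGUAUAGUU"
  expect_identical(
    simulate_utr_sites(400, mir, data.frame(position = 50, site_type = "8mer"), seed = 7),
    simulate_utr_sites(400, mir, data.frame(position = 50, site_type = "8mer"), seed = 7)
  )
  # different seeds give different draws
  expect_false(identical(simulate_cohort(seed = 7), simulate_cohort(seed = 8)))
})

test_that("cohort generator validates parameters and planted structure", {
  expect_error(simulate_cohort(depth = 0), "depth")
  expect_error(simulate_cohort(dispersion = -1), "dispersion")
  expect_error(simulate_cohort(n_mirnas = 10, n_fibromirs = 8, n_myomirs = 8),
               "exceed")
  sim <- simulate_cohort(seed = 3)
  expect_true(all(sim$counts >= 0))
  expect_true(all(sim$counts == round(sim$counts)))
  expect_identical(dim(sim$counts), c(300L, 11L))
  # default cohort plants exactly 3 low / 5 high dystrophic samples
  expect_identical(as.vector(table(sim$samples$latent_class)[c("low", "high")]),
                   c(3L, 5L))
  expect_true(all(sim$samples$latent_fibrosis >= 0))
  expect_identical(as.vector(table(sim$mirnas$class)[c("fibromiR", "myomiR")]),
                   c(20L, 20L))
})

test_that("generated counts follow the NB mean-variance law", {
  # many replicate samples of the same background condition: empirical
  # variance tracks mu + alpha * mu^2
  sim <- simulate_design(
    n_replicates = 2500,
    archetype_counts = c(C1 = 0, C2 = 0, C3 = 0, C4 = 0, background = 6),
    dispersion = 0.1, depth = 1e4, seed = 21
  )
  m <- rowMeans(sim$counts)
  v <- apply(sim$counts, 1, var)
  expected <- m + 0.1 * m^2
  expect_true(all(abs(v / expected - 1) < 0.15))
})

test_that("beta = 0 decouples planted miRNAs from latent fibrosis", {
  set.seed(101)
  rs <- replicate(200, {
    sim <- simulate_cohort(n_control = 12, n_dmd = 12, n_mirnas = 30,
                           n_fibromirs = 10, n_myomirs = 10, beta = 0,
                           depth = 1e5, seed = sample.int(1e6, 1))
    l2 <- normalized_log2(sim$counts)
    planted <- sim$mirnas$class != "background"
    mean(cor(t(l2[planted, ]), sim$samples$latent_fibrosis))
  })
  expect_lt(abs(mean(rs)), 0.05)
})

test_that("planted fibromiRs are recovered by score correlation at beta = 2", {
  set.seed(102)
  recall <- replicate(50, {
    sim <- simulate_cohort(n_control = 12, n_dmd = 12, beta = 2,
                           dispersion = 0.05, seed = sample.int(1e6, 1))
    ann <- annotate_fibrosis(sim$markers)
    sig <- correlate_with_score(normalized_log2(sim$counts), ann)
    planted <- sim$mirnas$mirna_id[sim$mirnas$class == "fibromiR"]
    mean(sig$r[match(planted, sig$mirna_id)] > 0.5)
  })
  expect_gte(mean(recall), 0.9)
})

test_that("stratification recovers the planted low/high dystrophic pattern", {
  set.seed(103)
  # cohort-level recovery of the exact planted 3 low / 5 high allocation;
  # the Monte-Carlo expectation at the frozen generator defaults is ~0.9
  ok <- replicate(100, {
    sim <- simulate_cohort(seed = sample.int(1e6, 1))
    ann <- annotate_fibrosis(sim$markers)
    dmd <- sim$samples$group == "DMD"
    all((ann$stratum[dmd] == "High") ==
          (sim$samples$latent_class[dmd] == "high"))
  })
  expect_gte(mean(ok), 0.78)
})

test_that("null design yields unclassified profiles; planted archetypes classify", {
  null <- simulate_design(
    archetype_counts = c(C1 = 0, C2 = 0, C3 = 0, C4 = 0, background = 100),
    seed = 5
  )
  calls <- classify_archetypes(condition_means(null$counts,
                                               null$samples$condition))
  expect_gte(mean(calls$class == "unclassified"), 0.95)

  d <- simulate_design(enrichment_lfc = 4, response_lfc = 2,
                       dispersion = 0.02, seed = 6)
  calls <- classify_archetypes(condition_means(d$counts,
                                               d$samples$condition))
  c4 <- d$mirnas$class == "C4"
  expect_gte(mean(calls$class[c4] == "C4"), 0.9)
})

test_that("ct table generator inverts exactly without noise", {
  ct <- simulate_ct_table(n_samples = 4, true_log2_fold = 1, noise_sd = 0,
                          seed = 2)
  arms <- split(ct, ct$condition)
  expect_equal(ddct_fold_change(arms$treated, arms$control)$fold_change, 2)
  ct0 <- simulate_ct_table(n_samples = 4, true_log2_fold = 0, noise_sd = 0,
                           seed = 2)
  arms0 <- split(ct0, ct0$condition)
  expect_equal(ddct_fold_change(arms0$treated, arms0$control)$fold_change, 1)
})

test_that("noisy ct tables recover the planted fold on average", {
  set.seed(104)
  folds <- replicate(100, {
    ct <- simulate_ct_table(n_samples = 6, true_log2_fold = 1,
                            noise_sd = 0.2, seed = sample.int(1e6, 1))
    arms <- split(ct, ct$condition)
    ddct_fold_change(arms$treated, arms$control)$fold_change
  })
  expect_lt(abs(mean(folds) / 2 - 1), 0.05)
})

test_that("utr generator plants exactly the requested sites", {
  mir <- "UGAGGUAGUAGGUUGUAUAGUU"
  # single 7mer-m8
  one <- simulate_utr_sites(300, mir,
                            data.frame(position = 50, site_type = "7mer-m8"),
                            seed = 4)
  found <- seed_sites(mir, one$sequence)
  expect_identical(nrow(found), 1L)
  expect_identical(found$start, 50L)
  expect_identical(found$site_type, "7mer-m8")
  # none planted -> none found
  none <- simulate_utr_sites(300, mir, NULL, seed = 4)
  expect_identical(nrow(seed_sites(mir, none$sequence)), 0L)
  # 8mer + 6mer, checked against a hand-derived reverse complement
  two <- simulate_utr_sites(300, mir,
                            data.frame(position = c(10, 200),
                                       site_type = c("8mer", "6mer")),
                            seed = 4)
  found <- seed_sites(mir, two$sequence)
  expect_identical(found$site_type, c("8mer", "6mer"))
  expect_identical(found$start, c(10L, 200L))
  rc7 <- oracle_rc(substr(mir, 2, 8))
  expect_identical(found$site_seq, c(paste0(rc7, "A"), substr(rc7, 2, 7)))
  # invalid placements error
  expect_error(simulate_utr_sites(100, mir,
                                  data.frame(position = 98, site_type = "8mer")),
               "bounds")
  expect_error(simulate_utr_sites(100, mir,
                                  data.frame(position = c(10, 12),
                                             site_type = c("6mer", "6mer"))),
               "overlap")
})
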