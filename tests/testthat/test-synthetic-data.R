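test_that("generated bundles validate, are reproducible and sized as configured", {
  b1 <- gen_ground_truth_bundle("U1553-like", seed = 3)
  b2 <- gen_ground_truth_bundle("U1553-like", seed = 3)
  expect_identical(b1$coccospheres, b2$coccospheres)
  expect_identical(b1$lith_sizes, b2$lith_sizes)
  expect_identical(b1$assemblages, b2$assemblages)

  expect_silent(validate_coccosphere_table(b1$coccospheres))
  expect_silent(validate_lith_size_table(b1$lith_sizes))
  expect_silent(validate_assemblage_table(b1$assemblages))

  # 7 placolith morphogroups x 375 coccospheres
  expect_equal(nrow(b1$coccospheres), 7 * 375)
  # 10 morphogroups x 18 samples x 50 lengths
  expect_equal(nrow(b1$lith_sizes), 10 * 18 * 50)
  expect_true(all(b1$lith_sizes$coccolith_length > 0))
  # every sample counts exactly 300 coccoliths
  totals <- tapply(b1$assemblages$count, b1$assemblages$sample_id, sum)
  expect_true(all(totals == 300))
})

test_that("noise-free coccospheres yield exact allometry recovery", {
  truth <- ground_truth("U1553-like")
  cs <- gen_coccosphere_dataset(truth, n = 100, noise_sd = 0, seed = 5)
  for (mg in c("Chiasmolithus", "Cyclicargolithus")) {
    fit <- fit_loglog_regression(cs[cs$morphogroup == mg, ])
    expect_equal(fit$alpha, truth$morphogroups[[mg]]$alpha, tolerance = 1e-9)
    expect_equal(fit$beta, truth$morphogroups[[mg]]$beta, tolerance = 1e-9)
  }
})

test_that("driftless lith-size samples have stationary medians", {
  truth <- ground_truth("U1553-like")
  # Coccolithus has no drift in this preset: a rank test across the 18
  # samples should be non-significant at the 1% level in nearly all seeds
  nonsig <- 0
  n_seeds <- 40
  for (seed in seq_len(n_seeds)) {
    ls <- gen_lith_size_samples(truth, n_per_sample = 50, seed = 2000 + seed)
    d <- ls[ls$morphogroup == "Coccolithus", ]
    p <- stats::kruskal.test(d$coccolith_length,
                             factor(d$sample_id))$p.value
    nonsig <- nonsig + (p > 0.01)
  }
  expect_gte(nonsig / n_seeds, 0.9)

  # the R. umbilicus group drift is visible as a declining median
  ls <- gen_lith_size_samples(truth, seed = 77)
  d <- ls[ls$morphogroup == "R. umbilicus group", ]
  med <- tapply(d$coccolith_length, d$sample_id, median)
  expect_lt(med[length(med)], med[1])
})

test_that("assemblage sampling is calibrated against its Wald intervals", {
  truth <- ground_truth("U1553-like")
  p_true <- truth$lith_props[1, ]
  taxon <- "Cyclicargolithus"
  hits <- 0
  n_seeds <- 200
  for (seed in seq_len(n_seeds)) {
    set.seed(3000 + seed)
    counts <- as.integer(rmultinom(1, 300, p_true))
    names(counts) <- colnames(truth$lith_props)
    ci <- relative_abundance_with_ci(counts)
    row <- ci[ci$taxon == taxon, ]
    hits <- hits + (row$ci_low <= p_true[taxon] &&
                      p_true[taxon] <= row$ci_high)
  }
  expect_gte(hits / n_seeds, 0.90)
  expect_lte(hits / n_seeds, 0.99)
})

test_that("the minimal preset reconstruction equals its single morphogroup", {
  b <- gen_ground_truth_bundle("minimal", seed = 4)
  res <- run_trait_pipeline(b$coccospheres, b$lith_sizes, b$assemblages,
                            b$registry, b$age_model, seed = 4)
  expect_equal(length(res$reconstructions), 1)
  recon <- res$reconstructions[[1]]
  d <- res$distributions[[1]][["Coccolithus"]]
  expect_equal(recon$size_structure$weight, d$size_bins$weight)
  expect_equal(recon$community_pic_poc, d$mean_pic / d$mean_poc,
               tolerance = 1e-9)
})

test_that("bundle files written to disk pass validation on re-read", {
  dir <- withr::local_tempdir()
  gen_ground_truth_bundle("U1553-like", seed = 9, dir = dir)
  expect_silent(read_coccosphere_table(file.path(dir, "coccospheres.csv")))
  expect_silent(read_lith_size_table(file.path(dir, "lith_sizes.csv")))
  expect_silent(read_assemblage_table(file.path(dir, "assemblages.csv")))
  reg <- read_param_registry(file.path(dir, "registry.json"))
  expect_equal(reg[["Sphenolithus"]]$c_o, 1.18)
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"))
  expect_equal(meta$seed, 9)
})

test_that("pipeline output is deterministic given identical inputs and seed", {
  b <- gen_ground_truth_bundle("U1553-like", seed = 2)
  r1 <- run_trait_pipeline(b$coccospheres, b$lith_sizes, b$assemblages,
                           b$registry, b$age_model, seed = 2)
  r2 <- run_trait_pipeline(b$coccospheres, b$lith_sizes, b$assemblages,
                           b$registry, b$age_model, seed = 2)
  expect_identical(r1$summary, r2$summary)
  expect_identical(r1$partitions, r2$partitions)
})
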