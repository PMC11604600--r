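test_that("Wald confidence intervals match the hand formula", {
  r <- relative_abundance_with_ci(c(A = 150, B = 150))
  expect_equal(r$proportion, c(0.5, 0.5))
  half <- qnorm(0.975) * sqrt(0.25 / 300)
  expect_equal(r$ci_low, rep(0.5 - half, 2), tolerance = 1e-12)
  expect_equal(r$ci_high, rep(0.5 + half, 2), tolerance = 1e-12)
  expect_equal(r$ci_low[1], 0.4434, tolerance = 1e-4)
  expect_equal(r$ci_high[1], 0.5566, tolerance = 1e-4)

  # degenerate zero count collapses the Wald interval
  z <- relative_abundance_with_ci(c(A = 0, B = 300))
  expect_equal(z$ci_low[1], 0)
  expect_equal(z$ci_high[1], 0)
  expect_equal(sum(z$proportion), 1)

  w <- relative_abundance_with_ci(c(A = 0, B = 300), method = "wilson")
  expect_gt(w$ci_high[1], 0)   # Wilson keeps positive width at p = 0
  expect_error(relative_abundance_with_ci(c(A = 0, B = 0)), ">= 1")
})

test_that("five-point smoothing averages with symmetric end truncation", {
  const <- matrix(0.5, 8, 2, dimnames = list(NULL, c("A", "B")))
  expect_equal(smooth_abundance(const), const)

  imp <- matrix(0, 9, 1); imp[5, 1] <- 1
  sm <- smooth_abundance(imp, renormalize = FALSE)
  expect_equal(as.numeric(sm), c(0, 0, 0.2, 0.2, 0.2, 0.2, 0.2, 0, 0))

  set.seed(6)
  x <- matrix(runif(12), 12, 1)
  sm <- smooth_abundance(x, renormalize = FALSE)
  for (i in 3:10) expect_equal(sm[i, 1], mean(x[(i - 2):(i + 2), 1]))
  expect_equal(sm[1, 1], x[1, 1])              # window 1 at the end point
  expect_equal(sm[2, 1], mean(x[1:3, 1]))      # window 3 one step in
})

test_that("coccolith-to-cell conversion divides by mean coccoliths per cell", {
  expect_equal(coccolith_to_cell_abundance(c(A = 0.8, B = 0.2),
                                           c(A = 16, B = 4)),
               c(A = 0.5, B = 0.5))
  expect_equal(coccolith_to_cell_abundance(c(A = 0.3, B = 0.7),
                                           c(A = 10, B = 10)),
               c(A = 0.3, B = 0.7))
  expect_equal(unname(coccolith_to_cell_abundance(c(A = 1), c(A = 12))), 1)
  expect_error(coccolith_to_cell_abundance(c(A = 0.5, B = 0.5), c(A = 10)),
               "configuration error")
})

make_point_dist <- function(mg, size, poc, pic) {
  # degenerate trait distribution concentrated in one size bin
  structure(list(
    morphogroup = mg, sample_id = NA_character_,
    size_bins = data.frame(center = bin_center(size, 1), weight = 1,
                           mean_poc = poc, mean_pic = pic),
    poc_bins = data.frame(center = bin_center(poc, 30), weight = 1),
    pic_bins = data.frame(center = bin_center(pic, 30), weight = 1),
    ratio_bins = data.frame(center = bin_center(pic / poc, 0.1), weight = 1),
    mean_size = size, mean_poc = poc, mean_pic = pic, mean_ratio = pic / poc,
    bin_widths = default_bin_widths(),
    nodes = data.frame()), class = "trait_distribution")
}

test_that("stacking one morphogroup reproduces its own distribution", {
  p <- test_placolith_params()
  set.seed(14)
  cl_h <- cl_histogram(rlnorm(50, log(8), 0.15), 0.5)
  cn_h <- cn_histogram(6:18, random_hist(6:18, seed = 3))
  d <- morphogroup_trait_distribution(build_weight_grid(cl_h, cn_h), p)
  recon <- stack_community(list(Testolithus = d), c(Testolithus = 1))
  expect_equal(recon$size_structure$weight, d$size_bins$weight)
  expect_equal(recon$size_structure$center, d$size_bins$center)
  expect_equal(recon$total_poc, 100 * d$mean_poc, tolerance = 1e-9)
  expect_equal(recon$community_pic_poc, d$mean_pic / d$mean_poc,
               tolerance = 1e-9)
})

test_that("community PIC:POC mixes by POC weighting", {
  # two groups with equal POC totals and cellular ratios 1 and 3 -> 2.0
  a <- make_point_dist("A", 8.2, 100, 100)
  b <- make_point_dist("B", 12.3, 100, 300)
  recon <- stack_community(list(A = a, B = b), c(A = 0.5, B = 0.5))
  expect_equal(recon$community_pic_poc, 2.0)
  expect_equal(recon$total_poc, 100 * 100)
  # identity: community ratio equals the POC-weighted mean of bin ratios
  ss <- recon$size_structure
  expect_equal(recon$community_pic_poc,
               weighted.mean(ss$pic / ss$poc, ss$poc), tolerance = 1e-12)
})

test_that("community PIC:POC is bounded by contributing cellular ratios", {
  set.seed(11)
  for (rep in 1:20) {
    k <- sample(2:4, 1)
    dists <- lapply(seq_len(k), function(i) {
      make_point_dist(LETTERS[i], runif(1, 3, 18), runif(1, 20, 400),
                      runif(1, 10, 900))
    })
    names(dists) <- LETTERS[seq_len(k)]
    w <- random_hist(seq_len(k), seed = 100 + rep)
    recon <- stack_community(dists, setNames(w, LETTERS[seq_len(k)]))
    ratios <- vapply(dists, function(d) d$mean_ratio, 0)
    expect_gte(recon$community_pic_poc, min(ratios) - 1e-12)
    expect_lte(recon$community_pic_poc, max(ratios) + 1e-12)
    expect_equal(sum(recon$size_structure$weight), 1, tolerance = 1e-9)
  }
})

test_that("size-class partitioning conserves cells and carbon", {
  a <- make_point_dist("A", 9.2, 100, 150)   # 8-11 class
  recon <- stack_community(list(A = a), c(A = 1))
  part <- partition_size_classes(recon)
  expect_equal(part$pct_cells[part$class == "8-11"], 100)
  expect_equal(part$pct_poc[part$class == "8-11"], 100)
  expect_equal(part$pct_pic[part$class == "8-11"], 100)
  expect_true(is.na(part$pic_poc[part$class == "2-5"]))  # empty class

  b <- make_point_dist("B", 16.4, 200, 100)  # 15-20 class
  recon2 <- stack_community(list(A = a, B = b), c(A = 0.25, B = 0.75))
  part2 <- partition_size_classes(recon2)
  expect_equal(sum(part2$pct_cells), 100, tolerance = 1e-6)
  expect_equal(sum(part2$pct_poc), 100, tolerance = 1e-6)
  expect_equal(sum(part2$pct_pic), 100, tolerance = 1e-6)
  # hand-partitioned two-class sums
  poc_a <- 100 * 0.25 * 100; poc_b <- 100 * 0.75 * 200
  expect_equal(part2$pct_poc[part2$class == "8-11"],
               100 * poc_a / (poc_a + poc_b), tolerance = 1e-9)
  expect_equal(part2$pic_poc[part2$class == "15-20"], 100 / 200)
  expect_error(partition_size_classes(recon, edges = c(5, 2)),
               "configuration error")
})

test_that("the cold/eutrophic index applies the documented thresholds", {
  props <- c(`Chiasmolithus` = 0.20, `R. daviesii` = 0.15, Other = 0.65)
  idx <- ecological_index(props, taxa = c("Chiasmolithus", "R. daviesii"))
  expect_equal(idx$index_pct, 35)
  expect_equal(idx$label, "cooler")

  expect_warning(
    none <- ecological_index(c(Other = 1),
                             taxa = c("Chiasmolithus", "R. daviesii")),
    "unknown")
  expect_equal(none$index_pct, 0)
  expect_equal(none$label, "warmer")

  mid <- ecological_index(c(`Chiasmolithus` = 0.20, Other = 0.80),
                          taxa = "Chiasmolithus")
  expect_equal(mid$label, "intermediate")
})

test_that("scenario totals scale reconstructions to standing stocks", {
  a <- list(total_poc = 5000, total_pic = 8000, standing_stock = 100)
  same <- scenario_totals(a, a, 120, 120)
  expect_equal(same$poc_change_pct, 0)
  expect_equal(same$pic_change_pct, 0)
  expect_equal(same$stock_change_pct, 0)

  b <- list(total_poc = 6000, total_pic = 8800, standing_stock = 100)
  sc <- scenario_totals(a, b, 100, 110, poc_budget = 3300)
  expect_equal(sc$poc_a, 5000)
  expect_equal(sc$poc_b, 6600)
  expect_equal(sc$poc_change_pct, 32)
  expect_equal(sc$implied_stock, 3300 / 60)
  expect_error(scenario_totals(a, b, 0, 100), "> 0")
})
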