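test_that("binning convention is half-open with the documented lattices", {
  expect_equal(bin_center(11.2, 1), 11.5)
  expect_equal(bin_center(12.0, 1), 12.5)   # boundary goes to the upper bin
  expect_equal(bin_center(44, 30), 45)
  expect_equal(bin_center(0.17, 0.1), 0.15)
  expect_equal(bin_center(3.4, 0.5), 3.25)
})

test_that("coccolith-length histograms are normalized with increasing centers", {
  set.seed(2)
  lengths <- rlnorm(50, log(8), 0.2)
  h <- cl_histogram(lengths, 0.5)
  expect_equal(sum(h$freq), 1, tolerance = 1e-12)
  expect_true(all(diff(h$cl) > 0))
  expect_error(cl_histogram(numeric(0)), "insufficient")
  expect_error(cl_histogram(c(1, -2)), "> 0")
})

test_that("the joint weight grid is the product of its marginals", {
  u2 <- cl_histogram(c(1.1, 2.1), 1)       # uniform two-bin
  cn2 <- cn_histogram(c(10, 20), c(0.5, 0.5))
  g <- build_weight_grid(u2, cn2)
  expect_equal(g$weight, rep(0.25, 4))

  g1 <- build_weight_grid(cl_histogram(5, 1), cn_histogram(12, 1))
  expect_equal(g1$weight, 1)

  # marginalization oracle on random 10 x 10 histograms
  cl_h <- cl_histogram(1:10 + 0.2, 1)
  cl_h$freq <- random_hist(cl_h$cl, seed = 4)
  cn_h <- cn_histogram(5:14, random_hist(5:14, seed = 5))
  g <- build_weight_grid(cl_h, cn_h)
  expect_equal(sum(g$weight), 1, tolerance = 1e-12)
  expect_equal(as.numeric(tapply(g$weight, g$cl, sum)), cl_h$freq,
               tolerance = 1e-12)
  expect_equal(as.numeric(tapply(g$weight, g$cn, sum)), cn_h$freq,
               tolerance = 1e-12)
})

test_that("a single-node grid produces unit-weight bins holding the direct values", {
  p <- test_placolith_params()
  g <- build_weight_grid(cl_histogram(8.2, 0.5), cn_histogram(12, 1))
  d <- morphogroup_trait_distribution(g, p)
  theta <- cell_diameter_placolith(8.25, 12, p)  # 8.2 binned at 0.5 -> 8.25
  expect_equal(d$size_bins$weight, 1)
  expect_equal(d$size_bins$center, bin_center(theta, 1))
  expect_equal(d$poc_bins$weight, 1)
  expect_equal(d$mean_poc, poc_from_volume(sphere_volume(theta)))
  expect_equal(d$ratio_bins$weight, 1)
})

test_that("distribution construction matches the exhaustive enumeration oracle", {
  p <- test_placolith_params(alpha = 0.478, beta = 0.151, ks = 0.06)
  cl_h <- cl_histogram(seq(4.1, 13.6, by = 0.5), 0.5)
  cl_h$freq <- random_hist(cl_h$cl, seed = 8)          # 20 bins
  cn_h <- cn_histogram(6:20, random_hist(6:20, seed = 9))  # 15 bins
  g <- build_weight_grid(cl_h, cn_h)
  expect_equal(nrow(g), 300)

  d <- morphogroup_trait_distribution(g, p)
  oracle <- brute_force_distribution(g, p, default_bin_widths())
  # exact comparison (no tolerance): accumulated weights must agree bit for bit
  expect_equal(d$size_bins[, c("center", "weight")], oracle$size,
               ignore_attr = TRUE)
  expect_equal(d$poc_bins, oracle$poc, ignore_attr = TRUE)
  expect_equal(d$pic_bins, oracle$pic, ignore_attr = TRUE)
  expect_equal(d$ratio_bins, oracle$ratio, ignore_attr = TRUE)
})

test_that("binned means stay within half a bin width of exact weighted means", {
  p <- test_placolith_params()
  for (seed in 1:5) {
    cl_h <- cl_histogram(seq(3.2, 12.7, by = 0.5), 0.5)
    cl_h$freq <- random_hist(cl_h$cl, seed = seed)
    cn_h <- cn_histogram(6:18, random_hist(6:18, seed = seed + 100))
    d <- morphogroup_trait_distribution(build_weight_grid(cl_h, cn_h), p)
    binned_mean <- sum(d$size_bins$center * d$size_bins$weight)
    expect_lt(abs(binned_mean - d$mean_size), 0.5)
    binned_ratio <- sum(d$ratio_bins$center * d$ratio_bins$weight)
    expect_lt(abs(binned_ratio - d$mean_ratio), 0.05)
  }
})

test_that("every trait axis conserves total weight", {
  p <- test_placolith_params()
  cl_h <- cl_histogram(seq(4.1, 9.6, by = 0.5), 0.5)
  cl_h$freq <- random_hist(cl_h$cl, seed = 21)
  cn_h <- cn_histogram(6:18, random_hist(6:18, seed = 22))
  d <- morphogroup_trait_distribution(build_weight_grid(cl_h, cn_h), p)
  for (b in list(d$size_bins, d$poc_bins, d$pic_bins, d$ratio_bins)) {
    expect_equal(sum(b$weight), 1, tolerance = 1e-9)
  }
})

test_that("shifting the length histogram up shifts the trait distributions up", {
  p <- test_placolith_params()
  cn_h <- cn_histogram(6:18, random_hist(6:18, seed = 30))
  cl_h <- cl_histogram(seq(4.1, 9.6, by = 0.5), 0.5)
  cl_h$freq <- random_hist(cl_h$cl, seed = 31)
  shifted <- cl_h
  shifted$cl <- shifted$cl + 0.5
  d0 <- morphogroup_trait_distribution(build_weight_grid(cl_h, cn_h), p)
  d1 <- morphogroup_trait_distribution(build_weight_grid(shifted, cn_h), p)
  expect_gt(d1$mean_size, d0$mean_size)
  expect_gt(d1$mean_poc, d0$mean_poc)
  expect_gt(d1$mean_pic, d0$mean_pic)
})

test_that("the weighted mean ratio is not the ratio of weighted means on a skewed fixture", {
  p <- test_placolith_params(alpha = 1, beta = 0, ks = 0.4)
  cl_h <- cl_histogram(c(rep(3.1, 8), rep(12.1, 2)), 0.5)  # strongly skewed
  cn_h <- cn_histogram(c(6, 30), c(0.7, 0.3))
  d <- morphogroup_trait_distribution(build_weight_grid(cl_h, cn_h), p)
  expect_true(is.finite(d$mean_ratio))
  expect_gt(abs(d$mean_ratio - d$mean_pic / d$mean_poc),
            0.01 * d$mean_ratio)
})

test_that("summaries read percentiles off the binned cumulative weight", {
  p <- test_placolith_params()
  d1 <- morphogroup_trait_distribution(
    build_weight_grid(cl_histogram(8.2, 0.5), cn_histogram(12, 1)), p)
  s1 <- summarize_distribution(d1)
  expect_equal(s1$p5[s1$axis == "size"], s1$p95[s1$axis == "size"])
  expect_equal(s1$mean[s1$axis == "size"], d1$mean_size)

  # uniform weights over bins 1..10: the median is the first bin whose
  # cumulative weight reaches 0.5, i.e. bin 5
  fake <- d1
  fake$size_bins <- data.frame(center = 1:10 + 0.5, weight = rep(0.1, 10),
                               mean_poc = 1, mean_pic = 1)
  s <- summarize_distribution(fake, percentiles = c(50, 95))
  expect_equal(s$p50[s$axis == "size"], 5.5)

  # cumulative-scan oracle on a random 50-bin distribution
  w <- random_hist(1:50, seed = 40)
  fake$size_bins <- data.frame(center = 1:50 + 0.5, weight = w,
                               mean_poc = 1, mean_pic = 1)
  s <- summarize_distribution(fake, percentiles = c(5, 95))
  cum <- cumsum(w)
  expect_equal(s$p5[s$axis == "size"], (1:50 + 0.5)[which(cum >= 0.05)[1]])
  expect_equal(s$p95[s$axis == "size"], (1:50 + 0.5)[which(cum >= 0.95)[1]])
  expect_gte(cum[match(s$p95[s$axis == "size"], 1:50 + 0.5)], 0.95)
})
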