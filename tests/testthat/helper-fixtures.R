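# Shared fixtures, built in code.

# Noise-free coccosphere records lying exactly on a given allometry:
# cell diameters and coccolith counts are drawn, coccolith length follows
# log10(cl) = alpha * log10(pi * theta^2 / cn) + beta (+ optional scatter).
make_coccospheres <- function(n = 50, alpha = 0.5, beta = 0.1,
                              noise_sd = 0, morphogroup = "Testolithus",
                              seed = 1) {
  set.seed(seed)
  theta <- rlnorm(n, log(12), 0.25)
  cn <- as.numeric(sample(6:18, n, replace = TRUE))
  eps <- if (noise_sd > 0) rnorm(n, 0, noise_sd) else 0
  cl <- 10^(alpha * log10(pi * theta^2 / cn) + beta + eps)
  data.frame(morphogroup = morphogroup, coccolith_length = cl,
             coccolith_count = cn, coccosphere_diameter = theta * 1.15,
             cell_diameter = theta, source_sample = NA_character_)
}

# A normalized random histogram on given support.
random_hist <- function(values, seed = 1) {
  set.seed(seed)
  w <- runif(length(values))
  w / sum(w)
}

# A small placolith parameter entry for direct trait-distribution tests.
test_placolith_params <- function(alpha = 0.5, beta = 0.1, ks = 0.06) {
  list(morphogroup = "Testolithus", mode = "placolith",
       alpha = alpha, beta = beta, c_o = NA_real_, ar = NA_real_,
       cn_mean = 12, cn_sd = 2, cn_range = c(6, 18),
       ks = ks, ks_dimension = "distal shield length",
       pic_dim_scale = 1, pooled_sizes = FALSE)
}

# Independent brute-force trait-distribution oracle: loops over every grid
# node, computes the trait values with the same published equations written
# out long-hand, and accumulates weights into half-open bins node by node.
brute_force_distribution <- function(grid, params, bin_widths) {
  acc <- list(size = new.env(), poc = new.env(), pic = new.env(),
              ratio = new.env())
  # per-bin node weights are collected and summed once at the end, in node
  # order, so the totals are directly comparable with grouped summation
  add <- function(env, center, w) {
    key <- as.character(center)
    assign(key, c(if (exists(key, env)) get(key, env), w), envir = env)
  }
  for (i in seq_len(nrow(grid))) {
    cl <- grid$cl[i]; cn <- grid$cn[i]; w <- grid$weight[i]
    theta <- if (params$mode == "placolith") {
      sa <- cn * 10^((log10(cl) - params$beta) / params$alpha)
      2 * sqrt(sa / (4 * pi))
    } else {
      (cl / 2) * sqrt(params$c_o * cn / params$ar)
    }
    poc <- 0.228 * ((pi / 6) * theta^3)^0.899
    pic <- (cl * params$pic_dim_scale)^3 * params$ks * 2.7 * 0.12 * cn
    add(acc$size, (floor(theta / bin_widths$size) + 0.5) * bin_widths$size, w)
    add(acc$poc, (floor(poc / bin_widths$carbon) + 0.5) * bin_widths$carbon, w)
    add(acc$pic, (floor(pic / bin_widths$carbon) + 0.5) * bin_widths$carbon, w)
    add(acc$ratio,
        (floor((pic / poc) / bin_widths$ratio) + 0.5) * bin_widths$ratio, w)
  }
  lapply(acc, function(env) {
    centers <- sort(as.numeric(ls(env)))
    data.frame(center = centers,
               weight = vapply(as.character(centers),
                               function(k) sum(get(k, envir = env)), 0,
                               USE.NAMES = FALSE))
  })
}
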