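## Synthetic-data generator. Emulates the statistical structure of the
## microscopy datasets the pipeline consumes - coccosphere geometry with a
## power-law coccolith-length <-> cell-size allometry and Gaussian-like
## integer coccolith counts, right-skewed (lognormal) loose-coccolith length
## samples, and multinomial assemblage counts around smooth temporal
## abundance paths - with the generating parameters recorded as ground truth
## so recovery can be tested at every stage.

.truth_morphogroup <- function(params, theta_median = NA, cl_median = NA,
                               cl_sdlog = 0.15, theta_sdlog = 0.2,
                               cl_meanlog_drift = 0,
                               lith_layer_fraction = 0.15) {
  p <- params
  p$theta_sdlog <- theta_sdlog
  p$cl_sdlog <- cl_sdlog
  p$cl_meanlog_drift <- cl_meanlog_drift
  p$lith_layer_fraction <- lith_layer_fraction
  if (p$mode == "placolith") {
    # loose-lith length median consistent with the allometry at the mean
    # coccoliths-per-cell, so lith samples and coccospheres tell one story
    p$theta_meanlog <- log(theta_median)
    p$cl_meanlog <- log(10^(p$alpha *
                              log10(pi * theta_median^2 / p$cn_mean) + p$beta))
  } else {
    p$cl_meanlog <- log(cl_median)
  }
  p
}

#' Ground truth for a synthetic study
#'
#' The `"U1553-like"` preset uses the published morphogroup model constants
#' (allometry slopes/intercepts, shape factors, coverage factors and
#' coccoliths-per-cell simulation settings) as the generating truth, with
#' ten morphogroups, 18 samples, smooth abundance paths (a logistic rise of
#' *Cyclicargolithus*, an early decline of the *R. umbilicus* group with a
#' drifting size median, a transient *Clausicoccus* acme) and a four-datum
#' age model. The `"minimal"` preset is one placolith morphogroup in one
#' sample.
#'
#' @param preset `"U1553-like"` or `"minimal"`.
#' @param n_samples Number of assemblage/lith-size samples (default 18 for
#'   `"U1553-like"`).
#' @return A `ground_truth` list: per-morphogroup generating parameters,
#'   per-sample true coccolith proportions, sample depths and the age model.
#' @export
ground_truth <- function(preset = c("U1553-like", "minimal"),
                         n_samples = NULL) {
  preset <- match.arg(preset)
  reg <- default_morphogroup_params()
  if (preset == "minimal") {
    n_samples <- n_samples %||% 1L
    mgs <- list(.truth_morphogroup(reg[["Coccolithus"]], theta_median = 13))
    names(mgs) <- "Coccolithus"
    props <- matrix(1, n_samples, 1, dimnames = list(NULL, "Coccolithus"))
    depths <- seq(100, 110, length.out = n_samples)
  } else {
    n_samples <- n_samples %||% 18L
    theta_medians <- c(`Chiasmolithus` = 15, `Coccolithus` = 13,
                       `Clausicoccus` = 14, `Cyclicargolithus` = 8.5,
                       `R. bisecta group` = 10, `R. lockeri group` = 8.4,
                       `R. umbilicus group` = 9)
    cl_medians <- c(`Sphenolithus` = 3.9, `Discoaster` = 11.2,
                    `Z. bijugatus` = 8.5)
    mgs <- lapply(names(reg), function(nm) {
      .truth_morphogroup(
        reg[[nm]],
        theta_median = if (nm %in% names(theta_medians)) theta_medians[[nm]] else NA,
        cl_median = if (nm %in% names(cl_medians)) cl_medians[[nm]] else NA,
        cl_sdlog = if (reg[[nm]]$mode == "placolith") 0.12 else 0.18,
        cl_meanlog_drift = if (nm == "R. umbilicus group") -log(1.5) else 0)
    })
    names(mgs) <- names(reg)
    # smooth true coccolith-proportion paths, u = 0 oldest -> 1 youngest
    u <- if (n_samples > 1) (seq_len(n_samples) - 1) / (n_samples - 1) else 0.5
    raw <- cbind(
      `Chiasmolithus` = 0.10 - 0.02 * u,
      `Coccolithus` = 0.20 - 0.08 * u,
      `Clausicoccus` = 0.02 + 0.06 * exp(-((u - 0.25) / 0.15)^2),
      `Cyclicargolithus` = 0.05 + 0.40 / (1 + exp(-10 * (u - 0.45))),
      `R. bisecta group` = 0.12 + 0.05 * u,
      `R. lockeri group` = rep(0.10, n_samples),
      `R. umbilicus group` = 0.20 * exp(-3 * u),
      `Sphenolithus` = rep(0.03, n_samples),
      `Discoaster` = rep(0.01, n_samples),
      `Z. bijugatus` = rep(0.04, n_samples))
    props <- raw / rowSums(raw)
    depths <- seq(200, 10, length.out = n_samples)
  }
  structure(list(
    preset = preset,
    morphogroups = mgs,
    n_samples = n_samples,
    sample_ids = sprintf("S%02d", seq_len(n_samples)),
    depths = depths,
    lith_props = props,
    age_model = age_model(depth = c(0, 60, 120, 210),
                          age = c(26.0, 28.2, 31.0, 34.7)),
    noise_sd = 0.05,
    n_spheres = 375
  ), class = "ground_truth")
}

#' Generate a synthetic coccosphere geometry dataset
#'
#' For each placolith morphogroup: cell diameters are lognormal, coccolith
#' counts are rounded truncated-Gaussian, and the measured coccolith length
#' follows the morphogroup's allometry with multiplicative lognormal scatter
#' (`10^eps`, `eps ~ Normal(0, noise_sd)` in log10 units) so that at
#' `noise_sd = 0` the regression fit recovers the generating slope and
#' intercept exactly. The coccosphere (external) diameter adds a fixed
#' coccolith-layer fraction to the cell diameter.
#'
#' @param truth A [ground_truth()].
#' @param n Coccospheres per placolith morphogroup.
#' @param noise_sd Allometric scatter, log10 units.
#' @param seed Integer seed.
#' @return A coccosphere table (see [validate_coccosphere_table()]).
#' @export
gen_coccosphere_dataset <- function(truth, n = truth$n_spheres,
                                    noise_sd = truth$noise_sd, seed = 1) {
  stopifnot(inherits(truth, "ground_truth"))
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  set.seed(seed)
  placoliths <- Filter(function(p) p$mode == "placolith", truth$morphogroups)
  out <- lapply(placoliths, function(p) {
    theta <- rlnorm(n, p$theta_meanlog, p$theta_sdlog)
    cn <- .draw_truncated_cn(n, p$cn_mean, p$cn_sd, p$cn_range)
    eps <- rnorm(n, 0, noise_sd)
    cl <- 10^(p$alpha * log10(pi * theta^2 / cn) + p$beta + eps)
    data.frame(morphogroup = p$morphogroup,
               coccolith_length = cl,
               coccolith_count = cn,
               coccosphere_diameter = theta * (1 + p$lith_layer_fraction),
               cell_diameter = theta,
               source_sample = NA_character_)
  })
  validate_coccosphere_table(do.call(rbind, c(out, make.row.names = FALSE)))
}

.draw_truncated_cn <- function(n, mu, sd, range) {
  draws <- integer(0)
  mass <- pnorm(range[2] + 0.5, mu, sd) - pnorm(range[1] - 0.5, mu, sd)
  if (mass < 1e-12) stop("cn_range admits no mass", call. = FALSE)
  while (length(draws) < n) {
    cand <- round(rnorm(ceiling((n - length(draws)) / mass * 1.1) + 16, mu, sd))
    draws <- c(draws, cand[cand >= range[1] & cand <= range[2]])
  }
  draws[seq_len(n)]
}

#' Generate per-sample loose coccolith length tables
#'
#' Lognormal lengths per morphogroup and sample (right-skewed, positive
#' support), with an optional linear drift of the log-median across the
#' record (the `"U1553-like"` preset uses it for the *R. umbilicus* group
#' size decline).
#'
#' @param truth A [ground_truth()].
#' @param n_per_sample Measurements per morphogroup per sample (default 50).
#' @param seed Integer seed.
#' @return A long lith-size table (see [validate_lith_size_table()]).
#' @export
gen_lith_size_samples <- function(truth, n_per_sample = 50, seed = 1) {
  stopifnot(inherits(truth, "ground_truth"))
  if (n_per_sample < 2) stop("n_per_sample must be >= 2", call. = FALSE)
  set.seed(seed)
  n_s <- truth$n_samples
  u <- if (n_s > 1) (seq_len(n_s) - 1) / (n_s - 1) else 0.5
  rows <- list()
  for (p in truth$morphogroups) {
    for (s in seq_len(n_s)) {
      ml <- p$cl_meanlog + p$cl_meanlog_drift * u[s]
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = truth$sample_ids[s], morphogroup = p$morphogroup,
        coccolith_length = rlnorm(n_per_sample, ml, p$cl_sdlog))
    }
  }
  validate_lith_size_table(do.call(rbind, c(rows, make.row.names = FALSE)))
}

#' Generate an assemblage count series
#'
#' Multinomial coccolith counts around the truth's smooth proportion paths.
#'
#' @param truth A [ground_truth()].
#' @param total_count Coccoliths identified per sample (default 300, the
#'   counting minimum).
#' @param seed Integer seed.
#' @return A long assemblage count table (see
#'   [validate_assemblage_table()]).
#' @export
gen_assemblage_series <- function(truth, total_count = 300, seed = 1) {
  stopifnot(inherits(truth, "ground_truth"))
  if (total_count < 1) stop("total_count must be >= 1", call. = FALSE)
  set.seed(seed)
  taxa <- colnames(truth$lith_props)
  rows <- lapply(seq_len(truth$n_samples), function(s) {
    counts <- as.integer(rmultinom(1, total_count, truth$lith_props[s, ]))
    data.frame(sample_id = truth$sample_ids[s], depth = truth$depths[s],
               taxon = taxa, count = counts)
  })
  validate_assemblage_table(do.call(rbind, c(rows, make.row.names = FALSE)))
}

#' True per-sample community quantities under a ground truth
#'
#' Generator-side closure reference, computed from the generating
#' distributions rather than any sampled data: the coccolith-length
#' distribution is integrated on an equal-probability lognormal quantile
#' grid, the coccoliths-per-cell distribution uses its exact
#' truncated-rounded-normal probabilities, the trait equations are evaluated
#' with the true parameters, and true cell proportions follow from the true
#' coccolith proportions and exact mean coccoliths-per-cell.
#'
#' @param truth A [ground_truth()].
#' @param n_quantiles Lognormal quantile-grid resolution.
#' @return Data frame with one row per sample: true mean community cell
#'   size, total POC/PIC per 100 cells and community PIC:POC.
#' @export
true_community_values <- function(truth, n_quantiles = 400) {
  stopifnot(inherits(truth, "ground_truth"))
  pq <- (seq_len(n_quantiles) - 0.5) / n_quantiles
  n_s <- truth$n_samples
  u <- if (n_s > 1) (seq_len(n_s) - 1) / (n_s - 1) else 0.5
  mg_names <- names(truth$morphogroups)
  cn_exact <- lapply(truth$morphogroups, exact_cn_distribution)
  mean_cn <- vapply(cn_exact, function(h) sum(h$cn * h$freq), 0)
  per_mg_sample <- function(p, s) {
    ml <- p$cl_meanlog + p$cl_meanlog_drift * u[s]
    cl <- stats::qlnorm(pq, ml, p$cl_sdlog)
    h <- cn_exact[[p$morphogroup]]
    cl_g <- rep(cl, times = nrow(h))
    cn_g <- rep(h$cn, each = n_quantiles)
    w <- rep(h$freq / n_quantiles, each = n_quantiles)
    theta <- if (p$mode == "placolith") {
      cell_diameter_placolith(cl_g, cn_g, p)
    } else {
      cell_diameter_nonplacolith(cl_g, p$ar, cn_g, p$c_o)
    }
    poc <- poc_from_volume(sphere_volume(theta))
    pic <- cellular_pic(coccolith_pic(cl_g * p$pic_dim_scale, p$ks), cn_g)
    c(size = sum(w * theta), poc = sum(w * poc), pic = sum(w * pic))
  }
  out <- lapply(seq_len(n_s), function(s) {
    m <- vapply(truth$morphogroups, per_mg_sample, numeric(3), s = s)
    lith <- truth$lith_props[s, mg_names]
    cells <- (lith / mean_cn[mg_names])
    cells <- cells / sum(cells)
    total_poc <- 100 * sum(cells * m["poc", ])
    total_pic <- 100 * sum(cells * m["pic", ])
    data.frame(sample_id = truth$sample_ids[s], depth = truth$depths[s],
               mean_community_size = sum(cells * m["size", ]),
               total_poc = total_poc, total_pic = total_pic,
               community_pic_poc = total_pic / total_poc)
  })
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Generate a complete synthetic input bundle with recorded ground truth
#'
#' Produces every input the pipeline consumes - coccosphere geometry,
#' per-sample lith sizes, assemblage counts, the parameter registry and the
#' age model - plus the generating truth and its true community values.
#' Optionally writes the tables (CSV), registry (JSON) and a metadata
#' sidecar (JSON, recording preset and seed) to a directory.
#'
#' @param preset Passed to [ground_truth()].
#' @param seed Integer seed; a single stream drives the whole bundle.
#' @param dir Optional output directory.
#' @return List with `coccospheres`, `lith_sizes`, `assemblages`,
#'   `registry`, `age_model`, `truth`, `true_values`, `seed`.
#' @export
gen_ground_truth_bundle <- function(preset = c("U1553-like", "minimal"),
                                    seed = 1, dir = NULL) {
  truth <- ground_truth(preset)
  bundle <- list(
    coccospheres = gen_coccosphere_dataset(truth, seed = seed),
    lith_sizes = gen_lith_size_samples(truth, seed = seed + 1L),
    assemblages = gen_assemblage_series(truth, seed = seed + 2L),
    registry = truth$morphogroups,
    age_model = truth$age_model,
    truth = truth,
    true_values = true_community_values(truth),
    seed = seed
  )
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_coccosphere_table(bundle$coccospheres,
                            file.path(dir, "coccospheres.csv"))
    write_lith_size_table(bundle$lith_sizes, file.path(dir, "lith_sizes.csv"))
    write_assemblage_table(bundle$assemblages,
                           file.path(dir, "assemblages.csv"))
    write_param_registry(bundle$registry, file.path(dir, "registry.json"))
    write.csv(data.frame(depth = bundle$age_model$depth,
                         age = bundle$age_model$age),
              file.path(dir, "age_tie_points.csv"), row.names = FALSE)
    jsonlite::write_json(list(preset = truth$preset, seed = seed),
                         file.path(dir, "metadata.json"), auto_unbox = TRUE)
  }
  bundle
}
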