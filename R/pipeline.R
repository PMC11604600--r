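#' Run the full size-trait reconstruction pipeline
#'
#' End-to-end driver: fits the placolith allometry per morphogroup from the
#' coccosphere data, builds coccoliths-per-cell histograms (empirical for
#' placolith groups, simulated for nannolith/holococcolith groups),
#' constructs per-sample likelihood-weighted trait distributions from the
#' loose-coccolith length samples (rare groups flagged `pooled_sizes` pool
#' their measurements across all samples), converts smoothed coccolith
#' proportions to cell proportions, stacks the community per sample and
#' partitions it into size classes.
#'
#' @param coccospheres Coccosphere geometry table.
#' @param lith_sizes Long lith-size table.
#' @param assemblages Long assemblage count table.
#' @param registry Morphogroup parameter registry (see
#'   [default_morphogroup_params()]); its names define the modeled
#'   community, over which raw proportions are renormalized.
#' @param age_mod Optional [age_model()] for sample ages.
#' @param bin_widths Trait-axis bin widths, see [default_bin_widths()].
#' @param cl_bin_width Coccolith-length histogram bin width, um.
#' @param standing_stock Accounting community size (default 100 cells).
#' @param cn_draws Draws for simulated coccoliths-per-cell distributions.
#' @param smooth_window Moving-average window for abundance smoothing.
#' @param size_class_edges Size-class edges for carbon partitioning, um.
#' @param seed Integer seed driving the coccoliths-per-cell simulation.
#' @return List with `fits` (per-morphogroup allometry fits), `cn_hists`,
#'   `mean_cn`, `distributions` (per sample, per morphogroup),
#'   `reconstructions`, `partitions`, and a per-sample `summary` data frame
#'   (depth, age, mean community size, totals, community PIC:POC).
#' @export
run_trait_pipeline <- function(coccospheres, lith_sizes, assemblages,
                               registry = default_morphogroup_params(),
                               age_mod = NULL,
                               bin_widths = default_bin_widths(),
                               cl_bin_width = 0.5,
                               standing_stock = 100,
                               cn_draws = 10000,
                               smooth_window = 5,
                               size_class_edges = c(2, 5, 8, 11, 15, 20),
                               seed = 1) {
  coccospheres <- validate_coccosphere_table(coccospheres)
  lith_sizes <- validate_lith_size_table(lith_sizes)
  assemblages <- validate_assemblage_table(assemblages)
  lapply(registry, validate_morphogroup_params)
  mg_names <- names(registry)

  ## allometry fits and coccoliths-per-cell histograms
  fits <- list(); cn_hists <- list()
  for (i in seq_along(mg_names)) {
    mg <- mg_names[i]
    p <- registry[[mg]]
    if (p$mode == "placolith") {
      rec <- coccospheres[coccospheres$morphogroup == mg, , drop = FALSE]
      if (nrow(rec) >= 3) {
        fit <- fit_loglog_regression(rec)
        registry[[mg]]$alpha <- fit$alpha
        registry[[mg]]$beta <- fit$beta
        fits[[mg]] <- fit
        cn_hists[[mg]] <- empirical_cn_histogram(rec)
      } else if (nrow(rec) > 0) {
        cn_hists[[mg]] <- empirical_cn_histogram(rec)
      } else {
        # no coccosphere data: registry alpha/beta and its count settings
        cn_hists[[mg]] <- exact_cn_distribution(p)
      }
    } else {
      cn_hists[[mg]] <- simulate_cn_distribution(p, n_draws = cn_draws,
                                                 seed = seed + i)
    }
  }
  mean_cn <- vapply(cn_hists, function(h) sum(h$cn * h$freq), 0)

  ## assemblage: renormalize over the modeled morphogroups, smooth, convert
  counts <- assemblage_matrix(assemblages)
  sample_depths <- attr(counts, "depth")
  present <- intersect(colnames(counts), mg_names)
  if (!length(present)) {
    stop("configuration error: no modeled morphogroup present in the ",
         "assemblage table", call. = FALSE)
  }
  counts <- counts[, present, drop = FALSE]
  props <- counts / rowSums(counts)
  props <- smooth_abundance(props, window = smooth_window)
  sample_ids <- rownames(props)
  depths <- sample_depths[sample_ids]
  ages <- if (!is.null(age_mod)) age_from_depth(age_mod, depths)
          else rep(NA_real_, length(depths))

  ## trait distributions; rare groups pool lith sizes across samples
  pooled <- vapply(registry, function(p) isTRUE(p$pooled_sizes), TRUE)
  pooled_dists <- list()
  for (mg in present[pooled[present]]) {
    lengths <- lith_sizes$coccolith_length[lith_sizes$morphogroup == mg]
    if (!length(lengths)) {
      stop("configuration error: no lith sizes for ", mg, call. = FALSE)
    }
    grid <- build_weight_grid(
      cl_histogram(lengths, cl_bin_width, morphogroup = mg),
      cn_hists[[mg]])
    pooled_dists[[mg]] <- morphogroup_trait_distribution(grid, registry[[mg]],
                                                         bin_widths)
  }

  distributions <- list(); reconstructions <- list(); partitions <- list()
  for (s in seq_along(sample_ids)) {
    sid <- sample_ids[s]
    cell_props <- coccolith_to_cell_abundance(
      setNames(props[s, ], colnames(props)), mean_cn)
    dists <- list()
    for (mg in names(cell_props)[cell_props > 0]) {
      if (pooled[[mg]]) {
        dists[[mg]] <- pooled_dists[[mg]]
      } else {
        lengths <- lith_sizes$coccolith_length[
          lith_sizes$morphogroup == mg & lith_sizes$sample_id == sid]
        if (!length(lengths)) {
          stop("configuration error: no lith sizes for ", mg,
               " in sample ", sid, call. = FALSE)
        }
        grid <- build_weight_grid(
          cl_histogram(lengths, cl_bin_width, sample_id = sid,
                       morphogroup = mg),
          cn_hists[[mg]])
        dists[[mg]] <- morphogroup_trait_distribution(grid, registry[[mg]],
                                                      bin_widths)
      }
    }
    recon <- stack_community(dists, cell_props,
                             standing_stock = standing_stock,
                             sample_id = sid, age = ages[s])
    distributions[[sid]] <- dists
    reconstructions[[sid]] <- recon
    partitions[[sid]] <- partition_size_classes(recon, size_class_edges)
  }

  summary <- do.call(rbind, lapply(seq_along(sample_ids), function(s) {
    r <- reconstructions[[s]]
    data.frame(sample_id = sample_ids[s], depth = unname(depths[s]),
               age = ages[s],
               mean_community_size = r$mean_community_size,
               total_poc = r$total_poc, total_pic = r$total_pic,
               community_pic_poc = r$community_pic_poc)
  }))

  list(fits = fits, cn_hists = cn_hists, mean_cn = mean_cn,
       registry = registry, proportions = props,
       distributions = distributions, reconstructions = reconstructions,
       partitions = partitions, summary = summary)
}
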