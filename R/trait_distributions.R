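## The model core: every (coccolith length, coccoliths-per-cell) combination
## is weighted by the product of its two marginal likelihoods, the cell-size
## and carbon equations are evaluated at each node, and node weights are
## accumulated into bins along each trait axis.
##
## Bin convention (half-open [lower, upper)): a value x falls in bin
## floor(x / width), whose center is (floor(x / width) + 0.5) * width. With
## the default widths this puts cell-size bins of 1 um centered on
## half-integers (..., 11.5, 12.5), POC and PIC bins of 30 pg C centered on
## 15 + 30k, and PIC:POC bins of 0.1 centered on 0.05 + 0.1k.

#' Bin center of a value under the half-open binning convention
#' @param x Values.
#' @param width Bin width.
#' @return Bin centers `(floor(x/width) + 0.5) * width`.
#' @export
bin_center <- function(x, width) (floor(x / width) + 0.5) * width

#' Default trait-axis bin widths
#' @return List with `size` (um), `carbon` (pg C, POC and PIC axes) and
#'   `ratio` (PIC:POC) bin widths.
#' @export
default_bin_widths <- function() list(size = 1, carbon = 30, ratio = 0.1)

#' Coccolith length histogram from raw measurements
#'
#' Bins the loose-coccolith length measurements of one morphogroup in one
#' sample (target n = 50) at 0.5 um resolution by default - finer bins would
#' be spurious given the 0.26 um optical resolution of the measurements.
#'
#' @param lengths Coccolith lengths, um (> 0).
#' @param bin_width Bin width, um.
#' @param sample_id,morphogroup Optional labels.
#' @return A `cl_histogram` data frame with columns `cl` (bin centers) and
#'   `freq`, and a `bin_width` attribute.
#' @export
cl_histogram <- function(lengths, bin_width = 0.5, sample_id = NA_character_,
                         morphogroup = NA_character_) {
  if (!length(lengths)) stop("insufficient data: no lengths", call. = FALSE)
  if (any(lengths <= 0)) stop("lengths must be > 0", call. = FALSE)
  centers <- bin_center(lengths, bin_width)
  tab <- table(centers)
  df <- data.frame(cl = as.numeric(names(tab)),
                   freq = as.numeric(tab) / length(lengths))
  structure(
    df[order(df$cl), , drop = FALSE],
    class = c("cl_histogram", "data.frame"),
    bin_width = bin_width, sample_id = sample_id, morphogroup = morphogroup)
}

.check_hist <- function(h, value_col) {
  if (is.null(h) || !nrow(h)) stop("insufficient data: empty histogram",
                                   call. = FALSE)
  if (abs(sum(h$freq) - 1) > 1e-9) {
    stop("histogram frequencies must sum to 1", call. = FALSE)
  }
  invisible(h)
}

#' Joint likelihood grid over coccolith length and coccoliths per cell
#'
#' The two marginals are treated as independent: the weight of a node is the
#' product of its coccolith-length frequency (sample-specific) and its
#' coccoliths-per-cell frequency (from fossil coccospheres or simulation).
#'
#' @param cl_hist A [cl_histogram()].
#' @param cn_hist A [cn_histogram()].
#' @return Data frame with columns `cl`, `cn`, `weight`; weights sum to 1.
#' @export
build_weight_grid <- function(cl_hist, cn_hist) {
  .check_hist(cl_hist, "cl")
  .check_hist(cn_hist, "cn")
  grid <- expand.grid(cl = cl_hist$cl, cn = cn_hist$cn, KEEP.OUT.ATTRS = FALSE)
  grid$weight <- rep(cl_hist$freq, times = nrow(cn_hist)) *
    rep(cn_hist$freq, each = nrow(cl_hist))
  structure(grid, cl_bin_width = attr(cl_hist, "bin_width"),
            sample_id = attr(cl_hist, "sample_id"))
}

#' Per-morphogroup trait distribution
#'
#' Evaluates the cell-size model (placolith allometry or coverage-factor
#' equation), the POC power law and the shape-factor PIC model at every grid
#' node, then accumulates node weights into bins along the four trait axes
#' (cell size, POC, PIC, PIC:POC). The PIC dimension at a node is the
#' measured coccolith length times the entry's `pic_dim_scale` (1 for
#' placoliths; 0.5 for *Discoaster* ray length; the height:base ratio for
#' *Z. bijugatus*).
#'
#' Per-size-bin conditional mean POC and PIC are retained so that community
#' stacking can partition carbon across the size structure.
#'
#' @param grid A [build_weight_grid()] result.
#' @param params Morphogroup parameter entry (see
#'   [default_morphogroup_params()]); for placolith entries `alpha`/`beta`
#'   may come from [fit_loglog_regression()].
#' @param bin_widths See [default_bin_widths()].
#' @return A `trait_distribution` with normalized `size_bins`, `poc_bins`,
#'   `pic_bins`, `ratio_bins`, exact (unbinned) weighted means `mean_size`,
#'   `mean_poc`, `mean_pic`, `mean_ratio`, and the evaluated `nodes`.
#'   `mean_ratio` is the weighted mean of per-node PIC:POC, which is not
#'   `mean_pic / mean_poc` in general.
#' @export
morphogroup_trait_distribution <- function(grid, params,
                                           bin_widths = default_bin_widths()) {
  validate_morphogroup_params(params)
  if (!nrow(grid)) stop("insufficient data: empty grid", call. = FALSE)
  if (abs(sum(grid$weight) - 1) > 1e-9) {
    stop("grid weights must sum to 1", call. = FALSE)
  }
  theta <- if (params$mode == "placolith") {
    cell_diameter_placolith(grid$cl, grid$cn, params)
  } else {
    cell_diameter_nonplacolith(grid$cl, params$ar, grid$cn, params$c_o)
  }
  poc <- poc_from_volume(sphere_volume(theta))
  pic <- cellular_pic(coccolith_pic(grid$cl * params$pic_dim_scale, params$ks),
                      grid$cn)
  ratio <- pic_poc_ratio(pic, poc)

  accumulate <- function(values, width) {
    centers <- bin_center(values, width)
    w <- tapply(grid$weight, centers, sum)
    out <- data.frame(center = as.numeric(names(w)), weight = as.numeric(w))
    out[order(out$center), , drop = FALSE]
  }
  size_bins <- accumulate(theta, bin_widths$size)
  size_key <- as.character(bin_center(theta, bin_widths$size))
  cond_mean <- function(v) {
    m <- tapply(grid$weight * v, size_key, sum) / tapply(grid$weight, size_key, sum)
    as.numeric(m[as.character(size_bins$center)])
  }
  size_bins$mean_poc <- cond_mean(poc)
  size_bins$mean_pic <- cond_mean(pic)

  structure(list(
    morphogroup = params$morphogroup,
    sample_id = attr(grid, "sample_id") %||% NA_character_,
    size_bins = size_bins,
    poc_bins = accumulate(poc, bin_widths$carbon),
    pic_bins = accumulate(pic, bin_widths$carbon),
    ratio_bins = accumulate(ratio, bin_widths$ratio),
    mean_size = sum(grid$weight * theta),
    mean_poc = sum(grid$weight * poc),
    mean_pic = sum(grid$weight * pic),
    mean_ratio = sum(grid$weight * ratio),
    bin_widths = bin_widths,
    nodes = data.frame(cl = grid$cl, cn = grid$cn, weight = grid$weight,
                       theta = theta, poc = poc, pic = pic, ratio = ratio)
  ), class = "trait_distribution")
}

#' @export
print.trait_distribution <- function(x, ...) {
  cat(sprintf(
    "Trait distribution for %s%s: mean cell size %.2f um, POC %.1f pg C, PIC %.1f pg C, PIC:POC %.2f\n",
    x$morphogroup,
    if (is.na(x$sample_id)) "" else paste0(" in ", x$sample_id),
    x$mean_size, x$mean_poc, x$mean_pic, x$mean_ratio))
  invisible(x)
}

#' Summary of a trait distribution (pooled mean and percentile band)
#'
#' Percentiles are read off the binned cumulative weight and reported as bin
#' centers: a percentile lands in the first bin whose cumulative weight
#' reaches the target.
#'
#' @param dist A [morphogroup_trait_distribution()] result.
#' @param percentiles Two percentiles (default 5th and 95th).
#' @return Data frame with one row per trait axis: pooled mean and the
#'   percentile band bin centers.
#' @export
summarize_distribution <- function(dist, percentiles = c(5, 95)) {
  stopifnot(inherits(dist, "trait_distribution"))
  axes <- list(size = dist$size_bins, poc = dist$poc_bins,
               pic = dist$pic_bins, ratio = dist$ratio_bins)
  means <- c(size = dist$mean_size, poc = dist$mean_poc,
             pic = dist$mean_pic, ratio = dist$mean_ratio)
  rows <- lapply(names(axes), function(ax) {
    b <- axes[[ax]]
    if (abs(sum(b$weight) - 1) > 1e-9) {
      stop("unnormalized distribution on axis ", ax, call. = FALSE)
    }
    cum <- cumsum(b$weight)
    loc <- vapply(percentiles / 100, function(p) {
      b$center[which(cum >= p - 1e-12)[1]]
    }, 0)
    data.frame(axis = ax, mean = unname(means[ax]),
               lower = loc[1], upper = loc[2])
  })
  out <- do.call(rbind, rows)
  names(out)[3:4] <- paste0("p", percentiles)
  out
}
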