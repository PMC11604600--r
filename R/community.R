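## Assemblage-level pipeline: relative abundances with confidence intervals,
## moving-average smoothing, conversion of coccolith counts to cell
## proportions via mean coccoliths-per-cell, stacking of abundance-weighted
## morphogroup trait distributions into a community reconstruction, and
## size-class carbon partitioning. "Community" means a fixed standing stock
## of 100 cells: community POC/PIC are pg C per 100 cells, and community
## PIC:POC is independent of the standing stock.

#' Relative abundances with binomial confidence intervals
#'
#' Proportions are count/total; the default 95% interval is the Wald
#' interval `p +/- z * sqrt(p (1 - p) / N)` clamped to `[0, 1]` (degenerate
#' at p = 0 or 1), with Wilson score intervals selectable.
#'
#' @param counts Named non-negative integer vector of counts for one sample.
#' @param conf Confidence level.
#' @param method `"wald"` (default) or `"wilson"`.
#' @return Data frame with `taxon`, `count`, `proportion`, `ci_low`,
#'   `ci_high`.
#' @export
relative_abundance_with_ci <- function(counts, conf = 0.95,
                                       method = c("wald", "wilson")) {
  method <- match.arg(method)
  n <- sum(counts)
  if (n < 1) stop("total count must be >= 1", call. = FALSE)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  p <- counts / n
  z <- qnorm(1 - (1 - conf) / 2)
  if (method == "wald") {
    half <- z * sqrt(p * (1 - p) / n)
    lo <- pmax(0, p - half)
    hi <- pmin(1, p + half)
  } else {
    denom <- 1 + z^2 / n
    mid <- (p + z^2 / (2 * n)) / denom
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
    lo <- pmax(0, mid - half)
    hi <- pmin(1, mid + half)
  }
  data.frame(taxon = names(counts) %||% seq_along(counts), count = as.numeric(counts),
             proportion = as.numeric(p), ci_low = as.numeric(lo),
             ci_high = as.numeric(hi), row.names = NULL)
}

#' Centered moving-average smoothing of abundance series
#'
#' A five-point centered moving average down each taxon's depth-ordered
#' series, with the window truncated symmetrically at the series ends
#' (window 1 at the end points, 3 one step in, ...), so a linear trend is
#' smoothed without bias. Rows (samples) are renormalized to sum to 1
#' afterwards when `renormalize = TRUE`.
#'
#' @param props Samples-by-taxa proportion matrix, rows in depth order.
#' @param window Odd window length (default 5).
#' @param renormalize Renormalize each row across taxa after smoothing.
#' @return Smoothed matrix of the same shape.
#' @export
smooth_abundance <- function(props, window = 5, renormalize = TRUE) {
  props <- as.matrix(props)
  if (window %% 2 != 1 || window < 1) {
    stop("window must be a positive odd integer", call. = FALSE)
  }
  n <- nrow(props)
  half <- (window - 1) / 2
  out <- props
  for (i in seq_len(n)) {
    h <- min(half, i - 1, n - i)
    out[i, ] <- colMeans(props[(i - h):(i + h), , drop = FALSE])
  }
  if (renormalize) {
    rs <- rowSums(out)
    if (any(rs <= 0)) stop("smoothed rows must have positive sums", call. = FALSE)
    out <- out / rs
  }
  out
}

#' Convert relative coccolith abundance to relative cell abundance
#'
#' A taxon shedding many coccoliths per cell is over-represented in loose
#' coccolith counts; dividing each proportion by the morphogroup's mean
#' coccoliths-per-cell and renormalizing recovers cell proportions.
#'
#' @param lith_props Named proportions of coccolith counts over the modeled
#'   morphogroups (renormalized internally to sum to 1).
#' @param mean_cn Named mean coccoliths-per-cell, one per morphogroup present.
#' @return Named cell proportions summing to 1.
#' @export
coccolith_to_cell_abundance <- function(lith_props, mean_cn) {
  nm <- names(lith_props)
  if (is.null(nm)) stop("lith_props must be named", call. = FALSE)
  missing <- setdiff(nm[lith_props > 0], names(mean_cn))
  if (length(missing)) {
    stop("configuration error: no mean coccoliths-per-cell for ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(mean_cn[names(mean_cn) %in% nm] <= 0)) {
    stop("mean coccoliths-per-cell must be > 0", call. = FALSE)
  }
  s <- sum(lith_props)
  if (s <= 0) stop("lith proportions must have a positive sum", call. = FALSE)
  p <- lith_props / s
  cells <- p / as.numeric(mean_cn[nm])
  cells / sum(cells)
}

#' Stack morphogroup trait distributions into a community reconstruction
#'
#' The community size distribution is the cell-proportion-weighted mixture
#' of the morphogroup size distributions; POC and PIC per size bin are the
#' standing stock times the mixture of each morphogroup's per-bin carbon
#' content (bin weight times conditional mean carbon). Community PIC:POC is
#' total PIC over total POC.
#'
#' @param dists Named list of [morphogroup_trait_distribution()] results.
#' @param cell_props Named cell proportions summing to 1; every positive
#'   entry must have a distribution in `dists`.
#' @param standing_stock Cells in the accounting community (default 100).
#' @param sample_id,age Optional labels.
#' @return A `community_reconstruction`: `size_structure` (data frame with
#'   bin `center`, cell fraction `weight`, `poc` and `pic` in pg C per
#'   standing stock), `cell_proportions`, `mean_community_size` (on bin
#'   centers), `total_poc`, `total_pic`, `community_pic_poc`.
#' @export
stack_community <- function(dists, cell_props, standing_stock = 100,
                            sample_id = NA_character_, age = NA_real_) {
  cell_props <- cell_props[cell_props > 0]
  if (abs(sum(cell_props) - 1) > 1e-9) {
    stop("cell proportions must sum to 1", call. = FALSE)
  }
  missing <- setdiff(names(cell_props), names(dists))
  if (length(missing)) {
    stop("configuration error: no trait distribution for ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  centers <- sort(unique(unlist(lapply(dists[names(cell_props)],
                                       function(d) d$size_bins$center))))
  weight <- poc <- pic <- numeric(length(centers))
  for (mg in names(cell_props)) {
    b <- dists[[mg]]$size_bins
    idx <- match(b$center, centers)
    weight[idx] <- weight[idx] + cell_props[mg] * b$weight
    poc[idx] <- poc[idx] + cell_props[mg] * b$weight * b$mean_poc
    pic[idx] <- pic[idx] + cell_props[mg] * b$weight * b$mean_pic
  }
  poc <- standing_stock * poc
  pic <- standing_stock * pic
  structure(list(
    sample_id = sample_id, age = age,
    cell_proportions = cell_props,
    standing_stock = standing_stock,
    size_structure = data.frame(center = centers, weight = weight,
                                poc = poc, pic = pic),
    mean_community_size = sum(weight * centers),
    total_poc = sum(poc), total_pic = sum(pic),
    community_pic_poc = sum(pic) / sum(poc)
  ), class = "community_reconstruction")
}

#' @export
print.community_reconstruction <- function(x, ...) {
  cat(sprintf(
    "Community reconstruction%s%s: mean size %.2f um, POC %.0f pg C, PIC %.0f pg C per %d cells, PIC:POC %.2f\n",
    if (is.na(x$sample_id)) "" else paste0(" ", x$sample_id),
    if (is.na(x$age)) "" else sprintf(" (%.2f Ma)", x$age),
    x$mean_community_size, x$total_poc, x$total_pic, x$standing_stock,
    x$community_pic_poc))
  invisible(x)
}

#' Partition a community reconstruction into cell-size classes
#'
#' Percentages of cells, total POC and total PIC falling in each size class
#' (default edges 2, 5, 8, 11, 15, 20 um), plus the class PIC:POC. Cells
#' outside the edge span are tracked in explicit overflow classes so the
#' percentages sum to 100.
#'
#' @param recon A [stack_community()] result.
#' @param edges Strictly increasing size-class edges, um. Class membership
#'   is half-open `[lower, upper)` on bin centers.
#' @return Data frame with one row per class (overflow classes included):
#'   `class`, `lower`, `upper`, `pct_cells`, `pct_poc`, `pct_pic`,
#'   `pic_poc` (NA for empty classes).
#' @export
partition_size_classes <- function(recon, edges = c(2, 5, 8, 11, 15, 20)) {
  stopifnot(inherits(recon, "community_reconstruction"))
  if (any(diff(edges) <= 0)) {
    stop("configuration error: edges must be strictly increasing",
         call. = FALSE)
  }
  ss <- recon$size_structure
  lower <- c(-Inf, edges)
  upper <- c(edges, Inf)
  labels <- c(paste0("<", edges[1]),
              paste0(edges[-length(edges)], "-", edges[-1]),
              paste0(">=", edges[length(edges)]))
  cls <- findInterval(ss$center, edges) + 1L
  agg <- function(v) vapply(seq_along(labels), function(k) sum(v[cls == k]), 0)
  cells <- agg(ss$weight); poc <- agg(ss$poc); pic <- agg(ss$pic)
  data.frame(
    class = labels, lower = lower, upper = upper,
    pct_cells = 100 * cells / sum(ss$weight),
    pct_poc = 100 * poc / sum(ss$poc),
    pct_pic = 100 * pic / sum(ss$pic),
    pic_poc = ifelse(poc > 0, pic / poc, NA_real_)
  )
}

#' Cold / eutrophic taxon percentage index
#'
#' Summed percentage abundance of an indicator taxon list, with interval
#' labels: "cooler" above 30% cold taxa, "warmer" below 10%, otherwise
#' "intermediate".
#'
#' @param props Named proportions (summing to at most 1).
#' @param taxa Indicator taxa; unknown names warn and contribute 0.
#' @param thresholds `(cooler, warmer)` proportions (default 0.30, 0.10).
#' @return List with `index_pct` and `label`.
#' @export
ecological_index <- function(props,
                             taxa = c("Chiasmolithus", "R. daviesii",
                                      "Cl. subdistichus"),
                             thresholds = c(0.30, 0.10)) {
  if (sum(props) > 1 + 1e-9) stop("proportions must sum to <= 1", call. = FALSE)
  unknown <- setdiff(taxa, names(props))
  if (length(unknown)) {
    warning("unknown taxa treated as absent: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  idx <- 100 * sum(props[intersect(taxa, names(props))])
  label <- if (idx > 100 * thresholds[1]) "cooler"
           else if (idx < 100 * thresholds[2]) "warmer"
           else "intermediate"
  list(index_pct = idx, label = label)
}

.total_per_stock <- function(x) {
  if (inherits(x, "community_reconstruction")) {
    list(poc = x$total_poc, pic = x$total_pic, stock = x$standing_stock)
  } else {
    list(poc = x$total_poc, pic = x$total_pic,
         stock = x$standing_stock %||% 100)
  }
}

#' Hypothetical standing-stock scenarios
#'
#' Scales two community reconstructions (pg C per accounting standing stock)
#' to assumed absolute standing stocks (cells per mL) and reports total POC
#' and PIC per mL, integer-rounded percent changes, and - when a fixed
#' carbon budget is supplied - the standing stock that budget would sustain
#' given scenario B's mean cellular POC.
#'
#' @param recon_a,recon_b Community reconstructions (or lists with
#'   `total_poc`, `total_pic`, `standing_stock`).
#' @param stock_a,stock_b Standing stocks, cells per mL (> 0).
#' @param poc_budget Optional fixed community POC budget, pg C per mL.
#' @return List with per-scenario totals (`poc_a`, `pic_a`, `poc_b`,
#'   `pic_b`, pg C per mL), percent changes (`poc_change_pct`,
#'   `pic_change_pct`, `stock_change_pct`, rounded to integers), and
#'   `implied_stock` when `poc_budget` is given.
#' @export
scenario_totals <- function(recon_a, recon_b, stock_a, stock_b,
                            poc_budget = NULL) {
  if (stock_a <= 0 || stock_b <= 0) {
    stop("standing stocks must be > 0", call. = FALSE)
  }
  a <- .total_per_stock(recon_a); b <- .total_per_stock(recon_b)
  poc_a <- stock_a * a$poc / a$stock
  pic_a <- stock_a * a$pic / a$stock
  poc_b <- stock_b * b$poc / b$stock
  pic_b <- stock_b * b$pic / b$stock
  out <- list(
    poc_a = poc_a, pic_a = pic_a, poc_b = poc_b, pic_b = pic_b,
    poc_change_pct = round(100 * (poc_b / poc_a - 1)),
    pic_change_pct = round(100 * (pic_b / pic_a - 1)),
    stock_change_pct = round(100 * (stock_b / stock_a - 1))
  )
  if (!is.null(poc_budget)) {
    if (poc_budget <= 0) stop("poc_budget must be > 0", call. = FALSE)
    out$implied_stock <- poc_budget / (b$poc / b$stock)
  }
  out
}
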