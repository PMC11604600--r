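## Cell-size model. Placolith-bearing morphogroups: intact fossil
## coccospheres constrain a log-log allometry between coccolith length and
## cell surface area per coccolith, which is inverted to predict cell
## diameter for any (coccolith length, coccoliths-per-cell) combination.
## Nannolith/holococcolith morphogroups lack intact coccospheres and use a
## coverage-factor parameterization of the same surface-area budget instead.
## Cell surface area is that of a sphere of diameter Theta (SA = pi Theta^2).

#' Fit the placolith coccosphere allometry
#'
#' Ordinary least squares of log10(coccolith length) on log10(cell surface
#' area / coccoliths per cell), with cell surface area taken as that of a
#' sphere of the measured internal (cell) diameter. The slope `alpha` and
#' intercept `beta` parameterize the cell-size model that is later inverted
#' by [cell_diameter_placolith()].
#'
#' @param records Coccosphere geometry table (see
#'   [validate_coccosphere_table()]), typically one morphogroup.
#' @return An `allometry_fit`: `alpha`, `beta`, `n_spheres`, the residual
#'   standard error `sigma`, and 95% confidence intervals `alpha_ci`,
#'   `beta_ci`.
#' @export
fit_loglog_regression <- function(records) {
  records <- validate_coccosphere_table(records)
  x <- log10(pi * records$cell_diameter^2 / records$coccolith_count)
  y <- log10(records$coccolith_length)
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3) {
    stop("insufficient data: need >= 3 usable coccospheres", call. = FALSE)
  }
  x <- x[ok]; y <- y[ok]
  if (diff(range(x)) < 1e-12) {
    stop("degenerate fit: zero variance in cell surface area per coccolith",
         call. = FALSE)
  }
  fit <- lm(y ~ x)
  # summary.lm and confint warn on an exactly collinear (noise-free) fit;
  # the point estimates and intervals are still what we report
  ci <- suppressWarnings(confint(fit, level = 0.95))
  smry <- suppressWarnings(summary(fit))
  structure(list(
    morphogroup = if (length(unique(records$morphogroup)) == 1)
      records$morphogroup[1] else NA_character_,
    alpha = unname(coef(fit)[2]),
    beta = unname(coef(fit)[1]),
    n_spheres = sum(ok),
    sigma = smry$sigma,
    r_squared = smry$r.squared,
    alpha_ci = unname(ci["x", ]),
    beta_ci = unname(ci["(Intercept)", ])
  ), class = "allometry_fit")
}

#' @export
print.allometry_fit <- function(x, ...) {
  cat(sprintf(
    "Placolith allometry%s: alpha = %.4f [%.4f, %.4f], beta = %.4f [%.4f, %.4f] (n = %d, R2 = %.3f)\n",
    if (is.na(x$morphogroup)) "" else paste0(" (", x$morphogroup, ")"),
    x$alpha, x$alpha_ci[1], x$alpha_ci[2],
    x$beta, x$beta_ci[1], x$beta_ci[2], x$n_spheres, x$r_squared))
  invisible(x)
}

#' Cell diameter from the placolith allometry
#'
#' Inverts the fitted regression: the cell surface area implied by a
#' coccolith of length `cl` is `cn * 10^((log10(cl) - beta)/alpha)`, and the
#' cell diameter is that of a sphere with this surface area,
#' `Theta = 2 * sqrt(SA / (4*pi))`.
#'
#' @param cl Coccolith length, um (> 0).
#' @param cn Coccoliths per cell (>= 1).
#' @param params An `allometry_fit` or any list with `alpha` and `beta`.
#' @return Cell diameter Theta, um.
#' @export
cell_diameter_placolith <- function(cl, cn, params) {
  alpha <- params$alpha; beta <- params$beta
  if (!is.finite(alpha) || alpha == 0 || !is.finite(beta)) {
    stop("invalid allometry parameters", call. = FALSE)
  }
  if (any(cl <= 0) || any(cn < 1)) {
    stop("coccolith length must be > 0 and coccolith count >= 1",
         call. = FALSE)
  }
  sa <- cn * 10^((log10(cl) - beta) / alpha)
  2 * sqrt(sa / (4 * pi))
}

#' Cell diameter for nannolith / holococcolith morphogroups
#'
#' The cell surface area is the summed coccolith area scaled by the coverage
#' factor: `SA = cn * (pi/4) * clp * (clp/ar) * c_o`, each lith an ellipse of
#' length `clp` (proximal-shield/base length) and width `clp/ar`. The cell
#' diameter reduces to `Theta = (clp/2) * sqrt(c_o * cn / ar)`.
#'
#' A coverage factor below one models overlapping liths (e.g. `c_o = 0.8`
#' imposes a 20% reduction of the summed coccolith area); above one it
#' accounts for gaps between abutting liths.
#'
#' @param clp Coccolith proximal-shield (base) length, um.
#' @param ar Coccolith aspect ratio (mean length / mean width), >= 1.
#' @param cn Coccoliths per cell (>= 1).
#' @param c_o Coverage factor, > 0.
#' @return Cell diameter Theta, um.
#' @export
cell_diameter_nonplacolith <- function(clp, ar, cn, c_o) {
  if (any(clp <= 0) || any(ar <= 0) || any(cn < 1) || any(c_o <= 0)) {
    stop("all inputs must be positive (cn >= 1)", call. = FALSE)
  }
  (clp / 2) * sqrt(c_o * cn / ar)
}

#' Coccoliths-per-cell histogram
#'
#' A normalized frequency distribution over integer coccoliths-per-cell.
#'
#' @param cn Integer bin values.
#' @param freq Relative frequencies (will be checked to sum to 1).
#' @param morphogroup Optional label.
#' @return A `cn_histogram` data frame with columns `cn`, `freq`.
#' @export
cn_histogram <- function(cn, freq, morphogroup = NA_character_) {
  if (length(cn) != length(freq) || !length(cn)) {
    stop("cn and freq must be non-empty and the same length", call. = FALSE)
  }
  if (any(cn < 1) || any(cn != round(cn))) {
    stop("cn values must be integers >= 1", call. = FALSE)
  }
  if (any(freq < 0) || abs(sum(freq) - 1) > 1e-9) {
    stop("frequencies must be >= 0 and sum to 1", call. = FALSE)
  }
  ord <- order(cn)
  structure(data.frame(cn = as.integer(cn[ord]), freq = freq[ord]),
            class = c("cn_histogram", "data.frame"),
            morphogroup = morphogroup)
}

#' Empirical coccoliths-per-cell histogram from coccosphere records
#'
#' @param records Coccosphere geometry table (one morphogroup).
#' @return A [cn_histogram()] of within-group counts.
#' @export
empirical_cn_histogram <- function(records) {
  records <- validate_coccosphere_table(records)
  if (!nrow(records)) stop("insufficient data: no coccospheres", call. = FALSE)
  tab <- table(records$coccolith_count)
  cn_histogram(as.integer(names(tab)), as.numeric(tab) / sum(tab),
               morphogroup = if (length(unique(records$morphogroup)) == 1)
                 records$morphogroup[1] else NA_character_)
}

#' Simulate a coccoliths-per-cell distribution
#'
#' For morphogroups without intact-coccosphere observations, an artificial
#' coccoliths-per-cell dataset is simulated as Gaussian draws (given mean and
#' standard deviation), rounded to the nearest integer and redrawn while
#' outside the admissible range (truncation by rejection, so no probability
#' mass piles on the bounds).
#'
#' @param params Parameter entry with `cn_mean`, `cn_sd`, `cn_range`.
#' @param n_draws Number of simulated cells (>= 1).
#' @param seed Optional integer seed for reproducibility.
#' @return A [cn_histogram()].
#' @export
simulate_cn_distribution <- function(params, n_draws = 10000, seed = NULL) {
  r <- params$cn_range
  mu <- params$cn_mean
  sd <- params$cn_sd
  if (is.null(r) || is.null(mu) || is.null(sd) || sd <= 0) {
    stop("params must provide cn_mean, cn_sd > 0 and cn_range", call. = FALSE)
  }
  if (n_draws < 1) stop("n_draws must be >= 1", call. = FALSE)
  mass <- pnorm(r[2] + 0.5, mu, sd) - pnorm(r[1] - 0.5, mu, sd)
  if (mass < 1e-12) {
    stop("configuration error: cn_range [", r[1], ", ", r[2],
         "] admits no mass under Normal(", mu, ", ", sd, ")", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  draws <- integer(0)
  while (length(draws) < n_draws) {
    cand <- round(rnorm(ceiling((n_draws - length(draws)) / mass * 1.1) + 16,
                        mu, sd))
    draws <- c(draws, cand[cand >= r[1] & cand <= r[2]])
  }
  draws <- draws[seq_len(n_draws)]
  tab <- table(draws)
  cn_histogram(as.integer(names(tab)), as.numeric(tab) / n_draws,
               morphogroup = params$morphogroup %||% NA_character_)
}

#' Exact truncated-rounded-normal coccoliths-per-cell probabilities
#'
#' The analytic counterpart of [simulate_cn_distribution()]: the probability
#' of integer `k` is the Normal mass on `[k - 0.5, k + 0.5)` renormalized
#' over the admissible range. Used as generator-side ground truth.
#'
#' @inheritParams simulate_cn_distribution
#' @return A [cn_histogram()].
#' @export
exact_cn_distribution <- function(params) {
  r <- params$cn_range
  k <- seq(r[1], r[2])
  p <- pnorm(k + 0.5, params$cn_mean, params$cn_sd) -
    pnorm(k - 0.5, params$cn_mean, params$cn_sd)
  if (sum(p) < 1e-12) {
    stop("configuration error: cn_range admits no mass", call. = FALSE)
  }
  cn_histogram(k, p / sum(p), morphogroup = params$morphogroup %||% NA_character_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
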