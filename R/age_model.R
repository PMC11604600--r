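#' Age-depth model with linear sedimentation between tie points
#'
#' Ages are interpolated piecewise-linearly between the tie points (a
#' constant sedimentation rate within each interval), with no extrapolation
#' beyond the outermost datums. Depths are on the composite splice (m-CCSF),
#' ages in Ma.
#'
#' @param depth Tie-point depths, m-CCSF.
#' @param age Tie-point ages, Ma.
#' @return An object of class `age_model`.
#' @export
age_model <- function(depth, age) {
  if (length(depth) != length(age) || length(depth) < 2) {
    stop("need >= 2 (depth, age) tie points", call. = FALSE)
  }
  ord <- order(depth)
  depth <- as.numeric(depth[ord])
  age <- as.numeric(age[ord])
  if (anyNA(depth) || anyNA(age)) stop("tie points must be finite", call. = FALSE)
  if (any(diff(depth) <= 0)) {
    stop("tie-point depths must be strictly monotone", call. = FALSE)
  }
  if (any(diff(age) <= 0)) {
    stop("tie-point ages must be strictly monotone in depth", call. = FALSE)
  }
  structure(list(depth = depth, age = age), class = "age_model")
}

#' @export
print.age_model <- function(x, ...) {
  cat("Age-depth model:", length(x$depth), "tie points,",
      sprintf("%.3f-%.3f m-CCSF, %.3f-%.3f Ma\n",
              min(x$depth), max(x$depth), min(x$age), max(x$age)))
  invisible(x)
}

#' Interpolate age at depth
#'
#' @param model An [age_model()].
#' @param depth Depths (m-CCSF) within the tie-point span; out-of-range
#'   depths are an error (no extrapolation).
#' @return Ages in Ma; exact at tie points.
#' @export
age_from_depth <- function(model, depth) {
  stopifnot(inherits(model, "age_model"))
  if (any(depth < min(model$depth) - 1e-12 | depth > max(model$depth) + 1e-12)) {
    stop("depth outside the tie-point range [", min(model$depth), ", ",
         max(model$depth), "] m-CCSF; no extrapolation", call. = FALSE)
  }
  approx(model$depth, model$age, xout = depth, method = "linear",
         ties = "ordered")$y
}

#' Per-interval sedimentation rates
#'
#' @param model An [age_model()].
#' @return Data frame with one row per tie-point interval: top/bottom depth,
#'   top/bottom age and the linear sedimentation rate in m/Myr.
#' @export
sedimentation_rate <- function(model) {
  stopifnot(inherits(model, "age_model"))
  n <- length(model$depth)
  data.frame(
    depth_top = model$depth[-n], depth_bottom = model$depth[-1],
    age_top = model$age[-n], age_bottom = model$age[-1],
    rate_m_per_myr = diff(model$depth) / diff(model$age)
  )
}
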