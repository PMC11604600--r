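#' Morphogroup parameter registry
#'
#' Model constants for the ten latest Eocene--Oligocene morphogroups. Each
#' entry carries the cell-size mode ("placolith" groups use the fitted
#' log-log allometry; "nonplacolith" groups use the coverage-factor
#' parameterization), the allometry slope/intercept (`alpha`, `beta`), the
#' coverage factor `c_o` and coccolith aspect ratio `ar`, the
#' coccoliths-per-cell simulation settings (`cn_mean`, `cn_sd`, `cn_range`),
#' the calcite shape factor `ks` with the coccolith dimension it applies to,
#' and `pic_dim_scale`, the multiplier taking the measured coccolith length
#' to that dimension (0.5 for *Discoaster*, whose ray length is half the
#' circumscribing-circle diameter; the mean height:base ratio for
#' *Z. bijugatus*, whose shape factor applies to lith height).
#'
#' `pooled_sizes` marks rare groups whose coccolith-length measurements are
#' pooled across samples into a single dataset.
#'
#' @param morphogroup Optional label; if given, return that single entry.
#' @return A named list of parameter entries (or one entry).
#' @export
default_morphogroup_params <- function(morphogroup = NULL) {
  placolith <- function(name, alpha, beta, ks, cn_mean, cn_sd, cn_range) {
    list(morphogroup = name, mode = "placolith",
         alpha = alpha, beta = beta,
         c_o = NA_real_, ar = NA_real_,
         cn_mean = cn_mean, cn_sd = cn_sd, cn_range = cn_range,
         ks = ks, ks_dimension = "distal shield length",
         pic_dim_scale = 1, pooled_sizes = FALSE)
  }
  nonplacolith <- function(name, c_o, ar, cn_mean, cn_sd, cn_range,
                           ks, ks_dimension, pic_dim_scale) {
    list(morphogroup = name, mode = "nonplacolith",
         alpha = NA_real_, beta = NA_real_,
         c_o = c_o, ar = ar,
         cn_mean = cn_mean, cn_sd = cn_sd, cn_range = cn_range,
         ks = ks, ks_dimension = ks_dimension,
         pic_dim_scale = pic_dim_scale, pooled_sizes = TRUE)
  }
  reg <- list(
    `Chiasmolithus`       = placolith("Chiasmolithus",       0.478,  0.151, 0.060,  8, 2.0, c(4, 14)),
    `Coccolithus`         = placolith("Coccolithus",         0.623, -0.122, 0.060, 14, 3.0, c(7, 22)),
    `Clausicoccus`        = placolith("Clausicoccus",        0.513, -0.025, 0.050, 12, 2.5, c(6, 19)),
    `Cyclicargolithus`    = placolith("Cyclicargolithus",    0.441,  0.275, 0.080, 16, 3.0, c(8, 25)),
    `R. bisecta group`    = placolith("R. bisecta group",    0.574,  0.052, 0.070, 14, 3.0, c(7, 22)),
    `R. lockeri group`    = placolith("R. lockeri group",    0.574,  0.052, 0.050, 12, 2.5, c(6, 19)),
    `R. umbilicus group`  = placolith("R. umbilicus group",  0.574,  0.052, 0.045, 14, 3.0, c(7, 22)),
    `Sphenolithus`        = nonplacolith("Sphenolithus",  1.18, 1.00, 42.5, (60 - 27) / 6, c(27, 60),
                                         0.050, "base length", 1),
    `Discoaster`          = nonplacolith("Discoaster",    0.80, 1.00, 20.0, (31 - 10) / 6, c(10, 31),
                                         0.220, "ray length", 0.5),
    `Z. bijugatus`        = nonplacolith("Z. bijugatus",  1.13, 1.25, 22.0, (37 - 9) / 6, c(9, 37),
                                         0.400, "lith height", 0.7)
  )
  if (is.null(morphogroup)) return(reg)
  if (!morphogroup %in% names(reg)) {
    stop("unknown morphogroup: ", morphogroup, call. = FALSE)
  }
  reg[[morphogroup]]
}

.ks_dimension_kinds <- c("distal shield length", "base length",
                         "ray length", "lith height")

validate_morphogroup_params <- function(p) {
  stopifnot(is.list(p), !is.null(p$morphogroup), !is.null(p$mode))
  if (!p$mode %in% c("placolith", "nonplacolith")) {
    stop("mode must be 'placolith' or 'nonplacolith' for ", p$morphogroup,
         call. = FALSE)
  }
  if (p$mode == "placolith") {
    if (!is.finite(p$alpha) || p$alpha == 0 || !is.finite(p$beta)) {
      stop("placolith entry '", p$morphogroup,
           "' needs finite alpha (non-zero) and beta", call. = FALSE)
    }
  } else {
    if (!is.finite(p$c_o) || p$c_o <= 0) {
      stop("nonplacolith entry '", p$morphogroup, "' needs c_o > 0",
           call. = FALSE)
    }
    if (!is.finite(p$ar) || p$ar < 1) {
      stop("nonplacolith entry '", p$morphogroup, "' needs aspect ratio >= 1",
           call. = FALSE)
    }
  }
  if (!is.null(p$cn_range)) {
    r <- p$cn_range
    if (length(r) != 2 || r[1] < 1 || r[1] >= r[2]) {
      stop("cn_range for '", p$morphogroup,
           "' must be (min, max) with 1 <= min < max", call. = FALSE)
    }
    if (!is.null(p$cn_mean) && (p$cn_mean < r[1] || p$cn_mean > r[2])) {
      stop("cn_mean for '", p$morphogroup, "' must lie within cn_range",
           call. = FALSE)
    }
  }
  if (!is.null(p$ks)) {
    if (!is.finite(p$ks) || p$ks <= 0) {
      stop("ks for '", p$morphogroup, "' must be > 0", call. = FALSE)
    }
    if (!p$ks_dimension %in% .ks_dimension_kinds) {
      stop("ks_dimension for '", p$morphogroup, "' must be one of: ",
           paste(.ks_dimension_kinds, collapse = ", "), call. = FALSE)
    }
  }
  invisible(p)
}

#' Read / write a morphogroup parameter registry (JSON)
#'
#' @param path File path.
#' @return `read_param_registry` returns a validated named list of entries.
#' @export
read_param_registry <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  reg <- lapply(raw, function(p) {
    p$cn_range <- as.numeric(unlist(p$cn_range))
    for (f in c("alpha", "beta", "c_o", "ar", "cn_mean", "cn_sd", "ks",
                "pic_dim_scale")) {
      p[[f]] <- if (is.null(p[[f]])) NA_real_ else as.numeric(p[[f]])
    }
    validate_morphogroup_params(p)
    p
  })
  names(reg) <- vapply(reg, `[[`, "", "morphogroup")
  reg
}

#' @rdname read_param_registry
#' @param registry Named list of parameter entries.
#' @export
write_param_registry <- function(registry, path) {
  lapply(registry, validate_morphogroup_params)
  jsonlite::write_json(registry, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}
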