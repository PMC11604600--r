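## Delimited-text table IO for the three dataset kinds the pipeline consumes:
## coccosphere geometry (one coccosphere per row), loose coccolith lengths
## (long format, one measurement per row) and assemblage counts (long format,
## one taxon count per row). All tables are comma-delimited UTF-8 with a
## single header row and "." as the decimal separator.

.require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop("schema error in '", path, "': missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
}

.check_numeric <- function(x, col, path) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(v) & !is.na(x))
  if (length(bad)) {
    stop("row ", bad[1], " of '", path, "': non-numeric value in column '",
         col, "'", call. = FALSE)
  }
  if (anyNA(v)) {
    stop("row ", which(is.na(v))[1], " of '", path, "': missing value in '",
         col, "'", call. = FALSE)
  }
  v
}

#' Validate a coccosphere geometry table
#'
#' Each row is one measured intact fossil coccosphere: morphogroup label,
#' coccolith length (um), number of coccoliths per cell, coccosphere
#' (external) diameter and cell (internal) diameter, both um. Invariants:
#' positive lengths, integer coccolith count >= 1, and coccosphere diameter
#' at least the cell diameter (the coccolith layer adds to it).
#'
#' @param df Data frame to validate.
#' @param path Label used in error messages.
#' @return The validated data frame, invisibly reordered to canonical columns.
#' @export
validate_coccosphere_table <- function(df, path = "coccosphere table") {
  cols <- c("morphogroup", "coccolith_length", "coccolith_count",
            "coccosphere_diameter", "cell_diameter")
  .require_columns(df, cols, path)
  for (col in cols[-1]) df[[col]] <- .check_numeric(df[[col]], col, path)
  bad_row <- function(cond, msg) {
    i <- which(cond)
    if (length(i)) stop("row ", i[1], " of '", path, "': ", msg, call. = FALSE)
  }
  bad_row(df$coccolith_length <= 0, "coccolith_length must be > 0")
  bad_row(df$coccolith_count < 1 |
            df$coccolith_count != round(df$coccolith_count),
          "coccolith_count must be an integer >= 1")
  bad_row(df$cell_diameter <= 0, "cell_diameter must be > 0")
  bad_row(df$coccosphere_diameter < df$cell_diameter,
          "coccosphere_diameter must be >= cell_diameter")
  if (!"source_sample" %in% names(df)) df$source_sample <- NA_character_
  df[, c(cols, "source_sample")]
}

#' Read / write coccosphere geometry tables
#' @param path CSV file path.
#' @return `read_coccosphere_table` returns the validated data frame with row
#'   order preserved.
#' @export
read_coccosphere_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  validate_coccosphere_table(read.csv(path, stringsAsFactors = FALSE), path)
}

#' @rdname read_coccosphere_table
#' @param df Coccosphere table.
#' @export
write_coccosphere_table <- function(df, path) {
  df <- validate_coccosphere_table(df)
  write.csv(df, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Validate a loose coccolith length table (long format)
#'
#' One measurement per row: `sample_id`, `morphogroup`, `coccolith_length`
#' (um, > 0).
#' @inheritParams validate_coccosphere_table
#' @export
validate_lith_size_table <- function(df, path = "lith size table") {
  .require_columns(df, c("sample_id", "morphogroup", "coccolith_length"), path)
  df$coccolith_length <- .check_numeric(df$coccolith_length,
                                        "coccolith_length", path)
  i <- which(df$coccolith_length <= 0)
  if (length(i)) {
    stop("row ", i[1], " of '", path, "': coccolith_length must be > 0",
         call. = FALSE)
  }
  df[, c("sample_id", "morphogroup", "coccolith_length")]
}

#' @rdname validate_lith_size_table
#' @export
read_lith_size_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  validate_lith_size_table(read.csv(path, stringsAsFactors = FALSE), path)
}

#' @rdname validate_lith_size_table
#' @export
write_lith_size_table <- function(df, path) {
  df <- validate_lith_size_table(df)
  write.csv(df, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Group a long lith-size table into per-(sample, morphogroup) records
#'
#' @param df Validated lith-size table.
#' @return List of records with `sample_id`, `morphogroup`, `lengths`.
#' @export
lith_size_samples <- function(df) {
  df <- validate_lith_size_table(df)
  key <- interaction(df$sample_id, df$morphogroup, drop = TRUE, sep = "\r")
  lapply(split(df, key), function(d) {
    list(sample_id = d$sample_id[1], morphogroup = d$morphogroup[1],
         lengths = d$coccolith_length)
  })
}

#' Validate an assemblage count table (long format)
#'
#' One taxon count per row: `sample_id`, `depth` (m-CCSF), `taxon`,
#' `count` (non-negative integer). Each sample must total >= 1 identified
#' coccolith and carry a single depth.
#' @inheritParams validate_coccosphere_table
#' @export
validate_assemblage_table <- function(df, path = "assemblage table") {
  .require_columns(df, c("sample_id", "depth", "taxon", "count"), path)
  df$depth <- .check_numeric(df$depth, "depth", path)
  df$count <- .check_numeric(df$count, "count", path)
  i <- which(df$count < 0 | df$count != round(df$count))
  if (length(i)) {
    stop("row ", i[1], " of '", path,
         "': count must be a non-negative integer", call. = FALSE)
  }
  dup <- duplicated(df[, c("sample_id", "taxon")])
  if (any(dup)) {
    stop("row ", which(dup)[1], " of '", path,
         "': duplicate taxon within a sample", call. = FALSE)
  }
  totals <- tapply(df$count, df$sample_id, sum)
  if (any(totals < 1)) {
    stop("sample '", names(totals)[which(totals < 1)[1]],
         "' in '", path, "' has a zero total count", call. = FALSE)
  }
  ndep <- tapply(df$depth, df$sample_id, function(d) length(unique(d)))
  if (any(ndep > 1)) {
    stop("sample '", names(ndep)[which(ndep > 1)[1]], "' in '", path,
         "' has inconsistent depths", call. = FALSE)
  }
  df[, c("sample_id", "depth", "taxon", "count")]
}

#' @rdname validate_assemblage_table
#' @export
read_assemblage_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  validate_assemblage_table(read.csv(path, stringsAsFactors = FALSE), path)
}

#' @rdname validate_assemblage_table
#' @export
write_assemblage_table <- function(df, path) {
  df <- validate_assemblage_table(df)
  write.csv(df, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Pivot an assemblage table to a samples-by-taxa count matrix
#'
#' Rows are ordered by decreasing depth (oldest first); a `depth` attribute
#' carries the per-sample depths in row order.
#'
#' @param df Validated assemblage table.
#' @return Integer matrix with samples as rows, taxa as columns.
#' @export
assemblage_matrix <- function(df) {
  df <- validate_assemblage_table(df)
  samples <- unique(df$sample_id)
  depths <- vapply(samples, function(s) df$depth[df$sample_id == s][1], 0)
  ord <- order(-depths)
  samples <- samples[ord]
  depths <- depths[ord]
  taxa <- unique(df$taxon)
  m <- matrix(0, length(samples), length(taxa),
              dimnames = list(samples, taxa))
  m[cbind(match(df$sample_id, samples), match(df$taxon, taxa))] <- df$count
  attr(m, "depth") <- setNames(depths, samples)
  m
}
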