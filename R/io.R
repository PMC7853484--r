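# Tidy TSV schemas shared by the whole pipeline. One row per observation,
# tab delimiter, UTF-8, "." decimal separator, fixed column order; report
# numerics carry 4 decimal places so outputs are bit-reproducible.

.exine_schemas <- function() {
  list(
    morphology = list(
      cols = c(species_code = "character", species_name = "character",
               family = "character", shape = "character",
               size_category = "character", aperture_min = "integer",
               aperture_max = "integer", source = "character"),
      key = "species_code",
      enums = list(shape = c("saccate", "oblate", "prolate", "spheroidal",
                             "elliptic"),
                   size_category = c("small", "medium", "large")),
      na_ok = "aperture_max",
      min = list(aperture_min = 0)
    ),
    grinding_counts = list(
      cols = c(species_code = "character", bead_size_mm = "numeric",
               replicate_id = "integer", time_s = "numeric",
               intact_count = "integer"),
      key = c("species_code", "bead_size_mm", "replicate_id", "time_s"),
      enums = list(bead_size_mm = c(0.5, 1.4, 2.8, 5.0)),
      min = list(time_s = 0, intact_count = 0)
    ),
    read_counts = list(
      cols = c(marker = "character", treatment_code = "character",
               replicate = "integer", species_code = "character",
               reads = "integer"),
      key = c("marker", "treatment_code", "replicate", "species_code"),
      min = list(reads = 0)
    ),
    kinetics = list(
      cols = c(species_code = "character", bead_size_mm = "numeric",
               model = "character", k = "numeric", rss = "numeric",
               t33 = "numeric", t67 = "numeric", t95 = "numeric",
               t_complete = "numeric", flags = "character"),
      key = c("species_code", "bead_size_mm"),
      na_ok = c("t33", "t67", "t95", "t_complete"),
      min = list(k = 0, rss = 0)
    ),
    rupture_times = list(
      cols = c(species_code = "character", optimal_bead_mm = "numeric",
               t95_s = "numeric"),
      key = "species_code",
      min = list(t95_s = 0)
    ),
    presence = list(
      cols = c(marker = "character", species_code = "character",
               present = "integer"),
      key = c("marker", "species_code"),
      enums = list(present = c(0L, 1L))
    ),
    deviation = list(
      cols = c(marker = "character", treatment_code = "character",
               replicate = "integer", D = "numeric"),
      key = c("marker", "treatment_code", "replicate"),
      na_ok = "D",
      min = list(D = 0)
    ),
    deviation_summary = list(
      cols = c(marker = "character", treatment_code = "character",
               mean_D = "numeric", sd_D = "numeric", n_used = "integer",
               optimal = "integer"),
      key = c("marker", "treatment_code"),
      na_ok = c("mean_D", "sd_D"),
      enums = list(optimal = c(0L, 1L))
    ),
    trends = list(
      cols = c(marker = "character", species_code = "character",
               category = "character"),
      key = c("marker", "species_code"),
      enums = list(category = c("ABOVE_ALL", "BELOW_ALL", "NEAR_ALL",
                                "CONVERGENT", "MIXED"))
    ),
    anova = list(
      cols = c(term = "character", df = "integer", sum_sq = "numeric",
               mean_sq = "numeric", f_value = "numeric", p_value = "numeric"),
      key = "term",
      na_ok = c("f_value", "p_value"),
      min = list(sum_sq = 0)
    )
  )
}

#' Names of the TSV schemas understood by the package
#'
#' @return character vector of schema names usable with [read_exine_table()]
#'   and [write_exine_table()].
#' @export
exine_schemas <- function() names(.exine_schemas())

.get_schema <- function(schema) {
  all <- .exine_schemas()
  if (!schema %in% names(all))
    stop("unknown schema '", schema, "'; see exine_schemas()", call. = FALSE)
  all[[schema]]
}

.validate_table <- function(df, schema, where = "table") {
  sc <- .get_schema(schema)
  missing <- setdiff(names(sc$cols), names(df))
  if (length(missing))
    stop(sprintf("%s: missing column(s) for schema '%s': %s",
                 where, schema, paste(missing, collapse = ", ")),
         call. = FALSE)
  df <- df[names(sc$cols)]
  na_ok <- sc$na_ok %||% character(0)
  for (col in names(sc$cols)) {
    type <- sc$cols[[col]]
    raw <- df[[col]]
    if (type %in% c("numeric", "integer")) {
      val <- suppressWarnings(as.numeric(raw))
      bad <- which(is.na(val) & !(is.na(raw) | raw %in% c("NA", "")))
      if (length(bad))
        stop(sprintf("%s: non-numeric value '%s' in column '%s' at row %d",
                     where, as.character(raw[bad[1]]), col, bad[1]),
             call. = FALSE)
      if (!col %in% na_ok && anyNA(val))
        stop(sprintf("%s: missing value in column '%s' at row %d",
                     where, col, which(is.na(val))[1]), call. = FALSE)
      if (type == "integer") {
        whole <- is.na(val) | val == floor(val)
        if (!all(whole))
          stop(sprintf("%s: non-integer value in column '%s' at row %d",
                       where, col, which(!whole)[1]), call. = FALSE)
        val <- as.integer(round(val))
      }
      df[[col]] <- val
    } else {
      df[[col]] <- as.character(raw)
    }
    lo <- sc$min[[col]]
    if (!is.null(lo)) {
      bad <- which(!is.na(df[[col]]) & df[[col]] < lo)
      if (length(bad))
        stop(sprintf("%s: column '%s' below %s at row %d (value %s)",
                     where, col, format(lo), bad[1],
                     format(df[[col]][bad[1]])), call. = FALSE)
    }
    allowed <- sc$enums[[col]]
    if (!is.null(allowed)) {
      bad <- which(!is.na(df[[col]]) & !df[[col]] %in% allowed)
      if (length(bad))
        stop(sprintf("%s: column '%s' has disallowed value '%s' at row %d",
                     where, col, format(df[[col]][bad[1]]), bad[1]),
             call. = FALSE)
    }
  }
  if (nrow(df) > 0) {
    keys <- do.call(paste, c(df[sc$key], sep = "\r"))
    if (anyDuplicated(keys))
      stop(sprintf("%s: duplicate key (%s) at row %d",
                   where, paste(sc$key, collapse = ", "),
                   which(duplicated(keys))[1]), call. = FALSE)
  }
  rownames(df) <- NULL
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a validated TSV table
#'
#' Reads a tab-separated table and validates it against one of the package
#' schemas: required columns must be present, numeric columns must parse,
#' value constraints (non-negative counts, enumerated categories) must hold
#' and the schema key must be unique. Row order is preserved.
#'
#' @param path path to a TSV file with a header line.
#' @param schema schema name; see [exine_schemas()].
#' @return data.frame with typed columns in schema order.
#' @examples
#' p <- system.file("extdata", "morphology.tsv", package = "exine")
#' head(read_exine_table(p, "morphology"))
#' @export
read_exine_table <- function(path, schema) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, colClasses = "character",
                          check.names = FALSE, fileEncoding = "UTF-8",
                          na.strings = "NA")
  .validate_table(df, schema, where = basename(path))
}

#' Write a validated TSV table
#'
#' Validates against the schema, then writes atomically (temporary file in
#' the same directory, then rename) so a failed run never leaves a
#' truncated table. Non-integer numeric columns are written with 4 decimal
#' places; `read_exine_table()` on the result reproduces any table whose
#' values carry at most 4 decimals.
#'
#' @param df data.frame conforming to the schema.
#' @param path output path.
#' @param schema schema name; see [exine_schemas()].
#' @return `path`, invisibly.
#' @export
write_exine_table <- function(df, path, schema) {
  sc <- .get_schema(schema)
  df <- .validate_table(df, schema, where = "write_exine_table input")
  out <- df
  for (col in names(sc$cols)) {
    if (sc$cols[[col]] == "numeric") {
      v <- out[[col]]
      out[[col]] <- ifelse(is.na(v), "NA", sprintf("%.4f", v))
    }
  }
  tmp <- tempfile(pattern = basename(path), tmpdir = dirname(path))
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  con <- file(tmp, open = "w", encoding = "UTF-8")
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  close(con)
  if (!file.rename(tmp, path))
    stop("cannot write to ", path, call. = FALSE)
  invisible(path)
}
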