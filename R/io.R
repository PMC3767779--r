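# TSV interchange with schema checking, and JSON configuration.

#' Write a table as TSV
#'
#' Tab-separated, header row, no quoting, missing values written as "NA".
#'
#' @param table data.frame
#' @param path output path
#' @return the path, invisibly
#' @export
write_table <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a TSV table with optional schema checking
#'
#' @param path input path
#' @param schema optional named character vector mapping column name to type
#'   ("character", "numeric", "integer", "logical"); extra columns beyond the
#'   schema are allowed only with `exact = FALSE`
#' @param exact require exactly the schema's columns
#' @return data.frame; "NA" cells become missing values, never zeros
#' @export
read_table <- function(path, schema = NULL, exact = FALSE) {
  if (!file.exists(path)) stop_input("input file does not exist: %s", path)
  raw <- utils::read.delim(path, colClasses = "character",
                           check.names = FALSE, na.strings = NULL)
  if (!is.null(schema)) {
    missing_cols <- setdiff(names(schema), colnames(raw))
    extra_cols <- setdiff(colnames(raw), names(schema))
    if (length(missing_cols) || (exact && length(extra_cols)))
      stop_input("schema mismatch in %s: missing [%s]; extra [%s]", path,
                 paste(missing_cols, collapse = ", "),
                 paste(extra_cols, collapse = ", "))
    for (col in names(schema)) raw[[col]] <- convert_column(raw[[col]], schema[[col]], col)
    for (col in extra_cols) raw[[col]] <- convert_column(raw[[col]], "guess", col)
  } else {
    for (col in colnames(raw)) raw[[col]] <- convert_column(raw[[col]], "guess", col)
  }
  raw
}

convert_column <- function(x, type, col) {
  x[x == "NA"] <- NA_character_
  if (type == "guess") {
    num <- suppressWarnings(as.numeric(x))
    if (all(is.na(num) == is.na(x))) return(num)
    if (all(x %in% c("TRUE", "FALSE", NA))) return(as.logical(x))
    return(x)
  }
  if (type == "character") return(x)
  out <- switch(type,
                numeric = suppressWarnings(as.numeric(x)),
                integer = suppressWarnings(as.integer(x)),
                logical = as.logical(x),
                stop_input("unknown schema type '%s'", type))
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad))
    stop_input("column '%s': malformed %s value '%s' at data row %d",
               col, type, x[bad[1]], bad[1])
  out
}

# Schemas of the interchange tables.
DESIGN_SCHEMA <- c(run_id = "character", genotype = "character",
                   condition = "character", bio_replicate = "integer",
                   tech_replicate = "integer", enzyme = "character",
                   scale_factor = "numeric")
BLOT_SCHEMA <- c(lane_id = "character", genotype = "character",
                 condition = "character", timepoint = "numeric",
                 heads_loaded = "numeric", replicate = "integer",
                 membrane_id = "character", phospho_signal = "numeric",
                 total_signal = "numeric")
IP_SCHEMA <- c(site_id = "character", replicate = "integer",
               p_input = "numeric", t_input = "numeric",
               p_ip = "numeric", t_ip = "numeric")
SCREEN_SCHEMA <- c(mutant_id = "character", gene = "character",
                   site_id = "character", condition = "character",
                   stage = "character", replicate = "integer",
                   relative_phospho_pct = "numeric")

#' Read a feature table TSV
#'
#' Metadata columns are typed by the feature-table schema; every remaining
#' column is a numeric per-run abundance ("NA" = not detected).
#'
#' @param path TSV written by [write_table()]
#' @return feature table data.frame
#' @export
read_feature_table <- function(path) {
  meta_schema <- c(feature_id = "character", peptide_sequence = "character",
                   site_id = "character", n_phospho = "integer",
                   site_localized = "logical", charge = "integer",
                   mz = "numeric", rt = "numeric")
  tab <- read_table(path, schema = meta_schema, exact = FALSE)
  for (r in setdiff(colnames(tab), names(meta_schema)))
    tab[[r]] <- convert_column(as.character(tab[[r]]), "numeric", r)
  tab
}

#' Read a run design TSV
#' @param path TSV path
#' @return validated run design data.frame
#' @export
read_run_design <- function(path) {
  validate_run_design(read_table(path, schema = DESIGN_SCHEMA, exact = FALSE))
}
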